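#' Phantom specification
#'
#' Describes a synthetic layered OCT volume with known ground truth.  The
#' phantom emulates the reflectivity relations the segmentation relies on
#' in real swept-source scans: a dark vitreous noise floor, a dim inner
#' retina over a thin hyperreflective RPE band whose base is the choroid
#' inner boundary, a bright choroidal stroma carrying dark vessel lumens
#' (biased towards the deep, large-vessel layer), a moderately reflective
#' sclera crossed by oblique dark SPCA tracks, a global bowl-shaped warp
#' from the curvature of the eye, exponential depth attenuation, and
#' multiplicative speckle.
#'
#' @param dims `(axial, lateral, n_bscans)` (default `c(256, 256, 64)`, a
#'   scale at which the 6 x 6 filtering and the cross-B-scan smoothing
#'   behave as at full scale while a volume segments in seconds).
#' @param lateral_extent_mm physical field size (default 12).
#' @param vitreous_intensity,inner_intensity,rpe_intensity reflectivities
#'   (8-bit) of the vitreous floor, inner retina and RPE band.
#' @param retina_top depth of the inner retinal surface before warping.
#' @param cib depth of the choroid inner boundary (last retinal row,
#'   0-based) before warping.
#' @param rpe_thickness thickness of the bright RPE band ending at `cib`.
#' @param choroid_thickness COB - CIB (px).
#' @param stroma_intensity,lumen_intensity choroidal stroma / vessel-lumen
#'   reflectivities.
#' @param vessel_density expected lumens per lateral pixel per B-scan
#'   (default 0.12).
#' @param vessel_radius_lat,vessel_radius_ax lumen semi-axis ranges
#'   (lateral, axial), px.
#' @param sclera_intensity scleral reflectivity (dimmer than the stroma, as
#'   the signal fades below the interface).
#' @param attenuation_coeff exponential intensity decay per axial pixel
#'   (default 0.005).
#' @param speckle_level variance of the multiplicative mean-1 Gamma speckle
#'   (default 0.15).
#' @param n_spca number of scleral vessel tracks (default 14, within the
#'   histological 10-20 range).
#' @param spca_positions optional n x 2 matrix of en-face entry
#'   coordinates (mm, columns x and y); sampled uniformly away from the
#'   field edge when `NULL`.
#' @param spca_radius_px,spca_intensity,spca_slope,spca_length_px geometry
#'   of the oblique tracks: lateral radius, reflectivity, lateral drift per
#'   axial pixel, and axial extent below the interface.
#' @param curvature amplitude of the bowl warp (px at the field corner).
#' @param seed RNG seed; a fixed seed reproduces the volume bit-exactly.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(axial = 256, lateral = 256, n_bscans = 64),
                         lateral_extent_mm = 12,
                         vitreous_intensity = 35,
                         inner_intensity = 55,
                         rpe_intensity = 240,
                         retina_top = 40,
                         cib = 80,
                         rpe_thickness = 3,
                         choroid_thickness = 50,
                         stroma_intensity = 150,
                         lumen_intensity = 40,
                         vessel_density = 0.12,
                         vessel_radius_lat = c(6, 12),
                         vessel_radius_ax = c(4, 7),
                         sclera_intensity = 70,
                         attenuation_coeff = 0.005,
                         speckle_level = 0.15,
                         n_spca = 14,
                         spca_positions = NULL,
                         spca_radius_px = 2.5,
                         spca_intensity = 20,
                         spca_slope = 0.3,
                         spca_length_px = 60,
                         curvature = 12,
                         seed = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 2)) stop("dims must be 3 values >= 2")
  if (retina_top >= cib || rpe_thickness < 1 || choroid_thickness < 1)
    stop("layer bands must be ordered with positive thickness")
  if (cib + choroid_thickness + curvature >= dims[1])
    stop("bands exceed the axial extent after warping")
  ints <- c(vitreous_intensity, inner_intensity, rpe_intensity,
            stroma_intensity, lumen_intensity, sclera_intensity,
            spca_intensity)
  if (any(ints <= 0 | ints > 255)) stop("reflectivities must lie in (0, 255]")
  if (speckle_level < 0 || vessel_density < 0 || curvature < 0)
    stop("noise, density and curvature must be nonnegative")
  structure(as.list(environment()), class = "phantom_spec")
}

bowl_warp <- function(spec) {
  ny <- spec$dims[2]; nx <- spec$dims[3]
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  r2 <- ((yy - cy) / cy)^2 + ((xx - cx) / cx)^2
  spec$curvature * r2 / 2      # 0 at centre, `curvature` at the corners
}

#' Generate a synthetic OCT phantom
#'
#' Builds the layered reflectivity volume described by a [phantom_spec()],
#' applies the bowl warp, depth attenuation and multiplicative speckle,
#' quantizes to 8 bits, and returns the volume together with the exact
#' ground truth (CIB/COB surfaces in the representation the detector
#' emits, and the planted SPCA entry marks).
#'
#' @param spec a [phantom_spec()].
#' @param layer_masks set `TRUE` to also return an integer array labelling
#'   each voxel's layer (1 vitreous, 2 inner retina, 3 RPE, 4 choroid
#'   stroma, 5 lumen, 6 sclera, 7 SPCA track).
#' @return list with `volume` ([oct_volume()]) and `truth` (list with
#'   `cib_true`, `cob_true` as final [boundary_surface()]s,
#'   `spca_marks_true` as [vessel_marks()], and optionally `layers`).
#' @export
generate_phantom <- function(spec = phantom_spec(), layer_masks = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nz <- spec$dims[1]; ny <- spec$dims[2]; nx <- spec$dims[3]
  warp <- bowl_warp(spec)
  cib_true <- spec$cib + warp
  cob_true <- cib_true + spec$choroid_thickness

  # SPCA entry positions (mm; x = B-scan axis, y = lateral axis)
  ext <- spec$lateral_extent_mm
  pos <- spec$spca_positions
  if (is.null(pos)) {
    pos <- cbind(x_mm = runif(spec$n_spca, 1.5, ext - 1.5),
                 y_mm = runif(spec$n_spca, 1.5, ext - 1.5))
  } else {
    pos <- as.matrix(pos)
    if (nrow(pos) != spec$n_spca) stop("spca_positions must have n_spca rows")
  }
  spca_dir <- matrix(rnorm(spec$n_spca * 2), ncol = 2)
  spca_dir <- spca_dir / sqrt(rowSums(spca_dir^2))

  vol <- array(0, dim = c(nz, ny, nx))
  layers <- if (layer_masks) array(0L, dim = c(nz, ny, nx)) else NULL
  zcol <- 0:(nz - 1)
  px_y <- ny / ext            # lateral pixels per mm
  px_x <- nx / ext            # B-scan pixels per mm
  n_vessels <- round(spec$vessel_density * ny)

  for (x in seq_len(nx)) {
    ct <- cib_true[, x]; ot <- cob_true[, x]; rt <- spec$retina_top + warp[, x]
    sl <- matrix(spec$vitreous_intensity, nz, ny)
    lay <- matrix(1L, nz, ny)
    zm <- matrix(zcol, nz, ny)
    rtm <- matrix(rt, nz, ny, byrow = TRUE)
    cim <- matrix(ct, nz, ny, byrow = TRUE)
    com <- matrix(ot, nz, ny, byrow = TRUE)
    inner <- zm >= rtm & zm <= cim - spec$rpe_thickness
    rpe <- zm > cim - spec$rpe_thickness & zm <= cim
    chor <- zm > cim & zm <= com
    scler <- zm > com
    sl[inner] <- spec$inner_intensity; lay[inner] <- 2L
    sl[rpe] <- spec$rpe_intensity;     lay[rpe] <- 3L
    sl[chor] <- spec$stroma_intensity; lay[chor] <- 4L
    sl[scler] <- spec$sclera_intensity; lay[scler] <- 6L

    # choroidal vessel lumens, biased to the deep (large-vessel) layer
    if (n_vessels > 0) {
      cy <- sample.int(ny, n_vessels, replace = TRUE)
      frac <- runif(n_vessels, 0.35, 0.85)
      a <- runif(n_vessels, spec$vessel_radius_lat[1], spec$vessel_radius_lat[2])
      b <- runif(n_vessels, spec$vessel_radius_ax[1], spec$vessel_radius_ax[2])
      yy <- matrix(seq_len(ny), nz, ny, byrow = TRUE)
      for (v in seq_len(n_vessels)) {
        cz <- ct[cy[v]] + frac[v] * spec$choroid_thickness
        lum <- ((yy - cy[v]) / a[v])^2 + ((zm - cz) / b[v])^2 <= 1
        lum <- lum & zm > cim & zm <= com - 2   # stay inside the band
        sl[lum] <- spec$lumen_intensity
        lay[lum] <- 5L
      }
    }

    # oblique SPCA tracks crossing the sclera towards the choroid
    for (v in seq_len(spec$n_spca)) {
      y0 <- pos[v, 2] * px_y          # lateral entry, px (0-based scale)
      x0 <- pos[v, 1] * px_x          # B-scan entry, px
      dseq <- seq(-3, spec$spca_length_px)
      xs <- x0 + spca_dir[v, 1] * spec$spca_slope * dseq * (px_x / px_y)
      sel <- abs(xs - (x - 1)) <= spec$spca_radius_px * (px_x / px_y)
      if (!any(sel)) next
      for (k in which(sel)) {
        dd <- dseq[k]
        yc <- y0 + spca_dir[v, 2] * spec$spca_slope * dd
        yi <- which(abs(seq_len(ny) - 1 - yc) <= spec$spca_radius_px)
        if (!length(yi)) next
        zc <- round(ot[yi] + dd)              # depth along the local interface
        okz <- zc >= 1 & zc <= nz - 1 & zc > ct[yi]
        sl[cbind(zc[okz] + 1, yi[okz])] <- spec$spca_intensity
        lay[cbind(zc[okz] + 1, yi[okz])] <- 7L
      }
    }

    sl <- sl * exp(-spec$attenuation_coeff * zm)
    if (spec$speckle_level > 0) {
      shape <- 1 / spec$speckle_level
      sl <- sl * matrix(rgamma(nz * ny, shape = shape, scale = 1 / shape),
                        nz, ny)
    }
    vol[, , x] <- pmin(pmax(round(sl), 0), 255)
    if (layer_masks) layers[, , x] <- lay
  }

  marks <- vessel_marks(
    tibble::tibble(eye_id = "phantom", observer_id = "truth", trial_id = 1L,
                   x_mm = pos[, 1], y_mm = pos[, 2]),
    lateral_extent_mm = ext
  )
  truth <- list(
    cib_true = boundary_surface(cib_true, "CIB", "final", nz),
    cob_true = boundary_surface(cob_true, "COB", "final", nz),
    spca_marks_true = marks
  )
  if (layer_masks) truth$layers <- layers
  list(volume = oct_volume(vol, lateral_extent_mm = ext,
                           source = sprintf("phantom(seed=%d)", spec$seed)),
       truth = truth)
}

#' Simulate an observer's trial over a set of true marks
#'
#' Each truth mark is independently dropped with probability `drop_prob`
#' (a mark the observer fails to identify) and otherwise displaced by
#' isotropic Gaussian jitter of scale `jitter_sd_mm` (localization error).
#' Positions are clamped into the field.
#'
#' @param truth a [vessel_marks()] tibble.
#' @param jitter_sd_mm per-axis jitter SD in mm.
#' @param drop_prob per-mark drop probability.
#' @param seed RNG seed.
#' @param observer_id,trial_id identity stamped on the simulated trial.
#' @return a [vessel_marks()] tibble.
#' @export
perturb_marks <- function(truth, jitter_sd_mm = 0.2, drop_prob = 0.05,
                          seed = 1, observer_id = "obs1", trial_id = 1L) {
  if (drop_prob < 0 || drop_prob > 1) stop("drop_prob must be in [0, 1]")
  if (jitter_sd_mm < 0) stop("jitter_sd_mm must be nonnegative")
  set.seed(seed)
  ext <- attr(truth, "lateral_extent_mm") %||% 12
  keep <- runif(nrow(truth)) >= drop_prob
  out <- tibble::as_tibble(truth)[keep, , drop = FALSE]
  n <- nrow(out)
  out$x_mm <- pmin(pmax(out$x_mm + rnorm(n, 0, jitter_sd_mm), 0), ext)
  out$y_mm <- pmin(pmax(out$y_mm + rnorm(n, 0, jitter_sd_mm), 0), ext)
  out$observer_id <- observer_id
  out$trial_id <- trial_id
  vessel_marks(out, lateral_extent_mm = ext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
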