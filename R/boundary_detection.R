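#' Segmentation parameters
#'
#' Tunables of the choroid inner boundary (CIB) and choroid outer boundary
#' (COB) detectors and of the cross-B-scan smoothing.
#'
#' @param binarize_threshold 8-bit intensity cut applied to the normalized
#'   enhanced image (default 128, mid-grayscale).
#' @param min_component_frac minimum connected-component area kept by
#'   morphological cleaning, as a fraction of the B-scan area (default
#'   0.001; the retained boundary evidence forms thin ribbons, so the
#'   threshold guards against speckle clusters rather than sizing whole
#'   layers); `min_component_px` overrides with an absolute pixel count.
#' @param min_component_px optional absolute minimum component area.
#' @param morph_close_radius disc radius of the morphological closing that
#'   merges the closely spaced bright components (default 2).
#' @param morph_bridge_width width of a 1-px-tall horizontal-line closing
#'   applied after the disc closing; it bridges breaks in the thin
#'   horizontal ribbons of boundary evidence so they survive the
#'   component-area filter (default 15; 0 disables).
#' @param morph_open_width width of the horizontal-line opening that removes
#'   isolated specks; the retained boundary evidence forms thin horizontal
#'   ribbons, so the opening element is 1 pixel tall (default 3; 0 disables).
#' @param rloess_span span of the robust LOESS smoother across B-scans
#'   (default 0.2 of the series; the local window must hold clearly more
#'   inliers than any run of correlated spurious B-scan traces for the
#'   bisquare reweighting to reject them).
#' @param rloess_iterations robustifying (bisquare reweighting) iterations
#'   (default 5).
#' @param tv_scale tensor-voting influence scale in pixels (default 15).
#' @param tv_depth_penalty depth-disagreement weight of the saliency pass
#'   (default 4), see [tensor_vote_interpolate()].
#' @param tail_margin_frac tail-margin excluded from binarization, see
#'   [binarize_enhanced()] (default 0.1).
#' @param below_cib_margin rows below the CIB excluded from the COB search
#'   so the search region starts safely inside the choroid (default 2).
#' @param envelope_tol tolerance (px) of the lower-envelope filter on the
#'   per-column extreme points: an extreme point is kept only if it lies
#'   within this distance of the deepest extreme point among the columns
#'   inside one voting scale, so evidence sitting on top of a vessel lumen
#'   (locally far above the interface) does not vote (default 6).
#' @param min_anchors minimum number of per-column extreme points required
#'   for a B-scan's COB interpolation (default 5); fewer flags the scan as
#'   low-evidence and leaves it to the orthogonal smoothing.
#' @param trace_roughness_max maximum median absolute step (px) between
#'   neighbouring columns of an initial CIB trace; a rougher trace carries
#'   no coherent layer boundary (pure speckle passes the area filter as
#'   fragmented chains but jumps tens of pixels between columns) and the
#'   B-scan is flagged empty (default 5).
#' @param max_empty_frac volume-level failure threshold: if more than this
#'   fraction of B-scans yields no boundary evidence the segmentation
#'   aborts (default 0.5).
#' @param surface_consistency_max volume-level failure threshold on the
#'   median absolute deviation (px) between the initial CIB estimates and
#'   the smoothed consensus surface; layered anatomy produces estimates
#'   that agree across neighbouring B-scans, whereas structureless input
#'   (pure speckle) leaves mutually inconsistent traces (default 8).
#' @param max_thickness_frac volume-level plausibility bound: the median
#'   segmented choroid thickness may not exceed this fraction of the axial
#'   depth (default 0.5).  The choroid is a thin band; structureless input
#'   yields a pseudo-CIB at the tail margin and a pseudo-COB near the
#'   image bottom, a "choroid" spanning most of the A-scan.
#' @param normalize binarization normalization mode, `"column"` or
#'   `"global"` (see [binarize_enhanced()]).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(binarize_threshold = 128,
                                min_component_frac = 0.001,
                                min_component_px = NULL,
                                morph_close_radius = 2,
                                morph_bridge_width = 15,
                                morph_open_width = 3,
                                rloess_span = 0.2,
                                rloess_iterations = 5,
                                tv_scale = 15,
                                tv_depth_penalty = 4,
                                tail_margin_frac = 0.1,
                                below_cib_margin = 2,
                                envelope_tol = 6,
                                min_anchors = 5,
                                trace_roughness_max = 5,
                                max_empty_frac = 0.5,
                                surface_consistency_max = 8,
                                max_thickness_frac = 0.5,
                                normalize = c("column", "global")) {
  if (binarize_threshold <= 0 || binarize_threshold >= 255)
    stop("binarize_threshold must be in (0, 255)")
  if (rloess_span <= 0 || rloess_span > 1)
    stop("rloess_span must be in (0, 1]")
  if (tv_scale <= 0 || morph_close_radius < 0)
    stop("radii and scales must be positive")
  structure(
    list(binarize_threshold = binarize_threshold,
         min_component_frac = min_component_frac,
         min_component_px = min_component_px,
         morph_close_radius = morph_close_radius,
         morph_bridge_width = morph_bridge_width,
         morph_open_width = morph_open_width,
         rloess_span = rloess_span,
         rloess_iterations = rloess_iterations,
         tv_scale = tv_scale,
         tv_depth_penalty = tv_depth_penalty,
         tail_margin_frac = tail_margin_frac,
         below_cib_margin = below_cib_margin,
         envelope_tol = envelope_tol,
         min_anchors = min_anchors,
         trace_roughness_max = trace_roughness_max,
         max_empty_frac = max_empty_frac,
         surface_consistency_max = surface_consistency_max,
         max_thickness_frac = max_thickness_frac,
         normalize = match.arg(normalize)),
    class = "segmentation_params"
  )
}

min_component_area <- function(params, mask) {
  if (!is.null(params$min_component_px)) params$min_component_px
  else max(1, round(params$min_component_frac * length(mask)))
}

# morphological close (disc) + open (horizontal line) + connected-component
# area filter; returns the cleaned logical mask
clean_mask <- function(mask, params) {
  if (!any(mask)) return(mask)
  m <- EBImage::Image(mask * 1)
  if (params$morph_close_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$morph_close_radius + 1, shape = "disc")
    m <- EBImage::closing(m, brush)
  }
  if (params$morph_bridge_width > 1) {
    bridge <- matrix(1, nrow = 1, ncol = params$morph_bridge_width)
    m <- EBImage::closing(m, bridge)
  }
  if (params$morph_open_width > 1) {
    line <- matrix(1, nrow = 1, ncol = params$morph_open_width)
    m <- EBImage::opening(m, line)
  }
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_component_area(params, mask))
  out <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  out
}

#' Initial CIB estimate for one B-scan
#'
#' Runs the CIB pipeline on a preprocessed B-scan: vertically flipped
#' exponentiation/nonlinear enhancement, mid-gray binarization,
#' morphological close/open with connected-component filtering that keeps
#' only the large components of the retinal layers, and per-column
#' extraction of the retained retinal mass's boundary facing the choroid
#' (its deepest pixel after un-flipping).  Columns without retained
#' evidence are returned as `NA` gaps for the orthogonal smoothing to fill.
#'
#' @param scan preprocessed B-scan (see [preprocess_bscan()]).
#' @param params a [segmentation_params()].
#' @param enh an [enhancement_params()].
#' @return numeric vector of 0-based depths (one per lateral column), with
#'   attribute `empty = TRUE` when no component survived in the whole scan.
#' @export
detect_cib_initial <- function(scan, params = segmentation_params(),
                               enh = enhancement_params()) {
  e <- enhance_for_cib(scan, enh)
  b <- binarize_enhanced(e, params$binarize_threshold,
                         params$tail_margin_frac, params$normalize)
  b <- clean_mask(b, params)
  nz <- nrow(b)
  # un-flip: row f (1-based) in the flipped frame is original depth nz - f
  mask <- b[nz:1, , drop = FALSE]
  trace <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_real_ else max(w) - 1
  })
  # coherence check: a boundary varies slowly between neighbouring columns
  steps <- abs(diff(trace))
  steps <- steps[!is.na(steps)]
  if (all(is.na(trace)) ||
      (length(steps) >= 4 && median(steps) > params$trace_roughness_max)) {
    trace[] <- NA_real_
    attr(trace, "empty") <- TRUE
  }
  trace
}

#' Initial COB estimate for one B-scan
#'
#' Runs the COB pipeline on a preprocessed B-scan: exponentiation/nonlinear
#' enhancement in the original orientation, binarization, restriction of
#' the evidence to the region below the (final) CIB, morphological cleaning
#' to isolate the sections of deep choroidal tissue and vessels, selection
#' of the per-column extreme point towards the sclera (maximum depth), and
#' tensor-voting interpolation of the sparse extreme points into a
#' continuous trace.
#'
#' @param scan preprocessed B-scan.
#' @param cib final CIB trace for the same B-scan (vector of depths, one
#'   per column), used to restrict the search region below the retina.
#' @param params a [segmentation_params()].
#' @param enh an [enhancement_params()].
#' @return numeric vector of 0-based depths per column; all-`NA` with
#'   attribute `empty = TRUE` when fewer than `min_anchors` extreme points
#'   were found.
#' @export
detect_cob_initial <- function(scan, cib, params = segmentation_params(),
                               enh = enhancement_params()) {
  scan <- as.matrix(scan)
  if (length(cib) != ncol(scan))
    stop("CIB trace length must match the number of columns")
  e <- enhance_for_cob(scan, enh)
  b <- binarize_enhanced(e, params$binarize_threshold,
                         params$tail_margin_frac, params$normalize)
  # keep only evidence safely below the retina
  zmat <- matrix(0:(nrow(b) - 1), nrow(b), ncol(b))
  lim <- matrix(cib + params$below_cib_margin, nrow(b), ncol(b), byrow = TRUE)
  b[zmat <= lim] <- FALSE
  b <- clean_mask(b, params)
  anchors_z <- apply(b, 2, function(col) {
    w <- which(col)
    if (length(w) == 0L) NA_real_ else max(w) - 1
  })
  have <- which(!is.na(anchors_z))
  # lower-envelope filter: only locally deepest extreme points vote
  if (length(have) > 0 && params$envelope_tol >= 0) {
    env <- vapply(have, function(i) {
      max(anchors_z[have[abs(have - i) <= params$tv_scale]])
    }, numeric(1))
    have <- have[anchors_z[have] >= env - params$envelope_tol]
  }
  if (length(have) < params$min_anchors) {
    trace <- rep(NA_real_, ncol(scan))
    attr(trace, "empty") <- TRUE
    return(trace)
  }
  tensor_vote_interpolate(have - 1, anchors_z[have], ncol(scan),
                          scale = params$tv_scale,
                          depth_penalty = params$tv_depth_penalty)
}

rloess_series <- function(z, span, iterations) {
  n <- length(z)
  ok <- !is.na(z)
  if (sum(ok) < 4) return(rep(NA_real_, n))
  df <- data.frame(t = seq_len(n)[ok], z = z[ok])
  # the span must cover enough points for a local quadratic fit
  span_eff <- max(span, min(1, 7 / sum(ok)))
  fit <- tryCatch(
    suppressWarnings(loess(
      z ~ t, data = df, span = span_eff, degree = 2, family = "symmetric",
      control = loess.control(surface = "direct", iterations = iterations))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(rep(NA_real_, n))
  out <- tryCatch(
    suppressWarnings(as.numeric(
      predict(fit, newdata = data.frame(t = seq_len(n))))),
    error = function(e) rep(NA_real_, n)
  )
  if (length(out) != n || anyNA(out)) return(rep(NA_real_, n))
  # guard against end-window overshoot of the local quadratic
  pmin(pmax(out, min(df$z)), max(df$z))
}

#' Smooth a stacked surface across B-scans
#'
#' Volumetric smoothing of an initial boundary surface.  For every lateral
#' column the 1D series of depths across the B-scan index is smoothed by
#' robust LOESS (local quadratic fit with bisquare reweighting), which
#' fills gaps and suppresses the spurious detections of individual B-scans;
#' each B-scan's trace is then regularized by tensor voting along its
#' columns to remove minor deformations.  The result is gap-free.
#'
#' @param surface initial [boundary_surface()], or a bare depth matrix
#'   (lateral rows, B-scan columns) with `NA` gaps.
#' @param params a [segmentation_params()].
#' @param axial_depth_px axial extent used for clamping and for the output
#'   surface; required when `surface` is a bare matrix.
#' @return a final-stage [boundary_surface()].
#' @export
smooth_orthogonal <- function(surface, params = segmentation_params(),
                              axial_depth_px = NULL) {
  if (inherits(surface, "boundary_surface")) {
    depth <- surface$depth
    kind <- surface$kind
    if (is.null(axial_depth_px)) axial_depth_px <- surface$axial_depth_px
  } else {
    depth <- as.matrix(surface)
    kind <- "CIB"
    if (is.null(axial_depth_px))
      stop("`axial_depth_px` is required for a bare depth matrix")
  }
  ny <- nrow(depth); nx <- ncol(depth)

  # pass 1: robust LOESS along the B-scan index for each lateral column
  sm <- t(apply(depth, 1, rloess_series,
                span = params$rloess_span,
                iterations = params$rloess_iterations))
  # lateral columns with too few observations: interpolate from neighbours
  bad <- which(apply(sm, 1, function(r) anyNA(r)))
  if (length(bad)) {
    if (length(bad) == ny)
      stop("no column has enough boundary evidence to smooth")
    warning(length(bad), " lateral column(s) filled from neighbouring columns")
    good <- setdiff(seq_len(ny), bad)
    for (j in seq_len(nx)) {
      sm[bad, j] <- approx(good, sm[good, j], xout = bad, rule = 2)$y
    }
  }

  # pass 2: tensor voting along the columns of each B-scan
  if (params$tv_scale > 0) {
    for (j in seq_len(nx)) {
      sm[, j] <- tensor_vote_interpolate(0:(ny - 1), sm[, j], ny,
                                         scale = params$tv_scale,
                                         depth_penalty = params$tv_depth_penalty)
    }
  }
  sm <- pmin(pmax(sm, 0), axial_depth_px - 1)
  boundary_surface(sm, kind = kind, stage = "final",
                   axial_depth_px = axial_depth_px)
}

#' Segment the choroid boundaries of a whole volume
#'
#' Runs the four-step schematic over an OCT volume: (i) initial CIB
#' estimates B-scan by B-scan, stacked in 3D; (ii) final CIB by smoothing
#' in the orthogonal direction; (iii) initial COB estimates conditioned on
#' the final CIB; (iv) final COB by the same orthogonal smoothing.  The
#' final surfaces are gap-free and satisfy CIB < COB everywhere (the COB is
#' clamped to CIB + 1 where the estimates cross; the number of clamped
#' A-scans is recorded).
#'
#' @param volume an [oct_volume()].
#' @param params a [segmentation_params()].
#' @param enh an [enhancement_params()].
#' @return list of class `choroid_segmentation` with elements `cib` and
#'   `cob` (final [boundary_surface()]s), `n_clamped`, `empty_bscans`, and
#'   the parameter sets used.
#' @export
segment_volume <- function(volume, params = segmentation_params(),
                           enh = enhancement_params()) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensities)
  nz <- d[1]; ny <- d[2]; nx <- d[3]

  pre <- vector("list", nx)
  for (i in seq_len(nx))
    pre[[i]] <- preprocess_bscan(volume$intensities[, , i], enh)

  cib_init <- matrix(NA_real_, ny, nx)
  empty <- logical(nx)
  for (i in seq_len(nx)) {
    tr <- detect_cib_initial(pre[[i]], params, enh)
    empty[i] <- isTRUE(attr(tr, "empty"))
    cib_init[, i] <- tr
  }
  if (mean(empty) > params$max_empty_frac)
    stop(sprintf(
      "volume-level failure: %d of %d B-scans carry no retinal boundary evidence",
      sum(empty), nx))
  cib <- smooth_orthogonal(
    boundary_surface(cib_init, "CIB", "initial", nz), params)
  consistency <- median(abs(cib_init - cib$depth), na.rm = TRUE)
  if (!is.finite(consistency) ||
      consistency > params$surface_consistency_max)
    stop(sprintf(
      "volume-level failure: initial CIB estimates deviate %.1f px (median) from the volumetric consensus; no spatially consistent retinal boundary",
      consistency))

  cob_init <- matrix(NA_real_, ny, nx)
  empty_cob <- logical(nx)
  for (i in seq_len(nx)) {
    tr <- detect_cob_initial(pre[[i]], cib$depth[, i], params, enh)
    empty_cob[i] <- isTRUE(attr(tr, "empty"))
    cob_init[, i] <- tr
  }
  if (mean(empty_cob) > params$max_empty_frac)
    stop(sprintf(
      "volume-level failure: %d of %d B-scans carry no choroid-sclera evidence",
      sum(empty_cob), nx))
  cob <- smooth_orthogonal(
    boundary_surface(cob_init, "COB", "initial", nz), params)
  cob$kind <- "COB"

  med_th <- median(cob$depth - cib$depth)
  if (med_th > params$max_thickness_frac * nz)
    stop(sprintf(
      "volume-level failure: median segmented thickness %.0f px exceeds %.0f%% of the axial depth; the volume carries no plausible layered anatomy",
      med_th, 100 * params$max_thickness_frac))

  viol <- cob$depth <= cib$depth
  n_clamped <- sum(viol)
  if (n_clamped > 0) {
    cob$depth[viol] <- pmin(cib$depth[viol] + 1, nz - 1)
    message(n_clamped, " A-scan(s) clamped to keep CIB < COB")
  }

  structure(
    list(cib = cib, cob = cob, n_clamped = n_clamped,
         empty_bscans = which(empty | empty_cob),
         params = params, enhancement = enh),
    class = "choroid_segmentation"
  )
}

#' @export
print.choroid_segmentation <- function(x, ...) {
  th <- x$cob$depth - x$cib$depth
  cat(sprintf(
    "<choroid_segmentation> %d x %d A-scans; thickness %.1f px (sd %.1f)\n",
    nrow(th), ncol(th), mean(th), sd(as.numeric(th))))
  invisible(x)
}
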