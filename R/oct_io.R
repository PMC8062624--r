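#' OCT volume container
#'
#' Wraps a 3D grid of 8-bit intensities with axes ordered (axial depth z,
#' lateral column y, B-scan index x), the orientation in which a B-scan is a
#' depth-by-lateral image with depth running down the rows.  Depth indices
#' used throughout the package are 0-based, so a boundary at depth `d` refers
#' to pixel row `d + 1` of the underlying R array.
#'
#' @param intensities 3D numeric array, values in `[0, 255]`, dims
#'   `(axial, lateral, n_bscans)`, each dimension at least 2.
#' @param lateral_extent_mm physical size of the scanned en-face field (the
#'   wide-field protocol covers 12 x 12 mm); applies to both lateral axes.
#' @param source optional character tag recording where the volume came from.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, lateral_extent_mm = 12, source = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (axial, lateral, n_bscans)")
  d <- dim(intensities)
  if (any(d < 2L))
    stop("all three volume dimensions must be >= 2")
  rng <- range(intensities)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255] with no missing values")
  if (!is.numeric(lateral_extent_mm) || lateral_extent_mm <= 0)
    stop("`lateral_extent_mm` must be positive")
  structure(
    list(
      intensities = intensities,
      lateral_extent_mm = lateral_extent_mm,
      axial_depth_px = d[1],
      source = source
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<oct_volume> %d axial x %d lateral x %d B-scans, %.4g x %.4g mm field\n",
    d[1], d[2], d[3], x$lateral_extent_mm, x$lateral_extent_mm
  ))
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensities)

#' Extract one B-scan from a volume
#'
#' @param volume an [oct_volume()].
#' @param index B-scan index (1-based along the x axis).
#' @return a depth-by-lateral numeric matrix with values in `[0, 255]`.
#' @export
get_bscan <- function(volume, index) {
  stopifnot(inherits(volume, "oct_volume"))
  nb <- dim(volume$intensities)[3]
  if (index < 1 || index > nb) stop("B-scan index out of range")
  volume$intensities[, , index]
}

read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB(A)
  img
}

#' Load an OCT volume from disk
#'
#' Reads either a multi-page grayscale TIFF (one page per B-scan) or a
#' directory of per-B-scan TIFF/PNG images (pages ordered by file name).
#' Within a page, rows are axial depth and columns are lateral position; the
#' page order defines the B-scan (x) axis.  Inputs are converted to 8-bit
#' integers; fractional gray levels in the source raise a warning.
#'
#' @param path file or directory path.
#' @param layout `"auto"` (default, inferred from `path`), `"tiff"` for a
#'   multi-page TIFF, or `"dir"` for a directory of single images.
#' @param lateral_extent_mm physical field size, see [oct_volume()].
#' @return an [oct_volume()].
#' @export
load_volume <- function(path, layout = c("auto", "tiff", "dir"),
                        lateral_extent_mm = 12) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (layout == "auto") layout <- if (dir.exists(path)) "dir" else "tiff"
  pages <- if (layout == "tiff") {
    p <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(p)) p <- list(p)
    lapply(p, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  } else {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF/PNG files found in ", path)
    lapply(files, read_image_gray)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent B-scan dimensions across pages")
  vals <- vapply(pages, function(m) m * 255, matrix(0, dims[1, 1], dims[2, 1]))
  if (max(abs(vals - round(vals))) > 1e-6)
    warning("input is not 8-bit; gray levels rounded to the nearest integer")
  vol <- round(vals)
  oct_volume(vol, lateral_extent_mm = lateral_extent_mm, source = path)
}

#' Save an OCT volume as a multi-page 8-bit TIFF
#'
#' The round trip `load_volume(save_volume(v))` is voxel-exact.
#'
#' @param volume an [oct_volume()].
#' @param path output file path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  nb <- dim(volume$intensities)[3]
  pages <- lapply(seq_len(nb), function(i) volume$intensities[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

#' Load vessel entry-site marks from CSV
#'
#' Marks record en-face positions of identified SPCA entry sites.  The CSV
#' must carry a header with columns `eye_id`, `observer_id`, `trial_id` and
#' either millimetre positions (`x_mm`, `y_mm`) or pixel positions (`x_px`,
#' `y_px`), the latter being converted with
#' `mm = px * extent_mm / pixel_count` per axis.  Positions are relative to
#' the image corner (top-left of the en-face view); statistical routines
#' re-base to a bottom-left origin where required.
#'
#' @param path CSV file path.
#' @param extent_mm,pixels field extent and en-face pixel count per axis,
#'   needed only for pixel-coordinate files.  `pixels` may be length 2
#'   `(x, y)`.
#' @return a tibble of class `vessel_marks` with columns `eye_id`,
#'   `observer_id`, `trial_id`, `x_mm`, `y_mm` (plus `laterality` if present
#'   in the file), and attribute `lateral_extent_mm`.
#' @export
load_marks <- function(path, extent_mm = 12, pixels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  idcols <- c("eye_id", "observer_id", "trial_id")
  miss <- setdiff(idcols, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (all(c("x_mm", "y_mm") %in% names(df))) {
    xy <- c("x_mm", "y_mm")
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    if (is.null(pixels))
      stop("pixel-coordinate CSV requires `pixels` (en-face pixel count)")
    pixels <- rep(pixels, length.out = 2)
    df$x_mm <- df$x_px * extent_mm / pixels[1]
    df$y_mm <- df$y_px * extent_mm / pixels[2]
    xy <- c("x_px", "y_px")
  } else {
    stop("need either x_mm/y_mm or x_px/y_px columns")
  }
  for (cl in xy) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("non-numeric ", cl, " at data row(s): ", paste(bad, collapse = ", "))
    if (anyNA(v)) stop("missing ", cl, " at data row(s): ",
                       paste(which(is.na(v)), collapse = ", "))
  }
  keep <- c(idcols, if ("laterality" %in% names(df)) "laterality", "x_mm", "y_mm")
  out <- tibble::as_tibble(df[, keep, drop = FALSE])
  vessel_marks(out, lateral_extent_mm = extent_mm)
}

#' Construct a mark set
#'
#' @param marks data frame with columns `eye_id`, `observer_id`, `trial_id`,
#'   `x_mm`, `y_mm` and optionally `laterality` (`"OD"`/`"OS"`).
#' @param lateral_extent_mm field extent; positions must lie inside
#'   `[0, lateral_extent_mm]` on both axes.
#' @return tibble of class `vessel_marks`.
#' @export
vessel_marks <- function(marks, lateral_extent_mm = 12) {
  marks <- tibble::as_tibble(marks)
  need <- c("eye_id", "observer_id", "trial_id", "x_mm", "y_mm")
  miss <- setdiff(need, names(marks))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(marks) > 0 &&
      (any(marks$x_mm < 0 | marks$x_mm > lateral_extent_mm) ||
       any(marks$y_mm < 0 | marks$y_mm > lateral_extent_mm)))
    stop("mark positions outside the [0, ", lateral_extent_mm, "] mm field")
  structure(marks, lateral_extent_mm = lateral_extent_mm,
            class = c("vessel_marks", class(marks)))
}

#' Save a mark set as CSV
#'
#' @param marks a [vessel_marks()] tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_marks <- function(marks, path) {
  write.csv(as.data.frame(marks), path, row.names = FALSE)
  invisible(path)
}

#' Boundary surface container
#'
#' A per-(lateral column, B-scan) grid of axial depths for one layer
#' boundary.  Depths are 0-based pixel indices, fractional after smoothing.
#'
#' @param depth numeric matrix (lateral y rows, B-scan x columns); `NA`
#'   entries mark gaps and are only permitted at the `"initial"` stage.
#' @param kind `"CIB"` or `"COB"`.
#' @param stage `"initial"` or `"final"`.
#' @param axial_depth_px axial extent of the parent volume; depths must lie
#'   in `[0, axial_depth_px)`.
#' @return object of class `boundary_surface`.
#' @export
boundary_surface <- function(depth, kind = c("CIB", "COB"),
                             stage = c("initial", "final"),
                             axial_depth_px) {
  kind <- match.arg(kind)
  stage <- match.arg(stage)
  depth <- as.matrix(depth)
  if (stage == "final" && anyNA(depth))
    stop("a final-stage surface must not contain missing values")
  ok <- depth[!is.na(depth)]
  if (length(ok) && (min(ok) < 0 || max(ok) >= axial_depth_px))
    stop("depths must lie in [0, axial_depth_px)")
  structure(
    list(depth = depth, kind = kind, stage = stage,
         axial_depth_px = axial_depth_px),
    class = "boundary_surface"
  )
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat(sprintf("<boundary_surface> %s (%s), %d x %d, depth %.1f-%.1f px\n",
              x$kind, x$stage, nrow(x$depth), ncol(x$depth),
              min(x$depth, na.rm = TRUE), max(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.boundary_surface <- function(x) dim(x$depth)

surface_depth <- function(s) if (inherits(s, "boundary_surface")) s$depth else as.matrix(s)

#' Save / load a boundary surface
#'
#' Surfaces are stored as a plain CSV grid of depths (lateral rows, B-scan
#' columns) plus a JSON sidecar carrying kind, stage and the axial extent.
#'
#' @param surface a [boundary_surface()].
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `prefix` (for `save_surface`); a `boundary_surface` (for
#'   `load_surface`).
#' @export
save_surface <- function(surface, prefix) {
  stopifnot(inherits(surface, "boundary_surface"))
  write.table(surface$depth, paste0(prefix, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(kind = surface$kind, stage = surface$stage,
         axial_depth_px = surface$axial_depth_px),
    paste0(prefix, ".json"), auto_unbox = TRUE
  )
  invisible(prefix)
}

#' @rdname save_surface
#' @export
load_surface <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  depth <- as.matrix(read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(depth) <- NULL
  boundary_surface(depth, kind = meta$kind, stage = meta$stage,
                   axial_depth_px = meta$axial_depth_px)
}

#' Save an en-face image as 8-bit PNG or TIFF
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param path output path; format chosen by extension (`.png`/`.tif`).
#' @return `path`, invisibly.
#' @export
save_enface <- function(image, path) {
  m <- pmin(pmax(image, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, path)
  else tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}
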