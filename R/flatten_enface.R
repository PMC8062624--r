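#' Flatten the choroid-sclera interface
#'
#' Shifts every A-scan axially so that its COB depth lands on a common
#' plane, turning the curved choroid-sclera interface into a flat one from
#' which constant-depth scleral en-face slices can be read.  The default
#' plane is the maximum COB depth over the volume.  In the default integer
#' mode each A-scan is shifted by a whole number of pixels (bit-exact and
#' invertible); sub-pixel mode resamples each A-scan by 1D linear
#' interpolation for smoother en-face slices.  Vacated voxels fill with 0.
#'
#' @param volume an [oct_volume()].
#' @param cob final-stage COB [boundary_surface()] for the volume.
#' @param plane_depth axial index of the flattening plane; default
#'   `max(round(cob))`.
#' @param mode `"integer"` (default) or `"subpixel"`.
#' @return object of class `flattened_volume`: list with `intensities`,
#'   `flatten_plane_depth`, `shift_map` (per-(y, x) applied shift, px),
#'   `mode` and `lateral_extent_mm`.
#' @export
flatten_volume <- function(volume, cob, plane_depth = NULL,
                           mode = c("integer", "subpixel")) {
  stopifnot(inherits(volume, "oct_volume"))
  mode <- match.arg(mode)
  if (!inherits(cob, "boundary_surface") || cob$stage != "final")
    stop("`cob` must be a final-stage boundary surface")
  d <- dim(volume$intensities)
  if (!all(dim(cob$depth) == d[2:3]))
    stop("COB dimensions do not match the volume")
  depth <- if (mode == "integer") round(cob$depth) else cob$depth
  if (is.null(plane_depth)) plane_depth <- max(depth)
  shift <- plane_depth - depth           # >= 0 when plane is the max: shift down
  nz <- d[1]
  out <- array(0, dim = d)
  z <- seq_len(nz)
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      s <- shift[y, x]
      a <- volume$intensities[, y, x]
      if (s == 0) {
        out[, y, x] <- a
      } else if (mode == "integer") {
        if (s > 0) out[(s + 1):nz, y, x] <- a[1:(nz - s)]
        else out[1:(nz + s), y, x] <- a[(1 - s):nz]
      } else {
        out[, y, x] <- approx(z + s, a, xout = z, rule = 1, yleft = 0,
                              yright = 0)$y
        out[is.na(out[, y, x]), y, x] <- 0
      }
    }
  }
  structure(
    list(intensities = out, flatten_plane_depth = plane_depth,
         shift_map = shift, mode = mode,
         lateral_extent_mm = volume$lateral_extent_mm),
    class = "flattened_volume"
  )
}

#' Undo the flattening shifts
#'
#' Applies the negated shift map; the original volume is restored exactly
#' over all voxels that were not vacated or cropped by the forward shift
#' (integer mode).
#'
#' @param flat a [flatten_volume()] result.
#' @return an [oct_volume()].
#' @export
unflatten_volume <- function(flat) {
  stopifnot(inherits(flat, "flattened_volume"))
  d <- dim(flat$intensities)
  nz <- d[1]
  out <- array(0, dim = d)
  for (x in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      s <- flat$shift_map[y, x]
      a <- flat$intensities[, y, x]
      if (s == 0) out[, y, x] <- a
      else if (s > 0) out[1:(nz - s), y, x] <- a[(s + 1):nz]
      else out[(1 - s):nz, y, x] <- a[1:(nz + s)]
    }
  }
  oct_volume(out, lateral_extent_mm = flat$lateral_extent_mm,
             source = "unflattened")
}

#' Extract the scleral en-face stack
#'
#' Reads the constant-depth slices of a flattened volume from the flatten
#' plane (the choroid-sclera interface) downward.
#'
#' @param flat a [flatten_volume()] result.
#' @param max_depth_px maximum number of slices; the stack is truncated at
#'   the image bottom when fewer remain.
#' @return object of class `enface_stack`: list with `slices` (3D array,
#'   lateral y x B-scan x x slice) and `depth_offsets` (0-based depths
#'   below the interface).
#' @export
extract_enface_stack <- function(flat, max_depth_px) {
  stopifnot(inherits(flat, "flattened_volume"))
  if (max_depth_px <= 0) stop("`max_depth_px` must be positive")
  nz <- dim(flat$intensities)[1]
  p <- round(flat$flatten_plane_depth)
  n <- min(max_depth_px, nz - p)
  if (n < 1) stop("flatten plane lies at or below the image bottom")
  offs <- 0:(n - 1)
  slices <- aperm(flat$intensities[p + 1 + offs, , , drop = FALSE], c(2, 3, 1))
  structure(
    list(slices = slices, depth_offsets = offs,
         truncated = n < max_depth_px,
         lateral_extent_mm = flat$lateral_extent_mm),
    class = "enface_stack"
  )
}

#' Project an en-face substack
#'
#' Collapses a run of consecutive en-face slices into a single image.  SPCA
#' entry sites appear as hyporeflective (dark) dots or short tracks; a
#' substack of a handful of slices is projected to confirm that a dark spot
#' persists across depths rather than being speckle.
#'
#' @param stack an [extract_enface_stack()] result.
#' @param first 1-based index of the first slice of the substack.
#' @param count number of slices; bounded to `[5, 30]` unless
#'   `enforce_bounds = FALSE`.
#' @param mode `"mean"` (default) or `"min"` intensity projection.
#' @param enforce_bounds set `FALSE` to lift the substack-size bounds.
#' @return numeric matrix (lateral y x B-scan x) in `[0, 255]`.
#' @export
project_substack <- function(stack, first = 1, count = 10,
                             mode = c("mean", "min"), enforce_bounds = TRUE) {
  stopifnot(inherits(stack, "enface_stack"))
  mode <- match.arg(mode)
  nslice <- dim(stack$slices)[3]
  if (enforce_bounds && (count < 5 || count > 30))
    stop("substack size must lie in [5, 30] (use enforce_bounds = FALSE to override)")
  if (first < 1 || first > nslice) stop("`first` out of range")
  idx <- first:min(first + count - 1, nslice)
  sub <- stack$slices[, , idx, drop = FALSE]
  if (mode == "mean") apply(sub, c(1, 2), mean) else apply(sub, c(1, 2), min)
}

#' Suggest a substack window by dark-spot contrast
#'
#' Ranks candidate substack windows by the contrast between their darkest
#' pixels and the slice median (hyporeflective vessel cross-sections pull
#' the lower tail down).  A convenience only: substack choice remains with
#' the user.
#'
#' @param stack an [extract_enface_stack()] result.
#' @param count substack size to evaluate.
#' @return tibble with `first`, `contrast`, ordered best first.
#' @export
suggest_substack <- function(stack, count = 10) {
  stopifnot(inherits(stack, "enface_stack"))
  nslice <- dim(stack$slices)[3]
  starts <- seq_len(max(1, nslice - count + 1))
  contrast <- vapply(starts, function(f) {
    pr <- project_substack(stack, f, count, mode = "mean",
                           enforce_bounds = FALSE)
    as.numeric(median(pr) - quantile(pr, 0.02))
  }, numeric(1))
  tibble::tibble(first = starts, contrast = contrast)[order(-contrast), ]
}
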