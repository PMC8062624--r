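#' Enhancement parameters
#'
#' Parameters of the per-B-scan preprocessing and the two-step
#' exponentiation / nonlinear enhancement shared by both boundary detectors.
#'
#' @param raw_exponent power applied to the normalized gray level when
#'   forming the raw intensity, `(I/255)^raw_exponent` (default 4).  The
#'   fourth power crushes moderate reflectivities so that the brightest
#'   layer dominates the columnar sums of the next step.
#' @param enh_exponent exponent `n` of the exponentiation enhancement
#'   (default 10).
#' @param median_window side of the square median-filter window (default 6).
#' @param median_passes number of sequential median passes; the default 2
#'   implements second-order median filtering.
#' @param clahe_tiles contrast-limited adaptive histogram equalization tiling
#'   as `c(rows, cols)` (default 6 x 6).
#' @param clahe_clip normalized CLAHE clip limit (default 0.01).
#' @return a list of class `enhancement_params`.
#' @export
enhancement_params <- function(raw_exponent = 4, enh_exponent = 10,
                               median_window = 6, median_passes = 2,
                               clahe_tiles = c(6, 6), clahe_clip = 0.01) {
  if (raw_exponent < 1 || enh_exponent < 1)
    stop("exponents must be >= 1")
  clahe_tiles <- rep(as.integer(clahe_tiles), length.out = 2)
  if (median_window < 2 || any(clahe_tiles < 2))
    stop("median window and CLAHE tile counts must be >= 2")
  structure(
    list(raw_exponent = raw_exponent, enh_exponent = enh_exponent,
         median_window = as.integer(median_window),
         median_passes = as.integer(median_passes),
         clahe_tiles = clahe_tiles, clahe_clip = clahe_clip),
    class = "enhancement_params"
  )
}

clahe_padded <- function(m, tiles, clip) {
  nr <- nrow(m); nc <- ncol(m)
  nx <- tiles[1]; ny <- tiles[2]
  nr2 <- ceiling(nr / nx) * nx
  nc2 <- ceiling(nc / ny) * ny
  mp <- matrix(0, nr2, nc2)
  mp[1:nr, 1:nc] <- m
  if (nr2 > nr) mp[(nr + 1):nr2, 1:nc] <-
      matrix(mp[nr, 1:nc], nr2 - nr, nc, byrow = TRUE)
  if (nc2 > nc) mp[, (nc + 1):nc2] <- mp[, nc]
  out <- EBImage::clahe(mp / 255, nx = nx, ny = ny, bins = 256,
                        limit = clip * 256, keep.range = TRUE) * 255
  out[1:nr, 1:nc, drop = FALSE]
}

#' Preprocess a B-scan
#'
#' Applies second-order median filtering (two sequential passes of a square
#' median window) to suppress speckle, followed by contrast-limited adaptive
#' histogram equalization to even out depth-dependent contrast.  Output
#' stays on the 8-bit `[0, 255]` scale (double precision, not re-quantized).
#'
#' @param scan depth-by-lateral numeric matrix in `[0, 255]`.
#' @param params an [enhancement_params()].
#' @return preprocessed matrix, same dimensions.
#' @export
preprocess_bscan <- function(scan, params = enhancement_params()) {
  scan <- as.matrix(scan)
  if (length(scan) == 0) stop("empty B-scan")
  k <- params$median_window
  if (k > nrow(scan) || k > ncol(scan))
    stop("median window larger than the B-scan")
  out <- scan
  for (i in seq_len(params$median_passes))
    out <- medfilt2_rect(out, k, k)
  out <- clahe_padded(out, params$clahe_tiles, params$clahe_clip)
  pmin(pmax(out, 0), 255)
}

#' Raw intensity image
#'
#' Maps 8-bit gray levels to dimensionless raw intensities
#' `(I/255)^p` in `[0, 1]` (default `p = 4`).
#'
#' @param scan matrix in `[0, 255]`.
#' @param exponent the power `p`.
#' @return matrix of raw intensities in `[0, 1]`.
#' @export
raw_intensity <- function(scan, exponent = 4) {
  (as.matrix(scan) / 255)^exponent
}

#' Exponentiation enhancement
#'
#' Each pixel is replaced by the ratio of its raw intensity to twice the
#' cumulative tail sum of raw intensities from its own row down to the
#' bottom of the column, raised to the power `n`:
#' `(I_raw(x, y) / (2 * sum_{k = x..p} I_raw(k, y)))^n`.  Because the tail
#' includes the pixel itself the ratio is at most 1/2, so the output is
#' bounded by `0.5^n`.  The tail-relative form boosts the deepest remaining
#' signal in each A-scan, compensating the attenuation suffered by deeper
#' posterior-segment layers.  Columns whose tail sum is zero (no signal
#' below the pixel) map to 0.
#'
#' @param raw matrix of raw intensities in `[0, 1]` (see [raw_intensity()]).
#' @param n exponent, `>= 1` (default 10).
#' @return enhanced matrix with attribute `stage = "exponentiated"`.
#' @export
exponentiation_enhance <- function(raw, n = 10) {
  raw <- as.matrix(raw)
  if (n < 1) stop("`n` must be >= 1")
  if (min(raw) < 0 || max(raw) > 1) stop("raw intensities must lie in [0, 1]")
  # reversed cumulative sum down each column: tail[k] = sum(raw[k:nrow])
  tail_sum <- apply(raw, 2, function(col) rev(cumsum(rev(col))))
  tail_sum <- matrix(tail_sum, nrow(raw), ncol(raw))
  out <- matrix(0, nrow(raw), ncol(raw))
  pos <- tail_sum > 0
  out[pos] <- (raw[pos] / (2 * tail_sum[pos]))^n
  structure(out, stage = "exponentiated")
}

#' Nonlinear (depth-weighted) enhancement
#'
#' Multiplies the exponentiation-enhanced image by the squared axial row
#' index, `x^2 * I_expenh(x, y)`, amplifying deeper rows.  Row indices are
#' 0-based, so the first row is forced to zero; boundaries never lie at
#' row 0.
#'
#' @param exp_img output of [exponentiation_enhance()].
#' @return depth-weighted matrix with attribute `stage = "nonlinear"`.
#' @export
nonlinear_enhance <- function(exp_img) {
  if (!identical(attr(exp_img, "stage"), "exponentiated"))
    stop("input must be the exponentiated image")
  z <- matrix(0:(nrow(exp_img) - 1), nrow(exp_img), ncol(exp_img))
  structure(z^2 * unclass(exp_img), stage = "nonlinear")
}

flip_vertical <- function(m) m[nrow(m):1, , drop = FALSE]

#' Enhancement chains for the two boundary detectors
#'
#' `enhance_for_cib()` vertically flips the (preprocessed) B-scan, then
#' applies [raw_intensity()], [exponentiation_enhance()] and
#' [nonlinear_enhance()].  With the retina at the bottom of the flipped
#' frame, retinal reflectors saturate through their high row indices while
#' choroid and sclera are attenuated; the result is returned in the flipped
#' frame (attribute `orientation = "flipped"`) and detected boundaries are
#' un-flipped by the caller.  `enhance_for_cob()` applies the same chain in
#' the original orientation, enhancing choroidal structure at depth.
#'
#' @param scan preprocessed B-scan matrix in `[0, 255]`.
#' @param params an [enhancement_params()].
#' @return enhanced matrix with attributes `stage = "nonlinear"` and
#'   `orientation` (`"flipped"` or `"original"`).
#' @export
enhance_for_cib <- function(scan, params = enhancement_params()) {
  e <- nonlinear_enhance(exponentiation_enhance(
    raw_intensity(flip_vertical(as.matrix(scan)), params$raw_exponent),
    params$enh_exponent
  ))
  attr(e, "orientation") <- "flipped"
  e
}

#' @rdname enhance_for_cib
#' @export
enhance_for_cob <- function(scan, params = enhancement_params()) {
  e <- nonlinear_enhance(exponentiation_enhance(
    raw_intensity(as.matrix(scan), params$raw_exponent),
    params$enh_exponent
  ))
  attr(e, "orientation") <- "original"
  e
}

#' Binarize an enhanced image
#'
#' The exponent `n = 10` stretches the enhanced image over tens of orders of
#' magnitude, so a fixed mid-gray cut is applied after normalization.  By
#' default each A-scan column is normalized by its own maximum (the
#' enhancement itself is columnar); `normalize = "global"` rescales by the
#' image maximum instead.  A margin of rows at the tail end of the summation
#' direction (image bottom in the operating frame) is excluded beforehand:
#' there the cumulative-tail denominator makes the ratio approach 1/2
#' regardless of content, which would otherwise dominate any normalization.
#'
#' @param enh enhanced image (from [enhance_for_cib()] / [enhance_for_cob()]).
#' @param threshold 8-bit cut applied after normalization to `[0, 255]`
#'   (default 128).
#' @param tail_margin_frac fraction of rows excluded at the tail end
#'   (default 0.1).
#' @param normalize `"column"` (default) or `"global"`.
#' @return logical matrix, `TRUE` where the enhanced intensity exceeds the
#'   cut.
#' @export
binarize_enhanced <- function(enh, threshold = 128, tail_margin_frac = 0.1,
                              normalize = c("column", "global")) {
  normalize <- match.arg(normalize)
  if (threshold <= 0 || threshold >= 255) stop("threshold must be in (0, 255)")
  e <- unclass(enh)
  nr <- nrow(e)
  margin <- floor(tail_margin_frac * nr)
  if (margin > 0) e[(nr - margin + 1):nr, ] <- 0
  if (normalize == "column") {
    mx <- apply(e, 2, max)
    mx[mx <= 0] <- 1
    e <- sweep(e, 2, mx, "/")
  } else {
    mx <- max(e)
    if (mx > 0) e <- e / mx
  }
  e * 255 > threshold
}
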