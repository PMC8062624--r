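#' Tensor-voting curve interpolation
#'
#' Completes a dense depth trace from sparse (column, depth) anchor points
#' using a first-order stick-voting scheme.  Each anchor is assigned a local
#' tangent by Gaussian-weighted least squares over neighbouring anchors.  In
#' a first pass anchors vote for each other: anchor `j` predicts the depth
#' at anchor `i` by extending its tangent line, and the vote strength decays
#' with both the column distance and the squared disagreement between the
#' prediction and the receiver's depth.  The accumulated votes give each
#' anchor a saliency, so anchors consistent with a smooth curve through
#' their neighbours are reinforced and isolated outliers are down-weighted.
#' In the second pass every output column receives tangent-line votes from
#' all anchors, weighted by Gaussian distance decay times anchor saliency,
#' and the trace is the weighted mean of the predictions.
#'
#' Anchored columns reproduce their anchor depth (exactly for mutually
#' consistent anchors, within rounding otherwise); a single anchor yields a
#' constant trace; collinear anchors reproduce their line.
#'
#' @param columns integer vector of anchor columns (0-based).
#' @param depths numeric vector of anchor depths (same length).
#' @param width number of output columns.
#' @param scale voting influence scale in pixels (default 15).
#' @param depth_penalty weight of the depth-disagreement term relative to
#'   the column-distance term in the saliency pass (default 4).
#' @return numeric vector of length `width` with one depth per column.
#' @export
tensor_vote_interpolate <- function(columns, depths, width, scale = 15,
                                    depth_penalty = 4) {
  n <- length(columns)
  if (n == 0L) stop("tensor voting requires at least one anchor point")
  if (length(depths) != n) stop("columns and depths must have equal length")
  if (n == 1L) return(rep(depths, width))
  ord <- order(columns)
  ac <- as.numeric(columns)[ord]
  az <- as.numeric(depths)[ord]

  # local tangents: Gaussian-weighted least-squares slope around each anchor
  dc <- outer(ac, ac, "-")                      # dc[i, j] = ac[i] - ac[j]
  w <- exp(-(dc / scale)^2)
  slopes <- vapply(seq_len(n), function(i) {
    wi <- w[i, ]
    mc <- sum(wi * ac) / sum(wi)
    mz <- sum(wi * az) / sum(wi)
    den <- sum(wi * (ac - mc)^2)
    if (den < 1e-12) 0 else sum(wi * (ac - mc) * (az - mz)) / den
  }, numeric(1))

  # pass 1: anchor-to-anchor votes -> saliency
  pred_at <- function(cols) {
    # rows: voters, cols: receiver positions
    outer(az, rep(1, length(cols))) +
      slopes * (matrix(cols, n, length(cols), byrow = TRUE) - ac)
  }
  pa <- pred_at(ac)                              # n x n, pa[j, i] = vote of j at i
  disagree <- sweep(pa, 2, az, "-")
  vote <- exp(-(dc^2 + depth_penalty * t(disagree)^2) / scale^2)
  diag(vote) <- 0
  saliency <- 1 + colSums(vote)

  # refine tangents with saliency weights so an outlying anchor does not
  # contaminate its neighbours' orientations
  slopes <- vapply(seq_len(n), function(i) {
    wi <- w[i, ] * saliency
    mc <- sum(wi * ac) / sum(wi)
    mz <- sum(wi * az) / sum(wi)
    den <- sum(wi * (ac - mc)^2)
    if (den < 1e-12) 0 else sum(wi * (ac - mc) * (az - mz)) / den
  }, numeric(1))

  # pass 2: dense completion
  cols_out <- 0:(width - 1)
  # constant continuation outside the anchored span: tangent-line
  # extrapolation far beyond the last anchor can run away
  cols_eff <- pmin(pmax(cols_out, min(ac)), max(ac))
  g <- exp(-pmin((outer(ac, cols_eff, "-") / scale)^2, 700))  # n x width
  g <- g * saliency
  pred <- pred_at(cols_eff)
  den <- colSums(g)
  out <- colSums(g * pred) / den
  # interior columns beyond voting range: nearest anchor depth
  far <- den < 1e-12 | !is.finite(out)
  if (any(far)) {
    ni <- vapply(cols_eff[far], function(cc) which.min(abs(ac - cc)), integer(1))
    out[far] <- az[ni]
  }
  out
}
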