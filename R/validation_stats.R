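#' Dice coefficient of two pixel-index sets
#'
#' `DC = 2 |a intersect b| / (|a| + |b|)`, the overlap statistic between the
#' pixel-index sets of two thickness measurements at one A-scan.  `DC = 1`
#' means the measurements are equal, `DC = 0` that they are disjoint.  Two
#' empty sets are defined to agree perfectly (`DC = 1`): both raters report
#' no tissue at that A-scan.
#'
#' @param a,b integer vectors of pixel indices (duplicates ignored).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Dice between two contiguous index ranges [s1, e1], [s2, e2] (closed,
# integer); empty ranges are encoded by e < s
dice_interval <- function(s1, e1, s2, e2) {
  n1 <- pmax(0, e1 - s1 + 1)
  n2 <- pmax(0, e2 - s2 + 1)
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  out <- ifelse(n1 + n2 == 0, 1, 2 * ov / (n1 + n2))
  out
}

#' Average two segmentations
#'
#' The "mean rater" reference: per-A-scan arithmetic mean of the two
#' boundary depths, rounded half up to an integer pixel index.
#'
#' @param seg1,seg2 [boundary_surface()]s (or depth matrices) of the same
#'   kind and dimensions.
#' @return a [boundary_surface()] when the inputs are surfaces, otherwise a
#'   depth matrix.
#' @export
average_segmentation <- function(seg1, seg2) {
  d1 <- surface_depth(seg1); d2 <- surface_depth(seg2)
  if (!all(dim(d1) == dim(d2))) stop("segmentation dimensions differ")
  avg <- floor((d1 + d2) / 2 + 0.5)
  if (inherits(seg1, "boundary_surface"))
    boundary_surface(avg, kind = seg1$kind, stage = "final",
                     axial_depth_px = seg1$axial_depth_px)
  else avg
}

#' Dice validation report for two segmentations
#'
#' Compares two segmentations of the same volume A-scan by A-scan.  For
#' each A-scan a contiguous pixel-index set is built from the surfaces and
#' the Dice coefficient computed; per-B-scan means and the overall
#' mean (SD) over B-scans are aggregated.  Three set constructions cover
#' the plausible readings of a thickness-based Dice: `"cib"` uses the band
#' from the image top to the CIB, `"cob"` the band from the top to the COB
#' (each validating one boundary), and `"band"` the choroid band between
#' CIB and COB.
#'
#' @param seg1,seg2 lists with elements `cib` and `cob`
#'   ([boundary_surface()]s or depth matrices of equal dimensions), e.g. a
#'   [segment_volume()] result and a reference.
#' @param boundary `"band"` (default), `"cib"` or `"cob"`.
#' @param comparison optional character tag (e.g. `"algorithm-vs-manual"`).
#' @return object of class `dice_report`: list with `per_ascan` (matrix of
#'   DC values), `per_bscan` (tibble), `mean`, `sd`, `boundary`,
#'   `comparison`.
#' @export
dice_report <- function(seg1, seg2, boundary = c("band", "cib", "cob"),
                        comparison = NULL) {
  boundary <- match.arg(boundary)
  c1 <- round(surface_depth(seg1$cib)); o1 <- round(surface_depth(seg1$cob))
  c2 <- round(surface_depth(seg2$cib)); o2 <- round(surface_depth(seg2$cob))
  if (!all(dim(c1) == dim(c2)) || !all(dim(o1) == dim(o2)))
    stop("segmentation dimensions differ")
  dc <- switch(boundary,
    cib  = dice_interval(0, c1, 0, c2),
    cob  = dice_interval(0, o1, 0, o2),
    band = dice_interval(c1 + 1, o1, c2 + 1, o2)
  )
  dc <- matrix(dc, nrow(c1), ncol(c1))
  per_bscan <- tibble::tibble(
    bscan = seq_len(ncol(dc)),
    mean_dc = colMeans(dc),
    sd_dc = apply(dc, 2, sd)
  )
  structure(
    list(per_ascan = dc, per_bscan = per_bscan,
         mean = mean(per_bscan$mean_dc),
         sd = sd(per_bscan$mean_dc),
         boundary = boundary, comparison = comparison),
    class = "dice_report"
  )
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> %s: mean DC %.4f (SD %.4f) over %d B-scans%s\n",
              x$boundary, x$mean,
              ifelse(is.na(x$sd), 0, x$sd), nrow(x$per_bscan),
              if (!is.null(x$comparison)) paste0(" [", x$comparison, "]") else ""))
  invisible(x)
}

#' Radial position consistency of marks
#'
#' Re-bases en-face mark positions to a bottom-left origin, computes the
#' radial position `sqrt(X^2 + Y^2)` in pixels, and, when an expert
#' position series `Z` is supplied, flags whether
#' `|Z - sqrt(X^2 + Y^2)| < epsilon` holds for each mark.  The radial
#' scalar discards angular information; it is the positional summary used
#' for the observer-agreement correlations.
#'
#' @param marks a [vessel_marks()] tibble (positions in mm, top-left
#'   origin) or a data frame with pixel columns `X`, `Y` already re-based
#'   to the bottom-left corner.
#' @param expert_z optional numeric series of expert positions (pixels),
#'   one per mark.
#' @param epsilon robustness tolerance in pixels (default 1.5).
#' @param extent_mm,pixels field extent and en-face pixel count, used to
#'   convert mm positions; `pixels` defaults to 1024.
#' @return tibble with `X`, `Y` (pixels, bottom-left origin), `z` (radial
#'   position) and, if `expert_z` was given, `valid`.
#' @export
position_consistency <- function(marks, expert_z = NULL, epsilon = 1.5,
                                 extent_mm = 12, pixels = 1024) {
  if (epsilon < 0) stop("`epsilon` must be nonnegative")
  marks <- tibble::as_tibble(marks)
  if (all(c("X", "Y") %in% names(marks))) {
    X <- marks$X; Y <- marks$Y
  } else {
    scale <- pixels / extent_mm
    X <- marks$x_mm * scale
    Y <- (extent_mm - marks$y_mm) * scale   # re-base: bottom-left origin
  }
  out <- tibble::tibble(X = X, Y = Y, z = sqrt(X^2 + Y^2))
  if (!is.null(expert_z)) {
    if (length(expert_z) != nrow(out))
      stop("`expert_z` must have one value per mark")
    out$valid <- abs(expert_z - out$z) < epsilon
  }
  out
}

#' Pearson correlation with a defined-ness flag
#'
#' Standard product-moment correlation; a zero-variance argument yields
#' `NA` with attribute `undefined = TRUE` rather than propagating `NaN`.
#'
#' @param u,v numeric series of equal length `>= 2`.
#' @return correlation in `[-1, 1]`, or flagged `NA`.
#' @export
pearson_r <- function(u, v) {
  if (length(u) != length(v)) stop("series lengths differ")
  if (length(u) < 2) stop("need at least two observations")
  if (sd(u) == 0 || sd(v) == 0)
    return(structure(NA_real_, undefined = TRUE))
  cor(u, v)
}

#' Qualify a correlation coefficient
#'
#' Maps `|r|` to the empirical qualification bins: below 0.20 very weak,
#' 0.20 to 0.40 weak, 0.40 to 0.60 moderate, 0.60 to 0.80 strong, above
#' 0.80 very strong.  A value exactly at a bin edge belongs to the higher
#' bin.  The magnitude is used so that negative correlations are labelled
#' by strength; the sign is the caller's to report.
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @return one of `"very weak correlation"`, `"weak correlation"`,
#'   `"moderate correlation"`, `"strong correlation"`,
#'   `"very strong correlation"`.
#' @export
qualify_correlation <- function(r) {
  if (anyNA(r) || any(abs(r) > 1)) stop("r must lie in [-1, 1]")
  a <- abs(r)
  labels <- c("very weak correlation", "weak correlation",
              "moderate correlation", "strong correlation",
              "very strong correlation")
  labels[findInterval(a, c(0.20, 0.40, 0.60, 0.80)) + 1]
}

#' Median as the mean of the two middle order statistics
#'
#' For an even-length series the median is the average of the two middle
#' sorted values (for 18 eyes, the 9th and 10th sorted correlations).
#'
#' @param x numeric vector.
#' @return the median.
#' @export
median_midpair <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 0) stop("empty series")
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

#' Pair marks between two trials
#'
#' Greedy nearest-neighbour matching of two mark sets of the same eye
#' (closest pairs first, each mark used once, pairs farther apart than
#' `max_dist_mm` discarded).  Used to build the paired radial-position
#' series that feed the agreement correlations.
#'
#' @param a,b data frames with `x_mm`, `y_mm`.
#' @param max_dist_mm matching tolerance (default 1 mm).
#' @return tibble with the matched indices `i_a`, `i_b` and the pair
#'   distance `dist_mm`.
#' @export
match_marks <- function(a, b, max_dist_mm = 1) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(tibble::tibble(i_a = integer(), i_b = integer(),
                          dist_mm = numeric()))
  d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a$x_mm[i] - b$x_mm[j])^2 + (a$y_mm[i] - b$y_mm[j])^2)
  })
  pairs <- list()
  repeat {
    m <- which.min(d)
    if (length(m) == 0 || d[m] > max_dist_mm) break
    ij <- arrayInd(m, dim(d))
    pairs[[length(pairs) + 1]] <- c(ij[1], ij[2], d[m])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  if (length(pairs) == 0)
    return(tibble::tibble(i_a = integer(), i_b = integer(),
                          dist_mm = numeric()))
  m <- do.call(rbind, pairs)
  tibble::tibble(i_a = as.integer(m[, 1]), i_b = as.integer(m[, 2]),
                 dist_mm = m[, 3])
}

#' Build paired radial-position series from repeated mark sets
#'
#' For `mode = "auto"` (intra-observer) each observer's trial `t` is paired
#' with trial `t + 1` of the same eye; for `mode = "cross"`
#' (inter-observer) the two observers' same-numbered trials are paired.
#' Marks are matched by nearest neighbour and converted to radial
#' bottom-left positions (see [position_consistency()]).
#'
#' @param marks a [vessel_marks()] tibble with `observer_id` and
#'   `trial_id`.
#' @param mode `"auto"` or `"cross"`.
#' @param extent_mm,pixels coordinate conversion, see
#'   [position_consistency()].
#' @param max_dist_mm mark-matching tolerance.
#' @return tibble with `eye_id`, `pair` (label), `z_t`, `z_t1`.
#' @export
pair_trials <- function(marks, mode = c("auto", "cross"), extent_mm = 12,
                        pixels = 1024, max_dist_mm = 1) {
  mode <- match.arg(mode)
  marks <- tibble::as_tibble(marks)
  radial <- function(df) position_consistency(df, extent_mm = extent_mm,
                                              pixels = pixels)$z
  out <- list()
  for (eye in unique(marks$eye_id)) {
    me <- marks[marks$eye_id == eye, , drop = FALSE]
    combos <- if (mode == "auto") {
      obs <- unique(me$observer_id)
      do.call(rbind, lapply(obs, function(o) {
        tr <- sort(unique(me$trial_id[me$observer_id == o]))
        if (length(tr) < 2) return(NULL)
        data.frame(o1 = o, t1 = tr[-length(tr)], o2 = o, t2 = tr[-1])
      }))
    } else {
      obs <- sort(unique(me$observer_id))
      if (length(obs) < 2) NULL
      else {
        tr <- intersect(unique(me$trial_id[me$observer_id == obs[1]]),
                        unique(me$trial_id[me$observer_id == obs[2]]))
        if (length(tr) == 0) NULL
        else data.frame(o1 = obs[1], t1 = tr, o2 = obs[2], t2 = tr)
      }
    }
    if (is.null(combos) || nrow(combos) == 0) next
    for (k in seq_len(nrow(combos))) {
      a <- me[me$observer_id == combos$o1[k] & me$trial_id == combos$t1[k], ]
      b <- me[me$observer_id == combos$o2[k] & me$trial_id == combos$t2[k], ]
      mm <- match_marks(a, b, max_dist_mm)
      if (nrow(mm) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        eye_id = eye,
        pair = sprintf("%s/%s-%s/%s", combos$o1[k], combos$t1[k],
                       combos$o2[k], combos$t2[k]),
        z_t = radial(a[mm$i_a, ]),
        z_t1 = radial(b[mm$i_b, ])
      )
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(eye_id = character(), pair = character(),
                          z_t = numeric(), z_t1 = numeric()))
  dplyr::bind_rows(out)
}

#' Observer-agreement correlation analysis
#'
#' Computes the Pearson correlation between paired radial-position series
#' for each eye, the median correlation over eyes (for an even number of
#' eyes the average of the two middle order statistics), and the
#' qualitative label of the median.  Eyes with an undefined correlation
#' (zero variance or fewer than 3 pairs) are dropped with a warning.
#'
#' @param pairs tibble from [pair_trials()] (columns `eye_id`, `z_t`,
#'   `z_t1`), or a [vessel_marks()] tibble, in which case `mode` and the
#'   conversion arguments are forwarded to [pair_trials()].
#' @param mode `"auto"` or `"cross"` (used when `pairs` holds raw marks).
#' @param ... passed on to [pair_trials()].
#' @return object of class `agreement_report`: list with `per_eye`
#'   (tibble of `eye_id`, `n_pairs`, `r`, `label`), `median_r`, `label`,
#'   `mode`.
#' @export
agreement_analysis <- function(pairs, mode = c("auto", "cross"), ...) {
  mode <- match.arg(mode)
  if (!all(c("z_t", "z_t1") %in% names(pairs)))
    pairs <- pair_trials(pairs, mode = mode, ...)
  if (nrow(pairs) == 0) stop("no paired marks to analyse")
  per_eye <- dplyr::group_by(pairs, .data$eye_id)
  per_eye <- dplyr::summarise(
    per_eye,
    n_pairs = dplyr::n(),
    r = if (dplyr::n() >= 3) as.numeric(pearson_r(.data$z_t, .data$z_t1))
        else NA_real_,
    .groups = "drop"
  )
  bad <- is.na(per_eye$r)
  if (any(bad)) {
    warning(sum(bad), " eye(s) dropped: undefined correlation")
    per_eye <- per_eye[!bad, , drop = FALSE]
  }
  if (nrow(per_eye) == 0) stop("no eye has a defined correlation")
  per_eye$label <- qualify_correlation(per_eye$r)
  med <- median_midpair(per_eye$r)
  structure(
    list(per_eye = per_eye, median_r = med,
         label = qualify_correlation(med), mode = mode),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s: median r = %.4f (%s) over %d eye(s)\n",
              x$mode, x$median_r, x$label, nrow(x$per_eye)))
  invisible(x)
}
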