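#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (per B-scan, per eye, per sector), `glance()` a
#' one-row summary.
#'
#' @param x a `dice_report`, `agreement_report`, `sector_distribution`,
#'   `eye_summary` or `choroid_segmentation`.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy dice_report
#' @export
tidy.dice_report <- function(x, ...) x$per_bscan

#' @rdname tidiers
#' @method glance dice_report
#' @export
glance.dice_report <- function(x, ...) {
  tibble::tibble(boundary = x$boundary, mean_dc = x$mean, sd_dc = x$sd,
                 n_bscans = nrow(x$per_bscan),
                 comparison = x$comparison %||% NA_character_)
}

#' @rdname tidiers
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$per_eye

#' @rdname tidiers
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(mode = x$mode, median_r = x$median_r, label = x$label,
                 n_eyes = nrow(x$per_eye))
}

#' @rdname tidiers
#' @method tidy sector_distribution
#' @export
tidy.sector_distribution <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @method glance eye_summary
#' @export
glance.eye_summary <- function(x, ...) {
  tibble::tibble(n_included = x$n_included,
                 mean_count = x$mean_count,
                 sd_count = x$sd_count,
                 sd_defined = x$sd_defined)
}

#' @rdname tidiers
#' @method tidy eye_summary
#' @export
tidy.eye_summary <- function(x, ...) x$eyes

#' @rdname tidiers
#' @method tidy choroid_segmentation
#' @export
tidy.choroid_segmentation <- function(x, ...) {
  th <- x$cob$depth - x$cib$depth
  tibble::tibble(
    bscan = seq_len(ncol(th)),
    mean_thickness_px = colMeans(th),
    mean_cib = colMeans(x$cib$depth),
    mean_cob = colMeans(x$cob$depth)
  )
}

#' @rdname tidiers
#' @method glance choroid_segmentation
#' @export
glance.choroid_segmentation <- function(x, ...) {
  th <- x$cob$depth - x$cib$depth
  tibble::tibble(
    n_ascans = length(th),
    mean_thickness_px = mean(th),
    sd_thickness_px = sd(as.numeric(th)),
    n_clamped = x$n_clamped,
    n_empty_bscans = length(x$empty_bscans)
  )
}
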