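#' Posterior-pole sector grid
#'
#' The 3 x 3 grid of square sectors covering the en-face field (nine 4 x 4
#' mm sectors over the 12 x 12 mm posterior pole).
#'
#' @param extent_mm full field size (default 12).
#' @param sector_mm sector edge (default 4); must satisfy
#'   `extent_mm == 3 * sector_mm`.
#' @return list of class `sector_grid`.
#' @export
sector_grid <- function(extent_mm = 12, sector_mm = 4) {
  if (abs(extent_mm - 3 * sector_mm) > 1e-9)
    stop("the grid must be 3 x 3: extent_mm == 3 * sector_mm")
  structure(list(extent_mm = extent_mm, sector_mm = sector_mm),
            class = "sector_grid")
}

sector_cell <- function(pos_mm, grid) {
  # half-open cells [a, a + sector) except the final cell, which is closed
  idx <- floor(pos_mm / grid$sector_mm)
  pmin(pmax(idx, 0), 2)
}

sector_label_from_cell <- function(row, col, laterality) {
  vert <- c("superior", "central", "inferior")[row + 1]
  horiz <- ifelse(laterality == "OD",
                  c("temporal", "central", "nasal")[col + 1],
                  c("nasal", "central", "temporal")[col + 1])
  ifelse(vert == "central" & horiz == "central", "central",
    ifelse(vert == "central", horiz,
      ifelse(horiz == "central", vert, paste(vert, horiz, sep = "-"))))
}

#' Assign marks to posterior-pole sectors
#'
#' Maps each en-face mark to its 3 x 3 grid cell via
#' `floor(position / sector_mm)` per axis (half-open cells, far edge closed)
#' and attaches the anatomical label.  Vertically, smaller `y_mm` (upper
#' image) is superior.  Horizontally the temporal retina lies on the left
#' of a fundus-orientation image for a right eye (OD) and on the right for
#' a left eye (OS).
#'
#' @param marks a [vessel_marks()] tibble (or data frame with `x_mm`,
#'   `y_mm`).
#' @param grid a [sector_grid()].
#' @param laterality `"OD"` or `"OS"`; defaults to the marks' `laterality`
#'   column.  Required for anatomical labels.
#' @return the marks tibble with added columns `cell_row`, `cell_col`
#'   (0-based, row 0 superior, col 0 image-left) and `sector`.
#' @export
assign_sector <- function(marks, grid = sector_grid(), laterality = NULL) {
  marks <- tibble::as_tibble(marks)
  if (is.null(laterality)) {
    if (!"laterality" %in% names(marks))
      stop("laterality unknown: supply `laterality` or a laterality column")
    laterality <- marks$laterality
  }
  if (!all(laterality %in% c("OD", "OS")))
    stop('laterality must be "OD" or "OS"')
  if (nrow(marks) > 0 &&
      (any(marks$x_mm < 0 | marks$x_mm > grid$extent_mm) ||
       any(marks$y_mm < 0 | marks$y_mm > grid$extent_mm)))
    stop("mark outside the sector-grid field")
  row <- sector_cell(marks$y_mm, grid)
  col <- sector_cell(marks$x_mm, grid)
  marks$cell_row <- as.integer(row)
  marks$cell_col <- as.integer(col)
  marks$sector <- sector_label_from_cell(row, col,
                                         rep(laterality, length.out = nrow(marks)))
  marks
}

#' Sector distribution of entry-site marks
#'
#' Counts marks per sector over all nine cells and converts to percentages
#' of the total.  Percentages are kept at full precision; rounding for
#' report tables (half away from zero, matching integer report
#' conventions) is available via `round_half_away()`.
#'
#' @param marks a [vessel_marks()] tibble; must contain at least one mark.
#' @param grid a [sector_grid()].
#' @param laterality see [assign_sector()].
#' @return tibble of class `sector_distribution` with one row per cell:
#'   `cell_row`, `cell_col`, `sector`, `count`, `percentage`; attribute
#'   `total` carries the mark count.
#' @export
compute_distribution <- function(marks, grid = sector_grid(),
                                 laterality = NULL) {
  if (nrow(marks) == 0)
    stop("distribution undefined for an empty mark set")
  assigned <- assign_sector(marks, grid, laterality)
  lat1 <- if (!is.null(laterality)) laterality[1] else assigned$laterality[1]
  cells <- tidyr::expand_grid(cell_row = 0:2, cell_col = 0:2)
  counts <- dplyr::count(assigned, .data$cell_row, .data$cell_col,
                         name = "count")
  out <- dplyr::left_join(cells, counts, by = c("cell_row", "cell_col"))
  out$count[is.na(out$count)] <- 0L
  out$sector <- sector_label_from_cell(out$cell_row, out$cell_col,
                                       rep(lat1, nrow(out)))
  total <- sum(out$count)
  out$percentage <- 100 * out$count / total
  out <- out[, c("cell_row", "cell_col", "sector", "count", "percentage")]
  structure(out, total = total,
            class = c("sector_distribution", class(out)))
}

#' Round half away from zero
#'
#' Report-table rounding for integer percentages (R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Low-count exclusion rule
#'
#' Eyes in which fewer than `min_count` arteries could be identified are
#' excluded, the cut-off being the minimum number of SPCAs reported in
#' histological studies (10).
#'
#' @param marks a [vessel_marks()] tibble covering one or more eyes.
#' @param min_count exclusion threshold (default 10); an eye with
#'   `count < min_count` is excluded.
#' @param group additional grouping columns beyond `eye_id` (e.g.
#'   `c("observer_id", "trial_id")`) whose combinations are counted
#'   separately.
#' @return tibble with one row per group: the grouping columns, `n_marks`
#'   and `included`.
#' @export
apply_exclusion <- function(marks, min_count = 10, group = character()) {
  marks <- tibble::as_tibble(marks)
  out <- dplyr::count(marks, dplyr::across(dplyr::all_of(c("eye_id", group))),
                      name = "n_marks")
  out$included <- out$n_marks >= min_count
  out
}

#' Cohort summary of per-eye mark counts
#'
#' Applies the low-count exclusion, then reports the arithmetic mean and
#' sample (n - 1) standard deviation of per-eye mark counts over the
#' included eyes, together with the pooled sector distribution of all
#' included marks.  With a single included eye the SD is undefined and
#' reported as 0 with `sd_defined = FALSE`.
#'
#' @param marks a [vessel_marks()] tibble covering the cohort.
#' @param grid a [sector_grid()].
#' @param min_count exclusion threshold (default 10).
#' @param laterality see [assign_sector()].
#' @return list of class `eye_summary` with `eyes` (per-eye tibble),
#'   `mean_count`, `sd_count`, `sd_defined`, `n_included`, `distribution`.
#' @export
summarize_eyes <- function(marks, grid = sector_grid(), min_count = 10,
                           laterality = NULL) {
  excl <- apply_exclusion(marks, min_count)
  inc <- excl$eye_id[excl$included]
  if (length(inc) == 0) stop("all eyes excluded by the low-count rule")
  kept <- marks[marks$eye_id %in% inc, , drop = FALSE]
  counts <- excl$n_marks[excl$included]
  structure(
    list(eyes = excl,
         mean_count = mean(counts),
         sd_count = if (length(counts) > 1) sd(counts) else 0,
         sd_defined = length(counts) > 1,
         n_included = length(inc),
         distribution = compute_distribution(kept, grid, laterality)),
    class = "eye_summary"
  )
}

#' @export
print.eye_summary <- function(x, ...) {
  cat(sprintf("<eye_summary> %d eye(s) included; %.1f (SD %.1f) marks/eye\n",
              x$n_included, x$mean_count, x$sd_count))
  if (!x$sd_defined) cat("  (single eye: SD undefined, reported as 0)\n")
  invisible(x)
}
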