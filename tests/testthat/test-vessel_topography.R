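mk_marks <- function(x, y, eye = "e1", lat = NULL) {
  df <- tibble::tibble(eye_id = eye, observer_id = "o1", trial_id = 1L,
                       x_mm = x, y_mm = y)
  if (!is.null(lat)) df$laterality <- lat
  vessel_marks(df)
}

test_that("sector assignment follows the half-open cell convention", {
  g <- sector_grid()
  a <- assign_sector(mk_marks(6, 6), g, "OD")
  expect_identical(c(a$cell_row, a$cell_col), c(1L, 1L))
  expect_identical(a$sector, "central")

  a <- assign_sector(mk_marks(0, 0), g, "OD")
  expect_identical(c(a$cell_row, a$cell_col), c(0L, 0L))

  # 4.0 belongs to [4, 8); 7.9 to the middle row
  a <- assign_sector(mk_marks(4, 7.9), g, "OD")
  expect_identical(c(a$cell_row, a$cell_col), c(1L, 1L))

  # the far edge is closed into the last cell
  a <- assign_sector(mk_marks(12, 12), g, "OD")
  expect_identical(c(a$cell_row, a$cell_col), c(2L, 2L))

  # brute-force boundary sweep against floor arithmetic
  for (v in c(0, 0.05, 3.95, 4, 4.05, 7.95, 8, 11.95, 12)) {
    a <- assign_sector(mk_marks(v, 6), g, "OD")
    expect_identical(a$cell_col, as.integer(min(floor(v / 4), 2)))
  }

  expect_error(assign_sector(mk_marks(6, 6), g), "laterality")
  m <- mk_marks(6, 6); m$x_mm <- 13
  expect_error(assign_sector(m, g, "OD"), "outside")
})

test_that("every in-field point maps to exactly one cell", {
  g <- sector_grid()
  pts <- expand.grid(x = seq(0, 12, by = 0.1), y = seq(0, 12, by = 0.1))
  m <- vessel_marks(tibble::tibble(eye_id = "e", observer_id = "o",
                                   trial_id = 1L, x_mm = pts$x, y_mm = pts$y))
  a <- assign_sector(m, g, "OD")
  expect_true(all(a$cell_row %in% 0:2 & a$cell_col %in% 0:2))
  expect_false(anyNA(a$sector))
  # the nine cells partition the field
  expect_identical(sort(unique(paste(a$cell_row, a$cell_col))),
                   sort(as.character(outer(0:2, 0:2, paste))))
})

test_that("anatomical labels respect laterality and vertical orientation", {
  g <- sector_grid()
  # temporal is image-left for OD, image-right for OS
  expect_identical(assign_sector(mk_marks(1, 6), g, "OD")$sector, "temporal")
  expect_identical(assign_sector(mk_marks(1, 6), g, "OS")$sector, "nasal")
  expect_identical(assign_sector(mk_marks(11, 6), g, "OS")$sector, "temporal")
  # smaller y is superior
  expect_identical(assign_sector(mk_marks(6, 1), g, "OD")$sector, "superior")
  expect_identical(assign_sector(mk_marks(6, 11), g, "OD")$sector, "inferior")

  # mirror symmetry: flipping x and laterality leaves labels unchanged
  set.seed(41)
  x <- runif(50, 0, 12); y <- runif(50, 0, 12)
  lab_od <- assign_sector(mk_marks(x, y), g, "OD")$sector
  lab_os <- assign_sector(mk_marks(12 - x, y), g, "OS")$sector
  # mirrored positions can cross a cell edge exactly at 4/8; exclude those
  inner <- abs(x %% 4) > 1e-9
  expect_identical(lab_od[inner], lab_os[inner])
})

test_that("distributions conserve counts and are order-invariant", {
  set.seed(42)
  x <- runif(40, 0, 12); y <- runif(40, 0, 12)
  d1 <- compute_distribution(mk_marks(x, y), laterality = "OD")
  expect_identical(sum(d1$count), 40L)
  expect_equal(sum(d1$percentage), 100)
  perm <- sample(40)
  d2 <- compute_distribution(mk_marks(x[perm], y[perm]), laterality = "OD")
  expect_equal(tidy(d1), tidy(d2))

  # all marks at the centre: central cell holds 100%
  dc <- compute_distribution(mk_marks(rep(6, 10), rep(6, 10)),
                             laterality = "OD")
  expect_equal(dc$percentage[dc$sector == "central"], 100)
  expect_true(all(dc$percentage[dc$sector != "central"] == 0))

  # one mark per cell centre: 11.1% each
  d9 <- compute_distribution(mk_marks(rep(c(2, 6, 10), 3),
                                      rep(c(2, 6, 10), each = 3)),
                             laterality = "OD")
  expect_true(all(d9$count == 1L))
  expect_equal(d9$percentage, rep(100 / 9, 9))

  expect_error(compute_distribution(mk_marks(numeric(), numeric()),
                                    laterality = "OD"), "empty")
})

test_that("the low-count rule excludes at 9 and includes at 10", {
  m <- dplyr::bind_rows(
    mk_marks(runif(9, 0, 12), runif(9, 0, 12), eye = "e9"),
    mk_marks(runif(10, 0, 12), runif(10, 0, 12), eye = "e10"),
    mk_marks(runif(14, 0, 12), runif(14, 0, 12), eye = "e14")
  )
  ex <- apply_exclusion(m)
  expect_identical(ex$included[match(c("e9", "e10", "e14"), ex$eye_id)],
                   c(FALSE, TRUE, TRUE))
})

test_that("cohort summaries aggregate included eyes", {
  set.seed(43)
  m <- dplyr::bind_rows(
    mk_marks(runif(12, 0, 12), runif(12, 0, 12), eye = "a"),
    mk_marks(runif(14, 0, 12), runif(14, 0, 12), eye = "b"),
    mk_marks(runif(16, 0, 12), runif(16, 0, 12), eye = "c"),
    mk_marks(runif(5, 0, 12), runif(5, 0, 12), eye = "excluded")
  )
  s <- summarize_eyes(m, laterality = "OD")
  expect_identical(s$n_included, 3L)
  expect_equal(s$mean_count, 14)
  expect_equal(s$sd_count, 2)
  expect_true(s$sd_defined)
  expect_identical(sum(s$distribution$count), 42L)
  expect_equal(sum(s$distribution$percentage), 100)

  # single eye: SD undefined, reported as 0 with the flag down
  s1 <- summarize_eyes(mk_marks(runif(11, 0, 12), runif(11, 0, 12)),
                       laterality = "OD")
  expect_false(s1$sd_defined)
  expect_identical(s1$sd_count, 0)
  expect_error(summarize_eyes(mk_marks(runif(3, 0, 12), runif(3, 0, 12))),
               "excluded")
})

test_that("report rounding is half away from zero", {
  expect_identical(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_identical(round_half_away(11.15, 1), 11.2)
})
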