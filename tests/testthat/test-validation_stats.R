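test_that("Dice coefficient anchors and closed forms", {
  expect_identical(dice_coefficient(0:9, 0:9), 1)
  expect_identical(dice_coefficient(1:10, 11:20), 0)
  expect_equal(dice_coefficient(1:10, 6:15), 0.5)
  expect_identical(dice_coefficient(integer(), integer()), 1)
  expect_equal(dice_coefficient(1:4, integer()), 0)
})

test_that("Dice is symmetric and decreases as overlap shrinks", {
  set.seed(51)
  for (i in 1:25) {
    a <- sample(0:40, sample(0:20, 1))
    b <- sample(0:40, sample(0:20, 1))
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
  }
  # DC = 1 iff equal sets (non-empty case)
  expect_lt(dice_coefficient(1:10, 1:11), 1)
  # fixed sizes, shrinking overlap
  dcs <- vapply(10:0, function(k) {
    dice_coefficient(1:10, (11 - k):(20 - k))
  }, numeric(1))
  expect_true(all(diff(dcs) <= 0))
})

test_that("interval Dice matches the explicit pixel-set oracle", {
  set.seed(52)
  for (i in 1:50) {
    s1 <- sample(0:20, 1); e1 <- s1 + sample(-1:30, 1)
    s2 <- sample(0:20, 1); e2 <- s2 + sample(-1:30, 1)
    a <- if (e1 >= s1) s1:e1 else integer()
    b <- if (e2 >= s2) s2:e2 else integer()
    expect_equal(octchoroid:::dice_interval(s1, e1, s2, e2),
                 dice_coefficient(a, b))
  }
})

test_that("dice_report aggregates per A-scan sets correctly", {
  set.seed(53)
  cib <- matrix(sample(30:40, 60, replace = TRUE), 10, 6)
  cob <- cib + sample(20:30, 60, replace = TRUE)
  seg <- list(cib = cib, cob = cob)
  r <- dice_report(seg, seg, boundary = "band")
  expect_true(all(r$per_ascan == 1))
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)

  # uniform +k shift of the COB on thickness-t A-scans:
  # band sets [cib+1, cob] vs [cib+1, cob+k] -> DC = 2t / (2t + k)
  t <- 25; k <- 4
  seg1 <- list(cib = matrix(30, 8, 4), cob = matrix(30 + t, 8, 4))
  seg2 <- list(cib = matrix(30, 8, 4), cob = matrix(30 + t + k, 8, 4))
  r2 <- dice_report(seg1, seg2, boundary = "band")
  expect_equal(r2$mean, 2 * t / (2 * t + k), tolerance = 1e-12)

  # brute-force oracle on random surfaces
  seg3 <- list(cib = cib + sample(-2:2, 60, replace = TRUE),
               cob = cob + sample(-3:3, 60, replace = TRUE))
  r3 <- dice_report(seg, seg3, boundary = "band")
  oracle <- matrix(0, 10, 6)
  for (i in 1:10) for (j in 1:6) {
    a <- (cib[i, j] + 1):cob[i, j]
    b <- (seg3$cib[i, j] + 1):seg3$cob[i, j]
    oracle[i, j] <- dice_coefficient(a, b)
  }
  expect_equal(r3$per_ascan, oracle, tolerance = 1e-12)
  expect_equal(r3$mean, mean(colMeans(oracle)), tolerance = 1e-12)

  expect_error(dice_report(seg, list(cib = cib[1:5, ], cob = cob[1:5, ])),
               "dimensions")
})

test_that("the mean-rater reference rounds half up per A-scan", {
  m1 <- matrix(c(10, 11, 20, 33), 2, 2)
  m2 <- matrix(c(11, 12, 21, 36), 2, 2)
  expect_equal(average_segmentation(m1, m2),
               matrix(c(11, 12, 21, 35), 2, 2))  # .5 rounds up, 34.5 -> 35
})

test_that("radial position consistency follows the 3-4-5 anchor", {
  df <- tibble::tibble(X = 3, Y = 4)
  out <- position_consistency(df, expert_z = 5)
  expect_equal(out$z, 5)
  expect_true(out$valid)
  out2 <- position_consistency(df, expert_z = 6, epsilon = 0.5)
  expect_false(out2$valid)
  expect_error(position_consistency(df, epsilon = -1), "nonnegative")

  # mm marks re-base to the bottom-left corner
  m <- tibble::tibble(x_mm = 3, y_mm = 12)   # bottom edge -> Y = 0
  out3 <- position_consistency(m, extent_mm = 12, pixels = 1024)
  expect_equal(out3$Y, 0)
  expect_equal(out3$z, 3 * 1024 / 12)
})

test_that("pearson correlation: anchors, flags and affine invariance", {
  expect_equal(as.numeric(pearson_r(1:5, 1:5)), 1)
  expect_equal(as.numeric(pearson_r(1:5, -(1:5))), -1)
  expect_equal(as.numeric(pearson_r(c(1, 2, 3), c(1, 2, 4))), 0.9819805,
               tolerance = 1e-6)
  flag <- pearson_r(rep(1, 4), 1:4)
  expect_true(is.na(flag) && isTRUE(attr(flag, "undefined")))
  set.seed(54)
  u <- rnorm(30); v <- rnorm(30)
  expect_equal(as.numeric(pearson_r(u, v)),
               as.numeric(pearson_r(2 + 3 * u, v)), tolerance = 1e-12)
})

test_that("correlation qualification bins partition [0, 1]", {
  expect_identical(qualify_correlation(0.9406), "very strong correlation")
  expect_identical(qualify_correlation(0.54), "moderate correlation")
  expect_identical(qualify_correlation(0.10), "very weak correlation")
  # boundary ownership: the lower edge belongs to the higher bin
  expect_identical(qualify_correlation(c(0.20, 0.40, 0.60, 0.80)),
                   c("weak correlation", "moderate correlation",
                     "strong correlation", "very strong correlation"))
  # total on a grid; magnitude is used for negative r
  grid <- seq(-1, 1, by = 0.01)
  expect_false(anyNA(qualify_correlation(grid)))
  expect_identical(qualify_correlation(-0.7), "strong correlation")
  expect_error(qualify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("even-count median averages the two middle order statistics", {
  set.seed(55)
  for (i in 1:200) {
    x <- rnorm(sample(2:25, 1))
    s <- sort(x); n <- length(s)
    oracle <- if (n %% 2) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
    expect_identical(median_midpair(x), oracle)
    expect_equal(median_midpair(x), median(x))
  }
})

test_that("mark matching pairs nearest neighbours within tolerance", {
  a <- tibble::tibble(x_mm = c(1, 5, 9), y_mm = c(1, 5, 9))
  b <- tibble::tibble(x_mm = c(5.1, 1.2, 11.9), y_mm = c(5.0, 0.9, 11.9))
  mm <- match_marks(a, b, max_dist_mm = 1)
  expect_identical(nrow(mm), 2L)
  expect_identical(mm$i_a[order(mm$i_a)], c(1L, 2L))
  expect_identical(mm$i_b[order(mm$i_a)], c(2L, 1L))
})

test_that("agreement analysis: constant eyes, labels, drop rules", {
  # 18 eyes with identical pair structure give the common correlation
  set.seed(56)
  base_z <- runif(12, 10, 900)
  pairs <- dplyr::bind_rows(lapply(1:18, function(e) {
    noise <- rnorm(12, 0, 30)
    tibble::tibble(eye_id = paste0("e", e), z_t = base_z + noise,
                   z_t1 = base_z + noise)   # r = 1 per eye
  }))
  rep <- agreement_analysis(pairs)
  expect_equal(rep$median_r, 1)
  expect_identical(rep$label, "very strong correlation")
  expect_identical(nrow(rep$per_eye), 18L)

  # an eye with zero variance is dropped with a warning
  bad <- dplyr::bind_rows(pairs,
                          tibble::tibble(eye_id = "flat", z_t = rep(1, 5),
                                         z_t1 = 1:5))
  expect_warning(r2 <- agreement_analysis(bad), "dropped")
  expect_false("flat" %in% r2$per_eye$eye_id)
})
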