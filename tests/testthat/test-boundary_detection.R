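test_that("initial CIB lands on the lower edge of a bright retinal band", {
  set.seed(21)
  scan <- make_band_bscan()                    # band rows 41..81 (depth 40..80)
  scan <- pmin(pmax(round(scan * matrix(rgamma(length(scan), 40, 40),
                                        nrow(scan))), 0), 255)
  pre <- preprocess_bscan(scan)
  trace <- detect_cib_initial(pre)
  found <- !is.na(trace)
  expect_gt(mean(found), 0.8)
  expect_lt(mean(abs(trace[found] - 80)), 3)
})

test_that("a gap punched in the retinal band yields gaps only there", {
  # the gap must be wider than the ribbon-bridging closing (15 px)
  scan <- make_band_bscan(gap_cols = 39:62)
  pre <- preprocess_bscan(scan)
  trace <- detect_cib_initial(pre)
  # the flanks are detected; the central gap columns (with a safety margin
  # for the 6x6 filtering and morphology) carry no retinal-base evidence
  expect_true(all(!is.na(trace[c(5:33, 68:92)])))
  expect_true(all(abs(trace[c(5:33, 68:92)] - 80) <= 3))
  inside <- trace[46:55]
  expect_true(all(is.na(inside) | abs(inside - 80) > 5))
})

test_that("an all-zero B-scan raises the empty-trace flag", {
  trace <- detect_cib_initial(matrix(0, 64, 64))
  expect_true(all(is.na(trace)))
  expect_true(isTRUE(attr(trace, "empty")))
})

test_that("initial COB follows the deep edge of the choroidal tissue", {
  set.seed(22)
  nz <- 192; ny <- 96
  scan <- matrix(25, nz, ny)
  scan[31:61, ] <- 220                        # retina, CIB* = 60
  scan[62:111, ] <- 150                       # choroid band, COB* = 110
  scan[112:nz, ] <- 60                        # dim sclera
  # dark lumens whose lower envelope hugs the COB
  yy <- matrix(1:ny, nz, ny, byrow = TRUE)
  zm <- matrix(0:(nz - 1), nz, ny)
  for (cy in seq(10, 90, by = 16)) {
    lum <- ((yy - cy) / 7)^2 + ((zm - 102) / 6)^2 <= 1
    scan[lum & zm > 60 & zm <= 108] <- 40
  }
  scan <- pmin(pmax(round(scan * exp(-0.004 * zm) *
                            matrix(rgamma(nz * ny, 30, 30), nz)), 0), 255)
  pre <- preprocess_bscan(scan)
  trace <- detect_cob_initial(pre, rep(60, ny))
  expect_true(all(!is.na(trace)))
  expect_lt(mean(abs(trace - 110)), 4)
})

test_that("too little deep evidence flags the B-scan as low-evidence", {
  trace <- detect_cob_initial(matrix(0, 64, 64), rep(10, 64))
  expect_true(isTRUE(attr(trace, "empty")))
})

test_that("orthogonal smoothing recovers a plane under gross outliers", {
  set.seed(23)
  ny <- 128; nx <- 64
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  plane <- 60 + 0.2 * xx + 0.1 * yy
  noisy <- plane
  idx <- sample(length(plane), round(0.05 * length(plane)))
  noisy[idx] <- noisy[idx] + 50
  sm <- smooth_orthogonal(boundary_surface(noisy, "CIB", "initial", 256),
                          segmentation_params())
  expect_s3_class(sm, "boundary_surface")
  expect_identical(sm$stage, "final")
  expect_lt(sqrt(mean((sm$depth - plane)^2)), 1)

  # inliers barely move when 95% of the surface is clean
  moved <- abs(sm$depth - plane)[-idx]
  expect_lt(quantile(moved, 0.99), 2)
})

test_that("orthogonal smoothing is a near-identity on clean surfaces", {
  const <- matrix(80, 64, 32)
  sm <- smooth_orthogonal(boundary_surface(const, "CIB", "initial", 256),
                          segmentation_params())
  expect_lt(max(abs(sm$depth - 80)), 0.5)

  # a missing B-scan trace is filled between its neighbours
  ny <- 64; nx <- 32
  plane <- 60 + 0.3 * matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  gap <- plane; gap[, 15] <- NA
  sm2 <- smooth_orthogonal(boundary_surface(gap, "CIB", "initial", 256),
                           segmentation_params())
  expect_true(all(sm2$depth[, 15] >= pmin(plane[, 14], plane[, 16]) - 0.5 &
                  sm2$depth[, 15] <= pmax(plane[, 14], plane[, 16]) + 0.5))
})

test_that("segment_volume is deterministic and respects CIB < COB", {
  fix <- cached_small_segmentation(9)
  seg <- fix$seg
  expect_true(all(seg$cib$depth < seg$cob$depth))
  expect_false(anyNA(seg$cib$depth))
  expect_false(anyNA(seg$cob$depth))
  # repeated runs are identical: no random steps anywhere
  seg2 <- suppressMessages(segment_volume(fix$phantom$volume))
  expect_identical(seg$cib$depth, seg2$cib$depth)
  expect_identical(seg$cob$depth, seg2$cob$depth)
})

test_that("segmentation accuracy on a reduced phantom matches ground truth", {
  fix <- cached_small_segmentation(9)
  truth <- fix$phantom$truth
  expect_lt(mean(abs(fix$seg$cib$depth - truth$cib_true$depth)), 2)
  dr <- dice_report(fix$seg, list(cib = truth$cib_true, cob = truth$cob_true),
                    boundary = "band")
  expect_gt(dr$mean, 0.93)
})

test_that("a volume of pure speckle noise fails at volume level", {
  set.seed(24)
  noise <- array(sample(0:120, 256 * 128 * 16, replace = TRUE),
                 dim = c(256, 128, 16))
  expect_error(suppressWarnings(segment_volume(oct_volume(noise))),
               "volume-level failure")
})

test_that("segmentation round trips through volume save/load unchanged", {
  fix <- cached_small_segmentation(9)
  path <- withr::local_tempfile(fileext = ".tif")
  save_volume(fix$phantom$volume, path)
  seg2 <- suppressMessages(segment_volume(load_volume(path)))
  expect_identical(fix$seg$cib$depth, seg2$cib$depth)
  expect_identical(fix$seg$cob$depth, seg2$cob$depth)
})
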