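test_that("phantom generation is reproducible bit-exactly under a seed", {
  sp <- phantom_spec(dims = c(96, 64, 8), cib = 40, retina_top = 20,
                     choroid_thickness = 24, curvature = 4,
                     spca_length_px = 10, n_spca = 3, seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$spca_marks_true$x_mm, b$truth$spca_marks_true$x_mm)
})

test_that("noise-free, flat phantom reproduces the layer reflectivities", {
  sp <- phantom_spec(dims = c(192, 48, 6), speckle_level = 0, curvature = 0,
                     n_spca = 0, vessel_density = 0, seed = 2)
  ph <- generate_phantom(sp, layer_masks = TRUE)
  v <- ph$volume$intensities
  att <- exp(-sp$attenuation_coeff * (0:191))
  # piecewise-constant by layer: every voxel equals its attenuated
  # reflectivity exactly
  expect_true(all(v[10, , ] == round(sp$vitreous_intensity * att[10])))
  expect_true(all(v[60, , ] == round(sp$inner_intensity * att[60])))
  expect_true(all(v[81, , ] == round(sp$rpe_intensity * att[81])))     # z=80
  expect_true(all(v[100, , ] == round(sp$stroma_intensity * att[100])))
  expect_true(all(v[160, , ] == round(sp$sclera_intensity * att[160])))
  # truth surfaces in detector representation, CIB < COB
  expect_s3_class(ph$truth$cib_true, "boundary_surface")
  expect_true(all(ph$truth$cib_true$depth < ph$truth$cob_true$depth))
  expect_true(all(ph$truth$cib_true$depth == sp$cib))
  # layer masks agree with the construction
  expect_identical(sort(unique(as.integer(ph$truth$layers))),
                   c(1L, 2L, 3L, 4L, 6L))
})

test_that("phantom invariants: band ordering and spec validation", {
  expect_error(phantom_spec(retina_top = 90, cib = 80), "ordered")
  expect_error(phantom_spec(dims = c(100, 64, 8)), "axial")  # bands overflow
  expect_error(phantom_spec(speckle_level = -1), "nonnegative")
  expect_error(phantom_spec(stroma_intensity = 0), "reflectivities")
})

test_that("planted SPCA marks appear as dark spots at the interface", {
  ph <- cached_small_segmentation(9)$phantom
  marks <- ph$truth$spca_marks_true
  expect_identical(nrow(marks), 6L)
  fl <- flatten_volume(ph$volume, ph$truth$cob_true)
  st <- extract_enface_stack(fl, 8)
  sl <- st$slices[, , 4]
  ny <- dim(sl)[1]; nx <- dim(sl)[2]
  py <- pmin(round(marks$y_mm * ny / 12) + 1, ny)
  px <- pmin(round(marks$x_mm * nx / 12) + 1, nx)
  dark <- vapply(seq_len(nrow(marks)), function(k) {
    ys <- max(1, py[k] - 4):min(ny, py[k] + 4)
    xs <- max(1, px[k] - 2):min(nx, px[k] + 2)
    min(sl[ys, xs]) < 0.6 * median(sl)
  }, logical(1))
  expect_gt(mean(dark), 0.8)
})

test_that("recovered truth marks reproduce the planted sector distribution", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(10:20, 1)
    sp <- phantom_spec(dims = c(96, 48, 8), cib = 40, retina_top = 20,
                       choroid_thickness = 20, curvature = 2,
                       spca_length_px = 8, n_spca = n, seed = 600 + rep)
    pos <- cbind(x_mm = runif(n, 0.5, 11.5), y_mm = runif(n, 0.5, 11.5))
    sp$spca_positions <- pos
    truth <- generate_phantom(sp)$truth$spca_marks_true
    expect_equal(truth$x_mm, unname(pos[, 1]))
    expect_equal(truth$y_mm, unname(pos[, 2]))
    planted <- compute_distribution(truth, laterality = "OD")
    # direct floor arithmetic over the planted coordinates
    oracle <- table(factor(paste(pmin(pos[, 2] %/% 4, 2),
                                 pmin(pos[, 1] %/% 4, 2)),
                           levels = paste(rep(0:2, each = 3), rep(0:2, 3))))
    expect_identical(planted$count, as.integer(oracle))
    expect_identical(sum(planted$count), n)
  }
})

test_that("perturb_marks models the observer as jitter plus dropout", {
  truth <- make_truth_marks(1, 40)
  # identity when nothing is perturbed
  same <- perturb_marks(truth, 0, 0, seed = 3)
  expect_equal(same$x_mm, truth$x_mm)
  expect_equal(same$y_mm, truth$y_mm)
  # certain dropout empties the set
  expect_identical(nrow(perturb_marks(truth, 0.1, 1, seed = 3)), 0L)
  # mean displacement follows the Rayleigh mean sd * sqrt(pi / 2)
  big <- make_truth_marks(2, 1000)
  j <- perturb_marks(big, 0.2, 0, seed = 4)
  disp <- sqrt((j$x_mm - big$x_mm)^2 + (j$y_mm - big$y_mm)^2)
  expect_lt(abs(mean(disp) - 0.2 * sqrt(pi / 2)) / (0.2 * sqrt(pi / 2)), 0.05)
})

test_that("detector error grows with the phantom speckle level", {
  errs <- vapply(c(0.05, 0.15, 0.35), function(sl) {
    fix <- cached_small_segmentation(9, speckle = sl)
    mean(abs(fix$seg$cob$depth - fix$phantom$truth$cob_true$depth)) +
      mean(abs(fix$seg$cib$depth - fix$phantom$truth$cib_true$depth))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
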