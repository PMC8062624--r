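# Shared fixtures: phantoms and segmentations are expensive, so they are
# generated lazily and cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(seed, speckle = 0.15) {
  key <- sprintf("ph_%d_%g", seed, speckle)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom(
      phantom_spec(seed = seed, speckle_level = speckle))
  .fixture_cache[[key]]
}

cached_segmentation <- function(seed, speckle = 0.15) {
  key <- sprintf("seg_%d_%g", seed, speckle)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressMessages(
      segment_volume(cached_phantom(seed, speckle)$volume))
  .fixture_cache[[key]]
}

# a reduced phantom (fewer B-scans) for tests that need a segmentable
# volume but not the full default scale
small_phantom_spec <- function(seed, speckle = 0.15) {
  phantom_spec(dims = c(axial = 256, lateral = 128, n_bscans = 24),
               seed = seed, speckle_level = speckle, n_spca = 6)
}

cached_small_segmentation <- function(seed, speckle = 0.15) {
  key <- sprintf("sseg_%d_%g", seed, speckle)
  if (is.null(.fixture_cache[[key]])) {
    ph <- generate_phantom(small_phantom_spec(seed, speckle))
    .fixture_cache[[key]] <- list(
      phantom = ph,
      seg = suppressMessages(segment_volume(ph$volume)))
  }
  .fixture_cache[[key]]
}

# random true mark sets for observer-simulation tests
make_truth_marks <- function(eye, n, extent = 12) {
  vessel_marks(tibble::tibble(
    eye_id = paste0("eye", eye), observer_id = "truth", trial_id = 0L,
    x_mm = runif(n, 0.5, extent - 0.5),
    y_mm = runif(n, 0.5, extent - 0.5)
  ), lateral_extent_mm = extent)
}

# two same-observer trials per eye, as the agreement simulation expects
simulate_observer_marks <- function(n_eyes, jitter_sd_mm, drop_prob,
                                    seed_base = 0) {
  set.seed(seed_base)
  sizes <- sample(10:20, n_eyes, replace = TRUE)
  dplyr::bind_rows(lapply(seq_len(n_eyes), function(e) {
    truth <- make_truth_marks(e, sizes[e])
    dplyr::bind_rows(
      perturb_marks(truth, jitter_sd_mm, drop_prob,
                    seed = seed_base + 17 * e, observer_id = "o1",
                    trial_id = 1L),
      perturb_marks(truth, jitter_sd_mm, drop_prob,
                    seed = seed_base + 31 * e + 7, observer_id = "o1",
                    trial_id = 2L)
    )
  }))
}

# a synthetic B-scan with a retinal band (dim inner body over a thin
# bright base, as in real scans where the RPE dominates the reflectivity)
# over a dim background; the CIB is the base's lower edge
make_band_bscan <- function(nz = 192, ny = 96, band_top = 41, band_bottom = 81,
                            base_rows = 3, body_value = 45, base_value = 240,
                            background = 35, gap_cols = integer()) {
  m <- matrix(background, nz, ny)
  m[band_top:band_bottom, ] <- body_value
  m[(band_bottom - base_rows + 1):band_bottom, ] <- base_value
  if (length(gap_cols)) m[band_top:band_bottom, gap_cols] <- background
  m
}
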