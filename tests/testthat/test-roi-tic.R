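test_that("uniform frames give a constant TIC on the frame grid", {
  frames <- array(3.0, dim = c(10, 6, 6))
  cine <- cine_loop(frames, frame_interval = 0.5)
  mask <- matrix(FALSE, 6, 6); mask[2:4, 3:5] <- TRUE
  curve <- extract_tic(cine, roi_mask(mask))
  expect_equal(curve$intensity_au, rep(3.0, 10))
  expect_equal(curve$time_s, seq(0, 4.5, by = 0.5))
})

test_that("a planted TIC is recovered exactly from a noiseless cine", {
  p <- canonical_params()
  sim <- simulate_cine(p, duration = 5, seed = 2)
  curve <- extract_tic(sim$cine, sim$roi)
  expect_equal(curve$intensity_au,
               evaluate_model(p, curve$time_s), tolerance = 1e-12)
})

test_that("extraction is mask-permutation invariant and linear", {
  set.seed(8)
  vals <- matrix(runif(12 * 9, 1, 5), nrow = 12)   # 12 frames, 9 ROI pixels
  build <- function(order) {
    frames <- array(0.5, dim = c(12, 5, 5))
    mask <- matrix(FALSE, 5, 5); mask[2:4, 2:4] <- TRUE
    idx <- which(as.vector(mask))
    flat <- matrix(frames, nrow = 12)
    flat[, idx] <- vals[, order]
    list(cine = cine_loop(array(flat, dim = c(12, 5, 5))), roi = roi_mask(mask))
  }
  a <- build(1:9)
  b <- build(sample(9))   # same multiset of in-mask values per frame
  expect_equal(extract_tic(a$cine, a$roi)$intensity_au,
               extract_tic(b$cine, b$roi)$intensity_au)

  # linearity over same-shape loops
  f1 <- array(runif(12 * 25, 0, 2), dim = c(12, 5, 5))
  f2 <- array(runif(12 * 25, 0, 2), dim = c(12, 5, 5))
  mask <- matrix(FALSE, 5, 5); mask[1:3, 1:2] <- TRUE
  s <- extract_tic(cine_loop(f1 + f2), roi_mask(mask))$intensity_au
  expect_equal(s,
               extract_tic(cine_loop(f1), roi_mask(mask))$intensity_au +
               extract_tic(cine_loop(f2), roi_mask(mask))$intensity_au)
})

test_that("ROI averaging suppresses pixel noise by sqrt(N)", {
  p <- bolus_params(O = 50, A = 0, mu = 1, sigma = 0.5, t0 = 0)  # flat at 50
  sigma_px <- 5
  sds <- vapply(1:6, function(s) {
    sim <- simulate_cine(p, duration = 3, pixel_noise_sd = sigma_px,
                         speckle_sd = 0, background_level = 1, seed = s)
    sd(extract_tic(sim$cine, sim$roi)$intensity_au)
  }, numeric(1))
  n_px <- sum(simulate_cine(p, duration = 3, seed = 1)$roi$mask)
  expect_equal(mean(sds), sigma_px / sqrt(n_px), tolerance = 0.1)
})

test_that("dimension mismatches and empty masks are rejected", {
  cine <- cine_loop(array(1, dim = c(8, 4, 4)))
  expect_error(extract_tic(cine, roi_mask(matrix(TRUE, 5, 5))), "match")
  expect_error(roi_mask(matrix(FALSE, 4, 4)), "at least one")
  expect_error(cine_loop(array(1, dim = c(4, 4, 4))), "at least 8")
  expect_error(cine_loop(array(-1, dim = c(8, 4, 4))), "finite and >= 0")
})

test_that("cine TIFF and mask files round-trip within quantisation", {
  p <- canonical_params()
  sim <- simulate_cine(p, duration = 1, field_px = 96, seed = 3)
  dir <- withr::local_tempdir()
  cine_path <- file.path(dir, "loop.tif")
  write_cine_tiff(sim$cine, cine_path)
  back <- read_cine_tiff(cine_path)
  expect_equal(back$frame_interval, sim$cine$frame_interval)
  expect_lt(max(abs(back$frames - sim$cine$frames)),
            max(sim$cine$frames) / 65535)

  mask_path <- file.path(dir, "loop_mask.tif")
  write_roi_mask(sim$roi, mask_path)
  expect_identical(read_roi_mask(mask_path)$mask, sim$roi$mask)
})

test_that("JSON polygons rasterise to the expected region", {
  # an axis-aligned rectangle spanning rows 3..7, cols 2..9 (pixel centres)
  spec <- list(rows = 10, cols = 12,
               polygon = list(c(2.5, 1.5), c(2.5, 9.5), c(7.5, 9.5), c(7.5, 1.5)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  m <- read_roi_mask(path)$mask
  expected <- matrix(FALSE, 10, 12); expected[3:7, 2:9] <- TRUE
  expect_identical(m, expected)
})

test_that("the planted ellipse area matches its analytic area", {
  sim <- simulate_cine(canonical_params(), diameter_mm = 2.0, pixel_size = 0.02,
                       field_px = 128, duration = 1, seed = 1)
  a <- 2.0 / 2 / 0.02
  b <- 0.75 * a
  expect_equal(sum(sim$roi$mask), pi * a * b, tolerance = 0.05)
})
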