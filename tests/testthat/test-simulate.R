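test_that("simulate_tic is exact without noise and reproducible with it", {
  p <- canonical_params()
  clean <- simulate_tic(p, noise_sd = 0)
  expect_equal(clean$intensity_au, evaluate_model(p, clean$time_s))
  expect_equal(nrow(clean), 55 * 36 + 1)

  a <- simulate_tic(p, noise_sd = 1.5, seed = 42)
  b <- simulate_tic(p, noise_sd = 1.5, seed = 42)
  expect_identical(a$intensity_au, b$intensity_au)
  c <- simulate_tic(p, noise_sd = 1.5, seed = 43)
  expect_false(identical(a$intensity_au, c$intensity_au))
})

test_that("simulated noise has the configured standard deviation", {
  p <- canonical_params()
  clean <- simulate_tic(p, noise_sd = 0)
  noisy <- simulate_tic(p, noise_sd = 0.6, seed = 77)
  resid <- noisy$intensity_au - clean$intensity_au
  expect_equal(sd(resid), 0.6, tolerance = 0.05)
})

test_that("a background-only mask yields a temporally flat TIC", {
  sim <- simulate_cine(canonical_params(), duration = 2, field_px = 64,
                       diameter_mm = 0.9, seed = 4)
  outside <- roi_mask(!sim$roi$mask)
  curve <- extract_tic(sim$cine, outside)
  expect_equal(sd(curve$intensity_au), 0)
})

test_that("study tables have the configured shape and are seed-reproducible", {
  cfg <- study_config(n_per_group = 2, timepoints = "day10", seed = 5)
  st <- simulate_study(cfg)
  expect_equal(nrow(st), 4)
  expect_setequal(unique(st$arm), c("treated", "control"))

  full <- study_config(seed = 6)
  s1 <- simulate_study(full)
  s2 <- simulate_study(full)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * 10 * 3)
  # all drawn measurements respect the positivity truncation
  meas <- s1[, setdiff(names(s1), c("arm", "timepoint", "animal_id"))]
  expect_true(all(as.matrix(meas) > 0))
})

test_that("group draws concentrate around the configured cell means", {
  st <- simulate_study(study_config(seed = 21))
  d10 <- st[st$timepoint == "day10", ]
  m_treat <- mean(d10$follicle_diameter_mm[d10$arm == "treated"])
  m_ctrl <- mean(d10$follicle_diameter_mm[d10$arm == "control"])
  # within 2 standard errors of the configured means (n = 10 per arm)
  expect_lt(abs(m_treat - 0.659), 2 * 0.07 / sqrt(10))
  expect_lt(abs(m_ctrl - 0.170), 2 * 0.05 / sqrt(10))
})

test_that("the recorded ground-truth PE survives the fit round-trip", {
  cfg <- study_config(n_per_group = 2, timepoints = "day20",
                      noise_relative = 0, seed = 9)
  st <- simulate_study(cfg, generate_tics = TRUE)
  for (i in 1:2) {
    fit <- fit_bolus_model(st$tic[[i]], fit_config(seed = i))
    expect_lt(abs(extract_parameters(fit)$pe / st$pe[i] - 1), 0.01)
  }
})

test_that("back-solved curve parameters reproduce the drawn PE and AUC", {
  st <- simulate_study(study_config(n_per_group = 3, timepoints = "day0",
                                    seed = 13), match_auc = TRUE)
  pe_true <- vapply(seq_len(nrow(st)), function(i)
    ceusquant:::bolus_peak_enhancement(
      bolus_params(st$true_O[i], st$true_A[i], st$true_mu[i],
                   st$true_sigma[i], st$true_t0[i])), numeric(1))
  expect_equal(pe_true, st$pe, tolerance = 1e-9)
  expect_equal(st$true_A, st$auc, tolerance = 1e-9)
})

test_that("study CSV round-trips the measurement columns by value", {
  st <- simulate_study(study_config(n_per_group = 2, timepoints = "day0",
                                    seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(st, path)
  back <- read_study_csv(path)
  expect_equal(back$pe, st$pe)
  expect_equal(back$follicle_diameter_mm, st$follicle_diameter_mm)
  expect_identical(back$arm, st$arm)
})
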