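# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms and derivative expressions: the model is rewritten
# from its definition, extrema come from grid search plus refinement of
# finite differences, and integrals from trapezoids / adaptive quadrature.

# Lognormal bolus model, written out from the definition.
oracle_curve <- function(t, O, A, mu, sigma, t0) {
  y <- rep(O, length(t))
  post <- t > t0
  x <- t[post] - t0
  y[post] <- O + A * exp(-(log(x) - mu)^2 / (2 * sigma^2)) /
    (x * sigma * sqrt(2 * pi))
  y
}

# Brute-force perfusion parameters: 1 ms grid over [0, 200] s for the
# amplitude/slope/tangent quantities, adaptive quadrature over (t0, Inf) for
# the area and first moment.
oracle_perfusion <- function(O, A, mu, sigma, t0, time_origin = 0,
                             h = 1e-3, t_max = 200) {
  f <- function(t) oracle_curve(t, O, A, mu, sigma, t0)
  grid <- seq(0, t_max, by = h)
  y <- f(grid)

  i_pk <- which.max(y)
  refine <- stats::optimize(f, c(grid[max(i_pk - 1, 1)], grid[min(i_pk + 1, length(grid))]),
                            maximum = TRUE, tol = 1e-12)
  t_peak <- refine$maximum
  pe <- refine$objective - O

  # max slope via central finite differences, refined
  sl <- (y[-(1:2)] - y[1:(length(y) - 2)]) / (2 * h)
  t_mid <- grid[-c(1, length(grid))]
  keep <- t_mid > t0 & t_mid < t_peak
  i_ms <- which.max(sl[keep])
  t_ms0 <- t_mid[keep][i_ms]
  fd_slope <- function(t) (f(t + h / 2) - f(t - h / 2)) / h
  ms <- stats::optimize(fd_slope, c(t_ms0 - h, t_ms0 + h), maximum = TRUE,
                        tol = 1e-12)
  wir <- ms$objective
  t_i <- ms$maximum - (f(ms$maximum) - O) / wir
  rt <- t_peak - t_i

  # area and first moment in log-time (u = ln(t - t0)), where the integrands
  # are well-behaved Gaussians times e^u; no closed form is used
  dens_u <- function(u) exp(-(u - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  auc <- A * stats::integrate(dens_u, -Inf, Inf, rel.tol = 1e-11,
                              subdivisions = 500L)$value
  moment_u <- function(u)   # exp(u) * dens_u(u) with the exponents combined
    exp(u - (u - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  mtt <- A * stats::integrate(moment_u, -Inf, Inf, rel.tol = 1e-11,
                              subdivisions = 500L)$value / auc
  wi_grid <- seq(max(t_i, t0), t_peak, length.out = 20001)
  wy <- f(wi_grid) - O
  wiauc <- sum((wy[-1] + wy[-length(wy)]) / 2) * diff(wi_grid[1:2])

  tibble::tibble(pe = pe, wir = wir, ttp = t_peak - time_origin, rt = rt,
                 auc = auc, mtt = mtt, pi = auc / mtt, wipi = wiauc / rt,
                 wiauc = wiauc)
}

# Two-sided permutation test for a difference in means.
oracle_permutation_p <- function(x, y, n_perm = 1e4, seed = 1) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n <- length(x)
  withr::with_seed(seed, {
    stats <- replicate(n_perm, {
      idx <- sample.int(length(pool), n)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
  })
  (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
}

# Effects table with both arms identical (the null study conditions).
null_effects <- function() {
  eff <- reference_effects()
  ctrl <- eff[eff$arm == "control", c("timepoint", "parameter", "mean", "sd")]
  dplyr::bind_rows(
    dplyr::mutate(ctrl, arm = "treated"),
    dplyr::mutate(ctrl, arm = "control")
  )
}

canonical_params <- function() bolus_params(O = 5, A = 100, mu = 1, sigma = 0.5, t0 = 2)
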