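#' Estimate baseline level and bolus arrival from a TIC
#'
#' The baseline is the robust central value (median) of the pre-arrival
#' samples; the arrival guess is the first time the intensity exceeds
#' `baseline + k * MAD` of that window. Because the pre-arrival extent is not
#' known a priori, the window starts as the earliest `pre_arrival_fraction`
#' of the record and is refined iteratively: after each arrival detection the
#' window shrinks to the samples before the detected arrival and baseline,
#' MAD and threshold are recomputed, until the window is stable. This removes
#' the bias a fixed window suffers when the bolus arrives inside it. If the
#' curve never exceeds the threshold (or is constant to machine tolerance)
#' arrival is reported as not detected and the first sample time is returned.
#'
#' @param x A TIC (see [tic()]).
#' @param pre_arrival_fraction Fraction of the earliest samples forming the
#'   initial window, in (0, 0.5). Default 0.1.
#' @param k Detection threshold in MADs above baseline. Default 5. When the
#'   window MAD is zero (noiseless data) a small absolute floor of
#'   `1e-8 * max(|y|, 1)` is used instead.
#' @return A one-row tibble: `baseline_au`, `arrival_s`, `arrival_detected`.
#' @export
estimate_baseline <- function(x, pre_arrival_fraction = 0.1, k = 5) {
  x <- validate_tic(x)
  if (pre_arrival_fraction <= 0 || pre_arrival_fraction >= 0.5) {
    stop("`pre_arrival_fraction` must be in (0, 0.5)", call. = FALSE)
  }
  y <- x$intensity_au
  t <- x$time_s
  tol <- 1e-8 * max(abs(y), 1)
  n_pre <- max(2L, ceiling(pre_arrival_fraction * length(y)))

  if (diff(range(y)) <= tol) {
    return(tibble::tibble(baseline_au = stats::median(y[seq_len(n_pre)]),
                          arrival_s = t[1], arrival_detected = FALSE))
  }

  for (iter in 1:30) {
    pre <- y[seq_len(n_pre)]
    baseline <- stats::median(pre)
    thresh <- baseline + k * max(stats::mad(pre), tol)
    idx <- which(y > thresh)
    if (length(idx) == 0) {
      # window may still straddle the arrival, inflating the MAD: shrink it
      if (n_pre > 2L) {
        n_pre <- max(2L, n_pre %/% 2L)
        next
      }
      return(tibble::tibble(baseline_au = baseline, arrival_s = t[1],
                            arrival_detected = FALSE))
    }
    n_new <- max(2L, idx[1] - 1L)
    if (n_new == n_pre) break
    n_pre <- n_new
  }
  tibble::tibble(baseline_au = baseline, arrival_s = t[idx[1]],
                 arrival_detected = TRUE)
}

#' Fitting configuration for the bolus model
#'
#' Bounds and search settings for [fit_bolus_model()]. Defaults: `O` in
#' `[0, max(y)]`, `A` in `[0, 10 * range(y) * duration]`, `mu` in
#' `[ln 0.1, ln 60]`, `sigma` in `[0.05, 3]`, `t0` in `[0, duration/2]`
#' (data-dependent bounds are resolved at fit time), 8 seeded multi-starts,
#' 200 Levenberg-Marquardt iterations per start.
#'
#' @param n_starts Number of multi-start attempts (>= 1).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed for the start perturbations.
#' @param bounds Optional named list overriding any of the default bounds;
#'   each element is `c(lower, upper)` for one of `O`, `A`, `mu`, `sigma`, `t0`.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 8, max_iter = 200, seed = 1L, bounds = list()) {
  stopifnot(n_starts >= 1, max_iter >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 bounds = bounds),
            class = "fit_config")
}

resolve_bounds <- function(config, t, y) {
  duration <- max(t) - min(t)
  def <- list(
    O     = c(0, max(y)),
    A     = c(0, 10 * diff(range(y)) * max(duration, 1)),
    mu    = c(log(0.1), log(60)),
    sigma = c(0.05, 3),
    t0    = c(0, max(t) / 2)
  )
  for (nm in names(config$bounds)) def[[nm]] <- config$bounds[[nm]]
  lower <- vapply(def, `[`, numeric(1), 1L)
  upper <- vapply(def, `[`, numeric(1), 2L)
  list(lower = lower[c("O", "A", "mu", "sigma", "t0")],
       upper = upper[c("O", "A", "mu", "sigma", "t0")])
}

#' Fit the lognormal bolus model to a TIC
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) minimising the residual sum of squares of
#' [evaluate_model()] against the observed curve. Initialisation comes from
#' [estimate_baseline()] and curve landmarks (observed peak height and time);
#' `n_starts` perturbed restarts guard against local minima and the
#' lowest-RSS converged solution is returned. An all-constant curve yields a
#' zero-area ("non-perfused") fit.
#'
#' @param x A TIC with at least 8 samples.
#' @param config A [fit_config()].
#' @param time_origin Reference time for time-to-peak, s. Defaults to the
#'   first sample time (acquisition start, since recording begins at contrast
#'   administration).
#' @return An object of class `bolus_fit`: list with `params`
#'   ([bolus_params()]), `rss`, `converged`, `non_perfused`, `n_starts`,
#'   `time_origin`, and `data` (the input TIC).
#' @seealso [tidy.bolus_fit()], [glance.bolus_fit()], [extract_parameters()]
#' @export
fit_bolus_model <- function(x, config = fit_config(), time_origin = NULL) {
  x <- validate_tic(x)
  t <- x$time_s
  y <- x$intensity_au
  if (is.null(time_origin)) time_origin <- t[1]

  tol <- 1e-8 * max(abs(y), 1)
  if (diff(range(y)) <= tol) {
    params <- bolus_params(O = stats::median(y), A = 0, mu = 0, sigma = 0.5, t0 = 0)
    fit <- new_bolus_fit(params, rss = sum((y - params$O)^2), converged = TRUE,
                         non_perfused = TRUE, n_starts = 0L,
                         time_origin = time_origin, data = x)
    return(fit)
  }

  b <- resolve_bounds(config, t, y)
  base <- estimate_baseline(x)
  start0 <- initial_guess(t, y, base)

  starts <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(i) {
      if (i == 1) return(start0)
      perturb_start(start0, b)
    })
  })

  resid_fn <- function(par) {
    p <- list(O = par[1], A = par[2], mu = par[3], sigma = par[4], t0 = par[5])
    model_curve(p, t) - y
  }

  best <- NULL
  for (s in starts) {
    par0 <- pmin(pmax(unlist(s), b$lower), b$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = b$lower, upper = b$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || rss < best$rss ||
        (conv && !best$converged && rss <= best$rss * (1 + 1e-9))) {
      best <- list(par = res$par, rss = rss, converged = conv)
    }
  }

  if (is.null(best)) {
    params <- bolus_params(start0$O, max(start0$A, 0), start0$mu, start0$sigma,
                           max(start0$t0, 0))
    return(new_bolus_fit(params, rss = sum(resid_fn(unlist(start0))^2),
                         converged = FALSE, non_perfused = FALSE,
                         n_starts = length(starts),
                         time_origin = time_origin, data = x))
  }

  par <- best$par
  params <- bolus_params(O = par[1], A = par[2], mu = par[3],
                         sigma = par[4], t0 = par[5])
  new_bolus_fit(params, rss = best$rss, converged = best$converged,
                non_perfused = params$A == 0, n_starts = length(starts),
                time_origin = time_origin, data = x)
}

# model evaluated from a plain list without class overhead (hot path)
model_curve <- function(p, t) {
  y <- rep(p$O, length(t))
  if (p$A > 0) {
    post <- t > p$t0
    y[post] <- p$O + p$A * stats::dlnorm(t[post] - p$t0, p$mu, max(p$sigma, 1e-10))
  }
  y
}

initial_guess <- function(t, y, base) {
  O0 <- base$baseline_au
  t0_0 <- if (base$arrival_detected) max(base$arrival_s - 0.25, 0) else t[1]
  i_pk <- which.max(y)
  tp <- max(t[i_pk] - t0_0, 0.2)
  sigma0 <- 0.5
  mu0 <- log(tp) + sigma0^2
  pe0 <- max(y[i_pk] - O0, 1e-6 * max(abs(y), 1))
  A0 <- bolus_area_for_pe(pe0, mu0, sigma0)
  list(O = O0, A = A0, mu = mu0, sigma = sigma0, t0 = t0_0)
}

perturb_start <- function(s, b) {
  list(
    O = s$O * stats::runif(1, 0.8, 1.2),
    A = s$A * exp(stats::rnorm(1, 0, 0.5)),
    mu = s$mu + stats::rnorm(1, 0, 0.4),
    sigma = min(max(s$sigma * exp(stats::rnorm(1, 0, 0.3)), b$lower[["sigma"]]),
                b$upper[["sigma"]]),
    t0 = max(s$t0 + stats::rnorm(1, 0, 1), 0)
  )
}

new_bolus_fit <- function(params, rss, converged, non_perfused, n_starts,
                          time_origin, data) {
  structure(
    list(params = params, rss = rss, converged = converged,
         non_perfused = non_perfused, n_starts = n_starts,
         time_origin = time_origin, data = data),
    class = "bolus_fit"
  )
}

#' @export
print.bolus_fit <- function(x, ...) {
  cat("<bolus_fit>",
      if (x$non_perfused) "(non-perfused)" else if (x$converged) "(converged)"
      else "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  rss = %.6g on %d samples, %d start(s), time origin %.3g s\n",
              x$rss, nrow(x$data), x$n_starts, x$time_origin))
  invisible(x)
}

#' Tidy a bolus fit
#'
#' @param x A `bolus_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`).
#' @method tidy bolus_fit
#' @export
tidy.bolus_fit <- function(x, ...) {
  tibble::tibble(
    term = c("O", "A", "mu", "sigma", "t0"),
    estimate = unlist(x$params, use.names = FALSE)
  )
}

#' One-row summary of a bolus fit
#'
#' @param x A `bolus_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `rss`, `converged`, `non_perfused`, `n_starts`,
#'   `n_obs`, `time_origin`.
#' @method glance bolus_fit
#' @export
glance.bolus_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 non_perfused = x$non_perfused, n_starts = x$n_starts,
                 n_obs = nrow(x$data), time_origin = x$time_origin)
}

#' Plot a bolus fit over its data
#'
#' @param object A `bolus_fit`.
#' @param ... Unused.
#' @return A ggplot: observed TIC (points) with the fitted curve (line).
#' @method autoplot bolus_fit
#' @export
autoplot.bolus_fit <- function(object, ...) {
  d <- object$data
  grid <- seq(min(d$time_s), max(d$time_s), length.out = 400)
  fitted <- tibble::tibble(time_s = grid,
                           intensity_au = evaluate_model(object$params, grid))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$intensity_au)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Intensity (a.u.)",
                  subtitle = sprintf("RSS = %.3g", object$rss)) +
    ggplot2::theme_minimal()
}

#' Write / read a fit result as JSON
#'
#' Serialises parameters, RSS, convergence flags and the time origin (not the
#' raw data) so fits can be archived next to their TICs.
#'
#' @param fit A `bolus_fit`.
#' @param path Output path.
#' @return `write_fit_json()`: `path` invisibly. `read_fit_json()`: a list
#'   with `params` ([bolus_params()]) and the scalar fields.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(params = unclass(fit$params), rss = fit$rss,
              converged = fit$converged, non_perfused = fit$non_perfused,
              n_starts = fit$n_starts, time_origin = fit$time_origin)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params <- as_bolus_params(obj$params)
  obj
}
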