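#' Bolus wash-in kinetic model parameters
#'
#' Constructs and validates the parameter set of the lognormal bolus model used
#' to describe a contrast wash-in time-intensity curve (TIC). The model is
#'
#' \deqn{f(t) = O + A \,
#'   \frac{\exp\{-(\ln(t - t_0) - \mu)^2 / (2\sigma^2)\}}{(t - t_0)\,\sigma\sqrt{2\pi}}
#'   \quad (t > t_0), \qquad f(t) = O \quad (t \le t_0),}
#'
#' i.e. a baseline offset plus a lognormal density in time since bolus arrival,
#' scaled by the bolus area `A`. The lognormal form is the standard
#' parametric choice for bolus CEUS wash-in kinetics: it is supported on
#' positive time since arrival, right-skewed, and integrates in closed form, so
#' downstream perfusion parameters (AUC, mean transit time, peak enhancement)
#' have analytic expressions.
#'
#' @param O Baseline offset, linear arbitrary units (a.u.), `>= 0`.
#' @param A Bolus area scale, a.u.·s, `>= 0`. `A` equals the area under the
#'   baseline-subtracted curve to infinite time.
#' @param mu Log-time location parameter, ln(s).
#' @param sigma Log-time spread, dimensionless, `> 0`.
#' @param t0 Bolus arrival time, s, `>= 0`.
#'
#' @return An object of class `bolus_params`: a named list with fields
#'   `O`, `A`, `mu`, `sigma`, `t0`.
#' @seealso [evaluate_model()], [fit_bolus_model()], [extract_parameters()]
#' @export
#' @examples
#' p <- bolus_params(O = 5, A = 100, mu = 1, sigma = 0.5, t0 = 2)
#' evaluate_model(p, c(0, 2, 4.117, 20))
bolus_params <- function(O, A, mu, sigma, t0) {
  O <- unname(O); A <- unname(A); mu <- unname(mu)
  sigma <- unname(sigma); t0 <- unname(t0)
  vals <- c(O = O, A = A, mu = mu, sigma = sigma, t0 = t0)
  if (!all(is.finite(vals))) {
    stop("all bolus model parameters must be finite", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (A < 0) stop("`A` must be >= 0", call. = FALSE)
  if (O < 0) stop("`O` must be >= 0", call. = FALSE)
  if (t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  structure(
    list(O = O, A = A, mu = mu, sigma = sigma, t0 = t0),
    class = "bolus_params"
  )
}

#' @export
print.bolus_params <- function(x, ...) {
  cat("<bolus_params>  lognormal wash-in model\n")
  cat(sprintf(
    "  O = %.4g a.u.   A = %.4g a.u.s   mu = %.4g ln(s)   sigma = %.4g   t0 = %.4g s\n",
    x$O, x$A, x$mu, x$sigma, x$t0
  ))
  invisible(x)
}

as_bolus_params <- function(x) {
  if (inherits(x, "bolus_params")) return(x)
  x <- as.list(x)
  bolus_params(x$O, x$A, x$mu, x$sigma, x$t0)
}

#' Evaluate the bolus model on a time grid
#'
#' Applies the piecewise lognormal bolus formula: exactly `O` at and before
#' arrival `t0`, baseline plus scaled lognormal density afterwards.
#'
#' @param params A [bolus_params()] object (or coercible named list).
#' @param times Numeric vector of times, s, finite and `>= 0`.
#' @return Numeric vector of model intensities, a.u., same length as `times`.
#' @export
evaluate_model <- function(params, times) {
  params <- as_bolus_params(params)
  if (!is.numeric(times) || !all(is.finite(times))) {
    stop("`times` must be finite numeric", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  y <- rep(params$O, length(times))
  if (params$A > 0) {
    post <- times > params$t0
    y[post] <- params$O +
      params$A * stats::dlnorm(times[post] - params$t0,
                               meanlog = params$mu, sdlog = params$sigma)
  }
  y
}

# Closed-form landmarks of the lognormal bolus (used by perfusion extraction
# and by the study simulator's back-solve). All measured from t0 unless noted.
bolus_peak_time <- function(params) {
  params$t0 + exp(params$mu - params$sigma^2)
}

bolus_peak_enhancement <- function(params) {
  if (params$A == 0) return(0)
  params$A * exp(params$sigma^2 / 2 - params$mu) /
    (params$sigma * sqrt(2 * pi))
}

bolus_mean_transit_time <- function(params) {
  exp(params$mu + params$sigma^2 / 2)
}

# Invert the peak-enhancement closed form for A at fixed (mu, sigma).
bolus_area_for_pe <- function(pe, mu, sigma) {
  pe * sigma * sqrt(2 * pi) * exp(mu - sigma^2 / 2)
}

# First derivative of the model for t > t0 (0 elsewhere); vectorised.
bolus_model_slope <- function(params, times) {
  out <- numeric(length(times))
  post <- times > params$t0
  if (params$A == 0 || !any(post)) return(out)
  x <- times[post] - params$t0
  dens <- stats::dlnorm(x, meanlog = params$mu, sdlog = params$sigma)
  # d/dx dlnorm(x) = -dlnorm(x) * (1 + (ln x - mu)/sigma^2) / x
  out[post] <- -params$A * dens * (1 + (log(x) - params$mu) / params$sigma^2) / x
  out
}
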