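#' Welch's unequal-variance t-test from group summaries
#'
#' Two-sample, two-tailed t-test with unequal variances, computed from group
#' means, standard deviations and sizes — the form needed when only published
#' summary statistics are available:
#' \deqn{t = \frac{m_1 - m_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},}
#' with Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'   {(s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1)}}
#' and the p-value from the two-tailed central t distribution.
#'
#' @param mean1,sd1,n1 Summary of group 1 (`sd >= 0`, `n >= 2`).
#' @param mean2,sd2,n2 Summary of group 2.
#' @param alpha Significance level for the flag. Default 0.05.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' # day-10 dominant-follicle diameters, treated vs control, n = 10 per arm
#' welch_from_summary(0.659, 0.07, 10, 0.170, 0.05, 10)
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  vals <- c(mean1, sd1, n1, mean2, sd2, n2)
  if (!all(is.finite(vals))) stop("summaries must be finite", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    stop("degenerate comparison: both groups have zero variance", call. = FALSE)
  }
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(t_stat = t_stat, df = df, p_value = p,
                 significant = p < alpha)
}

#' Welch's t-test from raw samples
#'
#' Summarises each sample (mean, sd, n) and delegates to
#' [welch_from_summary()]; the two routes agree exactly by construction.
#'
#' @param x,y Numeric vectors, each of length `>= 2`, finite.
#' @inheritParams welch_from_summary
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `significant`.
#' @export
welch_from_samples <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  welch_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y), alpha = alpha)
}

#' Per-timepoint two-arm comparison of a study table
#'
#' Runs [welch_from_samples()] for every measured parameter at every
#' timepoint, treated arm versus control arm — one cell per parameter x
#' timepoint, each tested independently at `alpha` (no multiple-testing
#' correction by default, matching the per-cell testing convention of the
#' study design; `adjust = "BH"` applies Benjamini-Hochberg across all cells
#' for reuse beyond that convention). A timepoint missing one arm, or with
#' fewer than 2 animals in an arm, yields an `NA` cell rather than an abort.
#'
#' @param study A study table ([simulate_study()] / [read_study_csv()]):
#'   columns `arm` (`"treated"`/`"control"`), `timepoint`, and numeric
#'   measurement columns.
#' @param parameters Measurement columns to test; defaults to every numeric
#'   column except the ground-truth `true_*` columns.
#' @param alpha Per-cell significance level. Default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `ceus_comparison`: `timepoint`, `parameter`,
#'   per-arm `mean`/`sd`/`n`, `t_stat`, `df`, `p_value`, `significant`.
#' @export
compare_study <- function(study, parameters = NULL, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("arm", "timepoint") %in% names(study)))
  if (is.null(parameters)) {
    num <- names(study)[vapply(study, is.numeric, logical(1))]
    parameters <- setdiff(num, grep("^true_", num, value = TRUE))
  }
  timepoints <- unique(study$timepoint)

  cells <- tidyr::expand_grid(timepoint = timepoints, parameter = parameters)
  out <- purrr::pmap_dfr(cells, function(timepoint, parameter) {
    x <- study[[parameter]][study$arm == "treated" & study$timepoint == timepoint]
    y <- study[[parameter]][study$arm == "control" & study$timepoint == timepoint]
    base <- tibble::tibble(
      timepoint = timepoint, parameter = parameter,
      mean_treated = if (length(x)) mean(x) else NA_real_,
      sd_treated = if (length(x) > 1) stats::sd(x) else NA_real_,
      n_treated = length(x),
      mean_control = if (length(y)) mean(y) else NA_real_,
      sd_control = if (length(y) > 1) stats::sd(y) else NA_real_,
      n_control = length(y)
    )
    res <- tryCatch(welch_from_samples(x, y, alpha = alpha),
                    error = function(e) tibble::tibble(
                      t_stat = NA_real_, df = NA_real_,
                      p_value = NA_real_, significant = NA))
    dplyr::bind_cols(base, res)
  })

  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  }
  class(out) <- c("ceus_comparison", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Plot a study comparison
#'
#' Group means with +/- 1 sd error bars per parameter and timepoint, treated
#' vs control, faceted by parameter on free scales; significant cells are
#' marked.
#'
#' @param object A `ceus_comparison` from [compare_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ceus_comparison
#' @export
autoplot.ceus_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    cols = c("mean_treated", "mean_control"),
    names_to = "arm", names_prefix = "mean_", values_to = "mean"
  )
  long$sd <- ifelse(long$arm == "treated", long$sd_treated, long$sd_control)
  lab <- dplyr::filter(object, .data$significant %in% TRUE)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$mean,
                                          colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Group mean ± sd", colour = "Arm") +
    ggplot2::theme_minimal()
  if (nrow(lab) > 0) {
    p <- p + ggplot2::geom_text(
      data = lab, inherit.aes = FALSE, colour = "black", vjust = 0,
      ggplot2::aes(x = .data$timepoint, label = "*",
                   y = pmax(.data$mean_treated, .data$mean_control)))
  }
  p
}

#' Write a comparison table as CSV
#'
#' @param x A `ceus_comparison`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
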