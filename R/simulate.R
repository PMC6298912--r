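#' Simulate a noisy time-intensity curve
#'
#' Evaluates the bolus model on a uniform acquisition grid and adds i.i.d.
#' Gaussian noise, clipped at zero (intensities are non-negative). Defaults
#' mirror the acquisition protocol: 55 s of wash-in recorded at 36 frames/s
#' starting at contrast administration.
#'
#' @param params A [bolus_params()] object.
#' @param duration Acquisition length, s. Default 55.
#' @param frame_rate Frames per second. Default 36.
#' @param noise_sd Additive Gaussian noise standard deviation, a.u., `>= 0`.
#' @param seed Integer seed; the curve is reproducible given the seed.
#' @return A [tic()] on the grid `0, 1/frame_rate, ..., <= duration`.
#' @export
simulate_tic <- function(params, duration = 55, frame_rate = 36,
                         noise_sd = 0, seed = 1L) {
  params <- as_bolus_params(params)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  times <- seq(0, duration, by = 1 / frame_rate)
  clean <- evaluate_model(params, times)
  if (noise_sd > 0) {
    noisy <- withr::with_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sd))
    clean <- pmax(noisy, 0)
  }
  tic(times, clean, meta = list(true_params = unclass(params),
                                noise_sd = noise_sd, seed = seed))
}

#' Simulate a cine loop with an elliptical perfused region
#'
#' Builds a frame stack in which the pixels inside an elliptical "ovary"
#' follow the bolus model TIC (each in-ROI pixel gets the model value plus
#' optional i.i.d. Gaussian noise), over a static speckled background
#' (multiplicative lognormal-like speckle around a constant level). The
#' returned mask is exactly the planted ellipse, so
#' `extract_tic(simulate_cine(...))` with zero noise reproduces the model
#' curve.
#'
#' @param params A [bolus_params()].
#' @param diameter_mm Ovary major diameter, mm; the study organ ranges over
#'   1-2.5 mm. Default 1.8. The minor diameter is 0.75 of the major.
#' @param pixel_size Pixel size, mm/pixel. Default 0.02.
#' @param field_px Field edge, pixels (square field). Default 128.
#' @param duration,frame_rate Acquisition grid, as in [simulate_tic()].
#' @param pixel_noise_sd Additive Gaussian noise per in-ROI pixel, a.u.
#' @param background_level Mean background intensity, a.u. Default 2.
#' @param speckle_sd Relative sd of the static multiplicative background
#'   speckle. Default 0.1.
#' @param seed Integer seed.
#' @return A list with elements `cine` ([cine_loop()]) and `roi`
#'   ([roi_mask()]).
#' @export
simulate_cine <- function(params, diameter_mm = 1.8, pixel_size = 0.02,
                          field_px = 128, duration = 10, frame_rate = 36,
                          pixel_noise_sd = 0, background_level = 2,
                          speckle_sd = 0.1, seed = 1L) {
  params <- as_bolus_params(params)
  a_px <- diameter_mm / 2 / pixel_size          # semi-major, pixels
  b_px <- 0.75 * a_px                           # semi-minor
  if (2 * a_px >= field_px) {
    stop("ellipse does not fit in the field; enlarge `field_px`", call. = FALSE)
  }
  cy <- (field_px + 1) / 2
  rows <- matrix(seq_len(field_px), field_px, field_px)
  cols <- t(rows)
  mask <- ((rows - cy) / b_px)^2 + ((cols - cy) / a_px)^2 <= 1

  times <- seq(0, duration, by = 1 / frame_rate)
  curve <- evaluate_model(params, times)
  n_frames <- length(times)
  n_in <- sum(mask)

  frames <- withr::with_seed(seed, {
    bg <- background_level *
      pmax(1 + stats::rnorm(field_px^2, 0, speckle_sd), 0)  # static speckle
    flat <- matrix(rep(bg, each = n_frames), nrow = n_frames)  # frame x pixel
    inside <- which(as.vector(mask))
    roi_vals <- matrix(rep(curve, n_in), nrow = n_frames)
    if (pixel_noise_sd > 0) {
      roi_vals <- pmax(roi_vals +
        stats::rnorm(n_frames * n_in, 0, pixel_noise_sd), 0)
    }
    flat[, inside] <- roi_vals
    array(flat, dim = c(n_frames, field_px, field_px))
  })

  list(cine = cine_loop(frames, frame_interval = 1 / frame_rate,
                        pixel_size = pixel_size),
       roi = roi_mask(mask))
}

#' Reference two-arm study effects
#'
#' Per-timepoint group means and standard deviations (treated arm = GnRH-a
#' decapeptyl, control arm = saline) for the two B-mode measurements (ovary
#' and dominant-follicle diameter, mm) and the nine CEUS perfusion parameters,
#' encoding a murine ovarian down-regulation study at days 0, 10 and 20.
#' These are the generative defaults of [study_config()].
#'
#' @return A tibble with columns `timepoint`, `parameter`, `arm`, `mean`, `sd`.
#' @export
reference_effects <- function() {
  # parameter, then day0/10/20 x (treated mean, sd, control mean, sd)
  rows <- list(
    ovary_diameter_mm    = c(2.427, 0.70, 2.039, 0.38,  2.805, 0.66, 2.260, 0.50,  2.470, 0.77, 2.183, 0.48),
    follicle_diameter_mm = c(0.242, 0.07, 0.183, 0.06,  0.659, 0.07, 0.170, 0.05,  0.430, 0.13, 0.235, 0.05),
    pe    = c(80.95, 6.86, 41.80, 9.47,   87.25, 0.21, 88.60, 57.56,  117.10, 18.67, 145.00, 12.73),
    wir   = c(27.83, 15.84, 29.67, 14.00, 58.87, 48.04, 66.25, 68.94, 19.09, 10.35, 98.65, 28.78),
    ttp   = c(5.22, 2.02, 4.07, 1.85,     9.94, 8.10, 4.04, 2.00,     4.19, 0.67, 3.04, 0.62),
    rt    = c(4.27, 1.66, 3.65, 1.58,     9.125, 7.66, 3.460, 1.39,   3.45, 0.74, 2.545, 0.49),
    auc   = c(3145.00, 657.61, 2120.00, 735.39, 5045.00, 2538.51, 2450.00, 1088.94, 362.50, 195.87, 4975.00, 473.76),
    mtt   = c(41.76, 25.51, 59.60, 17.34, 76.13, 26.51, 27.34, 0.23,  42.79, 33.60, 55.82, 14.40),
    pi    = c(86.70, 37.19, 35.30, 1.98,  64.40, 10.89, 89.35, 39.10, 14.84, 16.21, 91.20, 15.27),
    wipi  = c(54.60, 3.82, 29.15, 7.00,   62.80, 4.24, 62.25, 43.06,  11.35, 12.23, 97.70, 8.91),
    wiauc = c(230.00, 73.54, 100.65, 20.29, 589.50, 519.72, 185.50, 62.93, 34.65, 33.87, 246.50, 24.75)
  )
  days <- c("day0", "day10", "day20")
  purrr::map_dfr(names(rows), function(p) {
    v <- rows[[p]]
    tibble::tibble(
      timepoint = rep(days, each = 2),
      parameter = p,
      arm = rep(c("treated", "control"), 3),
      mean = v[c(1, 3, 5, 7, 9, 11)],
      sd = v[c(2, 4, 6, 8, 10, 12)]
    )
  })
}

#' Study-generator configuration
#'
#' Defines the conditions of a simulated two-arm longitudinal study: group
#' sizes, timepoints, per-parameter generative means/sds for each arm
#' ([reference_effects()] by default), the acquisition grid, and TIC noise.
#'
#' @param n_per_group Animals per arm (default 10).
#' @param timepoints Character timepoint labels (subset of the effects
#'   table's).
#' @param effects Effects tibble (`timepoint`, `parameter`, `arm`, `mean`,
#'   `sd`), sds `> 0`.
#' @param duration,frame_rate Acquisition grid for generated TICs.
#' @param noise_relative TIC noise sd as a fraction of each curve's peak
#'   enhancement. Default 0.02.
#' @param seed Integer seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_per_group = 10, timepoints = c("day0", "day10", "day20"),
                         effects = reference_effects(), duration = 55,
                         frame_rate = 36, noise_relative = 0.02, seed = 1L) {
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (any(effects$sd <= 0)) stop("all effect sds must be > 0", call. = FALSE)
  if (duration * frame_rate < 8) stop("acquisition grid too short", call. = FALSE)
  stopifnot(all(timepoints %in% unique(effects$timepoint)))
  structure(list(n_per_group = as.integer(n_per_group), timepoints = timepoints,
                 effects = effects, duration = duration, frame_rate = frame_rate,
                 noise_relative = noise_relative, seed = as.integer(seed)),
            class = "study_config")
}

# normal draw truncated at (0, Inf) by redraw; bounded retries
rtrunc_pos <- function(n, mean, sd, max_tries = 100L) {
  out <- stats::rnorm(n, mean, sd)
  tries <- 0L
  while (any(out <= 0) && tries < max_tries) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    tries <- tries + 1L
  }
  if (any(out <= 0)) {
    stop("could not draw a positive value from N(", mean, ", ", sd, ")",
         call. = FALSE)
  }
  out
}

#' Simulate a full two-arm study table
#'
#' For every arm x timepoint x animal the generator draws each measured
#' parameter (diameters and perfusion parameters) from the configured normal
#' distribution for that cell, truncated at zero. For the CEUS curve it
#' back-solves bolus model parameters so the curve's true peak enhancement
#' equals the drawn `pe` (and, with `match_auc = TRUE`, its area equals the
#' drawn `auc`): `sigma` is fixed at 0.5, `mu` is the log of a 4-8 s transit
#' draw (or solved from `auc` and `pe`), the area `A` follows from the
#' closed-form peak-enhancement expression, arrival `t0` is drawn uniformly
#' in 1-4 s and baseline `O` in 2-8 a.u. With `generate_tics = TRUE` the
#' noisy TIC itself is attached as a list-column.
#'
#' @param config A [study_config()].
#' @param generate_tics Attach simulated TICs (`tic` list-column)? Default
#'   `FALSE` (the parameter draws alone support the statistical comparison).
#' @param match_auc Also match the drawn AUC (solves `mu` instead of drawing
#'   it)? Default `FALSE`.
#' @return A tibble of class `study_table`, one row per animal x timepoint:
#'   `arm`, `timepoint`, `animal_id`, the measurement columns, and
#'   ground-truth curve parameters `true_O`, `true_A`, `true_mu`,
#'   `true_sigma`, `true_t0`.
#' @export
simulate_study <- function(config = study_config(), generate_tics = FALSE,
                           match_auc = FALSE) {
  stopifnot(inherits(config, "study_config"))
  eff <- dplyr::filter(config$effects, .data$timepoint %in% config$timepoints)
  params <- unique(eff$parameter)
  cells <- tidyr::expand_grid(
    arm = c("treated", "control"),
    timepoint = config$timepoints
  )

  tab <- withr::with_seed(config$seed, {
    rows <- purrr::pmap_dfr(cells, function(arm, timepoint) {
      cell_eff <- eff[eff$arm == arm & eff$timepoint == timepoint, ]
      draws <- lapply(params, function(p) {
        e <- cell_eff[cell_eff$parameter == p, ]
        rtrunc_pos(config$n_per_group, e$mean, e$sd)
      })
      names(draws) <- params
      out <- tibble::as_tibble(draws)
      out$arm <- arm
      out$timepoint <- timepoint
      out$animal_id <- sprintf("%s_%02d", substr(arm, 1, 4),
                               seq_len(config$n_per_group))
      out
    })

    # back-solve curve parameters from the drawn PE (and optionally AUC)
    n <- nrow(rows)
    sigma <- rep(0.5, n)
    t0 <- stats::runif(n, 1, 4)
    O <- stats::runif(n, 2, 8)
    if (match_auc && all(c("pe", "auc") %in% params)) {
      A <- rows$auc
      mu <- sigma^2 / 2 + log(A / (rows$pe * sigma * sqrt(2 * pi)))
    } else {
      mu <- log(stats::runif(n, 4, 8))
      A <- bolus_area_for_pe(rows$pe, mu, sigma)
    }
    rows$true_O <- O
    rows$true_A <- A
    rows$true_mu <- mu
    rows$true_sigma <- sigma
    rows$true_t0 <- t0

    if (generate_tics) {
      seeds <- sample.int(.Machine$integer.max, n)
      rows$tic <- purrr::map(seq_len(n), function(i) {
        simulate_tic(
          bolus_params(O[i], A[i], mu[i], sigma[i], t0[i]),
          duration = config$duration, frame_rate = config$frame_rate,
          noise_sd = config$noise_relative * rows$pe[i], seed = seeds[i])
      })
    }
    rows
  })

  front <- c("arm", "timepoint", "animal_id")
  tab <- tab[, c(front, setdiff(names(tab), front))]
  class(tab) <- c("study_table", class(tab))
  attr(tab, "config") <- config
  tab
}

#' Read / write a study table as CSV
#'
#' The `tic` list-column (if present) is dropped on write; everything else
#' round-trips by value.
#'
#' @param x A study table.
#' @param path CSV path.
#' @return `write_study_csv()`: `path` invisibly. `read_study_csv()`: a
#'   `study_table` tibble.
#' @export
write_study_csv <- function(x, path) {
  x <- as.data.frame(x[, !vapply(x, is.list, logical(1))])
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("study_table", class(out))
  out
}
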