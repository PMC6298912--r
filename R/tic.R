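#' Build a time-intensity curve (TIC) tibble
#'
#' A TIC is the sampled mean contrast intensity inside a region of interest
#' over the frames of a cine loop. Throughout the package a TIC is a tibble
#' with columns `time_s` (seconds, strictly increasing, first value >= 0) and
#' `intensity_au` (linear arbitrary units). Provenance (animal id, timepoint,
#' ROI id) travels in the `"meta"` attribute.
#'
#' @param time_s Numeric vector of sample times, s.
#' @param intensity_au Numeric vector of intensities, a.u., same length.
#' @param meta Optional named list of provenance fields.
#' @return A tibble of class `tic` with columns `time_s`, `intensity_au`.
#' @export
#' @examples
#' tic(seq(0, 10, by = 0.5), rexp(21) + 5)
tic <- function(time_s, intensity_au, meta = list()) {
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        intensity_au = as.numeric(intensity_au))
  out <- structure(out, meta = meta, class = c("tic", class(out)))
  validate_tic(out)
}

#' Validate a TIC
#'
#' Checks the TIC invariants: at least 8 samples, equal-length finite columns,
#' strictly increasing non-negative times. Returns the input invisibly-checked
#' (so it chains), or stops with an informative error.
#'
#' @param x A data frame with columns `time_s` and `intensity_au`.
#' @return `x`, classed as `tic`.
#' @export
validate_tic <- function(x) {
  if (!is.data.frame(x) || !all(c("time_s", "intensity_au") %in% names(x))) {
    stop("a TIC needs columns `time_s` and `intensity_au`", call. = FALSE)
  }
  t <- x$time_s
  y <- x$intensity_au
  if (length(t) < 8) stop("a TIC needs at least 8 samples", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    stop("TIC times and intensities must all be finite", call. = FALSE)
  }
  if (t[1] < 0) stop("TIC times must start at or after 0", call. = FALSE)
  if (any(diff(t) <= 0)) stop("TIC times must be strictly increasing", call. = FALSE)
  if (!inherits(x, "tic")) class(x) <- c("tic", class(x))
  x
}

#' Read / write a TIC as delimited text
#'
#' The on-disk format is a two-column CSV with header `time_s,intensity_au`;
#' the reader tolerates `#` comment lines and blank lines.
#'
#' @param path File path.
#' @return `read_tic()`: a validated `tic` tibble. `write_tic()`: `path`,
#'   invisibly.
#' @export
read_tic <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", blank.lines.skip = TRUE,
                        strip.white = TRUE)
  if (!all(c("time_s", "intensity_au") %in% names(df))) {
    stop("TIC file must have header `time_s,intensity_au`: ", path, call. = FALSE)
  }
  tic(df$time_s, df$intensity_au, meta = list(source = path))
}

#' @rdname read_tic
#' @param x A TIC (validated on the way out).
#' @export
write_tic <- function(x, path) {
  x <- validate_tic(x)
  utils::write.csv(as.data.frame(x)[, c("time_s", "intensity_au")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linearise a log-compressed intensity curve
#'
#' CEUS quantification assumes intensities proportional to microbubble
#' concentration. Display data are often log-compressed over a dynamic range
#' `DR` (dB); this helper undoes that compression, mapping a compressed value
#' `y` (on a 0..`y_max` display scale) back to a linear amplitude
#' `10^(DR * (y/y_max - 1) / 20)`, rescaled so `y_max` maps to itself.
#'
#' @param x A TIC whose `intensity_au` is log-compressed display data.
#' @param dynamic_range_db Compression dynamic range, dB. Default 40.
#' @param y_max Full-scale display value; defaults to the observed maximum.
#' @return A `tic` with linearised intensities.
#' @export
linearise_tic <- function(x, dynamic_range_db = 40, y_max = max(x$intensity_au)) {
  x <- validate_tic(x)
  if (dynamic_range_db <= 0) stop("`dynamic_range_db` must be > 0", call. = FALSE)
  if (y_max <= 0) stop("`y_max` must be > 0", call. = FALSE)
  lin <- y_max * 10^(dynamic_range_db * (x$intensity_au / y_max - 1) / 20)
  tic(x$time_s, lin, meta = attr(x, "meta"))
}

#' Plot a TIC
#'
#' @param object A `tic` tibble.
#' @param ... Unused.
#' @return A ggplot object: intensity vs time.
#' @method autoplot tic
#' @export
autoplot.tic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$intensity_au)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}
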