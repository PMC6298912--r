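#' Cine loop and ROI mask containers
#'
#' A cine loop is a 3-D intensity stack (frame x row x column) in linear a.u.,
#' with a fixed frame interval (default 1/36 s, the contrast-mode frame rate
#' of the acquisition protocol) and a pixel size in mm. An ROI mask is a
#' logical matrix matching the spatial dimensions; the region is fixed for the
#' whole loop (the probe is mechanically fixed during acquisition, so no
#' motion tracking is applied).
#'
#' @param frames Numeric 3-D array `(frame, row, column)`, finite, `>= 0`,
#'   at least 8 frames.
#' @param frame_interval Seconds between frames, `> 0`. Default `1/36`.
#' @param pixel_size Pixel edge length, mm/pixel. Default 0.02.
#' @return `cine_loop()`: an object of class `cine_loop`.
#' @export
cine_loop <- function(frames, frame_interval = 1 / 36, pixel_size = 0.02) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("`frames` must be a 3-D array (frame, row, column)", call. = FALSE)
  }
  if (dim(frames)[1] < 8) stop("a cine loop needs at least 8 frames", call. = FALSE)
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("frame intensities must be finite and >= 0", call. = FALSE)
  }
  if (frame_interval <= 0) stop("`frame_interval` must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "cine_loop")
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_loop> %d frames of %d x %d px, dt = %.5g s (%.4g s total), %.3g mm/px\n",
              d[1], d[2], d[3], x$frame_interval, (d[1] - 1) * x$frame_interval,
              x$pixel_size))
  invisible(x)
}

#' @rdname cine_loop
#' @param mask Logical matrix (rows x columns) with at least one `TRUE` pixel.
#' @return `roi_mask()`: an object of class `roi_mask`.
#' @export
roi_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("ROI mask must contain at least one pixel", call. = FALSE)
  structure(list(mask = mask), class = "roi_mask")
}

#' Extract a mean-intensity TIC from a cine loop
#'
#' The intensity at frame `k` is the arithmetic mean of the pixels inside the
#' ROI mask; times are `k * frame_interval` with frame 0 at acquisition start.
#'
#' @param cine A [cine_loop()].
#' @param roi An [roi_mask()] whose dimensions match the frames.
#' @return A [tic()] with one sample per frame.
#' @export
extract_tic <- function(cine, roi) {
  if (!inherits(cine, "cine_loop")) stop("`cine` must be a cine_loop", call. = FALSE)
  if (!inherits(roi, "roi_mask")) stop("`roi` must be an roi_mask", call. = FALSE)
  d <- dim(cine$frames)
  if (!all(dim(roi$mask) == d[2:3])) {
    stop("ROI mask dimensions must match the frame dimensions", call. = FALSE)
  }
  flat <- matrix(cine$frames, nrow = d[1])  # frame x pixel, column-major spatial
  inside <- as.vector(roi$mask)
  intens <- rowMeans(flat[, inside, drop = FALSE])
  tic((seq_len(d[1]) - 1L) * cine$frame_interval,
      intens, meta = list(n_roi_pixels = sum(inside)))
}

#' Read / write a cine loop as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame. Because baseline TIFF stores values in `[0, 1]`,
#' intensities are scaled by a factor recorded in the sidecar
#' (`<path>.json`: `frame_interval_s`, `pixel_size_mm`, `intensity_scale`)
#' and rescaled on read.
#'
#' @param cine A [cine_loop()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_cine_tiff()`: `path` invisibly. `read_cine_tiff()`: a
#'   `cine_loop`.
#' @export
write_cine_tiff <- function(cine, path) {
  scale <- max(cine$frames, 1e-12)
  pages <- lapply(seq_len(dim(cine$frames)[1]),
                  function(k) cine$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(frame_interval_s = cine$frame_interval,
         pixel_size_mm = cine$pixel_size,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_tiff
#' @export
read_cine_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]] * side$intensity_scale
  cine_loop(frames, frame_interval = side$frame_interval_s,
            pixel_size = side$pixel_size_mm)
}

#' Read an ROI mask from TIFF or a JSON polygon
#'
#' A single-page TIFF is thresholded at 0.5 (0/255 convention). A JSON file
#' `{"rows": r, "cols": c, "polygon": [[row, col], ...]}` is rasterised with
#' the even-odd rule at pixel centres.
#'
#' @param path Path to a `.tif`/`.tiff` or `.json` mask.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    poly <- matrix(unlist(spec$polygon), ncol = 2, byrow = is.list(spec$polygon))
    if (is.list(spec$polygon)) poly <- do.call(rbind, spec$polygon)
    roi_mask(rasterise_polygon(poly, spec$rows, spec$cols))
  } else {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    roi_mask(img > 0.5)
  }
}

#' @rdname read_roi_mask
#' @param roi An [roi_mask()] (written as 0/1 single-page TIFF).
#' @export
write_roi_mask <- function(roi, path) {
  tiff::writeTIFF(roi$mask * 1, path, bits.per.sample = 8)
  invisible(path)
}

# Even-odd rule point-in-polygon at pixel centres. poly is an n x 2 matrix of
# (row, col) vertices in pixel coordinates.
rasterise_polygon <- function(poly, rows, cols) {
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  mask <- matrix(FALSE, rows, cols)
  px <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > px$row) != (yj > px$row)) &
      (px$col < (xj - xi) * (px$row - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(px$row, px$col)] <- inside
  mask
}
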