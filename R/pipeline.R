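#' Pipeline configuration
#'
#' Collects paths, fitting settings and extraction conventions for
#' [run_pipeline()].
#'
#' @param input_dir Directory of inputs: TIC CSVs (`time_s,intensity_au`),
#'   and/or cine loops (`<stem>.tif` + `<stem>.tif.json` sidecar with an ROI
#'   mask at `<stem>_mask.tif` or `<stem>_mask.json`), optionally a
#'   `manifest.csv` (`file,arm,timepoint,animal_id`) enabling the two-arm
#'   comparison, or a ready-made `study.csv` study table.
#' @param output_dir Directory for results (created if missing).
#' @param fit A [fit_config()].
#' @param wiauc_from Wash-in integration start convention, see
#'   [extract_parameters()].
#' @param log_compressed Are input intensities log-compressed display data?
#'   If `TRUE` they are linearised with [linearise_tic()] before fitting.
#' @param dynamic_range_db Dynamic range for linearisation, dB. Default 40.
#' @param alpha Significance level for the comparison. Default 0.05.
#' @param seed Integer master seed (propagated to the fit configuration).
#' @param verbose Print per-item progress?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, fit = fit_config(),
                            wiauc_from = c("tangent", "arrival"),
                            log_compressed = FALSE, dynamic_range_db = 40,
                            alpha = 0.05, seed = 1L, verbose = FALSE) {
  wiauc_from <- match.arg(wiauc_from)
  if (!dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  }
  fit$seed <- as.integer(seed)
  structure(list(input_dir = input_dir, output_dir = output_dir, fit = fit,
                 wiauc_from = wiauc_from, log_compressed = log_compressed,
                 dynamic_range_db = dynamic_range_db, alpha = alpha,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

# md5 over the canonical JSON of the analysis-semantic fields: fitting
# settings, extraction conventions, alpha and seed — not data locations or
# verbosity, so the same analysis of the same data hashes identically
# wherever it is run from.
config_hash <- function(config) {
  sem <- unclass(config)
  sem$verbose <- NULL
  sem$input_dir <- NULL
  sem$output_dir <- NULL
  sem$fit <- unclass(sem$fit)
  json <- jsonlite::toJSON(sem, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full quantification pipeline over a directory
#'
#' For every input item: cine loops are reduced to TICs over their ROI mask
#' ([extract_tic()]), TICs are (optionally linearised and) fitted with the
#' bolus model, and the nine perfusion parameters are extracted. If a
#' `manifest.csv` assigns arms and timepoints, the per-animal parameters are
#' assembled into a study table and compared arm-against-arm per timepoint;
#' a ready-made `study.csv` is compared directly. Failures are recorded
#' per item and the pipeline continues over the remaining items.
#'
#' Outputs written to `output_dir`: `parameters.csv` (one row per item),
#' `comparison.csv` (when a comparison was possible), `fits/<stem>.json`,
#' and `log.json` (package version, seed, config hash, per-item status —
#' no timestamps, so a rerun with the same seed and config is byte-identical).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `parameters` (tibble), `comparison` (tibble or
#'   `NULL`), `log` (list), `n_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  in_dir <- config$input_dir
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)

  all_csv <- list.files(in_dir, pattern = "\\.csv$", ignore.case = TRUE)
  tifs <- list.files(in_dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  tifs <- tifs[!grepl("_mask\\.tiff?$", tifs, ignore.case = TRUE)]
  tic_files <- setdiff(all_csv, c("manifest.csv", "study.csv"))
  study_file <- file.path(in_dir, "study.csv")

  if (length(tic_files) == 0 && length(tifs) == 0 && !file.exists(study_file)) {
    stop("no inputs found in ", in_dir, call. = FALSE)
  }

  items <- c(tic_files, tifs)
  status <- character(0)
  rows <- list()
  for (f in items) {
    if (config$verbose) message("processing ", f)
    res <- tryCatch({
      curve <- if (grepl("\\.csv$", f, ignore.case = TRUE)) {
        read_tic(file.path(in_dir, f))
      } else {
        stem <- sub("\\.tiff?$", "", f, ignore.case = TRUE)
        mask_path <- Filter(file.exists, file.path(in_dir, paste0(
          stem, c("_mask.tif", "_mask.tiff", "_mask.json"))))
        if (length(mask_path) == 0) stop("no ROI mask for ", f)
        extract_tic(read_cine_tiff(file.path(in_dir, f)),
                    read_roi_mask(mask_path[[1]]))
      }
      if (config$log_compressed) {
        curve <- linearise_tic(curve, config$dynamic_range_db)
      }
      fit <- fit_bolus_model(curve, config$fit)
      write_fit_json(fit, file.path(out_dir, "fits",
                                    paste0(sub("\\.[^.]+$", "", f), ".json")))
      pars <- extract_parameters(fit, wiauc_from = config$wiauc_from)
      dplyr::bind_cols(tibble::tibble(file = f, converged = fit$converged,
                                      non_perfused = fit$non_perfused,
                                      rss = fit$rss), pars)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      status[f] <- paste("FAILED:", res)
    } else {
      status[f] <- "ok"
      rows[[f]] <- res
    }
  }

  parameters <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  if (!is.null(parameters)) {
    utils::write.csv(as.data.frame(parameters),
                     file.path(out_dir, "parameters.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  comparison <- NULL
  manifest_file <- file.path(in_dir, "manifest.csv")
  if (!is.null(parameters) && file.exists(manifest_file)) {
    manifest <- utils::read.csv(manifest_file, stringsAsFactors = FALSE)
    study <- dplyr::inner_join(tibble::as_tibble(manifest), parameters,
                               by = "file")
    if (length(unique(study$arm)) == 2) {
      comparison <- compare_study(
        study,
        parameters = c("pe", "wir", "ttp", "rt", "auc", "mtt", "pi",
                       "wipi", "wiauc"),
        alpha = config$alpha)
    }
  } else if (file.exists(study_file)) {
    comparison <- compare_study(read_study_csv(study_file),
                                alpha = config$alpha)
    status["study.csv"] <- "ok"
  }
  if (!is.null(comparison)) {
    write_comparison_csv(comparison, file.path(out_dir, "comparison.csv"))
  }

  log <- list(
    package = "ceusquant",
    version = as.character(utils::packageVersion("ceusquant")),
    seed = config$seed,
    config_hash = config_hash(config),
    items = as.list(status)
  )
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  n_failed <- sum(grepl("^FAILED", status))
  if (n_failed > 0) {
    warning(n_failed, " item(s) failed; see log.json", call. = FALSE)
  }
  invisible(list(parameters = parameters, comparison = comparison,
                 log = log, n_failed = n_failed))
}
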