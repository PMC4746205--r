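#' Configuration of a phantom validation experiment
#'
#' Bundles everything needed to reproduce an end-to-end experiment: the
#' phantom size grid, the shared phantom parameters, the edge-detection
#' parameters, the shift model and the master seed. Serialises losslessly
#' to JSON via [write_experiment_config()].
#'
#' @param size_grid data frame with columns \code{edv} and \code{esv}, ml.
#' @param phantom a [phantom_spec()] supplying the shared phantom
#'   parameters (its own edv/esv are overridden per study).
#' @param params an [edge_params()]; detection parameters shared by both
#'   modes (the mode field itself is ignored: both modes are always run).
#' @param shift a [shift_model()].
#' @param seed master integer seed; study i uses \code{seed + i}.
#' @param out_dir optional directory for the JSON/CSV report.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(size_grid, phantom = phantom_spec(120, 48),
                              params = edge_params(), shift = shift_model(),
                              seed = 1L, out_dir = NULL) {
  size_grid <- as.data.frame(size_grid)
  names(size_grid)[1:2] <- c("edv", "esv")
  if (any(size_grid$esv >= size_grid$edv))
    stop("every pair must satisfy esv < edv")
  structure(list(size_grid = size_grid, phantom = phantom, params = params,
                 shift = shift, seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Write / read an experiment configuration as JSON
#'
#' The round trip \code{read_experiment_config(write_experiment_config(x))}
#' reproduces the configuration exactly.
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return \code{write_experiment_config} returns \code{path} invisibly;
#'   \code{read_experiment_config} returns the \code{experiment_config}.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(size_grid = config$size_grid,
            phantom = unclass(config$phantom),
            params = unclass(config$params),
            shift = list(s0 = config$shift$s0, v0 = config$shift$v0),
            seed = config$seed, out_dir = config$out_dir)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- x$phantom
  experiment_config(
    size_grid = as.data.frame(x$size_grid),
    phantom = phantom_spec(ph$edv_true, ph$esv_true, ph$wall_thickness_ed,
                           ph$long_axis_ratio, ph$n_frames, ph$grid_shape,
                           ph$voxel_size, ph$psf_fwhm, ph$total_counts,
                           ph$seed),
    params = do.call(edge_params, as.list(x$params)),
    shift = shift_model(x$shift$s0, x$shift$v0),
    seed = x$seed,
    out_dir = x$out_dir)
}

#' Run a phantom validation experiment
#'
#' Generates one phantom per size-grid row, quantifies each study in both
#' fixed and volume-corrected mode (the segmentation is shared; the modes
#' differ only in the outward shift), and assembles the method-comparison
#' report: per-study records, regression of measured on true values,
#' absolute and percent Bland-Altman summaries, EF-error correlation with
#' true EF, and small-heart counts per mode (ESV <= 20 ml rule).
#' Deterministic given the configuration seed.
#'
#' @param config an [experiment_config()].
#' @param verbose emit progress messages.
#' @return an object of class \code{validation_report}: list with
#'   \code{records} (data frame, one row per study) and \code{stats}
#'   (per mode and per quantity). Written as JSON + CSV when the
#'   configuration has an \code{out_dir}.
#' @export
run_validation <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  studies <- sweep_phantoms(config$size_grid, config$phantom, config$seed)
  rows <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    rec <- tryCatch(
      .quantify_engine(st, config$params, config$shift),
      error = function(e) stop(sprintf("study %d (EDV %.1f, ESV %.1f): %s",
                                       i, config$size_grid$edv[i],
                                       config$size_grid$esv[i],
                                       conditionMessage(e)), call. = FALSE))
    tr <- phantom_truth(st)
    ff <- .lv_function(rec$vol_fixed)
    fc <- .lv_function(rec$vol_corrected)
    rows[[i]] <- data.frame(
      study = i, edv_true = tr$edv, esv_true = tr$esv, ef_true = tr$ef,
      edv_fixed = ff$edv, esv_fixed = ff$esv, ef_fixed = ff$ef,
      edv_corrected = fc$edv, esv_corrected = fc$esv, ef_corrected = fc$ef,
      v_mid = rec$v_mid, shift_mm = rec$shift_mm,
      small_fixed = ff$small_heart, small_corrected = fc$small_heart)
    if (verbose)
      message(sprintf("study %d/%d: truth %.1f/%.1f ml, fixed %.1f/%.1f ml, corrected %.1f/%.1f ml",
                      i, length(studies), tr$edv, tr$esv,
                      ff$edv, ff$esv, fc$edv, fc$esv))
  }
  records <- do.call(rbind, rows)
  modes <- c("fixed", "corrected")
  stats_out <- list()
  for (mode in modes) {
    for (q in c("edv", "esv", "ef")) {
      meas <- records[[paste0(q, "_", mode)]]
      tru <- records[[paste0(q, "_true")]]
      key <- paste0(q, "_", mode)
      stats_out[[key]] <- list(
        regression = if (nrow(records) >= 3) unclass(linreg_see(tru, meas)) else NULL,
        bland_altman_absolute = unclass(bland_altman(meas, tru, "absolute"))[
          c("bias", "sd", "loa_low", "loa_high", "n")],
        bland_altman_percent = unclass(bland_altman(meas, tru, "percent"))[
          c("bias", "sd", "loa_low", "loa_high", "n")])
    }
    ef_err <- records[[paste0("ef_", mode)]] - records$ef_true
    stats_out[[paste0("ef_error_vs_true_ef_", mode)]] <-
      if (stats::sd(records$ef_true) > 0 && nrow(records) >= 3)
        stats::cor(ef_err, records$ef_true) else NA_real_
  }
  report <- structure(list(
    records = records,
    stats = stats_out,
    small_heart_counts = c(fixed = sum(records$small_fixed),
                           corrected = sum(records$small_corrected)),
    seed = config$seed,
    n_studies = nrow(records)), class = "validation_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (verbose)
      message("report written to ", config$out_dir)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Phantom validation report: %d studies (seed %d)\n",
              x$n_studies, x$seed))
  cat(sprintf("  small hearts (ESV <= 20 ml): fixed %d, corrected %d\n",
              x$small_heart_counts["fixed"], x$small_heart_counts["corrected"]))
  pct <- function(m, q) {
    ba <- x$stats[[paste0(q, "_", m)]]$bland_altman_percent
    sprintf("%+.1f%% [%.1f, %.1f]", ba$bias, ba$loa_low, ba$loa_high)
  }
  for (q in c("edv", "esv", "ef"))
    cat(sprintf("  %s percent difference vs truth: fixed %s, corrected %s\n",
                toupper(q), pct("fixed", q), pct("corrected", q)))
  cat(sprintf("  EF-error vs true-EF correlation: fixed %.2f, corrected %.2f\n",
              x$stats$ef_error_vs_true_ef_fixed,
              x$stats$ef_error_vs_true_ef_corrected))
  invisible(x)
}
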