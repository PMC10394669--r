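# End-to-end pipeline: load/filter -> fit -> filter/report -> export, with a
# serialized run log sufficient to re-execute the run.

#' Configuration of a full analysis run
#'
#' Collects every knob of the four-step workflow (load and filter curves,
#' fit, filter fits and summarize peaks, export).  Every field except the
#' input path has a default.
#'
#' @param input Path to a correlogram CSV/TSV (see [read_correlograms()]).
#' @param output_dir Directory receiving the artifacts.
#' @param setup A [dls_setup()].
#' @param format,tau_unit,sep Passed to [read_correlograms()].
#' @param min_intercept,max_baseline_sd,baseline_fraction Raw-curve filter
#'   thresholds, see [filter_raw_curves()].
#' @param alpha A number for a fixed regularization parameter or `"lcurve"`
#'   for automatic selection.
#' @param lcurve_start,lcurve_stop,lcurve_step Alpha-ladder exponents used
#'   when `alpha = "lcurve"`.
#' @param n_grid,r_min_nm,r_max_nm Radius-grid parameters.
#' @param max_residual_rms Fit filter threshold, see [filter_fits()].
#' @param rois List of regions of interest (nm) for [peak_search()].
#' @return An object of class `dls_run_config`.
#' @export
run_config <- function(input, output_dir = ".", setup = dls_setup(),
                       format = "auto", tau_unit = "us", sep = "auto",
                       min_intercept = 0.05, max_baseline_sd = 0.01,
                       baseline_fraction = 0.2,
                       alpha = 0.01, lcurve_start = -6, lcurve_stop = 1,
                       lcurve_step = 0.2,
                       n_grid = 200, r_min_nm = 0.1, r_max_nm = 1e6,
                       max_residual_rms = 0.01,
                       rois = list(c(1, 100))) {
  .assert_setup(setup)
  if (!(identical(alpha, "lcurve") ||
        (is.numeric(alpha) && length(alpha) == 1L && alpha >= 0)))
    stop("'alpha' must be a non-negative number or \"lcurve\"", call. = FALSE)
  structure(list(input = input, output_dir = output_dir, setup = setup,
                 format = format, tau_unit = tau_unit, sep = sep,
                 min_intercept = min_intercept,
                 max_baseline_sd = max_baseline_sd,
                 baseline_fraction = baseline_fraction, alpha = alpha,
                 lcurve_start = lcurve_start, lcurve_stop = lcurve_stop,
                 lcurve_step = lcurve_step, n_grid = n_grid,
                 r_min_nm = r_min_nm, r_max_nm = r_max_nm,
                 max_residual_rms = max_residual_rms, rois = rois),
            class = "dls_run_config")
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$setup <- list(wavelength_nm = config$setup$wavelength * 1e9,
                    angle_deg = config$setup$angle * 180 / pi,
                    temperature_C = config$setup$temperature - 273.15,
                    refractive_index = config$setup$refractive_index,
                    viscosity_Pa_s = config$setup$viscosity)
  out
}

#' Rebuild a run configuration from a run log
#'
#' @param path Path to the `run_log.json` written by [run_pipeline()].
#' @return The `dls_run_config` of the logged run.
#' @export
load_run_config <- function(path) {
  log <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- log$config
  rois <- cfg$rois
  if (is.matrix(rois)) rois <- lapply(seq_len(nrow(rois)), function(i) rois[i, ])
  if (is.data.frame(rois)) rois <- lapply(seq_len(nrow(rois)), function(i) as.numeric(rois[i, ]))
  run_config(input = cfg$input, output_dir = cfg$output_dir,
             setup = do.call(dls_setup, as.list(cfg$setup)),
             format = cfg$format, tau_unit = cfg$tau_unit, sep = cfg$sep,
             min_intercept = cfg$min_intercept,
             max_baseline_sd = cfg$max_baseline_sd,
             baseline_fraction = cfg$baseline_fraction,
             alpha = if (identical(cfg$alpha, "lcurve")) "lcurve" else as.numeric(cfg$alpha),
             lcurve_start = cfg$lcurve_start, lcurve_stop = cfg$lcurve_stop,
             lcurve_step = cfg$lcurve_step, n_grid = cfg$n_grid,
             r_min_nm = cfg$r_min_nm, r_max_nm = cfg$r_max_nm,
             max_residual_rms = cfg$max_residual_rms, rois = rois)
}

#' Run the full analysis pipeline
#'
#' Loads correlograms, filters raw curves, fits every survivor (fixed alpha
#' or L-curve selection), filters the fits on residuals, summarizes peaks per
#' region of interest and writes all artifacts to the output directory:
#' `filter_report.csv`, `distribution.csv`, `peaks.csv`, `fits.json`,
#' `lcurve_<id>.csv` (when alpha is selected automatically) and
#' `run_log.json` (the configuration plus every per-curve decision; it
#' suffices to re-execute the run via [load_run_config()]).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fits`, `kept_fits`, `filter_report`,
#'   `peaks`, `log`, and `status` (0 iff at least one curve was fitted).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dls_run_config"))
  if (!file.exists(config$input))
    stop("input not readable: ", config$input, call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  curves <- read_correlograms(config$input, format = config$format,
                              tau_unit = config$tau_unit, sep = config$sep)
  flt <- filter_raw_curves(curves, min_intercept = config$min_intercept,
                           max_baseline_sd = config$max_baseline_sd,
                           baseline_fraction = config$baseline_fraction)
  utils::write.csv(flt$report,
                   file.path(config$output_dir, "filter_report.csv"),
                   row.names = FALSE)

  grid <- radius_grid(config$setup, n = config$n_grid,
                      r_min_nm = config$r_min_nm, r_max_nm = config$r_max_nm)
  alphas <- alpha_sequence(config$lcurve_start, config$lcurve_stop,
                           config$lcurve_step)
  fits <- list(); events <- list()
  for (cv in flt$kept) {
    res <- tryCatch(fit_curve(cv, config$setup, alpha = config$alpha,
                              grid = grid, alphas = alphas),
                    error = function(e) e)
    if (inherits(res, "error")) {
      events[[cv$id]] <- list(id = cv$id, fitted = FALSE,
                              error = conditionMessage(res))
      next
    }
    fits[[cv$id]] <- res
    events[[cv$id]] <- list(id = cv$id, fitted = TRUE, beta = res$beta,
                            alpha = res$alpha,
                            truncation_index = res$truncation_index,
                            fidelity = res$fidelity, penalty = res$penalty,
                            rms_residual = sqrt(mean(res$residuals_g2^2)))
    if (!is.null(res$lcurve)) {
      utils::write.csv(res$lcurve$table,
                       file.path(config$output_dir,
                                 paste0("lcurve_", cv$id, ".csv")),
                       row.names = FALSE)
    }
  }

  kept_fits <- filter_fits(fits, config$max_residual_rms)
  write_distribution(kept_fits,
                     file.path(config$output_dir, "distribution.csv"))

  peaks <- if (length(kept_fits)) {
    do.call(rbind, lapply(kept_fits, function(f) {
      ps <- peak_search(intensity_distribution(f), config$rois)
      cbind(curve_id = f$id, ps)
    }))
  } else {
    data.frame(curve_id = character(0))
  }
  utils::write.csv(peaks, file.path(config$output_dir, "peaks.csv"),
                   row.names = FALSE)

  log <- list(config = .config_as_list(config),
              n_input = length(curves),
              n_kept_raw = length(flt$kept),
              n_fitted = length(fits),
              n_kept_fits = length(kept_fits),
              curves = events)
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unname(events),
                       file.path(config$output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits = fits, kept_fits = kept_fits,
                 filter_report = flt$report, peaks = peaks, log = log,
                 status = if (length(fits) >= 1L) 0L else 1L))
}
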