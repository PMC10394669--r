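# Correlogram container, CSV/TSV import/export, and raw-curve quality filters.

#' Construct a correlogram
#'
#' A correlogram is one normalized second-order autocorrelation curve
#' g2(tau) as exported by a DLS instrument (or produced by
#' [simulate_correlogram()]).
#'
#' @param tau_s Lag times in seconds; strictly increasing, all > 0, length >= 4.
#' @param g2 Normalized second-order autocorrelation values, same length.
#' @param id Character label for the curve.
#' @param metadata Optional named list (sample, dilution, instrument, ...).
#' @return An object of class `dls_correlogram`.
#' @export
correlogram <- function(tau_s, g2, id = "curve", metadata = list()) {
  tau_s <- as.numeric(tau_s); g2 <- as.numeric(g2)
  if (length(tau_s) != length(g2))
    stop("'tau_s' and 'g2' must have the same length", call. = FALSE)
  if (length(tau_s) < 4L)
    stop("a correlogram needs at least 4 points", call. = FALSE)
  if (any(!is.finite(tau_s)) || any(!is.finite(g2)))
    stop("non-finite values in correlogram", call. = FALSE)
  if (tau_s[1] <= 0)
    stop("lag times must be strictly positive", call. = FALSE)
  bad <- which(diff(tau_s) <= 0)
  if (length(bad))
    stop("lag times must be strictly increasing (violation at row ",
         bad[1] + 1L, ")", call. = FALSE)
  structure(list(id = as.character(id), tau = tau_s, g2 = g2,
                 metadata = metadata),
            class = "dls_correlogram")
}

#' @export
print.dls_correlogram <- function(x, ...) {
  cat(sprintf("Correlogram '%s': %d points, tau %.3g-%.3g s, g2 range [%.4f, %.4f]\n",
              x$id, length(x$tau), min(x$tau), max(x$tau), min(x$g2), max(x$g2)))
  invisible(x)
}

.tau_unit_factor <- function(unit) {
  switch(unit, s = 1, ms = 1e-3, us = 1e-6,
         stop("unknown lag-time unit '", unit, "'", call. = FALSE))
}

# Unit suffix on the lag-time column header wins over the tau_unit argument.
.sniff_tau_unit <- function(header, fallback) {
  h <- tolower(header)
  if (grepl("_s$", h)) return("s")
  if (grepl("_ms$", h)) return("ms")
  if (grepl("(_us|_µs)$", h)) return("us")
  fallback
}

#' Read correlograms from a delimited text file
#'
#' Two layouts are supported.  `"wide"`: the first column holds lag times and
#' every further column one curve (column name becomes the curve id).
#' `"long"`: three columns `curve_id`, `lag_time`, `g2`.  With
#' `format = "auto"` a file whose first three (case-insensitive) column names
#' are `curve_id`, `lag_time`, `g2` is read as long, anything else as wide.
#' The lag-time unit is taken from a `_s` / `_ms` / `_us` suffix on the
#' lag-time column header when present, otherwise from `tau_unit`
#' (microseconds by default, the common instrument export).
#'
#' @param path Path to a CSV or TSV file.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param tau_unit Fallback lag-time unit: `"us"`, `"ms"` or `"s"`.
#' @param sep Field delimiter; `"auto"` sniffs comma vs tab from the header.
#' @return A list of [correlogram()] objects.
#' @export
read_correlograms <- function(path, format = c("auto", "wide", "long"),
                              tau_unit = c("us", "ms", "s"), sep = "auto") {
  format <- match.arg(format)
  tau_unit <- match.arg(tau_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "auto")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("need at least two columns in ", path, call. = FALSE)
  lowered <- tolower(names(df))
  if (format == "auto") {
    format <- if (ncol(df) >= 3L &&
                  identical(lowered[1:3], c("curve_id", "lag_time", "g2")))
      "long" else "wide"
  }
  if (format == "long") {
    if (!all(c("curve_id", "lag_time", "g2") %in% lowered))
      stop("long format needs columns curve_id, lag_time, g2", call. = FALSE)
    names(df) <- lowered
    unit <- .sniff_tau_unit("lag_time", tau_unit)
    fac <- .tau_unit_factor(unit)
    ids <- unique(df$curve_id)
    curves <- lapply(ids, function(cid) {
      sub <- df[df$curve_id == cid, , drop = FALSE]
      correlogram(sub$lag_time * fac, sub$g2, id = as.character(cid),
                  metadata = list(source = path, tau_unit = unit))
    })
  } else {
    unit <- .sniff_tau_unit(names(df)[1], tau_unit)
    fac <- .tau_unit_factor(unit)
    tau <- as.numeric(df[[1]]) * fac
    curves <- lapply(names(df)[-1], function(cid) {
      correlogram(tau, df[[cid]], id = cid,
                  metadata = list(source = path, tau_unit = unit))
    })
  }
  curves
}

#' Write correlograms to a wide-format CSV
#'
#' All curves must share one lag-time vector (the layout instruments export).
#' Lag times are written in seconds under the header `lag_time_s`, so a
#' written file re-reads without unit guessing.
#'
#' @param curves List of [correlogram()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlograms <- function(curves, path) {
  stopifnot(length(curves) >= 1L)
  tau <- curves[[1]]$tau
  for (cv in curves) {
    if (length(cv$tau) != length(tau) || any(cv$tau != tau))
      stop("all curves must share the same lag-time vector for wide export",
           call. = FALSE)
  }
  df <- data.frame(lag_time_s = tau, check.names = FALSE)
  for (cv in curves) df[[cv$id]] <- cv$g2
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Filter raw correlograms on intercept and baseline quality
#'
#' Removes curves that look like buffer (no decay above the baseline) or that
#' carry a bumpy baseline symptomatic of dust and large aggregates.  The
#' intercept is estimated as the mean of g2 - 1 over the first three points;
#' baseline roughness as the standard deviation of g2 over the last
#' `baseline_fraction` of points.  A curve is kept iff
#' intercept >= `min_intercept` and roughness <= `max_baseline_sd`.
#' Filtering never raises: every curve gets a row in the report.
#'
#' @param curves List of [correlogram()] objects.
#' @param min_intercept Minimum acceptable intercept (default 0.05).
#' @param max_baseline_sd Maximum acceptable baseline SD (default 0.01).
#' @param baseline_fraction Fraction of trailing points treated as baseline.
#' @return A list with `kept` (the surviving curves) and `report`
#'   (a data.frame with columns `id`, `intercept`, `baseline_sd`, `kept`,
#'   `reason`).
#' @export
filter_raw_curves <- function(curves, min_intercept = 0.05,
                              max_baseline_sd = 0.01,
                              baseline_fraction = 0.2) {
  if (baseline_fraction <= 0 || baseline_fraction >= 1)
    stop("'baseline_fraction' must lie in (0, 1)", call. = FALSE)
  rows <- lapply(curves, function(cv) {
    n <- length(cv$g2)
    intercept <- mean(cv$g2[seq_len(min(3L, n))]) - 1
    tail_n <- max(2L, ceiling(baseline_fraction * n))
    baseline_sd <- stats::sd(cv$g2[(n - tail_n + 1L):n])
    reasons <- character(0)
    if (!is.finite(intercept) || intercept < min_intercept)
      reasons <- c(reasons, sprintf("intercept %.4f < %.4f", intercept, min_intercept))
    if (!is.finite(baseline_sd) || baseline_sd > max_baseline_sd)
      reasons <- c(reasons, sprintf("baseline SD %.4f > %.4f", baseline_sd, max_baseline_sd))
    data.frame(id = cv$id, intercept = intercept, baseline_sd = baseline_sd,
               kept = length(reasons) == 0L,
               reason = if (length(reasons)) paste(reasons, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(kept = curves[report$kept], report = report)
}

#' Export fitted radius distributions to CSV
#'
#' One row per grid point per fit, columns `curve_id`, `r_h_nm`,
#' `intensity_weight`, `alpha`, `residual_norm`, `penalty_norm`.  Weights per
#' curve sum to 1.
#'
#' @param fits List of `dls_fit` objects from [fit_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(fits, path) {
  if (length(fits) == 0L) {
    df <- data.frame(curve_id = character(0), r_h_nm = numeric(0),
                     intensity_weight = numeric(0), alpha = numeric(0),
                     residual_norm = numeric(0), penalty_norm = numeric(0))
  } else {
    df <- do.call(rbind, lapply(fits, function(f) {
      data.frame(curve_id = f$id, r_h_nm = f$grid$r_nm,
                 intensity_weight = f$weights, alpha = f$alpha,
                 residual_norm = f$fidelity, penalty_norm = f$penalty,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distribution CSV written by [write_distribution()]
#'
#' @param path Path to the CSV.
#' @return A data.frame with the exported columns, numeric where appropriate.
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("r_h_nm", "intensity_weight", "alpha", "residual_norm", "penalty_norm")
  for (cn in intersect(num, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df
}
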