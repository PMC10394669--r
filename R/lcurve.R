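# Regularization-parameter selection: alpha ladder, L-curve tracing and
# triangle-method corner detection.

#' Log-evenly spaced ladder of regularization parameters
#'
#' Generates alpha values 10^(start + k step) for k = 0, 1, ... while
#' start + k step <= stop.  The defaults (-6, 1, 0.2) give 36 values between
#' 1e-6 and 10, a ladder fine enough to resolve the L-curve corner.
#'
#' @param start,stop Exponent range (start <= stop).
#' @param step Exponent increment (> 0).
#' @return Increasing numeric vector of alphas.
#' @examples
#' length(alpha_sequence(-6, 1, 0.2))    # 36
#' length(alpha_sequence(-6, 2, 0.25))   # 33
#' @export
alpha_sequence <- function(start = -6, stop = 1, step = 0.2) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be > 0", call. = FALSE)
  if (start > stop) stop("'start' must be <= 'stop'", call. = FALSE)
  k <- 0:floor((stop - start) / step + 1e-9)
  10^(start + k * step)
}

#' Locate the corner of an L-curve with the triangle method
#'
#' Given points (log10 fidelity, log10 penalty) ordered by increasing alpha,
#' each interior point is made the apex of a triangle whose other two
#' vertices are the first and last points.  Candidates are the apexes lying
#' on the convex (origin-facing) side of the chord; among them the apex with
#' the sharpest vertex angle is the corner.  Angle ties are broken toward
#' larger alpha (the smoother solution).
#'
#' @param points A two-column matrix or data.frame: column 1 log10 fidelity,
#'   column 2 log10 penalty, rows ordered by alpha.  At least 4 rows.
#' @param tol Collinearity tolerance on the oriented area.
#' @return The corner row index.  Errors with "no corner detected" when all
#'   points are collinear within `tol` or no candidate lies on the convex
#'   side; callers typically fall back to a fixed default alpha.
#' @export
triangle_corner <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("'points' must have two columns", call. = FALSE)
  m <- nrow(pts)
  if (m < 4L) stop("need at least 4 points to locate a corner", call. = FALSE)
  p1 <- pts[1, ]; pl <- pts[m, ]
  chord <- pl - p1
  scale2 <- sum(chord^2)
  if (scale2 < tol^2) stop("no corner detected: degenerate L-curve", call. = FALSE)
  best <- NA_integer_; best_angle <- Inf
  for (j in 2:(m - 1L)) {
    pj <- pts[j, ]
    # oriented area of (first, last, candidate); negative = convex side,
    # i.e. the candidate sits toward small fidelity AND small penalty
    area <- chord[1] * (pj[2] - p1[2]) - chord[2] * (pj[1] - p1[1])
    if (area >= -tol * sqrt(scale2)) next
    u <- p1 - pj; v <- pl - pj
    ang <- acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    if (ang < best_angle - 1e-12) {
      best_angle <- ang; best <- j
    } else if (ang <= best_angle + 1e-12) {
      best <- j  # tie: prefer larger alpha
    }
  }
  if (is.na(best))
    stop("no corner detected: L-curve is collinear or concave", call. = FALSE)
  best
}

#' Trace the L-curve of a correlogram over an alpha ladder
#'
#' Fits the curve at every alpha and records the fidelity (residual) and
#' penalty (solution roughness) norms; the corner of the resulting log-log
#' curve balances goodness of fit against smoothness and is located with
#' [triangle_corner()].
#'
#' @inheritParams fit_curve
#' @param alphas Increasing vector of regularization parameters (length >= 4).
#' @return An object of class `dls_lcurve`: a data.frame with columns
#'   `alpha`, `fidelity`, `penalty`, `log_fidelity`, `log_penalty`, plus
#'   attributes `corner_index` and `corner_alpha` (NA when no corner was
#'   found).  Accessors: `x$corner_alpha` via `$` works on the returned list.
#' @export
trace_lcurve <- function(curve, setup, alphas = alpha_sequence(-6, 1, 0.2),
                         grid = NULL, beta = NULL, constraint_weight = 100,
                         min_points = 5L) {
  stopifnot(inherits(curve, "dls_correlogram"))
  .assert_setup(setup)
  if (length(alphas) < 2L)
    stop("need an alpha ladder, not a single value, to trace an L-curve",
         call. = FALSE)
  if (is.unsorted(alphas, strictly = TRUE))
    stop("'alphas' must be strictly increasing", call. = FALSE)
  if (is.null(grid)) grid <- radius_grid(setup)
  if (is.null(beta)) beta <- estimate_beta(curve)
  trunc <- truncate_and_invert(curve, beta, min_points = min_points)
  A <- decay_kernel(trunc$tau, grid)
  L <- second_derivative_matrix(grid$n)
  rows <- lapply(alphas, function(al) {
    sol <- tryCatch(tikhonov_nnls(A, trunc$g1, L, al,
                                  constraint_weight = constraint_weight),
                    error = function(e) {
                      warning("fit failed at alpha = ", al, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(sol)) return(NULL)
    data.frame(alpha = al, fidelity = sol$fidelity, penalty = sol$penalty)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 4L)
    stop("fewer than 4 alphas produced a fit; cannot trace an L-curve",
         call. = FALSE)
  eps <- .Machine$double.eps
  tab$log_fidelity <- log10(pmax(tab$fidelity, eps))
  tab$log_penalty <- log10(pmax(tab$penalty, eps))
  # Tikhonov theory: fidelity non-decreasing, penalty non-increasing in alpha
  if (any(diff(tab$fidelity) < -1e-9 * (1 + tab$fidelity[-1])))
    warning("fidelity not monotone in alpha beyond solver tolerance")
  if (any(diff(tab$penalty) > 1e-9 * (1 + tab$penalty[-1])))
    warning("penalty not monotone in alpha beyond solver tolerance")
  corner <- tryCatch(
    triangle_corner(cbind(tab$log_fidelity, tab$log_penalty)),
    error = function(e) NA_integer_)
  corner_alpha <- if (is.na(corner)) NA_real_ else tab$alpha[corner]
  if (!is.na(corner) && (corner == 1L || corner == nrow(tab)))
    warning("L-curve corner at the ladder end point; widen the ladder")
  structure(list(table = tab, corner_index = corner,
                 corner_alpha = corner_alpha, beta = beta),
            class = "dls_lcurve")
}

#' @export
print.dls_lcurve <- function(x, ...) {
  cat(sprintf("L-curve: %d alphas in [%.3g, %.3g]\n", nrow(x$table),
              min(x$table$alpha), max(x$table$alpha)))
  if (is.na(x$corner_index)) cat("  no corner detected\n")
  else cat(sprintf("  corner at alpha = %.4g (index %d)\n",
                   x$corner_alpha, x$corner_index))
  invisible(x)
}
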