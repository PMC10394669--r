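# Core inversion: coherence-factor estimation, Siegert conversion with
# truncation, radius grid and decay kernel, and the Tikhonov-Phillips
# regularized NNLS solve.

#' Log-spaced hydrodynamic-radius grid
#'
#' The inversion support: `n` radii log-spaced between `r_min_nm` and
#' `r_max_nm` with, for each radius, the inverse decay rate s = 1 / (D q^2)
#' implied by the instrument setup.  The defaults (200 points spanning 0.1 nm
#' to 1e6 nm) cover everything from free dye to um-scale dust.
#'
#' @param setup A [dls_setup()] object; s values are setup-dependent, and a
#'   grid must only ever be used with curves measured under the same setup.
#' @param n Number of grid points (>= 3).
#' @param r_min_nm,r_max_nm Grid end points in nm.
#' @return An object of class `dls_radius_grid` with fields `r_nm`, `s`
#'   (seconds), `n` and `setup`.
#' @export
radius_grid <- function(setup, n = 200, r_min_nm = 0.1, r_max_nm = 1e6) {
  .assert_setup(setup)
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("'n' must be >= 3", call. = FALSE)
  n <- as.integer(n)
  if (r_min_nm <= 0 || r_min_nm >= r_max_nm)
    stop("need 0 < r_min_nm < r_max_nm", call. = FALSE)
  r_nm <- 10^seq(log10(r_min_nm), log10(r_max_nm), length.out = n)
  structure(list(r_nm = r_nm, s = inverse_decay_from_radius(r_nm, setup),
                 n = n, setup = setup),
            class = "dls_radius_grid")
}

#' @export
print.dls_radius_grid <- function(x, ...) {
  cat(sprintf("Radius grid: %d log-spaced points, %.3g-%.3g nm (s: %.3g-%.3g s)\n",
              x$n, min(x$r_nm), max(x$r_nm), min(x$s), max(x$s)))
  invisible(x)
}

.same_setup <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Estimate the coherence factor beta from the short-lag limit
#'
#' Fits a least-squares quadratic in tau through the g2 points with lag times
#' below `tau_max_us` and reads beta off the extrapolated intercept:
#' g2(0) = 1 + beta since g1(0) = 1.
#'
#' @param curve A [correlogram()].
#' @param tau_max_us Upper lag-time bound of the fit window, microseconds.
#' @return The estimated beta (scalar).  Errors if fewer than 3 points fall
#'   inside the window or if the estimate is non-positive.
#' @export
estimate_beta <- function(curve, tau_max_us = 5) {
  stopifnot(inherits(curve, "dls_correlogram"))
  sel <- curve$tau < tau_max_us * 1e-6
  if (sum(sel) < 3L)
    stop("fewer than 3 points below ", tau_max_us,
         " us; supply beta manually (curve '", curve$id, "')", call. = FALSE)
  tau <- curve$tau[sel]; g2 <- curve$g2[sel]
  co <- stats::coef(stats::lm(g2 ~ tau + I(tau^2)))
  beta <- unname(co[1]) - 1
  if (!is.finite(beta) || beta <= 0)
    stop("estimated beta <= 0; curve '", curve$id,
         "' has no usable decay above the baseline", call. = FALSE)
  if (beta > 1)
    warning("estimated beta > 1 for curve '", curve$id, "'")
  beta
}

#' Convert a correlogram to first-order data, truncating at the baseline
#'
#' Applies the inverse Siegert relation to the points preceding the first
#' occurrence of g2 < 1 (all points when g2 never dips below 1); beyond that
#' point the square root is undefined and the curve is baseline noise.
#'
#' @param curve A [correlogram()].
#' @param beta Coherence factor (> 0), typically from [estimate_beta()].
#' @param min_points Minimum number of surviving points (default 5); fewer
#'   indicates a curve dominated by baseline noise and raises an error.
#' @return A list with `tau` (seconds), `g1`, and `truncation_index` (the
#'   number of points used).
#' @export
truncate_and_invert <- function(curve, beta, min_points = 5L) {
  stopifnot(inherits(curve, "dls_correlogram"))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar", call. = FALSE)
  below <- which(curve$g2 < 1)
  k <- if (length(below)) below[1] - 1L else length(curve$g2)
  if (k < min_points)
    stop("only ", k, " points precede the first g2 < 1 (need >= ", min_points,
         "); curve '", curve$id, "' is dominated by baseline noise", call. = FALSE)
  idx <- seq_len(k)
  list(tau = curve$tau[idx],
       g1 = siegert_invert(curve$g2[idx], beta),
       truncation_index = k)
}

#' Exponential decay kernel matrix
#'
#' A\[i, j\] = exp(-tau_i / s_j): the contribution of grid species j to
#' g1 at lag time tau_i.
#'
#' @param tau Lag times in seconds (rows).
#' @param grid A [radius_grid()] (columns).
#' @return An m x n matrix with entries in (0, 1\].
#' @export
decay_kernel <- function(tau, grid) {
  stopifnot(inherits(grid, "dls_radius_grid"))
  exp(-outer(as.numeric(tau), 1 / grid$s))
}

#' Second-order finite-difference matrix
#'
#' The (n - 2) x n matrix with rows (1, -2, 1); annihilates constant and
#' affine sequences, so the penalty \eqn{\|Lx\|} measures curvature of the
#' contribution vector across neighbouring grid points.
#'
#' @param n Number of grid points (>= 3).
#' @return The (n - 2) x n matrix.
#' @export
second_derivative_matrix <- function(n) {
  if (n < 3) stop("'n' must be >= 3", call. = FALSE)
  L <- matrix(0, n - 2L, n)
  for (k in seq_len(n - 2L)) L[k, k:(k + 2L)] <- c(1, -2, 1)
  L
}

#' Tikhonov-Phillips regularized non-negative least squares
#'
#' Minimizes \eqn{\|Ax - b\|^2 + \alpha \|Lx\|^2 + w^2 (\sum x - 1)^2} over
#' x >= 0 as one stacked Lawson-Hanson NNLS solve:
#' rows \[A; sqrt(alpha) L; w 1'\] against \[b; 0; w\].  The sum-to-one
#' constraint is soft (weight `constraint_weight` relative to unit-scale data
#' rows); the returned weights are renormalized to sum exactly to 1, while
#' the fidelity and penalty norms are reported for the raw minimizer.
#'
#' @param A Kernel matrix (m x n), see [decay_kernel()].
#' @param b First-order autocorrelation data (length m).
#' @param L Regularization matrix, see [second_derivative_matrix()].
#' @param alpha Regularization parameter (>= 0).
#' @param constraint_weight Weight of the soft sum-to-one row (default 100).
#' @return A list with `x` (raw non-negative solution), `weights`
#'   (renormalized, sum exactly 1), `fidelity` = ||Ax - b||, `penalty` = ||Lx||.
#' @export
tikhonov_nnls <- function(A, b, L, alpha, constraint_weight = 100) {
  A <- as.matrix(A); L <- as.matrix(L); b <- as.numeric(b)
  n <- ncol(A)
  if (ncol(L) != n) stop("A and L must have the same number of columns", call. = FALSE)
  if (length(b) != nrow(A)) stop("length(b) must equal nrow(A)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("'alpha' must be a scalar >= 0", call. = FALSE)
  if (constraint_weight <= 0)
    stop("'constraint_weight' must be > 0", call. = FALSE)
  Astack <- rbind(A, sqrt(alpha) * L, rep(constraint_weight, n))
  bstack <- c(b, rep(0, nrow(L)), constraint_weight)
  sol <- tryCatch(pracma::lsqnonneg(Astack, bstack),
                  error = function(e) stop("NNLS solver failed at alpha = ",
                                           alpha, ": ", conditionMessage(e),
                                           call. = FALSE))
  x <- pmax(sol$x, 0)
  total <- sum(x)
  if (total <= 0)
    stop("NNLS returned the zero vector at alpha = ", alpha, call. = FALSE)
  list(x = x,
       weights = x / total,
       fidelity = sqrt(sum((A %*% x - b)^2)),
       penalty = sqrt(sum((L %*% x)^2)))
}

#' Fit one correlogram into a hydrodynamic-radius distribution
#'
#' The full per-curve pipeline: estimate beta (unless supplied), convert to
#' first-order data with baseline truncation, build the kernel on a
#' log-spaced radius grid and solve the regularized NNLS problem.  With
#' `alpha = "lcurve"` the regularization parameter is chosen at the corner of
#' the L-curve traced over `alphas` (falling back to 0.01 when no corner is
#' detected).
#'
#' @param curve A [correlogram()].
#' @param setup A [dls_setup()]; must match the setup of `grid` if one is given.
#' @param alpha Regularization parameter: a non-negative number, or the string
#'   `"lcurve"` for automatic selection.
#' @param grid Optional [radius_grid()]; built with defaults otherwise.
#' @param beta Optional coherence factor; estimated from the curve if `NULL`.
#' @param alphas Ladder used when `alpha = "lcurve"` (default
#'   [alpha_sequence()] over 1e-6 to 10).
#' @param constraint_weight Soft sum-to-one weight, see [tikhonov_nnls()].
#' @param min_points Minimum surviving points after truncation.
#' @return An object of class `dls_fit`: `id`, `weights` (length n, sum 1),
#'   `beta`, `alpha`, `fidelity`, `penalty`, `truncation_index`, `g1`, `tau`,
#'   `residuals` (first-order domain), `residuals_g2` (measurement
#'   domain), `grid`, and `lcurve` (NULL unless selected automatically).
#' @export
fit_curve <- function(curve, setup, alpha = 0.01, grid = NULL, beta = NULL,
                      alphas = alpha_sequence(-6, 1, 0.2),
                      constraint_weight = 100, min_points = 5L) {
  stopifnot(inherits(curve, "dls_correlogram"))
  .assert_setup(setup)
  if (is.null(grid)) grid <- radius_grid(setup)
  if (!inherits(grid, "dls_radius_grid"))
    stop("'grid' must be a radius_grid", call. = FALSE)
  if (!.same_setup(grid$setup, setup))
    stop("grid was built with a different instrument setup than the curve's; ",
         "rebuild it with the matching dls_setup", call. = FALSE)
  if (is.null(beta)) beta <- estimate_beta(curve)
  lcurve <- NULL
  if (identical(alpha, "lcurve")) {
    lcurve <- tryCatch(
      trace_lcurve(curve, setup, alphas = alphas, grid = grid, beta = beta,
                   constraint_weight = constraint_weight,
                   min_points = min_points),
      error = function(e) NULL)
    alpha <- if (is.null(lcurve) || is.na(lcurve$corner_alpha)) 0.01
             else lcurve$corner_alpha
  }
  trunc <- truncate_and_invert(curve, beta, min_points = min_points)
  A <- decay_kernel(trunc$tau, grid)
  L <- second_derivative_matrix(grid$n)
  sol <- tikhonov_nnls(A, trunc$g1, L, alpha,
                       constraint_weight = constraint_weight)
  g1_hat <- as.numeric(A %*% sol$x)
  structure(list(id = curve$id, weights = sol$weights, beta = beta,
                 alpha = alpha, fidelity = sol$fidelity, penalty = sol$penalty,
                 truncation_index = trunc$truncation_index, g1 = trunc$g1,
                 tau = trunc$tau,
                 residuals = g1_hat - trunc$g1,
                 residuals_g2 = siegert_forward(g1_hat, beta) -
                   curve$g2[seq_len(trunc$truncation_index)],
                 grid = grid, lcurve = lcurve),
            class = "dls_fit")
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("DLS fit '%s': beta = %.4f, alpha = %.4g, %d/%d lag points used\n",
              x$id, x$beta, x$alpha, x$truncation_index, x$truncation_index))
  cat(sprintf("  fidelity ||Ax-b|| = %.4g, penalty ||Lx|| = %.4g\n",
              x$fidelity, x$penalty))
  d <- intensity_distribution(x)
  cat(sprintf("  WHM = %.3g nm, mode = %.3g nm\n",
              weighted_harmonic_mean(d), d$grid$r_nm[which.max(d$weights)]))
  invisible(x)
}

#' Filter fits on residual size
#'
#' Keeps fits whose root-mean-square residual over the used lag points is at
#' most `max_residual_rms`; poorly fitted curves (dust events, unstable
#' baselines) are dropped.  Residuals are measured in the g2 domain, where
#' the instrument noise lives (typical SD a few 1e-3): the inverse Siegert
#' transform amplifies baseline noise without bound as g1 approaches 0, so
#' no fixed threshold works on first-order residuals.
#'
#' @param fits List of `dls_fit` objects.
#' @param max_residual_rms RMS g2-residual threshold (default 0.01, about
#'   five times the typical instrument noise SD).
#' @return The surviving fits (list).
#' @export
filter_fits <- function(fits, max_residual_rms = 0.01) {
  keep <- vapply(fits, function(f) {
    sqrt(mean(f$residuals_g2^2)) <= max_residual_rms
  }, logical(1))
  fits[keep]
}
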