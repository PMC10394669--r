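# Shared fixtures and independent oracles used across the suite.

plate_setup <- function() dls_setup(wavelength_nm = 817, angle_deg = 150,
                                    temperature_C = 20,
                                    refractive_index = 1.33,
                                    viscosity_Pa_s = 0.00089)

# Exact NNLS oracle by exhaustive support enumeration: the global minimizer
# of ||Cx - d||^2 over x >= 0 restricted to its support solves the
# unconstrained least-squares problem on that support, so scanning every
# support and keeping the best feasible candidate is exact.  Viable for
# ncol(C) <= ~10.
nnls_oracle <- function(C, d) {
  n <- ncol(C)
  best_obj <- sum(d^2); best_x <- rep(0, n)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sol <- tryCatch(qr.solve(C[, idx, drop = FALSE], d),
                    error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-12)) next
    x <- rep(0, n); x[idx] <- pmax(sol, 0)
    obj <- sum((C %*% x - d)^2)
    if (obj < best_obj) { best_obj <- obj; best_x <- x }
  }
  list(objective = best_obj, x = best_x)
}

# Stacked Tikhonov objective evaluated on a raw (unnormalized) solution.
tikhonov_objective <- function(A, b, L, alpha, w, x) {
  sum((A %*% x - b)^2) + alpha * sum((L %*% x)^2) + w^2 * (sum(x) - 1)^2
}

# Exhaustive-angle corner oracle: same candidate rule as the triangle
# method (convex side of the first-last chord), implemented independently
# by direct enumeration of every vertex angle.
corner_oracle <- function(pts) {
  pts <- as.matrix(pts)
  m <- nrow(pts)
  p1 <- pts[1, ]; pl <- pts[m, ]
  angles <- rep(Inf, m)
  for (j in 2:(m - 1)) {
    pj <- pts[j, ]
    cross <- (pl[1] - p1[1]) * (pj[2] - p1[2]) -
             (pl[2] - p1[2]) * (pj[1] - p1[1])
    if (cross >= 0) next
    u <- p1 - pj; v <- pl - pj
    angles[j] <- acos(min(1, max(-1,
      sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  if (!any(is.finite(angles))) return(NA_integer_)
  amin <- min(angles)
  max(which(angles <= amin + 1e-12))  # ties toward larger alpha
}
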