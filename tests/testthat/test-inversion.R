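test_that("beta is read off an exact quadratic and fails without early points", {
  tau <- seq(0.5, 20, by = 0.5) * 1e-6
  g2 <- 1.2 - 1e3 * tau + 1e5 * tau^2
  curve <- correlogram(tau, g2)
  expect_equal(estimate_beta(curve), 0.2, tolerance = 1e-10)
  late <- correlogram(tau + 9.5e-6, g2)   # first point at 10 us
  expect_error(estimate_beta(late), "supply beta manually")
  flat <- correlogram(tau, rep(1, length(tau)))
  expect_error(estimate_beta(flat), "beta")
})

test_that("beta recovery from simulated curves is unbiased within 0.02", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 80)
  betas <- vapply(1:100, function(s) {
    sim <- simulate_correlogram(population(6, 10), setup, seed = 1000 + s,
                                grid = grid)
    estimate_beta(sim$curve)
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.2), 0.02)
  expect_lt(stats::sd(betas), 0.02)
})

test_that("truncation stops before the first g2 < 1", {
  tau <- c(1, 2, 3, 4) * 1e-6
  curve <- correlogram(tau, c(1.2, 1.1, 0.99, 1.05))
  tr <- truncate_and_invert(curve, 0.2, min_points = 2)
  expect_equal(tr$truncation_index, 2)
  expect_equal(tr$g1, c(1, sqrt(0.5)), tolerance = 1e-12)
  # default minimum: too few surviving points is an error
  expect_error(truncate_and_invert(curve, 0.2), "baseline noise")
  all_above <- correlogram(tau, c(1.2, 1.15, 1.1, 1.05))
  expect_equal(truncate_and_invert(all_above, 0.2, min_points = 2)$truncation_index, 4)
  early_dip <- correlogram(tau, c(1.2, 0.98, 1.1, 1.05))
  expect_error(truncate_and_invert(early_dip, 0.2, min_points = 2),
               "baseline noise")
})

test_that("the radius grid is log-spaced with the documented defaults", {
  setup <- plate_setup()
  grid <- radius_grid(setup)
  expect_equal(grid$n, 200)
  expect_equal(grid$r_nm[1], 0.1)
  expect_equal(grid$r_nm[200], 1e6)
  ratios <- grid$r_nm[-1] / grid$r_nm[-200]
  expect_equal(ratios, rep((1e7)^(1 / 199), 199), tolerance = 1e-12)
  g3 <- radius_grid(setup, n = 3)
  expect_equal(g3$r_nm, c(0.1, 10^2.5, 1e6), tolerance = 1e-12)
  # s follows the radius through Stokes-Einstein and q
  expect_equal(grid$s, inverse_decay_from_radius(grid$r_nm, setup))
  expect_true(all(diff(grid$s) > 0))
  expect_error(radius_grid(setup, n = 2), ">= 3")
  expect_error(radius_grid(setup, r_min_nm = 10, r_max_nm = 1), "r_min")
})

test_that("the decay kernel is an exponential in tau/s", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 10)
  A <- decay_kernel(grid$s, grid)           # tau_i = s_i on the diagonal
  expect_equal(diag(A), rep(exp(-1), 10), tolerance = 1e-12)
  expect_equal(as.numeric(decay_kernel(0, grid)), rep(1, 10))
  A2 <- decay_kernel(c(1e-6, 1e-5, 1e-4), grid)
  expect_true(all(A2 > 0 & A2 <= 1))
  expect_true(all(apply(A2, 2, diff) < 0))  # decreasing down each column
  # scale consistency: tau and s scaled together leave the kernel unchanged
  grid10 <- grid; grid10$s <- grid$s * 10
  expect_equal(decay_kernel(c(1e-6, 1e-5, 1e-4) * 10, grid10), A2)
})

test_that("the second-derivative matrix annihilates constant and affine trends", {
  L4 <- second_derivative_matrix(4)
  expect_equal(L4, rbind(c(1, -2, 1, 0), c(0, 1, -2, 1)))
  L <- second_derivative_matrix(30)
  expect_equal(dim(L), c(28, 30))
  expect_equal(as.numeric(L %*% rep(1, 30)), rep(0, 28))
  expect_equal(as.numeric(L %*% (0:29)), rep(0, 28))
  expect_error(second_derivative_matrix(2), ">= 3")
})

test_that("regularized NNLS recovers single species and exact uniform data", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 60)
  tau <- default_lag_times(n = 80)
  A <- decay_kernel(tau, grid)
  L <- second_derivative_matrix(60)
  for (j in c(15, 30, 45)) {
    b <- A[, j]
    sol <- tikhonov_nnls(A, b, L, alpha = 0)
    expect_lt(sol$fidelity, 1e-6)
    near <- max(1, j - 2):min(60, j + 2)
    expect_gte(sum(sol$weights[near]), 0.99)
  }
  u <- rep(1 / 60, 60)
  for (alpha in c(1e-4, 1e-2, 1)) {
    sol <- tikhonov_nnls(A, as.numeric(A %*% u), L, alpha)
    expect_equal(sol$x, u, tolerance = 1e-6)
  }
})

test_that("NNLS solutions match the exhaustive-support oracle on small problems", {
  setup <- plate_setup()
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    grid <- radius_grid(setup, n = n, r_min_nm = 1, r_max_nm = 1000)
    tau <- 10^seq(-6, -2, length.out = sample(6:12, 1))
    A <- decay_kernel(tau, grid)
    L <- second_derivative_matrix(n)
    w_true <- stats::runif(n); w_true <- w_true / sum(w_true)
    b <- as.numeric(A %*% w_true) + stats::rnorm(length(tau), 0, 0.01)
    alpha <- 10^stats::runif(1, -4, 0)
    cw <- 100
    sol <- tikhonov_nnls(A, b, L, alpha, constraint_weight = cw)
    Cs <- rbind(A, sqrt(alpha) * L, rep(cw, n))
    ds <- c(b, rep(0, n - 2), cw)
    oracle <- nnls_oracle(Cs, ds)
    expect_equal(tikhonov_objective(A, b, L, alpha, cw, sol$x),
                 oracle$objective, tolerance = 1e-6)
  }
})

test_that("fidelity grows and penalty shrinks along the alpha ladder", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 80)
  sim <- simulate_correlogram(population(6, 10), setup, seed = 5, grid = grid)
  lc <- trace_lcurve(sim$curve, setup, grid = grid)
  tab <- lc$table
  expect_equal(nrow(tab), 36)
  expect_true(all(diff(tab$fidelity) >= -1e-9 * (1 + tab$fidelity[-1])))
  expect_true(all(diff(tab$penalty) <= 1e-9 * (1 + tab$penalty[-1])))
})

test_that("fit_curve recovers a monodisperse 2 nm sample and is deterministic", {
  setup <- plate_setup()
  grid <- radius_grid(setup)
  sim <- simulate_correlogram(population(2, 10), setup, seed = 11, grid = grid)
  fit <- fit_curve(sim$curve, setup, alpha = 0.01, grid = grid)
  peak <- peak_search(intensity_distribution(fit), list(c(0.1, 100)))
  true_whm <- weighted_harmonic_mean(sim$intensity_dist)
  expect_lt(abs(peak$whm_r_nm / true_whm - 1), 0.10)
  fit2 <- fit_curve(sim$curve, setup, alpha = 0.01, grid = grid)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$beta, fit2$beta)
  # grids from another instrument setup are refused
  other <- dls_setup(wavelength_nm = 658, angle_deg = 90)
  expect_error(fit_curve(sim$curve, other, grid = grid), "different instrument setup")
})

test_that("baseline-only curves fail in truncation with the stage named", {
  tau <- default_lag_times(50)
  set.seed(8)
  g2 <- 1 + stats::rnorm(50, 0, 0.002)
  g2[1:4] <- c(1.2, 1.18, 1.15, 0.99)  # dips below 1 almost immediately
  curve <- correlogram(tau, g2)
  expect_error(fit_curve(curve, plate_setup(), beta = 0.2), "baseline noise")
})

test_that("fit filtering drops corrupted curves by RMS residual", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 80)
  clean <- simulate_correlogram(population(6, 10), setup, noise_sd = 0,
                                grid = grid)$curve
  broken_g2 <- clean$g2
  n <- length(broken_g2)
  broken_g2[seq(floor(2 * n / 3), n)] <- broken_g2[seq(floor(2 * n / 3), n)] + 0.1
  broken <- correlogram(clean$tau, broken_g2, id = "broken")
  fits <- list(fit_curve(clean, setup, beta = 0.2, grid = grid),
               fit_curve(broken, setup, beta = 0.2, grid = grid))
  kept <- filter_fits(fits, max_residual_rms = 0.01)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$id, "sim")
  expect_length(filter_fits(fits, max_residual_rms = Inf), 2)
})
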