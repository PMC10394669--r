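test_that("size distributions normalize and validate", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 10, r_min_nm = 1, r_max_nm = 100)
  d <- size_distribution(grid, rep(2, 10))
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_error(size_distribution(grid, rep(-1, 10)), "non-negative")
  expect_error(size_distribution(grid, rep(0, 10)), "positive sum")
  expect_error(size_distribution(grid, rep(1, 9)), "match the grid")
})

test_that("weighted harmonic mean and weighted mean match hand arithmetic", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 3, r_min_nm = 1, r_max_nm = 4)  # radii 1, 2, 4
  d <- size_distribution(grid, c(0.5, 0.5, 0))
  expect_equal(weighted_harmonic_mean(d), 4 / 3, tolerance = 1e-12)
  expect_equal(weighted_mean_radius(d), 1.5, tolerance = 1e-12)
  point <- size_distribution(grid, c(0, 1, 0))
  expect_equal(weighted_harmonic_mean(point), 2, tolerance = 1e-12)
  expect_equal(weighted_mean_radius(point), 2, tolerance = 1e-12)
})

test_that("the mean inequality WHM <= GM <= WM holds on random distributions", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 50, r_min_nm = 0.5, r_max_nm = 500)
  set.seed(17)
  for (rep in 1:20) {
    w <- stats::rexp(50)
    d <- size_distribution(grid, w)
    whm <- weighted_harmonic_mean(d)
    wm <- weighted_mean_radius(d)
    gm <- exp(sum(d$weights * log(grid$r_nm)))
    expect_lte(whm, gm * (1 + 1e-12))
    expect_lte(gm, wm * (1 + 1e-12))
  }
})

test_that("polydispersity reduces to (sigma/mu)^2 and is scale invariant", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 40, r_min_nm = 1, r_max_nm = 1000)
  w <- stats::dnorm(grid$r_nm, 30, 6)
  d <- size_distribution(grid, w)
  mom <- distribution_moments(d)
  pd <- polydispersity(d)
  expect_equal(pd$pdi, (mom$sd / mom$mean)^2, tolerance = 1e-12)
  expect_equal(pd$percent_pdi, 100 * sqrt(pd$pdi), tolerance = 1e-12)
  # pre-normalization scaling of the weights changes nothing
  d10 <- size_distribution(grid, 10 * w)
  expect_equal(polydispersity(d10)$pdi, pd$pdi, tolerance = 1e-14)
  # point mass: zero polydispersity
  point <- size_distribution(grid, as.numeric(seq_len(40) == 7))
  expect_equal(polydispersity(point)$pdi, 0)
})

test_that("peak search separates a bimodal distribution by region of interest", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 120)
  w <- stats::dnorm(log10(grid$r_nm), log10(3), 0.05) +
       0.8 * stats::dnorm(log10(grid$r_nm), log10(300), 0.05)
  d <- size_distribution(grid, w)
  res <- peak_search(d, list(c(0.1, 100), c(100, 1e6), c(1e4, 1e6)))
  expect_equal(res$mode_r_nm[1], 3, tolerance = 0.12)    # within a grid step
  expect_equal(res$mode_r_nm[2], 300, tolerance = 0.12)
  expect_true(res$empty[3])
  expect_true(is.na(res$mode_r_nm[3]))
  expect_equal(sum(res$area[1:2]), 1, tolerance = 1e-6)
  # full-grid ROI: the mode is the global argmax
  full <- peak_search(d, list(c(0.1, 1e6)))
  expect_equal(full$mode_r_nm, grid$r_nm[which.max(d$weights)])
  expect_error(peak_search(d, list(c(1e7, 1e8))), "outside the grid")
})

test_that("peak statistics ignore detached trace weight at the grid edge", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 200)
  w <- stats::dnorm(log10(grid$r_nm), log10(6), 0.03)
  w[1] <- 0.003 * max(w)   # isolated spurious weight at 0.1 nm
  d <- size_distribution(grid, w)
  res <- peak_search(d, list(c(0.1, 100)))
  expect_equal(res$whm_r_nm, 6, tolerance = 0.02)
  # the ROI-wide harmonic mean, by contrast, is dragged down by the artifact
  expect_lt(weighted_harmonic_mean(d, c(0.1, 100)) / res$whm_r_nm, 0.97)
})

test_that("intensity-to-volume conversion follows r^3 / Mie in the Rayleigh limit", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 3, r_min_nm = 1, r_max_nm = 4)  # radii 1, 2, 4
  d <- size_distribution(grid, c(0.5, 0.5, 0), "intensity")
  expect_warning(v <- to_volume_weights(d), "hard spheres")
  # I ~ r^6 and V ~ r^3, so the 2 nm species is demoted by ~1/8
  expect_equal(v$weights[2] / v$weights[1], 1 / 8, tolerance = 0.01)
  expect_equal(sum(v$weights), 1, tolerance = 1e-12)
  expect_equal(v$weighting, "volume")
  # a point mass is unchanged
  point <- size_distribution(grid, c(0, 1, 0), "intensity")
  expect_warning(vp <- to_volume_weights(point), "hard spheres")
  expect_equal(vp$weights, c(0, 1, 0))
  expect_error(suppressWarnings(to_volume_weights(v)), "intensity-weighted")
})

test_that("replicate aggregation reports mean and SD of the WHM", {
  setup <- plate_setup()
  grid <- radius_grid(setup, n = 100)
  fits <- lapply(1:5, function(s) {
    sim <- simulate_correlogram(population(6, 10), setup, seed = 300 + s,
                                grid = grid)
    fit_curve(sim$curve, setup, alpha = 0.01, grid = grid)
  })
  agg <- aggregate_fits(fits, roi = c(0.1, 100))
  expect_equal(agg$n, 5)
  expect_equal(agg$mean_whm, mean(agg$whm))
  expect_gt(agg$sd_whm, 0)
  expect_equal(sum(agg$mean_distribution$weights), 1, tolerance = 1e-12)
  # identical replicates: zero spread; single fit: SD absent
  same <- aggregate_fits(list(fits[[1]], fits[[1]]))
  expect_equal(same$sd_whm, 0)
  expect_true(is.na(aggregate_fits(fits[1])$sd_whm))
  other_grid <- radius_grid(setup, n = 50)
  sim <- simulate_correlogram(population(6, 10), setup, seed = 400,
                              grid = other_grid)
  f_other <- fit_curve(sim$curve, setup, alpha = 0.01, grid = other_grid)
  expect_error(aggregate_fits(c(fits, list(f_other))), "same radius grid")
})
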