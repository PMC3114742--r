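test_that("credible bands are nested and collapse for degenerate samples", {
  set.seed(40)
  b <- ansatz_basis(1, 5)
  lab <- sample.int(5, 60, TRUE)
  C <- indicator_matrix(lab, 5)
  ch <- run_chain(chain_config(S_phi = 5e3), C, flat_prior(5))
  g <- seq(0, 1, length.out = 101)
  band <- density_band(ch, b, g)
  for (li in 1:3) {
    expect_true(all(band$lower[, li] >= band$lower[, li + 1] - 1e-12))
    expect_true(all(band$upper[, li] <= band$upper[, li + 1] + 1e-12))
  }
  expect_true(all(band$lower[, 1] <= band$upper[, 1] + 1e-12))
  # identical draws: zero-width bands
  ch0 <- ch
  ch0$draws <- ch$draws[rep(1, 200), ]
  ch0$log_posterior <- rep(ch$log_posterior[1], 200)
  ch0$burn_in <- 0L
  band0 <- density_band(ch0, b, g)
  expect_equal(band0$lower[, 3], band0$upper[, 3])
  expect_warning(density_band(ch0, b, g[1:5], levels = 0.9), NA)
})

test_that("density bands match direct sampling of the conjugate posterior", {
  set.seed(41)
  J <- 4
  b <- ansatz_basis(1, J)
  lab <- sample.int(J, 100, TRUE)
  C <- indicator_matrix(lab, J)
  nj <- tabulate(lab, J)
  ch <- run_chain(chain_config(S_phi = 1e5), C, flat_prior(J))
  g <- seq(0.05, 0.95, length.out = 61)
  band <- density_band(ch, b, g, levels = 0.95)
  # independent oracle: exact Dirichlet(n + 1) sampling
  L <- basis_eval(b, g)
  vals <- L %*% t(rdirichlet(2e5, nj + 1))
  lo <- apply(vals, 1, quantile, 0.025)
  hi <- apply(vals, 1, quantile, 0.975)
  big <- hi > 0.1 * max(hi)
  expect_lt(max(abs(band$lower[big, 1] - lo[big]) / hi[big]), 0.05)
  expect_lt(max(abs(band$upper[big, 1] - hi[big]) / hi[big]), 0.05)
})

test_that("95 percent bands cover fresh posterior draws at the right rate", {
  set.seed(42)
  J <- 4
  b <- ansatz_basis(1, J)
  lab <- sample.int(J, 100, TRUE)
  C <- indicator_matrix(lab, J)
  nj <- tabulate(lab, J)
  ch <- run_chain(chain_config(S_phi = 1e5), C, flat_prior(J))
  g <- seq(0.05, 0.95, length.out = 41)
  band <- density_band(ch, b, g, levels = 0.95)
  fresh <- basis_eval(b, g) %*% t(rdirichlet(2e4, nj + 1))
  cover <- mean(fresh >= band$lower[, 1] & fresh <= band$upper[, 1])
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("the pointwise mean curve equals the density at the mean weights", {
  set.seed(43)
  b <- ansatz_basis(1, 6)
  draws <- rdirichlet(500, rep(2, 6))
  fake <- structure(list(draws = draws, log_posterior = rnorm(500),
                         burn_in = 0L), class = "posterior_sample")
  g <- seq(0, 1, length.out = 101)
  band <- density_band(fake, b, g)
  expect_equal(band$mean, density_eval(b, colMeans(draws), g),
               tolerance = 1e-12)
})

test_that("prediction bands are superpositions with no new simulation", {
  set.seed(44)
  m <- decay_model()
  b <- ansatz_basis(1, 4, sigma = 0.15)
  spec <- noise_spec()
  g <- output_grid(5e-3, 3, 201)
  comps <- output_density_components(b, m, times = c(0.5, 1), S = 300,
                                     grid = matrix(g), noise = spec)
  lab <- sample.int(4, 50, TRUE)
  C <- indicator_matrix(lab, 4)
  ch <- run_chain(chain_config(S_phi = 4000), C, flat_prior(4))
  t0 <- Sys.time()
  pb <- prediction_band(ch, comps)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 5)           # pure algebra on precomputed components
  expect_length(pb, 2)
  # point-mass posterior: band collapses onto the single prediction
  ch0 <- ch
  ch0$draws <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), 200), 200,
                      byrow = TRUE)
  ch0$log_posterior <- rep(0, 200); ch0$burn_in <- 0L
  pb0 <- prediction_band(ch0, comps)
  expect_equal(pb0[[1]]$lower[, 4], pb0[[1]]$upper[, 4])
  expect_equal(pb0[[1]]$map, output_density(comps, rep(0.25, 4))[, 1])
})

test_that("integrated squared error has its analytic values and symmetry", {
  g <- seq(0, 1, by = 5e-4)
  expect_equal(imse(dnorm(g, 0.5, 0.1), dnorm(g, 0.5, 0.1), g), 0)
  a <- as.numeric(g >= 0.1 & g < 0.2) * 10      # unit-mass box, w = 0.1
  b <- as.numeric(g >= 0.5 & g < 0.6) * 10
  expect_equal(imse(a, b, g), 2 / 0.1, tolerance = 0.01)
  expect_equal(imse(a, b, g), imse(b, a, g))
  expect_error(imse(a[-1], b, g), "lengths")
  # 2-D tensor grid variant
  ax <- seq(0, 1, length.out = 101)
  A <- outer(dnorm(ax, 0.4, 0.1), dnorm(ax, 0.6, 0.1))
  expect_equal(imse(A, A, list(ax, ax)), 0)
  expect_gt(imse(A, 0 * A, list(ax, ax)), 0)
})

test_that("estimation error shrinks with the number of measured cells", {
  # qualitative convergence on the univariate study at reduced scale
  set.seed(45)
  counts <- c(100, 1000, 10000)
  err <- matrix(NA, 3, length(counts))
  g <- seq(0, 1, length.out = 201)
  for (r in 1:3) for (ci in seq_along(counts)) {
    fx <- study_fixture("univariate", cells_per_time = counts[ci])
    pr <- beta_prior_from_extremum(rep(1 / 15, 15), 0.05^2)
    ex <- generate_snapshots(fx$truth, fx$design, fx$model)
    C <- conditional_matrix(ex$data, fx$basis, fx$model, fx$noise,
                            S_c = 200, method = "grid")
    fit <- map_estimate(C, pr)
    err[r, ci] <- imse(density_eval(fx$basis, fit$phi, g),
                       fx$truth$density(g), g)
  }
  expect_true(all(diff(colMeans(err)) < 0))
})
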