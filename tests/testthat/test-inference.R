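test_that("snapshot datasets partition cells by time", {
  set.seed(10)
  y <- rlnorm(60, log(0.3), 0.4)
  tt <- rep(c(0, 1, 4), each = 20)
  d <- snapshot_dataset(tt, y, cell_id = 1:60)
  expect_equal(d$M, 60)
  expect_equal(d$M_j, c(`1` = 20L, `2` = 20L, `3` = 20L))
  expect_equal(sort(unname(unlist(d$snapshot_index))), 1:60)
  expect_equal(d$snapshot_times, c(0, 1, 4))
  expect_error(snapshot_dataset(c(0, 0), c(1, -1)), "positive")
  expect_error(snapshot_dataset(c(0, 1), c(1, 1), cell_id = c(7, 7)),
               "at most once")
})

test_that("conditional matrix collapses to the noise density for point-mass components", {
  set.seed(12)
  m <- decay_model()
  spec <- noise_spec()
  b <- ansatz_basis(1, 3, sigma = 1e-5)
  d <- snapshot_dataset(rep(1, 5), rlnorm(5, log(0.5), 0.3))
  C <- conditional_matrix(d, b, m, spec, S_c = 50, method = "exact")
  for (j in 1:3) {
    y0 <- exp(-b$centers[j, 1] * 1)
    expect_equal(C$values[, j],
                 cond_density(d$y[, 1], rep(y0, 5), spec),
                 tolerance = 1e-3)
  }
})

test_that("Monte Carlo conditional probabilities agree with quadrature", {
  # light version of the oracle check (the full-size one is in the
  # acceptance suite)
  set.seed(13)
  m <- decay_model()
  spec <- noise_spec(0, 0.15, log(0.05), 0.3)
  b <- ansatz_basis(1, 3, sigma = 0.25)
  truth <- true_density_mixture(1, rbind(0.5), 0.15)
  # short observation times keep every (cell, component) pair well
  # supported, so relative Monte Carlo errors are uniformly small;
  # the full-size check (S_c = 1e4) lives in the acceptance suite
  ex <- generate_snapshots(truth, experiment_design(c(0.25, 0.5), 3, spec), m)
  C <- conditional_matrix(ex$data, b, m, spec, S_c = 4000, method = "exact")
  kk <- seq(1e-6, 1 - 1e-6, length.out = 2001)
  for (i in 1:ex$data$M) for (j in 1:3) {
    f <- basis_eval(b, matrix(kk))[, j] *
      cond_density(matrix(rep(ex$data$y[i, 1], length(kk))),
                   matrix(exp(-kk * ex$data$time[i])), spec)
    expect_lt(abs(C$values[i, j] - trapz_(kk, f)) / trapz_(kk, f), 0.1)
  }
})

test_that("Monte Carlo error of matrix entries scales as S_c^(-1/2)", {
  set.seed(14)
  m <- decay_model()
  spec <- noise_spec()
  b <- ansatz_basis(1, 2, sigma = 0.25)
  d <- snapshot_dataset(c(1, 1), c(0.4, 0.6))
  sizes <- c(250, 1000, 4000)
  # a well-supported entry: cell yhat = 0.4 against the component
  # centered at k = 1 (output ~ exp(-1)); rare-event entries have
  # heavy-tailed Monte Carlo errors and no clean scaling
  sds <- sapply(sizes, function(S) {
    reps <- replicate(12, conditional_matrix(d, b, m, spec, S_c = S,
                                             method = "exact")$values[1, 2])
    sd(reps)
  })
  slope <- coef(lm(log(sds) ~ log(sizes)))[2]
  expect_lt(abs(slope + 0.5), 0.2)
})

test_that("beta priors hit the requested mode and variance", {
  pe <- rep(1 / 15, 15)
  pr <- beta_prior_from_extremum(pe, 0.05^2)
  mode <- (pr$alpha - 1) / (pr$alpha + pr$beta - 2)
  v <- pr$alpha * pr$beta /
    ((pr$alpha + pr$beta)^2 * (pr$alpha + pr$beta + 1))
  expect_equal(mode, pe, tolerance = 1e-6)
  expect_equal(v, rep(0.05^2, 15), tolerance = 1e-8)
  # sigma = 0.285 is the nearly uniform end of the scale
  pr_u <- beta_prior_from_extremum(rep(0.2, 5), 0.285^2)
  expect_true(all(pr_u$alpha < 1.25 & pr_u$beta < 1.25))
  expect_warning(beta_prior_from_extremum(1, 0.12), "infeasible")
})

test_that("the log prior enforces the simplex support", {
  pr <- flat_prior(4)
  expect_identical(log_prior(c(0.5, 0.5, 0.1, -0.1), pr), -Inf)
  expect_identical(log_prior(c(0.4, 0.4, 0.2, 0.1), pr), -Inf)
  expect_equal(log_prior(c(0.25, 0.25, 0.25, 0.25), pr), 0)
  expect_equal(log_prior(c(1, 0, 0, 0), pr), 0)
})

test_that("the posterior reduces to scalar products with multinomial limits", {
  set.seed(15)
  lab <- sample.int(3, 30, TRUE)
  C <- indicator_matrix(lab, 3)
  nj <- tabulate(lab, 3)
  pr <- flat_prior(3)
  phi <- c(0.2, 0.5, 0.3)
  expect_equal(log_posterior_unnorm(phi, C, pr), sum(nj * log(phi)))
  # n_comp = 1 scalar case
  C1 <- matrix(runif(10, 0.5, 2))
  expect_equal(log_posterior_unnorm(1, C1, flat_prior(1)), sum(log(C1)))
  # a zero-likelihood cell forces -Inf
  expect_identical(log_posterior_unnorm(c(0, 1, 0), C, pr), -Inf)
  # invariance to cell ordering
  perm <- sample(30)
  expect_equal(log_posterior_unnorm(phi, C[perm, ], pr),
               log_posterior_unnorm(phi, C, pr))
})

test_that("the restricted log-likelihood is concave on the simplex", {
  set.seed(16)
  C <- matrix(rexp(40 * 4), 40, 4)
  pr <- flat_prior(4)
  f <- function(psi) log_posterior_unnorm(c(psi, 1 - sum(psi)), C, pr)
  for (r in 1:5) {
    psi <- as.numeric(rdirichlet(1, rep(2, 4)))[1:3]
    H <- matrix(NA, 3, 3)
    h <- 1e-5
    for (a in 1:3) for (b2 in 1:3) {
      ea <- replace(rep(0, 3), a, h); eb <- replace(rep(0, 3), b2, h)
      H[a, b2] <- (f(psi + ea + eb) - f(psi + ea) - f(psi + eb) + f(psi)) / h^2
    }
    expect_lt(max(eigen((H + t(H)) / 2, only.values = TRUE)$values), 1e-4)
  }
})

test_that("MAP estimation matches closed forms and grid search", {
  set.seed(17)
  # indicator rows, flat prior: multinomial MLE n_j / M
  lab <- sample.int(4, 80, TRUE)
  C <- indicator_matrix(lab, 4)
  fit <- map_estimate(C, flat_prior(4))
  expect_equal(fit$phi, tabulate(lab, 4) / 80, tolerance = 1e-8)
  expect_lt(fit$kkt, 1e-6)
  # n_comp = 1 is constraint-forced
  expect_equal(map_estimate(matrix(runif(5, 1, 2)))$phi, 1)
  # exhaustive simplex grid search oracle at n_comp = 3
  Cr <- matrix(rexp(20 * 3), 20, 3)
  fit3 <- map_estimate(Cr, flat_prior(3))
  step <- 1e-3
  best <- c(-Inf, NA, NA)
  for (a in seq(0, 1, by = step)) {
    b2 <- seq(0, 1 - a, by = step)
    ll <- colSums(log(Cr %*% rbind(a, b2, 1 - a - b2)))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], a, b2[i])
  }
  phi_grid <- c(best[2], best[3], 1 - best[2] - best[3])
  expect_lt(max(abs(fit3$phi - phi_grid)), 2e-3)
  # objective at the optimum beats every tested simplex point
  expect_gte(log_posterior_unnorm(fit3$phi, Cr, flat_prior(3)) + 1e-9,
             best[1])
  # permuting cells leaves the estimate unchanged
  fitp <- map_estimate(Cr[sample(20), ], flat_prior(3))
  expect_equal(fitp$phi, fit3$phi, tolerance = 1e-6)
})

test_that("MAP with an informative beta prior shrinks toward the prior mode", {
  set.seed(18)
  lab <- sample.int(3, 30, TRUE, prob = c(0.7, 0.2, 0.1))
  C <- indicator_matrix(lab, 3)
  mle <- tabulate(lab, 3) / 30
  pr <- beta_prior_from_extremum(rep(1 / 3, 3), 0.01^2)
  fit <- map_estimate(C, pr)
  # strictly between the MLE and the prior mode
  expect_true(all(abs(fit$phi - 1 / 3) < abs(mle - 1 / 3) + 1e-9))
  expect_lt(fit$kkt, 1e-5)
})
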