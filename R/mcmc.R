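#' Metropolis-Hastings chain configuration
#'
#' The posterior lives on the `(n-1)`-dimensional probability simplex,
#' so proposals are drawn in reduced coordinates (the first `n - 1`
#' weights) from a multivariate normal, and the last weight is set by
#' the closing condition `phi_n = 1 - sum(others)`.  Candidates with a
#' negative coordinate are rejected by the acceptance rule, never
#' repaired.
#'
#' @param S_phi chain length.
#' @param Sigma_r proposal covariance (`(n-1) x (n-1)`); default
#'   diagonal with standard deviation `0.05 / sqrt(n)`.
#' @param phi0 initial simplex point (default: uniform weights; the
#'   MAP estimate is a good choice when available).
#' @param burn_in fraction of the chain discarded by summaries, in
#'   `[0, 0.5]`.
#' @param thin thinning stride for stored draws.
#' @param adapt if `TRUE`, the proposal scale is tuned by a
#'   Robbins-Monro rule toward 23 percent acceptance during burn-in
#'   only, then frozen (adaptation after burn-in would break the
#'   Markov property).
#' @param close_index which coordinate is computed from the closing
#'   condition (default the last).
#' @return object of class `chain_config`.
#' @export
chain_config <- function(S_phi = 1e5, Sigma_r = NULL, phi0 = NULL,
                         burn_in = 0.1, thin = 1, adapt = FALSE,
                         close_index = NULL) {
  stopifnot(S_phi >= 10, burn_in >= 0, burn_in <= 0.5, thin >= 1)
  structure(list(S_phi = as.integer(S_phi), Sigma_r = Sigma_r,
                 phi0 = phi0, burn_in = burn_in, thin = as.integer(thin),
                 adapt = adapt, close_index = close_index),
            class = "chain_config")
}

#' Simplex proposal with closing condition
#'
#' Draws the reduced coordinates from a normal centered at the current
#' point and closes the remaining weight so the sum is exactly one.
#' The proposal is symmetric in the reduced coordinates, so the
#' Hastings ratio reduces to the posterior ratio.
#'
#' @param phi current simplex point.
#' @param Sigma_chol Cholesky factor (upper) of the reduced proposal
#'   covariance.
#' @param close_index coordinate computed from the closing condition.
#' @return candidate weight vector summing to one; entries may be
#'   negative (handled by the acceptance probability).
#' @export
propose <- function(phi, Sigma_chol, close_index = length(phi)) {
  n <- length(phi)
  red <- setdiff(seq_len(n), close_index)
  z <- drop(rnorm(n - 1) %*% Sigma_chol)
  cand <- phi
  cand[red] <- phi[red] + z
  cand[close_index] <- 1 - sum(cand[red])
  cand
}

#' Acceptance probability of a proposed weight vector
#'
#' Zero whenever the candidate has a negative coordinate (the density
#' constraint), otherwise the Metropolis ratio of unnormalized
#' posteriors.
#'
#' @param phi_new,phi_old candidate and current weight vectors.
#' @param C a [conditional_matrix()].
#' @param prior a `prior_spec`.
#' @return probability in `[0, 1]`.
#' @export
acceptance_probability <- function(phi_new, phi_old, C, prior) {
  if (any(phi_new < 0)) return(0)
  lp_new <- log_posterior_unnorm(phi_new, C, prior)
  lp_old <- log_posterior_unnorm(phi_old, C, prior)
  if (!is.finite(lp_new)) return(0)
  min(1, exp(lp_new - lp_old))
}

#' Sample the posterior over the weight simplex
#'
#' Metropolis-Hastings with the reduced-proposal/closing-condition
#' scheme.  The conditional matrix is precomputed, so one iteration
#' costs a single matrix-vector product; rejected moves repeat the
#' previous state.  Deterministic for a fixed RNG state.
#'
#' @param config a [chain_config()].
#' @param C a [conditional_matrix()] (or plain matrix).
#' @param prior a `prior_spec`.
#' @return object of class `posterior_sample`: `draws`
#'   (`S x n` matrix of stored states), `log_posterior` trace,
#'   `acceptance` rate, `burn_in` (number of stored draws to discard),
#'   and the configuration.
#' @export
run_chain <- function(config, C, prior) {
  Cm <- cond_values(C)
  J <- ncol(Cm)
  close_index <- if (is.null(config$close_index)) J else config$close_index
  red <- setdiff(seq_len(J), close_index)
  phi <- if (is.null(config$phi0)) rep(1 / J, J) else
    density_parameters(config$phi0, J)
  Sigma_r <- if (is.null(config$Sigma_r))
    diag((0.05 / sqrt(J))^2, J - 1) else config$Sigma_r
  scale <- 1
  chol_base <- chol(Sigma_r)

  lpost <- function(p) {
    if (any(p < 0)) return(-Inf)
    lik <- Cm %*% p
    if (any(lik <= 0)) return(-Inf)
    sum(log(lik)) + sum(dbeta(pmin(p, 1), prior$alpha, prior$beta,
                              log = TRUE))
  }
  lp <- lpost(phi)
  if (!is.finite(lp))
    stop("initial point has zero posterior probability")

  S <- config$S_phi
  n_burn_iter <- floor(config$burn_in * S)
  keep <- seq(1, S, by = config$thin)
  draws <- matrix(NA_real_, length(keep), J)
  lptrace <- numeric(length(keep))
  n_acc <- 0; ki <- 1
  for (k in seq_len(S)) {
    z <- drop(rnorm(J - 1) %*% chol_base) * scale
    cand <- phi
    cand[red] <- phi[red] + z
    cand[close_index] <- 1 - sum(cand[red])
    accepted <- FALSE
    if (all(cand >= 0)) {
      lp_new <- lpost(cand)
      if (is.finite(lp_new) && log(runif(1)) < lp_new - lp) {
        phi <- cand; lp <- lp_new; accepted <- TRUE
      }
    } else {
      runif(1)  # keep the RNG stream aligned across accept branches
    }
    if (accepted) n_acc <- n_acc + 1
    if (config$adapt && k <= n_burn_iter)
      scale <- exp(log(scale) + k^(-0.6) * ((if (accepted) 1 else 0) - 0.23))
    if (k == keep[ki]) {
      draws[ki, ] <- phi
      lptrace[ki] <- lp
      ki <- ki + 1
    }
  }
  acc_rate <- n_acc / S
  if (acc_rate < 0.01)
    warning(sprintf("acceptance rate %.2f%%: consider rescaling Sigma_r",
                    100 * acc_rate))
  structure(list(draws = draws, log_posterior = lptrace,
                 acceptance = acc_rate,
                 burn_in = sum(keep <= n_burn_iter),
                 config = config, scale = scale),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("<posterior_sample> %d stored draws (%d burn-in), %d weights, acceptance %.1f%%\n",
              nrow(x$draws), x$burn_in, ncol(x$draws), 100 * x$acceptance))
  invisible(x)
}

#' Post-burn-in draws
#'
#' @param sample a `posterior_sample`.
#' @return matrix of retained weight vectors.
#' @export
posterior_draws <- function(sample) {
  if (x_burn <- sample$burn_in)
    sample$draws[-seq_len(x_burn), , drop = FALSE]
  else sample$draws
}

# batch-means Monte Carlo standard error of the chain mean
mcmc_se <- function(x, n_batch = 50) {
  n <- length(x)
  n_batch <- min(n_batch, max(2, n %/% 10))
  bsize <- n %/% n_batch
  bm <- vapply(seq_len(n_batch),
               function(b) mean(x[((b - 1) * bsize + 1):(b * bsize)]),
               numeric(1))
  sd(bm) / sqrt(n_batch)
}
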