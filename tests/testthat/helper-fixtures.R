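# shared fixtures: built in code, no stored data

# one-state exponential decay cell, the standard toy for oracle checks
decay_model <- function(k = 0.5) {
  sc_model(
    name = "decay1", state_dim = 1L,
    param_names = "k", nominal = c(k = k),
    rhs = function(t, x, p) -p[["k"]] * x,
    output_map = function(x) x[, 1, drop = FALSE],
    output_names = "x",
    heterogeneous = "k",
    initial_condition = function(p) 1)
}

# indicator conditional matrix: cell i assigned deterministically to
# component lab[i]; the posterior under a flat prior is then
# Dirichlet(n + 1)
indicator_matrix <- function(lab, J) {
  M <- length(lab)
  C <- matrix(0, M, J)
  C[cbind(seq_len(M), lab)] <- 1
  C
}

# direct Dirichlet sampler via gamma draws (independent oracle)
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

# analytic CDF of a univariate truncated-Gaussian mixture on [0, 1]
mixture_cdf <- function(x, weights, centers, sigmas) {
  out <- 0
  for (j in seq_along(weights)) {
    lo <- pnorm((0 - centers[j]) / sigmas[j])
    hi <- pnorm((1 - centers[j]) / sigmas[j])
    out <- out + weights[j] *
      (pnorm((x - centers[j]) / sigmas[j]) - lo) / (hi - lo)
  }
  out
}

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
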