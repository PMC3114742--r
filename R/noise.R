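#' Log-normal measurement noise specification
#'
#' Measured outputs are modeled as `yhat_k = eta_x_k * y_k + eta_a_k`
#' with independent log-normal multiplicative noise
#' `eta_x_k ~ LogN(mu_mult, sigma_mult)` and additive noise
#' `eta_a_k ~ LogN(mu_add, sigma_add)`, per output dimension `k`.
#' The defaults are the setting of the univariate TNF study:
#' 10 percent multiplicative noise around 1 plus additive background
#' around 0.05.
#'
#' @param mu_mult,sigma_mult log-scale location and scale of the
#'   multiplicative noise (sigma > 0).
#' @param mu_add,sigma_add log-scale location and scale of the
#'   additive noise (sigma > 0).
#' @param m number of output dimensions; scalar arguments are
#'   recycled.
#' @return object of class `noise_spec`: an `m x 4` parameter matrix.
#' @export
noise_spec <- function(mu_mult = 0, sigma_mult = 0.1,
                       mu_add = log(0.05), sigma_add = 0.3, m = 1) {
  par <- cbind(mu_mult = rep_len(mu_mult, m),
               sigma_mult = rep_len(sigma_mult, m),
               mu_add = rep_len(mu_add, m),
               sigma_add = rep_len(sigma_add, m))
  if (any(par[, c(2, 4)] <= 0)) stop("noise scale parameters must be > 0")
  structure(list(par = par, m = m), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat("<noise_spec> per-dimension log-normal parameters:\n")
  print(x$par)
  invisible(x)
}

#' Corrupt simulated outputs with measurement noise
#'
#' Applies the multiplicative-plus-additive log-normal noise model to
#' a matrix of true outputs.  Noise draws are independent across cells
#' and output dimensions; results are strictly positive.
#'
#' @param y matrix `n x m` (or vector) of non-negative true outputs.
#' @param spec a [noise_spec()].
#' @return matrix of corrupted outputs, same shape as `y`.
#' @export
apply_noise <- function(y, spec) {
  y <- as.matrix(y)
  if (ncol(y) != spec$m) stop("output dimension does not match noise spec")
  if (any(y < 0)) stop("true outputs must be non-negative")
  out <- y
  for (k in seq_len(spec$m)) {
    p <- spec$par[k, ]
    n <- nrow(y)
    out[, k] <- rlnorm(n, p[1], p[2]) * y[, k] + rlnorm(n, p[3], p[4])
  }
  out
}

#' Conditional density of a measured output given the true output
#'
#' Evaluates `p(yhat | y)` under the log-normal noise model.  The set
#' of noise realizations `(eta_x, eta_a)` compatible with a pair
#' `(yhat, y)` is the line `eta_x * y + eta_a = yhat` in the positive
#' quadrant; parameterizing it by the additive component gives the
#' convolution integral
#' `p(yhat|y) = integral_0^yhat f_add(s) f_mult((yhat - s)/y) / y ds`,
#' evaluated by adaptive Simpson quadrature.  This parameterization is
#' the one under which `p(yhat|y)` integrates to one in `yhat` for
#' every `y`, which is the property the likelihood requires.  For
#' `y = 0` only the additive noise remains and the density is the
#' additive log-normal itself.
#'
#' For multi-dimensional outputs the per-dimension densities are
#' multiplied (independent output errors).
#'
#' @param yhat measured output: vector (single point, length `m`) or
#'   `n x m` matrix.
#' @param y true output, recycled to the shape of `yhat`.
#' @param spec a [noise_spec()].
#' @param tol absolute quadrature tolerance.
#' @return vector of density values (length `n`).
#' @export
cond_density <- function(yhat, y, spec, tol = 1e-10) {
  yhat <- as.matrix(yhat)
  y <- as.matrix(y)
  if (ncol(yhat) == 1 && spec$m == 1) {
    n <- max(nrow(yhat), nrow(y))
    yh <- rep_len(yhat[, 1], n); yy <- rep_len(y[, 1], n)
    return(.Call("c_cond_density", as.numeric(yh), as.numeric(yy),
                 as.numeric(spec$par[1, ]), tol, PACKAGE = "popsnap"))
  }
  if (ncol(yhat) != spec$m || ncol(y) != spec$m)
    stop("output dimension does not match noise spec")
  n <- max(nrow(yhat), nrow(y))
  dens <- rep(1, n)
  for (k in seq_len(spec$m)) {
    dens <- dens * .Call("c_cond_density",
                         as.numeric(rep_len(yhat[, k], n)),
                         as.numeric(rep_len(y[, k], n)),
                         as.numeric(spec$par[k, ]), tol,
                         PACKAGE = "popsnap")
  }
  dens
}
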