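#' Truncated-Gaussian ansatz basis for the parameter density
#'
#' The unknown parameter density on the unit box `[0,1]^q` is expanded
#' as a finite weighted sum of fixed component densities ("ansatz
#' functions"): truncated Gaussians with centers on a regular grid and
#' common isotropic covariance `sigma^2 I`.  Each component is
#' renormalized to integrate to one over the box; for axis-aligned
#' covariances the normalizer is an exact product of Gaussian CDF
#' differences.
#'
#' @param dim parameter dimension `q` (1 or 2 in the shipped studies;
#'   any dimension is accepted).
#' @param n_per_dim number of grid centers per dimension (>= 2).
#' @param sigma component standard deviation; defaults to 0.55 times
#'   the grid spacing, preserving the overlap ratio of the
#'   100-component bivariate setting (spacing 1/9, sigma 0.06).
#' @param domain two-element range of every coordinate, default `c(0, 1)`.
#' @return object of class `ansatz_basis` with `n_comp = n_per_dim^dim`
#'   components.
#' @export
ansatz_basis <- function(dim, n_per_dim, sigma = NULL, domain = c(0, 1)) {
  stopifnot(dim >= 1, n_per_dim >= 2)
  spacing <- diff(domain) / (n_per_dim - 1)
  if (is.null(sigma)) sigma <- 0.55 * spacing
  if (sigma <= 0) stop("sigma must be positive")
  ax <- seq(domain[1], domain[2], length.out = n_per_dim)
  centers <- as.matrix(expand.grid(rep(list(ax), dim)))
  colnames(centers) <- paste0("theta", seq_len(dim))
  # truncation normalizer: product of per-axis Gaussian masses in the box
  mass <- pnorm((domain[2] - centers) / sigma) -
          pnorm((domain[1] - centers) / sigma)
  s_j <- apply(mass, 1, prod)
  structure(list(dim = dim, n_comp = nrow(centers), centers = centers,
                 sigma = sigma, domain = domain, normalizer = s_j),
            class = "ansatz_basis")
}

#' @export
print.ansatz_basis <- function(x, ...) {
  cat(sprintf("<ansatz_basis> %d truncated Gaussians on [%g,%g]^%d, sigma = %g\n",
              x$n_comp, x$domain[1], x$domain[2], x$dim, x$sigma))
  invisible(x)
}

# hash used to tie precomputed objects to the basis they came from
basis_hash <- function(basis) {
  v <- c(basis$dim, basis$n_comp, basis$sigma, basis$domain,
         as.numeric(basis$centers))
  paste0("b", format(sum(v * seq_along(v)) %% 1e9, scientific = FALSE))
}

#' Evaluate ansatz components at parameter points
#'
#' @param basis an [ansatz_basis()].
#' @param theta matrix `n x q` of evaluation points (vector accepted
#'   when `q = 1`).
#' @return matrix `n x n_comp` of component densities `Lambda_j(theta)`
#'   (zero outside the domain).
#' @export
basis_eval <- function(basis, theta) {
  theta <- as.matrix(theta)
  if (ncol(theta) != basis$dim) stop("theta dimension mismatch")
  n <- nrow(theta)
  inside <- rowSums(theta < basis$domain[1] | theta > basis$domain[2]) == 0
  L <- matrix(0, n, basis$n_comp)
  for (j in seq_len(basis$n_comp)) {
    z <- sweep(theta, 2, basis$centers[j, ], "-") / basis$sigma
    L[, j] <- apply(dnorm(z) / basis$sigma, 1, prod) / basis$normalizer[j]
  }
  L[!inside, ] <- 0
  L
}

#' Weight vector of the ansatz expansion
#'
#' Validates a simplex weight vector: non-negative entries summing to
#' one (tolerance 1e-12 on the sum).
#'
#' @param phi numeric weight vector.
#' @param n_comp expected length (optional).
#' @return the validated vector.
#' @export
density_parameters <- function(phi, n_comp = NULL) {
  if (!is.null(n_comp) && length(phi) != n_comp)
    stop("phi must have length ", n_comp)
  if (any(phi < 0)) stop("phi must be non-negative")
  if (abs(sum(phi) - 1) > 1e-12) stop("phi must sum to one")
  phi
}

#' Evaluate the parameterized parameter density
#'
#' `Theta_phi(theta) = sum_j phi_j Lambda_j(theta)`: a convex
#' combination of the basis components, hence itself a probability
#' density on the domain.
#'
#' @inheritParams basis_eval
#' @param phi simplex weight vector of length `n_comp`.
#' @return vector of density values.
#' @export
density_eval <- function(basis, phi, theta) {
  phi <- density_parameters(phi, basis$n_comp)
  drop(basis_eval(basis, theta) %*% phi)
}

#' Sample parameter vectors from one ansatz component
#'
#' Exact inverse-CDF sampling of the axis-aligned truncated Gaussian.
#'
#' @inheritParams basis_eval
#' @param j component index.
#' @param n number of draws.
#' @return matrix `n x q` of draws inside the domain.
#' @export
sample_ansatz <- function(basis, j, n) {
  stopifnot(j >= 1, j <= basis$n_comp, n >= 1)
  mu <- basis$centers[j, ]
  lo <- pnorm((basis$domain[1] - mu) / basis$sigma)
  hi <- pnorm((basis$domain[2] - mu) / basis$sigma)
  th <- vapply(seq_len(basis$dim), function(d) {
    u <- runif(n, lo[d], hi[d])
    mu[d] + basis$sigma * qnorm(u)
  }, numeric(n))
  th <- matrix(th, nrow = n)
  pmin(pmax(th, basis$domain[1]), basis$domain[2])
}

#' Sample from the full parameter density
#'
#' Draws component labels from `phi` and then parameters from the
#' selected components.
#'
#' @inheritParams density_eval
#' @param n number of draws.
#' @return matrix `n x q`.
#' @export
sample_density <- function(basis, phi, n) {
  phi <- density_parameters(phi, basis$n_comp)
  lab <- sample.int(basis$n_comp, n, replace = TRUE, prob = phi)
  th <- matrix(NA_real_, n, basis$dim)
  for (j in unique(lab)) {
    idx <- which(lab == j)
    th[idx, ] <- sample_ansatz(basis, j, length(idx))
  }
  th
}

# --- kernel density estimation of output densities -------------------

#' Rule-of-thumb bandwidth for log-normal kernels
#'
#' Silverman-type bandwidth computed in log space (the geometry of the
#' log-normal kernel): per dimension
#' `h_d = sd(log y_d) * (4 / ((m + 2) S))^(1 / (m + 4))`, shrinking as
#' `S^{-1/(m+4)}`.  Degenerate (zero-spread) dimensions fall back to a
#' floor bandwidth with a warning.
#'
#' @param samples matrix `S x m` of positive output samples.
#' @param floor minimum bandwidth (log scale).
#' @return diagonal bandwidth matrix `H` (`m x m`), entries `h_d^2`.
#' @export
bandwidth_rule_of_thumb <- function(samples, floor = 1e-3) {
  samples <- as.matrix(samples)
  S <- nrow(samples); m <- ncol(samples)
  if (S < 2) stop("need at least two samples")
  if (any(samples <= 0)) stop("log-normal kernels require positive samples")
  sdlog <- apply(log(samples), 2, sd)
  if (any(sdlog < .Machine$double.eps^0.5)) {
    warning("zero-spread sample dimension; using floor bandwidth")
    sdlog <- pmax(sdlog, floor)
  }
  h <- sdlog * (4 / ((m + 2) * S))^(1 / (m + 4))
  h <- pmax(h, floor)
  diag(h^2, m)
}

#' Kernel density estimate with log-normal kernels
#'
#' `Yhat(y) = (1/S) sum_i K_H(y | y_i)` with multivariate log-normal
#' kernels, which keep the estimate supported on positive outputs.
#'
#' @param samples matrix `S x m` of positive samples.
#' @param H diagonal bandwidth matrix (see
#'   [bandwidth_rule_of_thumb()]); if `NULL`, the rule of thumb is
#'   applied.
#' @param grid matrix `G x m` of positive evaluation points.
#' @return vector of `G` density values.
#' @export
kde_lognormal <- function(samples, grid, H = NULL) {
  samples <- as.matrix(samples); grid <- as.matrix(grid)
  if (any(samples <= 0)) stop("log-normal kernels require positive samples")
  if (any(grid <= 0)) stop("evaluation grid must be positive")
  if (ncol(samples) != ncol(grid)) stop("dimension mismatch")
  if (is.null(H)) H <- bandwidth_rule_of_thumb(samples)
  m <- ncol(samples)
  h <- sqrt(diag(as.matrix(H))[seq_len(m)])
  lg <- log(grid); ls <- log(samples)
  dens <- matrix(1, nrow(grid), nrow(samples))
  for (d in seq_len(m)) {
    z <- outer(lg[, d], ls[, d], "-") / h[d]
    dens <- dens * dnorm(z) / (h[d] * grid[, d])
  }
  rowMeans(dens)
}

#' Output-density components of the ansatz basis
#'
#' For each ansatz component `Lambda_j`, draws `S` parameter vectors,
#' simulates the single-cell model, optionally corrupts the outputs
#' with measurement noise (to predict measured rather than true
#' outputs), and applies the log-normal KDE on a fixed output grid.
#' The resulting per-component output densities are computed once and
#' reused for every weight vector: the population response obeys the
#' superposition principle in `phi`.
#'
#' @param basis an [ansatz_basis()].
#' @param model an [sc_model()]; its heterogeneous dimension must
#'   equal `basis$dim`.
#' @param times measurement times.
#' @param S trajectories per component (>= 100 recommended).
#' @param grid output evaluation grid: vector (m = 1) or `G x m`
#'   matrix of positive points.
#' @param noise optional [noise_spec()]; when supplied the components
#'   describe measured-output densities.
#' @param u stimulus level.
#' @return object of class `output_components` with a `values` array
#'   `G x length(times) x n_comp`.
#' @export
output_density_components <- function(basis, model, times, S = 1000,
                                      grid, noise = NULL, u = 1) {
  if (model$q != basis$dim)
    stop("model heterogeneous dimension and basis dimension differ")
  grid <- as.matrix(grid)
  G <- nrow(grid)
  vals <- array(0, c(G, length(times), basis$n_comp))
  bw <- array(NA_real_, c(length(times), basis$n_comp, model$m))
  for (j in seq_len(basis$n_comp)) {
    th <- sample_ansatz(basis, j, S)
    ys <- simulate_population(model, th, times, u = u)
    for (ti in seq_along(times)) {
      yt <- matrix(ys[, ti, ], nrow = S)
      if (!is.null(noise)) yt <- apply_noise(yt, noise)
      else if (any(yt <= 0))
        stop("true outputs contain zeros at t = ", times[ti],
             "; supply a noise spec or restrict times to t > 0")
      H <- bandwidth_rule_of_thumb(yt)
      bw[ti, j, ] <- diag(as.matrix(H))[seq_len(model$m)]
      vals[, ti, j] <- kde_lognormal(yt, grid, H = H)
    }
  }
  structure(list(grid = grid, times = times, values = vals, S = S,
                 bandwidth = bw,
                 noisy = !is.null(noise), basis_hash = basis_hash(basis)),
            class = "output_components")
}

#' Population output density by superposition
#'
#' `Y(y | t, Theta_phi) = sum_j phi_j Y(y | t, Lambda_j)`: linear in
#' the weights, evaluated on the precomputed component grid.
#'
#' @param components an [output_density_components()] result.
#' @param phi simplex weight vector.
#' @return matrix `G x length(times)`.
#' @export
output_density <- function(components, phi) {
  phi <- density_parameters(phi, dim(components$values)[3])
  G <- dim(components$values)[1]; nt <- dim(components$values)[2]
  out <- matrix(0, G, nt)
  for (ti in seq_len(nt))
    out[, ti] <- matrix(components$values[, ti, ], nrow = G) %*% phi
  out
}

#' Default positive output grid
#'
#' Log-spaced grid suitable for log-normal-kernel output densities.
#'
#' @param lower,upper grid range (positive).
#' @param n number of points.
#' @return numeric vector.
#' @export
output_grid <- function(lower = 1e-3, upper = 3, n = 201) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Exact measured-output density of a known parameter density
#'
#' Computes the measured-output density implied by a known
#' (ground-truth) parameter density by direct quadrature over the
#' one-dimensional parameter domain:
#' `Ybar(yhat | t) = integral p(yhat | y(t, theta)) f(theta) dtheta`.
#' Unlike a kernel density estimate of a finite synthetic sample, the
#' result carries no sampling error, which makes it the right
#' reference when checking prediction-band calibration.  To compare
#' against KDE-based predictions on equal footing the curve can be
#' convolved with the same log-normal kernel via [smooth_lognormal()].
#'
#' @param truth a [true_density_mixture()] with `q = 1`.
#' @param model an [sc_model()] with one heterogeneous parameter.
#' @param times measurement times.
#' @param grid positive output evaluation points (vector).
#' @param spec a [noise_spec()].
#' @param n_quad quadrature nodes over the parameter domain.
#' @param u stimulus level.
#' @return matrix `length(grid) x length(times)`.
#' @export
true_output_density <- function(truth, model, times, grid, spec,
                                n_quad = 601, u = 1) {
  if (truth$q != 1)
    stop("exact quadrature reference implemented for 1-D parameters only")
  # midpoint nodes: keeps parameters strictly inside the domain (the
  # boundary can be degenerate for threshold parameters) and handles
  # the truncated-Gaussian mass cleanly
  hstep <- diff(truth$domain) / n_quad
  th <- truth$domain[1] + hstep * (seq_len(n_quad) - 0.5)
  w <- truth$density(matrix(th))
  ys <- simulate_population(model, matrix(th), times, u = u)  # n_quad x nt x 1
  grid <- as.numeric(grid)
  out <- matrix(0, length(grid), length(times))
  for (ti in seq_along(times)) {
    P <- vapply(seq_len(n_quad), function(k)
      cond_density(matrix(grid), matrix(ys[k, ti, 1]), spec),
      numeric(length(grid)))
    out[, ti] <- P %*% (w * hstep)
  }
  out
}

#' Smooth a density curve with a log-normal kernel
#'
#' Convolves a density on a positive grid with the log-normal kernel
#' of (log-scale) variance `H`, reproducing the smoothing a kernel
#' density estimate with that bandwidth applies in the large-sample
#' limit.
#'
#' @param grid positive, ascending evaluation points.
#' @param values density values on `grid`.
#' @param H kernel variance (log scale, scalar).
#' @return smoothed density values on `grid`.
#' @export
smooth_lognormal <- function(grid, values, H) {
  h <- sqrt(H)
  lg <- log(grid)
  K <- outer(lg, lg, function(a, b) dnorm((a - b) / h)) / (h * grid)
  as.numeric(vapply(seq_along(grid), function(i)
    trapz(grid, K[i, ] * values), numeric(1)))
}
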