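#' Population snapshot dataset
#'
#' A collection of single-cell data points `(t_i, yhat_i)` grouped
#' into snapshots by measurement time.  Cells are measured at most
#' once (no tracking), so all data points are independent.
#'
#' @param time numeric vector of per-cell measurement times.
#' @param y matrix `M x m` (or vector) of measured outputs; must be
#'   strictly positive (log-normal noise support).
#' @param cell_id optional identifiers; duplicates are rejected
#'   because a cell can appear in at most one snapshot.
#' @param time_tol times closer than this are grouped into one
#'   snapshot.
#' @return object of class `snapshot_dataset` with fields `y`, `time`,
#'   `snapshot_times`, `snapshot_index` (index sets), `M`, `M_j`.
#' @export
snapshot_dataset <- function(time, y, cell_id = NULL, time_tol = 1e-9) {
  y <- as.matrix(y)
  if (length(time) != nrow(y)) stop("time and y lengths differ")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("measured outputs must be finite and strictly positive")
  if (!is.null(cell_id) && anyDuplicated(cell_id))
    stop("duplicate cell_id: each cell is measured at most once")
  ord <- order(time)
  time <- time[ord]; y <- y[ord, , drop = FALSE]
  if (!is.null(cell_id)) cell_id <- cell_id[ord]
  ut <- time[c(TRUE, diff(time) > time_tol)]
  tidx <- findInterval(time, ut + time_tol) + 1L
  idx <- split(seq_along(time), tidx)
  structure(list(y = y, time = time, cell_id = cell_id,
                 snapshot_times = ut, time_index = tidx,
                 snapshot_index = idx, M = length(time),
                 M_j = lengths(idx), m = ncol(y)),
            class = "snapshot_dataset")
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  cat(sprintf("<snapshot_dataset> %d cells, %d output dim(s)\n", x$M, x$m))
  cat("  snapshots:",
      paste(sprintf("t=%g (%d)", x$snapshot_times, x$M_j), collapse = ", "),
      "\n")
  invisible(x)
}

#' Conditional-probability matrix
#'
#' Precomputes `c_ij = p(D_i | Lambda_j)`, the probability of the
#' i-th single-cell datum under the j-th ansatz component, by Monte
#' Carlo integration: `S_c` parameter vectors are drawn from each
#' component, each is simulated once over all snapshot times, and the
#' measurement-noise density links simulated to measured outputs.
#' Afterwards every posterior evaluation is a scalar product
#' `<c_i, phi>` and requires no further simulation.
#'
#' @param data a [snapshot_dataset()].
#' @param basis an [ansatz_basis()].
#' @param model an [sc_model()].
#' @param spec a [noise_spec()].
#' @param S_c Monte Carlo draws per ansatz component.
#' @param method noise-density evaluation: `"exact"` adaptive Simpson
#'   per pair, `"grid"` a bilinear table on a log-log grid (used
#'   automatically for very large problems under `"auto"`).
#' @param tol quadrature tolerance for the noise density (the
#'   Monte Carlo error of the matrix entries dominates well before
#'   this).
#' @param u stimulus level.
#' @return object of class `cond_matrix`: field `values` is the
#'   `M x n_comp` matrix, plus provenance metadata.  Cells whose row
#'   is entirely zero (unexplainable under the basis) trigger a
#'   warning.
#' @export
conditional_matrix <- function(data, basis, model, spec, S_c = 1000,
                               method = c("auto", "exact", "grid"),
                               tol = 1e-8, u = 1) {
  method <- match.arg(method)
  if (S_c < 2) stop("S_c too small")
  if (data$m != model$m) stop("data and model output dimensions differ")
  nt <- length(data$snapshot_times)
  J <- basis$n_comp
  # one simulation per draw, evaluated at all snapshot times
  ysim <- array(NA_real_, c(S_c, nt, model$m, J))
  for (j in seq_len(J)) {
    th <- sample_ansatz(basis, j, S_c)
    ysim[, , , j] <- simulate_population(model, th, data$snapshot_times, u = u)
  }
  n_pairs <- as.numeric(data$M) * J * S_c * model$m
  use_grid <- switch(method, exact = FALSE, grid = TRUE,
                     auto = n_pairs > 2e6)
  C <- .Call("c_cond_matrix", data$y, as.integer(data$time_index),
             as.numeric(ysim), as.integer(c(S_c, nt, model$m, J)),
             spec$par, tol, use_grid, c(400L, 240L),
             PACKAGE = "popsnap")
  zero_rows <- which(rowSums(C) == 0)
  if (length(zero_rows))
    warning("cells with zero likelihood under every component: ",
            paste(utils::head(zero_rows, 10), collapse = ", "))
  structure(list(values = C, S_c = S_c, basis_hash = basis_hash(basis),
                 method = if (use_grid) "grid" else "exact",
                 model = model$name),
            class = "cond_matrix")
}

cond_values <- function(C) if (inherits(C, "cond_matrix")) C$values else as.matrix(C)

# --- priors ----------------------------------------------------------

#' Beta-product prior over the weight simplex
#'
#' Each weight gets an independent beta density whose mode sits at the
#' requested extremum and whose variance equals `sigma2`; the shape
#' parameters are solved numerically.  At `sigma = 0.285` the prior is
#' practically uniform (the mode-constrained beta variance approaches
#' 1/12 as `alpha, beta -> 1`), so that value marks the uninformative
#' end of the scale.  The simplex constraint itself (non-negativity,
#' unit sum) is enforced by the prior support, not by these factors.
#'
#' @param phi_ext simplex vector of per-weight extremum (mode)
#'   locations; a flat-shaped prior uses `rep(1/n, n)`.
#' @param sigma2 prior variance per weight, in `(0, 0.285^2]`.
#' @return object of class `prior_spec` with vectors `alpha`, `beta`.
#' @export
beta_prior_from_extremum <- function(phi_ext, sigma2) {
  phi_ext <- density_parameters(phi_ext)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  n <- length(phi_ext)
  alpha <- beta <- numeric(n)
  for (j in seq_len(n)) {
    mj <- phi_ext[j]
    varfun <- function(s) {
      a <- 1 + mj * (s - 2); b <- s - a
      a * b / ((a + b)^2 * (a + b + 1)) - sigma2
    }
    # variance decreases in s = alpha + beta; s -> 2 gives 1/12
    if (varfun(2 + 1e-9) <= 0) {
      warning("requested prior variance infeasible for a mode at ",
              signif(mj, 3), "; using the nearest (almost uniform) beta")
      s <- 2 + 1e-9
    } else {
      s <- uniroot(varfun, c(2 + 1e-9, 1e8), tol = 1e-12)$root
    }
    alpha[j] <- 1 + mj * (s - 2)
    beta[j] <- s - alpha[j]
  }
  structure(list(family = "beta-product", phi_ext = phi_ext,
                 sigma2 = sigma2, alpha = alpha, beta = beta),
            class = "prior_spec")
}

#' Flat prior over the weight simplex
#'
#' All beta factors are Beta(1, 1); only the simplex support matters.
#'
#' @param n number of weights.
#' @return a `prior_spec`.
#' @export
flat_prior <- function(n) {
  structure(list(family = "beta-product", phi_ext = rep(1 / n, n),
                 sigma2 = NA_real_, alpha = rep(1, n), beta = rep(1, n)),
            class = "prior_spec")
}

#' Log prior density of a weight vector
#'
#' Returns `-Inf` off the simplex (any negative weight, or sum away
#' from one beyond 1e-9); on the simplex, the sum of the log beta
#' factors.
#'
#' @param phi weight vector.
#' @param prior a `prior_spec`.
#' @return scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(phi, prior) {
  if (any(phi < 0) || abs(sum(phi) - 1) > 1e-9) return(-Inf)
  sum(dbeta(pmin(phi, 1), prior$alpha, prior$beta, log = TRUE))
}

#' Unnormalized log posterior of the weight vector
#'
#' `sum_i log <c_i, phi> + log p(Theta_phi)`: the precomputed
#' conditional matrix turns the data likelihood into `M` scalar
#' products, so no simulation happens here.
#'
#' @param phi weight vector.
#' @param C a [conditional_matrix()] (or plain matrix).
#' @param prior a `prior_spec`.
#' @return scalar (possibly `-Inf` when a cell has zero likelihood or
#'   `phi` is off the simplex).
#' @export
log_posterior_unnorm <- function(phi, C, prior) {
  lp <- log_prior(phi, prior)
  if (!is.finite(lp)) return(-Inf)
  lik <- cond_values(C) %*% phi
  if (any(lik <= 0)) return(-Inf)
  sum(log(lik)) + lp
}

# --- MAP estimation --------------------------------------------------

# EM / multiplicative updates for the flat-prior (maximum likelihood)
# problem; globally convergent for this concave objective
em_weights <- function(Cm, phi0, iter = 500, tol = 1e-12) {
  phi <- phi0
  M <- nrow(Cm)
  for (it in seq_len(iter)) {
    lik <- drop(Cm %*% phi)
    lik[lik <= 0] <- 1e-300
    newphi <- phi * drop(crossprod(Cm, 1 / lik)) / M
    newphi <- newphi / sum(newphi)
    if (max(abs(newphi - phi)) < tol) { phi <- newphi; break }
    phi <- newphi
  }
  phi
}

#' Maximum a posteriori weight estimate
#'
#' Maximizes the unnormalized log posterior over the weight simplex.
#' For beta priors with `alpha, beta >= 1` the negative objective is
#' convex; it is solved by a logarithmic-barrier interior method
#' ([stats::constrOptim()]) in the `n - 1` reduced coordinates, warm
#' started from expectation-maximization updates of the likelihood
#' part.  Under a flat prior the EM fixed point itself is the global
#' optimum and is returned when it scores at least as well.
#'
#' @param C a [conditional_matrix()] (or plain `M x n` matrix).
#' @param prior a `prior_spec`; default flat.
#' @param maxit iteration budget for the barrier solver.
#' @return list with `phi` (the MAP weights), `log_posterior`, and
#'   `kkt` (max-norm of the projected gradient at the solution).
#' @export
map_estimate <- function(C, prior = NULL, maxit = 500) {
  Cm <- cond_values(C)
  J <- ncol(Cm); M <- nrow(Cm)
  if (is.null(prior)) prior <- flat_prior(J)
  if (any(prior$alpha < 1) || any(prior$beta < 1))
    warning("prior is not log-concave (alpha or beta < 1); ",
            "the solver may find a local optimum")
  if (J == 1) {
    phi <- 1
    return(list(phi = phi, log_posterior = log_posterior_unnorm(phi, Cm, prior),
                kkt = 0))
  }
  Cm_safe <- pmax(Cm, 1e-300)    # floor inside the solver only

  neg_obj <- function(psi) {
    phi <- c(psi, 1 - sum(psi))
    lik <- drop(Cm_safe %*% phi)
    if (any(lik <= 0) || any(phi < 0)) return(1e12)
    -(sum(log(lik)) +
        sum((prior$alpha - 1) * log(pmax(phi, 1e-300))) +
        sum((prior$beta - 1) * log(pmax(1 - phi, 1e-300))))
  }
  neg_grad <- function(psi) {
    phi <- c(psi, 1 - sum(psi))
    lik <- drop(Cm_safe %*% phi)
    gfull <- drop(crossprod(Cm_safe, 1 / lik)) +
      (prior$alpha - 1) / pmax(phi, 1e-300) -
      (prior$beta - 1) / pmax(1 - phi, 1e-12)
    -(gfull[-J] - gfull[J])
  }

  # feasible interior warm start from EM on the likelihood part
  phi_em <- em_weights(Cm_safe, rep(1 / J, J), iter = 400)
  starts <- list(0.999 * phi_em + 0.001 / J, rep(1 / J, J))
  if (!all(prior$alpha == 1) || !all(prior$beta == 1))
    starts <- c(starts, list(0.5 * phi_em + 0.5 * prior$phi_ext))

  # linear inequality constraints on psi: psi >= 0, sum(psi) <= 1
  ui <- rbind(diag(J - 1), rep(-1, J - 1))
  ci <- c(rep(0, J - 1), -1)
  best <- NULL
  for (s in starts) {
    psi0 <- pmin(pmax(s[-J], 1e-10), 1 - 1e-10)
    fit <- tryCatch(
      constrOptim(psi0, neg_obj, neg_grad, ui = ui, ci = ci,
                  mu = 1e-8, outer.iterations = 50, outer.eps = 1e-10,
                  method = "BFGS",
                  control = list(maxit = maxit, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("MAP solver failed; check the conditional matrix")
  phi <- c(best$par, 1 - sum(best$par))
  phi[phi < 0] <- 0
  phi <- phi / sum(phi)

  # under a flat prior the EM fixed point is the exact optimum; keep
  # whichever scores better
  if (all(prior$alpha == 1) && all(prior$beta == 1)) {
    phi_em <- em_weights(Cm_safe, phi_em, iter = 2000)
    if (neg_obj_full(phi_em, Cm_safe, prior) <
        neg_obj_full(phi, Cm_safe, prior))
      phi <- phi_em
  }

  # KKT residual: projected gradient on the active simplex face
  lik <- drop(Cm_safe %*% phi)
  g <- drop(crossprod(Cm_safe, 1 / lik)) +
    (prior$alpha - 1) / pmax(phi, 1e-300) -
    (prior$beta - 1) / pmax(1 - phi, 1e-12)
  act_set <- phi > 1e-9
  kkt <- if (any(act_set)) max(abs(g[act_set] - mean(g[act_set]))) / M else Inf
  list(phi = phi, log_posterior = log_posterior_unnorm(phi, Cm, prior),
       kkt = kkt)
}

neg_obj_full <- function(phi, Cm, prior) {
  lik <- drop(Cm %*% phi)
  -(sum(log(pmax(lik, 1e-300))) +
      sum((prior$alpha - 1) * log(pmax(phi, 1e-300))) +
      sum((prior$beta - 1) * log(pmax(1 - phi, 1e-300))))
}
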