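#' Pointwise credible band for the parameter density
#'
#' For every grid point `theta`, the posterior sample of weight
#' vectors induces a sample of density values
#' `Theta_phi(theta) = <Lambda(theta), phi>`; percentile intervals of
#' that sample (linear interpolation between closest ranks) give
#' pointwise credible bands.  Bands are pointwise, not simultaneous:
#' the 95 percent band covers the density value at each `theta`
#' separately with posterior probability 0.95.
#'
#' @param sample a [run_chain()] result.
#' @param basis the [ansatz_basis()] the chain was run against.
#' @param grid matrix (or vector) of parameter evaluation points.
#' @param levels credible levels, default `c(0.80, 0.90, 0.95, 0.99)`.
#' @return object of class `confidence_band`: `grid`, `levels`,
#'   `lower`/`upper` (matrices, one column per level), `map` (curve at
#'   the highest-posterior stored draw) and `mean` (pointwise chain
#'   mean).
#' @export
density_band <- function(sample, basis, grid,
                         levels = c(0.80, 0.90, 0.95, 0.99)) {
  draws <- posterior_draws(sample)
  if (nrow(draws) < 100)
    warning("fewer than 100 posterior draws; percentiles are unstable")
  grid <- as.matrix(grid)
  L <- basis_eval(basis, grid)              # G x J
  vals <- L %*% t(draws)                    # G x K
  lp <- drop_burn(sample$log_posterior, sample$burn_in)
  center <- drop(L %*% draws[which.max(lp), ])
  band_from_values(vals, grid, levels, center)
}

drop_burn <- function(x, n) if (n > 0) x[-seq_len(n)] else x

# pointwise percentile band: for level L the interval is
# [q((1-L)/2), q(1-(1-L)/2)], linear rank interpolation
band_from_values <- function(vals, grid, levels, center) {
  levels <- sort(levels)
  nl <- length(levels)
  qs <- c((1 - levels) / 2, 1 - (1 - levels) / 2)
  Q <- t(apply(vals, 1, quantile, probs = qs, names = FALSE, type = 7))
  structure(list(grid = grid, levels = levels,
                 lower = Q[, seq_len(nl), drop = FALSE],
                 upper = Q[, nl + seq_len(nl), drop = FALSE],
                 map = center, mean = rowMeans(vals)),
            class = "confidence_band")
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf("<confidence_band> %d grid points, levels %s\n",
              nrow(as.matrix(x$grid)),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Pointwise prediction band for the output density
#'
#' Maps every posterior draw to a predicted output density by
#' superposition of the precomputed per-component output densities
#' (no ODE is solved here), then takes pointwise percentiles in `y`.
#' The center curve is the prediction at the highest-posterior draw.
#'
#' @param sample a [run_chain()] result.
#' @param components an [output_density_components()] result covering
#'   the requested times.
#' @param levels credible levels.
#' @return named list of `confidence_band` objects, one per time.
#' @export
prediction_band <- function(sample, components,
                            levels = c(0.80, 0.90, 0.95, 0.99)) {
  draws <- posterior_draws(sample)
  lp <- drop_burn(sample$log_posterior, sample$burn_in)
  phi_map <- draws[which.max(lp), ]
  out <- vector("list", length(components$times))
  G <- dim(components$values)[1]
  for (ti in seq_along(components$times)) {
    V <- matrix(components$values[, ti, ], nrow = G)   # G x J
    vals <- V %*% t(draws)
    out[[ti]] <- band_from_values(vals, components$grid, levels,
                                  drop(V %*% phi_map))
  }
  names(out) <- paste0("t=", components$times)
  out
}

#' Integrated squared difference between two densities
#'
#' `integral (a - b)^2 dtheta` by the trapezoidal rule; the sampling
#' metric used to score estimated against true parameter densities
#' (integrated mean square error when averaged over realizations).
#' Supports a one-dimensional grid (vectors) or a two-dimensional
#' tensor grid (list of two axes with matrix-valued curves).
#'
#' @param density_a,density_b density values on the common grid.
#' @param grid numeric vector, or list of two axis vectors.
#' @return non-negative scalar.
#' @export
imse <- function(density_a, density_b, grid) {
  if (is.list(grid)) {
    A <- as.matrix(density_a) - as.matrix(density_b)
    if (!all(dim(A) == c(length(grid[[1]]), length(grid[[2]]))))
      stop("curves do not match the tensor grid")
    rowint <- apply(A^2, 2, function(col) trapz(grid[[1]], col))
    return(trapz(grid[[2]], rowint))
  }
  if (length(density_a) != length(grid) ||
      length(density_b) != length(grid))
    stop("curves and grid have different lengths")
  trapz(grid, (density_a - density_b)^2)
}

#' Local maxima of a density curve
#'
#' Interior local maxima above a prominence threshold, used to count
#' and locate modes of an estimated density.
#'
#' @param grid ascending evaluation points.
#' @param values density values.
#' @param min_height modes below `min_height * max(values)` are
#'   ignored.
#' @return data frame with `location` and `height`.
#' @export
find_modes <- function(grid, values, min_height = 0.1) {
  n <- length(values)
  is_max <- c(FALSE, values[2:(n - 1)] > values[1:(n - 2)] &
                     values[2:(n - 1)] >= values[3:n], FALSE)
  is_max <- is_max & values > min_height * max(values)
  data.frame(location = grid[is_max], height = values[is_max])
}
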