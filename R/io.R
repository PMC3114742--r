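#' Read and write snapshot datasets
#'
#' Snapshot files are plain CSV with columns `cell_id`, `time` and one
#' or two output columns (`y_1`, `y_2`).  Reading validates the data:
#' rows with non-positive or non-finite outputs are rejected with
#' their line numbers, and duplicate cell identifiers are an error
#' since a cell can be measured at most once.  An optional JSON
#' sidecar (`<path>.json`) records provenance (seed, generator
#' settings) and is written alongside when supplied.
#'
#' @param path CSV file path.
#' @param sidecar optional list serialized to `<path>.json`.
#' @param time_tol grouping tolerance for snapshot times.
#' @return `read_snapshots()`: a [snapshot_dataset()];
#'   `write_snapshots()`: the path, invisibly.
#' @export
read_snapshots <- function(path, time_tol = 1e-9) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty snapshot file: ", path)
  need <- c("cell_id", "time")
  if (!all(need %in% names(df)))
    stop("snapshot file must have columns cell_id, time, y_1[, y_2]")
  ycols <- grep("^y_[0-9]+$", names(df), value = TRUE)
  if (!length(ycols)) stop("no output columns (y_1, ...) in ", path)
  y <- as.matrix(df[, ycols, drop = FALSE])
  bad <- which(!is.finite(y) | y <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rows <- sort(unique(bad[, 1]))
    warning("rejected ", length(rows),
            " row(s) with non-positive outputs (lines ",
            paste(utils::head(rows + 1L, 10), collapse = ", "),
            " of the file)")
    df <- df[-rows, , drop = FALSE]
    y <- y[-rows, , drop = FALSE]
    if (!nrow(df)) stop("no valid rows left in ", path)
  }
  snapshot_dataset(df$time, y, cell_id = df$cell_id, time_tol = time_tol)
}

#' @rdname read_snapshots
#' @param data a [snapshot_dataset()].
#' @export
write_snapshots <- function(data, path, sidecar = NULL) {
  y <- as.matrix(data$y)
  df <- data.frame(cell_id = if (is.null(data$cell_id))
    seq_len(data$M) else data$cell_id,
    time = data$time)
  for (k in seq_len(ncol(y))) df[[paste0("y_", k)]] <- y[, k]
  write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of an end-to-end run in one (serializable)
#' object: model and heterogeneous-parameter selection, ansatz basis,
#' prior, noise, Monte Carlo sizes, chain settings, grids and seed.
#' A configuration round-trips losslessly through YAML.
#'
#' @param model_name registry key, e.g. `"tnf4"`.
#' @param outputs measured outputs.
#' @param heterogeneous heterogeneous parameter names.
#' @param basis list `(n_per_dim, sigma)`.
#' @param prior list `(phi_ext = "flat"` or vector`, sigma2)`;
#'   `sigma2 = NULL` requests a flat prior.
#' @param noise list of [noise_spec()] arguments.
#' @param S_c Monte Carlo draws per component for the conditional
#'   matrix.
#' @param S trajectories per component for output densities.
#' @param chain list of [chain_config()] arguments.
#' @param theta_grid_n points per dimension of the parameter grid.
#' @param output_grid list `(lower, upper, n)`.
#' @param seed integer seed; `NULL` draws one and records it.
#' @return object of class `run_config`.
#' @export
run_config <- function(model_name = "tnf4", outputs = "C3a",
                       heterogeneous = "b3",
                       basis = list(n_per_dim = 15, sigma = NULL),
                       prior = list(phi_ext = "flat", sigma2 = 0.05^2),
                       noise = list(mu_mult = 0, sigma_mult = 0.1,
                                    mu_add = log(0.05), sigma_add = 0.3),
                       S_c = 1000, S = 1000,
                       chain = list(S_phi = 1e4),
                       theta_grid_n = 201,
                       output_grid = list(lower = 1e-3, upper = 3, n = 201),
                       seed = NULL) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; using and recording seed ", seed)
  }
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$noise <- lapply(obj$noise, as.numeric)
  do.call(run_config, obj)
}

#' End-to-end analysis pipeline
#'
#' Runs the full procedure on a snapshot dataset: precompute
#' per-component output simulations and the conditional matrix, fit
#' the MAP weights, sample the posterior, and compute credible bands
#' for the parameter density and prediction bands for the measured
#' output density.  Rerunning with the same configuration and data
#' reproduces identical results.
#'
#' @param data a [snapshot_dataset()] (or path to a snapshot CSV).
#' @param config a [run_config()].
#' @param truth optional [true_density_mixture()]; when given, the
#'   integrated squared error of the MAP density against it is
#'   reported.
#' @param out_dir optional directory; when set, band tables and the
#'   MAP weights are written as CSV with a JSON provenance sidecar.
#' @return list with `map`, `chain`, `density_band`,
#'   `prediction_bands`, `theta_grid`, `imse` (or `NULL`), `config`.
#' @export
run_pipeline <- function(data, config, truth = NULL, out_dir = NULL) {
  if (is.character(data)) data <- read_snapshots(data)
  set.seed(config$seed)
  model <- get_model(config$model_name, outputs = config$outputs,
                     heterogeneous = config$heterogeneous)
  basis <- ansatz_basis(model$q, config$basis$n_per_dim,
                        sigma = config$basis$sigma)
  spec <- do.call(noise_spec, c(config$noise, list(m = model$m)))
  prior <- if (is.null(config$prior$sigma2)) flat_prior(basis$n_comp)
  else {
    pe <- config$prior$phi_ext
    if (identical(pe, "flat")) pe <- rep(1 / basis$n_comp, basis$n_comp)
    beta_prior_from_extremum(pe, config$prior$sigma2)
  }

  C <- conditional_matrix(data, basis, model, spec, S_c = config$S_c)
  map <- map_estimate(C, prior)
  cc <- do.call(chain_config, modifyList(config$chain,
                                         list(phi0 = map$phi)))
  chain <- run_chain(cc, C, prior)

  axes <- lapply(seq_len(model$q), function(d)
    seq(0, 1, length.out = config$theta_grid_n))
  theta_grid <- as.matrix(expand.grid(axes))
  dband <- density_band(chain, basis, theta_grid)

  ogrid <- output_grid(config$output_grid$lower, config$output_grid$upper,
                       config$output_grid$n)
  ogrid_m <- do.call(cbind, rep(list(ogrid), model$m))
  comps <- output_density_components(basis, model, data$snapshot_times,
                                     S = config$S, grid = ogrid_m,
                                     noise = spec)
  pbands <- prediction_band(chain, comps)

  err <- if (!is.null(truth)) {
    truth_vals <- truth$density(theta_grid)
    map_vals <- density_eval(basis, map$phi, theta_grid)
    if (model$q == 1) imse(map_vals, truth_vals, theta_grid[, 1])
    else imse(matrix(map_vals, config$theta_grid_n),
              matrix(truth_vals, config$theta_grid_n), axes)
  }

  res <- list(map = map, chain = chain, density_band = dband,
              prediction_bands = pbands, theta_grid = theta_grid,
              components = comps, imse = err, config = config,
              basis = basis)
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

# band tables and MAP weights as delimited text with provenance
export_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bt <- band_table(res$density_band)
  write.csv(bt, file.path(out_dir, "density_band.csv"), row.names = FALSE)
  for (nm in names(res$prediction_bands)) {
    fn <- paste0("prediction_band_", gsub("[^0-9a-zA-Z.]", "_", nm), ".csv")
    write.csv(band_table(res$prediction_bands[[nm]]),
              file.path(out_dir, fn), row.names = FALSE)
  }
  write.csv(data.frame(component = seq_along(res$map$phi),
                       phi = res$map$phi),
            file.path(out_dir, "map_weights.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = res$config$seed, model = res$config$model_name,
         S_c = res$config$S_c, S = res$config$S,
         basis_hash = res$components$basis_hash,
         acceptance = res$chain$acceptance,
         imse = res$imse),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Flatten a confidence band into a table
#'
#' @param band a `confidence_band`.
#' @return data frame with grid, level, lower, upper and center
#'   columns (long format over levels).
#' @export
band_table <- function(band) {
  g <- as.matrix(band$grid)
  do.call(rbind, lapply(seq_along(band$levels), function(li) {
    data.frame(grid = g[, 1],
               grid2 = if (ncol(g) > 1) g[, 2] else NA_real_,
               level = band$levels[li],
               lower = band$lower[, li], upper = band$upper[, li],
               map = band$map, mean = band$mean)
  }))
}
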