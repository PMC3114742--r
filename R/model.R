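#' Generic single-cell ODE model
#'
#' A single-cell model couples a parameter-dependent vector field with
#' an output map and an initial-condition rule.  The population layer
#' only ever calls [simulate_output()] on it, so any ODE model can be
#' plugged into the inference machinery.
#'
#' @param name model identifier.
#' @param state_dim number of state variables.
#' @param param_names names of the full parameter vector.
#' @param nominal named numeric vector of nominal parameter values
#'   (must cover `param_names`).
#' @param rhs function `(t, x, p)` returning the time derivative as a
#'   numeric vector; `p` is the full named parameter vector including
#'   the stimulus `u`.
#' @param output_map function mapping a state matrix (rows = time
#'   points) to an output matrix with `m` columns.
#' @param output_names names of the measured outputs.
#' @param heterogeneous names of the parameters treated as the
#'   cell-to-cell variable vector `theta` (in order).
#' @param initial_condition optional function `(p)` returning the
#'   initial state; defaults to the steady state at `u = 0`.
#' @param compiled optional list with entries `func`, `initfunc`,
#'   `dllname` and `parm_order` selecting a compiled derivative
#'   function for [deSolve::ode()].
#' @param ss_pin optional index of a state pinned to zero when solving
#'   for the resting steady state.
#'
#' @return an object of class `sc_model`.
#' @seealso [tnf_model()] for the built-in TNF signaling model.
#' @export
sc_model <- function(name, state_dim, param_names, nominal, rhs,
                     output_map, output_names,
                     heterogeneous = character(),
                     initial_condition = NULL, compiled = NULL,
                     ss_pin = NULL) {
  stopifnot(state_dim >= 1, length(output_names) >= 1)
  if (!all(param_names %in% names(nominal)))
    stop("nominal values must be supplied for all parameters")
  if (!all(heterogeneous %in% param_names))
    stop("heterogeneous parameters must be a subset of param_names")
  structure(list(name = name, state_dim = state_dim,
                 param_names = param_names,
                 nominal = nominal[param_names],
                 rhs = rhs, output_map = output_map,
                 output_names = output_names,
                 m = length(output_names),
                 q = length(heterogeneous),
                 heterogeneous = heterogeneous,
                 initial_condition = initial_condition,
                 compiled = compiled, ss_pin = ss_pin),
            class = "sc_model")
}

#' @export
print.sc_model <- function(x, ...) {
  cat(sprintf("<sc_model '%s'>  states: %d  outputs: %s\n", x$name,
              x$state_dim, paste(x$output_names, collapse = ", ")))
  cat(sprintf("  heterogeneous: %s\n",
              if (x$q) paste(x$heterogeneous, collapse = ", ") else "(none)"))
  invisible(x)
}

# merge a heterogeneous parameter vector theta into the full parameter
# set; unnamed theta is matched positionally to model$heterogeneous
complete_params <- function(model, theta = NULL, u = 1) {
  p <- model$nominal
  if (!is.null(theta) && length(theta)) {
    nm <- names(theta)
    if (is.null(nm)) {
      if (length(theta) != model$q)
        stop("theta must have length ", model$q)
      nm <- model$heterogeneous
    }
    if (!all(nm %in% model$param_names))
      stop("unknown parameter(s): ", paste(setdiff(nm, model$param_names),
                                           collapse = ", "))
    p[nm] <- as.numeric(theta)
  }
  c(p, u = unname(u))
}

#' Hill-type activation and inhibition functions
#'
#' Sigmoidal interaction terms of the TNF model.  `act()` rises from 0
#' to 1 with half-activation at `x = a`; `inh()` falls from 1 to 0 with
#' half-inhibition at `x = b`.  Both use Hill exponent 2.
#'
#' @param x relative activity (non-negative; negative values are
#'   clamped to zero).
#' @param a,b activation / inhibition threshold in (0, 1).
#' @return value in `[0, 1]`.
#' @export
act <- function(x, a) {
  if (any(a <= 0)) stop("activation threshold must be positive")
  xp <- pmax(x, 0)
  xp^2 / (a^2 + xp^2)
}

#' @rdname act
#' @export
inh <- function(x, b) {
  if (any(b <= 0)) stop("inhibition threshold must be positive")
  xp <- pmax(x, 0)
  b^2 / (b^2 + xp^2)
}

#' Nominal parameters of the TNF signaling model
#'
#' Activation thresholds `a1..a4` and inhibition thresholds `b1..b5`
#' of the four-state TNF model; all lie strictly between 0 and 1.
#'
#' @return named numeric vector of length 9.
#' @export
tnf_nominal <- function() {
  c(a1 = 0.6, a2 = 0.2, a3 = 0.2, a4 = 0.5,
    b1 = 0.4, b2 = 0.7, b3 = 0.3, b4 = 0.5, b5 = 0.4)
}

#' Right-hand side of the TNF signaling model
#'
#' Four states: relative activities of C8a, C3a, NF-kB and I-kB.  TNF
#' (stimulus `u`) activates caspase-8 and NF-kB; C8a activates C3a;
#' NF-kB inhibits C8a (FLIP) and C3a (XIAP, threshold `b3`) and induces
#' its own inhibitor I-kB (threshold `a4`); C3a antagonizes the
#' survival branch by inhibiting NF-kB and I-kB.
#'
#' @param x state vector (length 4) of relative activities.
#' @param u TNF stimulus level (non-negative).
#' @param p named parameter vector with entries `a1..a4`, `b1..b5`.
#' @return derivative vector of length 4.
#' @export
tnf_rhs <- function(x, u, p) {
  if (any(!is.finite(x))) stop("non-finite state passed to tnf_rhs")
  c(-x[1] + act(u, p[["a1"]]) * inh(x[3], p[["b1"]]),
    -x[2] + act(x[1], p[["a2"]]) * inh(x[3], p[["b3"]]),
    -x[3] + act(u, p[["a3"]]) * inh(x[2], p[["b2"]]) * inh(x[4], p[["b4"]]),
    -x[4] + act(x[3], p[["a4"]]) * inh(x[2], p[["b5"]]))
}

#' Built-in TNF signaling model
#'
#' Constructs the four-state TNF pathway model as an [sc_model()].  The
#' resting state (initial condition) is the steady state with zero C3a
#' activity at `u = 0`.  Integration uses a stiff-capable adaptive
#' solver through a compiled derivative function.
#'
#' @param outputs which states are measured; any subset of
#'   `c("C3a", "NFkB")` (ordered as given).
#' @param heterogeneous names of cell-to-cell variable parameters;
#'   defaults to `"b3"` (univariate setting).  The bivariate setting
#'   uses `c("b3", "a4")`.
#' @param nominal named parameter vector, defaulting to [tnf_nominal()].
#' @return an `sc_model` named `"tnf4"`.
#' @export
tnf_model <- function(outputs = "C3a", heterogeneous = "b3",
                      nominal = tnf_nominal()) {
  outputs <- match.arg(outputs, c("C3a", "NFkB"), several.ok = TRUE)
  if (any(nominal <= 0 | nominal >= 1))
    stop("all TNF thresholds must lie in (0, 1)")
  state_idx <- c(C3a = 2L, NFkB = 3L)[outputs]
  sc_model(
    name = "tnf4", state_dim = 4L,
    param_names = names(tnf_nominal()), nominal = nominal,
    rhs = function(t, x, p) tnf_rhs(x, p[["u"]], p),
    output_map = function(x) x[, state_idx, drop = FALSE],
    output_names = outputs,
    heterogeneous = heterogeneous,
    # the resting state with zero C3a at u = 0 is the origin for all
    # thresholds in (0,1): act(0, a) = 0 and act(u = 0, a) = 0 propagate
    # zero through every equation (verified against steady_state() in
    # the test suite)
    initial_condition = function(p) numeric(4L),
    compiled = list(func = "tnf_derivs", initfunc = "tnf_initmod",
                    dllname = "popsnap",
                    parm_order = c(names(tnf_nominal()), "u")),
    ss_pin = 2L)
}

# model registry ------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' Models are registered under a name so that run configurations can
#' refer to them by string.  `"tnf4"` is registered on load.
#'
#' @param name registry key.
#' @param constructor function returning an [sc_model()].
#' @export
register_model <- function(name, constructor) {
  stopifnot(is.function(constructor))
  assign(name, constructor, envir = .model_registry)
  invisible(name)
}

#' @rdname register_model
#' @param ... arguments forwarded to the registered constructor.
#' @export
get_model <- function(name, ...) {
  if (!exists(name, envir = .model_registry))
    stop("unknown model '", name, "'")
  get(name, envir = .model_registry)(...)
}

.onLoad <- function(libname, pkgname) {
  register_model("tnf4", tnf_model)
}

# steady state --------------------------------------------------------

#' Resting steady state of a single-cell model
#'
#' Finds a steady state of the vector field at stimulus `u`, starting
#' from a long pre-simulation and refining by damped Newton iteration
#' on a finite-difference Jacobian.  For models with a pinned state
#' (the TNF model pins C3a to 0) that coordinate is held at zero
#' exactly rather than solved for, since the resting branch of a
#' possibly multistable model is the one with no caspase activity.
#' Local stability is verified through the Jacobian eigenvalues.
#'
#' @param model an [sc_model()].
#' @param theta heterogeneous parameter vector (optional).
#' @param u stimulus level, default 0.
#' @param tol residual tolerance on the max-norm of the derivative.
#' @param check_stable verify that all Jacobian eigenvalues have
#'   negative real part (numerical check; warns otherwise).
#' @return steady-state vector with attribute `"residual"`.
#' @export
steady_state <- function(model, theta = NULL, u = 0, tol = 1e-8,
                         check_stable = FALSE) {
  p <- complete_params(model, theta, u = u)
  f <- function(x) model$rhs(0, x, p)
  n <- model$state_dim
  pin <- model$ss_pin
  free <- setdiff(seq_len(n), pin)

  # initial guess from a pre-simulation of the relaxation dynamics
  x <- rep(0, n)
  sim <- simulate_states(model, theta, times = c(0, 60), u = u, x0 = x)
  x <- pmax(sim[nrow(sim), ], 0)
  if (length(pin)) x[pin] <- 0

  fd_jac <- function(x, idx) {
    h <- 1e-7
    vapply(idx, function(k) {
      xp <- x; xp[k] <- xp[k] + h
      (f(xp)[idx] - f(x)[idx]) / h
    }, numeric(length(idx)))
  }

  for (it in seq_len(60)) {
    r <- f(x)[free]
    if (max(abs(f(x))) <= tol) break
    J <- fd_jac(x, free)
    step <- tryCatch(solve(J, -r), error = function(e) -r)
    lam <- 1
    repeat {
      xn <- x
      xn[free] <- x[free] + lam * step
      if (max(abs(f(xn)[free])) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  res <- max(abs(f(x)))
  if (res > tol)
    stop(sprintf("steady-state solve did not converge (residual %.3e)", res))
  if (check_stable) {
    Jfull <- vapply(seq_len(n), function(k) {
      h <- 1e-7; xp <- x; xp[k] <- xp[k] + h
      (f(xp) - f(x)) / h
    }, numeric(n))
    ev <- eigen(Jfull, only.values = TRUE)$values
    if (any(Re(ev) >= 0))
      warning("steady state is not locally stable (eigenvalue check)")
  }
  structure(x, residual = res)
}

# state trajectories (internal): rows = times, cols = states
simulate_states <- function(model, theta = NULL, times, u = 1, x0 = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  p <- complete_params(model, theta, u = u)
  if (is.null(x0)) {
    x0 <- if (is.null(model$initial_condition))
      as.numeric(steady_state(model, theta, u = 0))
    else model$initial_condition(p)
  }
  tt <- sort(unique(c(0, times)))
  if (any(times < 0)) stop("measurement times must be non-negative")
  if (length(tt) == 1)                  # only t = 0 requested
    return(matrix(as.numeric(x0), length(times), model$state_dim,
                  byrow = TRUE))
  if (!is.null(model$compiled)) {
    out <- deSolve::ode(y = as.numeric(x0), times = tt,
                        func = model$compiled$func,
                        parms = unname(p[model$compiled$parm_order]),
                        dllname = model$compiled$dllname,
                        initfunc = model$compiled$initfunc,
                        rtol = rtol, atol = atol)
  } else {
    out <- deSolve::ode(y = as.numeric(x0), times = tt,
                        func = function(t, x, parms) list(model$rhs(t, x, parms)),
                        parms = p, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed for theta = (",
         paste(signif(theta, 6), collapse = ", "), ")")
  out[match(times, tt), -1, drop = FALSE]
}

#' Simulate measured outputs of a single cell
#'
#' Integrates the single-cell ODE from its resting state under a
#' constant stimulus (unit step at t = 0 by default) and returns the
#' model outputs at the requested times.  Relative tolerance 1e-8 and
#' absolute tolerance 1e-10 are used; tiny negative values arising from
#' solver error are clamped to zero.
#'
#' @inheritParams steady_state
#' @param times non-negative, ascending measurement times.
#' @param u stimulus level for t >= 0 (default 1).
#' @param rtol,atol solver tolerances.
#' @return matrix `length(times) x m` of outputs.
#' @export
simulate_output <- function(model, theta = NULL, times, u = 1,
                            rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(times)) stop("times must be ascending")
  st <- simulate_states(model, theta, times, u = u, rtol = rtol, atol = atol)
  y <- model$output_map(st)
  y[y < 0] <- 0
  colnames(y) <- model$output_names
  y
}

#' Simulate a population of cells
#'
#' Vectorized wrapper around [simulate_output()] for a matrix of
#' heterogeneous parameter vectors.
#'
#' @inheritParams simulate_output
#' @param Theta matrix `n x q` of parameter vectors (one row per cell).
#' @return array `n x length(times) x m`.
#' @export
simulate_population <- function(model, Theta, times, u = 1,
                                rtol = 1e-8, atol = 1e-10) {
  Theta <- as.matrix(Theta)
  n <- nrow(Theta)
  out <- array(NA_real_, c(n, length(times), model$m))
  for (i in seq_len(n))
    out[i, , ] <- simulate_output(model, Theta[i, ], times, u = u,
                                  rtol = rtol, atol = atol)
  out
}
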