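#' Parametric ODE reaction-network model
#'
#' Represents a biochemical reaction network with `l` species and `m`
#' reactions as the ODE system `dx/dt = S v(x; p)`, `x(0) = x0`, where `S` is
#' the time-invariant stoichiometric matrix and `v` the vector of
#' non-negative rate laws.  Each rate law `j` is of the multiplicative form
#' `v_j = p_j * r_j(x; p)`: the factor `p_j` is the reaction's
#' *multiplicative kinetic constant*, and projecting it to 0 deletes
#' reaction `j` from the network.  That reformulation of structural model
#' reduction as a parameter-space projection is what the whole package is
#' built on.
#'
#' @param state_names character vector of the `l` species names.
#' @param x0 non-negative numeric vector of initial concentrations, one per
#'   state (recycled names allowed; if unnamed, taken in `state_names`
#'   order).
#' @param parameter_names character vector of the `d >= m` parameter names.
#' @param reactions list of `m` reactions.  Each reaction is a list with
#'   elements `stoichiometry` (named numeric vector, state -> signed
#'   integer), `rate` (character; arithmetic expression in states and
#'   parameters, restricted grammar), and `constant` (name of the
#'   multiplicative kinetic constant of this reaction).
#'
#' @return an object of class `"parametric_model"` with fields
#'   `state_names`, `parameter_names`, `x0`, `stoichiometry` (`l x m`
#'   matrix), `rate_exprs` (parsed expressions), and
#'   `multiplicative_constants` (character vector, one per reaction).
#' @seealso [simulate_model()], [predict.parametric_model()],
#'   [projection_catalog()]
#' @export
parametric_model <- function(state_names, x0, parameter_names, reactions) {
  stopifnot(is.character(state_names), length(state_names) >= 1L,
            is.character(parameter_names), length(parameter_names) >= 1L,
            is.list(reactions), length(reactions) >= 1L)
  if (anyDuplicated(state_names)) stop("duplicate state names", call. = FALSE)
  if (anyDuplicated(parameter_names)) stop("duplicate parameter names", call. = FALSE)
  if (length(intersect(state_names, parameter_names)) > 0L) {
    stop("states and parameters must have distinct names", call. = FALSE)
  }
  l <- length(state_names)
  m <- length(reactions)
  d <- length(parameter_names)
  if (d < m) {
    stop(sprintf("need at least as many parameters as reactions (d = %d < m = %d)", d, m),
         call. = FALSE)
  }
  if (is.null(names(x0))) {
    stopifnot(length(x0) == l)
    names(x0) <- state_names
  } else {
    stopifnot(setequal(names(x0), state_names))
    x0 <- x0[state_names]
  }
  if (any(!is.finite(x0)) || any(x0 < 0)) {
    stop("initial state must be finite and non-negative", call. = FALSE)
  }

  S <- matrix(0, nrow = l, ncol = m, dimnames = list(state_names, NULL))
  rate_exprs <- vector("list", m)
  constants <- character(m)
  allowed <- c(state_names, parameter_names)
  for (j in seq_len(m)) {
    rx <- reactions[[j]]
    if (is.null(rx$stoichiometry) || is.null(rx$rate) || is.null(rx$constant)) {
      stop(sprintf("reaction %d must have 'stoichiometry', 'rate' and 'constant'", j),
           call. = FALSE)
    }
    st <- rx$stoichiometry
    if (is.null(names(st)) || !all(names(st) %in% state_names)) {
      stop(sprintf("reaction %d: stoichiometry must be named by declared states", j),
           call. = FALSE)
    }
    S[names(st), j] <- as.numeric(st)
    rate_exprs[[j]] <- tf_parse_expr(rx$rate, allowed,
                                     where = sprintf("rate law of reaction %d", j))
    if (!rx$constant %in% parameter_names) {
      stop(sprintf("reaction %d: multiplicative constant '%s' is not a declared parameter",
                   j, rx$constant), call. = FALSE)
    }
    constants[j] <- rx$constant
  }

  structure(
    list(state_names = state_names,
         parameter_names = parameter_names,
         x0 = x0,
         stoichiometry = S,
         rate_exprs = rate_exprs,
         rate_strings = vapply(reactions, function(r) as.character(r$rate), ""),
         multiplicative_constants = constants,
         reactions = reactions),
    class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  cat(sprintf("parametric ODE model: %d states, %d reactions, %d parameters\n",
              length(x$state_names), ncol(x$stoichiometry), length(x$parameter_names)))
  cat("states:     ", paste(x$state_names, collapse = ", "), "\n")
  cat("parameters: ", paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

#' Bounded parameter space
#'
#' The box `P = [p1_min, p1_max] x ... x [pd_min, pd_max]` that sampling and
#' search operate in.  Parameters flagged `"log"` are explored on a log10
#' scale (and must therefore have strictly positive lower bounds).
#'
#' @param lower,upper named (or `parameter_names`-ordered) numeric vectors of
#'   bounds, `lower <= upper` elementwise.
#' @param scale `"linear"` or `"log"`, recycled to the number of parameters.
#' @param parameter_names optional character vector fixing name order.
#' @return an object of class `"parameter_space"`.
#' @export
parameter_space <- function(lower, upper, scale = "linear", parameter_names = NULL) {
  if (is.null(parameter_names)) {
    parameter_names <- names(lower) %||% names(upper)
  }
  if (is.null(parameter_names)) stop("parameter names are required", call. = FALSE)
  if (!is.null(names(lower))) lower <- lower[parameter_names]
  if (!is.null(names(upper))) upper <- upper[parameter_names]
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(parameter_names)
  stopifnot(length(lower) == d, length(upper) == d)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper)) {
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  }
  scale <- rep_len(match.arg(scale, c("linear", "log"), several.ok = TRUE), d)
  if (any(scale == "log" & lower <= 0)) {
    stop("log-scaled parameters need strictly positive lower bounds", call. = FALSE)
  }
  names(lower) <- names(upper) <- names(scale) <- parameter_names
  structure(list(parameter_names = parameter_names,
                 lower = lower, upper = upper, scale = scale),
            class = "parameter_space")
}

#' Experiment definition
#'
#' One experimental condition: optional parameter/initial-state overrides,
#' dosing events (instantaneous additions to a state), named observables
#' (arithmetic expressions over states and parameters), and the measurement
#' times.
#'
#' @param name condition identifier.
#' @param times non-negative, strictly increasing measurement times.
#' @param observables named character vector (or named list of strings) of
#'   observable expressions; validated against the model at problem assembly.
#' @param parameter_overrides,state_overrides optional named numeric vectors.
#' @param events optional data frame with columns `time`, `state`, `amount`;
#'   at `time` the given `amount` is added to `state`.
#' @return an object of class `"tf_experiment"`.
#' @export
experiment <- function(name, times, observables,
                       parameter_overrides = NULL, state_overrides = NULL,
                       events = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("measurement times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (is.list(observables)) observables <- unlist(observables)
  if (is.null(names(observables)) || any(names(observables) == "")) {
    stop("observables must be a named character vector", call. = FALSE)
  }
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("time", "state", "amount") %in% names(events)))
    events$time <- as.numeric(events$time)
    events$amount <- as.numeric(events$amount)
    events$state <- as.character(events$state)
  }
  structure(list(name = as.character(name), times = times,
                 observables = observables,
                 parameter_overrides = parameter_overrides,
                 state_overrides = state_overrides,
                 events = events),
            class = "tf_experiment")
}

#' Integration control settings
#'
#' @param rtol,atol relative and absolute solver tolerances.  Defaults
#'   `1e-6` / `1e-9` are tight enough that projected (often degenerate)
#'   dynamics still integrate reliably.
#' @param method a `deSolve` method name; the default `"lsoda"` switches
#'   automatically between stiff and non-stiff regimes.
#' @param neg_tol negative concentrations above `-neg_tol` are clamped to 0
#'   (solver overshoot); anything more negative marks the evaluation
#'   non-viable instead of crashing the search.
#' @param maxsteps maximal number of internal solver steps.
#' @return a list of class `"tf_control"`.
#' @export
integration_control <- function(rtol = 1e-6, atol = 1e-9,
                                method = "lsoda",
                                neg_tol = max(100 * atol, 1e-7),
                                maxsteps = 50000L) {
  structure(list(rtol = rtol, atol = atol, method = method,
                 neg_tol = neg_tol, maxsteps = maxsteps),
            class = "tf_control")
}

#' Simulate a model for one experiment
#'
#' Integrates `dx/dt = S v(x; p)` and returns the states at the
#' experiment's measurement times.  Dosing events are applied as state
#' discontinuities.  An integration failure (stiff blow-up, non-finite
#' states, strongly negative concentrations) does not raise an error: the
#' returned object carries `ok = FALSE` so that the calling search can score
#' the parameter point as non-viable and move on.
#'
#' @param model a [parametric_model()].
#' @param p named (or ordered) numeric parameter vector.
#' @param experiment a [experiment()].
#' @param control an [integration_control()].
#' @return a matrix (times x states) with attributes `ok` (logical) and
#'   `times`.
#' @export
simulate_model <- function(model, p, experiment, control = integration_control()) {
  stopifnot(inherits(model, "parametric_model"), inherits(experiment, "tf_experiment"))
  p <- tf_full_params(model, p)
  if (!is.null(experiment$parameter_overrides)) {
    ov <- experiment$parameter_overrides
    p[names(ov)] <- as.numeric(ov)
  }
  x0 <- model$x0
  if (!is.null(experiment$state_overrides)) {
    ov <- experiment$state_overrides
    x0[names(ov)] <- as.numeric(ov)
  }

  ev <- experiment$events
  times <- sort(unique(c(0, experiment$times, if (!is.null(ev)) ev$time)))
  S <- model$stoichiometry
  exprs <- model$rate_exprs
  env <- list2env(as.list(p), parent = baseenv())
  snames <- model$state_names
  m <- length(exprs)
  deriv <- function(t, x, parms) {
    for (i in seq_along(snames)) assign(snames[i], x[[i]], envir = env)
    v <- numeric(m)
    for (j in seq_len(m)) v[j] <- eval(exprs[[j]], env)
    list(as.vector(S %*% v))
  }
  events <- NULL
  if (!is.null(ev) && nrow(ev) > 0L) {
    events <- list(data = data.frame(var = ev$state, time = ev$time,
                                     value = ev$amount, method = "add"))
  }
  out <- try(suppressWarnings(
    deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                 method = control$method, rtol = control$rtol,
                 atol = control$atol, maxsteps = control$maxsteps,
                 events = events)
  ), silent = TRUE)

  fail <- function() {
    res <- matrix(NA_real_, nrow = length(experiment$times), ncol = length(snames),
                  dimnames = list(NULL, snames))
    attr(res, "ok") <- FALSE
    attr(res, "times") <- experiment$times
    res
  }
  if (inherits(out, "try-error")) return(fail())
  out <- unclass(out)
  if (nrow(out) < length(times) || any(!is.finite(out[, snames, drop = FALSE]))) return(fail())
  xs <- out[, snames, drop = FALSE]
  if (min(xs) < -control$neg_tol) return(fail())
  if (min(xs) < 0) {
    warning("small negative concentrations clamped to 0", call. = FALSE)
    xs[xs < 0] <- 0
  }
  keep <- match(experiment$times, out[, "time"])
  res <- xs[keep, , drop = FALSE]
  attr(res, "ok") <- TRUE
  attr(res, "times") <- experiment$times
  res
}

tf_full_params <- function(model, p) {
  pn <- model$parameter_names
  if (is.null(names(p))) {
    stopifnot(length(p) == length(pn))
    names(p) <- pn
  } else {
    stopifnot(all(pn %in% names(p)))
    p <- p[pn]
  }
  as.numeric(p) -> v; names(v) <- pn
  v
}

#' Model predictions for a set of experiments
#'
#' Concatenates observable values into the prediction vector `y(p)` in the
#' canonical order: experiments in list order, then observables in declared
#' order, then measurement times ascending.  Data tables are canonicalized
#' to the same order on load, so predictions and data always align.
#'
#' @param object a [parametric_model()].
#' @param p parameter vector.
#' @param experiments a list of [experiment()] objects (non-empty).
#' @param control an [integration_control()].
#' @param ... unused.
#' @return a numeric vector with attribute `ok`; when any simulation fails,
#'   `ok` is `FALSE` and the values are `NA` (a non-viable marker, not an
#'   error).
#' @export
predict.parametric_model <- function(object, p, experiments,
                                     control = integration_control(), ...) {
  if (inherits(experiments, "tf_experiment")) experiments <- list(experiments)
  stopifnot(length(experiments) >= 1L)
  blocks <- vector("list", length(experiments))
  ok <- TRUE
  for (e in seq_along(experiments)) {
    ex <- experiments[[e]]
    traj <- simulate_model(object, p, ex, control)
    if (!attr(traj, "ok")) {
      ok <- FALSE
      blocks[[e]] <- rep(NA_real_, length(ex$observables) * length(ex$times))
      next
    }
    obs_names <- names(ex$observables)
    vals <- numeric(0)
    for (o in seq_along(obs_names)) {
      oexpr <- tf_parse_expr(ex$observables[[o]],
                             c(object$state_names, object$parameter_names),
                             where = sprintf("observable '%s'", obs_names[o]))
      pfull <- tf_full_params(object, p)
      ov <- vapply(seq_len(nrow(traj)), function(i) {
        env <- c(as.list(traj[i, ]), as.list(pfull))
        eval(oexpr, env)
      }, numeric(1))
      vals <- c(vals, ov)
    }
    blocks[[e]] <- vals
  }
  y <- unlist(blocks, use.names = FALSE)
  attr(y, "ok") <- ok
  y
}
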