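#' Closed-form solution of the ligand-reporter network
#'
#' The two-species test network: a ligand `x1`, present at `t = 0` and
#' degraded at rate `k1 x1`, enhances (at rate `x1`) the production of a
#' reporter `x2` that is also produced constitutively at rate `k2` and
#' degraded at rate `x2`:
#' `dx1/dt = -k1 x1`, `dx2/dt = k2 + x1 - x2`, `x1(0) = x1_0 > 0`,
#' `x2(0) = 0`.  The exact solution is
#' `x1(t) = x1_0 exp(-k1 t)` and, for `k1 != 1`,
#' `x2(t) = k2 (1 - e^{-t}) + x1_0 (e^{-k1 t} - e^{-t}) / (1 - k1)`,
#' with the `k1 = 1` limit `x2(t) = k2 (1 - e^{-t}) + x1_0 t e^{-t}`.
#' Steady states: `(0, k2)` for `k1 > 0` and `(x1_0, x1_0 + k2)` for
#' `k1 = 0`.
#'
#' @param k1,k2 rate constants (`k1 >= 0`).
#' @param x1_0 initial ligand concentration.
#' @param t time point(s), `t >= 0`.
#' @return a list with numeric vectors `x1` and `x2` at the requested
#'   times.
#' @export
ligand_reporter_closed_form <- function(k1, k2, x1_0, t) {
  stopifnot(k1 >= 0, all(t >= 0))
  x1 <- x1_0 * exp(-k1 * t)
  x2 <- if (abs(k1 - 1) < 1e-12) {
    k2 * (1 - exp(-t)) + x1_0 * t * exp(-t)
  } else {
    k2 * (1 - exp(-t)) + x1_0 * (exp(-k1 * t) - exp(-t)) / (1 - k1)
  }
  list(x1 = x1, x2 = x2)
}

#' The ligand-reporter filtering problem
#'
#' A complete, self-contained problem instance built around the
#' ligand-reporter network: the reporter is observed once, close to steady
#' state, and the datum corresponds to the maximally reduced model
#' (`k1 = k2 = 0`), so the "correct" answer is the rank-2 reduction of
#' both multiplicative constants.  This instance is the package's standard
#' demonstration of the rank-1 heuristic caveat: projecting either
#' constant to 0 alone leaves the reporter either too high (`k1 = 0`:
#' `y -> x1_0 + k2`) or too low (`k2 = 0`: `y -> 0`), so the viable rank-2
#' reduction is invisible to a rank-1 search with 0-projections -- but not
#' to a rank-2 search, nor to a rank-1 search with suitably chosen finite
#' surrogate projection values.
#'
#' Three projection-value variants are provided:
#' * `"zero"`: both constants project to 0 (the true projection values);
#' * `"epsilon"`: finite surrogate values derived from the closed form at
#'   build time -- a small `eps1` for `k1` (the ligand decays only
#'   partially by the measurement time) and `eps2 = x1_0 - x1_0 *
#'   (e^{-eps1 t*} - e^{-t*}) / (1 - eps1)` for `k2`, chosen so that the
#'   surrogate reporter production exactly compensates the residual ligand
#'   signal.  With these values the rank-2 reduction is discoverable via
#'   two consecutive rank-1 steps (first `k1 := eps1`, then `k2 := eps2`);
#' * `"large"`: `k1` projects to a value far above its upper bound (the
#'   ligand's half-life becomes negligible against `t*`), `k2` to 0; then
#'   `k1` alone is reducible.
#'
#' @param x1_0 initial ligand concentration (default 10).
#' @param sigma1 measurement standard deviation (default `0.05 * x1_0`).
#' @param tstar measurement time (default 1000, at which the slowest
#'   in-bounds ligand decay `e^{-k1_min t*}` is below `1e-5`, so the
#'   near-steady-state premise holds quantitatively).
#' @param k1_bounds,k2_bounds parameter bounds boxes.
#' @param projection `"zero"`, `"epsilon"` or `"large"`.
#' @param noisy draw the datum as `x1_0 + eps`, `eps ~ N(0, sigma1^2)`;
#'   the default is the deterministic `eps = 0` variant.
#' @param seed seed for the noisy variant.
#' @param alpha for `"epsilon"`: the residual ligand fraction
#'   `e^{-eps1 tstar}` used to derive `eps1` (default 0.12).
#' @return a list with `problem` (a [tf_problem()]), `init_point` (a
#'   viable root-model parameter point), and the instance constants
#'   (`x1_0`, `sigma1`, `tstar`, `epsilon` values when applicable).
#' @export
ligand_reporter_problem <- function(x1_0 = 10, sigma1 = 0.05 * x1_0, tstar = 1000,
                                    k1_bounds = c(0.0117, 0.027),
                                    k2_bounds = c(1.3, 11.7),
                                    projection = c("zero", "epsilon", "large"),
                                    noisy = FALSE, seed = 1L, alpha = 0.12) {
  projection <- match.arg(projection)
  stopifnot(x1_0 > 0, sigma1 > 0, tstar > 0)

  model <- parametric_model(
    state_names = c("x1", "x2"),
    x0 = c(x1 = x1_0, x2 = 0),
    parameter_names = c("k1", "k2", "k3", "k4"),
    reactions = list(
      list(stoichiometry = c(x1 = -1), rate = "k1 * x1", constant = "k1"),
      list(stoichiometry = c(x2 = +1), rate = "k2",      constant = "k2"),
      list(stoichiometry = c(x2 = +1), rate = "k3 * x1", constant = "k3"),
      list(stoichiometry = c(x2 = -1), rate = "k4 * x2", constant = "k4")))

  space <- parameter_space(
    lower = c(k1 = k1_bounds[1], k2 = k2_bounds[1], k3 = 1, k4 = 1),
    upper = c(k1 = k1_bounds[2], k2 = k2_bounds[2], k3 = 1, k4 = 1))

  eps <- NULL
  proj_vals <- switch(projection,
    zero = c(k1 = 0, k2 = 0),
    epsilon = {
      eps1 <- -log(alpha) / tstar
      contrib <- x1_0 * (exp(-eps1 * tstar) - exp(-tstar)) / (1 - eps1)
      eps2 <- x1_0 - contrib
      eps <- c(eps1 = eps1, eps2 = eps2)
      c(k1 = eps1, k2 = eps2)
    },
    large = c(k1 = 1000 * k1_bounds[2], k2 = 0))
  catalog <- projection_catalog(space$parameter_names,
                                reducible = c("k1", "k2"),
                                projection_values = proj_vals)

  noise <- if (noisy) {
    set.seed(as.integer(seed))
    stats::rnorm(1L, 0, sigma1)
  } else 0
  dataset <- tf_dataset(y0 = x1_0 + noise, sigma = sigma1)
  ex <- experiment("steady-state", times = tstar, observables = c(y1 = "x2"))
  sm <- score_model(dataset, type = "nll", q = 0.95)
  problem <- tf_problem(space, catalog, sm, model = model, experiments = list(ex))

  list(problem = problem,
       init_point = c(k1 = 0.02, k2 = x1_0, k3 = 1, k4 = 1),
       x1_0 = x1_0, sigma1 = sigma1, tstar = tstar, epsilon = eps)
}

#' Analytic lattice problem with a pattern-only score
#'
#' Isolates the search mechanics from sampling and simulation: the score
#' depends only on *which* coordinates sit exactly at their projection
#' values, so the viability of a reduction is sample-independent by
#' construction and the whole viable sublattice is known in closed form
#' from the predicate.  `d_tilde` reducible parameters live in the box
#' `[1, 2]^d` with projection value 0; a point whose projected index set
#' `I` satisfies `predicate(I)` scores 0, anything else 1, with threshold
#' 0.5.
#'
#' @param d_tilde number of reducible parameters.
#' @param predicate function over sorted integer index sets; must accept
#'   `integer(0)` and return `TRUE` for it (the root model is viable).
#' @return a list with `problem`, `init_point` and `predicate`.
#' @export
lattice_problem <- function(d_tilde, predicate = function(I) TRUE) {
  stopifnot(d_tilde >= 1L, is.function(predicate))
  if (!isTRUE(predicate(integer(0)))) {
    stop("the root model must be viable: predicate(integer(0)) is FALSE", call. = FALSE)
  }
  nms <- paste0("q", seq_len(d_tilde))
  space <- parameter_space(lower = stats::setNames(rep(1, d_tilde), nms),
                           upper = stats::setNames(rep(2, d_tilde), nms))
  catalog <- projection_catalog(nms, reducible = nms)
  score_fn <- function(p) {
    I <- sort(which(as.numeric(p) == 0))
    if (isTRUE(predicate(as.integer(I)))) 0 else 1
  }
  sm <- score_model(type = "custom", score_fn = score_fn, threshold = 0.5,
                    score_on = "parameters")
  problem <- tf_problem(space, catalog, sm)
  list(problem = problem,
       init_point = stats::setNames(rep(1.5, d_tilde), nms),
       predicate = predicate)
}

#' The four-parameter union-jump example
#'
#' Four reducible parameters in `[0.5, 1.5]^4` with projection value 0 and
#' the parameter-space score `s(p) = (p4 - 1)^2` with threshold 0.5: from
#' the sample `(1, 1, 1, 1)` exactly the three rank-1 projections of
#' `q1, q2, q3` are viable (projecting `q4` to 0 scores 1), their union
#' `{q1, q2, q3}` is a single rank-3 jump over the skipped rank-2 level,
#' and that union is viable.  The canonical small worked example for the
#' union-jump and backtracking mechanics.
#'
#' @return a list with `problem` and `init_point` (`(1, 1, 1, 1)`).
#' @export
union_jump_example <- function() {
  nms <- paste0("q", 1:4)
  space <- parameter_space(lower = stats::setNames(rep(0.5, 4), nms),
                           upper = stats::setNames(rep(1.5, 4), nms))
  catalog <- projection_catalog(nms, reducible = nms)
  sm <- score_model(type = "custom",
                    score_fn = function(p) (as.numeric(p)[4] - 1)^2,
                    threshold = 0.5, score_on = "parameters")
  list(problem = tf_problem(space, catalog, sm),
       init_point = stats::setNames(rep(1, 4), nms))
}

#' Random mass-action model with a known ground-truth submodel
#'
#' Generates a connected mass-action network of first-order conversions
#' with constant synthesis and terminal degradation, emulating -- at
#' reduced scale -- the shape of intracellular signaling case studies: a
#' non-removable "core" backbone (synthesis of the first species, a
#' conversion chain, degradation of the last species) plus hypothetical
#' extra reactions (random conversions or degradations) whose
#' multiplicative constants are reducible.  A random subset of the
#' hypothetical reactions is truly inactive; the data are simulated from
#' that ground-truth submodel with seeded Gaussian noise, so recovery of
#' the inactive set can be tested.
#'
#' @param n_states number of species (`>= 2`).
#' @param n_reactions total reactions; must be at least `n_states + 1`
#'   (the core backbone size) plus one hypothetical reaction.
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param n_times number of measurement times (all states observed).
#' @param noise_cv coefficient of variation of the measurement noise.
#' @return a list with `problem`, `init_point` (root-model point: true
#'   active rates, inactive rates at their lower bound), `truth` (list:
#'   `p_true`, `active`, `inactive`), and `model`.
#' @export
random_massaction_model <- function(n_states = 6L, n_reactions = 10L, seed = 1L,
                                    n_times = 4L, noise_cv = 0.05) {
  stopifnot(n_states >= 2L, n_reactions >= n_states + 2L)
  set.seed(as.integer(seed))
  l <- n_states
  snames <- paste0("s", seq_len(l))
  m <- n_reactions
  pnames <- paste0("k", seq_len(m))

  reactions <- vector("list", m)
  # core backbone: synthesis -> chain -> terminal degradation
  reactions[[1L]] <- list(stoichiometry = stats::setNames(1, snames[1L]),
                          rate = pnames[1L], constant = pnames[1L])
  for (i in seq_len(l - 1L)) {
    reactions[[1L + i]] <- list(
      stoichiometry = stats::setNames(c(-1, 1), snames[c(i, i + 1L)]),
      rate = paste0(pnames[1L + i], " * ", snames[i]),
      constant = pnames[1L + i])
  }
  reactions[[l + 1L]] <- list(stoichiometry = stats::setNames(-1, snames[l]),
                              rate = paste0(pnames[l + 1L], " * ", snames[l]),
                              constant = pnames[l + 1L])
  # hypothetical extras: random conversions or degradations
  n_hyp <- m - (l + 1L)
  for (h in seq_len(n_hyp)) {
    j <- l + 1L + h
    from <- sample.int(l, 1L)
    to <- sample.int(l + 1L, 1L)  # l + 1 encodes degradation
    while (to == from) to <- sample.int(l + 1L, 1L)
    st <- if (to > l) stats::setNames(-1, snames[from]) else
      stats::setNames(c(-1, 1), snames[c(from, to)])
    reactions[[j]] <- list(stoichiometry = st,
                           rate = paste0(pnames[j], " * ", snames[from]),
                           constant = pnames[j])
  }

  x0 <- stats::setNames(round(stats::runif(l, 1, 3), 3), snames)
  model <- parametric_model(snames, x0, pnames, reactions)

  hyp <- pnames[(l + 2L):m]
  # at least one active and one inactive hypothetical reaction
  n_inactive <- sample.int(n_hyp - 1L, 1L)
  inactive <- sort(sample(hyp, n_inactive))
  active_hyp <- setdiff(hyp, inactive)

  p_true <- stats::setNames(round(stats::runif(m, 0.5, 2), 3), pnames)
  p_true[inactive] <- 0

  lower <- stats::setNames(rep(0.05, m), pnames)
  lower[hyp] <- 1e-3
  upper <- stats::setNames(rep(5, m), pnames)
  space <- parameter_space(lower, upper)
  catalog <- projection_catalog(pnames, reducible = hyp)

  times <- seq(1, 5, length.out = n_times)
  ex <- experiment("timecourse", times = times,
                   observables = stats::setNames(snames, paste0("y_", snames)))
  y_true <- predict(model, p_true, list(ex))
  sigma <- pmax(noise_cv * abs(y_true), 0.02)
  y0 <- y_true + stats::rnorm(length(y_true), 0, sigma)
  dataset <- tf_dataset(y0, sigma)
  sm <- score_model(dataset, type = "nll", q = 0.95)
  problem <- tf_problem(space, catalog, sm, model = model, experiments = list(ex))

  init_point <- p_true
  init_point[inactive] <- lower[inactive]

  list(problem = problem, init_point = init_point,
       truth = list(p_true = p_true, active = active_hyp, inactive = inactive),
       model = model)
}
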