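#' Measurement dataset
#'
#' The `k` measured values `y0` with their known standard deviations
#' `sigma`, in the canonical prediction order (experiment, then observable,
#' then time; see [predict.parametric_model()]).  Errors are modelled as
#' independent Gaussians, `y0 = y + eps`, `eps ~ N(0, sigma^2)`.
#'
#' @param y0 numeric vector of measured values.
#' @param sigma strictly positive numeric vector of standard deviations,
#'   same length as `y0`.
#' @return an object of class `"tf_dataset"` with fields `y0`, `sigma`, `k`.
#' @export
tf_dataset <- function(y0, sigma) {
  y0 <- as.numeric(y0); sigma <- as.numeric(sigma)
  stopifnot(length(y0) == length(sigma), length(y0) >= 1L)
  if (any(!is.finite(y0)) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be strictly positive and all values finite", call. = FALSE)
  }
  structure(list(y0 = y0, sigma = sigma, k = length(y0)), class = "tf_dataset")
}

#' Variance-weighted residual sum of squares
#'
#' `Phi = sum_i ((y_i - y0_i) / sigma_i)^2`.  Under the Gaussian error
#' model, `Phi` evaluated at the true parameters is chi-squared distributed
#' with `k` degrees of freedom, which is what the default viability
#' threshold exploits.  Residuals are divided by `sigma` *before* squaring
#' (weighting by the variance, not the standard deviation); only this
#' weighting makes `Phi` chi-squared and yields the familiar `1.96 sigma`
#' band at `k = 1`.
#'
#' @param y prediction vector of length `k`.
#' @param dataset a [tf_dataset()].
#' @return non-negative real; `+Inf` when any prediction is non-finite
#'   (non-viable marker).
#' @export
residual_score <- function(y, dataset) {
  stopifnot(inherits(dataset, "tf_dataset"))
  if (length(y) != dataset$k) {
    stop(sprintf("prediction length %d does not match k = %d", length(y), dataset$k),
         call. = FALSE)
  }
  if (any(!is.finite(y))) return(Inf)
  sum(((y - dataset$y0) / dataset$sigma)^2)
}

# log-space normalization constant C = 0.5 * (k log(2*pi) + 2 sum(log sigma))
tf_log_norm_const <- function(dataset) {
  0.5 * (dataset$k * log(2 * pi) + 2 * sum(log(dataset$sigma)))
}

#' Negative log-likelihood score
#'
#' `l = Phi/2 + C` with `C = log(sqrt((2 pi)^k prod(sigma_i^2)))`, computed
#' in log space so that large `k` cannot overflow the product.  This is the
#' default scoring function.
#'
#' @inheritParams residual_score
#' @return the negative log-likelihood of the data given the model at `y`.
#' @export
neg_log_likelihood <- function(y, dataset) {
  phi <- residual_score(y, dataset)
  phi / 2 + tf_log_norm_const(dataset)
}

#' Chi-squared quantile viability threshold
#'
#' The default, model-independent threshold `s0 = C + Q_chisq(q, k) / 2` on
#' the negative log-likelihood scale, so that a point is viable exactly when
#' `Phi <= Q_chisq(q, k)` -- the standard goodness-of-fit bound.  At
#' `k = 1, q = 0.95` the viable residual band is `|y - y0| <= 1.96 sigma`.
#'
#' @param dataset a [tf_dataset()].
#' @param q quantile in (0, 1); default 0.95.
#' @return the threshold `s0` (negative log-likelihood scale).
#' @export
chi2_threshold <- function(dataset, q = 0.95) {
  stopifnot(inherits(dataset, "tf_dataset"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("quantile q must lie strictly between 0 and 1", call. = FALSE)
  }
  tf_log_norm_const(dataset) + stats::qchisq(q, df = dataset$k) / 2
}

#' Mean-plus-two-standard-deviations viability threshold
#'
#' The original threshold used before the chi-squared quantile became the
#' default: the expected value plus two standard deviations of the
#' chi-squared residual statistic over all data points, i.e. a bound
#' `Phi <= k + 2 sqrt(2 k)`, converted to the negative log-likelihood scale
#' as `C + (k + 2 sqrt(2 k)) / 2`.
#'
#' @param dataset a [tf_dataset()].
#' @return the threshold `s0` (negative log-likelihood scale).
#' @export
legacy_threshold <- function(dataset) {
  stopifnot(inherits(dataset, "tf_dataset"))
  k <- dataset$k
  tf_log_norm_const(dataset) + (k + 2 * sqrt(2 * k)) / 2
}

#' Scoring model: score function plus viability threshold
#'
#' Bundles the dataset, the scoring function `s` and the threshold `s0`
#' that together define the viable subspace `{p : s(p; y0) <= s0(y0)}`.
#' Three kinds are supported:
#'
#' * `"nll"` (default): negative log-likelihood with the chi-squared
#'   quantile threshold [chi2_threshold()];
#' * `"legacy"`: negative log-likelihood with [legacy_threshold()];
#' * `"custom"`: any user score.  A custom score may consume the prediction
#'   vector (`score_on = "prediction"`) or the raw parameter vector
#'   (`score_on = "parameters"`), the latter enabling likelihood-free
#'   applications -- e.g. scoring a synthetic circuit design by a
#'   performance objective -- with no dataset attached at all.
#'
#' The engine treats every kind identically: viability is
#' `score <= threshold`, ties included.
#'
#' @param dataset a [tf_dataset()], or `NULL` for dataset-free custom
#'   scores.
#' @param type `"nll"`, `"legacy"` or `"custom"`.
#' @param q chi-squared quantile for the default threshold.
#' @param score_fn for `type = "custom"`: function of `(y, dataset)` when
#'   `score_on = "prediction"`, or of the parameter vector alone when
#'   `score_on = "parameters"`.
#' @param threshold for `type = "custom"`: a constant, or a function of the
#'   dataset.
#' @param score_on what the custom score consumes.
#' @return an object of class `"score_model"` with fields `dataset`, `fn`,
#'   `s0`, `type`, `q`, `score_on`.
#' @export
score_model <- function(dataset = NULL, type = c("nll", "legacy", "custom"),
                        q = 0.95, score_fn = NULL, threshold = NULL,
                        score_on = c("prediction", "parameters")) {
  type <- match.arg(type)
  score_on <- match.arg(score_on)
  if (type %in% c("nll", "legacy")) {
    if (is.null(dataset)) stop(sprintf("type '%s' requires a dataset", type), call. = FALSE)
    score_on <- "prediction"
    fn <- neg_log_likelihood
    s0 <- if (type == "nll") chi2_threshold(dataset, q) else legacy_threshold(dataset)
  } else {
    if (!is.function(score_fn)) stop("custom scoring requires score_fn", call. = FALSE)
    if (is.null(threshold)) stop("custom scoring requires a threshold", call. = FALSE)
    fn <- score_fn
    s0 <- if (is.function(threshold)) threshold(dataset) else as.numeric(threshold)
  }
  structure(list(dataset = dataset, fn = fn, s0 = s0, type = type, q = q,
                 score_on = score_on),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score model: type = %s, threshold s0 = %.6g, scores %s\n",
              x$type, x$s0, x$score_on))
  invisible(x)
}

#' Assemble a filtering problem
#'
#' The container passed to every search operation: the model, its bounded
#' parameter space, the projection catalog, the experiments, and the
#' scoring model.  For parameter-space scores (`score_on = "parameters"`)
#' the model and experiments may be omitted.
#'
#' @param space a [parameter_space()].
#' @param catalog a [projection_catalog()].
#' @param score_model a [score_model()].
#' @param model a [parametric_model()] (required for prediction scores).
#' @param experiments list of [experiment()]s (required for prediction
#'   scores).
#' @param control an [integration_control()].
#' @return an object of class `"tf_problem"`.
#' @export
tf_problem <- function(space, catalog, score_model, model = NULL,
                       experiments = NULL, control = integration_control()) {
  stopifnot(inherits(space, "parameter_space"),
            inherits(catalog, "projection_catalog"),
            inherits(score_model, "score_model"))
  if (!identical(space$parameter_names, catalog$parameter_names)) {
    stop("parameter space and projection catalog disagree on parameter names", call. = FALSE)
  }
  if (score_model$score_on == "prediction") {
    if (is.null(model) || is.null(experiments)) {
      stop("prediction-based scoring requires a model and experiments", call. = FALSE)
    }
    if (inherits(experiments, "tf_experiment")) experiments <- list(experiments)
    if (!identical(model$parameter_names, space$parameter_names)) {
      stop("model and parameter space disagree on parameter names", call. = FALSE)
    }
    for (ex in experiments) {
      for (o in seq_along(ex$observables)) {
        tf_parse_expr(ex$observables[[o]],
                      c(model$state_names, model$parameter_names),
                      where = sprintf("observable '%s'", names(ex$observables)[o]))
      }
    }
  }
  structure(list(model = model, space = space, catalog = catalog,
                 experiments = experiments, score_model = score_model,
                 control = control),
            class = "tf_problem")
}

#' Score a parameter point and decide viability
#'
#' Runs the model (for prediction scores), applies the scoring function and
#' compares against the threshold.  The comparison is inclusive
#' (`score == s0` is viable).  Simulation failures and non-finite scores
#' yield `(FALSE, Inf)` rather than an error, so the search survives
#' degenerate projected dynamics.  Every call increments the evaluation
#' counter when one is supplied -- this is the budget accounting used by
#' the search, and it counts re-validations of known points too.
#'
#' @param problem a [tf_problem()].
#' @param p parameter vector (projected coordinates, if any, already at
#'   their projection values).
#' @param counter optional counter environment from `tf_new_counter()`.
#' @return list with elements `viable` (logical) and `score` (numeric).
#' @export
is_viable <- function(problem, p, counter = NULL) {
  stopifnot(inherits(problem, "tf_problem"))
  if (!is.null(counter)) counter$evaluations <- counter$evaluations + 1L
  sm <- problem$score_model
  score <- if (sm$score_on == "parameters") {
    tryCatch(as.numeric(sm$fn(p)), error = function(e) Inf)
  } else {
    y <- predict(problem$model, p, problem$experiments, problem$control)
    if (!attr(y, "ok")) Inf else tryCatch(as.numeric(sm$fn(y, sm$dataset)),
                                          error = function(e) Inf)
  }
  if (!is.finite(score)) return(list(viable = FALSE, score = Inf))
  list(viable = score <= sm$s0, score = score)
}

# Batched viability checks; the unit distributed at parallel level 1.
# Scoring is deterministic given p, so the batch result is independent of
# execution order and of the worker count.
tf_viability_batch <- function(problem, points, counter = NULL, workers = 1L) {
  apply_fun <- if (workers > 1L) {
    function(X, FUN) parallel::mclapply(X, FUN, mc.cores = workers)
  } else {
    lapply
  }
  res <- apply_fun(points, function(p) is_viable(problem, p))
  if (!is.null(counter)) counter$evaluations <- counter$evaluations + length(points)
  res
}
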