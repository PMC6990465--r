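#' Sampler configuration
#'
#' Tuning knobs for viable-subspace exploration.  `n_evals` is the maximal
#' number of score evaluations per sampling step; re-sampling between
#' filtering steps is triggered when fewer than `ceiling(resample_fraction
#' * n_evals)` carried-over samples survive re-validation (default 1/20).
#'
#' @param n_evals evaluation budget per sampling step (> 0).
#' @param d_min,d_max minimal and maximal sample-set sizes; `d_max` defaults
#'   to `10 * ceiling(resample_fraction * n_evals)`.
#' @param resample_fraction the trigger fraction `f` in (0, 1).
#' @param target_accept,grow,shrink,adapt_window random-walk step-scale
#'   adaptation: every `adapt_window` proposals the per-coordinate step
#'   scale is multiplied by `grow` when the window acceptance rate exceeds
#'   `target_accept` and by `shrink` otherwise.
#' @param init_step initial step scale, as a fraction of each free
#'   coordinate's (possibly log-scale) range.
#' @param n_ellipsoids number of covariance ellipsoids fitted (k-means
#'   clusters); capped by what the data supports.
#' @param inflation multiplicative inflation of the fitted ellipsoid axes.
#' @param walk_share fraction of the budget given to the random-walk phase
#'   when re-sampling; the remainder goes to ellipsoid expansion.
#' @param restart_every the walk restarts from a randomly chosen seed after
#'   this many proposals, so that disconnected viable islands all seed
#'   chains.
#' @return an object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_evals = 1000L,
                           d_min = 1L,
                           d_max = NULL,
                           resample_fraction = 1 / 20,
                           target_accept = 0.3,
                           grow = 1.1,
                           shrink = 0.9,
                           adapt_window = 20L,
                           init_step = 0.1,
                           n_ellipsoids = 2L,
                           inflation = 1.5,
                           walk_share = 0.5,
                           restart_every = 25L) {
  stopifnot(n_evals >= 0, resample_fraction > 0, resample_fraction < 1,
            d_min >= 1, walk_share >= 0, walk_share <= 1)
  if (is.null(d_max)) d_max <- 10L * as.integer(ceiling(resample_fraction * max(n_evals, 1)))
  d_max <- max(as.integer(d_max), as.integer(d_min))
  structure(list(n_evals = as.integer(n_evals), d_min = as.integer(d_min),
                 d_max = d_max, resample_fraction = resample_fraction,
                 target_accept = target_accept, grow = grow, shrink = shrink,
                 adapt_window = as.integer(adapt_window), init_step = init_step,
                 n_ellipsoids = as.integer(n_ellipsoids), inflation = inflation,
                 walk_share = walk_share, restart_every = as.integer(restart_every)),
            class = "sampler_config")
}

#' Viable sample set
#'
#' Parameter points carried between filtering steps, all viable under the
#' owning reduction's score model, with their scores and a provenance tag
#' (`initial`, `carried-over`, `walk`, `ellipsoid`).  Projected coordinates
#' equal their projection values exactly.
#'
#' @param points numeric matrix, one row per point (columns = parameters).
#' @param scores numeric vector of scores, one per point.
#' @param origin character vector of provenance tags (recycled).
#' @param reduction the owning [reduction()].
#' @return an object of class `"sample_set"`.
#' @export
sample_set <- function(points, scores, origin, reduction) {
  if (is.null(dim(points))) points <- matrix(points, nrow = if (length(scores) > 0L) 1L else 0L)
  stopifnot(nrow(points) == length(scores))
  structure(list(points = points, scores = as.numeric(scores),
                 origin = rep_len(as.character(origin), max(nrow(points), 0L)),
                 reduction = reduction),
            class = "sample_set")
}

tf_empty_samples <- function(problem, reduction) {
  d <- length(problem$space$parameter_names)
  sample_set(matrix(numeric(0), nrow = 0, ncol = d,
                    dimnames = list(NULL, problem$space$parameter_names)),
             numeric(0), character(0), reduction)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample set: %d viable points for reduction %s\n",
              nrow(x$points), x$reduction$id))
  invisible(x)
}

# --- coordinate transforms -------------------------------------------------
# Free coordinates of a reduction, walked on log10 scale where flagged.

tf_free_idx <- function(problem, reduction) {
  setdiff(seq_along(problem$space$parameter_names), reduction$index_set)
}

tf_to_walk <- function(space, p_free, free_idx) {
  isl <- space$scale[free_idx] == "log"
  out <- p_free
  out[isl] <- log10(p_free[isl])
  out
}

tf_from_walk <- function(space, z, free_idx) {
  isl <- space$scale[free_idx] == "log"
  out <- z
  out[isl] <- 10^z[isl]
  out
}

tf_walk_bounds <- function(space, free_idx) {
  isl <- space$scale[free_idx] == "log"
  lo <- space$lower[free_idx]; hi <- space$upper[free_idx]
  lo[isl] <- log10(lo[isl]); hi[isl] <- log10(hi[isl])
  list(lower = lo, upper = hi)
}

tf_reflect <- function(z, lower, upper) {
  w <- upper - lower
  for (i in seq_along(z)) {
    if (w[i] <= 0) { z[i] <- lower[i]; next }
    # reflect into [lower, upper]
    while (z[i] < lower[i] || z[i] > upper[i]) {
      if (z[i] < lower[i]) z[i] <- 2 * lower[i] - z[i]
      if (z[i] > upper[i]) z[i] <- 2 * upper[i] - z[i]
    }
  }
  z
}

# assemble a full parameter vector: free coords from walk space, projected
# coords exactly at their projection values
tf_assemble <- function(problem, reduction, z, free_idx) {
  p <- stats::setNames(numeric(length(problem$space$parameter_names)),
                       problem$space$parameter_names)
  p[free_idx] <- tf_from_walk(problem$space, z, free_idx)
  if (length(reduction$index_set) > 0L) {
    nms <- problem$catalog$parameter_names[reduction$index_set]
    p[nms] <- problem$catalog$projection_values[nms]
  }
  p
}

# --- random-walk exploration ----------------------------------------------

#' Adaptive random-walk exploration of the viable subspace
#'
#' An adaptive Gaussian random walk in the reduced coordinate system
#' (projected coordinates frozen at their projection values, log-scaled
#' coordinates walked in log space).  Any viable proposal is accepted and
#' recorded; the per-coordinate step scale adapts toward a target
#' acceptance rate.  The walk restarts periodically from a randomly chosen
#' seed so that disconnected viable regions are all explored.  This is a
#' deliberately simple sampler: the filtering engine only relies on its
#' contract -- seeded, budgeted, and returning exclusively viable points.
#'
#' @param problem a [tf_problem()].
#' @param seeds a [sample_set()] of viable starting points (non-empty
#'   unless the budget is zero).
#' @param config a [sampler_config()].
#' @param reduction the [reduction()] whose viable space is explored.
#' @param budget maximal number of score evaluations (defaults to
#'   `config$n_evals`).
#' @param counter optional evaluation counter.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return a [sample_set()] containing the seeds plus all accepted
#'   proposals (capped at `config$d_max`).
#' @export
explore_walk <- function(problem, seeds, config, reduction,
                         budget = config$n_evals, counter = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nrow(seeds$points) == 0L) {
    if (budget > 0L) warning("explore_walk: no viable seeds available", call. = FALSE)
    return(seeds)
  }
  if (budget <= 0L) return(seeds)

  free_idx <- tf_free_idx(problem, reduction)
  if (length(free_idx) == 0L) return(seeds)
  wb <- tf_walk_bounds(problem$space, free_idx)
  range_w <- pmax(wb$upper - wb$lower, 0)
  scale <- config$init_step * range_w
  scale[scale == 0] <- 0

  pts <- seeds$points
  scs <- seeds$scores
  org <- seeds$origin
  n_seeds <- nrow(pts)

  pick_seed <- function() {
    i <- sample.int(nrow(pts), 1L)
    tf_to_walk(problem$space, pts[i, free_idx], free_idx)
  }
  z <- pick_seed()
  spent <- 0L
  window_acc <- 0L
  window_n <- 0L
  since_restart <- 0L

  while (spent < budget && nrow(pts) < config$d_max) {
    if (since_restart >= config$restart_every) {
      z <- pick_seed()
      since_restart <- 0L
    }
    zp <- z + stats::rnorm(length(z)) * scale
    zp <- tf_reflect(zp, wb$lower, wb$upper)
    p <- tf_assemble(problem, reduction, zp, free_idx)
    res <- is_viable(problem, p, counter)
    spent <- spent + 1L
    window_n <- window_n + 1L
    since_restart <- since_restart + 1L
    if (res$viable) {
      window_acc <- window_acc + 1L
      pts <- rbind(pts, p)
      scs <- c(scs, res$score)
      org <- c(org, "walk")
      z <- zp
    }
    if (window_n >= config$adapt_window) {
      rate <- window_acc / window_n
      scale <- scale * if (rate > config$target_accept) config$grow else config$shrink
      window_acc <- 0L; window_n <- 0L
    }
  }
  rownames(pts) <- NULL
  out <- sample_set(pts, scs, org, reduction)
  attr(out, "evaluations") <- spent
  out
}

# --- ellipsoid expansion ---------------------------------------------------

#' Ellipsoid-based expansion of a viable sample set
#'
#' Fits one or more covariance ellipsoids to the viable points
#' (k-means clustering, per-cluster mean and covariance, axes scaled by
#' `sqrt(d + 2)` so the ellipsoid matches the support of uniformly
#' distributed points, then inflated), draws uniform proposals inside the
#' union of ellipsoids, and keeps the viable ones.  Degenerate covariances
#' are regularized by diagonal inflation.  With fewer than `d_free + 1`
#' input points the function falls back to [explore_walk()].
#'
#' @inheritParams explore_walk
#' @param samples a [sample_set()] of viable points to expand from.
#' @return a [sample_set()] containing the inputs plus viable proposals.
#' @export
expand_ellipsoids <- function(problem, samples, config, reduction,
                              budget = config$n_evals, counter = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (budget <= 0L) return(samples)
  free_idx <- tf_free_idx(problem, reduction)
  d_free <- length(free_idx)
  n <- nrow(samples$points)
  if (d_free == 0L) return(samples)
  if (n < d_free + 1L) {
    return(explore_walk(problem, samples, config, reduction, budget, counter, seed = NULL))
  }

  Z <- t(apply(samples$points[, free_idx, drop = FALSE], 1L, function(pf)
    tf_to_walk(problem$space, pf, free_idx)))
  if (d_free == 1L) Z <- matrix(as.numeric(Z), ncol = 1L)
  wb <- tf_walk_bounds(problem$space, free_idx)

  n_distinct <- nrow(unique(Z))
  k <- max(1L, min(config$n_ellipsoids, n_distinct, floor(n / (d_free + 1L))))
  cluster_id <- if (k > 1L) {
    km <- tryCatch(stats::kmeans(Z, centers = k, nstart = 2L),
                   error = function(e) NULL)
    if (is.null(km)) rep(1L, n) else km$cluster
  } else {
    rep(1L, n)
  }

  ells <- lapply(sort(unique(cluster_id)), function(ci) {
    Zi <- Z[cluster_id == ci, , drop = FALSE]
    mu <- colMeans(Zi)
    S <- if (nrow(Zi) >= 2L) stats::cov(Zi) else diag(0, d_free)
    # regularize: degenerate directions get a sliver of the box range
    reg <- pmax(1e-8, 1e-4 * (wb$upper - wb$lower))^2
    S <- S + diag(reg, d_free)
    R <- tryCatch(chol(S), error = function(e) diag(sqrt(diag(S)), d_free))
    list(mu = mu, R = R * sqrt(d_free + 2) * config$inflation)
  })

  pts <- samples$points
  scs <- samples$scores
  org <- samples$origin
  spent <- 0L
  attempts <- 0L
  max_attempts <- 50L * budget + 100L
  while (spent < budget && nrow(pts) < config$d_max && attempts < max_attempts) {
    attempts <- attempts + 1L
    e <- ells[[sample.int(length(ells), 1L)]]
    u <- stats::rnorm(d_free)
    u <- u / sqrt(sum(u^2)) * stats::runif(1L)^(1 / d_free)
    z <- as.numeric(e$mu + drop(u %*% e$R))
    if (any(z < wb$lower - 1e-12) || any(z > wb$upper + 1e-12)) next
    z <- pmin(pmax(z, wb$lower), wb$upper)
    p <- tf_assemble(problem, reduction, z, free_idx)
    res <- is_viable(problem, p, counter)
    spent <- spent + 1L
    if (res$viable) {
      pts <- rbind(pts, p)
      scs <- c(scs, res$score)
      org <- c(org, "ellipsoid")
    }
  }
  rownames(pts) <- NULL
  out <- sample_set(pts, scs, org, reduction)
  attr(out, "evaluations") <- spent
  attr(out, "n_ellipsoids") <- length(ells)
  out
}

# --- point preparation between filtering steps -----------------------------

#' Prepare the viable points for a filtering step
#'
#' Re-validates the carried-over points under the current reduction (every
#' re-validation costs one evaluation -- a point viable for the parent need
#' not stay viable after further projection).  If at least
#' `ceiling(f * n_evals)` survive, they are passed through (capped at
#' `d_max`) and no sampling happens.  Otherwise adaptive re-sampling is
#' triggered: a random walk seeded with all previously known viable points
#' for this reduction plus the survivors, followed by ellipsoid expansion,
#' until the budget is spent or `d_max` points are found.  Survivors are
#' always part of the result.
#'
#' @param problem a [tf_problem()].
#' @param carryover matrix of candidate points (rows), already projected to
#'   the reduction's projection values.
#' @param history matrix of previously found viable points for this
#'   reduction (may be `NULL`); used as additional walk seeds after
#'   re-validation.
#' @param config a [sampler_config()].
#' @param reduction the owning [reduction()].
#' @param counter optional evaluation counter.
#' @param seed integer seed for the sampling phase.
#' @return a [sample_set()]; the attribute `"resampled"` records whether
#'   the adaptive re-sampling trigger fired.  Empty carryover and history
#'   yield an empty set with a warning: the reduction is unexplorable from
#'   this branch.
#' @export
prepare_points <- function(problem, carryover, history = NULL, config = sampler_config(),
                           reduction, counter = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- length(problem$space$parameter_names)
  if (is.null(dim(carryover))) {
    carryover <- matrix(carryover, ncol = d, byrow = FALSE,
                        dimnames = list(NULL, problem$space$parameter_names))
  }
  threshold <- as.integer(ceiling(config$resample_fraction * config$n_evals))

  revalidate <- function(mat, tag, max_keep = Inf) {
    pts <- NULL; scs <- numeric(0)
    if (!is.null(mat) && nrow(mat) > 0L) {
      for (i in seq_len(nrow(mat))) {
        if (length(scs) >= max_keep) break
        p <- stats::setNames(as.numeric(mat[i, ]), problem$space$parameter_names)
        res <- is_viable(problem, p, counter)
        if (res$viable) {
          pts <- rbind(pts, p)
          scs <- c(scs, res$score)
        }
      }
    }
    list(points = pts, scores = scs, tag = tag)
  }

  surv <- revalidate(carryover, "carried-over")
  n_surv <- length(surv$scores)

  if (n_surv >= max(threshold, config$d_min) || config$n_evals == 0L) {
    keep <- seq_len(min(n_surv, config$d_max))
    if (n_surv == 0L) {
      warning("prepare_points: no viable points for reduction ", reduction$id, call. = FALSE)
      out <- tf_empty_samples(problem, reduction)
      attr(out, "resampled") <- FALSE
      return(out)
    }
    pts <- surv$points[keep, , drop = FALSE]
    rownames(pts) <- NULL
    out <- sample_set(pts, surv$scores[keep], "carried-over", reduction)
    attr(out, "resampled") <- FALSE
    return(out)
  }

  # trigger: too few samples carried over -> adaptive re-sampling
  hist_surv <- revalidate(history, "history", max_keep = config$d_max)
  seed_pts <- rbind(surv$points, hist_surv$points)
  seed_scs <- c(surv$scores, hist_surv$scores)
  if (is.null(seed_pts) || nrow(seed_pts) == 0L) {
    warning("prepare_points: no viable points for reduction ", reduction$id, call. = FALSE)
    out <- tf_empty_samples(problem, reduction)
    attr(out, "resampled") <- FALSE
    return(out)
  }
  rownames(seed_pts) <- NULL
  seeds <- sample_set(seed_pts, seed_scs,
                      rep(c("carried-over", "history"),
                          c(length(surv$scores), length(hist_surv$scores))),
                      reduction)

  walk_budget <- as.integer(floor(config$walk_share * config$n_evals))
  walked <- explore_walk(problem, seeds, config, reduction,
                         budget = walk_budget, counter = counter, seed = NULL)
  rest <- config$n_evals - (attr(walked, "evaluations") %||% 0L)
  out <- expand_ellipsoids(problem, walked, config, reduction,
                           budget = max(rest, 0L), counter = counter, seed = NULL)
  if (nrow(out$points) > config$d_max) {
    keep <- seq_len(config$d_max)
    pts <- out$points[keep, , drop = FALSE]
    rownames(pts) <- NULL
    out <- sample_set(pts, out$scores[keep], out$origin[keep], reduction)
  }
  attr(out, "resampled") <- TRUE
  out
}
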