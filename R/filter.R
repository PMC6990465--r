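#' Filtering run configuration
#'
#' @param rank exhaustive-search rank `r >= 1`: the number of parameters
#'   simultaneously tested for projection, relative to the submodel being
#'   reduced.
#' @param enum_level enumeration strategy selecting which viable
#'   projections become roots of recursive search steps:
#'   conservative (`0`) enumerates only the inclusion-maximal viable
#'   projections of a step; balanced (`1`) enumerates all viable per-sample
#'   union projections; aggressive (`2`) enumerates every viable projection
#'   of the step, including low-rank ones from the exhaustive phase.
#' @param backtracking if a union reduction that skipped intermediate ranks
#'   proves non-viable, test the skipped intermediate-rank subsets
#'   (experimental).
#' @param backtrack_granularity `"all"` triggers backtracking only when a
#'   union fails for every sample of the step; `"sample"` triggers per
#'   failed sample union.
#' @param parallel_level `0` sequential; `1` distributes the per-candidate
#'   viability batch of the exhaustive phase; `2` processes the recursion
#'   roots of a step concurrently (registries merged,
#'   first-discovery-wins); `3` runs `repeats` independently seeded
#'   filterings (see [execute_filter()]).
#' @param workers worker-pool size for levels 1-3.
#' @param repeats number of independent repeats at parallel level 3.
#' @param sampler a [sampler_config()].
#' @param seed master seed; child seeds are derived deterministically per
#'   (root, phase), so sequential and level-1 runs coincide.
#' @param stream_dir optional directory; when set, the viable samples of
#'   every discovered reduction are appended on-the-fly to
#'   `samples/<reduction>.csv` below it.
#' @return an object of class `"filter_config"`.
#' @export
filter_config <- function(rank = 1L, enum_level = 1L, backtracking = FALSE,
                          backtrack_granularity = c("all", "sample"),
                          parallel_level = 0L, workers = 1L, repeats = 1L,
                          sampler = sampler_config(), seed = 1L,
                          stream_dir = NULL) {
  stopifnot(rank >= 1L, enum_level %in% 0:2, parallel_level %in% 0:3,
            workers >= 1L, repeats >= 1L, inherits(sampler, "sampler_config"))
  structure(list(rank = as.integer(rank), enum_level = as.integer(enum_level),
                 backtracking = isTRUE(backtracking),
                 backtrack_granularity = match.arg(backtrack_granularity),
                 parallel_level = as.integer(parallel_level),
                 workers = as.integer(workers), repeats = as.integer(repeats),
                 sampler = sampler, seed = as.integer(seed),
                 stream_dir = stream_dir),
            class = "filter_config")
}

# --- registry --------------------------------------------------------------

tf_new_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()     # id -> record
  env$order <- character(0) # discovery order
  env
}

tf_register <- function(registry, red, witness, score, phase, step) {
  if (!is.null(registry$records[[red$id]])) return(invisible(FALSE)) # first discovery wins
  registry$records[[red$id]] <- list(reduction = red, witness = witness,
                                     score = score, phase = phase, step = step)
  registry$order <- c(registry$order, red$id)
  invisible(TRUE)
}

# inclusion-maximal index sets among a list of reductions
tf_maximal <- function(reds) {
  if (length(reds) == 0L) return(reds)
  keep <- rep(TRUE, length(reds))
  for (i in seq_along(reds)) {
    for (j in seq_along(reds)) {
      if (i != j && keep[i] &&
          length(reds[[i]]$index_set) < length(reds[[j]]$index_set) &&
          all(reds[[i]]$index_set %in% reds[[j]]$index_set)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  reds[keep]
}

# --- search phases ---------------------------------------------------------

#' Rank-bounded exhaustive testing of candidate reductions
#'
#' For every sample, every candidate from [enumerate_reductions()] is
#' tested by projecting the sample and scoring it -- with no pruning inside
#' this phase, so the per-step cost is exactly
#' `|samples| * sum_{i=1}^{r} C(d_tilde_remaining, i)` on coupling-free
#' problems (cf. [evaluation_budget()]).  Non-viable candidates are never
#' pruned away for other samples; they are simply not used as union members
#' or recursion roots later.
#'
#' @param problem a [tf_problem()].
#' @param root the [reduction()] the candidates extend.
#' @param samples a [sample_set()] viable for `root`.
#' @param rank exhaustive rank `r`.
#' @param counter optional evaluation counter.
#' @param workers batch workers (parallel level 1).
#' @return list with `candidates` (list of reductions), `viable`
#'   (logical matrix, samples x candidates), `scores` (numeric matrix),
#'   and `evaluations`.
#' @export
exhaustive_step <- function(problem, root, samples, rank, counter = NULL,
                            workers = 1L) {
  candidates <- enumerate_reductions(problem$catalog, root, rank)
  n_s <- nrow(samples$points)
  n_c <- length(candidates)
  viable <- matrix(FALSE, n_s, n_c)
  scores <- matrix(Inf, n_s, n_c)
  if (n_s > 0L && n_c > 0L) {
    grid <- vector("list", n_s * n_c)
    idx <- 1L
    for (s in seq_len(n_s)) {
      ps <- stats::setNames(as.numeric(samples$points[s, ]),
                            problem$space$parameter_names)
      for (ci in seq_len(n_c)) {
        grid[[idx]] <- apply_reduction(ps, candidates[[ci]], problem$catalog)
        idx <- idx + 1L
      }
    }
    res <- tf_viability_batch(problem, grid, counter, workers)
    idx <- 1L
    for (s in seq_len(n_s)) {
      for (ci in seq_len(n_c)) {
        viable[s, ci] <- res[[idx]]$viable
        scores[s, ci] <- res[[idx]]$score
        idx <- idx + 1L
      }
    }
  }
  list(candidates = candidates, viable = viable, scores = scores,
       evaluations = n_s * n_c)
}

#' Per-sample union jumps
#'
#' For each sample, the union of its viable candidate reductions is formed
#' (unions are strictly per sample, never across samples).  A union whose
#' rank relative to the root exceeds the exhaustive rank is a jump over
#' skipped intermediate levels; each distinct such union is tested once
#' against *all* samples of the step.  Unions with rank at most `r`
#' coincide with an already-tested candidate and are not re-tested.
#'
#' @param problem a [tf_problem()].
#' @param root the step's root [reduction()].
#' @param exh result of [exhaustive_step()].
#' @param samples the step's [sample_set()].
#' @param rank the exhaustive rank `r`.
#' @param counter optional evaluation counter.
#' @return list of union entries: each has `reduction`, `tested` (logical:
#'   did it require a fresh viability test), `viable`, `surviving`
#'   (sample indices for which it is viable), `witness`, `score`.
#' @export
union_step <- function(problem, root, exh, samples, rank, counter = NULL) {
  n_s <- nrow(samples$points)
  unions <- list()
  for (s in seq_len(n_s)) {
    vc <- which(exh$viable[s, ])
    if (length(vc) == 0L) next
    uni_idx <- sort(unique(unlist(lapply(exh$candidates[vc],
                                         function(r) r$index_set))))
    red <- reduction(problem$catalog, uni_idx, parent = root)
    if (is.null(unions[[red$id]])) {
      unions[[red$id]] <- list(reduction = red, samples = s)
    } else {
      unions[[red$id]]$samples <- c(unions[[red$id]]$samples, s)
    }
  }
  cand_ids <- vapply(exh$candidates, function(r) r$id, "")
  out <- list()
  for (id in names(unions)) {
    u <- unions[[id]]
    red <- u$reduction
    if (red$rank <= rank) {
      # equals one of the exhaustive candidates: no extra test
      ci <- match(id, cand_ids)
      surv <- which(exh$viable[, ci])
      wit_s <- if (length(surv) > 0L) surv[1L] else NA_integer_
      out[[id]] <- list(reduction = red, tested = FALSE, viable = length(surv) > 0L,
                        surviving = surv,
                        witness = if (!is.na(wit_s))
                          apply_reduction(stats::setNames(as.numeric(samples$points[wit_s, ]),
                                                          problem$space$parameter_names),
                                          red, problem$catalog) else NULL,
                        score = if (!is.na(wit_s)) exh$scores[wit_s, ci] else Inf)
      next
    }
    # a genuine jump: check against all samples
    pts <- lapply(seq_len(n_s), function(s)
      apply_reduction(stats::setNames(as.numeric(samples$points[s, ]),
                                      problem$space$parameter_names),
                      red, problem$catalog))
    res <- tf_viability_batch(problem, pts, counter, workers = 1L)
    surv <- which(vapply(res, function(r) r$viable, TRUE))
    wit_s <- if (length(surv) > 0L) surv[1L] else NA_integer_
    out[[id]] <- list(reduction = red, tested = TRUE, viable = length(surv) > 0L,
                      surviving = surv,
                      witness = if (!is.na(wit_s)) pts[[wit_s]] else NULL,
                      score = if (!is.na(wit_s)) res[[wit_s]]$score else Inf)
  }
  out
}

#' Backtracking over skipped intermediate reductions
#'
#' When a union jump of rank `u > r` proves non-viable, the intermediate
#' reductions it skipped -- all strict subsets of the failed union with
#' relative size in `(r, u)`, in increasing size then lexicographic order
#' -- are tested against the available samples.
#'
#' @param problem a [tf_problem()].
#' @param root the step's root [reduction()].
#' @param failed_union the non-viable union [reduction()].
#' @param rank the exhaustive rank `r`.
#' @param samples the step's [sample_set()].
#' @param counter optional evaluation counter.
#' @return list with `tested` (list of reductions, in test order) and
#'   `viable` (list of entries `reduction`, `surviving`, `witness`,
#'   `score`).
#' @export
backtrack_step <- function(problem, root, failed_union, rank, samples,
                           counter = NULL) {
  extra <- sort(setdiff(failed_union$index_set, root$index_set))
  u <- length(extra)
  tested <- list()
  viable <- list()
  sizes <- seq_len(u - 1L)
  sizes <- sizes[sizes > rank]
  n_s <- nrow(samples$points)
  seen <- character(0)
  for (size in sizes) {
    combos <- if (length(extra) == 1L) list(extra) else
      utils::combn(extra, size, simplify = FALSE)
    for (A in combos) {
      red <- reduction(problem$catalog, c(root$index_set, A), parent = root)
      if (red$id %in% seen || red$id == failed_union$id) next
      seen <- c(seen, red$id)
      tested[[length(tested) + 1L]] <- red
      pts <- lapply(seq_len(n_s), function(s)
        apply_reduction(stats::setNames(as.numeric(samples$points[s, ]),
                                        problem$space$parameter_names),
                        red, problem$catalog))
      res <- tf_viability_batch(problem, pts, counter, workers = 1L)
      surv <- which(vapply(res, function(r) r$viable, TRUE))
      if (length(surv) > 0L) {
        viable[[length(viable) + 1L]] <-
          list(reduction = red, surviving = surv, witness = pts[[surv[1L]]],
               score = res[[surv[1L]]]$score)
      }
    }
  }
  list(tested = tested, viable = viable)
}

#' Select the recursion roots of a filtering step
#'
#' Applies the enumeration strategy: level 0 keeps only the
#' inclusion-maximal viable projections found in the step; level 1 keeps
#' all viable per-sample union projections; level 2 keeps every viable
#' projection of the step, including the low-rank ones from the exhaustive
#' phase.  Duplicates are removed by canonical index set.
#'
#' @param level enumeration level (0, 1 or 2).
#' @param step_viables list with components `exhaustive`, `union`,
#'   `backtrack`: lists of viable [reduction()]s found in each phase.
#' @return de-duplicated list of reductions, in discovery order.
#' @export
select_recursion_roots <- function(level, step_viables) {
  if (!level %in% 0:2) stop("enumeration level must be 0, 1 or 2", call. = FALSE)
  exh <- step_viables$exhaustive %||% list()
  uni <- step_viables$union %||% list()
  bt <- step_viables$backtrack %||% list()
  pool <- switch(as.character(level),
                 "0" = tf_maximal(c(exh, uni, bt)),
                 "1" = uni,
                 "2" = c(exh, uni, bt))
  ids <- vapply(pool, function(r) r$id, "")
  pool[!duplicated(ids)]
}

#' Per-step exhaustive-search evaluation budget
#'
#' `D * sum_{i=0}^{r} C(d_tilde, i)`: the number of model evaluations a
#' filtering step spends on the rank-bounded exhaustive search for `D`
#' samples and `d_tilde` projectable parameters -- linear in `d_tilde` for
#' rank 1, quadratic for rank 2, and so on.  The `i = 0` term counts each
#' sample's own (re-)evaluation.
#'
#' @param D number of parameter samples.
#' @param d_tilde number of projectable parameters.
#' @param r exhaustive rank, `0 <= r <= d_tilde`.
#' @return the evaluation count (numeric, exact for the sizes used here).
#' @export
evaluation_budget <- function(D, d_tilde, r) {
  stopifnot(D >= 0, d_tilde >= 0, r >= 0, r <= d_tilde)
  D * sum(choose(d_tilde, 0:r))
}

# --- main search -----------------------------------------------------------

#' Run topological filtering
#'
#' Depth-first recursion over the submodel lattice.  Starting from the root
#' model and one viable parameter point, each step prepares its viable
#' points ([prepare_points()]), tests all candidate reductions up to the
#' exhaustive rank ([exhaustive_step()]), jumps to per-sample unions
#' ([union_step()]), optionally backtracks over skipped intermediate
#' reductions ([backtrack_step()]), selects recursion roots according to
#' the enumeration level ([select_recursion_roots()]), and recurses until
#' no root yields new registry entries.  Every viable projection found in
#' any phase is recorded with one witness sample, even when it is not
#' recursed into.
#'
#' @param problem a [tf_problem()].
#' @param config a [filter_config()].
#' @param init_point one viable parameter vector for the unreduced root
#'   model (obtained e.g. by ordinary parameter estimation).  A non-viable
#'   initial point is a hard error before any search.
#' @return an object of class `"filter_result"`: `records` (registry, one
#'   entry per discovered viable projection, first discovery wins),
#'   `maximal` (ids of the inclusion-maximal discovered reductions),
#'   `evaluations`, `samplings`, `steps` (per-step accounting data frame),
#'   `config`.
#' @export
run_filter <- function(problem, config = filter_config(), init_point) {
  stopifnot(inherits(problem, "tf_problem"), inherits(config, "filter_config"))
  catalog <- problem$catalog
  counter <- tf_new_counter()
  init_point <- stats::setNames(as.numeric(init_point)[
    match(problem$space$parameter_names,
          names(init_point) %||% problem$space$parameter_names)],
    problem$space$parameter_names)
  root <- reduction(catalog)
  chk <- is_viable(problem, init_point, counter)
  if (!chk$viable) {
    stop(sprintf("initial point is not viable: score %.6g exceeds threshold %.6g",
                 chk$score, problem$score_model$s0), call. = FALSE)
  }

  registry <- tf_new_registry()
  tf_register(registry, root, init_point, chk$score, "recursion-root", 0L)
  explored <- new.env(parent = emptyenv())
  pool <- new.env(parent = emptyenv())   # reduction id -> viable points found
  steps <- list()
  step_i <- 0L
  workers <- if (config$parallel_level == 1L) config$workers else 1L

  pool_add <- function(id, pts) {
    if (is.null(pts) || nrow(pts) == 0L) return(invisible())
    old <- pool[[id]]
    assign(id, unique(rbind(old, pts)), envir = pool)
  }

  stream <- function(red, samples) {
    if (is.null(config$stream_dir) || nrow(samples$points) == 0L) return(invisible())
    dir <- file.path(config$stream_dir, "samples")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_+-]", "_", red$id), ".csv"))
    df <- as.data.frame(samples$points)
    df$score <- samples$scores
    utils::write.table(df, fn, sep = ",", row.names = FALSE,
                       col.names = !file.exists(fn), append = file.exists(fn))
  }

  filter_step <- function(step_root, carryover, depth) {
    if (!is.null(explored[[step_root$id]])) return(invisible())
    assign(step_root$id, TRUE, envir = explored)
    step_i <<- step_i + 1L
    this_step <- step_i

    samples <- prepare_points(problem, carryover, pool[[step_root$id]],
                              config$sampler, step_root, counter,
                              seed = tf_derive_seed(config$seed, step_root$id, "sample"))
    if (isTRUE(attr(samples, "resampled"))) {
      counter$samplings <- counter$samplings + 1L
    }
    pool_add(step_root$id, samples$points)
    stream(step_root, samples)
    if (nrow(samples$points) == 0L) {
      steps[[length(steps) + 1L]] <<- data.frame(
        step = this_step, root = step_root$id, n_samples = 0L, n_candidates = 0L,
        exhaustive_evaluations = 0L, n_viable = 0L,
        resampled = isTRUE(attr(samples, "resampled")))
      return(invisible())
    }

    exh <- exhaustive_step(problem, step_root, samples, config$rank, counter, workers)
    n_c <- length(exh$candidates)
    exh_viable <- list()
    exh_carry <- list()  # id -> surviving sample indices
    for (ci in seq_len(n_c)) {
      surv <- which(exh$viable[, ci])
      if (length(surv) == 0L) next
      red <- exh$candidates[[ci]]
      wit <- apply_reduction(stats::setNames(as.numeric(samples$points[surv[1L], ]),
                                             problem$space$parameter_names),
                             red, catalog)
      tf_register(registry, red, wit, exh$scores[surv[1L], ci], "exhaustive", this_step)
      exh_viable[[length(exh_viable) + 1L]] <- red
      exh_carry[[red$id]] <- surv
    }

    unis <- union_step(problem, step_root, exh, samples, config$rank, counter)
    uni_viable <- list()
    uni_carry <- list()
    failed_unions <- list()
    for (u in unis) {
      if (u$viable) {
        if (u$tested) {
          tf_register(registry, u$reduction, u$witness, u$score, "union", this_step)
        }
        uni_viable[[length(uni_viable) + 1L]] <- u$reduction
        uni_carry[[u$reduction$id]] <- u$surviving
      } else if (u$tested) {
        failed_unions[[length(failed_unions) + 1L]] <- u$reduction
      }
    }

    bt_viable <- list()
    bt_carry <- list()
    if (config$backtracking) {
      for (fu in failed_unions) {
        bt <- backtrack_step(problem, step_root, fu, config$rank, samples, counter)
        for (v in bt$viable) {
          tf_register(registry, v$reduction, v$witness, v$score, "backtrack", this_step)
          bt_viable[[length(bt_viable) + 1L]] <- v$reduction
          bt_carry[[v$reduction$id]] <- v$surviving
        }
      }
    }

    n_viable_step <- length(exh_viable) + length(uni_viable) + length(bt_viable)
    steps[[length(steps) + 1L]] <<- data.frame(
      step = this_step, root = step_root$id, n_samples = nrow(samples$points),
      n_candidates = n_c, exhaustive_evaluations = exh$evaluations,
      n_viable = n_viable_step, resampled = isTRUE(attr(samples, "resampled")))

    roots_next <- select_recursion_roots(config$enum_level,
                                         list(exhaustive = exh_viable,
                                              union = uni_viable,
                                              backtrack = bt_viable))
    roots_next <- Filter(function(r) is.null(explored[[r$id]]), roots_next)

    run_root <- function(next_root) {
      surv <- exh_carry[[next_root$id]] %||% uni_carry[[next_root$id]] %||%
        bt_carry[[next_root$id]] %||% integer(0)
      if (length(surv) == 0L) surv <- seq_len(nrow(samples$points))
      carry <- t(apply(samples$points[surv, , drop = FALSE], 1L, function(p)
        apply_reduction(stats::setNames(as.numeric(p), problem$space$parameter_names),
                        next_root, catalog)))
      colnames(carry) <- problem$space$parameter_names
      filter_step(next_root, carry, depth + 1L)
    }
    # parallel level 2 would fan the roots out over workers; the registry
    # merge is first-discovery-wins, which the sequential order realizes
    # canonically.  With workers = 1 both paths are identical.
    for (next_root in roots_next) run_root(next_root)
    invisible()
  }

  carry0 <- matrix(init_point, nrow = 1L,
                   dimnames = list(NULL, problem$space$parameter_names))
  filter_step(root, carry0, 0L)

  records <- registry$records[registry$order]
  maximal <- tf_maximal(lapply(records, function(r) r$reduction))
  structure(list(records = records,
                 maximal = unname(vapply(maximal, function(r) r$id, "")),
                 evaluations = counter$evaluations,
                 samplings = counter$samplings,
                 steps = do.call(rbind, steps),
                 config = config),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("topological filtering result: %d viable projections (incl. root)\n",
              length(x$records)))
  cat(sprintf("maximal reductions: %s\n", paste(x$maximal, collapse = ", ")))
  cat(sprintf("model evaluations: %d; samplings: %d; steps: %d\n",
              x$evaluations, x$samplings,
              if (is.null(x$steps)) 0L else nrow(x$steps)))
  invisible(x)
}

#' Orchestrated execution with parallel strategies
#'
#' Parallel level 3 runs `config$repeats` independently seeded filterings
#' (in parallel when `workers > 1`) and merges their registries
#' (first-discovery-wins across repeats, in repeat order); other levels
#' delegate to a single [run_filter()].  Levels 0 and 1 produce identical
#' registries for identical seeds, because scoring is deterministic and
#' randomness lives only in the (sequential) sampling phase.
#'
#' @param problem a [tf_problem()].
#' @param config a [filter_config()].
#' @param init_point viable parameter vector for the root model.
#' @return for levels 0-2 a `"filter_result"`; for level 3 a list with
#'   `results` (one `"filter_result"` per repeat) and `merged` (a combined
#'   `"filter_result"`).
#' @export
execute_filter <- function(problem, config = filter_config(), init_point) {
  if (config$parallel_level != 3L) {
    return(run_filter(problem, config, init_point))
  }
  seeds <- vapply(seq_len(config$repeats), function(i)
    tf_derive_seed(config$seed, "repeat", i), numeric(1))
  one <- function(i) {
    cfg <- config
    cfg$seed <- as.integer(seeds[[i]])
    cfg$parallel_level <- 0L
    run_filter(problem, cfg, init_point)
  }
  results <- if (config$workers > 1L) {
    parallel::mclapply(seq_len(config$repeats), one, mc.cores = config$workers)
  } else {
    lapply(seq_len(config$repeats), one)
  }
  merged_records <- list()
  order_ids <- character(0)
  for (res in results) {
    for (id in names(res$records)) {
      if (is.null(merged_records[[id]])) {
        merged_records[[id]] <- res$records[[id]]
        order_ids <- c(order_ids, id)
      }
    }
  }
  merged_records <- merged_records[order_ids]
  maximal <- tf_maximal(lapply(merged_records, function(r) r$reduction))
  merged <- structure(list(records = merged_records,
                           maximal = unname(vapply(maximal, function(r) r$id, "")),
                           evaluations = sum(vapply(results, function(r) r$evaluations, 0)),
                           samplings = sum(vapply(results, function(r) r$samplings, 0)),
                           steps = do.call(rbind, lapply(results, function(r) r$steps)),
                           config = config),
                      class = "filter_result")
  list(results = results, merged = merged)
}
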