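# Shared independent oracles and fixture builders for the test suite.

# Brute-force enumeration of the viable sublattice of a pattern predicate:
# all 2^d subsets, tested directly against the predicate.  Completely
# independent of the search code.
brute_force_lattice <- function(d, predicate) {
  ids <- character(0)
  for (k in 0:d) {
    combos <- if (k == 0) list(integer(0)) else utils::combn(seq_len(d), k, simplify = FALSE)
    for (A in combos) {
      if (isTRUE(predicate(as.integer(A)))) {
        ids <- c(ids, if (length(A) == 0) "(root)" else
          paste(paste0("q", A), collapse = "+"))
      }
    }
  }
  sort(ids)
}

# Random downward-closed (monotone) viability predicate: a set is viable iff
# it is contained in one of a few random maximal sets.
random_monotone_predicate <- function(d, n_max = 3) {
  maxsets <- lapply(seq_len(n_max), function(i) sort(sample(seq_len(d), sample.int(d, 1))))
  function(I) any(vapply(maxsets, function(M) all(I %in% M), logical(1)))
}

# Graph-reachability oracle for coupling closure: plain BFS over the raw
# coupling edges, written independently of close_couplings().
reachability_closure <- function(couplings, start, all_names) {
  seen <- start
  repeat {
    nxt <- unique(unlist(lapply(seen, function(s) couplings[[s]])))
    new <- setdiff(nxt, seen)
    if (length(new) == 0) break
    seen <- c(seen, new)
  }
  sort(match(seen, all_names))
}

# A 2-d unconstrained test problem with a parameter-space score.
flat_problem <- function(score_fn, threshold = 1, lower = c(a = -10, b = -10),
                         upper = c(a = 10, b = 10)) {
  nms <- names(lower)
  space <- parameter_space(lower = lower, upper = upper)
  catalog <- projection_catalog(nms, reducible = character(0))
  sm <- score_model(type = "custom", score_fn = score_fn, threshold = threshold,
                    score_on = "parameters")
  tf_problem(space, catalog, sm)
}

# Small sampler budgets keep the ODE-backed searches fast.
fast_sampler <- function(n_evals = 80, ...) sampler_config(n_evals = n_evals, d_max = 20, ...)
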