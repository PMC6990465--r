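one_sample <- function(problem, p, red = reduction(problem$catalog)) {
  m <- matrix(p, nrow = 1, dimnames = list(NULL, problem$space$parameter_names))
  sample_set(m, is_viable(problem, p)$score, "initial", red)
}

test_that("exhaustive step on the four-parameter example finds the three viable 1P reductions", {
  uj <- union_jump_example()
  root <- reduction(uj$problem$catalog)
  s <- one_sample(uj$problem, uj$init_point)
  cnt <- tf_new_counter()
  exh <- exhaustive_step(uj$problem, root, s, 1, cnt)
  ids <- vapply(exh$candidates, function(r) r$id, "")
  expect_equal(ids, c("q1", "q2", "q3", "q4"))
  expect_equal(ids[exh$viable[1, ]], c("q1", "q2", "q3"))
  # no pruning: all four candidates were evaluated
  expect_identical(cnt$evaluations, 4L)
  expect_equal(exh$evaluations, 4L)
})

test_that("exhaustive step at rank 2 additionally finds exactly the pairs without q4", {
  uj <- union_jump_example()
  root <- reduction(uj$problem$catalog)
  s <- one_sample(uj$problem, uj$init_point)
  exh <- exhaustive_step(uj$problem, root, s, 2)
  ids <- vapply(exh$candidates, function(r) r$id, "")
  viable_ids <- ids[exh$viable[1, ]]
  expect_setequal(viable_ids,
                  c("q1", "q2", "q3", "q1+q2", "q1+q3", "q2+q3"))
  expect_length(ids, choose(4, 1) + choose(4, 2))
})

test_that("union step jumps once over the skipped rank-2 level", {
  uj <- union_jump_example()
  root <- reduction(uj$problem$catalog)
  s <- one_sample(uj$problem, uj$init_point)
  cnt <- tf_new_counter()
  exh <- exhaustive_step(uj$problem, root, s, 1, cnt)
  us <- union_step(uj$problem, root, exh, s, 1, cnt)
  expect_length(us, 1L)
  u <- us[[1]]
  expect_equal(u$reduction$id, "q1+q2+q3")
  expect_equal(u$reduction$rank, 3L)
  expect_true(u$tested)
  expect_true(u$viable)
  # the union cost exactly one extra test (one sample in the set)
  expect_identical(cnt$evaluations, 4L + 1L)
})

test_that("a sample with a single viable reduction unions to itself without re-testing", {
  # only q4 is NOT reducible to 0; make only q1 viable
  nms <- paste0("q", 1:4)
  space <- parameter_space(lower = setNames(rep(0.5, 4), nms),
                           upper = setNames(rep(1.5, 4), nms))
  catalog <- projection_catalog(nms, reducible = nms)
  sm <- score_model(type = "custom",
                    score_fn = function(p) as.numeric(sum(as.numeric(p)[2:4] == 0) > 0),
                    threshold = 0.5, score_on = "parameters")
  prob <- tf_problem(space, catalog, sm)
  root <- reduction(catalog)
  s <- one_sample(prob, setNames(rep(1, 4), nms))
  exh <- exhaustive_step(prob, root, s, 1)
  us <- union_step(prob, root, exh, s, 1)
  expect_length(us, 1L)
  expect_equal(us[[1]]$reduction$id, "q1")
  expect_false(us[[1]]$tested)  # already tested in the exhaustive phase
  expect_true(us[[1]]$viable)
})

test_that("unions are formed per sample, never across samples", {
  # sample-dependent score: projecting q_i is viable iff p's free marker
  # coordinate selects it; two samples with disjoint viable singletons must
  # not union into a rank-2 jump
  nms <- c("q1", "q2", "m")
  space <- parameter_space(lower = c(q1 = 1, q2 = 1, m = 0),
                           upper = c(q1 = 2, q2 = 2, m = 1))
  catalog <- projection_catalog(nms, reducible = c("q1", "q2"))
  sm <- score_model(type = "custom", score_fn = function(p) {
    z <- as.numeric(p)
    I <- which(z[1:2] == 0)
    if (length(I) == 0) return(0)                      # root always viable
    if (identical(I, 1L) && z[3] < 0.5) return(0)      # sample A: only q1
    if (identical(I, 2L) && z[3] >= 0.5) return(0)     # sample B: only q2
    1
  }, threshold = 0.5, score_on = "parameters")
  prob <- tf_problem(space, catalog, sm)
  root <- reduction(catalog)
  pts <- rbind(c(1.5, 1.5, 0), c(1.5, 1.5, 1))
  colnames(pts) <- nms
  s <- sample_set(pts, c(0, 0), "initial", root)
  exh <- exhaustive_step(prob, root, s, 1)
  us <- union_step(prob, root, exh, s, 1)
  expect_setequal(vapply(us, function(u) u$reduction$id, ""), c("q1", "q2"))
  expect_false(any(vapply(us, function(u) u$tested, logical(1))))
})

test_that("backtracking tests exactly the skipped intermediate subsets", {
  uj <- union_jump_example()
  catalog <- uj$problem$catalog
  root <- reduction(catalog)
  s <- one_sample(uj$problem, uj$init_point)
  # failed rank-3 union with r = 1: the three rank-2 subsets
  fu3 <- reduction(catalog, c("q1", "q2", "q3"))
  bt <- backtrack_step(uj$problem, root, fu3, 1, s)
  expect_equal(vapply(bt$tested, function(r) r$id, ""),
               c("q1+q2", "q1+q3", "q2+q3"))
  # failed union of size r + 1: nothing was skipped
  fu2 <- reduction(catalog, c("q1", "q2"))
  expect_length(backtrack_step(uj$problem, root, fu2, 1, s)$tested, 0L)
  # failed rank-4 union with r = 1: C(4,2) + C(4,3) = 10 subsets
  fu4 <- reduction(catalog, paste0("q", 1:4))
  expect_length(backtrack_step(uj$problem, root, fu4, 1, s)$tested, 10L)
})

test_that("enumeration levels select the documented recursion roots", {
  uj <- union_jump_example()
  catalog <- uj$problem$catalog
  exh_v <- lapply(c("q1", "q2", "q3"), function(n) reduction(catalog, n))
  uni_v <- list(reduction(catalog, c("q1", "q2", "q3")))
  sv <- list(exhaustive = exh_v, union = uni_v)
  ids <- function(x) vapply(x, function(r) r$id, "")
  expect_equal(ids(select_recursion_roots(0, sv)), "q1+q2+q3")
  expect_equal(ids(select_recursion_roots(1, sv)), "q1+q2+q3")
  expect_setequal(ids(select_recursion_roots(2, sv)),
                  c("q1", "q2", "q3", "q1+q2+q3"))
  # two incomparable unions are both level-0 maximal
  two <- list(exhaustive = list(),
              union = list(reduction(catalog, c("q1", "q2")),
                           reduction(catalog, c("q1", "q3"))))
  expect_setequal(ids(select_recursion_roots(0, two)), c("q1+q2", "q1+q3"))
  expect_error(select_recursion_roots(5, sv), "level")
})

test_that("evaluation_budget reproduces the binomial-sum formula", {
  expect_equal(evaluation_budget(7, 10, 0), 7)      # empty-set term only
  expect_equal(evaluation_budget(100, 18, 1), 1900)
  expect_equal(evaluation_budget(1, 4, 2), 11)      # 1 + 4 + 6
  # direct subset-enumeration oracle
  d <- 6; r <- 3
  n_subsets <- sum(vapply(0:r, function(k) length(
    if (k == 0) list(integer(0)) else utils::combn(seq_len(d), k, simplify = FALSE)), 0L))
  expect_equal(evaluation_budget(5, d, r), 5 * n_subsets)
})

test_that("run_filter recovers the exact viable lattice on an analytic fixture", {
  lat <- lattice_problem(5, function(I) all(I %in% 1:3))
  res <- run_filter(lat$problem,
                    filter_config(rank = 1, enum_level = 2,
                                  sampler = sampler_config(n_evals = 60), seed = 3),
                    lat$init_point)
  expect_setequal(names(res$records),
                  c("(root)", "q1", "q2", "q3", "q1+q2", "q1+q3", "q2+q3", "q1+q2+q3"))
  expect_equal(res$maximal, "q1+q2+q3")
  # no subset containing 4 or 5 sneaks in
  expect_false(any(grepl("q4|q5", names(res$records))))
  # soundness: every registry witness re-scores viable
  for (rec in res$records) {
    expect_true(is_viable(lat$problem, rec$witness)$viable)
  }
  # no phantom reductions: closed and within the reducible set
  for (rec in res$records) {
    I <- rec$reduction$index_set
    expect_true(all(I %in% lat$problem$catalog$reducible_idx))
    expect_identical(close_couplings(lat$problem$catalog, I), I)
  }
})

test_that("a non-viable initial point is a hard error before any search", {
  lat <- lattice_problem(3, function(I) length(I) == 0)
  bad <- lat$init_point
  # any point is viable for the root here; break it with an impossible score
  sm <- score_model(type = "custom", score_fn = function(p) 2, threshold = 0.5,
                    score_on = "parameters")
  prob <- tf_problem(lat$problem$space, lat$problem$catalog, sm)
  expect_error(run_filter(prob, filter_config(sampler = sampler_config(n_evals = 10)), bad),
               "not viable")
})

test_that("per-step exhaustive accounting matches the budget formula exactly", {
  lat <- lattice_problem(6, function(I) TRUE)
  cfg <- filter_config(rank = 2, enum_level = 0,
                       sampler = sampler_config(n_evals = 40, d_max = 5), seed = 8)
  res <- run_filter(lat$problem, cfg, lat$init_point)
  st <- res$steps
  for (i in seq_len(nrow(st))) {
    d_rem <- 6 - (if (st$root[i] == "(root)") 0 else
      length(strsplit(st$root[i], "+", fixed = TRUE)[[1]]))
    expected <- st$n_samples[i] * sum(choose(d_rem, seq_len(min(2, d_rem))))
    expect_equal(st$exhaustive_evaluations[i], expected)
  }
})

test_that("backtracking recovers intermediate reductions skipped by a failed union", {
  # viable sets: all singletons of {1,2,3} and the pairs, but NOT the triple:
  # the union {1,2,3} fails, backtracking must find the pairs
  lat <- lattice_problem(4, function(I) all(I %in% 1:3) && length(I) <= 2)
  cfg_bt <- filter_config(rank = 1, enum_level = 2, backtracking = TRUE,
                          sampler = sampler_config(n_evals = 60), seed = 2)
  res_bt <- run_filter(lat$problem, cfg_bt, lat$init_point)
  expect_true(all(c("q1+q2", "q1+q3", "q2+q3") %in% names(res_bt$records)))
  phases <- vapply(res_bt$records[c("q1+q2", "q1+q3", "q2+q3")],
                   function(r) r$phase, "")
  expect_true(any(phases == "backtrack"))
  expect_false("q1+q2+q3" %in% names(res_bt$records))
})

test_that("parallel level 1 reproduces the sequential registry; level 3 merges repeats", {
  lat <- lattice_problem(5, function(I) all(I %in% 1:3))
  base <- function(pl, workers = 1) filter_config(
    rank = 1, enum_level = 2, parallel_level = pl, workers = workers,
    sampler = sampler_config(n_evals = 60), seed = 5)
  r0 <- run_filter(lat$problem, base(0), lat$init_point)
  r1 <- run_filter(lat$problem, base(1, 2), lat$init_point)
  expect_identical(names(r0$records), names(r1$records))
  expect_identical(r0$evaluations, r1$evaluations)

  e3 <- execute_filter(lat$problem,
                       filter_config(rank = 1, enum_level = 2, parallel_level = 3,
                                     repeats = 3, sampler = sampler_config(n_evals = 60),
                                     seed = 5),
                       lat$init_point)
  expect_length(e3$results, 3L)
  # merged registry contains every repeat's registry
  for (res in e3$results) {
    expect_true(all(names(res$records) %in% names(e3$merged$records)))
  }
})

test_that("search terminates with recursion bounded by the reducible count", {
  lat <- lattice_problem(6, function(I) TRUE)
  res <- run_filter(lat$problem,
                    filter_config(rank = 1, enum_level = 2,
                                  sampler = sampler_config(n_evals = 40, d_max = 5),
                                  seed = 1),
                    lat$init_point)
  expect_equal(length(res$records), 2^6)
  # each reduction explored at most once
  expect_lte(nrow(res$steps), 2^6)
})
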