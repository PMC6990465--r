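root_of <- function(problem) reduction(problem$catalog)

seed_set <- function(problem, pts, red = root_of(problem)) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  colnames(pts) <- problem$space$parameter_names
  scores <- vapply(seq_len(nrow(pts)), function(i)
    is_viable(problem, pts[i, ])$score, numeric(1))
  sample_set(pts, scores, "initial", red)
}

test_that("walk in a fully viable box fills up to the point cap", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  seeds <- seed_set(prob, c(a = 0, b = 0))
  cfg <- sampler_config(n_evals = 50, d_max = 30)
  out <- explore_walk(prob, seeds, cfg, root_of(prob), budget = 50, seed = 1)
  expect_equal(nrow(out$points), 30)  # acceptance 1 -> capped at d_max
  cfg2 <- sampler_config(n_evals = 15, d_max = 100)
  out2 <- explore_walk(prob, seeds, cfg2, root_of(prob), budget = 15, seed = 1)
  expect_equal(nrow(out2$points), 1 + 15)  # every proposal accepted
})

test_that("walk output satisfies the viability predicate exactly", {
  # half-space viable region {a < 2}
  prob <- flat_problem(function(p) as.numeric(as.numeric(p)[1] >= 2), threshold = 0.5)
  seeds <- seed_set(prob, c(a = 0, b = 0))
  out <- explore_walk(prob, seeds, sampler_config(n_evals = 200, d_max = 500),
                      root_of(prob), budget = 200, seed = 3)
  expect_gt(nrow(out$points), 10)
  expect_true(all(out$points[, "a"] < 2))
  # output purity: every returned point re-scores viable
  ok <- vapply(seq_len(nrow(out$points)), function(i)
    is_viable(prob, out$points[i, ])$viable, logical(1))
  expect_true(all(ok))
})

test_that("zero budget returns the seeds unchanged", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  seeds <- seed_set(prob, rbind(c(0, 0), c(1, 1)))
  out <- explore_walk(prob, seeds, sampler_config(n_evals = 100), root_of(prob),
                      budget = 0, seed = 1)
  expect_identical(out$points, seeds$points)
})

test_that("log-scaled coordinates are walked in log space within bounds", {
  space <- parameter_space(lower = c(a = 1e-6, b = -1), upper = c(a = 1e2, b = 1),
                           scale = c("log", "linear"))
  catalog <- projection_catalog(c("a", "b"), reducible = character(0))
  sm <- score_model(type = "custom", score_fn = function(p) 0, threshold = 1,
                    score_on = "parameters")
  prob <- tf_problem(space, catalog, sm)
  seeds <- seed_set(prob, c(a = 1e-3, b = 0))
  out <- explore_walk(prob, seeds, sampler_config(n_evals = 150, d_max = 200),
                      root_of(prob), budget = 150, seed = 5)
  expect_true(all(out$points[, "a"] >= 1e-6 & out$points[, "a"] <= 1e2))
  # a linear walk of this box would essentially never land below 1e-2;
  # the log walk covers small magnitudes
  expect_gt(mean(out$points[, "a"] < 1e-2), 0.2)
})

test_that("ellipsoid proposals from points inside an ellipsoidal region mostly hit it", {
  prob <- flat_problem(function(p) {
    z <- as.numeric(p); (z[1] / 4)^2 + (z[2] / 2)^2
  }, threshold = 1)
  set.seed(1)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < 40) {
    cand <- c(runif(1, -4, 4), runif(1, -2, 2))
    if ((cand[1] / 4)^2 + (cand[2] / 2)^2 <= 1) pts <- rbind(pts, cand)
  }
  seeds <- seed_set(prob, pts)
  cfg <- sampler_config(n_evals = 200, d_max = 1000, inflation = 1.0, n_ellipsoids = 1)
  out <- expand_ellipsoids(prob, seeds, cfg, root_of(prob), budget = 200, seed = 42)
  accepted <- nrow(out$points) - 40
  expect_gte(accepted / attr(out, "evaluations"), 0.5)
})

test_that("identical input points take the regularization path and stay viable", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  same <- matrix(rep(0, 24), ncol = 2)
  seeds <- seed_set(prob, same)
  out <- expand_ellipsoids(prob, seeds, sampler_config(n_evals = 40, d_max = 100),
                           root_of(prob), budget = 40, seed = 3)
  expect_gt(nrow(out$points), nrow(same))
  ok <- vapply(seq_len(nrow(out$points)), function(i)
    is_viable(prob, out$points[i, ])$viable, logical(1))
  expect_true(all(ok))
})

test_that("two well-separated viable islands get one ellipsoid each", {
  prob <- flat_problem(function(p) {
    z <- as.numeric(p)
    if (sum((z - c(-5, -5))^2) < 1 || sum((z - c(5, 5))^2) < 1) 0 else 2
  }, threshold = 1)
  set.seed(2)
  isl <- rbind(matrix(rnorm(20, -5, 0.3), 10, 2), matrix(rnorm(20, 5, 0.3), 10, 2))
  isl <- isl[apply(isl, 1, function(z)
    sum((z - c(-5, -5))^2) < 1 | sum((z - c(5, 5))^2) < 1), , drop = FALSE]
  seeds <- seed_set(prob, isl)
  out <- expand_ellipsoids(prob, seeds, sampler_config(n_evals = 300, d_max = 1000,
                                                       n_ellipsoids = 2),
                           root_of(prob), budget = 300, seed = 9)
  expect_equal(attr(out, "n_ellipsoids"), 2L)
  new_pts <- out$points[-seq_len(nrow(isl)), , drop = FALSE]
  in1 <- sum(apply(new_pts, 1, function(z) sum((z - c(-5, -5))^2) < 1))
  in2 <- sum(apply(new_pts, 1, function(z) sum((z - c(5, 5))^2) < 1))
  expect_gt(in1, 0)
  expect_gt(in2, 0)
})

test_that("too few points for an ellipsoid fall back to the walk", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  seeds <- seed_set(prob, c(a = 0, b = 0))  # 1 < d_free + 1
  out <- expand_ellipsoids(prob, seeds, sampler_config(n_evals = 20, d_max = 50),
                           root_of(prob), budget = 20, seed = 4)
  expect_gt(nrow(out$points), 1)
  expect_true(all(out$origin[-1] == "walk"))
})

test_that("prepare_points passes through or triggers re-sampling at the 1/20 threshold", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  root <- root_of(prob)
  cfg <- sampler_config(n_evals = 1000)  # trigger threshold: ceil(1000/20) = 50
  co_many <- matrix(runif(200, -1, 1), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
  cnt <- tf_new_counter()
  out <- prepare_points(prob, co_many, NULL, cfg, root, cnt, seed = 1)
  expect_false(attr(out, "resampled"))
  expect_equal(nrow(out$points), 100)           # passthrough
  expect_identical(cnt$evaluations, 100L)       # one re-validation each
  expect_true(all(out$origin == "carried-over"))

  co_few <- co_many[1:10, , drop = FALSE]
  cnt2 <- tf_new_counter()
  out2 <- prepare_points(prob, co_few, NULL, cfg, root, cnt2, seed = 1)
  expect_true(attr(out2, "resampled"))
  expect_gt(nrow(out2$points), 10)
  # budget invariant: evaluations <= n + |carryover|
  expect_lte(cnt2$evaluations, 1000 + 10)
  # exact boundary: exactly ceil(f n) survivors -> no re-sampling
  co_edge <- co_many[1:50, , drop = FALSE]
  out3 <- prepare_points(prob, co_edge, NULL, cfg, root, seed = 1)
  expect_false(attr(out3, "resampled"))
})

test_that("projected coordinates stay frozen exactly through re-sampling", {
  # viable iff |b| < 1; the reduction freezes b at its projection value 0
  nms <- c("a", "b")
  space <- parameter_space(lower = c(a = -2, b = -2), upper = c(a = 2, b = 2))
  catalog <- projection_catalog(nms, reducible = "b",
                                projection_values = c(b = 0))
  sm <- score_model(type = "custom",
                    score_fn = function(p) as.numeric(abs(as.numeric(p)[2]) >= 1),
                    threshold = 0.5, score_on = "parameters")
  prob <- tf_problem(space, catalog, sm)
  red <- reduction(catalog, "b")
  co <- rbind(c(0.5, 0), c(1.5, 0))  # both already projected, both viable
  colnames(co) <- nms
  out <- prepare_points(prob, co, NULL, sampler_config(n_evals = 100), red, seed = 2)
  expect_true(attr(out, "resampled"))
  expect_gt(nrow(out$points), 2)
  # frozen coordinate: b stays exactly 0 in every output point
  expect_true(all(out$points[, "b"] == 0))
  # unchanged reduction: carried-over points re-validate as viable
  expect_true(all(vapply(seq_len(nrow(out$points)), function(i)
    is_viable(prob, out$points[i, ])$viable, logical(1))))
})

test_that("samplers are deterministic under identical seeds", {
  prob <- flat_problem(function(p) sum(as.numeric(p)^2) / 20, threshold = 1)
  seeds <- seed_set(prob, rbind(c(0, 0), c(1, 1)))
  cfg <- sampler_config(n_evals = 120, d_max = 60)
  w1 <- explore_walk(prob, seeds, cfg, root_of(prob), budget = 60, seed = 77)
  w2 <- explore_walk(prob, seeds, cfg, root_of(prob), budget = 60, seed = 77)
  expect_identical(w1$points, w2$points)
  e1 <- expand_ellipsoids(prob, w1, cfg, root_of(prob), budget = 60, seed = 78)
  e2 <- expand_ellipsoids(prob, w2, cfg, root_of(prob), budget = 60, seed = 78)
  expect_identical(e1$points, e2$points)
  p1 <- prepare_points(prob, seeds$points, NULL, cfg, root_of(prob), seed = 79)
  p2 <- prepare_points(prob, seeds$points, NULL, cfg, root_of(prob), seed = 79)
  expect_identical(p1$points, p2$points)
})

test_that("empty carryover and history yield an empty set with a warning", {
  prob <- flat_problem(function(p) 0, threshold = 1)
  expect_warning(
    out <- prepare_points(prob, matrix(numeric(0), ncol = 2), NULL,
                          sampler_config(n_evals = 10), root_of(prob), seed = 1),
    "no viable points")
  expect_equal(nrow(out$points), 0)
})
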