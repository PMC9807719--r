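# Fold construction, summary statistics, and the three training protocols.

# small protocol scale used throughout: 16x16 images, 45 samples, 3 folds
proto_fixture <- function(seed = 1L) {
  spec <- model_spec(c(16L, 16L, 1L),
                     list(conv2d(4L, 3L), avg_pool2d(2L), flatten(),
                          dense(3L, "softmax")), name = "proto")
  ds <- generate_phantoms(phantom_config(n_samples = 45L, image_size = 16L,
                                         tumor_radius_range = c(2, 3),
                                         seed = seed))
  data <- list(x = ds$x, y = ds$y, class_names = ds$class_names)
  plan <- make_folds(data$y, k = 3L, seed = seed)
  tc <- train_config(learning_rate = 0.005, max_epochs = 2L, batch_size = 15L,
                     seed = seed)
  list(spec = spec, data = data, plan = plan, tc = tc)
}

test_that("fold plans are balanced, stratified and deterministic", {
  plan <- make_folds(rep(0:2, length.out = 10), k = 5, seed = 1,
                     stratified = FALSE)
  expect_equal(unname(table(plan$assignment)), rep(2L, 5), ignore_attr = TRUE)
  # the reference dataset's class counts split into test folds of 612-613
  y <- rep(0:2, c(708, 1426, 930))
  plan <- make_folds(y, k = 5, seed = 7)
  sizes <- tabulate(plan$assignment, 5L)
  expect_true(all(sizes %in% c(612L, 613L)))
  expect_equal(sum(sizes), 3064L)
  # stratification: per-class fold sizes differ by at most one
  for (cl in 0:2) {
    cs <- tabulate(plan$assignment[y == cl], 5L)
    expect_lte(diff(range(cs)), 1L)
  }
  plan2 <- make_folds(y, k = 5, seed = 7)
  expect_identical(plan$assignment, plan2$assignment)
  expect_error(make_folds(c(0, 0, 0, 1), k = 3), "at least k members")
})

test_that("group-aware folds keep whole groups together", {
  y <- rep(0:2, each = 20)
  g <- rep(1:12, each = 5)
  plan <- make_folds(y, k = 3, seed = 2, groups = g)
  for (gr in unique(g))
    expect_length(unique(plan$assignment[g == gr]), 1L)
})

test_that("mean/SD summaries use the sample (n-1) convention", {
  ms <- mean_sd(c(92.82, 93.64, 92.82, 92.66, 93.46))
  expect_equal(round(unname(ms["mean"]), 2), 93.08)
  expect_equal(round(unname(ms["sd"]), 2), 0.44)
  expect_equal(unname(mean_sd(rep(5, 4))["sd"]), 0)
  # two-pass variance oracle
  withr::with_seed(3, x <- rnorm(20, 50, 4))
  m <- mean(x)
  expect_equal(unname(mean_sd(x)["sd"]), sqrt(sum((x - m)^2) / (length(x) - 1)))
  expect_error(mean_sd(1), "at least two")
})

test_that("plain cross-validation keeps folds disjoint and leak-free", {
  fx <- proto_fixture()
  cfg <- protocol_config("case1", fx$spec, fx$tc, seed = 1L)
  res <- run_case1(fx$data, fx$plan, cfg)
  expect_length(res$per_unit, 3L)
  expect_true(all(lengths(res$leakage_audit) == 0L))
  for (u in res$per_unit) {
    expect_length(intersect(u$train_idx, u$test_idx), 0L)
    expect_setequal(u$test_idx, which(fx$plan$assignment == u$fold))
    # each fold trains a fresh model: exactly one lineage event
    expect_length(u$state$lineage, 1L)
  }
  # summary equals the arithmetic mean of the per-fold reports
  accs <- vapply(res$per_unit, function(u) u$report$accuracy, 0)
  expect_equal(res$summary$mean[res$summary$metric == "accuracy"], mean(accs))
  expect_equal(res$summary$sd[res$summary$metric == "accuracy"], sd(accs))
})

test_that("a single-iteration case-2 run reduces exactly to case 1", {
  fx <- proto_fixture()
  cfg1 <- protocol_config("case1", fx$spec, fx$tc, seed = 1L)
  cfg2 <- protocol_config("case2", fx$spec, fx$tc, n_iterations = 1L,
                          seed = 1L)
  r1 <- run_case1(fx$data, fx$plan, cfg1)
  r2 <- run_case2(fx$data, fx$plan, cfg2)
  for (f in seq_along(r1$per_unit)) {
    expect_identical(r2$per_unit[[f]]$state$weights,
                     r1$per_unit[[f]]$state$weights)
    expect_identical(r2$per_unit[[f]]$history, r1$per_unit[[f]]$history)
    expect_equal(r2$per_unit[[f]]$report$accuracy,
                 r1$per_unit[[f]]$report$accuracy)
  }
  expect_equal(r2$summary, r1$summary)
  expect_true(all(lengths(r2$leakage_audit) == 0L))
})

test_that("iterated transfer learning carries weights and audits leakage", {
  fx <- proto_fixture()
  cfg <- protocol_config("case2", fx$spec, fx$tc, n_iterations = 3L,
                         seed = 1L)
  res <- run_case2(fx$data, fx$plan, cfg)
  expect_length(res$per_unit, 9L)
  # iteration-3 models inherit exactly 2 prior events, plus their own
  for (u in res$per_unit) {
    expect_length(u$state$lineage, u$iteration)
    expect_equal(u$state$lineage[[length(u$state$lineage)]]$fold, u$fold)
  }
  # leakage: iteration 1 clean; later iterations expose test samples the
  # carried model has already trained on
  k <- fx$plan$n_folds
  carry_events <- list()
  for (i in seq_along(res$per_unit)) {
    u <- res$per_unit[[i]]
    seen <- sort(unique(unlist(lapply(carry_events,
                                      function(e) e), use.names = FALSE)))
    if (u$iteration == 1L) {
      expect_length(res$leakage_audit[[i]], 0L)
    } else {
      expected <- sort(intersect(u$test_idx, seen))
      expect_identical(res$leakage_audit[[i]], expected)
      # the carried model only ever trains on the carry fold's training
      # sets, so every fold but the carry fold sees its test data leaked
      if (u$fold != k) expect_gt(length(expected), 0L)
      else expect_length(expected, 0L)
    }
    if (u$fold == k) {
      # events accumulated by the carried (last-fold) model
      carry_events <- lapply(u$state$lineage, `[[`, "train_idx")
    }
  }
})

test_that("fold-to-fold transfer reproduces the carry semantics and leakage identity", {
  fx <- proto_fixture()
  cfg <- protocol_config("case3", fx$spec, fx$tc, seed = 1L)
  res <- run_case3(fx$data, fx$plan, cfg)
  k <- fx$plan$n_folds
  for (j in seq_len(k)) {
    u <- res$per_unit[[j]]
    expect_length(u$state$lineage, j)           # fold j carries j events
    # leakage is exactly (union of earlier test folds) intersect train_j
    earlier <- which(fx$plan$assignment %in% seq_len(j - 1L))
    expect_identical(res$leakage_audit[[j]],
                     sort(intersect(earlier, u$train_idx)))
  }
  expect_length(res$leakage_audit[[1L]], 0L)
  expect_gt(length(res$leakage_audit[[k]]), 0L)
  # the final state is the last fold's model
  expect_identical(res$final_state$weights, res$per_unit[[k]]$state$weights)
})

test_that("the stability pass fine-tunes isolated copies of one source model", {
  fx <- proto_fixture()
  cfg <- protocol_config("case3", fx$spec, fx$tc, seed = 1L)
  res3 <- run_case3(fx$data, fx$plan, cfg)
  src <- res3$per_unit[[2L]]$state
  src_weights <- src$weights
  st <- stability_pass(src, fx$data, fx$plan, cfg)
  expect_length(st$per_unit, 3L)
  for (u in st$per_unit) {
    # every fold starts from the same source lineage, then adds one event
    expect_identical(u$state$lineage[seq_along(src$lineage)], src$lineage)
    expect_length(u$state$lineage, length(src$lineage) + 1L)
  }
  # source model untouched by the pass
  expect_identical(src$weights, src_weights)
  # a model without case-3 lineage is refused
  fresh <- build_model(fx$spec, 1L)
  expect_error(stability_pass(fresh, fx$data, fx$plan, cfg), "case-3")
})

test_that("protocol artifacts serialize to CSV and JSON", {
  fx <- proto_fixture()
  cfg <- protocol_config("case3", fx$spec, fx$tc, seed = 1L)
  res <- run_case3(fx$data, fx$plan, cfg)
  dir <- withr::local_tempdir()
  write_protocol_result(res, dir)
  units <- read.csv(file.path(dir, "units.csv"))
  expect_equal(nrow(units), 3L)
  expect_equal(units$accuracy,
               vapply(res$per_unit, function(u) u$report$accuracy, 0))
  leaks <- read.csv(file.path(dir, "leakage.csv"))
  expect_equal(nrow(leaks), sum(lengths(res$leakage_audit)))
  doc <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(doc$case, "case3")
})
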