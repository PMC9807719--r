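#' Cross-validation fold plan
#'
#' Assigns every sample to exactly one of `k` folds; each fold serves once
#' as the test set (test fraction `1/k`). With `stratified = TRUE`
#' (default) the split preserves class composition: per class, fold sizes
#' differ by at most one, and the per-class remainders are dealt to the
#' folds with the smallest running totals so overall fold sizes are as
#' even as possible. With `groups` given (e.g. patient identifiers), whole
#' groups are kept in one fold (unstratified greedy balancing) for
#' leakage-free splits of clustered data.
#'
#' @param labels integer class labels `0..K-1`, one per sample.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given it.
#' @param stratified preserve class proportions per fold.
#' @param groups optional grouping factor; overrides `stratified`.
#' @return a `"fold_plan"`: list with `n_folds`, `assignment` (fold index
#'   per sample), `stratified`, `seed`.
#' @examples
#' plan <- make_folds(rep(0:2, c(708, 1426, 930)), k = 5, seed = 1)
#' table(plan$assignment)  # 613 613 613 613 612
#' @export
make_folds <- function(labels, k = 5L, seed = 42L, stratified = TRUE,
                       groups = NULL) {
  y <- as.integer(labels)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  assignment <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (!is.null(groups)) {
      g <- as.factor(groups)
      sizes <- table(g)
      ord <- sample(levels(g))                     # shuffle, then greedy
      ord <- ord[order(-sizes[ord])]
      totals <- numeric(k)
      for (lev in ord) {
        f <- which.min(totals)
        assignment[g == lev] <- f
        totals[f] <- totals[f] + sizes[[lev]]
      }
    } else if (stratified) {
      classes <- sort(unique(y))
      if (min(table(y)) < k)
        stop("stratified folds need at least k members per class")
      totals <- numeric(k)
      for (cl in classes) {
        idx <- sample(which(y == cl))
        n_c <- length(idx)
        sizes <- rep(n_c %/% k, k)
        r <- n_c %% k
        if (r > 0L) {
          extra <- order(totals, seq_len(k))[seq_len(r)]
          sizes[extra] <- sizes[extra] + 1L
        }
        fold_of <- rep(seq_len(k), times = sizes)
        assignment[idx] <- fold_of
        totals <- totals + sizes
      }
    } else {
      idx <- sample(n)
      sizes <- rep(n %/% k, k)
      sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      assignment[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  structure(list(n_folds = k, assignment = assignment,
                 stratified = stratified && is.null(groups),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Protocol configuration
#'
#' Settings for the three training protocols: `case1` is plain k-fold
#' cross-validation (fresh weights per fold); `case2` repeats the full
#' cross-validation for `n_iterations`, seeding every fold of an iteration
#' with the model carried from the previous iteration (`carry_fold`, the
#' last fold by default); `case3` carries the trained model from fold to
#' fold within a single pass (internal transfer learning), which leaks
#' earlier test folds into later training sets — quantified, never hidden,
#' by the leakage audit.
#'
#' @param case one of `"case1"`, `"case2"`, `"case3"`.
#' @param spec the `"cnn_spec"` to train.
#' @param train_config a [train_config()].
#' @param n_iterations case-2 iteration count.
#' @param carry_fold which fold's trained model seeds the next case-2
#'   iteration.
#' @param stability_source_fold default source fold for [stability_pass()].
#' @param val_fraction fraction of each fold's training portion held out
#'   (stratified) as the early-stopping validation set.
#' @param seed base seed from which per-(iteration, fold) build and
#'   shuffle seeds are derived.
#' @return a `"protocol_config"` list.
#' @export
protocol_config <- function(case = c("case1", "case2", "case3"), spec,
                            train_config = btcfcnn::train_config(),
                            n_iterations = 5L, carry_fold = NULL,
                            stability_source_fold = 4L, val_fraction = 0.1,
                            seed = 42L) {
  case <- match.arg(case)
  stopifnot(inherits(spec, "cnn_spec"), n_iterations >= 1,
            val_fraction > 0, val_fraction < 0.5)
  structure(list(case = case, spec = spec, train_config = train_config,
                 n_iterations = as.integer(n_iterations),
                 carry_fold = carry_fold,
                 stability_source_fold = as.integer(stability_source_fold),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "protocol_config")
}

# deterministic sub-seeds, kept well below 2^31
unit_seed <- function(base, iteration, fold, salt = 0L) {
  (abs(base) %% 1000003L + 7919L * iteration + 131L * fold + salt * 17L) %%
    2147483587L
}

subset_data <- function(data, idx) {
  list(x = data$x[, , , idx, drop = FALSE], y = data$y[idx])
}

# stratified holdout of a validation slice from the training indices
split_train_val <- function(train_idx, labels, fraction, seed) {
  y <- labels[train_idx]
  val <- withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      pool <- train_idx[y == cl]
      n_val <- max(1L, round(length(pool) * fraction))
      sample(pool, min(n_val, length(pool)))
    }), use.names = FALSE)
  })
  list(train = setdiff(train_idx, val), val = val)
}

# train one (iteration, fold) unit and evaluate on its test fold
fit_unit <- function(data, config, init_state, iteration, fold, train_idx,
                     test_idx, protocol) {
  tv <- split_train_val(train_idx, data$y, config$val_fraction,
                        unit_seed(config$seed, iteration, fold, salt = 3L))
  tc <- config$train_config
  tc$seed <- unit_seed(config$seed, iteration, fold, salt = 1L)
  fit <- train_model(init_state, subset_data(data, tv$train),
                     subset_data(data, tv$val), tc, protocol = protocol,
                     iteration = iteration, fold = fold, train_idx = tv$train)
  report <- evaluate_model(fit$state, subset_data(data, test_idx),
                           class_names = data$class_names)
  list(iteration = iteration, fold = fold, state = fit$state,
       report = report, history = fit$history,
       stopped_epoch = fit$stopped_epoch, best_epoch = fit$best_epoch,
       train_idx = sort(train_idx), test_idx = sort(test_idx))
}

finish_result <- function(case, units, plan, config, final_state, leakage) {
  structure(list(case = case, per_unit = units, summary = summarize(units),
                 final_state = final_state, leakage_audit = leakage,
                 plan = plan, config = config),
            class = "protocol_result")
}

#' Run the plain cross-validation protocol (case 1)
#'
#' Each fold trains a freshly initialized model on its training portion
#' (minus a stratified validation slice for early stopping) and is
#' evaluated on its disjoint test fold. The leakage audit is empty by
#' construction.
#'
#' @param data list with `x` (image array `(h, w, c, n)`), `y` (labels
#'   `0..K-1`) and optional `class_names`.
#' @param plan a [make_folds()] plan over `data$y`.
#' @param config a [protocol_config()].
#' @return a `"protocol_result"`: per-unit evaluation reports, a
#'   mean/sample-SD `summary` over folds, the `final_state`, and the
#'   `leakage_audit` (one integer vector of sample indices per unit).
#' @export
run_case1 <- function(data, plan, config) {
  check_protocol_inputs(data, plan)
  k <- plan$n_folds
  units <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    init <- build_model(config$spec, unit_seed(config$seed, 1L, f, salt = 5L))
    units[[f]] <- fit_unit(data, config, init, 1L, f, train_idx, test_idx,
                           "case1")
  }
  leakage <- rep(list(integer(0)), k)
  finish_result("case1", units, plan, config, units[[k]]$state, leakage)
}

#' Run the iterated transfer-learning protocol (case 2)
#'
#' Repeats the full k-fold cross-validation `n_iterations` times. In
#' iteration 1 every fold starts from fresh weights (so a single-iteration
#' run is behaviorally identical to [run_case1()] under the same seeds);
#' from iteration 2 onward every fold starts from a copy of the model
#' carried out of the previous iteration (`carry_fold`, last fold by
#' default). Because the carried model has already trained on data that
#' includes later test folds, the leakage audit lists, per unit, the test
#' samples already seen in the carried model's training lineage.
#'
#' @inheritParams run_case1
#' @return a `"protocol_result"` with one unit per (iteration, fold).
#' @export
run_case2 <- function(data, plan, config) {
  check_protocol_inputs(data, plan)
  k <- plan$n_folds
  carry_fold <- config$carry_fold %||% k
  stopifnot(carry_fold >= 1L, carry_fold <= k)
  units <- list()
  leakage <- list()
  carried <- NULL
  for (it in seq_len(config$n_iterations)) {
    iter_units <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(plan$assignment == f)
      train_idx <- which(plan$assignment != f)
      init <- if (it == 1L)
        build_model(config$spec, unit_seed(config$seed, it, f, salt = 5L))
      else carried
      seen <- seen_in_lineage(init)
      iter_units[[f]] <- fit_unit(data, config, init, it, f, train_idx,
                                  test_idx, "case2")
      leakage <- c(leakage, list(sort(intersect(test_idx, seen))))
    }
    carried <- iter_units[[carry_fold]]$state
    units <- c(units, iter_units)
  }
  finish_result("case2", units, plan, config, carried, leakage)
}

#' Run the fold-to-fold internal transfer-learning protocol (case 3)
#'
#' A single cross-validation pass in which fold 1 trains from scratch and
#' every later fold retrains the model carried from the previous fold.
#' This is the protocol's defining shortcut and also its methodological
#' hazard: the training set of fold `j` contains the test samples of all
#' earlier folds, so later per-fold scores are not leakage-free estimates.
#' The leakage audit records, for each fold `j`, exactly the union of
#' earlier test folds intersected with fold `j`'s training set.
#'
#' @inheritParams run_case1
#' @return a `"protocol_result"`; `final_state` is the model after the
#'   last fold.
#' @export
run_case3 <- function(data, plan, config) {
  check_protocol_inputs(data, plan)
  k <- plan$n_folds
  units <- vector("list", k)
  leakage <- vector("list", k)
  state <- build_model(config$spec, unit_seed(config$seed, 1L, 1L, salt = 5L))
  earlier_tests <- integer(0)
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    units[[f]] <- fit_unit(data, config, state, 1L, f, train_idx, test_idx,
                           "case3")
    state <- units[[f]]$state
    leakage[[f]] <- sort(intersect(earlier_tests, train_idx))
    earlier_tests <- c(earlier_tests, test_idx)
  }
  finish_result("case3", units, plan, config, state, leakage)
}

#' Post-hoc stability pass over a trained model
#'
#' Fine-tunes an independent copy of one trained model (typically the
#' case-3 model saved after a chosen fold) on each fold's training portion
#' and evaluates on that fold's test set, summarizing the spread. All
#' folds start from identical copies; nothing is carried between them.
#'
#' @param state a trained `"model_state"` with case-3 lineage.
#' @inheritParams run_case1
#' @return a `"protocol_result"` tagged `"stability"`.
#' @export
stability_pass <- function(state, data, plan, config) {
  stopifnot(inherits(state, "model_state"))
  if (!any(vapply(state$lineage, function(e) e$protocol == "case3", TRUE)))
    stop("stability_pass expects a model with case-3 training lineage")
  check_protocol_inputs(data, plan)
  k <- plan$n_folds
  units <- vector("list", k)
  seen <- seen_in_lineage(state)
  leakage <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    units[[f]] <- fit_unit(data, config, state, 2L, f, train_idx, test_idx,
                           "stability")
    leakage[[f]] <- sort(intersect(test_idx, seen))
  }
  finish_result("stability", units, plan, config, units[[k]]$state, leakage)
}

check_protocol_inputs <- function(data, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  n <- dim(data$x)[4L]
  if (is.null(n) || n != length(data$y) || n != length(plan$assignment))
    stop("data and fold plan disagree on the number of samples")
}

seen_in_lineage <- function(state) {
  sort(unique(unlist(lapply(state$lineage, `[[`, "train_idx"))))
}

#' Mean and sample standard deviation
#'
#' The summary convention used in every protocol table: arithmetic mean and
#' the n-1 (sample) standard deviation.
#'
#' @param x numeric vector with at least two values.
#' @return named numeric `c(mean, sd)`.
#' @examples
#' mean_sd(c(92.82, 93.64, 92.82, 92.66, 93.46))  # 93.08, 0.44
#' @export
mean_sd <- function(x) {
  if (length(x) < 2L) stop("sample SD needs at least two values")
  c(mean = mean(x), sd = sd(x))
}

#' Summarize per-unit evaluation reports
#'
#' Collects accuracy, loss and the macro metrics across the units of a
#' protocol run and reports their mean and sample SD.
#'
#' @param units list of per-unit records (each carrying an
#'   `"eval_report"`), or a `"protocol_result"`.
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
summarize <- function(units) {
  if (inherits(units, "protocol_result")) units <- units$per_unit
  if (length(units) < 2L) stop("summary needs at least two units")
  m <- do.call(rbind, lapply(units, function(u) {
    r <- u$report
    c(accuracy = r$accuracy, loss = r$loss, f1 = r$macro[["f1"]],
      precision = r$macro[["precision"]], recall = r$macro[["recall"]],
      specificity = r$macro[["specificity"]])
  }))
  data.frame(metric = colnames(m), mean = colMeans(m), sd = apply(m, 2L, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s | %d unit(s)\n", x$case,
              length(x$per_unit)))
  for (u in x$per_unit)
    cat(sprintf("  it %d fold %d: accuracy %.2f%%  loss %.4f  (epochs %d)\n",
                u$iteration, u$fold, u$report$accuracy, u$report$loss,
                u$stopped_epoch))
  cat("summary:\n")
  print(round_df(x$summary, 4L), row.names = FALSE)
  n_leak <- sum(lengths(x$leakage_audit))
  cat(sprintf("leakage audit: %d leaked sample-occurrence(s)\n", n_leak))
  invisible(x)
}

#' Write protocol-result artifacts
#'
#' Emits `units.csv` (per-unit metrics), `summary.json`, `leakage.csv`
#' (one row per leaked sample occurrence) into a directory.
#'
#' @param result a `"protocol_result"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol_result <- function(result, dir) {
  stopifnot(inherits(result, "protocol_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- do.call(rbind, lapply(seq_along(result$per_unit), function(i) {
    u <- result$per_unit[[i]]
    data.frame(iteration = u$iteration, fold = u$fold,
               accuracy = u$report$accuracy, loss = u$report$loss,
               f1 = u$report$macro[["f1"]],
               precision = u$report$macro[["precision"]],
               recall = u$report$macro[["recall"]],
               specificity = u$report$macro[["specificity"]],
               n_test = length(u$test_idx),
               stopped_epoch = u$stopped_epoch,
               n_leaked = length(result$leakage_audit[[i]]))
  }))
  write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(case = result$case,
                                   summary = result$summary),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "summary.json"))
  leaks <- do.call(rbind, lapply(seq_along(result$per_unit), function(i) {
    u <- result$per_unit[[i]]
    li <- result$leakage_audit[[i]]
    if (!length(li)) return(NULL)
    data.frame(iteration = u$iteration, fold = u$fold, sample_index = li)
  }))
  if (is.null(leaks))
    leaks <- data.frame(iteration = integer(0), fold = integer(0),
                        sample_index = integer(0))
  write.csv(leaks, file.path(dir, "leakage.csv"), row.names = FALSE)
  invisible(dir)
}
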