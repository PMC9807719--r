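# Trainable runtime: realization, activations, loss, gradients, training,
# prediction, checkpointing.

test_that("activation functions match their closed forms", {
  expect_equal(relu(c(-3, 0, 3)), c(0, 0, 3))
  expect_equal(sigmoid(0), 0.5)
  expect_equal(tanh_act(c(-1, 0, 2)), tanh(c(-1, 0, 2)))
  expect_equal(softmax_probs(rbind(c(0, 0, 0)))[1, ], rep(1 / 3, 3))
  p <- softmax_probs(matrix(rnorm(30), 10, 3))
  expect_equal(rowSums(p), rep(1, 10))
})

test_that("sparse cross-entropy matches the one-hot oracle and clamps zeros", {
  expect_equal(sparse_cce(0L, rbind(c(1, 0, 0))), 0)
  expect_equal(sparse_cce(1L, rbind(c(0.25, 0.5, 0.25))), -log(0.5))
  withr::with_seed(4, {
    p <- softmax_probs(matrix(rnorm(60), 20, 3))
    y <- sample(0:2, 20, replace = TRUE)
    onehot <- diag(3)[y + 1L, ]
    expect_equal(sparse_cce(y, p), mean(-rowSums(onehot * log(p))))
  })
  # zero probability at the true class: finite, epsilon-clamped
  expect_equal(sparse_cce(0L, rbind(c(0, 1, 0))), -log(1e-7))
  expect_error(sparse_cce(3L, rbind(c(1, 0, 0))), "out of range")
  expect_error(sparse_cce(0L, rbind(c(0.5, 0.1, 0.1))), "sum to 1")
})

test_that("realized parameter count equals the static audit", {
  for (spec in list(btc_fcnn_spec(), btc_fcnn_spec(input_size = 64L),
                    btc_fcnn_spec(FALSE, input_size = 64L), tiny_spec())) {
    st <- build_model(spec, seed = 11L)
    expect_identical(realized_params(st), audit(spec)$total_params)
    expect_length(st$lineage, 0L)
  }
  # degenerate: a single dense softmax head
  spec1 <- model_spec(c(2, 2, 1), list(flatten(), dense(3, "softmax")))
  expect_identical(realized_params(build_model(spec1, 1L)), 15L)
})

test_that("initialization is bit-deterministic in the seed", {
  s1 <- build_model(tiny_spec(), 123L)
  s2 <- build_model(tiny_spec(), 123L)
  expect_identical(s1$weights, s2$weights)
  s3 <- build_model(tiny_spec(), 124L)
  expect_false(identical(s1$weights, s3$weights))
})

test_that("backpropagated gradients match central finite differences", {
  spec <- tiny_spec()
  st <- build_model(spec, 7L)
  withr::with_seed(21, {
    x <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
    y <- c(0L, 1L, 2L, 0L)
    fw <- btcfcnn:::forward_pass(st, x, keep_cache = TRUE)
    gr <- btcfcnn:::backward_pass(st, fw$caches, fw$out, y)
    lossfn <- function(s) sparse_cce(y, t(btcfcnn:::forward_pass(s, x)$out))
    eps <- 1e-6
    for (li in seq_along(st$weights)) {
      if (is.null(st$weights[[li]])) next
      for (nm in c("W", "b")) {
        n_el <- length(st$weights[[li]][[nm]])
        for (j in sample(n_el, min(4L, n_el))) {
          sp <- st; sp$weights[[li]][[nm]][j] <- sp$weights[[li]][[nm]][j] + eps
          sm <- st; sm$weights[[li]][[nm]][j] <- sm$weights[[li]][[nm]][j] - eps
          num <- (lossfn(sp) - lossfn(sm)) / (2 * eps)
          expect_equal(gr[[li]][[nm]][j], num, tolerance = 1e-5)
        }
      }
    }
  })
})

test_that("training drives a separable problem to perfect training accuracy", {
  d <- tiny_separable_data(60L)
  tr <- list(x = d$x[, , , 1:45, drop = FALSE], y = d$y[1:45])
  va <- list(x = d$x[, , , 46:60, drop = FALSE], y = d$y[46:60])
  fit <- train_model(build_model(tiny_spec(), 3L), tr, va,
                     train_config(max_epochs = 40L, batch_size = 10L,
                                  early_stopping_patience = 40L, seed = 5L))
  expect_equal(tail(fit$history$acc, 1), 1)
  expect_length(fit$state$lineage, 1L)
  expect_equal(nrow(fit$history), fit$stopped_epoch)
})

test_that("training is bit-reproducible and honors the early-stopping contract", {
  d <- tiny_separable_data(30L)
  tr <- list(x = d$x[, , , 1:24, drop = FALSE], y = d$y[1:24])
  va <- list(x = d$x[, , , 25:30, drop = FALSE], y = d$y[25:30])
  cfg <- train_config(max_epochs = 6L, batch_size = 8L,
                      early_stopping_patience = 0L, seed = 9L)
  f1 <- train_model(build_model(tiny_spec(), 2L), tr, va, cfg)
  f2 <- train_model(build_model(tiny_spec(), 2L), tr, va, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$state$weights, f2$state$weights)
  # monitored quantity: best epoch minimizes validation loss, and with
  # patience p training never continues more than p+1 epochs past it
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
  expect_lte(f1$stopped_epoch, f1$best_epoch + 1L)
  # restored weights reproduce the best epoch's validation loss
  ev <- evaluate_model(f1$state, va)
  expect_equal(ev$loss, min(f1$history$val_loss), tolerance = 1e-12)
})

test_that("training rejects degenerate inputs", {
  d <- tiny_separable_data(12L)
  empty <- list(x = d$x[, , , 0, drop = FALSE], y = integer(0))
  full <- list(x = d$x, y = d$y)
  st <- build_model(tiny_spec(), 1L)
  expect_error(train_model(st, empty, full, train_config()), "empty")
  expect_error(train_model(st, full, empty, train_config()), "empty")
})

test_that("prediction yields normalized rows, argmax labels, shape errors", {
  st <- build_model(tiny_spec(), 31L)
  withr::with_seed(8, x <- array(runif(8 * 8 * 50), c(8, 8, 1, 50)))
  pr <- predict(st, x)
  expect_equal(rowSums(pr$probs), rep(1, 50), tolerance = 1e-6)
  expect_identical(pr$labels, argmax_labels(pr$probs))
  # untrained net on random inputs: mean class probability near uniform
  expect_equal(unname(colMeans(pr$probs)), rep(1 / 3, 3), tolerance = 0.15)
  # argmax tie-break goes to the lowest class index
  expect_identical(argmax_labels(rbind(c(0.4, 0.4, 0.2), c(0.2, 0.4, 0.4))),
                   c(0L, 1L))
  expect_error(predict(st, array(0, c(9, 9, 1, 2))), "\\(8, 8, 1\\)")
})

test_that("full-batch evaluation is invariant to sample order", {
  d <- tiny_separable_data(30L)
  st <- build_model(tiny_spec(), 5L)
  perm <- rev(seq_len(30))
  e1 <- evaluate_model(st, list(x = d$x, y = d$y))
  e2 <- evaluate_model(st, list(x = d$x[, , , perm, drop = FALSE],
                                y = d$y[perm]))
  expect_equal(e1$loss, e2$loss, tolerance = 1e-12)
  expect_equal(e1$accuracy, e2$accuracy)
})

test_that("checkpoints round-trip weights, lineage and predictions", {
  d <- tiny_separable_data(30L)
  tr <- list(x = d$x[, , , 1:24, drop = FALSE], y = d$y[1:24])
  va <- list(x = d$x[, , , 25:30, drop = FALSE], y = d$y[25:30])
  fit <- train_model(build_model(tiny_spec(), 2L), tr, va,
                     train_config(max_epochs = 2L, batch_size = 8L, seed = 1L),
                     protocol = "case1", fold = 2L, train_idx = 1:24)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_state(fit$state, path)
  back <- load_state(path)
  expect_identical(back$weights, fit$state$weights)
  expect_identical(back$lineage, fit$state$lineage)
  expect_identical(predict(back, va$x)$probs, predict(fit$state, va$x)$probs)
  # tampered sidecar: spec hash mismatch must refuse to load
  sidecar <- paste0(path, ".json")
  doc <- jsonlite::fromJSON(sidecar, simplifyDataFrame = FALSE)
  doc$spec_hash <- "deadbeef"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), sidecar)
  expect_error(load_state(path), "hash")
  expect_error(load_state(tempfile()), "not found")
})
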