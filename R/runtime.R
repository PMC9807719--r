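#' Training configuration
#'
#' Hyper-parameters for [train_model()]. The defaults are the reference
#' training recipe: Adam with initial learning rate 0.01, at most 10
#' epochs, mini-batches of 25, sparse categorical cross-entropy, and early
#' stopping on validation loss with patience 2 (best-epoch weights
#' restored).
#'
#' @param learning_rate positive step size for Adam.
#' @param max_epochs maximum number of training epochs.
#' @param batch_size mini-batch size.
#' @param optimizer optimizer name; only `"adam"` is implemented.
#' @param early_stopping_patience epochs without validation-loss improvement
#'   tolerated before stopping; the monitored quantity is always validation
#'   loss.
#' @param seed integer seed driving epoch shuffling (and, through
#'   [build_model()], weight initialization when the same seed is reused).
#' @return a `"train_config"` list.
#' @export
train_config <- function(learning_rate = 0.01, max_epochs = 10L,
                         batch_size = 25L, optimizer = "adam",
                         early_stopping_patience = 2L, seed = 42L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            early_stopping_patience >= 0)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 monitor = "val_loss", seed = as.integer(seed)),
            class = "train_config")
}

#' Materialize a model from its specification
#'
#' Allocates and seeds the weight tensors of every parameterized layer.
#' Weights are Glorot-uniform (limit `sqrt(6 / (fan_in + fan_out))`),
#' biases start at zero; the draw order is fixed so the same
#' specification and seed always yield bit-identical weights. The realized
#' parameter count is checked against the static [audit()] of the same
#' specification.
#'
#' @param spec a `"cnn_spec"`.
#' @param seed integer RNG seed for the initialization.
#' @return a `"model_state"`: list with `spec`, per-layer `weights`
#'   (`NULL` for pooling/flatten), an empty training `lineage`, and
#'   `rng_seed`.
#' @export
build_model <- function(spec, seed = 42L) {
  stopifnot(inherits(spec, "cnn_spec"))
  shapes <- shape_chain(spec)
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  }
  weights <- withr::with_seed(as.integer(seed), {
    lapply(seq_along(spec$layers), function(i) {
      l <- spec$layers[[i]]
      s_in <- shapes[[i]]
      if (l$kind == "conv2d") {
        if (l$padding != 0L)
          stop("runtime supports valid (zero) padding only; layer ", i)
        dm <- c(l$kernel_h, l$kernel_w, s_in[3L], l$n_filters)
        list(W = array(glorot(prod(dm), prod(dm[1:3]),
                              l$kernel_h * l$kernel_w * l$n_filters), dm),
             b = numeric(l$n_filters))
      } else if (l$kind == "dense") {
        list(W = matrix(glorot(l$n_units * s_in[1L], s_in[1L], l$n_units),
                        nrow = l$n_units, ncol = s_in[1L]),
             b = numeric(l$n_units))
      } else NULL
    })
  })
  state <- structure(list(spec = spec, weights = weights, lineage = list(),
                          rng_seed = as.integer(seed)),
                     class = "model_state")
  stopifnot(realized_params(state) == audit(spec)$total_params)
  state
}

#' Number of realized trainable parameters
#' @param state a `"model_state"`.
#' @return integer count of weight and bias scalars actually allocated.
#' @export
realized_params <- function(state) {
  sum(vapply(state$weights, function(w)
    if (is.null(w)) 0L else length(w$W) + length(w$b), 0L))
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> %s | %s parameters | %d lineage event(s)\n",
              x$spec$name, format(realized_params(x), big.mark = ","),
              length(x$lineage)))
  for (ev in x$lineage)
    cat(sprintf("  %s it %s fold %s (%d epochs, n=%d)\n", ev$protocol,
                ev$iteration, ev$fold, ev$epochs, ev$n_train))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

as_batch <- function(x, spec) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop(sprintf("images must be an array (h, w, c[, n]); expected input (%s)",
                 paste(spec$input_shape, collapse = ", ")))
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (!all(d[1:3] == spec$input_shape))
    stop(sprintf("image shape (%s) does not match spec input (%s)",
                 paste(d[1:3], collapse = ", "),
                 paste(spec$input_shape, collapse = ", ")))
  x
}

forward_pass <- function(state, x, keep_cache = FALSE) {
  layers <- state$spec$layers
  shapes <- shape_chain(state$spec)
  a <- x
  caches <- if (keep_cache) vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "conv2d") {
      wt <- state$weights[[i]]
      z <- .conv2d_forward(a, wt$W, wt$b, l$stride)
      if (l$activation == "softmax")
        stop("softmax is supported only on the final dense layer")
      out <- apply_act(l$activation, z)
      if (keep_cache) caches[[i]] <- list(a_prev = a, z = z, a = out)
    } else if (l$kind == "avgpool2d") {
      if (keep_cache) caches[[i]] <- list(in_dim = dim(a))
      out <- .avgpool_forward(a, l$kernel_h, l$kernel_w, l$stride)
    } else if (l$kind == "flatten") {
      if (keep_cache) caches[[i]] <- list(in_dim = dim(a))
      out <- a
      dim(out) <- c(prod(dim(a)[1:3]), dim(a)[4L])
    } else { # dense
      wt <- state$weights[[i]]
      z <- wt$W %*% a + wt$b
      out <- if (l$activation == "softmax") {
        if (i != length(layers))
          stop("softmax is supported only on the final dense layer")
        col_softmax(z)
      } else apply_act(l$activation, z)
      if (keep_cache) caches[[i]] <- list(a_prev = a, z = z, a = out)
    }
    a <- out
  }
  list(out = a, caches = caches)
}

# Gradients of mean sparse cross-entropy wrt every weight tensor.
# probs: (K x n) output of forward_pass with softmax head; y: 0-based labels.
backward_pass <- function(state, caches, probs, y) {
  layers <- state$spec$layers
  n <- ncol(probs)
  grads <- vector("list", length(layers))
  # combined softmax + cross-entropy gradient at the head
  d <- probs
  d[cbind(y + 1L, seq_len(n))] <- d[cbind(y + 1L, seq_len(n))] - 1
  d <- d / n
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    ch <- caches[[i]]
    if (l$kind == "dense") {
      dz <- if (l$activation == "softmax") d else d * act_grad(l$activation, ch$z, ch$a)
      grads[[i]] <- list(W = dz %*% t(ch$a_prev), b = rowSums(dz))
      d <- t(state$weights[[i]]$W) %*% dz
    } else if (l$kind == "flatten") {
      dim(d) <- ch$in_dim
    } else if (l$kind == "avgpool2d") {
      d <- .avgpool_backward(d, ch$in_dim[1L], ch$in_dim[2L],
                             l$kernel_h, l$kernel_w, l$stride)
    } else { # conv2d
      dz <- d * act_grad(l$activation, ch$z, ch$a)
      bk <- .conv2d_backward(ch$a_prev, state$weights[[i]]$W, dz, l$stride)
      grads[[i]] <- list(W = bk$dw, b = bk$db)
      d <- bk$dx
    }
  }
  grads
}

adam_init <- function(weights) {
  lapply(weights, function(w) {
    if (is.null(w)) return(NULL)
    list(mW = array(0, dim = dim(w$W) %||% length(w$W)), vW = array(0, dim = dim(w$W) %||% length(w$W)),
         mb = numeric(length(w$b)), vb = numeric(length(w$b)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(weights, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(weights)) {
    if (is.null(weights[[i]])) next
    g <- grads[[i]]
    o <- opt[[i]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$W
    o$vW <- beta2 * o$vW + (1 - beta2) * g$W * g$W
    weights[[i]]$W <- weights[[i]]$W - lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
    o$mb <- beta1 * o$mb + (1 - beta1) * g$b
    o$vb <- beta2 * o$vb + (1 - beta2) * g$b * g$b
    weights[[i]]$b <- weights[[i]]$b - lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
    opt[[i]] <- o
  }
  list(weights = weights, opt = opt)
}

# ---- prediction / evaluation ----------------------------------------------

#' Predict class probabilities and labels
#'
#' Runs the forward pass in evaluation mode, in memory-bounded chunks.
#' Labels are the argmax of the probability row, ties broken toward the
#' lowest class index.
#'
#' @param object a `"model_state"`.
#' @param newdata image array `(h, w, c, n)` (or a single `(h, w, c)`
#'   image) matching the spec input shape.
#' @param chunk_size images per forward chunk.
#' @param ... unused.
#' @return list with `probs` (n x K matrix, rows sum to 1) and `labels`
#'   (integer vector, classes `0..K-1`).
#' @export
predict.model_state <- function(object, newdata, chunk_size = 64L, ...) {
  x <- as_batch(newdata, object$spec)
  n <- dim(x)[4L]
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  probs <- do.call(rbind, lapply(idx, function(ii) {
    t(forward_pass(object, x[, , , ii, drop = FALSE])$out)
  }))
  rownames(probs) <- NULL
  list(probs = probs, labels = argmax_labels(probs))
}

#' Argmax labels from a probability matrix
#' @param probs n x K matrix.
#' @return integer labels `0..K-1`; ties resolved to the lowest index.
#' @export
argmax_labels <- function(probs) {
  max.col(as.matrix(probs), ties.method = "first") - 1L
}

#' Evaluate a model on a labelled set
#'
#' @param state a `"model_state"`.
#' @param data list with `x` (image array) and `y` (integer labels
#'   `0..K-1`).
#' @param class_names optional class names for the confusion matrix.
#' @return an `"eval_report"` (see [eval_report()]) carrying the mean
#'   sparse cross-entropy in `$loss`.
#' @export
evaluate_model <- function(state, data, class_names = NULL) {
  pr <- predict(state, data$x)
  k <- ncol(pr$probs)
  cm <- confusion_matrix(data$y, pr$labels, k, class_names)
  eval_report(cm, loss = sparse_cce(data$y, pr$probs))
}

# ---- training --------------------------------------------------------------

#' Train a model
#'
#' Mini-batch gradient training with Adam and sparse categorical
#' cross-entropy. After every epoch the validation loss is computed
#' full-batch; training stops early once it has failed to improve for more
#' than `early_stopping_patience` consecutive epochs, and the weights of
#' the best epoch are restored. Each call appends one event to the model's
#' training lineage. With a fixed `config$seed` (and fixed incoming
#' weights) the run is bit-reproducible in this single-threaded runtime.
#'
#' @param state a `"model_state"` (fresh from [build_model()] or carried
#'   over from a previous training event for transfer learning).
#' @param train_set,val_set lists with `x` (image array `(h, w, c, n)`
#'   scaled to `[0, 1]`) and `y` (integer labels `0..K-1`); both non-empty.
#' @param config a [train_config()].
#' @param protocol,iteration,fold,train_idx provenance recorded in the
#'   lineage event (which training protocol produced this event, and the
#'   indices of the training samples within the parent dataset).
#' @return a `"train_result"`: list with the updated `state`, a `history`
#'   data.frame (epoch, loss, acc, val_loss, val_acc), `stopped_epoch` and
#'   `best_epoch`.
#' @export
train_model <- function(state, train_set, val_set, config = train_config(),
                        protocol = "adhoc", iteration = 1L, fold = NA_integer_,
                        train_idx = NULL) {
  stopifnot(inherits(state, "model_state"), inherits(config, "train_config"))
  xt <- as_batch(train_set$x, state$spec); yt <- as.integer(train_set$y)
  xv <- as_batch(val_set$x, state$spec);   yv <- as.integer(val_set$y)
  n <- dim(xt)[4L]
  if (n == 0L || length(yt) != n) stop("empty or inconsistent training set")
  if (dim(xv)[4L] == 0L) stop("empty validation set")

  weights <- state$weights
  opt <- adam_init(weights)
  step <- 0L
  hist <- list()
  best <- Inf; best_epoch <- 0L; best_weights <- weights; wait <- 0L
  stopped <- 0L

  eval_set <- function(w, x, y) {
    st <- state; st$weights <- w
    pr <- predict(st, x)
    list(loss = sparse_cce(y, pr$probs), acc = mean(pr$labels == y))
  }

  for (epoch in seq_len(config$max_epochs)) {
    shuffle_seed <- as.integer((as.numeric(config$seed) + 104729 * epoch) %%
                                 2147483587)
    ord <- withr::with_seed(shuffle_seed, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      st <- state; st$weights <- weights
      fw <- forward_pass(st, xt[, , , b, drop = FALSE], keep_cache = TRUE)
      probs <- fw$out                         # K x |b|
      yb <- yt[b]
      bl <- sparse_cce(yb, t(probs))
      if (!is.finite(bl))
        stop(sprintf("non-finite training loss at epoch %d; aborting", epoch))
      ep_loss <- ep_loss + bl * length(b)
      ep_correct <- ep_correct + sum(argmax_labels(t(probs)) == yb)
      grads <- backward_pass(st, fw$caches, probs, yb)
      step <- step + 1L
      upd <- adam_step(weights, grads, opt, config$learning_rate, step)
      weights <- upd$weights; opt <- upd$opt
    }
    vl <- eval_set(weights, xv, yv)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / n,
                                acc = ep_correct / n, val_loss = vl$loss,
                                val_acc = vl$acc)
    stopped <- epoch
    if (vl$loss < best) {
      best <- vl$loss; best_epoch <- epoch; best_weights <- weights; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$early_stopping_patience) break
    }
  }

  state$weights <- best_weights
  state$lineage <- c(state$lineage, list(list(
    protocol = protocol, iteration = as.integer(iteration),
    fold = as.integer(fold), epochs = stopped, best_epoch = best_epoch,
    n_train = n, train_idx = as.integer(train_idx %||% integer(0)),
    seed = config$seed)))
  structure(list(state = state, history = do.call(rbind, hist),
                 stopped_epoch = stopped, best_epoch = best_epoch),
            class = "train_result")
}

# ---- checkpointing ---------------------------------------------------------

#' Save and restore a trained model
#'
#' `save_state` writes the weight tensors (RDS archive) plus a JSON sidecar
#' (`<path>.json`) recording the architecture, the training lineage, the
#' seed, and a hash of the specification. `load_state` restores the state,
#' verifies the sidecar hash against the restored specification, and checks
#' that the realized weights are consistent with the static audit.
#'
#' @param state a `"model_state"`.
#' @param path checkpoint file path.
#' @return `save_state`: `path` invisibly; `load_state`: a
#'   `"model_state"`.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(state, path)
  sidecar <- list(spec = jsonlite::fromJSON(spec_to_json(state$spec),
                                            simplifyDataFrame = FALSE),
                  spec_hash = rlang::hash(spec_to_json(state$spec)),
                  n_params = realized_params(state),
                  rng_seed = state$rng_seed,
                  lineage = state$lineage)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  state <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupt checkpoint: ", path))
  if (!inherits(state, "model_state")) stop("not a model_state checkpoint: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("missing checkpoint sidecar: ", sidecar_path)
  sidecar <- jsonlite::fromJSON(sidecar_path, simplifyDataFrame = FALSE)
  if (!identical(sidecar$spec_hash, rlang::hash(spec_to_json(state$spec))))
    stop("checkpoint sidecar spec hash does not match the stored model")
  if (realized_params(state) != audit(state$spec)$total_params)
    stop("checkpoint weights inconsistent with the architecture audit")
  state
}
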