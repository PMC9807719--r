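# Shared fixtures: tiny architectures and datasets built in code at test time.

# minimal conv net that exercises every layer kind
tiny_spec <- function(input = c(8L, 8L, 1L)) {
  model_spec(input, list(conv2d(2L, 3L), avg_pool2d(2L), flatten(),
                         dense(4L, "relu"), dense(3L, "softmax")),
             name = "tiny")
}

# three visually trivial classes: a bright square in one of three corners
tiny_separable_data <- function(n = 60L, size = 8L, seed = 1L) {
  withr::with_seed(seed, {
    x <- array(0, c(size, size, 1L, n))
    y <- integer(n)
    for (i in seq_len(n)) {
      cls <- (i - 1L) %% 3L
      m <- matrix(0.1, size, size)
      if (cls == 0L) m[2:4, 2:4] <- 1
      else if (cls == 1L) m[5:7, 5:7] <- 1
      else m[2:4, 5:7] <- 1
      x[, , 1L, i] <- m + matrix(rnorm(size^2, 0, 0.02), size, size)
      y[i] <- cls
    }
    list(x = x, y = y)
  })
}

# random valid sequential specs for property tests
random_spec <- function(seed) {
  withr::with_seed(seed, {
    size <- sample(12:24, 1L)
    layers <- list()
    ch <- 1L
    for (i in seq_len(sample(1:3, 1L))) {
      nf <- sample(2:8, 1L)
      layers <- c(layers, list(conv2d(nf, sample(1:3, 1L))))
      ch <- nf
      if (runif(1) < 0.5) layers <- c(layers, list(avg_pool2d(2L)))
    }
    layers <- c(layers, list(flatten(), dense(sample(2:6, 1L), "relu"),
                             dense(3L, "softmax")))
    model_spec(c(size, size, 1L), layers, name = sprintf("rand%d", seed))
  })
}

# brute-force per-sample metric oracle, independent of the package path
oracle_metrics <- function(truth, pred, k) {
  per <- lapply(seq_len(k) - 1L, function(c0) {
    tp <- sum(truth == c0 & pred == c0)
    fp <- sum(truth != c0 & pred == c0)
    fn <- sum(truth == c0 & pred != c0)
    tn <- sum(truth != c0 & pred != c0)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    100 * c(precision = prec, recall = rec, f1 = f1, specificity = spec)
  })
  m <- do.call(rbind, per)
  list(per_class = m, macro = colMeans(m),
       accuracy = 100 * mean(truth == pred))
}

# rule-based phantom classifier: brightness and position of the lesion,
# thresholds taken from the generator's stated priors (bright discs at 0.95
# vs textured blobs <= 0.75; pituitary-like lesions 0.18*s from the center,
# meningioma-like ones >= 0.28*s)
centroid_classifier <- function(ds) {
  s <- dim(ds$x)[1L]
  c0 <- (s + 1) / 2
  vapply(seq_along(ds$y), function(i) {
    img <- ds$x[, , 1L, i]
    top <- order(img, decreasing = TRUE)[1:20]
    if (mean(img[top]) < 0.85) return(1L)       # dull textured blob: glioma-like
    ctr <- colMeans(arrayInd(top, c(s, s)))
    d <- sqrt(sum((ctr - c0)^2))
    if (d < 0.23 * s) 2L else 0L                # central: pituitary-like
  }, 0L)
}
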