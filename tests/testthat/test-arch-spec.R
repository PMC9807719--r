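# Shape inference, parameter counting and MAC cost accounting.

# reference configuration of the canonical 256x256 network:
# kind, filters, out_h, out_w, out_c (NA after flatten), out_len, params
canonical_table <- data.frame(
  kind = c("conv2d", "conv2d", "avgpool2d", "conv2d", "conv2d", "conv2d",
           "avgpool2d", "conv2d", "conv2d", "conv2d", "avgpool2d", "flatten",
           "dense", "dense"),
  out_h = c(254, 254, 127, 127, 125, 125, 62, 62, 60, 60, 30, NA, NA, NA),
  out_w = c(254, 254, 127, 127, 125, 125, 62, 62, 60, 60, 30, NA, NA, NA),
  out_c = c(32, 10, 10, 10, 32, 10, 10, 10, 32, 10, 10, NA, NA, NA),
  out_len = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 9000, 64, 3),
  n_params = c(320, 330, 0, 110, 2912, 330, 0, 110, 2912, 330, 0, 0,
               576064, 195))

test_that("canonical architecture reproduces the published shape and parameter table", {
  a <- audit(btc_fcnn_spec())
  pl <- a$per_layer
  expect_equal(nrow(pl), 14L)
  expect_equal(pl$kind, canonical_table$kind)
  r3 <- !is.na(canonical_table$out_h)
  expect_equal(pl$out_h[r3], canonical_table$out_h[r3])
  expect_equal(pl$out_w[r3], canonical_table$out_w[r3])
  expect_equal(pl$out_c[r3], canonical_table$out_c[r3])
  expect_equal(pl$out_len[!r3], canonical_table$out_len[!r3])
  expect_equal(pl$n_params, canonical_table$n_params)
  expect_identical(a$total_params, 583613L)
  expect_identical(a$depth, 13L)
})

test_that("ablation variant removes every 1x1 convolution and stays self-consistent", {
  spec <- btc_fcnn_spec(include_bottlenecks = FALSE)
  k1 <- vapply(spec$layers, function(l)
    l$kind == "conv2d" && l$kernel_h == 1L && l$kernel_w == 1L, TRUE)
  expect_false(any(k1))
  a <- audit(spec)
  # same inference rules as the full network: totals re-derive per layer
  shapes <- list(spec$input_shape)
  manual <- 0
  for (i in seq_along(spec$layers)) {
    manual <- manual + count_parameters(spec$layers[[i]], shapes[[i]])
    shapes[[i + 1L]] <- infer_output_shape(spec$layers[[i]], shapes[[i]])
  }
  expect_equal(a$total_params, manual)
  expect_gt(a$total_mac, audit(btc_fcnn_spec())$total_mac)
})

test_that("shape inference follows valid-padding arithmetic", {
  expect_equal(infer_output_shape(conv2d(32, 3), c(256, 256, 1)),
               c(254, 254, 32))
  expect_equal(infer_output_shape(avg_pool2d(2), c(254, 254, 10)),
               c(127, 127, 10))
  # 1x1 convolution preserves spatial dims for arbitrary inputs
  for (s in list(c(5, 9, 2), c(64, 64, 1), c(17, 3, 7)))
    expect_equal(infer_output_shape(conv2d(4, 1), s), c(s[1:2], 4))
  expect_error(infer_output_shape(conv2d(4, 9), c(5, 5, 1), layer_index = 3L),
               "layer 3")
  expect_error(model_spec(c(4, 4, 1), list(conv2d(2, 3), conv2d(2, 3))),
               "non-positive")
})

test_that("model validation rejects malformed stacks", {
  expect_error(model_spec(c(8, 8, 1), list(dense(3))), "after the flatten")
  expect_error(model_spec(c(8, 8, 1), list(flatten(), flatten(), dense(3))),
               "at most one flatten")
  expect_error(model_spec(c(0, 8, 1), list(flatten())), "positive")
})

test_that("parameter counts include biases", {
  expect_equal(count_parameters(conv2d(32, 3), c(256, 256, 1)), 320L)
  expect_equal(count_parameters(dense(64), c(9000L)), 576064L)
  expect_equal(count_parameters(conv2d(1, 1), c(1, 1, 1)), 2L)
  expect_equal(count_parameters(avg_pool2d(2), c(8, 8, 3)), 0L)
})

test_that("MAC cost counts multiplications of the convolution sweep", {
  expect_equal(layer_cost(conv2d(32, 3), c(256, 256, 32)), 594579456)
  expect_equal(layer_cost(conv2d(1, 1), c(1, 1, 1)), 1)
  # published pair cost: the 10-filter bottleneck costed on the 254x254
  # grid, then the 3x3 spatial convolution over its 10 channels
  pair <- layer_cost(conv2d(10, 1), c(254, 254, 32)) +
    layer_cost(conv2d(32, 3), c(256, 256, 10))
  expect_equal(pair, 206451200)
  expect_equal(layer_cost(avg_pool2d(2), c(8, 8, 4)), 0)
  expect_equal(layer_cost(dense(3), c(10L)), 30)
})

test_that("audit totals equal brute-force per-layer summation on random specs", {
  for (seed in 1:12) {
    spec <- random_spec(seed)
    a <- audit(spec)
    shapes <- list(spec$input_shape)
    p <- 0; m <- 0
    for (i in seq_along(spec$layers)) {
      p <- p + count_parameters(spec$layers[[i]], shapes[[i]])
      m <- m + layer_cost(spec$layers[[i]], shapes[[i]])
      shapes[[i + 1L]] <- infer_output_shape(spec$layers[[i]], shapes[[i]])
    }
    expect_equal(a$total_params, p)
    expect_equal(a$total_mac, m)
    expect_equal(a$depth, sum(a$per_layer$kind != "flatten"))
  }
})

test_that("a 1x1 bottleneck below the break-even width never increases pair cost", {
  # pair cost <= plain cost iff k <= f^2 * c * nf / (c + f^2 * nf)
  withr::with_seed(99, {
    for (rep in 1:25) {
      c_in <- sample(4:64, 1)
      nf <- sample(4:64, 1)
      h <- sample(16:64, 1)
      f <- 3L
      kmax <- floor(f^2 * c_in * nf / (c_in + f^2 * nf))
      k <- sample(seq_len(max(1L, kmax)), 1)
      plain <- layer_cost(conv2d(nf, f), c(h, h, c_in))
      pair <- layer_cost(conv2d(k, 1), c(h, h, c_in)) +
        layer_cost(conv2d(nf, f), c(h, h, k))
      expect_lte(pair, plain)
    }
  })
})

test_that("spec JSON round trip preserves structure and audit", {
  spec <- btc_fcnn_spec(input_size = 64L)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  back <- spec_from_json(path)
  expect_equal(back$layers, spec$layers)
  expect_equal(back$input_shape, spec$input_shape)
  expect_equal(audit(back)$total_params, audit(spec)$total_params)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name": "x"}', bad)
  expect_error(spec_from_json(bad), "missing input_shape")
})

test_that("audit CSV carries per-layer rows plus a totals row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_audit_csv(audit(btc_fcnn_spec()), path)
  df <- read.csv(path)
  expect_equal(nrow(df), 15L)
  expect_equal(df$n_params[15L], 583613L)
  expect_equal(df$kind[15L], "total")
})
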