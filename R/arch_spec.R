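#' @useDynLib btcfcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd
#' @importFrom utils read.csv write.csv head
NULL

#' Layer specifications
#'
#' Constructors for the four layer kinds understood by the sequential CNN
#' engine: 2-D convolution, 2-D average pooling, flatten, and dense (fully
#' connected). A layer specification is purely declarative; shapes,
#' parameter counts and multiply-accumulate (MAC) costs are derived from it
#' by [infer_output_shape()], [count_parameters()], [layer_cost()] and
#' [audit()], and weights are only materialised by [build_model()].
#'
#' Convolutions and poolings use "valid" spatial arithmetic: the output
#' extent along an axis of size `n` is `floor((n - kernel + 2*padding) /
#' stride) + 1`. Pooling stride defaults to the pooling kernel
#' (non-overlapping windows). Convolution layers carry one bias per filter;
#' dense layers one bias per unit.
#'
#' @param n_filters number of convolution filters (output channels).
#' @param kernel kernel size in pixels; a scalar or `c(height, width)`.
#' @param stride stride in pixels (scalar, both axes).
#' @param padding zero-padding in pixels added to each side.
#' @param activation one of `"relu"`, `"sigmoid"`, `"tanh"`, `"softmax"`,
#'   `"linear"`.
#' @param n_units number of dense-layer output units.
#' @return an object of class `"cnn_layer"`.
#' @examples
#' conv2d(32, 3)                     # 3x3 convolution, 32 filters, ReLU
#' conv2d(10, 1)                     # 1x1 bottleneck
#' avg_pool2d(2)                     # 2x2 average pooling, stride 2
#' dense(3, activation = "softmax")  # classification head
#' @name layer_spec
NULL

.activations <- c("relu", "sigmoid", "tanh", "softmax", "linear")

#' @rdname layer_spec
#' @export
conv2d <- function(n_filters, kernel, stride = 1L, padding = 0L,
                   activation = "relu") {
  stride <- stride[1L]
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stopifnot(n_filters >= 1, all(kernel >= 1), stride >= 1, padding >= 0)
  activation <- match.arg(activation, .activations)
  structure(list(kind = "conv2d", kernel_h = kernel[1L], kernel_w = kernel[2L],
                 n_filters = as.integer(n_filters), stride = as.integer(stride),
                 padding = as.integer(padding), activation = activation),
            class = "cnn_layer")
}

#' @rdname layer_spec
#' @export
avg_pool2d <- function(kernel = 2L, stride = kernel, padding = 0L) {
  stride <- stride[1L]
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stopifnot(all(kernel >= 1), stride >= 1, padding >= 0)
  structure(list(kind = "avgpool2d", kernel_h = kernel[1L],
                 kernel_w = kernel[2L], stride = as.integer(stride),
                 padding = as.integer(padding)),
            class = "cnn_layer")
}

#' @rdname layer_spec
#' @export
flatten <- function() {
  structure(list(kind = "flatten"), class = "cnn_layer")
}

#' @rdname layer_spec
#' @export
dense <- function(n_units, activation = "linear") {
  stopifnot(n_units >= 1)
  activation <- match.arg(activation, .activations)
  structure(list(kind = "dense", n_units = as.integer(n_units),
                 activation = activation),
            class = "cnn_layer")
}

#' @export
print.cnn_layer <- function(x, ...) {
  cat(format_layer(x), "\n")
  invisible(x)
}

format_layer <- function(l) {
  switch(l$kind,
    conv2d = sprintf("conv2d %dx%d, %d filters, stride %d, pad %d, %s",
                     l$kernel_h, l$kernel_w, l$n_filters, l$stride, l$padding,
                     l$activation),
    avgpool2d = sprintf("avg_pool2d %dx%d, stride %d", l$kernel_h, l$kernel_w,
                        l$stride),
    flatten = "flatten",
    dense = sprintf("dense %d, %s", l$n_units, l$activation))
}

#' Sequential model specification
#'
#' Bundles an input shape with an ordered list of layer specifications and
#' validates that shape inference succeeds through every layer (no
#' non-positive spatial extent), that at most one flatten layer occurs, and
#' that dense layers only follow the flatten.
#'
#' @param input_shape integer `c(height, width, channels)` of the input.
#' @param layers list of [conv2d()] / [avg_pool2d()] / [flatten()] /
#'   [dense()] specifications, in forward order.
#' @param name model name used in reports.
#' @return an object of class `"cnn_spec"`.
#' @seealso [btc_fcnn_spec()] for the canonical architecture, [audit()] for
#'   the derived shape/parameter/cost table.
#' @export
model_spec <- function(input_shape, layers, name = "cnn") {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("input_shape must be a positive (height, width, channels) triple")
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "cnn_layer")))
    stop("layers must be a non-empty list of cnn_layer specifications")
  kinds <- vapply(layers, `[[`, "", "kind")
  nflat <- sum(kinds == "flatten")
  if (nflat > 1L) stop("at most one flatten layer is allowed")
  if (any(kinds == "dense")) {
    first_dense <- min(which(kinds == "dense"))
    if (nflat == 0L || min(which(kinds == "flatten")) > first_dense)
      stop("dense layers may only appear after the flatten layer")
  }
  spec <- structure(list(input_shape = input_shape, layers = layers,
                         name = name), class = "cnn_spec")
  shape_chain(spec)  # validates; errors name the offending layer
  spec
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %s  input (%s)\n", x$name,
              paste(x$input_shape, collapse = ", ")))
  shapes <- shape_chain(x)
  for (i in seq_along(x$layers))
    cat(sprintf("  %2d. %-50s -> (%s)\n", i, format_layer(x$layers[[i]]),
                paste(shapes[[i + 1L]], collapse = ", ")))
  invisible(x)
}

#' Infer the output shape of one layer
#'
#' Shape arithmetic for a single layer applied to a given input shape.
#' Convolution and pooling use valid-padding arithmetic
#' `floor((n - kernel + 2*padding)/stride) + 1` per spatial axis;
#' convolution sets the channel count to its filter count while pooling
#' preserves channels; flatten collapses `(h, w, c)` to a rank-1 length
#' `h*w*c`; dense maps any rank-1 length to its unit count.
#'
#' @param layer a `"cnn_layer"`.
#' @param in_shape integer `c(h, w, c)` for conv/pool/flatten, or a single
#'   length for dense.
#' @param layer_index optional index used in error messages.
#' @return integer shape vector (length 3, or 1 after flatten/dense).
#' @export
infer_output_shape <- function(layer, in_shape, layer_index = NA_integer_) {
  in_shape <- as.integer(in_shape)
  where <- if (is.na(layer_index)) "" else sprintf(" (layer %d)", layer_index)
  need_rank <- function(r) {
    if (length(in_shape) != r)
      stop(sprintf("layer kind '%s'%s expects a rank-%d input shape",
                   layer$kind, where, r))
  }
  switch(layer$kind,
    conv2d = , avgpool2d = {
      need_rank(3L)
      k <- c(layer$kernel_h, layer$kernel_w)
      out_sp <- (in_shape[1:2] - k + 2L * layer$padding) %/% layer$stride + 1L
      if (any(out_sp < 1L))
        stop(sprintf(
          "invalid spec%s: %s kernel %dx%d on input (%s) gives non-positive output",
          where, layer$kind, k[1L], k[2L], paste(in_shape, collapse = ", ")))
      ch <- if (layer$kind == "conv2d") layer$n_filters else in_shape[3L]
      c(out_sp, ch)
    },
    flatten = { need_rank(3L); prod(in_shape) },
    dense = { need_rank(1L); layer$n_units },
    stop("unknown layer kind: ", layer$kind))
}

shape_chain <- function(spec) {
  shapes <- vector("list", length(spec$layers) + 1L)
  shapes[[1L]] <- spec$input_shape
  for (i in seq_along(spec$layers))
    shapes[[i + 1L]] <- infer_output_shape(spec$layers[[i]], shapes[[i]], i)
  shapes
}

#' Count trainable parameters of one layer
#'
#' Convolution: `(kernel_h * kernel_w * c_in + 1) * n_filters` (one bias per
#' filter). Dense: `(len_in + 1) * n_units`. Pooling and flatten have no
#' trainable parameters.
#'
#' @inheritParams infer_output_shape
#' @return integer parameter count.
#' @export
count_parameters <- function(layer, in_shape, layer_index = NA_integer_) {
  infer_output_shape(layer, in_shape, layer_index)  # validates shape
  in_shape <- as.integer(in_shape)
  switch(layer$kind,
    conv2d = (layer$kernel_h * layer$kernel_w * in_shape[3L] + 1L) *
      layer$n_filters,
    dense = (in_shape[1L] + 1L) * layer$n_units,
    0L)
}

#' Multiply-accumulate cost of one layer
#'
#' The computational-cost measure used throughout the package counts
#' multiplications only: for a convolution,
#' `kernel_h * kernel_w * c_in * h_out * w_out * n_filters`. Bias additions
#' and accumulations are not counted. By convention dense layers cost
#' `len_in * n_units` and pooling/flatten cost 0.
#'
#' @inheritParams infer_output_shape
#' @return MAC count (double, to avoid integer overflow).
#' @examples
#' # a 3x3, 32-filter convolution on a (256, 256, 32) input
#' layer_cost(conv2d(32, 3), c(256, 256, 32))   # 594,579,456
#' # 10-filter 1x1 bottleneck ahead of it cuts the pair to 206,451,200
#' layer_cost(conv2d(10, 1), c(256, 256, 32)) +
#'   layer_cost(conv2d(32, 3), c(254, 254, 10))
#' @export
layer_cost <- function(layer, in_shape, layer_index = NA_integer_) {
  out <- infer_output_shape(layer, in_shape, layer_index)
  in_shape <- as.integer(in_shape)
  switch(layer$kind,
    conv2d = as.double(layer$kernel_h) * layer$kernel_w * in_shape[3L] *
      out[1L] * out[2L] * layer$n_filters,
    dense = as.double(in_shape[1L]) * layer$n_units,
    0)
}

#' Audit a model specification
#'
#' Runs shape inference, parameter counting and MAC costing through every
#' layer of a specification and returns the per-layer table plus totals and
#' the model depth. Depth follows the convention used for the canonical
#' 13-layer network: convolution, pooling and dense layers are counted,
#' flatten is not (it moves no information and has no parameters).
#'
#' @param spec a `"cnn_spec"`.
#' @return an object of class `"cnn_audit"`: list with `per_layer` (a
#'   data.frame with columns `layer_index`, `kind`, `n_filters`, `kernel`,
#'   `out_h`, `out_w`, `out_c` (NA after flatten), `out_len`, `n_params`,
#'   `mac_cost`), `total_params`, `total_mac` and `depth`.
#' @examples
#' a <- audit(btc_fcnn_spec())
#' a$total_params  # 583,613
#' a$depth         # 13
#' @export
audit <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  shapes <- shape_chain(spec)
  n <- length(spec$layers)
  rows <- lapply(seq_len(n), function(i) {
    l <- spec$layers[[i]]
    out <- shapes[[i + 1L]]
    rank3 <- length(out) == 3L
    data.frame(
      layer_index = i,
      kind = l$kind,
      n_filters = if (l$kind == "conv2d") l$n_filters else NA_integer_,
      kernel = if (l$kind %in% c("conv2d", "avgpool2d"))
        sprintf("%dx%d", l$kernel_h, l$kernel_w) else NA_character_,
      out_h = if (rank3) out[1L] else NA_integer_,
      out_w = if (rank3) out[2L] else NA_integer_,
      out_c = if (rank3) out[3L] else NA_integer_,
      out_len = prod(out),
      n_params = count_parameters(l, shapes[[i]], i),
      mac_cost = layer_cost(l, shapes[[i]], i),
      stringsAsFactors = FALSE)
  })
  per_layer <- do.call(rbind, rows)
  structure(list(per_layer = per_layer,
                 total_params = sum(per_layer$n_params),
                 total_mac = sum(per_layer$mac_cost),
                 depth = sum(per_layer$kind != "flatten"),
                 name = spec$name),
            class = "cnn_audit")
}

#' @export
print.cnn_audit <- function(x, ...) {
  cat(sprintf("<cnn_audit> %s\n", x$name))
  print(x$per_layer, row.names = FALSE)
  cat(sprintf("depth %d | total parameters %s | total MACs %s\n", x$depth,
              format(x$total_params, big.mark = ","),
              format(x$total_mac, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Write an audit table to CSV
#'
#' Emits the per-layer audit (layer type, filters, kernel, output size,
#' parameter count, MAC cost) followed by total rows.
#'
#' @param x a `"cnn_audit"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(x, path) {
  stopifnot(inherits(x, "cnn_audit"))
  df <- x$per_layer
  df$output_size <- ifelse(is.na(df$out_c), as.character(df$out_len),
                           sprintf("(%d, %d, %d)", df$out_h, df$out_w, df$out_c))
  out <- df[, c("layer_index", "kind", "n_filters", "kernel", "output_size",
                "n_params", "mac_cost")]
  tot <- data.frame(layer_index = NA, kind = "total", n_filters = NA,
                    kernel = NA, output_size = "",
                    n_params = x$total_params, mac_cost = x$total_mac)
  write.csv(rbind(out, tot), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The canonical 13-layer bottlenecked CNN
#'
#' Builds the BTC-fCNN architecture: a compact sequential network for
#' three-class tumor classification of single-channel square images. The
#' network interleaves 3x3 feature-extracting convolutions (32 filters,
#' ReLU) with 1x1 bottleneck convolutions (10 filters by default, ReLU)
#' that shrink the channel count before each spatial convolution — cutting
#' the multiply-accumulate cost roughly threefold — and 2x2 average
#' poolings, followed by a 64-unit dense layer and a 3-unit softmax head.
#' At the default 256x256 input it has 583,613 trainable parameters and
#' depth 13 (8 conv + 3 pool + 2 dense; flatten not counted).
#'
#' @param include_bottlenecks if `FALSE`, return the ablation variant with
#'   every 1x1 convolution removed (same inference rules, different shapes
#'   and counts).
#' @param input_size input image side in pixels (square, single channel).
#'   256 is the reference size; 64 is convenient for fast experiments.
#' @param n_bottleneck number of filters in the 1x1 bottleneck layers.
#' @param n_classes number of output classes.
#' @return a `"cnn_spec"`.
#' @examples
#' audit(btc_fcnn_spec())$total_params            # 583,613
#' audit(btc_fcnn_spec(FALSE))                    # ablation, no 1x1 layers
#' @export
btc_fcnn_spec <- function(include_bottlenecks = TRUE, input_size = 256L,
                          n_bottleneck = 10L, n_classes = 3L) {
  bn <- function() if (include_bottlenecks) list(conv2d(n_bottleneck, 1L))
    else list()
  layers <- c(
    list(conv2d(32L, 3L)), bn(), list(avg_pool2d(2L)),
    bn(), list(conv2d(32L, 3L)), bn(), list(avg_pool2d(2L)),
    bn(), list(conv2d(32L, 3L)), bn(), list(avg_pool2d(2L)),
    list(flatten(), dense(64L, activation = "relu"),
         dense(n_classes, activation = "softmax")))
  name <- if (include_bottlenecks) "btc_fcnn" else "btc_fcnn_no_bottleneck"
  if (input_size != 256L) name <- sprintf("%s_%d", name, input_size)
  model_spec(c(input_size, input_size, 1L), layers, name = name)
}

#' Serialize / restore a model specification as JSON
#'
#' The JSON document holds the input shape, the model name, and the layer
#' list with each layer's explicit fields; `spec_from_json` re-validates on
#' read so a corrupted document fails loudly.
#'
#' @param spec a `"cnn_spec"`.
#' @param path file path; for `spec_to_json`, `NULL` returns the JSON text.
#' @return `spec_to_json`: the path (or JSON string); `spec_from_json`: a
#'   `"cnn_spec"`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  doc <- list(name = spec$name, input_shape = spec$input_shape,
              layers = lapply(spec$layers, unclass))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$input_shape) || is.null(doc$layers))
    stop("not a model-spec JSON document: missing input_shape or layers")
  layers <- lapply(doc$layers, function(l) {
    switch(as.character(l$kind),
      conv2d = conv2d(l$n_filters, c(l$kernel_h, l$kernel_w), l$stride,
                      l$padding, l$activation),
      avgpool2d = avg_pool2d(c(l$kernel_h, l$kernel_w), l$stride, l$padding),
      flatten = flatten(),
      dense = dense(l$n_units, l$activation),
      stop("unknown layer kind in JSON: ", l$kind))
  })
  model_spec(unlist(doc$input_shape), layers,
             name = if (is.null(doc$name)) "cnn" else doc$name)
}
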