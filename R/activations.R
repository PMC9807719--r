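#' Activation functions
#'
#' Elementwise nonlinearities used by the network runtime. `relu` is
#' `max(0, x)`; `sigmoid` is `1/(1 + exp(-x))`; `tanh_act` is the standard
#' hyperbolic tangent; `softmax_probs` maps each row of a score matrix to a
#' probability vector (max-subtracted for numerical stability, rows sum
#' to 1).
#'
#' @param x numeric vector/array of finite values.
#' @param scores numeric matrix, one row of class scores per observation.
#' @return same-shape numeric values; `softmax_probs` returns a matrix of
#'   row-normalized probabilities.
#' @examples
#' relu(c(-3, 3))          # 0 3
#' sigmoid(0)              # 0.5
#' softmax_probs(rbind(c(0, 0, 0)))  # 1/3 1/3 1/3
#' @name activations
NULL

#' @rdname activations
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname activations
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname activations
#' @export
tanh_act <- function(x) tanh(x)

#' @rdname activations
#' @export
softmax_probs <- function(scores) {
  scores <- as.matrix(scores)
  z <- exp(scores - apply(scores, 1L, max))
  z / rowSums(z)
}

# Column-wise softmax on a (units x n) activation block.
col_softmax <- function(z) {
  z <- exp(sweep(z, 2L, apply(z, 2L, max), `-`))
  sweep(z, 2L, colSums(z), `/`)
}

#' Sparse categorical cross-entropy
#'
#' Mean negative log-probability of the true class: integer labels, not
#' one-hot vectors, index the predicted probability rows. Probabilities are
#' clamped below at `eps` so a zero probability at the true class yields a
#' large finite loss rather than `Inf`.
#'
#' @param true_labels integer classes in `0..K-1`.
#' @param predicted_probs numeric matrix (n x K), each row a probability
#'   vector summing to 1 (checked within tolerance).
#' @param eps clamping floor for probabilities.
#' @return non-negative scalar loss.
#' @examples
#' sparse_cce(0L, rbind(c(1, 0, 0)))                 # 0
#' sparse_cce(1L, rbind(c(0.25, 0.5, 0.25)))         # -log(0.5)
#' @export
sparse_cce <- function(true_labels, predicted_probs, eps = 1e-7) {
  p <- as.matrix(predicted_probs)
  y <- as.integer(true_labels)
  if (length(y) != nrow(p)) stop("labels and probability rows differ in length")
  if (any(y < 0L | y >= ncol(p))) stop("labels out of range 0..K-1")
  if (any(abs(rowSums(p) - 1) > 1e-4))
    stop("probability rows must sum to 1")
  mean(-log(pmax(p[cbind(seq_along(y), y + 1L)], eps)))
}

# Activation derivative wrt pre-activation z (a = act(z) supplied where cheap).
act_grad <- function(activation, z, a) {
  switch(activation,
    relu = (z > 0) + 0,
    sigmoid = a * (1 - a),
    tanh = 1 - a * a,
    linear = array(1, dim = if (is.null(dim(z))) length(z) else dim(z)),
    stop("no elementwise gradient for activation: ", activation))
}

apply_act <- function(activation, z) {
  switch(activation,
    relu = relu(z),
    sigmoid = sigmoid(z),
    tanh = tanh(z),
    linear = z,
    stop("activation not applicable here: ", activation))
}
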