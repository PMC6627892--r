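#' Feature map stack from the last convolutional layer
#'
#' Container for the `u x v x K` activations `f_k(x, y)` produced by the last
#' convolutional layer of a CNN for a single input image. Rows index the
#' spatial coordinate `x` (height `u`), columns the coordinate `y` (width
#' `v`), and the third dimension the channel `k`.
#'
#' @param values Numeric array of dimension `c(u, v, K)`; a plain matrix is
#'   promoted to a single-channel stack. All values must be finite.
#' @param image_id Optional opaque identifier carried through to maps.
#' @return An object of class `feature_map_stack` with elements `values`,
#'   `u`, `v`, `K` and `image_id`.
#' @seealso [global_average_pool()], [compute_class_scores()]
#' @export
feature_map_stack <- function(values, image_id = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_invalid("'values' must be a u x v x K array (or a matrix)")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_invalid("feature map activations must all be finite")
  d <- dim(values)
  if (any(d < 1L)) stop_invalid("u, v and K must all be >= 1")
  structure(
    list(values = values, u = d[1L], v = d[2L], K = d[3L], image_id = image_id),
    class = "feature_map_stack"
  )
}

#' @export
print.feature_map_stack <- function(x, ...) {
  cat(sprintf("<feature_map_stack %d x %d x %d channels%s>\n",
              x$u, x$v, x$K,
              if (is.null(x$image_id)) "" else paste0(", image ", x$image_id)))
  invisible(x)
}

#' Dense classification head of a GAP-head CNN
#'
#' The GAP-to-output weight matrix `w_k^c` and per-class biases: the only
#' trained parameters the mapping algorithms read.
#'
#' @param weights Numeric `K x N` matrix; entry `[k, c]` connects feature
#'   channel `k` to output class `c`.
#' @param biases Numeric vector of length `N` (default all zero).
#' @return An object of class `dense_head` with elements `weights`, `biases`,
#'   `K` and `N`.
#' @export
dense_head <- function(weights, biases = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop_invalid("'weights' must be a numeric K x N matrix")
  if (any(!is.finite(weights))) stop_invalid("head weights must be finite")
  N <- ncol(weights)
  if (N < 1L) stop_invalid("head must have at least one output class")
  if (is.null(biases)) biases <- numeric(N)
  if (length(biases) != N || any(!is.finite(biases)))
    stop_invalid("'biases' must be a finite numeric vector of length ncol(weights)")
  structure(
    list(weights = weights, biases = as.numeric(biases),
         K = nrow(weights), N = N),
    class = "dense_head"
  )
}

#' @export
print.dense_head <- function(x, ...) {
  cat(sprintf("<dense_head %d channels -> %d classes>\n", x$K, x$N))
  invisible(x)
}

#' Global average pooling
#'
#' Spatially averages each feature map into one scalar per channel:
#' `GAP_k = mean over (x, y) of f_k(x, y)`. The mean convention (divide by
#' `u * v`) matches standard GAP layers; every normalized or thresholded
#' product downstream is invariant to this positive scale factor.
#'
#' @param fm A [feature_map_stack()].
#' @return Numeric vector of length `K`.
#' @export
global_average_pool <- function(fm) {
  stopifnot(inherits(fm, "feature_map_stack"))
  colMeans(matrix(fm$values, nrow = fm$u * fm$v, ncol = fm$K))
}

#' Class scores of a GAP-head CNN
#'
#' Computes the pre-activation prediction scores (logits)
#' `S_c = sum_k w_k^c * GAP_k + b_c` and the predicted class
#' `argmax_c S_c` (ties broken by the lowest class index).
#'
#' @param fm A [feature_map_stack()].
#' @param head A [dense_head()] whose channel dimension matches `fm`.
#' @return An object of class `class_scores` with elements `scores`
#'   (numeric length `N`, logits — the inputs to softmax, not
#'   probabilities) and `predicted_class` (1-based index).
#' @export
compute_class_scores <- function(fm, head) {
  stopifnot(inherits(fm, "feature_map_stack"), inherits(head, "dense_head"))
  if (head$K != fm$K)
    stop_contract(sprintf("head has %d channels but feature stack has %d",
                          head$K, fm$K))
  s <- drop(crossprod(head$weights, global_average_pool(fm))) + head$biases
  structure(
    list(scores = as.numeric(s), predicted_class = which.max(s), N = head$N),
    class = "class_scores"
  )
}

#' @export
print.class_scores <- function(x, ...) {
  cat(sprintf("<class_scores N=%d, predicted class %d>\n", x$N, x$predicted_class))
  print(x$scores)
  invisible(x)
}

#' Adapter contract to a CAM-compatible CNN
#'
#' Wraps a trained model whose head is exactly
#' convolution -> global average pooling -> single dense layer, the shape
#' the CAM derivation requires. Heads with multiple dense layers are
#' unsupported. The adapter must be deterministic: re-invoking it on the
#' same image yields identical outputs.
#'
#' @param forward Function of an image returning a list with elements
#'   `features` (a [feature_map_stack()]) and `scores` (a `class_scores`
#'   object, the model's own forward-pass logits).
#' @param head Function of no arguments returning the model's
#'   [dense_head()].
#' @param input_size Integer `c(height, width)` the adapter expects.
#' @param gradients Optional function `(image, class)` returning the
#'   `u x v x K` array of gradients of the class score with respect to the
#'   feature maps.
#' @param id Optional adapter identifier.
#' @return An object of class `model_adapter`.
#' @export
model_adapter <- function(forward, head, input_size, gradients = NULL, id = NULL) {
  if (!is.function(forward) || !is.function(head))
    stop_invalid("'forward' and 'head' must be functions")
  if (!is.null(gradients) && !is.function(gradients))
    stop_invalid("'gradients' must be a function or NULL")
  structure(
    list(forward = forward, head = head,
         input_size = as.integer(input_size),
         gradients = gradients, id = id),
    class = "model_adapter"
  )
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter%s, input %d x %d%s>\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              x$input_size[1L], x$input_size[2L],
              if (is.null(x$gradients)) "" else ", gradients available"))
  invisible(x)
}

#' Extract feature maps, head and scores for one image
#'
#' Runs the adapter's forward pass and returns the last-convolution feature
#' stack, the dense head, and the class scores, verifying that the
#' adapter's own logits agree with [compute_class_scores()] applied to the
#' extracted stack and head (relative tolerance `1e-5`) — the consistency
#' check that the wrapped model really has the GAP-head shape.
#'
#' @param adapter A [model_adapter()].
#' @param image Numeric matrix (grayscale, values in `[0, 1]`) of the
#'   adapter's expected size.
#' @return List with elements `features`, `head`, `scores`.
#' @export
extract <- function(adapter, image) {
  stopifnot(inherits(adapter, "model_adapter"))
  if (!is.matrix(image) && !(is.array(image) && length(dim(image)) == 2L))
    stop_invalid("'image' must be a numeric matrix")
  if (!all(dim(image)[1:2] == adapter$input_size))
    stop_invalid(sprintf("image is %d x %d but adapter expects %d x %d",
                         nrow(image), ncol(image),
                         adapter$input_size[1L], adapter$input_size[2L]))
  out <- adapter$forward(image)
  head <- adapter$head()
  recomputed <- compute_class_scores(out$features, head)
  denom <- pmax(abs(out$scores$scores), 1)
  if (max(abs(out$scores$scores - recomputed$scores) / denom) > 1e-5)
    stop_unsupported(paste(
      "adapter logits disagree with GAP-head recomputation;",
      "the wrapped model is not CAM-compatible (conv -> GAP -> dense)"))
  list(features = out$features, head = head, scores = out$scores)
}
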