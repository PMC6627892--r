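#' Activation map container
#'
#' A `u x v` spatial map produced by one of the mapping methods, with
#' provenance. CRM and Grad-CAM maps are non-negative by construction; CAM
#' maps may contain negative values.
#'
#' @param values Numeric `u x v` matrix.
#' @param method One of `"CAM"`, `"GradCAM"`, `"CRM"`.
#' @param target_class 1-based class index, or `"all"` (CRM aggregates every
#'   output node and exposes no class argument).
#' @param image_id Optional identifier inherited from the feature stack.
#' @return An object of class `activation_map`.
#' @export
activation_map <- function(values, method = c("CAM", "GradCAM", "CRM"),
                           target_class = "all", image_id = NULL) {
  method <- match.arg(method)
  if (!is.matrix(values) || !is.numeric(values) || any(!is.finite(values)))
    stop_invalid("'values' must be a finite numeric matrix")
  if (method %in% c("CRM", "GradCAM") && any(values < 0))
    stop_contract(sprintf("%s values must be non-negative", method))
  structure(
    list(values = values, method = method, target_class = target_class,
         image_id = image_id),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map %s, class %s, %d x %d>\n", x$method,
              paste(x$target_class), nrow(x$values), ncol(x$values)))
  invisible(x)
}

.check_class_index <- function(c, N) {
  if (length(c) != 1L || !is.numeric(c) || c != as.integer(c) || c < 1L || c > N)
    stop_range(sprintf("class index must be an integer in 1..%d", N))
  as.integer(c)
}

# (u*v) x K unrolling shared by all mapping methods; column-major, so row
# index x + (y-1)*u corresponds to spatial element (x, y).
.fm_matrix <- function(fm) matrix(fm$values, nrow = fm$u * fm$v, ncol = fm$K)

#' Class activation map (CAM)
#'
#' `M_c(x, y) = sum_k w_k^c * f_k(x, y)`: the dense-weight-weighted sum of
#' the last-convolution feature maps for one class. No ReLU is applied and
#' the bias is excluded, so negative values are preserved.
#'
#' @param fm A [feature_map_stack()].
#' @param head A [dense_head()].
#' @param class 1-based target class index.
#' @return An [activation_map()] with `method = "CAM"`.
#' @export
compute_cam <- function(fm, head, class) {
  stopifnot(inherits(fm, "feature_map_stack"), inherits(head, "dense_head"))
  if (head$K != fm$K)
    stop_contract("head channel dimension does not match feature stack")
  class <- .check_class_index(class, head$N)
  m <- matrix(.fm_matrix(fm) %*% head$weights[, class], fm$u, fm$v)
  activation_map(m, "CAM", target_class = class, image_id = fm$image_id)
}

#' Grad-CAM channel weights
#'
#' `alpha_k^c = sum over (x, y) of dS_c / df_k(x, y)`. Two routes are
#' supported: the analytic route for GAP heads, where
#' `dS_c/df_k(x, y) = w_k^c / (u * v)` and hence `alpha_k^c = w_k^c`
#' exactly (Grad-CAM collapses onto the CAM weights for CAM-compatible
#' architectures), and a gradient route fed by externally computed
#' per-element gradients (for example the adapter's finite-difference
#' oracle).
#'
#' @param fm A [feature_map_stack()] (supplies `u`, `v`, `K`).
#' @param head A [dense_head()] for the analytic route, or `NULL`.
#' @param gradients A `u x v x K` array of `dS_c/df_k(x, y)` for the
#'   gradient route, or `NULL`. Exactly one of `head`/`gradients` is
#'   required.
#' @param class 1-based target class index (used by the analytic route).
#' @return An object of class `gradient_weights` with element `alpha`
#'   (numeric length `K`) and `target_class`.
#' @export
gradcam_weights <- function(fm, head = NULL, gradients = NULL, class = 1L) {
  stopifnot(inherits(fm, "feature_map_stack"))
  if (is.null(head) && is.null(gradients))
    stop_contract("supply a dense head (analytic route) or a gradient array")
  if (!is.null(gradients)) {
    if (!is.array(gradients) || !all(dim(gradients) == c(fm$u, fm$v, fm$K)))
      stop_contract("'gradients' must be a u x v x K array matching the stack")
    alpha <- colSums(matrix(gradients, nrow = fm$u * fm$v, ncol = fm$K))
  } else {
    stopifnot(inherits(head, "dense_head"))
    if (head$K != fm$K)
      stop_contract("head channel dimension does not match feature stack")
    class <- .check_class_index(class, head$N)
    # sum_{x,y} w_k^c/(u v) = w_k^c: the spatial sum cancels the GAP mean
    alpha <- head$weights[, class]
  }
  if (any(!is.finite(alpha))) stop_invalid("gradient weights must be finite")
  structure(list(alpha = as.numeric(alpha), target_class = class),
            class = "gradient_weights")
}

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' `Grad_M_c(x, y) = ReLU(sum_k alpha_k^c * f_k(x, y))`. The ReLU removes
#' the influence of negatively weighted channels; it is the only difference
#' from CAM when the model is CAM-compatible.
#'
#' @param fm A [feature_map_stack()].
#' @param alpha A `gradient_weights` object from [gradcam_weights()], or a
#'   numeric vector of length `K`.
#' @param class 1-based target class recorded in the map's provenance.
#' @return An [activation_map()] with `method = "GradCAM"`, non-negative.
#' @export
compute_gradcam <- function(fm, alpha, class = NULL) {
  stopifnot(inherits(fm, "feature_map_stack"))
  if (inherits(alpha, "gradient_weights")) {
    if (is.null(class)) class <- alpha$target_class
    alpha <- alpha$alpha
  }
  if (length(alpha) != fm$K)
    stop_contract(sprintf("alpha has length %d but stack has %d channels",
                          length(alpha), fm$K))
  m <- matrix(pmax(0, .fm_matrix(fm) %*% alpha), fm$u, fm$v)
  activation_map(m, "GradCAM",
                 target_class = if (is.null(class)) "unknown" else class,
                 image_id = fm$image_id)
}

#' Class-selective relevance map (CRM)
#'
#' Scores each spatial element `(l, m)` of the feature maps by the total
#' squared change it induces across *all* `N` output-class scores when it
#' is removed from every feature map:
#' `R(l, m) = sum_c (S_c - S_c(l, m))^2`,
#' where `S_c(l, m)` is the score recomputed with element `(l, m)` zeroed
#' in every channel (the GAP divisor `u * v` stays fixed; removal drops the
#' term from the sum without renormalizing). Under the mean-GAP convention
#' this has the closed form
#' `R(l, m) = sum_c (sum_k w_k^c f_k(l, m) / (u * v))^2`:
#' the sum of squared per-class CAM contributions. Biases cancel in the
#' score difference. Because every output node enters, the map reflects
#' both positive contributions to the target class and negative
#' contributions to the others, making the highlighted region
#' class-discriminative.
#'
#' @param fm A [feature_map_stack()].
#' @param head A [dense_head()].
#' @return An [activation_map()] with `method = "CRM"`, non-negative,
#'   aggregated over all classes (`target_class = "all"`).
#' @seealso [brute_force_crm()] for the literal leave-one-out computation.
#' @export
compute_crm <- function(fm, head) {
  stopifnot(inherits(fm, "feature_map_stack"), inherits(head, "dense_head"))
  if (head$K != fm$K)
    stop_contract("head channel dimension does not match feature stack")
  z <- .fm_matrix(fm) %*% head$weights / (fm$u * fm$v)
  activation_map(matrix(rowSums(z^2), fm$u, fm$v), "CRM",
                 target_class = "all", image_id = fm$image_id)
}

#' Brute-force leave-one-out CRM (oracle)
#'
#' Literal realization of the removal definition: for every spatial
#' element, zero it across all `K` feature maps, recompute the class
#' scores through [compute_class_scores()], and accumulate the squared
#' score differences over all classes. `O(u * v)` forward recomputations;
#' intended as the independent correctness oracle for [compute_crm()] in
#' tests, not for production use.
#'
#' @inheritParams compute_crm
#' @return An [activation_map()] with `method = "CRM"`.
#' @export
brute_force_crm <- function(fm, head) {
  stopifnot(inherits(fm, "feature_map_stack"), inherits(head, "dense_head"))
  if (head$K != fm$K)
    stop_contract("head channel dimension does not match feature stack")
  s0 <- compute_class_scores(fm, head)$scores
  r <- matrix(0, fm$u, fm$v)
  for (l in seq_len(fm$u)) {
    for (m in seq_len(fm$v)) {
      vals <- fm$values
      vals[l, m, ] <- 0
      s1 <- compute_class_scores(feature_map_stack(vals), head)$scores
      r[l, m] <- sum((s0 - s1)^2)
    }
  }
  activation_map(r, "CRM", target_class = "all", image_id = fm$image_id)
}

#' Class-level average CRM map
#'
#' Elementwise arithmetic mean of the CRM maps of all images in one class,
#' yielding the class-level region of greatest model attention.
#'
#' @param maps List of [activation_map()] objects, all `method = "CRM"` and
#'   all of the same spatial size.
#' @param class_label Class label the maps belong to.
#' @return An object of class `average_map` with elements `values`,
#'   `class_label` and `n_images`.
#' @export
average_crm <- function(maps, class_label = NA) {
  if (!is.list(maps) || length(maps) == 0L)
    stop_invalid("'maps' must be a non-empty list of CRM activation maps")
  for (m in maps) {
    if (!inherits(m, "activation_map") || m$method != "CRM")
      stop_contract("all maps must be activation_map objects with method CRM")
  }
  d <- dim(maps[[1L]]$values)
  for (m in maps[-1L]) {
    if (!all(dim(m$values) == d))
      stop_contract("all maps must share the same u x v size")
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  structure(
    list(values = avg, class_label = class_label, n_images = length(maps)),
    class = "average_map"
  )
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("<average_map class %s, %d x %d, n=%d>\n", paste(x$class_label),
              nrow(x$values), ncol(x$values), x$n_images))
  invisible(x)
}
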