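# Fixture CNN: a small CAM-compatible network (stacked 3x3 conv blocks with
# 2x2 max pooling, a final 3x3 convolution, global average pooling, one
# dense layer) trained from scratch on the synthetic dataset. Convolution
# kernels live in compiled code; the training loop, ReLU and Adam live here.

#' Specification of the tiny fixture CNN
#'
#' The head is exactly conv -> GAP -> dense, the CAM-compatible shape. The
#' default on 64 x 64 input yields 8 x 8 feature maps with `K = 64`
#' channels feeding a 7-class dense layer.
#'
#' @param input_size Input image side length.
#' @param block_channels Output channels of each conv+pool block; the number
#'   of blocks is `length(block_channels)` and each block halves the
#'   resolution.
#' @param feature_channels Channels `K` of the final (unpooled) conv layer
#'   whose activations are the feature-map stack every mapping method reads.
#' @param num_classes Output classes `N`.
#' @param kernel Square kernel size (odd).
#' @return An object of class `tiny_model_spec`.
#' @export
tiny_model_spec <- function(input_size = 64L, block_channels = c(8L, 16L, 32L),
                            feature_channels = 64L, num_classes = 7L,
                            kernel = 3L) {
  fmres <- input_size / 2^length(block_channels)
  if (fmres != as.integer(fmres) || fmres < 4L)
    stop_invalid(sprintf(
      "configuration yields %.1f x %.1f feature maps; at least 4 x 4 required",
      fmres, fmres))
  if (kernel %% 2L != 1L) stop_invalid("'kernel' must be odd")
  structure(
    list(input_size = as.integer(input_size),
         block_channels = as.integer(block_channels),
         feature_channels = as.integer(feature_channels),
         num_classes = as.integer(num_classes),
         kernel = as.integer(kernel),
         feature_size = as.integer(fmres)),
    class = "tiny_model_spec"
  )
}

# He-uniform initialization; relies on the caller having seeded the RNG
.init_params <- function(spec) {
  k <- spec$kernel
  chans <- c(1L, spec$block_channels, spec$feature_channels)
  conv <- vector("list", length(chans) - 1L)
  for (l in seq_along(conv)) {
    cin <- chans[l]; cout <- chans[l + 1L]
    lim <- sqrt(6 / (k * k * cin))
    conv[[l]] <- list(
      W = matrix(runif(k * k * cin * cout, -lim, lim), k * k * cin, cout),
      b = numeric(cout), cin = cin, cout = cout)
  }
  K <- spec$feature_channels; N <- spec$num_classes
  lim <- sqrt(6 / K)
  list(conv = conv,
       dense = list(W = matrix(runif(K * N, -lim, lim), K, N), b = numeric(N)))
}

# forward pass; the last conv layer is not pooled and its ReLU output is
# the feature-map stack. Inputs are mean-centered per image (standard
# preprocessing; also prevents the GAP head from keying on global
# intensity instead of localized structure).
.net_forward <- function(params, img, spec, cache = FALSE) {
  k <- spec$kernel
  nb <- length(spec$block_channels)
  img <- img - mean(img)
  x <- array(img, dim = c(dim(img), 1L))
  caches <- list()
  for (l in seq_along(params$conv)) {
    z <- conv2d_forward(x, params$conv[[l]]$W, params$conv[[l]]$b, k)
    a <- pmax(z, 0)
    if (l <= nb) {
      mp <- maxpool2_forward(a)
      if (cache) caches[[l]] <- list(x = x, z = z, a = a, idx = mp$idx,
                                     dim_in = dim(a))
      x <- mp$y
    } else {
      if (cache) caches[[l]] <- list(x = x, z = z)
      x <- a
    }
  }
  gap <- colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3L]))
  scores <- drop(crossprod(params$dense$W, gap)) + params$dense$b
  list(features = x, gap = gap, scores = scores, caches = caches)
}

# backward pass from dL/dscores; returns gradients shaped like params
.net_backward <- function(params, fwd, dscores, spec) {
  k <- spec$kernel
  nb <- length(spec$block_channels)
  gd <- list(W = outer(fwd$gap, dscores), b = dscores)
  u <- dim(fwd$features)[1L]; v <- dim(fwd$features)[2L]
  dgap <- drop(params$dense$W %*% dscores)
  dx <- array(rep(dgap / (u * v), each = u * v), dim = dim(fwd$features))
  gconv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    cc <- fwd$caches[[l]]
    if (l <= nb)
      dx <- maxpool2_backward(cc$idx, dx, cc$dim_in[1L], cc$dim_in[2L])
    dz <- dx * (cc$z > 0)
    bw <- conv2d_backward(cc$x, params$conv[[l]]$W, dz, k)
    gconv[[l]] <- list(W = bw$gw, b = as.numeric(bw$gb))
    dx <- bw$gx
  }
  list(conv = gconv, dense = gd)
}

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# flatten/unflatten parameter pytrees for the Adam update
.param_vec <- function(p) {
  c(unlist(lapply(p$conv, function(l) c(l$W, l$b))), p$dense$W, p$dense$b)
}

.vec_param <- function(vec, template) {
  pos <- 1L
  take <- function(n) {
    out <- vec[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  conv <- lapply(template$conv, function(l) {
    W <- matrix(take(length(l$W)), nrow(l$W), ncol(l$W))
    b <- take(length(l$b))
    list(W = W, b = b, cin = l$cin, cout = l$cout)
  })
  dW <- matrix(take(length(template$dense$W)),
               nrow(template$dense$W), ncol(template$dense$W))
  db <- take(length(template$dense$b))
  list(conv = conv, dense = list(W = dW, b = db))
}

.dataset_accuracy <- function(params, spec, images, labels) {
  if (length(images) == 0L) return(NA_real_)
  pred <- vapply(images, function(im)
    which.max(.net_forward(params, im, spec)$scores), integer(1))
  mean(pred == labels)
}

#' Build an adapter around a tiny CNN
#'
#' Wraps (optionally untrained) network parameters in the
#' [model_adapter()] contract. The gradient route evaluates
#' `dS_c/df_k(x, y)` by central finite differences of the head score as a
#' function of the feature stack — a route independent of the analytic
#' `alpha = w` identity, usable as its oracle.
#'
#' @param spec A [tiny_model_spec()].
#' @param seed Seed for weight initialization when `params` is `NULL`.
#' @param params Optional trained parameter set (from
#'   [train_fixture_model()]).
#' @return A [model_adapter()].
#' @export
build_tiny_cnn <- function(spec = tiny_model_spec(), seed = 1L, params = NULL) {
  stopifnot(inherits(spec, "tiny_model_spec"))
  if (is.null(params)) params <- .with_seed(seed, .init_params(spec))
  forward <- function(image) {
    if (!all(dim(image)[1:2] == spec$input_size))
      stop_invalid(sprintf("image must be %d x %d", spec$input_size,
                           spec$input_size))
    fwd <- .net_forward(params, image, spec)
    fs <- feature_map_stack(fwd$features)
    list(features = fs,
         scores = structure(list(scores = fwd$scores,
                                 predicted_class = which.max(fwd$scores),
                                 N = spec$num_classes),
                            class = "class_scores"))
  }
  head_fn <- function() dense_head(params$dense$W, params$dense$b)
  gradients <- function(image, class) {
    fwd <- .net_forward(params, image, spec)
    f <- fwd$features
    u <- dim(f)[1L]; v <- dim(f)[2L]; K <- dim(f)[3L]
    W <- params$dense$W; b <- params$dense$b
    score_of <- function(vals)
      sum(W[, class] * colMeans(matrix(vals, u * v, K))) + b[class]
    g <- array(0, dim = dim(f))
    h <- 1e-4
    for (idx in seq_len(u * v * K)) {
      fp <- f; fp[idx] <- fp[idx] + h
      fm <- f; fm[idx] <- fm[idx] - h
      g[idx] <- (score_of(fp) - score_of(fm)) / (2 * h)
    }
    g
  }
  adapter <- model_adapter(forward, head_fn,
                           input_size = c(spec$input_size, spec$input_size),
                           gradients = gradients, id = "tiny_cnn")
  adapter$params <- params
  adapter$spec <- spec
  adapter
}

#' Train the fixture CNN on a synthetic dataset
#'
#' Minimizes the softmax cross-entropy with Adam over the training split,
#' deterministically for a fixed seed: weight initialization and the
#' per-epoch shuffling both derive from `seed`, samples are processed in
#' shuffled order within mini-batches, and all computation is
#' single-threaded. The defaults are calibrated once so the default
#' synthetic dataset reaches at least 0.95 test accuracy.
#'
#' @param dataset A [generate_dataset()] result with a non-empty train
#'   split.
#' @param seed Training seed.
#' @param epochs Number of epochs (0 evaluates the untrained network:
#'   accuracy sits at chance).
#' @param spec A [tiny_model_spec()].
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size (default 10).
#' @param cutout Side length of the random-erasing augmentation square
#'   (0 disables). Each training sample has a random patch overwritten
#'   with the image mean, discouraging the network from leaning on any
#'   single context location and pushing class evidence onto the
#'   (redundant) discriminative structure itself — the role ImageNet
#'   pretraining plays for a full-scale backbone.
#' @param verbose Print per-epoch loss and validation accuracy.
#' @return List with elements `adapter` (a [model_adapter()]), `params`,
#'   `spec` and `metrics` (`train_loss`, `val_accuracy`, `test_accuracy`,
#'   `epochs`).
#' @export
train_fixture_model <- function(dataset, seed = 1L, epochs = 30L,
                                spec = tiny_model_spec(), lr = 1e-3,
                                batch_size = 10L, cutout = 12L,
                                verbose = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            inherits(spec, "tiny_model_spec"))
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "val")
  te <- dataset_split(dataset, "test")
  n <- length(tr$images)
  if (n == 0L) stop_invalid("dataset has an empty training split")
  if (!all(dim(tr$images[[1L]]) == spec$input_size))
    stop_invalid("dataset image size does not match the model spec")

  .with_seed(seed, {
    params <- .init_params(spec)
    theta <- .param_vec(params)
    m <- numeric(length(theta)); v2 <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    last_loss <- NA_real_
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        grad <- numeric(length(theta))
        bl <- 0
        for (i in batch) {
          img <- tr$images[[i]]
          if (cutout > 0L) {
            r0 <- sample.int(nrow(img) - cutout + 1L, 1L)
            c0 <- sample.int(ncol(img) - cutout + 1L, 1L)
            img[r0:(r0 + cutout - 1L), c0:(c0 + cutout - 1L)] <- mean(img)
          }
          fwd <- .net_forward(params, img, spec, cache = TRUE)
          p <- .softmax(fwd$scores)
          y <- tr$labels[i]
          bl <- bl - log(max(p[y], 1e-12))
          ds <- p
          ds[y] <- ds[y] - 1
          grad <- grad + .param_vec(.net_backward(params, fwd, ds, spec))
        }
        grad <- grad / length(batch)
        t <- t + 1L
        m <- b1 * m + (1 - b1) * grad
        v2 <- b2 * v2 + (1 - b2) * grad^2
        theta <- theta - lr * (m / (1 - b1^t)) / (sqrt(v2 / (1 - b2^t)) + eps)
        params <- .vec_param(theta, params)
        losses <- c(losses, bl / length(batch))
      }
      last_loss <- mean(losses)
      if (verbose) {
        va_acc <- .dataset_accuracy(params, spec, va$images, va$labels)
        message(sprintf("epoch %2d  loss %.4f  val acc %.3f",
                        ep, last_loss, va_acc))
      }
    }
    metrics <- list(
      train_loss = last_loss,
      val_accuracy = .dataset_accuracy(params, spec, va$images, va$labels),
      test_accuracy = .dataset_accuracy(params, spec, te$images, te$labels),
      epochs = epochs)
    list(adapter = build_tiny_cnn(spec, params = params), params = params,
         spec = spec, metrics = metrics)
  })
}

#' Export the trained dense head as CSV
#'
#' Writes the GAP-to-output weight matrix and biases as plain CSV so the
#' mapping algorithms can run without the training machinery.
#'
#' @param head A [dense_head()].
#' @param weights_path,biases_path Output CSV paths.
#' @return Invisibly, the paths.
#' @export
export_dense_head <- function(head, weights_path, biases_path) {
  stopifnot(inherits(head, "dense_head"))
  utils::write.csv(head$weights, weights_path, row.names = FALSE)
  utils::write.csv(data.frame(bias = head$biases), biases_path,
                   row.names = FALSE)
  invisible(c(weights_path, biases_path))
}
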