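# The hand-checkable worked example used throughout: a 2 x 2 x 2 feature
# stack with identity head weights.
#   f_1 = [[1, 0], [0, 1]],  f_2 = [[0, 2], [0, 0]],  W = I_2, b = 0
toy_stack <- function() {
  feature_map_stack(array(c(1, 0, 0, 1,
                            0, 0, 2, 0), dim = c(2, 2, 2)), image_id = "toy")
}

toy_head <- function() dense_head(diag(2))

toy_crm_expected <- matrix(c(0.0625, 0, 0.25, 0.0625), 2, 2)

# random small instances for property tests
random_stack <- function(u = sample(1:8, 1), v = sample(1:8, 1),
                         K = sample(1:16, 1)) {
  feature_map_stack(array(rnorm(u * v * K), dim = c(u, v, K)))
}

random_head <- function(K, N = sample(2:7, 1)) {
  dense_head(matrix(rnorm(K * N), K, N), biases = rnorm(N))
}

# deterministic CAM-compatible adapter over a fixed random projection of
# 8 x 8 block means of a 16 x 16 image; channels are non-negative when
# `positive` so the CAM/Grad-CAM identity is exercisable
matrix_adapter <- function(K = 3L, N = 2L, seed = 99L, positive = FALSE) {
  set.seed(seed)
  W <- matrix(rnorm(K * N), K, N)
  if (positive) W <- abs(W)
  b <- rnorm(N)
  chans <- abs(matrix(rnorm(K * 3), K, 3))   # per-channel affine of block stats
  head <- dense_head(W, b)
  feat_fn <- function(image) {
    blocks <- matrix(0, 64, 3)  # 8x8 blocks of a 16x16 image
    idx <- 1L
    for (i in seq(1, 16, by = 2)) {
      for (j in seq(1, 16, by = 2)) {
        p <- image[i:(i + 1), j:(j + 1)]
        blocks[idx, ] <- c(mean(p), mean(p^2), max(p))
        idx <- idx + 1L
      }
    }
    vals <- blocks %*% t(chans)             # 64 x K, non-negative
    feature_map_stack(array(vals, dim = c(8, 8, K)))
  }
  model_adapter(
    forward = function(image) {
      fs <- feat_fn(image)
      list(features = fs, scores = compute_class_scores(fs, head))
    },
    head = function() head,
    input_size = c(16L, 16L),
    id = "matrix_adapter"
  )
}
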