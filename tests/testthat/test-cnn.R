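# naive direct convolution, the oracle for the compiled im2col kernels
naive_conv <- function(x, w4, b) {
  k <- dim(w4)[1]; p <- (k - 1) / 2
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w4)[4]
  out <- array(0, dim = c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (di in seq_len(k)) {
        for (dj in seq_len(k)) {
          ii <- seq_len(H) + di - 1 - p
          jj <- seq_len(W) + dj - 1 - p
          ok_i <- ii >= 1 & ii <= H
          ok_j <- jj >= 1 & jj <= W
          acc[ok_i, ok_j] <- acc[ok_i, ok_j] +
            w4[di, dj, ci, co] * x[ii[ok_i], jj[ok_j], ci]
        }
      }
    }
    out[, , co] <- acc
  }
  out
}

test_that("compiled convolution matches the naive oracle", {
  set.seed(141)
  for (rep in 1:5) {
    H <- sample(3:7, 1); W <- sample(3:7, 1)
    Cin <- sample(1:3, 1); Cout <- sample(1:4, 1)
    x <- array(rnorm(H * W * Cin), dim = c(H, W, Cin))
    w4 <- array(rnorm(9 * Cin * Cout), dim = c(3, 3, Cin, Cout))
    b <- rnorm(Cout)
    got <- crmap:::conv2d_forward(x, matrix(w4, 9 * Cin, Cout), b, 3L)
    expect_equal(got, naive_conv(x, w4, b), tolerance = 1e-12)
  }
})

test_that("convolution gradients pass a finite-difference check", {
  set.seed(151)
  H <- 4; W <- 5; Cin <- 2; Cout <- 3
  x <- array(rnorm(H * W * Cin), dim = c(H, W, Cin))
  w <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
  b <- rnorm(Cout)
  gy <- array(rnorm(H * W * Cout), dim = c(H, W, Cout))
  loss <- function(xx, ww, bb)
    sum(crmap:::conv2d_forward(xx, ww, bb, 3L) * gy)
  bw <- crmap:::conv2d_backward(x, w, gy, 3L)
  h <- 1e-6
  for (idx in sample(length(x), 12)) {
    up <- x; up[idx] <- up[idx] + h
    dn <- x; dn[idx] <- dn[idx] - h
    expect_equal(bw$gx[idx], (loss(up, w, b) - loss(dn, w, b)) / (2 * h),
                 tolerance = 1e-5)
  }
  for (idx in sample(length(w), 12)) {
    up <- w; up[idx] <- up[idx] + h
    dn <- w; dn[idx] <- dn[idx] - h
    expect_equal(bw$gw[idx], (loss(x, up, b) - loss(x, dn, b)) / (2 * h),
                 tolerance = 1e-5)
  }
  expect_equal(as.numeric(bw$gb),
               vapply(seq_len(Cout), function(co) sum(gy[, , co]), numeric(1)),
               tolerance = 1e-10)
})

test_that("max pooling selects maxima and routes gradients to them", {
  set.seed(161)
  x <- array(rnorm(6 * 8 * 2), dim = c(6, 8, 2))
  mp <- crmap:::maxpool2_forward(x)
  for (c in 1:2) {
    for (i in 1:3) {
      for (j in 1:4) {
        expect_equal(mp$y[i, j, c],
                     max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
      }
    }
  }
  gy <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
  gx <- crmap:::maxpool2_backward(mp$idx, gy, 6L, 8L)
  expect_equal(sum(gx != 0), 24L)        # one winner per pooling window
  expect_equal(sum(gx), sum(gy), tolerance = 1e-12)
})

test_that("the model spec enforces the CAM-compatible geometry", {
  spec <- tiny_model_spec()
  expect_identical(spec$feature_size, 8L)
  expect_identical(spec$feature_channels, 64L)
  expect_identical(spec$num_classes, 7L)
  expect_error(tiny_model_spec(input_size = 16L,
                               block_channels = c(4L, 8L, 16L)),
               class = "crmap_invalid_input")
})

test_that("an untrained network already satisfies the adapter contract", {
  spec <- tiny_model_spec(input_size = 32L, block_channels = c(4L, 8L),
                          feature_channels = 16L)
  ad <- build_tiny_cnn(spec, seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  ex <- extract(ad, img)
  expect_identical(dim(ex$features$values), c(8L, 8L, 16L))
  expect_identical(dim(ex$head$weights), c(16L, 7L))
  crm <- compute_crm(ex$features, ex$head)
  expect_true(all(is.finite(crm$values)) && all(crm$values >= 0))

  ex2 <- extract(ad, img)
  expect_identical(ex$features$values, ex2$features$values)
})

test_that("finite-difference adapter gradients reproduce alpha = w", {
  spec <- tiny_model_spec(input_size = 32L, block_channels = c(4L, 8L),
                          feature_channels = 8L, num_classes = 3L)
  ad <- build_tiny_cnn(spec, seed = 13)
  img <- matrix(runif(32 * 32), 32, 32)
  fs <- ad$forward(img)$features
  for (cl in c(1L, 3L)) {
    g <- ad$gradients(img, cl)
    a <- gradcam_weights(fs, gradients = g)
    expect_equal(a$alpha, ad$head()$weights[, cl], tolerance = 1e-5)
  }
})

test_that("training is deterministic and learns above chance", {
  ds <- small_dataset()
  spec <- tiny_model_spec(block_channels = c(4L, 8L, 16L),
                          feature_channels = 16L)
  f1 <- train_fixture_model(ds, seed = 2, epochs = 4, spec = spec)
  f2 <- train_fixture_model(ds, seed = 2, epochs = 4, spec = spec)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$params$dense$W, f2$params$dense$W)

  f0 <- train_fixture_model(ds, seed = 2, epochs = 0, spec = spec)
  expect_lt(abs(f0$metrics$test_accuracy - 1 / 7), 0.3)  # chance-level
  expect_gt(f1$metrics$train_loss, 0)

  empty <- generate_dataset(generator_config(
    images_per_class = c(train = 0L, val = 0L, test = 1L), seed = 3L))
  expect_error(train_fixture_model(empty, epochs = 1, spec = spec),
               class = "crmap_invalid_input")
})

test_that("the dense head exports to CSV and reads back exactly", {
  head <- random_head(5, N = 4)
  wp <- tempfile(fileext = ".csv"); bp <- tempfile(fileext = ".csv")
  export_dense_head(head, wp, bp)
  W <- as.matrix(utils::read.csv(wp))
  expect_equal(unname(W), unname(head$weights), tolerance = 1e-12)
  expect_equal(utils::read.csv(bp)$bias, head$biases, tolerance = 1e-12)
  unlink(c(wp, bp))
})
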