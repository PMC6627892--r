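test_that("CAM reproduces the worked example, preserving negatives", {
  cam <- compute_cam(toy_stack(), toy_head(), 1)
  expect_equal(cam$values, matrix(c(1, 0, 0, 1), 2, 2))
  expect_identical(cam$method, "CAM")

  zero_w <- dense_head(matrix(0, 2, 2))
  expect_equal(compute_cam(toy_stack(), zero_w, 1)$values, matrix(0, 2, 2))

  mixed <- dense_head(matrix(c(1, -1, 0, 1), 2, 2))  # w^1 = (1, -1)
  expect_equal(compute_cam(toy_stack(), mixed, 1)$values,
               matrix(c(1, 0, -2, 1), 2, 2))

  expect_error(compute_cam(toy_stack(), toy_head(), 3),
               class = "crmap_range_error")
  expect_error(compute_cam(toy_stack(), toy_head(), 0),
               class = "crmap_range_error")
})

test_that("analytic Grad-CAM weights equal the dense weight column", {
  a <- gradcam_weights(toy_stack(), head = toy_head(), class = 1)
  expect_equal(a$alpha, c(1, 0))
  zero_w <- dense_head(matrix(0, 2, 2))
  expect_equal(gradcam_weights(toy_stack(), head = zero_w, class = 2)$alpha,
               c(0, 0))
  expect_error(gradcam_weights(toy_stack()),
               class = "crmap_contract_violation")
})

test_that("gradient-route weights match the analytic route", {
  # independent route: finite differences of the score through the head
  set.seed(31)
  fm <- random_stack(u = 3, v = 4, K = 5)
  head <- random_head(5, N = 3)
  for (cl in 1:3) {
    g <- array(0, dim = c(3, 4, 5))
    h <- 1e-5
    for (idx in seq_len(length(g))) {
      up <- fm$values; up[idx] <- up[idx] + h
      dn <- fm$values; dn[idx] <- dn[idx] - h
      g[idx] <- (compute_class_scores(feature_map_stack(up), head)$scores[cl] -
                 compute_class_scores(feature_map_stack(dn), head)$scores[cl]) / (2 * h)
    }
    a_grad <- gradcam_weights(fm, gradients = g)
    a_ana <- gradcam_weights(fm, head = head, class = cl)
    expect_equal(a_grad$alpha, a_ana$alpha, tolerance = 1e-5)
  }
})

test_that("Grad-CAM applies ReLU to the weighted sum", {
  gm <- compute_gradcam(toy_stack(), c(1, -1))
  expect_equal(gm$values, matrix(c(1, 0, 0, 1), 2, 2))

  # with non-negative alpha and activations, Grad-CAM equals CAM exactly
  pos_head <- dense_head(matrix(c(0.5, 2, 1, 0), 2, 2))
  cam <- compute_cam(toy_stack(), pos_head, 1)
  gc <- compute_gradcam(toy_stack(),
                        gradcam_weights(toy_stack(), head = pos_head, class = 1))
  expect_identical(gc$values, cam$values)

  zero <- feature_map_stack(array(0, dim = c(2, 2, 2)))
  expect_equal(compute_gradcam(zero, c(1, 2))$values, matrix(0, 2, 2))
  expect_error(compute_gradcam(toy_stack(), c(1, 2, 3)),
               class = "crmap_contract_violation")
})

test_that("CRM closed form matches the worked example and special cases", {
  crm <- compute_crm(toy_stack(), toy_head())
  expect_equal(crm$values, toy_crm_expected)
  expect_identical(crm$target_class, "all")

  # single-output head: R = CAM^2 / (u v)^2
  set.seed(41)
  fm <- random_stack(u = 4, v = 3, K = 6)
  head1 <- dense_head(matrix(rnorm(6), 6, 1))
  expect_equal(compute_crm(fm, head1)$values,
               compute_cam(fm, head1, 1)$values^2 / (4 * 3)^2,
               tolerance = 1e-12)

  zero <- feature_map_stack(array(0, dim = c(2, 2, 2)))
  expect_equal(compute_crm(zero, toy_head())$values, matrix(0, 2, 2))
})

test_that("brute-force removal oracle agrees with the closed form", {
  expect_equal(brute_force_crm(toy_stack(), toy_head())$values,
               toy_crm_expected)

  set.seed(51)
  for (rep in 1:30) {
    fm <- random_stack()
    head <- random_head(fm$K)
    a <- compute_crm(fm, head)$values
    b <- brute_force_crm(fm, head)$values
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("CRM is local: removing an isolated element marks only it", {
  vals <- array(0, dim = c(5, 6, 3))
  vals[2, 4, ] <- c(1, -2, 0.5)
  fm <- feature_map_stack(vals)
  head <- random_head(3, N = 4)
  r <- compute_crm(fm, head)$values
  expect_true(r[2, 4] > 0)
  r[2, 4] <- 0
  expect_equal(r, matrix(0, 5, 6))
})

test_that("average_crm is the elementwise mean with validation", {
  m1 <- activation_map(matrix(c(0, 0, 2, 0), 2, 2), "CRM")
  m2 <- activation_map(matrix(c(2, 0, 0, 0), 2, 2), "CRM")
  avg <- average_crm(list(m1, m2), class_label = 3)
  expect_equal(avg$values, matrix(c(1, 0, 1, 0), 2, 2))
  expect_identical(avg$n_images, 2L)

  expect_equal(average_crm(list(m1, m1))$values, m1$values)   # idempotent
  expect_equal(average_crm(list(m1))$values, m1$values)       # n = 1
  expect_error(average_crm(list()), class = "crmap_invalid_input")
  expect_error(average_crm(list(m1, activation_map(matrix(0, 3, 3), "CRM"))),
               class = "crmap_contract_violation")
  expect_error(average_crm(list(compute_cam(toy_stack(), toy_head(), 1))),
               class = "crmap_contract_violation")
})

test_that("maps are scale-equivariant: CAM ~ alpha, CRM ~ alpha^2", {
  set.seed(61)
  for (rep in 1:10) {
    fm <- random_stack()
    head <- random_head(fm$K)
    alpha <- runif(1, 0.2, 4)
    fm2 <- feature_map_stack(fm$values * alpha)
    expect_equal(compute_cam(fm2, head, 1)$values,
                 alpha * compute_cam(fm, head, 1)$values, tolerance = 1e-9)
    expect_equal(compute_crm(fm2, head)$values,
                 alpha^2 * compute_crm(fm, head)$values, tolerance = 1e-9)
    # normalized maps are unchanged by positive scaling
    expect_equal(normalize_map(compute_crm(fm2, head))$values,
                 normalize_map(compute_crm(fm, head))$values, tolerance = 1e-9)
  }
})

test_that("maps are equivariant under spatial permutations", {
  set.seed(71)
  fm <- random_stack(u = 4, v = 5, K = 6)
  head <- random_head(6)
  perm <- sample(4 * 5)
  vals <- fm$values
  pvals <- array(apply(vals, 3, function(sl) matrix(as.vector(sl)[perm], 4, 5)),
                 dim = dim(vals))
  pfm <- feature_map_stack(pvals)
  for (fn in list(function(f) compute_cam(f, head, 2)$values,
                  function(f) compute_crm(f, head)$values)) {
    expect_equal(as.vector(fn(pfm)), as.vector(fn(fm))[perm], tolerance = 1e-12)
  }
})

test_that("average_crm commutes with scaling and ignores list order", {
  set.seed(81)
  maps <- lapply(1:4, function(i)
    activation_map(matrix(abs(rnorm(12)), 3, 4), "CRM"))
  a1 <- average_crm(maps)$values
  expect_equal(average_crm(rev(maps))$values, a1)
  scaled <- lapply(maps, function(m)
    activation_map(m$values * 2.5, "CRM"))
  expect_equal(average_crm(scaled)$values, 2.5 * a1, tolerance = 1e-12)
})
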