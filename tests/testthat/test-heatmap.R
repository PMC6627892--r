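test_that("normalization divides non-negative maps by their max", {
  nm <- normalize_map(activation_map(toy_crm_expected, "CRM"))
  expect_equal(nm$values, matrix(c(0.25, 0, 1, 0.25), 2, 2))

  zero <- normalize_map(activation_map(matrix(0, 3, 3), "CRM"))
  expect_equal(zero$values, matrix(0, 3, 3))

  expect_equal(normalize_map(nm)$values, nm$values)  # idempotent
})

test_that("negative-valued maps are min-max normalized, idempotently", {
  m <- matrix(c(-2, 0, 2, 6), 2, 2)
  nm <- normalize_map(activation_map(m, "CAM", target_class = 1))
  expect_equal(nm$values, matrix(c(0, 0.25, 0.5, 1), 2, 2))
  expect_equal(normalize_map(nm)$values, nm$values)
  expect_true(all(nm$values >= 0 & nm$values <= 1))
})

test_that("thresholding counts strict exceedances", {
  nm <- normalize_map(activation_map(toy_crm_expected, "CRM"))
  expect_equal(sum(threshold_map(nm, 0.2)$mask), 3L)
  m7 <- threshold_map(nm, 0.7)
  expect_equal(sum(m7$mask), 1L)
  expect_true(m7$mask[1, 2])

  expect_error(threshold_map(nm, 0), class = "crmap_range_error")
  expect_error(threshold_map(nm, 1), class = "crmap_range_error")
})

test_that("retained pixels are monotone non-increasing in the threshold", {
  set.seed(91)
  for (rep in 1:10) {
    nm <- normalize_map(activation_map(matrix(abs(rnorm(48)), 6, 8), "CRM"))
    fracs <- sort(runif(5, 0.05, 0.95))
    masks <- lapply(fracs, function(f) threshold_map(nm, f)$mask)
    for (i in seq_len(4)) {
      expect_true(all(masks[[i]] | !masks[[i + 1]]))  # superset relation
    }
    # the argmax always survives any fraction < 1
    expect_true(masks[[5]][which.max(nm$values)])
  }
})

test_that("upsampling preserves constants, range and identity size", {
  const <- normalize_map(activation_map(matrix(0.5, 2, 2) * 2, "CRM"))
  up <- upsample_map(const, c(7, 9))
  expect_equal(up$values, matrix(1, 7, 9))   # constant normalized to 1

  set.seed(101)
  nm <- normalize_map(activation_map(matrix(abs(rnorm(4)), 2, 2), "CRM"))
  up2 <- upsample_map(nm, c(4, 4))
  expect_true(all(up2$values >= min(nm$values) - 1e-12 &
                  up2$values <= max(nm$values) + 1e-12))
  expect_equal(upsample_map(nm, c(2, 2))$values, nm$values)
  expect_error(upsample_map(nm, c(1, 4)), class = "crmap_range_error")

  near <- upsample_map(nm, c(6, 6), method = "nearest")
  expect_true(all(near$values %in% nm$values))
})

test_that("normalize-upsample-threshold is invariant to positive scaling", {
  set.seed(111)
  raw <- matrix(abs(rnorm(20)), 4, 5)
  pipeline <- function(m) {
    nm <- upsample_map(normalize_map(activation_map(m, "CRM")), c(16, 20))
    threshold_map(nm, 0.2)$mask
  }
  expect_identical(pipeline(raw), pipeline(raw * 37.5))
})

test_that("overlays blend only suprathreshold pixels", {
  img <- matrix(runif(64), 8, 8)
  zero <- structure(list(values = matrix(0, 8, 8), method = "CRM",
                         size = c(8L, 8L)), class = "normalized_map")
  out <- render_overlay(img, zero)
  expect_equal(dim(out), c(8, 8, 3))
  for (ch in 1:3) expect_equal(out[, , ch], img)

  hot <- zero
  hot$values[3, 5] <- 1
  out2 <- render_overlay(img, hot)
  changed <- which(out2[, , 1] != img, arr.ind = TRUE)
  expect_equal(unname(changed[1, ]), c(3, 5))
  expect_equal(nrow(changed), 1L)

  expect_error(render_overlay(matrix(0, 4, 4), hot),
               class = "crmap_contract_violation")
})

test_that("class ROI bounding boxes hug the suprathreshold pixels", {
  m <- matrix(0, 4, 4)
  m[2, 2] <- 1
  m[3, 3] <- 0.9
  bb <- class_roi_bbox(m, 0.7)
  expect_equal(c(bb$row_min, bb$row_max, bb$col_min, bb$col_max), c(2, 3, 2, 3))

  m2 <- matrix(0, 5, 5); m2[4, 2] <- 3
  bb2 <- class_roi_bbox(m2, 0.7)
  expect_equal(c(bb2$row_min, bb2$row_max, bb2$col_min, bb2$col_max),
               c(4, 4, 2, 2))

  uni <- class_roi_bbox(matrix(1, 3, 6), 0.7)
  expect_equal(c(uni$row_min, uni$row_max, uni$col_min, uni$col_max),
               c(1, 3, 1, 6))

  expect_error(class_roi_bbox(matrix(0, 3, 3)), class = "crmap_invalid_input")
  expect_error(class_roi_bbox(matrix(1, 3, 3), 1.2), class = "crmap_range_error")
})

test_that("the bounding box contains the argmax pixel", {
  set.seed(121)
  for (rep in 1:10) {
    m <- matrix(abs(rnorm(63)), 7, 9)
    bb <- class_roi_bbox(m, runif(1, 0.3, 0.9))
    am <- which(m == max(m), arr.ind = TRUE)[1, ]
    expect_true(am[1] >= bb$row_min && am[1] <= bb$row_max &&
                am[2] >= bb$col_min && am[2] <= bb$col_max)
  }
})
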