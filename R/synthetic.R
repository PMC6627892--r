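# Synthetic seven-class "modality-like" image generator.
#
# Each class has a class-consistent discriminative structure at a known
# location (the ground-truth object mask) embedded in background clutter
# that is shared across classes, emulating the key property of medical
# modality datasets: high intra-class similarity of shapes or patterns,
# with class identity carried by a localized structure rather than by
# global image statistics. Class recipes (1-based labels):
#
#   1  elliptical ring with interior blobs        (CT-like)
#   2  two concentric lobed ellipses              (MRI-like)
#   3  bright sector/fan on a dark field          (ultrasound-like)
#   4  two side-by-side dark lobes, bright body   (chest-X-ray-like)
#   5  random bright speckles on a dark field     (fluorescence-like)
#   6  large disc with a small bright off-center
#      disc on a randomized side                  (fundus-like; the small
#                                                  disc plays the optic disc)
#   7  two perpendicular axis lines + a polyline  (statistical-graph-like)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic dataset generator configuration
#'
#' @param images_per_class Named integer vector: images per class for the
#'   `train`, `val` and `test` splits.
#' @param image_size Side length in pixels of the square grayscale images.
#' @param noise_level Standard deviation of the additive pixel noise.
#' @param rotation_range Structure rotation range in degrees.
#' @param shift_range Structure translation range in pixels (applied to
#'   both axes independently).
#' @param seed Master seed; every per-image seed derives from it, with
#'   disjoint seed ranges across splits so no image recurs between splits.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(images_per_class = c(train = 50L, val = 10L, test = 10L),
                             image_size = 64L,
                             noise_level = 0.05,
                             rotation_range = c(-5, 5),
                             shift_range = c(-3, 3),
                             seed = 42L) {
  if (!all(c("train", "val", "test") %in% names(images_per_class)))
    stop_invalid("'images_per_class' needs named entries train, val, test")
  if (any(images_per_class < 0L) || sum(images_per_class) == 0L)
    stop_invalid("at least one image must be requested")
  if (any(images_per_class > 4000L))
    stop_invalid("at most 4000 images per class per split are supported")
  if (image_size < 16L) stop_invalid("'image_size' must be at least 16")
  structure(
    list(images_per_class = images_per_class,
         image_size = as.integer(image_size),
         noise_level = noise_level,
         rotation_range = rotation_range, shift_range = shift_range,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

.n_classes <- 7L

# centered, shifted, rotated coordinate grids for a structure
.struct_grid <- function(s, theta, dx, dy) {
  x <- matrix(seq_len(s), s, s) - (s + 1) / 2 - dx   # rows
  y <- matrix(seq_len(s), s, s, byrow = TRUE) - (s + 1) / 2 - dy  # cols
  list(xr = cos(theta) * x - sin(theta) * y,
       yr = sin(theta) * x + cos(theta) * y)
}

.disc <- function(xr, yr, cx, cy, r) (xr - cx)^2 + (yr - cy)^2 <= r^2

# binary dilation with a disc structuring element, via the package's own
# convolution kernel; r in pixels
.dilate <- function(mask, r = 2L) {
  k <- 2L * r + 1L
  off <- seq_len(k) - r - 1L
  disc <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= r^2))
  hit <- conv2d_forward(array(as.numeric(mask), dim = c(dim(mask), 1L)),
                        matrix(disc, k * k, 1L), 0, k)
  hit[, , 1L] > 0.5
}

# separable Gaussian blur emulating the imaging chain's point-spread
# function; applied to every structure rendering so edges are soft
.psf_blur <- function(img, sigma = 1.2) {
  r <- ceiling(3 * sigma)
  kern <- exp(-(-r:r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)), , drop = FALSE]
  K <- length(kern)
  conv1 <- function(m) {
    out <- matrix(0, nrow(m) - K + 1L, ncol(m))
    for (i in seq_len(K)) out <- out + kern[i] * m[i:(i + nrow(out) - 1L), , drop = FALSE]
    out
  }
  img <- conv1(pad(img, r))              # rows
  img <- t(conv1(pad(t(img), r)))        # cols
  img
}

# recipe functions return list(img = structure-only image, mask = logical)
.recipe_ct <- function(s, g, scale) {
  a <- 0.36 * s * scale; b <- 0.30 * s * scale
  rho <- sqrt((g$xr / a)^2 + (g$yr / b)^2)
  img <- matrix(0.07, s, s)
  img[rho <= 1] <- 0.35
  img[rho <= 1 & rho >= 0.78] <- 0.85
  for (i in 1:3) {
    ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0.1, 0.5)
    img[.disc(g$xr / a, g$yr / b, rad * cos(ang), rad * sin(ang), 0.16)] <- 0.65
  }
  list(img = img, mask = rho <= 1)
}

.recipe_mri <- function(s, g, scale) {
  a <- 0.34 * s * scale; b <- 0.29 * s * scale
  phi <- atan2(g$yr / b, g$xr / a)
  lobe <- 1 + 0.18 * cos(2 * phi)
  rho <- sqrt((g$xr / a)^2 + (g$yr / b)^2) / lobe
  img <- matrix(0.07, s, s)
  img[rho <= 1] <- 0.75
  img[rho <= 0.55] <- 0.45
  img[rho <= 1 & rho >= 0.88] <- 0.9
  list(img = img, mask = rho <= 1)
}

.recipe_us <- function(s, g, scale) {
  # apex near the top edge; fan opens downward (in the rotated frame).
  # The near-field band at the apex is rendered bright, as under a real
  # transducer, and belongs to the fan structure.
  ax <- -0.38 * s; ay <- 0
  dxr <- g$xr - ax; dyr <- g$yr - ay
  ang <- atan2(dyr, dxr)          # 0 = straight down the rows
  rad <- sqrt(dxr^2 + dyr^2)
  # worst-case dilated mask area: 0.55*R^2 sector + 4 px rim = 0.588 < 0.60
  fan <- abs(ang) <= 0.55 & rad <= 0.78 * s * scale
  img <- matrix(0.07, s, s)
  # spatially correlated speckle (finite grain size, as in real B-mode
  # images): a coarse random field upsampled to pixel resolution, so the
  # texture survives the CNN's pooling instead of averaging out
  grain <- max(8L, round(s / 5))
  coarse <- matrix(runif(grain * grain, -0.3, 0.3), grain, grain)
  Ri <- .interp_matrix(s, grain, "bilinear")
  speck <- Ri %*% coarse %*% t(Ri)
  img[fan] <- 0.62 + speck[fan]
  near <- fan & rad <= 0.12 * s
  img[near] <- 0.9
  list(img = img, mask = fan)
}

.recipe_cxr <- function(s, g, scale) {
  # the discriminative structure is the whole two-dark-lobes-in-bright-frame
  # configuration, so the mask is the body ellipse (drawn without scale
  # jitter to keep its area fraction fixed at ~0.50)
  body <- sqrt((g$xr / (0.38 * s))^2 + (g$yr / (0.34 * s))^2) <= 1
  img <- matrix(0.07, s, s)
  img[body] <- 0.75
  off <- 0.17 * s * scale
  a <- 0.13 * s * scale; b <- 0.19 * s * scale
  lobes <- sqrt(((g$yr - off) / a)^2 + (g$xr / b)^2) <= 1 |
           sqrt(((g$yr + off) / a)^2 + (g$xr / b)^2) <= 1
  img[lobes] <- 0.15
  list(img = img, mask = body)
}

.recipe_fluor <- function(s, g, scale) {
  img <- matrix(0.07, s, s)
  mask <- matrix(FALSE, s, s)
  # soft-edged cell-scale blobs (like cells at low magnification, imaged
  # with a finite point-spread function); the mask is each blob's support,
  # i.e. wherever its contribution is still visible above the dark field
  n <- sample(4:7, 1)
  # budget each blob's worst-case dilated footprint (halo support is a
  # disc of radius <= 1.76 r, later dilated by 4 px) so the final mask can
  # never approach the 60% area cap, for any seed
  budget <- matrix(FALSE, s, s)
  for (i in seq_len(n)) {
    cx <- runif(1, -0.42, 0.42) * s; cy <- runif(1, -0.42, 0.42) * s
    r <- runif(1, 0.05, 0.07) * s * scale
    amp <- runif(1, 0.75, 1.0)
    big <- budget | .disc(g$xr, g$yr, cx, cy, 1.76 * r + 4.5)
    if (i > 1L && mean(big) > 0.55) break
    budget <- big
    d2 <- (g$xr - cx)^2 + (g$yr - cy)^2
    core <- d2 <= r^2
    halo <- exp(-pmax(sqrt(d2) - r, 0)^2 / (2 * (0.35 * r)^2))
    img <- pmax(img, amp * halo)
    img[core] <- amp
    mask <- mask | (amp * halo > 0.1)
  }
  list(img = img, mask = mask)
}

.recipe_fundus <- function(s, g, scale) {
  rho <- sqrt(g$xr^2 + g$yr^2) / (0.42 * s * scale)
  img <- matrix(0.07, s, s)
  img[rho <= 1] <- 0.45 * (1 - 0.35 * rho[rho <= 1])
  side <- sample(c(-1, 1), 1)   # optic-disc analogue lands on either side
  cy <- side * runif(1, 0.18, 0.24) * s
  cx <- runif(1, -0.08, 0.08) * s
  # disc diameter ~ a quarter of the fundus diameter, spanning 2-3 feature
  # map cells, comparable to the optic disc's share of a real fundus
  # photo; soft-edged, with the mask covering the disc's visible support
  r <- 0.115 * s * scale
  d2 <- (g$xr - cx)^2 + (g$yr - cy)^2
  halo <- exp(-pmax(sqrt(d2) - r, 0)^2 / (2 * 1.5^2))
  img <- pmax(img, halo)
  img[d2 <= r^2] <- 1.0
  list(img = img, mask = halo > 0.1)
}

.seg_dist <- function(xr, yr, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  tt <- ((xr - x1) * vx + (yr - y1) * vy) / (vx^2 + vy^2)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((xr - (x1 + tt * vx))^2 + (yr - (y1 + tt * vy))^2)
}

.recipe_graph <- function(s, g, scale) {
  # dark-theme rendering: bright strokes on the same dark field as the
  # imaging classes, so background statistics carry no class signal
  img <- matrix(0.07, s, s)
  # axes in the structure frame: vertical axis (constant y), horizontal
  # axis (constant x); drawn as thin dark bands
  y0 <- -0.34 * s; x0 <- 0.35 * s
  vert <- abs(g$yr - y0) <= 1.5 & g$xr >= -0.38 * s & g$xr <= x0 + 1.5
  horiz <- abs(g$xr - x0) <= 1.5 & g$yr >= y0 - 1.5 & g$yr <= 0.40 * s
  dist <- matrix(Inf, s, s)
  np <- 6L
  py <- seq(y0 + 0.06 * s, 0.38 * s, length.out = np)
  # data series as a bounded random walk: keeps the polyline's arc length
  # (hence the dilated mask area) bounded for every seed
  px <- numeric(np)
  px[1L] <- runif(1, -0.25, 0.20)
  for (i in 2L:np)
    px[i] <- min(max(px[i - 1L] + runif(1, -0.16, 0.16), -0.30), 0.26)
  px <- px * s * scale
  for (i in seq_len(np - 1L)) {
    dist <- pmin(dist, .seg_dist(g$xr, g$yr, px[i], py[i], px[i + 1L], py[i + 1L]))
  }
  curve <- dist <= 1.5
  img[vert | horiz | curve] <- 0.9
  # mask = drawn strokes dilated to the feature-map cell scale
  mask_v <- abs(g$yr - y0) <= 1.8 & g$xr >= -0.38 * s - 1.8 & g$xr <= x0 + 1.8
  mask_h <- abs(g$xr - x0) <= 1.8 & g$yr >= y0 - 1.8 & g$yr <= 0.40 * s + 1.8
  list(img = img, mask = mask_v | mask_h | dist <= 1.8)
}

.recipes <- list(.recipe_ct, .recipe_mri, .recipe_us, .recipe_cxr,
                 .recipe_fluor, .recipe_fundus, .recipe_graph)

#' Generate one synthetic class image
#'
#' Deterministic for a fixed `(class_label, seed)` pair. The structure's
#' position, rotation and scale are randomized within the configured
#' ranges; background clutter (faint blobs shared across all class
#' recipes plus Gaussian pixel noise) is added on top; pixel values are
#' clipped to `[0, 1]`. The returned ground-truth mask marks the
#' class-discriminative structure and always covers between 2% and 60% of
#' the image area.
#'
#' @param class_label Integer in `1..7` (see the recipe table in the
#'   package source / vignette).
#' @param seed Integer seed for this image.
#' @param size Image side length (default 64).
#' @param noise_level Additive Gaussian noise standard deviation.
#' @param rotation_range,shift_range Structure perturbation ranges
#'   (degrees; pixels).
#' @return An object of class `synthetic_image` with elements `pixels`
#'   (matrix in `[0, 1]`), `class_label`, `object_mask` (logical matrix),
#'   `seed`.
#' @export
generate_class_image <- function(class_label, seed, size = 64L,
                                 noise_level = 0.05,
                                 rotation_range = c(-5, 5),
                                 shift_range = c(-3, 3)) {
  if (length(class_label) != 1L || !class_label %in% seq_len(.n_classes))
    stop_range(sprintf("class_label must be an integer in 1..%d", .n_classes))
  s <- as.integer(size)
  .with_seed(seed, {
    theta <- runif(1, rotation_range[1L], rotation_range[2L]) * pi / 180
    dx <- runif(1, shift_range[1L], shift_range[2L])
    dy <- runif(1, shift_range[1L], shift_range[2L])
    scale <- runif(1, 0.88, 1.12)
    g <- .struct_grid(s, theta, dx, dy)
    rec <- .recipes[[class_label]](s, g, scale)
    img <- rec$img
    # clutter common to all classes: faint blobs that a classifier must
    # learn to ignore
    for (i in 1:3) {
      bx <- runif(1, -0.45, 0.45) * s; by <- runif(1, -0.45, 0.45) * s
      br <- runif(1, 0.06, 0.12) * s
      blob <- exp(-((g$xr - bx)^2 + (g$yr - by)^2) / (2 * br^2))
      img <- img + 0.12 * blob
    }
    img <- .psf_blur(img)
    img <- img + matrix(rnorm(s * s, 0, noise_level), s, s)
    img <- pmin(pmax(img, 0), 1)
    # ground truth = drawn structure dilated by half a feature-map cell
    # (4 px at the default stride of 8): the localization tolerance
    # inherent to saliency maps computed at map resolution, in the spirit
    # of the pointing game's tolerance margin
    rec$mask <- .dilate(rec$mask, 4L)
    frac <- mean(rec$mask)
    if (frac < 0.02 || frac > 0.60)
      stop_contract(sprintf(
        "mask area fraction %.3f outside [0.02, 0.60] (class %d, seed %d)",
        frac, class_label, seed))
    structure(
      list(pixels = img, class_label = as.integer(class_label),
           object_mask = rec$mask, seed = as.integer(seed)),
      class = "synthetic_image"
    )
  })
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image class %d, %d x %d, mask %.1f%%, seed %d>\n",
              x$class_label, nrow(x$pixels), ncol(x$pixels),
              100 * mean(x$object_mask), x$seed))
  invisible(x)
}

.image_seed <- function(master, split_idx, class_label, i) {
  base <- master %% 19991L
  base * 100000L + (split_idx - 1L) * 30000L + (class_label - 1L) * 4000L + i
}

#' Generate a synthetic train/val/test dataset
#'
#' Produces per-class images for each split with a manifest. Per-image
#' seeds are derived from the master seed with disjoint ranges per split,
#' so two runs with the same master seed give identical datasets and no
#' image is duplicated across splits.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional directory; when given, images and masks are written
#'   as PGM under `dir/images` and `dir/masks` plus a `manifest.csv`.
#' @return An object of class `synthetic_dataset`: `images` (named list of
#'   `synthetic_image`), `manifest` (data frame with columns `id`, `path`,
#'   `mask_path`, `class`, `split`, `seed`), `config`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  splits <- c("train", "val", "test")
  images <- list()
  rows <- list()
  for (si in seq_along(splits)) {
    split <- splits[si]
    n <- cfg$images_per_class[[split]]
    for (cl in seq_len(.n_classes)) {
      for (i in seq_len(n)) {
        sd <- .image_seed(cfg$seed, si, cl, i)
        im <- generate_class_image(cl, sd, size = cfg$image_size,
                                   noise_level = cfg$noise_level,
                                   rotation_range = cfg$rotation_range,
                                   shift_range = cfg$shift_range)
        id <- sprintf("%s_c%d_%03d", split, cl, i)
        images[[id]] <- im
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, path = NA_character_, mask_path = NA_character_,
          class = cl, split = split, seed = sd, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- structure(list(images = images, manifest = manifest, config = cfg),
                  class = "synthetic_dataset")
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(nrow(manifest))) {
      id <- manifest$id[j]
      p <- file.path(dir, "images", paste0(id, ".pgm"))
      mp <- file.path(dir, "masks", paste0(id, ".pgm"))
      write_pgm(images[[id]]$pixels, p)
      write_pgm(images[[id]]$object_mask, mp)
      manifest$path[j] <- p
      manifest$mask_path[j] <- mp
    }
    ds$manifest <- manifest
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset %d images (%s), %d x %d, master seed %d>\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$split)),
                            table(x$manifest$split)), collapse = ", "),
              x$config$image_size, x$config$image_size, x$config$seed))
  invisible(x)
}

#' Extract one split of a dataset as plain lists
#'
#' @param ds A [generate_dataset()] result.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return List with `images` (list of matrices), `labels` (integer
#'   vector), `masks` (list of logical matrices), `ids`.
#' @export
dataset_split <- function(ds, split = c("train", "val", "test")) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  split <- match.arg(split)
  ids <- ds$manifest$id[ds$manifest$split == split]
  list(images = lapply(ds$images[ids], `[[`, "pixels"),
       labels = vapply(ds$images[ids], `[[`, integer(1), "class_label"),
       masks = lapply(ds$images[ids], `[[`, "object_mask"),
       ids = ids)
}

#' Read a dataset written by [generate_dataset()] back from disk
#'
#' @param dir Directory containing `manifest.csv`, `images/`, `masks/`.
#' @return A `synthetic_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  images <- list()
  for (j in seq_len(nrow(mf))) {
    images[[mf$id[j]]] <- structure(
      list(pixels = read_pgm(file.path(dir, "images", paste0(mf$id[j], ".pgm"))),
           class_label = mf$class[j],
           object_mask = read_pgm(file.path(dir, "masks", paste0(mf$id[j], ".pgm"))) > 0.5,
           seed = mf$seed[j]),
      class = "synthetic_image")
  }
  structure(list(images = images, manifest = mf, config = NULL),
            class = "synthetic_dataset")
}
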