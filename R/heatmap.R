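#' Normalize an activation map to [0, 1]
#'
#' CRM and Grad-CAM maps are non-negative and are divided by their
#' maximum. A map containing negative values (CAM can) is min-max
#' normalized — the standard display convention for class activation
#' maps, under which the zero level lands at mid-gray rather than being
#' clipped away. The two rules coincide whenever the minimum is zero, so
#' identical raw maps are always treated identically. An identically zero
#' map stays zero — no division takes place. Rendering to the 8-bit range
#' [0, 255] is a display concern handled at write time; the normalized map
#' itself lives on [0, 1].
#'
#' @param m An [activation_map()], `average_map`, or plain numeric matrix.
#' @return An object of class `normalized_map` with elements `values`
#'   (matrix in `[0, 1]`), `method` and `size`.
#' @export
normalize_map <- function(m) {
  method <- "unknown"
  if (inherits(m, "activation_map")) {
    method <- m$method
    m <- m$values
  } else if (inherits(m, "average_map")) {
    method <- "CRM"
    m <- m$values
  } else if (inherits(m, "normalized_map")) {
    method <- m$method
    m <- m$values
  }
  if (!is.matrix(m) || any(!is.finite(m)))
    stop_invalid("map values must form a finite numeric matrix")
  mn <- min(m)
  mx <- max(m)
  if (mn < 0) {
    m <- if (mx > mn) (m - mn) / (mx - mn) else matrix(0, nrow(m), ncol(m))
  } else if (mx > 0) {
    m <- m / mx
  }
  structure(list(values = m, method = method, size = dim(m)),
            class = "normalized_map")
}

#' @export
print.normalized_map <- function(x, ...) {
  cat(sprintf("<normalized_map %s, %d x %d>\n", x$method, x$size[1L], x$size[2L]))
  invisible(x)
}

#' Threshold a normalized map into an ROI mask
#'
#' Retains pixels whose normalized value strictly exceeds
#' `fraction` (the display convention "above 20\% of the max score" with
#' the default `fraction = 0.2`). The retained-pixel count is monotone
#' non-increasing in `fraction`.
#'
#' @param nm A [normalize_map()] result.
#' @param fraction Relative threshold in `(0, 1)`.
#' @return An object of class `roi_mask` with elements `mask` (logical
#'   matrix), `threshold_fraction` and `resolution`.
#' @export
threshold_map <- function(nm, fraction = 0.2) {
  stopifnot(inherits(nm, "normalized_map"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_range("'fraction' must lie strictly inside (0, 1)")
  structure(
    list(mask = nm$values > fraction, threshold_fraction = fraction,
         resolution = dim(nm$values)),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %d x %d, %d pixels above %.2f>\n",
              x$resolution[1L], x$resolution[2L], sum(x$mask),
              x$threshold_fraction))
  invisible(x)
}

# Interpolation matrix from n_in source samples to n_out output samples
# using the half-pixel-center convention (source cell i covers the output
# span ((i-1)*n_out/n_in, i*n_out/n_in] and is sampled at its center), so
# an upsampled map stays registered with the receptive-field patch each
# source cell summarizes. Each output row has at most two nonzero weights.
.interp_matrix <- function(n_out, n_in, method) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    A[, 1L] <- 1
    return(A)
  }
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(floor(pos + 0.5), 1L), n_in)
    A[cbind(seq_len(n_out), idx)] <- 1
  } else {
    lo <- pmin(floor(pos), n_in - 1L)
    w <- pos - lo
    A[cbind(seq_len(n_out), lo)] <- 1 - w
    A[cbind(seq_len(n_out), lo + 1L)] <- A[cbind(seq_len(n_out), lo + 1L)] + w
  }
  A
}

#' Upsample a normalized map to input-image resolution
#'
#' Bilinear interpolation by default (endpoints aligned with the map
#' corners), with nearest-neighbor available for mask-exact tests. Output
#' values stay within the input's `[min, max]`; constant maps stay
#' constant; upsampling to the source size is the identity.
#'
#' @param nm A [normalize_map()] result.
#' @param target Integer `c(height, width)`, each at least the source size.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A `normalized_map` at the target resolution.
#' @export
upsample_map <- function(nm, target, method = c("bilinear", "nearest")) {
  stopifnot(inherits(nm, "normalized_map"))
  method <- match.arg(method)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < dim(nm$values)))
    stop_range("'target' must be c(height, width) >= the source dimensions")
  v <- nm$values
  R <- .interp_matrix(target[1L], nrow(v), method)
  C <- .interp_matrix(target[2L], ncol(v), method)
  out <- R %*% v %*% t(C)
  # guard against interpolation rounding drifting a hair outside [0, 1]
  out <- pmin(pmax(out, 0), 1)
  structure(list(values = out, method = nm$method, size = dim(out)),
            class = "normalized_map")
}

# jet-style colormap: blue -> cyan -> yellow -> red, v in [0,1]
.jet <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

#' Render a heatmap overlay on an image
#'
#' Alpha-blends a jet-style colormap (red = high relevance) over the input
#' image. Pixels at or below `threshold` are fully transparent, so an
#' all-zero map returns the input unchanged.
#'
#' @param image Numeric matrix (grayscale in `[0, 1]`) or `H x W x 3`
#'   array.
#' @param nm A [normalize_map()] result already upsampled to the image
#'   size.
#' @param threshold Transparency cutoff (default 0.2, the display
#'   threshold).
#' @param alpha Blend weight of the heatmap over the image.
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @export
render_overlay <- function(image, nm, threshold = 0.2, alpha = 0.5) {
  stopifnot(inherits(nm, "normalized_map"))
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop_invalid("'image' must be a grayscale matrix or an H x W x 3 array")
  if (!all(dim(image)[1:2] == dim(nm$values)))
    stop_contract("heatmap must be upsampled to the image size before overlay")
  v <- nm$values
  hot <- v > threshold
  col <- .jet(as.vector(v))
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[hot] <- (1 - alpha) * plane[hot] +
      alpha * matrix(col[, ch], nrow(v), ncol(v))[hot]
    out[, , ch] <- plane
  }
  pmin(pmax(out, 0), 1)
}

#' Class-level ROI bounding box
#'
#' The class-level ROI is the set of pixels whose class-averaged CRM score
#' strictly exceeds `fraction` of the map maximum (default 70%); the
#' bounding box is the single tight axis-aligned hull of all such pixels.
#'
#' @param am An `average_map`, [normalize_map()] result, or numeric matrix
#'   with a nonzero maximum.
#' @param fraction Relative threshold in `(0, 1)`, default `0.7`.
#' @return An object of class `bounding_box` with 1-based inclusive fields
#'   `row_min`, `row_max`, `col_min`, `col_max`.
#' @export
class_roi_bbox <- function(am, fraction = 0.7) {
  if (inherits(am, "average_map") || inherits(am, "normalized_map")) am <- am$values
  if (!is.matrix(am) || any(!is.finite(am)))
    stop_invalid("map values must form a finite numeric matrix")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_range("'fraction' must lie strictly inside (0, 1)")
  mx <- max(am)
  if (mx <= 0) stop_invalid("empty ROI: map has no positive values")
  sel <- which(am > fraction * mx, arr.ind = TRUE)
  structure(
    list(row_min = min(sel[, 1L]), row_max = max(sel[, 1L]),
         col_min = min(sel[, 2L]), col_max = max(sel[, 2L]),
         threshold_fraction = fraction),
    class = "bounding_box"
  )
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box rows [%d, %d], cols [%d, %d]>\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

# 0-based inclusive serialization used by JSON sidecars
.bbox_as_list <- function(b) {
  list(row_min = b$row_min - 1L, row_max = b$row_max - 1L,
       col_min = b$col_min - 1L, col_max = b$col_max - 1L)
}

#' Draw a bounding box outline onto an RGB image
#'
#' @param image `H x W x 3` numeric array.
#' @param bbox A [class_roi_bbox()] result.
#' @param color Length-3 RGB vector in `[0, 1]`.
#' @return The image with a 1-pixel box outline burned in.
#' @export
draw_bbox <- function(image, bbox, color = c(0, 1, 0)) {
  stopifnot(inherits(bbox, "bounding_box"))
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  r <- bbox$row_min:bbox$row_max
  c <- bbox$col_min:bbox$col_max
  for (ch in 1:3) {
    image[c(bbox$row_min, bbox$row_max), c, ch] <- color[ch]
    image[r, c(bbox$col_min, bbox$col_max), ch] <- color[ch]
  }
  image
}
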