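#' ROI size statistics over a set of masks
#'
#' Mean number of retained pixels per image and its ratio to the total
#' pixel count, across all ROI masks of one class and method — the ROI
#' size accounting performed at input-image resolution.
#'
#' @param masks List of [threshold_map()] results, all at one resolution.
#' @param class_label Class the masks belong to.
#' @param method Mapping method that produced the masks.
#' @return An object of class `roi_stats` with fields `method`,
#'   `class_label`, `mean_pixel_count`, `mean_ratio`, `n_images`.
#' @export
roi_pixel_stats <- function(masks, class_label = NA, method = NA) {
  if (!is.list(masks) || length(masks) == 0L)
    stop_invalid("'masks' must be a non-empty list of roi_mask objects")
  for (m in masks) if (!inherits(m, "roi_mask"))
    stop_invalid("every element of 'masks' must be an roi_mask")
  res <- masks[[1L]]$resolution
  for (m in masks[-1L]) if (!all(m$resolution == res))
    stop_contract("all masks must share one resolution")
  counts <- vapply(masks, function(m) sum(m$mask), numeric(1))
  structure(
    list(method = method, class_label = class_label,
         mean_pixel_count = mean(counts),
         mean_ratio = mean(counts) / prod(res),
         n_images = length(masks)),
    class = "roi_stats"
  )
}

#' Pooled mapping-score distribution
#'
#' Pools every pixel of every normalized map (all values, background
#' included) and reports the sample mean and the population standard
#' deviation (denominator `n`; at pooled-pixel sample sizes the choice is
#' immaterial, it is fixed for determinism).
#'
#' @param maps List of [normalize_map()] results.
#' @param class_label Class the maps belong to.
#' @param method Mapping method that produced the maps.
#' @return An object of class `score_distribution` with fields `method`,
#'   `class_label`, `mean`, `std`, `n_values`.
#' @export
score_distribution <- function(maps, class_label = NA, method = NA) {
  if (!is.list(maps) || length(maps) == 0L)
    stop_invalid("'maps' must be a non-empty list of normalized_map objects")
  for (m in maps) if (!inherits(m, "normalized_map"))
    stop_invalid("every element of 'maps' must be a normalized_map")
  x <- unlist(lapply(maps, function(m) as.vector(m$values)))
  mu <- mean(x)
  structure(
    list(method = method, class_label = class_label,
         mean = mu, std = sqrt(mean((x - mu)^2)), n_values = length(x)),
    class = "score_distribution"
  )
}

.map_methods <- c("CAM", "GradCAM", "CRM")

# one normalized, upsampled-to-image-resolution map for one method
.method_map <- function(method, features, head, pred, target, upsample) {
  raw <- switch(method,
    CAM = compute_cam(features, head, pred),
    GradCAM = compute_gradcam(
      features, gradcam_weights(features, head = head, class = pred)),
    CRM = compute_crm(features, head)
  )
  upsample_map(normalize_map(raw), target, method = upsample)
}

#' Compare mapping methods over an image set
#'
#' Drives the full localization-evaluation machinery: for every image the
#' adapter is run once, each selected method's map is computed (CAM and
#' Grad-CAM target the predicted class; CRM aggregates all classes),
#' normalized at map resolution, upsampled to input resolution, and
#' thresholded. Results are summarized per class and method as ROI size
#' statistics and pooled score distributions. Deterministic given a fixed
#' adapter and inputs.
#'
#' @param adapter A [model_adapter()].
#' @param images List of grayscale image matrices.
#' @param labels Class label per image (same length as `images`).
#' @param methods Subset of `c("CAM", "GradCAM", "CRM")`.
#' @param display_threshold Relative ROI threshold (default 0.2).
#' @param upsample `"bilinear"` or `"nearest"`.
#' @return A `data.frame` with one row per class and method: columns
#'   `class`, `method`, `n_images`, `mean_pixels`, `mean_ratio`,
#'   `score_mean`, `score_std`.
#' @export
compare_methods <- function(adapter, images, labels,
                            methods = .map_methods,
                            display_threshold = 0.2,
                            upsample = c("bilinear", "nearest")) {
  stopifnot(inherits(adapter, "model_adapter"))
  upsample <- match.arg(upsample)
  if (!is.list(images) || length(images) == 0L)
    stop_invalid("'images' must be a non-empty list of image matrices")
  if (length(labels) != length(images))
    stop_invalid("'labels' must have one entry per image")
  bad <- setdiff(methods, .map_methods)
  if (length(bad))
    stop_range(paste("unknown method(s):", paste(bad, collapse = ", ")))

  per <- list()  # [[class]][[method]] -> list(masks, maps)
  for (i in seq_along(images)) {
    img <- images[[i]]
    ex <- extract(adapter, img)
    pred <- ex$scores$predicted_class
    for (method in methods) {
      nm <- .method_map(method, ex$features, ex$head, pred, dim(img), upsample)
      key <- paste(labels[[i]], method, sep = "\r")
      slot <- per[[key]]
      if (is.null(slot)) slot <- list(masks = list(), maps = list())
      slot$masks[[length(slot$masks) + 1L]] <- threshold_map(nm, display_threshold)
      slot$maps[[length(slot$maps) + 1L]] <- nm
      per[[key]] <- slot
    }
  }

  rows <- lapply(names(per), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    st <- roi_pixel_stats(per[[key]]$masks, parts[1L], parts[2L])
    sd <- score_distribution(per[[key]]$maps, parts[1L], parts[2L])
    data.frame(class = parts[1L], method = parts[2L],
               n_images = st$n_images,
               mean_pixels = st$mean_pixel_count,
               mean_ratio = st$mean_ratio,
               score_mean = sd$mean, score_std = sd$std,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$class, match(out$method, .map_methods)), , drop = FALSE]
}

#' Write a method-comparison report
#'
#' Serializes a [compare_methods()] table as CSV and/or JSON.
#'
#' @param report Data frame from [compare_methods()].
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(report)
}
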