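#' Build a per-region mask
#'
#' A region mask bundles a binary mask `B`, an optional soft pixel-level mask
#' `P` in [0, 1], and the four mask-level constants `a, c, d, f` that control
#' how the two are fused by [combine_mask()]. With the defaults
#' `a = 1, c = 0, d = 0, f = 1` the combined mask reduces to the binary mask.
#'
#' @param region Region name, one of [SPINAL_REGIONS].
#' @param binary Logical or 0/1 numeric matrix.
#' @param pixel Optional numeric matrix in [0, 1], same shape; defaults to
#'   zeros.
#' @param a,c,d,f Mask-fusion constants; `f` must be > 0. They can be tuned
#'   per dataset; the defaults give pure binary masking.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(region, binary, pixel = NULL,
                        a = 1, c = 0, d = 0, f = 1) {
  region <- match.arg(region, SPINAL_REGIONS)
  if (is.logical(binary)) binary <- binary * 1
  check_image(binary, "binary")
  if (!all(binary %in% c(0, 1))) {
    stop_invalid("`binary` must contain only 0/1 values", field = "binary")
  }
  pixel <- pixel %||% matrix(0, nrow(binary), ncol(binary))
  check_image(pixel, "pixel")
  check_same_shape(binary, pixel, c("binary", "pixel"))
  if (any(pixel < 0 | pixel > 1)) {
    stop_invalid("`pixel` values must lie in [0, 1]", field = "pixel")
  }
  if (f <= 0) stop_invalid("`f` must be > 0", field = "f")
  structure(
    list(region = region, binary = binary, pixel = pixel,
         a = a, c = c, d = d, f = f),
    class = "region_mask"
  )
}

#' Fuse the binary and soft masks of a region
#'
#' Computes, elementwise, `a * B + c * P^f + d^f`. The constant offset `d^f`
#' applies everywhere, so callers that need a zero-outside-support mask should
#' keep `d = 0` (the default).
#'
#' @param mask A [region_mask()].
#' @return Numeric matrix of non-negative combined mask values.
#' @examples
#' m <- region_mask("lumbar", matrix(1, 2, 2), matrix(0.5, 2, 2),
#'                  a = 1, c = 1, d = 1, f = 2)
#' combine_mask(m)[1, 1] # 1 + 0.25 + 1 = 2.25
#' @export
combine_mask <- function(mask) {
  if (!inherits(mask, "region_mask")) {
    stop_invalid("`mask` must be a region_mask", field = "mask")
  }
  combined <- mask$a * mask$binary + mask$c * mask$pixel^mask$f + mask$d^mask$f
  if (any(!is.finite(combined)) || any(combined < 0)) {
    stop_invalid("combined mask must be finite and non-negative")
  }
  combined
}

#' Extract one region's segment image from a saliency map
#'
#' Each contributing mask adds `log(1 + SMI * combined)` elementwise, where
#' `SMI` is the saliency map. The `log1p` form is zero exactly where the
#' combined mask (or the saliency map) is zero and preserves ordering of the
#' masked responses, so segment support never leaks outside mask support.
#'
#' @param saliency A `saliency_result` (or a numeric saliency-map matrix).
#' @param masks A [region_mask()] or a list of them contributing to the same
#'   region.
#' @return Numeric matrix, the segment image (non-negative).
#' @export
segment_region <- function(saliency, masks) {
  smi <- if (inherits(saliency, "saliency_result")) saliency$saliency_map else saliency
  check_image(smi, "saliency")
  if (inherits(masks, "region_mask")) masks <- list(masks)
  out <- matrix(0, nrow(smi), ncol(smi))
  for (m in masks) {
    combined <- combine_mask(m)
    check_same_shape(smi, combined, c("saliency", "mask"))
    out <- out + log1p(smi * combined)
  }
  out
}

#' Segment a saliency map into the five spinal regions
#'
#' Applies [segment_region()] per region and counts each segment's nonzero
#' pixels. Binary mask supports must be pairwise disjoint; overlaps are an
#' error naming the offending regions.
#'
#' @param saliency A `saliency_result`.
#' @param masks List of five [region_mask()] objects, one per region (any
#'   order; matched by the mask's own `region` field).
#' @return An object of class `region_segmentation`: list with `segments`
#'   (named list of matrices) and `pixel_counts` (named integer vector).
#' @export
segment_all_regions <- function(saliency, masks) {
  if (length(masks) != 5L) {
    stop_invalid("`masks` must contain exactly five region masks", field = "masks")
  }
  regions <- vapply(masks, function(m) m$region, character(1))
  if (!setequal(regions, SPINAL_REGIONS)) {
    stop_invalid("`masks` must cover each spinal region exactly once", field = "masks")
  }
  masks <- masks[match(SPINAL_REGIONS, regions)]
  cover <- Reduce(`+`, lapply(masks, function(m) m$binary))
  if (any(cover > 1)) {
    bad <- which(cover > 1, arr.ind = TRUE)[1, ]
    offenders <- SPINAL_REGIONS[vapply(masks, function(m) m$binary[bad[1], bad[2]] > 0,
                                       logical(1))]
    stop_invalid(sprintf("binary masks overlap (regions: %s)",
                         paste(offenders, collapse = ", ")))
  }
  segments <- purrr::map(masks, ~ segment_region(saliency, .x))
  names(segments) <- SPINAL_REGIONS
  counts <- vapply(segments, function(s) sum(s > 0), integer(1))
  structure(
    list(segments = segments, pixel_counts = counts),
    class = "region_segmentation"
  )
}

#' Ground-truth region masks from a phantom label map
#'
#' @param labels Integer label map (0 background, 1-5 regions).
#' @param ... Mask constants passed to [region_mask()].
#' @return List of five [region_mask()] objects in anatomical order.
#' @export
masks_from_labels <- function(labels, ...) {
  purrr::map(seq_len(5), function(i) {
    region_mask(SPINAL_REGIONS[i], labels == i, ...)
  })
}

#' Fit a per-pixel region classifier
#'
#' Learns to classify every pixel into background or one of the five spinal
#' regions from simple per-pixel features (intensity, normalized row and
#' column position, 3x3 local mean intensity). A decision tree is used: the
#' phantom geometry is axis-aligned in exactly these features, the fit is
#' fast, and it is deterministic (no cross-validation resampling). The fit is
#' the desk-scale stand-in for a heavier region-proposal backend and sits
#' behind this interface so one can be plugged in.
#'
#' @param samples List of `phantom_sample` objects (>= 2) with label maps.
#' @param config List of training settings: `seed` (sub-sampling seed,
#'   default 1), `pixels_per_sample` (default 1500), `cp` (tree complexity,
#'   default 1e-4), `minsplit` (default 5).
#' @return An object of class `pixel_classifier`.
#' @export
fit_pixel_classifier <- function(samples, config = list()) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop_invalid("need at least 2 training samples", field = "samples")
  }
  seed <- config$seed %||% 1L
  per_sample <- config$pixels_per_sample %||% 1500L
  cp <- config$cp %||% 1e-4
  minsplit <- config$minsplit %||% 5L

  sub_seeds <- derive_seeds(seed, length(samples))
  df <- purrr::map2_dfr(samples, sub_seeds, function(s, ss) {
    feats <- pixel_features(s$image)
    feats$label <- factor(label_levels()[as.vector(s$region_labels) + 1L],
                          levels = label_levels())
    n_take <- min(per_sample, nrow(feats))
    withr::with_seed(ss, feats[sample.int(nrow(feats), n_take), ])
  })
  if (length(unique(df$label)) < 2L) {
    stop_invalid("training labels contain a single class; cannot fit a pixel classifier")
  }
  fit <- rpart::rpart(
    label ~ intensity + row_frac + col_frac + local_mean,
    data = df, method = "class",
    control = rpart::rpart.control(cp = cp, minsplit = minsplit, xval = 0)
  )
  structure(list(fit = fit, config = list(seed = seed, cp = cp,
                                          minsplit = minsplit)),
            class = "pixel_classifier")
}

# per-pixel feature tibble for an intensity matrix
pixel_features <- function(image) {
  h <- nrow(image); w <- ncol(image)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- image
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + padded[(1:h) + dr, (1:w) + dc]
  }
  tibble(
    intensity = as.vector(image),
    row_frac = rep((seq_len(h) - 0.5) / h, times = w),
    col_frac = rep((seq_len(w) - 0.5) / w, each = h),
    local_mean = as.vector(acc / 9)
  )
}

#' Predict the five region masks for a slice
#'
#' Scores every pixel with the fitted classifier and assigns it to the class
#' with the highest posterior; ties break toward the earlier class in fixed
#' order (background first, then cervical to coccygeal), which makes the
#' prediction deterministic and the five masks disjoint by construction.
#'
#' @param predictor A [fit_pixel_classifier()] result.
#' @param image Intensity matrix.
#' @param ... Mask constants passed to [region_mask()].
#' @return List of five [region_mask()] objects in anatomical order.
#' @export
predict_masks <- function(predictor, image, ...) {
  if (!inherits(predictor, "pixel_classifier")) {
    stop_invalid("`predictor` must be a pixel_classifier", field = "predictor")
  }
  check_image(image)
  feats <- pixel_features(image)
  prob <- predict(predictor$fit, newdata = feats, type = "prob")
  prob <- prob[, intersect(label_levels(), colnames(prob)), drop = FALSE]
  cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  purrr::map(seq_len(5), function(i) {
    mat <- matrix(cls == SPINAL_REGIONS[i], nrow(image), ncol(image))
    region_mask(SPINAL_REGIONS[i], mat, ...)
  })
}

#' @export
print.region_segmentation <- function(x, ...) {
  cat("<region_segmentation> pixel counts:",
      paste(sprintf("%s=%d", names(x$pixel_counts), x$pixel_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.region_segmentation <- function(x, ...) {
  tibble(region = names(x$pixel_counts),
         pixel_count = as.integer(x$pixel_counts))
}
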