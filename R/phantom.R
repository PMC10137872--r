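#' Specify a synthetic spinal phantom
#'
#' A phantom is a 2-D grayscale slice showing a bright vertical cord band on a
#' dark background, split top-to-bottom into the five spinal regions at
#' cumulative row fractions, optionally carrying one circular tumor lesion per
#' affected region, plus additive Gaussian noise. The spec is a plain record
#' validated here once; [generate_phantom()] renders it deterministically.
#'
#' @param height,width Image extent in pixels.
#' @param region_extents Five positive row-span fractions, ordered
#'   cervical to coccygeal, summing to 1. The defaults approximate the
#'   anatomical proportions of the vertebral column.
#' @param cord_intensity Cord brightness in (0, 1]; must exceed
#'   `background_intensity` so foreground is separable.
#' @param background_intensity Background brightness in [0, 1).
#' @param cord_width Width of the cord band in pixels; default about a quarter
#'   of the image width.
#' @param tumor_regions Character vector (subset of [SPINAL_REGIONS]) naming
#'   regions that carry a lesion.
#' @param tumor_radius Lesion disc radius in pixels (>= 1 when any region has
#'   a tumor). Discs are clamped fully inside their region and the cord band;
#'   the effective radius shrinks if the region cannot contain the disc.
#' @param tumor_contrast Signed intensity offset of the lesion relative to the
#'   cord; the rendered image is clipped to [0, 1] after noise.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed making rendering deterministic.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(tumor_regions = "lumbar", seed = 1)
#' sample <- generate_phantom(spec)
#' dim(sample$image)
#' @export
phantom_spec <- function(height = 96L, width = 64L,
                         region_extents = c(0.20, 0.40, 0.25, 0.10, 0.05),
                         cord_intensity = 0.7, background_intensity = 0.1,
                         cord_width = NULL,
                         tumor_regions = character(), tumor_radius = 3,
                         tumor_contrast = 0.25, noise_sigma = 0.05,
                         seed = 1L) {
  if (height < 5 || width < 3) {
    stop_invalid("`height` must be >= 5 and `width` >= 3", field = "height")
  }
  if (length(region_extents) != 5L) {
    stop_invalid("`region_extents` must have exactly 5 entries", field = "region_extents")
  }
  if (any(region_extents <= 0)) {
    stop_invalid("every entry of `region_extents` must be > 0", field = "region_extents")
  }
  if (abs(sum(region_extents) - 1) > 1e-9) {
    stop_invalid("`region_extents` must sum to 1 (within 1e-9)", field = "region_extents")
  }
  if (cord_intensity <= 0 || cord_intensity > 1) {
    stop_invalid("`cord_intensity` must lie in (0, 1]", field = "cord_intensity")
  }
  if (background_intensity < 0 || background_intensity >= 1) {
    stop_invalid("`background_intensity` must lie in [0, 1)", field = "background_intensity")
  }
  if (cord_intensity <= background_intensity) {
    stop_invalid("`cord_intensity` must exceed `background_intensity`",
                 field = "cord_intensity")
  }
  tumor_regions <- as.character(tumor_regions)
  if (!all(tumor_regions %in% SPINAL_REGIONS)) {
    stop_invalid("`tumor_regions` must be a subset of the five spinal regions",
                 field = "tumor_regions")
  }
  if (length(tumor_regions) > 0L && tumor_radius < 1) {
    stop_invalid("`tumor_radius` must be >= 1 when tumors are requested",
                 field = "tumor_radius")
  }
  if (noise_sigma < 0) {
    stop_invalid("`noise_sigma` must be >= 0", field = "noise_sigma")
  }
  cord_width <- cord_width %||% max(3L, round(width / 4))
  if (cord_width < 1 || cord_width > width) {
    stop_invalid("`cord_width` must lie in [1, width]", field = "cord_width")
  }
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      region_extents = setNames(as.numeric(region_extents), SPINAL_REGIONS),
      cord_intensity = cord_intensity,
      background_intensity = background_intensity,
      cord_width = as.integer(cord_width),
      tumor_regions = unique(tumor_regions),
      tumor_radius = tumor_radius,
      tumor_contrast = tumor_contrast,
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# row span (first, last) of each region given height and extents
region_row_spans <- function(height, extents) {
  breaks <- round(cumsum(extents) * height)
  breaks[5] <- height
  first <- c(1L, head(breaks, -1) + 1L)
  if (any(breaks - first + 1L < 1L)) {
    stop_invalid("every region must span at least one row; increase `height`",
                 field = "region_extents")
  }
  tibble(region = SPINAL_REGIONS, first = as.integer(first), last = as.integer(breaks))
}

#' Render one synthetic phantom sample
#'
#' Draws the cord as a vertical band with region boundaries at cumulative row
#' fractions, stamps one lesion disc per affected region (fully inside the
#' region and the cord band), adds Gaussian noise of sd `noise_sigma`, and
#' clips intensities to [0, 1]. The label map is noise-free. Rendering is a
#' pure function of the spec, including its seed.
#'
#' The sample stores the ground-truth spread probability: the normalized
#' region-weighted aggregation (see [spread_probability()]) applied to the
#' binary tumor flags with this sample's per-region cord pixel counts.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_sample`: list with `image` (numeric
#'   matrix in [0, 1]), `region_labels` (integer matrix, 0 = background,
#'   1-5 = cervical..coccygeal), `tumor_status` (named logical of length 5),
#'   `spread_probability_actual`, and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_invalid("`spec` must be a phantom_spec", field = "spec")
  }
  h <- spec$height; w <- spec$width
  spans <- region_row_spans(h, spec$region_extents)

  cord_first <- max(1L, floor((w - spec$cord_width) / 2) + 1L)
  cord_last <- min(w, cord_first + spec$cord_width - 1L)
  cord_cols <- cord_first:cord_last

  labels <- matrix(0L, h, w)
  for (i in seq_len(5)) {
    labels[spans$first[i]:spans$last[i], cord_cols] <- i
  }

  image <- matrix(spec$background_intensity, h, w)
  image[labels > 0L] <- spec$cord_intensity

  status <- setNames(SPINAL_REGIONS %in% spec$tumor_regions, SPINAL_REGIONS)

  withr::with_seed(spec$seed, {
    for (i in which(status)) {
      rows <- spans$first[i]:spans$last[i]
      half_rows <- (length(rows) - 1L) %/% 2L
      half_cols <- (length(cord_cols) - 1L) %/% 2L
      r_eff <- max(1L, min(floor(spec$tumor_radius), half_rows, half_cols))
      cr_lo <- spans$first[i] + r_eff
      cr_hi <- spans$last[i] - r_eff
      center_row <- if (cr_hi > cr_lo) sample(cr_lo:cr_hi, 1L) else cr_lo
      center_col <- cord_first + half_cols
      rr <- pmax(1L, center_row - r_eff):pmin(h, center_row + r_eff)
      cc <- pmax(1L, center_col - r_eff):pmin(w, center_col + r_eff)
      for (r in rr) for (cl in cc) {
        if ((r - center_row)^2 + (cl - center_col)^2 <= r_eff^2) {
          image[r, cl] <- spec$cord_intensity + spec$tumor_contrast
        }
      }
    }
    if (spec$noise_sigma > 0) {
      image <- image + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
    }
  })
  image <- clip01(image)

  counts <- region_pixel_counts(labels)
  lengths <- region_lengths(counts)
  weights <- region_weights(lengths)
  actual <- spread_probability(
    calls = setNames(as.numeric(status), SPINAL_REGIONS),
    weights = weights, variant = "normalized"
  )$spread_probability

  structure(
    list(
      image = image, region_labels = labels, tumor_status = status,
      spread_probability_actual = actual, spec = spec
    ),
    class = "phantom_sample"
  )
}

# cord pixel count per region from a label map
region_pixel_counts <- function(labels) {
  counts <- vapply(seq_len(5), function(i) sum(labels == i), integer(1))
  setNames(counts, SPINAL_REGIONS)
}

#' Generate a seeded cohort of phantoms
#'
#' Tumor presence is drawn independently per sample and region from
#' `tumor_prevalence`; each sample is rendered by [generate_phantom()] under a
#' sub-seed derived from `seed`, so the whole cohort is reproducible.
#'
#' @param spec Baseline [phantom_spec()]; its `tumor_regions` and `seed` are
#'   overridden per sample.
#' @param n Number of samples (>= 1).
#' @param tumor_prevalence Per-region tumor probability; scalar or named
#'   length-5 vector in [0, 1].
#' @param seed Master seed for tumor assignment and per-sample rendering.
#' @return List of `phantom_sample` objects.
#' @examples
#' cohort <- generate_cohort(phantom_spec(), n = 4, tumor_prevalence = 0.5, seed = 7)
#' cohort_manifest(cohort)
#' @export
generate_cohort <- function(spec, n, tumor_prevalence = 0.5, seed = 1L) {
  if (!inherits(spec, "phantom_spec")) {
    stop_invalid("`spec` must be a phantom_spec", field = "spec")
  }
  if (n < 1) stop_invalid("`n` must be >= 1", field = "n")
  prev <- per_region(tumor_prevalence, "tumor_prevalence")
  if (any(prev < 0 | prev > 1)) {
    stop_invalid("`tumor_prevalence` entries must lie in [0, 1]",
                 field = "tumor_prevalence")
  }
  n <- as.integer(n)
  flags <- withr::with_seed(seed, {
    matrix(rbinom(n * 5L, 1L, rep(prev, each = n)) == 1L, n, 5L,
           dimnames = list(NULL, SPINAL_REGIONS))
  })
  sub_seeds <- derive_seeds(seed + 1L, n)
  purrr::map(seq_len(n), function(i) {
    s <- spec
    s$tumor_regions <- SPINAL_REGIONS[flags[i, ]]
    s$seed <- sub_seeds[i]
    generate_phantom(s)
  })
}

#' Summarize a cohort as a tibble
#'
#' One row per sample: per-region tumor flags and the ground-truth spread
#' probability. This is the manifest written next to exported cohorts.
#'
#' @param cohort List of `phantom_sample` objects.
#' @return A tibble with columns `sample`, one logical column per region, and
#'   `spread_probability_actual`.
#' @export
cohort_manifest <- function(cohort) {
  purrr::imap_dfr(cohort, function(s, i) {
    tibble(
      sample = i,
      !!!as.list(s$tumor_status),
      spread_probability_actual = s$spread_probability_actual
    )
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, cord %.2f on background %.2f, noise sd %.3f\n",
              x$height, x$width, x$cord_intensity, x$background_intensity,
              x$noise_sigma))
  cat(sprintf("  region extents: %s\n",
              paste(sprintf("%s=%.2f", SPINAL_REGIONS, x$region_extents),
                    collapse = ", ")))
  if (length(x$tumor_regions)) {
    cat(sprintf("  tumors in: %s (radius %g, contrast %+g)\n",
                paste(x$tumor_regions, collapse = ", "),
                x$tumor_radius, x$tumor_contrast))
  }
  invisible(x)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, tumors: %s, actual spread %.3f\n",
              nrow(x$image), ncol(x$image),
              if (any(x$tumor_status)) paste(names(which(x$tumor_status)), collapse = ", ")
              else "none",
              x$spread_probability_actual))
  invisible(x)
}
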