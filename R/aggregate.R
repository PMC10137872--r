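#' Relative region lengths from pixel counts
#'
#' Each region's approximate length is its share of the total segmented cord
#' pixels: `L_i = N_i / sum(N)`. The five lengths therefore sum to 1.
#'
#' @param seg A `region_segmentation`, or a named (or ordered) numeric vector
#'   of five per-region pixel counts.
#' @return Named numeric vector of five lengths summing to 1.
#' @examples
#' region_lengths(c(30, 25, 20, 15, 10))
#' @export
region_lengths <- function(seg) {
  counts <- if (inherits(seg, "region_segmentation")) seg$pixel_counts else seg
  counts <- per_region(counts, "pixel counts")
  if (any(counts < 0)) stop_invalid("pixel counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop_invalid("all pixel counts are zero; lengths undefined")
  counts / total
}

#' Region weights from lengths
#'
#' `W_i = L_i / sum(L)`. Because lengths already sum to 1, the weights equal
#' the lengths numerically; the renormalization is kept so the function also
#' accepts unnormalized length vectors.
#'
#' @param lengths Named (or ordered) numeric vector of five lengths.
#' @return Named numeric vector of five weights summing to 1.
#' @export
region_weights <- function(lengths) {
  lengths <- per_region(lengths, "lengths")
  if (any(lengths < 0)) stop_invalid("lengths must be >= 0")
  total <- sum(lengths)
  if (total <= 0) stop_invalid("lengths sum to zero; weights undefined")
  lengths / total
}

#' Aggregate per-region tumor calls into a spread probability
#'
#' The cancer-spread probability is the weight-averaged tumor probability
#' over the five regions. Two variants are recorded: `"normalized"` (the
#' default), `sum(p_i * W_i)`, bounded in [0, 1]; and `"as_printed"`, the
#' same sum divided by 5, bounded in [0, 0.2]. The normalized variant is
#' always exactly 5 times the as-printed one; downstream correlation against
#' actual probabilities in [0, 1] uses the normalized scale.
#'
#' @param calls Five-row tibble with `region` and `probability` columns (as
#'   returned by [classify_all_regions()]), or a named numeric vector of five
#'   per-region tumor probabilities.
#' @param weights Named numeric vector of five weights summing to 1 (within
#'   1e-6).
#' @param variant `"normalized"` or `"as_printed"`.
#' @return An object of class `spread_estimate`: list with
#'   `spread_probability`, `weights`, `lengths` (= weights), `tumor_probs`
#'   and `variant`.
#' @examples
#' w <- region_weights(c(0.3, 0.25, 0.2, 0.15, 0.1))
#' p <- c(cervical = 1, thoracic = 0, lumbar = 0, sacral = 0, coccygeal = 0)
#' spread_probability(p, w)$spread_probability # 0.3
#' @export
spread_probability <- function(calls, weights,
                               variant = c("normalized", "as_printed")) {
  variant <- match.arg(variant)
  if (is.data.frame(calls)) {
    missing <- setdiff(SPINAL_REGIONS, calls$region)
    if (length(missing) > 0L) {
      stop_invalid(sprintf("missing region call(s): %s",
                           paste(missing, collapse = ", ")))
    }
    probs <- setNames(calls$probability[match(SPINAL_REGIONS, calls$region)],
                      SPINAL_REGIONS)
  } else {
    probs <- per_region(calls, "calls")
  }
  if (any(is.na(probs))) stop_invalid("tumor probabilities contain NA")
  if (any(probs < 0 | probs > 1)) {
    stop_invalid("tumor probabilities must lie in [0, 1]")
  }
  weights <- per_region(weights, "weights")
  if (abs(sum(weights) - 1) > 1e-6) {
    stop_invalid("weights must sum to 1")
  }
  raw <- sum(probs * weights)
  p <- switch(variant, normalized = raw, as_printed = raw / 5)
  structure(
    list(spread_probability = p, weights = weights, lengths = weights,
         tumor_probs = probs, variant = variant),
    class = "spread_estimate"
  )
}

#' @export
print.spread_estimate <- function(x, ...) {
  cat(sprintf("<spread_estimate> %.4f (%s variant)\n",
              x$spread_probability, x$variant))
  invisible(x)
}

#' @export
as_tibble.spread_estimate <- function(x, ...) {
  tibble(region = SPINAL_REGIONS,
         tumor_probability = as.numeric(x$tumor_probs),
         weight = as.numeric(x$weights),
         spread_probability = x$spread_probability,
         variant = x$variant)
}
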