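#' Correlate predicted and actual spread probabilities
#'
#' Computes two statistics over paired sequences of actual and obtained
#' spread probabilities. `c_pearson` is the standard product-moment
#' correlation and is the statistic the training-pool gate uses; when both
#' sequences are identical constants it is defined as 1 (perfect agreement),
#' and when either sequence is constant but they differ it is NA (flagged
#' undefined). `c_printed` is the historical residual ratio
#' `sum(d) / sum(d^2)` with `d = actual - obtained`, reported alongside for
#' audit; its 0/0 case (exact agreement) is defined as 1.
#'
#' @param p_actual,p_obtained Equal-length numeric vectors (length >= 2) of
#'   probabilities in [0, 1].
#' @return An object of class `correlation_report`: list with `c_printed`,
#'   `c_pearson`, `n`.
#' @examples
#' correlation(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.8))
#' @export
correlation <- function(p_actual, p_obtained) {
  if (length(p_actual) != length(p_obtained)) {
    stop_invalid("`p_actual` and `p_obtained` must have equal length")
  }
  if (length(p_actual) < 2L) {
    stop_invalid("need at least 2 paired values")
  }
  if (any(p_actual < 0 | p_actual > 1 | p_obtained < 0 | p_obtained > 1)) {
    stop_invalid("probabilities must lie in [0, 1]")
  }
  d <- p_actual - p_obtained
  denom <- sum(d^2)
  c_printed <- if (denom == 0) 1 else sum(d) / denom

  sa <- sd(p_actual); so <- sd(p_obtained)
  c_pearson <- if (sa == 0 || so == 0) {
    if (all(d == 0)) 1 else NA_real_
  } else {
    cor(p_actual, p_obtained)
  }
  structure(
    list(c_printed = c_printed, c_pearson = c_pearson,
         n = length(p_actual)),
    class = "correlation_report"
  )
}

#' Create an empty training pool
#'
#' The pool is an append-only collection of evaluated samples; its size never
#' decreases. [update_pool()] returns a grown copy when the correlation gate
#' passes.
#'
#' @param samples Optional initial list of samples.
#' @return An object of class `training_pool`.
#' @export
training_pool <- function(samples = list()) {
  structure(list(samples = samples, size = length(samples)),
            class = "training_pool")
}

#' Gate a batch of samples into the training pool
#'
#' Appends every sample of the batch when the batch's Pearson correlation
#' strictly exceeds the threshold (default 0.999); otherwise the pool is
#' returned unchanged. The decision is all-or-none per batch and a pure
#' function of the report and threshold. The decision is recorded on the
#' returned pool as `last_decision`.
#'
#' @param pool A [training_pool()].
#' @param batch List of samples evaluated in this batch.
#' @param report A [correlation()] report for the batch.
#' @param threshold Gate threshold in (0, 1]; default 0.999.
#' @return The (possibly grown) `training_pool`.
#' @export
update_pool <- function(pool, batch, report, threshold = 0.999) {
  if (!inherits(pool, "training_pool")) {
    stop_invalid("`pool` must be a training_pool", field = "pool")
  }
  if (!inherits(report, "correlation_report")) {
    stop_invalid("`report` must be a correlation_report", field = "report")
  }
  if (threshold <= 0 || threshold > 1) {
    stop_invalid("`threshold` must lie in (0, 1]", field = "threshold")
  }
  passed <- !is.na(report$c_pearson) && report$c_pearson > threshold
  if (passed) {
    pool$samples <- c(pool$samples, batch)
    pool$size <- length(pool$samples)
  }
  pool$last_decision <- list(gate_passed = passed,
                             c_pearson = report$c_pearson,
                             threshold = threshold)
  pool
}

#' Correlation-gated continuous evaluation loop
#'
#' Iterates over a stream of evaluation batches: each round scores the batch
#' with the current models (saliency, predicted or ground-truth masks,
#' per-region classification, spread aggregation), correlates obtained
#' against actual spread probabilities, gates the batch into the training
#' pool, and optionally retrains the region classifiers from the grown pool
#' every `retrain_every` rounds. Held-out accuracy is measured each round on
#' a fixed cohort so the trace is comparable across rounds.
#'
#' @param stream List of batches (each a list of `phantom_sample`).
#' @param models Named list from [train_region_classifiers()].
#' @param pool A [training_pool()] seeding retraining.
#' @param heldout List of `phantom_sample` used for the per-round accuracy.
#' @param config List: `threshold` (gate, default 0.999), `retrain_every`
#'   (0 = never, the default), `bins` (saliency bins, 256),
#'   `mask_source` (`"truth"` or a `pixel_classifier`), `classifier_config`
#'   (for retraining), `variant` (spread variant, `"normalized"`).
#' @return List with `log` (one tibble row per round: `round`, `n`,
#'   `c_printed`, `c_pearson`, `gate_passed`, `pool_size`, `accuracy`),
#'   `models`, `pool`.
#' @export
continuous_loop <- function(stream, models, pool = training_pool(),
                            heldout = list(), config = list()) {
  threshold <- config$threshold %||% 0.999
  retrain_every <- config$retrain_every %||% 0L
  bins <- config$bins %||% 256L
  variant <- config$variant %||% "normalized"

  rows <- vector("list", length(stream))
  for (round in seq_along(stream)) {
    batch <- stream[[round]]
    scored <- tryCatch(
      purrr::map_dfr(batch, function(s) {
        est <- score_sample(s, models, bins = bins,
                            mask_source = config$mask_source, variant = variant)
        tibble(actual = s$spread_probability_actual,
               obtained = est$spread_probability)
      }),
      error = function(e) {
        abort(sprintf("round %d failed: %s", round, conditionMessage(e)),
              parent = e)
      }
    )
    report <- correlation(scored$actual, scored$obtained)
    pool <- update_pool(pool, batch, report, threshold)

    if (retrain_every > 0L && round %% retrain_every == 0L && pool$size >= 2L) {
      cc <- config$classifier_config %||% classifier_config()
      trainable <- vapply(SPINAL_REGIONS, function(r) {
        length(unique(vapply(pool$samples, function(s) s$tumor_status[[r]],
                             logical(1)))) > 1L
      }, logical(1))
      if (all(trainable)) {
        models <- train_region_classifiers(pool$samples, cc, bins = bins)
      }
    }

    acc <- NA_real_
    if (length(heldout) > 0L) {
      calls <- purrr::map_dfr(heldout, function(s) {
        est <- score_sample(s, models, bins = bins,
                            mask_source = config$mask_source, variant = variant)
        tibble(pred = as.numeric(est$tumor_probs > 0.5),
               truth = as.numeric(s$tumor_status))
      })
      acc <- accuracy(calls$pred, calls$truth)
    }

    rows[[round]] <- tibble(
      round = round, n = report$n, c_printed = report$c_printed,
      c_pearson = report$c_pearson,
      gate_passed = pool$last_decision$gate_passed,
      pool_size = pool$size, accuracy = acc
    )
  }
  list(log = dplyr::bind_rows(rows), models = models, pool = pool)
}

# score one sample end to end: saliency -> masks -> segments -> calls -> spread
score_sample <- function(sample, models, bins = 256L, mask_source = NULL,
                         variant = "normalized") {
  sal <- extract_saliency(sample$image, bins)
  masks <- if (inherits(mask_source, "pixel_classifier")) {
    predict_masks(mask_source, sample$image)
  } else {
    masks_from_labels(sample$region_labels)
  }
  seg <- segment_all_regions(sal, masks)
  calls <- classify_all_regions(seg, models)
  counts <- seg$pixel_counts
  if (sum(counts) == 0) {
    # no cord found: fall back to uniform weights so the estimate is defined
    weights <- setNames(rep(0.2, 5), SPINAL_REGIONS)
  } else {
    weights <- region_weights(region_lengths(counts))
  }
  spread_probability(calls, weights, variant = variant)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> n=%d, pearson=%s, printed=%.4g\n",
              x$n,
              if (is.na(x$c_pearson)) "NA" else sprintf("%.6f", x$c_pearson),
              x$c_printed))
  invisible(x)
}

#' @export
print.training_pool <- function(x, ...) {
  cat(sprintf("<training_pool> %d samples\n", x$size))
  invisible(x)
}
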