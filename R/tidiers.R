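#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained region classifier
#'
#' One row per softmax-head coefficient (term/estimate), broom style.
#'
#' @param x A `region_classifier`.
#' @param ... Unused.
#' @return Tibble with `region`, `term`, `estimate`.
#' @export
tidy.region_classifier <- function(x, ...) {
  if (!isTRUE(x$trained)) {
    return(tibble(region = x$region, term = character(), estimate = numeric()))
  }
  co <- x$coef
  tibble(region = x$region, term = names(co), estimate = as.numeric(co))
}

#' @rdname tidy.region_classifier
#' @return `glance()`: one-row tibble with fit summaries.
#' @export
glance.region_classifier <- function(x, ...) {
  if (!isTRUE(x$trained)) {
    return(tibble(region = x$region, trained = FALSE, n_train = NA_integer_,
                  n_features = NA_integer_, n_maps_retained = NA_integer_,
                  train_accuracy = NA_real_))
  }
  tibble(region = x$region, trained = TRUE, n_train = x$n_train,
         n_features = length(x$stat_cols),
         n_maps_retained = length(x$retained_maps),
         train_accuracy = x$train_accuracy)
}

#' Tidy a correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `c_pearson`, `c_printed`.
#' @export
tidy.correlation_report <- function(x, ...) {
  tibble(n = x$n, c_pearson = x$c_pearson, c_printed = x$c_printed)
}

#' Summaries of a pipeline run
#'
#' `glance()` returns the headline metrics as one tibble row; `tidy()`
#' returns the per-region accuracy table.
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.pipeline_result <- function(x, ...) {
  r <- x$report
  tibble(
    accuracy_percent = r$accuracy_percent,
    mean_dice = r$mean_dice,
    mean_psnr_db = r$mean_psnr_db,
    spread_mae = r$spread_mae,
    c_pearson = r$c_pearson,
    gate_passed = r$gate_passed,
    pool_size = r$pool_size,
    n_test = nrow(x$per_image)
  )
}

#' @rdname glance.pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) {
  x$per_region
}
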