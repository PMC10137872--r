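# ggplot2 views of the package's result types

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_line
#'   geom_point scale_fill_viridis_c scale_fill_manual coord_fixed labs
#'   theme_minimal facet_wrap
#' @export
ggplot2::autoplot

# long tibble of pixels for raster plotting
image_to_tibble <- function(image, value_name = "intensity") {
  tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    !!value_name := as.vector(image)
  )
}

#' Plot a phantom sample
#'
#' Side-by-side rasters of the rendered image and its region label map.
#'
#' @param object A `phantom_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_sample <- function(object, ...) {
  img <- image_to_tibble(object$image)
  img$panel <- "image"
  lab <- image_to_tibble(object$region_labels / 5)
  lab$panel <- "region labels"
  df <- dplyr::bind_rows(img, lab)
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = NULL) +
    coord_fixed() +
    facet_wrap(~panel) +
    labs(x = NULL, y = NULL, title = "Spinal phantom") +
    theme_minimal()
}

#' Plot a saliency result
#'
#' Raster of the saliency map (foreground-masked intensities).
#'
#' @param object A `saliency_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_result <- function(object, ...) {
  df <- image_to_tibble(object$saliency_map)
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "saliency") +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = sprintf("Saliency map (entropy %.3f bits)", object$entropy)) +
    theme_minimal()
}

#' Plot a region segmentation
#'
#' Raster with each pixel colored by its region assignment.
#'
#' @param object A `region_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_segmentation <- function(object, ...) {
  assignment <- matrix("background",
                       nrow(object$segments[[1]]), ncol(object$segments[[1]]))
  for (r in SPINAL_REGIONS) {
    assignment[object$segments[[r]] > 0] <- r
  }
  df <- image_to_tibble(matrix(match(assignment, label_levels()),
                               nrow(assignment)), "code")
  df$region <- factor(label_levels()[df$code], levels = label_levels())
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$region)) +
    geom_raster() +
    coord_fixed() +
    labs(x = NULL, y = NULL, title = "Region segmentation") +
    theme_minimal()
}

#' Plot a spread estimate
#'
#' Per-region tumor probabilities scaled by their weights, with the
#' aggregated spread probability in the title.
#'
#' @param object A `spread_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spread_estimate <- function(object, ...) {
  df <- as_tibble(object)
  df$region <- factor(df$region, levels = SPINAL_REGIONS)
  ggplot(df, aes(x = .data$region, y = .data$tumor_probability * .data$weight)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "weighted tumor probability",
         title = sprintf("Spread probability %.3f (%s)",
                         object$spread_probability, object$variant)) +
    theme_minimal()
}

#' Plot a continuous-learning run log
#'
#' Pool size and held-out accuracy per round.
#'
#' @param log The `log` tibble from [continuous_loop()].
#' @return A ggplot object.
#' @export
plot_adapt_log <- function(log) {
  df <- tidyr::pivot_longer(
    dplyr::select(log, "round", "pool_size", "accuracy"),
    cols = c("pool_size", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot(df, aes(x = .data$round, y = .data$value)) +
    geom_line() +
    geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "round", y = NULL, title = "Correlation-gated learning trace") +
    theme_minimal()
}
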