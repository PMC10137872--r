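#' Convolution layer geometry
#'
#' Bundles kernel size, stride, padding and activation slope, and validates
#' that the layer would not annihilate its input.
#'
#' @param kernel_size Kernel side length in pixels (>= 1).
#' @param stride Stride in pixels (>= 1).
#' @param padding Zero padding in pixels (>= 0).
#' @param channels Number of output feature maps.
#' @param leaky_slope Leaky-ReLU slope in (0, 1); default 0.01.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(kernel_size, stride = 1L, padding = 0L, channels = 1L,
                      leaky_slope = 0.01) {
  if (kernel_size < 1) stop_invalid("`kernel_size` must be >= 1", field = "kernel_size")
  if (stride < 1) stop_invalid("`stride` must be >= 1", field = "stride")
  if (padding < 0) stop_invalid("`padding` must be >= 0", field = "padding")
  if (leaky_slope <= 0 || leaky_slope >= 1) {
    stop_invalid("`leaky_slope` must lie in (0, 1)", field = "leaky_slope")
  }
  structure(
    list(kernel_size = as.integer(kernel_size), stride = as.integer(stride),
         padding = as.integer(padding), channels = as.integer(channels),
         leaky_slope = leaky_slope),
    class = "conv_spec"
  )
}

#' Output size of a strided, padded convolution
#'
#' `floor((n_in + 2 * padding - kernel_size) / stride) + 1`, the count of
#' valid window placements. An output size below 1 is an error: the layer
#' would annihilate its input.
#'
#' @param n_in Input extent in pixels.
#' @param spec A [conv_spec()].
#' @return Integer output extent.
#' @examples
#' conv_output_size(7, conv_spec(3)) # 5
#' conv_output_size(7, conv_spec(3, padding = 1)) # 7: "same" padding
#' @export
conv_output_size <- function(n_in, spec) {
  n_out <- (n_in + 2L * spec$padding - spec$kernel_size) %/% spec$stride + 1L
  if (n_out < 1L) {
    stop_invalid(sprintf(
      "layer annihilates input: n_in=%d, k=%d, p=%d, s=%d gives output %d",
      n_in, spec$kernel_size, spec$padding, spec$stride, n_out
    ))
  }
  as.integer(n_out)
}

# raw cross-correlation (no activation): zero padding, stride; vectorized by
# accumulating kernel-shifted submatrices
conv2d <- function(x, kernel, stride = 1L, padding = 0L) {
  k_r <- nrow(kernel); k_c <- ncol(kernel)
  h <- nrow(x); w <- ncol(x)
  hp <- h + 2L * padding; wp <- w + 2L * padding
  if (padding > 0L) {
    padded <- matrix(0, hp, wp)
    padded[(padding + 1L):(padding + h), (padding + 1L):(padding + w)] <- x
  } else {
    padded <- x
  }
  out_r <- (hp - k_r) %/% stride + 1L
  out_c <- (wp - k_c) %/% stride + 1L
  if (out_r < 1L || out_c < 1L) {
    stop_invalid("kernel larger than padded input")
  }
  rows0 <- (seq_len(out_r) - 1L) * stride
  cols0 <- (seq_len(out_c) - 1L) * stride
  acc <- matrix(0, out_r, out_c)
  for (a in seq_len(k_r)) {
    for (b in seq_len(k_c)) {
      acc <- acc + kernel[a, b] * padded[rows0 + a, cols0 + b, drop = FALSE]
    }
  }
  acc
}

#' Leaky-ReLU convolution
#'
#' Strided, zero-padded cross-correlation of a segment image with a kernel,
#' followed by the leaky rectifier `max(x, slope * x)`. The output shape obeys
#' [conv_output_size()] in each dimension.
#'
#' @param segment Numeric matrix (a segment image or feature map).
#' @param kernel Numeric weight matrix.
#' @param spec A [conv_spec()]; its `kernel_size` must match the kernel's
#'   side lengths (square kernels) or be omitted via `spec = NULL` to take
#'   geometry from `stride`/`padding` arguments.
#' @param stride,padding,leaky_slope Used when `spec` is NULL.
#' @return Feature map matrix.
#' @examples
#' x <- matrix(runif(25), 5, 5)
#' f <- conv_leaky(x, matrix(1, 3, 3)) # 3x3 neighborhood sums
#' dim(f) # 3 3
#' @export
conv_leaky <- function(segment, kernel, spec = NULL,
                       stride = 1L, padding = 0L, leaky_slope = 0.01) {
  check_image(segment, "segment")
  check_image(kernel, "kernel")
  if (!is.null(spec)) {
    if (!inherits(spec, "conv_spec")) {
      stop_invalid("`spec` must be a conv_spec", field = "spec")
    }
    if (nrow(kernel) != spec$kernel_size || ncol(kernel) != spec$kernel_size) {
      stop_invalid(sprintf(
        "kernel is %dx%d but spec declares kernel_size %d",
        nrow(kernel), ncol(kernel), spec$kernel_size
      ))
    }
    stride <- spec$stride; padding <- spec$padding; leaky_slope <- spec$leaky_slope
  }
  leaky_relu(conv2d(segment, kernel, stride, padding), leaky_slope)
}

# non-overlapping block max pooling; trailing partial blocks are dropped
max_pool <- function(x, size = 2L) {
  out_r <- nrow(x) %/% size
  out_c <- ncol(x) %/% size
  if (out_r < 1L || out_c < 1L) return(x)
  out <- matrix(-Inf, out_r, out_c)
  for (a in seq_len(size)) {
    for (b in seq_len(size)) {
      out <- pmax(out, x[(seq_len(out_r) - 1L) * size + a,
                         (seq_len(out_c) - 1L) * size + b, drop = FALSE])
    }
  }
  out
}

#' Block-level summary statistics of a feature map
#'
#' The seven per-block statistics used to summarize convolutional feature
#' maps: mean, max, standard deviation, excess kurtosis, Shannon entropy of
#' the min-max-normalized values over `bins` bins, variance, and the lag-1
#' horizontal spatial autocorrelation. Degenerate blocks (constant, or too
#' narrow for a lag) report 0 for kurtosis, entropy and correlation.
#'
#' @param block Numeric matrix.
#' @param bins Bins for the entropy statistic; default 8.
#' @return Named numeric vector of length 7.
#' @export
block_stats <- function(block, bins = 8L) {
  check_image(block, "block")
  x <- as.vector(block)
  n <- length(x)
  mu <- sum(x) / n
  centered <- x - mu
  m2 <- sum(centered^2) / n
  v <- if (n > 1L) sum(centered^2) / (n - 1L) else 0
  kur <- if (m2 > 0) sum(centered^4) / n / m2^2 - 3 else 0
  rng <- diff(range(x))
  ent <- if (rng > 0) {
    image_entropy(matrix((x - min(x)) / rng, nrow(block)), bins = bins)$entropy
  } else 0
  corr <- 0
  if (ncol(block) >= 2L) {
    a <- as.vector(block[, -ncol(block), drop = FALSE])
    b <- as.vector(block[, -1L, drop = FALSE])
    if (sd(a) > 0 && sd(b) > 0) corr <- cor(a, b)
  }
  c(mean = mu, max = max(x), sd = sqrt(v), kurtosis = kur,
    entropy = ent, variance = v, correlation = corr)
}

#' Variance-threshold feature selection
#'
#' Retains the feature maps whose variance reaches a data-derived threshold.
#' The variance probability `pv` is the fraction of features whose variance
#' strictly exceeds the median variance, clamped to [0.01, 0.99]; the
#' threshold is `mean(variances) * pv / (1 - pv)`. The historical form of the
#' threshold with denominator `pv - 1` is available as
#' `variant = "as_printed"`; it is negative on (0, 1) and therefore retains
#' everything. The maximum-variance feature always survives; an all-constant
#' feature set returns only the first feature, with a warning.
#'
#' @param features List of numeric matrices (or vectors), one per feature.
#' @param pv Optional override of the variance probability in (0, 1).
#' @param variant `"corrected"` (default) or `"as_printed"`.
#' @return List with `features` (retained list), `retained` (integer
#'   indices), `variances` (all input variances), `pv` and `threshold`.
#' @export
variance_pool <- function(features, pv = NULL,
                          variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  if (!is.list(features) || length(features) < 1L) {
    stop_invalid("`features` must be a non-empty list", field = "features")
  }
  s <- vapply(features, function(f) {
    f <- as.numeric(f)
    if (length(f) > 1L) var(f) else 0
  }, numeric(1))
  sel <- variance_threshold_select(s, pv, variant)
  c(list(features = features[sel$retained]), sel)
}

# the variance-threshold selection rule on a vector of variances
variance_threshold_select <- function(s, pv = NULL,
                                      variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  if (!all(is.finite(s))) stop_invalid("feature variances must be finite")
  if (all(s == 0)) {
    warn("all features are constant; retaining the first feature only")
    return(list(retained = 1L, variances = s,
                pv = NA_real_, threshold = NA_real_))
  }
  if (is.null(pv)) {
    pv <- mean(s > median(s))
    pv <- min(max(pv, 0.01), 0.99)
  }
  if (pv <= 0 || pv >= 1) stop_invalid("`pv` must lie in (0, 1)", field = "pv")
  threshold <- switch(variant,
    corrected = mean(s) * pv / (1 - pv),
    as_printed = mean(s) * pv / (pv - 1)
  )
  retained <- which(s >= threshold)
  if (length(retained) == 0L) retained <- which.max(s)
  list(retained = retained, variances = s, pv = pv, threshold = threshold)
}

#' Default desk-scale classifier settings
#'
#' Two banks of seeded random 3x3 leaky-ReLU kernels (8 maps each) with 2x2
#' max pooling after each bank, variance-threshold map selection frozen at
#' training time, seven block statistics per retained map, and a softmax head
#' trained with weight decay. `input_size` is the square side length region
#' crops are resampled to before convolution.
#'
#' @param input_size Resampled crop side (default 16 px).
#' @param n_kernels Feature maps per bank (default `c(8, 8)`).
#' @param kernel_size Kernel side (default 3).
#' @param leaky_slope Activation slope (default 0.01).
#' @param dropout Training-time feature dropout probability (default 0.1).
#' @param decay Softmax-head weight decay (default 0.01).
#' @param maxit Head optimizer iteration cap (default 300).
#' @param variance_variant Variance-threshold variant (see [variance_pool()]).
#' @param seed Seed for kernels, dropout and head initialization.
#' @return List of settings.
#' @export
classifier_config <- function(input_size = 16L, n_kernels = c(8L, 8L),
                              kernel_size = 3L, leaky_slope = 0.01,
                              dropout = 0.1, decay = 0.01, maxit = 300L,
                              variance_variant = "corrected", seed = 1L) {
  list(input_size = as.integer(input_size), n_kernels = as.integer(n_kernels),
       kernel_size = as.integer(kernel_size), leaky_slope = leaky_slope,
       dropout = dropout, decay = decay, maxit = as.integer(maxit),
       variance_variant = variance_variant, seed = as.integer(seed))
}

# crop the bounding box of nonzero pixels and resample (nearest neighbor) to
# a size x size square; NULL when the segment is entirely zero
crop_resize <- function(segment, size) {
  nz <- which(segment > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(NULL)
  rr <- range(nz[, 1]); cc <- range(nz[, 2])
  crop <- segment[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  ri <- pmax(1L, ceiling(seq_len(size) / size * nrow(crop)))
  ci <- pmax(1L, ceiling(seq_len(size) / size * ncol(crop)))
  crop[ri, ci, drop = FALSE]
}

# seeded random kernel banks: list of (k x k x n_in x n_out) arrays
make_kernel_banks <- function(config) {
  k <- config$kernel_size
  banks <- list()
  n_in <- 1L
  for (li in seq_along(config$n_kernels)) {
    n_out <- config$n_kernels[li]
    banks[[li]] <- array(rnorm(k * k * n_in * n_out, sd = 0.5),
                         dim = c(k, k, n_in, n_out))
    n_in <- n_out
  }
  banks
}

# forward pass: conv banks + max pool; returns final-layer feature maps
conv_forward <- function(x, banks, slope) {
  maps <- list(x)
  for (bank in banks) {
    n_out <- dim(bank)[4]
    new_maps <- vector("list", n_out)
    for (j in seq_len(n_out)) {
      acc <- NULL
      for (i in seq_along(maps)) {
        c_ij <- conv2d(maps[[i]], bank[, , i, j], stride = 1L, padding = 1L)
        acc <- if (is.null(acc)) c_ij else acc + c_ij
      }
      new_maps[[j]] <- max_pool(leaky_relu(acc, slope), 2L)
    }
    maps <- new_maps
  }
  maps
}

# full feature vector: stats of every final-layer map (selection happens later)
segment_feature_matrix <- function(segments, model_or_config, banks, slope, size) {
  feats <- purrr::map(segments, function(seg) {
    x <- crop_resize(seg, size)
    if (is.null(x)) return(NULL)
    maps <- conv_forward(x, banks, slope)
    list(maps = maps,
         stats = unlist(purrr::map(maps, block_stats), use.names = FALSE))
  })
  feats
}

#' Train one tumor classifier per spinal region
#'
#' For each region the cohort's segment images (saliency map restricted to the
#' ground-truth region mask) are resampled to a fixed square, pushed through
#' seeded random leaky-ReLU convolution banks with max pooling, reduced by
#' variance-threshold map selection (frozen on the training set), summarized
#' by seven block statistics per retained map, and fed to a softmax head
#' (two-class multinomial fit with weight decay). Training is deterministic
#' given `config$seed`. A region whose cohort carries a single class is
#' flagged untrainable with a warning instead of a model.
#'
#' @param cohort List of `phantom_sample` objects with both classes per
#'   region.
#' @param config A [classifier_config()].
#' @param bins Saliency histogram bins (default 256).
#' @return Named list of five `region_classifier` objects (untrainable ones
#'   carry `trained = FALSE`).
#' @export
train_region_classifiers <- function(cohort, config = classifier_config(),
                                     bins = 256L) {
  if (length(cohort) < 2L) stop_invalid("cohort must contain >= 2 samples")
  seg_by_region <- purrr::map(cohort, function(s) {
    sal <- extract_saliency(s$image, bins)
    seg <- segment_all_regions(sal, masks_from_labels(s$region_labels))
    seg$segments
  })
  models <- purrr::map(seq_len(5), function(ri) {
    region <- SPINAL_REGIONS[ri]
    y <- vapply(cohort, function(s) s$tumor_status[[region]], logical(1))
    if (length(unique(y)) < 2L) {
      warn(sprintf("region '%s' has a single class; model marked untrainable", region))
      return(structure(list(region = region, trained = FALSE),
                       class = "region_classifier"))
    }
    train_one_region(purrr::map(seg_by_region, region), y, region, config, ri)
  })
  setNames(models, SPINAL_REGIONS)
}

train_one_region <- function(segments, y, region, config, region_index) {
  seed <- config$seed + region_index
  banks <- withr::with_seed(seed, make_kernel_banks(config))
  raw <- segment_feature_matrix(segments, config, banks, config$leaky_slope,
                                config$input_size)
  keep <- !purrr::map_lgl(raw, is.null)
  if (sum(keep) < 2L || length(unique(y[keep])) < 2L) {
    warn(sprintf("region '%s': not enough non-empty segments; untrainable", region))
    return(structure(list(region = region, trained = FALSE),
                     class = "region_classifier"))
  }
  raw <- raw[keep]; y <- y[keep]

  # freeze variance-threshold map selection on training-set mean variances
  n_maps <- length(raw[[1]]$maps)
  var_mat <- t(vapply(raw, function(r) {
    vapply(r$maps, function(m) var(as.vector(m)), numeric(1))
  }, numeric(n_maps)))
  mean_vars <- colMeans(var_mat)
  sel <- variance_threshold_select(mean_vars, variant = config$variance_variant)
  # translate retained map indices to stat-vector columns (7 stats per map)
  stat_cols <- as.vector(vapply(sel$retained,
                                function(i) (i - 1L) * 7L + 1:7, integer(7)))

  X <- t(vapply(raw, function(r) r$stats[stat_cols],
                numeric(length(stat_cols))))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  feat_mean <- colMeans(X)
  feat_sd <- apply(X, 2, sd)
  feat_sd[feat_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, feat_mean), 2, feat_sd, "/")

  if (config$dropout > 0) {
    Xs <- withr::with_seed(seed + 1000L, {
      mask <- matrix(rbinom(length(Xs), 1L, 1 - config$dropout),
                     nrow(Xs), ncol(Xs))
      Xs * mask / (1 - config$dropout)
    })
  }

  df <- as.data.frame(Xs)
  df$y <- factor(ifelse(y, "tumor", "non_tumor"),
                 levels = c("non_tumor", "tumor"))
  fit <- withr::with_seed(seed + 2000L, {
    nnet::multinom(y ~ ., data = df, decay = config$decay,
                   maxit = config$maxit, trace = FALSE)
  })
  train_prob <- predict(fit, newdata = df, type = "probs")
  train_acc <- mean((train_prob >= 0.5) == (df$y == "tumor"))

  structure(
    list(region = region, trained = TRUE, config = config, banks = banks,
         retained_maps = sel$retained, map_variances = mean_vars,
         variance_pv = sel$pv, variance_threshold = sel$threshold,
         stat_cols = stat_cols, feat_mean = feat_mean, feat_sd = feat_sd,
         head = fit, coef = stats::coef(fit), n_train = length(y),
         train_accuracy = train_acc),
    class = "region_classifier"
  )
}

#' Score one region segment for tumor presence
#'
#' Runs the stored convolutional feature extractor and softmax head on a
#' segment image and returns the per-region call: tumor probability and the
#' binary label. The decision threshold is 0.5 on the tumor probability, with
#' the exact tie resolving to non-tumor (strict `>`), so an uninformative
#' head with equal logits calls no tumor.
#'
#' @param segment Segment image matrix with at least one nonzero pixel.
#' @param model A trained `region_classifier`.
#' @return One-row tibble: `region`, `probability` (tumor), `label`
#'   (logical, TRUE = tumor).
#' @export
classify_region <- function(segment, model) {
  if (!inherits(model, "region_classifier")) {
    stop_invalid("`model` must be a region_classifier", field = "model")
  }
  if (!isTRUE(model$trained)) {
    stop_invalid(sprintf("model for region '%s' is untrained", model$region))
  }
  check_image(segment, "segment")
  x <- crop_resize(segment, model$config$input_size)
  if (is.null(x)) stop_invalid("segment is entirely zero; nothing to classify")
  maps <- conv_forward(x, model$banks, model$config$leaky_slope)
  stats_vec <- unlist(purrr::map(maps, block_stats), use.names = FALSE)
  feats <- (stats_vec[model$stat_cols] - model$feat_mean) / model$feat_sd
  df <- as.data.frame(as.list(setNames(feats, paste0("f", seq_along(feats)))))
  p_tumor <- as.numeric(predict(model$head, newdata = df, type = "probs"))
  tibble(region = model$region, probability = p_tumor,
         label = p_tumor > 0.5)
}

#' Score all five regions of one segmentation
#'
#' Convenience wrapper applying [classify_region()] per region; a region with
#' an empty segment or an untrained model gets probability 0 and a non-tumor
#' label (no evidence).
#'
#' @param segmentation A `region_segmentation`.
#' @param models Named list from [train_region_classifiers()].
#' @return Five-row tibble of region calls.
#' @export
classify_all_regions <- function(segmentation, models) {
  purrr::map_dfr(SPINAL_REGIONS, function(region) {
    seg <- segmentation$segments[[region]]
    model <- models[[region]]
    if (!isTRUE(model$trained) || all(seg == 0)) {
      return(tibble(region = region, probability = 0, label = FALSE))
    }
    classify_region(seg, model)
  })
}

#' @export
print.region_classifier <- function(x, ...) {
  if (!isTRUE(x$trained)) {
    cat(sprintf("<region_classifier> %s (untrained)\n", x$region))
  } else {
    cat(sprintf(
      "<region_classifier> %s: %d retained maps of %d, %d features, train acc %.3f\n",
      x$region, length(x$retained_maps), length(x$map_variances),
      length(x$stat_cols), x$train_accuracy
    ))
  }
  invisible(x)
}
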