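#' Read a grayscale slice from PNG or NIfTI
#'
#' PNG values arrive already scaled to [0, 1]; RGB(A) PNGs are collapsed to
#' their channel mean. NIfTI data outside [0, 1] is min-max rescaled so every
#' reader yields intensities in [0, 1]; data already inside the range is left
#' untouched (so write/read round-trips are exact for NIfTI).
#'
#' @param path File path ending in `.png`, `.nii` or `.nii.gz`.
#' @return Numeric intensity matrix in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path), field = "path")
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                   c(1, 2), mean)
    }
    return(img)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) > 2L) arr <- arr[, , 1]
    arr <- matrix(as.numeric(arr), nrow = nrow(arr))
    rng <- range(arr)
    if (rng[1] < 0 || rng[2] > 1) {
      arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    }
    return(arr)
  }
  stop_invalid(sprintf("unsupported image format: %s", path), field = "path")
}

#' Write a grayscale slice as PNG or NIfTI
#'
#' PNG output is 8-bit grayscale (quantized to 1/255); NIfTI output keeps the
#' full floating-point values.
#'
#' @param image Numeric matrix in [0, 1].
#' @param path Destination ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  if (any(image < 0 | image > 1)) {
    stop_invalid("intensities must lie in [0, 1] before writing")
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else {
    stop_invalid(sprintf("unsupported image format: %s", path), field = "path")
  }
  invisible(path)
}

# label-map PNG palette: label k is stored as intensity k / 5 (k = 0..5)
#' Write / read a region label map as an 8-bit PNG
#'
#' Label `k` (0 = background, 1-5 = cervical..coccygeal) is stored as
#' intensity `k / 5`, so label maps survive 8-bit quantization exactly.
#'
#' @param labels Integer matrix with values 0-5.
#' @param path PNG path.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   returns the integer label matrix.
#' @export
write_label_map <- function(labels, path) {
  if (!all(labels %in% 0:5)) {
    stop_invalid("labels must be integers 0-5", field = "labels")
  }
  png::writePNG(labels / 5, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- read_image(path)
  matrix(as.integer(round(img * 5)), nrow(img))
}

#' Export a cohort to disk
#'
#' Writes each sample's image (`sample_###.png`) and label map
#' (`sample_###_labels.png`) plus a `manifest.csv` with the per-region tumor
#' flags and the ground-truth spread probability.
#'
#' @param cohort List of `phantom_sample`.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort_manifest(cohort)
  manifest$file <- sprintf("sample_%03d.png", manifest$sample)
  purrr::iwalk(cohort, function(s, i) {
    write_image(s$image, file.path(dir, sprintf("sample_%03d.png", i)))
    write_label_map(s$region_labels,
                    file.path(dir, sprintf("sample_%03d_labels.png", i)))
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated list:
#' phantom spec, cohort size and prevalence, saliency bins, mask-fusion
#' constants, classifier settings, spread variant, gate threshold, split
#' fractions and the master seed. The configuration round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param phantom A [phantom_spec()].
#' @param n_images Cohort size (default 200).
#' @param tumor_prevalence Per-region tumor probability (default 0.5).
#' @param bins Saliency histogram bins (default 256).
#' @param mask_constants Named list `a, c, d, f` (defaults 1, 0, 0, 1).
#' @param mask_source `"learned"` (pixel classifier fit on the training
#'   split) or `"truth"` (ground-truth label masks).
#' @param classifier A [classifier_config()].
#' @param spread_variant `"normalized"` or `"as_printed"`.
#' @param gate_threshold Correlation gate threshold (default 0.999).
#' @param split_fractions Train/validation/test fractions (default
#'   `c(0.6, 0.1, 0.3)`).
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            n_images = 200L, tumor_prevalence = 0.5,
                            bins = 256L,
                            mask_constants = list(a = 1, c = 0, d = 0, f = 1),
                            mask_source = c("learned", "truth"),
                            classifier = classifier_config(),
                            spread_variant = c("normalized", "as_printed"),
                            gate_threshold = 0.999,
                            split_fractions = c(0.6, 0.1, 0.3),
                            seed = 1L) {
  mask_source <- match.arg(mask_source)
  spread_variant <- match.arg(spread_variant)
  if (n_images < 3) stop_invalid("`n_images` must be >= 3", field = "n_images")
  if (gate_threshold <= 0 || gate_threshold > 1) {
    stop_invalid("`gate_threshold` must lie in (0, 1]", field = "gate_threshold")
  }
  stopifnot(all(c("a", "c", "d", "f") %in% names(mask_constants)))
  structure(
    list(phantom = phantom, n_images = as.integer(n_images),
         tumor_prevalence = tumor_prevalence, bins = as.integer(bins),
         mask_constants = mask_constants, mask_source = mask_source,
         classifier = classifier, spread_variant = spread_variant,
         gate_threshold = gate_threshold, split_fractions = split_fractions,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$phantom <- unclass(plain$phantom)
  plain$phantom$region_extents <- as.list(plain$phantom$region_extents)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ph <- raw$phantom
  phantom <- phantom_spec(
    height = ph$height, width = ph$width,
    region_extents = unlist(ph$region_extents),
    cord_intensity = ph$cord_intensity,
    background_intensity = ph$background_intensity,
    cord_width = ph$cord_width,
    tumor_regions = ph$tumor_regions %||% character(),
    tumor_radius = ph$tumor_radius, tumor_contrast = ph$tumor_contrast,
    noise_sigma = ph$noise_sigma, seed = ph$seed
  )
  pipeline_config(
    phantom = phantom, n_images = raw$n_images,
    tumor_prevalence = unlist(raw$tumor_prevalence),
    bins = raw$bins, mask_constants = raw$mask_constants,
    mask_source = raw$mask_source,
    classifier = do.call(classifier_config, raw$classifier),
    spread_variant = raw$spread_variant,
    gate_threshold = raw$gate_threshold,
    split_fractions = unlist(raw$split_fractions),
    seed = raw$seed
  )
}

# stable hash of a configuration (via its YAML form)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a seeded cohort, splits it 60:10:30 (by default), trains the
#' per-region classifiers on the training split (and, when
#' `mask_source = "learned"`, a pixel classifier for region masks), then
#' scores every test image: saliency extraction, five-region segmentation,
#' per-region tumor calls, and the region-weighted spread probability.
#' Obtained spread probabilities are correlated against the cohort's
#' ground-truth values and the batch is offered to the training pool through
#' the correlation gate. The run is a pure function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the evaluation report
#'   (JSON), the per-image results (CSV) and the configuration (YAML) are
#'   written there.
#' @return An object of class `pipeline_result`: list with `report` (named
#'   list of summary metrics), `per_image` (tibble), `per_region` (tibble),
#'   `correlation` (a `correlation_report`), `pool` (post-gate
#'   `training_pool`), `models`, `split`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config", field = "config")
  }
  seeds <- derive_seeds(config$seed, 4L)
  cohort <- generate_cohort(config$phantom, config$n_images,
                            config$tumor_prevalence, seed = seeds[1])
  split <- split_cohort(length(cohort), config$split_fractions, seed = seeds[2])
  train_set <- cohort[split$train]

  cc <- config$classifier
  cc$seed <- seeds[3]
  models <- train_region_classifiers(train_set, cc, bins = config$bins)

  mask_source <- NULL
  if (config$mask_source == "learned") {
    mask_source <- fit_pixel_classifier(train_set, list(seed = seeds[4]))
  }

  mc <- config$mask_constants
  test_set <- cohort[split$test]
  per_image <- purrr::imap_dfr(test_set, function(s, i) {
    stage <- "score"
    tryCatch({
      sal <- extract_saliency(s$image, config$bins)
      masks <- if (is.null(mask_source)) {
        masks_from_labels(s$region_labels, a = mc$a, c = mc$c, d = mc$d, f = mc$f)
      } else {
        predict_masks(mask_source, s$image, a = mc$a, c = mc$c, d = mc$d, f = mc$f)
      }
      seg <- segment_all_regions(sal, masks)
      calls <- classify_all_regions(seg, models)
      counts <- seg$pixel_counts
      weights <- if (sum(counts) > 0) {
        region_weights(region_lengths(counts))
      } else setNames(rep(0.2, 5), SPINAL_REGIONS)
      est <- spread_probability(calls, weights, variant = config$spread_variant)

      pred_labels <- matrix(0L, nrow(s$image), ncol(s$image))
      for (ri in seq_len(5)) {
        pred_labels[masks[[ri]]$binary > 0] <- ri
      }
      dice_by_region <- vapply(seq_len(5), function(ri) {
        dice(masks[[ri]]$binary > 0, s$region_labels == ri)
      }, numeric(1))

      tibble(
        image = split$test[i],
        !!!setNames(as.list(calls$probability), paste0("p_", calls$region)),
        !!!setNames(as.list(calls$label), paste0("call_", calls$region)),
        !!!setNames(as.list(s$tumor_status), paste0("truth_", SPINAL_REGIONS)),
        spread_obtained = est$spread_probability,
        spread_actual = s$spread_probability_actual,
        psnr_db = segmentation_psnr(pred_labels, s$region_labels),
        mean_dice = mean(dice_by_region)
      )
    }, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed on test image %d: %s",
                    stage, split$test[i], conditionMessage(e)), parent = e)
    })
  })

  per_region <- purrr::map_dfr(SPINAL_REGIONS, function(r) {
    pred <- per_image[[paste0("call_", r)]]
    truth <- per_image[[paste0("truth_", r)]]
    tibble(region = r, n = length(pred),
           accuracy = accuracy(pred, truth))
  })

  all_pred <- unlist(purrr::map(SPINAL_REGIONS, ~ per_image[[paste0("call_", .x)]]))
  all_truth <- unlist(purrr::map(SPINAL_REGIONS, ~ per_image[[paste0("truth_", .x)]]))

  corr <- if (nrow(per_image) >= 2L) {
    correlation(per_image$spread_actual, per_image$spread_obtained)
  } else NULL
  pool <- training_pool()
  if (!is.null(corr)) {
    pool <- update_pool(pool, test_set, corr, config$gate_threshold)
  }

  report <- list(
    accuracy_percent = accuracy(all_pred, all_truth),
    n_correct = sum(all_pred == all_truth),
    n_total = length(all_truth),
    per_region_accuracy = setNames(as.list(per_region$accuracy),
                                   per_region$region),
    mean_psnr_db = mean(pmin(per_image$psnr_db, PSNR_CAP_DB)),
    mean_dice = mean(per_image$mean_dice),
    spread_mae = mean(abs(per_image$spread_obtained - per_image$spread_actual)),
    c_pearson = if (is.null(corr)) NA_real_ else corr$c_pearson,
    c_printed = if (is.null(corr)) NA_real_ else corr$c_printed,
    gate_passed = pool$last_decision$gate_passed %||% NA,
    pool_size = pool$size,
    split_counts = lengths(split),
    config_hash = config_hash(config)
  )

  result <- structure(
    list(report = report, per_image = per_image, per_region = per_region,
         correlation = corr, pool = pool, models = models, split = split,
         config = config, config_hash = report$config_hash),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "report.json"))
    readr::write_csv(per_image, file.path(out_dir, "per_image.csv"))
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  }
  result
}

# deterministic JSON serialization of the report (stable key order and digits)
write_report_json <- function(report, path) {
  report$mean_psnr_db <- min(report$mean_psnr_db, PSNR_CAP_DB)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<pipeline_result> %d test images\n",
           "  region-call accuracy: %.2f%% (%d/%d)\n",
           "  mean Dice %.3f, mean PSNR %.2f dB\n",
           "  spread correlation (Pearson) %s, gate %s, pool size %d\n"),
    nrow(x$per_image), r$accuracy_percent, r$n_correct, r$n_total,
    r$mean_dice, r$mean_psnr_db,
    if (is.na(r$c_pearson)) "NA" else sprintf("%.4f", r$c_pearson),
    if (isTRUE(r$gate_passed)) "passed" else "held", r$pool_size
  ))
  invisible(x)
}
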