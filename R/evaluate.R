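#' Classification accuracy in percent
#'
#' `100 * n_correct / n_total` over paired label vectors.
#'
#' @param predictions,truth Equal-length vectors (length >= 1) of labels.
#' @return Accuracy in percent.
#' @examples
#' accuracy(c(1, 0, 1, 1), c(1, 0, 0, 1)) # 75
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop_invalid("`predictions` and `truth` must have equal length")
  }
  if (length(truth) < 1L) stop_invalid("need at least one pair")
  100 * sum(predictions == truth) / length(truth)
}

#' PSNR between two label maps
#'
#' Both maps are one-hot encoded over the union of their classes and the mean
#' squared error is taken over every pixel-channel entry, giving
#' `10 * log10(max_value^2 / MSE)` in decibels. Identical maps have zero
#' error; they report `Inf`, which file writers cap at the documented
#' sentinel of 99 dB. Complementary binary maps give exactly 0 dB.
#'
#' @param predicted_labels,truth_labels Integer label matrices, same shape.
#' @param max_value Peak signal value; 1 for one-hot maps (default).
#' @return PSNR in dB (`Inf` for an exact match).
#' @export
segmentation_psnr <- function(predicted_labels, truth_labels, max_value = 1) {
  check_image(predicted_labels, "predicted_labels")
  check_image(truth_labels, "truth_labels")
  check_same_shape(predicted_labels, truth_labels,
                   c("predicted_labels", "truth_labels"))
  classes <- sort(union(unique(as.vector(predicted_labels)),
                        unique(as.vector(truth_labels))))
  if (length(classes) < 2L) classes <- union(classes, classes[1] + 1)
  sq_err <- 0
  for (k in classes) {
    sq_err <- sq_err + sum(((predicted_labels == k) - (truth_labels == k))^2)
  }
  mse <- sq_err / (length(truth_labels) * length(classes))
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

# sentinel used when serializing an exact-match PSNR
PSNR_CAP_DB <- 99

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks; two empty
#' masks agree perfectly by convention (Dice 1).
#'
#' @param predicted_mask,truth_mask Logical or 0/1 matrices, same shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(predicted_mask, truth_mask) {
  if (is.logical(predicted_mask)) predicted_mask <- predicted_mask * 1
  if (is.logical(truth_mask)) truth_mask <- truth_mask * 1
  check_image(predicted_mask, "predicted_mask")
  check_image(truth_mask, "truth_mask")
  check_same_shape(predicted_mask, truth_mask,
                   c("predicted_mask", "truth_mask"))
  if (!all(predicted_mask %in% c(0, 1)) || !all(truth_mask %in% c(0, 1))) {
    stop_invalid("masks must be binary")
  }
  denom <- sum(predicted_mask) + sum(truth_mask)
  if (denom == 0) return(1)
  2 * sum(predicted_mask * truth_mask) / denom
}

#' Seeded train/validation/test split
#'
#' Shuffles indices under the seed and assigns `floor(n * f)` samples to the
#' training and validation sets; every remainder goes to the test set, so the
#' three sets always partition the cohort.
#'
#' @param n Cohort size (>= 3), or a list whose length is used.
#' @param fractions Three fractions summing to 1; default `c(0.6, 0.1, 0.3)`.
#' @param seed Shuffle seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(split_cohort(10, seed = 1)) # 6 1 3
#' @export
split_cohort <- function(n, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (n < 3L) stop_invalid("cohort must contain at least 3 samples", field = "n")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("`fractions` must be three values summing to 1",
                 field = "fractions")
  }
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  list(
    train = sort(idx[seq_len(n_train)]),
    validation = sort(idx[n_train + seq_len(n_val)]),
    test = if (n_train + n_val < n) sort(idx[seq.int(n_train + n_val + 1L, n)])
           else integer(0)
  )
}
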