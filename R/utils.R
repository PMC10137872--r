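# shared small helpers; all internal

stop_invalid <- function(msg, field = NULL) {
  abort(msg, class = "spinescan_invalid", field = field)
}

check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(sprintf("`%s` must be a numeric matrix", arg), field = arg)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_invalid(sprintf("`%s` must have at least one row and column", arg), field = arg)
  }
  if (!all(is.finite(x))) {
    stop_invalid(sprintf("`%s` contains non-finite values", arg), field = arg)
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a), dim(b))) {
    stop_invalid(sprintf(
      "`%s` (%s) and `%s` (%s) must share the same shape",
      what[1], paste(dim(a), collapse = "x"),
      what[2], paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# leaky rectifier, slope in (0,1): identity for x >= 0, slope*x below
leaky_relu <- function(x, slope = 0.01) pmax(x, slope * x)

# numerically stable softmax over a vector of logits
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# named per-region numeric vector, recycling a scalar
per_region <- function(x, arg = "value") {
  if (length(x) == 1L) x <- rep(x, 5L)
  if (length(x) != 5L) {
    stop_invalid(sprintf("`%s` must have length 1 or 5", arg), field = arg)
  }
  if (is.null(names(x))) names(x) <- SPINAL_REGIONS
  if (!setequal(names(x), SPINAL_REGIONS)) {
    stop_invalid(sprintf("`%s` names must be the five spinal regions", arg), field = arg)
  }
  x[SPINAL_REGIONS]
}

# deterministic sub-seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
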