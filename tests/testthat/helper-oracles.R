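# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay independent
# of the package's implementation paths.

# Shannon entropy of the empirical bin distribution, by direct enumeration
oracle_entropy <- function(image, bins) {
  idx <- pmin(floor(as.vector(image) * bins) + 1L, bins)
  freq <- table(idx) / length(idx)
  -sum(freq * log2(freq))
}

# nested-loop cross-correlation with zero padding and stride, then leaky ReLU
oracle_conv_leaky <- function(x, kernel, stride = 1L, padding = 0L,
                              slope = 0.01) {
  h <- nrow(x); w <- ncol(x)
  hp <- h + 2L * padding; wp <- w + 2L * padding
  padded <- matrix(0, hp, wp)
  padded[(padding + 1):(padding + h), (padding + 1):(padding + w)] <- x
  kr <- nrow(kernel); kc <- ncol(kernel)
  out_r <- floor((hp - kr) / stride) + 1L
  out_c <- floor((wp - kc) / stride) + 1L
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      acc <- 0
      for (a in seq_len(kr)) {
        for (b in seq_len(kc)) {
          acc <- acc + kernel[a, b] * padded[(i - 1) * stride + a,
                                             (j - 1) * stride + b]
        }
      }
      out[i, j] <- if (acc >= 0) acc else slope * acc
    }
  }
  out
}

# count of valid window placements by explicit enumeration
oracle_conv_size <- function(n_in, k, p, s) {
  padded <- n_in + 2L * p
  count <- 0L
  pos <- 1L
  while (pos + k - 1L <= padded) {
    count <- count + 1L
    pos <- pos + s
  }
  count
}

# easy, quickly separable phantom settings used in training tests
easy_spec <- function(seed = 1L, noise_sigma = 0.02, tumor_contrast = 0.4) {
  phantom_spec(noise_sigma = noise_sigma, tumor_contrast = tumor_contrast,
               seed = seed)
}
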