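test_that("spec validation names the violated field", {
  expect_error(phantom_spec(region_extents = rep(0.25, 4)), "5 entries",
               class = "spinescan_invalid")
  expect_error(phantom_spec(region_extents = c(0.5, 0.2, 0.2, 0.2, -0.1)),
               "> 0")
  expect_error(phantom_spec(region_extents = c(0.3, 0.3, 0.2, 0.1, 0.2)),
               "sum to 1")
  expect_error(phantom_spec(cord_intensity = 0.1, background_intensity = 0.5),
               "exceed")
  expect_error(phantom_spec(tumor_regions = "lumbar", tumor_radius = 0),
               "tumor_radius")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(tumor_regions = "pelvis"), "subset")
})

test_that("noiseless phantom without tumor has exactly two intensity values", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 3))
  expect_identical(sort(unique(as.vector(s$image))), c(0.1, 0.7))
})

test_that("noiseless phantom with tumor has exactly three intensity values", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, tumor_regions = "thoracic",
                                     tumor_contrast = 0.2, seed = 3))
  expect_length(unique(as.vector(s$image)), 3L)
})

test_that("uniform extents split rows evenly", {
  s <- generate_phantom(phantom_spec(height = 100, width = 20,
                                     region_extents = rep(0.2, 5),
                                     noise_sigma = 0, seed = 1))
  rows_per_region <- vapply(1:5, function(i) {
    sum(apply(s$region_labels == i, 1, any))
  }, integer(1))
  expect_identical(rows_per_region, rep(20L, 5))
})

test_that("same spec and seed render bit-identical samples", {
  spec <- phantom_spec(tumor_regions = c("lumbar", "sacral"), seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a, b)
  c <- generate_phantom(phantom_spec(tumor_regions = c("lumbar", "sacral"),
                                     seed = 100))
  expect_false(identical(a$image, c$image))
})

test_that("label maps give every region pixels matching extents within rounding", {
  s <- generate_phantom(phantom_spec(height = 90, seed = 2))
  counts <- vapply(1:5, function(i) sum(s$region_labels == i), integer(1))
  expect_true(all(counts >= 1))
  cord_cols <- sum(apply(s$region_labels > 0, 2, any))
  expected_rows <- s$spec$region_extents * 90
  observed_rows <- counts / cord_cols
  expect_true(all(abs(observed_rows - expected_rows) <= 1))
})

test_that("tumor discs stay inside their region and the image", {
  for (region in SPINAL_REGIONS) {
    s <- generate_phantom(phantom_spec(noise_sigma = 0, tumor_regions = region,
                                       tumor_contrast = 0.25, seed = 5))
    tumor_px <- which(s$image == 0.95, arr.ind = TRUE)
    expect_gt(nrow(tumor_px), 0)
    labels_at_tumor <- s$region_labels[tumor_px]
    expect_true(all(labels_at_tumor == match(region, SPINAL_REGIONS)))
  }
})

test_that("stored actual spread probability is self-consistent with aggregation", {
  s <- generate_phantom(phantom_spec(tumor_regions = c("cervical", "coccygeal"),
                                     seed = 11))
  counts <- vapply(1:5, function(i) sum(s$region_labels == i), numeric(1))
  w <- region_weights(region_lengths(setNames(counts, SPINAL_REGIONS)))
  expected <- spread_probability(
    setNames(as.numeric(s$tumor_status), SPINAL_REGIONS), w
  )$spread_probability
  expect_equal(s$spread_probability_actual, expected, tolerance = 1e-12)
})

test_that("cohort generation respects degenerate and nominal prevalences", {
  spec <- phantom_spec(seed = 1)
  none <- generate_cohort(spec, 10, tumor_prevalence = 0, seed = 4)
  expect_true(all(!unlist(purrr::map(none, "tumor_status"))))
  all_t <- generate_cohort(spec, 10, tumor_prevalence = 1, seed = 4)
  expect_true(all(unlist(purrr::map(all_t, "tumor_status"))))
  expect_error(generate_cohort(spec, 0), "n")
})

test_that("empirical prevalence converges to nominal (binomial bound)", {
  small <- phantom_spec(height = 20, width = 12, noise_sigma = 0, seed = 1)
  n <- 2000L
  cohort <- generate_cohort(small, n, tumor_prevalence = 0.3, seed = 8)
  flags <- vapply(cohort, function(s) s$tumor_status[["thoracic"]], logical(1))
  p_hat <- mean(flags)
  # 3 standard deviations of a Binomial(n, 0.3) proportion
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("cohort manifest carries flags and actual spread per sample", {
  cohort <- generate_cohort(phantom_spec(seed = 1), 5, 0.5, seed = 2)
  m <- cohort_manifest(cohort)
  expect_equal(nrow(m), 5)
  expect_true(all(SPINAL_REGIONS %in% names(m)))
  expect_equal(m$spread_probability_actual,
               vapply(cohort, function(s) s$spread_probability_actual,
                      numeric(1)))
})
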