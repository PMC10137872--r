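test_that("mask fusion reduces to each component and matches hand evaluation", {
  B <- matrix(c(1, 0, 1, 0), 2, 2)
  P <- matrix(c(0.5, 0.25, 1, 0), 2, 2)

  m_bin <- region_mask("cervical", B, P, a = 1, c = 0, d = 0, f = 1)
  expect_identical(combine_mask(m_bin), B)

  m_pix <- region_mask("cervical", B, P, a = 0, c = 1, d = 0, f = 1)
  expect_identical(combine_mask(m_pix), P)

  # a=1, c=1, d=1, f=2 at a pixel with B=1, P=0.5: 1 + 0.25 + 1
  m <- region_mask("cervical", matrix(1, 1, 1), matrix(0.5, 1, 1),
                   a = 1, c = 1, d = 1, f = 2)
  expect_equal(combine_mask(m)[1, 1], 2.25, tolerance = 1e-12)
})

test_that("mask fusion is monotone in a and c and validates its inputs", {
  B <- matrix(c(1, 0, 1, 1), 2, 2)
  P <- matrix(c(0.2, 0.8, 0.5, 0.1), 2, 2)
  base <- combine_mask(region_mask("lumbar", B, P, a = 1, c = 1))
  more_a <- combine_mask(region_mask("lumbar", B, P, a = 2, c = 1))
  more_c <- combine_mask(region_mask("lumbar", B, P, a = 1, c = 2))
  expect_true(all(more_a >= base))
  expect_true(all(more_c >= base))

  expect_error(region_mask("lumbar", B, P, f = 0), "f")
  expect_error(region_mask("lumbar", B, matrix(0.5, 3, 3)), "shape")
  expect_error(region_mask("lumbar", matrix(2, 2, 2)), "0/1")
})

test_that("segment extraction has the closed forms and additivity", {
  smi <- matrix(1, 3, 3)

  zero_mask <- region_mask("sacral", matrix(0, 3, 3))
  expect_true(all(segment_region(smi, zero_mask) == 0))

  ones <- region_mask("sacral", matrix(1, 3, 3))
  expect_equal(segment_region(smi, ones), matrix(log(2), 3, 3),
               tolerance = 1e-12)

  two <- segment_region(smi, list(ones, ones))
  expect_equal(two, 2 * segment_region(smi, ones), tolerance = 1e-12)
})

test_that("segment output is nonnegative and zero exactly outside support", {
  withr::with_seed(21, {
    smi <- matrix(runif(30), 5, 6)
    B <- matrix(rbinom(30, 1, 0.4), 5, 6)
  })
  seg <- segment_region(smi, region_mask("thoracic", B))
  expect_true(all(seg >= 0))
  expect_true(all(seg[B == 0] == 0))
  expect_true(all((seg > 0) == (B > 0 & smi > 0)))
})

test_that("five-region segmentation reproduces phantom label counts", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 31,
                                     tumor_regions = "thoracic"))
  sal <- extract_saliency(s$image)
  seg <- segment_all_regions(sal, masks_from_labels(s$region_labels))
  truth_counts <- vapply(1:5, function(i) sum(s$region_labels == i), integer(1))
  expect_identical(unname(seg$pixel_counts), truth_counts)
  for (i in 1:5) {
    expect_equal(dice(seg$segments[[i]] > 0, s$region_labels == i), 1)
  }
})

test_that("segmentation rejects overlapping masks and is order-independent", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 31))
  sal <- extract_saliency(s$image)
  masks <- masks_from_labels(s$region_labels)

  shuffled <- segment_all_regions(sal, masks[c(3, 1, 5, 2, 4)])
  expect_identical(shuffled, segment_all_regions(sal, masks))

  masks[[2]]$binary <- masks[[1]]$binary # thoracic duplicates cervical
  expect_error(segment_all_regions(sal, masks), "cervical, thoracic")
})

test_that("an empty region mask yields zero count without touching others", {
  s <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 31))
  sal <- extract_saliency(s$image)
  masks <- masks_from_labels(s$region_labels)
  full <- segment_all_regions(sal, masks)
  masks[[5]]$binary <- masks[[5]]$binary * 0
  partial <- segment_all_regions(sal, masks)
  expect_identical(unname(partial$pixel_counts[5]), 0L)
  expect_identical(partial$pixel_counts[1:4], full$pixel_counts[1:4])
})

test_that("pixel classifier recovers regions on its training phantom", {
  cohort <- generate_cohort(phantom_spec(noise_sigma = 0, seed = 1), 3,
                            tumor_prevalence = 0, seed = 2)
  pc <- fit_pixel_classifier(cohort, list(seed = 5))
  masks <- predict_masks(pc, cohort[[1]]$image)
  for (i in 1:5) {
    expect_gte(dice(masks[[i]]$binary > 0, cohort[[1]]$region_labels == i),
               0.95)
  }
})

test_that("pixel classifier is deterministic and handles degenerate inputs", {
  cohort <- generate_cohort(phantom_spec(noise_sigma = 0.02, seed = 1), 4,
                            tumor_prevalence = 0.5, seed = 2)
  pc1 <- fit_pixel_classifier(cohort, list(seed = 5))
  pc2 <- fit_pixel_classifier(cohort, list(seed = 5))
  m1 <- predict_masks(pc1, cohort[[2]]$image)
  m2 <- predict_masks(pc2, cohort[[2]]$image)
  expect_identical(m1, m2)

  background <- matrix(0.1, 96, 64)
  masks <- predict_masks(pc1, background)
  expect_true(all(vapply(masks, function(m) sum(m$binary), numeric(1)) == 0))

  flat <- cohort
  for (i in seq_along(flat)) {
    flat[[i]]$region_labels <- flat[[i]]$region_labels * 0L
  }
  expect_error(fit_pixel_classifier(flat, list(seed = 1)), "single class")
  expect_error(fit_pixel_classifier(cohort[1], list(seed = 1)), "2 training")
})
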