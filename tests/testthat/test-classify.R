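test_that("conv geometry matches window-placement enumeration", {
  expect_equal(conv_output_size(7, conv_spec(3)), 5)
  expect_equal(conv_output_size(7, conv_spec(3, padding = 1)), 7)
  expect_equal(conv_output_size(8, conv_spec(2, stride = 2)), 4)
  expect_error(conv_output_size(2, conv_spec(5)), "annihilates")
  expect_error(conv_spec(0), "kernel_size")
  expect_error(conv_spec(3, leaky_slope = 1.5), "leaky_slope")
})

test_that("leaky convolution has the identity and null closed forms", {
  withr::with_seed(2, x <- matrix(runif(25), 5, 5))
  expect_true(all(conv_leaky(matrix(0, 4, 4), matrix(1, 3, 3)) == 0))
  expect_equal(conv_leaky(x, matrix(1, 1, 1)), x, tolerance = 1e-12)
  sums <- conv_leaky(x, matrix(1, 3, 3))
  expect_equal(dim(sums), c(3L, 3L))
  expect_equal(sums[2, 2], sum(x[2:4, 2:4]), tolerance = 1e-12)
})

test_that("conv_leaky agrees with the nested-loop oracle across geometries", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n_in <- sample(3:10, 1)
      k <- sample(1:min(3, n_in), 1)
      p <- sample(0:2, 1)
      s <- sample(1:3, 1)
      x <- matrix(runif(n_in^2, -1, 1), n_in, n_in)
      kern <- matrix(runif(k^2, -1, 1), k, k)
      got <- conv_leaky(x, kern, stride = s, padding = p)
      want <- oracle_conv_leaky(x, kern, stride = s, padding = p)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("block statistics match library-grade references", {
  skip_if_not_installed("e1071")
  withr::with_seed(23, {
    for (i in 1:10) {
      block <- matrix(rnorm(48), 6, 8)
      st <- block_stats(block)
      x <- as.vector(block)
      expect_equal(st[["mean"]], mean(x), tolerance = 1e-8)
      expect_equal(st[["max"]], max(x), tolerance = 1e-8)
      expect_equal(st[["sd"]], sd(x), tolerance = 1e-8)
      expect_equal(st[["variance"]], var(x), tolerance = 1e-8)
      expect_equal(st[["kurtosis"]], e1071::kurtosis(x, type = 1),
                   tolerance = 1e-8)
      a <- as.vector(block[, -ncol(block)])
      b <- as.vector(block[, -1])
      expect_equal(st[["correlation"]], cor(a, b), tolerance = 1e-8)
      norm <- (x - min(x)) / diff(range(x))
      expect_equal(st[["entropy"]], oracle_entropy(matrix(norm, 6), 8),
                   tolerance = 1e-8)
    }
  })
  # degenerate block: constant
  st0 <- block_stats(matrix(2, 3, 3))
  expect_equal(unname(st0[c("sd", "kurtosis", "entropy", "variance",
                            "correlation")]), rep(0, 5))
})

test_that("variance-threshold selection follows the stated rule", {
  # single feature survives unchanged
  one <- variance_pool(list(matrix(c(1, 2, 3, 4), 2)))
  expect_identical(one$retained, 1L)

  # the max-variance feature always survives
  feats <- list(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                matrix(c(-5, 5, -5, 5), 2))
  kept <- variance_pool(feats)
  expect_true(4L %in% kept$retained)

  # all-constant set warns and keeps only the first feature
  expect_warning(flat <- variance_pool(list(matrix(1, 2, 2), matrix(2, 2, 2))),
                 "constant")
  expect_identical(flat$retained, 1L)

  # 10 features with variances ~1..10: replay the rule by hand
  withr::with_seed(31, {
    feats <- purrr::map(1:10, ~ matrix(rnorm(100, sd = sqrt(.x)), 10))
  })
  got <- variance_pool(feats)
  s <- vapply(feats, function(f) var(as.vector(f)), numeric(1))
  pv <- min(max(mean(s > median(s)), 0.01), 0.99)
  fth <- mean(s) * pv / (1 - pv)
  want <- which(s >= fth)
  if (length(want) == 0) want <- which.max(s)
  expect_identical(got$retained, want)
  expect_equal(got$threshold, fth, tolerance = 1e-12)
  # no retained feature sits below the retained minimum by construction
  expect_true(all(s[got$retained] >= min(s[got$retained])))

  # the as-printed threshold is negative, so everything is retained
  printed <- variance_pool(feats, variant = "as_printed")
  expect_identical(printed$retained, 1:10)
  expect_lt(printed$threshold, 0)
})

test_that("softmax head outputs sum to 1 and are shift-invariant", {
  sm <- spinescan:::softmax
  expect_equal(sm(c(0, 0)), c(0.5, 0.5), tolerance = 1e-12)
  for (z in c(-7, 0, 3.2)) {
    expect_equal(sm(c(z, z)), c(0.5, 0.5), tolerance = 1e-12)
  }
  withr::with_seed(4, {
    for (i in 1:20) {
      logits <- rnorm(2, sd = 5)
      p <- sm(logits)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, sm(logits + 100), tolerance = 1e-9)
    }
  })
})

test_that("region classifiers train deterministically and recover easy labels", {
  cohort <- generate_cohort(easy_spec(), 40, tumor_prevalence = 0.5, seed = 60)
  cfg <- classifier_config(seed = 7)
  m1 <- train_region_classifiers(cohort, cfg)
  m2 <- train_region_classifiers(cohort, cfg)
  expect_identical(purrr::map(m1, "coef"), purrr::map(m2, "coef"))
  expect_identical(purrr::map_dbl(m1, "train_accuracy"),
                   purrr::map_dbl(m2, "train_accuracy"))

  # hold out a fresh small batch from the same settings
  heldout <- generate_cohort(easy_spec(seed = 2), 20, 0.5, seed = 61)
  calls <- purrr::map_dfr(heldout, function(s) {
    sal <- extract_saliency(s$image)
    seg <- segment_all_regions(sal, masks_from_labels(s$region_labels))
    dplyr::mutate(classify_all_regions(seg, m1),
                  truth = as.vector(s$tumor_status))
  })
  expect_gte(accuracy(calls$label, calls$truth), 85)
})

test_that("single-class regions are flagged untrainable, not fitted", {
  cohort <- generate_cohort(phantom_spec(seed = 1), 8,
                            tumor_prevalence = c(cervical = 0, thoracic = 0.5,
                                                 lumbar = 0.5, sacral = 0.5,
                                                 coccygeal = 0.5),
                            seed = 3)
  w <- capture_warnings(
    models <- train_region_classifiers(cohort, classifier_config())
  )
  expect_true(any(grepl("cervical.*untrainable", w)))
  expect_false(models$cervical$trained)
  expect_error(classify_region(matrix(1, 4, 4), models$cervical), "untrained")
})

test_that("classify_region validates its inputs", {
  cohort <- generate_cohort(easy_spec(), 10, 0.5, seed = 9)
  models <- train_region_classifiers(cohort, classifier_config(seed = 1))
  trained <- purrr::detect(models, ~ isTRUE(.x$trained))
  expect_error(classify_region(matrix(0, 8, 8), trained), "entirely zero")
  call <- classify_region(matrix(runif(64), 8, 8), trained)
  expect_true(call$probability >= 0 && call$probability <= 1)
  expect_identical(call$label, call$probability > 0.5)
})

test_that("conv output size formula matches conv_leaky shapes (spot grid)", {
  withr::with_seed(15, {
    for (n_in in c(4, 9, 16)) {
      for (k in c(1, 3, 5)) {
        for (p in 0:2) {
          for (s in 1:3) {
            if (n_in + 2 * p - k < 0) next
            x <- matrix(runif(n_in^2), n_in, n_in)
            kern <- matrix(runif(k^2), k, k)
            got <- conv_leaky(x, kern, stride = s, padding = p)
            expect_equal(nrow(got),
                         conv_output_size(n_in, conv_spec(k, s, p)))
          }
        }
      }
    }
  })
})
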