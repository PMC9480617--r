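test_that("z-scoring normalises, is idempotent and re-applicable", {
  z <- zscore(data.frame(a = c(1, 2, 3)))
  expect_equal(as.numeric(z$values), c(-1, 0, 1))
  z2 <- zscore(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  tab <- simulate_feature_table(40, seed = 2)
  zs <- zscore(tab)
  expect_equal(unname(colMeans(zs$values)), rep(0, 16), tolerance = 1e-9)
  expect_equal(unname(apply(zs$values, 2, sd)), rep(1, 16), tolerance = 1e-9)
  # stored (mean, sd) reproduce the normalized matrix bit-for-bit
  expect_identical(apply_zscore(tab, zs$center, zs$scale), zs$values)
  expect_error(zscore(data.frame(a = c(1, 1, 1))), "a")
})

test_that("cross-term construction yields p(p-1)/2 products in fixed order", {
  z16 <- zscore(simulate_feature_table(30, seed = 3))
  cm <- make_cross_terms(z16$values)
  expect_equal(ncol(cm$values), 136L)
  expect_equal(ncol(cm$values) - cm$n_primaries, 120L)
  expect_identical(cm$names[1:16], postural_feature_names())
  expect_identical(cm$names[17], "MP3 × Mean-AP")
  # C(3, 2) = 3
  z3 <- zscore(simulate_feature_table(10, n_features = 3, seed = 4))
  expect_equal(ncol(make_cross_terms(z3$values)$values), 6L)
  # count formula against exhaustive enumeration for several widths
  for (p in c(2, 5, 9, 16, 30)) {
    zp <- zscore(simulate_feature_table(p + 5, n_features = p, seed = p))
    cmp <- make_cross_terms(zp$values)
    expect_equal(ncol(cmp$values) - p, p * (p - 1) / 2)
    expect_equal(anyDuplicated(cmp$names), 0L)
  }
  # each product column equals the elementwise product before re-normalisation
  zx <- zscore(simulate_feature_table(25, n_features = 4, seed = 6))
  cmx <- make_cross_terms(zx$values)
  expect_equal(unname(cmx$raw_products[, 1]),
               unname(zx$values[, 1] * zx$values[, 2]))
  expect_error(make_cross_terms(zx$values[, c(1, 1)]), "duplicate")
})

test_that("median split applies the strict-inequality rule", {
  ms <- median_split(c(3, 41, 41, 50))
  expect_equal(ms$median, 41)
  expect_equal(ms$status, c(0L, 0L, 0L, 1L))
  # tie-free continuous scores, even n: exactly half mindful
  set.seed(5)
  sc <- rnorm(80)
  expect_equal(sum(median_split(sc)$status), 40L)
  # brute-force rule application on random integers
  set.seed(6)
  ints <- sample(14:56, 51, replace = TRUE)
  expect_equal(median_split(ints)$status,
               as.integer(ints > median(ints)))
  expect_error(median_split(numeric(0)))
})

test_that("the 70/30 split is a seeded stratified partition", {
  split <- split_trainval_test(156, seed = 1)
  expect_equal(sum(split == "trainval"), 109L)
  expect_equal(sum(split == "test"), 47L)
  # balanced stratification is preserved
  status <- rep(c(0L, 1L), each = 5)
  s2 <- split_trainval_test(10, fraction = 0.5, stratify = status, seed = 2)
  expect_equal(sum(s2 == "trainval"), 5L)
  expect_equal(sum(s2 == "trainval" & status == 1), sum(s2 == "trainval" & status == 0), tolerance = 1)
  # partition property across seeds
  for (seed in 1:5) {
    sp <- split_trainval_test(37, stratify = rep_len(c(0L, 1L), 37),
                              seed = seed)
    expect_equal(sort(unique(sp)), c("test", "trainval"))
    expect_length(sp, 37)
  }
  # stratified 156 keeps 109/47 too
  st <- rep_len(c(0L, 1L), 156)
  s3 <- split_trainval_test(156, stratify = st, seed = 3)
  expect_equal(sum(s3 == "trainval"), 109L)
  expect_error(split_trainval_test(5, stratify = c(0, 0, 0, 0, 1)),
               "stratum")
})

test_that("questionnaire totals respect the 14-56 range and item-13 reversal", {
  low <- matrix(1, 1, 14); low[, 13] <- 4
  high <- matrix(4, 1, 14); high[, 13] <- 1
  expect_equal(fmi_total(low), 14L)
  expect_equal(fmi_total(high), 56L)
  set.seed(7)
  items <- matrix(sample(1:4, 14 * 50, replace = TRUE), 50, 14)
  totals <- fmi_total(items)
  expect_true(all(totals >= 14 & totals <= 56))
  # reversal: raising item 13 lowers the total
  more <- items; more[, 13] <- pmin(more[, 13] + 1, 4)
  expect_true(all(fmi_total(more) <= totals))
  expect_error(fmi_total(items[, 1:13]), "14 items")
  expect_error(fmi_total(items - 1), "1..4")
})

test_that("labelled cohorts wire normalisation, labels and split together", {
  feats <- simulate_feature_table(60, seed = 8)
  pl <- plant_response(feats, list(c("Mean-ML", "PF95AP")), 3, noise_sd = 2,
                       response_link = "latent", seed = 9)
  lc <- labeled_cohort(feats, pl$score, split_seed = 10)
  expect_s3_class(lc, "labeled_cohort")
  expect_equal(ncol(lc$candidates$values), 136L)
  expect_equal(sum(lc$split == "trainval"), 42L)
  expect_identical(lc$status, as.integer(pl$score > lc$median_used))
  # training-only provenance normalises over trainval rows only
  lc2 <- labeled_cohort(feats, pl$score, split_seed = 10,
                        provenance = "training-only")
  tv <- lc2$split == "trainval"
  expect_equal(unname(colMeans(lc2$candidates$values[tv, 1:16])),
               rep(0, 16), tolerance = 1e-9)
})
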