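test_that("zero-noise traces sit at the configured fixed point", {
  cfg <- cohort_config(n_subjects = 4, conditions = "EC", duration = 5,
                       sway_params = list(noise = c(0, 0),
                                          offset_ml = c(2, 0),
                                          offset_ap = c(-3, 0)),
                       seed = 1)
  rec <- simulate_cop_trace(cfg, 1, "EC")
  expect_equal(rec$n_samples, 200L)
  expect_equal(rec$ml, rep(2, 200), tolerance = 1e-12)
  expect_equal(rec$ap, rep(-3, 200), tolerance = 1e-12)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- cohort_config(n_subjects = 5, conditions = c("EC", "EO"),
                       duration = 8, seed = 42)
  a <- simulate_cop_trace(cfg, 3, "EO")
  b <- simulate_cop_trace(cfg, 3, "EO")
  expect_identical(a$ml, b$ml)
  expect_identical(a$ap, b$ap)
  # different subjects / conditions give different draws
  expect_false(identical(a$ml, simulate_cop_trace(cfg, 2, "EO")$ml))
  expect_false(identical(a$ml, simulate_cop_trace(cfg, 3, "EC")$ml))
  expect_identical(simulate_feature_table(7, seed = 9),
                   simulate_feature_table(7, seed = 9))
})

test_that("invalid condition labels are rejected by name", {
  cfg <- cohort_config(n_subjects = 4, duration = 5, seed = 1)
  expect_error(simulate_cop_trace(cfg, 1, "XX"), "EC, EO")
})

test_that("trace variance matches a long-run simulation of the same process", {
  # package trace: 250 s at 40 Hz (10 000 steps)
  cfg <- cohort_config(n_subjects = 4, conditions = "EC", duration = 250,
                       sway_params = list(freq = c(0.4, 0), damping = c(0.7, 0),
                                          noise = c(15, 0),
                                          offset_ml = c(0, 0),
                                          offset_ap = c(0, 0),
                                          condition_gain = c(EC = 1)),
                       seed = 5)
  rec <- simulate_cop_trace(cfg, 1, "EC")
  # oracle: 10x longer independent Euler simulation of the same process
  set.seed(99)
  dt <- 1 / 40; omega <- 2 * pi * 0.4; zeta <- 0.7; sig <- 15
  n_long <- 10L * rec$n_samples
  x <- numeric(n_long); xx <- 0; xv <- 0
  shocks <- rnorm(n_long, 0, sig * sqrt(dt))
  for (i in seq_len(n_long)) {
    xv <- xv + dt * (-2 * zeta * omega * xv - omega^2 * xx) + shocks[i]
    xx <- xx + dt * xv
    x[i] <- xx
  }
  x <- x[-seq_len(40L)]
  v_oracle <- var(x)
  # standard error of the trace's sample variance via batch means
  batches <- split(rec$ml, rep(seq_len(20), each = rec$n_samples / 20))
  bv <- vapply(batches, var, numeric(1))
  se <- sd(bv) / sqrt(length(bv))
  expect_lt(abs(var(rec$ml) - v_oracle), 3 * se + 0.05 * v_oracle)
})

test_that("null cohort yields the constant intercept score", {
  cfg <- cohort_config(n_subjects = 4, conditions = "EC", duration = 15,
                       planted_terms = list(), effect_sizes = numeric(0),
                       noise_sd = 0, intercept = 35, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(co$scores$score, rep(35, 4))
})

test_that("a single planted term with zero noise gives exact linearity", {
  cfg <- cohort_config(n_subjects = 8, conditions = "EC", duration = 15,
                       planted_terms = list(c("Mean-ML", "log-MV")),
                       effect_sizes = 5, noise_sd = 0,
                       response_link = "latent", seed = 7)
  co <- simulate_cohort(cfg)
  expect_equal(cor(co$scores$score, co$cross_terms[, 1]), 1,
               tolerance = 1e-12)
})

test_that("planted effects are recovered by least squares on realized terms", {
  feats <- simulate_feature_table(300, seed = 21)
  pl <- plant_response(feats, list(c("Mean-ML", "log-Alpha-AP"),
                                   c("MP3", "Beta-AP")),
                       effect_sizes = c(4, 3), noise_sd = 2,
                       response_link = "latent", seed = 22)
  fit <- summary(lm(pl$score ~ pl$cross_terms))
  est <- coef(fit)[2:3, ]
  expect_lt(abs(est[1, "Estimate"] - 4), 3 * est[1, "Std. Error"])
  expect_lt(abs(est[2, "Estimate"] - 3), 3 * est[2, "Std. Error"])
})

test_that("feature tables honour the requested correlation structure", {
  tab <- simulate_feature_table(10000, seed = 31)
  cors <- cor(as.matrix(tab))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  expect_identical(names(tab), postural_feature_names())
  # degenerate size
  one <- simulate_feature_table(1, seed = 1)
  expect_equal(nrow(one), 1L)
  # non-PSD rejected
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(simulate_feature_table(5, n_features = 3, correlation = bad),
               "positive semi-definite")
})

test_that("unknown planted features are rejected", {
  expect_error(cohort_config(planted_terms = list(c("Mean-ML", "NotAFeat")),
                             effect_sizes = 1),
               "NotAFeat")
  feats <- simulate_feature_table(10, seed = 1)
  expect_error(plant_response(feats, list(c("Mean-ML", "nope")), 1),
               "unresolvable")
})
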