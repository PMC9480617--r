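test_that("mean position and path length follow the defining arithmetic", {
  rec <- toy_recording(rep(2, 10), rep(-1, 10))
  expect_equal(mean_position(rec, "ml"), 2)
  expect_equal(mean_position(toy_recording(c(-1, 1), c(0, 0)), "ml"), 0)
  # 3-4-5 step
  expect_equal(path_length(toy_recording(c(0, 3), c(0, 4))), 5)
  # constant trace has zero length and a guarded log
  const <- toy_recording(rep(1, 600), rep(1, 600))
  expect_equal(path_length(const), 0)
  # a motionless record fails feature extraction with a named feature:
  # no velocity crossings and a zero path length are both degenerate
  expect_error(extract_features(const), "insufficient crossings|degenerate")
  # random trace equals the brute-force pairwise-step oracle
  rec2 <- sim_recording(seed = 3, duration = 10)
  steps <- sqrt(diff(rec2$ml)^2 + diff(rec2$ap)^2)
  expect_equal(path_length(rec2), sum(steps))
  expect_equal(mean_velocity(rec2, "ml"),
               sum(abs(diff(rec2$ml))) / ((rec2$n_samples - 1) / 40))
})

test_that("velocity zero crossings count sign changes of the filtered velocity", {
  t <- seq(0, 5 - 1 / 40, by = 1 / 40)   # 5 full 1 Hz periods
  rec <- toy_recording(sin(2 * pi * t), sin(2 * pi * t))
  expect_equal(zero_crossings_velocity(rec, "ap"), 10)
  ramp <- toy_recording(seq(0, 10, length.out = 200),
                        seq(0, 10, length.out = 200))
  expect_equal(zero_crossings_velocity(ramp, "ap"), 0)
  # random trace: equals an independent sign-change count on the same
  # filtered central-difference velocity
  rec2 <- sim_recording(seed = 5, duration = 20)
  x <- rec2$ap; n <- length(x)
  v <- (x[3:n] - x[1:(n - 2)]) / 2 * 40
  bf <- signal::butter(4, 10 / 20, type = "low")
  vp <- c(2 * v[1] - v[13:2], v, 2 * v[length(v)] - v[(length(v) - 1):(length(v) - 12)])
  fv <- as.numeric(signal::filter(bf, vp))
  fv <- rev(as.numeric(signal::filter(bf, rev(fv))))[13:(12 + length(v))]
  s <- sign(fv); s <- s[s != 0]
  expect_equal(zero_crossings_velocity(rec2, "ap"), sum(diff(s) != 0))
})

test_that("Gamma fits recover known parameters and degenerate limits", {
  set.seed(17)
  durations <- rgamma(10000, shape = 2, scale = 3)
  fit <- fit_gamma_durations(durations)
  expect_equal(fit$alpha, 2, tolerance = 0.05)
  expect_equal(fit$beta, 3, tolerance = 0.05)
  # cross-check against an independent MLE implementation
  ref <- MASS::fitdistr(durations, "gamma")
  expect_equal(fit$alpha, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$beta, 1 / unname(ref$estimate["rate"]), tolerance = 1e-3)
  # all-equal durations: shape diverges, mean alpha*beta is the duration
  deg <- fit_gamma_durations(rep(0.25, 8))
  expect_equal(deg$alpha * deg$beta, 0.25, tolerance = 1e-9)
  expect_gt(deg$alpha, 1e6)
  expect_error(fit_gamma_durations(c(1, 2, 3)), "insufficient")
})

test_that("crossing durations equal a run-length oracle on the speed series", {
  rec <- sim_recording(seed = 6, duration = 20)
  durations <- velocity_crossing_durations(rec, "ml")
  x <- rec$ml; n <- length(x)
  speed <- abs((x[3:n] - x[1:(n - 2)]) / 2 * 40)
  above <- speed > mean(speed)
  # manual run-length scan
  runs <- numeric(0); len <- 0
  for (i in seq_along(above)) {
    if (above[i]) len <- len + 1
    else if (len > 0) { runs <- c(runs, len); len <- 0 }
  }
  if (len > 0) runs <- c(runs, len)
  expect_equal(durations, runs / 40)
})

test_that("sway density matches geometry and the O(n^2) oracle", {
  const <- toy_recording(rep(0, 200), rep(0, 200))
  sd_const <- sway_density(const, R = 3)
  expect_equal(sd_const$values, rep(200 / 40, 200))
  # alternating between two points 10 mm apart at R = 3: only the sample itself
  alt <- toy_recording(rep(c(0, 10), 100), rep(0, 200))
  expect_equal(sway_density(alt, R = 3)$values, rep(1 / 40, 200))
  # oracle equivalence on a short simulated trace
  rec <- sim_recording(seed = 7, duration = 12)
  stopifnot(rec$n_samples <= 500)
  for (R in c(2, 3, 5)) {
    curve <- sway_density(rec, R)
    expect_equal(curve$values,
                 sway_density_oracle(rec$ml, rec$ap, R) / 40)
  }
})

test_that("spectral features localise tones and satisfy Parseval", {
  t <- seq(0, 40 - 1 / 40, by = 1 / 40)
  tone <- toy_recording(rnorm(length(t), 0, 0.01),
                        sin(2 * pi * 2 * t))
  spec <- spectral_features(tone)
  expect_lt(abs(spec$pf95_ap - 2), 0.1 + 1e-9)  # within one bin (0.1 Hz)
  # total power approximates the variance of the mean-removed planar series
  rec <- sim_recording(seed = 9, duration = 40)
  spec2 <- spectral_features(rec)
  planar_var <- var(rec$ml) + var(rec$ap)
  expect_equal(spec2$power_total, planar_var, tolerance = 0.05)
  # doubling one axis quadruples its power
  set.seed(11)
  w <- rnorm(2048)
  r1 <- toy_recording(w, rnorm(2048))
  r2 <- toy_recording(2 * w, rnorm(2048))
  expect_equal(spectral_features(r2)$power_ml /
                 spectral_features(r1)$power_ml, 4, tolerance = 0.01)
})

test_that("the full feature vector is complete, deterministic and composed of its parts", {
  cfg <- cohort_config(n_subjects = 6, conditions = "EC", duration = 20,
                       seed = 13)
  recs <- lapply(1:6, function(i)
    lowpass_filter(simulate_cop_trace(cfg, i, "EC")))
  tab <- extract_feature_table(recs)
  expect_equal(nrow(tab), 6)
  expect_identical(setdiff(names(tab), c("subject_id", "condition")),
                   postural_feature_names())
  expect_false(anyNA(tab))
  expect_identical(extract_features(recs[[1]]), extract_features(recs[[1]]))
  fv <- extract_features(recs[[2]])
  rec <- recs[[2]]
  expect_equal(unname(fv["Mean-AP"]), mean_position(rec, "ap"))
  expect_equal(unname(fv["MP3"]), mean_peak(rec, 3))
  expect_equal(unname(fv["log-LNG"]), log(path_length(rec)))
  expect_equal(unname(fv["log-MV-ML"]), log(mean_velocity(rec, "ml")))
  expect_equal(unname(fv["Zero-cross-V-AP"]),
               zero_crossings_velocity(rec, "ap"))
  gam <- velocity_crossing_gamma(rec, "ap")
  expect_equal(unname(fv["Beta-AP"]), gam$beta)
  expect_equal(unname(fv["log-Alpha-AP"]), log(gam$alpha))
  expect_equal(unname(fv["log-slope-MP"]), log(abs(slope_mp(rec))))
  expect_equal(unname(fv["PF95AP"]), spectral_features(rec)$pf95_ap)
})

test_that("features transform correctly under translation, scaling and time reversal", {
  rec <- sim_recording(seed = 15, duration = 20)
  fv <- extract_features(rec)
  # translation: only the mean positions move
  shifted <- rec; shifted$ml <- rec$ml + 7; shifted$ap <- rec$ap - 4
  fs <- extract_features(shifted)
  expect_equal(unname(fs["Mean-ML"]), unname(fv["Mean-ML"]) + 7)
  expect_equal(unname(fs["Mean-AP"]), unname(fv["Mean-AP"]) - 4)
  others <- setdiff(postural_feature_names(),
                    c("Mean-ML", "Mean-AP", "MP3", "log-slope-MP"))
  expect_equal(fs[others], fv[others], tolerance = 1e-9)
  # sway-density features use absolute radii but are translation invariant too
  expect_equal(unname(fs["MP3"]), unname(fv["MP3"]), tolerance = 1e-9)
  # scaling by c > 1: path/velocity scale by c, powers by c^2,
  # frequency-domain and crossing-count features are unchanged
  c0 <- 2.5
  scaled <- rec; scaled$ml <- rec$ml * c0; scaled$ap <- rec$ap * c0
  fc <- extract_features(scaled)
  expect_equal(unname(fc["log-LNG"]), unname(fv["log-LNG"]) + log(c0),
               tolerance = 1e-9)
  expect_equal(unname(fc["log-MV"]), unname(fv["log-MV"]) + log(c0),
               tolerance = 1e-9)
  expect_equal(unname(fc["log-Power"]), unname(fv["log-Power"]) + 2 * log(c0),
               tolerance = 1e-9)
  expect_equal(unname(fc["PF95AP"]), unname(fv["PF95AP"]))
  expect_equal(unname(fc["Zero-cross-V-AP"]), unname(fv["Zero-cross-V-AP"]))
  expect_equal(unname(fc["log-Alpha-ML"]), unname(fv["log-Alpha-ML"]),
               tolerance = 1e-9)
  # time reversal: lengths, velocities, powers and duration sets unchanged
  revd <- rec; revd$ml <- rev(rec$ml); revd$ap <- rev(rec$ap)
  expect_equal(path_length(revd), path_length(rec))
  expect_equal(spectral_features(revd)$power_total,
               spectral_features(rec)$power_total, tolerance = 1e-9)
  expect_equal(sort(velocity_crossing_durations(revd, "ml")),
               sort(velocity_crossing_durations(rec, "ml")))
  # the raw sway-density curve reverses with the series (peak thinning may
  # then resolve near-ties differently, so the curve is the invariant)
  expect_equal(sway_density(revd, 3)$values, rev(sway_density(rec, 3)$values),
               tolerance = 1e-12)
})

test_that("feature tables round-trip through CSV exactly", {
  cfg <- cohort_config(n_subjects = 4, conditions = "EC", duration = 15,
                       seed = 19)
  recs <- lapply(1:4, function(i)
    lowpass_filter(simulate_cop_trace(cfg, i, "EC")))
  tab <- extract_feature_table(recs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  back <- read_feature_csv(path)
  for (nm in postural_feature_names())
    expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-12)
})
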