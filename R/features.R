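#' Conventions for postural feature extraction
#'
#' All tunable conventions of the feature extractor live in one place so they
#' can be revised together. Defaults: velocity by central finite difference,
#' smoothed with the same zero-phase Butterworth family at 10 Hz; sway-density
#' curves smoothed with a 0.5 s moving average before peak picking; peaks are
#' strict local maxima at least 0.25 s apart; Welch spectra use 10 s Hann
#' segments with 50% overlap.
#'
#' @param velocity_cutoff Low-pass cutoff (Hz) applied to the CoP velocity
#'   before zero-crossing counting.
#' @param filter_order Butterworth order for velocity smoothing.
#' @param sd_radius Sway-density radius R (mm) for the mean-peak feature.
#' @param slope_radii Radii (mm) of the mean-peak-vs-R regression.
#' @param sd_smooth_s Moving-average window (s) for sway-density smoothing.
#' @param peak_min_sep_s Minimum separation (s) between retained peaks.
#' @param welch_segment_s Welch segment length (s).
#' @param welch_overlap Welch segment overlap fraction.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(velocity_cutoff = 10, filter_order = 4,
                           sd_radius = 3, slope_radii = 2:5,
                           sd_smooth_s = 0.5, peak_min_sep_s = 0.25,
                           welch_segment_s = 10, welch_overlap = 0.5) {
  structure(list(velocity_cutoff = velocity_cutoff,
                 filter_order = filter_order,
                 sd_radius = sd_radius, slope_radii = slope_radii,
                 sd_smooth_s = sd_smooth_s, peak_min_sep_s = peak_min_sep_s,
                 welch_segment_s = welch_segment_s,
                 welch_overlap = welch_overlap),
            class = "feature_config")
}

axis_series <- function(rec, axis) {
  axis <- match.arg(axis, c("ml", "ap"))
  rec[[axis]]
}

#' Mean CoP position on one axis
#'
#' @param rec A [cop_recording()].
#' @param axis `"ml"` or `"ap"`.
#' @return Mean position in mm.
#' @export
mean_position <- function(rec, axis) {
  x <- axis_series(rec, axis)
  if (length(x) < 1L) stop("empty series", call. = FALSE)
  mean(x)
}

#' Path length and mean velocity of the CoP trajectory
#'
#' `path_length` is the total length (mm) of the planar CoP trajectory, the
#' sum of Euclidean step lengths. `mean_velocity` divides the travelled
#' distance by the record duration `(n - 1) / sampling_rate`; the per-axis
#' variants use the summed absolute increments on that axis only.
#'
#' @param rec A [cop_recording()].
#' @param axis `"planar"` (default), `"ml"` or `"ap"`.
#' @return mm (`path_length`) or mm/s (`mean_velocity`).
#' @export
path_length <- function(rec) {
  if (rec$n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  sum(sqrt(diff(rec$ml)^2 + diff(rec$ap)^2))
}

#' @rdname path_length
#' @export
mean_velocity <- function(rec, axis = c("planar", "ml", "ap")) {
  axis <- match.arg(axis)
  if (rec$n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  duration <- (rec$n_samples - 1L) / rec$sampling_rate
  dist <- switch(axis,
                 planar = path_length(rec),
                 ml = sum(abs(diff(rec$ml))),
                 ap = sum(abs(diff(rec$ap))))
  dist / duration
}

# Central-difference velocity (mm/s) on the interior samples of one axis.
cop_velocity <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for a velocity", call. = FALSE)
  (x[3:n] - x[1:(n - 2L)]) / 2 * sampling_rate
}

#' Zero crossings of the low-pass filtered CoP velocity
#'
#' The velocity is computed by central finite differences, low-pass filtered
#' with the same zero-phase Butterworth family used for preprocessing, and
#' strict sign changes are counted (exact zeros are dropped before counting).
#'
#' @param rec A [cop_recording()].
#' @param axis Axis, default `"ap"`.
#' @param config A [feature_config()].
#' @return Integer count of sign changes.
#' @export
zero_crossings_velocity <- function(rec, axis = "ap",
                                    config = feature_config()) {
  v <- cop_velocity(axis_series(rec, axis), rec$sampling_rate)
  nyq <- rec$sampling_rate / 2
  if (config$velocity_cutoff < nyq) {
    bf <- signal::butter(config$filter_order, config$velocity_cutoff / nyq,
                         type = "low")
    v <- zero_phase_filter(v, bf$b, bf$a, config$filter_order)
  }
  s <- sign(v)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Durations of supra-threshold CoP speed runs and their Gamma fit
#'
#' The instantaneous speed |v(t)| on one axis is thresholded at its record
#' mean; the durations (s) of maximal runs above threshold — the bursts
#' between mean-velocity crossings — are modelled as Gamma distributed.
#' `velocity_crossing_durations` returns the run durations;
#' `velocity_crossing_gamma` fits Gamma(shape alpha, scale beta) by maximum
#' likelihood; `fit_gamma_durations` is the fitting seam for precomputed
#' durations.
#'
#' @param rec A [cop_recording()].
#' @param axis `"ml"` or `"ap"`.
#' @return `velocity_crossing_durations`: numeric vector of durations in s.
#'   `velocity_crossing_gamma` / `fit_gamma_durations`: list with `alpha`
#'   (shape), `beta` (scale, s), and `n_durations`.
#' @export
velocity_crossing_durations <- function(rec, axis) {
  speed <- abs(cop_velocity(axis_series(rec, axis), rec$sampling_rate))
  runs <- rle(speed > mean(speed))
  durations <- runs$lengths[runs$values] / rec$sampling_rate
  if (length(durations) < 5L)
    stop("insufficient crossings: fewer than 5 supra-threshold runs",
         call. = FALSE)
  durations
}

#' @rdname velocity_crossing_durations
#' @param durations Positive run durations in seconds (>= 5 values).
#' @export
fit_gamma_durations <- function(durations) {
  if (length(durations) < 5L)
    stop("insufficient crossings: need at least 5 durations", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  m <- mean(durations)
  s <- log(m) - mean(log(durations))   # >= 0 by Jensen; 0 iff all equal
  if (s < 1e-12) {
    # degenerate: all durations (numerically) equal; shape diverges while
    # the mean alpha*beta stays at the common duration
    alpha <- 1e8
  } else {
    alpha <- mean(durations)^2 / max(var(durations), 1e-300)  # MoM start
    for (i in seq_len(200L)) {
      f <- log(alpha) - digamma(alpha) - s
      fp <- 1 / alpha - trigamma(alpha)
      step <- f / fp
      alpha_new <- alpha - step
      if (alpha_new <= 0) alpha_new <- alpha / 2
      if (abs(alpha_new - alpha) < 1e-12 * alpha) { alpha <- alpha_new; break }
      alpha <- alpha_new
      if (i == 200L) stop("Gamma MLE did not converge", call. = FALSE)
    }
  }
  list(alpha = alpha, beta = m / alpha, n_durations = length(durations))
}

#' @rdname velocity_crossing_durations
#' @export
velocity_crossing_gamma <- function(rec, axis) {
  fit_gamma_durations(velocity_crossing_durations(rec, axis))
}

# Centered moving average with partial windows at the edges.
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  csum <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

# Local maxima of `x` (plateau-aware: a run of equal values strictly above
# both flanking runs is one peak at its midpoint), thinned so retained peaks
# are at least `min_sep` indices apart (greedy, highest first).
find_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- 2:(k - 1L)
  is_peak <- r$values[interior] > r$values[interior - 1L] &
             r$values[interior] > r$values[interior + 1L]
  runs <- interior[is_peak]
  if (!length(runs)) return(integer(0))
  cand <- as.integer((starts[runs] + ends[runs]) %/% 2L)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

#' Sway-density curve and its peak statistics
#'
#' The sway-density curve measures, at each sample t, how long the CoP stays
#' within a disc of radius R centred on CoP(t): the number of consecutive
#' samples around t (both directions, t included) within R, divided by the
#' sampling rate. Peaks of the (smoothed) curve index postural stabilisation
#' episodes. `mean_peak` averages the peak values; `slope_mp` is the
#' least-squares slope of the mean peak value against R over `radii`.
#'
#' @param rec A [cop_recording()].
#' @param R Radius in mm (> 0).
#' @param config A [feature_config()].
#' @return `sway_density`: an object of class `sway_density_curve` with
#'   fields `radius`, `values` (raw, s), `smoothed`, `peak_indices`,
#'   `peak_values` and `sampling_rate`. `mean_peak`: seconds. `slope_mp`:
#'   s/mm.
#' @export
sway_density <- function(rec, R, config = feature_config()) {
  if (R <= 0) stop("R must be positive", call. = FALSE)
  counts <- sway_density_counts(rec$ml, rec$ap, R)
  values <- counts / rec$sampling_rate
  width <- max(1L, as.integer(round(config$sd_smooth_s * rec$sampling_rate)))
  smoothed <- moving_average(values, width)
  min_sep <- max(1L, as.integer(round(config$peak_min_sep_s * rec$sampling_rate)))
  if (diff(range(smoothed)) < 1e-12) {
    # saturated curve (whole record inside one disc of radius R): the record
    # is a single stabilisation episode whose peak value is the duration
    peaks <- as.integer(ceiling(length(smoothed) / 2))
  } else {
    peaks <- find_peaks(smoothed, min_sep)
  }
  structure(list(radius = R, values = values, smoothed = smoothed,
                 peak_indices = peaks, peak_values = smoothed[peaks],
                 sampling_rate = rec$sampling_rate),
            class = "sway_density_curve")
}

#' @rdname sway_density
#' @export
mean_peak <- function(rec, R, config = feature_config()) {
  curve <- sway_density(rec, R, config)
  if (!length(curve$peak_indices))
    stop(sprintf("no sway-density peaks found at R = %g mm", R), call. = FALSE)
  mean(curve$peak_values)
}

#' @rdname sway_density
#' @param radii Radii (mm) used in the regression (default 2:5).
#' @export
slope_mp <- function(rec, radii = 2:5, config = feature_config()) {
  mp <- vapply(radii, function(r) mean_peak(rec, r, config), numeric(1))
  unname(coef(lm.fit(cbind(1, radii), mp))[2L])
}

# One-sided Welch power spectral density estimate with Hann windows.
# Returns freq (Hz, including 0) and psd (mm^2/Hz); integral over (0, Nyquist]
# approximates the variance of the (mean-removed) input.
welch_psd <- function(x, fs, segment_s, overlap) {
  L <- as.integer(round(segment_s * fs))
  n <- length(x)
  if (n < L)
    stop(sprintf("record shorter than one Welch segment (%d < %d samples)",
                 n, L), call. = FALSE)
  x <- x - mean(x)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1L) / (L - 1L))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- abs(fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = seq(0, by = fs / L, length.out = nfreq), psd = psd * dbl,
       df = fs / L)
}

#' Spectral features of a CoP recording
#'
#' Welch power spectral densities (Hann segments, see [feature_config()]) of
#' the mean-removed ML and AP series. Total power integrates the PSD over
#' (0, Nyquist]; the planar total is the ML + AP sum; `pf95_ap` is the
#' smallest frequency below which 95% of the AP power lies.
#'
#' @param rec A [cop_recording()].
#' @param config A [feature_config()].
#' @return List with `power_total` (mm^2), `power_ml` (mm^2), `power_ap`
#'   (mm^2) and `pf95_ap` (Hz).
#' @export
spectral_features <- function(rec, config = feature_config()) {
  if (rec$n_samples < 256L)
    stop("need at least 256 samples for spectral features", call. = FALSE)
  pml <- welch_psd(rec$ml, rec$sampling_rate, config$welch_segment_s,
                   config$welch_overlap)
  pap <- welch_psd(rec$ap, rec$sampling_rate, config$welch_segment_s,
                   config$welch_overlap)
  power_ml <- sum(pml$psd[-1L]) * pml$df
  power_ap <- sum(pap$psd[-1L]) * pap$df
  cum_ap <- cumsum(pap$psd[-1L]) * pap$df
  pf95 <- pap$freq[-1L][which(cum_ap >= 0.95 * power_ap)[1L]]
  list(power_total = power_ml + power_ap, power_ml = power_ml,
       power_ap = power_ap, pf95_ap = pf95)
}

log_guarded <- function(x, feature) {
  if (!is.finite(x) || x <= 0)
    stop(sprintf("degenerate recording: %s requires a positive argument (got %g)",
                 feature, x), call. = FALSE)
  log(x)
}

#' Extract the 16 individual-specific postural features
#'
#' Computes the full postural feature vector from a preprocessed (low-pass
#' filtered) recording: sway-density mean peak at R = 3 mm, mean positions,
#' velocity zero crossings, Gamma crossing-duration shape/scale per axis,
#' the sway-density mean-peak slope over R = 2..5 mm, path length, mean
#' velocities, spectral powers and the 95% power frequency. Features named
#' `log-*` store natural logs; a non-positive argument to any log (e.g. zero
#' path length) raises a "degenerate recording" error.
#'
#' @param rec A [cop_recording()], already filtered (see [lowpass_filter()]).
#' @param config A [feature_config()].
#' @return Named numeric vector of length 16 (names
#'   [postural_feature_names()]).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4, conditions = "EC", duration = 30, seed = 1)
#' rec <- lowpass_filter(simulate_cop_trace(cfg, 1, "EC"))
#' extract_features(rec)
extract_features <- function(rec, config = feature_config()) {
  grab <- function(feature, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature %s: %s", feature, conditionMessage(e)),
           call. = FALSE))
  }
  gamma_ml <- grab("Beta-ML/log-Alpha-ML", velocity_crossing_gamma(rec, "ml"))
  gamma_ap <- grab("Beta-AP/log-Alpha-AP", velocity_crossing_gamma(rec, "ap"))
  spec <- grab("log-Power/log-Power-ML/PF95AP", spectral_features(rec, config))
  lng <- grab("log-LNG", path_length(rec))
  out <- c(
    grab("MP3", mean_peak(rec, config$sd_radius, config)),
    grab("Mean-AP", mean_position(rec, "ap")),
    grab("Mean-ML", mean_position(rec, "ml")),
    grab("Zero-cross-V-AP", zero_crossings_velocity(rec, "ap", config)),
    gamma_ml$beta,
    log_guarded(gamma_ml$alpha, "log-Alpha-ML"),
    log_guarded(gamma_ap$alpha, "log-Alpha-AP"),
    gamma_ap$beta,
    log_guarded(abs(grab("log-slope-MP", slope_mp(rec, config$slope_radii, config))),
                "log-slope-MP"),
    log_guarded(lng, "log-LNG"),
    log_guarded(grab("log-MV", mean_velocity(rec, "planar")), "log-MV"),
    log_guarded(grab("log-MV-ML", mean_velocity(rec, "ml")), "log-MV-ML"),
    log_guarded(grab("log-MV-AP", mean_velocity(rec, "ap")), "log-MV-AP"),
    log_guarded(spec$power_total, "log-Power"),
    log_guarded(spec$power_ml, "log-Power-ML"),
    spec$pf95_ap
  )
  names(out) <- TABLE1_NAMES
  out
}

#' Feature table for a set of recordings
#'
#' Applies [extract_features()] to each recording and assembles one row per
#' subject-by-condition with the 16 feature columns.
#'
#' @param recordings List of [cop_recording()]s.
#' @param config A [feature_config()].
#' @return Data frame with columns `subject_id`, `condition` and the 16
#'   features (names preserved verbatim).
#' @export
extract_feature_table <- function(recordings, config = feature_config()) {
  rows <- lapply(recordings, function(r) {
    fv <- extract_features(r, config)
    df <- data.frame(subject_id = r$subject_id, condition = r$condition,
                     stringsAsFactors = FALSE)
    for (nm in names(fv)) df[[nm]] <- fv[[nm]]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write feature tables as CSV
#'
#' One row per subject-by-condition, columns `subject_id`, `condition` and
#' the 16 feature names verbatim. Values are written with enough digits that
#' a round-trip is exact to better than 1e-12.
#'
#' @param table A feature table (see [extract_feature_table()]).
#' @param path File path.
#' @return `read_feature_csv`: the feature table. `write_feature_csv`:
#'   `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  out <- table
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = 17,
                                                    format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "condition") %in% names(df)))
    stop("feature CSV must have subject_id and condition columns",
         call. = FALSE)
  if (anyNA(df)) stop("feature CSV contains missing values", call. = FALSE)
  df
}
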