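#' Configuration of a synthetic quiet-standing cohort
#'
#' Defines the generative conditions for a synthetic study: cohort size, the
#' standing conditions recorded (eyes closed EC, eyes open EO), the sampling
#' regime, the per-axis sway process, and a trait-like response planted on
#' cross-terms of postural features.
#'
#' Each axis of each subject follows a damped second-order stochastic system
#' (a noise-driven damped oscillator, discretised by Euler–Maruyama with a
#' 1 s burn-in), which concentrates sway power below 2 Hz as real CoP traces
#' do. Oscillator natural frequency, damping ratio, noise intensity and the
#' per-axis offset are per-subject random effects so that between-subject
#' feature variance exists. The response is
#' `intercept + sum_j effect_j * z(t1_j) z(t2_j) + eps` where `z(.)` are
#' cohort-z-scored planted features computed from the (filtered) EC
#' recordings and `eps ~ N(0, noise_sd^2)`; the `"integer"` link rounds and
#' clips to the questionnaire range 14..56, the `"latent"` link returns the
#' continuous value (tie-free, for median-split tests).
#'
#' @param n_subjects Number of subjects (>= 4). Default 156.
#' @param conditions Subset of `c("EC", "EO")`.
#' @param sampling_rate Hz, default 40.
#' @param duration Seconds, default 52.
#' @param sway_params List of per-subject random-effect hyperparameters, each
#'   `c(mean, sd)`: `freq` (oscillator natural frequency, Hz), `damping`
#'   (damping ratio), `noise` (noise intensity, mm s^-3/2), `offset_ml` /
#'   `offset_ap` (static offsets, mm); plus `condition_gain`, a named
#'   multiplier of the noise intensity per condition (eyes closed sways more).
#' @param planted_terms List of feature-name pairs (see
#'   [postural_feature_names()]) whose products carry the planted effect.
#' @param effect_sizes Numeric, one per planted term.
#' @param noise_sd Response noise standard deviation (score units).
#' @param intercept Response centre (score units), default 41.
#' @param response_link `"integer"` or `"latent"`.
#' @param seed Integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 156,
                          conditions = c("EC", "EO"),
                          sampling_rate = 40,
                          duration = 52,
                          sway_params = list(),
                          planted_terms = list(c("Mean-ML", "log-Alpha-AP"),
                                               c("Mean-ML", "PF95AP")),
                          effect_sizes = c(4, 3),
                          noise_sd = 4,
                          intercept = 41,
                          response_link = c("integer", "latent"),
                          seed = 1L) {
  response_link <- match.arg(response_link)
  if (n_subjects < 4L) stop("n_subjects must be >= 4", call. = FALSE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", lower = 1e-9)
  stopifnot_scalar_number(duration, "duration", lower = 1e-9)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  conditions <- match.arg(conditions, c("EC", "EO"), several.ok = TRUE)
  defaults <- list(freq = c(0.4, 0.08), damping = c(0.7, 0.1),
                   noise = c(15, 3), offset_ml = c(0, 3), offset_ap = c(0, 3),
                   condition_gain = c(EC = 1.3, EO = 1.0))
  sway_params <- utils::modifyList(defaults, sway_params)
  if (length(planted_terms) != length(effect_sizes))
    stop("one effect size per planted term is required", call. = FALSE)
  for (term in planted_terms) {
    if (length(term) != 2L || !all(term %in% TABLE1_NAMES))
      stop("planted terms must be pairs of Table-1 feature names; unknown: ",
           paste(setdiff(term, TABLE1_NAMES), collapse = ", "), call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 sampling_rate = sampling_rate, duration = duration,
                 sway_params = sway_params, planted_terms = planted_terms,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 intercept = intercept, response_link = response_link,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-subject random effects, a pure function of (config, subject_index).
subject_sway_params <- function(config, subject_index) {
  sp <- config$sway_params
  with_seed(derive_seed(config$seed, 100000L + subject_index), {
    # truncated draws: no near-static, near-undamped or ultra-stiff subjects
    draw <- function(h, lower, upper = Inf)
      min(max(rnorm(1, h[1L], h[2L]), lower), upper)
    list(freq = draw(sp$freq, 0.15, 0.8),
         damping = draw(sp$damping, 0.3, 1.2),
         noise = draw(sp$noise, sp$noise[1L] / 3),
         offset_ml = rnorm(1, sp$offset_ml[1L], sp$offset_ml[2L]),
         offset_ap = rnorm(1, sp$offset_ap[1L], sp$offset_ap[2L]))
  })
}

# Euler-Maruyama discretisation of x'' = -2 zeta w x' - w^2 (x - offset) + s xi,
# started at the fixed point, with `burn` seconds discarded.
simulate_oscillator <- function(n, dt, freq, damping, noise, offset,
                                burn_steps) {
  omega <- 2 * pi * freq
  total <- n + burn_steps
  x <- numeric(total)
  xv <- 0
  xx <- offset
  shocks <- if (noise > 0) rnorm(total, 0, noise * sqrt(dt)) else numeric(total)
  for (i in seq_len(total)) {
    xv <- xv + dt * (-2 * damping * omega * xv - omega^2 * (xx - offset)) +
      shocks[i]
    xx <- xx + dt * xv
    x[i] <- xx
  }
  x[(burn_steps + 1L):total]
}

#' Simulate one CoP trace
#'
#' Generates the ML and AP series of one subject in one condition from the
#' cohort's sway process. A pure function of `(config, subject_index,
#' condition)`: the same triple always returns the identical recording.
#'
#' @param config A [cohort_config()].
#' @param subject_index Subject number in `1..n_subjects`.
#' @param condition `"EC"` or `"EO"`.
#' @return A [cop_recording()] (unfiltered).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4, duration = 10, seed = 7)
#' simulate_cop_trace(cfg, 1, "EC")
simulate_cop_trace <- function(config, subject_index, condition) {
  stopifnot(inherits(config, "cohort_config"))
  if (!condition %in% c("EC", "EO"))
    stop("invalid condition '", condition, "': allowed labels are EC, EO",
         call. = FALSE)
  if (subject_index < 1L || subject_index > config$n_subjects)
    stop("subject_index out of range", call. = FALSE)
  pars <- subject_sway_params(config, subject_index)
  gain <- config$sway_params$condition_gain[[condition]] %||% 1
  n <- as.integer(round(config$duration * config$sampling_rate))
  dt <- 1 / config$sampling_rate
  burn <- as.integer(config$sampling_rate)  # 1 s burn-in
  cond_idx <- match(condition, c("EC", "EO"))
  with_seed(derive_seed(config$seed, 2L * subject_index + 1000003L * cond_idx), {
    ml <- simulate_oscillator(n, dt, pars$freq, pars$damping,
                              pars$noise * gain, pars$offset_ml, burn)
    ap <- simulate_oscillator(n, dt, pars$freq, pars$damping,
                              pars$noise * gain, pars$offset_ap, burn)
    cop_recording(sprintf("S%03d", subject_index), condition,
                  config$sampling_rate, ml, ap)
  })
}

#' Plant a trait-like response on feature cross-terms
#'
#' Given a feature table, z-scores the planted features over the cohort,
#' forms the planted cross-terms and returns
#' `intercept + sum_j effect_j z(t1_j) z(t2_j) + eps`, mapped through the
#' response link. Exposed separately so selection and modelling tests can use
#' fast Gaussian feature tables (see [simulate_feature_table()]) without
#' simulating signals.
#'
#' @param features Data frame or matrix whose columns include every planted
#'   feature name.
#' @param planted_terms,effect_sizes,noise_sd,intercept,response_link,seed
#'   As in [cohort_config()].
#' @return List with `score` (numeric), `latent` (pre-link value) and
#'   `cross_terms` (matrix of the realized planted products).
#' @export
plant_response <- function(features, planted_terms, effect_sizes,
                           noise_sd = 0, intercept = 41,
                           response_link = c("integer", "latent"),
                           seed = 1L) {
  response_link <- match.arg(response_link)
  features <- as.data.frame(features, check.names = FALSE)
  n <- nrow(features)
  cross <- matrix(0, n, length(planted_terms))
  colnames(cross) <- vapply(planted_terms, paste, "", collapse = " \u00d7 ")
  for (j in seq_along(planted_terms)) {
    term <- planted_terms[[j]]
    if (!all(term %in% names(features)))
      stop("planted feature unresolvable: ",
           paste(setdiff(term, names(features)), collapse = ", "),
           call. = FALSE)
    z1 <- as.numeric(scale(features[[term[1L]]]))
    z2 <- as.numeric(scale(features[[term[2L]]]))
    cross[, j] <- z1 * z2
  }
  signal_part <- if (length(planted_terms))
    as.numeric(cross %*% effect_sizes) else numeric(n)
  eps <- if (noise_sd > 0)
    with_seed(derive_seed(seed, 424243L), rnorm(n, 0, noise_sd))
  else numeric(n)
  latent <- intercept + signal_part + eps
  score <- switch(response_link,
                  integer = pmin(pmax(round(latent), 14), 56),
                  latent = latent)
  list(score = score, latent = latent, cross_terms = cross)
}

#' Simulate a full synthetic cohort
#'
#' Generates one recording per subject per condition and a trait-like
#' response planted on cross-terms of postural features computed from the
#' eyes-closed recordings (first configured condition if EC is absent),
#' preprocessed with the standard 10 Hz zero-phase filter.
#'
#' @param config A [cohort_config()].
#' @return List with `recordings` (named list of [cop_recording()]s),
#'   `scores` (data frame `subject_id`, `score`, `latent`), `features` (the
#'   realized feature table of the response condition) and `cross_terms`
#'   (realized planted products, for test introspection).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recordings <- list()
  for (cond in config$conditions)
    for (i in seq_len(config$n_subjects)) {
      rec <- simulate_cop_trace(config, i, cond)
      recordings[[paste(rec$subject_id, cond, sep = ".")]] <- rec
    }
  response_cond <- if ("EC" %in% config$conditions) "EC"
                   else config$conditions[1L]
  resp_recs <- recordings[grepl(paste0("\\.", response_cond, "$"),
                                names(recordings))]
  filtered <- lapply(resp_recs, lowpass_filter)
  features <- extract_feature_table(filtered)
  planted <- plant_response(features, config$planted_terms,
                            config$effect_sizes, config$noise_sd,
                            config$intercept, config$response_link,
                            seed = config$seed)
  scores <- data.frame(subject_id = features$subject_id,
                       score = planted$score, latent = planted$latent,
                       stringsAsFactors = FALSE)
  list(recordings = recordings, scores = scores, features = features,
       cross_terms = planted$cross_terms)
}

#' Simulate a Gaussian postural feature table
#'
#' Fast path for selection and modelling tests: draws rows from a zero-mean
#' multivariate Gaussian with the given correlation, named like the 16
#' postural features when `n_features = 16`.
#'
#' @param n Number of rows (>= 1).
#' @param n_features Number of columns (default 16).
#' @param correlation Correlation matrix (symmetric positive semi-definite);
#'   identity by default.
#' @param seed Integer seed.
#' @return Data frame of simulated features.
#' @export
simulate_feature_table <- function(n, n_features = 16,
                                   correlation = NULL, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(correlation)) correlation <- diag(n_features)
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != n_features || ncol(correlation) != n_features)
    stop("correlation must be n_features x n_features", call. = FALSE)
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  x <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, n_features),
                                     Sigma = correlation))
  x <- matrix(x, nrow = n)  # mvrnorm drops dims at n = 1
  nms <- if (n_features == 16L) TABLE1_NAMES
         else sprintf("F%02d", seq_len(n_features))
  colnames(x) <- nms
  as.data.frame(x, check.names = FALSE)
}
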