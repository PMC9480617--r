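# Shared fixtures, built in code at test time.

# A recording with prescribed axis series (defaults: smooth pseudo-sway).
toy_recording <- function(ml, ap = NULL, fs = 40, subject = "t1",
                          condition = "EC") {
  if (is.null(ap)) ap <- rev(ml)
  cop_recording(subject, condition, fs, ml, ap)
}

# A small filtered sway recording from the generator (deterministic).
sim_recording <- function(seed = 11, duration = 30, subject_index = 1,
                          filtered = TRUE) {
  cfg <- cohort_config(n_subjects = 4, conditions = "EC",
                       duration = duration, seed = seed)
  rec <- simulate_cop_trace(cfg, subject_index, "EC")
  if (filtered) lowpass_filter(rec) else rec
}

# Brute-force O(n^2) sway-density counts: for each t, consecutive samples
# around t (both directions, t included) within radius R.
sway_density_oracle <- function(ml, ap, R) {
  n <- length(ml)
  out <- integer(n)
  for (t in seq_len(n)) {
    count <- 1L
    k <- t - 1L
    while (k >= 1L && (ml[k] - ml[t])^2 + (ap[k] - ap[t])^2 <= R^2) {
      count <- count + 1L; k <- k - 1L
    }
    k <- t + 1L
    while (k <= n && (ml[k] - ml[t])^2 + (ap[k] - ap[t])^2 <= R^2) {
      count <- count + 1L; k <- k + 1L
    }
    out[t] <- count
  }
  out
}

# Pairwise-concordance AUC oracle, O(n^2), ties counted half.
auc_oracle <- function(y, scores) {
  pos <- which(y == 1); neg <- which(y == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# Explicit greedy projection oracle for OFR on centered vectors.
ofr_oracle <- function(X, y) {
  X <- sweep(as.matrix(X), 2, colMeans(X))
  y <- y - mean(y)
  remaining <- seq_len(ncol(X))
  order_out <- integer(0); cos2_out <- numeric(0)
  while (length(remaining)) {
    ck <- vapply(remaining, function(j)
      sum(X[, j] * y)^2 / (sum(X[, j]^2) * sum(y^2)), numeric(1))
    pick <- remaining[which.max(ck)]
    order_out <- c(order_out, pick)
    cos2_out <- c(cos2_out, max(ck))
    v <- X[, pick] / sqrt(sum(X[, pick]^2))
    for (j in setdiff(remaining, pick))
      X[, j] <- X[, j] - v * sum(v * X[, j])
    y <- y - v * sum(v * y)
    remaining <- setdiff(remaining, pick)
  }
  list(order = order_out, cos2 = cos2_out)
}
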