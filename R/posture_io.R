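#' Construct a center-of-pressure recording
#'
#' A `cop_recording` holds one subject-by-condition CoP trace: the
#' medio-lateral (ML, rightward positive) and antero-posterior (AP, forward
#' positive) position series in millimetres, with the sampling rate in Hz.
#' The coordinate origin is the platform centre.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param condition Condition label, `"EC"` (eyes closed) or `"EO"` (eyes
#'   open).
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param ml,ap Numeric series of equal length (>= 2), in mm, no missing
#'   values.
#' @return An object of class `cop_recording`.
#' @export
#' @examples
#' rec <- cop_recording("s1", "EC", 40, sin(1:100 / 10), cos(1:100 / 10))
#' rec
cop_recording <- function(subject_id, condition, sampling_rate, ml, ap) {
  condition <- match.arg(condition, c("EC", "EO"))
  stopifnot_scalar_number(sampling_rate, "sampling_rate", lower = 1e-12)
  ml <- as.numeric(ml)
  ap <- as.numeric(ap)
  if (length(ml) != length(ap))
    stop("`ml` and `ap` must have equal length", call. = FALSE)
  if (length(ml) < 2L)
    stop("a recording needs at least 2 samples", call. = FALSE)
  if (anyNA(ml) || anyNA(ap) || !all(is.finite(ml)) || !all(is.finite(ap)))
    stop("CoP series must be finite with no missing values", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         sampling_rate = sampling_rate, ml = ml, ap = ap,
         n_samples = length(ml)),
    class = "cop_recording"
  )
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf(
    "CoP recording: subject %s, %s, %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$condition, x$n_samples, x$sampling_rate,
    x$n_samples / x$sampling_rate))
  cat(sprintf("  ML: mean %.2f mm, sd %.2f mm;  AP: mean %.2f mm, sd %.2f mm\n",
              mean(x$ml), sd(x$ml), mean(x$ap), sd(x$ap)))
  invisible(x)
}

#' Compute the CoP trajectory from four-sensor platform frames
#'
#' Force platforms of the kind modelled here measure the position of the
#' vertical ground-reaction vector under the heel and metatarsal of each foot
#' (sensors LH, LM, RH, RM). The whole-body CoP at each time step is the
#' barycenter of the four sensor positions; with `average = "weighted"` the
#' positions are weighted by the vertical load on each sensor (a true pressure
#' centroid), with `average = "plain"` they are averaged unweighted. At equal
#' loads the two coincide.
#'
#' @param frames Data frame with columns `subject_id`, `condition`,
#'   `sample_index`, `sensor` (one of LH, LM, RH, RM), `pos_x_mm`, `pos_y_mm`,
#'   `load_n` (newtons, >= 0). Exactly 4 sensors per `sample_index`.
#' @param sampling_rate Sampling rate in Hz of the frame sequence.
#' @param average `"weighted"` (default) or `"plain"`.
#' @return A [cop_recording()] with `ml` = x barycenter, `ap` = y barycenter.
#' @export
cop_from_frames <- function(frames, sampling_rate = 40,
                            average = c("weighted", "plain")) {
  average <- match.arg(average)
  needed <- c("subject_id", "condition", "sample_index", "sensor",
              "pos_x_mm", "pos_y_mm", "load_n")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols))
    stop("platform frames missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(unique(frames$subject_id)) != 1L ||
      length(unique(frames$condition)) != 1L)
    stop("`cop_from_frames` expects frames of a single subject and condition",
         call. = FALSE)
  if (!all(frames$sensor %in% c("LH", "LM", "RH", "RM")))
    stop("sensor labels must be LH, LM, RH or RM", call. = FALSE)
  idx <- sort(unique(frames$sample_index))
  ml <- ap <- numeric(length(idx))
  for (i in seq_along(idx)) {
    fr <- frames[frames$sample_index == idx[i], ]
    if (nrow(fr) != 4L)
      stop(sprintf("frame %s does not have exactly 4 sensors", idx[i]),
           call. = FALSE)
    if (any(fr$load_n < 0))
      stop(sprintf("negative load in frame %s", idx[i]), call. = FALSE)
    total <- sum(fr$load_n)
    if (average == "weighted") {
      if (total <= 0)
        stop(sprintf("zero total load in frame %s", idx[i]), call. = FALSE)
      w <- fr$load_n / total
    } else {
      w <- rep(0.25, 4L)
    }
    ml[i] <- sum(w * fr$pos_x_mm)
    ap[i] <- sum(w * fr$pos_y_mm)
  }
  cop_recording(frames$subject_id[1L], frames$condition[1L],
                sampling_rate, ml, ap)
}

# Zero-phase IIR pass on one series: even-reflection padding of 3*order
# samples at both ends, forward filter, reverse, filter, reverse, strip pads.
zero_phase_filter <- function(x, b, a, order) {
  pad <- 3L * order
  n <- length(x)
  if (n <= pad + 1L)
    stop(sprintf("record too short to pad (%d samples, need > %d)", n, pad + 1L),
         call. = FALSE)
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  k <- max(length(a), length(b)) - 1L
  # steady-state initial conditions (constant past equal to the edge value)
  # suppress the zero-state transient at both ends of each pass
  run <- function(z) as.numeric(signal::filter(b, a, z,
                                               init.x = rep(z[1L], k),
                                               init.y = rep(z[1L], k)))
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase Butterworth low-pass filtering of a CoP recording
#'
#' Applies a digital Butterworth low-pass filter (bilinear-transform design)
#' forward and backward over each axis, yielding zero phase lag; the effective
#' amplitude response is the squared single-pass response (so the nominal
#' cutoff sits at -6 dB of the two-pass response). Each pass uses
#' even-reflection padding of `3 * order` samples at both ends.
#'
#' @param rec A [cop_recording()].
#' @param cutoff Cutoff frequency in Hz (default 10); must be below Nyquist.
#' @param order Filter order (default 4).
#' @return A filtered [cop_recording()] of identical length.
#' @export
lowpass_filter <- function(rec, cutoff = 10, order = 4) {
  stopifnot(inherits(rec, "cop_recording"))
  nyq <- rec$sampling_rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyq), call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  rec$ml <- zero_phase_filter(rec$ml, bf$b, bf$a, order)
  rec$ap <- zero_phase_filter(rec$ap, bf$b, bf$a, order)
  rec
}

#' Read and write CoP recordings as delimited text
#'
#' The CoP CSV dialect has the header
#' `subject_id,condition,sample_index,ml_mm,ap_mm` (comma separated, UTF-8,
#' `.` decimal); one file may hold several subjects and conditions. Sample
#' indices must be consecutive within each subject-by-condition block. The
#' sampling rate travels either as the `sampling_rate` argument or in a
#' sidecar YAML file `<path>.yaml` with key `sampling_rate`.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz; if `NULL`, read from the sidecar
#'   YAML.
#' @return `read_cop_csv`: a named list of [cop_recording()]s (names
#'   `subject.condition`). `write_cop_csv`: `path`, invisibly.
#' @export
read_cop_csv <- function(path, sampling_rate = NULL) {
  if (is.null(sampling_rate)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("no `sampling_rate` given and no sidecar YAML found at ", sidecar,
           call. = FALSE)
    sampling_rate <- yaml::read_yaml(sidecar)$sampling_rate
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "condition", "sample_index", "ml_mm", "ap_mm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("CoP CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("sample_index", "ml_mm", "ap_mm")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("non-numeric value in column %s near line %d", col,
                   bad + 1L), call. = FALSE)
    }
  }
  if (anyNA(df))
    stop(sprintf("missing value near line %d", which(!stats::complete.cases(df))[1L] + 1L),
         call. = FALSE)
  key <- paste(df$subject_id, df$condition, sep = ".")
  out <- list()
  offset <- 0L
  for (k in unique(key)) {
    block <- df[key == k, ]
    si <- block$sample_index
    if (any(diff(si) != 1L)) {
      gap <- which(diff(si) != 1L)[1L]
      stop(sprintf("gap in sample index for %s near line %d", k,
                   which(key == k)[gap] + 2L), call. = FALSE)
    }
    out[[k]] <- cop_recording(block$subject_id[1L], block$condition[1L],
                              sampling_rate, block$ml_mm, block$ap_mm)
    offset <- offset + nrow(block)
  }
  out
}

#' @rdname read_cop_csv
#' @param recordings A [cop_recording()] or list of them.
#' @param digits Significant digits written (default 12; round-trip is exact
#'   to well below 1e-9 mm).
#' @export
write_cop_csv <- function(recordings, path, digits = 12) {
  if (inherits(recordings, "cop_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(r) {
    data.frame(subject_id = r$subject_id, condition = r$condition,
               sample_index = seq_len(r$n_samples),
               ml_mm = signif(r$ml, digits), ap_mm = signif(r$ap, digits),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cop_from_frames
#' @param path Path to a platform-frame CSV with header
#'   `subject_id,condition,sample_index,sensor,pos_x_mm,pos_y_mm,load_n`.
#' @export
read_platform_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "condition", "sample_index", "sensor",
              "pos_x_mm", "pos_y_mm", "load_n")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("platform CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}
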