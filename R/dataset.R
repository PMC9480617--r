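cross_name <- function(a, b) paste0(a, " \u00d7 ", b)

#' Z-score normalisation with recorded provenance
#'
#' Centers and scales each numeric column to zero mean and unit standard
#' deviation (denominator n - 1) over the reference rows, and records the
#' (mean, sd) pairs so the identical transform can be applied to held-out
#' rows. With `reference_rows = NULL` the whole sample is the reference
#' (the convention used for reproducing the original analysis); passing the
#' training rows instead avoids test-set leakage in new studies.
#'
#' @param table Data frame or matrix of numeric feature columns.
#' @param reference_rows Integer or logical row index of the reference
#'   subjects, or `NULL` for all rows.
#' @return List with `values` (normalized matrix), `center`, `scale` (named
#'   vectors) and `provenance` (`"whole-sample"` or `"training-only"`).
#' @export
zscore <- function(table, reference_rows = NULL) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("all columns must be numeric", call. = FALSE)
  ref <- if (is.null(reference_rows)) seq_len(nrow(x)) else reference_rows
  center <- colMeans(x[ref, , drop = FALSE])
  scale <- apply(x[ref, , drop = FALSE], 2L, sd)
  zero <- which(!is.finite(scale) | scale <= 0)
  if (length(zero))
    stop("zero standard deviation in feature(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  list(values = sweep(sweep(x, 2L, center), 2L, scale, "/"),
       center = center, scale = scale,
       provenance = if (is.null(reference_rows)) "whole-sample"
                    else "training-only")
}

#' @rdname zscore
#' @param center,scale Stored normalisation vectors from a previous call.
#' @export
apply_zscore <- function(table, center, scale) {
  x <- as.matrix(table)
  sweep(sweep(x[, names(center), drop = FALSE], 2L, center), 2L, scale, "/")
}

#' Build the candidate matrix of primaries and cross-terms
#'
#' Appends to the z-scored primary features all their unordered pairwise
#' products (`p (p - 1) / 2` cross-terms, no squares), computed on the
#' normalized primaries and then re-z-scored so all candidates share one
#' scale for cosine-based ranking. With the 16 postural features this yields
#' 120 cross-terms and 136 candidates. Cross-term names are
#' "A \u00d7 B" with A before B in primary column order; columns are ordered
#' primaries first, then pairs in lexicographic index order.
#'
#' @param primaries Z-scored primary feature matrix or data frame (>= 2
#'   columns, unique names).
#' @param reference_rows Reference rows for the cross-term re-normalisation
#'   (`NULL` = all rows).
#' @return An object of class `candidate_matrix`: list with `values` (N x P
#'   matrix), `names`, `n_primaries`, `normalization` (center/scale of the
#'   product columns) and `provenance`.
#' @export
#' @examples
#' z <- zscore(simulate_feature_table(20, seed = 1))
#' cm <- make_cross_terms(z$values)
#' ncol(cm$values)  # 136
make_cross_terms <- function(primaries, reference_rows = NULL) {
  x <- as.matrix(primaries)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 primary columns", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate primary names", call. = FALSE)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  prods <- x[, pairs[, 1L], drop = FALSE] * x[, pairs[, 2L], drop = FALSE]
  colnames(prods) <- cross_name(colnames(x)[pairs[, 1L]],
                                colnames(x)[pairs[, 2L]])
  zs <- zscore(prods, reference_rows)
  values <- cbind(x, zs$values)
  structure(list(values = values, names = colnames(values),
                 n_primaries = p,
                 normalization = list(center = zs$center, scale = zs$scale),
                 provenance = zs$provenance,
                 raw_products = prods),
            class = "candidate_matrix")
}

#' @export
print.candidate_matrix <- function(x, ...) {
  cat(sprintf("Candidate matrix: %d rows, %d primaries + %d cross-terms = %d candidates (%s normalisation)\n",
              nrow(x$values), x$n_primaries, ncol(x$values) - x$n_primaries,
              ncol(x$values), x$provenance))
  invisible(x)
}

#' Median split of trait scores into a binary status
#'
#' A subject is labelled 1 ("mindful" in the trait-mindfulness application)
#' if the score is strictly greater than the sample median, 0 otherwise;
#' ties at the median fall in class 0. With tie-free scores and even n the
#' two classes are exactly balanced.
#'
#' @param scores Numeric vector (length >= 2).
#' @return List with `status` (integer 0/1) and `median`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores", call. = FALSE)
  med <- median(scores)
  list(status = as.integer(scores > med), median = med)
}

#' Split subjects into training/validation and test sets
#'
#' Draws a seeded split with `round(fraction * N)` subjects in the
#' training/validation set, optionally stratified on a binary status so class
#' proportions carry over (per-stratum sizes by largest-remainder rounding).
#'
#' @param n Number of subjects, or a status vector when stratifying.
#' @param fraction Training/validation fraction in (0, 1); default 0.70.
#' @param stratify Binary status vector of length `n`, or `NULL`.
#' @param seed Integer seed.
#' @return Character vector of `"trainval"` / `"test"`, length `n`.
#' @export
#' @examples
#' table(split_trainval_test(156, seed = 1))  # 109 trainval, 47 test
split_trainval_test <- function(n, fraction = 0.70, stratify = NULL,
                                seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  target <- as.integer(round(fraction * n))
  out <- rep("test", n)
  if (is.null(stratify)) {
    idx <- with_seed(seed, sample.int(n, target))
    out[idx] <- "trainval"
    return(out)
  }
  if (length(stratify) != n)
    stop("stratify must have length n", call. = FALSE)
  strata <- split(seq_len(n), stratify)
  sizes <- vapply(strata, length, integer(1))
  if (any(sizes < 2L)) stop("every stratum needs at least 2 subjects",
                            call. = FALSE)
  raw <- fraction * sizes
  take <- floor(raw)
  short <- target - sum(take)
  if (short > 0) {
    order_frac <- order(raw - take, decreasing = TRUE)
    take[order_frac[seq_len(short)]] <- take[order_frac[seq_len(short)]] + 1L
  } else if (short < 0) {
    order_frac <- order(raw - take)
    take[order_frac[seq_len(-short)]] <- take[order_frac[seq_len(-short)]] - 1L
  }
  with_seed(seed, {
    for (s in seq_along(strata))
      out[sample(strata[[s]], take[s])] <- "trainval"
  })
  out
}

#' Total score of a 14-item trait-mindfulness questionnaire
#'
#' Items are rated 1 (rarely) to 4 (almost always); item 13 is reverse scored
#' (5 minus the rating); the total is the sum over the 14 items, an integer
#' between 14 and 56.
#'
#' @param items Matrix or data frame, one row per respondent, 14 columns of
#'   integer ratings in 1..4.
#' @return Integer vector of total scores.
#' @export
fmi_total <- function(items) {
  x <- as.matrix(items)
  if (ncol(x) != 14L) stop("expected 14 items", call. = FALSE)
  if (any(x < 1 | x > 4 | x != round(x)))
    stop("item ratings must be integers in 1..4", call. = FALSE)
  x[, 13L] <- 5 - x[, 13L]
  as.integer(rowSums(x))
}

#' Assemble a labelled modelling cohort
#'
#' Convenience constructor combining normalisation, cross-term construction,
#' the median-split status and the train/test split into one object used by
#' the pipeline.
#'
#' @param features Primary feature table (numeric columns only).
#' @param scores Numeric trait scores, one per row of `features`.
#' @param fraction Training/validation fraction.
#' @param stratify Stratify the split on the median-split status?
#' @param split_seed Seed for the split.
#' @param provenance `"whole-sample"` (default) or `"training-only"`
#'   normalisation reference.
#' @return An object of class `labeled_cohort`: candidate matrix, scores,
#'   `status`, `median_used`, and the `split` assignment.
#' @export
labeled_cohort <- function(features, scores, fraction = 0.70,
                           stratify = TRUE, split_seed = 1L,
                           provenance = c("whole-sample", "training-only")) {
  provenance <- match.arg(provenance)
  if (nrow(features) != length(scores))
    stop("one score per feature row is required", call. = FALSE)
  ms <- median_split(scores)
  split <- split_trainval_test(length(scores), fraction,
                               stratify = if (stratify) ms$status else NULL,
                               seed = split_seed)
  ref <- if (provenance == "training-only") which(split == "trainval")
         else NULL
  z <- zscore(features, ref)
  cm <- make_cross_terms(z$values, ref)
  structure(list(candidates = cm, scores = scores, status = ms$status,
                 median_used = ms$median, split = split,
                 primary_normalization = list(center = z$center,
                                              scale = z$scale),
                 provenance = z$provenance),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("Labelled cohort: %d subjects (%d trainval / %d test), median score %g, %d candidates\n",
              length(x$scores), sum(x$split == "trainval"),
              sum(x$split == "test"), x$median_used,
              ncol(x$candidates$values)))
  invisible(x)
}
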