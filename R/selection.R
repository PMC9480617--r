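#' Rank candidate variables by Orthogonal Forward Regression
#'
#' Works in observation space: each candidate column and the response are
#' N-vectors. At every step the candidate with the largest squared cosine to
#' the current (residual) response is selected; the remaining candidates and
#' the response are then orthogonalised against it (modified Gram–Schmidt)
#' and the step repeats until all candidates are ranked or the residual
#' response norm falls below `tol` times its initial norm. With
#' `center = TRUE` (default) vectors are centered first, so the squared
#' cosine equals the squared Pearson correlation; ties break towards the
#' lowest column index.
#'
#' @param candidates Numeric matrix (or data frame), one named column per
#'   candidate variable.
#' @param response Numeric response vector (not constant).
#' @param center Center the vectors before the cosine computation?
#' @param tol Relative residual-norm tolerance for early stopping.
#' @return Data frame with columns `name`, `rank` and `cos2` (squared cosine
#'   at selection; `NA` for variables left unrankable after the response was
#'   exhausted or whose residual norm vanished).
#' @export
#' @examples
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' y <- X[, 2] + rnorm(50, 0, 0.1)
#' ofr_rank(X, y)$name[1]
ofr_rank <- function(candidates, response, center = TRUE, tol = 1e-10) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- as.numeric(response)
  if (nrow(X) != length(y)) stop("dimension mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (center) {
    if (sd(y) == 0) stop("response is constant", call. = FALSE)
    X <- sweep(X, 2L, colMeans(X))
    y <- y - mean(y)
  } else if (all(y == 0)) {
    stop("response is the zero vector", call. = FALSE)
  }
  p <- ncol(X)
  nm <- colnames(X)
  y0_norm <- sqrt(sum(y^2))
  remaining <- seq_len(p)
  ranked <- integer(0)
  cos2 <- numeric(0)
  dropped <- integer(0)
  norm_floor <- 1e-12 * max(sqrt(colSums(X^2)), y0_norm)
  while (length(remaining)) {
    ynorm2 <- sum(y^2)
    if (sqrt(ynorm2) < tol * y0_norm) break
    cnorm2 <- colSums(X[, remaining, drop = FALSE]^2)
    alive <- cnorm2 > norm_floor^2
    if (any(!alive)) {
      dropped <- c(dropped, remaining[!alive])
      remaining <- remaining[alive]
      cnorm2 <- cnorm2[alive]
      if (!length(remaining)) break
    }
    proj <- as.numeric(crossprod(X[, remaining, drop = FALSE], y))
    ck <- proj^2 / (cnorm2 * ynorm2)
    best <- which.max(ck)  # first max = lowest column index tie-break
    j <- remaining[best]
    ranked <- c(ranked, j)
    cos2 <- c(cos2, ck[best])
    v <- X[, j] / sqrt(sum(X[, j]^2))
    remaining <- remaining[-best]
    if (length(remaining)) {
      coefs <- as.numeric(crossprod(X[, remaining, drop = FALSE], v))
      X[, remaining] <- X[, remaining, drop = FALSE] -
        outer(v, coefs)
    }
    y <- y - v * sum(v * y)
  }
  # With more candidates than observation-space dimensions, vectors must
  # vanish once the space is exhausted; only a collapse before the space
  # could possibly be exhausted (e.g. duplicated candidates) is anomalous.
  dim_budget <- length(y) - if (center) 1L else 0L
  if (length(dropped) && (length(ranked) + length(dropped)) < dim_budget)
    warning(sprintf("%d candidate(s) had zero norm after orthogonalisation and were ranked last",
                    length(dropped)), call. = FALSE)
  leftovers <- c(setdiff(remaining, dropped), sort(dropped))
  out <- data.frame(
    name = nm[c(ranked, leftovers)],
    rank = seq_len(length(ranked) + length(leftovers)),
    cos2 = c(cos2, rep(NA_real_, length(leftovers))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Probe risks from a joint ranking
#'
#' Given an OFR ranking of true candidates and random probes together, the
#' risk attached to a candidate is the fraction of probes ranked strictly
#' before it — an estimate of the probability that a pure-noise variable
#' outranks it, i.e. the risk of keeping that candidate although it is
#' irrelevant.
#'
#' @param ranking Data frame from [ofr_rank()] over candidates and probes.
#' @param is_probe Logical vector, one entry per ranking row.
#' @return Data frame of the non-probe rows with a `probe_risk` column.
#' @export
probe_risks <- function(ranking, is_probe) {
  if (nrow(ranking) != length(is_probe))
    stop("`is_probe` must match the ranking rows", call. = FALSE)
  n_probes <- sum(is_probe)
  if (n_probes < 1L) stop("need at least one probe", call. = FALSE)
  probes_before <- cumsum(is_probe) - is_probe
  out <- ranking[!is_probe, , drop = FALSE]
  out$probe_risk <- probes_before[!is_probe] / n_probes
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select variables by OFR ranking with random probes
#'
#' Appends `n_probes` random probe vectors (i.i.d. standard normal, seeded)
#' to the candidate set, ranks everything jointly with [ofr_rank()], computes
#' each candidate's probe risk and retains candidates whose risk does not
#' exceed `threshold`. The default `"prefix"` rule keeps the maximal prefix
#' of the candidate ranking whose members all pass (OFR relevance is
#' conditional on the earlier selections, so retaining a later variable
#' while discarding an earlier one would be incoherent); `"per-variable"`
#' keeps every passing candidate regardless of position.
#'
#' @inheritParams ofr_rank
#' @param threshold Retention threshold in (0, 1]; task- and
#'   condition-specific (e.g. 0.10 eyes-closed, 0.05 / 0.20 eyes-open
#'   regression / classification in the motivating study).
#' @param n_probes Number of probes (default 100).
#' @param probe_seed Seed for the probe draw.
#' @param rule `"prefix"` (default) or `"per-variable"`.
#' @return An object of class `ofr_selection`: list with `ranking` (name,
#'   rank, cos2, probe_risk, retained), `retained` (character), `threshold`,
#'   `n_probes`, `probe_seed`, `rule`.
#' @export
select_variables <- function(candidates, response, threshold,
                             n_probes = 100, probe_seed = 1L,
                             rule = c("prefix", "per-variable"),
                             center = TRUE) {
  rule <- match.arg(rule)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  n <- nrow(X)
  probes <- with_seed(probe_seed, matrix(rnorm(n * n_probes), n, n_probes))
  colnames(probes) <- sprintf(".probe%03d", seq_len(n_probes))
  joint <- cbind(X, probes)
  jr <- ofr_rank(joint, response, center = center)
  is_probe <- startsWith(jr$name, ".probe")
  ranking <- probe_risks(jr, is_probe)
  pass <- ranking$probe_risk <= threshold
  retained_flag <- if (rule == "prefix") {
    first_fail <- which(!pass)[1L]
    if (is.na(first_fail)) pass else seq_along(pass) < first_fail
  } else pass
  ranking$retained <- retained_flag
  retained <- ranking$name[retained_flag]
  if (!length(retained))
    warning("no variables retained at this threshold", call. = FALSE)
  structure(list(ranking = ranking, retained = retained,
                 threshold = threshold, n_probes = n_probes,
                 probe_seed = probe_seed, rule = rule),
            class = "ofr_selection")
}

#' @export
print.ofr_selection <- function(x, ...) {
  cat(sprintf("OFR selection (%s rule, threshold %.2f, %d probes, seed %d)\n",
              x$rule, x$threshold, x$n_probes, x$probe_seed))
  cat(sprintf("Retained %d of %d candidates:\n", length(x$retained),
              nrow(x$ranking)))
  top <- head(x$ranking, max(length(x$retained) + 2L, 5L))
  print(top, digits = 3)
  invisible(x)
}

#' Serialise a selection result to JSON
#'
#' @param selection An `ofr_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(
    list(threshold = selection$threshold, n_probes = selection$n_probes,
         probe_seed = selection$probe_seed, rule = selection$rule,
         retained = selection$retained, ranking = selection$ranking),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
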