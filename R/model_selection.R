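#' Screen a model complexity by the rank of its Jacobian
#'
#' Trains `probe_restarts` models of the given complexity on the full
#' training/validation set and checks the Jacobian rank of the
#' best-objective fit. A rank-deficient Jacobian means some parameters have
#' linearly dependent effects on the output — the model has too many
#' parameters for the data and is discarded before the (expensive)
#' leave-one-out scoring. A complexity with more parameters than examples
#' fails automatically (rank <= N < q).
#'
#' @inheritParams slnn
#' @param probe_restarts Restarts used for the screening fit.
#' @param base_seed Seed for the restarts.
#' @return List with `pass` (logical), `rank`, `q`, and `model` (the best
#'   screening fit, or `NULL` when q > N).
#' @export
screen_by_rank <- function(x, y, task, n_hidden, probe_restarts = 5L,
                           base_seed = 1L) {
  X <- as.matrix(x)
  q <- slnn_npar(n_hidden, ncol(X))
  if (q > nrow(X))
    return(list(pass = FALSE, rank = nrow(X), q = q, model = NULL))
  ms <- slnn_multistart(X, y, task, n_hidden, n_restarts = probe_restarts,
                        base_seed = base_seed)
  jr <- jacobian_rank(slnn_jacobian(ms$best))
  list(pass = jr$full_rank, rank = jr$rank, q = q, model = ms$best)
}

#' Leave-one-out score of one model specification
#'
#' Runs N refits, each excluding one example and all starting from the same
#' initial parameter vector (one set of initial values per LOO run, drawn
#' from `init_seed`). For regression the raw score is the mean squared
#' withheld-example error; `score` reports its square root so it shares the
#' RMSE unit in complexity plots. For classification the score is the
#' fraction of withheld examples misclassified at probability threshold 0.5.
#' A failed refit is retried once from a derived seed; more than 10%
#' failures abort.
#'
#' @inheritParams slnn
#' @param init_seed Seed of the shared initial parameter draw.
#' @param warm_start Start each refit from the full-data fit instead of the
#'   raw initial draw (a faster variant; not used for faithful reproduction
#'   runs).
#' @return An object of class `loo_result`: `score` (reported scale),
#'   `raw` (mean squared error or misclassification fraction),
#'   `per_example_errors`, `task`, `n_hidden`, `init_seed`.
#' @export
loo_score <- function(x, y, task = c("regression", "classification"),
                      n_hidden = 0L, init_seed = 1L, init_sd = 0.1,
                      max_iter = 500L, warm_start = FALSE) {
  task <- match.arg(task)
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 examples for leave-one-out",
                   call. = FALSE)
  q <- slnn_npar(n_hidden, ncol(X))
  theta0 <- with_seed(init_seed, rnorm(q, 0, init_sd))
  if (warm_start) {
    full <- slnn_fit_from(X, y, task, n_hidden, theta0 = theta0,
                          max_iter = max_iter)
    theta0 <- full$theta
  }
  errors <- numeric(n)
  failures <- 0L
  for (k in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(slnn_fit_from(X[-k, , drop = FALSE], y[-k], task,
                                     n_hidden, theta0 = theta0,
                                     max_iter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      retry_theta <- with_seed(derive_seed(init_seed, 7919L + k),
                               rnorm(q, 0, init_sd))
      fit <- tryCatch(
        suppressWarnings(slnn_fit_from(X[-k, , drop = FALSE], y[-k], task,
                                       n_hidden, theta0 = retry_theta,
                                       max_iter = max_iter)),
        error = function(e) NULL)
      if (is.null(fit)) stop("leave-one-out refit failed twice on example ",
                             k, call. = FALSE)
    }
    s <- slnn_raw_output(fit$theta, X[k, , drop = FALSE], n_hidden)
    if (task == "regression") {
      errors[k] <- y[k] - s
    } else {
      errors[k] <- as.numeric((stats::plogis(s) >= 0.5) != y[k])
    }
  }
  if (failures > 0.1 * n)
    stop("more than 10% of leave-one-out refits failed", call. = FALSE)
  raw <- if (task == "regression") mean(errors^2) else mean(errors)
  structure(list(score = if (task == "regression") sqrt(raw) else raw,
                 raw = raw, per_example_errors = errors, task = task,
                 n_hidden = as.integer(n_hidden), init_seed = init_seed),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("LOO result: %s, %d hidden unit(s), score %.4g (raw %.4g), seed %d\n",
              x$task, x$n_hidden, x$score, x$raw, x$init_seed))
  invisible(x)
}

#' Select model complexity by Jacobian screening and leave-one-out
#'
#' For each number of hidden units from 0 (the multilinear or logistic
#' model) to `max_hidden`: screen the complexity by the Jacobian rank of a
#' trained model, then run `n_restarts` leave-one-out scorings with distinct
#' initial-value seeds and keep the smallest score. The selected complexity
#' minimises the LOO score over the surviving complexities. The training
#' score of the best full-data fit is retained per complexity so the
#' LOO-vs-complexity curve can be plotted against the training error.
#'
#' @inheritParams loo_score
#' @param max_hidden Largest number of hidden units tried (default 5).
#' @param n_restarts LOO runs (initialisation draws) per complexity.
#' @param base_seed Base seed; run r of complexity h derives its seed from
#'   `(base_seed, h, r)`.
#' @param screen_restarts Restarts for the Jacobian screening fits.
#' @return An object of class `complexity_sweep`: `table` (data frame
#'   `n_hidden, screened, train_score, loo_score, loo_raw, best_seed`),
#'   `selected` (list `n_hidden`, `init_seed`), `task`.
#' @export
sweep_complexity <- function(x, y, task = c("regression", "classification"),
                             max_hidden = 5L, n_restarts = 20L,
                             base_seed = 1L, screen_restarts = 5L,
                             max_iter = 500L, warm_start = FALSE) {
  task <- match.arg(task)
  X <- as.matrix(x)
  if (ncol(X) < 1L) stop("no input variables", call. = FALSE)
  rows <- list()
  for (h in 0:max_hidden) {
    scr <- screen_by_rank(X, y, task, h, probe_restarts = screen_restarts,
                          base_seed = derive_seed(base_seed, 500L + h))
    if (!scr$pass) {
      rows[[length(rows) + 1L]] <- data.frame(
        n_hidden = h, screened = TRUE, train_score = NA_real_,
        loo_score = NA_real_, loo_raw = NA_real_, best_seed = NA_integer_)
      next
    }
    train_score <- if (task == "regression")
      sqrt(mean(residuals(scr$model)^2))
    else mean((predict(scr$model) >= 0.5) != scr$model$y)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      seed_r <- derive_seed(base_seed, 1000L * h + r)
      res <- loo_score(X, y, task, h, init_seed = seed_r,
                       max_iter = max_iter, warm_start = warm_start)
      if (is.null(best) || res$score < best$score) best <- res
      if (h == 0L && r == 1L) break  # convex: every restart is identical
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_hidden = h, screened = FALSE, train_score = train_score,
      loo_score = best$score, loo_raw = best$raw,
      best_seed = best$init_seed)
  }
  table <- do.call(rbind, rows)
  ok <- !table$screened
  if (!any(ok)) stop("all complexities were screened out", call. = FALSE)
  sel <- table[ok, ][which.min(table$loo_score[ok]), ]
  structure(list(table = table,
                 selected = list(n_hidden = sel$n_hidden,
                                 init_seed = sel$best_seed,
                                 loo_score = sel$loo_score),
                 task = task, n_restarts = n_restarts,
                 base_seed = base_seed),
            class = "complexity_sweep")
}

#' @export
print.complexity_sweep <- function(x, ...) {
  cat(sprintf("Complexity sweep (%s, %d LOO restarts per complexity)\n",
              x$task, x$n_restarts))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("Selected: %d hidden unit(s), LOO score %.4g\n",
              x$selected$n_hidden, x$selected$loo_score))
  invisible(x)
}

#' @export
plot.complexity_sweep <- function(x, ...) {
  tab <- x$table[!x$table$screened, ]
  ylab <- if (x$task == "regression") "score (RMSE units)"
          else "misclassification rate"
  graphics::matplot(tab$n_hidden, cbind(tab$train_score, tab$loo_score),
                    type = "b", pch = c(1, 19), lty = c(2, 1),
                    xlab = "hidden units", ylab = ylab, ...)
  graphics::legend("topright", c("training", "leave-one-out"),
                   pch = c(1, 19), lty = c(2, 1), bty = "n")
  invisible(x)
}

#' Write the complexity-sweep table to CSV
#'
#' Columns `n_hidden, screened, train_score, loo_score, best_seed`, enough
#' to redraw the LOO-vs-complexity curves.
#'
#' @param sweep A `complexity_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
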