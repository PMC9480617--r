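# Parameter vector layout for a single-hidden-layer network with p inputs and
# h hidden units: c(a0, a_1..a_h, then per hidden unit j: b_j, w_j1..w_jp),
# i.e. output bias, output weights, hidden (bias, weights) blocks.
# q = h (p + 1) + (h + 1); for h = 0, theta = c(intercept, slopes), q = p + 1.

slnn_npar <- function(n_hidden, n_inputs) {
  if (n_hidden == 0L) n_inputs + 1L
  else n_hidden * (n_inputs + 1L) + n_hidden + 1L
}

unpack_theta <- function(theta, n_hidden, p) {
  a0 <- theta[1L]
  a <- theta[seq.int(2L, 1L + n_hidden)]
  rest <- matrix(theta[-seq_len(1L + n_hidden)], nrow = n_hidden,
                 ncol = p + 1L, byrow = TRUE)
  list(a0 = a0, a = a, b = rest[, 1L], W = rest[, -1L, drop = FALSE])
}

# Linear (pre-logistic) network output.
slnn_raw_output <- function(theta, X, n_hidden) {
  p <- ncol(X)
  if (n_hidden == 0L) return(as.numeric(theta[1L] + X %*% theta[-1L]))
  pars <- unpack_theta(theta, n_hidden, p)
  H <- tanh(sweep(X %*% t(pars$W), 2L, pars$b, "+"))
  as.numeric(pars$a0 + H %*% pars$a)
}

# Analytic derivative of the raw output wrt every parameter (N x q).
slnn_raw_jacobian <- function(theta, X, n_hidden) {
  n <- nrow(X); p <- ncol(X)
  if (n_hidden == 0L) return(cbind(1, X, deparse.level = 0))
  pars <- unpack_theta(theta, n_hidden, p)
  Z <- sweep(X %*% t(pars$W), 2L, pars$b, "+")
  Th <- tanh(Z)
  Sech2 <- 1 - Th^2
  J <- matrix(0, n, length(theta))
  J[, 1L] <- 1
  J[, seq.int(2L, 1L + n_hidden)] <- Th
  col <- 1L + n_hidden
  for (j in seq_len(n_hidden)) {
    g <- pars$a[j] * Sech2[, j]
    J[, col + 1L] <- g                              # d/db_j
    J[, col + 1L + seq_len(p)] <- g * X             # d/dw_jk
    col <- col + 1L + p
  }
  J
}

new_slnn <- function(task, n_hidden, theta, X, y, objective, init_seed,
                     converged, input_names) {
  structure(list(task = task, n_hidden = as.integer(n_hidden),
                 input_names = input_names, theta = as.numeric(theta),
                 q = length(theta), objective = objective,
                 init_seed = init_seed, converged = converged,
                 X = X, y = y),
            class = "slnn")
}

xent_objective <- function(theta, X, y, n_hidden) {
  s <- slnn_raw_output(theta, X, n_hidden)
  p <- stats::plogis(s)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

xent_gradient <- function(theta, X, y, n_hidden) {
  s <- slnn_raw_output(theta, X, n_hidden)
  p <- stats::plogis(s)
  as.numeric(crossprod(slnn_raw_jacobian(theta, X, n_hidden), p - y))
}

# Core fit from a given initial parameter vector (NULL = seeded draw).
slnn_fit_from <- function(X, y, task, n_hidden, theta0 = NULL,
                          init_seed = 1L, init_sd = 0.1, max_iter = 500L,
                          grad_tol = 1e-8) {
  q <- slnn_npar(n_hidden, ncol(X))
  if (is.null(theta0))
    theta0 <- with_seed(init_seed, rnorm(q, 0, init_sd))
  if (n_hidden == 0L && task == "regression") {
    fit <- lm.fit(cbind(1, X), y)
    theta <- unname(fit$coefficients)
    if (anyNA(theta)) stop("singular design in linear fit", call. = FALSE)
    return(list(theta = theta, objective = sum(fit$residuals^2),
                converged = TRUE))
  }
  if (n_hidden == 0L && task == "classification") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    theta <- unname(fit$coefficients)
    if (anyNA(theta)) stop("singular design in logistic fit", call. = FALSE)
    return(list(theta = theta, objective = fit$deviance / 2,
                converged = fit$converged))
  }
  if (task == "regression") {
    # nls.lm warns when the iteration budget is hit; convergence is recorded
    # from fit$info instead
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = theta0,
      fn = function(th) y - slnn_raw_output(th, X, n_hidden),
      jac = function(th) -slnn_raw_jacobian(th, X, n_hidden),
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024L), ptol = 1e-12, ftol = 1e-12,
        gtol = grad_tol)))
    obj <- sum(fit$fvec^2)
    if (!is.finite(obj)) stop("non-finite training objective", call. = FALSE)
    return(list(theta = fit$par, objective = obj,
                converged = fit$info %in% 1:4))
  }
  fit <- optim(theta0, fn = xent_objective, gr = xent_gradient,
               X = X, y = y, n_hidden = n_hidden, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  if (!is.finite(fit$value)) stop("non-finite training objective",
                                  call. = FALSE)
  list(theta = fit$par, objective = fit$value,
       converged = fit$convergence == 0L)
}

#' Fit a linear, logistic or single-hidden-layer network model
#'
#' The model family used throughout the package: with `n_hidden = 0` a
#' multilinear regression (least squares via QR) or a logistic regression
#' (IRLS); with `n_hidden >= 1` a network with one layer of tanh hidden
#' units, biases on the hidden and output units and a linear (regression) or
#' logistic (classification) output. Regression minimises the sum of squared
#' residuals by Levenberg–Marquardt with the analytic Jacobian;
#' classification minimises the cross-entropy by BFGS with the analytic
#' gradient. Initial parameters are drawn N(0, `init_sd`^2) from `init_seed`,
#' so the fit is a deterministic function of (data, spec, seed).
#'
#' @param x Numeric input matrix (columns = selected variables).
#' @param y Response: numeric scores (regression) or 0/1 status
#'   (classification).
#' @param task `"regression"` or `"classification"`.
#' @param n_hidden Number of hidden units (0 = linear/logistic model).
#' @param init_seed Seed of the initial parameter draw.
#' @param init_sd Standard deviation of the initial parameter draw.
#' @param max_iter Optimiser iteration budget.
#' @param theta0 Optional explicit initial parameter vector (overrides
#'   `init_seed`).
#' @return An object of class `slnn` with elements `theta` (parameter
#'   vector), `objective` (SSR or cross-entropy at the optimum), `converged`,
#'   and the training data for `residuals()`/`summary()`.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("u", "v")))
#' y <- 1 + X[, 1] - 2 * X[, 2] + rnorm(30, 0, 0.1)
#' m <- slnn(X, y, "regression", n_hidden = 0)
#' coef(m)
slnn <- function(x, y, task = c("regression", "classification"),
                 n_hidden = 0L, init_seed = 1L, init_sd = 0.1,
                 max_iter = 500L, theta0 = NULL) {
  task <- match.arg(task)
  X <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("dimension mismatch", call. = FALSE)
  if (task == "classification" && !all(y %in% c(0, 1)))
    stop("classification needs a 0/1 response", call. = FALSE)
  q <- slnn_npar(n_hidden, ncol(X))
  if (nrow(X) <= q)
    warning(sprintf("more parameters (%d) than examples (%d)", q, nrow(X)),
            call. = FALSE)
  fit <- slnn_fit_from(X, y, task, n_hidden, theta0 = theta0,
                       init_seed = init_seed, init_sd = init_sd,
                       max_iter = max_iter)
  new_slnn(task, n_hidden, fit$theta, X, y, fit$objective, init_seed,
           fit$converged, colnames(X) %||% sprintf("x%d", seq_len(ncol(X))))
}

#' @export
predict.slnn <- function(object, newdata = NULL, type = c("response", "link"),
                         ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  if (ncol(X) != length(object$input_names))
    stop(sprintf("expected %d input column(s), got %d",
                 length(object$input_names), ncol(X)), call. = FALSE)
  s <- slnn_raw_output(object$theta, X, object$n_hidden)
  if (object$task == "classification" && type == "response")
    stats::plogis(s)
  else s
}

#' @export
coef.slnn <- function(object, ...) {
  th <- object$theta
  if (object$n_hidden == 0L) {
    names(th) <- c("(Intercept)", object$input_names)
  } else {
    h <- object$n_hidden
    nm <- c("a0", sprintf("a%d", seq_len(h)))
    for (j in seq_len(h))
      nm <- c(nm, sprintf("b%d", j), sprintf("w%d.%s", j, object$input_names))
    names(th) <- nm
  }
  th
}

#' @export
residuals.slnn <- function(object, ...) {
  object$y - predict(object)
}

#' @export
print.slnn <- function(x, ...) {
  kind <- if (x$n_hidden == 0L) {
    if (x$task == "regression") "multilinear regression"
    else "logistic regression"
  } else sprintf("%d-hidden-unit tanh network (%s)", x$n_hidden, x$task)
  cat(sprintf("slnn: %s, %d input(s) [%s], q = %d parameters\n", kind,
              length(x$input_names), paste(x$input_names, collapse = ", "),
              x$q))
  cat(sprintf("  training objective %.6g (%s), init seed %d%s\n",
              x$objective,
              if (x$task == "regression") "SSR" else "cross-entropy",
              x$init_seed, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
summary.slnn <- function(object, ...) {
  res <- residuals(object)
  out <- list(model = object,
              train_rmse = sqrt(mean(res^2)),
              train_error = if (object$task == "classification")
                mean((predict(object) >= 0.5) != object$y) else NA_real_,
              jacobian_full_rank =
                jacobian_rank(slnn_jacobian(object))$full_rank)
  class(out) <- "summary.slnn"
  out
}

#' @export
print.summary.slnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  train RMSE %.4g", x$train_rmse))
  if (!is.na(x$train_error))
    cat(sprintf(", misclassification rate %.3f", x$train_error))
  cat(sprintf(", Jacobian full rank: %s\n", x$jacobian_full_rank))
  invisible(x)
}

#' Multi-restart training
#'
#' Trains the same specification from `n_restarts` independent seeded
#' initialisations and returns all fits ordered by restart index, with the
#' best (lowest training objective) singled out. Restarts whose optimisation
#' fails (non-finite objective, singular fit) are recorded as `NULL` entries
#' rather than raised.
#'
#' @inheritParams slnn
#' @param n_restarts Number of restarts (>= 1).
#' @param base_seed Base seed; restart r uses a seed derived from
#'   `(base_seed, r)`.
#' @return List with `models` (length `n_restarts`, `NULL` where a restart
#'   failed), `best` (an `slnn`), `best_index`.
#' @export
slnn_multistart <- function(x, y, task, n_hidden, n_restarts = 300L,
                            base_seed = 1L, ...) {
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  models <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    m <- tryCatch(
      suppressWarnings(slnn(x, y, task, n_hidden,
                            init_seed = derive_seed(base_seed, r), ...)),
      error = function(e) NULL)
    models[[r]] <- m
  }
  objs <- vapply(models, function(m) if (is.null(m)) Inf else m$objective,
                 numeric(1))
  if (all(!is.finite(objs))) stop("all restarts failed", call. = FALSE)
  best_index <- which.min(objs)
  list(models = models, best = models[[best_index]],
       best_index = best_index)
}

#' Jacobian of a fitted model and its rank
#'
#' `slnn_jacobian` returns the N x q matrix of derivatives of the model
#' output with respect to each parameter, evaluated at the fitted parameters
#' (analytic; for classifiers the derivative of the pre-logistic output, so
#' rank deficiency reflects parameter redundancy rather than sigmoid
#' saturation). `jacobian_rank` counts singular values above
#' `max(N, q) * eps * max(singular value)`; a model whose Jacobian is not of
#' full column rank has redundant parameters and is flagged as
#' overfitting-prone.
#'
#' @param model A fitted `slnn`.
#' @param newdata Optional input matrix (defaults to the training inputs).
#' @return `slnn_jacobian`: N x q matrix. `jacobian_rank`: list with `rank`
#'   and `full_rank`.
#' @export
slnn_jacobian <- function(model, newdata = NULL) {
  X <- if (is.null(newdata)) model$X else as.matrix(newdata)
  slnn_raw_jacobian(model$theta, X, model$n_hidden)
}

#' @rdname slnn_jacobian
#' @param J An N x q Jacobian matrix.
#' @export
jacobian_rank <- function(J) {
  J <- as.matrix(J)
  if (!all(is.finite(J))) stop("non-finite entries in Jacobian",
                               call. = FALSE)
  sv <- svd(J, nu = 0, nv = 0)$d
  tol <- max(dim(J)) * .Machine$double.eps * max(sv, 0)
  rank <- sum(sv > tol)
  list(rank = rank, full_rank = rank == ncol(J))
}

#' Serialise a fitted model to JSON
#'
#' Writes the specification, parameter vector, seed and (optionally) the
#' normalisation metadata of the inputs the model expects.
#'
#' @param model A fitted `slnn`.
#' @param path Output path.
#' @param normalization Optional list of center/scale vectors to embed.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, normalization = NULL) {
  jsonlite::write_json(
    list(task = model$task, n_hidden = model$n_hidden,
         input_names = model$input_names, theta = model$theta,
         init_seed = model$init_seed, objective = model$objective,
         normalization = normalization),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(task = obj$task, n_hidden = as.integer(obj$n_hidden),
                 input_names = obj$input_names, theta = as.numeric(obj$theta),
                 q = length(obj$theta), objective = obj$objective,
                 init_seed = obj$init_seed, converged = NA,
                 X = NULL, y = NULL, normalization = obj$normalization),
            class = "slnn")
}
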