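rand_X <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
}

test_that("prediction follows the closed-form network arithmetic", {
  X <- rand_X(20, 3, seed = 1)
  y <- rnorm(20)
  m0 <- suppressWarnings(slnn(X, y, "regression", n_hidden = 1,
                              theta0 = rep(0.01, 6), max_iter = 1))
  # all-zero parameters: regression predicts 0, classification 0.5
  zero_reg <- m0; zero_reg$theta <- rep(0, 6)
  expect_equal(predict(zero_reg, X), rep(0, 20))
  yb <- rep_len(c(0, 1), 20)
  mc <- suppressWarnings(slnn(X, yb, "classification", n_hidden = 1,
                              max_iter = 1))
  mc$theta <- rep(0, mc$q)
  expect_equal(predict(mc, X), rep(0.5, 20))
  # hand-built 1-hidden-unit net on 3 inputs
  theta <- c(0.3, 1.7, -0.2, 0.5, -1.1, 0.8)  # a0, a1, b1, w11, w12, w13
  m <- zero_reg; m$theta <- theta
  manual <- 0.3 + 1.7 * tanh(-0.2 + X %*% c(0.5, -1.1, 0.8))
  expect_equal(predict(m, X), as.numeric(manual), tolerance = 1e-12)
  expect_error(predict(m, X[, 1:2]), "input")
})

test_that("linear specifications reproduce the closed-form fits", {
  X <- rand_X(60, 3, seed = 2)
  y <- 2 + X %*% c(1, -1, 0.5) + rnorm(60, 0, 0.3)
  m <- slnn(X, y, "regression", n_hidden = 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(coef(m)), ols, tolerance = 1e-8)
  yb <- as.integer(plogis(X %*% c(1, -1, 0.5)) > runif(60))
  mlog <- slnn(X, yb, "classification", n_hidden = 0)
  ref <- unname(coef(glm(yb ~ X, family = binomial())))
  expect_equal(unname(coef(mlog)), ref, tolerance = 1e-6)
})

test_that("training is deterministic and fits a realizable target to machine precision", {
  X <- rand_X(200, 2, seed = 3)
  a <- slnn(X, rnorm(200), "regression", n_hidden = 2, init_seed = 5)
  b <- slnn(X, a$y, "regression", n_hidden = 2, init_seed = 5)
  expect_identical(a$theta, b$theta)
  # data generated by a known 2-hidden-unit network, zero noise
  theta_true <- c(0.5, 2, -1.5, 0.3, 1, -0.7, -0.2, 0.8, 1.2)
  gen <- a; gen$theta <- theta_true
  y <- predict(gen, X)
  ms <- slnn_multistart(X, y, "regression", n_hidden = 2, n_restarts = 30,
                        base_seed = 7)
  expect_lt(ms$best$objective, 1e-6)
})

test_that("multistart is ordered, reproducible and monotone in its envelope", {
  X <- rand_X(80, 2, seed = 4)
  y <- tanh(X[, 1]) * 2 + rnorm(80, 0, 0.2)
  ms <- slnn_multistart(X, y, "regression", n_hidden = 1, n_restarts = 10,
                        base_seed = 9)
  expect_length(ms$models, 10)
  # singleton equals a direct call with the derived seed
  single <- slnn_multistart(X, y, "regression", n_hidden = 1, n_restarts = 1,
                            base_seed = 9)
  expect_identical(single$best$theta, ms$models[[1]]$theta)
  # convex case: all restarts agree
  msl <- slnn_multistart(X, y, "regression", n_hidden = 0, n_restarts = 4,
                         base_seed = 9)
  objs <- vapply(msl$models, `[[`, numeric(1), "objective")
  expect_lt(max(objs) - min(objs), 1e-6)
  # best objective over nested restart sets is non-increasing
  objs_nn <- vapply(ms$models, `[[`, numeric(1), "objective")
  running <- cummin(objs_nn)
  expect_true(all(diff(running) <= 0))
})

test_that("the Jacobian matches its definitions and finite differences", {
  X <- rand_X(25, 2, seed = 6)
  y <- rnorm(25)
  lin <- slnn(X, y, "regression", n_hidden = 0)
  expect_equal(slnn_jacobian(lin), cbind(1, X), ignore_attr = TRUE)
  nn <- slnn(X, y, "regression", n_hidden = 2, init_seed = 3)
  J <- slnn_jacobian(nn)
  eps <- 1e-6
  for (i in seq_len(nn$q)) {
    up <- nn; up$theta[i] <- up$theta[i] + eps
    dn <- nn; dn$theta[i] <- dn$theta[i] - eps
    fd <- (predict(up, X) - predict(dn, X)) / (2 * eps)
    expect_equal(J[, i], fd, tolerance = 1e-5)
  }
  # classification Jacobian is taken on the pre-logistic output
  yb <- rep_len(c(0, 1), 25)
  mc <- suppressWarnings(slnn(X, yb, "classification", n_hidden = 1,
                              init_seed = 2, max_iter = 50))
  Jc <- slnn_jacobian(mc)
  upc <- mc; upc$theta[1] <- upc$theta[1] + eps
  dnc <- mc; dnc$theta[1] <- dnc$theta[1] - eps
  fdc <- (predict(upc, X, type = "link") - predict(dnc, X, type = "link")) /
    (2 * eps)
  expect_equal(Jc[, 1], fdc, tolerance = 1e-5)
})

test_that("rank detection flags duplicated hidden units and passes random designs", {
  X <- rand_X(40, 2, seed = 8)
  nn <- slnn(X, rnorm(40), "regression", n_hidden = 2, init_seed = 1,
             max_iter = 5)
  # force two identical hidden units: (b, w) blocks and output weights equal
  nn$theta <- c(0.1, 0.7, 0.7, 0.4, 1.1, -0.6, 0.4, 1.1, -0.6)
  J <- slnn_jacobian(nn)
  expect_equal(J[, 2], J[, 3])
  jr <- jacobian_rank(J)
  expect_false(jr$full_rank)
  # random Gaussian N x q has rank q almost surely
  set.seed(10)
  expect_true(jacobian_rank(matrix(rnorm(200), 40, 5))$full_rank)
  expect_error(jacobian_rank(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("models survive a JSON round-trip", {
  X <- rand_X(30, 2, seed = 12)
  m <- slnn(X, rnorm(30), "regression", n_hidden = 1, init_seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$theta, m$theta)
  expect_equal(predict(back, X), predict(m, X))
})
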