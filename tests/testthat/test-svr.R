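test_that("SMO reproduces frozen reference solutions (linear kernel)", {
  # reference dual coefficients and intercepts from an independent
  # epsilon-SVR implementation (LIBSVM, tol 1e-10) on this exact fixture
  set.seed(42)
  M <- 14
  X <- matrix(rbinom(M * 6, 1, 0.4), M, 6)
  y <- as.numeric(scale(X %*% c(2, -1, 0, 0, 1, 0) + rnorm(M, 0, 0.3)))
  ref <- list(
    `0.05` = list(
      b = -0.0313914846,
      beta = c(0.05, -0.05, -0.05, 0.05, 0.05, 0, 0, -0.05, 0.05, -0.05,
               -0.05, 0.05, 0.05, -0.05)),
    `1` = list(
      b = -0.6884709648,
      beta = c(0.7734866906, 0, -1, 0.3862071535, -1, 0, 0, -0.1023039551,
               0.2381944496, 0, 0, 0.7044818367, 0, -0.0000661753)),
    `100` = list(
      b = -0.8197373482,
      beta = c(0, 0, -100, 0.5525136034, -99.2970166770, 0, 97.5684994359,
               0, 1.5277649965, 0, 98.6244996443, 0.9169152216, 0,
               0.1068237753)))
  for (Cs in names(ref)) {
    C <- as.numeric(Cs)
    fit <- fit_svr(X, y, "linear", C = C, scale_y = FALSE, tol = 1e-10)
    expect_equal(fit$dual_coef, ref[[Cs]]$beta,
                 tolerance = 1e-6 * max(1, C))
    expect_equal(fit$intercept, ref[[Cs]]$b, tolerance = 1e-6)
  }
})

test_that("SMO reproduces the frozen rbf reference solution", {
  set.seed(43)
  M <- 12
  X <- matrix(rnorm(M * 4), M, 4)
  y <- as.numeric(scale(sin(X[, 1]) + rnorm(M, 0, 0.2)))
  ref_beta <- c(0.9556287588, -0.9771387181, -0.0458993542, 1.2320635725,
                -0.4762556354, 0.1141052832, 0.5863697615, -1.0932879582,
                -0.8563616306, -1.1566383256, 1.6104508182, 0.1069634280)
  fit <- fit_svr(X, y, "rbf", C = 2, gamma = 0.5, scale_y = FALSE,
                 tol = 1e-10)
  expect_equal(fit$dual_coef, ref_beta, tolerance = 1e-6)
  expect_equal(fit$intercept, 0.2385612195, tolerance = 1e-6)
})

test_that("SMO is never worse than the QP route on the primal objective", {
  # second, live oracle route: the same problem as a quadratic program;
  # solve.QP's ridge can leave its solution slightly infeasible, so the
  # comparison is on (feasibility-respecting) primal objective values
  set.seed(42)
  M <- 14
  X <- matrix(rbinom(M * 6, 1, 0.4), M, 6)
  y <- as.numeric(scale(X %*% c(2, -1, 0, 0, 1, 0) + rnorm(M, 0, 0.3)))
  K <- tcrossprod(X)
  primal <- function(beta, b, C) {
    0.5 * sum(beta * (K %*% beta)) +
      C * sum(pmax(abs(y - as.numeric(K %*% beta) - b) - 0.1, 0))
  }
  for (C in c(0.05, 1, 100)) {
    fit <- fit_svr(X, y, "linear", C = C, scale_y = FALSE, tol = 1e-10)
    oracle <- qp_svr_oracle(K, y, C, 0.1)
    if (!is.finite(oracle$b)) next
    expect_lte(primal(fit$dual_coef, fit$intercept, C),
               primal(oracle$beta, oracle$b, C) + 1e-6 * max(1, C))
  }
})

test_that("fitting is deterministic and respects the box constraint", {
  set.seed(44)
  X <- matrix(rbinom(200, 1, 0.3), 20, 10)
  y <- rnorm(20)
  f1 <- fit_svr(X, y, "linear", C = 0.5)
  f2 <- fit_svr(X, y, "linear", C = 0.5)
  expect_identical(f1$dual_coef, f2$dual_coef)
  expect_identical(f1$intercept, f2$intercept)
  expect_true(all(abs(f1$dual_coef) <= 0.5 + 1e-12))
})

test_that("constant deficit yields zero weights and intercept = constant", {
  X <- matrix(rbinom(60, 1, 0.5), 12, 5)
  f <- fit_svr(X, rep(21, 12), "linear", C = 1)
  expect_true(all(f$dual_coef == 0))
  expect_equal(unique(predict(f)), 21)
})

test_that("a single perfectly correlated feature is fit at large C", {
  set.seed(46)
  x <- rbinom(30, 1, 0.5)
  y <- 2 * x + 0.1 * rnorm(30)
  f <- fit_svr(cbind(x), y, "linear", C = 2^10)
  expect_gt(cor(predict(f), y), 0.99)
})

test_that("extract_beta reproduces model predictions (primal-dual consistency)", {
  co <- small_cohort(seed = 53, M = 20)
  d <- build_multilesion_design(co$ail, co$wmh, k = 3, "none")
  ps <- prepare_scores(co$table)
  f <- fit_svr(d, ps$deficit, "linear", C = 0.1)
  bm <- extract_beta(f, d)
  beta_vec <- c(bm$beta$AIL, bm$beta$WMH)
  expect_length(bm$beta$AIL, d$block_sizes[["AIL"]])
  expect_length(bm$beta$WMH, d$block_sizes[["WMH"]])
  pred_primal <- as.numeric(d$matrix %*% beta_vec) + f$intercept
  pred_dual <- as.numeric(f$K %*% f$dual_coef) + f$intercept
  expect_lt(max(abs(pred_primal - pred_dual)), 1e-6)
  # all-zero column gets beta exactly 0
  Xz <- cbind(d$matrix[, 1:5], 0)
  fz <- fit_svr(Xz, ps$deficit, "linear", C = 0.1)
  expect_equal(as.numeric(crossprod(Xz, fz$dual_coef))[6], 0)
})

test_that("scaling covariance: design and C rescaling keeps predictions", {
  set.seed(47)
  X <- matrix(rbinom(240, 1, 0.3), 24, 10)
  y <- as.numeric(scale(X %*% rnorm(10) + rnorm(24)))
  c0 <- 4
  f1 <- fit_svr(X, y, "linear", C = c0, scale_y = FALSE)
  # scaling features by s scales the kernel by s^2; C/s^2... the dual box
  # rescales as C' = C / s^2 for an identical decision function
  s <- 0.5
  f2 <- fit_svr(X * s, y, "linear", C = c0 / s^2, scale_y = FALSE)
  expect_lt(max(abs(predict(f1) - predict(f2))), 1e-4)
})

test_that("LOOCV grid defaults follow the stated endpoint convention", {
  expect_equal(mlsmap:::default_c_grid("linear"), 2^seq(-20, 20))
  expect_equal(mlsmap:::default_c_grid("rbf"), 2^seq(-20, 6))
  expect_equal(mlsmap:::default_gamma_grid(), 1:16)
})

test_that("LOOCV recovers a noiseless linear signal and selects by accuracy", {
  # determined case (fewer voxels than subjects): the fit can identify the
  # sparse generator and held-out error is bounded by the epsilon tube
  set.seed(48)
  M <- 24
  X <- matrix(rbinom(M * 12, 1, 0.3), M, 12)
  w <- numeric(12); w[c(3, 7)] <- c(2, 1)
  y <- as.numeric(X %*% w)
  rep <- loocv_train(X, y, "linear", C_grid = 2^seq(-10, 10, 2))
  expect_gte(rep$best$accuracy, 0.99)
  expect_equal(rep$best$accuracy, max(rep$grid$accuracy, na.rm = TRUE))
  # tie-break: the smallest C attaining the maximum is selected
  first_max <- rep$grid$C[which.max(rep$grid$accuracy)]
  expect_equal(rep$best$C, first_max)
  expect_error(loocv_train(X, rep(1, M), "linear"), "constant")
})

test_that("LOOCV accuracy is sign-convention invariant", {
  set.seed(49)
  M <- 20
  X <- matrix(rbinom(M * 30, 1, 0.3), M, 30)
  y <- as.numeric(X %*% rbinom(30, 1, 0.2)) + rnorm(M, 0, 0.5)
  g <- 2^seq(-6, 6, 3)
  r1 <- loocv_train(X, y, "linear", C_grid = g)
  r2 <- loocv_train(X, -y, "linear", C_grid = g)
  expect_equal(r1$best$accuracy, r2$best$accuracy, tolerance = 1e-5)
})

test_that("rbf LOOCV searches the C x gamma grid", {
  set.seed(50)
  M <- 16
  X <- matrix(rbinom(M * 10, 1, 0.4), M, 10)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(M, 0, 0.3)
  rep <- loocv_train(X, y, "rbf", C_grid = 2^c(-2, 0, 2), gamma_grid = 1:2)
  expect_equal(nrow(rep$grid), 6L)
  expect_false(is.na(rep$best$gamma))
})
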