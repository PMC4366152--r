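test_that("environment designs are reference-coded with full rank", {
  fx <- default_panel()
  d10 <- build_env_design(fx$pheno, "site_year")
  Z <- env_design_matrix(d10, fx$pheno)
  expect_equal(ncol(Z), 10L) # intercept + 9 dummies
  expect_equal(qr(Z)$rank, 10L)
  one <- fx$pheno[fx$pheno$env == "N3", ]
  d1 <- build_env_design(one, "none")
  expect_equal(ncol(env_design_matrix(d1, one)), 1L)
  expect_error(build_env_design(one, "year_within_site"), "degenerate")
})

test_that("rr_blup solves the penalised normal equations exactly", {
  # single marker, lambda = 0: exact least squares
  x1 <- matrix(c(-1, 1, -1, 1), 4, 1, dimnames = list(NULL, "m1"))
  y1 <- x1[, 1]
  f1 <- fit_rr_blup(x1, y1, lambda = 0)
  expect_equal(unname(f1$beta), 1, tolerance = 1e-12)
  expect_equal(unname(f1$gamma), 0, tolerance = 1e-12)
  # infinite-shrinkage limit
  finf <- fit_rr_blup(x1, y1 + 2, lambda = 1e12)
  expect_lt(abs(unname(finf$beta)), 1e-9)
  expect_equal(unname(finf$gamma), mean(y1 + 2), tolerance = 1e-6)

  # 50 x 100: matches the brute-force (X'X + lambda I)^-1 oracle
  set.seed(31)
  X <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(NULL, paste0("m", 1:100)))
  y <- X[, 1] * 2 + rnorm(50)
  lam <- 3.7
  fit <- fit_rr_blup(X, y, lambda = lam)
  A <- rbind(c(50, colSums(X)),
             cbind(colSums(X), crossprod(X) + diag(lam, 100)))
  oracle <- solve(A, c(sum(y), crossprod(X, y)))
  expect_lt(max(abs(c(fit$gamma, fit$beta) - oracle)), 1e-8)

  # shrinkage monotonicity in lambda
  norms <- vapply(c(0.1, 1, 10, 100), function(l)
    sqrt(sum(fit_rr_blup(X, y, lambda = l)$beta^2)), 0)
  expect_true(all(diff(norms) < 0))

  # marker column order does not change the fit
  perm <- sample(100)
  fit_p <- fit_rr_blup(X[, perm], y, lambda = lam)
  expect_equal(fit_p$beta[names(fit$beta)], fit$beta, tolerance = 1e-10)
})

test_that("REML-selected penalty recovers signal competitively", {
  set.seed(32)
  X <- binary_X(120, 300, seed = 32)
  y <- X[, 1:10] %*% rep(0.5, 10) + rnorm(120)
  fit <- fit_rr_blup(X, as.vector(y))
  expect_gt(fit$lambda, 0)
  expect_gt(cor(predict(fit, X), as.vector(y)), 0.7)
})

test_that("Gibbs samplers honour their priors' degenerate limits", {
  X <- binary_X(40, 8, seed = 33)
  # zero-variance phenotype: all posterior-mean effects near zero
  spec0 <- model_spec("bayes_a", iters = 1200L, burnin = 200L, thin = 2L,
                      seed = 2)
  f0 <- fit_bayes(X, rep(5, 40), family = "bayes_a", spec = spec0)
  expect_lt(max(abs(f0$beta)), 0.05)
  expect_equal(unname(f0$gamma[1]), 5, tolerance = 0.05)
  # BayesB with pi = 1: every effect exactly zero in every sweep
  y <- X[, 1] + rnorm(40)
  fz <- fit_bayes(X, y, family = "bayes_b",
                  spec = model_spec("bayes_b", iters = 600L, burnin = 100L,
                                    thin = 1L, pi = 1, keep_samples = TRUE))
  expect_true(all(fz$samples == 0))
  expect_true(all(fz$beta == 0))
  # identical seeds reproduce identical fits
  fa <- fit_bayes(X, y, family = "bayes_lasso",
                  spec = model_spec("bayes_lasso", iters = 500L,
                                    burnin = 100L, thin = 1L, seed = 9))
  fb <- fit_bayes(X, y, family = "bayes_lasso",
                  spec = model_spec("bayes_lasso", iters = 500L,
                                    burnin = 100L, thin = 1L, seed = 9))
  expect_identical(fa$beta, fb$beta)
})

test_that("BayesA posterior means shrink monotonically with the prior scale", {
  X <- binary_X(50, 5, seed = 34)
  y <- X[, 1] * 0.8 + rnorm(50, sd = 0.5)
  eff <- vapply(c(1, 0.1, 0.01, 0.001), function(S) {
    f <- fit_bayes(X, y, family = "bayes_a",
                   spec = model_spec("bayes_a", iters = 3000L, burnin = 500L,
                                     thin = 2L, S = S, nu = 4, seed = 4))
    abs(unname(f$beta["m1"]))
  }, 0)
  expect_true(all(diff(eff) < 0))
})

test_that("RKHS kernel BLUP matches ridge duality and absorbs covariates", {
  set.seed(35)
  X <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(NULL, paste0("m", 1:100)))
  y <- X[, 2] + rnorm(50)
  lam <- 2.5
  fr <- fit_rr_blup(X, y, lambda = lam)
  fk <- fit_rkhs(X, y, spec = model_spec("rkhs", kernel = "linear",
                                         lambda = lam))
  expect_lt(max(abs(predict(fk, X) - predict(fr, X))), 1e-6)
  # prediction on a training row reproduces the fitted value
  g <- fit_rkhs(X, y, spec = model_spec("rkhs", theta = 8, lambda = 1))
  K <- exp(-(as.matrix(dist(X)) / 8)^2)
  expect_equal(unname(diag(K)), rep(1, 50)) # D = 0 on the diagonal
  fitted <- as.vector(g$gamma[1] + K %*% g$alpha)
  expect_lt(max(abs(predict(g, X) - fitted)), 1e-10)
  # theta -> Inf: the kernel flattens and predictions collapse to the mean
  ginf <- fit_rkhs(X, y, spec = model_spec("rkhs", theta = 1e8, lambda = 1))
  expect_lt(max(abs(predict(ginf, X) - mean(y))), 0.05)
  expect_error(fit_rkhs(X, y, spec = model_spec("rkhs", theta = -1)),
               "theta")
})

test_that("epsilon-insensitive SVR behaves like its quadratic program", {
  # constant response inside the tube: no support vectors needed
  x <- matrix(seq(-1, 1, length.out = 8), 8, 1,
              dimnames = list(NULL, "m1"))
  yc <- rep(2, 8) + c(-1, 1)[rep(1:2, 4)] * 0.001
  fc <- fit_svr(x, yc, kernel = "linear",
                spec = model_spec("svr_linear", cost_grid = 1,
                                  epsilon_grid = 0.5))
  expect_lt(max(abs(predict(fc, x) - mean(yc))), 0.01)
  # noiseless line, epsilon = 0, large C: recovers the least-squares slope
  y <- 0.7 * x[, 1]
  fl <- fit_svr(x, y, kernel = "linear",
                spec = model_spec("svr_linear", cost_grid = 1000,
                                  epsilon_grid = 1e-6))
  expect_lt(max(abs(predict(fl, x) - y)), 1e-3)
  slope <- diff(predict(fl, matrix(c(0, 1), 2, 1,
                                   dimnames = list(NULL, "m1"))))
  expect_lt(abs(slope - 0.7), 1e-3)
  # wide Gaussian kernel converges to linear-kernel behaviour
  set.seed(36)
  X <- binary_X(40, 6, seed = 36)
  yz <- as.vector(scale(X[, 1] + 0.5 * X[, 2]))
  pl <- predict(fit_svr(X, yz, kernel = "linear",
                        spec = model_spec("svr_linear", cost_grid = 100,
                                          epsilon_grid = 0.001)), X)
  # cost scales with width^2: the wide-kernel linear term is O(1/width^2)
  pg <- predict(fit_svr(X, yz, kernel = "gaussian",
                        spec = model_spec("svr_gaussian",
                                          cost_grid = 100 * 30^2,
                                          epsilon_grid = 0.001,
                                          width_factors = 30)), X)
  expect_lt(max(abs(pl - pg)), 1e-2)
  expect_error(fit_svr(X, yz, spec = model_spec("svr_linear",
                                                cost_grid = numeric(0))),
               "grid")
})

test_that("random forest uses mtry = p/3 and ranks a causal marker first", {
  fx <- default_panel()
  x <- fx$panel$coded
  f <- fit_rf(x[, 1:1248], rnorm(nrow(x)),
              spec = model_spec("random_forest", num_trees = 5L),
              importance = FALSE)
  expect_equal(f$mtry, 416L) # round(1248 / 3)
  # strong single causal marker dominates the importance ranking
  X <- binary_X(80, 30, seed = 37)
  top <- vapply(1:10, function(s) {
    y <- X[, 1] + rnorm(80, sd = 0.1)
    fr <- fit_rf(X, y, spec = model_spec("random_forest",
                                         num_trees = 300L, seed = s))
    names(which.max(fr$importance))
  }, "")
  expect_gte(sum(top == "m1"), 9)
  # pure noise: importances centred near zero
  fn <- fit_rf(X, rnorm(80), spec = model_spec("random_forest",
                                               num_trees = 500L, seed = 1))
  expect_lt(abs(mean(fn$importance)),
            2 * sd(fn$importance) / sqrt(ncol(X)) + 0.02)
  expect_error(fit_rf(X[1:5, ], rnorm(5)), "n >= 10")
})

test_that("prediction is deterministic, equivariant and marker-checked", {
  X <- binary_X(30, 12, seed = 38)
  y <- X[, 3] + rnorm(30, sd = 0.2)
  fit <- fit_rr_blup(X, y, lambda = 1)
  perm <- sample(30)
  expect_equal(predict(fit, X[perm, ]), predict(fit, X)[perm])
  expect_error(predict(fit, X[, 1:5]), "m6")
  # rr_blup with n > p and lambda = 0 reproduces training data exactly
  f0 <- fit_rr_blup(X[, 1, drop = FALSE], X[, 1], lambda = 0)
  expect_equal(predict(f0, X[, 1, drop = FALSE]), X[, 1],
               tolerance = 1e-10, ignore_attr = TRUE)
})
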