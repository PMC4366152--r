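# Eight whole-genome prediction models under one fit/predict contract.
# Linear and kernel families (RR-BLUP, Bayesian LASSO, BayesA, BayesB,
# RKHS) take environment dummies as unpenalised fixed effects estimated
# jointly with the genetic term; margin/tree methods (SVR, random
# forest), which have no native fixed-effect notion, are fitted on
# phenotypes residualised against environment means.

GS_FAMILIES <- c("rr_blup", "bayes_lasso", "bayes_a", "bayes_b",
                 "rkhs", "svr_linear", "svr_gaussian", "random_forest")

#' Specify a genomic-prediction model
#'
#' @param family one of `rr_blup`, `bayes_lasso`, `bayes_a`, `bayes_b`,
#'   `rkhs`, `svr_linear`, `svr_gaussian`, `random_forest`.
#' @param seed integer seed used by stochastic fits.
#' @param ... family-specific hyperparameters overriding the defaults
#'   (e.g. `lambda`, `iters`, `burnin`, `thin`, `pi`, `theta`,
#'   `cost_grid`, `epsilon_grid`, `num_trees`, `mtry_fraction`).
#' @return a `gs_model_spec`.
#' @export
model_spec <- function(family, seed = 1L, ...) {
  family <- match.arg(family, GS_FAMILIES)
  hp <- utils::modifyList(default_hyperparams(family), list(...))
  if (family %in% c("bayes_lasso", "bayes_a", "bayes_b") &&
      hp$iters <= hp$burnin)
    stop("MCMC iters must exceed burnin")
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "gs_model_spec")
}

default_hyperparams <- function(family) {
  switch(family,
    rr_blup = list(lambda = NULL),
    bayes_lasso = list(iters = 12000L, burnin = 2000L, thin = 5L,
                       R2 = 0.5, lambda2 = NULL, sample_lambda = TRUE,
                       sigma2e = NULL, keep_samples = FALSE),
    bayes_a = list(iters = 12000L, burnin = 2000L, thin = 5L, R2 = 0.5,
                   nu = 4, S = NULL, sigma2e = NULL, keep_samples = FALSE),
    bayes_b = list(iters = 12000L, burnin = 2000L, thin = 5L, R2 = 0.5,
                   nu = 4, S = NULL, pi = 0.95, sigma2e = NULL,
                   keep_samples = FALSE),
    rkhs = list(theta = NULL, theta_grid = c(0.25, 0.5, 1, 2, 4),
                lambda = NULL, kernel = "gaussian", inner_k = 5L),
    svr_linear = list(cost_grid = c(0.1, 1, 10, 100),
                      epsilon_grid = c(0.01, 0.1, 0.5), inner_k = 5L),
    svr_gaussian = list(cost_grid = c(0.1, 1, 10, 100),
                        epsilon_grid = c(0.01, 0.1, 0.5),
                        width_factors = c(0.5, 1, 2), inner_k = 5L),
    random_forest = list(num_trees = 1000L, mtry_fraction = 1 / 3,
                         min_node_size = 5L))
}

#' Environment covariate design
#'
#' Reference-coded dummies for the site-year environments of a phenotype
#' table. `scheme = "site_year"` gives one dummy per non-reference
#' environment; `"year_within_site"` codes years only (for per-region
#' fits); `"none"` is intercept-only.
#'
#' @param pheno a [phenotype_table()].
#' @param scheme covariate scheme.
#' @return an `env_design` with the environment keys and a
#'   [env_design_matrix()]-compatible level set.
#' @export
build_env_design <- function(pheno,
                             scheme = c("site_year", "year_within_site",
                                        "none")) {
  scheme <- match.arg(scheme)
  keys <- unique(pheno[, c("site", "year", "env")])
  keys <- keys[order(keys$site, keys$year), , drop = FALSE]
  if (!nrow(keys)) stop("phenotype table has no environments")
  levels <- switch(scheme,
    site_year = keys$env,
    year_within_site = unique(keys$year),
    none = character(0))
  if (scheme == "year_within_site" && length(levels) < 2)
    stop("year_within_site design is degenerate with a single year")
  structure(list(scheme = scheme, keys = keys, levels = levels,
                 reference = if (length(levels)) levels[1] else NA_character_),
            class = "env_design")
}

#' Record-level covariate matrix for an environment design
#'
#' @param design an [build_env_design()] result.
#' @param pheno phenotype records the rows correspond to.
#' @return numeric matrix with an intercept column plus reference-coded
#'   dummies (full column rank).
#' @export
env_design_matrix <- function(design, pheno) {
  n <- nrow(pheno)
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  lev <- design$levels
  if (length(lev) >= 2) {
    val <- switch(design$scheme, site_year = pheno$env,
                  year_within_site = pheno$year)
    unknown <- setdiff(unique(val), lev)
    if (length(unknown)) stop("environment level(s) not in design: ",
                              paste(unknown, collapse = ", "))
    for (l in lev[-1]) Z <- cbind(Z, as.numeric(val == l))
    colnames(Z) <- c("(Intercept)", paste0("env", lev[-1]))
  }
  Z
}

# ---- shared linear-algebra helpers -----------------------------------------

# REML estimate of delta = sigma2e/sigma2u for y = Z gamma + u + e,
# u ~ N(0, sigma2u * K); spectral form after projecting out Z.
reml_delta <- function(K, y, Z) {
  n <- length(y); q <- ncol(Z)
  Zqr <- qr(Z)
  if (Zqr$rank < q) stop("singular covariate block")
  Py <- qr.resid(Zqr, y)
  M <- qr.resid(Zqr, t(qr.resid(Zqr, K)))
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- seq_len(n - q)
  d <- pmax(es$values[keep], 0)
  eta <- as.vector(crossprod(es$vectors[, keep, drop = FALSE], Py))
  crit <- function(logd) {
    delta <- exp(logd)
    (n - q) * log(sum(eta^2 / (d + delta))) + sum(log(d + delta))
  }
  grid <- seq(-8, 8, length.out = 33)
  vals <- vapply(grid, crit, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(crit, c(lo, hi))
  delta <- exp(opt$minimum)
  sigma2u <- sum(eta^2 / (d + delta)) / (n - q)
  list(delta = delta, sigma2u = sigma2u, sigma2e = delta * sigma2u)
}

# GLS fixed effects + kernel BLUP dual coefficients at fixed ridge delta:
# gamma = (Z' V^-1 Z)^-1 Z' V^-1 y, alpha = V^-1 (y - Z gamma), V = K + delta I
kernel_blup_solve <- function(K, y, Z, delta) {
  V <- K + diag(delta, nrow(K))
  Vc <- tryCatch(chol(V), error = function(e)
    stop("kernel system is singular (is lambda = 0 with a rank-deficient ",
         "kernel?)"))
  Vi_y <- backsolve(Vc, forwardsolve(t(Vc), y))
  Vi_Z <- backsolve(Vc, forwardsolve(t(Vc), Z))
  A <- crossprod(Z, Vi_Z)
  gamma <- tryCatch(solve(A, crossprod(Z, Vi_y)), error = function(e)
    stop("singular covariate block"))
  alpha <- Vi_y - Vi_Z %*% gamma
  list(gamma = drop(gamma), alpha = drop(alpha))
}

check_xy <- function(x, y, Z) {
  if (anyNA(x)) stop("marker matrix must be complete (impute first)")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (!is.null(Z) && nrow(Z) != length(y)) stop("covariate rows mismatch")
  if (is.null(colnames(x))) stop("marker matrix needs column names")
}

# ---- model fits ------------------------------------------------------------

#' Ridge-regression BLUP (RR-BLUP)
#'
#' Minimises `RSS + lambda * sum(beta^2)` with the intercept and
#' environment covariates unpenalised, solved exactly (through the n-by-n
#' dual when p > n). With `lambda = NULL` the penalty is set to the
#' REML-estimated variance ratio `sigma2e / sigma2beta` of the equivalent
#' random-marker-effect mixed model.
#'
#' @param x complete numeric line(record)-by-marker matrix.
#' @param y phenotype vector.
#' @param covariates optional design matrix from [env_design_matrix()]
#'   (defaults to an intercept).
#' @param lambda fixed ridge penalty, or `NULL` for REML.
#' @return a `gs_fit`.
#' @export
fit_rr_blup <- function(x, y, covariates = NULL, lambda = NULL) {
  Z <- covariates %||% matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  check_xy(x, y, Z)
  n <- nrow(x); p <- ncol(x)
  reml <- NULL
  if (is.null(lambda)) {
    reml <- reml_delta(tcrossprod(x), y, Z)
    lambda <- reml$delta
  }
  if (p < n || lambda == 0) {
    # primal joint normal equations (exact at lambda = 0 when full rank)
    A <- rbind(cbind(crossprod(Z), crossprod(Z, x)),
               cbind(crossprod(x, Z), crossprod(x) + diag(lambda, p)))
    b <- c(crossprod(Z, y), crossprod(x, y))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("normal equations singular (lambda = 0 with collinear markers?)"))
    gamma <- sol[seq_len(ncol(Z))]
    beta <- sol[-seq_len(ncol(Z))]
  } else {
    ks <- kernel_blup_solve(tcrossprod(x), y, Z, lambda)
    gamma <- ks$gamma
    beta <- as.vector(crossprod(x, ks$alpha))
  }
  new_gs_fit("rr_blup", gamma = setNames(gamma, colnames(Z)),
             beta = setNames(beta, colnames(x)), marker_ids = colnames(x),
             lambda = lambda, reml = reml)
}

#' Bayesian whole-genome regression (BL / BayesA / BayesB)
#'
#' Gibbs sampler with the classical conditional updates. Bayesian LASSO
#' places a double-exponential prior on marker effects via per-marker
#' exponential-mixture variances; BayesA uses per-marker scaled
#' inverse-chi-square variances (scaled-t marginal); BayesB adds a point
#' mass at zero with probability `pi`. Marker effects are posterior
#' means over the kept sweeps; runs are exactly repeatable given `seed`.
#'
#' @inheritParams fit_rr_blup
#' @param family `"bayes_lasso"`, `"bayes_a"` or `"bayes_b"`.
#' @param spec a [model_spec()] of the matching family (or `NULL` for
#'   defaults); its `hyperparams` control MCMC length, the prior scale
#'   (via `R2` or explicit `S`/`lambda2`), `pi`, and whether `sigma2e`
#'   is sampled or held fixed.
#' @return a `gs_fit` with posterior-mean effects and MCMC diagnostics
#'   (split-chain R-hat of the residual-variance and intercept traces;
#'   values above 1.1 are recorded as a convergence flag, not an error).
#' @export
fit_bayes <- function(x, y, covariates = NULL,
                      family = c("bayes_lasso", "bayes_a", "bayes_b"),
                      spec = NULL) {
  family <- match.arg(family)
  Z <- covariates %||% matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  check_xy(x, y, Z)
  spec <- spec %||% model_spec(family)
  if (spec$family != family) stop("spec family mismatch")
  hp <- spec$hyperparams
  vy <- max(var(y), 1e-8) # floor guards the zero-variance phenotype case
  msx <- sum(apply(x, 2, var))
  if (msx <= 0) msx <- 1
  R2 <- hp$R2
  nu <- hp$nu %||% 4
  S <- hp$S
  if (is.null(S)) {
    S <- vy * R2 / msx * (nu + 2) / nu
    if (family == "bayes_b") S <- S / max(1 - hp$pi, 0.01)
  }
  lambda2 <- hp$lambda2 %||% (2 * (1 - R2) * msx / R2)
  sample_sigma2e <- is.null(hp$sigma2e)
  sigma2e0 <- hp$sigma2e %||% ((1 - R2) * vy)
  nue <- 5; Se <- (1 - R2) * vy * (nue + 2) / nue
  set.seed(spec$seed)
  res <- .gibbs_wgr(x, y, Z,
                    family = match(family, c("bayes_lasso", "bayes_a",
                                             "bayes_b")) - 1L,
                    niter = as.integer(hp$iters),
                    burnin = as.integer(hp$burnin),
                    thin = as.integer(hp$thin),
                    pi_zero = if (family == "bayes_b") hp$pi else 0,
                    nu_beta = nu, S_beta = S,
                    lambda2_init = lambda2,
                    sample_lambda = isTRUE(hp$sample_lambda %||% FALSE) &&
                      family == "bayes_lasso",
                    lambda_shape = 1.1, lambda_rate = 0.1 / lambda2,
                    sigma2e_init = sigma2e0,
                    sample_sigma2e = sample_sigma2e,
                    nu_e = nue, S_e = Se,
                    keep_samples = isTRUE(hp$keep_samples))
  diag_ <- list(
    rhat_sigma2e = split_rhat(res$sigma2e_chain),
    rhat_mu = split_rhat(res$mu_chain),
    n_kept = res$n_kept,
    sigma2e_mean = mean(res$sigma2e_chain))
  diag_$converged <- is.na(diag_$rhat_sigma2e) || diag_$rhat_sigma2e < 1.1
  new_gs_fit(family, gamma = setNames(res$gamma, colnames(Z)),
             beta = setNames(as.vector(res$beta), colnames(x)),
             marker_ids = colnames(x), diagnostics = diag_,
             incl_prob = setNames(as.vector(res$incl_prob), colnames(x)),
             samples = res$beta_samples)
}

#' Split-chain R-hat (potential scale reduction) of a single trace
#' @param chain numeric vector of MCMC draws.
#' @export
split_rhat <- function(chain) {
  m <- length(chain) %/% 2
  if (m < 4) return(NA_real_)
  halves <- list(chain[seq_len(m)], chain[m + seq_len(m)])
  W <- mean(vapply(halves, var, 0))
  B <- m * var(vapply(halves, mean, 0))
  if (W <= 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Reproducing-kernel Hilbert-space regression
#'
#' Kernel BLUP with the Gaussian kernel
#' `K_ij = exp(-(D_ij / theta)^2)` on the Euclidean marker distance
#' `D_ij` between lines. Fixed effects are profiled out by GLS; the
#' ridge level is the REML variance ratio unless `lambda` is fixed.
#' `theta` is chosen from `theta_grid * median(D)` by inner
#' cross-validation unless given. `kernel = "linear"` uses `K = X X'`,
#' making the fit the exact dual of [fit_rr_blup()].
#'
#' @inheritParams fit_rr_blup
#' @param spec a [model_spec()] for family `rkhs` (or `NULL`).
#' @return a `gs_fit` holding the dual coefficients and kernel
#'   parameters.
#' @export
fit_rkhs <- function(x, y, covariates = NULL, spec = NULL) {
  Z <- covariates %||% matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  check_xy(x, y, Z)
  spec <- spec %||% model_spec("rkhs")
  hp <- spec$hyperparams
  kernel <- hp$kernel %||% "gaussian"
  theta <- hp$theta
  if (kernel == "linear") {
    K <- tcrossprod(x); theta <- NA_real_
  } else {
    D <- as.matrix(dist(x))
    med <- median(D[upper.tri(D)])
    if (is.null(theta)) {
      grid <- hp$theta_grid * med
      theta <- if (length(grid) == 1) grid else
        select_theta_cv(D, y, Z, grid, k = hp$inner_k %||% 5L,
                        lambda = hp$lambda, seed = spec$seed)
    }
    if (theta <= 0) stop("theta must be positive")
    K <- exp(-(D / theta)^2)
  }
  lambda <- hp$lambda %||% reml_delta(K, y, Z)$delta
  ks <- kernel_blup_solve(K, y, Z, lambda)
  new_gs_fit("rkhs", gamma = setNames(ks$gamma, colnames(Z)),
             alpha = ks$alpha, marker_ids = colnames(x),
             x_train = x, kernel = kernel, theta = theta, lambda = lambda)
}

select_theta_cv <- function(D, y, Z, grid, k, lambda, seed) {
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  mse <- vapply(grid, function(th) {
    K <- exp(-(D / th)^2)
    err <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      lam <- lambda %||%
        tryCatch(reml_delta(K[tr, tr], y[tr], Z[tr, , drop = FALSE])$delta,
                 error = function(e) 1)
      ks <- kernel_blup_solve(K[tr, tr], y[tr], Z[tr, , drop = FALSE], lam)
      pred <- Z[!tr, , drop = FALSE] %*% ks$gamma +
        K[!tr, tr, drop = FALSE] %*% ks$alpha
      err <- err + sum((y[!tr] - pred)^2)
    }
    err
  }, 0)
  grid[which.min(mse)]
}

#' Epsilon-insensitive support vector regression
#'
#' Fits `e1071::svm` on phenotypes residualised against environment
#' means (SVR has no native fixed-effect notion); only residuals larger
#' than the tube half-width epsilon are penalised. Cost, epsilon and
#' (for the Gaussian kernel) the kernel width are tuned by grid search
#' over inner cross-validation; the width grid is centred on the
#' median-pairwise-distance heuristic.
#'
#' @inheritParams fit_rr_blup
#' @param env optional character/factor of environment labels per
#'   record; their means are removed before fitting and added back at
#'   prediction.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param spec a [model_spec()] for family `svr_linear`/`svr_gaussian`.
#' @return a `gs_fit` wrapping the fitted SVM.
#' @export
fit_svr <- function(x, y, env = NULL, kernel = c("linear", "gaussian"),
                    spec = NULL) {
  kernel <- match.arg(kernel)
  check_xy(x, y, NULL)
  spec <- spec %||% model_spec(paste0("svr_", kernel))
  hp <- spec$hyperparams
  if (!length(hp$cost_grid) || !length(hp$epsilon_grid))
    stop("empty hyperparameter grid")
  rs <- residualize_env(y, env)
  gammas <- NA_real_
  if (kernel == "gaussian") {
    D <- dist(x)
    med <- median(as.vector(D))
    gammas <- 1 / (med * (hp$width_factors %||% 1))^2
  }
  grid <- expand.grid(cost = hp$cost_grid, epsilon = hp$epsilon_grid,
                      gamma = gammas)
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    k <- hp$inner_k %||% 5L
    set.seed(spec$seed)
    fold <- sample(rep_len(seq_len(k), length(y)))
    mse <- vapply(seq_len(nrow(grid)), function(i) {
      err <- 0
      for (f in seq_len(k)) {
        tr <- fold != f
        m <- svm_call(x[tr, , drop = FALSE], rs$resid[tr], kernel,
                      grid$cost[i], grid$epsilon[i], grid$gamma[i])
        err <- err + sum((rs$resid[!tr] -
                            predict(m, x[!tr, , drop = FALSE]))^2)
      }
      err
    }, 0)
    best <- grid[which.min(mse), ]
  }
  model <- svm_call(x, rs$resid, kernel, best$cost, best$epsilon, best$gamma)
  new_gs_fit(paste0("svr_", kernel), marker_ids = colnames(x),
             svm = model, env_means = rs$means, grand_mean = rs$grand,
             tuned = as.list(best))
}

svm_call <- function(x, y, kernel, cost, epsilon, gamma) {
  # fitted = FALSE: a response entirely inside the epsilon tube needs no
  # support vectors, and e1071 cannot evaluate fitted values then
  if (kernel == "linear")
    e1071::svm(x = x, y = y, type = "eps-regression", kernel = "linear",
               cost = cost, epsilon = epsilon, scale = FALSE,
               fitted = FALSE)
  else
    e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE,
               fitted = FALSE)
}

residualize_env <- function(y, env) {
  grand <- mean(y)
  if (is.null(env)) return(list(resid = y - grand, means = NULL,
                                grand = grand))
  env <- as.character(env)
  means <- tapply(y, env, mean)
  list(resid = y - means[env], means = means, grand = grand)
}

#' Random-forest regression on markers
#'
#' Regression forest (via `ranger`) on environment-residualised
#' phenotypes: bootstrap per tree, `mtry = round(p/3)` candidate markers
#' per split, variance-reduction splitting, minimum node size 5. The
#' out-of-bag MSE and per-marker permutation importance (mean OOB error
#' increase under marker permutation) are retained; permutation rather
#' than impurity importance is used throughout the selection stage since
#' it is less distorted by correlated markers.
#'
#' @inheritParams fit_svr
#' @param spec a [model_spec()] for family `random_forest`.
#' @param importance compute permutation importance (default `TRUE`).
#' @return a `gs_fit` with `oob_mse` and `importance`.
#' @export
fit_rf <- function(x, y, env = NULL, spec = NULL, importance = TRUE) {
  check_xy(x, y, NULL)
  if (length(y) < 10) stop("random forest needs n >= 10")
  spec <- spec %||% model_spec("random_forest")
  hp <- spec$hyperparams
  rs <- residualize_env(y, env)
  p <- ncol(x)
  mtry <- max(1L, as.integer(round(p * (hp$mtry_fraction %||% (1 / 3)))))
  model <- ranger::ranger(
    x = x, y = rs$resid,
    num.trees = as.integer(hp$num_trees %||% 1000L), mtry = mtry,
    min.node.size = as.integer(hp$min_node_size %||% 5L),
    importance = if (importance) "permutation" else "none",
    seed = spec$seed, num.threads = 1L)
  new_gs_fit("random_forest", marker_ids = colnames(x), rf = model,
             env_means = rs$means, grand_mean = rs$grand,
             oob_mse = model$prediction.error, mtry = mtry,
             importance = if (importance) model$variable.importance else NULL)
}

# ---- the common fit object -------------------------------------------------

new_gs_fit <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("<gs_fit:%s> %d markers\n", x$family, length(x$marker_ids)))
  invisible(x)
}

#' Predict phenotypes (or genetic values) from a fitted model
#'
#' Deterministic given the fit. Linear families return
#' `Z gamma + X beta` exactly; RKHS evaluates the kernel against the
#' training lines; SVR/RF add back the training environment mean (the
#' grand mean when `env` is `NULL` or unseen).
#'
#' @param object a `gs_fit`.
#' @param x_new numeric matrix whose marker columns match training.
#' @param covariates matrix for linear/kernel families (same columns as
#'   at fit time; `NULL` uses the intercept only).
#' @param env environment labels for SVR/RF predictions.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gs_fit <- function(object, x_new, covariates = NULL, env = NULL,
                           ...) {
  miss <- setdiff(object$marker_ids, colnames(x_new))
  if (length(miss))
    stop("marker(s) missing from x_new: ", paste(miss, collapse = ", "))
  x_new <- x_new[, object$marker_ids, drop = FALSE]
  n <- nrow(x_new)
  if (!is.null(object$beta)) {
    fixed <- if (is.null(covariates)) rep(object$gamma[1], n)
             else as.vector(covariates %*% object$gamma)
    return(fixed + as.vector(x_new %*% object$beta))
  }
  if (object$family == "rkhs") {
    K_new <- if (object$kernel == "linear") tcrossprod(x_new, object$x_train)
      else {
        D <- cross_dist(x_new, object$x_train)
        exp(-(D / object$theta)^2)
      }
    fixed <- if (is.null(covariates)) rep(object$gamma[1], n)
             else as.vector(covariates %*% object$gamma)
    return(fixed + as.vector(K_new %*% object$alpha))
  }
  offset <- if (is.null(env) || is.null(object$env_means)) {
    if (is.null(object$env_means)) object$grand_mean
    else mean(object$env_means)
  } else {
    m <- object$env_means[as.character(env)]
    m[is.na(m)] <- object$grand_mean
    m
  }
  if (!is.null(object$svm)) {
    if (object$svm$tot.nSV == 0) # all residuals inside the tube
      return(rep(-object$svm$rho, n) + offset)
    return(as.vector(predict(object$svm, x_new)) + offset)
  }
  if (!is.null(object$rf))
    return(predict(object$rf, x_new, num.threads = 1L)$predictions + offset)
  stop("unknown fit type")
}

cross_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit any family through the uniform contract
#'
#' Dispatches to the family-specific fitting routine. Linear/kernel
#' families receive the covariate matrix; SVR and random forest receive
#' the environment labels for residualisation.
#'
#' @param spec a [model_spec()].
#' @param x,y training markers and phenotypes.
#' @param covariates covariate matrix (linear/kernel families).
#' @param env environment labels (SVR/RF).
#' @return a `gs_fit`.
#' @export
fit_model <- function(spec, x, y, covariates = NULL, env = NULL) {
  switch(spec$family,
    rr_blup = fit_rr_blup(x, y, covariates,
                          lambda = spec$hyperparams$lambda),
    bayes_lasso = ,
    bayes_a = ,
    bayes_b = fit_bayes(x, y, covariates, family = spec$family, spec = spec),
    rkhs = fit_rkhs(x, y, covariates, spec = spec),
    svr_linear = fit_svr(x, y, env, kernel = "linear", spec = spec),
    svr_gaussian = fit_svr(x, y, env, kernel = "gaussian", spec = spec),
    random_forest = fit_rf(x, y, env, spec = spec,
                           importance = isTRUE(spec$hyperparams$importance)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
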