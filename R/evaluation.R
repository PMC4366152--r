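# Repeated k-fold cross-validation with fold plans shared across models
# (all models see exactly the same train/test splits), Pearson-correlation
# accuracy, model-comparison tables and breeding-value estimation.

#' Build a repeated k-fold plan on lines
#'
#' Folds are drawn on lines, not line-by-environment records, so a line
#' is never split across train and test. Fold sizes differ by at most
#' one. The plan carries a content hash so results can assert they
#' shared folds.
#'
#' @param line_ids character vector of lines.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed; the same seed reproduces the same plan.
#' @return a `fold_plan` with an `assignments` matrix (lines x repeats).
#' @export
make_folds <- function(line_ids, k = 10, repeats = 10, seed = 1L) {
  n <- length(line_ids)
  if (k > n) stop("k must not exceed the number of lines")
  if (anyDuplicated(line_ids)) stop("line_ids must be unique")
  set.seed(seed)
  assignments <- vapply(seq_len(repeats),
                        function(r) sample(rep_len(seq_len(k), n)),
                        integer(n))
  dimnames(assignments) <- list(line_ids, paste0("rep", seq_len(repeats)))
  plan <- list(k = as.integer(k), repeats = as.integer(repeats),
               assignments = assignments, seed = as.integer(seed))
  plan$hash <- rlang::hash(plan[c("k", "repeats", "assignments")])
  structure(plan, class = "fold_plan")
}

#' Cross-validate one model family over environments
#'
#' For every environment and repeat, out-of-fold predictions are
#' assembled over all k folds and one Pearson correlation between
#' observed and predicted phenotype is computed per repeat (pooled over
#' folds; `pooling = "per_fold"` averages fold-wise correlations
#' instead). Folds with fewer than 3 test observations in an environment
#' are skipped with a logged warning.
#'
#' @param spec a [model_spec()].
#' @param panel a `genotype_panel` from [qc_filter()].
#' @param pheno a [phenotype_table()].
#' @param plan a [make_folds()] plan covering all phenotyped panel lines.
#' @param environments optional character vector of env labels to
#'   evaluate (default: all in `pheno`).
#' @param pooling accuracy pooling rule per repeat.
#' @return a `cv_result` data frame (family, env, repeat, accuracy) with
#'   the fold-plan hash attached.
#' @export
cross_validate <- function(spec, panel, pheno, plan, environments = NULL,
                           pooling = c("per_repeat", "per_fold")) {
  pooling <- match.arg(pooling)
  envs <- environments %||% unique(pheno$env)
  lines_panel <- rownames(panel$coded)
  out <- list(); skipped <- 0L
  for (e in envs) {
    rec <- pheno[pheno$env == e & !is.na(pheno$ft_days), ]
    lid <- intersect(lines_panel, rec$line_id)
    miss_plan <- setdiff(lid, rownames(plan$assignments))
    if (length(miss_plan))
      stop("fold plan does not cover line(s): ",
           paste(head(miss_plan, 5), collapse = ", "))
    y <- setNames(rec$ft_days[match(lid, rec$line_id)], lid)
    x <- panel$coded[lid, , drop = FALSE]
    for (r in seq_len(plan$repeats)) {
      fold <- plan$assignments[lid, r]
      pred <- setNames(rep(NA_real_, length(lid)), lid)
      rs <- numeric(0)
      for (f in seq_len(plan$k)) {
        test <- lid[fold == f]
        if (length(test) < 3) { skipped <- skipped + 1L; next }
        train <- lid[fold != f]
        spec_f <- spec
        spec_f$seed <- spec$seed + 977L * r + f
        fit <- fit_model(spec_f, x[train, , drop = FALSE], y[train])
        pred[test] <- predict(fit, x[test, , drop = FALSE])
        if (pooling == "per_fold" && sd(y[test]) > 0)
          rs <- c(rs, cor(y[test], pred[test]))
      }
      ok <- !is.na(pred)
      acc <- if (pooling == "per_repeat") {
        if (sum(ok) >= 3) cor(y[ok], pred[ok]) else NA_real_
      } else mean(rs)
      out[[length(out) + 1L]] <- data.frame(
        family = spec$family, env = e, rep = r, accuracy = acc)
    }
  }
  res <- do.call(rbind, out)
  if (skipped > 0)
    warning(sprintf("%d fold(s) skipped (fewer than 3 test observations)",
                    skipped))
  structure(res, class = c("cv_result", "data.frame"),
            plan_hash = plan$hash, family = spec$family,
            skipped_folds = skipped)
}

#' Summarise a cv_result per (family, environment)
#' @param result a `cv_result`.
#' @return data frame with mean and sd accuracy.
#' @export
summarize_cv <- function(result) {
  agg <- aggregate(accuracy ~ family + env, data = result,
                   FUN = function(z) c(mean = mean(z, na.rm = TRUE),
                                       sd = sd(z)))
  data.frame(family = agg$family, env = agg$env,
             mean = agg$accuracy[, "mean"], sd = agg$accuracy[, "sd"])
}

#' Model-comparison table over shared folds
#'
#' Builds the environments-by-families matrix of mean CV accuracy, flags
#' the best family per environment (ties broken by family name order),
#' and appends a per-family average row. All inputs must share the same
#' fold plan.
#'
#' @param results list of `cv_result` objects (one per family).
#' @return a `gs_comparison`: list with `table` (wide data frame),
#'   `best` (named character, per environment), and `summary` (long form
#'   with sd for error bars).
#' @export
compare_models <- function(results) {
  hashes <- vapply(results, function(r) attr(r, "plan_hash"), "")
  if (length(unique(hashes)) != 1)
    stop("cv results do not share a fold plan")
  long <- do.call(rbind, lapply(results, function(r) summarize_cv(r)))
  envs <- unique(long$env)
  fams <- sort(unique(long$family))
  tab <- matrix(NA_real_, length(envs), length(fams),
                dimnames = list(envs, fams))
  for (i in seq_len(nrow(long)))
    tab[long$env[i], long$family[i]] <- long$mean[i]
  best <- apply(tab, 1, function(z) colnames(tab)[which.max(z)])
  wide <- data.frame(env = c(envs, "Average"),
                     rbind(tab, colMeans(tab)), check.names = FALSE)
  rownames(wide) <- NULL
  structure(list(table = wide, best = best, summary = long,
                 plan_hash = hashes[1]),
            class = "gs_comparison")
}

#' @export
print.gs_comparison <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 3)
  print(tab)
  invisible(x)
}

#' Estimate genomic breeding values
#'
#' Two-stage GEBV estimation: line values are first adjusted for
#' environment covariates (site-year combinations for the overall GEBV;
#' year within site for per-region EBVs) by fixed-effect regression,
#' then shrunk by kernel BLUP with a Gaussian-kernel RKHS model (the
#' package default) at the REML variance ratio. GEBVs are centred to
#' mean zero.
#'
#' @param panel a `genotype_panel`.
#' @param pheno a [phenotype_table()].
#' @param scope `"overall"` or `"per_region"`.
#' @param spec model for the genetic term; defaults to
#'   `model_spec("rkhs")`.
#' @return data frame (`line_id`, `scope`, `gebv`) of class
#'   `gebv_table`; for `per_region`, one block per site with data.
#' @export
estimate_gebv <- function(panel, pheno, scope = c("overall", "per_region"),
                          spec = NULL) {
  scope <- match.arg(scope)
  spec <- spec %||% model_spec("rkhs")
  lines_panel <- rownames(panel$coded)
  rec <- pheno[!is.na(pheno$ft_days) & pheno$line_id %in% lines_panel, ]
  if (scope == "overall") {
    if (length(unique(rec$env)) < 2)
      stop("overall GEBV needs >= 2 environments")
    blocks <- list(overall = rec)
  } else {
    blocks <- split(rec, rec$site)
    empty <- setdiff(SITE_LEVELS, names(blocks))
    if (length(empty))
      warning("region(s) without data skipped: ",
              paste(empty, collapse = ", "))
  }
  out <- lapply(names(blocks), function(b) {
    d <- blocks[[b]]
    covar <- if (scope == "overall") d$env else d$year
    adj <- adjusted_line_means(d$ft_days, d$line_id, covar)
    x <- panel$coded[names(adj), , drop = FALSE]
    fit <- fit_rkhs(x, adj, spec = spec)
    g <- predict(fit, x) - fit$gamma[1]
    data.frame(line_id = names(adj), scope = b, gebv = g - mean(g))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("gebv_table", "data.frame"))
}

# Fixed-effect adjustment: line means after removing covariate effects
# (ordinary least squares on line + covariate dummies; exact for
# balanced designs and unbiased for unbalanced ones).
adjusted_line_means <- function(y, line, covar) {
  line <- factor(line)
  if (length(unique(covar)) < 2) {
    m <- tapply(y, line, mean)
    return(m - mean(m) + mean(y))
  }
  covar <- factor(covar)
  fit <- lm(y ~ 0 + line + covar)
  cf <- coef(fit)[paste0("line", levels(line))]
  setNames(as.vector(cf), levels(line))
}
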