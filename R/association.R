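# Selection of trait-associated SNPs: random-forest permutation
# importance of tag SNPs against region breeding values (averaged over
# many forests), recursive 5%-step inclusion choosing the minimal-MSE
# set, expansion of selected tags to the SNPs they represent, and
# allelic-direction consistency across environments.

#' Rank tag SNPs by averaged random-forest importance
#'
#' Fits `n_runs` independently seeded regression forests of the tag
#' markers on the breeding values and averages the per-marker
#' permutation importances. Ranks are descending with deterministic
#' ties broken by marker id.
#'
#' @param x numeric line-by-tag matrix.
#' @param ebv named breeding-value vector (names = lines, all present
#'   in `x`).
#' @param n_runs forests to average.
#' @param spec a [model_spec()] for `random_forest` (or `NULL`).
#' @return data frame (`marker_id`, `importance_mean`, `rank`) sorted by
#'   rank.
#' @export
rank_importance <- function(x, ebv, n_runs = 20, spec = NULL) {
  if (ncol(x) < 2) stop("need >= 2 tag markers")
  spec <- spec %||% model_spec("random_forest")
  miss <- setdiff(names(ebv), rownames(x))
  if (length(miss)) stop("EBV line(s) missing from x: ",
                         paste(head(miss, 5), collapse = ", "))
  # canonical column order so the ranking is invariant to input order
  x <- x[names(ebv), order(colnames(x)), drop = FALSE]
  imp <- rep(0, ncol(x))
  for (run in seq_len(n_runs)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + 7919L * run
    fit <- fit_rf(x, ebv, spec = spec_r, importance = TRUE)
    imp <- imp + fit$importance[colnames(x)]
  }
  imp <- imp / n_runs
  ord <- order(-imp, colnames(x))
  data.frame(marker_id = colnames(x)[ord], importance_mean = imp[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Recursive 5%-step inclusion to the minimal-MSE tag set
#'
#' Starting from the top 5% of ranked tags and adding 5% more per step,
#' fits a forest at each inclusion fraction and records its out-of-bag
#' MSE, averaged over `n_reps` repetitions; the fraction minimising the
#' mean MSE is selected (ties go to the smaller fraction).
#'
#' @param ranking output of [rank_importance()].
#' @param x,ebv as in [rank_importance()].
#' @param step inclusion step in `(0, 0.5]`.
#' @param n_reps forests averaged per fraction.
#' @param spec a [model_spec()] for `random_forest` (or `NULL`).
#' @return list with `inclusion_curve` (data frame `fraction`,
#'   `n_tags`, `mean_mse`), `selected_fraction` and `selected_tags`.
#' @export
recursive_inclusion <- function(ranking, x, ebv, step = 0.05, n_reps = 20,
                                spec = NULL) {
  if (step <= 0 || step > 0.5) stop("step must be in (0, 0.5]")
  spec <- spec %||% model_spec("random_forest")
  x <- x[names(ebv), ranking$marker_id, drop = FALSE]
  p <- ncol(x)
  fracs <- round(seq(step, 1, by = step), 10)
  if (fracs[length(fracs)] < 1) fracs <- c(fracs, 1)
  sizes <- pmin(ceiling(fracs * p), p)
  mse <- vapply(seq_along(fracs), function(i) {
    xi <- x[, seq_len(sizes[i]), drop = FALSE]
    if (ncol(xi) < 1) return(NA_real_)
    mean(vapply(seq_len(n_reps), function(rep) {
      spec_r <- spec
      spec_r$seed <- spec$seed + 104729L * i + rep
      fit_rf(xi, ebv, spec = spec_r, importance = FALSE)$oob_mse
    }, 0))
  }, 0)
  best <- which.min(mse) # first minimum = smallest fraction on ties
  list(inclusion_curve = data.frame(fraction = fracs, n_tags = sizes,
                                    mean_mse = mse),
       selected_fraction = fracs[best],
       selected_tags = ranking$marker_id[seq_len(sizes[best])])
}

#' Expand selected tags to the SNPs they represent
#'
#' @param selected_tags tag marker ids.
#' @param clustering a `tag_clustering` from [ld_prune()].
#' @return character vector: union of the clusters of the selected tags
#'   (always a superset of the tags themselves).
#' @export
expand_tags <- function(selected_tags, clustering) {
  unknown <- setdiff(selected_tags, clustering$tags)
  if (length(unknown)) stop("unknown tag(s): ",
                            paste(unknown, collapse = ", "))
  names(clustering$cluster_of)[clustering$cluster_of %in% selected_tags]
}

#' Full per-region SNP selection
#'
#' Composes [rank_importance()], [recursive_inclusion()] and
#' [expand_tags()] against one region's breeding values.
#'
#' @param panel a `genotype_panel`.
#' @param clustering a `tag_clustering`.
#' @param ebv named region EBV vector.
#' @param region label stored in the result.
#' @param n_runs,n_reps,step see the stage functions.
#' @param spec forest settings.
#' @return a `selection_result` list.
#' @export
select_associated_snps <- function(panel, clustering, ebv, region = NA,
                                   n_runs = 20, n_reps = 20, step = 0.05,
                                   spec = NULL) {
  x <- panel$coded[, clustering$tags, drop = FALSE]
  ranking <- rank_importance(x, ebv, n_runs = n_runs, spec = spec)
  inc <- recursive_inclusion(ranking, x, ebv, step = step, n_reps = n_reps,
                             spec = spec)
  structure(list(region = region, importance = ranking,
                 inclusion_curve = inc$inclusion_curve,
                 selected_fraction = inc$selected_fraction,
                 selected_tags = inc$selected_tags,
                 expanded_snps = expand_tags(inc$selected_tags, clustering)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result:%s> %d tags -> %d SNPs (fraction %.2f)\n",
              x$region, length(x$selected_tags), length(x$expanded_snps),
              x$selected_fraction))
  invisible(x)
}

#' Cross-region overlap of expanded SNP sets
#'
#' @param results named list of `selection_result`s (one per region).
#' @return list with per-region counts, the union/intersection sizes and
#'   per-SNP region membership (a Venn-style summary).
#' @export
region_overlap <- function(results) {
  sets <- lapply(results, function(r) r$expanded_snps)
  all_snps <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_snps %in% s,
                   logical(length(all_snps)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  n_regions <- rowSums(member)
  list(per_region = lengths(sets), union = length(all_snps),
       shared_all = sum(n_regions == length(sets)),
       specific = sum(n_regions == 1),
       membership = data.frame(snp_id = all_snps, member,
                               n_regions = n_regions, row.names = NULL))
}

#' Welch's two-sample t-test (closed form)
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p` (two-sided). Zero-variance inputs
#'   with equal means give `t = 0, p = 1`.
#' @export
welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  dm <- mean(a) - mean(b)
  if (se2 <= 0) {
    if (abs(dm) < .Machine$double.eps^0.5) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(dm) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Allelic-direction analysis across environments
#'
#' For every SNP and environment, compares mean flowering time of the A
#' and B genotype classes by Welch's t-test (unequal variances; DH
#' classes can be unbalanced) and records the early allele (the class
#' with the smaller mean). A SNP is direction-consistent when the early
#' allele is identical across all environments where the test is
#' significant at `alpha`; SNPs significant nowhere form a separate
#' `no_significant_env` category rather than being counted consistent.
#'
#' @param snps SNP ids to examine.
#' @param geno a post-QC [genotype_table()] (raw A/B calls).
#' @param pheno a [phenotype_table()].
#' @param alpha significance level per (SNP, environment) test.
#' @return a `direction_report`: list with `per_env` (snp, env, class
#'   means, t, p, early allele) and `per_snp` (early allele set,
#'   significant envs, consistency category).
#' @export
allele_direction <- function(snps, geno, pheno, alpha = 0.05) {
  miss <- setdiff(snps, colnames(geno))
  if (length(miss)) stop("SNP(s) absent from genotypes: ",
                         paste(head(miss, 5), collapse = ", "))
  envs <- unique(pheno$env)
  rows <- vector("list", length(snps) * length(envs)); ri <- 0L
  for (s in snps) {
    gcall <- geno[, s]
    for (e in envs) {
      rec <- pheno[pheno$env == e & !is.na(pheno$ft_days), ]
      g <- gcall[rec$line_id]
      ya <- rec$ft_days[!is.na(g) & g == "A"]
      yb <- rec$ft_days[!is.na(g) & g == "B"]
      if (length(ya) < 2 || length(yb) < 2) next # class absent: skip env
      wt <- welch_t(ya, yb)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        snp_id = s, env = e, mean_ft_A = mean(ya), mean_ft_B = mean(yb),
        n_A = length(ya), n_B = length(yb), t_stat = wt$t, p_value = wt$p,
        early_allele = if (wt$p >= 1 || mean(ya) == mean(yb)) NA_character_
                       else if (mean(ya) < mean(yb)) "A" else "B")
    }
  }
  per_env <- do.call(rbind, rows[seq_len(ri)])
  per_snp <- do.call(rbind, lapply(snps, function(s) {
    d <- per_env[per_env$snp_id == s, , drop = FALSE]
    sig <- d[!is.na(d$p_value) & d$p_value < alpha & !is.na(d$early_allele), ]
    category <- if (!nrow(sig)) "no_significant_env"
      else if (length(unique(sig$early_allele)) == 1) "consistent"
      else "inconsistent"
    data.frame(snp_id = s, n_env_tested = nrow(d), n_env_significant = nrow(sig),
               early_allele = if (category == "consistent")
                 sig$early_allele[1] else NA_character_,
               category = category,
               significant_envs = paste(sig$env, collapse = ","))
  }))
  structure(list(per_env = per_env, per_snp = per_snp, alpha = alpha),
            class = "direction_report")
}
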