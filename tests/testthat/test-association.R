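test_that("a planted QTL dominates averaged forest importance", {
  set.seed(41)
  X <- binary_X(150, 47, seed = 41, prefix = "t")
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    ebv <- setNames(X[, "t1"] * 1.0 + rnorm(150), rownames(X))
    rk <- rank_importance(X, ebv, n_runs = 5,
                          spec = model_spec("random_forest",
                                            num_trees = 200L, seed = s))
    rk$marker_id[1] == "t1"
  }, TRUE)
  expect_gte(sum(hits), 9)
  expect_error(rank_importance(X[, 1, drop = FALSE],
                               setNames(rnorm(150), rownames(X))),
               "2 tag")
})

test_that("importance ranking is invariant to tag column order", {
  X <- binary_X(100, 20, seed = 42, prefix = "t")
  ebv <- setNames(X[, 2] + rnorm(100, sd = 0.5), rownames(X))
  spec <- model_spec("random_forest", num_trees = 200L, seed = 7)
  r1 <- rank_importance(X, ebv, n_runs = 3, spec = spec)
  r2 <- rank_importance(X[, sample(20)], ebv, n_runs = 3, spec = spec)
  expect_equal(r1$marker_id, r2$marker_id)
})

test_that("shuffled EBVs produce no importance outliers", {
  X <- binary_X(120, 40, seed = 43, prefix = "t")
  set.seed(44)
  ebv <- setNames(sample(rnorm(120)), rownames(X))
  rk <- rank_importance(X, ebv, n_runs = 5,
                        spec = model_spec("random_forest",
                                          num_trees = 300L, seed = 3))
  thr <- quantile(rk$importance_mean, 0.95)
  iqr <- IQR(rk$importance_mean)
  expect_lt(max(rk$importance_mean) - thr, 5 * iqr + 1e-8)
})

test_that("recursive inclusion walks 5% steps and respects ties", {
  X <- binary_X(120, 47, seed = 45, prefix = "t")
  ebv <- setNames(X[, 1] + 0.8 * X[, 2] + rnorm(120, sd = 0.6),
                  rownames(X))
  rk <- rank_importance(X, ebv, n_runs = 3,
                        spec = model_spec("random_forest",
                                          num_trees = 150L, seed = 2))
  inc <- recursive_inclusion(rk, X, ebv, n_reps = 3,
                             spec = model_spec("random_forest",
                                               num_trees = 150L, seed = 2))
  expect_equal(inc$inclusion_curve$fraction, seq(0.05, 1, by = 0.05))
  expect_equal(inc$inclusion_curve$n_tags[1], 3L) # ceil(0.05 * 47)
  expect_equal(length(inc$selected_tags),
               inc$inclusion_curve$n_tags[
                 match(inc$selected_fraction, inc$inclusion_curve$fraction)])
  expect_error(recursive_inclusion(rk, X, ebv, step = 0.7), "step")
  # pure-noise EBV: the curve's MSE stays near Var(EBV)
  set.seed(46)
  ebv0 <- setNames(rnorm(120), rownames(X))
  rk0 <- rank_importance(X, ebv0, n_runs = 3,
                         spec = model_spec("random_forest",
                                           num_trees = 200L, seed = 5))
  inc0 <- recursive_inclusion(rk0, X, ebv0, n_reps = 3,
                              spec = model_spec("random_forest",
                                                num_trees = 200L, seed = 5))
  expect_lt(abs(min(inc0$inclusion_curve$mean_mse) - var(ebv0)),
            0.15 * var(ebv0))
})

test_that("tag expansion takes cluster unions with arithmetic identities", {
  cl <- structure(list(
    tags = c("t1", "t2", "t3"),
    cluster_of = c(setNames(rep("t1", 10), paste0("a", 1:10)),
                   setNames(rep("t2", 5), paste0("b", 1:5)),
                   t3 = "t3"),
    r2_to_tag = NULL), class = "tag_clustering")
  expect_equal(length(expand_tags(c("t1", "t2", "t3"), cl)), 16L)
  expect_equal(expand_tags("t3", cl), "t3") # singleton cluster
  expect_error(expand_tags("zzz", cl), "unknown tag")
  # region overlap obeys inclusion-exclusion
  mk <- function(snps) structure(list(expanded_snps = snps),
                                 class = "selection_result")
  ov <- region_overlap(list(north = mk(c("a1", "a2", "s")),
                            south = mk(c("a2", "s", "b1")),
                            east = mk(c("s"))))
  expect_equal(ov$union, 4L)
  expect_equal(ov$shared_all, 1L)
  expect_equal(ov$specific, 2L)
  expect_equal(sum(ov$membership$n_regions == 2), 1L)
})

test_that("Welch t matches the closed form and directions behave", {
  a <- c(10, 12, 11); b <- c(20, 22, 21)
  wt <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / (var(a)^2 / (9 * 2) + var(b)^2 / (9 * 2))
  expect_equal(wt$t, t_hand, tolerance = 1e-10)
  expect_equal(wt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # identical means with zero variance: t = 0, p = 1
  wt0 <- welch_t(c(5, 5), c(5, 5))
  expect_equal(wt0$t, 0); expect_equal(wt0$p, 1)
})

test_that("allelic directions are consistent in the noiseless limit and
           antisymmetric under label swap", {
  map <- marker_map(data.frame(marker_id = c("q1", "q2"),
                               chrom = c("A1", "A2"), pos_cM = 0))
  g <- simulate_dh_genotypes(map, 60, seed = 47)
  truth <- sim_truth(additive = data.frame(marker_id = c("q1", "q2"),
                                           effect = c(2, -1)),
                     env_means = default_environments(), h2 = 1)
  ph <- simulate_phenotypes(g, truth, seed = 48)$pheno
  rep1 <- allele_direction(c("q1", "q2"), g, ph)
  expect_equal(rep1$per_snp$category, c("consistent", "consistent"))
  expect_equal(rep1$per_snp$n_env_significant, c(10L, 10L))
  # positive effect: B allele (+1) flowers later, so A is early
  expect_equal(rep1$per_snp$early_allele, c("A", "B"))
  # swapping allele labels flips every early allele, keeps consistency
  gsw <- genotype_table(ifelse(unclass(g) == "A", "B", "A"))
  rep2 <- allele_direction(c("q1", "q2"), gsw, ph)
  expect_equal(rep2$per_snp$early_allele, c("B", "A"))
  expect_equal(rep2$per_snp$category, rep1$per_snp$category)
  expect_equal(rep2$per_env$p_value, rep1$per_env$p_value)
  # equal group means: no early allele, not significant
  g3 <- geno_from_rows(lapply(setNames(1:8, paste0("L", 1:8)),
                              function(i) if (i <= 4) "A" else "B"), "s1")
  ph3 <- phenotype_table(data.frame(line_id = paste0("L", 1:8),
                                    site = "north", year = 2003,
                                    ft_days = rep(c(99, 100, 101, 100), 2)))
  r3 <- allele_direction("s1", g3, ph3)
  expect_true(is.na(r3$per_env$early_allele))
  expect_equal(r3$per_snp$category, "no_significant_env")
})
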