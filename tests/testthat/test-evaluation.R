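test_that("fold plans are balanced, exhaustive and seed-deterministic", {
  ids <- sprintf("L%03d", 1:20)
  p <- make_folds(ids, k = 10, repeats = 3, seed = 1)
  sizes <- apply(p$assignments, 2, function(a) table(factor(a, 1:10)))
  expect_true(all(sizes == 2))
  # n = 182, k = 10: sizes 18 x 8 and 19 x 2
  p182 <- make_folds(sprintf("L%03d", 1:182), k = 10, repeats = 2, seed = 2)
  tab <- sort(as.vector(table(p182$assignments[, 1])))
  expect_equal(tab, c(rep(18, 8), rep(19, 2)))
  # determinism and hashing
  q <- make_folds(ids, k = 10, repeats = 3, seed = 1)
  expect_identical(p$assignments, q$assignments)
  expect_identical(p$hash, q$hash)
  expect_false(make_folds(ids, 10, 3, seed = 2)$hash == p$hash)
  expect_error(make_folds(ids[1:5], k = 10), "k must not exceed")
})

test_that("cross-validation accuracy is bounded by the oracle and null", {
  fx <- default_panel()
  panel <- fx$panel
  lines <- rownames(panel$coded)
  plan <- make_folds(lines, k = 10, repeats = 2, seed = 3)

  # an oracle predictor (truth leaked through a perfect marker score)
  gval <- fx$sim$truth$genetic_value[lines]
  oracle_pheno <- phenotype_table(data.frame(
    line_id = lines, site = "north", year = 2003, ft_days = 150 + gval))
  xo <- cbind(panel$coded, ".g" = gval)
  panel_o <- panel; panel_o$coded <- xo[, ".g", drop = FALSE]
  cv_o <- cross_validate(model_spec("rr_blup", lambda = 1e-8), panel_o,
                         oracle_pheno, plan)
  expect_true(all(cv_o$accuracy > 0.999))

  # independent-noise phenotypes: mean accuracy within 2 SE of zero.
  # each draw gets fresh noise — repeats on one fixed noise vector are
  # not independent and can sit far from zero for that realisation
  accs <- vapply(1:10, function(s) {
    set.seed(40 + s)
    noise_pheno <- phenotype_table(data.frame(
      line_id = lines, site = "north", year = 2003,
      ft_days = 150 + rnorm(length(lines))))
    plan1 <- make_folds(lines, k = 10, repeats = 1, seed = s)
    cv <- cross_validate(model_spec("rr_blup", lambda = 1), panel,
                         noise_pheno, plan1)
    mean(cv$accuracy)
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs)), 2 * se + 0.05)
})

test_that("rr_blup reaches the expected accuracy range at h2 = 0.6", {
  fx <- default_panel()
  plan <- make_folds(rownames(fx$panel$coded), k = 10, repeats = 2,
                     seed = 6)
  cv <- cross_validate(model_spec("rr_blup"), fx$panel, fx$pheno, plan,
                       environments = "S4")
  # theoretical ceiling sqrt(h2) ~ 0.77, with sampling slack
  expect_gt(mean(cv$accuracy), 0.45)
  expect_lt(mean(cv$accuracy), 0.85)
})

test_that("comparison tables are arithmetically self-consistent", {
  fx <- default_panel()
  plan <- make_folds(rownames(fx$panel$coded), k = 10, repeats = 2,
                     seed = 7)
  envs <- c("N3", "S4")
  r1 <- cross_validate(model_spec("rr_blup"), fx$panel, fx$pheno, plan,
                       environments = envs)
  cmp1 <- compare_models(list(r1))
  expect_equal(unname(cmp1$best), rep("rr_blup", 2))
  # a duplicated model ties; tie broken by family name order
  r2 <- r1; r2$family <- "aaa_copy"
  attr(r2, "plan_hash") <- attr(r1, "plan_hash")
  cmp2 <- compare_models(list(r1, r2))
  expect_equal(unname(cmp2$best), rep("aaa_copy", 2))
  # average row recomputes from the cells
  tab <- cmp2$table
  body <- tab[tab$env != "Average", -1]
  expect_equal(unlist(tab[tab$env == "Average", -1]),
               colMeans(body), tolerance = 1e-12, ignore_attr = TRUE)
  # mismatched fold plans are rejected
  r3 <- cross_validate(model_spec("rr_blup"), fx$panel, fx$pheno,
                       make_folds(rownames(fx$panel$coded), 10, 2, seed = 99),
                       environments = "N3")
  expect_error(compare_models(list(r1, r3)), "share a fold plan")
})

test_that("GEBVs absorb environment effects and recover genetic values", {
  fx <- default_panel()
  gebv <- estimate_gebv(fx$panel, fx$pheno, scope = "overall",
                        spec = model_spec("rkhs", theta_grid = 1))
  expect_equal(mean(gebv$gebv), 0, tolerance = 1e-10)
  truth <- fx$sim$truth$genetic_value[gebv$line_id]
  expect_gt(cor(gebv$gebv, truth), 0.7)
  # per-region EBVs exist for all three regions here
  pr <- estimate_gebv(fx$panel, fx$pheno, scope = "per_region",
                      spec = model_spec("rkhs", theta_grid = 1))
  expect_setequal(unique(pr$scope), c("north", "south", "east"))
  expect_gt(cor(pr$gebv[pr$scope == "north"], truth), 0.6)
})

test_that("GEBV variance collapses when there is no genetic signal", {
  map <- make_marker_map(n_markers = 150, n_chrom = 5, seed = 8)
  g <- simulate_dh_genotypes(map, 100, seed = 9)
  ratios <- vapply(1:5, function(s) {
    tr <- sim_truth(additive = data.frame(marker_id = "q", effect = 1e-6),
                    env_means = default_environments(), residual_sd = 1)
    tr$additive$marker_id <- map$marker_id[1]
    sim <- simulate_phenotypes(g, tr, seed = 10 + s)
    panel <- qc_filter(g)
    gb <- estimate_gebv(panel, sim$pheno, "overall",
                        spec = model_spec("rkhs", theta_grid = 1))
    var(gb$gebv) / var(sim$pheno$ft_days)
  }, 0)
  expect_lt(mean(ratios), 0.1)
})
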