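test_that("SNP-to-gene mapping follows the 1 kb window convention", {
  genes <- gene_table(data.frame(
    chrom = "A1", start = c(5500, 6100), end = c(6000, 7000),
    gene_id = c("g_near", "g_far")))
  map <- marker_map(data.frame(marker_id = "s1", chrom = "A1", pos_cM = 1,
                               pos_bp = 5000L))
  hits <- snps_to_genes(map, genes, window_bp = 1000)
  expect_equal(hits$s1, "g_near") # gap 500 <= 1000; gap 1100 > 1000
  # missing physical position: skipped with a warning
  map2 <- marker_map(data.frame(marker_id = c("s1", "s2"), chrom = "A1",
                                pos_cM = 1:2, pos_bp = c(5000L, NA)))
  expect_warning(h2 <- snps_to_genes(map2, genes), "skipped")
  expect_equal(names(h2), "s1")
})

test_that("window mapping agrees with a brute-force all-pairs scan", {
  for (s in 1:20) {
    set.seed(500 + s)
    genes <- gene_table(data.frame(
      chrom = sample(c("A1", "A2"), 15, TRUE),
      start = st <- sample(0:20000, 15), end = st + sample(100:3000, 15),
      gene_id = paste0("g", 1:15)))
    map <- marker_map(data.frame(
      marker_id = paste0("s", 1:10), chrom = sample(c("A1", "A2"), 10, TRUE),
      pos_cM = 1:10, pos_bp = sample(0:20000, 10)))
    hits <- snps_to_genes(map, genes, window_bp = 1000)
    for (i in seq_len(nrow(map))) {
      expected <- character(0)
      for (j in seq_len(nrow(genes))) { # independent interval logic
        lo <- map$pos_bp[i] - 1000; hi <- map$pos_bp[i] + 1000
        covered <- any(seq(genes$start[j], genes$end[j] - 1) >= lo &
                         seq(genes$start[j], genes$end[j] - 1) <= hi)
        if (genes$chrom[j] == map$chrom[i] && covered)
          expected <- c(expected, genes$gene_id[j])
      }
      expect_setequal(hits[[map$marker_id[i]]], expected)
    }
  }
})

test_that("term enrichment matches the exact hypergeometric tail", {
  # N = 20, K = 5, n = 5, k = 4
  universe <- paste0("g", 1:20)
  terms <- term_table(data.frame(gene_id = paste0("g", 1:5),
                                 term_id = "T1", term_name = "t"))
  cand <- c(paste0("g", 1:4), "g20")
  row <- term_enrichment(cand, terms, universe = universe)
  oracle <- sum(choose(5, 4:5) * choose(15, 5 - (4:5))) / choose(20, 5)
  expect_equal(row$fisher_p, oracle, tolerance = 1e-10)
  expect_equal(row$fold_enrichment, (4 / 5) / (5 / 20))
  # k = n = K = N degenerate: fold 1, p 1
  r2 <- term_enrichment(universe, term_table(data.frame(
    gene_id = universe, term_id = "T", term_name = "t")))
  expect_equal(r2$fold_enrichment, 1); expect_equal(r2$fisher_p, 1)
  # k = 0: fold 0, p 1
  r3 <- term_enrichment("g20", terms, universe = universe)
  expect_equal(r3$fold_enrichment, 0); expect_equal(r3$fisher_p, 1)
  expect_error(term_enrichment(character(0), terms), "empty")
  expect_error(term_enrichment("zzz", terms, universe = universe),
               "outside")
})

test_that("enrichment p-values equal an exhaustive tail oracle for N <= 30", {
  set.seed(60)
  for (rep in 1:20) {
    N <- sample(10:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    universe <- paste0("g", 1:N)
    terms <- term_table(data.frame(gene_id = paste0("g", 1:K),
                                   term_id = "T", term_name = "t"))
    cand <- sample(universe, n)
    k <- sum(cand %in% paste0("g", 1:K))
    p <- term_enrichment(cand, terms, universe = universe)$fisher_p
    ks <- k:min(n, K)
    oracle <- sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
    expect_equal(p, min(oracle, 1), tolerance = 1e-12)
  }
})

test_that("cluster scores follow the -log10 geometric mean exactly", {
  expect_equal(cluster_score(0.05), 1.30103, tolerance = 1e-5)
  expect_equal(cluster_score(c(1, 1)), 0)
  expect_equal(cluster_score(c(0.01, 0.25)), -log10(sqrt(0.0025)),
               tolerance = 1e-12)
  # permutation invariance and monotonicity
  ps <- c(0.3, 0.01, 0.9)
  expect_equal(cluster_score(ps), cluster_score(rev(ps)))
  expect_gt(cluster_score(c(0.3, 0.005, 0.9)), cluster_score(ps))
  expect_error(cluster_score(c(0.1, 0)), "positive")
  expect_error(cluster_score(numeric(0)), "empty")
})

test_that("cluster significance is strict at the 1.3 threshold", {
  rows <- data.frame(term_id = c("a", "b", "c", "d"),
                     fisher_p = c(0.05, 0.05, 0.051, 0.051))
  out <- significant_clusters(list(at = c("a", "b"), just_under = c("c", "d"),
                                   single = "a"), rows)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
  expect_equal(out$score[2], -log10(0.051), tolerance = 1e-10)
  expect_equal(out$score[3], -log10(0.05), tolerance = 1e-10)
  expect_error(significant_clusters(list(bad = "zzz"), rows), "unknown")
})
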