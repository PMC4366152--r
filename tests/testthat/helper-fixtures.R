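# Shared fixtures, all built in code.

# random -1/+1 marker matrix with named lines/markers
binary_X <- function(n, p, seed = 1, prefix = "m") {
  set.seed(seed)
  matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p,
         dimnames = list(sprintf("L%03d", seq_len(n)),
                         paste0(prefix, seq_len(p))))
}

# small genotype table from a character layout (rows = lines)
geno_from_rows <- function(rows, markers) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), markers)
  genotype_table(m)
}

# hand-enumerated QC cascade toy: L3 removed by the sample rule (exactly
# 20% missing), then m2 by the marker rule (25% > 10% on the survivors),
# then m4 by MAF = 0; survivors {L1, L2, L4, L5} x 8 markers
qc_toy <- function() {
  base <- c("A", "B", "A", "A", "B", "A", "B", "A", "B", "A")
  rows <- list(
    L1 = base,
    L2 = replace(c("B", "A", "B", "A", "A", "B", "A", "B", "A", "B"), 2, NA),
    L3 = replace(base, c(2, 5), NA),
    L4 = c("B", "B", "B", "A", "A", "A", "B", "B", "A", "B"),
    L5 = c("A", "A", "A", "A", "B", "B", "A", "A", "B", "A"))
  geno_from_rows(rows, paste0("m", 1:10))
}

# standard simulated panel, cached across test files
.fixture_cache <- new.env(parent = emptyenv())
default_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    sim <- simulate_dh_panel(seed = 1)
    panel <- qc_filter(sim$geno)
    .fixture_cache$panel <- list(
      sim = sim, panel = panel,
      clustering = ld_prune(panel$coded, sim$map),
      pheno = sim$pheno[sim$pheno$line_id %in% rownames(panel$coded), ])
  }
  .fixture_cache$panel
}

# batch-means Monte-Carlo standard error of a (possibly autocorrelated)
# chain
mc_se <- function(chain, n_batch = 20) {
  m <- length(chain) %/% n_batch
  bm <- vapply(seq_len(n_batch),
               function(b) mean(chain[((b - 1) * m + 1):(b * m)]), 0)
  sd(bm) / sqrt(n_batch)
}

# quadrature posterior mean for a single-marker regression with known
# residual variance and prior density `prior(beta)`
quadrature_posterior_mean <- function(x, y, sigma2e, prior,
                                      lim = 5, n_grid = 20001) {
  bgrid <- seq(-lim, lim, length.out = n_grid)
  loglik <- vapply(bgrid,
                   function(b) -sum((y - x * b)^2) / (2 * sigma2e), 0)
  w <- exp(loglik - max(loglik)) * prior(bgrid)
  sum(bgrid * w) / sum(w)
}
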