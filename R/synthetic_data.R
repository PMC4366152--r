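# Simulation of biparental doubled-haploid (DH) panels: each line is a
# doubled gamete from the F1, so every marker is homozygous for one of the
# two parental alleles. Crossovers follow a no-interference (Haldane)
# model on the genetic map, which makes the allele sequence along a
# chromosome a two-state Markov chain with switch probability
# r = (1 - exp(-2d/100)) / 2 between markers d cM apart.

#' Build a synthetic marker map
#'
#' Markers are spread uniformly at random along each linkage group, with
#' chromosome names following the *B. napus* A1-A10 / C1-C9 convention
#' when 19 groups are requested. Physical positions are derived from the
#' genetic ones at a fixed 500 kb/cM expansion so that window-based
#' annotation can be exercised on simulated data.
#'
#' @param n_markers total marker count (split as evenly as possible).
#' @param n_chrom number of linkage groups.
#' @param chrom_length_cM genetic length of every group.
#' @param seed integer seed.
#' @return a [marker_map()].
#' @export
make_marker_map <- function(n_markers = 1674, n_chrom = 19,
                            chrom_length_cM = 90, seed = 1L) {
  stopifnot(n_markers >= n_chrom, n_chrom >= 1)
  set.seed(seed)
  chroms <- if (n_chrom == 19) c(paste0("A", 1:10), paste0("C", 1:9))
            else sprintf("chr%02d", seq_len(n_chrom))
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  rows <- lapply(seq_len(n_chrom), function(i) {
    pos <- sort(runif(per[i], 0, chrom_length_cM))
    data.frame(marker_id = sprintf("M%s_%04d", chroms[i], seq_len(per[i])),
               chrom = chroms[i], pos_cM = pos,
               pos_bp = as.integer(round(pos * 5e5)))
  })
  marker_map(do.call(rbind, rows))
}

#' Simulate DH genotypes from a genetic map
#'
#' Each line is an independent doubled gamete: the allele at the first
#' marker of a chromosome is A or B with probability 1/2, and between
#' adjacent markers the allele switches with the Haldane recombination
#' fraction for their cM distance. There are no heterozygotes and no
#' segregation distortion.
#'
#' @param map a [marker_map()].
#' @param n_lines number of DH lines (>= 2).
#' @param seed integer seed.
#' @return a complete [genotype_table()] (no missing cells).
#' @export
simulate_dh_genotypes <- function(map, n_lines, seed = 1L) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  set.seed(seed)
  out <- matrix(NA_character_, n_lines, nrow(map),
                dimnames = list(sprintf("DH%03d", seq_len(n_lines)),
                                map$marker_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_cM[idx]
    if (is.unsorted(pos)) stop("map positions not monotone within ", ch)
    m <- length(idx)
    state <- matrix(0L, n_lines, m)
    state[, 1] <- as.integer(runif(n_lines) < 0.5)
    if (m > 1) {
      r <- haldane_r(diff(pos))
      switches <- matrix(runif(n_lines * (m - 1)) <
                           rep(r, each = n_lines), n_lines, m - 1)
      cum <- switches
      if (m > 2) cum <- t(apply(switches, 1, cumsum))
      state[, -1] <- (state[, 1] + cum) %% 2L
    }
    out[, idx] <- ifelse(state == 1L, "B", "A")
  }
  genotype_table(out)
}

#' Haldane map function: cM distance to recombination fraction
#' @param d_cM genetic distance(s) in centimorgans.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Ground truth for a simulated trait
#'
#' @param additive data frame (`marker_id`, `effect`) of additive QTL
#'   effects in trait units (days): the two genotype classes at a QTL
#'   with effect `a` differ by `2a`.
#' @param epistatic data frame (`marker1`, `marker2`, `effect`) of
#'   product-coded pairwise interactions (may have zero rows).
#' @param env_means data frame (`site`, `year`, `mean_days`) of
#'   environment main effects, in days, relative to `mu_days`.
#' @param h2 target narrow-sense heritability within one environment,
#'   in (0, 1]; drives the derived residual SD unless `residual_sd` is
#'   supplied directly.
#' @param gxe_sd SD (days) of independent line-by-environment deviates.
#' @param mu_days grand mean flowering time.
#' @param residual_sd optional explicit residual SD; when `NULL` it is
#'   derived from `h2` and the realized genetic variance.
#' @return a list of class `sim_truth`.
#' @export
sim_truth <- function(additive, epistatic = NULL, env_means,
                      h2 = 0.6, gxe_sd = 0, mu_days = 150,
                      residual_sd = NULL) {
  if (is.null(epistatic))
    epistatic <- data.frame(marker1 = character(), marker2 = character(),
                            effect = numeric())
  stopifnot(all(c("marker_id", "effect") %in% names(additive)),
            all(c("marker1", "marker2", "effect") %in% names(epistatic)),
            all(c("site", "year", "mean_days") %in% names(env_means)))
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  if (gxe_sd < 0) stop("gxe_sd must be nonnegative")
  if (nrow(epistatic)) {
    if (any(epistatic$marker1 == epistatic$marker2))
      stop("epistatic pairs must involve two distinct markers")
    key <- apply(epistatic[, c("marker1", "marker2")], 1,
                 function(z) paste(sort(z), collapse = "|"))
    if (anyDuplicated(key)) stop("duplicated epistatic pair(s)")
  }
  structure(list(additive = additive, epistatic = epistatic,
                 env_means = env_means, h2 = h2, gxe_sd = gxe_sd,
                 mu_days = mu_days, residual_sd = residual_sd),
            class = "sim_truth")
}

#' The default ten-environment design: four north years, four south
#' years, two east years, with fixed environment mean offsets in days.
#' @export
default_environments <- function() {
  data.frame(
    site = c(rep("north", 4), rep("south", 4), rep("east", 2)),
    year = c(2003:2006, 2003:2006, 2006:2007),
    mean_days = c(8, 11, 6, 9, -4, -7, -2, -5, 1, -1))
}

#' Default planted truth for the standard panel
#'
#' Thirty additive QTLs spread over the genome with exponentially
#' distributed effect magnitudes and random signs (a few large, many
#' small effects), plus two planted epistatic pairs. Effects are scaled
#' so the within-environment phenotypic SD is about 10 days at the
#' requested heritability; one third of the non-genetic variance is
#' genotype-by-environment interaction.
#'
#' @param map a [marker_map()].
#' @param n_qtl,n_epi numbers of additive QTLs and epistatic pairs.
#' @param h2 target heritability.
#' @param seed integer seed.
#' @return a `sim_truth`.
#' @export
make_default_truth <- function(map, n_qtl = 30, n_epi = 2, h2 = 0.6,
                               seed = 1L) {
  set.seed(seed + 7L)
  qtl <- sample(map$marker_id, n_qtl + 2 * n_epi)
  mag <- stats::rexp(n_qtl)
  eff <- mag * sample(c(-1, 1), n_qtl, replace = TRUE)
  # scale relative effects to roughly a 10-day within-env phenotypic SD:
  # sd(g) = sqrt(h2) * sd_P, with independent loci sd(g) ~ sqrt(sum a^2)
  scale <- sqrt(h2) * 10 / sqrt(sum(eff^2))
  additive <- data.frame(marker_id = qtl[seq_len(n_qtl)],
                         effect = eff * scale)
  epistatic <- NULL
  if (n_epi > 0) {
    em <- matrix(qtl[n_qtl + seq_len(2 * n_epi)], ncol = 2)
    epistatic <- data.frame(marker1 = em[, 1], marker2 = em[, 2],
                            effect = rep(mean(abs(additive$effect)), n_epi))
  }
  env <- default_environments()
  truth <- sim_truth(additive, epistatic, env, h2 = h2, mu_days = 150)
  truth$gxe_share <- 1 / 3
  truth
}

#' Convert A/B calls to the -1/+1 numeric coding (NA preserved)
#' @param geno a [genotype_table()].
#' @export
code_alleles <- function(geno) {
  x <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  x[geno == "A"] <- -1
  x[geno == "B"] <- 1
  x
}

#' Simulate multi-environment flowering-time phenotypes
#'
#' Generates `y(line, env) = mu + env_mean + g + gxe + eps` with
#' `g = sum(a_j x_j) + sum(w_l x_a x_b)` on the -1/+1 coding. The
#' residual SD is derived so that the genetic fraction of the
#' within-environment variance equals the target `h2`
#' (`var(eps) + gxe_sd^2 = var(g) (1 - h2) / h2`), unless the truth
#' carries an explicit `residual_sd`. When the truth has a `gxe_share`
#' field, `gxe_sd` is set to that share of the non-genetic variance.
#'
#' @param geno a complete [genotype_table()] (simulate before injecting
#'   missingness).
#' @param truth a [sim_truth()].
#' @param environments optional data frame (`site`, `year`) restricting
#'   the environments; defaults to those in `truth$env_means`.
#' @param seed integer seed.
#' @return list with `pheno` (a [phenotype_table()]) and `truth` (the
#'   input with `residual_sd`, realized `var_g` and per-line genetic
#'   values `genetic_value` filled in).
#' @export
simulate_phenotypes <- function(geno, truth, environments = NULL,
                                seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  env <- truth$env_means
  if (!is.null(environments))
    env <- merge(environments[, c("site", "year")], truth$env_means,
                 by = c("site", "year"), sort = FALSE)
  ids <- c(truth$additive$marker_id, truth$epistatic$marker1,
           truth$epistatic$marker2)
  missing_ids <- setdiff(ids, colnames(geno))
  if (length(missing_ids))
    stop("truth marker(s) absent from genotypes: ",
         paste(missing_ids, collapse = ", "))
  x <- code_alleles(geno)
  if (anyNA(x)) stop("genotypes must be complete for simulation")
  n <- nrow(x)
  g <- rep(0, n)
  if (nrow(truth$additive))
    g <- as.vector(x[, truth$additive$marker_id, drop = FALSE] %*%
                     truth$additive$effect)
  if (nrow(truth$epistatic))
    for (l in seq_len(nrow(truth$epistatic)))
      g <- g + truth$epistatic$effect[l] *
        x[, truth$epistatic$marker1[l]] * x[, truth$epistatic$marker2[l]]
  var_g <- if (n > 1) var(g) else 0
  noise_var <- var_g * (1 - truth$h2) / truth$h2
  gxe_sd <- truth$gxe_sd
  if (!is.null(truth$gxe_share))
    gxe_sd <- sqrt(noise_var * truth$gxe_share)
  residual_sd <- truth$residual_sd
  if (is.null(residual_sd)) {
    res_var <- noise_var - gxe_sd^2
    if (res_var < -1e-9)
      stop("gxe_sd too large for the target h2")
    residual_sd <- sqrt(max(res_var, 0))
  }
  set.seed(seed)
  recs <- vector("list", nrow(env))
  for (k in seq_len(nrow(env))) {
    gxe <- if (gxe_sd > 0) rnorm(n, 0, gxe_sd) else 0
    eps <- if (residual_sd > 0) rnorm(n, 0, residual_sd) else 0
    recs[[k]] <- data.frame(line_id = rownames(geno),
                            site = env$site[k], year = env$year[k],
                            ft_days = truth$mu_days + env$mean_days[k] +
                              g + gxe + eps)
  }
  truth$residual_sd <- residual_sd
  truth$gxe_sd <- gxe_sd
  truth$var_g <- var_g
  truth$genetic_value <- setNames(g, rownames(geno))
  list(pheno = phenotype_table(do.call(rbind, recs), genotypes = geno),
       truth = truth)
}

#' Inject missing genotype calls
#'
#' Background cells are knocked out independently at `cell_rate`; listed
#' bad samples lose a fixed 25% of their markers (above the 20% QC
#' threshold) and listed bad markers a fixed 15% of their lines (above
#' the 10% threshold). Overlaps are harmless: a cell is simply missing.
#'
#' @param geno a [genotype_table()].
#' @param cell_rate background missingness rate in `[0, 1)`.
#' @param bad_sample_ids,bad_marker_ids ids to degrade.
#' @param seed integer seed.
#' @param bad_sample_frac,bad_marker_frac fractions knocked out for
#'   listed samples/markers.
#' @return a [genotype_table()] with `NA` cells added.
#' @export
inject_missing <- function(geno, cell_rate = 0, bad_sample_ids = character(),
                           bad_marker_ids = character(), seed = 1L,
                           bad_sample_frac = 0.25, bad_marker_frac = 0.15) {
  if (cell_rate < 0 || cell_rate >= 1) stop("cell_rate must be in [0, 1)")
  stopifnot(all(bad_sample_ids %in% rownames(geno)),
            all(bad_marker_ids %in% colnames(geno)))
  set.seed(seed)
  out <- unclass(geno)
  if (cell_rate > 0)
    out[matrix(runif(length(out)) < cell_rate, nrow(out))] <- NA_character_
  for (s in bad_sample_ids)
    out[s, sample(ncol(out), ceiling(bad_sample_frac * ncol(out)))] <- NA_character_
  for (m in bad_marker_ids)
    out[sample(nrow(out), ceiling(bad_marker_frac * nrow(out))), m] <- NA_character_
  genotype_table(out)
}

#' Simulate a complete DH study panel at the default scale
#'
#' One call reproducing the scale of the reference design: 190 DH lines
#' genotyped at 1,674 markers on 19 linkage groups, ten environments in
#' three regions, planted additive and epistatic QTLs at h2 = 0.6, and
#' missingness patterned so that the QC cascade removes 8 lines and
#' thins the marker panel to roughly 1,250 markers.
#'
#' @param n_lines,n_markers panel dimensions.
#' @param h2 target heritability.
#' @param n_qtl,n_epi planted architecture.
#' @param with_missing knock out cells so QC has work to do.
#' @param seed integer seed driving map, genotypes, truth and noise.
#' @return list with `map`, `geno` (with missingness), `geno_complete`,
#'   `pheno`, `truth`.
#' @export
simulate_dh_panel <- function(n_lines = 190, n_markers = 1674, h2 = 0.6,
                              n_qtl = 30, n_epi = 2, with_missing = TRUE,
                              seed = 1L) {
  map <- make_marker_map(n_markers = n_markers, seed = seed)
  geno <- simulate_dh_genotypes(map, n_lines, seed = seed + 1L)
  truth <- make_default_truth(map, n_qtl = n_qtl, n_epi = n_epi, h2 = h2,
                              seed = seed)
  sim <- simulate_phenotypes(geno, truth, seed = seed + 2L)
  dirty <- geno
  if (with_missing) {
    set.seed(seed + 3L)
    bad_lines <- sample(rownames(geno), min(8, n_lines - 2))
    ok_markers <- setdiff(colnames(geno),
                          c(truth$additive$marker_id,
                            truth$epistatic$marker1, truth$epistatic$marker2))
    bad_markers <- sample(ok_markers, round(0.25 * n_markers))
    dirty <- inject_missing(geno, cell_rate = 0.02,
                            bad_sample_ids = bad_lines,
                            bad_marker_ids = bad_markers, seed = seed + 4L)
  }
  list(map = map, geno = dirty, geno_complete = geno, pheno = sim$pheno,
       truth = sim$truth)
}
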