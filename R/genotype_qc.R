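# Quality control follows the classical cascade for chip-genotyped DH
# panels, applied in this fixed order with each rule computed on the set
# surviving the previous one:
#   1. drop samples with >= 20% uncharacterised markers,
#   2. drop markers missing in more than 10% of the remaining samples,
#   3. drop markers with minor allele frequency strictly below 0.05.
# The boundary conventions (>= for samples, > for markers, < for MAF)
# are deliberate and tested.

#' Per-marker minor allele frequency
#' @param geno a [genotype_table()].
#' @return named numeric vector in `[0, 0.5]` (NA for all-missing markers).
#' @export
marker_maf <- function(geno) {
  fa <- colMeans(geno == "A", na.rm = TRUE)
  pmin(fa, 1 - fa)
}

#' Apply the QC cascade, then code and impute
#'
#' @param geno a [genotype_table()].
#' @param sample_miss_max samples with missingness `>=` this are dropped.
#' @param marker_miss_max markers with missingness `>` this are dropped.
#' @param maf_min markers with MAF `<` this are dropped (a marker at
#'   exactly the cutoff is retained).
#' @return a `genotype_panel`: list with `base` (post-QC
#'   [genotype_table()]), `coded` (complete numeric matrix, A = -1,
#'   B = +1, missing imputed by the per-marker mean), `maf`, and
#'   `qc_log` (ordered list of rule/removed-id pairs).
#' @export
qc_filter <- function(geno, sample_miss_max = 0.20, marker_miss_max = 0.10,
                      maf_min = 0.05) {
  if (!nrow(geno) || !ncol(geno)) stop("empty genotype table")
  qc_log <- list()

  smiss <- rowMeans(is.na(geno))
  drop_s <- rownames(geno)[smiss >= sample_miss_max]
  qc_log$sample_missingness <- drop_s
  g <- geno[!rownames(geno) %in% drop_s, , drop = FALSE]
  if (!nrow(g)) stop("no samples survive QC")

  mmiss <- colMeans(is.na(g))
  drop_m1 <- colnames(g)[mmiss > marker_miss_max]
  qc_log$marker_missingness <- drop_m1
  g <- g[, !colnames(g) %in% drop_m1, drop = FALSE]

  maf <- marker_maf(structure(g, class = "genotype_table"))
  drop_m2 <- colnames(g)[is.na(maf) | maf < maf_min]
  qc_log$maf <- drop_m2
  g <- g[, !colnames(g) %in% drop_m2, drop = FALSE]
  if (!ncol(g)) stop("no markers survive QC")

  base <- structure(g, class = "genotype_table")
  structure(list(base = base, coded = impute_and_code(base),
                 maf = marker_maf(base), qc_log = qc_log),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d lines x %d markers after QC (removed: %s)\n",
              nrow(x$base), ncol(x$base),
              paste(sprintf("%s=%d", names(x$qc_log),
                            lengths(x$qc_log)), collapse = ", ")))
  invisible(x)
}

#' Numeric coding with mean imputation
#'
#' A maps to -1, B to +1; a missing call becomes the mean of the
#' observed coded values of its marker (equal to `1 - 2 freq(A)`), which
#' preserves each marker's mean and keeps `|coded| <= 1`.
#'
#' @param geno a [genotype_table()].
#' @return complete numeric matrix.
#' @export
impute_and_code <- function(geno) {
  x <- code_alleles(geno)
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    if (anyNA(mu))
      stop("marker(s) with no observed calls: ",
           paste(colnames(x)[is.na(mu)], collapse = ", "))
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' r2 is the squared Pearson correlation of the coded marker columns.
#' For a fully homozygous DH design this equals the classical haplotype
#' r2 identically (each line carries one gamete's alleles). A constant
#' column has r2 defined as 0 against every other marker.
#'
#' @param coded complete numeric line-by-marker matrix.
#' @return symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
ld_r2 <- function(coded) {
  if (nrow(coded) < 2) stop("need >= 2 lines")
  sds <- apply(coded, 2, sd)
  r2 <- suppressWarnings(cor(coded))^2
  r2[is.na(r2)] <- 0
  r2[sds == 0, ] <- 0
  r2[, sds == 0] <- 0
  diag(r2) <- 1
  pmin(pmax(r2, 0), 1)
}

#' Greedy map-ordered LD pruning into tag-SNP clusters
#'
#' Markers are scanned in map order (chromosome by chromosome). A marker
#' joins the cluster of the first already-accepted tag it has
#' `r2 >= r2_max` with; otherwise it becomes a new tag. Tags therefore
#' have pairwise `r2 < r2_max`, and every retained marker belongs to
#' exactly one cluster (a tag represents itself with r2 = 1).
#'
#' @param coded complete numeric matrix (post-QC).
#' @param map a [marker_map()] covering all coded markers.
#' @param r2_max pruning threshold (markers at or above it cluster).
#' @return a `tag_clustering`: list with `tags`, `cluster_of` (named
#'   character vector marker -> tag) and `r2_to_tag`.
#' @export
ld_prune <- function(coded, map, r2_max = 0.7) {
  ids <- colnames(coded)
  missing_ids <- setdiff(ids, map$marker_id)
  if (length(missing_ids))
    stop("marker(s) absent from map: ", paste(missing_ids, collapse = ", "))
  ord <- map$marker_id[map$marker_id %in% ids]
  n <- nrow(coded)
  xs <- scale(coded[, ord, drop = FALSE]) # unit-variance columns, NaN if constant
  xs[, colSums(!is.finite(xs)) > 0] <- 0  # constant markers: r2 = 0 to all

  tags <- character(0)
  tagmat <- matrix(numeric(0), n, 0)
  cluster_of <- r2_to_tag <- setNames(vector("list", length(ord)), ord)
  for (m in ord) {
    hit <- NA_character_; hit_r2 <- 1
    if (length(tags)) {
      r2 <- as.vector(crossprod(tagmat, xs[, m]) / (n - 1))^2
      i <- which(r2 >= r2_max)
      if (length(i)) { hit <- tags[i[1]]; hit_r2 <- r2[i[1]] }
    }
    if (is.na(hit)) {
      tags <- c(tags, m)
      tagmat <- cbind(tagmat, xs[, m])
      cluster_of[[m]] <- m; r2_to_tag[[m]] <- 1
    } else {
      cluster_of[[m]] <- hit; r2_to_tag[[m]] <- hit_r2
    }
  }
  structure(list(tags = tags,
                 cluster_of = unlist(cluster_of),
                 r2_to_tag = unlist(r2_to_tag)),
            class = "tag_clustering")
}

#' @export
print.tag_clustering <- function(x, ...) {
  cat(sprintf("<tag_clustering> %d markers in %d clusters\n",
              length(x$cluster_of), length(x$tags)))
  invisible(x)
}

#' Long-form LD export (marker_i, marker_j, r2) for the upper triangle
#' @param r2 matrix from [ld_r2()].
#' @export
ld_long <- function(r2) {
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  data.frame(marker_i = rownames(r2)[idx[, 1]],
             marker_j = colnames(r2)[idx[, 2]],
             r2 = r2[idx])
}
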