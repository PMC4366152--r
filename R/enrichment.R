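# Database-free functional enrichment: SNPs are mapped to genes within
# a +/- 1 kb window, candidate gene sets are scored per term by
# fold-enrichment and a one-sided hypergeometric (Fisher) test, and
# term groups get a cluster enrichment score, -log10 of the geometric
# mean of the member p-values, with 1.3 (i.e. p = 0.05) as the
# significance threshold.

#' Map SNPs to nearby genes by window overlap
#'
#' A gene is assigned to a SNP when the closed window
#' `[pos - window_bp, pos + window_bp]` around the SNP's physical
#' position overlaps the half-open gene interval `[start, end)`.
#' Multiple genes per SNP are allowed. SNPs without a physical position
#' are skipped with a warning.
#'
#' @param map a [marker_map()] with `pos_bp` filled in.
#' @param genes a [gene_table()] (0-based half-open, as in BED).
#' @param window_bp window half-width in bp.
#' @param snps optional subset of marker ids (default: all mapped).
#' @return named list, SNP id -> character vector of gene ids (possibly
#'   empty).
#' @export
snps_to_genes <- function(map, genes, window_bp = 1000, snps = NULL) {
  snps <- snps %||% map$marker_id
  m <- map[match(snps, map$marker_id), , drop = FALSE]
  if (anyNA(m$marker_id))
    stop("SNP(s) absent from map: ",
         paste(setdiff(snps, map$marker_id), collapse = ", "))
  no_bp <- is.na(m$pos_bp)
  if (any(no_bp)) {
    warning(sum(no_bp), " SNP(s) without physical position skipped")
    m <- m[!no_bp, , drop = FALSE]
  }
  out <- setNames(vector("list", nrow(m)), m$marker_id)
  for (i in seq_len(nrow(m))) {
    lo <- m$pos_bp[i] - window_bp
    hi <- m$pos_bp[i] + window_bp
    hit <- genes$chrom == m$chrom[i] & lo < genes$end & hi >= genes$start
    out[[i]] <- genes$gene_id[hit]
  }
  out
}

#' Per-term fold enrichment and Fisher (hypergeometric) test
#'
#' For each term with `K` annotated genes in a universe of `N`, and `k`
#' hits among `n` candidate genes, reports
#' `fold_enrichment = (k/n) / (K/N)` and the one-sided
#' over-representation p-value `P(X >= k)` of the hypergeometric
#' distribution. Rows are sorted by p-value.
#'
#' @param candidates character vector of candidate gene ids (non-empty,
#'   all inside the universe).
#' @param terms a [term_table()].
#' @param universe background gene ids; defaults to all genes in
#'   `terms`.
#' @param ease apply the conservative EASE-style adjustment (one
#'   candidate hit removed before the test); off by default.
#' @return data frame (`term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `fisher_p`).
#' @export
term_enrichment <- function(candidates, terms, universe = NULL,
                            ease = FALSE) {
  candidates <- unique(candidates)
  if (!length(candidates)) stop("empty candidate set")
  universe <- unique(universe %||% terms$gene_id)
  outside <- setdiff(candidates, universe)
  if (length(outside))
    stop("candidate(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  N <- length(universe); n <- length(candidates)
  by_term <- split(terms$gene_id, terms$term_id)
  nm <- terms$term_name[match(names(by_term), terms$term_id)]
  rows <- lapply(seq_along(by_term), function(i) {
    g <- unique(by_term[[i]])
    K <- length(g)
    k <- length(intersect(g, candidates))
    k_test <- if (ease) max(k - 1, 0) else k
    p <- if (k_test == 0) 1 else
      phyper(k_test - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = names(by_term)[i], term_name = nm[i],
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), fisher_p = p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fisher_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster enrichment score
#'
#' `-log10` of the geometric mean of the member p-values; a group whose
#' members all sit at p = 0.05 scores 1.301, the classical 1.3
#' significance threshold.
#'
#' @param member_pvalues numeric vector in `(0, 1]`.
#' @return the enrichment score (nonnegative real).
#' @export
cluster_score <- function(member_pvalues) {
  if (!length(member_pvalues)) stop("empty p-value list")
  if (any(member_pvalues <= 0)) stop("p-values must be positive")
  if (any(member_pvalues > 1)) stop("p-values must be <= 1")
  -mean(log10(member_pvalues))
}

#' Flag significant functional clusters
#'
#' @param groups named list of term-id vectors (each group a set of
#'   related terms).
#' @param rows output of [term_enrichment()].
#' @param threshold strict score threshold (default 1.3, equivalent to
#'   p = 0.05).
#' @return data frame (`group`, `n_terms`, `score`, `significant`).
#' @export
significant_clusters <- function(groups, rows, threshold = 1.3) {
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    unknown <- setdiff(ids, rows$term_id)
    if (length(unknown))
      stop("group '", g, "' references unknown term(s): ",
           paste(unknown, collapse = ", "))
    sc <- cluster_score(rows$fisher_p[match(ids, rows$term_id)])
    data.frame(group = g, n_terms = length(ids), score = sc,
               significant = sc > threshold)
  })
  do.call(rbind, out)
}
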