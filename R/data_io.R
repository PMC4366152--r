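#' @section File dialect:
#' All tables are tab-separated UTF-8 with a header row. Missing values are
#' accepted as `NA` or the empty string on read and written canonically as
#' `NA`.
#' @name dhgs-io
NULL

SITE_LEVELS <- c("north", "south", "east")

#' Construct a line-by-marker genotype table
#'
#' A genotype table stores biparental DH genotype calls as a character
#' matrix with rows = lines and columns = markers. Allele `"A"` marks the
#' first parent (e.g. Tapidor), `"B"` the second (e.g. Ningyou7); `NA`
#' marks an uncharacterised call. DH lines are fully homozygous, so a
#' single letter per cell is sufficient.
#'
#' @param alleles character matrix of `"A"`/`"B"`/`NA` with rownames
#'   (line ids) and colnames (marker ids).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(alleles) {
  if (!is.matrix(alleles) || !is.character(alleles))
    stop("`alleles` must be a character matrix")
  if (is.null(rownames(alleles)) || is.null(colnames(alleles)))
    stop("`alleles` must carry line ids as rownames and marker ids as colnames")
  obj <- structure(alleles, class = "genotype_table")
  validate_genotype_table(obj)
  obj
}

validate_genotype_table <- function(x) {
  lid <- rownames(x); mid <- colnames(x)
  dup <- lid[duplicated(lid)]
  if (length(dup)) stop("duplicated line id(s): ", paste(unique(dup), collapse = ", "))
  dup <- mid[duplicated(mid)]
  if (length(dup)) stop("duplicated marker id(s): ", paste(unique(dup), collapse = ", "))
  if (any(grepl("[\t\n]", c(lid, mid))))
    stop("ids must not contain tab or newline characters")
  bad <- setdiff(unique(as.vector(x)), c("A", "B", NA))
  if (length(bad))
    stop("unrecognized allele token(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d lines x %d markers, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype table from TSV
#'
#' Expects a header row of marker ids and a first column of line ids.
#' Cells must be `A`, `B`, `NA` or empty; any other token is an error
#' (never silently coerced to missing).
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path) {
  check_rectangular(path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("genotype file needs a line-id column plus >= 1 marker")
  lid <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- lid
  genotype_table(m)
}

check_rectangular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]))
  }
  invisible(TRUE)
}

#' Construct a marker map
#'
#' @param df data frame with columns `marker_id`, `chrom`, `pos_cM` and
#'   optionally `pos_bp`. Genetic positions must be nonnegative and
#'   sortable within chromosome.
#' @return a `marker_map` data frame sorted by chromosome and cM position.
#' @export
marker_map <- function(df) {
  need <- c("marker_id", "chrom", "pos_cM")
  if (!all(need %in% names(df)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker_id))
    stop("duplicated marker id(s): ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  if (any(df$pos_cM < 0)) stop("pos_cM must be nonnegative")
  if (!"pos_bp" %in% names(df)) df$pos_bp <- NA_integer_
  df <- df[order(df$chrom, df$pos_cM, df$marker_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("marker_map", "data.frame"))
}

#' @rdname marker_map
#' @param path TSV with columns marker_id, chrom, pos_cM[, pos_bp].
#' @export
read_marker_map <- function(path) {
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""))
  marker_map(df)
}

#' Construct a multi-environment phenotype table
#'
#' One record per (line, site, year). An environment is a site-year
#' combination; sites follow the three-region vocabulary
#' north/south/east. Flowering time `ft_days` is in days and must be
#' positive when present; missing phenotypes are kept and flagged so that
#' downstream policy stays with the evaluation stage.
#'
#' @param df data frame with columns `line_id`, `site`, `year`, `ft_days`.
#' @param genotypes optional [genotype_table()]; when given, every
#'   `line_id` must appear in it.
#' @return a `phenotype_table` data frame with an added display column
#'   `env` (`<site initial><final year digit>`, e.g. `S4`).
#' @export
phenotype_table <- function(df, genotypes = NULL) {
  need <- c("line_id", "site", "year", "ft_days")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  df$site <- normalize_site(df$site)
  df$year <- as.character(df$year)
  key <- paste(df$line_id, df$site, df$year)
  if (anyDuplicated(key))
    stop("duplicated (line_id, site, year) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(!is.na(df$ft_days) & df$ft_days <= 0))
    stop("ft_days must be positive; offending line(s): ",
         paste(df$line_id[!is.na(df$ft_days) & df$ft_days <= 0], collapse = ", "))
  if (!is.null(genotypes)) {
    miss <- setdiff(unique(df$line_id), rownames(genotypes))
    if (length(miss))
      stop("line id(s) absent from genotype table: ", paste(miss, collapse = ", "))
  }
  df$env <- env_label(df$site, df$year)
  rownames(df) <- NULL
  structure(df[, c("line_id", "site", "year", "env", "ft_days")],
            class = c("phenotype_table", "data.frame"))
}

normalize_site <- function(site) {
  s <- tolower(trimws(as.character(site)))
  s[s %in% c("n")] <- "north"; s[s %in% c("s")] <- "south"; s[s %in% c("e")] <- "east"
  bad <- setdiff(unique(s), SITE_LEVELS)
  if (length(bad))
    stop("unknown site token(s): ", paste(bad, collapse = ", "),
         " (expected north/south/east)")
  s
}

#' Display label for a site-year environment, e.g. "S4" for south 2004
#' @param site,year vectors of site names and year strings.
#' @export
env_label <- function(site, year) {
  y <- as.character(year)
  paste0(toupper(substr(site, 1, 1)), substr(y, nchar(y), nchar(y)))
}

#' @rdname phenotype_table
#' @param path TSV with columns line_id, site, year, ft_days.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""))
  df$ft_days <- as.numeric(df$ft_days)
  phenotype_table(df, genotypes = genotypes)
}

#' Read a BED-like gene coordinate table
#'
#' Columns `chrom`, `start`, `end`, `gene_id` with 0-based half-open
#' intervals, as in BED.
#' @param path file path.
#' @return data frame of class `gene_table`.
#' @export
read_gene_table <- function(path) {
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  gene_table(df)
}

#' @rdname read_gene_table
#' @param df data frame with the four columns above.
#' @export
gene_table <- function(df) {
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(df))) stop("gene table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$start >= df$end)) stop("gene intervals must satisfy start < end")
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id(s)")
  structure(df[, need], class = c("gene_table", "data.frame"))
}

#' Read a gene-to-term annotation table
#' @param path TSV with columns gene_id, term_id, term_name.
#' @return data frame of class `term_table`.
#' @export
read_term_table <- function(path) {
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  term_table(df)
}

#' @rdname read_term_table
#' @param df data frame with the three columns above.
#' @export
term_table <- function(df) {
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% names(df))) stop("term table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(!nzchar(df$term_id))) stop("term_ids must be non-empty")
  structure(df[, need], class = c("term_table", "data.frame"))
}

#' Write a pipeline table deterministically
#'
#' Writes tab-separated UTF-8 with a header, canonical `NA` for missing
#' values and fixed 15-significant-digit formatting for reals, so that
#' identical objects always produce byte-identical files.
#'
#' @param obj a data frame or [genotype_table()].
#' @param path output path.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(obj, path) {
  out <- obj
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.15g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_table.genotype_table <- function(obj, path) {
  df <- data.frame(line_id = rownames(obj), unclass(obj)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table.data.frame(df, path)
}

#' @export
write_table.default <- function(obj, path) {
  stop("write_table: unsupported object of class ",
       paste(class(obj), collapse = "/"))
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' Collects every tunable threshold and hyperparameter of the pipeline in
#' one validated list: QC cutoffs, LD pruning threshold, CV design, MCMC
#' lengths, random-forest and MARS settings, and the master seed.
#'
#' @param seed master seed for all stochastic stages.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    sample_miss_max = 0.20, marker_miss_max = 0.10, maf_min = 0.05,
    r2_max = 0.7,
    cv_k = 10L, cv_repeats = 10L,
    mcmc_iters = 12000L, mcmc_burnin = 2000L, mcmc_thin = 5L,
    bayesb_pi = 0.95,
    rf_trees = 1000L, rf_mtry_fraction = 1 / 3,
    rf_importance_runs = 20L,
    inclusion_step = 0.05, inclusion_reps = 20L,
    mars_penalty = 3, mars_runs = 10L, mars_k = 10L,
    enrichment_window_bp = 1000L, enrichment_score_min = 1.3,
    direction_alpha = 0.05)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML file whose entries override the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot_range <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(sprintf("config field `%s` out of range", name))
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config must carry a seed")
  stopifnot_range(cfg$sample_miss_max, 0, 1, "sample_miss_max")
  stopifnot_range(cfg$marker_miss_max, 0, 1, "marker_miss_max")
  stopifnot_range(cfg$maf_min, 0, 0.5, "maf_min")
  stopifnot_range(cfg$r2_max, 0, 1, "r2_max", lo_open = TRUE)
  stopifnot_range(cfg$cv_k, 2, 1e6, "cv_k")
  stopifnot_range(cfg$cv_repeats, 1, 1e6, "cv_repeats")
  if (cfg$mcmc_iters <= cfg$mcmc_burnin)
    stop("config: mcmc_iters must exceed mcmc_burnin")
  stopifnot_range(cfg$bayesb_pi, 0, 1, "bayesb_pi")
  stopifnot_range(cfg$rf_mtry_fraction, 0, 1, "rf_mtry_fraction", lo_open = TRUE)
  stopifnot_range(cfg$inclusion_step, 0, 0.5, "inclusion_step", lo_open = TRUE)
  stopifnot_range(cfg$direction_alpha, 0, 1, "direction_alpha", lo_open = TRUE)
  invisible(cfg)
}

#' Write a reproducibility manifest for a run
#'
#' Records the seed, a hash of the full configuration, and the package
#' version, so any stochastic stage can be replayed exactly.
#'
#' @param config a `run_config`.
#' @param path output JSON path.
#' @param extra optional named list of additional fields.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("dhgs")),
    written_at = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
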