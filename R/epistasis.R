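# Pairwise epistasis mapping by multivariate adaptive regression splines
# (MARS): greedy forward selection of reflected-hinge basis pairs with
# products capped at interaction degree 2, generalized-cross-validation
# (GCV) backward pruning, and cross-validated stability selection of the
# surviving marker-by-marker product terms. With -1/+1 coded markers
# every hinge is affine in its marker, so a surviving degree-2 product
# term is exactly a marker-by-marker interaction.

#' Fit a MARS model
#'
#' Forward pass: starting from the intercept, repeatedly add the
#' reflected hinge pair `h(x_v - t), h(t - x_v)` (possibly multiplied
#' into one existing term, keeping at most 2 distinct markers per term)
#' that most reduces the residual sum of squares; knots are placed at
#' observed predictor values only. The pass stops at `max_terms`, when
#' no candidate improves the fit, or when the effective parameter count
#' approaches n. Backward pass: terms are deleted one at a time, keeping
#' the subset minimising `GCV = RSS / (n (1 - C(M)/n)^2)` with
#' `C(M) = M + penalty * (M - 1) / 2`.
#'
#' @param x numeric predictor matrix (markers coded -1/+1, or any
#'   numeric covariates).
#' @param y response vector.
#' @param max_terms forward-pass cap; default
#'   `min(2 * ncol(x) + 1, floor(n / 2), 41)`.
#' @param degree maximum interaction degree (capped at 2).
#' @param penalty GCV cost per knot.
#' @param max_knots per-variable cap on candidate knots (quantile
#'   thinning for continuous predictors).
#' @return a `mars_model`: surviving terms (with marker ids, knots and
#'   hinge directions), coefficients, GCV, fitted values.
#' @export
mars_fit <- function(x, y, max_terms = NULL, degree = 2, penalty = 3,
                     max_knots = 20) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  max_terms <- max_terms %||% min(2L * ncol(x) + 1L, n %/% 2L, 41L)
  if (max_terms < 3) stop("max_terms must be >= 3")
  if (degree > 2) stop("interaction degree is capped at 2")
  fw <- .mars_forward(x, y, as.integer(max_terms), as.integer(degree),
                      as.integer(max_knots))
  B <- fw$B
  M <- ncol(B)
  # effective-parameter count: coefficients + penalty per knot, where a
  # knot is one forward selection event (a reflected pair shares a knot)
  gcv_of <- function(rss, cols) {
    cM <- length(cols) + penalty * length(unique(fw$event[cols][cols > 1]))
    if (cM >= n) return(Inf)
    rss / (n * (1 - cM / n)^2)
  }
  rss_of <- function(cols) {
    f <- .lm.fit(B[, cols, drop = FALSE], y)
    sum(f$residuals^2)
  }
  # backward pruning: drop the term whose removal hurts RSS least,
  # tracking the best GCV along the deletion path
  current <- seq_len(M)
  best_cols <- current
  best_gcv <- gcv_of(rss_of(current), current)
  path_cols <- current
  while (length(path_cols) > 1) {
    cand <- path_cols[-1] # never drop the intercept
    rs <- vapply(cand, function(j) rss_of(setdiff(path_cols, j)), 0)
    drop_j <- cand[which.min(rs)]
    path_cols <- setdiff(path_cols, drop_j)
    g <- gcv_of(min(rs), path_cols)
    if (g <= best_gcv) { best_gcv <- g; best_cols <- path_cols }
  }
  # interaction-vs-additivity refinement: a surviving degree-2 product
  # can act as a proxy for a main effect the model lacks. Try swapping
  # each product for the marginal hinge(s) of its markers; adopt a swap
  # when it does not worsen the GCV. A genuine interaction loses fit
  # under every swap and survives.
  gcv_count <- function(rss, M, K) {
    cM <- M + penalty * K
    if (cM >= n) return(Inf)
    rss / (n * (1 - cM / n)^2)
  }
  rss_mat <- function(mat) sum(.lm.fit(mat, y)$residuals^2)
  h_col <- function(v, k, d) pmax(if (d > 0) x[, v] - k else k - x[, v], 0)
  add_term <- function(v, k, d, col) {
    fw$v1 <<- c(fw$v1, v); fw$k1 <<- c(fw$k1, k); fw$d1 <<- c(fw$d1, d)
    fw$v2 <<- c(fw$v2, 0L); fw$k2 <<- c(fw$k2, 0); fw$d2 <<- c(fw$d2, 0L)
    fw$event <<- c(fw$event, max(fw$event) + 1L)
    B <<- cbind(B, col)
    ncol(B)
  }
  n_knots <- function(cols) length(unique(fw$event[cols][cols > 1]))
  repeat {
    improved <- FALSE
    for (j in best_cols[fw$v1[best_cols] > 0 & fw$v2[best_cols] > 0]) {
      specs <- list(c(fw$v1[j], fw$k1[j], fw$d1[j]),
                    c(fw$v2[j], fw$k2[j], fw$d2[j]))
      cols <- lapply(specs, function(s) h_col(s[1], s[2], s[3]))
      base_cols <- setdiff(best_cols, j)
      gcv_cur <- gcv_count(rss_mat(B[, best_cols, drop = FALSE]),
                           length(best_cols), n_knots(best_cols))
      for (alt in list(1L, 2L, 1:2)) {
        Balt <- cbind(B[, base_cols, drop = FALSE],
                      do.call(cbind, cols[alt]))
        g_alt <- gcv_count(rss_mat(Balt), ncol(Balt),
                           n_knots(base_cols) + length(alt))
        if (g_alt <= gcv_cur + 1e-12) {
          new_cols <- vapply(alt, function(a)
            add_term(specs[[a]][1], specs[[a]][2], specs[[a]][3],
                     cols[[a]]), 0L)
          best_cols <- c(base_cols, new_cols)
          best_gcv <- g_alt
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  fit <- .lm.fit(B[, best_cols, drop = FALSE], y)
  cf <- numeric(length(best_cols))
  cf[fit$pivot] <- fit$coefficients # .lm.fit returns pivoted coefficients
  cf[is.na(cf)] <- 0
  i1 <- fw$v1[best_cols]; i2 <- fw$v2[best_cols]
  terms <- data.frame(
    term = best_cols,
    var1 = ifelse(i1 > 0, colnames(x)[pmax(i1, 1)], NA),
    knot1 = fw$k1[best_cols], dir1 = fw$d1[best_cols],
    var2 = ifelse(i2 > 0, colnames(x)[pmax(i2, 1)], NA),
    knot2 = fw$k2[best_cols], dir2 = fw$d2[best_cols],
    coef = cf, row.names = NULL)
  structure(list(terms = terms, gcv = best_gcv,
                 rss = sum(fit$residuals^2),
                 fitted = as.vector(B[, best_cols, drop = FALSE] %*% cf),
                 forward_rss = fw$rss_trace,
                 forward_gcv = gcv_of(fw$rss_trace[length(fw$rss_trace)],
                                      seq_len(M)),
                 n = n, penalty = penalty, var_names = colnames(x)),
            class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("<mars_model> %d terms (of which %d interactions), GCV %.4g\n",
              nrow(x$terms), sum(!is.na(x$terms$var2)), x$gcv))
  invisible(x)
}

#' Evaluate a fitted MARS model on new data
#' @param object a `mars_model`.
#' @param x_new numeric matrix with the training columns.
#' @param ... unused.
#' @export
predict.mars_model <- function(object, x_new, ...) {
  h <- function(v, knot, dir) pmax(if (dir > 0) v - knot else knot - v, 0)
  out <- rep(0, nrow(x_new))
  for (i in seq_len(nrow(object$terms))) {
    tm <- object$terms[i, ]
    b <- rep(1, nrow(x_new))
    if (!is.na(tm$var1)) b <- b * h(x_new[, tm$var1], tm$knot1, tm$dir1)
    if (!is.na(tm$var2)) b <- b * h(x_new[, tm$var2], tm$knot2, tm$dir2)
    out <- out + tm$coef * b
  }
  unname(out)
}

#' Marker pairs carried by surviving degree-2 MARS terms
#' @param model a `mars_model`.
#' @return data frame (`marker1`, `marker2`) of distinct unordered pairs
#'   (lexicographically ordered within pair).
#' @export
mars_pairs <- function(model) {
  tm <- model$terms[!is.na(model$terms$var1) & !is.na(model$terms$var2), ]
  if (!nrow(tm)) return(data.frame(marker1 = character(),
                                   marker2 = character()))
  pairs <- t(apply(tm[, c("var1", "var2")], 1, sort))
  unique(data.frame(marker1 = pairs[, 1], marker2 = pairs[, 2],
                    row.names = NULL))
}

#' Stability selection of epistatic SNP pairs
#'
#' Runs `runs` rounds of `k`-fold cross-validation: in each round a MARS
#' model is fitted on every training fold, and a marker pair is credited
#' for the round when a degree-2 term on it appears in the majority of
#' that round's fold models. Pairs credited in at least half the rounds
#' are reported with their stability count and mean absolute
#' coefficient.
#'
#' @param x numeric line-by-tag matrix (selected tag SNPs).
#' @param ebv named breeding-value vector.
#' @param runs rounds of cross-validation.
#' @param k folds per round.
#' @param seed integer seed.
#' @param region label stored in the result.
#' @param stability_min minimum rounds for reporting (default
#'   `ceiling(runs / 2)`).
#' @param ... passed to [mars_fit()] (e.g. `penalty`, `max_terms`).
#' @return an `interaction_set`: data frame of pairs with `stability`
#'   and `mean_abs_coef`, plus the run design.
#' @export
select_interactions <- function(x, ebv, runs = 10, k = 10, seed = 1L,
                                region = NA, stability_min = NULL, ...) {
  stability_min <- stability_min %||% ceiling(runs / 2)
  x <- x[names(ebv), order(colnames(x)), drop = FALSE]
  n <- nrow(x)
  credit <- list(); coefs <- list()
  set.seed(seed)
  for (r in seq_len(runs)) {
    fold <- sample(rep_len(seq_len(k), n))
    pair_count <- list()
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- mars_fit(x[tr, , drop = FALSE], ebv[tr], ...)
      pr <- mars_pairs(m)
      if (!nrow(pr)) next
      keys <- paste(pr$marker1, pr$marker2, sep = "\r")
      for (key in keys)
        pair_count[[key]] <- (pair_count[[key]] %||% 0L) + 1L
      tm <- m$terms[!is.na(m$terms$var1) & !is.na(m$terms$var2), ]
      tkey <- paste(pmin(tm$var1, tm$var2), pmax(tm$var1, tm$var2),
                    sep = "\r")
      for (i in seq_along(tkey))
        coefs[[tkey[i]]] <- c(coefs[[tkey[i]]], abs(tm$coef[i]))
    }
    won <- names(pair_count)[unlist(pair_count) > k / 2]
    for (key in won) credit[[key]] <- (credit[[key]] %||% 0L) + 1L
  }
  keys <- names(credit)[unlist(credit) >= stability_min]
  pairs <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(marker1 = parts[, 1], marker2 = parts[, 2],
               stability = unlist(credit[keys], use.names = FALSE),
               mean_abs_coef = vapply(keys, function(z)
                 mean(coefs[[z]] %||% NA_real_), 0, USE.NAMES = FALSE))
  } else data.frame(marker1 = character(), marker2 = character(),
                    stability = integer(), mean_abs_coef = numeric())
  pairs <- pairs[order(-pairs$stability, pairs$marker1, pairs$marker2), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(region = region, pairs = pairs, runs = runs, k = k,
                 stability_min = stability_min),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set:%s> %d pair(s), stability >= %d of %d\n",
              x$region, nrow(x$pairs), x$stability_min, x$runs))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Cross-region replication of epistatic pairs
#'
#' @param sets named list of `interaction_set`s (one per region).
#' @return data frame (`marker1`, `marker2`, one logical column per
#'   region, `n_regions`); pairs found in >= 2 regions are the
#'   replicated ones.
#' @export
replicate_across_regions <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 regions")
  keyed <- lapply(sets, function(s)
    paste(s$pairs$marker1, s$pairs$marker2, sep = "\r"))
  all_keys <- sort(unique(unlist(keyed)))
  member <- vapply(keyed, function(kk) all_keys %in% kk,
                   logical(length(all_keys)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(all_keys))
  colnames(member) <- names(sets)
  parts <- if (length(all_keys))
    do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
    else matrix(character(), 0, 2)
  data.frame(marker1 = parts[, 1], marker2 = parts[, 2], member,
             n_regions = rowSums(member), row.names = NULL)
}
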