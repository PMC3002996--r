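#' Rank genes by a phenotype score
#'
#' Orders genes by descending score (ties broken by gene id, so the order is
#' stable and reproducible). Typical phenotypes: mean day-0 acetylation,
#' day-5 acetylation change, day-5 expression change.
#'
#' @param scores Named numeric vector (names = gene ids), or a data.frame
#'   with columns `gene_id` and `score`.
#' @param phenotype Free-text phenotype name.
#' @return Object of class `ranked_list`: list with `genes` (ordered ids),
#'   `scores` (named, same order), `phenotype`.
#' @export
rank_genes <- function(scores, phenotype = "score") {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$gene_id)
  }
  if (is.null(names(scores))) stop("scores must be named by gene", call. = FALSE)
  if (anyDuplicated(names(scores))) {
    stop("duplicate gene ids in scores", call. = FALSE)
  }
  drop_n <- sum(is.na(scores))
  if (drop_n > 0) {
    message(sprintf("dropping %d gene(s) with missing scores", drop_n))
    scores <- scores[!is.na(scores)]
  }
  ord <- order(-scores, names(scores))
  structure(list(genes = names(scores)[ord], scores = scores[ord],
                 phenotype = phenotype),
            class = "ranked_list")
}

#' Weighted running-sum enrichment score of a gene set
#'
#' Walks down the ranked list and accumulates a running sum: hitting a
#' gene-set member increments by `|score|^weight_exponent` normalized over
#' the hits; missing decrements by `1 / (N - N_hit)`. The enrichment score
#' is the extremum of the running sum (signed), positive when the set
#' concentrates at the top of the list, negative at the bottom. With
#' `weight_exponent = 0` this is the classic unweighted Kolmogorov-Smirnov
#' statistic, invariant under monotone transformations of the scores.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Exponent on `|score|` for hit increments.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- ranked$genes %in% gene_set
  n <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (n_hit == n) stop("gene set covers the whole list", call. = FALSE)
  w <- abs(ranked$scores)^weight_exponent
  inc <- numeric(n)
  denom <- sum(w[hit])
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / n_hit
  inc[!hit] <- -1 / (n - n_hit)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Permutation p-value for an enrichment score
#'
#' The background distribution comes from random gene-label reassignment:
#' each permutation scores a uniformly drawn gene set of the same size. The
#' reported empirical p-value is
#' `(1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)` (add-one, so p is never
#' exactly zero).
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed.
#' @param set_name Name recorded in the result.
#' @return Object of class `enrichment_result`: list with `set`,
#'   `phenotype`, `es`, `p`, `n_perm`, `direction` (`"top"` or
#'   `"bottom"`).
#' @export
empirical_pvalue <- function(ranked, gene_set, n_perm = 1000, seed = 1L,
                             weight_exponent = 1, set_name = "set") {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  es <- enrichment_score(ranked, gene_set, weight_exponent)
  k <- sum(ranked$genes %in% gene_set)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm_set <- sample(ranked$genes, k)
    if (abs(enrichment_score(ranked, perm_set, weight_exponent)) >= abs(es)) {
      exceed <- exceed + 1L
    }
  }
  structure(list(set = set_name, phenotype = ranked$phenotype, es = es,
                 p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
                 direction = if (es >= 0) "top" else "bottom"),
            class = "enrichment_result")
}

#' Enrichment panel: every gene set against every phenotype ordering
#'
#' One enrichment test per (phenotype, gene set) pair; no multiple-testing
#' correction is applied (the panel is small by design, e.g. five sets
#' against three orderings gives 15 tests).
#'
#' @param score_tables Named list of score vectors (or [rank_genes()]
#'   results), one per phenotype.
#' @param gene_sets Named list of gene-id vectors.
#' @inheritParams empirical_pvalue
#' @return data.frame with one row per pair: `phenotype`, `set`, `es`, `p`,
#'   `n_perm`, `direction`.
#' @export
enrichment_panel <- function(score_tables, gene_sets, n_perm = 1000,
                             seed = 1L, weight_exponent = 1) {
  rows <- list()
  for (ph in names(score_tables)) {
    ranked <- score_tables[[ph]]
    if (!inherits(ranked, "ranked_list")) ranked <- rank_genes(ranked, ph)
    for (gs in names(gene_sets)) {
      r <- empirical_pvalue(ranked, gene_sets[[gs]], n_perm = n_perm,
                            seed = derive_seed(seed, paste0(ph, ".", gs)),
                            weight_exponent = weight_exponent, set_name = gs)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, set = gs, es = r$es, p = r$p, n_perm = r$n_perm,
        direction = r$direction, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(phenotype = character(), set = character(),
                      es = numeric(), p = numeric(), n_perm = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard phenotype scores for the enrichment panel
#'
#' Builds the three orderings used to characterize gene sets: mean day-0
#' acetylation signal, acetylation change on the final day, and expression
#' change on the final day.
#'
#' @param binned A [bin_profiles()] result.
#' @param changes A [build_changes()] result.
#' @param day Final day (default: last day in `changes`).
#' @return Named list of three named score vectors.
#' @export
phenotype_scores <- function(binned, changes, day = NULL) {
  day <- day %||% max(changes$days)
  col <- paste0("day", day)
  p0 <- profile_matrix(binned, 0)
  list(
    acet_day0_mean = rowMeans(p0)[changes$genes],
    acet_change = changes$A[, col],
    expr_change = changes$E[, col])
}
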