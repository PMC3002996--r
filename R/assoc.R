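#' Build aligned acetylation-change and expression-change matrices
#'
#' Anchors the analysis on day 0: for every later day `t`, the expression
#' change is mean expression on day `t` minus mean expression on day 0 (over
#' replicates), and the acetylation change is the profile summary (mean or
#' median over the bins) on day `t` minus the summary on day 0. Per-day full
#' change profiles (genes x bins) are kept alongside the summaries.
#'
#' @param binned A [bin_profiles()] result.
#' @param expr_table Expression table (replicates are averaged here).
#' @param summary `"mean"` or `"median"` bin summary for the acetylation side.
#' @return Object of class `change_matrices`: list with `A` (genes x days
#'   acetylation change), `E` (genes x days expression change), `profiles`
#'   (named list of genes x bins change matrices, one per day), `days`
#'   (days after 0), `genes`, `summary`.
#' @export
build_changes <- function(binned, expr_table, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  sfun <- if (summary == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  expr <- average_replicates(expr_table)
  days_all <- sort(unique(binned$day))
  if (!0 %in% days_all) stop("day 0 missing from profiles", call. = FALSE)
  days <- setdiff(days_all, 0)

  e0 <- expr[expr$day == 0, ]
  genes <- intersect(unique(binned$gene_id), e0$gene_id)
  dropped <- length(unique(binned$gene_id)) - length(genes)
  if (dropped > 0) {
    warning(sprintf("%d gene(s) without day-0 expression excluded", dropped))
  }
  p0 <- profile_matrix(binned, 0)[genes, , drop = FALSE]
  s0 <- sfun(p0)
  e0v <- stats::setNames(e0$expression, e0$gene_id)[genes]

  A <- E <- matrix(NA_real_, length(genes), length(days),
                   dimnames = list(genes, paste0("day", days)))
  profiles <- stats::setNames(vector("list", length(days)), paste0("day", days))
  for (j in seq_along(days)) {
    pt <- profile_matrix(binned, days[j])[genes, , drop = FALSE]
    A[, j] <- sfun(pt) - s0
    profiles[[j]] <- pt - p0
    et <- expr[expr$day == days[j], ]
    E[, j] <- stats::setNames(et$expression, et$gene_id)[genes] - e0v
  }
  structure(list(A = A, E = E, profiles = profiles, days = days,
                 genes = genes, summary = summary),
            class = "change_matrices")
}

#' Day-pair correlation matrix between acetylation and expression changes
#'
#' Entry (s, t) is the genome-wide correlation between the acetylation-change
#' summary on day `s` and the expression change on day `t`, with the analytic
#' p-value from the standard null for the chosen method.
#'
#' @param changes A [build_changes()] result.
#' @param method `"pearson"` or `"spearman"`.
#' @return Object of class `correlation_report`: list with `r` (acet day x
#'   expr day matrix), `p` (analytic p-values), `method`, `n`. Entries with a
#'   zero-variance column are `NA`.
#' @export
correlation_matrix <- function(changes, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- changes$A
  E <- changes$E
  if (nrow(A) < 3L) stop("need at least 3 genes", call. = FALSE)
  nd <- ncol(A)
  r <- p <- matrix(NA_real_, nd, nd,
                   dimnames = list(acet = colnames(A), expr = colnames(E)))
  for (s in seq_len(nd)) {
    for (t in seq_len(nd)) {
      if (stats::sd(A[, s]) == 0 || stats::sd(E[, t]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(A[, s], E[, t], method = method, exact = FALSE))
      r[s, t] <- unname(ct$estimate)
      p[s, t] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, method = method, n = nrow(A)),
            class = "correlation_report")
}

#' Structure-preserving permutation p-values for the correlation matrix
#'
#' The analytic null assumes independent genes, which genomic data violate.
#' Here each permutation applies one random gene relabelling to the whole
#' expression matrix (all days jointly), preserving the inter-day and
#' inter-gene correlation structure within each data layer, and the full
#' day-pair correlation matrix is recomputed. The empirical p-value is
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)` per entry.
#'
#' @inheritParams correlation_matrix
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed.
#' @return The [correlation_matrix()] report with an added `p_perm` matrix
#'   and `n_perm`.
#' @export
permutation_significance <- function(changes, method = c("pearson", "spearman"),
                                     n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  obs <- correlation_matrix(changes, method)
  A <- changes$A
  E <- changes$E
  n <- nrow(A)
  exceed <- matrix(0, nrow(obs$r), ncol(obs$r))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    Ep <- E[sample.int(n), , drop = FALSE]
    rp <- stats::cor(A, Ep, method = method)
    exceed <- exceed + (abs(rp) >= abs(obs$r))
  }
  obs$p_perm <- (1 + exceed) / (1 + n_perm)
  dimnames(obs$p_perm) <- dimnames(obs$r)
  obs$n_perm <- n_perm
  obs
}

#' One-dimensional canonical correlation of a profile block with expression
#'
#' With a one-dimensional expression block, CCA reduces to the multiple
#' correlation of the expression change on the bins: the canonical
#' correlation equals the square root of the R-squared of the least-squares
#' fit, and the weight vector is the coefficient vector scaled to unit
#' variance of the canonical variate. Summarizing the profile by its mean
#' corresponds to fixing equal weights, so the canonical correlation is
#' always at least the mean-summary correlation in magnitude.
#'
#' @param X Numeric matrix genes x bins (change profiles).
#' @param y Numeric vector of expression changes.
#' @param ridge_eps Ridge added to the cross-product when `X` is
#'   rank-deficient.
#' @return List with `weights` (length `ncol(X)`), `rho` (canonical
#'   correlation in `[0, 1]`).
#' @export
cca_1d <- function(X, y, ridge_eps = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more genes than bins", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  if (rcond(G) < 1e-12) G <- G + diag(ridge_eps * mean(diag(G)), ncol(G))
  a <- solve(G, crossprod(Xc, yc))
  v <- drop(Xc %*% a)
  rho <- if (stats::sd(v) == 0 || stats::sd(yc) == 0) 0 else
    abs(stats::cor(v, yc))
  sdv <- stats::sd(v)
  if (sdv > 0) a <- a / sdv
  list(weights = drop(a), rho = rho)
}

#' Shrinkage estimate of the partial-correlation matrix
#'
#' Estimates the correlation matrix with analytic shrinkage toward the
#' identity (the Ledoit-Wolf/Schaefer-Strimmer estimator): the intensity
#' \eqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) / \sum_{i \ne j}
#' r_{ij}^2}, clipped to `[0, 1]`, guarantees a positive-definite,
#' invertible estimate even with more variables than observations. Partial
#' correlations come from the standardized inverse:
#' \eqn{\rho_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}}.
#'
#' @param X Numeric matrix observations (genes) x variables, e.g. stacked
#'   binned profiles over several days.
#' @param lambda Optional fixed shrinkage intensity; `NULL` estimates it
#'   analytically. Forcing `lambda = 0` with fewer rows than columns is an
#'   error (the sample correlation matrix would be singular).
#' @param group Free-text tag describing the gene group.
#' @return Object of class `pcor_result`: list with `pcor` (symmetric,
#'   unit-diagonal matrix), `lambda`, `n`, `labels`, `group`.
#' @export
shrinkage_pcor <- function(X, lambda = NULL, group = "all") {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!is.null(lambda) && lambda == 0 && n <= p) {
    stop("fewer rows than columns requires shrinkage > 0", call. = FALSE)
  }
  labels <- colnames(X) %||% paste0("v", seq_len(p))
  Z <- scale(X)  # unit-variance standardization
  Z[is.nan(Z)] <- 0
  R <- crossprod(Z) / (n - 1)
  if (is.null(lambda)) {
    # analytic intensity: sum of estimated variances of r_ij over sum r_ij^2
    num <- 0
    den <- 0
    for (j in seq_len(p - 1L)) {
      W <- Z[, j] * Z[, (j + 1L):p, drop = FALSE]
      wbar <- colMeans(W)
      vr <- n / ((n - 1)^3) * colSums(sweep(W, 2, wbar)^2)
      num <- num + sum(vr)
      den <- den + sum((R[j, (j + 1L):p])^2)
    }
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  }
  Rs <- (1 - lambda) * R + lambda * diag(p)
  omega <- solve(Rs)
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- list(labels, labels)
  structure(list(pcor = pc, lambda = lambda, n = n, labels = labels,
                 group = group),
            class = "pcor_result")
}

#' Stack binned profiles over several days into one variable block
#'
#' Produces the genes x (bins * days) matrix whose conditional-independence
#' structure the partial-correlation analysis describes; variables are
#' labelled `b<bin>.d<day>`.
#'
#' @param binned A [bin_profiles()] result.
#' @param days Days to stack (default: all days after 0).
#' @param genes Optional subset of gene ids.
#' @return Numeric matrix genes x (bins * length(days)).
#' @export
stack_profiles <- function(binned, days = NULL, genes = NULL) {
  all_days <- sort(unique(binned$day))
  days <- days %||% setdiff(all_days, 0)
  mats <- lapply(days, function(d) {
    m <- profile_matrix(binned, d)
    colnames(m) <- sprintf("b%d.d%s", seq_len(ncol(m)), d)
    m
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  if (!is.null(genes)) common <- intersect(common, genes)
  do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
}

#' Significant edges of a partial-correlation graph
#'
#' Tests each partial correlation with the Fisher z-transform using effective
#' degrees of freedom `n - p - 1` (n observations, p variables), applies
#' Benjamini-Hochberg across all pairs, and keeps edges with q-value at most
#' `cutoff`.
#'
#' @param pcor_result A [shrinkage_pcor()] result.
#' @param cutoff BH q-value cutoff for an edge.
#' @return data.frame with `var_a`, `var_b`, `pcor`, `p`, `q`, sorted by
#'   `q`; zero rows when nothing is significant.
#' @export
pcor_edges <- function(pcor_result, cutoff = 0.05) {
  pc <- pcor_result$pcor
  p <- ncol(pc)
  n <- pcor_result$n
  kappa <- n - p - 1
  if (kappa < 1) stop("too few observations for edge tests", call. = FALSE)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  r <- pc[ut]
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r) * sqrt(kappa)
  pv <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(pv, method = "BH")
  out <- data.frame(var_a = pcor_result$labels[ut[, 1]],
                    var_b = pcor_result$labels[ut[, 2]],
                    pcor = pc[ut], p = pv, q = q,
                    stringsAsFactors = FALSE)
  out <- out[out$q <= cutoff, , drop = FALSE]
  out[order(out$q, -abs(out$pcor)), , drop = FALSE]
}

#' Difference between two partial-correlation matrices
#'
#' @param pcor_a,pcor_b [shrinkage_pcor()] results with identical variable
#'   labels (e.g. differential vs. non-differential gene groups).
#' @return Elementwise difference matrix `pcor_a - pcor_b`.
#' @export
group_difference <- function(pcor_a, pcor_b) {
  if (!identical(pcor_a$labels, pcor_b$labels)) {
    stop("variable labels differ between the two results", call. = FALSE)
  }
  pcor_a$pcor - pcor_b$pcor
}
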