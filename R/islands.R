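#' Fit the control-probe background null per day
#'
#' The control probes are designed to be un-acetylated and provide the
#' negative control; per day we estimate a robust location (median) and scale
#' (MAD-derived sigma) of their replicate-averaged signal. Because day-to-day
#' variability of the background is itself estimated from limited data, the
#' per-day scale is shrunk toward the pooled cross-day scale:
#' \deqn{\hat\sigma_d = \lambda_d s_d + (1 - \lambda_d) s_{pooled}, \quad
#'       \lambda_d = n_d / (n_d + n_0)}
#' where \eqn{n_d} is the number of control probes on day `d` and `n0` the
#' shrinkage prior weight.
#'
#' @param probe_table Probe table containing control probes (`gene_id` `NA`);
#'   replicates are averaged per (probe, day) before fitting.
#' @param min_controls Minimum control probes required per day.
#' @param n0 Prior weight governing shrinkage toward the pooled scale.
#' @return An object of class `null_model`: data.frame with one row per day
#'   (`day`, `n`, `location`, `scale_day`, `lambda`, `scale`) plus a
#'   `pooled_scale` attribute. `scale` is the shrunken value used downstream.
#' @export
fit_null <- function(probe_table, min_controls = 50, n0 = 50) {
  ctrl <- probe_table[is.na(probe_table$gene_id), , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no control probes in table", call. = FALSE)
  ctrl <- average_replicates(ctrl)
  days <- sort(unique(ctrl$day))
  n_d <- vapply(days, function(d) sum(ctrl$day == d), 1L)
  if (any(n_d < min_controls)) {
    stop(sprintf("need at least %d control probes per day (min found: %d)",
                 min_controls, min(n_d)), call. = FALSE)
  }
  loc <- vapply(days, function(d) stats::median(ctrl$signal[ctrl$day == d]), 1)
  sc <- vapply(days, function(d) {
    stats::mad(ctrl$signal[ctrl$day == d])
  }, 1)
  pooled <- stats::mad(ctrl$signal - loc[match(ctrl$day, days)], center = 0)
  lambda <- n_d / (n_d + n0)
  out <- data.frame(day = days, n = n_d, location = loc, scale_day = sc,
                    lambda = lambda, scale = lambda * sc + (1 - lambda) * pooled)
  attr(out, "pooled_scale") <- pooled
  class(out) <- c("null_model", "data.frame")
  out
}

null_params <- function(null_model, day) {
  i <- match(day, null_model$day)
  if (is.na(i)) stop(sprintf("day %s not in null model", day), call. = FALSE)
  list(location = null_model$location[i], scale = null_model$scale[i])
}

#' Call per-probe acetylation states against the background null
#'
#' Each gene-assigned probe's replicate-averaged signal is compared against
#' the day's background null (one-sided, upper tail: acetylation is signal
#' above the noise), giving a p-value per probe per day. P-values are
#' Benjamini-Hochberg corrected across all probes within a day, and a probe
#' is called acetylated when its q-value is at most `fdr`.
#'
#' @param probe_table Probe table (controls allowed; they are ignored here).
#' @param null_model A [fit_null()] result covering the table's days.
#' @param fdr FDR cutoff on the within-day q-value distribution.
#' @return An object of class `state_matrix`: a long data.frame with columns
#'   `gene_id`, `probe_id`, `offset_bp`, `day`, `signal`, `p`, `q`,
#'   `acetylated`.
#' @export
call_states <- function(probe_table, null_model, fdr = 0.10) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("fdr must lie in (0, 1)", call. = FALSE)
  }
  gp <- probe_table[!is.na(probe_table$gene_id), , drop = FALSE]
  gp <- average_replicates(gp)
  days <- sort(unique(gp$day))
  res <- lapply(days, function(d) {
    sub <- gp[gp$day == d, , drop = FALSE]
    pr <- null_params(null_model, d)
    if (pr$scale < 1e-12) {
      p <- ifelse(sub$signal > pr$location, 0, 1)
    } else {
      p <- stats::pnorm(sub$signal, mean = pr$location, sd = pr$scale,
                        lower.tail = FALSE)
    }
    q <- stats::p.adjust(p, method = "BH")
    data.frame(gene_id = sub$gene_id, probe_id = sub$probe_id,
               offset_bp = sub$offset_bp, day = d, signal = sub$signal,
               p = p, q = q, acetylated = q <= fdr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "fdr") <- fdr
  attr(out, "days") <- days
  class(out) <- c("state_matrix", "data.frame")
  out
}

#' Summarize probe-state transitions between two days
#'
#' For each gene, conditional on the state at `day_a`: `p_stay_ac` is the
#' fraction of probes acetylated at `day_a` that remain acetylated at
#' `day_b`; `p_stay_unac` is the analogous fraction for un-acetylated probes.
#' Genes with fewer than `min_state_count` probes in either state at `day_a`
#' are flagged `discarded` because their estimates would be unstable.
#'
#' @param state_matrix A [call_states()] result.
#' @param day_a,day_b The day pair (conditioning day first).
#' @param min_state_count Minimum probes per state at `day_a`.
#' @return Object of class `transition_summary`: data.frame with `gene_id`,
#'   `n_unac`, `n_ac`, `p_stay_unac`, `p_stay_ac`, `discarded`.
#' @export
transition_summary <- function(state_matrix, day_a, day_b,
                               min_state_count = 3) {
  cnt <- transition_counts(state_matrix, day_a, day_b)
  finish_transitions(cnt, min_state_count)
}

# per-gene counts: unac->unac / unac total, ac->ac / ac total, for one pair
transition_counts <- function(state_matrix, day_a, day_b) {
  a <- state_matrix[state_matrix$day == day_a, c("gene_id", "probe_id",
                                                 "acetylated")]
  b <- state_matrix[state_matrix$day == day_b, c("probe_id", "acetylated")]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both days must be present in the state matrix", call. = FALSE)
  }
  m <- merge(a, b, by = "probe_id", suffixes = c("_a", "_b"))
  ac_a <- m$acetylated_a
  ac_b <- m$acetylated_b
  g <- m$gene_id
  data.frame(
    gene_id = sort(unique(g)),
    n_unac = as.integer(tapply(!ac_a, g, sum)),
    n_ac = as.integer(tapply(ac_a, g, sum)),
    stay_unac = as.integer(tapply(!ac_a & !ac_b, g, sum)),
    stay_ac = as.integer(tapply(ac_a & ac_b, g, sum)),
    stringsAsFactors = FALSE)
}

finish_transitions <- function(cnt, min_state_count) {
  out <- data.frame(
    gene_id = cnt$gene_id,
    n_unac = cnt$n_unac,
    n_ac = cnt$n_ac,
    p_stay_unac = ifelse(cnt$n_unac > 0, cnt$stay_unac / cnt$n_unac, NA_real_),
    p_stay_ac = ifelse(cnt$n_ac > 0, cnt$stay_ac / cnt$n_ac, NA_real_),
    discarded = pmin(cnt$n_unac, cnt$n_ac) < min_state_count,
    stringsAsFactors = FALSE)
  class(out) <- c("transition_summary", "data.frame")
  out
}

#' Pooled probe-state transitions over all consecutive day pairs
#'
#' Pools the per-gene transition counts over every consecutive day pair,
#' assuming the change distribution is the same for all time points, then
#' forms the stay probabilities from the pooled counts.
#'
#' @inheritParams transition_summary
#' @return A `transition_summary` as in [transition_summary()].
#' @export
pooled_transition_summary <- function(state_matrix, min_state_count = 3) {
  days <- attr(state_matrix, "days") %||% sort(unique(state_matrix$day))
  if (length(days) < 2L) stop("need at least two days", call. = FALSE)
  pairs <- lapply(seq_len(length(days) - 1L), function(i) {
    transition_counts(state_matrix, days[i], days[i + 1L])
  })
  pooled <- pairs[[1]]
  for (p in pairs[-1]) {
    m <- match(p$gene_id, pooled$gene_id)
    for (col in c("n_unac", "n_ac", "stay_unac", "stay_ac")) {
      pooled[[col]][m] <- pooled[[col]][m] + p[[col]]
    }
  }
  finish_transitions(pooled, min_state_count)
}
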