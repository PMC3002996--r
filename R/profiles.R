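#' Bin a gene's probe signals into a fixed-length TSS profile
#'
#' Genes are represented by different numbers of probes at varying positions;
#' to make profiles comparable between genes, probes are averaged in
#' equi-distant bins around the TSS. With the defaults (0.5 kb bins over
#' +/-3.5 kb) a profile has exactly 14 entries; bin `k` (1-based) covers
#' `[-3500 + 500(k-1), -3500 + 500k)` bp, with the right window edge included
#' in the last bin. Only signal above background enters: each probe
#' contributes `max(signal - location, 0)` where `location` is the day's
#' background-null location, so binning does not depend on the FDR cutoff
#' used for island calls. Bins with no probes, or none above background, are
#' zero.
#'
#' @param offsets Signed probe offsets to the TSS in bp.
#' @param signals Probe signals (replicate-averaged).
#' @param bg_location Background location for the day (from [fit_null()]).
#' @param window_bp Half-width of the profile window.
#' @param bin_bp Bin width in bp.
#' @return Numeric vector of per-bin means (length `2 * window_bp / bin_bp`).
#' @export
bin_profile <- function(offsets, signals, bg_location = 0,
                        window_bp = 3500, bin_bp = 500) {
  n_bins <- as.integer(2 * window_bp / bin_bp)
  keep <- !is.na(offsets) & abs(offsets) <= window_bp
  offsets <- offsets[keep]
  signals <- signals[keep]
  above <- pmax(signals - bg_location, 0)
  bin <- pmin(floor((offsets + window_bp) / bin_bp) + 1L, n_bins)
  out <- numeric(n_bins)
  if (length(bin) > 0L) {
    means <- tapply(above, factor(bin, levels = seq_len(n_bins)), mean)
    out[!is.na(means)] <- means[!is.na(means)]
  }
  out
}

#' Bin all genes and days of a probe table
#'
#' Vectorized application of [bin_profile()] across a probe table; replicates
#' are averaged first.
#'
#' @param probe_table Probe table (controls are ignored).
#' @param null_model A [fit_null()] result supplying per-day background
#'   locations (pass `NULL` for a zero background).
#' @inheritParams bin_profile
#' @return Object of class `binned_profiles`: data.frame with `gene_id`,
#'   `day`, and bin columns `b1`..`b14` (values >= 0).
#' @export
bin_profiles <- function(probe_table, null_model = NULL,
                         window_bp = 3500, bin_bp = 500) {
  n_bins <- as.integer(2 * window_bp / bin_bp)
  gp <- probe_table[!is.na(probe_table$gene_id), , drop = FALSE]
  gp <- average_replicates(gp)
  gp <- gp[abs(gp$offset_bp) <= window_bp, , drop = FALSE]
  loc <- if (is.null(null_model)) {
    rep(0, nrow(gp))
  } else {
    null_model$location[match(gp$day, null_model$day)]
  }
  above <- pmax(gp$signal - loc, 0)
  bin <- pmin(floor((gp$offset_bp + window_bp) / bin_bp) + 1L, n_bins)
  f_gene <- factor(gp$gene_id)
  f_day <- factor(gp$day)
  key <- interaction(f_gene, f_day, factor(bin, levels = seq_len(n_bins)),
                     drop = FALSE)
  sums <- rowsum(above, key)
  cnts <- rowsum(rep(1, length(above)), key)
  grid <- expand.grid(gene_id = levels(f_gene), day = levels(f_day),
                      bin = seq_len(n_bins), stringsAsFactors = FALSE)
  vals <- numeric(nrow(grid))
  present <- match(rownames(sums), levels(key))
  vals[present] <- sums[, 1] / cnts[, 1]
  # genes with no probe on a given day keep an all-zero row (they are rare
  # and flagged by the caller via the probe table itself)
  mat <- matrix(vals, ncol = n_bins)
  out <- data.frame(gene_id = grid$gene_id[seq_len(nrow(mat))],
                    day = as.numeric(grid$day[seq_len(nrow(mat))]),
                    mat, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("b", seq_len(n_bins))
  out <- out[order(out$day, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_profiles", "data.frame")
  out
}

#' Extract the bin matrix for one day
#'
#' @param binned A [bin_profiles()] result.
#' @param day Day to extract.
#' @return Numeric matrix genes x bins with gene ids as row names.
#' @export
profile_matrix <- function(binned, day) {
  sub <- binned[binned$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("day %s not in profiles", day), call. = FALSE)
  m <- as.matrix(sub[, grep("^b[0-9]+$", names(sub)), drop = FALSE])
  rownames(m) <- sub$gene_id
  m
}

# distance of a bin's center to the TSS (TSS sits between bins 7 and 8)
bin_tss_dist <- function(k, n_bins, window_bp = 3500) {
  bin_bp <- 2 * window_bp / n_bins
  abs(-window_bp + (k - 0.5) * bin_bp)
}

#' Find the peak region of a binned profile
#'
#' A peak is the smallest contiguous bin interval that contains the profile
#' maximum and covers at least `coverage` of the total signal. The interval
#' is grown greedily from the argmax: at each step the neighboring bin with
#' the larger signal is added; ties are broken toward the TSS, then leftward.
#' The argmax itself is tie-broken the same way.
#'
#' @param profile Numeric vector of non-negative bin values.
#' @param coverage Required fraction of total signal.
#' @return Object of class `peak_region`: list with 1-based inclusive bin
#'   interval `lo`, `hi` and `covered_fraction`. An all-zero profile returns
#'   the no-peak sentinel (`lo`, `hi`, `covered_fraction` all `NA`).
#' @export
find_peak <- function(profile, coverage = 0.30) {
  n <- length(profile)
  total <- sum(profile)
  if (total <= 0) {
    return(structure(list(lo = NA_integer_, hi = NA_integer_,
                          covered_fraction = NA_real_),
                     class = "peak_region"))
  }
  dist <- bin_tss_dist(seq_len(n), n)
  best <- order(-profile, dist, seq_len(n))[1]
  lo <- hi <- best
  covered <- profile[best]
  while (covered < coverage * total) {
    lval <- if (lo > 1L) profile[lo - 1L] else -Inf
    rval <- if (hi < n) profile[hi + 1L] else -Inf
    take_left <- if (lval > rval) {
      TRUE
    } else if (rval > lval) {
      FALSE
    } else {
      ld <- bin_tss_dist(lo - 1L, n)
      rd <- bin_tss_dist(hi + 1L, n)
      ld <= rd  # toward TSS, then leftward
    }
    if (take_left) {
      lo <- lo - 1L
      covered <- covered + profile[lo]
    } else {
      hi <- hi + 1L
      covered <- covered + profile[hi]
    }
  }
  structure(list(lo = lo, hi = hi, covered_fraction = covered / total),
            class = "peak_region")
}

#' Categorize the stability of a peak between two days
#'
#' Compares two peak intervals of the same gene and returns one of
#' `identical`, `contained`, `overlapping`, `disjoint` (in decreasing order
#' of agreement). With `mismatch_tol = t`, each interval endpoint may differ
#' by up to `t` bins before a category degrades: intervals are `identical`
#' if both endpoints agree within `t`, `contained` if one interval lies
#' within the other extended by `t`, and `overlapping` if the gap between
#' them is at most `t` bins.
#'
#' @param peak_a,peak_b [find_peak()] results for the same gene.
#' @param mismatch_tol Allowed per-endpoint mismatch in bins.
#' @return Character scalar category; `"undefined"` if either side is the
#'   no-peak sentinel.
#' @export
peak_stability <- function(peak_a, peak_b, mismatch_tol = 0) {
  if (is.na(peak_a$lo) || is.na(peak_b$lo)) return("undefined")
  t <- mismatch_tol
  a <- c(peak_a$lo, peak_a$hi)
  b <- c(peak_b$lo, peak_b$hi)
  if (all(abs(a - b) <= t)) return("identical")
  a_in_b <- a[1] >= b[1] - t && a[2] <= b[2] + t
  b_in_a <- b[1] >= a[1] - t && b[2] <= a[2] + t
  if (a_in_b || b_in_a) return("contained")
  if (max(a[1], b[1]) <= min(a[2], b[2]) + t) return("overlapping")
  "disjoint"
}

#' Per-bin change between two profiles of the same gene
#'
#' @param profile_t,profile_0 Numeric bin vectors of equal length.
#' @return `profile_t - profile_0`.
#' @export
delta_profile <- function(profile_t, profile_0) {
  stopifnot(length(profile_t) == length(profile_0))
  profile_t - profile_0
}

#' Per-bin quantile bands of a group of change profiles
#'
#' Summarizes the distribution of per-bin acetylation changes over a gene
#' group by empirical quantiles (linear interpolation), the standard
#' visualization for broad-loss/narrow-gain comparisons between regulation
#' classes.
#'
#' @param delta_profiles Numeric matrix, genes x bins.
#' @param probs Quantile levels.
#' @return Matrix `length(probs)` x bins with quantile levels as row names.
#' @export
quantile_band_summary <- function(delta_profiles,
                                  probs = c(0.10, 0.25, 0.75, 0.90)) {
  if (is.null(dim(delta_profiles))) {
    delta_profiles <- matrix(delta_profiles, nrow = 1)
  }
  if (nrow(delta_profiles) == 0L) {
    stop("empty gene group", call. = FALSE)
  }
  apply(delta_profiles, 2, stats::quantile, probs = probs, type = 7,
        names = TRUE)
}
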