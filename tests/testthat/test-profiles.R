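test_that("binning the default window yields exactly 14 bins", {
  prof <- bin_profile(offsets = 0, signals = 1, bg_location = 0)
  expect_length(prof, 14L)
  d <- shared_sim()
  b <- bin_profiles(d$probe_table)
  expect_equal(sum(grepl("^b[0-9]+$", names(b))), 14L)
  expect_true(all(as.matrix(b[, paste0("b", 1:14)]) >= 0))
})

test_that("bin arithmetic places probes in the documented half-open bins", {
  # one probe at +250 bp, 3.0 above background -> bin 8 (covers [0, 500) bp)
  prof <- bin_profile(offsets = 250, signals = 3, bg_location = 0)
  expect_equal(prof[8], 3)
  expect_equal(sum(prof), 3)
  # boundary cases: -3500 in bin 1; 0 in bin 8; +3500 clamps into bin 14
  expect_equal(which(bin_profile(-3500, 1) > 0), 1L)
  expect_equal(which(bin_profile(0, 1) > 0), 8L)
  expect_equal(which(bin_profile(3500, 1) > 0), 14L)
})

test_that("background handling zeroes empty and sub-background bins", {
  # all probes at or below background -> zero vector
  prof <- bin_profile(offsets = c(-1000, 0, 1000), signals = c(0.5, 1, 0.2),
                      bg_location = 1)
  expect_equal(prof, rep(0, 14))
  # probes uniformly c above background in every bin -> constant vector c
  off <- seq(-3500, 3400, by = 100)
  prof2 <- bin_profile(off, rep(3.5, length(off)), bg_location = 1.5)
  expect_equal(prof2, rep(2, 14))
})

test_that("binning is invariant to probe order and monotone in signal", {
  set.seed(5)
  off <- sample(seq(-3400, 3400, by = 248))
  sig <- runif(length(off), 0, 4)
  p1 <- bin_profile(off, sig)
  ord <- sample(length(off))
  expect_equal(bin_profile(off[ord], sig[ord]), p1)
  p2 <- bin_profile(off, sig + 1)
  expect_true(sum(p2) > sum(p1))
})

test_that("bin_profiles agrees with per-gene bin_profile", {
  d <- shared_sim()
  nm <- fit_null(d$probe_table)
  b <- bin_profiles(d$probe_table, nm)
  avg <- average_replicates(
    d$probe_table[!is.na(d$probe_table$gene_id), ])
  g <- d$truth$gene_id[5]
  for (day in c(0, 5)) {
    sub <- avg[avg$gene_id == g & avg$day == day, ]
    expected <- bin_profile(sub$offset_bp, sub$signal,
                            nm$location[nm$day == day])
    got <- as.numeric(b[b$gene_id == g & b$day == day, paste0("b", 1:14)])
    expect_equal(got, expected)
  }
})

test_that("peak finding matches hand-computed examples", {
  # single nonzero bin
  p <- find_peak(c(rep(0, 5), 7, rep(0, 8)))
  expect_equal(c(p$lo, p$hi), c(6, 6))
  expect_equal(p$covered_fraction, 1)
  # unimodal profile with total 20: bin value 9 >= 0.3 * 20 alone
  prof <- c(1, 2, 9, 3, 1, 4, rep(0, 8))
  p2 <- find_peak(prof, coverage = 0.3)
  expect_equal(c(p2$lo, p2$hi), c(3, 3))
  expect_equal(p2$covered_fraction, 9 / 20)
  # uniform positive profile: ceiling(0.3 * 14) = 5 bins containing the
  # tie-broken argmax (bin 7, nearest the TSS then leftward)
  p3 <- find_peak(rep(1, 14), coverage = 0.3)
  expect_equal(p3$hi - p3$lo + 1L, 5L)
  expect_true(p3$lo <= 7 && p3$hi >= 7)
  # all-zero profile -> no-peak sentinel
  p4 <- find_peak(rep(0, 14))
  expect_true(is.na(p4$lo) && is.na(p4$covered_fraction))
})

test_that("peak coverage contract holds on random profiles", {
  set.seed(77)
  for (i in 1:200) {
    prof <- runif(14) * rbinom(14, 1, 0.6)
    if (sum(prof) == 0) next
    pk <- find_peak(prof, coverage = 0.3)
    expect_gte(pk$covered_fraction, 0.3)
    expect_true(pk$lo <= which.max(prof) && pk$hi >= which.max(prof))
    # shrinking coverage never widens the interval
    pk2 <- find_peak(prof, coverage = 0.15)
    expect_lte(pk2$hi - pk2$lo, pk$hi - pk$lo)
  }
})

test_that("peak stability categories follow the endpoint rules", {
  mk <- function(lo, hi) structure(list(lo = lo, hi = hi,
                                        covered_fraction = 0.5),
                                   class = "peak_region")
  expect_equal(peak_stability(mk(3, 5), mk(3, 5)), "identical")
  expect_equal(peak_stability(mk(3, 5), mk(3, 6), 0), "contained")
  expect_equal(peak_stability(mk(3, 5), mk(3, 6), 1), "identical")
  expect_equal(peak_stability(mk(2, 5), mk(4, 8), 0), "overlapping")
  for (tol in 0:6) {
    expect_equal(peak_stability(mk(1, 2), mk(9, 10), tol), "disjoint")
  }
  none <- find_peak(rep(0, 14))
  expect_equal(peak_stability(none, mk(1, 2)), "undefined")
})

test_that("profiles unchanged across days classify as identical peaks", {
  d <- simulate_dataset(sim_config(n_genes = 50, n_control_probes = 200,
                                   frac_up = 0, frac_down = 0, frac_esc = 0,
                                   noise_sd_acet = 0, gene_day_sd = 0, seed = 13))
  b <- bin_profiles(d$probe_table)
  m0 <- profile_matrix(b, 0)
  m5 <- profile_matrix(b, 5)
  cats <- vapply(rownames(m0), function(g) {
    peak_stability(find_peak(m0[g, ]), find_peak(m5[g, ]))
  }, "")
  expect_true(all(cats == "identical"))
})

test_that("delta profiles and quantile bands follow order statistics", {
  a <- c(1:14) / 2
  b <- rep(1, 14)
  expect_equal(delta_profile(a, a), rep(0, 14))
  expect_equal(delta_profile(a, rep(0, 14)), a)
  expect_equal(delta_profile(a, b), a - 1)
  # constant group: all quantiles equal the constant
  grp <- matrix(2, nrow = 6, ncol = 14)
  qb <- quantile_band_summary(grp)
  expect_true(all(qb == 2))
  expect_equal(dim(qb), c(4L, 14L))
  # single gene: all quantiles equal its profile
  qb1 <- quantile_band_summary(matrix(a, nrow = 1))
  expect_true(all(apply(qb1, 1, function(r) all(r == a))))
  # 4-gene hand example, one bin: values 1,2,3,4 -> type-7 quantiles
  m <- matrix(c(1, 2, 3, 4), ncol = 1)
  qb4 <- quantile_band_summary(m, probs = c(0.25, 0.75))
  expect_equal(unname(qb4[, 1]), c(1.75, 3.25))
  expect_error(quantile_band_summary(matrix(numeric(0), ncol = 14)), "empty")
})
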