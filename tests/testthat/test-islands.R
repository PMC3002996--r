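test_that("null model recovers location and scale of Gaussian controls", {
  set.seed(101)
  days <- c(0, 1, 3, 5)
  ctrl <- make_control_table(setNames(
    lapply(days, function(d) rnorm(5000)), days))
  nm <- fit_null(ctrl)
  expect_equal(nm$day, days)
  expect_true(all(nm$scale > 0.95 & nm$scale < 1.05))
  expect_true(all(abs(nm$location) < 0.05))
  expect_true(all(nm$lambda >= 0 & nm$lambda <= 1))
})

test_that("a shifted day shows up in its null location only", {
  set.seed(7)
  ctrl <- make_control_table(list("0" = rnorm(500), "1" = rnorm(500) + 10))
  nm <- fit_null(ctrl)
  expect_lt(abs(nm$location[nm$day == 0]), 0.2)
  expect_lt(abs(nm$location[nm$day == 1] - 10), 0.2)
  # identical controls each day: shrinkage is irrelevant, scales equal
  x <- rnorm(300)
  nm2 <- fit_null(make_control_table(list("0" = x, "1" = x)))
  expect_equal(nm2$scale[1], nm2$scale[2])
})

test_that("too few control probes is an error", {
  ctrl <- make_control_table(list("0" = rnorm(10)))
  expect_error(fit_null(ctrl), "control probes")
})

test_that("state calling is one-sided and respects obvious cases", {
  set.seed(33)
  ctrl <- make_control_table(setNames(lapply(c(0, 1), function(d) rnorm(500)),
                                      c(0, 1)))
  nm <- fit_null(ctrl)
  # probes far above the null are all called; probes at the location never
  probes <- rbind(
    make_probe_table("hi", offsets = seq(-300, 300, by = 100),
                     signals = rep(8, 7), day = 0),
    make_probe_table("lo", offsets = seq(-300, 300, by = 100),
                     signals = rep(nm$location[1], 7), day = 0))
  st <- call_states(rbind(probes, ctrl), nm, fdr = 0.1)
  expect_true(all(st$acetylated[st$gene_id == "hi"]))
  expect_false(any(st$acetylated[st$gene_id == "lo"]))
  expect_true(all(st$q >= 0 & st$q <= 1))
  expect_error(call_states(probes, nm, fdr = 1.2), "fdr")
})

test_that("raising the FDR cutoff never un-calls a probe", {
  d <- shared_sim()
  nm <- fit_null(d$probe_table)
  st1 <- call_states(d$probe_table, nm, fdr = 0.05)
  st2 <- call_states(d$probe_table, nm, fdr = 0.20)
  expect_identical(st1$probe_id, st2$probe_id)
  expect_true(all(st2$acetylated[st1$acetylated]))
})

test_that("false-call rate under a pure null stays at or below the nominal FDR", {
  rates <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    ctrl <- make_control_table(list("0" = rnorm(500)))
    probes <- make_probe_table("gN", offsets = seq(-3400, 3400, by = 50),
                               signals = rnorm(137), day = 0)
    st <- call_states(rbind(probes, ctrl), fit_null(ctrl), fdr = 0.1)
    mean(st$acetylated)
  }, 1)
  # every call is false under the null; realized rate within MC error of FDR
  expect_lte(mean(rates), 0.1 + 2 * sd(rates) / sqrt(20))
})

test_that("transition summaries match hand counts", {
  sm <- make_state_matrix("gA", paste0("p", 1:5), list(
    "0" = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    "1" = c(TRUE, FALSE, FALSE, FALSE, TRUE)))
  tr <- transition_summary(sm, 0, 1, min_state_count = 2)
  expect_equal(tr$p_stay_ac, 0.5)
  expect_equal(tr$p_stay_unac, 2 / 3)
  expect_equal(tr$n_ac, 2L)
  expect_equal(tr$n_unac, 3L)
  expect_false(tr$discarded)
  # min_state_count controls the discarded flag
  tr3 <- transition_summary(sm, 0, 1, min_state_count = 3)
  expect_true(tr3$discarded)
})

test_that("identical and flipped state patterns give the extreme stay rates", {
  states <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  same <- make_state_matrix("gA", paste0("p", 1:6),
                            list("0" = states, "1" = states))
  tr <- transition_summary(same, 0, 1)
  expect_equal(c(tr$p_stay_unac, tr$p_stay_ac), c(1, 1))
  flip <- make_state_matrix("gA", paste0("p", 1:6),
                            list("0" = states, "1" = !states))
  trf <- transition_summary(flip, 0, 1)
  expect_equal(c(trf$p_stay_unac, trf$p_stay_ac), c(0, 0))
})

test_that("transition probabilities are invariant to probe order", {
  sm <- make_state_matrix("gA", paste0("p", 1:5), list(
    "0" = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    "1" = c(TRUE, FALSE, FALSE, FALSE, TRUE)))
  perm <- sm[sample(nrow(sm)), ]
  attr(perm, "days") <- attr(sm, "days")
  class(perm) <- class(sm)
  expect_equal(transition_summary(perm, 0, 1)$p_stay_ac,
               transition_summary(sm, 0, 1)$p_stay_ac)
})

test_that("pooling consecutive day pairs reproduces repeated identical pairs", {
  sm <- make_state_matrix("gA", paste0("p", 1:5), list(
    "0" = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    "1" = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    "3" = c(TRUE, TRUE, FALSE, FALSE, FALSE)))
  # manually: pair (0,1): ac 2 stay 1; unac 3 stay 2
  #           pair (1,3): ac 2 stay 1; unac 3 stay 2
  pooled <- pooled_transition_summary(sm, min_state_count = 2)
  expect_equal(pooled$p_stay_ac, 0.5)
  expect_equal(pooled$p_stay_unac, 2 / 3)
  expect_equal(pooled$n_ac, 4L)
})

test_that("zero-noise pipeline gives perfect pooled stay probabilities", {
  d <- simulate_dataset(sim_config(n_genes = 60, n_control_probes = 200,
                                   frac_up = 0, frac_down = 0, frac_esc = 0,
                                   noise_sd_acet = 0, gene_day_sd = 0, seed = 8))
  st <- call_states(d$probe_table, fit_null(d$probe_table))
  tr <- pooled_transition_summary(st)
  ok <- !tr$discarded
  expect_true(any(ok))
  expect_true(all(tr$p_stay_ac[ok] == 1, na.rm = TRUE))
  expect_true(all(tr$p_stay_unac[ok] == 1, na.rm = TRUE))
})
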