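test_that("CCG counts match direct enumeration, including boundary lags", {
  a <- spike_train("a", c(1, 2), 0, 3)
  b <- spike_train("b", c(1, 2), 0, 3)
  ep <- epoch_set(0, 3, "NREM")
  cc <- compute_ccg(a, b, ep, "NREM", bin_width = 0.005, max_lag = 1)
  expect_equal(length(cc$counts), 400)
  expect_equal(sum(cc$counts), 4)           # lags 0, 0, -1, +1
  expect_equal(cc$counts[[201]], 2)         # bin holding lag 0
  expect_equal(cc$counts[[1]], 1)           # lag -1 s
  expect_equal(cc$counts[[400]], 1)         # lag +1 s
})

test_that("only same-epoch spike pairs are counted", {
  a <- spike_train("a", c(1, 2), 0, 30)
  b <- spike_train("b", c(11, 12), 0, 30)
  ep <- epoch_set(c(0, 10), c(10, 20), "NREM")
  cc <- compute_ccg(a, b, ep, "NREM")
  expect_equal(sum(cc$counts), 0)
  expect_false(cc$empty)
  expect_error(compute_ccg(a, b, ep, "REM"), "no epochs")
  empty_a <- spike_train("a", numeric(0), 0, 30)
  expect_warning(cc0 <- compute_ccg(empty_a, b, ep, "NREM"), "no spikes")
  expect_true(cc0$empty)
})

test_that("homogeneous Poisson pair matches the analytic coincidence rate", {
  set.seed(7)
  a <- poisson_train("a", 2, 0, 1000)
  b <- poisson_train("b", 2, 0, 1000)
  ep <- epoch_set(0, 1000, "NREM")
  cc <- compute_ccg(a, b, ep, "NREM")
  # condition on the realized counts: expected pairs = n_a * n_b * 2 s / T,
  # up to edge effects of order max_lag / T
  expected_total <- n_spikes(a) * n_spikes(b) * 2 / 1000
  expect_lt(abs(sum(cc$counts) - expected_total) / expected_total, 0.03)
  # per-bin level matches the analytic coincidence rate 2*2*T*bw
  expect_lt(abs(mean(cc$counts) - 2 * 2 * 1000 * 0.005) / 20, 0.1)
})

test_that("CCG reversal symmetry and DCE swap invariance hold", {
  set.seed(8)
  sc <- small_schedule()
  pr <- generate_pair("ANTIPHASE", sc$updown, 8, 8, sc$cfg, seed = 9)
  ep <- epochs_with_label(sc$states, "NREM")
  ab <- compute_ccg(pr$a, pr$b, ep)
  ba <- compute_ccg(pr$b, pr$a, ep)
  expect_equal(rev(ab$counts), ba$counts)
  d_ab <- pair_dce(pr$a, pr$b, ep)
  d_ba <- pair_dce(pr$b, pr$a, ep)
  expect_equal(d_ab$dce, d_ba$dce, tolerance = 1e-10)
})

test_that("triangular smoothing is unit-area and matches a direct oracle", {
  flat <- statesync:::new_ccg(c("a", "b"), statesync:::ccg_lag_centers(0.005, 1),
                              rep(3.5, 400), 0.005, 1, 1)
  expect_equal(smooth_triangular(flat)$counts, rep(3.5, 400))
  imp <- flat; imp$counts <- rep(0, 400); imp$counts[200] <- 10
  sm <- smooth_triangular(imp)
  expect_equal(sum(sm$counts), 10, tolerance = 1e-6)
  expect_equal(which.max(sm$counts), 200)
  set.seed(10)
  rnd <- flat; rnd$counts <- rpois(400, 20)
  sm2 <- smooth_triangular(rnd, window = 1)
  expect_equal(sm2$counts, tri_conv_oracle(rnd$counts, 100), tolerance = 1e-12)
  expect_error(smooth_triangular(flat, window = 0.005), "two bins")
})

test_that("log-ratio normalization behaves as specified", {
  lag <- statesync:::ccg_lag_centers(0.005, 1)
  raw <- statesync:::new_ccg(c("a", "b"), lag, rep(50, 400), 0.005, 1, 1)
  nc <- normalize_ccg(raw, raw)
  expect_equal(max(abs(nc$values)), 0)
  base <- raw; base$counts <- rep(1e6, 400)
  up <- raw; up$counts <- exp(1) * base$counts
  nc2 <- normalize_ccg(up, base)
  expect_equal(nc2$values, rep(1, 400), tolerance = 1e-4)
  bad <- statesync:::new_ccg(c("a", "b"), lag[-1], rep(1, 399), 0.005, 1, 1)
  expect_error(normalize_ccg(raw, bad), "lag grids")
})

test_that("DCE of a flat CCG is exactly zero and not significant", {
  lag <- statesync:::ccg_lag_centers(0.005, 1)
  raw <- statesync:::new_ccg(c("a", "b"), lag, rep(12, 400), 0.005, 1, 1)
  d <- compute_dce(normalize_ccg(raw, smooth_triangular(raw)))
  expect_lt(abs(d$dce), 1e-9)
  expect_false(d$significant)
  expect_equal(d$dce_sig, 0)
})

test_that("a constructed center elevation yields dce near 1 and significance", {
  lag <- statesync:::ccg_lag_centers(0.005, 1)
  base <- statesync:::new_ccg(c("a", "b"), lag, rep(1e6, 400), 0.005, 1, 1)
  raw <- base
  set.seed(11)
  bump <- ifelse(abs(lag) <= 0.125, exp(1), 1)
  raw$counts <- base$counts * bump * exp(rnorm(400, 0, 1e-3))
  d <- compute_dce(normalize_ccg(raw, base))
  expect_equal(d$dce, 1, tolerance = 0.01)
  expect_true(d$significant)
  expect_equal(d$n_center, 50)   # 250 ms center window at 5 ms bins
})

test_that("DCE window preconditions are enforced", {
  lag <- statesync:::ccg_lag_centers(0.005, 0.5)
  raw <- statesync:::new_ccg(c("a", "b"), lag, rep(5, 200), 0.005, 0.5, 1)
  nc <- normalize_ccg(raw, raw)
  expect_error(compute_dce(nc, variant = "STANDARD"), "max_lag")
  expect_error(compute_dce(nc, variant = "UP_ONLY"), "max_lag")
})

test_that("interval jitter stays in its partition window and preserves rate structure", {
  ep <- epoch_set(0, 10, "NREM")
  tr <- spike_train("a", c(0.30, 9.81), 0, 10)
  set.seed(12)
  for (i in 1:20) {
    j <- statesync:::jitter_train(tr, ep, 0.5)
    expect_true(j$times[1] >= 0 && j$times[1] < 0.5)
    expect_true(j$times[2] >= 9.5 && j$times[2] < 10)
  }
  # independence: jittered CCG approximates the raw CCG in expectation
  set.seed(13)
  a <- poisson_train("a", 5, 0, 300)
  b <- poisson_train("b", 5, 0, 300)
  ep2 <- epoch_set(0, 300, "NREM")
  raw <- compute_ccg(a, b, ep2, "NREM")
  jit <- jitter_baseline(a, b, ep2, "NREM", reps = 20, seed = 14)
  expect_lt(abs(mean(jit$counts) - mean(raw$counts)) / mean(raw$counts), 0.02)
  # synchrony: jitter flattens a zero-lag peak
  bs <- spike_train("b", pmin(a$times + 0.001, 300), 0, 300)
  raw_s <- compute_ccg(a, bs, ep2, "NREM")
  jit_s <- jitter_baseline(a, bs, ep2, "NREM", reps = 5, seed = 15)
  peak_bin <- which.max(raw_s$counts)
  expect_lt(jit_s$counts[peak_bin], 0.2 * raw_s$counts[peak_bin])
})

test_that("triangular and jitter normalizations agree on a structured pair", {
  sc <- small_schedule()
  pr <- generate_pair("ANTIPHASE", sc$updown, 10, 10, sc$cfg, seed = 16)
  nrem <- epochs_with_label(sc$states, "NREM")
  d_tri <- pair_dce(pr$a, pr$b, nrem)
  raw <- compute_ccg(pr$a, pr$b, nrem)
  jit <- jitter_baseline(pr$a, pr$b, nrem, reps = 20, seed = 17)
  d_jit <- compute_dce(normalize_ccg(raw, jit))
  expect_gt(abs(d_jit$dce), 0.2)
  expect_lt(abs(d_tri$dce - d_jit$dce), 0.1 * abs(d_jit$dce))
})

test_that("independent Poisson pairs are almost never significant", {
  set.seed(18)
  ep <- epoch_set(0, 1500, "NREM")
  n_sig <- 0
  for (i in 1:40) {
    a <- poisson_train("a", runif(1, 2, 5), 0, 1500)
    b <- poisson_train("b", runif(1, 2, 5), 0, 1500)
    if (pair_dce(a, b, ep, "NREM")$significant) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1)
})
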