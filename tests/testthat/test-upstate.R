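test_that("UP/DOWN detection recovers generator silences", {
  cfg <- synth_config(duration_h = 0.5, n_units = 12, seed = 31,
                      class_fractions = c(INDEPENDENT = 1, COACTIVE = 0,
                                          ANTIPHASE = 0))
  rec <- generate_recording(cfg)
  det <- detect_up_down(rec$trains, rec$states)
  true_down <- epochs_with_label(rec$updown, "DOWN")
  det_down <- epochs_with_label(det, "DOWN")
  # Jaccard overlap of detected vs true DOWN time
  grid <- seq(min(rec$states$start), max(rec$states$end), by = 0.005)
  in_true <- statesync:::spikes_in_epochs(grid, true_down)
  in_det <- statesync:::spikes_in_epochs(grid, det_down)
  jac <- sum(in_true & in_det) / sum(in_true | in_det)
  expect_gt(jac, 0.8)
  # constant-rate population with no silences yields no DOWN states
  set.seed(32)
  flat <- lapply(1:12, function(i) poisson_train(paste0("f", i), 20, 0, 300))
  ep <- epoch_set(0, 300, "NREM")
  det_flat <- detect_up_down(flat, ep)
  expect_equal(sum(det_flat$label == "DOWN"), 0)
})

test_that("UP-only DCE excludes DOWN spikes and honours trim_to", {
  ud <- regular_updown(60, up_dur = 1, down_dur = 0.3)
  down <- epochs_with_label(ud, "DOWN")
  # pair firing only in DOWN states: zero CCG, dce 0
  set.seed(33)
  mk_down_train <- function(id) {
    t <- unlist(lapply(seq_len(nrow(down)), function(i)
      runif(3, down$start[i], down$end[i])))
    spike_train(id, sort(t), 0, max(ud$end))
  }
  a <- mk_down_train("a"); b <- mk_down_train("b")
  d <- suppressWarnings(up_only_dce(a, b, ud))
  expect_equal(d$dce, 0)
  expect_false(d$significant)
  # trim_to = full durations is identical to untrimmed
  sc <- small_schedule()
  pr <- generate_pair("ANTIPHASE", sc$updown, 8, 8, sc$cfg, seed = 34)
  up <- epochs_with_label(sc$updown, "UP")
  d1 <- up_only_dce(pr$a, pr$b, sc$updown)
  d2 <- up_only_dce(pr$a, pr$b, sc$updown, trim_to = up$end - up$start)
  expect_equal(d1$dce, d2$dce)
})

test_that("UPnext scrambling is an identity for identical UP patterns", {
  ud <- regular_updown(40, up_dur = 1, down_dur = 0.2)
  up <- epochs_with_label(ud, "UP")
  # offsets chosen so no pairwise lag falls on a 5 ms bin edge
  pat <- c(0.123, 0.357, 0.801)
  a <- spike_train("a", as.vector(outer(pat, up$start, "+")), 0, max(ud$end))
  b <- spike_train("b", as.vector(outer(c(0.2, 0.61), up$start, "+")), 0,
                   max(ud$end))
  sc <- scramble_up_next(a, b, ud)
  cc_orig <- compute_ccg(restrict_train(a, sc$epochs), sc$b, sc$epochs, "UP",
                         max_lag = 2)
  cc_scr <- compute_ccg(sc$a, sc$b, sc$epochs, "UP", max_lag = 2)
  expect_equal(cc_scr$counts, cc_orig$counts)
  # unshifted unit keeps its within-trimmed-UP spike count
  expect_equal(n_spikes(sc$b),
               sum(statesync:::spikes_in_epochs(b$times, sc$epochs)))
})

test_that("UPnext scrambling destroys antiphase structure", {
  sc <- small_schedule()
  n_destroyed <- 0; n <- 6
  for (i in seq_len(n)) {
    pr <- generate_pair("ANTIPHASE", sc$updown, 9, 9, sc$cfg, seed = 40 + i)
    scr <- scramble_up_next(pr$a, pr$b, sc$updown)
    d0 <- suppressWarnings(
      up_only_dce(pr$a, pr$b, scr$epochs, trim_to = scr$trim_to))
    d1 <- suppressWarnings(up_only_dce(scr$a, scr$b, scr$epochs))
    expect_lt(d0$dce, 0)
    if (d1$dce_sig >= 0) n_destroyed <- n_destroyed + 1
  }
  expect_equal(n_destroyed, n)
})

test_that("UP spike profiles recover construction", {
  ud <- regular_updown(50, up_dur = 1, down_dur = 0.2)
  up <- epochs_with_label(ud, "UP")
  onset <- spike_train("o", up$start + 1e-6, 0, max(ud$end))
  p <- up_spike_profile(onset, ud)
  expect_equal(p$bin_probs[1], 1)
  expect_equal(sum(p$bin_probs), 1, tolerance = 1e-9)
  set.seed(35)
  unif <- spike_train("u", sort(as.vector(
    sapply(seq_len(nrow(up)), function(i) runif(40, up$start[i], up$end[i])))),
    0, max(ud$end))
  pu <- up_spike_profile(unif, ud)
  expect_lt(max(abs(pu$bin_probs - 0.02)), 0.01)
  expect_equal(pu$mean_rate_up, 40, tolerance = 0.01)
  # early-biased unit: peak bin within the first decile
  set.seed(36)
  ud2 <- regular_updown(200, up_dur = 1, down_dur = 0.2)
  up2 <- epochs_with_label(ud2, "UP")
  early_prob <- statesync:::discretize_beta_profile(1, 8)
  t <- statesync:::sim_profile_spikes(up2$start, up2$end, 15, early_prob)
  pe <- up_spike_profile(spike_train("e", t, 0, max(ud2$end)), ud2)
  expect_lte(which.max(pe$bin_probs), 5)
})

test_that("profile-based simulation preserves rates and profiles", {
  ud <- regular_updown(2000, up_dur = 1, down_dur = 0.2)
  prof <- structure(list(unit_id = "m", bin_probs = rep(0.02, 50),
                         mean_rate_up = 10, n_up_used = 2000),
                    class = "up_profile")
  first_bin <- structure(list(unit_id = "f",
                              bin_probs = c(1, rep(0, 49)),
                              mean_rate_up = 5, n_up_used = 2000),
                         class = "up_profile")
  set.seed(37)
  pr <- simulate_profile_pair(first_bin, prof, ud)
  up <- epochs_with_label(ud, "UP")
  ph <- (pr$a$times - up$start[statesync:::epoch_index_of(pr$a$times, up)])
  expect_true(all(ph < 0.02 + 1e-9))       # all spikes in the first 2%
  # rate preservation
  expect_equal(n_spikes(pr$b), 10 * epoch_duration(up), tolerance = 0.03)
  # mean-preservation: averaged profile of simulated spikes ~ input (L1)
  pb <- up_spike_profile(pr$b, ud)
  expect_lt(sum(abs(pb$bin_probs - prof$bin_probs)), 0.05)
})

test_that("profile-simulation null flags a real antiphase trough", {
  sc <- small_schedule()
  pr <- generate_pair("ANTIPHASE", sc$updown, 10, 10, sc$cfg, seed = 38)
  d_real <- suppressWarnings(up_only_dce(pr$a, pr$b, sc$updown))
  pa <- up_spike_profile(pr$a, sc$updown)
  pb <- up_spike_profile(pr$b, sc$updown)
  nl <- dce_null_from_simulation(pa, pb, sc$updown, d_real$dce, n_sims = 30,
                                 seed = 39)
  expect_lt(nl$p, 0.01)
  expect_lt(d_real$dce, nl$null_mean)
  # observed equal to the null mean gives z = 0
  nl0 <- dce_null_from_simulation(pa, pb, sc$updown, nl$null_mean,
                                  n_sims = 30, seed = 39)
  expect_equal(nl0$z, 0, tolerance = 1e-9)
  expect_equal(nl0$p, 1, tolerance = 1e-9)
})

test_that("within-UP timing metrics match construction", {
  ud <- regular_updown(30, up_dur = 1, down_dur = 0.2)
  up <- epochs_with_label(ud, "UP")
  t_a <- as.vector(outer(c(0.2, 0.5), up$start, "+"))
  a <- spike_train("a", t_a, 0, max(ud$end))
  ident <- up_timing_metrics(a, spike_train("b", t_a, 0, max(ud$end)), ud)
  expect_equal(ident$mean_diff_first, 0)
  expect_equal(ident$sd_diff_first, 0)
  expect_equal(ident$mean_diff_mean, 0)
  # a leads b by exactly 50 ms
  b <- spike_train("b", t_a + 0.05, 0, max(ud$end))
  lead <- up_timing_metrics(a, b, ud)
  expect_equal(lead$mean_diff_first, -0.05)
  expect_equal(lead$sd_diff_first, 0, tolerance = 1e-12)
  expect_equal(lead$n_up_used, 30)
  expect_false(lead$flagged)
})

test_that("trough pairs have more variable timing than peak pairs", {
  sc <- small_schedule()
  metrics <- list(); rows <- list()
  for (i in 1:8) {
    cls <- if (i <= 4) "ANTIPHASE" else "COACTIVE"
    pr <- generate_pair(cls, sc$updown, 9, 9, sc$cfg, seed = 50 + i,
                        ids = sprintf("p%02d%s", i, c("a", "b")))
    metrics[[i]] <- up_timing_metrics(pr$a, pr$b, sc$updown)
    d <- pair_dce(pr$a, pr$b, sc$states, "NREM")
    rows[[i]] <- data.frame(unit_a = pr$a$unit_id, unit_b = pr$b$unit_id,
                            state = "NREM", dce = d$dce, p_value = d$p_value,
                            significant = d$significant, dce_sig = d$dce_sig)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("dce_table", "data.frame")
  # 5-per-group precondition enforced
  expect_error(timing_metric_contrast(metrics[1:5], tab[1:5, ]), "at least 5")
  sd_anti <- sapply(metrics[1:4], `[[`, "sd_diff_first")
  sd_co <- sapply(metrics[5:8], `[[`, "sd_diff_first")
  expect_gt(min(sd_anti), max(sd_co))
})
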