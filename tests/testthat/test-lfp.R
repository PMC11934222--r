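test_that("band power localizes a pure tone and scales with bandwidth", {
  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  tone <- structure(list(samples = sin(2 * pi * 4 * t), rate = fs),
                    class = "lfp")
  bands <- data.frame(f_lo = c(3.5, 49), f_hi = c(4.3, 60))
  bp <- band_power_timeseries(tone, bands, normalize = FALSE)
  expect_gt(mean(bp$power[, 1]), 100 * mean(bp$power[, 2]))
  expect_error(band_power_timeseries(tone, data.frame(f_lo = 90, f_hi = 120)),
               "Nyquist")
  # white noise: integrated band power proportional to bandwidth
  set.seed(71)
  wn <- structure(list(samples = rnorm(fs * 600), rate = fs), class = "lfp")
  wb <- data.frame(f_lo = c(10, 30), f_hi = c(20, 50))
  bpw <- band_power_timeseries(wn, wb, normalize = FALSE)
  ratio <- mean(bpw$power[, 2]) / mean(bpw$power[, 1])
  expect_lt(abs(ratio - 2), 0.4)          # 20 Hz vs 10 Hz band
})

test_that("z-normalization is centered and idempotent", {
  set.seed(72)
  x <- c(rnorm(1000), 8, -9, 12)           # planted outliers
  z <- statesync:::znorm_outliers(x)
  keep <- !is.na(z)
  expect_lt(abs(mean(z[keep])), 1e-9)
  expect_equal(stats::sd(z[keep]), 1, tolerance = 1e-9)
  expect_true(all(is.na(z[1001:1003])))
  z2 <- statesync:::znorm_outliers(z)
  expect_equal(z2[keep], z[keep], tolerance = 1e-6)
})

lfp_fixture <- function() fixture("lfp_rec", {
  generate_recording(synth_config(
    duration_h = 24, n_units = 12,
    class_fractions = c(INDEPENDENT = 1 / 3, COACTIVE = 0, ANTIPHASE = 2 / 3),
    antiphase_bursty_frac = 0, wake_anticorr_frac = 0,
    antiphase_depth = 0.7, delta_coupling = 2, drift_amp = 0.4, seed = 73))
})

test_that("generator LFP has nonREM-dominant delta power", {
  rec <- lfp_fixture()
  band <- data.frame(f_lo = 3.5, f_hi = 4.3)
  nr <- band_power_timeseries(rec$lfp, band, epochs = rec$states,
                              label = "NREM", normalize = FALSE)
  wk <- band_power_timeseries(rec$lfp, band, epochs = rec$states,
                              label = "WAKE", normalize = FALSE)
  expect_gt(mean(nr$power[, 1]), 3 * mean(wk$power[, 1]))
})

test_that("windowed DCE/band-power correlation recovers the coupling signs", {
  rec <- lfp_fixture()
  tab <- state_dce_table(rec$trains, rec$states, pairs = rec$truth$pairs)
  sel <- select_trough_pairs(tab)
  expect_gte(nrow(sel), 3)
  bands <- data.frame(f_lo = c(3.5, 49), f_hi = c(4.3, 60))
  wc <- windowed_dce_power_correlation(rec$trains, rec$states, rec$lfp, sel,
                                       bands)
  expect_gt(wc$correlations$R[1], 0)       # delta band, |DCE|
  expect_lt(wc$correlations$p[1], 0.05)
  expect_lt(wc$correlations$R[2], 0)       # gamma band
  expect_lt(wc$correlations$p[2], 0.05)
  # sign-split consistency: signed dce (all negative) flips the delta sign
  wcs <- windowed_dce_power_correlation(rec$trains, rec$states, rec$lfp, sel,
                                        bands, use_abs = FALSE)
  expect_lt(wcs$correlations$R[1], 0)
  # constant power is flagged
  flat <- rec$lfp; flat$samples <- rep(0, length(flat$samples))
  wc0 <- windowed_dce_power_correlation(rec$trains, rec$states, flat, sel,
                                        data.frame(f_lo = 3.5, f_hi = 4.3))
  expect_true(wc0$correlations$flagged[1])
})

test_that("quartile analysis partitions epochs and tracks delta power", {
  rec <- lfp_fixture()
  tab <- fixture("lfp_tab", state_dce_table(rec$trains, rec$states,
                                            pairs = rec$truth$pairs))
  sel <- select_trough_pairs(tab)
  q <- quartile_dce_power(rec$trains, rec$states, rec$lfp, sel[1, ])
  expect_equal(nrow(q$quartiles), 4)       # one dce per quartile
  expect_lt(q$R, 0)                        # deeper trough at higher delta
  # exhaustive and disjoint partition under identical powers
  nrem <- epochs_with_label(rec$states, "NREM")
  qs <- cut(rank(rep(1, nrow(nrem)), ties.method = "first"), 4,
            labels = FALSE)
  expect_equal(sort(unique(qs)), 1:4)
  expect_equal(length(qs), nrow(nrem))
})

test_that("epoch duration correlates with plateau delta and against gamma", {
  rec <- lfp_fixture()
  bands <- data.frame(f_lo = c(3.5, 49), f_hi = c(4.3, 60))
  ed <- epoch_duration_power_correlation(rec$states, rec$lfp, bands)
  expect_gt(ed$correlations$R[1], 0)
  expect_lt(ed$correlations$p[1], 0.05)
  expect_lt(ed$correlations$R[2], 0)
  expect_lt(ed$correlations$p[2], 0.05)
  expect_gte(ed$n_excluded, 0)
  # trimming longer than any epoch excludes everything
  expect_error(epoch_duration_power_correlation(rec$states, rec$lfp, bands,
                                                min_dur_s = 1e6),
               "qualifying")
})

test_that("DCE stability matrix separates real structure from shuffles", {
  rec <- lfp_fixture()
  tab <- fixture("lfp_tab", state_dce_table(rec$trains, rec$states,
                                            pairs = rec$truth$pairs))
  stm <- dce_stability_matrix(rec$trains, rec$states, table = tab, seed = 74)
  expect_lt(stm$mean_sd, stm$shuffle_mean_sd)
  expect_lt(stm$z, -3)
  short <- clip_epochs(rec$states, 0, 9000)
  expect_error(dce_stability_matrix(rec$trains, short, table = tab,
                                    seed = 74), "2 windows")
})
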