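# small two-state recording shared across tests in this file
state_fixture <- function() fixture("state_rec", {
  cfg <- synth_config(duration_h = 1.2, n_units = 6,
                      class_fractions = c(INDEPENDENT = 1 / 3,
                                          COACTIVE = 1 / 3,
                                          ANTIPHASE = 1 / 3),
                      antiphase_bursty_frac = 0, wake_anticorr_frac = 0,
                      seed = 21)
  rec <- generate_recording(cfg)
  rec
})

mk_table <- function(df) {
  class(df) <- c("dce_table", "data.frame")
  df
}

test_that("state_dce_table covers every pair and present state", {
  rec <- state_fixture()
  tab <- state_dce_table(rec$trains, rec$states)
  present <- intersect(c("NREM", "WAKE", "REM"), unique(rec$states$label))
  expect_equal(nrow(tab), choose(6, 2) * length(present))
  expect_true(all(tab$unit_a < tab$unit_b))
  expect_equal(anyDuplicated(tab[, c("unit_a", "unit_b", "state")]), 0)
  # delegation: rows agree with direct pair computation
  d <- pair_dce(rec$trains[[1]], rec$trains[[2]], rec$states, "NREM")
  row <- tab[tab$unit_a == rec$trains[[1]]$unit_id &
             tab$unit_b == rec$trains[[2]]$unit_id & tab$state == "NREM", ]
  expect_equal(row$dce, d$dce)
  expect_equal(row$p_value, d$p_value)
})

test_that("designated antiphase pairs show NREM-specific troughs", {
  rec <- state_fixture()
  tab <- state_dce_table(rec$trains, rec$states, pairs = rec$truth$pairs)
  anti <- rec$truth$pairs[rec$truth$pairs$class == "ANTIPHASE", ]
  nrem <- tab[tab$state == "NREM" & tab$unit_a %in% anti$unit_a, ]
  expect_true(all(nrem$significant & nrem$dce < 0))
  wake <- tab[tab$state == "WAKE" & tab$unit_a %in% anti$unit_a, ]
  expect_true(all(wake$dce_sig >= 0))
})

test_that("proportion_summary percentages match row-level counts exactly", {
  df <- mk_table(data.frame(
    unit_a = rep(sprintf("u%03d", 1:100), 1), unit_b = "z", state = "NREM",
    dce = c(rep(-0.5, 4), rep(0.3, 10), rep(0.01, 86)),
    p_value = c(rep(1e-6, 14), rep(0.5, 86)),
    significant = c(rep(TRUE, 14), rep(FALSE, 86))))
  df$dce_sig <- ifelse(df$significant, df$dce, 0)
  ps <- proportion_summary(df)
  expect_equal(ps$trough_pct, 4)
  expect_equal(ps$peak_pct, 10)
  expect_equal(ps$n_pairs, 100)
})

test_that("state-specificity crosstab follows the zero-DCE convention", {
  # 4 pairs: NREM-specific trough, both-state trough, peak pair, null pair
  df <- mk_table(data.frame(
    unit_a = rep(c("a", "b", "c", "d"), each = 2),
    unit_b = rep(c("x", "y", "z", "w"), each = 2),
    state = rep(c("NREM", "WAKE"), 4),
    dce = c(-1, 0.01, -1, -1, 0.5, 0.5, 0, 0),
    p_value = c(1e-9, 0.5, 1e-9, 1e-9, 1e-9, 1e-9, 0.9, 0.9),
    significant = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)))
  df$dce_sig <- ifelse(df$significant, df$dce, 0)
  ct <- state_specificity_crosstab(df)
  get <- function(x, y) ct$pct[ct$state_neg == x & ct$state_zero == y]
  expect_equal(get("NREM", "WAKE"), 25)   # only the NREM-specific pair
  expect_equal(get("WAKE", "NREM"), 0)
  none <- df; none$significant <- FALSE; none$dce_sig <- 0
  expect_true(all(state_specificity_crosstab(none)$pct == 0))
})

test_that("compare_abs_dce detects a scaled state and not identical ones", {
  set.seed(22)
  mk <- function(scale_nrem) {
    n <- 30
    base <- abs(rnorm(n, 0.5, 0.05))
    mk_table(data.frame(
      unit_a = rep(sprintf("p%02d", 1:n), 3), unit_b = "q",
      state = rep(c("NREM", "WAKE", "REM"), each = n),
      dce = c(base * scale_nrem, base + rnorm(n, 0, 0.05),
              base + rnorm(n, 0, 0.05)),
      p_value = 1e-9, significant = TRUE, dce_sig = 1))
  }
  same <- compare_abs_dce(mk(1))
  expect_equal(same$n_pairs, 30)
  expect_true(all(same$pairwise$p_adj > 0.05))
  scaled <- compare_abs_dce(mk(2))
  p <- scaled$pairwise
  expect_lt(p$p_adj[grepl("NREM", p$contrast) & grepl("WAKE", p$contrast)], 0.01)
  expect_lt(p$p_adj[grepl("NREM", p$contrast) & grepl("REM-", p$contrast) |
                    grepl("REM-NREM", p$contrast)][1], 0.01)
  # empty selection gives an empty report, not an error
  none <- mk(1); none$significant <- FALSE
  expect_equal(compare_abs_dce(none)$n_pairs, 0)
})

test_that("downsampling matches durations and never increases spike counts", {
  rec <- state_fixture()
  states <- rec$states
  durs <- sapply(c("NREM", "WAKE", "REM"), function(s)
    epoch_duration(states, s))
  ref <- names(which.min(durs))
  tab <- downsample_matched_dce(rec$trains, states,
                                pairs = rec$truth$pairs, reps = 2, seed = 23)
  expect_s3_class(tab, "dce_table")
  expect_equal(sort(unique(tab$state)), sort(names(durs)[durs > 0]))
  # antiphase pair stays more negative in NREM than wake after matching
  anti <- rec$truth$pairs[rec$truth$pairs$class %in%
                          c("ANTIPHASE", "BURSTY_ANTIPHASE"), ][1, ]
  d_n <- tab$dce[tab$unit_a == anti$unit_a & tab$state == "NREM"]
  d_w <- tab$dce[tab$unit_a == anti$unit_a & tab$state == "WAKE"]
  expect_lt(d_n, d_w)
  expect_lt(d_n, 0)
})

test_that("stacked CCG matrix is sorted by the reference-state DCE", {
  rec <- state_fixture()
  stk <- stacked_ccg_matrix(rec$trains, rec$states, pairs = rec$truth$pairs,
                            significant_only = TRUE)
  expect_true(!is.unsorted(stk$dce))
  expect_equal(ncol(stk$NREM), 400)
  expect_equal(nrow(stk$NREM), length(stk$order))
})
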