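#' Detect UP/DOWN states from population spiking
#'
#' Convenience detector for recordings without curated UP/DOWN epochs: the
#' population spike count inside nonREM epochs is binned at 10 ms, smoothed
#' with a short triangular kernel, and DOWN states are maximal runs below a
#' rate threshold (default 10% of the mean nonREM population rate) lasting at
#' least `min_down_s`; UP states are the complementary intervals of at least
#' `min_up_s`. Curated epochs, when available, should be used instead.
#'
#' @param trains List of `spike_train`s (>= 5 units recommended).
#' @param nrem_epochs An `epoch_set`; rows labeled NREM are used.
#' @param bin_s Count bin (default 0.01 s).
#' @param thresh_frac DOWN threshold as a fraction of the mean nonREM
#'   population rate.
#' @param min_down_s,min_up_s Minimum DOWN / UP durations (s).
#' @param smooth_bins Width of the triangular smoothing kernel in bins (odd).
#' @return An `epoch_set` with labels UP/DOWN.
#' @export
detect_up_down <- function(trains, nrem_epochs, bin_s = 0.01,
                           thresh_frac = 0.1, min_down_s = 0.05,
                           min_up_s = 0.1, smooth_bins = 3) {
  nrem <- epochs_with_label(nrem_epochs, "NREM")
  if (!nrow(nrem)) stop("no NREM epochs")
  all_t <- sort(unlist(lapply(trains, function(x) x$times)))
  mean_rate <- sum(spikes_in_epochs(all_t, nrem)) / epoch_duration(nrem)
  thr <- thresh_frac * mean_rate
  kern <- (ceiling(smooth_bins / 2) - abs(seq(-floor(smooth_bins / 2),
                                              floor(smooth_bins / 2))))
  kern <- kern / sum(kern)
  out <- NULL
  for (i in seq_len(nrow(nrem))) {
    s <- nrem$start[i]; e <- nrem$end[i]
    nb <- max(1L, floor((e - s) / bin_s))
    edges <- s + (0:nb) * bin_s
    cnt <- graphics::hist(all_t[all_t >= s & all_t < s + nb * bin_s],
                          breaks = edges, plot = FALSE)$counts
    rate <- as.numeric(stats::filter(cnt / bin_s, kern, sides = 2))
    rate[is.na(rate)] <- cnt[is.na(rate)] / bin_s
    low <- rate < thr
    r <- rle(low)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
    down <- which(r$values & r$lengths * bin_s >= min_down_s)
    d_start <- s + (starts_i[down] - 1) * bin_s
    d_end <- pmin(e, s + ends_i[down] * bin_s)
    bounds <- sort(c(s, d_start, d_end, e))
    seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    seg <- seg[seg$end > seg$start + 1e-12, , drop = FALSE]
    is_down <- vapply(seq_len(nrow(seg)), function(k)
      any(abs(seg$start[k] - d_start) < 1e-9), logical(1))
    seg$label <- ifelse(is_down, "DOWN", "UP")
    seg <- seg[!(seg$label == "UP" & seg$end - seg$start < min_up_s), ,
               drop = FALSE]
    out <- rbind(out, seg)
  }
  if (is.null(out) || !nrow(out)) stop("no UP/DOWN intervals detected")
  epoch_set(out$start, out$end, out$label)
}

#' UP-state-only DCE for a pair
#'
#' CCGs computed within each UP state and summed, normalized against the
#' triangular baseline, and summarized with the UP_ONLY DCE (center 250 ms
#' vs 1-2 s lags, avoiding the boundary undershoot of bell-shaped UP CCGs).
#' `trim_to` truncates each UP state before counting, which is how UP-only
#' results are duration-matched to the UPnext scrambled control.
#'
#' @param a,b `spike_train`s.
#' @param up_epochs An `epoch_set`; rows labeled UP are used.
#' @param trim_to Optional numeric vector of durations (s), one per UP epoch.
#' @param bin_width,max_lag,smooth_window,pseudocount,alpha CCG/DCE
#'   parameters; `max_lag` defaults to 2 s.
#' @return A `dce_result` (variant UP_ONLY).
#' @export
up_only_dce <- function(a, b, up_epochs, trim_to = NULL, bin_width = 0.005,
                        max_lag = 2, smooth_window = 1.0, pseudocount = 1.0,
                        alpha = 1e-4) {
  up <- epochs_with_label(up_epochs, "UP")
  if (nrow(up) < 10)
    warning("fewer than 10 UP epochs; UP-only DCE will be unstable")
  if (!is.null(trim_to)) {
    stopifnot(length(trim_to) == nrow(up))
    up <- epoch_set(up$start, pmin(up$end, up$start + trim_to), "UP")
  }
  d <- pair_dce(a, b, up, "UP", bin_width = bin_width, max_lag = max_lag,
                smooth_window = smooth_window, pseudocount = pseudocount,
                variant = "UP_ONLY", alpha = alpha)
  d
}

#' UPnext scrambling control
#'
#' Shifts unit `a`'s within-UP spike pattern to the previous UP state: for
#' each UP state N >= 2, `a`'s spikes are re-anchored (as offsets from UP-N
#' onset) at UP N-1's onset, and the receiving UP state is trimmed to the
#' lesser of the two durations; spikes beyond the trimmed duration are
#' discarded, unit `b` is unchanged but equally trimmed, and the first UP
#' state's own pattern is dropped. This destroys simultaneous within-UP
#' structure while preserving each unit's per-UP statistics.
#'
#' @param a,b `spike_train`s.
#' @param up_epochs An `epoch_set` with >= 2 UP rows.
#' @return List with `a` (shifted train), `b` (trimmed train), `epochs`
#'   (trimmed receiving `epoch_set`), and `trim_to` (the trimmed durations,
#'   usable as `trim_to` for the duration-matched unscrambled comparison via
#'   [up_only_dce()] on the same receiving epochs).
#' @export
scramble_up_next <- function(a, b, up_epochs) {
  up <- epochs_with_label(up_epochs, "UP")
  if (nrow(up) < 2) stop("need at least 2 UP epochs")
  n <- nrow(up)
  dur <- up$end - up$start
  trim <- pmin(dur[-n], dur[-1])       # receiving UP k paired with source k+1
  recv <- epoch_set(up$start[-n], up$start[-n] + trim, "UP")
  # shift a's spikes from UP k+1 to UP k
  src_i <- epoch_index_of(a$times, up)
  keep <- !is.na(src_i) & src_i >= 2
  off <- a$times[keep] - up$start[src_i[keep]]
  dest <- src_i[keep] - 1L
  ok <- off < trim[dest]
  a_new <- a
  a_new$times <- sort(up$start[dest[ok]] + off[ok])
  b_new <- restrict_train(b, recv)
  list(a = a_new, b = b_new, epochs = recv, trim_to = trim)
}

#' UP-state spike-phase profile of a unit
#'
#' Divides each UP state into 50 equal phase bins (0% = UP onset, 100% = UP
#' end), converts each UP state's spike counts to a probability distribution,
#' and averages the distributions over UP states (UP states without spikes
#' are skipped).
#'
#' @param train A `spike_train`.
#' @param up_epochs An `epoch_set`; rows labeled UP are used.
#' @param n_bins Number of phase bins (default 50).
#' @return A list of class `up_profile`: `unit_id`, `bin_probs` (sums to 1),
#'   `mean_rate_up` (total UP spikes / total UP duration, Hz), `n_up_used`.
#' @export
up_spike_profile <- function(train, up_epochs, n_bins = 50L) {
  up <- epochs_with_label(up_epochs, "UP")
  if (!nrow(up)) stop("no UP epochs")
  ei <- epoch_index_of(train$times, up)
  keep <- !is.na(ei)
  if (!any(keep)) stop("unit ", train$unit_id, " has no UP-state spikes")
  t <- train$times[keep]; ei <- ei[keep]
  ph <- (t - up$start[ei]) / (up$end[ei] - up$start[ei])
  bin <- pmin(n_bins, floor(ph * n_bins) + 1L)
  cnt <- table(factor(ei, levels = unique(ei)),
               factor(bin, levels = seq_len(n_bins)))
  probs <- colMeans(sweep(cnt, 1, rowSums(cnt), "/"))
  structure(list(unit_id = train$unit_id, bin_probs = as.numeric(probs),
                 mean_rate_up = length(t) / epoch_duration(up),
                 n_up_used = nrow(cnt)),
            class = "up_profile")
}

#' @export
print.up_profile <- function(x, ...) {
  cat(sprintf("<up_profile> unit %s: %.2f Hz in UP, peak bin %d/%d (n_up=%d)\n",
              x$unit_id, x$mean_rate_up, which.max(x$bin_probs),
              length(x$bin_probs), x$n_up_used))
  invisible(x)
}

#' Simulate a pair of spike trains from averaged UP profiles
#'
#' Rebuilds spiking from per-unit average statistics alone: over a given
#' UP/DOWN schedule, each unit fires as an inhomogeneous Poisson process
#' whose rate over the 50 phase bins of each UP state is
#' `mean_rate_up * n_bins * bin_probs` (preserving the unit's UP firing
#' rate), with zero DOWN-state firing and the two trains drawn
#' independently. Comparing the resulting CCG/DCE with the real pair's tests
#' whether averaged per-cell statistics can reproduce the observed
#' correlation structure.
#'
#' @param prof_a,prof_b `up_profile` objects.
#' @param updown An `epoch_set` (UP rows used) giving the schedule.
#' @param seed Optional seed.
#' @return List with `spike_train`s `a` and `b`.
#' @export
simulate_profile_pair <- function(prof_a, prof_b, updown, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up <- epochs_with_label(updown, "UP")
  if (!nrow(up)) stop("no UP epochs")
  t1 <- max(up$end)
  mk <- function(prof, id) {
    t <- sim_profile_spikes(up$start, up$end, prof$mean_rate_up,
                            prof$bin_probs)
    spike_train(id, t, t_start = 0, t_end = t1)
  }
  list(a = mk(prof_a, paste0(prof_a$unit_id, "_sim")),
       b = mk(prof_b, paste0(prof_b$unit_id, "_sim")))
}

#' Profile-simulation null distribution for an observed DCE
#'
#' Simulates `n_sims` independent pairs from the two units' averaged UP
#' profiles over the same UP/DOWN schedule, computes the UP-only DCE of
#' each, and z-tests the observed DCE against that null.
#'
#' @param prof_a,prof_b `up_profile`s.
#' @param updown Schedule `epoch_set`.
#' @param observed_dce The real pair's UP-only DCE value.
#' @param n_sims Number of simulations (>= 30; default 100).
#' @param seed Optional seed.
#' @param ... Passed to [up_only_dce()].
#' @return List: `null_mean`, `null_sd`, `null_dces`, `z`, `p` (two-sided).
#' @export
dce_null_from_simulation <- function(prof_a, prof_b, updown, observed_dce,
                                     n_sims = 100, seed = NULL, ...) {
  stopifnot(n_sims >= 30)
  if (!is.null(seed)) set.seed(seed)
  dces <- vapply(seq_len(n_sims), function(i) {
    pr <- simulate_profile_pair(prof_a, prof_b, updown)
    suppressWarnings(up_only_dce(pr$a, pr$b, updown, ...)$dce)
  }, numeric(1))
  m <- mean(dces); s <- stats::sd(dces)
  if (s < 1e-12) stop("degenerate null distribution (sd = 0)")
  z <- (observed_dce - m) / s
  list(null_mean = m, null_sd = s, null_dces = dces, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Within-UP spike-timing difference metrics for a pair
#'
#' For each UP state where both units fire at least one spike: the
#' difference of first spike times and of mean spike times (seconds from UP
#' onset, unit a minus unit b). Returns the mean and SD of each difference
#' across qualifying UP states.
#'
#' @param a,b `spike_train`s.
#' @param up_epochs `epoch_set` with UP rows.
#' @return A list of class `spike_timing_metrics`: `pair`, `mean_diff_first`,
#'   `sd_diff_first`, `mean_diff_mean`, `sd_diff_mean`, `n_up_used`,
#'   `flagged` (TRUE when fewer than 10 qualifying UP states).
#' @export
up_timing_metrics <- function(a, b, up_epochs) {
  up <- epochs_with_label(up_epochs, "UP")
  fa <- per_up_stats(a, up); fb <- per_up_stats(b, up)
  common <- intersect(fa$up, fb$up)
  ia <- match(common, fa$up); ib <- match(common, fb$up)
  d_first <- fa$first[ia] - fb$first[ib]
  d_mean <- fa$mean[ia] - fb$mean[ib]
  structure(list(pair = c(a$unit_id, b$unit_id),
                 mean_diff_first = mean(d_first),
                 sd_diff_first = stats::sd(d_first),
                 mean_diff_mean = mean(d_mean),
                 sd_diff_mean = stats::sd(d_mean),
                 n_up_used = length(common),
                 flagged = length(common) < 10),
            class = "spike_timing_metrics")
}

per_up_stats <- function(train, up) {
  ei <- epoch_index_of(train$times, up)
  keep <- !is.na(ei)
  ei <- ei[keep]
  off <- train$times[keep] - up$start[ei]
  sp <- split(off, ei)
  list(up = as.integer(names(sp)),
       first = vapply(sp, min, numeric(1)),
       mean = vapply(sp, mean, numeric(1)))
}

#' Contrast timing metrics between trough and peak pairs
#'
#' Splits pairs into trough (significant negative DCE) and peak (significant
#' positive DCE) groups using a DCE table, then for each of the four timing
#' metrics compares the two groups (Wilcoxon rank-sum) and reports the
#' fraction of pairs in each group whose mean timing difference is
#' significantly nonzero (per-pair one-sample t test from the summary
#' statistics).
#'
#' @param metrics List of `spike_timing_metrics` (one per pair).
#' @param dce_table A `dce_table` (typically the NREM rows or UP-only DCEs)
#'   with one row per pair.
#' @param alpha_pair Per-pair one-sample alpha (default 0.05).
#' @return A list with `n_trough`, `n_peak`, and a data frame `tests`
#'   (metric, trough/peak means, p), plus `nonzero_frac` per group/metric.
#' @export
timing_metric_contrast <- function(metrics, dce_table, alpha_pair = 0.05) {
  key <- vapply(metrics, function(m) paste(sort(m$pair), collapse = "|"),
                character(1))
  tab_key <- paste(pmin(dce_table$unit_a, dce_table$unit_b),
                   pmax(dce_table$unit_a, dce_table$unit_b), sep = "|")
  idx <- match(key, tab_key)
  if (anyNA(idx)) stop("metrics contain pairs missing from the DCE table")
  grp <- ifelse(dce_table$significant[idx] & dce_table$dce[idx] < 0, "trough",
                ifelse(dce_table$significant[idx] & dce_table$dce[idx] > 0,
                       "peak", NA_character_))
  if (sum(grp == "trough", na.rm = TRUE) < 5 ||
      sum(grp == "peak", na.rm = TRUE) < 5)
    stop("need at least 5 trough and 5 peak pairs")
  m2df <- function(m) data.frame(mean_diff_first = m$mean_diff_first,
                                 sd_diff_first = m$sd_diff_first,
                                 mean_diff_mean = m$mean_diff_mean,
                                 sd_diff_mean = m$sd_diff_mean,
                                 n = m$n_up_used)
  df <- do.call(rbind, lapply(metrics, m2df))
  df$group <- grp
  df <- df[!is.na(df$group), , drop = FALSE]
  cols <- c("mean_diff_first", "sd_diff_first", "mean_diff_mean",
            "sd_diff_mean")
  tests <- do.call(rbind, lapply(cols, function(cl) {
    x <- abs(df[[cl]][df$group == "trough"])
    y <- abs(df[[cl]][df$group == "peak"])
    data.frame(metric = cl, trough_mean = mean(x), peak_mean = mean(y),
               p = stats::wilcox.test(x, y)$p.value,
               stringsAsFactors = FALSE)
  }))
  # per-pair one-sample t on the mean difference, from summary stats
  one_sample_p <- function(m, s, n) {
    tt <- m / (s / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1)
  }
  nz <- do.call(rbind, lapply(c("first", "mean"), function(which) {
    m <- df[[paste0("mean_diff_", which)]]
    s <- df[[paste0("sd_diff_", which)]]
    p <- one_sample_p(m, s, df$n)
    data.frame(metric = paste0("diff_", which),
               trough_nonzero_frac = mean(p[df$group == "trough"] < alpha_pair),
               peak_nonzero_frac = mean(p[df$group == "peak"] < alpha_pair),
               stringsAsFactors = FALSE)
  }))
  list(n_trough = sum(df$group == "trough"), n_peak = sum(df$group == "peak"),
       tests = tests, nonzero_frac = nz)
}
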