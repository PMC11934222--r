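#' Default analysis frequency bands
#'
#' Log-spaced bands over 0.5-80 Hz, including bands matching the 3.5-4.3 Hz
#' (delta-range) and 49-60 Hz (gamma-range) examples used in the band-power
#' modulation analyses.
#'
#' @param n Number of log-spaced bands in addition to the two named examples.
#' @return Data frame with columns `f_lo`, `f_hi` (Hz).
#' @export
default_bands <- function(n = 18) {
  edges <- exp(seq(log(0.5), log(80), length.out = n + 1))
  b <- data.frame(f_lo = edges[-length(edges)], f_hi = edges[-1])
  b <- rbind(b, data.frame(f_lo = c(3.5, 49), f_hi = c(4.3, 60)))
  b[order(b$f_lo), , drop = FALSE]
}

# Hann-windowed short-time power spectra, chunked to bound memory.
# Returns list(times = frame centers, power = frames x freq matrix, freq)
stft_power <- function(samples, rate, window_s = 1, overlap = 0.5,
                       chunk_frames = 20000L) {
  n <- round(window_s * rate)
  hop <- max(1L, round(n * (1 - overlap)))
  n_frames <- max(0L, (length(samples) - n) %/% hop + 1L)
  if (n_frames < 1) stop("LFP shorter than one analysis window")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  freq <- (seq_len(n %/% 2 + 1) - 1) * rate / n
  times <- ((seq_len(n_frames) - 1) * hop + n / 2) / rate
  pow <- matrix(NA_real_, n_frames, length(freq))
  f0 <- 1L
  while (f0 <= n_frames) {
    f1 <- min(n_frames, f0 + chunk_frames - 1L)
    starts <- (seq(f0, f1) - 1L) * hop
    seg <- matrix(samples[outer(seq_len(n), starts, "+")], nrow = n)
    seg <- seg * win
    sp <- stats::mvfft(seg)[seq_along(freq), , drop = FALSE]
    pow[f0:f1, ] <- t(Mod(sp)^2 / sum(win^2))
    f0 <- f1 + 1L
  }
  list(times = times, power = pow, freq = freq)
}

# iterated z-scoring with |z| > z_cut outlier removal; outliers become NA.
# Iterating until the retained set stabilizes makes the operation idempotent.
znorm_outliers <- function(x, z_cut = 3, max_iter = 20) {
  keep <- is.finite(x)
  for (i in seq_len(max_iter)) {
    m <- mean(x[keep]); s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) break
    z <- (x - m) / s
    new_keep <- is.finite(x) & abs(z) <= z_cut
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  m <- mean(x[keep]); s <- stats::sd(x[keep])
  out <- (x - m) / s
  out[!keep] <- NA_real_
  out
}

#' Band-power time series from an LFP trace
#'
#' Welch-style short-time power (Hann window, default 1 s frames with half
#' overlap) averaged over the frequency bins of each requested band. Frames
#' can be restricted to epochs of a given label, and each band's series can
#' be z-scored over time with |z| > 3 outliers removed (iterated until the
#' outlier set stabilizes, so re-normalizing is a no-op).
#'
#' @param lfp An `lfp` object (list with `samples`, `rate`), or such a list.
#' @param bands Data frame with `f_lo`, `f_hi` columns (Hz).
#' @param window_s Frame length in seconds.
#' @param epochs Optional `epoch_set` restriction.
#' @param label Label within `epochs` (default NREM when epochs given).
#' @param normalize Z-score with outlier removal (default TRUE).
#' @return A list of class `band_power`: `times` (frame centers, s), `power`
#'   (frames x bands matrix; NA where outliers were removed), `bands`,
#'   `normalized`.
#' @export
band_power_timeseries <- function(lfp, bands = default_bands(), window_s = 1,
                                  epochs = NULL, label = "NREM",
                                  normalize = TRUE) {
  stopifnot(all(bands$f_lo < bands$f_hi))
  if (any(bands$f_hi > lfp$rate / 2))
    stop("band above Nyquist frequency for this sample rate")
  st <- stft_power(lfp$samples, lfp$rate, window_s)
  if (!is.null(epochs)) {
    e <- epochs_with_label(epochs, label)
    keep <- spikes_in_epochs(st$times, e)
    st$times <- st$times[keep]
    st$power <- st$power[keep, , drop = FALSE]
  }
  df <- lfp$rate / round(window_s * lfp$rate)
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    cols <- st$freq >= bands$f_lo[i] & st$freq < bands$f_hi[i]
    if (!any(cols)) rep(NA_real_, nrow(st$power))
    else rowSums(st$power[, cols, drop = FALSE]) * df   # integrated power
  }, numeric(nrow(st$power)))
  bp <- matrix(bp, nrow = nrow(st$power))
  if (normalize) bp <- apply(bp, 2, znorm_outliers)
  structure(list(times = st$times, power = bp, bands = bands,
                 normalized = normalize),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %d frames x %d bands (%.2g-%.3g Hz)%s\n",
              length(x$times), nrow(x$bands), min(x$bands$f_lo),
              max(x$bands$f_hi), if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

windows_of <- function(total, window_s, min_last = window_s / 3) {
  starts <- seq(0, total - 1e-9, by = window_s)
  ends <- pmin(starts + window_s, total)
  keep <- (ends - starts) >= min_last
  data.frame(start = starts[keep], end = ends[keep])
}

#' Windowed DCE vs band-power correlation
#'
#' Divides the recording into windows (default 3 h, final partial window
#' kept if at least 1 h), computes each selected pair's nonREM-only DCE per
#' window and the mean normalized nonREM band power of the same window, and
#' reports per band the Spearman correlation between DCE and power pooled
#' over (pair, window) points. `use_abs = TRUE` correlates |DCE| (the
#' convention for trough-pair selections); `use_abs = FALSE` gives the
#' sign-split variant.
#'
#' @param trains List of `spike_train`s.
#' @param states State `epoch_set`.
#' @param lfp An `lfp` object.
#' @param pairs Data frame `unit_a`, `unit_b` of pairs to include (typically
#'   pairs with significant negative whole-recording NREM DCE; see
#'   [select_trough_pairs()]).
#' @param bands Band table.
#' @param window_s Window length in seconds (default 10800).
#' @param use_abs Correlate |DCE| (default) or signed DCE.
#' @param min_points Minimum pooled points per band before flagging.
#' @param ... CCG/DCE parameters.
#' @return A list with `points` (pair, window, dce, per-band power) and
#'   `correlations` (band, R, p, n, flagged).
#' @export
windowed_dce_power_correlation <- function(trains, states, lfp, pairs,
                                           bands = default_bands(),
                                           window_s = 10800, use_abs = TRUE,
                                           min_points = 10, ...) {
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  total <- max(states$end)
  win <- windows_of(total, window_s)
  if (nrow(win) < 2) stop("recording shorter than two windows")
  bp <- band_power_timeseries(lfp, bands, epochs = states, label = "NREM",
                              normalize = TRUE)
  pts <- list()
  for (w in seq_len(nrow(win))) {
    nrem_w <- clip_epochs(epochs_with_label(states, "NREM"),
                          win$start[w], win$end[w])
    if (!nrow(nrem_w)) next
    fr <- bp$times >= win$start[w] & bp$times < win$end[w]
    pw <- colMeans(bp$power[fr, , drop = FALSE], na.rm = TRUE)
    for (i in seq_len(nrow(pairs))) {
      d <- tryCatch(pair_dce(trains[[pairs$unit_a[i]]],
                             trains[[pairs$unit_b[i]]], nrem_w, NULL, ...),
                    error = function(e) NULL)
      if (is.null(d)) next
      pts[[length(pts) + 1]] <- c(pair = i, window = w, dce = d$dce, pw)
    }
  }
  if (!length(pts)) stop("no (pair, window) points")
  mat <- do.call(rbind, pts)
  dvec <- if (use_abs) abs(mat[, "dce"]) else mat[, "dce"]
  cors <- do.call(rbind, lapply(seq_len(nrow(bands)), function(bi) {
    p <- mat[, 3 + bi]
    ok <- is.finite(p) & is.finite(dvec)
    flagged <- sum(ok) < min_points || stats::sd(p[ok]) == 0
    if (flagged || stats::sd(dvec[ok]) == 0) {
      data.frame(f_lo = bands$f_lo[bi], f_hi = bands$f_hi[bi], R = NA_real_,
                 p = NA_real_, n = sum(ok), flagged = TRUE)
    } else {
      ct <- suppressWarnings(stats::cor.test(dvec[ok], p[ok],
                                             method = "spearman"))
      data.frame(f_lo = bands$f_lo[bi], f_hi = bands$f_hi[bi],
                 R = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 flagged = FALSE)
    }
  }))
  list(points = mat, correlations = cors, window_s = window_s,
       use_abs = use_abs)
}

#' Select pairs with significant negative nonREM DCE
#'
#' @param table A `dce_table`.
#' @param state State to select on (default NREM).
#' @param sign `-1` for troughs (default) or `+1` for peaks.
#' @return Data frame `unit_a`, `unit_b`.
#' @export
select_trough_pairs <- function(table, state = "NREM", sign = -1) {
  sub <- table[table$state == state & table$significant &
               sign * table$dce > 0, , drop = FALSE]
  data.frame(unit_a = sub$unit_a, unit_b = sub$unit_b,
             stringsAsFactors = FALSE)
}

#' Per-quartile DCE vs nonREM epoch band power
#'
#' Ranks nonREM epochs into four quartiles by their mean band power, pools
#' the epochs of each quartile into one CCG/DCE per pair, and correlates
#' (Pearson) quartile mean power with DCE over (pair, quartile) points.
#'
#' @param trains List of `spike_train`s.
#' @param states State `epoch_set` (NREM rows used).
#' @param lfp An `lfp` object.
#' @param pairs Pair selection data frame.
#' @param band Single-row band data frame (`f_lo`, `f_hi`).
#' @param ... CCG/DCE parameters.
#' @return List with `quartiles` (pair, quartile, mean power, dce), `R`, `p`.
#' @export
quartile_dce_power <- function(trains, states, lfp, pairs,
                               band = data.frame(f_lo = 3.5, f_hi = 4.3),
                               ...) {
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  nrem <- epochs_with_label(states, "NREM")
  if (nrow(nrem) < 8) stop("need at least 8 nonREM epochs")
  bp <- band_power_timeseries(lfp, band, epochs = states, label = "NREM",
                              normalize = TRUE)
  ep_pow <- vapply(seq_len(nrow(nrem)), function(i) {
    fr <- bp$times >= nrem$start[i] & bp$times < nrem$end[i]
    mean(bp$power[fr, 1], na.rm = TRUE)
  }, numeric(1))
  # stable tie-break: rank by power then by epoch order
  qs <- cut(rank(ep_pow, ties.method = "first"), breaks = 4, labels = FALSE)
  rows <- list()
  for (q in 1:4) {
    eq <- nrem[qs == q, , drop = FALSE]
    if (!nrow(eq)) stop("empty power quartile")
    class(eq) <- c("epoch_set", "data.frame")
    for (i in seq_len(nrow(pairs))) {
      d <- pair_dce(trains[[pairs$unit_a[i]]], trains[[pairs$unit_b[i]]],
                    eq, NULL, ...)
      rows[[length(rows) + 1]] <- data.frame(
        pair = i, quartile = q, power = mean(ep_pow[qs == q], na.rm = TRUE),
        dce = d$dce)
    }
  }
  df <- do.call(rbind, rows)
  ct <- suppressWarnings(stats::cor.test(df$power, df$dce))
  list(quartiles = df, R = unname(ct$estimate), p = ct$p.value)
}

#' NonREM epoch duration vs plateau band power
#'
#' For nonREM epochs longer than `min_dur_s` (default 200 s), averages each
#' band's normalized power over the epoch plateau (dropping the first
#' `trim_head_s` = 120 s and last `trim_tail_s` = 50 s, where power ramps
#' regardless of epoch duration) and reports the Pearson correlation of
#' epoch duration with plateau power per band.
#'
#' @param states State `epoch_set` (NREM rows used).
#' @param lfp An `lfp` object.
#' @param bands Band table.
#' @param min_dur_s,trim_head_s,trim_tail_s Epoch selection and trimming.
#' @return List with `epochs` (duration + per-band plateau power),
#'   `correlations` (band, R, p, n), `n_excluded`.
#' @export
epoch_duration_power_correlation <- function(states, lfp,
                                             bands = default_bands(),
                                             min_dur_s = 200,
                                             trim_head_s = 120,
                                             trim_tail_s = 50) {
  nrem <- epochs_with_label(states, "NREM")
  dur <- nrem$end - nrem$start
  cand <- which(dur > min_dur_s &
                dur > trim_head_s + trim_tail_s + 1)
  n_excluded <- nrow(nrem) - length(cand)
  if (length(cand) < 10) stop("fewer than 10 qualifying nonREM epochs")
  bp <- band_power_timeseries(lfp, bands, epochs = states, label = "NREM",
                              normalize = TRUE)
  pw <- t(vapply(cand, function(i) {
    fr <- bp$times >= nrem$start[i] + trim_head_s &
          bp$times < nrem$end[i] - trim_tail_s
    colMeans(bp$power[fr, , drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(bands))))
  d <- dur[cand]
  cors <- do.call(rbind, lapply(seq_len(nrow(bands)), function(bi) {
    ok <- is.finite(pw[, bi])
    if (sum(ok) < 3 || stats::sd(d[ok]) == 0 || stats::sd(pw[ok, bi]) == 0)
      return(data.frame(f_lo = bands$f_lo[bi], f_hi = bands$f_hi[bi],
                        R = NA_real_, p = NA_real_, n = sum(ok),
                        flagged = TRUE))
    ct <- stats::cor.test(d[ok], pw[ok, bi])
    data.frame(f_lo = bands$f_lo[bi], f_hi = bands$f_hi[bi],
               R = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               flagged = FALSE)
  }))
  list(epochs = data.frame(duration = d, pw), correlations = cors,
       n_excluded = n_excluded)
}

#' DCE temporal-stability matrix
#'
#' Selects the `n_units` units participating in the most significant
#' negative nonREM DCE pairs, builds the pair x window matrix of windowed
#' nonREM DCEs for those pairs, and compares the mean per-pair SD over
#' windows against the distribution obtained by shuffling values within each
#' window (z-test). A small real-vs-shuffled SD indicates pair correlation
#' tendencies are conserved over the recording.
#'
#' @param trains List of `spike_train`s.
#' @param states State `epoch_set`.
#' @param table Optional precomputed whole-recording `dce_table`.
#' @param window_s Window length (default 10800 s).
#' @param n_units Number of least-synchronized units to keep (default 20).
#' @param n_shuffle Number of within-window shuffles (default 200).
#' @param seed Optional seed.
#' @param ... CCG/DCE parameters.
#' @return List: `matrix` (pair x window DCE), `mean_sd`, `shuffle_mean_sd`,
#'   `z`, `p`, `pairs`.
#' @export
dce_stability_matrix <- function(trains, states, table = NULL,
                                 window_s = 10800, n_units = 20,
                                 n_shuffle = 200, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  total <- max(states$end)
  win <- windows_of(total, window_s)
  if (nrow(win) < 2) stop("need at least 2 windows")
  if (is.null(table)) table <- state_dce_table(trains, states, ...)
  neg <- table[table$state == "NREM" & table$significant & table$dce < 0, ,
               drop = FALSE]
  if (!nrow(neg)) stop("no significant negative NREM pairs")
  units <- sort(table(c(neg$unit_a, neg$unit_b)), decreasing = TRUE)
  keep_units <- names(units)[seq_len(min(n_units, length(units)))]
  sel <- neg[neg$unit_a %in% keep_units & neg$unit_b %in% keep_units, ,
             drop = FALSE]
  if (!nrow(sel)) sel <- neg
  m <- matrix(NA_real_, nrow(sel), nrow(win))
  for (w in seq_len(nrow(win))) {
    nrem_w <- clip_epochs(epochs_with_label(states, "NREM"),
                          win$start[w], win$end[w])
    if (!nrow(nrem_w)) next
    for (i in seq_len(nrow(sel))) {
      d <- tryCatch(pair_dce(trains[[sel$unit_a[i]]], trains[[sel$unit_b[i]]],
                             nrem_w, NULL, ...), error = function(e) NULL)
      if (!is.null(d)) m[i, w] <- d$dce
    }
  }
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  mean_sd <- mean(sds, na.rm = TRUE)
  shuf <- vapply(seq_len(n_shuffle), function(k) {
    ms <- apply(m, 2, function(col) sample(col))
    mean(apply(ms, 1, stats::sd, na.rm = TRUE), na.rm = TRUE)
  }, numeric(1))
  z <- (mean_sd - mean(shuf)) / stats::sd(shuf)
  list(matrix = m, mean_sd = mean_sd, shuffle_mean_sd = mean(shuf),
       z = z, p = 2 * stats::pnorm(-abs(z)),
       pairs = sel[, c("unit_a", "unit_b")])
}
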