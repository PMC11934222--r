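#' @useDynLib statesync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_ccg <- function(pair, lag_centers, counts, bin_width, max_lag, n_epochs,
                    empty = FALSE) {
  structure(list(pair = pair, lag_centers = lag_centers, counts = counts,
                 bin_width = bin_width, max_lag = max_lag,
                 n_epochs = n_epochs, empty = empty),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> pair (%s, %s): %d bins of %.1f ms, max lag %.2f s, %d epochs, %g pair counts%s\n",
              x$pair[1], x$pair[2], length(x$counts), 1000 * x$bin_width,
              x$max_lag, x$n_epochs, sum(x$counts),
              if (isTRUE(x$empty)) " [empty]" else ""))
  invisible(x)
}

ccg_lag_centers <- function(bin_width, max_lag) {
  n_bins <- round(2 * max_lag / bin_width)
  seq(-max_lag + bin_width / 2, by = bin_width, length.out = n_bins)
}

#' Cross-correlogram of two spike trains over labeled epochs
#'
#' Counts spike pairs with lag `t_b - t_a` in `[-max_lag, max_lag)`,
#' separately within each epoch carrying `label` (only same-epoch pairs are
#' counted), and sums the per-epoch histograms.
#'
#' @param a,b `spike_train` objects. The lag convention is `t_b - t_a`, so a
#'   positive-lag count means `b` fires after `a`.
#' @param epochs An `epoch_set`; only intervals with `label` are used
#'   (`label = NULL` uses all intervals).
#' @param label Epoch label to select (e.g. `"NREM"`).
#' @param bin_width Histogram bin width in seconds. Default 5 ms so the
#'   downstream 250 ms center and 125 ms edge windows contain whole bins.
#' @param max_lag Maximum lag in seconds; must be a positive integer multiple
#'   of `bin_width`.
#' @return A `ccg` object. If no spikes of either train fall in the selected
#'   epochs, all counts are zero and the `empty` flag is set (with a warning).
#' @export
compute_ccg <- function(a, b, epochs, label = NULL, bin_width = 0.005,
                        max_lag = 1) {
  if (!inherits(a, "spike_train") || !inherits(b, "spike_train"))
    stop("a and b must be spike_train objects")
  stopifnot(bin_width > 0, max_lag > 0)
  n_bins <- round(2 * max_lag / bin_width)
  if (abs(n_bins * bin_width / 2 - max_lag) > 1e-9)
    stop("max_lag must be an integer multiple of bin_width")
  e <- epochs_with_label(epochs, label)
  if (!nrow(e)) stop("no epochs with label ", paste(label, collapse = "/"))
  counts <- .ccg_count_cpp(a$times, b$times, e$start, e$end, bin_width, n_bins)
  empty <- sum(spikes_in_epochs(a$times, e)) == 0 ||
           sum(spikes_in_epochs(b$times, e)) == 0
  if (empty) warning("no spikes of one or both trains in the selected epochs")
  new_ccg(c(a$unit_id, b$unit_id), ccg_lag_centers(bin_width, max_lag),
          as.numeric(counts), bin_width, max_lag, nrow(e), empty = empty)
}

#' Triangular smoothing of a CCG
#'
#' Convolves the counts with a unit-area symmetric triangular kernel. Near the
#' lag-range boundaries the kernel is renormalized over its in-range support,
#' so a flat CCG stays exactly flat. This smoothed CCG is the standard
#' normalization baseline: it is the expectation of the CCG under local
#' interval jitter of both trains (see [jitter_baseline()]).
#'
#' @param ccg A `ccg` object.
#' @param window Total kernel width in seconds (default 1 s). Rounded to the
#'   nearest odd number of bins; the realized width is stored in the result's
#'   `smooth_window` field.
#' @return A `ccg` with smoothed counts.
#' @export
smooth_triangular <- function(ccg, window = 1.0) {
  bw <- ccg$bin_width
  if (window < 2 * bw) stop("smoothing window must be at least two bins wide")
  n_k <- round(window / bw)
  if (n_k %% 2 == 0) n_k <- n_k + 1    # nearest odd bin count, rounding up
  half <- (n_k - 1L) / 2L
  kern <- (half + 1) - abs(seq(-half, half))
  kern <- kern / sum(kern)
  x <- ccg$counts
  n <- length(x)
  sm <- stats::filter(x, kern, sides = 2)
  sm <- as.numeric(sm)
  # renormalized edges: average with the truncated kernel
  for (i in seq_len(min(half, n))) {
    j <- max(1, i - half):min(n, i + half)
    k <- kern[j - i + half + 1]
    sm[i] <- sum(x[j] * k) / sum(k)
    i2 <- n - i + 1
    j <- max(1, i2 - half):min(n, i2 + half)
    k <- kern[j - i2 + half + 1]
    sm[i2] <- sum(x[j] * k) / sum(k)
  }
  out <- ccg
  out$counts <- sm
  out$smooth_window <- n_k * bw
  out
}

#' Interval-jitter baseline CCG
#'
#' Re-draws every spike of both trains uniformly within its fixed jitter
#' partition window (contiguous `jitter_window`-second windows anchored at
#' each epoch's start), recomputes the CCG, and averages over `reps`
#' repetitions. Interval jitter preserves coarse rate covariation while
#' destroying spike-timing structure finer than the window, so dividing the
#' raw CCG by this baseline isolates fine-timescale structure. Its
#' expectation equals the raw CCG convolved with a triangular kernel of
#' twice the window width, which is why [smooth_triangular()] is the default
#' (deterministic and cheaper) baseline.
#'
#' @inheritParams compute_ccg
#' @param jitter_window Partition width in seconds (default 0.5 s).
#' @param reps Number of jitter repetitions to average (default 3).
#' @param seed Optional integer seed.
#' @return A `ccg` whose counts are the mean over repetitions.
#' @export
jitter_baseline <- function(a, b, epochs, label = NULL, jitter_window = 0.5,
                            reps = 3, seed = NULL, bin_width = 0.005,
                            max_lag = 1) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  e <- epochs_with_label(epochs, label)
  if (!nrow(e)) stop("no epochs with label ", paste(label, collapse = "/"))
  acc <- NULL
  for (r in seq_len(reps)) {
    aj <- jitter_train(a, e, jitter_window)
    bj <- jitter_train(b, e, jitter_window)
    cc <- suppressWarnings(compute_ccg(aj, bj, e, NULL, bin_width, max_lag))
    acc <- if (is.null(acc)) cc$counts else acc + cc$counts
  }
  out <- suppressWarnings(compute_ccg(a, b, e, NULL, bin_width, max_lag))
  out$counts <- acc / reps
  out
}

# uniform re-draw of each spike inside its jitter partition window
# (windows anchored at epoch start; last partial window clipped to epoch end)
jitter_train <- function(train, epochs, jitter_window) {
  t <- train$times
  ep <- epoch_index_of(t, epochs)
  keep <- !is.na(ep)
  t <- t[keep]; ep <- ep[keep]
  if (length(t)) {
    s <- epochs$start[ep]; e <- epochs$end[ep]
    w0 <- s + floor((t - s) / jitter_window) * jitter_window
    w1 <- pmin(w0 + jitter_window, e)
    t <- w0 + stats::runif(length(t)) * (w1 - w0)
  }
  out <- train
  out$times <- sort(t)
  out
}

#' Normalize a CCG against a baseline
#'
#' Bin-wise natural-log ratio `log((raw + pseudocount) / (baseline +
#' pseudocount))`. The baseline is typically [smooth_triangular()] of the raw
#' CCG, or a [jitter_baseline()]. A flat raw CCG yields values of exactly 0;
#' the log makes positive (peak) and negative (trough) deviations comparable
#' in amplitude.
#'
#' @param raw,baseline `ccg` objects on the same lag grid.
#' @param pseudocount Added to numerator and denominator to bound the log at
#'   zero counts (default 1).
#' @param variant `"STANDARD"` or `"UP_ONLY"`; recorded for downstream DCE
#'   window selection.
#' @return A `norm_ccg` object with element `values` (dimensionless log
#'   ratios) on the shared lag grid. The log base (natural) and pseudocount
#'   are recorded in the object.
#' @export
normalize_ccg <- function(raw, baseline, pseudocount = 1.0,
                          variant = c("STANDARD", "UP_ONLY")) {
  variant <- match.arg(variant)
  if (length(raw$lag_centers) != length(baseline$lag_centers) ||
      max(abs(raw$lag_centers - baseline$lag_centers)) > 1e-9)
    stop("raw and baseline CCGs are on different lag grids")
  structure(list(pair = raw$pair, lag_centers = raw$lag_centers,
                 values = log((raw$counts + pseudocount) /
                              (baseline$counts + pseudocount)),
                 variant = variant, log_base = "e",
                 pseudocount = pseudocount,
                 bin_width = raw$bin_width, max_lag = raw$max_lag),
            class = "norm_ccg")
}

crop_ccg <- function(ccg, max_lag) {
  keep <- abs(ccg$lag_centers) <= max_lag + 1e-9
  out <- ccg
  out$lag_centers <- ccg$lag_centers[keep]
  out$counts <- ccg$counts[keep]
  out$max_lag <- max_lag
  out
}

#' Normalized CCG for a pair in one call
#'
#' Convenience wrapper: raw CCG, triangular-smoothed baseline, log-ratio
#' normalization. The raw CCG is computed on a lag grid extended by half the
#' smoothing window and cropped back after smoothing, so the baseline is free
#' of kernel-truncation bias at the lag-range boundaries (this keeps the
#' triangular baseline interchangeable with the jitter baseline out to the
#' edge windows).
#'
#' @inheritParams compute_ccg
#' @param smooth_window Triangular kernel width in seconds.
#' @param pseudocount See [normalize_ccg()].
#' @param variant See [normalize_ccg()].
#' @param pad Extend the lag grid before smoothing (default TRUE).
#' @export
normalized_ccg <- function(a, b, epochs, label = NULL, bin_width = 0.005,
                           max_lag = 1, smooth_window = 1.0, pseudocount = 1.0,
                           variant = c("STANDARD", "UP_ONLY"), pad = TRUE) {
  ext <- if (pad) ceiling(smooth_window / 2 / bin_width) * bin_width else 0
  raw <- suppressWarnings(compute_ccg(a, b, epochs, label, bin_width,
                                      max_lag + ext))
  sm <- smooth_triangular(raw, smooth_window)
  if (ext > 0) {
    raw <- crop_ccg(raw, max_lag)
    sm <- crop_ccg(sm, max_lag)
  }
  normalize_ccg(raw, sm, pseudocount, match.arg(variant))
}

#' @export
print.norm_ccg <- function(x, ...) {
  cat(sprintf("<norm_ccg> pair (%s, %s), %s, %d bins, range [%.3f, %.3f]\n",
              x$pair[1], x$pair[2], x$variant, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Center-minus-edge statistic (DCE) of a normalized CCG
#'
#' The DCE is the mean normalized-CCG amplitude in the central 250 ms lag
#' window minus the mean amplitude in the edge windows, with significance
#' from a Welch two-sample t test between the two sets of bin values at
#' alpha 1e-4. Positive DCE indicates a central peak (synchrony), negative a
#' central trough (antisynchrony).
#'
#' Edge definition by variant: `STANDARD` uses the outermost 125 ms at both
#' ends of the lag range (requires `max_lag >= 1` s); `UP_ONLY` uses
#' 1 s <= |lag| <= 2 s (requires `max_lag >= 2` s), avoiding the boundary
#' undershoot produced by bell-shaped UP-state CCGs.
#'
#' @param nccg A `norm_ccg`.
#' @param variant `"STANDARD"` or `"UP_ONLY"`; defaults to the variant stored
#'   in `nccg`.
#' @param alpha Significance level (default 1e-4).
#' @param center_halfwidth Half-width of the center window in seconds
#'   (default 0.125, i.e. a 250 ms window).
#' @param edge_width Width of each edge window in seconds for the STANDARD
#'   variant (default 0.125).
#' @return A `dce_result` list: `pair`, `variant`, `dce`, `p_value`,
#'   `significant` (`p < alpha`), `dce_sig` (`dce` if significant else 0, the
#'   the "nonzero DCE means significant" convention used in population
#'   summaries),
#'   `center_window`, `edge_window`, `n_center`, `n_edge`.
#' @export
compute_dce <- function(nccg, variant = NULL, alpha = 1e-4,
                        center_halfwidth = 0.125, edge_width = 0.125) {
  if (is.null(variant)) variant <- nccg$variant
  variant <- match.arg(variant, c("STANDARD", "UP_ONLY"))
  lag <- nccg$lag_centers
  tol <- 1e-9
  center <- abs(lag) <= center_halfwidth + tol
  if (variant == "STANDARD") {
    if (nccg$max_lag < 1 - tol)
      stop("STANDARD DCE needs max_lag >= 1 s")
    edge <- abs(lag) >= nccg$max_lag - edge_width - tol
    edge_window <- c(nccg$max_lag - edge_width, nccg$max_lag)
  } else {
    if (nccg$max_lag < 2 - tol)
      stop("UP_ONLY DCE needs max_lag >= 2 s")
    edge <- abs(lag) >= 1 - tol & abs(lag) <= 2 + tol
    edge_window <- c(1, 2)
  }
  cv <- nccg$values[center]; ev <- nccg$values[edge]
  if (length(cv) < 2 || length(ev) < 2)
    stop("fewer than 2 bins in a DCE window")
  dce <- mean(cv) - mean(ev)
  if (stats::sd(cv) < 1e-12 && stats::sd(ev) < 1e-12) {
    p <- if (abs(dce) < 1e-12) 1 else 0
  } else {
    p <- stats::t.test(cv, ev)$p.value   # Welch, unequal variance
  }
  sig <- is.finite(p) && p < alpha
  structure(list(pair = nccg$pair, variant = variant, dce = dce,
                 p_value = p, significant = sig,
                 dce_sig = if (sig) dce else 0,
                 center_window = c(-center_halfwidth, center_halfwidth),
                 edge_window = edge_window,
                 n_center = length(cv), n_edge = length(ev),
                 alpha = alpha),
            class = "dce_result")
}

#' @export
print.dce_result <- function(x, ...) {
  cat(sprintf("<dce_result> pair (%s, %s) %s: dce = %.4f, p = %.3g%s\n",
              x$pair[1], x$pair[2], x$variant, x$dce, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pair DCE for one state in one call
#'
#' Raw CCG, triangular baseline, normalization, and DCE.
#'
#' @inheritParams normalized_ccg
#' @inheritParams compute_dce
#' @export
pair_dce <- function(a, b, epochs, label = NULL, bin_width = 0.005,
                     max_lag = 1, smooth_window = 1.0, pseudocount = 1.0,
                     variant = c("STANDARD", "UP_ONLY"), alpha = 1e-4) {
  variant <- match.arg(variant)
  compute_dce(normalized_ccg(a, b, epochs, label, bin_width, max_lag,
                             smooth_window, pseudocount, variant),
              alpha = alpha)
}
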