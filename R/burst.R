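#' Fit a two-component Gaussian mixture to log10 ISIs
#'
#' Models a unit's log10 interspike-interval distribution as a mixture of a
#' fast (within-burst) and a slow component. The unit is flagged bimodal
#' only when the component means are at least 1 log10(s) apart. The burst
#' threshold is two standard deviations from the fast mean toward the
#' separatrix (the density minimum between the two means), capped at the
#' separatrix.
#'
#' @param train A `spike_train` with >= 100 ISIs.
#' @param min_separation Required component-mean separation in log10 s
#'   (default 1).
#' @importFrom mclust Mclust mclustBIC
#' @return A list of class `burst_model`: `unit_id`, `mu_fast`, `sigma_fast`,
#'   `mu_slow`, `sigma_slow` (log10 s), `weight_fast`, `separatrix` (log10 s),
#'   `threshold_s` (seconds; `NA` unless bimodal), `bimodal`.
#' @export
fit_log_isi_mixture <- function(train, min_separation = 1.0) {
  isi <- diff(train$times)
  isi <- isi[isi > 0]
  if (length(isi) < 100) stop("need at least 100 positive ISIs")
  l <- log10(isi)
  fit <- tryCatch(
    mclust::Mclust(l, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  out <- list(unit_id = train$unit_id, mu_fast = NA_real_,
              sigma_fast = NA_real_, mu_slow = NA_real_,
              sigma_slow = NA_real_, weight_fast = NA_real_,
              separatrix = NA_real_, threshold_s = NA_real_, bimodal = FALSE)
  class(out) <- "burst_model"
  if (is.null(fit) || length(fit$parameters$mean) != 2) return(out)
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; w <- w[o]
  out$mu_fast <- mu[1]; out$sigma_fast <- sg[1]
  out$mu_slow <- mu[2]; out$sigma_slow <- sg[2]
  out$weight_fast <- w[1]
  if (any(sg < 1e-6) || (mu[2] - mu[1]) < min_separation) return(out)
  # separatrix: density minimum between the means (0.001 log10-s scan)
  grid <- seq(mu[1], mu[2], by = 0.001)
  dens <- w[1] * stats::dnorm(grid, mu[1], sg[1]) +
          w[2] * stats::dnorm(grid, mu[2], sg[2])
  out$separatrix <- grid[which.min(dens)]
  out$bimodal <- TRUE
  out$threshold_s <- 10^min(mu[1] + 2 * sg[1], out$separatrix)
  out
}

#' @export
print.burst_model <- function(x, ...) {
  if (x$bimodal)
    cat(sprintf("<burst_model> unit %s: bimodal (mu %.2f/%.2f log10 s), threshold %.1f ms\n",
                x$unit_id, x$mu_fast, x$mu_slow, 1000 * x$threshold_s))
  else
    cat(sprintf("<burst_model> unit %s: not bimodal\n", x$unit_id))
  invisible(x)
}

#' Indices of burst spikes
#'
#' Burst spikes are the members of maximal runs of three or more consecutive
#' spikes whose successive ISIs are all below `threshold_s`; every spike of
#' such a run (including the first) is marked.
#'
#' @param train A `spike_train`.
#' @param threshold_s ISI threshold in seconds.
#' @param keep_run_head If TRUE, the first spike of each run is not marked
#'   (alternative reading of the removal rule; default FALSE).
#' @return Integer vector of spike indices.
#' @export
find_burst_spikes <- function(train, threshold_s, keep_run_head = FALSE) {
  stopifnot(threshold_s > 0)
  n <- length(train$times)
  if (n < 3) return(integer(0))
  fast <- diff(train$times) < threshold_s
  r <- rle(fast)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 2)   # >= 2 fast ISIs = >= 3 spikes
  idx <- unlist(lapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k] + 1L      # spike span of the ISI run
    if (keep_run_head) (i0 + 1L):i1 else i0:i1
  }))
  sort(unique(as.integer(idx)))
}

#' Remove specific or random spikes from a train
#'
#' Either removes the spikes at `indices`, or (`n_random` mode) removes
#' `n_random` spikes drawn uniformly without replacement from the spikes
#' inside the NREM epochs — the count-matched control for burst removal.
#'
#' @param train A `spike_train`.
#' @param indices Spike indices to remove.
#' @param n_random Number of random NREM spikes to remove (exclusive with
#'   `indices`).
#' @param nrem_epochs Required for `n_random` mode.
#' @param seed Optional seed.
#' @return A `spike_train`.
#' @export
remove_spikes <- function(train, indices = NULL, n_random = NULL,
                          nrem_epochs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(indices) && !is.null(n_random))
    stop("give either indices or n_random, not both")
  if (!is.null(n_random)) {
    stopifnot(!is.null(nrem_epochs))
    pool <- which(spikes_in_epochs(train$times,
                                   epochs_with_label(nrem_epochs, "NREM")))
    if (n_random > length(pool))
      stop("n_random exceeds the available NREM spikes")
    indices <- sample(pool, n_random)
  }
  out <- train
  if (length(indices)) out$times <- train$times[-indices]
  out
}

#' Post-removal DCE relative to the original DCE
#'
#' `dce_post / dce_original`, categorized: above 1 the correlation or
#' anticorrelation is amplified, between 0 and 1 reduced, below 0 reversed.
#'
#' @param dce_post,dce_original DCE values; `dce_original` must be nonzero.
#' @return List with `ratio` and `category`.
#' @export
dce_ratio <- function(dce_post, dce_original) {
  if (dce_original == 0) stop("dce_original is zero; ratio undefined")
  r <- dce_post / dce_original
  list(ratio = r,
       category = if (r > 1) "AMPLIFIED" else if (r >= 0) "REDUCED"
                  else "REVERSED")
}

#' Burst / random spike-removal sweep for a pair
#'
#' Recomputes the pair's nonREM DCE after removing spikes at increasing
#' levels, in three matched modes: `BURST_THRESHOLD` scales the ISI cutoff
#' (`level * threshold_s` per unit) and removes the resulting burst runs;
#' `BURST_PERCENT` removes, per unit, a random subset of the at-threshold
#' burst spikes of the same size as the threshold mode removed at that
#' level; `RANDOM` removes the same per-unit count anywhere in nonREM. A
#' level of 0 removes nothing (ratio 1) and a level of 1 corresponds to the
#' full fitted threshold.
#'
#' @param a,b `spike_train`s.
#' @param states `epoch_set` with NREM rows (DCE is computed in NREM).
#' @param levels Numeric removal levels in `[0, 1]`.
#' @param models Optional list of two `burst_model`s (fitted on NREM ISIs
#'   otherwise).
#' @param modes Subset of the three modes.
#' @param seed Optional seed.
#' @param ... CCG/DCE parameters passed through.
#' @return Data frame with columns `mode`, `level`, `n_removed_a`,
#'   `n_removed_b`, `dce_post`, `dce_ratio`, `category`, `flagged` (TRUE when
#'   the original DCE is 0 and the ratio is undefined). Attribute
#'   `dce_original`.
#' @export
removal_sweep <- function(a, b, states, levels = c(0, 0.25, 0.5, 0.75, 1),
                          models = NULL,
                          modes = c("BURST_THRESHOLD", "BURST_PERCENT",
                                    "RANDOM"),
                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nrem <- epochs_with_label(states, "NREM")
  a_n <- restrict_train(a, nrem); b_n <- restrict_train(b, nrem)
  if (is.null(models))
    models <- list(fit_log_isi_mixture(a_n), fit_log_isi_mixture(b_n))
  thr <- vapply(models, function(m)
    if (isTRUE(m$bimodal)) m$threshold_s else NA_real_, numeric(1))
  if (anyNA(thr))
    stop("both units need a bimodal log-ISI mixture (burst threshold)")
  d0 <- pair_dce(a, b, states, "NREM", ...)
  base_burst <- list(find_burst_spikes(a_n, thr[1]),
                     find_burst_spikes(b_n, thr[2]))
  trains_n <- list(a_n, b_n)
  rows <- list()
  for (lv in levels) {
    # threshold mode defines the per-unit matched counts at this level
    idx_thr <- lapply(1:2, function(u)
      if (lv <= 0) integer(0)
      else find_burst_spikes(trains_n[[u]], lv * thr[u]))
    n_rm <- lengths(idx_thr)
    for (md in modes) {
      idx <- switch(md,
        BURST_THRESHOLD = idx_thr,
        BURST_PERCENT = lapply(1:2, function(u)
          if (n_rm[u] == 0) integer(0)
          else sample(base_burst[[u]], min(n_rm[u],
                                           length(base_burst[[u]])))),
        RANDOM = lapply(1:2, function(u)
          if (n_rm[u] == 0) integer(0)
          else sample.int(length(trains_n[[u]]$times), n_rm[u])))
      a2 <- remove_spikes(trains_n[[1]], indices = idx[[1]])
      b2 <- remove_spikes(trains_n[[2]], indices = idx[[2]])
      d <- pair_dce(a2, b2, states, "NREM", ...)
      flag <- d0$dce == 0
      rows[[length(rows) + 1]] <- data.frame(
        mode = md, level = lv, n_removed_a = length(idx[[1]]),
        n_removed_b = length(idx[[2]]), dce_post = d$dce,
        dce_ratio = if (flag) NA_real_ else d$dce / d0$dce,
        category = if (flag) NA_character_
                   else dce_ratio(d$dce, d0$dce)$category,
        flagged = flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dce_original") <- d0$dce
  attr(out, "thresholds_s") <- thr
  out
}
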