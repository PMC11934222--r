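#' Per-state DCE table for a set of spike trains
#'
#' Computes, for every requested unit pair and every sleep state present in
#' `states`, the normalized CCG and its DCE. This is the population-level
#' entry point behind stacked-CCG displays and the trough/peak summaries.
#'
#' @param trains List of `spike_train`s (names are taken from the unit ids).
#' @param states An `epoch_set` with labels among WAKE/NREM/REM.
#' @param pairs Optional data frame with columns `unit_a`, `unit_b` selecting
#'   the pairs to analyze (e.g. a generator's designated pairs). Default: all
#'   unordered pairs.
#' @param bin_width,max_lag,smooth_window,pseudocount,alpha Passed to the CCG
#'   and DCE layer.
#' @param recording_id Optional identifier stored on the table.
#' @return A data frame of class `dce_table` with one row per (pair, state):
#'   `unit_a`, `unit_b`, `state`, `dce`, `p_value`, `significant`, `dce_sig`
#'   (`dce` when significant, else 0). Pairs are ordered `unit_a < unit_b`.
#' @export
state_dce_table <- function(trains, states, pairs = NULL, bin_width = 0.005,
                            max_lag = 1, smooth_window = 1.0,
                            pseudocount = 1.0, alpha = 1e-4,
                            recording_id = NA_character_) {
  stopifnot(length(trains) >= 2)
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  if (is.null(pairs)) {
    cmb <- utils::combn(sort(ids), 2)
    pairs <- data.frame(unit_a = cmb[1, ], unit_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  swap <- pairs$unit_a > pairs$unit_b
  tmp <- pairs$unit_a[swap]
  pairs$unit_a[swap] <- pairs$unit_b[swap]
  pairs$unit_b[swap] <- tmp
  present <- intersect(c("NREM", "WAKE", "REM"), unique(states$label))
  present <- present[vapply(present, function(s)
    epoch_duration(states, s) > 0, logical(1))]
  rows <- vector("list", nrow(pairs) * length(present))
  k <- 0
  for (i in seq_len(nrow(pairs))) {
    a <- trains[[pairs$unit_a[i]]]; b <- trains[[pairs$unit_b[i]]]
    if (is.null(a) || is.null(b))
      stop("pair refers to unknown unit: ", pairs$unit_a[i], "/",
           pairs$unit_b[i])
    for (s in present) {
      d <- pair_dce(a, b, states, s, bin_width = bin_width, max_lag = max_lag,
                    smooth_window = smooth_window, pseudocount = pseudocount,
                    alpha = alpha)
      k <- k + 1
      rows[[k]] <- data.frame(unit_a = pairs$unit_a[i],
                              unit_b = pairs$unit_b[i], state = s,
                              dce = d$dce, p_value = d$p_value,
                              significant = d$significant,
                              dce_sig = d$dce_sig, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "recording_id") <- recording_id
  attr(out, "params") <- list(bin_width = bin_width, max_lag = max_lag,
                              smooth_window = smooth_window,
                              pseudocount = pseudocount, alpha = alpha)
  class(out) <- c("dce_table", "data.frame")
  out
}

#' Duration- and spike-matched downsampled DCE table
#'
#' Controls for unequal sampling across states: per repetition, whole NREM
#' and WAKE epochs are selected at random without replacement until their
#' cumulative duration first reaches the reference state's total (the state
#' with the least total duration, normally REM; slight overshoot by at most
#' one epoch is allowed), then spikes within the selected epochs are randomly
#' deleted so all states match the minimum per-state spike count. DCE is
#' computed per pair per state on the matched data; the returned `dce` is the
#' mean over repetitions and `significant` the majority vote.
#'
#' @inheritParams state_dce_table
#' @param reps Number of repetitions (default 3).
#' @param seed Optional seed.
#' @return A `dce_table` (with `p_value` the median over reps).
#' @export
downsample_matched_dce <- function(trains, states, pairs = NULL, reps = 3,
                                   seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  present <- intersect(c("NREM", "WAKE", "REM"), unique(states$label))
  durs <- vapply(present, function(s) epoch_duration(states, s), numeric(1))
  if (!length(durs) || min(durs) <= 0)
    stop("reference state has zero total duration")
  ref <- present[which.min(durs)]
  acc <- NULL
  for (r in seq_len(reps)) {
    sel <- lapply(present, function(s) {
      e <- epochs_with_label(states, s)
      if (s == ref) return(e)
      ord <- sample.int(nrow(e))
      cum <- cumsum((e$end - e$start)[ord])
      take <- ord[seq_len(which(cum >= durs[[ref]])[1])]
      ee <- e[sort(take), , drop = FALSE]
      rownames(ee) <- NULL
      class(ee) <- c("epoch_set", "data.frame")
      ee
    })
    names(sel) <- present
    counts <- vapply(present, function(s)
      sum(vapply(trains, function(tr)
        sum(spikes_in_epochs(tr$times, sel[[s]])), numeric(1))), numeric(1))
    n_min <- min(counts)
    sub_states <- do.call(rbind, lapply(present, function(s) {
      data.frame(start = sel[[s]]$start, end = sel[[s]]$end, label = s)
    }))
    sub_states <- epoch_set(sub_states$start, sub_states$end, sub_states$label)
    # per state, delete spikes uniformly at random across units
    trains_r <- trains
    for (s in present) {
      drop_n <- counts[[s]] - n_min
      if (drop_n <= 0) next
      per_unit <- lapply(trains, function(tr)
        which(spikes_in_epochs(tr$times, sel[[s]])))
      tot <- sum(lengths(per_unit))
      drop_g <- sample.int(tot, drop_n)
      offs <- cumsum(c(0, lengths(per_unit)))
      for (u in seq_along(trains_r)) {
        local_idx <- drop_g[drop_g > offs[u] & drop_g <= offs[u + 1]] - offs[u]
        if (length(local_idx)) {
          rm_idx <- per_unit[[u]][local_idx]
          trains_r[[u]]$times <- trains_r[[u]]$times[-rm_idx]
        }
      }
    }
    tab <- state_dce_table(trains_r, sub_states, pairs = pairs, ...)
    tab$rep <- r
    acc <- rbind(acc, tab)
  }
  ag <- stats::aggregate(cbind(dce, p_value, significant) ~
                           unit_a + unit_b + state, data = acc, FUN = mean)
  out <- data.frame(unit_a = ag$unit_a, unit_b = ag$unit_b, state = ag$state,
                    dce = ag$dce,
                    p_value = stats::aggregate(p_value ~ unit_a + unit_b + state,
                                               acc, stats::median)$p_value,
                    significant = ag$significant > 0.5,
                    stringsAsFactors = FALSE)
  out$dce_sig <- ifelse(out$significant, out$dce, 0)
  attr(out, "reps") <- reps
  class(out) <- c("dce_table", "data.frame")
  out
}

#' Trough/peak proportions per state
#'
#' Percentage of pairs with a significant negative DCE (trough) and a
#' significant positive DCE (peak) in each state.
#'
#' @param table A `dce_table`.
#' @return Data frame with columns `state`, `n_pairs`, `trough_pct`,
#'   `peak_pct` (percent of `n_pairs`).
#' @export
proportion_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  do.call(rbind, lapply(split(table, table$state), function(s) {
    data.frame(state = s$state[1], n_pairs = nrow(s),
               trough_pct = 100 * mean(s$significant & s$dce < 0),
               peak_pct = 100 * mean(s$significant & s$dce > 0),
               stringsAsFactors = FALSE)
  }))
}

#' State-specificity crosstab of negative DCEs
#'
#' For each ordered state pair (X, Y): the percentage of pairs with a
#' significant negative DCE in X but a zero (non-significant) DCE in Y,
#' following the convention that a non-significant DCE counts as zero.
#'
#' @param table A `dce_table` with at least two states.
#' @return Data frame with columns `state_neg`, `state_zero`, `pct`, `n`.
#' @export
state_specificity_crosstab <- function(table) {
  states <- unique(table$state)
  if (length(states) < 2) stop("need at least two states")
  key <- paste(table$unit_a, table$unit_b)
  wide_sig <- tapply(table$significant, list(key, table$state), identity)
  wide_neg <- tapply(table$significant & table$dce < 0,
                     list(key, table$state), identity)
  out <- NULL
  for (x in states) for (y in setdiff(states, x)) {
    ok <- !is.na(wide_neg[, x]) & !is.na(wide_sig[, y])
    n <- sum(ok)
    pct <- if (n) 100 * mean(wide_neg[ok, x] & !wide_sig[ok, y]) else 0
    out <- rbind(out, data.frame(state_neg = x, state_zero = y,
                                 pct = pct, n = n, stringsAsFactors = FALSE))
  }
  out
}

#' Compare |DCE| across states
#'
#' One-way comparison of the absolute DCE across states for a selected set
#' of pairs, with Tukey-Kramer corrected pairwise p-values.
#'
#' @param table A `dce_table`.
#' @param selection `"all"` (pairs significant in every state present) or a
#'   state name (pairs significant in that state).
#' @return A list with `n_pairs`, `means` (mean |dce| per state), `anova_p`,
#'   and `pairwise` (TukeyHSD table as a data frame), or an empty report
#'   (`n_pairs = 0`) if no pairs qualify.
#' @export
compare_abs_dce <- function(table, selection = "all") {
  states <- unique(table$state)
  if (length(states) < 2) stop("need at least two states")
  key <- paste(table$unit_a, table$unit_b)
  sig <- tapply(table$significant, list(key, table$state), identity)
  keep_keys <- if (identical(selection, "all")) {
    rownames(sig)[rowSums(sig, na.rm = TRUE) == length(states) &
                  rowSums(!is.na(sig)) == length(states)]
  } else {
    stopifnot(selection %in% states)
    rownames(sig)[!is.na(sig[, selection]) & sig[, selection]]
  }
  sub <- table[key %in% keep_keys, , drop = FALSE]
  n_pairs <- length(keep_keys)
  if (n_pairs == 0)
    return(list(n_pairs = 0, means = NULL, anova_p = NA_real_,
                pairwise = NULL))
  sub$absdce <- abs(sub$dce)
  means <- tapply(sub$absdce, sub$state, mean)
  if (length(unique(sub$state)) < 2 || n_pairs < 2)
    return(list(n_pairs = n_pairs, means = means, anova_p = NA_real_,
                pairwise = NULL))
  fit <- stats::aov(absdce ~ state, data = sub)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$state
  pairwise <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  list(n_pairs = n_pairs, means = means, anova_p = anova_p,
       pairwise = pairwise)
}

#' Stacked CCG matrix sorted by DCE
#'
#' Normalized CCG values for many pairs as a matrix (pairs x lag bins),
#' sorted by the DCE of a reference state, for stacked-CCG style displays.
#'
#' @inheritParams state_dce_table
#' @param sort_state State whose DCE defines the row order (deepest trough
#'   first).
#' @param states_shown States to return matrices for.
#' @param significant_only Keep only pairs significant in `sort_state`.
#' @return A list with `order` (pair labels) and one matrix per shown state.
#' @export
stacked_ccg_matrix <- function(trains, states, pairs = NULL,
                               sort_state = "NREM",
                               states_shown = c("NREM", "WAKE", "REM"),
                               significant_only = TRUE, bin_width = 0.005,
                               max_lag = 1, smooth_window = 1.0,
                               alpha = 1e-4) {
  ids <- vapply(trains, function(x) x$unit_id, character(1))
  names(trains) <- ids
  if (is.null(pairs)) {
    cmb <- utils::combn(sort(ids), 2)
    pairs <- data.frame(unit_a = cmb[1, ], unit_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  states_shown <- intersect(states_shown, unique(states$label))
  vals <- list(); dces <- numeric(nrow(pairs)); sig <- logical(nrow(pairs))
  for (s in states_shown) vals[[s]] <-
    matrix(NA_real_, nrow(pairs), round(2 * max_lag / bin_width))
  for (i in seq_len(nrow(pairs))) {
    for (s in states_shown) {
      nc <- normalized_ccg(trains[[pairs$unit_a[i]]],
                           trains[[pairs$unit_b[i]]], states, s,
                           bin_width, max_lag, smooth_window)
      vals[[s]][i, ] <- nc$values
      if (s == sort_state) {
        d <- compute_dce(nc, alpha = alpha)
        dces[i] <- d$dce; sig[i] <- d$significant
      }
    }
  }
  keep <- if (significant_only) which(sig) else seq_len(nrow(pairs))
  ord <- keep[order(dces[keep])]
  out <- lapply(vals, function(m) m[ord, , drop = FALSE])
  out$order <- paste(pairs$unit_a[ord], pairs$unit_b[ord], sep = ":")
  out$dce <- dces[ord]
  out$lag_centers <- ccg_lag_centers(bin_width, max_lag)
  out
}
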