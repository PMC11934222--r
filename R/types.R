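#' Construct a spike train
#'
#' A spike train is one unit's sorted spike times over a recording, together
#' with the recording bounds. Times are in seconds.
#'
#' @param unit_id Identifier for the unit (coerced to character).
#' @param times Numeric vector of spike times in seconds. Sorted on input;
#'   unsorted input is sorted with a warning (or an error if `strict = TRUE`).
#' @param t_start,t_end Recording bounds in seconds. Default to the data range.
#' @param strict Error instead of warning on unsorted input.
#' @return An object of class `spike_train`: a list with elements `unit_id`,
#'   `times`, `t_start`, `t_end`.
#' @export
spike_train <- function(unit_id, times, t_start = NULL, t_end = NULL,
                        strict = FALSE) {
  times <- as.numeric(times)
  if (is.unsorted(times)) {
    if (strict) stop("spike times for unit ", unit_id, " are not sorted")
    warning("spike times for unit ", unit_id, " were not sorted; sorting")
    times <- sort(times)
  }
  if (is.null(t_start)) t_start <- if (length(times)) times[1] else 0
  if (is.null(t_end))   t_end   <- if (length(times)) times[length(times)] else 0
  if (length(times) && (times[1] < t_start || times[length(times)] > t_end))
    stop("spike times outside [t_start, t_end] for unit ", unit_id)
  structure(list(unit_id = as.character(unit_id), times = times,
                 t_start = t_start, t_end = t_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes in [%.3f, %.3f] s\n",
              x$unit_id, length(x$times), x$t_start, x$t_end))
  invisible(x)
}

#' Number of spikes in a spike train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$times)

#' Construct a labeled epoch set
#'
#' Labeled, half-open time intervals `[start, end)` representing sleep states
#' (`WAKE`/`NREM`/`REM`) or UP/DOWN states (`UP`/`DOWN`). Intervals sharing a
#' label must not overlap.
#'
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @param label Character vector of labels (recycled if length 1).
#' @param strict Error (rather than warn) on overlapping intervals within a
#'   label stream.
#' @return A `data.frame` of class `epoch_set` with columns `start`, `end`,
#'   `label`, sorted by `start`.
#' @export
epoch_set <- function(start, end, label, strict = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  label <- as.character(rep_len(label, length(start)))
  if (any(end <= start)) stop("epoch_set: every interval needs start < end")
  df <- data.frame(start = start, end = end, label = label,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (lb in unique(df$label)) {
    sub <- df[df$label == lb, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)] - 1e-12)) {
      msg <- paste0("epoch_set: overlapping '", lb, "' intervals")
      if (strict) stop(msg) else warning(msg)
    }
  }
  class(df) <- c("epoch_set", "data.frame")
  df
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(x$label)
  dur <- tapply(x$end - x$start, x$label, sum)
  cat("<epoch_set>", nrow(x), "intervals\n")
  for (lb in names(tab))
    cat(sprintf("  %-5s n=%4d  total %.1f s\n", lb, tab[[lb]], dur[[lb]]))
  invisible(x)
}

#' Subset an epoch set by label
#' @param epochs An `epoch_set`.
#' @param label Label(s) to keep; `NULL` keeps all.
#' @export
epochs_with_label <- function(epochs, label = NULL) {
  if (is.null(label)) return(epochs)
  out <- epochs[epochs$label %in% label, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epoch_set", "data.frame")
  out
}

#' Total duration of an epoch set (optionally one label)
#' @inheritParams epochs_with_label
#' @export
epoch_duration <- function(epochs, label = NULL) {
  e <- epochs_with_label(epochs, label)
  sum(e$end - e$start)
}

#' Restrict spike times to an epoch set
#'
#' Keeps spikes falling inside any `[start, end)` interval of `epochs`
#' (optionally only those with a given label).
#'
#' @param train A `spike_train`.
#' @inheritParams epochs_with_label
#' @return A `spike_train` with the filtered times.
#' @export
restrict_train <- function(train, epochs, label = NULL) {
  e <- epochs_with_label(epochs, label)
  keep <- spikes_in_epochs(train$times, e)
  out <- train
  out$times <- train$times[keep]
  out
}

# logical index of spikes inside any [start,end) of a sorted epoch table
spikes_in_epochs <- function(times, epochs) {
  if (!nrow(epochs) || !length(times)) return(rep(FALSE, length(times)))
  brk <- as.vector(rbind(epochs$start, epochs$end))
  idx <- findInterval(times, brk)
  idx %% 2L == 1L
}

# epoch index (row of `epochs`) for each spike, NA if outside all epochs
epoch_index_of <- function(times, epochs) {
  if (!nrow(epochs)) return(rep(NA_integer_, length(times)))
  brk <- as.vector(rbind(epochs$start, epochs$end))
  idx <- findInterval(times, brk)
  out <- (idx + 1L) %/% 2L
  out[idx %% 2L == 0L] <- NA_integer_
  out
}

#' Clip an epoch set to a time window
#' @param epochs An `epoch_set`.
#' @param lo,hi Window bounds in seconds.
#' @return An `epoch_set` with intervals intersected with `[lo, hi)`; empty
#'   intersections dropped.
#' @export
clip_epochs <- function(epochs, lo, hi) {
  s <- pmax(epochs$start, lo); e <- pmin(epochs$end, hi)
  keep <- e > s
  if (!any(keep)) {
    out <- epochs[0, , drop = FALSE]
    class(out) <- c("epoch_set", "data.frame")
    return(out)
  }
  epoch_set(s[keep], e[keep], epochs$label[keep])
}
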