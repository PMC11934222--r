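#' Read spike trains from a tab-separated table
#'
#' Expected columns: `unit_id<TAB>time_s` (header optional; detected from
#' the first line). Times are seconds, sorted within unit; unsorted times
#' are sorted with a warning unless `strict = TRUE`.
#'
#' @param path File path.
#' @param t_start,t_end Optional recording bounds applied to every train.
#' @param strict Error on unsorted times.
#' @return Named list of `spike_train`s.
#' @export
read_spikes <- function(path, t_start = NULL, t_end = NULL, strict = FALSE) {
  first <- readLines(path, n = 1)
  if (!length(first)) return(list())
  has_header <- grepl("unit", first, ignore.case = TRUE)
  if (has_header && length(readLines(path, n = 2)) < 2) return(list())
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          col.names = c("unit_id", "time_s"),
                          colClasses = list(character = 1, numeric = 2))
  if (!nrow(dt)) return(list())
  if (anyNA(dt$time_s)) stop("malformed spike rows (non-numeric time) in ",
                             path)
  sp <- split(dt$time_s, dt$unit_id)
  lo <- if (is.null(t_start)) min(dt$time_s) else t_start
  hi <- if (is.null(t_end)) max(dt$time_s) else t_end
  out <- lapply(names(sp), function(u)
    spike_train(u, sp[[u]], t_start = lo, t_end = hi, strict = strict))
  stats::setNames(out, names(sp))
}

#' Write spike trains to a tab-separated table
#' @param trains List of `spike_train`s.
#' @param path Output path.
#' @export
write_spikes <- function(trains, path) {
  if (!length(trains)) {
    writeLines("unit_id\ttime_s", path)
    return(invisible(path))
  }
  dt <- data.table::rbindlist(lapply(trains, function(tr)
    data.table::data.table(unit_id = tr$unit_id, time_s = tr$times)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an epoch set from a tab-separated table
#'
#' Expected columns: `start_s<TAB>end_s<TAB>label`, half-open intervals.
#'
#' @param path File path.
#' @param strict Error on overlapping intervals within a label.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path, strict = FALSE) {
  first <- readLines(path, n = 1)
  if (!length(first)) stop("empty epoch file: ", path)
  has_header <- grepl("start", first, ignore.case = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          col.names = c("start_s", "end_s", "label"))
  if (anyNA(dt$start_s) || anyNA(dt$end_s))
    stop("malformed epoch rows in ", path)
  epoch_set(dt$start_s, dt$end_s, dt$label, strict = strict)
}

#' Write an epoch set
#' @param epochs An `epoch_set`.
#' @param path Output path.
#' @export
write_epochs <- function(epochs, path) {
  data.table::fwrite(data.table::data.table(start_s = epochs$start,
                                            end_s = epochs$end,
                                            label = epochs$label),
                     path, sep = "\t")
  invisible(path)
}

#' Read an LFP trace
#'
#' Two formats: a flat binary of little-endian 16-bit integers with a YAML
#' sidecar header `<path>.yaml` holding `rate` (Hz) and `scale` (volts or
#' arbitrary units per count), or a two-column tab-separated table
#' `time_s<TAB>value` (rate inferred from the time step).
#'
#' @param path Path to `.bin`/`.dat` (with sidecar) or a tabular file.
#' @return An `lfp` object (list with `samples`, `rate`).
#' @export
read_lfp <- function(path) {
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    hdr <- yaml::read_yaml(side)
    n <- file.info(path)$size / 2
    x <- readBin(path, "integer", n = n, size = 2, signed = TRUE,
                 endian = "little")
    return(structure(list(samples = x * hdr$scale, rate = hdr$rate),
                     class = "lfp"))
  }
  dt <- data.table::fread(path, sep = "\t", header = "auto")
  if (ncol(dt) != 2) stop("tabular LFP needs two columns: time_s, value")
  tm <- as.numeric(dt[[1]])
  rate <- 1 / stats::median(diff(tm))
  structure(list(samples = as.numeric(dt[[2]]), rate = rate), class = "lfp")
}

#' Write an LFP trace as int16 binary plus YAML sidecar
#'
#' Samples are scaled to span the int16 range; the scale is recorded in the
#' sidecar so [read_lfp()] round-trips to within one quantization step.
#'
#' @param lfp An `lfp` object.
#' @param path Output path (sidecar written to `<path>.yaml`).
#' @export
write_lfp <- function(lfp, path) {
  scale <- max(abs(lfp$samples), 1e-12) / 32000
  q <- as.integer(round(lfp$samples / scale))
  writeBin(q, path, size = 2, endian = "little")
  yaml::write_yaml(list(rate = lfp$rate, scale = scale,
                        n_samples = length(q)), paste0(path, ".yaml"))
  invisible(path)
}

#' Write a DCE table
#' @param table A `dce_table`.
#' @param path Output path.
#' @export
write_dce_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}

#' Read a DCE table written by [write_dce_table()]
#' @param path File path.
#' @export
read_dce_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  class(df) <- c("dce_table", "data.frame")
  df
}
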