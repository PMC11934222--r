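#' Run configuration for the full pipeline
#'
#' Bundles inputs (file paths or in-memory objects, or a [synth_config()] to
#' generate them), stage parameters, the master seed and the output
#' directory. Every parameter is echoed into the run manifest.
#'
#' @param spikes,states,updown,lfp Paths or objects (`NULL` where absent).
#' @param synth Optional [synth_config()]; when given, inputs are generated.
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param pairs Optional pair-selection data frame.
#' @param params Named list of CCG/DCE parameter overrides
#'   (`bin_width`, `max_lag`, `smooth_window`, `pseudocount`, `alpha`).
#' @param stages Character vector of stages to run, among
#'   `c("state", "up", "burst", "lfp")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spikes = NULL, states = NULL, updown = NULL,
                       lfp = NULL, synth = NULL, out_dir = "statesync_out",
                       seed = 1L, pairs = NULL, params = list(),
                       stages = c("state", "up", "burst", "lfp")) {
  structure(list(spikes = spikes, states = states, updown = updown,
                 lfp = lfp, synth = synth, out_dir = out_dir,
                 seed = as.integer(seed), pairs = pairs, params = params,
                 stages = stages),
            class = "run_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 1009L + 97L * k) %% 2147483646L + 1L

#' Run the full analysis pipeline
#'
#' Executes, in order: per-state DCE tables and summaries; UP-state analyses
#' (UP-only DCE, UPnext scrambling, timing metrics); burst analysis
#' (log-ISI mixtures, removal sweeps on significant-trough pairs); and LFP
#' band-power analyses (windowed DCE/power correlation, epoch-duration
#' relation) when an LFP is available. One tab-separated report per stage is
#' written to the output directory plus a JSON manifest with the seed and
#' every parameter. All randomness derives from the configured seed, so a
#' rerun with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the per-stage result objects.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- utils::modifyList(list(bin_width = 0.005, max_lag = 1,
                              smooth_window = 1, pseudocount = 1,
                              alpha = 1e-4), config$params)
  load_stage <- function(x, reader) {
    if (is.null(x) || !is.character(x)) x else reader(x)
  }
  if (!is.null(config$synth)) {
    sc <- config$synth
    sc$seed <- config$seed
    rec <- generate_recording(sc)
    trains <- rec$trains; states <- rec$states; updown <- rec$updown
    lfp <- rec$lfp
    pairs <- if (is.null(config$pairs)) rec$truth$pairs[, c("unit_a", "unit_b")]
             else config$pairs
  } else {
    trains <- load_stage(config$spikes, read_spikes)
    states <- load_stage(config$states, read_epochs)
    updown <- load_stage(config$updown, read_epochs)
    lfp <- load_stage(config$lfp, read_lfp)
    pairs <- config$pairs
    if (is.null(trains) || is.null(states))
      stop("stage 'inputs': spikes and states are required")
  }
  names(trains) <- vapply(trains, function(x) x$unit_id, character(1))
  out <- list()
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("state" %in% config$stages) {
    results$state <- run_stage("state", {
      tab <- state_dce_table(trains, states, pairs = pairs,
                             bin_width = p$bin_width, max_lag = p$max_lag,
                             smooth_window = p$smooth_window,
                             pseudocount = p$pseudocount, alpha = p$alpha)
      write_dce_table(tab, file.path(config$out_dir, "state_dce.tsv"))
      ps <- proportion_summary(tab)
      data.table::fwrite(ps, file.path(config$out_dir, "proportions.tsv"),
                         sep = "\t")
      if (length(unique(tab$state)) >= 2) {
        ct <- state_specificity_crosstab(tab)
        data.table::fwrite(ct, file.path(config$out_dir, "specificity.tsv"),
                           sep = "\t")
      }
      tab
    })
  }

  if ("up" %in% config$stages) {
    results$up <- run_stage("up", {
      ud <- if (!is.null(updown)) updown
            else detect_up_down(trains, states)
      pr <- if (!is.null(pairs)) pairs else {
        cmb <- utils::combn(sort(names(trains)), 2)
        data.frame(unit_a = cmb[1, ], unit_b = cmb[2, ])
      }
      rows <- lapply(seq_len(nrow(pr)), function(i) {
        a <- trains[[pr$unit_a[i]]]; b <- trains[[pr$unit_b[i]]]
        d_up <- suppressWarnings(up_only_dce(a, b, ud,
                                             bin_width = p$bin_width,
                                             alpha = p$alpha))
        sc <- scramble_up_next(a, b, ud)
        d_scr <- suppressWarnings(up_only_dce(sc$a, sc$b, sc$epochs,
                                              bin_width = p$bin_width,
                                              alpha = p$alpha))
        tm <- up_timing_metrics(a, b, ud)
        data.frame(unit_a = pr$unit_a[i], unit_b = pr$unit_b[i],
                   dce_up = d_up$dce, p_up = d_up$p_value,
                   sig_up = d_up$significant,
                   dce_upnext = d_scr$dce, p_upnext = d_scr$p_value,
                   sig_upnext = d_scr$significant,
                   mean_diff_first = tm$mean_diff_first,
                   sd_diff_first = tm$sd_diff_first,
                   mean_diff_mean = tm$mean_diff_mean,
                   sd_diff_mean = tm$sd_diff_mean,
                   n_up_used = tm$n_up_used)
      })
      up_tab <- do.call(rbind, rows)
      data.table::fwrite(up_tab, file.path(config$out_dir, "up_dce.tsv"),
                         sep = "\t")
      up_tab
    })
  }

  if ("burst" %in% config$stages) {
    results$burst <- run_stage("burst", {
      stab <- results$state
      sel <- if (!is.null(stab)) select_trough_pairs(stab) else NULL
      rows <- list()
      if (!is.null(sel) && nrow(sel)) {
        for (i in seq_len(nrow(sel))) {
          sw <- tryCatch(
            removal_sweep(trains[[sel$unit_a[i]]], trains[[sel$unit_b[i]]],
                          states, seed = stage_seed(config$seed, 300 + i),
                          bin_width = p$bin_width, max_lag = p$max_lag,
                          alpha = p$alpha),
            error = function(e) NULL)
          if (!is.null(sw)) {
            sw$unit_a <- sel$unit_a[i]; sw$unit_b <- sel$unit_b[i]
            rows[[length(rows) + 1]] <- sw
          }
        }
      }
      burst_tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(mode = character(0), level = numeric(0))
      data.table::fwrite(burst_tab,
                         file.path(config$out_dir, "burst_sweep.tsv"),
                         sep = "\t")
      burst_tab
    })
  }

  if ("lfp" %in% config$stages) {
    if (is.null(lfp)) {
      message("no LFP available; skipping LFP stage")
    } else {
      results$lfp <- run_stage("lfp", {
        stab <- results$state
        sel <- if (!is.null(stab)) select_trough_pairs(stab) else NULL
        res <- list()
        if (!is.null(sel) && nrow(sel) &&
            max(states$end) >= 2 * 10800) {
          wc <- windowed_dce_power_correlation(trains, states, lfp, sel,
                                               bin_width = p$bin_width,
                                               max_lag = p$max_lag,
                                               alpha = p$alpha)
          data.table::fwrite(wc$correlations,
                             file.path(config$out_dir, "band_dce.tsv"),
                             sep = "\t")
          res$windowed <- wc
        }
        ed <- tryCatch(epoch_duration_power_correlation(states, lfp),
                       error = function(e) NULL)
        if (!is.null(ed))
          data.table::fwrite(ed$correlations,
                             file.path(config$out_dir,
                                       "epoch_duration_power.tsv"),
                             sep = "\t")
        res$duration <- ed
        res
      })
    }
  }

  manifest <- list(package = "statesync",
                   version = as.character(utils::packageVersion("statesync")),
                   seed = config$seed, params = p, stages = config$stages,
                   n_units = length(trains),
                   synthetic = !is.null(config$synth))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
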