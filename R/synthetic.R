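#' Configuration for the synthetic recording generator
#'
#' Bundles every parameter of the seeded generator. The defaults describe a
#' 24 h rodent frontal-cortex-like recording: alternating wake/nonREM/REM
#' bouts; UP/DOWN alternation inside nonREM at ~1.3 Hz with exactly zero
#' DOWN-state firing; per-unit UP firing rates log-uniform over 2-20 Hz; a
#' roster of designated unit pairs split into INDEPENDENT, COACTIVE and
#' ANTIPHASE classes (a configurable fraction of ANTIPHASE pairs emits burst
#' spikes); and an LFP whose delta-band amplitude rises, and gamma-band
#' amplitude falls, with nonREM epoch duration, with fixed-length power ramps
#' at epoch boundaries. The anticorrelation depth of ANTIPHASE pairs is
#' coupled to the per-epoch delta amplitude via `delta_coupling`.
#'
#' The ANTIPHASE mechanism: within each UP state one unit of the pair
#' occupies the early half and the other the late half, the assignment
#' swapping at random from UP to UP; `antiphase_depth` is the probability
#' that a spike is confined to its unit's half (the remainder is uniform over
#' the whole UP). BURSTY variants emit the half-confined portion as short
#' bursts (3-5 spikes, 3-8 ms ISI) and the rest as isolated spikes.
#' COACTIVE pairs share an early-biased UP phase profile, a common lognormal
#' per-UP rate gain, and a small fraction of near-coincident spikes.
#' A fraction `wake_anticorr_frac` of ANTIPHASE pairs keeps a weaker
#' block-alternation anticorrelation during wake (depth
#' `wake_anticorr_strength`); REM is always structureless homogeneous
#' Poisson, rate-matched to the unit's overall nonREM rate.
#'
#' @param duration_h Recording length in hours.
#' @param n_units Number of units; designated pairs are (1,2), (3,4), ...
#' @param class_fractions Named fractions over designated pairs
#'   (INDEPENDENT/COACTIVE/ANTIPHASE); must sum to 1.
#' @param antiphase_bursty_frac Fraction of ANTIPHASE pairs that are bursty.
#' @param up_rate_range UP-state firing-rate range (Hz), log-uniform per unit.
#' @param wake_meanlog,wake_sdlog,nrem_meanlog,nrem_sdlog,rem_meanlog,rem_sdlog
#'   Lognormal epoch-duration parameters (seconds) per state.
#' @param rem_prob Probability that a REM bout follows a nonREM bout.
#' @param up_meanlog,up_sdlog,up_range UP duration lognormal and clip range (s).
#' @param down_meanlog,down_sdlog,down_range DOWN duration lognormal and clip
#'   range (s).
#' @param antiphase_depth Baseline half-confinement probability.
#' @param antiphase_gap Dead zone around mid-UP (phase units) separating the
#'   two halves; larger values deepen the trough.
#' @param delta_coupling Exponent coupling per-epoch antiphase depth to
#'   relative delta amplitude (0 = no coupling).
#' @param wake_anticorr_frac,wake_anticorr_strength,wake_block_s Wake
#'   carryover anticorrelation parameters for ANTIPHASE pairs.
#' @param coactive_gain_sd Lognormal sd of the shared per-UP rate gain.
#' @param coactive_coinc_frac Fraction of the slower unit's rate emitted as
#'   shared near-coincident spikes.
#' @param coactive_coinc_jitter SD (s) of the per-unit jitter on shared spikes.
#' @param burst_isi_range Within-burst ISI range (s).
#' @param burst_size_range Burst size range (spikes; uniform over integers).
#' @param burst_frac Fraction of a bursty unit's UP rate emitted in bursts.
#' @param lfp_rate LFP sample rate (Hz).
#' @param delta_freq,gamma_freq Oscillation frequencies (Hz) of the delta and
#'   gamma LFP components.
#' @param delta_base,delta_dur_slope,delta_dur_cap NonREM delta amplitude =
#'   `delta_base + delta_dur_slope * min(duration, delta_dur_cap)`, times the
#'   slow drift.
#' @param gamma_base,gamma_dur_slope NonREM gamma amplitude analogously,
#'   anti-varying with duration and drift.
#' @param ramp_up_s,ramp_down_s Fixed LFP envelope ramp lengths (s) at nonREM
#'   epoch start and end, independent of epoch duration.
#' @param lfp_noise_sd White-noise floor SD.
#' @param drift_amp,drift_cycles Slow sinusoidal drift of delta amplitude
#'   across the recording (gamma anti-varies), providing between-window power
#'   variance.
#' @param wr_delta,wake_gamma,rem_gamma Delta/gamma amplitudes outside nonREM.
#' @param amp_noise_sd Lognormal sd of per-epoch amplitude noise.
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_h = 24,
                         n_units = 40,
                         class_fractions = c(INDEPENDENT = 0.80,
                                             COACTIVE = 0.12,
                                             ANTIPHASE = 0.08),
                         antiphase_bursty_frac = 0.5,
                         up_rate_range = c(2, 20),
                         wake_meanlog = log(140), wake_sdlog = 0.9,
                         nrem_meanlog = log(170), nrem_sdlog = 0.8,
                         rem_meanlog = log(80), rem_sdlog = 0.5,
                         rem_prob = 0.6,
                         up_meanlog = log(0.6), up_sdlog = 0.45,
                         up_range = c(0.2, 2),
                         down_meanlog = log(0.12), down_sdlog = 0.4,
                         down_range = c(0.05, 0.5),
                         antiphase_depth = 0.95,
                         antiphase_gap = 0.1,
                         delta_coupling = 1.0,
                         wake_anticorr_frac = 0.5,
                         wake_anticorr_strength = 0.5,
                         wake_block_s = 0.5,
                         coactive_gain_sd = 0.5,
                         coactive_coinc_frac = 0.15,
                         coactive_coinc_jitter = 0.02,
                         burst_isi_range = c(0.003, 0.008),
                         burst_size_range = c(3L, 5L),
                         burst_frac = 0.75,
                         lfp_rate = 200,
                         delta_freq = 3.9, gamma_freq = 54,
                         delta_base = 0.6, delta_dur_slope = 0.0025,
                         delta_dur_cap = 800,
                         gamma_base = 0.8, gamma_dur_slope = 0.0015,
                         ramp_up_s = 100, ramp_down_s = 50,
                         lfp_noise_sd = 0.3,
                         drift_amp = 0.3, drift_cycles = 1.5,
                         wr_delta = 0.12, wake_gamma = 0.85, rem_gamma = 0.85,
                         amp_noise_sd = 0.05,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (any(up_rate_range <= 0)) stop("all rates must be > 0")
  if (max(burst_isi_range) * max(burst_size_range) >= min(up_range))
    stop("infeasible config: bursts longer than the shortest UP state")
  class(cfg) <- "synth_config"
  cfg
}

clip_lognorm <- function(n, meanlog, sdlog, range) {
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), range[1]), range[2])
}

#' Generate the wake/nonREM/REM state schedule
#'
#' Draws wake -> nonREM -> (with probability `rem_prob`) REM cycles with
#' lognormal bout durations until the configured recording length is reached;
#' the final bout is clipped.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return An `epoch_set` with labels WAKE/NREM/REM covering `[0, duration)`.
#' @export
generate_state_schedule <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  total <- config$duration_h * 3600
  start <- numeric(0); end <- numeric(0); label <- character(0)
  t <- 0
  while (t < total) {
    durs <- c(WAKE = stats::rlnorm(1, config$wake_meanlog, config$wake_sdlog),
              NREM = stats::rlnorm(1, config$nrem_meanlog, config$nrem_sdlog))
    if (stats::runif(1) < config$rem_prob)
      durs <- c(durs, REM = stats::rlnorm(1, config$rem_meanlog,
                                          config$rem_sdlog))
    for (lb in names(durs)) {
      if (t >= total) break
      d <- min(durs[[lb]], total - t)
      start <- c(start, t); end <- c(end, t + d); label <- c(label, lb)
      t <- t + d
    }
  }
  epoch_set(start, end, label)
}

#' Generate UP/DOWN alternation inside nonREM epochs
#'
#' Tiles every nonREM epoch with alternating UP and DOWN intervals (starting
#' with UP) drawn from clipped lognormal distributions; the final interval of
#' each epoch is clipped to the epoch end.
#'
#' @param nrem_epochs An `epoch_set` (only rows labeled NREM are used).
#' @param config A [synth_config()].
#' @param seed Optional seed.
#' @return An `epoch_set` with labels UP/DOWN; attribute `parent` gives, for
#'   each row, the index of its parent nonREM epoch (row number within the
#'   NREM subset).
#' @export
generate_up_down <- function(nrem_epochs, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nrem <- epochs_with_label(nrem_epochs, "NREM")
  if (!nrow(nrem)) stop("no NREM epochs to tile")
  res <- vector("list", nrow(nrem))
  for (i in seq_len(nrow(nrem))) {
    s <- nrem$start[i]; e <- nrem$end[i]
    dur <- e - s
    # draw enough intervals to cover the epoch, then clip
    n_guess <- ceiling(dur / 0.4) + 10
    up <- clip_lognorm(n_guess, config$up_meanlog, config$up_sdlog,
                       config$up_range)
    dn <- clip_lognorm(n_guess, config$down_meanlog, config$down_sdlog,
                       config$down_range)
    seq_d <- as.vector(rbind(up, dn))
    cum <- cumsum(seq_d)
    while (cum[length(cum)] < dur) {
      up2 <- clip_lognorm(n_guess, config$up_meanlog, config$up_sdlog,
                          config$up_range)
      dn2 <- clip_lognorm(n_guess, config$down_meanlog, config$down_sdlog,
                          config$down_range)
      seq_d <- c(seq_d, as.vector(rbind(up2, dn2)))
      cum <- cumsum(seq_d)
    }
    k <- which(cum >= dur)[1]
    seq_d <- seq_d[seq_len(k)]
    ends <- s + cumsum(seq_d)
    starts <- c(s, ends[-k])
    ends[k] <- e
    keep <- ends > starts
    res[[i]] <- data.frame(start = starts[keep], end = ends[keep],
                           label = rep_len(c("UP", "DOWN"), k)[keep],
                           parent = i)
  }
  all <- do.call(rbind, res)
  out <- epoch_set(all$start, all$end, all$label)
  # epoch_set sorts by start; order is already by start here
  attr(out, "parent") <- all$parent
  out
}

# --- spike placement primitives (times relative to recording clock) --------

# profile-based inhomogeneous Poisson within UP states
# up_s/up_e: UP bounds; rate: Hz; prob: 50-bin phase profile; gain: per-UP
sim_profile_spikes <- function(up_s, up_e, rate, prob, gain = 1) {
  d <- up_e - up_s
  lam <- rate * d * gain
  n <- stats::rpois(length(d), lam)
  if (!sum(n)) return(numeric(0))
  up_i <- rep.int(seq_along(d), n)
  bins <- sample.int(50L, sum(n), replace = TRUE, prob = prob)
  ph <- (bins - 1 + stats::runif(sum(n))) / 50
  sort(up_s[up_i] + ph * d[up_i])
}

# half-UP-confined spikes: side (0 = early, 1 = late) per UP; each spike is
# confined to its side with probability depth, else uniform over the UP.
# gap is the dead zone around mid-UP (phase units): early side occupies
# [0, 0.5 - gap), late side [0.5 + gap, 1)
sim_antiphase_spikes <- function(up_s, up_e, rate, side, depth, gap = 0.1) {
  d <- up_e - up_s
  n <- stats::rpois(length(d), rate * d)
  if (!sum(n)) return(numeric(0))
  up_i <- rep.int(seq_along(d), n)
  conf <- stats::runif(sum(n)) < rep.int(depth, n)
  u <- stats::runif(sum(n))
  w <- 0.5 - gap
  ph <- ifelse(conf, rep.int(side, n) * (0.5 + gap) + u * w, u)
  sort(up_s[up_i] + ph * d[up_i])
}

# bursty half-confined spikes: a burst_frac portion of the rate is emitted as
# bursts whose anchors follow the antiphase rule; the rest is isolated and
# uniform over the whole UP (so bursts, not isolated spikes, carry the
# anticorrelation)
sim_bursty_antiphase_spikes <- function(up_s, up_e, rate, side, depth,
                                        burst_frac, isi_range, size_range,
                                        gap = 0.1) {
  d <- up_e - up_s
  mean_size <- mean(seq.int(size_range[1], size_range[2]))
  n_iso <- stats::rpois(length(d), (1 - burst_frac) * rate * d)
  iso <- if (sum(n_iso)) {
    up_i <- rep.int(seq_along(d), n_iso)
    up_s[up_i] + stats::runif(sum(n_iso)) * d[up_i]
  } else numeric(0)
  n_ev <- stats::rpois(length(d), burst_frac * rate * d / mean_size)
  bur <- numeric(0)
  if (sum(n_ev)) {
    up_i <- rep.int(seq_along(d), n_ev)
    conf <- stats::runif(sum(n_ev)) < rep.int(depth, n_ev)
    u <- stats::runif(sum(n_ev))
    w <- 0.5 - gap
    ph <- ifelse(conf, rep.int(side, n_ev) * (0.5 + gap) + u * w, u)
    anchor <- up_s[up_i] + ph * d[up_i]
    size <- sample(seq.int(size_range[1], size_range[2]), sum(n_ev),
                   replace = TRUE)
    sp_i <- rep.int(seq_along(anchor), size)
    isi <- stats::runif(length(sp_i), isi_range[1], isi_range[2])
    cs <- cumsum(isi)
    first <- cumsum(c(1L, size[-length(size)]))
    off <- cs - isi - rep.int(cs[first] - isi[first], size)
    bur <- anchor[sp_i] + off
    bur <- bur[bur < up_e[up_i][sp_i]]     # clip bursts at UP end
  }
  sort(c(iso, bur))
}

# homogeneous Poisson over a set of epochs
sim_poisson_epochs <- function(starts, ends, rate) {
  d <- ends - starts
  n <- stats::rpois(length(d), rate * d)
  if (!sum(n)) return(numeric(0))
  ep <- rep.int(seq_along(d), n)
  sort(starts[ep] + stats::runif(sum(n)) * d[ep])
}

# block-alternation anticorrelated pair over epochs (wake carryover):
# fixed blocks anchored at epoch start; per block one unit runs at
# rate*(1+s), the other at rate*(1-s), sides swapping at random
sim_wake_anticorr_pair <- function(starts, ends, rate_a, rate_b, strength,
                                   block_s) {
  ta <- numeric(0); tb <- numeric(0)
  for (i in seq_along(starts)) {
    d <- ends[i] - starts[i]
    nb <- ceiling(d / block_s)
    b0 <- starts[i] + (seq_len(nb) - 1) * block_s
    b1 <- pmin(b0 + block_s, ends[i])
    bd <- b1 - b0
    coin <- stats::rbinom(nb, 1, 0.5) * 2 - 1
    na <- stats::rpois(nb, rate_a * (1 + strength * coin) * bd)
    nbk <- stats::rpois(nb, rate_b * (1 - strength * coin) * bd)
    if (sum(na)) {
      bi <- rep.int(seq_len(nb), na)
      ta <- c(ta, b0[bi] + stats::runif(sum(na)) * bd[bi])
    }
    if (sum(nbk)) {
      bi <- rep.int(seq_len(nb), nbk)
      tb <- c(tb, b0[bi] + stats::runif(sum(nbk)) * bd[bi])
    }
  }
  list(a = sort(ta), b = sort(tb))
}

discretize_beta_profile <- function(shape1, shape2, n_bins = 50) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  p <- diff(stats::pbeta(edges, shape1, shape2))
  p / sum(p)
}

#' Generate one synthetic pair of spike trains over UP states
#'
#' Standalone pair generator used both by [generate_recording()] and for
#' building focused test populations. Spikes are emitted only inside the UP
#' intervals of `up_epochs`.
#'
#' @param class One of `"INDEPENDENT"`, `"COACTIVE"`, `"ANTIPHASE"`,
#'   `"BURSTY_ANTIPHASE"`.
#' @param up_epochs An `epoch_set`; rows labeled UP are used.
#' @param rate_a,rate_b UP-state firing rates (Hz).
#' @param config A [synth_config()] supplying mechanism parameters.
#' @param depth Optional per-UP antiphase depth vector (recycled); defaults
#'   to `config$antiphase_depth`.
#' @param seed Optional seed.
#' @param ids Unit ids for the returned trains.
#' @return List with `spike_train`s `a` and `b`.
#' @export
generate_pair <- function(class, up_epochs, rate_a = 8, rate_b = 8,
                          config = synth_config(), depth = NULL, seed = NULL,
                          ids = c("a", "b")) {
  if (!is.null(seed)) set.seed(seed)
  up <- epochs_with_label(up_epochs, "UP")
  if (!nrow(up)) stop("no UP epochs")
  n_up <- nrow(up)
  if (is.null(depth)) depth <- config$antiphase_depth
  depth <- rep_len(depth, n_up)
  t0 <- min(up$start); t1 <- max(up$end)
  mk <- function(id, t) spike_train(id, t, t_start = min(t0, 0), t_end = t1)
  if (class == "INDEPENDENT") {
    pa <- rep(1 / 50, 50); pb <- pa
    a <- sim_profile_spikes(up$start, up$end, rate_a, pa)
    b <- sim_profile_spikes(up$start, up$end, rate_b, pb)
  } else if (class == "COACTIVE") {
    prob <- discretize_beta_profile(1.2, 3.5)
    sd <- config$coactive_gain_sd
    gain <- stats::rlnorm(n_up, -sd^2 / 2, sd)
    rmin <- min(rate_a, rate_b)
    rc <- config$coactive_coinc_frac * rmin
    shared <- sim_profile_spikes(up$start, up$end, rc, prob, gain)
    jit <- config$coactive_coinc_jitter
    a <- sort(c(sim_profile_spikes(up$start, up$end, rate_a - rc, prob, gain),
                pmin(pmax(shared + stats::rnorm(length(shared), 0, jit), t0), t1)))
    b <- sort(c(sim_profile_spikes(up$start, up$end, rate_b - rc, prob, gain),
                pmin(pmax(shared + stats::rnorm(length(shared), 0, jit), t0), t1)))
  } else if (class %in% c("ANTIPHASE", "BURSTY_ANTIPHASE")) {
    side_a <- stats::rbinom(n_up, 1, 0.5)
    side_b <- 1 - side_a
    gap <- config$antiphase_gap
    if (class == "ANTIPHASE") {
      a <- sim_antiphase_spikes(up$start, up$end, rate_a, side_a, depth, gap)
      b <- sim_antiphase_spikes(up$start, up$end, rate_b, side_b, depth, gap)
    } else {
      a <- sim_bursty_antiphase_spikes(up$start, up$end, rate_a, side_a, depth,
                                       config$burst_frac,
                                       config$burst_isi_range,
                                       config$burst_size_range, gap)
      b <- sim_bursty_antiphase_spikes(up$start, up$end, rate_b, side_b, depth,
                                       config$burst_frac,
                                       config$burst_isi_range,
                                       config$burst_size_range, gap)
    }
  } else stop("unknown pair class: ", class)
  list(a = mk(ids[1], a), b = mk(ids[2], b))
}

#' Generate the LFP trace
#'
#' White-noise floor plus a delta-frequency and a gamma-frequency sinusoid
#' whose amplitudes are set per epoch: inside nonREM they follow the
#' per-epoch amplitudes in `nrem_meta` with fixed-length linear ramps at
#' epoch boundaries; outside nonREM they are the configured wake/REM levels.
#'
#' @param states State `epoch_set`.
#' @param nrem_meta Data frame with per-nonREM-epoch `start`, `end`,
#'   `a_delta`, `a_gamma` (as produced by [generate_recording()]).
#' @param config A [synth_config()].
#' @param seed Optional seed.
#' @return An `lfp` object: list with `samples` and `rate`.
#' @export
generate_lfp <- function(states, nrem_meta, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$lfp_rate
  total <- max(states$end)
  n <- floor(total * fs)
  x <- stats::rnorm(n, 0, config$lfp_noise_sd)
  tt <- (seq_len(n) - 1) / fs
  two_pi <- 2 * pi
  add_osc <- function(idx, t, a_d, a_g, env) {
    x[idx] <<- x[idx] +
      a_d * env * sin(two_pi * config$delta_freq * t + 0.3) +
      a_g * env * sin(two_pi * config$gamma_freq * t + 1.1)
  }
  for (i in seq_len(nrow(states))) {
    i0 <- floor(states$start[i] * fs) + 1
    i1 <- min(n, ceiling(states$end[i] * fs))
    if (i1 < i0) next
    idx <- i0:i1
    t <- tt[idx]
    if (states$label[i] == "NREM") {
      j <- which(abs(nrem_meta$start - states$start[i]) < 1e-6)[1]
      env <- pmin(1, pmax(0, pmin((t - states$start[i]) / config$ramp_up_s,
                                  (states$end[i] - t) / config$ramp_down_s)))
      add_osc(idx, t, nrem_meta$a_delta[j], nrem_meta$a_gamma[j], env)
    } else {
      gam <- if (states$label[i] == "WAKE") config$wake_gamma else config$rem_gamma
      add_osc(idx, t, config$wr_delta, gam, 1)
    }
  }
  structure(list(samples = x, rate = fs), class = "lfp")
}

#' @export
print.lfp <- function(x, ...) {
  cat(sprintf("<lfp> %d samples at %g Hz (%.1f s)\n", length(x$samples),
              x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Generate a full synthetic recording
#'
#' Produces spike trains for all units, the state schedule, the UP/DOWN
#' tiling, the LFP, and the ground truth (designated pair classes and
#' per-nonREM-epoch delta/gamma amplitudes and antiphase depths). All
#' randomness flows from `config$seed`; the same config yields identical
#' output.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_recording` with elements `trains` (list of
#'   `spike_train`), `states` (`epoch_set`), `updown` (`epoch_set` with
#'   `parent` attribute), `lfp`, `truth` (list: `pairs` data frame with
#'   `unit_a`, `unit_b`, `class`, `wake_anticorr`; `nrem_meta` per-epoch
#'   amplitudes/depths; `up_parent`), and `config`.
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  states <- generate_state_schedule(config, seed = NULL)
  updown <- generate_up_down(states, config, seed = NULL)
  nrem <- epochs_with_label(states, "NREM")
  up <- updown[updown$label == "UP", , drop = FALSE]
  up_parent <- attr(updown, "parent")[updown$label == "UP"]

  # per-nonREM-epoch LFP amplitudes: duration-coupled + slow drift + noise
  dur <- nrem$end - nrem$start
  mid <- (nrem$start + nrem$end) / 2
  total <- config$duration_h * 3600
  drift <- 1 + config$drift_amp *
    sin(2 * pi * config$drift_cycles * mid / total + stats::runif(1, 0, 2 * pi))
  a_delta <- (config$delta_base +
              config$delta_dur_slope * pmin(dur, config$delta_dur_cap)) *
    drift * stats::rlnorm(length(dur), 0, config$amp_noise_sd)
  a_gamma <- pmax(0.15, config$gamma_base -
                  config$gamma_dur_slope * pmin(dur, config$delta_dur_cap)) *
    (2 - drift) * stats::rlnorm(length(dur), 0, config$amp_noise_sd)
  rel <- a_delta / mean(a_delta)
  depth_ep <- pmin(0.98, pmax(0.10,
                              config$antiphase_depth * rel^config$delta_coupling))
  # per-pair depth heterogeneity: antiphase pairs differ in trough strength,
  # as real pairs do; keeps the population dce spectrum broad
  depth_pair_scale <- stats::runif(floor(config$n_units / 2), 0.55, 1)
  nrem_meta <- data.frame(start = nrem$start, end = nrem$end, duration = dur,
                          a_delta = a_delta, a_gamma = a_gamma,
                          depth = depth_ep)
  depth_up <- depth_ep[up_parent]   # per-UP depth via parent epoch

  # designated pairs and classes
  n_pairs <- floor(config$n_units / 2)
  fr <- config$class_fractions
  n_anti <- round(fr[["ANTIPHASE"]] * n_pairs)
  n_co <- round(fr[["COACTIVE"]] * n_pairs)
  n_ind <- n_pairs - n_anti - n_co
  classes <- c(rep("INDEPENDENT", n_ind), rep("COACTIVE", n_co),
               rep("ANTIPHASE", n_anti))
  bursty <- rep(FALSE, n_pairs)
  if (n_anti > 0) {
    anti_idx <- which(classes == "ANTIPHASE")
    nb <- round(config$antiphase_bursty_frac * n_anti)
    if (nb > 0) bursty[anti_idx[seq_len(nb)]] <- TRUE
  }
  classes[bursty] <- "BURSTY_ANTIPHASE"
  wake_anti <- rep(FALSE, n_pairs)
  anti_all <- which(classes %in% c("ANTIPHASE", "BURSTY_ANTIPHASE"))
  if (length(anti_all)) {
    nw <- round(config$wake_anticorr_frac * length(anti_all))
    if (nw > 0) wake_anti[anti_all[seq_len(nw)]] <- TRUE
  }

  rates <- exp(stats::runif(config$n_units, log(config$up_rate_range[1]),
                            log(config$up_rate_range[2])))
  up_frac <- sum(up$end - up$start) / max(sum(nrem$end - nrem$start), 1e-9)
  wake <- epochs_with_label(states, "WAKE")
  rem <- epochs_with_label(states, "REM")

  unit_ids <- sprintf("u%02d", seq_len(config$n_units))
  nrem_times <- vector("list", config$n_units)
  # nonREM spikes, pair by pair (mechanisms are pairwise)
  for (p in seq_len(n_pairs)) {
    ia <- 2 * p - 1; ib <- 2 * p
    pr <- generate_pair(classes[p], up, rates[ia], rates[ib], config,
                        depth = pmin(0.98, depth_up * depth_pair_scale[p]),
                        seed = NULL, ids = unit_ids[c(ia, ib)])
    nrem_times[[ia]] <- pr$a$times
    nrem_times[[ib]] <- pr$b$times
  }
  if (config$n_units %% 2 == 1) {  # odd unit out: independent
    i <- config$n_units
    nrem_times[[i]] <- sim_profile_spikes(up$start, up$end, rates[i],
                                          rep(1 / 50, 50))
  }

  # wake and REM: rate-matched homogeneous Poisson (block-alternation
  # carryover for flagged antiphase pairs in wake only)
  other_times <- vector("list", config$n_units)
  match_rate <- rates * up_frac
  done <- rep(FALSE, config$n_units)
  for (p in seq_len(n_pairs)) {
    ia <- 2 * p - 1; ib <- 2 * p
    if (wake_anti[p] && nrow(wake)) {
      wk <- sim_wake_anticorr_pair(wake$start, wake$end, match_rate[ia],
                                   match_rate[ib],
                                   config$wake_anticorr_strength,
                                   config$wake_block_s)
      other_times[[ia]] <- wk$a
      other_times[[ib]] <- wk$b
      done[c(ia, ib)] <- TRUE
    }
  }
  for (i in seq_len(config$n_units)) {
    wt <- if (done[i]) other_times[[i]]
          else sim_poisson_epochs(wake$start, wake$end, match_rate[i])
    rt <- sim_poisson_epochs(rem$start, rem$end, match_rate[i])
    other_times[[i]] <- sort(c(wt, rt))
  }

  trains <- stats::setNames(lapply(seq_len(config$n_units), function(i)
    spike_train(unit_ids[i], sort(c(nrem_times[[i]], other_times[[i]])),
                t_start = 0, t_end = total)), unit_ids)
  lfp <- generate_lfp(states, nrem_meta, config, seed = NULL)

  truth <- list(
    pairs = data.frame(unit_a = unit_ids[2 * seq_len(n_pairs) - 1],
                       unit_b = unit_ids[2 * seq_len(n_pairs)],
                       class = classes, wake_anticorr = wake_anti,
                       stringsAsFactors = FALSE),
    nrem_meta = nrem_meta,
    up_parent = up_parent,
    depth_pair_scale = depth_pair_scale,
    rates = stats::setNames(rates, unit_ids),
    up_fraction = up_frac)
  structure(list(trains = trains, states = states, updown = updown,
                 lfp = lfp, truth = truth, config = config),
            class = "synth_recording")
}

#' @export
print.synth_recording <- function(x, ...) {
  cat(sprintf("<synth_recording> %d units, %.1f h, %d designated pairs (seed %d)\n",
              length(x$trains), x$config$duration_h, nrow(x$truth$pairs),
              x$config$seed))
  print(table(x$truth$pairs$class))
  invisible(x)
}
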