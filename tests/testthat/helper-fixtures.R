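# shared fixtures, built once per session and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# deterministic UP/DOWN tiling: n_up UP states of fixed duration
regular_updown <- function(n_up, up_dur = 1, down_dur = 0.2, start = 0) {
  cyc <- up_dur + down_dur
  s <- start + (seq_len(n_up) - 1) * cyc
  epoch_set(c(s, s + up_dur), c(s + up_dur, s + cyc),
            rep(c("UP", "DOWN"), each = n_up))
}

poisson_train <- function(id, rate, t0, t1) {
  n <- stats::rpois(1, rate * (t1 - t0))
  spike_train(id, sort(stats::runif(n, t0, t1)), t_start = t0, t_end = t1)
}

# direct double-loop triangular convolution with renormalized edge kernels
tri_conv_oracle <- function(x, half) {
  kern <- (half + 1) - abs(-half:half)
  kern <- kern / sum(kern)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    k <- kern[j - i + half + 1]
    out[i] <- sum(x[j] * k) / sum(k)
  }
  out
}

# exhaustive burst-spike oracle: a spike is a burst spike iff it belongs to
# some stretch of >= 3 consecutive spikes whose ISIs are all below thr
burst_oracle <- function(times, thr) {
  n <- length(times)
  marked <- rep(FALSE, n)
  if (n < 3) return(integer(0))
  for (i in 1:(n - 2)) {
    j <- i
    while (j < n && times[j + 1] - times[j] < thr) j <- j + 1
    if (j - i >= 2) marked[i:j] <- TRUE
  }
  which(marked)
}

# lognormal-ish UP/DOWN schedule from the generator, cached
small_schedule <- function(hours = 0.6, seed = 101) {
  fixture(paste0("sched", hours, "_", seed), {
    cfg <- synth_config(duration_h = hours, n_units = 4, seed = seed)
    st <- generate_state_schedule(cfg)
    ud <- generate_up_down(st, cfg)
    list(cfg = cfg, states = st, updown = ud)
  })
}
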