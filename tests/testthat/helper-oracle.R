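# Independent, deliberately naive reference implementations used as oracles.
# These are written directly from the model definitions, step by step, and
# share no code with the package internals.

# Naive forward-Euler integration of the Izhikevich model. Both derivatives
# from the current state, simultaneous advance, threshold test on the
# updated state, spike stamped at that step's time, then reset.
oracle_izhikevich <- function(I, params = regular_spiking(), dt = 1,
                              t_window = 1000, v0 = params$v_r, u0 = 0) {
  n_steps <- round(t_window / dt)
  v <- v0
  u <- u0
  spikes <- numeric(0)
  for (s in seq_len(n_steps)) {
    dv <- (params$k * (v - params$v_r) * (v - params$v_t) - u + I) / params$C
    du <- params$a * (params$b * (v - params$v_r) - u)
    v <- v + dt * dv
    u <- u + dt * du
    if (v >= params$v_peak) {
      spikes <- c(spikes, s * dt)
      v <- params$c
      u <- u + params$d
    }
  }
  spikes
}

# Exhaustive nearest-AFR search: scans all classes, keeping the first
# (smallest-index) minimizer.
oracle_nearest_afr <- function(fr, afr) {
  best <- 1L
  for (k in seq_along(afr)) {
    if (abs(afr[k] - fr) < abs(afr[best] - fr)) best <- k
  }
  best
}

# Small planted problem shared by classifier tests (kept cheap: short
# simulation windows are exercised elsewhere; training tests shrink p/MCN).
make_small_planted <- function(seed = 11, classes = 2, features = 3, n = 20) {
  make_planted(classes = classes, features = features, n = n, seed = seed)
}
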