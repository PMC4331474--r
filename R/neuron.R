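#' Izhikevich neuron parameters
#'
#' Constructs the nine-constant parameter set of the Izhikevich simple model
#' \deqn{C \dot v = k (v - v_r)(v - v_t) - u + I, \qquad
#'       \dot u = a (b (v - v_r) - u),}
#' with after-spike reset: if \eqn{v \ge v_{peak}} then \eqn{v \leftarrow c},
#' \eqn{u \leftarrow u + d}. The constants are used dimensionlessly, with
#' voltages conventionally read in mV, time in ms and currents in pA.
#'
#' @param C membrane capacitance; must be positive.
#' @param k gain of the quadratic voltage nonlinearity.
#' @param v_r resting membrane potential (mV).
#' @param v_t instantaneous threshold potential (mV); must exceed `v_r`.
#' @param v_peak spike cutoff value (mV); must exceed `v_t`.
#' @param a recovery time constant.
#' @param b resonance/amplification coefficient of the recovery current
#'   (`b < 0` amplifying, `b > 0` resonant).
#' @param c membrane potential reset value (mV).
#' @param d after-spike increment of the recovery current.
#'
#' @return An object of class `izhikevich_params` (a named list).
#' @seealso [regular_spiking()] for the standard cortical regular-spiking set.
#' @export
#' @examples
#' izhikevich_params(C = 100, k = 0.7, v_r = -60, v_t = -40, v_peak = 35,
#'                   a = 0.03, b = -2, c = -50, d = 100)
izhikevich_params <- function(C, k, v_r, v_t, v_peak, a, b, c, d) {
  vals <- c(C = C, k = k, v_r = v_r, v_t = v_t, v_peak = v_peak,
            a = a, b = b, c = c, d = d)
  if (!all(is.finite(vals))) {
    stop("all Izhikevich parameters must be finite", call. = FALSE)
  }
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (!(v_r < v_t && v_t < v_peak)) {
    stop("require v_r < v_t < v_peak", call. = FALSE)
  }
  structure(as.list(vals), class = "izhikevich_params")
}

#' Regular-spiking (RS) parameter set
#'
#' The tonic-firing regime of typical cortical pyramidal neurons:
#' `C = 100`, `k = 0.7`, `v_r = -60`, `v_t = -40`, `v_peak = 35`,
#' `a = 0.03`, `b = -2`, `c = -50`, `d = 100`. This regime shows class 1
#' excitability: the firing rate grows smoothly with the injected current,
#' which is what makes the neuron usable as a rate-coding classifier.
#'
#' @return An `izhikevich_params` object.
#' @export
#' @examples
#' regular_spiking()
regular_spiking <- function() {
  izhikevich_params(C = 100, k = 0.7, v_r = -60, v_t = -40, v_peak = 35,
                    a = 0.03, b = -2, c = -50, d = 100)
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat("<izhikevich_params>\n")
  cat(" ", paste(names(x), unlist(x), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Integration settings for the forward-Euler simulation of the neuron.
#'
#' @param dt integration step (ms). Default 1.
#' @param t_window stimulation window length (ms). Must be an integer
#'   multiple of `dt` (within floating tolerance). Default 1000.
#' @param v0 initial membrane potential (mV). `NULL` (the default) means the
#'   resting potential `v_r` of the parameter set used at simulation time,
#'   so that zero input current provably produces zero spikes. The model's
#'   initial state is not prescribed by the rate-coding scheme itself; the
#'   resting equilibrium is this package's documented choice.
#' @param u0 initial recovery current. Default 0.
#'
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' simulation_config()            # dt = 1 ms, T = 1000 ms, rest start
#' simulation_config(dt = 0.5, t_window = 500)
simulation_config <- function(dt = 1, t_window = 1000, v0 = NULL, u0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t_window) || length(t_window) != 1L ||
      !is.finite(t_window) || t_window <= 0) {
    stop("`t_window` must be a single positive number", call. = FALSE)
  }
  steps <- t_window / dt
  if (abs(steps - round(steps)) > 1e-8) {
    stop("`t_window` must be an integer multiple of `dt`", call. = FALSE)
  }
  if (!is.null(v0) && (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0))) {
    stop("`v0` must be NULL or a single finite number", call. = FALSE)
  }
  if (!is.numeric(u0) || length(u0) != 1L || !is.finite(u0)) {
    stop("`u0` must be a single finite number", call. = FALSE)
  }
  structure(list(dt = dt, t_window = t_window, v0 = v0, u0 = u0,
                 n_steps = as.integer(round(steps))),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> dt =", x$dt, "ms, T =", x$t_window, "ms, v0 =",
      if (is.null(x$v0)) "v_r (rest)" else x$v0, ", u0 =", x$u0, "\n")
  invisible(x)
}

# Resolve the initial state against a parameter set.
initial_state <- function(params, config) {
  list(v0 = if (is.null(config$v0)) params$v_r else config$v0, u0 = config$u0)
}

new_spike_train <- function(spike_times, t_window, dt, current, trace = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(spike_times) &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > t_window)) {
    stop("spike times must lie in [0, t_window]", call. = FALSE)
  }
  if (length(spike_times) > 1L &&
      any(diff(spike_times) < dt - 1e-12)) {
    stop("consecutive spikes must be at least `dt` apart", call. = FALSE)
  }
  structure(list(spike_times = spike_times,
                 n_spikes = length(spike_times),
                 t_window = t_window, dt = dt, current = current,
                 trace = trace),
            class = "spike_train")
}

#' Simulate the Izhikevich neuron under a constant input current
#'
#' Integrates the model with the forward-Euler method and records every
#' threshold crossing as a spike. Both derivatives are evaluated on the
#' current state and both state variables advanced together; the threshold
#' test `v >= v_peak` runs on the updated state, the spike is stamped at
#' that step's time, and then `v <- c`, `u <- u + d`. The discrete reset
#' enforces an absolute refractory period of one step, so at most `1/dt`
#' spikes per ms can occur.
#'
#' @param current constant input current (pA) applied over the whole window.
#' @param params an [izhikevich_params()] object. Default [regular_spiking()].
#' @param config a [simulation_config()] object.
#' @param keep_trace if `TRUE`, record the full `(t, v, u)` trajectory (the
#'   raw, pre-reset membrane potential) for diagnostics and plotting.
#'
#' @return A `spike_train` object: `spike_times` (ms), `n_spikes`,
#'   `t_window`, `dt`, `current`, and (optionally) `trace`, a tibble with
#'   columns `t`, `v`, `u`.
#' @export
#' @examples
#' st <- simulate_neuron(100)
#' st$n_spikes
#' firing_rate(st)
simulate_neuron <- function(current, params = regular_spiking(),
                            config = simulation_config(),
                            keep_trace = FALSE) {
  stopifnot(inherits(params, "izhikevich_params"),
            inherits(config, "simulation_config"))
  if (!is.numeric(current) || length(current) != 1L || !is.finite(current)) {
    stop("`current` must be a single finite number", call. = FALSE)
  }
  s0 <- initial_state(params, config)
  res <- izh_simulate_cpp(current, params$C, params$k, params$v_r, params$v_t,
                          params$v_peak, params$a, params$b, params$c,
                          params$d, config$dt, config$n_steps, s0$v0, s0$u0,
                          keep_trace)
  trace <- if (keep_trace) tibble::as_tibble(res$trace) else NULL
  new_spike_train(res$spike_times, config$t_window, config$dt, current, trace)
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", x$n_spikes, "spikes in", x$t_window,
      "ms (I =", paste0(x$current, ")"),
      "rate =", format(firing_rate(x), digits = 4), "spikes/ms\n")
  invisible(x)
}

#' Firing rate of a spike train
#'
#' The number of spikes in the stimulation window divided by the window
#' length: `fr = N_sp / T`, in spikes per ms. Bounded above by `1/dt`
#' because the discrete reset admits at most one spike per step.
#'
#' @param train a `spike_train` from [simulate_neuron()].
#' @return A non-negative number (spikes/ms).
#' @export
#' @examples
#' firing_rate(simulate_neuron(100))
firing_rate <- function(train) {
  if (!inherits(train, "spike_train")) {
    stop("`train` must be a spike_train", call. = FALSE)
  }
  if (train$t_window <= 0) stop("invalid window: T must be > 0", call. = FALSE)
  train$n_spikes / train$t_window
}

#' Spike counts for a batch of input currents
#'
#' Runs the same Euler integration as [simulate_neuron()] once per current
#' and returns only the spike counts. This is the kernel used by the
#' classifier, where every fitness evaluation simulates the neuron once per
#' training pattern.
#'
#' @inheritParams simulate_neuron
#' @param currents numeric vector of constant input currents.
#' @return Integer vector of spike counts, one per current.
#' @export
spike_counts <- function(currents, params = regular_spiking(),
                         config = simulation_config()) {
  stopifnot(inherits(params, "izhikevich_params"),
            inherits(config, "simulation_config"))
  if (!is.numeric(currents) || !all(is.finite(currents))) {
    stop("`currents` must be finite numbers", call. = FALSE)
  }
  s0 <- initial_state(params, config)
  izh_count_spikes_cpp(as.numeric(currents), params$C, params$k, params$v_r,
                       params$v_t, params$v_peak, params$a, params$b,
                       params$c, params$d, config$dt, config$n_steps,
                       s0$v0, s0$u0)
}

#' Rate-current (f-I) curve
#'
#' Convenience sweep of the neuron over a grid of input currents.
#'
#' @inheritParams spike_counts
#' @return A tibble with columns `current`, `n_spikes`, `firing_rate`.
#' @export
#' @examples
#' fi_curve(seq(0, 200, by = 20))
fi_curve <- function(currents, params = regular_spiking(),
                     config = simulation_config()) {
  n <- spike_counts(currents, params, config)
  tibble::tibble(current = as.numeric(currents), n_spikes = as.integer(n),
                 firing_rate = n / config$t_window)
}

#' @rdname tidiers
#' @export
tidy.spike_train <- function(x, ...) {
  tibble::tibble(spike = seq_along(x$spike_times), time = x$spike_times)
}

#' Write a simulation trace as delimited text
#'
#' Dumps the `(t, v, u)` trajectory of a traced simulation to a CSV file
#' for external plotting.
#'
#' @param train a `spike_train` simulated with `keep_trace = TRUE`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(train, path) {
  if (!inherits(train, "spike_train") || is.null(train$trace)) {
    stop("`train` must be a spike_train with a recorded trace", call. = FALSE)
  }
  readr::write_csv(train$trace, path)
  invisible(path)
}
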