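#' Leaky-integrate-and-fire neuron parameters
#'
#' Validated parameter set for the clock-driven LIF simulation. Defaults
#' are standard cortical-neuron textbook values; all are exposed through
#' the `lif` section of [snn_config()].
#'
#' @param tau_m membrane time constant, ms.
#' @param v_rest resting potential, mV.
#' @param v_thresh firing threshold, mV.
#' @param v_reset post-spike reset potential, mV (must be <= `v_rest`).
#' @param t_ref absolute refractory period, ms.
#' @param psc_tau exponential decay constant of the post-synaptic current, ms.
#' @param dt integration step, ms.
#' @return A list of class `"lif_params"`.
#' @export
lif_params <- function(tau_m = 10, v_rest = -65, v_thresh = -50,
                       v_reset = -70, t_ref = 2, psc_tau = 2, dt = 0.1) {
  p <- list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
            v_reset = v_reset, t_ref = t_ref, psc_tau = psc_tau, dt = dt)
  stopifnot(p$tau_m > 0, p$dt > 0, p$psc_tau > 0, p$t_ref >= 0,
            p$v_reset <= p$v_rest, p$v_rest < p$v_thresh)
  class(p) <- "lif_params"
  p
}

#' Initial LIF neuron state
#'
#' @param p [lif_params()].
#' @param t start time, ms.
#' @return A list of class `"lif_state"` with the membrane potential `v`,
#'   the end of the current refractory period `refractory_until`, the
#'   running clock `t` and the accumulated `spike_times`.
#' @export
lif_state <- function(p = lif_params(), t = 0) {
  structure(list(v = p$v_rest, refractory_until = -Inf, t = t,
                 spike_times = numeric(0)),
            class = "lif_state")
}

#' Advance one LIF neuron by one integration step
#'
#' Exponential-Euler update: the membrane potential decays exactly toward
#' `v_rest` with time constant `tau_m`, plus `current * dt / tau_m` from the
#' input held constant over the step. Crossing `v_thresh` records a spike at
#' the current time, resets to `v_reset` and starts the refractory period,
#' during which the potential is clamped and inputs are ignored. This is
#' the reference single-neuron implementation of the update rule used by
#' the compiled cluster simulator.
#'
#' @param state a [lif_state()].
#' @param current input current for this step (finite).
#' @param p [lif_params()].
#' @return The updated `"lif_state"`.
#' @examples
#' s <- lif_state()
#' s <- step_lif(s, current = 0)
#' s$v  # stays at rest
#' @export
step_lif <- function(state, current, p = lif_params()) {
  if (!is.finite(current)) stop("input current must be finite", call. = FALSE)
  t <- state$t
  if (t < state$refractory_until) {
    state$v <- p$v_reset
  } else {
    state$v <- p$v_rest + (state$v - p$v_rest) * exp(-p$dt / p$tau_m) +
      current * p$dt / p$tau_m
    if (state$v >= p$v_thresh) {
      state$spike_times <- c(state$spike_times, t)
      state$v <- p$v_reset
      state$refractory_until <- t + p$t_ref
    }
  }
  state$t <- t + p$dt
  state
}

#' Teacher signal
#'
#' A supervised perturbation injected into one decode neuron during
#' training: an encouraging signal is a suprathreshold positive current
#' pulse that forces the target to spike at its injection time (so STDP
#' potentiates causally earlier inputs); a punishing signal is a strong
#' hyperpolarizing pulse that suppresses firing.
#'
#' @param polarity `"encourage"` or `"punish"`.
#' @param target decode-neuron index (class label, 0-based).
#' @param time injection time, ms.
#' @param magnitude pulse magnitude in current units (positive; the sign is
#'   set by `polarity`).
#' @return A list of class `"teacher_signal"`.
#' @export
teacher_signal <- function(polarity = c("encourage", "punish"), target, time,
                           magnitude = 3000) {
  polarity <- match.arg(polarity)
  stopifnot(length(target) == 1L, target >= 0, time >= 0, magnitude > 0)
  structure(list(polarity = polarity, target = as.integer(target),
                 time = as.numeric(time), magnitude = as.numeric(magnitude)),
            class = "teacher_signal")
}

#' Simulate one cluster on an input spike train
#'
#' Clock-driven simulation of the cluster's decode layer: every input event
#' injects an exponentially decaying current, weighted by the live synapse,
#' into each decode neuron; teacher signals inject their pulses at their
#' injection times. Pruned (dead) synapses inject nothing, exactly as if
#' their weight were zero. The simulation is fully deterministic.
#'
#' @param net a cluster from [build_network()] (see [new_cluster()]).
#' @param train a [spike_train()] with `n_channels == net$n_inputs`.
#' @param teachers list of [teacher_signal()]s (empty for teacher-free
#'   evaluation).
#' @param p [lif_params()].
#' @param window_ms simulation window; defaults to the train's window.
#' @return A `"firing_record"`: list with `fired` (0-based indices of decode
#'   neurons that spiked), `spike_times` (list of per-neuron spike time
#'   vectors), `first_spike` (per-neuron earliest time, `NA` if silent) and
#'   `n_decode`.
#' @export
simulate_cluster <- function(net, train, teachers = list(),
                             p = lif_params(),
                             window_ms = attr(train, "window_ms")) {
  stopifnot(inherits(train, "spike_train"))
  if (attr(train, "n_channels") != net$n_inputs)
    stop("spike train has ", attr(train, "n_channels"),
         " channels but the cluster expects ", net$n_inputs, call. = FALSE)
  n_te <- length(teachers)
  te_target <- integer(n_te); te_time <- numeric(n_te); te_amp <- numeric(n_te)
  for (i in seq_len(n_te)) {
    te <- teachers[[i]]
    if (te$time < 0 || te$time >= window_ms)
      stop("teacher time outside simulation window", call. = FALSE)
    if (te$target < 0 || te$target >= net$n_decode)
      stop("teacher target outside decode layer", call. = FALSE)
    te_target[i] <- te$target
    te_time[i] <- te$time
    te_amp[i] <- if (te$polarity == "encourage") te$magnitude else -te$magnitude
  }
  w_eff <- net$W * net$alive
  spikes <- lif_cluster_sim(train$channel - 1L, train$time_ms, w_eff,
                            te_target, te_time, te_amp,
                            p$tau_m, p$v_rest, p$v_thresh, p$v_reset,
                            p$t_ref, p$psc_tau, p$dt, window_ms)
  firing_record(spikes)
}

firing_record <- function(spikes) {
  n <- length(spikes)
  first <- vapply(spikes, function(s) if (length(s)) s[1] else NA_real_,
                  numeric(1))
  structure(list(fired = which(!is.na(first)) - 1L,
                 spike_times = spikes,
                 first_spike = first,
                 n_decode = n),
            class = "firing_record")
}

#' @export
print.firing_record <- function(x, ...) {
  counts <- lengths(x$spike_times)
  cat(sprintf("firing record: %d/%d decode neurons fired\n",
              length(x$fired), x$n_decode))
  if (length(x$fired))
    cat("  counts:", paste(sprintf("%d:%d", x$fired, counts[x$fired + 1L]),
                           collapse = " "), "\n")
  invisible(x)
}
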