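#' Advance a single Adex neuron by one Euler step
#'
#' Forward-Euler update of the membrane potential and adaptation current,
#' exponential decay of the synaptic conductances (exact by default), discrete
#' conductance jumps for incoming spikes, and spike/reset/refractory handling.
#' This scalar R implementation defines the reference dynamics; the network
#' engine (in compiled code) implements the same update and is tested for
#' parity against it.
#'
#' The membrane equation is
#' `C dV/dt = -g_L (V - E_L) + g_L delta exp((V - V_th)/delta) - w - I_syn + I_ext`
#' with `I_syn = g_E (V - E_E) + g_I (V - E_I)`, and
#' `tau_w dw/dt = a (V - E_L) - w`. A spike is detected when `V >= v_cut`
#' (default `v_cut = V_th`); at a spike `V` is reset to `V_rest`, `w` jumps by
#' `b`, and both `V` and `w` are held fixed for the refractory period `T_ref`
#' while the conductances keep decaying and accumulating input.
#'
#' @param state A [neuron_state()].
#' @param params An [adex_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param t Current time (ms); used for the refractory clock.
#' @param n_exc_spikes,n_inh_spikes Number of presynaptic excitatory /
#'   inhibitory spikes arriving during this step.
#' @param I_ext External current (nA).
#' @param dt Time step (ms); reference value 0.1.
#' @param conductance_decay `"exact"` (analytic exponential decay of the
#'   linear conductance ODE) or `"euler"` (forward Euler, for parity
#'   experiments).
#' @return A list with the updated `state` and logical `spiked`.
#' @export
step_neuron <- function(state, params, kinetics, t = 0,
                        n_exc_spikes = 0, n_inh_spikes = 0,
                        I_ext = 0, dt = 0.1,
                        conductance_decay = c("exact", "euler")) {
  conductance_decay <- match.arg(conductance_decay)
  if (dt <= 0) stop("dt must be positive")
  if (!all(is.finite(c(state$V, state$w, state$g_E, state$g_I))))
    stop("non-finite neuron state")
  p <- params

  # Synapse-side bookkeeping runs regardless of refractoriness.
  dec_E <- if (conductance_decay == "exact") exp(-dt / kinetics$tau_E) else 1 - dt / kinetics$tau_E
  dec_I <- if (conductance_decay == "exact") exp(-dt / kinetics$tau_I) else 1 - dt / kinetics$tau_I
  g_E <- state$g_E * dec_E + n_exc_spikes * kinetics$Q
  g_I <- state$g_I * dec_I + n_inh_spikes * kinetics$Q

  if (t < state$refractory_until) {
    state$g_E <- g_E
    state$g_I <- g_I
    return(list(state = state, spiked = FALSE))
  }

  V <- state$V
  w <- state$w
  x <- min((V - p$V_th) / p$delta, 30)
  I_exp <- p$g_L * p$delta * exp(x)
  I_syn <- g_E * (V - p$E_E) + g_I * (V - p$E_I)
  V_new <- V + dt * (-p$g_L * (V - p$E_L) + I_exp - w - I_syn + I_ext * 1e3) / p$C
  w_new <- w + dt * (p$a * (V - p$E_L) - w) / p$tau_w

  spiked <- V_new >= p$v_cut
  if (spiked) {
    V_new <- p$V_rest
    w_new <- w_new + p$b
    state$refractory_until <- t + dt + p$T_ref
  }
  state$V <- V_new
  state$w <- w_new
  state$g_E <- g_E
  state$g_I <- g_I
  list(state = state, spiked = spiked)
}

#' Simulate an isolated Adex neuron driven by a current trace
#'
#' Iterates [step_neuron()] over a current trace sampled at `dt`. Deterministic
#' given its inputs.
#'
#' @param params An [adex_params()].
#' @param current_trace External current (nA), one value per time step.
#' @param dt Time step (ms).
#' @param kinetics Optional [synapse_kinetics()] (only relevant if synaptic
#'   input is added via `exc_spike_steps`/`inh_spike_steps`).
#' @param exc_spike_steps,inh_spike_steps Integer step indices (1-based) at
#'   which presynaptic spikes arrive.
#' @param state Initial [neuron_state()]; defaults to rest (`V = E_L`).
#' @param conductance_decay Passed to [step_neuron()].
#' @return A list with `spike_times` (ms), `V_trace` (mV, one value per step,
#'   post-update) and `w_trace` (pA).
#' @examples
#' p <- adex_params("RS")
#' out <- simulate_single_neuron(p, rep(0.3, 5000), dt = 0.1)
#' length(out$spike_times)  # tonic adapting response to 0.3 nA
#' @export
simulate_single_neuron <- function(params, current_trace, dt = 0.1,
                                   kinetics = synapse_kinetics(),
                                   exc_spike_steps = integer(),
                                   inh_spike_steps = integer(),
                                   state = NULL,
                                   conductance_decay = "exact") {
  n <- length(current_trace)
  if (n == 0)
    return(list(spike_times = numeric(), V_trace = numeric(), w_trace = numeric()))
  if (is.null(state)) state <- neuron_state(V = params$E_L)
  n_exc <- tabulate(exc_spike_steps, nbins = n)
  n_inh <- tabulate(inh_spike_steps, nbins = n)
  V_trace <- numeric(n)
  w_trace <- numeric(n)
  spike_times <- numeric()
  for (k in seq_len(n)) {
    out <- step_neuron(state, params, kinetics, t = (k - 1) * dt,
                       n_exc_spikes = n_exc[k], n_inh_spikes = n_inh[k],
                       I_ext = current_trace[k], dt = dt,
                       conductance_decay = conductance_decay)
    state <- out$state
    if (out$spiked) spike_times <- c(spike_times, k * dt)
    V_trace[k] <- state$V
    w_trace[k] <- state$w
  }
  list(spike_times = spike_times, V_trace = V_trace, w_trace = w_trace)
}

#' Ramp-plateau current protocol
#'
#' The standard single-cell characterization drive: a linear ramp from 0 to
#' `peak` nA, a constant plateau, and a linear ramp back to 0.
#'
#' @param peak Plateau amplitude (nA).
#' @param ramp_ms,plateau_ms Durations (ms).
#' @param dt Time step (ms).
#' @return Current trace (nA) sampled at `dt`.
#' @export
ramp_plateau_current <- function(peak = 0.5, ramp_ms = 250, plateau_ms = 500,
                                 dt = 0.1) {
  n_ramp <- round(ramp_ms / dt)
  n_plat <- round(plateau_ms / dt)
  c(seq(0, peak, length.out = n_ramp),
    rep(peak, n_plat),
    seq(peak, 0, length.out = n_ramp))
}

#' Read a current trace from a two-column CSV
#'
#' Expects columns `time_ms` and `current_nA` sampled on a uniform grid.
#'
#' @param path CSV path.
#' @return A list with `current` (nA) and `dt` (ms).
#' @export
read_current_trace <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_ms", "current_nA") %in% names(df)))
  dts <- diff(df$time_ms)
  if (length(dts) && diff(range(dts)) > 1e-9 * max(dts))
    stop("current trace is not uniformly sampled")
  list(current = df$current_nA, dt = if (length(dts)) dts[1] else 0.1)
}
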