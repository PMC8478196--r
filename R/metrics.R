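#' Synchrony index from the population-rate autocorrelation
#'
#' The population rate (1 ms bins) is autocorrelated, the autocorrelation is
#' fitted to a damped cosine `A exp(-lambda_d t) cos(2 pi nu t)`, and the
#' fitted value at zero lag (`A`) is the synchrony index. A global oscillation
#' is flagged only when the fit converges, the decay rate stays at or below
#' `decay_threshold` (100 /s), and the fitted amplitude rises above
#' `min_amplitude` (purely stochastic rates fit `A ~ 0` with an arbitrary
#' decay, which must not count as an oscillation). The normalized
#' autocorrelation makes the index invariant to rescaling the rate trace.
#'
#' @param sim A `sim_result`, a `population_rate()` list, or a numeric rate
#'   vector sampled at `1000/bin` Hz.
#' @param bin Bin width (ms) when `sim` is a `sim_result`.
#' @param population Optional population restriction.
#' @param max_lag_ms Autocorrelation fitting range (ms).
#' @param decay_threshold Decay-rate cutoff (1/s) above which the oscillation
#'   flag is false.
#' @param min_amplitude Minimum fitted amplitude for a credible oscillation.
#' @return A list: `SI` (fitted zero-lag value), `oscillation_flag`,
#'   `fitted_freq` (Hz), `decay_rate` (1/s), `fit` (the nls object or NULL).
#' @export
synchrony_index <- function(sim, bin = 1, population = NULL, max_lag_ms = 150,
                            decay_threshold = 100, min_amplitude = 0.05) {
  rate <- if (inherits(sim, "sim_result"))
    population_rate(sim, bin = bin, population = population)$rate
  else if (is.list(sim)) sim$rate else as.numeric(sim)
  if (length(rate) < 1000 / bin)
    stop("need at least one second of activity")
  if (sd(rate) == 0)
    return(list(SI = 0, oscillation_flag = FALSE, fitted_freq = NA_real_,
                decay_rate = NA_real_, fit = NULL))
  lag_max <- round(max_lag_ms / bin)
  ac <- as.numeric(acf(rate, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)[-1]  # drop lag 0 (shot-noise peak)
  lag_s <- (seq_along(ac) * bin) / 1000
  # frequency start value from the rate spectrum
  f0 <- tryCatch(spectral_peak(rate, fs = 1000 / bin, band = c(5, 200))$freq,
                 error = function(e) 40)
  fit <- tryCatch(
    minpack.lm::nlsLM(ac ~ A * exp(-lam * lag_s) * cos(2 * pi * f * lag_s),
                      start = list(A = max(abs(ac)), lam = 30, f = f0),
                      lower = c(0, 0, 1), upper = c(2, 2000, 500),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(SI = NA_real_, oscillation_flag = FALSE,
                fitted_freq = NA_real_, decay_rate = NA_real_, fit = NULL))
  cf <- coef(fit)
  flag <- is.finite(cf["lam"]) && cf["lam"] <= decay_threshold &&
    cf["A"] >= min_amplitude
  list(SI = unname(cf["A"]), oscillation_flag = unname(flag),
       fitted_freq = unname(cf["f"]), decay_rate = unname(cf["lam"]),
       fit = fit)
}

#' Membrane-potential synchrony
#'
#' `chi^2 = Var_t(Vbar(t)) / mean_i(Var_t(V_i))` where `Vbar` is the
#' population-averaged voltage trace; `chi = 1` for identical traces and
#' `chi ~ 1/sqrt(N)` for independent ones.
#'
#' @param V Voltage traces: a time x neuron matrix (as recorded in
#'   `sim$traces$V`).
#' @return `chi` (scalar in `[0, 1]` up to finite-sample fluctuation).
#' @export
membrane_synchrony <- function(V) {
  V <- as.matrix(V)
  if (ncol(V) < 2) stop("membrane_synchrony needs at least two neurons")
  v_i <- apply(V, 2, var)
  if (any(v_i == 0)) stop("a trace has zero variance")
  sqrt(var(rowMeans(V)) / mean(v_i))
}

#' Excitation/inhibition balance
#'
#' Ratio between the average excitatory and inhibitory synaptic currents:
#' the currents are first averaged over the recorded neurons at each time
#' point, the ratio of their magnitudes is formed, and that ratio is averaged
#' over time. Values below 1 indicate an inhibition-dominated regime.
#'
#' @param sim A `sim_result` with recorded traces, or a list with `I_exc`,
#'   `I_inh` (time x neuron matrices, pA).
#' @param from_ms Discard this initial interval (ms); defaults to the
#'   simulation burn-in.
#' @param include_drive Count the external-drive current as part of the
#'   excitatory current (default TRUE; the drive enters the same synaptic
#'   current term as recurrent excitation, and the balance of an
#'   interneuron-only network is only defined drive-inclusive).
#'   `FALSE` restricts `I_exc` to recurrent excitation, the quantity that
#'   expresses inhibition dominance of the recurrent loop.
#' @return The scalar balance ratio `< |<I_exc>_N| / |<I_inh>_N| >_t`.
#' @export
network_balance <- function(sim, from_ms = NULL, include_drive = TRUE) {
  if (inherits(sim, "sim_result")) {
    if (is.null(sim$traces)) stop("no recorded currents; rerun with record=")
    ie <- sim$traces$I_exc
    if (include_drive && !is.null(sim$traces$I_drive))
      ie <- ie + sim$traces$I_drive
    ii <- sim$traces$I_inh
    if (is.null(from_ms)) from_ms <- sim$meta$burn_in
    keep <- seq_len(nrow(ie)) * sim$meta$dt > from_ms
    ie <- ie[keep, , drop = FALSE]
    ii <- ii[keep, , drop = FALSE]
  } else {
    ie <- as.matrix(sim$I_exc)
    ii <- as.matrix(sim$I_inh)
  }
  me <- rowMeans(ie)
  mi <- rowMeans(ii)
  if (all(mi == 0)) stop("inhibitory current is identically zero")
  ok <- mi != 0
  mean(abs(me[ok]) / abs(mi[ok]))
}

#' Parameter sweep over synaptic constants
#'
#' Runs short scaled simulations over a grid of either synaptic time
#' constants `(tau_E, tau_I)` (with synaptic gains renormalized as
#' `Q = Q_ref * tau_ref / tau` so the charge per spike is conserved) or, for
#' the inhibitory-only GAMMA architecture, `(p_connect, Q_I)`. For each grid
#' point it reports the mean single-neuron rate, the synchrony index with its
#' oscillation flag and fitted frequency, the E/I balance, and the membrane
#' synchrony of a recorded subset.
#'
#' @param network `"AI"` (tau sweep; PING-like points live in this plane) or
#'   `"GAMMA"` (p/Q sweep).
#' @param grid Data frame with columns `tau_E`, `tau_I` (ms) or `p`, `Q_I`
#'   (probability, nS).
#' @param scale Network scale factor for the sweep runs.
#' @param duration,dt Simulation settings (ms).
#' @param mu Per-train drive rate (Hz); defaults to the architecture's gamma
#'   value.
#' @param n_record Neurons recorded per population for balance / chi.
#' @param seed Seed.
#' @return A data frame: the grid columns plus `mean_rate_Hz`, `SI`,
#'   `oscillation`, `freq_Hz`, `balance`, `chi`.
#' @export
parameter_sweep <- function(network = c("AI", "GAMMA"), grid, scale = 0.1,
                            duration = 2000, dt = 0.1, mu = NULL,
                            n_record = 50, seed = 1) {
  network <- match.arg(network)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    spec <- build_network(network, seed = seed + g)
    if (network == "AI") {
      tau_e <- grid$tau_E[g]
      tau_i <- grid$tau_I[g]
      # synaptic gain normalization relative to the 5 ms reference constants
      spec$synapses$Q <- ifelse(spec$synapses$source == "FS",
                                5 * 5 / tau_i, 1 * 5 / tau_e)
      spec$tau_E <- tau_e
      spec$tau_I <- tau_i
    } else {
      spec$synapses$p_connect <- grid$p[g]
      spec$synapses$Q <- grid$Q_I[g]
    }
    spec <- scale_network(spec, scale)
    sim <- simulate_network(spec, "gamma", duration = duration, dt = dt,
                            seed = seed + g,
                            profile = if (is.null(mu)) NULL else rate_constant(mu),
                            record = record_per_population(n_record))
    analysis_s <- (duration - sim$meta$burn_in) / 1000
    mean_rate <- nrow(sim$spikes[sim$spikes$time > sim$meta$burn_in, ]) /
      (sim$meta$n_neurons * analysis_s)
    si <- synchrony_index(sim)
    keep <- seq_len(round(duration / dt)) * dt > sim$meta$burn_in
    chi <- membrane_synchrony(sim$traces$V[keep, , drop = FALSE])
    bal <- tryCatch(network_balance(sim), error = function(e) NA_real_)
    cbind(grid[g, , drop = FALSE],
          data.frame(mean_rate_Hz = mean_rate, SI = si$SI,
                     oscillation = si$oscillation_flag,
                     freq_Hz = si$fitted_freq, balance = bal, chi = chi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
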