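#' Simulate a network
#'
#' Runs a spiking simulation of a [build_network()] architecture: per-neuron
#' Adex dynamics (forward Euler at `dt`), exact exponential conductance decay,
#' event-queue delivery of recurrent spikes after the synaptic delay, and a
#' shared-train external Poissonian drive sampled on the fly. Identical seeds
#' give identical spike rasters.
#'
#' @param spec A `network_spec` (possibly passed through [scale_network()]).
#' @param state `"gamma"` or `"ai"`: selects the published per-train drive
#'   rate for the architecture (`spec$mu_gamma` / `spec$mu_ai`). Ignored when
#'   `profile` is supplied.
#' @param duration Simulated time (ms), including `burn_in`.
#' @param dt Integration step (ms); reference 0.1. The 1.5 ms synaptic delay
#'   must be an integer multiple of `dt`.
#' @param seed Master seed; initial conditions, wiring, drive and stimulus
#'   each use a derived sub-stream.
#' @param profile Optional [rate_profiles] object overriding the state's
#'   constant drive rate.
#' @param stim_profile Optional second rate profile whose events are drawn
#'   from an independent random stream and added on top of the drive
#'   (Poisson superposition). Because the baseline stream is untouched, a run
#'   with and a run without `stim_profile` are exactly paired.
#' @param i_ext Optional injected current: a function of time (ms) returning
#'   nA, applied to every neuron (used by the oscillatory-current control).
#' @param record Integer vector of neuron ids whose `V`, `g_E`, `g_I` and
#'   synaptic currents are recorded every step, or a count `n` to record the
#'   first `n` neurons of each population.
#' @param burn_in Initial interval (ms) flagged in the result so analyses can
#'   discard the startup transient; default 1000 (the slow adaptation current,
#'   `tau_w` = 500 ms, needs on the order of a second to equilibrate).
#' @param net Optional pre-realized wiring from [realize_network()], shared
#'   across repeated runs (paired protocols keep the network fixed while the
#'   drive varies); default: realized from `seed`.
#' @param init `"uniform"` (V uniform in `[E_L, V_th)`) or `"rest"` (V =
#'   `E_L`, useful for deterministic contracts).
#' @param conductance_decay `"exact"` or `"euler"`.
#' @return An object of class `sim_result`: list with `spikes` (data frame
#'   `neuron`, `time` ms), `neuron_pop`, `is_inh`, `offsets`, `traces`
#'   (recorded step-by-step matrices `V`, `g_E`, `g_I`, `g_ext`, `I_exc`,
#'   `I_inh`, `I_drive`, or NULL; recurrent and external-drive excitation are
#'   tracked separately though they act identically on the membrane),
#'   `record` ids, and `meta` (durations, dt, seeds, network name, state).
#' @examples
#' \donttest{
#' spec <- scale_network(build_network("PING"), 0.05)
#' sim <- simulate_network(spec, "gamma", duration = 1000, seed = 1)
#' head(sim$spikes)
#' }
#' @export
simulate_network <- function(spec, state = c("gamma", "ai"), duration = 3000,
                             dt = 0.1, seed = 1, profile = NULL,
                             stim_profile = NULL, i_ext = NULL,
                             record = integer(), burn_in = 1000,
                             init = c("uniform", "rest"),
                             conductance_decay = c("exact", "euler"),
                             net = NULL) {
  state <- match.arg(state)
  init <- match.arg(init)
  conductance_decay <- match.arg(conductance_decay)
  stopifnot(inherits(spec, "network_spec"), duration > 0, dt > 0)
  delay <- unique(spec$synapses$delay)
  stopifnot(length(delay) == 1)
  delay_steps <- delay / dt
  if (abs(delay_steps - round(delay_steps)) > 1e-9)
    stop(sprintf("synaptic delay (%g ms) is not an integer multiple of dt (%g ms)",
                 delay, dt))
  delay_steps <- as.integer(round(delay_steps))
  n_steps <- as.integer(round(duration / dt))

  # The realized wiring can be supplied (and thereby shared across paired or
  # repeated runs); by default it is sampled from the master seed.
  if (is.null(net)) net <- realize_network(spec, seed = seed)
  n <- length(net$neuron_pop)

  # Cell-type parameter matrix (rows: unique types present).
  types <- unique(net$neuron_type)
  par_list <- lapply(types, function(ty) network_cell_params(ty, spec$threshold))
  par <- do.call(rbind, lapply(par_list, function(p)
    c(p$C, p$g_L, p$E_L, p$V_th, p$delta, p$T_ref, p$tau_w, p$a, p$b,
      p$V_rest, p$E_E, p$E_I, p$v_cut)))
  type_idx <- match(net$neuron_type, types) - 1L

  syn_ptr <- net$csr$ptr
  syn_tgt <- net$csr$tgt
  syn_q <- net$csr$q

  # Drive rate per step (per-train Hz).
  if (is.null(profile))
    profile <- rate_constant(if (state == "gamma") spec$mu_gamma else spec$mu_ai)
  t_grid <- (seq_len(n_steps) - 1L) * dt
  drive_rate <- eval_rate_profile(profile, t_grid) * net$drive_wiring$rate_factor
  stim_rate <- if (is.null(stim_profile)) numeric() else
    eval_rate_profile(stim_profile, t_grid) * net$drive_wiring$rate_factor
  i_ext_vec <- if (is.null(i_ext)) numeric() else i_ext(t_grid) * 1e3  # nA -> pA

  record <- resolve_record(record, spec, net)
  v_init <- if (init == "rest") par[cbind(type_idx + 1L, 3L)] else numeric()

  res <- cpp_simulate_network(
    type_idx, par, net$is_inh,
    rep(spec$tau_E, n), rep(spec$tau_I, n),
    syn_ptr, syn_tgt, syn_q, delay_steps,
    as.integer(net$drive_wiring$train_ptr), as.integer(net$drive_wiring$train_tgt),
    net$q_ext, drive_rate, stim_rate, i_ext_vec,
    dt, n_steps,
    derive_seed(seed, "init"), derive_seed(seed, "drive"), derive_seed(seed, "stim"),
    as.integer(record - 1L), conductance_decay == "exact", v_init)

  structure(list(
    spikes = data.frame(neuron = res$neuron, time = res$time),
    neuron_pop = net$neuron_pop, is_inh = net$is_inh, offsets = net$offsets,
    traces = res$traces, record = record,
    meta = list(network = spec$name, state = state, duration = duration,
                dt = dt, burn_in = burn_in, seed = seed, scale = spec$scale,
                n_neurons = n)),
    class = "sim_result")
}

resolve_record <- function(record, spec, net) {
  if (length(record) == 1 && isTRUE(attr(record, "per_pop"))) {
    k <- as.integer(record)
    record <- unlist(lapply(seq_len(nrow(spec$populations)), function(i) {
      off <- net$offsets[[spec$populations$name[i]]]
      off + seq_len(min(k, spec$populations$size[i]))
    }))
  }
  as.integer(record)
}

#' Record the first k neurons of each population
#'
#' Helper for the `record` argument of [simulate_network()].
#' @param k Count per population.
#' @return A tagged scalar understood by [simulate_network()].
#' @export
record_per_population <- function(k) structure(as.integer(k), per_pop = TRUE)

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %s (%s state), %d neurons, %g ms, %d spikes>\n",
              x$meta$network, x$meta$state, x$meta$n_neurons, x$meta$duration,
              nrow(x$spikes)))
  invisible(x)
}

#' Population firing rate
#'
#' Total spike count per time bin divided by the bin duration: the
#' instantaneous population rate in spikes/s.
#'
#' @param sim A `sim_result`, or a data frame with `neuron` and `time` (ms).
#' @param bin Bin width (ms); reference 1 ms.
#' @param population Optional population name (e.g. `"RS"`) to restrict to.
#' @param from,to Analysis window (ms); defaults to `[burn_in, duration]` for
#'   a `sim_result`.
#' @return A list: `time` (bin centers, ms), `rate` (spikes/s), `bin` (ms).
#' @export
population_rate <- function(sim, bin = 1, population = NULL, from = NULL,
                            to = NULL) {
  if (inherits(sim, "sim_result")) {
    spikes <- sim$spikes
    if (!is.null(population)) {
      keep <- sim$neuron_pop[spikes$neuron] == population
      spikes <- spikes[keep, , drop = FALSE]
    }
    if (is.null(from)) from <- sim$meta$burn_in
    if (is.null(to)) to <- sim$meta$duration
  } else {
    spikes <- sim
    if (is.null(from)) from <- 0
    if (is.null(to)) to <- max(spikes$time, 0)
  }
  edges <- seq(from, to, by = bin)
  if (length(edges) < 2) stop("analysis window shorter than one bin")
  sel <- spikes$time > from & spikes$time <= to
  counts <- tabulate(findInterval(spikes$time[sel], edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  list(time = edges[-length(edges)] + bin / 2, rate = counts / (bin * 1e-3),
       bin = bin)
}

#' Spectral peak of a signal (Welch estimate)
#'
#' Frequency of the maximum of the Welch-averaged power spectrum inside a
#' band: the signal is split into Hann-tapered segments with 50% overlap and
#' the segment periodograms are averaged. Network rhythms in the
#' fluctuation-driven regime have broad, noisy spectra; segment averaging is
#' the standard way to obtain a stable peak estimate for them.
#'
#' @param x Signal values on a uniform grid.
#' @param fs Sampling rate (Hz).
#' @param band Search band (Hz), default 20-100 (the gamma range plus margin).
#' @param segment Segment length in samples (default 1024, i.e. ~1 Hz
#'   resolution at 1 kHz); shortened automatically for short signals.
#' @param spans Optional extra smoothing (moving-average width in bins)
#'   applied to the averaged spectrum; default 3.
#' @return A list: `freq` (Hz, peak), `power` (at the peak), `spectrum`
#'   (data frame `freq`, `power` within the band).
#' @export
spectral_peak <- function(x, fs, band = c(20, 100), segment = 1024,
                          spans = 3) {
  stopifnot(length(x) > 64, band[1] < band[2])
  x <- x - mean(x)
  n <- length(x)
  segment <- min(segment, n)
  step <- max(1, floor(segment / 2))
  starts <- seq(1, n - segment + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))  # Hann
  pow <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1)] * win
    pow <- pow + Mod(fft(seg))^2
  }
  pow <- pow / length(starts)
  freq <- (seq_len(segment) - 1) * fs / segment
  if (spans > 1) {
    k <- rep(1 / spans, spans)
    pow <- as.numeric(stats::filter(pow, k, sides = 2))
  }
  keep <- which(freq >= band[1] & freq <= band[2] & !is.na(pow))
  if (!length(keep)) stop("no spectral estimate inside the requested band")
  i <- keep[which.max(pow[keep])]
  list(freq = freq[i], power = pow[i],
       spectrum = data.frame(freq = freq[keep], power = pow[keep]))
}

#' Dominant network oscillation frequency
#'
#' Convenience wrapper: population rate at 1 ms bins, then [spectral_peak()].
#'
#' @param sim A `sim_result`.
#' @param band Search band (Hz).
#' @param population Optional population restriction.
#' @return Peak frequency (Hz).
#' @export
network_frequency <- function(sim, band = c(20, 100), population = NULL) {
  pr <- population_rate(sim, bin = 1, population = population)
  spectral_peak(pr$rate, fs = 1000 / pr$bin, band = band)$freq
}

#' Export spikes as a two-column CSV
#'
#' @param sim A `sim_result` or spike data frame.
#' @param path Output CSV path (`neuron_id`, `time_ms`). A companion
#'   `<path>.populations.csv` with the population table is written for a
#'   `sim_result`.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(sim, path) {
  spikes <- if (inherits(sim, "sim_result")) sim$spikes else sim
  write.csv(data.frame(neuron_id = spikes$neuron, time_ms = spikes$time),
            path, row.names = FALSE)
  if (inherits(sim, "sim_result")) {
    pops <- data.frame(neuron_id = seq_along(sim$neuron_pop),
                       population = sim$neuron_pop, is_inh = sim$is_inh)
    write.csv(pops, paste0(path, ".populations.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read spikes from a two-column CSV
#'
#' Accepts `neuron_id`/`time_ms` (as written by [write_spikes_csv()]) or
#' `neuron`/`time` headers, from any source (including real recordings).
#'
#' @param path CSV path.
#' @return Data frame with `neuron` and `time` (ms).
#' @export
read_spikes_csv <- function(path) {
  df <- read.csv(path)
  nm <- names(df)
  neuron <- df[[if ("neuron_id" %in% nm) "neuron_id" else "neuron"]]
  time <- df[[if ("time_ms" %in% nm) "time_ms" else "time"]]
  data.frame(neuron = neuron, time = time)
}
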