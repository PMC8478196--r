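#' Responsiveness arithmetic
#'
#' The responsiveness of a network to a stimulus over a window of duration
#' `T` is the stimulus-evoked excess spike count normalized by window length
#' and network size: `R = (N_spikes_S - N_spikes) / (T * N_n)`, in
#' spikes/s/neuron.
#'
#' @param n_spikes_stim Total spikes in the window with the stimulus.
#' @param n_spikes_base Total spikes in the window without the stimulus.
#' @param T_s Window duration (s).
#' @param n_neurons Number of neurons the count is normalized by.
#' @return `R` (spikes/s/neuron).
#' @examples
#' responsiveness_value(1500, 1000, T_s = 0.5, n_neurons = 25000)  # 0.04
#' @export
responsiveness_value <- function(n_spikes_stim, n_spikes_base, T_s, n_neurons) {
  if (T_s <= 0) stop("window duration must be positive")
  (n_spikes_stim - n_spikes_base) / (T_s * n_neurons)
}

# Drive profile inducing a gamma burst: ramp from the AI-like rate to the
# gamma rate, plateau covering the analysis window.
gamma_induction_profile <- function(spec, t_on, ramp = 100, t_off = Inf) {
  rate_ramp_plateau(spec$mu_ai, spec$mu_gamma, t_on = t_on, ramp = ramp,
                    t_off = t_off)
}

#' Responsiveness to slowly-varying (integration-mode) stimuli
#'
#' Measures, for a grid of Gaussian stimulus amplitudes, the network
#' responsiveness `R` (see [responsiveness_value()]) in a `T`-long window,
#' separately for the excitatory and inhibitory populations, as the mean +/-
#' SEM over repetitions of paired runs. Pairing is exact: the baseline and
#' stimulated run of a repetition share wiring, initial conditions and the
#' baseline drive realization; the stimulus adds an independent Poisson
#' stream (superposition), so with amplitude 0 the two runs are identical.
#'
#' States: `"gamma"` drives the network with a stereotyped fluctuation (ramp
#' from the AI-like to the gamma drive rate, 100 ms ramp, plateau covering
#' the window) so the stimulus lands inside induced gamma activity;
#' `"ai_like"` keeps the drive at the architecture's AI-like rate;
#' `"ai_control"` is meant for the AI architecture (constant 3 Hz drive, no
#' oscillation at any drive level).
#'
#' @param spec A `network_spec` (typically scaled for desk runs).
#' @param state `"gamma"`, `"ai_like"` or `"ai_control"`.
#' @param amplitudes Gaussian stimulus amplitudes (Hz, per-train); reference
#'   grid 0.05-2.5 Hz in 0.05 steps.
#' @param stim_sd Stimulus standard deviation (ms); reference 50.
#' @param window_T Window duration (ms); reference 500.
#' @param n_rep Repetitions per amplitude.
#' @param seed Master seed. Wiring is fixed across repetitions; drive and
#'   stimulus streams vary by repetition.
#' @param dt Integration step (ms).
#' @return A data frame of class `responsiveness_result`: `amplitude`,
#'   `population` (`exc`/`inh`), `R` (mean), `sem`, `n_rep`, `state`.
#' @export
responsiveness_curve <- function(spec, state = c("gamma", "ai_like", "ai_control"),
                                 amplitudes = c(0.5, 1, 2), stim_sd = 50,
                                 window_T = 500, n_rep = 20, seed = 1,
                                 dt = 0.1) {
  state <- match.arg(state)
  if (window_T <= 0) stop("window_T must be positive")
  burn_in <- 600                  # settle the slow adaptation current
  t_on <- burn_in + 100           # gamma induction ramp start
  win0 <- t_on + 200              # window opens after the rhythm settles
  win1 <- win0 + window_T
  duration <- win1 + 50
  stim_center <- (win0 + win1) / 2
  profile <- switch(state,
    gamma = gamma_induction_profile(spec, t_on = t_on),
    ai_like = rate_constant(spec$mu_ai),
    ai_control = rate_constant(3))
  net <- realize_network(spec, seed = derive_seed(seed, "protocol-wiring"))
  n_exc <- sum(!net$is_inh)
  n_inh <- sum(net$is_inh)
  T_s <- window_T / 1000

  count_window <- function(sim) {
    sel <- sim$spikes$time > win0 & sim$spikes$time <= win1
    inh <- sim$is_inh[sim$spikes$neuron[sel]]
    c(exc = sum(!inh), inh = sum(inh))
  }

  rows <- lapply(amplitudes, function(A) {
    R_exc <- numeric(n_rep)
    R_inh <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      seed_r <- derive_seed(seed, paste0("rep", r))
      base <- simulate_network(spec, duration = duration, dt = dt,
                               seed = seed_r, profile = profile,
                               burn_in = burn_in, net = net)
      stim <- simulate_network(spec, duration = duration, dt = dt,
                               seed = seed_r, profile = profile,
                               stim_profile = rate_gaussian_bump(
                                 0, A, center = stim_center, sd = stim_sd),
                               burn_in = burn_in, net = net)
      nb <- count_window(base)
      ns <- count_window(stim)
      R_exc[r] <- responsiveness_value(ns["exc"], nb["exc"], T_s, n_exc)
      R_inh[r] <- if (n_inh > 0)
        responsiveness_value(ns["inh"], nb["inh"], T_s, n_inh) else NA_real_
    }
    data.frame(amplitude = A,
               population = c("exc", "inh"),
               R = c(mean(R_exc), mean(R_inh)),
               sem = c(sd(R_exc), sd(R_inh)) / sqrt(n_rep),
               n_rep = n_rep, state = state)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("responsiveness_result", "data.frame")
  out
}

#' Phase-dependent (coincidence-detection-mode) responsiveness
#'
#' Applies a precisely-timed Gaussian stimulus (reference: 50 Hz amplitude,
#' 1 ms SD -- much shorter than a gamma cycle) at a grid of times, reads the
#' oscillation phase at each stimulus time, and measures the responsiveness
#' in a one-gamma-cycle window centered on the stimulus, binned by phase.
#'
#' Three states are supported: during `"gamma"` the phase is read from the
#' band-filtered LFP of the paired baseline run and stimuli falling outside
#' detected gamma bursts are discarded (and counted); during `"ai_like"` the
#' phase is read from the (weak, non-rhythmic) filtered LFP, which yields a
#' flat profile; `"ai_current"` adds a sinusoidal injected current (0 to
#' `i_max` nA at `f_gamma`) and reads the phase of that current, which
#' yields a genuinely phase-modulated response. When `normalize = TRUE`
#' (default) all `R` values are divided by the mean `ai_like` response, so
#' the function runs `ai_like` alongside the requested states.
#'
#' @param spec A `network_spec`.
#' @param states Subset of `c("gamma", "ai_like", "ai_current")`.
#' @param window_T Response window (ms): one gamma cycle (25 ms for
#'   PING/CHING, 18 ms for ING).
#' @param f_gamma Control-current frequency (Hz): 40 for PING/CHING, 55 for
#'   ING.
#' @param stim_amplitude,stim_sd Gaussian stimulus (Hz per train, ms).
#' @param n_positions Number of stimulus times (tiling ~3 gamma cycles).
#' @param n_seeds Drive seeds per position set.
#' @param n_bins Phase bins over `(-pi, pi]`.
#' @param i_max Peak of the control current (nA).
#' @param seed,dt As elsewhere.
#' @param normalize Normalize by the mean `ai_like` response.
#' @return A data frame of class `phase_response`: `state`, `theta` (bin
#'   center), `R` (mean, normalized if requested), `sem`, `n`; attribute
#'   `n_discarded` counts gamma-state stimuli without a resolved phase, and
#'   attribute `ai_mean` holds the normalization constant (spikes/s/neuron).
#' @export
phase_dependent_responsiveness <- function(spec,
                                           states = c("gamma", "ai_like", "ai_current"),
                                           window_T = 25, f_gamma = 40,
                                           stim_amplitude = 50, stim_sd = 1,
                                           n_positions = 40, n_seeds = 10,
                                           n_bins = 12, i_max = 0.1,
                                           seed = 1, dt = 0.1,
                                           normalize = TRUE) {
  states <- match.arg(states, several.ok = TRUE)
  run_states <- if (normalize) union(states, "ai_like") else states
  burn_in <- 600
  t_on <- burn_in + 100
  stim_win0 <- t_on + 200
  span <- 3 * 1000 / f_gamma            # stimulus times tile ~3 cycles
  duration <- stim_win0 + span + window_T + 60
  positions <- stim_win0 + (seq_len(n_positions) - 0.5) / n_positions * span
  net <- realize_network(spec, seed = derive_seed(seed, "protocol-wiring"))
  n_n <- length(net$is_inh)
  T_s <- window_T / 1000
  fspec <- filter_spec()
  geom <- place_neurons(n_n, seed = derive_seed(seed, "geom"))

  wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi
  results <- list()
  n_discarded <- 0L

  for (st in run_states) {
    profile <- if (st == "gamma") gamma_induction_profile(spec, t_on = t_on)
               else rate_constant(spec$mu_ai)
    i_fun <- if (st == "ai_current")
      function(t) i_max / 2 * (1 + sin(2 * pi * f_gamma * t / 1000)) else NULL
    theta <- c()
    Rv <- c()
    for (s in seq_len(n_seeds)) {
      seed_s <- derive_seed(seed, paste0(st, "-", s))
      base <- simulate_network(spec, duration = duration, dt = dt,
                               seed = seed_s, profile = profile, i_ext = i_fun,
                               burn_in = burn_in, net = net)
      if (st == "ai_current") {
        ph_at <- function(tm) wrap_pi(2 * pi * f_gamma * tm / 1000 - pi / 2)
        burst_ok <- function(tm) TRUE
      } else {
        lfp <- compute_lfp(base, geom)
        ps <- analytic_signal(bandpass_fir(lfp, fspec), fs = lfp$fs)
        ph_at <- function(tm) ps$phase[pmin(pmax(round(tm * ps$fs / 1000) + 1, 1),
                                            length(ps$phase))]
        if (st == "gamma") {
          bursts <- detect_bursts(ps, k_sd = 1, spec = fspec)
          burst_ok <- function(tm) nrow(bursts) > 0 &&
            any(tm >= bursts$start & tm <= bursts$end)
        } else burst_ok <- function(tm) TRUE
      }
      base_counts <- vapply(positions, function(tp)
        sum(base$spikes$time > tp - window_T / 2 &
            base$spikes$time <= tp + window_T / 2), 1)
      for (j in seq_along(positions)) {
        tp <- positions[j]
        if (!burst_ok(tp)) { n_discarded <- n_discarded + 1L; next }
        stim <- simulate_network(spec, duration = duration, dt = dt,
                                 seed = seed_s, profile = profile,
                                 i_ext = i_fun,
                                 stim_profile = rate_gaussian_bump(
                                   0, stim_amplitude, center = tp, sd = stim_sd),
                                 burn_in = burn_in, net = net)
        ns <- sum(stim$spikes$time > tp - window_T / 2 &
                  stim$spikes$time <= tp + window_T / 2)
        theta <- c(theta, ph_at(tp))
        Rv <- c(Rv, responsiveness_value(ns, base_counts[j], T_s, n_n))
      }
    }
    results[[st]] <- data.frame(state = st, theta = theta, R = Rv)
  }

  ai_mean <- if ("ai_like" %in% names(results))
    mean(results[["ai_like"]]$R) else NA_real_
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  out <- do.call(rbind, lapply(results[intersect(run_states, states)], function(df) {
    bin <- cut(df$theta, edges, include.lowest = TRUE, labels = FALSE)
    agg <- lapply(seq_len(n_bins), function(b) {
      v <- df$R[bin == b]
      if (normalize && is.finite(ai_mean) && ai_mean != 0) v <- v / ai_mean
      data.frame(state = df$state[1],
                 theta = (edges[b] + edges[b + 1]) / 2,
                 R = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v))
    })
    do.call(rbind, agg)
  }))
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_discarded
  attr(out, "ai_mean") <- ai_mean
  class(out) <- c("phase_response", "data.frame")
  out
}

#' Resonance map: response to sinusoidally modulated drive
#'
#' Drives the network with Poissonian input whose per-train rate oscillates
#' as `mu_noise + delta_noise * sin(2 pi f t)` for each frequency on a grid,
#' accumulates the spikes of the target cell type per oscillation-phase bin
#' (the cycle is split into `n_phase_bins` equal intervals; the phase of time
#' `t` is the sine argument wrapped to `(-pi, pi]`), averages per neuron and
#' per time bin, and normalizes the whole map by its grand mean (so the map
#' mean is exactly 1 and state-dependent rate levels drop out).
#'
#' @param spec A `network_spec`.
#' @param state `"gamma"` or `"ai"`; selects `mu_noise` (the architecture's
#'   published per-state drive rate) unless `mu_noise` is given.
#' @param freqs Modulation frequencies (Hz); reference 5-100 by 5.
#' @param delta_noise Modulation amplitude (Hz); reference 0.5.
#' @param mu_noise Baseline drive rate (Hz); default the state's rate.
#' @param n_phase_bins Phase bins (reference 25).
#' @param cell_type Population whose spikes are accumulated (default RS; the
#'   GAMMA architecture falls back to FS).
#' @param duration Simulated time per frequency (ms), including burn-in.
#' @param seed,dt As elsewhere.
#' @return An object of class `resonance_map`: list with `matrix`
#'   (frequency x phase-bin, grand mean 1), `raw` (mean spikes per neuron per
#'   time bin), `freqs`, `theta` (bin centers), `state`, `mu_noise`,
#'   `delta_noise`.
#' @export
resonance_map <- function(spec, state = c("gamma", "ai"), freqs = seq(10, 80, 10),
                          delta_noise = 0.5, mu_noise = NULL,
                          n_phase_bins = 25, cell_type = NULL,
                          duration = 2200, seed = 1, dt = 0.1) {
  state <- match.arg(state)
  if (is.null(mu_noise))
    mu_noise <- if (state == "gamma") spec$mu_gamma else spec$mu_ai
  if (mu_noise - delta_noise < 0)
    warning("mu_noise - delta_noise < 0: drive rate clipped at 0")
  if (is.null(cell_type))
    cell_type <- if ("RS" %in% spec$populations$name) "RS"
                 else spec$populations$name[1]
  burn_in <- 600
  net <- realize_network(spec, seed = derive_seed(seed, "protocol-wiring"))
  n_cells <- spec$populations$size[spec$populations$name == cell_type]
  edges <- seq(-pi, pi, length.out = n_phase_bins + 1)
  wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi
  analysis_s <- (duration - burn_in) / 1000

  raw <- matrix(NA_real_, length(freqs), n_phase_bins,
                dimnames = list(paste0(freqs, "Hz"), NULL))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sim <- simulate_network(spec, duration = duration, dt = dt,
                            seed = derive_seed(seed, paste0("res", f)),
                            profile = rate_sinusoid(mu_noise, delta_noise, f),
                            burn_in = burn_in, net = net)
    sel <- sim$spikes$time > burn_in &
      sim$neuron_pop[sim$spikes$neuron] == cell_type
    th <- wrap_pi(2 * pi * f * sim$spikes$time[sel] / 1000)
    counts <- tabulate(cut(th, edges, include.lowest = TRUE, labels = FALSE),
                       nbins = n_phase_bins)
    # number of time bins of each phase over the analysis window: f*D per bin
    n_time_bins <- f * analysis_s
    raw[i, ] <- counts / (n_cells * n_time_bins)
  }
  gm <- mean(raw)
  structure(list(matrix = if (gm > 0) raw / gm else raw, raw = raw,
                 freqs = freqs, theta = (edges[-1] + edges[-length(edges)]) / 2,
                 state = state, mu_noise = mu_noise,
                 delta_noise = delta_noise, cell_type = cell_type),
            class = "resonance_map")
}

#' @export
print.resonance_map <- function(x, ...) {
  cat(sprintf("<resonance_map: %s state, %s cells, %d freqs x %d phase bins>\n",
              x$state, x$cell_type, length(x$freqs), ncol(x$matrix)))
  depth <- apply(x$matrix, 1, function(r) max(r) - min(r))
  cat("modulation depth by frequency:\n")
  print(round(setNames(depth, rownames(x$matrix)), 3))
  invisible(x)
}

#' Row-wise modulation depth of a resonance map
#'
#' `max - min` of the normalized phase profile at each drive frequency; the
#' resonance peak is the frequency maximizing it.
#'
#' @param map A [resonance_map()].
#' @return Named numeric vector (one value per frequency).
#' @export
resonance_depth <- function(map) {
  setNames(apply(map$matrix, 1, function(r) max(r) - min(r)), map$freqs)
}
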