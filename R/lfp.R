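#' Spatiotemporal LFP kernel parameters
#'
#' Each spike contributes a Gaussian pulse to the LFP whose amplitude decays
#' exponentially with the neuron-electrode distance and whose peak is delayed
#' by a constant plus the axonal propagation time:
#' `K(x, t) = A0 exp(-|x - x_p| / lambda) * exp(-(t - t_peak)^2 / (2 sigma^2))`
#' with `t_peak = t0 + d + |x - x_p| / v_a`. Excitatory and inhibitory
#' contributions use separate parameter sets ([lfp_kernel_excitatory()],
#' [lfp_kernel_inhibitory()]).
#'
#' The numeric defaults are synthetic: they are on the scale reported for
#' measured unitary LFPs (sub-microvolt amplitudes, ~0.2 mm spatial decay,
#' millisecond-scale width, ~10 ms synaptic/measurement delay, 0.2 mm/ms
#' axonal speed), with the inhibitory amplitude larger than and of opposite
#' sign to the excitatory one, but they are configuration entries, not fitted
#' constants. All burst-detection logic downstream thresholds the envelope in
#' SD units and is insensitive to their exact values.
#'
#' @param A0 Maximal amplitude at zero distance (uV; sign encodes polarity).
#' @param lambda Spatial decay constant (mm).
#' @param sigma Temporal standard deviation (ms).
#' @param d Constant delay (ms).
#' @param v_a Axonal speed (mm/ms).
#' @return An object of class `kernel_params`.
#' @export
lfp_kernel_params <- function(A0, lambda = 0.2, sigma = 1.5, d = 10.4,
                              v_a = 0.2) {
  stopifnot(lambda > 0, sigma > 0, v_a > 0)
  structure(list(A0 = A0, lambda = lambda, sigma = sigma, d = d, v_a = v_a),
            class = "kernel_params")
}

#' @rdname lfp_kernel_params
#' @export
lfp_kernel_excitatory <- function() lfp_kernel_params(A0 = -0.16, sigma = 1.5)

#' @rdname lfp_kernel_params
#' @export
lfp_kernel_inhibitory <- function() lfp_kernel_params(A0 = 0.48, sigma = 1.2)

#' Place neurons in a square arena
#'
#' Uniform random 2-D positions inside a square, with the recording electrode
#' at its center. The simulated networks have no intrinsic geometry; this is
#' the random displacement used to give every neuron a distance to the
#' electrode. The default arena side (0.4 mm) matches the spatial scale of a
#' multielectrode grid spacing; it is arbitrary and configurable.
#'
#' @param n Number of neurons.
#' @param arena_side Side of the square (mm).
#' @param seed Seed.
#' @return An object of class `lfp_geometry`: list with `positions`
#'   (n x 2 matrix, mm), `electrode` (length-2, mm), `arena_side`.
#' @export
place_neurons <- function(n, arena_side = 0.4, seed = 1) {
  stopifnot(n > 0)
  if (arena_side <= 0) stop("arena_side must be positive")
  set.seed(derive_seed(seed, "geometry"))
  pos <- cbind(runif(n, 0, arena_side), runif(n, 0, arena_side))
  structure(list(positions = pos,
                 electrode = c(arena_side / 2, arena_side / 2),
                 arena_side = arena_side),
            class = "lfp_geometry")
}

#' Synthesize the LFP from spike trains
#'
#' Sums, over all neurons and spikes, the spatiotemporal kernel contributions
#' (see [lfp_kernel_params()]): the LFP is a linear superposition of one
#' distance-attenuated, distance-delayed Gaussian pulse per spike, with the
#' excitatory or inhibitory kernel chosen by the neuron's class.
#'
#' @param sim A `sim_result`, or a list with `spikes` (data frame `neuron`,
#'   `time`) and `is_inh` (logical per neuron).
#' @param geometry An [place_neurons()] geometry covering every spiking
#'   neuron.
#' @param kE,kI Excitatory / inhibitory [lfp_kernel_params()].
#' @param dt_out Output sampling step (ms); default 1 ms (1 kHz), the typical
#'   LFP processing rate.
#' @param duration Output duration (ms); defaults to the simulation duration
#'   or the last spike time plus a margin.
#' @return A list of class `lfp_trace`: `time` (ms), `lfp` (uV), `fs` (Hz).
#' @export
compute_lfp <- function(sim, geometry, kE = lfp_kernel_excitatory(),
                        kI = lfp_kernel_inhibitory(), dt_out = 1,
                        duration = NULL) {
  spikes <- sim$spikes
  is_inh <- sim$is_inh
  if (is.null(spikes) || is.null(is_inh)) stop("sim must carry spikes and is_inh")
  if (is.null(duration))
    duration <- if (!is.null(sim$meta$duration)) sim$meta$duration
                else if (nrow(spikes)) max(spikes$time) + 50 else 100
  n_out <- as.integer(floor(duration / dt_out)) + 1L
  tt <- (seq_len(n_out) - 1L) * dt_out
  if (nrow(spikes) == 0)
    return(structure(list(time = tt, lfp = numeric(n_out), fs = 1000 / dt_out),
                     class = "lfp_trace"))
  if (max(spikes$neuron) > nrow(geometry$positions))
    stop("geometry does not cover every spiking neuron")
  dist <- sqrt(rowSums((geometry$positions -
                          matrix(geometry$electrode, nrow(geometry$positions),
                                 2, byrow = TRUE))^2))
  lfp <- numeric(n_out)
  for (class_inh in c(FALSE, TRUE)) {
    k <- if (class_inh) kI else kE
    sel <- is_inh[spikes$neuron] == class_inh
    if (!any(sel)) next
    d_s <- dist[spikes$neuron[sel]]
    amp <- k$A0 * exp(-d_s / k$lambda)
    t_peak <- spikes$time[sel] + k$d + d_s / k$v_a
    lfp <- lfp + cpp_kernel_lfp(spikes$time[sel], amp, t_peak, k$sigma,
                                dt_out, n_out)
  }
  structure(list(time = tt, lfp = lfp, fs = 1000 / dt_out), class = "lfp_trace")
}

#' Write / read an LFP trace as a two-column CSV
#'
#' Columns `time_ms`, `lfp_uV`.
#' @param lfp An `lfp_trace` (or list with `time`, `lfp`).
#' @param path CSV path.
#' @return `path` (write) or an `lfp_trace` (read).
#' @export
write_lfp_csv <- function(lfp, path) {
  write.csv(data.frame(time_ms = lfp$time, lfp_uV = lfp$lfp), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_ms", "lfp_uV") %in% names(df)))
  dt <- median(diff(df$time_ms))
  structure(list(time = df$time_ms, lfp = df$lfp_uV, fs = 1000 / dt),
            class = "lfp_trace")
}
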