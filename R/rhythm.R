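#' Band-pass filter specification
#'
#' Kaiser-window FIR band-pass design: the filter order and window shape are
#' chosen from the required stop-band attenuation and transition width, the
#' same design rule as the `kaiserord`/`firwin` pair of scipy.
#'
#' @param band Pass band `[low, high]` (Hz); default 30-50, the gamma band
#'   used throughout.
#' @param attenuation Stop-band attenuation (dB); default 60.
#' @param transition Transition width from pass to stop (Hz); default 5.
#' @param fs Sampling rate (Hz); default 1000.
#' @return An object of class `filter_spec` with the designed coefficients
#'   (`coef`), the group delay in samples (`group_delay`), and the reference
#'   frequency `f_ref` (band center) used by the 3-cycle burst rule.
#' @export
filter_spec <- function(band = c(30, 50), attenuation = 60, transition = 5,
                        fs = 1000) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] + transition >= fs / 2)
    stop("band (plus transition width) exceeds the Nyquist frequency")
  dev <- 10^(-attenuation / 20)
  ko <- signal::kaiserord(c(band[1] - transition, band[1],
                            band[2], band[2] + transition),
                          c(0, 1, 0), dev = rep(dev, 3), Fs = fs)
  n <- ko$n
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length, integer group delay
  h <- signal::fir1(n, band / (fs / 2), type = "pass",
                    window = signal::kaiser(n + 1, ko$beta), scale = FALSE)
  structure(list(band = band, attenuation = attenuation,
                 transition = transition, fs = fs, coef = as.numeric(h),
                 group_delay = n / 2, f_ref = mean(band)),
            class = "filter_spec")
}

#' Band-pass an LFP with a Kaiser-window FIR filter
#'
#' Filters causally (direct-form FIR, as `lfilter` would) and, by default,
#' compensates the constant FIR group delay by shifting the output back by
#' `(order)/2` samples so filtered samples are aligned with the input clock --
#' required for spike-phase assignment. The last `group_delay` samples are
#' zero-padded continuations; edge intervals of about one filter length are
#' unreliable, as with any FIR.
#'
#' @param lfp An `lfp_trace`, or a numeric vector.
#' @param spec A [filter_spec()]; its `fs` must match the trace.
#' @param zero_phase Compensate the group delay (default TRUE). `FALSE` gives
#'   the raw causal output for parity experiments.
#' @return Numeric vector, same length as the input.
#' @export
bandpass_fir <- function(lfp, spec = filter_spec(), zero_phase = TRUE) {
  x <- if (inherits(lfp, "lfp_trace")) lfp$lfp else as.numeric(lfp)
  if (inherits(lfp, "lfp_trace") && abs(lfp$fs - spec$fs) > 1e-6)
    stop(sprintf("filter designed for fs = %g Hz but trace is %g Hz",
                 spec$fs, lfp$fs))
  if (length(x) <= length(spec$coef))
    stop("signal shorter than the filter; use a longer segment")
  gd <- spec$group_delay
  if (zero_phase) {
    y <- as.numeric(signal::filter(spec$coef, 1, c(x, numeric(gd))))
    y[(gd + 1):length(y)]
  } else {
    as.numeric(signal::filter(spec$coef, 1, x))
  }
}

#' Analytic signal: envelope and instantaneous phase
#'
#' Computes the analytic signal by the FFT construction (positive frequencies
#' doubled, negative zeroed), then returns the envelope (modulus) and the
#' instantaneous phase (argument, in `(-pi, pi]`). For a pure tone
#' `A cos(2 pi f t)` the envelope is `A` and the phase advances at
#' `2 pi f` rad/s, so phase 0 marks the oscillation peak; spikes at negative
#' phases occur earlier in the cycle than spikes at positive phases.
#'
#' @param filtered Band-passed signal (numeric), or an `lfp_trace`.
#' @param fs Sampling rate (Hz); taken from the trace if available.
#' @return An object of class `phase_series`: list with `envelope`, `phase`,
#'   `fs`, `time` (ms).
#' @export
analytic_signal <- function(filtered, fs = 1000) {
  if (inherits(filtered, "lfp_trace")) {
    fs <- filtered$fs
    filtered <- filtered$lfp
  }
  x <- as.numeric(filtered)
  if (!all(is.finite(x))) stop("non-finite input signal")
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  structure(list(envelope = Mod(z), phase = Arg(z), fs = fs,
                 time = (seq_len(n) - 1) * 1000 / fs),
            class = "phase_series")
}

#' Detect gamma bursts from the envelope
#'
#' A burst is a maximal contiguous interval where the envelope exceeds its
#' global mean by at least `k_sd` standard deviations (mean and SD taken over
#' the analyzed segment), kept only if it lasts at least 3 cycles of the
#' band's reference frequency (the band center: 75 ms for the 30-50 Hz band).
#' Burst boundaries are the threshold crossings themselves (the strict
#' reading); `extend_to_mean = TRUE` optionally widens each burst to where
#' the envelope falls back to its mean. Thresholding in SD units makes
#' detection invariant to any positive rescaling of the LFP.
#'
#' @param ps A [analytic_signal()] phase series.
#' @param k_sd SD multiplier; reference values: 1 for simulated signals, 2
#'   for recorded data.
#' @param spec The [filter_spec()] that produced the band (supplies `f_ref`).
#' @param min_cycles Minimum duration in reference cycles (default 3).
#' @param electrode_id Identifier copied into the result.
#' @param extend_to_mean Widen bursts down to the envelope mean.
#' @return A data frame of class `gamma_bursts`: `electrode_id`, `start`,
#'   `end` (ms), `n_cycles`; non-overlapping and sorted.
#' @export
detect_bursts <- function(ps, k_sd = 1, spec = filter_spec(), min_cycles = 3,
                          electrode_id = 1L, extend_to_mean = FALSE) {
  stopifnot(inherits(ps, "phase_series"), k_sd > 0)
  env <- ps$envelope
  f_ref <- spec$f_ref
  min_dur <- min_cycles * 1000 / f_ref  # ms
  empty <- data.frame(electrode_id = integer(), start = numeric(),
                      end = numeric(), n_cycles = numeric())
  class(empty) <- c("gamma_bursts", "data.frame")
  if (length(env) * 1000 / ps$fs < min_dur) return(empty)
  thr <- mean(env) + k_sd * sd(env)
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s_idx <- starts[keep]
  e_idx <- ends[keep]
  if (extend_to_mean) {
    m <- mean(env)
    below <- env <= m
    for (b in seq_along(s_idx)) {
      while (s_idx[b] > 1 && !below[s_idx[b] - 1]) s_idx[b] <- s_idx[b] - 1L
      while (e_idx[b] < length(env) && !below[e_idx[b] + 1]) e_idx[b] <- e_idx[b] + 1L
    }
    # merge overlaps created by extension
    if (length(s_idx) > 1) {
      keep2 <- c(TRUE, s_idx[-1] > e_idx[-length(e_idx)])
      grp <- cumsum(keep2)
      s_idx <- tapply(s_idx, grp, min)
      e_idx <- tapply(e_idx, grp, max)
    }
  }
  start <- ps$time[s_idx]
  end <- ps$time[e_idx]
  dur <- end - start
  ok <- dur >= min_dur
  out <- data.frame(electrode_id = rep(electrode_id, sum(ok)),
                    start = start[ok], end = end[ok],
                    n_cycles = dur[ok] * f_ref / 1000)
  class(out) <- c("gamma_bursts", "data.frame")
  out
}

#' Assign gamma phases to spikes inside bursts
#'
#' For each neuron, returns the instantaneous oscillation phase at each of
#' its spikes that falls inside a detected burst of its own electrode.
#' Spikes outside bursts are never assigned a phase; spikes outside the
#' recorded interval are excluded and counted in a warning.
#'
#' @param spikes A `sim_result` or a data frame `neuron`, `time` (ms).
#' @param ps The [analytic_signal()] phase series (same clock as the LFP).
#' @param bursts A [detect_bursts()] result.
#' @param electrode Map from neuron id to electrode id; default: all neurons
#'   on electrode 1 (the single simulated electrode).
#' @return A data frame `neuron`, `time`, `phase` (radians in `(-pi, pi]`),
#'   `electrode_id`, with attribute `n_excluded` (spikes outside the recorded
#'   interval).
#' @export
spike_phases <- function(spikes, ps, bursts, electrode = NULL) {
  df <- if (inherits(spikes, "sim_result")) spikes$spikes else spikes
  stopifnot(inherits(ps, "phase_series"))
  t0 <- ps$time[1]
  t1 <- ps$time[length(ps$time)]
  inside_rec <- df$time >= t0 & df$time <= t1
  n_excluded <- sum(!inside_rec)
  if (n_excluded > 0)
    warning(sprintf("%d spike(s) outside the recorded interval excluded",
                    n_excluded))
  df <- df[inside_rec, , drop = FALSE]
  elec <- if (is.null(electrode)) rep(1L, nrow(df)) else electrode[df$neuron]
  in_burst <- rep(FALSE, nrow(df))
  for (b in seq_len(nrow(bursts))) {
    hit <- elec == bursts$electrode_id[b] &
      df$time >= bursts$start[b] & df$time <= bursts$end[b]
    in_burst <- in_burst | hit
  }
  df <- df[in_burst, , drop = FALSE]
  idx <- pmin(pmax(round((df$time - t0) * ps$fs / 1000) + 1, 1),
              length(ps$phase))
  out <- data.frame(neuron = df$neuron, time = df$time,
                    phase = ps$phase[idx],
                    electrode_id = if (nrow(df)) (if (is.null(electrode)) 1L
                                                  else electrode[df$neuron])
                                   else integer())
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write / read detected bursts as CSV
#'
#' Columns `electrode_id`, `start_ms`, `end_ms`.
#' @param bursts A [detect_bursts()] result.
#' @param path CSV path.
#' @return `path` (write) or a `gamma_bursts` data frame (read).
#' @export
write_bursts_csv <- function(bursts, path) {
  write.csv(data.frame(electrode_id = bursts$electrode_id,
                       start_ms = bursts$start, end_ms = bursts$end),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts_csv
#' @export
read_bursts_csv <- function(path) {
  df <- read.csv(path)
  out <- data.frame(electrode_id = df$electrode_id, start = df$start_ms,
                    end = df$end_ms,
                    n_cycles = (df$end_ms - df$start_ms) * 40 / 1000)
  class(out) <- c("gamma_bursts", "data.frame")
  out
}
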