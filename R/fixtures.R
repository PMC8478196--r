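#' Synthetic fixture specification
#'
#' Describes a synthetic data set emulating the structure of a multielectrode
#' unit recording: `K` data segments, each containing a known total amount of
#' gamma activity, a cohort of neurons with per-neuron ground-truth
#' phase-locking (von Mises concentration `kappa`, preferred phase `mu`) and
#' firing rates inside/outside gamma bursts. The statistics modules must
#' recover these labels; the generator is the package's calibration
#' instrument, not a stand-in for real recordings.
#'
#' @param n_neurons Cohort size.
#' @param K Number of segments.
#' @param segment_s Segment duration (s).
#' @param gamma_s Total gamma-burst time per segment (s); reference layout:
#'   13 s of gamma per segment, 5 segments.
#' @param kappa Per-neuron von Mises concentration inside bursts (scalar or
#'   length `n_neurons`); 0 = uniform phases.
#' @param mu Per-neuron preferred phase (radians).
#' @param f_out Firing rate outside bursts (Hz; scalar or per neuron).
#' @param f_gamma Firing rate inside bursts (Hz).
#' @param carrier_hz Gamma carrier frequency of the synthetic LFP.
#' @param burst_len_s Duration of each embedded burst (s).
#' @param fs LFP sampling rate (Hz).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_neurons = 50, K = 5, segment_s = 60, gamma_s = 13,
                         kappa = 2, mu = 0, f_out = 2, f_gamma = 4,
                         carrier_hz = 40, burst_len_s = 0.5, fs = 1000) {
  stopifnot(n_neurons >= 0, K >= 1, segment_s > 0, gamma_s >= 0,
            gamma_s < segment_s, all(kappa >= 0), all(f_out >= 0),
            all(f_gamma >= 0))
  if (any(f_gamma > 0) && gamma_s == 0)
    stop("in-burst firing requested but the segments contain no gamma time")
  rep_n <- function(x) if (length(x) == 1) rep(x, n_neurons) else
    { stopifnot(length(x) == n_neurons); x }
  structure(list(n_neurons = n_neurons, K = K, segment_s = segment_s,
                 gamma_s = gamma_s, kappa = rep_n(kappa), mu = rep_n(mu),
                 f_out = rep_n(f_out), f_gamma = rep_n(f_gamma),
                 carrier_hz = carrier_hz, burst_len_s = burst_len_s, fs = fs),
            class = "fixture_spec")
}

#' Generate a synthetic spike + LFP fixture
#'
#' Builds, per segment, a synthetic LFP (white noise plus an
#' amplitude-modulated gamma-band carrier confined to known burst intervals)
#' and per-neuron spike trains: Poisson at `f_out` outside bursts and, inside
#' bursts, `f_gamma`-rate spikes whose carrier phases are drawn from the
#' neuron's von Mises law (`kappa = 0` gives uniform phases). Returns the
#' ground truth alongside, so the detection and statistics chain can be
#' calibrated end to end.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed.
#' @param dir Optional directory: writes `segment<k>_spikes.csv`,
#'   `segment<k>_lfp.csv` and `truth.csv`.
#' @return A list of class `fixture`: `segments` (list of lists with
#'   `spikes` data frame, `lfp` trace, `bursts_true` data frame), `truth`
#'   (per-neuron data frame with `kappa`, `mu`, `f_out`, `f_gamma`), `spec`.
#' @export
generate_fixture <- function(spec, seed = 1, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(derive_seed(seed, "fixture"))
  fs <- spec$fs
  seg_ms <- spec$segment_s * 1000
  n_samp <- round(spec$segment_s * fs)
  n_bursts <- if (spec$gamma_s > 0)
    max(1L, round(spec$gamma_s / spec$burst_len_s)) else 0L
  burst_ms <- if (n_bursts > 0) spec$gamma_s * 1000 / n_bursts else 0

  segments <- vector("list", spec$K)
  for (k in seq_len(spec$K)) {
    # non-overlapping burst intervals with guard gaps
    if (n_bursts > 0) {
      slot <- seg_ms / n_bursts
      if (burst_ms > 0.8 * slot)
        stop("requested gamma time too dense for the segment layout")
      start <- (seq_len(n_bursts) - 1) * slot +
        runif(n_bursts, 0.05 * slot, slot - burst_ms - 0.05 * slot)
      bursts <- data.frame(electrode_id = 1L, start = start,
                           end = start + burst_ms)
    } else {
      bursts <- data.frame(electrode_id = integer(), start = numeric(),
                           end = numeric())
    }
    tt <- (seq_len(n_samp) - 1) / fs * 1000  # ms
    carrier_amp <- numeric(n_samp)
    for (b in seq_len(nrow(bursts)))
      carrier_amp[tt >= bursts$start[b] & tt <= bursts$end[b]] <- 1
    phase_t <- 2 * pi * spec$carrier_hz * tt / 1000
    lfp_sig <- carrier_amp * cos(phase_t) * 5 + rnorm(n_samp, sd = 1)
    lfp <- structure(list(time = tt, lfp = lfp_sig, fs = fs),
                     class = "lfp_trace")

    spikes <- list()
    for (i in seq_len(spec$n_neurons)) {
      # outside-burst spikes: homogeneous Poisson on the complement
      t_out_ms <- seg_ms - sum(bursts$end - bursts$start)
      n_out <- rpois(1, spec$f_out[i] * t_out_ms / 1000)
      out_times <- if (n_out > 0) sample_outside(n_out, seg_ms, bursts) else numeric()
      # inside-burst spikes: von Mises phases mapped onto carrier cycles
      in_times <- numeric()
      if (n_bursts > 0 && spec$f_gamma[i] > 0) {
        for (b in seq_len(nrow(bursts))) {
          n_in <- rpois(1, spec$f_gamma[i] * burst_ms / 1000)
          if (n_in == 0) next
          ph <- rvonmises(n_in, spec$mu[i], spec$kappa[i])
          # time with carrier phase ph: cycles fully inside the burst
          cyc_ms <- 1000 / spec$carrier_hz
          n_cyc <- floor((bursts$end[b] - bursts$start[b]) / cyc_ms) - 1
          if (n_cyc < 1) next
          cyc0 <- ceiling(bursts$start[b] / cyc_ms) + 1
          cyc <- cyc0 + sample.int(n_cyc, n_in, replace = TRUE) - 1
          in_times <- c(in_times, (cyc + ph / (2 * pi)) * cyc_ms)
        }
      }
      times <- sort(c(out_times, in_times))
      if (length(times))
        spikes[[length(spikes) + 1]] <- data.frame(neuron = i, time = times)
    }
    spikes <- if (length(spikes)) do.call(rbind, spikes)
              else data.frame(neuron = integer(), time = numeric())
    segments[[k]] <- list(spikes = spikes, lfp = lfp, bursts_true = bursts)
  }

  truth <- data.frame(neuron_id = seq_len(spec$n_neurons), kappa = spec$kappa,
                      mu = spec$mu, f_out = spec$f_out,
                      f_gamma = spec$f_gamma)
  fx <- structure(list(segments = segments, truth = truth, spec = spec),
                  class = "fixture")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(spec$K)) {
      write_spikes_csv(segments[[k]]$spikes,
                       file.path(dir, sprintf("segment%d_spikes.csv", k)))
      write_lfp_csv(segments[[k]]$lfp,
                    file.path(dir, sprintf("segment%d_lfp.csv", k)))
    }
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  fx
}

# Uniform times on the complement of the burst intervals.
sample_outside <- function(n, seg_ms, bursts) {
  if (nrow(bursts) == 0) return(runif(n, 0, seg_ms))
  gaps_start <- c(0, bursts$end)
  gaps_end <- c(bursts$start, seg_ms)
  len <- pmax(gaps_end - gaps_start, 0)
  g <- sample.int(length(len), n, replace = TRUE, prob = len)
  gaps_start[g] + runif(n) * len[g]
}

#' Draw von Mises samples
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform.
#'
#' @param n Sample count.
#' @param mu Location (radians).
#' @param kappa Concentration (>= 0).
#' @return Phases in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-9) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k_ok <- sum(ok)
    if (k_ok > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1):(got + k_ok)] <- theta
      got <- got + k_ok
    }
  }
  (((out + mu) + pi) %% (2 * pi)) - pi
}
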