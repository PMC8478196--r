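# Band-pass filtering, analytic signal, burst detection, spike-phase
# assignment.

tone <- function(freq, amp = 1, dur_ms = 4000, fs = 1000, phase0 = 0) {
  t <- seq(0, dur_ms / 1000, by = 1 / fs)
  amp * cos(2 * pi * freq * t + phase0)
}

test_that("the Kaiser FIR passes the gamma band and rejects outside it", {
  fspec <- filter_spec()
  mid <- 1000:3000
  y40 <- bandpass_fir(tone(40), fspec)
  expect_equal(max(abs(y40[mid])), 1, tolerance = 0.02)
  y10 <- bandpass_fir(tone(10), fspec)
  expect_lt(max(abs(y10[mid])), 10^(-60 / 20) * 2)  # >= 60 dB down
  ydc <- bandpass_fir(rep(1, 3000), fspec)
  expect_lt(max(abs(ydc[1000:2500])), 1e-3)
  expect_error(filter_spec(band = c(30, 600), fs = 1000), "Nyquist")
  expect_error(bandpass_fir(rep(0, 10), fspec), "shorter")
})

test_that("group-delay compensation aligns the filtered tone with the input", {
  fspec <- filter_spec()
  x <- tone(40)
  y <- bandpass_fir(x, fspec)
  mid <- 1500:2500
  lagfit <- which.max(sapply(-5:5, function(l)
    cor(x[mid], y[mid + l]))) - 6
  expect_equal(lagfit, 0)
  # causal mode lags the zero-phase output by exactly the group delay
  # (checked on noise, whose autocorrelation is not periodic)
  set.seed(3)
  xn <- rnorm(4000)
  y0 <- bandpass_fir(xn, fspec)
  yc <- bandpass_fir(xn, fspec, zero_phase = FALSE)
  gd <- fspec$group_delay
  lags <- seq(gd - 30, gd + 30)
  cc <- sapply(lags, function(l) cor(y0[1000:2500], yc[1000:2500 + l]))
  expect_equal(lags[which.max(cc)], gd)
})

test_that("the analytic signal recovers envelope and phase of a tone", {
  x <- tone(40, amp = 2.5)
  ps <- analytic_signal(x, fs = 1000)
  mid <- 500:3500
  expect_equal(median(ps$envelope[mid]), 2.5, tolerance = 0.01)
  expect_true(all(abs(ps$phase) <= pi + 1e-12))
  # phase advances at 2 pi f: slope of unwrapped phase within 1%
  dphi <- diff(ps$phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  f_est <- mean(dphi) * 1000 / (2 * pi)
  expect_equal(f_est, 40, tolerance = 0.01 * 40)
  # wraps once per 25 ms
  wraps <- sum(diff(ps$phase[1001:2000]) < -pi)
  expect_equal(wraps, 40, tolerance = 1)
  expect_equal(analytic_signal(rep(0, 100))$envelope, rep(0, 100))
  expect_error(analytic_signal(c(1, NA, 3)), "finite")
})

test_that("filter + analytic pipeline recovers an in-band frequency within 1%", {
  x <- tone(44) + rnorm(4001, sd = 0.3)
  ps <- analytic_signal(bandpass_fir(x, filter_spec()), fs = 1000)
  mid <- 1000:3000
  dphi <- diff(ps$phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi) * 1000 / (2 * pi), 44, tolerance = 0.01 * 44)
})

test_that("burst detection applies the SD threshold and 3-cycle rule", {
  # constant envelope: nothing exceeds the mean -> no bursts
  ps_flat <- manual_phase_series(rep(3, 2000))
  expect_equal(nrow(detect_bursts(ps_flat)), 0)

  # an embedded strong 40 Hz tone of 5 cycles (125 ms) in weak noise
  set.seed(7)
  noise <- rnorm(4001, sd = 0.2)
  sig <- noise
  on <- 2000:2125
  sig[on] <- sig[on] + 5 * 0.2 * cos(2 * pi * 40 * (on / 1000))
  ps <- analytic_signal(bandpass_fir(sig, filter_spec()), fs = 1000)
  b <- detect_bursts(ps, k_sd = 1)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$start - 2000), 40)
  expect_lt(abs(b$end - 2125), 40)
  expect_gte(b$n_cycles, 3)

  # the 3-cycle floor, on an exactly controlled envelope: a 60 ms
  # suprathreshold excursion is rejected, a 100 ms one kept (f_ref = 40 Hz
  # -> floor at 75 ms)
  env <- rep(1, 3000)
  env[1000:1059] <- 10
  expect_equal(nrow(detect_bursts(manual_phase_series(env), k_sd = 1)), 0)
  env[1000:1099] <- 10
  expect_equal(nrow(detect_bursts(manual_phase_series(env), k_sd = 1)), 1)

  # positive rescaling leaves the bursts unchanged (SD-unit thresholds)
  ps_scaled <- analytic_signal(bandpass_fir(sig * 37.3, filter_spec()),
                               fs = 1000)
  b_scaled <- detect_bursts(ps_scaled, k_sd = 1)
  expect_equal(b_scaled$start, b$start)
  expect_equal(b_scaled$end, b$end)

  # segment shorter than 3 cycles -> empty
  expect_equal(nrow(detect_bursts(manual_phase_series(rnorm(50)))), 0)
})

test_that("bursts are sorted and non-overlapping", {
  set.seed(11)
  sig <- rnorm(8001, sd = 0.2)
  for (s in c(1200, 3000, 5200)) {
    on <- s:(s + 150)
    sig[on] <- sig[on] + 1.5 * cos(2 * pi * 40 * on / 1000)
  }
  ps <- analytic_signal(bandpass_fir(sig, filter_spec()), fs = 1000)
  b <- detect_bursts(ps, k_sd = 1)
  expect_gte(nrow(b), 2)
  expect_true(all(diff(b$start) > 0))
  expect_true(all(b$start[-1] > b$end[-nrow(b)]))
})

test_that("spike phases are assigned only inside bursts, on the shared clock", {
  # pure tone everywhere above threshold except the edges
  x <- c(rep(0, 500), tone(40, amp = 1, dur_ms = 1000), rep(0, 500))
  ps <- analytic_signal(x, fs = 1000)
  bursts <- detect_bursts(ps, k_sd = 0.5)
  expect_gte(nrow(bursts), 1)
  # spikes at tone peaks (phase 0): t = 500 + k * 25 ms
  peak_times <- 500 + seq(100, 900, by = 25)
  spk <- data.frame(neuron = 1L, time = peak_times)
  ph <- spike_phases(spk, ps, bursts)
  expect_gt(nrow(ph), 20)
  expect_true(all(abs(ph$phase) < 0.3))
  # spikes outside bursts are never assigned phases
  spk_out <- data.frame(neuron = 2L, time = c(100, 200, 1900))
  expect_equal(nrow(spike_phases(spk_out, ps, bursts)), 0)
  # spikes outside the recorded interval are excluded with a warning
  spk_far <- data.frame(neuron = 3L, time = c(750, 5000))
  expect_warning(ph3 <- spike_phases(spk_far, ps, bursts), "excluded")
  expect_equal(attr(ph3, "n_excluded"), 1L)
})
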