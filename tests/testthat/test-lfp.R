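# Kernel-based LFP synthesis: closed-form single-spike pulses, linearity,
# geometry statistics.

test_that("neuron placement is uniform in the arena, electrode centered", {
  g1 <- place_neurons(1, arena_side = 0.4, seed = 3)
  d <- sqrt(sum((g1$positions[1, ] - g1$electrode)^2))
  expect_lte(d, 0.4 * sqrt(2) / 2)
  expect_identical(place_neurons(5, seed = 9)$positions,
                   place_neurons(5, seed = 9)$positions)
  # mean distance to center of a unit square: (sqrt(2) + asinh(1)) / 6
  g <- place_neurons(20000, arena_side = 1, seed = 1)
  dd <- sqrt(rowSums((g$positions - 0.5)^2))
  analytic <- (sqrt(2) + log(1 + sqrt(2))) / 6
  expect_lt(abs(mean(dd) - analytic), 4 * sd(dd) / sqrt(20000))
  expect_error(place_neurons(3, arena_side = 0))
})

test_that("a single spike produces the closed-form kernel pulse", {
  kE <- lfp_kernel_excitatory()
  geom <- manual_geometry(matrix(c(0, 0), 1, 2))  # at the electrode
  s <- spike_set(1, 100, is_inh = FALSE)
  lfp <- compute_lfp(s, geom, dt_out = 0.5, duration = 200)
  i_peak <- which.max(abs(lfp$lfp))
  expect_equal(lfp$time[i_peak], 100 + kE$d, tolerance = 0.5)
  # grid sampling sits at most dt_out/2 from the true peak
  expect_equal(lfp$lfp[i_peak], kE$A0, tolerance = 0.005)

  # at distance lambda: amplitude A0/e, peak delayed by lambda / v_a
  geom2 <- manual_geometry(matrix(c(kE$lambda, 0), 1, 2))
  lfp2 <- compute_lfp(s, geom2, dt_out = 0.5, duration = 200)
  i2 <- which.max(abs(lfp2$lfp))
  expect_equal(lfp2$lfp[i2], kE$A0 / exp(1), tolerance = 0.005)
  expect_equal(lfp2$time[i2], 100 + kE$d + kE$lambda / kE$v_a, tolerance = 0.5)
})

test_that("the LFP is a linear superposition of spike contributions", {
  geom <- place_neurons(20, seed = 2)
  inh <- rep(c(FALSE, TRUE), 10)
  set.seed(1)
  t1 <- sort(runif(40, 0, 800))
  n1 <- sample(1:20, 40, replace = TRUE)
  t2 <- sort(runif(25, 0, 800))
  n2 <- sample(1:20, 25, replace = TRUE)
  la <- compute_lfp(spike_set(n1, t1, inh), geom, duration = 1000)
  lb <- compute_lfp(spike_set(n2, t2, inh), geom, duration = 1000)
  lab <- compute_lfp(spike_set(c(n1, n2), c(t1, t2), inh), geom,
                     duration = 1000)
  expect_equal(lab$lfp, la$lfp + lb$lfp, tolerance = 1e-12)
  # doubling a train doubles the trace
  l2 <- compute_lfp(spike_set(c(n1, n1), c(t1, t1), inh), geom,
                    duration = 1000)
  expect_equal(l2$lfp, 2 * la$lfp, tolerance = 1e-12)
  # empty input -> identically zero
  l0 <- compute_lfp(spike_set(integer(), numeric(), inh), geom,
                    duration = 500)
  expect_true(all(l0$lfp == 0))
})

test_that("time-shifting all spikes shifts the LFP", {
  geom <- place_neurons(5, seed = 4)
  inh <- rep(FALSE, 5)
  base <- compute_lfp(spike_set(1:5, c(100, 150, 200, 250, 300), inh), geom,
                      dt_out = 1, duration = 1000)
  shft <- compute_lfp(spike_set(1:5, c(100, 150, 200, 250, 300) + 50, inh),
                      geom, dt_out = 1, duration = 1000)
  expect_equal(shft$lfp[61:900], base$lfp[11:850], tolerance = 1e-12)
})

test_that("peak contribution decreases strictly with distance", {
  kE <- lfp_kernel_excitatory()
  peaks <- vapply(seq(0, 0.5, by = 0.05), function(d) {
    geom <- manual_geometry(matrix(c(d, 0), 1, 2))
    max(abs(compute_lfp(spike_set(1, 50, FALSE), geom, dt_out = 0.5,
                        duration = 150)$lfp))
  }, 1)
  expect_true(all(diff(peaks) < 0))
})

test_that("LFP traces round-trip through CSV and fail without geometry", {
  geom <- place_neurons(3, seed = 1)
  lfp <- compute_lfp(spike_set(1:3, c(50, 60, 70), rep(FALSE, 3)), geom,
                     duration = 300)
  path <- tempfile(fileext = ".csv")
  write_lfp_csv(lfp, path)
  back <- read_lfp_csv(path)
  expect_equal(back$lfp, lfp$lfp)
  expect_equal(back$fs, lfp$fs)
  expect_error(compute_lfp(spike_set(1:5, rep(10, 5), rep(FALSE, 5)),
                           place_neurons(2, seed = 1), duration = 100),
               "geometry")
})
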