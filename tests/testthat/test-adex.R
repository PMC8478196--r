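# Single-neuron Adex dynamics: fixed points, adaptation, refractory/reset
# contracts, and integration accuracy.

test_that("presets reproduce the published cell constants and invariants", {
  rs <- adex_params("RS")
  fs <- adex_params("FS")
  ch <- adex_params("Ch")
  expect_equal(rs$V_th, -40)
  expect_equal(rs$b, 20)
  expect_equal(rs$delta, 2)
  expect_equal(fs$a, 0)
  expect_equal(fs$b, 0)
  expect_equal(ch$a, 80)
  expect_equal(ch$E_L, -58)
  expect_equal(ch$T_ref, 1)
  for (p in list(rs, fs, ch)) {
    expect_true(p$delta > 0 && p$C > 0 && p$g_L > 0 && p$tau_w > 0)
    expect_true(p$E_I < p$E_L && p$E_L < p$E_E)
  }
  # shifted network reading: exponential threshold -50, detection at the
  # printed value, for every cell type
  for (ty in c("RS", "FS", "Ch")) {
    ps <- network_cell_params(ty, "shifted")
    expect_equal(ps$V_th, -50)
    expect_equal(ps$v_cut, adex_params(ty)$V_th)
  }
  expect_identical(network_cell_params("FS2")$cell_type, "FS")
})

test_that("presets round-trip through the shipped parameter file", {
  presets <- read_cell_presets(system.file("extdata", "cell_presets.yaml",
                                           package = "gammanet"))
  for (ty in c("RS", "FS", "Ch"))
    for (f in c("V_th", "delta", "T_ref", "tau_w", "a", "b", "C", "g_L",
                "E_L", "E_E", "E_I", "V_rest"))
      expect_equal(presets[[ty]][[f]], adex_params(ty)[[f]],
                   label = paste(ty, f))
})

test_that("rest is a fixed point: no input, V stays at E_L, no spikes", {
  out <- simulate_single_neuron(adex_params("RS"), rep(0, 10000), dt = 0.1)
  expect_length(out$spike_times, 0)
  # the exponential term at E_L contributes ~1e-4 pA; drift stays < 0.01 mV
  expect_true(all(abs(out$V_trace - (-65)) < 0.01))
})

test_that("sub-rheobase current converges to the root-found equilibrium", {
  p <- adex_params("RS")
  I_pA <- 100  # 0.1 nA
  # stationary condition with w = a (V - E_L): independent root-find oracle
  f <- function(V) -p$g_L * (V - p$E_L) + p$g_L * p$delta *
    exp((V - p$V_th) / p$delta) + I_pA - p$a * (V - p$E_L)
  V_star <- uniroot(f, c(-65, -45), tol = 1e-10)$root
  out <- simulate_single_neuron(p, rep(0.1, 30000), dt = 0.1)
  expect_length(out$spike_times, 0)
  expect_lt(abs(tail(out$V_trace, 1) - V_star), 0.05)
})

test_that("RS adapts under the ramp-plateau drive; FS does not", {
  cur <- ramp_plateau_current(peak = 0.5, ramp_ms = 250, plateau_ms = 500)
  rs <- simulate_single_neuron(adex_params("RS"), cur)
  expect_gt(length(rs$spike_times), 5)
  plateau <- rs$spike_times[rs$spike_times > 300 & rs$spike_times < 750]
  isi <- diff(plateau)
  expect_gt(tail(isi, 1), head(isi, 1) * 1.2)  # inter-spike intervals lengthen

  fs <- simulate_single_neuron(adex_params("FS"), cur)
  plateau_fs <- fs$spike_times[fs$spike_times > 350 & fs$spike_times < 700]
  isi_fs <- diff(plateau_fs)
  expect_lt(sd(isi_fs) / mean(isi_fs), 0.02)   # tonic, non-adapting
  expect_gt(length(plateau_fs), length(plateau))
})

test_that("Ch cells fire with short refractoriness under constant drive", {
  ch <- simulate_single_neuron(adex_params("Ch"), rep(1, 10000))
  expect_gt(length(ch$spike_times), 5)
  isi <- diff(ch$spike_times)
  expect_gte(min(isi), 1)       # T_ref = 1 ms floor
  expect_lt(min(isi), 5)        # closer doublets than any RS/FS can produce
})

test_that("conductances decay exactly exponentially between events", {
  st <- neuron_state(V = -65, g_E = 10, g_I = 4)
  kin <- synapse_kinetics(tau_E = 3, tau_I = 8)
  out <- step_neuron(st, adex_params("RS"), kin, dt = 0.5)
  expect_equal(out$state$g_E, 10 * exp(-0.5 / 3), tolerance = 1e-12)
  expect_equal(out$state$g_I, 4 * exp(-0.5 / 8), tolerance = 1e-12)
  # forward-Euler option
  out2 <- step_neuron(st, adex_params("RS"), kin, dt = 0.5,
                      conductance_decay = "euler")
  expect_equal(out2$state$g_E, 10 * (1 - 0.5 / 3), tolerance = 1e-12)
})

test_that("refractory and reset contracts hold under strong drive", {
  p <- adex_params("RS")
  out <- simulate_single_neuron(p, rep(1.5, 20000), dt = 0.1)
  expect_gt(length(out$spike_times), 10)
  expect_true(all(diff(out$spike_times) >= p$T_ref))
  # V immediately after any spike equals V_rest exactly
  idx <- round(out$spike_times / 0.1)
  expect_true(all(out$V_trace[idx] == p$V_rest))
  # V and w held during refractoriness
  k <- idx[5]
  held <- out$V_trace[k:(k + round(p$T_ref / 0.1) - 1)]
  expect_true(all(held == p$V_rest))
})

test_that("halving dt changes the spike count by at most one", {
  p <- adex_params("RS")
  n1 <- length(simulate_single_neuron(p, rep(0.4, 10000), dt = 0.1)$spike_times)
  n2 <- length(simulate_single_neuron(p, rep(0.4, 20000), dt = 0.05)$spike_times)
  expect_lte(abs(n1 - n2), 1)
})

test_that("invalid inputs fail fast", {
  p <- adex_params("RS")
  expect_error(step_neuron(neuron_state(), p, synapse_kinetics(), dt = 0),
               "dt")
  st <- neuron_state()
  st$V <- NaN
  expect_error(step_neuron(st, p, synapse_kinetics()), "non-finite")
  expect_error(adex_params("RS", nonsense = 1), "unknown")
  out <- simulate_single_neuron(p, numeric())
  expect_length(out$spike_times, 0)
  expect_length(out$V_trace, 0)
})
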