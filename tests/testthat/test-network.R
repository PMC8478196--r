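# Network construction, scaling, drive generation, and engine contracts.

test_that("architectures carry the published populations and synapse groups", {
  ping <- build_network("PING")
  expect_equal(ping$populations$size, c(20000L, 5000L))
  expect_equal(ping$tau_I, 7.5)
  expect_equal(sort(unique(ping$synapses$Q)), c(3.34, 5))
  expect_true(all(ping$synapses$delay == 1.5))

  ing <- build_network("ING")
  expect_equal(ing$populations$size, c(20000L, 4000L, 1000L))
  expect_true(ing$populations$is_inh[ing$populations$name == "FS2"])
  fs2fs2 <- ing$synapses[ing$synapses$source == "FS2" & ing$synapses$target == "FS2", ]
  expect_equal(fs2fs2$p_connect, 0.6)
  expect_equal(ing$synapses$p_connect[ing$synapses$source == "FS" &
                                      ing$synapses$target == "FS2"], 0.03)

  ching <- build_network("CHING")
  expect_equal(ching$populations$size, c(19000L, 1000L, 5000L))
  q_fs_rs <- ching$synapses$Q[ching$synapses$source == "FS" &
                              ching$synapses$target == "RS"]
  q_fs_fs <- ching$synapses$Q[ching$synapses$source == "FS" &
                              ching$synapses$target == "FS"]
  expect_equal(q_fs_rs, 7)
  expect_equal(q_fs_fs, 5)
  expect_equal(unname(ching$drive$q_ext["FS"]), 0.75)

  expect_equal(build_network("GAMMA")$populations$size, 1000L)
  expect_error(build_network("NOPE"), "arg")
})

test_that("realized wiring matches binomial edge-count expectations", {
  spec <- build_network("GAMMA")
  net <- realize_network(spec, seed = 7)
  n_edges <- length(net$edges$src)
  mu <- 0.6 * 1000 * 999
  sigma <- sqrt(mu * 0.4)
  expect_lt(abs(n_edges - mu), 4 * sigma)
  # no autapses
  expect_false(any(net$edges$src == net$edges$tgt))
  # zero-probability group yields zero edges
  spec0 <- spec
  spec0$synapses$p_connect <- 0
  expect_length(realize_network(spec0, seed = 1)$edges$src, 0)
  # same seed -> identical graph
  net2 <- realize_network(spec, seed = 7)
  expect_identical(net$edges, net2$edges)
})

test_that("scaling preserves expected in-degrees, flooring dense sources", {
  spec <- build_network("PING")
  expect_identical(scale_network(spec, 1), spec)
  sc <- scale_network(spec, 0.2)
  expect_equal(sc$populations$size, c(4000L, 1000L))
  expect_equal(unique(sc$synapses$p_connect), 0.1)
  # expected in-degree from RS preserved: p * N_src
  expect_equal(sc$synapses$p_connect[1] * 4000,
               spec$synapses$p_connect[1] * 20000)
  # drive ensemble untouched: in-degree and correlation structure preserved
  expect_equal(sc$drive$n_ext, spec$drive$n_ext)
  expect_equal(sc$drive$p_connect, spec$drive$p_connect)

  # the 60%-connected population cannot shrink below factor 0.6
  expect_message(g2 <- scale_network(build_network("GAMMA"), 0.5), "held")
  expect_equal(g2$populations$size, 600L)
  expect_equal(g2$synapses$p_connect * 600, 0.6 * 1000)

  ing <- suppressMessages(scale_network(build_network("ING"), 0.2))
  expect_equal(ing$populations$size[ing$populations$name == "FS2"], 600L)
  fs2fs2 <- ing$synapses[ing$synapses$source == "FS2" &
                         ing$synapses$target == "FS2", ]
  expect_equal(fs2fs2$p_connect * 600, 600)  # in-degree 600 - 1 realized
  expect_error(scale_network(spec, 0))
})

test_that("scaled in-degrees match the full network (realized graph)", {
  sc <- suppressMessages(scale_network(build_network("ING"), 0.2))
  net <- realize_network(sc, seed = 3)
  # FS2 in-degree from FS2: expected size-1 at p = 1
  fs2_ids <- which(net$neuron_pop == "FS2")
  sel <- net$edges$src %in% fs2_ids & net$edges$tgt %in% fs2_ids
  indeg <- tabulate(net$edges$tgt[sel] - min(fs2_ids) + 1L, nbins = 600)
  expect_true(all(indeg == 599))
})

test_that("drive generation follows the Poisson law and profile semantics", {
  d <- drive_spec(n_ext = 200, p_connect = 0.1, q_ext = 1)
  # zero rate -> no events
  out0 <- generate_drive(d, rate_constant(0), n_neurons = 50, duration = 500)
  expect_equal(nrow(out0$events), 0)
  # constant profile: train-spike count within 4 sigma of Poisson
  out <- generate_drive(d, rate_constant(10), n_neurons = 50,
                        duration = 2000, seed = 5)
  lam <- 200 * 10 * 2
  expect_lt(abs(out$n_train_spikes - lam), 4 * sqrt(lam))
  # gaussian bump: per-train rate peaks at mu + amplitude at the center
  prof <- rate_gaussian_bump(2, 2, center = 500, sd = 50)
  expect_equal(eval_rate_profile(prof, 500), 4)
  expect_lt(eval_rate_profile(prof, 900), 2.01)
  # rates clipped at zero
  prof2 <- rate_sinusoid(0.2, 1, 10)
  expect_true(all(eval_rate_profile(prof2, seq(0, 1000, 0.5)) >= 0))
  expect_error(rate_constant(-1))
})

test_that("simulation is empty without input and deterministic with it", {
  spec <- chain_spec()
  sim <- simulate_network(spec, duration = 300, seed = 1, init = "rest",
                          burn_in = 0)
  expect_equal(nrow(sim$spikes), 0)

  tiny <- tiny_network("PING", 0.04)
  s1 <- simulate_network(tiny, "gamma", duration = 600, seed = 42, burn_in = 0)
  s2 <- simulate_network(tiny, "gamma", duration = 600, seed = 42, burn_in = 0)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- simulate_network(tiny, "gamma", duration = 600, seed = 43, burn_in = 0)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("delivered events arrive exactly one synaptic delay after the spike", {
  spec <- chain_spec(Q = 5, delay = 1.5)
  sim <- simulate_network(spec, duration = 400, seed = 1, init = "rest",
                          burn_in = 0, record = 1:2,
                          i_ext = function(t) ifelse(t > 50, 0.6, 0))
  src_spikes <- sim$spikes$time[sim$spikes$neuron == 1]
  expect_gt(length(src_spikes), 3)
  gE <- sim$traces$g_E[, 2]
  # trace row r holds the state at time r*dt; an arrival joining at the start
  # of a step first shows in the row written at that step's end, so the
  # arrival time is one dt before the first changed row
  jumps <- which(diff(gE) > 2.5) + 1L   # +5 nS arrivals dwarf the decay
  jump_times <- (jumps - 1L) * 0.1
  for (ts in src_spikes[src_spikes < 390])
    expect_true(any(abs(jump_times - (ts + 1.5)) < 0.051),
                label = sprintf("arrival for spike at %g", ts))
  expect_error(simulate_network(spec, duration = 100, dt = 0.4),
               "multiple")
})

test_that("the AI state's recurrent loop is inhibition-dominated", {
  tiny <- tiny_network("AI", 0.04)
  sim <- simulate_network(tiny, "ai", duration = 2000, seed = 2,
                          record = record_per_population(40), burn_in = 500)
  bal <- network_balance(sim, include_drive = FALSE)
  expect_lt(bal, 1)
  expect_gt(bal, 0)
  # drive-inclusive ratio is larger by construction
  expect_gt(network_balance(sim), bal)
})

test_that("spike tables round-trip through CSV", {
  tiny <- tiny_network("PING", 0.04)
  sim <- simulate_network(tiny, "gamma", duration = 700, seed = 1,
                          burn_in = 0)
  path <- tempfile(fileext = ".csv")
  write_spikes_csv(sim, path)
  back <- read_spikes_csv(path)
  expect_equal(back$neuron, sim$spikes$neuron)
  expect_equal(back$time, sim$spikes$time)
  pops <- read.csv(paste0(path, ".populations.csv"))
  expect_equal(nrow(pops), sim$meta$n_neurons)
})
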