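# Circular statistics, Poisson rate-change test, and consistency bookkeeping.

test_that("Rayleigh statistic behaves at the degenerate extremes", {
  r <- rayleigh_test(rep(1.3, 10))
  expect_equal(r$mean_resultant_length, 1, tolerance = 1e-12)
  expect_equal(r$Z, 10, tolerance = 1e-9)
  expect_equal(r$circular_mean, 1.3)

  eq <- rayleigh_test(seq(-pi, pi, length.out = 13)[-13])
  expect_lt(eq$Z, 1e-20)
  expect_error(rayleigh_test(numeric()), "at least one")
})

test_that("Rayleigh p approximation agrees with a Monte-Carlo null", {
  set.seed(42)
  B <- 20000
  for (n in c(20, 80)) {
    z_null <- replicate(B, {
      th <- runif(n, -pi, pi)
      Mod(sum(exp(1i * th)))^2 / n
    })
    # targets across the p range of interest
    for (ztest in quantile(z_null, c(0.9, 0.99, 0.999))) {
      p_mc <- mean(z_null >= ztest)
      th_fake <- ztest  # analytic p at this Z
      p_approx <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n * ztest)) - (1 + 2 * n))
      expect_lt(abs(log(p_approx / p_mc)), log(2),
                label = sprintf("n=%d p_mc=%.4g", n, p_mc))
    }
  }
})

test_that("a concentrated sample is detected far below alpha", {
  set.seed(1)
  r <- rayleigh_test(rvonmises(50, mu = 1, kappa = 2))
  expect_lt(r$p, 0.01)
  # p decreases monotonically with n at fixed resultant length
  rbar <- 0.3
  ps <- sapply(c(10, 30, 100, 300), function(n) {
    Z <- n * rbar^2
    exp(sqrt(1 + 4 * n + 4 * (n^2 - n * Z)) - (1 + 2 * n))
  })
  expect_true(all(diff(ps) < 0))
  # closed-form critical value inverts the approximation
  for (n in c(10, 50, 500)) {
    zc <- gammanet:::rayleigh_critical_z(1e-4, n)
    p_at <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n * zc)) - (1 + 2 * n))
    expect_equal(p_at, 1e-4, tolerance = 1e-8)
  }
})

test_that("von Mises fits recover parameters and handle degeneracies", {
  set.seed(3)
  fit <- fit_von_mises(rvonmises(10000, mu = -2, kappa = 5))
  expect_lt(abs(fit$mu - (-2)), 0.05)
  expect_lt(abs(fit$kappa - 5) / 5, 0.10)

  expect_lt(fit_von_mises(runif(5000, -pi, pi))$kappa, 0.1)
  expect_equal(fit_von_mises(c(0, pi))$kappa, 0)
  expect_equal(fit_von_mises(rep(0.5, 20))$kappa, 1e3)  # capped
  expect_error(fit_von_mises(1), "two")
})

test_that("phase-locking labels follow the inconclusive and Bonferroni rules", {
  set.seed(9)
  # 4 spikes -> inconclusive regardless of concentration
  df4 <- data.frame(neuron = 1L, phase = rep(0.2, 4), electrode_id = 1L)
  expect_equal(classify_phase_locking(df4, gamma_time_s = 100)$label,
               "inconclusive")
  # < 1 s of gamma on the electrode -> inconclusive
  df <- data.frame(neuron = 1L, phase = rvonmises(200, 0, 3),
                   electrode_id = 1L)
  expect_equal(classify_phase_locking(df, gamma_time_s = 0.8)$label,
               "inconclusive")
  # strongly concentrated sample among 100 tested neurons -> locked
  res <- classify_phase_locking(df, gamma_time_s = 100, n_tested = 100)
  expect_equal(res$label, "locked")
  expect_equal(res$Z, res$n_spikes_in_bursts * res$mean_resultant_length^2,
               tolerance = 1e-9)
  # uniform sample -> not locked
  dfu <- data.frame(neuron = 2L, phase = runif(200, -pi, pi),
                    electrode_id = 1L)
  expect_equal(classify_phase_locking(dfu, gamma_time_s = 100,
                                      n_tested = 100)$label, "not_locked")
  # silent neurons listed in neuron_ids come back inconclusive
  all_res <- classify_phase_locking(df, neuron_ids = 1:3,
                                    gamma_time_s = 100)
  expect_equal(all_res$label, c("locked", "inconclusive", "inconclusive"))
})

test_that("false-positive rate respects the Bonferroni bound", {
  set.seed(21)
  n_rep <- 1000
  n_neuron <- 100
  alpha <- 0.01
  locked <- 0L
  for (r in seq_len(n_rep)) {
    p_min <- min(replicate(n_neuron, rayleigh_test(runif(20, -pi, pi))$p))
    locked <- locked + (p_min < alpha / n_neuron)
  }
  # family-wise error <= alpha, margin 3x
  expect_lte(locked / n_rep, 3 * alpha)
})

test_that("power: kappa = 2 with 100 spikes is almost always detected", {
  set.seed(5)
  hits <- mean(replicate(200, {
    rayleigh_test(rvonmises(100, 0, 2))$p < 0.01 / 100
  }))
  expect_gt(hits, 0.95)
})

test_that("rate-change classification matches the enumerated Poisson oracle", {
  bursts <- data.frame(electrode_id = 1L, start = seq(0, 9000, 1000),
                       end = seq(1000, 10000, 1000))  # T_gamma = 10 s
  seg_s <- 100
  # f_out = 1 Hz: 90 spikes in the 90 s outside bursts
  out_times <- seq(10000.5, 99999, length.out = 90)
  # enumerated-CDF oracle for lambda = 10
  lam <- 1 * 10
  n_c_oracle <- which(cumsum(dpois(0:100, lam)) >= 0.95)[1] - 1
  n_lo_oracle <- which(cumsum(dpois(0:100, lam)) >= 0.05)[1] - 1

  mk_in <- function(k) if (k > 0) seq(10, 990, length.out = k) else numeric()
  lab <- function(k) classify_rate_change(c(mk_in(k), out_times), bursts,
                                          seg_s)$label
  r <- classify_rate_change(c(mk_in(16), out_times), bursts, seg_s)
  expect_equal(r$n_c, n_c_oracle)
  expect_equal(r$f_out, 1)
  expect_equal(r$T_gamma, 10)
  expect_equal(lab(n_c_oracle + 1), "increase")
  expect_equal(lab(n_c_oracle), "no_change")
  expect_equal(lab(round(lam)), "no_change")   # the mean never exceeds q95
  expect_equal(lab(n_lo_oracle - 1), "decrease")
  # f_out below 0.1 Hz -> inconclusive
  few <- classify_rate_change(c(seq(20000, 90000, length.out = 5), 500),
                              bursts, seg_s)
  expect_equal(few$label, "inconclusive")
  # no gamma time -> inconclusive
  none <- classify_rate_change(out_times,
                               bursts[0, , drop = FALSE], seg_s)
  expect_equal(none$label, "inconclusive")
})

test_that("false-increase rate sits near the one-sided 5% level", {
  set.seed(8)
  lam <- 12
  n_c <- qpois(0.95, lam)
  inc <- mean(rpois(1000, lam) > n_c)
  p_true <- 1 - ppois(n_c, lam)
  expect_lt(abs(inc - p_true), 3 * sqrt(p_true * (1 - p_true) / 1000))
  expect_lte(p_true, 0.05)
})

test_that("consistency analysis tallies labels across segments", {
  mk <- function(labels) {
    df <- data.frame(neuron_id = seq_along(labels), label = labels)
    class(df) <- c("phase_lock_result", "data.frame")
    df
  }
  # neuron 1 locked in all 5 segments; neuron 2 never; neuron 3 mixed
  segs <- replicate(5, mk(c("locked", "not_locked", "inconclusive")),
                    simplify = FALSE)
  ct <- consistency_analysis(segs)
  expect_equal(ct$per_neuron$times_locked, c(5, 0, 0))
  expect_equal(unname(ct$lock_hist["5"]), 1)
  expect_equal(ct$per_neuron$n_inconclusive_lock[3], 5)
  # inconclusive segments are tallied separately, not as zero-locked
  expect_equal(unname(ct$lock_hist["0"]), 2)

  # bimodal cohort: mass only at 0 and K
  segs2 <- replicate(5, mk(c(rep("locked", 2), rep("not_locked", 18))),
                     simplify = FALSE)
  ct2 <- consistency_analysis(segs2)
  expect_equal(unname(ct2$lock_hist[c("0", "5")]), c(18, 2))
  expect_equal(sum(ct2$lock_hist), 20)

  bad <- mk(c("locked", "locked"))
  expect_error(consistency_analysis(list(segs[[1]], bad)), "ids")
})
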