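#' Rayleigh test of circular uniformity
#'
#' Mean resultant length `Rbar = |sum exp(i theta)| / n`, Rayleigh statistic
#' `Z = n Rbar^2`, and the standard large-sample approximation of the p-value
#' `p = exp(sqrt(1 + 4n + 4(n^2 - n Z)) - (1 + 2n))`, accurate over the whole
#' p range of interest and validated against Monte-Carlo nulls in the test
#' suite. The circular mean is `arg(sum exp(i theta))` in `(-pi, pi]`.
#'
#' @param phases Phases (radians).
#' @return A list: `n`, `Z`, `p`, `mean_resultant_length`, `circular_mean`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 1) stop("rayleigh_test needs at least one phase")
  s <- sum(exp(1i * phases))
  rbar <- Mod(s) / n
  Z <- n * rbar^2
  arg <- 1 + 4 * n + 4 * (n^2 - n * Z)
  p <- if (arg < 0) 0 else exp(sqrt(arg) - (1 + 2 * n))
  list(n = n, Z = Z, p = min(max(p, 0), 1),
       mean_resultant_length = rbar, circular_mean = Arg(s))
}

# Critical Z at significance alpha for sample size n: closed-form inversion of
# the Rayleigh p approximation.
rayleigh_critical_z <- function(alpha, n) {
  (1 + 4 * n + 4 * n^2 - (log(alpha) + 1 + 2 * n)^2) / (4 * n)
}

#' Fit a von Mises distribution to phases
#'
#' Maximum-likelihood fit: `mu` is the circular mean; `kappa` is obtained by
#' inverting `A1(kappa) = Rbar` (ratio of Bessel functions), started from the
#' Best-Fisher approximation and refined by Newton steps. With all phases
#' (nearly) identical `Rbar -> 1` and the ML `kappa` diverges; it is capped
#' at `kappa_max`.
#'
#' @param phases Phases (radians), `n >= 2`.
#' @param kappa_max Cap on the concentration (default 1e3).
#' @return A list: `mu` (radians), `kappa`, `Rbar`, `n`.
#' @export
fit_von_mises <- function(phases, kappa_max = 1e3) {
  n <- length(phases)
  if (n < 2) stop("fit_von_mises needs at least two phases")
  s <- sum(exp(1i * phases))
  rbar <- Mod(s) / n
  mu <- Arg(s)
  if (rbar < 1e-12) return(list(mu = mu, kappa = 0, Rbar = rbar, n = n))
  # Best & Fisher starting value
  k <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
       else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
       else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  if (!is.finite(k) || k <= 0) k <- kappa_max
  k <- min(k, kappa_max)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
                    besselI(k, 0, expon.scaled = TRUE)
  for (it in 1:25) {  # Newton on A1(k) - rbar = 0; A1'(k) = 1 - A1/k - A1^2
    A1 <- a1(k)
    dA1 <- 1 - A1 / k - A1^2
    if (!is.finite(dA1) || abs(dA1) < 1e-14) break
    k_new <- k - (A1 - rbar) / dA1
    if (!is.finite(k_new) || k_new <= 0) break
    k_new <- min(k_new, kappa_max)
    if (abs(k_new - k) < 1e-10 * (1 + k)) { k <- k_new; break }
    k <- k_new
  }
  list(mu = mu, kappa = min(k, kappa_max), Rbar = rbar, n = n)
}

#' Classify phase-locking per neuron
#'
#' Applies the Bonferroni-corrected Rayleigh test to each neuron's gamma-burst
#' spike phases. A neuron is `inconclusive` if it spiked fewer than
#' `min_spikes` (5) times inside bursts or its electrode accumulated less than
#' `min_gamma_s` (1 s) of gamma in the segment; otherwise it is `locked` when
#' `p < alpha / n_tested` and `not_locked` otherwise. The preferred phase is
#' the von Mises location (equal to the circular mean).
#'
#' @param phase_df A [spike_phases()] data frame (`neuron`, `phase`,
#'   `electrode_id`), or a named list of per-neuron phase vectors.
#' @param neuron_ids Ids of all neurons under test (so silent neurons are
#'   classified too); defaults to those present in `phase_df`.
#' @param gamma_time_s Total gamma time (s) per electrode: a single number or
#'   a vector indexed by electrode id.
#' @param alpha Family significance level (default 0.01).
#' @param n_tested Bonferroni denominator: number of neurons tested in the
#'   segment (defaults to `length(neuron_ids)`).
#' @param min_spikes,min_gamma_s Inconclusive-rule thresholds.
#' @return A data frame of class `phase_lock_result`, one row per neuron:
#'   `neuron_id`, `n_spikes_in_bursts`, `Z`, `p`, `Z_c` (critical value),
#'   `preferred_phase`, `mean_resultant_length`, `label`.
#' @export
classify_phase_locking <- function(phase_df, neuron_ids = NULL,
                                   gamma_time_s = Inf, alpha = 0.01,
                                   n_tested = NULL, min_spikes = 5,
                                   min_gamma_s = 1) {
  if (is.list(phase_df) && !is.data.frame(phase_df)) {
    phase_df <- do.call(rbind, lapply(names(phase_df), function(nm)
      data.frame(neuron = as.integer(nm), phase = phase_df[[nm]],
                 electrode_id = 1L)))
  }
  if (is.null(phase_df$electrode_id)) phase_df$electrode_id <- 1L
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(phase_df$neuron))
  if (is.null(n_tested)) n_tested <- length(neuron_ids)
  alpha_eff <- alpha / n_tested
  rows <- lapply(neuron_ids, function(id) {
    ph <- phase_df$phase[phase_df$neuron == id]
    n <- length(ph)
    elec <- if (n > 0) phase_df$electrode_id[phase_df$neuron == id][1] else 1L
    gt <- if (length(gamma_time_s) == 1) gamma_time_s else gamma_time_s[elec]
    z_c <- rayleigh_critical_z(alpha_eff, max(n, 1))
    if (gt < min_gamma_s || n < min_spikes) {
      rt <- if (n >= 1) rayleigh_test(ph) else
        list(Z = NA_real_, p = NA_real_, mean_resultant_length = NA_real_,
             circular_mean = NA_real_)
      return(data.frame(neuron_id = id, n_spikes_in_bursts = n, Z = rt$Z,
                        p = rt$p, Z_c = z_c,
                        preferred_phase = rt$circular_mean,
                        mean_resultant_length = rt$mean_resultant_length,
                        label = "inconclusive"))
    }
    rt <- rayleigh_test(ph)
    vm <- fit_von_mises(ph)
    data.frame(neuron_id = id, n_spikes_in_bursts = n, Z = rt$Z, p = rt$p,
               Z_c = z_c, preferred_phase = vm$mu,
               mean_resultant_length = rt$mean_resultant_length,
               label = if (rt$p < alpha_eff) "locked" else "not_locked")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_lock_result", "data.frame")
  out
}

#' Classify firing-rate change inside gamma bursts
#'
#' Compares each neuron's observed spike count inside gamma bursts with the
#' count expected from its outside-burst rate: under the null the in-burst
#' count is Poisson with mean `lambda = f_out * T_gamma`. The neuron
#' `increase`s its firing if the observed count exceeds the 95% Poisson
#' quantile (`n_c`, the percent-point function), `decrease`s it if the count
#' falls below the symmetric 5% quantile, and is `inconclusive` when
#' `f_out < 0.1 Hz` or the electrode saw less than 1 s of gamma.
#'
#' @param spike_times Spike times (ms) of one neuron over the segment, or a
#'   data frame `neuron`, `time` for many neurons.
#' @param bursts A [detect_bursts()] result (the neuron's own electrode).
#' @param segment_duration_s Total segment duration (s).
#' @param min_f_out,min_gamma_s Inconclusive thresholds (Hz, s).
#' @return One row (or one per neuron) of class `rate_change_result`:
#'   `neuron_id`, `f_out` (Hz), `f_gamma` (Hz), `T_gamma` (s), `n_obsv`,
#'   `n_c`, `label` in `{increase, decrease, no_change, inconclusive}`.
#' @export
classify_rate_change <- function(spike_times, bursts, segment_duration_s,
                                 min_f_out = 0.1, min_gamma_s = 1) {
  if (is.data.frame(spike_times)) {
    ids <- sort(unique(spike_times$neuron))
    out <- do.call(rbind, lapply(ids, function(id) {
      r <- classify_rate_change(spike_times$time[spike_times$neuron == id],
                                bursts, segment_duration_s, min_f_out,
                                min_gamma_s)
      r$neuron_id <- id
      r
    }))
    class(out) <- c("rate_change_result", "data.frame")
    return(out)
  }
  t_gamma <- sum(bursts$end - bursts$start) / 1000  # s
  in_burst <- rep(FALSE, length(spike_times))
  for (b in seq_len(nrow(bursts)))
    in_burst <- in_burst | (spike_times >= bursts$start[b] &
                            spike_times <= bursts$end[b])
  n_obsv <- sum(in_burst)
  n_out <- length(spike_times) - n_obsv
  t_out <- segment_duration_s - t_gamma
  f_out <- if (t_out > 0) n_out / t_out else NA_real_
  f_gamma <- if (t_gamma > 0) n_obsv / t_gamma else NA_real_
  if (t_gamma <= 0 || t_gamma < min_gamma_s || !is.finite(f_out) ||
      f_out < min_f_out) {
    label <- "inconclusive"
    n_c <- NA_integer_
  } else {
    lambda <- f_out * t_gamma
    n_c <- qpois(0.95, lambda)       # smallest k with CDF >= 0.95
    n_lo <- qpois(0.05, lambda)      # smallest k with CDF >= 0.05
    label <- if (n_obsv > n_c) "increase"
             else if (n_obsv < n_lo) "decrease"
             else "no_change"
  }
  out <- data.frame(neuron_id = NA_integer_, f_out = f_out, f_gamma = f_gamma,
                    T_gamma = t_gamma, n_obsv = n_obsv, n_c = n_c,
                    label = label)
  class(out) <- c("rate_change_result", "data.frame")
  out
}

#' Cross-segment behavior consistency
#'
#' Counts, for each neuron followed over `K` data segments, how many segments
#' classified it as phase-locked and how many as rate-increasing, and
#' tabulates the distribution of those consistency indexes over neurons
#' (0 = never, K = in every segment). Segments where a neuron was
#' `inconclusive` are tallied separately, not folded into 0. With per-segment
#' durations given, a time-weighted variant reports the percentage of total
#' recording time each neuron spent in each label.
#'
#' @param lock_results List (length K) of [classify_phase_locking()] results.
#' @param rate_results List (length K) of [classify_rate_change()] results.
#' @param segment_durations_s Optional per-segment durations (s) for the
#'   time-weighted variant.
#' @return A list of class `consistency_table`: `per_neuron` (data frame:
#'   `neuron_id`, `times_locked`, `times_rate_increase`, `n_inconclusive_lock`,
#'   `n_inconclusive_rate`), `lock_labels` and `rate_labels` (neuron x
#'   segment label matrices), `lock_hist` and `rate_hist` (consistency 0..K
#'   distributions over conclusive neurons), optionally `time_weighted`.
#' @export
consistency_analysis <- function(lock_results, rate_results = NULL,
                                 segment_durations_s = NULL) {
  K <- length(lock_results)
  ids <- lock_results[[1]]$neuron_id
  for (r in lock_results)
    if (!identical(r$neuron_id, ids)) stop("neuron ids differ across segments")
  lock_mat <- vapply(lock_results, function(r) r$label, character(length(ids)))
  dim(lock_mat) <- c(length(ids), K)
  times_locked <- rowSums(lock_mat == "locked")
  n_inc_lock <- rowSums(lock_mat == "inconclusive")
  out <- list(
    per_neuron = data.frame(neuron_id = ids, times_locked = times_locked,
                            n_inconclusive_lock = n_inc_lock),
    lock_labels = lock_mat,
    lock_hist = tabulate(times_locked + 1L, nbins = K + 1L))
  names(out$lock_hist) <- 0:K
  if (!is.null(rate_results)) {
    for (r in rate_results)
      if (!identical(r$neuron_id, ids)) stop("neuron ids differ across segments")
    rate_mat <- vapply(rate_results, function(r) r$label, character(length(ids)))
    dim(rate_mat) <- c(length(ids), K)
    out$per_neuron$times_rate_increase <- rowSums(rate_mat == "increase")
    out$per_neuron$n_inconclusive_rate <- rowSums(rate_mat == "inconclusive")
    out$rate_labels <- rate_mat
    out$rate_hist <- tabulate(out$per_neuron$times_rate_increase + 1L,
                              nbins = K + 1L)
    names(out$rate_hist) <- 0:K
  }
  if (!is.null(segment_durations_s)) {
    w <- segment_durations_s / sum(segment_durations_s)
    as_pct <- function(lbl) {
      m <- matrix(as.numeric(lock_mat == lbl), length(ids), K)
      100 * drop(m %*% w)
    }
    out$time_weighted <- data.frame(
      neuron_id = ids,
      pct_time_locked = as_pct("locked"),
      pct_time_not_locked = as_pct("not_locked"))
  }
  class(out) <- "consistency_table"
  out
}

#' @export
print.consistency_table <- function(x, ...) {
  K <- ncol(x$lock_labels)
  cat(sprintf("<consistency_table: %d neurons, %d segments>\n",
              nrow(x$per_neuron), K))
  cat("phase-locking consistency (0..K):\n")
  print(x$lock_hist)
  if (!is.null(x$rate_hist)) {
    cat("rate-increase consistency (0..K):\n")
    print(x$rate_hist)
  }
  invisible(x)
}

#' Export per-neuron statistics as tidy CSV
#'
#' One row per neuron per segment with phase-locking and rate-change labels
#' and the underlying statistics, plus preferred phase and resultant length
#' for polar plotting.
#'
#' @param lock_results,rate_results Lists of per-segment results.
#' @param path Output CSV path.
#' @return The tidy data frame, invisibly; written to `path` if given.
#' @export
export_unit_statistics <- function(lock_results, rate_results = NULL,
                                   path = NULL) {
  rows <- lapply(seq_along(lock_results), function(k) {
    df <- as.data.frame(lock_results[[k]])
    df$segment <- k
    if (!is.null(rate_results)) {
      rr <- as.data.frame(rate_results[[k]])
      df$rate_label <- rr$label[match(df$neuron_id, rr$neuron_id)]
      df$f_out <- rr$f_out[match(df$neuron_id, rr$neuron_id)]
      df$f_gamma <- rr$f_gamma[match(df$neuron_id, rr$neuron_id)]
    }
    df
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  invisible(out)
}
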