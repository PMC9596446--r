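## Akritas nonparametric-bootstrap calibration of the Hall-Wellner critical
## value: resample (time, event) pairs with replacement, refit the
## Kaplan-Meier curve, and take the empirical level-quantile of the
## HW-normalised supremum statistic
##   A*_j = sqrt(n) sup_{t in [a,b]} |S*_j(t) - S(t)| / {(1 + tau(t)) S(t)},
## whose limit is the Brownian-bridge supremum on [0, K].  No lookup tables
## are involved, so any confidence level can be used.

#' Resample a survival sample and refit the Kaplan-Meier curve
#'
#' Draws an n-out-of-n with-replacement resample of the subject-level
#' `(time, event)` pairs and refits.
#'
#' @param fit A [fit_km()] object (the subject-level sample it retains is
#'   resampled).
#' @param seed Seed for the resampling stream (restored afterwards);
#'   `NULL` uses the current stream.
#' @return A `km_fit` of the resampled data.
#' @export
km_resample <- function(fit, seed = NULL) {
  check_km_fit(fit)
  smp <- fit$sample
  n <- nrow(smp)
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  tm <- smp$time[idx]
  ev <- smp$event[idx]
  if (sum(ev) == 0) {
    stop_survband("degenerate resample: no events.")
  }
  new_km_fit(km_compute(tm, ev), tibble::tibble(time = tm, event = ev))
}

# statistic on a plain km_compute() core, for the hot loop
akritas_statistic_core <- function(boot_core, eval_time, eval_est,
                                   eval_weight, n) {
  idx <- findInterval(eval_time, boot_core$time)
  s_boot <- c(1, boot_core$estimate)[idx + 1L]
  sqrt(n) * max(abs(s_boot - eval_est) * eval_weight)
}

#' Bootstrap supremum statistic for Hall-Wellner calibration
#'
#' \eqn{A^* = \sqrt n \sup_t |\hat S^*(t) - \hat S(t)| / \{(1 + \tau(t))
#' \hat S(t)\}}, the supremum taken over the original curve's event times
#' inside \eqn{[a, b]} (where the step functions attain their extremes),
#' with \eqn{\tau} and \eqn{\hat S} from the original fit.
#'
#' @param boot A `km_fit` of a bootstrap resample.
#' @param orig The original [fit_km()] object.
#' @param tmin,tmax Band range; defaults as in [km_band()].
#' @return The statistic (nonnegative scalar).
#' @export
akritas_statistic <- function(boot, orig, tmin = NULL, tmax = NULL) {
  check_km_fit(boot)
  check_km_fit(orig)
  rng <- band_range_idx(orig, tmin, tmax, "hw")
  crv <- orig$curve
  w <- 1 / ((1 + crv$tau[rng$idx]) * crv$estimate[rng$idx])
  akritas_statistic_core(
    list(time = boot$curve$time, estimate = boot$curve$estimate),
    crv$time[rng$idx], crv$estimate[rng$idx], w, orig$n
  )
}

#' Bootstrap-calibrated Hall-Wellner band
#'
#' Replaces the analytic Brownian-bridge critical value of the Hall-Wellner
#' band with the empirical `level` quantile \eqn{\hat k} of the resampled
#' supremum statistics \eqn{A^*_1, \ldots, A^*_d} (order statistic at index
#' \eqn{\lceil level \cdot d\rceil}).  Replicates whose resample contains
#' no events are skipped and counted; more than 1\% of them is an error.
#'
#' @inheritParams pointwise_band
#' @param x A data frame of subject-level records or a [fit_km()] object.
#' @param boot_reps Number of bootstrap replicates \eqn{d \ge 100} (a
#'   warning is given below 1000).
#' @param seed Seed for the resampling stream (restored afterwards).
#' @param time,event Column selections when `x` is a data frame.
#' @return A `km_band`; diagnostics carry the calibration (`k_hat`, `K`,
#'   the replicate count used, skipped replicates, the seed and the
#'   resampled statistics `A_stats`).
#' @examples
#' df <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.9))
#' bootstrap_hw_band(df, boot_reps = 200, seed = 1)
#' @export
bootstrap_hw_band <- function(x, level = 0.95, tmin = NULL, tmax = NULL,
                              boot_reps = 1000, seed = NULL, clamp = TRUE,
                              time = time, event = event) {
  check_level(level)
  fit <- if (is_km_fit(x)) x else fit_km(x, time = {{ time }}, event = {{ event }})
  if (!is.numeric(boot_reps) || boot_reps < 100) {
    stop_usage("`boot_reps` must be at least 100.")
  }
  boot_reps <- as.integer(boot_reps)
  if (boot_reps < 1000) {
    warn("fewer than 1000 bootstrap replicates: the calibrated quantile will be noisy.")
  }
  rng <- band_range_idx(fit, tmin, tmax, "hw")
  crv <- fit$curve
  eval_time <- crv$time[rng$idx]
  eval_est <- crv$estimate[rng$idx]
  eval_weight <- 1 / ((1 + crv$tau[rng$idx]) * eval_est)
  tau_b <- crv$tau[max(rng$idx)]
  kk <- tau_b / (1 + tau_b)
  smp_time <- fit$sample$time
  smp_event <- fit$sample$event
  n <- fit$n
  stats <- numeric(boot_reps)
  skipped <- 0L
  with_seed(seed, {
    for (j in seq_len(boot_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      ev <- smp_event[idx]
      if (sum(ev) == 0L) {
        skipped <- skipped + 1L
        stats[j] <- NA_real_
        next
      }
      core <- km_compute(smp_time[idx], ev)
      stats[j] <- akritas_statistic_core(core, eval_time, eval_est, eval_weight, n)
    }
  })
  if (skipped > 0.01 * boot_reps) {
    stop_survband(paste0(
      "more than 1% of bootstrap resamples were degenerate (", skipped,
      " of ", boot_reps, " had no events)."
    ))
  }
  a_stats <- stats[!is.na(stats)]
  d_used <- length(a_stats)
  k_hat <- sort(a_stats)[ceiling(level * d_used)]
  est <- eval_est
  half <- k_hat * (1 + crv$tau[rng$idx]) / sqrt(n) * est
  new_km_band(fit, rng$idx, est - half, est + half,
    method = "boot_hw", transform = "linear", level = level,
    range = c(rng$a, rng$b),
    critical = new_critical_value(k_hat,
      family = "bridge_sup", level = level, domain = c(0, kk),
      method = "bootstrap",
      mc_error = sqrt(level * (1 - level) / d_used) /
        max(approx(density(a_stats), xout = k_hat)$y, 1e-6)
    ),
    diagnostics = list(
      K = kk, k_hat = k_hat, boot_reps = boot_reps, used = d_used,
      skipped = skipped, seed = seed, A_stats = a_stats
    ),
    clamp = clamp
  )
}
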