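## Thomas-Grunkemeier nonparametric likelihood-ratio intervals and the
## Hollander-type simultaneous likelihood-ratio band.
##
## For right-censored data the nonparametric likelihood over survival
## functions is maximised, subject to S(t) = p, by discrete hazards
## d_i / (n_i + lambda) at the event times t_i <= t (Lagrange multiplier
## lambda, lambda = 0 giving the Kaplan-Meier estimate).  The profile
## deviance -2 log R(p, t) follows in closed form given lambda, so the
## whole machinery reduces to monotone one-dimensional root finding in
## lambda.

# event-time rows of the curve at or before t; errors if t precedes the
# first event or if the estimate has already hit zero
lr_rows <- function(fit, t) {
  i <- km_index(fit, t)
  if (i == 0L) {
    stop_survband("`t` must be at or after the first event time.")
  }
  crv <- fit$curve[seq_len(i), ]
  if (any(crv$n_event >= crv$n_risk)) {
    stop_survband(
      "the survival estimate reaches 0 at or before `t`; the likelihood ratio is undefined there."
    )
  }
  crv
}

# pole of the constrained hazards: n_i + lambda must exceed d_i
lambda_pole <- function(d, n_risk) max(d - n_risk)

constrained_log_surv <- function(d, n_risk, lambda) {
  sum(log1p(-d / (n_risk + lambda)))
}

# -2 log R as a function of lambda (closed form given the multiplier)
deviance_at_lambda <- function(d, n_risk, lambda) {
  nd <- n_risk - d
  2 * sum(
    d * log((n_risk + lambda) / n_risk) +
      nd * (log(nd) + log(n_risk + lambda) - log(n_risk) - log(n_risk + lambda - d))
  )
}

#' Constrained product-limit survival estimate
#'
#' \eqn{\hat S_\lambda(t) = \prod_{t_i \le t} (1 - d_i / (n_i + \lambda))}:
#' the survival function maximising the nonparametric likelihood subject to
#' a constraint at \eqn{t}, indexed by its Lagrange multiplier.  It is
#' strictly increasing in \eqn{\lambda} and equals the Kaplan-Meier
#' estimate at \eqn{\lambda = 0}.
#'
#' @param fit A [fit_km()] object.
#' @param t Time at or after the first event (and before the estimate hits
#'   zero).
#' @param lambda Multiplier; must exceed the pole
#'   \eqn{\max_i (d_i - n_i)}.
#' @return The constrained survival probability at `t`.
#' @examples
#' fit <- fit_km(data.frame(time = 1:4, event = rep(1, 4)))
#' constrained_survival(fit, 2.5, 0) # the KM estimate, 0.5
#' @export
constrained_survival <- function(fit, t, lambda) {
  check_km_fit(fit)
  crv <- lr_rows(fit, t)
  pole <- lambda_pole(crv$n_event, crv$n_risk)
  if (!is.finite(lambda) || lambda <= pole) {
    stop_survband(paste0(
      "`lambda` must exceed the pole max(d_i - n_i) = ", format(pole), "."
    ))
  }
  exp(constrained_log_surv(crv$n_event, crv$n_risk, lambda))
}

# solve S_lambda(t) = p for lambda (monotone in lambda)
solve_lambda <- function(d, n_risk, p) {
  target <- log(p)
  pole <- lambda_pole(d, n_risk)
  f <- function(l) constrained_log_surv(d, n_risk, l) - target
  eps <- max(1e-9, 1e-12 * max(n_risk))
  lo <- pole + eps
  while (f(lo) > 0 && eps > 1e-300) { # p below the value at the bracket edge
    eps <- eps * 1e-3
    lo <- pole + eps
  }
  hi <- max(max(n_risk), pole + 1)
  for (i in 1:80) {
    if (f(hi) >= 0) break
    hi <- hi * 2
  }
  uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Nonparametric likelihood-ratio deviance for the survival function
#'
#' \eqn{-2 \log R(p, t)} where \eqn{R(p,t) = \sup\{L(S) : S(t) = p\} /
#' L(\hat S)} over all nonincreasing survival functions: the profile
#' empirical-likelihood deviance for \eqn{S(t)}.  Zero exactly at
#' \eqn{p = \hat S(t)} and strictly increasing as \eqn{p} moves away in
#' either direction.
#'
#' @inheritParams constrained_survival
#' @param p Hypothesised survival probability in (0, 1).
#' @return The deviance (nonnegative scalar).
#' @examples
#' fit <- fit_km(data.frame(time = 1:4, event = rep(1, 4)))
#' neg2_log_R(fit, 2.5, 0.25) # binomial empirical likelihood: 4 log(4/3)
#' @export
neg2_log_R <- function(fit, t, p) {
  check_km_fit(fit)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop_survband("`p` must be a single probability strictly inside (0, 1).")
  }
  crv <- lr_rows(fit, t)
  s_hat <- crv$estimate[nrow(crv)]
  if (p == s_hat) {
    return(0)
  }
  lambda <- solve_lambda(crv$n_event, crv$n_risk, p)
  deviance_at_lambda(crv$n_event, crv$n_risk, lambda)
}

# both solutions of deviance(lambda) = threshold, mapped back to survival
# probabilities; used by tg_interval and lr_band
tg_limits_at_threshold <- function(d, n_risk, s_hat, threshold) {
  if (threshold <= 0) {
    return(c(s_hat, s_hat))
  }
  pole <- lambda_pole(d, n_risk)
  dev <- function(l) deviance_at_lambda(d, n_risk, l)
  # lower limit: lambda in (pole, 0); deviance decreases from +Inf to 0
  eps <- max(1e-9, 1e-12 * max(n_risk))
  lo <- pole + eps
  while (dev(lo) < threshold && eps > 1e-300) {
    eps <- eps * 1e-3
    lo <- pole + eps
  }
  l_low <- if (dev(lo) < threshold) {
    lo # threshold unreachable this close to the pole; limit is essentially 0
  } else {
    uniroot(function(l) dev(l) - threshold,
      lower = lo, upper = 0, tol = 1e-11
    )$root
  }
  # upper limit: lambda in (0, Inf); deviance increases from 0, but only
  # logarithmically once the hazards are tiny — if the constrained survival
  # reaches 1 to machine precision before the threshold is met, the upper
  # limit is 1
  hi <- max(max(n_risk), 1)
  reached <- FALSE
  for (i in 1:300) {
    if (dev(hi) >= threshold) {
      reached <- TRUE
      break
    }
    if (constrained_log_surv(d, n_risk, hi) > -1e-15) break
    hi <- hi * 2
  }
  upper <- if (reached) {
    l_high <- uniroot(function(l) dev(l) - threshold,
      lower = 0, upper = hi, tol = 1e-11
    )$root
    exp(constrained_log_surv(d, n_risk, l_high))
  } else {
    1
  }
  c(exp(constrained_log_surv(d, n_risk, l_low)), upper)
}

#' Thomas-Grunkemeier likelihood-ratio pointwise interval
#'
#' The set \eqn{\{p : -2\log R(p, t) \le \chi^2_{1, level}\}}, found by
#' monotone root finding on each side of the Kaplan-Meier estimate.  The
#' interval is inside \eqn{[0,1]} by construction and is asymmetric around
#' the estimate near the boundaries.
#'
#' @inheritParams constrained_survival
#' @param level Confidence level in (0, 1).
#' @return A tibble with columns `time`, `estimate`, `lower`, `upper`,
#'   `level`.
#' @examples
#' fit <- fit_km(data.frame(time = 1:4, event = rep(1, 4)))
#' tg_interval(fit, 2.5, 0.95)
#' @export
tg_interval <- function(fit, t, level = 0.95) {
  check_km_fit(fit)
  check_level(level)
  crv <- lr_rows(fit, t)
  s_hat <- crv$estimate[nrow(crv)]
  lim <- tg_limits_at_threshold(
    crv$n_event, crv$n_risk, s_hat, qchisq(level, 1)
  )
  tibble::tibble(
    time = t, estimate = s_hat, lower = lim[1], upper = lim[2], level = level
  )
}

#' Simultaneity correction for likelihood-ratio bands
#'
#' Implements the rescaling chain that converts a simultaneous
#' Brownian-bridge critical value into an equivalent pointwise
#' likelihood-ratio confidence level: \eqn{\hat A = \sqrt{\tau(b)}},
#' \eqn{\hat d = \hat A^2/(1+\hat A^2)}, \eqn{k} the `level` quantile of
#' \eqn{\sup_{[0,\hat d]}|B|}, \eqn{\hat C = k(1+\hat A^2)/\hat A} and
#' \eqn{\alpha^* = P\{\chi^2_1 > \hat C^2\}}.  Inverting the pointwise
#' deviance at confidence \eqn{1-\alpha^*} (threshold \eqn{\hat C^2}) at
#' the range end \eqn{b} then matches the simultaneous calibration there.
#'
#' @inheritParams constrained_survival
#' @param b Upper end of the band range (at or after the first event, with
#'   \eqn{\hat S(b) > 0}).
#' @param level Simultaneous confidence level.
#' @return A one-row tibble with columns `A_hat`, `d_hat`, `k`, `C_hat`,
#'   `alpha_star`.
#' @export
alpha_star <- function(fit, b, level = 0.95) {
  check_km_fit(fit)
  check_level(level)
  crv <- lr_rows(fit, b)
  tau_b <- crv$tau[nrow(crv)]
  if (!is.finite(tau_b) || tau_b <= 0) {
    stop_survband("tau(b) must be positive and finite.")
  }
  a_hat <- sqrt(tau_b)
  d_hat <- tau_b / (1 + tau_b)
  k <- as.numeric(bridge_sup_quantile(d_hat, level))
  c_hat <- k * (1 + tau_b) / a_hat
  tibble::tibble(
    A_hat = a_hat, d_hat = d_hat, k = k, C_hat = c_hat,
    alpha_star = pchisq(c_hat^2, df = 1, lower.tail = FALSE)
  )
}

#' Simultaneous likelihood-ratio confidence band
#'
#' At each event time in \eqn{[a, b]} the band inverts the nonparametric
#' likelihood-ratio deviance, \eqn{\{p : -2\log R(p, t) \le C^2(t)\}}.  The
#' deviance process converges to the squared standardised Brownian bridge
#' \eqn{B(x(t))^2/\{x(t)(1-x(t))\}}, so the default threshold
#' \deqn{C^2(t) = k^2 (1+\tau(t))^2/\tau(t),}
#' with \eqn{k} the `level` quantile of \eqn{\sup_{[0,\hat d]}|B|} and
#' \eqn{\hat d = \tau(b)/(1+\tau(b))}, makes the simultaneous coverage
#' event asymptotically identical to \eqn{\{\sup_{[0,\hat d]}|B| \le k\}}.
#' `threshold = "fixed"` instead applies the constant \eqn{\hat C^2 =
#' C^2(b)} at every time — the single-level rescaling used when a pointwise
#' likelihood-ratio routine only accepts one confidence level (see
#' [alpha_star()]); it is exact at \eqn{b} but increasingly conservative at
#' earlier times when \eqn{\tau(b)} is large.
#'
#' The limits are inside \eqn{[0,1]} by construction and need no
#' transformation.  Monotonicity of the limits across times is checked and
#' reported in the diagnostics (`monotone_violations`), not enforced.
#'
#' @inheritParams pointwise_band
#' @param threshold `"time-varying"` (default) or `"fixed"`.
#' @return A `km_band`; diagnostics carry the [alpha_star()] chain.
#' @export
lr_band <- function(fit, level = 0.95, tmin = NULL, tmax = NULL,
                    threshold = c("time-varying", "fixed")) {
  check_km_fit(fit)
  check_level(level)
  threshold <- match.arg(threshold)
  rng <- band_range_idx(fit, tmin, tmax, "lr")
  crv <- fit$curve
  astar <- alpha_star(fit, rng$b, level)
  k <- astar$k
  tau_t <- crv$tau[rng$idx]
  c2 <- if (threshold == "time-varying") {
    k^2 * (1 + tau_t)^2 / tau_t
  } else {
    rep(astar$C_hat^2, length(rng$idx))
  }
  lims <- vapply(seq_along(rng$idx), function(j) {
    i <- rng$idx[j]
    rows <- seq_len(i)
    tg_limits_at_threshold(
      crv$n_event[rows], crv$n_risk[rows], crv$estimate[i], c2[j]
    )
  }, numeric(2))
  lower <- lims[1, ]
  upper <- lims[2, ]
  viol <- sum(diff(lower) > 1e-10) + sum(diff(upper) > 1e-10)
  new_km_band(fit, rng$idx, lower, upper,
    method = "lr", transform = "linear", level = level,
    range = c(rng$a, rng$b),
    critical = new_critical_value(k,
      family = "bridge_sup", level = level, domain = c(0, astar$d_hat)
    ),
    diagnostics = c(
      as.list(astar),
      list(threshold = threshold, monotone_violations = viol)
    ),
    clamp = FALSE
  )
}
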