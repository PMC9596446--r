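## Confidence-band assembly.  All bands are step functions reported at the
## distinct event times inside the requested range [tmin, tmax]; step
## interpolation between rows is the caller's contract.  The variance time
## scale throughout is tau(t) = n * g(t) (see fit_km), and the bridge-time
## map is x(t) = tau(t) / (1 + tau(t)).

`%||%` <- function(a, b) if (is.null(a)) b else a

new_km_band <- function(fit, idx, lower, upper, method, transform, level,
                        range, critical, diagnostics, clamp) {
  crv <- fit$curve
  if (clamp) {
    lower <- pmin(pmax(lower, 0), 1)
    upper <- pmin(pmax(upper, 0), 1)
  }
  out <- tibble::tibble(
    time = crv$time[idx],
    n_risk = crv$n_risk[idx],
    n_event = crv$n_event[idx],
    estimate = crv$estimate[idx],
    std_err = crv$std_err[idx],
    lower = lower,
    upper = upper
  )
  structure(
    out,
    method = method, transform = transform, level = level,
    range = range, critical = critical, diagnostics = diagnostics,
    n = fit$n, clamped = clamp,
    class = c("km_band", class(out))
  )
}

band_attr <- function(band, what) attr(band, what, exact = TRUE)

# event-time rows eligible for a simultaneous band: positive survival and
# strictly below the largest uncensored observation (the variance scale at
# and beyond that point is not estimable)
band_range_idx <- function(fit, tmin, tmax, method) {
  crv <- fit$curve
  first_event <- crv$time[1L]
  if (method == "pointwise") {
    elig <- seq_len(nrow(crv))
  } else {
    elig <- which(crv$estimate > 0 & crv$time < fit$t_max_event)
    if (!length(elig)) {
      stop_survband(paste0(
        "no event times with positive survival strictly below the largest ",
        "uncensored observation: a simultaneous band cannot be anchored."
      ))
    }
  }
  tmin <- tmin %||% if (method %in% c("hw", "pointwise")) 0 else first_event
  tmax <- tmax %||% max(crv$time[elig])
  if (!is.numeric(tmin) || !is.numeric(tmax) || tmin >= tmax) {
    stop_usage("`tmin` must be smaller than `tmax`.")
  }
  if (method == "ep" && tmin < first_event) {
    stop_survband(paste0(
      "equal-precision bands are undefined at zero variance: `tmin` (",
      format(tmin), ") must be at or after the first event time (",
      format(first_event), ")."
    ))
  }
  if (method == "lr") tmin <- max(tmin, first_event)
  idx <- elig[crv$time[elig] >= tmin & crv$time[elig] <= tmax]
  if (!length(idx)) {
    stop_survband("no event times inside the requested [tmin, tmax] range.")
  }
  list(idx = idx, a = max(tmin, first_event), b = crv$time[max(idx)])
}

#' Confidence bands for a Kaplan-Meier survival curve
#'
#' One front door for every band this package implements.  `method`
#' chooses the construction:
#' \describe{
#'   \item{`"pointwise"`}{The naive band obtained by connecting pointwise
#'     Wald intervals; it does **not** have simultaneous coverage and is
#'     provided for comparison.}
#'   \item{`"gill"`}{Constant relative half-width
#'     \eqn{\hat S(t)\sqrt{\tau(b)/n}\; G_\gamma}, calibrated by the
#'     supremum of |Brownian motion| on \eqn{[0,1]}.}
#'   \item{`"hw"`}{Hall-Wellner: half-width
#'     \eqn{k_{1-\alpha} (1+\tau(t)) \hat S(t)/\sqrt n}, calibrated by the
#'     supremum of the |Brownian bridge| on \eqn{[0, K]},
#'     \eqn{K = \tau(b)/(1+\tau(b))}.}
#'   \item{`"ep"`}{Nair's equal-precision band: half-width
#'     \eqn{e_{1-\alpha}\, se(t)} — the pointwise interval's shape with a
#'     larger, simultaneous critical value.}
#'   \item{`"lr"`}{Likelihood-ratio band: inverts the nonparametric
#'     likelihood-ratio deviance at each event time; see [lr_band()].}
#'   \item{`"boot_hw"`}{Hall-Wellner shape with the critical value
#'     calibrated by the nonparametric bootstrap; see
#'     [bootstrap_hw_band()].}
#' }
#'
#' The `"log"` transform maps the Hall-Wellner or equal-precision band to
#' \eqn{\{\hat S^{1/\theta}, \hat S^{\theta}\}} and `"arcsin"` to the
#' arcsine-square-root limits; both keep the band inside \eqn{[0,1]}.
#' Transforms are defined for `method = "hw"` and `"ep"` only (the
#' likelihood-ratio band needs none: it lives in \eqn{[0,1]} by
#' construction).
#'
#' @param x A data frame of subject-level records or a [fit_km()] object.
#' @param method Band construction (see Details).
#' @param transform `"linear"`, `"log"` or `"arcsin"`.
#' @param level Simultaneous confidence level in (0, 1); any level is
#'   accepted (critical values are computed, not looked up).
#' @param tmin,tmax Time range \eqn{[a, b]} of the band.  Defaults: `tmin`
#'   is the first event time (0 for `"hw"` and `"pointwise"`); `tmax` is the
#'   largest event time with positive survival strictly below the largest
#'   uncensored observation, and a user `tmax` is capped there.
#' @param boot_reps Bootstrap replicates (`method = "boot_hw"` only).
#' @param seed Seed for the bootstrap resampling stream.
#' @param clamp Clamp linear limits into \eqn{[0,1]}?  Default `TRUE`.
#' @param time,event Column selections when `x` is a data frame.
#' @return A `km_band`: a tibble with columns `time`, `n_risk`, `n_event`,
#'   `estimate`, `std_err`, `lower`, `upper`, carrying the method,
#'   transform, level, range, critical value and method-specific
#'   diagnostics as attributes (see [glance.km_band()]).
#' @examples
#' df <- data.frame(time = 1:6, event = c(1, 1, 0, 1, 0, 1))
#' km_band(df, method = "hw", transform = "log", level = 0.95)
#' @export
km_band <- function(x, method = c("pointwise", "gill", "hw", "ep", "lr", "boot_hw"),
                    transform = c("linear", "log", "arcsin"),
                    level = 0.95, tmin = NULL, tmax = NULL,
                    boot_reps = 1000, seed = NULL, clamp = TRUE,
                    time = time, event = event) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  fit <- if (is_km_fit(x)) x else fit_km(x, time = {{ time }}, event = {{ event }})
  if (transform != "linear" && !method %in% c("hw", "ep")) {
    stop_usage(paste0(
      "`transform = \"", transform, "\"` is defined for methods \"hw\" and ",
      "\"ep\" only."
    ))
  }
  switch(method,
    pointwise = pointwise_band(fit, level = level, tmin = tmin, tmax = tmax, clamp = clamp),
    gill = gill_band(fit, level = level, tmin = tmin, tmax = tmax, clamp = clamp),
    hw = hall_wellner_band(fit,
      level = level, tmin = tmin, tmax = tmax,
      transform = transform, clamp = clamp
    ),
    ep = ep_band(fit,
      level = level, tmin = tmin, tmax = tmax,
      transform = transform, clamp = clamp
    ),
    lr = lr_band(fit, level = level, tmin = tmin, tmax = tmax),
    boot_hw = bootstrap_hw_band(fit,
      level = level, tmin = tmin, tmax = tmax,
      boot_reps = boot_reps, seed = seed, clamp = clamp
    )
  )
}

#' Naive pointwise Wald band (no simultaneous coverage)
#'
#' Joins the linear pointwise intervals over the event times.  Marginally
#' each interval has the stated coverage; as a band over a time range the
#' joint coverage is far below nominal (see [coverage_experiment()]).
#'
#' @inheritParams km_band
#' @param fit A [fit_km()] object.
#' @return A `km_band`; its diagnostics flag `simultaneous = FALSE`.
#' @export
pointwise_band <- function(fit, level = 0.95, tmin = NULL, tmax = NULL,
                           clamp = FALSE) {
  check_km_fit(fit)
  check_level(level)
  rng <- band_range_idx(fit, tmin, tmax, "pointwise")
  crv <- fit$curve
  z <- qnorm((1 + level) / 2)
  half <- z * crv$std_err[rng$idx]
  est <- crv$estimate[rng$idx]
  new_km_band(fit, rng$idx, est - half, est + half,
    method = "pointwise", transform = "linear", level = level,
    range = c(rng$a, rng$b),
    critical = new_critical_value(z, "normal", level, c(0, 0)),
    diagnostics = list(simultaneous = FALSE), clamp = clamp
  )
}

#' Gill band: constant relative half-width
#'
#' \eqn{\hat S(t) \pm \hat S(t) \sqrt{\tau(b)/n}\, G_\gamma} over
#' \eqn{[a, b]}, where \eqn{G_\gamma} is the level-\eqn{\gamma} quantile of
#' \eqn{\sup_{[0,1]} |W|}.  The half-width relative to the estimate is
#' constant in \eqn{t} (it uses the variance at the range end \eqn{b}
#' everywhere), which makes these bands wide at early times.
#'
#' @inheritParams pointwise_band
#' @return A `km_band`.
#' @export
gill_band <- function(fit, level = 0.95, tmin = NULL, tmax = NULL,
                      clamp = TRUE) {
  check_km_fit(fit)
  check_level(level)
  rng <- band_range_idx(fit, tmin, tmax, "gill")
  crv <- fit$curve
  tau_b <- crv$tau[max(rng$idx)]
  if (!is.finite(tau_b) || tau_b <= 0) {
    stop_survband("tau(b) must be positive and finite (no events before `tmax`).")
  }
  g_crit <- bm_sup_quantile(level)
  est <- crv$estimate[rng$idx]
  half <- est * sqrt(tau_b / fit$n) * as.numeric(g_crit)
  new_km_band(fit, rng$idx, est - half, est + half,
    method = "gill", transform = "linear", level = level,
    range = c(rng$a, rng$b), critical = g_crit,
    diagnostics = list(tau_b = tau_b), clamp = clamp
  )
}

#' Hall-Wellner band
#'
#' \eqn{\hat S(t) \pm k_{1-\alpha} (1 + \tau(t)) \hat S(t) / \sqrt{n}} over
#' \eqn{[a,b]}, with \eqn{k_{1-\alpha}} the level quantile of the Brownian
#' bridge supremum on \eqn{[0, K]}, \eqn{K = \tau(b)/(1+\tau(b))}.  The
#' lower range end may be 0.  `transform = "log"` uses
#' \eqn{\theta_{HW}(t) = \exp\{k_{1-\alpha}(1+\tau(t))/(\sqrt n \log \hat
#' S(t))\}} and `"arcsin"` uses \eqn{\gamma_{HW}(t) =
#' k_{1-\alpha}(1+\tau(t))/(2\sqrt n)}; see [transform_limits()].
#'
#' @inheritParams pointwise_band
#' @param transform `"linear"`, `"log"` or `"arcsin"`.
#' @return A `km_band`; diagnostics carry `K` and `tau_b`.
#' @export
hall_wellner_band <- function(fit, level = 0.95, tmin = NULL, tmax = NULL,
                              transform = c("linear", "log", "arcsin"),
                              clamp = TRUE) {
  check_km_fit(fit)
  check_level(level)
  transform <- match.arg(transform)
  rng <- band_range_idx(fit, tmin, tmax, "hw")
  crv <- fit$curve
  tau_b <- crv$tau[max(rng$idx)]
  kk <- tau_b / (1 + tau_b)
  k_crit <- bridge_sup_quantile(kk, level)
  k <- as.numeric(k_crit)
  est <- crv$estimate[rng$idx]
  tau_t <- crv$tau[rng$idx]
  rootn <- sqrt(fit$n)
  lims <- switch(transform,
    linear = {
      half <- k * (1 + tau_t) / rootn * est
      list(lower = est - half, upper = est + half)
    },
    log = {
      check_transform_domain(est, crv$time[rng$idx])
      theta <- exp(k * (1 + tau_t) / (rootn * log(est)))
      transform_limits(est, "log", theta)
    },
    arcsin = {
      check_transform_domain(est, crv$time[rng$idx])
      gam <- k * (1 + tau_t) / (2 * rootn)
      transform_limits(est, "arcsin", gam)
    }
  )
  new_km_band(fit, rng$idx, lims$lower, lims$upper,
    method = "hw", transform = transform, level = level,
    range = c(rng$a, rng$b), critical = k_crit,
    diagnostics = list(K = kk, tau_b = tau_b),
    clamp = clamp && transform == "linear"
  )
}

#' Equal-precision (Nair) band
#'
#' \eqn{\hat S(t) \pm e_{1-\alpha}\, se(t)} over \eqn{[a,b]}: proportional
#' to the pointwise standard error, differing from the pointwise interval
#' only in the critical value.  \eqn{e_{1-\alpha}} is the level quantile of
#' the standardised Brownian bridge supremum over the bridge-time window
#' \eqn{[x_L, x_U]}, \eqn{x_L = \tau(a)/(1+\tau(a))}, \eqn{x_U =
#' \tau(b)/(1+\tau(b))}.  The range must start at or after the first event
#' time (the standardisation needs positive variance).  `transform = "log"`
#' uses \eqn{\theta_{EP}(t) = \exp\{e_{1-\alpha}\sqrt{\tau(t)}/(\sqrt n \log
#' \hat S(t))\}} and `"arcsin"` uses \eqn{\gamma_{EP}(t) =
#' e_{1-\alpha}\sqrt{\tau(t)}/(2\sqrt n)}.
#'
#' @inheritParams hall_wellner_band
#' @return A `km_band`; diagnostics carry the bridge-time window.
#' @export
ep_band <- function(fit, level = 0.95, tmin = NULL, tmax = NULL,
                    transform = c("linear", "log", "arcsin"),
                    clamp = TRUE) {
  check_km_fit(fit)
  check_level(level)
  transform <- match.arg(transform)
  rng <- band_range_idx(fit, tmin, tmax, "ep")
  crv <- fit$curve
  tau_a <- crv$tau[min(rng$idx)]
  tau_b <- crv$tau[max(rng$idx)]
  x_lower <- tau_a / (1 + tau_a)
  x_upper <- tau_b / (1 + tau_b)
  e_crit <- ep_sup_quantile(x_lower, x_upper, level)
  e <- as.numeric(e_crit)
  est <- crv$estimate[rng$idx]
  tau_t <- crv$tau[rng$idx]
  rootn <- sqrt(fit$n)
  lims <- switch(transform,
    linear = {
      half <- e * crv$std_err[rng$idx]
      list(lower = est - half, upper = est + half)
    },
    log = {
      check_transform_domain(est, crv$time[rng$idx])
      theta <- exp(e * sqrt(tau_t) / (rootn * log(est)))
      transform_limits(est, "log", theta)
    },
    arcsin = {
      check_transform_domain(est, crv$time[rng$idx])
      gam <- e * sqrt(tau_t) / (2 * rootn)
      transform_limits(est, "arcsin", gam)
    }
  )
  new_km_band(fit, rng$idx, lims$lower, lims$upper,
    method = "ep", transform = transform, level = level,
    range = c(rng$a, rng$b), critical = e_crit,
    diagnostics = list(
      x_lower = x_lower, x_upper = x_upper,
      tau_a = tau_a, tau_b = tau_b
    ),
    clamp = clamp && transform == "linear"
  )
}

check_transform_domain <- function(est, times) {
  bad <- which(est <= 0 | est >= 1)
  if (length(bad)) {
    stop_survband(paste0(
      "transformed limits need survival estimates strictly inside (0, 1); ",
      "violated at time(s) ", paste(format(times[head(bad, 5L)]), collapse = ", "), "."
    ))
  }
  invisible(TRUE)
}

#' Transformed confidence limits for a survival probability
#'
#' `kind = "log"` maps an estimate \eqn{S} to
#' \eqn{(S^{1/\theta}, S^{\theta})}; since \eqn{\log S < 0} forces
#' \eqn{\theta < 1} for any positive band width, \eqn{S^{\theta}} is the
#' upper limit.  `kind = "arcsin"` gives
#' \deqn{lower = \sin^2(\max\{0, \arcsin\sqrt S - \gamma\sqrt{S/(1-S)}\}),}
#' \deqn{upper = \sin^2(\min\{\pi/2, \arcsin\sqrt S + \gamma\sqrt{S/(1-S)}\}).}
#' Both transforms keep the limits inside \eqn{[0,1]} and enclose the
#' estimate.
#'
#' @param estimate Survival values strictly inside (0, 1).
#' @param kind `"log"` or `"arcsin"`.
#' @param param \eqn{\theta > 0} for `"log"`; \eqn{\gamma \ge 0} for
#'   `"arcsin"`.  Recycled against `estimate`.
#' @return A list with components `lower` and `upper`.
#' @examples
#' transform_limits(0.5, "arcsin", 0.2)
#' @export
transform_limits <- function(estimate, kind = c("log", "arcsin"), param) {
  kind <- match.arg(kind)
  if (any(estimate <= 0 | estimate >= 1)) {
    stop_survband("`estimate` must be strictly inside (0, 1).")
  }
  if (kind == "log") {
    if (any(param <= 0)) stop_usage("log-transform `param` (theta) must be > 0.")
    list(lower = estimate^(1 / param), upper = estimate^param)
  } else {
    if (any(param < 0)) stop_usage("arcsin-transform `param` (gamma) must be >= 0.")
    centre <- asin(sqrt(estimate))
    offset <- param * sqrt(estimate / (1 - estimate))
    list(
      lower = sin(pmax(0, centre - offset))^2,
      upper = sin(pmin(pi / 2, centre + offset))^2
    )
  }
}

#' Band width profile
#'
#' @param band A `km_band`.
#' @return A tibble with columns `time` and `width` (`upper - lower`).
#' @export
band_width <- function(band) {
  if (!inherits(band, "km_band")) stop_usage("`band` must be a `km_band`.")
  tibble::tibble(time = band$time, width = band$upper - band$lower)
}

#' @export
print.km_band <- function(x, ...) {
  cat(sprintf(
    "%s confidence band (%s transform), level %.3g, range [%.4g, %.4g]\n",
    band_attr(x, "method"), band_attr(x, "transform"),
    band_attr(x, "level"), band_attr(x, "range")[1], band_attr(x, "range")[2]
  ))
  crit <- band_attr(x, "critical")
  if (!is.null(crit)) {
    cat(sprintf(
      "critical value %.4f (%s)\n", as.numeric(crit), attr(crit, "family")
    ))
  }
  NextMethod()
}

#' Tidy and summarise a `km_band`
#'
#' `tidy()` returns the band rows as a plain tibble; `glance()` returns a
#' one-row tibble of the band's metadata (method, transform, level, range,
#' critical value and the method's diagnostics that are scalar).
#'
#' @param x A `km_band`.
#' @param ... Unused.
#' @export
tidy.km_band <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.km_band
#' @export
glance.km_band <- function(x, ...) {
  diag <- band_attr(x, "diagnostics")
  scalars <- diag[vapply(diag, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  out <- tibble::tibble(
    method = band_attr(x, "method"),
    transform = band_attr(x, "transform"),
    level = band_attr(x, "level"),
    tmin = band_attr(x, "range")[1],
    tmax = band_attr(x, "range")[2],
    critical = as.numeric(band_attr(x, "critical")),
    critical_family = attr(band_attr(x, "critical"), "family"),
    n = band_attr(x, "n"),
    n_times = nrow(x)
  )
  if (length(scalars)) out <- dplyr::bind_cols(out, tibble::as_tibble(scalars))
  out
}
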