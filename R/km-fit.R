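#' Fit a Kaplan-Meier curve with Greenwood variance accumulations
#'
#' Estimates the product-limit survival curve \eqn{\hat S(t) = \prod_{t_i \le
#' t} (1 - d_i / n_i)} from right-censored follow-up data, together with the
#' Greenwood variance accumulations used by every confidence band in this
#' package:
#' \itemize{
#'   \item \eqn{g(t) = \sum_{t_i \le t} d_i / (n_i (n_i - d_i))} (the
#'     Greenwood sum),
#'   \item \eqn{\tau(t) = n\, g(t)} (the sample-size-scaled variance of
#'     \eqn{\hat S / S}, the time scale on which the limiting Gaussian
#'     process lives),
#'   \item \eqn{se(t) = \hat S(t) \sqrt{g(t)}} (the Greenwood standard
#'     error).
#' }
#'
#' Subjects censored at an event time are counted as still at risk at that
#' time (events precede censorings at ties).  Where \eqn{\hat S(t_i) = 0}
#' the Greenwood sum is infinite and the standard error is reported as 0
#' (the estimate is degenerate there).
#'
#' @param data A data frame with one row per subject.
#' @param time <[`tidy-select`][dplyr::dplyr_tidy_select]> Column of
#'   nonnegative follow-up times (any consistent unit).
#' @param event <[`tidy-select`][dplyr::dplyr_tidy_select]> Column of event
#'   indicators: 1/TRUE = event observed at `time`, 0/FALSE = right-censored.
#'
#' @return An object of class `km_fit`: a list with elements
#'   \item{curve}{tibble with one row per distinct event time: `time`,
#'     `n_risk`, `n_event`, `estimate`, `gw`, `tau`, `std_err`.}
#'   \item{n}{number of subjects.}
#'   \item{t_max_event}{largest observed (uncensored) event time.}
#'   \item{sample}{the subject-level data as a `time`/`event` tibble,
#'     retained for resampling.}
#'
#' @examples
#' df <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 0, 1))
#' fit <- fit_km(df)
#' tidy(fit)
#' @export
fit_km <- function(data, time = time, event = event) {
  if (!is.data.frame(data)) {
    stop_usage("`data` must be a data frame of subject-level records.")
  }
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  validate_sample(tm, ev)
  core <- km_compute(tm, as.integer(ev))
  new_km_fit(core, tibble::tibble(time = tm, event = as.integer(ev)))
}

validate_sample <- function(tm, ev) {
  if (length(tm) != length(ev)) {
    stop_survband("`time` and `event` must have the same length.")
  }
  if (length(tm) < 1L) {
    stop_survband("at least one subject is required.")
  }
  if (!is.numeric(tm)) {
    stop_survband("follow-up times must be numeric.")
  }
  bad <- which(!is.finite(tm) | tm < 0)
  if (length(bad)) {
    stop_survband(paste0(
      "follow-up times must be finite and nonnegative; offending row(s): ",
      paste(head(bad, 5L), collapse = ", "), "."
    ))
  }
  if (is.logical(ev)) ev <- as.integer(ev)
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad)) {
    stop_survband(paste0(
      "event indicators must be 0/1 (or FALSE/TRUE); offending row(s): ",
      paste(head(bad, 5L), collapse = ", "), "."
    ))
  }
  if (sum(ev) == 0) {
    stop_survband(
      "no events: every record is censored, so no survival curve (or band) can be estimated."
    )
  }
  invisible(TRUE)
}

# fast core used by the bootstrap and simulation loops: no tibbles, no checks
km_compute <- function(tm, ev) {
  n <- length(tm)
  ev_times <- tm[ev == 1L]
  ut <- sort(unique(ev_times))
  d <- tabulate(match(ev_times, ut), nbins = length(ut))
  # risk set: subjects with follow-up >= t (censoring ties stay at risk)
  n_risk <- n - findInterval(ut, sort(tm), left.open = TRUE)
  haz <- d / n_risk
  surv <- cumprod(1 - haz)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), Inf)
  gw <- cumsum(gw_terms)
  tau <- n * gw
  se <- ifelse(surv > 0, surv * sqrt(gw), 0)
  list(
    time = ut, n_risk = n_risk, n_event = d, estimate = surv,
    gw = gw, tau = tau, std_err = se,
    n = n, t_max_event = max(ev_times)
  )
}

new_km_fit <- function(core, sample) {
  structure(
    list(
      curve = tibble::tibble(
        time = core$time, n_risk = core$n_risk, n_event = core$n_event,
        estimate = core$estimate, gw = core$gw, tau = core$tau,
        std_err = core$std_err
      ),
      n = core$n,
      t_max_event = core$t_max_event,
      sample = sample
    ),
    class = "km_fit"
  )
}

is_km_fit <- function(x) inherits(x, "km_fit")

# right-continuous step lookup into the fitted curve; returns the row index
# of the largest event time <= t, or 0 before the first event
km_index <- function(fit, t) {
  step_index(fit$curve$time, t)
}

#' Greenwood variance of a fitted Kaplan-Meier curve at a time point
#'
#' Returns the step-function values, at the largest event time \eqn{\le t},
#' of the Greenwood sum `gw` \eqn{= g(t)}, the scaled variance `tau`
#' \eqn{= n g(t)} and the standard error `std_err`
#' \eqn{= \hat S(t)\sqrt{g(t)}}.
#'
#' @param fit A [fit_km()] object.
#' @param t Vector of evaluation times, each at or after the first event
#'   time (before the first event the Greenwood variance is identically
#'   zero and no variance statement is made).
#' @return A tibble with columns `time`, `estimate`, `gw`, `tau`, `std_err`.
#' @examples
#' fit <- fit_km(data.frame(time = 1:6, event = c(1, 1, 0, 1, 0, 1)))
#' km_variance(fit, 2)
#' @export
km_variance <- function(fit, t) {
  check_km_fit(fit)
  if (any(!is.finite(t))) stop_usage("`t` must be finite.")
  idx <- km_index(fit, t)
  if (any(idx == 0L)) {
    stop_survband(paste0(
      "variance undefined before the first event time (",
      format(fit$curve$time[1L]), ")."
    ))
  }
  tibble::tibble(
    time = t,
    estimate = fit$curve$estimate[idx],
    gw = fit$curve$gw[idx],
    tau = fit$curve$tau[idx],
    std_err = fit$curve$std_err[idx]
  )
}

check_km_fit <- function(fit) {
  if (!is_km_fit(fit)) {
    stop_usage("expected a `km_fit` object (see `fit_km()`).")
  }
  invisible(fit)
}

#' Linear (Wald) confidence interval from an estimate and standard error
#'
#' The normal-approximation interval \eqn{\hat S \pm z_{1-\alpha/2}\, se}.
#' This is the pointwise interval printed by standard survival software and
#' the building block of the naive "connect-the-intervals" band.
#'
#' @param estimate,std_err Numeric vectors (recycled).
#' @param level Confidence level in (0, 1).
#' @param clamp Clamp the limits into \eqn{[0,1]}?  Appropriate when the
#'   estimate is a probability.
#' @return A tibble with columns `estimate`, `std_err`, `lower`, `upper`,
#'   `level`.
#' @examples
#' wald_interval(0.507, 0.036) # the 95% interval, [0.44, 0.58] to 2 dp
#' @export
wald_interval <- function(estimate, std_err, level = 0.95, clamp = FALSE) {
  check_level(level)
  z <- qnorm((1 + level) / 2)
  lower <- estimate - z * std_err
  upper <- estimate + z * std_err
  if (clamp) {
    lower <- pmin(pmax(lower, 0), 1)
    upper <- pmin(pmax(upper, 0), 1)
  }
  tibble::tibble(
    estimate = estimate, std_err = std_err,
    lower = lower, upper = upper, level = level
  )
}

#' Pointwise Wald interval for the survival probability at given times
#'
#' @param fit A [fit_km()] object.
#' @param t Vector of times at or after the first event.
#' @param level Confidence level in (0, 1).
#' @param clamp Clamp limits into \eqn{[0,1]}?  Default `TRUE` for user
#'   output; internal coverage experiments use the raw linear limits.
#' @return A tibble with columns `time`, `estimate`, `std_err`, `lower`,
#'   `upper`, `level`.
#' @examples
#' fit <- fit_km(data.frame(time = 1:6, event = c(1, 1, 0, 1, 0, 1)))
#' km_pointwise(fit, c(2, 4))
#' @export
km_pointwise <- function(fit, t, level = 0.95, clamp = TRUE) {
  v <- km_variance(fit, t)
  w <- wald_interval(v$estimate, v$std_err, level = level, clamp = clamp)
  tibble::tibble(
    time = t, estimate = v$estimate, std_err = v$std_err,
    lower = w$lower, upper = w$upper, level = level
  )
}

#' @export
print.km_fit <- function(x, ...) {
  n_events <- sum(x$curve$n_event)
  cat("Kaplan-Meier fit: ", x$n, " subjects, ", n_events, " events at ",
    nrow(x$curve), " distinct times\n",
    sep = ""
  )
  print(x$curve, ...)
  invisible(x)
}

#' @rdname fit_km
#' @param x,object A `km_fit` object.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) {
  x$curve
}

#' @rdname fit_km
#' @export
glance.km_fit <- function(x, ...) {
  crv <- x$curve
  med <- crv$time[crv$estimate <= 0.5]
  tibble::tibble(
    n = x$n,
    n_events = sum(crv$n_event),
    n_censored = x$n - sum(crv$n_event),
    n_event_times = nrow(crv),
    median_survival = if (length(med)) med[1L] else NA_real_,
    t_max_event = x$t_max_event
  )
}
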