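## Synthetic data and coverage experiments.  The study design: event times
## exponential with rate 1, censoring uniform on [0, 10] (about 10%
## censoring), n = 200 subjects, containment of the true curve
## S(t) = exp(-rate * t) checked over [0, 5] across 1000 replicates.  The
## defaults below ARE that design.

#' Simulate right-censored survival data
#'
#' Event times \eqn{T \sim} Exponential(`rate`), censoring times \eqn{C
#' \sim} Uniform(0, `cens_max`), observed follow-up \eqn{\min(T, C)} with
#' event indicator \eqn{1\{T \le C\}}.  With the defaults the expected
#' censoring fraction is \eqn{(1 - e^{-10})/10 \approx 0.10}.
#'
#' @param n Number of subjects.
#' @param rate Exponential event rate (> 0).
#' @param cens_max Upper limit of the uniform censoring window (> 0).
#' @param seed Seed for the simulation stream (restored afterwards);
#'   `NULL` uses the current stream.
#' @return A tibble with columns `time` and `event`.
#' @examples
#' simulate_survival(10, seed = 1)
#' @export
simulate_survival <- function(n = 200, rate = 1, cens_max = 10, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop_usage("`n` must be a positive count.")
  if (!is.numeric(rate) || rate <= 0) stop_usage("`rate` must be > 0.")
  if (!is.numeric(cens_max) || cens_max <= 0) stop_usage("`cens_max` must be > 0.")
  with_seed(seed, {
    tt <- rexp(n, rate = rate)
    cc <- runif(n, 0, cens_max)
    tibble::tibble(
      time = pmin(tt, cc),
      event = as.integer(tt <= cc)
    )
  })
}

# containment check returning the first violation time (NA if covered)
band_covers_detail <- function(band, rate, tmin, tmax, check = "times") {
  simultaneous <- !identical(band_attr(band, "diagnostics")$simultaneous, FALSE)
  rng <- band_attr(band, "range")
  tmin <- tmin %||% rng[1]
  # a simultaneous band makes no claim beyond its own range end; the naive
  # pointwise band is drawn (as software draws it) out to the requested end
  tmax <- if (simultaneous) min(tmax %||% rng[2], rng[2]) else tmax %||% rng[2]
  keep <- band$time <= tmax
  if (check == "times") {
    # rows where the estimate has hit zero carry a degenerate [0, 0]
    # "interval" (standard software prints NaN limits there) and make no
    # confidence claim
    keep <- keep & band$time >= tmin & band$upper > 0
  }
  if (!any(keep)) {
    stop_survband("the band is empty on the requested range.")
  }
  tt <- band$time[keep]
  lo <- band$lower[keep]
  up <- band$upper[keep]
  if (check == "times") {
    s_t <- exp(-rate * tt)
    ok <- s_t >= lo & s_t <= up
    if (all(ok)) {
      return(list(covered = TRUE, first_violation = NA_real_))
    }
    return(list(covered = FALSE, first_violation = tt[which(!ok)[1L]]))
  }
  starts <- pmax(tt, tmin)
  ends <- pmin(c(tt[-1L], tmax), tmax)
  live <- ends >= tmin & starts <= ends
  s_start <- exp(-rate * starts)
  s_end <- exp(-rate * ends)
  # S is continuous and decreasing, the limits are constant on each piece:
  # containment on a piece is exactly {S(start) <= upper} & {S(end) >= lower}
  ok <- !live | (s_start <= up & s_end >= lo)
  if (all(ok)) {
    list(covered = TRUE, first_violation = NA_real_)
  } else {
    i <- which(!ok)[1L]
    viol <- if (s_start[i] > up[i]) starts[i] else ends[i]
    list(covered = FALSE, first_violation = viol)
  }
}

#' Does a band contain the true exponential survival curve?
#'
#' Containment check of \eqn{S(t) = e^{-rate\, t}} against the
#' step-function band over \eqn{[tmin, tmax]}.  Two conventions:
#' \describe{
#'   \item{`check = "times"` (default)}{containment is required at the
#'     band's reported event times — the points at which survival software
#'     states the limits.  Rows where the estimate has hit zero are
#'     skipped: their "interval" is degenerate at 0 (standard software
#'     prints NaN limits there) and makes no confidence claim.}
#'   \item{`check = "pieces"`}{exact containment of the continuous curve
#'     against the right-continuous step band: on each constant piece,
#'     \eqn{S} is decreasing, so containment holds iff \eqn{S} at the piece
#'     start is below the upper limit and \eqn{S} at the piece end is above
#'     the lower limit.  This is at least as strict as any grid check and
#'     penalises the drop of \eqn{S} between event times, which no
#'     event-time-anchored band can follow.}
#' }
#' Containment starts at the first band time (no confidence statement is
#' made before the first event), and for a simultaneous band ends at the
#' band's own range end.
#'
#' @param band A `km_band`.
#' @param rate True exponential rate.
#' @param tmin,tmax Containment range; defaults to the band's range.
#' @param check `"times"` or `"pieces"` (see Details).
#' @return `TRUE`/`FALSE`, with the first violation time (or `NA`) in
#'   attribute `"first_violation"`.
#' @export
band_covers <- function(band, rate = 1, tmin = NULL, tmax = NULL,
                        check = c("times", "pieces")) {
  if (!inherits(band, "km_band")) stop_usage("`band` must be a `km_band`.")
  if (!is.numeric(rate) || rate <= 0) stop_usage("`rate` must be > 0.")
  check <- match.arg(check)
  res <- band_covers_detail(band, rate, tmin, tmax, check)
  structure(res$covered, first_violation = res$first_violation)
}

#' Simultaneous-coverage experiment under exponential survival
#'
#' Repeatedly simulates right-censored samples ([simulate_survival()]),
#' builds the requested band on each, and records the proportion of
#' replicates in which the true curve \eqn{S(t) = e^{-rate\,t}} stays
#' inside the band throughout the containment range.  With the default
#' design and `method = "pointwise"` the band covers the whole curve in
#' only about 39\% of replicates despite its 95\% pointwise level; the
#' simultaneous methods restore the nominal rate.
#'
#' Each replicate draws its own substream seeded deterministically from
#' (`seed`, replicate index), so individual replicates are reproducible.
#'
#' @inheritParams simulate_survival
#' @param method,transform,level Band construction, as in [km_band()].
#' @param reps Number of replicates.
#' @param tmin,tmax Containment range (the band's lower range end is never
#'   before the first event of a replicate).
#' @param check Containment convention, as in [band_covers()].
#' @param boot_reps Inner bootstrap replicates for `method = "boot_hw"`.
#' @param seed Master seed.
#' @return A one-row tibble (class `coverage_result`): `method`,
#'   `transform`, `level`, `n`, `reps`, `covered`, `coverage`, `mc_se`,
#'   `seed`, with the per-replicate first violation times in attribute
#'   `"failures"`.
#' @examples
#' coverage_experiment(method = "pointwise", n = 50, reps = 20, seed = 1)
#' @export
coverage_experiment <- function(method = "pointwise", transform = "linear",
                                level = 0.95, n = 200, reps = 1000,
                                rate = 1, cens_max = 10,
                                tmin = 0, tmax = 5,
                                check = c("times", "pieces"),
                                boot_reps = 500, seed = 1) {
  check_level(level)
  check <- match.arg(check)
  if (!is.numeric(reps) || reps < 1) stop_usage("`reps` must be >= 1.")
  reps <- as.integer(reps)
  if (tmin >= tmax) stop_usage("`tmin` must be smaller than `tmax`.")
  failures <- rep(NA_real_, reps)
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    smp <- simulate_survival(n, rate, cens_max, seed = replicate_seed(seed, i))
    fit <- fit_km(smp)
    band_tmin <- if (tmin <= fit$curve$time[1L]) NULL else tmin
    band <- km_band(fit,
      method = method, transform = transform, level = level,
      tmin = band_tmin, tmax = tmax, boot_reps = boot_reps,
      seed = replicate_seed(seed, i + reps), clamp = FALSE
    )
    res <- band_covers_detail(band, rate, tmin = band_tmin, tmax = tmax, check = check)
    covered[i] <- res$covered
    failures[i] <- res$first_violation
  }
  p <- mean(covered)
  out <- tibble::tibble(
    method = method, transform = transform, level = level,
    n = as.integer(n), reps = reps, covered = sum(covered), coverage = p,
    mc_se = sqrt(p * (1 - p) / reps), seed = seed
  )
  structure(out,
    failures = failures,
    class = c("coverage_result", class(out))
  )
}
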