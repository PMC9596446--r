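# a mid-size synthetic curve used across band tests
band_test_fit <- function() {
  fit_km(simulate_survival(n = 120, seed = 2024))
}

test_that("wald-shaped simultaneous bands contain the pointwise band on their range", {
  fit <- band_test_fit()
  pw <- pointwise_band(fit, 0.95, clamp = FALSE)
  for (m in c("gill", "hw", "ep")) {
    band <- km_band(fit, method = m, level = 0.95, clamp = FALSE)
    i <- match(band$time, pw$time)
    expect_true(all(band$lower <= pw$lower[i] + 1e-9), label = paste(m, "lower"))
    expect_true(all(band$upper >= pw$upper[i] - 1e-9), label = paste(m, "upper"))
  }
  # the likelihood-ratio band has a different (likelihood) shape: it need
  # not contain the Wald interval endpoint-by-endpoint, but it is wider
  lr <- km_band(fit, method = "lr", level = 0.95)
  i <- match(lr$time, pw$time)
  expect_true(all((lr$upper - lr$lower) > (pw$upper - pw$lower)[i]))
})

test_that("bands nest in the confidence level", {
  fit <- band_test_fit()
  for (m in c("pointwise", "gill", "hw", "ep", "lr")) {
    lo <- km_band(fit, method = m, level = 0.90, clamp = FALSE)
    hi <- km_band(fit, method = m, level = 0.99, clamp = FALSE)
    expect_true(all(hi$lower <= lo$lower + 1e-9), label = m)
    expect_true(all(hi$upper >= lo$upper - 1e-9), label = m)
  }
})

test_that("gill band has constant relative half-width scaled 2.2414/1.96 vs pointwise at b", {
  fit <- fit_km(fixture_censored())
  g <- gill_band(fit, 0.95, clamp = FALSE)
  rel <- (g$upper - g$estimate) / g$estimate
  expect_equal(max(rel) - min(rel), 0, tolerance = 1e-12)
  # at t = b the pointwise and Gill half-widths share the scale S(b)*sqrt(g(b)),
  # so their ratio is exactly the ratio of critical values
  pw <- pointwise_band(fit, 0.95, clamp = FALSE)
  b <- max(g$time)
  ratio <- (g$upper - g$lower)[g$time == b] / (pw$upper - pw$lower)[pw$time == b]
  expect_equal(ratio, 2.2414 / qnorm(0.975), tolerance = 1e-3)
  # the critical value vanishes with the level, shrinking the band
  expect_lt(as.numeric(bm_sup_quantile(1e-6)), 0.35)
  tiny <- gill_band(fit, 1e-6, clamp = FALSE)
  mid <- gill_band(fit, 0.95, clamp = FALSE)
  expect_true(all(tiny$upper - tiny$lower < (mid$upper - mid$lower) / 5))
})

test_that("hall-wellner band follows the formula and its bridge-time endpoint", {
  fit <- fit_km(fixture_censored()) # tau = (0.2, 0.5, 1.5) at times 1, 2, 4
  hw <- hall_wellner_band(fit, 0.95, clamp = FALSE)
  gl <- glance(hw)
  expect_equal(gl$K, 1.5 / 2.5) # tau(b)/(1+tau(b))
  k <- as.numeric(attr(hw, "critical"))
  expect_equal(
    hw$upper - hw$estimate,
    k * (1 + c(0.2, 0.5, 1.5)) / sqrt(6) * hw$estimate,
    tolerance = 1e-12
  )
  # the range end is capped strictly below the largest uncensored
  # observation: here the last event (t = 2) is ineligible, so b = 1 with
  # tau(1) = 1/3 and K = tau/(1 + tau) = 1/4
  fit2 <- fit_km(data.frame(time = 1:4, event = c(1, 1, 0, 0)))
  hw2 <- hall_wellner_band(fit2, 0.95)
  expect_equal(max(hw2$time), 1)
  expect_equal(glance(hw2)$K, (1 / 3) / (4 / 3))
})

test_that("log transform orders the limits by theta < 1 and stays in [0,1]", {
  fit <- band_test_fit()
  for (m in c("hw", "ep")) {
    band <- km_band(fit, method = m, transform = "log", level = 0.95)
    expect_true(all(band$lower >= 0 & band$upper <= 1))
    expect_true(all(band$lower < band$estimate & band$estimate < band$upper))
    # reconstruct theta from the upper limit: upper = S^theta with theta < 1
    theta <- log(band$upper) / log(band$estimate)
    expect_true(all(theta < 1 & theta > 0))
    expect_equal(band$lower, band$estimate^(1 / theta), tolerance = 1e-9)
  }
})

test_that("transform_limits handles identity, saturation and domain errors", {
  id_log <- transform_limits(0.5, "log", 1)
  expect_equal(c(id_log$lower, id_log$upper), c(0.5, 0.5))
  id_asin <- transform_limits(0.5, "arcsin", 0)
  expect_equal(c(id_asin$lower, id_asin$upper), c(0.5, 0.5))
  sat <- transform_limits(0.5, "arcsin", 50)
  expect_equal(c(sat$lower, sat$upper), c(0, 1))
  expect_error(transform_limits(1, "log", 0.5), "inside")
  expect_error(transform_limits(0.5, "log", -1), "theta")
  # enclosure for a grid of estimates and parameters
  s <- seq(0.05, 0.95, by = 0.1)
  for (gam in c(0.05, 0.3, 1)) {
    lims <- transform_limits(s, "arcsin", gam)
    expect_true(all(lims$lower >= 0 & lims$upper <= 1))
    expect_true(all(lims$lower <= s & s <= lims$upper))
  }
})

test_that("arcsine bands apply the transform with the method's gamma", {
  fit <- fit_km(fixture_censored())
  hw <- hall_wellner_band(fit, 0.95, transform = "arcsin")
  k <- as.numeric(attr(hw, "critical"))
  gam <- k * (1 + c(0.2, 0.5, 1.5)) / (2 * sqrt(6))
  ref <- transform_limits(hw$estimate, "arcsin", gam)
  expect_equal(hw$lower, ref$lower, tolerance = 1e-12)
  expect_equal(hw$upper, ref$upper, tolerance = 1e-12)
})

test_that("equal-precision band is the pointwise shape with a larger multiplier", {
  fit <- band_test_fit()
  ep <- ep_band(fit, 0.95, clamp = FALSE)
  e <- as.numeric(attr(ep, "critical"))
  expect_gt(e, qnorm(0.975))
  expect_equal(ep$upper - ep$estimate, e * ep$std_err, tolerance = 1e-12)
  # degenerate range: one event time only, e collapses to the normal quantile
  t1 <- fit$curve$time[5]
  ep1 <- ep_band(fit, 0.95, tmin = t1, tmax = fit$curve$time[6] - 1e-9, clamp = FALSE)
  expect_equal(as.numeric(attr(ep1, "critical")), qnorm(0.975))
  pw <- km_pointwise(fit, t1, clamp = FALSE)
  expect_equal(ep1$lower[1], pw$lower, tolerance = 1e-9)
  # the range must not start before the first event
  expect_error(ep_band(fit, 0.95, tmin = 0), "zero variance")
})

test_that("band_width orders the methods as expected", {
  fit <- band_test_fit()
  pw <- band_width(pointwise_band(fit, 0.95, clamp = FALSE))
  for (m in c("gill", "hw", "ep", "lr")) {
    w <- band_width(km_band(fit, method = m, level = 0.95, clamp = FALSE))
    i <- match(w$time, pw$time)
    expect_true(all(w$width > pw$width[i] - 1e-9), label = m)
    expect_true(all(w$width >= 0), label = m)
  }
  # HW width increases whenever tau increases (unclamped linear band)
  hw <- hall_wellner_band(fit, 0.95, clamp = FALSE)
  w <- band_width(hw)$width / hw$estimate
  expect_true(all(diff(w) > -1e-12))
})

test_that("km_band validates method/transform combinations and input", {
  df <- fixture_censored()
  expect_s3_class(km_band(df, method = "hw", transform = "log"), "km_band")
  expect_error(km_band(df, method = "gill", transform = "log"), "transform")
  expect_error(km_band(df, method = "lr", transform = "arcsin"), "transform")
  expect_error(km_band(df, method = "hw", tmin = 5, tmax = 2), "tmin")
  fit <- fit_km(df)
  expect_error(hall_wellner_band(fit, level = 1.5), "level")
})

test_that("linear limits are clamped only when requested", {
  fit <- fit_km(fixture_censored())
  raw <- pointwise_band(fit, 0.95, clamp = FALSE)
  expect_gt(max(raw$upper), 1)
  clamped <- pointwise_band(fit, 0.95, clamp = TRUE)
  expect_lte(max(clamped$upper), 1)
  expect_gte(min(clamped$lower), 0)
})

test_that("band CSV metadata and glance expose the calibration", {
  fit <- fit_km(fixture_censored())
  hw <- hall_wellner_band(fit, 0.95)
  gl <- glance(hw)
  expect_equal(gl$method, "hw")
  expect_equal(gl$critical, as.numeric(attr(hw, "critical")))
  expect_equal(gl$n, 6L)
})
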