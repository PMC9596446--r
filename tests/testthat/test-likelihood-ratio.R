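# independent brute-force oracle for the profile deviance: maximise the
# discrete-hazard likelihood subject to prod(1 - h_i) = p by optimising the
# allocation of log p across the per-time log survival contributions
brute_force_deviance <- function(d, n_risk, p) {
  m <- length(d)
  loglik <- function(h) sum(d * log(h) + (n_risk - d) * log(1 - h))
  h_hat <- d / n_risk
  if (m == 1L) {
    return(2 * (loglik(h_hat) - loglik(1 - p)))
  }
  obj <- function(theta) {
    w <- exp(c(theta, 0))
    w <- w / sum(w)
    h <- 1 - exp(log(p) * w) # prod(1-h) = p by construction
    -loglik(h)
  }
  best <- Inf
  for (start in list(rep(0, m - 1), rep(0.5, m - 1), rep(-0.5, m - 1))) {
    o <- optim(start, obj, method = "BFGS", control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, o$value)
  }
  2 * (loglik(h_hat) + best)
}

test_that("constrained survival is anchored at lambda = 0 and monotone", {
  fit <- fit_km(fixture_censored())
  expect_equal(constrained_survival(fit, 4, 0), 4 / 9)
  expect_equal(constrained_survival(fit, 2, 0), 2 / 3)
  # hazards vanish as lambda grows
  expect_gt(constrained_survival(fit, 4, 1e8), 1 - 1e-6)
  lams <- c(-1, 0, 2, 10)
  s <- vapply(lams, function(l) constrained_survival(fit, 4, l), numeric(1))
  expect_true(all(diff(s) > 0))
  # the pole is rejected
  expect_error(constrained_survival(fit, 4, -10), "pole")
})

test_that("deviance vanishes at the KM estimate and matches the binomial closed form", {
  fit4 <- fit_km(fixture_complete(4))
  expect_identical(neg2_log_R(fit4, 2.5, 0.5), 0)
  # no censoring: empirical likelihood for a proportion, closed form
  expect_equal(neg2_log_R(fit4, 2.5, 0.25), 4 * log(4 / 3), tolerance = 1e-9)
  binom_dev <- function(n, k, p) 2 * (k * log(k / (n * p)) + (n - k) * log((n - k) / (n * (1 - p))))
  for (p in c(0.1, 0.35, 0.6, 0.9)) {
    expect_equal(neg2_log_R(fit4, 2.5, p), binom_dev(4, 2, p), tolerance = 1e-8)
  }
})

test_that("deviance increases monotonically away from the estimate", {
  fit <- fit_km(fixture_censored())
  s_hat <- 2 / 3
  up <- vapply(seq(s_hat + 0.02, 0.98, by = 0.04), function(p) neg2_log_R(fit, 2, p), numeric(1))
  dn <- vapply(seq(s_hat - 0.02, 0.02, by = -0.04), function(p) neg2_log_R(fit, 2, p), numeric(1))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
})

test_that("deviance matches a brute-force constrained maximisation", {
  for (seed in 1:5) {
    df <- random_fixture_with_events(n = 12, seed = seed)
    fit <- fit_km(df)
    crv <- fit$curve
    ok <- crv$estimate > 0
    t_eval <- max(crv$time[ok])
    i <- which(crv$time == t_eval)
    d <- crv$n_event[seq_len(i)]
    nr <- crv$n_risk[seq_len(i)]
    s_hat <- crv$estimate[i]
    for (p in c(0.8 * s_hat, pmin(0.98, s_hat + 0.6 * (1 - s_hat)))) {
      expect_equal(
        neg2_log_R(fit, t_eval, p),
        brute_force_deviance(d, nr, p),
        tolerance = 1e-6
      )
    }
  }
})

test_that("TG intervals match binomial empirical likelihood without censoring", {
  fit <- fit_km(fixture_complete(8)) # S(4.5) = 0.5, k = 4 survivors
  ti <- tg_interval(fit, 4.5, 0.95)
  binom_dev <- function(p) 2 * (4 * log(4 / (8 * p)) + 4 * log(4 / (8 * (1 - p))))
  thr <- qchisq(0.95, 1)
  lo <- uniroot(function(p) binom_dev(p) - thr, c(1e-6, 0.5 - 1e-9), tol = 1e-12)$root
  hi <- uniroot(function(p) binom_dev(p) - thr, c(0.5 + 1e-9, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(ti$lower, lo, tolerance = 1e-7)
  expect_equal(ti$upper, hi, tolerance = 1e-7)
  # always inside [0,1] and collapsing with the level
  expect_true(ti$lower > 0 && ti$upper < 1)
  tiny <- tg_interval(fit, 4.5, 1e-8)
  expect_equal(c(tiny$lower, tiny$upper), c(0.5, 0.5), tolerance = 1e-4)
})

test_that("alpha_star implements the rescaling chain", {
  # two events among four subjects then censoring: tau(b) = 1
  fit <- fit_km(data.frame(time = 1:4, event = c(1, 1, 0, 0)))
  a <- alpha_star(fit, 2, 0.95)
  expect_equal(a$A_hat, 1)
  expect_equal(a$d_hat, 0.5)
  expect_equal(a$k, as.numeric(bridge_sup_quantile(0.5, 0.95)), tolerance = 1e-9)
  expect_equal(a$C_hat, 2 * a$k)
  expect_equal(a$alpha_star, pchisq(4 * a$k^2, 1, lower.tail = FALSE))
  # simultaneity costs pointwise level
  expect_lt(a$alpha_star, 0.05)
  expect_gte(a$C_hat, a$k)
})

test_that("lr_band lives in [0,1] and relates to the TG interval as promised", {
  fit <- fit_km(simulate_survival(n = 120, seed = 99))
  full <- lr_band(fit, 0.95)
  expect_true(all(full$lower >= 0 & full$upper <= 1))
  # a moderate range end keeps alpha* representable for the comparisons below
  band <- lr_band(fit, 0.95, tmax = 0.7)
  expect_true(all(band$lower >= 0 & band$upper <= 1))
  expect_true(all(band$lower <= band$estimate & band$estimate <= band$upper))
  # fixed-threshold variant: at every time it is the TG interval at level
  # 1 - alpha*, hence strictly contains the TG interval at the nominal level
  bandf <- lr_band(fit, 0.95, tmax = 0.7, threshold = "fixed")
  astar <- glance(bandf)$alpha_star
  for (t in bandf$time[c(1, 5, nrow(bandf))]) {
    ref <- tg_interval(fit, t, 1 - astar)
    i <- which(bandf$time == t)
    expect_equal(bandf$lower[i], ref$lower, tolerance = 1e-7)
    expect_equal(bandf$upper[i], ref$upper, tolerance = 1e-7)
    nominal <- tg_interval(fit, t, 0.95)
    expect_lt(bandf$lower[i], nominal$lower)
    expect_gt(bandf$upper[i], nominal$upper)
  }
  # time-varying threshold agrees with the fixed one at t = b
  b <- max(band$time)
  expect_equal(
    band$lower[band$time == b], bandf$lower[bandf$time == b],
    tolerance = 1e-9
  )
  expect_equal(
    band$upper[band$time == b], bandf$upper[bandf$time == b],
    tolerance = 1e-9
  )
})

test_that("likelihood machinery rejects undefined inputs", {
  fit <- fit_km(fixture_censored())
  expect_error(neg2_log_R(fit, 0.5, 0.5), "first event")
  expect_error(neg2_log_R(fit, 2, 1.2), "inside")
  expect_error(neg2_log_R(fit, 6, 0.5), "reaches 0")
  expect_error(tg_interval(fit, 6, 0.95), "reaches 0")
})
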