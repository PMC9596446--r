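## Quantiles and probabilities of the Gaussian-process suprema that
## calibrate each simultaneous band:
##   bm_sup:      sup_{0<x<1} |W(x)|            (Brownian motion)   -> Gill
##   bridge_sup:  sup_{0<=t<=d} |B(t)|          (Brownian bridge)   -> Hall-Wellner, LR
##   ep_sup:      sup_{xL<=x<=xU} |B(x)|/sqrt(x(1-x))               -> equal precision
## Everything is computed directly (series / numerical integration / Monte
## Carlo), so any confidence level in (0,1) can be used.

new_critical_value <- function(value, family, level, domain,
                               method = "analytic", mc_error = NA_real_) {
  structure(
    value,
    family = family, level = level, domain = domain,
    method = method, mc_error = mc_error,
    class = "critical_value"
  )
}

#' @export
print.critical_value <- function(x, ...) {
  dom <- paste(format(attr(x, "domain"), digits = 4), collapse = ", ")
  cat(
    sprintf(
      "<critical value %s: %.6g (level %s, domain [%s], %s%s)>\n",
      attr(x, "family"), as.numeric(x), format(attr(x, "level")), dom,
      attr(x, "method"),
      if (is.finite(attr(x, "mc_error"))) {
        sprintf(", mc se %.2g", attr(x, "mc_error"))
      } else {
        ""
      }
    )
  )
  invisible(x)
}

## ---- Brownian motion: sup_{[0,1]} |W| --------------------------------------

# P(sup_{0<=x<=1} |W(x)| <= q), reflection series
# (4/pi) sum_{k>=0} (-1)^k/(2k+1) exp(-pi^2 (2k+1)^2 / (8 q^2))
bm_sup_cdf <- function(q) {
  vapply(q, function(x) {
    if (!is.finite(x) || x <= 0) {
      return(if (is.finite(x)) 0 else 1)
    }
    k <- 0:ceiling(8 * max(1, x)) # exponent decays like (2k+1)^2 / x^2
    s <- sum((-1)^k / (2 * k + 1) * exp(-pi^2 * (2 * k + 1)^2 / (8 * x^2)))
    min(max(4 / pi * s, 0), 1)
  }, numeric(1))
}

#' Critical values for the supremum of Brownian-motion and bridge processes
#'
#' `bm_sup_quantile()` returns the value \eqn{G_\gamma} with
#' \eqn{P\{\sup_{0<x<1} |W(x)| \le G_\gamma\} = \gamma} for standard
#' Brownian motion \eqn{W}; this is the Gill-band critical value.
#'
#' `bridge_sup_prob()` and `bridge_sup_quantile()` give the distribution of
#' \eqn{\sup_{0 \le t \le d} |B(t)|} for a standard Brownian bridge
#' \eqn{B} on \eqn{[0,1]}; at \eqn{d = 1} this is the Kolmogorov
#' distribution.  The restricted case \eqn{d < 1} is computed exactly by
#' conditioning on \eqn{B(d)} (method-of-images absorption series under the
#' conditional Brownian-motion law, integrated against the
#' \eqn{N(0, d(1-d))} law of the endpoint).  This is the Hall-Wellner
#' critical value \eqn{k_{1-\alpha}} with \eqn{d = K = \tau(b)/(1+\tau(b))}.
#'
#' `ep_sup_quantile()` returns \eqn{e_{1-\alpha}} with
#' \eqn{P\{\sup_{x_L \le x \le x_U} |B(x)|/\sqrt{x(1-x)} \le e\} = } `level`,
#' the equal-precision critical value.  The default solves the
#' Miller-Siegmund tail approximation
#' \deqn{\alpha \approx 4\phi(e)/e + \phi(e)(e - 1/e)
#'   \log\{x_U(1-x_L)/(x_L(1-x_U))\},}
#' which is the approximation production software uses for these bands;
#' `method = "mc"` estimates the quantile by Monte Carlo instead (the
#' standardised bridge is a stationary Ornstein-Uhlenbeck process on the
#' log-odds time scale and is simulated exactly on a grid with a
#' segment-maximum correction).
#'
#' @param level Confidence level in (0, 1).
#' @param d Bridge-time endpoint, \eqn{0 < d \le 1}.
#' @param q Threshold (nonnegative).
#' @param x_lower,x_upper Bridge-time window, \eqn{0 < x_L \le x_U < 1}.
#' @param method For `ep_sup_quantile()`: `"approx"` (default) or `"mc"`.
#' @param paths,grid,seed Monte Carlo settings for `method = "mc"`.
#' @return Quantile functions return a `critical_value`: a number carrying
#'   the family, level, domain and method as attributes.
#'   `bridge_sup_prob()` returns a bare probability.
#' @examples
#' bm_sup_quantile(0.95) # ~2.2414
#' bridge_sup_quantile(1, 0.95) # Kolmogorov: ~1.3581
#' ep_sup_quantile(0.1, 0.6, 0.95)
#' @export
bm_sup_quantile <- function(level) {
  check_level(level)
  root <- uniroot(function(x) bm_sup_cdf(x) - level,
    lower = 1e-6, upper = 20, tol = 1e-10
  )
  new_critical_value(root$root,
    family = "bm_sup", level = level, domain = c(0, 1)
  )
}

## ---- Brownian bridge: sup_{[0,d]} |B| --------------------------------------

# Kolmogorov distribution P(sup |B| <= q) on the full bridge
kolmogorov_cdf <- function(q) {
  if (q <= 0) {
    return(0)
  }
  if (q < 1) {
    # dual theta series, accurate for small q
    k <- 1:20
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * q^2)))
    return(min(max(sqrt(2 * pi) / q * s, 0), 1))
  }
  k <- 1:20
  min(max(1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * q^2)), 0), 1)
}

#' @rdname bm_sup_quantile
#' @export
bridge_sup_prob <- function(d, q) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1) {
    stop_usage("`d` must be a single value in (0, 1].")
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stop_usage("`q` must be a single nonnegative number.")
  }
  if (q == 0) {
    return(0)
  }
  if (d == 1) {
    return(kolmogorov_cdf(q))
  }
  if (q / sqrt(d) < 0.18) {
    return(0) # below ~1e-20; the images series would need huge k
  }
  sd_end <- sqrt(d * (1 - d))
  # conditional two-sided absorption probability given W(d) = y, times the
  # bridge endpoint density; substitution y = u * sd_end keeps the
  # integrand O(1) even as d -> 1
  integrand <- function(u) {
    y <- u * sd_end
    tot <- numeric(length(y))
    k <- 0L
    repeat {
      if (k == 0L) {
        term <- 1 - exp((y^2 - (2 * q - y)^2) / (2 * d))
      } else {
        term <-
          exp((y^2 - (y - 4 * k * q)^2) / (2 * d)) -
          exp((y^2 - (2 * q - y + 4 * k * q)^2) / (2 * d)) +
          exp((y^2 - (y + 4 * k * q)^2) / (2 * d)) -
          exp((y^2 - (2 * q - y - 4 * k * q)^2) / (2 * d))
      }
      tot <- tot + term
      k <- k + 1L
      if (k > 3L && max(abs(term)) < 1e-16) break
      if (k > 1e5L) break
    }
    tot * dnorm(u)
  }
  lim <- min(q / sd_end, 8.5)
  p <- integrate(integrand, -lim, lim, rel.tol = 1e-10, abs.tol = 1e-12)$value
  min(max(p, 0), 1)
}

#' @rdname bm_sup_quantile
#' @export
bridge_sup_quantile <- function(d, level) {
  check_level(level)
  root <- uniroot(function(x) bridge_sup_prob(d, x) - level,
    lower = 1e-6, upper = 10, tol = 1e-9
  )
  new_critical_value(root$root,
    family = "bridge_sup", level = level, domain = c(0, d)
  )
}

## ---- standardised bridge: sup |B(x)|/sqrt(x(1-x)) on [xL, xU] --------------

check_ep_window <- function(x_lower, x_upper) {
  if (!is.numeric(x_lower) || !is.numeric(x_upper) ||
      length(x_lower) != 1L || length(x_upper) != 1L ||
      x_lower <= 0 || x_upper >= 1 || x_lower > x_upper) {
    stop_usage("the window must satisfy 0 < x_lower <= x_upper < 1.")
  }
}

# log-odds half-length of the window: the standardised bridge is a
# stationary OU process in s = log(x/(1-x))/2, so the window has OU length
# 2T = log( xU(1-xL) / (xL(1-xU)) )
ep_log_window <- function(x_lower, x_upper) {
  log(x_upper * (1 - x_lower) / (x_lower * (1 - x_upper)))
}

ep_tail_approx <- function(e, L) {
  4 * dnorm(e) / e + dnorm(e) * (e - 1 / e) * L
}

#' @rdname bm_sup_quantile
#' @export
ep_sup_quantile <- function(x_lower, x_upper, level,
                            method = c("approx", "mc"),
                            paths = 4e4, grid = 2000, seed = 104003L) {
  check_ep_window(x_lower, x_upper)
  check_level(level)
  method <- match.arg(method)
  if (x_lower == x_upper) {
    # a single point: B(x)/sqrt(x(1-x)) is standard normal
    return(new_critical_value(qnorm((1 + level) / 2),
      family = "ep_sup", level = level, domain = c(x_lower, x_upper)
    ))
  }
  L <- ep_log_window(x_lower, x_upper)
  if (method == "approx") {
    alpha <- 1 - level
    z <- qnorm((1 + level) / 2)
    root <- uniroot(function(e) ep_tail_approx(e, L) - alpha,
      lower = max(z, 1), upper = 20, tol = 1e-9, extendInt = "downX"
    )
    return(new_critical_value(root$root,
      family = "ep_sup", level = level, domain = c(x_lower, x_upper),
      method = "approx"
    ))
  }
  mc_sup_oracle("ep_sup",
    x_lower = x_lower, x_upper = x_upper, level = level,
    paths = paths, grid = grid, seed = seed
  )
}

## ---- Monte-Carlo oracle ----------------------------------------------------

#' Monte-Carlo oracle for Gaussian-process supremum quantiles
#'
#' Simulates the supremum of the requested process and returns the empirical
#' `level` quantile with its Monte-Carlo standard error.  Paths are generated
#' exactly at the grid points and the supremum between grid points is drawn
#' from the exact Brownian-bridge segment-maximum law given the endpoints, so
#' the estimate carries no grid discretisation bias (for `ep_sup` the
#' segment law is the locally-Brownian approximation of the
#' Ornstein-Uhlenbeck segment, accurate for fine grids).  Used as the
#' independent ground truth for the analytic routines.
#'
#' @param family `"bm_sup"`, `"bridge_sup"` or `"ep_sup"`.
#' @param d Bridge-time endpoint for `bridge_sup` (and upper limit 1 for
#'   `bm_sup`).
#' @param x_lower,x_upper Window for `ep_sup`.
#' @param level Quantile level in (0, 1).
#' @param paths Number of simulated paths (>= 1000).
#' @param grid Number of grid steps (>= 64).
#' @param seed Seed for the simulation stream (restored afterwards).
#' @return A `critical_value` with `method = "monte_carlo"` and the
#'   estimated standard error of the quantile in `mc_error`.
#' @examples
#' mc_sup_oracle("bridge_sup", d = 1, level = 0.95, paths = 5000, grid = 256)
#' @export
mc_sup_oracle <- function(family = c("bm_sup", "bridge_sup", "ep_sup"),
                          d = 1, x_lower = NULL, x_upper = NULL,
                          level = 0.95, paths = 2e5, grid = 1e4,
                          seed = 104729L) {
  family <- match.arg(family)
  check_level(level)
  if (paths < 1000 || grid < 64) {
    stop_usage("`paths` must be >= 1000 and `grid` >= 64.")
  }
  paths <- as.integer(paths)
  grid <- as.integer(grid)
  sups <- with_seed(seed, switch(family,
    bm_sup = mc_sup_bm(paths, grid),
    bridge_sup = {
      if (d <= 0 || d > 1) stop_usage("`d` must be in (0, 1].")
      mc_sup_bridge(paths, grid, d)
    },
    ep_sup = {
      check_ep_window(x_lower, x_upper)
      mc_sup_ou(paths, grid, ep_log_window(x_lower, x_upper))
    }
  ))
  q_hat <- sort(sups)[ceiling(level * paths)]
  f_hat <- approx(density(sups), xout = q_hat)$y
  mc_se <- sqrt(level * (1 - level) / paths) / max(f_hat, 1e-6)
  dom <- switch(family,
    bm_sup = c(0, 1), bridge_sup = c(0, d), ep_sup = c(x_lower, x_upper)
  )
  new_critical_value(q_hat,
    family = family, level = level, domain = dom,
    method = "monte_carlo", mc_error = mc_se
  )
}

# exact max of a Brownian-bridge segment above its endpoints:
# given endpoints y0, y1 over time h, M - max(y0,y1) has the known
# inverse-exponential law; U ~ U(0,1)
segment_max <- function(y0, y1, h, u) {
  (y0 + y1 + sqrt((y1 - y0)^2 - 2 * h * log(u))) / 2
}

mc_sup_bm <- function(paths, grid) {
  h <- 1 / grid
  w <- numeric(paths)
  sup <- numeric(paths)
  for (i in seq_len(grid)) {
    w1 <- w + rnorm(paths, sd = sqrt(h))
    m_hi <- segment_max(w, w1, h, runif(paths))
    m_lo <- -segment_max(-w, -w1, h, runif(paths))
    sup <- pmax(sup, m_hi, -m_lo)
    w <- w1
  }
  sup
}

mc_sup_bridge <- function(paths, grid, d) {
  # bridge pinned at t = 1, simulated sequentially over [0, d]
  tt <- seq(0, d, length.out = grid + 1L)
  b <- numeric(paths)
  sup <- numeric(paths)
  for (i in seq_len(grid)) {
    t0 <- tt[i]
    t1 <- tt[i + 1L]
    h <- t1 - t0
    mean1 <- b * (1 - t1) / (1 - t0)
    sd1 <- sqrt(h * (1 - t1) / (1 - t0))
    b1 <- mean1 + if (sd1 > 0) rnorm(paths, sd = sd1) else 0
    m_hi <- segment_max(b, b1, h, runif(paths))
    m_lo <- -segment_max(-b, -b1, h, runif(paths))
    sup <- pmax(sup, m_hi, -m_lo)
    b <- b1
  }
  sup
}

mc_sup_ou <- function(paths, grid, two_t) {
  # stationary OU with corr exp(-|s-s'|) over an interval of length T =
  # two_t / 2; exact AR(1) at grid points, locally-Brownian (variance 2 ds)
  # segment-maximum correction in between
  t_len <- two_t / 2
  ds <- t_len / grid
  rho <- exp(-ds)
  innov_sd <- sqrt(1 - rho^2)
  h_eff <- 2 * ds
  z <- rnorm(paths)
  sup <- abs(z)
  for (i in seq_len(grid)) {
    z1 <- rho * z + innov_sd * rnorm(paths)
    m_hi <- segment_max(z, z1, h_eff, runif(paths))
    m_lo <- -segment_max(-z, -z1, h_eff, runif(paths))
    sup <- pmax(sup, m_hi, -m_lo)
    z <- z1
  }
  sup
}
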