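---
title: "Simultaneous confidence bands for Kaplan-Meier curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous confidence bands for Kaplan-Meier curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survband)
```

## The problem

A Kaplan-Meier curve is a random *function* of time, yet the uncertainty
displayed with it is almost always a sequence of pointwise confidence
intervals joined into a band.  Each interval is valid at its own time
point; the connected band is not a valid confidence statement for the whole
curve, for the same reason that unadjusted multiple tests inflate the
type-I error.  Under a design where the truth is known (exponential
survival, uniform censoring, `coverage_experiment()`), the naive 95% band
contains the whole curve in well under half of the replicates, while
properly calibrated *simultaneous* bands restore the nominal rate.

This package implements the standard simultaneous constructions — Gill,
Hall-Wellner (HW), Nair's equal-precision (EP), the nonparametric
likelihood-ratio (LR) band, and a bootstrap-calibrated HW band — together
with direct computation of every critical value involved, so that any
confidence level in (0, 1) can be used rather than the three levels
precomputed tables allow.

## Variance conventions

All bands are driven by two accumulations attached to the fit by
`fit_km()`:

* the Greenwood sum \(g(t) = \sum_{t_i \le t} d_i /\{n_i(n_i-d_i)\}\),
  giving the familiar standard error \(se(t) = \hat S(t)\sqrt{g(t)}\);
* the scaled variance \(\tau(t) = n\,g(t)\), which estimates the variance
  of the limiting process of \(\sqrt n(\hat S/S - 1)\).

Centred and scaled, \(\sqrt n(\hat S(t) - S(t)) \approx -S(t)\,
W(\tau(t))\) with \(W\) a standard Brownian motion in the variance time
scale.  The bridge-time map \(x(t) = \tau(t)/(1+\tau(t)) \in (0,1)\)
converts that motion into a Brownian bridge \(B(x)\); every band below is a
statement about the supremum of one of these processes.  Ties of events and
censorings at the same time are resolved with events first (the censored
subject is still at risk).  All step functions are right-continuous, and
bands are reported at the distinct event times of their range — step
interpolation between rows is the caller's contract.

## The bands

With confidence level \(\gamma = 1-\alpha\) and a time range \([a, b]\):

* **Pointwise (for contrast):** \(\hat S(t) \pm z_{1-\alpha/2}\, se(t)\).
* **Gill:** \(\hat S(t) \pm \hat S(t)\sqrt{\tau(b)/n}\; G_\gamma\), where
  \(G_\gamma\) solves \(P\{\sup_{[0,1]}|W| \le G\} = \gamma\).  The
  relative half-width is constant — it uses the variance at \(b\)
  everywhere — which makes these bands needlessly wide early and they are
  generally not recommended; they are included for completeness.
* **Hall-Wellner:** \(\hat S(t) \pm k_{1-\alpha}\,(1+\tau(t))\hat
  S(t)/\sqrt n\), with \(k_{1-\alpha}\) the \(\gamma\)-quantile of
  \(\sup_{[0,K]}|B|\), \(K = x(b)\).  The lower range end may be 0.
* **Equal precision:** \(\hat S(t) \pm e_{1-\alpha}\, se(t)\) — exactly the
  pointwise shape with the larger multiplier \(e_{1-\alpha}\), the
  \(\gamma\)-quantile of \(\sup_{[x_L, x_U]} |B(x)|/\sqrt{x(1-x)}\) over
  the bridge-time window of the range.  The range must start at or after
  the first event (positive variance).
* **Likelihood ratio:** inverts the Thomas-Grunkemeier profile deviance
  \(-2\log R(p,t)\) at each event time against a simultaneous threshold
  (next section).  Its limits respect \([0,1]\) without any transformation.
* **Bootstrap HW:** the HW shape with \(k\) replaced by the empirical
  quantile of the resampled supremum statistic (below).

The `log` transform maps HW/EP bands to \(\{\hat S^{1/\theta}, \hat
S^{\theta}\}\) and `arcsin` to arcsine-square-root limits; both keep the
band inside \([0,1]\) and are the recommended forms in moderate samples.
For the arcsine limits we use the standard convention — lower limit
\(\sin^2(\max\{0,\, \arcsin\sqrt{\hat S} - \gamma\sqrt{\hat S/(1-\hat
S)}\})\), upper with \(\min\{\pi/2,\, \cdot + \gamma \cdot\}\) — so that
the limits are ordered and enclose the estimate.

### Range conventions

The upper range end \(b\) is capped at the largest event time that still
has positive survival and lies strictly below the largest uncensored
observation: at and beyond that point \(\tau\) is not estimable (the
Greenwood sum diverges when the estimate hits zero) and no simultaneous
calibration is possible.  A user-specified `tmax` beyond the cap is
truncated to it, and the band reports its effective range.

## Critical values

The package computes all three supremum distributions directly:

* \(\sup_{[0,1]}|W|\): the classical reflection series
  \(P(\cdot \le q) = (4/\pi)\sum_{k\ge 0} \frac{(-1)^k}{2k+1}
  e^{-\pi^2(2k+1)^2/(8q^2)}\), inverted by bisection.
* \(\sup_{[0,d]}|B|\), \(d<1\): conditioning on the endpoint
  \(B(d) \sim N(0, d(1-d))\).  Given \(B(d) = y\), the restricted path is
  Brownian motion conditioned to end at \(y\), whose two-sided absorption
  probability has the method-of-images series; integrating that series
  against the endpoint law (with the substitution \(y = u\sqrt{d(1-d)}\) so
  the integrand stays \(O(1)\) as \(d \to 1\)) gives the exact probability,
  and monotone root finding the quantile.  At \(d=1\) the Kolmogorov series
  is used.  Agreement with the Monte-Carlo oracle is within 0.003 at the
  levels used in practice.
* \(\sup_{[x_L,x_U]} |B(x)|/\sqrt{x(1-x)}\): on the log-odds time scale
  \(s = \tfrac12\log\{x/(1-x)\}\) the standardised bridge is a stationary
  Ornstein-Uhlenbeck process, and the two-sided boundary-crossing
  probability has the Miller-Siegmund tail approximation
  \(\alpha \approx 4\phi(e)/e + \phi(e)(e-1/e)\log\{x_U(1-x_L)/(x_L(1-x_U))\}\),
  the same approximation production survival software uses.  Solving it for
  \(e\) is the default; `ep_sup_quantile(..., method = "mc")` estimates the
  quantile by simulation instead.  Against the Monte-Carlo oracle the
  approximation is accurate to better than 0.007 at levels 0.90-0.99, both
  for moderate windows and for the near-full window.

`mc_sup_oracle()` is the independent ground truth used by the test suite:
paths are simulated exactly at the grid points (sequential bridge
conditioning; exact AR(1) for the OU form), and the supremum *between*
grid points is drawn from the exact Brownian-bridge segment-maximum law
given the endpoints, so the estimated quantile carries no first-order grid
bias.  Defaults (2e5 paths) put the Monte-Carlo standard error of a 95%
quantile near 0.002; the tests run it at 1e5 paths and a few hundred grid
steps, which keeps each comparison under ten seconds at the same accuracy
scale.

## The likelihood-ratio band

For fixed \(t\), the constrained maximiser of the censored-data
nonparametric likelihood subject to \(S(t) = p\) has discrete hazards
\(d_i/(n_i+\lambda)\) at the event times up to \(t\); the constraint is a
monotone function of the Lagrange multiplier \(\lambda\), so the profile
deviance \(-2\log R(p,t)\) is available in closed form once a single
one-dimensional root is solved.  Inverting the deviance at
\(\chi^2_{1,\gamma}\) gives the Thomas-Grunkemeier pointwise interval
(`tg_interval()`), which reduces exactly to binomial empirical likelihood
when there is no censoring.

For a *simultaneous* band, the deviance process at the true curve
converges to \(B(x(t))^2/\{x(t)(1-x(t))\}\).  The band inverts
\(-2\log R(p,t) \le C^2(t)\) with
\[
C^2(t) = k^2\,(1+\tau(t))^2/\tau(t),
\]
where \(k\) is the \(\gamma\)-quantile of \(\sup_{[0,\hat d]}|B|\) and
\(\hat d = x(b)\): with this choice the asymptotic coverage event is
exactly \(\{\sup_{[\approx 0, \hat d]}|B| \le k\}\), the same event that
calibrates the Hall-Wellner band.  This is the package's default
(`threshold = "time-varying"`).  The alternative `threshold = "fixed"`
applies the single constant \(C^2(b)\) at every time — equivalent to
running a pointwise likelihood-ratio routine at the rescaled confidence
level \(1-\alpha^*\) with \(\alpha^* = P\{\chi^2_1 > C^2(b)\}\)
(`alpha_star()`), which is the only option when such a routine accepts one
level.  The fixed threshold is exact at \(b\) but increasingly conservative
at earlier times as \(\tau(b)\) grows (the constant \(C(b) =
k(1+\tau(b))/\sqrt{\tau(b)}\) is unbounded in \(\tau(b)\)), and in the
wide-range simulation below it pushes simultaneous coverage to essentially
1; the time-varying threshold restores nominal coverage, which is why it
is the default.

Monotonicity of the band limits across time holds asymptotically but is
not guaranteed at finite \(n\); violations are counted and reported in the
band diagnostics (`monotone_violations`), never silently repaired.  In the
simulation design used here they are rare.

At tail times the threshold \(C^2(t)\) can exceed the largest deviance any
\(p < 1\) can produce before the constrained survival reaches 1 to machine
precision; the upper limit is then reported as 1 exactly.

## Bootstrap calibration

Following the resampling idea for these bands, `bootstrap_hw_band()` draws
\(d\) with-replacement resamples of the \((time, event)\) pairs, refits the
curve, and computes for each
\[
A^*_j = \sqrt n\, \sup_{t}\; \frac{|\hat S^*_j(t) - \hat S(t)|}
       {(1+\tau(t))\,\hat S(t)},
\]
the supremum over the original curve's event times in \([a,b]\) (both
curves are step functions jumping only there, so nothing is lost).  The
weight is the Hall-Wellner normalisation evaluated at \(t\); with it,
\(A^*\) converges to \(\sup_{[0,K]}|B|\) and its empirical
\(\gamma\)-quantile \(\hat k\) is a drop-in replacement for the analytic
\(k_{1-\alpha}\) at any level.  (A fixed weight \((1-K)\) taken at \(b\)
is sometimes written instead; it damps every interior time by
\((1-K)/(1-x(t))\), so its quantile calibrates nothing recognisable — with
\(K\) near 1 it collapses toward zero — and we do not use it.)  The
empirical quantile is the order statistic at \(\lceil \gamma d\rceil\)
(type-1), making runs bit-reproducible under a seed.  Resamples with no
events cannot be fit and are skipped and counted; more than 1% of them
aborts the calibration.  At \(n = 500\), \(d = 2000\), over a range ending
near the median survival time, the bootstrap \(\hat k\) lands within ~0.03
of the analytic bridge quantile.

## The coverage harness

`simulate_survival()` draws event times \(T \sim\) Exp(rate 1) and
censoring \(C \sim U(0, 10)\) — about 10% censoring — with \(n = 200\) by
default; `coverage_experiment()` repeats the draw (1000 replicates by
default, per-replicate substreams derived from one master seed), builds the
requested band, and checks whether \(S(t) = e^{-t}\) stays inside it over
\([0, 5]\).  This design follows the true curve essentially to extinction
(\(S(5) \approx 0.007\)), which is deliberately harsh: roughly half the
replicates exhaust their risk set before \(t = 5\).

What the generator emulates: independent non-informative right censoring,
a smooth monotone hazard, moderate sample size.  What it does not: covariate
structure, dependent or informative censoring, non-exponential shapes, or
ties (times are continuous).  Conclusions from the harness are about
calibration of the band machinery under clean assumptions, not about
robustness to violations of them.

### Containment conventions

`band_covers()` offers two checks.  The default (`check = "times"`)
requires the true curve to lie inside the limits at the band's reported
event times, skipping rows where the estimate has already hit zero — there
the "interval" is degenerate at 0 and standard software prints NaN limits,
so no confidence claim exists.  This is the statement survival software
actually makes, and under it the naive pointwise band covers the whole
curve in ~35-39% of replicates, the headline contrast the harness is built
to show.  The alternative (`check = "pieces"`) is an exact containment of
the continuous curve against the step band (checked analytically piece by
piece; at least as strict as any grid).  It additionally penalises the
decay of \(S\) *between* event times, which no band anchored at event
times can follow, and the pointwise figure drops to ~15%; both numbers are
reported by the same machinery so the distinction is explicit rather than
buried in a convention.

### What the experiments show

At 1000 replicates (design above, level 0.95, times convention):
naive pointwise ~0.35-0.39 coverage; log-HW ~0.95; LR (time-varying
threshold) ~0.96; bootstrap-HW ~0.92 (its linear shape plus calibration
noise from 500 inner resamples sit at the low edge of nominal).  The
log-EP band measures ~0.92 when anchored at the very first event time.  That deficit is structural, not an
implementation artefact: at the first event \(\hat S = 1 - 1/n\) and the
log-transformed upper limit \(\hat S^{\theta}\) is strictly below 1
(about \(1 - 1.7\times 10^{-4}\) at \(n = 200\)), while the true curve is
still essentially 1; the event \(S(t_1) > \hat S(t_1)^\theta\) has
probability ~3.5%, and the next few event times leak similarly.  The
equal-precision construction is simply not designed for bridge-time
coordinates that close to zero — published tables for \(e_{1-\alpha}\)
start at \(x_L = 0.02\) — and anchoring the band where \(x(t)\) reaches
~0.05 (around the 10th event at this \(n\)) restores coverage to ~0.97.
Practical advice, reflected in the tests: use log-EP on a range that
starts a handful of events in, or prefer log-HW / LR when the band must
start at the first event.

Band *widths* are compared in the setting such comparisons are published
in: a follow-up range over which survival stays moderate (here
\([first\ event, 0.8]\), \(S(0.8) \approx 0.45\)) and the
fixed-threshold likelihood-ratio recipe.  There the LR band is on average
about 19% narrower than the linear Hall-Wellner band (0.150 vs 0.186
across 500 replicates) while the naive pointwise band is narrowest — the
expected ordering.  Over the extinction range \([0,5]\) every
likelihood-ratio threshold diverges at the earliest event times (the
\(1/\tau(t)\) factor), the band there spans nearly all of \([0,1]\), and
no narrowness claim holds or is made.

## Numerical choices

* Root finding is monotone bisection/`uniroot` throughout: critical-value
  quantiles on \([10^{-6}, 10]\) (probability tolerance \(10^{-9}\));
  the likelihood multiplier \(\lambda\) on (pole \(+\ \varepsilon\),
  expanding upper bracket) with \(\varepsilon\) shrunk adaptively when a
  huge threshold demands it, tolerance \(10^{-11}\).
* Step-function lookups are right-continuous (`findInterval`).
* Linear band limits may leave \([0,1]\) and are clamped only on user
  output (`clamp = TRUE` default in `km_band()`); coverage experiments use
  the raw limits.  Transformed and LR limits are in \([0,1]\) by
  construction.
* Where the estimate is zero the standard error is reported as 0 and the
  Greenwood sums as `Inf`; such times are never part of a simultaneous
  band's range.
* All randomness flows through explicit seeds; internal seeding
  saves and restores the caller's RNG state.  Test and simulation sizes
  (1000 coverage replicates; \(10^5\) Monte-Carlo paths for oracle
  comparisons; 500x500 for the bootstrap coverage check) were chosen so the
  whole suite demonstrates each claim at tolerances matched to its
  Monte-Carlo error.

## Limitations

Left truncation, interval censoring, competing risks and covariate
adjustment are out of scope, as are bands for cumulative hazards or
cumulative incidence and the bias-corrected likelihood-ratio variants.
The wild bootstrap is not implemented.  The equal-precision approximation
is a tail approximation: for confidence levels below ~0.5 use
`method = "mc"`.
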