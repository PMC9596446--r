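# survband

Simultaneous confidence bands for Kaplan–Meier survival curves.

## The problem

A survival curve estimated by the Kaplan–Meier method is a random function
of time, but the uncertainty drawn around it in practice is a sequence of
*pointwise* confidence intervals joined into a band. Each interval is valid
at its own time point; the connected band is **not** a valid confidence
region for the whole curve — under a known truth (exponential survival with
rate 1, uniform censoring on [0, 10], n = 200), the naive 95% band contains
the entire curve over [0, 5] in well under half of replicates. A
*simultaneous* band replaces the normal quantile z with the quantile of the
supremum of the limiting Gaussian process of the whole standardised curve,
restoring joint coverage.

With the Greenwood sum g(t) = Σ dᵢ/{nᵢ(nᵢ−dᵢ)}, τ(t) = n·g(t) and
se(t) = Ŝ(t)√g(t), the package provides, over a time range [a, b]:

| method | band | critical value |
|---|---|---|
| `pointwise` | Ŝ ± z·se(t) | normal quantile (for contrast) |
| `gill` | Ŝ ± Ŝ·√(τ(b)/n)·G | sup of Brownian motion on [0,1] |
| `hw` (Hall–Wellner) | Ŝ ± k·(1+τ(t))·Ŝ/√n | sup of Brownian bridge on [0, K], K = τ(b)/(1+τ(b)) |
| `ep` (equal precision) | Ŝ ± e·se(t) | sup of standardised bridge \|B(x)\|/√(x(1−x)) on the range's bridge-time window |
| `lr` (likelihood ratio) | {p : −2 log R(p,t) ≤ C²(t)} | bridge sup, via the profile empirical-likelihood deviance |
| `boot_hw` | HW shape | bootstrap quantile of the resampled supremum statistic |

`log` and `arcsin` transforms keep the Hall–Wellner and equal-precision
bands inside [0, 1]; the likelihood-ratio band needs no transform. All
critical values are computed directly (series, numerical integration,
bootstrap or Monte Carlo), so **any** confidence level in (0, 1) works —
no lookup tables. See `vignette("confidence-bands", package = "survband")`
for the methods and the design decisions.

## Worked example

```r
library(survband)

df  <- simulate_survival(n = 200, seed = 42)   # Exp(1) events, U(0,10) censoring
fit <- fit_km(df)
glance(fit)
#>       n n_events n_censored n_event_times median_survival t_max_event
#> 1   200      169         31           169           0.730        6.85

band <- km_band(fit, method = "hw", transform = "log", level = 0.95)
glance(band)
#>   method transform level   tmin  tmax critical critical_family     n n_times     K tau_b
#> 1 hw     log        0.95 0.0288  3.97     1.36 bridge_sup        200     168 0.987  78.2
```

The fitted curve has 169 distinct event times; the band runs from the
first event to the last usable event time (capped strictly below the
largest uncensored observation), its bridge-time endpoint is K = 0.987,
and the Hall–Wellner critical value there is 1.36 — the replacement for
1.96. At one year:

```r
km_pointwise(fit, 1)                          # pointwise Wald interval
#>    time estimate std_err lower upper level
#> 1     1    0.399  0.0356 0.329 0.469  0.95
dplyr::filter(tidy(band), abs(time - 1) < 0.02)  # simultaneous log-HW rows nearby
autoplot(band)                                # step ribbon of the band
```

The simultaneous band at the same time is wider than [0.33, 0.47] —
that is the price of a statement that holds jointly over the whole range.

How badly do connected pointwise intervals fail? The coverage harness
repeats the simulation, builds the band, and checks containment of the
true curve S(t) = e^(−t) over [0, 5]:

```r
coverage_experiment(method = "pointwise", n = 200, reps = 1000, tmax = 5, seed = 1)
#>   method    transform level     n  reps covered coverage  mc_se  seed
#> 1 pointwise linear     0.95   200  1000     353    0.353 0.0151     1
coverage_experiment(method = "hw", transform = "log", n = 200, reps = 1000, tmax = 5, seed = 1)
#>   method    transform level     n  reps covered coverage  mc_se  seed
#> 1 hw        log        0.95   200  1000     952    0.952 0.0068     1
```

The naive band covers the whole curve 35% of the time despite its "95%"
label; the log-transformed Hall–Wellner band is calibrated.

## Command line

A thin CLI wraps the same functions (`inst/cli/kmband`):

```sh
Rscript inst/cli/kmband band --input subjects.csv --method ep --transform log \
    --level 0.9 --tmax 5 --output band.csv
Rscript inst/cli/kmband coverage --method pointwise --n 200 --reps 1000 --tmax 5 --seed 1
```

Input is subject-level CSV (`time`, `event` columns); band output is CSV
with `#`-prefixed metadata recording method, level, range and the critical
value used. Exit codes: 0 success, 1 data/domain error, 2 usage error.

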