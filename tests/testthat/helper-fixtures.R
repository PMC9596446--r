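# shared fixtures, all built in code

# censored hand fixture: events at 1, 2, 4, 6; censored at 3, 5
fixture_censored <- function() {
  data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 0, 1))
}

# complete follow-up: the KM estimate is the empirical survival function
fixture_complete <- function(n = 4) {
  data.frame(time = seq_len(n), event = rep(1, n))
}

# random right-censored fixture with ties (both event/event and
# event/censoring ties occur because times are rounded)
random_fixture <- function(n, seed, round_to = 1) {
  set.seed(seed)
  data.frame(
    time = round(rexp(n, rate = 0.5), round_to),
    event = rbinom(n, 1, 0.8)
  )
}

# deterministic per-replicate seed for test simulation loops
replicate_seed_test <- function(seed, index) {
  as.integer((seed + 104729 * index) %% 2147483646) + 1L
}

# ensure a fixture has at least one event (rejection by reseeding)
random_fixture_with_events <- function(n, seed, round_to = 1) {
  df <- random_fixture(n, seed, round_to)
  while (sum(df$event) == 0) {
    seed <- seed + 1000
    df <- random_fixture(n, seed, round_to)
  }
  df
}
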