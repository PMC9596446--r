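## internal helpers shared across modules

# classed conditions: "survband_error" for data/domain problems (CLI exit 1),
# "survband_usage_error" for argument problems (CLI exit 2)
stop_survband <- function(msg, class = "survband_error") {
  abort(msg, class = c(class, "survband_condition"))
}

stop_usage <- function(msg) {
  abort(msg, class = c("survband_usage_error", "survband_condition"))
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop_usage("`level` must be a single number strictly between 0 and 1.")
  }
  level
}

check_probability <- check_level

# evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs code against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_usage("`seed` must be a single finite number or NULL.")
  }
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-replicate substream seed, kept below 2^31 - 1
replicate_seed <- function(seed, index) {
  s <- (as.double(seed) + 104729 * as.double(index)) %% 2147483646
  as.integer(s) + 1L
}

# largest index i with times[i] <= t (0 if none); right-continuous step lookup
step_index <- function(times, t) {
  findInterval(t, times)
}
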