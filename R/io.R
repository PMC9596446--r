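## CSV input/output.  Dialect: comma-separated, '.' decimal, UTF-8,
## '#'-prefixed comment/metadata lines.  Time units are the caller's
## responsibility; nothing is rescaled.

#' Read a subject-level survival sample from CSV
#'
#' One row per subject.  The event column accepts 0/1 or FALSE/TRUE.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @param time_col,event_col Column names (defaults `"time"`, `"event"`).
#' @return A tibble with columns `time` and `event`, validated (finite
#'   nonnegative times, 0/1 events, at least one event).
#' @export
read_survival_csv <- function(path, time_col = "time", event_col = "event") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_survband(paste0("file not found: ", path))
  }
  df <- tryCatch(
    readr::read_csv(path,
      comment = "#", show_col_types = FALSE, progress = FALSE
    ),
    error = function(e) stop_survband(paste0("could not parse ", path, ": ", conditionMessage(e)))
  )
  if (nrow(df) == 0L) {
    stop_survband(paste0("empty file: ", path))
  }
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df)) {
      stop_survband(paste0("missing column '", col, "' in ", path))
    }
  }
  tm <- df[[time_col]]
  ev <- df[[event_col]]
  if (is.character(ev)) {
    ev_up <- toupper(trimws(ev))
    ev <- ifelse(ev_up %in% c("TRUE", "1"), 1L,
      ifelse(ev_up %in% c("FALSE", "0"), 0L, NA_integer_)
    )
  }
  if (is.logical(ev)) ev <- as.integer(ev)
  bad <- which(is.na(ev) | !(ev %in% c(0, 1)))
  if (length(bad)) {
    stop_survband(paste0(
      "unparseable event indicator (expect 0/1 or FALSE/TRUE) at row(s): ",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  if (!is.numeric(tm)) {
    stop_survband(paste0("column '", time_col, "' is not numeric in ", path))
  }
  bad <- which(!is.finite(tm) | tm < 0)
  if (length(bad)) {
    stop_survband(paste0(
      "non-finite or negative follow-up time at row(s): ",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  validate_sample(tm, as.integer(ev))
  tibble::tibble(time = tm, event = as.integer(ev))
}

fmt_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.10g", x), as.character(x))
}

#' Write and read a confidence band as annotated CSV
#'
#' `write_band_csv()` serialises a `km_band` as `#`-prefixed metadata lines
#' (method, transform, level, range, critical value, sample size, seed when
#' the method is resampling-based) followed by a header and one row per
#' event time, with deterministic number formatting (10 significant
#' digits); two writes of the same band are byte-identical.
#' `read_band_csv()` reads the file back into a `km_band` (round-trip
#' faithful to the serialised precision).
#'
#' @param band A `km_band`.
#' @param path Output (input) path.
#' @return `write_band_csv()` returns `path` invisibly; `read_band_csv()`
#'   returns a `km_band`.
#' @export
write_band_csv <- function(band, path) {
  if (!inherits(band, "km_band")) stop_usage("`band` must be a `km_band`.")
  crit <- band_attr(band, "critical")
  diag <- band_attr(band, "diagnostics")
  rng <- band_attr(band, "range")
  meta <- c(
    method = band_attr(band, "method"),
    transform = band_attr(band, "transform"),
    level = fmt_num(band_attr(band, "level")),
    tmin = fmt_num(rng[1]),
    tmax = fmt_num(rng[2]),
    critical_value = fmt_num(as.numeric(crit)),
    critical_family = attr(crit, "family"),
    n = fmt_num(band_attr(band, "n"))
  )
  if (!is.null(diag$seed)) meta <- c(meta, seed = fmt_num(diag$seed))
  cols <- c("time", "n_risk", "n_event", "estimate", "std_err", "lower", "upper")
  rows <- vapply(seq_len(nrow(band)), function(i) {
    paste(vapply(cols, function(cl) fmt_num(band[[cl]][i]), character(1)),
      collapse = ","
    )
  }, character(1))
  lines <- c(
    paste0("# ", names(meta), ": ", meta),
    paste(cols, collapse = ","),
    rows
  )
  con <- file(path, open = "wb") # fixed EOLs so repeated writes are identical
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_band_csv
#' @export
read_band_csv <- function(path) {
  if (!file.exists(path)) stop_survband(paste0("file not found: ", path))
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*: ?", "", kv))
    meta[[key]] <- val
  }
  df <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  need <- c("time", "n_risk", "n_event", "estimate", "std_err", "lower", "upper")
  if (!all(need %in% names(df))) {
    stop_survband(paste0("not a band CSV (missing columns): ", path))
  }
  out <- tibble::as_tibble(df[need])
  structure(
    out,
    method = meta$method %||% NA_character_,
    transform = meta$transform %||% NA_character_,
    level = as.numeric(meta$level %||% NA),
    range = c(as.numeric(meta$tmin %||% NA), as.numeric(meta$tmax %||% NA)),
    critical = new_critical_value(
      as.numeric(meta$critical_value %||% NA),
      family = meta$critical_family %||% "unknown",
      level = as.numeric(meta$level %||% NA),
      domain = c(NA_real_, NA_real_)
    ),
    diagnostics = list(),
    n = as.numeric(meta$n %||% NA),
    clamped = NA,
    class = c("km_band", class(out))
  )
}
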