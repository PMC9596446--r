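## ggplot2 methods.  Bands are step functions; ribbons are drawn on
## step-expanded coordinates so the plotted region matches the band's
## right-continuous convention exactly.

# expand (time, value...) rows to step coordinates out to `xmax`
step_expand <- function(df, xmax) {
  m <- nrow(df)
  x <- c(df$time, xmax)
  idx <- rep(seq_len(m), each = 2L)
  out <- df[idx, , drop = FALSE]
  out$time <- as.vector(rbind(x[-length(x)], x[-1L]))
  out
}

#' Plot a Kaplan-Meier fit
#'
#' Step plot of the survival estimate, optionally with the naive pointwise
#' Wald limits.
#'
#' @param object A [fit_km()] object.
#' @param pointwise Overlay pointwise Wald limits at this level (`NULL` to
#'   omit).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_fit <- function(object, pointwise = 0.95, ...) {
  crv <- dplyr::bind_rows(
    tibble::tibble(
      time = 0, estimate = 1, std_err = 0,
      n_risk = object$n, n_event = 0L, gw = 0, tau = 0
    ),
    object$curve
  )
  p <- ggplot2::ggplot(crv, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
  if (!is.null(pointwise)) {
    pw <- km_pointwise(object, object$curve$time, level = pointwise, clamp = TRUE)
    steps <- step_expand(pw, max(pw$time))
    p <- p + ggplot2::geom_ribbon(
      data = steps,
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2
    )
  }
  p
}

#' Plot a confidence band
#'
#' Step plot of the estimate with the band drawn as a step ribbon.
#'
#' @param object A `km_band`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_band <- function(object, ...) {
  rngb <- band_attr(object, "range")[2]
  steps <- step_expand(tibble::as_tibble(unclass(object)[names(object)]), rngb)
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.25
    ) +
    ggplot2::geom_step(ggplot2::aes(y = .data$estimate)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability",
      title = sprintf(
        "%s band (%s), level %.3g",
        band_attr(object, "method"), band_attr(object, "transform"),
        band_attr(object, "level")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Compare the width profiles of several bands
#'
#' @param bands A named list of `km_band` objects on the same fit.
#' @return A ggplot of width against time, one line per band.
#' @export
plot_band_widths <- function(bands) {
  if (!is.list(bands) || !all(vapply(bands, inherits, logical(1), "km_band"))) {
    stop_usage("`bands` must be a list of `km_band` objects.")
  }
  nms <- names(bands) %||% vapply(bands, band_attr, character(1), "method")
  df <- dplyr::bind_rows(
    purrr::map2(bands, nms, function(b, nm) {
      dplyr::mutate(band_width(b), band = nm)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$width, colour = .data$band
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "band width") +
    ggplot2::theme_minimal()
}
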