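# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_rect geom_smooth labs theme_minimal scale_fill_gradient2
#'   coord_polar geom_abline
#' @export
ggplot2::autoplot

#' @rdname ecc_curve
#' @param object a `strain_curve` tibble.
#' @param ... unused.
#' @export
autoplot.strain_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$strain_pct,
                     group = interaction(.data$component, .data$label),
                     colour = .data$label)) +
    geom_line() +
    labs(x = "time (s)", y = "strain (%)", colour = "label") +
    theme_minimal()
}

#' @rdname volume_trace
#' @param object a `volume_trace` tibble.
#' @param ... unused.
#' @export
autoplot.volume_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$volume_ul)) +
    geom_line() +
    labs(x = "time (s)", y = "cavity volume (uL)") +
    theme_minimal()
}

#' @rdname ea_field
#' @param object an `ea_field` tibble.
#' @param frame frame to display (default: the peak-systole frame).
#' @param ... unused.
#' @export
autoplot.ea_field <- function(object, frame = NULL, ...) {
  pf <- frame %||% attr(object, "peak_frame")
  df <- object[object$frame == pf, , drop = FALSE]
  ggplot(df, aes(x = .data$rotation, y = .data$band, fill = .data$ea_pct)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "rotation (anterior = 1)", y = "band (base = 1)",
         fill = "E_a (%)", title = sprintf("surface-area strain, frame %d", pf)) +
    theme_minimal()
}

#' Bullseye plot of a 17-segment map
#'
#' Polar (bullseye) rendering of per-segment peak surface-area strain:
#' basal ring outside, apex cap in the centre, anterior at the top.
#'
#' @param object a `segment_map` from [segment_peak_ea()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.segment_map <- function(object, ...) {
  ring <- c(rep(3, 6), rep(2, 6), rep(1, 4), 0)
  n_sec <- c(rep(6, 6), rep(6, 6), rep(4, 4), 1)
  start <- c((0:5) * 60 - 30, (0:5) * 60 - 30, (0:3) * 90 - 45, 0)
  df <- tibble(
    segment = object$segment, value = object$peak_ea_pct,
    r0 = ring, r1 = ring + 1,
    a0 = start, a1 = start + 360 / n_sec)
  df$a1[17] <- 360; df$a0[17] <- 0
  ggplot(df) +
    geom_rect(aes(xmin = .data$a0, xmax = .data$a1,
                  ymin = .data$r0, ymax = .data$r1, fill = .data$value),
              colour = "grey30") +
    coord_polar(theta = "x", start = -pi, direction = -1) +
    scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
                         midpoint = 0) +
    labs(fill = "peak E_a (%)", x = NULL, y = NULL) +
    theme_minimal()
}

#' @rdname write_pressure
#' @param object a `pressure_trace` tibble.
#' @param ... unused.
#' @export
autoplot.pressure_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$pressure_mmhg)) +
    geom_line() +
    labs(x = "time (s)", y = "LV pressure (mmHg)") +
    theme_minimal()
}

#' @rdname linear_fit
#' @param object a `strain_fit`.
#' @export
autoplot.strain_fit <- function(object, ...) {
  g <- glance(object)
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_abline(slope = g$slope, intercept = g$intercept, colour = "#b2182b") +
    labs(x = object$x_name, y = object$y_name,
         title = sprintf("R^2 = %.3f, p = %.3g", g$r.squared, g$p.value)) +
    theme_minimal()
}
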