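# Volumetric function indices and invasive contractility:
#   EF = (LVEDV - LVESV) / LVEDV * 100     SV = LVEDV - LVESV
#   CO = SV * HR (uL -> mL/min)            HR = 60 / cycle duration
#   +dP/dt_max = peak positive first time-derivative of LV pressure.

#' Ejection fraction
#' @param lvedv_ul end-diastolic volume, uL (> 0).
#' @param lvesv_ul end-systolic volume, uL (`0 <= LVESV <= LVEDV`).
#' @return EF in percent.
#' @export
ejection_fraction <- function(lvedv_ul, lvesv_ul) {
  if (any(lvedv_ul <= 0)) abort("`lvedv_ul` must be positive.")
  if (any(lvesv_ul < 0) || any(lvesv_ul > lvedv_ul))
    abort("`lvesv_ul` must satisfy 0 <= LVESV <= LVEDV.")
  (lvedv_ul - lvesv_ul) / lvedv_ul * 100
}

#' Stroke volume
#' @inheritParams ejection_fraction
#' @return SV in uL.
#' @export
stroke_volume <- function(lvedv_ul, lvesv_ul) {
  if (any(lvesv_ul > lvedv_ul)) abort("LVESV exceeds LVEDV.")
  if (any(lvedv_ul < 0) || any(lvesv_ul < 0)) abort("volumes must be non-negative.")
  lvedv_ul - lvesv_ul
}

#' Cardiac output
#' @param sv_ul stroke volume, uL (>= 0).
#' @param hr_bpm heart rate, beats/min (> 0).
#' @return CO in mL/min.
#' @export
cardiac_output <- function(sv_ul, hr_bpm) {
  if (any(sv_ul < 0)) abort("`sv_ul` must be >= 0.")
  if (any(hr_bpm <= 0)) abort("`hr_bpm` must be positive.")
  sv_ul * hr_bpm / 1000
}

#' Heart rate from the gated cycle duration
#' @param cycle_duration_s one cardiac cycle, s.
#' @return HR in beats/min.
#' @export
heart_rate <- function(cycle_duration_s) {
  if (any(cycle_duration_s <= 0)) abort("`cycle_duration_s` must be positive.")
  60 / cycle_duration_s
}

#' Peak positive pressure derivative (+dP/dt max)
#'
#' Maximum of the first time-derivative of an LV pressure trace, computed
#' with central differences (one-sided at the ends). For physiological
#' traces the maximum lies on the isovolumetric systolic upstroke.
#'
#' @param trace a tibble/data frame with `time_s` (strictly increasing
#'   with at least 3 samples) and `pressure_mmhg`.
#' @return +dP/dt max in mmHg/s.
#' @export
dpdt_max <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "pressure_mmhg") %in% names(trace)))
    abort("`trace` needs columns `time_s` and `pressure_mmhg`.")
  tt <- trace$time_s; p <- trace$pressure_mmhg
  n <- length(tt)
  if (n < 3L) abort("pressure trace needs at least 3 samples.")
  if (any(diff(tt) <= 0)) abort("`time_s` must be strictly increasing.")
  dp <- numeric(n)
  dp[1] <- (p[2] - p[1]) / (tt[2] - tt[1])
  dp[n] <- (p[n] - p[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2L)
    dp[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  max(dp)
}

#' Volumetric function report
#'
#' Global function indices from a mesh volume trace, with `+dP/dt max`
#' appended when a pressure trace is supplied. LVEDV is the frame-1
#' (end-diastolic reference) volume, LVESV the cycle minimum, and heart
#' rate is derived from the gated cycle duration.
#'
#' @param mesh a [mesh4d()].
#' @param pressure optional pressure trace for [dpdt_max()].
#' @return a one-row tibble: `lvedv_ul`, `lvesv_ul`, `ef_pct`, `sv_ul`,
#'   `hr_bpm`, `co_ml_min`, `dpdt_max_mmhg_s`.
#' @export
function_report <- function(mesh, pressure = NULL) {
  vt <- volume_trace(mesh)
  edv <- attr(vt, "lvedv_ul"); esv <- attr(vt, "lvesv_ul")
  sv <- stroke_volume(edv, esv)
  hr <- heart_rate(mesh$cycle_duration_s)
  tibble(
    lvedv_ul = edv, lvesv_ul = esv,
    ef_pct = ejection_fraction(edv, esv),
    sv_ul = sv, hr_bpm = hr,
    co_ml_min = cardiac_output(sv, hr),
    dpdt_max_mmhg_s = if (is.null(pressure)) NA_real_ else dpdt_max(pressure))
}

#' Ordinary least-squares fit between two study variables
#'
#' Simple linear regression used to relate strain metrics to
#' contractility (e.g. global peak surface-area strain vs `+dP/dt max`).
#'
#' @param data a data frame.
#' @param x,y column names (tidy-eval) of predictor and response.
#' @return an object of class `strain_fit`; use [generics::tidy()] for
#'   per-term statistics, [generics::glance()] for `slope`, `intercept`,
#'   `r.squared`, `p.value` and `n`, and `autoplot()` for a scatter plot
#'   with the fitted line.
#' @export
linear_fit <- function(data, x, y) {
  xq <- rlang::enquo(x); yq <- rlang::enquo(y)
  xv <- rlang::eval_tidy(xq, data); yv <- rlang::eval_tidy(yq, data)
  if (length(xv) < 3L) abort("need at least 3 observations.")
  if (diff(range(xv)) == 0) abort("`x` is constant; slope undefined.")
  fit <- lm(yv ~ xv, data = data.frame(xv = xv, yv = yv))
  structure(list(fit = fit,
                 x_name = rlang::as_label(xq), y_name = rlang::as_label(yq),
                 data = tibble(x = xv, y = yv)),
            class = "strain_fit")
}

#' @export
print.strain_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<strain_fit> %s ~ %s: slope %.4g, intercept %.4g, R^2 %.3f, p %.3g (n = %d)\n",
              x$y_name, x$x_name, g$slope, g$intercept, g$r.squared, g$p.value, g$n))
  invisible(x)
}

# summary.lm warns on exact fits; exact fits are routine on phantoms
quiet_lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname linear_fit
#' @param x a `strain_fit` object.
#' @param ... unused.
#' @export
tidy.strain_fit <- function(x, ...) {
  sm <- quiet_lm_summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", x$x_name),
         estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @rdname linear_fit
#' @export
glance.strain_fit <- function(x, ...) {
  sm <- quiet_lm_summary(x$fit)
  co <- sm$coefficients
  tss <- sum((x$data$y - mean(x$data$y))^2)
  r2 <- if (tss == 0) 0 else sm$r.squared    # constant response: no variance explained
  slope <- if (nrow(co) > 1) co[2, 1] else 0
  slope_p <- if (nrow(co) > 1 && tss > 0) co[2, 4] else NA_real_
  tibble(slope = slope, intercept = co[1, 1], r.squared = r2,
         p.value = slope_p, n = nrow(x$data))
}
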