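# Strain-based infarct sizing: akinetic tissue is identified as patches
# whose peak-systolic surface-area strain magnitude falls below a
# threshold (default 20%), and infarct size is the fraction of the
# end-diastolic (reference) endocardial surface area they cover.

#' Akinesis mask
#'
#' Flags every patch whose surface-area strain magnitude at the
#' peak-systole frame (or, optionally, the maximum magnitude over the
#' whole cycle) is strictly below the threshold.
#'
#' @param field an [ea_field()].
#' @param threshold_pct akinesis threshold in percent strain (default 20).
#' @param at `"peak"` (peak-systole frame, default) or `"max"` (maximum
#'   magnitude over the cycle).
#' @return a tibble (`band`, `rotation`, `ea_pct`, `area_ref_mm2`,
#'   `akinetic`).
#' @export
akinesis_mask <- function(field, threshold_pct = 20, at = c("peak", "max")) {
  at <- match.arg(at)
  if (threshold_pct <= 0) abort("`threshold_pct` must be positive.")
  if (nrow(field) == 0L) abort("empty strain field.")
  if (at == "peak") {
    pk <- ea_at_peak(field)
    out <- tibble(band = pk$band, rotation = pk$rotation,
                  ea_pct = pk$ea_pct, area_ref_mm2 = pk$area_ref_mm2)
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(field, .data$band, .data$rotation),
      ea_pct = .data$ea_pct[which.max(abs(.data$ea_pct))],
      area_ref_mm2 = .data$area_ref_mm2[1], .groups = "drop")
  }
  out$akinetic <- abs(out$ea_pct) < threshold_pct
  out
}

#' Strain-based infarct size
#'
#' Fraction of the end-diastolic endocardial surface area covered by
#' akinetic patches (peak-systolic surface-area strain magnitude strictly
#' below `threshold_pct`), in percent.
#'
#' @inheritParams akinesis_mask
#' @return a one-row tibble (`threshold_pct`, `infarct_pct`,
#'   `area_total_mm2`, `area_akinetic_mm2`, `peak_frame`) of class
#'   `infarct_estimate`, with the akinesis mask attached as attribute
#'   `mask`.
#' @export
infarct_size <- function(field, threshold_pct = 20, at = c("peak", "max")) {
  mask <- akinesis_mask(field, threshold_pct = threshold_pct, at = at)
  total <- sum(mask$area_ref_mm2)
  ak <- sum(mask$area_ref_mm2[mask$akinetic])
  out <- tibble(
    threshold_pct = threshold_pct,
    infarct_pct = 100 * ak / total,
    area_total_mm2 = total,
    area_akinetic_mm2 = ak,
    peak_frame = attr(field, "peak_frame") %||% NA_integer_)
  attr(out, "mask") <- mask
  class(out) <- c("infarct_estimate", class(out))
  out
}
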