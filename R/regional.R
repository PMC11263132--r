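# Regional mapping: AHA 17-segment model and the six longitudinal wall
# regions.
#
# Angular convention (declared, configurable by rotating the mesh): the
# anterior wall sits at angle 0, angles increase counterclockwise viewed
# from the apex, so sectors advance anterior -> anteroseptal ->
# inferoseptal -> inferior -> inferolateral -> anterolateral; the septum
# spans 30 deg - 150 deg. Sector boundaries are half-open [a, b).

AHA17_NAMES <- c(
  "basal anterior", "basal anteroseptal", "basal inferoseptal",
  "basal inferior", "basal inferolateral", "basal anterolateral",
  "mid anterior", "mid anteroseptal", "mid inferoseptal",
  "mid inferior", "mid inferolateral", "mid anterolateral",
  "apical anterior", "apical septal", "apical inferior", "apical lateral",
  "apex")

WALL_REGIONS6 <- c("anterior", "anterior septum", "posterior septum",
                   "posterior", "posterior free wall", "anterior free wall")

#' AHA 17-segment id for a mesh location
#'
#' Deterministic mapping from a normalized base-to-apex position and a
#' rotation angle to the American Heart Association 17-segment model:
#' basal third to segments 1-6 and mid third to 7-12 (60 deg sectors,
#' anterior centred at angle 0), the apical level to 13-16 (90 deg
#' sectors), and the apex cap (last `1 - apex_cap` of the long axis) to
#' segment 17.
#'
#' @param z_fraction base-to-apex position in `[0, 1]` (vectorised).
#' @param theta rotation angle in radians, anterior at 0 (vectorised).
#' @param apex_cap z-fraction at which the apex-cap segment 17 begins
#'   (default 0.9).
#' @return integer segment ids in 1..17.
#' @export
aha17_segment <- function(z_fraction, theta, apex_cap = 0.9) {
  if (any(z_fraction < 0 | z_fraction > 1)) abort("`z_fraction` must be in [0, 1].")
  n <- max(length(z_fraction), length(theta))
  z_fraction <- rep_len(z_fraction, n); theta <- rep_len(theta, n)
  sec6 <- 1L + as.integer(floor(((theta + pi / 6) %% (2 * pi)) / (pi / 3)))
  sec4 <- 1L + as.integer(floor(((theta + pi / 4) %% (2 * pi)) / (pi / 2)))
  out <- integer(n)
  basal <- z_fraction < 1 / 3
  mid <- !basal & z_fraction < 2 / 3
  apical <- !basal & !mid & z_fraction < apex_cap
  out[basal] <- sec6[basal]
  out[mid] <- 6L + sec6[mid]
  out[apical] <- 12L + sec4[apical]
  out[!basal & !mid & !apical] <- 17L
  out
}

#' Six-region wall label for a rotation angle
#'
#' Partitions the circumference into six half-open 60 deg sectors with
#' the anterior wall centred at angle 0: anterior, anterior septum,
#' posterior septum, posterior, posterior free wall, anterior free wall
#' (in order of increasing angle).
#'
#' @param theta rotation angle(s) in radians.
#' @return factor with levels in the order above.
#' @export
wall_region6 <- function(theta) {
  sec <- 1L + as.integer(floor(((theta + pi / 6) %% (2 * pi)) / (pi / 3)))
  factor(WALL_REGIONS6[sec], levels = WALL_REGIONS6)
}

# map the patches of an ea_field to segments using patch centres
field_segments <- function(field, apex_cap = 0.9) {
  d <- attr(field, "dims")
  if (is.null(d)) abort("`field` must be an ea_field with dims attribute.")
  B <- d[["n_bands"]]; Th <- d[["n_rotations"]]
  zf <- (field$band - 0.5) / B
  th <- 2 * pi * (field$rotation - 0.5) / Th
  aha17_segment(zf, th, apex_cap = apex_cap)
}

#' Per-segment peak surface-area strain
#'
#' Reference-area-weighted mean of the peak-systolic surface-area strain
#' of every patch within each AHA segment. Segments containing no patch
#' are reported as `NA` with a warning.
#'
#' @param field an [ea_field()].
#' @param apex_cap passed to [aha17_segment()].
#' @return a tibble (`segment`, `segment_name`, `peak_ea_pct`,
#'   `area_mm2`) with 17 rows, of class `segment_map`.
#' @export
segment_peak_ea <- function(field, apex_cap = 0.9) {
  pk <- ea_at_peak(field)
  seg <- field_segments(pk, apex_cap = apex_cap)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(segment = seg, ea = pk$ea_pct, w = pk$area_ref_mm2),
                    .data$segment),
    peak_ea_pct = sum(.data$ea * .data$w) / sum(.data$w),
    area_mm2 = sum(.data$w), .groups = "drop")
  out <- dplyr::left_join(
    tibble(segment = 1:17, segment_name = AHA17_NAMES), agg, by = "segment")
  if (anyNA(out$peak_ea_pct)) {
    missing <- out$segment[is.na(out$peak_ea_pct)]
    warn(sprintf("segment(s) with no patches flagged missing: %s",
                 paste(missing, collapse = ", ")))
  }
  class(out) <- c("segment_map", class(out))
  out
}

#' Basal / mid / apical level averages
#'
#' Mean peak strain of the basal (segments 1-6), mid (7-12) and apical
#' (13-17, apex cap included) levels of a segment map.
#'
#' @param seg a `segment_map` from [segment_peak_ea()].
#' @return a one-row tibble (`basal_pct`, `mid_pct`, `apical_pct`).
#' @export
level_average <- function(seg) {
  stopifnot(is.data.frame(seg), nrow(seg) == 17L)
  lvl <- list(basal = 1:6, mid = 7:12, apical = 13:17)
  vals <- lapply(lvl, function(ix) {
    v <- seg$peak_ea_pct[match(ix, seg$segment)]
    if (anyNA(v))
      abort(sprintf("missing segment(s) %s in level average.",
                    paste(ix[is.na(v)], collapse = ", ")))
    mean(v)
  })
  tibble(basal_pct = vals$basal, mid_pct = vals$mid, apical_pct = vals$apical)
}
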