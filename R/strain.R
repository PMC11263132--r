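# Strain engine: the three Lagrangian strain components read from the 4D
# mesh, all referenced to frame 1 (end diastole).
#
#   circumferential  E_cc(z,t) = 1/2 [ (C(z,t)/C_D(z))^2 - 1 ] * 100
#   longitudinal     E_ll(th,t) = (L(th,t) - L_D(th)) / L_D(th) * 100
#   surface area     E_a(z,th,t) = (A(z,th,t) - A_D(z,th)) / A_D(z,th) * 100
#
# C is the endocardial slice circumference, L the base-to-apex meridian
# length at one rotation, A the endocardial patch area between sequential
# slices; the D subscript marks the end-diastolic reference.

DEGENERATE_TOL <- 1e-9

new_strain_curve <- function(df) {
  class(df) <- c("strain_curve", class(df))
  df
}

#' Circumferential strain curve for one slice
#'
#' Circumferential component of the Green-Lagrange strain tensor from the
#' endocardial slice circumference, in percent, over the cardiac cycle.
#'
#' @param mesh a [mesh4d()].
#' @param slice 1-based slice index.
#' @return a tibble (`component`, `label`, `frame`, `time_s`,
#'   `strain_pct`) of class `strain_curve`; `strain_pct` is exactly 0 at
#'   frame 1.
#' @export
ecc_curve <- function(mesh, slice) {
  C <- circumference_matrix(mesh, "endo")
  if (C[1, slice] <= DEGENERATE_TOL)
    abort(sprintf("degenerate slice %d: zero reference circumference.", slice))
  new_strain_curve(tibble(
    component = "Ecc", label = as.character(slice),
    frame = seq_len(nrow(C)), time_s = mesh_times(mesh),
    strain_pct = 50 * ((C[, slice] / C[1, slice])^2 - 1)))
}

#' Longitudinal strain curve for one rotation
#'
#' Engineering (small-strain) fractional change of the apex-to-base
#' endocardial boundary length at a fixed rotation, in percent.
#'
#' @param mesh a [mesh4d()].
#' @param rotation 1-based rotation index.
#' @return a `strain_curve` tibble; see [ecc_curve()].
#' @export
ell_curve <- function(mesh, rotation) {
  L <- meridian_matrix(mesh, "endo")
  if (L[1, rotation] <= DEGENERATE_TOL)
    abort(sprintf("zero reference meridian length at rotation %d.", rotation))
  new_strain_curve(tibble(
    component = "Ell", label = as.character(rotation),
    frame = seq_len(nrow(L)), time_s = mesh_times(mesh),
    strain_pct = 100 * (L[, rotation] / L[1, rotation] - 1)))
}

#' Surface-area strain field
#'
#' Fractional change of every endocardial patch area between sequential
#' slices, in percent, for all frames. The result carries the reference
#' patch areas (mm^2) used as weights by the regional and infarct
#' modules, and the peak-systole frame (minimum cavity volume) as an
#' attribute.
#'
#' @param mesh a [mesh4d()].
#' @return a tibble (`frame`, `time_s`, `band`, `rotation`, `ea_pct`,
#'   `area_ref_mm2`) of class `ea_field`, with attributes `dims`
#'   (n_time, n_bands, n_rotations), `peak_frame` and `cycle_duration_s`.
#' @export
ea_field <- function(mesh) {
  A <- patch_area_array(mesh, "endo")         # (T, Z-1, Th)
  d <- dim(A); Tn <- d[1]; B <- d[2]; Th <- d[3]
  aD <- A[1, , ]
  if (any(aD <= DEGENERATE_TOL)) {
    bad <- which(aD <= DEGENERATE_TOL, arr.ind = TRUE)
    abort(sprintf("degenerate reference patch area at (band, rotation): %s",
                  paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " ")))
  }
  ea <- 100 * (sweep(A, c(2, 3), aD, "/") - 1)
  out <- tibble(
    frame = rep(seq_len(Tn), times = B * Th),
    time_s = rep(mesh_times(mesh), times = B * Th),
    band = rep(rep(seq_len(B), each = Tn), times = Th),
    rotation = rep(seq_len(Th), each = Tn * B),
    ea_pct = as.vector(ea),
    area_ref_mm2 = rep(as.vector(aD), each = Tn))
  attr(out, "dims") <- c(n_time = Tn, n_bands = B, n_rotations = Th)
  attr(out, "peak_frame") <- peak_systole_frame(cavity_volume(mesh))
  attr(out, "cycle_duration_s") <- mesh$cycle_duration_s
  class(out) <- c("ea_field", class(out))
  out
}

# rows of an ea_field at its peak-systole frame
ea_at_peak <- function(field, peak_frame = NULL) {
  pf <- peak_frame %||% attr(field, "peak_frame")
  if (is.null(pf)) abort("ea_field is missing its peak-systole frame.")
  field[field$frame == pf, , drop = FALSE]
}

#' Peak-systole frame
#'
#' Frame of minimum cavity volume; ties resolve to the earliest frame.
#'
#' @param volumes numeric vector of per-frame cavity volumes, or a
#'   [volume_trace()] tibble.
#' @return 1-based frame index.
#' @export
peak_systole_frame <- function(volumes) {
  if (is.data.frame(volumes)) volumes <- volumes$volume_ul
  if (length(volumes) < 2L) abort("need at least 2 frames.")
  which.min(volumes)
}

#' Cavity volume trace
#'
#' @param mesh a [mesh4d()].
#' @return a tibble (`frame`, `time_s`, `volume_ul`) of class
#'   `volume_trace`, with `lvedv_ul` (frame-1 reference volume) and
#'   `lvesv_ul` (minimum) as attributes.
#' @export
volume_trace <- function(mesh) {
  v <- cavity_volume(mesh)
  out <- tibble(frame = seq_along(v), time_s = mesh_times(mesh), volume_ul = v)
  attr(out, "lvedv_ul") <- v[1]
  attr(out, "lvesv_ul") <- min(v)
  attr(out, "cycle_duration_s") <- mesh$cycle_duration_s
  class(out) <- c("volume_trace", class(out))
  out
}

#' Global peak strain summary
#'
#' Evaluates all three strain components at the peak-systole frame
#' (minimum cavity volume): global circumferential strain is the mean over
#' non-degenerate slices, global longitudinal strain the mean over the six
#' wall regions (each region the mean of its rotations), and global
#' surface-area strain the reference-area-weighted mean over all patches.
#' Slices with a degenerate reference circumference are excluded with a
#' warning.
#'
#' @param mesh a [mesh4d()].
#' @return a one-row tibble: `peak_frame`, `peak_time_s`,
#'   `global_ecc_pct`, `global_ell_pct`, `global_ea_pct`.
#' @export
global_peaks <- function(mesh) {
  vols <- cavity_volume(mesh)
  pf <- peak_systole_frame(vols)

  C <- circumference_matrix(mesh, "endo")
  ok <- C[1, ] > DEGENERATE_TOL
  if (!any(ok)) abort("all slices degenerate at the reference frame.")
  if (!all(ok))
    warn(sprintf("excluding %d degenerate slice(s) from global Ecc.", sum(!ok)))
  ecc_pk <- 50 * ((C[pf, ok] / C[1, ok])^2 - 1)

  L <- meridian_matrix(mesh, "endo")
  ell_pk <- 100 * (L[pf, ] / L[1, ] - 1)
  regions <- wall_region6(mesh_angles(mesh))
  ell_regional <- tapply(ell_pk, regions, mean)

  A <- patch_area_array(mesh, "endo")
  aD <- A[1, , ]
  ea_pk <- 100 * (A[pf, , ] / aD - 1)

  tibble(
    peak_frame = pf,
    peak_time_s = mesh_times(mesh)[pf],
    global_ecc_pct = mean(ecc_pk),
    global_ell_pct = mean(ell_regional),
    global_ea_pct = sum(ea_pk * aD) / sum(aD))
}

#' Per-slice and per-region peak strains
#'
#' Long-format peak-systolic strain: circumferential per slice,
#' longitudinal per wall region, surface-area per patch band.
#'
#' @param mesh a [mesh4d()].
#' @return a tibble (`component`, `label`, `peak_pct`).
#' @export
strain_peaks <- function(mesh) {
  pf <- peak_systole_frame(cavity_volume(mesh))
  C <- circumference_matrix(mesh, "endo")
  ok <- which(C[1, ] > DEGENERATE_TOL)
  ecc <- tibble(component = "Ecc", label = as.character(ok),
                peak_pct = 50 * ((C[pf, ok] / C[1, ok])^2 - 1))
  L <- meridian_matrix(mesh, "endo")
  ell_pk <- 100 * (L[pf, ] / L[1, ] - 1)
  regions <- wall_region6(mesh_angles(mesh))
  ell <- tibble(component = "Ell",
                label = levels(regions),
                peak_pct = as.numeric(tapply(ell_pk, regions, mean)))
  A <- patch_area_array(mesh, "endo")
  aD <- A[1, , ]
  ea_pk <- 100 * (A[pf, , ] / aD - 1)
  ea <- tibble(component = "Ea", label = as.character(seq_len(nrow(aD))),
               peak_pct = rowSums(ea_pk * aD) / rowSums(aD))
  dplyr::bind_rows(ecc, ell, ea)
}

#' Systolic strain rate
#'
#' Least-squares slope of a strain curve against time from end diastole
#' (frame 1) to the peak-systole frame, in %/s.
#'
#' @param curve a `strain_curve` tibble (needs `frame`, `time_s`,
#'   `strain_pct`).
#' @param peak_frame 1-based peak-systole frame (e.g. from
#'   [peak_systole_frame()]); the systolic window is frames
#'   `1..peak_frame` and must hold at least 2 frames.
#' @return slope in %/s.
#' @export
strain_rate <- function(curve, peak_frame) {
  stopifnot(is.data.frame(curve))
  win <- curve[curve$frame <= peak_frame, , drop = FALSE]
  if (nrow(win) < 2L) abort("systolic window shorter than 2 frames.")
  tt <- win$time_s - mean(win$time_s)
  if (all(tt == 0)) abort("degenerate time values in systolic window.")
  sum(tt * (win$strain_pct - mean(win$strain_pct))) / sum(tt^2)
}
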