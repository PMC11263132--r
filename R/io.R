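# File formats. All tables are UTF-8 comma-separated CSV with a mandatory
# header row and '.' decimals, written at full double precision so a
# write/read round trip is bit-exact. Meshes and control points use the
# long layout  frame,surface,slice,rotation,x_mm,y_mm,z_mm  with a JSON
# sidecar (<path>.json) holding the cycle duration and conventions.
#
# Reading goes through base read.csv: its strtod parser is correctly
# rounded, which keeps the round trip exact to the last ulp.

read_csv_exact <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

MESH_COLUMNS <- c("frame", "surface", "slice", "rotation", "x_mm", "y_mm", "z_mm")

mesh_sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, cycle_duration_s, dims) {
  jsonlite::write_json(list(
    cycle_duration_s = cycle_duration_s,
    dims = as.list(dims),
    units = list(length = "mm", volume = "uL", time = "s"),
    conventions = list(
      frame1 = "end diastole (Lagrangian reference)",
      slice1 = "base; slices ordered base to apex",
      rotation1 = "anterior wall; increasing counterclockwise viewed from apex")),
    mesh_sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
}

#' Write / read a 4D mesh
#'
#' Long-format CSV (`frame,surface,slice,rotation,x_mm,y_mm,z_mm`) plus a
#' JSON sidecar (`<path>.json`) carrying the cycle duration and the
#' package's index conventions. The round trip is bit-exact.
#'
#' @param mesh a [mesh4d()].
#' @param path CSV file path.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns
#'   a [mesh4d()].
#' @export
write_mesh <- function(mesh, path) {
  readr::write_csv(as_tibble(mesh), path)
  write_sidecar(path, mesh$cycle_duration_s, mesh_dim(mesh))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, MESH_COLUMNS, "mesh CSV")
  side <- jsonlite::read_json(mesh_sidecar_path(path), simplifyVector = TRUE)
  Tn <- max(df$frame); Z <- max(df$slice); Th <- max(df$rotation)
  if (nrow(df) != Tn * 2 * Z * Th)
    abort(sprintf("mesh CSV has %d rows; expected %d for a %d x 2 x %d x %d grid.",
                  nrow(df), Tn * 2 * Z * Th, Tn, Z, Th))
  coords <- array(NA_real_, c(Tn, 2, Z, Th, 3))
  s <- match(df$surface, SURFACES)
  if (anyNA(s)) abort("`surface` must be 'endo' or 'epi'.")
  ix <- cbind(df$frame, s, df$slice, df$rotation)
  coords[cbind(ix, 1)] <- df$x_mm
  coords[cbind(ix, 2)] <- df$y_mm
  coords[cbind(ix, 3)] <- df$z_mm
  if (anyNA(coords)) abort("mesh CSV does not cover the full index grid.")
  mesh4d(coords, side$cycle_duration_s)
}

#' Write / read a tracked control-point set
#'
#' Same long CSV layout and JSON sidecar as [write_mesh()], with `slice`
#' in 1..4 and `rotation` (point index) in 1..6.
#'
#' @param cp a [control_points()] set.
#' @param path CSV file path.
#' @return `write_control_points()` returns `path` invisibly;
#'   `read_control_points()` returns a [control_points()] set.
#' @export
write_control_points <- function(cp, path) {
  d <- dim(cp$coords)
  grid <- expand.grid(frame = seq_len(d[1]), surface = SURFACES,
                      slice = 1:4, rotation = 1:6,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- tibble(frame = grid$frame, surface = grid$surface,
               slice = grid$slice, rotation = grid$rotation,
               x_mm = as.vector(cp$coords[, , , , 1]),
               y_mm = as.vector(cp$coords[, , , , 2]),
               z_mm = as.vector(cp$coords[, , , , 3]))
  readr::write_csv(df, path)
  jsonlite::write_json(list(
    cycle_duration_s = cp$cycle_duration_s,
    slice_positions = cp$slice_positions,
    dims = list(n_frames = d[1], n_slices = 4L, n_points = 6L),
    units = list(length = "mm", time = "s")),
    mesh_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, MESH_COLUMNS, "control-point CSV")
  side <- jsonlite::read_json(mesh_sidecar_path(path), simplifyVector = TRUE)
  Fn <- max(df$frame)
  if (nrow(df) != Fn * 48)
    abort(sprintf("control-point CSV has %d rows; expected %d (48 per frame).",
                  nrow(df), Fn * 48))
  coords <- array(NA_real_, c(Fn, 2, 4, 6, 3))
  s <- match(df$surface, SURFACES)
  if (anyNA(s)) abort("`surface` must be 'endo' or 'epi'.")
  ix <- cbind(df$frame, s, df$slice, df$rotation)
  coords[cbind(ix, 1)] <- df$x_mm
  coords[cbind(ix, 2)] <- df$y_mm
  coords[cbind(ix, 3)] <- df$z_mm
  if (anyNA(coords)) abort("control-point CSV does not cover the full grid.")
  control_points(coords, side$cycle_duration_s,
                 slice_positions = side$slice_positions %||% (c(0, 1, 2, 3) / 3))
}

#' Write / read a pressure trace
#'
#' CSV with columns `time_s` (strictly increasing) and `pressure_mmhg`.
#'
#' @param trace a pressure-trace tibble.
#' @param path CSV file path.
#' @return `read_pressure()` returns a tibble of class `pressure_trace`.
#' @export
write_pressure <- function(trace, path) {
  check_columns(trace, c("time_s", "pressure_mmhg"), "pressure trace")
  readr::write_csv(trace[, c("time_s", "pressure_mmhg")], path)
  invisible(path)
}

#' @rdname write_pressure
#' @export
read_pressure <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, c("time_s", "pressure_mmhg"), "pressure CSV")
  if (any(diff(df$time_s) <= 0))
    abort("`time_s` must be strictly increasing (duplicate or unordered timestamps).")
  class(df) <- c("pressure_trace", class(df))
  df
}

#' Write / read a labeled section mask
#'
#' 8-bit grayscale PNG whose byte values are the labels themselves
#' (0 background, 1 healthy myocardium, 2 infarct); the pixel size is
#' stored in a JSON sidecar.
#'
#' @param mask a [section_mask()].
#' @param path PNG file path.
#' @return `read_mask()` returns a [section_mask()].
#' @export
write_mask <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, path)
  jsonlite::write_json(list(pixel_size_mm = attr(mask, "pixel_size_mm"),
                            level = attr(mask, "level")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  section_mask(round(img * 255), pixel_size_mm = side$pixel_size_mm,
               level = side$level)
}

#' Write strain curves to CSV
#'
#' Long format `component,label,frame,time_s,strain_pct`.
#'
#' @param curves a `strain_curve` tibble (or several row-bound together).
#' @param path CSV file path.
#' @export
write_strain_csv <- function(curves, path) {
  check_columns(curves, c("component", "label", "frame", "time_s", "strain_pct"),
                "strain table")
  readr::write_csv(curves[, c("component", "label", "frame", "time_s", "strain_pct")],
                   path)
  invisible(path)
}
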