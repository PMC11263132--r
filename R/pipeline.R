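# End-to-end pipeline: simulate -> strain -> regional -> infarct ->
# function -> histology -> report, driven by one configuration list and
# fully determined by (config, seed).

#' Run the full analysis pipeline
#'
#' Generates (or loads) a dataset, computes the strain components,
#' regional maps, strain-based infarct estimate, volumetric function
#' report and histological infarct sizes, and writes every result with a
#' run log into `out_dir`. When `config$cohort_size > 0` an additional
#' graded-contractility phantom cohort is run and the linear relation
#' between global peak surface-area strain and `+dP/dt max` is reported.
#'
#' @param config a [phantom_config()] (the simulated input), or a list
#'   with elements `phantom` (a `phantom_config`) and optionally
#'   `threshold_pct`, `cohort_size`.
#' @param out_dir output directory, created if missing.
#' @param threshold_pct akinesis threshold for the infarct estimate.
#' @param cohort_size number of graded-contractility phantoms for the
#'   strain-vs-contractility correlation (0 = skip).
#' @return a list of class `strain4d_run` with the in-memory results and
#'   the paths written.
#' @export
run_pipeline <- function(config, out_dir, threshold_pct = 20, cohort_size = 0L) {
  if (inherits(config, "phantom_config")) {
    cfg <- config
  } else if (is.list(config) && inherits(config$phantom, "phantom_config")) {
    cfg <- config$phantom
    threshold_pct <- config$threshold_pct %||% threshold_pct
    cohort_size <- config$cohort_size %||% cohort_size
  } else {
    abort("`config` must be a phantom_config() or a list with $phantom.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  ph <- generate_phantom(cfg)
  mesh <- ph$mesh
  write_mesh(mesh, pth("mesh.csv"))
  write_control_points(sample_control_points(mesh), pth("control_points.csv"))

  d <- mesh_dim(mesh)
  curves <- dplyr::bind_rows(
    purrr::map(seq_len(d[["n_slices"]]), ~ecc_curve(mesh, .x)),
    purrr::map(seq_len(d[["n_rotations"]]), ~ell_curve(mesh, .x)))
  write_strain_csv(curves, pth("strain_curves.csv"))

  field <- ea_field(mesh)
  seg <- segment_peak_ea(field)
  readr::write_csv(seg, pth("segment_map17.csv"))
  pk <- ea_at_peak(field)
  readr::write_csv(pk[, c("band", "rotation", "ea_pct", "area_ref_mm2")],
                   pth("peak_ea_heatmap.csv"))

  inf <- infarct_size(field, threshold_pct = threshold_pct)
  jsonlite::write_json(as.list(inf), pth("infarct_estimate.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(attr(inf, "mask"), pth("akinesis_mask.csv"))

  pres <- generate_pressure(period_s = cfg$cycle_duration_s)
  write_pressure(pres$trace, pth("pressure.csv"))
  fun <- function_report(mesh, pres$trace)
  jsonlite::write_json(as.list(fun), pth("function_report.json"),
                       auto_unbox = TRUE, digits = NA)

  masks <- generate_histology(cfg)
  for (i in seq_along(masks)) write_mask(masks[[i]], pth(sprintf("section_%d.png", i)))
  hist_est <- heart_infarct_size(masks)
  readr::write_csv(hist_est$sections, pth("histology_sections.csv"))

  correlation <- NULL
  if (cohort_size > 0L) {
    correlation <- contractility_cohort(cfg, cohort_size)
    corr_tbl <- dplyr::transmute(
      correlation$glance,
      x_name = paste0("global_", .data$component, "_pct"),
      y_name = "dpdt_max_mmhg_s",
      slope = .data$slope, intercept = .data$intercept,
      r2 = .data$r.squared, p = .data$p.value)
    readr::write_csv(corr_tbl, pth("correlation.csv"))
    readr::write_csv(correlation$table, pth("cohort.csv"))
  }

  globals <- global_peaks(mesh)
  jsonlite::write_json(as.list(globals), pth("global_peaks.json"),
                       auto_unbox = TRUE, digits = NA)

  log <- list(
    package = "strain4d",
    version = as.character(utils::packageVersion("strain4d")),
    config_hash = rlang::hash(cfg),
    threshold_pct = threshold_pct,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, pth("run_log.json"), auto_unbox = TRUE, digits = NA)

  structure(list(
    mesh = mesh, truth = ph$truth, curves = curves, field = field,
    segments = seg, infarct = inf, function_report = fun,
    histology = hist_est, globals = globals, correlation = correlation,
    out_dir = out_dir), class = "strain4d_run")
}

# graded-contractility cohort: phantoms spanning peak contraction scales
# with matched pressure amplitudes; returns the per-phantom table and the
# strain-vs-dP/dt fits
contractility_cohort <- function(base_cfg, n = 6L,
                                 lambda_range = c(0.70, 0.95)) {
  lam <- seq(lambda_range[1], lambda_range[2], length.out = n)
  rows <- purrr::map(lam, function(l) {
    cfg <- base_cfg
    cfg$lambda_min <- l
    cfg$mu_min <- 1 - 0.5 * (1 - l)
    cfg$infarct <- infarct_patch()         # healthy cohort
    ph <- generate_phantom(cfg)
    g <- global_peaks(ph$mesh)
    pres <- generate_pressure(
      amplitude_mmhg = 10 + 120 * (1 - l),
      period_s = cfg$cycle_duration_s,
      fs_hz = 1000)
    vols <- cavity_volume(ph$mesh)
    ecc_sr <- strain_rate(ecc_curve(ph$mesh, max(2L, cfg$n_slices %/% 2L)),
                          peak_systole_frame(vols))
    tibble(lambda_min = l, mu_min = cfg$mu_min,
           global_ecc_pct = g$global_ecc_pct,
           global_ell_pct = g$global_ell_pct,
           global_ea_pct = g$global_ea_pct,
           ecc_strain_rate_pct_s = ecc_sr,
           dpdt_max_mmhg_s = dpdt_max(pres$trace))
  })
  table <- dplyr::bind_rows(rows)
  fits <- list(
    ea = linear_fit(table, global_ea_pct, dpdt_max_mmhg_s),
    ecc = linear_fit(table, global_ecc_pct, dpdt_max_mmhg_s),
    ell = linear_fit(table, global_ell_pct, dpdt_max_mmhg_s))
  list(table = table, fits = fits,
       glance = dplyr::bind_rows(purrr::imap(fits, ~dplyr::mutate(glance(.x),
                                                                  component = .y,
                                                                  .before = 1))))
}
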