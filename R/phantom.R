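# Synthetic contracting-LV phantom with analytic ground truth.
#
# The phantom emulates what the imaging pipeline consumes: a truncated
# half-ellipsoid (or cylinder) endocardial/epicardial surface contracting
# through one cardiac cycle, with an optional akinetic patch of prescribed
# angular and longitudinal extent, plus matched pressure traces and
# histology masks. Every generated dataset carries closed-form or
# independently computed ground truth.

#' Akinetic patch description for the phantom
#'
#' @param theta_center_deg angular centre of the patch (0 = anterior wall).
#' @param theta_extent_deg full angular extent of the akinetic core, deg.
#' @param z_range longitudinal extent as fractions of base-to-apex length,
#'   `c(from, to)` in `[0, 1]`.
#' @param severity 0 (fully contracting) .. 1 (fully akinetic).
#' @param border_width_deg width of the smoothstep border zone blended
#'   outward from the core, deg.
#' @return a list of class `infarct_patch`.
#' @export
infarct_patch <- function(theta_center_deg = 0, theta_extent_deg = 0,
                          z_range = c(0, 1), severity = 0,
                          border_width_deg = 0) {
  if (severity < 0 || severity > 1) abort("`severity` must be in [0, 1].")
  if (length(z_range) != 2L || any(z_range < 0) || any(z_range > 1) ||
      z_range[1] > z_range[2])
    abort("`z_range` must be increasing fractions within [0, 1].")
  if (theta_extent_deg < 0 || theta_extent_deg > 360)
    abort("`theta_extent_deg` must be in [0, 360].")
  structure(list(theta_center_deg = theta_center_deg,
                 theta_extent_deg = theta_extent_deg,
                 z_range = z_range, severity = severity,
                 border_width_deg = border_width_deg),
            class = "infarct_patch")
}

#' Phantom configuration
#'
#' Geometry, contraction kinematics and infarct description of the
#' synthetic left ventricle. Defaults approximate a rat LV: 4 mm
#' end-diastolic cavity radius, 12 mm cavity length, 2 mm wall, 0.17 s
#' cycle (~350 bpm), peak systole at 35% of the cycle, and healthy peak
#' contraction scales 0.8 (circumferential) and 0.9 (longitudinal).
#'
#' @param geometry `"ellipsoid"` (truncated half-ellipsoid, default) or
#'   `"cylinder"` (used for exact analytic oracles).
#' @param endo_radius_mm end-diastolic endocardial equatorial radius, mm.
#' @param endo_length_mm end-diastolic base-to-apex cavity length, mm.
#' @param wall_thickness_mm myocardial wall thickness, mm.
#' @param cycle_duration_s cardiac-cycle duration, s.
#' @param systole_fraction time of peak contraction as a fraction of the
#'   cycle.
#' @param lambda_min circumferential scale at peak systole (<= 1).
#' @param mu_min longitudinal scale at peak systole (<= 1).
#' @param infarct an [infarct_patch()].
#' @param nontransmural if `TRUE`, generated histology labels the scar in
#'   the mid-wall only (the strain kinematics are unaffected).
#' @param noise_sd_mm SD of independent Gaussian node jitter, mm.
#' @param seed RNG seed used for the jitter.
#' @param n_time,n_slices,n_rotations mesh grid dimensions.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(geometry = c("ellipsoid", "cylinder"),
                           endo_radius_mm = 4, endo_length_mm = 12,
                           wall_thickness_mm = 2, cycle_duration_s = 0.17,
                           systole_fraction = 0.35,
                           lambda_min = 0.8, mu_min = 0.9,
                           infarct = infarct_patch(),
                           nontransmural = FALSE,
                           noise_sd_mm = 0, seed = 1L,
                           n_time = 60L, n_slices = 60L, n_rotations = 60L) {
  geometry <- match.arg(geometry)
  if (lambda_min <= 0 || lambda_min > 1 || mu_min <= 0 || mu_min > 1)
    abort("contraction scales must be in (0, 1].")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    abort("`systole_fraction` must be in (0, 1).")
  if (!inherits(infarct, "infarct_patch")) abort("`infarct` must be an infarct_patch().")
  structure(list(
    geometry = geometry, endo_radius_mm = endo_radius_mm,
    endo_length_mm = endo_length_mm, wall_thickness_mm = wall_thickness_mm,
    cycle_duration_s = cycle_duration_s, systole_fraction = systole_fraction,
    lambda_min = lambda_min, mu_min = mu_min, infarct = infarct,
    nontransmural = nontransmural, noise_sd_mm = noise_sd_mm,
    seed = as.integer(seed), n_time = as.integer(n_time),
    n_slices = as.integer(n_slices), n_rotations = as.integer(n_rotations)),
    class = "phantom_config")
}

# raised-cosine activation: 0 at end diastole, 1 at the systole fraction,
# smoothly periodic over the cycle
activation_curve <- function(t_frac, systole_fraction) {
  p <- systole_fraction
  ifelse(t_frac <= p,
         (1 - cos(pi * t_frac / p)) / 2,
         (1 + cos(pi * (t_frac - p) / (1 - p))) / 2)
}

# smoothstep akinesis blend in [0, 1] at given angles/z-fractions
akinesis_blend <- function(theta, z_frac, infarct) {
  if (infarct$theta_extent_deg <= 0 || infarct$severity < 0) {
    return(array(0, dim = c(length(theta), length(z_frac))))
  }
  th_c <- infarct$theta_center_deg * pi / 180
  h <- infarct$theta_extent_deg * pi / 360          # half extent, rad
  bw <- infarct$border_width_deg * pi / 180
  d <- abs(((theta - th_c + pi) %% (2 * pi)) - pi)
  bt <- ifelse(d <= h, 1,
        ifelse(d >= h + bw | bw <= 0, 0,
               { x <- (d - h) / bw; 1 - (3 * x^2 - 2 * x^3) }))
  bz <- as.numeric(z_frac >= infarct$z_range[1] & z_frac <= infarct$z_range[2])
  outer(bt, bz)
}

# reference (end-diastolic) surface: list of radius (Z x Th is constant in
# theta here -> length Z), z (length Z) per surface
phantom_reference <- function(cfg) {
  Z <- cfg$n_slices
  a <- cfg$endo_radius_mm; cc <- cfg$endo_length_mm; w <- cfg$wall_thickness_mm
  if (cfg$geometry == "cylinder") {
    zf <- (seq_len(Z) - 1) / (Z - 1)
    list(endo = list(r = rep(a, Z), z = cc * zf),
         epi  = list(r = rep(a + w, Z), z = cc * zf),
         z_frac = zf)
  } else {
    # truncated one node-row above the pole: phi_max = (pi/2) (Z-1)/Z
    phi <- (pi / 2) * (seq_len(Z) - 1) / Z
    zf <- (seq_len(Z) - 1) / (Z - 1)
    list(endo = list(r = a * cos(phi), z = cc * sin(phi)),
         epi  = list(r = (a + w) * cos(phi), z = (cc + w) * sin(phi)),
         z_frac = zf)
  }
}

#' Generate a contracting-LV phantom with ground truth
#'
#' Builds a dense [mesh4d()] of a contracting truncated-ellipsoid (or
#' cylinder) left ventricle. Healthy tissue follows a raised-cosine time
#' course between the end-diastolic shape and peak-systolic scales
#' `(lambda_min, mu_min)` (circumferential/longitudinal); inside the
#' akinetic patch the local scales are blended back toward 1 in proportion
#' to `severity`, with a smoothstep border zone. Frame 1 is the undeformed
#' end-diastolic reference.
#'
#' @param cfg a [phantom_config()].
#' @return a list of class `lv_phantom` with elements `mesh` ([mesh4d()]),
#'   `truth` (one-row tibble of analytic ground truth) and `config`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  Tn <- cfg$n_time; Z <- cfg$n_slices; Th <- cfg$n_rotations
  theta <- 2 * pi * (seq_len(Th) - 1) / Th
  ref <- phantom_reference(cfg)
  t_frac <- (seq_len(Tn) - 1) / Tn
  wact <- activation_curve(t_frac, cfg$systole_fraction)
  lam_t <- 1 - (1 - cfg$lambda_min) * wact
  mu_t <- 1 - (1 - cfg$mu_min) * wact
  sev <- cfg$infarct$severity
  blend <- akinesis_blend(theta, ref$z_frac, cfg$infarct)   # Th x Z

  coords <- array(NA_real_, c(Tn, 2, Z, Th, 3))
  cth <- cos(theta); sth <- sin(theta)
  for (s in 1:2) {
    surf <- if (s == 1) ref$endo else ref$epi
    r0 <- matrix(surf$r, nrow = Th, ncol = Z, byrow = TRUE)   # Th x Z
    z0 <- matrix(surf$z, nrow = Th, ncol = Z, byrow = TRUE)
    for (f in seq_len(Tn)) {
      lam_loc <- lam_t[f] + sev * blend * (1 - lam_t[f])      # Th x Z
      mu_loc <- mu_t[f] + sev * blend * (1 - mu_t[f])
      coords[f, s, , , 1] <- t(lam_loc * r0 * cth)
      coords[f, s, , , 2] <- t(lam_loc * r0 * sth)
      coords[f, s, , , 3] <- t(mu_loc * z0)
    }
  }
  if (cfg$noise_sd_mm > 0) {
    set.seed(cfg$seed)
    coords <- coords + array(stats::rnorm(length(coords), sd = cfg$noise_sd_mm),
                             dim = dim(coords))
  }
  mesh <- mesh4d(coords, cfg$cycle_duration_s)

  truth <- phantom_truth(cfg, mesh)
  structure(list(mesh = mesh, truth = truth, config = cfg),
            class = "lv_phantom")
}

# closed-form strain values where exact, independent numeric volumes, and
# reference-area infarct fraction
phantom_truth <- function(cfg, mesh) {
  lam <- cfg$lambda_min; mu <- cfg$mu_min
  iso <- isTRUE(all.equal(lam, mu))
  exact <- cfg$geometry == "cylinder" || iso
  lam_inf <- lam + cfg$infarct$severity * (1 - lam)
  mu_inf <- mu + cfg$infarct$severity * (1 - mu)
  ecc <- function(l) 50 * (l^2 - 1)
  ell <- function(m) 100 * (m - 1)
  ea <- function(l, m) 100 * (l * m - 1)

  # reference-area infarct fraction by numeric summation of patch areas.
  # The akinetic tissue of the generated mesh is the set of surface
  # patches all of whose corner nodes lie in the akinetic core (the
  # deformation is applied at nodes, so a patch contracts iff its
  # bounding nodes do); the outer fraction additionally admits any patch
  # touching the border zone.
  aD <- patch_area_array(mesh, "endo")[1, , ]                 # (Z-1) x Th
  Z <- cfg$n_slices; Th <- cfg$n_rotations
  th_n <- 2 * pi * (seq_len(Th) - 1) / Th
  zf_n <- (seq_len(Z) - 1) / (Z - 1)
  sharp <- cfg$infarct; sharp$border_width_deg <- 0; sharp$severity <- 1
  wide <- sharp
  wide$theta_extent_deg <- min(360, sharp$theta_extent_deg +
                                 2 * cfg$infarct$border_width_deg)
  bn <- t(akinesis_blend(th_n, zf_n, sharp) >= 1)             # Z x Th at nodes
  bo <- t(akinesis_blend(th_n, zf_n, wide) >= 1)
  thn <- c(2:Th, 1)
  corner_all <- bn[-Z, ] & bn[-Z, thn] & bn[-1, ] & bn[-1, thn]
  corner_any <- bo[-Z, ] | bo[-Z, thn] | bo[-1, ] | bo[-1, thn]
  has_inf <- cfg$infarct$theta_extent_deg > 0 && cfg$infarct$severity > 0
  frac_core <- if (has_inf) sum(aD[corner_all]) / sum(aD) else 0
  frac_outer <- if (has_inf) sum(aD[corner_any]) / sum(aD) else 0

  vols <- numeric_volume_trace(mesh)
  tibble(
    ecc_healthy_pct = if (exact) ecc(lam) else NA_real_,
    ell_healthy_pct = if (exact) ell(mu) else NA_real_,
    ea_healthy_pct = if (exact) ea(lam, mu) else NA_real_,
    ecc_infarct_pct = if (exact) ecc(lam_inf) else NA_real_,
    ell_infarct_pct = if (exact) ell(mu_inf) else NA_real_,
    ea_infarct_pct = if (exact) ea(lam_inf, mu_inf) else NA_real_,
    infarct_area_fraction = frac_core,
    infarct_area_fraction_outer = frac_outer,
    lvedv_ul = vols[1],
    lvesv_ul = min(vols),
    peak_frame = which.min(vols))
}

# independent numeric cavity volume: shoelace cross-section areas +
# trapezoidal integration along z (distinct from the divergence-theorem
# route in cavity_volume())
numeric_volume_trace <- function(mesh) {
  P <- surface_coords(mesh, "endo")
  d <- dim(P); Tn <- d[1]; Z <- d[2]; Th <- d[3]
  thn <- c(2:Th, 1)
  vapply(seq_len(Tn), function(f) {
    x <- matrix(P[f, , , 1], Z, Th); y <- matrix(P[f, , , 2], Z, Th)
    zc <- rowMeans(matrix(P[f, , , 3], Z, Th))
    A <- abs(0.5 * rowSums(x * y[, thn] - x[, thn] * y))
    sum((A[-Z] + A[-1]) / 2 * abs(diff(zc)))
  }, numeric(1))
}

#' Sample a 48-point control set from a dense mesh
#'
#' Picks 4 (near-)equally spaced slices and 6 equally spaced rotations per
#' surface from the mesh nodes, emulating the tracked boundary points the
#' resampler consumes: 4 x 6 x 2 = 48 points per frame.
#'
#' @param mesh a [mesh4d()] with at least 4 slices and 6 rotations.
#' @return a [control_points()] set with the mesh's frames.
#' @export
sample_control_points <- function(mesh) {
  d <- mesh_dim(mesh)
  if (d[["n_slices"]] < 4L || d[["n_rotations"]] < 6L)
    abort("mesh too coarse: need >= 4 slices and >= 6 rotations.")
  sl <- round(seq(1, d[["n_slices"]], length.out = 4))
  rt <- 1 + round((0:5) * d[["n_rotations"]] / 6)
  cp <- mesh$coords[, , sl, rt, , drop = FALSE]
  control_points(cp, mesh$cycle_duration_s,
                 slice_positions = (sl - 1) / (d[["n_slices"]] - 1))
}

#' Generate a synthetic LV pressure trace
#'
#' Sinusoid-plus-baseline pressure with known analytic peak derivative
#' `amplitude * 2 * pi / period`.
#'
#' @param amplitude_mmhg sinusoid amplitude, mmHg.
#' @param baseline_mmhg baseline pressure, mmHg.
#' @param period_s cycle period, s.
#' @param duration_s trace duration, s (default three cycles).
#' @param fs_hz sampling rate, Hz.
#' @return list with `trace` (tibble `time_s`, `pressure_mmhg` of class
#'   `pressure_trace`) and `dpdt_max_truth` in mmHg/s.
#' @export
generate_pressure <- function(amplitude_mmhg = 40, baseline_mmhg = 80,
                              period_s = 0.17, duration_s = 3 * period_s,
                              fs_hz = 1000) {
  if (amplitude_mmhg < 0) abort("`amplitude_mmhg` must be >= 0.")
  tt <- seq(0, duration_s, by = 1 / fs_hz)
  trace <- tibble(time_s = tt,
                  pressure_mmhg = baseline_mmhg +
                    amplitude_mmhg * sin(2 * pi * tt / period_s))
  class(trace) <- c("pressure_trace", class(trace))
  list(trace = trace, dpdt_max_truth = amplitude_mmhg * 2 * pi / period_s)
}

#' Generate labeled histology cross-section masks
#'
#' Rasterises annular short-axis sections of the phantom at equally
#' spaced levels from base to apex. Pixels are labeled 0 (background),
#' 1 (healthy myocardium) or 2 (infarct scar); the scar occupies the
#' akinetic core's angular and longitudinal extent, full thickness for
#' transmural phantoms or the mid-third of the wall when
#' `nontransmural = TRUE`.
#'
#' @param cfg a [phantom_config()].
#' @param n_sections number of sections (default 4).
#' @param image_size raster side length in pixels (>= 256).
#' @return list of [section_mask()] objects.
#' @export
generate_histology <- function(cfg, n_sections = 4, image_size = 512) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (image_size < 256) abort("`image_size` must be >= 256.")
  a <- cfg$endo_radius_mm; w <- cfg$wall_thickness_mm
  half_field <- (a + w) * 1.15
  px_mm <- 2 * half_field / image_size
  ctr <- (image_size + 1) / 2
  ix <- matrix(rep(seq_len(image_size), image_size), image_size)
  iy <- t(ix)
  xm <- (ix - ctr) * px_mm
  ym <- (iy - ctr) * px_mm
  rr <- sqrt(xm^2 + ym^2)
  ang <- atan2(ym, xm) %% (2 * pi)
  th_c <- cfg$infarct$theta_center_deg * pi / 180
  h <- cfg$infarct$theta_extent_deg * pi / 360
  dang <- abs(((ang - th_c + pi) %% (2 * pi)) - pi)
  has_inf <- cfg$infarct$theta_extent_deg > 0 && cfg$infarct$severity > 0

  lapply(seq_len(n_sections), function(k) {
    zf <- (k - 0.5) / n_sections
    if (cfg$geometry == "cylinder") {
      r_en <- a
    } else {
      r_en <- a * cos(pi / 2 * zf)
    }
    r_ep <- r_en + w
    if (r_ep - r_en < 2 * px_mm) abort("wall thinner than 2 px at this level.")
    lab <- matrix(0L, image_size, image_size)
    myo <- rr >= r_en & rr <= r_ep
    lab[myo] <- 1L
    if (has_inf && zf >= cfg$infarct$z_range[1] && zf <= cfg$infarct$z_range[2]) {
      in_wedge <- myo & dang <= h
      if (cfg$nontransmural) {
        in_wedge <- in_wedge & rr >= r_en + w / 3 & rr <= r_en + 2 * w / 3
      }
      lab[in_wedge] <- 2L
    }
    section_mask(lab, pixel_size_mm = px_mm, level = k)
  })
}
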