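# Strain components, peak extraction and strain rate.

test_that("strain formulas reproduce their closed-form values", {
  # cylinder contracting to lam = 0.8, mu = 0.85 at the last frame
  lam <- function(tf) 1 - 0.2 * tf
  mu <- function(tf) 1 - 0.15 * tf
  m <- make_mesh(cylinder_fun(3, 10, lam, mu),
                 n_time = 5, n_slices = 10, n_rotations = 12)
  ec <- ecc_curve(m, 4)
  el <- ell_curve(m, 7)
  # C/C_D = 0.8 at tf = 1 -> frame 5 has tf = 4/5 -> lam = 0.84
  expect_equal(ec$strain_pct[5], 50 * (0.84^2 - 1), tolerance = 1e-12)
  expect_equal(el$strain_pct[5], 100 * (0.88 - 1), tolerance = 1e-12)
  # Lagrangian zero at frame 1
  expect_identical(ec$strain_pct[1], 0)
  expect_identical(el$strain_pct[1], 0)

  # expansion: C/C_D = 1.1 -> +10.5 %, L/L_D = 1.05 -> +5 %
  mx <- make_mesh(cylinder_fun(3, 10, function(tf) 1 + 0.2 * tf,
                               function(tf) 1 + 0.1 * tf),
                  n_time = 2, n_slices = 6, n_rotations = 8)
  expect_equal(ecc_curve(mx, 2)$strain_pct[2], 10.5, tolerance = 1e-12)
  expect_equal(ell_curve(mx, 3)$strain_pct[2], 5, tolerance = 1e-12)
})

test_that("surface-area strain matches the cylinder product rule", {
  # radial scale 0.8 and axial scale 0.9 at peak: A scales by lam * mu
  ph <- generate_phantom(phantom_config(geometry = "cylinder",
                                        lambda_min = 0.8, mu_min = 0.9,
                                        n_time = 10, n_slices = 16,
                                        n_rotations = 18,
                                        systole_fraction = 0.3))
  f <- ea_field(ph$mesh)
  pk <- f[f$frame == attr(f, "peak_frame"), ]
  expect_lt(max(abs(pk$ea_pct - (-28))), 1e-9)
  expect_true(all(f$ea_pct[f$frame == 1] == 0))
})

test_that("degenerate reference geometry raises errors", {
  m <- make_mesh(cylinder_fun(3, 10), n_time = 2, n_slices = 6, n_rotations = 8)
  m$coords[, , 2, , 1:2] <- 0   # collapse slice 2 to the axis at all frames
  expect_error(ecc_curve(m, 2), "degenerate")
  m2 <- make_mesh(cylinder_fun(3, 10), n_time = 2, n_slices = 6, n_rotations = 8)
  m2$coords[, , 3, , ] <- m2$coords[, , 2, , ]   # zero-area band 2
  expect_error(ea_field(m2), "degenerate")
  # all nodes coincident: zero reference meridian length
  expect_error(ell_curve(mesh4d(array(0, c(2, 2, 4, 6, 3)), 0.2), 1),
               "meridian")
})

test_that("strains are invariant under a rigid motion of all frames", {
  ph <- generate_phantom(fast_cylinder(
    infarct = infarct_patch(theta_extent_deg = 80, severity = 0.7)))
  m <- ph$mesh
  mr <- rigid_transform(m)
  expect_equal(ecc_curve(mr, 5)$strain_pct, ecc_curve(m, 5)$strain_pct,
               tolerance = 1e-9)
  expect_equal(ell_curve(mr, 3)$strain_pct, ell_curve(m, 3)$strain_pct,
               tolerance = 1e-9)
  expect_equal(ea_field(mr)$ea_pct, ea_field(m)$ea_pct, tolerance = 1e-9)
})

test_that("isotropic scaling obeys the closed forms on the ellipsoid", {
  s <- 0.9
  ph <- generate_phantom(phantom_config(lambda_min = s, mu_min = s,
                                        n_time = 12, n_slices = 30,
                                        n_rotations = 30,
                                        systole_fraction = 1 / 3))
  g <- global_peaks(ph$mesh)
  expect_equal(g$global_ecc_pct, 50 * (s^2 - 1), tolerance = 1e-6)
  expect_equal(g$global_ell_pct, 100 * (s - 1), tolerance = 1e-6)
  expect_equal(g$global_ea_pct, 100 * (s^2 - 1), tolerance = 1e-6)
})

test_that("small isotropic strains linearise correctly", {
  for (eps in c(1e-3, 1e-2)) {
    s <- 1 + eps
    # frame 2 of 2 sits at tf = 0.5, so the scale doubles with tf
    m <- make_mesh(cylinder_fun(3, 10, function(tf) 1 + eps * 2 * tf,
                                function(tf) 1 + eps * 2 * tf),
                   n_time = 2, n_slices = 8, n_rotations = 10)
    ecc <- ecc_curve(m, 3)$strain_pct[2]
    ea <- ea_field(m)
    ea2 <- ea$ea_pct[ea$frame == 2][1]
    expect_lte(abs(ecc - 100 * eps), 100 * eps^2 + 1e-12)
    expect_lte(abs(ea2 - 200 * eps), 200 * eps^2 + 1e-9)
  }
})

test_that("ea_field agrees with a brute-force per-triangle recomputation", {
  pert <- make_mesh(function(tf, zf, th) {
    r <- (3 + 0.4 * cos(2 * th) * zf) * (1 - 0.15 * tf)
    c(r * cos(th), r * sin(th), 9 * zf * (1 - 0.1 * tf) + 0.1 * sin(th))
  }, n_time = 4, n_slices = 5, n_rotations = 8)
  f <- ea_field(pert)
  aD <- brute_patch_areas(pert, 1)
  for (fr in 1:4) {
    A <- brute_patch_areas(pert, fr)
    want <- 100 * (A / aD - 1)
    got <- matrix(NA_real_, 4, 8)
    sub <- f[f$frame == fr, ]
    got[cbind(sub$band, sub$rotation)] <- sub$ea_pct
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("peak systole is the earliest minimum-volume frame", {
  expect_identical(peak_systole_frame(c(10, 8, 5, 2, 4, 9)), 4L)
  expect_identical(peak_systole_frame(c(9, 5, 2, 6, 2, 7)), 3L)
  expect_identical(peak_systole_frame(c(9, 8, 7, 6)), 4L)
  expect_error(peak_systole_frame(5), "2 frames")
})

test_that("global peaks collapse to the closed forms for uniform motion", {
  # identity motion
  ph0 <- generate_phantom(fast_cylinder(lambda_min = 1, mu_min = 1))
  g0 <- global_peaks(ph0$mesh)
  expect_equal(g0$global_ecc_pct, 0, tolerance = 1e-12)
  expect_equal(g0$global_ell_pct, 0, tolerance = 1e-12)
  expect_equal(g0$global_ea_pct, 0, tolerance = 1e-12)

  # cylinder lam = 0.8, mu = 0.9
  ph <- generate_phantom(fast_cylinder(lambda_min = 0.8, mu_min = 0.9))
  g <- global_peaks(ph$mesh)
  expect_equal(g$global_ecc_pct, -18, tolerance = 1e-9)
  expect_equal(g$global_ell_pct, -10, tolerance = 1e-9)
  expect_equal(g$global_ea_pct, -28, tolerance = 1e-9)
})

test_that("volume trace carries the reference and minimum volumes", {
  ph <- generate_phantom(fast_cylinder())
  vt <- volume_trace(ph$mesh)
  expect_equal(attr(vt, "lvedv_ul"), vt$volume_ul[1])
  expect_equal(attr(vt, "lvesv_ul"), min(vt$volume_ul))
  expect_identical(peak_systole_frame(vt), which.min(vt$volume_ul))
})

test_that("strain rate equals the least-squares slope of the systolic limb", {
  # linear ramp 0 -> -18 % over 0.06 s
  curve <- tibble::tibble(frame = 1:7, time_s = seq(0, 0.06, length.out = 7),
                          strain_pct = seq(0, -18, length.out = 7))
  expect_equal(strain_rate(curve, 7), -300, tolerance = 1e-9)

  # constant curve
  flat <- tibble::tibble(frame = 1:5, time_s = seq(0, 0.1, length.out = 5),
                         strain_pct = rep(0, 5))
  expect_equal(strain_rate(flat, 5), 0)

  # quadratic segment vs brute-force normal equations
  tt <- seq(0, 0.1, by = 1 / 60)
  qc <- tibble::tibble(frame = seq_along(tt), time_s = tt,
                       strain_pct = -100 * tt^2)
  n <- length(tt)
  slope_brute <- (n * sum(tt * qc$strain_pct) - sum(tt) * sum(qc$strain_pct)) /
    (n * sum(tt^2) - sum(tt)^2)
  expect_equal(strain_rate(qc, n), slope_brute, tolerance = 1e-12)

  expect_error(strain_rate(curve, 1), "window")
})
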