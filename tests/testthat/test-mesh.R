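# Mesh construction, resampling and geometric primitives.

test_that("control-point sets enforce their invariants", {
  ph <- generate_phantom(fast_cylinder())
  cp <- sample_control_points(ph$mesh)
  expect_s3_class(cp, "control_points")
  expect_identical(dim(cp$coords)[2:5], c(2L, 4L, 6L, 3L))

  # wrong shape
  expect_error(control_points(array(0, c(3, 2, 4, 5, 3)), 0.2), "slices")
  # too few frames
  expect_error(control_points(cp$coords[1, , , , , drop = FALSE], 0.2),
               "2 frames")
  # non-positive cycle
  expect_error(control_points(cp$coords, 0), "positive")
  # endo outside epi
  bad <- cp$coords
  bad[, 1, , , 1:2] <- bad[, 2, , , 1:2] * 2
  expect_error(control_points(bad, 0.2), "outside")
})

test_that("resampling conserves the requested node counts", {
  ph <- generate_phantom(fast_cylinder())
  cp <- sample_control_points(ph$mesh)
  for (spec in list(sampling_spec(8, 10, 12), sampling_spec(5, 21, 7))) {
    m <- resample_mesh(cp, spec)
    expect_identical(unname(mesh_dim(m)),
                     c(spec$n_time, spec$n_slices, spec$n_rotations))
  }
})

test_that("the interpolating surface passes through every control point", {
  # grids chosen so the output parameters include the control parameters
  cfg <- phantom_config(n_time = 10, n_slices = 55, n_rotations = 60)
  ph <- generate_phantom(cfg)
  cp <- sample_control_points(ph$mesh)
  m <- resample_mesh(cp, sampling_spec(10, 55, 60))
  sl <- round(seq(1, 55, length.out = 4))
  rt <- 1 + round((0:5) * 60 / 6)
  expect_lt(max(abs(m$coords[, , sl, rt, ] - cp$coords)), 1e-9)
})

test_that("control points on an exact cylinder resample onto the cylinder", {
  ph <- generate_phantom(phantom_config(geometry = "cylinder",
                                        n_time = 8, n_slices = 16,
                                        n_rotations = 18,
                                        lambda_min = 0.8, mu_min = 0.9))
  m <- resample_mesh(sample_control_points(ph$mesh), sampling_spec(8, 30, 40))
  for (s in c("endo", "epi")) {
    si <- if (s == "endo") 1 else 2
    r <- sqrt(m$coords[, si, , , 1]^2 + m$coords[, si, , , 2]^2)
    r0 <- sqrt(ph$mesh$coords[, si, 1, 1, 1]^2 + ph$mesh$coords[, si, 1, 1, 2]^2)
    # per-frame radius of the generating cylinder
    rf <- sqrt(ph$mesh$coords[, si, 1, 1, 1]^2 + ph$mesh$coords[, si, 1, 1, 2]^2)
    expect_lt(max(abs(sweep(r, 1, rf, "/") - 1)), 1e-6)
  }
})

test_that("static control points give a static mesh", {
  ph <- generate_phantom(fast_cylinder(lambda_min = 1, mu_min = 1))
  m <- resample_mesh(sample_control_points(ph$mesh), sampling_spec(9, 11, 13))
  for (f in 2:9) expect_equal(m$coords[f, , , , ], m$coords[1, , , , ])
})

test_that("degenerate coincident control points are rejected", {
  ph <- generate_phantom(fast_cylinder())
  cp <- sample_control_points(ph$mesh)
  cp$coords[1, 1, 2, , ] <- rep(c(0, 0, 5), each = 6)
  expect_error(resample_mesh(cp, sampling_spec(4, 4, 6)), "degenerate|coincident")
})

test_that("slice circumference matches closed forms and scales linearly", {
  m <- make_mesh(cylinder_fun(radius = 3, height = 10),
                 n_time = 2, n_slices = 5, n_rotations = 60)
  # regular 60-gon of radius 3
  expect_equal(slice_circumference(m, 1, 2), 120 * 3 * sin(pi / 60),
               tolerance = 1e-12)
  m2 <- mesh4d(m$coords * 2, m$cycle_duration_s)
  expect_equal(slice_circumference(m2, 1, 2),
               2 * slice_circumference(m, 1, 2), tolerance = 1e-12)
  # all-coincident slice
  mc <- m
  mc$coords[1, 1, 3, , ] <- rep(c(1, 2, 3), each = 60)
  expect_equal(slice_circumference(mc, 1, 3), 0)
})

test_that("meridian length matches closed forms", {
  m <- make_mesh(cylinder_fun(radius = 3, height = 10),
                 n_time = 2, n_slices = 60, n_rotations = 8)
  expect_equal(meridian_length(m, 1, 1), 10, tolerance = 1e-12)
  # semicircular meridian of radius 5: chord sum slightly below the arc
  semi <- make_mesh(function(tf, zf, th) {
    phi <- pi * zf
    c((5 * sin(phi) + 6) * cos(th), (5 * sin(phi) + 6) * sin(th), -5 * cos(phi))
  }, n_time = 2, n_slices = 60, n_rotations = 8)
  L <- meridian_length(semi, 1, 1)
  expect_lte(L, 5 * pi)
  expect_gt(L, 5 * pi * (1 - 0.002))
  # coincident nodes
  mc <- m
  mc$coords[1, 1, , 2, ] <- rep(c(0, 3, 0), each = 60)
  expect_equal(meridian_length(mc, 1, 2), 0)
})

test_that("patch areas match planar geometry and the brute-force oracle", {
  # planar unit square: radius chosen so adjacent chord = 1 and dz = 1
  r <- 0.5 / sin(pi / 4)   # 4 rotations -> chord = 2 r sin(pi/4)
  m <- make_mesh(cylinder_fun(radius = r, height = 2),
                 n_time = 2, n_slices = 3, n_rotations = 4)
  expect_equal(patch_area(m, 1, 1, 1), 1, tolerance = 1e-12)

  # cylinder patch: chord x dz
  m2 <- make_mesh(cylinder_fun(radius = 3, height = 0.5 * 59),
                  n_time = 2, n_slices = 60, n_rotations = 60)
  expect_equal(patch_area(m2, 1, 10, 7), 2 * 3 * sin(pi / 60) * 0.5,
               tolerance = 1e-12)

  # degenerate collinear corners
  md <- m
  md$coords[1, 1, 1:2, 1:2, ] <- 0
  md$coords[1, 1, 1, 2, 1] <- 1
  md$coords[1, 1, 2, 1, 1] <- 2
  md$coords[1, 1, 2, 2, 1] <- 3
  expect_equal(patch_area(md, 1, 1, 1), 0)

  # brute-force oracle on a perturbed cylinder
  set.seed(42)
  pert <- make_mesh(function(tf, zf, th) {
    r <- 3 + 0.3 * sin(3 * th + 2 * pi * zf)
    c(r * cos(th), r * sin(th), 10 * zf + 0.2 * cos(th))
  }, n_time = 4, n_slices = 5, n_rotations = 8)
  for (f in c(1, 3)) {
    got <- sapply(1:8, function(h) sapply(1:4, function(z) patch_area(pert, f, z, h)))
    expect_equal(got, brute_patch_areas(pert, f), tolerance = 1e-12)
  }
})

test_that("lengths are invariant under rigid motion", {
  ph <- generate_phantom(fast_cylinder())
  m <- ph$mesh
  mr <- rigid_transform(m)
  expect_equal(slice_circumference(mr, 3, 5), slice_circumference(m, 3, 5),
               tolerance = 1e-9)
  expect_equal(meridian_length(mr, 2, 4), meridian_length(m, 2, 4),
               tolerance = 1e-9)
  expect_equal(patch_area(mr, 2, 3, 4), patch_area(m, 2, 3, 4),
               tolerance = 1e-9)
})

test_that("cavity volume matches analytic solids and scales as s^3", {
  # half ellipsoid a = b = 3, c = 7 truncated at the equator
  half <- make_mesh(function(tf, zf, th) {
    phi <- (pi / 2) * zf * (59 / 60)
    c(3 * cos(phi) * cos(th), 3 * cos(phi) * sin(th), 7 * sin(phi))
  }, n_time = 2, n_slices = 60, n_rotations = 60)
  expect_equal(cavity_volume(half, 1), (2 / 3) * pi * 9 * 7, tolerance = 0.02)

  # capped cylinder r = 3, h = 10
  cyl <- make_mesh(cylinder_fun(radius = 3, height = 10),
                   n_time = 2, n_slices = 60, n_rotations = 60)
  expect_equal(cavity_volume(cyl, 1), 90 * pi, tolerance = 0.02)

  s <- 1.7
  cyl2 <- mesh4d(cyl$coords * s, cyl$cycle_duration_s)
  expect_equal(cavity_volume(cyl2, 1) / cavity_volume(cyl, 1), s^3,
               tolerance = 1e-9)
})

test_that("cavity volume error shrinks with resolution on the ellipsoid", {
  truth <- (2 / 3) * pi * 9 * 7
  errs <- sapply(c(30, 60, 120), function(n) {
    m <- make_mesh(function(tf, zf, th) {
      phi <- (pi / 2) * zf * ((n - 1) / n)
      c(3 * cos(phi) * cos(th), 3 * cos(phi) * sin(th), 7 * sin(phi))
    }, n_time = 2, n_slices = n, n_rotations = n)
    abs(cavity_volume(m, 1) - truth)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("an inverted surface is flagged instead of returning a volume", {
  cyl <- make_mesh(cylinder_fun(radius = 3, height = 10),
                   n_time = 2, n_slices = 10, n_rotations = 12)
  flipped <- mesh4d(cyl$coords[, , , 12:1, , drop = FALSE], cyl$cycle_duration_s)
  expect_error(cavity_volume(flipped), "inverted|self-intersecting")
})

test_that("mesh tibble conversion round-trips the coordinate array", {
  ph <- generate_phantom(fast_cylinder())
  df <- tibble::as_tibble(ph$mesh)
  expect_identical(nrow(df), as.integer(prod(mesh_dim(ph$mesh))) * 2L)
  i <- which(df$frame == 3 & df$surface == "endo" & df$slice == 5 & df$rotation == 7)
  expect_identical(c(df$x_mm[i], df$y_mm[i], df$z_mm[i]),
                   unname(ph$mesh$coords[3, 1, 5, 7, ]))
})
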