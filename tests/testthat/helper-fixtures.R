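# Fixtures built in code: parametric meshes, annulus masks and
# brute-force oracles shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a mesh4d from a parametric surface f(t_frac, z_frac, theta) -> xyz;
# the same surface is used for endo and epi unless f_epi is given
make_mesh <- function(f, n_time = 4, n_slices = 12, n_rotations = 16,
                      cycle_duration_s = 0.2, f_epi = NULL) {
  f_epi <- f_epi %||% function(tf, zf, th) f(tf, zf, th) * 1.2
  coords <- array(NA_real_, c(n_time, 2, n_slices, n_rotations, 3))
  tfs <- (seq_len(n_time) - 1) / n_time
  zfs <- (seq_len(n_slices) - 1) / (n_slices - 1)
  ths <- 2 * pi * (seq_len(n_rotations) - 1) / n_rotations
  for (ti in seq_len(n_time)) for (zi in seq_len(n_slices))
    for (hi in seq_len(n_rotations)) {
      coords[ti, 1, zi, hi, ] <- f(tfs[ti], zfs[zi], ths[hi])
      coords[ti, 2, zi, hi, ] <- f_epi(tfs[ti], zfs[zi], ths[hi])
    }
  mesh4d(coords, cycle_duration_s)
}

# cylinder surface generator: radius and height scales per frame
cylinder_fun <- function(radius = 3, height = 10,
                         lam = function(tf) 1, mu = function(tf) 1) {
  function(tf, zf, th) {
    c(lam(tf) * radius * cos(th), lam(tf) * radius * sin(th),
      mu(tf) * height * zf)
  }
}

# rigid transform applied to every node of a mesh (same for all frames)
rigid_transform <- function(mesh, angles = c(0.3, -0.5, 1.1),
                            shift = c(5, -2, 7)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  R <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
       matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
       matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  d <- dim(mesh$coords)
  m <- matrix(mesh$coords, ncol = 3)
  m <- m %*% t(R)
  m <- sweep(m, 2, shift, "+")
  mesh4d(array(m, d), mesh$cycle_duration_s)
}

# brute-force patch areas: per-triangle loop, no vectorisation shared
# with the implementation
brute_patch_areas <- function(mesh, frame) {
  P <- mesh$coords[frame, 1, , , , drop = TRUE]   # Z x Th x 3
  Z <- dim(P)[1]; Th <- dim(P)[2]
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                     u[3] * v[1] - u[1] * v[3],
                     u[1] * v[2] - u[2] * v[1])^2))
  }
  out <- matrix(NA_real_, Z - 1, Th)
  for (z in 1:(Z - 1)) for (h in 1:Th) {
    h1 <- if (h == Th) 1 else h + 1
    p00 <- P[z, h, ]; p01 <- P[z, h1, ]; p10 <- P[z + 1, h, ]; p11 <- P[z + 1, h1, ]
    out[z, h] <- tri_area(p00, p01, p11) + tri_area(p00, p11, p10)
  }
  out
}

# synthetic annulus mask with an optional infarct wedge
annulus_mask <- function(size = 512, r_endo = 0.25, r_epi = 0.42,
                         wedge_deg = 0, wedge_center_deg = 0,
                         midwall_only = FALSE, pixel_size_mm = 0.02,
                         center = c(0, 0)) {
  ctr <- (size + 1) / 2
  ix <- matrix(rep(seq_len(size), size), size)
  iy <- t(ix)
  xm <- (ix - ctr) / size - center[1]
  ym <- (iy - ctr) / size - center[2]
  rr <- sqrt(xm^2 + ym^2)
  lab <- matrix(0L, size, size)
  myo <- rr >= r_endo & rr <= r_epi
  lab[myo] <- 1L
  if (wedge_deg > 0) {
    ang <- atan2(ym, xm)
    d <- abs(((ang - wedge_center_deg * pi / 180 + pi) %% (2 * pi)) - pi)
    wedge <- myo & d <= wedge_deg * pi / 360
    if (midwall_only) {
      w <- r_epi - r_endo
      wedge <- wedge & rr >= r_endo + w / 3 & rr <= r_epi - w / 3
    }
    lab[wedge] <- 2L
  }
  section_mask(lab, pixel_size_mm = pixel_size_mm, level = 1L)
}

# small healthy cylinder phantom config for fast tests; the systole
# fraction is placed exactly on a frame time so peak scales are attained
fast_cylinder <- function(...) {
  phantom_config(geometry = "cylinder", n_time = 12, n_slices = 16,
                 n_rotations = 18, systole_fraction = 1 / 3, ...)
}
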