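#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats splinefun spline lm coef
NULL

SURFACES <- c("endo", "epi")

surf_idx <- function(surface) {
  surface <- match.arg(surface, SURFACES)
  match(surface, SURFACES)
}

#' Tracked control-point set
#'
#' Container for the sparse boundary points tracked over one cardiac cycle:
#' 4 short-axis slices x 6 rotational points x 2 surfaces (endocardium,
#' epicardium) = 48 points per frame. Frame 1 is end diastole and the
#' frames are assumed uniformly spaced over one cycle.
#'
#' @param coords numeric array with dim `(frames, 2, 4, 6, 3)`:
#'   frame, surface (1 = endo, 2 = epi), slice (base to apex), point
#'   (increasing rotation angle), and x/y/z in mm.
#' @param cycle_duration_s cardiac-cycle duration in seconds (> 0).
#' @param slice_positions normalized base-to-apex positions of the four
#'   tracked slices in `[0, 1]`; defaults to equal spacing. Recording the
#'   true acquisition positions lets the resampler place its long-axis
#'   knots correctly when the slices are only nominally equally spaced.
#' @return an object of class `control_points`.
#' @export
control_points <- function(coords, cycle_duration_s,
                           slice_positions = c(0, 1, 2, 3) / 3) {
  if (length(slice_positions) != 4L || is.unsorted(slice_positions, strictly = TRUE) ||
      slice_positions[1] < 0 || slice_positions[4] > 1)
    abort("`slice_positions` must be 4 strictly increasing fractions in [0, 1].")
  if (!is.array(coords) || length(dim(coords)) != 5L)
    abort("`coords` must be a 5-D array (frame, surface, slice, point, xyz).")
  d <- dim(coords)
  if (!identical(d[2:5], c(2L, 4L, 6L, 3L)))
    abort(sprintf(
      "`coords` must be (frames, 2 surfaces, 4 slices, 6 points, 3 coords); got (%s).",
      paste(d, collapse = ", ")))
  if (d[1] < 2L) abort("at least 2 frames are required.")
  if (!is.numeric(cycle_duration_s) || cycle_duration_s <= 0)
    abort("`cycle_duration_s` must be positive.")
  if (anyNA(coords)) abort("`coords` contains missing values.")
  # endo must lie radially inside epi at the same (slice, point) index
  for (f in seq_len(d[1])) for (sl in 1:4) {
    en <- coords[f, 1, sl, , , drop = TRUE]   # 6 x 3
    ep <- coords[f, 2, sl, , , drop = TRUE]
    cen <- colMeans(en[, 1:2, drop = FALSE])
    cep <- colMeans(ep[, 1:2, drop = FALSE])
    r_en <- sqrt((en[, 1] - cen[1])^2 + (en[, 2] - cen[2])^2)
    r_ep <- sqrt((ep[, 1] - cep[1])^2 + (ep[, 2] - cep[2])^2)
    if (any(r_en > r_ep + 1e-9))
      abort(sprintf("endocardial point outside epicardium (frame %d, slice %d).", f, sl))
  }
  structure(
    list(coords = coords, cycle_duration_s = as.numeric(cycle_duration_s),
         slice_positions = as.numeric(slice_positions)),
    class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<control_points> %d frames, 48 points/frame, cycle %.4g s\n",
              d[1], x$cycle_duration_s))
  invisible(x)
}

#' Mesh sampling specification
#'
#' Grid dimensions for resampling the sparse control points into a dense
#' 4D mesh. The defaults (60 time points, 60 slices base to apex, 60
#' rotations) give 3600 nodes per surface at each timepoint.
#'
#' @param n_time,n_slices,n_rotations grid sizes, each >= 4.
#' @return an object of class `sampling_spec`.
#' @export
sampling_spec <- function(n_time = 60L, n_slices = 60L, n_rotations = 60L) {
  v <- c(n_time = n_time, n_slices = n_slices, n_rotations = n_rotations)
  if (any(v < 4L)) abort("all sampling dimensions must be >= 4.")
  structure(lapply(as.list(v), as.integer), class = "sampling_spec")
}

#' Dense 4D left-ventricular surface mesh
#'
#' The central container: node coordinates in mm indexed by
#' (frame, surface, slice, rotation). Conventions: frame 1 is end diastole
#' (the Lagrangian reference for every strain); slices are ordered base
#' (slice 1) to apex (slice Z); rotation angles are `2*pi*(j-1)/Theta`
#' with the anterior wall at angle 0, increasing counterclockwise viewed
#' from the apex; the apex lies in the +z direction from the base plane.
#'
#' @param coords numeric array with dim `(T, 2, Z, Theta, 3)`.
#' @param cycle_duration_s cycle duration in seconds.
#' @return an object of class `mesh4d`.
#' @export
mesh4d <- function(coords, cycle_duration_s) {
  if (!is.array(coords) || length(dim(coords)) != 5L || dim(coords)[2] != 2L ||
      dim(coords)[5] != 3L)
    abort("`coords` must be a (T, 2, Z, Theta, 3) array.")
  if (dim(coords)[1] < 2L) abort("a mesh needs at least 2 frames.")
  if (!is.numeric(cycle_duration_s) || cycle_duration_s <= 0)
    abort("`cycle_duration_s` must be positive.")
  structure(
    list(coords = coords, cycle_duration_s = as.numeric(cycle_duration_s)),
    class = "mesh4d")
}

#' @export
print.mesh4d <- function(x, ...) {
  d <- mesh_dim(x)
  cat(sprintf(
    "<mesh4d> %d frames x 2 surfaces x %d slices x %d rotations (%d nodes/surface/frame), cycle %.4g s\n",
    d["n_time"], d["n_slices"], d["n_rotations"], d["n_slices"] * d["n_rotations"],
    x$cycle_duration_s))
  invisible(x)
}

#' Mesh grid dimensions
#' @param mesh a [mesh4d()] object.
#' @return named integer vector `n_time`, `n_slices`, `n_rotations`.
#' @export
mesh_dim <- function(mesh) {
  d <- dim(mesh$coords)
  c(n_time = d[1], n_slices = d[3], n_rotations = d[4])
}

#' Frame times of a mesh
#' @param mesh a [mesh4d()] object.
#' @return numeric vector of length `n_time`, starting at 0 (end diastole).
#' @export
mesh_times <- function(mesh) {
  T_ <- mesh_dim(mesh)[["n_time"]]
  mesh$cycle_duration_s * (seq_len(T_) - 1) / T_
}

#' Mesh rotation angles
#' @param mesh a [mesh4d()] object.
#' @return angles in radians, length `n_rotations`, starting at 0 (anterior).
#' @export
mesh_angles <- function(mesh) {
  Th <- mesh_dim(mesh)[["n_rotations"]]
  2 * pi * (seq_len(Th) - 1) / Th
}

#' @rdname mesh4d
#' @param x a `mesh4d` object.
#' @param ... unused.
#' @export
as_tibble.mesh4d <- function(x, ...) {
  d <- mesh_dim(x)
  grid <- expand.grid(
    frame = seq_len(d[["n_time"]]),
    surface = SURFACES,
    slice = seq_len(d[["n_slices"]]),
    rotation = seq_len(d[["n_rotations"]]),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble(
    frame = grid$frame, surface = grid$surface,
    slice = grid$slice, rotation = grid$rotation,
    x_mm = as.vector(x$coords[, , , , 1]),
    y_mm = as.vector(x$coords[, , , , 2]),
    z_mm = as.vector(x$coords[, , , , 3]))
}

# coordinates of one surface as a (T, Z, Theta, 3) array
surface_coords <- function(mesh, surface) {
  s <- surf_idx(surface)
  a <- mesh$coords[, s, , , , drop = FALSE]
  dim(a) <- dim(mesh$coords)[c(1, 3, 4, 5)]
  a
}

# ---- resampling --------------------------------------------------------

# linear operator of a cubic interpolating spline on fixed knots:
# out[i, j] = basis_j(xout_i)
spline_matrix <- function(knots, xout, method) {
  n <- length(knots)
  vapply(seq_len(n), function(j) {
    y <- numeric(n); y[j] <- 1
    if (method == "periodic") {
      f <- splinefun(c(knots, knots[1] + attr(knots, "period")),
                     c(y, y[1]), method = "periodic")
    } else {
      f <- splinefun(knots, y, method = method)
    }
    f(xout)
  }, numeric(length(xout)))
}

# apply matrix M (m x n) along the first dimension of array a (n x ...)
apply_first_dim <- function(M, a) {
  d <- dim(a)
  out <- M %*% matrix(a, nrow = d[1])
  dim(out) <- c(nrow(M), d[-1])
  out
}

#' Resample tracked control points into a dense 4D mesh
#'
#' Interpolates the 48 tracked boundary points per frame into a dense
#' space-time grid. Time interpolation uses a periodic cubic spline across
#' the cardiac cycle; within each short-axis slice the six points are
#' interpolated with a periodic cubic spline of radius and height against
#' the node angle about the slice centroid (so circular contours are
#' reproduced exactly); slices are then interpolated along the long axis
#' with a natural cubic spline. The interpolating surface passes through
#' every control point at its own parameters.
#'
#' @param cp a [control_points()] set.
#' @param spec a [sampling_spec()]; defaults give 3600 nodes per surface
#'   per timepoint.
#' @return a [mesh4d()].
#' @export
resample_mesh <- function(cp, spec = sampling_spec()) {
  stopifnot(inherits(cp, "control_points"), inherits(spec, "sampling_spec"))
  Fi <- dim(cp$coords)[1]
  Tn <- spec$n_time; Z <- spec$n_slices; Th <- spec$n_rotations
  cyc <- cp$cycle_duration_s

  # 1) periodic time interpolation (linear operator, shared by all points)
  tk <- structure(cyc * (seq_len(Fi) - 1) / Fi, period = cyc)
  tout <- cyc * (seq_len(Tn) - 1) / Tn
  Mt <- spline_matrix(tk, tout, "periodic")
  ct <- apply_first_dim(Mt, cp$coords)        # (Tn, 2, 4, 6, 3)

  # 2) periodic in-slice interpolation in polar form about the centroid
  theta_out <- 2 * pi * (seq_len(Th) - 1) / Th
  rad <- array(NA_real_, c(Tn, 2, 4, Th))
  hei <- array(NA_real_, c(Tn, 2, 4, Th))
  cenx <- array(NA_real_, c(Tn, 2, 4))
  ceny <- array(NA_real_, c(Tn, 2, 4))
  for (f in seq_len(Tn)) for (s in 1:2) for (sl in 1:4) {
    p <- matrix(ct[f, s, sl, , ], nrow = 6)   # 6 x 3
    cx <- mean(p[, 1]); cy <- mean(p[, 2])
    r <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
    if (max(r) < 1e-9)
      abort(sprintf("degenerate (coincident) control points on slice %d.", sl))
    phi <- atan2(p[, 2] - cy, p[, 1] - cx)
    ord <- order(phi)
    phi <- phi[ord]; r <- r[ord]; zz <- p[ord, 3]
    if (min(diff(phi)) < 1e-9)
      abort(sprintf("control points with coincident angles on slice %d.", sl))
    phik <- structure(phi, period = 2 * pi)
    to <- phi[1] + (theta_out - phi[1]) %% (2 * pi)
    Mth <- spline_matrix(phik, to, "periodic")
    rad[f, s, sl, ] <- Mth %*% r
    hei[f, s, sl, ] <- Mth %*% zz
    cenx[f, s, sl] <- cx; ceny[f, s, sl] <- cy
  }

  # 3) cubic interpolation base->apex at the recorded slice positions
  # (with four slices this is the unique interpolating cubic, which
  # tracks the curved base/apex profile far better than natural end
  # conditions)
  zk <- cp$slice_positions
  Mz <- spline_matrix(zk, seq(zk[1], zk[4], length.out = Z), "fmm")  # Z x 4
  coords <- array(NA_real_, c(Tn, 2, Z, Th, 3))
  cth <- cos(theta_out); sth <- sin(theta_out)
  for (f in seq_len(Tn)) for (s in 1:2) {
    rz <- Mz %*% rad[f, s, , ]          # Z x Th
    hz <- Mz %*% hei[f, s, , ]
    cxz <- drop(Mz %*% cenx[f, s, ])    # Z
    cyz <- drop(Mz %*% ceny[f, s, ])
    coords[f, s, , , 1] <- cxz + rz * rep(cth, each = Z)
    coords[f, s, , , 2] <- cyz + rz * rep(sth, each = Z)
    coords[f, s, , , 3] <- hz
  }
  mesh4d(coords, cyc)
}

# ---- geometric primitives ---------------------------------------------

# all slice circumferences of one surface: (T, Z) matrix
circumference_matrix <- function(mesh, surface = "endo") {
  P <- surface_coords(mesh, surface)                 # (T, Z, Th, 3)
  Th <- dim(P)[3]
  Q <- P[, , c(2:Th, 1), , drop = FALSE]
  D <- Q - P
  seg <- sqrt(D[, , , 1]^2 + D[, , , 2]^2 + D[, , , 3]^2)   # (T, Z, Th)
  colSums(aperm(seg, c(3, 1, 2)))
}

# all meridian lengths of one surface: (T, Theta) matrix
meridian_matrix <- function(mesh, surface = "endo") {
  P <- surface_coords(mesh, surface)
  Z <- dim(P)[2]
  D <- P[, 2:Z, , , drop = FALSE] - P[, 1:(Z - 1), , , drop = FALSE]
  seg <- sqrt(D[, , , 1]^2 + D[, , , 2]^2 + D[, , , 3]^2)   # (T, Z-1, Th)
  colSums(aperm(seg, c(2, 1, 3)))
}

cross3 <- function(u, v) {
  # u, v: matrices n x 3 -> n x 3 cross products
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# areas of all quadrilateral patches, split along the (z,th)-(z+1,th+1)
# diagonal: (T, Z-1, Theta) array
patch_area_array <- function(mesh, surface = "endo") {
  P <- surface_coords(mesh, surface)
  d <- dim(P); Tn <- d[1]; Z <- d[2]; Th <- d[3]
  idx <- function(zs, ts) {
    m <- P[, zs, ts, , drop = FALSE]
    dim(m) <- c(Tn * (Z - 1) * Th, 3)
    m
  }
  thn <- c(2:Th, 1)
  p00 <- idx(1:(Z - 1), 1:Th)
  p01 <- idx(1:(Z - 1), thn)
  p10 <- idx(2:Z, 1:Th)
  p11 <- idx(2:Z, thn)
  a1 <- cross3(p01 - p00, p11 - p00)
  a2 <- cross3(p11 - p00, p10 - p00)
  area <- 0.5 * (sqrt(rowSums(a1^2)) + sqrt(rowSums(a2^2)))
  array(area, c(Tn, Z - 1, Th))
}

#' Slice circumference
#'
#' Closed-polygon perimeter over the rotational nodes of one short-axis
#' slice.
#'
#' @param mesh a [mesh4d()].
#' @param frame,slice 1-based frame and slice indices.
#' @param surface `"endo"` (default) or `"epi"`.
#' @return length in mm.
#' @export
slice_circumference <- function(mesh, frame, slice, surface = "endo") {
  circumference_matrix(mesh, surface)[frame, slice]
}

#' Meridian length
#'
#' Open polyline length from base to apex along the slice nodes at one
#' fixed rotation.
#'
#' @inheritParams slice_circumference
#' @param rotation 1-based rotation index.
#' @return length in mm.
#' @export
meridian_length <- function(mesh, frame, rotation, surface = "endo") {
  meridian_matrix(mesh, surface)[frame, rotation]
}

#' Surface patch area
#'
#' Area of the quadrilateral patch between two sequential slices and two
#' sequential rotations, computed as two triangles split along the
#' (slice, rotation)-(slice+1, rotation+1) diagonal. The rotation index
#' wraps periodically.
#'
#' @inheritParams slice_circumference
#' @param slice patch band index (1 .. n_slices - 1).
#' @param rotation patch rotation index (wraps at n_rotations).
#' @return area in mm^2.
#' @export
patch_area <- function(mesh, frame, slice, rotation, surface = "endo") {
  Z <- mesh_dim(mesh)[["n_slices"]]
  if (slice >= Z) abort("`slice` must be < n_slices for a patch band.")
  patch_area_array(mesh, surface)[frame, slice, rotation]
}

# signed cavity volumes for all frames via the divergence theorem on the
# triangulated endocardial surface closed with planar caps
cavity_volume_all <- function(mesh) {
  P <- surface_coords(mesh, "endo")
  d <- dim(P); Tn <- d[1]; Z <- d[2]; Th <- d[3]
  thn <- c(2:Th, 1)
  vols <- numeric(Tn)
  for (f in seq_len(Tn)) {
    Sm <- matrix(array(P[f, , , ], c(Z, Th, 3)), nrow = Z * Th)  # (Z*Th) x 3, z fastest
    tet <- function(a, b, cc)
      sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
    zs <- rep(1:(Z - 1), times = Th); zs1 <- zs + 1
    ts <- rep(1:Th, each = Z - 1); ts1 <- rep(thn, each = Z - 1)
    lin <- function(z, t) z + (t - 1) * Z
    p00 <- Sm[lin(zs, ts), , drop = FALSE]
    p01 <- Sm[lin(zs, ts1), , drop = FALSE]
    p10 <- Sm[lin(zs1, ts), , drop = FALSE]
    p11 <- Sm[lin(zs1, ts1), , drop = FALSE]
    v <- tet(p00, p01, p11) + tet(p00, p11, p10)
    # base cap (slice 1), outward normal toward -z side of the base plane
    ring_b <- Sm[lin(rep(1L, Th), 1:Th), , drop = FALSE]
    cb <- matrix(colMeans(ring_b), nrow = Th, ncol = 3, byrow = TRUE)
    v <- v + tet(cb, ring_b[thn, , drop = FALSE], ring_b)
    # apex cap (slice Z)
    ring_a <- Sm[lin(rep(Z, Th), 1:Th), , drop = FALSE]
    ca <- matrix(colMeans(ring_a), nrow = Th, ncol = 3, byrow = TRUE)
    v <- v + tet(ca, ring_a, ring_a[thn, , drop = FALSE])
    vols[f] <- v
  }
  vols
}

#' Cavity volume
#'
#' Volume enclosed by the endocardial surface, closed with planar caps at
#' the base and apex rings, computed with the divergence theorem on the
#' triangulated surface. A non-positive signed volume (inverted or
#' self-intersecting surface under the package's orientation conventions)
#' is an error.
#'
#' @param mesh a [mesh4d()].
#' @param frame 1-based frame index; `NULL` returns all frames.
#' @return volume in microliters (mm^3); a numeric vector if `frame` is
#'   `NULL`.
#' @export
cavity_volume <- function(mesh, frame = NULL) {
  v <- cavity_volume_all(mesh)
  if (any(v <= 0))
    abort("non-positive signed cavity volume: surface is inverted or self-intersecting.")
  if (is.null(frame)) v else v[frame]
}
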