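#' Parametric tibia phantom specification
#'
#' A phantom is a tapered hollow-elliptical shaft with cosine-blended
#' proximal/distal flares and a sagittal (anterior) bow. It is the synthetic
#' stand-in for a real tibia: rich enough that a four-landmark reconstruction
#' is genuinely under-determined, simple enough that volumes and section
#' properties have closed forms.
#'
#' The shared coordinate convention is a right-handed shank frame:
#' +X anterior, +Y lateral, +Z proximal along the long axis, units mm.
#' The distal end sits at z = 0 and the proximal end at z = length.
#'
#' @param length shaft length (mm).
#' @param a0,b0 base periosteal anteroposterior (a0) and mediolateral (b0)
#'   semi-axes at the distal third (mm); the linear taper is anchored there
#'   so distal-third section properties are known exactly.
#' @param endo_frac endosteal fraction in (0, 1): the endosteal surface is the
#'   periosteal surface scaled by this factor in each cross-section.
#' @param flare_prox,flare_dist dimensionless end-flare multipliers (>= 1
#'   typical); blended in over the outer 25% of the shaft with a cosine ramp.
#' @param bow anterior bow amplitude (mm); the section centre is offset by
#'   `bow * sin(pi * z/length)` in +X.
#' @param taper dimensionless linear taper slope of the base semi-axes along
#'   normalized axial position (anchored at the distal third).
#' @param nz,nc node grid resolution: axial rings and circumferential points.
#'   All phantoms of a population must share (nz, nc) for correspondence.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(length = 400, a0 = 13.8, b0 = 12.3, endo_frac = 0.51,
                         flare_prox = 1.6, flare_dist = 1.35, bow = 4,
                         taper = 0.15, nz = 33, nc = 16) {
  if (!is.finite(length) || length <= 0) stop("phantom length must be > 0", call. = FALSE)
  if (a0 <= 0 || b0 <= 0) stop("periosteal semi-axes must be > 0", call. = FALSE)
  if (endo_frac <= 0 || endo_frac >= 1) stop("endosteal fraction must lie in (0, 1)", call. = FALSE)
  if (nz < 2 || nc < 8) stop("grid resolution too coarse (need nz >= 2, nc >= 8)", call. = FALSE)
  if (nc %% 4 != 0) stop("nc must be a multiple of 4 (landmarks sit on the axes)", call. = FALSE)
  structure(list(length = length, a0 = a0, b0 = b0, endo_frac = endo_frac,
                 flare_prox = flare_prox, flare_dist = flare_dist, bow = bow,
                 taper = taper, nz = as.integer(nz), nc = as.integer(nc)),
            class = "phantom_spec")
}

# cosine blend: 0 for t <= 0, 1 for t >= 1, smooth in between
.cos_blend <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  0.5 * (1 - cos(pi * t))
}

#' Periosteal semi-axes and section-centre offset at normalized axial position
#'
#' @param spec a [phantom_spec()].
#' @param zt normalized axial position(s) in `[0, 1]` (0 = distal).
#' @return a list with numeric vectors `a` (AP semi-axis, mm), `b` (ML, mm)
#'   and `cx` (anterior offset of the section centre, mm).
#' @export
phantom_profile <- function(spec, zt) {
  base <- 1 + spec$taper * (zt - 1 / 3)
  flare <- 1 +
    (spec$flare_prox - 1) * .cos_blend((zt - 0.75) / 0.25) +
    (spec$flare_dist - 1) * .cos_blend((0.25 - zt) / 0.25)
  w <- base * flare
  list(a = spec$a0 * w, b = spec$b0 * w, cx = spec$bow * sin(pi * zt))
}

# ring node coordinates for one surface: n_z x n_c grid, ring-major ordering.
# scale applies to the semi-axes (1 = periosteal, endo_frac = endosteal).
.phantom_rings <- function(spec, nz, nc, scale = 1) {
  zt <- seq(0, 1, length.out = nz)
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  pr <- phantom_profile(spec, zt)
  x <- outer(pr$cx, rep(1, nc)) + outer(pr$a * scale, cos(th))
  y <- outer(pr$b * scale, sin(th))
  z <- outer(zt * spec$length, rep(1, nc))
  # ring-major: row index varies slowest
  cbind(as.vector(t(x)), as.vector(t(y)), as.vector(t(z)))
}

#' Triangulated surface mesh of a phantom
#'
#' Builds a watertight, consistently wound triangle mesh of the periosteal
#' (or, with `scale = endo_frac`, endosteal) surface on the spec's node grid,
#' closed with fan caps at both ends. Node semantics are identical for every
#' phantom sharing (nz, nc), which is what puts a population in
#' point correspondence.
#'
#' @param spec a [phantom_spec()].
#' @param nz,nc optional grid override (defaults to the spec's resolution).
#' @param scale cross-section scale factor (1 = periosteal surface).
#' @return a `surface_mesh`: list with `vertices` (n x 3 matrix, mm) and
#'   `faces` (m x 3 integer matrix, outward wound).
#' @export
phantom_surface <- function(spec, nz = spec$nz, nc = spec$nc, scale = 1) {
  v <- .phantom_rings(spec, nz, nc, scale = scale)
  ctr_b <- colMeans(v[seq_len(nc), , drop = FALSE])
  ctr_t <- colMeans(v[(nz - 1) * nc + seq_len(nc), , drop = FALSE])
  v <- rbind(v, ctr_b, ctr_t)
  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  i <- rep(seq_len(nz - 1L), each = nc)
  j <- rep(seq_len(nc), nz - 1L)
  # side quads split along the (i,j)-(i+1,j+1) diagonal; outward winding
  f1 <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j))
  jb <- seq_len(nc)
  cap_b <- cbind(nz * nc + 1L, idx(1L, jb + 1L), idx(1L, jb))
  cap_t <- cbind(nz * nc + 2L, idx(nz, jb), idx(nz, jb + 1L))
  mesh <- structure(list(vertices = unname(v),
                         faces = rbind(f1, f2, cap_b, cap_t)),
                    class = "surface_mesh")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Construct a surface mesh from raw arrays
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return a `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  structure(list(vertices = unname(as.matrix(vertices)),
                 faces = unname(matrix(as.integer(as.matrix(faces)), ncol = 3))),
            class = "surface_mesh")
}

#' Enclosed volume of a triangle mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); positive for outward-wound watertight meshes.
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6
}

#' Check that every mesh edge is shared by exactly two faces
#' @param mesh a `surface_mesh`.
#' @return TRUE if the mesh is combinatorially watertight.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Landmark node indices on the phantom grid
#'
#' Landmarks sit at fixed parametric grid locations, so their node indices are
#' identical across any population sharing (nz, nc): condyles and malleoli on
#' the medial/lateral axes of the end rings, the tibial tuberosity and the
#' anterior-border points on the anterior axis, and a fibular-head surrogate
#' on the lateral aspect of the proximal shaft (the phantom is tibia-only, so
#' the surrogate keeps the nine-landmark configuration at full count).
#'
#' @param nz,nc grid resolution.
#' @return named integer vector of vertex indices into the surface mesh.
#' @export
phantom_landmark_nodes <- function(nz, nc) {
  stopifnot(nc %% 4 == 0)
  j_ant <- 1L
  j_lat <- nc / 4L + 1L
  j_med <- 3L * nc / 4L + 1L
  ring <- function(frac) as.integer(round((nz - 1) * frac)) + 1L
  idx <- function(i, j) (i - 1L) * nc + j
  c(medial_condyle    = idx(nz, j_med),
    lateral_condyle   = idx(nz, j_lat),
    medial_malleolus  = idx(1L, j_med),
    lateral_malleolus = idx(1L, j_lat),
    tibial_tuberosity = idx(ring(0.85), j_ant),
    fibular_head      = idx(ring(0.9), j_lat),
    ant_border_25     = idx(ring(0.75), j_ant),
    ant_border_50     = idx(ring(0.5), j_ant),
    ant_border_75     = idx(ring(0.25), j_ant))
}

#' Landmark coordinate table for a phantom surface
#'
#' @param mesh a `surface_mesh` on the phantom grid.
#' @param nz,nc the grid resolution of `mesh`.
#' @param noise_sd isotropic Gaussian offset SD (mm) emulating soft-tissue /
#'   placement error; 0 (default) places landmarks exactly on the bone.
#' @return a tibble with columns `name`, `x_mm`, `y_mm`, `z_mm`.
#' @export
phantom_landmarks <- function(mesh, nz, nc, noise_sd = 0) {
  nodes <- phantom_landmark_nodes(nz, nc)
  p <- mesh$vertices[nodes, , drop = FALSE]
  if (noise_sd > 0) p <- p + matrix(stats::rnorm(length(p), 0, noise_sd), ncol = 3)
  tibble::tibble(name = names(nodes), x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3])
}

#' Marker configurations for landmark-guided reconstruction
#'
#' The 4-marker set is the minimal motion-capture set (femoral condyles and
#' malleoli); the 9-marker set adds the palpable reference landmarks
#' (tuberosity, fibular head and three anterior-border points).
#'
#' @param name `"4-marker"` or `"9-marker"`.
#' @return a `marker_config`: list with `name` and ordered `landmarks`.
#' @export
marker_config <- function(name = c("4-marker", "9-marker")) {
  name <- match.arg(name)
  lm4 <- c("medial_condyle", "lateral_condyle", "medial_malleolus", "lateral_malleolus")
  lm9 <- c(lm4, "tibial_tuberosity", "fibular_head",
           "ant_border_25", "ant_border_50", "ant_border_75")
  structure(list(name = name, landmarks = if (name == "4-marker") lm4 else lm9),
            class = "marker_config")
}

# landmark tibble -> named m x 3 matrix in a fixed order
.landmark_matrix <- function(landmarks, names_needed) {
  miss <- setdiff(names_needed, landmarks$name)
  if (length(miss) > 0) {
    stop("missing landmark(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  i <- match(names_needed, landmarks$name)
  m <- as.matrix(landmarks[i, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- names_needed
  m
}
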