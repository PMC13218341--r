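#' @title Structured tetrahedral meshing of tibia phantoms
#' @description
#' Volume meshes are built by structured splitting of the phantom's
#' parametric cells: hexahedral cells (axial x circumferential x radial) are
#' split into 6 tetrahedra each with the Freudenthal (Kuhn) scheme, whose
#' face diagonals are consistent in index space, so the mesh conforms across
#' cells including the circumferential wrap; the innermost layer uses wedge
#' cells around the section axis, split into 3 tetrahedra with matching
#' diagonals. This avoids any general-purpose mesher dependency.
#' @name tetmesh
NULL

# Freudenthal 6-tet split of the unit cube in index space.
# corner(b1,b2,b3) with b1 = axial, b2 = circumferential, b3 = radial step.
# Rows: tets as corner ids 1..8 where id = 1 + b1 + 2*b2 + 4*b3.
.freudenthal_tets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(vapply(perms, function(p) {
    b <- c(0, 0, 0)
    ids <- integer(4)
    ids[1] <- 1L
    for (k in 1:3) {
      b[p[k]] <- 1
      ids[k + 1] <- as.integer(1 + b[1] + 2 * b[2] + 4 * b[3])
    }
    ids
  }, integer(4)))
})

# signed volumes of tets (M x 4 index matrix into nodes)
.tet_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - p1
  b <- nodes[elems[, 3], , drop = FALSE] - p1
  c3 <- nodes[elems[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
     a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
     a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Element volumes of a tetrahedral mesh
#' @param mesh a `tet_mesh`.
#' @return numeric vector of positive element volumes (mm^3).
#' @export
tet_volumes <- function(mesh) .tet_volumes(mesh$nodes, mesh$elems)

# orient all tets positively (node swap does not affect face conformity)
.orient_tets <- function(nodes, elems) {
  v <- .tet_volumes(nodes, elems)
  neg <- which(v < 0)
  if (length(neg) > 0) elems[neg, 3:4] <- elems[neg, 4:3]
  if (any(abs(.tet_volumes(nodes, elems)) < 1e-12)) {
    stop("meshing error: degenerate (zero-volume) element", call. = FALSE)
  }
  elems
}

#' Tetrahedral mesh from periosteal/endosteal ring grids
#'
#' Takes two corresponding ring grids (arrays of dimension `nz x nc x 3`,
#' same grid semantics as [phantom_surface()]) and fills the volume with
#' radially graded node stations: `nr_in` trabecular layers from the section
#' axis to the endosteal surface and `nr_c` cortical layers from endosteal to
#' periosteal. Elements are labeled by construction: layers inside the
#' endosteal interface are trabecular (equivalently, every element centroid
#' lies on its side of the endosteal surface, since radial stations align
#' with the interface).
#'
#' @param peri,endo ring grids, arrays `nz x nc x 3` (mm).
#' @param nr_in,nr_c radial layer counts (trabecular / cortical).
#' @return a `tet_mesh`: `nodes` (N x 3), `elems` (M x 4, positively
#'   oriented), `material` (character, "cortical"/"trabecular"),
#'   `node_sets` (list with `proximal_plateau`, `distal_surface`).
#' @export
tet_mesh_from_grids <- function(peri, endo, nr_in = 2L, nr_c = 1L) {
  stopifnot(length(dim(peri)) == 3, all(dim(peri) == dim(endo)))
  nz <- dim(peri)[1]; nc <- dim(peri)[2]
  nr_in <- max(1L, as.integer(nr_in)); nr_c <- max(1L, as.integer(nr_c))
  ns <- nr_in + nr_c
  npl <- 1L + ns * nc                      # nodes per level: axis + stations
  nnode <- nz * npl

  nodes <- matrix(0, nnode, 3)
  for (i in seq_len(nz)) {
    pe <- matrix(peri[i, , ], nc, 3)
    en <- matrix(endo[i, , ], nc, 3)
    ctr <- colMeans(en)
    base <- (i - 1L) * npl
    nodes[base + 1L, ] <- ctr
    for (s in seq_len(ns)) {
      ring <- if (s <= nr_in) {
        t0 <- s / nr_in
        sweep(en - matrix(ctr, nc, 3, byrow = TRUE), 2, rep(1, 3), "*") * t0 +
          matrix(ctr, nc, 3, byrow = TRUE)
      } else {
        t0 <- (s - nr_in) / nr_c
        en + (pe - en) * t0
      }
      nodes[base + 1L + (s - 1L) * nc + seq_len(nc), ] <- ring
    }
  }

  axis_id <- function(i) (i - 1L) * npl + 1L
  stn_id <- function(i, s, j) (i - 1L) * npl + 1L + (s - 1L) * nc + ((j - 1L) %% nc) + 1L

  elems <- vector("list", 2L)
  # wedge core (station 0 -> 1), 3 tets each, diagonals through the low corner
  i <- rep(seq_len(nz - 1L), each = nc)
  j <- rep(seq_len(nc), nz - 1L)
  A0 <- axis_id(i); A1 <- axis_id(i + 1L)
  B00 <- stn_id(i, 1L, j); B10 <- stn_id(i, 1L, j + 1L)
  B01 <- stn_id(i + 1L, 1L, j); B11 <- stn_id(i + 1L, 1L, j + 1L)
  wedge <- rbind(cbind(A0, A1, B01, B11),
                 cbind(A0, B00, B10, B11),
                 cbind(A0, B00, B11, B01))
  wedge_mat <- rep(if (nr_in >= 1L) "trabecular" else "cortical", nrow(wedge))

  hex <- NULL; hex_mat <- character(0)
  if (ns >= 2L) {
    grid <- expand.grid(i = seq_len(nz - 1L), j = seq_len(nc), s = seq_len(ns - 1L))
    # corner id = 1 + b1 + 2*b2 + 4*b3 (b1 axial, b2 circumferential, b3 radial)
    corners <- matrix(0L, nrow(grid), 8L)
    for (cid in 1:8) {
      b1 <- (cid - 1L) %% 2L; b2 <- ((cid - 1L) %/% 2L) %% 2L; b3 <- (cid - 1L) %/% 4L
      corners[, cid] <- stn_id(grid$i + b1, grid$s + b3, grid$j + b2)
    }
    hex <- do.call(rbind, lapply(seq_len(nrow(.freudenthal_tets)), function(tt) {
      corners[, .freudenthal_tets[tt, ], drop = FALSE]
    }))
    # layer between stations s and s+1 is trabecular iff s < nr_in
    hex_mat <- rep(ifelse(grid$s < nr_in, "trabecular", "cortical"),
                   nrow(.freudenthal_tets))
  }
  elems <- rbind(wedge, hex)
  material <- c(wedge_mat, hex_mat)
  elems <- .orient_tets(nodes, elems)

  structure(list(nodes = nodes, elems = unname(elems), material = material,
                 node_sets = list(
                   distal_surface = (1L - 1L) * npl + seq_len(npl),
                   proximal_plateau = (nz - 1L) * npl + seq_len(npl)),
                 grid = list(nz = nz, nc = nc, nr_in = nr_in, nr_c = nr_c)),
            class = "tet_mesh")
}

# periodic + axial linear interpolation of a ring grid to a new resolution
.interp_grid <- function(grid, nz_out, nc_out) {
  nz <- dim(grid)[1]; nc <- dim(grid)[2]
  out <- array(0, c(nz_out, nc_out, 3))
  zt_in <- seq(0, 1, length.out = nz)
  zt_out <- seq(0, 1, length.out = nz_out)
  u_out <- (seq_len(nc_out) - 1) / nc_out * nc  # fractional index in [0, nc)
  j0 <- floor(u_out); w <- u_out - j0
  jA <- (j0 %% nc) + 1L; jB <- ((j0 + 1) %% nc) + 1L
  for (d in 1:3) {
    ring_interp <- grid[, jA, d] * matrix(1 - w, nz, nc_out, byrow = TRUE) +
      grid[, jB, d] * matrix(w, nz, nc_out, byrow = TRUE)
    out[, , d] <- apply(ring_interp, 2, function(col) {
      stats::approx(zt_in, col, xout = zt_out)$y
    })
  }
  out
}

# ring-major surface_mesh vertices (phantom grid + 2 caps) -> nz x nc x 3 array
.grid_from_mesh <- function(mesh, nz, nc) {
  v <- mesh$vertices[seq_len(nz * nc), , drop = FALSE]
  array(c(matrix(v[, 1], nz, nc, byrow = TRUE),
          matrix(v[, 2], nz, nc, byrow = TRUE),
          matrix(v[, 3], nz, nc, byrow = TRUE)), c(nz, nc, 3))
}

#' Tetrahedral volume mesh of a phantom
#'
#' Evaluates the analytic periosteal and endosteal surfaces at a resolution
#' set by `target_edge` and fills the volume with labeled tetrahedra
#' (see [tet_mesh_from_grids()]).
#'
#' @param spec a [phantom_spec()].
#' @param target_edge target element edge length (mm, > 0).
#' @return a `tet_mesh`.
#' @export
make_tet_mesh <- function(spec, target_edge) {
  if (!is.finite(target_edge) || target_edge <= 0) {
    stop("target edge length must be > 0", call. = FALSE)
  }
  rbar <- (spec$a0 + spec$b0) / 2
  nz <- max(3L, as.integer(round(spec$length / target_edge)) + 1L)
  nc <- max(8L, 4L * as.integer(ceiling(2 * pi * rbar / target_edge / 4)))
  nr_in <- max(1L, as.integer(round(spec$endo_frac * rbar / target_edge)))
  nr_c <- max(1L, as.integer(round((1 - spec$endo_frac) * rbar / target_edge)))
  peri <- .phantom_grid(spec, nz, nc, 1)
  endo <- .phantom_grid(spec, nz, nc, spec$endo_frac)
  tet_mesh_from_grids(peri, endo, nr_in, nr_c)
}

# analytic ring grid (nz x nc x 3) at a given cross-section scale
.phantom_grid <- function(spec, nz, nc, scale) {
  v <- .phantom_rings(spec, nz, nc, scale = scale)
  array(c(matrix(v[, 1], nz, nc, byrow = TRUE),
          matrix(v[, 2], nz, nc, byrow = TRUE),
          matrix(v[, 3], nz, nc, byrow = TRUE)), c(nz, nc, 3))
}

#' Tetrahedral volume mesh from reconstructed cortical/trabecular surfaces
#'
#' Resamples two corresponding phantom-grid surface meshes (e.g. a shape-model
#' reconstruction and its predicted endosteal surface) to a target element
#' size and fills the volume.
#'
#' @param cortical,trabecular `surface_mesh` objects on the same
#'   phantom grid.
#' @param nz,nc the grid resolution of the input meshes.
#' @param target_edge target element edge length (mm).
#' @return a `tet_mesh`.
#' @export
tet_mesh_from_surfaces <- function(cortical, trabecular, nz, nc, target_edge) {
  peri <- .grid_from_mesh(cortical, nz, nc)
  endo <- .grid_from_mesh(trabecular, nz, nc)
  len <- max(peri[, , 3]) - min(peri[, , 3])
  rbar <- mean(sqrt((peri[, , 1] - rowMeans(peri[, , 1]))^2 +
                      (peri[, , 2] - rowMeans(peri[, , 2]))^2))
  nz_t <- max(3L, as.integer(round(len / target_edge)) + 1L)
  nc_t <- max(8L, 4L * as.integer(ceiling(2 * pi * rbar / target_edge / 4)))
  f <- mean(sqrt(rowSums(matrix(endo, ncol = 3)[, 1:2]^2)) /
              pmax(sqrt(rowSums(matrix(peri, ncol = 3)[, 1:2]^2)), 1e-9))
  nr_in <- max(1L, as.integer(round(f * rbar / target_edge)))
  nr_c <- max(1L, as.integer(round((1 - f) * rbar / target_edge)))
  tet_mesh_from_grids(.interp_grid(peri, nz_t, nc_t),
                      .interp_grid(endo, nz_t, nc_t), nr_in, nr_c)
}

#' Structured tetrahedral mesh of a rectangular prism
#'
#' Axis-aligned box `[0,lx] x [0,ly] x [0,lz]` meshed with Freudenthal
#' 6-tet cells; used for analytic finite-element verification (axial bar,
#' cantilever, patch test).
#'
#' @param lx,ly,lz box dimensions (mm).
#' @param target_edge target element edge length (mm).
#' @param material material label applied to every element.
#' @return a `tet_mesh` with node sets `distal_surface` (z = 0) and
#'   `proximal_plateau` (z = lz).
#' @export
tet_mesh_box <- function(lx, ly, lz, target_edge, material = "cortical") {
  n1 <- max(1L, as.integer(round(lx / target_edge)))
  n2 <- max(1L, as.integer(round(ly / target_edge)))
  n3 <- max(1L, as.integer(round(lz / target_edge)))
  xs <- seq(0, lx, length.out = n1 + 1L)
  ys <- seq(0, ly, length.out = n2 + 1L)
  zs <- seq(0, lz, length.out = n3 + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) (k - 1L) * (n1 + 1L) * (n2 + 1L) + (j - 1L) * (n1 + 1L) + i
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2), k = seq_len(n3))
  corners <- matrix(0L, nrow(grid), 8L)
  for (cid in 1:8) {
    b1 <- (cid - 1L) %% 2L; b2 <- ((cid - 1L) %/% 2L) %% 2L; b3 <- (cid - 1L) %/% 4L
    corners[, cid] <- nid(grid$i + b1, grid$j + b2, grid$k + b3)
  }
  elems <- do.call(rbind, lapply(seq_len(nrow(.freudenthal_tets)), function(tt) {
    corners[, .freudenthal_tets[tt, ], drop = FALSE]
  }))
  elems <- .orient_tets(nodes, elems)
  structure(list(nodes = unname(nodes), elems = unname(elems),
                 material = rep(material, nrow(elems)),
                 node_sets = list(
                   distal_surface = which(nodes[, 3] < 1e-9),
                   proximal_plateau = which(abs(nodes[, 3] - lz) < 1e-9)),
                 grid = list(box = c(lx, ly, lz))),
            class = "tet_mesh")
}
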