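#' @title Reconstruction accuracy and cross-section metrics
#' @name geom_metrics
#' @description
#' Volumetric overlap (Jaccard index on a shared voxel grid), per-vertex
#' surface error, tibial length, and distal-third hollow-ellipse section
#' properties.
NULL

# inside-test of a watertight mesh on a voxel grid by ray-parity along +Z.
# Returns a logical matrix (columns = x,y cells; rows = z cells).
# A fixed sub-voxel jitter of the ray grid avoids edge-on hits; if any
# column still sees an odd crossing count the jitter is re-drawn.
.voxel_inside <- function(mesh, x0, y0, z0, nx, ny, nzv, h) {
  v <- mesh$vertices; f <- mesh$faces
  inside <- matrix(FALSE, nzv, nx * ny)
  for (attempt in 1:6) {
    jit <- c(0.211324865, 0.366025404) * h * attempt  # irrational-ish offsets
    xc <- x0 + (seq_len(nx) - 0.5) * h + jit[1]
    yc <- y0 + (seq_len(ny) - 0.5) * h + jit[2]
    p1 <- v[f[, 1], , drop = FALSE]
    p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    txmin <- pmin(p1[, 1], p2[, 1], p3[, 1]); txmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
    tymin <- pmin(p1[, 2], p2[, 2], p3[, 2]); tymax <- pmax(p1[, 2], p2[, 2], p3[, 2])
    ix0 <- pmax(1L, ceiling((txmin - jit[1] - x0) / h - 0.5 + 1e-12))
    ix1 <- pmin(nx, floor((txmax - jit[1] - x0) / h + 0.5 - 1e-12))
    iy0 <- pmax(1L, ceiling((tymin - jit[2] - y0) / h - 0.5 + 1e-12))
    iy1 <- pmin(ny, floor((tymax - jit[2] - y0) / h + 0.5 - 1e-12))
    ncx <- pmax(0L, ix1 - ix0 + 1L); ncy <- pmax(0L, iy1 - iy0 + 1L)
    npair <- ncx * ncy
    keep <- which(npair > 0)
    if (length(keep) == 0) return(inside & FALSE)
    tri <- rep(keep, npair[keep])
    # enumerate candidate (ix, iy) cells under each triangle
    offs <- sequence(npair[keep]) - 1L
    ix <- ix0[tri] + offs %% ncx[tri]
    iy <- iy0[tri] + offs %/% ncx[tri]
    px <- xc[ix]; py <- yc[iy]
    ax <- p1[tri, 1]; ay <- p1[tri, 2]
    bx <- p2[tri, 1]; by <- p2[tri, 2]
    cx <- p3[tri, 1]; cy <- p3[tri, 2]
    den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
    ok <- abs(den) > 1e-12
    w1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / den
    w2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / den
    w3 <- 1 - w1 - w2
    hit <- ok & w1 >= 0 & w2 >= 0 & w3 >= 0 & w1 <= 1 & w2 <= 1 & w3 <= 1
    if (!any(hit)) return(inside & FALSE)
    zc <- w1[hit] * p1[tri[hit], 3] + w2[hit] * p2[tri[hit], 3] + w3[hit] * p3[tri[hit], 3]
    col <- (iy[hit] - 1L) * nx + ix[hit]
    ord <- order(col, zc)
    col <- col[ord]; zc <- zc[ord]
    cnt <- tabulate(col, nbins = nx * ny)
    if (any(cnt %% 2L == 1L)) next  # edge-on hit somewhere: re-jitter
    # parity fill: z intervals (z_{2k-1}, z_{2k}] per column
    is_start <- unlist(lapply(cnt[cnt > 0], function(m) rep(c(TRUE, FALSE), m / 2)))
    za <- zc[is_start]; zb <- zc[!is_start]
    ca <- col[is_start]
    ia <- floor((za - z0) / h + 0.5)   # last center index at/below za
    ib <- floor((zb - z0) / h + 0.5)
    ia <- pmax(ia, 0L); ib <- pmin(ib, nzv)
    len <- pmax(0L, ib - ia)
    if (sum(len) > 0) {
      rows <- sequence(len[len > 0], from = ia[len > 0] + 1L)
      cols <- rep(ca[len > 0], len[len > 0])
      inside[cbind(rows, cols)] <- TRUE
    }
    return(inside)
  }
  stop("geometry error: ray-parity voxelization failed (degenerate mesh?)",
       call. = FALSE)
}

#' Jaccard index of two watertight meshes on a shared voxel grid
#'
#' Volumetric overlap |A intersect B| / |A union B|, evaluated on an
#' axis-aligned voxel grid covering the union bounding box padded by one
#' voxel; the inside test is ray parity with a fixed sub-voxel jitter and a
#' re-jitter fallback on degenerate hits. Exactly symmetric in its
#' arguments (shared grid).
#'
#' @param mesh_a,mesh_b watertight `surface_mesh` objects (mm).
#' @param voxel_mm voxel edge length (mm, > 0); default 1 mm.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(mesh_a, mesh_b, voxel_mm = 1) {
  if (voxel_mm <= 0) stop("voxel size must be > 0", call. = FALSE)
  for (m in list(mesh_a, mesh_b)) {
    if (nrow(m$faces) == 0) stop("undefined: empty mesh", call. = FALSE)
    if (!is_watertight(m)) stop("geometry error: mesh is not watertight", call. = FALSE)
  }
  lo <- pmin(apply(mesh_a$vertices, 2, min), apply(mesh_b$vertices, 2, min)) - voxel_mm
  hi <- pmax(apply(mesh_a$vertices, 2, max), apply(mesh_b$vertices, 2, max)) + voxel_mm
  nx <- max(1L, ceiling((hi[1] - lo[1]) / voxel_mm))
  ny <- max(1L, ceiling((hi[2] - lo[2]) / voxel_mm))
  nzv <- max(1L, ceiling((hi[3] - lo[3]) / voxel_mm))
  A <- .voxel_inside(mesh_a, lo[1], lo[2], lo[3], nx, ny, nzv, voxel_mm)
  B <- .voxel_inside(mesh_b, lo[1], lo[2], lo[3], nx, ny, nzv, voxel_mm)
  un <- sum(A | B)
  if (un == 0) stop("undefined: both meshes voxelize to empty sets", call. = FALSE)
  sum(A & B) / un
}

# exact point-to-triangle distances, vectorized over query points
.dist_to_surface <- function(P, mesh, chunk = 64L) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  nt <- nrow(f)
  seg_d2 <- function(px, py, pz, ax, ay, az, bx, by, bz) {
    ux <- bx - ax; uy <- by - ay; uz <- bz - az
    tt <- ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) /
      pmax(ux^2 + uy^2 + uz^2, 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    (px - ax - tt * ux)^2 + (py - ay - tt * uy)^2 + (pz - az - tt * uz)^2
  }
  n <- pracma_cross <- NULL
  e1 <- B - A; e2 <- C - A
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- rowSums(nrm^2)
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  det <- pmax(d11 * d22 - d12^2, 1e-300)
  out <- numeric(nrow(P))
  for (s in seq(1, nrow(P), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(P))
    m <- length(idx)
    px <- rep(P[idx, 1], each = nt); py <- rep(P[idx, 2], each = nt); pz <- rep(P[idx, 3], each = nt)
    ax <- rep(A[, 1], m); ay <- rep(A[, 2], m); az <- rep(A[, 3], m)
    wx <- px - ax; wy <- py - ay; wz <- pz - az
    r1 <- wx * rep(e1[, 1], m) + wy * rep(e1[, 2], m) + wz * rep(e1[, 3], m)
    r2 <- wx * rep(e2[, 1], m) + wy * rep(e2[, 2], m) + wz * rep(e2[, 3], m)
    u <- (rep(d22, m) * r1 - rep(d12, m) * r2) / rep(det, m)
    w <- (rep(d11, m) * r2 - rep(d12, m) * r1) / rep(det, m)
    inside <- u >= 0 & w >= 0 & (u + w) <= 1
    dn <- wx * rep(nrm[, 1], m) + wy * rep(nrm[, 2], m) + wz * rep(nrm[, 3], m)
    d2_plane <- dn^2 / rep(pmax(nn, 1e-300), m)
    bx <- rep(B[, 1], m); by <- rep(B[, 2], m); bz <- rep(B[, 3], m)
    cx <- rep(C[, 1], m); cy <- rep(C[, 2], m); cz <- rep(C[, 3], m)
    d2_edge <- pmin(seg_d2(px, py, pz, ax, ay, az, bx, by, bz),
                    seg_d2(px, py, pz, ax, ay, az, cx, cy, cz),
                    seg_d2(px, py, pz, bx, by, bz, cx, cy, cz))
    d2 <- ifelse(inside, pmin(d2_plane, d2_edge), d2_edge)
    out[idx] <- sqrt(apply(matrix(d2, nt, m), 2, min))
  }
  out
}

#' Surface error between a reconstruction and a reference mesh
#'
#' Mode `"correspondence"` takes the absolute Euclidean distance between
#' same-index vertices (meshes from the same model grid); mode `"nearest"`
#' takes each reconstruction vertex's exact distance to the nearest point of
#' the reference surface.
#'
#' @param recon,ref `surface_mesh` objects.
#' @param mode `"correspondence"` (default) or `"nearest"`.
#' @return a tibble with `mean_mm` and `max_mm`.
#' @export
surface_error <- function(recon, ref, mode = c("correspondence", "nearest")) {
  mode <- match.arg(mode)
  if (mode == "correspondence") {
    if (nrow(recon$vertices) != nrow(ref$vertices)) {
      stop("correspondence mode requires equal vertex counts", call. = FALSE)
    }
    d <- sqrt(rowSums((recon$vertices - ref$vertices)^2))
  } else {
    d <- .dist_to_surface(recon$vertices, ref)
  }
  tibble::tibble(mean_mm = mean(d), max_mm = max(d))
}

#' Tibial length from landmarks or from a mesh
#'
#' Landmark mode: distance between the condyle-pair midpoint and the
#' malleolus-pair midpoint. Mesh mode: extent along the long (+Z) axis.
#'
#' @param x a landmark tibble or a `surface_mesh`.
#' @return length in mm.
#' @export
tibial_length <- function(x) {
  if (inherits(x, "surface_mesh")) {
    return(max(x$vertices[, 3]) - min(x$vertices[, 3]))
  }
  m <- .landmark_matrix(x, c("medial_condyle", "lateral_condyle",
                             "medial_malleolus", "lateral_malleolus"))
  sqrt(sum((colMeans(m[1:2, ]) - colMeans(m[3:4, ]))^2))
}

#' Hollow-ellipse cross-section
#'
#' @param a_o,b_o periosteal anteroposterior / mediolateral semi-axes (mm).
#' @param a_i,b_i endosteal semi-axes (mm); 0 for a solid section.
#' @param center optional section centre (x, y, z) in mm.
#' @return a `hollow_ellipse_section`.
#' @export
hollow_ellipse_section <- function(a_o, b_o, a_i = 0, b_i = 0, center = c(0, 0, 0)) {
  if (a_o <= 0 || b_o <= 0) stop("periosteal semi-axes must be > 0", call. = FALSE)
  if (a_i < 0 || b_i < 0 || a_i >= a_o || b_i >= b_o) {
    stop("geometry error: endosteal semi-axes must satisfy 0 <= inner < outer",
         call. = FALSE)
  }
  structure(list(a_o = a_o, b_o = b_o, a_i = a_i, b_i = b_i, center = center),
            class = "hollow_ellipse_section")
}

#' Closed-form section properties of a hollow ellipse
#'
#' CSA = pi (a_o b_o - a_i b_i); I_ML = (pi/4)(b_o a_o^3 - b_i a_i^3)
#' (bending about the mediolateral axis, anterior fiber distance a_o);
#' I_AP = (pi/4)(a_o b_o^3 - a_i b_i^3).
#'
#' @param section a [hollow_ellipse_section()].
#' @return a tibble with `csa_mm2`, `I_ml_mm4`, `I_ap_mm4`.
#' @export
section_properties <- function(section) {
  s <- section
  tibble::tibble(
    csa_mm2 = pi * (s$a_o * s$b_o - s$a_i * s$b_i),
    I_ml_mm4 = pi / 4 * (s$b_o * s$a_o^3 - s$b_i * s$a_i^3),
    I_ap_mm4 = pi / 4 * (s$a_o * s$b_o^3 - s$a_i * s$b_i^3))
}

# intersection contour points of mesh edges with the plane z = z_cut
.section_contour <- function(mesh, z_cut) {
  v <- mesh$vertices; f <- mesh$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  z1 <- v[e[, 1], 3]; z2 <- v[e[, 2], 3]
  crossing <- (z1 - z_cut) * (z2 - z_cut) < 0
  if (!any(crossing)) {
    stop("geometry error: cutting plane misses the mesh", call. = FALSE)
  }
  tt <- (z_cut - z1[crossing]) / (z2[crossing] - z1[crossing])
  v[e[crossing, 1], , drop = FALSE] +
    tt * (v[e[crossing, 2], , drop = FALSE] - v[e[crossing, 1], , drop = FALSE])
}

#' Distal-third hollow-ellipse section of reconstructed surfaces
#'
#' Cuts both surfaces with a plane perpendicular to +Z at
#' `distal end + fraction * length` and takes the periosteal semi-axes as
#' half the maximal anteroposterior / mediolateral extents of the raw cut
#' contour (not a fitted ellipse), endosteal likewise from the trabecular
#' contour.
#'
#' @param cortical periosteal `surface_mesh`.
#' @param trabecular endosteal `surface_mesh`, or NULL for a solid section.
#' @param fraction axial position of the cut from the distal end (default 1/3).
#' @return a `hollow_ellipse_section` with the cut centre stored.
#' @export
fit_distal_section <- function(cortical, trabecular = NULL, fraction = 1 / 3) {
  zr <- range(cortical$vertices[, 3])
  z_cut <- zr[1] + fraction * (zr[2] - zr[1])
  pc <- .section_contour(cortical, z_cut)
  a_o <- (max(pc[, 1]) - min(pc[, 1])) / 2
  b_o <- (max(pc[, 2]) - min(pc[, 2])) / 2
  ctr <- c((max(pc[, 1]) + min(pc[, 1])) / 2, (max(pc[, 2]) + min(pc[, 2])) / 2, z_cut)
  a_i <- b_i <- 0
  if (!is.null(trabecular)) {
    pt <- .section_contour(trabecular, z_cut)
    a_i <- (max(pt[, 1]) - min(pt[, 1])) / 2
    b_i <- (max(pt[, 2]) - min(pt[, 2])) / 2
  }
  hollow_ellipse_section(a_o, b_o, a_i, b_i, center = ctr)
}

#' Reconstruction accuracy report for one fitted phantom
#'
#' Aligns the reconstruction to the reference frame by landmark-based rigid
#' Procrustes (no scaling, so size errors are charged to the fit), then
#' computes the Jaccard index and correspondence-mode surface errors.
#'
#' @param fit an `ssm_fit`.
#' @param ref_mesh reference `surface_mesh` (ground-truth phantom).
#' @param ref_landmarks reference landmark tibble.
#' @param landmark_nodes named vertex-index map of the model grid
#'   (see [phantom_landmark_nodes()]), used for the rigid pre-alignment.
#' @param voxel_mm Jaccard voxel size (mm).
#' @return one-row tibble: `config`, `k_sd`, `jaccard`, `mean_err_mm`,
#'   `max_err_mm`.
#' @export
reconstruction_report <- function(fit, ref_mesh, ref_landmarks, landmark_nodes,
                                  voxel_mm = 1) {
  cfg <- marker_config(fit$config)
  recon <- fit$mesh
  Y <- .landmark_matrix(ref_landmarks, cfg$landmarks)
  X <- recon$vertices[landmark_nodes[cfg$landmarks], , drop = FALSE]
  report_align <- .kabsch(X, Y, scale = FALSE)
  recon_al <- surface_mesh(.apply_pose(recon$vertices, report_align), recon$faces)
  se <- surface_error(recon_al, ref_mesh, mode = "correspondence")
  tibble::tibble(config = fit$config, k_sd = fit$k_sd,
                 jaccard = jaccard_index(recon_al, ref_mesh, voxel_mm = voxel_mm),
                 mean_err_mm = se$mean_mm, max_err_mm = se$max_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
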