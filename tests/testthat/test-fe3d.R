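mat_std <- fe_materials()

test_that("element stiffness matches a dense B'DB oracle and is symmetric", {
  set.seed(8)
  for (material in c("cortical", "trabecular")) {
    nodes <- matrix(rnorm(12), 4, 3)
    el <- matrix(1:4, 1)
    if (tibload::tet_volumes(structure(list(nodes = nodes, elems = el),
                                       class = "tet_mesh")) < 0) {
      el <- matrix(c(1, 2, 4, 3), 1)
    }
    mesh <- structure(list(nodes = nodes, elems = el, material = material,
                           node_sets = list(proximal_plateau = 1L,
                                            distal_surface = 2L)),
                      class = "tet_mesh")
    asm <- fe_assemble(mesh, mat_std)
    K <- as.matrix(asm$K)
    expect_lt(max(abs(K - t(K))), 1e-8 * max(abs(K)))
    # dense oracle in element-local node order
    perm <- el[1, ]
    p <- nodes[perm, ]
    e2 <- p[2, ] - p[1, ]; e3 <- p[3, ] - p[1, ]; e4 <- p[4, ] - p[1, ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    det <- sum(e2 * cr(e3, e4))
    g <- rbind(-(cr(e3, e4) + cr(e4, e2) + cr(e2, e3)) / det,
               cr(e3, e4) / det, cr(e4, e2) / det, cr(e2, e3) / det)
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- g[a, 1]; B[2, c0 + 2] <- g[a, 2]; B[3, c0 + 3] <- g[a, 3]
      B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
      B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
      B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
    }
    E <- mat_std$E_MPa[[material]]; nu <- mat_std$nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
    D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
    diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
    Ke <- abs(det) / 6 * t(B) %*% D %*% B
    # scatter oracle into global dof order
    Kg <- matrix(0, 12, 12)
    for (a in 1:4) for (b in 1:4) {
      Kg[3 * (perm[a] - 1) + 1:3, 3 * (perm[b] - 1) + 1:3] <-
        Ke[3 * (a - 1) + 1:3, 3 * (b - 1) + 1:3]
    }
    expect_lt(max(abs(K - Kg)), 1e-8 * max(abs(Kg)))
  }
})

test_that("applied nodal forces conserve the load and zero load gives zero response", {
  bx <- tet_mesh_box(20, 20, 100, 10)
  mod <- build_fe_model(bx, mat_std, c(ap = 37, ml = -12, axial = -4000))
  expect_equal(sum(mod$f[seq(1, length(mod$f), 3)]), 37, tolerance = 1e-9)
  expect_equal(sum(mod$f[seq(2, length(mod$f), 3)]), -12, tolerance = 1e-9)
  expect_equal(sum(mod$f[seq(3, length(mod$f), 3)]), 4000, tolerance = 1e-9)
  mod0 <- build_fe_model(bx, mat_std, c(ap = 0, ml = 0, axial = 0))
  expect_true(all(mod0$f == 0))
  sol0 <- solve_fe(mod0)
  expect_true(all(sol0$u == 0))
  expect_error(build_fe_model(structure(c(unclass(bx),
                                          list()), class = "tet_mesh")[
                                            c("nodes", "elems", "material")] |>
                                (\(x) structure(c(x, list(node_sets = list())),
                                                class = "tet_mesh"))(),
                              mat_std, c(ap = 0, ml = 0, axial = 0)),
               "node set")
})

test_that("uniform axial stress state is exact for linear tetrahedra", {
  # roller support (z fixed on top, rigid modes pinned) + consistent load:
  # the constant-stress solution is in the element space, so it is exact
  bx <- tet_mesh_box(20, 20, 200, 5)
  nb <- bx$nodes
  top <- bx$node_sets$proximal_plateau
  c1 <- which(nb[, 1] < 1e-9 & nb[, 2] < 1e-9 & abs(nb[, 3] - 200) < 1e-9)
  c2 <- which(abs(nb[, 1] - 20) < 1e-9 & nb[, 2] < 1e-9 & abs(nb[, 3] - 200) < 1e-9)
  fixed <- sort(c(3 * (top - 1) + 3, 3 * (c1 - 1) + 1, 3 * (c1 - 1) + 2,
                  3 * (c2 - 1) + 2))
  asm <- fe_assemble(bx, mat_std)
  f <- fe_consistent_load(bx, "distal_surface", c(0, 0, 4000))  # push up
  sol <- solve_fe(asm, f = f, fixed_dofs = fixed)
  fld <- fe_field_metrics(sol, asm)
  expect_lt(max(abs(fld$szz - (-10))) / 10, 1e-9)
  expect_lt(max(abs(fld$sxx)), 1e-8)
  expect_lt(max(abs(fld$sxy)), 1e-8)
  # pressure-modified von Mises strain reduces to |eps_axial| = sigma / E
  expect_equal(fld$pmvm_ue, rep(1e6 * 10 / 17000, nrow(fld)), tolerance = 1e-9)
})

test_that("global equilibrium: reactions balance the applied load", {
  sp <- phantom_spec()
  tm <- make_tet_mesh(sp, 6)
  F <- c(ap = -700, ml = 90, axial = -4200)
  mod <- build_fe_model(tm, mat_std, F)
  sol <- solve_fe(mod)
  rsum <- c(sum(sol$reactions[seq(1, length(sol$reactions), 3)]),
            sum(sol$reactions[seq(2, length(sol$reactions), 3)]),
            sum(sol$reactions[seq(3, length(sol$reactions), 3)]))
  applied <- c(F[["ap"]], F[["ml"]], -F[["axial"]])
  expect_lt(max(abs(rsum + applied)) / max(abs(applied)), 1e-6)
})

test_that("solution is exactly linear in the load", {
  sp <- phantom_spec()
  tm <- make_tet_mesh(sp, 8)
  mod <- build_fe_model(tm, mat_std)
  f1 <- tibload:::.fe_rhs(tm, c(ap = -500, ml = 50, axial = -3000))
  s1 <- solve_fe(mod, f = f1)
  s2 <- solve_fe(mod, f = 2 * f1)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-9)
  fl1 <- fe_field_metrics(s1, mod)
  fl2 <- fe_field_metrics(s2, mod)
  expect_equal(fl2$s1, 2 * fl1$s1, tolerance = 1e-9)
  expect_equal(fl2$pmvm_ue, 2 * fl1$pmvm_ue, tolerance = 1e-9)
  # strained volume is nondecreasing in load magnitude
  sm1 <- summarize_fe_fields(fl1, tm)
  sm2 <- summarize_fe_fields(fl2, tm)
  expect_gte(sm2$strained_vol_mm3, sm1$strained_vol_mm3)
})

test_that("affine boundary displacement reproduces the exact constant strain field", {
  bx <- tet_mesh_box(10, 10, 10, 2.5)
  asm <- fe_assemble(bx, mat_std)
  A <- rbind(c(1e-3, 2e-4, 0), c(3e-4, -5e-4, 1e-4), c(0, 4e-4, 2e-3))
  nb <- bx$nodes
  bnd <- which(nb[, 1] < 1e-9 | nb[, 1] > 10 - 1e-9 | nb[, 2] < 1e-9 |
                 nb[, 2] > 10 - 1e-9 | nb[, 3] < 1e-9 | nb[, 3] > 10 - 1e-9)
  fixed <- as.vector(t(outer(3 * (bnd - 1), 1:3, `+`)))   # per-node x,y,z order
  vals <- as.vector(t(nb[bnd, ] %*% t(A)))
  sol <- solve_fe(asm, f = numeric(3 * nrow(nb)), fixed_dofs = fixed,
                  fixed_values = vals)
  expect_lt(max(abs(sol$u - nb %*% t(A))), 1e-12)
  fld <- fe_field_metrics(sol, asm)
  Asym <- (A + t(A)) / 2
  expect_equal(fld$exx, rep(Asym[1, 1], nrow(fld)), tolerance = 1e-10)
  expect_equal(fld$exy, rep(Asym[1, 2], nrow(fld)), tolerance = 1e-10)
  expect_equal(fld$eyz, rep(Asym[2, 3], nrow(fld)), tolerance = 1e-10)
})

test_that("principal stresses are correct for constructed strain states", {
  bx <- tet_mesh_box(10, 10, 10, 5)
  asm <- fe_assemble(bx, mat_std)
  nb <- bx$nodes
  bnd <- seq_len(nrow(nb))
  fixed <- as.vector(t(outer(3 * (bnd - 1), 1:3, `+`)))
  # pure shear gamma_xy: principal stresses (tau, 0, -tau)
  gam <- 1e-3
  U <- cbind(gam * nb[, 2], 0, 0)
  sol <- solve_fe(asm, f = numeric(3 * nrow(nb)), fixed_dofs = fixed,
                  fixed_values = as.vector(t(U)))
  fld <- fe_field_metrics(sol, asm)
  mu <- mat_std$E_MPa[["cortical"]] / (2 * (1 + mat_std$nu))
  tau <- mu * gam
  expect_equal(fld$s1, rep(tau, nrow(fld)), tolerance = 1e-9)
  expect_equal(fld$s2, rep(0, nrow(fld)), tolerance = 1e-9 * tau)
  expect_equal(fld$s3, rep(-tau, nrow(fld)), tolerance = 1e-9)
  expect_true(all(diff(t(as.matrix(fld[1, c("s1", "s2", "s3")]))) <= 0))
})

test_that("field summaries implement volume-weighted percentiles and strained volume", {
  expect_equal(volume_weighted_percentile(c(1000, 5000), c(9, 1), 95), 5000)
  expect_equal(volume_weighted_percentile(c(5000, 1000), c(1, 9), 95), 5000)
  expect_equal(volume_weighted_percentile(c(1000, 5000), c(99, 1), 95), 1000)
  fld <- tibble::tibble(pmvm_ue = c(1000, 2000), vol_mm3 = c(4, 6),
                        s1 = c(10, 20), s3 = c(-5, -30))
  mesh <- list(elems = matrix(5:8, 2, 4), node_sets = list(proximal_plateau = 99L))
  sm <- summarize_fe_fields(fld, mesh, threshold_ue = 3000)
  expect_equal(sm$strained_vol_mm3, 0)
  sm2 <- summarize_fe_fields(dplyr::mutate(fld, pmvm_ue = c(4000, 5000)), mesh)
  expect_equal(sm2$strained_vol_mm3, 10)
  expect_equal(sm2$peak_tens_MPa, 20)
  expect_equal(sm2$peak_comp_MPa, -30)
})

test_that("the convergence rule picks the first sufficiently stable refinement", {
  tb <- tibble::tibble(size_mm = c(5.5, 3.6, 2.7, 2.0),
                       pct95_pmvm_ue = c(100, 90, 86, 85.5),
                       peak_tens_MPa = c(100, 90, 86, 85.5),
                       peak_comp_MPa = -c(100, 90, 86, 85.5))
  res <- apply_convergence_rule(tb, tol_pct = 5)
  expect_true(res$converged)
  expect_equal(res$converged_size_mm, 2.7)   # changes 10%, 4.4%, 0.6%
  # constant metrics converge at the first comparison
  tbc <- dplyr::mutate(tb, pct95_pmvm_ue = 50, peak_tens_MPa = 10,
                       peak_comp_MPa = -20)
  resc <- apply_convergence_rule(tbc, 5)
  expect_equal(resc$converged_size_mm, 3.6)
})

test_that("an axial bar phantom converges immediately across the ladder", {
  # roller support + consistent traction admit the exact constant-stress
  # state, so every ladder entry reports identical metrics
  conv <- run_mesh_convergence(
    function(sz) tet_mesh_box(20, 20, 100, sz),
    c(ap = 0, ml = 0, axial = -4000),
    sizes = c(10, 6.7, 5), materials = mat_std,
    support = "roller", load_style = "consistent")
  expect_true(conv$converged)
  expect_equal(conv$converged_size_mm, 6.7)
  expect_lt(max(conv$table$max_change_pct, na.rm = TRUE), 0.01)
  expect_equal(conv$table$pct95_pmvm_ue, rep(1e6 * 10 / 17000, 3),
               tolerance = 1e-6)
})
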