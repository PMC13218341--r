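test_that("Jaccard index matches analytic overlap and is exactly symmetric", {
  s1 <- sphere_mesh(10, 30)
  s2 <- sphere_mesh(20, 30)
  expect_equal(jaccard_index(s1, s1, voxel_mm = 1), 1)
  # concentric spheres of radius r and 2r: analytic ratio r^3 / (2r)^3
  expect_equal(jaccard_index(s1, s2, voxel_mm = 0.5), 0.125, tolerance = 0.01 / 0.125)
  s3 <- sphere_mesh(10, 30, center = c(100, 0, 0))
  expect_equal(jaccard_index(s1, s3, voxel_mm = 1), 0)
  expect_identical(jaccard_index(s1, s2, voxel_mm = 0.5),
                   jaccard_index(s2, s1, voxel_mm = 0.5))
  expect_error(jaccard_index(s1, s2, voxel_mm = 0), "voxel")
  open_mesh <- surface_mesh(s1$vertices, s1$faces[-1, ])
  expect_error(jaccard_index(open_mesh, s2), "watertight")
})

test_that("halving the voxel size changes phantom Jaccard by < 0.02", {
  pop <- fix_population()
  for (i in c(1, 2)) {
    a <- pop$mesh[[i]]
    b <- pop$mesh[[i + 2]]
    j2 <- jaccard_index(a, b, voxel_mm = 2)
    j1 <- jaccard_index(a, b, voxel_mm = 1)
    expect_lt(abs(j2 - j1), 0.02)
  }
})

test_that("surface error matches constructed offsets in both modes", {
  s1 <- sphere_mesh(10, 30)
  expect_equal(unlist(surface_error(s1, s1)), c(mean_mm = 0, max_mm = 0))
  shifted <- surface_mesh(sweep(s1$vertices, 2, c(0, 0, 2), "+"), s1$faces)
  se <- surface_error(shifted, s1, mode = "correspondence")
  expect_equal(se$mean_mm, 2); expect_equal(se$max_mm, 2)
  s11 <- sphere_mesh(11, 30)
  sn <- surface_error(s1, s11, mode = "nearest")
  expect_equal(sn$mean_mm, 1, tolerance = 0.02)
  expect_equal(sn$max_mm, 1, tolerance = 0.02)
  expect_error(surface_error(s1, sphere_mesh(10, 12)), "equal vertex counts")
  # triangle inequality on corresponding meshes
  pop <- fix_population()
  A <- pop$mesh[[1]]; B <- pop$mesh[[2]]; C <- pop$mesh[[3]]
  expect_lte(surface_error(A, C)$mean_mm,
             surface_error(A, B)$mean_mm + surface_error(B, C)$mean_mm + 1e-12)
})

test_that("tibial length works from landmarks and meshes, and is isometric", {
  lm <- tibble::tibble(
    name = c("medial_condyle", "lateral_condyle", "medial_malleolus",
             "lateral_malleolus"),
    x_mm = c(-10, 10, -8, 8), y_mm = c(5, -5, 4, -4), z_mm = c(400, 400, 0, 0))
  expect_equal(tibial_length(lm), 400)
  sp <- phantom_spec(length = 385)
  expect_equal(tibial_length(phantom_surface(sp)), 385, tolerance = 1e-9)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  lm2 <- lm
  P <- as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]) %*% R
  lm2$x_mm <- P[, 1]; lm2$y_mm <- P[, 2]; lm2$z_mm <- P[, 3]
  expect_equal(tibial_length(lm2), 400, tolerance = 1e-9)
  expect_error(tibial_length(lm[-1, ]), "missing landmark")
})

test_that("distal-third section recovers known phantom semi-axes", {
  sp <- phantom_spec()
  cort <- phantom_surface(sp)
  trab <- phantom_surface(sp, scale = sp$endo_frac)
  sec <- fit_distal_section(cort, trab)
  expect_equal(sec$a_o, sp$a0, tolerance = 0.02)
  expect_equal(sec$b_o, sp$b0, tolerance = 0.02)
  expect_equal(sec$a_i / sec$a_o, sp$endo_frac, tolerance = 0.02)
  # circular shaft: equal semi-axes
  spc <- phantom_spec(a0 = 12, b0 = 12, bow = 0)
  secc <- fit_distal_section(phantom_surface(spc))
  expect_equal(secc$a_o, secc$b_o, tolerance = 1e-6)
  expect_equal(secc$a_i, 0)
  # plane missing the trabecular mesh errors
  tiny <- surface_mesh(trab$vertices * 0.01 + matrix(c(0, 0, 500), nrow(trab$vertices), 3, byrow = TRUE),
                       trab$faces)
  expect_error(fit_distal_section(cort, tiny), "misses")
})

test_that("hollow-ellipse section properties match closed forms and an integration oracle", {
  solid <- hollow_ellipse_section(10, 10)
  sp1 <- section_properties(solid)
  expect_equal(sp1$csa_mm2, pi * 100, tolerance = 1e-12)
  expect_equal(sp1$I_ml_mm4, pi * 1e4 / 4, tolerance = 1e-12)
  sec <- hollow_ellipse_section(15, 12, 10, 8)
  sp2 <- section_properties(sec)
  expect_equal(sp2$csa_mm2, pi * (180 - 80), tolerance = 1e-12)
  expect_equal(sp2$I_ml_mm4, pi / 4 * (12 * 3375 - 8 * 1000), tolerance = 1e-12)
  # 2D numerical-integration oracle on a fine grid
  h <- 0.01
  xs <- seq(-15, 15, by = h); ys <- seq(-12, 12, by = h)
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  inside <- (gx / 15)^2 + (gy / 12)^2 <= 1 & (gx / 10)^2 + (gy / 8)^2 > 1
  expect_equal(sum(inside) * h^2, sp2$csa_mm2, tolerance = 1e-3)
  expect_equal(sum(gx[inside]^2) * h^2, sp2$I_ml_mm4, tolerance = 1e-3)
  expect_equal(sum(gy[inside]^2) * h^2, sp2$I_ap_mm4, tolerance = 1e-3)
  # dimensional scaling: s^2 for areas, s^4 for second moments
  s <- 1.7
  sps <- section_properties(hollow_ellipse_section(15 * s, 12 * s, 10 * s, 8 * s))
  expect_equal(sps$csa_mm2, s^2 * sp2$csa_mm2, tolerance = 1e-12)
  expect_equal(sps$I_ml_mm4, s^4 * sp2$I_ml_mm4, tolerance = 1e-12)
  expect_error(hollow_ellipse_section(10, 10, 11, 5), "geometry error")
})

test_that("9-marker reconstructions overlap truth better than 4-marker on average", {
  pop <- fix_population()
  model <- fix_model()
  lmn <- phantom_landmark_nodes(33L, 16L)
  evalpop <- generate_population(8, seed = 91)
  rep9 <- rep4 <- numeric(8)
  for (i in 1:8) {
    f9 <- fit_landmarks(model, evalpop$landmarks[[i]], marker_config("9-marker"), 3)
    f4 <- fit_landmarks(model, evalpop$landmarks[[i]], marker_config("4-marker"), 2)
    rep9[i] <- reconstruction_report(f9, evalpop$mesh[[i]], evalpop$landmarks[[i]],
                                     lmn, voxel_mm = 2)$jaccard
    rep4[i] <- reconstruction_report(f4, evalpop$mesh[[i]], evalpop$landmarks[[i]],
                                     lmn, voxel_mm = 2)$jaccard
  }
  expect_gt(mean(rep9), mean(rep4))
})
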