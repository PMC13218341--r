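test_that("PCA model has orthonormal modes and full variance accounting", {
  model <- fix_model()
  K <- n_modes(model)
  expect_lte(K, 29)
  expect_lt(max(abs(crossprod(model$modes) - diag(K))), 1e-8)
  expect_true(all(diff(model$lambda) <= 1e-9))
  expect_true(all(model$lambda >= 0))
  expect_equal(sum(model$all_lambda), model$total_var, tolerance = 1e-6)
  # zero scores reproduce the mean exactly
  m0 <- ssm_reconstruct(model)
  expect_equal(as.vector(t(m0$vertices)), unname(model$mean))
})

test_that("identical training meshes give a zero-variance model equal to the input", {
  sp <- phantom_spec()
  meshes <- replicate(5, phantom_surface(sp), simplify = FALSE)
  model <- build_ssm(meshes, landmark_nodes = phantom_landmark_nodes(33L, 16L))
  expect_lt(max(model$all_lambda), 1e-8)
  ctr <- sweep(meshes[[1]]$vertices, 2, colMeans(meshes[[1]]$vertices))
  expect_equal(matrix(model$mean, ncol = 3, byrow = TRUE), unname(ctr),
               tolerance = 1e-8)
})

test_that("a rank-1 population recovers its displacement field and variance", {
  sp <- phantom_spec()
  base <- phantom_surface(sp)
  set.seed(42)
  field <- matrix(rnorm(length(base$vertices)), ncol = 3)
  field <- field / sqrt(sum(field^2))
  # remove the translation component so centering does not distort the field
  field <- sweep(field, 2, colMeans(field))
  field <- field / sqrt(sum(field^2))
  coef_sd <- 2.5
  coefs <- rnorm(30, 0, coef_sd)
  meshes <- lapply(coefs, function(cc) surface_mesh(base$vertices + cc * field,
                                                    base$faces))
  model <- build_ssm(meshes, var_explained = 0.999)
  f_flat <- as.vector(t(field))
  cosang <- abs(sum(model$modes[, 1] * f_flat))
  expect_gt(cosang, 0.99)
  expect_equal(model$lambda[1], var(coefs), tolerance = 0.1 * var(coefs))
})

test_that("reconstruction is linear in the scores and matches direct arithmetic", {
  model <- fix_model()
  b <- 0.5 * sqrt(model$lambda)
  d1 <- ssm_reconstruct(model, b)$vertices - ssm_reconstruct(model)$vertices
  d2 <- ssm_reconstruct(model, 2 * b)$vertices - ssm_reconstruct(model)$vertices
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # single-mode reconstruction equals mean + sqrt(lambda_1) * mode 1
  e1 <- c(sqrt(model$lambda[1]), rep(0, n_modes(model) - 1))
  direct <- model$mean + sqrt(model$lambda[1]) * model$modes[, 1]
  expect_equal(as.vector(t(ssm_reconstruct(model, e1)$vertices)),
               unname(direct), tolerance = 1e-12)
  expect_error(ssm_reconstruct(model, rep(0, n_modes(model) + 1)), "longer")
})

test_that("landmarks from the mean shape yield near-zero scores; k = 0 pins the mean", {
  model <- fix_model()
  lms <- grid_landmarks(ssm_reconstruct(model))
  fit <- fit_landmarks(model, lms, marker_config("9-marker"), k_sd = 3)
  expect_true(all(abs(fit$scores) < 1e-3 * sqrt(model$lambda)))
  fit0 <- fit_landmarks(model, lms, marker_config("4-marker"), k_sd = 0)
  expect_true(all(fit0$scores == 0))
  # k = 0 returns the posed mean regardless of input shape
  lms2 <- fix_population()$landmarks[[7]]
  fit02 <- fit_landmarks(model, lms2, marker_config("9-marker"), k_sd = 0)
  expect_true(all(fit02$scores == 0))
  expect_error(fit_landmarks(model, lms, marker_config("4-marker"), k_sd = -1),
               "k_sd")
  expect_error(fit_landmarks(model, lms[-1, ], marker_config("4-marker"), 3),
               "missing landmark")
})

test_that("9-marker fit recovers generating scores, verified by grid search", {
  # two-parameter family so the full score space can be searched exhaustively
  r <- default_phantom_ranges()
  for (p in c("endo_frac", "flare_prox", "flare_dist", "taper",
              "b0")) r[[p]][2] <- 0
  r$length[2] <- 15; r$bow[2] <- 2
  pop <- generate_population(30, ranges = r, seed = 21)
  model <- build_ssm(pop$mesh, landmark_nodes = phantom_landmark_nodes(33L, 16L),
                     var_explained = 0.9999)
  K <- n_modes(model)
  set.seed(1)
  b_true <- numeric(K)
  b_true[1:2] <- 0.8 * sqrt(model$lambda[1:2]) * c(1, -1)
  shape <- ssm_reconstruct(model, b_true)
  fit <- fit_landmarks(model, grid_landmarks(shape), marker_config("9-marker"),
                       k_sd = 3)
  expect_lt(max(abs(fit$scores - b_true) / sqrt(model$lambda)), 1e-3)
  # brute-force grid over the first two modes at 0.05*sqrt(lambda) resolution
  rows <- as.integer(t(outer(model$landmark_nodes - 1L, 1:3,
                             function(n, d) 3L * n + d)))
  A <- model$modes[rows, 1:2, drop = FALSE]
  mu <- model$mean[rows]
  y <- as.vector(t(as.matrix(grid_landmarks(shape)[, c("x_mm", "y_mm", "z_mm")])))
  # landmarks already sit in the model frame here, so the grid search can
  # compare unposed residuals
  obj <- function(b1, b2) sum((mu + A %*% c(b1, b2) - y)^2)
  g1 <- seq(-3, 3, by = 0.05) * sqrt(model$lambda[1])
  g2 <- seq(-3, 3, by = 0.05) * sqrt(model$lambda[2])
  vals <- outer(g1, g2, Vectorize(obj))
  best <- arrayInd(which.min(vals), dim(vals))
  grid_best <- c(g1[best[1]], g2[best[2]])
  expect_lt(max(abs(fit$scores[1:2] - grid_best) / sqrt(model$lambda[1:2])), 0.06)
})

test_that("tightening the score bounds never improves the landmark objective", {
  model <- fix_model()
  lms <- fix_population()$landmarks[[13]]
  objs <- vapply(c(3, 2, 1, 0), function(k) {
    fit_landmarks(model, lms, marker_config("4-marker"), k_sd = k)$objective
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-6))
})

test_that("9-marker fit of model-span shapes is far more accurate than 4-marker", {
  model <- fix_model()
  set.seed(77)
  ratio <- vapply(1:20, function(i) {
    b <- runif(n_modes(model), -1, 1) * sqrt(model$lambda)
    shape <- ssm_reconstruct(model, b)
    lms <- grid_landmarks(shape)
    e9 <- surface_error(fit_landmarks(model, lms, marker_config("9-marker"), 3)$mesh,
                        shape)$mean_mm
    e4 <- surface_error(fit_landmarks(model, lms, marker_config("4-marker"), 3)$mesh,
                        shape)$mean_mm
    c(e9, e4)
  }, numeric(2))
  expect_lt(mean(ratio[1, ]), 0.05 * mean(ratio[2, ]))
})

test_that("rigidly transforming the landmarks changes the pose, not the scores", {
  model <- fix_model()
  lms <- fix_population()$landmarks[[4]]
  fit1 <- fit_landmarks(model, lms, marker_config("9-marker"), k_sd = 3)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lms2 <- lms
  P <- as.matrix(lms[, c("x_mm", "y_mm", "z_mm")]) %*% R +
    matrix(c(12, -30, 5), nrow(lms), 3, byrow = TRUE)
  lms2$x_mm <- P[, 1]; lms2$y_mm <- P[, 2]; lms2$z_mm <- P[, 3]
  fit2 <- fit_landmarks(model, lms2, marker_config("9-marker"), k_sd = 3)
  expect_equal(fit1$scores, fit2$scores, tolerance = 1e-6)
})

test_that("trabecular regression recovers constructed endosteal geometry", {
  # training population with a fixed endosteal fraction of 0.6
  r <- default_phantom_ranges()
  r$endo_frac <- c(0.6, 0)
  pop <- generate_population(20, ranges = r, seed = 31)
  model <- build_ssm(pop$mesh, landmark_nodes = phantom_landmark_nodes(33L, 16L))
  endo <- lapply(pop$spec, function(s) phantom_surface(s, scale = s$endo_frac))
  tm <- train_trabecular_model(model, pop$mesh, endo)
  fit <- fit_landmarks(model, pop$landmarks[[5]], marker_config("9-marker"), 3)
  recon_c <- ssm_reconstruct(model, fit$scores)
  pred <- predict_trabecular(fit$scores, tm)
  sec <- fit_distal_section(recon_c, pred)
  expect_equal(sec$a_i / sec$a_o, 0.6, tolerance = 0.02)
  expect_equal(sec$b_i / sec$b_o, 0.6, tolerance = 0.02)
  # predicted endosteal surface lies strictly inside the cortical surface
  rad_c <- sqrt(rowSums(sweep(recon_c$vertices[, 1:2], 2,
                              colMeans(recon_c$vertices[, 1:2]))^2))
  rad_t <- sqrt(rowSums(sweep(pred$vertices[, 1:2], 2,
                              colMeans(recon_c$vertices[, 1:2]))^2))
  ring <- seq_len(33 * 16)
  expect_true(all(rad_t[ring] < rad_c[ring]))
  # in-sample prediction error is bounded by the regression residual scale
  tru <- phantom_surface(pop$spec[[5]], scale = 0.6)
  al <- tibload:::.kabsch(pred$vertices, tru$vertices)
  err <- mean(sqrt(rowSums((tibload:::.apply_pose(pred$vertices, al) -
                              tru$vertices)^2)))
  expect_lt(err, 1)
  expect_error(predict_trabecular(fit$scores, structure(list(trained = FALSE),
                                                        class = "trabecular_model")),
               "not trained")
})

test_that("zero-variance training set predicts a constant endosteal surface", {
  sp <- phantom_spec()
  meshes <- replicate(5, phantom_surface(sp), simplify = FALSE)
  endo <- replicate(5, phantom_surface(sp, scale = sp$endo_frac), simplify = FALSE)
  model <- build_ssm(meshes, landmark_nodes = phantom_landmark_nodes(33L, 16L))
  tm <- train_trabecular_model(model, meshes, endo)
  p1 <- predict_trabecular(numeric(n_modes(model)), tm)
  # the constant prediction reproduces the (centred) common endosteal surface
  ctr <- sweep(endo[[1]]$vertices, 2, colMeans(meshes[[1]]$vertices))
  expect_equal(p1$vertices, unname(ctr), tolerance = 1e-6)
  expect_error(predict_trabecular(rep(0, n_modes(model) + 2), tm),
               "does not match")
})
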