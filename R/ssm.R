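#' @title Statistical shape model: PCA over corresponding meshes and
#'   bounded landmark-guided reconstruction
#' @description
#' The shape model is a point-distribution model: after generalized
#' Procrustes alignment of a population of corresponding meshes, principal
#' component analysis yields a mean shape, orthonormal variation modes and
#' per-mode variances. New geometry is reconstructed from sparse landmarks by
#' alternating a closed-form pose (Kabsch) with a box-bound-constrained
#' quadratic update of the principal-component scores, the bound being
#' +/- k standard deviations per mode.
#' @name shapemodel
NULL

# ---- small rigid/similarity registration helpers ------------------------

# Kabsch/Umeyama: returns pose mapping X onto Y (row-vector points):
# y ~= s * x %*% R + t. With scale = FALSE, s = 1.
.kabsch <- function(X, Y, scale = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  H <- crossprod(X0, Y0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (scale) sum(sv$d * c(1, 1, d)) / sum(X0^2) else 1
  t <- cy - s * as.vector(cx %*% R)
  list(R = R, s = s, t = t)
}

.apply_pose <- function(X, pose) {
  sweep(pose$s * X %*% pose$R, 2, pose$t, "+")
}

.invert_pose_points <- function(Y, pose) {
  sweep(Y, 2, pose$t) %*% t(pose$R) / pose$s
}

.identity_pose <- function() list(R = diag(3), s = 1, t = c(0, 0, 0))

# vertices matrix <-> flat (x1,y1,z1,x2,...) vector
.flatten <- function(V) as.vector(t(V))
.unflatten <- function(x) matrix(x, ncol = 3, byrow = TRUE)

#' Generalized Procrustes alignment of corresponding vertex sets
#'
#' Rigid (rotation + translation) by default; isotropic scaling optional.
#' With `scale = FALSE` size differences stay in the shape space, so the
#' first mode of the subsequent PCA captures general size variation.
#'
#' @param verts list of n x 3 vertex matrices with identical row semantics.
#' @param scale allow isotropic scaling in the alignment.
#' @param iter maximum alignment iterations.
#' @return list of aligned vertex matrices (attribute `"mean"`: mean shape).
#' @export
procrustes_align <- function(verts, scale = FALSE, iter = 10) {
  aligned <- lapply(verts, function(V) sweep(V, 2, colMeans(V)))
  ref <- aligned[[1]]
  for (k in seq_len(iter)) {
    aligned <- lapply(aligned, function(V) .apply_pose(V, .kabsch(V, ref, scale = scale)))
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    if (sum((new_ref - ref)^2) < 1e-12 * max(1, sum(ref^2))) {
      ref <- new_ref
      break
    }
    ref <- new_ref
  }
  attr(aligned, "mean") <- ref
  aligned
}

#' Build a PCA statistical shape model from corresponding meshes
#'
#' @param meshes list of `surface_mesh` objects in point correspondence
#'   (identical vertex counts and semantics).
#' @param landmark_nodes named integer vector mapping landmark names to
#'   vertex indices (identical across the population).
#' @param var_explained retain the smallest number of modes explaining this
#'   fraction of total post-alignment variance (capped at n - 1).
#' @param scale allow isotropic scaling during Procrustes alignment
#'   (default FALSE: size stays in the scores).
#' @return a `shape_model`: `mean` (3N vector, mm), `modes` (3N x K,
#'   orthonormal columns), `lambda` (mm^2 per mode, nonincreasing), `faces`,
#'   `landmark_nodes`, `n_train`, `total_var`.
#' @export
build_ssm <- function(meshes, landmark_nodes = NULL, var_explained = 0.99,
                      scale = FALSE) {
  if (length(meshes) < 3) stop("need at least 3 training meshes", call. = FALSE)
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  if (length(unique(nv)) != 1) {
    stop("correspondence error: training meshes have different vertex counts",
         call. = FALSE)
  }
  aligned <- procrustes_align(lapply(meshes, `[[`, "vertices"), scale = scale)
  X <- do.call(rbind, lapply(aligned, .flatten))
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (n - 1)
  total_var <- sum(lambda)
  kmax <- min(n - 1, sum(lambda > 1e-12 * max(lambda, 1)))
  k <- if (kmax == 0) 0 else max(1, which(cumsum(lambda[seq_len(kmax)]) >=
                                            var_explained * total_var)[1])
  if (is.na(k)) k <- kmax
  structure(list(mean = mu,
                 modes = sv$v[, seq_len(k), drop = FALSE],
                 lambda = lambda[seq_len(k)],
                 all_lambda = lambda[seq_len(max(kmax, 1))],
                 total_var = total_var,
                 faces = meshes[[1]]$faces,
                 landmark_nodes = landmark_nodes,
                 n_train = n,
                 scale = scale),
            class = "shape_model")
}

#' Number of retained modes of a shape model
#' @param model a `shape_model`.
#' @return integer mode count K.
#' @export
n_modes <- function(model) ncol(model$modes)

#' Reconstruct a surface from principal-component scores
#'
#' Vertices are `pose(mean + modes %*% b)`; linear in the scores.
#'
#' @param model a `shape_model`.
#' @param scores numeric score vector b (mm), length <= K; padded with zeros.
#' @param pose optional pose list (`R`, `s`, `t`) as returned in an
#'   [fit_landmarks()] result; identity by default.
#' @return a `surface_mesh`.
#' @export
ssm_reconstruct <- function(model, scores = numeric(0), pose = NULL) {
  K <- n_modes(model)
  if (length(scores) > K) {
    stop("score vector longer than the number of retained modes (", K, ")",
         call. = FALSE)
  }
  b <- c(scores, rep(0, K - length(scores)))
  x <- model$mean + as.vector(model$modes %*% b)
  V <- .unflatten(x)
  if (!is.null(pose)) V <- .apply_pose(V, pose)
  surface_mesh(V, model$faces)
}

# landmark rows of the flat representation for given node indices
.lm_rows <- function(nodes) as.vector(t(outer(nodes - 1L, 1:3, function(n, d) 3L * n + d)))

#' Fit a shape model to observed landmarks under bounded PC scores
#'
#' Minimizes the sum of squared distances between the posed model landmarks
#' and the observed landmarks over the pose and the PC scores, subject to the
#' hard box bounds `|b_j| <= k_sd * sqrt(lambda_j)`. The optimizer alternates
#' a closed-form Kabsch pose with a bound-constrained quadratic score update
#' (deterministic start at b = 0, identity pose) until the objective changes
#' by less than `tol` or `max_iter` alternations. Degenerate landmark sets
#' are resolved toward the smallest-norm score vector by a vanishing
#' Tikhonov term.
#'
#' @param model a `shape_model` with `landmark_nodes`.
#' @param observed landmark tibble (`name`, `x_mm`, `y_mm`, `z_mm`)
#'   containing every landmark of `config`.
#' @param config a [marker_config()].
#' @param k_sd bound multiplier k in SD units (>= 0); `k_sd = 0` forces all
#'   scores to zero and returns the posed mean shape.
#' @param scale allow isotropic scaling in the pose (default FALSE).
#' @param max_iter,tol alternation limit and objective-change tolerance.
#' @return an `ssm_fit`: `scores`, `k_sd`, `config`, `pose`, `mesh`
#'   (posed reconstruction), `objective` (mm^2), `iterations`, `converged`,
#'   `bound_active` (logical per mode).
#' @export
fit_landmarks <- function(model, observed, config, k_sd = 3, scale = FALSE,
                          max_iter = 200, tol = 1e-9) {
  if (!inherits(config, "marker_config")) stop("config must be a marker_config", call. = FALSE)
  if (!is.finite(k_sd) || k_sd < 0) stop("k_sd must be >= 0", call. = FALSE)
  if (is.null(model$landmark_nodes)) stop("model carries no landmark map", call. = FALSE)
  nodes <- model$landmark_nodes[config$landmarks]
  if (anyNA(nodes)) {
    stop("model landmark map is missing: ",
         paste(config$landmarks[is.na(nodes)], collapse = ", "), call. = FALSE)
  }
  Y <- .landmark_matrix(observed, config$landmarks)
  if (!all(is.finite(Y))) stop("non-finite landmark coordinates", call. = FALSE)

  rows <- .lm_rows(nodes)
  mu_lm <- model$mean[rows]
  A <- model$modes[rows, , drop = FALSE]
  K <- n_modes(model)
  bound <- k_sd * sqrt(model$lambda)
  free <- bound > 0
  b <- rep(0, K)
  pose <- .identity_pose()

  ridge <- 1e-10                      # tie-break: prefer smallest-norm scores
  AtA <- crossprod(A[, free, drop = FALSE]) + ridge * diag(sum(free))
  obj <- Inf
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max(1, max_iter))) {
    iters <- it
    P <- .unflatten(mu_lm + as.vector(A %*% b))
    pose <- .kabsch(P, Y, scale = scale)
    new_obj <- sum((.apply_pose(P, pose) - Y)^2)
    if (any(free)) {
      d <- .flatten(.invert_pose_points(Y, pose)) - mu_lm
      Atd <- crossprod(A[, free, drop = FALSE], d)
      fn <- function(bf) {
        r <- as.numeric(crossprod(bf, AtA %*% bf)) - 2 * sum(bf * Atd)
        r
      }
      gr <- function(bf) 2 * as.vector(AtA %*% bf - Atd)
      opt <- stats::optim(b[free], fn, gr, method = "L-BFGS-B",
                          lower = -bound[free], upper = bound[free],
                          control = list(factr = 10))
      b[free] <- opt$par
    }
    if (is.finite(obj) && abs(obj - new_obj) < tol) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  # final pose/objective at the final scores
  P <- .unflatten(mu_lm + as.vector(A %*% b))
  pose <- .kabsch(P, Y, scale = scale)
  obj <- sum((.apply_pose(P, pose) - Y)^2)

  structure(list(scores = b, k_sd = k_sd, config = config$name, pose = pose,
                 mesh = ssm_reconstruct(model, b, pose),
                 objective = obj, iterations = iters, converged = converged,
                 bound_active = free & (abs(abs(b) - bound) < 1e-9 * pmax(bound, 1)),
                 model_modes = K),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat("Bounded SSM landmark fit (", x$config, ", +/-", x$k_sd, " SD)\n", sep = "")
  cat("  objective:", format(x$objective, digits = 6), "mm^2 in",
      x$iterations, "alternations\n")
  cat("  modes:", x$model_modes, "| active bounds:", sum(x$bound_active), "\n")
  invisible(x)
}

#' Project a corresponding mesh into a shape model's score space
#'
#' Aligns the mesh to the model mean (full-vertex Kabsch) and projects the
#' residual onto the modes; used for training regressions and for recovering
#' generating scores of model-span shapes.
#'
#' @param model a `shape_model`.
#' @param mesh a `surface_mesh` in correspondence with the model.
#' @return list with `scores` and the alignment `pose`.
#' @export
ssm_project <- function(model, mesh) {
  mu_V <- .unflatten(model$mean)
  pose <- .kabsch(mesh$vertices, mu_V, scale = model$scale)
  x <- .flatten(.apply_pose(mesh$vertices, pose)) - model$mean
  list(scores = as.vector(crossprod(model$modes, x)), pose = pose)
}

# ---- trabecular (endosteal) surface prediction ---------------------------

#' Train the endosteal-surface regression from cortical PC scores
#'
#' Builds an endosteal shape model from the training phantoms' endosteal
#' surfaces expressed in the cortical model frame, then fits a least-squares
#' linear regression from cortical PC scores to endosteal PC scores.
#'
#' @param cortical_model the cortical `shape_model`.
#' @param cortical_meshes,endosteal_meshes training surfaces, pairwise in the
#'   same participant frame and in grid correspondence.
#' @return a `trabecular_model`: endosteal mean/modes plus the regression
#'   coefficient matrix (with intercept).
#' @export
train_trabecular_model <- function(cortical_model, cortical_meshes, endosteal_meshes) {
  stopifnot(length(cortical_meshes) == length(endosteal_meshes))
  n <- length(cortical_meshes)
  B <- matrix(0, n, n_modes(cortical_model))
  E <- matrix(0, n, 3 * nrow(endosteal_meshes[[1]]$vertices))
  for (i in seq_len(n)) {
    pr <- ssm_project(cortical_model, cortical_meshes[[i]])
    B[i, ] <- pr$scores
    E[i, ] <- .flatten(.apply_pose(endosteal_meshes[[i]]$vertices, pr$pose))
  }
  mu_e <- colMeans(E)
  Ec <- sweep(E, 2, mu_e)
  sv <- svd(Ec, nu = 0)
  lambda_e <- sv$d^2 / (n - 1)
  ke <- max(1, min(n - 1, sum(lambda_e > 1e-10 * max(lambda_e, 1e-300))))
  modes_e <- sv$v[, seq_len(ke), drop = FALSE]
  S <- Ec %*% modes_e                     # endosteal scores per training shape
  X <- cbind(1, B)
  W <- tryCatch(solve(crossprod(X) + 1e-10 * diag(ncol(X)), crossprod(X, S)),
                error = function(e) stop("trabecular regression failed: ",
                                         conditionMessage(e), call. = FALSE))
  resid <- S - X %*% W
  structure(list(mean = mu_e, modes = modes_e, lambda = lambda_e[seq_len(ke)],
                 coef = W, faces = endosteal_meshes[[1]]$faces,
                 rms_residual = sqrt(mean(resid^2)), trained = TRUE),
            class = "trabecular_model")
}

#' Predict the endosteal (trabecular) surface from a cortical fit
#'
#' @param fit an `ssm_fit` (or a bare cortical score vector).
#' @param trab_model a trained [train_trabecular_model()] result.
#' @param pose pose to apply; defaults to the fit's pose.
#' @return a `surface_mesh` of the predicted endosteal surface, posed into
#'   the observed frame.
#' @export
predict_trabecular <- function(fit, trab_model, pose = NULL) {
  if (!inherits(trab_model, "trabecular_model") || !isTRUE(trab_model$trained)) {
    stop("trabecular model is not trained", call. = FALSE)
  }
  scores <- if (inherits(fit, "ssm_fit")) fit$scores else as.numeric(fit)
  if (length(scores) != nrow(trab_model$coef) - 1L) {
    stop("score vector length does not match the trained regression (",
         nrow(trab_model$coef) - 1L, " modes)", call. = FALSE)
  }
  if (is.null(pose) && inherits(fit, "ssm_fit")) pose <- fit$pose
  s_e <- as.vector(c(1, scores) %*% trab_model$coef)
  V <- .unflatten(trab_model$mean + as.vector(trab_model$modes %*% s_e))
  # the prediction lives in the model frame; the fit pose carries it into the
  # observed frame
  if (!is.null(pose)) V <- .apply_pose(V, pose)
  surface_mesh(V, trab_model$faces)
}
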