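#' @title Gait processing, static optimization and ankle joint contact force
#' @name musculo
#' @description
#' Stance-phase signal conditioning (zero-lag Butterworth, 10 N stance
#' detection, 101-point time normalization), foot-strike classification,
#' muscle force estimation by static optimization (minimum sum of cubed
#' muscle stresses under joint-moment equality constraints), assembly of the
#' fibula-scaled ankle joint contact force, and the sagittal free-body
#' bending moment at a shaft section.
NULL

#' Preprocess a gait trial to 101-point stance
#'
#' Applies a fourth-order zero-lag Butterworth low-pass (second order passed
#' forward and backward) to every channel - kinetic channels (forces,
#' moments) at `kinetic_cutoff`, kinematic channels at `kinematic_cutoff` -
#' detects stance as the maximal contiguous interval with filtered vertical
#' GRF above 10 N, and linearly resamples all channels to 101 points over
#' stance (0-100%).
#'
#' @param trial a `gait_trial` (see [generate_gait_trials()]).
#' @param kinematic_cutoff,kinetic_cutoff low-pass cutoffs (Hz), must be
#'   below the Nyquist frequency.
#' @param stance_threshold_N vertical-GRF stance threshold (N).
#' @return the trial with `data` replaced by a 101-row tibble (plus
#'   `pct_stance`), and `stance_s` holding the detected bounds.
#' @export
preprocess_gait <- function(trial, kinematic_cutoff = 10, kinetic_cutoff = 20,
                            stance_threshold_N = 10) {
  d <- trial$data
  fs <- trial$rate_hz
  for (cutoff in c(kinematic_cutoff, kinetic_cutoff)) {
    if (cutoff <= 0 || cutoff >= fs / 2) {
      stop("cutoff must be positive and below the Nyquist frequency", call. = FALSE)
    }
  }
  if (nrow(d) < 24) stop("series shorter than the filter warm-up", call. = FALSE)
  kinetic_cols <- intersect(c("grf_z_N", "rf_ax_N", "rf_ap_N", "rf_ml_N",
                              "ankle_moment_Nm", "knee_moment_Nm",
                              "ankle_frontal_moment_Nm"), names(d))
  kinematic_cols <- setdiff(names(d), c(kinetic_cols, "time_s"))
  bf_kin <- signal::butter(2, kinetic_cutoff / (fs / 2), type = "low")
  bf_kmt <- signal::butter(2, kinematic_cutoff / (fs / 2), type = "low")
  filt <- d
  for (cl in kinetic_cols) filt[[cl]] <- .zero_lag_filter(bf_kin, d[[cl]])
  for (cl in kinematic_cols) filt[[cl]] <- .zero_lag_filter(bf_kmt, d[[cl]])

  on <- filt$grf_z_N > stance_threshold_N
  if (!any(on)) stop("no-stance error: vertical GRF never exceeds ",
                     stance_threshold_N, " N", call. = FALSE)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]

  t <- d$time_s
  t_out <- seq(t[i0], t[i1], length.out = 101)
  out <- tibble::tibble(pct_stance = seq(0, 100, length.out = 101))
  for (cl in setdiff(names(d), "time_s")) {
    out[[cl]] <- stats::approx(t, filt[[cl]], xout = t_out)$y
  }
  trial$data <- out
  trial$stance_s <- c(t[i0], t[i1])
  trial$rate_hz <- NULL
  trial
}

# forward-backward filtering with mirror padding so edges (and constants)
# are free of start-up transients
.zero_lag_filter <- function(bf, x) {
  n <- length(x)
  # detrend to the endpoint chord (a constant or linear signal then passes
  # exactly), mirror-pad, filter forward-backward, restore the trend
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / max(n - 1, 1)
  xd <- x - line
  np <- min(n - 1L, 200L)
  xp <- c(-xd[(np + 1L):2L], xd, -xd[(n - 1L):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1L):(np + n)] + line
}

#' Classify foot strike from the foot-ground angle at contact
#'
#' Rearfoot strike iff the sagittal foot angle at initial contact exceeds
#' 8 degrees (strict); otherwise non-rearfoot.
#'
#' @param angle_deg foot angle(s) at contact, degrees (toes-up positive).
#' @return character vector: `"rearfoot"` or `"non-rearfoot"`.
#' @export
classify_foot_strike <- function(angle_deg) {
  if (any(!is.finite(angle_deg))) stop("non-finite foot strike angle", call. = FALSE)
  ifelse(angle_deg > 8.0, "rearfoot", "non-rearfoot")
}

#' Muscle forces by static optimization
#'
#' Minimizes the sum of cubed muscle stresses, `sum((f_i / PCSA_i)^3)`,
#' subject to the joint-moment equality constraints
#' `sum_i r_{d,i} f_i = M_d` for each constrained degree of freedom and
#' `f_i >= 0`. Solved exactly through the smooth concave dual (per-muscle
#' closed-form primal recovery, damped Newton on the dual multipliers with
#' a deterministic bracketing start), so the KKT conditions hold to solver
#' tolerance.
#'
#' @param target_moments named numeric vector of joint moments (N·m); names
#'   must match columns `arm_<dof>_m` of `muscles` (default DOFs:
#'   `c(ankle = ..., knee = ...)`).
#' @param muscles muscle tibble from [generate_muscle_set()].
#' @param tol convergence tolerance on the moment residual (relative).
#' @param lambda0 optional warm-start dual multipliers.
#' @return a `muscle_solution`: tibble `forces` (`name`, `force_N`,
#'   `stress_MPa`), `objective`, `residual_Nm`, `lambda` (dual multipliers).
#' @export
solve_static_optimization <- function(target_moments, muscles, tol = 1e-9,
                                      lambda0 = NULL) {
  dofs <- names(target_moments)
  if (is.null(dofs) || any(!nzchar(dofs))) {
    stop("target_moments must be a named vector (e.g. c(ankle = ..., knee = ...))",
         call. = FALSE)
  }
  arm_cols <- paste0("arm_", dofs, "_m")
  if (!all(arm_cols %in% names(muscles))) {
    stop("muscle set lacks moment arms for DOF(s): ",
         paste(dofs[!arm_cols %in% names(muscles)], collapse = ", "), call. = FALSE)
  }
  R <- t(as.matrix(muscles[, arm_cols]))   # n_dof x n_muscle
  if (any(!is.finite(R))) stop("non-finite moment arms", call. = FALSE)
  A <- muscles$pcsa_mm2
  M <- as.numeric(target_moments)
  nd <- length(M)

  f_of <- function(lam) {
    s <- as.vector(crossprod(R, lam))
    ifelse(s > 0, A^1.5 * sqrt(pmax(s, 0) / 3), 0)
  }
  g_of <- function(lam) {     # dual objective (to maximize)
    s <- as.vector(crossprod(R, lam))
    sum(lam * M) - (2 / (3 * sqrt(3))) * sum(ifelse(s > 0, s^1.5 * A^1.5, 0))
  }
  scale_M <- max(1, max(abs(M)))
  if (max(abs(M)) < 1e-12) {
    return(.muscle_solution(muscles, rep(0, nrow(muscles)), M, R, rep(0, nd)))
  }

  # feasibility direction + magnitude bracketing for the start
  u <- tryCatch(solve(R %*% t(R) + 1e-12 * diag(nd), M), error = function(e) M)
  t_lo <- 1e-18; t_hi <- 1e-18
  h <- function(tt) sum(u * (M - R %*% f_of(tt * u)))
  while (h(t_hi) > 0 && t_hi < 1e14) t_hi <- t_hi * 10
  if (t_hi >= 1e14) {
    worst <- dofs[which.max(abs(M - as.vector(R %*% f_of(t_hi * u))))]
    stop("infeasible static-optimization problem: no muscle can balance DOF '",
         worst, "'", call. = FALSE)
  }
  lam <- if (!is.null(lambda0)) lambda0 else as.vector(t_hi / 2 * u)

  g <- g_of(lam)
  for (it in 1:200) {
    f <- f_of(lam)
    grad <- M - as.vector(R %*% f)
    if (max(abs(grad)) < tol * scale_M) break
    s <- as.vector(crossprod(R, lam))
    D <- ifelse(s > 1e-300, A^1.5 / (2 * sqrt(3 * pmax(s, 1e-300))), 0)
    H <- R %*% (t(R) * D) + 1e-14 * diag(nd)
    step <- tryCatch(solve(H, grad), error = function(e) grad * 1e-6)
    alpha <- 1
    for (ls in 1:60) {
      cand <- lam + alpha * step
      if (g_of(cand) > g - 1e-18) break
      alpha <- alpha / 2
    }
    lam <- lam + alpha * step
    g <- g_of(lam)
  }
  f <- f_of(lam)
  resid <- M - as.vector(R %*% f)
  if (max(abs(resid)) > 1e-6 * scale_M) {
    stop("static optimization failed to meet the moment constraints (residual ",
         format(max(abs(resid))), " N·m)", call. = FALSE)
  }
  .muscle_solution(muscles, f, M, R, lam)
}

.muscle_solution <- function(muscles, f, M, R, lam) {
  structure(list(
    forces = tibble::tibble(name = muscles$name, force_N = f,
                            stress_MPa = f / muscles$pcsa_mm2),
    objective = sum((f / muscles$pcsa_mm2)^3),
    residual_Nm = as.vector(M - R %*% f),
    lambda = lam),
    class = "muscle_solution")
}

#' Assemble the ankle joint contact force over stance
#'
#' Per stance sample, `F = (1 - fibula_share) * (RF + sum_i f_i * dir_i)`
#' component-wise in the shank frame (AP = +X, ML = +Y, axial = +Z), where
#' RF is the ankle joint reaction force and f_i the static-optimization
#' muscle forces resolved along their lines of action. The load case is
#' taken at the sample of peak resultant |F| (earliest sample on ties).
#'
#' @param trial a preprocessed (101-point) `gait_trial`.
#' @param muscle_forces 101 x n matrix of per-sample muscle forces (N).
#' @param muscles the muscle tibble (for lines of action).
#' @param fibula_share fraction of the ankle force carried by the fibula,
#'   in `[0, 1)`; default 0.1 (the classical 0.9 tibial scaling).
#' @return a `load_case`: `F_ajcf` (named ap/ml/axial, N), `peak_index`,
#'   `muscle_forces_peak`, `fibula_share`, and the per-sample `series`.
#' @export
assemble_ajcf <- function(trial, muscle_forces, muscles, fibula_share = 0.1) {
  if (fibula_share < 0 || fibula_share >= 1) {
    stop("fibula share must lie in [0, 1)", call. = FALSE)
  }
  d <- trial$data
  stopifnot(nrow(d) == nrow(muscle_forces), ncol(muscle_forces) == nrow(muscles))
  mf_x <- muscle_forces %*% muscles$dir_x
  mf_y <- muscle_forces %*% muscles$dir_y
  mf_z <- muscle_forces %*% muscles$dir_z
  sc <- 1 - fibula_share
  Fx <- sc * (d$rf_ap_N + as.vector(mf_x))
  Fy <- sc * (d$rf_ml_N + as.vector(mf_y))
  Fz <- sc * (d$rf_ax_N + as.vector(mf_z))
  mag <- sqrt(Fx^2 + Fy^2 + Fz^2)
  pk <- which.max(mag)                    # which.max returns the earliest tie
  structure(list(
    F_ajcf = c(ap = Fx[pk], ml = Fy[pk], axial = Fz[pk]),
    peak_index = pk,
    muscle_forces_peak = muscle_forces[pk, ],
    fibula_share = fibula_share,
    series = tibble::tibble(pct_stance = d$pct_stance, F_ap_N = Fx,
                            F_ml_N = Fy, F_axial_N = Fz, F_res_N = mag)),
    class = "load_case")
}

#' Sagittal free-body bending moment at a shaft section
#'
#' Quasi-static moment about the mediolateral (+Y) axis at the section, from
#' all forces applied distal to it:
#' `M_ML = (z_app - z_sec) * F_AP + (x_app - x_sec) * F_axial` (N·mm -> N·m)
#' with the axial component in the compression-negative reporting
#' convention; this is the y-component of r x F for the actual applied
#' force vector, with r from the section centroid to the application point.
#' Positive M_ML produces anterior tension (posterior ankle shear and a
#' compressive force line posterior to an anteriorly bowed section both
#' yield M > 0).
#'
#' @param load a `load_case` (or a named F vector with ap/ml/axial, N).
#' @param section_center section centroid (x, y, z) in mm.
#' @param application_point force application point (x, y, z) in mm,
#'   typically the ankle joint centre on the distal articular surface.
#' @param bone_z_range optional (z_min, z_max) of the bone; the section must
#'   lie inside it.
#' @return bending moment M_ML in N·m.
#' @export
bending_moment_at_section <- function(load, section_center, application_point,
                                      bone_z_range = NULL) {
  F <- if (inherits(load, "load_case")) load$F_ajcf else load
  if (!is.null(bone_z_range)) {
    if (section_center[3] <= min(bone_z_range) || section_center[3] >= max(bone_z_range)) {
      stop("section lies outside the bone", call. = FALSE)
    }
  }
  r <- application_point - section_center       # mm
  (r[3] * F[["ap"]] + r[1] * F[["axial"]]) / 1000
}
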