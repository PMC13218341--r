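#' @title Hollow-ellipse beam-theory normal stress
#' @name beam2d
#' @description
#' Distal-third normal stress as the superposition of axial stress
#' (`N / CSA`) and bending stress (`M * c / I_ML`) on the hollow elliptical
#' cross-section, with the fiber distance `c = a_o` (periosteal AP
#' semi-axis) on both the anterior and posterior aspect. Tension positive.
NULL

#' Anterior/posterior normal stress at a hollow-ellipse section
#'
#' `sigma_ant = N/CSA + M a_o / I_ML`, `sigma_post = N/CSA - M a_o / I_ML`,
#' in the consistent N-mm-MPa unit system (the moment is supplied in N·m and
#' converted internally).
#'
#' @param axial_force_N axial force N (compression negative), vectorized.
#' @param moment_Nm bending moment about the ML axis (N·m; positive =
#'   anterior tension), vectorized.
#' @param section a [hollow_ellipse_section()].
#' @return tibble with `sigma_ant_MPa` and `sigma_post_MPa`.
#' @export
beam_normal_stress <- function(axial_force_N, moment_Nm, section) {
  sp <- section_properties(section)
  if (sp$csa_mm2 <= 0 || sp$I_ml_mm4 <= 0) {
    stop("degenerate section: zero CSA or second moment", call. = FALSE)
  }
  ax <- axial_force_N / sp$csa_mm2
  bend <- 1000 * moment_Nm * section$a_o / sp$I_ml_mm4
  tibble::tibble(sigma_ant_MPa = ax + bend, sigma_post_MPa = ax - bend)
}

#' Beam stress series over stance
#'
#' @param axial_series_N 101-sample axial force (N).
#' @param moment_series_Nm 101-sample ML bending moment (N·m).
#' @param section a [hollow_ellipse_section()].
#' @return a `beam_stress_series` tibble: `pct_stance`, `sigma_ant_MPa`,
#'   `sigma_post_MPa`.
#' @export
beam_stress_series <- function(axial_series_N, moment_series_Nm, section) {
  stopifnot(length(axial_series_N) == length(moment_series_Nm))
  s <- beam_normal_stress(axial_series_N, moment_series_Nm, section)
  out <- tibble::tibble(pct_stance = seq(0, 100, length.out = length(axial_series_N)),
                        sigma_ant_MPa = s$sigma_ant_MPa,
                        sigma_post_MPa = s$sigma_post_MPa)
  class(out) <- c("beam_stress_series", class(out))
  out
}

#' Stance peaks of a beam stress series
#'
#' Peak anterior = maximum anterior stress over stance (most tensile; may be
#' negative for an all-compressive series), peak posterior = minimum
#' posterior stress (most compressive), with their sample indices.
#'
#' @param series a [beam_stress_series()].
#' @return one-row tibble: `peak_ant_MPa`, `peak_post_MPa`, `idx_ant`,
#'   `idx_post`.
#' @export
peak_stresses <- function(series) {
  if (nrow(series) == 0) stop("empty stress series", call. = FALSE)
  ia <- which.max(series$sigma_ant_MPa)
  ip <- which.min(series$sigma_post_MPa)
  tibble::tibble(peak_ant_MPa = series$sigma_ant_MPa[ia],
                 peak_post_MPa = series$sigma_post_MPa[ip],
                 idx_ant = ia, idx_post = ip)
}
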