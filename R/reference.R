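#' Published group-level reference summaries
#'
#' Group means and standard deviations reported in the motion-capture
#' running literature for the quantities this pipeline computes:
#' reconstruction accuracy per marker configuration (Jaccard index, surface
#' errors against imaging-based reference geometry), tibial length and
#' distal-third hollow-ellipse section properties, and per-condition tibial
#' loading outcomes from 2D beam theory and 3D finite element analysis.
#' They serve as arithmetic inputs for percentage-change cross-checks and as
#' calibration context for the synthetic generator; the package never fits
#' to them.
#'
#' @return a tibble with columns `block` (reconstruction / geometry /
#'   loading), `variable`, `level` (marker configuration or foot-strike
#'   condition, NA for scalars), `mean`, `sd`.
#' @export
reference_group_summary <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      block = "reconstruction",
      variable = rep(c("jaccard", "mean_err_mm", "max_err_mm"), each = 4),
      level = rep(c("9-marker ±3SD", "4-marker ±3SD", "4-marker ±2SD",
                    "4-marker ±1SD"), 3),
      mean = c(0.64, 0.49, 0.53, 0.55,
               6.49, 10.05, 8.79, 8.70,
               13.11, 19.43, 16.68, 16.38),
      sd = c(0.05, 0.10, 0.09, 0.10,
             2.22, 2.28, 2.04, 2.65,
             3.82, 4.27, 3.79, 3.91)),
    tibble::tibble(
      block = "geometry",
      variable = c("tibial_length_marker_mm", "tibial_length_model_mm",
                   "csa_mm2", "I_ml_mm4", "I_ap_mm4"),
      level = NA_character_,
      mean = c(398.2, 403.6, 393.1, 23607.5, 18894.2),
      sd = c(14.0, 24.7, 65.4, 8368.2, 6251.5)),
    tibble::tibble(
      block = "loading",
      variable = rep(c("peak_ant_MPa", "pct95_pmvm_ue", "strained_vol_mm3",
                       "peak_tens_MPa", "peak_comp_MPa"), each = 3),
      level = rep(c("hRFS", "iRFS", "iFFS"), 5),
      mean = c(76.8, 64.2, 89.8,
               3625.9, 3067.4, 4260.0,
               5916.0, 3071.3, 8716.5,
               82.9, 69.1, 98.4,
               -98.4, -81.4, -114.3),
      sd = c(26.2, 20.0, 31.2,
             955.7, 709.4, 1222.3,
             4333.0, 2723.6, 4397.6,
             21.9, 15.4, 27.4,
             26.5, 20.5, 32.4)))
}

#' Percentage changes between conditions of the reference loading summary
#'
#' Recomputes, from the published per-condition group means, the relative
#' change of each loading outcome between two foot-strike conditions.
#'
#' @param from,to condition labels.
#' @return tibble: `variable`, `from`, `to`, `pct_change` (one decimal).
#' @export
reference_percent_changes <- function(from = "hRFS", to = "iFFS") {
  ref <- reference_group_summary()
  ref <- ref[ref$block == "loading", ]
  w <- tidyr::pivot_wider(ref[, c("variable", "level", "mean")],
                          names_from = "level", values_from = "mean")
  pc <- round(percent_change(w[[from]], w[[to]]), 1)
  tibble::tibble(variable = w$variable, from = from, to = to, pct_change = pc)
}
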