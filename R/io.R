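#' @title File interfaces
#' @name io
#' @description
#' Plain-text interchange: ASCII STL/PLY surface meshes, landmark and gait
#' CSV tables, and load-case JSON (raw newtons and body-weight normalized).
NULL

#' Write a surface mesh as ASCII STL
#' @param mesh a `surface_mesh`. @param path output file.
#' @return the path, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid tibload", con)
  chunk <- sprintf(
    "facet normal %g %g %g\nouter loop\nvertex %g %g %g\nvertex %g %g %g\nvertex %g %g %g\nendloop\nendfacet",
    n[, 1], n[, 2], n[, 3], p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(chunk, con)
  writeLines("endsolid tibload", con)
  invisible(path)
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a `surface_mesh`. @param path output file.
#' @return the path, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Write / read a landmark table (`name,x_mm,y_mm,z_mm`)
#' @param landmarks landmark tibble. @param path CSV file.
#' @return the path, invisibly (writer); a landmark tibble (reader).
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("name", "x_mm", "y_mm", "z_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a gait trial CSV
#'
#' Columns `time_s,grf_z_N,rf_ax_N,rf_ap_N,rf_ml_N,ankle_moment_Nm,
#' knee_moment_Nm,foot_angle_deg` (the foot angle at contact is a scalar,
#' repeated per row).
#' @param trial a `gait_trial`. @param path CSV file.
#' @return the path, invisibly (writer); a `gait_trial` (reader).
#' @export
write_gait_csv <- function(trial, path) {
  d <- trial$data
  d$foot_angle_deg <- trial$foot_angle_deg
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_csv
#' @param rate_hz sampling rate if the file has no `time_s` column.
#' @export
read_gait_csv <- function(path, rate_hz = NULL) {
  d <- tibble::as_tibble(utils::read.csv(path))
  angle <- if ("foot_angle_deg" %in% names(d)) d$foot_angle_deg[1] else NA_real_
  d$foot_angle_deg <- NULL
  if (is.null(rate_hz)) {
    if (!"time_s" %in% names(d)) stop("need time_s column or rate_hz", call. = FALSE)
    rate_hz <- 1 / stats::median(diff(d$time_s))
  }
  structure(list(data = d, foot_angle_deg = angle, rate_hz = rate_hz),
            class = "gait_trial")
}

#' Write a load case as JSON
#'
#' Mirrors the supplementary-table schema: ankle joint contact force
#' components (axial, anteroposterior, mediolateral) at the peak instant,
#' raw (N) and body-weight normalized, plus the fibular share.
#'
#' @param load a `load_case`. @param mass_kg participant mass for the
#'   body-weight normalization. @param path JSON file.
#' @return the path, invisibly.
#' @export
write_load_case_json <- function(load, mass_kg, path) {
  bw <- mass_kg * 9.81
  jsonlite::write_json(list(
    fibula_share = load$fibula_share,
    peak_index = load$peak_index,
    raw_N = as.list(load$F_ajcf),
    bw_normalized = as.list(load$F_ajcf / bw)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_load_case_json
#' @export
read_load_case_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(F_ajcf = unlist(j$raw_N), peak_index = j$peak_index,
                 fibula_share = j$fibula_share, series = NULL,
                 muscle_forces_peak = NULL), class = "load_case")
}
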