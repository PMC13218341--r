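#' @title End-to-end experiments
#' @name pipeline
#' @description
#' Orchestrates the two studies: the reconstruction-accuracy experiment
#' (marker-configuration sensitivity of the bounded shape-model fit) and the
#' foot-strike loading study (reconstruction, muscle forces, ankle joint
#' contact force, 2D beam and 3D finite element stress, nonparametric
#' statistics and 2D-vs-3D agreement). Both are fully reproducible from
#' their configuration and seed.
NULL

#' Study configuration
#'
#' @param seed integer master seed.
#' @param n_train shape-model training population size.
#' @param n_eval evaluation population size (reconstruction experiment).
#' @param n_participants runners in the loading study.
#' @param sd_ladder bound multipliers evaluated for the 4-marker fit.
#' @param chosen_k_sd bound multiplier of the study's chosen configuration
#'   (4-marker fit used for the loading study).
#' @param voxel_mm Jaccard voxel size.
#' @param fe_size_mm element size of the loading-study FE meshes.
#' @param mesh_ladder_mm convergence ladder.
#' @param fibula_share fibular load share (0.1 gives the 0.9 scaling).
#' @param kappa strain-measure asymmetry parameter.
#' @param effect_spec per-condition loading effects,
#'   see [default_effect_spec()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_train = 30, n_eval = 20, n_participants = 18,
                       sd_ladder = c(3, 2, 1), chosen_k_sd = 2, voxel_mm = 1,
                       fe_size_mm = 3.6, mesh_ladder_mm = c(5.5, 3.6, 2.7, 2.0),
                       fibula_share = 0.1, kappa = 1,
                       effect_spec = default_effect_spec()) {
  structure(list(seed = as.integer(seed), n_train = n_train, n_eval = n_eval,
                 n_participants = n_participants, sd_ladder = sd_ladder,
                 chosen_k_sd = chosen_k_sd, voxel_mm = voxel_mm,
                 fe_size_mm = fe_size_mm, mesh_ladder_mm = mesh_ladder_mm,
                 fibula_share = fibula_share, kappa = kappa,
                 effect_spec = effect_spec), class = "run_config")
}

#' Screen participants by stature against the training population
#'
#' Excluded iff height falls outside mean +/- 2 SD of the shape-model
#' training population (bounds inclusive: a height exactly on a bound is
#' included).
#'
#' @param heights_cm participant heights (cm, > 0).
#' @param train_mean_cm,train_sd_cm training population stature mean and SD.
#' @return tibble: `height_cm`, `lower_cm`, `upper_cm`, `included`.
#' @export
screen_participants <- function(heights_cm, train_mean_cm = 176.1, train_sd_cm = 11.6) {
  if (any(heights_cm <= 0)) stop("non-positive height", call. = FALSE)
  if (train_mean_cm <= 0 || train_sd_cm <= 0) {
    stop("training mean/SD must be > 0", call. = FALSE)
  }
  lo <- train_mean_cm - 2 * train_sd_cm
  hi <- train_mean_cm + 2 * train_sd_cm
  tibble::tibble(height_cm = heights_cm, lower_cm = lo, upper_cm = hi,
                 included = heights_cm >= lo & heights_cm <= hi)
}

# post-hoc significance letters in Table style: one letter per condition pair
.posthoc_letters <- function(pairwise) {
  paste(LETTERS[seq_len(nrow(pairwise))][pairwise$significant], collapse = ", ")
}

#' Reconstruction-accuracy experiment
#'
#' Builds the shape model on a training population, then fits every
#' evaluation phantom's landmarks under the four marker configurations
#' (9-marker +/-3 SD reference; 4-marker at each ladder bound), computing
#' the Jaccard index and surface errors against the ground-truth phantom,
#' followed by Friedman + Bonferroni-corrected Wilcoxon post hocs across
#' configurations for each metric.
#'
#' @param config a [run_config()].
#' @return a `reconstruction_experiment`: `metrics` (phantom x
#'   configuration tibble), `summary` (mean/SD per configuration),
#'   `stats` (per metric: main effect + post-hoc letters), `model`.
#' @export
run_reconstruction_experiment <- function(config = run_config()) {
  restore <- .with_seed(config$seed)
  on.exit(restore())
  seeds <- sample.int(2^30, 2)
  training <- generate_population(config$n_train, seed = seeds[1])
  evalpop <- generate_population(config$n_eval, seed = seeds[2])
  ranges <- default_phantom_ranges()
  lm_nodes <- phantom_landmark_nodes(ranges$nz, ranges$nc)
  model <- build_ssm(training$mesh, landmark_nodes = lm_nodes)

  cells <- dplyr::bind_rows(
    tibble::tibble(config_name = "9-marker", k_sd = 3),
    tibble::tibble(config_name = "4-marker", k_sd = config$sd_ladder))
  metrics <- purrr::map_dfr(seq_len(nrow(evalpop)), function(i) {
    purrr::map_dfr(seq_len(nrow(cells)), function(j) {
      fit <- fit_landmarks(model, evalpop$landmarks[[i]],
                           marker_config(cells$config_name[j]),
                           k_sd = cells$k_sd[j])
      rep_ <- reconstruction_report(fit, evalpop$mesh[[i]], evalpop$landmarks[[i]],
                                    lm_nodes, voxel_mm = config$voxel_mm)
      dplyr::bind_cols(tibble::tibble(phantom = evalpop$id[i]), rep_)
    })
  })
  metrics$cell <- paste0(metrics$config, " ±", metrics$k_sd, "SD")

  summary <- metrics |>
    dplyr::group_by(cell) |>
    dplyr::summarise(dplyr::across(c(jaccard, mean_err_mm, max_err_mm),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  stats_tbl <- purrr::map_dfr(c("jaccard", "mean_err_mm", "max_err_mm"), function(v) {
    cc <- compare_conditions(metrics, value = v, condition = "cell",
                             participant = "phantom")
    dplyr::bind_cols(tibble::tibble(metric = v), cc$main,
                     tibble::tibble(posthoc = .posthoc_letters(cc$pairwise)))
  })
  structure(list(metrics = metrics, summary = summary, stats = stats_tbl,
                 model = model, config = config),
            class = "reconstruction_experiment")
}

# per-sample static optimization over the 101-point stance, warm-started.
# Only the sagittal ankle DOF is constrained: the eleven tibia-spanning
# muscles all cross the ankle, and only the gastrocnemii cross the knee (as
# flexors), so a knee equality constraint would be infeasible whenever the
# stance knee moment is extensor.
.muscle_force_series <- function(trial, muscles) {
  d <- trial$data
  n <- nrow(d)
  out <- matrix(0, n, nrow(muscles))
  lam <- NULL
  for (t in seq_len(n)) {
    M <- c(ankle = d$ankle_moment_Nm[t])
    if (max(abs(M)) < 1e-9) next
    sol <- solve_static_optimization(M, muscles, lambda0 = lam)
    lam <- sol$lambda
    out[t, ] <- sol$forces$force_N
  }
  out
}

#' Foot-strike loading study
#'
#' The full two-model pipeline on a synthetic cohort: stature screening,
#' 4-marker bounded reconstruction (the chosen configuration), endosteal
#' prediction, distal-third section properties, per-sample static
#' optimization, ankle joint contact force assembly (fibula-scaled),
#' 2D beam stress and 3D finite element stress/strain per condition,
#' then the rank-based statistics and the 2D-vs-3D agreement analysis.
#'
#' @param config a [run_config()].
#' @param progress print per-participant progress.
#' @return a `loading_study` list: `outcomes` (participant x condition
#'   tibble of 2D and 3D metrics), `stats` (per outcome), `agreement`
#'   (hRFS -> iFFS percentage-change method agreement), `lengths` (marker
#'   vs model length agreement), `sections`, `sex_descriptives`,
#'   `screening`, `config`.
#' @export
run_loading_experiment <- function(config = run_config(), progress = FALSE) {
  ds <- generate_study_dataset(config$n_participants, config$n_train,
                               seed = config$seed,
                               effect_spec = config$effect_spec)
  # stature screening against the synthetic training population
  train_heights <- vapply(ds$training$spec, function(s) s$length / 2.4, numeric(1))
  scr <- screen_participants(ds$participants$height_cm,
                             mean(train_heights), stats::sd(train_heights))
  keep <- scr$included
  participants <- ds$participants[keep, ]

  ranges <- default_phantom_ranges()
  lm_nodes <- phantom_landmark_nodes(ranges$nz, ranges$nc)
  model <- build_ssm(ds$training$mesh, landmark_nodes = lm_nodes)
  endo_meshes <- purrr::map(ds$training$spec, function(s)
    phantom_surface(s, scale = s$endo_frac))
  trab_model <- train_trabecular_model(model, ds$training$mesh, endo_meshes)
  materials <- fe_materials()

  rows <- list(); sec_rows <- list(); len_rows <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$id[i]
    if (progress) message("participant ", pid)
    fit <- fit_landmarks(model, participants$landmarks[[i]],
                         marker_config("4-marker"), k_sd = config$chosen_k_sd)
    # all loading computations run in the bone's canonical frame (+Z long
    # axis): loads are expressed in the anatomical shank frame, which the
    # reconstruction's own axes realize; the fitted pose only matters when
    # comparing against observed geometry
    recon_c <- ssm_reconstruct(model, fit$scores)
    trab <- predict_trabecular(fit$scores, trab_model)
    section <- fit_distal_section(recon_c, trab)
    sp <- section_properties(section)
    sec_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(participant = pid, sex = participants$sex[i],
                     a_o = section$a_o, b_o = section$b_o,
                     a_i = section$a_i, b_i = section$b_i), sp)
    len_rows[[i]] <- tibble::tibble(
      participant = pid,
      marker_mm = tibial_length(participants$landmarks[[i]]),
      model_mm = tibial_length(recon_c))

    # one FE mesh and factorization per participant, reused across conditions
    fe_mesh <- tet_mesh_from_surfaces(recon_c, trab, ranges$nz, ranges$nc,
                                      config$fe_size_mm)
    fe_model_i <- build_fe_model(fe_mesh, materials)
    # distal application point (ankle centre) of the reconstructed tibia
    zr <- range(recon_c$vertices[, 3])
    distal_ring <- recon_c$vertices[recon_c$vertices[, 3] < zr[1] + 1e-6, ,
                                    drop = FALSE]
    app_pt <- colMeans(distal_ring)

    trials_i <- ds$trials[ds$trials$id == pid, ]
    for (j in seq_len(nrow(trials_i))) {
      cond <- trials_i$condition[j]
      trial <- preprocess_gait(trials_i$trial[[j]])
      mf <- .muscle_force_series(trial, ds$muscles)
      lc <- assemble_ajcf(trial, mf, ds$muscles, fibula_share = config$fibula_share)
      # beam series: free-body ML moment at the distal-third section
      r <- app_pt - section$center
      m_series <- (r[3] * lc$series$F_ap_N + r[1] * lc$series$F_axial_N) / 1000
      bser <- beam_stress_series(lc$series$F_axial_N, m_series, section)
      pk <- peak_stresses(bser)

      sol <- solve_fe(fe_model_i, f = .fe_rhs(fe_mesh, lc$F_ajcf))
      fld <- fe_field_metrics(sol, fe_model_i, kappa = config$kappa)
      sm <- summarize_fe_fields(fld, fe_mesh)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(participant = pid, sex = participants$sex[i],
                       condition = cond,
                       foot_strike = classify_foot_strike(trial$foot_angle_deg),
                       load_hash = .hash_load(lc$F_ajcf),
                       F_axial_N = lc$F_ajcf[["axial"]],
                       F_ap_N = lc$F_ajcf[["ap"]],
                       F_ml_N = lc$F_ajcf[["ml"]],
                       peak_moment_Nm = m_series[pk$idx_ant]),
        pk[, c("peak_ant_MPa", "peak_post_MPa")], sm)
    }
  }
  outcomes <- dplyr::bind_rows(rows)
  sections <- dplyr::bind_rows(sec_rows)
  lengths <- dplyr::bind_rows(len_rows)

  out_vars <- c("peak_ant_MPa", "pct95_pmvm_ue", "strained_vol_mm3",
                "peak_tens_MPa", "peak_comp_MPa")
  stats_tbl <- purrr::map_dfr(out_vars, function(v) {
    cc <- compare_conditions(outcomes, value = v, condition = "condition",
                             participant = "participant")
    dplyr::bind_cols(tibble::tibble(outcome = v), cc$main,
                     tibble::tibble(posthoc = .posthoc_letters(cc$pairwise)))
  })

  wide <- function(v) {
    tidyr::pivot_wider(outcomes[, c("participant", "condition", v)],
                       names_from = "condition", values_from = dplyr::all_of(v))
  }
  w2 <- wide("peak_ant_MPa"); w3 <- wide("peak_tens_MPa")
  agreement <- method_agreement(percent_change(w2$hRFS, w2$iFFS),
                                percent_change(w3$hRFS, w3$iFFS),
                                id = w2$participant)

  structure(list(
    outcomes = outcomes,
    stats = stats_tbl,
    agreement = agreement,
    lengths = length_agreement(lengths$marker_mm, lengths$model_mm),
    length_table = lengths,
    sections = sections,
    sex_descriptives = dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(variable = "csa_mm2"),
                       group_descriptives(sections$csa_mm2, sections$sex)),
      purrr::map_dfr(unique(outcomes$condition), function(cd) {
        o <- outcomes[outcomes$condition == cd, ]
        dplyr::bind_cols(tibble::tibble(variable = paste0("peak_ant_MPa_", cd)),
                         group_descriptives(o$peak_ant_MPa, o$sex))
      })),
    screening = scr, n_analyzed = nrow(participants), config = config),
    class = "loading_study")
}

# right-hand side for a load case on an existing mesh (uniform coupling)
.fe_rhs <- function(mesh, F) {
  f <- numeric(3 * nrow(mesh$nodes))
  ds <- mesh$node_sets$distal_surface
  per <- c(F[["ap"]], F[["ml"]], -F[["axial"]]) / length(ds)
  f[3 * (ds - 1L) + 1L] <- per[1]
  f[3 * (ds - 1L) + 2L] <- per[2]
  f[3 * (ds - 1L) + 3L] <- per[3]
  f
}

.hash_load <- function(F) paste(sprintf("%.6f", unname(F)), collapse = "|")

#' @export
print.loading_study <- function(x, ...) {
  cat("Foot-strike loading study:", x$n_analyzed, "participants x",
      length(unique(x$outcomes$condition)), "conditions\n")
  cat("\nGroup means by condition:\n")
  print(dplyr::summarise(dplyr::group_by(x$outcomes, condition),
                         dplyr::across(c(peak_ant_MPa, peak_tens_MPa,
                                         pct95_pmvm_ue, strained_vol_mm3),
                                       mean)))
  cat("\nMain effects:\n")
  print(x$stats[, c("outcome", "statistic", "p.value", "kendall_w", "posthoc")])
  print(x$agreement)
  invisible(x)
}
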