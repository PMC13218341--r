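#' Default phantom parameter distributions
#'
#' Normal mean/SD pairs for each phantom parameter, emulating a young,
#' healthy-adult training population (lengths follow stature at
#' roughly 2.4 mm per cm of height; distal-third semi-axes and endosteal
#' fraction are set so the population mean hollow-ellipse section matches
#' typical adult distal-third tibia properties: CSA ~ 393 mm^2,
#' I_ML ~ 23.6e3 mm^4, I_AP ~ 18.9e3 mm^4).
#'
#' @param length_mean,length_sd shaft length distribution (mm).
#' @return named list of `c(mean, sd)` pairs plus the shared grid resolution.
#' @export
default_phantom_ranges <- function(length_mean = 422.6, length_sd = 27.8) {
  list(length = c(length_mean, length_sd),
       a0 = c(13.8, 1.6), b0 = c(12.3, 1.5),
       endo_frac = c(0.51, 0.06),
       flare_prox = c(1.6, 0.3), flare_dist = c(1.35, 0.25),
       bow = c(4, 2.5), taper = c(0.15, 0.1),
       nz = 33L, nc = 16L)
}

# truncated-normal draw keeping parameters in their valid domain
.draw_param <- function(n, ms, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, ms[1], ms[2])
  pmin(pmax(x, lo), hi)
}

#' Generate a tibia phantom population in point correspondence
#'
#' Draws phantom parameters from truncated normal distributions and builds
#' the periosteal surface mesh, the 9-landmark set and the spec for each
#' phantom. All meshes share the grid resolution, so node i has the same
#' parametric location in every phantom and landmark node indices are
#' population-wide constants.
#'
#' @param n population size (>= 3).
#' @param ranges parameter distributions, see [default_phantom_ranges()].
#' @param seed integer RNG seed.
#' @param landmark_noise_sd isotropic landmark offset SD (mm), default 0.
#' @return a tibble with one row per phantom and list-columns `mesh`
#'   (`surface_mesh`), `landmarks` (tibble) and `spec` (`phantom_spec`).
#' @export
generate_population <- function(n, ranges = default_phantom_ranges(), seed = 1,
                                landmark_noise_sd = 0) {
  if (n < 3) stop("population size must be >= 3", call. = FALSE)
  for (p in c("length", "a0", "b0")) {
    if (ranges[[p]][1] <= 0) stop("invalid parameter range: ", p, " mean must be > 0",
                                  call. = FALSE)
  }
  if (ranges$endo_frac[1] <= 0 || ranges$endo_frac[1] >= 1) {
    stop("invalid parameter range: endo_frac mean must lie in (0,1)", call. = FALSE)
  }
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  draws <- tibble::tibble(
    length = .draw_param(n, ranges$length, lo = 50),
    a0 = .draw_param(n, ranges$a0, lo = 2),
    b0 = .draw_param(n, ranges$b0, lo = 2),
    endo_frac = .draw_param(n, ranges$endo_frac, lo = 0.2, hi = 0.85),
    flare_prox = .draw_param(n, ranges$flare_prox, lo = 1),
    flare_dist = .draw_param(n, ranges$flare_dist, lo = 1),
    bow = .draw_param(n, ranges$bow, lo = 0),
    taper = .draw_param(n, ranges$taper, lo = 0))
  specs <- purrr::pmap(draws, phantom_spec, nz = ranges$nz, nc = ranges$nc)
  meshes <- purrr::map(specs, phantom_surface)
  landmarks <- purrr::map(meshes, phantom_landmarks, nz = ranges$nz, nc = ranges$nc,
                          noise_sd = landmark_noise_sd)
  tibble::tibble(id = sprintf("P%02d", seq_len(n)), mesh = meshes,
                 landmarks = landmarks, spec = specs)
}

# deterministic local RNG scope; restores the caller's RNG state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate the 11-muscle geometry set
#'
#' The eleven ankle-crossing muscles spanning the tibia (triceps surae, deep
#' posterior compartment, peroneals and the anterior compartment) with
#' plausible physiological cross-sectional areas (mm^2), sagittal moment
#' arms for the ankle and knee (m; dorsiflexion and knee extension positive
#' - only the biarticular gastrocnemii have nonzero knee arms, as flexors)
#' and unit lines of action in the shank frame (+X anterior, +Y lateral,
#' +Z proximal; muscle pull on the tibia is predominantly compressive, -Z,
#' with the plantarflexors acting slightly posteriorly). Values are drawn
#' once from narrow distributions around literature-scale magnitudes so
#' repeated calls with one seed are bit-identical.
#'
#' @param seed integer RNG seed.
#' @return a tibble: `name`, `group` ("plantarflexor"/"dorsiflexor"),
#'   `pcsa_mm2`, `arm_ankle_m`, `arm_knee_m`, `dir_x`, `dir_y`, `dir_z`
#'   (unit vectors).
#' @export
generate_muscle_set <- function(seed = 1) {
  base <- tibble::tibble(
    name = c("soleus", "med_gastroc", "lat_gastroc", "tib_post",
             "flex_hal_long", "flex_dig_long", "per_long", "per_brev",
             "tib_ant", "ext_dig_long", "ext_hal_long"),
    group = c(rep("plantarflexor", 8), rep("dorsiflexor", 3)),
    pcsa_mm2 = c(15800, 6800, 3300, 4600, 1700, 1100, 2900, 1400,
                 4300, 1600, 900),
    arm_ankle_m = c(-0.049, -0.047, -0.046, -0.014, -0.012, -0.010, -0.009,
                    -0.008, 0.037, 0.030, 0.025),
    arm_knee_m = c(0, -0.018, -0.018, 0, 0, 0, 0, 0, 0, 0, 0),
    dir_x = c(-0.12, -0.13, -0.13, -0.06, -0.05, -0.05, -0.04, -0.04,
              0.15, 0.12, 0.10),
    dir_y = c(0, -0.03, 0.05, -0.04, -0.03, -0.04, 0.08, 0.07, 0.02, 0.05, 0.03),
    dir_z = -1)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  ms <- base
  ms$pcsa_mm2 <- ms$pcsa_mm2 * exp(stats::rnorm(nrow(ms), 0, 0.03))
  nrm <- sqrt(ms$dir_x^2 + ms$dir_y^2 + ms$dir_z^2)
  ms$dir_x <- ms$dir_x / nrm; ms$dir_y <- ms$dir_y / nrm; ms$dir_z <- ms$dir_z / nrm
  ms
}

#' Default per-condition effect specification for gait synthesis
#'
#' Encodes the study conditions: per-condition foot-strike-angle mean/SD
#' (degrees) and per-condition multiplicative scaling of the peak ankle
#' plantarflexion moment, the axial/mediolateral ankle reaction force, and
#' the anteroposterior shear, plus a stance-timing skew (forefoot loading
#' peaks earlier). The scalers are calibrated so plantar-flexor demand, and
#' with it tibial loading, is ordered iFFS > hRFS > iRFS by construction;
#' the channels scale non-proportionally across conditions, as foot strike
#' reshapes the load vector rather than merely rescaling it.
#'
#' @return a tibble with one row per condition (`hRFS`, `iRFS`, `iFFS`).
#' @export
default_effect_spec <- function() {
  tibble::tibble(
    condition = c("hRFS", "iRFS", "iFFS"),
    fsa_mean_deg = c(14.3, 29.0, -4.4),
    fsa_sd_deg = c(4.3, 5.7, 4.7),
    moment_scale = c(1.00, 0.84, 1.18),
    rf_scale = c(1.00, 0.94, 1.06),
    ap_scale = c(1.00, 0.80, 1.25),
    skew = c(0.6, 0.7, 0.35))
}

# smooth stance bump, zero outside [t0, t1], unit peak
.stance_bump <- function(t, t0, t1, skew = 0) {
  u <- (t - t0) / (t1 - t0)
  out <- numeric(length(t))
  inside <- u > 0 & u < 1
  v <- u[inside]
  out[inside] <- sin(pi * v)^2 * (1 + skew * (v - 0.5))
  out
}

#' Generate per-condition stance gait trials
#'
#' Emits raw-rate (1000 Hz) shank-frame time series per participant and
#' condition: vertical ground reaction force, the three ankle joint reaction
#' force components, sagittal ankle and knee moments, and the foot angle at
#' contact. Waveforms are smooth stance bumps whose peaks scale with body
#' mass, the participant factor and the per-condition effect spec, plus
#' multiplicative trial noise; group-mean peak ankle plantarflexion moments
#' are ordered iFFS > hRFS > iRFS by construction of the moment scalers.
#'
#' @param participants tibble with columns `id` and `mass_kg` (and
#'   optionally `height_cm`).
#' @param conditions character vector of condition labels (must appear in
#'   `effect_spec`).
#' @param effect_spec see [default_effect_spec()].
#' @param seed integer RNG seed.
#' @param noise_sd multiplicative trial-to-trial noise SD.
#' @param participant_sd SD of the lognormal participant strength factor
#'   shared across a participant's conditions; with `noise_sd = 0` and
#'   `participant_sd = 0`, equal-mass participants are identical within a
#'   condition.
#' @param rate_hz sampling rate of the emitted series.
#' @return tibble with one row per participant x condition; list-column
#'   `trial` holds each `gait_trial` (data plus `foot_angle_deg`, `rate_hz`).
#' @export
generate_gait_trials <- function(participants, conditions = c("hRFS", "iRFS", "iFFS"),
                                 effect_spec = default_effect_spec(), seed = 1,
                                 noise_sd = 0.05, participant_sd = 0.12,
                                 rate_hz = 1000) {
  unknown <- setdiff(conditions, effect_spec$condition)
  if (length(unknown) > 0) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  g <- 9.81
  t <- seq(0, 0.4, by = 1 / rate_hz)
  t0 <- 0.05; t1 <- 0.30                     # stance window, s
  out <- tidyr::expand_grid(participants, condition = conditions)
  es <- effect_spec[match(out$condition, effect_spec$condition), ]
  # participant-level strength factor, shared across that participant's conditions
  pf <- stats::setNames(exp(stats::rnorm(nrow(participants), 0, participant_sd)),
                        participants$id)
  trials <- vector("list", nrow(out))
  for (r in seq_len(nrow(out))) {
    bw <- out$mass_kg[r] * g
    fac <- pf[[out$id[r]]] *
      (if (noise_sd > 0) exp(stats::rnorm(1, 0, noise_sd)) else 1)
    m_pk <- -2.45 * out$mass_kg[r] * es$moment_scale[r] * fac   # plantarflexion < 0
    k_pk <- 2.2 * out$mass_kg[r] * fac                          # knee extension > 0
    rf_ax <- -2.4 * bw * es$rf_scale[r] * fac                   # compression < 0
    rf_ap <- -0.8 * bw * es$ap_scale[r] * fac                   # posterior shear
    rf_ml <- 0.12 * bw * es$rf_scale[r] * fac
    grf_pk <- 2.5 * bw * fac
    bump <- .stance_bump(t, t0, t1)
    bump_late <- .stance_bump(t, t0, t1, skew = es$skew[r])
    trial <- structure(list(
      data = tibble::tibble(
        time_s = t,
        grf_z_N = grf_pk * bump,
        rf_ax_N = rf_ax * bump_late,
        rf_ap_N = rf_ap * bump_late,
        rf_ml_N = rf_ml * bump,
        ankle_moment_Nm = m_pk * bump_late,
        knee_moment_Nm = k_pk * bump),
      foot_angle_deg = stats::rnorm(1, es$fsa_mean_deg[r], es$fsa_sd_deg[r]),
      rate_hz = rate_hz, stance_window_s = c(t0, t1)),
      class = "gait_trial")
    trials[[r]] <- trial
  }
  out$trial <- trials
  out
}

#' Generate a complete synthetic study dataset
#'
#' Bundles everything the loading study consumes: a training phantom
#' population (emulating the shape model's source population), participants
#' with stature-linked tibia phantoms, their gait trials per condition, and
#' the muscle set. Reproducible from `(n, seed)` and the generator defaults.
#'
#' @param n_participants number of runners.
#' @param n_training shape-model training population size.
#' @param seed integer RNG seed.
#' @param conditions condition labels.
#' @param effect_spec see [default_effect_spec()].
#' @param height_mean_cm,height_sd_cm participant stature distribution.
#' @param landmark_noise_sd soft-tissue/placement offset SD (mm) applied to
#'   the participants' landmarks (they emulate skin-mounted motion-capture
#'   markers, unlike the exactly digitized training landmarks); default 3.
#' @return list with `training` (population tibble), `participants` (tibble
#'   with phantom mesh/landmarks/spec, height, mass, sex), `trials` (gait
#'   tibble), `muscles`, `conditions`, `seed`.
#' @export
generate_study_dataset <- function(n_participants = 18, n_training = 30, seed = 1,
                                   conditions = c("hRFS", "iRFS", "iFFS"),
                                   effect_spec = default_effect_spec(),
                                   height_mean_cm = 166.4, height_sd_cm = 6.3,
                                   landmark_noise_sd = 3) {
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  sub_seeds <- sample.int(2^30, 4)
  training <- generate_population(n_training, seed = sub_seeds[1])

  withr_seed2 <- .with_seed(sub_seeds[2])
  heights <- stats::rnorm(n_participants, height_mean_cm, height_sd_cm)
  masses <- stats::rnorm(n_participants, 61.6, 6.6)
  sexes <- rep(c("M", "F"), length.out = n_participants)
  withr_seed2()

  ranges <- default_phantom_ranges()
  part_pop <- generate_population(n_participants, seed = sub_seeds[3])
  # tie each participant's phantom length to stature (~2.4 mm per cm)
  for (i in seq_len(n_participants)) {
    sp <- part_pop$spec[[i]]
    sp$length <- 2.4 * heights[i]
    part_pop$spec[[i]] <- sp
    part_pop$mesh[[i]] <- phantom_surface(sp)
    part_pop$landmarks[[i]] <- phantom_landmarks(part_pop$mesh[[i]], sp$nz, sp$nc,
                                                 noise_sd = landmark_noise_sd)
  }
  participants <- tibble::tibble(id = part_pop$id, height_cm = heights,
                                 mass_kg = masses, sex = sexes,
                                 mesh = part_pop$mesh,
                                 landmarks = part_pop$landmarks,
                                 spec = part_pop$spec)
  trials <- generate_gait_trials(participants[, c("id", "mass_kg")],
                                 conditions = conditions,
                                 effect_spec = effect_spec,
                                 seed = sub_seeds[4])
  list(training = training, participants = participants, trials = trials,
       muscles = generate_muscle_set(seed = seed), conditions = conditions,
       seed = seed)
}
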