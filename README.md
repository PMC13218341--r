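# tibload

Internal tibial loading during running, estimated at two levels of model
complexity from sparse-landmark bone reconstructions.

Tibial stress injuries in runners are driven by repetitive internal bone
loading, but participant-specific loading estimates normally require medical
imaging for the bone geometry. `tibload` implements a pipeline that works
without imaging: participant-specific tibia geometry is reconstructed from
the four palpable shank landmarks of routine motion capture (femoral
condyles and malleoli) with a statistical shape model under bounded
principal-component scores, and internal stress and strain are then computed
with both a simplified 2D beam-theory model and a full 3D linear-elastic
finite element model driven by identical loading inputs. The package is
aimed at biomechanics researchers who want to study *relative*,
condition-dependent changes in tibial loading (for example across
foot-strike patterns) when imaging is unavailable.

The core machinery:

* **Statistical shape model** — generalized Procrustes alignment + PCA over
  a corresponding mesh population; reconstruction from landmarks solves

  `min_{pose, b} || pose(L(mean + Phi b)) - y ||^2  s.t.  |b_j| <= k sqrt(lambda_j)`

  by alternating a closed-form Kabsch pose with a bound-constrained
  quadratic score update, plus a linear score-to-score regression that
  predicts the endosteal (trabecular) surface from the cortical fit.
* **Reconstruction accuracy** — voxel-overlap Jaccard index, per-vertex
  surface error, tibial length agreement (Spearman rho, MAE, signed-rank).
* **Muscle forces** — static optimization minimizing the sum of cubed
  muscle stresses `sum_i (f_i / PCSA_i)^3` under joint-moment equality
  constraints, solved exactly through the concave dual (KKT-verified);
  the ankle joint contact force is `F = 0.9 (RF + sum_i f_i d_i)`, the 0.9
  accounting for fibular load sharing.
* **2D beam theory** — distal-third hollow-ellipse section,
  `sigma = N/CSA ± M c / I_ML`, anterior tension positive.
* **3D finite elements** — 4-node tetrahedra on a structured conforming
  mesh, cortical 17 GPa / trabecular 1 GPa, nu = 0.3, fixed proximal
  plateau, uniform distal coupling; pressure-modified von Mises equivalent
  strain, volume-weighted 95th percentile, strained volume above 3000
  microstrain, peak principal stresses, and a <5% mesh-convergence ladder.
* **Statistics** — Friedman tests with Kendall's W (exact small-sample
  null), Wilcoxon signed-rank post hocs with Bonferroni correction (exact
  enumeration for n <= 25), and the per-participant 2D-vs-3D
  percentage-change agreement analysis.

A first-class synthetic-data module generates every input — a tibia phantom
population in point correspondence with 4- and 9-landmark sets, an
11-muscle geometry set, and per-condition stance loading ordered
iFFS > hRFS > iRFS (imposed forefoot / habitual rearfoot / imposed rearfoot
strike) — so the whole pipeline runs, and is tested, end to end without any
external data.

## Worked example

```r
library(tibload)

# a synthetic training population and its shape model
pop <- generate_population(30, seed = 1)
model <- build_ssm(pop$mesh, landmark_nodes = phantom_landmark_nodes(33, 16))
model$lambda[1] / model$total_var
#> [1] 0.908813        # mode 1 is general size, ~91% of variance

# reconstruct a new tibia from its four motion-capture landmarks,
# bounded to +/- 2 SD per mode
target <- generate_population(3, seed = 99)
fit <- fit_landmarks(model, target$landmarks[[1]],
                     marker_config("4-marker"), k_sd = 2)
surface_error(fit$mesh, target$mesh[[1]])
#> # A tibble: 1 × 2
#>   mean_mm max_mm
#> 1    1.41   4.43

# predicted endosteal surface and distal-third section properties
endo <- lapply(pop$spec, function(s) phantom_surface(s, scale = s$endo_frac))
trab_model <- train_trabecular_model(model, pop$mesh, endo)
recon <- ssm_reconstruct(model, fit$scores)
trab <- predict_trabecular(fit$scores, trab_model)
sec <- fit_distal_section(recon, trab)
section_properties(sec)
#> # A tibble: 1 × 3
#>   csa_mm2 I_ml_mm4 I_ap_mm4
#> 1    389.   23952.   18428.

# muscle forces for a 160 N·m plantarflexion demand
muscles <- generate_muscle_set(seed = 1)
sol <- solve_static_optimization(c(ankle = -160), muscles)
head(tidy(sol), 3)
#> # A tibble: 3 × 3
#>   name        force_N stress_MPa
#> 1 soleus        2329.     0.150
#> 2 med_gastroc    668.     0.0977
#> 3 lat_gastroc    213.     0.0663

# distal-third normal stress for a peak load case
beam_normal_stress(axial_force_N = -4400, moment_Nm = 120, sec)
#> # A tibble: 1 × 2
#>   sigma_ant_MPa sigma_post_MPa
#> 1          58.4          -81.1
```

The mean surface error of 1.4 mm says the bounded 4-marker fit recovers
this phantom to millimetre accuracy; the section properties (CSA
~389 mm², I_ML ~24,000 mm⁴) are typical adult distal-third values; and the
beam stresses show the characteristic running pattern of anterior tension
(+58 MPa) with larger posterior compression (−81 MPa).

The two study-level drivers are `run_reconstruction_experiment()` (marker
configurations 9-marker ±3 SD vs 4-marker ±3/±2/±1 SD, with Friedman and
corrected post-hoc statistics) and `run_loading_experiment()` (18 synthetic
participants × 3 foot-strike conditions through both stress models, the
condition statistics, and the 2D-vs-3D agreement analysis). Both are
deterministic given a seed. `plot_condition_outcomes()`,
`autoplot()` on the agreement object, and `plot_convergence()` provide the
standard displays.

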