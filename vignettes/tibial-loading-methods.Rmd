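---
title: "Methods: sparse-landmark tibia reconstruction and two-level internal loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-landmark tibia reconstruction and two-level internal loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tibload` implements a two-level analysis of internal tibial loading during
running. The first level asks a geometric question: how well can
participant-specific tibia geometry be reconstructed from the four palpable
shank landmarks routinely available in motion capture (femoral condyles and
malleoli), compared with an established nine-landmark configuration, when
the reconstruction is driven by a statistical shape model under bounded
principal-component scores? The second level asks a mechanical question:
given identical loading inputs (ankle joint reaction forces plus eleven
muscle forces), do a simplified 2D beam-theory model and a full 3D linear
elastic finite element model agree on how internal tibial stress and strain
change across foot-strike conditions (habitual rearfoot, imposed rearfoot,
imposed forefoot)?

Because no imaging or motion-capture data ship with the package, a
synthetic-data module generates every input with the statistical structure
the analysis assumes. This vignette documents the models, the synthetic
study conditions, the numerical choices, and what the passing test suite
does and does not establish about real data.

## Coordinate convention and units

All modules share a right-handed shank frame: +X anterior, +Y lateral,
+Z proximal along the long axis, coordinates in millimetres. Forces are in
newtons, moments in newton-metres at the user interface, stresses in MPa
(the internal finite element system is mm-N-MPa, so Young's moduli of 17
and 1 GPa enter as 17 000 and 1 000 MPa). Axial force components follow the
biomechanical compression-negative reporting convention; the finite element
loader converts a negative axial component into a proximally directed push
on the distal articular surface.

## The tibia phantom and its population

A phantom (`phantom_spec()`) is a tapered hollow-elliptical shaft with
cosine-blended proximal and distal flares and a sinusoidal anterior bow.
The periosteal cross-section at normalized axial position $t \in [0,1]$
(0 = distal) has semi-axes

$$a(t) = a_0\,[1 + \tau (t - \tfrac13)]\,\phi(t), \qquad
  b(t) = b_0\,[1 + \tau (t - \tfrac13)]\,\phi(t),$$

where $\phi$ blends the end flares over the outer quarters of the shaft and
the taper is anchored at the distal third, so the distal-third section has
known semi-axes $(a_0, b_0)$ exactly. The endosteal surface is the
periosteal one scaled by the endosteal fraction $f$, so the cortical
cross-section is a hollow ellipse by construction and volumes have closed
forms (`1 - f^2` of the section area is cortical).

Population defaults (`default_phantom_ranges()`) were chosen once as
realistic for a young healthy adult training population: lengths follow
stature at 2.4 mm per cm (422.6 ± 27.8 mm, matching a 176.1 ± 11.6 cm
population), and the distal-third defaults $a_0 = 13.8$ mm, $b_0 = 12.3$ mm,
$f = 0.51$ solve the system CSA $= \pi(a_ob_o - a_ib_i) \approx 393$ mm²,
$I_{ML} \approx 23.6\times10^3$ mm⁴, $I_{AP} \approx 18.9\times10^3$ mm⁴ —
typical adult distal-third values. Shape-parameter spreads (flares, bow,
taper, semi-axes) were set so that the first principal component of the
resulting shape model carries roughly 90% of the variance (size-dominated,
as reported for real tibia-fibula shape models) while enough independent
shape variance remains that a four-landmark fit is genuinely
under-determined. The distributional form of inter-individual variation in
real training sets is unknown; independent truncated normals are a free
choice and documented as such.

All phantoms of a population share a node grid (33 axial rings x 16
circumferential points plus two cap centres), so node *i* has the same
parametric location on every phantom: the population is in point
correspondence by construction and landmark node indices are
population-wide constants. Landmarks sit at fixed parametric locations
(condyles and malleoli on the medial/lateral axes of the end rings, the
tuberosity and three anterior-border points on the anterior axis, and a
fibular-head surrogate on the lateral proximal shaft, which keeps the
nine-landmark configuration at full count on a tibia-only phantom).

## Statistical shape model and bounded landmark fitting

`build_ssm()` aligns the training meshes by generalized Procrustes
analysis and extracts principal components of the aligned coordinates.
Alignment is rigid (rotation + translation) by default: size then lives in
the scores, so the first mode captures general size variation, consistent
with published tibia-fibula models; an isotropic-scale switch exists for
users who prefer size-free shape spaces. Modes explaining 99% of variance
are retained (capped at $n-1$), configurable.

`fit_landmarks()` minimizes the sum of squared distances between the posed
model landmarks and the observed landmarks over a rigid pose and the
PC scores, subject to hard box bounds $|b_j| \le k\sqrt{\lambda_j}$
(the "±k SD" reading of principal-component constraints; a Mahalanobis-ball
alternative is documented but not used). The optimizer alternates a
closed-form Kabsch pose with a bound-constrained quadratic score update
(L-BFGS-B on the exact quadratic with analytic gradient), from the
deterministic start b = 0, identity pose, until the objective changes by
less than 1e-9 or 200 alternations. A vanishing Tikhonov term (1e-10)
resolves degenerate landmark sets toward the smallest-norm scores. With
`k_sd = 0` the bounds force b = 0 and the posed mean is returned. The pose
is rigid by default (the same scale switch applies); scores are invariant
to rigid transformation of the observed landmarks to optimizer tolerance.

The endosteal (trabecular) surface is predicted by a least-squares linear
regression from cortical PC scores to endosteal PC scores, trained on
phantoms whose endosteal surfaces are known and expressed in the cortical
model frame. The exact predictors used by published trabecular regressions
are not available; the score-to-score linear map is the documented
substitute.

## Reconstruction metrics

The Jaccard index voxelizes both watertight surfaces on a shared
axis-aligned grid covering the padded union bounding box (default voxel
1 mm) with a ray-parity inside test (fixed sub-voxel jitter; re-jitter on
degenerate edge-on hits), making `J(A,B)` exactly symmetric. Surface error
is the per-vertex absolute Euclidean distance, either between same-index
vertices (correspondence mode, the default when both meshes come from the
model grid) or to the nearest point of the reference surface (exact
point-to-triangle distances, for references from other sources). Before
metrics, the reconstruction is aligned to the reference frame by
landmark-based rigid Procrustes without scaling, so size errors are charged
to the fit rather than absorbed by the alignment.

The distal-third cross-section is cut perpendicular to +Z at one third of
the axial extent from the distal end; periosteal semi-axes are half the
maximal AP and ML extents of the raw cut contour (not a least-squares
ellipse), endosteal likewise, and CSA, $I_{ML}$, $I_{AP}$ follow the
hollow-ellipse closed forms.

## Gait synthesis and processing

Per participant and condition, the generator emits raw 1000 Hz stance
waveforms: vertical ground reaction force, three ankle joint reaction force
components in the shank frame, sagittal ankle and knee moments, and the
foot angle at contact. Waveform peaks scale with body weight, a lognormal
participant strength factor (SD 0.12), multiplicative trial noise (SD
0.05), and per-condition effect scalers
(`default_effect_spec()`): foot-strike angles are drawn from
14.3 ± 4.3° (hRFS), 29.0 ± 5.7° (iRFS), −4.4 ± 4.7° (iFFS); peak ankle
plantarflexion moment scales 1.00 / 0.84 / 1.18, the axial reaction force
1.00 / 0.94 / 1.06, and the anteroposterior shear 1.00 / 0.80 / 1.25, with
a condition-specific stance-timing skew (forefoot loading peaks earlier).
The scalers encode increased plantar-flexor demand under an imposed
forefoot strike, ordering loading iFFS > hRFS > iRFS by construction, and
deliberately scale the load channels non-proportionally: foot strike
reshapes the load vector rather than rescaling it. Participant landmarks
carry an isotropic 3 mm soft-tissue/placement offset (they emulate skin
markers), while training and reconstruction-experiment landmarks are exact
(they emulate image-digitized points).

Processing follows standard practice: a fourth-order zero-lag Butterworth
low-pass (second order passed forward and backward, with endpoint-chord
detrending and mirror padding so constants pass exactly), 10 Hz for
kinematic and 20 Hz for kinetic channels; stance is the maximal contiguous
interval with filtered vertical GRF above 10 N; all channels are linearly
resampled to 101 points (0-100% stance). A rearfoot strike is a contact
angle strictly greater than 8°.

## Muscle forces and the ankle joint contact force

The muscle set is the eleven ankle-crossing muscles spanning the tibia
(triceps surae, deep posterior compartment, peroneals, anterior
compartment) with literature-scale PCSAs, sagittal ankle moment arms, and
unit lines of action that are predominantly compressive (−Z) with small
anterior/posterior components. Static optimization minimizes the sum of
cubed muscle stresses $\sum_i (f_i/\mathrm{PCSA}_i)^3$ subject to joint
moment equality constraints and $f_i \ge 0$. The solver maximizes the
smooth concave dual (per-muscle closed-form primal recovery
$f_i = \mathrm{PCSA}_i^{3/2}\sqrt{s_i/3}$ for positive muscle-side prices
$s_i$, damped Newton on the multipliers with a deterministic bracketing
start and warm starts along the stance series), so KKT stationarity holds
to solver tolerance and equality residuals are verified below
1e-6 x max(1, |M|). No upper force bounds are imposed by default.

Only the sagittal ankle degree of freedom is constrained in the pipeline:
with this muscle set only the biarticular gastrocnemii cross the knee, as
flexors, so a knee equality constraint would be infeasible for the extensor
stance knee moments; resolving the knee properly requires a full-limb
model, which is out of scope. The solver itself is DOF-generic and solves
any named moment set whose signs are feasible, including the knee.

The ankle joint contact force is
$F = (1 - s)\,(RF + \sum_i f_i\,\hat d_i)$ per stance sample and component,
with fibular share $s = 0.1$ (the classical 0.9 tibial scaling), and the
load case is taken at the sample of peak resultant $|F|$ (earliest sample
on ties). The distal-third bending moment about the ML axis is the
quasi-static free body of all distally applied forces,
$M_{ML} = r_z F_{AP} + r_x F_{axial}$ (axial in the compression-negative
convention), with r from the section centroid to the application point;
positive $M_{ML}$ produces anterior tension. Both sign conventions were
pinned against the finite element solver: posterior ankle shear and a
compressive force line posterior to the anteriorly bowed centroid each
produce anterior tension. Loading computations run in the bone's canonical
frame (+Z long axis) — the anatomical shank frame that the reconstruction's
own axes realize — so landmark-noise-induced pose tilt affects accuracy
metrics but not the mechanics.

## 2D beam theory

Anterior/posterior normal stress at the distal-third section superposes
axial and bending parts: $\sigma = N/\mathrm{CSA} \pm M_{ML}\,c/I_{ML}$
with the fiber distance $c = a_o$ (periosteal AP semi-axis) on both
aspects, tension positive. Peak anterior stress is the stance maximum of
the anterior series (it may be negative for an all-compressive series);
peak posterior is the stance minimum. Statistics are run on anterior stress
only; posterior is reported descriptively.

## 3D finite element model

The volume mesh splits the phantom's parametric cells (axial x
circumferential x radial) into tetrahedra: Freudenthal/Kuhn 6-tet splitting
of hexahedral cells with index-space-consistent face diagonals (conforming
across cells including the circumferential wrap) and a 3-tet wedge core at
the section axis. Elements default to 4-node linear tetrahedra; published
workflows often use 10-node quadratic elements in commercial solvers, and
the convergence ladder plus the analytic oracles justify the linear choice
here. Radial stations align with the endosteal interface, so cortical
(17 GPa) and trabecular (1 GPa) labels are exact by construction
(equivalently, by the element-centroid side of the endosteal surface);
Poisson's ratio is 0.3 for both. The proximal plateau is fully fixed and
the ankle joint contact force is distributed equally per node over the
distal articular node set (a uniform distributing coupling, per the
uniform-load-distribution description; not a rigid kinematic coupling).
Element stiffness uses the closed-form constant-strain-tet expression
(verified against a dense $B^TDB$ oracle), the global system is solved by
sparse Cholesky with the factorization reused across a participant's three
conditions, and the relative residual is checked below 1e-8.

Per-element (centroid) strain and stress, sorted principal stresses
(trigonometric closed form for symmetric 3x3 eigenvalues), and the
pressure-modified von Mises equivalent strain are recovered from the
solution. The equivalent strain is

$$\varepsilon_{pm} = c_1 I_1 + \sqrt{(c_1 I_1)^2 + \varepsilon_{vm}^2/\kappa},
  \qquad c_1 = \frac{\kappa - 1}{2\kappa},$$

with $I_1$ the first strain invariant and
$\varepsilon_{vm} = \frac{1}{1+\nu}\sqrt{\tfrac12[(\varepsilon_1-\varepsilon_2)^2
+ (\varepsilon_2-\varepsilon_3)^2 + (\varepsilon_3-\varepsilon_1)^2]}$ the
Poisson-normalized von Mises equivalent strain, so that $\kappa = 1$
reproduces the von Mises strain exactly and a uniaxial stress state yields
exactly $|\varepsilon_{axial}|$. The exact tension-compression asymmetry
constant used by published bone formulations is not restated in the
available sources, so $\kappa$ is exposed in the configuration with default
1 (pure von Mises) rather than guessed.

Summary metrics: strained volume is the total volume of elements whose
equivalent strain exceeds 3000 με (a fatigue-damage-associated threshold);
the 95th percentile is volume-weighted (strain at which cumulative sorted
element volume first reaches 95%) — element-count weighting is the
documented alternative; peak principal tensile/compressive stresses are
extrema over elements outside a fixed exclusion band (default 10% of the
axial extent) adjacent to the constrained and load-introduction faces.
The band is a constant fraction of length rather than one element layer
because the clamped-face stress concentration and the equal-per-node
coupling artifacts do not converge under refinement; a fixed physical band
keeps the extraction domain identical across the ladder (St. Venant
argument). Whether published percentiles and peaks were computed at
integration points, element means or nodes is unstated; element centroids
are used here.

Mesh convergence runs the ladder 5.5, 3.6, 2.7, 2.0 mm coarse to fine and
declares convergence at the first size whose three key metrics (95th
percentile equivalent strain, peak principal tensile and compressive
stress) all change by less than 5% relative to the previous size;
non-convergence yields a report, not an error. For verification problems
the runner also offers roller support and consistent (area-weighted)
loading, which admit exact constant-stress states — the axial-bar ladder is
then identical across sizes to solver tolerance, while the production
boundary conditions intentionally remain those of the study pipeline.

## Statistics

All comparisons are rank-based. The Friedman test uses within-row midranks
with tie correction; Kendall's $W = \chi^2/[n(k-1)]$; the p-value is exact
(full enumeration of within-row permutations) when $(k!)^n \le 10^5$ and
chi-square asymptotic otherwise. A fully tied table returns
$\chi^2 = 0, W = 0, p = 1$ flagged "degenerate" rather than an error.
Wilcoxon signed-rank post hocs drop zero differences (the original rule),
use midranks for tied magnitudes, and compute the exact two-sided
sign-assignment distribution by dynamic programming for $n \le 25$
(tie-corrected normal approximation beyond); Bonferroni correction is
$\min(1, m\,p)$ over the condition pairs. Shapiro-Wilk normality screening
is available as a pass-through descriptive (`group_descriptives(shapiro =
TRUE)`) and drives no branching. Length agreement uses Spearman's rank
correlation, mean absolute error, and the paired signed-rank test. Method
agreement compares per-participant percentage changes
$100(\mathrm{iFFS}-\mathrm{hRFS})/\mathrm{hRFS}$ between the 2D and 3D
models: mean and SD of the absolute between-method difference, and the
fraction of participants with matching signs (directional concordance);
zero baselines yield reported NA rows, never silent drops.

## Study orchestration and problem sizes

`run_reconstruction_experiment()` trains the shape model on 30 phantoms,
fits 20 evaluation phantoms under 9-marker ±3 SD (the reference
configuration) and 4-marker ±3/±2/±1 SD, and compares the three accuracy
metrics across configurations (Friedman + Bonferroni-corrected post hocs,
letter-coded). `run_loading_experiment()` runs 18 participants x 3
conditions with the 4-marker ±2 SD reconstruction (the chosen
configuration), stature screening against the training population
(inclusive mean ± 2 SD bounds), per-sample static optimization over the
101-point stance, and both stress models per condition on identical load
cases (recorded by hash). The loading-study finite element meshes use
3.6 mm elements (about 10^5 linear tetrahedra per participant), one
assembly and factorization per participant; these sizes keep the full
study to a few minutes on one core while the ladder demonstrates metric
stability. Both experiments are bit-reproducible from `(config, seed)`.

## What the synthetic study does and does not show

The generator reproduces the statistical structure the analysis needs:
a size-dominated corresponding shape population, condition-ordered loading
with realistic between-participant spread, skin-marker landmark noise, and
plausible distal-third geometry. Passing tests therefore demonstrate the
correctness of the machinery (fits, solvers, metrics, statistics) and the
qualitative study findings (marker-count ordering of reconstruction
accuracy; iFFS > hRFS > iRFS loading; directional 2D-3D agreement). They
do not establish quantitative accuracy on real tibiae: the phantom family
is smooth and low-dimensional, so absolute Jaccard indices run higher and
surface errors lower than against real anatomy; the linear mode space can
interpolate four exact-length landmarks, so tibial-length agreement is
nearly perfect rather than ~1% off; and because both stress models respond
almost proportionally to the same load cases on fixed per-participant
geometry, the mean absolute 2D-vs-3D percentage-change difference is near
zero, whereas real geometries produce a few percent of between-method
spread. Strained-volume magnitudes are particularly sensitive to the strain
distribution's tail and should be read as condition contrasts, not
absolute volumes. Known limitations beyond these: no heterogeneous
density-mapped materials, no contact, no dynamics, fibular load sharing
only through the 0.9 scalar, and no validation against injury outcomes.
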