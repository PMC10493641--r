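---
title: "Methods: stimulation-site and network mapping for STN-DBS outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulation-site and network mapping for STN-DBS outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-frequency subthalamic deep brain stimulation (STN-DBS) can alleviate,
leave unchanged, or worsen freezing of gait (FOG) in Parkinson's disease,
and a large part of that variability is attributable to *where* within and
around the STN the stimulation field acts and *which* fibre systems and
functional networks it recruits. `stimmap` implements the standard analysis
chain used to answer that question from a cohort of implanted patients:

1. a volume-of-tissue-activated (VTA) model per hemisphere,
2. stimulation-site analysis at three levels — active-contact coordinates,
   VTA overlap with STN subregions, and a voxel-wise probabilistic
   stimulation map (PSM) of "sweet" and "sour" spots,
3. discriminative fibre filtering against a streamline set,
4. a seed-based functional-connectivity R-map against a normative
   connectome, and
5. leave-one-out cross-validation (LOOCV) with covariate adjustment for
   all three predictive models.

Because the individual patient data such a study uses cannot ship with a
package, `stimmap` also contains a first-class synthetic-cohort generator
with *planted* ground truth — known beneficial and detrimental stimulation
sites and known positive and negative fibre bundles — so that the entire
chain can be validated against what was planted.

## Outcome scale

The clinical outcome is the percent change of the Freezing of Gait
Questionnaire total, `%change = (pre - post) / pre * 100`, positive for
improvement. Patients are grouped as *alleviation* (> 30%), *minor*
(0-30%, boundaries included) and *deterioration* (< 0%). The boundary
assignment to the middle class follows from reading "below 0" as strict
deterioration and "> 30%" as strict improvement.

## The VTA model

The electric potential around the active contact is modelled
quasi-statically: `div(sigma grad phi) = 0` on a voxel grid, discretised
with the standard 7-point finite-difference stencil and harmonic-mean face
conductances. The volume conductor has four compartments: grey matter
(0.33 S/m), white matter (0.14 S/m), electrode contacts (1e8 S/m) and
insulated shaft (1e-8 S/m). Stimulation is treated as monopolar and
cathodic: the active-contact voxels carry a Dirichlet condition at the
programmed amplitude. Pulse width and frequency are carried as metadata
but do not enter the field model, which is amplitude-driven at a fixed
activation threshold.

Two boundary conditions are available:

* `grounded` (default): `phi = 0` on the grid boundary, the
  case-as-ground monopolar return. The box half-width (default 6 mm
  around the active contact) therefore acts as the return-electrode
  distance; VTA volumes depend mildly on it, which is why the margin is a
  configuration value held fixed across a study.
* `open`: a radiation condition matching `1/r` decay, used when the
  solution is to be compared against the infinite-medium analytic
  monopole `c/r` (the grounded solution is `A(1/r - 1/R)` and deviates
  from `c/r` by construction at any finite box size).

The linear operator is scaled by amplitude, so the unit problem is solved
once and rescaled; zero amplitude short-circuits to a zero field, doubling
the amplitude exactly doubles the potential, and VTA masks are nested in
amplitude by construction. The symmetric system is Jacobi-scaled before
sparse Cholesky factorisation, which keeps the solve stable under the
16-orders-of-magnitude conductivity contrast; the relative residual of the
scaled system must be below 1e-8 or the solve errors out.

The binary VTA is the set of voxels where the central-difference field
magnitude reaches 0.2 V/mm. Contact voxels are selected with a half-open
axial span so the discrete source tiles the 1.5 mm contact length exactly
at any resolution; without this the effective source (and the VTA) grows
by one voxel slab per axial end as the grid is refined, which is what the
discretisation-stability test guards (halving the default 0.5 mm voxel
changes the VTA volume by about 9%).

Each hemisphere is solved on a lead-local 0.5 mm grid (half-width 6 mm)
and the mask is resampled onto the shared 1 mm analysis grid for group
statistics. A single common space is used throughout; the native-to-
template transport of a clinical pipeline is out of scope by design.

Default contact geometry is a quadripolar lead with 1.5 mm contacts,
0.5 mm spacing and 0.635 mm radius, configurable via `default_lead_spec()`.

## The synthetic study

`make_toy_atlas()` builds a mirror-symmetric template-like space: two
ellipsoidal STNs (semi-axes 5.5/3/4 mm) whose long axes run dorsolateral
to ventromedial, partitioned along that axis into sensorimotor (50%),
associative (30%) and limbic (20%) subregions, plus one "SMA-like" and one
"PFC-like" spherical grey-matter parcel per side as network targets.

`default_ground_truth()` plants, per side and mirror-symmetrically:

* a **sweet sphere** (radius 2.5 mm) 3 mm dorsolateral of the STN centre,
  gain +1.2 %/mm^3 of VTA overlap;
* a **sour sphere** (radius 2.5 mm) 3 mm ventromedial, gain -0.8 %/mm^3;
* a **positive bundle effect** of +15% and a **negative bundle effect**
  of -15%, scaled by the fraction of the corresponding planted bundle the
  patient's VTAs touch;
* outcome noise with SD 40 on the percent-change scale.

`sample_cohort()` draws 76 bilateral patients: lead tips jittered
(SD 1.5 mm) around a target 3.75 mm below each STN centre so the four
contacts straddle the nucleus dorsoventrally; the active contact is drawn
with dorsally biased probabilities (0.10/0.20/0.35/0.35), reflecting that
clinical titration tends to settle on dorsal contacts; amplitudes, pulse
widths and frequencies come from truncated normals matching the cohort
summary scale (about 2.4 +/- 0.55 V, 68-70 +/- 11 us, 131 +/- 21 Hz with
the >= 90 Hz high-frequency inclusion rule). Baseline questionnaire
totals are drawn from 10-24 and the post-operative total is the rounded,
clipped image of the latent percent change, so realised outcomes inherit
the questionnaire's discreteness and the [-100, 100] clipping of the
percent scale.

These values were calibrated once, on the generator alone, to land the
realised cohort on the clinical outcome scale (mean percent change about
+25 to +30, SD about 44, alleviation/minor/deterioration roughly 33/19/24
at the default seed) while keeping the planted spatial effect recoverable
(sweet-overlap rank correlation with outcome about 0.6, variance explained
about 0.4). They were not revisited afterwards.

`make_synthetic_streamlines()` plants two *coherent* bundles — tubes of
500 fibres entering the STN at the planted sphere centres (0.6 mm entry
scatter) and arcing to the SMA-like and PFC-like parcels respectively —
plus 19 000 tortuous correlated random walks confined to the atlas box as
distractors. Bundle membership is recorded as ground-truth labels.
`make_synthetic_functional_connectome()` builds per-subject voxel time
series (default 20 subjects x 200 time points on a 2 mm grid) as two
shared low-rank networks — one loading on the SMA-like parcels plus the
sensorimotor STN, one on the PFC-like parcels plus the limbic STN — in
white noise.

What the generator does **not** emulate: registration error, anatomical
lead trajectories (leads are vertical), realistic fibre geometry beyond
the two planted tubes, scanner noise structure, or item-level
questionnaire behaviour. Passing tests therefore demonstrate that the
analysis recovers known effects under idealised geometry, not that it is
robust to the registration and reconstruction errors of clinical data.

## Mapping-level statistics

A patient's coverage is the union of the left and right VTA masks on the
analysis grid (the bilateral-union choice also defines fibre and seed
connectivity). Voxels covered by fewer than `ceiling(0.2 * n)` patients
are excluded (16 of 76); the ceiling resolves the ambiguity in "a minimum
of 20%". Per eligible voxel the PSM carries the mean percent change of
the covering patients, masked at voxel-wise uncorrected p < 0.05 from a
two-tailed nonparametric rank test comparing covered against non-covered
patients' outcomes.

That per-voxel test deserves a note: the source method names a signed-rank
test for what is an unpaired two-group comparison at every voxel. A
signed-rank test is paired and cannot apply as written, so the default
here is the unpaired Mann-Whitney rank-sum test (exact for combined
n <= 20 without ties, normal approximation with tie and continuity
corrections otherwise — matching `wilcox.test`), with a one-sample
signed-rank-versus-grand-median variant available behind
`psm_voxel_test(method = "signedrank")` for sensitivity analysis.

No voxel-wise multiple-testing correction is applied inside the PSM —
the map is a descriptive model whose validity is assessed by LOOCV, not
by voxel-level inference. Null calibration is checked instead: with
permuted outcomes the fraction of eligible voxels below p = 0.05 must sit
near the nominal level (the acceptance suite requires the 20-replicate
mean within [0.02, 0.10]).

Positive surviving voxels form the sweet spot, negative the sour spot;
cluster centroids weight voxel coordinates by the absolute retained mean
effect, peaks take the extreme voxel with ties broken by the first voxel
in column-major order. A patient's *probabilistic mapping score* is the
sum of retained mean-effect values over the voxels their VTAs cover.

## Fibre filtering

Streamlines are resampled at 0.5 mm arc-length steps (halving the step
changes under 1% of connectivity entries); a fibre connects to a patient
when any resampled point falls in the bilateral VTA union. Fibres
connected to fewer than `ceiling(0.2 * n)` patients are dropped. Each
retained fibre gets a pooled-variance two-sample t score contrasting
outcomes of connected against unconnected patients (Welch behind a
switch; pooled is the convention of the era's toolboxes), positive when
connected patients improve more. The patient-level prediction is the mean
T over the patient's connected retained fibres (sum and weighted variants
provided); the source never states its aggregation rule, and the mean is
the scale-stable choice.

A caveat the synthetic experiments make explicit: per-fibre T scores are
*patient-mediated*. Any fibre whose connected patient set resembles the
planted bundle's — for example a random walker that happens to thread the
sweet zone — receives a similar score, so the upper tail of the
distractor T distribution approaches the bundle's own scores. Bundle
recovery is therefore assessed by the bundle mean being strongly positive
and by LOOCV prediction, while the tail comparison against distractors is
reported for what it is: a selection-effect-limited bound.

## Functional R-map

The bilateral VTA union seeds each normative subject's time series; the
seed mean is correlated with every voxel, r is clipped to +/-(1 - 1e-6),
Fisher z-transformed and averaged over subjects. Across patients, each
voxel's z value is correlated with the percent outcome change — by rank
(Spearman) by default, consistent with how effect sizes are reported
throughout, with Pearson switchable. Voxels with constant or missing
values across patients are flagged invalid rather than zero-filled. The
LOOCV prediction for a held-out patient is the spatial Pearson
correlation between their z-map and the training R-map over valid voxels
(the similarity rule is unstated in the source; spatial correlation is
the field's default).

## Validation machinery

`loocv()` refits the supplied model n times, predicts each held-out
patient, and Spearman-correlates predictions with observed outcomes. Two
null-behaviour facts the permutation tests account for: a permuted
training set whose PSM retains no voxels predicts a constant, leaving the
validation correlation undefined — which is evidence of *no* signal, and
is counted as a non-significant validation; and leave-one-out validation
is mildly pessimistic under the null (the held-out outcome anti-correlates
with the training outcomes when permuting without replacement; measured
null mean similarity-correlation about -0.15 for the functional model), so
the calibration check is that no spurious *positive* predictive signal
appears. The
reported p is one-sided positive by default — a predictive map is only
meaningful if it predicts in the stated direction — with the two-sided
value available. Covariate adjustment residualises both prediction and
outcome on sex, disease duration, pre-operative MoCA, HAM-A, HAM-D, LEDD
reduction and UPDRS-III percent change by least squares and
rank-correlates the residuals; the source names a GLM with these
covariates but reports Spearman R, and double residualisation is the
composition that honours both. A variable fully explained by the
covariates has, by convention, adjusted correlation 0. Rank-deficient
covariate designs are refused with the collinear columns named.

`spearman()` uses tie-corrected mid-ranks; p-values are exact by full
permutation enumeration up to n = 8 (40 320 permutations; beyond that the
enumeration cost outweighs the accuracy gain over the t approximation,
which is what is used for the cohort-scale tests at n = 76). Bonferroni
adjustment is `min(1, m p)` with the family size stated at each call
site (6 for coordinate correlations: 3 axes x 2 hemispheres; 3 per
hemisphere for subgroup contrasts; the region count for overlap
correlations).

## Numerical and design notes

* Voxel indices are 0-based internally; every user-facing coordinate is
  world mm through the image affine. Loaders refuse mismatched grids
  rather than resampling silently; the deliberate exception is
  atlas-label lookup at solve-grid voxel centres, which is a documented
  nearest-neighbour sample across resolutions in the same world space.
* All randomness flows from one master seed; stage seeds are fixed
  offsets of it, and identical configurations reproduce every artifact
  bit for bit (the provenance record stores MD5 hashes to check this).
* Problem sizes used by the validation suite: 48^3 atlas at 1 mm, VTA
  solves on 25^3 lead-local grids at 0.5 mm, 20 000 streamlines, a 24^3
  connectome at 2 mm with 20 subjects x 200 time points, and 20-replicate
  permutation nulls evaluated on a 2 mm analysis grid.
* Degenerate inputs are contracts, not surprises: empty seeds error;
  constant coordinate axes, zero-variance overlaps and constant outcomes
  yield missing correlations with warnings; voxels with an empty
  comparison group get p = 1; infinite t under zero pooled variance is
  capped at 1e6 with a warning, or 0 when the means agree.

## Known limitations

The field model is isotropic and monopolar (no DTI-derived conductivity
tensors, no bipolar configurations, no charge-balanced waveform model);
the VTA threshold is not adjusted for pulse width; the synthetic space is
a single common grid, so cross-space transport error is untested; and the
planted-effect design makes spatial and network effects collinear by
construction (they are in the brain too, but the degree here is chosen,
not measured).
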