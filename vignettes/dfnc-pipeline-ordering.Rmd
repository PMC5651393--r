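---
title: "Methods: preprocessing order and dynamic connectivity in dfncpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing order and dynamic connectivity in dfncpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic validation does — and does
not — establish about real data.

## The analysis in one paragraph

Resting-state fMRI runs (5 minutes at TR = 2 s; 150 frames of which the
first 5 are discarded) are preprocessed through one of four step orderings
(PA–PD) that differ only in *where* spike regression and motion regression
happen relative to group spatial ICA. The cleaned component time courses are
converted to dynamic functional network connectivity (dFNC): tapered
sliding-window Pearson correlations between all component pairs, clustered
by L1-norm k-means into recurring whole-brain "states". Each subject is
summarised by state occupancy rates and per-state mean connectivity
vectors; groups (healthy controls vs. mild traumatic brain injury) are
compared by occupancy t-tests, pipelines by MANOVA/ANOVA and covariate
|β| strengths, and finally a covariate-adjusted linear least-squares SVM
with nested double leave-one-out cross-validation selects, per held-out
subject, the best of the 108 analysis configurations
(4 pipelines × 3 spike thresholds × 3 model orders × 3 window widths).

## The synthetic-data model

Real cohorts of this kind are not publicly deposited, so the package ships a
generator whose defaults encode the study design it emulates:

* **Design**: `n_pairs = 50` age/gender-matched HC/mTBI pairs;
  `n_frames = 150` at `tr_s = 2` (5-minute runs); ages N(28, 9²) truncated
  at 18; gender balanced. These are cosmetic except for the matched-pair
  structure, which the outlier-exclusion rule needs.
* **Sources**: `n_sources = 5` smooth Gaussian blobs on a small
  (`grid_shape = 8x8x8`) voxel grid, resampled until all pairwise spatial
  correlations are below 0.3 so spatial ICA is identifiable at desk scale.
* **States**: source time courses switch between two planted correlation
  matrices — a *segregated* state (two strongly intra-connected,
  anti-correlated blocks) and an *integrated* state (cross-block coupling).
  Couplings are shrunk automatically until both matrices are positive
  semi-definite with margin. Within-state series are built by empirically
  whitening a temporally smoothed Gaussian series and colouring it with the
  state matrix, so in the single-state, noise-free limit the *sample*
  correlation equals the planted matrix exactly — which is what the
  noise-free unit tests assert.
* **State dynamics**: a semi-Markov chain with geometric dwell times. The
  mean dwell is proportional to the target occupancy per state and the
  embedded jump chain is uniform, so long-run occupancy matches
  `occupancy_by_group` (default HC 60/40 vs mTBI 40/60 — a 20-point planted
  group difference) in expectation. The default `dwell_mean_tr = 25` was
  chosen once, as a dwell comparable to the sliding-window lengths in use
  (15–45 TR): much shorter dwells cannot be resolved by a 33-frame tapered
  window, much longer ones leave too few state visits in a 145-frame run
  for occupancy statistics to be stable. Real state dwell-time distributions
  are not characterised by the emulated study; geometric dwell is an
  assumption.
* **Motion**: six realignment parameters as smoothed random walks with
  occasional jumps, linear in `motion_amp_mm` (default 0.25 mm; rotations
  scaled 0.02 rad per mm). Motion couples into the signal as a rank-1
  additive term — a fixed spatial gradient map times the frame-wise
  translation magnitude, scaled by `motion_coupling` — so nuisance
  regression has something real, and not perfectly linear in the
  regressors, to remove.
* **Spikes**: Poisson-count global intensity deviations
  (`spike_rate_per_min = 0.5`, amplitude 5 per-voxel SDs, random sign),
  never at frame 1.
* **Noise**: i.i.d. Gaussian, `noise_sd = 0.4` against unit-SD sources and
  a baseline intensity of 100 (needed because DVARS works on percent signal
  change).

Everything is deterministic given `seed`; each subject and stage draws from
a derived substream.

## Preprocessing: definitions and numerical choices

* **DVARS** is computed on the series scaled to percent signal change about
  each voxel's temporal mean (the convention of the method's originators);
  a frame is a spike when the z-score of its DVARS value against the whole
  trace's mean/SD exceeds the threshold. Z-scoring is single-pass (already
  flagged frames are not excluded and the detection is not iterated) — the
  simplest reading of "standard deviations" — so very high spike densities
  inflate the reference SD and saturate detection; at the default planted
  rates this does not occur. Frame 1 has no backward difference and is
  never flagged, and spike sets are nested across thresholds by
  construction.
* **Nuisance regression** is ordinary least squares with an intercept,
  applied voxel-wise before gICA and component-wise after; residuals are
  orthogonal to every regressor column to 1e-8 (relative). Trends use
  orthogonal polynomials (degree 1–3); motion derivatives are backward
  differences with 0 at frame 1; each spike contributes a unit indicator
  column. Rank-deficient designs fall back to the SVD pseudo-inverse with a
  warning.
* **Smoothing** is separable 3D Gaussian convolution with
  σ_vox = FWHM/(voxel·2√(2 ln 2)) and half-sample-symmetric (reflective)
  boundaries, which leaves constant frames untouched and preserves frame
  means.
* **Spike interpolation** fits a cubic spline (Forsythe–Malcolm–Moler end
  conditions, so exact on cubics) through non-spike frames; boundary spikes
  outside the valid span take the nearest valid value, with a warning.
* **Band-pass filtering** applies the 5th-order Butterworth 0.01–0.15 Hz
  design with zero phase by multiplying the spectrum of the demeaned,
  symmetrically extended series with |H(ω)|² — exactly the forward-backward
  (filtfilt) response. The time-domain forward-backward recursion was
  rejected deliberately: with a 0.01 Hz band edge its startup transients
  span most of a 145-frame run. Zero phase matters here because phase
  shifts would displace state transitions relative to the planted truth.
* **Orderings**: the four step plans are fixed data
  (`pipeline_plans()`); no other ordering is constructible through the
  public interface. All frame indices are 1-based.

## Group ICA and stability

The gICA stage reduces each subject by temporal PCA (to 1.5× the model
order), concatenates, reduces again to the model order, and runs fixed-point
spatial ICA (tanh contrast, symmetric decorrelation) from `n_runs` seeded
starts. This is a deliberate divergence from the Infomax/GIFT
implementation the emulated study used: the downstream analysis depends
only on obtaining stable independent spatial sources, and the fixed-point
iteration is deterministic given a seed, which the test suite requires.
Components are clustered across runs by absolute spatial correlation
(average-linkage); each cluster's centrotype becomes an aggregate map. The
quality index Iq is the average within-cluster minus between-cluster
similarity; the R-index is the mean, over clusters, of within-cluster
dissimilarity divided by the dissimilarity to the nearest other cluster (the
cited stability literature gives the idea but no closed formula; this ratio
form is implemented and documented as the package's choice). Model-order
selection keeps candidates with at most 2 components below Iq 0.7 and takes
the one within 5% of the minimal R-index, ties to the smaller order.

Maps are sign-fixed (positive skewness) and z-scored; subject time courses
come from spatial (dual) regression on the aggregate maps. Artifact
flagging reduces the frequency-content criterion to one number — the
fraction of time-course power below 0.10 Hz, pooled across subjects — with
components below `theta_lf = 0.5` labelled artifacts. The default is the
package's own operating point (a flat spectrum at TR = 2 s gives 0.4, a
hemodynamic component well above 0.8); the emulated study's exact
parameters are not restated anywhere, and manual expert review is out of
scope.

Because ICA component order and sign are arbitrary, connectivity pairs are
only comparable across pipelines after `align_components()` (optimal
assignment on |spatial correlation|, with sign flips propagated to the time
courses). `run_all()` aligns every configuration to the first.

## dFNC states

Window weights are a rectangle of the window width convolved with a
Gaussian (σ = 3 TR, support ±3σ), normalised to sum 1; windows slide in
1-TR steps, giving frames − support + 1 windows. Correlations are
taper-weighted Pearson; zero-variance components inside a window yield 0
with a warning, and values are clipped to [−1, 1]. Correlations are
clustered raw (no Fisher z, no covariance regularisation), pooling windows
across subjects.

k-means uses L1 distance with median centroid updates (the objective is
non-increasing per iteration, asserted in tests); empty clusters are
re-seeded at the farthest window; the best of `restarts` seeded random
initialisations wins. The elbow rule computes the within-cluster dispersion
curve anchored at k = 1 (dispersion about the global median — no clustering
needed) and returns the k of maximum discrete curvature; the anchor lets
the smallest candidate k itself be an elbow, which matters when only two
states exist. A within/between validity curve is returned for inspection.
Flat curves return the smallest k with a warning.

## Statistics

Occupancy rates (% of a subject's windows per state; rows sum to 100) are
compared by unpaired t-tests (mTBI − HC) per state and paired t-tests
between states within group; degenerate variances report t = 0, p = 1 with
a warning. The pipeline MANOVA fits `stats::manova` per state and reports
Wilks' λ with the Bartlett χ² approximation,
χ² = −(n − 1 − (p + g)/2)·log λ on p(g − 1) df; singular within-group SSP
matrices are ridge-shrunk (1e-8 of the mean diagonal) with a warning.
Per-edge ANOVAs call the classical equal-variance one-way test. Covariate
strength fits per-edge OLS on diagnosis, gender, age, TRN, ROT and spike
count (continuous covariates standardised) and compares per-edge |β|
distributions across pipelines by ANOVA. ROT stays in radians (no
sphere-radius conversion), and second-level tests are reported uncorrected
by default with Benjamini–Hochberg available via `p.adjust` on the returned
tables — matching how such second-level summaries are usually reported.

The outlier rule treats {TRN, ROT, spike count} as the "displacement
measures": subjects above mean + 3 SD on at least two of them are excluded
together with their matched pair partners.

## Classification

Features are the concatenated per-state mean dFNC vectors; occupancy rates
can be appended (`include_occupancy`, on by default in `run_all()` — in the
synthetic design the group difference lives in occupancy, so purely
state-conditional means carry little signal). Missing state means are
imputed to the cohort mean and flagged. Covariates (all but diagnosis) are
regressed out per feature; inside the nested loop this adjustment is refit
on each outer training fold and applied to the held-out subject, so no
statistic ever sees the held-out subject (asserted by a perturbation test).

The least-squares SVM solves the dual KKT system of
min ‖w‖²/2 + C·Σeᵢ² s.t. yᵢ(w·xᵢ + b) = 1 − eᵢ exactly (one linear solve;
C = 0.01). AUC uses midranks. The nested double LOOCV scores every
configuration by an inner LOOCV on the n−1 remaining subjects, picks the
max-AUC configuration (ties broken by enumeration order — first wins),
trains it on the n−1 and classifies the held-out subject; the
subjects × configurations grid of inner AUCs is kept. The "null model" for
configuration mean AUCs is realised as label permutation (a common
permutation per replicate, every configuration re-scored), with the 95th
percentile of the pooled null as threshold. Note that leave-one-out AUC is
pessimistically biased under the null (the held-out subject's class is
always underrepresented in training), so null distributions centre below
0.5; the permutation threshold accounts for this automatically, which is a
reason to prefer it over a fixed 0.5 reference.

## What the synthetic validation shows — and what it does not

The test suite verifies, at desk scale (grids of 6³–8³ voxels, 5 sources,
2 states, 16–48 subjects, 60–150 frames — sizes chosen so the full suite
runs in minutes on one CPU):

* exact structural counts (108 configurations, 406 pairs at 29 components,
  145 retained frames, 96 retained subjects, subjects × configurations AUC
  grid entries);
* analytic oracles (hand-solved SVM KKT system, closed-form ANOVA F,
  hand-summed displacement, closed-form Gaussian kernels, filter frequency
  response);
* recovery of planted structure: ICA maps at |r| > 0.95 from clean
  mixtures, elbow selection of the planted k through the full pipeline,
  group occupancy within 10 points through the state-analysis stage, and
  ≥90% detection of the planted 20-point occupancy difference over 20
  seeded replicates;
* the pipeline-ordering contrast: under strong motion coupling
  (amplitude 1 mm, coupling 3 — conditions where motion variance rivals the
  sources), the mean nested inner AUC of the motion-regression-before-ICA
  orderings (PA/PB) is at least that of PC/PD as a trend over 10 seeds.
  This is asserted as a trend, not per seed: at 32 subjects the per-seed
  AUC contrast is noisy.

None of this certifies behaviour on real fMRI: the generator has no
scanner physics, no spatially structured noise, no slice-timing or
susceptibility artifacts, sources are compact Gaussian blobs rather than
cortical networks, and the occupancy-recovery bound is established for the
state-analysis stage driven by the planted source dynamics — through the
full gICA path, imperfect unmixing adds a systematic bias toward the
integrated state (mixed time courses inflate positive cross-correlations)
that is visible even at desk scale and would require more voxels per
source to shrink.

## Known limitations

* Single-pass DVARS saturates at very high spike densities.
* The elbow rule, like all elbow rules, is a heuristic; the validity curve
  is returned so users can inspect it.
* The R-index and the artifact threshold are package operating points, not
  reproductions of any published parameterisation.
* Nested LOOCV over many configurations is O(n² · configs · n³) in the
  worst case; at the full 96 × 108 scale it is a batch job, not an
  interactive one.
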