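---
title: "Physiology-based regularization of the inverse problem of electrocardiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiology-based regularization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electrocardiographic imaging (ECGI) reconstructs the electrical activity of
the heart surface from body-surface potential recordings. Under quasi-static
assumptions, potentials on a closed surface around the heart (the epicardium)
determine the potentials everywhere in the source-free volume between heart
and torso, giving the linear forward relation

$$\Phi_B(t) = A\,\Phi_H(t),$$

where $\Phi_H(t)$ are the $n$ epicardial node potentials at instant $t$,
$\Phi_B(t)$ the $m$ electrode potentials, and $A$ the $m \times n$ transfer
matrix determined by geometry and conductivity alone. Inverting this relation
is severely ill-posed: the volume conductor attenuates a spatial harmonic of
degree $l$ on the heart surface roughly like $(r_H/r_B)^{l+1}$, so fine
spatial detail is buried under sensor noise and regularization is mandatory.

Two regularization families are implemented:

* **Tikhonov** (`ecgi_reconstruct(..., method = "tikhonov")`), the classical
  baseline: per instant,
  $\min_{\Phi_H} \|A\Phi_H - \Phi_B\|_2^2 + \lambda(t)\,\|R\,\Phi_H\|_2^2$,
  with $R$ the identity (order 0), an edge-difference gradient (order 1) or
  the umbrella graph Laplacian (order 2), and $\lambda(t)$ chosen per instant
  at the corner of the L-curve. The weight multiplies the squared seminorm
  directly; a $\lambda^2$ convention can be emulated by squaring the supplied
  weight.
* **Physiology-based regularization (PBR)**
  (`ecgi_reconstruct(..., method = "pbr")`): propagating action potentials
  are *simulated* on the patient (here: phantom) heart geometry from many
  pacing origins; the simulated patterns, concatenated into one
  nodes-by-(beats × samples) matrix, are decomposed as $\Phi_H = UDV^T$, and
  a truncated set of spatial components $U_k$ serves as the solution basis.
  Per instant the coefficients solve the budget-form Lasso
  $\min_\beta \|A U_k \beta - \Phi_B(t)\|_2^2$ subject to
  $\|\beta\|_1 \le \lambda(t)$, and $\hat\Phi_H(t) = U_k\,\beta(t)$. The
  L1 budget keeps the reconstruction a sparse mix of physiologically
  plausible patterns.

## Forward model and its oracle

The transfer matrix is computed by a boundary-element method: vertex
collocation with piecewise-constant elements weighted by barycentric dual
areas, on two closed triangulated surfaces, with zero normal flux on the
torso. The singular double-layer diagonal is fixed by the solid-angle row-sum
identity, which makes "constant in, constant out" exact by construction —
every row of $A$ sums to 1 to solver precision, a property the tests assert
on every phantom.

Because the phantom heart and torso are concentric spheres (the torso
optionally an ellipsoid), the forward solution is known in closed form: a
degree-$l$ spherical harmonic prescribed on the inner sphere of radius $a$
appears on the outer sphere of radius $b$ attenuated by
$(2l+1)a^{l+1}b^l / \big((l+1)a^{2l+1} + l\,b^{2l+1}\big)$
(`analytic_spheres_attenuation()`). At the mesh sizes used in the tests
(642 heart / 812 torso nodes) the BEM reproduces degree-1 and degree-2
patterns within about 1%, and the error decreases under refinement.

## Simulated propagation

Each heart-mesh vertex carries a single-cell action-potential model; vertices
connected by a triangulation edge of length $d$ exchange current
$I = (\bar g / d^2)\,\Delta V$. Conduction is homogeneous and isotropic. Two
cell models are provided:

* **FitzHugh–Nagumo** with
  $\dot v = c\,(v - v^3/3 - w) + I$, $\dot w = c\,\varepsilon\,(v + \beta_0 - \gamma w)$,
  $c = 0.4\,\mathrm{ms}^{-1}$, $\varepsilon = 0.0125$, $\beta_0 = 0.7$,
  $\gamma = 0.8$. The two-timescale split gives an upstroke of a few
  milliseconds and an action-potential duration near 150 ms. The resting
  state is the exact real root of the nullcline system (computed by
  `polyroot`), and the dimensionless voltage is mapped affinely so that rest
  is exactly −80 mV and the canonical single-cell peak +20 mV. This makes the
  first SVD component of any beat ensemble a near-constant negative pattern
  (the resting offset), cleanly separable from the propagation patterns.
* **Luo–Rudy 1991**, the eight-variable guinea-pig ventricular model, natively
  in mV. Its resting state is computed as an exact equilibrium by nested
  root-finding (gates at steady state, calcium from its balance equation,
  voltage from zero total current), landing near −84.5 mV.

Integration is explicit — forward Euler for FHN, a Rush–Larsen/forward-Euler
hybrid for the LR gates — on a substep grid finer than the 1 ms output
sampling. The substep count is raised automatically when strong coupling
would violate the explicit stability bound (the coupling operator's spectral
radius is bounded by twice its largest row sum).

The coupling strength $\bar g$ is not taken from any reference; it is
*calibrated* (`calibrate_gbar()`): log-scale bisection until the spread
between first and last nodal activation of a paced beat lies in 60–100 ms,
the range that produces, in order, a propagating activation front, fully
activated ventricles, a recovery wave and fully recovered ventricles within a
550-sample beat. A stimulus of 2 ms is delivered at the origin vertex and its
1-ring (single-vertex stimuli can fail to capture on coarse meshes).

Beat origins are sampled pseudo-randomly within geometric regions of the
phantom epicardium — LV free wall, RV free wall, and base/apex polar caps
(top 20% / bottom 10% of the axial extent) — with a minimum pairwise spacing
(greedy rejection sampling) so that origins are roughly uniform. Fifty
origins per region is the default ensemble; a single beat is simulated per
origin.

## Basis construction

Beats are concatenated and decomposed by SVD. The decomposition runs through
the Gram matrix of the node dimension ($\Phi_H \Phi_H^T$, accumulated beat by
beat), so the 812 × 41 250 default ensemble never needs to be held as one
dense matrix and the right singular vectors (a temporal basis, diagnostic
only) are computed only on request. Singular-vector signs are fixed by making
each column's largest-magnitude entry positive, so results are reproducible
across linear-algebra backends. A consequence of the Gram route is a noise
floor near $\sqrt{\epsilon}\,\sigma_1$ on the smallest singular values; the
rank used to validate truncation ranges uses a $10^{-7}\sigma_1$ threshold.

The default basis keeps components 2–10 (nine vectors): component 1 is the
resting-offset pattern, which has no role when zero-mean electrograms are
reconstructed. Dropping it is exposed as configuration (`components`) for
models without a fixed offset.

## Per-instant inverse solves

Tikhonov solutions use the normal equations, or an SVD filter-factor fast
path for order 0 that evaluates the whole L-curve grid for all instants with
a few matrix products. The L-curve corner is the maximum of the discrete
signed curvature of (log residual, log seminorm) over a 40-point grid
spanning $[10^{-8}, 10^{2}]\,\sigma_1(A)^2$; a flat curve falls back to the
smallest weight with a warning.

The budget-form Lasso is solved by the LARS homotopy with the lasso
modification: the solution path is piecewise linear in the budget, so the
constrained solution at any budget is obtained exactly by interpolating
between path knots (the tests verify coefficient-wise agreement with an
independent projected-gradient minimizer). The per-instant budget is chosen
by K-fold cross-validation across electrodes (rows of $AU_k$), minimizing
held-out squared error over a 40-point log grid scaled to the L1 norm of the
least-squares solution — the resampling scheme behind "mean-square-error
minimizing" selection is not prescribed anywhere, and electrode-wise
cross-validation is this package's choice.

Body potentials are re-referenced to zero mean across electrodes per instant
before inversion (the constant component is unobservable up to reference;
`rereference = FALSE` disables). Because recorded body-surface potentials are
always band-limited, the benchmark low-pass filters the synthetic recordings
with a 5-sample centered moving average before inversion
(`smooth_body_potentials()`, `filter_window` in the configuration); with
white 30 dB sensor noise at 1 ms sampling this stabilizes the per-instant
support of the Lasso solution substantially.

## Activation and recovery mapping

Two criteria are implemented. The *temporal-only* criterion marks activation
at the steepest downslope within the QRS window and recovery at the steepest
upslope within the T-wave window (forward differences, value assigned to the
earlier sample, ties to the earliest instant). The *spatiotemporal* criterion
multiplies the node's spatial gradient magnitude (per-triangle linear
gradients averaged onto vertices by area weights — exact annihilation of
constants) with its temporal derivative and takes the extremum of the product
over the window; nodes whose spatial gradient never rises above $10^{-6}$ of
the global maximum fall back to the temporal estimate and are flagged.

Two practical options matter for noisy reconstructions and are off by
default, preserving the plain printed criteria: `smooth_window` replaces the
forward difference by a centered local-linear (Savitzky-style) derivative
estimate, and `interpolate` refines the extremum to sub-sample precision by
parabolic interpolation. The benchmark applies both (window 9) to
reconstructed potentials — per-instant sparse solutions change support
between adjacent samples, and the resulting single-sample jumps otherwise
dominate slope-based timing — while ground-truth timings use the unsmoothed
criteria.

**Polarity.** The printed criteria describe extracellular electrograms, which
deflect *downward* as a wavefront passes. The phantom's ground truth consists
of simulated action potentials, which deflect *upward* at activation. All
timing functions therefore take `polarity = "electrogram"` (default) or
`"ap"` (both criteria sign-mirrored); the benchmark uses `"ap"` consistently
for ground truth and reconstructions.

QRS and T-wave windows are estimated from the RMS-over-nodes curve of the
spatially de-meaned record, thresholded at 10% of its peak; the first
sustained suprathreshold run is the QRS, the next the T window. On
AP-shaped records the spatial spread stays near 20% of peak during the
plateau, merging both runs into one; the single run is then split at its
interior minimum between the two dominant peaks. Manual overrides take
precedence. The beat origin is localized as the vertex with the earliest
activation time (ties to the lowest index) and compared with the true pacing
site by Euclidean distance (geodesic distance is available).

## The synthetic benchmark

No recorded data ship with the package; the benchmark
(`run_benchmark()`) builds everything from its configuration:

1. concentric-sphere phantom — 40 mm heart (812 nodes), 120 mm torso
   (1002 nodes), 200 electrodes; BEM transfer matrix;
2. calibrated FHN propagation; 50 origins per region by default (the shipped
   test suite and reproduction script run with 25 per region, which the
   beat-count analysis below shows is already deep in the saturated regime);
   region-specific and all-region SVD bases (components 2–10);
3. held-out test beats paced from vertices disjoint from every basis origin,
   forward-projected with 30 dB additive Gaussian sensor noise (the noise
   level is a package choice — the study it emulates used real recordings —
   and is configuration-exposed);
4. Tikhonov (order 0, per-instant L-curve) and PBR (all-region and
   region-specific bases, per-instant cross-validated budget)
   reconstructions;
5. evaluation at 103 epicardial sites (two circumferential bands of 99 total
   plus 4 apical — a sock-electrode surrogate) matched to their nearest heart
   nodes: per-site Pearson correlation between ground-truth and reconstructed
   traces, both re-referenced to zero spatial mean across the sites (the
   phantom analogue of comparing zero-average electrograms, since unipolar
   recordings carry no absolute reference); pooled activation/recovery timing
   correlations; per-beat localization errors; paired Wilcoxon signed-rank
   comparisons of the per-site correlations.

All randomness derives from one master seed; two runs with the same
configuration are bitwise identical. Optional sweeps rebuild the basis from
the first $m$ beats of a region-balanced, seeded order (beat-count
dependency) or from other component ranges (basis-size dependency).

At these conditions PBR reconstructs electrograms with median correlation
near 0.9 while the Tikhonov baseline collapses almost to zero — more extreme
than the corresponding contrast on animal data, and worth understanding
rather than glossing over: the phantom's heart-to-torso radius ratio of 1:3
attenuates spatial detail so strongly that at 30 dB only harmonics up to
about degree 3 rise above the noise floor, which is too coarse to correlate
with sharp activation wavefronts; PBR side-steps the attenuation because its
nine basis coefficients are identifiable from the low-degree field they
produce. Reconstruction quality saturates once roughly six beats feed the
basis, and median localization error of the spatiotemporal criterion on PBR
reconstructions is below 10 mm — synthetic in-distribution conditions (test
beats come from the same simulator family as the basis) are kinder than any
real torso.

## What the phantom does and does not emulate

The phantom shares with real ECGI the ill-posed volume-conductor physics,
realistic activation/recovery sequences, sensor noise, electrode-to-node
matching, and held-out (never-simulated) test-beat origins. It does **not**
emulate: geometry error (the transfer matrix is exact for the phantom that
generated the data); the transmembrane-vs-extracellular mismatch (ground
truth is AP-shaped, while real electrograms are extracellular fields — the
benchmark's evaluation convention handles the reference, not the waveform
shape); anisotropic or heterogeneous conduction; torso inhomogeneities
(lungs, bone); beat-to-beat variability or drift. Passing benchmarks here
therefore validates the *method implementation* — solvers, bases, timing,
statistics — not clinical-grade reconstruction accuracy.

## Numerical choices and degenerate inputs

* Meshes are validated as closed, consistently wound 2-manifolds (each
  directed edge once, its reverse once); zero-area faces are rejected.
* The BEM system is solved by dense LU; "constant in, constant out" is exact
  by the row-sum diagonal, independent of mesh quality.
* Explicit integration guards: voltages outside [−150, +90] mV abort with a
  step-size suggestion; the substep count scales with the coupling row sum.
* `gbar = 0` reduces every node to the isolated single-cell trajectory
  exactly (tested); an empty L1 budget returns the zero solution; `lambda = 0`
  with a rank-deficient normal matrix raises a singularity error rather than
  silently pseudo-inverting.
* Ties: nearest-node matching and origin localization break ties toward the
  lowest index; the L-curve returns an element of its grid and falls back to
  the smallest weight when the curve is flat.
* Problem sizes in the shipped tests (up to 812/1002-node surfaces, 25
  origins per region, 5 test beats) are the package's desk-scale defaults;
  all of them are configuration, not constants.

## Known limitations

* The propagation model is a heuristic surface reaction–coupling scheme, not
  a monodomain solver; it produces realistic spatial patterns (which is all
  the basis construction needs) but untrustworthy absolute conduction
  velocities.
* Spherical phantoms cannot probe segmentation error or electrode-position
  uncertainty.
* The spatiotemporal recovery criterion mirrors the activation product
  criterion (arg-extremum over the T window); no published formula exists for
  it, and the mirrored construction is this package's.
* Wilcoxon p-values are reported raw, without multiple-testing correction,
  matching the evaluation design the benchmark emulates.
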