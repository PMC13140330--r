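---
title: "Models and design of the xmuscle pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the xmuscle pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the signal models, the tunable parameters, the
synthetic phantom that stands in for patient data, and the numerical and
design choices behind each stage. It is the place to look when a default
needs changing or a result needs interpreting.

## The measurement problem

Fatty replacement, edema-like change and disturbed Na⁺/K⁺ homeostasis are
three distinct faces of progressive muscle disease, and each is visible to
a different MRI contrast: chemical-shift imaging for the proton-density
fat fraction (PDFF), multi-echo spin-echo (MESE) relaxometry for the T2 of
the remaining muscle water, and X-nuclei (²³Na, ³⁹K, ²³Na
inversion-recovery) imaging for apparent tissue ion concentrations (aTSC,
aTPC) and intracellular weighting. The quantities are coupled: fat both
inflates the measured T2 and dilutes the measured ion signal, so the PDFF
map feeds the T2 model and the ion corrections, and muscles beyond 50%
PDFF are excluded from both rather than corrected.

## Dixon water–fat separation

Per voxel, the complex gradient-echo signal is modelled as

$$S(TE) = \bigl(W + F \sum_p a_p e^{i 2\pi f_p TE}\bigr)\,
          e^{i 2\pi \psi TE}\, e^{-R_2^* TE},$$

with complex water and fat amplitudes $W, F$, field offset $\psi$ (Hz), a
single $R_2^*$, and an 8-peak triglyceride spectrum $(a_p, f_p)$
(methyl through olefinic protons; `default_fat_spectrum()`, offsets scaled
by the 3 T proton frequency of 127.73 Hz/ppm). The same table is the
generator default, so model-matched simulations recover fat fractions to
numerical precision; a deliberate 6-peak-on-8-peak mismatch test bounds
the model-error bias at a few percent PDFF.

Estimation is split the standard way:

1. **Field map.** For each candidate $\psi$ on a grid spanning one period
   of the echo spacing (101 candidates by default), the
   variable-projection residual of the linear $(W, F)$ fit — maximised
   over a coarse $R_2^*$ grid — is computed for all voxels at once. The
   candidate labels are then smoothed by iterated conditional modes (ICM)
   with a squared neighbour-difference penalty (6-connected,
   `smoothness_weight` in units of signal energy per candidate period).
   The smooth solution picks the correct basin at water/fat-swap
   ambiguities; a graph cut would find the same minima and could be
   swapped in, but swap-free recovery on the phantom is the acceptance
   property, not algorithm identity. The chosen candidate is refined by
   quadratic interpolation of the residual.
2. **Separation.** After per-voxel demodulation by $\psi$, $R_2^*$ is
   found by a bounded grid search on $[0, 300]\,\mathrm{s^{-1}}$ followed
   by a vectorised golden-section polish (40 iterations, interval
   $\sim 10^{-8}$ of the search range), with $(W, F)$ solved linearly at
   every candidate through the closed-form 2×2 normal equations.

PDFF is stored as a fraction in $[0,1]$ and reported as percent in tables.
The estimator uses magnitude discrimination — denominator $|W+F|$ and the
dominant-component form ($|F|/|W+F|$ where fat dominates, $1 - |W|/|W+F|$
where water dominates) — which removes the first-order noise bias of the
naive magnitude ratio; the choice is recorded in the result object
(`pdff_method`).

## Water T2

Region-mean MESE decays are fit with the tri-exponential model

$$S(TE) = A_w e^{-TE/T2_w} + A_f\bigl(c_1 e^{-TE/T2_{f1}} +
          c_2 e^{-TE/T2_{f2}}\bigr),$$

with the fat pair $(c_1, T2_{f1}; c_2, T2_{f2})$, $c_1 + c_2 = 1$, fixed
per subject from a bi-exponential fit to the subcutaneous-fat region mean
(fallback defaults 0.55/45 ms and 0.45/170 ms on non-convergence, with a
warning). Fitting is region-level because the endpoints of interest are
region statistics and the region mean has far higher effective SNR than a
voxel; the two fat exponentials are nearly collinear over 16 echoes to
160 ms, so their individual parameters are only well determined at
region-mean SNR — another reason not to fit voxelwise by default.
Optimisation uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
$T2_w \in [10, 100]$ ms, amplitudes $\ge 0$) with a log-linear start for
$T2_w$, making fits deterministic. All echoes are used; down-weighting the
first echo for stimulated-echo contamination is a config option left off
by default. Muscles with mean PDFF above `pdff_exclusion_percent`
(default 50) are excluded before fitting and carry
`exclusion_reason = "pdff_gt_threshold"`.

## X-nuclei quantification

The low-resolution ²³Na/³⁹K/²³Na-IR volumes are quantified region-wise:

1. **Partial-volume correction.** The geometric transfer matrix
   $M_{ij}$ = mean over region $i$ of the PSF-blurred indicator of region
   $j$, with the background as an explicit region to absorb spill-in;
   $M s = b$ is solved by least squares. With the true PSF this inverts
   the blur exactly for piecewise-constant images, which is what the
   phantom provides and what the brute-force pseudo-inverse oracle checks.
   The acquisition PSF is not derivable from data here, so it is a
   configured Gaussian FWHM (default 15 mm ≈ 1.5 X-nuclei voxels); a
   ±25% FWHM-mismatch test bounds the resulting error at the ~10% level.
   A condition-number limit flags unstable geometries (e.g. regions
   smaller than the blur).
2. **Relaxation correction.** Corrected SI is divided by a per-class
   factor (muscle, fat, reference solution; `default_relaxation_factors()`)
   given directly or computed as $(1 - e^{-TR/T1}) e^{-TE/T2^*}$ from
   timing constants — both supported because sequence constants are
   deployment-specific.
3. **Calibration.** Ordinary least squares of corrected tube SI on the
   nominal ladder (Na 10/20/25/30/40 mM against K 240/210/180/150/120 mM),
   free intercept by default with a through-zero switch; $R^2$, slope
   validity and back-predicted concentrations are reported.

The Gaussian blur is implemented with voxel-integrated kernel bins and a
5σ support, so the truncated tail is below $3\times10^{-7}$ and a blurred
step edge matches the analytic erf profile to the same order.

## Fat correction, relative IR, and the two-compartment model

Apparent region values mix tissue and fat compartments by area; the
correction inverts that mixing exactly:

$$v_{fc} = \frac{v - \mathrm{PDFF} \cdot v_{fat}}{1 - \mathrm{PDFF}},$$

with $v_{fat}$ = 7.9 mM (aTSC), 0 mM (aTPC), 2.5 a.u. (IR). The formula is
the standard two-compartment areal inversion; it is also precisely the
generator's mixing rule, which is what the machine-precision identity test
exercises. Values at PDFF ≥ 50% are excluded, not corrected.

Relative ²³Na-IR intensities divide each region's fat-corrected IR signal
by the prediction of an ordinary-least-squares regression of IR on aTSC
fitted to control muscle regions only, so controls scatter around 1;
values < 1 indicate extracellular-volume-driven sodium increase, > 1 a
higher intracellular fraction.

The two-compartment model treats tissue concentration as
$c = v_e C_e + (1 - v_e) C_i$. The intracellular concentration is inferred
from the control mean at the healthy extracellular fraction
$v_{e0} = 0.07$, and the $v_e$ that would explain a patient concentration
on its own follows by inversion. Serum concentrations default to
$C_e(\mathrm{Na}) = 140$ mM and $C_e(\mathrm{K}) = 4.2$ mM — mid-normal
adult serum values, configurable because study populations differ.

## Group statistics

Normality is screened with a Lilliefors test whose p-value comes from a
seeded Monte-Carlo null (10⁴ standard-normal samples of the same size,
cached per n) rather than table interpolation. Both-normal endpoints get a
pooled-variance unpaired t-test with $r_{eff} = \sqrt{t^2/(t^2+df)}$;
otherwise a Mann–Whitney U with tie-corrected normal-approximation
$z$ for $r_{eff} = |z|/\sqrt{N}$ (exact enumeration for the p-value when
both groups have n ≤ 8 without ties).

Muscle-specific p-values are adjusted with the Dubey–Armitage–Parmar
procedure, $p_{adj} = 1 - (1-p)^{m^{1-\bar r}}$, with $\bar r_j$ the mean
pairwise-complete Pearson correlation of endpoint $j$ with the others,
computed on the pooled two-group matrix (a config switch restricts it to
one group) and clamped to $[0, 1]$. At $\bar r = 0$ this is the Šidák form
$1-(1-p)^m$ — the "Bonferroni-like" conservative limit, the naming
difference being purely algebraic — and at $\bar r = 1$ p-values pass
through unchanged. Two properties worth knowing: the adjustment is
monotone and never below the raw p-value; and at intermediate endpoint
correlations (ρ ≈ 0.3–0.5) the procedure is mildly anti-conservative —
simulated family-wise error ≈ 0.08–0.10 at nominal 0.05 — recovering
control in both the near-independent and the fully-correlated limits. The
property suite asserts exactly that behaviour rather than a blanket bound.

## The synthetic phantom

`phantom_truth()` defines a lower-leg cross-section on a 160 × 200 mm
field of view: seven muscle compartments (GM, GL, SOL, TA, TP, PER, EDL)
as ellipses, tibia/fibula marrow discs, a subcutaneous-fat fill of the
remaining leg interior, and a 5-tube reference holder strip below the leg
(12 mm tube radius). Masks are rasterised consistently onto the ¹H grid
(64 × 80 × 3 at 2.5 × 2.5 × 6 mm) and the 4× coarser X-nuclei grid
(16 × 20 × 3 at 10 mm in-plane); overlap conflicts resolve to the
earlier-painted region with a warning.

Two cohort presets set the study conditions. *Control*: muscle fat
fraction 0.03–0.08, water T2 ≈ 31 ms, Na 23 mM, K 109 mM. *MFM-like*:
per-muscle fat fractions 0.1–0.9 with the clinical pattern (highest in
soleus and medial gastrocnemius, lowest in lateral gastrocnemius),
elevated water T2, Na 55.6 mM and K 75.4 mM in remaining muscle.
`subject_truth()` jitters fat fractions, concentrations (SD 2 mM control /
5 mM patient for Na), T2 and field offsets per subject so cohorts have
realistic between-subject spread around those means. Echo-time defaults
(six Dixon echoes from 1.1 ms at 1.2 ms spacing; sixteen MESE echoes at
10 ms spacing) are typical 3 T protocol values and config-exposed.

Noise is complex Gaussian on Dixon echoes and Rician on magnitudes, with
SNR defined on the first-echo mean of a named reference region and all
streams seeded (per-acquisition seeds split deterministically from a
master seed). The generator deliberately omits coil sensitivity profiles,
B0/B1 inhomogeneity beyond per-region field offsets, relaxation during
readout, stack-of-stars sampling artefacts, and inter-scanner
repositioning/registration error. Passing recovery tests therefore
demonstrates correctness of the estimation chain under its own forward
models — not robustness to those instrumental effects, which is what real
validation data would add.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: the default
3-slice phantom for map-level checks; single-slice grids (48 × 60 ¹H,
16 × 20 X-nuclei) for the 19-subject cohort replicates (a replicate runs
in ~13 s); 20 replicates for the study-replica acceptance check; 150
seeded decays for T2 recovery; 20 random geometries for the PVC oracle.
Region statistics are computed in the native grid of each quantitative map
after nearest-neighbour mask resampling in world coordinates — the
generator emits co-registered masks, so rigid resampling replaces the
non-rigid registration a clinical pipeline would need. Pipeline runs are
deterministic at the table level for a fixed configuration and seed; the
only internal randomness (the Lilliefors null) uses a fixed seed and is
cached.

## Known limitations

- Voxelwise T2 or concentration maps are out of scope; all ion and T2
  results are region-level by design.
- The PVC assumes piecewise-constant regions and a known Gaussian PSF;
  within-region gradients or a mis-specified PSF shape bias the result
  (bounded, but not removed, by the FWHM sensitivity test).
- The DAP adjustment's mild anti-conservativeness at intermediate
  correlations is inherent to the procedure, not to this implementation.
- Bi-exponential fat-pair parameters are ill-conditioned at single-decay
  SNR; calibration should always run on a large fat region (the
  implementation warns and falls back to defaults when it cannot).
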