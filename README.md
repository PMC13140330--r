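# xmuscle

Multi-parametric quantitative MRI of skeletal muscle, end to end, on a
synthetic digital leg phantom.

Muscle diseases such as the myofibrillar myopathies replace contractile
tissue with fat, raise muscle water T2 through edema-like change, and
disturb Na⁺/K⁺ ion homeostasis. Quantifying these processes in vivo takes
four coupled MRI measurements — chemical-shift (Dixon) water–fat imaging,
multi-echo spin-echo T2 relaxometry, and low-resolution ²³Na and ³⁹K
X-nuclei imaging against external reference phantoms — plus a chain of
corrections that link them: the fat fraction feeds both the T2 model and
the ion-concentration corrections. `xmuscle` implements that whole chain as
a tested R package for researchers developing or validating such pipelines,
with a ground-truth phantom generator in place of patient data so every
stage is verifiable.

## What the package computes

**PDFF (Dixon).** Complex 6-echo gradient-echo signal modelled as

    S(TE) = (W + F Σₚ aₚ e^{i2π fₚ TE}) e^{i2π ψ TE} e^{−R2* TE}

with an 8-peak triglyceride spectrum (aₚ, fₚ). The field map ψ is selected
per voxel on a discrete candidate grid by the variable-projection residual,
smoothed by iterated conditional modes to resolve the water–fat swap
ambiguity; W, F and a single R2* are then fit jointly, and
PDFF = |F|/(|W|+|F|) with magnitude discrimination against noise bias.

**Water T2 (MESE).** Region-mean decays are fit with a tri-exponential
model, `A_w e^{−TE/T2w} + A_f (c₁ e^{−TE/T2f1} + c₂ e^{−TE/T2f2})`, whose
fat pair (c, T2f) is calibrated per subject from subcutaneous fat. Muscles
with mean PDFF > 50% are excluded, never fitted.

**aTSC / aTPC (X-nuclei).** Region-based partial-volume correction through
a geometric transfer matrix (PSF-blurred region indicators, background as
an explicit region), relaxation-weighting correction per tissue class, and
linear calibration against a 5-tube NaCl/KCl ladder
([Na⁺]/[K⁺] = 10/240, 20/210, 25/180, 30/150, 40/120 mM).

**Corrections and two-compartment inversion.** Ion values are
fat-corrected by inverting the areal mixing,
`v_fc = (v − PDFF·v_fat)/(1 − PDFF)` with aTSC_fat = 7.9 mM,
aTPC_fat = 0 mM, IR_fat = 2.5 a.u.; inversion-recovery sodium intensities
are expressed relative to a control regression on aTSC. The extracellular
volume fraction explaining a concentration follows from
`ve = (c − C_i)/(C_e − C_i)` with C_i inferred from the control mean at
ve₀ = 0.07.

**Statistics.** Per-muscle group comparisons (Lilliefors-screened t or
Mann–Whitney with effect sizes r_eff), Pearson/Spearman correlation, and
the Dubey–Armitage–Parmar adjustment
`p_adj = 1 − (1 − p)^{m^{1−r̄}}` for correlated muscle endpoints.

## Worked example

Quantify tissue sodium on the default leg phantom (noisy acquisition,
Gaussian PSF of 15 mm FWHM):

```r
library(xmuscle)
truth <- phantom_truth()
masks <- build_leg_phantom(truth)
psf   <- psf_spec("gaussian", fwhm_mm = 15)
na_img <- synthesize_xnuclei(truth, masks$xn, "na", psf = psf,
                             noise = noise_spec("rician_magnitude", snr = 40, seed = 7))
q <- quantify_xnuclei(na_img, masks$xn, psf)
glance(attr(q, "calibration"))
#> # A tibble: 1 × 3
#>   r_squared n_points valid
#>       <dbl>    <int> <lgl>
#> 1     1.000        5 TRUE
dplyr::select(dplyr::filter(q, class == "muscle"), region, value, si_raw, si_corrected)
#> # A tibble: 7 × 4
#>   region value si_raw si_corrected
#>   <chr>  <dbl>  <dbl>        <dbl>
#> 1 GM      22.3  10.5          22.1
#> 2 GL      22.5  10.6          22.4
#> 3 SOL     22.2  11.0          22.0
#> 4 TA      22.2  10.2          22.0
#> 5 TP      22.2   8.88         22.0
#> 6 PER     21.9   9.02         21.8
#> 7 EDL     22.1   9.28         21.9
```

`value` is the apparent tissue sodium concentration in mM: the phantom's
muscle truth is 23 mM mixed with ~5% fat at 7.9 mM (≈ 22.2 mM apparent),
and the raw region means (`si_raw`, heavily diluted by the coarse
resolution and blur) are restored by the partial-volume and relaxation
corrections before calibration. The tube regression is exact (R² = 1).

The two-compartment inversion for the group means:

```r
c_i <- infer_intracellular(23.2, ve0 = 0.07, c_e = 140)  # 14.41 mM
ecv_from_concentration(55.6, two_compartment_model(c_i, 140))
#> # A tibble: 1 × 3
#>      ve ve_raw out_of_range
#>   <dbl>  <dbl> <lgl>
#> 1 0.328  0.328 FALSE
```

i.e. a patient-group mean aTSC of 55.6 mM would, on its own, require the
extracellular volume fraction to rise from 0.07 to ≈ 0.33.

A full simulated two-group study runs with
`simulate_cohort_study()` → `process_study()`, or from disk via
`simulate_study()` and `run_pipeline("study.yaml")` (also exposed by the
`inst/cli/xmuscle` script: `simulate`, `run`, `stats`).

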