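# punctate

Confocal puncta quantification with image-based subcellular fractionation,
for studies of receptor trafficking between intracellular, extrasynaptic and
synaptic pools.

## The problem

Neurotransmitter receptors redistribute between spatial pools — intracellular
stores, the extrasynaptic plasma membrane, and synapses — without the total
amount necessarily changing, so bulk biochemistry can miss the effect
entirely. A high-resolution alternative images two immunolabels in confocal
z-stacks: the receptor of interest (e.g. the GABA_A receptor γ2 subunit) and
a presynaptic marker (synaptophysin), whose ring-like outline also identifies
large motor-neuron somata (diameter > 40 µm). `punctate` implements this
analysis as a tested, scriptable pipeline:

- **Thresholding**: cutoffs derived from negative-control stacks as
  mean + *k*·sd of control voxels (strict `>`), via `derive_threshold()`.
- **Neuropil measures**: per-plane receptor pixels, marker pixels, and their
  pixel-wise colocalization R ∧ M (synaptically localized receptor), summed
  over the z-series (`neuropil_measures()`).
- **Image-based subcellular fraction**: select the plane z\* maximizing
  |R ∧ M|, trace the somatic membrane (manual polygon or automatic ring
  trace), rasterize a band B = {p : dist(p, contour) ≤ t/2} with t = 2 µm,
  and partition receptor pixels in the band into synaptic |R ∧ M ∧ B| and
  extrasynaptic |R ∧ ¬M ∧ B| pools (`membrane_measures()`).
- **Deconvolution** (optional): fixed-iteration Richardson–Lucy with an
  explicit Gaussian or supplied PSF, reflective boundaries, default 3
  iterations (`richardson_lucy()`).
- **Statistics**: mixed-design ANOVA (dose between subjects; injection side
  and rostrocaudal distance within), Tukey HSD post-hoc across doses, and
  ANCOVA adjusting synaptic measures for total receptor signal to separate
  trafficking from synthesis (`mixed_anova()`, `tukey_posthoc()`,
  `ancova()`); plus quantitative western-blot helpers (`normalize_blot()`,
  `linear_range_r2()`, `band_background_correct()`).
- **Synthetic data**: a ground-truthed scene generator (somatic marker ring,
  three planted puncta pools, Gaussian PSF, Poisson noise) and a cohort
  simulator with a configurable U-shaped dose–response model and
  contralateral spread (`generate_scene()`, `dose_model()`,
  `simulate_cohort_counts()`, `generate_cohort()`).

Stacks are calibrated `(channel, z, y, x)` arrays read and written as
multi-page TIFF with a key=value metadata sidecar (`read_stack()`,
`write_stack()`). Tabular results are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_dose_response()` figures.

## Worked example

Simulate one soma, derive thresholds from a background-only control, and
quantify it:

```r
library(punctate)

scene <- generate_scene(scene_params(seed = 42))
ctrl  <- generate_scene(scene_params(n_synaptic = 0, n_extrasynaptic = 0,
                                     n_intracellular = 0, n_marker_only = 0,
                                     ring_amplitude = 0, seed = 99))$stack
th <- threshold_spec(derive_threshold(ctrl, "receptor", 3),
                     derive_threshold(ctrl, "marker", 3),
                     method = "control_mean_plus_k_sd", min_component_px = 4)

neuropil_measures(scene$stack, th, count_puncta = TRUE)
#> <puncta_measurement> 9 plane(s)
#>   totals: receptor 2539 px, marker 15122 px, colocalized 608 px
#>   components: 118 receptor, 36 colocalized

membrane_measures(scene$stack, th, contour = scene$truth$contour_true)
#> <membrane_fraction> plane 4, 2 um band (2144 px): 231 synaptic, 143 extrasynaptic px

recover_scene_counts(scene$stack, th, contour = scene$truth$contour_true)
#> # A tibble: 1 × 4
#>   synaptic extrasynaptic intracellular plane_index
#> 1       12             8            23           4
```

The scene was planted with 12 synaptic, 8 extrasynaptic and 20 intracellular
puncta: the synaptic and extrasynaptic pools are recovered exactly under
shot noise and PSF blur; the intracellular pool picks up a few noise
components. The membrane fraction reports pixel pools inside the 2 µm band
on the automatically selected equatorial plane (z = 4).

A full dosed cohort (3 doses × 4 subjects × 2 sides × 13 sampling points)
and its statistics:

```r
rec <- simulate_cohort_counts(dose_model(), n_subjects_per_dose = 4,
                              neurons_per_side = 13, seed = 1)
mixed_anova(rec, "membrane_synaptic_px")
#> <mixed ANOVA> outcome: membrane_synaptic_px (aov_strata)
#>       term df den_df statistic   p.value
#>       dose  2      9   208.173 2.916e-08
#>       side  1      9     1.555 2.438e-01
#>   distance 12    132     1.053 4.051e-01
#>  dose:side  2      9     1.167 3.544e-01

ancova(rec, "membrane_synaptic_px", "neuropil_total_px")
#> <ANCOVA> membrane_synaptic_px adjusted for neuropil_total_px (slope 0.2767 +/- 0.0255, aov_strata)
#>       term df den_df statistic   p.value
#>  covariate  1    143 56.501873 5.630e-12
#>       dose  2      8  9.081499 8.742e-03
#>       side  1     10  0.003369 9.549e-01
```

The dose effect on synaptic receptor is large (F(2,9) = 208) and survives
adjustment for total receptor signal (p = 0.0087): the planted redistribution
toward synapses is detected as trafficking, not as a by-product of the total
increase. `tukey_posthoc(rec, "neuropil_total_px")` resolves the planted
U-shape: the middle dose sits significantly below both the low dose
(difference −157, adj. p < 1e-5) and the high dose (+517, adj. p < 1e-9).

An end-to-end run (simulate → deconvolve → quantify → analyze, with caching
and logs) is `run_pipeline(run_config(...))`, or from a shell:

```sh
Rscript inst/scripts/punctate-pipeline.R --seed 1 --out demo-run --subjects-per-dose 2
```

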