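---
title: "Quantifying receptor pools from confocal stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor pools from confocal stacks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctate)
```

## The measurement problem

Inhibitory GABA~A~ receptors move between three spatial pools on and around
a neuron: an intracellular pool, an extrasynaptic plasma-membrane pool, and
a synaptic pool apposed to presynaptic terminals. Bulk biochemistry
(membrane fractionation plus quantitative western blotting) often lacks the
spatial resolution to see a redistribution between these pools when the
total amount of receptor barely changes. `punctate` implements an
image-based alternative: two-channel confocal z-stacks — a receptor
immunolabel and a presynaptic marker (synaptophysin) whose ring-like somatic
outline identifies large motor neurons (diameter > 40 µm) — are thresholded,
colocalized pixel-wise, and partitioned into pools using a
fixed-physical-thickness band around the traced membrane, the *image-based
subcellular fraction*.

Two quantification passes mirror the two original analysis macros:

1. **Neuropil pass** (`neuropil_measures()`): in every plane of the
   z-series, count receptor pixels above threshold, marker pixels above
   threshold, and their pixel-wise AND (colocalized, i.e. synaptically
   localized receptor). Totals over planes give neuropil-level measures.
2. **Membrane pass** (`membrane_measures()`): pick the plane with the
   highest receptor/marker colocalization (`select_max_coloc_plane()`, ties
   to the lowest index for determinism), obtain the somatic contour — a
   manually traced polygon takes priority; otherwise the marker ring is
   auto-traced — rasterize a 2 µm-thick band centred on the contour, and
   split receptor pixels inside the band into synaptic (marker-positive)
   and extrasynaptic (marker-negative) pools. By construction
   `synaptic_px + extrasynaptic_px` equals the receptor pixels in the band.

Pixel counts are the primary outcome; discrete puncta are also available as
8-connected in-plane components with a minimum-size floor
(`min_component_px`), since "puncta" in common usage can mean either.

## Thresholds

Thresholds come from negative-control stacks: `derive_threshold()` pools
every voxel of the named channel and returns mean + *k*·sd (population sd),
with *k* = 3 by default. A pixel counts as signal only when it strictly
*exceeds* the cutoff. Both the rule and *k* are configuration: any fixed
cutoff can be supplied through `threshold_spec()`, and thresholds are logged
by the pipeline so a run can be reproduced exactly.

## The band rasterizer

`band_from_contour()` computes, for every pixel centre, the exact Euclidean
distance to the closed contour polyline (point-to-segment, vectorized per
segment) and keeps pixels within half the band thickness. The 2 µm band is
therefore centred on the trace — half inside the cell, half outside — which
is the symmetric reading of a "band containing the plasma membrane";
`anchor = "inside"`/`"outside"` shifts it entirely to one side when a
different convention is wanted. On circular contours of radius 20–80 px at
0.1–0.3 µm/px the band area stays within ~2 % of the analytic annulus.
Thickness below one pixel at the current calibration is rejected.

## Deconvolution

The pipeline optionally applies Richardson–Lucy deconvolution
(`richardson_lucy()`) with a fixed iteration count (default 3, the count
used for receptor-label stacks in the protocol this emulates) and a
parametric Gaussian PSF. The original workflow used commercial *blind*
deconvolution; blind PSF estimation is out of proportion to its role here,
so the PSF is explicit (`psf_model()`), and a measured kernel can be
supplied. Boundaries are reflective, which keeps edge planes from dimming
and conserves total intensity to well below 0.1 % per iteration;
non-negativity is preserved by the multiplicative update. Both channels are
deconvolved by default; `deconvolve_stack(channels=)` restricts it.

## The synthetic-scene generator

No images are distributed with the studies this pipeline targets, so the
package ships a generator (`generate_scene()`) that renders the geometry the
analysis assumes: a spherical soma (default diameter 42 µm) whose membrane
ring is drawn on every plane the sphere intersects; synaptic puncta as
receptor + marker blobs sharing a centre on the equatorial ring;
extrasynaptic puncta as receptor blobs placed in planted gaps of the marker
ring; intracellular puncta in the soma interior; optional marker-only
terminals on the ring. Puncta are truncated Gaussians (sigma = radius/2,
cut at the radius), so the noiseless footprint of each punctum is exactly
the set of pixel centres within its radius — this is what makes the
"exact closure" tests possible: with no PSF, no noise, and a zero
threshold, the measured pixel sets equal the planted footprints identically.
Scenes are then blurred with a Gaussian PSF (default 0.2 µm lateral,
0.4 µm axial) and corrupted with Poisson shot noise over a constant
background (default 40 counts), with optional Gaussian read noise.

Default physical scales: 0.35 µm/px and 0.5 µm z-steps over a 160×160×9
field for full-size scenes (analysis functions default to 0.14 µm/px, a
typical 63×/1.4 NA sampling, when no calibration is supplied); puncta have
0.7 µm radius and a 2.2 µm minimum centre separation so footprints stay
disjoint and components countable. What the generator does *not* emulate:
tissue autofluorescence texture, vasculature, overlapping neighbouring
somata, depth-dependent attenuation, or non-Gaussian optics. Passing the
recovery tests therefore shows the *algorithmic* chain is correct and
robust to shot noise and modest blur — not that segmentation would survive
arbitrary tissue artifacts; on real data the manual-contour path and the
supervised plane override exist precisely for those cases.

## The dose model and cohorts

`dose_model()` encodes the experimental design: doses {0.01, 0.1, 1} µM
with an albumin-vehicle injection on the contralateral hemicord of every
subject, 4 subjects per dose, and one neuron sampled every 100 µm out to
±600 µm from the injection centre. Per-neuron planted counts are negative
binomial (variance µ + φµ², default φ = 0.05); φ = 0 gives deterministic
counts for degenerate tests. Effects are multiplicative per pool. The
default profile is U-shaped for the total and extrasynaptic pools
(mid < low < high: 0.8 / 1.3 / 1.8 and 0.8 / 1.4 / 1.9 × baseline) and
high-dominant for the synaptic pool (1.1 / 1.0 / 2.0), with a contralateral
"spread" fraction rising from 0.1 at the low dose to 0.95 at the high dose
— the high-dose effect extends essentially undiminished across the cord.
These magnitudes are simulation parameters chosen to be biologically
plausible, not measured values; the studies this emulates report the shape
of the response, not effect sizes.

Monte-Carlo statistics run on *count-level* cohorts
(`simulate_cohort_counts()`), which draw the identical dose model without
rendering images — rendering 500 × 312 scenes would add hours of
computation and nothing statistical. The rendered path
(`generate_cohort()` → `measure_cohort()`) is exercised end-to-end on
smaller cohorts (64×64×5 scenes at 0.8 µm/px in the packaged pipeline
defaults, sizes chosen to keep a full demo run in seconds).

## Statistics

Neurons are aggregated to subject × side × distance cell means before any
inference: the subject is the experimental unit, and with n = 4 subjects
per dose the neuron-level pseudo-replication would otherwise be severe.
Distance enters as a categorical within-subject factor (its functional form
is not part of the design this mirrors, and categorical coding makes no
monotonicity assumption).

`mixed_anova()` fits the mixed design — dose between subjects; side and
distance within — using the classical repeated-measures partitioning
(`aov` with `Error(subject/(side*distance))` strata) whenever the design is
balanced. We initially fitted a subject-random-intercept mixed model with
Satterthwaite F-tests instead, but at n = 4 subjects per dose the REML
subject variance sits on the zero boundary in roughly half of null
data sets and the dose test becomes conservative (empirical size ~0.02–0.04
instead of 0.05); the classical strata are exact in the balanced case
(empirical size ~0.045–0.055 over 500 null cohorts). Unbalanced designs
fall back to the mixed model with type-III sums of squares and a warning.
`ancova()` adds the matching total-signal covariate ahead of the factors —
the trafficking-versus-synthesis adjustment — and reports the covariate
slope from the subject-random-intercept model, which is unbiased (the
packaged recovery check plants slope 0.5 and recovers it within ~1–2 %).
`tukey_posthoc()` runs Tukey HSD across dose groups on subject means.
Significance is α = 0.05 throughout; no cross-outcome multiplicity
correction is applied, matching the analysis this reproduces.

## Western-blot arithmetic

The densitometry helpers are deliberately small: `normalize_blot()` divides
receptor band intensity by the loading-control intensity (N-cadherin in the
motivating protocol), `average_blot_runs()` averages per-run normalized
ratios across counterbalanced replicate gels, `linear_range_r2()` reports
the OLS R² of a dilution curve (the check that intensities sit in the
antibody's linear range), and `band_background_correct()` subtracts the
mean of the median pixel densities above and below a band from its
integrated intensity.

## Numerical conventions and degenerate inputs

* Axes are `(channel, z, y, x)`; pixel coordinates 0-based; y grows
  downward; z = 0 is the first acquired plane. No function re-infers axes.
* All crops and intervals are half-open; the band test is a closed
  inequality on exact distances.
* Thresholding is strict (`>`); an all-zero plane at threshold 0 is empty.
* Plane-selection ties break to the lowest z.
* A constant outcome in `mixed_anova()` returns F = 0, p = 1 rather than
  failing; a constant ANCOVA covariate is an error.
* `EBImage::bwlabel` is 4-connected, so diagonal-touching labels are merged
  through a label-adjacency graph to give the 8-connectivity the component
  counts are defined with.
* Every random stage (scenes, cohorts, pipeline) takes an explicit integer
  seed; identical seed and parameters give bit-identical stacks and tables.

## Known limitations

Single soma per scene; no dendritic membrane tracing; the subcellular
fraction is a 2-D band in one plane, not a 3-D shell; colocalization is
binary mask overlap, not intensity correlation (Manders/Pearson are out of
scope); auto-tracing assumes a closed bright ring and needs a morphological
closing radius (`close_radius_px`) when the ring has planted or biological
gaps — failing that, it asks for a manual contour, which is the authentic
workflow for real tissue.
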