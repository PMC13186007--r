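---
title: "Quantifying heterogeneous photoreceptor degeneration with the Outer Retina ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneous photoreceptor degeneration with the Outer Retina ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orrquant)
```

## The problem and the metric

Pharmacologically induced photoreceptor degeneration — here the feline
model induced by intravitreal ATP — is strongly heterogeneous: regions of
near-intact retina sit directly beside severely degenerated patches in the
same eye. Pooled, whole-eye measures average this structure away.
`orrquant` implements a local, eccentricity-agnostic score, the **Outer
Retina ratio (ORr)**: in a full-thickness cross-section,

$$\mathrm{ORr} = \frac{T_{OS} + T_{IS} + T_{ONL} + T_{OPL}}
{T_{\text{total}}},$$

the thickness of the outer retina (photoreceptor outer and inner segments,
outer nuclear layer, outer plexiform layer) divided by the total retinal
thickness from the inner limiting membrane (ILM) surface to the
outer-segment edge. Being a ratio, ORr is invariant to uniform scaling of
all thicknesses, which absorbs both eccentricity-dependent thickness
variation and modest obliqueness of the cutting plane; the package tests
assert this invariance exactly.

Sections are split into adjacent, non-overlapping **250 µm regions**
(left-aligned; a trailing remainder shorter than one region is discarded
and logged). Within each region, ORr is sampled at **50 µm intervals**
and averaged.

### Sampling scheme

"Every 50 µm within a 250 µm region" admits two readings: 6 fence posts
(0, 50, ..., 250) or 5 interior points. We default to **5 interval
midpoints** (25, 75, 125, 175, 225 µm past the region start) so that
adjacent regions never share a sample and region means stay independent;
the fence-post variant is available via `scheme = "fencepost"`. For any
field that is linear across the window, midpoint sampling returns the
mid-window value exactly (tested to 10⁻⁶).

### Other geometric conventions

* **ILM handling.** The ILM is a membrane, not a band: total thickness is
  measured *up to the ILM surface* rather than adding an ILM band. This
  keeps the denominator measurable and monotone.
* **Measurement direction.** Thickness is measured along the image column
  (vertically), not along the local surface normal; the ratio's scale
  invariance is precisely what makes this acceptable for oblique sections.
* **Orientation.** Row 1 of every image is the vitread (ILM) side;
  columns run along the section.
* **Boundary input.** Boundaries come from annotation: either an integer
  label mask (1–7 for GCL, IPL, INL, OPL, ONL, IS, OS; converted to
  boundary curves by a per-column extremal scan in `profile_from_mask()`)
  or explicit depth curves via `layer_profile()`. The package does not
  segment raw H&E stain; that is out of scope.
* **Unmeasurable regions.** If any sample in a region has zero total
  thickness, the region is flagged unmeasurable (`NA` mean), mimicking
  the delineation failures of severely degenerated tissue, and excluded
  from group statistics but counted in logs.

## Normative threshold and degeneration groups

The normative threshold is the control-eye mean ORr minus two control
standard deviations (`fit_normative()`). We use the sample (n − 1) SD —
the standard choice when estimating a population SD, and numerically
negligible at hundreds of control regions. Under a normal model this
threshold sits at the 100·Φ(−2) ≈ 2.3rd percentile of control values
(`normative_percentile()`). The threshold is carried at full precision
internally; printed summaries round to two decimals.

Regions are then graded (`classify_region()`):

| group | meaning    | rule                              |
|-------|------------|-----------------------------------|
| 0     | control    | all control regions, any ORr      |
| 1     | none       | treated, ORr ≥ threshold          |
| 2     | mild       | threshold > ORr ≥ 0.35            |
| 3     | moderate   | 0.35 > ORr ≥ 0.2                  |
| 4     | severe     | ORr < 0.2                         |

The 0.35 and 0.2 cutoffs are configurable conventions with closed lower
bounds (exactly 0.35 → group 2; exactly 0.2 → group 3). Where a figure
caption and the rule disagree for a boundary value (an ORr of exactly
0.20 is occasionally described as "severe"), the rule wins: rules are
normative, captions qualitative. Classification is monotone (lower ORr
never gives a lower group) and partitions every measurable treated
region — both properties are tested.

## The log-linear ONL density model

ONL cell density per mm of retina, $CD$, relates to ORr on the decibel
scale:

$$10\,\log_{10} CD = A + B \cdot \mathrm{ORr} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2_{dB}),$$

fitted by ordinary least squares in dB space (`fit_onl_density()`). The
10·log₁₀ convention is fixed by the model equation (not 20·log₁₀).
Goodness of fit is reported where the model lives: $R^2_{dB}$ and
$RMSE_{dB}$, with two fold-scale companions:

* the **multiplicative RMSE factor** $F = 10^{RMSE_{dB}/10}$, the
  "times-or-divided-by" error of a back-transformed prediction; and
* the **Duan smearing factor** $S = \mathrm{mean}_i\, 10^{r_i/10}$ over
  the residuals, which multiplies the naive back-transform
  $10^{(A + B\,\mathrm{ORr})/10}$ (a conditional-median estimate) into a
  conditional-mean estimate. For an intercept fit $S \ge 1$ by Jensen's
  inequality, and for Gaussian residuals
  $S \to \exp((\sigma_{dB}\ln 10/10)^2/2)$ (≈ 1.107 at σ = 1.96 dB).

`predict()` exposes both the unsmeared (median-scale) and smeared
(mean-scale) back-transform and labels which is which, rather than
guessing which one a published curve shows. The RMSE denominator defaults
to n (a population-style RMSE) with a `"df"` switch for n − 2, since
either convention is defensible and neither is universal. Regions whose
ONL could not be counted are excluded upstream; whether a single
countable severe-group point enters the fit is the caller's choice — both
modes work.

## Marker quantification

* **Fluorescence intensity** is the mean over a target mask minus the
  mean over a choroid (background) mask, making it invariant to constant
  illumination offsets. Negative values (below background) are retained
  and flagged, never clamped, so distributional statistics stay unbiased.
  Interactive "magic wand" region selection is deliberately replaced by
  layer-mask means — the interactive tool is not reproducible.
* **Control normalization** divides by the mean of the
  *background-subtracted* control intensities of the same animal and
  marker; subtracting before averaging is what makes the normalization
  offset-invariant (the order of operations is otherwise ambiguous).
* **Nuclei counting** (`count_nuclei()`) mirrors particle analysis:
  automatic Otsu threshold computed on the pixels inside the layer mask,
  distance-transform watershed to split touching nuclei, then an
  area/circularity filter (circularity $= 4\pi A/P^2$). The permissive
  defaults (min area 0, circularity [0, 1]) impose no shape filtering,
  so the count equals the raw post-watershed component count. Counts are
  normalized by the lateral mask extent in mm. A saturated band (no
  intensity contrast) is flagged low-confidence rather than failing.
* **Positive nuclei** replace a manual count with an explicit operator: a
  nucleus is marker-positive when ≥ 50% (configurable) of its pixels
  exceed an intensity threshold in the co-registered channel.
* **DAB positive area** defaults to colour deconvolution with the
  standard haematoxylin/DAB optical-density vectors and a DAB-OD
  threshold of 0.15; haematoxylin-blue pixels have zero DAB density by
  construction. A plain HSV brown-hue window (10–60°) is provided as an
  alternative rule. The original interactive RGB thresholds are
  unrecoverable, so both rules are documented configurations, not claims
  of equivalence. Output is positive area per retinal length (µm²/µm),
  additive over disjoint masks and blind to pixels outside the mask.
* **Group-4 gate.** Photoreceptor markers (rhodopsin, cone opsin, ONL
  nuclei) are not quantified in group-4 or unmeasurable regions, where
  outer layers cannot be delineated (`photoreceptor_quantifiable()`).

## Cortical metrics

Per recording channel, the **activation threshold** is the injected
current eliciting 50% of the channel's maximum spike count in the
3–20 ms post-stimulus window. A logistic with floor 0 and fitted ceiling,
$M\,\mathrm{plogis}((I - m)/s)$, is least-squares fitted
(`minpack.lm::nlsLM`, unbounded, with post-hoc validation of the
solution) and the midpoint $m$ returned; if the fit fails or lands
outside the tested range, the threshold falls back to linear
interpolation of the monotone upper envelope at half the observed
maximum. Channels whose maximum count is below a noise floor (default 5
spikes) are non-responsive. The **best threshold** of a stimulating
electrode is the minimum finite channel threshold across both
hemispheres.

**d′ spatial selectivity** is implemented literally from its verbal
definition — the rate of reduction of max-normalized firing with
Euclidean distance from the best channel — as the negative least-squares
slope (per mm), computed within the best channel's hemisphere. The
original selectivity index descends from companion work whose full
machinery is not reproduced here; equivalence is not claimed. The firing
map is taken at twice the best threshold by default (configurable; the
evaluation level is otherwise unspecified). Both metrics are invariant
to uniform scaling of spike counts.

A caveat the tests make explicit: under Poisson spike noise, the
empirical best channel is sometimes misidentified, which attenuates and
disperses d′ estimates (they remain monotone in the true falloff). On
noiseless recruitment curves both threshold and d′ are recovered
essentially exactly.

## Group statistics

Kruskal–Wallis (via `stats::kruskal.test`, tie-corrected) with Dunn's
post hoc pairwise z tests on pooled midranks, including the standard tie
correction in the variance, and Holm step-down adjustment
(`stats::p.adjust`). Dunn's test is implemented in the package (no
suitable implementation ships with the environment's R packages) and is
verified against a brute-force rank oracle on all small inputs. Design
choices: midranks everywhere; two-sided z p-values; the Holm family is
the set of pairwise comparisons within one marker × layer analysis (10
pairs for 5 groups), not the whole study. Correlations between retinal
and cortical metrics are reported both as Pearson's r and Spearman's ρ
(Pearson applied to midranks, t-based p), with pairwise deletion of
missing values and an explicit `NA` report for degenerate pairs.

## The synthetic-data generator

`generate_section()` renders a ground-truthed section: a structural
channel, DAPI nuclei, a rhodopsin-like fluorescence channel, a DAB RGB
channel, and an integer layer label mask. It emulates the statistical
structure the analysis assumes:

* control region ORr ~ Normal(0.55, 0.05) truncated to [0.39, 0.69];
* treated region ORr drawn from a degeneration-group mixture (defaults
  272 : 220 : 263 : 79, spanning 0–0.64) through a Gaussian copula whose
  correlation length (default 500 µm) couples neighbouring regions —
  adjacency of severe and intact patches is a qualitative feature of the
  model, but no within-eye spatial statistics are published, so the
  correlation length is a free parameter and the marginal mixture is
  exact by construction;
* ONL nuclei density 10^((A + B·ORr + ε)/10) with A = 20.86, B = 25.56,
  ε ~ N(0, 1.96² dB), Poisson-sampled counts, dart-throwing placement
  with a minimum centre distance of 1.8 nucleus radii (pairwise overlap
  well under 60%, so watershed splitting is exercised but solvable);
* per-group multiplicative marker effects: outer-segment intensity
  (1, 0.85, 0.7, 0.55, 0.25 for groups 0–4), ectopic opsin-positive ONL
  nucleus rates (0, 0.05, 0.12, 0.2, 0.3), DAB area per length in the
  IPL (0.5–1.5 µm²/µm, increasing with severity), and an RBPMS-positive
  GCL fraction dropping 44% from control in all treated groups;
* DAB rendered by Beer–Lambert with the standard haematoxylin/DAB stain
  chromaticities, so chromatic classification has exact ground truth.

Geometry: the inner retina is held at 90 µm (fractions GCL 0.20 /
IPL 0.45 / INL 0.35) and the outer retina scaled as
inner·ORr/(1 − ORr), giving a ~200 µm control retina; outer fractions
OS 0.20 / IS 0.15 / ONL 0.50 / OPL 0.15. Inner nuclei run at 420 /mm
(INL) and 60 /mm (GCL), chosen to land near published per-region
counts. Nuclei are 2 µm-radius anti-aliased disks.

`generate_cortical()` builds per-electrode spike tables: logistic
recruitment per channel, channel maxima falling off linearly with
distance from the best channel at the ground-truth d′ rate (default
0.55/mm), channel midpoints rising 10 µA/mm away from the best site, a
contralateral hemisphere with attenuated maxima and +30 µA thresholds,
and the best channel's true threshold drawn around the group mean
(82.43, 88.64, 98.25, 117.25, 124.26 µA for groups 0–4). Published
dispersions are standard errors without a stated n, so the
between-electrode SD is a package choice, fixed at 25 µA — a realistic
spread for suprachoroidal stimulation. Optional Poisson count noise.

What the generator does **not** emulate: H&E texture, optical PSF or
scanner noise, stain variability, real nucleus morphology (ellipticity,
chromatin texture), electrode-pocket tissue damage, or cortical
binocularity. Passing round trips therefore demonstrate the estimators'
correctness on data satisfying the model assumptions, not performance on
real tissue.

Two rendering caveats are deliberate: (i) at control-level ONL densities
the dart-throwing placement saturates below the drawn target count
(random sequential packing has a jamming limit), so the ground truth
records both the model-drawn and the actually rendered counts — image
round trips compare against the rendered count, density round trips use
the drawn counts via the fast `render = FALSE` path; (ii) rendered
boundaries are quantized to pixel rows, so mask-derived ORr agrees with
ground truth to about half a pixel of thickness.

## Numerical choices and problem sizes

Determinism: every generator is a pure function of (spec, seed); the RNG
state is restored afterwards. The test suite and the pipeline default to
sections of 1–3 mm at 2 px/µm, 20 seeds × 700 regions for density
parameter recovery, 400 independent regions for mixture recovery, 150
electrodes per group (noiseless) for threshold-ordering checks, and 10⁶
simulated residuals for the smearing-factor reproduction — sizes at
which the Monte-Carlo error of each check is comfortably below its
tolerance.

## Known limitations

* Boundaries must be supplied (annotation or synthesis); no automatic
  layer segmentation.
* Regions are treated as independent in the statistics; within-eye
  correlation is not modelled (no mixed effects), inheriting a known
  limitation of the pooled analysis.
* The DAB thresholds and the exact interactive thresholding of the
  original workflow are unrecoverable; the deconvolution rule is a
  reproducible stand-in, not a re-derivation.
* d′ under spike noise is attenuated by best-channel misidentification;
  comparisons across conditions remain valid, absolute values are
  conservative.
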