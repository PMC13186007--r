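# orrquant

Quantification of heterogeneous photoreceptor degeneration in layered
retinal cross-sections via the **Outer Retina ratio (ORr)**, with the
downstream marker, cortical-response and statistical machinery to relate
local degeneration to retinal remodeling and to the performance of an
implanted retinal prosthesis.

## Who this is for

Vision scientists and bioengineers working with histological
cross-sections of degenerating retina (e.g. the ATP-induced feline
model) who need a *local*, eccentricity-agnostic severity score instead
of pooled whole-eye measures, and who want every analysis stage testable
against ground truth without access to the original tissue.

## The metric and the model

For each adjacent 250 µm region of a section, sampled every 50 µm,

```
ORr = (OS + IS + ONL + OPL thickness) / total retinal thickness
```

(outer segments, inner segments, outer nuclear layer, outer plexiform
layer over the ILM-surface-to-outer-segment-edge distance). Being a
ratio, ORr is invariant to eccentricity-dependent thickness scaling and
to oblique sectioning. Regions are graded against a normative threshold
(control mean − 2 SD, the 2.3rd percentile under a normal model) into
groups 0 (control) and 1–4 (none / mild / moderate / severe, with cutoffs
at 0.35 and 0.2).

ONL cell density (cells/mm) relates to ORr on the decibel scale:

```
10 log10(CD_ONL) = A + B * ORr + e,   e ~ N(0, sigma_dB^2)
```

fitted by OLS, with fold-scale diagnostics: the multiplicative RMSE
factor `F = 10^(RMSE_dB/10)` and the Duan smearing factor
`S = mean(10^(residual/10))` that turns the median-scale back-transform
into a mean-scale prediction.

Companion modules quantify immunofluorescence (choroid-background
subtracted, control-normalized), DAB positive-pixel area by H-DAB colour
deconvolution, DAPI nuclei counts with watershed splitting, electrically
evoked cortical thresholds (50% of maximum spike count) and d′ spatial
selectivity, plus Kruskal–Wallis / Holm-adjusted Dunn group tests and
Pearson–Spearman correlation matrices. A fully ground-truthed synthetic
section and cortical generator backs every test. See
`vignettes/orr-methods.Rmd` for the full methods account.

## Worked example

```r
library(orrquant)

# one synthetic control and one ATP-like eye, analysed from their masks
sec_c <- generate_section(section_spec(2000, px_per_um = 2,
                                       condition = "control", seed = 1))
sec_t <- generate_section(section_spec(2000, px_per_um = 2,
                                       condition = "treated", seed = 2))
regions <- rbind(
  measure_regions(profile_from_mask(sec_c$label_mask, 2),
                  eye_id = "ctrl", condition = "control"),
  measure_regions(profile_from_mask(sec_t$label_mask, 2),
                  eye_id = "atp", condition = "treated"))

norm <- fit_normative(regions$mean_orr[regions$condition == "control"])
norm
#> Normative ORr model (n = 8 control regions)
#>   mean 0.557, SD 0.043
#>   threshold (mean - 2 SD): 0.47

regions <- classify_regions(regions, norm)
table(regions$condition, regions$group_name)
#>           control mild moderate
#>   control       8    0        0
#>   treated       0    6        2

d <- simulate_onl_density(700, seed = 3)   # (ORr, density) pairs
fit <- fit_onl_density(d$orr, d$density)
summary(fit)
#> Log-linear ONL density model (dB scale)
#>
#> Coefficients:
#>   Estimate Std. Error
#> A  20.6320     0.3382
#> B  25.9871     0.7341
#>
#> n = 700, R2_dB = 0.642, RMSE_dB = 1.933 dB
#> F = 1.561x (fold RMSE), Duan S = 1.1018

predict(fit, 0.44)                  # 1609.3 cells/mm (median scale)
predict(fit, 0.44, smeared = TRUE)  # 1773.1 cells/mm (mean scale)
```

The normative model says: a healthy eye's regions cluster near ORr 0.56,
and anything below ~0.47 in this small sample would not pass for
healthy. The treated eye's regions land in the mild/moderate groups. The
density fit recovers the generating parameters (A = 20.86, B = 25.56,
sigma = 1.96 dB) within their standard errors; F says back-transformed
density predictions are typically right to a factor of ~1.56, and S is
the multiplier converting them into conditional means.

The whole chain — simulate → segment → classify → fit density →
quantify markers → cortical metrics → statistics → report bundle — runs
as one seeded, reproducible call:

```r
res <- run_pipeline(pipeline_config(seed = 7, out_dir = "run7"))
```

A thin command-line wrapper with `simulate`, `classify`, `fit-density`,
`cortical`, `stats` and `run` subcommands is at
`inst/scripts/orr-cli.R`.

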