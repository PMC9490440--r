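# bioapatite

Chemometric tools for studying early postmortem change in bone mineral and
its survival through burning.

## The problem

Cremated remains turn up in both forensic casework and archaeological
funerary contexts, and a recurring question is whether the body was burnt
fresh or after a period of decomposition. Bone mineral — bioapatite, a
carbonate-substituted hydroxyapatite — changes measurably within the first
year after death: potassium, sodium and chlorine (the extracellular-fluid
elements) deplete or accumulate as the bone dehydrates, and crystallinity
rises. Burning at calcination temperatures reorders the mineral but leaves
much of the elemental signal intact. This package implements that analysis
as a reusable pipeline:

* **FT-IR**: baseline correction anchored at 450/800/900/1200 cm⁻¹,
  peak-height extraction with the ±5 cm⁻¹ shift rule, the ten standard
  ratio indices — IRSF (crystallinity/splitting factor,
  (h₅₆₅ + h₆₀₅)/h_valley), C/P, BPI, API, C/C, CN/P, CO/CO₃, N/P, APR,
  PHT — and categorical heat markers (β-TCP at 1123 + 547 cm⁻¹, the
  1080–1100 cm⁻¹ extra peak, OH–Cl).
* **EMPA**: zonal oxide-wt% point tables (OC/MC/IC/HC zones),
  detection-limit censoring to exact 0.00, removal of points with
  analytical totals < 50 wt%, oxide→element conversion, Ca/P molar
  ratios, and mean/2SE/CV summaries.
* **Statistics**: z-scoring, per-parameter regression against the
  postmortem interval (PMI), correlation-matrix PCA, Fisher LDA with
  ridge-stabilised scatter and posterior "confidence scores", and MANOVA
  (Wilks' Λ) with pairwise Hotelling T² post hoc tests under Holm
  adjustment.
* **Decision rules**: burnt/unburnt classification (cyanamide-first
  fallback or a fitted LDA), heat-marker temperature banding, and the
  potassium rule — mean elemental K under 0.07 ± 0.01 wt% in the inner
  and mid-cortical zones of burnt bone indicates the bone was *not* burnt
  fresh but after roughly three months or more of surface exposure;
  below-detection K in mid-cortical bone indicates a delay over a year.
* **Synthetic data**: a calibrated generator (spectra as Gaussian band
  sums, EMPA points from anchored element trajectories) reproducing the
  published group structure, so the whole pipeline is testable without
  any restricted specimen data.

## Worked example

A synthetic burnt-bone spectrum (91 days of surface exposure before
burning) ships with the package:

```r
library(bioapatite)

sp <- read_spectrum(system.file("extdata", "synthetic_burnt_spectrum.csv",
                                package = "bioapatite"))
corr <- baseline_correct(sp)
compute_ratios(corr, state = "burnt")
#> <ftir_ratio_record> synthetic-burnt-091d (burnt, PMI 91 d)
#>   IRSF    C/P    BPI    API    C/C   CN/P CO/CO3    N/P    APR    PHT
#> 4.5169 0.1349 0.1936 0.0685 2.8246 0.0684 0.1404     NA     NA 0.3560
```

IRSF ≈ 4.5 is well above the unburnt range (~2.9–3.3): crystallinity
reordered by heat. CN/P ≈ 0.068 flags the cyanamide band that only
appears in burnt bone; N/P and APR are not-applicable because the amide
bands are destroyed by burning. Markers and temperature banding:

```r
m <- detect_markers(corr)
m$extra_peak_1080_1100$present   # TRUE  - common in burnt bone
m$oh_cl_peak$present             # TRUE  - Cl substituting into OH sites
assess_heat_markers(m, "burnt")$band
#> > 600 degrees C reached (OH-Cl substitution band)
```

The potassium rule on zone means (elemental wt%) from the same specimen's
microprobe data:

```r
k_pmi_rule(c(IC = 0.046, MC = 0.044, HC = 0.047, OC = 0.101), "burnt")
#> <pmi_assessment> delayed burn (>= ~3 months surface exposure)
#>   K wt%: IC=0.046 MC=0.044 HC=0.047 OC=0.101 (threshold 0.070 +/- 0.010)
#>   caveat: burial slows dehydration: ...
#>   caveat: OC values are not decisive: the outer cortex can take up potassium from soil
```

IC and MC are both under threshold − band (0.06 wt%), so burning did not
happen fresh; the elevated outer-cortical value (soil uptake) is reported
but never drives the verdict.

The full pipeline — simulate a 64-specimen study, extract ratios, clean
and summarise EMPA points, run the statistical battery, classify every
specimen and write a collated report — is one call:

```r
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
```

or from a shell:
`Rscript inst/scripts/run_pipeline.R --seed 1 --out run1`.

## Documentation

The methods vignette (`vignettes/bioapatite-methods.Rmd`) describes the
models, the calibration of the synthetic generator, every tunable
parameter with units and defaults, the numerical edge cases, and what
passing tests do and do not establish about real assemblages.
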