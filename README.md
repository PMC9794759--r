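# octplaq

Quantitative plaque morphometry and risk modelling for intravascular
optical coherence tomography (IVOCT).

Coronary lesions imaged by IVOCT before stenting carry geometric
signatures — lumen narrowing, calcific deposits, and above all the
fibrous cap (FC) overlying lipid pools — that predict later in-stent
complications such as neoatherosclerosis. `octplaq` implements the full
quantitative chain for this kind of study, for imaging scientists and
interventional-cardiology researchers who want a tested, reproducible
reference implementation that runs without any patient data:

1. **Synthetic data with known truth.** A phantom generator renders
   polar-coordinate pullbacks (rows = A-lines over 0–360°, columns =
   radial samples) with planted lumen contours, calcium deposits and
   fibrous caps, plus the analytic value of every feature; a cohort
   generator draws lesion feature tables with two-group Gaussian
   structure and exact Spearman collinearity blocks via a Gaussian
   copula.
2. **Boundary segmentation.** The FC abluminal boundary appears as a
   gradual bright-to-dark radial intensity transition; it is traced per
   angular window as the global minimum-cost path of a dynamic program
   over the smoothed radial gradient, under a smoothness cap, with ties
   broken toward the thinner (riskier) cap.
3. **Feature extraction.** 17 lesion-level features: lesion length
   *L = n·Δz*; min/mean lumen area and diameter (shoelace polygon area,
   area-equivalent diameter); max/min calcium angle, thickness, depth;
   max/min FC angle; min FC thickness; max FC area; FC surface area
   *S = Σ_frames (covered lumen arc) · Δz*; and FC burden
   *B = Σ (FC cross-sectional area) · Δz / Σ (lumen perimeter) · Δz*.
4. **Statistics.** Student t-test group comparison; Spearman ρ heatmap
   with hierarchical clustering (squared Euclidean distance on the ρ²
   profiles); collinearity pruning at |ρ| > 0.9 keeping the
   smallest-p representative; univariate → multivariate logistic
   regression with odds ratios and 95% Wald CIs; ROC analysis with a
   tie-corrected Mann–Whitney AUC, DeLong CI, and the Youden cutoff
   (max sensitivity + specificity).

## Worked example

The end-to-end demo simulates a pullback phantom (traced and measured),
then a 180-lesion cohort (19 events / 161 controls) in which FC surface
area is the only genuinely predictive feature among six planted
collinearity blocks, and runs the complete statistical chain:

```r
library(octplaq)
rep <- run_pipeline(run_config(seed = 7), out_dir = "demo-run")
#> [octplaq] stage simulate-pullback: rendering phantom
#> [octplaq] stage extract: 10 frames, 10 traced cap windows
#> [octplaq] stage simulate-cohort: 180 lesions (19 pos / 161 neg), 6.27% draws truncated at 0
#> [octplaq] stage select-features: 9 retained, 8 eliminated (|rho| > 0.90)
#> [octplaq] stage analyze: 1 univariate-significant feature(s); AUC(fc_surface_area) = 0.973

rep$multivariate$table[, c("term", "or", "ci_lo", "ci_hi", "p")]
#>              term   or ci_lo ci_hi        p
#> 1 fc_surface_area 1.43  1.23  1.66 2.31e-06
```

Reading: the pruning step eliminated the 8 features that duplicate a
within-block representative (no retained pair has |ρ| > 0.9), and in the
multivariate model a 1 mm² increase in FC surface area multiplies the
odds of neoatherosclerosis by 1.43 (95% CI 1.23–1.66). The ROC block of
the same report gives AUC 0.973 (95% CI 0.941–1.000) with a Youden
cutoff of 17.1 mm² (sensitivity 0.95, specificity 0.93). `demo-run/`
holds the pullback (16-bit TIFF + JSON annotation sidecar), `cohort.csv`,
`selection.json` and the full `report.json`.

A thin CLI wraps the same functions
(`simulate-pullback`, `simulate-cohort`, `extract`, `select-features`,
`analyze`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","octplaq",package="octplaq"))')" \
    run --seed 7 --out demo-run
```

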