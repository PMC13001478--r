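# omiflim

Single-cell **optical metabolic imaging (OMI)** analysis from fluorescence
lifetime imaging (FLIM) decays, in R.

Label-free autofluorescence of the metabolic cofactors NAD(P)H and FAD
carries information about single-cell metabolic state: the lifetime of each
cofactor splits into a short (free) and long (protein-bound) component, and
the balance between them shifts with metabolic activity. This package
implements the full analysis chain used to phenotype peripheral blood
mononuclear cells (PBMCs — T, B, NK cells and monocytes) from such data:

1. **Decay fitting.** Per-pixel TCSPC histograms are spatially binned
   (sliding (2b+1)×(2b+1) photon sum; bin factor 2 for NAD(P)H, 3 for FAD),
   thresholded at a 2,500-photon floor, and fit to a biexponential with
   instrument-response reconvolution by Poisson maximum likelihood:

   *I(t) = α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂) + C*,  τm = (α₁τ₁ + α₂τ₂)/(α₁ + α₂)

2. **Per-cell features.** The 10 OMI variables per segmented cell — NAD(P)H
   and FAD τm, τ₁, τ₂, α₁, the optical redox ratio
   ORR = I_NAD(P)H / (I_NAD(P)H + I_FAD) from summed intensities (bounded in
   [0, 1]), and cell area — with quality-control exclusions (intensity < 10
   a.u., area < 70 px, χ² > 1.3, NAD(P)H τ₁ < 350 ps) and CD69 / CD56
   intensity gating.

3. **Statistics.** Cohen's d effect sizes,
   d = (M₁ − M₂)/√((SD₁² + SD₂²)/2), with the standard
   none/small/medium/large categories; coefficient-of-variation
   heterogeneity; z-scoring and Ward/Euclidean hierarchical clustering.

4. **Classification.** Minority-class undersampling, 70/30 random split,
   one-vs-rest random forests on the 10 OMI variables, with per-class
   ROC/AUC, accuracy, precision/recall, confusion matrices and feature
   importances.

Because raw clinical FLIM images are rarely shareable, the package ships a
first-class synthetic generator: ground-truthed multi-cell fields of view
(two-channel Poisson decay cubes through a Gaussian IRF, label masks, truth
tables) and fast direct sampling of feature cohorts, both driven by
configurable per-cell-type parameter distributions.

## Worked example

```r
library(omiflim)

# a quiescent PBMC cohort: 300 cells per type, 5 types
profiles <- default_pbmc_profiles("quiescent")
cells <- sample_feature_table(profiles, n_per_type = 300, rng_seed = 1)
cells <- qc_filter(apply_qc(cells))

# balanced one-vs-rest random forest on the 10 OMI variables
report <- run_classification(cells, "cell_type",
                             classifier_config(rng_seed = 2))
print(report)
#> <classification_report> accuracy 59.6% over 446 test cells
#>   B              AUC 0.829  precision 0.531  recall 0.537 (n=95)
#>   cytotoxic_T    AUC 0.732  precision 0.391  recall 0.262 (n=103)
#>   helper_T       AUC 0.774  precision 0.326  recall 0.380 (n=79)
#>   monocyte       AUC 0.999  precision 0.973  recall 0.947 (n=76)
#>   NK             AUC 0.976  precision 0.748  recall 0.925 (n=93)

round(head(sort(report$importances, decreasing = TRUE), 3), 3)
#>      area_px nadph_alpha1   fad_alpha1
#>        0.215        0.138        0.120

cohens_d(cells$nadph_tau_m[cells$cell_type == "monocyte"],
         cells$nadph_tau_m[cells$cell_type != "monocyte"])
#> <effect_size> d = -1.901 (large, decrease; n = 298 vs 1193)
```

Reading: monocytes are nearly perfectly separable from lymphocytes (AUC
1.00, driven by their larger area and higher NAD(P)H α₁ and lower τm — the
monocyte-vs-rest τm effect size is large and negative), NK cells moderately
so, while the two T-cell subsets and B cells largely overlap in OMI space —
the qualitative structure such measurements show in practice.

For the image path, `build_scene()` → `fit_image()` (per channel) →
`extract_features()` → `apply_qc()` takes a ground-truthed field of view to
a per-cell feature table; on the default two-type demo scene the per-cell
NAD(P)H τm estimates correlate with ground truth at r ≈ 0.99
(`analysis/02_fit_extract.R`).

## Analysis workflow

Numbered scripts run the whole study on synthetic inputs and write their
tables under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | quiescent + activated cohorts (per-type counts of the imaging study) and one exported FLIM scene |
| `analysis/02_fit_extract.R` | decay-fits both channels of the scene, extracts + QC-filters per-cell features |
| `analysis/03_stats.R` | activation effect-size matrix, heterogeneity (COV) table, Ward clustering with Newick export |
| `analysis/04_classify.R` | cell-type and activation classifiers with full metric reports |
| `analysis/05_gating.R` | CD56 bright/dim and CD69⁺ gating demonstrations |

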