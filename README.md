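# tfivolume

Quantification of the **tumor–fat interface volume** from multiphase breast
MRI, with the complete downstream statistics for evaluating it as a
predictor of pathologic complete response (pCR) to neoadjuvant chemotherapy.

## The problem and who this is for

Adipocytes neighbouring a breast tumor influence it in a paracrine manner,
and a larger volume of direct tumor–fat contact on pretreatment MRI has
been associated with a *worse* pathologic response to neoadjuvant
chemotherapy. The biomarker is defined on a voxel label map (background /
fat / fibroglandular tissue / tumor) derived from dynamic contrast-enhanced
breast MRI:

> **interface volume** = (number of fat voxels with at least one tumor
> voxel among their 6 face-adjacent 3D neighbours) × voxel volume, in cm³.

This package is for imaging scientists and biostatisticians who want to
reproduce, validate, or extend that measurement chain and its statistical
evaluation. The original patient cohorts (development n = 1004, external
validation n = 136) are private, so the package ships:

* a **phantom generator** producing multiphase breast-MRI studies
  (fat-suppressed pre-contrast, post-contrast, subtraction) with exact
  voxel-level ground truth;
* the **measurement front end**: chest-wall surface interpolation from
  every-fifth-slice contours, breast search-region masking, two-stage
  k-means tissue clustering (fat vs non-fat on the pre-contrast channel,
  then tumor vs fibroglandular on the subtraction channel), and 6-adjacency
  interface counting;
* a **cohort simulator** with a configurable logistic outcome model for
  parameter-recovery studies;
* the **statistical toolbox** used to evaluate the biomarker: Youden's J
  dichotomization, 2×2 and logistic-regression odds ratios with Wald CIs,
  the p < 0.05 univariable entry rule with VIF screening, the DeLong test,
  continuous NRI and IDI, AIC comparison of nested models, Spearman
  correlation, and ICC(2,1) interobserver agreement;
* the **published contingency counts** of the originating cohorts, from
  which every unadjusted odds ratio and pCR rate of the original report is
  recomputable exactly.

## Worked example

Generate a phantom, run the measurement chain, and compare an odds ratio
against the published counts:

```r
library(tfivolume)

cfg <- phantom_config(seed = 42)           # 64 x 128 x 128 at 3 x 0.8 x 0.8 mm
ph <- generate_phantom(cfg)
wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
mask <- build_breast_mask(ph$study, wall)
labels <- cluster_tissues(ph$study, mask, seed = 42)
summarize_volumes(labels)[, 1:5]
#>   breast_volume_cm3 fat_volume_cm3 fgt_volume_cm3 tumor_volume_cm3 interface_volume_cm3
#> 1            358.61         219.16         132.61             6.84                 2.19
ph$truth$true_volumes$interface_volume_cm3
#> [1] 1.8

counts <- reported_counts()
dev <- counts[counts$variable == "interface_group" & counts$cohort == "development", ]
odds_ratio_2x2(dev$a, dev$b, dev$c, dev$d)
#> OR 1.626 (95% CI 1.242-2.127)
```

The measured interface (2.19 cm³ here, truth 1.80 cm³) illustrates the one
caveat of the default noisy setting: the interface is a one-voxel-thin
shell, so it is the most noise-sensitive of the five volumetric quantities
(per-tissue Dice stays above 0.94). On noiseless phantoms every quantity,
including the interface, is recovered exactly. The odds ratio reproduces
the published development-cohort value: high tumor–fat interface carries
1.626 times the odds of *not* achieving pCR.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
re-implementation; each is a thin narrative over package functions and
writes its tables under `results/`:

| script | what it does |
|---|---|
| `01_phantom_imaging.R` | phantom batch through the measurement chain; recovery vs ground truth |
| `02_cohort_tables.R` | simulated development/validation cohorts; Youden cutoff; descriptive tables |
| `03_regression_models.R` | univariable screen → VIF → multivariable model, both cohorts |
| `04_model_comparison.R` | conventional vs interface-augmented model: DeLong, NRI, IDI, AIC |
| `05_agreement_and_reported_values.R` | simulated two-reader ICC study; odds ratios from the published counts |

Run them in order with `Rscript analysis/01_phantom_imaging.R` etc.
`run_pipeline()` performs the cohort stages as one seeded, reproducible
call (`run_config()` controls sizes, cutoff policy, and output directory).

## Documentation

The methods vignette
(`vignettes/tumor-fat-interface-methods.Rmd`) documents the models and
their assumptions, every fixed convention (event coding, cutoff ties,
ICC form, continuous NRI), the phantom's idealizations and what passing
tests do and do not demonstrate about clinical data, and known limitations.
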