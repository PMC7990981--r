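# petref

Reference-region selection for intensity normalization of brain
^18^F-FDG PET.

## The problem

Brain FDG-PET images are only comparable across subjects after dividing by
the uptake of a reference region (proportional scaling, SUVr). For studies
of healthy ageing this choice is delicate: glucose metabolism declines with
age in almost every brain region, so a reference that declines too absorbs
or inverts the very signal being measured. `petref` implements a data-driven
selection procedure and the voxelwise analysis used to validate it, for
researchers choosing a normalization strategy for semi-quantitative brain
PET.

## The method

Given a subjects × regions matrix of mean regional uptake *M*, for every
candidate reference region *r*:

1. compute SUVr: *S⁽ʳ⁾ᵢₖ = Mᵢₖ / Mᵢᵣ*;
2. correlate every target region's SUVr with age (Pearson), filling one row
   of a reference × target correlation grid (the self-normalized diagonal is
   undefined and excluded);
3. score each reference by the **median** and the **strongest (most
   negative)** coefficient of its row.

References with **median r < −0.5** are selected and grouped into anatomical
structures (cerebellar lobes + vermis → cerebellum; pons → pons). The
short-listed normalizations are then compared with a mass-univariate
voxelwise linear model (age + sex covariates, one-sided decline contrast),
permutation max-T family-wise error control, 26-connectivity cluster
labelling and mm³ cluster volumetrics.

Because the underlying clinical scans are not distributable, the package
also ships a seeded synthetic-cohort generator (regional linear decline, a
planted age-stable region, per-subject lognormal global factors, additive
noise, scanner-resolution Gaussian smoothing, demographic presets for a
conventional n = 56 and a digital n = 78 control cohort) and a packaged
plain-text fixture of the published 120-region per-reference correlation
summaries for both PET systems.

## Worked example

Apply the selection rule to the packaged table of published per-reference
summaries (digital PET system):

```r
library(petref)
fix <- load_table1_fixture()
sel <- select_references(fixture_summary(fix, "digital"))
sel
#> selection_result: 6 region(s) with median r < -0.5
#>   regions:    Cerebelum_8_L, Cerebelum_8_R, Vermis_8, Cerebelum_9_L, Pons, Cerebelum_9_R
#>   structures: cerebellum, pons
head(sel$ranking, 3)
#>          region strongest_r   median_r
#> 1 Cerebelum_8_L  -0.8236969 -0.6309730
#> 2 Cerebelum_8_R  -0.8125311 -0.6184692
#> 3      Vermis_8  -0.7902190 -0.6164437
```

Six regions pass the median < −0.5 rule in the digital cohort; at structure
level the candidates are exactly **cerebellum** and **pons**. Comparing the
published significant cluster volumes of the short-listed normalizations
(conventional system):

```r
significant_volume_report(
  c(pons = 143330, cerebellum = 84216, whole_grey_matter = 41528),
  t_max = c(pons = 10.2, cerebellum = 9.8, whole_grey_matter = 8.3))
#>           reference total_significant_mm3 t_max fold_vs_top
#> 1              pons                143330  10.2    1.000000
#> 2        cerebellum                 84216   9.8    1.701933
#> 3 whole_grey_matter                 41528   8.3    3.451406
```

Pons normalization exposes 1.7× the significant age-related volume of
cerebellum normalization and 3.5× that of whole-grey-matter scaling.

The same machinery runs end to end on a synthetic cohort with a planted
age-stable region:

```r
atl <- build_toy_atlas(c(32, 40, 32), c(4, 4, 4), n_regions = 12, seed = 1)
cfg <- cohort_preset("digital", seed = 1)
model <- ageing_model_for_atlas(atl, stable_regions = "Pons", seed = 1)
gen <- generate_cohort(atl, cfg, model)
mat <- uptake_matrix_from_volumes(gen$volumes, gen$meta, atl)
head(rank_references(summarize_reference(compute_correlation_grid(mat))), 3)
#>   region strongest_r   median_r
#> 1   Pons  -0.8413618 -0.6432994
#> 2   R006  -0.6260201 -0.3211409
#> 3   R009  -0.5617313 -0.2467082
```

The planted stable region is recovered as the top-ranked reference, with a
median far below every declining region's.

A full pipeline run (simulate → extract → grid → score → GLM → report) with
all artifacts written to disk:

```r
run_pipeline(default_pipeline_config(seed = 1), out_dir = "petref_run")
# or from a shell:
#   Rscript inst/scripts/run_pipeline.R --out petref_run --seed 1
```

See `vignettes/reference-region-selection.Rmd` for the model, parameter
defaults and numerical conventions.

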