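# ki67ck

Quantitative multispectral imaging analysis of the Ki67 proliferation marker
in breast-cancer tissue, with survival-based biomarker grading.

## The problem

Ki67 labels cycling tumour cells and is one of the standard prognostic
markers in breast cancer, but scoring it by eye (percent-positive nuclei) is
notoriously irreproducible. An alternative is multiplexed quantum-dot (QD)
immunofluorescence: nuclear Ki67 and cytoplasmic cytokeratin (CK, a mask for
all carcinoma cells) are stained with QDs emitting at 605 nm and 525 nm, a
multispectral camera records a 21-band cube (450–650 nm, 10-nm steps) for
each tissue-microarray core, and the per-core totals of unmixed Ki67 and CK
signal define a machine-read proliferation statistic — the **Ki67/CK ratio**
— that replaces the manual percentage. This package implements that analysis
chain end to end for imaging scientists and biostatisticians, together with
a synthetic-data module so every stage is testable without any microscope.

## What it computes

- **Spectral unmixing.** Each pixel spectrum `y` (21 bands) is decomposed
  over the endmember matrix `E = [e_CK, e_Ki67, e_AF]` by non-negative least
  squares, `a* = argmin_{a ≥ 0} ||E a − y||₂`, solved exactly by active-set
  enumeration and vectorised over pixels. The autofluorescence component is
  deleted before quantification.
- **Quantification.** Per view field, Ki67 signal = Σ ki67-abundance and CK
  signal = Σ ck-abundance over supra-threshold pixels; six fields are summed
  into the per-core `Ki67 sum`, `CK sum`, and `ratio = Ki67 sum / CK sum`
  (values above 1 are legitimate).
- **Best-P grading.** A biomarker is dichotomised at the observed value `c`
  maximising the two-group log-rank statistic for `value ≤ c` vs `value > c`
  (both groups ≥ 10% of patients), i.e. the X-tile-style best-P principle.
  Because the scan selects the minimal p, the raw p is reported alongside the
  Miller–Siegmund corrected p for maximally selected statistics.
- **Survival evaluation.** Kaplan–Meier curves and log-rank tests per grade,
  multivariate Cox proportional-hazards models (Breslow ties) reporting
  HR (95% CI), and ROC/AUC for five-year recurrence with Hanley–McNeil
  confidence intervals.
- **Synthetic data.** Spectral scenes (elliptical CK-positive tumour nests
  containing Ki67-positive nuclei at a controlled proliferation fraction,
  plus autofluorescence and Gaussian noise) with exact ground-truth sums, and
  patient cohorts whose five-year disease-free survival follows a
  proportional-hazards model on the Ki67/CK ratio.

## Worked example

```r
library(ki67ck)

# image branch: one synthetic core, six fields, default study conditions
lib  <- build_default_library()
core <- simulate_core(scene_params(seed = 42), lib, n_fields = 6)
fields <- lapply(core$cubes, function(cb)
  quantify_field(drop_autofluorescence(unmix_cube(cb, lib))))
aggregate_core(fields)
#> core (6 fields): Ki67 sum 6.2783e+06, CK sum 1.52475e+07, Ki67/CK ratio 0.4118
core$truth$true_ratio      # ground truth: 0.4077 (recovered within ~1%)

# cohort branch: grade the ratio by its best-P cut-point and evaluate it
co  <- simulate_cohort(cohort_params(seed = 42))   # 240 patients, 60 months
cut <- optimal_cutpoint(co$ki67_ck_ratio, co$dfs_months, co$event)
cut
#> best-P cut-point: 0.174274 (chi-square 17.610, raw p 2.71e-05, corrected p 0.0011)
#>   groups: 122 low (grade I) / 118 high (grade II), 193 candidates scanned

g <- assign_grade(co$ki67_ck_ratio, cut$cutoff)
cox_fit(co$dfs_months, co$event, data.frame(
  n_stage = co$n_stage, histo_grade = co$histo_grade,
  ratio_grade_ii = as.integer(g == "II")))
#> Cox proportional-hazards fit (66 events, log-likelihood -338.764)
#>            term          HR (95%CI)        p
#>         n_stage 1.140 (0.924-1.407) 2.22e-01
#>     histo_grade 1.095 (0.763-1.572) 6.22e-01
#>  ratio_grade_ii 3.037 (1.779-5.184) 4.68e-05

ro <- roc_outcome(co$dfs_months, co$event)         # recurrence within 60 months
roc_auc(as.integer(g == "II")[ro$keep], ro$outcome)
#> ROC: AUC 0.662 (95%CI 0.580-0.744), p = 9.847e-05 (66 cases / 152 controls)
```

Reading the numbers: the recovered core ratio (0.4118) matches the noise-free
ground truth (0.4077) to about 1%, the scan dichotomises the cohort near the
hazard model's true threshold, and grade II carries a significantly elevated
recurrence hazard — the corrected p guards against the optimism of scanning
193 candidate cut-points.

The whole chain is also available as one call, `run_pipeline(config)`, or
from the shell via the bundled CLI
(`Rscript inst/cli/ki67ck.R run-all --config inst/extdata/demo_config.yaml
--seed 1 --out out/`), with subcommands for each stage (`simulate-images`,
`simulate-cohort`, `unmix`, `quantify`, `grade`, `run-all`).

Real cohort tables (one row per patient with `ki67_sum`, `ck_sum`,
clinico-pathological covariates and DFS follow-up) are ingested with
`read_cohort_table(path, column_map = ...)`; rows failing validation are
rejected with row-level log messages.

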