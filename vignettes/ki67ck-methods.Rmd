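---
title: "Methods: multispectral Ki67/CK quantification and survival grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral Ki67/CK quantification and survival grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67ck)
```

## The measurement model

A multispectral acquisition of a QD-stained tissue core records, for each
pixel, an emission spectrum sampled on 21 bands from 450 to 650 nm in 10-nm
steps. Under the linear mixing model the pixel spectrum is

  y = a_CK · e_CK + a_Ki67 · e_Ki67 + a_AF · e_AF + ε,

where the endmembers e are the reference emission spectra of the CK-bound
525-nm quantum dot, the Ki67-bound 605-nm quantum dot and broadband tissue
autofluorescence, the abundances a ≥ 0 carry the intensity scale (arbitrary
units), and ε is detector noise. Unmixing inverts this model per pixel by
non-negative least squares (NNLS):

  a* = argmin_{a ≥ 0} ‖E a − y‖₂.

With only three endmembers the exact optimum is found by enumerating all
column subsets: the NNLS optimum restricted to its active support satisfies
the normal equations on that support, so it must coincide with one of the
2³ unconstrained least-squares subset solutions that happens to be
non-negative, and among the feasible candidates the one with the smallest
residual is the global optimum of the convex objective. `unmix_cube()`
evaluates this enumeration in vectorised form (eight small matrix solves for
the entire image), which is both exact and fast. The residual is recomputed
directly as ‖E a* − y‖ afterwards, because the expanded quadratic form used
for fast subset comparison loses precision to cancellation near zero.

The autofluorescence component is retained through unmixing (it is needed to
explain the background signal) and deleted immediately before
quantification, mirroring the background-elimination step of the commercial
acquisition workflow the model emulates. No spatial regularisation is
applied: pixels are unmixed independently.

### Endmember spectra

Only the QD peak wavelengths are knowable; measured spectral shapes of the
QD conjugates and of tissue autofluorescence are not published anywhere we
can draw from, so the library is parametric: Gaussians with 30 nm FWHM for
both QDs (a typical QD emission width) at 525 and 605 nm, and a broad
Gaussian (peak 500 nm, FWHM 150 nm) for autofluorescence. The 525 and 605 nm
peaks fall between grid bands (bands sit at …520, 530… and …600, 610…), so
each sampled spectrum is renormalised to a maximum of exactly 1; a pure
pixel's abundance then equals its peak signal intensity. The default library
is well conditioned (condition number ≈ 3), so unmixing is stable; the
constructor refuses libraries whose columns are collinear.

## Quantification

Per view field, the Ki67 signal is the sum of the unmixed Ki67 abundance
over all pixels above a threshold (default 0), and likewise for CK; counts
of supra-threshold pixels are carried along as diagnostics. "Signal" is
interpreted as summed intensity rather than a binary pixel count because the
quantity of interest is total fluorescent signal; both readings are
available in `field_quant`. Six fields are summed into the per-core Ki67
sum and CK sum, and the proliferation statistic is their ratio. Cores with
zero CK sum are rejected as degenerate rather than imputed. The ratio is
scale-free: multiplying a cube by c > 0 multiplies both sums by c and leaves
the ratio unchanged (tested as an invariant).

## Best-P grading

A continuous biomarker is dichotomised by scanning every observed value c
whose split (value ≤ c vs > c) leaves at least 10% of patients in each
group, computing the two-group log-rank chi-square at each candidate, and
keeping the maximiser (ties break to the smaller cut-point, so the reported
cut-off is always an attainable patient value). The 10% guard is the usual
X-tile-style protection against extreme splits. Because the minimal p from
such a scan is optimistically biased, the Miller–Siegmund correction

  p_corr = φ(z)(z − 1/z) · log[ ε_hi(1−ε_lo) / (ε_lo(1−ε_hi)) ] + 4φ(z)/z,
  z = Φ⁻¹(1 − p_raw/2),

is reported alongside the raw p, with ε_lo/ε_hi the smallest and largest
scanned low-group fraction; the result is clamped into (p_raw, 1]. In null
simulations (no true effect, 50 replicates) the raw minimal p rejects at
α = 0.05 far above nominal while the corrected p stays below 10%; both
behaviours are asserted in the test suite. No training/validation split is
applied by default — the scan runs on the full cohort, matching the
clinical workflow this package reproduces; users wanting honest effect
estimates after selection should validate on independent data.

## Survival statistics

Kaplan–Meier estimation, the log-rank test and the Cox model are delegated
to the `survival` package behind tidy wrappers (`km_fit`, `logrank_test`,
`cox_fit`); the cut-point scan uses an internal fast two-group log-rank
chi-square that is verified against `survival::survdiff` to 1e-10. Cox
models use Breslow tie handling by default (the convention of the clinical
statistics software this analysis style comes from; Efron is available) and
Wald intervals exp(b ± 1.96·se). Covariates for the multivariate model are
coded as integer scores for ordered stages (T 1–3, N 0–3, histological
grade 1–3) and 0/1 indicators for ER, HER2 and biomarker grade II, so each
factor reports a single per-increment HR.

ROC analysis targets recurrence within a 60-month horizon. The AUC is the
Mann–Whitney concordance probability with ties counted half, its confidence
interval uses the Hanley–McNeil standard error, and the p-value tests
AUC = 0.5. Subjects censored before the horizon have unknown 60-month
status and are excluded with a logged count; this choice (rather than, say,
inverse-probability weighting) keeps the estimand simple and is stated
rather than hidden.

## Synthetic data: what it emulates and what it does not

`simulate_field()` draws elliptical CK-positive tumour nests (rejection
sampling keeps centres apart; if the frame cannot hold the requested count
the number is reduced with a warning), fills each nest with nuclei and marks
each nucleus Ki67-positive with probability `proliferation_fraction`, adds a
constant autofluorescence layer, and renders the cube through the endmember
matrix plus additive Gaussian noise clipped at zero. Ground-truth sums come
from the noise-free abundance maps, so the true ratio is independent of the
noise and autofluorescence settings by construction. Positivity is drawn as
`runif(n) < p`, so for a fixed seed the positive set grows monotonically
with p — the monotonicity of the recovered ratio in the proliferation
fraction is then an exact property, not a statistical one. Per-field seeds
inside a core are `seed + field index`, keeping cores reproducible while
fields stay independent.

Default scene parameters emulate a tumour-dense 100× core view on a
256 × 256 px field: six nests with 28–48 px semi-axes (≈ 40–50% frame
coverage), nuclei of radius 3 px at 0.03 nuclei/px² (nuclei occupy ~85% of
nest area — carcinoma nests are packed epithelial sheets), proliferation
fraction 0.25 (a mid-range Ki67 index for breast cancer), amplitudes CK 100,
Ki67 200, autofluorescence 10 a.u., and noise sd 1 (1% of the CK amplitude).
Tissue density matters quantitatively: NNLS non-negativity rectifies noise
on true-zero Ki67 pixels into a small positive bias (≈ 0.4σ per zero pixel),
so the relative error of the recovered ratio scales with the zero-pixel to
signal-pixel balance. At the defaults the end-to-end ratio error is ≈ 1%;
in very sparse scenes it would be larger. The simulator does not attempt
histological realism: no texture, no in-situ vs invasive architecture, no
stromal Ki67 (observed rarely in real tissue), no detector response,
photobleaching or QD blinking. Passing tests therefore demonstrate the
correctness of the computational chain under the linear mixing model, not
robustness to every real-world artefact.

`simulate_cohort()` draws the Ki67/CK ratio and the CK sum as independent
log-normals and event times from an exponential proportional-hazards model:
hazard = `baseline_hazard · exp(log_hr · 1[ratio > true_cutoff])`, censored
by the minimum of an exponential censoring time and the 60-month follow-up.
Defaults describe a 240-patient cohort with median ratio 0.186 and median
Ki67 sum 2.30 × 10⁷ (log-sd 1.6 and 0.8, set from the spanned ranges of
such cohorts), threshold 0.186, log HR = ln 2, baseline hazard 0.004/month
(≈ 21% vs 38% five-year event risk by group) and censoring hazard
0.002/month. Clinico-pathological covariates (age, menopausal status, T, N,
histological grade, ER, HER2) are drawn from realistic marginal frequencies
only; their joint dependence with the ratio is deliberately not modelled —
the covariates exist so that multivariate pipelines are exercised, not to
claim a dependence structure nobody has measured. In real cohorts the Ki67
sum and CK sum are correlated (both scale with tumour cellularity); the
independence assumption here slightly widens the simulated Ki67-sum
distribution.

## Numerical and design choices

- **Cut-point ties** break to the smaller candidate; candidates are observed
  values, so reported cut-offs are attainable.
- **Raw p floors**: the scan floors p_raw at the smallest positive double
  before correction, so astronomically significant scans do not produce 0.
- **Cube container**: the canonical `.scube` file is a gzipped JSON-header +
  little-endian-double container and round-trips bit-exactly; the TIFF
  dialect stores 32-bit samples scaled by a power of two into [0, 1]
  (resolution ≈ 2⁻³¹ of the cube maximum, scale in a JSON sidecar) and
  exists for interoperability with image viewers.
- **Negative intensities** (possible in background-subtracted real data) are
  clipped to zero before unmixing with a logged count.
- **Degenerate inputs**: empty field lists, zero CK sums, all-identical
  biomarkers, zero events, single-class ROC outcomes and rank-deficient
  libraries all raise typed errors rather than propagating NaN.
- **Problem sizes** used by the test-suite and the acceptance script — six
  256 × 256 × 21 fields per core, nine proliferation settings, cohorts of
  240–1000 patients, 50 null replicates, 10,000 permutations — were chosen
  as the smallest sizes at which the statistical assertions have comfortable
  power.

## Known limitations

- Ingestion accepts CSV/TSV with a user-supplied column map; legacy XLS
  must be exported to CSV first.
- The best-P scan searches a single cut-point (two grades); the original
  X-tile three-category search and its matrix display are out of scope.
- No proportional-hazards diagnostics, time-dependent ROC or competing
  risks.
- Endmember spectra are parametric stand-ins; analyses of real cubes should
  replace them with measured reference spectra via `endmember_library()`.
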