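---
title: "Inter-subject functional connectivity: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject functional connectivity: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfcr)
```

## The problem

When several people watch the same movie in an MRI scanner, part of each
brain region's BOLD fluctuation is locked to the stimulus and therefore
shared across viewers, while the rest is intrinsic or noise. Ordinary
within-subject functional connectivity mixes the two. Inter-subject
functional connectivity (ISFC) separates them by correlating region *i* in
one subject with region *j* in a *different* subject: intrinsic dynamics and
scanner noise are independent across brains, so only stimulus-driven
coupling survives. The special case *i = j* is the inter-subject correlation
(ISC) of a single region.

`isfcr` implements a complete two-group ISFC comparison pipeline:
post-fMRIPrep confound cleaning of regional time series, pairwise ISFC with
median group summaries, a subject-wise permutation test of group
differences, and cross-dataset replication statistics. Because clinical
naturalistic-fMRI datasets are rarely shareable, the package also ships a
synthetic multi-subject generator with a closed-form expected-ISFC oracle,
and every statistical component is validated against that oracle.

## Pairwise ISFC and the median summary

For subjects $a \ne b$ with cleaned, standardized series $x^{(a)}, x^{(b)}
\in \mathbb{R}^{T \times R}$, the raw cross-subject correlation matrix is
$C^{(ab)}_{ij} = \mathrm{corr}(x^{(a)}_{\cdot i}, x^{(b)}_{\cdot j})$.
Direction of coupling is not analyzed, so each pair matrix is symmetrized as
$(C + C^\top)/2$ before any summary. For a group of $n$ subjects all
$n(n-1)/2$ unordered pairs are computed ("pairwise" ISFC, as opposed to
leave-one-out averaging), and the group summary is the entrywise **median**
across pair matrices — robust to the non-normal, heavy-tailed distribution
of correlation values across pairs. For an $R$-region atlas the symmetric
summary holds $R(R-1)/2$ unique off-diagonal values (`unique_pair_count(273)`
= 37,128).

Two deliberate conventions:

* **Symmetrize per pair, then take the median.** The median of symmetrized
  matrices is not identical to symmetrizing a median matrix; the per-pair
  order matches the definition of an undirected pair estimate.
* **No Fisher z-transform before the median.** The median is equivariant
  under monotone transforms, so the median of correlations equals the
  back-transformed median of z-values; transforming would only add numerical
  noise.

Diagonal (ISC) values are computed and stored but excluded from the unique
pair accounting, the significance masks, and all replication statistics.

## Confound cleaning

The cleaning chain mirrors common post-fMRIPrep practice. For each subject,
a single joint least-squares fit per region removes: an intercept, a linear
trend, the six rigid-body motion parameters, mean white-matter and CSF
signals, and a discrete cosine high-pass basis with
$K = \lfloor 2\,T\,\mathrm{TR} / \mathrm{cutoff} \rfloor$ non-constant
columns (cutoff 128 s, the fMRIPrep default; the basis columns are mutually
orthogonal). All regressors are fitted **jointly in one pass** because
sequential residualization is order-dependent. Residuals are then shifted to
zero mean and scaled to unit sample standard deviation (denominator
$T-1$). Constant nuisance columns are dropped before the fit (they are
spanned by the intercept); a genuinely rank-deficient design or a region
with zero residual variance is an error that names the offending columns.

Subject exclusion uses Power-style framewise displacement computed from the
motion parameters: $\mathrm{FD}_t = \sum |\Delta \mathrm{trans}_t| +
50\,\mathrm{mm} \cdot \sum |\Delta \mathrm{rot}_t|$, with
$\mathrm{FD}_1 = 0$. A subject is excluded when mean FD exceeds 0.5 mm
**strictly** — a subject exactly on the threshold is retained (the boundary
is a convention; the strict rule is recorded in the exclusion report either
way). Exclusion is applied per run; multi-run aggregation is out of scope.

## Subject-wise permutation inference

The observed statistic per region pair is the difference of within-group
median ISFC (first group minus second; `neurotypical - autism` in the
pipeline defaults). The null model shuffles **whole subjects'** group labels
— never time points — preserving within-subject temporal structure and
group sizes. Because every pooled subject pair's matrix is precomputed
(`pooled_pair_tensor()`), each of the 5000 default permutations only
re-selects within-group pair columns and re-medians them.

Significance is two-sided at the per-pair level: a difference is significant
at $\alpha$ when it exceeds the $1 - \alpha/2$ percentile or falls below the
$\alpha/2$ percentile of that pair's own permutation null (97.5th/2.5th for
$\alpha = .05$; 99.5th/0.5th for the stricter $\alpha = .01$ map). Per-pair
p-values use the add-one convention $(1 + \#\{|null| \ge |obs|\})/(1 + P)$,
so they are never zero. No multiple-comparison correction is applied — mask
files record $\alpha$ and the permutation count so downstream users can
judge the uncorrected maps. Design choices worth stating:

* Null percentiles are **per pair**, not pooled across pairs, consistent
  with element-level significance calls.
* Label shuffles are drawn uniformly with replacement; when the number of
  distinct assignments is at most the requested permutation count the test
  switches to exhaustive enumeration automatically (with a warning).
* Unequal group sizes are preserved in every shuffle.

Per-ROI count maps summarize each region's number of significantly
positive and negative connections. The same permutation machinery, applied
to a scalar statistic, tests group differences in inter-subject motion
coupling (pairwise correlation of FD series) — a control analysis that
rules out stimulus-locked head motion as a driver of apparent ISFC effects.

## Replication across datasets

One dataset is labelled *discovery*, the other *replication*; the choice is
explicit in the run configuration because it defines the denominator of the
replication rate. A region pair replicates when it is significant in both
datasets **at identical region indices and with the same sign** — the
signed overlap matrix takes values in $\{-2,\dots,+2\}$ and only $\pm 2$
counts. The replication rate is the number of such cells divided by the
number of significant discovery pairs (diagonal excluded from both).

Chance overlap is assessed with an ROI-shuffle null: one random region
permutation is applied simultaneously to the rows and columns of the
replication mask (discovery held fixed — either choice gives the same null
distribution; fixing one is reproducible), the rate is recomputed, and the
p-value is the add-one exceedance proportion over 5000 shuffles by default.
The same null provides a two-sided permutation p for the Pearson
correlation between the two datasets' difference matrices over the unique
upper-triangle values. The ROI shuffle is a plain label permutation; it
does not preserve spatial autocorrelation, and anatomically informed
("spin") nulls are deliberately out of scope.

## The synthetic generator

The generator emulates the essential causal structure of naturalistic
two-group fMRI without pretending to be a biophysical simulator. All
subjects share one draw of a latent stimulus signal $u \in \mathbb{R}^{T
\times R}$ with cross-region correlation $\Sigma_u$ (unit diagonal,
positive semidefinite) and AR(1) temporal coloring with coefficient
$e^{-1/\text{smoothness}}$ applied uniformly to all regions — uniform
coloring preserves $\Sigma_u$ exactly. Subject $s$ of group $g$ observes

$$x^{(s)}_{tr} = w_{g,r}\, u_{tr} + \sigma\, \varepsilon^{(s)}_{tr},
\qquad \varepsilon \sim \mathcal{N}(0, 1) \text{ i.i.d.},$$

with region weights $w_g \in [0,1]^R$. Group differences are planted
through the weights rather than group-specific $\Sigma_u$, so the latent
stimulus remains genuinely shared across groups — exactly the logic that
makes ISFC interpretable. Because latent signals have unit variance,
$\sigma$ reads directly as a noise-to-signal ratio. The model admits a
closed-form population ISFC between two different subjects of one group:

$$\rho_{ij} = \frac{w_i w_j \Sigma_{u,ij}}
{\sqrt{(w_i^2 + \sigma^2)(w_j^2 + \sigma^2)}},$$

which `expected_pairwise_isfc()` evaluates and every downstream validation
uses as its oracle. `build_dataset()` also enumerates the planted pairs —
all $(i,j)$ where the two groups' expected ISFC differ by more than
$10^{-12}$, signed as first minus second group.

Simulated motion consists of six random-walk parameters per subject
(rotation steps 1/50 of translation steps), rescaled so mean FD hits its
target exactly — mean FD is linear in a global step-size factor, so the
rescaling is closed-form rather than iterative. White-matter and CSF
nuisance signals are autocorrelated noise independent of the stimulus, and
motion is independent across subjects.

### Default conditions

The defaults describe a small two-group naturalistic study and are fixed
once:

| parameter | default | why |
|---|---|---|
| `n_regions` | 15 | desk-scale stand-in for a parcellation; statistics scale combinatorially, not anatomically |
| `n_timepoints`, `tr_seconds` | 300, 2 s | a ~10-minute movie run |
| `group_sizes` | 19, 18 | a realistic post-exclusion two-group cohort |
| `stimulus_correlation` | compound symmetry 0.3 | moderate stimulus-driven coupling everywhere |
| `weights` | 0.7 baseline; regions 1–5 at 0.9 vs 0.4 | plants inter-subject hypoconnectivity in group 2; maximal expected median-ISFC gap ≈ 0.09, the order of magnitude reported in adult autism movie-fMRI comparisons |
| `noise_sd` | 1 | idiosyncratic signal as strong as the shared signal — ISC ≈ 0.2–0.45, typical of naturalistic fMRI |
| `smoothness` | 2 TR | BOLD-like temporal autocorrelation |
| `motion_mean_fd` | 0.15 / 0.25 mm | second group moves more, as commonly observed |
| `high_mover_fraction` | 0.1 | a minority of subjects crosses the 0.5 mm exclusion threshold |

### What passing tests do and do not show

The generator has Gaussian, temporally stationary signals, linear mixing,
and noise that is independent across regions and subjects. Passing
validation therefore demonstrates that the *statistics* are implemented
correctly and calibrated under exchangeability — it does **not**
demonstrate robustness to hemodynamic nonlinearity, spatially correlated
noise, global signal fluctuations, non-stationary engagement, or
motion-correlated artifacts in real BOLD data. The motion tables feed the
cleaning and exclusion code paths but are not injected into the BOLD
signal, so the pipeline's ability to *remove* motion artifact from data is
exercised only at the interface level.

## Validation experiments and numerical choices

The test suite runs these experiments (sizes chosen to make each check
sharp at desk scale):

* **Oracle equivalence.** The cross-product fast path for pairwise ISFC
  agrees with a naive per-entry Pearson double loop to $10^{-10}$; the
  confound fit agrees with an independent normal-equations solve to
  $10^{-8}$.
* **Closed-form recovery.** Median pairwise ISFC at $T = 2000$, $n = 12$
  per group matches $\rho_{ij}$ entrywise within $\pm 0.03$, and the hand
  case $w_i = w_j = 0.8$, $\Sigma_{u,ij} = 0.5$, $\sigma = 0.6$ recovers
  $0.64 \cdot 0.5 = 0.32$. This experiment uses a white latent
  (`smoothness = 0`): AR(1) coloring with coefficient $\phi$ inflates the
  sampling variance of correlations by $(1+\phi^2)/(1-\phi^2) \approx 2.2$
  at the default smoothness, and because the single latent draw is shared
  by all subjects its realization error cannot be averaged away — the
  white-latent design isolates the oracle comparison at its nominal
  sampling error, while the coloring's correlation-preservation is tested
  separately.
* **Type-I calibration.** Over 200 null datasets (equal weights, $R = 15$,
  $T = 200$, $n = 10 + 10$, 500 permutations) the mean per-pair rejection
  rate at $\alpha = .05$ must lie in $[0.03, 0.07]$.
* **Power.** With weights 0.9 vs 0.3 on 5 of 15 regions ($\sigma = 1$,
  $T = 1000$, $n = 15 + 15$, 1000 permutations), at least 80% of planted
  pairs must be flagged positive at $\alpha = .05$.
* **Replication calibration.** Identical sparse masks give rate 1.0 with
  ROI-shuffle $p \le .01$; for independent random masks the mean null rate
  matches the analytic chance expectation (half the replication-mask
  density per sign-matched cell) and the p-values are uniform
  (Kolmogorov–Smirnov over 200 simulations).
* **Determinism.** Any command re-run with the same seed produces
  byte-identical artifacts (matrices are written with 17 significant
  digits so doubles survive the text round trip exactly).

Other numerical conventions: correlations are computed on standardized
columns via the cross-product identity; permutation null percentiles use
R's default type-7 quantile interpolation; eigendecomposition (not
Cholesky) factorizes $\Sigma_u$ so positive *semi*-definite matrices with
zero eigenvalues are accepted and indefinite ones are rejected by naming
the offending eigenvalue; the even-pair-count median is the midpoint of
the two central order statistics.

## A worked example

```{r example, eval = FALSE}
library(isfcr)
cfg <- default_run_config(seed = 1, output_dir = "isfc_run",
                          n_permutations = 1000, n_shuffles = 1000)
res <- run_pipeline(cfg)
res$replication_summary
```

The run simulates a discovery and a replication dataset under the default
conditions, cleans them, tests group differences in each, and writes all
artifacts (median ISFC matrices, difference maps, signed masks, per-ROI
count maps, the overlap matrix, and JSON sidecars recording seeds and
sizes) under `isfc_run/`, finishing with the replication rate, its
ROI-shuffle p-value and the cross-dataset correlation.

## Limitations

* The pipeline consumes ROI-by-time tables; voxel-level preprocessing,
  atlas construction and NIfTI handling are upstream concerns.
* Only undirected, static ISFC is computed — no lagged or sliding-window
  variants.
* Significance is uncorrected by design; users needing family-wise control
  should treat the masks as descriptive.
* Covariate adjustment of pair-level group differences (age, sex,
  education) is not implemented: mapping subject-level covariates onto
  subject-pair statistics is ambiguous and any particular choice would be
  arbitrary.
* The permutation memory footprint grows as
  $N(N-1)/2 \times R(R+1)/2$ doubles for the pooled tensor; a 273-region
  atlas with ~50 subjects fits comfortably, but thousands of regions would
  need a chunked design.
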