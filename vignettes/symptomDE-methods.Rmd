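---
title: "Models and methods behind symptomDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind symptomDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`symptomDE` analyses bulk RNA-Seq against a continuous, multidimensional
symptom phenotype — the PCL-17 PTSD checklist with its total score and four
subdimensions (re-experiencing, avoidance, numbing, hyperarousal). This
vignette explains the models, the defaults and the design decisions, in the
order the pipeline runs them.

## The negative-binomial GAM

For gene $g$ and subject $i$ the count model is

$$\log E[Y_{gi}] = \log s_i + \beta_{0g} + f_g(\mathrm{PCL}_i)
  + \mathbf{x}_i^\top \boldsymbol\beta_g,
  \qquad Y_{gi} \sim \mathrm{NB}(\mu_{gi}, \theta_g),$$

with $s_i$ a median-of-ratios size factor (computed over genes expressed in
every sample and rescaled to geometric mean one), $\mathbf{x}_i$ the linear
adjustment covariates (age, race indicator, five immune-cell proportions,
surrogate variables), and $f_g$ a penalized smooth of the phenotype.

**The smooth.** $f_g$ is a cubic B-spline with 10 basis functions and a
second-order difference penalty (a P-spline). The penalty's null space is
the linear functions, which is the property the whole nonlinearity analysis
rests on: when the smoothing parameter is driven to infinity the fit
collapses to a straight line and the effective degrees of freedom (edf) of
the smooth equals exactly 1. The edf — the trace of the smooth's influence
contribution — is therefore a continuous nonlinearity measure, and a
significant gene with edf > 1.5 is called a nonlinear DE gene. The smooth is
centered (sum-to-zero), separating it from the intercept. Ten basis
functions comfortably cover the dose–response shapes a 17–85 score range can
support while keeping edf bounded by 9; the basis size must stay below the
sample count.

**Estimation.** Smoothing parameter and NB dispersion are estimated jointly
by REML within each gene's fit (`mgcv::gam` with the `nb` family). An
earlier design estimated gene-wise dispersion first and shrank it toward a
log-linear mean–dispersion trend with weight 0.5; simulation at the
generator's own dispersion spread (log-normal, sd 0.5 on the log scale)
showed that this biases per-gene dispersions enough to inflate the type-I
error of the smooth test well above nominal, while joint REML estimation is
calibrated. The shrinkage route was therefore dropped.

**Smoothness-selection inflation.** Smoothing selection uses a
degrees-of-freedom inflation factor `gamma = 1.3`. With `gamma = 1`, REML
occasionally attributes noise wiggliness to the smooth, so a noticeable
minority of genuinely linear effects receive edf > 1.5 and would be
miscalled nonlinear; `gamma = 1.3` suppresses these spurious wiggles with no
measurable cost to the test's null calibration, while `gamma = 1.4` starts
to make the null test conservative. The trade-off was mapped by simulation
(null fraction of p < 0.05, edf distribution of planted linear effects, edf
of planted sigmoid effects — the hardest nonlinear shape) and 1.3 sits at
the joint optimum; the acceptance script re-measures all three quantities.

**The test.** The reported p-value tests $H_0: f_g \equiv 0$ — linear part
included — using the Wald-type smooth test of standard penalized-GAM
practice, with reference degrees of freedom tied to the edf. The study-style
pipeline runs this per dimension (total plus four subscores) and applies
Benjamini–Hochberg FDR over the converged fits; non-converged genes are
reported with NA p-values and excluded from the BH family rather than
propagated.

**What is deliberately approximate.** Scaling one sample's counts together
with its size factor is *almost* absorbed by the offset: the NB information
weight of that sample changes, so coefficients move at the $10^{-3}$ level
rather than being bitwise identical. The test suite asserts the invariance
at that realistic tolerance.

## Isoform and splicing analysis

Isoform abundances enter as $\log(\mathrm{TPM}+1)$ (natural log). Splicing
events are consumed in SUPPA-style ioe form (inclusion transcripts, total
transcripts); per event and sample

$$\mathrm{PSI} = \frac{\sum \mathrm{TPM}(\text{inclusion})}
                      {\sum \mathrm{TPM}(\text{total})},$$

set to NA when the total TPM falls below a floor of 1 (the ratio is not
estimable from essentially unexpressed events). PSI is analysed on the
log-odds scale, $\log(\mathrm{PSI}/(1-\mathrm{PSI}))$, after clipping to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$; clipping keeps
boundary events (PSI exactly 0 or 1) finite without discarding them, and the
transform is antisymmetric and monotone on the clipped range. Both feature
types go through the Gaussian analogue of the count model: the same
penalized spline and covariates, an F-type test of the smooth, per-feature
deletion of NA samples, and exclusion (with a log message) of features with
fewer than `n_basis + n_covariates + 2` usable samples or zero variance.
Isoforms are pre-filtered at mean TPM ≥ 1 and events at ≥ 80% non-NA
samples; both knobs are exposed and the removed fraction is logged.

## Post-hoc clustering of fitted smooths

The fitted smooths of significant nonlinear genes are evaluated on a common
100-point grid spanning the observed phenotype range and centered to mean
zero; amplitudes are *not* rescaled by default, because the size of an
estimated expression change is meaningful (unit-variance scaling is exposed
as an option). Clustering is k-medoids (PAM, build + swap, Euclidean
distance on the grid vectors), which is deterministic given the data.

The number of clusters comes from the gap statistic: within-cluster
dispersion $W_k$ in Tibshirani's pairwise form (per cluster, the sum of
pairwise squared distances divided by twice the cluster size), reference
data drawn uniformly over the principal-component-aligned bounding box of
the curves, and $\mathrm{Gap}(k) = \overline{\log W^*_k} - \log W_k$ over 50
reference draws by default.

**Selection rule.** The classic "first" rules — Tibshirani's
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$ and the first-local-max
variant — turn out to be fragile exactly on curve-set data: the gap curve is
typically flat, with a noise-level dip, between $k = 1$ and $k = 2$, and
both rules then stop at $k = 1$ even when the curve later rises by two log
units. (The same happens with `cluster::clusGap` on the same data, so this
is a property of the rules, not of this implementation.) The package
therefore selects the smallest $k$ whose gap is within one standard error of
the **global** maximum (`globalSEmax`). On planted fixtures this recovers
five archetypes, two archetypes, and $k = 1$ for unstructured noise,
consistently across seeds; identical curves short-circuit to $k = 1$ by
definition.

## Cross-dimension comparison

A feature is *unique* to a subdimension when it passes FDR < 0.05 there and
has p > 0.1 in each of the other three subdimensions — the second condition
demands clear non-significance, not merely absence of an FDR call.
Dimension agreement is summarised by Pearson correlation of $-\log_{10} p$
vectors (pairwise-complete; the base only rescales the vectors and leaves
the correlation unchanged, which the tests assert); p-values are floored at
$10^{-300}$ so underflow cannot produce infinities. Venn region counts and
counts of p < t across thresholds complete the picture.

The splicing event-type composition of a significant set is compared with
the transcriptome-wide background by a chi-square goodness-of-fit test.
Categories whose expected count falls below 5 are pooled into a single
combined category — the pool grows by the smallest-expected remaining type,
ties broken alphabetically, until every expected count (pool included)
reaches 5 or only two categories remain — and the Pearson statistic is
computed on the merged table with df = #categories − 1. Merging preserves
totals exactly; the statistic is verified against an independent textbook
implementation in the tests.

## Preranked GSEA

Genes are ranked by $-\log_{10} p$ (ties broken by gene id, so rankings are
reproducible), gene sets are trimmed to their members present in the
ranking and kept if the trimmed size lies in [15, 500]. The enrichment score
is the extremum of the weighted Kolmogorov–Smirnov running sum with weight
exponent 1 (weight 0 reduces to the classic KS statistic on ranks — a
reduction the tests verify against a brute-force scan). Because the ranking
is unsigned, null scores come from gene-label permutation; nominal p is the
matching-sign tail frequency with +1 smoothing (so p is never exactly 0),
NES divides ES by the mean |null ES| of matching sign, and FDR q follows the
positive/negative pooled-null convention of the classic method. A set whose
members all carry score 0 falls back to equal hit weights rather than 0/0.
When no set reaches q < 0.1, sets at p < 0.001 are flagged for reporting
instead; set-level uniqueness across dimensions uses (q < 0.1 or p < 0.001)
in the target and p > 0.1 elsewhere. Annotation of dimension-unique gene
lists is provided locally as a hypergeometric over-representation test with
BH FDR over user-supplied GMT collections; the package deliberately ships no
gene-set collections (licensing and version drift).

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, with
ground truth, at any size. What it emulates:

- **Item structure.** 17 ordinal items scored 1–5 from a latent multivariate
  normal, thresholded at fixed cutpoints; items map to subdimensions by the
  DSM-IV four-factor split (5/2/5/5). The latent correlation is
  `dimension_correlation` between items of different dimensions and
  `max(0.55, dimension_correlation)` within a dimension. The cutpoint
  probabilities (0.44, 0.23, 0.14, 0.11, 0.08) were calibrated once so the
  default cohort reproduces the target marginals — total score mean ≈ 36.6,
  SD ≈ 15.4, subscale correlations ≈ 0.66–0.75 — and were not revisited.
  Driving `dimension_correlation` toward 1 drives the subscale correlations
  toward 1, which the tests exercise at 0.99.
- **Counts.** NB draws with log-mean = baseline (uniform 2–6) + planted
  effect + small covariate effects + log library factor (log-normal, sd
  0.2); per-gene dispersion log-normal around `dispersion_mean` (default
  0.15, log-sd 0.5) — a realistic mean–dispersion spread for whole blood.
- **Planted effects.** Each feature is null, linear or nonlinear
  (`frac_*`, default 0.8/0.1/0.1). Nonlinear features cycle through five
  named archetypes — quadratic, saturating, sigmoid, U, inverted-U — each
  standardized to mean 0, sd 1 over the scaled phenotype, multiplied by a
  signed amplitude (`effect_size`, default 0.4 on the log scale). The
  default amplitude was calibrated once to give power > 0.9 at the default
  cohort size, per the stated study conditions.
- **Splicing.** Each event gets one inclusion and one exclusion transcript;
  the generating PSI follows a logistic model with the planted effect on the
  logit scale; transcript abundances are the event total split by PSI and
  column-normalized to $10^6$ (the TPM convention). The event-type mix makes
  skipping exons the modal type, as in transcriptome-wide catalogues.

What it does **not** emulate: raw reads and alignment artifacts, GC or
length bias, correlated gene–gene structure beyond the shared library
factor, cell-type mixture signal in the expression values (proportions are
covariates only), missingness mechanisms other than low-expression PSI
floors, and batch structure beyond generic surrogate-variable covariates. A
green test suite therefore demonstrates the statistical machinery under the
model's own assumptions, not robustness to everything real cohorts contain.

## Problem sizes and numerical choices

The test suite measures operating characteristics at the sizes the package
documents: type-I error on 2000 null genes × 200 subjects (nominal band
0.035–0.065 at the 0.05 level), null BH behaviour over 20 seeded cohorts,
shape recovery on 800 genes × 226 subjects with a 60/20/20
null/linear/nonlinear mixture, and gap-statistic recovery of the five
archetypes over 20 seeds of 70 curves (noise sd 10% of amplitude). The
planted-effect cohort keeps a 60% null backbone deliberately: size-factor
estimation by median-of-ratios assumes most genes are not associated with
the phenotype, and an all-signal matrix makes the estimated factors
correlate with the phenotype and distorts every downstream smooth.

Other numerical conventions: IRLS/REML convergence is delegated to `mgcv`
with its defaults; non-converged or error-raising fits yield NA p-values,
excluded from BH; singular covariate designs abort with the collinear
columns named; TPM normalization refuses all-zero sample columns; the
all-identical-curves clustering case returns one cluster without touching
the reference distribution; permutation p-values are +1-smoothed; every
stochastic step (generator, gap references, GSEA permutations) takes an
explicit integer seed and the pipeline manifest records the full
configuration and MD5 checksums of every output.

## Known limitations

- The smooth test's p-values are approximate (penalized Wald with
  edf-linked reference df); calibration is verified by simulation, not
  exact.
- The NB-GAM engine is `mgcv`; the package is a faithful implementation of
  the described model class, not a bit-compatible clone of any particular
  published tool.
- The DSM-IV 5/2/5/5 item-to-dimension mapping is assumed; instruments with
  other factor structures would need a different mapping.
- The gap-statistic selection rule (`globalSEmax`) is a deliberate deviation
  from the textbook first-max rules, for the reasons documented above.
- Uniqueness calling is threshold logic, not a formal test of
  dimension-specificity; p > 0.1 in other dimensions is evidence of absence
  only in the colloquial sense.
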