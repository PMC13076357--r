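---
title: "Building and validating an RRBS methylation clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating an RRBS methylation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reduced representation bisulphite sequencing (RRBS) measures, at each CpG
site and sample, how many reads were methylated and how many were not. In
many mammals a subset of CpG sites gains or loses methylation monotonically
with age, so a penalised linear model over those sites — an *epigenetic
clock* — can predict chronological age from a blood sample. `methclock`
implements the full path from per-sample coverage files to such a clock and
its downstream analyses, for cohorts in which the same animal is sampled
repeatedly over years (zoo populations, long-term field studies). The
motivating setting is a captive population of Asian elephants: around 30
animals, ~90 blood samples spanning ages 0–56 years, a heavily
female-biased sex ratio, and two thirds of the animals sampled
longitudinally.

Because repeated samples of one animal are strongly correlated, the central
methodological commitment of the package is *individual-aware* validation:
leave-one-individual-out cross-validation (LOIOCV), where every fold holds
out all samples of one animal.

## The model

Let $x_{js}$ be the methylation ratio of CpG $j$ in sample $s$ (methylated
reads over total reads). After filtering and imputation (below), each
sample's ratios over the candidate-site universe are replaced by normal
quantiles of their within-sample ranks,
$\Phi^{-1}\!\big((r - a)/(n + 1 - 2a)\big)$ with $a = 3/8$ for $n \le 10$
and $a = 1/2$ otherwise — the `qqnorm` plotting positions. The transform is
strictly per-sample: it commutes with sample subsetting, so a new sample can
be normalised identically at prediction time without touching training
data, and no training state leaks through normalisation.

Age is modelled as an affine function of the normalised methylation at a
selected set of clock CpGs,
$$\hat{a}(x) = \beta_0 + \sum_j \beta_j \, \tilde{x}_j,$$
with coefficients from the elastic net:
$$\min_{\beta_0, \beta}\; \frac{1}{2n}\sum_s\big(a_s - \beta_0 - x_s^\top
\beta\big)^2 + \lambda\Big(\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big).$$

Candidate sites are pre-selected by Pearson correlation with age,
$|r| > 0.5$ (strict inequality). Both hyper- and hypomethylating sites are
informative, so the absolute-value reading is the default; a signed mode
(`r > 0.5` literally) is retained as an option. Pre-selection on all
samples followed by regression is the default (`selection_mode = "paper"`),
because it is the workflow the clock literature reports; a `"nested"` mode
re-selects within every cross-validation fold so the optimism of pooled
pre-selection can be quantified on the same folds.

## Solver

The elastic net is solved by cyclic coordinate descent with
soft-thresholding on internally standardised features (population-SD
scaling, so $\sum_i x_{ij}^2 / n = 1$), a 100-point log-spaced lambda path
from $\lambda_{\max}$ down to $10^{-3}\lambda_{\max}$, warm starts, and
active-set iteration. Because the selected clock sites are strongly
mutually correlated, plain coordinate descent converges slowly at the small
end of the path; once the active set stabilises, the solver therefore
solves the penalised least-squares system restricted to the active
coordinates exactly (signs held fixed, Cholesky) and accepts the step only
when the signs are consistent. Convergence is always declared by the
original criterion — a full sweep moving no coefficient by $10^{-7}$
(standardised scale) — so the acceleration cannot relax the solution
quality; Karush–Kuhn–Tucker residuals of returned fits are at numerical
precision, and the test suite pins the solver to the ridge closed form
($\alpha = 0$), ordinary least squares ($\lambda = 0$), the lasso null
($\lambda \ge \lambda_{\max}$), and an independent reference implementation.

$\lambda_{\max}$ is infinite at $\alpha = 0$, so it is computed at
$\max(\alpha, 0.001)$, the conventional surrogate. $\lambda$ is tuned by
internal $n$-fold cross-validation (default 10 folds) minimising MSE;
when grouping labels are supplied the internal folds keep all samples of an
individual together. $\alpha$ is tuned on a grid (default 0 to 1 in steps
of 0.01) by cross-validated $R^2$ — the squared Pearson correlation between
held-out predictions and age — with ties broken toward the larger $\alpha$,
i.e. the sparser model; the same fold assignment is reused across the grid
so the comparison is paired.

## Preprocessing rules and their boundaries

* **Coverage**: mean depth over all samples $\ge$ 5×, a missing entry
  counting as depth 0. A site observed nowhere has depth 0 and fails.
* **Mean methylation** within $[0.1, 0.9]$, bounds inclusive: removes
  constitutively hyper-/hypomethylated sites that cannot carry an age
  signal. Boundary sites are vanishingly rare in count data.
* **Missingness**: fraction of missing entries strictly below 5%; a
  fraction exactly at the bound excludes the site. The fraction is computed
  over samples by default. With repeated sampling a per-individual reading
  is also defensible, so `missing_unit = "individual"` counts an individual
  as missing only when none of its samples covers the site; the default
  stays at the per-sample unit because it is stricter and unambiguous.

Missing is defined operationally as zero total reads — the only definition
available from count data. Remaining gaps are filled by k-nearest-neighbour
imputation over sites (k = 10, Euclidean distance over the samples where
both sites are observed, neighbours restricted to sites observed in the
target sample, imputed values clipped to $[0,1]$); sites missing in at
least half the samples fall back to their row mean. The search is
exhaustive — every site pair is scored, blockwise via matrix products — so
results are identical at any cohort size, and observed values are never
altered.

At prediction time a new sample is normalised over the *candidate-site
universe* stored in the model (not just the final clock sites), because
that reproduces the training-time value distribution of the transform; up
to 5% of the universe may be absent, filled with stored training-set site
means. Which universe the original workflow used at test time is not
documentable from the outside; storing it in the model makes the choice
explicit and reproducible.

## What the synthetic cohort does and does not emulate

The generator (`cohort_spec()`, `simulate_cohort()`) draws, for each site,
a class — age-hypermethylating, age-hypomethylating, constitutively
high/low, or null — and for sample $i$ at site $j$ generates
$$p_{ij} = \mathrm{logit}^{-1}\!\big(\beta_{0j} + \beta_{1j}\,\mathrm{age}_i
+ e_{ij}\big), \quad e_{ij} \sim N(0, \sigma), $$
total reads from a negative binomial (zeroed with a missingness
probability) and methylated reads binomially. Defaults are fixed as study
conditions: 30 individuals; 70% sampled longitudinally with 2–5 samples at
0.5–5-year gaps (expected cohort ≈ 82 samples); ages 0–56 years (uniform,
or an `"elephant"` life-stage mixture weighted 7/4/41/30/9 over
calves/juveniles/subadults/adults/seniors); sex ratio 0.9 female; baseline
methylation targeting a global mean of 0.66 via a Beta draw; slopes
$|\beta_1| \in [0.03, 0.08]$ per year on the logit scale (centred at the
cohort mid-age so trajectories stay inside the dynamic range);
$\sigma = 0.3$; negative-binomial coverage with mean 30 and size 5;
2% missingness. Slope ranges are calibrated only so that $|r| > 0.5$ is
attainable at these noise levels — no per-site effect-size distribution is
observable for the real cohort, and no claim of biological realism is made
for them. All randomness flows from one seed through per-operation
substreams, so a fixed seed reproduces cohorts byte-identically.

The generator is logit-linear and stationary: it does not model the
late-life plateau of methylation drift, batch effects, cell-composition
shifts, bisulphite conversion error, or spatial correlation along the
genome. Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers what it is pointed at under its stated assumptions — not
that a real cohort of this size would achieve the same accuracy.

A small annotation simulator (`simulate_annotation()`) provides synthetic
CpG islands and strand-aware gene models for exercising the context
classifiers; shipped fixtures derived from it are named `synthetic_*`.

## Downstream analyses

**Metrics.** MAE, Pearson's $r$, and $R^2$ reported as the squared Pearson
correlation (the clock literature's pairing; the $1 - SSE/SST$ variant is
computed alongside as `r2_sse`). The relative error is
$100 \cdot \mathrm{MAE} / L$ with $L$ the species' maximum recorded
lifespan, 79.6 years by default.

**Life stages.** Ages partition into calf $[0,1)$, juvenile $[1,5)$,
subadult $[5,20)$, adult $[20,50)$, senior $[50,\infty)$ — half-open on the
left boundary, a documented convention (an exact 50 must belong somewhere
and is classed senior). Group contrasts use one-way ANOVA plus pairwise
Welch t-tests (unequal variances suit the strongly unbalanced groups) with
Benjamini–Hochberg adjustment and a compact-letter display.

**Longitudinal change.** Per individual, only the chronologically first and
last samples are kept; pairs less than one day (1/365.25 years) apart are
dropped as near-duplicates. The change in DNAm age is tested by a
one-sample t-test against zero, *one-sided (greater)*: the direction is the
scientific question (does epigenetic age advance with time?), and with
published values $t = 1.70$, $\mathrm{df} = 17$ only the one-sided reading
matches a reported p of 0.05 (two-sided would be ≈ 0.11). Intervals are
recomputed from chronological ages rather than trusted from printed tables;
the shipped example table contains one internally inconsistent printed
interval, which the package flags instead of reproducing.

**Sex.** Site-wise linear models methylation ~ DNAm age × sex; the per-site
p-value is the smaller of the sex main effect and the interaction (which
term won is recorded rather than collapsed, since either can carry the
biology), BH-adjusted across sites, flagged at FDR < 0.05. A companion
Gaussian model tests the delta-age residuals on sex, with and without age
adjustment. With fewer than 3 samples of either sex the analysis is skipped
with an explicit notice — mirroring how underpowered single-digit male
cohorts should be treated.

**Genomic context.** CpG density: island / shore (within 2,000 bp of an
island boundary, inclusive) / outside, computed on merged islands so no
site is double-counted. Genic: promoter (within ±2,000 bp of the
strand-aware TSS, inclusive) > exon > intron > intergenic — the precedence
is a declared convention, as overlap resolution is never stated in the
clock literature. Nearest-gene ties break by lower gene start, then
lexicographic id. Upstream/downstream are 5′/3′ of the gene's strand.

## Numerical choices and degenerate inputs

* Zero-variance sites: skipped with a warning in feature selection and PCA
  (correlation undefined); zero-variance features get coefficient 0 in the
  elastic net.
* Coordinate descent: at most $10^5$ sweeps per lambda, tolerance $10^{-7}$
  on the standardised coefficient change; non-convergence is an error, not
  a warning.
* Rank ties take mean ranks; the transform is monotone (Spearman r = 1 with
  its input by construction).
* Strand collapsing (off by default; the generator emits collapsed sites)
  greedily merges adjacent (p, p+1) pairs left to right, is idempotent and
  conserves read totals.
* Duplicate (individual, age) records in longitudinal extraction keep the
  earliest-listed sample with a warning.
* Negative DNAm-age predictions are reported as-is; clamping would bias the
  longitudinal deltas.

## Problem sizes

The validation suite exercises the full pipeline on a scaled-down cohort —
30 individuals (~80 samples), 20,000 CpG sites with 300 planted
age-associated sites, coverage mean 30, $\sigma = 0.3$ — chosen so the
whole simulate–preprocess–tune–cross-validate cycle is comfortable on a
single CPU while keeping more sites than samples by two orders of
magnitude, the regime the elastic net exists for. The alpha grid in the
end-to-end runs uses steps of 0.1 (the 0.01 grid is exercised on small
instances where each fit is cheap). Under these conditions the assembled
LOIOCV predictions reach $r \ge 0.9$ and MAE $\le 4$ years, and
correlation pre-selection recovers $\ge 80\%$ of the recoverable planted
sites with $\le 1\%$ false selections; the numbers actually achieved are
recomputed by `scripts/acceptance.R` on every run.

## Known limitations

* Pooled pre-selection (the default, kept for fidelity to the published
  workflow) is optimistic; LOIOCV bounds but does not remove the bias.
  Use `selection_mode = "nested"` to measure it.
* The kNN imputation is exhaustive; beyond a few hundred thousand sites the
  blockwise distance computation dominates runtime.
* The train/test split defaults to the per-sample unit, which lets an
  individual's repeats straddle the split (again for fidelity);
  `unit = "individual"` gives the leakage-free variant.
* The generator's independence across sites understates the redundancy of
  real methylation data; selection false-positive rates on synthetic nulls
  are therefore optimistic relative to real cohorts.
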