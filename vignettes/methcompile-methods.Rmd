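---
title: "Methods: models, parameters and design choices in methcompile"
author: "methcompile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methcompile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcompile)
```

# Scope

`methcompile` analyses compilations of blood DNA methylation (DNAm) array
profiles pooled across many studies and two array platforms. The package
covers the stages such an analysis needs — quality control, cell-type
deconvolution, study-bias removal, variance decomposition, hashed sample
search, power analysis and differential-methylation replication — plus a
synthetic-compilation generator with complete ground truth. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, and what the synthetic data can and cannot tell you
about real compilations.

# The synthetic compilation generator

## Signal model

Each sample is a bulk mixture of six leukocyte types. Per sample $s$ with
cell fractions $w_s$ (a Dirichlet draw specific to its sample type) and a
reference panel $R$ of per-cell-type mean Beta-values, the generator forms

$$\eta_{ps} = \mathrm{logit}\!\big(R_{p\cdot} w_s\big)
  + u_{\mathrm{study}(s)} + \ell_p\,\mathbb{1}[\text{male}]
  + a_p\,\mathrm{age}_s + g_p^\top \mathrm{anc}_s + \varepsilon_{ps},$$

and stores $\beta_{ps} = \mathrm{logit}^{-1}(\eta_{ps})$ clamped to
$[10^{-6}, 1-10^{-6}]$. Effects are additive on the natural-logit scale —
the same scale family (up to the base of the logarithm) on which the
modelling stages operate via M-values — and mapped back, which keeps every
stored value a valid methylation fraction and keeps logits finite.

## Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `study_offset_sd` | 0.3 (logit units) | per-study offsets that visibly dominate single-probe variance without drowning biology; raised to 0.5–0.6 in the batch-focused experiments |
| `noise_sd` | 0.5 (logit units) | measurement noise giving mid-range Beta SD ≈ 0.1, typical of array replicates |
| `sample_type_probs` | 0.50/0.15/0.25/0.10 (whole blood/cord/PBMC/other) | whole blood most prevalent, PBMC second, as in public blood compilations |
| Dirichlet α, whole blood | (8, 4, 2, 2, 2, 30) | granulocyte-dominant (median Gran ≈ 0.6) |
| Dirichlet α, PBMC | (12, 8, 4, 4, 4, 0.3) | granulocytes depleted during PBMC preparation; a 5 % contamination tail (Gran ~ U(0.2, 0.5)) exercises the QC filter |
| `sex_effect_delta` | 0.2 (Beta scale) | a clearly detectable differential-methylation effect |
| `age_slope_sd` | 0.005 (logit / year) | lifetime drift of up to ~0.35 logit units at age 70 for 1-SD probes |
| `ancestry_loading_sd` | 0.1 (logit / score SD) | ancestry-correlated probes contribute visibly to leading principal components |
| `shared_probe_fraction` | 0.9 | most probes shared by both platforms, a minority exclusive to the larger platform |

Ages are U(20, 70) years (0 for cord blood); ancestry scores are N(0, 1);
sex is Bernoulli(1/2); platform is assigned per study (one array per
study, with both platforms guaranteed present when there are ≥ 2 studies).

## Calibrated sex effects

A fixed logit shift does not produce a fixed Beta-scale difference: the
inverse logit shrinks shifts, asymmetrically for up- versus down-shifts,
and by an amount depending on where the probe's signal distribution sits.
The generator therefore solves, per planted probe, for the logit shift
whose *expected* Beta-scale male−female difference equals
`sex_effect_delta`, integrating over the probe's realized signal
distribution (empirical quantiles) and the noise distribution (mid-point
quadrature, 21 nodes), by `uniroot` to $10^{-10}$. Planted probes are
restricted to autosomal, platform-shared, non-cross-reactive probes with
baseline means in (0.2, 0.65) so the target difference is reachable.

## What the generator does not emulate

No raw two-channel intensities, probe-chemistry artifacts, or
normalization residue: QC metrics are drawn from a plausible mixture
rather than recomputed from signals. Batch offsets are a single scalar
per study rather than probe-specific; this is the hardest case for
downstream deconvolution (see Limitations) but simpler than real batch
geometry. Cell-type reference profiles are synthetic, with designated
discriminating probes (target-cell mean separated by ≥ 0.3 from all other
types) rather than measured sorted-cell profiles. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not performance on any particular real compilation.

# Preprocessing

M-values are $\log_2(\beta/(1-\beta))$ with $\beta$ clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$ by default
(any value in (0, 0.5) is accepted); the clamp absorbs boundary values
instead of producing infinities, and `m_to_beta()` inverts the transform
inside the clamp.

Sample QC removes a sample iff (i) its log2 median methylated **and**
unmethylated signals are both below 10, or (ii) it failed ≥ 2 of the 5
most informative BeadArray metrics; the two rules carry distinct reason
codes, and missing metrics give a third code. The granulocyte filter
removes PBMC samples with estimated Gran ≥ 0.25 — inclusive at the
boundary — and never touches other sample types. Free-text sample-type
labels are harmonized by an ordered, case-insensitive regular-expression
rule table (first match wins, fallback `other`); only the four target
classes are supported, not a full metadata vocabulary.

## Deconvolution

Per sample the package solves
$\min_w \|b - Rw\|^2$ subject to $w \ge 0$, $\sum_i w_i \le 1$,
over the reference's discriminating probes. The inequality (rather than
equality) sum constraint follows the convention of constrained-projection
deconvolution: $1 - \sum_i w_i$ is reported as the *unexplained* share
of the mixture, a useful diagnostic in its own right. With only seven
constraints the problem is solved exactly by enumerating active sets
(128 candidate sets, each a small KKT linear solve, dual feasibility
checked at tolerance $10^{-9}$); convexity makes the feasible KKT point
the global optimum, so no iterative solver or convergence parameter is
involved. A rank-deficient reference is rejected with the collinear
cell-type columns named.

# Study-bias adjustment

Per probe, the package jointly fits
$M = X\beta + B\gamma + \varepsilon$ by least squares, where $X$ holds
the covariates to preserve (default: the 11 non-technical variables) and
$B$ is the sum-to-zero-coded batch design, then returns $M - B\hat\gamma$.
$\hat\gamma$ is computed by partialling (regressing the
covariate-residualized batch design on the responses), which equals the
joint-fit coefficients and handles collinear covariates gracefully. A
batch level whose residualized design column vanishes (norm below
$10^{-8}$ of its raw norm) is perfectly confounded with a covariate; the
error names the most-correlated covariate. The operation is an orthogonal
projection, hence idempotent, and a single batch level returns the input
unchanged.

Two strategies exist. *Uniform* adjustment codes every study as its own
batch level. *Exact subset* adjustment (`subset_batches`) keeps only a
chosen 2–4 studies as distinct levels and merges the rest into one
reference level before coding. In the repeated bias simulation, the
"adjustment 2" arm instead restricts the analysis to the drawn subset's
samples and adjusts each subset study exactly: merging leaves the merged
studies' relative offsets in place and collapses study-explained variance
only partially and erratically, whereas both the uniform and the
subsetted-exact strategies collapse it by roughly two orders of magnitude
— the behaviour the simulation is designed to exhibit. Both code paths
remain available and tested.

# Variance decomposition

`anova_fev()` reports each variable's sequential (type-I) sum of squares
as a fraction of the total: variables enter in the fixed documented order
technical (platform, study) → demographic (age, sex, ancestry) →
biological (sample type, six fractions). Putting the technical block
first is deliberately conservative: shared variance is credited to study
before biology, so any post-adjustment rise in biological FEV is not an
ordering artifact. The order is an argument, and on balanced orthogonal
designs all orders agree (tested).

Implementation: term blocks are orthogonalized incrementally
(Gram–Schmidt against the accumulated basis, applied twice for numerical
stability, rank decided at relative tolerance $10^{-9}$), which
vectorizes across hundreds of probe responses sharing one design and
makes FEV + residual sum to exactly 1 by construction. Fully aliased
terms contribute zero new basis directions: by default that is an error
naming the term; with `on_alias = "drop"` they are retained in the table
with FEV 0 — the mode the simulation uses, since true cell fractions sum
to 1 (the sixth fraction is exactly aliased with the intercept) and a
sampled study set may be single-platform. The per-probe FEVs of a
repetition are aggregated by the median, and the non-residual variance
ratio (adjusted over unadjusted, $(1-\mathrm{res}_a)/(1-\mathrm{res}_u)$)
by the median of per-probe ratios.

`pca_fev()` runs centered PCA by SVD on hashed profiles (constant
columns, e.g. empty hash buckets, dropped with a warning), then the same
ANOVA on each of the top component scores, with category FEV as the sum
of member-variable FEVs.

# Feature hashing and the search index

Feature hashing maps each probe id through a 32-bit MurmurHash3 of the id
string: bucket = hash mod `dim`, sign = an independent hash bit (signed
variant, the default, makes hashed inner products unbiased for the
original inner products; the unsigned variant is kept for comparison
experiments). The hash family and seed are stored as attributes on the
hashed matrix, and `query_neighbors()` refuses — an error, not a warning —
queries hashed under different parameters. The map is linear and exactly
reproducible; `dim` defaults to 1000.

The k-NN index is a hierarchical navigable small-world graph implemented
in R: geometric layer assignment with rate $1/\log M$, greedy descent
through upper layers, beam search (`ef_construction` = 200) on insertion,
`M` = 16 links per node (2M on the ground layer), query beam
`ef_search` = 300. Defaults are conventional small-world settings; with
them, recall@10 against the exact scan exceeds 0.99 on 500-sample
indexes. Euclidean distance is the default; cosine is available via row
normalization. The exact brute-force scan is exported both as the test
oracle and as a fallback (`exact = TRUE`), with ties broken by
lexicographic sample id so results are fully deterministic. Indexes
serialize to a single RDS file and round-trip to identical query results.

# Power analysis

The simulation draws per-probe Beta values from moment-matched Beta
distributions (probe mean and population-convention variance estimated
from a reference compilation, variance clipped to the feasible region
$v < m(1-m)$). A target set of probes (default 500) receives mean shifts
$|N(\delta, \tau^2)|$ with random sign, re-drawn if the shifted mean
leaves (0, 1) or makes the dispersion infeasible; $\tau$ defaults to
0.01, a small spread around the nominal effect. Testing is a vectorized
Welch t-test on M-values (chosen over a moderated-variance test so its
calibration can be verified exactly; moderation is a noted extension),
followed by Benjamini–Hochberg at FDR 0.05. Marginal power counts only
true targets whose absolute shift exceeds the 0.01 technical detection
limit; when no target does, power is flagged missing rather than 0.
`power_curve()` averages over `n_sims` per (N, δ) grid point with a
Monte-Carlo standard error, and `find_min_n()` reports both the smallest
grid N reaching the target power and the linear interpolation between the
bracketing grid points.

# Sex-DMP replication

Surrogate variables are the top left singular vectors of the M-value
matrix residualized against the known design — a deliberately simple
residual-SVD variant of surrogate-variable analysis (k defaults to 2; the
full iteratively reweighted procedure is out of scope). DMP calling is
per-probe OLS of M on sex plus the adjustment covariates (six cell
fractions, age, platform, study) plus surrogates; the sex coefficient is
the male−female M difference, with two-sided t p-values and Bonferroni
(default) or BH adjustment. Covariate columns aliased with earlier ones
are dropped with a warning (platform nested in study, the sixth exact
fraction); sex itself being aliased is an error. Top-k sets order by
p-value, then |effect| descending, then probe id, so the set is invariant
to row order; concordance-at-the-top is the cumulative overlap of the
ranked list with a discovery set. Replication summaries partition
discovery probes into only-tissue-1 / only-tissue-2 / both, report the
percentage rounded to the nearest integer (the exact fraction is kept
alongside; rounding, not truncation, reproduces both printed values of
the worked examples the tests pin down), and compute direction agreement
over replicated probes where signs are available in every replicating
source. CpG-island proximity defaults to {island, shore}.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes generation → QC/deconvolution → adjustment →
the toggled analyses, writing TSVs, a checksummed manifest and the
resolved YAML configuration; unknown configuration keys are rejected by
name. All randomness derives from one master seed through per-stage
hashed child seeds, so reruns are checksum-identical. Matrices serialize
as plain TSV (probe ids in the first column), the package's on-disk
format for all tabular artifacts.

The test and acceptance workloads use deliberately compact problem sizes
— compilations of 150–2 000 probes and 100–500 samples for unit
properties, a 20 000-probe, 400-sample compilation for the end-to-end
DMP experiment, 20 repetitions for the bias simulation and 20 simulations
per power grid point — chosen so the full suite runs in minutes while
keeping every Monte-Carlo margin comfortable (the asserted properties are
scale-free).

# Known limitations

- **Deconvolution absorbs uniform batch shifts.** A scalar per-study
  logit offset moves every discriminating probe coherently, so
  constrained least squares partially converts study offsets into
  fraction estimates. Preserving such estimated fractions during
  study-effect removal then re-protects study variance. Probe-specific
  batch geometry (real arrays) dilutes this; with the generator's scalar
  offsets it is maximal. The bias simulation therefore models the true
  covariates, and analyses that adjust on estimated fractions should
  expect attenuated batch removal.
- The BeadArray metrics are consumed as a precomputed failure count, not
  recomputed from raw channels.
- The granulocyte cutoff is a parameter (default 0.25), not re-derived
  from a contamination-distribution quantile.
- Surrogate variables are a single-pass residual SVD, not the full
  iterative estimation.
- The HNSW implementation targets compilation-scale cohorts (hundreds to
  thousands of samples); it is not tuned for million-sample indexes.
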