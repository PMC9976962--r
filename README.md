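# methcompile

Cross-study analysis of compiled blood DNA methylation (DNAm) array data.

Public repositories hold thousands of HM450K and EPIC blood methylation
profiles, but combining them across studies raises recurring problems:
study-to-study technical bias dwarfs biology, sample metadata are
heterogeneous free text, cell composition confounds everything, and it is
unclear how large a cross-study compilation must be to detect differential
methylation. `methcompile` implements the analysis stack such compilations
need, end to end, with a synthetic-compilation generator that carries full
ground truth so every stage can be validated:

- **Preprocessing** — Beta/M-value conversion (M = log2(β/(1−β))), sample QC
  (low median methylated/unmethylated signal; BeadArray metric failures),
  a granulocyte-contamination filter for PBMC samples (Gran ≥ 0.25),
  sex-chromosome / cross-reactive / SNP probe filters, and free-text
  sample-type harmonization.
- **Cell-type deconvolution** — reference-based constrained least squares
  per sample: min‖b − Rw‖² with w ≥ 0, Σw ≤ 1 over six leukocyte fractions
  (CD4T, CD8T, NK, B cells, monocytes, granulocytes), solved exactly by an
  active-set method.
- **Study-bias adjustment** — per probe, a joint linear fit
  M = Xβ + Bγ + ε with sum-to-zero batch coding; returns M − Bγ̂ so the
  modelled covariates are preserved. Uniform (all studies) and exact
  (2–4-study subset) strategies.
- **Variance decomposition** — sequential (type-I) ANOVA fraction of
  explained variance (FEV = SS_v / SS_total) over 13 variables in three
  categories (technical: platform, study; demographic: age, sex, two
  ancestry scores; biological: sample type, six cell fractions), a
  repeated bias-adjustment simulation (500 probes × 5 studies per
  repetition), and FEV decomposition of the top principal components of
  hashed profiles.
- **Feature hashing and sample search** — deterministic signed feature
  hashing of the probe dimension (MurmurHash3) to a fixed 1000-D-style
  representation, and a hierarchical navigable small-world (HNSW) k-NN
  index over hashed profiles with an exact brute-force oracle and
  neighbour-label profiling.
- **Power analysis** — simulation-based EWAS power: two equal groups drawn
  probe-wise from moment-matched Beta distributions, a target set of
  probes shifted by δ, Welch t-tests on M-values, Benjamini–Hochberg at
  FDR 5 %, marginal power above a 0.01 detection limit, power curves over
  N and minimal-N estimates.
- **Sex-DMP replication** — residual-SVD surrogate variables, per-probe
  regression of M-values on sex with cell-fraction/age/platform/study
  adjustment, top-k significant sets, concordance-at-the-top curves,
  two-tissue replication summaries with direction agreement, and CpG-island
  overlap.

## Worked example

```r
library(methcompile)

ref <- generate_reference_profiles(n_probes = 2000, seed = 1)
cfg <- generator_config(n_probes = 2000, n_studies = 6, samples_per_study = 40,
                        study_offset_sd = 0.5, n_sex_dmps = 60, seed = 1)
ds <- generate_dataset(cfg, ref)
#> Synthetic DNAm compilation: 2000 probes x 240 samples; 6 studies; 60 planted sex DMPs

dec <- qc_filter_samples(ds$qc)
sum(!dec$keep)                          # 7 samples fail signal/BeadArray QC

est <- deconvolve_cell_fractions(ds$beta, ref)
sqrt(mean((est - ds$truth$cell_fractions)^2))   # 0.049 fraction RMSE vs truth

M <- beta_to_m(ds$beta)
anova_fev(M[5, ], ds$metadata, on_alias = "drop")
#> Fraction of explained variance (sequential ANOVA):
#>      variable    category       fev
#>      platform   technical 5.530e-02
#>      study_id   technical 5.840e-01
#>           age demographic 7.599e-03
#>           sex demographic 2.838e-04
#>  ...
#>      residual    residual 2.810e-01

adj <- remove_study_effects(M, ds$metadata)
anova_fev(adj[5, ], ds$metadata, on_alias = "drop")$fev[2]
#> study FEV drops from 0.584 to 0.00306
```

Here study identity explains 58 % of this probe's variance before
adjustment and 0.3 % after, while the biological and demographic fractions
are left in place — the motivating observation for compilation-wide
study-bias correction. `run_pipeline(pipeline_config(), out_dir)` chains
all stages (generation → QC → deconvolution → adjustment → variance /
index / power / DMP analyses) and writes TSV outputs with a checksummed
manifest and the resolved YAML configuration.

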