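# maraprog

Motif activity inference and regulatory-program decomposition for
multi-condition expression studies.

`maraprog` is aimed at regulatory genomicists who have (i) a
promoter-level log2 expression matrix across samples (e.g. RMA-normalized
microarrays summarized per promoter) and (ii) predicted
transcription-factor binding-site counts per promoter and motif, and who
want to know *which regulators* drive the expression changes across
conditions and time — not just which genes move. The package was built
around the analysis pattern of liver toxicogenomics compendia
(kinetic treated/control time courses, knockout × treatment factorials,
tumor vs surrounding tissue), and ships a synthetic-study generator that
plants known activities so every stage is validated by recovery.

## The model

Motif activity response analysis (MARA) assumes promoter expression is
linear in predicted binding-site counts:

```
e_ps = c_p + n_s + Σ_m N_pm · A_ms + ε_ps
```

- `e_ps` — log2 expression of promoter *p* in sample *s*
- `c_p` — basal activity of promoter *p*; `n_s` — per-sample normalization
- `N_pm` — predicted binding-site count for motif *m* in promoter *p*
- `A_ms` — latent **motif activity**, the quantity being inferred

The nuisance terms are removed exactly by double-centering `E` and
column-centering `N`; activities are then estimated per sample by ridge
regression, `A = (Ñ'Ñ + λI)⁻¹ Ñ'Ẽ`, with standard errors from the
Gaussian posterior covariance and an overall per-motif significance
`z_m = sqrt(mean_s (A_ms/σ_ms)²)`. Downstream:

- **Programs** — SVD of the activity matrix, `A = UΛV'`, yields
  orthonormal characteristic activity profiles (right singular vectors),
  variance fractions, and per-motif projections `P = UΛ` and correlations
  `ρ = P/‖a‖`.
- **Contrasts** — replicate-averaged condition activities compared by a
  z-statistic, strictly within dataset (batch); categorical calls for
  pathway dependence (WT vs KO response) and tumor specificity.
- **Selection** — representative motifs per program, ranked jointly by
  projection and correlation, refined by significance, cognate-TF
  expression (log2 ≥ 6.0) and per-timepoint z patterns, with a full audit
  trail.

See `vignettes/motif-activity-programs.Rmd` for the methods account.

## Worked example

Simulate a 7-timepoint treated/control study, infer activities, decompose
into programs, and pick the motifs representing the sustained
treatment-response program:

```r
library(maraprog)

cfg   <- generator_config(n_promoters = 300, n_motifs = 10, seed = 7)
study <- generate_study(cfg)

fit <- fit_activities(study$expr, study$counts, fit_config(ridge_penalty = "cv", seed = 7))
#> activity_table: 10 motifs x 14 samples
#>   ridge penalty 0.0001, residual sd 0.06347

dec <- orient_components(decompose_activities(fit), study$design, "treatment_positive")
#> program_decomposition: 10 motifs x 14 samples, 10 components
#>   variance fractions: 0.405 0.347 0.154 0.094 0.000 0.000 ...

tz <- timepoint_contrasts(fit, study$design, "kinetic")
round(tz[1:4, "91"], 1)
#> day-91 treated-vs-control z, first 4 motifs: 0.6 -53.6 21.6 -99.3

sel <- select_representatives(component_scores(dec), fit$motif_z, study$tfmap, tz,
                              selection_config(component = 2, timepoint_rule = "sustained"))
#> motif_selection (component 2): 4 positive, 3 negative, 3 removed
sel$positive
#> "motif_06" "motif_08" "motif_04" "motif_03"
```

Reading the output: the cross-validated penalty lands at the small end of
the grid (the simulated noise is mild), the residual SD ≈ 0.063 matches
the planted expression noise, and the four planted temporal programs
carry essentially all activity variance (fractions 0.405/0.347/0.154/0.094,
then numerically zero). The day-91 contrast z values show which motifs
still diverge between arms at the end of the course, and the selection
returns the positively and negatively correlated clusters for the
sustained-response component, with the three removed candidates
attributed to a filter in `sel$audit`.

The same steps run as a file-driven workflow in `analysis/01_simulate.R`
… `analysis/05_select_motifs.R` (each writes its tables under
`results/`), or as one config-driven call via `run_analysis()`, which
also emits a run manifest with md5 hashes of every input and output.

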