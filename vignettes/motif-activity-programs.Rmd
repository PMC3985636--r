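---
title: "Inferring motif activities and disentangling regulatory programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring motif activities and disentangling regulatory programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`maraprog` implements motif activity response analysis (MARA) together
with the downstream machinery needed to interpret it in multi-condition
*in vivo* studies: program decomposition by SVD, differential-activity
contrasts, and representative-motif selection.

The measured quantity is a promoter log2-expression matrix
$e_{ps}$ (promoters $p$, samples $s$), typically RMA-normalized
microarray intensities summarized per promoter. The explanatory data are
computationally predicted transcription-factor binding-site counts
$N_{pm}$ per promoter and motif, produced upstream by probabilistic TFBS
prediction. MARA assumes expression is linear in the site counts:

$$ e_{ps} = c_p + n_s + \sum_m N_{pm} A_{ms} + \varepsilon_{ps}, $$

where $c_p$ is the basal activity of promoter $p$, $n_s$ a per-sample
normalization constant, and $A_{ms}$ the latent *activity* of motif $m$
in sample $s$ — the amount by which expression of a promoter would drop
if one binding site for $m$ were removed. Positive activity means the
motif's predicted targets are coherently upregulated beyond what the
other motifs explain.

## Fitting

The two nuisance blocks $c_p$ and $n_s$ are never fitted explicitly.
Double-centering $E$ (subtracting row and column means, adding back the
grand mean) and column-centering $N$ eliminates them at the exact
least-squares optimum, and has a useful side effect: every fitted
activity profile is mean-centered across samples, which is what later
makes the SVD correlation identity exact. Because the planted or true
activity mean per motif is not identifiable in this model (it is
absorbed by $c_p$), activities are reported row-centered and the removed
means are kept in `fit_meta`.

Each sample's coefficient vector then solves a ridge problem

$$ \hat A_{\cdot s} = (\tilde N^\top \tilde N + \lambda I)^{-1}
   \tilde N^\top \tilde E_{\cdot s}, $$

implemented through the economy SVD of $\tilde N$ (one factorization
serves all samples, and numerically rank-deficient directions are
handled explicitly). The penalty $\lambda$ is not prescribed by the
underlying method description, so it is a first-class parameter:
a fixed value, or `"cv"` (the default) selecting from a 7-point
log-spaced grid $10^{-4}..10^2$ by 5-fold cross-validation over
*promoter* folds — folds split rows, not samples, because the model's
exchangeable unit is the promoter. The fold assignment is seeded and
deterministic.

Error bars come from the Gaussian posterior covariance
$\hat\sigma^2 (\tilde N^\top \tilde N + \lambda I)^{-1}$. The exact
Bayesian treatment used by the original MARA implementation is not
publicly specified; the ridge-Gaussian posterior is this package's
stated analogue. The residual variance $\hat\sigma^2$ is pooled over
samples with degrees of freedom $PS - S\,M_\mathrm{eff}$, where
$M_\mathrm{eff}$ is the trace of the hat matrix — pooling stabilizes the
error bars when a dataset has few samples. Supplying `known_noise_sd`
bypasses the estimate (useful in simulation studies). Samples are fitted
independently with a shared penalty; whether the original analysis
shared information across samples is unstated, and independent fits are
the conservative reading.

The per-motif overall significance is
$z_m = \sqrt{\tfrac1S \sum_s (A_{ms}/\tilde\sigma_{ms})^2}$, the
root-mean-square signal-to-noise ratio of the motif's profile.

All-zero site-count columns are retained by the readers (I/O carries no
modeling policy) and dropped with a warning inside `fit_activities()`,
where the decision belongs: such motifs are unidentifiable.

# Differential activity between conditions

Replicate samples of a condition $c$ are averaged,
$\bar A_{mc} = \tfrac1R \sum_r A_{mr}$, with standard error
$\bar\sigma_{mc} = \sqrt{\sum_r \tilde\sigma^2_{mr}}/R$ — the SE of the
mean under independent per-sample posteriors, the conservative choice.
Two conditions are compared by

$$ z_m(c_1, c_2) = \frac{\bar A_{m c_1} - \bar A_{m c_2}}
   {\sqrt{\bar\sigma^2_{m c_1} + \bar\sigma^2_{m c_2}}}. $$

Contrasts are only defined *within* a dataset (batch); cross-dataset
pairs are refused with an error, and the pipeline orchestrator enforces
the same rule a second time by fitting each dataset separately. Motifs
are called `up`/`down`/`ns` at a configurable threshold. The threshold
default is 2.0 (two-sided $\approx$ 95%); the numeric cutoffs used in
the motivating analyses are not recoverable, so the value always lives
in configuration and is echoed into every output table.

Two categorical composites support knockout and tumor designs.
`dependency_call()` labels a motif *downstream* of a pathway when its
treatment response is present in wild type but absent in the pathway
knockout, and *independent* when present in both with the same sign; a
response that flips sign between WT and KO fits neither pattern and is
labelled `none` (a deliberate choice — an inverted response is evidence
of interaction, not of independence). `tumor_specificity_call()` labels
motifs dysregulated only in promoted tumors as promotion-specific.

Calibration: when the standard errors are known and the true activities
are equal, $z$ is standard normal; the test suite checks the rejection
rate at 1.96, the mean and the variance over 10,000 seeded draws.

# Program decomposition

The motif-activity matrix is decomposed as $A = U \Lambda V^\top$. The
right singular vectors $v_k$ are orthonormal *characteristic activity
profiles* — independent temporal/condition programs shared by many
motifs; the variance fractions $\lambda_k^2 / \sum_j \lambda_j^2$ say
how much of the total activity variation each explains. Because the rows
of $A$ are mean-centered, each $v_k$ (with $\lambda_k > 0$) is
mean-centered as well, so for each motif

* the **projection** $P_{ik} = (U\Lambda)_{ik} = a_i \cdot v_k$ measures
  overlap in raw activity units (scale-sensitive), and
* the **correlation** $\rho_{ik} = P_{ik} / \lVert a_i \rVert$ *is* the
  Pearson correlation between the motif profile and $v_k$ (scale-free).

The two are deliberately not interchangeable: a high-activity motif can
project strongly onto a program its profile does not resemble, and a
near-silent motif can correlate perfectly while projecting weakly.
Representative motifs must rank highly in both.

Numerical choices: the decomposition is thin; singular values below
$10^{-12}\lambda_1$ are treated as numerical rank and their components
dropped (their right vectors are arbitrary completions of the basis and,
in particular, need not be mean-centered); the matrix is decomposed as
fitted, never re-standardized per motif, precisely to preserve the
projection/correlation distinction. SVD signs are arbitrary, so
components are canonicalized: `max_abs_positive` (default — the
dominant entry of each $v_k$ made positive, deterministic with no
metadata) or `treatment_positive` (treated-sample mean of $v_k$ at least
the control mean, which reads naturally in treated/control studies).
Zero-profile motifs get $\rho = 0$ by convention. The decomposition is
applied to the full activity table by default; a significance prefilter
is the caller's decision (`motif_z` is exposed), since whether the
original analyses prefiltered is unknown.

# Representative-motif selection

For a component $k$, candidates per direction are the *intersection* of
the top-$n$ motifs by projection and the top-$n$ by correlation
(ascending orders for the negative cluster), ordered by $|P|$ with ties
broken by $|\rho|$ then motif id — a total order, so selection is fully
deterministic. Three refinement filters follow, in a fixed order chosen
for audit stability (the early filters commute in output):

1. **Overall significance**: keep motifs with $z_m$ at or above a
   per-component cutoff. Defaults 3.0 for components 1–2 and 1.5 for
   components 3–4 — stricter for the high-variance programs, mirroring
   the two-tier convention of the motivating analysis whose exact values
   are not legible; both are configuration, not constants.
2. **Cognate-TF expression**: a motif is kept iff *any* cognate TF has
   mean log2 expression ≥ 6.0 across samples. The any-TF rule reflects
   that motifs represent binding specificities of TF families; one
   expressed member suffices to make the motif actionable. The summary
   statistic (mean across samples) is a package choice; the source gives
   only the scalar cutoff.
3. **Per-timepoint pattern**: the treated-vs-control $z$ per timepoint
   must match the component's temporal character — `sustained` (past
   the threshold at ≥ 4 of the 7 timepoints by default), `day_first`,
   or `day_last`. Whether the qualifying $z$ is signed or absolute is
   ambiguous in the source; both are offered via `direction_sign`
   (default absolute).

Every removal is recorded with the stage and reason, so a selection is
an auditable object, not just two lists.

`tf_expression_activity_correlation()` closes the loop on
interpretation: a positive correlation between a TF's own expression and
its motif's activity supports that TF (rather than a family member)
driving the program.

# The synthetic-data generator

The generator emulates the structure of a liver toxicogenomics
compendium: a kinetic study with seven timepoints (days 1, 3, 7, 14, 28,
57, 91) in treated and control arms with replicates, plus two-group
designs (knockout × treatment factorials, tumor vs surrounding tissue).
Its defaults are the package's reference study conditions: 500
promoters, 20 motifs, Poisson(0.5) site counts, four planted temporal
programs, and expression noise at 0.1× the SD of the regulatory signal
term. That noise level leaves per-motif recovery high but finite, so
solver regressions surface as correlation drops rather than hard
failures.

Planted activities are built as $A = WB$: $B$ holds four orthonormalized
mean-centered program shapes — a postnatal-development decay (drop after
day 14, identical in both arms), a sustained treated/control offset, a
first-day-only divergence, and a late divergence over the last month —
and each signal motif loads on exactly one program with a random sign
and a magnitude drawn around `signal_scale`; decoys load nothing.
Activities are planted row-centered so the truth lives in the same
identifiable subspace the fitter reports. The synthetic motif–TF map
assigns one TF per motif, places expressed TFs near log2 = 8 (optionally
tracking their motif's activity, for correlation tests) and unexpressed
TFs near 4, straddling the 6.0 filter cutoff.

Because the generator draws from exactly the model the fitter assumes,
noise-free recovery is an identity up to centering conventions — the
core of the test suite. What the generator does *not* emulate, and what
passing tests therefore do not demonstrate about real data: probe-level
microarray noise and normalization artifacts, batch effects between
datasets, correlated site-count columns from overlapping motif
definitions (Poisson columns are nearly orthogonal at these sizes; real
$N$ matrices are collinear and activities correspondingly less
identifiable), model misspecification (real expression is not linear in
site counts), and tumor mutation processes. Site counts are Poisson
rather than posterior-weighted TFBS predictions; only their
non-negative, sparse character matters for exercising the solver.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest
sizes — up to 500 promoters × 20 motifs × 28 samples for recovery
studies, 10,000 draws for null calibration, a 23-motif planted-selection
study — chosen because every property they check is already sharply
diagnostic at that scale: oracle agreement at $10^{-10}$, noise-free
recovery at $10^{-6}$, subspace angles under 5°, rejection rates within
[0.04, 0.06]. Every stochastic step (generator, CV folds) is seeded;
the pipeline manifest records md5 hashes of all inputs and outputs, and
an identical rerun reproduces identical bytes.

# Known limitations

* Per-promoter target scoring ("which promoters does motif $m$ act
  through") is out of scope; only motif-level activities are modeled.
* Standard errors are conditional on the chosen $\lambda$; the
  uncertainty of the penalty selection itself is not propagated.
* The per-motif $z$ and the contrast $z$ are used with fixed cutoffs, as
  in the motivating analysis; no multiple-testing correction across
  motifs is applied.
* Activities of motifs with strongly collinear site-count columns are
  only identified jointly; the ridge penalty shrinks but does not
  resolve such degeneracy.
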