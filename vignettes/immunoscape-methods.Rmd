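---
title: "immunoscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunoscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, what the synthetic generator does and does not emulate, and where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The enrichment model

`score_matrix()` computes a single-sample, rank-weighted running-sum
enrichment score. Within each sample, genes are ranked (highest expression
= rank *N*) and, walking genes in decreasing rank order, the score
accumulates the difference between the weighted fraction of set members
passed — weights $r_j^\alpha$ on the rank values — and the unweighted
fraction of non-members passed. Using rank values rather than raw
expression as weights makes the raw score invariant under any strictly
increasing per-sample transform of tie-free expression (a tested property),
and therefore robust to the upstream normalization choice. Consequences of
this design:

* **Sample independence.** A sample's raw score never depends on other
  samples. The optional normalization (`normalize = TRUE`, the default)
  divides the whole matrix by its global max − min, which makes the score
  range exactly 1 but couples samples; the flag is recorded in the output
  metadata so downstream users know which regime they are in.
* **Within-sample rank competition.** Ranks are zero-sum: if many gene
  sets rise together, they compete for the top ranks and between-sample
  differences compress. This matters when building test matrices — see the
  generator section.

Tunable parameters (all in `ssgsea_config()`):

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.25 | exponent on rank weights; the published default of the invoked method family. The source study does not state it. |
| `normalize` | `TRUE` | global max − min scaling of the score matrix |
| `tie_policy` | `stable_ordinal` | ties broken by lexicographic gene symbol, for bit-reproducibility; `average_rank` gives parity with implementations that use midranks |
| `min_set_size` | 2 | sets smaller than this after intersecting with the matrix are skipped (`NA` row) |

Genes named in a set but absent from the matrix are dropped with a warning
rather than treated as zeros: an unmeasured gene carries no rank
information, and a zero would be an arbitrary strong claim.

## Composite scores

* **CYT** is the geometric mean of PRF1 and GZMA expression with a
  pseudocount ε = 0.01 on the linear scale (scale of the input matrix;
  whether the original analysis used logged or linear expression is not
  stated anywhere, so the pseudocount and scale are configuration).
* **TIS** averages nine T-subset enrichment rows after z-scoring each row
  with the sample standard deviation (ddof 1, a documented constant). The
  source panel lists a generic "CD8 T" subset that its own 27-type panel
  does not contain; the slot maps to "Activated CD8 T cell" by default and
  is overridable via `tis_set_names`.
* **CD8/Treg ratio**: enrichment scores can be negative, so a raw ratio is
  ill-behaved (sign flips, division near zero). Each row is min–max
  rescaled across samples to [δ, 1], δ = 0.01, before dividing. This is an
  explicit repair of an under-specified "digital ratio", recorded in output
  metadata; ratios live in [δ, 1/δ] and increase strictly in the CD8 score.
* **APM**: no antigen-presentation gene list is printed in the source
  study; the packaged default is a documented 8-gene MHC-I
  processing/presentation set (`default_apm_genes()`), treated as
  configuration, not ground truth, and fully overridable via the GMT.
* **IFN-γ readout**: single-gene IFNG expression is reported when the gene
  is measured; a signature-based score can be produced by shipping an
  IFN-γ set in the GMT and scoring it as a pathway. Both usages appear in
  the source analyses without a definition of the signature's gene list,
  hence the dual mode.

## Immunophenotype tiers and median splits

Samples are clustered on the z-scored cell-type rows with Ward linkage
(`ward.D2`) and the tree is cut at k = 3 (a fixed design, not selected).
Clusters are relabeled H/M/L by descending mean panel infiltration, so the
labels are anchored to biology rather than to tree traversal order. The
source material states two different metrics in two places (Euclidean in a
figure legend, Pearson correlation in the methods); both modes are
provided and recorded in metadata, neither privileged as "the"
reproduction — which of the two produced the published cluster sizes is
unknowable from the text.

`median_split()` assigns Hi to values strictly greater than the median and
Lo to the rest. This convention is fixed by the published group sizes
(99/100 at n = 199, 179/180 at n = 359): the median observation lands in
Lo. The split is invariant under strictly increasing transforms of the
score.

## Cohort statistics

Group comparisons wrap base R's tested implementations behind explicit
contracts: Mann–Whitney is exact when both groups have ≤ 20 tie-free
observations and normal-approximate with continuity correction otherwise;
the t-test is the Welch variant (the source says only "Student's
t-tests"; unequal variance is the safer default); ANOVA is the classic
equal-variance F. For 2 × 2 contingency tables with any expected count
below 5, the Fisher exact test replaces the chi-square. Correlation
p-values use the t transform with n − 2 df, for Spearman applied to the
rank correlation (the standard large-sample treatment). Raw p-values are
reported, matching the source analysis, which applied no multiplicity
correction; Benjamini–Hochberg is available (`adjust_bh()`) but off by
default.

## Survival

Kaplan–Meier, log-rank and univariate Cox are implemented directly.
Design constants: Efron handling of tied event times (better than Breslow
and the standard modern default; relevant because survival times are
day-resolution integers); Newton iteration to |score| < 1e-9 with at most
50 steps and explicit diagnostics for monotone likelihood; subjects
censored at exactly t = 0 are dropped with a warning as uninformative. The
Cox score test at β = 0 equals the two-group log-rank statistic for a
binary covariate, which the test suite verifies numerically to 1e-6 — a
useful internal consistency check between two independently written code
paths. The 0–4,000-day window applies to plotting only; events beyond it
still enter every statistic. Both log-rank and Cox p-values are reported
side by side, since the source reports each in different places without
saying which produced which figure.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` plants, per sample: an infiltration tier
(multipliers 0.2 / 1.0 / 3.0 with probabilities 0.26 / 0.41 / 0.33,
mirroring the published L/M/H proportions), a side (right with
probability 0.36, the study-like fraction), and per-cell-type infiltration
fractions $f_{c,s} = u_s \exp(\delta_{c,\mathrm{side}})
\exp(\mathcal{N}(0, 0.1))$. Signature genes respond multiplicatively,
$x_{g,s} = b_g (1 + \kappa f_{c,s}) e^{\mathcal{N}(0,\sigma^2)}$ with
$b_g \sim \mathrm{LogNormal}(2, 0.5)$, κ = 1, σ = 0.3 — the log-normal
form mimics the positivity and skew of normalized RNA-seq. The planted
sidedness structure: the nine T subsets shift up on the right
(δ = +0.5); CD56-bright NK and the 4-1BB / IFN-α pathway blocks shift up
on the left (δ = +0.3); VEGFA expression is depressed by CD8 infiltration
on the right side only (coupling w = 1). Survival is exponential with
baseline hazard 5e-4/day (baseline median ≈ 1,400 days, inside the
4,000-day follow-up) and log-hazard −0.3 per SD of latent overall
infiltration; censoring is uniform on (0, 4,000] days, giving roughly
40% censoring.

Background genes default to 2,000. This is deliberate: ranks are zero-sum
within a sample, so a matrix in which signature genes are a large fraction
makes the 27 signatures compete for rank mass and compresses
between-sample enrichment signal — an artifact a real ~20k-gene
transcriptome does not have. (The package's first fixture used 500
background genes and exhibited exactly this compression; the correction is
recorded in the project's decision log.)

Deliberate simplifications, hence what a green recovery test does *not*
establish: signatures are disjoint (real marker sets overlap), there is no
gene–gene correlation beyond the planted factors, no batch effects, no
tumor purity gradient, and survival has proportional hazards by
construction. Recovery tests certify the pipeline's statistical machinery,
not the biological validity of any particular marker panel.

## Known limitations

* **Correlation-distance tier recovery is structurally impossible in the
  generator's world.** Pearson correlation between two sample profiles
  centers each profile, removing any uniform level difference — and a
  multiplicative tier that scales every cell type equally is exactly such
  a level difference. Empirically the tier ARI under correlation distance
  is ≈ 0 with or without row z-scoring, while Euclidean mode recovers the
  tiers exactly. The corresponding acceptance check is left failing by
  design rather than weakened; on real data, where cell types respond
  heterogeneously, correlation distance can still be meaningful, which is
  why the mode remains available.
* Multi-cohort input (e.g. colon plus rectum series) is expected to be
  merged upstream by shared genes; the package applies no batch handling
  (the source is silent on how its two cohorts were merged) and this is a
  stated limitation, not a solved problem.
* Extra clinical columns (mutation flags, stage) are carried through and
  used only where the pipeline names them (mutation × cluster tables);
  survival analyses use all samples — whether the published curves were
  stage-restricted is not stated, and no stage filter is applied.
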