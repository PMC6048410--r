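# immunoscape

Immune-landscape scoring and sidedness analysis for bulk tumor
transcriptomes.

Colorectal tumors arising on the right side of the colon (cecum to
transverse colon) and on the left (splenic flexure to rectum, rectal tumors
included) differ in their immune microenvironment, and those differences
carry prognostic and treatment-selection weight. `immunoscape` implements
the complete analysis skeleton used to characterize such differences from a
genes × samples expression matrix:

- **ssGSEA scoring** of immune cell-type marker signatures, from scratch.
  For a sample with *N* measured genes and a set of *m* members, genes are
  ordered by decreasing within-sample rank *r* and

  *ES = Σᵢ [ P_in(i) − P_out(i) ]*,  
  *P_in(i) = Σ_{j≤i, j∈set} r_j^α / Σ_{j∈set} r_j^α*,
  *P_out(i) = #{j ≤ i, j∉set} / (N − m)*, with α = 0.25.

- **Composite immune scores**: cytolytic activity
  CYT = √((PRF1+ε)(GZMA+ε)); the T-cell infiltration score TIS (mean of
  nine z-scored T-subset enrichments); CD8/Treg digital ratio (on a
  [0.01, 1] min–max rescale); pathway signatures (4-1BB signaling,
  IFN-α response, antigen presentation machinery) via the same engine.

- **Immunophenotype tiers**: Ward hierarchical clustering of samples into
  High/Median/Low infiltration groups (Euclidean on z-scored rows, or
  correlation distance), relabeled by mean panel infiltration.

- **Cohort statistics**: Mann–Whitney / Welch-t sidedness contrasts,
  one-way ANOVA across tiers, Pearson/Spearman correlations (e.g.
  VEGFA vs CD8 enrichment per side), mutation × cluster contingency tests.

- **Survival**: Kaplan–Meier product-limit curves (0–4,000-day display
  window), the k-sample log-rank test, and univariate Cox regression by
  Newton iteration on the Efron partial likelihood — all implemented
  directly and cross-checked against the `survival` package in the tests.

- **A synthetic cohort generator** with planted ground truth (infiltration
  tiers, side shifts, a right-side-only VEGFA–CD8 anti-correlation, and
  score-dependent exponential survival), so every stage is testable for
  signal recovery without any external download.

## Worked example

Simulate a 120-patient cohort with the default planted structure and run
the full pipeline:

```r
library(immunoscape)
s <- run_pipeline(list(simulate = TRUE, n_samples = 120, seed = 2,
                       out_dir = "run_out"))
s$cluster_sizes
#> $H  27   $M  59   $L  34
subset(s$contrasts, grouping == "side" & score %in% c("cyt", "tis"))
#>  score grouping         test     n statistic      p_value direction
#>    cyt     side mann_whitney 74/46      1241 0.0129330008        -1
#>    tis     side mann_whitney 74/46      1034 0.0003146643        -1
s$correlations$vegfa_cd8_right$r   #> -0.92   (left side: -0.004)
```

The H/M/L sizes are the three infiltration tiers found by Ward clustering
of the 27 cell-type enrichment rows. Each `side` contrast row is a
two-sided Mann–Whitney of a composite score between left (n = 74) and
right (n = 46) tumors; `direction = -1` means the right side scores
higher, recovering the planted T-subset shift. The VEGFA–CD8 Pearson
correlation is strongly negative on the right side only, the planted
coupling asymmetry. `run_out/` receives `enrichment.tsv`, `scores.tsv`,
`classes.tsv`, `stats.tsv`, `km_curves.pdf`, `truth.tsv` and a
deterministic `summary.json`.

Real data enter the same way: point the config at a genes × samples TSV
(or MatrixMarket triplet), a GMT of marker sets and a clinical TSV
(`sample_id`, `os_days`, `event`, `side`):

```r
run_pipeline(list(expression = "expr.tsv", gmt = "sets.gmt",
                  clinical = "clinical.tsv", out_dir = "out"))
```

Tiny packaged examples live in `inst/extdata/` (`toy_expression.tsv`,
`toy_sets.gmt`, `toy_clinical.tsv`; the marker sets there are synthetic
stand-ins, not curated signatures). A command-line front end with verbs
`simulate`, `ssgsea` and `run-all` is in `inst/cli/immunoscape.R`.

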