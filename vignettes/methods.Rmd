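---
title: "Methods: secretome prioritization and biomarker evaluation in stromascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secretome prioritization and biomarker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascreen)
```

`stromascreen` prioritizes stroma-derived secreted proteins from a
comparative fibroblast-versus-cancer-epithelium secretome experiment and
evaluates candidate markers with survival, association and ROC
statistics. This vignette documents the statistical model behind each
stage, the tunable parameters and their defaults, the synthetic-data
model used for testing, and the numerical and design choices a
maintainer should know about.

## Target-decoy identification filtering

Protein identifications arrive as per-run tables with a protein-level
confidence score (an "unused" score: evidence from peptides not already
claimed by higher-ranking proteins), a count of distinct peptides at the
table's confidence level, and a decoy flag from a reversed/shuffled
database search.

`estimate_fdr_threshold()` uses the **simple target-decoy ratio**: the
threshold is the smallest observed score $t$ with
$\#\{\text{decoys} \ge t\} / \#\{\text{targets} \ge t\} \le \alpha$,
default $\alpha = 0.01$. We deliberately use the plain decoy/target
estimator rather than the doubled ($2D/(T+D)$) variant: it is the
conservative textbook choice when the search engine's own FDR machinery
is out of scope, and it matches the "one score cutoff per run" usage the
pipeline needs. Candidate thresholds are the observed scores themselves,
so the returned value is always attainable by the data.

Degenerate inputs: an empty run or an all-decoy run is an error; a run
with **no decoys** returns the minimum score with a warning (the
empirical FDR is already zero everywhere, and failing would make
decoy-free reprocessed tables unusable).

`accept_proteins()` accepts a protein if, in at least
`require_in_n_runs` runs (default 1), its score is **strictly above**
the run threshold — "above" is taken literally, so a protein scoring
exactly at the cutoff is rejected — and it has at least
`min_unique_peptides` (default 2) distinct peptides. The peptide count
column is agnostic to the confidence level at which peptides were
counted; 95% is the default semantics and the level is a property of
the input table, not a switch inside the package, because upstream
search engines disagree on how they report it. Decoys surviving the
same rule are reported as `residual_decoys` and as an overall empirical
FDR; a stringent threshold-plus-peptide rule typically removes all of
them.

`merge_runs()` combines runs by accession and, given per-run
quantitation availability, partitions the catalog into proteins
quantified in all runs, in some, and in none. Only the all-runs subset
is eligible for replicate-consistent enrichment calls.

## iTRAQ enrichment calls

The 8-plex design ratios every channel to a reference channel that
itself labels a fibroblast sample (default: channels 113–117 fibroblast,
118/119/121 cancer, reference 113). Consequences of that design, both
deliberate:

* the reference column is identically 1 and is validated as such;
* the constant 1 **is a member of the fibroblast sample vector** in the
  per-protein test, since channel 113 is a real fibroblast sample. The
  alternative (dropping the reference from its group) is available by
  passing a `channel_design()` whose groups exclude it.

Per run, the fold change is the ratio of raw-scale group means,
$FC = \bar r_{\text{fib}} / \bar r_{\text{can}}$ — raw means, because
the reported "average fold change" convention in this field is
arithmetic. The p value comes from a two-sample pooled-variance
Student's t test on **log2 ratios** (default): isobaric ratio noise is
multiplicative, and testing on the log scale makes the group-swap
symmetry exact ($FC \mapsto 1/FC$, p unchanged). Raw-scale testing and
Welch's unequal-variance variant are configuration switches for
sensitivity analysis. `per_run_enrichment()` computes these statistics
vectorized over proteins; the test suite asserts row-by-row agreement
with the scalar `two_sample_ttest()` wrapper around `stats::t.test()`.

Missing channels are handled pairwise-complete within a run; a protein
needs at least two usable ratios per group to be quantifiable in that
run. Zero pooled variance is resolved explicitly: identical constant
groups give $p = 1$, separated constants give $p \to 0$.

`call_enrichment()` applies the replicate-consistency rule: fibroblast-
enriched iff $FC \ge 2$ and $p < 0.05$ in **every** run (defaults
`fc_min = 2`, `alpha = 0.05`, `require_all = TRUE`); epithelial-enriched
with $FC \le 1/2$ symmetrically; otherwise neither. The three calls
partition the catalog. Under the null, the all-runs conjunction bounds
the per-direction false-call rate by roughly $\alpha^R$ before the fold-
change condition tightens it further. The reported `average_fc` is the
arithmetic mean of per-run fold changes in fibroblast/cancer
orientation; for epithelial calls readers usually quote the reciprocal.

## Localization classification

The classifier is a strict priority cascade, applied per protein:

1. **secreted** — any secreted-tier evidence: an annotation term in the
   secreted dictionary (default: secreted, extracellular
   region/space/matrix), a classical signal-peptide predictor consensus,
   or a non-classical secretion prediction;
2. **plasma membrane** — otherwise, any membrane-tier term (plasma
   membrane, cell membrane, cell junction);
3. **intracellular** — everything else.

The tier order is taken literally: secreted evidence wins even against a
co-occurring membrane annotation, which makes the cascade monotone
(adding secreted evidence can never demote a protein). Term matching is
case-insensitive on whole terms, and the dictionaries ship as a
versioned YAML (`inst/extdata/localization_terms.yaml`) because the
underlying vocabularies are open-ended — users curating from a different
annotation source can extend them without touching code.

Exosome-catalog membership (`exosome_hits`, the number of catalog
experiments containing the protein) is reported as evidence but **never
reclassifies**: catalog presence says a protein was detected in vesicle
preparations, not that secretion is its annotated localization. High
overlap of even the intracellular class with exosome catalogs is the
expected biological signal, not a classification failure.

`summarize_localization()` reports counts and integer-rounded
percentages (`round(100 * count / total)`), which is why a 587/182/345
split of 1114 prints as 53/16/31.

## Vote-count screen

Each gene carries the number of independent microarray analyses that
called it significantly up- or downregulated (at each source analysis's
own p < 0.05). The call is *cancer-up* iff `n_up >= up_min` and
`n_down <= down_max` (defaults 15 and 1), mirrored for *cancer-down*.
The **inclusive** `>= 15` is intentional: the bundled reference table
contains up-genes with exactly 15 supporting analyses, so an exclusive
reading of "more than 15" would contradict the table it summarizes.
Dashes in count columns parse as zero. The bundled 28-row table
(`stromal_vote_table()`) doubles as a deterministic fixture: 20 genes
screen cancer-up and 8 cancer-down at the defaults.

## Biomarker evaluation statistics

These are implemented from first principles — the package exposes the
risk-set bookkeeping, and the test suite cross-checks every one against
an independent oracle and against `survival`, `pROC` or
`stats::fisher.test`.

* **Kaplan-Meier** (`km_curve()`): product-limit estimator
  $S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$; right-continuous,
  $S(0) = 1$. Subjects censored at an event time remain at risk for that
  time's events (events-before-censorings, the Mantel-Cox convention).
* **Log-rank** (`logrank_test()`): unweighted k-group Mantel-Cox with
  the hypergeometric variance-covariance accumulated over pooled event
  times; $\chi^2$ on $k - 1$ df (so a four-way comparison of
  stroma/epithelium positivity combinations uses 3 df). A singular
  covariance (a group exhausted before the first event) falls back to a
  pseudoinverse.
* **Median split** (`dichotomize_by_median()`): ties at the median go to
  the lower group by default — deterministic and documented; an
  `exclude` variant drops ties, and only that variant guarantees the
  group-imbalance-bounded-by-ties property.
* **IHC scoring** (`ihc_score()`): intensity is the mean of IOD/area
  over a sample region's images; positive iff intensity **strictly
  exceeds** the cutoff (default 0.043, dimensionless optical density per
  area). Strict inequality is chosen because such cutoffs are placed
  manually *between* ranked samples, so boundary behavior is
  unobservable; the choice is documented rather than consequential.
* **Fisher's exact** (`fisher_exact_2x2()`): two-sided p as the sum of
  hypergeometric probabilities of all tables no more probable than the
  observed one (with the customary $1 + 10^{-7}$ tolerance against
  floating-point ties), matching `stats::fisher.test`.
* **ROC** (`roc_points()`, `auc()`, `optimal_cutoff()`): the curve
  sweeps every observed concentration as a threshold (positive means
  concentration at or above it), with endpoints (0,0) and (1,1);
  trapezoid AUC equals the Mann-Whitney statistic with tie half-credit;
  the optimal cutoff maximizes Youden's J = sensitivity + specificity −
  1, ties broken toward the lower concentration (favoring sensitivity
  in a screening context). Cases are assumed to run higher;
  `roc_analysis()` warns when AUC < 0.5 instead of silently flipping.

## The synthetic-data model

Every pipeline input can be generated with planted ground truth
(`synthetic_config()` plus one generator per input). Defaults encode the
study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_proteins`, `n_runs` | 1000, 3 | catalog size, LC-MS replicates |
| `id_thresholds` | 2, 1.62, 2.01 | planted per-run 1%-FDR score cutoffs |
| `fraction_decoy` | 0.10 | decoy rows per run |
| `planted_fibro_enriched` / `planted_epi_enriched` | 116 / 44 | planted differential proteins |
| `fc_effect`, `ratio_cv` | 8, 0.2 | true group ratio and log-normal ratio CV |
| `localization_mix` | 0.53/0.16/0.31 | secreted/membrane/intracellular |
| `exosome_rate` | 0.95 | catalog-membership probability |
| `n_vote_up` / `n_vote_down` | 20 / 8 | planted screen genes (of `n_genes` = 150) |
| plasma | 42 cases at 61.6 ± 12, 48 controls at 45.0 ± 8 ng/mL | two-group marker model |
| survival | n = 90, HR = 2, median 51 months, uniform censoring on (0, 85] | cohort model |

Model choices: iTRAQ ratios are log-normal (multiplicative noise; the
CV maps to `sdlog` via $\sqrt{\log(1+CV^2)}$) with the planted effect
placed on the cancer channels so the reference stays a valid fibroblast
sample. Decoy scores are drawn from a low null with exactly enough
contamination at and above the planted threshold that the simple
estimator's 1%-FDR crossing sits at the planted value — one decoy is
pinned exactly at the threshold so the crossing is an observed candidate
score and recovery is exact to one score-grid step (grid 0.01). Plasma
concentrations are normal truncated at zero; the group standard
deviations are not dictated by the design, so 8 (controls) and 12
(cases) ng/mL were fixed once as realistic dispersions — cases more
variable — giving a closed-form binormal AUC
$\Phi(\Delta/\sqrt{\sigma_1^2+\sigma_2^2}) \approx 0.87$, and the tests
compare the empirical AUC against that closed form rather than against
any external figure. Survival times are exponential with group-ratio
hazards and uniform censoring.

What the generator does **not** emulate: correlated channel noise and
ratio compression of real isobaric data, shared-peptide protein
inference, batch structure between runs, annotation errors, or
non-proportional hazards. Passing tests therefore demonstrate that the
algorithms implement their definitions and recover planted truth under
idealized noise — not that the thresholds are optimal for any particular
real dataset.

## Problem sizes and tolerances in the test suite

The suite runs the recovery studies at the design scale (1000 proteins,
3 runs) over 20 seeds, the null study at 5 × 1000 proteins, the
plasma closed-form comparison over 200 replicates of the 42 + 48 design,
and the oracle equivalences on 100 random small instances per statistic —
sizes chosen so each study has enough replication for its binomial or
Monte-Carlo error bound while the whole suite stays interactive (about
twenty seconds). Stochastic assertions use pre-registered error bands
(3–4 standard errors plus a small truncation allowance), not tuned
margins.

## Known limitations

* The FDR estimator is the simple decoy/target ratio; no q-value
  monotonization or doubled-decoy variant is provided.
* `two_sample_ttest()` requires two observations per group; single-
  observation channels make a protein unquantifiable in that run rather
  than borrowing variance across proteins (no moderated/empirical-Bayes
  test).
* The localization cascade is term-driven; it cannot adjudicate between
  genuinely conflicting annotations beyond its tier order.
* The ROC machinery assumes a single continuous marker and binary truth;
  no confidence intervals on AUC or the cutoff are produced.
* `run_pipeline()` is deterministic given inputs and seed, but the
  simulated-input mode regenerates inputs rather than versioning them;
  persist the written TSVs if you need a frozen dataset.
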