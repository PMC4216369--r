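---
title: "Methods: smoking-status-stratified miRNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoking-status-stratified miRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mirsmoke analyzes miRNA sequencing data (RPKM units) from lung
adenocarcinoma cohorts in which each patient contributes a matched tumor
and non-malignant lung sample and carries a smoking history: current
smoker (CS, smoking at diagnosis), former smoker (FS, quit at least a year
before diagnosis), or never smoker (NS, under 100 lifetime cigarettes).
The scientific question is whether miRNA deregulation in tumors and in
exposed normal tissue is smoking-status-specific, whether smoke-induced
changes revert after cessation, and whether miRNA expression stratifies
patient survival differently across smoking groups. This vignette
documents the statistical procedures, their tunable parameters, the
synthetic cohort generator used as the test bed, and the design decisions
taken where the procedures left latitude.

## Detection and fold change

RPKM below 1 is treated as "not expressed". Two consequences run through
everything:

* `filter_expressed()` removes miRNAs never reaching 1 RPKM in any sample
  (strict `< 1`: a miRNA peaking at exactly 1.0 is kept).
* `fold_change(t, n) = max(t, 1) / max(n, 1)`. Flooring both sides keeps
  ratios of undetectable values at exactly 1 instead of producing
  unstable or undefined quotients. A consequence worth knowing: an
  underexpression call (fold < 0.5) requires normal-side expression of at
  least 2 RPKM, and the fold of a 4-fold effect is fully visible only
  when the normal side is at or above the floor.

## Group-level differential expression

`smoke_response_de()` compares two sample groups (canonically CS-normal
vs NS-normal tissue, the two exposure extremes) per miRNA:

* a two-sided permutation test on log2(RPKM + 1) with the difference of
  group means as statistic. 10,000 Monte-Carlo label permutations are
  shared across miRNAs (one weight-matrix product per batch), and the
  add-one estimator `(1 + #extreme)/(n_perm + 1)` prevents zero p-values.
  For tiny groups, where the number of distinct label assignments is
  at most `n_perm`, the test enumerates the full null support instead and
  marks the result exact.
* Benjamini–Hochberg correction across the tested miRNAs.
* an average fold change: the ratio of floored group mean RPKMs. We read
  "average fold change" as ratio-of-means rather than mean-of-ratios; it
  is the form that remains usable when matched normals are unavailable
  and pooled group means are all one has (the external-validation
  setting), and it is less dominated by single-pair outliers.

A miRNA is called over/underexpressed when q < 0.05 **and** the fold is
> 2.0 or < 0.5. Both gates are strict inequalities; the q threshold and
fold gates sit in `analysis_config()` and the underexpression gate is
always the reciprocal of the overexpression gate.

## Recurrence ("penetrance") calling and specificity

Within one smoking group's matched pairs, `recurrence_scan()` calls a
miRNA deregulated when

1. the Wilcoxon signed-rank test on per-pair log2 fold values survives
   B-H at q < 0.05, the family being the group's full tested miRNA set
   (never per-miRNA, and each smoking group is its own family), and
2. the fold exceeds 2 (or falls below 0.5) in at least 25% of the
   group's pairs — inclusive, so 2 of 8 pairs qualifies.

Zero per-pair differences are dropped before ranking (Wilcoxon's original
treatment); for up to 15 retained pairs the p-value enumerates all 2^n
sign assignments, beyond that a tie-corrected normal approximation with
continuity correction is used. If both directions pass the frequency
gate, the more frequent wins and an exact tie yields no call.

`classify_specificity()` then counts, per miRNA and direction, how many
groups met the criteria: exactly one group makes the miRNA
smoking-status-specific to that group, all three make it shared, two make
it partial. Directions are classified independently, so a miRNA can be,
e.g., CS-specifically underexpressed and NS-specifically overexpressed at
once.

## Reversibility after smoking cessation

Smoke-responsive miRNAs are those differentially expressed between CS and
NS normal tissue. `classify_reversibility()` asks what former-smoker
normal tissue does: still differentially expressed against NS normals in
the same direction is irreversible; returned to never-smoker levels (no
DE) is reversible. The reference comparison is FS-normal vs NS-normal —
the natural reading of "returned to never-smoker levels"; comparing FS to
CS instead would conflate partial reversion with no reversion. An FS
shift opposite to the CS shift is contradictory under this model and is
classed not-smoke-responsive with a warning.

## External-cohort validation

External cohorts typically lack enough matched normals, so each external
tumor's fold change is computed against the pooled mean of that cohort's
normal samples of the same smoking status. A specific miRNA validates
when the disruption frequency (fraction of tumors beyond the fold gate)
differs between the focal group and the rest both by Fisher's exact test
(p < 0.05) and by at least 15 percentage points. The frequency gate makes
validation monotone in the focal disruption count at fixed group sizes.

## Clustering

`ward_cluster()` z-scores each miRNA across samples on the log2(RPKM + 1)
scale, drops constant rows, and applies Ward's minimum-variance
agglomeration in the `ward.D2` form (the Lance–Williams update on
Euclidean distances) via `hclust`, cut at a user-chosen k (2 for
tumor/normal separation, 3 within a tissue compartment are the defaults
we use). `hclust` breaks equal-height merge ties by its own deterministic
rule, so dendrograms are reproducible for fixed input. Composition is
tested by Fisher's exact test for 2x2 cluster-by-label tables and Pearson
chi-square for larger ones; clinical covariates are screened by one-way
ANOVA F across clusters (stage encoded as the ordinal I–IV), with
pack-years/years-quit contrasts between two named clusters by Student's
t-test, and constant covariates reported as F = 0, p = 1.

## Survival analysis

Per miRNA and stratum (all patients, then each smoking group):

* the two-thirds detectability gate: tested only if RPKM >= 1 in at least
  `ceiling(2n/3)` of the stratum's patients (146 of 218 — expression in
  145 is not enough).
* tertile split: patients sorted by expression with ties broken by
  patient identifier; bottom and top `floor(n/3)` kept, middle discarded.
  When the cohort is a merge of sources with systematically different
  RPKM scales, tertiles are computed within cohort of origin and the
  tails pooled — pooling raw values would stratify by cohort, not
  biology. The `cohort` column added by `merge_cohorts()` triggers this
  automatically.
* log-rank (Mantel–Haenszel, 1 df) comparing top against bottom tertile,
  B-H within stratum; the reported direction is whichever tertile's
  Kaplan–Meier curve lies lower at the stratum's median follow-up. Zero
  total events returns p = 1 by convention.

Kaplan–Meier estimation, the log-rank test and Cox regression are
executed by the survival package (`survfit`, `survdiff`, `coxph`); the
test suite checks them against hand product-limit computations, a hand
O−E/V risk-table oracle, and a brute-force grid search of the written-out
Breslow partial likelihood. `coxph_fit()` uses Breslow tie handling (the
simplest form consistent with the closed-form partial likelihood; Efron
is the common alternative), one-hot encodes factors against their first
level, enters stage as the ordinal 1–4 and expression as log2(RPKM + 1),
refuses zero-variance covariates by name, and flags non-convergence
within 50 Newton–Raphson iterations. Conventions follow the source
procedures: log-rank p < 0.05, Cox p < 0.1, MANOVA p < 0.05.
`expression_covariate_manova()` screens confounding by running the Wilks
MANOVA of expression against each covariate (numeric covariates binned
into tertiles for grouping).

## Self-implemented test primitives

The permutation test, Wilcoxon signed-rank, Benjamini–Hochberg, Fisher's
exact 2x2 (two-sided by the point-probability rule; the doubling rule is
a documented alternative), Pearson chi-square, tie-corrected
Kruskal–Wallis, and one-way Wilks MANOVA with Rao's F are implemented in
the package rather than delegated, with enumeration or closed-form
oracles in the test suite (base R's `wilcox.test`, `fisher.test`,
`p.adjust`, `kruskal.test`, `manova` serve only as independent
cross-checks). Every Monte-Carlo operation takes an explicit seed and
records it in its result.

## Target networks

`build_network()` consumes a miRNA-to-gene prediction table already
carrying per-pair source-support counts; `filter_predictions()` keeps
pairs supported by at least 6 sources (inclusive). Each miRNA node
carries a group tag (its specificity group, or `common`), inherited by
its edges. "Only the most highly connected miRNAs" is operationalized as
a `min_degree` parameter (no published cutoff exists); dropped miRNAs
take their edges with them and degrees are recomputed. Gene nodes can be
restricted to a reference list such as a curated prognostic-gene set,
which never increases any degree. The summary tabulates genes targeted
exclusively by one group tag versus genes shared across tags; exports are
a flat TSV edge list and GraphML. Functional annotations are carried as
optional node columns, never computed.

## The synthetic cohort generator

`simulate_cohort()` produces the test bed for everything above. Defaults
mirror the reference cohort's statistical shape: 94 patients (43 CS / 24
FS / 27 NS), two libraries each (188 samples), 1372 miRNAs of which 445
are forced below the detection floor everywhere (so the filter leaves
exactly 927), log-normal resting expression (meanlog 1.5, sdlog 1.5 on
the natural scale — continuous, heavy-tailed, two parameters; a negative
binomial would model counts, but the pipeline consumes RPKM), and
per-measurement log-normal noise.

Planted structure, all at fold 4:

* 196 over- and 36 underexpressed miRNAs deregulated in tumors of all
  three groups; 14/11 (CS), 12/2 (FS), 26/1 (NS) deregulated in exactly
  one group. Effects apply per pair with probability 0.5 (the
  "penetrance"), mirroring recurrence-style calling.
* 37 smoke-responsive miRNAs (25 up, 12 down) shifted in both
  compartments of current smokers — the exposure affects the lung tissue
  the tumor arises from, so within-pair folds are untouched. 15 of them
  remain shifted in former smokers (irreversible); the remaining 22
  revert (reversible).
* one prognostic miRNA whose standardized log2 tumor expression
  multiplies an exponential hazard (baseline 0.02 events/month, log
  hazard ratio 0.7 per SD), under uniform-entry administrative censoring
  calibrated to a 30% censoring fraction. Exponential survival with a
  multiplicative hazard is the simplest model satisfying the proportional
  hazards assumption the Cox stage must recover; uniform administrative
  censoring keeps the KM/log-rank assumptions exact.

Two generator properties are deliberate:

* planted rows draw their baseline from the detectable range (resting
  RPKM >= 4). A floored fold-change criterion cannot represent a planted
  effect on a sub-floor miRNA, and the candidate lists such criteria
  produce on real data are by construction detectable.
* `noise_log_sd` defaults to 0.25 (natural-log SD, roughly 29% CV),
  a realistic magnitude for measurement plus residual within-patient
  variation of detectably expressed miRNAs in matched tissue; the
  matched-pair design removes between-patient variation from the fold
  values by construction. At the configured penetrance and group sizes,
  recovery of planted specific miRNAs is insensitive to this parameter
  below about 0.3: the limiting factor is the binomial draw of how many
  pairs carry an effect, since a row carried by only a third of a
  24-pair group sits at the edge of what the signed-rank/B-H criterion
  can flag. Consequently per-seed sensitivities fluctuate; at the default
  seed the suite verifies at least 80% per specific group with a
  false-discovery proportion at most 0.2.

What the generator does **not** emulate: library-size artifacts,
miRNA-family cross-mapping, isomiR ambiguity, batch structure,
correlation between miRNAs (rows are independent), or informative
censoring. Passing tests therefore demonstrate the machinery's
correctness and its operating characteristics under the stated model, not
performance on any real cohort.

Determinism: one integer seed drives the Mersenne-Twister generator; the
RNG kind is recorded in the config, and identical configs reproduce
bit-identical cohorts, which the pipeline's manifest digests verify end
to end.

## Problem sizes in the test suite

The suite exercises full-size synthetic cohorts (1372 x 188) for the
recovery checks, 1000-replicate null simulations for type-I-error
calibration of the permutation, log-rank and Kruskal–Wallis tests
(rejection rates required to lie in [0.03, 0.07] at alpha = 0.05),
200-replicate n = 300 simulations for Cox hazard-ratio recovery (mean
within ±0.15 of the true 0.7), and exhaustive enumeration oracles for
every instance small enough to enumerate. `scripts/acceptance.R` re-runs
the same computations from scratch at a caller-supplied seed.

## Known limitations

* The recurrence criterion's power depends on the carrier fraction per
  group; planted-recovery rates quoted above are properties of the
  default configuration, not guarantees for arbitrary settings.
* Reversibility classification inherits the detection thresholds of the
  group-level DE step; weak smoke responses (fold near 2) classify
  unstably on real-scale noise.
* The external-validation rule conditions on pooled normal means and is
  sensitive to cohort-scale RPKM shifts; it is a reproducibility screen,
  not an effect-size estimate.
* `min_degree` ("most highly connected") has no principled default; the
  pipeline records the value used in its manifest.
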