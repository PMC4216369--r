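# mirsmoke

Smoking-status-stratified analysis of miRNA sequencing data from paired
tumor/normal cohorts.

Lung adenocarcinoma arises in current smokers (CS), former smokers (FS)
and never smokers (NS) through partly distinct molecular routes.
`mirsmoke` implements a complete, tested pipeline for asking how miRNA
expression tracks smoking history across matched tumor and non-malignant
lung tissue: which miRNAs respond to active smoke exposure in normal
tissue, which of those revert after cessation, which are recurrently
deregulated in tumors of exactly one smoking group, whether such calls
reproduce in an external cohort, how miRNA expression stratifies
survival within smoking groups, and which genes the smoking-specific
miRNAs are predicted to target. It is aimed at computational biologists
working with miRNA-seq RPKM tables plus clinical metadata; every stage
is driven by ordinary tibbles and returns tibbles, so results compose
with dplyr/ggplot2 workflows.

## The statistical core

For expression matrix entries `x` (RPKM), with detection floor 1:

* **Detection**: a miRNA is expressed if RPKM ≥ 1; rows below the floor
  everywhere are dropped. Fold changes are floored:
  `FC = max(t, 1) / max(n, 1)`.
* **Smoke response** (CS-normal vs NS-normal): two-sided permutation
  test (10,000 permutations, difference of group means on
  log2(RPKM+1)), Benjamini–Hochberg across miRNAs; called when
  q < 0.05 and the group-mean fold is > 2.0 or < 0.5.
* **Recurrence per smoking group** (paired tumor/normal): Wilcoxon
  signed-rank on per-pair log2 folds with B-H q < 0.05, **and** fold
  > 2 (or < 0.5) in ≥ 25 % of the group's pairs. Satisfying the
  criteria in exactly one group makes a miRNA smoking-status-specific.
* **Reversibility**: smoke-responsive miRNAs still shifted in FS
  normals vs NS normals are irreversible; those back at never-smoker
  levels are reversible.
* **Validation**: Fisher exact p < 0.05 plus a ≥ 15-percentage-point
  disruption-frequency difference, with external folds taken against
  pooled same-smoking-status normal means.
* **Survival**: per miRNA, top vs bottom expression tertile (middle
  discarded, two-thirds detectability gate) by Mantel–Haenszel
  log-rank; multivariate Cox (Breslow ties) over expression, age, sex,
  ethnicity, stage and smoking status; Wilks MANOVA confounding screen.
* **Networks**: bipartite miRNA–gene graphs from ≥ 6-source target
  predictions, group-tagged edges, degree reports, prognostic-gene
  restriction, GraphML/TSV export.

The permutation, signed-rank, B-H, Fisher, chi-square, Kruskal–Wallis
and Wilks-MANOVA primitives are implemented in the package and verified
against enumeration oracles in the test suite. A synthetic cohort
generator (`simulate_cohort()`) reproduces the statistical shape of a
94-patient paired cohort — 1372 miRNAs of which 927 are detectable,
group sizes 43/24/27, planted shared/specific/reversible/irreversible
and prognostic effects — so the whole pipeline is testable without
patient data.

## Worked example

```r
library(mirsmoke)
library(dplyr)

co <- simulate_cohort(simulation_config(seed = 42))
f  <- filter_expressed(co$expression)
c(nrow(co$expression), nrow(f))
#> [1] 1372  927

pairs <- build_pairs(co$metadata)
table(pairs$group)
#> CS FS NS
#> 43 24 27

# smoke-responsive miRNAs in normal tissue (CS vs NS)
de <- smoke_response_de(f, co$metadata, "CS", "NS", "normal")
de |> filter(status != "none") |> arrange(q) |> head(3)
#> # A tibble: 3 × 6
#>   mirna_id statistic         p       q mean_fold status
#>   <chr>        <dbl>     <dbl>   <dbl>     <dbl> <chr>
#> 1 mir-0017      1.85 0.0001000 0.00251     4.22  over
#> 2 mir-0058     -1.53 0.0001000 0.00251     0.263 under
#> 3 mir-0074      1.95 0.0001000 0.00251     4.00  over

# recurrence calling per group, then specificity patterns
rec <- purrr::map_dfr(c("CS", "FS", "NS"),
                      \(g) recurrence_scan(f, pairs[pairs$group == g, ]))
spec <- classify_specificity(rec)
count(spec, pattern)
#> # A tibble: 5 × 2
#>   pattern         n
#>   <chr>       <int>
#> 1 CS-specific    25
#> 2 FS-specific    12
#> 3 NS-specific    25
#> 4 partial        44
#> 5 shared-all    188

# tertile log-rank survival scan across all patients
surv <- survival_scan(f, co$metadata, strata = "ALL")
surv |> arrange(p) |> head(2)
#> # A tibble: 2 × 8
#>   mirna_id stratum n_low n_high logrank_chi2       p  bh_q direction
#>   <chr>    <chr>   <int>  <int>        <dbl>   <dbl> <dbl> <chr>
#> 1 mir-1000 ALL        31     31         9.62 0.00192 0.599 high-worse
#> 2 mir-1155 ALL        31     31         8.92 0.00282 0.599 low-worse
```

The three smoke-response rows are planted 4-fold shifts in
current-smoker tissue recovered at q ≈ 0.0025 with mean folds ≈ 4 and
≈ 0.26 (1/4). The specificity table recovers the planted single-group
miRNAs (25/14/27 CS/FS/NS planted; two FS and two NS rows fall at the
power boundary at this seed). The top survival hit, `mir-1000`, is this
cohort's planted prognostic miRNA (log hazard ratio 0.7 per SD of
expression); at 94 patients it is the strongest raw-p signal, and at
combined-cohort scale (~200 patients) it survives B-H correction.

`run_pipeline(<yaml or list>, out_dir)` chains every stage (simulate or
load → filter → cluster → DE → specificity → reversibility → optional
validation → survival → Cox → optional network), writing per-stage TSVs
plus a JSON manifest with the config snapshot, seed and input digests;
identical configs reproduce byte-identical stage outputs.

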