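# rnaconcord

Integrative analysis of paired tumor DNA and RNA profiling reports at the
call level. The package is aimed at precision-oncology analysts who receive,
per patient, a list of genomic alterations (DNA panel) and a list of
expression alterations (RNA panel) and want to answer three questions:

1. **Concordance** — in which patients and genes do the two assays agree,
   i.e. where is the *same gene* reported altered by both DNA and RNA
   profiling?
2. **Association** — across the cohort, which (DNA gene, RNA gene) pairs
   co-occur more often than chance, including cross-gene pairs such as a
   transcription factor's alteration pairing with a target's overexpression?
3. **Prognosis** — does the per-patient count of expression-altered genes,
   the *tumor transcriptional burden* (TTB), stratify overall survival?

## The statistics at the core

For every pair (g, h) with g among the genes reported by DNA profiling and
h among the genes reported by RNA profiling, patients are cross-classified
into the 2x2 table

|                 | no RNA alt. in h | RNA alt. in h |
|-----------------|------------------|---------------|
| **no DNA alt. in g** | n00          | n01           |
| **DNA alt. in g**    | n10          | n11           |

and tested with the two-sided Fisher exact test (minimum-likelihood rule:
p = sum of hypergeometric probabilities of all tables with the observed
margins no more probable than the observed one). Benjamini-Hochberg
correction is applied across the full family of |G_dna| x |G_rna| pairs.
Significant pairs with g = h are *concordant pairs*; the rest are
discordant. Genes from significant pairs feed a one-sided hypergeometric
over-representation analysis against a GMT gene-set collection (sets with
>= 10 and < 250 genes; overlaps >= 10 reported at adjusted p < 0.05), and a
TRRUST-style edge list flags pairs whose DNA-side gene is a transcription
factor regulating the RNA-side gene. TTB strata (0-2 / 3-5 / >= 6 altered
genes by default) are compared with Kaplan-Meier curves and the log-rank
test.

Because patient-level clinical profiling data of this kind are generally not
redistributable, the package ships a seeded synthetic-cohort generator
(`generate_cohort()`) calibrated to the summary statistics such cohorts
exhibit, so that every pipeline stage is exercisable and testable
end-to-end. See the methods vignette (`vignettes/concordance-methods.Rmd`)
for the generative model and its calibration targets.

## Worked example

```r
library(rnaconcord)

co  <- generate_cohort(simulation_config(), seed = 1)
co
#> <cohort> 253 patients, 1134 DNA calls (216 genes), 671 RNA calls (52 genes)

rep <- run_report(co)
rep
#> == DNA-RNA concordance report ==
#> Cohort: 253 patients; 216 unique DNA genes, 52 unique RNA genes
#> Concordant events: 59 events in 53 patients (15 genes)
#>   copy-number vs expression Spearman rho = 0.69 (n = 47)
#>   purity, concordant vs not: Mann-Whitney p = 0.00764
#> Screen: 11232 pairs; 1 significant at adjusted p < 0.05 (0 concordant, 1 discordant)
#>   top pairs: TP53-VEGFA (adj p 5.4e-12)
#> <ttb_survival> 224 patients (treated only), strata by TTB breaks {2, 5}
#>   low: n=114, events=90, median OS 12.7 months
#>   mid: n=89, events=71, median OS 11.1 months
#>   high: n=21, events=17, median OS 4.9 months
#>   log-rank: chi-squared 9.98 on 2 df, p = 0.0068
#> TTB by PD-L1 (negative vs positive): Mann-Whitney p = 0.000549
```

Reading the output: 53 of the 253 simulated patients carry at least one
same-gene DNA/RNA concordant event (59 events in all), and among the
copy-number events the copy-number value and the expression score agree in
rank (Spearman 0.69) — concordance is detected preferentially in high-purity
samples (Mann-Whitney p = 0.008). The exhaustive screen over all 11,232
gene pairs recovers the one association planted by the default generator
configuration — TP53 alteration with VEGFA overexpression — as its only
discovery after FDR control. Survival stratified by TTB shows the >= 6-gene
stratum with markedly shorter median OS (4.9 months; log-rank p = 0.007),
and high-TTB patients are more often PD-L1 negative.

Each result has `tidy()`/`glance()` methods and an `autoplot()` for quick
inspection, e.g. `autoplot(rep$survival)` draws the stratified Kaplan-Meier
curves. `run_report(..., out_dir = "out")` writes every stage table
(`events.tsv`, `pairs.tsv`, `enrichment.tsv`, `network_edges.tsv`,
`survival.tsv`, `km_curves.tsv`) plus a JSON run manifest with checksums
and row counts; cohorts round-trip through `write_cohort()`/`read_cohort()`
as plain TSV.

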