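# genoscreen

Genome-first screening analysis for autosomal-recessive disease in
EHR-linked cohorts, modelled on cystic fibrosis (CF) at the *CFTR* locus.

A *genome-first* screen starts from DNA: every individual in a sequenced
cohort is called screen-positive when they carry a **bi-allelic
pathogenic genotype** — homozygous for one pathogenic allele, or
heterozygous for two distinct pathogenic alleles (a compound
heterozygote, assumed in trans) — and the clinical phenotype is reviewed
afterwards from the electronic health record (EHR). `genoscreen`
implements the full analysis chain for this design:

1. **Variant knowledge base** — load dated CFTR2-style and ClinVar-style
   assertion snapshots; an allele is *pathogenic* when CFTR2 calls it
   "CF causing" **or** ClinVar calls it "Pathogenic"/"Likely pathogenic"
   (union rule; review stars are recorded, not filtered on). Queries are
   date-aware, so historical knowledge states can be replayed.
2. **Cohort I/O and marker QC** — minimal VCF + manifest + ICD-10 code
   and chart-fact sidecars; array-marker QC with call rate > 98%, exact
   Hardy–Weinberg test p > 1e-06 (conditional enumeration), and minor
   allele count ≥ 2.
3. **Genotype screen** — per-individual status
   `BIALLELIC_POSITIVE` / `CARRIER` / `NEGATIVE`, allele accounting, and
   cross-platform (exome vs clinical test) concordance with an era-aware
   explanation of historical panel misses.
4. **EHR cross-reference** — diagnosis-code positivity (default code set
   E84.0, E84.11, E84.19, E84.8, E84.9) and the open-chart-review queue:
   all screen positives plus code-positive screen negatives.
5. **Adjudication** — a deterministic rule engine for the chart-review
   criteria (sweat chloride > 60 mmol/L as evidence of CFTR dysfunction,
   bi-allelic genetics, structured clinical features), mapping every
   individual to TP/FP/TN/FN.
6. **Statistics** — sensitivity, specificity, PPV, NPV, accuracy and
   prevalence with exact Clopper–Pearson intervals
   (`low = qbeta(α/2, x, n−x+1)`, `high = qbeta(1−α/2, x+1, n−x)`).
7. **Synthetic cohorts** — a seeded generator with Hardy–Weinberg
   recessive genetics (carrier frequency 1/28, one allele carrying 70%
   of pathogenic copies), tunable penetrance, chart completeness, code
   sensitivity and knowledge-base completeness, plus closed-form
   expectations for parameter-recovery testing.

A worked case study — 26 chart-reviewed individuals and 6 code-positive
variant-free individuals embedded in a 50,778-exome cohort, with their
14 *CFTR* alleles and curated assertions — ships as plain-text fixtures
(`inst/extdata`; genomic coordinates are synthetic placeholders).

## Worked example

```r
library(genoscreen)

kb     <- kb_fixture()                    # 2018 assertion snapshots
cohort <- cohort_fixture(n_total = 50778) # case study + padding
report <- run_pipeline(cohort, kb)
#> [genoscreen] load: 50778 individuals, 66 stored calls
#> [genoscreen] screen: 24 bi-allelic positive / 2 carrier / 50752 negative
#> [genoscreen] crossref: review queue of 32 (24 screen-positive + 8 code-positive screen-negative)
#> [genoscreen] adjudicate: TP 21, FP 3, TN 50753, FN 1
#> [genoscreen] concordance: 20/20 comparable samples concordant

report$stats
#> <screening_stats> (clopper-pearson, 95% CI, percent scale)
#>   sensitivity  95.45 (77.16-99.88)  [21/22]
#>   specificity  99.99 (99.98-100.00)  [50753/50756]
#>   ppv          87.50 (67.64-97.34)  [21/24]
#>   npv         100.00 (99.99-100.00)  [50753/50754]
#>   accuracy     99.99 (99.98-100.00)  [50774/50778]
#>   prevalence    0.04 (0.03-0.07)  [22/50778]
```

Reading: of 24 bi-allelic screen positives, 21 had a confirmable CF
diagnosis in the EHR (PPV 87.50%); 3 were "potential" false positives
whose charts held insufficient evidence *for or against* CF. One
confirmed case was screen-negative because its second causal allele was
absent from both databases at the snapshot dates (sensitivity 95.45%).
`tidy(report$stats)` returns the same table as a tibble;
`autoplot(report$stats)` plots the intervals.

The simulator closes the loop without any real data:

```r
sim <- simulate_cohort(sim_params(n_individuals = 200000, seed = 1))
rep <- run_pipeline(sim$cohort, sim$kb, quiet = TRUE)
expected_stats(sim$params)   # analytic prevalence / sensitivity / PPV
```

## Scope notes

- Phase is never inferred: two pathogenic heterozygous calls are assumed
  in trans. Cis pairs would be false screen-positives by construction.
- Assertions are authoritative input; no computational pathogenicity
  prediction, no live database clients.
- See `vignettes/genome-first-screening.Rmd` for the model, the
  adjudication rules, simulator assumptions and known limitations.
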