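---
title: "Genome-first screening for recessive disease: models, rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-first screening for recessive disease: models, rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoscreen)
```

## The problem

Cystic fibrosis (CF) is an autosomal-recessive condition of the *CFTR*
gene: disease requires a bi-allelic pathogenic genotype, either a
homozygote for one pathogenic allele or a compound heterozygote carrying
two different pathogenic alleles. In a population cohort with exome
sequence linked to electronic health records (EHR), a *genome-first*
screen inverts the usual clinical order: it calls screen positives from
DNA alone and only then asks the record whether the person actually has
the disease. The quantities of interest are the screen's predictive
values — above all the PPV, the probability that a bi-allelic genotype
corresponds to a real diagnosis — measured against a rule-based reading
of the EHR.

`genoscreen` implements that analysis as a pipeline of small, testable
stages, plus a synthetic-cohort generator so that every stage and the
end-to-end statistics can be exercised at desk scale with known truth.

## Pathogenicity model

The knowledge base holds dated assertions from two kinds of source: an
expert-curation table (CFTR2-like: "CF causing", "Varying clinical
consequence", "Non CF-causing") and a submission database (ClinVar-like:
"Pathogenic" … "Benign", with 0–4 review stars). The screen's call is a
union rule:

> PATHOGENIC ⇔ CFTR2 says "CF causing" **or** ClinVar says
> "Pathogenic"/"Likely pathogenic".

Three consequences worth making explicit:

- *Review stars are recorded but never filtered on.* The curated record
  this package models accepted a two-star pathogenic assertion; making
  stars a gate would change the screen.
- *"Varying clinical consequence" alone does not qualify.* In the
  packaged fixture the one such allele (R117H) qualifies through its
  four-star ClinVar assertion, so the union rule is used unchanged.
- `NOT_PATHOGENIC` requires an explicitly benign assertion from at least
  one source with no qualifying pathogenic call; everything else —
  absent from both sources, or only indeterminate labels (VUS-like) —
  is `UNKNOWN`. This keeps the three-way call total over any input.

Assertions carry an `asserted_date`; queries at date *d* ignore later
assertions, which is how the package replays historical knowledge
states (a 2009 clinical panel cannot know about an allele first
asserted in 2013). Undated assertions default to "always known", so
era-filtering is opt-in.

Poly-T/TG tract modifiers (e.g. R117H `T5/TG11`) ride along as
annotation strings and are deliberately ignored by classification: the
screen this package models counted such genotypes positive without a
separate tract-calling step.

Variant identity is the normalized `(chrom, pos, ref, alt)` tuple —
common suffix trimmed, then common prefix with the position advanced,
always keeping one anchor base (the VCF left-alignment convention).
Nothing in the analysis depends on allele labels once coordinates are
available on both sides.

## The screen and its one structural assumption

Per individual, pathogenic allele copies are counted: a homozygote
contributes 2, each distinct heterozygous pathogenic variant 1. Count
≥ 2 ⇒ `BIALLELIC_POSITIVE`, 1 ⇒ `CARRIER`, 0 ⇒ `NEGATIVE`. Three or
more pathogenic alleles still map to positive, with all alleles listed.

**Phase is never inferred.** Two heterozygous pathogenic calls are
assumed in trans. A cis pair would be a false screen-positive by
construction; with rare alleles under random mating the cis probability
is of the order of the product of allele frequencies, but the
assumption is structural and is stated in the report output rather than
corrected for.

## Chart-review adjudication

The published screen this package models used expert chart review; the
package encodes a deterministic approximation that reproduces all 26
reviewed case labels of the worked fixture without overrides. The
guiding clinical principle: a CF diagnosis needs *evidence of CFTR
dysfunction* plus *a clinical presentation*, and is never assumed from
genotype alone.

Structured inputs per reviewed chart: sweat chloride values (mmol/L;
`QNS` — quantity not sufficient — is treated as no usable value;
censored values like `<10` are kept), clinical genetic-test alleles,
and yes/no/unknown flags for bronchiectasis, pancreatic enzyme
supplementation, respiratory pseudomonas, longitudinal CF-clinic care,
and a CF diagnosis documented in the EHR.

Derived predicates:

- *diagnostic sweat*: any value > 60 mmol/L (the guideline threshold);
- *negative sweat workup*: values present and all < 60;
- *bi-allelic genetics*: screen-positive, or a clinical test reporting
  two knowledge-base pathogenic alleles (multiplicity counts);
- *clinical features*: yes-count over {bronchiectasis, pancreatic
  supplementation, CF-clinic care, documented CF diagnosis}.

Rules, in order: diagnostic sweat + bi-allelic genetics ⇒ confirmed;
diagnostic sweat + ≥ 2 features ⇒ confirmed (dysfunction plus
presentation — this is how a confirmed case whose second allele is
missing from the databases is still recognised); no diagnostic sweat +
bi-allelic genetics + ≥ 2 features ⇒ confirmed; negative sweat workup +
not bi-allelic + CF-diagnosis context ⇒ CRMS (CFTR-related metabolic
syndrome); bi-allelic but nothing confirming and no negative workup ⇒
INSUFFICIENT; otherwise NOT_CF.

Two design choices here were genuinely open and deserve their
rationale:

- *The feature set.* Respiratory pseudomonas is recorded but not
  counted as a confirming feature: colonization is common in non-CF
  bronchiectasis, and counting it would auto-confirm an elderly
  bi-allelic individual whose chart the experts read as insufficient.
  Conversely a documented CF diagnosis in the EHR *is* counted: it
  separates individuals under longitudinal CF care whose workup lives
  partly outside the record from never-diagnosed incidental genotypes.
  With this set, the rule engine reproduces every reviewed label; with
  either alternative it provably cannot.
- *Intermediate sweat values.* A sweat result in the 30–59 mmol/L band
  neither confirms nor excludes. The "no diagnostic sweat" branch
  therefore keys on the absence of a value > 60 rather than the absence
  of any value, so an intermediate result falls through to the
  genetics-plus-features rule rather than blocking confirmation.

Categories follow mechanically: positive × confirmed ⇒ TP; positive ×
anything else ⇒ FP (flagged *potential* when the label is INSUFFICIENT
— evidence was missing, not negative); non-positive × confirmed ⇒ FN;
all other non-positives ⇒ TN. Individuals outside the review queue
(screen-negative and code-negative) are TN by construction. Adding a
confirming chart fact can only move a case FP→TP or TN→FN, never the
reverse; this monotonicity is property-tested.

## Statistics

All six statistics (sensitivity, specificity, PPV, NPV, accuracy,
prevalence) are binomial proportions; intervals are exact
Clopper–Pearson by default, via Beta quantiles:
`low = qbeta(α/2, x, n−x+1)` (0 at x = 0),
`high = qbeta(1−α/2, x+1, n−x)` (1 at x = n). The exact interval
reproduces the published sensitivity interval for 21/22 (77.16–99.88)
and the prevalence interval for 22/50,778 (0.03–0.07). A Wilson-score
option exists; the exact method behind the published PPV/NPV bounds is
not stated in the source record and matches neither, so no conclusion
is tied to those two intervals. Zero-denominator statistics are
reported as undefined, never 0. Machine output carries unrounded
values; only display formatting rounds.

The exact Hardy–Weinberg marker-QC test is the conditional-enumeration
test: given the allele counts, the heterozygote count has probability
∝ `2^h n! / (n_AA! h! n_BB!)`, and the two-sided p-value sums all
counts no more probable than the observed one. It is implemented in log
space and verified exhaustively against an independent
recurrence-relation enumerator for all genotype totals up to 200.

## The synthetic cohort: what it emulates, and what not

`sim_params()` defaults are the study conditions of the modelled
screen, chosen once:

| parameter | default | meaning |
|---|---|---|
| `carrier_frequency` | 1/28 | total pathogenic carrier rate; rare-allele arithmetic `q = 1/56`, so the affected fraction is `q² = 1/3136` (the familiar 1-in-3200) |
| `f508del_share` | 0.70 | share of pathogenic copies on the major allele, remainder split over 11 minor alleles |
| `penetrance` | 1.0 | bi-allelic genotypes manifest; CF penetrance is essentially complete |
| `chart_completeness` | 0.875 | probability a true case has confirmable chart facts — the complement reproduces the observed 3-in-24 "insufficient data" mechanism |
| `code_sensitivity` | 0.95 | true cases carry a CF ICD-10 code; diagnosed CF is proactively coded |
| `code_fpr` | 1.2e-4 | non-cases carrying a CF code (≈ 6 per 50,000, the observed order) |
| `kb_completeness` | 1.0 | per-variant probability of being asserted; < 1 creates false negatives whose missing allele is simply unasserted |
| `array_missing_rate` | 0.005 | array no-call rate, for marker-QC exercises |

Haplotypes are drawn i.i.d. from the frequency spectrum (random mating,
Hardy–Weinberg, no linkage, no inbreeding) — the same arithmetic the
1-in-3200 prevalence figure rests on: affected fraction
`q² ≈ 0.032%`. Chart facts for a confirmable case are generated to fire
the dysfunction rule (sweat 75–110 mmol/L plus care features);
unconfirmable cases get uninformative charts and adjudicate
INSUFFICIENT, exactly the potential-false-positive mechanism. Every
individual who can reach the review queue receives a chart row.

Closed-form companions (`expected_stats()`): prevalence
`= q²·penetrance`; screen sensitivity under per-variant knowledge-base
inclusion at rate *k* is `k²(1−h) + k·h`, where `h = Σf²/q²` is the
probability a bi-allelic genotype is homozygous (`k²` is the
compound-het limit); measured pipeline sensitivity additionally
conditions on missed cases being code-captured,
`s/(s + (1−s)·code_sensitivity)`; PPV
`= penetrance · chart_completeness`.

What the generator does **not** emulate — and hence what passing tests
do not show about real cohorts: population structure and ancestry-
dependent allele spectra; cis double-heterozygotes; age-dependent
ascertainment; correlated EHR phenotyping (code and chart completeness
are drawn independently); genotype error beyond uniform call dropout;
and any newborn-screening (IRT) pathway.

## Numerical and engineering choices

- Exact HWE ties are compared with a 1e-10 relative tolerance so that
  floating-point noise cannot split genuinely tied heterozygote counts;
  the exhaustive sweep against the independent enumerator agrees to
  1e-12.
- Transcript selection (for anchoring cDNA/protein names) filters to
  LRG-annotated transcripts with annotated start/stop codons, takes the
  longest coding sequence, and breaks ties by smallest accession —
  deterministic under any input order.
- All report outputs are sorted; re-running the pipeline on identical
  inputs is byte-identical.
- Problem sizes used by the test-suite properties: exhaustive HWE sweep
  to genotype totals of 200; interval-inversion oracle to n = 50;
  simulator recovery at 200,000 individuals × 20 seeds and one
  1,000,000-individual prevalence draw — sizes at which Monte-Carlo
  error is far below the tolerances asserted.

## Known limitations

- The adjudication engine is a reproducible approximation of expert
  review; charts outside its structured vocabulary (free-text evidence)
  need the `overrides` mechanism.
- Carrier-rate estimation from the screen output is deliberately not a
  reported statistic: its denominator and variant set are
  design-dependent.
- ICD-9 histories are out of scope; the code set is ICD-10.
- The fixture's genomic coordinates are synthetic placeholders; the
  fixture encodes the curated names, classifications and genotype
  configurations, not a reference-genome alignment.
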