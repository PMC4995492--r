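---
title: "Methods: tumor-informed plasma ctDNA concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed plasma ctDNA concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaconcord)
```

## The problem

In early-stage non-small cell lung cancer, the tumor sheds little DNA into
the circulation: plasma variant allele frequencies (VAFs) sit mostly between
0.1% and a few percent, while the resected tissue shows 5–60%. A
tumor-informed liquid-biopsy analysis asks, per patient, which somatic
mutations found in tumor tissue (tDNA) reappear in plasma cell-free DNA
(cfDNA) and vice versa, and summarizes the cohort as concordance,
sensitivity, specificity and plasma positive predictive value (PPV), with
tissue as the reference standard. This package implements that analysis —
variant filtering, mutation matching, the fractional confusion-matrix
allocation, dilution-series validation and the clinical association tests —
together with a synthetic-cohort generator that makes the whole pipeline
testable without patient-level data.

## Variant filtering

Calls from each compartment pass three stages plus germline subtraction.
All threshold comparisons are *strict*, matching the conventional printed
form of such filters (">1000", ">20", ">5%", "p < 0.01"):

| profile | sample mean depth | variant coverage | VAF | p-value |
|---|---|---|---|---|
| tissue | > 1000x | > 20 reads | > 5% | < 0.01 |
| plasma | > 10000x | > 10 reads | > 0.1% | < 0.01 |

A failed *sample-level* mean-depth bound removes every call of that sample
with disposition `mean_depth` — this is QC semantics, not an error. A
zero-depth call has undefined VAF and fails the VAF step by definition.

**p-value.** Variant callers rarely document their significance model, so
the package uses a declared stand-in: the exact binomial upper tail
`P[X >= alt_reads]` for `X ~ Binomial(depth, error_rate)` with a default
per-base error rate of 0.001. `stats::pbinom` is exact at any panel depth,
so no normal approximation is needed. Limiting cases are fixed by
definition: `alt_reads = 0` gives p = 1, and `error_rate = 0` with observed
alt reads gives p = 0.

**Strand bias.** Manual inspection of strand artifacts in a genome viewer
does not replicate, so stage two is a two-sided Fisher exact test on the
2×2 table of forward/reverse read-orientation counts for the reference and
alternate alleles, dropping a call only below a conservative alpha of 0.001.
Strand counts are read-orientation counts; no reference-strand
normalization is attempted. An all-zero table carries no evidence and is
kept.

**Hotspot restriction.** Variants are 1-based (VCF convention), panel
regions 0-based half-open (BED convention). The conversion lives in one
function: position p is inside (start, end] iff `start < p <= end`, i.e.
the first base of a region is `start + 1`. Consequently a variant at
1-based position equal to the raw BED `start` is *outside* the region — the
boundary tests pin this down explicitly.

**Germline subtraction.** Mutation identity everywhere is
`(chrom, pos, ref, alt)` after representation normalization (shared
suffix/prefix trimming with position shift), so padded indel spellings
cannot defeat matching. Any call whose key appears in the matched
white-blood-cell (WBC) call set is removed. The WBC compartment itself
passes only threshold filtering — it is the germline reference, not a
somatic call set. Full left-alignment against a reference genome is out of
scope; the trimming rule covers the representation differences a single
caller produces.

Each filter is a pure predicate on the call, so the surviving set is
independent of stage order (property-tested); the *trace* attributes each
removal to the first failing stage in the fixed order
threshold → strand → hotspot → germline, and the dispositions partition the
input exactly.

## The fractional allocation statistic

Per pair, let C be the number of concordant mutations, Fp the plasma-only
and Fn the tumor-only count, T = C + Fp + Fn. True negatives are pairs with
no mutation at all (tn = 1). Otherwise each mutation carries weight 1/T
toward its statistical group:

$$tp = C/T, \quad fp = F_p/T, \quad fn = F_n/T.$$

Every pair thus contributes exactly one pair-equivalent, keeping the cohort
denominator at n pairs. A pair with three plasma-only and two tumor-only
mutations contributes fp = 3/5 = 0.6 and fn = 2/5 = 0.4. The same weight
applies to concordant mutations in mixed pairs (tp = C/T): the allocation
formula is symmetric across the three groups, and a pure-concordant pair
yields tp = 1. The implementation computes the ratios directly (C/T, not
(1/T)·C) so the printed decimals are exact in floating point.

Aggregates: concordance (tp+tn)/n, sensitivity tp/(tp+fn), specificity
tn/(tn+fp), plasma PPV tp/(tp+fp), summed over pairs. A metric whose
denominator is zero is *undefined* and reported as `NA` — silently printing
0 would fabricate a result.

**Intervals.** The effective counts are fractional, so the default 95%
interval is the Wilson score interval evaluated at z = 1.959964 directly on
the fractional numerator/denominator; it is well behaved at small n and at
the 0/1 boundaries. Wald and Clopper-Pearson (on rounded counts) are
selectable, and the method used is recorded in the output. Reported
intervals from other implementations will be close but not necessarily
identical, since the interval method behind published CIs of this kind is
usually unstated.

**Tallies.** Compartment mutation totals double-count concordant mutations
(one per compartment); the distinct total is
`n_tdna + n_ctdna - n_concordant`. Both tallies are reported, and the
per-positive-pair average uses the distinct tally — with the familiar
aggregate counts 59 tDNA + 76 ctDNA − 34 concordant over 45 positive pairs
this gives 101/45 = 2.24.

```{r}
t <- mutation_tallies(59, 76, 34, 45)
c(distinct = t$distinct, per_positive_pair = round(t$per_positive_pair, 2))
```

## Reference-standard validation

`simulate_reference_standards()` models mutant/wild-type plasmid mixtures at
nominal fractions 0, 0.1%, 0.5% and 1%, sequenced 12 times at 10,000x over
six control loci (KRAS G12C, PIK3CA E545K, PIK3CA H1047R, BRAF V600E, EGFR
L858R, EGFR E746_A750del). Read evidence at a site is
`Binomial(depth, f + (1-f)e)`. Standards bypass hotspot restriction and
germline subtraction — the six loci are the site universe.

Because the criterion behind a published "detection limit" is typically
unstated, the detection rule is explicit and configurable: the LoD is the
lowest tested fraction whose mean per-site detection rate reaches 50%
(default "majority"; "all" and "any" selectable). Accuracy is the share of
negative replicates with zero calls anywhere on the panel. Note the
knife-edge at 0.1%: the expected 10 mutant reads at 10,000x sit exactly on
the strict ">10" coverage bound, giving a detection probability of
`1 - pbinom(10, 1e4, 1e-3)` ≈ 0.417 per site, versus ≈ 0.542 under the
inclusive ">= 10" reading; `filter_profile(inclusive = TRUE)` exposes the
second reading, and `detection_probability()` provides the closed form the
Monte-Carlo rates are tested against.

## Clinical associations

cfDNA concentration is compared between clinical groups by the
Mann-Whitney U test: U from rank sums with midranks for ties, exact
enumeration for small untied samples (pooled n ≤ 12, via
`stats::wilcox.test`), otherwise the normal approximation with tie and
continuity correction — the realistic group sizes (e.g. 46 vs 12) need the
approximation anyway. Feature splits: age at 65, stage I vs II, GGO
dominance strictly > 50%, and the remaining dichotomous covariates. Group
summaries report mean ± SD *and* median/IQR, since skewed cfDNA
distributions are conventionally described by medians while group tables
often print means. Raw p-values are reported without multiplicity
correction, and this is deliberate: the table mirrors the conventional
presentation of such cohort tables; readers should treat borderline values
accordingly.

Serum markers are positive at value ≥ cut-off (the clinical rule defines
*negativity* by strict <): CA125 35 U/ml, CA19-9 39 U/ml, CEA 4.7 ng/ml,
CYFRA21-1 3.3 ng/ml, NSE 16.3 ng/ml. "cfDNA positive" means a quantifiable
concentration, strictly above a configurable floor (default 0 ng/ml),
because assay-specific quantification limits vary. In an all-cancer cohort
each modality's "PPV" is arithmetically its detection rate; the report
labels it as such.

## The synthetic cohort generator

The generator's defaults are the study conditions the analysis assumes,
fixed once:

* 58 patients — stages IA 30 / IB 16 / IIA 12, histology AC 51 / SCC 7,
  33 male, 22 smokers, 8 GGO-dominant; age ~ Normal(64.5, 9.3) clamped to
  35–90.
* Tumor mutations per patient ~ Poisson(59/58), drawn from a 739-site,
  50-gene hotspot catalogue whose weights concentrate in EGFR (then TP53,
  PIK3CA, KRAS), with indels confined to EGFR and MNPs to KRAS; tissue
  VAFs ~ Uniform(0.05, 0.60).
* Each tumor mutation is shed into plasma with probability 34/59; plasma
  VAFs are log-normal with median 0.9% and log-sd 1.25, truncated to
  [0.01%, 20%], placing ~95% of draws in the observed 0.1–16% range;
  plasma-private mutations arrive at rate 42/58 per patient. These rates
  reproduce the observed pair structure (compartment totals near 59/76 with
  ~34 concordant) in expectation.
* Two germline variants per patient are planted at VAF 0.5 identically in
  tumor, plasma and WBC — they exercise germline subtraction and must never
  survive filtering.
* Read evidence is binomial at Poisson-distributed depths with means 2000x
  (tissue, WBC) and 12000x (plasma); published descriptions state only the
  QC floors (1000x/10000x), and the means are set above them so simulated
  samples pass the strict sample-level bound. Per-base error 0.001.
* cfDNA ~ log-normal with mean 4.57 ng/ml for stage-I solid-dominant
  disease, multiplied by 14.28/4.57 for stage II and 0.66/7.53 for
  GGO-dominant tumors, CV 1.5; non-quantifiable (0 ng/ml) with probability
  6/58. With CV → 0 the group means recover the multipliers exactly
  (tested).
* Marker values are log-normal, calibrated so the expected positivity rates
  at the cut-offs are 0/58, 2/58, 8/58, 16/58 and 4/58 (CA125, CA19-9, CEA,
  CYFRA21-1, NSE), log-sd 0.6.

Reproducibility: one master seed; each patient's draws come from a
deterministic substream derived from it, so results do not depend on
iteration order, and identical seeds give byte-identical cohorts.

**What the generator does not emulate.** Sequencing-error haplotype
structure, UMI families, copy-number and structural variation, FFPE
deamination artifacts, batch effects between runs, and correlation between
mutation burden and clinical covariates (smoking/histology) are all absent;
mutation sites are drawn independently per patient, and error calls are
independent across sites. Passing tests on synthetic cohorts therefore
demonstrate the *statistical machinery* — filtering thresholds, allocation
arithmetic, interval coverage, LoD behavior — not the biological fidelity
of any particular dataset.

## Numerical and design choices

* Strict inequalities throughout the filters; the inclusive variant is an
  explicit option, not a silent default.
* Degenerate inputs: empty call sets flow through every stage; depth-0
  calls fail as undefined VAF; the all-zero strand table is kept; an empty
  WBC set makes germline subtraction the identity; an empty hotspot panel
  removes all calls (restriction to nothing).
* Allocation uses direct ratios; conservation (tp+fp+fn+tn = 1) is asserted
  to 1e-12 over random pairs.
* Metrics with zero denominators are `NA`; aggregation of zero pairs is an
  error, not an empty summary.
* Duplicate mutation keys within one compartment collapse to one with a
  warning — matching is set-based.
* The per-pair manifest encoder (`read_pair_manifest`) lets externally
  curated post-filter mutation lists run through the same estimator; the
  package does not bundle any such list.

## Problem sizes in the test suite

The suite runs desk-scale by choice: property batteries use 1e4 random
allocation pairs, 150 p-value oracle comparisons at depths ≤ 1000,
exhaustive Mann-Whitney enumeration at pooled n ≤ 8, dilution series of
100 replicates × 6 sites per fraction, and simulated cohorts of 10–58
patients (pooled across five seeds for the direction-of-effect check on the
cfDNA multipliers). The full suite completes in well under a minute.

## Known limitations

* The binomial p-value is a declared stand-in for an undocumented caller
  test; absolute p-values are interpretable only relative to the configured
  error rate.
* Indel normalization trims shared padding but does not left-align against
  a reference genome.
* Wilson intervals on fractional counts are an analytic convenience; their
  frequentist coverage under the fractional-allocation sampling model has
  no closed-form guarantee (coverage behaves well empirically at these n).
* The hotspot panel ships with synthetic coordinates; real analyses must
  supply their own BED (genome build and panel coordinates are user input).
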