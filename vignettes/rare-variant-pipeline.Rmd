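---
title: "Rare-variant enrichment testing in small extreme-phenotype cohorts"
author: "rareburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant enrichment testing in small extreme-phenotype cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareburden)
library(dplyr)
```

## The analysis problem

Extreme-phenotype designs sequence a handful of individuals at the far tail
of a trait — here the motivating setting is whole genomes of women validated
to be 110 years or older — and ask whether any rare protein-altering variant,
or any gene collecting such variants, is shared by the cases more often than
chance allows. Two features dominate the statistics:

* **The cohort is tiny.** With 13 cases against 34 genotype-level controls
  and a 379-individual reference frequency panel, only very strong sharing
  is detectable at genome-wide thresholds, and it is essential to compute
  that detectability boundary honestly rather than discover it post hoc.
* **Screening enriches for artefacts.** Selecting apparent rare
  protein-altering calls preferentially selects sequencing errors and
  platform-specific bad sites; the pipeline therefore filters on a
  platform-control no-call rate and supports quality-tier sensitivity
  re-runs, and the simulator injects errors at the rate such studies have
  observed (about 30% of candidate rare calls).

`rareburden` implements the full chain: consequence annotation, a
three-stage rarity filter with a per-variant audit trail, a variant-level
Fisher enrichment scan, the RVT1 collapsing burden test, a recessive
two-or-more-variants scan, power calculators, and an incidental-findings
screen over an ACMG-style gene list, plus a deterministic synthetic-data
generator that makes every stage testable without any external download.

## Consequence model

Variants are classified per transcript into six protein-altering
categories — missense, frameshift, non-frameshift indel, stop-gain,
stop-loss, splice-site — or `non_protein_altering`. The splice definition is
deliberately narrow: only the two intronic bases flanking a coding exon
(the canonical GT donor / AG acceptor on the coding strand). Coding SNVs are
decided by codon translation under the standard genetic code; coding indels
by the net length change modulo three. Precedences, chosen once: stop-gain
over missense when a codon becomes a stop; frameshift/non-frameshift over
splice-site when an indel touches both the CDS and a splice dinucleotide;
start-codon SNVs that do not create a stop are counted as missense, because
the six-category scheme has no start-loss class. One transcript per gene is
the expected input; with several, a gene is protein-altering if any
transcript's call is (the OR rule), which matches "any protein-altering
variant" counting without inventing a canonical-transcript rule.

## The filter cascade

Three rules, applied in a fixed order with the first failing rule recorded
per variant:

| stage | rule | default |
|---|---|---|
| `low_quality` | mask low-tier genotype calls to no-calls; drop variants whose carriers vanish | on |
| `platform_nocall` | drop variants whose no-call fraction among platform controls **strictly exceeds** the threshold | 0.5 |
| `known_variant` | drop variants present (allele-aware) in a known-variant catalogue | variant path only |
| `maf` | keep only panel MAF `< 0.015` **and** empirical alt frequency `< 0.10` | gene path only |

The two analysis paths use different stages because the single-variant scan
filters common variation by catalogue membership while the burden test
filters by panel and empirical frequency; both share the platform no-call
rule. All cutoffs are strict inequalities (a variant at exactly 50% no-call
or exactly 1.5% MAF survives/falls as documented in `filter_config()`), and
sensitivity analyses — a 5% panel cutoff, keeping low-quality calls — are
expressed purely through configuration, never through code changes. A
variant absent from the panel is treated as frequency zero ("novel"). The
empirical-MAF denominator is the called alleles of cases and controls
combined; since the source analysis does not state whether controls entered
that denominator, a `cases`-only switch is exposed.

"No-call" is interpreted at the genotype level: a half-called genotype
(`0/.`) is missing for that individual. This is the conservative reading of
platform no-call semantics, and it feeds both the platform filter numerator
and the per-sample called-site denominators of the burden test.

## Statistics

**Variant scan.** Per retained variant, a one-sided Fisher exact test on
carriers per genome: cases carrying at least one alternate allele among
`n_cases`, versus carrier individuals in the panel. Carrier counting (not
allele counting) is the deliberate choice: with 4 of 13 case carriers and an
absent variant in 379 panel individuals it gives
$\binom{13}{4}/\binom{392}{4} = 7.4\times10^{-7}$, the detectability
headline the design reproduces; allele-level counting would give
$9.6\times10^{-7}$ and is rejected. Panel carrier counts are approximated by
the alt-allele count (exact for the rare variants the scan runs on, where
homozygotes are essentially absent). Bonferroni correction always uses the
number of tests actually performed in the scan at hand.

**RVT1 burden test.** For gene $g$, each sample $i$ gets
$x_i = r_i / n_i$, the proportion of the gene's rare protein-altering sites
at which $i$ carries an alternate allele, over the sites called in $i$.
Case status is regressed on $x_i$ by logistic regression, and significance
is the likelihood-ratio statistic against the intercept-only model on
$\chi^2_1$. In the regime this scan lives in, carriers are often exclusively
cases, which is **quasi-separation**: the slope estimate diverges, but the
likelihood-ratio statistic converges to a finite boundary value. With a
single predictor the separated geometry is a threshold, so the boundary
supremum has a closed form: perfectly predicted samples contribute zero
log-likelihood and the group tied at the separating proportion contributes a
binomial log-likelihood at its own case fraction. For $k$ case carriers (one
distinct site each) out of 13 cases and no carriers among 34 controls,

$$\mathrm{LRT}(k) = 2\Big[(13-k)\ln\tfrac{13-k}{47-k} + 34\ln\tfrac{34}{47-k}
 - 13\ln\tfrac{13}{47} - 34\ln\tfrac{34}{47}\Big],$$

giving 21.62 ($p = 3.3\times10^{-6}$) at $k=7$ and 17.96
($p = 2.3\times10^{-5}$) at $k=6$ — hence the package's power calculator
reports 7 as the minimum detectable carrier count at the gene-scan
threshold $0.05/10508 = 4.758\times10^{-6}$. Separation is detected
geometrically (the carrier proportions of one class bound the other's), not
by coefficient-magnitude heuristics, though a fitted |slope| above 30 logits
also raises the flag; the implementation was cross-checked against a pinned
large-slope iterative fit in the test suite. A degenerate gene (identical
$x_i$ everywhere) returns $p = 1$ with a zero statistic.

**Recessive scan.** Per gene, samples whose summed alt-allele count over the
gene's rare protein-altering sites is at least two — two heterozygous sites
or one homozygous site — are compared between cases and controls by Fisher's
exact test. Phase is never inferred; the two-or-more criterion is exactly
the phase-agnostic compound-heterozygote surrogate. Sidedness of this test
is not pinned down by the source description, so both are exposed with
one-sided enrichment as the default.

**Follow-up allele test.** Resequencing a candidate gene in an independent
cohort yields carrier-allele counts; `followup_allele_test()` applies the
same 1.5% panel-MAF filter and runs a two-sided Fisher exact test on the
allele-level 2×2 table. On the shipped follow-up table (8 carrier alleles
among 198, versus 213 among 8600; 4.0% vs 2.5%) the computed p-value is
0.1637 — two decimals of the published rounding (0.17) are not recoverable
because the reference counts are themselves rounded summaries.

All Fisher p-values are computed from hypergeometric tail / point-probability
sums (`stats::dhyper`); the two-sided rule sums all tables whose point
probability does not exceed the observed one, the same convention as
`stats::fisher.test`, against which (and against explicit enumeration) the
implementation is property-tested exhaustively for all tables with total at
most 60.

## Incidental-findings screen

Independently of rarity, every sample is screened for reportable variants in
a configurable gene list (the shipped reference fixture is the ACMG 56-gene
secondary-findings list, 45 of them flagged LoF-actionable; both files are
editable TSVs because gene lists and classifications version over time). A
(sample, variant) pair is reported when the sample carries the variant and
either a catalogue source classifies it pathogenic, or it is a clear
loss-of-function consequence (frameshift, stop-gain, stop-loss,
splice-site) in a LoF-actionable gene. A benign classification in **any**
source vetoes reporting regardless of other evidence; `uncertain` entries
neither trigger nor veto. Zygosity is reported but never used as a
criterion.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions: 13 cases, 34 controls, 54
platform controls, a 379-individual frequency panel, a Beta(0.3, 40) rare
site-frequency spectrum (median well below 1%; the source states no
spectrum, so this is a one-time modelling choice exposed in the config), a
configurable common/known stratum, spiked genes with case-only carriers,
bad sites whose platform-control no-call probability is 0.55 (so they
usually, but not always, exceed the 50% filter), and injected false calls —
novel case singletons — scaled so the expected error share of candidate
rare coding calls is 0.30. Randomness flows from one master seed through
named substreams per operation, so adding sites to one stage never perturbs
another, and identical configurations yield byte-identical FASTA/VCF/TSV
outputs.

Deliberate simplifications: background coding polymorphism is drawn as
missense/synonymous only (standing loss-of-function polymorphism is rare,
and this keeps the incidental-screen truth exact); spiked genes carry only
their spike sites, so a spike's carrier configuration is exactly as
configured; genes are uniform three-exon models on alternating strands;
there is no linkage disequilibrium, population structure, or read-level
error model. Passing tests on these cohorts therefore demonstrate the
statistical machinery and bookkeeping, not robustness to stratification or
calling artefacts beyond the modelled no-call/error processes.

Problem sizes used in the shipped tests were chosen to exercise the
genome-wide logic at desk scale: 200-gene genomes (about 1000–3000 coding
sites) for end-to-end runs, 500-gene null batteries for the type-I-error
property, and exhaustive enumeration up to table total 60 for the Fisher
oracle.

## Numerical and design notes

* Coordinates are 1-based inclusive (VCF convention) everywhere a user sees
  them; indel keys are normalised by suffix-then-prefix trimming so that
  catalogue and panel membership is representation-invariant.
* Multi-allelic records are decomposed into biallelic keys with per-allele
  counts recomputed; decomposition preserves each sample's total
  alternate-allele count.
* Ranked outputs sort by ascending p-value with ties broken by gene symbol,
  so reports are deterministic.
* A variant with zero called alleles in the cohort cannot have an empirical
  frequency; it is judged by the panel rule alone and flagged.
* The boundary LRT is the supremum of the likelihood, so the reported
  statistic can only overstate — never understate — what an iterative fit
  with a finite coefficient cap would reach; the difference is bounded by
  the cap's tail mass and is negligible at 30 logits.
* `run_pipeline()` records every threshold, per-stage count, the package
  version and a configuration hash in `report.yaml`; re-running an
  identical configuration reproduces identical result tables.

## Known limitations

Single-transcript gene models are the intended input; overlapping genes are
supported but share variants. The recessive scan's two-or-more criterion
counts two alternate alleles at one site and two sites equally, as designed,
but cannot distinguish cis from trans pairs. Panel carrier counts in the
variant scan are an approximation above roughly 5% frequency — far above
the scan's filter cutoff. Equal-length multi-base substitutions are
classified as non-frameshift indels rather than translated; the generator
never emits them and real decomposed VCFs rarely contain them.
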