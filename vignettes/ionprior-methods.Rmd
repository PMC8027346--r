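---
title: "ionprior: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionprior: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionprior)
```

This vignette is the package's own account of the computation it
implements: the model behind each stage, the tunable parameters and why
their defaults are what they are, what the synthetic-cohort generator
does and does not emulate, and the numerical choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The diagnostic model

A proband's molecular diagnosis in an inherited optic neuropathy (ION)
panel is a function of (i) which variants the proband really carries in
the 22 panel genes, (ii) how reliably those variants are called, and
(iii) a prioritization policy that separates causative genotypes from
benign variation. `ionprior` factors this into independently testable
stages; each stage is a pure function of its inputs, so reruns with the
same configuration are bitwise reproducible (the run manifest records
per-stage content hashes).

### Allele normalization

Callers describe the same edit in different ways: multiallelic records,
right-shifted indels in repeat runs, alleles padded with shared context.
Cross-caller comparison therefore happens on the canonical
representative of each variant's haplotype-equivalence class:
multiallelic records are decomposed (one record per alternate allele,
genotypes restricted to that allele, unphased pairs written in canonical
order), then each allele pair is iteratively right-trimmed
(left-extending with the preceding reference base whenever an allele
would empty) and finally left-trimmed down to a single anchor base. This
is the standard parsimony-plus-left-alignment definition; the package's
tests verify it against a brute-force oracle that enumerates every
haplotype-equivalent `(pos, ref, alt)` triple in randomized repetitive
60-bp windows, filters them by the parsimony invariant, and selects the
minimal position.

Two numerical edges are handled explicitly:

* `max_shift` (default 1000 bp) caps the leftward walk; exceeding it in
  a pathological repeat expanse is an error, never a silent stop.
* A repeat-unit deletion whose run reaches the contig start has no
  left-anchored VCF representation at all; `left_align_trim()` raises an
  error rather than inventing a right-anchored form. The randomized
  canonicality tests skip these degenerate draws.

### Consensus calling

A variant enters the consensus set for a sample when at least
`min_support` callers report its normalized key. The default is
**m = 2 of 6**: one caller's private calls are overwhelmingly artifacts
on amplicon data, while demanding near-unanimity would punish legitimate
caller dropout on indels; both the threshold and non-PASS counting are
configuration (`min_support`, `count_nonpass`). Callers that produced no
call set for a sample reduce the denominator (`n_callers_run`) rather
than voting "absent". Genotypes are reconciled by majority vote over
het/hom-alt among supporting callers; ties go to the fixed caller
priority order (the Torrent Suite caller first, then GATK
UnifiedGenotyper, VarScan2, SNVer, LoFreq, Platypus) — an arbitrary but
documented and deterministic rule.

### Annotation

Gene assignment is by overlap with the panel design regions (a variant
overlapping two genes is annotated against the first and flagged
ambiguous). The consequence engine works on toy transcript models:

* coding SNVs are translated codon-wise with the standard genetic code —
  stop gained = nonsense, amino-acid change = missense, silent =
  synonymous; a destroyed stop codon is reported as missense (the class
  set has no stop-loss bucket and the event cannot arise from the
  generator);
* coding indels are frameshift iff the net length change is not a
  multiple of 3, else in-frame;
* the canonical splice region is the first and last `splice_window`
  (default **2**) bases of each intron — the universal GT/AG dinucleotides —
  and overrides the intronic class; the window is configurable because
  "splice-disrupting" has no single community definition;
* exonic but untranslated positions are bucketed with intronic: the
  pipeline's decision logic never distinguishes them, and the class set
  stays closed;
* protein changes are simplified `p.<ref><codon><alt>` strings, not full
  HGVS.

Population frequency and clinical significance come from packaged
tables keyed by normalized variant; a key absent from the frequency
table means "absent from public databases". Pre-computed in-silico
scores (SIFT, PolyPhen2, ...) may ride along as extra columns but the
decision logic never conditions on them: the prioritization policy is
defined purely by rarity, novelty, functional class and segregation.

### Prioritization

The cascade per proband:

1. **LHON pre-screen** — any of m.3460G>A, m.11778G>A, m.14484T>C
   (exact allele match) excludes the proband from autosomal analysis.
2. **Rarity filters** — dominant candidates need MAF < `dominant_max`
   (default **1e-4**), recessive candidates MAF < `recessive_max`
   (default **5e-3**); both strict, and database-absent variants always
   pass. The asymmetry reflects carrier frequencies: recessive alleles
   circulate in the population at frequencies that would exclude any
   dominant cause.
3. **Tier ladder** — T1 reported pathogenic / likely pathogenic in a
   known gene; T2 novel loss-of-function (nonsense, frameshift, splice)
   in a known gene; T3 novel missense in a known gene; T4 any
   qualifying variant in a candidate-status gene, reported as a variant
   of uncertain significance. "Novel" means *unreported in the clinical
   table*; a variant catalogued as VUS is therefore neither reported
   pathogenic nor novel and cannot tier in a known gene. Benign,
   synonymous and deep-intronic variants never tier.
4. **Genotype pattern** — biallelic means one homozygous qualifying
   variant or two distinct heterozygous ones; phase is unknown, so two
   hets are presumed compound-heterozygous unless a genotyped parent
   carries both (then they are taken as cis and segregation is
   inconsistent). A compound-het pair's tier is its weaker allele's
   tier, since the diagnosis needs both.
5. **Segregation** — dominant: every genotyped affected relative must
   carry the variant and, under the default strict policy, no genotyped
   unaffected relative may (`allow_unaffected_carriers = TRUE` relaxes
   this for incomplete penetrance); recessive: affected relatives must
   be biallelic, unaffected ones must not. No genotyped non-proband
   relative means `untested`.
6. **Selection** — candidate diagnoses are ranked by tier, then
   segregation status (consistent < untested < inconsistent), then a
   fixed panel gene order; in a gene that carries both inheritance
   modes (OPA1, WFS1, ACO2, SPG7) a constructible biallelic genotype
   beats a monoallelic one, because it explains the phenotype more
   completely — the case is flagged `both_modes_constructible` either
   way. Same-rank ties across genes are resolved by the gene order and
   flagged. A tier 1–3 winner solves the case; tier 4 alone yields
   `vus_candidate`; a lone heterozygote in a recessive-only gene is
   reported `unsolved` with a `monoallelic_recessive_hit` flag rather
   than guessed at.

### Coverage QC and cohort summary

Coverage fractions count design bases **strictly above** each threshold
(a `ge` switch flips to ≥, since ">25×" is ambiguous in prose);
backfill intervals are maximal merged runs of bases at or below
`min_depth` (default 25), labeled with gene and transcription-order
exon. The cohort summary computes yield and mode split over the cohort
size, per-gene shares over the mode totals (two-decimal percentages),
and the variant-class tally over *distinct* variants, identified by
normalized key — the same variant found in many families counts once.
Candidate-gene (`vus_candidate`) families carry an inheritance mode and
are counted inside their mode's bucket, as diagnostic cohorts report
candidate-gene families alongside known-gene ones. OPA1 protein-domain
attribution uses a packaged, explicitly approximate domain table
(N-terminal, coiled-coil, GTPase, central dynamin, GED) scaled onto the
toy protein; domain boundaries are configuration, not code.

## The synthetic cohort

The generator emulates the study conditions the analysis assumes; its
defaults are fixed once and are not tuning knobs.

* **Cohort composition** — 22.23% of probands carry a causal genotype,
  split 186:59 dominant:recessive; per-gene frequencies follow the
  published per-gene family counts (`ion_default_gene_counts()`), with
  the 27 dominant candidate-gene families spread over seven placeholder
  candidate genes (the real candidates are unpublished).
* **Variant classes** — OPA1-dominant causal variants follow the
  36/26/24/14 splice/nonsense/missense/frameshift split; every other
  gene uses the overall 120/22/20/28
  missense/nonsense/frameshift/splice tally, because per-gene class
  spectra are not published gene by gene. Sites are drawn from per-gene
  catalogs enumerated on the toy genome and re-verified against the
  consequence engine after normalization, so a drawn "frameshift" is
  guaranteed to still be one in canonical form.
* **Zygosity** — dominant truths are heterozygous; recessive truths are
  homozygous half the time, else compound-heterozygous with two
  distinct alleles.
* **Novelty** — 60% of known-gene causal variants are catalogued
  pathogenic (tier 1), the rest novel (tiers 2/3); half of all causal
  variants get a tiny (< 5e-5) frequency entry, half stay
  database-absent. These fractions shape tier composition only, never
  recoverability.
* **Noise** — per-call caller sensitivity 0.95, 10% indel
  representation jitter (right-shift within the repeat context or
  padding with the following base; haplotype equivalence is preserved
  by construction), 2% genotype miscalls, and Poisson(1) false
  positives per caller-sample drawn from disjoint caller-specific
  artifact-site catalogs — systematic, caller-private error sites, so
  independent artifacts cannot meet a 2-caller consensus by collision,
  which is also how real caller-specific artifacts behave. Artifact
  sites additionally carry 2% population frequency, so even a chance
  consensus would fail both rarity filters.
* **Background variation** — Poisson(3) benign variants per proband
  from a 220-site common-polymorphism catalog with MAFs in 0.01–0.05
  (above both thresholds: filter-exercising, never tier-qualifying);
  20% of the catalog is additionally labeled benign in the clinical
  table.
* **Pedigrees** — 30% of solved probands get a trio (plus one sibling
  half the time) with Sanger-style relative genotypes consistent with
  the truth mode: a dominant variant sits in one affected parent;
  recessive parents are unaffected carriers, one per allele of a
  compound-het pair. An inconsistency-injection rate exists purely for
  negative tests.
* **Depth track** — design bases are deeply covered (> 100×) outside
  short low-coverage runs entered with probability 0.0025 per base and
  mean length 20 bp, i.e. ~95% of bases clear 25×/50×/100×
  simultaneously, the signature of amplicon dropouts.
* **Toy genome** — one short contig per gene (2–5 exons, proper
  start/stop codons, GT..AG introns, both strands, codons spanning
  exon junctions), built deterministically from a fixed internal seed.

What the generator does **not** emulate: read-level sequencing error,
alignment artifacts, copy-number and structural variants, mosaicism,
mtDNA heteroplasmy beyond the three-mutation screen, population
stratification of allele frequencies, and locus-specific mutation-rate
structure. Passing tests therefore demonstrate the correctness of the
*decision logic and representation handling* under realistic call-level
noise — not robustness to upstream read-processing failure modes.

## Statistical verification

Three properties anchor the test suite (problem sizes chosen to give
the checks real statistical teeth while keeping the default run fast):

* **Truth recovery** — on noise-free and jitter-only cohorts of 1,000
  probands, recovery of (gene, mode, exact causal keys) must be 100%,
  with zero background-only probands diagnosed; jitter-only recovery is
  what the normalization stage earns.
* **Detection calibration** — with per-caller dropout 0.2 and m = 2,
  the per-variant detection rate over ≥10,000 true variants (3,200
  probands) must match the binomial tail P(Bin(6, 0.8) ≥ 2) = 0.9984
  within three Monte-Carlo standard errors.
* **Composition recovery** — a 5,000-proband default cohort must
  reproduce the configured per-gene shares and the OPA1 class split.
  This check spans ~26 binomial cells; at per-cell 95% confidence the
  joint test would reject a provably unbiased sampler more often than
  it accepted it, so the cells use simultaneous Clopper–Pearson
  intervals at family-wise 95% (per-cell level 1 − 0.05/K), backed by a
  per-mode chi-square goodness-of-fit test at α = 0.05. This is a
  multiplicity correction chosen with the design, not a widened band.

## Known limitations

* The consequence engine targets the closed class set the decision
  logic consumes; UTR/regulatory classes, stop-loss, start-loss and
  MNP re-decomposition are out of scope.
* Compound-het phasing uses parental genotypes only; population-based
  or read-backed phasing is not attempted.
* The prioritization is a four-tier policy, not a full ACMG/AMP
  28-criterion classifier.
* Domain attribution for OPA1 relies on approximate, configurable
  residue boundaries.
* Variants at contig position 1 requiring a left anchor are rejected
  rather than re-anchored to the right.
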