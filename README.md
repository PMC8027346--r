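# ionprior

Consensus variant calling and tiered causative-variant prioritization for
a targeted 22-gene inherited optic neuropathy (ION) panel.

## The problem

Inherited optic neuropathies — dominant optic atrophy, recessive optic
atrophy, and their syndromic forms — are caused by variants in a compact
set of genes, most of them encoding mitochondrial proteins (*OPA1*,
*WFS1*, *ACO2*, *SPG7*, *TMEM126A*, *RTN4IP1*, ...). Diagnostic
laboratories resequence these genes with targeted amplicon panels and
must then turn six different callers' VCFs into one defensible molecular
diagnosis per proband. `ionprior` implements that computation as a
tested, reusable pipeline:

1. **Normalization / decomposition** — every called allele is reduced to
   its canonical representation (multiallelic split, parsimonious,
   left-aligned), so calls from different callers become comparable.
2. **Consensus calling** — a variant is retained when at least
   *m* of the six callers (Torrent Suite VariantCaller, GATK
   UnifiedGenotyper, VarScan2, SNVer, LoFreq, Platypus) agree on its
   normalized key (*m* = 2 by default); genotypes are reconciled by
   majority vote with a fixed caller-priority tie-break.
3. **Annotation** — gene assignment by panel-region overlap, a
   transcript-model consequence engine (codon translation, frame
   arithmetic, ±2 bp canonical splice window), population MAF and
   reported-clinical-significance lookup from packaged tables.
4. **Prioritization** — per proband: an mtDNA pre-screen for the three
   primary LHON mutations (m.3460G>A, m.11778G>A, m.14484T>C);
   mode-specific rarity filters (dominant MAF < 1e-4, recessive
   MAF < 5e-3, absent always passes); a tier ladder
   (reported pathogenic → novel LoF → novel missense in known genes →
   candidate-gene VUS); biallelic / compound-heterozygote detection; and
   pedigree segregation matching.
5. **Coverage QC** — fractions of design bases above depth thresholds
   and the merged low-coverage intervals needing Sanger backfill.
6. **Cohort summary** — diagnostic yield, dominant/recessive split,
   per-gene shares by mode, distinct-variant class tally, and the OPA1
   exon/class/domain spectrum.

Because no patient data ship with the package, a seeded
**synthetic-cohort generator** emulates the study conditions end to end
on a deterministic toy panel genome: causal variants drawn per-gene and
per-class from configurable frequency vectors, benign background
polymorphisms, per-caller dropout, indel representation jitter,
caller-specific false positives, pedigrees with Sanger-style relative
genotypes, and a ground-truth table.

## Worked example

```r
library(ionprior)

spec <- cohort_spec(n_probands = 200, seed = 7)   # study-like conditions
cohort <- generate_cohort(spec)
run <- run_ion_pipeline(run_config(seed = 7, spec = spec),
                        cohort = cohort)
print(run)
truth_recovery(run)
```

```
ION pipeline run (seed 7): 200 probands, 7 stages
ION cohort summary: 200 probands, 42 solved (21.00%)
  dominant:  34 (17.00% of cohort)
  recessive: 8 (4.00% of cohort)
  distinct variants: 47
         mode     gene     n   pct
 1:  dominant     OPA1    15 44.12
 2:  dominant     WFS1     5 14.71
 3:  dominant     ACO2     4 11.76
 ...
$recovery
[1] 1

$false_solved
[1] 0
```

Of 200 simulated probands, 42 carry a causal genotype; the pipeline
recovers every one (gene, inheritance mode and exact causal alleles) and
diagnoses none of the background-only probands, despite 5% per-caller
dropout, representation jitter on indels, and one false positive per
caller-sample on average. The per-gene table mirrors the composition a
diagnostic ION cohort reports: *OPA1* dominates the dominant cases, with
*ACO2* and *WFS1* next, and *WFS1*/*ACO2*/*RTN4IP1* leading the
recessive ones.

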