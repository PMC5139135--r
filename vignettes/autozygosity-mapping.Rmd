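---
title: "Autozygosity mapping and private-variant triage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and private-variant triage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The analysis model

`autozyg` implements the classic mapping-plus-filtering route to a
recessive disease gene in a small, inbred-like pedigree:

* **Identity by state (IBS).** For two samples, each co-called marker
  contributes an allele-sharing score — 1 if the genotypes are
  identical, 0.5 if they share exactly one allele (e.g. AB vs BB), 0 if
  they share none (AA vs BB) — and `compute_ibs()` reports 100 times the
  mean. This is the arithmetic of PLINK's `DST` statistic. A fully
  identical pair scores 100%, the signature used to confirm monozygotic
  twins on a dense panel. Worth stating explicitly because "IBS" has
  variants: any symmetric per-marker scoring must give the two cross
  comparisons AB/BB and BB/AB the same score, and here both count 0.5.

* **Runs of homozygosity (ROH).** A run is a maximal window of
  consecutive markers on one chromosome containing at most
  `max_het_in_run` heterozygous (default 0) and `max_missing_in_run`
  missing calls (default 2), trimmed to its outermost homozygous
  markers, and reported only if it spans at least `min_length_bp`
  (default 1 Mb — the conventional threshold for autozygous tracts on
  ~50–800k panels) and `min_markers` (default 20) markers. "Maximal"
  means extending either end violates a budget; when missing calls
  exceed the budget locally, two maximal windows can overlap, and both
  are reported rather than merged — merging across an excess-missing gap
  would claim homozygosity where there is no evidence. Intervals are
  0-based half-open (`[first marker pos − 1, last marker pos)`),
  BED-compatible; 1-based coordinates appear only in VCF output.

* **Case-shared candidate regions.** `shared_case_regions()` intersects
  the cases' runs and keeps maximal sub-intervals where every called
  case is homozygous for the *same* allele (all-missing markers are
  neutral; a conflicting or heterozygous marker is a breakpoint), then
  re-applies the span/marker thresholds. `exclude_parental()` then
  drops any region where a parent is homozygous for the case-shared
  allele at more than `max_parent_hom_fraction` of checkable markers —
  a carrier parent should be heterozygous throughout a true autozygous
  tract.

* **Private-variant triage.** Under the recessive hypothesis,
  `recessive_branch()` chains: homozygous coding variants in the index
  case → inside candidate regions (step I) → alternate allele seen in no
  control genome (step II) → absent from the population-database site
  list (step III) → protein-changing. The heterozygous
  (`dominant_branch()`) variant of the funnel skips step I. Steps II and
  III are pure set subtractions on the normalized
  `(chrom, pos, ref, alt)` key, so they commute; "private" means zero
  observations of the alternate allele in any comparison genome, not a
  frequency threshold.

* **Consequence annotation.** Variants are projected through each
  transcript's CDS exon chain (strand-aware), deletions are 3′-shifted
  to their HGVS-canonical position, and the edited CDS is translated
  directly. For a frameshift, the first changed residue counts as 1, the
  new stop at offset N gives `p.XaaKYaafsN*`, and the mutant length is
  `K + N − 2`; when the first new codon is itself a stop the name is the
  stop-gain-style `p.XaaK*`. A frameshift that never reaches a stop is
  reported with an explicit `no_stop` flag, not an error. Truncation
  statistics call a domain *lost* when it lies entirely beyond the
  mutant length and *truncated* when partially (a domain ending exactly
  at the mutant length is neither).

* **Segregation.** `genotype_counts()` cross-tabulates genotypes by
  cohort (missing calls tallied separately and excluded from
  denominators), `perfect_association()` requires every called affected
  sample homozygous-alternate and no other sample homozygous-alternate,
  and `carrier_frequency()` is `100 · het / called`. Obligate-carrier
  status is derived from the pedigree (parent of an affected,
  homozygous-alternate individual), and a homozygous-reference parent of
  such a case is flagged as a Mendelian violation.

## What the simulator states, and why

The generator (`sim_config()` defaults) is the stated world the tests
and the recovery analysis run in:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 30 Mb | large enough for multiple >1 Mb tracts, desk-scale fast |
| markers | 10,000, jittered uniform grid | ~6 kb spacing, a scaled-down dense SNP array |
| founder allele frequency | 0.5 | maximally informative markers; no LD model (the method consumes homozygosity, not LD decay) |
| missing rate | 0.5% per call | exercises the ROH missing-call budget |
| seeded IBD tracts | chr1:10–12.5 Mb, chr2:5–6.8 Mb | two >1 Mb tracts, one housing the target gene |
| cases / carriers | MZ twin pair + two half-sib cases; 3 carrier parents | the pedigree structure of the motivating study design |
| control genomes / popdb genomes | 106 / 1,119 | the comparison-cohort sizes of that design |
| population controls, carrier fraction | 1,201, 4% | a genotyped breed sample with a few-percent carrier frequency |
| background coding variants | 500, hom in case w.p. 0.5 | a scaled-down coding variant load |
| cohort sharing | in controls w.p. 0.9, in popdb w.p. 0.8 | chosen once so the desk-scale funnel narrows the way a real one does (hundreds → a handful); not stated by the study design and not revisited |

Within each seeded tract, every case is homozygous for one shared
founder haplotype and every carrier parent is *strictly* heterozygous —
that is what a true IBD tract transmitted from a common ancestor looks
like at informative markers, and it is the pattern the mapping stage is
entitled to assume. Elsewhere, transmissions are drawn per marker
(gene-dropping), so long chance runs are vanishingly rare. All
randomness flows from `rng_seed` through fixed per-stage offsets, and
identical configurations reproduce byte-identical files.

The simulator does **not** emulate: linkage disequilibrium,
recombination maps, genotyping-error miscalls (missingness only),
breed demography or realistic site-frequency spectra, multi-nucleotide
or structural variants. A green recovery test therefore establishes
that the pipeline's logic recovers the seeded truth under Mendelian
sampling noise — not that it is robust to array artefacts or population
structure.

## Numerical and design choices

* **Parental-exclusion tolerance.** The type-level default for
  `exclude_parental()` is strict (0.0): any parental homozygosity for
  the shared allele discards the region. The *pipeline* default is
  `max_parent_hom_fraction = 0.05`, and the difference is deliberate. A
  detected case run routinely extends a marker or two beyond the true
  tract boundary (each flanking marker continues the run with
  probability ≈ ½ at informative markers). At such a flanking marker a
  parent that transmitted the case's allele is homozygous for it with
  probability ½, so at least one parent conflicts with probability ¾ —
  a strict threshold would discard a large share of true regions for a
  boundary artefact. Chance extensions conflict at a few markers of
  hundreds (fraction ≪ 0.05), while a genuinely homozygous parent
  conflicts at ~50% of region markers, so 0.05 separates the two cases
  cleanly at either marker density.
* **Variant-site normalization.** Multi-allelic records are decomposed
  into biallelic site–allele pairs; shared suffix then shared prefix are
  trimmed (position advanced), identically for every cohort, before any
  comparison. Full left-alignment against a genome is not performed —
  the pipeline carries CDS sequences, not a whole-genome FASTA — and the
  simulator emits one consistent representation; with external call sets
  from different callers, variants should be pre-normalized upstream.
* **3′ normalization is per transcript.** The same genomic deletion may
  normalize to different cDNA positions on different isoforms; names are
  therefore computed in each transcript's own cDNA space (which is how
  one genomic event legitimately carries two c. names).
* **Splice boundaries.** A deletion spanning an exon–intron boundary is
  flagged (`splice_flag`) and classified non-coding rather than guessed
  at; splice-site disruption is reported, not counted as
  protein-changing.
* **Degenerate inputs.** IBS with no co-called marker, carrier frequency
  with an empty denominator, and unassigned samples in the count table
  are errors naming the offending items; an empty region list simply
  empties the recessive funnel; ambiguity codes in sequences are
  rejected at entry.
* **Ties and determinism.** Runs are sorted by position, duplicate
  trimmed runs collapsed, funnel stages recorded with their variant
  lists; reports and artifacts contain no timestamps, so byte-level
  determinism is testable.
* **Performance.** Protein translation uses a plain codon lookup table
  (identical output to, but much faster than, calling a fuzzy-codon
  translator per variant); the test-suite oracle uses the independent
  `Biostrings::translate()` path.

## Known limitations

* ROH detection is run-based with explicit budgets, not a windowed
  PLINK emulation; parameter values are declared, not inferred from any
  published chip analysis.
* The truncated fraction is computed exactly from the mutant length; on
  the shipped fixture the long isoform loses 246 of 881 residues
  (27.9%). Rounded prose claims like "more than 30%" are not
  reproduced.
* The dominant branch filters only against the cohorts; parental chip
  genotypes are not used to confirm de-novo status (the
  obligate-carrier check reports, but does not filter).
* Carrier-frequency reporting assumes a biallelic variant and a closed
  set of genotype codes.
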