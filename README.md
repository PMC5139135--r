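# autozyg

Autozygosity mapping and private-variant triage for recessive
disease-gene discovery in small pedigrees.

## The problem

When a rare recessive disorder surfaces in a closely related family —
here the motivating setting is a livestock pedigree with an affected
monozygotic twin pair and two affected half-siblings, all tracing back to
one common ancestor — the causal mutation can be found with a classic
two-stage strategy:

1. **Autozygosity (homozygosity) mapping.** The affected animals are
   expected to be identical by descent (IBD) around the causal locus, so
   they share long runs of homozygosity (ROH, > 1 Mb) with the *same*
   alleles, while their unaffected carrier parents are heterozygous
   there. Dense SNP-array genotypes localize these candidate regions.
   Pairwise identity by state (IBS) — the mean per-marker allele-sharing
   score, 1 for identical genotypes, ½ for one shared allele, 0 for none
   — confirms twin zygosity (100% across a dense panel).
2. **Private-variant triage.** Whole-genome variant calls from one case
   are filtered in three steps: (I) keep homozygous coding variants
   inside the candidate IBD regions; (II) remove everything observed in
   a control-genome cohort; (III) remove everything present in a large
   population variant database. What survives and changes the protein is
   the candidate list — ideally a single frameshift. A parallel
   heterozygous branch (steps II–III without the region restriction)
   covers the de-novo dominant hypothesis.

The surviving candidate is then annotated (HGVS c./p. names, premature
stop position `fsN*`, truncated fraction, lost protein domains) and
checked for perfect recessive segregation and population carrier
frequency, `100 · n_het / n_called`.

Every stage is a tibble-in / tibble-out function, so the package also
ships a seeded simulator (pedigree gene-dropping with imposed IBD
tracts, cohort variant sharing, two-transcript gene models) that makes
the whole pipeline testable without any external data.

## Worked example

```r
library(autozyg)

report <- run_pipeline(sim_config(rng_seed = 3L))
print(report)
#> <pipeline_report>
#> twin IBS: 100.00%; candidate regions: 2; causal recovered: TRUE
#> recessive funnel:
#>   stage               n
#> 1 coding_hom        277
#> 2 in_ibd_regions     52
#> 3 not_in_controls     6
#> 4 not_in_popdb        2
#> 5 nonsynonymous       2
#> dominant funnel:
#>   stage               n
#> 1 coding_het        224
#> 2 not_in_controls    32
#> 3 not_in_popdb        6
#> 4 nonsynonymous       4
#> segregation: perfect=TRUE carrier%=4.33
```

The twin cases show 100% IBS; both seeded IBD tracts come back as
candidate regions; the recessive funnel narrows 277 homozygous coding
variants to 2 protein-changing private candidates, and the seeded
deletion is among them. The candidate annotation names the same genomic
deletion on both transcripts of the target gene — the two isoforms differ
by a 99-nt alternative first exon, so one event gets two cDNA names:

```r
cand <- report$candidates
cand[cand$category == "frameshift",
     c("transcript_id", "cdna_hgvs", "protein_hgvs",
       "mutant_length", "fraction_lost")]
#>   transcript_id  cdna_hgvs    protein_hgvs mutant_length fraction_lost
#> 1     geneT-201 c.1881delG p.Ser628Valfs9*           635     0.2792281
#> 2     geneT-202 c.1782delG p.Ser595Valfs9*           602     0.2900943
```

The 1-bp deletion shifts the frame at Ser628 (Ser595 on the short
isoform), a stop appears as the 9th codon of the new frame, and the
truncated protein loses 246 residues (27.9%) including its two
C-terminal domains. Segregation is perfect (only affected animals are
homozygous for the deletion) with a carrier frequency of ~4% among
population controls.

Individual stages are plain functions over tibbles —
`compute_ibs()`, `detect_roh()`, `shared_case_regions()`,
`exclude_parental()`, `recessive_branch()`, `dominant_branch()`,
`annotate_variants()`, `segregation_report()` — with `tidy()`/`glance()`
methods on funnel and segregation objects and `plot_roh()`,
`plot_funnel()`, `plot_protein()` for figures. Standard formats are
read and written with `read_plink()`/`write_plink()` (PED/MAP),
`read_vcf()`/`write_vcf()`, `read_bed()`/`write_bed()`, and
`read_gene_models()`/`write_gene_models()` (GFF3 + CDS FASTA). A thin
command-line front-end with `simulate` / `map-roh` / `triage` /
`annotate` / `segregate` / `run` subcommands lives at
`inst/cli/autozyg.R`.

See `vignettes/autozygosity-mapping.Rmd` for the model, parameter
choices and known limitations.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantity from
scratch — it simulates a fully-called 10,000-marker genotype vector,
duplicates it as a second sample, and reports the pairwise IBS
percentage of the pair — and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
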