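# hand-built two-exon transcripts for projection tests
plus_tr <- tibble::tibble(
  transcript_id = "plus", gene_id = "g", chrom = "chrT", strand = "+",
  exon_start = list(c(1001L, 2001L)), exon_end = list(c(1006L, 2003L)),
  cds_seq = "ATGAAATGA", protein_length = 2L
)
minus_tr <- tibble::tibble(
  transcript_id = "minus", gene_id = "g", chrom = "chrT", strand = "-",
  # 5'->3' order means descending genomic coordinates
  exon_start = list(c(2001L, 1001L)), exon_end = list(c(2002L, 1007L)),
  cds_seq = "ATGAAATGA", protein_length = 2L
)

test_that("cDNA projection honours exon chains and strand", {
  # first CDS base of a plus-strand transcript is c.1
  expect_identical(project_to_cdna(plus_tr, 1001L), 1L)
  expect_identical(project_to_cdna(plus_tr, 1006L), 6L)
  expect_identical(project_to_cdna(plus_tr, 2001L), 7L)
  expect_identical(project_to_cdna(plus_tr, 2003L), 9L)
  expect_true(is.na(project_to_cdna(plus_tr, 1500L)))   # intron

  # minus strand: the genomic position at the CDS 5' end is the HIGHEST coord
  expect_identical(project_to_cdna(minus_tr, 2002L), 1L)
  expect_identical(project_to_cdna(minus_tr, 2001L), 2L)
  expect_identical(project_to_cdna(minus_tr, 1007L), 3L)
  expect_identical(project_to_cdna(minus_tr, 1001L), 9L)
})

test_that("projection and inverse projection are mutually inverse on both strands", {
  withr::local_seed(7)
  for (tr in list(plus_tr, minus_tr)) {
    n_cds <- sum(tr$exon_end[[1]] - tr$exon_start[[1]] + 1L)
    cpos <- seq_len(n_cds)
    g <- cdna_to_genomic(tr, cpos)
    expect_identical(project_to_cdna(tr, g), cpos)
  }
})

test_that("3' normalization shifts deletions maximally without changing the edit", {
  # delete one G from the run in AGGGT: any of positions 2..4 is equivalent,
  # reported at the most 3' position 4
  expect_identical(normalize_3prime("AGGGT", 2L), 4L)
  expect_identical(normalize_3prime("AGGGT", 3L), 4L)
  expect_identical(normalize_3prime("AGGGT", 4L), 4L)
  # no identical neighbour: unchanged
  expect_identical(normalize_3prime("ACGTA", 3L), 3L)
  # idempotent
  expect_identical(normalize_3prime("AGGGT", normalize_3prime("AGGGT", 2L)), 4L)

  # property: normalization never changes the edited string
  withr::local_seed(11)
  for (i in 1:200) {
    cds <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    del <- sample(60L, 1)
    del2 <- normalize_3prime(cds, del)
    edit <- function(s, p) paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
    expect_identical(edit(cds, del), edit(cds, del2))
  }
})

test_that("protein effect prediction handles the documented edit cases", {
  # deleting c.7 (G) of ATG AAA GTG ACC TAA turns codon 3 into TGA:
  # the first changed codon is itself a stop
  call <- predict_protein_effect("ATGAAAGTGACCTAA",
                                 list(type = "del", start = 7L, len = 1L))
  expect_identical(call$category, "frameshift")
  expect_identical(call$protein_hgvs, "p.Val3*")
  expect_identical(call$mutant_length, 2L)
  expect_identical(call$stop_offset, 1L)

  # synonymous third-position change GAA -> GAG
  syn <- predict_protein_effect("ATGGAATGA",
                                list(type = "snv", pos = 6L, alt = "G"))
  expect_identical(syn$category, "synonymous")
  expect_identical(syn$mutant_length, 2L)
  expect_identical(syn$fraction_lost, 0)

  # missense and stop-gain
  mis <- predict_protein_effect("ATGTCCTGA",
                                list(type = "snv", pos = 5L, alt = "G"))
  expect_identical(mis$category, "missense")
  expect_identical(mis$protein_hgvs, "p.Ser2Cys")
  sg <- predict_protein_effect("ATGTACAAATGA",
                               list(type = "snv", pos = 6L, alt = "A"))
  expect_identical(sg$category, "stop-gain")
  expect_identical(sg$protein_hgvs, "p.Tyr2*")
  expect_identical(sg$mutant_length, 1L)

  # frameshift with no downstream stop is a flagged result, not an error
  ns <- predict_protein_effect("ATGAAAAAAAAATAA",
                               list(type = "del", start = 4L, len = 1L))
  expect_identical(ns$category, "frameshift")
  expect_true(ns$no_stop)

  # ambiguity codes are rejected
  expect_error(predict_protein_effect("ATGANATGA",
                                      list(type = "snv", pos = 5L, alt = "G")),
               "outside")
})

test_that("the fixture deletion reproduces the two-transcript fs9* calls", {
  cfg <- tiny_config(seed = 6L)
  fx <- make_transcript_fixture(cfg)
  ann <- annotate_variants(fx$causal, fx$transcripts, fx$domains)
  ann <- ann[!is.na(ann$transcript_id) & grepl("^geneT", ann$transcript_id), ]
  ann <- dplyr::arrange(ann, ann$transcript_id)

  expect_identical(ann$cdna_hgvs, c("c.1881delG", "c.1782delG"))
  expect_identical(ann$protein_hgvs, c("p.Ser628Valfs9*", "p.Ser595Valfs9*"))
  expect_identical(ann$category, c("frameshift", "frameshift"))
  expect_identical(ann$mutant_length, c(635L, 602L))
  # both truncated proteins lose the two C-terminal domains
  expect_identical(ann$lost_domains, list(c("MBB", "MOSC"), c("MBB", "MOSC")))
  # 246 residues lost from the 881-aa protein
  expect_equal(ann$fraction_lost[1], 246 / 881, tolerance = 1e-12)
})

test_that("truncation statistics use the exact boundary definition", {
  dom <- tibble::tibble(domain = c("D1", "D2", "D3"),
                        aa_start = c(10L, 50L, 120L),
                        aa_end = c(40L, 100L, 150L))
  call <- tibble::tibble(mutant_length = 100L, fraction_lost = 0.3)
  ts <- truncation_stats(call, dom)
  # D2 ends exactly at the mutant length: neither lost nor truncated
  expect_identical(ts$lost, "D3")
  expect_identical(ts$truncated, character(0))

  call2 <- tibble::tibble(mutant_length = 99L, fraction_lost = 0.3)
  expect_identical(truncation_stats(call2, dom)$truncated, "D2")

  call3 <- tibble::tibble(mutant_length = 150L, fraction_lost = 0)
  ts3 <- truncation_stats(call3, dom)
  expect_identical(ts3$lost, character(0))
  expect_identical(ts3$truncated, character(0))
})

test_that("frameshift naming agrees with the edit-and-translate oracle on fuzzed CDS", {
  withr::local_seed(1234)
  n_cases <- 300L
  ok <- logical(n_cases)
  for (i in seq_len(n_cases)) {
    cds <- random_orf_chr(sample(10:120, 1))
    del <- sample(nchar(cds) - 3L, 1)    # keep the terminal stop intact
    call <- predict_protein_effect(cds, list(type = "del", start = del, len = 1L))
    want <- oracle_deletion_effect(cds, del)

    good <- identical(call$category, "frameshift") &&
      identical(call$mutant_length, as.integer(want$mutant_length)) &&
      identical(call$no_stop, want$no_stop) &&
      # the protein prefix before the first changed residue is preserved
      identical(substr(want$mut, 1, want$k - 1),
                substr(want$wt, 1, want$k - 1))
    # reconstruct the expected HGVS name from the oracle's quantities
    if (good && !want$no_stop && want$k <= want$wt_len) {
      wt_aa <- aa3_of(substr(want$wt, want$k, want$k))
      mut_aa <- substr(want$mut, want$k, want$k)
      expected <- if (mut_aa == "*") {
        sprintf("p.%s%d*", wt_aa, want$k)
      } else {
        sprintf("p.%s%d%sfs%d*", wt_aa, want$k, aa3_of(mut_aa),
                want$stop_offset)
      }
      good <- identical(call$protein_hgvs, expected)
    }
    ok[i] <- good
  }
  expect_identical(sum(ok), n_cases)
})

test_that("variants spanning an exon boundary are flagged, not mistranslated", {
  # deletion spanning the junction of plus_tr's exon 1 into the intron
  # (anchored at 1004: deleted bases 1005..1008 straddle the boundary)
  v <- tibble::tibble(chrom = "chrT", pos = 1004L, ref = "AAAAA", alt = "A")
  ann <- annotate_variants(v, plus_tr)
  expect_identical(ann$category, "non-coding")
  expect_true(ann$splice_flag)

  # a variant overlapping no transcript at all is a single non-coding row
  v2 <- tibble::tibble(chrom = "chrT", pos = 5000L, ref = "A", alt = "C")
  ann2 <- annotate_variants(v2, plus_tr)
  expect_identical(nrow(ann2), 1L)
  expect_identical(ann2$category, "non-coding")
  expect_true(is.na(ann2$transcript_id))
})
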