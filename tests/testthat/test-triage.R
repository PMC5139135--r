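# small helper: variant tibble from parallel vectors, dosages for one sample
vtbl <- function(chrom, pos, ref, alt, ...) {
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        ref = ref, alt = alt)
  dots <- list(...)
  for (s in names(dots)) out[[s]] <- as.integer(dots[[s]])
  out
}

test_that("variant normalization decomposes and trims representations", {
  v <- vtbl("chr1", c(100, 200, 300, 400), c("A", "CTT", "GAT", "CTT"),
            c("G,T", "C", "GCT", "CT"), s = c(1, 2, 1, 2))
  n <- normalize_variants(v)
  expect_identical(nrow(n), 5L)                     # multi-allelic split
  # CTT>C is already parsimonious (a 2-bp anchored deletion)
  expect_true(any(n$pos == 200 & n$ref == "CTT" & n$alt == "C"))
  # GAT>GCT: shared suffix T then shared prefix G -> A>C at 301
  expect_true(any(n$pos == 301 & n$ref == "A" & n$alt == "C"))
  # CTT>CT: shared suffix T -> CT>C at 400 (anchored 1-bp deletion)
  expect_true(any(n$pos == 400 & n$ref == "CT" & n$alt == "C"))
  # idempotent
  expect_identical(normalize_variants(n), n)
})

test_that("coding selection honours CDS overlap, zygosity and site dedup", {
  cfg <- tiny_config(seed = 4L)
  fx <- make_transcript_fixture(cfg)
  tr <- fx$transcripts
  a <- tr[tr$transcript_id == "geneT-201", ]
  shared_exon_pos <- a$exon_start[[1]][4] + 10L      # in a shared CDS exon
  intron_pos <- a$exon_end[[1]][4] + 50L             # between CDS exons

  v <- vtbl("chr1", c(shared_exon_pos, intron_pos, shared_exon_pos + 1L),
            c("A", "A", "A"), c("C", "C", "G"),
            CASE1 = c(2, 2, 1))
  got <- select_coding_by_zygosity(v, tr, "hom-alt", "CASE1")
  # intron excluded, het excluded; exonic hom kept once though 2 transcripts overlap
  expect_identical(got$pos, shared_exon_pos)

  got_het <- select_coding_by_zygosity(v, tr, "het", "CASE1")
  expect_identical(got_het$pos, shared_exon_pos + 1L)

  expect_warning(
    out <- select_coding_by_zygosity(
      vtbl("chrUn", 500L, "A", "C", CASE1 = 2), tr, "hom-alt", "CASE1"),
    "unknown"
  )
  expect_identical(nrow(out), 0L)
})

test_that("region restriction uses half-open boundaries", {
  regions <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L)
  v <- vtbl("chr1", c(1000L, 1001L, 2000L, 2001L), "A", "C", s = 2)
  kept <- filter_step1_regions(v, regions)
  # first base of the region (0-based start 1000 -> 1-based 1001) is kept,
  # one base before is dropped; end is inclusive of base 2000 only
  expect_identical(kept$pos, c(1001L, 2000L))
  expect_identical(nrow(filter_step1_regions(v, regions[0, ])), 0L)
})

test_that("control and popdb filters are allele-aware set subtractions", {
  case <- vtbl("chr1", c(10, 20, 30), c("A", "C", "G"), c("T", "G", "A"),
               CASE1 = c(2, 2, 2))
  # site 10 carried het by one control; site 20 present with a DIFFERENT alt
  controls <- vtbl("chr1", c(10, 20), c("A", "C"), c("T", "A"),
                   CTRL1 = c(1, 0), CTRL2 = c(0, 2))
  out <- filter_step2_controls(case, controls)
  expect_identical(sort(out$pos), c(20L, 30L))

  popdb <- tibble::tibble(chrom = "chr1", pos = 30L, ref = "G", alt = "A")
  out2 <- filter_step3_popdb(out, popdb)
  expect_identical(out2$pos, 20L)

  # a control row where nobody actually carries the allele does not filter
  controls_uncarried <- vtbl("chr1", 20, "C", "G", CTRL1 = 0, CTRL2 = 0)
  expect_identical(nrow(filter_step2_controls(case, controls_uncarried)), 3L)
})

test_that("non-synonymous selection mirrors codon-level consequences", {
  cfg <- tiny_config(seed = 4L)
  fx <- make_transcript_fixture(cfg)
  a <- fx$transcripts[fx$transcripts$transcript_id == "geneT-201", ]

  # build SNVs at chosen cDNA positions via the genomic projection
  snv_at <- function(cpos, alt) {
    g <- cdna_to_genomic(a, cpos)
    vtbl(a$chrom, g, substr(a$cds_seq, cpos, cpos), alt, CASE1 = 2)
  }
  # find a GAx codon (Glu/Asp family): synonymous third-position swap
  codons <- substring(a$cds_seq, seq(1, nchar(a$cds_seq) - 2, 3),
                      seq(3, nchar(a$cds_seq), 3))
  k_gaa <- which(codons == "GAA")[1]
  skip_if(is.na(k_gaa), "no GAA codon in fixture CDS")
  syn <- snv_at(3L * k_gaa, "G")       # GAA -> GAG, both Glu
  expect_identical(nrow(select_nonsynonymous(syn, fx$transcripts)), 0L)

  # TCC -> TGC is Ser -> Cys (missense) at the second codon position
  k_tcc <- which(codons == "TCC")[1]
  skip_if(is.na(k_tcc), "no TCC codon in fixture CDS")
  mis <- snv_at(3L * k_tcc - 1L, "G")
  expect_identical(nrow(select_nonsynonymous(mis, fx$transcripts)), 1L)
  ann <- annotate_variants(mis, fx$transcripts)
  expect_true(any(ann$category == "missense" &
                    grepl("^p\\.Ser\\d+Cys$", ann$protein_hgvs)))

  # the seeded 1-bp CDS deletion is kept (frameshift)
  expect_identical(nrow(select_nonsynonymous(fx$causal |>
                                               dplyr::mutate(CASE1 = 2L),
                                             fx$transcripts)), 1L)
})

test_that("triage funnel equals brute-force set algebra and is monotone", {
  cfg <- tiny_config(seed = 19L)
  fx <- make_transcript_fixture(cfg)
  co <- simulate_variant_cohort(cfg, fx)
  sim <- simulate_pedigree_genotypes(cfg)
  p <- roh_params()
  runs <- dplyr::bind_rows(detect_roh(sim$geno, "CASE1", p),
                           detect_roh(sim$geno, "CASE2", p))
  regions <- exclude_parental(
    shared_case_regions(runs, sim$geno, c("CASE1", "CASE2"), p),
    sim$geno, c("SIRE", "DAM"), 0.02)

  fun <- recessive_branch(co$case_variants, fx$transcripts, regions,
                          co$control_variants, co$popdb_sites, "CASE1")
  expect_true(all(diff(fun$stages$n) <= 0))

  # independent set-algebra oracle on variant keys
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  s0 <- fun$variants$coding_hom
  in_region <- vapply(seq_len(nrow(s0)), function(i) {
    any(regions$chrom == s0$chrom[i] & regions$start < s0$pos[i] &
          s0$pos[i] <= regions$end)
  }, logical(1))
  ctrl_keys <- key(co$control_variants[rowSums(
    as.matrix(co$control_variants[, variant_samples(co$control_variants)]),
    na.rm = TRUE) > 0, ])
  popdb_keys <- key(co$popdb_sites)
  want_s3 <- setdiff(setdiff(key(s0[in_region, ]), ctrl_keys), popdb_keys)
  expect_setequal(key(fun$variants$not_in_popdb), want_s3)

  # steps II and III commute (pure set subtractions)
  s1 <- fun$variants$in_ibd_regions
  a <- filter_step3_popdb(filter_step2_controls(s1, co$control_variants),
                          co$popdb_sites)
  b <- filter_step2_controls(filter_step3_popdb(s1, co$popdb_sites),
                             co$control_variants)
  expect_setequal(key(a), key(b))

  # the seeded causal deletion survives to the final list
  expect_identical(
    nrow(dplyr::semi_join(funnel_candidates(fun), fx$causal,
                          by = c("chrom", "pos", "ref", "alt"))), 1L)

  # tidy()/glance() expose the funnel shape
  td <- tidy(fun)
  expect_identical(td$n, fun$stages$n)
  expect_identical(glance(fun)$n_final, td$n[length(td$n)])
})

test_that("dominant branch runs without regions and is empty when no het-private nonsyn exists", {
  cfg <- tiny_config(seed = 23L, n_background_coding_variants = 0L)
  fx <- make_transcript_fixture(cfg)
  co <- simulate_variant_cohort(cfg, fx)
  # only the causal deletion exists and it is hom-alt, so the het branch is empty
  fun <- dominant_branch(co$case_variants, fx$transcripts,
                         co$control_variants, co$popdb_sites, "CASE1")
  expect_identical(fun$stages$n[1], 0L)
  expect_identical(nrow(funnel_candidates(fun)), 0L)
  expect_true(all(diff(fun$stages$n) <= 0))

  # with background variants, the branch still equals set algebra
  cfg2 <- tiny_config(seed = 29L, n_background_coding_variants = 50L)
  fx2 <- make_transcript_fixture(cfg2)
  co2 <- simulate_variant_cohort(cfg2, fx2)
  fun2 <- dominant_branch(co2$case_variants, fx2$transcripts,
                          co2$control_variants, co2$popdb_sites, "CASE1")
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  ctrl_keys <- key(co2$control_variants[rowSums(
    as.matrix(co2$control_variants[, variant_samples(co2$control_variants)]),
    na.rm = TRUE) > 0, ])
  want <- setdiff(setdiff(key(fun2$variants$coding_het), ctrl_keys),
                  key(co2$popdb_sites))
  expect_setequal(key(fun2$variants$not_in_popdb), want)
  expect_true(all(diff(fun2$stages$n) <= 0))
})
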