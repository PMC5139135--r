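#' Build the default study pedigree
#'
#' A nuclear family with a sire, a dam and a monozygotic twin case pair,
#' optionally extended by one or two affected paternal half-siblings from
#' a second dam (so the obligate carriers are sire, dam and second dam).
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `id`, `sire`, `dam`, `sex`
#'   (`"male"`/`"female"`) and `status`
#'   (`"affected"`/`"unaffected"`/`"unknown"`).
#' @export
make_pedigree <- function(config) {
  ped <- tibble(
    id = c("SIRE", "DAM", "CASE1", "CASE2"),
    sire = c(NA, NA, "SIRE", "SIRE"),
    dam = c(NA, NA, "DAM", "DAM"),
    sex = c("male", "female", "male", "male"),
    status = c("unaffected", "unaffected", "affected", "affected")
  )
  if (config$n_cases >= 3) {
    ped <- bind_rows(
      ped,
      tibble(id = "DAM2", sire = NA, dam = NA,
             sex = "female", status = "unaffected"),
      tibble(id = paste0("CASE", seq(3, config$n_cases)),
             sire = "SIRE", dam = "DAM2",
             sex = rep(c("female", "male"), length.out = config$n_cases - 2),
             status = "affected")
    )
  }
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  parents <- c(ped$sire, ped$dam)
  unknown <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(unknown) > 0) {
    abort(paste0("pedigree names unknown parent(s): ", paste(unknown, collapse = ", ")))
  }
  # no individual is its own ancestor
  for (i in ped$id) {
    seen <- character()
    frontier <- i
    while (length(frontier) > 0) {
      rows <- ped[ped$id %in% frontier, ]
      frontier <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), seen)
      if (i %in% frontier) abort(paste0("pedigree cycle at individual ", i))
      seen <- c(seen, frontier)
    }
  }
  invisible(ped)
}

# marker map on a jittered uniform grid, strictly increasing per chromosome
.make_markers <- function(config) {
  gl <- config$genome_layout
  n_by_chrom <- pmax(1L, round(config$n_markers * gl$length / sum(gl$length)))
  purrr::map2_dfr(gl$chrom, seq_len(nrow(gl)), function(ch, i) {
    n <- n_by_chrom[i]
    spacing <- gl$length[i] / n
    pos <- round((seq_len(n) - 0.5) * spacing + runif(n, -0.3, 0.3) * spacing)
    pos <- pmin(pmax(pos, 1), gl$length[i])
    a_idx <- sample(4L, n, replace = TRUE)
    b_idx <- 1L + (a_idx - 1L + sample(3L, n, replace = TRUE)) %% 4L
    bases <- c("A", "C", "G", "T")
    tibble(chrom = ch, pos = as.integer(pos),
           allele_a = bases[a_idx], allele_b = bases[b_idx])
  })
}

# indices of markers falling in a 0-based half-open region
.markers_in_region <- function(markers, chrom, start, end) {
  which(markers$chrom == chrom & markers$pos > start & markers$pos <= end)
}

#' Simulate pedigree genotypes with seeded autozygous tracts
#'
#' Founders receive independent random haplotypes (B-allele frequency
#' `maf`); genotypes drop through the pedigree by per-marker Mendelian
#' gene-dropping. Within each seeded IBD region every case is made
#' homozygous for one shared founder haplotype and every parent of a case
#' a strict heterozygous carrier of it, which is the genotype pattern the
#' downstream homozygosity mapping searches for. If `mz_twin_pair`, the
#' two twin case call vectors are identical at every marker (including
#' missingness). Deterministic given `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `pedigree` (see [make_pedigree()]) and
#'   `geno` (genotype matrix tibble, see [geno_samples()]).
#' @export
simulate_pedigree_genotypes <- function(config) {
  validate_sim_config(config)
  ped <- make_pedigree(config)
  withr::with_seed(.derive_seed(config, "genotypes"), {
    markers <- .make_markers(config)
    n <- nrow(markers)

    regions <- config$seeded_ibd_regions
    region_idx <- purrr::pmap(regions, function(chrom, start, end, ...) {
      idx <- .markers_in_region(markers, chrom, start, end)
      if (length(idx) == 0) {
        abort(paste0("seeded region ", chrom, ":", start, "-", end,
                     " too small to contain any marker"))
      }
      idx
    })

    founders <- ped$id[is.na(ped$sire)]
    haps <- list()
    for (f in founders) {
      haps[[f]] <- cbind(rbinom(n, 1, config$maf), rbinom(n, 1, config$maf))
    }
    # seeded regions: founder parents become strict het carriers of the
    # shared haplotype h
    shared_h <- vector("list", length(region_idx))
    for (r in seq_along(region_idx)) {
      idx <- region_idx[[r]]
      h <- rbinom(length(idx), 1, config$maf)
      shared_h[[r]] <- h
      for (f in founders) {
        haps[[f]][idx, 1] <- h
        haps[[f]][idx, 2] <- 1L - h
      }
    }

    drop_child <- function(sire, dam) {
      cbind(
        haps[[sire]][cbind(seq_len(n), 1L + rbinom(n, 1, 0.5))],
        haps[[dam]][cbind(seq_len(n), 1L + rbinom(n, 1, 0.5))]
      )
    }
    kids <- ped$id[!is.na(ped$sire)]
    for (k in kids) {
      row <- ped[ped$id == k, ]
      if (k == "CASE2" && config$mz_twin_pair) {
        haps[[k]] <- haps[["CASE1"]]
      } else {
        haps[[k]] <- drop_child(row$sire, row$dam)
      }
    }
    # cases autozygous for the shared haplotype in every seeded region
    for (r in seq_along(region_idx)) {
      idx <- region_idx[[r]]
      for (k in ped$id[ped$status == "affected"]) {
        haps[[k]][idx, 1] <- shared_h[[r]]
        haps[[k]][idx, 2] <- shared_h[[r]]
      }
    }

    geno <- markers
    codes <- c("AA", "AB", "BB")
    for (s in ped$id) {
      g <- codes[haps[[s]][, 1] + haps[[s]][, 2] + 1L]
      g[runif(n) < config$missing_rate] <- NA
      geno[[s]] <- g
    }
    if (config$mz_twin_pair) geno[["CASE2"]] <- geno[["CASE1"]]
  })
  list(pedigree = ped, geno = geno)
}

# ---------------------------------------------------------------------------
# transcript fixture

.NONSTOP_CODONS <- NULL

.nonstop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# random open reading frame of n_aa residues plus terminal stop
.random_orf <- function(n_aa) {
  pool <- .nonstop_codons()
  paste0("ATG", paste(sample(pool, n_aa - 1, replace = TRUE), collapse = ""), "TAA")
}

#' Build the transcript/gene-model fixture
#'
#' Emits one target gene with two transcripts that share all downstream
#' exons but differ in their first exon (so a single genomic variant maps
#' to two distinct cDNA coordinates, 99 nt apart), plus a set of
#' single-transcript background genes tiled over the genome. The target
#' CDS is constructed so that a specific 1-bp deletion, 3'-normalized,
#' sits at the last base of a codon, leaves that codon's residue intact,
#' substitutes a valine for the following serine and hits a new-frame stop
#' nine codons in (a `p.Ser...Valfs9*` pattern on both transcripts), with
#' the two C-terminal protein domains lying entirely beyond the truncated
#' protein. Each target protein carries three named domains.
#'
#' @param config A [sim_config()].
#' @return List of class `transcript_fixture` with elements `transcripts`
#'   (tibble: `transcript_id`, `gene_id`, `chrom`, `strand`, list-columns
#'   `exon_start`/`exon_end` of CDS segments in genomic 1-based inclusive
#'   coordinates ordered 5'->3', `cds_seq`, `protein_length`), `domains`
#'   (tibble: `transcript_id`, `domain`, `aa_start`, `aa_end`) and
#'   `causal` (one-row variant tibble: the anchored 1-bp deletion).
#' @export
make_transcript_fixture <- function(config) {
  validate_sim_config(config)
  withr::with_seed(.derive_seed(config, "fixture"), {
    region1 <- config$seeded_ibd_regions[1, ]
    g0 <- as.integer(region1$start + floor((region1$end - region1$start) * 0.32))

    # target CDS, transcript A: 881 aa + stop = 2646 nt
    a_cds <- .random_orf(881)
    substr(a_cds, 1879, 1884) <- "TCGAGT"      # codon 627 Ser(TCG), 628 Ser(AGT)
    substr(a_cds, 1885, 1885) <- "T"
    for (p in 1886:1906) {
      substr(a_cds, p, p) <- if ((p - 1886) %% 3 == 0) "G" else "T"
    }
    substr(a_cds, 1907, 1911) <- "TAACA"       # new-frame stop; old frame TTA/ACA
    stopifnot(nchar(a_cds) == 2646)
    # transcript B: alternative 51-nt first exon, shared tail from A pos 151
    exon1b <- substr(.random_orf(17), 1, 51)    # ATG + 16 non-stop codons
    b_cds <- paste0(exon1b, substr(a_cds, 151, 2646))
    stopifnot(nchar(b_cds) == 2547)

    prot_a <- .translate_chr(a_cds)
    prot_b <- .translate_chr(b_cds)
    stopifnot(
      substr(prot_a, 882, 882) == "*", !grepl("\\*", substr(prot_a, 1, 881)),
      substr(prot_b, 849, 849) == "*", !grepl("\\*", substr(prot_b, 1, 848))
    )

    shared_w <- c(300L, 280L, 260L, 300L, 250L, 240L, 300L, 286L, 280L)
    shared_starts <- g0 + 10000L +
      cumsum(c(0L, utils::head(shared_w + 500L, -1)))
    tr <- tibble(
      transcript_id = c("geneT-201", "geneT-202"),
      gene_id = "geneT",
      chrom = region1$chrom,
      strand = "+",
      exon_start = list(c(g0, shared_starts), c(g0 + 5000L, shared_starts)),
      exon_end = list(
        c(g0 + 149L, shared_starts + shared_w - 1L),
        c(g0 + 5050L, shared_starts + shared_w - 1L)
      ),
      cds_seq = c(a_cds, b_cds),
      protein_length = c(881L, 848L)
    )

    domains <- bind_rows(
      tibble(transcript_id = "geneT-201",
             domain = c("AAT", "MBB", "MOSC"),
             aa_start = c(50L, 640L, 780L), aa_end = c(480L, 760L, 860L)),
      tibble(transcript_id = "geneT-202",
             domain = c("AAT", "MBB", "MOSC"),
             aa_start = c(17L, 607L, 747L), aa_end = c(447L, 727L, 827L))
    )

    # background genes: 2 exons (300 + 150 nt CDS), alternating strand
    gl <- config$genome_layout
    n_bg <- config$n_background_genes
    n_by_chrom <- pmax(0L, round(n_bg * gl$length / sum(gl$length)))
    bg <- list()
    k <- 0L
    for (i in seq_len(nrow(gl))) {
      for (j in seq_len(n_by_chrom[i])) {
        k <- k + 1L
        gs <- as.integer(round(gl$length[i] * (j - 0.5) / n_by_chrom[i]))
        if (gs >= g0 - 2000L && gs <= g0 + 20000L &&
            gl$chrom[i] == region1$chrom) {
          gs <- gs + 25000L   # keep clear of the target gene
        }
        strand <- if (k %% 2 == 0) "-" else "+"
        cds <- .random_orf(149)                 # 450 nt
        ex_s <- c(gs, gs + 700L)
        ex_e <- c(gs + 299L, gs + 849L)
        if (strand == "-") {                    # 5'->3' is descending genomic
          ex_s2 <- c(gs + 550L, gs)
          ex_e2 <- c(gs + 849L, gs + 149L)
          ex_s <- ex_s2; ex_e <- ex_e2
        }
        bg[[k]] <- tibble(
          transcript_id = sprintf("bg%02d-201", k), gene_id = sprintf("bg%02d", k),
          chrom = gl$chrom[i], strand = strand,
          exon_start = list(ex_s), exon_end = list(ex_e),
          cds_seq = cds, protein_length = 149L
        )
      }
    }
    if (length(bg) > 0) {
      bg <- bind_rows(bg)
      tr <- bind_rows(tr, bg)
      domains <- bind_rows(
        domains,
        tibble(transcript_id = bg$transcript_id, domain = "DOM",
               aa_start = 20L, aa_end = 120L)
      )
    }

    # causal 1-bp deletion: cDNA c.1881 on transcript A, anchored VCF form
    gpos <- cdna_to_genomic(tr[tr$transcript_id == "geneT-201", ], 1881L)
    anchor <- cdna_to_genomic(tr[tr$transcript_id == "geneT-201", ], 1880L)
    stopifnot(anchor == gpos - 1L)
    causal <- tibble(
      chrom = region1$chrom, pos = as.integer(anchor),
      ref = paste0(substr(a_cds, 1880, 1880), substr(a_cds, 1881, 1881)),
      alt = substr(a_cds, 1880, 1880)
    )
    # the causal interval must sit inside exactly one seeded region
    hits <- sum(config$seeded_ibd_regions$chrom == causal$chrom &
                  config$seeded_ibd_regions$start < causal$pos &
                  causal$pos + 1 <= config$seeded_ibd_regions$end)
    if (hits != 1) abort("causal variant is not inside exactly one seeded IBD region")
  })
  structure(list(transcripts = tr, domains = domains, causal = causal),
            class = "transcript_fixture")
}

# ---------------------------------------------------------------------------
# variant cohort

# genomic base at a position covered by a transcript's CDS
.genomic_base <- function(tr_row, gpos) {
  cpos <- project_to_cdna(tr_row, gpos)
  base <- substr(tr_row$cds_seq, cpos, cpos)
  if (tr_row$strand == "-") base <- chartr("ACGT", "TGCA", base)
  base
}

#' Simulate the case/control/population variant cohorts
#'
#' Scatters background coding SNVs over the CDS of the supplied gene
#' models with configurable sharing across the control cohort and the
#' population-database site list, seeds the causal 1-bp coding deletion
#' (hom-alt in every case, het in every carrier parent, absent from all
#' control genomes and from the population database), and draws the
#' population-control genotype table in which `carrier_fraction` of
#' controls are heterozygous carriers and none is homozygous alternate.
#' Deterministic given `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param fixture A `transcript_fixture` from [make_transcript_fixture()].
#' @return List of class `variant_cohort`: `case_variants` (variant tibble
#'   with one dosage column `CASE1`), `control_variants` (variant tibble,
#'   one dosage column per control genome; only sites carried by at least
#'   one control), `popdb_sites` (tibble `chrom`, `pos`, `ref`, `alt`),
#'   `population_genotypes` (tibble `sample`, `group`, `genotype`) and
#'   `causal` (the seeded deletion).
#' @export
simulate_variant_cohort <- function(config, fixture) {
  validate_sim_config(config)
  tr <- fixture$transcripts
  causal <- fixture$causal

  # the causal deleted base must be coding in at least one transcript
  del_pos <- causal$pos + 1L
  in_cds <- purrr::pmap_lgl(tr, function(chrom, exon_start, exon_end, ...) {
    chrom == causal$chrom && any(del_pos >= exon_start & del_pos <= exon_end)
  })
  if (!any(in_cds)) abort("causal variant does not fall in any CDS")

  withr::with_seed(.derive_seed(config, "cohort"), {
    # pool of coding genomic positions (unique across transcripts)
    pool <- purrr::pmap_dfr(tr, function(transcript_id, chrom, exon_start,
                                         exon_end, ...) {
      tibble(chrom = chrom, gpos = unlist(purrr::map2(exon_start, exon_end, seq)),
             transcript_id = transcript_id)
    }) |>
      distinct(.data$chrom, .data$gpos, .keep_all = TRUE)

    n_bg <- min(config$n_background_coding_variants, nrow(pool))
    bases <- c("A", "C", "G", "T")
    if (n_bg > 0) {
      picked <- pool[sort(sample(nrow(pool), n_bg)), ]
      ref <- character(nrow(picked))
      for (tid in unique(picked$transcript_id)) {
        trr <- tr[tr$transcript_id == tid, ]
        sel <- which(picked$transcript_id == tid)
        cpos <- project_to_cdna(trr, picked$gpos[sel])
        b <- substring(trr$cds_seq, cpos, cpos)
        if (trr$strand == "-") b <- chartr("ACGT", "TGCA", b)
        ref[sel] <- b
      }
      alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
      bg <- tibble(chrom = picked$chrom, pos = as.integer(picked$gpos),
                   ref = ref, alt = alt)
      bg$case_dosage <- ifelse(runif(n_bg) < config$case_hom_fraction, 2L, 1L)
      bg$in_controls <- runif(n_bg) < config$control_sharing
      bg$in_popdb <- runif(n_bg) < config$popdb_sharing
    } else {
      bg <- tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), case_dosage = integer(),
                   in_controls = logical(), in_popdb = logical())
    }

    case_variants <- bind_rows(
      bg |> select(all_of(.variant_key)) |> mutate(CASE1 = bg$case_dosage),
      causal |> mutate(CASE1 = 2L)
    ) |> arrange(.data$chrom, .data$pos, .data$alt)

    ctrl_ids <- sprintf("CTRL%03d", seq_len(config$n_control_genomes))
    shared <- bg[bg$in_controls, ]
    if (nrow(shared) > 0) {
      gmat <- matrix(0L, nrow(shared), length(ctrl_ids),
                     dimnames = list(NULL, ctrl_ids))
      for (i in seq_len(nrow(shared))) {
        n_carr <- 1L + rbinom(1, 4, 0.4)
        carriers <- sample(length(ctrl_ids), min(n_carr, length(ctrl_ids)))
        gmat[i, carriers] <- sample(c(1L, 2L), length(carriers),
                                    replace = TRUE, prob = c(0.8, 0.2))
      }
      control_variants <- bind_cols(
        shared |> select(all_of(.variant_key)),
        as_tibble(gmat)
      ) |> arrange(.data$chrom, .data$pos, .data$alt)
    } else {
      control_variants <- bind_cols(
        tibble(chrom = character(), pos = integer(),
               ref = character(), alt = character()),
        as_tibble(matrix(integer(), 0, length(ctrl_ids),
                         dimnames = list(NULL, ctrl_ids)))
      )
    }

    popdb_sites <- bg[bg$in_popdb, .variant_key] |>
      arrange(.data$chrom, .data$pos, .data$alt)

    ped <- make_pedigree(config)
    carriers <- setdiff(unique(stats::na.omit(c(
      ped$sire[ped$status == "affected"], ped$dam[ped$status == "affected"]
    ))), NA)
    popn <- config$n_population_controls
    pop_gt <- ifelse(runif(popn) < config$carrier_fraction, "het", "hom-ref")
    n_other <- config$n_control_genomes + config$n_popdb_genomes
    population_genotypes <- bind_rows(
      tibble(sample = ped$id[ped$status == "affected"],
             group = "affected", genotype = "hom-alt"),
      tibble(sample = carriers, group = "obligate_carriers", genotype = "het"),
      tibble(sample = sprintf("POP%04d", seq_len(popn)),
             group = "population_controls", genotype = pop_gt),
      tibble(sample = sprintf("OB%04d", seq_len(n_other)),
             group = "other_breeds", genotype = "hom-ref")
    )
  })
  structure(list(case_variants = case_variants,
                 control_variants = control_variants,
                 popdb_sites = popdb_sites,
                 population_genotypes = population_genotypes,
                 causal = causal),
            class = "variant_cohort")
}
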