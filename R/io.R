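#' Write genotypes as PLINK text PED/MAP
#'
#' White-space separated, alleles as A/C/G/T, missing coded 0. Phenotype
#' is 2 for affected, 1 for unaffected, 0 for unknown.
#'
#' @param geno Genotype matrix tibble.
#' @param pedigree Pedigree tibble.
#' @param prefix Output path prefix (writes `<prefix>.ped`,
#'   `<prefix>.map`).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, pedigree, prefix) {
  .assert_geno(geno, pedigree$id)
  map <- sprintf("%s %s 0 %d", geno$chrom,
                 paste0(geno$chrom, "_", geno$pos), geno$pos)
  writeLines(map, paste0(prefix, ".map"))

  sexcode <- c(male = 1L, female = 2L)
  phecode <- c(affected = 2L, unaffected = 1L, unknown = 0L)
  lines <- vapply(seq_len(nrow(pedigree)), function(i) {
    s <- pedigree$id[i]
    g <- geno[[s]]
    a1 <- ifelse(is.na(g), "0", ifelse(g == "BB", geno$allele_b, geno$allele_a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == "AA", geno$allele_a, geno$allele_b))
    paste("FAM1", s,
          ifelse(is.na(pedigree$sire[i]), "0", pedigree$sire[i]),
          ifelse(is.na(pedigree$dam[i]), "0", pedigree$dam[i]),
          sexcode[[pedigree$sex[i]]], phecode[[pedigree$status[i]]],
          paste(a1, a2, collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK text PED/MAP
#'
#' Marker alleles are recovered from the observed calls (alphabetical
#' order; a monomorphic marker gets `allele_b = "N"`).
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return List `pedigree`, `geno` as in [simulate_pedigree_genotypes()].
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped_raw <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  n_mark <- nrow(map)
  stopifnot(ncol(ped_raw) == 6 + 2 * n_mark)

  sexes <- c("1" = "male", "2" = "female", "0" = "unknown")
  phes <- c("2" = "affected", "1" = "unaffected", "0" = "unknown")
  pedigree <- tibble(
    id = ped_raw[[2]],
    sire = ifelse(ped_raw[[3]] == "0", NA, ped_raw[[3]]),
    dam = ifelse(ped_raw[[4]] == "0", NA, ped_raw[[4]]),
    sex = unname(sexes[ped_raw[[5]]]),
    status = unname(phes[ped_raw[[6]]])
  )

  a1 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_mark) - 1, drop = FALSE])
  a2 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_mark), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  alleles <- purrr::map(seq_len(n_mark), function(j) {
    sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
  })
  allele_a <- purrr::map_chr(alleles, function(a) if (length(a) >= 1) a[1] else "N")
  allele_b <- purrr::map_chr(alleles, function(a) if (length(a) >= 2) a[2] else "N")

  geno <- tibble(chrom = map$chrom, pos = map$pos,
                 allele_a = allele_a, allele_b = allele_b)
  for (i in seq_len(nrow(pedigree))) {
    x1 <- unname(a1[i, ]); x2 <- unname(a2[i, ])
    call <- ifelse(is.na(x1) | is.na(x2), NA_character_,
                   ifelse(x1 == x2,
                          ifelse(x1 == allele_a, "AA", "BB"),
                          "AB"))
    geno[[pedigree$id[i]]] <- call
  }
  list(pedigree = pedigree, geno = geno)
}

.dosage_to_gt <- function(d) {
  ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
}

#' Write a variant table as VCF v4.2
#'
#' Deterministic formatter (no dates), GT-only.
#'
#' @param variants Variant tibble (dosage columns per sample).
#' @param path Output path.
#' @param contigs Optional tibble `chrom`, `length` for contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  .assert_variant_tbl(variants)
  samples <- variant_samples(variants)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=autozyg")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$chrom, as.integer(contigs$length)))
  }
  hdr <- c(hdr,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  v <- arrange(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  gt_cols <- purrr::map(samples, function(s) .dosage_to_gt(v[[s]]))
  body <- do.call(paste, c(
    list(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", ".", "GT"),
    gt_cols, sep = "\t"
  ))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses with `VariantAnnotation::readVcf` and converts GT fields to
#' allele dosages; multi-allelic records are decomposed into biallelic
#' rows (the dosage of each row counts that alternate allele).
#'
#' @param path VCF path.
#' @return Variant tibble.
#' @export
read_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  gt <- VariantAnnotation::geno(v)$GT
  alts <- VariantAnnotation::alt(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(v))
  samples <- colnames(gt)

  rows <- list()
  for (i in seq_len(nrow(gt))) {
    a <- as.character(alts[[i]])
    parts <- strsplit(gt[i, , drop = TRUE], "[/|]")
    for (j in seq_along(a)) {
      dos <- unname(purrr::map_int(parts, function(p) {
        if (any(p == ".")) return(NA_integer_)
        sum(p == as.character(j))
      }))
      row <- tibble(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = a[j])
      for (k in seq_along(samples)) row[[samples[k]]] <- dos[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
    for (s in samples) out[[s]] <- integer()
    return(out)
  }
  bind_rows(rows)
}

#' Write genomic intervals as BED
#'
#' Intervals are stored 0-based half-open, matching BED directly.
#'
#' @param regions Tibble `chrom`, `start`, `end` (plus optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name
        else paste0("region", seq_len(nrow(regions)))
  df <- data.frame(chrom = regions$chrom, start = as.integer(regions$start),
                   end = as.integer(regions$end), name = nm)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end`, `name` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         name = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' Write gene models as GFF3 plus a CDS FASTA
#'
#' Emits gene / mRNA / CDS features; exon intervals are the CDS segments
#' of each transcript. The FASTA holds each transcript's CDS sequence.
#'
#' @param transcripts Transcript tibble.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, `gff_path`.
#' @export
write_gene_models <- function(transcripts, gff_path, fasta_path) {
  feats <- purrr::pmap_dfr(transcripts, function(transcript_id, gene_id, chrom,
                                                 strand, exon_start, exon_end,
                                                 ...) {
    bind_rows(
      tibble(chrom = chrom, start = min(exon_start), end = max(exon_end),
             strand = strand, type = "mRNA", ID = transcript_id,
             Parent = gene_id),
      tibble(chrom = chrom, start = exon_start, end = exon_end,
             strand = strand, type = "CDS",
             ID = paste0(transcript_id, ".cds", seq_along(exon_start)),
             Parent = transcript_id,
             # GFF3 phase: bases to skip before the first full codon
             phase = as.integer((3L - cumsum(c(0L, utils::head(
               exon_end - exon_start + 1L, -1L))) %% 3L) %% 3L))
    )
  })
  genes <- feats |>
    filter(.data$type == "mRNA") |>
    group_by(chrom = .data$chrom, ID = .data$Parent) |>
    summarise(start = min(.data$start), end = max(.data$end),
              strand = dplyr::first(.data$strand), .groups = "drop") |>
    mutate(type = "gene", Parent = NA_character_)
  feats <- bind_rows(genes, feats) |>
    arrange(.data$chrom, .data$start, factor(.data$type, c("gene", "mRNA", "CDS")))

  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand, type = feats$type, ID = feats$ID,
    Parent = ifelse(is.na(feats$Parent), NA, feats$Parent),
    phase = feats$phase
  )
  rtracklayer::export(gr, gff_path, format = "gff3")

  seqs <- Biostrings::DNAStringSet(setNames(transcripts$cds_seq,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(gff_path)
}

#' Read gene models from GFF3 plus a CDS FASTA
#'
#' @param gff_path GFF3 path written by [write_gene_models()] (or any GFF3
#'   with mRNA/CDS features and `Parent` attributes).
#' @param fasta_path FASTA of CDS sequences named by transcript id.
#' @return Transcript tibble.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cds <- gr[gr$type == "CDS"]
  parent <- vapply(cds$Parent, function(x) x[1], character(1))
  mrna <- gr[gr$type == "mRNA"]
  gene_of <- setNames(vapply(mrna$Parent, function(x) x[1], character(1)),
                      as.character(mrna$ID))

  tibble(
    transcript_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  ) |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = unname(gene_of[dplyr::first(.data$transcript_id)]),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      exon_start = list(if (dplyr::first(.data$strand) == "-")
        rev(.data$start) else .data$start),
      exon_end = list(if (dplyr::first(.data$strand) == "-")
        rev(.data$end) else .data$end),
      .groups = "drop"
    ) |>
    mutate(
      cds_seq = unname(as.character(seqs[.data$transcript_id])),
      protein_length = nchar(.data$cds_seq) %/% 3L - 1L
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand",
           "exon_start", "exon_end", "cds_seq", "protein_length")
}

#' Write / read the protein-domain table
#'
#' @param domains Tibble `transcript_id`, `domain`, `aa_start`, `aa_end`.
#' @param path TSV path.
#' @return `path` / the tibble.
#' @export
write_domains <- function(domains, path) {
  readr::write_tsv(domains, path)
  invisible(path)
}

#' @rdname write_domains
#' @export
read_domains <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    transcript_id = "c", domain = "c",
                    aa_start = "i", aa_end = "i"
                  ))
}
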