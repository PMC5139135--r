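#' Normalize variant representation for cross-cohort comparison
#'
#' Decomposes multi-allelic records into biallelic site-allele pairs and
#' applies parsimony trimming (shared suffix, then shared prefix with the
#' position advanced) so that the same event is keyed identically in every
#' cohort. The same normalization is applied to all cohorts before any
#' set comparison.
#'
#' @param variants Variant tibble (`alt` may contain comma-separated
#'   alleles; per-sample dosages, if present, are carried through —
#'   multi-allelic dosages count any alternate allele).
#' @return Normalized variant tibble.
#' @export
normalize_variants <- function(variants) {
  .assert_variant_tbl(variants)
  v <- if (any(grepl(",", variants$alt, fixed = TRUE))) {
    tidyr::separate_rows(variants, "alt", sep = ",")
  } else {
    variants
  }
  todo <- which(nchar(v$ref) > 1 & nchar(v$alt) > 1)
  for (i in todo) {
    pos <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    # shared suffix
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
    }
    # shared prefix
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    v$pos[i] <- pos; v$ref[i] <- ref; v$alt[i] <- alt
  }
  arrange(v, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Select coding variants of a given zygosity in the index case
#'
#' Keeps variants whose reference span intersects a CDS exon of at least
#' one transcript and whose genotype in the index case matches the
#' requested zygosity. Variants on chromosomes absent from the transcript
#' set are excluded with a warning. Sites are deduplicated.
#'
#' @param variants Variant tibble.
#' @param transcripts Transcript tibble.
#' @param zygosity `"hom-alt"` or `"het"`.
#' @param case_sample Index-case sample column (default the first sample
#'   column).
#' @return Filtered variant tibble.
#' @export
select_coding_by_zygosity <- function(variants, transcripts,
                                      zygosity = c("hom-alt", "het"),
                                      case_sample = NULL) {
  .assert_variant_tbl(variants)
  zygosity <- match.arg(zygosity)
  if (nrow(variants) == 0) return(variants)
  case_sample <- case_sample %||% variant_samples(variants)[1]

  known <- unique(transcripts$chrom)
  bad <- !(variants$chrom %in% known)
  if (any(bad)) {
    warn(paste0(sum(bad), " variant(s) on chromosome(s) unknown to the ",
                "transcript set were excluded: ",
                paste(unique(variants$chrom[bad]), collapse = ", ")))
    variants <- variants[!bad, ]
  }

  want <- if (zygosity == "hom-alt") 2L else 1L
  variants <- variants[!is.na(variants[[case_sample]]) &
                         variants[[case_sample]] == want, ]
  if (nrow(variants) == 0) return(variants)

  cds <- tibble(
    chrom = rep(transcripts$chrom, lengths(transcripts$exon_start)),
    start = unlist(transcripts$exon_start),
    end = unlist(transcripts$exon_end)
  )
  cds_gr <- GenomicRanges::GRanges(cds$chrom, IRanges::IRanges(cds$start, cds$end))
  v_gr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L)
  )
  hit <- IRanges::overlapsAny(v_gr, cds_gr)
  distinct(variants[hit, ], across(all_of(.variant_key)), .keep_all = TRUE)
}

#' Triage step I: restrict to candidate autozygous regions
#'
#' Keeps variants whose position lies inside a candidate region (regions
#' are 0-based half-open; a variant at the first base of a region is
#' kept, one base before is dropped).
#'
#' @param variants Variant tibble.
#' @param regions Region tibble with `chrom`, `start`, `end`.
#' @return Filtered variant tibble.
#' @export
filter_step1_regions <- function(variants, regions) {
  .assert_variant_tbl(variants)
  if (nrow(variants) == 0 || nrow(regions) == 0) return(variants[0, ])
  r_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)
  )
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
  variants[IRanges::overlapsAny(v_gr, r_gr), ]
}

# sites (chrom,pos,ref,alt) at which any sample carries the alternate allele
.observed_sites <- function(cohort) {
  s <- variant_samples(cohort)
  if (length(s) == 0) return(cohort[, .variant_key])
  carried <- rowSums(as.matrix(cohort[, s, drop = FALSE]) >= 1,
                     na.rm = TRUE) > 0
  cohort[carried, .variant_key]
}

#' Triage step II: remove variants observed in the control cohort
#'
#' Drops any variant whose alternate allele is carried (het or hom-alt)
#' by at least one control genome. Matching is allele-aware on the
#' normalized `(chrom, pos, ref, alt)` key.
#'
#' @param variants Variant tibble.
#' @param control_cohort Control variant tibble (dosage columns per
#'   control genome; rows with no carrier are ignored).
#' @return Filtered variant tibble.
#' @export
filter_step2_controls <- function(variants, control_cohort) {
  .assert_variant_tbl(variants)
  if (nrow(variants) == 0) return(variants)
  seen <- .observed_sites(normalize_variants(control_cohort))
  anti_join(normalize_variants(variants), seen, by = .variant_key)
}

#' Triage step III: remove variants present in the population database
#'
#' @param variants Variant tibble.
#' @param popdb_sites Site list tibble with `chrom`, `pos`, `ref`, `alt`.
#' @return Filtered variant tibble.
#' @export
filter_step3_popdb <- function(variants, popdb_sites) {
  .assert_variant_tbl(variants)
  if (nrow(variants) == 0) return(variants)
  sites <- normalize_variants(popdb_sites)[, .variant_key]
  anti_join(normalize_variants(variants), sites, by = .variant_key)
}

#' Keep protein-changing (non-synonymous) variants
#'
#' Retains variants whose predicted consequence on at least one
#' transcript is missense, stop-gain, stop-loss, frameshift or in-frame
#' indel. Synonymous and non-coding variants are dropped; splice-boundary
#' disruption is carried as a flag by [annotate_variants()] but not
#' counted as non-synonymous.
#'
#' @param variants Variant tibble.
#' @param transcripts Transcript tibble.
#' @return Filtered variant tibble.
#' @export
select_nonsynonymous <- function(variants, transcripts) {
  .assert_variant_tbl(variants)
  if (nrow(variants) == 0) return(variants)
  ann <- annotate_variants(variants, transcripts)
  keep_keys <- ann |>
    filter(.data$category %in%
             c("missense", "stop-gain", "stop-loss", "frameshift",
               "inframe-indel")) |>
    distinct(across(all_of(.variant_key)))
  semi_join(variants, keep_keys, by = .variant_key)
}

.new_funnel <- function(branch, stages, case_sample) {
  structure(
    list(branch = branch,
         stages = tibble(stage = names(stages),
                         n = unname(purrr::map_int(stages, nrow))),
         variants = stages,
         case_sample = case_sample),
    class = "triage_funnel"
  )
}

#' Recessive branch of the private-variant triage
#'
#' The triple-step private-variant filter under the recessive hypothesis:
#' homozygous coding variants in the index case, restricted to the
#' candidate autozygous regions (step I), then stripped of variants seen
#' in the control cohort (step II) and in the population database
#' (step III), and finally reduced to protein-changing variants.
#'
#' @param variants Case variant tibble.
#' @param transcripts Transcript tibble.
#' @param regions Candidate region tibble.
#' @param controls Control cohort variant tibble.
#' @param popdb Population-database site tibble.
#' @param case_sample Index-case sample column.
#' @return A `triage_funnel` object; `tidy()` gives per-stage counts.
#' @export
recessive_branch <- function(variants, transcripts, regions, controls, popdb,
                             case_sample = NULL) {
  case_sample <- case_sample %||% variant_samples(variants)[1]
  s0 <- select_coding_by_zygosity(variants, transcripts, "hom-alt", case_sample)
  s1 <- filter_step1_regions(s0, regions)
  s2 <- filter_step2_controls(s1, controls)
  s3 <- filter_step3_popdb(s2, popdb)
  s4 <- select_nonsynonymous(s3, transcripts)
  .new_funnel("recessive",
              list(coding_hom = s0, in_ibd_regions = s1,
                   not_in_controls = s2, not_in_popdb = s3,
                   nonsynonymous = s4),
              case_sample)
}

#' Dominant (de novo) branch of the private-variant triage
#'
#' Parallel branch for the heterozygous de-novo hypothesis: heterozygous
#' coding variants in the index case filtered against the control cohort
#' and the population database (no region restriction), then reduced to
#' protein-changing variants.
#'
#' @inheritParams recessive_branch
#' @return A `triage_funnel` object.
#' @export
dominant_branch <- function(variants, transcripts, controls, popdb,
                            case_sample = NULL) {
  case_sample <- case_sample %||% variant_samples(variants)[1]
  s0 <- select_coding_by_zygosity(variants, transcripts, "het", case_sample)
  s2 <- filter_step2_controls(s0, controls)
  s3 <- filter_step3_popdb(s2, popdb)
  s4 <- select_nonsynonymous(s3, transcripts)
  .new_funnel("dominant",
              list(coding_het = s0, not_in_controls = s2,
                   not_in_popdb = s3, nonsynonymous = s4),
              case_sample)
}

#' @export
print.triage_funnel <- function(x, ...) {
  cat(sprintf("<triage_funnel: %s branch, case %s>\n", x$branch, x$case_sample))
  print(x$stages)
  invisible(x)
}

#' Per-stage counts of a triage funnel
#'
#' @param x A `triage_funnel`.
#' @param ... Unused.
#' @return Tibble `branch`, `stage`, `n`.
#' @export
tidy.triage_funnel <- function(x, ...) {
  mutate(x$stages, branch = x$branch, .before = 1)
}

#' One-row summary of a triage funnel
#'
#' @param x A `triage_funnel`.
#' @param ... Unused.
#' @return Tibble `branch`, `n_input`, `n_final`, `n_stages`.
#' @export
glance.triage_funnel <- function(x, ...) {
  tibble(branch = x$branch,
         n_input = x$stages$n[1],
         n_final = x$stages$n[nrow(x$stages)],
         n_stages = nrow(x$stages))
}

#' Final candidate list of a funnel
#'
#' @param funnel A `triage_funnel`.
#' @return Variant tibble of the last stage.
#' @export
funnel_candidates <- function(funnel) {
  funnel$variants[[length(funnel$variants)]]
}
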