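#' Project genomic positions onto a transcript's CDS
#'
#' Maps genomic coordinates through the transcript's ordered exon chain,
#' honoring strand (on the minus strand CDS coordinates run against the
#' genome). Positions outside every CDS exon map to `NA`.
#'
#' @param transcript One-row transcript tibble (see
#'   [make_transcript_fixture()] for the layout).
#' @param gpos Integer vector of genomic positions (1-based).
#' @return Integer vector of CDS positions (1-based), `NA` where
#'   non-coding.
#' @export
project_to_cdna <- function(transcript, gpos) {
  stopifnot(nrow(transcript) == 1)
  .project_pos(transcript$exon_start[[1]], transcript$exon_end[[1]],
               transcript$strand, gpos)
}

.project_pos <- function(es, ee, strand, gpos) {
  w <- ee - es + 1L
  cum <- cumsum(c(0L, w))[seq_along(w)]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(es)) {
    hit <- !is.na(gpos) & gpos >= es[i] & gpos <= ee[i]
    if (strand == "+") {
      out[hit] <- cum[i] + (gpos[hit] - es[i]) + 1L
    } else {
      out[hit] <- cum[i] + (ee[i] - gpos[hit]) + 1L
    }
  }
  out
}

#' Inverse of [project_to_cdna()]
#'
#' @param transcript One-row transcript tibble.
#' @param cpos Integer vector of CDS positions (1-based).
#' @return Integer vector of genomic positions; `NA` beyond the CDS.
#' @export
cdna_to_genomic <- function(transcript, cpos) {
  stopifnot(nrow(transcript) == 1)
  es <- transcript$exon_start[[1]]
  ee <- transcript$exon_end[[1]]
  w <- ee - es + 1L
  cum <- cumsum(c(0L, w))
  out <- rep(NA_integer_, length(cpos))
  for (i in seq_along(es)) {
    hit <- !is.na(cpos) & cpos > cum[i] & cpos <= cum[i + 1L]
    off <- cpos[hit] - cum[i] - 1L
    out[hit] <- if (transcript$strand == "+") es[i] + off else ee[i] - off
  }
  out
}

#' 3'-normalize a deletion within a CDS
#'
#' Shifts a deletion to the most 3' position that yields an identical
#' edited sequence (the HGVS convention), so that c. names are stable.
#' Idempotent, and never changes the edited nucleotide string.
#'
#' @param cds CDS sequence (character scalar, ACGT).
#' @param del_start 1-based first deleted position.
#' @param del_len Deletion length in nt.
#' @return The shifted `del_start`.
#' @export
normalize_3prime <- function(cds, del_start, del_len = 1L) {
  n <- nchar(cds)
  stopifnot(del_start >= 1, del_start + del_len - 1 <= n)
  s <- strsplit(cds, "")[[1]]
  while (del_start + del_len <= n &&
         s[del_start] == s[del_start + del_len]) {
    del_start <- del_start + 1L
  }
  del_start
}

.aa_at <- function(prot, k) substr(prot, k, k)

#' Predict the protein-level effect of a CDS edit
#'
#' Applies the edit to the CDS, translates, and classifies the result.
#' Deletions are 3'-normalized first. For frameshifts the first altered
#' residue (counting from 1) and the offset of the new stop are reported
#' (`fsN*`: the first changed residue counts as 1, so the new stop is the
#' N-th codon of the shifted frame) and the mutant length is
#' `first_changed + N - 2`. When the first new codon is itself a stop a
#' stop-gain-style `p.Xaa#*` name is emitted. An edited sequence with no
#' downstream stop yields an explicit `no_stop` flag, not an error.
#'
#' @param cds CDS sequence (character scalar over ACGT, length divisible
#'   by 3, single terminal stop).
#' @param edit A list: `list(type = "del", start =, len =)` or
#'   `list(type = "snv", pos =, alt =)`, in CDS coordinates.
#' @return One-row tibble: `category`, `cdna_hgvs`, `protein_hgvs`,
#'   `wt_length`, `mutant_length`, `fraction_lost`, `stop_offset`,
#'   `no_stop`.
#' @export
predict_protein_effect <- function(cds, edit) {
  .check_dna(cds, "CDS")
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  wt_prot <- .translate_chr(cds)
  wt_len <- nchar(wt_prot) - 1L           # strip terminal stop
  if (.aa_at(wt_prot, nchar(wt_prot)) != "*") {
    abort("CDS does not end in a stop codon")
  }

  res <- function(category, cdna_hgvs, protein_hgvs, mutant_length,
                  stop_offset = NA_integer_, no_stop = FALSE) {
    tibble(category = category, cdna_hgvs = cdna_hgvs,
           protein_hgvs = protein_hgvs, wt_length = wt_len,
           mutant_length = as.integer(mutant_length),
           fraction_lost = max(0, (wt_len - mutant_length) / wt_len),
           stop_offset = as.integer(stop_offset), no_stop = no_stop)
  }

  if (edit$type == "snv") {
    p <- edit$pos
    ref <- substr(cds, p, p)
    if (identical(ref, edit$alt)) abort("SNV ref and alt are identical")
    .check_dna(edit$alt, "alt allele")
    cdna <- sprintf("c.%d%s>%s", p, ref, edit$alt)
    k <- (p - 1L) %/% 3L + 1L
    codon <- substr(cds, 3L * k - 2L, 3L * k)
    mcodon <- codon
    substr(mcodon, (p - 1L) %% 3L + 1L, (p - 1L) %% 3L + 1L) <- edit$alt
    x <- .translate_chr(codon)
    y <- .translate_chr(mcodon)
    if (x == y) {
      return(res("synonymous", cdna, sprintf("p.%s%d=", .aa3(x), k), wt_len))
    }
    if (y == "*") {
      return(res("stop-gain", cdna, sprintf("p.%s%d*", .aa3(x), k), k - 1L,
                 stop_offset = 0L))
    }
    if (x == "*") {
      return(res("stop-loss", cdna,
                 sprintf("p.*%d%sext*?", k, .aa3(y)), wt_len))
    }
    return(res("missense", cdna,
               sprintf("p.%s%d%s", .aa3(x), k, .aa3(y)), wt_len))
  }

  if (edit$type != "del") abort("edit$type must be 'snv' or 'del'")
  len <- edit$len
  start <- normalize_3prime(cds, edit$start, len)
  delbases <- substr(cds, start, start + len - 1L)
  cdna <- if (len == 1L) sprintf("c.%ddel%s", start, delbases)
          else sprintf("c.%d_%ddel", start, start + len - 1L)
  edited <- paste0(substr(cds, 1L, start - 1L),
                   substr(cds, start + len, nchar(cds)))
  mut_prot <- .translate_chr(edited)

  wt_chr <- strsplit(wt_prot, "")[[1]]
  mut_chr <- strsplit(mut_prot, "")[[1]]
  m <- min(length(wt_chr), length(mut_chr))
  diffs <- which(wt_chr[seq_len(m)] != mut_chr[seq_len(m)])
  k <- if (length(diffs) > 0) diffs[1] else m + 1L

  if (len %% 3L == 0L) {
    stop_at <- which(mut_chr == "*")
    mut_len <- if (length(stop_at) > 0) stop_at[1] - 1L else length(mut_chr)
    return(res("inframe-indel", cdna,
               sprintf("p.%d_%ddel", k, k + len %/% 3L - 1L), mut_len))
  }

  # frameshift
  if (k > length(mut_chr)) {
    # mutant is a pure prefix of wild type with no stop reached
    return(res("frameshift", cdna,
               sprintf("p.%s%dfs*?", .aa3(wt_chr[min(k, wt_len)]), k),
               length(mut_chr), no_stop = TRUE))
  }
  if (mut_chr[k] == "*") {
    return(res("frameshift", cdna,
               sprintf("p.%s%d*", .aa3(wt_chr[k]), k), k - 1L,
               stop_offset = 1L))
  }
  stop_rel <- which(mut_chr[seq(k, length(mut_chr))] == "*")
  if (length(stop_rel) == 0) {
    return(res("frameshift", cdna,
               sprintf("p.%s%d%sfs*?", .aa3(wt_chr[k]), k, .aa3(mut_chr[k])),
               length(mut_chr), no_stop = TRUE))
  }
  n_off <- stop_rel[1]                     # first changed residue counts as 1
  res("frameshift", cdna,
      sprintf("p.%s%d%sfs%d*", .aa3(wt_chr[k]), k, .aa3(mut_chr[k]), n_off),
      k + n_off - 2L, stop_offset = n_off)
}

#' Truncation and domain-loss statistics for a consequence call
#'
#' @param call One-row tibble from [predict_protein_effect()] (frameshift
#'   or stop-gain).
#' @param domains Tibble `domain`, `aa_start`, `aa_end` for the
#'   transcript's protein.
#' @return List `fraction_lost`, `lost` (domains entirely beyond the
#'   mutant length), `truncated` (domains partially beyond it). A domain
#'   ending exactly at the mutant length is neither lost nor truncated.
#' @export
truncation_stats <- function(call, domains) {
  ml <- call$mutant_length
  list(
    fraction_lost = call$fraction_lost,
    lost = domains$domain[domains$aa_start > ml],
    truncated = domains$domain[domains$aa_start <= ml & domains$aa_end > ml]
  )
}

# derive the CDS-space edit of a genomic variant on one transcript
# (plain-list form: tr has fields chrom, strand, es, ee);
# returns list(kind = "snv"/"del"/"non-coding"/"split-span", ...)
.variant_cds_edit_fast <- function(chrom, pos, ref, alt, tr) {
  if (chrom != tr$chrom) return(list(kind = "non-coding"))
  nref <- nchar(ref)
  nalt <- nchar(alt)
  comp <- function(x) chartr("ACGT", "TGCA", x)

  if (nref == 1L && nalt == 1L) {
    cpos <- .project_pos(tr$es, tr$ee, tr$strand, pos)
    if (is.na(cpos)) return(list(kind = "non-coding"))
    if (tr$strand == "-") alt <- comp(alt)
    return(list(kind = "snv", edit = list(type = "snv", pos = cpos, alt = alt)))
  }
  if (nref > 1L && nalt == 1L && substr(ref, 1L, 1L) == alt) {
    # anchored deletion: deleted genomic bases are pos+1 .. pos+nref-1
    gdel <- seq(pos + 1L, pos + nref - 1L)
    cpos <- .project_pos(tr$es, tr$ee, tr$strand, gdel)
    if (all(is.na(cpos))) return(list(kind = "non-coding"))
    if (any(is.na(cpos))) return(list(kind = "split-span"))
    cpos <- sort(cpos)
    if (!all(diff(cpos) == 1L)) return(list(kind = "split-span"))
    return(list(kind = "del",
                edit = list(type = "del", start = cpos[1], len = length(cpos))))
  }
  # other allele shapes (insertions, MNVs) are not produced by this
  # pipeline's sources; flag rather than guess
  list(kind = "unsupported")
}

.variant_cds_edit <- function(variant, transcript) {
  .variant_cds_edit_fast(
    variant$chrom, variant$pos, variant$ref, variant$alt,
    list(chrom = transcript$chrom, strand = transcript$strand,
         es = transcript$exon_start[[1]], ee = transcript$exon_end[[1]])
  )
}

#' Annotate variants against a transcript set
#'
#' Projects each variant onto every overlapping transcript, names the
#' cDNA and protein change, classifies the consequence, and computes
#' truncation/domain-loss statistics for truncating calls. Variants
#' spanning an exon boundary are flagged (`splice_flag`) and classified
#' `non-coding` rather than counted as protein-changing.
#'
#' @param variants Variant tibble.
#' @param transcripts Transcript tibble (see [make_transcript_fixture()]).
#' @param domains Optional domain tibble (`transcript_id`, `domain`,
#'   `aa_start`, `aa_end`).
#' @return Tibble with one row per variant x overlapping transcript (plus
#'   a single `non-coding` row for variants overlapping none): variant
#'   key, `transcript_id`, `category`, `cdna_hgvs`, `protein_hgvs`,
#'   `wt_length`, `mutant_length`, `fraction_lost`, `stop_offset`,
#'   `no_stop`, `splice_flag`, `lost_domains`, `truncated_domains`.
#' @export
.empty_annotation <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), transcript_id = character(),
         category = character(), cdna_hgvs = character(),
         protein_hgvs = character(), wt_length = integer(),
         mutant_length = integer(), fraction_lost = double(),
         stop_offset = integer(), no_stop = logical(),
         splice_flag = logical(), lost_domains = list(),
         truncated_domains = list())
}

annotate_variants <- function(variants, transcripts, domains = NULL) {
  .assert_variant_tbl(variants)
  if (nrow(variants) == 0) return(.empty_annotation())
  rows <- purrr::pmap(variants[, .variant_key], function(chrom, pos, ref, alt) {
    v <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
    hits <- list()
    for (i in seq_len(nrow(transcripts))) {
      trr <- transcripts[i, ]
      ed <- .variant_cds_edit(v, trr)
      if (ed$kind == "non-coding") next
      if (ed$kind %in% c("split-span", "unsupported")) {
        hits[[length(hits) + 1L]] <- bind_cols(
          v, tibble(transcript_id = trr$transcript_id, category = "non-coding",
                    cdna_hgvs = NA_character_, protein_hgvs = NA_character_,
                    wt_length = trr$protein_length, mutant_length = NA_integer_,
                    fraction_lost = NA_real_, stop_offset = NA_integer_,
                    no_stop = FALSE, splice_flag = ed$kind == "split-span",
                    lost_domains = list(character()),
                    truncated_domains = list(character()))
        )
        next
      }
      call <- predict_protein_effect(trr$cds_seq, ed$edit)
      dom <- if (!is.null(domains)) {
        domains[domains$transcript_id == trr$transcript_id, ]
      } else {
        tibble(domain = character(), aa_start = integer(), aa_end = integer())
      }
      ts <- if (call$category %in% c("frameshift", "stop-gain")) {
        truncation_stats(call, dom)
      } else {
        list(lost = character(), truncated = character())
      }
      hits[[length(hits) + 1L]] <- bind_cols(
        v, tibble(transcript_id = trr$transcript_id),
        call, tibble(splice_flag = FALSE,
                     lost_domains = list(ts$lost),
                     truncated_domains = list(ts$truncated))
      )
    }
    if (length(hits) == 0) {
      return(bind_cols(
        v, tibble(transcript_id = NA_character_, category = "non-coding",
                  cdna_hgvs = NA_character_, protein_hgvs = NA_character_,
                  wt_length = NA_integer_, mutant_length = NA_integer_,
                  fraction_lost = NA_real_, stop_offset = NA_integer_,
                  no_stop = FALSE, splice_flag = FALSE,
                  lost_domains = list(character()),
                  truncated_domains = list(character()))
      ))
    }
    bind_rows(hits)
  })
  bind_rows(rows)
}
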