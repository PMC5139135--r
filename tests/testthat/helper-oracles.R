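# Independent oracles used to cross-check the package implementations.
# These deliberately take the dumbest correct path (exhaustive enumeration,
# direct string editing, Biostrings translation) rather than sharing code
# with the package.

# brute-force ROH: enumerate every marker window, keep windows satisfying
# the het/missing budgets, keep only maximal ones, trim to outermost
# homozygous markers, then apply the span/marker thresholds
oracle_roh <- function(pos, calls, params) {
  n <- length(calls)
  het <- !is.na(calls) & calls == "AB"
  mis <- is.na(calls)
  hom <- !het & !mis
  H <- cumsum(c(0L, het))
  M <- cumsum(c(0L, mis))
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      valid[i, j] <- (H[j + 1L] - H[i]) <= params$max_het_in_run &&
        (M[j + 1L] - M[i]) <= params$max_missing_in_run
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!valid[i, j]) next
      grow_left <- i > 1 && valid[i - 1, j]
      grow_right <- j < n && valid[i, j + 1]
      if (grow_left || grow_right) next      # not maximal
      homs <- which(hom[i:j]) + i - 1L
      if (length(homs) == 0) next
      i2 <- homs[1]; j2 <- homs[length(homs)]
      nm <- j2 - i2 + 1L
      span <- pos[j2] - pos[i2] + 1L
      if (nm < params$min_markers || span < params$min_length_bp) next
      out[[length(out) + 1L]] <- c(start = pos[i2] - 1L, end = pos[j2],
                                   n_markers = nm)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_markers = integer()))
  }
  dplyr::distinct(tibble::as_tibble(do.call(rbind, out)))
}

# direct edit-and-translate frameshift oracle (Biostrings translation path)
oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1, n))))
}

oracle_deletion_effect <- function(cds, del_start, del_len = 1L) {
  wt <- oracle_translate(cds)
  edited <- paste0(substr(cds, 1, del_start - 1),
                   substr(cds, del_start + del_len, nchar(cds)))
  mut <- oracle_translate(edited)
  wt_chr <- strsplit(wt, "")[[1]]
  mut_chr <- strsplit(mut, "")[[1]]
  m <- min(length(wt_chr), length(mut_chr))
  diffs <- which(wt_chr[seq_len(m)] != mut_chr[seq_len(m)])
  k <- if (length(diffs)) diffs[1] else m + 1L
  wt_len <- length(wt_chr) - 1L
  if (k > length(mut_chr)) {
    return(list(k = k, stop_offset = NA, mutant_length = length(mut_chr),
                no_stop = TRUE, wt_len = wt_len, wt = wt, mut = mut))
  }
  stops <- which(mut_chr[k:length(mut_chr)] == "*")
  if (length(stops) == 0) {
    list(k = k, stop_offset = NA, mutant_length = length(mut_chr),
         no_stop = TRUE, wt_len = wt_len, wt = wt, mut = mut)
  } else {
    list(k = k, stop_offset = stops[1], mutant_length = k + stops[1] - 2L,
         no_stop = FALSE, wt_len = wt_len, wt = wt, mut = mut)
  }
}

aa3_of <- function(aa1) {
  unname(c(Biostrings::AMINO_ACID_CODE, "*" = "*")[aa1])
}

# exhaustive per-trio Mendelian compatibility check on genotype codes:
# the child's A-allele count must be achievable as one donation from each
# parent (a 2-count parent donates A, a 0-count parent donates B)
oracle_mendelian_ok <- function(geno, ped) {
  count_a <- function(g) unname(c(AA = 2, AB = 1, BB = 0)[g])
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$sire[i])) next
    kid <- count_a(geno[[ped$id[i]]])
    sire <- count_a(geno[[ped$sire[i]]])
    dam <- count_a(geno[[ped$dam[i]]])
    lo <- (sire == 2) + (dam == 2)
    hi <- (sire > 0) + (dam > 0)
    ok <- is.na(kid) | is.na(sire) | is.na(dam) | (kid >= lo & kid <= hi)
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov >= 0.5 * (e1 - s1) && ov >= 0.5 * (e2 - s2)
}

# compact genotype-matrix builder: calls is a named list of call vectors
make_geno <- function(pos, calls, chrom = "chr1",
                      allele_a = "A", allele_b = "C") {
  g <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                      allele_a = allele_a, allele_b = allele_b)
  for (s in names(calls)) g[[s]] <- calls[[s]]
  g
}

random_orf_chr <- function(n_aa) {
  gc <- Biostrings::GENETIC_CODE
  pool <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(pool, n_aa - 1, replace = TRUE), collapse = ""),
         "TAA")
}
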