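#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_chr map_int map_dbl map_lgl pmap imap keep
#' @importFrom stats rbinom runif setNames
NULL

# Columns that identify a variant site; everything else in a variant tibble is
# taken to be a per-sample allele-dosage column (0, 1, 2 or NA).
.variant_key <- c("chrom", "pos", "ref", "alt")

#' Sample columns of a variant table
#'
#' Variant tables are tibbles with the fixed columns `chrom`, `pos`, `ref`,
#' `alt` plus one integer allele-dosage column per sample (0 = hom-ref,
#' 1 = het, 2 = hom-alt, `NA` = missing).
#'
#' @param variants A variant tibble.
#' @return Character vector of sample column names.
#' @export
variant_samples <- function(variants) {
  setdiff(names(variants), c(.variant_key, "id", "qual", "filter"))
}

.assert_variant_tbl <- function(variants) {
  miss <- setdiff(.variant_key, names(variants))
  if (length(miss) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(variants)
}

# genotype-code helpers; calls are "AA", "AB", "BB" or NA
.is_hom <- function(g) !is.na(g) & (g == "AA" | g == "BB")
.is_het <- function(g) !is.na(g) & g == "AB"

# marker columns of a genotype matrix tibble
.geno_key <- c("chrom", "pos", "allele_a", "allele_b")

#' Sample columns of a genotype matrix
#'
#' Genotype matrices are tibbles with the fixed marker columns `chrom`,
#' `pos`, `allele_a`, `allele_b` plus one call column per sample holding
#' `"AA"`, `"AB"`, `"BB"` or `NA` (missing). `"AA"` means homozygous for
#' `allele_a`, `"BB"` homozygous for `allele_b`.
#'
#' @param geno A genotype matrix tibble.
#' @return Character vector of sample column names.
#' @export
geno_samples <- function(geno) {
  setdiff(names(geno), .geno_key)
}

.assert_geno <- function(geno, samples = character()) {
  miss <- setdiff(.geno_key, names(geno))
  if (length(miss) > 0) {
    abort(paste0("genotype matrix lacks column(s): ", paste(miss, collapse = ", ")))
  }
  absent <- setdiff(samples, names(geno))
  if (length(absent) > 0) {
    abort(paste0("sample(s) not in genotype matrix: ", paste(absent, collapse = ", ")))
  }
  invisible(geno)
}

# three-letter amino-acid codes keyed by one-letter code; '*' handled apart
.aa3 <- function(aa1) {
  tbl <- c(Biostrings::AMINO_ACID_CODE, "*" = "*")
  unname(tbl[aa1])
}

# codon -> one-letter amino-acid lookup, built once per session
.codon_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- c(Biostrings::GENETIC_CODE)
    tbl
  }
})

# translate a DNA string (character) to protein, dropping any trailing
# partial codon; returns a character scalar of one-letter codes incl. '*'
.translate_chr <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n == 0L) return("")
  codons <- substring(dna, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"   # ambiguity codes are rejected upstream
  paste(aa, collapse = "")
}

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside {A,C,G,T}: ",
                 paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}
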