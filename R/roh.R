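#' Run-of-homozygosity detection parameters
#'
#' @param min_length_bp Minimum run span in bp (default 1 Mb, the
#'   threshold used for candidate autozygous tracts).
#' @param min_markers Minimum number of markers spanned by a run.
#' @param max_missing_in_run Maximum missing calls tolerated inside a run.
#' @param max_het_in_run Maximum heterozygous calls tolerated inside a
#'   run (default 0: strict homozygosity).
#' @return A validated parameter list.
#' @export
roh_params <- function(min_length_bp = 1e6, min_markers = 20L,
                       max_missing_in_run = 2L, max_het_in_run = 0L) {
  p <- list(min_length_bp = min_length_bp, min_markers = as.integer(min_markers),
            max_missing_in_run = as.integer(max_missing_in_run),
            max_het_in_run = as.integer(max_het_in_run))
  if (p$min_length_bp <= 0) abort("min_length_bp must be positive")
  if (any(unlist(p) < 0)) abort("ROH parameters must be non-negative")
  p
}

#' Pairwise identity by state
#'
#' Allele-sharing score between two samples averaged over co-called
#' markers: a marker contributes 1 if the genotypes are identical, 0.5 if
#' they share exactly one allele, 0 otherwise. 100% across a dense panel
#' is the monozygotic-twin signature.
#'
#' @param geno Genotype matrix tibble.
#' @param s1,s2 Sample ids.
#' @return Percentage in \[0, 100\].
#' @export
compute_ibs <- function(geno, s1, s2) {
  .assert_geno(geno, c(s1, s2))
  g1 <- geno[[s1]]
  g2 <- geno[[s2]]
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) abort("no marker is called in both samples; IBS undefined")
  g1 <- g1[ok]; g2 <- g2[ok]
  score <- ifelse(g1 == g2, 1,
                  ifelse(g1 == "AB" | g2 == "AB", 0.5,
                         0))  # AA vs BB shares nothing; AA/AB etc. share one
  100 * mean(score)
}

# maximal windows per chromosome under het/missing budgets (two-pointer),
# trimmed to their outermost homozygous markers
.roh_one_chrom <- function(pos, calls, alleles, params) {
  n <- length(calls)
  het <- .is_het(calls)
  mis <- is.na(calls)
  hom <- !het & !mis

  runs <- list()
  r <- 0L; n_het <- 0L; n_mis <- 0L
  r_prev <- 0L
  for (l in seq_len(n)) {
    if (r < l - 1L) { r <- l - 1L; n_het <- 0L; n_mis <- 0L }
    while (r < n &&
           n_het + het[r + 1L] <= params$max_het_in_run &&
           n_mis + mis[r + 1L] <= params$max_missing_in_run) {
      r <- r + 1L
      n_het <- n_het + het[r]
      n_mis <- n_mis + mis[r]
    }
    if (r >= l && (l == 1L || r > r_prev)) {
      runs[[length(runs) + 1L]] <- c(l, r)
    }
    r_prev <- r
    if (r >= l) {
      n_het <- n_het - het[l]
      n_mis <- n_mis - mis[l]
    }
  }
  if (length(runs) == 0) return(NULL)

  out <- purrr::map(runs, function(w) {
    i <- w[1]; j <- w[2]
    homs <- which(hom[i:j]) + i - 1L
    if (length(homs) == 0) return(NULL)
    i2 <- homs[1]; j2 <- homs[length(homs)]
    span <- pos[j2] - pos[i2] + 1L
    nm <- j2 - i2 + 1L
    if (nm < params$min_markers || span < params$min_length_bp) return(NULL)
    tibble(start = pos[i2] - 1L, end = pos[j2],
           n_markers = nm,
           n_het = sum(het[i2:j2]), n_missing = sum(mis[i2:j2]),
           alleles = list(alleles[i2:j2]),
           idx_start = i2, idx_end = j2)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(NULL)
  distinct(out, .data$start, .data$end, .keep_all = TRUE) |> arrange(.data$start)
}

#' Detect runs of homozygosity for one sample
#'
#' Returns every maximal run of consecutive markers on one chromosome with
#' at most `max_het_in_run` heterozygous and `max_missing_in_run` missing
#' calls (maximal: extending either end violates a budget), trimmed to its
#' outermost homozygous markers, spanning at least `min_markers` markers
#' and `min_length_bp` bp. Intervals are 0-based half-open, bounded by the
#' first/last marker position of the run. Abutting runs separated only by
#' excess missing calls are not merged (and may overlap).
#'
#' @param geno Genotype matrix tibble.
#' @param sample Sample id.
#' @param params A [roh_params()] list.
#' @return Tibble `sample`, `chrom`, `start`, `end`, `n_markers`, `n_het`,
#'   `n_missing`, `alleles` (list-column: the homozygous allele per
#'   marker, `NA` at missing/het markers).
#' @export
detect_roh <- function(geno, sample, params = roh_params()) {
  .assert_geno(geno, sample)
  out <- geno |>
    group_by(.data$chrom) |>
    group_map(function(d, key) {
      allele <- ifelse(is.na(d[[sample]]), NA_character_,
                       ifelse(d[[sample]] == "AA", d$allele_a,
                              ifelse(d[[sample]] == "BB", d$allele_b, NA)))
      r <- .roh_one_chrom(d$pos, d[[sample]], allele, params)
      if (is.null(r)) return(NULL)
      mutate(r, chrom = key$chrom, .before = 1)
    }) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(sample = character(), chrom = character(), start = integer(),
                  end = integer(), n_markers = integer(), n_het = integer(),
                  n_missing = integer(), alleles = list(),
                  idx_start = integer(), idx_end = integer()))
  }
  mutate(out, sample = sample, .before = 1) |>
    arrange(.data$chrom, .data$start)
}

#' Case-shared homozygous candidate regions
#'
#' Intersects the cases' homozygosity runs chromosome-wise and retains,
#' within each intersection, the maximal sub-intervals at which every
#' non-missing case genotype is homozygous for the same allele. Surviving
#' sub-intervals are re-checked against `min_length_bp` / `min_markers`
#' and trimmed to markers with a known shared allele.
#'
#' @param runs Tibble of runs from [detect_roh()] for all cases (stacked).
#' @param geno Genotype matrix tibble.
#' @param cases Character vector of case sample ids (length >= 1).
#' @param params A [roh_params()] list.
#' @return Tibble `chrom`, `start`, `end`, `n_markers`, `alleles`
#'   (list-column of the shared allele per marker, `NA` where all cases
#'   are missing).
#' @export
shared_case_regions <- function(runs, geno, cases, params = roh_params()) {
  if (length(cases) < 1) abort("at least one case sample is required")
  .assert_geno(geno, cases)

  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_markers = integer(), alleles = list())
  out <- geno |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chrom) |>
    group_map(function(d, key) {
      n <- nrow(d)
      in_run <- matrix(FALSE, n, length(cases))
      for (k in seq_along(cases)) {
        rk <- runs[runs$sample == cases[k] & runs$chrom == key$chrom, ]
        for (i in seq_len(nrow(rk))) {
          sel <- d$pos > rk$start[i] & d$pos <= rk$end[i]
          in_run[sel, k] <- TRUE
        }
      }
      all_in <- rowSums(in_run) == length(cases)

      # per-marker shared-allele status: allele if every called case is
      # homozygous for the same allele; NA if all missing; "" on conflict
      allele_mat <- vapply(cases, function(s) {
        ifelse(is.na(d[[s]]), NA_character_,
               ifelse(d[[s]] == "AA", d$allele_a,
                      ifelse(d[[s]] == "BB", d$allele_b, "")))
      }, character(n))
      allele_mat <- matrix(allele_mat, nrow = n)
      shared <- apply(allele_mat, 1, function(a) {
        a_known <- a[!is.na(a)]
        if (length(a_known) == 0) return(NA_character_)
        if (any(a_known == "") || length(unique(a_known)) > 1) return("")
        a_known[1]
      })

      ok <- all_in & (is.na(shared) | shared != "")
      if (!any(ok)) return(NULL)
      grp <- cumsum(!ok)[ok]
      idx_ok <- which(ok)
      purrr::map(split(idx_ok, grp), function(idx) {
        known <- idx[!is.na(shared[idx])]
        if (length(known) == 0) return(NULL)
        i2 <- known[1]; j2 <- known[length(known)]
        idx2 <- idx[idx >= i2 & idx <= j2]
        span <- d$pos[j2] - d$pos[i2] + 1L
        nm <- length(idx2)
        if (nm < params$min_markers || span < params$min_length_bp) return(NULL)
        tibble(chrom = key$chrom, start = d$pos[i2] - 1L, end = d$pos[j2],
               n_markers = nm, alleles = list(shared[idx2]))
      }) |> bind_rows()
    }) |>
    bind_rows()
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$start)
}

#' Drop regions where a parent is homozygous for the case-shared allele
#'
#' A candidate autozygous region is only credible if the (unaffected)
#' parents are carriers, i.e. not homozygous for the case-shared allele.
#' For each parent the fraction of checkable markers (parent called,
#' shared allele known) at which the parent is homozygous for the shared
#' allele is computed; the region is dropped when any parent's fraction
#' strictly exceeds `max_parent_hom_fraction`.
#'
#' @param regions Tibble from [shared_case_regions()].
#' @param geno Genotype matrix tibble.
#' @param parents Character vector of parent sample ids.
#' @param max_parent_hom_fraction Tolerated conflict fraction (default 0).
#' @return The retained regions with a `parent_conflicts` list-column
#'   (tibble `parent`, `n_checked`, `n_conflict`, `fraction` per region).
#' @export
exclude_parental <- function(regions, geno, parents,
                             max_parent_hom_fraction = 0) {
  .assert_geno(geno, parents)
  if (nrow(regions) == 0) {
    return(mutate(regions, parent_conflicts = list()))
  }
  res <- purrr::pmap(regions, function(chrom, start, end, n_markers, alleles, ...) {
    idx <- .markers_in_region(geno, chrom, start, end)
    shared <- alleles
    stopifnot(length(idx) == length(shared))
    conf <- purrr::map_dfr(parents, function(p) {
      g <- geno[[p]][idx]
      hom_allele <- ifelse(is.na(g), NA_character_,
                           ifelse(g == "AA", geno$allele_a[idx],
                                  ifelse(g == "BB", geno$allele_b[idx], NA)))
      check <- !is.na(shared) & !is.na(g)
      n_checked <- sum(check)
      n_conflict <- sum(check & !is.na(hom_allele) & hom_allele == shared)
      tibble(parent = p, n_checked = n_checked, n_conflict = n_conflict,
             fraction = ifelse(n_checked == 0, 0, n_conflict / n_checked))
    })
    list(keep = all(conf$fraction <= max_parent_hom_fraction), conflicts = conf)
  })
  keep <- purrr::map_lgl(res, "keep")
  out <- regions[keep, ]
  out$parent_conflicts <- purrr::map(res[keep], "conflicts")
  out
}
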