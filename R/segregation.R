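#' Cross-tabulate genotypes by cohort group
#'
#' @param genotypes Tibble with columns `sample`, `genotype` (one of
#'   `"hom-ref"`, `"het"`, `"hom-alt"`, or `NA`/`"missing"`) and, unless
#'   `groups` is given, `group`.
#' @param groups Optional tibble `sample`, `group` joined by sample id.
#' @return Tibble `group`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing`,
#'   `n_called`. Missing genotypes are tallied separately and excluded
#'   from `n_called` denominators.
#' @export
genotype_counts <- function(genotypes, groups = NULL) {
  g <- as_tibble(genotypes)
  if (!is.null(groups)) {
    g <- left_join(select(g, -any_of("group")), groups, by = "sample")
  }
  if (!all(c("sample", "genotype", "group") %in% names(g))) {
    abort("genotypes need columns sample, genotype and group (or a groups table)")
  }
  un <- g$sample[is.na(g$group)]
  if (length(un) > 0) {
    abort(paste0("sample(s) not assigned to any group: ",
                 paste(utils::head(un, 10), collapse = ", ")))
  }
  bad <- !is.na(g$genotype) & !(g$genotype %in% c("hom-ref", "het", "hom-alt", "missing"))
  if (any(bad)) {
    abort(paste0("unknown genotype code(s): ",
                 paste(unique(g$genotype[bad]), collapse = ", ")))
  }
  g$genotype[g$genotype %in% "missing"] <- NA
  # factor groups keep empty levels as all-zero rows
  g |>
    group_by(.data$group, .drop = !is.factor(g$group)) |>
    summarise(
      n_hom_ref = sum(.data$genotype == "hom-ref", na.rm = TRUE),
      n_het = sum(.data$genotype == "het", na.rm = TRUE),
      n_hom_alt = sum(.data$genotype == "hom-alt", na.rm = TRUE),
      n_missing = sum(is.na(.data$genotype)),
      .groups = "drop"
    ) |>
    mutate(n_called = .data$n_hom_ref + .data$n_het + .data$n_hom_alt)
}

#' Test perfect segregation under a recessive model
#'
#' True if and only if every called affected sample is homozygous
#' alternate and no sample outside the affected group is homozygous
#' alternate.
#'
#' @param counts Count table from [genotype_counts()].
#' @param affected_group Name of the affected group.
#' @return List `perfect` (flag) and `violations` (tibble `group`,
#'   `genotype`, `n` of offending cells).
#' @export
perfect_association <- function(counts, affected_group = "affected") {
  if (!affected_group %in% counts$group) {
    abort(paste0("no group named '", affected_group, "' in the count table"))
  }
  aff <- counts[counts$group == affected_group, ]
  oth <- counts[counts$group != affected_group, ]
  v <- bind_rows(
    tibble(group = affected_group, genotype = "hom-ref", n = aff$n_hom_ref),
    tibble(group = affected_group, genotype = "het", n = aff$n_het),
    tibble(group = oth$group, genotype = "hom-alt", n = oth$n_hom_alt)
  ) |> filter(.data$n > 0)
  list(perfect = nrow(v) == 0, violations = v)
}

#' Carrier frequency of a group
#'
#' @param counts Count table from [genotype_counts()].
#' @param group Group name.
#' @return Percentage: `100 * het / (hom-ref + het + hom-alt)`.
#' @export
carrier_frequency <- function(counts, group) {
  row <- counts[counts$group == group, ]
  if (nrow(row) != 1) abort(paste0("no group named '", group, "'"))
  if (row$n_called == 0) abort("carrier frequency undefined: no called genotypes")
  100 * row$n_het / row$n_called
}

#' Check obligate carriers against a pedigree
#'
#' Under recessive inheritance every parent of an affected homozygous-
#' alternate individual must carry at least one mutant allele; a
#' homozygous-reference parent is flagged. Heterozygous and missing
#' parental genotypes pass.
#'
#' @param pedigree Pedigree tibble (see [make_pedigree()]).
#' @param genotypes Tibble `sample`, `genotype`.
#' @return Tibble of violations: `parent`, `child`, `parent_genotype`.
#' @export
obligate_carrier_check <- function(pedigree, genotypes) {
  gt <- setNames(genotypes$genotype, genotypes$sample)
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    child <- pedigree$id[i]
    if (is.na(gt[child]) || gt[child] != "hom-alt") next
    if (!is.na(pedigree$status[i]) && pedigree$status[i] != "affected") next
    for (p in c(pedigree$sire[i], pedigree$dam[i])) {
      if (is.na(p) || !p %in% names(gt)) next
      if (!is.na(gt[p]) && gt[p] == "hom-ref") {
        out[[length(out) + 1L]] <- tibble(parent = p, child = child,
                                          parent_genotype = gt[[p]])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(parent = character(), child = character(),
                  parent_genotype = character()))
  }
  bind_rows(out)
}

#' Full segregation report
#'
#' @param genotypes Tibble `sample`, `group`, `genotype` for the candidate
#'   variant across all cohorts.
#' @param pedigree Optional pedigree tibble for the obligate-carrier
#'   check.
#' @param affected_group,carrier_group Group names for the association
#'   test and the carrier-frequency estimate.
#' @return Object of class `segregation_report` with elements `counts`,
#'   `perfect`, `violations`, `carrier_group`, `carrier_percent`
#'   (2 decimals and rounded integer), `pedigree_violations`.
#' @export
segregation_report <- function(genotypes, pedigree = NULL,
                               affected_group = "affected",
                               carrier_group = "population_controls") {
  counts <- genotype_counts(genotypes)
  assoc <- perfect_association(counts, affected_group)
  cp <- carrier_frequency(counts, carrier_group)
  pv <- if (!is.null(pedigree)) {
    obligate_carrier_check(pedigree, genotypes)
  } else {
    tibble(parent = character(), child = character(),
           parent_genotype = character())
  }
  structure(
    list(counts = counts, perfect = assoc$perfect,
         violations = assoc$violations,
         carrier_group = carrier_group,
         carrier_percent = round(cp, 2),
         carrier_percent_rounded = round(cp),
         pedigree_violations = pv),
    class = "segregation_report"
  )
}

#' @export
print.segregation_report <- function(x, ...) {
  cat("<segregation_report>\n")
  print(x$counts)
  cat(sprintf("perfect recessive association: %s\n", x$perfect))
  cat(sprintf("carrier frequency in %s: %.2f%% (~%d%%)\n",
              x$carrier_group, x$carrier_percent, x$carrier_percent_rounded))
  if (nrow(x$pedigree_violations) > 0) {
    cat("pedigree violations:\n"); print(x$pedigree_violations)
  }
  invisible(x)
}

#' Genotype counts of a segregation report
#'
#' @param x A `segregation_report`.
#' @param ... Unused.
#' @return The per-group count tibble.
#' @export
tidy.segregation_report <- function(x, ...) x$counts

#' One-row summary of a segregation report
#'
#' @param x A `segregation_report`.
#' @param ... Unused.
#' @return Tibble `perfect`, `carrier_percent`, `n_groups`, `n_samples`,
#'   `n_pedigree_violations`.
#' @export
glance.segregation_report <- function(x, ...) {
  tibble(perfect = x$perfect,
         carrier_percent = x$carrier_percent,
         n_groups = nrow(x$counts),
         n_samples = sum(x$counts$n_called) + sum(x$counts$n_missing),
         n_pedigree_violations = nrow(x$pedigree_violations))
}
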