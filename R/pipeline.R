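#' Run the full discovery pipeline on simulated data
#'
#' Orchestrates simulate -> homozygosity mapping -> private-variant triage
#' -> consequence annotation -> segregation reporting as one reproducible
#' run. With an `out_dir`, every intermediate artifact is persisted
#' (PED/MAP, truth BED, GFF3 + CDS FASTA, domain TSV, cohort VCFs,
#' candidate-region BED/TSV, per-stage VCFs, funnel JSON/TSV, annotation
#' TSV, segregation JSON) together with a final `report.json`. Two runs
#' with the same config produce byte-identical reports (no timestamps are
#' written).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory, or `NULL` to skip artifact writing.
#' @param params [roh_params()] for the mapping stage.
#' @param max_parent_hom_fraction Parental-conflict tolerance for
#'   [exclude_parental()]. The pipeline default (0.05) tolerates the few
#'   flanking markers at which a detected case run extends past the true
#'   autozygous tract and a carrier parent happens to be homozygous for
#'   the shared allele; a parent genuinely homozygous across a region
#'   conflicts at ~50% of its markers and is still discarded.
#' @return Invisibly, a list of class `pipeline_report`: `seed`,
#'   `ibs_twins`, `regions`, `funnels` (per-branch stage counts),
#'   `candidates` (annotated final recessive list), `causal_recovered`,
#'   `segregation` summary.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         params = roh_params(),
                         max_parent_hom_fraction = 0.05) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = paste0("autozyg_stage_", name))
    })
  }

  # --- simulate ------------------------------------------------------------
  fixture <- stage("simulate", make_transcript_fixture(config))
  sim <- stage("simulate", simulate_pedigree_genotypes(config))
  cohort <- stage("simulate", simulate_variant_cohort(config, fixture))
  ped <- sim$pedigree
  geno <- sim$geno

  if (!is.null(out_dir)) {
    simdir <- file.path(out_dir, "sim")
    dir.create(simdir, recursive = TRUE, showWarnings = FALSE)
    write_plink(geno, ped, file.path(simdir, "genotypes"))
    readr::write_tsv(ped, file.path(simdir, "pedigree.tsv"))
    write_bed(config$seeded_ibd_regions, file.path(simdir, "truth_regions.bed"))
    write_gene_models(fixture$transcripts, file.path(simdir, "genes.gff3"),
                      file.path(simdir, "cds.fasta"))
    write_domains(fixture$domains, file.path(simdir, "domains.tsv"))
    write_vcf(cohort$case_variants, file.path(simdir, "case.vcf"),
              contigs = config$genome_layout)
    write_vcf(cohort$control_variants, file.path(simdir, "controls.vcf"),
              contigs = config$genome_layout)
    readr::write_tsv(cohort$popdb_sites, file.path(simdir, "popdb_sites.tsv"))
    readr::write_tsv(cohort$population_genotypes,
                     file.path(simdir, "population_genotypes.tsv"))
  }

  # --- homozygosity mapping ------------------------------------------------
  cases <- intersect(c("CASE1", "CASE2"), ped$id)
  parents <- unique(stats::na.omit(unlist(ped[ped$id %in% cases,
                                              c("sire", "dam")])))
  res <- stage("map-roh", {
    ibs <- compute_ibs(geno, cases[1], cases[2])
    runs <- bind_rows(purrr::map(cases, ~detect_roh(geno, .x, params)))
    shared <- shared_case_regions(runs, geno, cases, params)
    regions <- exclude_parental(shared, geno, parents,
                                max_parent_hom_fraction)
    list(ibs = ibs, runs = runs, regions = regions)
  })
  regions <- res$regions

  if (!is.null(out_dir)) {
    rohdir <- file.path(out_dir, "roh")
    dir.create(rohdir, showWarnings = FALSE)
    readr::write_tsv(res$runs |> select(-"alleles"),
                     file.path(rohdir, "runs.tsv"))
    write_bed(regions, file.path(rohdir, "candidate_regions.bed"))
    readr::write_tsv(
      regions |>
        mutate(length_bp = .data$end - .data$start,
               parent_conflicts = purrr::map_chr(
                 .data$parent_conflicts,
                 ~paste(sprintf("%s:%d/%d", .x$parent, .x$n_conflict,
                                .x$n_checked), collapse = ";"))) |>
        select(-"alleles"),
      file.path(rohdir, "candidate_regions.tsv"))
  }

  # --- triage --------------------------------------------------------------
  funnels <- stage("triage", {
    list(
      recessive = recessive_branch(cohort$case_variants, fixture$transcripts,
                                   regions, cohort$control_variants,
                                   cohort$popdb_sites, "CASE1"),
      dominant = dominant_branch(cohort$case_variants, fixture$transcripts,
                                 cohort$control_variants, cohort$popdb_sites,
                                 "CASE1")
    )
  })
  candidates <- funnel_candidates(funnels$recessive)

  if (!is.null(out_dir)) {
    tridir <- file.path(out_dir, "triage")
    dir.create(tridir, showWarnings = FALSE)
    for (b in names(funnels)) {
      for (s in names(funnels[[b]]$variants)) {
        write_vcf(funnels[[b]]$variants[[s]],
                  file.path(tridir, paste0(b, "_", s, ".vcf")),
                  contigs = config$genome_layout)
      }
    }
    funnel_tbl <- bind_rows(tidy(funnels$recessive), tidy(funnels$dominant))
    readr::write_tsv(funnel_tbl, file.path(tridir, "funnel.tsv"))
    jsonlite::write_json(funnel_tbl, file.path(tridir, "funnel.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  # --- annotate ------------------------------------------------------------
  annotated <- stage("annotate", {
    annotate_variants(candidates, fixture$transcripts, fixture$domains)
  })
  if (!is.null(out_dir)) {
    anndir <- file.path(out_dir, "annotate")
    dir.create(anndir, showWarnings = FALSE)
    readr::write_tsv(
      annotated |>
        mutate(lost_domains = purrr::map_chr(.data$lost_domains, paste,
                                             collapse = ","),
               truncated_domains = purrr::map_chr(.data$truncated_domains,
                                                  paste, collapse = ",")),
      file.path(anndir, "candidates_annotated.tsv"))
  }

  # --- segregate -----------------------------------------------------------
  seg <- stage("segregate", {
    segregation_report(cohort$population_genotypes, pedigree = ped)
  })
  if (!is.null(out_dir)) {
    segdir <- file.path(out_dir, "segregate")
    dir.create(segdir, showWarnings = FALSE)
    jsonlite::write_json(
      list(counts = seg$counts, perfect = seg$perfect,
           carrier_percent = seg$carrier_percent,
           pedigree_violations = seg$pedigree_violations),
      file.path(segdir, "segregation.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  causal_key <- normalize_variants(cohort$causal)
  finals <- normalize_variants(candidates[, .variant_key])
  causal_recovered <- nrow(dplyr::semi_join(causal_key, finals,
                                            by = .variant_key)) == 1

  report <- structure(list(
    seed = config$rng_seed,
    ibs_twins = res$ibs,
    n_candidate_regions = nrow(regions),
    regions = regions |> select("chrom", "start", "end", "n_markers"),
    funnels = list(recessive = funnels$recessive$stages,
                   dominant = funnels$dominant$stages),
    n_final_candidates = nrow(distinct(candidates,
                                       across(all_of(.variant_key)))),
    candidates = annotated |> select(-"lost_domains", -"truncated_domains"),
    causal_recovered = causal_recovered,
    segregation = as.list(glance(seg))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("twin IBS: %.2f%%; candidate regions: %d; causal recovered: %s\n",
              x$ibs_twins, x$n_candidate_regions, x$causal_recovered))
  cat("recessive funnel:\n"); print(x$funnels$recessive)
  cat("dominant funnel:\n"); print(x$funnels$dominant)
  cat(sprintf("segregation: perfect=%s carrier%%=%.2f\n",
              x$segregation$perfect, x$segregation$carrier_percent))
  invisible(x)
}
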