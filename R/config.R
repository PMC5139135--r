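#' Simulation configuration
#'
#' Describes the synthetic world the generator emulates: a nuclear family
#' with a monozygotic twin case pair extended by two half-sibling cases,
#' SNP-array genotypes carrying seeded autozygous (IBD) tracts, a case
#' whole-genome variant call set, a control-genome cohort, a population
#' variant database site list, and a genotyped population-control sample
#' in which the causal allele segregates at a few percent carrier
#' frequency.
#'
#' @param genome_layout Tibble with columns `chrom`, `length` (bp).
#' @param n_markers Total marker count, allocated to chromosomes in
#'   proportion to length and placed on a jittered uniform grid.
#' @param n_cases Number of affected individuals (2 twins plus up to two
#'   half-sibling cases; 2..4).
#' @param mz_twin_pair If `TRUE` the first two cases are monozygotic
#'   twins with identical genotype vectors.
#' @param seeded_ibd_regions Tibble `chrom`, `start`, `end` (0-based
#'   half-open) of case-autozygous tracts: cases homozygous for one
#'   shared founder haplotype, parents strictly heterozygous carriers.
#' @param n_control_genomes Control genomes in the comparison cohort VCF.
#' @param n_popdb_genomes Genomes behind the population-database site
#'   list (count only; the database is a site list).
#' @param n_population_controls Population-control animals genotyped for
#'   the causal variant.
#' @param carrier_fraction Expected heterozygote proportion among
#'   population controls; none are homozygous alternate.
#' @param n_background_coding_variants Background coding SNVs scattered
#'   over gene CDS with configurable cohort sharing.
#' @param n_background_genes Single-transcript background genes tiled
#'   over the genome (in addition to the two-transcript target gene).
#' @param maf Founder allele frequency of the B allele at each marker.
#' @param missing_rate Per-call missing probability on the array.
#' @param case_hom_fraction Probability a background variant is hom-alt
#'   (rather than het) in the index case.
#' @param control_sharing Probability a background variant is present in
#'   at least one control genome.
#' @param popdb_sharing Probability a background variant is present in
#'   the population-database site list.
#' @param rng_seed Integer seed; all randomness flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_layout = tibble(
                         chrom = c("chr1", "chr2"),
                         length = c(30e6, 30e6)
                       ),
                       n_markers = 10000L,
                       n_cases = 4L,
                       mz_twin_pair = TRUE,
                       seeded_ibd_regions = tibble(
                         chrom = c("chr1", "chr2"),
                         start = c(10e6, 5e6),
                         end = c(12.5e6, 6.8e6)
                       ),
                       n_control_genomes = 106L,
                       n_popdb_genomes = 1119L,
                       n_population_controls = 1201L,
                       carrier_fraction = 0.04,
                       n_background_coding_variants = 500L,
                       n_background_genes = 30L,
                       maf = 0.5,
                       missing_rate = 0.005,
                       case_hom_fraction = 0.5,
                       control_sharing = 0.9,
                       popdb_sharing = 0.8,
                       rng_seed = 1L) {
  cfg <- list(
    genome_layout = as_tibble(genome_layout),
    n_markers = as.integer(n_markers),
    n_cases = as.integer(n_cases),
    mz_twin_pair = isTRUE(mz_twin_pair),
    seeded_ibd_regions = as_tibble(seeded_ibd_regions),
    n_control_genomes = as.integer(n_control_genomes),
    n_popdb_genomes = as.integer(n_popdb_genomes),
    n_population_controls = as.integer(n_population_controls),
    carrier_fraction = carrier_fraction,
    n_background_coding_variants = as.integer(n_background_coding_variants),
    n_background_genes = as.integer(n_background_genes),
    maf = maf,
    missing_rate = missing_rate,
    case_hom_fraction = case_hom_fraction,
    control_sharing = control_sharing,
    popdb_sharing = popdb_sharing,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  gl <- cfg$genome_layout
  if (!all(c("chrom", "length") %in% names(gl)) || nrow(gl) == 0) {
    abort("genome_layout needs columns chrom, length and at least one row")
  }
  if (anyDuplicated(gl$chrom) > 0) abort("genome_layout chromosomes must be unique")
  if (cfg$carrier_fraction < 0 || cfg$carrier_fraction > 1) {
    abort("carrier_fraction must lie in [0, 1]")
  }
  if (cfg$n_cases < 2 || cfg$n_cases > 4) abort("n_cases must be 2..4")
  if (is.na(cfg$rng_seed)) abort("rng_seed must be a finite integer")
  r <- cfg$seeded_ibd_regions
  if (nrow(r) > 0) {
    if (!all(r$chrom %in% gl$chrom)) {
      abort("seeded_ibd_regions reference unknown chromosomes")
    }
    lens <- gl$length[match(r$chrom, gl$chrom)]
    if (any(r$start < 0) || any(r$end > lens) || any(r$end <= r$start)) {
      abort("seeded_ibd_regions must be non-empty intervals within the genome")
    }
    # pairwise non-overlap within chromosome
    ov <- r |>
      arrange(.data$chrom, .data$start) |>
      group_by(.data$chrom) |>
      mutate(overlaps = .data$start < lag(.data$end, default = -Inf)) |>
      ungroup()
    if (any(ov$overlaps)) abort("seeded_ibd_regions must be pairwise non-overlapping")
  }
  invisible(cfg)
}

# seeds for the independent simulation stages, all derived from rng_seed
# and kept below 2^31
.derive_seed <- function(cfg, stage) {
  offs <- c(genotypes = 101L, fixture = 211L, cohort = 307L)
  (cfg$rng_seed %% 2000000000L) + offs[[stage]]
}
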