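# small, fast configuration used by most tests (the acceptance suite uses
# the full-size default); any field can be overridden through ...
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_markers = 2000L,
    n_control_genomes = 12L,
    n_popdb_genomes = 20L,
    n_population_controls = 150L,
    n_background_coding_variants = 60L,
    n_background_genes = 8L,
    rng_seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
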