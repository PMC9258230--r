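# small generator configurations shared across tests
tiny_cfg <- function(...) {
  args <- list(n_lineages = 2L, genomes_per_lineage = 4L,
               core_family_count = 5L, module_sizes = c(3L, 3L),
               seq_length = 60L, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# geometry for module-recovery experiments: many small lineages so that
# each lineage is a small fraction of the genome set, as in real
# domain-wide collections
module_cfg <- function(seed, n_lineages = 30L, genomes_per_lineage = 8L,
                       module_sizes = rep(30L, n_lineages), ...) {
  synthetic_config(n_lineages = n_lineages,
                   genomes_per_lineage = genomes_per_lineage,
                   module_sizes = module_sizes,
                   core_family_count = 40L,
                   seed = seed, ...)
}

planted_module_sets <- function(truth) {
  split(names(truth$planted_module_of_family),
        truth$planted_module_of_family)
}
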