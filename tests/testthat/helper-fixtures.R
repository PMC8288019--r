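# Shared fixture builders: everything is generated in code at test time.

one_scaffold <- function(len = 1e7, name = "s1") {
  data.frame(scaffold = name, length = len)
}

# small genome with per-tile depth, defaults chosen for sub-second simulation
quick_genome <- function(len = 1e7, theta = 200, target_F = 0, seed = 1,
                         depth_tile = 1e4, ...) {
  spec <- sim_genome_spec(one_scaffold(len), theta = theta,
                          target_F = target_F, depth_tile = depth_tile,
                          seed = seed, ...)
  simulate_diploid_genome(spec)
}

# hand-built variant table for filter tests
toy_variants <- function(n = 5, qual = 90, depth = 30, class = "het",
                         scaffold = "s1") {
  data.frame(sample = "t1", scaffold = scaffold,
             pos = seq_len(n) * 100L, genotype_class = rep_len(class, n),
             qual = rep_len(qual, n), depth = rep_len(depth, n),
             is_snp = TRUE)
}

calls_from_variants <- function(variants) {
  data.frame(scaffold = variants$scaffold, pos = variants$pos - 1L,
             het = variants$genotype_class == "het")
}
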