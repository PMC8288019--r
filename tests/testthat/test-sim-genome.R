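test_that("planted ROH tracts carry no heterozygous sites and hit the target fraction", {
  for (F in c(0.11, 0.45, 0.7)) {
    g <- quick_genome(len = 2e7, theta = 200, target_F = F, seed = 100 + F * 100)
    expect_equal(g$truth$true_F, F, tolerance = 1e-6)
    # truth intervals are disjoint and within bounds
    roh <- g$truth$roh
    expect_true(all(roh$start >= 0 & roh$end <= 2e7 & roh$start < roh$end))
    o <- order(roh$start)
    expect_true(all(roh$start[o][-1] >= roh$end[o][-nrow(roh)]))
    # no het site inside any planted tract (brute force recheck)
    het <- het_sites(g$variants)
    inside <- vapply(het$pos, function(p)
      any(p >= roh$start & p < roh$end), TRUE)
    expect_false(any(inside))
  }
})

test_that("degenerate simulations behave: F=1 silences autosomes, theta=0 emits no hets", {
  g1 <- quick_genome(len = 2e6, theta = 300, target_F = 1, seed = 5)
  expect_identical(sum(g1$variants$genotype_class == "het"), 0L)
  g0 <- quick_genome(len = 2e6, theta = 0, target_F = 0, seed = 6,
                     hom_alt_factor = 0)
  expect_identical(nrow(g0$variants), 0L)
  expect_gt(nrow(g0$depth), 0)          # callable depth track still emitted
  expect_equal(max(g0$depth$end), 2e6)
})

test_that("het-site counts match the Poisson expectation and a per-base Bernoulli oracle", {
  theta <- 200
  # oracle: independent per-base Bernoulli(theta/1e6) draws over 1 Mb
  set.seed(99)
  oracle <- replicate(40, sum(runif(1e6) < theta / 1e6))
  counts <- vapply(1:40, function(i) {
    g <- quick_genome(len = 1e6, theta = theta, target_F = 0, seed = 500 + i,
                      depth_tile = 1e5, hom_alt_factor = 0)
    sum(g$variants$genotype_class == "het")
  }, 0)
  # both estimate the same mean (theta); compare within 3 combined SE
  se <- sqrt(theta / 40 * 2)
  expect_lt(abs(mean(counts) - mean(oracle)), 3 * se)
  expect_lt(abs(mean(counts) - theta), 3 * sqrt(theta / 40))
})

test_that("large genome het count is within 3 sd of theta * L", {
  g <- quick_genome(len = 1e8, theta = 200, target_F = 0, seed = 7,
                    depth_tile = 1e6, hom_alt_factor = 0)
  n <- sum(g$variants$genotype_class == "het")
  expect_lt(abs(n - 20000), 3 * sqrt(20000))
})

test_that("simulation is byte-identical under the same seed", {
  g1 <- quick_genome(seed = 42, target_F = 0.3, depth_tile = 1e5)
  g2 <- quick_genome(seed = 42, target_F = 0.3, depth_tile = 1e5)
  g3 <- quick_genome(seed = 43, target_F = 0.3, depth_tile = 1e5)
  expect_identical(g1$variants, g2$variants)
  expect_identical(g1$depth, g2$depth)
  expect_identical(g1$truth$roh, g2$truth$roh)
  expect_false(identical(g1$variants, g3$variants))
})

test_that("unreachable target_F and out-of-bounds gene clusters fail explicitly", {
  sc <- one_scaffold(1e6)
  spec <- sim_genome_spec(sc, target_F = 0.5,
                          roh_mix = list(p_short = 0.5, mean_short = 5e6,
                                         mean_long = 5e7), seed = 1)
  expect_error(simulate_diploid_genome(spec), "unreachable")
  gs <- gene_set("big", n_genes = 10, exon_len = 300, gene_gap = 2e4,
                 scaffold = "s1", cluster_start = 9.9e5)
  spec2 <- sim_genome_spec(sc, gene_sets = list(gs), depth_tile = 1e4, seed = 2)
  expect_error(simulate_diploid_genome(spec2), "exceeds scaffold")
})

test_that("gene-set exons carry the heterozygosity multiplier and avoid ROH when asked", {
  gs <- list(gene_set("hot", n_genes = 30, exons_per_gene = 4, exon_len = 500,
                      intron_len = 500, gene_gap = 3000, het_multiplier = 5,
                      roh_avoidance = TRUE))
  spec <- sim_genome_spec(one_scaffold(2e7), theta = 200, target_F = 0.4,
                          gene_sets = gs, depth_tile = 1e5, seed = 21)
  g <- simulate_diploid_genome(spec)
  tr <- g$truth$gene_truth
  expect_identical(tr$set, "hot")
  # realized exon rate near 5 * 200 = 1000 SNPs/Mb (3 Poisson SE)
  expected <- 5 * 200 * tr$exon_bp / 1e6
  expect_lt(abs(tr$n_het - expected), 3 * sqrt(expected))
  # avoidance: no exon overlaps a planted tract
  roh <- g$truth$roh
  hit <- vapply(seq_len(nrow(g$exons)), function(i)
    any(g$exons$start[i] < roh$end & g$exons$end[i] > roh$start), TRUE)
  expect_false(any(hit))
})

test_that("invalid spec parameters are rejected", {
  sc <- one_scaffold()
  expect_error(sim_genome_spec(sc, theta = -1), "theta")
  expect_error(sim_genome_spec(sc, target_F = 1.2), "target_F")
  expect_error(sim_genome_spec(data.frame(scaffold = "a", length = 0)), "length")
})
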