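make_callability <- function(len = 1e7, scaffold = "s1", min_depth = 10) {
  structure(list(
    intervals = data.frame(scaffold = scaffold, start = 0L, end = len),
    totals = stats::setNames(len, scaffold), total = len,
    min_depth = min_depth), class = "callability")
}

test_that("the heterozygosity rate is het sites per callable megabase", {
  cal <- make_callability(1e7)
  het <- data.frame(scaffold = "s1", pos = seq(1000L, by = 1000L, length.out = 120))
  hr <- genome_het_rate(het, cal)
  expect_identical(hr$n_het, 120L)
  expect_equal(hr$rate_snps_per_mb, 12)
  hr0 <- genome_het_rate(het[0, ], cal)
  expect_equal(hr0$rate_snps_per_mb, 0)
  # sites outside callable intervals do not count
  cal2 <- make_callability(1e6)
  cal2$intervals$end <- 50000L
  cal2$total <- 50000L
  hr2 <- genome_het_rate(het, cal2)
  expect_identical(hr2$n_het, 49L)
  empty <- make_callability(0)
  empty$total <- 0
  expect_error(genome_het_rate(het, empty), "zero callable")
})

test_that("rate estimation recovers theta across 50-500 SNPs/Mb through the full filter chain", {
  sc <- one_scaffold(4e6)
  pol <- filter_policy()
  for (th in c(50, 200, 500)) {
    g <- quick_genome(len = 4e6, theta = th, seed = 300 + th, depth_tile = 1)
    md <- mean_genome_depth(g$depth)
    filt <- filter_genotypes(g$variants, pol, md)
    cal <- build_callability(g$depth, pol, md, sc)
    hr <- genome_het_rate(het_sites(filt), cal)
    se <- sqrt(hr$n_het) / hr$n_callable * 1e6
    expect_lt(abs(hr$rate_snps_per_mb - th), 3 * se)
  }
})

test_that("window tiling follows the 0-based half-open, drop-partial convention", {
  expect_identical(nrow(genome_windows(one_scaffold(250000))), 2L)
  expect_identical(nrow(genome_windows(one_scaffold(99999))), 0L)
  w <- window_het_counts(data.frame(scaffold = "s1", pos = 100000L),
                         one_scaffold(250000))
  expect_identical(w$het_count, c(0L, 1L))       # site at 1e5 -> second window
  w2 <- window_het_counts(data.frame(scaffold = "s1", pos = 99999L),
                          one_scaffold(250000))
  expect_identical(w2$het_count, c(1L, 0L))
})

test_that("window counts conserve the genome-wide het count", {
  g <- quick_genome(len = 1234567, theta = 500, target_F = 0.2, seed = 44,
                    depth_tile = 1e5)
  het <- het_sites(g$variants)
  w <- window_het_counts(het, one_scaffold(1234567))
  in_remainder <- sum(het$pos >= nrow(w) * 1e5)
  expect_identical(sum(w$het_count) + in_remainder, nrow(het))
})

test_that("the rate is invariant to scaffold order and site-list chunking", {
  sc <- data.frame(scaffold = c("a", "b"), length = c(2e6, 3e6))
  set.seed(5)
  het <- data.frame(scaffold = sample(c("a", "b"), 400, TRUE),
                    pos = sample.int(2e6, 400))
  cal <- structure(list(
    intervals = data.frame(scaffold = c("a", "b"), start = 0L,
                           end = c(2e6, 2e6)),
    totals = c(a = 2e6, b = 2e6), total = 4e6, min_depth = 10),
    class = "callability")
  r1 <- genome_het_rate(het, cal)
  r2 <- genome_het_rate(het[order(het$scaffold, decreasing = TRUE), ], cal)
  r3a <- genome_het_rate(het[het$scaffold == "a", ], cal)
  r3b <- genome_het_rate(het[het$scaffold == "b", ], cal)
  expect_identical(r1$n_het, r2$n_het)
  expect_identical(r1$n_het, r3a$n_het + r3b$n_het)
})

test_that("depth sweep rates are flat for uniform coverage and depressed after thinning", {
  sc <- one_scaffold(2e6)
  g <- quick_genome(len = 2e6, theta = 300, seed = 61, depth_tile = 1)
  uni <- g$depth
  uni$depth <- 30L
  v <- g$variants
  v$depth <- 30L
  sw <- depth_sweep(v, uni, filter_policy(), sc)
  expect_identical(nrow(sw), 9L)
  expect_true(all(sw$rate_snps_per_mb == sw$rate_snps_per_mb[1]))
  expect_true(all(diff(sw$n_callable) <= 0))
  # empty het set -> all-zero rates
  v0 <- v[v$genotype_class != "het", , drop = FALSE]
  sw0 <- depth_sweep(v0, uni, filter_policy(), sc)
  expect_true(all(sw0$rate_snps_per_mb == 0))

  # thinning to 40% of mean 30 loses callable sites and het calls at min depth 10
  thin <- thin_depth(g$depth, 0.4, seed = 62)
  vthin <- g$variants
  vthin$depth <- thin$depth[vthin$pos]      # per-base track, direct lookup
  sw_full <- depth_sweep(g$variants, g$depth, filter_policy(), sc,
                         depths = 10)
  sw_thin <- depth_sweep(vthin, thin, filter_policy(), sc, depths = 10)
  expect_lt(sw_thin$rate_snps_per_mb, sw_full$rate_snps_per_mb)
  expect_true(all(diff(depth_sweep(vthin, thin, filter_policy(), sc)$n_callable) <= 0))
})

test_that("gene-set heterozygosity uses callable exon bases and reports fold excess", {
  cal <- make_callability(1e7)
  exons <- data.frame(scaffold = "s1", start = c(1000L, 5000L),
                      end = c(2000L, 6000L))
  het <- data.frame(scaffold = "s1", pos = c(1100L, 1200L, 5500L, 900000L))
  gh <- gene_set_het(het, exons, cal, reference_rate = 150, name = "fam")
  expect_identical(gh$n_het, 3L)
  expect_identical(gh$n_callable, 2000)
  expect_equal(gh$rate_snps_per_mb, 1500)
  expect_equal(gh$excess, 10)
  # only the callable part of an exon counts in the denominator
  cal2 <- make_callability(1e7)
  cal2$intervals <- data.frame(scaffold = "s1", start = 0L, end = 1500L)
  gh2 <- gene_set_het(het, exons, cal2, name = "fam")
  expect_identical(gh2$n_callable, 500)
  expect_identical(gh2$n_het, 2L)
  cal3 <- make_callability(1e7)
  cal3$intervals <- data.frame(scaffold = "s1", start = 8000L, end = 9000L)
  expect_error(gene_set_het(het, exons, cal3, name = "fam"),
               "fam.*zero callable|zero callable")
})

test_that("a planted exon multiplier is recovered as fold excess within sampling error", {
  gs <- list(gene_set("hot", n_genes = 40, exons_per_gene = 5, exon_len = 400,
                      intron_len = 600, gene_gap = 2000, het_multiplier = 5))
  spec <- sim_genome_spec(one_scaffold(2e7), theta = 200, gene_sets = gs,
                          depth_tile = 1e4, seed = 71)
  g <- simulate_diploid_genome(spec)
  sc <- one_scaffold(2e7)
  md <- mean_genome_depth(g$depth)
  cal <- build_callability(g$depth, filter_policy(), md, sc)
  filt <- filter_genotypes(g$variants, filter_policy(), md)
  hr <- genome_het_rate(het_sites(filt), cal)
  gh <- gene_set_het(het_sites(filt), g$exons, cal,
                     reference_rate = hr$rate_snps_per_mb, name = "hot")
  # exon_bp = 40*5*400 = 80 kb; expected 1000 SNPs/Mb -> ~80 hets, SE ~ 11%
  se_rel <- sqrt(1 / gh$n_het + 1 / hr$n_het)
  expect_lt(abs(gh$excess - 5), 3 * 5 * se_rel)
})
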