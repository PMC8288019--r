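test_that("a written VCF round-trips through read_variants", {
  v <- data.frame(sample = "ind1", scaffold = c("s1", "s1", "s2"),
                  pos = c(101L, 205L, 50L),
                  genotype_class = c("het", "hom_alt", "missing"),
                  qual = c(50L, 88L, 12L), depth = c(15L, 31L, 7L),
                  is_snp = TRUE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f, scaffolds = data.frame(scaffold = c("s1", "s2"),
                                         length = c(1000L, 1000L)))
  r <- read_variants(f)
  expect_identical(nrow(r), 3L)
  expect_identical(r$genotype_class, c("het", "hom_alt", "missing"))
  expect_identical(r$pos, c(101L, 205L, 50L))
  expect_identical(r$depth, c(15L, 31L, 7L))
  expect_equal(r$qual, c(50, 88, 12))
  expect_true(all(r$is_snp))
})

test_that("simulated genomes survive a full VCF round-trip", {
  g <- quick_genome(len = 5e5, theta = 400, target_F = 0.2, seed = 31,
                    depth_tile = 100)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g$variants, f)
  r <- read_variants(f)
  expect_identical(nrow(r), nrow(g$variants))
  expect_identical(r$pos, g$variants$pos)
  expect_identical(r$genotype_class, g$variants$genotype_class)
  expect_identical(r$depth, g$variants$depth)
})

test_that("mean_genome_depth is length-weighted and rejects empty tracks", {
  t1 <- data.frame(scaffold = "s", start = 0L, end = 1000L, depth = 30)
  expect_identical(mean_genome_depth(t1), 30)
  t2 <- data.frame(scaffold = "s", start = c(0L, 500L), end = c(500L, 1000L),
                   depth = c(10, 30))
  expect_identical(mean_genome_depth(t2), 20)
  t3 <- data.frame(scaffold = "s", start = c(0L, 900L), end = c(900L, 1000L),
                   depth = c(10, 30))
  expect_identical(mean_genome_depth(t3), 12)
  expect_error(mean_genome_depth(t1[0, ]), "empty")
})

test_that("genotype filters drop low-quality, shallow, too-deep and non-SNP records", {
  pol <- filter_policy()
  expect_identical(nrow(filter_genotypes(toy_variants(qual = 29), pol, 30)), 0L)
  expect_identical(nrow(filter_genotypes(toy_variants(qual = 30), pol, 30)), 5L)
  expect_identical(nrow(filter_genotypes(toy_variants(depth = 61), pol, 30)), 0L)
  expect_identical(nrow(filter_genotypes(toy_variants(depth = 60), pol, 30)), 5L)
  expect_identical(nrow(filter_genotypes(toy_variants(depth = 9), pol, 30)), 0L)
  indel <- toy_variants(n = 1)
  indel$is_snp <- FALSE
  expect_identical(nrow(filter_genotypes(indel, pol, 30)), 0L)
  expect_identical(nrow(filter_genotypes(indel, filter_policy(snps_only = FALSE), 30)), 1L)
})

test_that("filtering agrees with a brute-force per-record recheck and is idempotent", {
  set.seed(77)
  n <- 100
  v <- data.frame(sample = "b", scaffold = "s1", pos = sample.int(1e6, n),
                  genotype_class = sample(c("het", "hom_alt"), n, TRUE),
                  qual = sample(10:120, n, TRUE),
                  depth = rpois(n, 25), is_snp = sample(c(TRUE, FALSE), n, TRUE))
  pol <- filter_policy()
  md <- 25
  got <- filter_genotypes(v, pol, md)
  keep <- logical(n)
  for (i in seq_len(n))       # independent oracle: re-check every record
    keep[i] <- v$qual[i] >= 30 && v$depth[i] >= 10 && v$depth[i] <= 50 &&
      v$is_snp[i]
  expect_identical(nrow(got), sum(keep))
  expect_identical(got$pos, v$pos[keep])
  expect_identical(filter_genotypes(got, pol, md), got)
})

test_that("callability covers exactly the depth-passing positions", {
  sc <- data.frame(scaffold = "s1", length = 10000L)
  pol <- filter_policy(min_depth = 10)
  t30 <- data.frame(scaffold = "s1", start = 0L, end = 10000L, depth = 30)
  expect_identical(build_callability(t30, pol, 30, sc)$total, 10000L)
  t5 <- data.frame(scaffold = "s1", start = 0L, end = 10000L, depth = 5)
  expect_identical(build_callability(t5, pol, 30, sc)$total, 0L)
  # alternating 1-kb blocks of depth 5 and 30 -> half the scaffold callable
  alt <- data.frame(scaffold = "s1", start = seq(0L, 9000L, 1000L),
                    end = seq(1000L, 10000L, 1000L), depth = rep(c(5, 30), 5))
  cal <- build_callability(alt, pol, 30, sc)
  expect_identical(cal$total, 5000L)
  expect_identical(nrow(cal$intervals), 5L)
  out <- data.frame(scaffold = "s1", start = 9500L, end = 10500L, depth = 30)
  expect_error(build_callability(out, pol, 30, sc), "outside scaffold bounds")
})

test_that("callable site count never increases with the minimum depth", {
  g <- quick_genome(len = 2e5, theta = 0, depth_tile = 1, seed = 15,
                    hom_alt_factor = 0)
  sc <- one_scaffold(2e5)
  md <- mean_genome_depth(g$depth)
  totals <- vapply(4:20, function(d)
    build_callability(g$depth, filter_policy(min_depth = d), md, sc)$total, 0)
  expect_true(all(diff(totals) <= 0))
})
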