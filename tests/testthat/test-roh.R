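window_fixture <- function(counts, scaffold = "s1", wsize = 1e5) {
  n <- length(counts)
  data.frame(scaffold = rep_len(scaffold, n),
             start = (seq_len(n) - 1) * wsize,
             end = seq_len(n) * wsize, het_count = as.integer(counts))
}

test_that("F_ROH is the proportion of zero-het windows", {
  lab <- window_roh(window_fixture(c(0, 2, 0, 1)))
  expect_equal(lab$F_ROH, 0.5)
  expect_identical(lab$windows$roh, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(window_roh(window_fixture(c(0, 0, 0)))$F_ROH, 1)
  expect_equal(window_roh(window_fixture(c(0, 2, 0, 1), wsize = 1e5),
                          max_het = 1)$F_ROH, 0.75)
  expect_error(window_roh(window_fixture(integer(0))), "zero complete windows")
})

test_that("window labels agree with a brute-force per-window recount", {
  g <- quick_genome(len = 7e6, theta = 300, target_F = 0.4, seed = 81,
                    depth_tile = 1e5)
  het <- het_sites(g$variants)
  w <- window_het_counts(het, one_scaffold(7e6))
  lab <- window_roh(w)
  for (i in seq_len(nrow(w))) {    # oracle: recount every window directly
    n_i <- sum(het$pos >= w$start[i] & het$pos < w$end[i])
    expect_identical(w$het_count[i], n_i)
    expect_identical(lab$windows$roh[i], n_i == 0L)
  }
  expect_equal(lab$F_ROH, lab$n_roh / lab$n_windows)
})

test_that("merging consecutive ROH windows conserves labelled length", {
  runs <- merge_runs(window_roh(window_fixture(c(0, 0, 3, 0))))
  expect_identical(runs$length, c(200000, 100000))
  expect_identical(runs$start, c(0, 300000))
  none <- merge_runs(window_roh(window_fixture(c(1, 2))))
  expect_identical(nrow(none), 0L)
  set.seed(9)
  for (rep in 1:5) {
    counts <- rbinom(50, 2, 0.4)
    lab <- window_roh(window_fixture(counts))
    runs <- merge_runs(lab)
    expect_equal(sum(runs$length), lab$n_roh * 1e5)
    if (nrow(runs) > 1)
      expect_true(all(runs$start[-1] > runs$end[-nrow(runs)]))
  }
})

test_that("runs never cross scaffold boundaries", {
  w <- rbind(window_fixture(c(0, 0), "a"), window_fixture(c(0, 1), "b"))
  runs <- merge_runs(window_roh(w))
  expect_identical(runs$scaffold, c("a", "b"))
  expect_identical(runs$length, c(200000, 100000))
})

test_that("the 50-site scan finds homozygous stretches and rejects het-dense ones", {
  hom <- data.frame(scaffold = "s1", pos = seq(0L, 299000L, by = 1000L),
                    het = FALSE)
  runs <- scan_roh(hom)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$start, 0L)
  expect_identical(runs$end, 299001L)
  # every 10th of 500 dense sites het -> 5 hets per 50-site window -> nothing
  dense <- data.frame(scaffold = "s1", pos = seq(0L, by = 1000L,
                                                 length.out = 500),
                      het = rep(c(TRUE, rep(FALSE, 9)), 50))
  expect_identical(nrow(scan_roh(dense)), 0L)
  expect_warning(scan_roh(hom[1:10, ]), "fewer than 50")
})

test_that("the scan recovers a planted 2-Mb tract almost exactly", {
  spec <- sim_genome_spec(one_scaffold(1e7), theta = 200, target_F = 0.2,
                          roh_mix = list(p_short = 0, mean_short = 5e5,
                                         mean_long = 2e6),
                          depth_tile = 1e4, seed = 9)
  g <- simulate_diploid_genome(spec)
  runs <- scan_roh(calls_from_variants(g$variants))
  roh <- g$truth$roh
  covered <- 0
  for (i in seq_len(nrow(runs)))
    covered <- covered + sum(pmax(0, pmin(runs$end[i], roh$end) -
                                     pmax(runs$start[i], roh$start)))
  expect_gte(covered / sum(roh$end - roh$start), 0.9)
})

test_that("the length spectrum splits fractions at 1 Mb and accumulates monotonically", {
  runs <- data.frame(length = c(5e5, 2e6))
  sp <- length_spectrum(runs, 1e7)
  expect_equal(sp$short_fraction, 0.05)
  expect_equal(sp$long_fraction, 0.2)
  expect_equal(sp$total_fraction, 0.25)
  expect_true(all(diff(sp$curve$cum_fraction) >= 0))
  empty <- length_spectrum(data.frame(length = numeric(0)), 1e7)
  expect_equal(empty$total_fraction, 0)
  expect_error(length_spectrum(runs, 0), "genome_length")
  g <- quick_genome(len = 2e7, theta = 300, target_F = 0.5, seed = 91,
                    depth_tile = 1e5)
  w <- window_het_counts(het_sites(g$variants), one_scaffold(2e7))
  lab <- window_roh(w)
  sp2 <- length_spectrum(merge_runs(lab), 2e7)
  expect_equal(sp2$total_fraction, lab$F_ROH)
})

test_that("method comparison needs 3 individuals and handles constant estimates", {
  Fm <- data.frame(window = c(0.1, 0.4, 0.7), scan = c(0.12, 0.45, 0.66))
  cmp <- compare_methods(Fm)
  expect_equal(cmp$correlations["window", "scan"],
               stats::cor(Fm$window, Fm$scan))
  expect_equal(unname(cmp$means), c(0.4, 0.41))
  ident <- data.frame(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3))
  expect_equal(compare_methods(ident)$correlations["a", "b"], 1)
  const <- data.frame(a = c(0.1, 0.2, 0.3), b = rep(0.5, 3))
  expect_true(is.na(compare_methods(const)$correlations["a", "b"]))
  expect_error(compare_methods(Fm[1:2, ]), "at least 3")
})

test_that("thinned coverage never lowers the window-method inbreeding estimate", {
  sc <- one_scaffold(5e6)
  g <- quick_genome(len = 5e6, theta = 200, target_F = 0.3, seed = 95,
                    depth_tile = 1)
  pol <- filter_policy()
  f_at <- function(track, variants) {
    md <- mean_genome_depth(track)
    filt <- filter_genotypes(variants, pol, md)
    window_roh(window_het_counts(het_sites(filt), sc))$F_ROH
  }
  thin <- thin_depth(g$depth, 0.4, seed = 96)
  vthin <- g$variants
  vthin$depth <- thin$depth[vthin$pos]
  expect_gte(f_at(thin, vthin), f_at(g$depth, g$variants))
})
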