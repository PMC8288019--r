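#' Simulate per-scaffold mean coverage for a female and a male
#'
#' Draws independent Poisson per-site depths for both sexes under the
#' scaffold-class copy-number design (autosome 2/2, X 2/1, Y 0/1 for
#' female/male) and summarises each scaffold by its mean depth per
#' individual.
#' The female:male ratio of these means concentrates at ~1 for autosomes,
#' ~2 for X-linked and ~0 for Y-linked scaffolds, which is the signal the
#' coverage-based sex classification exploits.
#'
#' @param scaffolds scaffold table with `scaffold`, `length` and `class`
#'   columns (`class` in autosome/X/Y).
#' @param mean_depth mean autosomal per-site depth (applies to both sexes).
#' @param n_sites number of sites sampled per scaffold (must be > 0).
#' @param seed integer seed.
#' @return data.frame with `scaffold`, `length`, `class`, `female_depth`,
#'   `male_depth` (per-scaffold means over `n_sites` sites).
#' @export
simulate_sex_coverage <- function(scaffolds, mean_depth = 30,
                                  n_sites = 10000, seed = NULL) {
  check_scaffold_table(scaffolds)
  if (is.null(scaffolds$class)) scaffolds$class <- "autosome"
  if (n_sites <= 0) stopf("n_sites must be > 0")
  cf <- scaffold_copy_number(scaffolds, "female")
  cm <- scaffold_copy_number(scaffolds, "male")
  with_seed(seed, {
    fd <- vapply(cf, function(cp) mean(rpois(n_sites, mean_depth * cp / 2)), 0)
    md <- vapply(cm, function(cp) mean(rpois(n_sites, mean_depth * cp / 2)), 0)
    data.frame(scaffold = scaffolds$scaffold, length = scaffolds$length,
               class = scaffolds$class, female_depth = fd, male_depth = md)
  })
}

#' Binomially thin a depth track
#'
#' Emulates downsampling of a sequencing library at the depth-track level:
#' the depth of each track interval is replaced by a
#' `Binomial(depth, retention)` draw (per site when the track is per-base),
#' so mean depth scales by `retention`.
#'
#' @param depth depth track data.frame (`scaffold`, `start`, `end`, `depth`).
#' @param retention retained fraction, in (0, 1]. `retention = 1` returns the
#'   track unchanged.
#' @param seed integer seed.
#' @return a depth track of the same shape with thinned depths.
#' @export
thin_depth <- function(depth, retention, seed = NULL) {
  if (!is.numeric(retention) || length(retention) != 1 ||
      retention <= 0 || retention > 1)
    stopf("retention must be a single value in (0, 1]")
  if (retention == 1) return(depth)
  with_seed(seed, {
    depth$depth <- rbinom(nrow(depth), depth$depth, retention)
    depth
  })
}
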