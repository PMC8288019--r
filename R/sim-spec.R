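#' Specification of a synthetic diploid genome
#'
#' Bundles all parameters of the synthetic-data generator: scaffold layout
#' (with autosome/X/Y classes), the background heterozygosity rate, the
#' target fraction of the genome planted as autozygous (ROH) tracts, the
#' tract-length mixture, clustered gene families with heterozygosity
#' multipliers, and the per-site Poisson depth model.
#'
#' @param scaffolds data.frame with columns `scaffold`, `length` (bp) and
#'   optionally `class` (one of `"autosome"`, `"X"`, `"Y"`; defaults to
#'   autosome). Copy numbers follow the mammalian design: autosomes 2/2
#'   (female/male), X 2/1, Y 0/1.
#' @param theta background heterozygosity rate in heterozygous sites per Mb
#'   on non-ROH sequence.
#' @param target_F target fraction of the autosomal genome covered by
#'   planted ROH tracts, in \[0, 1\].
#' @param roh_mix tract-length mixture: a list with `p_short`,
#'   `mean_short` and `mean_long` (bp). Tract lengths are drawn from a
#'   two-component exponential mixture, mimicking the short (< 1 Mb) versus
#'   long (> 1 Mb) ROH dichotomy of recent versus ancient inbreeding.
#' @param gene_sets list of gene-set descriptors built with [gene_set()].
#' @param mean_depth mean autosomal per-site read depth of the simulated
#'   individual. Per-site depth is Poisson with mean
#'   `mean_depth * copy_number / 2`.
#' @param hom_alt_factor rate of homozygous-alternative sites, as a multiple
#'   of `theta`; these are emitted genome-wide (including inside ROH) so that
#'   the "heterozygous sites only" filter is exercised downstream.
#' @param sex `"female"` or `"male"`; controls X/Y copy numbers.
#' @param qual_mean,qual_sd mean and sd of the Gaussian used for per-site
#'   Phred variant qualities (essentially all sites clear a Q30 filter at
#'   the defaults).
#' @param depth_tile tile width (bp) of the emitted depth track. `1` draws
#'   an independent Poisson depth for every base; larger tiles draw one
#'   depth per tile, keeping tracks small for large genomes.
#' @param seed integer seed; the whole simulation is reproducible from it.
#'
#' @return An object of class `sim_genome_spec` (a validated list).
#' @seealso [simulate_diploid_genome()], [gene_set()]
#' @export
sim_genome_spec <- function(scaffolds,
                            theta = 200,
                            target_F = 0,
                            roh_mix = list(p_short = 0.5,
                                           mean_short = 5e5,
                                           mean_long = 5e6),
                            gene_sets = list(),
                            mean_depth = 30,
                            hom_alt_factor = 0.5,
                            sex = c("female", "male"),
                            qual_mean = 90,
                            qual_sd = 15,
                            depth_tile = 1L,
                            seed = 1L) {
  check_scaffold_table(scaffolds)
  if (is.null(scaffolds$class)) scaffolds$class <- "autosome"
  if (!all(scaffolds$class %in% c("autosome", "X", "Y")))
    stopf("scaffold class must be autosome, X or Y")
  if (theta < 0) stopf("theta must be >= 0")
  if (target_F < 0 || target_F > 1) stopf("target_F must be in [0, 1]")
  stopifnot(is.list(roh_mix),
            roh_mix$p_short >= 0, roh_mix$p_short <= 1,
            roh_mix$mean_short > 0, roh_mix$mean_long > 0)
  if (mean_depth < 0) stopf("mean_depth must be >= 0")
  if (hom_alt_factor < 0) stopf("hom_alt_factor must be >= 0")
  for (gs in gene_sets) {
    if (!inherits(gs, "rohscape_gene_set")) stopf("gene_sets entries must be gene_set() objects")
    if (gs$het_multiplier < 0) stopf("het_multiplier must be >= 0")
  }
  if (depth_tile < 1) stopf("depth_tile must be >= 1")
  spec <- list(scaffolds = scaffolds, theta = theta, target_F = target_F,
               roh_mix = roh_mix, gene_sets = gene_sets,
               mean_depth = mean_depth, hom_alt_factor = hom_alt_factor,
               sex = match.arg(sex), qual_mean = qual_mean, qual_sd = qual_sd,
               depth_tile = as.integer(depth_tile), seed = as.integer(seed))
  class(spec) <- "sim_genome_spec"
  spec
}

#' Describe a clustered gene family for the genome simulator
#'
#' Genes of a set are laid out as one contiguous cluster on a single
#' scaffold, each gene contributing `exons_per_gene` exons of `exon_len` bp
#' separated by `intron_len` bp, with `gene_gap` bp between genes. Exons
#' carry heterozygous sites at `het_multiplier` times the background rate,
#' emulating balancing-selection hotspots such as MHC class I. With
#' `roh_avoidance = TRUE` the cluster is placed rejecting any overlap with
#' planted ROH tracts, creating a true exon-in-ROH deficiency for power
#' studies of the permutation test.
#'
#' @param name gene-set label (used in exon names `set:gene:exon`).
#' @param n_genes,exons_per_gene,exon_len,intron_len,gene_gap cluster layout
#'   in bp.
#' @param het_multiplier multiplicative factor on the background rate inside
#'   exons (>= 0).
#' @param roh_avoidance if `TRUE`, reject cluster placements overlapping
#'   planted ROH.
#' @param scaffold scaffold to place the cluster on (default: a random
#'   autosome long enough to hold it).
#' @param cluster_start optional fixed 0-based start; placement fails
#'   explicitly if the cluster would exceed the scaffold bounds.
#' @return An object of class `rohscape_gene_set`.
#' @export
gene_set <- function(name, n_genes, exons_per_gene = 5, exon_len = 300,
                     intron_len = 2000, gene_gap = 20000,
                     het_multiplier = 1, roh_avoidance = FALSE,
                     scaffold = NULL, cluster_start = NULL) {
  stopifnot(n_genes >= 1, exons_per_gene >= 1, exon_len >= 1,
            intron_len >= 0, gene_gap >= 0, het_multiplier >= 0)
  structure(list(name = name, n_genes = n_genes,
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 intron_len = intron_len, gene_gap = gene_gap,
                 het_multiplier = het_multiplier,
                 roh_avoidance = isTRUE(roh_avoidance),
                 scaffold = scaffold, cluster_start = cluster_start),
            class = "rohscape_gene_set")
}

# copy number of each scaffold for an individual of the given sex
scaffold_copy_number <- function(scaffolds, sex) {
  cls <- scaffolds$class
  if (sex == "female") ifelse(cls == "autosome", 2L, ifelse(cls == "X", 2L, 0L))
  else ifelse(cls == "autosome", 2L, 1L)
}

# total span of one gene cluster in bp
cluster_span <- function(gs) {
  gene_len <- gs$exons_per_gene * gs$exon_len +
    (gs$exons_per_gene - 1) * gs$intron_len
  gs$n_genes * gene_len + (gs$n_genes - 1) * gs$gene_gap
}
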