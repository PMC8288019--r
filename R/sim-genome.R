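#' Simulate a diploid genome with planted ROH and known truth
#'
#' Generates a single individual's variant calls, depth track, exon
#' annotations and scaffold table under a fully specified generative model:
#'
#' * Autozygous (ROH) tracts are drawn from the configured exponential
#'   length mixture and planted, non-overlapping, until the realized autosomal
#'   fraction reaches `target_F` (the last tract is trimmed so the realized
#'   fraction matches the target to the base pair).
#' * Heterozygous sites arise as a homogeneous Poisson process at rate
#'   `theta` per Mb outside ROH, `theta * het_multiplier` inside gene-set
#'   exons (outside ROH), and exactly 0 inside ROH tracts.
#' * Homozygous-alternative sites arise genome-wide at
#'   `hom_alt_factor * theta` per Mb, ROH included.
#' * Per-site depth is Poisson with mean `mean_depth * copy_number / 2`
#'   (autosome 2, X 2 in females / 1 in males, Y 0 in females / 1 in males),
#'   emitted as a BEDGRAPH-style track at `depth_tile` resolution. Depths in
#'   the variant records are read from the same track, so numerator and
#'   denominator filters stay consistent downstream.
#'
#' @param spec a [sim_genome_spec()].
#' @param sample_id sample name recorded in the variant table.
#' @return A list of class `sim_genome` with elements `variants` (one row
#'   per emitted site: scaffold, 1-based `pos`, `genotype_class`, `qual`,
#'   `depth`, `is_snp`, `sample`), `depth` (scaffold/start/end/depth,
#'   0-based half-open), `exons` (BED6-style data.frame), `scaffolds`
#'   (scaffold/length/class) and `truth` — the ground truth: planted ROH
#'   intervals, `theta`, realized `true_F`, per-gene-set realized exon het
#'   rates, per-scaffold sex labels, and the seed.
#' @examples
#' spec <- sim_genome_spec(
#'   data.frame(scaffold = "s1", length = 2e6),
#'   theta = 100, target_F = 0.3, seed = 7, depth_tile = 1000)
#' g <- simulate_diploid_genome(spec)
#' g$truth$true_F
#' @export
simulate_diploid_genome <- function(spec, sample_id = "sim1") {
  stopifnot(inherits(spec, "sim_genome_spec"))
  with_seed(spec$seed, {
    scaffolds <- spec$scaffolds
    copies <- scaffold_copy_number(scaffolds, spec$sex)
    auto <- scaffolds[scaffolds$class == "autosome", , drop = FALSE]

    roh <- draw_roh_tracts(auto, spec$target_F, spec$roh_mix)
    exons <- place_gene_sets(spec, roh)

    diploid <- scaffolds$scaffold[copies == 2L]
    het <- place_het_sites(spec, roh, exons, diploid)
    hom <- place_hom_alt_sites(spec, diploid, het)

    depth <- draw_depth_track(scaffolds, copies, spec$mean_depth, spec$depth_tile)
    variants <- assemble_variants(het, hom, depth, spec, sample_id)

    # hard invariant: planted ROH contain no heterozygous site
    if (points_in_intervals(het, roh) > 0L)
      stopf("internal error: heterozygous site inside planted ROH")

    truth <- list(
      roh = roh,
      theta = spec$theta,
      true_F = if (nrow(auto)) sum(roh$end - roh$start) / sum(auto$length) else 0,
      gene_truth = gene_truth_table(spec, exons, het),
      sex_labels = data.frame(scaffold = scaffolds$scaffold,
                              class = scaffolds$class),
      seed = spec$seed
    )
    structure(list(variants = variants, depth = depth, exons = exons,
                   scaffolds = scaffolds, truth = truth,
                   sample_id = sample_id),
              class = "sim_genome")
  })
}

# Draw one tract length from the exponential mixture
rtract_lengths <- function(n, mix) {
  short <- runif(n) < mix$p_short
  len <- numeric(n)
  len[short] <- rexp(sum(short), 1 / mix$mean_short)
  len[!short] <- rexp(sum(!short), 1 / mix$mean_long)
  pmax(1, round(len))
}

# Plant non-overlapping ROH tracts on the autosomes. Tracts are assigned to
# scaffolds with probability proportional to remaining free space; the last
# tract is trimmed so the planted total equals round(target_F * total)
# exactly. Within each scaffold, gaps between tracts follow a broken-stick
# (uniform Dirichlet) partition of the free sequence, i.e. placement is
# uniform among non-overlapping arrangements.
draw_roh_tracts <- function(auto, target_F, mix) {
  if (nrow(auto) == 0 || target_F == 0) return(empty_intervals())
  total <- sum(auto$length)
  target <- round(target_F * total)
  if (target == 0) return(empty_intervals())

  means <- c(if (mix$p_short > 0) mix$mean_short,
             if (mix$p_short < 1) mix$mean_long)
  if (min(means) > max(auto$length))
    stopf(paste0("target_F unreachable: mean ROH tract length (%g bp) ",
                 "exceeds the longest autosomal scaffold (%g bp)"),
          min(means), max(auto$length))
  free <- as.numeric(auto$length)
  names(free) <- auto$scaffold
  lens <- list()
  planted <- 0
  failures <- 0L
  while (planted < target) {
    l <- rtract_lengths(1L, mix)
    l <- min(l, target - planted)
    open <- which(free >= l)
    if (!length(open)) {
      failures <- failures + 1L
      if (failures > 2000L)
        stopf(paste0("target_F = %g unreachable: tract lengths from the ",
                     "mixture (means %g / %g bp) do not fit the remaining ",
                     "scaffold space"), target_F, mix$mean_short, mix$mean_long)
      next
    }
    s <- if (length(open) == 1L) open else
      sample(open, 1L, prob = free[open])
    lens[[length(lens) + 1L]] <- c(s, l)
    free[s] <- free[s] - l
    planted <- planted + l
  }

  m <- do.call(rbind, lens)
  out <- vector("list", nrow(auto))
  for (i in seq_len(nrow(auto))) {
    ls <- m[m[, 1] == i, 2]
    if (!length(ls)) next
    k <- length(ls)
    if (k > 1) ls <- sample(ls)           # exchangeable order
    freeL <- auto$length[i] - sum(ls)
    g <- rexp(k + 1)
    cuts <- cumsum(g) / sum(g) * freeL
    cuts <- round(c(0, cuts))
    cuts[k + 2] <- freeL
    gaps <- diff(cuts)
    starts <- cumsum(c(0, ls[-k])) + cumsum(gaps[seq_len(k)])
    out[[i]] <- data.frame(scaffold = auto$scaffold[i],
                           start = starts, end = starts + ls)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  # merge tracts that touch after rounding so truth intervals stay disjoint
  merged <- lapply(split(res, res$scaffold), function(x) {
    ir <- IRanges::reduce(as_iranges(x$start, x$end))
    ranges_to_df(ir, x$scaffold[1])
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  res
}

# Lay out each gene-set cluster; explicit failure when a fixed cluster
# exceeds scaffold bounds, or when roh_avoidance cannot be satisfied.
place_gene_sets <- function(spec, roh) {
  if (!length(spec$gene_sets))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      set = character(0)))
  auto <- spec$scaffolds[spec$scaffolds$class == "autosome", , drop = FALSE]
  roh_by_scaf <- split_ranges(roh)
  occupied <- list()  # avoid cluster-on-cluster overlap
  out <- list()
  for (gs in spec$gene_sets) {
    span <- cluster_span(gs)
    cand <- if (is.null(gs$scaffold)) auto$scaffold[auto$length > span]
            else gs$scaffold
    if (!length(cand))
      stopf("gene set '%s': no autosomal scaffold can hold its %d-bp cluster",
            gs$name, span)
    placed <- FALSE
    for (try in seq_len(5000L)) {
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      slen <- spec$scaffolds$length[spec$scaffolds$scaffold == s]
      if (!length(slen)) stopf("gene set '%s': unknown scaffold '%s'", gs$name, s)
      start <- if (!is.null(gs$cluster_start)) gs$cluster_start
               else floor(runif(1, 0, slen - span))
      if (start < 0 || start + span > slen)
        stopf("gene set '%s': cluster [%d, %d) exceeds scaffold '%s' bounds (%d bp)",
              gs$name, start, start + span, s, slen)
      cl <- IRanges::IRanges(start = start + 1L, width = span)
      clash <- (!is.null(occupied[[s]]) &&
                  sum(IRanges::countOverlaps(cl, occupied[[s]])) > 0)
      roh_hit <- (gs$roh_avoidance && !is.null(roh_by_scaf[[s]]) &&
                    sum(IRanges::countOverlaps(cl, roh_by_scaf[[s]])) > 0)
      if (!clash && !roh_hit) {
        occupied[[s]] <- if (is.null(occupied[[s]])) cl else c(occupied[[s]], cl)
        out[[gs$name]] <- cluster_exons(gs, s, start)
        placed <- TRUE
        break
      }
      if (!is.null(gs$cluster_start))
        stopf("gene set '%s': fixed position overlaps %s", gs$name,
              if (clash) "another cluster" else "planted ROH")
    }
    if (!placed)
      stopf("gene set '%s': could not place cluster avoiding ROH after 5000 tries",
            gs$name)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cluster_exons <- function(gs, scaffold, cluster_start) {
  gene_len <- gs$exons_per_gene * gs$exon_len +
    (gs$exons_per_gene - 1) * gs$intron_len
  rows <- list()
  for (g in seq_len(gs$n_genes)) {
    g0 <- cluster_start + (g - 1) * (gene_len + gs$gene_gap)
    e0 <- g0 + (seq_len(gs$exons_per_gene) - 1) * (gs$exon_len + gs$intron_len)
    rows[[g]] <- data.frame(
      scaffold = scaffold, start = e0, end = e0 + gs$exon_len,
      name = sprintf("%s:g%d:e%d", gs$name, g, seq_len(gs$exons_per_gene)),
      score = 0L, strand = "+", set = gs$name)
  }
  do.call(rbind, rows)
}

# Poisson point process at piecewise-constant rates: theta outside ROH,
# theta * multiplier on exon sequence outside ROH, 0 inside ROH.
place_het_sites <- function(spec, roh, exons, diploid) {
  theta_bp <- spec$theta / 1e6
  pts <- list()
  for (s in diploid) {
    slen <- spec$scaffolds$length[spec$scaffolds$scaffold == s]
    full <- IRanges::IRanges(start = 1L, end = as.integer(slen))
    roh_s <- roh[roh$scaffold == s, , drop = FALSE]
    nonroh <- if (nrow(roh_s)) IRanges::setdiff(full, as_iranges(roh_s$start, roh_s$end))
              else full
    segs <- list(list(ir = nonroh, rate = theta_bp))
    ex_s <- exons[exons$scaffold == s, , drop = FALSE]
    for (set in unique(ex_s$set)) {
      gs <- Filter(function(g) g$name == set, spec$gene_sets)[[1]]
      if (gs$het_multiplier == 1) next
      ex_ir <- IRanges::reduce(as_iranges(ex_s$start[ex_s$set == set],
                                          ex_s$end[ex_s$set == set]))
      hot <- IRanges::intersect(ex_ir, nonroh)
      if (!length(hot)) next
      segs[[1]]$ir <- IRanges::setdiff(segs[[1]]$ir, hot)
      segs[[length(segs) + 1L]] <- list(ir = hot, rate = theta_bp * gs$het_multiplier)
    }
    pos <- unlist(lapply(segs, function(sg) sample_poisson_points(sg$ir, sg$rate)))
    if (length(pos))
      pts[[s]] <- data.frame(scaffold = s, pos = sort(unique(pos)))
  }
  if (!length(pts)) return(data.frame(scaffold = character(0), pos = integer(0)))
  res <- do.call(rbind, pts)
  rownames(res) <- NULL
  res
}

# Uniform points at `rate` per bp inside an IRanges (returns 0-based positions)
sample_poisson_points <- function(ir, rate) {
  if (!length(ir) || rate <= 0) return(integer(0))
  w <- IRanges::width(ir)
  n <- rpois(length(ir), w * rate)
  idx <- rep(seq_along(ir), n)
  if (!length(idx)) return(integer(0))
  s0 <- IRanges::start(ir)[idx] - 1L
  unique(s0 + floor(runif(length(idx)) * w[idx]))
}

place_hom_alt_sites <- function(spec, diploid, het) {
  rate <- spec$hom_alt_factor * spec$theta / 1e6
  pts <- list()
  for (s in diploid) {
    slen <- spec$scaffolds$length[spec$scaffolds$scaffold == s]
    pos <- sample_poisson_points(IRanges::IRanges(1L, as.integer(slen)), rate)
    pos <- setdiff(pos, het$pos[het$scaffold == s])
    if (length(pos)) pts[[s]] <- data.frame(scaffold = s, pos = sort(pos))
  }
  if (!length(pts)) return(data.frame(scaffold = character(0), pos = integer(0)))
  res <- do.call(rbind, pts)
  rownames(res) <- NULL
  res
}

draw_depth_track <- function(scaffolds, copies, mean_depth, tile) {
  rows <- vector("list", nrow(scaffolds))
  for (i in seq_len(nrow(scaffolds))) {
    slen <- scaffolds$length[i]
    mu <- mean_depth * copies[i] / 2
    n <- ceiling(slen / tile)
    d <- if (mu > 0) rpois(n, mu) else integer(n)
    start <- (seq_len(n) - 1L) * tile
    rows[[i]] <- data.frame(scaffold = scaffolds$scaffold[i],
                            start = start,
                            end = pmin(start + tile, slen),
                            depth = d)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# depth of a 0-based position, looked up from a tiled track
depth_at <- function(depth, scaffold, pos, tile) {
  out <- integer(length(pos))
  for (s in unique(scaffold)) {
    sel <- scaffold == s
    ds <- depth[depth$scaffold == s, , drop = FALSE]
    out[sel] <- ds$depth[pos[sel] %/% tile + 1L]
  }
  out
}

assemble_variants <- function(het, hom, depth, spec, sample_id) {
  n_het <- nrow(het)
  n_hom <- nrow(hom)
  v <- data.frame(
    sample = rep(sample_id, n_het + n_hom),
    scaffold = c(het$scaffold, hom$scaffold),
    pos = as.integer(c(het$pos, hom$pos)) + 1L,   # VCF 1-based
    genotype_class = c(rep("het", n_het), rep("hom_alt", n_hom)),
    stringsAsFactors = FALSE)
  v <- v[order(v$scaffold, v$pos), , drop = FALSE]
  v$qual <- pmax(1, round(rnorm(nrow(v), spec$qual_mean, spec$qual_sd)))
  v$depth <- depth_at(depth, v$scaffold, v$pos - 1L, spec$depth_tile)
  v$is_snp <- rep(TRUE, nrow(v))
  rownames(v) <- NULL
  v
}

gene_truth_table <- function(spec, exons, het) {
  if (!length(spec$gene_sets)) {
    return(data.frame(set = character(0), het_multiplier = numeric(0),
                      exon_bp = integer(0), n_het = integer(0),
                      rate_snps_per_mb = numeric(0)))
  }
  rows <- lapply(spec$gene_sets, function(gs) {
    ex <- exons[exons$set == gs$name, , drop = FALSE]
    bp <- sum(ex$end - ex$start)
    nh <- points_in_intervals(data.frame(scaffold = het$scaffold, pos = het$pos), ex)
    data.frame(set = gs$name, het_multiplier = gs$het_multiplier,
               roh_avoidance = gs$roh_avoidance,
               exon_bp = bp, n_het = nh,
               rate_snps_per_mb = nh * 1e6 / bp)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Extract heterozygous-site positions from a variant table
#'
#' @param variants a variant data.frame (from [simulate_diploid_genome()],
#'   [read_variants()] or [filter_genotypes()]).
#' @return data.frame with `scaffold` and 0-based `pos` of heterozygous SNVs.
#' @export
het_sites <- function(variants) {
  h <- variants[variants$genotype_class == "het", , drop = FALSE]
  data.frame(scaffold = h$scaffold, pos = h$pos - 1L)
}
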