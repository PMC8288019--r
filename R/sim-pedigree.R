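#' Simulate realized autozygosity in a pedigree with Poisson recombination
#'
#' Tracks founder alleles through meioses to measure the realized autozygous
#' fraction of offspring genomes. Each offspring comes from an independent
#' replicate of the pedigree: founders carry globally unique allele labels,
#' gametes are formed with a Poisson number of crossovers placed uniformly in
#' genetic distance (no interference, uniform recombination rate along each
#' chromosome), and the offspring's autozygous fraction is the physical
#' fraction of the genome where the maternal and paternal haplotypes descend
#' from the same founder allele.
#'
#' For a full-sib mating the expected autozygous fraction is the classical
#' inbreeding coefficient of offspring of first-degree relatives, 0.25; for
#' selfing of a non-inbred founder it is 0.5. The realized fraction varies
#' around that expectation, the more so the fewer Morgans the genome has.
#'
#' @param n_offspring number of independent offspring to simulate.
#' @param chrom_map data.frame with columns `phys_bp` (physical length in bp)
#'   and `morgans` (genetic length) — one row per chromosome.
#' @param mating `"full_sib"` (two founder parents, two sibs, one offspring
#'   per replicate) or `"self"` (one founder selfed).
#' @param seed integer seed.
#' @param keep_segments if `TRUE`, also return the autozygous intervals of
#'   every offspring (0-based half-open, per chromosome), e.g. to rebuild a
#'   synthetic genome from them.
#' @return list of class `pedigree_ibd` with `F` (numeric vector of realized
#'   autozygous fractions), `chrom_map`, `mating`, and — if requested —
#'   `segments`, a list of per-offspring data.frames
#'   (`chrom`, `start`, `end`).
#' @examples
#' ped <- simulate_pedigree_ibd(200,
#'   data.frame(phys_bp = 1e7, morgans = 1), seed = 1)
#' mean(ped$F)  # near 0.25
#' @export
simulate_pedigree_ibd <- function(n_offspring, chrom_map,
                                  mating = c("full_sib", "self"),
                                  seed = NULL, keep_segments = FALSE) {
  mating <- match.arg(mating)
  if (!is.data.frame(chrom_map) || nrow(chrom_map) == 0)
    stopf("chrom_map must be a non-empty data.frame(phys_bp, morgans)")
  if (!all(c("phys_bp", "morgans") %in% names(chrom_map)))
    stopf("chrom_map needs columns 'phys_bp' and 'morgans'")
  if (any(chrom_map$phys_bp <= 0) || any(chrom_map$morgans < 0))
    stopf("physical lengths must be > 0 and genetic lengths >= 0")
  n_offspring <- as.integer(n_offspring)
  stopifnot(n_offspring >= 1)

  with_seed(seed, {
    total_bp <- sum(chrom_map$phys_bp)
    Fv <- numeric(n_offspring)
    segs <- if (keep_segments) vector("list", n_offspring)
    founder <- function(lab, L) list(ends = L, labels = lab)
    for (i in seq_len(n_offspring)) {
      shared_bp <- 0
      ch <- st <- en <- list()
      for (ci in seq_len(nrow(chrom_map))) {
        L <- chrom_map$phys_bp[ci]
        G <- chrom_map$morgans[ci]
        if (mating == "full_sib") {
          o1 <- meiosis(meiosis(founder(1L, L), founder(2L, L), G, L),
                        meiosis(founder(3L, L), founder(4L, L), G, L), G, L)
          o2 <- meiosis(meiosis(founder(1L, L), founder(2L, L), G, L),
                        meiosis(founder(3L, L), founder(4L, L), G, L), G, L)
        } else {
          o1 <- meiosis(founder(1L, L), founder(2L, L), G, L)
          o2 <- meiosis(founder(1L, L), founder(2L, L), G, L)
        }
        sh <- shared_segments(o1, o2)
        shared_bp <- shared_bp + sum(sh$end - sh$start)
        if (keep_segments && length(sh$start)) {
          k <- length(ch) + 1L
          ch[[k]] <- rep(sprintf("chr%d", ci), length(sh$start))
          st[[k]] <- sh$start
          en[[k]] <- sh$end
        }
      }
      Fv[i] <- shared_bp / total_bp
      if (keep_segments)
        segs[[i]] <- data.frame(chrom = unlist(ch) %||% character(0),
                                start = unlist(st) %||% numeric(0),
                                end = unlist(en) %||% numeric(0))
    }
    out <- list(F = Fv, chrom_map = chrom_map, mating = mating, seed = seed)
    if (keep_segments) out$segments <- segs
    class(out) <- "pedigree_ibd"
    out
  })
}

# One meiosis: recombine the parent's two haplotypes. Haplotypes are
# piecewise-constant founder-label tracks: list(ends, labels) with `ends`
# the increasing physical segment end positions (last = L).
meiosis <- function(h1, h2, G, L) {
  ncx <- rpois(1L, G)
  if (ncx == 0L) return(if (runif(1) < 0.5) h1 else h2)
  bounds <- c(0, sort(runif(ncx)) * L, L)
  cur <- sample.int(2L, 1L)
  ends <- numeric(0)
  labels <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    if (b <= a) { cur <- 3L - cur; next }
    h <- if (cur == 1L) h1 else h2
    starts_h <- c(0, h$ends[-length(h$ends)])
    j <- which(h$ends > a & starts_h < b)
    ends <- c(ends, pmin(h$ends[j], b))
    labels <- c(labels, h$labels[j])
    cur <- 3L - cur
  }
  keep <- c(labels[-1L] != labels[-length(labels)], TRUE)
  list(ends = ends[keep], labels = labels[keep])
}

# Intervals where two label tracks agree (0-based half-open, numeric bp)
shared_segments <- function(hA, hB) {
  ends <- sort(unique(c(hA$ends, hB$ends)))
  starts <- c(0, ends[-length(ends)])
  mid <- (starts + ends) / 2
  la <- hA$labels[findInterval(mid, hA$ends) + 1L]
  lb <- hB$labels[findInterval(mid, hB$ends) + 1L]
  same <- la == lb
  if (!any(same)) return(list(start = numeric(0), end = numeric(0)))
  # merge adjacent shared pieces
  r <- rle(same)
  hi <- cumsum(r$lengths)
  lo <- c(1L, head(hi, -1L) + 1L)
  keep <- which(r$values)
  list(start = starts[lo[keep]], end = ends[hi[keep]])
}

#' Window-based F_ROH re-estimation on simulated pedigree genomes
#'
#' Rebuilds each offspring genome as a heterozygosity landscape — Poisson
#' heterozygous sites at rate `theta` per Mb outside the realized
#' autozygous segments, none inside — and re-estimates the inbreeding
#' fraction as the proportion of complete windows with zero heterozygous
#' sites. Used to check that the window method recovers the known
#' per-offspring autozygous fraction.
#'
#' @param ped a `pedigree_ibd` simulated with `keep_segments = TRUE`.
#' @param theta background heterozygosity rate (SNPs/Mb) outside
#'   autozygous segments.
#' @param window_size window width in bp.
#' @param seed integer seed for the heterozygous-site placement.
#' @return numeric vector of window-method F_ROH estimates, one per
#'   offspring.
#' @export
pedigree_window_F <- function(ped, theta = 200, window_size = 1e5,
                              seed = NULL) {
  stopifnot(inherits(ped, "pedigree_ibd"))
  if (is.null(ped$segments))
    stopf("pedigree was simulated without keep_segments = TRUE")
  cm <- ped$chrom_map
  chroms <- sprintf("chr%d", seq_len(nrow(cm)))
  nwin <- cm$phys_bp %/% window_size
  theta_bp <- theta / 1e6
  with_seed(seed, {
    vapply(ped$segments, function(sg) {
      n_empty <- 0
      for (ci in seq_len(nrow(cm))) {
        if (nwin[ci] == 0) next
        L <- cm$phys_bp[ci]
        pos <- runif(rpois(1L, L * theta_bp)) * L
        s <- sg[sg$chrom == chroms[ci], , drop = FALSE]
        if (nrow(s)) {
          inside <- findInterval(pos, as.vector(rbind(s$start, s$end))) %% 2L == 1L
          pos <- pos[!inside]
        }
        pos <- pos[pos < nwin[ci] * window_size]
        counts <- tabulate(pos %/% window_size + 1L, nbins = nwin[ci])
        n_empty <- n_empty + sum(counts == 0L)
      }
      n_empty / sum(nwin)
    }, 0)
  })
}
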