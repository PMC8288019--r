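#' Genome-wide heterozygosity rate (SNPs/Mb)
#'
#' Rate = heterozygous sites inside callable intervals, times 1e6, divided
#' by the number of callable sites. Numerator and denominator must come
#' from the same individual filtered under the same policy; the function
#' enforces the denominator side by counting only heterozygous sites that
#' fall inside the callability track.
#'
#' @param het heterozygous-site table (`scaffold`, 0-based `pos`), e.g. from
#'   [het_sites()] on filtered records.
#' @param callability a `callability` object from [build_callability()].
#' @return list of class `het_rate`: `n_het`, `n_callable`,
#'   `rate_snps_per_mb`.
#' @export
genome_het_rate <- function(het, callability) {
  stopifnot(inherits(callability, "callability"))
  if (callability$total == 0) stopf("zero callable sites")
  n_het <- points_in_intervals(het, callability$intervals)
  structure(list(n_het = n_het, n_callable = callability$total,
                 rate_snps_per_mb = n_het * 1e6 / callability$total),
            class = "het_rate")
}

#' @export
print.het_rate <- function(x, ...) {
  cat(sprintf("%d het sites / %.0f callable sites = %s SNPs/Mb\n",
              x$n_het, x$n_callable, format_rate(x$rate_snps_per_mb)))
  invisible(x)
}

# paper-style display precision: integers above 100 SNPs/Mb, one decimal below
format_rate <- function(rate) {
  ifelse(rate > 100, sprintf("%.0f", rate), sprintf("%.1f", rate))
}

#' Heterozygosity-rate sensitivity to the minimum depth filter
#'
#' Re-applies the full filter chain at each minimum depth: variant records
#' are re-filtered, the callability track is rebuilt from the depth track,
#' and the rate recomputed, so numerator and denominator always share the
#' same threshold. The callable count is non-increasing in `min_depth`.
#'
#' @param variants variant records of one individual (unfiltered).
#' @param depth the individual's depth track.
#' @param policy base [filter_policy()]; its `min_depth` is overridden by
#'   each value of `depths`.
#' @param scaffolds scaffold table restricting the analysis.
#' @param depths minimum depths to evaluate (default 4 to 20 by 2).
#' @return data.frame with `min_depth`, `n_het`, `n_callable`,
#'   `rate_snps_per_mb`.
#' @export
depth_sweep <- function(variants, depth, policy = filter_policy(), scaffolds,
                        depths = seq(4, 20, by = 2)) {
  md <- mean_genome_depth(depth)
  keep <- variants$scaffold %in% scaffolds$scaffold
  variants <- variants[keep, , drop = FALSE]
  depth <- depth[depth$scaffold %in% scaffolds$scaffold, , drop = FALSE]
  rows <- lapply(depths, function(d) {
    pol <- policy
    pol$min_depth <- d
    filt <- filter_genotypes(variants, pol, md)
    callab <- build_callability(depth, pol, md, scaffolds)
    if (callab$total == 0) {
      data.frame(min_depth = d, n_het = 0L, n_callable = 0,
                 rate_snps_per_mb = NA_real_)
    } else {
      hr <- genome_het_rate(het_sites(filt), callab)
      data.frame(min_depth = d, n_het = hr$n_het, n_callable = hr$n_callable,
                 rate_snps_per_mb = hr$rate_snps_per_mb)
    }
  })
  do.call(rbind, rows)
}

#' Tile scaffolds into complete fixed-size windows
#'
#' Windows are anchored at scaffold coordinate 0; the partial remainder at
#' each scaffold end is dropped. Scaffolds shorter than one window
#' contribute no windows.
#'
#' @param scaffolds scaffold table.
#' @param window_size window width in bp (default 100 kb).
#' @return data.frame with `scaffold`, `start`, `end` (0-based half-open).
#' @export
genome_windows <- function(scaffolds, window_size = 1e5) {
  check_scaffold_table(scaffolds)
  rows <- lapply(seq_len(nrow(scaffolds)), function(i) {
    n <- scaffolds$length[i] %/% window_size
    if (n == 0) return(NULL)
    start <- (seq_len(n) - 1) * window_size
    data.frame(scaffold = scaffolds$scaffold[i], start = start,
               end = start + window_size)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- empty_intervals()
  rownames(res) <- NULL
  res
}

#' Heterozygous-site counts in non-overlapping windows
#'
#' @param het heterozygous-site table (`scaffold`, 0-based `pos`); should be
#'   restricted to the autosomal scaffold set beforehand.
#' @param scaffolds autosomal scaffold table.
#' @param window_size window width in bp (default 100 kb).
#' @return data.frame (`scaffold`, `start`, `end`, `het_count`), one row per
#'   complete window; sites in dropped terminal remainders are not counted.
#' @export
window_het_counts <- function(het, scaffolds, window_size = 1e5) {
  win <- genome_windows(scaffolds, window_size)
  win$het_count <- 0L
  if (nrow(win) && nrow(het)) {
    for (s in unique(win$scaffold)) {
      n <- sum(win$scaffold == s)
      pos <- het$pos[het$scaffold == s]
      pos <- pos[pos >= 0 & pos < n * window_size]
      if (length(pos))
        win$het_count[win$scaffold == s] <-
          tabulate(pos %/% window_size + 1L, nbins = n)
    }
  }
  win
}

#' Heterozygosity of a gene set's exons, with excess over a reference
#'
#' Numerator: heterozygous sites inside callable exon sequence; denominator:
#' callable exon positions (exon intervals intersected with the callability
#' track, so the same filters apply on both sides). The excess ratio divides
#' the gene-set rate by a caller-chosen reference rate, typically the
#' genome-wide rate of the same individual.
#'
#' @param het heterozygous-site table (`scaffold`, 0-based `pos`).
#' @param exons exon intervals (`scaffold`, `start`, `end`).
#' @param callability `callability` object for the same individual.
#' @param reference_rate optional reference rate in SNPs/Mb; when given, the
#'   result carries `excess = rate / reference_rate` (see [het_excess()]).
#' @param name gene-set name, used in error messages.
#' @return `het_rate` object with extra fields `set`, `reference_rate` and
#'   `excess`.
#' @export
gene_set_het <- function(het, exons, callability, reference_rate = NULL,
                         name = "gene_set") {
  stopifnot(inherits(callability, "callability"))
  callable <- split_ranges(callability$intervals)
  n_call <- 0
  n_het <- 0L
  for (s in intersect(unique(exons$scaffold), names(callable))) {
    ex <- exons[exons$scaffold == s, , drop = FALSE]
    ex_ir <- IRanges::reduce(as_iranges(ex$start, ex$end))
    hit <- IRanges::intersect(ex_ir, callable[[s]])
    n_call <- n_call + sum(IRanges::width(hit))
    if (length(hit)) {
      n_het <- n_het + points_in_intervals(
        het[het$scaffold == s, , drop = FALSE], ranges_to_df(hit, s))
    }
  }
  if (n_call == 0) stopf("gene set '%s': zero callable exon positions", name)
  rate <- n_het * 1e6 / n_call
  structure(list(set = name, n_het = n_het, n_callable = n_call,
                 rate_snps_per_mb = rate,
                 reference_rate = reference_rate,
                 excess = if (!is.null(reference_rate))
                   het_excess(rate, reference_rate)),
            class = "het_rate")
}

#' Heterozygosity excess ratio
#'
#' The fold-excess of a gene set's heterozygosity rate over a reference
#' rate, e.g. a rate of 2,509 SNPs/Mb against a genome-wide 198 SNPs/Mb is a
#' 12.7-fold excess.
#'
#' @param rate,reference_rate rates in SNPs/Mb; `reference_rate` must be > 0.
#' @return the ratio `rate / reference_rate`.
#' @export
het_excess <- function(rate, reference_rate) {
  if (any(reference_rate <= 0)) stopf("reference_rate must be > 0")
  rate / reference_rate
}
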