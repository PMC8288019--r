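#' Genotype filter policy
#'
#' The per-site filters applied identically to the heterozygosity numerator
#' (variant records) and, for the depth components, to the denominator
#' (callability track): minimum Phred site quality, minimum depth, and a
#' maximum depth expressed as a multiple of the individual's mean
#' genome-wide depth.
#'
#' @param min_quality minimum variant quality (Phred; default 30).
#' @param min_depth minimum per-site depth (default 10).
#' @param max_depth_factor maximum depth as a multiple of the individual's
#'   mean genome-wide depth (default 2).
#' @param snps_only drop non-SNV records (default TRUE).
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(min_quality = 30, min_depth = 10,
                          max_depth_factor = 2, snps_only = TRUE) {
  if (min_depth < 1) stopf("min_depth must be >= 1")
  if (max_depth_factor <= 0) stopf("max_depth_factor must be > 0")
  structure(list(min_quality = min_quality, min_depth = min_depth,
                 max_depth_factor = max_depth_factor,
                 snps_only = isTRUE(snps_only)),
            class = "filter_policy")
}

#' Read per-sample variant records from a VCF
#'
#' Parses a VCF (plain or bgzipped) via \pkg{vcfR} and returns one record
#' per site per sample with the genotype classified as `hom_ref`, `het`,
#' `hom_alt` or `missing`. A genotype is heterozygous when it carries two
#' distinct alleles (`0/1`, `1/2`, ...), so multiallelic sites are kept and
#' classified by their genotype. `is_snp` is TRUE when REF and all ALT
#' alleles are single bases.
#'
#' @param path path to a VCF file with GT and DP FORMAT fields.
#' @return data.frame with columns `sample`, `scaffold`, `pos` (1-based),
#'   `genotype_class`, `qual`, `depth`, `is_snp`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (!"GT" %in% fmt)
    stopf("VCF %s has no GT field (first site: %s:%s)", path,
          fix[1, "CHROM"], fix[1, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- if ("DP" %in% fmt) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
        else matrix(NA_real_, nrow(gt), ncol(gt))
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  is_snp <- nchar(fix[, "REF"]) == 1L &
    vapply(strsplit(alt, ","),
           function(a) length(a) > 0 && all(nchar(a) == 1L), TRUE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  samples <- colnames(gt)
  out <- lapply(samples, function(sm) {
    data.frame(sample = sm,
               scaffold = fix[, "CHROM"],
               pos = as.integer(fix[, "POS"]),
               genotype_class = classify_gt(gt[, sm]),
               qual = qual,
               depth = as.integer(dp[, sm]),
               is_snp = is_snp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

classify_gt <- function(g) {
  g[is.na(g)] <- "."
  al <- strsplit(g, "[/|]")
  vapply(al, function(a) {
    if (any(a == ".") || !length(a)) return("missing")
    if (length(unique(a)) > 1L) return("het")
    if (all(a == "0")) "hom_ref" else "hom_alt"
  }, character(1))
}

#' Write variant records as a single-sample VCF v4.2
#'
#' Serialises a variant table (e.g. from [simulate_diploid_genome()]) to a
#' plain-text VCF with GT and DP genotype fields. Synthetic alleles REF=A,
#' ALT=T are used; the statistics downstream only read position, genotype
#' class, quality and depth.
#'
#' @param variants variant data.frame for one sample.
#' @param path output path.
#' @param scaffolds optional scaffold table; adds `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, scaffolds = NULL) {
  if (length(unique(variants$sample)) > 1L)
    stopf("write_vcf writes one sample per file")
  gtmap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohscape-simulator",
           if (!is.null(scaffolds))
             sprintf("##contig=<ID=%s,length=%d>", scaffolds$scaffold,
                     scaffolds$length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", variants$sample[1] %||% "sample1",
                 sep = "\t"))
  body <- without_scipen(if (nrow(variants)) {
    v <- variants[order(variants$scaffold, variants$pos), , drop = FALSE]
    paste(v$scaffold, v$pos, ".", "A", "T", v$qual, "PASS", ".", "GT:DP",
          paste(gtmap[v$genotype_class], v$depth, sep = ":"), sep = "\t")
  } else character(0))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Length-weighted mean depth of a depth track
#'
#' @param depth depth track (`scaffold`, `start`, `end`, `depth`).
#' @return the mean genome-wide depth, weighting each interval by its width.
#' @export
mean_genome_depth <- function(depth) {
  if (is.null(depth) || nrow(depth) == 0) stopf("empty depth track")
  weighted.mean(depth$depth, depth$end - depth$start)
}

#' Apply the genotype filter policy to variant records
#'
#' Retains records with `qual >= min_quality` and depth within
#' `[min_depth, max_depth_factor * mean_depth]`; non-SNVs are dropped when
#' `snps_only` is set. Genotype classes are preserved; the result is always
#' a subset of the input and re-filtering is a no-op.
#'
#' @param variants variant records.
#' @param policy a [filter_policy()].
#' @param mean_depth the individual's mean genome-wide depth (used for the
#'   maximum-depth cap).
#' @return the retained records.
#' @export
filter_genotypes <- function(variants, policy = filter_policy(), mean_depth) {
  stopifnot(inherits(policy, "filter_policy"))
  if (missing(mean_depth) || !is.finite(mean_depth))
    stopf("mean_depth is required (compute it with mean_genome_depth())")
  cap <- policy$max_depth_factor * mean_depth
  keep <- !is.na(variants$qual) & variants$qual >= policy$min_quality &
    !is.na(variants$depth) &
    variants$depth >= policy$min_depth & variants$depth <= cap
  if (policy$snps_only) keep <- keep & variants$is_snp
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the callability track (heterozygosity denominator)
#'
#' Positions whose depth lies within `[min_depth, max_depth_factor *
#' mean_depth]` become callable; contiguous callable positions are merged
#' into sorted, disjoint 0-based half-open intervals per scaffold. The
#' callable-site total is the denominator of every heterozygosity rate, so
#' numerator and denominator pass the same depth filters.
#'
#' @param depth depth track.
#' @param policy a [filter_policy()].
#' @param mean_depth mean genome-wide depth of the same individual.
#' @param scaffolds scaffold table; track intervals outside scaffold bounds
#'   are an error.
#' @return list of class `callability` with `intervals` (scaffold/start/end),
#'   `totals` (named per-scaffold callable site counts), `total` and
#'   `min_depth`.
#' @export
build_callability <- function(depth, policy = filter_policy(), mean_depth,
                              scaffolds) {
  stopifnot(inherits(policy, "filter_policy"))
  check_scaffold_table(scaffolds)
  lens <- stats::setNames(scaffolds$length, scaffolds$scaffold)
  bad <- !(depth$scaffold %in% names(lens)) |
    depth$start < 0 | depth$end > lens[depth$scaffold]
  if (any(bad))
    stopf("depth track has %d interval(s) outside scaffold bounds (first: %s:%d-%d)",
          sum(bad), depth$scaffold[which(bad)[1]],
          depth$start[which(bad)[1]], depth$end[which(bad)[1]])
  cap <- policy$max_depth_factor * mean_depth
  ok <- depth[depth$depth >= policy$min_depth & depth$depth <= cap, ,
              drop = FALSE]
  if (nrow(ok)) {
    merged <- lapply(split(ok, ok$scaffold), function(x) {
      ranges_to_df(IRanges::reduce(as_iranges(x$start, x$end)), x$scaffold[1])
    })
    intervals <- do.call(rbind, merged)
    rownames(intervals) <- NULL
  } else {
    intervals <- empty_intervals()
  }
  widths <- intervals$end - intervals$start
  totals <- vapply(split(widths, intervals$scaffold), sum, 0)
  structure(list(intervals = intervals, totals = totals,
                 total = sum(widths), min_depth = policy$min_depth),
            class = "callability")
}

#' @export
print.callability <- function(x, ...) {
  cat(sprintf("callability track: %.0f callable sites on %d scaffold(s), min depth %g\n",
              x$total, length(x$totals), x$min_depth))
  invisible(x)
}

# ---- plain-text interval IO (BED / BEDGRAPH / FAI-like tables) ----

#' Read and write BED-like interval files
#'
#' Small TSV helpers for the package's 0-based half-open interval tables:
#' BED3+ exon/run files, BEDGRAPH depth tracks and two-column FAI-like
#' scaffold length tables.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @name interval_io
NULL

#' @rdname interval_io
#' @export
write_bedgraph <- function(x, path) {
  without_scipen(write.table(x[, c("scaffold", "start", "end", setdiff(names(x), c("scaffold", "start", "end")))],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE))
  invisible(path)
}

#' @rdname interval_io
#' @export
read_bedgraph <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("scaffold", "start", "end", "depth"),
                  colClasses = c("character", "integer", "integer", "numeric"))
  x
}

#' @rdname interval_io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("scaffold", "start", "end", "name", "score", "strand"),
                    names(x))
  without_scipen(write.table(x[, cols], path, sep = "\t", quote = FALSE,
                             row.names = FALSE, col.names = FALSE))
  invisible(path)
}

#' @rdname interval_io
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  names(x) <- c("scaffold", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' @rdname interval_io
#' @export
write_scaffold_table <- function(x, path) {
  cols <- intersect(c("scaffold", "length", "class"), names(x))
  without_scipen(write.table(x[, cols], path, sep = "\t", quote = FALSE,
                             row.names = FALSE, col.names = FALSE))
  invisible(path)
}

#' @rdname interval_io
#' @export
read_scaffold_table <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
  names(x) <- c("scaffold", "length", "class")[seq_len(ncol(x))]
  x$length <- as.integer(x$length)
  x
}
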