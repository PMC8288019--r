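#' Label ROH windows and estimate F_ROH (zero-heterozygote window method)
#'
#' A complete window is a ROH window when its heterozygous-site count is at
#' most `max_het` (default 0, i.e. the zero-heterozygote rule). F_ROH is the
#' proportion of ROH windows among all complete windows — an estimate of the
#' individual's inbreeding coefficient.
#'
#' @param windows window table from [window_het_counts()], built on
#'   autosomal scaffolds at least one window long.
#' @param max_het maximum heterozygous sites for a window to count as ROH.
#' @return list of class `roh_labeling`: `windows` (with logical `roh`
#'   column), `max_het`, `window_size`, `n_windows`, `n_roh`, `F_ROH`.
#' @export
window_roh <- function(windows, max_het = 0) {
  if (is.null(windows) || nrow(windows) == 0) stopf("zero complete windows")
  windows$roh <- windows$het_count <= max_het
  structure(list(windows = windows, max_het = max_het,
                 window_size = windows$end[1] - windows$start[1],
                 n_windows = nrow(windows), n_roh = sum(windows$roh),
                 F_ROH = mean(windows$roh)),
            class = "roh_labeling")
}

#' @export
print.roh_labeling <- function(x, ...) {
  cat(sprintf("F_ROH = %.4f (%d / %d windows of %g bp, <= %g het sites)\n",
              x$F_ROH, x$n_roh, x$n_windows, x$window_size, x$max_het))
  invisible(x)
}

#' Merge consecutive ROH windows into runs
#'
#' Consecutive ROH-labelled windows on the same scaffold become one run;
#' runs never cross scaffold boundaries, and the summed run length equals
#' `n_roh * window_size` exactly.
#'
#' @param labeling a `roh_labeling` from [window_roh()].
#' @return data.frame of runs (`scaffold`, `start`, `end`, `length`,
#'   `method = "window0het"`), empty when no window is labelled.
#' @export
merge_runs <- function(labeling) {
  stopifnot(inherits(labeling, "roh_labeling"))
  w <- labeling$windows
  runs <- lapply(split(seq_len(nrow(w)), w$scaffold), function(idx) {
    ws <- w[idx, , drop = FALSE]
    ws <- ws[order(ws$start), , drop = FALSE]
    r <- rle(ws$roh)
    hi <- cumsum(r$lengths)
    lo <- c(1L, head(hi, -1L) + 1L)
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(scaffold = ws$scaffold[1], start = ws$start[lo[keep]],
               end = ws$end[hi[keep]])
  })
  res <- do.call(rbind, runs)
  if (is.null(res))
    res <- empty_intervals()
  res$length <- res$end - res$start
  res$method <- rep("window0het", nrow(res))
  rownames(res) <- NULL
  res
}

#' Detect ROH with a simplified 50-site scanning window
#'
#' A deliberately simplified emulation of genotype-count scanning ROH
#' callers: over the sorted called sites (homozygous and heterozygous) of a
#' scaffold, every window of `snp_window` consecutive sites containing at
#' most `max_het` heterozygous positions "passes", a called site is
#' ROH-supporting when at least one passing window covers it, and maximal
#' stretches of ROH-supporting sites spanning at least `min_run_bp` of
#' physical sequence become runs. Output is tagged `method = "scan50"`; it
#' does not claim equivalence with any external caller's window-hit
#' machinery.
#'
#' @param calls data.frame of called sites: `scaffold`, 0-based `pos`,
#'   logical `het`. Typically all filtered variant records (hom_alt + het).
#' @param snp_window number of sites per scanning window (default 50).
#' @param max_het maximum heterozygous sites per passing window (default 1).
#' @param min_run_bp minimum physical run span in bp (default 100 kb).
#' @return data.frame of runs (`scaffold`, `start`, `end`, `length`,
#'   `method`). Scaffolds with fewer than `snp_window` called sites are
#'   skipped with a warning.
#' @export
scan_roh <- function(calls, snp_window = 50, max_het = 1, min_run_bp = 1e5) {
  out <- list()
  skipped <- character(0)
  for (s in unique(calls$scaffold)) {
    cs <- calls[calls$scaffold == s, , drop = FALSE]
    cs <- cs[order(cs$pos), , drop = FALSE]
    n <- nrow(cs)
    if (n < snp_window) {
      skipped <- c(skipped, s)
      next
    }
    nw <- n - snp_window + 1L
    S <- c(0L, cumsum(as.integer(cs$het)))
    wsum <- S[seq_len(nw) + snp_window] - S[seq_len(nw)]
    pass <- wsum <= max_het
    P <- c(0L, cumsum(as.integer(pass)))
    i <- seq_len(n)
    lo <- pmax(1L, i - snp_window + 1L)
    hi <- pmin(i, nw)
    supported <- hi >= lo & (P[hi + 1L] - P[lo]) > 0L
    r <- rle(supported)
    hc <- cumsum(r$lengths)
    lc <- c(1L, head(hc, -1L) + 1L)
    for (k in which(r$values)) {
      a <- cs$pos[lc[k]]
      b <- cs$pos[hc[k]] + 1L
      if (b - a >= min_run_bp)
        out[[length(out) + 1L]] <- data.frame(scaffold = s, start = a, end = b)
    }
  }
  if (length(skipped))
    warnf("scan_roh: skipped %d scaffold(s) with fewer than %d called sites (%s)",
          length(skipped), snp_window,
          paste(head(skipped, 5), collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_intervals()
  res$length <- res$end - res$start
  res$method <- rep("scan50", nrow(res))
  rownames(res) <- NULL
  res
}

#' Cumulative ROH length spectrum with the short/long split
#'
#' Orders runs by length and accumulates the genome fraction they cover,
#' giving the cumulative-fraction-in-ROH curve; the 1-Mb threshold splits
#' the total into a short-ROH fraction (older, bottleneck-era inbreeding)
#' and a long-ROH fraction (recent inbreeding). Runs of exactly the
#' threshold length count as short.
#'
#' @param runs run table (needs a `length` column).
#' @param genome_length total analysed genome length in bp (> 0).
#' @param long_threshold short/long boundary in bp (default 1 Mb).
#' @return list with `curve` (data.frame `length`, `cum_fraction`,
#'   non-decreasing), `short_fraction`, `long_fraction`, `total_fraction`.
#' @export
length_spectrum <- function(runs, genome_length, long_threshold = 1e6) {
  if (genome_length <= 0) stopf("genome_length must be > 0")
  lens <- sort(runs$length)
  curve <- data.frame(length = lens, cum_fraction = cumsum(lens) / genome_length)
  short_f <- sum(lens[lens <= long_threshold]) / genome_length
  long_f <- sum(lens[lens > long_threshold]) / genome_length
  list(curve = curve, short_fraction = short_f, long_fraction = long_f,
       total_fraction = short_f + long_f)
}

#' Compare F estimates across ROH methods
#'
#' Pearson correlations across individuals between per-method F estimates,
#' plus per-method means. A method constant across individuals has no
#' defined correlation and is reported as `NA`.
#'
#' @param F_estimates data.frame or matrix, one row per individual, one
#'   column per method; at least 3 individuals.
#' @return list with `correlations` (method x method matrix) and `means`.
#' @export
compare_methods <- function(F_estimates) {
  m <- as.matrix(F_estimates)
  if (nrow(m) < 3) stopf("need at least 3 individuals to compare methods")
  cors <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, stats::sd)
  cors[sds == 0, ] <- NA
  cors[, sds == 0] <- NA
  diag(cors) <- 1
  list(correlations = cors, means = colMeans(m))
}
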