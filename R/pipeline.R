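#' Read a pipeline configuration file
#'
#' YAML configuration for [run_pipeline()]. Recognised fields: `individuals`
#' (list of `id`, `sex`, `vcf`, `depth`, optional `exon_beds` overrides),
#' `scaffold_table`, `exon_beds` (named list of BED paths per gene set),
#' `filters` (`min_quality`, `min_depth`, `max_depth_factor`), `sex_class`
#' (`y_ratio_range`, `x_ratio_range`), `window_size`, `scan`
#' (`snp_window`, `max_het`, `min_run_bp`), `min_scaffold_len_call`,
#' `min_scaffold_len_roh`, `long_roh_bp`, `n_perm`, `seed`, `outdir`,
#' `plots`. Missing fields take the package defaults (Q >= 30, depth in
#' \[10, 2 x mean\], 40-kb calling / 100-kb ROH scaffold thresholds, 100-kb
#' windows, zero-het ROH rule, 50-site/1-het scan, 1-Mb long-ROH threshold,
#' 1,000 permutations).
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

default_config <- function(cfg) {
  defaults <- list(window_size = 1e5, min_scaffold_len_call = 4e4,
                   min_scaffold_len_roh = 1e5, long_roh_bp = 1e6,
                   n_perm = 1000, seed = 1L, plots = FALSE,
                   depth_sweep = FALSE, exon_beds = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  f <- cfg$filters %||% list()
  cfg$policy <- filter_policy(min_quality = f$min_quality %||% 30,
                              min_depth = f$min_depth %||% 10,
                              max_depth_factor = f$max_depth_factor %||% 2)
  s <- cfg$sex_class %||% list()
  cfg$sex_policy <- sex_class_policy(
    y_ratio_range = unlist(s$y_ratio_range) %||% c(0, 0.04),
    x_ratio_range = unlist(s$x_ratio_range) %||% c(1.5, 2.5),
    min_scaffold_len = cfg$min_scaffold_len_call)
  sc <- cfg$scan %||% list()
  cfg$scan <- list(snp_window = sc$snp_window %||% 50,
                   max_het = sc$max_het %||% 1,
                   min_run_bp = sc$min_run_bp %||% 1e5)
  cfg
}

#' Run the full per-individual genomic-landscape analysis
#'
#' Orchestrates, for every configured individual: variant reading and
#' filtering, callability construction, sex-scaffold classification from
#' female:male coverage ratios (when both sexes are present), genome-wide
#' heterozygosity (optionally the minimum-depth sweep), 100-kb window
#' heterozygosity, ROH labelling by the zero-heterozygote window rule and
#' the 50-site scan, run merging and length spectra, per-gene-set
#' heterozygosity excess, and the exon-in-ROH permutation test. Every stage
#' failure aborts with the stage name and offending input; a missing exon
#' BED only disables the gene-set stages with a warning.
#'
#' @param config a config list or path to a YAML file (see
#'   [read_run_config()]).
#' @return list of class `rohscape_report` with `individuals` (one row per
#'   individual: mean depth, het rate, F_ROH per method, short/long ROH
#'   fractions), `gene_sets` (per individual x gene set: rate, excess,
#'   exon-in-ROH proportion, permutation p), `runs` (all ROH runs),
#'   `scaffold_labels`, `method_comparison` (when >= 3 individuals) and
#'   `config`. Tables are also written as TSV/BED under `config$outdir`
#'   when set.
#' @export
run_pipeline <- function(config) {
  cfg <- default_config(if (is.character(config)) read_run_config(config)
                        else config)
  if (is.null(cfg$individuals) || !length(cfg$individuals))
    stopf("pipeline: config lists no individuals")
  scaffolds <- stage("scaffold_table", cfg$scaffold_table, {
    read_scaffold_table(cfg$scaffold_table)
  })

  ind <- lapply(cfg$individuals, function(x) {
    list(id = x$id, sex = x$sex %||% "male", vcf = x$vcf, depth = x$depth,
         exon_beds = x$exon_beds)
  })

  # per-individual depth tracks and per-scaffold mean depths
  tracks <- lapply(ind, function(x)
    stage("depth_track", x$depth, read_bedgraph(x$depth)))
  names(tracks) <- vapply(ind, `[[`, "", "id")

  labels <- stage("scaffold_classification", "coverage ratios", {
    classify_cohort_scaffolds(ind, tracks, scaffolds, cfg$sex_policy)
  })
  auto_call <- autosomal_subset(labels, scaffolds, cfg$min_scaffold_len_call)
  auto_roh <- autosomal_subset(labels, scaffolds, cfg$min_scaffold_len_roh)
  if (nrow(auto_call$scaffolds) == 0)
    stopf("pipeline: no autosomal scaffolds pass the calling length threshold")

  rows <- list(); gene_rows <- list(); run_rows <- list(); sweeps <- list()
  for (k in seq_along(ind)) {
    x <- ind[[k]]
    res <- analyse_individual(x, tracks[[x$id]], auto_call, auto_roh, cfg, k)
    rows[[k]] <- res$row
    gene_rows[[k]] <- res$gene_rows
    run_rows[[k]] <- res$runs
    sweeps[[k]] <- res$sweep
  }
  individuals <- do.call(rbind, rows)
  gene_sets <- do.call(rbind, gene_rows)
  runs <- do.call(rbind, run_rows)
  comparison <- if (nrow(individuals) >= 3)
    compare_methods(individuals[, c("F_window", "F_scan")])
  report <- structure(list(individuals = individuals, gene_sets = gene_sets,
                           runs = runs, scaffold_labels = labels,
                           method_comparison = comparison,
                           depth_sweeps = sweeps, config = cfg),
                      class = "rohscape_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

stage <- function(name, input, code) {
  tryCatch(code, error = function(e)
    stopf("pipeline stage '%s' failed on input '%s': %s", name,
          paste(format(input), collapse = ","), conditionMessage(e)))
}

# Female-vs-each-male classification with the unanimity rule; falls back to
# the scaffold table's own class column (or all-autosome) when the cohort
# does not contain both sexes.
classify_cohort_scaffolds <- function(ind, tracks, scaffolds, sex_policy) {
  sexes <- vapply(ind, `[[`, "", "sex")
  if (!("female" %in% sexes) || !("male" %in% sexes)) {
    lab <- data.frame(scaffold = scaffolds$scaffold,
                      label = scaffolds$class %||% rep("autosome", nrow(scaffolds)))
    return(lab)
  }
  summaries <- lapply(tracks, scaffold_mean_depth)
  female <- summaries[[which(sexes == "female")[1]]]
  males <- summaries[sexes == "male"]
  per_male <- lapply(males, function(m) {
    r <- coverage_ratio(
      data.frame(scaffold = female$scaffold, female_depth = female$mean_depth,
                 length = scaffolds$length[match(female$scaffold, scaffolds$scaffold)]),
      data.frame(scaffold = m$scaffold, male_depth = m$mean_depth))
    classify_scaffolds(r, sex_policy)$label
  })
  lab_mat <- do.call(cbind, per_male)
  unanimous <- apply(lab_mat, 1, function(z) length(unique(z)) == 1L)
  label <- lab_mat[, 1]
  if (any(!unanimous)) {
    warnf("%d scaffold(s) without unanimous sex classification: labelled autosome",
          sum(!unanimous))
    label[!unanimous] <- "autosome"
  }
  data.frame(scaffold = female$scaffold, label = label)
}

scaffold_mean_depth <- function(track) {
  w <- track$end - track$start
  agg <- vapply(split(seq_len(nrow(track)), track$scaffold),
                function(i) weighted.mean(track$depth[i], w[i]), 0)
  data.frame(scaffold = names(agg), mean_depth = unname(agg))
}

analyse_individual <- function(x, track, auto_call, auto_roh, cfg, k) {
  id <- x$id
  variants <- stage("read_variants", x$vcf, read_variants(x$vcf))
  md <- mean_genome_depth(track)
  auto_track <- track[track$scaffold %in% auto_call$scaffolds$scaffold, ,
                      drop = FALSE]
  filt <- filter_genotypes(variants, cfg$policy, md)
  filt <- filt[filt$scaffold %in% auto_call$scaffolds$scaffold, , drop = FALSE]
  callab <- stage("build_callability", id, {
    build_callability(auto_track, cfg$policy, md, auto_call$scaffolds)
  })
  hr <- stage("genome_het_rate", id,
              genome_het_rate(het_sites(filt), callab))

  sweep <- if (isTRUE(cfg$depth_sweep))
    depth_sweep(variants, auto_track, cfg$policy, auto_call$scaffolds)

  het_roh <- het_sites(filt[filt$scaffold %in% auto_roh$scaffolds$scaffold, ,
                            drop = FALSE])
  win <- window_het_counts(het_roh, auto_roh$scaffolds, cfg$window_size)
  labeling <- stage("window_roh", id, window_roh(win))
  wruns <- merge_runs(labeling)
  calls <- data.frame(scaffold = filt$scaffold, pos = filt$pos - 1L,
                      het = filt$genotype_class == "het")
  calls <- calls[calls$scaffold %in% auto_roh$scaffolds$scaffold, , drop = FALSE]
  sruns <- suppressWarnings(scan_roh(calls, cfg$scan$snp_window,
                                     cfg$scan$max_het, cfg$scan$min_run_bp))
  spec_w <- length_spectrum(wruns, auto_roh$total_length, cfg$long_roh_bp)
  F_scan <- sum(sruns$length) / auto_roh$total_length
  runs <- rbind(cbind(individual = id, wruns), cbind(individual = id, sruns))

  beds <- cfg$exon_beds
  if (!is.null(x$exon_beds)) beds[names(x$exon_beds)] <- x$exon_beds
  gene_rows <- NULL
  if (length(beds)) {
    gr <- list()
    for (gs in names(beds)) {
      if (!file.exists(beds[[gs]])) {
        warnf("individual %s: exon BED for gene set '%s' missing (%s); skipped",
              id, gs, beds[[gs]])
        next
      }
      exons <- read_bed(beds[[gs]])
      gh <- stage("gene_set_het", gs, {
        gene_set_het(het_sites(filt), exons, callab,
                     reference_rate = hr$rate_snps_per_mb, name = gs)
      })
      asg <- assign_exons(exons, labeling$windows)
      prop <- exon_roh_proportion(asg, labeling)
      pt <- permute_labels_test(asg, labeling, n_perm = cfg$n_perm,
                                seed = sub_seed(cfg$seed, 1000L * k + match(gs, names(beds))))
      gr[[gs]] <- data.frame(
        individual = id, gene_set = gs, n_exons = asg$n_assigned,
        rate_snps_per_mb = gh$rate_snps_per_mb, excess = gh$excess,
        observed = prop, expected = pt$expected, p_value = pt$p_value,
        n_perm = pt$n_perm, seed = pt$seed %||% NA_integer_)
    }
    gene_rows <- do.call(rbind, gr)
  }

  row <- data.frame(
    individual = id, sex = x$sex, mean_depth = md,
    n_het = hr$n_het, n_callable = hr$n_callable,
    het_rate_snps_per_mb = hr$rate_snps_per_mb,
    F_window = labeling$F_ROH, F_scan = F_scan,
    short_roh_fraction = spec_w$short_fraction,
    long_roh_fraction = spec_w$long_fraction,
    n_windows = labeling$n_windows)
  if (isTRUE(cfg$plots) && !is.null(cfg$outdir))
    write_track_plots(id, labeling, cfg)
  list(row = row, gene_rows = gene_rows, runs = runs, sweep = sweep)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) if (!is.null(x) && nrow(x))
    write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(report$individuals, "individual_report.tsv")
  tsv(report$gene_sets, "gene_set_report.tsv")
  tsv(report$scaffold_labels, "scaffold_labels.tsv")
  if (!is.null(report$runs) && nrow(report$runs)) {
    for (id in unique(report$runs$individual)) {
      r <- report$runs[report$runs$individual == id, , drop = FALSE]
      r$name <- r$method
      r$score <- r$length
      write_bed(r, file.path(outdir, sprintf("%s_roh.bed", id)))
    }
  }
  invisible(outdir)
}

write_track_plots <- function(id, labeling, cfg) {
  f <- file.path(cfg$outdir, sprintf("%s_het_track.png", id))
  grDevices::png(f, width = 1400, height = 300 *
                   length(unique(labeling$windows$scaffold)))
  on.exit(grDevices::dev.off())
  plot_het_track(labeling)
  invisible(f)
}

#' @export
print.rohscape_report <- function(x, ...) {
  cat(sprintf("rohscape report: %d individual(s)\n", nrow(x$individuals)))
  print(x$individuals, digits = 4)
  invisible(x)
}

#' Plot per-window heterozygosity with ROH bars
#'
#' One panel per scaffold: 100-kb window heterozygosity rates as vertical
#' bars with ROH-labelled windows marked as a dark rug underneath, the
#' classic genome-landscape view of inbred genomes.
#'
#' @param labeling a `roh_labeling` from [window_roh()].
#' @param scaffold optional subset of scaffolds to draw.
#' @export
plot_het_track <- function(labeling, scaffold = NULL) {
  stopifnot(inherits(labeling, "roh_labeling"))
  w <- labeling$windows
  if (!is.null(scaffold)) w <- w[w$scaffold %in% scaffold, , drop = FALSE]
  scafs <- unique(w$scaffold)
  op <- graphics::par(mfrow = c(length(scafs), 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  wsize <- labeling$window_size
  for (s in scafs) {
    ws <- w[w$scaffold == s, , drop = FALSE]
    rate <- ws$het_count * 1e6 / wsize
    graphics::plot(ws$start / 1e6, rate, type = "h", col = "grey40",
                   xlab = "position (Mb)", ylab = "het (SNPs/Mb)", main = s)
    if (any(ws$roh))
      graphics::rect(ws$start[ws$roh] / 1e6, -max(rate) * 0.04,
                     ws$end[ws$roh] / 1e6, 0, col = "firebrick", border = NA)
  }
  invisible(labeling)
}
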