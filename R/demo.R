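#' Generate the bundled six-individual synthetic cohort
#'
#' Writes a complete, self-contained input set for [run_pipeline()]: one
#' VCF and depth track per individual, a shared scaffold table, exon BEDs
#' for two clustered gene families, a ground-truth table, and a ready
#' `config.yaml`. The cohort emulates a small survey of highly inbred
#' genomes: six individuals spanning inbreeding fractions 0.11-0.70 whose
#' genome-wide heterozygosity rates land near 12-459 SNPs/Mb (the
#' generator's non-ROH rate is scaled by 1/(1-F) so the *observed* rate,
#' which averages over ROH deserts, matches the intended value). One
#' individual is female so that female:male coverage ratios drive the
#' X/Y scaffold classification. The "mhc1" gene family carries a strong
#' exon heterozygosity multiplier and is placed avoiding ROH (a true
#' deficiency signal, per-individual BED); the "olf" family has a milder
#' multiplier at a fixed shared position.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; all outputs are byte-identical given the seed.
#' @return list with `config` (path to the YAML), `truth` (per-individual
#'   truth table), `files`.
#' @export
make_demo_dataset <- function(outdir, seed = 20260101) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outdir <- normalizePath(outdir)
  scaffolds <- data.frame(
    scaffold = c("auto1", "auto2", "auto3", "auto4", "chrX", "chrY"),
    length = c(5e6, 4e6, 2.5e6, 3e4, 1.5e6, 3e5),
    class = c("autosome", "autosome", "autosome", "autosome", "X", "Y"))
  write_scaffold_table(scaffolds[, c("scaffold", "length")],
                       file.path(outdir, "scaffolds.tsv"))

  cohort <- data.frame(
    id = paste0("I", 1:6),
    sex = c("female", rep("male", 5)),
    rate_obs = c(459, 300, 200, 120, 100, 12),
    target_F = c(0.11, 0.30, 0.45, 0.50, 0.55, 0.70))

  truth_rows <- list()
  individuals <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    theta <- round(cohort$rate_obs[i] / (1 - cohort$target_F[i]))
    sets <- list(
      gene_set("olf", n_genes = 40, exons_per_gene = 3, exon_len = 300,
               intron_len = 1000, gene_gap = 4000, het_multiplier = 3.7,
               scaffold = "auto1", cluster_start = 1200000L),
      gene_set("mhc1", n_genes = 20, exons_per_gene = 6, exon_len = 300,
               intron_len = 1000, gene_gap = 5000, het_multiplier = 12,
               roh_avoidance = TRUE))
    spec <- sim_genome_spec(scaffolds, theta = theta,
                            target_F = cohort$target_F[i],
                            gene_sets = sets, mean_depth = 30,
                            sex = cohort$sex[i], depth_tile = 500L,
                            seed = sub_seed(seed, i))
    g <- simulate_diploid_genome(spec, sample_id = id)
    write_vcf(g$variants, file.path(outdir, sprintf("%s.vcf", id)), scaffolds)
    write_bedgraph(g$depth, file.path(outdir, sprintf("%s_depth.bedgraph", id)))
    mhc <- g$exons[g$exons$set == "mhc1", , drop = FALSE]
    write_bed(mhc, file.path(outdir, sprintf("%s_mhc1_exons.bed", id)))
    if (i == 1)
      write_bed(g$exons[g$exons$set == "olf", , drop = FALSE],
                file.path(outdir, "olf_exons.bed"))
    write_bed(cbind(g$truth$roh, name = "roh_truth"),
              file.path(outdir, sprintf("%s_true_roh.bed", id)))
    truth_rows[[i]] <- data.frame(
      individual = id, sex = cohort$sex[i], theta_nonroh = theta,
      target_rate_obs = cohort$rate_obs[i],
      target_F = cohort$target_F[i], true_F = g$truth$true_F)
    individuals[[i]] <- list(
      id = id, sex = cohort$sex[i],
      vcf = file.path(outdir, sprintf("%s.vcf", id)),
      depth = file.path(outdir, sprintf("%s_depth.bedgraph", id)),
      exon_beds = list(mhc1 = file.path(outdir, sprintf("%s_mhc1_exons.bed", id))))
  }
  truth <- do.call(rbind, truth_rows)
  write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- list(
    individuals = individuals,
    scaffold_table = file.path(outdir, "scaffolds.tsv"),
    exon_beds = list(olf = file.path(outdir, "olf_exons.bed")),
    n_perm = 1000, seed = seed,
    outdir = file.path(outdir, "results"))
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(config = cfg_path, truth = truth,
       files = list.files(outdir, full.names = TRUE))
}
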