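# rohscape

Per-individual analysis of the genomic landscape of diversity for small,
endangered or otherwise data-poor populations, where often only a handful
of whole genomes — sometimes a single one — are available and
population-based methods do not apply. From one individual's variant calls
and depth track, rohscape estimates:

* **genome-wide heterozygosity** in SNPs/Mb, with the numerator
  (heterozygous SNVs, quality ≥ 30, depth in [10, 2 × mean]) and the
  denominator (callable sites, same depth window) passing identical
  filters, plus a minimum-depth sensitivity sweep (4–20);
* **sex-linked scaffolds** from female:male coverage ratios
  (autosome ≈ 1, X ≈ 2 in [1.5, 2.5], Y ≈ 0 in [0, 0.04]);
* **runs of homozygosity (ROH)** by two detectors — the proportion of
  100-kb windows with zero heterozygous sites, and a simplified 50-site /
  max-1-het scanning rule (`scan50`) — merged into runs with cumulative
  length spectra split at 1 Mb (short runs: old bottlenecks; long runs:
  recent inbreeding);
* **the inbreeding coefficient** F_ROH as the fraction of windows in ROH;
* **gene-family statistics**: exon heterozygosity and fold excess over the
  genome (balancing-selection hotspots such as MHC class I), and a
  label-preserving window permutation test for *deficiency* of exons
  inside ROH (1,000 shuffles preserving the ROH window count, one-sided
  `p = (1 + #{null ≤ obs})/(n + 1)`).

A first-class synthetic-data module generates diploid genomes with planted
autozygous tracts, clustered gene families, copy-number-aware Poisson
depth and full ground truth, plus a pedigree simulator (founder-allele
tracking, Poisson recombination) whose offspring of full-sib matings
realize the classical inbreeding coefficient of 0.25 on average — so every
estimator is validated against known truth without any external data.

## Worked example

```r
library(rohscape)

demo   <- make_demo_dataset("demo", seed = 20260101)  # writes VCFs, depth,
report <- run_pipeline(demo$config)                   # exon BEDs, config.yaml
report$individuals
```

```
  individual    sex het_rate_snps_per_mb F_window F_scan long_roh_fraction true_F
1         I1 female                491.7   0.0783  0.103             0.000   0.11
2         I2   male                309.1   0.2522  0.283             0.000   0.30
3         I3   male                217.7   0.4174  0.444             0.409   0.45
4         I4   male                130.2   0.4348  0.446             0.226   0.50
5         I5   male                105.4   0.5304  0.549             0.391   0.55
6         I6   male                 12.4   0.6870  0.417             0.565   0.70
```

The six synthetic individuals span observed heterozygosity 12–492 SNPs/Mb
and planted inbreeding 0.11–0.70. `F_window` tracks the planted truth
(small genomes make the window estimate noisy and conservative; see the
methods vignette for the boundary-bias analysis), and the long-ROH
fraction flags the heavily inbred genomes. Gene-set results for the
extreme individuals:

```r
subset(report$gene_sets, individual %in% c("I1", "I6"))
```

```
 individual gene_set rate_snps_per_mb excess observed expected p_value
         I1      olf             2028   4.12        0   0.0783   0.772
         I1     mhc1             6000  12.20        0   0.0783   0.802
         I6      olf                0   0.00        1   0.6870   1.000
         I6     mhc1              528  42.44        0   0.6870   0.012
```

The planted multipliers surface as fold excess (mhc1 ≈ 12× in the outbred
I1); in the highly inbred I6 the ROH-avoiding mhc1 cluster shows an
exon-in-ROH proportion of 0 against an expectation of 0.69 (p = 0.012),
while the fixed-position olf cluster happens to sit entirely inside ROH —
its exon heterozygosity collapses to 0. Fold-excess arithmetic matches the
published-scale examples exactly:

```r
het_excess(2509, 198)   # 12.7
het_excess(9018, 459)   # 19.6
```

Lower-level entry points (`simulate_diploid_genome()`, `window_roh()`,
`scan_roh()`, `permute_labels_test()`, `simulate_pedigree_ibd()`, ...) are
documented individually; `vignettes/genomic-landscape-methods.Rmd`
explains the models, defaults and limitations.

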