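Package: rohscape
Title: Runs of Homozygosity and Heterozygosity Landscapes from Individual Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-individual analysis of the genomic landscape of diversity from
    whole-genome variant calls: depth-matched heterozygosity estimation in
    SNPs/Mb with identical numerator and denominator filters, sex-linked
    scaffold classification from female:male coverage ratios, runs of
    homozygosity (ROH) detection by a zero-heterozygote 100-kb window method
    and a simplified SNP-count scanning method, F_ROH inbreeding estimation
    with short/long ROH length spectra, gene-family heterozygosity excess
    ratios, and a label-preserving window permutation test for ROH deficiency
    in gene exons. Includes a synthetic diploid-genome generator with planted
    autozygous tracts, clustered gene families, a copy-number-aware Poisson
    depth model, and a pedigree simulator with Poisson recombination that
    yields known realized autozygosity, so every stage is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
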