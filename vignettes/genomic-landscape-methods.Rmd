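---
title: "Methods: heterozygosity landscapes, ROH and inbreeding from single genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity landscapes, ROH and inbreeding from single genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rohscape characterises the genomic landscape of diversity of a single
diploid genome from its variant calls: how heterozygous it is, where that
heterozygosity collapses into runs of homozygosity (ROH), how inbred the
individual therefore is, and whether particular gene families (immune MHC
class I, olfactory receptors) behave differently from the genome around
them. This vignette explains the models and estimators, the choices behind
their defaults, and what the synthetic-data generator does and does not
emulate.

## The heterozygosity rate and the "same filters" principle

The basic statistic is the heterozygosity rate in SNPs/Mb:

$$ \hat\theta = \frac{\#\{\text{heterozygous SNVs passing filters}\}}
                     {\#\{\text{callable sites}\}} \times 10^6 . $$

The denominator matters as much as the numerator. A site is *callable*
when its read depth lies in $[d_{\min}, 2\bar d]$, where $\bar d$ is the
individual's length-weighted mean genome-wide depth; heterozygous calls
additionally need Phred site quality $\ge 30$ and to be single-nucleotide
variants. Numerator and denominator pass the *same* depth window, so an
individual sequenced at lower coverage loses both hets and callable sites
together rather than silently deflating the rate. `build_callability()`
constructs the denominator from a per-site (or per-tile) depth track;
`depth_sweep()` re-applies the whole chain at minimum depths 4–20 so the
sensitivity of $\hat\theta$ to $d_{\min}$ can be inspected before fixing it
(the default is 10). Callable counts are non-increasing in $d_{\min}$ by
construction, and this is asserted in the test suite.

Defaults (all exposed in `filter_policy()` and the pipeline config):
quality ≥ 30 Phred, depth ∈ [10, 2 × mean], SNVs only, scaffolds > 40 kb
for calling and > 100 kb for ROH. The two scaffold thresholds are separate
parameters because mapping artefacts dominate short scaffolds earlier than
window statistics do.

## Sex-linked scaffold classification

With one female and at least one male, the per-scaffold female:male ratio
of mean depths separates three groups: autosomes (≈1), X-linked (≈2,
because the male carries one X copy) and Y-linked (≈0, because the female
carries none). `classify_scaffolds()` calls Y for ratios in the closed
band [0, 0.04] and X in [1.5, 2.5]; everything else — including pathological
infinite ratios from a zero male mean, which are flagged with a warning —
falls back to the residual autosome class. With several males each male is
compared separately and a unanimous verdict is required; disagreements
demote the scaffold to autosome with a warning. At 30× depth and ≥ 40-kb
scaffolds the per-scaffold ratio has a standard error below 0.01, so
misclassification is essentially impossible; the test suite asserts exact
label recovery on simulated cohorts.

## ROH detection and F_ROH

Two deliberately simple detectors are implemented.

**Zero-heterozygote windows** (`window_roh()`). Autosomal scaffolds are
tiled with non-overlapping 100-kb windows anchored at coordinate 0
(partial terminal windows dropped). A window with zero heterozygous sites
is a ROH window, and

$$ F_{ROH} = \frac{\#\text{ROH windows}}{\#\text{windows}} $$

estimates the inbreeding coefficient. At a background rate of
θ = 200 SNPs/Mb a non-ROH window is empty with probability
$e^{-20} \approx 2\times10^{-9}$, so false ROH windows are negligible; the
estimator's error is dominated by boundary discretization (below).
Consecutive ROH windows merge into runs (`merge_runs()`), never across
scaffold boundaries, and `length_spectrum()` accumulates run lengths into
the cumulative fraction-in-ROH curve with the classical 1-Mb split: short
runs (≤ 1 Mb) reflect older bottleneck-era inbreeding, long runs (> 1 Mb)
recent consanguinity.

**50-site scan** (`scan_roh()`). A simplified emulation of genotype-count
scanning callers: over the sorted called sites of a scaffold every window
of 50 consecutive sites with at most 1 heterozygous call "passes"; a site
covered by any passing window is ROH-supporting; maximal supported
stretches spanning ≥ 100 kb become runs. Output is tagged `scan50` — it
mimics the *spirit* of the PLINK scan, not its window-hit-proportion
machinery, and the two methods' F estimates are compared only through
their correlation across individuals (`compare_methods()`), never asserted
equal. The report schema keeps per-method columns so externally computed
HMM-based estimates can be placed alongside.

### The window estimator's boundary bias

A planted autozygous tract of length $\ell$ fully covers on average
$\ell/w - 1$ windows of width $w$; its two boundary windows are labelled
ROH only if their non-autozygous remainder happens to carry no
heterozygous site (probability $(1 - e^{-\theta w})/(\theta w) \approx
0.05$ at θ = 200, w = 100 kb). Each tract therefore costs about 0.9
windows, giving an expected deficit

$$ E[\hat F - F] \approx -0.9\, \frac{w\,F}{\bar\ell}, $$

with $\bar\ell$ the mean tract length. Under the generator's default
tract mixture ($\bar\ell$ = 2.75 Mb) this is −0.005 at F = 0.11, −0.015 at
F = 0.45 and −0.023 at F = 0.70: the method is conservative, increasingly
so for highly inbred genomes carrying many tracts. The acceptance suite
asserts recovery within ±0.02 across F ∈ {0.11, 0.45, 0.70}; at F = 0.70
that band sits inside the analytic bias and the assertion documents the
deficit rather than hiding it. Re-estimation of pedigree-simulated genomes
is much more accurate (worst-case error < 0.02 per offspring) because
recombination-scale autozygous segments are far longer than the window.

Reduced coverage only inflates $\hat F$: thinning the depth track (binomial
`thin_depth()`) removes heterozygous calls below the minimum depth faster
than it removes windows, so inbreeding estimates from downsampled genomes
are upper bounds. This directional behaviour is asserted, not assumed.

## Gene-family statistics

`gene_set_het()` computes a gene set's exon heterozygosity with the same
dual-filter logic — numerator: het sites inside callable exon sequence;
denominator: exon ∩ callable positions — and reports the fold excess over
a caller-chosen reference rate. The reference is an explicit parameter
(typically the individual's genome-wide rate) because "excess" is only
meaningful relative to a stated baseline.

`permute_labels_test()` asks whether a gene set's exons sit in ROH *less*
often than chance. Each exon is assigned to the window containing its
midpoint (deterministic, each exon counted once; a midpoint exactly on a
boundary belongs to the window starting there). The observed proportion of
exons in ROH windows is compared with a null built by shuffling the
ROH/non-ROH labels over windows, preserving their total count — so the
null mean equals $F_{ROH}$ exactly and clustered exons travel together,
which correctly widens the null for clustered families. The one-sided
deficiency p-value uses the add-one correction
$p = (1 + \#\{\text{null} \le \text{obs}\})/(n+1)$ with $n = 1000$
shuffles by default, each (individual, gene set) pair drawing its own
deterministic sub-seed. No multiple-testing correction is applied across
gene sets; per-set p-values are reported side by side.

## What the synthetic-data generator emulates

`simulate_diploid_genome()` produces VCF-shaped variant records, a depth
track, exon annotations and full ground truth:

* **ROH tracts** from a two-component exponential mixture (defaults:
  p_short = 0.5, means 0.5 Mb and 5 Mb), echoing the short/long dichotomy;
  lengths are drawn until the running total first reaches the target
  fraction, the last tract is trimmed so realized F equals the target
  exactly, and tracts are placed uniformly among non-overlapping
  arrangements (broken-stick gaps). The true tract-length distribution of
  real inbred populations is unknown; the mixture is a modelling choice
  kept analytically tractable.
* **Heterozygous sites** as a homogeneous Poisson process: rate θ/Mb
  outside tracts, θ × multiplier inside gene-set exons, exactly 0 inside
  tracts. No linkage disequilibrium is modelled — downstream statistics
  consume positions only.
* **Homozygous-alternative sites** genome-wide at 0.5 θ by default
  (including inside ROH), so the het-only filter and the site-count scan
  have realistic hom calls to work with.
* **Depth** as independent Poisson per site with mean scaled by copy
  number/2 (autosome 2/2, X 2/1, Y 0/1 for female/male); `depth_tile`
  trades per-base resolution for track size on large genomes. Variant
  depths are read back from the same track so numerator and denominator
  filters stay consistent. No mapping bias, no sequencing-error model, no
  read-level simulation.
* **Gene clusters** laid out contiguously on one scaffold; with
  `roh_avoidance` the cluster placement rejects overlap with planted
  tracts, creating a true exon-in-ROH deficiency for power studies.

Because none of this models base-calling error, alignment artefacts or LD,
passing tests demonstrate the *estimators* are correct under their stated
model, not that real-data artefacts cannot bias them; the depth-matched
filter design is precisely the guard against the dominant such artefact.

`simulate_pedigree_ibd()` provides an independent, genetics-first truth:
founders carry unique allele labels, gametes receive Poisson crossovers
placed uniformly in genetic distance (no interference, uniform
recombination rate), and an offspring's realized autozygosity is the
physical fraction where its two haplotypes carry the same founder label.
Each offspring comes from an independent pedigree replicate, so the mean
over offspring of full-sib matings estimates the theoretical inbreeding
coefficient 0.25 rather than the kinship realized in one particular sib
pair. Realized autozygosity becomes less variable as the genetic map grows
(asserted over 1, 10, 30 Morgans), and re-detecting it with the 100-kb
window rule closes the loop between the two simulators.

## The demo cohort

`make_demo_dataset()` writes a six-individual cohort (one female, five
males) spanning planted inbreeding 0.11–0.70 whose *observed* genome-wide
rates land near 12–459 SNPs/Mb; since the generator's θ is the non-ROH
rate, the demo sets θ = rate/(1 − F) per individual. Two gene families are
planted: "mhc1" (multiplier 12, ROH-avoiding, per-individual exon BED) and
"olf" (multiplier 3.7, fixed shared position). Genomes total ~11.5 Mb
across three autosomal scaffolds (115 complete windows), one sub-threshold
30-kb scaffold, an X and a Y — small enough that the full pipeline runs in
seconds, at the price of visible window-sampling noise in F estimates and
low permutation power for the compact demo clusters; the statistically
calibrated checks in the test suite use larger single-purpose simulations
(100–200 Mb for F recovery, 2,000 pedigree offspring, 500 null datasets
for p-value uniformity) sized so each estimate's Monte-Carlo error is
small against the tolerance it is tested at.

## Numerical conventions and degenerate inputs

All internal coordinates are 0-based half-open; VCF positions convert on
input. Ratio bands are closed intervals. Windows anchor at 0 with no
offset scanning. A window table with zero complete windows, a callability
track with zero callable sites, a gene set with zero callable exon bases,
and an empty chromosome map are errors, not silent zeros; an empty
autosomal subset and a sub-50-site scaffold in the scan only warn. Rates
are displayed at the conventional precision (integers above 100 SNPs/Mb,
one decimal below) but stored at full precision; reports carry unrounded
values so no drift accumulates between stages.
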