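---
title: "medipscape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medipscape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage computes, which assumptions it makes, which parameters
matter, and where the design was genuinely open and a choice had to be
made.

## 1. The measurement model

MeDIP-seq enriches methylated DNA fragments by immunoprecipitation and
sequences them; the local density of uniquely mapped reads is a *relative*
methylation signal. The pipeline therefore never claims absolute
methylation levels. The genome is tiled into fixed 300-bp bins
(`make_bins()`), each read is attributed to the single bin containing its
strand-aware 5′ start (`count_reads()`), and low-information bins — fewer
than 10 reads summed over all samples — are removed (`filter_bins()`).
Retained bins are scored as

```
ES = count * 1e9 / (width * total_unique_mapped_reads)
```

(`enrichment_score()`), an RPKM-style density that cancels sequencing
depth and window length, so scores are comparable across samples and bin
sizes. The same formula at `width = 100 kb` (`windowed_rpkm()`) yields the
genome-wide landscape track.

Assumptions worth keeping in mind: reads are uniquely mapped and
deduplicated upstream; no mappability, GC, or antibody-affinity correction
is applied; per-sample depth normalization treats the library as a closed
composition (a region that gains reads necessarily dilutes all others —
see §6).

## 2. Annotation

Promoter zones are defined strand-aware around the TSS: distal
−2200..−1000, intermediate −1000..−200, proximal −200..+500 (negative =
upstream). Printed closed bounds become half-open intervals
`[TSS+lo, TSS+hi)`. When a bin touches several features the precedence is
proximal > intermediate > distal promoter > exon > intron > intergenic;
any shared base pair counts as overlap, so the classes partition the bins
exactly. "+500" is interpreted relative to the TSS (the alternative — the
first-exon end — is not used because it makes the zone depend on exon
annotation quality).

CpG islands are detected by a 1-bp-step 200-bp sliding window with CpG
observed/expected ratio `(#CpG * L) / (#C * #G)` above 0.6, the
Gardiner–Garden convention; no GC% criterion is imposed because the O/E
rule alone defines the object here (a GC filter is available as an
option). Qualifying windows are merged into maximal islands — without
merging, every island would surface as hundreds of 1-bp-shifted
duplicates — and each merged island's O/E is recomputed on its full span
(an island whose recomputed O/E no longer clears the threshold is
dropped, which keeps the emitted-island invariant `O/E > 0.6` simple and
testable). Windows containing non-ACGT characters are skipped rather than
imputed. Islands are classified against genes by strand-aware zones
(promoter −1000..+300 around the TSS; intragenic TSS+300..TES−300;
3′-transcript TES−300..TES+1000; otherwise intergenic) with precedence in
that order for boundary-spanning islands; an island overlapping two genes
takes the highest-precedence class over all of them.

## 3. Differential methylation

For each retained bin and each unordered pair of breeds,
`pairwise_tests()` runs a two-sample *pooled-variance* Student t-test on
per-sample enrichment scores. Welch's test is the usual default for
unequal variances, but with two replicates per group — the design this
pipeline targets — the Welch degrees of freedom degenerate and the pooled
test is the sane choice; `var_equal = FALSE` switches it. Bins where both
groups have zero variance are assigned p = 1 (no within-group information
at all). Fold change is the ratio of breed means with a pseudo-score
ε = 0.01 substituted for zero means, keeping ratios finite without
perturbing non-degenerate bins.

A DMR is a bin significant in at least one of the six comparisons at raw
P < 0.05. No multiple-testing correction is applied at this step by
design — the procedure is a screening rule, and corrected calling is
available behind `adjust =` — while gene-set enrichment (the place where
correction materially changes conclusions) always reports
Benjamini–Hochberg adjusted p-values. The fold-change filter is strict
(`> 2` or `< 0.5`; exactly 2.0 fails).

The breed-specificity rule is the strictest reading consistent with
disjoint per-breed sets: bin specific to breed B iff all three
comparisons involving B are significant with a consistent direction and
no other pair is significant. The last clause is what makes the per-breed
sets disjoint; `others_null = FALSE` relaxes it.

Clustering uses distance `1 − Pearson r` between unit profiles over
intergenic bins with more than 10 reads in every unit, average linkage,
and label-sorted columns so leaf order is deterministic. These are the
defaults of the clustering tools this analysis style is usually run with;
nothing downstream depends on the linkage beyond the reported tree.

## 4. Haplotype Fst

Sequences are uppercased, alignment columns containing any gap or
ambiguity are removed for all individuals (complete deletion, logged),
and identical sequences collapse to haplotypes. Pairwise Fst is the
two-level AMOVA fixation index on haplotype *identity* (0/1) distances —
equivalent to the variance-partitioning estimator on haplotype
frequencies — implemented directly on per-haplotype counts, so no
distance matrix is ever materialized. Negative estimates are reported as
computed: they are a well-known feature of the estimator under weak
differentiation, and truncating them at zero would bias downstream
summaries. Two populations fixed for the same single haplotype have no
variance to partition; that Fst is reported as `NA`, not 0. A
nucleotide-distance ΦST variant is out of scope. Permutation P-values
shuffle individuals between the two populations and use the add-one
estimator `(1 + #{Fst_perm ≥ Fst_obs}) / (n_perm + 1)`, which can never
return 0.

## 5. Expression integration

`relative_expression()` implements E^−ΔΔCt: technical wells averaged per
(sample, gene); ΔCt = Ct_target − mean(Ct_references) (arithmetic mean of
reference Cts, equivalent to geometric-mean quantity normalization at a
common efficiency); ΔΔCt subtracts the mean ΔCt of the calibrator
samples. The calibrator defaults to *all* samples (mean-centring), since
a pipeline cannot know which group a user regards as baseline; any change
of calibrator rescales all values by one constant, which the tests assert.
Efficiency E defaults to 2.0 (one cycle = one doubling) with per-call
override. Methylation–expression coupling is plain Pearson correlation
with `p` from `t = r√(n−2)/√(1−r²)`; zero-variance inputs give `NA`
rather than a fabricated p. `mbmi()` is weight/length² (kg, m).

## 6. The synthetic study generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes. Defaults describe a
desk-scale analogue of a four-breed, two-replicate design:

* **Genome**: 600 kb over two chromosomes (2,001 bins of 300 bp), 40
  genes with 2–5 exons and mixed strands, CpG-island tracts covering 2%
  of the genome (half centred on TSSs to mimic promoter CGIs). Background
  sequence is CpG-depleted (CpG sprinkled at 0.002/bp, so a 200-bp window
  essentially never reaches O/E 0.6 by chance); island tracts are GC-rich
  with CpG at 0.08/bp, comfortably above the detector threshold.
* **Per-bin read propensity** = element baseline × (1 + CpG density) ×
  shared lognormal bin effect (sdlog 1.0). Baselines encode the
  biological ordering the analysis is expected to recover: exons 2.0 >
  introns 1.0 > intergenic 0.8; promoter zones 0.7–1.2; bins in promoter
  CGI tracts multiplied by 0.25 (promoter islands are rarely methylated),
  other CGI bins by 1.3. The lognormal effect gives coverage its
  long-tailed heterogeneity, which is what real MeDIP tracks look like.
* **Reads**: each sample draws exactly `reads_per_sample` (default
  300,000, i.e. ~150 expected reads per bin) 5′ positions from a
  multinomial over bins with weights propensity × lognormal replicate
  noise (sd 0.05 on the log scale), uniform position within the bin,
  random strand, emitted as BED6. The noise scale is calibrated, per the
  generator's design contract, so that within-breed replicate Pearson
  correlation lands at ~0.99: with between-bin coefficient of variation
  c and per-bin mean μ, the expected replicate correlation is
  `c²μ² / (c²μ² + μ + (1+c²)μ²·sd²)`; at c ≈ 1.4, μ ≈ 150, sd = 0.05 this
  is ≈ 0.993, which the acceptance checks confirm empirically.
* **Planted DMRs**: `n_planted_dmrs` bins get their propensity multiplied
  (or divided) by `dmr_fold` (default 4) in one breed, cycling through
  breeds with alternating direction, so every planted bin has an exact
  ≥ fold propensity ratio against every other breed. Eligible bins are
  those with expected coverage in `dmr_expected_range` (default 150–500
  reads): a fold-4 change in a near-zero-coverage bin is undetectable by
  any two-replicate test (the noncentrality of the 2-vs-2 t-test scales
  as √μ, and its df-2 critical value is 4.30), while a fold-4 change in
  an extreme-coverage bin would consume a visible share of the sample's
  fixed read budget and shift the depth normalization of every other
  bin — a compositional artefact, not differential methylation. The band
  keeps planted effects both detectable and mass-neutral (~1% of reads at
  the sizes used here).
* **Haplotypes**: K = 10 root haplotypes mutated from one ancestor (each
  with a private diagnostic site); one base frequency vector; population
  frequencies drawn from a Dirichlet centred on it with concentration
  `(1/divergence − 1)·K`, so divergence 0 reproduces the base vector
  exactly and divergence → 1 approaches fixation; individuals i.i.d.
  within population.
* **Expression**: target Ct = baseline − slope·methylation + noise, so a
  positive slope couples methylation positively to E^−ΔΔCt expression.
  The default couplings (slopes ±2, noise sd 0.17 cycles, methylation
  uniform on 0.2–0.8) put the population correlation near |r| ≈ 0.9 at
  n = 9, matching the regime in which such couplings are realistically
  reported.

What the generator does *not* emulate: fragment-size distributions,
antibody affinity as a function of CpG count, sequencing error,
mappability structure, batch effects, or linkage between haplotype and
methylome. Tests passing on synthetic data therefore demonstrate that the
*computations* are correct and that the pipeline recovers planted truth
under its own model — not that the model captures every property of real
MeDIP data.

## 7. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including all BED I/O.
* Read→bin attribution is by 5′ start only, never fractional overlap:
  deterministic and count-conserving.
* Replicate averaging operates on enrichment scores, not raw counts,
  because scores are depth-normalized and counts are not.
* "Fewer than 10 reads across all individuals" is interpreted as the sum
  over samples < 10; `per_sample = TRUE` gives the stricter per-sample
  reading. "Total unique mapped reads" is per sample, not pooled.
* Empty annotation classes are reported with mean `NA`, never 0.
* Oracle-equivalence tests run at exact-integer agreement for counts and
  classes and 1e-10…1e-12 for reals.
* Single-replicate breeds: averaging is the identity and QC is skipped
  with a warning rather than an error.

## 8. Problem sizes used by the test suite

The packaged checks run on sizes chosen for single-CPU desk runs: the
default 2,001-bin study for replicate QC and the worked examples; three
~10⁴-bin null studies (10⁴ bins is where the 99% binomial band on a 5%
rejection rate, ±0.0056, becomes meaningful) for the type-I check; two
~10⁴-bin studies with 120 planted bins each for recovery; 100 seeded
small studies for clustering; 100 seeded qPCR panels for coupling. A note
on the type-I check: on discrete counts the 2-vs-2 pooled t-test is
intrinsically conservative at low coverage (simulated level ≈ 0.041 at
10 reads/bin, ≈ 0.049 at 100, nominal from ~200), so nominal-size
verification is meaningful only at adequate depth; at the default ~150
reads/bin the mixture level is ≈ 0.048, inside the band.

## 9. Known limitations

* Bin-level inference only; no merging of adjacent significant bins into
  larger regions, no covariate adjustment, no sex-chromosome handling.
* With two replicates per group the t-test has 2 df; power comes almost
  entirely from coverage, and the raw-p screening rule must be read as a
  candidate generator, not a controlled discovery procedure.
* Fst is haplotype-identity based; mutational distance between haplotypes
  is ignored.
* The E^−ΔΔCt model assumes equal amplification efficiency for targets
  and references unless per-call efficiencies are supplied.
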