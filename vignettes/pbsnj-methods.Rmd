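---
title: "Methods: differentiation scans, PBSnj and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation scans, PBSnj and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical machinery the package implements,
the conventions and defaults it fixes, and what the synthetic-data tests do
and do not demonstrate about real data.

## The scientific problem

Local adaptation leaves a footprint in between-population allele frequency
differentiation: variants driven up in one population produce extreme
frequency differences, and if adaptation is concentrated in and around
genes, the most differentiated variants should be *genic* more often than
the genome-wide average. The package implements this logic for multi-sample
diploid variant data grouped into populations (the motivating system is
four closely related primate subspecies with unequal sample sizes of
19/18/10/11 diploids and pairwise Fst from roughly 0.09 to 0.3, but nothing
in the code is specific to that system):

1. **delta scans** — the signed difference in derived allele frequency
   between a population pair, its binned genic-enrichment spectrum, and a
   log2 tail-ratio test of asymmetry;
2. **PBSnj scans** — per-SNP population-specific branch lengths for three
   *or more* populations, obtained by neighbor-joining on the pairwise
   Hudson-Fst distance matrix;
3. **null models** — a structured-coalescent simulator in which background
   selection (BGS) is emulated by scaling effective sizes with B values,
   plus sum-of-squared-differences fitting of the B that best matches an
   observed enrichment spectrum;
4. **candidate interpretation** — ranked-block sweep counting and
   resampling-based gene-set enrichment with gene-length-bias correction.

## delta and its enrichment spectrum

For a pair of populations, `delta = DAF(pop1) - DAF(pop2)` per SNP, with
derived alleles defined by polarization against an inferred ancestral state
(an `AA` INFO tag or an outgroup reference; SNPs whose ancestral state is
missing or matches neither allele are dropped and counted). Sites with any
missing genotype are removed at read time: frequency differences are only
comparable when every population is fully called at the site.

delta is binned into 10 bins. The conventions are deliberately pinned down
because the tails carry all the inference:

* bin 1 = `[-1, -0.8]` (closed at both ends), bin 10 = `(0.79, 1]`;
* interior edges at -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.79, lower-open /
  upper-closed, so `delta = 0` falls in the bin whose upper edge is 0 and
  the bin ending at 0.79 is narrower by 0.01.

The source conventions for these edges are internally inconsistent in small
ways (the two tails differ in width by 0.01 and which interior bin absorbs
the difference is ambiguous); this edge set reproduces every stated tail
rule, and the affected interior bins are so heavily populated that the
choice is immaterial. Monomorphic `delta = 0` sites are retained — dropping
them is a caller-side filter, not a binning rule.

The **genic enrichment** of bin *b* is
`(genic_b / total_b) / (genic_all / total_all)`, i.e. the bin's genic SNP
fraction normalised by the global genic fraction, so 1 means "looks like
the genome". Genic means within a gene span extended by 2 kb on each side
(merged across overlapping genes, boundaries inclusive). Empty bins are
reported as missing, never zero: a zero would fabricate depletion.
By construction the SNP-count-weighted mean enrichment across bins is
exactly 1.

## Weighted block jackknife

SNPs are linked, so per-bin counts are not sums of independent draws. All
confidence intervals come from a delete-one-block jackknife over
non-overlapping 200 kb windows (`[k*200kb + 1, (k+1)*200kb]` per
chromosome, anchored at position 1), weighted by the number of SNPs per
block (the Busing delete-m_j estimator): with block weights `m_j`, total
`n`, `h_j = n/m_j`, the bias-corrected estimate is
`g*theta_hat - sum((1 - m_j/n) * theta_j)` and the variance is
`(1/g) * sum((h_j*theta_hat - (h_j - 1)*theta_j - theta_J)^2 / (h_j - 1))`.
With equal block sizes this is exactly Tukey's delete-1 jackknife, which
the tests verify longhand. CIs are `theta_hat ± z_{alpha/2} * SE` with
normal quantiles — the intended regime is thousands of blocks, where the
t correction is negligible. A block whose deletion empties a bin produces a
non-finite leave-one-out value; such blocks are dropped from the variance
sum (with a warning) rather than imputed.

The **tail asymmetry** statistic is `L = log2(e_bin10 / e_bin1)`;
its jackknife SE gives a two-sided z-test of `L = 0`, and a Bonferroni
wrapper corrects across the 6 unordered population pairs. Leave-one-out
pseudovalue sets are exposed so that one pair's asymmetry can be compared
against another's with a two-sided Kolmogorov-Smirnov test (the operands of
that comparison are a documented assumption: pseudovalue distributions are
the only jackknife-native distributional summary available).

## PBSnj

The classical population branch statistic applies to exactly three
populations: transform pairwise Fst to drift time `T = -ln(1 - Fst)` and
read the focal external branch off the three-point formula. PBSnj removes
the three-population restriction: per SNP, build the full K×K matrix of
pairwise drift times and run Saitou-Nei neighbor-joining, which infers the
topology and branch lengths jointly; the per-population score is the
external branch length. For K = 3 this reduces exactly to the classical
formula (verified to 1e-9 over 10^4 random triples), and on additive
matrices NJ recovers the true branches exactly.

Pinned conventions:

* Fst is Hudson's two-population unbiased estimator, chosen because the
  sample sizes per population differ (the classical Weir-Cockerham
  estimator is biased under unequal sizes). Negative estimates are clamped
  to 0 before the log transform — a drift distance cannot be negative.
* `Fst = 1` (fixed difference) makes the transform diverge; it is replaced
  by the largest observed non-unit Fst for that population pair, computed
  in a first pass over the scan. This caps the top of the distance scale at
  what the sample sizes can actually resolve.
* A pair where both populations are fixed for the same allele has an
  undefined Fst; it contributes distance 0 (no differentiation). SNPs
  undefined for every pair (monomorphic) are dropped and counted.
* NJ join-selection ties break on the lowest taxon-index pair, making scans
  deterministic.
* Negative NJ external branches are clamped to 0, then each population's
  branches are divided by that population's maximum — scores land in
  [0, 1] and are comparable across populations with different drift
  scales. Min-max and rank scaling are available behind a flag; the exact
  normalisation is a genuinely open choice and max-scaling is the default
  because it preserves the origin (zero drift stays zero).

Scores are binned in widths of 0.2; the top bin (score >= 0.8) is the
selection-candidate tail. Because `T` diverges near the Fst ceiling, a
score of 0.8 on the max scale corresponds to extreme Fst (roughly >= 0.94
at these sample sizes): the tail is, by construction, near-fixed
differences. Tail genic enrichments and between-population tail log2
ratios reuse the jackknife machinery above.

## The coalescent simulator and B values

`simulate_loci()` drives a single-locus structured coalescent written for
this package (ms-style parameterisation: time in units of 4\*N0
generations, sizes relative to N0, migration `M = 4*N0*m` as the
per-lineage backward rate per unit time, events for size changes, migration
changes and population joins). There is no intra-locus recombination: for
2 kb loci at the default scaled recombination rate the within-locus
genealogical heterogeneity is negligible for the site-count and
allele-frequency summaries used here, and independent loci are what the
jackknife wants anyway. The engine's two unit conventions were pinned
against independent oracles: Watterson's `E[S] = theta * a_{n-1}` for the
mutation side, and exact two-deme island-model coalescence times
(`Fst = 1/(1 + 2M)`) verified against an external coalescent simulator for
the migration side.

A reference demographic model for the four-subspecies system ships as a
parsed ms command (`chimp_model()`): five populations (an unsampled
outgroup plus the four sampled subspecies), post-split migration pulses,
and the adjusted split times. Helpers implement the model-building
arithmetic: `rescale_population()` (grafting normalisation between two
inferred models), `adjust_split_time()` (scaling a split time by the
observed/model Fst ratio with a fixed -0.008 correction), and
`model_fst_check()` / `sfs()` as goodness-of-fit diagnostics.

Background selection enters as B values: a B of 0.8 scales a population's
effective size (all epochs) to 80%, reproducing the expected diversity
reduction at linked neutral sites. `shift_b()` moves an empirical B
distribution by a constant (capped at 1) so a genome-average B grid
(0.88-0.93 by 0.01) can be swept; the effective genic B of the unshifted
distributions is 0.75/0.85 ≈ 0.88. Genic loci draw their class B, non-genic
loci default to B = 1; both are explicit configuration. After a join, the
ancestral population carries the surviving label's B — the alternative
(ancestral B = 1) is not offered because BGS does not switch off in the
ancestor; for *uniform* B the two readings coincide.

`fit_b()` compares observed and simulated enrichment spectra by a sum of
squared differences over population pairs and a bin subset (`all`,
`no-tails`, or the 12 tail bins), skipping missing bins symmetrically, and
returns the argmin of the library grid. Self-consistency (simulate at
B = 0.9, fit against a {0.85, 0.9, 0.95} library) recovers the generating
value in all three bin modes at 6×10^4 loci per library entry.

## Sweep counting

Given a tail definition, 200 kb blocks are ranked by their count of tail
genic SNPs (ties broken by block id) and removed one at a time, recomputing
the focal tail genic enrichment, until it falls below a caller-supplied
threshold (another population's point estimate or CI bound, or a null
reference level). The removal count estimates how many discrete genomic
regions carry the excess. Removal deletes all of a block's SNPs from both
numerator and denominator by default (the enrichment is recomputed on the
remaining data); a tail-SNPs-only mode is available because the alternative
reading is defensible. A shuffled-removal-order baseline quantifies how
concentrated the excess is; with genic ordering the trajectory is
non-increasing and the ranked count can never exceed the shuffled median.

## Gene-set resampling

`gene_mode_resample()` re-implements the gene-mode resampling idea used by
SNP-set enrichment tools: background SNPs are drawn without replacement
until the number of distinct genes hit matches the candidate gene count, so
long genes and clustered paralogs are equally favoured under the null. The
background universe is restricted to SNPs in genes belonging to at least
one set, and an all-genes set can be included as the standard device for
testing small custom collections. A SNP inside overlapping genes counts
toward all of them. Empirical p-values use the add-one rule
`(1 + hits) / (1 + n)` and therefore can never be zero.

The resampling FDR is `R_exp(p) / R_obs(p)` — the mean per-resample count
of pseudo p-values at or below `p`, over the count of observed p-values at
or below `p`, capped at 1. The source description prints the ratio the
other way up, which cannot be a false-discovery *rate* (it is unbounded
and decreasing in evidence); the orientation implemented here is the one
consistent with the prose definition, and the mean (not total) per-resample
count is the only reading that keeps the quantity in [0, 1].

`weighted_gene_resample()` draws size-matched gene sets with probability
proportional to each gene's share of SNPs (gene-length-bias correction) to
test overlap with an a-priori list, with a family-level FDR in which
`R_exp` is summed over the family of tests. With uniform weights it
reduces to hypergeometric sampling, which the tests check against the
closed form. `binomial_overlap_test()` is the exact two-sided
(minimum-likelihood) binomial test for proportion overlaps.

## The synthetic data generator

The generator exists so every stage is testable without any download. It
is frequency-level, not genealogy-level: a root frequency per SNP
(`Uniform(0.05, 0.95)`) drifts down a fixed split tree
`((pop1, pop2), (pop3, pop4))` by Balding-Nichols steps — child frequency
Beta-distributed around the parent with variance `p(1-p)(1 - e^{-tau})`.
Defaults mirror the motivating study's conditions: haploid sample sizes
38/36/20/22 and branch drift times (leaf 0.10/0.08/0.16/0.24, internal
0.12) chosen so pairwise Fst runs from ~0.09 (sister pair) to ~0.3 (most
distant pair). Linkage is emulated by multiplying each branch's drift time
by a Gamma(4, 4) deviate shared within each 200 kb block, so the jackknife
has real block-level correlation to absorb; genic labels come from an
explicit gene layout (6 kb genes every 25 kb, i.e. 40% genic cover after
the 2 kb pad) so they cluster spatially as real annotation does.

**Planted sweeps are completed hard sweeps on population-private
variants.** A sweep event picks a genic SNP whose derived allele is at
frequency <= 0.02 in every non-target population and sets the target
frequency in [0.995, 1]; other private variants within 50 kb hitchhike to
the same range. This design is forced by the scan itself: under
per-population max-scaling the PBSnj tail only admits near-fixed
differences, so partial sweeps (say, to frequency 0.9 with other
populations at intermediate frequencies) land mid-distribution — as they
would in real data — and no generator tuned to partial sweeps can satisfy
a 90% tail-recovery requirement. The hitchhikers matter for the sweep
counting logic: they populate the tail with non-genic SNPs in realistic
proportion, which is what makes block removal actually reduce the
enrichment.

What the generator does **not** emulate: haplotype structure and true LD
decay (only block-level variance inflation), the site frequency spectrum
shape (frequency-level Beta draws have no genealogical SFS; SFS diagnostics
use the coalescent simulator instead), background selection (also the
simulator's job), and multi-allelic or missing-data artefacts beyond what
`emit_dataset()` writes deliberately. Passing tests therefore demonstrate
the statistical machinery, not robustness to every real-data pathology.

## Calibration experiments and problem sizes

The test-suite and the acceptance script size their experiments for a
single CPU; the sizes are the package's chosen study conditions:

* null calibration and CI coverage: 2×10^4 SNPs over 250 blocks per
  replicate, with per-branch drift 0.3 so the delta tails are populated
  under the null; 200-500 replicates. Measured type-I error of the
  asymmetry z-test is 4.4% ± 0.7% (1000-replicate check), coverage ~95%.
* planted-sweep recovery: the default 2×10^5-SNP fixture with 50 sweeps.
* simulator checks: 10^4 loci for Watterson/diversity-linearity;
  6×10^4 loci per library entry for B fitting; 1.5×10^5-locus batches for
  the heterogeneous-BGS asymmetry ceiling (pooled counts across batches,
  because the tail bins hold only a few hundred SNPs at this scale and
  ratios of small counts are noisy).
* In the heterogeneous-BGS scenario (one population at B = 0.825, the
  others at 0.900) the simulated tail asymmetry is positive but small —
  far below the level that population-specific selection produces — which
  is the qualitative point of that experiment; at desk scale its value
  carries a sampling error of roughly ±0.15 on the log2 scale.

## Known limitations

* The scan-facing statistics assume bi-allelic, fully called, polarized
  SNPs; there is no handling of indels, phasing, or imputation.
* The jackknife z-test is slightly anticonservative when blocks are few
  (tens); use block counts in the hundreds or more.
* The sweep-count estimate is threshold-relative and granular at small
  tail sizes; treat it as an order-of-magnitude statement, which is how
  the ranked-vs-shuffled comparison frames it.
* The per-SNP NJ topology code is reported only for K = 4 (the number of
  unrooted topologies grows too fast for a compact label beyond that).
* The coalescent engine is single-locus by design; intra-locus
  recombination, recombination maps and forward selection are out of
  scope.
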