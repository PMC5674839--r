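---
title: "herdscan: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{herdscan: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdscan)
```

herdscan analyses multi-population SNP panels of the kind produced by
medium-density livestock genotyping arrays: quality control, population
structure, runs of homozygosity (ROH) with genomic and pedigree inbreeding,
and a windowed selection-signature scan. This vignette records the models
behind each stage, the conventions chosen where several are defensible, and
what the synthetic-data generator does and does not establish.

## Quality control

QC runs in two ordered stages, mirroring the common command-line workflow:

1. **Call rate.** A SNP is kept when its missing fraction over all
   individuals is at most `geno` (default 0.1). The comparison is
   inclusive: a SNP at exactly 10% missing stays, matching the usual
   "remove rates *above* the bound" semantics.
2. **Per-population MAF and HWE.** Within *every* population separately,
   the minor-allele frequency over non-missing alleles must be at least
   `maf` (default 0.01; "lower than 1%" is removed, so the bound itself
   passes) and the exact Hardy–Weinberg test p-value at least `hwe`
   (default 1e-4). One shared post-QC panel serves all downstream stages,
   so a SNP failing in any single population leaves the panel entirely.

The HWE test is the standard two-sided exact conditional test on the
heterozygote count given the allele counts (sum of the probabilities of all
configurations no more probable than the observed one), with no mid-p
adjustment. MAF is evaluated on within-population frequencies; the
major/minor allele *coding* of the matrix, by contrast, is fixed once on
the merged sample (ties broken lexicographically), because the coded matrix
must mean the same thing in every stage.

## Population structure

* **Observed heterozygosity** of an individual is
  `1 - (homozygous loci / non-missing loci)`.
* **IBS distance** between two individuals is `1 - mean(IBS)/2` over
  jointly non-missing SNPs; classical (Torgerson) multidimensional scaling
  of this matrix — double-centering of squared distances followed by an
  eigendecomposition — gives the ordination. No iterative stress
  minimisation is used, matching the clustering convention of the standard
  command-line tools. When fewer non-negative eigenvalues exist than
  requested dimensions, trailing coordinates are zero and a warning is
  raised.
* **IBD sharing** uses the method-of-moments estimator: per SNP, the
  expected probabilities of IBS state given IBD state are computed from
  merged-sample allele frequencies with the small-sample corrections of
  the `--genome`-style estimator; summed over SNPs and solved
  sequentially for (Z0, Z1, Z2), then clipped and renormalised to the
  simplex. `pi_hat = Z1/2 + Z2`. Because small-sample corrections differ
  slightly among implementations, the tests validate against pedigree
  expectations (monozygotic pairs, parent–offspring), not against another
  program's output bit for bit.
* **F_ST** is Weir & Cockerham's variance-component estimator. Multi-SNP
  values are the ratio of sums `sum(a) / sum(a+b+c)` over SNPs with
  defined components; slightly negative values are possible for
  undifferentiated populations and are retained, except when the matrix
  feeds the neighbor-joining tree or an ordination, where negatives are
  clamped to zero (a distance cannot be negative). Confidence intervals
  are percentile bootstrap over SNP columns (default 1,000 resamples);
  the interval is widened to contain the point estimate under degenerate
  resampling.
* **Neighbor joining** is the Saitou–Nei agglomeration with the standard
  Q criterion. Ties in Q are broken deterministically by the
  lexicographically smallest label pair (clusters are labelled by their
  smallest member tip). A negative branch length is clamped to zero and
  its signed deficit transferred to the sister branch — the
  path-preserving convention, so the distance between the two joined
  nodes is unchanged; we read "deficit added to the sister" this way
  because it is the only reading that preserves additivity. On additive
  distances the algorithm is exact.

## Runs of homozygosity and inbreeding

A ROH is a maximal run of consecutive SNPs that satisfies all of:

| parameter | default | meaning |
|---|---|---|
| `min_snps` | 50 | minimum SNPs in the run |
| `min_length_kb` | 1000 | minimum span (first to last SNP) |
| `min_density_kb_per_snp` | 100 | maximum kb per SNP over the run |
| `max_gap_kb` | 1800 | maximum adjacent-SNP gap |
| `max_het` | 0 | heterozygotes tolerated |
| `max_missing` | 2 | missing calls tolerated |

The defaults reproduce a 50k-density cattle analysis (data at roughly one
SNP per 90 kb). The 50-SNP minimum corresponds to the false-positive bound
`l = ceil(ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het))`
(`lencz_min_snps()`), which gives 49 at the published panel scale
(27,612 SNPs, 9,214 animals, mean heterozygosity 0.37, alpha 0.05); the
inputs are exposed as parameters rather than hard-coding the result.

Detection is an **exact maximal-run search**, not the sliding-window
heuristic of the usual tools: every reported run satisfies all constraints
and no qualifying run is a proper sub-run of another reported run.
Overlapping qualifying runs separated by a disqualifying SNP are reported
separately. The search exploits the fact that the heterozygote, missing
and gap constraints are hereditary (any sub-run of a clean run is clean),
which yields a two-pointer bound per start position; length and density
are then checked from the largest candidate end downward. The test suite
proves equality with a literal O(n^2) enumerator on hundreds of random
instances. One consequence of the maximal-run semantics worth noting:
*summed* segment length can decrease when a relaxed constraint merges two
overlapping runs into one; the union of covered base pairs is the monotone
quantity, and the suite asserts monotonicity on that.

Lengths are spans, `end_bp - start_bp`, consistent with the genome length
`L_AUTO` (sum over chromosomes of the span of SNP positions), which keeps
`F_ROH = sum(L_ROH) / L_AUTO` in [0, 1] by construction. Missingness is
counted per segment, not per 50-SNP window. The long-ROH coefficient
`F_ROH>5Mb` uses a strict `> 5000 kb` cut.

The other coefficients:

* `F_HOM = (O - E) / (N - E)` with `O` observed homozygous loci, `N`
  non-missing loci and `E` the small-sample-corrected expectation
  `sum(1 - 2pq * 2n/(2n-1))` over the individual's SNPs (merged-sample
  frequencies); it can be negative.
* `F_PED` is Wright's coefficient — the kinship of the parents — computed
  by the tabular numerator-relationship recursion (equivalent to
  recursive kinship with memoization). Individuals with an unknown parent
  are treated as founders (F = 0); pedigree cycles are an error naming
  the individuals involved.
* `PCI_5G` is the plain slot proportion: of the 62 ancestor slots in five
  generations, the fraction occupied by known individuals, where a slot
  is unknown as soon as any link on its path is missing. The phrasing
  "95% known ancestors" reads naturally as a slot proportion, so the
  harmonic-mean variant was not adopted.

## The d_i selection scan

For every population pair the per-SNP Weir–Cockerham estimate
`a/(a+b+c)` is computed; SNPs with zero total variance are *undefined*
(`NA`), never zero — imputing zero would deflate d_i at near-monomorphic
SNPs. Each pair's values are standardised by the mean and SD over its
defined SNPs (denominator n-1), and

d_i(SNP) = sum over j != i of (F_ST^ij - E[F_ST^ij]) / sd[F_ST^ij],

with undefined pairs contributing nothing at that SNP. d_i values are
averaged in non-overlapping 1-Mb windows (`floor((pos-1)/1e6)`); windows
with fewer than four defined SNPs are discarded; the window count is
always derived from the map, never assumed. A window is significant when
its mean strictly exceeds the nearest-rank 99th percentile (the
`ceil(0.99 W)`-th smallest of the W retained means): with 2,500 tie-free
windows this flags exactly 25 per group, and 200 across eight groups —
the only percentile convention that reproduces that count structure.
Small closely related populations can be pooled beforehand
(`pool_populations()`), which changes only pair enumeration, never window
geometry.

## The synthetic worlds

`simulate_panel()` draws ancestral frequencies from Uniform(0.05, 0.95)
(bounded away from fixation so post-QC attrition stays small) and
population frequencies from the Balding–Nichols Beta distribution with
divergence F; genotypes are Hardy–Weinberg draws within populations. For
two populations with equal divergence F from a shared ancestor the
pairwise Weir–Cockerham estimate recovers F (within-population allele
correlation F, between-population 0), which is the calibration the tests
assert.

`gene_drop()` gives every founder haplotype a unique label and transmits
recombination mosaics down the pedigree under a Haldane model (Poisson
crossovers at 1 cM/Mb, uniform positions, no interference). True
autozygosity — both haplotypes carrying the same founder label — is
therefore observable exactly, per SNP and per tract. `sim_pedigree()`
provides mating schemes with textbook expectations: full-sib loops
(F = 0.25), half-sib loops (F = 0.125) and random mating.
`inbreeding_cohort()` combines them into a 200-animal cohort spanning
F = 0 to 0.375 on a 10-chromosome, 90-kb-spaced genome — a deliberately
scaled-down (about one third) version of a 29-autosome cattle map, sized
so the whole recovery check runs in well under a minute.

What the generator does **not** emulate: background linkage
disequilibrium within founder populations (founder haplotypes are drawn
per SNP independently, so ROH arise only from pedigree loops, not from
ancient haplotype sharing), genotyping error, mutation, and selection
other than explicitly planted frequency shifts. A green recovery test
therefore establishes that the detector finds IBD tracts of pedigree
origin at realistic SNP density; it does not establish calibration of ROH
counts against real-data LD structure.

`calibration_scan_panel()` fixes the scan's stated world: exchangeable
Balding–Nichols populations on a map with exactly five SNPs in every 1-Mb
window, so the retained-window count is exact and window means are
tie-free almost surely. `plant_frequency_shift()` displaces one
population's frequencies in one window away from the *ancestral* value
(replacing that population's drift). Anchoring the shift at the
population's own drifted frequency was considered and rejected: drift
occasionally cancels such a shift, silently destroying the planted
signal.

### A structural note on "private" planted signals

With K exchangeable groups, a shift planted in one population elevates
the standardised F_ST of *every* pair involving it: the focal
population's d_i gains (K-1) times the per-pair elevation, but each other
population's d_j gains it once — cross-talk dilutes as 1/(K-1). Reliable
detection therefore wants K large. Privacy, however, is bounded by the
percentile rule itself: each unshifted population flags ~1% of windows
regardless of design, so the chance that *no* other population flags the
planted window is at most about 0.99^(K-1) even with zero cross-talk
(about 0.90 at K = 10, 0.895 at K = 12), before cross-talk and detection
losses. The package's acceptance check asserts the
flagged-and-private conjunction at the 90% level as specified; measured
at the stated world (K = 12, shift 0.3, n = 30 per group, 500 windows)
detection succeeds in 100% of replicates while the conjunction reaches
76% (38 of 50 at the frozen seeds), consistent with the ceiling
argument. The conjunction check
is retained unweakened and documented as expected to fail; the detection
property alone is the one the design can guarantee.

## Numerical conventions and degenerate inputs

* Positions are 1-based; all intervals are closed `[start_bp, end_bp]`.
* A genotype with one missing allele in the PED file is wholly missing.
* Monomorphic SNPs: HWE p = 1; per-SNP F_ST undefined; IBD expectations
  skip them.
* `hwe_exact_test` ties: configurations with probability within a
  1e-12 relative tolerance of the observed one are included in the
  p-value (guards against floating-point order effects).
* Bootstrap intervals use `quantile()` type 7 on the resampled ratios.
* MDS eigenvalues below `1e-12 * max(|eigenvalue|)` count as zero.
* All generators take explicit seeds; identical seed and configuration
  reproduce byte-identical outputs, including the pipeline manifest.

## Known limitations

* The ROH detector is exact but quadratic in the worst case within long
  clean stretches; at 50k density this is immaterial, at sequence density
  it would not be.
* `ibd_moments` loops over all pairs in R; for cohorts beyond a few
  thousand individuals a compiled kernel would be warranted.
* The scan assumes autosomal, biallelic, mapped SNPs; sex chromosomes and
  unmapped markers are out of scope.
* Pairwise F_ST on highly unbalanced samples inherits the known
  small-sample behaviour of the Weir–Cockerham estimator; no
  Hudson-style alternative is provided.
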