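---
title: "Detecting ectopic gene conversion among LTR elements"
author: "ltrconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ectopic gene conversion among LTR elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Long Terminal Repeats (LTRs) are the 0.3–1.6 kb regulatory repeats that
flank Human Endogenous Retroviruses; recombination between the two LTRs of
a provirus leaves behind a single "solo" LTR. Because hundreds of
near-identical copies are scattered across the genome, LTRs are natural
substrates for *ectopic (non-allelic) gene conversion*: the unidirectional
copying of a short DNA tract from a paralogous "donor" into an "acceptor"
locus. On the haploid, non-recombining male-specific region of the Y
chromosome (MSY), conversion leaves a distinctive footprint. Wherever the
donor differs from the acceptor at paralogous sequence variants (PSVs), a
single conversion event deposits several new alleles at once — physically
close together and, crucially, on a *single branch* of the Y genealogy.

`ltrconv` implements the full inference chain for this footprint on
intra-species resequencing panels of haploid haplotypes:

1. variant calling from an aligned panel against a reference
   (`call_variants()`);
2. polarization of every variant on a fixed, known phylogeny
   (`polarize_and_assign()`), with homoplasy accounting
   (`count_events()`);
3. nucleotide diversity per region (`nucleotide_diversity()`);
4. detection of clusters of phylogenetically equivalent, closely spaced
   variants (`detect_clusters()`) and an excess test against a
   permutation null with a Poisson tail (`permutation_null()`,
   `poisson_tail_p()`), plus Fisher comparisons of clustered proportions
   between datasets (`fisher_exact_two_sided()`);
5. donor identification by exact identity of the derived tract
   (`match_donors()`) and conversion-tract bounds from flanking
   non-converted PSVs (`tract_bounds()`);
6. a forward simulator with complete ground truth
   (`simulate_dataset()`), used to calibrate and stress every stage.

## The model and its assumptions

**Polarity on a fixed tree.** The phylogeny is an input, never
re-estimated: the Y genealogy is assumed known from independent haplogroup
markers. Each biallelic variant is polarized by Fitch small parsimony with
the root state taken as the ancestral allele. When the root set is
ambiguous, the tie is broken by a designated outgroup tip (the natural
choice is a basal lineage, which reproduces polarity known from prior
haplogroup work) or, failing that, by the major allele; such variants are
flagged `placement_ambiguous`. Remaining freedom in the refinement is
resolved by propagating the parent state wherever the child's state set
allows it, which makes the output deterministic and invariant to tip
order. Each state change on an edge is one mutational event on that named
branch; events that restore the ancestral allele are labelled `back`.
Multi-allelic sites are rejected rather than guessed (`on_multiallelic =
"drop"` skips them with a warning in pipeline runs); indels are polarized
exactly like SNPs as presence/absence states.

**Clusters.** A cluster is a maximal same-branch chain of two or more
variants in which every *adjacent* pair is at most `max_gap = 50` bp
apart; the overall span may exceed 50 bp. Spans are counted inclusively
(`end − start + 1`). Homoplasic variants enter detection once per
(variant, branch) event, so a recurrent variant can anchor clusters on
several branches.

**The excess test.** Under the null, the observed variant count is
scattered uniformly over the sequenced length (distinct positions,
sampled without replacement) and branches are assigned uniformly at
random; 1000 replicates give the mean number of clustered variants,
`lambda`. The test statistic is the *number of clustered variants* (not
the number of clusters), and its upper tail is evaluated as
Poisson(`lambda`) in log space, so values far below `1e-300` retain an
exact `log10_p`. Two caveats are deliberate:

* the clustered count is *compound*: a chance pair contributes two
  clustered variants at once, so the null variance is roughly twice its
  mean and the Poisson tail is mildly anticonservative at conventional
  significance levels (the calibration test bounds the rejection rate at
  `alpha = 0.05` by 0.12 rather than 0.05). For the deep-tail excesses
  the method is used to assess — observed counts many times `lambda` —
  this slack is immaterial;
* with finite replicates `lambda` can be exactly 0; `excess_test()` then
  substitutes the continuity guard `1/(2·reps)` and flags the result.

**Diversity.** `nucleotide_diversity()` is the average number of pairwise
differences per site, without small-sample correction, and its standard
deviation is the square root of Nei's (1987, eq. 10.7) sampling variance
— the standard reading of "according to Nei"; `variance = "none"`
disables it. Sites with missing data are excluded pairwise-complete while
`L` stays fixed (published region lengths are fixed quantities); an indel
run counts as one difference regardless of length. Pooled estimates
concatenate regions (pooled differences over pooled length) rather than
averaging per-element values; the per-element table is also reported.

**Donors and tract bounds.** A donor-library entry explains a cluster iff
its acceptor-aligned bases are 100% identical to the *derived* state of
the cluster over its span — one mismatch destroys the hit. Clusters
spanning < 3 bp are excluded from the search (a 2 bp tract matches
paralogs everywhere by chance). The minimum conversion tract is the
observed span; the maximum is bounded by the nearest flanking PSVs at
which the converted chromosome retains the acceptor base, counting bases
strictly between them (`R − L − 1`). The printed data do not disambiguate
whether flanking PSV positions should be included, so the convention is
config-switchable (`mode = "inclusive"` gives `R − L + 1`). The
genome-wide donor search of the original analysis is replaced by exact
matching against a user-supplied donor library: the criterion is exact
identity either way, and a simple ungapped sliding aligner
(`align_donor()`) re-anchors near-equal-length paralogs.

## The synthetic-data generator

`simulate_dataset()` evolves an ancestral sequence down a fixed rooted
tree. On each branch it applies Poisson(`mut_rate`) point mutations at
uniform positions and Poisson(`conv_rate`) conversion events, each
copying a tract (uniform start; geometric length, mean `tract_mean`,
truncated at the locus end) verbatim from a uniformly chosen donor.
Donors are generated by `generate_donor_library()` as copies of the
ancestor mutated at Binomial(L, `psv_rate`) positions. Defaults emulate
the empirical scale of Y-chromosome LTR panels: 16 tips (30 branches),
1550 bp locus, 2% donor divergence, ~1 mutation per branch, geometric
tracts of mean 100 bp (observed maximum tracts average ≈99 bp), no
sequencing error (chromatogram-grade data; `error_rate` adds uniform
miscalls for robustness checks).

What the simulator deliberately does **not** model: donor evolution
(tracts are copied from the donor's ancestral state, keeping truth
unambiguous), coalescent tree variation, crossover recombination,
selection, and alignment error. Passing recovery tests therefore
demonstrate that the *inference chain* is correct under its own model —
clusters arise exactly where conversion tracts covered ≥2 PSVs — not that
real data are free of alignment or calling artefacts.

Ground-truth recovery (`truth_report()`) treats a conversion as
*detectable* when its tract covers at least `min_psvs` donor PSVs; with
the default operating point (2% divergence, tracts of mean 100 bp,
16 tips) tracts covering ≥3 PSVs are recovered with recall and precision
above 0.9 averaged over 100 replicate seeds, and reported
`[min, max]` bounds contain the true tract length in ≈98% of detections.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; BED-style inputs must be
  converted on read. The missing-genotype symbol is `N`; other ambiguity
  codes are rejected (meaningless on haploid data).
* Indels are collapsed to one variant anchored at the leftmost affected
  base and count as single differences/events throughout.
* Columns invariant in the panel but different from the reference are
  *reference-specific positions*, reported separately and never counted
  as polymorphisms.
* Variants with >20% missing genotypes are flagged but retained.
* Unlabeled internal Newick nodes are auto-named `b1..bk` in preorder, so
  branch assignments are reproducible across runs.
* The permutation null samples positions without replacement (distinct
  sites); branch labels are uniform. Preserving per-branch variant counts
  instead is a conceivable alternative null, not currently implemented.
* The published variant total is quoted as both 134 and 136 in different
  places; analyses here default to 134, and `run_config()` exposes
  `n_variants_override` so either convention is reproducible. Likewise
  the published table prints one cluster length (63) that disagrees with
  its own coordinates (64, inclusive); the recomputation treats the
  printed value as a typo and documents the exception.
* The pipeline reports raw p-values; no multiple-testing correction is
  applied across its handful of tests, matching standard practice for
  this analysis.

## Problem sizes used by the test-suite

Property tests compare implementations against brute-force oracles at
enumerable sizes: exhaustive parsimony labelings up to 12 tips,
exhaustive cluster-subset enumeration up to 15 variants, and direct
pairwise counting for diversity. Stochastic properties (null calibration,
recovery metrics) use fixed seeds, 500-dataset calibration batches and
100 replicate simulations at the default operating point — sizes chosen
so every claim is recomputed from scratch in well under a minute each.

## Worked example

```r
library(ltrconv)

sim <- simulate_dataset(sim_config(seed = 42))
res <- run_pipeline(run_config(sim = sim, out = tempfile(), seed = 7))

res$proportion   # clustered variants k / n and percentage
res$null$lambda  # mean clustered count under the permutation null
res$excess$p     # Poisson upper-tail probability of the observed count
res$donor_hits   # exact-identity donors with [min, max] tract bounds
```

## Limitations

Beyond the simulator's scope (above): the donor search is only as
complete as the supplied library; gapped donor alignment is out of scope;
the Poisson tail inherits the compound-count anticonservativeness noted
earlier; and polarization assumes the fixed tree is correct — variants
inside conversion hotspots are exactly the ones that can mislead tree
*building*, which is why the tree must come from independent markers.
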