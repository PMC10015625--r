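---
title: "Methods: windowed introgression landscapes with introscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed introgression landscapes with introscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

introscape characterises where in a genome interspecific introgression has
landed and how that placement relates to recombination rate and gene
density. The package covers the full chain from biallelic SNP genotypes to
classified genomic regions: site-pattern statistics that detect and
quantify admixture, per-window scans that localise it, topology weighting
that expresses the accompanying gene-tree discordance, a windowed
differentiation landscape, and a small comparative model for a binary
mating-system trait. A built-in multispecies-coalescent simulator supplies
ground-truthed data for every stage, and all of the package's own
calibration claims are made on that simulator, never on empirical data.

This vignette is the package's methods statement: the models, their
assumptions, the tunable parameters and why their defaults are what they
are, what the simulator does and does not emulate, and the numerical
conventions that make every result reproducible bit for bit.

## 1. The coalescent simulator

`species_tree_model()` describes a demography as a rooted, binary,
ultrametric species tree with branch lengths in generations, a diploid
effective size `Ne` per branch, a per-site per-generation mutation rate
`mu`, and a list of admixture pulses. A pulse `(time, donor, recipient, f)`
uses the standard backward-time convention: each sampled lineage present in
the recipient branch at the pulse time is rerouted into the donor branch
independently with probability `f`. Forward in time this is a hybridization
episode in which the recipient population acquires a fraction `f` of its
genome from the donor.

`simulate_dataset()` draws one genealogy per window under this demography
(coalescence at rate `choose(k,2)/(2*Ne)` within each branch), drops
infinite-sites mutations at rate `mu` per site, and emits diploid
alternate-allele dosages plus a truth table: per window, the rho covariate,
whether any sampled lineage was rerouted by a pulse (the `introgressed`
flag), and how many. Windows are genealogically independent: the analyses
downstream treat 10 kb windows as units, and a per-window single genealogy
preserves the distribution of every statistic tested while keeping the
simulator desk-scale. Two deliberate simplifications follow from that
choice:

* **No intra-window recombination.** Within-window site patterns are
  perfectly correlated in genealogy; across windows they are independent.
  Real data sit in between. This matters for significance machinery (see
  the block jackknife and the D_FOIL chi-square below) and is why the
  calibration conditions use a low mutation rate (few sites per window)
  when approximate site independence is the relevant regime.
* **rho is a covariate, not a mechanism.** The per-window
  population-scaled recombination rate is drawn (by default lognormal,
  meanlog `log(5)`, sdlog 1 — the right-skewed shape typical of per-10 kb
  rho tracks) and exported; it does not alter the within-window genealogy.
  This mirrors the analysis situation in which rho is an externally
  estimated track joined to the window table.

The link between recombination and introgression is modelled
phenomenologically by `apply_retention()`: each truly introgressed window
is kept with probability `retention(rho)` and otherwise relabelled and
re-simulated without pulses — the selective purging of introgressed
ancestry in low-recombination regions reduced to its observable
consequence. A monotone increasing retention function therefore induces,
by construction, a positive association between surviving introgressed
ancestry and rho; the landscape stage is tested on exactly that signal.

What the simulator does **not** emulate: selection at loci, continuous
migration, sequencing error, depth variation, missing genotypes, or
reference bias. Passing tests on simulated data show the statistics and
the pipeline plumbing are correct and calibrated under the model
assumptions; they do not show robustness to those real-data complications.

## 2. Site-pattern statistics

All frequency statistics consume `polarize()` output: derived-allele
frequencies per population with the ancestral state defined as the allele
fixed among genotyped outgroup samples. Outgroup-polymorphic and
outgroup-missing sites are dropped and counted; a near-fixation acceptance
threshold is available but the default is strict fixation, the
conservative reading of an unstated convention.

With `p1, p2, p3` the derived frequencies in a trio and the outgroup
ancestral by construction:

* `ABBA = sum (1-p1) p2 p3`, `BABA = sum p1 (1-p2) p3`,
  `D = (ABBA-BABA)/(ABBA+BABA)`.
* Significance comes from a delete-one block jackknife over contiguous
  equal-site blocks (default 20 blocks, the customary windowed-scan
  default), `Z = D/SE`, two-sided normal tail. With an estimated SE and
  20 blocks the normal tail is mildly anticonservative (t-like with 19
  df); the package's null-calibration check budgets for this by requiring
  the empirical type-I rate at nominal 0.05 to stay at or below 0.08,
  which it does (measured 0.078-0.080 over 400 ILS-only replicates).
* `d_min()` evaluates the three arrangements of an unordered triple and
  reports the minimum-|D| arrangement — the conservative choice when the
  species tree is not taken on faith — oriented so that D is nonnegative
  (P2 is the putative recipient). The least conservative
  (most-significant) arrangement is also exposed, but the pipeline always
  uses the minimum-|D| convention; the "most significant" aggregation in
  reporting happens across trios sharing a donor-recipient pair, not
  across arrangements.
* `f_hom = (ABBA1-BABA1)/(ABBA2-BABA2)`, the observed excess scaled by
  the excess under complete homogenization of P2 by P3 (the denominator
  substitutes P3 for P2). The plain-product denominator contains
  `E[p3_hat^2] = p3^2 + p3(1-p3)/(2n3)`, so the estimator is biased
  downward when the donor sample is small or divergence is shallow; it is
  the conservative member of the admixture-fraction family. The default
  study demography (below) keeps this bias inside a +/-0.05 recovery band
  at true fractions 0.05-0.2.
* `f_dm_track()` computes the windowed symmetric dynamic-donor
  admixture-proportion statistic: per site the numerator is ABBA-BABA;
  the denominator substitutes the per-site donor (whichever candidate has
  the larger derived frequency) for the recipient, with the mirrored
  negative form when the excess points at P1. Windows with fewer than 10
  usable SNPs (the standard scan threshold) are masked.
* `call_pir()` flags the top x% of defined windows by this statistic,
  with x set per trio to `100 * f_hom` (a negative estimate yields an
  empty set — a negative genome-wide fraction is uninterpretable). The
  introgression index of a window is the fraction of significant trios
  (Benjamini-Hochberg adjusted p below 0.01) flagging it.

## 3. Five-taxon D_FOIL tests

For a symmetric quintet ((P1,P2),(P3,P4),O) in which the P3-P4 split
predates the P1-P2 split, four statistics (DFO, DIL, DFI, DOL) are formed
from frequency-weighted biallelic site-pattern counts. Each statistic
pairs two 2-derived patterns with one 3-derived and one singleton pattern
per side; the corrections are what cancel terminal-branch-length
asymmetries, so that each statistic has expectation exactly zero under the
null by an exchangeability argument (P3<->P4 for DFO/DIL, P1<->P2 for
DFI/DOL). Quintets violating the divergence-order precondition are refused
rather than mislabelled.

Each statistic is tested with a one-degree-of-freedom chi-square on its
left/right pattern sums (the convention of the reference implementation of
these tests), and the joint sign pattern at level alpha (default 0.01) is
looked up in a frozen signature table: all four zero is `none`; DFO and
DIL jointly positive (negative) with DFI and DOL zero is `ancestral`
introgression involving P3 (P4) and the common ancestor of P1 and P2; the
eight directional scenarios each zero out exactly one pair-specific
statistic and are labelled donor-to-recipient. The table was frozen
against noiseless branch-length expectations accumulated over 30,000
simulated genealogies per scenario; all ten signatures are distinct, and a
regression test pins the exact symmetry `(DFO,DIL,DFI,DOL) ->
(-DIL,-DFO,-DOL,-DFI)` under the simultaneous P1<->P2, P3<->P4 swap.

The chi-square treats sites as independent. Sites sharing a window share a
genealogy, so the statistic is overdispersed in proportion to the number
of informative sites per window; the D_FOIL study conditions therefore use
a sparse mutation rate (2e-8, a handful of segregating sites per window)
and many windows, which keeps the spurious-significance rate of the
true-zero statistics low while the genuinely nonzero statistics
accumulate chi-square linearly in the window count.

## 4. Trees, topologies, weighting

Per-window trees are neighbor-joining on the dosage p-distance
`sum |d_i - d_j| / (2 n_shared)`; any externally supplied newick trees can
be used instead, since tree inference is deliberately pluggable.
`canonical_topology()` sorts children lexicographically at every node,
giving a branch-length-free identifier invariant to rotation and ladder
order. `count_topologies()` is the double factorial `(2m-3)!!` on the free
taxa (exact in double precision through roughly 18 free taxa, far beyond
the eight-group ceiling enforced by the weighting);
`enumerate_topologies()` provides the exhaustive cross-check for small
label sets.

`topology_weighting()` follows the Twisst scheme: sample one tip per taxon
group, prune, relabel tips by group, canonicalize, tally; exhaustively
when the combination count is at most 10,000 and by seeded uniform
Monte Carlo (default 1,000 draws) otherwise. Weights are normalized per
window; `main_topologies()` averages across windows and flags topologies
above a 1.5% genome-wide frequency. `quartet_score()` reports the fraction
of four-taxon subtrees of the gene trees that agree with a candidate
species tree, over all resolved shared quartets, with multi-tip species
handled through the group map; quartet topologies are read off unit-length
path distances via the four-point condition, and an independent
prune-and-canonicalize oracle confirms the route in tests.

The bootstrap-support window filter used by some windowed-phylogenomics
workflows is represented only as the `window_site_stats()` pass flags (at
least 200 sites and 20 parsimony-informative sites by default, where a PIS
is a site whose two alleles are each carried by at least two haplotypes,
counted on dosages with each diploid contributing two observations); a
site-resampling support filter was considered and left out of the default
path as it adds runtime without changing any tested property.

## 5. The differentiation landscape

`fst_windows()` implements the Weir-Cockerham (1984) two-population
variance components per site from dosages (heterozygotes are dosage-1
diploids), combined per window as the ratio of summed components — the
weighted windowed convention of the standard VCF tools. Sites where either
population has fewer than two genotyped diploids are excluded; window
values are reported unclamped, so slightly negative values are expected
and meaningful. The F_ST index of a window is the fraction of population
pairs for which the window is a top-5% outlier of that pair's track.

Region classes follow fixed, auditable rules: high-introgression windows
are the top 5% by introgression index (the realized index threshold is an
output, never an input), low-introgression windows have index exactly
zero, and high-F_ST windows (putative introgression barriers) exceed an
index of 1/3. Every top-q cut in the package takes exactly
`ceiling(q * n_defined)` windows, breaking ties by genomic order, so
counts are reproducible to the window.

`binned_correlation()` computes the Pearson correlation between bin means
after an equal-count partition of the covariate (default 20 bins; the bin
count in comparable published landscape plots is typically unstated, so
this default is flagged as a reproduction caveat), alongside the raw
per-window correlation for transparency. `sweep_intersect()` reproduces
the two-method sweep-calling scheme: union of per-reference top-1% windows
of one score family, intersected with the top-5% windows of a second
composite score; both score tracks are pluggable inputs, never computed
internally.

## 6. The mating-system Mk model

`fit_mk()` is a classic model-fitting function: two-state continuous-time
Markov model (state 0 self-compatible, state 1 self-incompatible) on a
dated tree, pruning-algorithm likelihood with the closed-form 2x2
transition matrix, root integrated against the stationary distribution of
the rate matrix (uniform prior optional). The symmetric model (one rate)
is fitted by 1-d bounded optimization on the log scale and the asymmetric
model (separate gain rate q01 and loss rate q10) by multi-start L-BFGS-B;
a nesting guard ensures the asymmetric likelihood never falls below the
symmetric one. Model choice is by a 1-df likelihood-ratio test and AIC.
`marginal_ancestral()` combines tip-ward and root-ward partial likelihoods
for proper marginal node probabilities, validated against exhaustive
enumeration over all internal-state assignments on 10-tip trees and
cross-checked against an independent implementation of the same model.
Maximum likelihood with LRT/AIC stands where a Bayesian engine might be
used for the same comparison; the symmetric-versus-asymmetric question is
itself a likelihood-ratio question and needs no sampler.

Calibration conditions: unit-depth 10-tip coalescent trees, rates around
1.5 changes per tree depth for the null (LRT rejects in well under 10% of
replicates at alpha 0.05) and a 5:1 rate ratio for recovery (median fitted
ratio within a factor of two of truth at 200 replicates). Boundary cases —
all tips in one state — are flagged degenerate rather than fitted
silently.

## 7. Stock study demographies and problem sizes

Two documented configurations drive all calibration and power checks; they
are ordinary `species_tree_model()` objects and every parameter can be
overridden.

* `default_demography()`: symmetric quintet
  `(((P1,P2),(P3,P4)),O)` with splits at 10, 15, 20 and 50 thousand
  generations, Ne 5,000 everywhere, mu 1e-7, samples 4+4+4+4+2 diploids
  (`default_samples()`). Divergences of one to a few 2Ne leave substantial
  ILS while keeping the homozygous-denominator admixture estimator inside
  its +/-0.05 recovery band: shallower splits push `f_hom` toward half its
  target because the denominator's `p3(1-p3)/(2n3)` sampling term rivals
  the true homogenization excess. Admixture-fraction recovery uses a pulse
  at 100 generations (recent hybridization, minimal post-pulse drift) and
  5,000 windows; null calibration uses mu 2e-8 and 300 windows per
  replicate trio so that sites are sparse within windows.
* `dfoil_demography()`: the same shape tuned for five-taxon power at a
  modest fraction (f = 0.2): P1-P2 split at 6,000 generations above a
  small ancestral size (Ne 1,000, so ancestral-pulse lineages have
  coalesced before the pulse at 11,000 generations), a reduced-Ne P3
  (2,000, so rerouted lineages actually capture donor ancestry), a long
  P3-P4 stem, mu 2e-8, 2,000 windows, two diploids per ingroup. Under
  these conditions both the directional (P3 into P2) and the ancestral
  (P3 into the P1-P2 ancestor) scenarios are classified correctly in well
  over 80% of replicates at alpha 0.01.

Other fixed problem sizes used by the test-suite and the acceptance
script: the retention landscape runs 2,000 windows with a logistic
retention centred on the rho median; the heavy-ILS weighting check uses a
five-ingroup tree with 4,000-5,000-generation internal branches, 300
windows, per-window NJ trees, and exhaustive weighting (64 combinations
per window). These sizes were chosen once as the smallest at which each
property is comfortably measurable, and the vignette text is the record
of that choice.

## 8. Numerical conventions and degenerate inputs

* Coordinates: VCF positions stay 1-based; windows and annotation
  intervals are 0-based half-open throughout.
* Every top-quantile cut takes `ceiling(q * n_defined)` items with
  genomic-order tie-breaking; quantile partitions place remainders in the
  lowest groups (101 windows in 5 groups -> 21,20,20,20,20).
* Zero denominators: D on zero ABBA+BABA is flagged undefined; f_hom on a
  zero homogenization denominator warns and returns NA; a D_FOIL
  statistic with empty pattern sums is zero-with-flag; F_ST windows with
  no usable site are NA; a constant response in the binned correlation is
  reported as r = 0 with a degenerate flag rather than NA, so downstream
  tables stay rectangular.
* Site filters are evaluated jointly on the unfiltered site list, so the
  retained set is independent of rule order; per-rule drop counts are
  attached to the genotype matrix and printed, keeping every filter
  auditable. Depth filters are logged no-ops when the VCF has no DP
  field, as with simulated data.
* All randomness flows through explicit integer seeds; a fixed seed fixes
  every output byte of `simulate_dataset()`, `apply_retention()`, and
  `run_pipeline()` artifacts.

## 9. Known limitations

* The significance machinery inherits the field's conventions — block
  jackknife with a normal tail, per-statistic chi-square — and both are
  mildly anticonservative under strong intra-window correlation. The
  package documents and budgets for this rather than replacing the
  conventions.
* The D_min arrangement choice is conservative by design; on triples
  whose true arrangement is uninformative it can understate evidence.
* `f_hom` is a conservative admixture-fraction estimator; with few donor
  samples or very shallow divergence it underestimates, and the package
  deliberately does not de-bias it (the complete-homogenization limit
  f_hom = 1 at p2 == p3 is part of its definition).
* The retention device models the recombination-introgression association
  at the window scale only; it says nothing about the haplotype-scale
  dynamics that produce it.
* The Mk model assumes a correct, error-free chronogram and binary,
  error-free tip states; rate estimates on ten-tip trees carry wide
  sampling intervals, which is why the recovery claim is a factor-of-two
  band on the median over replicates.

## 10. A minimal end-to-end run

```{r example}
library(introscape)

model <- default_demography(
  pulses = data.frame(time = 100, donor = "P3", recipient = "P2", f = 0.2))
windows <- window_model(2000, 1e4,
                        retention = function(rho)
                          plogis(2 * (log(rho) - log(5))))
sim <- simulate_dataset(model, windows, default_samples(), seed = 31)
sim <- apply_retention(sim, seed = 32)

run <- run_pipeline(sim = sim, seed = 31, out_dir = "introscape-demo")
print(run)

# windowed tracks, region classes, correlations:
head(run$windows)
run$regions
run$correlations$introg_vs_rho
```
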