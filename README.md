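# introscape

Windowed introgression landscapes, topology weighting, and ancestral
mating-system reconstruction for resequenced species complexes.

## The problem

In rapidly radiating plant and animal groups, hybridization leaves
introgressed ancestry scattered across the genome, and incomplete lineage
sorting (ILS) scatters gene-tree topologies on top of it. Questions that
follow from whole-genome resequencing of such a group — *which species
pairs exchanged genes, what fraction of the genome is introgressed, where
does introgressed ancestry survive, and does its placement track
recombination rate and gene density?* — are usually answered with a chain
of single-purpose command-line tools. introscape implements that chain as
one tested R package, aimed at population geneticists analysing biallelic
SNP matrices (a VCF plus a sample-to-population map and a designated
outgroup) in fixed nonoverlapping genomic windows, with every stage
exercisable against a built-in multispecies-coalescent simulator that
knows the truth.

## What it computes

For derived-allele frequencies $p_1, p_2, p_3$ in a trio $(P_1, P_2; P_3)$
polarized against an outgroup $O$:

* **ABBA-BABA / D:** with $\mathrm{ABBA}=\sum (1-p_1)p_2p_3$ and
  $\mathrm{BABA}=\sum p_1(1-p_2)p_3$,
  $D = (\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$, with
  a delete-one block-jackknife Z and two-sided p, Benjamini–Hochberg
  correction across trios, and the conservative $D_\mathrm{min}$
  arrangement choice over the three orderings of an unordered triple.
* **Admixture fraction:**
  $f_\mathrm{hom} = S(P_1,P_2,P_3,O)/S(P_1,P_3,P_3,O)$, the observed
  ABBA-BABA excess scaled by the excess under complete homogenization of
  $P_2$ by $P_3$; per species pair the maximum over $P_1$ choices is the
  reported genomic proportion of introgression.
* **Localization:** the windowed symmetric dynamic-donor statistic
  $f_{dM}$ per 10 kb window (windows under 10 SNPs masked), putatively
  introgressed regions (pIRs) as each significant trio's top
  $100 f_\mathrm{hom}\%$ of windows, and a per-window **introgression
  index** = fraction of significant trios flagging the window.
* **Five-taxon D_FOIL:** the four statistics DFO, DIL, DFI, DOL on a
  symmetric quintet $((P_1,P_2),(P_3,P_4)),O$, chi-square per statistic,
  and classification of the sign signature into none / ancestral / eight
  directional donor-recipient scenarios.
* **Discordance:** Twisst-style topology weighting over at most eight
  taxon groups (exhaustive or seeded Monte Carlo), canonical topology
  identifiers, genome-wide main topologies (frequency > 1.5%), rooted
  topology counts ($(2m-3)!!$; 10,395 for eight groups with a fixed
  outgroup), and the normalized quartet score of a species tree against
  per-window trees.
* **Differentiation landscape:** Weir–Cockerham $F_{ST}$ per window
  (ratio of summed variance components), a top-5% outlier **F_ST index**
  across population pairs, region classes (high introgression = top 5% of
  the introgression index; low = index 0; high $F_{ST}$ = index > 1/3),
  recombination-rate quintile partitions, binned Pearson correlations of
  any response against rho or gene density, and two-track selective-sweep
  intersection.
* **Mating system:** a two-state Mk model (self-compatible vs
  self-incompatible) on a dated tree — pruning likelihood, ML fits of
  symmetric ($q_{01}=q_{10}$) and asymmetric rates, 1-df LRT and AIC, and
  marginal ancestral-state probabilities at every node.

The simulator (`species_tree_model()`, `simulate_dataset()`) draws one
genealogy per window under a dated species tree with branch-specific Ne
and instantaneous admixture pulses of fraction $f$, drops infinite-sites
mutations, and emits diploid dosages plus per-window truth (introgression
flags, rho). `apply_retention()` keeps introgressed windows with
probability `retention(rho)`, reproducing the preferential survival of
introgressed ancestry in high-recombination regions as an explicit,
testable mechanism.

## Worked example

Simulate a four-ingroup radiation with a recent pulse from P3 into P2
(f = 0.2) and recombination-dependent retention, then run the full
pipeline:

```r
library(introscape)

model <- default_demography(
  pulses = data.frame(time = 100, donor = "P3", recipient = "P2", f = 0.2))
windows <- window_model(2000, 1e4,
                        retention = function(rho) plogis(2 * (log(rho) - log(5))))
sim <- simulate_dataset(model, windows, default_samples(), seed = 31)
sim <- apply_retention(sim, seed = 32)
run <- run_pipeline(sim = sim, seed = 31)
print(run)
```

```
introscape pipeline run (seed 31 )
  trios tested: 4 | significant: 3 (BH-adjusted p < 0.01)
  mean f_hom over significant trios: 0.0627
Region classification over 2000 windows
  high introgression: 100 (realized index threshold 0.3333)
  low introgression : 1712
  high F_ST         : 47
  high-F_ST overlap:  5 with high-, 36 with low-introgression windows
  introgression index vs rho: Binned correlation (20 bins): r = 0.71, p = 0.000457
  raw per-window: r = 0.128, p = 9.77e-09
```

Three of the four trios carry a significant introgression signal — the
pulse touches every trio containing P2 and P3. The trio table shows where:

```r
print(run$trios[, c("P1", "P2", "P3", "D", "Z", "p_adj", "f_hom")], digits = 3)
```

```
  P1 P2 P3      D     Z    p_adj  f_hom
1 P1 P2 P3 0.4627 18.90 4.57e-79 0.0919
2 P1 P2 P4 0.1224  2.76 7.64e-03 0.0173
3 P3 P4 P1 0.0401  1.16 2.47e-01     NA
4 P4 P3 P2 0.2574  9.59 1.74e-21 0.0789
```

The direct (P1,P2;P3) trio estimates f_hom = 0.092: about 9% of P2's
genome reads as introgressed *after* retention has purged roughly half of
the injected 20% (retention averages ~0.5 across the rho distribution).
The top-100 high-introgression windows sit at markedly higher
recombination rates than the 1,712 zero-index windows, and the binned
correlation of the introgression index against true rho is strongly
positive (r = 0.71, p = 0.0005) — the simulated counterpart of the
empirical observation that introgressed ancestry survives preferentially
where recombination is high.

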