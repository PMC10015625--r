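# Stock study demographies used by the package's own calibration and
# power checks. Both are ordinary species_tree_model objects; every
# parameter can be overridden. Rationale for the shapes and sizes is laid
# out in the methods vignette.

#' Default four-ingroup study demography
#'
#' A symmetric five-taxon species tree
#' `(((P1,P2),(P3,P4)),O)` with splits at 10, 15, 20 and 50 thousand
#' generations, a uniform diploid Ne of 5000 and mutation rate 1e-7 per
#' site per generation: divergences of a few Ne that leave substantial
#' incomplete lineage sorting while keeping admixture-fraction estimators
#' well conditioned. This is the stock configuration for D/f_hom
#' calibration and landscape simulations.
#'
#' @param pulses optional pulse data.frame (see [species_tree_model()]);
#'   branch ids are `P1..P4`, `O`, `A12`, `A34`, `AI`, `R`.
#' @param ne,mu overrides.
#' @return a [species_tree_model()].
#' @export
default_demography <- function(pulses = NULL, ne = 5000, mu = 1e-7) {
  species_tree_model(
    "(((P1:10000,P2:10000)A12:10000,(P3:15000,P4:15000)A34:5000)AI:30000,O:50000)R;",
    ne = ne, mu = mu, pulses = pulses)
}

#' Default diploid sample sizes for [default_demography()]
#'
#' Four diploids per ingroup species and two for the outgroup, the
#' sampling depth at which the homozygous-denominator admixture estimator
#' is well behaved.
#' @return named integer vector.
#' @export
default_samples <- function() c(P1 = 4, P2 = 4, P3 = 4, P4 = 4, O = 2)

#' Study demography for five-taxon D_FOIL scenario checks
#'
#' The same symmetric quintet shape tuned for D_FOIL power at a modest
#' admixture fraction: a recent (P1,P2) split above a small-Ne ancestral
#' branch (so ancestral-pulse lineages are coalesced before the pulse), a
#' reduced-Ne P3, and a long (P3,P4) stem. The two canonical scenarios
#' are exposed directly.
#'
#' @param scenario `"none"`, `"directional"` (P3 into P2 at 100
#'   generations), or `"ancestral"` (P3 into the ancestor of P1 and P2
#'   at 11,000 generations).
#' @param f admixture fraction for the pulse scenarios (default 0.2).
#' @param mu mutation rate (default 2e-8; sparse enough that site
#'   patterns are close to independent across windows).
#' @return a [species_tree_model()].
#' @export
dfoil_demography <- function(scenario = c("none", "directional", "ancestral"),
                             f = 0.2, mu = 2e-8) {
  scenario <- match.arg(scenario)
  pulses <- switch(scenario,
    none = NULL,
    directional = data.frame(time = 100, donor = "P3", recipient = "P2",
                             f = f),
    ancestral = data.frame(time = 11000, donor = "P3", recipient = "A12",
                           f = f))
  species_tree_model(
    "(((P1:6000,P2:6000)A12:14000,(P3:14000,P4:14000)A34:6000)AI:30000,O:50000)R;",
    ne = c(P1 = 5000, P2 = 5000, P3 = 2000, P4 = 5000, O = 5000,
           A12 = 1000, A34 = 5000, AI = 5000, R = 5000),
    mu = mu, pulses = pulses)
}

#' Sample sizes for the D_FOIL study demography
#' @return named integer vector (two diploids per ingroup, one outgroup).
#' @export
dfoil_samples <- function() c(P1 = 2, P2 = 2, P3 = 2, P4 = 2, O = 1)
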