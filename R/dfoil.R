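# Five-taxon D_FOIL tests: four statistics (DFO, DIL, DFI, DOL) over
# biallelic site-pattern counts for a symmetric quintet ((P1,P2),(P3,P4),O)
# in which the P3-P4 divergence predates the P1-P2 divergence. The joint
# sign pattern of the four statistics distinguishes ancestral introgression
# (involving the common ancestor of P1 and P2) from directional
# post-speciation gene flow, and identifies donor and recipient.

# Pattern labels: five letters over (P1,P2,P3,P4,O), B = derived,
# A = ancestral; the outgroup is ancestral by construction (polarized
# input), so the fifth letter is always A.
dfoil_pattern_names <- function() {
  g <- expand.grid(P4 = c("A", "B"), P3 = c("A", "B"),
                   P2 = c("A", "B"), P1 = c("A", "B"))
  paste0(g$P1, g$P2, g$P3, g$P4, "A")
}

# Left/right pattern groups of the four statistics (canonical D_FOIL
# groupings: each statistic pairs two 2-derived patterns with one
# 3-derived and one singleton pattern per side, so that terminal-branch
# asymmetries cancel under the null).
DFOIL_GROUPS <- list(
  DFO = list(L = c("BABAA", "BBBAA", "ABABA", "AAABA"),
             R = c("BAABA", "BBABA", "ABBAA", "AABAA")),
  DIL = list(L = c("ABBAA", "BBBAA", "BAABA", "AAABA"),
             R = c("ABABA", "BBABA", "BABAA", "AABAA")),
  DFI = list(L = c("BABAA", "BABBA", "ABABA", "ABAAA"),
             R = c("ABBAA", "ABBBA", "BAABA", "BAAAA")),
  DOL = list(L = c("BAABA", "BABBA", "ABBAA", "ABAAA"),
             R = c("ABABA", "ABBBA", "BABAA", "BAAAA"))
)

# Signature -> classification lookup. Signatures are the concatenated
# signs of (DFO, DIL, DFI, DOL) at the chosen significance level. The
# table was frozen against coalescent simulations of every single-pulse
# scenario (see the methods vignette): e.g. a pulse between P3 and the
# ancestor of (P1,P2) drives DFO and DIL positive while DFI and DOL stay
# centred on zero, and each directional scenario zeroes exactly one of
# the pair-specific statistics.
DFOIL_CLASSES <- c(
  "0000" = "none",
  "++00" = "ancestral",   # anc(P1,P2) <-> P3
  "--00" = "ancestral",   # anc(P1,P2) <-> P4
  "+0++" = "P3_to_P1",
  "+++0" = "P1_to_P3",
  "0+--" = "P3_to_P2",
  "++-0" = "P2_to_P3",
  "-0++" = "P4_to_P1",
  "--0+" = "P1_to_P4",
  "0---" = "P4_to_P2",
  "--0-" = "P2_to_P4"
)

#' Frequency-weighted five-taxon site-pattern counts
#'
#' For every site polarized against the outgroup, each of the 16
#' derived/ancestral patterns over (P1,P2,P3,P4) receives the product of
#' the matching derived or ancestral frequencies, so the 16 weights sum
#' to one per site.
#'
#' @param pf polarized frequencies from [polarize()].
#' @param P1,P2 the later-diverging pair; `P3,P4` the earlier-diverging
#'   pair.
#' @param P3,P4 see above.
#' @return named numeric vector of 16 pattern weights (class
#'   `dfoil_counts`), with attributes `n_sites` and `quintet`.
#' @export
pattern_counts5 <- function(pf, P1, P2, P3, P4) {
  stopifnot(inherits(pf, "polarized_freqs"))
  labs <- c(P1 = P1, P2 = P2, P3 = P3, P4 = P4)
  if (anyDuplicated(labs)) stop("quintet populations must be distinct")
  f <- pf$freq[, labs, drop = FALSE]
  use <- which(stats::complete.cases(f))
  f <- f[use, , drop = FALSE]
  nm <- dfoil_pattern_names()
  counts <- stats::setNames(numeric(16), nm)
  for (k in seq_along(nm)) {
    pat <- strsplit(nm[k], "")[[1]][1:4]
    w <- rep(1, length(use))
    for (j in 1:4)
      w <- w * (if (pat[j] == "B") f[, j] else 1 - f[, j])
    counts[k] <- sum(w)
  }
  structure(counts, n_sites = length(use), quintet = labs,
            class = "dfoil_counts")
}

dfoil_one_stat <- function(counts, grp) {
  L <- sum(counts[grp$L]); R <- sum(counts[grp$R])
  tot <- L + R
  if (tot <= 0) return(list(D = 0, chisq = 0, p = 1, flagged = TRUE))
  chisq <- (L - R)^2 / tot
  list(D = (L - R) / tot, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       flagged = FALSE)
}

#' D_FOIL statistics, signature, and introgression classification
#'
#' Computes DFO, DIL, DFI, DOL from five-taxon pattern counts, tests each
#' with a one-degree-of-freedom chi-square on its contributing pattern
#' sums, forms the sign signature at level `alpha` (statistics not
#' significant at `alpha` count as 0), and classifies it: `none`,
#' `ancestral` (introgression involving the common ancestor of P1 and
#' P2), a directional `X_to_Y` label, or `indeterminate` when the
#' signature matches no expected scenario.
#'
#' @param counts a `dfoil_counts` vector from [pattern_counts5()].
#' @param alpha per-statistic significance level (default 0.01).
#' @return object of class `dfoil_result`: `stats` (data.frame with D,
#'   chisq, p per statistic), `signature`, `classification`, `alpha`,
#'   `quintet`.
#' @export
dfoil_test <- function(counts, alpha = 0.01) {
  stopifnot(inherits(counts, "dfoil_counts"))
  if (attr(counts, "n_sites") < 1) stop("no informative sites")
  res <- lapply(DFOIL_GROUPS, dfoil_one_stat, counts = counts)
  st <- data.frame(
    statistic = names(res),
    D = vapply(res, `[[`, 0, "D"),
    chisq = vapply(res, `[[`, 0, "chisq"),
    p = vapply(res, `[[`, 0, "p"),
    zero_total = vapply(res, `[[`, TRUE, "flagged"),
    row.names = NULL
  )
  signs <- ifelse(st$p < alpha, ifelse(st$D > 0, "+", "-"), "0")
  signature <- paste(signs, collapse = "")
  cls <- DFOIL_CLASSES[signature]
  if (is.na(cls)) cls <- "indeterminate"
  structure(list(stats = st, signature = signature,
                 classification = unname(cls), alpha = alpha,
                 quintet = attr(counts, "quintet")),
            class = "dfoil_result")
}

#' @export
print.dfoil_result <- function(x, ...) {
  q <- x$quintet
  cat(sprintf("D_FOIL ((%s,%s),(%s,%s),O)\n", q["P1"], q["P2"], q["P3"], q["P4"]))
  for (i in seq_len(nrow(x$stats)))
    cat(sprintf("  %s = %8.4f  chisq = %8.2f  p = %.3g\n",
                x$stats$statistic[i], x$stats$D[i], x$stats$chisq[i],
                x$stats$p[i]))
  cat("  signature:", x$signature, "->", x$classification, "\n")
  invisible(x)
}

#' Run a D_FOIL test for a quintet directly from genotypes
#'
#' Convenience wrapper: checks the divergence-order precondition against
#' a species tree when supplied (the P3-P4 split must predate the P1-P2
#' split; violating quintets are refused rather than mislabeled), builds
#' pattern counts, and tests. `mode = "individual"` restricts each taxon
#' to a single diploid (chosen by index) to mirror per-individual
#' combination sweeps.
#'
#' @param pf polarized frequencies.
#' @param P1,P2,P3,P4 quintet labels.
#' @param species_tree optional rooted `phylo`/newick with branch lengths
#'   used to verify divergence order.
#' @param alpha significance level.
#' @return a `dfoil_result`.
#' @export
dfoil_quintet <- function(pf, P1, P2, P3, P4, species_tree = NULL,
                          alpha = 0.01) {
  if (!is.null(species_tree)) {
    if (is.character(species_tree))
      species_tree <- ape::read.tree(text = species_tree)
    t12 <- mrca_time(species_tree, P1, P2)
    t34 <- mrca_time(species_tree, P3, P4)
    if (t34 <= t12)
      stop("invalid quintet: divergence(P3,P4) must predate divergence(P1,P2)")
  }
  dfoil_test(pattern_counts5(pf, P1, P2, P3, P4), alpha = alpha)
}

mrca_time <- function(phy, a, b) {
  depth <- ape::node.depth.edgelength(phy)
  node <- ape::getMRCA(phy, c(a, b))
  max(depth) - depth[node]
}
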