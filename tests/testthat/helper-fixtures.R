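# Shared fixture builders and independent brute-force oracles.

# Genotype matrix from a literal dosage matrix (rows = sites).
make_gm <- function(dos, pops, chrom = "1", pos = NULL, outgroup = NULL) {
  dos <- as.matrix(dos)
  if (is.null(colnames(dos)))
    colnames(dos) <- paste0("s", seq_len(ncol(dos)))
  if (is.null(pos)) pos <- seq_len(nrow(dos)) * 10L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, dos, stats::setNames(pops, colnames(dos)),
                  outgroup = outgroup)
}

# Random polarized_freqs object over named populations.
make_pf <- function(n_sites, pops, seed = 1, chrom = "1") {
  set.seed(seed)
  freq <- matrix(runif(n_sites * length(pops)), n_sites,
                 dimnames = list(NULL, pops))
  structure(list(freq = freq,
                 n = matrix(2L, n_sites, length(pops),
                            dimnames = list(NULL, pops)),
                 sites = data.frame(chrom = chrom,
                                    pos = seq_len(n_sites) * 10L),
                 outgroup = "O",
                 dropped = c(outgroup_missing = 0L,
                             outgroup_polymorphic = 0L)),
            class = "polarized_freqs")
}

# Write a small VCF from text lines.
write_vcf_fixture <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=100000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

# --- independent oracles ---------------------------------------------------

# Per-site loop oracle for ABBA/BABA sums.
oracle_abba_baba <- function(p1, p2, p3) {
  abba <- 0; baba <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i]
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i]
  }
  c(ABBA = abba, BABA = baba)
}

# Straight-line per-site reimplementation of the windowed f_dM estimator.
oracle_fdm <- function(p1, p2, p3) {
  num <- 0; den <- 0
  for (i in seq_along(p1)) {
    num <- num + (1 - p1[i]) * p2[i] * p3[i] - p1[i] * (1 - p2[i]) * p3[i]
    if (p2[i] >= p1[i]) {
      pD <- max(p2[i], p3[i])
      den <- den + (1 - p1[i]) * pD * pD - p1[i] * (1 - pD) * pD
    } else {
      pD <- max(p1[i], p3[i])
      den <- den - ((1 - pD) * p2[i] * pD - pD * (1 - p2[i]) * pD)
    }
  }
  num / den
}

# Per-site loop oracle for the 16 five-taxon pattern weights.
oracle_counts5 <- function(p1, p2, p3, p4) {
  pats <- introscape:::dfoil_pattern_names()
  out <- stats::setNames(numeric(16), pats)
  for (i in seq_along(p1)) {
    ps <- c(p1[i], p2[i], p3[i], p4[i])
    for (pat in pats) {
      bits <- strsplit(pat, "")[[1]][1:4]
      w <- 1
      for (j in 1:4) w <- w * ifelse(bits[j] == "B", ps[j], 1 - ps[j])
      out[pat] <- out[pat] + w
    }
  }
  out
}

# Textbook Weir & Cockerham (1984) per-site theta written out in full,
# independent of the package's vectorized version.
oracle_wc_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Exhaustive-enumeration oracle for the 2-state Mk likelihood and node
# marginals: sums the joint probability over all internal-state
# assignments.
oracle_mk <- function(tree, states, q01, q10, root_prior = "stationary") {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  prior <- if (root_prior == "uniform" || q01 + q10 == 0) c(0.5, 0.5)
  else c(q10, q01) / (q01 + q10)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    introscape:::mk_pmat(q01, q10, tree$edge.length[e]))
  internal <- (ntip + 1L):nn
  k <- length(internal)
  total <- 0
  marg <- matrix(0, nn, 2)
  for (code in 0:(2^k - 1)) {
    asg <- integer(nn)
    asg[seq_len(ntip)] <- states
    asg[internal] <- as.integer(intToBits(code))[seq_len(k)]
    pr <- prior[asg[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- asg[tree$edge[e, 1]]; b <- asg[tree$edge[e, 2]]
      pr <- pr * P[[e]][a + 1L, b + 1L]
    }
    total <- total + pr
    marg[cbind(seq_len(nn), asg + 1L)] <-
      marg[cbind(seq_len(nn), asg + 1L)] + pr
  }
  list(loglik = log(total), marginals = marg / total)
}

# Independent quartet score: per 4-subset, root both pruned subtrees at the
# alphabetically first tip and compare canonical topologies of the
# remaining 3 tips' rooted shape.
oracle_quartet_score <- function(species_tree, gene_trees) {
  sp <- sort(species_tree$tip.label)
  quads <- utils::combn(sp, 4)
  id4 <- function(tree, tips) {
    sub <- ape::keep.tip(tree, tips)
    canonical_topology(sub, outgroup = sort(tips)[1], keep_outgroup = FALSE)
  }
  match_n <- 0; tot <- 0
  for (q in seq_len(ncol(quads))) {
    tips <- quads[, q]
    ref <- id4(species_tree, tips)
    for (g in gene_trees) {
      if (!all(tips %in% g$tip.label)) next
      tot <- tot + 1
      if (id4(g, tips) == ref) match_n <- match_n + 1
    }
  }
  match_n / tot
}

# Tiny two-state trait simulator on a tree (test data generator).
sim_binary_trait <- function(tree, q01, q10) {
  ntip <- length(tree$tip.label)
  st <- integer(ntip + tree$Nnode)
  pi1 <- if (q01 + q10 == 0) 0.5 else q01 / (q01 + q10)
  st[ntip + 1L] <- stats::rbinom(1, 1, pi1)
  for (e in rev(ape::postorder(tree))) {
    P <- introscape:::mk_pmat(q01, q10, tree$edge.length[e])
    st[tree$edge[e, 2]] <- stats::rbinom(1, 1, P[st[tree$edge[e, 1]] + 1L, 2])
  }
  stats::setNames(st[seq_len(ntip)], tree$tip.label)
}
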