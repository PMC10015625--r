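# Per-window tree building (neighbor joining on dosage p-distances),
# canonical topology identifiers, Twisst-style topology weighting over
# taxon groups, topology counting, and normalized quartet scores.

#' Neighbor-joining tree from a window of dosages
#'
#' Pairwise p-distance between diploids i and j is
#' `sum |d_i - d_j| / (2 * n_shared_sites)` over sites genotyped in both;
#' the tree is built with neighbor joining. Deterministic for a given
#' input.
#'
#' @param gm a [genotype_matrix()] (typically already subset to one
#'   window via `subset_sites`).
#' @param subset_sites optional integer site indices to use.
#' @return an `ape::phylo` (unrooted).
#' @export
nj_tree <- function(gm, subset_sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dos <- gm$dos
  if (!is.null(subset_sites)) dos <- dos[subset_sites, , drop = FALSE]
  n <- ncol(dos)
  if (n < 4) stop("neighbor joining needs at least 4 tips")
  if (nrow(dos) < 1) stop("no sites in window")
  D <- matrix(0, n, n, dimnames = list(colnames(dos), colnames(dos)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(dos[, i]) & !is.na(dos[, j])
    D[i, j] <- D[j, i] <-
      if (any(ok)) sum(abs(dos[ok, i] - dos[ok, j])) / (2 * sum(ok)) else 0
  }
  ape::nj(D)
}

#' Canonical identifier for a leaf-labeled rooted topology
#'
#' Branch lengths are ignored; at every internal node the child subtree
#' strings are sorted lexicographically, so any rotation or ladder order
#' of the same labeled shape yields the identical ID string. Unrooted
#' trees must be rooted first by supplying `outgroup` (the outgroup tip
#' is then dropped from the ID unless `keep_outgroup`).
#'
#' @param tree `phylo` or newick string.
#' @param outgroup optional tip label (or vector) to root on.
#' @param keep_outgroup keep the outgroup tip in the identifier.
#' @return canonical topology string, e.g. `"((A,B),C)"`.
#' @export
canonical_topology <- function(tree, outgroup = NULL, keep_outgroup = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    if (!keep_outgroup) {
      if (length(setdiff(tree$tip.label, outgroup)) < 2)
        stop("fewer than two ingroup tips after dropping the outgroup")
      tree <- ape::drop.tip(tree, outgroup)
    }
  } else if (!ape::is.rooted(tree)) {
    stop("unrooted tree: supply an outgroup to root on")
  }
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    sub <- sort(vapply(kids[[as.character(v)]], build, ""))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  build(ntip + 1L)
}

#' Count rooted bifurcating topologies
#'
#' With a fixed outgroup among `n_groups` taxa the count is the number of
#' rooted bifurcating topologies on the `n_groups - 1` ingroups,
#' `(2m - 3)!!` for `m` ingroups; without the flag all `n_groups` taxa
#' are free and the count is `(2*n_groups - 3)!!`. Computed in double
#' precision (exact for counts below 2^53, i.e. up to about 18 free
#' taxa).
#'
#' @param n_groups number of taxon groups (outgroup included when
#'   `rooted_with_fixed_outgroup`).
#' @param rooted_with_fixed_outgroup is one group a fixed outgroup?
#' @return numeric count.
#' @export
count_topologies <- function(n_groups, rooted_with_fixed_outgroup = TRUE) {
  stopifnot(n_groups >= 2)
  m <- if (rooted_with_fixed_outgroup) n_groups - 1L else n_groups
  if (m < 3) return(1)
  prod(seq(3, 2 * m - 3, by = 2))
}

#' Enumerate all rooted bifurcating topologies on a label set
#'
#' Exhaustive generation by stepwise tip addition (each new tip attached
#' to every existing edge and at the root); intended for small label sets
#' as an oracle for [count_topologies()] and topology classification.
#'
#' @param labels character vector of tip labels (2 to 8).
#' @return character vector of canonical topology strings.
#' @export
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 2, length(labels) <= 8)
  labels <- sort(labels)
  trees <- list(list(left = labels[1], right = labels[2]))
  join <- function(a, b) list(left = a, right = b)
  for (k in seq_along(labels)[-(1:2)]) {
    tip <- labels[k]
    nxt <- list()
    attach_all <- function(node) {
      # returns list of variants of `node` with tip inserted somewhere inside
      out <- list(join(node, tip))
      if (is.list(node)) {
        for (v in attach_all(node$left)) out <- c(out, list(join(v, node$right)))
        for (v in attach_all(node$right)) out <- c(out, list(join(node$left, v)))
      }
      out
    }
    for (tr in trees) nxt <- c(nxt, attach_all(tr))
    trees <- nxt
  }
  canon <- function(node) {
    if (!is.list(node)) return(node)
    sub <- sort(c(canon(node$left), canon(node$right)))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  unique(vapply(trees, canon, ""))
}

#' Topology weighting of a tree over taxon groups
#'
#' Twisst-style weighting: sample (or exhaustively enumerate) one tip per
#' group, prune the tree to the sampled tips, relabel tips by their
#' groups, canonicalize, and tally. Weights are normalized over the
#' combinations and sum to one.
#'
#' @param tree rooted `phylo` (or newick), or an unrooted tree plus an
#'   `outgroup_group`.
#' @param group_map named character vector: tip label -> group.
#' @param outgroup_group optional group used to root each pruned subtree;
#'   it is retained in the topology identifiers.
#' @param method `"auto"` (exhaustive when the number of combinations is
#'   at most `exhaustive_limit`, else Monte Carlo), `"exhaustive"`, or
#'   `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count (default 1000).
#' @param seed seed for Monte-Carlo sampling.
#' @param exhaustive_limit switchover point for `"auto"` (default 10000).
#' @return object of class `weighting_result`: `weights` (named numeric,
#'   sums to 1), `method`, `n_samples`.
#' @export
topology_weighting <- function(tree, group_map, outgroup_group = NULL,
                               method = c("auto", "exhaustive", "montecarlo"),
                               n_samples = 1000, seed = NULL,
                               exhaustive_limit = 1e4) {
  method <- match.arg(method)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  group_map <- group_map[names(group_map) %in% tree$tip.label]
  groups <- sort(unique(group_map))
  if (length(groups) > 8) stop("more than eight taxon groups are not supported")
  tips_by_group <- split(names(group_map), group_map)
  sizes <- lengths(tips_by_group)
  if (any(sizes == 0)) stop("every group needs at least one tip in the tree")
  if (!is.null(outgroup_group) && !outgroup_group %in% groups)
    stop("outgroup group not present: ", outgroup_group)
  n_comb <- prod(sizes)
  if (method == "auto")
    method <- if (n_comb <= exhaustive_limit) "exhaustive" else "montecarlo"

  one_combo <- function(tips) {
    sub <- ape::keep.tip(tree, tips)
    sub$tip.label <- unname(group_map[sub$tip.label])
    if (!is.null(outgroup_group))
      canonical_topology(sub, outgroup = outgroup_group, keep_outgroup = TRUE)
    else canonical_topology(sub)
  }

  if (method == "exhaustive") {
    grid <- do.call(expand.grid,
                    c(tips_by_group, list(stringsAsFactors = FALSE)))
    ids <- apply(as.matrix(grid), 1L, one_combo)
    n_used <- nrow(grid)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ids <- vapply(seq_len(n_samples), function(i)
      one_combo(vapply(tips_by_group, function(tt)
        tt[sample.int(length(tt), 1L)], "")), "")
    n_used <- n_samples
  }
  tab <- table(ids)
  structure(list(weights = stats::setNames(as.numeric(tab) / n_used,
                                           names(tab)),
                 method = method, n_samples = n_used, groups = groups),
            class = "weighting_result")
}

#' Genome-wide main topologies from per-window weightings
#'
#' Averages topology weights across windows and flags those whose mean
#' frequency exceeds `freq_threshold`.
#'
#' @param weightings list of `weighting_result`s (one per window).
#' @param freq_threshold minimum genome-wide frequency for a "main"
#'   topology (default 0.015, i.e. 1.5%).
#' @return data.frame `topology`, `frequency`, `main`, sorted by
#'   decreasing frequency.
#' @export
main_topologies <- function(weightings, freq_threshold = 0.015) {
  stopifnot(length(weightings) >= 1)
  all_ids <- unique(unlist(lapply(weightings, function(w) names(w$weights))))
  acc <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (w in weightings) acc[names(w$weights)] <- acc[names(w$weights)] + w$weights
  freq <- acc / length(weightings)
  out <- data.frame(topology = names(freq), frequency = as.numeric(freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$topology), , drop = FALSE]
  out$main <- out$frequency > freq_threshold
  rownames(out) <- NULL
  out
}

# Quartet topology of 4 tips in a tree from topological (unit-length)
# path distances: for quartet ab|cd, d(a,b)+d(c,d) is strictly the
# smallest pairing sum. Returns 1 for (t1,t2|t3,t4), 2 for (t1,t3|t2,t4),
# 3 for (t1,t4|t2,t3), 0 for unresolved ties.
quartet_split <- function(D, t1, t2, t3, t4) {
  s1 <- D[t1, t2] + D[t3, t4]
  s2 <- D[t1, t3] + D[t2, t4]
  s3 <- D[t1, t4] + D[t2, t3]
  s <- c(s1, s2, s3)
  w <- which(s == min(s))
  if (length(w) > 1) 0L else w
}

topo_dist <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::cophenetic.phylo(tree)
}

#' Normalized quartet score of a species tree against gene trees
#'
#' Over every gene tree and every four-taxon subset resolved in both the
#' species tree and that gene tree, the fraction whose induced quartet
#' topology matches the species tree. Gene trees with several tips per
#' species are handled through `group_map`: all one-tip-per-species
#' combinations contribute.
#'
#' @param species_tree `phylo`/newick over species labels.
#' @param gene_trees list of `phylo`/newick gene trees.
#' @param group_map optional named vector mapping gene-tree tips to
#'   species; defaults to identity.
#' @return list: `score` in \[0,1\], `n_quartets` compared (NA score with
#'   zero quartets).
#' @export
quartet_score <- function(species_tree, gene_trees, group_map = NULL) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  gene_trees <- lapply(gene_trees, function(g)
    if (is.character(g)) ape::read.tree(text = g) else g)
  Dsp <- topo_dist(species_tree)
  sp <- species_tree$tip.label
  match_n <- 0; tot_n <- 0
  for (g in gene_trees) {
    gmap <- if (is.null(group_map))
      stats::setNames(g$tip.label, g$tip.label)
    else group_map[g$tip.label]
    tips_by_sp <- split(names(gmap), gmap)
    present <- intersect(sp, names(tips_by_sp))
    if (length(present) < 4) next
    Dg <- topo_dist(g)
    quads <- utils::combn(present, 4)
    for (q in seq_len(ncol(quads))) {
      s4 <- quads[, q]
      ref <- quartet_split(Dsp, s4[1], s4[2], s4[3], s4[4])
      if (ref == 0L) next
      combos <- do.call(expand.grid,
                        c(tips_by_sp[s4], list(stringsAsFactors = FALSE)))
      for (r in seq_len(nrow(combos))) {
        gt <- as.character(combos[r, ])
        obs <- quartet_split(Dg, gt[1], gt[2], gt[3], gt[4])
        if (obs == 0L) next
        tot_n <- tot_n + 1
        if (obs == ref) match_n <- match_n + 1
      }
    }
  }
  if (tot_n == 0) {
    warning("no shared resolved quartets between species tree and gene trees")
    return(list(score = NA_real_, n_quartets = 0L))
  }
  list(score = match_n / tot_n, n_quartets = tot_n)
}
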