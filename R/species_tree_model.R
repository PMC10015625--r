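# Demographic model: a dated species tree with branch-specific effective
# sizes and instantaneous admixture pulses. Branches are identified by the
# label of the node (tip or internal) at their recent end; the branch above
# the root is the ancestral population and extends to time infinity.

#' Specify a multispecies-coalescent demography with admixture pulses
#'
#' @param tree rooted binary ultrametric tree (`ape::phylo` or newick
#'   string) whose branch lengths are in generations. Tip labels are the
#'   population names. Internal nodes may carry labels so they can be
#'   addressed as pulse donors/recipients; unlabeled internal nodes are
#'   auto-named `anc_<tip>.<tip>...` from their sorted descendant tips.
#' @param ne effective (diploid) population size: a single number applied
#'   to every branch, or a named vector with one entry per branch id
#'   (tips, internal nodes, and the root node).
#' @param mu per-site per-generation mutation rate.
#' @param pulses `NULL` or a data.frame with columns `time` (generations
#'   before present), `donor`, `recipient` (branch ids), and `f`
#'   (admixture fraction in \[0,1\]). Backward in time, each lineage in
#'   the recipient branch at the pulse time is rerouted into the donor
#'   branch with probability `f`. Donor and recipient must both exist as
#'   branches at the pulse time.
#' @return an object of class `species_tree_model`.
#' @examples
#' m <- species_tree_model("((A:1000,B:1000):1000,C:2000):500;",
#'                         ne = 5000, mu = 1e-8)
#' @export
species_tree_model <- function(tree, ne, mu, pulses = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)      # distance from root
  tmax <- max(depth)
  tbp <- tmax - depth                            # time before present
  if (max(abs(tbp[seq_len(ntip)])) > 1e-6 * max(tmax, 1))
    stop("species tree must be ultrametric (contemporaneous tips)")
  tbp[seq_len(ntip)] <- 0

  node_id <- character(ntip + nnode)
  node_id[seq_len(ntip)] <- tree$tip.label
  for (v in (ntip + 1L):(ntip + nnode)) {
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
    if (is.na(lab) || !nzchar(lab)) {
      tips <- ape::extract.clade(tree, v)$tip.label
      lab <- paste0("anc_", paste(sort(tips), collapse = "."))
    }
    node_id[v] <- lab
  }
  if (anyDuplicated(node_id)) stop("branch ids (tip/node labels) must be unique")

  parent <- rep(NA_integer_, ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- which(is.na(parent))
  branches <- data.frame(
    id = node_id,
    node = seq_len(ntip + nnode),
    parent = node_id[ifelse(is.na(parent), NA, parent)],
    t_start = tbp,
    t_end = ifelse(is.na(parent), Inf, tbp[parent]),
    stringsAsFactors = FALSE
  )

  if (length(ne) == 1L && is.null(names(ne))) {
    branches$ne <- as.numeric(ne)
  } else {
    miss <- setdiff(branches$id, names(ne))
    if (length(miss)) stop("ne missing for branches: ", paste(miss, collapse = ", "))
    branches$ne <- as.numeric(ne[branches$id])
  }
  if (any(branches$ne <= 0)) stop("ne must be positive")
  if (mu < 0) stop("mu must be nonnegative")

  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses)
    stopifnot(all(c("time", "donor", "recipient", "f") %in% names(pulses)))
    if (any(pulses$f < 0 | pulses$f > 1))
      stop("pulse fraction f must lie in [0, 1]")
    for (i in seq_len(nrow(pulses))) {
      for (role in c("donor", "recipient")) {
        b <- match(pulses[[role]][i], branches$id)
        if (is.na(b)) stop("unknown pulse ", role, ": ", pulses[[role]][i])
        if (pulses$time[i] < branches$t_start[b] ||
            pulses$time[i] >= branches$t_end[b])
          stop("pulse at time ", pulses$time[i], " lies outside the lifetime of ",
               role, " branch '", pulses[[role]][i], "'")
      }
      if (pulses$donor[i] == pulses$recipient[i])
        stop("pulse donor and recipient must differ")
    }
    pulses <- pulses[order(pulses$time), , drop = FALSE]
  }

  structure(list(phy = tree, branches = branches, root_id = node_id[root],
                 mu = mu, pulses = pulses),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Species-tree demographic model\n")
  cat("  populations:", paste(x$phy$tip.label, collapse = ", "), "\n")
  cat("  root height:", format(max(x$branches$t_start)), "generations\n")
  cat("  mu:", format(x$mu), "per site per generation\n")
  np <- if (is.null(x$pulses)) 0L else nrow(x$pulses)
  cat("  admixture pulses:", np, "\n")
  if (np > 0)
    for (i in seq_len(np))
      cat(sprintf("    t=%g  %s -> %s  f=%g\n", x$pulses$time[i],
                  x$pulses$donor[i], x$pulses$recipient[i], x$pulses$f[i]))
  invisible(x)
}

#' Describe the windowed structure of a simulated genome
#'
#' @param n_windows number of nonoverlapping windows (one independent
#'   genealogy each).
#' @param window_len window length in bp (default 10 kb).
#' @param rho per-window population-scaled recombination rate: `NULL` for
#'   the built-in lognormal default (meanlog `log(5)`, sdlog 1, the shape
#'   typical of per-10 kb rho tracks), a numeric vector of length
#'   `n_windows`, or a `function(n)` returning one. Here rho is an
#'   exported covariate of each window (and drives the optional retention
#'   model); it does not add intra-window recombination.
#' @param retention `NULL`, or a monotone `function(rho)` giving the
#'   probability that an introgressed window is retained as introgressed
#'   (see [apply_retention()]).
#' @param chrom chromosome name windows are laid on, consecutively.
#' @return an object of class `window_model`.
#' @export
window_model <- function(n_windows, window_len = 1e4, rho = NULL,
                         retention = NULL, chrom = "1") {
  stopifnot(n_windows >= 1, window_len >= 1)
  if (is.numeric(rho) && length(rho) != n_windows)
    stop("rho vector must have length n_windows")
  if (!is.null(retention) && !is.function(retention))
    stop("retention must be NULL or a function of rho")
  structure(list(n_windows = as.integer(n_windows),
                 window_len = as.integer(window_len),
                 rho = rho, retention = retention, chrom = chrom),
            class = "window_model")
}
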