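# Two-state continuous-time Markov (Mk) model of a binary trait (e.g.
# self-compatibility = state 0, self-incompatibility = state 1) on a dated
# phylogeny: pruning-algorithm likelihood, ML fits of the symmetric
# (q01 = q10) and asymmetric models with LRT/AIC comparison, and marginal
# ancestral-state reconstruction.

# 2x2 transition probability matrix for rates q01 (0->1) and q10 (1->0)
# over time t: P(t) = Pi + exp(-(q01+q10) t) (I - Pi), rows of Pi equal
# the stationary distribution.
mk_pmat <- function(q01, q10, t) {
  q <- q01 + q10
  if (q == 0) return(diag(2))
  pi1 <- q01 / q
  e <- exp(-q * t)
  matrix(c(1 - pi1 + pi1 * e, pi1 - pi1 * e,
           (1 - pi1) - (1 - pi1) * e, pi1 + (1 - pi1) * e),
         2, 2, byrow = TRUE)
}

mk_root_prior <- function(q01, q10, root_prior) {
  if (root_prior == "uniform" || q01 + q10 == 0) c(0.5, 0.5)
  else c(q10, q01) / (q01 + q10)
}

check_mk_inputs <- function(tree, tip_states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree needs nonnegative branch lengths")
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) stop("missing tip states: ", paste(miss, collapse = ", "))
  st <- tip_states[tree$tip.label]
  if (!all(st %in% c(0, 1))) stop("tip states must be 0 or 1")
  list(tree = tree, states = as.integer(st))
}

# Post-order conditional likelihoods: L[v, s] = P(data below v | state s).
mk_partials <- function(tree, states, q01, q10) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- matrix(0, nn, 2)
  L[cbind(seq_len(ntip), states + 1L)] <- 1
  ord <- rev(ape::postorder(tree))  # edges; process in postorder
  # iterate edges in postorder (children before parents)
  Ped <- vector("list", nrow(tree$edge))
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    Ped[[e]] <- mk_pmat(q01, q10, tree$edge.length[e])
  }
  done <- rep(FALSE, nn)
  done[seq_len(ntip)] <- TRUE
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    if (!done[parent]) { L[parent, ] <- 1; done[parent] <- TRUE }
    child <- tree$edge[e, 2]
    L[parent, ] <- L[parent, ] * as.numeric(Ped[[e]] %*% L[child, ])
  }
  list(L = L, Ped = Ped)
}

#' Mk log-likelihood of binary tip states on a dated tree
#'
#' Felsenstein pruning with the closed-form 2-state transition matrix;
#' the root is integrated against the stationary distribution of the
#' rate matrix (or a uniform prior).
#'
#' @param tree rooted `phylo` (or newick) with branch lengths in time
#'   units.
#' @param tip_states named vector of 0/1 states covering every tip.
#' @param q01 rate of 0 -> 1 transitions (per unit time).
#' @param q10 rate of 1 -> 0 transitions.
#' @param root_prior `"stationary"` (default) or `"uniform"`.
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, q01, q10,
                      root_prior = c("stationary", "uniform")) {
  root_prior <- match.arg(root_prior)
  if (q01 < 0 || q10 < 0) stop("rates must be nonnegative")
  inp <- check_mk_inputs(tree, tip_states)
  part <- mk_partials(inp$tree, inp$states, q01, q10)
  root <- length(inp$tree$tip.label) + 1L
  prior <- mk_root_prior(q01, q10, root_prior)
  log(sum(prior * part$L[root, ]))
}

#' Fit the Mk model by maximum likelihood and compare rate models
#'
#' Fits the symmetric model (one rate, 1-d bounded optimization) and the
#' asymmetric model (gain rate q01 and loss rate q10 free, 2-d
#' multi-start optimization), compares them with a 1-df likelihood-ratio
#' test and AIC, and reconstructs marginal ancestral states under the
#' better-supported parameterization.
#'
#' @inheritParams mk_loglik
#' @param n_starts multi-start count for the asymmetric fit.
#' @return object of class `mk_fit`: `symmetric` and `asymmetric`
#'   sublists (rates, logL, AIC, convergence), `lrt_p`, `preferred`,
#'   `degenerate` flag (single observed tip state), plus the inputs.
#' @export
fit_mk <- function(tree, tip_states, root_prior = c("stationary", "uniform"),
                   n_starts = 5) {
  root_prior <- match.arg(root_prior)
  inp <- check_mk_inputs(tree, tip_states)
  degenerate <- length(unique(inp$states)) == 1L
  depth <- max(ape::node.depth.edgelength(inp$tree))
  lo <- log(1e-8 / depth); hi <- log(100 / depth)

  nll_sym <- function(lq) -mk_loglik(inp$tree,
                                     stats::setNames(inp$states, inp$tree$tip.label),
                                     exp(lq), exp(lq), root_prior)
  o1 <- stats::optimize(nll_sym, c(lo, hi))
  q_sym <- exp(o1$minimum); ll_sym <- -o1$objective

  nll_asym <- function(lq) -mk_loglik(inp$tree,
                                      stats::setNames(inp$states, inp$tree$tip.label),
                                      exp(lq[1]), exp(lq[2]), root_prior)
  starts <- rbind(c(log(q_sym), log(q_sym)))
  if (n_starts > 1) {
    grid <- seq(lo + 1, hi - 1, length.out = max(2, n_starts - 1))
    starts <- rbind(starts, cbind(grid, rev(grid)))
  }
  best <- NULL
  conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    o <- try(stats::optim(starts[s, ], nll_asym, method = "L-BFGS-B",
                          lower = lo, upper = hi), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) { best <- o; conv <- o$convergence == 0 }
  }
  if (is.null(best)) stop("asymmetric optimization failed from every start")
  q01 <- exp(best$par[1]); q10 <- exp(best$par[2])
  ll_asym <- -best$value
  if (ll_asym < ll_sym) {  # nesting guard: never worse than symmetric
    q01 <- q10 <- q_sym; ll_asym <- ll_sym
  }
  lrt <- 2 * (ll_asym - ll_sym)
  fit <- structure(list(
    symmetric = list(q01 = q_sym, q10 = q_sym, logL = ll_sym,
                     AIC = 2 - 2 * ll_sym),
    asymmetric = list(q01 = q01, q10 = q10, logL = ll_asym,
                      AIC = 4 - 2 * ll_asym, converged = conv),
    lrt = lrt, lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    preferred = if (stats::pchisq(lrt, 1, lower.tail = FALSE) < 0.05)
      "asymmetric" else "symmetric",
    degenerate = degenerate, root_prior = root_prior,
    tree = inp$tree,
    tip_states = stats::setNames(inp$states, inp$tree$tip.label)),
    class = "mk_fit")
  fit$anc <- marginal_ancestral(fit)
  fit
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Two-state Mk model fit (root prior:", x$root_prior, ")\n")
  cat(sprintf("  symmetric : q = %.4g            logL = %.4f  AIC = %.2f\n",
              x$symmetric$q01, x$symmetric$logL, x$symmetric$AIC))
  cat(sprintf("  asymmetric: q01 = %.4g q10 = %.4g  logL = %.4f  AIC = %.2f\n",
              x$asymmetric$q01, x$asymmetric$q10, x$asymmetric$logL,
              x$asymmetric$AIC))
  cat(sprintf("  LRT (1 df): %.3f, p = %.4g -> %s rates\n",
              x$lrt, x$lrt_p, x$preferred))
  if (x$degenerate)
    cat("  note: all tips share one state; the comparison is degenerate\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, model = object$preferred, ...) {
  m <- object[[model]]
  c(q01 = m$q01, q10 = m$q10)
}

#' @export
logLik.mk_fit <- function(object, model = object$preferred, ...) {
  m <- object[[model]]
  structure(m$logL, df = if (model == "asymmetric") 2L else 1L,
            class = "logLik")
}

#' @export
summary.mk_fit <- function(object, ...) { print(object); invisible(object) }

#' Simulate binary tip states under the 2-state Markov chain
#'
#' Draws a root state from the stationary distribution and evolves it
#' down the tree with the exact transition probabilities; used for
#' calibration and power studies of [fit_mk()].
#'
#' @inheritParams mk_loglik
#' @return named 0/1 vector over the tips.
#' @export
simulate_mk_tips <- function(tree, q01, q10) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  st <- integer(ntip + tree$Nnode)
  pi1 <- if (q01 + q10 == 0) 0.5 else q01 / (q01 + q10)
  st[ntip + 1L] <- stats::rbinom(1, 1, pi1)
  for (e in rev(ape::postorder(tree))) {
    P <- mk_pmat(q01, q10, tree$edge.length[e])
    st[tree$edge[e, 2]] <- stats::rbinom(1, 1, P[st[tree$edge[e, 1]] + 1L, 2])
  }
  stats::setNames(st[seq_len(ntip)], tree$tip.label)
}

#' Marginal ancestral-state probabilities at every node
#'
#' Combines tip-ward conditional likelihoods (pruning) with root-ward
#' partial likelihoods so that each node's marginal uses the entire tree;
#' probabilities sum to one per node. Tips are returned with probability
#' one on their observed state.
#'
#' @param fit an `mk_fit`, or a tree (with `tip_states`, `q01`, `q10`
#'   supplied).
#' @param tip_states,q01,q10,root_prior used when `fit` is a tree.
#' @param model which parameterization of an `mk_fit` to use
#'   (default the preferred one).
#' @return matrix (tips + internal nodes) x 2 of state probabilities,
#'   rows in `ape` node order.
#' @export
marginal_ancestral <- function(fit, tip_states = NULL, q01 = NULL, q10 = NULL,
                               root_prior = "stationary",
                               model = NULL) {
  if (inherits(fit, "mk_fit")) {
    model <- model %||% fit$preferred
    tree <- fit$tree; states <- fit$tip_states
    q01 <- fit[[model]]$q01; q10 <- fit[[model]]$q10
    root_prior <- fit$root_prior
  } else {
    tree <- fit; states <- tip_states
  }
  inp <- check_mk_inputs(tree, states)
  tree <- inp$tree
  part <- mk_partials(tree, inp$states, q01, q10)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  prior <- mk_root_prior(q01, q10, root_prior)

  # Root-ward partials F[v, s]: likelihood of everything outside the
  # clade of v, given state s at v (includes the root prior).
  F <- matrix(NA_real_, nn, 2)
  F[root, ] <- prior
  edges_pre <- rev(ape::postorder(tree))  # parents before children
  kids_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (e in edges_pre) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    sib_edges <- setdiff(kids_of[[as.character(parent)]], e)
    sib_term <- rep(1, 2)
    for (se in sib_edges) {
      sc <- tree$edge[se, 2]
      sib_term <- sib_term * as.numeric(part$Ped[[se]] %*% part$L[sc, ])
    }
    # F[child, s_c] = sum_{s_p} F[parent, s_p] sib_term[s_p] P[s_p, s_c]
    F[child, ] <- as.numeric((F[parent, ] * sib_term) %*% part$Ped[[e]])
  }
  marg <- F * part$L
  marg <- marg / rowSums(marg)
  rownames(marg) <- c(tree$tip.label,
                      if (!is.null(tree$node.label)) tree$node.label
                      else paste0("node", seq_len(tree$Nnode) + ntip))
  colnames(marg) <- c("state0", "state1")
  marg
}
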