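# Multispecies-coalescent simulator with dated admixture pulses.
#
# Each window carries one independent genealogy (no intra-window
# recombination): lineages coalesce within their current branch at rate
# choose(k,2)/(2*Ne), branches merge root-ward at the split times, and at a
# pulse each lineage sitting in the recipient branch is rerouted into the
# donor branch with probability f (standard backward-time pulse semantics).
# Mutations are dropped on the realized genealogy under the infinite-sites
# model at rate mu per site per generation.

# Build the per-window event schedule (merges + pulses) as index-based
# structures for the inner loop.
build_sim_engine <- function(model, include_pulses = TRUE) {
  br <- model$branches
  B <- nrow(br)
  bidx <- stats::setNames(seq_len(B), br$id)
  events <- list()
  for (i in which(is.finite(br$t_start) & br$t_start > 0)) {
    kids <- which(!is.na(br$parent) & br$parent == br$id[i])
    if (length(kids) == 2L)
      events[[length(events) + 1L]] <-
        list(time = br$t_start[i], type = "merge",
             children = kids, parent = i)
  }
  if (include_pulses && !is.null(model$pulses) && nrow(model$pulses) > 0) {
    for (i in seq_len(nrow(model$pulses)))
      events[[length(events) + 1L]] <-
        list(time = model$pulses$time[i], type = "pulse",
             donor = bidx[[model$pulses$donor[i]]],
             recipient = bidx[[model$pulses$recipient[i]]],
             f = model$pulses$f[i], pulse = i)
  }
  events <- events[order(vapply(events, `[[`, 0, "time"))]
  list(B = B, ne2 = 2 * br$ne, events = events, bidx = bidx)
}

# Simulate one window genealogy. init_pop: branch index per haploid lineage.
# Returns branch list (descendant haploid sets + lengths) and pulse truth.
sim_one_window <- function(init_pop, engine) {
  m <- length(init_pop)
  pop <- init_pop
  tipset <- as.list(seq_len(m))
  birth <- numeric(m)
  desc <- vector("list", 2L * m)
  lens <- numeric(2L * m)
  nb <- 0L
  moved <- 0L
  pulse_hit <- integer(0)
  t <- 0
  ev <- engine$events
  n_ev <- length(ev)
  ev_i <- 1L
  ne2 <- engine$ne2
  B <- engine$B
  repeat {
    t_next <- if (ev_i <= n_ev) ev[[ev_i]]$time else Inf
    # within-branch coalescence until the next demographic event
    repeat {
      if (length(pop) == 1L) break
      k <- tabulate(pop, nbins = B)
      rates <- k * (k - 1) / 2 / ne2
      R <- sum(rates)
      if (R <= 0) { t <- t_next; break }
      dt <- stats::rexp(1L, R)
      if (t + dt >= t_next) { t <- t_next; break }
      t <- t + dt
      b <- sample.int(B, 1L, prob = rates)
      idx <- which(pop == b)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      for (j in pair) {
        nb <- nb + 1L
        desc[[nb]] <- tipset[[j]]
        lens[nb] <- t - birth[j]
      }
      i1 <- pair[1L]; i2 <- pair[2L]
      tipset[[i1]] <- c(tipset[[i1]], tipset[[i2]])
      birth[i1] <- t
      pop <- pop[-i2]; tipset <- tipset[-i2]; birth <- birth[-i2]
    }
    if (length(pop) == 1L && ev_i > n_ev) break
    if (ev_i > n_ev) stop("coalescent did not complete")  # cannot happen
    e <- ev[[ev_i]]
    ev_i <- ev_i + 1L
    if (e$type == "merge") {
      pop[pop %in% e$children] <- e$parent
    } else {
      idx <- which(pop == e$recipient)
      if (length(idx) > 0 && e$f > 0) {
        go <- idx[stats::runif(length(idx)) < e$f]
        if (length(go) > 0) {
          pop[go] <- e$donor
          moved <- moved + length(go)
          pulse_hit <- union(pulse_hit, e$pulse)
        }
      }
    }
  }
  list(desc = desc[seq_len(nb)], lens = lens[seq_len(nb)],
       moved = moved, pulses = pulse_hit)
}

#' Simulate a windowed genotype dataset with full ground truth
#'
#' Generates `windows$n_windows` independent window genealogies under the
#' demography in `model`, drops infinite-sites mutations, and emits diploid
#' derived-allele dosages for every sample together with per-window truth
#' (introgression flags and the rho covariate). Output is bit-identical for
#' identical seeds.
#'
#' @param model a [species_tree_model()].
#' @param windows a [window_model()].
#' @param samples_per_pop named integer vector of diploid sample counts,
#'   one entry per tip population (the outgroup included).
#' @param seed integer random seed (required, for reproducibility).
#' @return an object of class `sim_dataset` with elements
#'   `genotypes` (a [genotype_matrix()]; outgroup designation is left to
#'   the caller via `model` tips), `truth` (data.frame: window, chrom,
#'   start, end, rho, introgressed, n_moved, origin), `model`, `windows`,
#'   `samples_per_pop`, `seed`.
#' @export
simulate_dataset <- function(model, windows, samples_per_pop, seed) {
  stopifnot(inherits(model, "species_tree_model"),
            inherits(windows, "window_model"))
  if (missing(seed)) stop("a seed must be supplied")
  tips <- model$phy$tip.label
  if (!all(tips %in% names(samples_per_pop)))
    stop("samples_per_pop must name every tip population")
  samples_per_pop <- samples_per_pop[tips]
  if (any(samples_per_pop < 1)) stop("every population needs >= 1 diploid")
  if (length(tips) < 3)
    stop("need at least two ingroup populations plus an outgroup")

  set.seed(as.integer(seed))
  engine <- build_sim_engine(model, include_pulses = TRUE)

  ndip <- sum(samples_per_pop)
  sample_pop <- rep(tips, samples_per_pop)
  sample_id <- paste0(sample_pop, "_", unlist(lapply(samples_per_pop, seq_len)))
  # haploid lineage -> branch index; haplotypes 2i-1, 2i belong to diploid i
  init_pop <- engine$bidx[rep(sample_pop, each = 2L)]

  rho <- draw_rho(windows)
  W <- windows$n_windows
  L <- windows$window_len

  dos_list <- vector("list", W)
  pos_list <- vector("list", W)
  introgressed <- logical(W)
  n_moved <- integer(W)
  origin <- rep("species_tree", W)
  for (w in seq_len(W)) {
    g <- sim_one_window(init_pop, engine)
    introgressed[w] <- g$moved > 0L
    n_moved[w] <- g$moved
    if (g$moved > 0L)
      origin[w] <- paste0("pulse", paste(sort(g$pulses), collapse = "+"))
    mu_w <- mutate_window(g, model$mu, L, ndip)
    dos_list[[w]] <- mu_w$dos
    pos_list[[w]] <- mu_w$pos + (w - 1L) * L
  }

  gm <- assemble_genotypes(dos_list, pos_list, windows$chrom,
                           sample_id, sample_pop)
  truth <- data.frame(
    window = seq_len(W), chrom = windows$chrom,
    start = (seq_len(W) - 1L) * L, end = seq_len(W) * L,
    rho = rho, introgressed = introgressed, n_moved = n_moved,
    origin = origin, stringsAsFactors = FALSE
  )
  structure(list(genotypes = gm, truth = truth, model = model,
                 windows = windows, samples_per_pop = samples_per_pop,
                 seed = as.integer(seed)),
            class = "sim_dataset")
}

draw_rho <- function(windows) {
  if (is.null(windows$rho))
    stats::rlnorm(windows$n_windows, meanlog = log(5), sdlog = 1)
  else if (is.function(windows$rho))
    windows$rho(windows$n_windows)
  else windows$rho
}

# Drop infinite-sites mutations on a realized genealogy; returns the
# per-site diploid dosage matrix and 1-based positions within the window.
mutate_window <- function(g, mu, window_len, ndip) {
  Ltot <- sum(g$lens)
  nmut <- stats::rpois(1L, mu * window_len * Ltot)
  nmut <- min(nmut, window_len)  # infinite-sites cap: one mutation per bp
  if (nmut == 0L)
    return(list(dos = matrix(0L, 0L, ndip), pos = integer(0)))
  bmut <- sample.int(length(g$lens), nmut, replace = TRUE, prob = g$lens)
  pos <- sort(sample.int(window_len, nmut))
  dos <- matrix(0L, nmut, ndip)
  for (i in seq_len(nmut)) {
    hap <- g$desc[[bmut[i]]]
    cnt <- tabulate((hap + 1L) %/% 2L, nbins = ndip)
    dos[i, ] <- cnt
  }
  list(dos = dos, pos = pos)
}

assemble_genotypes <- function(dos_list, pos_list, chrom, sample_id,
                               sample_pop) {
  dos <- do.call(rbind, dos_list)
  pos <- unlist(pos_list)
  sites <- data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  colnames(dos) <- sample_id
  genotype_matrix(sites, dos,
                  pop_map = stats::setNames(sample_pop, sample_id),
                  outgroup = NULL)
}

#' Apply recombination-dependent retention of introgressed ancestry
#'
#' Phenomenological post-processing emulating the preferential retention of
#' introgressed ancestry in high-recombination regions: each introgressed
#' window is independently kept with probability `retention(rho)` (from the
#' dataset's [window_model()]); a rejected window is relabeled
#' non-introgressed and its genealogy (hence its genotypes) is replaced by
#' a fresh draw under the species tree without pulses. A monotone
#' increasing retention function therefore induces a positive association
#' between introgression and rho in the surviving truth labels.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param seed integer seed for the retention draws and replacement
#'   genealogies.
#' @return a `sim_dataset` with updated genotypes and truth.
#' @export
apply_retention <- function(sim, seed) {
  stopifnot(inherits(sim, "sim_dataset"))
  ret <- sim$windows$retention
  if (is.null(ret)) stop("no retention function configured in the window model")
  if (missing(seed)) stop("a seed must be supplied")
  set.seed(as.integer(seed))
  truth <- sim$truth
  p_keep <- ret(truth$rho)
  if (any(p_keep < 0 | p_keep > 1)) stop("retention probabilities outside [0,1]")
  drop <- truth$introgressed & (stats::runif(nrow(truth)) >= p_keep)
  if (!any(drop)) return(sim)

  engine <- build_sim_engine(sim$model, include_pulses = FALSE)
  tips <- sim$model$phy$tip.label
  sample_pop <- rep(tips, sim$samples_per_pop)
  init_pop <- engine$bidx[rep(sample_pop, each = 2L)]
  ndip <- sum(sim$samples_per_pop)
  L <- sim$windows$window_len

  gm <- sim$genotypes
  win_of_site <- gm$sites$pos %/% L - ifelse(gm$sites$pos %% L == 0, 1L, 0L) + 1L
  keep_site <- !(win_of_site %in% which(drop))
  sites <- gm$sites[keep_site, , drop = FALSE]
  dos <- gm$dos[keep_site, , drop = FALSE]

  new_sites <- list(); new_dos <- list()
  for (w in which(drop)) {
    g <- sim_one_window(init_pop, engine)
    mw <- mutate_window(g, sim$model$mu, L, ndip)
    if (nrow(mw$dos) > 0) {
      new_sites[[length(new_sites) + 1L]] <- data.frame(
        chrom = sim$windows$chrom, pos = mw$pos + (w - 1L) * L,
        ref = "A", alt = "T", stringsAsFactors = FALSE)
      new_dos[[length(new_dos) + 1L]] <- mw$dos
    }
  }
  if (length(new_sites)) {
    sites <- rbind(sites, do.call(rbind, new_sites))
    dos2 <- do.call(rbind, new_dos)
    colnames(dos2) <- colnames(dos)
    dos <- rbind(dos, dos2)
  }
  ord <- order(sites$chrom, sites$pos)
  gm$sites <- sites[ord, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$dos <- dos[ord, , drop = FALSE]

  truth$introgressed[drop] <- FALSE
  truth$n_moved[drop] <- 0L
  truth$origin[drop] <- "species_tree"
  sim$genotypes <- gm
  sim$truth <- truth
  sim
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated windowed dataset\n")
  cat("  windows:", x$windows$n_windows, "x", x$windows$window_len, "bp\n")
  cat("  samples:", sum(x$samples_per_pop), "diploids in",
      length(x$samples_per_pop), "populations\n")
  cat("  segregating sites:", nrow(x$genotypes$sites), "\n")
  cat("  realized introgressed fraction:",
      format(mean(x$truth$introgressed), digits = 4), "\n")
  invisible(x)
}

#' Write the simulated truth table as TSV
#'
#' Columns: window, chrom, start, end (0-based half-open), rho,
#' introgressed, n_moved, origin.
#' @param sim a `sim_dataset`.
#' @param path output file.
#' @export
write_truth_tsv <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
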