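# Combinatorial enumeration helpers and the end-to-end pipeline driver:
# simulate (or load), polarize, trio D statistics with BH gating, f_hom,
# per-window f_dM and pIRs, introgression/F_ST indices, region classes,
# topology weighting, correlations against covariates, and the Mk
# mating-system comparison.

#' Enumerate unordered four-taxon trios
#'
#' One trio per unordered ingroup triple (the P1/P2/P3 arrangement is
#' resolved downstream by [d_min()]); count = C(n, 3).
#'
#' @param populations ingroup population labels.
#' @param outgroup outgroup label (must not appear among the ingroups).
#' @return data.frame `A`, `B`, `C`, plus the outgroup as an attribute.
#' @export
enumerate_trios <- function(populations, outgroup) {
  if (outgroup %in% populations)
    stop("outgroup must not be listed among the ingroup populations")
  if (length(populations) < 3) stop("need at least 3 ingroup populations")
  cmb <- utils::combn(sort(populations), 3)
  out <- data.frame(A = cmb[1, ], B = cmb[2, ], C = cmb[3, ],
                    stringsAsFactors = FALSE)
  attr(out, "outgroup") <- outgroup
  out
}

#' Enumerate unordered population pairs
#'
#' @param populations population labels (>= 2).
#' @return data.frame `A`, `B`; count = C(n, 2).
#' @export
enumerate_pairs <- function(populations) {
  if (length(populations) < 2) stop("need at least 2 populations")
  cmb <- utils::combn(sort(populations), 2)
  data.frame(A = cmb[1, ], B = cmb[2, ], stringsAsFactors = FALSE)
}

#' Enumerate symmetric five-taxon quintets consistent with a species tree
#'
#' All ((P1,P2),(P3,P4),O) combinations such that the induced four-taxon
#' topology of {P1,P2,P3,P4} in the species tree is the symmetric
#' ((P1,P2),(P3,P4)) and the P3-P4 divergence is older than the P1-P2
#' divergence (ties oriented so the pair containing the alphabetically
#' first label is (P1,P2)). Within-pair label order is canonical
#' (alphabetical), so the output is deduplicated.
#'
#' @param species_tree rooted `phylo` or newick with branch lengths.
#' @param populations ingroup labels to consider (default: all tips
#'   except the outgroup).
#' @param outgroup outgroup label.
#' @return data.frame `P1`, `P2`, `P3`, `P4` (possibly 0 rows).
#' @export
enumerate_quintets <- function(species_tree, populations = NULL, outgroup) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  tips <- setdiff(species_tree$tip.label, outgroup)
  populations <- populations %||% tips
  stopifnot(all(populations %in% tips))
  populations <- sort(populations)
  if (length(populations) < 4) return(data.frame(P1 = character(0),
                                                 P2 = character(0),
                                                 P3 = character(0),
                                                 P4 = character(0)))
  quads <- utils::combn(populations, 4)
  rows <- list()
  for (qi in seq_len(ncol(quads))) {
    s4 <- quads[, qi]
    sub <- ape::keep.tip(species_tree, s4)
    # symmetric iff the root of the induced subtree has two 2-tip children
    id <- canonical_topology(sub)
    pairs <- regmatches(id, gregexpr("\\(([A-Za-z0-9_.-]+),([A-Za-z0-9_.-]+)\\)",
                                     id))[[1]]
    inner <- grep("^\\([^()]*\\)$", pairs, value = TRUE)
    if (length(inner) != 2 || nchar(gsub("[^(]", "", id)) != 3) next
    p_a <- strsplit(gsub("[()]", "", inner[1]), ",")[[1]]
    p_b <- strsplit(gsub("[()]", "", inner[2]), ",")[[1]]
    t_a <- mrca_time(species_tree, p_a[1], p_a[2])
    t_b <- mrca_time(species_tree, p_b[1], p_b[2])
    if (t_a == t_b) {
      first <- min(s4)
      young <- if (first %in% p_a) p_a else p_b
      old <- if (first %in% p_a) p_b else p_a
    } else if (t_a < t_b) {
      young <- p_a; old <- p_b
    } else {
      young <- p_b; old <- p_a
    }
    rows[[length(rows) + 1L]] <- data.frame(
      P1 = min(young), P2 = max(young), P3 = min(old), P4 = max(old),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(P1 = character(0), P2 = character(0),
                                       P3 = character(0), P4 = character(0)))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Run the windowed introgression-landscape pipeline end to end
#'
#' Stages: (1) simulate a dataset (or accept one), (2) polarize against
#' the outgroup, (3) D/D_min with block jackknife and BH gate over all
#' trios, f_hom for significant trios, (4) per-window f_dM, pIRs, and the
#' introgression index, (5) windowed F_ST over pairs and the F_ST index,
#' (6) region classification, (7) correlations of the indices against
#' rho (and gene density when supplied), (8) optional topology weighting
#' and quartet score, (9) optional Mk mating-system comparison. All
#' tabular artifacts are written as TSV under `out_dir` together with a
#' JSON manifest recording parameters and seed; a fixed seed reproduces
#' every output byte.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()], or `NULL` to
#'   simulate from `model`/`windows`/`samples_per_pop`.
#' @param model,windows,samples_per_pop simulation inputs (used when
#'   `sim` is NULL).
#' @param outgroup outgroup population label (defaults to the last tip
#'   of the model tree).
#' @param seed integer seed (required when simulating).
#' @param alpha BH-adjusted significance gate for trios (default 0.01).
#' @param min_snps f_dM window mask (default 10).
#' @param n_blocks jackknife blocks (default 20).
#' @param top_q_introg,top_q_fst,fst_index_threshold landscape thresholds
#'   (defaults 0.05, 0.05, 1/3).
#' @param n_bins correlation bins (default 20).
#' @param weighting run topology weighting with per-window NJ trees on
#'   passing windows (can be slow; default FALSE).
#' @param mk_tree,mk_states optional chronogram + named 0/1 states for
#'   the mating-system stage.
#' @param out_dir output directory (`NULL` = no files written).
#' @return object of class `introscape_run` with the stage results.
#' @export
run_pipeline <- function(sim = NULL, model = NULL, windows = NULL,
                         samples_per_pop = NULL, outgroup = NULL, seed = 1,
                         alpha = 0.01, min_snps = 10, n_blocks = 20,
                         top_q_introg = 0.05, top_q_fst = 0.05,
                         fst_index_threshold = 1 / 3, n_bins = 20,
                         weighting = FALSE, mk_tree = NULL, mk_states = NULL,
                         out_dir = NULL) {
  stopifnot(alpha > 0, alpha <= 1, min_snps >= 0,
            top_q_introg >= 0, top_q_introg <= 1,
            top_q_fst >= 0, top_q_fst <= 1)
  if (is.null(sim)) {
    if (is.null(model) || is.null(windows) || is.null(samples_per_pop))
      stop("supply either `sim` or model + windows + samples_per_pop")
    sim <- simulate_dataset(model, windows, samples_per_pop, seed = seed)
  }
  gm <- sim$genotypes
  tips <- sim$model$phy$tip.label
  outgroup <- outgroup %||% tips[length(tips)]
  gm$outgroup <- outgroup
  ingroups <- setdiff(unique(gm$pop_map), outgroup)

  pf <- polarize(gm)
  wt <- sim$truth[, c("chrom", "start", "end")]
  class(wt) <- c("window_table", "data.frame")

  # --- trio stage ---------------------------------------------------------
  trios <- enumerate_trios(ingroups, outgroup)
  trio_rows <- list()
  for (i in seq_len(nrow(trios))) {
    dm <- d_min(pf, trios$A[i], trios$B[i], trios$C[i], n_blocks = n_blocks)
    r <- dm$dmin
    trio_rows[[i]] <- data.frame(
      A = trios$A[i], B = trios$B[i], C = trios$C[i],
      P1 = r$trio["P1"], P2 = r$trio["P2"], P3 = r$trio["P3"],
      D = r$D, Z = r$Z, p = r$p, n_sites = r$n_sites,
      stringsAsFactors = FALSE)
  }
  trio_tab <- do.call(rbind, trio_rows)
  rownames(trio_tab) <- NULL
  trio_tab$p_adj <- bh_adjust(trio_tab$p)
  trio_tab$significant <- !is.na(trio_tab$p_adj) & trio_tab$p_adj < alpha
  trio_tab$f_hom <- NA_real_
  for (i in which(trio_tab$significant))
    trio_tab$f_hom[i] <- suppressWarnings(
      f_hom(pf, trio_tab$P1[i], trio_tab$P2[i], trio_tab$P3[i]))

  # --- f_dM / pIR / introgression index -----------------------------------
  sig <- which(trio_tab$significant & !is.na(trio_tab$f_hom))
  pir_list <- list(); def_list <- list(); fdm_tracks <- list()
  for (i in sig) {
    tr <- f_dm_track(pf, wt, trio_tab$P1[i], trio_tab$P2[i], trio_tab$P3[i],
                     min_snps = min_snps)
    key <- paste(trio_tab$P1[i], trio_tab$P2[i], trio_tab$P3[i], sep = "_")
    fdm_tracks[[key]] <- tr
    pir_list[[key]] <- call_pir(tr, 100 * trio_tab$f_hom[i])
    def_list[[key]] <- !is.na(tr$fdm)
  }
  if (length(pir_list)) {
    ii <- introgression_index(pir_list, def_list)
    wt$introg_index <- ii$index
  } else {
    wt$introg_index <- NA_real_
  }

  # --- F_ST stage ---------------------------------------------------------
  pairs <- enumerate_pairs(ingroups)
  fst_tracks <- list()
  for (i in seq_len(nrow(pairs))) {
    ft <- fst_windows(gm, pairs$A[i], pairs$B[i], wt)
    fst_tracks[[paste(pairs$A[i], pairs$B[i], sep = "_")]] <- ft$fst
  }
  oi <- outlier_index(fst_tracks, wt$chrom, wt$start, top_q = top_q_fst)
  wt$fst_index <- oi$index
  wt$rho <- sim$truth$rho

  regions <- classify_regions(wt$introg_index, wt$fst_index, wt$chrom,
                              wt$start, top_q = top_q_introg,
                              fst_threshold = fst_index_threshold)

  correlations <- list()
  if (any(!is.na(wt$introg_index)))
    correlations$introg_vs_rho <-
      binned_correlation(wt$introg_index, wt$rho, n_bins = n_bins)
  correlations$fst_vs_rho <-
    binned_correlation(wt$fst_index, wt$rho, n_bins = n_bins)

  # --- optional topology weighting ----------------------------------------
  weighting_res <- NULL
  if (isTRUE(weighting)) {
    weighting_res <- window_weightings(gm, wt, outgroup = outgroup,
                                       species_tree = sim$model$phy)
  }

  # --- optional mating-system stage ---------------------------------------
  mk <- NULL
  if (!is.null(mk_tree) && !is.null(mk_states))
    mk <- fit_mk(mk_tree, mk_states)

  run <- structure(list(
    sim = sim, trios = trio_tab, windows = wt, fdm_tracks = fdm_tracks,
    regions = regions, correlations = correlations,
    weighting = weighting_res, mk = mk,
    params = list(outgroup = outgroup, alpha = alpha, min_snps = min_snps,
                  n_blocks = n_blocks, top_q_introg = top_q_introg,
                  top_q_fst = top_q_fst,
                  fst_index_threshold = fst_index_threshold,
                  n_bins = n_bins, seed = sim$seed)),
    class = "introscape_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Per-window NJ trees + topology weighting + quartet score for passing
# windows. Returns list(weightings, main, quartet).
window_weightings <- function(gm, wt, outgroup, species_tree,
                              min_sites = 20, min_pis = 4) {
  ws <- window_site_stats(gm, wt, min_sites = min_sites, min_pis = min_pis)
  idx <- site_window_index(gm$sites, wt)
  group_map <- gm$pop_map
  weightings <- list(); trees <- list()
  for (w in which(ws$pass_flag)) {
    sites <- which(idx == w)
    tr <- try(nj_tree(gm, sites), silent = TRUE)
    if (inherits(tr, "try-error")) next
    trees[[length(trees) + 1L]] <- tr
    weightings[[length(weightings) + 1L]] <-
      topology_weighting(tr, group_map, outgroup_group = outgroup,
                         method = "montecarlo", n_samples = 200,
                         seed = w)
  }
  if (!length(weightings)) return(NULL)
  qs <- quartet_score(species_tree, trees, group_map = group_map)
  list(weightings = weightings, main = main_topologies(weightings),
       quartet = qs, n_windows = length(weightings))
}

#' @export
print.introscape_run <- function(x, ...) {
  cat("introscape pipeline run (seed", x$params$seed, ")\n")
  cat("  trios tested:", nrow(x$trios), "| significant:",
      sum(x$trios$significant), sprintf("(BH-adjusted p < %g)\n",
                                        x$params$alpha))
  sig_f <- x$trios$f_hom[x$trios$significant]
  if (length(sig_f) && any(!is.na(sig_f)))
    cat("  mean f_hom over significant trios:",
        format(mean(sig_f, na.rm = TRUE), digits = 3), "\n")
  print(x$regions)
  if (!is.null(x$correlations$introg_vs_rho)) {
    cat("  introgression index vs rho: ")
    print(x$correlations$introg_vs_rho)
  }
  if (!is.null(x$mk)) print(x$mk)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(run$trios, p("trio_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_window_table(run$windows, p("window_table.tsv"),
                     params = run$params[c("alpha", "min_snps",
                                           "top_q_introg", "top_q_fst")])
  utils::write.table(run$regions$regions, p("regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- run$regions$regions
  bed <- bed[bed$label != "other",
             c("chrom", "start", "label")]
  bed$end <- run$regions$regions$end %||% run$windows$end[match(
    paste(bed$chrom, bed$start),
    paste(run$windows$chrom, run$windows$start))]
  utils::write.table(bed[, c("chrom", "start", "end", "label")],
                     p("regions.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(run$weighting))
    utils::write.table(run$weighting$main, p("main_topologies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$mk)) {
    mk <- run$mk
    utils::write.table(
      data.frame(model = c("symmetric", "asymmetric"),
                 q01 = c(mk$symmetric$q01, mk$asymmetric$q01),
                 q10 = c(mk$symmetric$q10, mk$asymmetric$q10),
                 logL = c(mk$symmetric$logL, mk$asymmetric$logL),
                 AIC = c(mk$symmetric$AIC, mk$asymmetric$AIC)),
      p("mk_comparison.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- run$params
  manifest$n_windows <- nrow(run$windows)
  manifest$n_trios <- nrow(run$trios)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
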