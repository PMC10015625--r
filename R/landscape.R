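# Windowed differentiation and introgression landscape: Weir-Cockerham
# F_ST, top-quantile outlier indices, region classification, binned
# correlations against covariates, and sweep-track intersection.

# Per-site Weir & Cockerham (1984) variance components for two
# populations, from diploid dosages: returns a (among-population), b
# (among individuals within populations), c (within individuals).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham F_ST for a population pair
#'
#' Per-site Weir & Cockerham (1984) variance components are computed
#' from dosages (observed heterozygotes are dosage-1 diploids) and
#' combined per window as the ratio of sums (weighted estimator), the
#' convention of windowed VCF-based scans. Sites where either population
#' has fewer than two genotyped diploids are excluded; window values are
#' reported unclamped and may be slightly negative. Windows with no
#' usable site are NA.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param windows a window table.
#' @param min_diploids minimum genotyped diploids per population per
#'   site (default 2).
#' @return `windows` with columns `fst` and `n_fst_sites`; attribute
#'   `pair`.
#' @export
fst_windows <- function(gm, popA, popB, windows, min_diploids = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), popA != popB)
  colsA <- which(gm$pop_map == popA)
  colsB <- which(gm$pop_map == popB)
  if (!length(colsA) || !length(colsB)) stop("unknown population label")
  dA <- gm$dos[, colsA, drop = FALSE]; dB <- gm$dos[, colsB, drop = FALSE]
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  use <- n1 >= min_diploids & n2 >= min_diploids
  p1 <- rowSums(dA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dB, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(dA == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(dB == 1L, na.rm = TRUE) / n2
  comp <- wc_components(n1[use], p1[use], h1[use], n2[use], p2[use], h2[use])
  idx <- site_window_index(gm$sites[use, , drop = FALSE], windows)
  ok <- !is.na(idx)
  nw <- nrow(windows)
  a_w <- rowsum_by(comp$a[ok], idx[ok], nw)
  abc_w <- rowsum_by((comp$a + comp$b + comp$c)[ok], idx[ok], nw)
  n_w <- tabulate(idx[ok], nbins = nw)
  windows$fst <- ifelse(n_w > 0 & abc_w != 0, a_w / abc_w, NA_real_)
  windows$n_fst_sites <- n_w
  attr(windows, "pair") <- c(popA, popB)
  windows
}

#' Outlier index across score tracks
#'
#' For each track the top-`top_q` fraction of its defined windows are
#' flagged (ties broken by genomic order); the index of a window is the
#' fraction of tracks, among those defined there, that flag it.
#'
#' @param tracks list of numeric per-window score vectors on a common
#'   window grid (NA = undefined).
#' @param chrom,start window coordinates (tie-breaking).
#' @param top_q outlier fraction per track (default 0.05).
#' @return list `index` (per-window fraction), `n_tracks` (defined
#'   tracks per window), `flags` (logical matrix windows x tracks).
#' @export
outlier_index <- function(tracks, chrom, start, top_q = 0.05) {
  stopifnot(length(tracks) >= 1)
  flags <- vapply(tracks, function(v) top_q_flags(v, chrom, start, top_q),
                  logical(length(tracks[[1]])))
  flags <- matrix(flags, ncol = length(tracks))
  def <- vapply(tracks, function(v) !is.na(v), logical(length(tracks[[1]])))
  def <- matrix(def, ncol = length(tracks))
  n_def <- rowSums(def)
  idx <- ifelse(n_def > 0, rowSums(flags) / n_def, NA_real_)
  list(index = idx, n_tracks = n_def, flags = flags)
}

#' Classify windows into introgression/differentiation region classes
#'
#' High-introgression regions are the top-`top_q` windows by
#' introgression index (exact count, genomic-order tie-breaking; the
#' realized index threshold is reported, not assumed); low-introgression
#' regions have index exactly 0; high-F_ST regions (putative
#' introgression barriers) have F_ST index above `fst_threshold`. The
#' classes are recorded independently (a window may be both high-F_ST
#' and a member of an introgression class) and overlap counts are
#' summarized.
#'
#' @param introg_index per-window introgression index.
#' @param fst_index per-window F_ST index.
#' @param chrom,start window coordinates.
#' @param top_q high-introgression fraction (default 0.05).
#' @param fst_threshold F_ST-index cutoff (default 1/3).
#' @return object of class `region_classification`: data.frame `regions`
#'   (logicals `high_introgression`, `low_introgression`, `high_fst` and
#'   a primary `label`), `introg_threshold` (realized index at the
#'   high-introgression cut), `overlap` (count matrix).
#' @export
classify_regions <- function(introg_index, fst_index, chrom, start,
                             top_q = 0.05, fst_threshold = 1 / 3) {
  hi <- top_q_flags(introg_index, chrom, start, top_q)
  lo <- !is.na(introg_index) & introg_index == 0
  hf <- !is.na(fst_index) & fst_index > fst_threshold
  label <- ifelse(hi, "high_introgression",
                  ifelse(hf, "high_fst",
                         ifelse(lo, "low_introgression", "other")))
  label[is.na(introg_index) & !hf] <- "other"
  regions <- data.frame(chrom = chrom, start = start,
                        high_introgression = hi, low_introgression = lo,
                        high_fst = hf, label = label,
                        stringsAsFactors = FALSE)
  overlap <- rbind(
    high_introgression = c(n = sum(hi), overlap_high_fst = sum(hi & hf)),
    low_introgression = c(n = sum(lo), overlap_high_fst = sum(lo & hf))
  )
  structure(list(regions = regions,
                 introg_threshold = if (any(hi)) min(introg_index[hi]) else NA_real_,
                 overlap = overlap,
                 thresholds = list(top_q = top_q,
                                   fst_threshold = fst_threshold)),
            class = "region_classification")
}

#' @export
print.region_classification <- function(x, ...) {
  cat("Region classification over", nrow(x$regions), "windows\n")
  cat("  high introgression:", sum(x$regions$high_introgression),
      sprintf("(realized index threshold %s)",
              format(x$introg_threshold, digits = 4)), "\n")
  cat("  low introgression :", sum(x$regions$low_introgression), "\n")
  cat("  high F_ST         :", sum(x$regions$high_fst), "\n")
  cat("  high-F_ST overlap: ",
      x$overlap["high_introgression", 2], "with high-,",
      x$overlap["low_introgression", 2], "with low-introgression windows\n")
  invisible(x)
}

#' Binned correlation of a response against a covariate
#'
#' Windows are placed into `n_bins` equal-count bins on the covariate;
#' Pearson correlation (and a least-squares line) is computed between
#' bin-mean covariate and bin-mean response, as is conventional for
#' landscape plots; the raw per-window correlation is reported alongside.
#'
#' @param response,covariate numeric per-window vectors.
#' @param n_bins equal-count bins (default 20).
#' @return object of class `binned_correlation`: `bins` (data.frame of
#'   bin means and counts), `r`, `p`, `slope`, `intercept`, `raw_r`,
#'   `raw_p`, `degenerate` flag.
#' @export
binned_correlation <- function(response, covariate, n_bins = 20) {
  ok <- !is.na(response) & !is.na(covariate)
  x <- covariate[ok]; y <- response[ok]
  if (length(x) < n_bins) n_bins <- max(3L, length(x) %/% 2L)
  grp <- quantile_partition(x, seq_along(x), seq_along(x), k = n_bins)
  bx <- tapply(x, grp, mean); by <- tapply(y, grp, mean)
  bn <- tapply(x, grp, length)
  nonempty <- !is.na(bx)
  if (sum(nonempty) < 3) stop("need at least 3 non-empty bins")
  bx <- bx[nonempty]; by <- by[nonempty]
  degenerate <- stats::sd(by) == 0 || stats::sd(bx) == 0
  if (degenerate) {
    r <- 0; p <- NA_real_; slope <- 0; intercept <- mean(by)
  } else {
    ct <- stats::cor.test(bx, by)
    r <- unname(ct$estimate); p <- ct$p.value
    fit <- stats::lm(by ~ bx)
    slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  }
  raw <- if (stats::sd(y) == 0 || stats::sd(x) == 0)
    list(estimate = 0, p.value = NA_real_)
  else stats::cor.test(x, y)
  structure(list(bins = data.frame(covariate = as.numeric(bx),
                                   response = as.numeric(by),
                                   n = as.integer(bn[nonempty])),
                 r = r, p = p, slope = slope, intercept = intercept,
                 raw_r = unname(raw$estimate), raw_p = raw$p.value,
                 n_bins = length(bx), degenerate = degenerate),
            class = "binned_correlation")
}

#' @export
print.binned_correlation <- function(x, ...) {
  cat(sprintf("Binned correlation (%d bins): r = %s, p = %s%s\n",
              x$n_bins, format(x$r, digits = 3), format(x$p, digits = 3),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  cat(sprintf("  raw per-window: r = %s, p = %s\n",
              format(x$raw_r, digits = 3), format(x$raw_p, digits = 3)))
  invisible(x)
}

#' Intersect two sweep-score track families
#'
#' Mirrors the two-method sweep calling scheme: for each reference-based
#' track in `tracks_a` the top-`top_a` windows are taken, their union
#' deduplicated, and intersected with the top-`top_b` windows of
#' `track_b`. Returns the logical window set of highly confident sweeps.
#'
#' @param tracks_a list of per-window score vectors (one per reference
#'   population).
#' @param track_b single per-window score vector (composite method).
#' @param chrom,start window coordinates.
#' @param top_a,top_b top fractions (defaults 0.01 and 0.05).
#' @return logical vector: window in the intersection set.
#' @export
sweep_intersect <- function(tracks_a, track_b, chrom, start,
                            top_a = 0.01, top_b = 0.05) {
  stopifnot(length(tracks_a) >= 1)
  union_a <- Reduce(`|`, lapply(tracks_a, function(v)
    top_q_flags(v, chrom, start, top_a)))
  top_b_set <- top_q_flags(track_b, chrom, start, top_b)
  union_a & top_b_set
}
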