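# Allele-frequency ABBA-BABA machinery: D with block-jackknife
# significance, D_min over trio arrangements, f_hom admixture fractions,
# windowed f_dM, pIR calling, and the per-window introgression index.
#
# All statistics are computed from outgroup-polarized derived-allele
# frequencies (see polarize()): with p1, p2, p3 the derived frequencies in
# P1, P2, P3 and the outgroup ancestral by construction,
#   ABBA = sum (1-p1) p2 p3 ,   BABA = sum p1 (1-p2) p3 .

trio_spec <- function(P1, P2, P3) {
  labs <- c(P1 = P1, P2 = P2, P3 = P3)
  if (anyDuplicated(labs)) stop("trio populations must be distinct")
  labs
}

usable_trio_sites <- function(pf, labs) {
  f <- pf$freq[, labs, drop = FALSE]
  which(stats::complete.cases(f))
}

#' Frequency-weighted ABBA/BABA pattern counts for a trio
#'
#' Sites with a missing frequency in any trio population are excluded;
#' the remainder are partitioned into `n_blocks` contiguous equal-size
#' blocks for the jackknife.
#'
#' @param pf polarized frequencies from [polarize()].
#' @param P1,P2,P3 ingroup population labels (the outgroup is the one
#'   `pf` was polarized against).
#' @param n_blocks number of contiguous jackknife blocks (default 20).
#' @return object of class `pattern_counts`: totals `ABBA`, `BABA`,
#'   per-block sums, site count, and the trio labels.
#' @export
pattern_counts <- function(pf, P1, P2, P3, n_blocks = 20) {
  stopifnot(inherits(pf, "polarized_freqs"))
  labs <- trio_spec(P1, P2, P3)
  use <- usable_trio_sites(pf, labs)
  p1 <- pf$freq[use, P1]; p2 <- pf$freq[use, P2]; p3 <- pf$freq[use, P3]
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  n <- length(use)
  if (n >= n_blocks) {
    blk <- block_assignment(n, n_blocks)
    abba_b <- as.numeric(tapply(abba, blk, sum))
    baba_b <- as.numeric(tapply(baba, blk, sum))
  } else {
    abba_b <- if (n) sum(abba) else numeric(0)
    baba_b <- if (n) sum(baba) else numeric(0)
  }
  structure(list(ABBA = sum(abba), BABA = sum(baba),
                 abba_blocks = abba_b, baba_blocks = baba_b,
                 n_sites = n, trio = labs),
            class = "pattern_counts")
}

#' D statistic with delete-one block-jackknife significance
#'
#' D = (ABBA - BABA) / (ABBA + BABA); the standard error comes from a
#' delete-one jackknife over the contiguous blocks, Z = D/SE, and p is the
#' two-sided normal tail.
#'
#' @param counts a [pattern_counts()] object.
#' @return object of class `d_result` with `D`, `Z`, `p`, `n_blocks`,
#'   `n_sites`, `trio`.
#' @export
d_statistic <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  tot <- counts$ABBA + counts$BABA
  if (!counts$n_sites || tot <= 0)
    return(structure(list(D = NA_real_, Z = NA_real_, p = NA_real_,
                          n_blocks = length(counts$abba_blocks),
                          n_sites = counts$n_sites, trio = counts$trio,
                          undefined = TRUE), class = "d_result"))
  D <- (counts$ABBA - counts$BABA) / tot
  g <- length(counts$abba_blocks)
  if (g >= 5) {
    Dj <- vapply(seq_len(g), function(j) {
      a <- counts$ABBA - counts$abba_blocks[j]
      b <- counts$BABA - counts$baba_blocks[j]
      if (a + b <= 0) 0 else (a - b) / (a + b)
    }, 0)
    se <- sqrt((g - 1) / g * sum((Dj - mean(Dj))^2))
    Z <- if (se > 0) D / se else sign(D) * Inf
    p <- 2 * stats::pnorm(-abs(Z))
  } else {
    Z <- NA_real_; p <- NA_real_
  }
  structure(list(D = D, Z = Z, p = p, n_blocks = g,
                 n_sites = counts$n_sites, trio = counts$trio,
                 undefined = FALSE),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D((%s,%s);%s) = %s  Z = %s  p = %s  [%d sites, %d blocks]\n",
              x$trio["P1"], x$trio["P2"], x$trio["P3"],
              format(x$D, digits = 4), format(x$Z, digits = 3),
              format(x$p, digits = 3), x$n_sites, x$n_blocks))
  invisible(x)
}

#' Conservative D_min over the three trio arrangements
#'
#' Evaluates D for the three (P1,P2;P3) arrangements of an unordered
#' population triple and reports the one with minimum |D| (a conservative
#' lower bound on introgression evidence), alongside the most-significant
#' arrangement for reporting.
#'
#' @param pf polarized frequencies.
#' @param A,B,C the unordered ingroup triple.
#' @param n_blocks jackknife blocks.
#' @return object of class `dmin_result`: `dmin` (the minimum-|D|
#'   `d_result`), `most_significant` (smallest-p `d_result`), and
#'   `arrangements` (all three).
#' @export
d_min <- function(pf, A, B, C, n_blocks = 20) {
  labs <- sort(c(A, B, C))
  arr <- list(c(labs[1], labs[2], labs[3]),
              c(labs[1], labs[3], labs[2]),
              c(labs[2], labs[3], labs[1]))
  res <- lapply(arr, function(a)
    d_statistic(pattern_counts(pf, a[1], a[2], a[3], n_blocks)))
  ok <- !vapply(res, `[[`, TRUE, "undefined")
  if (!any(ok)) stop("D undefined for every arrangement of the trio")
  res_ok <- lapply(res[ok], orient_d)
  absd <- vapply(res_ok, function(r) abs(r$D), 0)
  pv <- vapply(res_ok, function(r) r$p %||% NA_real_, 0)
  structure(list(dmin = res_ok[[which.min(absd)]],
                 most_significant =
                   res_ok[[if (all(is.na(pv))) which.min(absd)
                           else which.min(pv)]],
                 arrangements = res),
            class = "dmin_result")
}

# Flip a d_result to the conventional orientation (D >= 0) by swapping
# P1 and P2; |Z| and p are unchanged.
orient_d <- function(r) {
  if (!r$undefined && !is.na(r$D) && r$D < 0) {
    r$trio[c("P1", "P2")] <- r$trio[c("P2", "P1")]
    r$D <- -r$D
    if (!is.na(r$Z)) r$Z <- -r$Z
  }
  r
}

#' @export
print.dmin_result <- function(x, ...) {
  cat("D_min arrangement: "); print(x$dmin)
  cat("Most significant : "); print(x$most_significant)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' f_hom admixture-fraction estimator for a trio
#'
#' f_hom = S(P1,P2,P3,O) / S(P1,P3,P3,O) = (ABBA1 - BABA1)/(ABBA2 - BABA2),
#' the observed ABBA-BABA excess scaled by the excess expected if P3 had
#' completely homogenized P2 (the denominator substitutes P3 for P2).
#'
#' @param pf polarized frequencies.
#' @param P1,P2,P3 trio labels.
#' @return scalar f_hom (NA with a warning when the denominator is zero).
#' @export
f_hom <- function(pf, P1, P2, P3) {
  labs <- trio_spec(P1, P2, P3)
  use <- usable_trio_sites(pf, labs)
  p1 <- pf$freq[use, P1]; p2 <- pf$freq[use, P2]; p3 <- pf$freq[use, P3]
  num <- sum((1 - p1) * p2 * p3 - p1 * (1 - p2) * p3)
  den <- sum((1 - p1) * p3 * p3 - p1 * (1 - p3) * p3)
  if (!length(use) || den == 0) {
    warning("f_hom undefined: zero homogenization denominator")
    return(NA_real_)
  }
  num / den
}

#' Maximum f_hom per (P2, P3) pair over all P1 choices
#'
#' Convenience aggregator mirroring the reporting convention that the
#' genomic proportion of introgression between a P2-P3 species pair is
#' the maximum f_hom across the candidate P1 populations.
#'
#' @param pf polarized frequencies.
#' @param trios data.frame with columns `P1`, `P2`, `P3` (e.g. rows of
#'   [enumerate_trios()] expanded to arrangements) and optionally
#'   `f_hom`; when `f_hom` is absent it is computed.
#' @return data.frame `P2`, `P3`, `f_hom_max`, `P1_max`.
#' @export
f_hom_max <- function(pf, trios) {
  if (!"f_hom" %in% names(trios))
    trios$f_hom <- mapply(function(a, b, c) f_hom(pf, a, b, c),
                          trios$P1, trios$P2, trios$P3)
  key <- paste(trios$P2, trios$P3, sep = "\r")
  out <- lapply(split(trios, key), function(d) {
    i <- which.max(d$f_hom)
    data.frame(P2 = d$P2[i], P3 = d$P3[i], f_hom_max = d$f_hom[i],
               P1_max = d$P1[i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Per-site f_dM numerator/denominator (dynamic-donor, symmetric form).
# Numerator: ABBA - BABA. Denominator: for sites with p2 >= p1 the donor
# is D = max(p2, p3) and the site term is S(P1, PD, PD, O); for p1 > p2
# the donor is D2 = max(p1, p3) and the term is -S(PD2, P2, PD2, O).
fdm_site_terms <- function(p1, p2, p3) {
  num <- (1 - p1) * p2 * p3 - p1 * (1 - p2) * p3
  den <- numeric(length(p1))
  up <- p2 >= p1
  pD <- pmax(p2, p3)
  den[up] <- ((1 - p1) * pD * pD - p1 * (1 - pD) * pD)[up]
  pD2 <- pmax(p1, p3)
  den[!up] <- -((1 - pD2) * p2 * pD2 - pD2 * (1 - p2) * pD2)[!up]
  list(num = num, den = den)
}

#' Windowed f_dM track for a trio
#'
#' The dynamic-donor, symmetric admixture-proportion statistic per window:
#' the ABBA-BABA excess over the excess under complete homogenization by
#' the per-site donor (whichever of the candidate donors has the larger
#' derived frequency), bounded in \[-1, 1\] and defined for introgression
#' in both directions. Windows with fewer than `min_snps` usable SNPs (or
#' a zero denominator) are masked.
#'
#' @param pf polarized frequencies.
#' @param windows a window table.
#' @param P1,P2,P3 trio labels.
#' @param min_snps minimum usable SNPs per window (default 10).
#' @return `windows` with columns `fdm`, `n_snps`; attribute `trio`.
#' @export
f_dm_track <- function(pf, windows, P1, P2, P3, min_snps = 10) {
  labs <- trio_spec(P1, P2, P3)
  use <- usable_trio_sites(pf, labs)
  terms <- fdm_site_terms(pf$freq[use, P1], pf$freq[use, P2],
                          pf$freq[use, P3])
  idx <- site_window_index(pf$sites[use, , drop = FALSE], windows)
  nw <- nrow(windows)
  ok <- !is.na(idx)
  num_w <- rowsum_by(terms$num[ok], idx[ok], nw)
  den_w <- rowsum_by(terms$den[ok], idx[ok], nw)
  n_w <- tabulate(idx[ok], nbins = nw)
  fdm <- ifelse(n_w >= min_snps & den_w != 0, num_w / den_w, NA_real_)
  windows$fdm <- fdm
  windows$n_snps <- n_w
  attr(windows, "trio") <- labs
  attr(windows, "min_snps") <- min_snps
  windows
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Call putatively introgressed regions (pIRs) from an f_dM track
#'
#' Flags the `ceiling(x_percent/100 * n_defined)` windows with the
#' largest f_dM values; ties at the cutoff are broken by genomic order so
#' the count is exact. By convention `x_percent` is 100 times the trio's
#' f_hom estimate (a negative f_hom yields an empty set).
#'
#' @param track output of [f_dm_track()].
#' @param x_percent percentage of defined windows to flag, in \[0, 100\];
#'   negative values are clamped to 0.
#' @return logical vector over the track's windows (TRUE = pIR).
#' @export
call_pir <- function(track, x_percent) {
  if (is.na(x_percent)) x_percent <- 0
  x_percent <- max(0, min(100, x_percent))
  top_q_flags(track$fdm, track$chrom, track$start, x_percent / 100)
}

#' Per-window introgression index over significant trios
#'
#' The fraction of contributing trios that flag each window as a pIR.
#' Only trios passing the significance gate should be supplied; windows
#' where a trio's track is undefined do not count toward that trio's
#' denominator.
#'
#' @param pir_list list of logical pIR vectors (one per trio, from
#'   [call_pir()]).
#' @param defined_list optional list of logical vectors marking windows
#'   where each trio's track is defined; defaults to all-defined.
#' @return list with `index` (numeric per window in \[0,1\], NA where no
#'   trio is defined) and `n_trios` (contributing trios per window).
#' @export
introgression_index <- function(pir_list, defined_list = NULL) {
  stopifnot(length(pir_list) >= 1)
  flags <- do.call(cbind, pir_list)
  if (is.null(defined_list)) {
    def <- matrix(TRUE, nrow(flags), ncol(flags))
  } else {
    def <- do.call(cbind, defined_list)
    stopifnot(dim(def) == dim(flags))
  }
  n_def <- rowSums(def)
  idx <- ifelse(n_def > 0, rowSums(flags & def) / n_def, NA_real_)
  list(index = idx, n_trios = n_def)
}
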