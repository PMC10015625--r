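# Window tables (0-based half-open, fixed width) and per-window site
# statistics: site counts, parsimony-informative sites, gene density.

#' Build a fixed-width nonoverlapping window table
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_len window width in bp (default 10 kb). A trailing
#'   partial window is kept (truncated at the chromosome end).
#' @return data.frame of class `window_table` with columns `chrom`,
#'   `start`, `end` (0-based half-open), sorted and disjoint.
#' @export
make_windows <- function(chrom_lengths, window_len = 1e4) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    s <- seq(0, len - 1, by = window_len)
    data.frame(chrom = ch, start = s, end = pmin(s + window_len, len),
               stringsAsFactors = FALSE)
  })
  wt <- do.call(rbind, out)
  class(wt) <- c("window_table", "data.frame")
  wt
}

# Index of the window containing each site (1-based positions against
# 0-based half-open windows); NA where a site falls in no window.
site_window_index <- function(sites, windows) {
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites$chrom == ch)
    if (!length(wi) || !length(si)) next
    j <- findInterval(sites$pos[si] - 1L, windows$start[wi])
    ok <- j >= 1L & (sites$pos[si] - 1L) < windows$end[wi][pmax(j, 1L)]
    idx[si[ok]] <- wi[j[ok]]
  }
  idx
}

#' Per-window site counts, parsimony-informative sites, and pass flags
#'
#' A parsimony-informative site (PIS) is a variable site where at least
#' two alleles are each carried by at least two haplotypes; the count is
#' taken at the allele-copy level from dosages (each diploid contributes
#' two observations). A window passes when it has at least `min_sites`
#' sites and `min_pis` PIS.
#'
#' @param gm a [genotype_matrix()].
#' @param windows a window table from [make_windows()].
#' @param min_sites,min_pis pass thresholds (defaults 200 and 20, the
#'   usual windowed-phylogenomics setting).
#' @return `windows` with added columns `n_sites`, `n_pis`, `pass_flag`.
#' @export
window_site_stats <- function(gm, windows, min_sites = 200, min_pis = 20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_nonmiss <- rowSums(!is.na(gm$dos))
  alt <- rowSums(gm$dos, na.rm = TRUE)
  ref <- 2L * n_nonmiss - alt
  is_pis <- pmin(alt, ref) >= 2L
  idx <- site_window_index(gm$sites, windows)
  nw <- nrow(windows)
  windows$n_sites <- tabulate(idx, nbins = nw)
  windows$n_pis <- tabulate(idx[is_pis], nbins = nw)
  windows$pass_flag <- windows$n_sites >= min_sites & windows$n_pis >= min_pis
  attr(windows, "filters") <- list(min_sites = min_sites, min_pis = min_pis)
  windows
}

#' Read gene intervals from a GFF3 annotation
#'
#' Intervals of the requested feature type are imported, converted to
#' 0-based half-open coordinates, and merged (overlaps collapsed) per
#' chromosome.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return data.frame of class `annotation_intervals` with columns
#'   `chrom`, `start`, `end` (0-based half-open, merged).
#' @export
read_gene_intervals <- function(path, feature = "gene") {
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == feature, , drop = FALSE]
  merge_intervals(data.frame(chrom = as.character(gff$seqid),
                             start = gff$start - 1L, end = gff$end,
                             stringsAsFactors = FALSE))
}

#' Merge possibly-overlapping intervals
#'
#' @param intervals data.frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return merged, sorted data.frame of class `annotation_intervals`.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(intervals$start < intervals$end))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_intervals", "data.frame")
  out
}

#' Per-window gene density
#'
#' Fraction of each window covered by (merged) gene intervals.
#'
#' @param ann intervals from [read_gene_intervals()] or
#'   [merge_intervals()].
#' @param windows a window table.
#' @return `windows` with an added `gene_density` column in \[0, 1\].
#' @export
gene_density <- function(ann, windows) {
  gr_ann <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end))
  gr_win <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  ov <- GenomicRanges::findOverlaps(gr_win, gr_ann)
  inter <- GenomicRanges::pintersect(
    gr_win[S4Vectors::queryHits(ov)], gr_ann[S4Vectors::subjectHits(ov)])
  cov <- rep(0, nrow(windows))
  if (length(ov)) {
    agg <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    cov[as.integer(names(agg))] <- agg
  }
  windows$gene_density <- cov / (windows$end - windows$start)
  windows
}

#' Write a window table as TSV
#'
#' @param windows window table (any extra columns included).
#' @param path output path.
#' @param params optional named list recorded as `##key=value` header
#'   comment lines.
#' @export
write_window_table <- function(windows, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("##%s=%s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","), "")),
               con)
  utils::write.table(windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-window track TSV
#'
#' Expects at least `chrom`, `start`, `end` columns; `##` comment lines
#' are skipped.
#' @param path TSV path.
#' @return data.frame of class `window_table`.
#' @export
read_window_table <- function(path) {
  wt <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  class(wt) <- c("window_table", "data.frame")
  wt
}
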