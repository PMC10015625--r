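# Genotype container and VCF input/output.
#
# Internal conventions: VCF positions stay 1-based as read; windows and
# annotation intervals are 0-based half-open. Dosages count copies of the
# alternate allele per diploid (0/1/2, NA = missing).

#' Construct a biallelic genotype matrix
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param dos integer matrix, sites x samples, alternate-allele dosages in
#'   `{0,1,2,NA}`; column names are sample ids.
#' @param pop_map named character vector mapping sample id to population
#'   label; must cover every sample column.
#' @param outgroup outgroup population label (or `NULL` if designated
#'   later); must appear in `pop_map` when given.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dos, pop_map, outgroup = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(dos))
  if (is.null(colnames(dos))) stop("dosage matrix needs sample column names")
  miss <- setdiff(colnames(dos), names(pop_map))
  if (length(miss))
    stop("samples absent from the population map: ", paste(miss, collapse = ", "))
  pop_map <- pop_map[colnames(dos)]
  if (!is.null(outgroup) && !outgroup %in% pop_map)
    stop("outgroup population '", outgroup, "' not present in pop_map")
  rownames(sites) <- NULL
  structure(list(sites = sites, dos = dos, pop_map = pop_map,
                 outgroup = outgroup),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$sites), "biallelic sites x",
      ncol(x$dos), "samples\n")
  cat("  populations:", paste(sort(unique(x$pop_map)), collapse = ", "), "\n")
  if (!is.null(x$outgroup)) cat("  outgroup:", x$outgroup, "\n")
  lg <- attr(x, "filter_log")
  if (!is.null(lg)) {
    cat("  sites dropped by filter:\n")
    for (nm in names(lg)) cat(sprintf("    %-14s %d\n", nm, lg[[nm]]))
  }
  invisible(x)
}

#' Read a two-column sample-to-population map
#'
#' TSV with columns sample, population (no header required; a header line
#' `sample<TAB>population` is tolerated).
#' @param path file path.
#' @return named character vector (names = samples).
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (nrow(df) && df$sample[1] == "sample") df <- df[-1, , drop = FALSE]
  stats::setNames(df$population, df$sample)
}

gt_to_dosage <- function(gt) {
  # GT strings like 0/1, 1|0, ./., possibly with trailing :FOO stripped
  # beforehand. Anything containing '.' is missing.
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0", "0|0", "0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1", "1")] <- 2L
  d
}

#' Read and filter a VCF into a genotype matrix
#'
#' Site filters mirror the usual resequencing workflow: indels are always
#' dropped; optionally multiallelic sites, sites whose QUAL falls below a
#' minimum, sites with too much missingness, and sites whose mean sample
#' depth (FORMAT/DP) falls outside bounds. Every enabled rule is evaluated
#' on the full site list independently, so the retained set does not
#' depend on rule order; per-rule drop counts are attached as the
#' `filter_log` attribute. Depth rules are no-ops (logged as such) when the
#' VCF carries no DP field, as is the case for simulated data.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param pop_map named character vector (see [read_pop_map()]).
#' @param outgroup optional outgroup population label.
#' @param biallelic_only drop sites with more than one ALT allele.
#' @param max_missing_fraction drop sites with a larger fraction of
#'   missing genotypes (`NULL` disables; the classic resequencing setting
#'   is 0.67... interpreted as "at most this fraction missing").
#' @param min_quality drop sites with QUAL below this (`NULL` disables;
#'   missing QUAL always passes).
#' @param mean_depth_bounds length-2 numeric `c(min, max)` on the mean
#'   FORMAT/DP across genotyped samples (`NULL` disables).
#' @return a [genotype_matrix()] with a `filter_log` attribute.
#' @export
read_vcf_filtered <- function(path, pop_map, outgroup = NULL,
                              biallelic_only = TRUE,
                              max_missing_fraction = 0.67,
                              min_quality = 30,
                              mean_depth_bounds = c(10, 500)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  n_sites <- nrow(fix) %||% 0L
  if (n_sites == 0L) {
    samples <- colnames(v@gt)[-1] %||% character(0)
    dos <- matrix(integer(0), 0L, length(samples),
                  dimnames = list(NULL, samples))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
    gm <- genotype_matrix(sites, dos, pop_map[samples] %||%
                            stats::setNames(character(0), character(0)),
                          outgroup)
    attr(gm, "filter_log") <- list()
    return(gm)
  }
  samples <- colnames(v@gt)[-1]
  miss <- setdiff(samples, names(pop_map))
  if (length(miss))
    stop("VCF samples absent from the population map: ",
         paste(miss, collapse = ", "))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L |
                       ref == "*" | alt == "*")
  # multiallelic sites containing an indel allele count as multiallelic
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(gt_to_dosage(sub(":.*$", "", gt)), nrow = n_sites,
                dimnames = list(NULL, samples))
  miss_frac <- rowMeans(is.na(dos))

  drop_rules <- list(indel = indel)
  if (isTRUE(biallelic_only)) drop_rules$multiallelic <- multi
  if (!is.null(max_missing_fraction))
    drop_rules$missingness <- miss_frac > max_missing_fraction
  if (!is.null(min_quality)) {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    drop_rules$quality <- !is.na(qual) & qual < min_quality
  }
  if (!is.null(mean_depth_bounds)) {
    if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
      dp <- suppressWarnings(
        matrix(as.numeric(vcfR::extract.gt(v, element = "DP")),
               nrow = n_sites))
      mdp <- rowMeans(dp, na.rm = TRUE)
      drop_rules$mean_depth <- !is.nan(mdp) &
        (mdp < mean_depth_bounds[1] | mdp > mean_depth_bounds[2])
    } else {
      drop_rules$mean_depth <- rep(FALSE, n_sites)  # no DP field: no-op
    }
  }
  drop_any <- Reduce(`|`, drop_rules)
  keep <- !drop_any

  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, dos[keep, , drop = FALSE],
                        pop_map, outgroup)
  attr(gm, "filter_log") <- lapply(drop_rules, sum)
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits diploid GT fields and one contig header line per chromosome.
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @param contig_lengths optional named vector of contig lengths; defaults
#'   to the maximum observed position per chromosome.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  chroms <- unique(gm$sites$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch)
      max(gm$sites$pos[gm$sites$chrom == ch], 0L), 0)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introscape",
           sprintf("##contig=<ID=%s,length=%d>", chroms,
                   as.integer(contig_lengths[chroms])),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm$dos)), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$dos + 1L], nrow = nrow(gm$dos))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(gm$dos) == 0L)
    body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Polarize sites against the outgroup and compute derived frequencies
#'
#' The ancestral allele at a site is the allele fixed among the genotyped
#' outgroup samples; sites where the outgroup is polymorphic (below the
#' `outgroup_fixed_min` majority threshold) or entirely missing are
#' dropped and counted. Derived allele frequency per ingroup population is
#' the derived dosage sum over twice the number of genotyped diploids
#' (`NA` where a population has no genotyped sample at the site).
#'
#' @param gm a [genotype_matrix()] with an outgroup designated (or pass
#'   `outgroup=`).
#' @param outgroup override the outgroup label stored in `gm`.
#' @param outgroup_fixed_min minimum majority-allele frequency among
#'   outgroup allele copies for the site to count as fixed; the default 1
#'   is strict fixation.
#' @return object of class `polarized_freqs`: `freq` (sites x populations
#'   derived-frequency matrix), `n` (genotyped diploids per site x
#'   population), `sites` (chrom/pos), `dropped` (named counts).
#' @export
polarize <- function(gm, outgroup = gm$outgroup, outgroup_fixed_min = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(outgroup)) stop("an outgroup population must be designated")
  if (!outgroup %in% gm$pop_map) stop("unknown outgroup: ", outgroup)
  og_cols <- which(gm$pop_map == outgroup)
  og <- gm$dos[, og_cols, drop = FALSE]
  og_n <- rowSums(!is.na(og))
  og_alt <- rowSums(og, na.rm = TRUE)
  og_f_alt <- og_alt / (2 * og_n)            # NaN where all missing
  all_missing <- og_n == 0L
  anc_is_ref <- !all_missing & og_f_alt <= 1 - outgroup_fixed_min
  anc_is_alt <- !all_missing & og_f_alt >= outgroup_fixed_min
  polymorphic <- !all_missing & !anc_is_ref & !anc_is_alt
  keep <- anc_is_ref | anc_is_alt

  pops <- setdiff(sort(unique(gm$pop_map)), outgroup)
  nk <- sum(keep)
  freq <- matrix(NA_real_, nk, length(pops), dimnames = list(NULL, pops))
  ncnt <- matrix(0L, nk, length(pops), dimnames = list(NULL, pops))
  flip <- anc_is_alt[keep]
  for (p in pops) {
    cols <- which(gm$pop_map == p)
    sub <- gm$dos[keep, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    alt <- rowSums(sub, na.rm = TRUE)
    f <- alt / (2 * n)
    f[flip] <- 1 - f[flip]
    f[n == 0L] <- NA_real_
    freq[, p] <- f
    ncnt[, p] <- n
  }
  structure(list(freq = freq, n = ncnt,
                 sites = gm$sites[keep, c("chrom", "pos"), drop = FALSE],
                 outgroup = outgroup,
                 dropped = c(outgroup_missing = sum(all_missing),
                             outgroup_polymorphic = sum(polymorphic))),
            class = "polarized_freqs")
}

#' @export
print.polarized_freqs <- function(x, ...) {
  cat("Polarized derived-allele frequencies:", nrow(x$freq), "sites x",
      ncol(x$freq), "populations (outgroup ", x$outgroup, ")\n", sep = "")
  cat("  dropped:", x$dropped["outgroup_missing"], "outgroup-missing,",
      x$dropped["outgroup_polymorphic"], "outgroup-polymorphic\n")
  invisible(x)
}
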