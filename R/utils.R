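# Shared internal helpers: top-quantile window selection with deterministic
# tie-breaking, contiguous block assignment for jackknives, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag the top-q windows of a score track
#'
#' Selects exactly `ceiling(q * n_defined)` windows with the largest values.
#' Ties at the cutoff are broken by genomic order (chrom, then start,
#' ascending) so the flagged count is exact and reproducible.
#'
#' @param values numeric score per window (NA = undefined, never flagged).
#' @param chrom,start window coordinates used for tie-breaking.
#' @param q fraction in \[0, 1\].
#' @return logical vector, TRUE for flagged windows.
#' @keywords internal
top_q_flags <- function(values, chrom, start, q) {
  stopifnot(q >= 0, q <= 1)
  n <- length(values)
  flags <- logical(n)
  defined <- which(!is.na(values))
  k <- ceiling(q * length(defined))
  if (k == 0L) return(flags)
  ord <- defined[order(-values[defined], as.character(chrom[defined]),
                       start[defined])]
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Assign n items to nb contiguous blocks of near-equal size
#'
#' Block sizes differ by at most one; larger blocks come first.
#' @keywords internal
block_assignment <- function(n, nb) {
  stopifnot(n >= nb, nb >= 1)
  sizes <- rep(n %/% nb, nb)
  extra <- n %% nb
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep.int(seq_len(nb), sizes)
}

#' Equal-count quantile groups with deterministic tie-breaking
#'
#' Orders windows by covariate value (ties resolved by genomic order) and
#' cuts the ordering into `k` contiguous groups whose sizes differ by at
#' most one (the remainder goes to the lowest groups).
#'
#' @param values covariate per window; NA values receive NA group.
#' @param chrom,start coordinates for tie-breaking.
#' @param k number of groups.
#' @param labels group labels, lowest to highest; default `g1..gk`.
#' @return integer (or factor when labels given) group per window.
#' @export
quantile_partition <- function(values, chrom = seq_along(values),
                               start = seq_along(values), k = 5,
                               labels = NULL) {
  defined <- which(!is.na(values))
  if (length(defined) < k)
    stop("covariate must be defined on at least k windows")
  if (length(unique(values[defined])) == 1L)
    warning("constant covariate: groups are determined by genomic order only")
  ord <- defined[order(values[defined], as.character(chrom[defined]),
                       start[defined])]
  grp <- rep(NA_integer_, length(values))
  grp[ord] <- block_assignment(length(ord), k)
  if (!is.null(labels)) {
    stopifnot(length(labels) == k)
    grp <- factor(labels[grp], levels = labels)
  }
  grp
}
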