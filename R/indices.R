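#' @title Endopolyploidy parameters
#'
#' @description
#' Let \eqn{n_k} be the number of nuclei in ploidy class \eqn{2^k \cdot 2C}
#' (\eqn{k = 0, 1, \dots} endocycles), \eqn{N = \sum_k n_k} and
#' \eqn{f_k = n_k / N}. The parameter suite is then
#' \itemize{
#'   \item EI (endoreduplication index): \eqn{\sum_k k f_k}, the mean number
#'     of endocycles per nucleus;
#'   \item MCV (mean C-value): \eqn{\sum_k 2^{k+1} f_k}, the count-weighted
#'     mean C-level;
#'   \item E4P: the mean C-level among endopolyploid (>= 4C) nuclei,
#'     \eqn{\sum_{k \ge 1} 2^{k+1} n_k / \sum_{k \ge 1} n_k}; undefined
#'     (returned as `NA`, never 0) when no nucleus is >= 4C;
#'   \item >=4C: \eqn{100 \sum_{k \ge 1} f_k}, percent of nuclei that entered
#'     the endocycle;
#'   \item ECmax: the largest \eqn{k} with \eqn{n_k > 0};
#'   \item meanDNA (tissue-specific mean DNA content):
#'     \eqn{\mathrm{MCV} \cdot 2C_{pg} / 2} picograms -- the genome size of
#'     the species scaled by the tissue's endopolyploidy level.
#' }
#' All functions accept a [ploidy_counts] object or a plain (optionally
#' named) non-negative vector over the classes 2C, 4C, 8C, ...; proportions
#' or percentages work as well as raw counts since every parameter is a
#' ratio.
#'
#' @param counts a [ploidy_counts] or non-negative numeric vector (names
#'   `"2C"`, `"4C"`, ... or unnamed, in doubling order from 2C).
#' @return a single numeric value.
#' @name endopoly-parameters
NULL

# -> list(k = 0:K, w = weights), dropping nothing
.class_weights <- function(counts) {
  if (inherits(counts, "ploidy_counts")) {
    w <- counts$counts
  } else {
    w <- counts
    w[is.na(w)] <- 0
    w <- stats::setNames(as.numeric(w),
                         paste0(.parse_c_levels(names(counts), length(counts)),
                                "C"))
  }
  lv <- .parse_c_levels(names(w), length(w))
  if (any(w < 0)) stop("class counts must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("empty ploidy counts", call. = FALSE)
  list(k = round(log2(lv / 2)), w = as.numeric(w))
}

#' @rdname endopoly-parameters
#' @export
endoreduplication_index <- function(counts) {
  cw <- .class_weights(counts)
  sum(cw$k * cw$w) / sum(cw$w)
}

#' @rdname endopoly-parameters
#' @export
mean_c_value <- function(counts) {
  cw <- .class_weights(counts)
  sum(2^(cw$k + 1) * cw$w) / sum(cw$w)
}

#' @rdname endopoly-parameters
#' @export
e4p <- function(counts) {
  cw <- .class_weights(counts)
  endo <- cw$k >= 1
  if (sum(cw$w[endo]) <= 0) return(NA_real_)
  sum(2^(cw$k[endo] + 1) * cw$w[endo]) / sum(cw$w[endo])
}

#' @rdname endopoly-parameters
#' @export
prop_4c <- function(counts) {
  cw <- .class_weights(counts)
  100 * sum(cw$w[cw$k >= 1]) / sum(cw$w)
}

#' @rdname endopoly-parameters
#' @export
ecmax <- function(counts) {
  cw <- .class_weights(counts)
  max(cw$k[cw$w > 0])
}

#' Tissue-specific mean DNA content (meanDNA)
#'
#' Combines the endopolyploidy level of a tissue (its mean C-value) with the
#' genome size of the species: `meanDNA = MCV * c2_pg / 2` picograms, i.e.
#' the mean C-value expressed through the species' 1C amount. A purely 2C
#' tissue (MCV = 2) returns the genome size unchanged.
#'
#' @param mcv mean C-value (>= 2), e.g. from [mean_c_value].
#' @param c2_pg species 2C DNA amount in picograms. By convention the
#'   species-level mean 2C is used, since genome sizes are measured on
#'   separate individuals.
#' @return meanDNA in picograms.
#' @export
mean_dna <- function(mcv, c2_pg) {
  if (any(mcv < 2, na.rm = TRUE)) stop("MCV cannot be below 2", call. = FALSE)
  if (any(c2_pg <= 0)) stop("2C amount must be positive", call. = FALSE)
  mcv * c2_pg / 2
}

#' Endopolyploidy predicate
#'
#' A tissue is called endopolyploid when its endoreduplication index exceeds
#' 0.1 -- i.e. on average more than one nucleus in ten has undergone an
#' endocycle.
#'
#' @param ei endoreduplication index value(s).
#' @param threshold EI threshold (default 0.1).
#' @return logical vector.
#' @export
is_endopolyploid <- function(ei, threshold = 0.1) ei > threshold

#' Compute the full endopolyploidy profile of one measurement
#'
#' @param counts a [ploidy_counts] or class-count vector.
#' @param c2_pg optional species 2C genome size (pg); when missing, meanDNA
#'   is `NA` (flagged missing, never 0).
#' @param meta optional named list overriding the metadata carried by
#'   `counts`.
#' @return a one-row data.frame of class `endopoly_profile` with columns
#'   species, organ, individual, replicate, n_nuclei, EI, MCV, E4P, p4c,
#'   ECmax, meanDNA.
#' @export
endopoly_profile <- function(counts, c2_pg = NA_real_, meta = NULL) {
  if (is.null(meta) && inherits(counts, "ploidy_counts")) meta <- counts$meta
  meta <- utils::modifyList(
    list(species = NA_character_, organ = NA_character_,
         individual = NA_character_, replicate = NA_integer_),
    if (is.null(meta)) list() else meta[!vapply(meta, is.null, logical(1))])
  cw <- .class_weights(counts)
  mcv <- sum(2^(cw$k + 1) * cw$w) / sum(cw$w)
  out <- data.frame(
    species = meta$species, organ = meta$organ,
    individual = meta$individual, replicate = meta$replicate,
    n_nuclei = sum(cw$w),
    EI = sum(cw$k * cw$w) / sum(cw$w),
    MCV = mcv,
    E4P = e4p(counts),
    p4c = 100 * sum(cw$w[cw$k >= 1]) / sum(cw$w),
    ECmax = max(cw$k[cw$w > 0]),
    meanDNA = if (is.na(c2_pg)) NA_real_ else mcv * c2_pg / 2,
    stringsAsFactors = FALSE)
  class(out) <- c("endopoly_profile", "data.frame")
  out
}

#' Average replicate profiles within one individual and organ
#'
#' Replicate measurements (e.g. several lateral roots of the same plant) are
#' averaged at the parameter level: EI, MCV, E4P, >=4C and meanDNA are
#' arithmetic means over replicates (E4P over the replicates where it is
#' defined), while ECmax is the maximum. Averaging indices rather than
#' pooling raw counts matches the replicate-handling convention of the study
#' design; pooled-count aggregation is available via [pool_counts].
#'
#' @param profiles a data.frame of profile rows (e.g. rbind of
#'   [endopoly_profile] outputs) for a single individual and organ.
#' @return a one-row `endopoly_profile`.
#' @export
average_individual <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  org <- unique(profiles$organ[!is.na(profiles$organ)])
  if (length(org) > 1)
    stop("profiles mix organs: ", paste(org, collapse = ", "), call. = FALSE)
  ind <- unique(profiles$individual[!is.na(profiles$individual)])
  if (length(ind) > 1)
    stop("profiles mix individuals", call. = FALSE)
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out <- profiles[1, , drop = FALSE]
  out$replicate <- NA_integer_
  out$n_nuclei <- sum(profiles$n_nuclei)
  for (col in c("EI", "MCV", "E4P", "p4c", "meanDNA"))
    out[[col]] <- avg(profiles[[col]])
  out$ECmax <- max(profiles$ECmax)
  rownames(out) <- NULL
  class(out) <- c("endopoly_profile", "data.frame")
  out
}

#' Pool ploidy counts across measurements
#'
#' Sums class counts over a list of [ploidy_counts]; by the linearity of EI,
#' MCV and >=4C, the index of the pooled counts equals the nucleus-weighted
#' mean of the per-measurement indices.
#'
#' @param counts_list list of [ploidy_counts] objects.
#' @return a single [ploidy_counts].
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  kmax <- max(vapply(counts_list, function(x) length(x$counts), integer(1)))
  acc <- numeric(kmax)
  for (x in counts_list) {
    stopifnot(inherits(x, "ploidy_counts"))
    acc[seq_along(x$counts)] <- acc[seq_along(x$counts)] + x$counts
  }
  names(acc) <- paste0(2 * 2^(0:(kmax - 1L)), "C")
  ploidy_counts(acc, meta = counts_list[[1]]$meta)
}
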