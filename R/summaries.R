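#' Endopolyploidy profiles for every row of a ploidy-count table
#'
#' @param df table in the [read_ploidy_table] dialect.
#' @param genome_sizes optional data.frame with `species` and `c2_mean`
#'   columns (e.g. [pulmonaria_genome_size] or a [genome_size_table]); used
#'   for meanDNA. Species without a genome size get `NA` meanDNA (flagged
#'   missing, never 0).
#' @return data.frame: one `endopoly_profile` row per measurement.
#' @export
profiles_from_table <- function(df, genome_sizes = NULL) {
  c2 <- function(sp) {
    if (is.null(genome_sizes)) return(NA_real_)
    i <- match(sp, genome_sizes$species)
    if (is.na(i)) NA_real_ else genome_sizes$c2_mean[i]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    endopoly_profile(row_to_counts(df[i, , drop = FALSE]),
                     c2_pg = c2(df$Species[i]))))
  rownames(out) <- NULL
  out
}

#' Average replicate profiles per individual and organ
#'
#' @param profiles data.frame of profile rows ([profiles_from_table]).
#' @return data.frame with one row per species x organ x individual.
#' @export
average_by_individual <- function(profiles) {
  key <- interaction(profiles$species, profiles$organ, profiles$individual,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(profiles, key), average_individual))
  out <- out[order(out$species, out$organ, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-proportion summary per species and organ
#'
#' Per-measurement class proportions are replicate-averaged per individual,
#' then summarised as mean and sample SD (percentage points) across
#' individuals, with the maximal endocycle number ever observed in the cell.
#'
#' @param df table in the [read_ploidy_table] dialect.
#' @return data.frame: one row per species x organ with `N`, mean and
#'   `sd_`-prefixed percent columns for `2C`..`64C`, and `ECmax`.
#' @export
summarize_class_proportions <- function(df) {
  cls <- c("2C", "4C", "8C", "16C", "32C", "64C")
  m <- as.matrix(df[, cls])
  m[is.na(m)] <- 0
  prop <- 100 * m / rowSums(m)
  key_ind <- interaction(df$Species, df$Organ, df$Plant, drop = TRUE)
  idx <- split(seq_len(nrow(df)), key_ind)
  ind <- t(vapply(idx, function(ii)
    colMeans(prop[ii, , drop = FALSE]), numeric(length(cls))))
  colnames(ind) <- cls
  ind_meta <- data.frame(
    Species = vapply(idx, function(ii) df$Species[ii[1]], ""),
    Organ = vapply(idx, function(ii) df$Organ[ii[1]], ""),
    stringsAsFactors = FALSE)
  rownames(ind) <- NULL
  cell <- interaction(ind_meta$Species, ind_meta$Organ, drop = TRUE)
  out <- do.call(rbind, lapply(levels(cell), function(lv) {
    rows <- ind[cell == lv, , drop = FALSE]
    d <- data.frame(species = ind_meta$Species[cell == lv][1],
                    organ = ind_meta$Organ[cell == lv][1],
                    N = nrow(rows), stringsAsFactors = FALSE)
    for (j in cls) d[[j]] <- mean(rows[, j])
    for (j in cls) d[[paste0("sd_", j)]] <-
      if (nrow(rows) > 1) stats::sd(rows[, j]) else NA_real_
    d$ECmax <- max(apply(rows, 1, function(r) max(which(r > 0)) - 1L))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Endopolyploidy-parameter summary per species and organ
#'
#' @param profiles replicate-averaged per-individual profiles
#'   ([average_by_individual]).
#' @return data.frame: one row per species x organ with `N` and mean /
#'   `sd_`-prefixed columns for EI, MCV, E4P, p4c and meanDNA, plus the cell
#'   `ECmax`.
#' @export
summarize_endopoly <- function(profiles) {
  cell <- interaction(profiles$species, profiles$organ, drop = TRUE)
  pars <- c("EI", "MCV", "E4P", "p4c", "meanDNA")
  out <- do.call(rbind, lapply(split(profiles, cell), function(d) {
    res <- data.frame(species = d$species[1], organ = d$organ[1],
                      N = nrow(d), stringsAsFactors = FALSE)
    for (p in pars) {
      v <- d[[p]][!is.na(d[[p]])]
      res[[p]] <- if (length(v)) mean(v) else NA_real_
      res[[paste0("sd_", p)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    res$ECmax <- max(d$ECmax)
    res
  }))
  out <- out[order(out$species, out$organ), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-group comparisons of one endopolyploidy parameter
#'
#' For each level of `within` (e.g. each organ), compares `parameter` across
#' the levels of `across` (e.g. species) with the gatekept test route and a
#' compact letter display.
#'
#' @param profiles per-individual profiles ([average_by_individual]).
#' @param parameter column to compare (e.g. `"EI"`, `"meanDNA"`).
#' @param across grouping column (default `"species"`).
#' @param within stratifying column (default `"organ"`).
#' @param alpha significance level.
#' @return named list of [compare_groups] results, one per `within` level
#'   with at least two groups of n >= 3.
#' @export
compare_by <- function(profiles, parameter = "EI", across = "species",
                       within = "organ", alpha = 0.05) {
  stopifnot(parameter %in% names(profiles))
  out <- list()
  for (lv in unique(profiles[[within]])) {
    d <- profiles[profiles[[within]] == lv & !is.na(profiles[[parameter]]), ]
    sizes <- table(d[[across]])
    sizes <- sizes[sizes >= 3]
    if (length(sizes) < 2) next
    d <- d[d[[across]] %in% names(sizes), ]
    out[[lv]] <- compare_groups(d[[parameter]], d[[across]], alpha = alpha)
  }
  out
}

#' Individuals x organs parameter matrix for ordination
#'
#' Builds the complete matrix that the centred PCA consumes: one row per
#' individual, one column per organ, values of the chosen parameter,
#' restricted to the given organs (leaves are excluded by default because
#' they could be measured only rarely) and to individuals measured in all of
#' them.
#'
#' @param profiles per-individual profiles.
#' @param parameter value column.
#' @param organs columns to include.
#' @return numeric matrix with rownames `<species>|<individual>` and an
#'   attribute `species`.
#' @export
organ_matrix <- function(profiles, parameter = "EI",
                         organs = c("root", "stem", "calyx", "corolla")) {
  d <- profiles[profiles$organ %in% organs & !is.na(profiles[[parameter]]), ]
  wide <- stats::reshape(
    d[, c("species", "individual", "organ", parameter)],
    idvar = c("species", "individual"), timevar = "organ",
    direction = "wide")
  val_cols <- paste(parameter, organs, sep = ".")
  val_cols <- val_cols[val_cols %in% names(wide)]
  complete <- stats::complete.cases(wide[, val_cols])
  wide <- wide[complete, , drop = FALSE]
  m <- as.matrix(wide[, val_cols])
  colnames(m) <- sub(paste0("^", parameter, "\\."), "", val_cols)
  rownames(m) <- paste(wide$species, wide$individual, sep = "|")
  attr(m, "species") <- wide$species
  m
}
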