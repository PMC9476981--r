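#' Read a per-nucleus event table
#'
#' The event dialect is delimiter-separated text with a header, one row per
#' nucleus: a numeric `intensity` column plus optional metadata columns
#' (`species`, `organ`, `individual`, `replicate`, constant within a file).
#' Rows with a non-numeric intensity are rejected with a warning reporting
#' how many were dropped.
#'
#' @param path file path.
#' @param intensity_col name of the intensity column.
#' @param sep field separator (default tab).
#' @return an [event_sample]; attribute `n_rejected` counts dropped rows.
#' @export
read_event_table <- function(path, intensity_col = "intensity", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!intensity_col %in% names(df))
    stop("missing intensity column '", intensity_col, "' in ", path,
         call. = FALSE)
  v <- suppressWarnings(as.numeric(df[[intensity_col]]))
  bad <- sum(is.na(v))
  if (bad > 0)
    warning(bad, " non-numeric intensity row(s) rejected in ", basename(path),
            call. = FALSE)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no usable intensity rows in ", path, call. = FALSE)
  grab <- function(col, default) if (col %in% names(df)) df[[col]][1] else default
  out <- event_sample(v,
                      species = grab("species", NA_character_),
                      organ = grab("organ", NA_character_),
                      individual = grab("individual", NA_character_),
                      replicate = grab("replicate", 1L),
                      scale_hint = grab("scale_hint", "linear"))
  attr(out, "n_rejected") <- bad
  out
}

#' Write a per-nucleus event table
#'
#' @param sample an [event_sample].
#' @param path output path (tab-separated, header).
#' @return `path`, invisibly.
#' @export
write_events <- function(sample, path) {
  stopifnot(inherits(sample, "event_sample"))
  m <- sample$meta
  df <- data.frame(intensity = sample$intensities,
                   species = m$species, organ = m$organ,
                   individual = m$individual, replicate = m$replicate,
                   scale_hint = sample$scale_hint,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PLOIDY_TABLE_COLS <- c("Species", "Locality", "Plant", "Organ", "ORG_rep",
                       "2C", "4C", "8C", "16C", "32C", "64C")

#' Read/write ploidy-count tables
#'
#' The exchange dialect for ploidy-class screens: tab-separated with columns
#' `Species`, `Locality`, `Plant`, `Organ`, `ORG_rep` and nucleus counts for
#' `2C` through `64C` (missing classes read as 0). Read and write are
#' lossless inverses.
#'
#' @param path file path.
#' @return `read_ploidy_table`: data.frame in the dialect.
#' @export
read_ploidy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("Species", "Plant", "Organ")
  if (!all(need %in% names(df)))
    stop("ploidy table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"Locality" %in% names(df)) df$Locality <- NA_character_
  if (!"ORG_rep" %in% names(df)) df$ORG_rep <- 1L
  for (cl in c("2C", "4C", "8C", "16C", "32C", "64C"))
    if (!cl %in% names(df)) df[[cl]] <- 0
  df[, PLOIDY_TABLE_COLS]
}

#' @rdname read_ploidy_table
#' @param df data.frame in the dialect.
#' @return `write_ploidy_table`: `path`, invisibly.
#' @export
write_ploidy_table <- function(df, path) {
  stopifnot(all(c("Species", "Plant", "Organ") %in% names(df)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write genome-size measurement tables
#'
#' The two-peak dialect for internal-standard genome-size runs:
#' tab-separated with columns `Species`, `Plant`, `Repetition`, and for the
#' internal standard and the sample the nucleus count, mean channel and CV:
#' `Area_std`, `Mean_std`, `CV_std`, `Area_sample`, `Mean_sample`,
#' `CV_sample`. A combined `Plant_repetition` column of the form
#' `<plant>_<rep>` is also accepted and split on read.
#'
#' @param path file path.
#' @return `read_gs_table`: data.frame with the columns above.
#' @export
read_gs_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if ("Plant_repetition" %in% names(df) && !"Plant" %in% names(df)) {
    parts <- strsplit(as.character(df$Plant_repetition), "_", fixed = TRUE)
    df$Plant <- vapply(parts, function(p)
      paste(p[-length(p)], collapse = "_"), "")
    df$Repetition <- vapply(parts, function(p)
      as.integer(p[length(p)]), integer(1))
  }
  need <- c("Species", "Plant", "Mean_std", "Mean_sample")
  if (!all(need %in% names(df)))
    stop("genome-size table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_gs_table
#' @param df data.frame with the dialect's columns.
#' @return `write_gs_table`: `path`, invisibly.
#' @export
write_gs_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a ploidy-count table row to a ploidy_counts object
#'
#' @param row one row of a table in the [read_ploidy_table] dialect.
#' @return a [ploidy_counts].
#' @export
row_to_counts <- function(row) {
  cls <- c("2C", "4C", "8C", "16C", "32C", "64C")
  cls <- cls[cls %in% names(row)]
  cnt <- as.numeric(row[1, cls])
  cnt[is.na(cnt)] <- 0
  names(cnt) <- cls
  ploidy_counts(cnt,
                meta = list(species = row$Species[1], organ = row$Organ[1],
                            individual = as.character(row$Plant[1]),
                            replicate = as.integer(row$ORG_rep[1])))
}
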