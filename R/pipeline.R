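#' Pipeline run configuration
#'
#' Collects the tunables shared by the pipeline commands. Every command
#' writes the resolved configuration next to its outputs, so a run is fully
#' described by its output directory.
#'
#' @param out_dir output directory (created if needed).
#' @param standard_2c_pg 2C DNA amount of the internal standard (pg).
#' @param n_bins,smoothing_window,min_prominence_fraction,tolerance_fraction
#'   gating parameters, see [fit_ploidy].
#' @param min_nuclei_gs,min_nuclei_endo,max_cv_percent QC thresholds.
#' @param alpha significance level for the comparison layer.
#' @param seed integer seed for the simulation command.
#' @return a `run_config` list.
#' @export
endo_config <- function(out_dir = ".", standard_2c_pg = 1.96, n_bins = 512,
                        smoothing_window = 9, min_prominence_fraction = 0.02,
                        tolerance_fraction = 0.10, min_nuclei_gs = 5000,
                        min_nuclei_endo = 3000, max_cv_percent = 5,
                        alpha = 0.05, seed = 1) {
  stopifnot(min_nuclei_gs > 0, min_nuclei_endo > 0, max_cv_percent > 0)
  structure(list(out_dir = out_dir, standard_2c_pg = standard_2c_pg,
                 n_bins = n_bins, smoothing_window = smoothing_window,
                 min_prominence_fraction = min_prominence_fraction,
                 tolerance_fraction = tolerance_fraction,
                 min_nuclei_gs = min_nuclei_gs,
                 min_nuclei_endo = min_nuclei_endo,
                 max_cv_percent = max_cv_percent, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_config <- function(config, name) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir, paste0(name, ".config.txt"))
  writeLines(paste0(names(config), "=",
                    vapply(config, function(v) paste(format(v), collapse = ","),
                           "")), path)
  invisible(path)
}

.log_line <- function(config, name, ...) {
  msg <- sprintf(...)
  message("[", name, "] ", msg)
  cat(format(Sys.time(), "%H:%M:%S"), msg, "\n",
      file = file.path(config$out_dir, paste0(name, ".log")), append = TRUE)
}

#' Pipeline command: simulate a fixture study
#'
#' Writes a ploidy-count table (and optionally event files) for a seeded
#' synthetic study into `config$out_dir`.
#'
#' @param config a [endo_config].
#' @param design a [study_design]; defaults to a small study (5 individuals
#'   per cell) at the config's seed.
#' @param events whether to also write per-measurement event files.
#' @return path of the written ploidy-count table, invisibly; the table has
#'   attribute `truth`.
#' @export
run_simulate <- function(config = endo_config(),
                         design = study_design(individuals = 5,
                                               seed = config$seed),
                         events = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_config(config, "simulate")
  events_dir <- if (events) {
    d <- file.path(config$out_dir, "events")
    dir.create(d, showWarnings = FALSE)
    d
  } else NULL
  tab <- simulate_study(design, events_dir = events_dir)
  path <- file.path(config$out_dir, "ploidy_counts.tsv")
  write_ploidy_table(tab, path)
  .log_line(config, "simulate", "wrote %d measurements to %s",
            nrow(tab), path)
  invisible(path)
}

#' Pipeline command: gate a directory of event tables
#'
#' Fits the doubling-series model to every event file, applies
#' endopolyploidy QC, and writes one ploidy-count row per passing
#' measurement. QC failures are listed in the log and excluded from the
#' table with a recorded reason -- never silently dropped.
#'
#' @param events_dir directory of event tables ([write_events] dialect).
#' @param config a [endo_config].
#' @return list with `table_path`, `n_ok`, `excluded` (data.frame of file /
#'   reason), invisibly.
#' @export
run_gate <- function(events_dir, config = endo_config()) {
  files <- list.files(events_dir, pattern = "\\.(tsv|txt|csv)$",
                      full.names = TRUE)
  if (!length(files)) stop("no event files in ", events_dir, call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_config(config, "gate")
  rows <- list()
  excluded <- list()
  for (f in files) {
    res <- tryCatch({
      s <- read_event_table(f)
      fit <- fit_ploidy(s, n_bins = config$n_bins,
                        smoothing_window = config$smoothing_window,
                        min_prominence_fraction = config$min_prominence_fraction,
                        tolerance_fraction = config$tolerance_fraction)
      qc <- qc_check(fit, mode = "endopolyploidy",
                     min_nuclei = config$min_nuclei_endo,
                     max_cv = config$max_cv_percent)
      list(fit = fit, qc = qc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[f]] <- conditionMessage(res)
      .log_line(config, "gate", "ERROR %s: %s", basename(f),
                conditionMessage(res))
      next
    }
    if (!res$qc$pass) {
      excluded[[f]] <- paste(res$qc$violations, collapse = "; ")
      .log_line(config, "gate", "QC-FAIL %s: %s", basename(f), excluded[[f]])
      next
    }
    cnt <- res$fit$counts
    m <- cnt$meta
    row <- data.frame(Species = m$species, Locality = NA_character_,
                      Plant = m$individual, Organ = m$organ,
                      ORG_rep = m$replicate, stringsAsFactors = FALSE)
    for (cl in c("2C", "4C", "8C", "16C", "32C", "64C"))
      row[[cl]] <- if (cl %in% names(cnt$counts)) cnt$counts[[cl]] else 0
    rows[[f]] <- row
  }
  if (!length(rows))
    stop("every event file failed gating or QC", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  path <- file.path(config$out_dir, "gated_counts.tsv")
  write_ploidy_table(tab, path)
  excl <- if (length(excluded)) {
    data.frame(file = basename(names(excluded)),
               reason = unlist(excluded, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(file = character(0), reason = character(0))
  }
  .log_line(config, "gate", "%d/%d files gated, %d excluded",
            nrow(tab), length(files), nrow(excl))
  invisible(list(table_path = path, n_ok = nrow(tab), excluded = excl))
}

#' Pipeline command: genome-size report from a measurement table
#'
#' @param gs_path path of a genome-size measurement table
#'   ([read_gs_table] dialect).
#' @param config a [endo_config].
#' @return the [genome_size_table], invisibly; also written as
#'   `genome_size.tsv` in the output directory.
#' @export
run_genomesize <- function(gs_path, config = endo_config()) {
  gs <- read_gs_table(gs_path)
  if (any(gs$Mean_std <= 0) || any(gs$Mean_sample <= 0))
    stop("non-positive peak mean channel in ", gs_path, call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_config(config, "genomesize")
  tab <- genome_size_table(gs, standard_2c_pg = config$standard_2c_pg)
  utils::write.table(as.data.frame(tab),
                     file.path(config$out_dir, "genome_size.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(config, "genomesize",
            "%d runs -> %d plants -> %d species (span %.1f%%)",
            nrow(gs), nrow(attr(tab, "plants")), nrow(tab),
            attr(tab, "span"))
  invisible(tab)
}

#' Pipeline command: endopolyploidy reports and comparisons
#'
#' From a ploidy-count table and species genome sizes, produces the
#' class-proportion summary, the parameter summary, the per-organ
#' between-species comparisons (with letter soundness implied by
#' construction) and the centred PCAs of EI and meanDNA.
#'
#' @param counts_path ploidy-count table path ([read_ploidy_table] dialect).
#' @param genome_sizes data.frame with `species`, `c2_mean` (e.g.
#'   [pulmonaria_genome_size] or a [genome_size_table]).
#' @param config a [endo_config].
#' @return list with `profiles`, `class_summary`, `param_summary`,
#'   `comparisons` (per parameter, per organ), `pca` (per parameter),
#'   invisibly; summaries are written as TSV to the output directory.
#' @export
run_endopoly <- function(counts_path, genome_sizes = pulmonaria_genome_size(),
                         config = endo_config()) {
  tab <- read_ploidy_table(counts_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_config(config, "endopoly")
  prof <- profiles_from_table(tab, genome_sizes)
  prof_ind <- average_by_individual(prof)
  class_summary <- summarize_class_proportions(tab)
  param_summary <- summarize_endopoly(prof_ind)
  utils::write.table(class_summary,
                     file.path(config$out_dir, "class_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(param_summary,
                     file.path(config$out_dir, "endopoly_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparisons <- list()
  for (p in c("EI", "meanDNA")) {
    if (all(is.na(prof_ind[[p]]))) {
      .log_line(config, "endopoly", "parameter %s all missing; skipped", p)
      next
    }
    comparisons[[p]] <- compare_by(prof_ind, parameter = p,
                                   alpha = config$alpha)
  }
  pca <- list()
  for (p in c("EI", "meanDNA")) {
    m <- try(organ_matrix(prof_ind, parameter = p), silent = TRUE)
    if (!inherits(m, "try-error") && nrow(m) >= 3)
      pca[[p]] <- pca_centered(m)
  }
  .log_line(config, "endopoly",
            "%d measurements -> %d individuals -> %d cells",
            nrow(tab), nrow(prof_ind), nrow(param_summary))
  invisible(list(profiles = prof_ind, class_summary = class_summary,
                 param_summary = param_summary, comparisons = comparisons,
                 pca = pca))
}
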