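#' Estimate the 2C DNA amount against an internal reference standard
#'
#' The sample's DNA amount is the standard's DNA amount multiplied by the
#' ratio of the sample and standard G0/G1 peak means, the canonical
#' internal-standard formula of plant flow cytometry. The default standard is
#' the tomato *Solanum lycopersicum* 'Stupicke polni tyckove rane'
#' (2C = 1.96 pg); any other standard can be configured.
#'
#' @param sample_peak_mean,standard_peak_mean G0/G1 peak mean channel values
#'   (vectorised); alternatively `sample_peak_mean` may be a pre-computed
#'   sample/standard ratio with `standard_peak_mean = 1`.
#' @param standard_2c_pg 2C DNA amount of the internal standard in pg.
#' @return 2C DNA amount(s) of the sample in pg.
#' @export
estimate_2c <- function(sample_peak_mean, standard_peak_mean = 1,
                        standard_2c_pg = 1.96) {
  if (any(sample_peak_mean <= 0) || any(standard_peak_mean <= 0))
    stop("peak means must be positive", call. = FALSE)
  if (any(standard_2c_pg <= 0))
    stop("standard 2C amount must be positive", call. = FALSE)
  standard_2c_pg * sample_peak_mean / standard_peak_mean
}

#' Convert picograms of DNA to megabase pairs
#'
#' Uses the standard equivalence 1 pg DNA = 978 Mbp.
#'
#' @param pg DNA amount(s) in picograms (>= 0).
#' @param digits optional rounding (use `0` for integer-Mbp table output).
#' @return DNA amount(s) in Mbp.
#' @export
pg_to_mbp <- function(pg, digits = NULL) {
  if (any(pg < 0)) stop("pg must be non-negative", call. = FALSE)
  out <- 978 * pg
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Mean DNA content per chromosome
#'
#' @param c2_pg 2C DNA amount (pg).
#' @param n2 somatic chromosome number (2n), e.g. 14, 16 or 18 for the
#'   diploid *Pulmonaria* species (an aneuploid 2n = 15 is equally valid).
#' @return pg of DNA per chromosome, `c2_pg / n2`.
#' @export
per_chromosome <- function(c2_pg, n2) {
  if (any(n2 < 1)) stop("2n must be >= 1", call. = FALSE)
  c2_pg / n2
}

#' Aggregate repeated genome-size measurements of one plant
#'
#' Each plant is conventionally measured three times on different days; the
#' plant's 2C value is the mean, and a stability flag is raised when the
#' between-day spread (range/mean) reaches 1.5 percent.
#'
#' @param c2_values per-measurement 2C estimates (pg), length >= 1.
#' @param max_spread_percent stability threshold (default 1.5).
#' @return list with `c2_pg` (mean), `spread_percent` (100 * range/mean),
#'   `stable` (logical), `n`.
#' @export
aggregate_plant <- function(c2_values, max_spread_percent = 1.5) {
  stopifnot(length(c2_values) >= 1, all(c2_values > 0))
  m <- mean(c2_values)
  spread <- 100 * (max(c2_values) - min(c2_values)) / m
  list(c2_pg = m, spread_percent = spread,
       stable = spread < max_spread_percent, n = length(c2_values))
}

#' Species-level genome-size summary
#'
#' @param plant_means per-plant 2C means (pg).
#' @param species species label for each plant mean.
#' @return data.frame with one row per species: `n_plants`, `c2_mean`,
#'   `c2_sd` (sample SD), `c2_min`, `c2_max`.
#' @export
species_summary <- function(plant_means, species) {
  stopifnot(length(plant_means) == length(species), all(plant_means > 0))
  sp <- split(plant_means, species)
  out <- data.frame(
    species = names(sp),
    n_plants = vapply(sp, length, integer(1)),
    c2_mean = vapply(sp, mean, numeric(1)),
    c2_sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                   numeric(1)),
    c2_min = vapply(sp, min, numeric(1)),
    c2_max = vapply(sp, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Genome-size span across species
#'
#' Percent difference between the largest and smallest species mean, with the
#' smallest mean as the 100 percent reference:
#' `100 * (max - min) / min`.
#'
#' @param species_means vector of species-level mean 2C values (pg).
#' @return span in percent (0 for a single species).
#' @export
genome_size_span <- function(species_means) {
  stopifnot(length(species_means) >= 1, all(species_means > 0))
  100 * (max(species_means) - min(species_means)) / min(species_means)
}

#' Build a genome-size report table from raw peak measurements
#'
#' Consumes a measurement table in the two-peak dialect (see
#' [read_gs_table]): one row per flow-cytometric run with standard and sample
#' G0/G1 peak mean channels, CVs and nucleus counts. Applies the
#' internal-standard formula per run, averages runs per plant with the
#' between-day stability flag, then summarises per species including the
#' sample/standard ratio, 1C amounts in pg and Mbp, and pg per chromosome.
#'
#' @param gs data.frame with columns `Species`, `Plant`, `Mean_std`,
#'   `Mean_sample` (and optionally `CV_std`, `CV_sample`, `Area_std`,
#'   `Area_sample` for QC).
#' @param karyotype optional data.frame with columns `species`, `n2` used for
#'   the per-chromosome column; defaults to [pulmonaria_karyotype].
#' @param standard_2c_pg 2C DNA amount of the internal standard (pg).
#' @return data.frame of class `genome_size_table`: one row per species with
#'   `n_plants`, `c2_mean`, `c2_sd`, `c2_min`, `c2_max`, `ratio_mean`,
#'   `ratio_sd`, `c1_pg`, `c1_mbp`, `pg_per_chromosome`, plus attribute
#'   `plants` (the per-plant aggregation with stability flags) and `span`.
#' @export
genome_size_table <- function(gs, karyotype = pulmonaria_karyotype(),
                              standard_2c_pg = 1.96) {
  need <- c("Species", "Plant", "Mean_std", "Mean_sample")
  if (!all(need %in% names(gs)))
    stop("genome-size table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  gs$c2 <- estimate_2c(gs$Mean_sample, gs$Mean_std, standard_2c_pg)
  gs$ratio <- gs$Mean_sample / gs$Mean_std
  key <- interaction(gs$Species, gs$Plant, drop = TRUE)
  plants <- do.call(rbind, lapply(split(gs, key), function(d) {
    agg <- aggregate_plant(d$c2)
    data.frame(species = d$Species[1], plant = d$Plant[1],
               c2_pg = agg$c2_pg, ratio = mean(d$ratio),
               spread_percent = agg$spread_percent, stable = agg$stable,
               n_runs = agg$n, stringsAsFactors = FALSE)
  }))
  rownames(plants) <- NULL
  out <- species_summary(plants$c2_pg, plants$species)
  rsp <- split(plants$ratio, plants$species)
  out$ratio_mean <- vapply(rsp, mean, numeric(1))[out$species]
  out$ratio_sd <- vapply(rsp, function(v)
    if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1))[out$species]
  out$c1_pg <- out$c2_mean / 2
  out$c1_mbp <- pg_to_mbp(out$c1_pg)
  n2 <- karyotype$n2[match(out$species, karyotype$species)]
  out$pg_per_chromosome <- ifelse(is.na(n2), NA_real_,
                                  per_chromosome(out$c2_mean, n2))
  attr(out, "plants") <- plants
  attr(out, "span") <- genome_size_span(out$c2_mean)
  class(out) <- c("genome_size_table", "data.frame")
  out
}

#' Estimate genome size directly from a two-population event sample
#'
#' Fits the histogram of a co-chopped sample + internal-standard measurement,
#' takes the two most prominent peaks, and applies the internal-standard
#' formula with the lower peak as the standard (`standard_is_lower = TRUE`,
#' the usual case for *Pulmonaria* vs tomato) or the upper one otherwise.
#'
#' @param x an [event_sample] or numeric intensities.
#' @param standard_2c_pg 2C amount of the standard (pg).
#' @param standard_is_lower is the standard the lower-intensity peak?
#' @param ... passed to [build_histogram]/[detect_peaks] via their defaults.
#' @return list with `ratio`, `c2_pg`, `peaks` (the detected `peak_set`) and
#'   `qc` (a [qc_check] report in genome-size mode).
#' @export
estimate_gs_from_events <- function(x, standard_2c_pg = 1.96,
                                    standard_is_lower = TRUE, ...) {
  v <- .as_intensities(x)
  h <- build_histogram(v, ...)
  pk <- detect_peaks(h)
  if (nrow(pk) < 2)
    stop("need both a standard and a sample peak; found ", nrow(pk),
         call. = FALSE)
  top2 <- pk[order(-pk$height)[1:2], , drop = FALSE]
  top2 <- top2[order(top2$position), , drop = FALSE]
  std <- if (standard_is_lower) top2$position[1] else top2$position[2]
  smp <- if (standard_is_lower) top2$position[2] else top2$position[1]
  top2$c_level <- c(2, 2)  # both are G0/G1 peaks of their species
  qc <- qc_check(length(v), mode = "genome_size", peaks = top2)
  list(ratio = smp / std, c2_pg = estimate_2c(smp, std, standard_2c_pg),
       peaks = pk, qc = qc)
}
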