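#' Template for one species x organ cell of the study design
#'
#' Holds everything the generator needs to emulate measurements of one organ:
#' mean ploidy-class proportions (any published species x organ row works),
#' a Dirichlet concentration controlling between-individual spread, the
#' expected 2C peak position, the peak CV and the debris fraction.
#'
#' @param species,organ labels.
#' @param proportions non-negative class proportions over 2C, 4C, ...
#'   (percentages accepted; normalised to sum to 1).
#' @param concentration Dirichlet concentration; the default 60 reproduces
#'   published between-individual SDs of a few percentage points.
#' @param anchor_position expected 2C peak channel (default 200; gating is
#'   scale-invariant so the value is cosmetic).
#' @param cv_percent fluorescence peak CV in percent, in (0, 10].
#' @param debris_fraction expected fraction of sub-2C debris events.
#' @return object of class `organ_template`.
#' @export
organ_template <- function(species, organ, proportions, concentration = 60,
                           anchor_position = 200, cv_percent = 3,
                           debris_fraction = 0.02) {
  proportions[is.na(proportions)] <- 0
  if (any(proportions < 0)) stop("proportions must be >= 0", call. = FALSE)
  if (sum(proportions) <= 0) stop("proportions sum to zero", call. = FALSE)
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  if (cv_percent <= 0 || cv_percent > 10)
    stop("cv_percent must be in (0, 10]", call. = FALSE)
  structure(list(species = species, organ = organ,
                 proportions = proportions / sum(proportions),
                 concentration = concentration,
                 anchor_position = anchor_position,
                 cv_percent = cv_percent,
                 debris_fraction = debris_fraction),
            class = "organ_template")
}

#' Draw per-individual class proportions from a template
#'
#' A Dirichlet draw centred on the template means with spread set by the
#' concentration (gamma-ratio construction); classes with zero template mean
#' stay exactly zero in every draw. As concentration grows, draws converge
#' to the template means.
#'
#' @param template an [organ_template].
#' @return proportion vector summing to 1, same length as the template.
#' @export
draw_individual_proportions <- function(template) {
  p <- template$proportions
  out <- numeric(length(p))
  nz <- p > 0
  g <- stats::rgamma(sum(nz), shape = template$concentration * p[nz], rate = 1)
  if (all(g == 0)) g[which.max(p[nz])] <- 1  # guard against underflow
  out[nz] <- g / sum(g)
  out
}

#' Simulate per-nucleus fluorescence events
#'
#' Class counts are multinomial in the given proportions; each nucleus of
#' class k gets a Gaussian intensity around `anchor_position * 2^k` with SD
#' equal to `cv_percent` of the peak position (instrument CVs are quoted on
#' the linear scale). Debris events are drawn from a decaying exponential
#' strictly below the 2C gate boundary. Event order is shuffled.
#'
#' @param proportions class proportions over 2C, 4C, ... (normalised
#'   internally).
#' @param anchor_position 2C peak channel position.
#' @param cv_percent peak coefficient of variation, percent.
#' @param debris_fraction expected fraction of events that are debris.
#' @param n total number of events (>= 1).
#' @param meta optional metadata list passed to [event_sample].
#' @return an [event_sample]; attribute `truth` holds the drawn class and
#'   debris counts.
#' @export
simulate_events <- function(proportions, anchor_position = 200,
                            cv_percent = 3, debris_fraction = 0, n = 5000,
                            meta = list()) {
  stopifnot(n >= 1)
  proportions[is.na(proportions)] <- 0
  p <- proportions / sum(proportions)
  n_debris <- stats::rbinom(1, n, debris_fraction)
  n_real <- n - n_debris
  counts <- if (n_real > 0) as.integer(stats::rmultinom(1, n_real, p))
            else integer(length(p))
  pos <- anchor_position * 2^(seq_along(p) - 1L)
  sdv <- cv_percent / 100 * pos
  xs <- unlist(lapply(seq_along(p), function(k) {
    if (counts[k] == 0) return(numeric(0))
    v <- stats::rnorm(counts[k], pos[k], sdv[k])
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), pos[k], sdv[k])
    v
  }))
  if (n_debris > 0) {
    hi <- anchor_position * 2^(-0.5)   # keep debris strictly below the 2C gate
    tau <- anchor_position / 5
    u <- stats::runif(n_debris)
    lo <- hi / 50
    # inverse CDF of an exponential truncated to (lo, hi)
    d <- -tau * log(exp(-lo / tau) - u * (exp(-lo / tau) - exp(-hi / tau)))
    xs <- c(xs, d)
  }
  xs <- xs[sample.int(length(xs))]
  out <- do.call(event_sample, c(list(intensities = xs, scale_hint = "log"),
                                 meta))
  attr(out, "truth") <- list(class_counts = counts, n_debris = n_debris)
  out
}

#' Simulate a genome-size measurement with an internal standard
#'
#' Draws a two-population sample: the internal standard's G0/G1 peak at
#' `standard_position` and the sample's G0/G1 peak at `true_ratio` times
#' that. A warning is issued when the true ratio sits within 5 percent of a
#' power of two of the standard, where the sample peak would collide with
#' the standard peak (or its doubling).
#'
#' @param true_ratio sample/standard peak ratio (> 0).
#' @param standard_position standard peak channel.
#' @param cvs length-2 peak CVs in percent (standard, sample).
#' @param n total nuclei.
#' @param prop_standard fraction of events belonging to the standard.
#' @param meta metadata list.
#' @return an [event_sample] with attribute `truth` (the ratio).
#' @export
simulate_gs_sample <- function(true_ratio, standard_position = 200,
                               cvs = c(3, 3), n = 5000, prop_standard = 0.5,
                               meta = list()) {
  stopifnot(true_ratio > 0, n >= 2)
  k <- log2(true_ratio)
  if (abs(k - round(k)) < log2(1.05))
    warning("sample peak within 5% of a doubling of the standard; ",
            "peaks may overlap", call. = FALSE)
  n_std <- stats::rbinom(1, n, prop_standard)
  n_smp <- n - n_std
  draw <- function(m, mu, cv) {
    if (m == 0) return(numeric(0))
    v <- stats::rnorm(m, mu, cv / 100 * mu)
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, cv / 100 * mu)
    v
  }
  xs <- c(draw(n_std, standard_position, cvs[1]),
          draw(n_smp, standard_position * true_ratio, cvs[2]))
  xs <- xs[sample.int(length(xs))]
  out <- do.call(event_sample, c(list(intensities = xs,
                                      scale_hint = "linear"), meta))
  attr(out, "truth") <- list(ratio = true_ratio, n_standard = n_std)
  out
}

#' Define a synthetic study design
#'
#' @param templates list of [organ_template]s (default: every published
#'   species x organ mean-proportion row, see
#'   [pulmonaria_class_proportions]).
#' @param individuals individuals per species x organ cell (default 20, as
#'   in the emulated study; the packaged test fixture uses 5).
#' @param replicates_root maximal replicate count for roots (one replicate
#'   count per root individual is drawn uniformly from 1..replicates_root;
#'   other organs get one measurement).
#' @param n_nuclei nuclei per measurement (>= 3000 passes endopolyploidy QC).
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return object of class `study_design`.
#' @export
study_design <- function(templates = default_templates(), individuals = 20,
                         replicates_root = 3, n_nuclei = 3000, seed = 1) {
  stopifnot(individuals >= 1, replicates_root >= 1, n_nuclei >= 1)
  structure(list(templates = templates, individuals = individuals,
                 replicates_root = replicates_root, n_nuclei = n_nuclei,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @rdname study_design
#' @param concentration,cv_percent,debris_fraction passed to every
#'   [organ_template].
#' @export
default_templates <- function(concentration = 60, cv_percent = 3,
                              debris_fraction = 0.02) {
  tab <- pulmonaria_class_proportions()
  lapply(seq_len(nrow(tab)), function(i)
    organ_template(tab$species[i], tab$organ[i],
                   proportions = as.numeric(tab[i, c("2C", "4C", "8C",
                                                     "16C", "32C", "64C")]),
                   concentration = concentration, cv_percent = cv_percent,
                   debris_fraction = debris_fraction))
}

#' Simulate a whole endopolyploidy study
#'
#' For every template cell, draws per-individual class proportions
#' (Dirichlet), then per-measurement nucleus counts (multinomial at
#' `n_nuclei`); root individuals get 1..`replicates_root` replicate
#' measurements. The result is a ploidy-count table in the standard exchange
#' dialect (`Species`, `Locality`, `Plant`, `Organ`, `ORG_rep`, `2C`..`64C`).
#' Optionally writes one event-table file per measurement.
#'
#' @param design a [study_design].
#' @param events_dir optional directory; when given, per-measurement event
#'   files are written there via [write_events] (slower).
#' @return data.frame in the ploidy-count dialect; attribute `truth` holds
#'   the per-individual true proportions.
#' @export
simulate_study <- function(design, events_dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  cls <- c("2C", "4C", "8C", "16C", "32C", "64C")
  rows <- list()
  truth <- list()
  for (tpl in design$templates) {
    for (ind in seq_len(design$individuals)) {
      p <- draw_individual_proportions(tpl)
      # plant ids are shared across organs of one individual, so the
      # ordination layer can assemble complete individuals x organs matrices
      ind_id <- sprintf("%s_%02d", gsub("[ .]+", "", tpl$species), ind)
      truth[[paste(ind_id, tpl$organ, sep = "|")]] <- p
      n_rep <- if (tpl$organ == "root" && design$replicates_root > 1)
        sample.int(design$replicates_root, 1) else 1L
      for (rep_i in seq_len(n_rep)) {
        cnt <- as.integer(stats::rmultinom(1, design$n_nuclei, p))
        row <- data.frame(Species = tpl$species, Locality = "SYN",
                          Plant = ind_id, Organ = tpl$organ,
                          ORG_rep = rep_i, stringsAsFactors = FALSE)
        for (j in seq_along(cls))
          row[[cls[j]]] <- if (j <= length(cnt)) cnt[j] else 0L
        rows[[length(rows) + 1L]] <- row
        if (!is.null(events_dir)) {
          s <- simulate_events(p, anchor_position = tpl$anchor_position,
                               cv_percent = tpl$cv_percent,
                               debris_fraction = tpl$debris_fraction,
                               n = design$n_nuclei,
                               meta = list(species = tpl$species,
                                           organ = tpl$organ,
                                           individual = ind_id,
                                           replicate = rep_i))
          write_events(s, file.path(events_dir,
                                    sprintf("%s_%s_rep%d.tsv", ind_id,
                                            tpl$organ, rep_i)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
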