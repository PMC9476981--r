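#' Organs recognised by the study design
#'
#' @keywords internal
ORGAN_LEVELS <- c("root", "stem", "leaf", "calyx", "corolla")

#' Construct a per-nucleus event sample
#'
#' An `event_sample` holds the relative fluorescence intensity of every nucleus
#' recorded in one flow-cytometric measurement, together with the sample
#' metadata (species, organ, individual, replicate). Intensities are in
#' arbitrary channel units; all downstream gating is scale-invariant.
#'
#' @param intensities numeric vector of positive fluorescence intensities.
#' @param species,organ,individual character labels (organ must be one of
#'   root, stem, leaf, calyx, corolla when given).
#' @param replicate integer replicate index within individual and organ.
#' @param scale_hint `"linear"` or `"log"` -- how the instrument displayed the
#'   histogram; endopolyploidy screens are conventionally logarithmic,
#'   genome-size runs linear. Informational only.
#' @return an object of class `event_sample`.
#' @export
event_sample <- function(intensities, species = NA_character_,
                         organ = NA_character_, individual = NA_character_,
                         replicate = 1L, scale_hint = c("linear", "log")) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1L)
    stop("event_sample requires at least one event", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("all intensities must be positive and finite", call. = FALSE)
  scale_hint <- match.arg(scale_hint)
  if (!is.na(organ)) organ <- match.arg(organ, ORGAN_LEVELS)
  structure(
    list(intensities = intensities,
         meta = list(species = species, organ = organ,
                     individual = individual, replicate = as.integer(replicate)),
         scale_hint = scale_hint),
    class = "event_sample")
}

#' @export
print.event_sample <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Event sample: %d nuclei", length(x$intensities)))
  lab <- c(m$species, m$organ, m$individual)
  lab <- lab[!is.na(lab)]
  if (length(lab)) cat(" [", paste(lab, collapse = " / "), "]", sep = "")
  cat(sprintf("\n  intensity range %.1f-%.1f (%s scale hint)\n",
              min(x$intensities), max(x$intensities), x$scale_hint))
  invisible(x)
}

#' @export
length.event_sample <- function(x) length(x$intensities)

.as_intensities <- function(x) {
  if (inherits(x, "event_sample")) x$intensities else as.numeric(x)
}
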