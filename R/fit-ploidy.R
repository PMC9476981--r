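#' Fit the doubling-series ploidy model to a fluorescence sample
#'
#' `fit_ploidy()` is the package's central estimator. It bins the per-nucleus
#' fluorescence intensities ([build_histogram]), locates fluorescence peaks
#' ([detect_peaks]), anchors the lowest consistent peak as 2C and assigns the
#' doubling series 2C, 4C, 8C, ... ([assign_doubling_series]), and gates every
#' event into a ploidy class ([gate_events]). The fit is fully deterministic:
#' all randomness in this package lives in the synthetic-data generator.
#'
#' @param x an [event_sample] or numeric vector of positive intensities.
#' @param n_bins,scale,floor passed to [build_histogram].
#' @param smoothing_window,min_prominence_fraction passed to [detect_peaks].
#' @param tolerance_fraction passed to [assign_doubling_series].
#' @return an object of class `ploidy_fit` with components `counts`
#'   (a [ploidy_counts]), `peaks` (a `peak_set`), `histogram`, `gates`
#'   (boundary positions), `n_events`, `meta` and `params`.
#'
#' @examples
#' set.seed(1)
#' s <- simulate_events(c(0.6, 0.3, 0.1), n = 5000)
#' fit <- fit_ploidy(s)
#' fit
#' coef(fit)
#' summary(fit)
#' @export
fit_ploidy <- function(x, n_bins = 512, scale = "log",
                       smoothing_window = 9, min_prominence_fraction = 0.02,
                       tolerance_fraction = 0.10, floor = NULL) {
  v <- .as_intensities(x)
  h <- build_histogram(v, n_bins = n_bins, scale = scale, floor = floor)
  pk <- detect_peaks(h, min_prominence_fraction = min_prominence_fraction,
                     smoothing_window = smoothing_window)
  pk <- assign_doubling_series(pk, tolerance_fraction = tolerance_fraction)
  counts <- gate_events(x, pk)
  assigned <- pk[!is.na(pk$c_level), , drop = FALSE]
  structure(
    list(counts = counts, peaks = pk, histogram = h,
         gates = .gate_boundaries(assigned$position),
         n_events = length(v),
         meta = if (inherits(x, "event_sample")) x$meta else list(),
         params = list(n_bins = n_bins, scale = scale,
                       smoothing_window = smoothing_window,
                       min_prominence_fraction = min_prominence_fraction,
                       tolerance_fraction = tolerance_fraction, floor = floor),
         call = match.call()),
    class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat("Ploidy doubling-series fit\n")
  print(x$peaks)
  prop <- 100 * x$counts$counts / x$counts$total
  cat("Gated classes: ",
      paste(sprintf("%s %.1f%%", names(prop), prop), collapse = ", "),
      sprintf("\n%d of %d events gated (%d debris below, %d above)\n",
              round(x$counts$total), x$n_events,
              x$counts$debris_low, x$counts$debris_high))
  invisible(x)
}

#' @describeIn fit_ploidy peak positions (channel units), named by C-level.
#' @param object,... method arguments.
#' @export
coef.ploidy_fit <- function(object, ...) {
  pk <- object$peaks
  nm <- ifelse(is.na(pk$c_level), "unassigned",
               paste0(format(pk$c_level, trim = TRUE), "C"))
  stats::setNames(pk$position, nm)
}

#' @describeIn fit_ploidy QC report plus the endopolyploidy profile of the
#'   gated counts.
#' @param mode QC mode for the embedded [qc_check].
#' @export
summary.ploidy_fit <- function(object, mode = "endopolyploidy", ...) {
  structure(list(fit = object,
                 qc = qc_check(object, mode = mode),
                 profile = endopoly_profile(object$counts)),
            class = "summary.ploidy_fit")
}

#' @export
print.summary.ploidy_fit <- function(x, ...) {
  print(x$fit)
  print(x$qc)
  cat("Endopolyploidy profile:\n")
  print(x$profile, ...)
  invisible(x)
}

#' @describeIn fit_ploidy classify intensities into the fitted gates; returns
#'   a factor with the class labels plus `"debris"`.
#' @param newdata numeric intensities or an [event_sample]; defaults to the
#'   training events' gate assignment summary.
#' @export
predict.ploidy_fit <- function(object, newdata = NULL, ...) {
  assigned <- object$peaks[!is.na(object$peaks$c_level), , drop = FALSE]
  labels <- paste0(format(assigned$c_level, trim = TRUE), "C")
  if (is.null(newdata)) {
    stop("supply newdata intensities to classify", call. = FALSE)
  }
  v <- .as_intensities(newdata)
  idx <- findInterval(v, object$gates)
  out <- ifelse(idx >= 1L & idx <= nrow(assigned), labels[pmax(idx, 1L)],
                "debris")
  factor(out, levels = c(labels, "debris"))
}

# expected bin counts under the fitted Gaussian-per-peak model
.fitted_bins <- function(object) {
  h <- object$histogram
  assigned <- object$peaks[!is.na(object$peaks$c_level), , drop = FALSE]
  expected <- numeric(length(h$counts))
  lower <- h$bin_edges[-length(h$bin_edges)]
  upper <- h$bin_edges[-1]
  for (j in seq_len(nrow(assigned))) {
    mu <- assigned$position[j]
    sdv <- assigned$cv_percent[j] / 100 * mu
    mass <- object$counts$counts[j]
    if (sdv <= 0) next
    expected <- expected +
      mass * (stats::pnorm(upper, mu, sdv) - stats::pnorm(lower, mu, sdv))
  }
  expected
}

#' @describeIn fit_ploidy expected histogram bin counts under the fitted
#'   Gaussian-peak mixture.
#' @export
fitted.ploidy_fit <- function(object, ...) .fitted_bins(object)

#' @describeIn fit_ploidy observed minus fitted bin counts.
#' @export
residuals.ploidy_fit <- function(object, ...) {
  object$histogram$counts - .fitted_bins(object)
}

#' @describeIn fit_ploidy draw new event samples from the fitted class
#'   proportions, anchor position and mean peak CV.
#' @param nsim number of samples to draw.
#' @param seed optional seed, handled as in [stats::simulate].
#' @export
simulate.ploidy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  assigned <- object$peaks[!is.na(object$peaks$c_level), , drop = FALSE]
  prop <- object$counts$counts / object$counts$total
  # proportions are stored over the full 2C..max series; keep as-is
  anchor <- assigned$position[which.min(assigned$c_level)]
  cv <- mean(assigned$cv_percent)
  n <- round(object$counts$total)
  out <- lapply(seq_len(nsim), function(i)
    simulate_events(prop, anchor_position = anchor, cv_percent = cv, n = n))
  if (nsim == 1) out[[1]] else out
}

#' @describeIn fit_ploidy histogram with detected peaks and gate boundaries.
#' @param x a `ploidy_fit`.
#' @export
plot.ploidy_fit <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$mids, h$counts, type = "h", log = if (h$scale == "log") "x" else "",
                 xlab = "fluorescence intensity (channel units)",
                 ylab = "nuclei", main = "DNA-content histogram", ...)
  assigned <- x$peaks[!is.na(x$peaks$c_level), , drop = FALSE]
  graphics::abline(v = x$gates, lty = 3, col = "grey50")
  graphics::points(assigned$position,
                   rep(max(h$counts), nrow(assigned)) * 1.0,
                   pch = 25, bg = "red")
  graphics::text(assigned$position, max(h$counts),
                 paste0(format(assigned$c_level, trim = TRUE), "C"),
                 pos = 3, xpd = NA)
  invisible(x)
}
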