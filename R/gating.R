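#' Bin fluorescence events into a DNA-content histogram
#'
#' Endopolyploidy histograms are conventionally binned uniformly in
#' log-intensity (so that the 2C, 4C, 8C ... doubling series is equally
#' spaced); genome-size runs use a linear axis. Events below `floor` are
#' treated as electronic noise/debris and excluded before binning (the number
#' excluded is kept on the object).
#'
#' @param x an [event_sample] or numeric vector of positive intensities.
#' @param n_bins number of bins (>= 16); the default 512 balances
#'   instrument-like resolution against per-bin counting noise at typical
#'   sample sizes of 3000-5000 nuclei.
#' @param scale `"log"` (default) or `"linear"`.
#' @param floor optional lower truncation threshold in channel units.
#' @return an object of class `dna_histogram` with fields `bin_edges`,
#'   `counts`, `mids`, `scale`, `n_excluded`.
#' @export
build_histogram <- function(x, n_bins = 512, scale = c("log", "linear"),
                            floor = NULL) {
  scale <- match.arg(scale)
  v <- .as_intensities(x)
  if (n_bins < 16) stop("n_bins must be >= 16", call. = FALSE)
  if (scale == "log" && any(v <= 0))
    stop("log-scale histogram requires strictly positive intensities",
         call. = FALSE)
  n_excluded <- 0L
  if (!is.null(floor)) {
    n_excluded <- sum(v < floor)
    v <- v[v >= floor]
  }
  if (!length(v)) stop("no events remain after floor truncation", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(rng[1] * 1e-6, 1e-9)
  # pad beyond the data extremes so a peak near the range edge can decay to
  # empty bins (otherwise its prominence is truncated by the axis)
  if (scale == "log") {
    rng <- rng * c(2^(-0.25), 2^(0.25))
    edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1L))
  } else {
    rng <- rng + c(-0.05, 0.05) * diff(rng)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  # nudge the top edge so max(v) lands in the last bin
  edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-12) + 1e-300
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- if (scale == "log") sqrt(edges[-1] * edges[-(n_bins + 1L)])
          else (edges[-1] + edges[-(n_bins + 1L)]) / 2
  structure(list(bin_edges = edges, counts = counts, mids = mids,
                 scale = scale, n_excluded = n_excluded),
            class = "dna_histogram")
}

#' @export
print.dna_histogram <- function(x, ...) {
  cat(sprintf("DNA-content histogram: %d bins (%s scale), %d events",
              length(x$counts), x$scale, sum(x$counts)))
  if (x$n_excluded > 0) cat(sprintf(" (+%d below floor)", x$n_excluded))
  cat("\n")
  invisible(x)
}

# centred running mean with edge replication; w forced odd
.smooth_counts <- function(counts, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(as.numeric(counts))
  h <- (w - 1L) %/% 2L
  n <- length(counts)
  padded <- c(rep(counts[1], h), counts, rep(counts[n], h))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(h + 1L):(h + n)]
}

# topographic prominence of a local maximum at index i:
# on each side, track the minimum until a strictly higher bin (or the edge)
# is met; the peak's base is the higher of the two side minima.
.prominence <- function(s, i) {
  n <- length(s)
  left_min <- s[i]
  j <- i - 1L
  while (j >= 1L && s[j] <= s[i]) { left_min <- min(left_min, s[j]); j <- j - 1L }
  right_min <- s[i]
  j <- i + 1L
  while (j <= n && s[j] <= s[i]) { right_min <- min(right_min, s[j]); j <- j + 1L }
  s[i] - max(left_min, right_min)
}

#' Detect fluorescence peaks in a DNA-content histogram
#'
#' Local maxima of the running-mean-smoothed histogram are kept when their
#' topographic prominence exceeds both a fraction of the tallest smoothed bin
#' and a Poisson counting-noise floor; shoulders without a deep valley
#' towards a taller neighbour are merged into it. Each retained peak is then
#' refined inside its full-width-at-half-maximum window: the reported
#' position is the count-weighted mean intensity over the window and the
#' peak CV (percent) is the within-window SD rescaled to the equivalent
#' full-Gaussian SD, so it matches the instrument convention for G0/G1 peak
#' CVs.
#'
#' @param hist a [build_histogram] result.
#' @param min_prominence_fraction prominence threshold as a fraction of the
#'   maximal smoothed bin count (default 0.02). A Poisson noise floor of
#'   `noise_mult` standard deviations of the smoothed local count is applied
#'   on top, so counting noise in sparse histograms does not surface as
#'   peaks.
#' @param smoothing_window running-mean width in bins (default 9, forced odd).
#' @param noise_mult multiplier for the counting-noise prominence floor.
#' @param valley_fraction two candidate peaks are kept apart only when the
#'   smoothed curve between them drops below this fraction of the smaller
#'   peak; otherwise the smaller one is treated as a shoulder and merged.
#' @return an object of class `peak_set`: a data.frame with columns
#'   `position`, `height`, `cv_percent`, `c_level` (NA until
#'   [assign_doubling_series] is applied), ordered by position.
#' @export
detect_peaks <- function(hist, min_prominence_fraction = 0.02,
                         smoothing_window = 9, noise_mult = 3,
                         valley_fraction = 0.5) {
  stopifnot(inherits(hist, "dna_histogram"))
  if (sum(hist$counts) == 0) stop("histogram is empty", call. = FALSE)
  s <- .smooth_counts(hist$counts, smoothing_window)
  n <- length(s)
  w <- max(1L, as.integer(smoothing_window))
  cand <- which(vapply(2:(n - 1L), function(i)
    s[i] > s[i - 1L] && s[i] >= s[i + 1L], logical(1))) + 1L
  if (length(cand)) {
    prom <- vapply(cand, function(i) .prominence(s, i), numeric(1))
    floor_i <- pmax(min_prominence_fraction * max(s),
                    noise_mult * sqrt(s[cand] / w + 0.5))
    cand <- cand[prom >= floor_i & s[cand] >= 3]
  }
  if (!length(cand))
    stop("no peak exceeds the prominence threshold", call. = FALSE)
  # merge shoulders: keep taller peaks first; a shorter candidate survives
  # only if a deep valley separates it from every accepted peak
  cand <- cand[order(-s[cand], cand)]
  accepted <- integer(0)
  for (i in cand) {
    ok <- TRUE
    for (a in accepted) {
      rng <- if (a < i) s[a:i] else s[i:a]
      if (min(rng) >= valley_fraction * min(s[i], s[a])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  cand <- sort(accepted)
  mids <- hist$mids
  # per-peak window: bins above half the smoothed peak height (FWHM),
  # clipped at the midpoint towards adjacent peaks; position is the
  # count-weighted mean inside, CV the within-window SD rescaled from the
  # half-maximum truncation to the full-Gaussian SD
  trunc_factor <- function(a) {
    # SD of a standard normal truncated to [-a, a], relative to sigma
    if (!is.finite(a) || a <= 0) return(1)
    sqrt(max(1e-6, 1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)))
  }
  refine <- function(j) {
    i <- cand[j]
    half <- 0.5 * s[i]
    left_clip <- if (j > 1) floor((cand[j - 1] + i) / 2) + 1L else 1L
    right_clip <- if (j < length(cand)) ceiling((cand[j + 1] + i) / 2) - 1L
                  else n
    lo <- i
    while (lo > left_clip && s[lo - 1L] >= half) lo <- lo - 1L
    hi <- i
    while (hi < right_clip && s[hi + 1L] >= half) hi <- hi + 1L
    w <- hist$counts[lo:hi]
    m <- mids[lo:hi]
    if (sum(w) == 0) return(c(mids[i], 0))
    mu <- sum(w * m) / sum(w)
    sd_win <- sqrt(sum(w * (m - mu)^2) / sum(w))
    # unwind the half-maximum truncation: solve sd_win = sigma * t(hw/sigma)
    hw <- (m[length(m)] - m[1]) / 2
    sdv <- sd_win
    if (sd_win > 0 && hw > 0 && length(m) >= 3 && sd_win < 0.95 * hw / sqrt(3)) {
      for (it in 1:8) sdv <- sd_win / trunc_factor(hw / sdv)
      sdv <- min(sdv, 3 * hw)
    }
    c(mu, 100 * sdv / mu)
  }
  ref <- t(vapply(seq_along(cand), refine, numeric(2)))
  out <- data.frame(position = ref[, 1],
                    height = hist$counts[cand],
                    cv_percent = ref[, 2],
                    c_level = NA_real_)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Assign peaks to the 2C doubling series
#'
#' The anchor (2C) peak is chosen by chain consistency: the lowest peak whose
#' doubling chain (positions near anchor * 2^k) matches at least one other
#' peak; when no chain matches any other peak, the tallest peak (ties broken
#' towards the lowest position) becomes the anchor. Peaks within
#' `tolerance_fraction` of anchor * 2^k receive C-level `2 * 2^k`; all others
#' (including any sub-anchor debris peak) are flagged unassigned, never
#' dropped.
#'
#' @param peaks a [detect_peaks] result.
#' @param tolerance_fraction maximal relative deviation from the expected
#'   doubling position (default 0.10; peak CVs of at most 5 percent make this
#'   a safe separator between successive doublings).
#' @return the `peak_set` with the `c_level` column filled where assigned.
#' @export
assign_doubling_series <- function(peaks, tolerance_fraction = 0.10) {
  stopifnot(inherits(peaks, "peak_set"), nrow(peaks) >= 1)
  p <- peaks$position
  n <- length(p)
  chain_matches <- function(a) {
    k <- round(log2(p / p[a]))
    ok <- k >= 1 & abs(p / (p[a] * 2^k) - 1) <= tolerance_fraction
    which(ok & seq_len(n) != a)
  }
  anchor <- NA_integer_
  for (a in seq_len(n)) {
    if (length(chain_matches(a))) { anchor <- a; break }
  }
  if (is.na(anchor)) {
    tallest <- which(peaks$height == max(peaks$height))
    anchor <- tallest[1L]  # positions sorted, so first = lowest position
  }
  lv <- rep(NA_real_, n)
  lv[anchor] <- 2
  k <- round(log2(p / p[anchor]))
  for (kk in sort(unique(k[k >= 1]))) {
    hit <- which(k == kk &
                   abs(p / (p[anchor] * 2^kk) - 1) <= tolerance_fraction)
    if (length(hit)) {
      best <- hit[which.min(abs(p[hit] / (p[anchor] * 2^kk) - 1))]
      lv[best] <- 2 * 2^kk
    }
  }
  peaks$c_level <- lv
  peaks
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$c_level <- ifelse(is.na(df$c_level), "unassigned",
                       paste0(format(df$c_level, trim = TRUE), "C"))
  print(format(df, digits = 4), ...)
  invisible(x)
}

# gate boundaries for assigned peaks: geometric midpoints between adjacent
# assigned peaks, outer bounds at peak * 2^(+-1/2)
.gate_boundaries <- function(positions) {
  k <- length(positions)
  inner <- if (k > 1) sqrt(positions[-k] * positions[-1]) else numeric(0)
  c(positions[1] * 2^(-0.5), inner, positions[k] * 2^(0.5))
}

#' Gate events into ploidy classes
#'
#' Every event between the outer gate boundaries is assigned to exactly one
#' C-level class; boundaries between adjacent assigned peaks sit at their
#' geometric midpoint (symmetric under the doubling structure on the log
#' axis). Events below the lowest or above the highest boundary are counted
#' as debris/aggregates and excluded from the total -- reported, never
#' silently dropped.
#'
#' @param x an [event_sample] or numeric intensity vector.
#' @param peaks a `peak_set` whose `c_level` column has been filled by
#'   [assign_doubling_series]; unassigned peaks are ignored for gating.
#' @return an object of class `ploidy_counts`.
#' @export
gate_events <- function(x, peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  assigned <- peaks[!is.na(peaks$c_level), , drop = FALSE]
  if (!nrow(assigned))
    stop("no assigned peaks; run assign_doubling_series first", call. = FALSE)
  v <- .as_intensities(x)
  bounds <- .gate_boundaries(assigned$position)
  idx <- findInterval(v, bounds)
  inside <- idx >= 1L & idx <= nrow(assigned)
  debris_low <- sum(idx < 1L)
  debris_high <- sum(idx > nrow(assigned))
  if (!any(inside))
    stop("no events fall inside the ploidy gates (insufficient nuclei)",
         call. = FALSE)
  counts <- tabulate(idx[inside], nbins = nrow(assigned))
  names(counts) <- paste0(format(assigned$c_level, trim = TRUE,
                                 scientific = FALSE), "C")
  meta <- if (inherits(x, "event_sample")) x$meta else list()
  ploidy_counts(counts, meta = meta,
                debris_low = debris_low, debris_high = debris_high)
}

#' Construct a ploidy-class count object
#'
#' @param counts named non-negative vector of nucleus counts; names are
#'   C-levels (`"2C"`, `"4C"`, ... or bare numbers `2, 4, ...`). Levels must
#'   belong to the doubling series 2 * 2^k.
#' @param meta list with species/organ/individual/replicate labels.
#' @param debris_low,debris_high events excluded below/above the gates.
#' @return object of class `ploidy_counts` with fields `counts` (named,
#'   complete from 2C to the highest observed level), `total`, `meta`,
#'   `debris_low`, `debris_high`.
#' @export
ploidy_counts <- function(counts, meta = list(), debris_low = 0L,
                          debris_high = 0L) {
  lv <- .parse_c_levels(names(counts), length(counts))
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("total nucleus count must be >= 1", call. = FALSE)
  k <- log2(lv / 2)
  if (any(abs(k - round(k)) > 1e-8) || any(k < -1e-8))
    stop("C-levels must belong to the doubling series 2, 4, 8, ...",
         call. = FALSE)
  k <- round(k)
  full <- numeric(max(k) + 1L)
  full[k + 1L] <- counts
  names(full) <- paste0(2 * 2^(0:max(k)), "C")
  structure(list(counts = full, total = sum(full), meta = meta,
                 debris_low = as.integer(debris_low),
                 debris_high = as.integer(debris_high)),
            class = "ploidy_counts")
}

.parse_c_levels <- function(nm, n) {
  if (is.null(nm)) return(2 * 2^(seq_len(n) - 1L))  # unnamed: 2C, 4C, ...
  lv <- suppressWarnings(as.numeric(sub("C$", "", nm)))
  if (any(is.na(lv))) stop("unparseable C-level names", call. = FALSE)
  lv
}

#' @export
print.ploidy_counts <- function(x, ...) {
  cat(sprintf("Ploidy counts: %s nuclei\n", format(x$total, big.mark = ",")))
  prop <- 100 * x$counts / x$total
  df <- data.frame(class = names(x$counts), n = x$counts,
                   percent = sprintf("%.2f", prop), row.names = NULL)
  print(df, ...)
  if (x$debris_low + x$debris_high > 0)
    cat(sprintf("Excluded: %d below gates, %d above\n",
                x$debris_low, x$debris_high))
  invisible(x)
}

#' Quality-control check for a flow-cytometric measurement
#'
#' Genome-size runs require at least 5000 nuclei and anchor-peak CVs of at
#' most 5 percent; endopolyploidy screens require at least 3000 nuclei.
#' Returns a report object (never throws): failed measurements should be
#' excluded with a logged reason, mirroring standard practice.
#'
#' @param x a `ploidy_fit`, `ploidy_counts`, or a plain total nucleus count.
#' @param mode `"genome_size"` or `"endopolyploidy"`.
#' @param peaks optional `peak_set` supplying CVs when `x` carries none.
#' @param min_nuclei,max_cv override the default thresholds.
#' @return object of class `qc_report` with fields `pass`, `violations`,
#'   `n_nuclei`, `cvs`.
#' @export
qc_check <- function(x, mode = c("genome_size", "endopolyploidy"),
                     peaks = NULL, min_nuclei = NULL, max_cv = 5) {
  mode <- match.arg(mode)
  if (is.null(min_nuclei))
    min_nuclei <- if (mode == "genome_size") 5000 else 3000
  if (inherits(x, "ploidy_fit")) {
    n <- x$counts$total
    if (is.null(peaks)) peaks <- x$peaks
  } else if (inherits(x, "ploidy_counts")) {
    n <- x$total
  } else {
    n <- as.numeric(x)
  }
  cvs <- if (!is.null(peaks)) peaks$cv_percent[!is.na(peaks$c_level)]
         else numeric(0)
  violations <- character(0)
  if (n < min_nuclei)
    violations <- c(violations,
                    sprintf("only %d nuclei (minimum %d for %s)",
                            round(n), min_nuclei, mode))
  bad_cv <- cvs[cvs > max_cv]
  if (length(bad_cv))
    violations <- c(violations,
                    sprintf("peak CV %.2f%% exceeds %.1f%%", bad_cv, max_cv))
  structure(list(pass = length(violations) == 0L, violations = violations,
                 n_nuclei = n, cvs = cvs, mode = mode),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC (%s): %s\n", x$mode, if (x$pass) "PASS" else "FAIL"))
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  invisible(x)
}
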