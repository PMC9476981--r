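#' Choose a parametric or nonparametric comparison route
#'
#' Multi-group comparisons use ANOVA + Tukey HSD only when every group passes
#' a Shapiro-Wilk normality test and the groups jointly pass Levene's
#' homoscedasticity test (both at `alpha`); otherwise the Kruskal-Wallis +
#' Dunn (Benjamini-Hochberg) route is taken. Degenerate groups (constant
#' values, where Shapiro-Wilk is undefined) are treated as failing normality.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 levels, each with n >= 3).
#' @param alpha gatekeeping significance level (default 0.05).
#' @param center Levene centring, `"mean"` (default) or `"median"`.
#' @return `"anova_tukey"` or `"kruskal_dunn_bh"`, with attribute `tests`
#'   holding the gatekeeping p-values.
#' @export
gatekeep <- function(values, groups, alpha = 0.05, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3))
    stop("each group needs n >= 3 (got ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  sw <- vapply(split(values, groups), function(v) {
    p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
    if (!is.finite(p)) 0 else p
  }, numeric(1))
  lev <- tryCatch(
    car::leveneTest(values ~ groups,
                    center = if (center == "mean") mean else stats::median)[1, "Pr(>F)"],
    error = function(e) 0)
  if (!is.finite(lev)) lev <- 0
  method <- if (all(sw > alpha) && lev > alpha) "anova_tukey"
            else "kruskal_dunn_bh"
  attr(method, "tests") <- list(shapiro_p = sw, levene_p = lev, alpha = alpha)
  method
}

# Dunn's rank-sum post-hoc z statistics with tie correction;
# two-sided unadjusted p-values
.dunn_pairs <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_r <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[p[1]] + 1 / n[p[2]]))
    (mean_r[p[1]] - mean_r[p[2]]) / se
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

# brute-force maximal cliques of the non-significance graph -> letters;
# sound by construction: two groups share a letter iff their pair is
# non-significant (edges inside a clique) -- and deterministic given the
# alphabetical group order
.letter_display <- function(levels_, pair_sig) {
  k <- length(levels_)
  adj <- matrix(TRUE, k, k, dimnames = list(levels_, levels_))
  for (i in seq_len(nrow(pair_sig)))
    if (pair_sig$significant[i]) {
      adj[pair_sig$group1[i], pair_sig$group2[i]] <- FALSE
      adj[pair_sig$group2[i], pair_sig$group1[i]] <- FALSE
    }
  subsets <- list()
  for (m in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
    if (!length(members)) next
    sub <- adj[members, members, drop = FALSE]
    if (all(sub)) subsets[[length(subsets) + 1L]] <- members
  }
  is_maximal <- vapply(subsets, function(s)
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1))), logical(1))
  cliques <- subsets[is_maximal]
  ord <- order(vapply(cliques, min, numeric(1)),
               -vapply(cliques, length, numeric(1)))
  cliques <- cliques[ord]
  lab <- rep("", k)
  for (i in seq_along(cliques))
    lab[cliques[[i]]] <- paste0(lab[cliques[[i]]], letters[i])
  stats::setNames(lab, levels_)
}

#' Compare parameter values between groups
#'
#' Runs the route chosen by [gatekeep] (or forced via `method`): one-way
#' ANOVA with Tukey HSD pairwise comparisons, or Kruskal-Wallis with Dunn's
#' pairwise z tests adjusted by Benjamini-Hochberg. Pairwise significance at
#' `alpha` is summarised as a compact letter display -- groups sharing a
#' letter are not significantly different.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param method `NULL` (auto via [gatekeep]), `"anova_tukey"` or
#'   `"kruskal_dunn_bh"`.
#' @param alpha significance level for letters (default 0.05).
#' @return an object of class `group_comparison`: list with `method`,
#'   `statistic`, `df`, `p_value` (global test), `pairwise` (data.frame with
#'   adjusted p-values), `letters` (named by group, alphabetical order) and
#'   `gatekeeping`.
#' @export
compare_groups <- function(values, groups, method = NULL, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  groups <- factor(groups, levels = sort(levels(groups)))
  if (length(unique(values)) == 1L)
    stop("all values identical across all groups (degenerate data)",
         call. = FALSE)
  gate <- NULL
  if (is.null(method)) {
    gate <- gatekeep(values, groups, alpha = alpha)
    method <- as.character(gate)
  }
  method <- match.arg(method, c("anova_tukey", "kruskal_dunn_bh"))
  if (method == "anova_tukey") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group1 = vapply(nm, `[`, "", 2L), group2 = vapply(nm, `[`, "", 1L),
      estimate = tk[, "diff"], p_adjusted = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    statistic <- an$`F value`[1]
    df <- unname(an$Df)
    p_value <- an$`Pr(>F)`[1]
  } else {
    kw <- stats::kruskal.test(values, groups)
    dn <- .dunn_pairs(values, groups)
    dn$p_adjusted <- stats::p.adjust(dn$p, method = "BH")
    pairwise <- data.frame(group1 = dn$group1, group2 = dn$group2,
                           estimate = dn$z, p_adjusted = dn$p_adjusted,
                           stringsAsFactors = FALSE)
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter)
    p_value <- kw$p.value
  }
  pairwise$significant <- pairwise$p_adjusted < alpha
  letters_ <- .letter_display(levels(groups), pairwise)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, pairwise = pairwise, letters = letters_,
                 alpha = alpha, gatekeeping = attr(gate, "tests")),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lbl <- if (x$method == "anova_tukey") "one-way ANOVA + Tukey HSD"
         else "Kruskal-Wallis + Dunn (BH)"
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", lbl, x$statistic, x$p_value))
  cat("Letters (alpha = ", x$alpha, "): ",
      paste(names(x$letters), x$letters, sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Spearman correlation matrix of endopolyploidy parameters
#'
#' @param profiles data.frame of per-measurement profiles (e.g. rbind of
#'   [endopoly_profile] rows).
#' @param params which columns to correlate.
#' @return symmetric matrix of Spearman rank correlations (average ranks for
#'   ties, pairwise-complete observations); constant columns give `NA`
#'   entries with a warning.
#' @export
spearman_matrix <- function(profiles,
                            params = c("EI", "MCV", "E4P", "p4c")) {
  stopifnot(all(params %in% names(profiles)))
  if (nrow(profiles) < 10)
    stop("need at least 10 profiles for a rank-correlation matrix",
         call. = FALSE)
  m <- as.matrix(profiles[, params, drop = FALSE])
  const <- apply(m, 2, function(v) stats::var(v[!is.na(v)]) == 0)
  out <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  if (any(const, na.rm = TRUE)) {
    out[const, ] <- NA
    out[, const] <- NA
    diag(out) <- ifelse(const, NA, 1)
    warning("constant column(s): ", paste(params[const], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  }
  out
}

#' Across-species coefficient of variation of organ-specific means
#'
#' For one parameter (EI, genome size or meanDNA) and one organ, the CV of
#' the per-species mean values: `100 * sample SD / mean`.
#'
#' @param species_means one mean per species (for this study design, n = 4).
#' @param parameter,organ labels carried into the output.
#' @return one-row data.frame with `parameter`, `organ`, `n`, `cv_percent`.
#' @export
cv_across_species <- function(species_means, parameter = NA_character_,
                              organ = NA_character_) {
  stopifnot(length(species_means) >= 2)
  m <- mean(species_means)
  if (m == 0) stop("mean of species means is zero", call. = FALSE)
  data.frame(parameter = parameter, organ = organ,
             n = length(species_means),
             cv_percent = 100 * stats::sd(species_means) / m,
             stringsAsFactors = FALSE)
}

#' Centred (not scaled) principal component analysis
#'
#' PCA of a complete individuals x organs parameter matrix, column-centred
#' but not unit-scaled, as appropriate when all columns share a unit.
#' Individuals with missing organ values must be dropped by the caller.
#'
#' @param x complete numeric matrix/data.frame (rows = samples, columns =
#'   organs or variables).
#' @return object of class `endo_pca`: list with `scores`,
#'   `variance_explained` (percent per PC, non-increasing, summing to 100),
#'   `loadings`, `center`.
#' @export
pca_centered <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x)))
    stop("PCA input must be complete; drop incomplete individuals first",
         call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, variance_explained = ve,
                 loadings = p$rotation, center = p$center),
            class = "endo_pca")
}

#' @export
print.endo_pca <- function(x, ...) {
  cat("Centred PCA: variance explained (%):\n")
  print(round(x$variance_explained, 2))
  invisible(x)
}

#' Standardize values to zero mean and unit variance
#'
#' @param x numeric vector, n >= 2 with nonzero sample SD.
#' @return z-scores (sample-SD convention).
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero standard deviation", call. = FALSE)
  (x - mean(x)) / s
}
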