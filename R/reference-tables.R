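#' Published reference values for the four Pulmonaria species
#'
#' These tables carry the published reference measurements for *Pulmonaria
#' mollis*, *P. murinii*, *P. obscura* and *P. officinalis* (four or five
#' organs per species, 19-25 individuals per organ) that the package's
#' synthetic generator emulates and the test-suite checks the parameter
#' algebra against. All tables are constructed in code; nothing is read from
#' disk.
#'
#' @return `pulmonaria_karyotype()`: data.frame with `species`, `n2` (somatic
#'   chromosome count) and `ploidy` annotation.
#' @name pulmonaria-reference
#' @export
pulmonaria_karyotype <- function() {
  data.frame(
    species = c("P. mollis", "P. murinii", "P. obscura", "P. officinalis"),
    n2 = c(18L, 14L, 14L, 16L),
    ploidy = "2x",
    stringsAsFactors = FALSE)
}

#' @rdname pulmonaria-reference
#' @return `pulmonaria_genome_size()`: one row per species with the
#'   sample/standard ratio (mean and SD over three plants), the 2C genome
#'   size (pg, mean/SD/min/max), the 1C amounts in pg and Mbp and the
#'   per-chromosome DNA content, as measured against a 1.96 pg tomato
#'   internal standard.
#' @export
pulmonaria_genome_size <- function() {
  data.frame(
    species = c("P. mollis", "P. murinii", "P. obscura", "P. officinalis"),
    n2 = c(18L, 14L, 14L, 16L),
    n_plants = 3L,
    c2_mean = c(3.176, 2.311, 2.687, 2.963),
    c2_sd = c(0.006, 0.040, 0.022, 0.018),
    c2_min = c(3.171, 2.269, 2.673, 2.943),
    c2_max = c(3.183, 2.347, 2.712, 2.978),
    ratio_mean = c(1.620, 1.179, 1.371, 1.511),
    ratio_sd = c(0.003, 0.020, 0.011, 0.009),
    c1_pg = c(1.588, 1.156, 1.343, 1.481),
    c1_mbp = c(1553, 1130, 1314, 1449),
    pg_per_chromosome = c(0.176, 0.165, 0.192, 0.185),
    stringsAsFactors = FALSE)
}

#' @rdname pulmonaria-reference
#' @return `pulmonaria_class_proportions()`: one row per species x organ with
#'   the mean and SD (percentage points, across individuals) of the nucleus
#'   proportion in each ploidy class 2C-64C, the number of individuals `N`
#'   and the recorded maximal endocycle number `ECmax`. Absent classes are 0.
#' @export
pulmonaria_class_proportions <- function() {
  rows <- list(
    #          species          organ      N   2C     4C     8C    16C    32C   64C  ecmax
    list("P. mollis",      "root",    20, c(35.88, 56.39,  7.73,  0,     0,    0   ), 2L),
    list("P. mollis",      "stem",    19, c(40.77, 34.65, 21.88,  2.68,  0.02, 0   ), 4L),
    list("P. mollis",      "leaf",     3, c(65.91, 27.25,  6.84,  0,     0,    0   ), 2L),
    list("P. mollis",      "calyx",   20, c(79.54, 19.88,  0.58,  0,     0,    0   ), 2L),
    list("P. mollis",      "corolla", 20, c(84.33, 15.07,  0.59,  0,     0,    0   ), 2L),
    list("P. murinii",     "root",    19, c(15.74, 53.77, 28.91,  1.56,  0.02, 0   ), 4L),
    list("P. murinii",     "stem",    20, c(24.05, 40.55, 19.77, 12.58,  3.02, 0.03), 5L),
    list("P. murinii",     "calyx",   20, c(52.55, 44.50,  2.89,  0.05,  0,    0   ), 3L),
    list("P. murinii",     "corolla", 20, c(57.87, 39.25,  2.88,  0,     0,    0   ), 2L),
    list("P. obscura",     "root",    25, c(18.25, 45.56, 31.91,  4.27,  0,    0   ), 3L),
    list("P. obscura",     "stem",    25, c(20.35, 41.46, 20.26, 15.25,  2.65, 0.04), 5L),
    list("P. obscura",     "leaf",    22, c(55.70, 35.37,  8.83,  0.10,  0,    0   ), 3L),
    list("P. obscura",     "calyx",   25, c(45.51, 50.74,  3.66,  0.09,  0,    0   ), 3L),
    list("P. obscura",     "corolla", 25, c(56.17, 41.61,  2.13,  0.10,  0,    0   ), 3L),
    list("P. officinalis", "root",    20, c(31.95, 48.25, 19.51,  0.29,  0,    0   ), 3L),
    list("P. officinalis", "stem",    20, c(29.16, 37.95, 18.99, 12.89,  1.01, 0   ), 4L),
    list("P. officinalis", "calyx",   20, c(80.96, 18.17,  0.87,  0,     0,    0   ), 2L),
    list("P. officinalis", "corolla", 20, c(80.08, 19.24,  0.69,  0,     0,    0   ), 2L))
  sds <- list(
    c(7.00, 6.07, 2.90, 0, 0, 0), c(6.37, 4.29, 3.12, 3.28, 0.07, 0),
    c(2.31, 2.07, 2.41, 0, 0, 0), c(10.58, 10.64, 0.87, 0, 0, 0),
    c(8.97, 8.06, 1.20, 0, 0, 0), c(4.15, 5.80, 6.30, 2.08, 0.09, 0),
    c(4.60, 3.82, 4.00, 3.61, 3.50, 0.12), c(16.00, 14.45, 1.87, 0.17, 0, 0),
    c(9.08, 8.00, 1.47, 0, 0, 0), c(6.26, 7.21, 7.73, 3.74, 0, 0),
    c(4.69, 4.48, 4.89, 6.71, 4.26, 0.20), c(8.71, 6.58, 7.48, 0.46, 0, 0),
    c(12.17, 11.51, 1.10, 0.22, 0, 0), c(10.22, 9.46, 1.00, 0.24, 0, 0),
    c(9.49, 7.26, 8.02, 0.51, 0, 0), c(5.20, 3.31, 3.26, 5.07, 1.51, 0),
    c(5.98, 5.59, 0.86, 0, 0, 0), c(5.12, 4.71, 0.62, 0, 0, 0))
  cls <- c("2C", "4C", "8C", "16C", "32C", "64C")
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    d <- data.frame(species = r[[1]], organ = r[[2]], N = as.integer(r[[3]]),
                    stringsAsFactors = FALSE)
    for (j in seq_along(cls)) d[[cls[j]]] <- r[[4]][j]
    for (j in seq_along(cls)) d[[paste0("sd_", cls[j])]] <- sds[[i]][j]
    d$ECmax <- r[[5]]
    d
  }))
  rownames(out) <- NULL
  out
}

#' @rdname pulmonaria-reference
#' @return `pulmonaria_endopoly_params()`: one row per species x organ with
#'   the published per-individual-averaged means and SDs of the five
#'   endopolyploidy parameters (EI, MCV, E4P, >=4C percent, meanDNA pg).
#' @export
pulmonaria_endopoly_params <- function() {
  rows <- list(
    #          species          organ      N     EI          MCV         E4P         p4c          meanDNA
    list("P. mollis",      "root",    20, c(0.72, 0.09, 3.59, 0.22, 4.47, 0.16, 64.12,  7.00, 5.70, 0.35)),
    list("P. mollis",      "stem",    19, c(0.87, 0.13, 4.39, 0.54, 6.00, 0.57, 59.23,  6.37, 6.97, 0.85)),
    list("P. mollis",      "leaf",     3, c(0.41, 0.04, 2.96, 0.13, 4.80, 0.24, 34.09,  2.31, 4.69, 0.21)),
    list("P. mollis",      "calyx",   20, c(0.21, 0.11, 2.43, 0.21, 4.14, 0.22, 20.46, 10.58, 3.86, 0.34)),
    list("P. mollis",      "corolla", 20, c(0.16, 0.10, 2.34, 0.22, 4.09, 0.16, 15.67,  8.97, 3.71, 0.35)),
    list("P. murinii",     "root",    19, c(1.16, 0.12, 5.03, 0.50, 5.59, 0.49, 84.26,  4.15, 5.82, 0.58)),
    list("P. murinii",     "stem",    20, c(1.30, 0.14, 6.68, 1.04, 8.13, 1.14, 75.95,  4.60, 7.72, 1.20)),
    list("P. murinii",     "calyx",   20, c(0.50, 0.18, 3.07, 0.39, 4.24, 0.11, 47.45, 16.00, 3.55, 0.45)),
    list("P. murinii",     "corolla", 20, c(0.45, 0.10, 2.96, 0.23, 4.26, 0.11, 42.13,  9.08, 3.42, 0.27)),
    list("P. obscura",     "root",    25, c(1.22, 0.17, 5.42, 0.71, 6.17, 0.73, 81.75,  6.26, 7.28, 0.96)),
    list("P. obscura",     "stem",    25, c(1.39, 0.21, 7.00, 1.56, 8.22, 1.67, 79.65,  4.69, 9.40, 2.10)),
    list("P. obscura",     "leaf",    22, c(0.53, 0.15, 3.25, 0.45, 4.76, 0.63, 44.30,  8.71, 4.37, 0.60)),
    list("P. obscura",     "calyx",   25, c(0.58, 0.13, 3.25, 0.27, 4.29, 0.08, 54.49, 12.17, 4.36, 0.36)),
    list("P. obscura",     "corolla", 25, c(0.46, 0.11, 2.97, 0.24, 4.22, 0.10, 43.83, 10.22, 3.99, 0.32)),
    list("P. officinalis", "root",    20, c(0.88, 0.16, 4.18, 0.49, 5.16, 0.43, 68.05,  9.49, 6.18, 0.73)),
    list("P. officinalis", "stem",    20, c(1.19, 0.17, 6.01, 0.92, 7.61, 1.05, 70.84,  5.20, 8.89, 1.36)),
    list("P. officinalis", "calyx",   20, c(0.20, 0.06, 2.42, 0.14, 4.17, 0.16, 19.04,  5.98, 3.58, 0.21)),
    list("P. officinalis", "corolla", 20, c(0.21, 0.06, 2.43, 0.12, 4.13, 0.11, 19.92,  5.12, 3.59, 0.18)))
  out <- do.call(rbind, lapply(rows, function(r) {
    v <- r[[4]]
    data.frame(species = r[[1]], organ = r[[2]], N = as.integer(r[[3]]),
               EI = v[1], sd_EI = v[2], MCV = v[3], sd_MCV = v[4],
               E4P = v[5], sd_E4P = v[6], p4c = v[7], sd_p4c = v[8],
               meanDNA = v[9], sd_meanDNA = v[10], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
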