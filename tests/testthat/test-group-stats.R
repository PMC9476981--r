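test_that("gatekeeping routes clean data to ANOVA and skewed data to KW", {
  set.seed(300)
  g <- rep(letters[1:4], each = 20)
  v <- rnorm(80, mean = rep(c(10, 11, 12, 13), each = 20), sd = 1)
  expect_equal(as.character(gatekeep(v, g)), "anova_tukey")

  # a heavy-tailed group trips the gate most of the time
  set.seed(102)
  routed_np <- sum(replicate(100, {
    v2 <- c(rnorm(60, 10, 1), rlnorm(20, meanlog = 2, sdlog = 1))
    as.character(gatekeep(v2, g)) == "kruskal_dunn_bh"
  }))
  expect_gte(routed_np, 90)

  # constant group: Shapiro-Wilk degenerate, treated as failing
  v3 <- c(rep(5, 20), rnorm(60, 10, 1))
  expect_equal(as.character(gatekeep(v3, g)), "kruskal_dunn_bh")

  expect_error(gatekeep(rnorm(5), c("a", "a", "a", "b", "b")), "n >= 3")
})

test_that("group comparison finds separation and stays quiet under the null", {
  # two identical distributions: adjusted p > 0.05 in >= 90/100 seeds
  set.seed(111)
  quiet <- sum(replicate(100, {
    v <- rnorm(100)
    g <- rep(c("a", "b"), each = 50)
    all(compare_groups(v, g, method = "kruskal_dunn_bh")$pairwise$p_adjusted >
          0.05)
  }))
  expect_gte(quiet, 90)

  # groups shifted by 5 SD: all pairs significant, all letters distinct
  set.seed(112)
  g <- rep(letters[1:4], each = 20)
  v <- rnorm(80, mean = rep(c(0, 5, 10, 15), each = 20), sd = 1)
  for (m in c("anova_tukey", "kruskal_dunn_bh")) {
    cmp <- compare_groups(v, g, method = m)
    expect_true(all(cmp$pairwise$significant))
    expect_equal(sort(unname(cmp$letters)), c("a", "b", "c", "d"))
  }

  expect_error(compare_groups(rep(1, 40), rep(c("a", "b"), 20)), "degenerate")
})

test_that("Dunn z statistics match an independent rank computation", {
  # small fixed dataset; expected z rebuilt from first principles here
  v <- c(3.1, 4.7, 2.2, 5.0, 6.1, 5.9, 8.3, 7.7, 9.0, 6.5, 2.2, 4.0)
  g <- rep(c("a", "b", "c"), each = 4)
  cmp <- compare_groups(v, g, method = "kruskal_dunn_bh")
  r <- rank(v)
  N <- 12
  tie_tab <- table(r)
  sigma2 <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  zab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / sqrt(sigma2 * (1 / 4 + 1 / 4))
  got <- cmp$pairwise
  expect_equal(got$estimate[got$group1 == "a" & got$group2 == "b"], zab)
  # BH adjustment comes from stats::p.adjust
  praw <- 2 * pnorm(-abs(got$estimate))
  expect_equal(got$p_adjusted, p.adjust(praw, "BH"))
})

test_that("letter displays are sound: shared letter iff non-significant pair", {
  set.seed(121)
  for (trial in 1:40) {
    k <- sample(3:5, 1)
    g <- rep(letters[1:k], each = 10)
    shift <- sample(0:3, k, replace = TRUE)
    v <- rnorm(k * 10, mean = rep(shift, each = 10))
    cmp <- compare_groups(v, g, method = "kruskal_dunn_bh")
    pw <- cmp$pairwise
    for (i in seq_len(nrow(pw))) {
      shared <- any(strsplit(cmp$letters[[pw$group1[i]]], "")[[1]] %in%
                      strsplit(cmp$letters[[pw$group2[i]]], "")[[1]])
      expect_equal(shared, !pw$significant[i])
    }
    expect_true(all(nchar(cmp$letters) >= 1))
  }
})

test_that("spearman matrices handle monotone, null and constant columns", {
  # perfectly monotone pair
  d <- data.frame(EI = 1:20, MCV = (1:20)^2, E4P = 20:1, p4c = log(1:20))
  m <- spearman_matrix(d)
  expect_equal(m["EI", "MCV"], 1)
  expect_equal(m["EI", "E4P"], -1)
  expect_true(isSymmetric(m))

  # independent columns: |r| < 0.1 in >= 90/100 seeds
  set.seed(131)
  small <- sum(replicate(100, {
    d2 <- data.frame(EI = rnorm(500), MCV = rnorm(500),
                     E4P = rnorm(500), p4c = rnorm(500))
    abs(spearman_matrix(d2)["EI", "MCV"]) < 0.1
  }))
  expect_gte(small, 90)

  # EI and MCV move together over realistic proportion ranges
  set.seed(132)
  tab <- pulmonaria_class_proportions()
  profs <- do.call(rbind, lapply(1:500, function(i) {
    tpl <- organ_template("s", "root",
                          as.numeric(tab[sample(nrow(tab), 1), CLASS_COLS]))
    p <- draw_individual_proportions(tpl)
    endopoly_profile(stats::setNames(p + 1e-12, CLASS_COLS))
  }))
  expect_gte(spearman_matrix(profs)["EI", "MCV"], 0.90)

  # constant column flagged undefined
  d3 <- data.frame(EI = rnorm(20), MCV = rnorm(20), E4P = rep(4, 20),
                   p4c = rnorm(20))
  expect_warning(m3 <- spearman_matrix(d3), "constant")
  expect_true(is.na(m3["E4P", "EI"]))
})

test_that("across-species CV is scale- but not shift-invariant", {
  gs <- c(3.176, 2.311, 2.687, 2.963)
  expect_equal(round(cv_across_species(gs)$cv_percent, 1), 13.4)
  expect_equal(cv_across_species(c(2, 2, 2))$cv_percent, 0)
  expect_equal(cv_across_species(c(1, 3))$cv_percent, 100 * sqrt(2) / 2)
  expect_equal(cv_across_species(10 * gs)$cv_percent,
               cv_across_species(gs)$cv_percent)
  expect_false(isTRUE(all.equal(cv_across_species(gs + 5)$cv_percent,
                                cv_across_species(gs)$cv_percent)))
  expect_error(cv_across_species(c(-1, 1)), "zero")
})

test_that("centred PCA matches a brute-force eigendecomposition", {
  set.seed(141)
  x <- matrix(rnorm(80 * 4), 80, 4) %*% diag(c(3, 2, 1, 0.5))
  p <- pca_centered(x)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(p$variance_explained, 100 * ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-9)
  expect_true(all(diff(p$variance_explained) <= 1e-12))

  # rank-1 input: PC1 explains everything
  r1 <- outer(rnorm(30), c(1, 2, 3, 4))
  expect_equal(pca_centered(r1)$variance_explained[1], 100)

  # mirroring the data leaves variance-explained unchanged
  xm <- rbind(x, -x)
  expect_equal(pca_centered(rbind(xm, xm))$variance_explained,
               pca_centered(xm)$variance_explained, tolerance = 1e-9)

  expect_error(pca_centered(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("standardization gives zero-mean unit-variance z-scores", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 7, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(2 + 3 * x), z)
  expect_error(standardize(rep(4, 10)), "zero")
})
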