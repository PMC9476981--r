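test_that("EI, MCV, E4P, >=4C, ECmax, meanDNA match hand computations", {
  # published mean-proportion rows
  expect_equal(round(endoreduplication_index(ref_row("P. mollis", "root")), 2),
               0.72)
  expect_equal(round(endoreduplication_index(ref_row("P. obscura", "stem")), 2),
               1.39)
  expect_equal(round(mean_c_value(ref_row("P. murinii", "stem")), 2), 6.68)

  # degenerate and simple cases
  expect_equal(endoreduplication_index(c("2C" = 100)), 0)
  expect_equal(mean_c_value(c("2C" = 100)), 2)
  expect_equal(mean_c_value(c("2C" = 50, "4C" = 50)), 3)
  expect_equal(e4p(c("2C" = 50, "4C" = 50)), 4)
  expect_true(is.na(e4p(c("2C" = 100))))
  # E4P from the P. mollis root row: (4*56.39 + 8*7.73) / 64.12
  expect_equal(round(e4p(ref_row("P. mollis", "root")), 2), 4.48)
  expect_equal(prop_4c(c("2C" = 100)), 0)
  expect_equal(prop_4c(c("2C" = 0, "4C" = 10)), 100)
  expect_equal(round(prop_4c(ref_row("P. obscura", "root")), 2), 100 - 18.25)
  expect_equal(ecmax(c("2C" = 1, "4C" = 0, "8C" = 2)), 2)
  expect_equal(ecmax(c("2C" = 9)), 0)
  expect_equal(ecmax(ref_row("P. murinii", "stem")), 5)

  expect_equal(mean_dna(2, 3.176), 3.176)
  m <- mean_c_value(ref_row("P. mollis", "root"))
  expect_equal(round(mean_dna(m, 3.176), 2), 5.70)
  expect_error(mean_dna(1.5, 2), "MCV")
  expect_error(endoreduplication_index(c("2C" = 0)), "empty")
})

test_that("full reproduction of the published parameter table from proportions", {
  prop_tab <- pulmonaria_class_proportions()
  par_tab <- pulmonaria_endopoly_params()
  gs <- pulmonaria_genome_size()
  for (i in seq_len(nrow(prop_tab))) {
    row <- stats::setNames(as.numeric(prop_tab[i, CLASS_COLS]), CLASS_COLS)
    ref <- ref_params(prop_tab$species[i], prop_tab$organ[i])
    c2 <- gs$c2_mean[gs$species == prop_tab$species[i]]
    expect_lt(abs(endoreduplication_index(row) - ref$EI), 0.011)
    expect_lt(abs(mean_c_value(row) - ref$MCV), 0.021)
    expect_lt(abs(prop_4c(row) - ref$p4c), 0.16)
    expect_lt(abs(mean_dna(mean_c_value(row), c2) - ref$meanDNA), 0.051)
    # E4P printed values average per-individual ratios, hence the wider band
    expect_lt(abs(e4p(row) - ref$E4P), 0.11)
    expect_equal(ecmax(row), prop_tab$ECmax[i])
  }
})

test_that("pooled-count indices equal nucleus-weighted means of parts", {
  set.seed(91)
  for (trial in 1:25) {
    k <- sample(3:6, 1)
    parts <- lapply(1:3, function(j) {
      cnt <- rpois(k, lambda = c(2000, 1500, 500, 200, 50, 5)[1:k]) + 1
      ploidy_counts(stats::setNames(cnt, paste0(2 * 2^(0:(k - 1)), "C")))
    })
    pooled <- pool_counts(parts)
    ns <- vapply(parts, function(p) p$total, numeric(1))
    for (f in list(endoreduplication_index, mean_c_value, prop_4c)) {
      per <- vapply(parts, f, numeric(1))
      expect_equal(f(pooled), sum(per * ns) / sum(ns), tolerance = 1e-12)
    }
  }
})

test_that("parameter bound chain and monotonicity hold on random counts", {
  set.seed(92)
  for (trial in 1:50) {
    k <- sample(1:6, 1)
    cnt <- rpois(k, 300) + 1
    names(cnt) <- paste0(2 * 2^(0:(k - 1)), "C")
    ei <- endoreduplication_index(cnt)
    mcv <- mean_c_value(cnt)
    em <- ecmax(cnt)
    expect_gte(ei, 0); expect_lte(ei, em)
    expect_gte(mcv, 2 * (1 + ei) - 1e-12)
    expect_lte(mcv, 2^(em + 1) + 1e-12)
    expect_gte(mean_dna(mcv, 2.7) / 2.7, 1 - 1e-12)
    expect_lte(mean_dna(mcv, 2.7) / 2.7, 2^em + 1e-12)
    if (k >= 2) {
      # promote one nucleus a class up: EI, MCV strictly increase,
      # >=4C never decreases
      j <- sample(k - 1, 1)
      cnt2 <- cnt
      cnt2[j] <- cnt2[j] - 1
      cnt2[j + 1] <- cnt2[j + 1] + 1
      expect_gt(endoreduplication_index(cnt2), ei)
      expect_gt(mean_c_value(cnt2), mcv)
      expect_gte(prop_4c(cnt2), prop_4c(cnt))
    }
  }
  # equality MCV = 2(1+EI) iff only 2C/4C occupied
  only24 <- c("2C" = 60, "4C" = 40)
  expect_equal(mean_c_value(only24), 2 * (1 + endoreduplication_index(only24)))
  with8 <- c("2C" = 60, "4C" = 30, "8C" = 10)
  expect_gt(mean_c_value(with8), 2 * (1 + endoreduplication_index(with8)))
})

test_that("replicate averaging works at the parameter level", {
  p1 <- endopoly_profile(c("2C" = 700, "4C" = 300),
                         meta = list(organ = "root", individual = "a",
                                     replicate = 1L))
  p2 <- endopoly_profile(c("2C" = 500, "4C" = 400, "8C" = 100),
                         meta = list(organ = "root", individual = "a",
                                     replicate = 2L))
  avg <- average_individual(rbind(p1, p2))
  expect_equal(avg$EI, mean(c(p1$EI, p2$EI)))
  expect_equal(avg$ECmax, 2)
  # E4P averaged only over replicates where defined
  p3 <- endopoly_profile(c("2C" = 100),
                         meta = list(organ = "root", individual = "a",
                                     replicate = 3L))
  avg2 <- average_individual(rbind(p1, p2, p3))
  expect_equal(avg2$E4P, mean(c(p1$E4P, p2$E4P)))
  # identical duplicates average to themselves
  same <- average_individual(rbind(p1, p1))
  expect_equal(same$EI, p1$EI)
  expect_equal(same$MCV, p1$MCV)
  # organ mixing is a contract violation
  p4 <- endopoly_profile(c("2C" = 10),
                         meta = list(organ = "stem", individual = "a"))
  expect_error(average_individual(rbind(p1, p4)), "organs")
})

test_that("averaging replicates tightens the EI estimate", {
  set.seed(93)
  truth <- c(0.36, 0.45, 0.15, 0.04)
  true_ei <- endoreduplication_index(truth)
  one_rep <- function() {
    cnt <- as.integer(rmultinom(1, 600, truth))
    endoreduplication_index(stats::setNames(cnt, paste0(c(2, 4, 8, 16), "C")))
  }
  err_avg <- c(); err_one <- c()
  for (trial in 1:100) {
    eis <- replicate(5, one_rep())
    err_avg <- c(err_avg, abs(mean(eis) - true_ei))
    err_one <- c(err_one, abs(eis[1] - true_ei))
  }
  # the 5-replicate average beats a single replicate most of the time and
  # has a clearly smaller RMSE (~1/sqrt(5))
  expect_gte(mean(err_avg < err_one), 0.60)
  expect_lt(sqrt(mean(err_avg^2)), 0.7 * sqrt(mean(err_one^2)))
})

test_that("the endopolyploidy predicate uses the EI > 0.1 criterion", {
  expect_true(is_endopolyploid(0.72))
  expect_false(is_endopolyploid(0.1))
  expect_equal(is_endopolyploid(c(0.05, 0.2)), c(FALSE, TRUE))
})
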