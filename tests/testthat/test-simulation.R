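all_configs <- function(snps) {
  g <- expand.grid(rep(list(0:2), length(snps)))
  names(g) <- snps
  g
}

test_that("the phenotype rule fires on exactly the stated allele configurations", {
  base <- tibble::tibble(
    S4 = 2L, S5 = 2L, S6 = 2L, S7 = 2L, S8 = 0L, S9 = 1L, S10 = 2L
  )
  expect_identical(truth_label(base), 1L) # rule A
  b <- tibble::tibble(S4 = 1L, S5 = 1L, S6 = 0L, S7 = 1L, S8 = 0L, S9 = 1L, S10 = 2L)
  expect_identical(truth_label(b), 1L) # rule B
  none <- tibble::tibble(S4 = 0L, S5 = 0L, S6 = 0L, S7 = 0L, S8 = 0L, S9 = 1L, S10 = 2L)
  expect_identical(truth_label(none), 0L)
})

test_that("rules A and B are mutually exclusive and the product expansion matches", {
  # I1 * I2 == 0 on all 81 configurations of S4..S7
  g4 <- all_configs(paste0("S", 4:7))
  g4$S8 <- 0L
  g4$S9 <- 0L
  g4$S10 <- 0L
  r <- epistasis_rules(g4)
  expect_true(all(!(r$A & r$B)))

  # label == 1 - (1 - I1)(1 - I2)(1 - I3) on all 3^7 configurations
  g7 <- all_configs(paste0("S", 4:10))
  r7 <- epistasis_rules(g7)
  i1 <- as.integer(r7$A)
  i2 <- as.integer(r7$B)
  i3 <- as.integer(r7$C)
  expect_identical(truth_label(g7), as.integer(1 - (1 - i1) * (1 - i2) * (1 - i3)))
})

test_that("exhaustive enumeration gives the closed-form case probability", {
  g7 <- all_configs(paste0("S", 4:10))
  expect_identical(sum(truth_label(g7)), 121L * 3L) # 3^7 configs, 3 * 729
  expect_equal(mean(truth_label(g7)), 121 / 729)
})

test_that("the rule expansion tops out at interaction order 7", {
  ex <- rule_expansion()
  expect_identical(max(ex$order), 7L)
  # no term assigns two levels to one SNP, and none involves noise SNPs
  pats <- parse_patterns(ex$pattern)
  expect_true(all(vapply(pats, function(p) !anyDuplicated(names(p)), logical(1))))
  expect_true(all(unlist(lapply(pats, names)) %in% paste0("S", 4:10)))
  # the expansion reproduces the label on every configuration
  g7 <- all_configs(paste0("S", 4:10))
  enc <- encode_patterns(g7, ex$pattern)
  recon <- as.numeric(as.matrix(enc) %*% ex$coefficient)
  expect_equal(recon, as.numeric(truth_label(g7)))
})

test_that("case probability and missing heritability follow their closed forms", {
  expect_equal(case_probability(0), 121 / 729)
  expect_equal(case_probability(0.5), 0.5)
  expect_equal(case_probability(0.2), (121 / 729) * 0.8 + (608 / 729) * 0.2)
  expect_lte(case_probability(0.2), 0.30)
  expect_equal(missing_heritability(0), 0)
  expect_equal(missing_heritability(0.5), 1)
  expect_equal(missing_heritability(0.1), 0.504, tolerance = 1e-2)
})

test_that("simulated case fractions track the closed form", {
  set.seed(101)
  sim <- simulate_epistasis(n_train = 60000, n_test = 10, epsilon = 0, p = 15)
  p_hat <- mean(sim$train$Y)
  se <- sqrt(p_hat * (1 - p_hat) / 60000)
  expect_lt(abs(p_hat - 121 / 729), 3 * se)

  sim5 <- simulate_epistasis(n_train = 20000, n_test = 10, epsilon = 0.5, p = 15)
  expect_lt(abs(mean(sim5$train$Y) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("simulation is reproducible under a fixed seed and validates inputs", {
  a <- simulate_epistasis(100, 50, 0.05, seed = 7)
  b <- simulate_epistasis(100, 50, 0.05, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_epistasis(10, 10, epsilon = 0.7), "epsilon")
  expect_error(simulate_epistasis(10, 10, p = 5), "p >= 10")
})

test_that("undersampling hits the class quotas exactly", {
  d1 <- subsample_imbalance(n = 1000, q = 0.025, epsilon = 0.01, seed = 8)
  expect_identical(nrow(d1), 1000L)
  expect_identical(sum(d1$Y), 25L)
  d2 <- subsample_imbalance(n = 1000, q = 0.20, epsilon = 0.01, seed = 9)
  expect_identical(sum(d2$Y), 200L)
  expect_identical(sum(d2$Y == 0), 800L)
})

test_that("undersampling preserves the within-class genotype law", {
  set.seed(102)
  under <- subsample_imbalance(n = 4000, q = 0.5, epsilon = 0, seed = 103)
  plain <- simulate_epistasis(n_train = 40000, n_test = 10, epsilon = 0, seed = 104)$train
  for (cls in 0:1) {
    u <- under[under$Y == cls, ]
    p <- plain[plain$Y == cls, ]
    for (snp in c("S4", "S8", "S12")) {
      fu <- tabulate(u[[snp]] + 1L, 3) / nrow(u)
      fp <- tabulate(p[[snp]] + 1L, 3) / nrow(p)
      expect_lt(max(abs(fu - fp)), 0.05)
    }
  }
})

test_that("bootstrap resampling follows the table proportions", {
  tab1 <- tibble::tibble(A = 1L, B = 2L, class = 1L, count = 7)
  bs <- bootstrap_from_table(tab1, n_train = 25, n_test = 10, seed = 5)
  expect_identical(nrow(bs$train), 25L)
  expect_identical(nrow(bs$test), 10L)
  expect_true(all(bs$train$A == 1L & bs$train$B == 2L & bs$train$Y == 1L))

  tab <- tibble::tibble(
    A = c(0L, 1L, 2L), class = c(0L, 1L, 0L), count = c(50, 30, 20)
  )
  big <- bootstrap_from_table(tab, n_train = 60000, n_test = 10, seed = 6)$train
  freq <- table(factor(big$A, levels = 0:2)) / 60000
  expect_equal(as.numeric(freq), c(0.5, 0.3, 0.2), tolerance = 0.02)
  expect_identical(big$Y, as.integer(big$A == 1L))

  expect_error(
    bootstrap_from_table(tibble::tibble(A = 1L, class = 1L, count = 0)),
    "all zero"
  )
})
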