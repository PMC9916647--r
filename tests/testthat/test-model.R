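test_that("a perfectly predictive pattern is selected first with a large weight", {
  set.seed(121)
  d <- random_labeled_data(120, 4, case_prob = 0.3)
  d$S1 <- ifelse(d$Y == 1, 2L, sample(0:1, nrow(d), replace = TRUE))
  fit <- hiprs(d, delta = 0.05, K = 3)
  expect_identical(fit$selection$pattern[1], "{S1=2}")
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(fit$coefficients[["{S1=2}"]], 2)
  expect_true(fit$separation) # perfect separation triggers the ridge fallback
  expect_identical(fit$settings$ridge > 0, fit$separation)
})

test_that("the score is the affine linear predictor over pattern indicators", {
  model <- structure(
    list(
      coefficients = c("(Intercept)" = 0, "{S1=0}" = 1, "{S2=2}" = -1),
      selection = tibble::tibble(
        rank = 1:2, pattern = c("{S1=0}", "{S2=2}"),
        length = c(1L, 1L), support = c(0.5, 0.5),
        mi = c(0.1, 0.05), redundancy = c(0, 0)
      ),
      settings = list(delta = 0.05, K = 2, l_max = Inf, outcome = "Y", ridge = 0),
      separation = FALSE, n = 10, n_cases = 5, snp_cols = c("S1", "S2")
    ),
    class = "hiprs"
  )
  g <- tibble::tibble(S1 = c(0L, 1L, 0L), S2 = c(0L, 1L, 2L))
  expect_equal(predict(model, g), c(1, 0, 0))
  expect_equal(predict(model, g, type = "response"), stats::plogis(c(1, 0, 0)))
  expect_error(predict(model, tibble::tibble(S1 = 0L)), "lacks SNP")
})

test_that("probabilities are the logistic transform of the score", {
  set.seed(122)
  d <- random_labeled_data(150, 5, case_prob = 0.35)
  fit <- hiprs(d, delta = 0.1, K = 4)
  link <- predict(fit, d)
  prob <- predict(fit, d, type = "response")
  expect_equal(prob, stats::plogis(link))
  expect_true(all(prob > 0 & prob < 1))
  expect_equal(stats::plogis(0), 0.5)
  expect_equal(stats::plogis(1), 1 / (1 + exp(-1)))
  # monotone: ordering by link equals ordering by probability
  expect_identical(order(link), order(prob))
})

test_that("fitting is deterministic and coefficients are logistic MLEs", {
  set.seed(123)
  sim <- simulate_epistasis(400, 100, 0.01, seed = 31)
  f1 <- hiprs(sim$train, delta = 0.1, K = 5)
  f2 <- hiprs(sim$train, delta = 0.1, K = 5)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$selection$pattern, f2$selection$pattern)
  if (!f1$separation) {
    enc <- encode_patterns(sim$train, f1$selection$pattern)
    ref <- stats::glm(sim$train$Y ~ as.matrix(enc), family = stats::binomial())
    expect_equal(unname(f1$coefficients), unname(stats::coef(ref)), tolerance = 1e-8)
  }
})

test_that("coefficients recover a known logistic generative model", {
  set.seed(124)
  n <- 5000
  g <- tibble::as_tibble(as.data.frame(matrix(
    sample(0:2, n * 6, replace = TRUE),
    nrow = n, dimnames = list(NULL, paste0("S", 1:6))
  )))
  truth <- c(-2, 1.5, 2, 2.5)
  eta <- truth[1] +
    truth[2] * (g$S1 == 0) + truth[3] * (g$S3 == 1) + truth[4] * (g$S5 == 2)
  g$Y <- stats::rbinom(n, 1, stats::plogis(eta))
  fit <- hiprs(g, delta = 0.02, K = 3, l_max = 1)
  expect_setequal(fit$selection$pattern, c("{S1=0}", "{S3=1}", "{S5=2}"))
  enc <- encode_patterns(g, fit$selection$pattern)
  ref <- stats::glm(g$Y ~ as.matrix(enc), family = stats::binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  truth_matched <- c(
    truth[1],
    truth[c(2, 3, 4)][match(fit$selection$pattern, c("{S1=0}", "{S3=1}", "{S5=2}"))]
  )
  expect_true(all(abs(fit$coefficients - truth_matched) < 3 * se))
})

test_that("degenerate inputs produce actionable errors and warnings", {
  # cases split between S1 = 0 and S1 = 1, so no pattern reaches support 0.99
  d <- tibble::tibble(S1 = rep(c(0L, 1L, 2L), 10), Y = rep(c(1L, 1L, 0L), 10))
  expect_error(suppressWarnings(hiprs(d, delta = 0.99)), "smaller delta")
  d_all1 <- tibble::tibble(S1 = rep(0:1, 10), Y = rep(1L, 20))
  expect_error(hiprs(d_all1), "both classes")
  d_major <- tibble::tibble(
    S1 = rep(0:2, 20), S2 = rep(c(0L, 1L, 2L), each = 20),
    Y = rep(c(1L, 1L, 0L), 20)
  )
  expect_warning(hiprs(d_major, delta = 0.1, K = 2), "outnumber")
})

test_that("model-size path reuses one selection pass consistently", {
  set.seed(125)
  sim <- simulate_epistasis(300, 100, 0.01, seed = 33)
  path <- hiprs_k_path(sim$train, delta = 0.1, K = c(3, 6))
  single <- hiprs(sim$train, delta = 0.1, K = 3)
  expect_identical(path$K3$coefficients, single$coefficients)
  expect_identical(
    path$K3$selection$pattern,
    path$K6$selection$pattern[1:3]
  )
})

test_that("tidy, glance, and autoplot expose the fitted model", {
  set.seed(126)
  d <- random_labeled_data(120, 4, case_prob = 0.4)
  fit <- hiprs(d, delta = 0.1, K = 3)
  td <- tidy(fit)
  expect_identical(td$term[1], "(Intercept)")
  expect_identical(nrow(td), 4L)
  expect_identical(td$estimate, unname(fit$coefficients))
  gl <- glance(fit)
  expect_identical(gl$K, 3L)
  expect_identical(gl$n, nrow(d))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "K = 3")
})

test_that("cross-validated grid search maximizes mean held-out AUC", {
  set.seed(127)
  sim <- simulate_epistasis(320, 10, 0.01, seed = 41)
  gs <- grid_search_prs(sim$train,
    delta_grid = c(0.05, 0.2), K_grid = c(2, 5),
    folds = 3, seed = 9
  )
  expect_identical(nrow(gs$cv), 4L * 3L)
  expect_identical(as.vector(table(paste(gs$cv$delta, gs$cv$K))), rep(3L, 4L))
  means <- tapply(gs$cv$auc, paste(gs$cv$delta, gs$cv$K), mean)
  expect_equal(gs$best$mean_auc, max(means))

  one <- grid_search_prs(sim$train,
    delta_grid = 0.1, K_grid = 3, folds = 2, seed = 10
  )
  expect_identical(one$best$delta, 0.1)
  expect_identical(one$best$K, 3)
  expect_identical(nrow(one$cv), 2L)
})

test_that("grid search demands enough samples per class for stratification", {
  d <- tibble::tibble(S1 = rep(0:2, 4), Y = c(1L, rep(0L, 11)))
  expect_error(
    grid_search_prs(d, delta_grid = 0.1, K_grid = 2, folds = 4),
    "at least"
  )
})
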