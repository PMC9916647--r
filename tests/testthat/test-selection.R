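test_that("mutual information handles canonical binary cases", {
  expect_equal(mutual_information(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(mutual_information(c(1, 1, 0, 0), c(1, 1, 0, 0)), log(2))
  expect_equal(mutual_information(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0)
  expect_error(mutual_information(c(1, 0), c(1, 0, 0)), "same length")
})

test_that("mutual information matches the 2x2 plug-in oracle and its symmetries", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    x <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
    expect_equal(mutual_information(x, y), oracle_mi(x, y))
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_equal(mutual_information(1 - x, 1 - y), mutual_information(x, y))
    expect_gte(mutual_information(x, y), 0)
  }
})

test_that("ranking orders candidates by relevance to the outcome", {
  set.seed(92)
  d <- random_labeled_data(60, 5)
  cands <- mine_patterns(d, delta = 0.05)
  ranked <- rank_patterns(cands, d)
  expect_s3_class(ranked, "hiprs_ranked")
  expect_true(all(diff(ranked$mi) <= 1e-12))
  # brute-force MI per candidate agrees
  enc <- encode_patterns(d[paste0("S", 1:5)], ranked$pattern)
  brute <- vapply(seq_len(ncol(enc)), function(k) oracle_mi(enc[[k]], d$Y), numeric(1))
  expect_equal(ranked$mi, brute)

  one <- rank_patterns(cands[7, ], d)
  expect_identical(nrow(one), 1L)
  expect_equal(one$mi, oracle_mi(encode_patterns(d, one$pattern)[[1]], d$Y))
})

test_that("a candidate reproducing the outcome exactly ranks first", {
  set.seed(93)
  d <- random_labeled_data(40, 4)
  d$S1 <- ifelse(d$Y == 1, 0L, sample(1:2, nrow(d), replace = TRUE))
  cands <- mine_patterns(d, delta = 0.05)
  ranked <- rank_patterns(cands, d)
  expect_identical(ranked$pattern[1], "{S1=0}")
  expect_equal(ranked$mi[1], oracle_mi(as.integer(d$S1 == 0), d$Y))
})

test_that("greedy selection follows the printed pseudocode literally", {
  # K = 1: just the global relevance argmax
  r1 <- make_ranked(c("{S1=0}", "{S2=1}"), mi = c(0.2, 0.3))
  expect_identical(select_patterns(r1, 1)$pattern, "{S2=1}")

  # mutually disjoint candidates: every iteration takes the zero-redundancy
  # branch, so the selection is top-K by MI
  r2 <- make_ranked(
    c("{S1=0}", "{S2=1}", "{S3=2}", "{S4=0}"),
    mi = c(0.10, 0.40, 0.25, 0.33)
  )
  expect_identical(
    select_patterns(r2, 3)$pattern,
    c("{S2=1}", "{S4=0}", "{S3=2}")
  )

  # literal zero-redundancy branch: A = {S1=0,S2=1,S3=2} picked first;
  # B = {S9=0} disjoint (W = 0), C shares two pairs with A. The literal rule
  # maximizes relevance over ALL remaining, so C (V = 0.45) beats B (V = 0.40)
  pats <- c("{S1=0,S2=1,S3=2}", "{S9=0}", "{S1=0,S2=1}")
  r3 <- make_ranked(pats, mi = c(0.50, 0.40, 0.45))
  lit <- select_patterns(r3, 2)
  expect_identical(lit$pattern, c("{S1=0,S2=1,S3=2}", "{S1=0,S2=1}"))
  # the restricted variant confines the argmax to zero-redundancy candidates
  res <- select_patterns(r3, 2, zero_redundancy = "restricted")
  expect_identical(res$pattern, c("{S1=0,S2=1,S3=2}", "{S9=0}"))
})

test_that("selection agrees with an independent greedy transcription", {
  set.seed(94)
  for (rep in 1:5) {
    d <- random_labeled_data(80, 5)
    cands <- mine_patterns(d, delta = 0.15)
    ranked <- rank_patterns(cands, d)
    K <- min(6, nrow(ranked))
    got <- select_patterns(ranked, K)$pattern
    want <- oracle_mrmr(ranked$pattern, d, K = K)
    expect_identical(got, want)
  }
})

test_that("selection has the prefix property and exhausts without duplicates", {
  set.seed(95)
  d <- random_labeled_data(70, 5)
  ranked <- rank_patterns(mine_patterns(d, delta = 0.1), d)
  K <- min(10, nrow(ranked))
  full <- select_patterns(ranked, K)$pattern
  expect_identical(anyDuplicated(full), 0L)
  for (k in seq_len(K - 1)) {
    expect_identical(select_patterns(ranked, k)$pattern, full[seq_len(k)])
  }
  everything <- select_patterns(ranked, nrow(ranked))$pattern
  expect_setequal(everything, ranked$pattern)
  expect_warning(
    all_of_them <- select_patterns(ranked, nrow(ranked) + 5),
    "exceeds"
  )
  expect_identical(all_of_them$pattern, everything)
})

test_that("recorded redundancy is the mean similarity to prior picks", {
  set.seed(96)
  d <- random_labeled_data(80, 5)
  ranked <- rank_patterns(mine_patterns(d, delta = 0.1), d)
  sel <- select_patterns(ranked, min(6, nrow(ranked)))
  for (k in seq_len(nrow(sel))[-1]) {
    manual <- mean(vapply(
      seq_len(k - 1),
      function(j) pattern_similarity(sel$pattern[k], sel$pattern[j]),
      numeric(1)
    ))
    expect_equal(sel$redundancy[k], manual)
  }
})
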