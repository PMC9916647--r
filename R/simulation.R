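#' Epistatic phenotype simulator
#'
#' Generates genotype/outcome data from a fully specified non-linear
#' generative model over `p >= 10` independent SNPs, each uniform on
#' \{0, 1, 2\}. The noiseless phenotype is 1 exactly when one of three allele
#' rules fires:
#'
#' * **A**: `S4 = 2, S5 = 2, S6 = 2, S7 = 2`
#' * **B**: `S4 = 1, S5 = 1, S6 != 2, S7 != 2`
#' * **C**: `S8 = S9 = S10` (any common level)
#'
#' The observed outcome flips the noiseless label independently per
#' observation with probability `epsilon`, which injects missing heritability
#' (see [missing_heritability()]). SNPs outside the rules (`S1..S3`,
#' `S11..Sp`) are pure noise predictors. Under these rules the noiseless case
#' probability is exactly 121/729 (about 16.6%).
#'
#' @param n_train,n_test Training and test sample sizes.
#' @param epsilon Label-flip probability in `[0, 0.5]`.
#' @param p Number of SNPs (at least 10; default 15).
#' @param q Optional target case fraction in `(0, 1)` for the *training* set;
#'   when set, training data are produced by [subsample_imbalance()] (test
#'   data are never undersampled).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with tibbles `train` and `test`, each with columns
#'   `S1..Sp` (integer allele categories) and `Y` (binary outcome).
#' @examples
#' sim <- simulate_epistasis(n_train = 200, n_test = 100, epsilon = 0.01, seed = 1)
#' mean(sim$train$Y)
#' @export
simulate_epistasis <- function(n_train = 1000, n_test = 500, epsilon = 0.01,
                               p = 15, q = NULL, seed = NULL) {
  check_sim_args(epsilon, p, q)
  if (!is.null(seed)) set.seed(seed)
  train <- if (is.null(q)) {
    draw_epistasis(n_train, epsilon, p)
  } else {
    subsample_imbalance(n = n_train, q = q, epsilon = epsilon, p = p)
  }
  test <- draw_epistasis(n_test, epsilon, p)
  list(train = train, test = test)
}

check_sim_args <- function(epsilon, p, q) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0, epsilon <= 0.5)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 10)
  if (!is.null(q)) stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  invisible(TRUE)
}

draw_epistasis <- function(n, epsilon, p) {
  geno <- matrix(
    sample(0:2, n * p, replace = TRUE),
    nrow = n, ncol = p, dimnames = list(NULL, paste0("S", seq_len(p)))
  )
  out <- tibble::as_tibble(geno)
  y_true <- truth_label(out)
  flip <- stats::rbinom(n, 1L, epsilon)
  out$Y <- as.integer((1L - flip) * y_true + flip * (1L - y_true))
  out
}

#' Noiseless phenotype rule of the epistatic simulator
#'
#' Evaluates the rule disjunction A | B | C (see [simulate_epistasis()]) on
#' each row of a genotype table. Equivalently, with indicator products
#' `I1 = 1\{S4=2\}...1\{S7=2\}`, `I2 = 1\{S4=1\}1\{S5=1\}(1 - 1\{S6=2\}1\{S7=2\})` and
#' `I3 = sum_l 1\{S8=l\}1\{S9=l\}1\{S10=l\}`, the label is
#' `1 - (1 - I1)(1 - I2)(1 - I3)`.
#'
#' @param geno A data frame or matrix with columns `S4..S10` (or, failing
#'   that, at least 10 positional columns, of which positions 4-10 are used).
#' @return An integer 0/1 vector, one label per row.
#' @examples
#' truth_label(tibble::tibble(
#'   S4 = 2L, S5 = 2L, S6 = 2L, S7 = 2L, S8 = 0L, S9 = 1L, S10 = 2L
#' ))
#' @export
truth_label <- function(geno) {
  r <- epistasis_rules(geno)
  as.integer(r$A | r$B | r$C)
}

#' @rdname truth_label
#' @return `epistasis_rules()`: a tibble with logical columns `A`, `B`, `C`,
#'   one row per input row.
#' @export
epistasis_rules <- function(geno) {
  geno <- as.data.frame(geno)
  need <- paste0("S", 4:10)
  if (all(need %in% names(geno))) {
    g <- geno[need]
  } else if (ncol(geno) >= 10L) {
    g <- geno[, 4:10]
    names(g) <- need
  } else {
    stop("genotypes must provide columns S4..S10 (or at least 10 columns)",
      call. = FALSE
    )
  }
  tibble::tibble(
    A = g$S4 == 2 & g$S5 == 2 & g$S6 == 2 & g$S7 == 2,
    B = g$S4 == 1 & g$S5 == 1 & g$S6 != 2 & g$S7 != 2,
    C = g$S8 == g$S9 & g$S9 == g$S10
  )
}

#' Closed-form case probability under label noise
#'
#' The noiseless case probability of the epistatic generative model is
#' exactly `121/729`. With label-flip probability `epsilon`, the observed
#' case probability is `p * (1 - epsilon) + (1 - p) * epsilon` with
#' `p = 121/729`; it stays at or below 30% for `epsilon <= 0.2`, keeping
#' cases the minority class.
#'
#' @param epsilon Label-flip probability (vectorized).
#' @return Case probability in `[0, 1]`.
#' @examples
#' case_probability(0) # 121/729
#' @export
case_probability <- function(epsilon = 0) {
  p_tilde <- 121 / 729
  p_tilde * (1 - epsilon) + (1 - p_tilde) * epsilon
}

#' Missing heritability induced by label noise
#'
#' Fraction of outcome variance that genotypes cannot explain under the
#' epistatic simulator with flip probability `epsilon`:
#' `1 - (1 - 2 epsilon)^2 p(1 - p) / (pY (1 - pY))` where `p = 121/729` is
#' the noiseless case probability and `pY` the noisy one. It is 0 at
#' `epsilon = 0` and 1 at `epsilon = 0.5` (labels independent of genotype);
#' at `epsilon = 0.1` it is about 0.504.
#'
#' @param epsilon Label-flip probability (vectorized).
#' @return Fraction in `[0, 1]`.
#' @examples
#' missing_heritability(0.1)
#' @export
missing_heritability <- function(epsilon) {
  p_tilde <- 121 / 729
  p_y <- case_probability(epsilon)
  1 - (1 - 2 * epsilon)^2 * p_tilde * (1 - p_tilde) / (p_y * (1 - p_y))
}

#' Undersample the simulator to an exact case fraction
#'
#' Produces a training set of exactly `round(n * q)` cases and
#' `n - round(n * q)` controls: fresh observations are drawn from the
#' epistatic simulator iteratively until both class quotas are met, then each
#' class is truncated to its quota, keeping the earliest-drawn observations.
#' Within-class genotype distributions are untouched — only the class mix
#' changes.
#'
#' @param n Total training size (default 1000).
#' @param q Target case fraction in `(0, 1)`.
#' @param epsilon Label-flip probability.
#' @param p Number of SNPs.
#' @param seed Optional integer seed.
#' @param batch Draw size per iteration (default `n`).
#' @return A tibble with `S1..Sp` and `Y`, `n` rows.
#' @examples
#' d <- subsample_imbalance(n = 200, q = 0.1, epsilon = 0.01, seed = 1)
#' sum(d$Y)
#' @export
subsample_imbalance <- function(n = 1000, q, epsilon = 0.01, p = 15,
                                seed = NULL, batch = n) {
  check_sim_args(epsilon, p, q)
  if (!is.null(seed)) set.seed(seed)
  n_cases <- round(n * q)
  n_controls <- n - n_cases
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  acc <- NULL
  repeat {
    acc <- rbind(acc, draw_epistasis(batch, epsilon, p))
    if (sum(acc$Y == 1L) >= n_cases && sum(acc$Y == 0L) >= n_controls) break
  }
  keep <- c(
    which(acc$Y == 1L)[seq_len(n_cases)],
    which(acc$Y == 0L)[seq_len(n_controls)]
  )
  acc[sort(keep), ]
}

#' Bootstrap datasets from an empirical genotype-by-class table
#'
#' Draws i.i.d. (genotype, class) observations with probabilities
#' proportional to the counts (or frequencies) of an empirical
#' genotype-by-class table — bootstrap resampling of the cohort the table
#' summarizes. Useful for emulating published case-control joint
#' distributions over a few loci.
#'
#' @param table A data frame with one or more genotype columns, a class
#'   column, and a count column.
#' @param n_train,n_test Sizes of the two generated datasets (defaults 5000
#'   and 1000).
#' @param seed Optional integer seed.
#' @param class_col,count_col Names of the class and count columns (defaults
#'   `"class"`, `"count"`).
#' @return A list with tibbles `train` and `test`; genotype columns as in
#'   `table` plus a binary `Y`.
#' @examples
#' tab <- tibble::tibble(
#'   M235 = c(0L, 2L), T174M = c(1L, 1L), ID = c(0L, 2L),
#'   class = c(0L, 1L), count = c(30, 10)
#' )
#' bootstrap_from_table(tab, n_train = 50, n_test = 20, seed = 1)$train
#' @export
bootstrap_from_table <- function(table, n_train = 5000, n_test = 1000,
                                 seed = NULL, class_col = "class",
                                 count_col = "count") {
  stopifnot(is.data.frame(table), class_col %in% names(table), count_col %in% names(table))
  counts <- table[[count_col]]
  if (any(counts < 0) || anyNA(counts)) stop("table counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("table counts are all zero: nothing to resample", call. = FALSE)
  if (!all(table[[class_col]] %in% c(0, 1))) {
    stop("class column must be binary 0/1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  geno_cols <- setdiff(names(table), c(class_col, count_col))
  draw <- function(n) {
    idx <- sample.int(nrow(table), n, replace = TRUE, prob = counts)
    out <- tibble::as_tibble(table[idx, geno_cols, drop = FALSE])
    out$Y <- as.integer(table[[class_col]][idx])
    out
  }
  list(train = draw(n_train), test = draw(n_test))
}

#' Indicator-product expansion of the phenotype rule
#'
#' Expands the noiseless phenotype `1 - (1 - I1)(1 - I2)(1 - I3)` of the
#' epistatic simulator into a linear combination of allele-pattern indicator
#' terms, dropping products that vanish identically (a product assigning two
#' different levels to the same SNP is identically zero — in particular
#' `I1 * I2`). The surviving terms give the exact interaction representation
#' of the generative rule set; the deepest terms have order 7 (rule A x
#' rule C: four SNPs plus three).
#'
#' @return A tibble with columns `pattern`, `coefficient`, and `order`,
#'   sorted by order then pattern.
#' @examples
#' max(rule_expansion()$order) # 7
#' @export
rule_expansion <- function() {
  # monomial: list(coef = numeric, pairs = named integer vector)
  mono <- function(coef, snps = character(), lvls = integer()) {
    list(coef = coef, pairs = stats::setNames(as.integer(lvls), snps))
  }
  # product of two monomials; NULL when indicators conflict (identically zero)
  mono_mult <- function(a, b) {
    shared <- intersect(names(a$pairs), names(b$pairs))
    if (any(a$pairs[shared] != b$pairs[shared])) return(NULL)
    pairs <- c(a$pairs, b$pairs[setdiff(names(b$pairs), names(a$pairs))])
    list(coef = a$coef * b$coef, pairs = pairs)
  }
  poly_mult <- function(pa, pb) {
    out <- list()
    for (a in pa) {
      for (b in pb) {
        m <- mono_mult(a, b)
        if (!is.null(m)) out[[length(out) + 1L]] <- m
      }
    }
    poly_simplify(out)
  }
  poly_simplify <- function(p) {
    keys <- vapply(p, function(m) {
      if (length(m$pairs) == 0L) {
        return("")
      }
      o <- order(names(m$pairs), method = "radix")
      paste0(names(m$pairs)[o], "=", m$pairs[o], collapse = ",")
    }, character(1))
    out <- list()
    for (k in unique(keys)) {
      idx <- which(keys == k)
      coef <- sum(vapply(p[idx], `[[`, numeric(1), "coef"))
      if (coef != 0) {
        m <- p[[idx[1]]]
        m$coef <- coef
        out[[length(out) + 1L]] <- m
      }
    }
    out
  }
  i1 <- list(mono(1, paste0("S", 4:7), c(2, 2, 2, 2)))
  # rule B: S4 = 1, S5 = 1, S6 != 2, S7 != 2 — each of S6, S7 individually
  # off level 2, i.e. 1{1}(S4) 1{1}(S5) (1 - 1{2}(S6)) (1 - 1{2}(S7))
  i2 <- poly_mult(
    poly_mult(
      list(mono(1, paste0("S", 4:5), c(1, 1))),
      list(mono(1), mono(-1, "S6", 2))
    ),
    list(mono(1), mono(-1, "S7", 2))
  )
  i3 <- lapply(0:2, function(l) mono(1, paste0("S", 8:10), rep(l, 3)))
  one <- list(mono(1))
  neg <- function(p) lapply(p, function(m) { m$coef <- -m$coef; m })
  complement <- function(p) poly_simplify(c(one, neg(p))) # 1 - p
  prod_all <- poly_mult(poly_mult(complement(i1), complement(i2)), complement(i3))
  expansion <- poly_simplify(c(one, neg(prod_all)))
  expansion <- Filter(function(m) length(m$pairs) > 0L, expansion)
  out <- tibble::tibble(
    pattern = vapply(expansion, function(m) {
      format_patterns(list(m$pairs), snp_order = paste0("S", 1:15))
    }, character(1)),
    coefficient = vapply(expansion, `[[`, numeric(1), "coef"),
    order = vapply(expansion, function(m) length(m$pairs), integer(1))
  )
  dplyr::arrange(out, .data$order, .data$pattern)
}
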