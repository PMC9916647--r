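# Independent oracles used to cross-check the implementation. They are
# deliberately naive (enumeration / pair counting / literal greedy loops) and
# share no code with the package internals they verify.

# random genotype table with a binary outcome
random_labeled_data <- function(n, p, levels = 0:2, case_prob = 0.4) {
  d <- as.data.frame(matrix(
    sample(levels, n * p, replace = TRUE),
    nrow = n, dimnames = list(NULL, paste0("S", seq_len(p)))
  ))
  d$Y <- stats::rbinom(n, 1L, case_prob)
  # ensure both classes
  if (sum(d$Y) == 0) d$Y[1] <- 1L
  if (sum(d$Y) == n) d$Y[1] <- 0L
  tibble::as_tibble(d)
}

# does `row` (1-row data frame) carry every (snp, level) pair of `pat`?
oracle_match <- function(pat, row) {
  all(vapply(names(pat), function(s) row[[s]] == pat[[s]], logical(1)))
}

# exhaustive frequent-pattern enumeration: all SNP subsets x level combos
oracle_mine <- function(data, outcome = "Y", delta, l_max = Inf, levels = 0:2) {
  snps <- setdiff(names(data), outcome)
  cases <- data[data[[outcome]] == 1, snps, drop = FALSE]
  n_o <- nrow(cases)
  out <- list()
  p <- length(snps)
  for (size in seq_len(min(p, l_max))) {
    subsets <- utils::combn(snps, size, simplify = FALSE)
    for (sub in subsets) {
      grids <- expand.grid(rep(list(levels), size))
      for (g in seq_len(nrow(grids))) {
        pat <- stats::setNames(as.integer(grids[g, ]), sub)
        cnt <- sum(vapply(
          seq_len(n_o),
          function(i) oracle_match(pat, cases[i, , drop = FALSE]),
          logical(1)
        ))
        if (cnt / n_o > delta) {
          out[[length(out) + 1L]] <- list(pat = pat, support = cnt / n_o)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(pattern = character(), support = numeric()))
  }
  tibble::tibble(
    pattern = vapply(out, function(x) {
      p <- x$pat[order(match(names(x$pat), snps))]
      paste0("{", paste0(names(p), "=", p, collapse = ","), "}")
    }, character(1)),
    support = vapply(out, `[[`, numeric(1), "support")
  )
}

# AUC by explicit concordant/discordant/tied pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# plug-in mutual information from an explicitly tabulated 2x2 joint
oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in 0:1) {
    for (b in 0:1) {
      nab <- sum(x == a & y == b)
      if (nab > 0) {
        total <- total + (nab / n) * log((nab / n) / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  max(total, 0)
}

# literal transcription of the greedy mRMR pseudocode, driven by the
# package's public mutual_information/pattern_similarity primitives
oracle_mrmr <- function(patterns, data, outcome = "Y", K) {
  enc <- encode_patterns(data[setdiff(names(data), outcome)], patterns)
  v <- vapply(seq_along(patterns), function(i) {
    mutual_information(enc[[i]], data[[outcome]])
  }, numeric(1))
  left <- seq_along(patterns)
  picked <- integer(0)
  picked <- which.max(v)
  left <- setdiff(left, picked)
  while (length(picked) < K && length(left) > 0) {
    w <- vapply(left, function(i) {
      mean(vapply(picked, function(j) pattern_similarity(patterns[i], patterns[j]), numeric(1)))
    }, numeric(1))
    star <- if (min(w) == 0) left[which.max(v[left])] else left[which.max(v[left] / w)]
    picked <- c(picked, star)
    left <- setdiff(left, star)
  }
  patterns[picked]
}

# build a ranked-candidates object directly, for controlled selection tests
make_ranked <- function(patterns, mi, support = rep(0.5, length(patterns))) {
  out <- tibble::tibble(
    pattern = patterns,
    length = lengths(parse_patterns(patterns)),
    support = support,
    mi = mi
  )
  ord <- order(-out$mi, -out$support, out$length, out$pattern, method = "radix")
  out <- out[ord, ]
  class(out) <- c("hiprs_ranked", class(out))
  out
}
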