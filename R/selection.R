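#' Empirical mutual information between two binary vectors
#'
#' Plug-in mutual information over the empirical 2x2 joint distribution, in
#' nats. Cells with zero count contribute zero (the 0 log 0 := 0 convention),
#' and tiny negative values from floating-point cancellation are clamped at
#' zero. Used as the relevance of an encoded interaction feature for the
#' outcome.
#'
#' @param feature,outcome Equal-length vectors with values in \{0, 1\}.
#' @return A single non-negative number (nats).
#' @examples
#' mutual_information(c(1, 1, 0, 0), c(1, 1, 0, 0)) # log(2)
#' mutual_information(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0
#' @export
mutual_information <- function(feature, outcome) {
  if (length(feature) != length(outcome)) {
    stop("feature and outcome must have the same length", call. = FALSE)
  }
  stopifnot(all(feature %in% c(0, 1)), all(outcome %in% c(0, 1)))
  mi_binary_cols(matrix(as.numeric(feature), ncol = 1), as.numeric(outcome))[1]
}

# Vectorized plug-in MI (nats) of each 0/1 column of `mat` with binary `y`.
mi_binary_cols <- function(mat, y) {
  n <- nrow(mat)
  n1y1 <- as.numeric(crossprod(mat, y))
  n1 <- colSums(mat)
  ny1 <- sum(y)
  cells <- cbind(
    n - n1 - ny1 + n1y1, # feature 0, outcome 0
    ny1 - n1y1, # feature 0, outcome 1
    n1 - n1y1, # feature 1, outcome 0
    n1y1 # feature 1, outcome 1
  )
  marg_f <- cbind(n - n1, n - n1, n1, n1)
  marg_y <- matrix(c(n - ny1, ny1, n - ny1, ny1), nrow = nrow(cells), ncol = 4, byrow = TRUE)
  term <- cells * log((cells * n) / (marg_f * marg_y))
  term[cells == 0] <- 0
  pmax(rowSums(term) / n, 0)
}

#' Rank candidate patterns by mutual information with the outcome
#'
#' Encodes each candidate pattern over the full training data (cases and
#' controls) and computes its empirical mutual information with the outcome.
#' The returned table is the relevance-ranked candidate list: rows are sorted
#' by MI (descending), with ties broken by higher support, shorter length,
#' then canonical pattern order, so the ranking is deterministic.
#'
#' @param candidates A `hiprs_candidates` tibble from [mine_patterns()], or
#'   any data frame with a `pattern` column (a `support` column is carried
#'   through if present).
#' @param data The labeled training data (genotypes plus outcome).
#' @param outcome Name of the outcome column (default `"Y"`).
#' @return A tibble of class `hiprs_ranked` with columns `pattern`, `length`,
#'   `support`, and `mi` (nats), sorted by relevance. The binary encoding is
#'   kept in the `encoded` attribute for downstream reuse.
#' @export
rank_patterns <- function(candidates, data, outcome = "Y") {
  if (nrow(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  y <- check_outcome(data, outcome)
  snp_order <- attr(candidates, "snp_cols")
  if (is.null(snp_order)) snp_order <- setdiff(names(data), outcome)
  pats <- as_pattern_list(candidates, snp_order = snp_order)
  enc <- encode_pattern_matrix(data, pats)
  mi <- mi_binary_cols(enc, y)
  support <- if ("support" %in% names(candidates)) candidates$support else rep(NA_real_, length(pats))
  len <- lengths(pats)
  key <- pattern_canon_key(pats, snp_order)
  ord <- order(-mi, -support, len, key, method = "radix")
  fmt <- format_patterns(pats, snp_order = snp_order)
  out <- tibble::tibble(
    pattern = fmt[ord],
    length = len[ord],
    support = support[ord],
    mi = mi[ord]
  )
  class(out) <- c("hiprs_ranked", class(out))
  attr(out, "pats") <- pats[ord]
  attr(out, "encoded") <- enc[, ord, drop = FALSE]
  attr(out, "outcome") <- y
  attr(out, "snp_cols") <- attr(candidates, "snp_cols")
  out
}

#' Greedy minimum-redundancy/maximum-relevance pattern selection
#'
#' Selects `K` interaction patterns from a relevance-ranked candidate list.
#' The first pick is the globally most relevant candidate. Each subsequent
#' iteration computes, for every remaining candidate, its relevance `V` (MI
#' with the outcome) and its average redundancy `W` — the mean pattern
#' similarity to the already-picked set. If the minimum `W` over the remaining
#' candidates is zero, the iteration selects the most relevant remaining
#' candidate outright; otherwise it selects the candidate maximizing `V / W`.
#'
#' The zero-redundancy branch is implemented literally as the greedy
#' pseudocode states it: the relevance argmax runs over *all* remaining
#' candidates, not only those with zero redundancy. Set
#' `zero_redundancy = "restricted"` to confine that argmax to candidates with
#' `W == 0` instead. Every argmax breaks ties by higher support, shorter
#' length, then canonical pattern order.
#'
#' @param ranked A `hiprs_ranked` tibble from [rank_patterns()].
#' @param K Number of patterns to select. If `K` exceeds the number of
#'   candidates, all candidates are returned with a warning.
#' @param zero_redundancy `"literal"` (default) or `"restricted"`; see above.
#' @return A tibble of class `hiprs_selection` with columns `rank`, `pattern`,
#'   `length`, `support`, `mi`, and `redundancy` (the average similarity to
#'   the previously picked set at selection time; 0 for the first pick).
#' @export
select_patterns <- function(ranked, K, zero_redundancy = c("literal", "restricted")) {
  zero_redundancy <- match.arg(zero_redundancy)
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1)
  if (!inherits(ranked, "hiprs_ranked")) {
    stop("`ranked` must come from rank_patterns()", call. = FALSE)
  }
  n_cand <- nrow(ranked)
  if (K > n_cand) {
    warning("K = ", K, " exceeds the ", n_cand, " candidates; returning all of them",
      call. = FALSE
    )
    K <- n_cand
  }
  pats <- as_pattern_list(ranked)
  # item incidence over the union (snp, level) alphabet: pairwise pattern
  # similarity is an inner product of incidence rows
  alphabet <- unique(unlist(lapply(pats, function(p) paste0(names(p), "=", p))))
  inc <- matrix(0, nrow = n_cand, ncol = length(alphabet))
  for (i in seq_len(n_cand)) {
    inc[i, match(paste0(names(pats[[i]]), "=", pats[[i]]), alphabet)] <- 1
  }
  v <- ranked$mi
  # rows are pre-sorted by (V, support, -length, canonical order), so the
  # first index attaining a maximum is already the tie-broken argmax
  picked <- integer(K)
  redundancy <- numeric(K)
  remaining <- rep(TRUE, n_cand)
  sum_sim <- numeric(n_cand) # running sum of similarities to picked set
  picked[1] <- 1L
  remaining[1] <- FALSE
  sum_sim <- sum_sim + as.numeric(inc %*% inc[1L, ])
  k <- 1L
  while (k < K) {
    w <- sum_sim / k
    idx <- which(remaining)
    if (min(w[idx]) == 0) {
      pool <- if (zero_redundancy == "restricted") idx[w[idx] == 0] else idx
      best <- pool[which.max(v[pool])]
    } else {
      best <- idx[which.max(v[idx] / w[idx])]
    }
    k <- k + 1L
    picked[k] <- best
    redundancy[k] <- w[best]
    remaining[best] <- FALSE
    sum_sim <- sum_sim + as.numeric(inc %*% inc[best, ])
  }
  out <- ranked[picked, c("pattern", "length", "support", "mi")]
  out <- tibble::add_column(out, rank = seq_len(K), .before = 1)
  out$redundancy <- redundancy
  class(out) <- c("hiprs_selection", setdiff(class(out), "hiprs_ranked"))
  attr(out, "pats") <- pats[picked]
  enc <- attr(ranked, "encoded")
  attr(out, "encoded") <- if (is.null(enc)) NULL else enc[, picked, drop = FALSE]
  attr(out, "outcome") <- attr(ranked, "outcome")
  attr(out, "zero_redundancy") <- zero_redundancy
  out
}
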