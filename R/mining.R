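#' Split a labeled dataset into case and control indices
#'
#' Cases are the observations with outcome 1 (the minority class under the
#' rare-outcome assumption); controls carry outcome 0. Pattern mining scans
#' the case class only.
#'
#' @param data A data frame with genotype columns and a binary outcome column.
#' @param outcome Name of the outcome column (default `"Y"`).
#' @return A list with integer index vectors `cases` and `controls`.
#' @examples
#' d <- tibble::tibble(S1 = c(0L, 1L, 2L, 0L), Y = c(1L, 0L, 1L, 0L))
#' minority_split(d)
#' @export
minority_split <- function(data, outcome = "Y") {
  y <- check_outcome(data, outcome)
  cases <- which(y == 1L)
  controls <- which(y == 0L)
  if (length(cases) == 0L) {
    stop("no observations in the positive class: nothing to mine", call. = FALSE)
  }
  if (length(controls) == 0L) {
    warning("no controls in the data; the outcome is constant", call. = FALSE)
  }
  list(cases = cases, controls = controls)
}

#' Mine frequent allele patterns from the case class
#'
#' Enumerates every interaction pattern whose empirical frequency among cases
#' is strictly greater than `delta` and whose length is at most `l_max`.
#' Support is anti-monotone (a super-pattern can never be more frequent than
#' any of its sub-patterns), so the search proceeds depth-first over
#' (SNP, level) items with tidset intersection, pruning any branch that falls
#' to or below the threshold. The result is exactly the frequent-pattern set a
#' level-wise Apriori search would return.
#'
#' Items are built from the levels actually observed in the cases, so an
#' allele level absent from the case class generates no candidates. Output
#' rows are ordered by support (descending), ties by canonical pattern order.
#'
#' @param data A data frame with genotype columns and a binary outcome column.
#' @param outcome Name of the outcome column (default `"Y"`).
#' @param delta Support threshold in `[0, 1)`; retained patterns have case
#'   frequency strictly above it. Default 0.05.
#' @param l_max Maximum pattern length (number of SNPs); `Inf` for unbounded.
#' @param snp_cols Optional character vector of genotype columns; defaults to
#'   every column except `outcome`.
#' @param levels Allele-level alphabet (default `0:2`).
#' @return A tibble of class `hiprs_candidates` with columns `pattern`
#'   (canonical string), `length`, and `support` (case-class frequency), and
#'   attributes `delta`, `l_max`, `n_cases`, and `snp_cols`.
#' @examples
#' d <- tibble::tibble(
#'   S1 = c(0L, 0L, 0L, 1L), S2 = c(1L, 1L, 2L, 1L),
#'   Y = c(1L, 1L, 1L, 1L)
#' )
#' mine_patterns(d, delta = 0.5, l_max = 2)
#' @export
mine_patterns <- function(data, outcome = "Y", delta = 0.05, l_max = Inf,
                          snp_cols = NULL, levels = 0:2) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  stopifnot(is.numeric(l_max), length(l_max) == 1L, l_max >= 1)
  snp_cols <- infer_snp_cols(data, outcome, snp_cols)
  validate_genotypes(data, snp_cols, levels)
  split <- minority_split(data, outcome)
  if (delta >= 1) {
    warning("delta >= 1 leaves no pattern above threshold; returning an empty set",
      call. = FALSE
    )
    return(new_candidates(
      character(), integer(), numeric(),
      delta, l_max, length(split$cases), snp_cols,
      parsed = list()
    ))
  }
  cases <- data[split$cases, snp_cols, drop = FALSE]
  res <- eclat_mine(cases, delta, l_max, levels)
  key <- pattern_sort_key(res$items, res$item_snp_idx, res$item_level)
  ord <- order(-res$count, key, method = "radix")
  parsed <- lapply(res$items[ord], function(it) {
    stats::setNames(res$item_level[it], snp_cols[res$item_snp_idx[it]])
  })
  pats <- vapply(parsed, function(p) {
    paste0("{", paste0(names(p), "=", p, collapse = ","), "}")
  }, character(1))
  new_candidates(
    pats, lengths(res$items)[ord], res$count[ord] / nrow(cases),
    delta, l_max, nrow(cases), snp_cols,
    parsed = parsed
  )
}

new_candidates <- function(pattern, length, support, delta, l_max, n_cases, snp_cols,
                           parsed = NULL) {
  out <- tibble::tibble(pattern = pattern, length = as.integer(length), support = support)
  attr(out, "pats") <- parsed
  class(out) <- c("hiprs_candidates", class(out))
  attr(out, "delta") <- delta
  attr(out, "l_max") <- l_max
  attr(out, "n_cases") <- n_cases
  attr(out, "snp_cols") <- snp_cols
  out
}

# Depth-first frequent-pattern search over (snp, level) items.
# Transactions are the case rows; each holds exactly one item per SNP, so
# extensions only ever consider items of strictly later SNP columns.
eclat_mine <- function(cases, delta, l_max, levels) {
  n_cases <- nrow(cases)
  p <- ncol(cases)
  # strict "> delta": integer counts, tiny relative slack against FP rounding
  min_count <- delta * n_cases * (1 + 1e-12)
  item_snp_idx <- integer(0)
  item_level <- integer(0)
  item_tids <- list()
  for (j in seq_len(p)) {
    col <- cases[[j]]
    for (l in levels) {
      tids <- which(col == l)
      if (length(tids) > min_count) {
        item_snp_idx <- c(item_snp_idx, j)
        item_level <- c(item_level, as.integer(l))
        item_tids[[length(item_tids) + 1L]] <- tids
      }
    }
  }
  n_items <- length(item_tids)
  acc_items <- vector("list", 2048L)
  acc_count <- integer(2048L)
  n_acc <- 0L
  push <- function(items, count) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc_count)) {
      length(acc_items) <<- 2L * length(acc_items)
      length(acc_count) <<- 2L * length(acc_count)
    }
    acc_items[[n_acc]] <<- items
    acc_count[n_acc] <<- count
  }
  recurse <- function(prefix, tids, start_item, depth) {
    for (i in seq.int(start_item, n_items)) {
      if (depth > 1L && item_snp_idx[i] == item_snp_idx[prefix[depth - 1L]]) next
      sub <- tids[cases[[item_snp_idx[i]]][tids] == item_level[i]]
      if (length(sub) > min_count) {
        items <- c(prefix, i)
        push(items, length(sub))
        if (depth < l_max && i < n_items) recurse(items, sub, i + 1L, depth + 1L)
      }
    }
  }
  if (n_items > 0L) {
    all_tids <- seq_len(n_cases)
    for (i in seq_len(n_items)) {
      push(i, length(item_tids[[i]]))
      if (l_max > 1 && i < n_items) recurse(i, item_tids[[i]], i + 1L, 2L)
    }
  }
  list(
    items = acc_items[seq_len(n_acc)],
    count = acc_count[seq_len(n_acc)],
    item_snp_idx = item_snp_idx,
    item_level = item_level
  )
}

# Deterministic total order on patterns: lexicographic over the canonical
# (snp position, level) pair sequence; a proper prefix sorts first.
pattern_sort_key <- function(items, item_snp_idx, item_level) {
  vapply(items, function(it) {
    paste(sprintf("%04d.%d", item_snp_idx[it], item_level[it]), collapse = "|")
  }, character(1))
}

#' @export
print.hiprs_candidates <- function(x, ...) {
  cat(
    "Frequent allele patterns: ", nrow(x), " candidates",
    " (delta = ", attr(x, "delta"),
    ", l_max = ", attr(x, "l_max"),
    ", cases = ", attr(x, "n_cases"), ")\n",
    sep = ""
  )
  NextMethod()
}
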