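#' Allele interaction patterns
#'
#' An interaction pattern is a conjunction of (SNP, allele level) conditions,
#' e.g. `{S2=1,S3=0,S5=1}`: it evaluates to 1 on a genotype exactly when every
#' listed SNP carries the listed level, and to 0 otherwise (a product of
#' per-SNP indicator functions). A pattern with a single pair is an ordinary
#' allele dummy. Levels follow the additive SNP coding: 0 = major-allele
#' homozygote, 1 = heterozygote, 2 = minor-allele homozygote.
#'
#' Internally a pattern is a named integer vector (names = SNP identifiers,
#' values = levels) in canonical order: by SNP identifier, then level.
#' Equality is order-insensitive; the canonical form makes serialization and
#' tie-breaking deterministic.
#'
#' @param x Character vector of pattern strings such as `"{S1=0,S2=1}"`
#'   (braces optional), or a list of named integer vectors.
#' @param snp_order Optional character vector giving the SNP ordering used to
#'   canonicalize pairs (typically the genotype column order). SNPs absent
#'   from `snp_order` sort after it, alphabetically.
#' @return `parse_patterns()`: a list of named integer vectors in canonical
#'   order. `format_patterns()`: a character vector of `{snp=level,...}`
#'   strings.
#' @examples
#' p <- parse_patterns(c("{S2=1,S3=0,S5=1}", "S1=0"))
#' format_patterns(p)
#' @export
parse_patterns <- function(x, snp_order = NULL) {
  if (is.list(x)) {
    return(lapply(x, canonicalize_pattern, snp_order = snp_order))
  }
  stopifnot(is.character(x))
  lapply(x, function(s) {
    s <- gsub("[{}[:space:]]", "", s)
    if (!nzchar(s)) {
      stop("empty pattern string: a pattern needs at least one SNP=level pair",
        call. = FALSE
      )
    }
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) {
      stop("malformed pattern component(s): ",
        paste(parts[bad], collapse = ", "),
        call. = FALSE
      )
    }
    snps <- vapply(kv, `[[`, character(1), 1L)
    lvls <- suppressWarnings(as.integer(vapply(kv, `[[`, character(1), 2L)))
    if (anyNA(lvls)) stop("non-integer allele level in pattern: ", s, call. = FALSE)
    canonicalize_pattern(stats::setNames(lvls, snps), snp_order = snp_order)
  })
}

#' @rdname parse_patterns
#' @export
format_patterns <- function(x, snp_order = NULL) {
  pats <- parse_patterns(x, snp_order = snp_order)
  vapply(pats, function(p) {
    paste0("{", paste0(names(p), "=", p, collapse = ","), "}")
  }, character(1))
}

# Canonical order: by position in snp_order when given, else by SNP name;
# duplicated SNPs within one pattern are invalid (at most one level per SNP).
canonicalize_pattern <- function(p, snp_order = NULL) {
  stopifnot(length(p) >= 1L, !is.null(names(p)), all(nzchar(names(p))))
  if (anyDuplicated(names(p))) {
    stop("pattern lists the same SNP twice: ",
      paste(names(p)[duplicated(names(p))], collapse = ", "),
      call. = FALSE
    )
  }
  p <- stats::setNames(as.integer(p), names(p))
  if (is.null(snp_order)) {
    p[order(names(p), method = "radix")]
  } else {
    idx <- match(names(p), snp_order)
    p[order(!is.na(idx), idx, names(p), method = "radix", decreasing = c(TRUE, FALSE, FALSE))]
  }
}

#' Redundancy between two allele patterns
#'
#' Counts the (SNP, level) pairs shared by two patterns — the number of common
#' alleles. A shared SNP held at *different* levels contributes nothing. The
#' measure is symmetric, bounded by the shorter pattern's length, and equals
#' `length(a)` exactly when `a` is a sub-pattern of `b`. It is the redundancy
#' term of the greedy minimum-redundancy/maximum-relevance selection.
#'
#' @param a,b Patterns: strings or named integer vectors (see
#'   [parse_patterns()]).
#' @return A single non-negative integer.
#' @examples
#' pattern_similarity("{S2=1,S3=0,S5=1}", "{S2=1,S3=2}") # 1
#' @export
pattern_similarity <- function(a, b) {
  one_pattern <- function(x) {
    if (is.character(x)) parse_patterns(x[1])[[1]] else parse_patterns(list(x))[[1]]
  }
  a <- one_pattern(a)
  b <- one_pattern(b)
  shared <- intersect(names(a), names(b))
  sum(a[shared] == b[shared])
}

#' Encode genotypes against allele patterns
#'
#' Re-encodes a genotype table as binary interaction features: column `k` is 1
#' for every sample whose genotype matches all (SNP, level) pairs of pattern
#' `k`, and 0 otherwise. Column order follows the input pattern order.
#'
#' @param data A data frame of genotypes; SNP columns must be integer-coded
#'   allele categories.
#' @param patterns Patterns as a character vector of strings, a list of named
#'   integer vectors, or a candidate tibble with a `pattern` column.
#' @return A tibble with `nrow(data)` rows and one integer 0/1 column per
#'   pattern, named by the pattern strings.
#' @examples
#' g <- tibble::tibble(S1 = c(0L, 1L), S2 = c(1L, 1L))
#' encode_patterns(g, "{S1=0,S2=1}")
#' @export
encode_patterns <- function(data, patterns) {
  pats <- as_pattern_list(patterns)
  if (length(pats) == 0L) stop("no patterns to encode", call. = FALSE)
  snps <- unique(unlist(lapply(pats, names)))
  missing <- setdiff(snps, names(data))
  if (length(missing) > 0L) {
    stop("unknown SNP identifier(s) in pattern: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  mat <- encode_pattern_matrix(data, pats)
  storage.mode(mat) <- "integer"
  colnames(mat) <- format_patterns(pats)
  tibble::as_tibble(mat)
}

as_pattern_list <- function(patterns, snp_order = NULL) {
  if (is.data.frame(patterns)) {
    stopifnot("pattern" %in% names(patterns))
    cached <- attr(patterns, "pats")
    if (!is.null(cached) && length(cached) == nrow(patterns)) {
      return(cached)
    }
    patterns <- patterns$pattern
  }
  if (is.numeric(patterns)) patterns <- list(patterns)
  parse_patterns(patterns, snp_order = snp_order)
}

# Deterministic sort key over canonical (snp position, level) pair sequences;
# a proper prefix sorts first.
pattern_canon_key <- function(pats, snp_order) {
  vapply(pats, function(p) {
    idx <- match(names(p), snp_order)
    idx[is.na(idx)] <- length(snp_order) + rank(names(p)[is.na(idx)])
    paste(sprintf("%04d.%d", idx, p), collapse = "|")
  }, character(1))
}

# Core encoder: integer matrix of 0/1, one column per pattern. A pattern
# matches a row iff the row carries all of its (snp, level) items, so the
# match count is an inner product of item-indicator matrices; columns are
# processed in blocks to bound transient memory.
encode_pattern_matrix <- function(data, pats) {
  n <- nrow(data)
  pair_snp <- unlist(lapply(pats, names), use.names = FALSE)
  pair_lvl <- unlist(pats, use.names = FALSE)
  pair_pat <- rep(seq_along(pats), lengths(pats))
  keys <- paste0(pair_snp, "\r", pair_lvl)
  alphabet <- unique(keys)
  first <- match(alphabet, keys)
  x <- matrix(0, nrow = n, ncol = length(alphabet))
  for (i in seq_along(alphabet)) {
    x[, i] <- as.numeric(data[[pair_snp[first[i]]]] == pair_lvl[first[i]])
  }
  inc <- matrix(0, nrow = length(alphabet), ncol = length(pats))
  inc[cbind(match(keys, alphabet), pair_pat)] <- 1
  len <- lengths(pats)
  out <- matrix(0, nrow = n, ncol = length(pats))
  block <- max(1L, floor(2e7 / max(n, 1L)))
  for (start in seq(1L, length(pats), by = block)) {
    idx <- start:min(start + block - 1L, length(pats))
    out[, idx] <- (x %*% inc[, idx, drop = FALSE] == rep(len[idx], each = n)) + 0
  }
  out
}

# Validate an allele-category table: every entry an integer level in `levels`,
# no missing values. Errors name the offending row/column (fail fast; the
# indicator semantics of pattern matching leave no meaning for NA).
validate_genotypes <- function(data, snp_cols, levels = 0:2) {
  for (cn in snp_cols) {
    v <- data[[cn]]
    if (anyNA(v)) {
      stop("missing genotype value in column '", cn, "' (row ",
        which(is.na(v))[1], "); missing entries are not supported",
        call. = FALSE
      )
    }
    ok <- v %in% levels
    if (!all(ok)) {
      stop("invalid genotype value '", v[which(!ok)[1]], "' in column '", cn,
        "' (row ", which(!ok)[1], "); allowed levels: ",
        paste(levels, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(data)
}

# SNP columns of a labeled table: everything except the outcome column,
# restricted to columns that look like allele categories.
infer_snp_cols <- function(data, outcome = NULL, snp_cols = NULL) {
  if (!is.null(snp_cols)) {
    missing <- setdiff(snp_cols, names(data))
    if (length(missing)) {
      stop("snp_cols not found in data: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    return(snp_cols)
  }
  setdiff(names(data), outcome)
}

check_outcome <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found in data", call. = FALSE)
  }
  y <- data[[outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column '", outcome, "' must be binary 0/1 with no missing values",
      call. = FALSE
    )
  }
  as.integer(y)
}
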