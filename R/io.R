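#' Read a genotype table
#'
#' Reads individual-level genotypes with allele-category coding
#' (0 = major-allele homozygote, 1 = heterozygote, 2 = minor-allele
#' homozygote) from either a delimited text file (`format = "csv"`, comma- or
#' tab-separated, header row of SNP names plus an outcome column) or a PLINK
#' `.raw`-style additive-coding export (`format = "plink_raw"`:
#' whitespace-delimited, header `FID IID PAT MAT SEX PHENOTYPE` followed by
#' SNP dosage columns; `PHENOTYPE` 1/2 is remapped to outcome 0/1).
#'
#' Every genotype entry must be a valid allele level with no missing values;
#' violations raise an error naming the offending row and column.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"plink_raw"`.
#' @param outcome Name of the outcome column in the returned tibble (default
#'   `"Y"`). For CSV input this column must exist in the file; pass `NULL`
#'   to read unlabeled genotypes.
#' @param levels Allele-level alphabet (default `0:2`).
#' @return A tibble of integer SNP columns, plus the binary outcome column
#'   when labeled.
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw"), outcome = "Y",
                           levels = 0:2) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    d <- readr::read_delim(path,
      delim = detect_delim(path), col_types = readr::cols(.default = "i"),
      progress = FALSE, show_col_types = FALSE
    )
    if (!is.null(outcome)) {
      y <- check_outcome(d, outcome)
      snp_cols <- setdiff(names(d), outcome)
    } else {
      snp_cols <- names(d)
    }
  } else {
    d <- suppressWarnings(readr::read_table(path,
      col_types = readr::cols(
        FID = "c", IID = "c", PAT = "c", MAT = "c",
        SEX = "i", PHENOTYPE = "i", .default = "i"
      ),
      progress = FALSE, show_col_types = FALSE
    ))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    missing <- setdiff(meta, names(d))
    if (length(missing) > 0L) {
      stop("not a PLINK .raw header; missing column(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    snp_cols <- setdiff(names(d), meta)
    pheno <- d$PHENOTYPE
    if (!all(pheno %in% c(1L, 2L))) {
      stop("PHENOTYPE must be coded 1 (control) / 2 (case)", call. = FALSE)
    }
    d <- d[snp_cols]
    if (!is.null(outcome)) d[[outcome]] <- pheno - 1L
  }
  validate_genotypes(d, snp_cols, levels)
  tibble::as_tibble(d)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Write simulated or processed genotype data to CSV
#'
#' @param data A tibble of SNP columns plus (optionally) an outcome column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

PRS_SCHEMA_VERSION <- "1"

#' Save / load a fitted risk model as JSON
#'
#' The JSON document stores the schema version, the fitting settings, the
#' selected interaction patterns (canonical strings), per-term mining
#' support, mutual information, selection rank and redundancy, and the
#' logistic coefficients at full precision, so a save/load round trip
#' reproduces scores bit-exactly.
#'
#' @param model A fitted `hiprs` model.
#' @param path File path.
#' @return `write_prs()`: `path` invisibly. `read_prs()`: a `hiprs` model.
#' @export
write_prs <- function(model, path) {
  stopifnot(inherits(model, "hiprs"))
  doc <- list(
    schema_version = PRS_SCHEMA_VERSION,
    settings = model$settings,
    n = model$n,
    n_cases = model$n_cases,
    separation = model$separation,
    snp_cols = model$snp_cols,
    selection = as.list(tibble::as_tibble(model$selection)),
    coefficients = list(
      term = names(model$coefficients),
      # 17 significant digits round-trip an IEEE double exactly
      estimate = sprintf("%.17g", unname(model$coefficients))
    )
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_prs
#' @export
read_prs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot parse model file: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$schema_version) || !identical(as.character(doc$schema_version), PRS_SCHEMA_VERSION)) {
    stop("unsupported model schema version: ",
      if (is.null(doc$schema_version)) "<missing>" else doc$schema_version,
      call. = FALSE
    )
  }
  settings <- doc$settings
  settings$l_max <- as.numeric(settings$l_max)
  if (is.null(settings$l_max) || is.na(settings$l_max)) settings$l_max <- Inf
  sel <- tibble::as_tibble(doc$selection)
  class(sel) <- c("hiprs_selection", class(sel))
  structure(
    list(
      coefficients = stats::setNames(
        as.numeric(doc$coefficients$estimate),
        doc$coefficients$term
      ),
      selection = sel,
      settings = settings,
      separation = isTRUE(doc$separation),
      n = doc$n,
      n_cases = doc$n_cases,
      snp_cols = doc$snp_cols
    ),
    class = "hiprs"
  )
}

#' Export candidate or selected patterns as TSV
#'
#' `write_candidates()` writes the mined candidate list (pattern, length,
#' support); `write_selection()` writes the greedy selection trace (rank,
#' pattern, mi, redundancy); `write_prs_terms()` writes the fitted terms and
#' their coefficients.
#'
#' @param x The corresponding object (candidates tibble, selection tibble,
#'   or fitted `hiprs` model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[c("pattern", "length", "support")], path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_candidates
#' @export
write_selection <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[c("rank", "pattern", "mi", "redundancy")], path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_candidates
#' @export
write_prs_terms <- function(x, path) {
  stopifnot(inherits(x, "hiprs"))
  readr::write_tsv(tidy(x)[c("term", "estimate")], path, progress = FALSE)
  invisible(path)
}

#' Read an empirical genotype-by-class table
#'
#' TSV with one row per multilocus genotype and class: genotype columns,
#' a `class` column (0/1), and a `count` column (non-negative). Input for
#' [bootstrap_from_table()].
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_genotype_class_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("class", "count") %in% names(d))) {
    stop("genotype-class table needs 'class' and 'count' columns", call. = FALSE)
  }
  d
}
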