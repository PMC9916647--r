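#' Fit a high-order interaction-aware polygenic risk score
#'
#' End-to-end pipeline: (1) mine allele patterns whose case-class frequency
#' exceeds `delta` ([mine_patterns()]); (2) rank them by mutual information
#' with the outcome over the full training data ([rank_patterns()]); (3) pick
#' `K` of them by greedy minimum-redundancy/maximum-relevance selection
#' ([select_patterns()]); (4) weight the selected binary interaction features
#' by an unpenalized maximum-likelihood logistic regression. The resulting
#' score for a genotype is the affine linear predictor
#' `beta_0 + sum_k beta_k * I_k(genotype)`.
#'
#' Interaction features enter the logistic fit as raw 0/1 dummies, so each
#' coefficient reads directly as the per-pattern effect size (log odds ratio).
#' When the likelihood fails to converge (perfect separation, common for
#' large `K` on small case counts), the fit falls back to a very lightly
#' ridge-penalized logistic regression; the fallback and its penalty are
#' recorded in the model metadata.
#'
#' @param data Training data: genotype columns plus a binary outcome column.
#' @param outcome Name of the outcome column (default `"Y"`).
#' @param delta Case-class support threshold for mining (default 0.05).
#' @param K Number of interaction terms in the final score (default 10).
#' @param l_max Maximum interaction order to mine; `Inf` (default) for
#'   unbounded.
#' @param zero_redundancy Zero-redundancy branch behavior of the greedy
#'   selection; see [select_patterns()].
#' @param snp_cols Optional explicit genotype columns.
#' @param levels Allele-level alphabet (default `0:2`).
#' @param ridge Ridge penalty used only by the separation fallback
#'   (default `1e-4`).
#' @return An object of class `hiprs`: a list with `coefficients` (named,
#'   intercept first), `selection` (the [select_patterns()] table),
#'   `settings`, `separation` (logical), `n`, `n_cases`, and `snp_cols`.
#'   Supports `predict()`, `tidy()`, `glance()`, `autoplot()`, `print()`.
#' @examples
#' sim <- simulate_epistasis(n_train = 300, n_test = 100, epsilon = 0.01, seed = 2)
#' fit <- hiprs(sim$train, delta = 0.1, K = 5)
#' tidy(fit)
#' auc(predict(fit, sim$test), sim$test$Y)
#' @export
hiprs <- function(data, outcome = "Y", delta = 0.05, K = 10, l_max = Inf,
                  zero_redundancy = c("literal", "restricted"),
                  snp_cols = NULL, levels = 0:2, ridge = 1e-4) {
  fits <- hiprs_k_path(data,
    outcome = outcome, delta = delta, K = K, l_max = l_max,
    zero_redundancy = zero_redundancy, snp_cols = snp_cols,
    levels = levels, ridge = ridge
  )
  fits[[1]]
}

#' Fit the pipeline once and weight several model sizes
#'
#' The mining, ranking, and greedy selection stages do not depend on `K`
#' beyond its maximum: the greedy selection has the prefix property (the
#' first `K - 1` picks of a `K`-run are the `K - 1`-run). This helper runs
#' those stages once at `max(K)` and fits one logistic weighting per
#' requested `K`, which is the natural way to profile model size.
#'
#' @inheritParams hiprs
#' @param K Integer vector of model sizes.
#' @return A named list of `hiprs` objects, one per `K` (names `"K<k>"`).
#' @export
hiprs_k_path <- function(data, outcome = "Y", delta = 0.05, K = c(10, 40),
                         l_max = Inf, zero_redundancy = c("literal", "restricted"),
                         snp_cols = NULL, levels = 0:2, ridge = 1e-4) {
  zero_redundancy <- match.arg(zero_redundancy)
  stopifnot(all(K >= 1))
  y <- check_outcome(data, outcome)
  if (all(y == y[1])) stop("both classes must be present to fit a risk score", call. = FALSE)
  if (mean(y) > 0.5) {
    warning("cases (Y = 1) outnumber controls; mining still scans the Y = 1 class",
      call. = FALSE
    )
  }
  cands <- mine_patterns(data,
    outcome = outcome, delta = delta, l_max = l_max,
    snp_cols = snp_cols, levels = levels
  )
  if (nrow(cands) == 0L) {
    stop("no candidate patterns above delta = ", delta, "; try a smaller delta",
      call. = FALSE
    )
  }
  ranked <- rank_patterns(cands, data, outcome = outcome)
  k_max <- min(max(K), nrow(ranked))
  sel <- select_patterns(ranked, k_max, zero_redundancy = zero_redundancy)
  enc <- attr(sel, "encoded")
  fits <- lapply(K, function(k) {
    k_eff <- as.integer(min(k, k_max))
    if (k_eff < k) {
      warning("K = ", k, " exceeds the ", nrow(ranked),
        " candidates; fitting all of them",
        call. = FALSE
      )
    }
    sel_k <- sel[seq_len(k_eff), ]
    attr(sel_k, "pats") <- attr(sel, "pats")[seq_len(k_eff)]
    attr(sel_k, "zero_redundancy") <- zero_redundancy
    w <- fit_logistic(enc[, seq_len(k_eff), drop = FALSE], y, ridge)
    structure(
      list(
        coefficients = stats::setNames(w$coef, c("(Intercept)", sel_k$pattern)),
        selection = sel_k,
        settings = list(
          delta = delta, K = k_eff, l_max = l_max,
          zero_redundancy = zero_redundancy, outcome = outcome,
          ridge = if (w$separation) ridge else 0
        ),
        separation = w$separation,
        n = length(y),
        n_cases = sum(y),
        snp_cols = attr(cands, "snp_cols")
      ),
      class = "hiprs"
    )
  })
  stats::setNames(fits, paste0("K", pmin(K, k_max)))
}

# Unpenalized logistic MLE with a tiny-ridge fallback on separation or
# non-convergence, so fits always terminate with finite weights.
fit_logistic <- function(x, y, ridge) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!separated && fit$converged && all(is.finite(fit$coefficients))) {
    return(list(coef = unname(fit$coefficients), separation = FALSE))
  }
  xx <- if (ncol(x) < 2L) cbind(x, `..pad` = 0) else x
  gfit <- glmnet::glmnet(xx, y,
    family = "binomial", alpha = 0, standardize = FALSE,
    lambda = 10^seq(1, log10(ridge), length.out = 25), maxit = 1e6
  )
  cf <- as.numeric(stats::coef(gfit, s = ridge, exact = FALSE))
  list(coef = cf[seq_len(ncol(x) + 1L)], separation = TRUE)
}

#' Score genotypes with a fitted risk model
#'
#' `type = "link"` (default) returns the polygenic risk score itself — the
#' affine linear predictor `beta_0 + sum_k beta_k I_k`. `type = "response"`
#' returns the logistic case probability.
#'
#' @param object A fitted `hiprs` model.
#' @param newdata A data frame containing every SNP column the model's
#'   interactions reference.
#' @param type `"link"` or `"response"`.
#' @param ... Unused.
#' @return A numeric vector, one value per row of `newdata`.
#' @export
predict.hiprs <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  pats <- as_pattern_list(object$selection)
  snps <- unique(unlist(lapply(pats, names)))
  missing <- setdiff(snps, names(newdata))
  if (length(missing) > 0L) {
    stop("newdata lacks SNP column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  enc <- encode_pattern_matrix(newdata, pats)
  eta <- as.numeric(object$coefficients[1] + enc %*% object$coefficients[-1])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.hiprs <- function(x, ...) {
  cat("High-order interaction-aware PRS\n")
  cat(
    "  K = ", x$settings$K, " interaction terms, delta = ", x$settings$delta,
    ", l_max = ", x$settings$l_max, "\n",
    sep = ""
  )
  cat("  fitted on ", x$n, " samples (", x$n_cases, " cases)",
    if (x$separation) " [ridge fallback: separation]" else "", "\n",
    sep = ""
  )
  print(utils::head(tidy(x), 8))
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' One row per model term (intercept first): the pattern, its logistic
#' coefficient, and — for interaction terms — the mining support, mutual
#' information, selection rank, and average redundancy at pick time.
#'
#' @param x A fitted `hiprs` model.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `rank`, `support`,
#'   `mi`, `redundancy`.
#' @export
tidy.hiprs <- function(x, ...) {
  sel <- x$selection
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    rank = c(NA_integer_, sel$rank),
    support = c(NA_real_, sel$support),
    mi = c(NA_real_, sel$mi),
    redundancy = c(NA_real_, sel$redundancy)
  )
}

#' Model-level summary of a fitted risk score
#'
#' @param x A fitted `hiprs` model.
#' @param ... Unused.
#' @return A one-row tibble: settings, sample counts, and whether the
#'   separation fallback engaged.
#' @export
glance.hiprs <- function(x, ...) {
  tibble::tibble(
    K = x$settings$K,
    delta = x$settings$delta,
    l_max = x$settings$l_max,
    n = x$n,
    n_cases = x$n_cases,
    separation = x$separation
  )
}

#' Coefficient plot for a fitted risk model
#'
#' Horizontal bar chart of the interaction-term effect sizes, the standard
#' way to read which allele patterns drive the score and in which direction.
#'
#' @param object A fitted `hiprs` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hiprs <- function(object, ...) {
  d <- tidy(object)[-1, ]
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "coefficient (log odds ratio)", y = NULL,
      title = "Selected interaction patterns and effect sizes"
    ) +
    ggplot2::theme_minimal()
}

#' Cross-validated grid search over (delta, K)
#'
#' Stratified `folds`-fold cross-validation of the full pipeline: for every
#' grid point, the score is refit from scratch on each training fold and its
#' AUC measured on the held-out fold. The best grid point maximizes the mean
#' held-out AUC (ties: smaller `K`, then larger `delta` — the simpler model).
#'
#' @inheritParams hiprs
#' @param delta_grid,K_grid Numeric vectors of thresholds and model sizes.
#' @param folds Number of stratified folds (default 4).
#' @param seed Optional integer seed for the fold assignment.
#' @return A list of class `hiprs_grid`: `best` (one-row tibble with `delta`,
#'   `K`, `mean_auc`), `cv` (tibble with one row per grid point x fold), and
#'   `folds`.
#' @export
grid_search_prs <- function(data, outcome = "Y", delta_grid, K_grid, folds = 4,
                            seed = NULL, l_max = Inf,
                            zero_redundancy = c("literal", "restricted"),
                            snp_cols = NULL, levels = 0:2) {
  zero_redundancy <- match.arg(zero_redundancy)
  stopifnot(folds >= 2)
  y <- check_outcome(data, outcome)
  if (min(sum(y == 1), sum(y == 0)) < folds) {
    stop("each class needs at least `folds` observations for stratified CV",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  grid <- tidyr::expand_grid(delta = delta_grid, K = K_grid)
  cv <- purrr::pmap_dfr(grid, function(delta, K) {
    purrr::map_dfr(seq_len(folds), function(f) {
      train <- data[fold_id != f, , drop = FALSE]
      held <- data[fold_id == f, , drop = FALSE]
      fit <- hiprs(train,
        outcome = outcome, delta = delta, K = K, l_max = l_max,
        zero_redundancy = zero_redundancy, snp_cols = snp_cols, levels = levels
      )
      tibble::tibble(
        delta = delta, K = K, fold = f,
        auc = auc(predict(fit, held), held[[outcome]])
      )
    })
  })
  summary <- cv |>
    dplyr::group_by(.data$delta, .data$K) |>
    dplyr::summarise(mean_auc = mean(.data$auc), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), .data$K, dplyr::desc(.data$delta))
  structure(
    list(best = summary[1, ], cv = cv, folds = folds),
    class = "hiprs_grid"
  )
}

#' @export
print.hiprs_grid <- function(x, ...) {
  cat(
    "Cross-validated grid search (", x$folds, " folds): best delta = ",
    x$best$delta, ", K = ", x$best$K,
    " (mean held-out AUC ", round(x$best$mean_auc, 4), ")\n",
    sep = ""
  )
  invisible(x)
}
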