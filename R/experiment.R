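#' Repeated-simulation evaluation harness
#'
#' Runs a grid of methods and simulation conditions over independent
#' repetitions of the epistatic simulator, recording test AUC and average
#' precision for each repetition. Rows of `plan` that share simulation
#' conditions (`n_train`, `n_test`, `epsilon`, `q`) are evaluated on the same
#' generated datasets within each repetition, so method comparisons are
#' paired; `hiprs` rows differing only in `K` additionally share one mining,
#' ranking, and selection pass (see [hiprs_k_path()]).
#'
#' Per-repetition seeds are derived deterministically from `seed`, so the
#' whole report is reproducible. A failing fit is recorded (its `error`
#' column holds the message, metrics become `NA`) without aborting the run.
#'
#' @param plan A data frame with a `method` column
#'   (`"hiprs"`, `"lasso"`, `"ridge"`, or `"elasticnet"`) and any of the
#'   optional columns `n_train` (default 1000), `n_test` (500), `epsilon`
#'   (0.01), `q` (`NA` = no undersampling), `K` (10, hiprs only), `delta`
#'   (0.05), `l_max` (`Inf`).
#' @param reps Number of independent repetitions per plan row (default 30).
#' @param seed Master seed (default 1).
#' @param p Number of simulated SNPs (default 15).
#' @return A tibble of class `hiprs_experiment`: one row per plan row x
#'   repetition with the condition columns, `rep`, `auc`, `ap`, and `error`.
#' @examples
#' plan <- tibble::tibble(method = c("hiprs", "lasso"), K = c(10, NA))
#' rep1 <- run_experiment(plan, reps = 1, seed = 42)
#' summarize_experiment(rep1)
#' @export
run_experiment <- function(plan, reps = 30, seed = 1, p = 15) {
  plan <- normalize_plan(plan)
  set.seed(as.integer(seed))
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max, reps * 2L),
    nrow = reps, ncol = 2L
  )
  sim_key <- paste(plan$n_train, plan$n_test, plan$epsilon, plan$q, sep = "|")
  out <- purrr::map_dfr(seq_len(reps), function(r) {
    purrr::map_dfr(unique(sim_key), function(key) {
      rows <- plan[sim_key == key, , drop = FALSE]
      cond <- rows[1, ]
      sim <- simulate_epistasis(
        n_train = cond$n_train, n_test = cond$n_test,
        epsilon = cond$epsilon, p = p,
        q = if (is.na(cond$q)) NULL else cond$q,
        seed = (rep_seeds[r, 1] + match(key, unique(sim_key)) * 7919L) %% .Machine$integer.max
      )
      eval_methods_on(rows, sim, r)
    })
  })
  class(out) <- c("hiprs_experiment", class(out))
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

normalize_plan <- function(plan) {
  plan <- tibble::as_tibble(plan)
  stopifnot("method" %in% names(plan))
  known <- c("hiprs", "lasso", "ridge", "elasticnet")
  bad <- setdiff(plan$method, known)
  if (length(bad) > 0L) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    n_train = 1000, n_test = 500, epsilon = 0.01, q = NA_real_,
    K = 10, delta = 0.05, l_max = Inf
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(plan)) plan[[nm]] <- defaults[[nm]]
    plan[[nm]][is.na(plan[[nm]]) & nm != "q"] <- defaults[[nm]]
  }
  plan
}

eval_methods_on <- function(rows, sim, r) {
  metric_row <- function(row, scores, err = NA_character_) {
    dplyr::bind_cols(
      row,
      tibble::tibble(
        rep = r,
        auc = if (is.null(scores)) NA_real_ else auc(scores, sim$test$Y),
        ap = if (is.null(scores)) NA_real_ else average_precision(scores, sim$test$Y),
        error = err
      )
    )
  }
  is_hiprs <- rows$method == "hiprs"
  out <- list()
  # hiprs rows sharing (delta, l_max) reuse one mine/rank/select pass
  if (any(is_hiprs)) {
    hrows <- rows[is_hiprs, , drop = FALSE]
    for (grp in split(hrows, paste(hrows$delta, hrows$l_max))) {
      res <- tryCatch(
        {
          fits <- hiprs_k_path(sim$train,
            delta = grp$delta[1], K = sort(unique(grp$K)), l_max = grp$l_max[1]
          )
          fit_ks <- vapply(fits, function(f) f$settings$K, numeric(1))
          purrr::map_dfr(split(grp, seq_len(nrow(grp))), function(row) {
            fit <- fits[[which(fit_ks == min(row$K, max(fit_ks)))[1]]]
            metric_row(row, predict(fit, sim$test))
          })
        },
        error = function(e) {
          purrr::map_dfr(
            split(grp, seq_len(nrow(grp))),
            function(row) metric_row(row, NULL, conditionMessage(e))
          )
        }
      )
      out[[length(out) + 1L]] <- res
    }
  }
  if (any(!is_hiprs)) {
    brows <- rows[!is_hiprs, , drop = FALSE]
    out[[length(out) + 1L]] <- purrr::map_dfr(
      split(brows, seq_len(nrow(brows))),
      function(row) {
        tryCatch(
          {
            fit <- fit_additive_prs(sim$train, penalty = row$method)
            metric_row(row, predict(fit, sim$test))
          },
          error = function(e) metric_row(row, NULL, conditionMessage(e))
        )
      }
    )
  }
  dplyr::bind_rows(out)
}

#' Summarize a repeated-simulation report
#'
#' Mean, standard deviation, and normal-approximation 95% confidence band
#' (mean +/- 1.96 sd / sqrt(reps)) of AUC and AP for each experimental cell.
#'
#' @param report A `hiprs_experiment` tibble from [run_experiment()].
#' @return A tibble with one row per cell: condition columns, `n_reps`,
#'   `n_failed`, and `mean`/`sd`/`lo`/`hi` for both metrics.
#' @export
summarize_experiment <- function(report) {
  band <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  report |>
    dplyr::group_by(
      .data$method, .data$n_train, .data$n_test, .data$epsilon,
      .data$q, .data$K, .data$delta
    ) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_failed = sum(!is.na(.data$error)),
      auc_mean = mean(.data$auc, na.rm = TRUE),
      auc_sd = stats::sd(.data$auc, na.rm = TRUE),
      auc_lo = .data$auc_mean - band(stats::na.omit(.data$auc)),
      auc_hi = .data$auc_mean + band(stats::na.omit(.data$auc)),
      ap_mean = mean(.data$ap, na.rm = TRUE),
      ap_sd = stats::sd(.data$ap, na.rm = TRUE),
      ap_lo = .data$ap_mean - band(stats::na.omit(.data$ap)),
      ap_hi = .data$ap_mean + band(stats::na.omit(.data$ap)),
      .groups = "drop"
    )
}

#' Performance panels for a repeated-simulation report
#'
#' Boxplots of per-repetition AUC and AP by method/model-size label, the
#' standard way to compare scoring approaches across repeated simulations.
#'
#' @param object A `hiprs_experiment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hiprs_experiment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- ifelse(d$method == "hiprs", paste0("hiprs K=", d$K), d$method)
  long <- tidyr::pivot_longer(
    d,
    cols = c("auc", "ap"), names_to = "metric", values_to = "value"
  )
  long$metric <- toupper(long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL, title = "Test performance across repetitions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
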