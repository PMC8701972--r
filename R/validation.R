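#' Repeated k-fold cross-validation of the final model
#'
#' Evaluates coefficient stability of the selected model: the selected
#' columns are held fixed (selection is not re-run per fold), coefficients
#' are refit on k-1 folds, and the held-out fold is predicted. Per repeat,
#' the out-of-fold predictions of all folds are pooled before computing
#' metrics; aggregates are means over repeats. Two R2 definitions are
#' reported: the squared Pearson correlation between observed and
#' predicted (`r2`) and `1 - SSE/SST` (`r2_sse`). `%RMSE` uses the mean
#' measured concentration over all sites as denominator.
#'
#' @param data Tibble with the response and selected predictor columns.
#' @param response Response column name.
#' @param predictors Selected predictor columns.
#' @param k Number of folds.
#' @param n_repeats Number of repeated random partitions.
#' @param seed Partition seed.
#' @return A `lur_cv` object; `tidy()` gives per-repeat metrics, `glance()`
#'   the aggregate row.
#' @export
kfold_cv <- function(data, response, predictors, k = 5L, n_repeats = 50L,
                     seed = 1L) {
  n <- nrow(data)
  if (n < k) abort("kfold_cv(): need n >= k")
  y <- data[[response]]
  reps <- with_seed(op_seed(seed, "kfold_cv"), {
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      fold <- sample(rep(seq_len(k), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(k)) {
        train <- data[fold != f, , drop = FALSE]
        if (nrow(train) <= length(predictors) + 1) {
          abort("kfold_cv(): training fold too small for the model")
        }
        fit <- fit_ols(train, response, predictors)
        pred[fold == f] <- predict(fit, data[fold == f, , drop = FALSE])
      }
      e <- y - pred
      tibble(repeat_id = r,
             r2 = cor(y, pred)^2,
             r2_sse = 1 - sum(e^2) / sum((y - mean(y))^2),
             rmse = sqrt(mean(e^2)),
             mae = mean(abs(e)))
    })
  })
  agg <- reps |>
    summarise(r2 = mean(.data$r2), r2_sse = mean(.data$r2_sse),
              rmse = mean(.data$rmse), mae = mean(.data$mae)) |>
    mutate(pct_rmse = 100 * .data$rmse / mean(y), k = as.integer(k),
           n_repeats = as.integer(n_repeats), n = as.integer(n))
  structure(list(repeats = reps, summary = agg, response = response,
                 predictors = predictors),
            class = "lur_cv")
}

#' @export
print.lur_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<lur_cv> %d-fold x %d repeats on %d sites: R2 %.3f, RMSE %.2f ppb (%.1f%% of mean), MAE %.2f ppb\n",
              s$k, s$n_repeats, s$n, s$r2, s$rmse, s$pct_rmse, s$mae))
  invisible(x)
}

#' @export
tidy.lur_cv <- function(x, ...) x$repeats

#' @export
glance.lur_cv <- function(x, ...) x$summary

#' @export
autoplot.lur_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$repeats, -"repeat_id",
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cross-validation metric stability") +
    ggplot2::theme_minimal()
}

#' Independent (historical) evaluation with frozen coefficients
#'
#' Applies a fitted model to sites not used in training: new raw predictor
#' values are standardized with the model's frozen training `(mean, sd)`
#' (never recomputed), predictions are compared with the new measurements,
#' and agreement metrics are returned, including the mean bias
#' `MB = mean(predicted - observed)` (negative = underprediction) and the
#' R2 change relative to the training fit. Sites missing any required
#' predictor are skipped and logged.
#'
#' @param model A `lur_model` with frozen `stats`.
#' @param new_data Tibble with the response column and raw predictor
#'   columns for the evaluation sites/period.
#' @param response Response column name in `new_data`.
#' @param training_r2 Training R2 for the `delta_r2` comparison; defaults
#'   to the model's fitted R2 when available.
#' @return One-row tibble (`n_sites`, `r2`, `r2_sse`, `rmse`, `mae`, `mb`,
#'   `delta_r2`), with skipped sites in the `skipped` attribute.
#' @export
external_evaluate <- function(model, new_data, response = "no2_ppb",
                              training_r2 = NULL) {
  need <- model$terms$column
  has <- stats::complete.cases(new_data[, intersect(need, names(new_data)),
                                        drop = FALSE])
  miss_cols <- setdiff(need, names(new_data))
  if (length(miss_cols)) {
    abort(sprintf("new_data lacks predictor column(s): %s",
                  paste(miss_cols, collapse = ", ")))
  }
  skipped <- new_data[!has, , drop = FALSE]
  kept <- new_data[has, , drop = FALSE]
  pred <- predict(model, kept, scale = "raw")
  obs <- kept[[response]]
  e <- pred - obs
  training_r2 <- training_r2 %||% (if (!is.null(model$fit)) model$fit$r2)
  r2 <- cor(obs, pred)^2
  out <- tibble(
    n_sites = nrow(kept),
    r2 = r2,
    r2_sse = 1 - sum(e^2) / sum((obs - mean(obs))^2),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mb = mean(e),
    delta_r2 = if (is.null(training_r2)) NA_real_ else r2 - training_r2
  )
  attr(out, "skipped") <- skipped
  out
}
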