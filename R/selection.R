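#' Ordinary least squares fit with LUR fit statistics
#'
#' Fits `response ~ predictors` with intercept and reports the statistics
#' used throughout the pipeline: R2, adjusted R2
#' (`1 - (1 - R2)(n - 1)/(n - p - 1)`), RMSE (`sqrt(mean(e^2))`, ppb) and
#' MAE (`mean(|e|)`, ppb). Predictors are normally the standardized
#' columns, so coefficients are in ppb per SD.
#'
#' @param data Tibble holding the response and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (may be
#'   empty: intercept-only model).
#' @return A `lur_ols` object.
#' @export
fit_ols <- function(data, response, predictors = character()) {
  y <- data[[response]]
  n <- length(y)
  p <- length(predictors)
  if (n <= p + 1) abort("fit_ols(): need n > p + 1")
  X <- if (p) as.matrix(data[, predictors, drop = FALSE]) else
    matrix(numeric(0), n, 0)
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < p + 1) {
    aliased <- colnames(cbind(1, X))[qx$pivot[-seq_len(qx$rank)]]
    abort(sprintf("fit_ols(): rank-deficient design; offending column(s): %s",
                  paste(aliased, collapse = ", ")))
  }
  df <- as.data.frame(cbind(.y = y, X))
  names(df) <- c(".y", predictors)
  fml <- stats::as.formula(paste(
    ".y ~", if (p) paste0("`", predictors, "`", collapse = " + ") else "1"))
  fit <- lm(fml, data = df)
  e <- resid(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(e^2) / sst
  structure(
    list(fit = fit, response = response, predictors = predictors,
         n = n, p = p,
         r2 = r2,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         rmse = sqrt(mean(e^2)),
         mae = mean(abs(e))),
    class = "lur_ols"
  )
}

#' @export
print.lur_ols <- function(x, ...) {
  cat(sprintf("<lur_ols> n = %d, p = %d, R2 = %.3f, adj R2 = %.3f, RMSE = %.2f ppb, MAE = %.2f ppb\n",
              x$n, x$p, x$r2, x$adj_r2, x$rmse, x$mae))
  invisible(x)
}

#' @export
tidy.lur_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = sub("^`|`$", "", rownames(s)),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.lur_ols <- function(x, ...) {
  tibble(r.squared = x$r2, adj.r.squared = x$adj_r2, rmse = x$rmse,
         mae = x$mae, nobs = x$n, df = x$p)
}

#' @export
predict.lur_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(stats::fitted(object$fit)))
  nd <- as.data.frame(newdata[, object$predictors, drop = FALSE])
  names(nd) <- object$predictors
  unname(predict(object$fit, newdata = nd))
}

#' Supervised, direction-constrained forward variable selection
#'
#' The LUR model-building algorithm. Starting from the intercept-only
#' model, each round refits the model with every remaining candidate added
#' in turn; a candidate is admissible iff
#' (i) its fitted coefficient matches its pre-defined expected direction,
#' (ii) no coefficient already in the model flips direction, and
#' (iii) adjusted R2 increases by more than `gain_threshold` (absolute).
#' The admissible candidate with the largest adjusted-R2 gain is added;
#' the process repeats until no candidate is admissible. Ties in gain
#' (within 1e-12) are broken by larger absolute Pearson correlation with
#' the response, then lexicographic column name, making selection fully
#' deterministic and invariant to candidate order. Candidates whose
#' addition makes the design rank-deficient are skipped (logged in the
#' trace). Direction is tested on the point estimate only; p-values are
#' reported post hoc, not used as a criterion.
#'
#' @param data Tibble with the response and standardized candidate columns
#'   (typically from [standardize_predictors()], whose `predictor_info` and
#'   `standardization` attributes supply signs and frozen column stats).
#' @param response Response column name (annual NO2, ppb).
#' @param candidates Character vector of candidate columns. Defaults to the
#'   columns listed in `predictor_info(data)`.
#' @param signs Named vector (`"+"`/`"-"`) of expected directions; defaults
#'   to `predictor_info(data)$expected_sign`.
#' @param gain_threshold Minimum absolute adjusted-R2 gain (default 0.01,
#'   i.e. ">1%").
#' @return A `lur_model`: ordered `terms` (with per-step incremental
#'   adjusted R2 and contribution %), the final `lur_ols` fit, the frozen
#'   `stats`, and a full audit `trace` of every (round, candidate) verdict.
#' @export
forward_select <- function(data, response, candidates = NULL, signs = NULL,
                           gain_threshold = 0.01) {
  info <- predictor_info(data)
  if (is.null(candidates)) {
    if (is.null(info)) abort("forward_select(): no candidates given and no predictor_info attribute")
    candidates <- intersect(info$column, names(data))
  }
  if (is.null(signs)) {
    if (is.null(info)) abort("forward_select(): no signs given and no predictor_info attribute")
    signs <- setNames(info$expected_sign, info$column)[candidates]
  }
  if (anyNA(signs[candidates])) {
    abort("forward_select(): every candidate needs an expected sign")
  }
  sgn <- ifelse(signs[candidates] == "+", 1, -1)
  names(sgn) <- candidates
  y <- data[[response]]
  n <- length(y)
  # round-one ranking / tie-break key: absolute correlation with y
  cors <- vapply(candidates, function(cn) {
    v <- data[[cn]]
    if (sd(v) == 0) 0 else abs(cor(y, v))
  }, 0)

  selected <- character()
  cur_adj <- 0
  trace <- list()
  steps <- list()
  remaining <- candidates[order(-cors[candidates], candidates)]
  round <- 0L
  repeat {
    round <- round + 1L
    best <- NULL
    for (cn in remaining) {
      cols <- c(selected, cn)
      X <- cbind(1, as.matrix(data[, cols, drop = FALSE]))
      fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
      verdict <- NULL
      gain <- NA_real_
      if (is.null(fit) || any(is.na(fit$coefficients)) ||
            fit$rank < ncol(X)) {
        verdict <- "rank_deficient"
      } else {
        beta <- fit$coefficients[-1]
        names(beta) <- cols
        gain <- adj_r2_from_fit(fit, y, length(cols)) - cur_adj
        if (sign(beta[[cn]]) != sgn[[cn]]) {
          verdict <- "wrong_sign"
        } else if (length(selected) &&
                     any(sign(beta[selected]) != sgn[selected])) {
          verdict <- "flips_included_sign"
        } else if (gain <= gain_threshold) {
          verdict <- "insufficient_gain"
        } else {
          verdict <- "admissible"
          better <- is.null(best) ||
            gain > best$gain + 1e-12 ||
            (abs(gain - best$gain) <= 1e-12 &&
               (cors[[cn]] > cors[[best$column]] ||
                  (cors[[cn]] == cors[[best$column]] && cn < best$column)))
          if (better) best <- list(column = cn, gain = gain)
        }
      }
      trace[[length(trace) + 1L]] <-
        tibble(round = round, candidate = cn, gain = gain,
               admissible = verdict == "admissible", verdict = verdict)
    }
    if (is.null(best)) break
    selected <- c(selected, best$column)
    cur_adj <- cur_adj + best$gain
    steps[[length(steps) + 1L]] <-
      tibble(step = length(selected), column = best$column,
             adj_r2 = cur_adj, gain = best$gain)
    remaining <- setdiff(remaining, best$column)
    if (!length(remaining)) break
  }

  final <- fit_ols(data, response, selected)
  steps <- if (length(steps)) bind_rows(steps) else
    tibble(step = integer(), column = character(), adj_r2 = double(),
           gain = double())
  coefs <- tidy(final)
  terms <- steps |>
    left_join(coefs, by = c(column = "term")) |>
    mutate(expected_sign = unname(signs[.data$column]),
           incremental_adj_r2 = .data$adj_r2,
           contribution_pct = 100 * .data$gain) |>
    select("step", "column", beta = "estimate", se = "std.error",
           p_value = "p.value", "expected_sign", "incremental_adj_r2",
           "contribution_pct")
  new_lur_model(
    intercept = unname(coef(final$fit)[1]),
    terms = terms,
    fit = final,
    stats = standardization_stats(data),
    trace = bind_rows(trace),
    gain_threshold = gain_threshold
  )
}

adj_r2_from_fit <- function(fit, y, p) {
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- length(y)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

new_lur_model <- function(intercept, terms, fit = NULL, stats = NULL,
                          trace = NULL, gain_threshold = NA_real_) {
  structure(list(intercept = intercept, terms = terms, fit = fit,
                 stats = stats, trace = trace,
                 gain_threshold = gain_threshold),
            class = "lur_model")
}

#' Construct a LUR model from known coefficients
#'
#' Builds a `lur_model` directly from an intercept and a table of
#' standardized coefficients — e.g. a published final model — so it can be
#' used for prediction, mapping, and external evaluation without refitting.
#'
#' @param intercept Intercept in ppb (the prediction when every
#'   standardized predictor is zero, i.e. at the training means).
#' @param terms Tibble with `column` and `beta` (ppb per SD); optional
#'   `se`, `incremental_adj_r2`.
#' @param stats Optional frozen standardization table (`column`, `mean`,
#'   `sd`) enabling raw-scale prediction.
#' @return A `lur_model`.
#' @export
#' @examples
#' m <- lur_model(27.4, tibble::tibble(column = "satellite", beta = 6.03))
#' predict(m, tibble::tibble(satellite = 0))
lur_model <- function(intercept, terms, stats = NULL) {
  stopifnot_cols(terms, c("column", "beta"), "terms")
  if (!"step" %in% names(terms)) terms$step <- seq_len(nrow(terms))
  if ("incremental_adj_r2" %in% names(terms)) {
    terms$contribution_pct <-
      100 * diff(c(0, terms$incremental_adj_r2))
  }
  new_lur_model(intercept, terms, stats = stats)
}

#' Predict from a LUR model
#'
#' `newdata` may hold standardized predictor columns (`scale =
#' "standardized"`, the default: prediction is
#' `intercept + sum(beta_k z_k)`) or raw columns (`scale = "raw"`), in
#' which case the model's frozen training `(mean, sd)` are applied first —
#' column statistics are never recomputed from new data.
#'
#' @param object A `lur_model`.
#' @param newdata Tibble of predictor columns; `NULL` returns training
#'   fitted values (fitted models only).
#' @param scale `"standardized"` or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of predictions (ppb).
#' @export
predict.lur_model <- function(object, newdata = NULL,
                              scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (is.null(newdata)) {
    if (is.null(object$fit)) abort("no fitted values: supply newdata")
    return(predict(object$fit))
  }
  if (scale == "raw") {
    if (is.null(object$stats)) {
      abort("raw-scale prediction needs the model's frozen standardization stats")
    }
    newdata <- apply_standardization(newdata, object$stats)
  }
  miss <- setdiff(object$terms$column, names(newdata))
  if (length(miss)) {
    abort(sprintf("newdata lacks model term(s): %s",
                  paste(miss, collapse = ", ")))
  }
  Z <- as.matrix(newdata[, object$terms$column, drop = FALSE])
  as.vector(object$intercept + Z %*% object$terms$beta)
}

#' Per-predictor contribution to explained variance
#'
#' The first selected predictor contributes 100 x its adjusted R2; each
#' later predictor 100 x the adjusted-R2 increment of its step. The
#' contributions telescope: they sum to 100 x the final adjusted R2.
#'
#' @param model A `lur_model` with `incremental_adj_r2` on its terms.
#' @return Tibble (`step`, `column`, `incremental_adj_r2`,
#'   `contribution_pct`).
#' @export
contribution_table <- function(model) {
  stopifnot_cols(model$terms, "incremental_adj_r2", "model$terms")
  model$terms |>
    select("step", "column", "incremental_adj_r2", "contribution_pct")
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> intercept %.2f ppb + %d term(s)\n",
              x$intercept, nrow(x$terms)))
  print(as.data.frame(x$terms), digits = 3)
  if (!is.null(x$fit)) {
    cat(sprintf("fit: R2 %.3f, adj R2 %.3f, RMSE %.2f ppb, MAE %.2f ppb\n",
                x$fit$r2, x$fit$adj_r2, x$fit$rmse, x$fit$mae))
  }
  invisible(x)
}

#' @export
tidy.lur_model <- function(x, ...) {
  bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept,
           std.error = if (!is.null(x$fit))
             summary(x$fit$fit)$coefficients[1, 2] else NA_real_,
           step = 0L, contribution_pct = NA_real_),
    tibble(term = x$terms$column, estimate = x$terms$beta,
           std.error = if ("se" %in% names(x$terms)) x$terms$se else
             NA_real_,
           step = x$terms$step,
           contribution_pct = x$terms$contribution_pct %||% NA_real_)
  )
}

#' @export
glance.lur_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    glance(x$fit)
  } else {
    tibble(r.squared = NA_real_,
           adj.r.squared = max(x$terms$incremental_adj_r2 %||% NA_real_),
           rmse = NA_real_, mae = NA_real_, nobs = NA_integer_,
           df = nrow(x$terms))
  }
}

#' @export
autoplot.lur_model <- function(object, ...) {
  df <- object$terms |>
    mutate(label = sprintf("%d. %s", .data$step, .data$column))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$label, .data$step),
                                   .data$incremental_adj_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("+%.0f%%", .data$contribution_pct)), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "cumulative adjusted R2",
                  title = "Forward-selection path") +
    ggplot2::theme_minimal()
}

#' Write / read a fitted LUR model as a YAML artefact
#'
#' @param model A `lur_model`.
#' @param path File path.
#' @return `write_lur_model()` returns `path` invisibly;
#'   `read_lur_model()` a `lur_model` (without the in-memory `lm` fit).
#' @export
write_lur_model <- function(model, path) {
  obj <- list(
    intercept_ppb = model$intercept,
    gain_threshold = model$gain_threshold,
    terms = purrr::transpose(as.list(model$terms)),
    stats = if (!is.null(model$stats))
      purrr::transpose(as.list(model$stats)),
    fit = if (!is.null(model$fit))
      list(r2 = model$fit$r2, adj_r2 = model$fit$adj_r2,
           rmse = model$fit$rmse, mae = model$fit$mae, n = model$fit$n)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_lur_model
#' @export
read_lur_model <- function(path) {
  obj <- yaml::read_yaml(path)
  terms <- bind_rows(lapply(obj$terms, function(t) as_tibble(t[!sapply(t, is.null)])))
  stats <- if (!is.null(obj$stats)) bind_rows(lapply(obj$stats, as_tibble))
  m <- lur_model(obj$intercept_ppb, terms, stats = stats)
  m$gain_threshold <- obj$gain_threshold %||% NA_real_
  m
}
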