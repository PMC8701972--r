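#' Variance inflation factors
#'
#' `VIF_k = 1/(1 - R2_k)`, where `R2_k` comes from regressing column `k` on
#' the other columns (with intercept). Values above `threshold` (default 3,
#' a conservative collinearity screen) are flagged. Perfect collinearity is
#' reported as `Inf` and flagged rather than erroring.
#'
#' @param data Tibble holding the model's predictor columns.
#' @param columns Character vector of at least two column names.
#' @param threshold Flag level.
#' @return Tibble (`column`, `r2_other`, `vif`, `flag`).
#' @export
vif_table <- function(data, columns, threshold = 3) {
  if (length(columns) < 2) abort("vif_table(): need at least two columns")
  purrr::map_dfr(columns, function(cn) {
    others <- setdiff(columns, cn)
    X <- cbind(1, as.matrix(data[, others, drop = FALSE]))
    yk <- data[[cn]]
    fit <- lm.fit(X, yk)
    r2 <- 1 - sum(fit$residuals^2) / sum((yk - mean(yk))^2)
    vif <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble(column = cn, r2_other = r2, vif = vif, flag = vif > threshold)
  })
}

#' Leave-one-out influence measures with LUR flag thresholds
#'
#' Cook's distance and standardized DFBETAS from the hat-matrix formulas
#' (via [stats::cooks.distance()] and [stats::dfbetas()]), flagged at the
#' conventional sample-size-scaled thresholds: `D_i > 4/n` and
#' `|DFBETAS_ik| > 2/sqrt(n)` (any coefficient, intercept included). A site
#' flagged by both rules at once is `jointly_flagged` — the trigger for
#' [sequential_removal()].
#'
#' @param fit A `lur_ols` from [fit_ols()] (needs `n > p + 2`).
#' @param site_id Optional site identifiers (defaults to row numbers).
#' @return Tibble with one row per observation: `site_id`, `cooks_d`,
#'   `cooks_flag`, one `dfbetas_*` column per coefficient,
#'   `max_abs_dfbetas`, `dfbetas_flag`, `jointly_flagged`.
#' @export
influence_table <- function(fit, site_id = NULL) {
  stopifnot(inherits(fit, "lur_ols"))
  if (fit$n <= fit$p + 2) abort("influence_table(): need n > p + 2")
  d <- unname(cooks.distance(fit$fit))
  dfb <- dfbetas(fit$fit)
  colnames(dfb) <- paste0("dfbetas_",
                          gsub("[`()]", "", colnames(dfb)))
  n <- fit$n
  out <- tibble(
    site_id = site_id %||% as.character(seq_len(n)),
    cooks_d = d,
    cooks_flag = d > 4 / n
  )
  out <- dplyr::bind_cols(out, as_tibble(dfb))
  out$max_abs_dfbetas <- apply(abs(dfb), 1, max)
  out$dfbetas_flag <- out$max_abs_dfbetas > 2 / sqrt(n)
  out$jointly_flagged <- out$cooks_flag & out$dfbetas_flag
  out
}

#' Deterministic sequential removal of influential sites
#'
#' A reproducible stand-in for case-by-case manual review of suspect
#' monitors: repeatedly refit, flag sites exceeding both the Cook's
#' distance (`> 4/n`) and DFBETAS (`> 2/sqrt(n)`, any coefficient) rules,
#' remove the doubly-flagged site with the largest Cook's distance, and
#' repeat until no site is doubly flagged or `max_removals` is reached.
#' Every removal is logged with the model's adjusted R2 and coefficients
#' before and after. Stops with a warning rather than reducing the fit
#' below `n > p + 2`.
#'
#' @param data Tibble with response, predictors, and a `site_id` column.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @param max_removals Safety cap on the number of removals.
#' @return The cleaned tibble, with the removal log in the `removal_log`
#'   attribute ([removal_log()]).
#' @export
sequential_removal <- function(data, response, predictors,
                               max_removals = 10L) {
  stopifnot_cols(data, c("site_id", response, predictors), "data")
  log <- list()
  repeat {
    fit <- fit_ols(data, response, predictors)
    infl <- influence_table(fit, site_id = data$site_id)
    flagged <- filter(infl, .data$jointly_flagged)
    if (nrow(flagged) == 0 || length(log) >= max_removals) break
    if (nrow(data) - 1 <= length(predictors) + 2) {
      warn("sequential_removal(): stopping early; removal would leave n <= p + 2")
      break
    }
    worst <- flagged$site_id[which.max(flagged$cooks_d)]
    after <- fit_ols(data[data$site_id != worst, ], response, predictors)
    log[[length(log) + 1L]] <- tibble(
      removal = length(log) + 1L,
      site_id = worst,
      cooks_d = max(flagged$cooks_d),
      n_before = fit$n, adj_r2_before = fit$adj_r2,
      adj_r2_after = after$adj_r2,
      coef_before = list(coef(fit$fit)), coef_after = list(coef(after$fit))
    )
    data <- data[data$site_id != worst, ]
  }
  attr(data, "removal_log") <- if (length(log)) bind_rows(log) else
    tibble(removal = integer(), site_id = character(), cooks_d = double(),
           n_before = integer(), adj_r2_before = double(),
           adj_r2_after = double(), coef_before = list(),
           coef_after = list())
  data
}

#' @rdname sequential_removal
#' @export
removal_log <- function(data) attr(data, "removal_log")

#' Spatial weight matrix for Moran's I
#'
#' Default `"idw"`: inverse Euclidean distance, zero diagonal, row sums
#' left unstandardized. `"knn"`: symmetric 0/1 weights for the `k` nearest
#' neighbours. `"adjacency"`: 0/1 weights for pairs within `adjacency_dist`
#' (useful for hand-checkable fixtures).
#'
#' @param x,y Site coordinates (metres).
#' @param scheme Weight scheme.
#' @param k Neighbour count for `"knn"`.
#' @param adjacency_dist Distance cut-off for `"adjacency"`.
#' @return An n x n numeric weight matrix with zero diagonal.
#' @export
spatial_weights <- function(x, y, scheme = c("idw", "knn", "adjacency"),
                            k = 8L, adjacency_dist = NULL) {
  scheme <- match.arg(scheme)
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- switch(scheme,
    idw = {
      wm <- 1 / d
      diag(wm) <- 0
      wm
    },
    knn = {
      wm <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(min(k, n - 1) + 1)]
        wm[i, nb] <- 1
      }
      pmax(wm, t(wm))
    },
    adjacency = {
      if (is.null(adjacency_dist)) abort("adjacency scheme needs adjacency_dist")
      wm <- (d > 0 & d <= adjacency_dist) * 1
      diag(wm) <- 0
      wm
    }
  )
  w
}

#' Moran's I of model residuals with a permutation test
#'
#' `I = (n/W) * sum_ij w_ij (e_i - ebar)(e_j - ebar) / sum_i (e_i - ebar)^2`
#' with `W = sum_ij w_ij`; the exact null expectation is
#' `E[I] = -1/(n - 1)`. The p-value comes from seeded random permutations
#' of the residuals over the site locations (two-sided, distance from
#' `E[I]`); the analytic normal-approximation p-value (randomization-free,
#' normality assumption) is reported alongside for reference.
#'
#' @param values Residual vector (length >= 4, non-constant).
#' @param x,y Site coordinates, or `weights` directly.
#' @param weights Optional n x n weight matrix (zero diagonal); overrides
#'   `scheme`.
#' @param scheme,k Passed to [spatial_weights()].
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param seed Permutation seed.
#' @return One-row tibble: `i`, `expectation`, `sd_norm`, `p_norm`,
#'   `p_perm`, `n`, `n_perm`, `scheme`.
#' @export
morans_i <- function(values, x = NULL, y = NULL, weights = NULL,
                     scheme = "idw", k = 8L, n_perm = 999L, seed = 1L) {
  n <- length(values)
  if (n < 4) abort("morans_i(): need at least 4 sites")
  if (sd(values) == 0) abort("morans_i(): zero variance in residuals")
  w <- weights %||% spatial_weights(x, y, scheme = scheme, k = k)
  stopifnot(nrow(w) == n, ncol(w) == n)

  moran_stat <- function(e) {
    ec <- e - mean(e)
    (n / sum(w)) * as.numeric(t(ec) %*% w %*% ec) / sum(ec^2)
  }
  i_obs <- moran_stat(values)
  e_i <- -1 / (n - 1)

  # analytic randomization variance (kurtosis-corrected) with a normal
  # approximation for the reference p-value
  w_sym <- w + t(w)
  s1 <- 0.5 * sum(w_sym^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  w0 <- sum(w)
  vc <- values - mean(values)
  kurt <- n * sum(vc^4) / sum(vc^2)^2
  var_rand <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * w0^2) -
                 kurt * (n * (n - 1) * s1 - 2 * n * s2 + 6 * w0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * w0^2) - 1 / (n - 1)^2
  sd_norm <- sqrt(var_rand)
  p_norm <- 2 * pnorm(abs(i_obs - e_i) / sd_norm, lower.tail = FALSE)

  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) moran_stat(sample(values)), 0)
  })
  p_perm <- (1 + sum(abs(perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)

  out <- tibble(i = i_obs, expectation = e_i, sd_norm = sd_norm,
                p_norm = p_norm, p_perm = p_perm, n = n,
                n_perm = as.integer(n_perm),
                scheme = if (is.null(weights)) scheme else "custom")
  attr(out, "permutations") <- perm
  out
}
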