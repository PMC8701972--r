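#' Parameter-recovery experiment over seeded synthetic worlds
#'
#' The package's end-to-end correctness experiment: for each of `n_worlds`
#' seeds, generate a full synthetic world (default study conditions: 105
#' sites, the four generative terms among 45 decoy candidates, generative
#' R2 calibrated to 0.63), run the extraction -> screening ->
#' standardization -> forward-selection chain, and compare the selected
#' model with the generating truth.
#'
#' @param n_worlds Number of seeded worlds.
#' @param seed Master seed; world `w` uses a sub-seed derived from it.
#' @param config_fn Function `(seed) -> world_config`, for customized
#'   conditions.
#' @return A list: `per_world` (one row per world: `exact`
#'   selected-set == truth, `contains_truth`, `n_extra`, `n_selected`,
#'   `true_r2` of the truth-term OLS fit), `coefficients` (per truth term:
#'   mean recovered beta over the worlds that selected it, Monte-Carlo SE,
#'   true beta), and `summary` (recovery rates).
#' @export
recovery_experiment <- function(n_worlds = 50L, seed = 1L,
                                config_fn = function(s) world_config(seed = s)) {
  per_world <- list()
  coef_rows <- list()
  for (w in seq_len(n_worlds)) {
    cfg <- config_fn(op_seed(seed, paste0("recovery_world_", w)))
    world <- generate_world(cfg)
    truth <- attr(world$annual, "truth")
    data <- dplyr::inner_join(world$z, world$annual, by = "site_id")
    attributes(data)$predictor_info <- predictor_info(world$z)
    attributes(data)$standardization <- standardization_stats(world$z)
    model <- forward_select(data, "no2_ppb")
    sel <- model$terms$column
    true_cols <- truth$terms$column
    true_fit <- fit_ols(data, "no2_ppb", intersect(true_cols, names(data)))
    per_world[[w]] <- tibble(
      world = w, seed = cfg$seed,
      exact = setequal(sel, true_cols),
      contains_truth = all(true_cols %in% sel),
      n_selected = length(sel),
      n_extra = length(setdiff(sel, true_cols)),
      true_r2 = true_fit$r2
    )
    hit <- model$terms[model$terms$column %in% true_cols, c("column", "beta")]
    if (nrow(hit)) coef_rows[[w]] <- mutate(hit, world = w)
  }
  per_world <- bind_rows(per_world)
  coefs <- bind_rows(coef_rows) |>
    group_by(.data$column) |>
    summarise(mean_beta = mean(.data$beta),
              mc_se = sd(.data$beta) / sqrt(dplyr::n()),
              n_recovered = dplyr::n(), .groups = "drop") |>
    left_join(rename(truth_model()$terms, true_beta = "beta"),
              by = "column") |>
    mutate(bias = .data$mean_beta - .data$true_beta,
           within_2se = abs(.data$bias) <= 2 * .data$mc_se)
  list(
    per_world = per_world,
    coefficients = coefs,
    summary = tibble(
      n_worlds = n_worlds,
      exact_rate = mean(per_world$exact),
      contains_rate = mean(per_world$contains_truth),
      mean_extra = mean(per_world$n_extra),
      mean_true_r2 = mean(per_world$true_r2)
    )
  )
}

#' Null-safety experiment: selection and CV when no predictor matters
#'
#' For each seeded world the measured response is replaced by pure noise
#' independent of every candidate; forward selection is run on the full
#' candidate set and repeated 5-fold CV on a fixed 4-column model,
#' measuring (a) how often the >1% adjusted-R2 gain rule admits at least
#' one spurious predictor and (b) the aggregate null CV R2.
#'
#' @inheritParams recovery_experiment
#' @param cv_repeats Repeats for the per-world null cross-validation.
#' @return List with `per_world` (`n_spurious`, `cv_r2`) and `summary`
#'   (`spurious_rate`, `mean_cv_r2`).
#' @export
null_experiment <- function(n_worlds = 50L, seed = 1L, cv_repeats = 50L,
                            config_fn = function(s) world_config(seed = s)) {
  rows <- list()
  for (w in seq_len(n_worlds)) {
    cfg <- config_fn(op_seed(seed, paste0("null_world_", w)))
    world <- generate_world(cfg)
    data <- world$z
    data$no2_ppb <- with_seed(op_seed(cfg$seed, "null_y"), {
      rnorm(nrow(data), 27.6, 10)
    })
    attributes(data)$predictor_info <- predictor_info(world$z)
    model <- forward_select(data, "no2_ppb")
    cv <- kfold_cv(data, "no2_ppb",
                   predictors = cfg$truth$terms$column,
                   k = 5L, n_repeats = cv_repeats, seed = cfg$seed)
    rows[[w]] <- tibble(world = w, seed = cfg$seed,
                        n_spurious = nrow(model$terms),
                        cv_r2 = glance(cv)$r2)
  }
  per_world <- bind_rows(rows)
  list(per_world = per_world,
       summary = tibble(n_worlds = n_worlds,
                        spurious_rate = mean(per_world$n_spurious >= 1),
                        mean_cv_r2 = mean(per_world$cv_r2)))
}
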