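test_that("fit_ols reproduces closed-form simple regression and exact fits", {
  # y exactly linear in z
  d <- tibble::tibble(z = c(-1, 0, 1, 2), y = 5 + 2 * c(-1, 0, 1, 2))
  f <- fit_ols(d, "y", "z")
  expect_equal(unname(coef(f$fit)), c(5, 2), tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-10)

  # hand-computed: x = {0,1,2}, y = {1,2,4} -> slope 1.5, intercept 5/6
  d2 <- tibble::tibble(x = c(0, 1, 2), y = c(1, 2, 4))
  f2 <- fit_ols(d2, "y", "x")
  expect_equal(unname(coef(f2$fit)), c(5 / 6, 1.5), tolerance = 1e-12)

  # independent y: adjusted R2 near zero, possibly negative
  set.seed(41)
  d3 <- tibble::tibble(z = rnorm(500), y = rnorm(500))
  f3 <- fit_ols(d3, "y", "z")
  expect_lt(abs(f3$adj_r2), 0.02)
  expect_lte(f3$adj_r2, f3$r2)

  # residuals sum to ~0 with an intercept
  expect_lt(abs(sum(resid(f3$fit))), 1e-8)
})

test_that("fit_ols names offending columns on rank deficiency", {
  set.seed(42)
  d <- tibble::tibble(a = rnorm(20))
  d$b <- 2 * d$a
  d$y <- rnorm(20)
  expect_error(fit_ols(d, "y", c("a", "b")), "b")
})

test_that("a single wrong-sign candidate yields the intercept-only model", {
  set.seed(43)
  z <- as.vector(scale(rnorm(50)))
  d <- tibble::tibble(z1 = z, y = 10 + 3 * z + rnorm(50, 0, 0.5))
  m <- forward_select(d, "y", candidates = "z1", signs = c(z1 = "-"))
  expect_equal(nrow(m$terms), 0)
  expect_equal(m$intercept, mean(d$y))
  expect_true(all(m$trace$verdict == "wrong_sign"))
})

test_that("selection agrees with the independent exhaustive greedy oracle", {
  for (seed in 1:12) {
    n <- sample(25:60, 1)
    p <- sample(3:6, 1)
    Z <- random_design(n, p, seed = 400 + seed)
    set.seed(500 + seed)
    k <- sample(1:p, 1)
    beta <- runif(p, -3, 3) * (seq_len(p) <= k)
    y <- 20 + Z %*% beta + rnorm(n, 0, 2)
    signs_chr <- ifelse(runif(p) < 0.5, "+", "-")
    # give true terms their actual sign so some are admissible
    signs_chr[seq_len(k)] <- ifelse(beta[seq_len(k)] >= 0, "+", "-")
    names(signs_chr) <- colnames(Z)
    d <- tibble::as_tibble(as.data.frame(Z))
    d$y <- as.vector(y)
    m <- forward_select(d, "y", candidates = colnames(Z), signs = signs_chr)
    oracle <- oracle_forward_select(
      as.vector(y), Z, as.list(ifelse(signs_chr == "+", 1, -1)))
    expect_identical(m$terms$column, oracle)
  }
})

test_that("selection is invariant to candidate order and self-consistent", {
  Z <- random_design(60, 6, seed = 45)
  set.seed(46)
  y <- 25 + 2 * Z[, 1] - 1.5 * Z[, 2] + rnorm(60, 0, 1.5)
  signs <- setNames(c("+", "-", "+", "-", "+", "-"), colnames(Z))
  d <- tibble::as_tibble(as.data.frame(Z)); d$y <- y
  m1 <- forward_select(d, "y", candidates = colnames(Z), signs = signs)
  perm <- rev(colnames(Z))
  m2 <- forward_select(d, "y", candidates = perm, signs = signs[perm])
  expect_identical(m1$terms$column, m2$terms$column)
  expect_equal(m1$terms$beta, m2$terms$beta)

  # greedy consistency: re-run on its own selection reproduces the model
  m3 <- forward_select(d, "y", candidates = m1$terms$column,
                       signs = signs[m1$terms$column])
  expect_identical(m3$terms$column, m1$terms$column)

  # sign safety and gain audit
  sgn <- ifelse(m1$terms$expected_sign == "+", 1, -1)
  expect_true(all(sign(m1$terms$beta) == sgn))
  expect_true(all(m1$terms$contribution_pct / 100 > m1$gain_threshold))
})

test_that("contributions telescope to 100 x final adjusted R2", {
  Z <- random_design(80, 5, seed = 47)
  set.seed(48)
  y <- 30 + 3 * Z[, 1] + 2 * Z[, 2] - 2 * Z[, 3] + rnorm(80, 0, 2)
  signs <- setNames(c("+", "+", "-", "+", "-"), colnames(Z))
  d <- tibble::as_tibble(as.data.frame(Z)); d$y <- y
  m <- forward_select(d, "y", candidates = colnames(Z), signs = signs)
  ct <- contribution_table(m)
  expect_equal(sum(ct$contribution_pct), 100 * m$fit$adj_r2,
               tolerance = 0.5)
  # single-predictor model: contribution = 100 x adj R2
  m1 <- forward_select(d, "y", candidates = colnames(Z)[1],
                       signs = signs[1])
  expect_equal(m1$terms$contribution_pct, 100 * m1$fit$adj_r2,
               tolerance = 1e-8)
})

test_that("a reference-style coefficient model predicts and round-trips through YAML", {
  terms <- tibble::tibble(
    column = c("satellite", "major_roads_5000", "vegetation_1800",
               "impervious_7000"),
    beta = c(6.03, 3.02, -3.43, 1.87),
    incremental_adj_r2 = c(0.45, 0.53, 0.61, 0.63))
  stats <- tibble::tibble(column = terms$column,
                          mean = c(8, 4, 30, 10), sd = c(3, 2, 15, 8))
  m <- lur_model(27.40, terms, stats = stats)
  z0 <- tibble::as_tibble(setNames(as.list(rep(0, 4)), terms$column))
  expect_equal(predict(m, z0), 27.40)
  # raw input at the training means standardizes to zero
  raw <- tibble::as_tibble(setNames(as.list(stats$mean), stats$column))
  expect_equal(predict(m, raw, scale = "raw"), 27.40)
  # one SD of satellite moves the prediction by its beta
  raw2 <- raw; raw2$satellite <- raw2$satellite + 3
  expect_equal(predict(m, raw2, scale = "raw"), 27.40 + 6.03)

  p <- withr::local_tempfile(fileext = ".yaml")
  write_lur_model(m, p)
  m2 <- read_lur_model(p)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms$beta, m$terms$beta)
  expect_equal(predict(m2, z0), 27.40)
  expect_equal(m2$terms$contribution_pct, c(45, 8, 8, 2), tolerance = 1e-9)
})

test_that("tidy and glance expose broom-style summaries", {
  Z <- random_design(40, 3, seed = 49)
  set.seed(50)
  y <- 20 + 2 * Z[, 1] + rnorm(40)
  d <- tibble::as_tibble(as.data.frame(Z)); d$y <- y
  m <- forward_select(d, "y", candidates = colnames(Z),
                      signs = setNames(c("+", "+", "-"), colnames(Z)))
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(td$term[1], "(Intercept)")
  g <- glance(m)
  expect_true(all(c("adj.r.squared", "rmse", "nobs") %in% names(g)))
})
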