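# Independent oracles used across the test files. These deliberately use
# different machinery (plain loops, lm()/summary(), uniroot) than the
# package's implementation paths.

# Exhaustive cell-membership mean: loop over every cell of the raster.
oracle_buffer_average <- function(raster, px, py, radius) {
  nx <- ncol(raster$values); ny <- nrow(raster$values)
  vals <- c(); n_in <- 0
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      cx <- raster$xmin + (ix - 0.5) * raster$cell
      cy <- raster$ymin + (iy - 0.5) * raster$cell
      if (sqrt((cx - px)^2 + (cy - py)^2) <= radius) {
        v <- raster$values[iy, ix]
        if (!is.na(v)) vals <- c(vals, v)
        n_in <- n_in + 1
      }
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

# Root-finding clip: length of a segment inside a disc, found by bisecting
# the signed distance |P(t) - C| - r on a fine grid of brackets.
oracle_segment_disc_length <- function(px, py, x0, y0, x1, y1, r) {
  f <- function(t) {
    sqrt((x0 + t * (x1 - x0) - px)^2 + (y0 + t * (y1 - y0) - py)^2) - r
  }
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ts <- seq(0, 1, length.out = 2001)
  fs <- vapply(ts, f, 0)
  roots <- c()
  for (i in seq_len(length(ts) - 1)) {
    if (fs[i] == 0) roots <- c(roots, ts[i])
    if (fs[i] * fs[i + 1] < 0) {
      roots <- c(roots, uniroot(f, c(ts[i], ts[i + 1]), tol = 1e-14)$root)
    }
  }
  if (fs[length(ts)] == 0) roots <- c(roots, 1)
  pts <- sort(unique(c(0, roots, 1)))
  inside <- 0
  for (i in seq_len(length(pts) - 1)) {
    mid <- (pts[i] + pts[i + 1]) / 2
    if (f(mid) <= 0) inside <- inside + (pts[i + 1] - pts[i])
  }
  inside * len
}

# Independent greedy sign-constrained forward selection using lm() and
# summary()$adj.r.squared; same admissibility semantics as the spec rule.
oracle_forward_select <- function(y, Z, signs, thr = 0.01) {
  cand <- colnames(Z)
  cors <- vapply(cand, function(cn) abs(cor(y, Z[, cn])), 0)
  sel <- character(0)
  cur <- 0
  repeat {
    rem <- setdiff(cand, sel)
    if (!length(rem)) break
    best <- NULL
    for (cn in rem) {
      df <- as.data.frame(Z[, c(sel, cn), drop = FALSE])
      df$.y <- y
      fit <- lm(.y ~ ., data = df)
      b <- coef(fit)[-1]
      names(b) <- c(sel, cn)
      if (any(is.na(b))) next
      if (sign(b[[cn]]) != signs[[cn]]) next
      if (length(sel) && any(sign(b[sel]) != unlist(signs[sel]))) next
      gain <- summary(fit)$adj.r.squared - cur
      if (gain <= thr) next
      if (is.null(best) || gain > best$gain + 1e-12 ||
            (abs(gain - best$gain) <= 1e-12 &&
               (cors[[cn]] > cors[[best$cn]] ||
                  (cors[[cn]] == cors[[best$cn]] && cn < best$cn)))) {
        best <- list(cn = cn, gain = gain)
      }
    }
    if (is.null(best)) break
    sel <- c(sel, best$cn)
    cur <- cur + best$gain
  }
  sel
}

# Explicit leave-one-out influence: refit without each row.
oracle_loo_influence <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  full <- lm.fit(Xi, y)
  s2_full <- sum(full$residuals^2) / (n - p - 1)
  cooks <- numeric(n)
  dfb <- matrix(0, n, p + 1)
  XtXinv <- solve(crossprod(Xi))
  for (i in seq_len(n)) {
    fi <- lm.fit(Xi[-i, , drop = FALSE], y[-i])
    db <- full$coefficients - fi$coefficients
    yhat_diff <- Xi %*% db
    cooks[i] <- sum(yhat_diff^2) / ((p + 1) * s2_full)
    s2_i <- sum(fi$residuals^2) / (n - 1 - p - 1)
    dfb[i, ] <- db / sqrt(s2_i * diag(XtXinv))
  }
  list(cooks = cooks, dfbetas = dfb)
}

# Brute-force double-sum Moran's I.
oracle_moran <- function(e, w) {
  n <- length(e)
  eb <- mean(e)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * (e[i] - eb) * (e[j] - eb)
  }
  (n / sum(w)) * num / sum((e - eb)^2)
}

# Scalar convenience wrapper around the tidy extraction surface.
buffer_mean_for_test <- function(raster, px, py, radius) {
  extract_buffer_average(tibble::tibble(site_id = "s", x = px, y = py),
                         raster, radius)
}

# Small random standardized design matrix helper.
random_design <- function(n, p, seed, prefix = "c") {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  colnames(Z) <- paste0(prefix, seq_len(p))
  Z
}
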