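# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (normal equations, textbook sums of
# squares, explicit product-limit and hypergeometric tables, exhaustive
# enumeration, plain nested loops) so they share no code path with the
# package implementations they check.

oracle_ols <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tss <- sum((y - mean(y))^2)
  list(slope = beta[2], se = se, t = beta[2] / se,
       p = 2 * stats::pt(-abs(beta[2] / se), n - 2),
       r2 = 1 - sum(resid^2) / tss)
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

oracle_anova_f <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(g) - 1; df2 <- length(values) - length(g)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

oracle_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# exact one-sided (greater) rank-sum p by exhaustive subset enumeration,
# computed on raw values with order()-based midranks
oracle_ranksum_exact <- function(x, y) {
  z <- c(x, y); nx <- length(x); n <- length(z)
  midrank <- function(v) {
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- (sum(v < v[i])) + (1 + sum(v == v[i])) / 2
    r
  }
  r <- midrank(z)
  w_obs <- sum(r[seq_len(nx)])
  subsets <- utils::combn(n, nx)
  ws <- apply(subsets, 2, function(ii) sum(r[ii]))
  mean(ws >= w_obs - 1e-9)
}

# eigendecomposition-of-covariance PCA oracle
oracle_pca <- function(x) {  # x: observations x features
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- xc %*% ev$vectors
  list(scores = scores, values = ev$values,
       var_explained = ev$values / sum(ev$values))
}

# explicit product-limit estimator, events processed before censorings
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_, n_risk = NA_real_,
                    n_event = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s; out$n_risk[i] <- at_risk; out$n_event[i] <- d
  }
  out
}

# explicit O / E / V log-rank table
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# plain-loop nested LOOCV: outer holds one out; inner LOOCV per k; smallest
# best k; retrain and call. Written with data frames, t.test and
# e1071::svm/predict only.
oracle_nested_loocv <- function(X, y, k_grid, cost = 1) {
  n <- ncol(X)
  feats <- rownames(X)
  rank_feats <- function(cols) {
    tv <- vapply(seq_len(nrow(X)), function(f) {
      a <- X[f, cols][y[cols] == 0]; b <- X[f, cols][y[cols] == 1]
      unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
    }, 1)
    feats[order(-abs(tv), feats)]
  }
  fit_predict <- function(train_cols, test_cols, use_feats) {
    tr <- t(X[use_feats, train_cols, drop = FALSE])
    mu <- colMeans(tr); sd_ <- apply(tr, 2, stats::sd)
    ztr <- scale(tr, center = mu, scale = sd_)
    m <- e1071::svm(ztr, factor(y[train_cols], levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
    zte <- scale(t(X[use_feats, test_cols, drop = FALSE]),
                 center = mu, scale = sd_)
    as.integer(as.character(predict(m, zte)))
  }
  k_grid <- sort(k_grid)
  k_star <- integer(n); call <- integer(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    acc <- numeric(length(k_grid))
    for (kk in seq_along(k_grid)) {
      hits <- logical(length(train))
      for (jj in seq_along(train)) {
        j <- train[jj]
        inner <- setdiff(train, j)
        rf <- rank_feats(inner)[seq_len(k_grid[kk])]
        hits[jj] <- fit_predict(inner, j, rf) == y[j]
      }
      acc[kk] <- mean(hits)
    }
    k_star[i] <- k_grid[which.max(acc)]
    rf <- rank_feats(train)[seq_len(k_star[i])]
    call[i] <- fit_predict(train, i, rf)
  }
  ks <- sort(unique(k_star))
  k_final <- ks[which.max(vapply(ks, function(k) sum(k_star == k), 1L))]
  list(k_star = k_star, call = call, accuracy = mean(call == y),
       k_final = k_final)
}
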