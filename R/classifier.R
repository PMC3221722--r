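# The prognosticator: pooled-t feature ranking + linear SVM, evaluated by
# (a) Monte-Carlo 2/3-split with an inner-LOOCV feature-frequency
# consensus and (b) nested LOOCV with data-driven signature size.
#
# The cross-validation drivers use a moment-subtraction fast path for the
# per-fold t statistics and standardization (sums and sums of squares per
# class, with held-out columns subtracted), so that every ranking and
# every standardization still uses only the fold's training portion; a
# naive triple-loop implementation pins the result exactly in the tests.

values_of <- function(expression) {
  if (inherits(expression, "expression_matrix")) expression$values
  else as.matrix(expression)
}

check_labels <- function(labels, n) {
  labels <- as.integer(as.character(labels))
  if (length(labels) != n) stop_named("labels length must match array count")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_named("labels must be binary 0/1")
  }
  labels
}

# pooled-variance two-sample t per feature, t = (mean_0 - mean_1) / se
t_stats_from_parts <- function(S0, Q0, n0, S1, Q1, n1) {
  m0 <- S0 / n0; m1 <- S1 / n1
  ss <- pmax(Q0 - n0 * m0^2, 0) + pmax(Q1 - n1 * m1^2, 0)
  sp2 <- ss / (n0 + n1 - 2)
  den <- sqrt(sp2 * (1 / n0 + 1 / n1))
  d <- m0 - m1
  t <- ifelse(den > 0, d / den, ifelse(d == 0, 0, sign(d) * Inf))
  t
}

class_moments <- function(X, X2, labels) {
  i1 <- labels == 1L
  list(S0 = rowSums(X[, !i1, drop = FALSE]),
       Q0 = rowSums(X2[, !i1, drop = FALSE]),
       n0 = sum(!i1),
       S1 = rowSums(X[, i1, drop = FALSE]),
       Q1 = rowSums(X2[, i1, drop = FALSE]),
       n1 = sum(i1))
}

drop_sample <- function(mom, x, x2, label) {
  if (label == 1L) {
    mom$S1 <- mom$S1 - x; mom$Q1 <- mom$Q1 - x2; mom$n1 <- mom$n1 - 1L
  } else {
    mom$S0 <- mom$S0 - x; mom$Q0 <- mom$Q0 - x2; mom$n0 <- mom$n0 - 1L
  }
  mom
}

#' Rank features by pooled-variance two-sample t statistic
#'
#' Per feature, the equal-variance two-sample t between classes
#' (`t = (mean of class 0 - mean of class 1) / se`); features are ordered
#' by decreasing |t| with deterministic ties broken by feature id. A
#' zero-pooled-variance feature gets |t| = Inf when the class means
#' differ and t = 0 when they are equal.
#'
#' @param expression an [expression_matrix()] or features x arrays matrix.
#' @param labels binary 0/1 labels, one per array (each class n >= 2).
#' @return data.frame with `feature`, `t`, `abs_t`, ordered by rank.
#' @export
t_rank <- function(expression, labels) {
  X <- values_of(expression)
  labels <- check_labels(labels, ncol(X))
  if (min(table(labels)) < 2) stop_named("each class needs n >= 2")
  mom <- class_moments(X, X * X, labels)
  t <- t_stats_from_parts(mom$S0, mom$Q0, mom$n0, mom$S1, mom$Q1, mom$n1)
  feats <- rownames(X) %||% as.character(seq_len(nrow(X)))
  ord <- order(-abs(t), feats)
  data.frame(feature = feats[ord], t = t[ord], abs_t = abs(t)[ord],
             stringsAsFactors = FALSE)
}

# Minimal linear-SVM fit wrapper; x is samples x features, y integer 0/1.
fit_linear_svm <- function(x, y, cost = 1) {
  yf <- factor(y, levels = c(0L, 1L))
  m <- e1071::svm(x, yf, type = "C-classification", kernel = "linear",
                  cost = cost, scale = FALSE, fitted = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  # libsvm: decision value > 0 predicts the class listed first in m$labels
  positive <- m$levels[m$labels[1]]
  list(w = w, rho = m$rho, positive = as.integer(positive))
}

# decision rule: f > 0 -> positive class, f < 0 -> the other,
# f == 0 (on the boundary) -> call 0
svm_calls <- function(fit, z) {
  f <- drop(z %*% fit$w) - fit$rho
  other <- 1L - fit$positive
  calls <- ifelse(f > 0, fit$positive, other)
  calls[f == 0] <- 0L
  as.integer(calls)
}

#' Train the SVM prognosticator on selected features
#'
#' Features are z-scored with the training mean and sd, then a linear
#' kernel SVM (cost `cost`) is fitted. The returned model carries
#' everything needed for standalone prediction (feature list,
#' standardization, weight vector, bias and orientation).
#'
#' @param expression an [expression_matrix()] or features x arrays matrix.
#' @param labels binary 0/1 labels (both classes represented).
#' @param features character vector of feature ids to use.
#' @param cost SVM cost parameter (default 1).
#' @return object of class `prognostic_model`.
#' @export
train_prognostic <- function(expression, labels, features, cost = 1) {
  X <- values_of(expression)
  labels <- check_labels(labels, ncol(X))
  if (length(unique(labels)) < 2) stop_named("training needs both classes")
  miss <- setdiff(features, rownames(X))
  if (length(miss) > 0) stop_named("feature '%s' not in expression matrix", miss[1])
  V <- X[features, , drop = FALSE]
  ctr <- rowMeans(V)
  scl <- apply(V, 1, stats::sd)
  if (any(scl == 0)) {
    stop_named("feature '%s' has zero variance in the training data",
               features[which(scl == 0)[1]])
  }
  z <- t((V - ctr) / scl)
  fit <- fit_linear_svm(z, labels, cost)
  calls <- svm_calls(fit, z)
  model <- structure(list(
    schema_version = 1L,
    features = features,
    center = stats::setNames(ctr, features),
    scale = stats::setNames(scl, features),
    w = stats::setNames(fit$w, features),
    rho = fit$rho,
    positive = fit$positive,
    cost = cost,
    mode = if (inherits(expression, "expression_matrix")) expression$mode
           else "unknown",
    training_accuracy = mean(calls == labels)
  ), class = "prognostic_model")
  model
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("prognostic_model: %d features, linear SVM (cost %.3g), mode %s\n",
              length(x$features), x$cost, x$mode))
  cat(sprintf("  training accuracy: %.3f\n", x$training_accuracy))
  invisible(x)
}

#' Predict recurrence calls with a trained prognosticator
#'
#' @param object a [train_prognostic()] model.
#' @param expression an [expression_matrix()] or features x arrays matrix
#'   containing at least the model's features, in the summarization mode
#'   the model was trained on.
#' @param ... unused.
#' @return named integer vector of calls, 0 = "no recurrence",
#'   1 = "recurrence"; samples exactly on the decision boundary get 0.
#' @export
predict.prognostic_model <- function(object, expression, ...) {
  X <- values_of(expression)
  miss <- setdiff(object$features, rownames(X))
  if (length(miss) > 0) {
    stop_named("model feature '%s' missing from expression matrix", miss[1])
  }
  if (inherits(expression, "expression_matrix") &&
      !identical(expression$mode, object$mode) && object$mode != "unknown") {
    warning(sprintf("expression mode '%s' differs from model mode '%s'",
                    expression$mode, object$mode))
  }
  V <- X[object$features, , drop = FALSE]
  z <- t((V - object$center) / object$scale)
  calls <- svm_calls(list(w = object$w, rho = object$rho,
                          positive = object$positive), z)
  stats::setNames(calls, colnames(X))
}

#' Serialize a prognostic model to JSON
#' @param model a `prognostic_model`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  json <- jsonlite::toJSON(unclass(model), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(path)
  } else {
    json
  }
}

#' Deserialize a prognostic model from JSON
#' @param x a file path or JSON string produced by [model_to_json()].
#' @export
model_from_json <- function(x) {
  obj <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x)
  for (f in c("center", "scale", "w")) {
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), obj$features)
  }
  obj$positive <- as.integer(obj$positive)
  obj$schema_version <- as.integer(obj$schema_version)
  structure(obj, class = "prognostic_model")
}

#' Leave-one-out feature-frequency consensus
#'
#' For each left-out array, ranks features by |t| on the remaining arrays
#' and records the top `k`; the consensus profile is the `k` features most
#' frequently appearing across the n folds, with ties broken by higher
#' mean |t| across folds and then by feature id.
#'
#' @inheritParams t_rank
#' @param k signature size (features recorded per fold).
#' @return list with `frequency` (data.frame feature/frequency/mean_abs_t)
#'   and `consensus` (character vector of k feature ids).
#' @export
inner_loocv_consensus <- function(expression, labels, k) {
  X <- values_of(expression)
  labels <- check_labels(labels, ncol(X))
  n <- ncol(X)
  if (n < 3) stop_named("need at least 3 arrays")
  res <- consensus_fast(X, X * X, seq_len(n), labels, k,
                        on_degenerate = "error")
  feats <- rownames(X) %||% as.character(seq_len(nrow(X)))
  ord <- order(-res$freq, -res$mean_abs, feats)
  keep <- ord[res$freq[ord] > 0]
  tab <- data.frame(feature = feats[keep], frequency = res$freq[keep],
                    mean_abs_t = res$mean_abs[keep], stringsAsFactors = FALSE)
  list(frequency = tab, consensus = feats[res$consensus])
}

# Shared fast path: LOOCV top-k frequency consensus over the arrays in
# `idx`. Returns integer feature indices (length k) plus the frequency and
# mean-|t| vectors over all features.
consensus_fast <- function(X, X2, idx, labels, k,
                           on_degenerate = c("error", "skip")) {
  on_degenerate <- match.arg(on_degenerate)
  p <- nrow(X)
  mom <- class_moments(X[, idx, drop = FALSE], X2[, idx, drop = FALSE],
                       labels[idx])
  freq <- integer(p)
  abs_sum <- numeric(p)
  n_folds <- 0L
  for (j in idx) {
    mj <- drop_sample(mom, X[, j], X2[, j], labels[j])
    if (mj$n0 < 1 || mj$n1 < 1) {
      if (on_degenerate == "error") {
        stop_named("class degenerate after leaving one array out")
      }
      next
    }
    t <- t_stats_from_parts(mj$S0, mj$Q0, mj$n0, mj$S1, mj$Q1, mj$n1)
    a <- abs(t)
    top <- order(-a)[seq_len(k)]
    freq[top] <- freq[top] + 1L
    abs_sum <- abs_sum + a
    n_folds <- n_folds + 1L
  }
  if (n_folds == 0L) stop_named("all leave-one-out folds were degenerate")
  mean_abs <- abs_sum / n_folds
  consensus <- order(-freq, -mean_abs, seq_len(p))[seq_len(k)]
  list(consensus = consensus, freq = freq, mean_abs = mean_abs,
       n_folds = n_folds)
}

# standardize the selected feature rows over training columns, via moments
standardize_block <- function(X, rows, cols) {
  V <- X[rows, cols, drop = FALSE]
  m <- rowMeans(V)
  s <- apply(V, 1, stats::sd)
  s[s == 0] <- 1  # constant feature carries no information after centering
  list(z = t((V - m) / s), m = m, s = s)
}

#' Monte-Carlo cross-validation of the prognosticator
#'
#' Per replicate: a uniform random two-thirds training split (resampled,
#' with a count kept, if a class ends up with fewer than 2 training
#' arrays, so both classes survive every inner leave-one-out fold), the
#' leave-one-out top-`k` feature-frequency consensus on the training
#' portion, an SVM trained on the consensus features, and the accuracy on
#' the held-out third. The 95% confidence interval is the normal
#' approximation `mean +/- 1.96 sd / sqrt(R)` over replicate accuracies.
#'
#' @inheritParams t_rank
#' @param R number of Monte-Carlo replicates (>= 2).
#' @param k fixed signature size (default 30).
#' @param seed integer seed; same seed and inputs give bit-identical
#'   results.
#' @param cost SVM cost parameter.
#' @return object of class `monte_carlo_result` with per-replicate
#'   accuracies, `mean_accuracy`, `ci_low`, `ci_high`.
#' @export
monte_carlo_evaluate <- function(expression, labels, R, k = 30, seed = 1,
                                 cost = 1) {
  X <- values_of(expression)
  labels <- check_labels(labels, ncol(X))
  n <- ncol(X)
  if (n < 9) stop_named("Monte-Carlo evaluation needs n >= 9")
  if (R < 2) stop_named("need R >= 2 replicates")
  X2 <- X * X
  n_train <- ceiling(2 * n / 3)
  set.seed(derive_seed(seed, "monte-carlo"))
  acc <- numeric(R)
  n_resampled <- 0L
  for (r in seq_len(R)) {
    repeat {
      tr <- sample.int(n, n_train)
      if (min(tabulate(labels[tr] + 1L, 2L)) >= 2L) break
      n_resampled <- n_resampled + 1L
    }
    te <- setdiff(seq_len(n), tr)
    cons <- consensus_fast(X, X2, tr, labels, k, on_degenerate = "skip")
    std <- standardize_block(X, cons$consensus, tr)
    fit <- fit_linear_svm(std$z, labels[tr], cost)
    zte <- t((X[cons$consensus, te, drop = FALSE] - std$m) / std$s)
    acc[r] <- mean(svm_calls(fit, zte) == labels[te])
  }
  m <- mean(acc)
  half <- 1.96 * stats::sd(acc) / sqrt(R)
  structure(list(R = R, k_fixed = k, seed = seed, accuracies = acc,
                 mean_accuracy = m, ci_low = m - half, ci_high = m + half,
                 n_resampled = n_resampled),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf(
    "monte_carlo_result: R = %d, k = %d; accuracy %.1f%% (95%% CI %.1f%% - %.1f%%)\n",
    x$R, x$k_fixed, 100 * x$mean_accuracy, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Compare two Monte-Carlo evaluations
#'
#' Welch two-sample t-test on the replicate accuracy vectors of two
#' [monte_carlo_evaluate()] results (the declared dialect for testing the
#' hypothesis that two assays have similar accuracy).
#'
#' @param result_a,result_b `monte_carlo_result` objects.
#' @return list with `t_stat`, `df`, `p_value`.
#' @export
compare_assays <- function(result_a, result_b) {
  a <- result_a$accuracies; b <- result_b$accuracies
  if (length(a) < 2 || length(b) < 2) stop_named("need R >= 2 on both sides")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t_stat = 0, df = NA_real_, p_value = 1))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = .Machine$double.xmin))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = clamp_p(ht$p.value))
}

#' Nested leave-one-out cross-validation with data-driven signature size
#'
#' Outer loop over arrays: with one array held out, an inner plain LOOCV
#' on the remaining N-1 (ranking on N-2, training, predicting the inner
#' held-out) measures the accuracy for each signature size in `k_grid`;
#' the best size k* (ties go to the smallest k) is then used to rank on
#' the N-1 arrays, train, and call the outer held-out array. The final
#' profile size is the modal k* across outer folds (ties to the smallest)
#' and the final features are the top-k_final ranking on all arrays.
#'
#' Rankings inside folds use the pooled-variance t statistic; a class
#' reduced to a single array still contributes its mean (with zero sum of
#' squares). Folds whose training portion loses a class entirely are
#' skipped and counted; more than `max_skip_frac` skipped folds aborts.
#'
#' @inheritParams t_rank
#' @param k_grid candidate signature sizes (subset of 1..n_features).
#' @param cost SVM cost parameter.
#' @param seed recorded for provenance; the procedure itself is
#'   deterministic.
#' @param max_skip_frac maximum tolerated fraction of skipped folds.
#' @return object of class `nested_cv_result`: per-outer-fold data.frame
#'   (`held_out`, `k_star`, `call`, `truth`, `correct`), `loocv_accuracy`,
#'   `k_final`, `final_features`.
#' @export
nested_loocv <- function(expression, labels,
                         k_grid = c(5, 10, 15, 20, 25, 30, 40, 50),
                         cost = 1, seed = 1, max_skip_frac = 0.2) {
  X <- values_of(expression)
  labels <- check_labels(labels, ncol(X))
  n <- ncol(X)
  if (n < 4) stop_named("nested LOOCV needs n >= 4")
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1) || any(k_grid > nrow(X))) {
    stop_named("k_grid must lie within 1..%d", nrow(X))
  }
  X2 <- X * X
  kmax <- max(k_grid)
  mom_all <- class_moments(X, X2, labels)
  ids <- colnames(X) %||% as.character(seq_len(n))

  k_star <- integer(n)
  call <- integer(n)
  skipped_outer <- logical(n)
  n_inner_skipped <- 0L
  n_inner_total <- 0L
  for (i in seq_len(n)) {
    mom_o <- drop_sample(mom_all, X[, i], X2[, i], labels[i])
    train <- setdiff(seq_len(n), i)
    if (mom_o$n0 < 1 || mom_o$n1 < 1) {
      skipped_outer[i] <- TRUE
      next
    }
    correct <- matrix(NA, length(train), length(k_grid))
    for (jj in seq_along(train)) {
      j <- train[jj]
      n_inner_total <- n_inner_total + 1L
      mom_ij <- drop_sample(mom_o, X[, j], X2[, j], labels[j])
      if (mom_ij$n0 < 1 || mom_ij$n1 < 1) {
        n_inner_skipped <- n_inner_skipped + 1L
        next
      }
      t <- t_stats_from_parts(mom_ij$S0, mom_ij$Q0, mom_ij$n0,
                              mom_ij$S1, mom_ij$Q1, mom_ij$n1)
      top <- order(-abs(t))[seq_len(kmax)]
      tidx <- setdiff(train, j)
      std <- standardize_block(X, top, tidx)
      znew_all <- (X[top, j] - std$m) / std$s
      for (kk in seq_along(k_grid)) {
        k <- k_grid[kk]
        fit <- fit_linear_svm(std$z[, seq_len(k), drop = FALSE],
                              labels[tidx], cost)
        pred <- svm_calls(fit, matrix(znew_all[seq_len(k)], 1))
        correct[jj, kk] <- pred == labels[j]
      }
    }
    acc_k <- colMeans(correct, na.rm = TRUE)
    if (all(is.nan(acc_k))) {
      skipped_outer[i] <- TRUE
      next
    }
    k_star[i] <- k_grid[which.max(acc_k)]  # k_grid ascending: ties -> smallest
    t_o <- t_stats_from_parts(mom_o$S0, mom_o$Q0, mom_o$n0,
                              mom_o$S1, mom_o$Q1, mom_o$n1)
    top_o <- order(-abs(t_o))[seq_len(k_star[i])]
    std_o <- standardize_block(X, top_o, train)
    fit_o <- fit_linear_svm(std_o$z, labels[train], cost)
    znew <- (X[top_o, i] - std_o$m) / std_o$s
    call[i] <- svm_calls(fit_o, matrix(znew, 1))
  }
  if (n_inner_total > 0 &&
      n_inner_skipped / n_inner_total > max_skip_frac) {
    stop_named("%.0f%% of inner folds skipped (class degeneracy): aborting",
               100 * n_inner_skipped / n_inner_total)
  }
  if (mean(skipped_outer) > max_skip_frac) {
    stop_named("%.0f%% of outer folds skipped (class degeneracy): aborting",
               100 * mean(skipped_outer))
  }
  ok <- !skipped_outer
  folds <- data.frame(held_out = ids[ok], k_star = k_star[ok],
                      call = call[ok], truth = labels[ok],
                      correct = call[ok] == labels[ok],
                      stringsAsFactors = FALSE)
  ks <- sort(unique(folds$k_star))
  counts <- vapply(ks, function(k) sum(folds$k_star == k), integer(1))
  k_final <- ks[which.max(counts)]  # ks ascending: ties -> smallest
  final_features <- t_rank(X, labels)$feature[seq_len(k_final)]
  structure(list(folds = folds,
                 loocv_accuracy = mean(folds$correct),
                 k_final = k_final,
                 final_features = final_features,
                 k_grid = k_grid, seed = seed,
                 n_inner_skipped = n_inner_skipped,
                 n_outer_skipped = sum(skipped_outer)),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf(
    "nested_cv_result: LOOCV accuracy %.1f%% over %d folds; k_final = %d\n",
    100 * x$loocv_accuracy, nrow(x$folds), x$k_final))
  invisible(x)
}
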