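# Per-array QC metrics, detection calls, self-self correlations, and the
# small regression/ANOVA machinery used throughout the analytical-condition
# comparisons.

#' One-sided Wilcoxon rank-sum test (greater)
#'
#' Detection dialect used for probe-set calls: exact enumeration of the
#' rank-sum permutation distribution (midranks, so ties are handled
#' exactly) when the combined sample size is at most 20, otherwise the
#' normal approximation with midranks and tie correction.
#'
#' @param x,y numeric vectors; tests H1: x stochastically greater than y.
#' @return list with `statistic` (rank sum of `x`) and `p_value`.
#' @export
rank_sum_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop_named("rank_sum_greater needs non-empty samples")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (n <= 20) {
    # exact permutation distribution of the rank sum over all subsets
    idx <- utils::combn(n, nx)
    sums <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(sums >= w - 1e-9)
  } else {
    mu <- nx * (n + 1) / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence of a shift
    } else {
      # 0.5 continuity correction toward the null
      z <- (w - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  list(statistic = w, p_value = clamp_p(p))
}

#' Per-array QC report
#'
#' For each array: arithmetic mean of measurement-probe intensities and of
#' background-probe intensities (both on the linear scale), the number of
#' detected probes and the number of detected probe sets. A probe is
#' detected when its one-sided empirical p-value against the array's
#' background-probe distribution, `(1 + #\{background >= probe\}) /
#' (1 + #background)`, is below `alpha`. A probe set is detected when the
#' one-sided Wilcoxon rank-sum test of its probes against the background
#' probes gives `p < alpha`.
#'
#' @param intensities probes x arrays matrix (linear scale).
#' @param annotation validated probe annotation.
#' @param alpha detection level (default 0.06).
#' @return data.frame of class `qc_report`, one row per array.
#' @export
qc_report <- function(intensities, annotation, alpha = 0.06) {
  stopifnot(is.matrix(intensities))
  if (!all(rownames(intensities) == annotation$probe_id)) {
    intensities <- intensities[annotation$probe_id, , drop = FALSE]
  }
  is_bg <- annotation$role == "background"
  if (!any(is_bg)) {
    stop_named("no background probes in annotation: detection unavailable")
  }
  is_meas <- !is_bg
  sets <- annotation$probeset_id[is_meas]
  set_index <- split(seq_len(sum(is_meas)), sets)

  res <- data.frame(
    array_id = colnames(intensities) %||% as.character(seq_len(ncol(intensities))),
    mean_intensity = NA_real_, mean_background = NA_real_,
    n_detected_probes = NA_integer_, n_detected_probesets = NA_integer_,
    detection_alpha = alpha, stringsAsFactors = FALSE
  )
  set_f <- factor(sets, levels = names(set_index))
  set_sizes <- as.vector(table(set_f))
  for (j in seq_len(ncol(intensities))) {
    v <- intensities[, j]
    bg <- v[is_bg]
    mv <- v[is_meas]
    res$mean_intensity[j] <- mean(mv)
    res$mean_background[j] <- mean(bg)

    sbg <- sort(bg)
    n_bg <- length(bg)
    # #{bg >= x} = n_bg - #{bg < x}; findInterval with left.open counts bg < x
    n_lt <- findInterval(mv, sbg, left.open = TRUE)
    n_le <- findInterval(mv, sbg)
    emp_p <- (1 + (n_bg - n_lt)) / (1 + n_bg)
    res$n_detected_probes[j] <- sum(emp_p < alpha)

    no_ties <- !any(n_le != n_lt) && !anyDuplicated(mv) && !anyDuplicated(bg)
    small <- (set_sizes + n_bg) <= 20
    if (no_ties && !any(small)) {
      # vectorized tie-free normal approximation; within-set midranks of a
      # tie-free set always sum to nx(nx+1)/2, so the combined rank sum is
      # W = nx(nx+1)/2 + sum over set probes of #{bg < probe}
      w <- as.vector(rowsum(as.numeric(n_lt), set_f, reorder = FALSE)) +
        set_sizes * (set_sizes + 1) / 2
      n_tot <- set_sizes + n_bg
      mu <- set_sizes * (n_tot + 1) / 2
      sigma2 <- set_sizes * n_bg * (n_tot + 1) / 12
      p <- stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
      res$n_detected_probesets[j] <- sum(p < alpha)
    } else {
      det <- vapply(set_index, function(ii) {
        rank_sum_greater(mv[ii], bg)$p_value < alpha
      }, logical(1))
      res$n_detected_probesets[j] <- sum(det)
    }
  }
  class(res) <- c("qc_report", "data.frame")
  res
}

#' Pairwise self-self Pearson correlations on log2 probe intensities
#'
#' Pearson correlation over the log2 intensities of all measurement probes
#' (all probes when no annotation is supplied), without background
#' subtraction.
#'
#' @param intensities probes x arrays matrix (linear scale).
#' @param annotation optional annotation; when given, only measurement
#'   probes enter the correlation.
#' @return symmetric arrays x arrays correlation matrix with unit diagonal.
#' @export
self_self_correlation <- function(intensities, annotation = NULL) {
  if (ncol(intensities) < 2) stop_named("need at least 2 arrays")
  if (!is.null(annotation)) {
    keep <- annotation$probe_id[annotation$role == "measurement"]
    intensities <- intensities[keep, , drop = FALSE]
  }
  l2 <- log2(intensities)
  sds <- apply(l2, 2, stats::sd)
  if (any(sds == 0)) {
    stop_named("array '%s' has constant intensities: correlation undefined",
               colnames(l2)[which(sds == 0)[1]])
  }
  r <- stats::cor(l2)
  diag(r) <- 1
  r
}

#' Simple linear regression (ordinary least squares)
#'
#' @param response,covariate numeric vectors of equal length (n >= 3);
#'   the covariate must not be constant.
#' @return list of class `regression_result`: `slope`, `se`, `t_stat`,
#'   `p_value` (two-sided, t with n - 2 df), `r_squared`, `intercept`, `n`.
#' @export
regress <- function(response, covariate) {
  n <- length(response)
  if (n != length(covariate)) stop_named("response/covariate length mismatch")
  if (n < 3) stop_named("regression needs n >= 3")
  if (stats::sd(covariate) == 0) stop_named("covariate is constant")
  fit <- stats::lm(response ~ covariate)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    slope = co[2, 1], se = co[2, 2], t_stat = co[2, 3],
    p_value = clamp_p(co[2, 4]), r_squared = s$r.squared,
    intercept = co[1, 1], n = n
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("b = %.4g +/- %.4g, t = %.3g, p = %.3g, R^2 = %.3f, n = %d\n",
              x$slope, x$se, x$t_stat, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Regress pairwise self-self correlations on input deviation
#'
#' For all pairs of arrays of one sample, regresses the pairwise log2
#' Pearson correlation on a deviation measure of the varied covariate:
#' `"log-ratio"` = |log2 ratio| (default, so doubling input has the same
#' deviation everywhere on the range), `"abs"` = absolute difference, or
#' `"mismatch"` = 0/1 same/different level (for categorical covariates
#' such as the chip lot).
#'
#' @param intensities probes x arrays matrix.
#' @param samples sample sheet rows for those arrays.
#' @param covariate sample-sheet column that varies across the arrays.
#' @param deviation deviation measure (see above).
#' @param annotation optional annotation (measurement probes only).
#' @param pairs `"same-sample"` (default) restricts to array pairs of the
#'   same `sample_id`; `"all"` uses every pair.
#' @return a `regression_result` with an extra `pairs` data.frame
#'   (array_a, array_b, r, deviation).
#' @export
correlation_vs_input_deviation <- function(intensities, samples,
                                           covariate = "rna_input_ng",
                                           deviation = c("log-ratio", "abs",
                                                         "mismatch"),
                                           annotation = NULL,
                                           pairs = c("same-sample", "all")) {
  deviation <- match.arg(deviation)
  pairs <- match.arg(pairs)
  if (!covariate %in% names(samples)) {
    stop_named("covariate '%s' not in sample sheet", covariate)
  }
  idx <- match(colnames(intensities), samples$array_id)
  if (anyNA(idx)) stop_named("sample sheet is missing some arrays")
  samples <- samples[idx, ]
  r <- self_self_correlation(intensities, annotation)
  cmb <- utils::combn(ncol(intensities), 2)
  if (pairs == "same-sample") {
    keep <- samples$sample_id[cmb[1, ]] == samples$sample_id[cmb[2, ]]
    cmb <- cmb[, keep, drop = FALSE]
  }
  if (ncol(cmb) < 3) stop_named("need at least 3 array pairs")
  v <- samples[[covariate]]
  dev <- switch(deviation,
    "log-ratio" = {
      num <- parse_covariate_numeric(v, covariate)
      abs(log2(num[cmb[1, ]] / num[cmb[2, ]]))
    },
    "abs" = {
      num <- parse_covariate_numeric(v, covariate)
      abs(num[cmb[1, ]] - num[cmb[2, ]])
    },
    "mismatch" = as.numeric(v[cmb[1, ]] != v[cmb[2, ]])
  )
  rr <- r[cbind(cmb[1, ], cmb[2, ])]
  if (stats::sd(dev) == 0) {
    stop_named("deviation is constant across pairs (degenerate design)")
  }
  out <- regress(rr, dev)
  out$pairs <- data.frame(array_a = colnames(intensities)[cmb[1, ]],
                          array_b = colnames(intensities)[cmb[2, ]],
                          r = rr, deviation = dev,
                          stringsAsFactors = FALSE)
  out
}

# "1:150" -> 150; numeric columns pass through
parse_covariate_numeric <- function(v, covariate) {
  if (is.numeric(v)) return(v)
  if (all(grepl("^1:[0-9]+$", v))) {
    return(as.numeric(sub("^1:", "", v)))
  }
  num <- suppressWarnings(as.numeric(v))
  if (anyNA(num)) {
    stop_named("covariate '%s' is not numeric; use deviation = 'mismatch'",
               covariate)
  }
  num
}

#' Two-group t-test or one-way ANOVA (equal variances)
#'
#' Two groups give the pooled-variance two-sample t-test; more give a
#' one-way fixed-effects ANOVA. Equal variances are assumed by default;
#' `equal_var = FALSE` switches the two-group case to the Welch test.
#'
#' @param values numeric vector.
#' @param groups group labels (each group needs n >= 2).
#' @param equal_var assume equal variances (default TRUE).
#' @return list of class `group_test_result`: `statistic` (`t` or `F`),
#'   `df` (single value for t, pair for F), `p_value`, and per-group
#'   `means` and `se`.
#' @export
compare_groups <- function(values, groups, equal_var = TRUE) {
  groups <- as.factor(groups)
  counts <- table(groups)
  if (length(counts) < 2) stop_named("need at least 2 groups")
  small <- names(counts)[counts < 2]
  if (length(small) > 0) stop_named("group '%s' has n < 2", small[1])
  means <- tapply(values, groups, mean)
  ses <- tapply(values, groups, function(v) stats::sd(v) / sqrt(length(v)))

  k <- length(counts)
  if (k == 2) {
    g <- levels(groups)
    a <- values[groups == g[1]]; b <- values[groups == g[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- if (mean(a) == mean(b)) {
        list(statistic = 0, parameter = length(values) - 2, p.value = 1)
      } else {
        list(statistic = sign(mean(a) - mean(b)) * Inf,
             parameter = length(values) - 2, p.value = .Machine$double.xmin)
      }
    } else {
      ht <- stats::t.test(a, b, var.equal = equal_var)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    out <- list(statistic = tt$statistic, df = tt$parameter,
                p_value = clamp_p(tt$p.value), means = means, se = ses,
                type = "t")
  } else {
    grand <- mean(values)
    ss_b <- sum(counts * (means - grand)^2)
    ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
    df1 <- k - 1; df2 <- length(values) - k
    if (ss_b == 0) {
      f <- 0; p <- 1
    } else if (ss_w == 0) {
      f <- Inf; p <- .Machine$double.xmin
    } else {
      f <- (ss_b / df1) / (ss_w / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    out <- list(statistic = f, df = c(df1, df2), p_value = clamp_p(p),
                means = means, se = ses, type = "F")
  }
  class(out) <- "group_test_result"
  out
}

#' @export
print.group_test_result <- function(x, ...) {
  if (x$type == "t") {
    cat(sprintf("t = %.3f, df = %s, p = %.3g\n", x$statistic,
                format(x$df), x$p_value))
  } else {
    cat(sprintf("F(%d, %d) = %.3f, p = %.3g\n", x$df[1], x$df[2],
                x$statistic, x$p_value))
  }
  invisible(x)
}
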