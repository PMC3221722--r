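# Principal-component analysis over arrays and quantification of
# between-kit variance on leading components.

#' Principal component analysis of an expression matrix
#'
#' Arrays are observations, probe sets are features. Features are centered
#' across arrays (no unit-variance scaling unless `scale. = TRUE`);
#' components come from the singular value decomposition, with a
#' deterministic sign convention: the largest-|loading| entry of each
#' component is positive.
#'
#' @param expression an [expression_matrix()].
#' @param features optional character vector of probe-set ids to use.
#' @param scale. scale features to unit variance (default FALSE).
#' @return object of class `pca_result`: `scores` (arrays x components),
#'   `loadings` (features x components), `variance_explained`, plus the
#'   feature tag.
#' @export
pca <- function(expression, features = NULL, scale. = FALSE) {
  stopifnot(inherits(expression, "expression_matrix"))
  v <- expression$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss) > 0) {
      stop_named("feature '%s' not present in expression matrix", miss[1])
    }
    v <- v[features, , drop = FALSE]
  }
  if (ncol(v) < 3) stop_named("PCA needs at least 3 arrays")
  x <- t(v)  # arrays x features
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  scores <- pr$x
  loadings <- pr$rotation
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(ncol(scores))],
                 features = if (is.null(features)) expression$features
                            else "subset",
                 center = pr$center, scaled = isTRUE(scale.)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("pca_result: %d arrays, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * ve[1],
              if (length(ve) > 1) 100 * ve[2] else NA))
  invisible(x)
}

#' Between-group variance of a principal component (eta squared)
#'
#' eta^2 = between-group sum of squares / total sum of squares of the
#' component's scores; the operationalization of "variance assigned to"
#' a grouping such as the extraction or labeling kit.
#'
#' @param pca_res a [pca()] result.
#' @param grouping group labels, one per array.
#' @param component component index (default 1).
#' @return list of class `group_variance_result` with `component`,
#'   `eta_squared` and `grouping_name`.
#' @export
between_group_variance <- function(pca_res, grouping, component = 1) {
  stopifnot(inherits(pca_res, "pca_result"))
  s <- pca_res$scores[, component]
  g <- as.factor(grouping)
  if (length(g) != length(s)) stop_named("grouping length mismatch")
  if (nlevels(droplevels(g)) < 2) stop_named("need at least 2 groups")
  grand <- mean(s)
  means <- tapply(s, g, mean)
  counts <- table(g)
  ss_b <- sum(counts * (means - grand)^2)
  ss_t <- sum((s - grand)^2)
  eta2 <- if (ss_t == 0) 0 else ss_b / ss_t
  structure(list(component = component, eta_squared = eta2,
                 grouping_name = deparse(substitute(grouping))),
            class = "group_variance_result")
}

#' Paired within- vs between-sample distances across kit levels
#'
#' For specimens profiled under both levels of a kit covariate, computes
#' in the space of the first two principal components the mean distance
#' between the two arrays of the same specimen under different kits
#' (within-sample/between-kit) and the mean pairwise distance between
#' different specimens under the same kit (between-sample/within-kit),
#' and reports their ratio. A ratio above 1 means a specimen is further
#' from itself across kits than from other specimens within a kit.
#'
#' @param expression an [expression_matrix()] covering all arrays.
#' @param samples sample sheet rows for those arrays.
#' @param kit_field `"extraction_kit"` or `"labeling_kit"`.
#' @return list of class `paired_kit_report` with the two mean distances
#'   and their `ratio`.
#' @export
paired_kit_analysis <- function(expression, samples, kit_field) {
  stopifnot(inherits(expression, "expression_matrix"))
  if (!kit_field %in% names(samples)) {
    stop_named("kit_field '%s' not in sample sheet", kit_field)
  }
  idx <- match(colnames(expression$values), samples$array_id)
  if (anyNA(idx)) stop_named("sample sheet is missing some arrays")
  samples <- samples[idx, ]
  kits <- unique(samples[[kit_field]])
  if (length(kits) != 2) stop_named("kit_field must have exactly 2 levels")
  tab <- table(samples$sample_id, samples[[kit_field]])
  unpaired <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(unpaired) > 0) {
    stop_named("sample '%s' is not present exactly once under each kit level",
               unpaired[1])
  }
  p <- pca(expression)
  sc <- p$scores[, seq_len(min(2, ncol(p$scores))), drop = FALSE]

  sid <- samples$sample_id
  kit <- samples[[kit_field]]
  within_sample <- vapply(unique(sid), function(s) {
    ii <- which(sid == s)
    sqrt(sum((sc[ii[1], ] - sc[ii[2], ])^2))
  }, numeric(1))
  between <- unlist(lapply(kits, function(k) {
    ii <- which(kit == k)
    if (length(ii) < 2) return(numeric(0))
    cmb <- utils::combn(ii, 2)
    sqrt(colSums((t(sc[cmb[1, ], , drop = FALSE]) -
                  t(sc[cmb[2, ], , drop = FALSE]))^2))
  }))
  ws <- mean(within_sample)
  bs <- mean(between)
  structure(list(within_sample_between_kit = ws,
                 between_sample_within_kit = bs,
                 ratio = if (bs == 0) Inf * sign(ws) else ws / bs,
                 kit_field = kit_field),
            class = "paired_kit_report")
}

#' @export
print.paired_kit_report <- function(x, ...) {
  cat(sprintf(
    "paired %s analysis: within-sample/between-kit %.3f, between-sample/within-kit %.3f, ratio %.2f\n",
    x$kit_field, x$within_sample_between_kit, x$between_sample_within_kit,
    x$ratio))
  invisible(x)
}
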