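# Probe-set summarization in the two modes used by the workflow: raw
# average-difference (the classifier's default input) and an RMA-style
# log2/quantile/median-polish pipeline (the correlation/PCA default).

#' Construct an expression matrix object
#'
#' @param values probe sets x arrays numeric matrix.
#' @param mode `"avg_diff_raw"` or `"rma_log2"`.
#' @param features feature-subset tag (e.g. `"human"` or `"all"`).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, mode = c("avg_diff_raw", "rma_log2"),
                              features = "all") {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values))
  structure(list(values = values, mode = mode, features = features),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probe sets x %d arrays (mode = %s, features = %s)\n",
              nrow(x$values), ncol(x$values), x$mode, x$features))
  invisible(x)
}

subset_measurement <- function(intensities, annotation, human_only) {
  keep <- annotation$role == "measurement"
  if (human_only) keep <- keep & annotation$species == "human"
  ann <- annotation[keep, , drop = FALSE]
  if (nrow(ann) == 0) stop_named("no measurement probes left after subsetting")
  list(x = intensities[ann$probe_id, , drop = FALSE], ann = ann)
}

#' Raw average-difference summarization
#'
#' Per probe set and array, the arithmetic mean of its measurement-probe
#' intensities on the linear scale: no background correction and no
#' cross-array normalization. This platform has perfect-match probes only,
#' so "average difference" reduces to the plain probe mean.
#'
#' @param intensities probes x arrays matrix (linear scale).
#' @param annotation validated probe annotation.
#' @param human_only restrict to human probe sets (default TRUE).
#' @return an `expression_matrix` with mode `"avg_diff_raw"`.
#' @export
avg_diff_raw <- function(intensities, annotation, human_only = TRUE) {
  s <- subset_measurement(intensities, annotation, human_only)
  grp <- factor(s$ann$probeset_id, levels = unique(s$ann$probeset_id))
  sums <- rowsum(s$x, grp, reorder = FALSE)
  counts <- as.vector(table(grp)[levels(grp)])
  if (any(counts == 0)) stop_named("empty probe set in annotation")
  vals <- sums / counts
  expression_matrix(as.matrix(vals), "avg_diff_raw",
                    if (human_only) "human" else "all")
}

#' RMA-style summarization (log2, quantile normalization, median polish)
#'
#' Pipeline: log2 transform, probe-level quantile normalization across
#' arrays (ties receive the mean of the reference quantiles they span),
#' then per-probe-set median-polish summarization of the probe x array
#' matrix; the expression index is the fitted overall plus array effect.
#' No background-correction step is applied (see the methods vignette).
#' A single array skips quantile normalization with a warning.
#'
#' @inheritParams avg_diff_raw
#' @return an `expression_matrix` with mode `"rma_log2"`.
#' @export
rma_like <- function(intensities, annotation, human_only = TRUE) {
  s <- subset_measurement(intensities, annotation, human_only)
  l2 <- log2(s$x)
  if (ncol(l2) >= 2) {
    l2 <- limma::normalizeQuantiles(l2, ties = TRUE)
  } else {
    warning("single array: skipping quantile normalization")
  }
  vals <- medpolish_summarize(l2, s$ann$probeset_id)
  expression_matrix(vals, "rma_log2", if (human_only) "human" else "all")
}

# Median-polish each probe set (probe x array matrix); returns the
# probe sets x arrays expression-index matrix (overall + array effect).
medpolish_summarize <- function(l2, probeset_ids, eps = 1e-6, maxiter = 20) {
  sets <- unique(probeset_ids)
  idx <- split(seq_len(nrow(l2)), factor(probeset_ids, levels = sets))
  out <- matrix(NA_real_, length(sets), ncol(l2),
                dimnames = list(sets, colnames(l2)))
  for (i in seq_along(sets)) {
    m <- l2[idx[[i]], , drop = FALSE]
    if (nrow(m) == 1) {
      out[i, ] <- m[1, ]
    } else {
      mp <- stats::medpolish(m, eps = eps, maxiter = maxiter, trace.iter = FALSE)
      out[i, ] <- mp$overall + mp$col
    }
  }
  out
}
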