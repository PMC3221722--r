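# Prognosticator-call robustness under analytical perturbations, and
# survival separation (Kaplan-Meier / log-rank) of predicted groups.

#' Prognosticator-call robustness across analytical conditions
#'
#' Summarizes replicate arrays with the model's summarization mode,
#' predicts each, and reports per-condition concordance with the call on
#' the sample's reference array (default analytical condition: 600 ng,
#' ATP 1:50, reference lot, RA extraction, FH labeling). Every replicate
#' must differ from the reference condition in exactly one covariate.
#'
#' @param model a [train_prognostic()] model.
#' @param intensities probes x arrays matrix containing the reference
#'   array of each sample and the condition replicates.
#' @param samples sample sheet rows for those arrays.
#' @param annotation validated probe annotation.
#' @return object of class `robustness_report`: per-replicate `calls`
#'   data.frame (sample, condition, level, call, reference call,
#'   concordant) and per-condition `concordance`.
#' @export
robustness_calls <- function(model, intensities, samples, annotation) {
  stopifnot(inherits(model, "prognostic_model"))
  idx <- match(colnames(intensities), samples$array_id)
  if (anyNA(idx)) stop_named("sample sheet is missing some arrays")
  samples <- samples[idx, ]
  ref <- reference_condition()
  covars <- names(ref)

  varied <- lapply(seq_len(nrow(samples)), function(i) {
    diffs <- covars[vapply(covars, function(cv) {
      !identical(as.character(samples[[cv]][i]), as.character(ref[[cv]]))
    }, logical(1))]
    diffs
  })
  n_diff <- lengths(varied)
  if (any(n_diff > 1)) {
    bad <- which(n_diff > 1)[1]
    stop_named("array '%s' varies %d covariates vs the reference (%s); one allowed",
               samples$array_id[bad], n_diff[bad],
               paste(varied[[bad]], collapse = ", "))
  }
  is_ref <- n_diff == 0
  missing_ref <- setdiff(samples$sample_id, samples$sample_id[is_ref])
  if (length(missing_ref) > 0) {
    stop_named("sample '%s' has no reference-condition array", missing_ref[1])
  }

  expr <- if (model$mode == "rma_log2") {
    rma_like(intensities, annotation, human_only = TRUE)
  } else {
    avg_diff_raw(intensities, annotation, human_only = TRUE)
  }
  calls <- predict(model, expr)

  ref_call <- stats::setNames(calls[samples$array_id[is_ref]],
                              samples$sample_id[is_ref])
  rep_rows <- which(!is_ref)
  tab <- data.frame(
    array_id = samples$array_id[rep_rows],
    sample_id = samples$sample_id[rep_rows],
    condition = unlist(varied[rep_rows]),
    level = vapply(rep_rows, function(i) {
      as.character(samples[[varied[[i]]]][i])
    }, character(1)),
    call = unname(calls[samples$array_id[rep_rows]]),
    reference_call = unname(ref_call[samples$sample_id[rep_rows]]),
    stringsAsFactors = FALSE
  )
  tab$concordant <- tab$call == tab$reference_call
  concordance <- tapply(tab$concordant, tab$condition, mean)
  structure(list(calls = tab,
                 reference_calls = ref_call,
                 concordance = concordance),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("robustness_report: per-condition call concordance vs reference\n")
  for (cond in names(x$concordance)) {
    cat(sprintf("  %-15s %.3f (%d replicates)\n", cond, x$concordance[[cond]],
                sum(x$calls$condition == cond)))
  }
  invisible(x)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator (via the survival package) with censoring
#' handled by at-risk decrement without a survival drop; at tied times
#' events are processed before censorings.
#'
#' @param time follow-up times in months (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param group group labels.
#' @return data.frame of class `km_curve`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (each group's curve starts at
#'   time 0 with survival 1).
#' @export
km_estimate <- function(time, event, group) {
  if (any(time < 0)) stop_named("negative follow-up time")
  if (length(unique(stats::na.omit(group))) < 1) stop_named("need >= 1 group")
  g <- as.factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time)) else {
    sub("^g=", "", as.character(s$strata))
  }
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    survival = s$surv, stringsAsFactors = FALSE)
  zero <- data.frame(group = levels(g),
                     time = 0, n_risk = as.vector(table(g)),
                     n_event = 0, n_censor = 0, survival = 1,
                     stringsAsFactors = FALSE)
  out <- rbind(zero, out)
  out <- out[order(out$group, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test for two groups
#'
#' Unweighted (Mantel-Haenszel) log-rank statistic: at each distinct event
#' time, observed vs expected events under the hypergeometric model;
#' chi-squared with 1 df.
#'
#' @inheritParams km_estimate
#' @param group labels with exactly 2 levels.
#' @return list of class `logrank_result`: `chi_squared`, `df`, `p_value`.
#' @export
logrank <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) stop_named("log-rank needs exactly 2 groups")
  if (sum(event) < 1) stop_named("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, rho = 0)
  chi <- sd$chisq
  structure(list(chi_squared = chi, df = 1L,
                 p_value = clamp_p(stats::pchisq(chi, 1, lower.tail = FALSE))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi^2 = %.3f (df = %d), p = %.3g\n",
              x$chi_squared, x$df, x$p_value))
  invisible(x)
}
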