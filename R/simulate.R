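#' Generate a synthetic FFPE miRNA-array cohort
#'
#' Simulates probe-level intensities for `n_samples` tumour specimens
#' hybridized under the reference analytical condition (600 ng input,
#' RecoverAll extraction, FlashTag HSR labeling, ATP-mix 1:50, one chip
#' lot), together with probe annotation, a sample sheet with recurrence
#' outcomes and follow-up, and the generating truth.
#'
#' The signal model is lognormal on the log2 scale. Each probe set is
#' expressed (with probability `frac_expressed`) or at background level;
#' per sample, the latent probe-set log2 mean is drawn from the expressed
#' or background distribution, and the `n_signature` planted probe sets are
#' shifted by `+effect_delta` in recurrence cases. Probe intensities add
#' per-probe replicate noise on the log2 scale, then above-background
#' signal is scaled by the RNA-input response and kit factors. Background
#' probes are drawn from the background distribution only. Recurrence
#' cases get exponential event times; recurrence-free cases are censored
#' after at least `min_followup_months` months.
#'
#' @param config a [sim_config()] object.
#' @param n_samples number of specimens (>= 4).
#' @return an object of class `synthetic_cohort`: list with `intensities`
#'   (probes x arrays, linear scale), `annotation`, `samples`, `truth`
#'   (signature ids, class labels, latent log2 means, fixed per-probe kit
#'   offsets) and `config`.
#' @export
generate_cohort <- function(config, n_samples) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 4) {
    stop_named("n_samples must be a single number >= 4")
  }
  n_samples <- as.integer(n_samples)

  ann <- make_annotation(config)
  meas <- ann[ann$role == "measurement", ]
  set_ids <- unique(meas$probeset_id)
  human_sets <- unique(meas$probeset_id[meas$species == "human"])

  # -- cohort-level structure ------------------------------------------------
  set.seed(derive_seed(config$seed, "structure"))
  expressed <- stats::runif(length(set_ids)) < config$frac_expressed
  names(expressed) <- set_ids
  candidates <- intersect(human_sets, set_ids[expressed])
  if (length(candidates) < config$n_signature) {
    candidates <- human_sets  # fall back if almost nothing is expressed
  }
  signature <- sort(sample(candidates, config$n_signature))

  # Fixed per-probe kit offsets, shared across samples (batch structure).
  # Mean-corrected on the linear scale (E[2^offset] = 1) so the kit-level
  # mean signal ratios stay at extraction_hp_scale / labeling_f_compression.
  n_meas <- nrow(meas)
  lognormal_mean_log2 <- function(s) s^2 * log(2) / 2
  extraction_offsets <- stats::rnorm(n_meas, 0, config$extraction_probe_sd) -
    lognormal_mean_log2(config$extraction_probe_sd)
  labeling_offsets <- stats::rnorm(n_meas, 0, config$labeling_probe_sd) -
    lognormal_mean_log2(config$labeling_probe_sd)
  names(extraction_offsets) <- names(labeling_offsets) <- meas$probe_id

  # Fixed probe-set baselines: expressed sets keep their identity across
  # samples; unexpressed sets sit at background level with no biological
  # variation (absent molecules).
  baseline_sd <- sqrt(config$expressed_log2_sd^2 - config$bio_log2_sd^2)
  baseline <- ifelse(expressed,
                     stats::rnorm(length(set_ids), config$expressed_log2_mean,
                                  baseline_sd),
                     stats::rnorm(length(set_ids), config$background_log2_mean,
                                  config$background_log2_sd))
  names(baseline) <- set_ids

  # Per-probe input sensitivities, drawn in their own stream: a probe's
  # log2 signal shifts by sensitivity * log2(input_ng / 600), so pairs of
  # arrays decorrelate in proportion to their |log2 input ratio|.
  set.seed(derive_seed(config$seed, "input-sensitivity"))
  input_offsets <- stats::rnorm(n_meas, 0, config$input_probe_sd)
  names(input_offsets) <- meas$probe_id

  # -- per-sample latent means, classes, outcomes ----------------------------
  set.seed(derive_seed(config$seed, "samples"))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  y <- stats::rbinom(n_samples, 1, config$p_recurrence)
  latent <- matrix(NA_real_, length(set_ids), n_samples,
                   dimnames = list(set_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    mu <- baseline +
      ifelse(expressed, stats::rnorm(length(set_ids), 0, config$bio_log2_sd), 0)
    if (y[j] == 1) mu[signature] <- mu[signature] + config$effect_delta
    latent[, j] <- mu
  }
  time_months <- numeric(n_samples)
  event <- integer(n_samples)
  for (j in seq_len(n_samples)) {
    if (y[j] == 1) {
      time_months[j] <- stats::rexp(1, rate = config$hazard_recurrence)
      event[j] <- 1L
    } else {
      time_months[j] <- config$min_followup_months + stats::runif(1, 0, 36)
      event[j] <- 0L
    }
  }

  # -- render the reference-condition array of every sample ------------------
  ref <- reference_condition()
  arrays <- matrix(NA_real_, nrow(ann), n_samples,
                   dimnames = list(ann$probe_id,
                                   paste0(sample_ids, "_ref")))
  for (j in seq_len(n_samples)) {
    arrays[, j] <- render_array(
      latent[, j], ann, config, ref,
      extraction_offsets, labeling_offsets, input_offsets,
      noise_seed = derive_seed(config$seed, "render", j, "reference")
    )
  }

  samples <- data.frame(
    array_id = colnames(arrays),
    sample_id = sample_ids,
    rna_input_ng = ref$rna_input_ng,
    atp_dilution = ref$atp_dilution,
    lot_id = ref$lot_id,
    extraction_kit = ref$extraction_kit,
    labeling_kit = ref$labeling_kit,
    recurrence = y,
    time_months = time_months,
    event = event,
    stringsAsFactors = FALSE
  )

  structure(list(
    intensities = arrays,
    annotation = ann,
    samples = samples,
    truth = list(signature = signature, classes = stats::setNames(y, sample_ids),
                 latent = latent, expressed = expressed,
                 extraction_offsets = extraction_offsets,
                 labeling_offsets = labeling_offsets,
                 input_offsets = input_offsets),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d probes x %d arrays (%d probe sets, %d background probes)\n",
    nrow(x$intensities), ncol(x$intensities),
    length(unique(x$annotation$probeset_id[x$annotation$role == "measurement"])),
    sum(x$annotation$role == "background")))
  cat(sprintf("  planted signature: %d probe sets, effect_delta = %.2f\n",
              length(x$truth$signature), x$config$effect_delta))
  cat(sprintf("  recurrence cases: %d / %d\n",
              sum(x$truth$classes), length(x$truth$classes)))
  invisible(x)
}

make_annotation <- function(config) {
  n_sets <- config$n_probesets
  n_human <- round(config$frac_human * n_sets)
  set_ids <- sprintf("PS%04d", seq_len(n_sets))
  probe_ids <- paste0(rep(set_ids, each = config$probes_per_set), "_p",
                      rep(seq_len(config$probes_per_set), n_sets))
  meas <- data.frame(
    probe_id = probe_ids,
    probeset_id = rep(set_ids, each = config$probes_per_set),
    species = rep(c(rep("human", n_human), rep("other", n_sets - n_human)),
                  each = config$probes_per_set),
    role = "measurement",
    stringsAsFactors = FALSE
  )
  bg_ids <- sprintf("BG%04d", seq_len(config$n_background_probes))
  bg <- data.frame(probe_id = bg_ids, probeset_id = bg_ids,
                   species = "other", role = "background",
                   stringsAsFactors = FALSE)
  validate_annotation(rbind(meas, bg))
}

# Render one array: latent probe-set log2 means -> linear probe intensities
# under a given analytical condition. Kit offsets are the cohort's fixed
# per-probe batch terms; all stochastic terms come from noise_seed.
render_array <- function(latent, annotation, config, condition,
                         extraction_offsets, labeling_offsets,
                         input_offsets, noise_seed) {
  meas <- annotation$role == "measurement"
  probe_set <- annotation$probeset_id[meas]
  set.seed(noise_seed)

  ref_ng <- reference_condition()$rna_input_ng
  noise_sd <- config$noise_log2_sd_base +
    config$noise_input_coeff / sqrt(condition$rna_input_ng)
  l2 <- latent[probe_set] + stats::rnorm(sum(meas), 0, noise_sd) +
    input_offsets[annotation$probe_id[meas]] *
      log2(condition$rna_input_ng / ref_ng)
  if (condition$extraction_kit == "HP") {
    l2 <- l2 + extraction_offsets[annotation$probe_id[meas]]
  }
  if (condition$labeling_kit == "F") {
    l2 <- l2 + labeling_offsets[annotation$probe_id[meas]]
  }
  x <- 2^l2

  bg_lin <- 2^config$background_log2_mean
  gain <- max(0.05, 1 + config$input_response_slope *
                (condition$rna_input_ng - ref_ng))
  if (condition$extraction_kit == "HP") gain <- gain * config$extraction_hp_scale
  x <- bg_lin + (x - bg_lin) * gain
  if (condition$labeling_kit == "F") {
    x <- bg_lin + config$labeling_f_compression * (x - bg_lin)
  }

  # background probes: background distribution only, no input/kit response
  n_bg <- sum(!meas)
  b <- 2^(stats::rnorm(n_bg, config$background_log2_mean,
                       config$background_log2_sd) +
            stats::rnorm(n_bg, 0, config$noise_log2_sd_base))

  out <- numeric(nrow(annotation))
  out[meas] <- x
  out[!meas] <- b
  pmax(out, 2^-4)
}

#' Re-render one cohort sample under perturbed analytical conditions
#'
#' Renders the *same* latent sample (identical latent probe-set means) as
#' one new array per condition spec. Varying `rna_input_ng` changes the
#' above-background signal gain and the replicate noise level;
#' `atp_dilution` and `lot_id` add replicate noise only (no systematic
#' term); `extraction_kit = "HP"` scales above-background signal by
#' `extraction_hp_scale` and adds the cohort's fixed per-probe extraction
#' offsets; `labeling_kit = "F"` compresses above-background signal by
#' `labeling_f_compression` and adds the fixed per-probe labeling offsets.
#'
#' @param cohort a [generate_cohort()] result.
#' @param sample_id one of the cohort's sample ids.
#' @param conditions a list of single-covariate condition specs, each a
#'   length-1 named list/vector, e.g.
#'   `list(c(rna_input_ng = 80), c(labeling_kit = "F"))`.
#' @param seed integer replicate seed (default: the cohort seed); the same
#'   seed and condition spec reproduce the replicate bit-identically.
#' @return list with `intensities` (probes x replicates) and `samples`
#'   (sample-sheet rows for the replicate arrays).
#' @export
generate_condition_replicates <- function(cohort, sample_id, conditions,
                                          seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!sample_id %in% cohort$samples$sample_id) {
    stop_named("unknown sample_id '%s'", sample_id)
  }
  seed <- seed %||% cohort$config$seed
  allowed <- list(
    rna_input_ng = function(v) is.numeric(v) && v > 0,
    atp_dilution = function(v) grepl("^1:[0-9]+$", v),
    lot_id = function(v) is.character(v) && nzchar(v),
    extraction_kit = function(v) v %in% c("HP", "RA"),
    labeling_kit = function(v) v %in% c("F", "FH")
  )
  ref <- reference_condition()
  cfg <- cohort$config
  ann <- cohort$annotation
  latent <- cohort$truth$latent[, sample_id]

  n_rep <- length(conditions)
  ints <- matrix(NA_real_, nrow(ann), n_rep)
  rownames(ints) <- ann$probe_id
  rows <- vector("list", n_rep)
  clin <- cohort$samples[match(sample_id, cohort$samples$sample_id), ]
  for (i in seq_len(n_rep)) {
    spec <- conditions[[i]]
    if (length(spec) != 1 || is.null(names(spec)) || !nzchar(names(spec))) {
      stop_named("condition spec %d must name exactly one covariate", i)
    }
    covar <- names(spec)
    level <- spec[[1]]
    if (!covar %in% names(allowed)) {
      stop_named("unknown condition covariate '%s' (allowed: %s)", covar,
                 paste(names(allowed), collapse = ", "))
    }
    if (covar == "rna_input_ng") level <- as.numeric(level)
    if (!allowed[[covar]](level)) {
      stop_named("invalid level '%s' for covariate '%s'", level, covar)
    }
    cond <- ref
    cond[[covar]] <- level
    noise_seed <- derive_seed(seed, "replicate", sample_id, covar,
                              as.character(level), i)
    ints[, i] <- render_array(latent, ann, cfg, cond,
                              cohort$truth$extraction_offsets,
                              cohort$truth$labeling_offsets,
                              cohort$truth$input_offsets, noise_seed)
    rows[[i]] <- data.frame(
      array_id = paste(sample_id, covar, gsub("[^A-Za-z0-9.]", "", level), i,
                       sep = "_"),
      sample_id = sample_id,
      rna_input_ng = cond$rna_input_ng,
      atp_dilution = cond$atp_dilution,
      lot_id = cond$lot_id,
      extraction_kit = cond$extraction_kit,
      labeling_kit = cond$labeling_kit,
      recurrence = clin$recurrence,
      time_months = clin$time_months,
      event = clin$event,
      stringsAsFactors = FALSE
    )
  }
  samples <- do.call(rbind, rows)
  colnames(ints) <- samples$array_id
  list(intensities = ints, samples = samples)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `intensities.tsv`, `annotation.tsv`, `samples.tsv` and
#' `truth.json` into a directory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_table(cohort$intensities, file.path(dir, "intensities.tsv"))
  write_probe_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  truth <- list(schema_version = 1L,
                signature = cohort$truth$signature,
                classes = as.list(cohort$truth$classes))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
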