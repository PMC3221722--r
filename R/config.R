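#' Simulation configuration for synthetic FFPE miRNA-array cohorts
#'
#' Builds the parameter set that drives [generate_cohort()] and
#' [generate_condition_replicates()]. Defaults are calibrated so that a
#' default-condition array (600 ng RNA input, RecoverAll extraction,
#' FlashTag HSR labeling, ATP-mix 1:50, reference chip lot) reproduces the
#' magnitude of published QC summaries for this platform: mean probe signal
#' near 349, mean background near 89, and roughly 2.4k detected probe sets
#' at detection alpha 0.06.
#'
#' @param n_probesets total number of measurement probe sets on the array.
#' @param probes_per_set probes per measurement probe set.
#' @param n_background_probes number of anti-genomic background probes.
#' @param frac_human fraction of probe sets targeting human small RNAs.
#' @param frac_expressed fraction of probe sets expressed above background.
#' @param expressed_log2_mean,expressed_log2_sd log2-intensity location and
#'   marginal per-sample spread of expressed probe-set latent means.
#' @param bio_log2_sd between-sample biological component of
#'   `expressed_log2_sd`: each expressed probe set has a fixed baseline
#'   (spread `sqrt(expressed_log2_sd^2 - bio_log2_sd^2)` across sets) and
#'   per-sample deviations with sd `bio_log2_sd` around it, so specimens
#'   share probe-set identity the way real cohorts do.
#' @param background_log2_mean,background_log2_sd log2-intensity location
#'   and spread of the background (and unexpressed) distribution.
#' @param input_response_slope linear gain per ng of RNA input on
#'   above-background signal, relative to the 600 ng reference. The default
#'   is calibrated so that the induced regression of mean signal intensity
#'   on input amount has slope near 0.03 intensity units per ng at the
#'   default intensity scale (`(349 - 89.3) * 0.00012 ~ 0.03`).
#' @param noise_log2_sd_base baseline per-probe replicate noise (log2 sd).
#' @param noise_input_coeff extra replicate noise, added as
#'   `noise_input_coeff / sqrt(input_ng)` (low input hybridizations are
#'   noisier).
#' @param input_probe_sd sd of fixed per-probe input sensitivities: each
#'   probe's log2 signal shifts by `sensitivity * log2(input_ng / 600)`
#'   (labeling efficiency responds to input in a sequence-specific way).
#'   This is what makes self-self correlations decay monotonically in the
#'   |log2 input ratio| of a pair.
#' @param extraction_hp_scale multiplicative above-background signal ratio
#'   of the HighPure (HP) extraction kit relative to RecoverAll (RA).
#' @param extraction_probe_sd log2 sd of fixed per-probe HP-kit offsets
#'   (drawn once per cohort; the batch component that separates kits in
#'   principal-component space).
#' @param labeling_f_compression fraction in (0, 1] of above-background
#'   signal retained by the old FlashTag (F) labeling kit relative to the
#'   HSR (FH) kit.
#' @param labeling_probe_sd log2 sd of fixed per-probe F-kit offsets.
#' @param n_signature number of probe sets carrying the planted prognostic
#'   effect.
#' @param effect_delta log2 shift added to signature probe sets in samples
#'   with recurrence (class 1).
#' @param p_recurrence probability that a sample is a recurrence case.
#' @param hazard_recurrence exponential hazard (events/month) for
#'   recurrence event times.
#' @param min_followup_months minimum follow-up for recurrence-free
#'   (censored) cases; censoring times are uniform on
#'   `min_followup_months + [0, 36]`.
#' @param seed integer seed; identical seed and config give bit-identical
#'   cohorts.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_probesets = 2500,
                       probes_per_set = 4,
                       n_background_probes = 200,
                       frac_human = 0.8,
                       frac_expressed = 0.95,
                       expressed_log2_mean = 8.08,
                       expressed_log2_sd = 1.1,
                       bio_log2_sd = 1.0,
                       background_log2_mean = 6.39,
                       background_log2_sd = 0.5,
                       input_response_slope = 0.00012,
                       noise_log2_sd_base = 0.08,
                       noise_input_coeff = 1.5,
                       input_probe_sd = 0.1,
                       extraction_hp_scale = 0.72,
                       extraction_probe_sd = 0.5,
                       labeling_f_compression = 0.24,
                       labeling_probe_sd = 2.0,
                       n_signature = 12,
                       effect_delta = 1.5,
                       p_recurrence = 0.5,
                       hazard_recurrence = 1 / 18,
                       min_followup_months = 32,
                       seed = 1L) {
  cfg <- list(
    n_probesets = n_probesets, probes_per_set = probes_per_set,
    n_background_probes = n_background_probes, frac_human = frac_human,
    frac_expressed = frac_expressed,
    expressed_log2_mean = expressed_log2_mean,
    expressed_log2_sd = expressed_log2_sd,
    bio_log2_sd = bio_log2_sd,
    background_log2_mean = background_log2_mean,
    background_log2_sd = background_log2_sd,
    input_response_slope = input_response_slope,
    noise_log2_sd_base = noise_log2_sd_base,
    noise_input_coeff = noise_input_coeff,
    input_probe_sd = input_probe_sd,
    extraction_hp_scale = extraction_hp_scale,
    extraction_probe_sd = extraction_probe_sd,
    labeling_f_compression = labeling_f_compression,
    labeling_probe_sd = labeling_probe_sd,
    n_signature = n_signature, effect_delta = effect_delta,
    p_recurrence = p_recurrence, hazard_recurrence = hazard_recurrence,
    min_followup_months = min_followup_months, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' @param cfg a named list with exactly the [sim_config()] fields.
#' @return the validated config, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  fields <- names(formals(sim_config))
  extra <- setdiff(names(cfg), fields)
  if (length(extra) > 0) {
    stop_named("unknown config field(s): %s", paste(extra, collapse = ", "))
  }
  missing <- setdiff(fields, names(cfg))
  if (length(missing) > 0) {
    stop_named("missing config field(s): %s", paste(missing, collapse = ", "))
  }
  chk <- function(cond, what) if (!isTRUE(cond)) {
    stop_named("invalid config: %s", what)
  }
  for (f in c("n_probesets", "probes_per_set", "n_background_probes",
              "n_signature")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 1 &&
          cfg[[f]] == round(cfg[[f]]), paste(f, "must be a positive count"))
  }
  for (f in c("frac_human", "frac_expressed", "p_recurrence")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste(f, "must be in [0, 1]"))
  }
  for (f in c("expressed_log2_sd", "background_log2_sd", "extraction_probe_sd",
              "labeling_probe_sd", "noise_log2_sd_base",
              "extraction_hp_scale", "hazard_recurrence")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] > 0, paste(f, "must be > 0"))
  }
  chk(cfg$labeling_f_compression > 0 && cfg$labeling_f_compression <= 1,
      "labeling_f_compression must be in (0, 1]")
  chk(is.numeric(cfg$bio_log2_sd) && cfg$bio_log2_sd > 0 &&
        cfg$bio_log2_sd <= cfg$expressed_log2_sd,
      "bio_log2_sd must be in (0, expressed_log2_sd]")
  chk(cfg$n_signature <= cfg$n_probesets * cfg$frac_human,
      "n_signature must not exceed the number of human probe sets")
  chk(cfg$noise_input_coeff >= 0, "noise_input_coeff must be >= 0")
  chk(is.numeric(cfg$input_probe_sd) && cfg$input_probe_sd >= 0,
      "input_probe_sd must be >= 0")
  chk(cfg$min_followup_months >= 0, "min_followup_months must be >= 0")
  chk(cfg$effect_delta >= 0, "effect_delta must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from a JSON file
#'
#' The JSON object must use exactly the [sim_config()] field names; any
#' field omitted keeps its default, unknown keys are rejected.
#'
#' @param path path to a JSON file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), names(formals(sim_config)))
  if (length(extra) > 0) {
    stop_named("unknown config field(s) in %s: %s", path,
               paste(extra, collapse = ", "))
  }
  do.call(sim_config, raw)
}

# Reference (default) analytical condition: Table-2-style hybridization.
reference_condition <- function() {
  list(rna_input_ng = 600, atp_dilution = "1:50", lot_id = "L1",
       extraction_kit = "RA", labeling_kit = "FH")
}
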