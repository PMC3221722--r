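# Shared fixtures: a desk-scale generator configuration and tiny hand-built
# datasets used across test files.

small_config <- function(...) {
  sim_config(n_probesets = 60, probes_per_set = 3, n_background_probes = 40,
             n_signature = 5, ...)
}

# tiny annotation: n_sets measurement probe sets + n_bg background probes
tiny_annotation <- function(n_sets = 4, probes_per_set = 2, n_bg = 3,
                            n_human = n_sets) {
  set_ids <- sprintf("PS%02d", seq_len(n_sets))
  meas <- data.frame(
    probe_id = paste0(rep(set_ids, each = probes_per_set), "_p",
                      rep(seq_len(probes_per_set), n_sets)),
    probeset_id = rep(set_ids, each = probes_per_set),
    species = rep(c(rep("human", n_human), rep("other", n_sets - n_human)),
                  each = probes_per_set),
    role = "measurement", stringsAsFactors = FALSE
  )
  bg <- data.frame(probe_id = sprintf("BG%02d", seq_len(n_bg)),
                   probeset_id = sprintf("BG%02d", seq_len(n_bg)),
                   species = "other", role = "background",
                   stringsAsFactors = FALSE)
  rbind(meas, bg)
}

tiny_sheet <- function(n = 3) {
  data.frame(
    array_id = sprintf("A%02d", seq_len(n)),
    sample_id = sprintf("S%02d", seq_len(n)),
    rna_input_ng = 600, atp_dilution = "1:50", lot_id = "L1",
    extraction_kit = "RA", labeling_kit = "FH",
    recurrence = rep_len(c(0L, 1L), n),
    time_months = seq_len(n) * 10, event = rep_len(c(0L, 1L), n),
    stringsAsFactors = FALSE
  )
}

# features x arrays matrix with named dims
rand_expr <- function(p, n, prefix = "F") {
  m <- matrix(stats::rnorm(p * n), p, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                              sprintf("A%03d", seq_len(n))))
  m
}

# assemble a paired two-kit dataset from a cohort (reference + one
# perturbed array per sample)
paired_kit_data <- function(cohort, covar, level) {
  ints <- cohort$intensities
  sheets <- cohort$samples
  for (s in cohort$samples$sample_id) {
    spec <- list(stats::setNames(list(level), covar))
    r <- generate_condition_replicates(cohort, s, spec)
    ints <- cbind(ints, r$intensities)
    sheets <- rbind(sheets, r$samples)
  }
  list(intensities = ints, samples = sheets)
}
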