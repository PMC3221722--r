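# Readers/writers for the probe-level interchange formats: tab-delimited,
# UTF-8, '.' decimal. All downstream modules consume the validated objects
# returned here, never files.

KIT_EXTRACTION <- c("HP", "RA")
KIT_LABELING <- c("F", "FH")

SAMPLE_SHEET_COLS <- c("array_id", "sample_id", "rna_input_ng",
                       "atp_dilution", "lot_id", "extraction_kit",
                       "labeling_kit", "recurrence", "time_months", "event")

#' Validate a probe annotation table
#'
#' @param ann data.frame with columns `probe_id`, `probeset_id`, `species`
#'   (`human`/`other`) and `role` (`measurement`/`background`).
#' @return the validated annotation (invisible errors otherwise).
#' @export
validate_annotation <- function(ann) {
  need <- c("probe_id", "probeset_id", "species", "role")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop_named("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup) > 0) {
    stop_named("duplicate probe_id in annotation: %s", dup[1])
  }
  bad <- setdiff(unique(ann$species), c("human", "other"))
  if (length(bad) > 0) {
    stop_named("unknown species level '%s' (allowed: human, other)", bad[1])
  }
  bad <- setdiff(unique(ann$role), c("measurement", "background"))
  if (length(bad) > 0) {
    stop_named("unknown role level '%s' (allowed: measurement, background)", bad[1])
  }
  bg <- ann[ann$role == "background", ]
  off <- bg$probe_id[bg$probe_id != bg$probeset_id]
  if (length(off) > 0) {
    stop_named("background probe '%s' must have probeset_id equal to its probe_id",
               off[1])
  }
  ann
}

#' Read a probe annotation TSV
#' @param path TSV with columns probe_id, probeset_id, species, role.
#' @return validated annotation data.frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_annotation(ann)
}

#' Write a probe annotation TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-level intensity table
#'
#' The TSV must have a `probe_id` first column and one column per array.
#' Every annotation probe must be present exactly once and every cell must
#' be a finite, strictly positive number; rows are reordered to annotation
#' order.
#'
#' @param path TSV path.
#' @param annotation validated probe annotation.
#' @return numeric matrix (probes x arrays) with probe_id rownames.
#' @export
read_intensity_table <- function(path, annotation) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "probe_id") {
    stop_named("intensity table must have 'probe_id' as its first column")
  }
  ids <- tab$probe_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop_named("duplicate probe '%s' in intensity table", dup[1])
  extra <- setdiff(ids, annotation$probe_id)
  if (length(extra) > 0) {
    stop_named("probe '%s' in intensity table is absent from the annotation",
               extra[1])
  }
  missing <- setdiff(annotation$probe_id, ids)
  if (length(missing) > 0) {
    stop_named("annotation probe '%s' is missing from the intensity table",
               missing[1])
  }
  arr_ids <- names(tab)[-1]
  dup <- arr_ids[duplicated(arr_ids)]
  if (length(dup) > 0) stop_named("duplicate array id '%s'", dup[1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop_named("non-numeric intensities in column '%s'", arr_ids[bad])
  }
  rownames(m) <- ids
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_named("non-positive intensity for probe '%s' in array '%s'",
               ids[bad[1, 1]], arr_ids[bad[1, 2]])
  }
  m[annotation$probe_id, , drop = FALSE]
}

#' Write a probe-level intensity table
#' @param intensities probes x arrays matrix with probe_id rownames.
#' @param path output path.
#' @export
write_intensity_table <- function(intensities, path) {
  # %.17g so that write -> read is an exact identity on doubles
  chr <- matrix(sprintf("%.17g", intensities), nrow(intensities),
                dimnames = dimnames(intensities))
  df <- data.frame(probe_id = rownames(intensities), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Expects exactly the lower-case columns `array_id`, `sample_id`,
#' `rna_input_ng`, `atp_dilution`, `lot_id`, `extraction_kit`,
#' `labeling_kit`, `recurrence`, `time_months`, `event`. Empty cells and
#' the token `NA` are parsed as missing; clinical fields may be missing
#' (technical-only studies), but `event = 1` requires `time_months`.
#'
#' @param path TSV path.
#' @return a validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  validate_sample_sheet(tab)
}

#' Validate a sample sheet
#' @param tab data.frame with the sample-sheet columns (character or typed).
#' @return typed, validated data.frame.
#' @export
validate_sample_sheet <- function(tab) {
  miss <- setdiff(SAMPLE_SHEET_COLS, names(tab))
  if (length(miss) > 0) {
    stop_named("sample sheet is missing column(s): %s",
               paste(miss, collapse = ", "))
  }
  tab <- tab[, SAMPLE_SHEET_COLS]
  dup <- tab$array_id[duplicated(tab$array_id)]
  if (length(dup) > 0) stop_named("duplicate array_id '%s'", dup[1])

  tab$rna_input_ng <- as.numeric(tab$rna_input_ng)
  if (anyNA(tab$rna_input_ng) || any(tab$rna_input_ng <= 0)) {
    stop_named("rna_input_ng must be positive for every array")
  }
  bad <- which(!grepl("^1:[0-9]+$", tab$atp_dilution))
  if (length(bad) > 0) {
    stop_named("array '%s': atp_dilution '%s' is not a ratio string like '1:50'",
               tab$array_id[bad[1]], tab$atp_dilution[bad[1]])
  }
  check_enum <- function(col, levels) {
    v <- as.character(tab[[col]])
    bad <- which(!v %in% levels)
    if (length(bad) > 0) {
      stop_named("array '%s': %s '%s' not in allowed levels {%s}",
                 tab$array_id[bad[1]], col, v[bad[1]],
                 paste(levels, collapse = ", "))
    }
    v
  }
  tab$extraction_kit <- check_enum("extraction_kit", KIT_EXTRACTION)
  tab$labeling_kit <- check_enum("labeling_kit", KIT_LABELING)
  for (col in c("recurrence", "event")) {
    v <- as.character(tab[[col]])
    bad <- which(!is.na(v) & !v %in% c("0", "1"))
    if (length(bad) > 0) {
      stop_named("array '%s': %s must be 0, 1 or NA", tab$array_id[bad[1]], col)
    }
    tab[[col]] <- as.integer(v)
  }
  tab$time_months <- as.numeric(as.character(tab$time_months))
  if (any(!is.na(tab$time_months) & tab$time_months < 0)) {
    stop_named("time_months must be >= 0")
  }
  bad <- which(!is.na(tab$event) & tab$event == 1 & is.na(tab$time_months))
  if (length(bad) > 0) {
    stop_named("array '%s': event = 1 requires time_months", tab$array_id[bad[1]])
  }
  tab
}

#' Write a sample sheet TSV
#' @param samples sample-sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
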