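required_cohort_cols <- function() {
  c(
    "patient_id", segment_names(), "nihss", "aspects", "mrs0", "mrs90"
  )
}

optional_cohort_cols <- function() {
  c(
    "treatment",
    "cbs_rater1", "cbs_rater2", "mcbs_rater1", "mcbs_rater2",
    "cbs", "mcbs"
  )
}

# Per-row validation reasons; NA-free rows with legal codes return "".
cohort_row_reasons <- function(df) {
  n <- nrow(df)
  reasons <- rep("", n)
  flag_reason <- function(bad, msg) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(
      reasons[bad] == "", msg, paste0(reasons[bad], "; ", msg)
    )
  }
  for (seg in segment_names()) {
    v <- df[[seg]]
    flag_reason(
      is.na(v) | !(v %in% c(0, 1)),
      paste0("illegal value in ", seg, " (expected 0/1)")
    )
  }
  in_range <- function(v, lo, hi) {
    !is.na(v) & v >= lo & v <= hi & v == round(v)
  }
  flag_reason(!in_range(df$nihss, 0, 42), "nihss outside 0..42")
  flag_reason(!in_range(df$aspects, 0, 10), "aspects outside 0..10")
  flag_reason(!in_range(df$mrs0, 0, 6), "mrs0 outside 0..6")
  flag_reason(is.na(df$mrs90), "missing 90-day outcome (mrs90)")
  flag_reason(
    !is.na(df$mrs90) & !in_range(df$mrs90, 0, 6), "mrs90 outside 0..6"
  )
  if ("treatment" %in% names(df)) {
    tr <- df$treatment
    flag_reason(
      !is.na(tr) & tr != "" & !tr %in% c("APT", "TPA", "EVT"),
      "treatment not one of APT/TPA/EVT"
    )
  }
  reasons
}

#' Read and validate a cohort CSV
#'
#' Reads the per-patient cohort schema: `patient_id`, the seven 0/1 segment
#' flag columns, `nihss`, `aspects`, `mrs0`, `mrs90`, plus optional
#' `treatment` (APT/TPA/EVT) and rater score columns. Header order is
#' irrelevant; extra columns are kept.
#'
#' In strict mode any invalid row aborts the read. In lenient mode (the
#' default) invalid rows — illegal codes, out-of-range scales, or a missing
#' 90-day outcome — are quarantined with a per-row reason and the valid
#' remainder is returned, mirroring complete-case flow accounting: every
#' excluded row appears exactly once in the quarantine report.
#'
#' @param path CSV file path.
#' @param strict Fail on any invalid row instead of quarantining.
#' @return A `cohort_table` tibble of valid rows, with attributes
#'   `quarantine` (tibble of `patient_id`, `reason`) and `provenance`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort_table(df, strict = strict, provenance = path)
}

#' Validate an in-memory cohort table
#'
#' Same validation as [read_cohort()] for a data frame already in memory
#' (e.g. a simulated cohort).
#'
#' @param df Data frame in the cohort schema.
#' @param strict Fail on any invalid row.
#' @param provenance Free-text origin recorded on the result.
#' @return A `cohort_table` tibble; see [read_cohort()].
#' @export
as_cohort_table <- function(df, strict = FALSE, provenance = "in-memory") {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(required_cohort_cols(), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id values: ",
      paste(unique(df$patient_id[duplicated(df$patient_id)]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  reasons <- cohort_row_reasons(df)
  bad <- reasons != ""
  if (strict && any(bad)) {
    stop(
      "invalid cohort rows in strict mode:\n",
      paste0(
        "  ", df$patient_id[bad], ": ", reasons[bad],
        collapse = "\n"
      ),
      call. = FALSE
    )
  }
  out <- df[!bad, , drop = FALSE]
  for (seg in segment_names()) out[[seg]] <- as.integer(out[[seg]])
  attr(out, "quarantine") <- tibble::tibble(
    patient_id = df$patient_id[bad], reason = reasons[bad]
  )
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("cohort_table", class(out)))
  out
}

#' Write a cohort CSV
#'
#' Serializes the cohort schema columns (plus any scored or rater columns
#' present) as comma-separated UTF-8 with booleans written as 0/1, so that
#' a read/write round trip is field-identical after canonicalization.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- tibble::as_tibble(cohort)
  keep <- intersect(
    c(required_cohort_cols(), optional_cohort_cols()), names(cohort)
  )
  out <- cohort[keep]
  for (seg in segment_names()) out[[seg]] <- as.integer(out[[seg]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
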