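#' Scored arterial segments
#'
#' The seven anterior-circulation segments carrying a thrombus flag for each
#' patient: infraclinoid and supraclinoid internal carotid artery (ICA),
#' proximal and distal halves of the MCA trunk (M1), the anterior cerebral
#' artery (ACA), and the superior and inferior M2 branches. Flags are
#' unilateral: one affected territory per patient.
#'
#' @return Character vector of the seven segment flag names, in canonical
#'   order.
#' @export
#' @examples
#' segment_names()
segment_names <- function() {
  c(
    "ica_infraclinoid", "ica_supraclinoid",
    "m1_proximal", "m1_distal",
    "aca", "m2_superior", "m2_inferior"
  )
}

#' Construct a single-patient segment status
#'
#' A segment status is a named logical vector over [segment_names()]. Every
#' flag must be `TRUE` or `FALSE`; a missing flag makes the patient
#' unscorable, so `NA` is rejected. Partially and completely occlusive
#' thrombi both count as presence.
#'
#' @param ... Named logical flags; any segment not mentioned defaults to
#'   `FALSE`.
#' @return Named logical vector of length 7.
#' @export
#' @examples
#' segment_status(ica_supraclinoid = TRUE, m1_proximal = TRUE)
segment_status <- function(...) {
  given <- list(...)
  status <- stats::setNames(rep(FALSE, 7L), segment_names())
  if (length(given)) {
    bad <- setdiff(names(given), segment_names())
    if (length(bad) || is.null(names(given)) || any(names(given) == "")) {
      stop("unknown segment flag(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    for (nm in names(given)) status[[nm]] <- given[[nm]]
  }
  validate_status(status)
  status
}

validate_status <- function(status) {
  if (!is.logical(status) || !all(segment_names() %in% names(status))) {
    stop("segment status must be a named logical vector over segment_names()",
      call. = FALSE
    )
  }
  if (anyNA(status[segment_names()])) {
    stop("segment status contains missing flags; patient is unscorable",
      call. = FALSE
    )
  }
  invisible(status)
}

#' Define a segment-weighted deduction scheme
#'
#' A scoring scheme starts every patient at `max_score` and subtracts a fixed
#' integer deduction for each item whose trigger fires. An item's trigger
#' fires when thrombus is present in *any* of its listed segments, which is
#' how the modified scheme collapses the two ICA segments into one item.
#'
#' Built-in schemes keep `max_score = 10` and deductions summing to 10, so a
#' thrombus-free patient scores 10 and a fully occluded one scores 0.
#' User-defined integer variants (e.g. for weight-sweep experiments) may use
#' any positive deductions, but every segment flag must participate in at
#' least one item.
#'
#' @param name Scheme identifier.
#' @param items A data frame with columns `item` (label), `segments` (list
#'   column of segment-name character vectors) and `deduction` (positive
#'   integer).
#' @param max_score Integer ceiling of the score (default 10).
#' @return An object of class `scoring_scheme`.
#' @seealso [builtin_scheme()] for the two published schemes.
#' @export
scoring_scheme <- function(name, items, max_score = 10L) {
  items <- tibble::as_tibble(items)
  stopifnot(
    all(c("item", "segments", "deduction") %in% names(items)),
    is.list(items$segments)
  )
  max_score <- as.integer(max_score)
  ded <- items$deduction
  if (any(is.na(ded)) || any(ded <= 0) || any(ded != as.integer(ded))) {
    stop("deductions must be positive integers", call. = FALSE)
  }
  items$deduction <- as.integer(ded)
  segs <- unlist(items$segments)
  if (!all(segs %in% segment_names())) {
    stop("unknown segment(s) in scheme items: ",
      paste(setdiff(segs, segment_names()), collapse = ", "),
      call. = FALSE
    )
  }
  uncovered <- setdiff(segment_names(), segs)
  if (length(uncovered)) {
    stop("segments not covered by any item: ",
      paste(uncovered, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(name = name, items = items, max_score = max_score),
    class = "scoring_scheme"
  )
}

#' Built-in clot burden schemes
#'
#' `"cbs"` is the original 10-point Clot Burden Score: 2 points deducted for
#' thrombus in each of the supraclinoid ICA, the proximal half of the MCA
#' trunk and the distal half of the MCA trunk; 1 point for the infraclinoid
#' ICA, the ACA and each affected M2 branch.
#'
#' `"mcbs"` is the ICA-weighted modification: a single intracranial-ICA item
#' deducting 3 points when thrombus is present in either ICA segment, with
#' the M1, ACA and M2 deductions unchanged, preserving the 0-10 range.
#'
#' @param name `"cbs"` or `"mcbs"` (case-insensitive).
#' @return A [scoring_scheme()].
#' @export
#' @examples
#' builtin_scheme("cbs")
#' builtin_scheme("mcbs")$items
builtin_scheme <- function(name) {
  key <- tolower(trimws(name))
  if (identical(key, "cbs")) {
    scoring_scheme("cbs", tibble::tibble(
      item = c(
        "supraclinoid ICA", "infraclinoid ICA", "proximal M1",
        "distal M1", "ACA", "M2 superior", "M2 inferior"
      ),
      segments = list(
        "ica_supraclinoid", "ica_infraclinoid", "m1_proximal",
        "m1_distal", "aca", "m2_superior", "m2_inferior"
      ),
      deduction = c(2L, 1L, 2L, 2L, 1L, 1L, 1L)
    ))
  } else if (identical(key, "mcbs")) {
    scoring_scheme("mcbs", tibble::tibble(
      item = c(
        "intracranial ICA", "proximal M1", "distal M1",
        "ACA", "M2 superior", "M2 inferior"
      ),
      segments = list(
        c("ica_infraclinoid", "ica_supraclinoid"),
        "m1_proximal", "m1_distal", "aca", "m2_superior", "m2_inferior"
      ),
      deduction = c(3L, 2L, 2L, 1L, 1L, 1L)
    ))
  } else {
    stop("unsupported scoring scheme: '", name,
      "' (supported: cbs, mcbs)",
      call. = FALSE
    )
  }
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "scoring_scheme")) {
    return(scheme)
  }
  if (is.character(scheme) && length(scheme) == 1L) {
    return(builtin_scheme(scheme))
  }
  stop("`scheme` must be a scoring_scheme or a built-in scheme name",
    call. = FALSE
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(
    "<scoring_scheme> ", x$name, " (max ", x$max_score, ", ",
    nrow(x$items), " items)\n",
    sep = ""
  )
  for (i in seq_len(nrow(x$items))) {
    cat(
      sprintf(
        "  -%d  %-18s [%s]\n", x$items$deduction[i], x$items$item[i],
        paste(x$items$segments[[i]], collapse = " | ")
      )
    )
  }
  invisible(x)
}

#' Score one patient under a deduction scheme
#'
#' Deterministically subtracts the deduction of every scheme item whose
#' trigger fires (thrombus in any of the item's segments) from the scheme
#' maximum. A score of `max_score` means no thrombus in any scored segment;
#' 0 reflects complete multisegment occlusion.
#'
#' @param status Named logical vector from [segment_status()] (a one-row
#'   data frame with the segment columns is also accepted).
#' @param scheme A [scoring_scheme()] or a built-in name (`"cbs"`,
#'   `"mcbs"`).
#' @param patient_id Optional identifier carried into the result.
#' @return A `score_result`: list with `patient_id`, `scheme`, `score`,
#'   `max_score` and a `triggered` tibble of (item, deduction).
#' @export
#' @examples
#' compute_score(segment_status(), "cbs")$score # 10
#' compute_score(segment_status(ica_supraclinoid = TRUE, m1_proximal = TRUE), "mcbs")$score # 5
compute_score <- function(status, scheme, patient_id = NA_character_) {
  scheme <- resolve_scheme(scheme)
  if (is.data.frame(status)) {
    stopifnot(nrow(status) == 1L)
    status <- vapply(
      status[segment_names()],
      function(v) as.logical(v[[1L]]), logical(1)
    )
  }
  validate_status(status)
  fired <- vapply(
    scheme$items$segments,
    function(segs) any(status[segs]), logical(1)
  )
  triggered <- scheme$items[fired, c("item", "deduction")]
  score <- scheme$max_score - sum(triggered$deduction)
  structure(
    list(
      patient_id = patient_id, scheme = scheme$name,
      score = as.integer(score), max_score = scheme$max_score,
      triggered = triggered
    ),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(
    "<score_result> ", x$scheme, " = ", x$score, "/", x$max_score,
    if (!is.na(x$patient_id)) paste0("  (patient ", x$patient_id, ")"),
    "\n",
    sep = ""
  )
  if (nrow(x$triggered)) {
    cat(
      "  deductions:",
      paste0(x$triggered$item, " (-", x$triggered$deduction, ")",
        collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

#' Score a cohort table
#'
#' Applies [compute_score()] row-wise to a cohort data frame carrying the
#' seven 0/1 segment columns. Rows with a missing or out-of-range segment
#' flag are not silently dropped: they are excluded from the scored output
#' and reported in the `unscorable` attribute with a per-row reason.
#'
#' @param cohort Data frame with `patient_id` and the segment flag columns
#'   (0/1 or logical).
#' @param scheme A [scoring_scheme()] or built-in name.
#' @return A tibble with one row per scorable patient (`patient_id`,
#'   `scheme`, `score`), input order preserved, with attribute `unscorable`
#'   a tibble of (`patient_id`, `reason`).
#' @export
score_cohort <- function(cohort, scheme) {
  scheme <- resolve_scheme(scheme)
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(segment_names(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing segment column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ids <- if ("patient_id" %in% names(cohort)) {
    as.character(cohort$patient_id)
  } else {
    as.character(seq_len(nrow(cohort)))
  }

  flags <- as.matrix(cohort[segment_names()])
  mode(flags) <- "numeric"
  ok_row <- apply(flags, 1L, function(r) all(!is.na(r) & r %in% c(0, 1)))

  scores <- integer(0)
  if (any(ok_row)) {
    lmat <- flags[ok_row, , drop = FALSE] == 1
    scores <- vapply(seq_len(nrow(lmat)), function(i) {
      compute_score(
        stats::setNames(lmat[i, ], segment_names()), scheme
      )$score
    }, integer(1))
  }
  out <- tibble::tibble(
    patient_id = ids[ok_row],
    scheme = scheme$name,
    score = scores
  )
  bad <- which(!ok_row)
  reasons <- vapply(bad, function(i) {
    flagged <- segment_names()[is.na(flags[i, ]) | !flags[i, ] %in% c(0, 1)]
    paste0(
      "invalid or missing segment flag(s): ",
      paste(flagged, collapse = ", ")
    )
  }, character(1))
  attr(out, "unscorable") <- tibble::tibble(
    patient_id = ids[bad], reason = reasons
  )
  out
}

#' Append CBS and mCBS columns to a cohort
#'
#' Convenience wrapper used by the evaluation pipeline and the scored-CSV
#' output: scores every row under both built-in schemes and appends integer
#' `cbs` and `mcbs` columns. All rows must be scorable.
#'
#' @param cohort Cohort data frame with the segment flag columns.
#' @return The input as a tibble with `cbs` and `mcbs` columns added.
#' @export
add_scores <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  for (nm in c("cbs", "mcbs")) {
    scored <- score_cohort(cohort, nm)
    if (nrow(attr(scored, "unscorable"))) {
      stop("cohort contains unscorable rows; see score_cohort() report",
        call. = FALSE
      )
    }
    cohort[[nm]] <- scored$score
  }
  cohort
}
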