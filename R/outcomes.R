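#' Outcome categories
#'
#' Each follow-up visit classifies a patient into exactly one of three
#' categories: `"quit"` (stopped the study drug, for lack of efficacy or side
#' effects), `"eff"` (still on drug and efficacious), or `"noeff"` (still on
#' drug, not efficacious). Efficacy means a reduction of at least 50% from the
#' baseline pain score.
#'
#' @format Character vector of the three category codes, in the canonical
#'   order `quit`, `eff`, `noeff`.
#' @export
OUTCOME_LEVELS <- c("quit", "eff", "noeff")

#' Classify a follow-up visit into an outcome category
#'
#' Quit status dominates: a patient who quit the drug is `"quit"` regardless
#' of pain scores. Otherwise the visit is `"eff"` when the follow-up pain
#' score shows a reduction of 50% or more from baseline (the boundary is
#' inclusive: follow-up exactly half of baseline is efficacious), else
#' `"noeff"`.
#'
#' All arguments are vectorized; lengths must match or be 1.
#'
#' @param baseline_pain Baseline pain score(s); must be strictly positive
#'   (the reduction fraction is undefined at zero).
#' @param followup_pain Follow-up pain score(s); may be `NA` only where
#'   `quit` is `TRUE`.
#' @param quit Logical; did the patient quit the study drug?
#' @return Character vector of categories from [OUTCOME_LEVELS].
#' @examples
#' classify_outcome(8, 4, FALSE)          # exactly 50% reduction -> "eff"
#' classify_outcome(8, 5, FALSE)          # 37.5% reduction -> "noeff"
#' classify_outcome(8, NA, TRUE)          # quit dominates
#' @export
classify_outcome <- function(baseline_pain, followup_pain = NA_real_,
                             quit = FALSE) {
  n <- max(length(baseline_pain), length(followup_pain), length(quit))
  baseline_pain <- rep_len(as.numeric(baseline_pain), n)
  followup_pain <- rep_len(as.numeric(followup_pain), n)
  quit <- rep_len(as.logical(quit), n)
  if (anyNA(quit)) rar_abort("quit status must be TRUE or FALSE, not NA")
  if (anyNA(baseline_pain) || any(baseline_pain <= 0)) {
    rar_abort("baseline_pain must be strictly positive (reduction fraction undefined otherwise)")
  }
  if (any(!quit & is.na(followup_pain))) {
    rar_abort("followup_pain is required whenever quit is FALSE")
  }
  ifelse(quit, "quit",
         ifelse(followup_pain <= 0.5 * baseline_pain, "eff", "noeff"))
}

out_cols <- function(visit_weeks) paste0("out_", visit_weeks)

#' Validate longitudinal patient records
#'
#' Checks a patient-records data frame (see [read_patient_csv()] for the
#' column layout) against the design's structural rules:
#'
#' * monotone quit (error): once a visit is `"quit"`, every later observed
#'   visit must also be `"quit"` — quitting the study drug is absorbing;
#' * out-of-schedule visits (error): `out_*` columns not in `visit_weeks`;
#' * gap patterns (warning): a later visit observed while an earlier one is
#'   still absent. Multisite data entry is asynchronous, so this is flagged
#'   for follow-up rather than treated as invalid.
#'
#' @param records Data frame with columns `patient_id`, `arm`, and one
#'   `out_<w>` column per visit week `w` (values in [OUTCOME_LEVELS] or `NA`
#'   for not-yet-observed).
#' @param visit_weeks Integer vector of scheduled visit weeks.
#' @return Data frame of violations with columns `row`, `patient_id`,
#'   `severity` (`"error"` or `"warning"`), `message`; zero rows iff the
#'   records are clean.
#' @export
validate_records <- function(records, visit_weeks = c(4, 8, 12)) {
  cols <- out_cols(visit_weeks)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    rar_abort(paste("records lack outcome columns:",
                    paste(missing_cols, collapse = ", ")),
              class = "rar_validation_error")
  }
  viol <- list()
  add <- function(rows, severity, msg) {
    if (length(rows) == 0) return()
    viol[[length(viol) + 1L]] <<- data.frame(
      row = rows,
      patient_id = as.character(records$patient_id[rows]),
      severity = severity, message = msg,
      stringsAsFactors = FALSE
    )
  }

  extra <- setdiff(grep("^out_", names(records), value = TRUE), cols)
  if (length(extra) > 0) {
    add(seq_len(nrow(records)), "error",
        paste("out-of-schedule visit columns:", paste(extra, collapse = ", ")))
  }

  out <- as.matrix(records[cols])
  bad_code <- !is.na(out) & !(out %in% OUTCOME_LEVELS)
  add(which(apply(bad_code, 1, any)), "error",
      paste("outcome codes must be one of", paste(OUTCOME_LEVELS, collapse = "/")))

  for (j in seq_along(cols)[-length(cols)]) {
    quit_j <- !is.na(out[, j]) & out[, j] == "quit"
    later <- out[, (j + 1):length(cols), drop = FALSE]
    broken <- later != "quit" & !is.na(later)
    rows <- which(quit_j & apply(broken, 1, any))
    add(rows, "error",
        sprintf("non-monotone quit: quit at week %d but a later visit is not quit",
                visit_weeks[j]))
  }

  for (j in seq_along(cols)[-1]) {
    earlier <- out[, 1:(j - 1), drop = FALSE]
    rows <- which(!is.na(out[, j]) & apply(is.na(earlier), 1, any))
    add(rows, "warning",
        sprintf("gap pattern: week %d observed but an earlier visit is absent",
                visit_weeks[j]))
  }

  if (length(viol) == 0) {
    return(data.frame(row = integer(0), patient_id = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, viol)
  res[order(res$row), , drop = FALSE]
}

#' Tally outcome-category counts for one arm at one visit
#'
#' Counts only records whose outcome at `visit_week` is observed; the triple
#' sums to the number of such records on the arm. This is the sufficient
#' statistic fed to the conjugate Dirichlet update.
#'
#' @inheritParams validate_records
#' @param arm Arm index in `1..n_arms`.
#' @param visit_week One of the scheduled visit weeks.
#' @param n_arms Number of arms; defaults to the maximum arm index present.
#' @return Named integer vector `c(quit=, eff=, noeff=)`.
#' @export
tally_counts <- function(records, arm, visit_week, n_arms = NULL) {
  n_arms <- n_arms %||% max(records$arm, 0L)
  if (length(arm) != 1 || !(arm %in% seq_len(n_arms))) {
    rar_abort(sprintf("unknown arm %s (trial has %d arms)",
                      paste(arm, collapse = ","), n_arms))
  }
  col <- paste0("out_", visit_week)
  if (!col %in% names(records)) {
    rar_abort(sprintf("visit week %s is not in the visit schedule", visit_week))
  }
  x <- records[[col]][records$arm == arm]
  counts <- table(factor(x[!is.na(x)], levels = OUTCOME_LEVELS))
  stats::setNames(as.integer(counts), OUTCOME_LEVELS)
}
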