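# Builders for in-memory patient records used across the tests.

empty_records <- function(visit_weeks = c(4, 8, 12)) {
  rec <- data.frame(patient_id = character(0), arm = integer(0),
                    enrollment_week = numeric(0), baseline_pain = numeric(0),
                    stringsAsFactors = FALSE)
  for (w in visit_weeks) {
    rec[[paste0("pain_", w)]] <- numeric(0)
    rec[[paste0("quit_", w)]] <- logical(0)
    rec[[paste0("out_", w)]] <- character(0)
  }
  rec
}

# One record with given outcome categories (NA = unobserved); pain scores and
# quit flags synthesized to be consistent with the categories at baseline 8.
record_row <- function(id, arm, out4 = NA, out8 = NA, out12 = NA,
                       enrollment_week = 0) {
  rec <- data.frame(patient_id = id, arm = as.integer(arm),
                    enrollment_week = enrollment_week, baseline_pain = 8,
                    stringsAsFactors = FALSE)
  outs <- list(`4` = out4, `8` = out8, `12` = out12)
  for (w in names(outs)) {
    o <- outs[[w]]
    rec[[paste0("pain_", w)]] <- if (is.na(o) || o == "quit") NA_real_
                                 else if (o == "eff") 3 else 6
    rec[[paste0("quit_", w)]] <- if (is.na(o)) NA else o == "quit"
    rec[[paste0("out_", w)]] <- as.character(o)
  }
  rec
}

records_from <- function(...) do.call(rbind, list(...))

# Fully observed records giving exact per-arm 12-week category counts.
# counts: n_arms x 3 matrix (quit, eff, noeff); weeks 4/8 mirror week 12 so
# monotone-quit always holds.
records_with_final_counts <- function(counts) {
  rows <- list()
  for (a in seq_len(nrow(counts))) {
    for (k in 1:3) {
      cat <- c("quit", "eff", "noeff")[k]
      n <- counts[a, k]
      if (n == 0) next
      for (i in seq_len(n)) {
        rows[[length(rows) + 1L]] <-
          record_row(sprintf("a%dc%di%d", a, k, i), a, cat, cat, cat)
      }
    }
  }
  do.call(rbind, rows)
}
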