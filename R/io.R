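#' Read patient records from CSV
#'
#' Expected columns: `patient_id, arm, enrollment_week, baseline_pain,
#' pain_4, quit_4, pain_8, quit_8, pain_12, quit_12` (one `pain_`/`quit_`
#' pair per configured visit week). Empty `pain_w` and `quit_w` cells mean
#' the visit is not yet observed; `quit_w = 1` marks a quit (the pain score
#' is then ignored); `quit_w = 0` requires a pain score, which is classified
#' against baseline by [classify_outcome()].
#'
#' Malformed rows (unparseable values, quit = 0 without a pain score, pain
#' present without a quit flag) and non-monotone quit patterns reject the
#' whole file with the offending row numbers. Soft findings — gap patterns
#' and pain scores outside `config$pain_range` — are returned in the
#' `"warnings"` attribute for the run log.
#'
#' @param path CSV file path.
#' @param config A [trial_config()] (visit schedule, arm count, pain range).
#' @return Patient-records data frame with derived `out_*` columns and a
#'   `"warnings"` attribute (data frame, possibly empty).
#' @export
read_patient_csv <- function(path, config = trial_config()) {
  if (!file.exists(path)) {
    rar_abort(paste("patient file not found:", path), class = "rar_input_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  weeks <- config$visit_weeks
  need <- c("patient_id", "arm", "enrollment_week", "baseline_pain",
            as.vector(rbind(paste0("pain_", weeks), paste0("quit_", weeks))))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    rar_abort(paste("patient CSV lacks columns:",
                    paste(missing_cols, collapse = ", ")),
              class = "rar_validation_error")
  }

  bad <- character(0)
  flag_bad <- function(rows, why) {
    if (length(rows) > 0) bad <<- c(bad, sprintf("row %d: %s", rows, why))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))

  arm <- suppressWarnings(as.integer(raw$arm))
  flag_bad(which(is.na(arm) | arm < 1 | arm > config$n_arms),
           sprintf("arm must be an integer in 1..%d", config$n_arms))
  enrollment_week <- num_or_na(raw$enrollment_week)
  flag_bad(which(is.na(enrollment_week) | enrollment_week < 0),
           "enrollment_week must be a nonnegative number")
  baseline <- num_or_na(raw$baseline_pain)
  flag_bad(which(is.na(baseline) | baseline <= 0),
           "baseline_pain must be a positive number")

  rec <- data.frame(patient_id = raw$patient_id, arm = arm,
                    enrollment_week = enrollment_week,
                    baseline_pain = baseline, stringsAsFactors = FALSE)
  warn <- list()
  for (w in weeks) {
    pain <- num_or_na(raw[[paste0("pain_", w)]])
    flag_bad(which(raw[[paste0("pain_", w)]] != "" & is.na(pain)),
             sprintf("pain_%d is not numeric", w))
    quit_raw <- raw[[paste0("quit_", w)]]
    quit <- rep(NA, length(quit_raw))
    quit[quit_raw %in% c("1", "TRUE", "true")] <- TRUE
    quit[quit_raw %in% c("0", "FALSE", "false")] <- FALSE
    flag_bad(which(quit_raw != "" & is.na(quit)),
             sprintf("quit_%d must be 0/1 or empty", w))
    flag_bad(which(quit %in% FALSE & is.na(pain)),
             sprintf("quit_%d = 0 requires a pain_%d score", w, w))
    flag_bad(which(is.na(quit) & !is.na(pain)),
             sprintf("pain_%d present without a quit_%d flag", w, w))

    out <- rep(NA_character_, nrow(raw))
    obs <- !is.na(quit) & (quit | !is.na(pain)) & !is.na(baseline) & baseline > 0
    if (any(obs)) {
      out[obs] <- classify_outcome(baseline[obs], pain[obs], quit[obs])
    }
    rng <- config$pain_range
    odd <- which(!is.na(pain) & (pain < rng[1] | pain > rng[2]))
    if (length(odd) > 0) {
      warn[[length(warn) + 1L]] <- data.frame(
        row = odd, patient_id = raw$patient_id[odd], severity = "warning",
        message = sprintf("pain_%d outside the configured range [%g, %g]",
                          w, rng[1], rng[2]),
        stringsAsFactors = FALSE)
    }
    rec[[paste0("pain_", w)]] <- pain
    rec[[paste0("quit_", w)]] <- quit
    rec[[paste0("out_", w)]] <- out
  }
  if (length(bad) > 0) {
    rar_abort(paste0("malformed patient rows:\n  ",
                     paste(bad, collapse = "\n  ")),
              class = "rar_validation_error")
  }

  report <- validate_records(rec, weeks)
  hard <- report[report$severity == "error", , drop = FALSE]
  if (nrow(hard) > 0) {
    rar_abort(paste0("invalid patient records:\n  ",
                     paste(sprintf("row %d (%s): %s", hard$row,
                                   hard$patient_id, hard$message),
                           collapse = "\n  ")),
              class = "rar_validation_error")
  }
  soft <- rbind(report[report$severity == "warning", , drop = FALSE],
                if (length(warn) > 0) do.call(rbind, warn))
  attr(rec, "warnings") <- soft
  rec
}

#' @rdname read_patient_csv
#' @param records Patient-records data frame.
#' @export
write_patient_csv <- function(records, path, config = trial_config()) {
  weeks <- config$visit_weeks
  cols <- c("patient_id", "arm", "enrollment_week", "baseline_pain",
            as.vector(rbind(paste0("pain_", weeks), paste0("quit_", weeks))))
  out <- records[cols]
  for (w in weeks) {
    q <- out[[paste0("quit_", w)]]
    out[[paste0("quit_", w)]] <- ifelse(is.na(q), "", as.integer(q))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write an allocation table as CSV
#'
#' Columns `slot_index, arm, assigned, stratum`. [write_allocation_export()]
#' writes the single-column `target_group` variant accepted by
#' electronic-data-capture allocation-table imports.
#'
#' @param path CSV file path.
#' @param n_arms Number of arms; defaults to the maximum arm code present.
#' @return `read_allocation_csv()` returns an `allocation_table`.
#' @export
read_allocation_csv <- function(path, n_arms = NULL) {
  if (!file.exists(path)) {
    rar_abort(paste("allocation table not found:", path),
              class = "rar_input_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slot_index", "arm", "assigned")
  if (length(setdiff(need, names(raw))) > 0) {
    rar_abort("allocation CSV must have columns slot_index, arm, assigned[, stratum]",
              class = "rar_validation_error")
  }
  stratum <- if ("stratum" %in% names(raw)) as.character(raw$stratum)
             else NA_character_
  stratum[is.na(stratum) | stratum == ""] <- NA_character_
  new_allocation_table(raw$slot_index, raw$arm, as.logical(raw$assigned),
                       stratum, n_arms %||% max(raw$arm))
}

#' @rdname read_allocation_csv
#' @param table An `allocation_table`.
#' @export
write_allocation_csv <- function(table, path) {
  out <- as.data.frame(table)
  out$stratum[is.na(out$stratum)] <- ""
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_allocation_csv
#' @param only_unassigned Export only the still-open slots (e.g. the newly
#'   appended block after an adaptation).
#' @export
write_allocation_export <- function(table, path, only_unassigned = FALSE) {
  x <- if (only_unassigned) table[!table$assigned, , drop = FALSE] else table
  utils::write.csv(data.frame(target_group = x$arm), path, row.names = FALSE)
  invisible(path)
}

#' Write an interim summary report
#'
#' One row per arm: label, enrolled count, posterior probability of being
#' best, posterior mean and variance of the utility. With `blinded = TRUE`
#' (the default, and what a safety monitoring board receives) arms carry the
#' generic codes from `config$arm_labels`; the code-to-treatment mapping
#' lives only in the configuration. Format follows the file extension:
#' `.json` writes JSON (including draw count and seed), anything else CSV.
#'
#' @param summary A [posterior_summary()].
#' @param path Output path.
#' @param config A [trial_config()] (for the blinded labels).
#' @param blinded Use generic arm codes instead of arm indices?
#' @export
write_summary_report <- function(summary, path, config = trial_config(),
                                 blinded = TRUE) {
  df <- data.frame(
    arm = if (blinded) config$arm_labels[summary$arm] else summary$arm,
    n_enrolled = summary$n_enrolled,
    p_max = summary$p_max,
    mean_utility = summary$mean_utility,
    var_utility = summary$var_utility
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(arms = df,
                    n_draws = attr(summary, "n_draws"),
                    m_imputations = attr(summary, "m_imputations"),
                    seed = attr(summary, "seed"))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Run manifest
#'
#' Every adaptation or simulation run emits one manifest: package version,
#' configuration hash, seed, MD5 digests of the input files, output paths,
#' and a timestamp. Manifests are appended as JSON lines to an append-only
#' log, mirroring the audit-trail discipline of trial data systems.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed used for the run (or `NA`).
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of output file paths.
#' @param step Short name of the pipeline step.
#' @param timestamp Override the wall-clock timestamp (used in tests; the
#'   default records the current UTC time).
#' @return The manifest as a named list.
#' @export
run_manifest <- function(config, seed = NA_integer_, inputs = character(0),
                         outputs = character(0), step = "run",
                         timestamp = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
  } else NULL
  list(
    step = step,
    package = "bayesrar",
    version = as.character(utils::packageVersion("bayesrar")),
    timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config_hash = config_hash(config),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    inputs = digests,
    outputs = as.list(outputs)
  )
}

#' @rdname run_manifest
#' @param manifest A manifest list from `run_manifest()`.
#' @param path JSON-lines file to append to.
#' @export
append_manifest <- function(manifest, path) {
  line <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(path)
}

#' Append an entry to the adaptation audit log
#'
#' JSON-lines log of every adaptation: config hash, seed, per-arm posterior
#' summary, randomization vector, loser set and slot counts.
#'
#' @param entry Named list to log.
#' @param path JSON-lines file to append to.
#' @export
audit_append <- function(entry, path) {
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(path)
}

#' Read a truth scenario from YAML
#'
#' Keys `p4`, `t_eff`, `t_noeff` (optional `t_eff2`, `t_noeff2`): each
#' either one triple (shared by all arms) or a list of per-arm triples;
#' optional `n_arms`.
#'
#' @param path YAML file path.
#' @return A [scenario_truth()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    rar_abort(paste("scenario file not found:", path), class = "rar_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rar_abort(paste("cannot parse scenario YAML:", conditionMessage(e)),
              class = "rar_config_error")
  })
  as_triples <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else as.numeric(x)
  }
  scenario_truth(p4 = as_triples(raw$p4),
                 t_eff = as_triples(raw$t_eff),
                 t_noeff = as_triples(raw$t_noeff),
                 t_eff2 = as_triples(raw$t_eff2),
                 t_noeff2 = as_triples(raw$t_noeff2),
                 n_arms = raw$n_arms %||% 4L)
}
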