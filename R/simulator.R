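#' Generative truth scenario for virtual trials
#'
#' Describes each arm's true outcome process: a probability triple over the
#' week-4 categories, and conditional triples for the next visit given the
#' current visit is on-drug efficacious (`t_eff`) or on-drug
#' non-efficacious (`t_noeff`). Quitting is absorbing. Transition triples
#' are shared between the 4-to-8 and 8-to-12 week steps unless step-2
#' overrides are given, so the implied 12-week marginal is available in
#' closed form by chain multiplication ([twelve_week_marginal()]).
#'
#' @param p4 Week-4 category probabilities: a length-3 vector (recycled
#'   across arms) or an `n_arms x 3` matrix with columns quit/eff/noeff.
#' @param t_eff,t_noeff Next-visit category triples conditional on the
#'   current visit being `eff` / `noeff`; same shapes as `p4`.
#' @param t_eff2,t_noeff2 Optional overrides for the 8-to-12 week step.
#' @param n_arms Number of arms (needed only when all triples are vectors).
#' @return Object of class `scenario_truth`.
#' @export
scenario_truth <- function(p4, t_eff, t_noeff, t_eff2 = NULL, t_noeff2 = NULL,
                           n_arms = 4L) {
  as_mat <- function(x, what) {
    if (is.null(dim(x))) x <- matrix(x, nrow = n_arms, ncol = 3, byrow = TRUE)
    if (ncol(x) != 3) rar_abort(paste(what, "must have 3 columns"))
    for (i in seq_len(nrow(x))) check_simplex(x[i, ], what)
    colnames(x) <- OUTCOME_LEVELS
    x
  }
  p4 <- as_mat(p4, "p4")
  n_arms <- nrow(p4)
  structure(list(
    p4 = p4,
    t_eff = as_mat(t_eff, "t_eff"),
    t_noeff = as_mat(t_noeff, "t_noeff"),
    t_eff2 = as_mat(t_eff2 %||% t_eff, "t_eff2"),
    t_noeff2 = as_mat(t_noeff2 %||% t_noeff, "t_noeff2"),
    n_arms = n_arms
  ), class = "scenario_truth")
}

#' Null scenario: four generatively identical arms
#'
#' The default null used for type I error estimation: every arm shares
#' week-4 probabilities quit 0.30 / efficacious 0.25 / non-efficacious 0.45,
#' and transition triples equal to the design's elicited conditional prior
#' means — (0.1, 0.7, 0.2) after an efficacious visit and (0.1, 0.2, 0.7)
#' after a non-efficacious one. These rates are an assumption of this
#' package's simulator, chosen as clinically plausible for a chronic-pain
#' population; they are not estimates from any trial.
#'
#' @param n_arms Number of identical arms.
#' @return A [scenario_truth()].
#' @export
null_scenario <- function(n_arms = 4L) {
  scenario_truth(p4 = c(0.30, 0.25, 0.45),
                 t_eff = c(0.1, 0.7, 0.2),
                 t_noeff = c(0.1, 0.2, 0.7),
                 n_arms = n_arms)
}

step_marginal <- function(m, te, tn) {
  cbind(m[, 1] + m[, 2] * te[, 1] + m[, 3] * tn[, 1],
        m[, 2] * te[, 2] + m[, 3] * tn[, 2],
        m[, 2] * te[, 3] + m[, 3] * tn[, 3])
}

#' Closed-form 12-week marginal of a scenario
#'
#' Chain-multiplies the week-4 triple through the two transition steps.
#' Useful as an analytic oracle for the simulated trajectories and for
#' computing each arm's true utility.
#'
#' @param truth A [scenario_truth()].
#' @return `n_arms x 3` matrix of 12-week category probabilities.
#' @export
twelve_week_marginal <- function(truth) {
  m8 <- step_marginal(truth$p4, truth$t_eff, truth$t_noeff)
  m12 <- step_marginal(m8, truth$t_eff2, truth$t_noeff2)
  colnames(m12) <- OUTCOME_LEVELS
  m12
}

sample_rows <- function(P) {
  u <- stats::runif(nrow(P))
  OUTCOME_LEVELS[1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])]
}

#' Simulate patient trajectories
#'
#' Draws a full longitudinal trajectory per patient from the scenario truth
#' (week-4 category, then conditional transitions with quit absorbing) and
#' synthesizes baseline/follow-up pain scores consistent with each category,
#' so generated records round-trip through [classify_outcome()]: efficacious
#' visits get a follow-up score at or below half of baseline, non-efficacious
#' visits above half, quit visits a quit flag and no score.
#'
#' All visits are generated up front; [mask_records()] applies the calendar
#' data cut at analysis time.
#'
#' @param truth A [scenario_truth()].
#' @param arms Integer vector of arm assignments (one patient per element).
#' @param enrollment_weeks Numeric vector of enrollment calendar weeks.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for generated patient identifiers.
#' @param baseline_range Range from which baseline pain scores are drawn
#'   uniformly.
#' @return Patient-records data frame (same layout as [read_patient_csv()]
#'   plus derived `out_*` columns).
#' @export
generate_patients <- function(truth, arms, enrollment_weeks = 0,
                              seed = NULL, id_prefix = "P",
                              baseline_range = c(4, 10)) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(arms)
  if (any(!arms %in% seq_len(truth$n_arms))) {
    rar_abort("arms contain indices outside the scenario's arm range")
  }
  enrollment_weeks <- rep_len(as.numeric(enrollment_weeks), n)
  baseline <- stats::runif(n, baseline_range[1], baseline_range[2])

  cat4 <- sample_rows(truth$p4[arms, , drop = FALSE])
  next_cat <- function(cur, te, tn) {
    nxt <- rep("quit", length(cur))
    for (s in c("eff", "noeff")) {
      sel <- cur == s
      if (!any(sel)) next
      P <- (if (s == "eff") te else tn)[arms[sel], , drop = FALSE]
      nxt[sel] <- sample_rows(P)
    }
    nxt
  }
  cat8 <- next_cat(cat4, truth$t_eff, truth$t_noeff)
  cat12 <- next_cat(cat8, truth$t_eff2, truth$t_noeff2)

  pain_for <- function(cat) {
    u <- stats::runif(length(cat))
    ifelse(cat == "eff", baseline * 0.5 * u,
           ifelse(cat == "noeff", baseline * (0.5 + 0.5 * pmax(u, 1e-9)), NA_real_))
  }
  rec <- data.frame(
    patient_id = paste0(id_prefix, seq_len(n)),
    arm = as.integer(arms),
    enrollment_week = enrollment_weeks,
    baseline_pain = baseline,
    stringsAsFactors = FALSE
  )
  for (pair in list(list(4, cat4), list(8, cat8), list(12, cat12))) {
    w <- pair[[1]]; cat <- pair[[2]]
    pain <- pain_for(cat)
    rec[[paste0("pain_", w)]] <- pain
    rec[[paste0("quit_", w)]] <- cat == "quit"
    rec[[paste0("out_", w)]] <- classify_outcome(baseline, pain, cat == "quit")
  }
  rec
}

#' Apply a calendar-time data cut
#'
#' Masks (sets to `NA`) every visit outcome whose visit has not yet occurred
#' by `analysis_week`: a patient's week-`w` outcome is observable only when
#' `enrollment_week + w <= analysis_week`. Interim analyses see exactly the
#' data a real data extract at that week would contain.
#'
#' @param records Patient-records data frame.
#' @param analysis_week Calendar week of the data cut.
#' @param visit_weeks Visit schedule.
#' @return The records with unreached `out_*`, `pain_*`, `quit_*` entries
#'   set to `NA`.
#' @export
mask_records <- function(records, analysis_week, visit_weeks = c(4, 8, 12)) {
  for (w in visit_weeks) {
    unseen <- records$enrollment_week + w > analysis_week
    for (p in c("out_", "pain_", "quit_")) {
      col <- paste0(p, w)
      if (col %in% names(records)) records[[col]][unseen] <- NA
    }
  }
  records
}

#' Simulate one complete adaptive trial
#'
#' Runs the full design against a generative truth: patients accrue over
#' calendar time and take the next available slot of the live allocation
#' table (burn-in table first); the first interim analysis fires when the
#' burn-in enrollment completes, and further interims follow every
#' `adaptation_interval_weeks`. Each interim applies the calendar data cut,
#' summarizes the posterior over patients with at least one observed visit,
#' updates the permanent loser set, checks the early-success rule, and —
#' when the trial continues — adapts the allocation table with the new
#' randomization vector. If enrollment reaches `max_n` the trial follows all
#' patients to the final visit and applies the success rule once more on
#' complete data (no imputation is needed at that point).
#'
#' @param truth A [scenario_truth()].
#' @param config A [trial_config()].
#' @param accrual_rate Patients per calendar week.
#' @param seed Optional integer seed; the same seed, config and truth
#'   reproduce the trial exactly.
#' @param accrual `"uniform"` for deterministic evenly-spaced arrivals,
#'   `"poisson"` for a Poisson arrival process at the same rate.
#' @param swap_lag_weeks Delay between an interim analysis and the adapted
#'   table going live; patients enrolling in the window use the old table
#'   (the spare-slot buffer's purpose). Default 0: instantaneous swap.
#' @return Object of class `trial_result`: `success`, `winner` (arm index or
#'   `NULL`), `stopped_early`, `n_enrolled`, `n_per_arm`, `duration_weeks`,
#'   `losers`, `interim_history` (per analysis: week, summary, q, losers),
#'   and the simulated `records`.
#' @export
run_trial <- function(truth, config = trial_config(), accrual_rate = 4,
                      seed = NULL, accrual = c("uniform", "poisson"),
                      swap_lag_weeks = 0) {
  if (!is.null(seed)) set.seed(seed)
  accrual <- match.arg(accrual)
  if (accrual_rate <= 0) rar_abort("accrual_rate must be positive")
  if (truth$n_arms != config$n_arms) {
    rar_abort("scenario and configuration disagree on the number of arms",
              class = "rar_config_error")
  }
  times <- if (accrual == "uniform") {
    (seq_len(config$max_n) - 1) / accrual_rate
  } else {
    cumsum(stats::rexp(config$max_n, rate = accrual_rate))
  }
  final_week <- config$visit_weeks[length(config$visit_weeks)]

  alloc <- make_burnin_table(config)
  pending <- NULL
  chunks <- list()
  losers <- integer(0)
  history <- list()
  enrolled <- 0L

  enroll_upto <- function(t_max) {
    while (enrolled < config$max_n && times[enrolled + 1] <= t_max) {
      if (!is.null(pending) && times[enrolled + 1] >= pending$active_week) {
        alloc <<- pending$table
        pending <<- NULL
      }
      hi <- enrolled
      while (hi < config$max_n && times[hi + 1] <= t_max &&
             (is.null(pending) || times[hi + 1] < pending$active_week)) {
        hi <- hi + 1L
      }
      k <- hi - enrolled
      ab <- assign_block(alloc, k)
      alloc <<- ab$table
      recs <- generate_patients(truth, ab$arms,
                                enrollment_weeks = times[(enrolled + 1):hi],
                                id_prefix = sprintf("P%04d_", enrolled + 1))
      chunks[[length(chunks) + 1L]] <<- recs
      enrolled <<- hi
    }
  }

  enroll_upto(times[config$burn_in_n])
  interim_week <- times[config$burn_in_n]
  winner <- NULL
  stopped_early <- FALSE
  duration <- NA_real_

  repeat {
    records <- do.call(rbind, chunks)
    records$patient_id <- make.unique(records$patient_id)
    masked <- mask_records(records, interim_week, config$visit_weeks)
    elig <- masked[has_observed_visit(masked, config$visit_weeks), , drop = FALSE]
    summ <- posterior_summary(elig, config, seed = sample.int(2147483646L, 1))
    losers <- check_losers(summ, config$loser_threshold, losers)
    winner <- check_success(summ, config$success_threshold)
    entry <- list(week = interim_week, summary = summ, losers = losers, q = NULL)
    if (!is.null(winner)) {
      stopped_early <- TRUE
      duration <- interim_week
      history[[length(history) + 1L]] <- entry
      break
    }
    q <- randomization_vector(summ, losers)
    entry$q <- q
    history[[length(history) + 1L]] <- entry
    adapted <- adapt_table(alloc, q, config$block_size)
    if (swap_lag_weeks > 0) {
      pending <- list(table = adapted, active_week = interim_week + swap_lag_weeks)
    } else {
      alloc <- adapted
    }

    next_week <- interim_week + config$adaptation_interval_weeks
    enroll_upto(next_week)
    if (enrolled >= config$max_n) {
      # follow everyone to the final visit, then the end-of-trial analysis
      records <- do.call(rbind, chunks)
      records$patient_id <- make.unique(records$patient_id)
      duration <- times[enrolled] + final_week
      summ <- posterior_summary(records, config, seed = sample.int(2147483646L, 1))
      losers <- check_losers(summ, config$loser_threshold, losers)
      winner <- check_success(summ, config$success_threshold)
      history[[length(history) + 1L]] <- list(week = duration, summary = summ,
                                              losers = losers, q = NULL)
      break
    }
    interim_week <- next_week
  }

  records <- do.call(rbind, chunks)
  records$patient_id <- make.unique(records$patient_id)
  n_per_arm <- as.integer(table(factor(records$arm, levels = seq_len(config$n_arms))))
  structure(list(
    success = !is.null(winner),
    winner = winner,
    stopped_early = stopped_early,
    n_enrolled = enrolled,
    n_per_arm = n_per_arm,
    duration_weeks = duration,
    losers = losers,
    interim_history = history,
    records = records,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Adaptive trial:", if (x$success) paste("SUCCESS, winner arm", x$winner)
      else "no winner declared", "\n")
  cat("  enrolled", x$n_enrolled, "(",
      paste(x$n_per_arm, collapse = "/"), "per arm ) over",
      round(x$duration_weeks, 1), "weeks;",
      length(x$interim_history), "analyses",
      if (x$stopped_early) "(stopped early)" else "", "\n")
  if (length(x$losers)) cat("  loser arms:", paste(x$losers, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate design operating characteristics by simulation
#'
#' Repeats [run_trial()] with independent seeds and aggregates: winner
#' declaration rate (the type I error under a null scenario, power under an
#' effect scenario) with its Monte-Carlo standard error, early-stop rate,
#' sample-size mean and SD, mean trial duration, mean per-arm allocation
#' shares, per-arm loser-declaration and win rates.
#'
#' @inheritParams run_trial
#' @param n_reps Number of simulated trials.
#' @param keep_results Keep the individual `trial_result` objects?
#' @return Object of class `oc_summary`.
#' @export
operating_characteristics <- function(truth, config = trial_config(),
                                      accrual_rate = 4, n_reps = 500,
                                      seed = NULL, accrual = "uniform",
                                      keep_results = FALSE) {
  if (n_reps < 1) rar_abort("n_reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2147483646L, n_reps)
  A <- config$n_arms
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res[[r]] <- run_trial(truth, config, accrual_rate, seed = seeds[r],
                          accrual = accrual)
  }
  succ <- vapply(res, `[[`, logical(1), "success")
  early <- vapply(res, `[[`, logical(1), "stopped_early")
  n_tot <- vapply(res, `[[`, numeric(1), "n_enrolled")
  dur <- vapply(res, `[[`, numeric(1), "duration_weeks")
  shares <- t(vapply(res, function(x) x$n_per_arm / x$n_enrolled, numeric(A)))
  loser_rate <- colMeans(t(vapply(res, function(x) seq_len(A) %in% x$losers,
                                  logical(A))))
  win_rate <- colMeans(t(vapply(res, function(x) seq_len(A) %in% (x$winner %||% 0L),
                                logical(A))))
  p <- mean(succ)
  structure(list(
    n_reps = n_reps,
    success_rate = p,
    success_se = sqrt(p * (1 - p) / n_reps),
    early_stop_rate = mean(early),
    mean_n = mean(n_tot), sd_n = stats::sd(n_tot),
    mean_duration = mean(dur),
    alloc_share = colMeans(shares),
    loser_rate = loser_rate,
    win_rate = win_rate,
    results = if (keep_results) res else NULL
  ), class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat("Operating characteristics over", x$n_reps, "simulated trials\n")
  cat(sprintf("  winner declared: %.1f%% (MC SE %.1f pp); early stop %.1f%%\n",
              100 * x$success_rate, 100 * x$success_se, 100 * x$early_stop_rate))
  cat(sprintf("  sample size: mean %.1f (SD %.1f); mean duration %.1f weeks\n",
              x$mean_n, x$sd_n, x$mean_duration))
  cat("  mean allocation share:",
      paste(sprintf("%.3f", x$alloc_share), collapse = " "), "\n")
  cat("  loser rate per arm:",
      paste(sprintf("%.3f", x$loser_rate), collapse = " "), "\n")
  invisible(x)
}
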