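#' Conjugate Dirichlet update
#'
#' The three-category 12-week outcome for an arm is multinomial with
#' probability triple `theta`; with a Dirichlet prior on `theta` the
#' posterior is Dirichlet with the observed category counts added to the
#' concentration parameters.
#'
#' @param prior Strictly positive concentration triple.
#' @param counts Nonnegative integer count triple.
#' @return Posterior concentration triple `prior + counts`.
#' @export
update_dirichlet <- function(prior, counts) {
  if (length(prior) != length(counts)) {
    rar_abort("prior and counts must have the same length")
  }
  if (any(prior <= 0)) rar_abort("prior concentrations must be strictly positive")
  if (any(counts < 0) || any(counts != round(counts))) {
    rar_abort("counts must be nonnegative integers")
  }
  prior + counts
}

#' Arm utility
#'
#' Scalar score of an arm's 12-week outcome probabilities combining
#' tolerability and efficacy: `U = weight * theta[2] + (1 - theta[1])`, where
#' `theta = (quit, eff, noeff)`. With the default weight 0.75 the utility
#' ranges over \[0, 1.75\]: 0 for certain quitting, 1.75 for certain
#' efficacious retention.
#'
#' @param theta Probability triple on the simplex, or an `n x 3` matrix of
#'   triples (rows are checked against the simplex to tolerance 1e-9).
#' @param weight Nonnegative weight on the efficacy probability.
#' @return Numeric utility (one value per row of `theta`).
#' @export
utility <- function(theta, weight = 0.75) {
  if (weight < 0) rar_abort("weight must be nonnegative")
  if (is.matrix(theta)) {
    if (ncol(theta) != 3) rar_abort("theta must have 3 columns")
    bad <- abs(rowSums(theta) - 1) > SIMPLEX_TOL | apply(theta < -SIMPLEX_TOL, 1, any)
    if (any(bad)) rar_abort("theta rows must lie on the probability simplex")
    return(weight * theta[, 2] + (1 - theta[, 1]))
  }
  if (length(theta) != 3) rar_abort("theta must be a probability triple")
  check_simplex(theta)
  weight * theta[2] + (1 - theta[1])
}

latest_interim_col <- function(records, interim_weeks) {
  # per record: index into interim_weeks of the latest observed interim
  # visit, NA if none observed
  latest <- rep(NA_integer_, nrow(records))
  for (j in seq_along(interim_weeks)) {
    obs <- !is.na(records[[paste0("out_", interim_weeks[j])]])
    latest[obs] <- j
  }
  latest
}

#' Fit conditional transition models for interim-to-final prediction
#'
#' For each arm and each interim visit week, two Dirichlet posteriors over
#' the 12-week category triple are maintained: one conditional on the interim
#' outcome being efficacious (prior Dirichlet(1, 7, 2) — a priori 12-week
#' rates of 10/70/20% for quit/eff/noeff) and one conditional on
#' non-efficacious (prior Dirichlet(1, 2, 7)). Each prior carries a prior
#' sample size of 10 patients, i.e. weakly informative. The models are fit
#' only on patients who stayed on drug at the interim visit: a patient who
#' quit needs no prediction, since quitting is absorbing and their final
#' outcome is already determined.
#'
#' A patient observed (on drug) at several interim visits with a final
#' outcome contributes a count to each corresponding visit model.
#'
#' @param records Patient-records data frame (see [read_patient_csv()]).
#' @param config A [trial_config()]; supplies the priors, arm count and
#'   visit schedule.
#' @return Object of class `transition_models`: arrays `eff` and `noeff` of
#'   dimension `n_arms x n_interim_visits x 3` holding posterior
#'   concentrations, plus the schedule.
#' @export
fit_transition_models <- function(records, config = trial_config()) {
  weeks <- config$visit_weeks
  interim_weeks <- weeks[-length(weeks)]
  final_week <- weeks[length(weeks)]
  A <- config$n_arms
  dn <- list(arm = as.character(seq_len(A)),
             week = as.character(interim_weeks),
             category = OUTCOME_LEVELS)
  eff <- array(rep(config$eff_prior, each = A * length(interim_weeks)),
               dim = c(A, length(interim_weeks), 3), dimnames = dn)
  noeff <- array(rep(config$noeff_prior, each = A * length(interim_weeks)),
                 dim = c(A, length(interim_weeks), 3), dimnames = dn)

  final <- records[[paste0("out_", final_week)]]
  for (j in seq_along(interim_weeks)) {
    interim <- records[[paste0("out_", interim_weeks[j])]]
    use <- !is.na(final) & !is.na(interim) & interim != "quit"
    if (!any(use)) next
    tab <- table(factor(records$arm[use], levels = seq_len(A)),
                 factor(interim[use], levels = c("eff", "noeff")),
                 factor(final[use], levels = OUTCOME_LEVELS))
    eff[, j, ] <- eff[, j, ] + tab[, "eff", ]
    noeff[, j, ] <- noeff[, j, ] + tab[, "noeff", ]
  }
  structure(list(eff = eff, noeff = noeff, interim_weeks = interim_weeks,
                 final_week = final_week, n_arms = A),
            class = "transition_models")
}

#' Impute one completion of the final-visit counts
#'
#' Produces per-arm 12-week category counts over all records, filling in
#' unobserved final outcomes from interim information:
#'
#' * an observed final outcome passes through unchanged;
#' * a patient whose latest observed interim outcome is `"quit"` is imputed
#'   `"quit"` with certainty (quitting is absorbing);
#' * otherwise the final category is drawn from the posterior predictive of
#'   the matching conditional transition model — a probability triple is
#'   drawn from the model's Dirichlet, then the category from it. When both
#'   interim visits are observed on-drug, the latest visit's model is used.
#'
#' Records with no observed visit at all violate the precondition (such
#' patients are excluded from interim analyses upstream) and raise an error.
#'
#' @inheritParams fit_transition_models
#' @param models A `transition_models` object from [fit_transition_models()].
#' @return Integer matrix `n_arms x 3` (columns `quit`, `eff`, `noeff`) of
#'   observed-plus-imputed final counts.
#' @export
impute_final_counts <- function(records, models, config = trial_config()) {
  stopifnot(inherits(models, "transition_models"))
  A <- config$n_arms
  final_col <- paste0("out_", models$final_week)
  final <- records[[final_col]]
  latest <- latest_interim_col(records, models$interim_weeks)
  if (any(is.na(final) & is.na(latest))) {
    rar_abort("records without any observed visit cannot be imputed; exclude them upstream",
              class = "rar_input_error")
  }

  imputed <- final
  todo <- which(is.na(final))
  if (length(todo) > 0) {
    wk_idx <- latest[todo]
    status <- records[[paste0("out_", models$interim_weeks[1])]][todo]
    for (j in seq_along(models$interim_weeks)) {
      sel <- wk_idx == j
      status[sel] <- records[[paste0("out_", models$interim_weeks[j])]][todo][sel]
    }
    is_quit <- status == "quit"
    imputed[todo[is_quit]] <- "quit"

    draw <- todo[!is_quit]
    if (length(draw) > 0) {
      conc <- matrix(NA_real_, length(draw), 3)
      dstat <- status[!is_quit]
      darm <- records$arm[draw]
      dwk <- latest[draw]
      for (j in seq_along(models$interim_weeks)) {
        for (s in c("eff", "noeff")) {
          sel <- dwk == j & dstat == s
          if (!any(sel)) next
          conc[sel, ] <- models[[if (s == "eff") "eff" else "noeff"]][darm[sel], j, ]
        }
      }
      g <- matrix(stats::rgamma(length(draw) * 3, shape = conc), ncol = 3)
      theta <- g / rowSums(g)
      u <- stats::runif(length(draw))
      cat_idx <- 1L + (u > theta[, 1]) + (u > theta[, 1] + theta[, 2])
      imputed[draw] <- OUTCOME_LEVELS[cat_idx]
    }
  }
  tab <- table(factor(records$arm, levels = seq_len(A)),
               factor(imputed, levels = OUTCOME_LEVELS))
  m <- matrix(as.integer(tab), nrow = A, dimnames = list(seq_len(A), OUTCOME_LEVELS))
  m
}

has_observed_visit <- function(records, visit_weeks) {
  obs <- rep(FALSE, nrow(records))
  for (w in visit_weeks) obs <- obs | !is.na(records[[paste0("out_", w)]])
  obs
}

#' Bayesian interim summary: P(best), posterior mean and variance of utility
#'
#' The interim-analysis workhorse. Records lacking any observed visit are
#' excluded (they carry no outcome information). The summary then repeats,
#' for each of `m_imputations` completions: impute the final counts
#' ([impute_final_counts()]), apply the conjugate update to each arm's
#' outcome prior, draw `n_draws / m_imputations` probability triples per arm
#' and convert each to a utility. Utility draws are pooled across
#' completions, so the reported posterior variance includes
#' between-imputation variance. Per pooled draw index the best arm is the
#' one with maximal utility (exact ties split uniformly at random);
#' `p_max` is each arm's share of wins.
#'
#' @inheritParams fit_transition_models
#' @param seed Optional integer seed; recorded in the result for audit.
#' @return Object of class `posterior_summary`: a data frame with one row
#'   per arm and columns `arm`, `n_enrolled`, `p_max`, `mean_utility`,
#'   `var_utility`, carrying attributes `n_draws`, `m_imputations`, `seed`.
#' @export
posterior_summary <- function(records, config = trial_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- config$n_arms
  if (nrow(records) > 0 && any(!records$arm %in% seq_len(A))) {
    rar_abort("records contain arm indices outside 1..n_arms")
  }
  records <- records[has_observed_visit(records, config$visit_weeks), , drop = FALSE]
  n_enrolled <- as.integer(table(factor(records$arm, levels = seq_len(A))))

  models <- fit_transition_models(records, config)
  m <- config$m_imputations
  per_m <- ceiling(config$n_draws / m)
  total <- per_m * m

  U <- matrix(NA_real_, total, A)
  for (i in seq_len(m)) {
    counts <- impute_final_counts(records, models, config)
    rows <- ((i - 1) * per_m + 1):(i * per_m)
    for (a in seq_len(A)) {
      alpha <- update_dirichlet(config$outcome_prior, counts[a, ])
      theta <- rdirichlet(per_m, alpha)
      U[rows, a] <- config$utility_weight * theta[, 2] + (1 - theta[, 1])
    }
  }

  best <- max.col(U, ties.method = "random")
  p_max <- tabulate(best, nbins = A) / total
  res <- data.frame(
    arm = seq_len(A),
    n_enrolled = n_enrolled,
    p_max = p_max,
    mean_utility = colMeans(U),
    var_utility = apply(U, 2, stats::var)
  )
  structure(res, class = c("posterior_summary", "data.frame"),
            n_draws = total, m_imputations = m,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior interim summary (", attr(x, "n_draws"), " draws, ",
      attr(x, "m_imputations"), " imputations)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
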