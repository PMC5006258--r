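#' Trial design configuration
#'
#' Bundles every tunable of the adaptive design. Defaults reproduce the
#' four-arm comparative-effectiveness design this package implements: a
#' burn-in of 80 patients equally allocated (plus 20 spare slots so
#' enrollment never stalls while a new table is prepared), a cap of 400
#' patients, interim analyses every 13 weeks after the 80th enrollment,
#' early-success threshold 0.925 and loser threshold 0.01 on the posterior
#' probability of being the best arm, utility weight 0.75 on the efficacy
#' rate, a Dirichlet(1/3, 1/3, 1/3) prior on each arm's 12-week category
#' probabilities, and Dirichlet(1, 7, 2) / (1, 2, 7) conditional priors
#' (prior sample size 10) for predicting 12-week outcomes from interim
#' efficacy / no-efficacy.
#'
#' @param n_arms Number of treatment arms.
#' @param burn_in_n Patients enrolled under fixed equal allocation before any
#'   adaptation; must be divisible by `n_arms`.
#' @param burn_in_spare Extra equally-allocated slots appended to the initial
#'   table as a buffer; must be divisible by `n_arms`.
#' @param max_n Maximum number of patients enrolled.
#' @param adaptation_interval_weeks Calendar weeks between interim analyses.
#' @param success_threshold Posterior probability of being the best arm at or
#'   above which the trial stops for success (inclusive).
#' @param loser_threshold Posterior probability at or below which an arm is
#'   permanently closed to enrollment (inclusive).
#' @param utility_weight Weight on the efficacy probability in the utility
#'   `U = w * theta_eff + (1 - theta_quit)`.
#' @param outcome_prior Dirichlet concentration triple for each arm's
#'   12-week category probabilities.
#' @param eff_prior,noeff_prior Dirichlet concentration triples of the
#'   conditional 12-week model given interim efficacy / no-efficacy.
#' @param visit_weeks Follow-up visit schedule; the last entry is the primary
#'   endpoint visit.
#' @param n_draws Total Monte-Carlo draws per arm in a posterior summary.
#' @param m_imputations Number of multiple-imputation completions per
#'   summary.
#' @param block_size Slots appended to the allocation table at each
#'   adaptation.
#' @param arm_labels Blinded arm codes used in reports.
#' @param pain_range Plausible pain-score range; scores outside it warn on
#'   import but are not rejected (the scale bounds are site convention, not a
#'   model assumption).
#' @return Object of class `trial_config` (a named list).
#' @export
trial_config <- function(n_arms = 4L,
                         burn_in_n = 80L,
                         burn_in_spare = 20L,
                         max_n = 400L,
                         adaptation_interval_weeks = 13,
                         success_threshold = 0.925,
                         loser_threshold = 0.01,
                         utility_weight = 0.75,
                         outcome_prior = c(1, 1, 1) / 3,
                         eff_prior = c(1, 7, 2),
                         noeff_prior = c(1, 2, 7),
                         visit_weeks = c(4L, 8L, 12L),
                         n_draws = 10000L,
                         m_imputations = 20L,
                         block_size = 100L,
                         arm_labels = NULL,
                         pain_range = c(0, 10)) {
  cfg <- list(
    n_arms = as.integer(n_arms),
    burn_in_n = as.integer(burn_in_n),
    burn_in_spare = as.integer(burn_in_spare),
    max_n = as.integer(max_n),
    adaptation_interval_weeks = as.numeric(adaptation_interval_weeks),
    success_threshold = as.numeric(success_threshold),
    loser_threshold = as.numeric(loser_threshold),
    utility_weight = as.numeric(utility_weight),
    outcome_prior = as.numeric(outcome_prior),
    eff_prior = as.numeric(eff_prior),
    noeff_prior = as.numeric(noeff_prior),
    visit_weeks = as.integer(visit_weeks),
    n_draws = as.integer(n_draws),
    m_imputations = as.integer(m_imputations),
    block_size = as.integer(block_size),
    arm_labels = arm_labels %||% LETTERS[seq_len(n_arms)],
    pain_range = as.numeric(pain_range)
  )
  validate_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_config <- function(cfg) {
  err <- function(msg) rar_abort(msg, class = "rar_config_error")
  if (cfg$n_arms < 2) err("need at least 2 arms")
  if (cfg$burn_in_n %% cfg$n_arms != 0) {
    err("burn_in_n must be divisible by n_arms for exact equal allocation")
  }
  if (cfg$burn_in_spare %% cfg$n_arms != 0) {
    err("burn_in_spare must be divisible by n_arms")
  }
  if (!(cfg$loser_threshold > 0 && cfg$loser_threshold < cfg$success_threshold &&
        cfg$success_threshold < 1)) {
    err("thresholds must satisfy 0 < loser_threshold < success_threshold < 1")
  }
  if (cfg$utility_weight < 0) err("utility_weight must be nonnegative")
  for (p in c("outcome_prior", "eff_prior", "noeff_prior")) {
    if (length(cfg[[p]]) != 3 || any(cfg[[p]] <= 0)) {
      err(paste(p, "must be a strictly positive concentration triple"))
    }
  }
  if (length(cfg$visit_weeks) < 2 || is.unsorted(cfg$visit_weeks, strictly = TRUE)) {
    err("visit_weeks must be strictly increasing with at least one interim visit")
  }
  if (cfg$n_draws < 1000) err("n_draws must be at least 1000")
  if (cfg$m_imputations < 1) err("m_imputations must be at least 1")
  if (cfg$block_size < 1) err("block_size must be at least 1")
  if (cfg$max_n < cfg$burn_in_n) err("max_n must be at least burn_in_n")
  if (length(cfg$arm_labels) != cfg$n_arms) {
    err("arm_labels must have one label per arm")
  }
  invisible(cfg)
}

#' Read / write a trial configuration as YAML
#'
#' The file stores the fields of [trial_config()] as plain key-value YAML;
#' unspecified fields take the design defaults. Configurations are versioned
#' by content through [config_hash()].
#'
#' @param path File path.
#' @return `read_config()` returns a `trial_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rar_abort(paste("config file not found:", path), class = "rar_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rar_abort(paste("cannot parse config YAML:", conditionMessage(e)),
              class = "rar_config_error")
  })
  known <- names(formals(trial_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rar_abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              class = "rar_config_error")
  }
  do.call(trial_config, raw)
}

#' @rdname read_config
#' @param config A `trial_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  # precision 17 makes doubles (e.g. the 1/3 prior) round-trip exactly,
  # so a written-and-reread config keeps the same content hash
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical JSON serialization (keys in fixed field order, full
#' numeric precision). Identical configurations hash identically regardless
#' of how they were constructed, making the hash a stable identifier for
#' audit logs and run manifests.
#'
#' @param config A `trial_config`.
#' @return Length-1 character MD5 digest.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  json <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Trial configuration:", x$n_arms, "arms, burn-in", x$burn_in_n,
      "(+", x$burn_in_spare, "spare), max N", x$max_n, "\n")
  cat("  interims every", x$adaptation_interval_weeks,
      "weeks; success >=", x$success_threshold,
      "; loser <=", x$loser_threshold, "\n")
  cat("  utility weight", x$utility_weight,
      "; visits at weeks", paste(x$visit_weeks, collapse = ", "), "\n")
  invisible(x)
}
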