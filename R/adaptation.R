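#' Information measure for adaptive allocation
#'
#' `I = sqrt(p_max * var_utility / (n + 1))`. Allocation proportional to
#' this measure favors arms likely to be best while still directing patients
#' to arms whose utility is uncertain: among arms with equal `p_max` and
#' posterior variance, the one with fewer patients (higher standard error)
#' receives more. Vectorized over arms.
#'
#' @param p_max Posterior probability (per arm) of being the best arm.
#' @param var_utility Posterior variance of the arm utility.
#' @param n Number of patients enrolled on the arm.
#' @return Nonnegative numeric vector.
#' @export
information_measure <- function(p_max, var_utility, n) {
  if (any(p_max < 0 | p_max > 1)) rar_abort("p_max must lie in [0, 1]")
  if (any(var_utility < 0)) rar_abort("var_utility must be nonnegative")
  if (any(n < 0)) rar_abort("n must be nonnegative")
  sqrt(p_max * var_utility / (n + 1))
}

#' Allocation probabilities from an interim summary
#'
#' Sets `q_a` proportional to each non-loser arm's information measure and
#' exactly zero on loser arms. If every non-loser arm has zero information
#' (degenerate posteriors) the non-losers share equal probability. An
#' all-loser input leaves no arm to allocate and is an error.
#'
#' @param summary A [posterior_summary()].
#' @param losers Integer vector of permanently closed arms.
#' @return Object of class `randomization_vector`: list with `q` (per-arm
#'   probabilities summing to 1) and `losers`.
#' @export
randomization_vector <- function(summary, losers = integer(0)) {
  A <- nrow(summary)
  losers <- sort(unique(as.integer(losers)))
  if (length(setdiff(seq_len(A), losers)) == 0) {
    rar_abort("every arm is a loser: allocation is undefined",
              class = "rar_input_error")
  }
  info <- information_measure(summary$p_max, summary$var_utility, summary$n_enrolled)
  info[losers] <- 0
  s <- sum(info)
  if (s == 0) {
    open <- setdiff(seq_len(A), losers)
    q <- numeric(A)
    q[open] <- 1 / length(open)
  } else {
    q <- info / s
  }
  structure(list(q = q, losers = losers), class = "randomization_vector")
}

#' @export
print.randomization_vector <- function(x, ...) {
  cat("Randomization probabilities:",
      paste(sprintf("%.3f", x$q), collapse = " "), "\n")
  if (length(x$losers) > 0) {
    cat("Closed (loser) arms:", paste(x$losers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Early/final success rule
#'
#' The trial succeeds when the most likely best arm reaches the success
#' threshold on its posterior probability of being best ("at least" — the
#' threshold is inclusive).
#'
#' @inheritParams randomization_vector
#' @param threshold Success threshold on `p_max`.
#' @return Winning arm index, or `NULL` when no arm qualifies.
#' @export
check_success <- function(summary, threshold = 0.925) {
  best <- which.max(summary$p_max)
  if (summary$p_max[best] >= threshold) best else NULL
}

#' Loser rule
#'
#' Any arm whose posterior probability of being best is no more than the
#' threshold (inclusive) is designated a loser and permanently closed:
#' loser status is never revoked even if the arm's posterior later recovers.
#'
#' @inheritParams check_success
#' @param threshold Loser threshold on `p_max`.
#' @param existing_losers Loser set carried over from earlier interims.
#' @return Updated (non-decreasing) integer loser set.
#' @export
check_losers <- function(summary, threshold = 0.01, existing_losers = integer(0)) {
  sort(unique(c(as.integer(existing_losers), which(summary$p_max <= threshold))))
}

new_allocation_table <- function(slot_index, arm, assigned, stratum, n_arms) {
  structure(
    data.frame(slot_index = as.integer(slot_index), arm = as.integer(arm),
               assigned = as.logical(assigned),
               stratum = as.character(stratum), stringsAsFactors = FALSE),
    class = c("allocation_table", "data.frame"), n_arms = as.integer(n_arms)
  )
}

#' Generate the initial (burn-in) allocation table
#'
#' The first `burn_in_n` slots contain exactly `burn_in_n / n_arms` slots
#' per arm in uniformly random order — the burn-in phase of fixed equal
#' allocation. A further `burn_in_spare` slots, also balanced across arms
#' and randomly ordered, follow as a buffer so the next patient can still be
#' randomized while an adapted table is being prepared. All slots start
#' unassigned. Under the default configuration the table has 100 slots:
#' 80 burn-in (20 per arm) plus 20 spare.
#'
#' @param config A [trial_config()].
#' @param seed Optional integer seed; the same seed reproduces the table.
#' @param stratum Optional stratum label applied to every slot (stratified
#'   designs keep one table section per stratum; the default is
#'   unstratified).
#' @return An `allocation_table` (data frame with columns `slot_index`,
#'   `arm`, `assigned`, `stratum`).
#' @export
make_burnin_table <- function(config = trial_config(), seed = NULL,
                              stratum = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  A <- config$n_arms
  burn <- sample(rep(seq_len(A), each = config$burn_in_n / A))
  spare <- if (config$burn_in_spare > 0) {
    sample(rep(seq_len(A), each = config$burn_in_spare / A))
  } else integer(0)
  arms <- c(burn, spare)
  new_allocation_table(seq_along(arms), arms, FALSE, stratum, A)
}

#' Adapt the allocation table after an interim analysis
#'
#' Deletes every unassigned slot, then appends `block_size` new unassigned
#' slots whose arms are drawn independently with the current allocation
#' probabilities (sampling with replacement, so appended-block frequencies
#' converge to `q` rather than being forced). Assigned slots are untouched
#' and keep their original slot indices; new slots continue the numbering.
#'
#' @param table An `allocation_table`.
#' @param q A [randomization_vector()] or bare probability vector.
#' @param block_size Number of slots to append.
#' @param seed Optional integer seed.
#' @param stratum Stratum label for the appended slots.
#' @return The updated `allocation_table`.
#' @export
adapt_table <- function(table, q, block_size = 100L, seed = NULL,
                        stratum = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(q, "randomization_vector")) q <- q$q
  A <- attr(table, "n_arms") %||% max(table$arm)
  if (length(q) != A) rar_abort("q must have one probability per arm")
  if (any(q < 0)) rar_abort("q must be nonnegative")
  if (sum(q) <= 0) rar_abort("q contains only zeros: no arm can be allocated")
  if (block_size < 1) rar_abort("block_size must be at least 1")
  kept <- table[table$assigned, , drop = FALSE]
  start <- if (nrow(table) > 0) max(table$slot_index) else 0L
  new_arms <- sample.int(A, size = block_size, replace = TRUE, prob = q)
  out <- rbind(
    as.data.frame(kept),
    data.frame(slot_index = start + seq_len(block_size), arm = new_arms,
               assigned = FALSE, stratum = as.character(stratum),
               stringsAsFactors = FALSE)
  )
  new_allocation_table(out$slot_index, out$arm, out$assigned, out$stratum, A)
}

#' Assign the next available slot
#'
#' Marks the first unassigned slot (within the stratum, if given) assigned
#' and returns its arm — the next-available-slot discipline of a central
#' randomization table. An exhausted table is an explicit error so trial
#' staff are signalled rather than silently unserved; the spare-slot buffer
#' in [make_burnin_table()] exists to make this rare.
#'
#' @param table An `allocation_table`.
#' @param stratum Optional stratum label to assign within.
#' @return List with `arm` (integer) and `table` (updated table).
#' @export
assign_next <- function(table, stratum = NULL) {
  open <- !table$assigned
  if (!is.null(stratum)) open <- open & table$stratum %in% stratum
  idx <- which(open)
  if (length(idx) == 0) {
    rar_abort("allocation table exhausted: no unassigned slot available",
              class = "rar_exhausted_error")
  }
  table$assigned[idx[1]] <- TRUE
  list(arm = table$arm[idx[1]], table = table)
}

# Batch form used by the simulator: assigns the next n slots in one pass.
assign_block <- function(table, n) {
  idx <- which(!table$assigned)
  if (length(idx) < n) {
    rar_abort(sprintf("allocation table exhausted: %d slots needed, %d available",
                      n, length(idx)), class = "rar_exhausted_error")
  }
  take <- idx[seq_len(n)]
  table$assigned[take] <- TRUE
  list(arms = table$arm[take], table = table)
}

#' @export
print.allocation_table <- function(x, ...) {
  cat("Allocation table:", nrow(x), "slots (",
      sum(x$assigned), "assigned,", sum(!x$assigned), "open)\n")
  print(table(arm = x$arm, assigned = x$assigned))
  invisible(x)
}
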