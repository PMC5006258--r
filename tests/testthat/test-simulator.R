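test_that("degenerate scenarios produce deterministic trajectories with absorbing quit", {
  all_quit <- scenario_truth(p4 = c(1, 0, 0), t_eff = c(0, 1, 0),
                             t_noeff = c(0, 0, 1), n_arms = 2L)
  recs <- generate_patients(all_quit, rep(1:2, 25), seed = 1)
  expect_true(all(recs$out_4 == "quit" & recs$out_8 == "quit" & recs$out_12 == "quit"))

  all_eff <- scenario_truth(p4 = c(0, 1, 0), t_eff = c(0, 1, 0),
                            t_noeff = c(0, 0, 1), n_arms = 2L)
  recs2 <- generate_patients(all_eff, rep(1:2, 25), seed = 2)
  expect_true(all(recs2$out_4 == "eff" & recs2$out_8 == "eff" & recs2$out_12 == "eff"))
})

test_that("generated records respect monotone quit and round-trip through classification", {
  set.seed(12)
  truth <- null_scenario()
  recs <- generate_patients(truth, sample(1:4, 400, replace = TRUE))
  rep <- validate_records(recs)
  expect_identical(nrow(rep[rep$severity == "error", ]), 0L)
  for (w in c(4, 8, 12)) {
    expect_identical(
      classify_outcome(recs$baseline_pain, recs[[paste0("pain_", w)]],
                       recs[[paste0("quit_", w)]]),
      recs[[paste0("out_", w)]]
    )
  }
  # quit absorbing in the raw trajectories
  expect_true(all(recs$out_8[recs$out_4 == "quit"] == "quit"))
  expect_true(all(recs$out_12[recs$out_8 == "quit"] == "quit"))
})

test_that("simulated 12-week frequencies match the closed-form chain marginal", {
  truth <- scenario_truth(p4 = rbind(c(.3, .25, .45), c(.15, .55, .3)),
                          t_eff = c(.05, .8, .15), t_noeff = c(.2, .2, .6),
                          n_arms = 2L)
  n <- 40000
  recs <- generate_patients(truth, rep(1:2, each = n / 2), seed = 14)
  marg <- twelve_week_marginal(truth)
  for (a in 1:2) {
    emp <- tally_counts(recs, a, 12, n_arms = 2) / (n / 2)
    for (k in 1:3) {
      se <- sqrt(marg[a, k] * (1 - marg[a, k]) / (n / 2))
      expect_lt(abs(emp[k] - marg[a, k]), 3.5 * se + 1e-12)
    }
  }
})

test_that("a trial is reproducible from its seed and respects the burn-in split", {
  truth <- null_scenario()
  cfg <- trial_config()
  r1 <- run_trial(truth, cfg, accrual_rate = 4, seed = 99)
  r2 <- run_trial(truth, cfg, accrual_rate = 4, seed = 99)
  expect_identical(r1[setdiff(names(r1), "interim_history")],
                   r2[setdiff(names(r2), "interim_history")])
  expect_equal(r1$interim_history, r2$interim_history)

  first80 <- r1$records[order(r1$records$enrollment_week), ][1:80, ]
  expect_equal(as.vector(table(first80$arm)), rep(20L, 4))
  expect_lte(r1$n_enrolled, cfg$max_n)
  expect_identical(r1$success, !is.null(r1$winner))
})

test_that("an overwhelmingly best arm wins early", {
  truth <- scenario_truth(
    p4 = rbind(c(.9, .05, .05), c(.9, .05, .05), c(.01, .97, .02), c(.9, .05, .05)),
    t_eff = c(.02, .96, .02), t_noeff = c(.3, .1, .6))
  wins <- vapply(1:5, function(s) {
    r <- run_trial(truth, trial_config(), accrual_rate = 4, seed = 1000 + s)
    r$success && r$winner == 3 && r$stopped_early
  }, logical(1))
  expect_true(all(wins))
})

test_that("no interim uses an outcome beyond its calendar week and losers stay closed", {
  truth <- scenario_truth(
    p4 = rbind(c(.30, .25, .45), c(.30, .25, .45), c(.10, .65, .25), c(.30, .25, .45)),
    t_eff = c(.1, .7, .2), t_noeff = c(.1, .2, .7))
  for (s in 1:4) {
    r <- run_trial(truth, trial_config(), accrual_rate = 4, seed = 400 + s)
    for (h in r$interim_history) {
      # counted patients must have their first visit reached by the data cut
      eligible <- sum(r$records$enrollment_week + 4 <= h$week)
      expect_lte(sum(h$summary$n_enrolled), eligible)
    }
    # permanence + no post-loser enrollment
    lsets <- lapply(r$interim_history, `[[`, "losers")
    for (i in seq_along(lsets)[-1]) {
      expect_true(all(lsets[[i - 1]] %in% lsets[[i]]))
    }
    for (i in seq_along(lsets)) {
      for (a in lsets[[i]]) {
        expect_identical(
          sum(r$records$arm == a &
                r$records$enrollment_week > r$interim_history[[i]]$week), 0L)
      }
    }
  }
})

test_that("operating characteristics aggregate shares and sizes coherently", {
  oc <- operating_characteristics(null_scenario(), trial_config(),
                                  accrual_rate = 4, n_reps = 4, seed = 21,
                                  keep_results = TRUE)
  expect_equal(sum(oc$alloc_share), 1, tolerance = 1e-9)
  expect_lte(oc$mean_n, 400)
  expect_identical(length(oc$results), 4L)
  expect_equal(oc$success_rate,
               mean(vapply(oc$results, `[[`, logical(1), "success")))
})
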