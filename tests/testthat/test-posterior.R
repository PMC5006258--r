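test_that("Dirichlet updating is conjugate and additive", {
  expect_equal(update_dirichlet(c(1, 1, 1) / 3, c(0, 0, 0)), c(1, 1, 1) / 3)
  expect_equal(update_dirichlet(c(1, 1, 1) / 3, c(2, 5, 3)),
               c(7 / 3, 16 / 3, 10 / 3))
  expect_equal(update_dirichlet(c(1, 7, 2), c(1, 1, 1)), c(2, 8, 3))
  expect_error(update_dirichlet(c(1, 1, 1), c(-1, 0, 0)), class = "rar_input_error")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(3, 0.1, 5)
    c1 <- rpois(3, 4); c2 <- rpois(3, 4)
    expect_equal(update_dirichlet(update_dirichlet(p, c1), c2),
                 update_dirichlet(p, c1 + c2))
  }
})

test_that("utility spans [0, 1.75] and matches hand evaluation", {
  expect_equal(utility(c(0, 1, 0)), 1.75)
  expect_equal(utility(c(1, 0, 0)), 0)
  expect_equal(utility(c(0.2, 0.5, 0.3)), 1.175)
  expect_equal(utility(c(0.2, 0.5, 0.3), weight = 0), 0.8)
  expect_error(utility(c(0.5, 0.5, 0.5)), class = "rar_input_error")
  m <- rbind(c(0, 1, 0), c(1, 0, 0), c(0.2, 0.5, 0.3))
  expect_equal(utility(m), c(1.75, 0, 1.175))
})

test_that("transition models start at their priors and count stay-on-drug pairs only", {
  cfg <- trial_config()
  prior_only <- fit_transition_models(empty_records(), cfg)
  for (a in 1:4) for (j in 1:2) {
    expect_equal(unname(prior_only$eff[a, j, ]), c(1, 7, 2))
    expect_equal(unname(prior_only$noeff[a, j, ]), c(1, 2, 7))
    expect_equal(sum(prior_only$eff[a, j, ]), 10)   # prior sample size 10
    expect_equal(sum(prior_only$noeff[a, j, ]), 10)
  }

  one <- record_row("p1", 2, NA, "eff", "eff")
  m1 <- fit_transition_models(one, cfg)
  expect_equal(unname(m1$eff["2", "8", ]), c(1, 8, 2))
  expect_equal(unname(m1$eff["2", "4", ]), c(1, 7, 2))   # week 4 unobserved
  expect_equal(unname(m1$noeff["2", "8", ]), c(1, 2, 7))
  expect_equal(unname(m1$eff["1", "8", ]), c(1, 7, 2))   # other arms untouched

  # an interim quit contributes to no transition model
  q <- record_row("p2", 3, "eff", "quit", "quit")
  m2 <- fit_transition_models(q, cfg)
  expect_equal(unname(m2$eff["3", "8", ]), c(1, 7, 2))
  expect_equal(unname(m2$noeff["3", "8", ]), c(1, 2, 7))
  # ... but its week-4 on-drug visit does feed the 4->12 model
  expect_equal(unname(m2$eff["3", "4", ]), c(2, 7, 2))
})

test_that("imputation passes observed finals through and makes interim quit deterministic", {
  cfg <- trial_config()
  complete <- records_with_final_counts(rbind(c(2, 5, 3), c(1, 1, 1),
                                              c(0, 4, 0), c(3, 0, 2)))
  models <- fit_transition_models(complete, cfg)
  for (s in c(1, 99)) {
    set.seed(s)
    counts <- impute_final_counts(complete, models, cfg)
    expect_identical(unname(counts[1, ]), c(2L, 5L, 3L))
    expect_identical(unname(counts[3, ]), c(0L, 4L, 0L))
  }

  quit4 <- record_row("pq", 2, "quit", NA, NA)
  counts <- impute_final_counts(quit4, fit_transition_models(quit4, cfg), cfg)
  expect_identical(unname(counts[2, ]), c(1L, 0L, 0L))

  bare <- record_row("pb", 1, NA, NA, NA)
  expect_error(impute_final_counts(bare, models, cfg), class = "rar_input_error")
})

test_that("posterior-predictive imputation under the prior-only model recovers the 70% rate", {
  cfg <- trial_config()
  one <- record_row("p1", 1, NA, "eff", NA)
  models <- fit_transition_models(one, cfg)  # prior only: Dirichlet(1,7,2)
  set.seed(202)
  n <- 5000
  eff_hits <- 0L
  for (i in seq_len(n)) {
    counts <- impute_final_counts(one, models, cfg)
    eff_hits <- eff_hits + counts[1, "eff"]
  }
  p_hat <- eff_hits / n
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("four arms with identical data give symmetric p_max and prior-only arms are allowed", {
  cfg <- trial_config(n_draws = 40000L, m_imputations = 1L)
  recs <- records_with_final_counts(matrix(rep(c(2, 5, 3), each = 4), 4))
  s <- posterior_summary(recs, cfg, seed = 3)
  expect_equal(sum(s$p_max), 1)
  expect_true(all(abs(s$p_max - 0.25) < 0.02))
  expect_equal(s$n_enrolled, rep(10L, 4))

  # zero records: every arm summarized from its prior, still symmetric
  s0 <- posterior_summary(empty_records(), cfg, seed = 4)
  expect_equal(sum(s0$p_max), 1)
  expect_true(all(abs(s0$p_max - 0.25) < 0.02))
  expect_equal(s0$n_enrolled, rep(0L, 4))
})

test_that("a degenerately separated arm takes essentially all of p_max", {
  cfg <- trial_config(n_draws = 2000L, m_imputations = 1L)
  counts <- rbind(c(0, 800, 0), c(800, 0, 0), c(800, 0, 0), c(800, 0, 0))
  recs <- records_with_final_counts(counts)
  s <- posterior_summary(recs, cfg, seed = 5)
  expect_gt(s$p_max[1], 0.999)
})

test_that("with complete data the summary is invariant to imputation count and seed interplay", {
  recs <- records_with_final_counts(rbind(c(2, 6, 2), c(3, 3, 4),
                                          c(1, 8, 1), c(4, 2, 4)))
  s1 <- posterior_summary(recs, trial_config(n_draws = 4000L, m_imputations = 1L), seed = 7)
  s20 <- posterior_summary(recs, trial_config(n_draws = 4000L, m_imputations = 20L), seed = 7)
  # same posterior regardless of m: compare moments within Monte-Carlo error
  expect_equal(s1$mean_utility, s20$mean_utility, tolerance = 0.02)
  # identical seeds reproduce identical numbers
  s1b <- posterior_summary(recs, trial_config(n_draws = 4000L, m_imputations = 1L), seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s1b))
})

test_that("posterior concentrates on the truth as per-arm n grows", {
  cfg2 <- trial_config(n_arms = 2L, burn_in_n = 40L, burn_in_spare = 10L,
                       max_n = 4000L, n_draws = 20000L, m_imputations = 1L,
                       arm_labels = c("A", "B"))
  truth <- scenario_truth(p4 = rbind(c(.3, .25, .45), c(.1, .6, .3)),
                          t_eff = c(.1, .7, .2), t_noeff = c(.1, .2, .7),
                          n_arms = 2L)
  set.seed(31)
  recs <- generate_patients(truth, rep(1:2, each = 1500))
  s <- posterior_summary(recs, cfg2, seed = 32)
  tru_u <- apply(twelve_week_marginal(truth), 1, utility)
  expect_equal(s$mean_utility, unname(tru_u), tolerance = 0.03)
  expect_gt(s$p_max[2], 0.99)
})
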