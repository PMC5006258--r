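fake_summary <- function(p_max, var_utility, n) {
  structure(data.frame(arm = seq_along(p_max), n_enrolled = n, p_max = p_max,
                       mean_utility = NA_real_, var_utility = var_utility),
            class = c("posterior_summary", "data.frame"))
}

test_that("the information measure follows sqrt(p_max * V / (n + 1))", {
  expect_equal(information_measure(0, 0.5, 10), 0)
  expect_equal(information_measure(0.25, 0.04, 20), sqrt(0.25 * 0.04 / 21))
  expect_equal(round(information_measure(0.25, 0.04, 20), 6), 0.021822)
  # strictly decreasing in n at fixed p_max and variance
  i_seq <- information_measure(0.5, 0.1, 0:50)
  expect_true(all(diff(i_seq) < 0))
  expect_error(information_measure(-0.1, 1, 1), class = "rar_input_error")
  expect_error(information_measure(0.5, -1, 1), class = "rar_input_error")
})

test_that("randomization probabilities normalize, zero out losers, and favor sparse arms", {
  s_sym <- fake_summary(rep(0.25, 4), rep(0.05, 4), rep(20L, 4))
  expect_equal(randomization_vector(s_sym)$q, rep(0.25, 4))

  q_l <- randomization_vector(s_sym, losers = c(1, 4))
  expect_equal(q_l$q, c(0, 0.5, 0.5, 0))
  expect_equal(sum(q_l$q), 1)

  # equal p_max and variance, unequal n: the under-sampled arm gets more
  s_n <- fake_summary(rep(0.25, 4), rep(0.05, 4), c(10L, 20L, 20L, 20L))
  q_n <- randomization_vector(s_n)$q
  expect_gt(q_n[1], q_n[2])
  expect_equal(q_n[2], q_n[3])
  expect_equal(q_n[3], q_n[4])

  # degenerate: all information zero -> equal split over non-losers
  s_0 <- fake_summary(rep(0.25, 4), rep(0, 4), rep(20L, 4))
  expect_equal(randomization_vector(s_0, losers = 2)$q, c(1, 0, 1, 1) / 3)

  expect_error(randomization_vector(s_sym, losers = 1:4),
               class = "rar_input_error")
})

test_that("success and loser thresholds are inclusive and loser status is permanent", {
  expect_identical(check_success(fake_summary(c(0.93, 0.03, 0.02, 0.02), 1:4, 1:4)), 1L)
  expect_null(check_success(fake_summary(c(0.92, 0.04, 0.02, 0.02), 1:4, 1:4)))
  expect_identical(check_success(fake_summary(c(0.925, 0.035, 0.02, 0.02), 1:4, 1:4)), 1L)

  s <- fake_summary(c(0.60, 0.30, 0.095, 0.005), 1:4, 1:4)
  expect_identical(check_losers(s), 4L)
  expect_identical(check_losers(fake_summary(c(0.97, 0.01, 0.01, 0.01), 1:4, 1:4)),
                   c(2L, 3L, 4L))  # exactly 0.01 is a loser
  # permanence: a recovered arm stays closed
  s_rec <- fake_summary(c(0.4, 0.2, 0.2, 0.2), 1:4, 1:4)
  expect_identical(check_losers(s_rec, existing_losers = 4L), 4L)
})

test_that("the burn-in table is exactly balanced, buffered, and seed-reproducible", {
  cfg <- trial_config()
  for (seed in c(1, 77, 123456)) {
    tab <- make_burnin_table(cfg, seed = seed)
    expect_identical(nrow(tab), 100L)
    expect_equal(as.vector(table(tab$arm[1:80])), rep(20L, 4))
    expect_equal(as.vector(table(tab$arm[81:100])), rep(5L, 4))
    expect_false(any(tab$assigned))
    expect_identical(tab$slot_index, 1:100)
  }
  expect_identical(make_burnin_table(cfg, seed = 9),
                   make_burnin_table(cfg, seed = 9))
  expect_error(make_burnin_table(trial_config(burn_in_n = 81L)),
               class = "rar_config_error")
})

test_that("adaptation deletes open slots, freezes assigned ones, and samples from q", {
  cfg <- trial_config()
  tab <- make_burnin_table(cfg, seed = 2)
  for (i in 1:80) tab$assigned[i] <- TRUE
  q <- c(0.1, 0.2, 0.3, 0.4)
  new <- adapt_table(tab, q, block_size = 100, seed = 5)
  expect_identical(nrow(new), 180L)
  expect_identical(as.data.frame(new[1:80, ]), as.data.frame(tab[1:80, ]))
  expect_true(all(new$assigned[1:80]))
  expect_false(any(new$assigned[81:180]))
  expect_identical(new$slot_index[81:180], 101:200)  # numbering continues

  deg <- adapt_table(tab, c(0, 0, 1, 0), block_size = 50, seed = 6)
  expect_true(all(deg$arm[!deg$assigned] == 3))

  expect_error(adapt_table(tab, c(0, 0, 0, 0), block_size = 10),
               class = "rar_input_error")

  # law of large numbers: appended frequencies converge to q
  big <- adapt_table(tab, q, block_size = 20000, seed = 8)
  freq <- tabulate(big$arm[!big$assigned], 4) / 20000
  expect_equal(freq, q, tolerance = 0.03)
})

test_that("assignment walks the table in slot order and signals exhaustion", {
  tab <- new_table <- adapt_table(make_burnin_table(trial_config(), seed = 3),
                                  c(1, 0, 0, 0), block_size = 3, seed = 3)
  first_arms <- tab$arm[!tab$assigned][1:3]
  a1 <- assign_next(new_table); new_table <- a1$table
  a2 <- assign_next(new_table); new_table <- a2$table
  a3 <- assign_next(new_table); new_table <- a3$table
  expect_identical(c(a1$arm, a2$arm, a3$arm), first_arms)
  expect_error(assign_next(new_table), class = "rar_exhausted_error")
})
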