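test_that("a deterministic chain gives every cell the same expression and zero CV", {
  # f -> D with certainty, D absorbing, one unit per step in D
  P <- diag(5); dimnames(P) <- list(microstates(), microstates())
  P["f", "f"] <- 0; P["f", "D"] <- 1
  p <- promoter_params(b_D = 1, b_S = 5)
  sim <- simulate_population(p, n_cells = 20, n_steps = 150, seed = 1, P = P)
  expect_true(all(sim$expression$expression == 150))
  expect_equal(population_noise(sim), 0)
})

test_that("a never-binding promoter yields zero expression and an undefined CV", {
  sim <- simulate_population(promoter_params(affinity = 0, tfiid_recruit = 0),
                             n_cells = 10, n_steps = 50, seed = 1)
  expect_true(all(sim$expression$expression == 0))
  expect_warning(cv <- population_noise(sim), "undefined")
  expect_true(is.na(cv))
})

test_that("expression equals the burst-weighted state occupancy of the history", {
  p <- rand_params()
  sim <- simulate_population(p, n_cells = 50, n_steps = 100, seed = 42)
  H <- state_history(sim)
  expect_equal(sim$expression$expression,
               p$b_S * rowSums(H == 4) + p$b_D * rowSums(H == 5))
  # per-entry accrual counted directly from the same histories
  sim2 <- simulate_population(p, n_cells = 50, n_steps = 100, seed = 42,
                              accrual = "per_entry")
  prev <- cbind(sim2$init_states, H[, -ncol(H)])
  expect_equal(sim2$expression$expression,
               p$b_S * rowSums(H == 4 & prev != 4) +
                 p$b_D * rowSums(H == 5 & prev != 5))
})

test_that("identical seeds give bit-identical simulations", {
  p <- params_tata_box()
  s1 <- simulate_population(p, n_cells = 40, n_steps = 60, seed = 7)
  s2 <- simulate_population(p, n_cells = 40, n_steps = 60, seed = 7)
  expect_identical(s1$histories, s2$histories)
  expect_identical(s1$expression, s2$expression)
  s3 <- simulate_population(p, n_cells = 40, n_steps = 60, seed = 8)
  expect_false(identical(s1$histories, s3$histories))
})

test_that("per-cell streams are stable when the population grows", {
  p <- params_tata_like()
  small <- simulate_population(p, n_cells = 10, n_steps = 80, seed = 3)
  big <- simulate_population(p, n_cells = 25, n_steps = 80, seed = 3)
  expect_identical(small$histories, big$histories[1:10, ])
})

test_that("long-run state frequencies match the stationary distribution", {
  set.seed(5)
  p <- mixing_params()
  P <- build_transition_matrix(p)
  sim <- simulate_population(p, n_cells = 1, n_steps = 50000, seed = 13)
  freq <- tabulate(sim$histories[1, ], nbins = 5) / 50000
  pi_hat <- stationary_distribution(P)
  expect_lt(sum(abs(freq - pi_hat)) / 2,
            3 * sum(stationary_se(P, 50000)))
})

test_that("a non-stochastic matrix is rejected", {
  P <- build_transition_matrix(params_tata_box())
  P[1, 1] <- P[1, 1] + 0.5
  expect_error(simulate_population(params_tata_box(), P = P), "stochastic")
})

test_that("waiting times read complete Off runs between On visits", {
  wt <- waiting_time_stats(c("f", "f", "D", "f", "f", "f", "S"))
  expect_equal(wt$runs$length, 3L)
  expect_equal(wt$mean, 3)
  # censored flanks are kept on request
  wt2 <- waiting_time_stats(c("f", "f", "D", "f", "f", "f", "S"),
                            include_censored = TRUE)
  expect_equal(sort(wt2$runs$length), c(2L, 3L))
  # all-Off history: empty, flagged
  expect_warning(wt3 <- waiting_time_stats(c("f", "T", "M", "f")), "On state")
  expect_equal(wt3$n_runs, 0L)
  expect_true(wt3$no_on)
})

test_that("turnover counts f -> {T, D} bindings per unit time", {
  # locked into D after a single binding
  P <- diag(5); dimnames(P) <- list(microstates(), microstates())
  P["f", "f"] <- 0; P["f", "D"] <- 1
  sim <- simulate_population(params_tata_box(), n_cells = 5, n_steps = 150,
                             seed = 1, P = P)
  expect_equal(as.numeric(turnover_rate(sim)), 1 / 150)
  # strict f <-> T alternation: one binding every two steps
  p <- promoter_params(affinity = 1, tfiid_recruit = 0, engage = 0,
                       t_off = 1)
  sim2 <- simulate_population(p, n_cells = 5, n_steps = 150, seed = 1)
  expect_equal(as.numeric(turnover_rate(sim2)), 0.5)
})

test_that("Mot1p-dominant TATA-box promoters wait longer and turn over faster than TATA-like", {
  waits <- matrix(0, 10, 2)
  turns <- matrix(0, 10, 2)
  for (s in 1:10) {
    st <- simulate_population(params_tata_box(), n_cells = 100, seed = s)
    sl <- simulate_population(params_tata_like(), n_cells = 100, seed = s + 100)
    waits[s, ] <- c(waiting_time_stats(st)$mean, waiting_time_stats(sl)$mean)
    turns[s, ] <- c(turnover_rate(st), turnover_rate(sl))
  }
  expect_true(all(waits[, 1] > waits[, 2]))
  expect_true(all(turns[, 1] > turns[, 2]))
})

test_that("population summaries and histories are exposed tidily", {
  sim <- simulate_population(params_tata_box(), n_cells = 30, seed = 2)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 30)
  gl <- glance(sim)
  expect_equal(gl$cv, population_noise(sim))
  expect_true(all(state_history(sim, "label") %in% microstates()))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_state_history(sim), "ggplot")
})

test_that("population CV matches hand computation", {
  expect_equal(population_noise(c(5, 5, 5, 5)), 0)
  expect_equal(population_noise(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
  expect_error(population_noise(5), "2 cells")
  expect_warning(expect_true(is.na(population_noise(c(0, 0)))), "undefined")
})
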