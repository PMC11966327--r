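test_that("decision tree applies the law of total probability over AKI status", {
  m <- trial_model()
  tree <- run_decision_tree(m, "collaborative_surveillance")
  expect_equal(sum(tree$occupancy), 1, tolerance = 1e-12)
  # P(death at 30 d) = p_aki * P(death | AKI) + (1 - p_aki) * P(death | no AKI),
  # with the no-AKI row renormalized from its printed 0.999 sum
  p_death <- 0.079 * 0.091 + 0.921 * (0.014 / 0.999)
  expect_equal(unname(tree$occupancy["death.post_aki"] + tree$occupancy["death.no_aki"]),
               p_death, tolerance = 1e-12)
  expect_equal(tree$tree_cost, 12.74 + 0.079 * 14000)
})

test_that("decision tree corner cases: no AKI, certain AKI with certain death", {
  m <- trial_model()
  m0 <- set_param(m, "p_aki.assistance", 0)
  tree0 <- run_decision_tree(m0, "assistance")
  d30 <- thirty_day_matrix(m0)
  expect_equal(unname(tree0$occupancy[5:8]), unname(d30["no_aki", ]))
  expect_equal(unname(tree0$occupancy[1:4]), rep(0, 4))
  expect_equal(tree0$tree_cost, 2.69)

  m1 <- set_param(m, "p_aki.assistance", 1)
  for (st in c("normal", "ckd", "esrd")) m1 <- set_param(m1, paste0("p30.aki.", st), 0)
  m1 <- set_param(m1, "p30.aki.death", 1)
  tree1 <- run_decision_tree(m1, "assistance")
  expect_equal(unname(tree1$occupancy["death.post_aki"]), 1)
  expect_equal(tree1$tree_cost, 2.69 + 14000)
})

test_that("a Markov step multiplies by the stratified transition matrix", {
  m <- trial_model()
  # identity annual tables leave any occupancy unchanged
  m_id <- m
  m_id$params$value[grepl("^annual\\.", m_id$params$id)] <- 0
  occ <- run_decision_tree(m_id, "collaborative")$occupancy
  expect_equal(step_markov(occ, m_id), occ, tolerance = 1e-15)

  # a pure post-AKI ESRD cohort decays by the ESRD death probability
  occ2 <- setNames(numeric(8), stratified_states())
  occ2["esrd.post_aki"] <- 1
  out <- step_markov(occ2, m)
  expect_equal(unname(out["esrd.post_aki"]), 0.655)
  expect_equal(unname(out["death.post_aki"]), 0.345)

  # conservation for arbitrary valid occupancies
  set.seed(7)
  for (k in 1:10) {
    w <- rgamma(8, 1); w <- w / sum(w)
    names(w) <- stratified_states()
    expect_equal(sum(step_markov(w, m)), 1, tolerance = 1e-12)
  }
  expect_error(step_markov(w * 2, m), "sum to 1")
})

test_that("degenerate healthy cohort reproduces closed-form discounted QALYs", {
  m0 <- degenerate_model(discount_rate = 0)
  for (acc in c("pre", "post")) {
    ev <- evaluate_strategy(m0, "assistance", accrual = acc)
    expect_equal(ev$total_qaly, 0.85 * 3, tolerance = 1e-12)
    expect_equal(ev$total_cost, 0)
  }
  m3 <- degenerate_model(discount_rate = 0.03)
  ev_post <- evaluate_strategy(m3, "assistance", accrual = "post")
  expect_equal(ev_post$total_qaly, 0.85 * sum(1.03^-(1:3)), tolerance = 1e-12)
  ev_pre <- evaluate_strategy(m3, "assistance", accrual = "pre")
  expect_equal(ev_pre$total_qaly, 0.85 * sum(1.03^-(0:2)), tolerance = 1e-12)
  ev_half <- evaluate_strategy(m3, "assistance", half_cycle = TRUE)
  expect_equal(ev_half$total_qaly,
               0.85 * (sum(1.03^-(0:2)) + sum(1.03^-(1:3))) / 2,
               tolerance = 1e-12)
})

test_that("cohort traces conserve occupancy and death is monotone", {
  for (seed in c(1, 2)) {
    m <- random_model(seed)
    for (s in strategy_names()) {
      ev <- evaluate_strategy(m, s)
      occ <- as.matrix(ev$trace[, stratified_states()])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      dead <- occ[, "death.post_aki"] + occ[, "death.no_aki"]
      expect_true(all(diff(dead) >= -1e-12))
    }
  }
})

test_that("branch decomposition agrees with per-strategy evaluation", {
  m <- trial_model()
  for (acc in c("pre", "post")) {
    for (hc in c(FALSE, TRUE)) {
      fast <- evaluate_strategies(m, accrual = acc, half_cycle = hc)
      for (i in seq_len(nrow(fast))) {
        ev <- evaluate_strategy(m, fast$strategy[i], accrual = acc, half_cycle = hc)
        expect_equal(fast$cost[i], ev$total_cost, tolerance = 1e-9)
        expect_equal(fast$qaly[i], ev$total_qaly, tolerance = 1e-9)
      }
    }
  }
})

test_that("totals respond monotonically to mortality, AKI rate and discounting", {
  m <- trial_model()
  base <- evaluate_strategies(m)
  cs <- function(df) df[df$strategy == "collaborative_surveillance", ]

  worse <- set_param(m, "annual.normal.no_aki.death", 0.1)
  expect_lt(cs(evaluate_strategies(worse))$qaly, cs(base)$qaly)

  riskier <- set_param(m, "p_aki.collaborative_surveillance", 0.12)
  expect_gt(cs(evaluate_strategies(riskier))$cost, cs(base)$cost)
  expect_lt(cs(evaluate_strategies(riskier))$qaly, cs(base)$qaly)

  rates <- c(0, 0.03, 0.08)
  costs <- qalys <- numeric(3)
  for (i in seq_along(rates)) {
    mr <- m; mr$settings$discount_rate <- rates[i]
    res <- cs(evaluate_strategies(mr))
    costs[i] <- res$cost; qalys[i] <- res$qaly
  }
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("microsimulated patients reproduce cohort expectations", {
  m <- trial_model()
  n <- 30000
  rec <- simulate_trial(m, n, seed = 99, arms = "collaborative_surveillance")
  acc <- accrue_records(rec, m)
  coh <- evaluate_strategies(m, "collaborative_surveillance")
  se_cost <- sd(acc$cost) / sqrt(n)
  se_qaly <- sd(acc$qaly) / sqrt(n)
  expect_lt(abs(mean(acc$cost) - coh$cost), 3 * se_cost)
  expect_lt(abs(mean(acc$qaly) - coh$qaly), 3 * se_qaly)
})

test_that("tidy traces expose per-cycle occupancy in long form", {
  ev <- evaluate_strategy(trial_model(), "collaborative")
  td <- tidy_trace(ev)
  expect_setequal(names(td), c("cycle", "state", "aki_history", "occupancy",
                               "disc_cost", "disc_qaly"))
  expect_equal(nrow(td), 8 * 4)
  sums <- tapply(td$occupancy, td$cycle, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
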