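test_that("incremental NMB is exactly linear in a strategy's upfront cost", {
  m <- trial_model()
  delta <- 5
  base <- get_param(m, "cost.upfront.collaborative_surveillance")
  ow <- run_owsa(m, "cost.upfront.collaborative_surveillance",
                 low = base - delta, high = base + delta)
  expect_equal(ow$nmb_low, ow$nmb_base + delta, tolerance = 1e-9)
  expect_equal(ow$nmb_high, ow$nmb_base - delta, tolerance = 1e-9)
  expect_equal(ow$width, 2 * delta, tolerance = 1e-9)

  degenerate <- run_owsa(m, "cost.upfront.assistance", low = 2.69, high = 2.69)
  expect_equal(degenerate$width, 0)
})

test_that("a parameter outside the pair's incremental pathway has zero bar", {
  m <- trial_model()
  ow <- run_owsa(m, "cost.upfront.collaborative",
                 pair = c("collaborative_surveillance", "assistance"))
  expect_equal(ow$width, 0, tolerance = 1e-9)
})

test_that("the preferred strategy is stable across every one-way range", {
  m <- trial_model()
  ow <- owsa_all(m, pair = c("collaborative_surveillance", "assistance"))
  # incremental NMB stays positive at every printed bound: the preferred
  # strategy only flips if a competitor's AKI rate drops below its own
  expect_true(all(ow$nmb_low > 0))
  expect_true(all(ow$nmb_high > 0))
  crossing <- run_owsa(m, "p_aki.collaborative_surveillance",
                       low = 0.064, high = 0.20,
                       pair = c("collaborative_surveillance", "assistance"))
  expect_lt(crossing$nmb_high, 0)
})

test_that("tornado ordering is a stable descending sort on bar width", {
  torn <- tornado(data.frame(parameter = c("a", "b"), low = 0, high = 1,
                             nmb_low = c(0, 0), nmb_high = c(3, 5),
                             nmb_base = 1, width = c(3, 5)))
  expect_equal(torn$parameter, c("b", "a"))
  single <- tornado(data.frame(parameter = "x", low = 0, high = 0,
                               nmb_low = 1, nmb_high = 1, nmb_base = 1, width = 0))
  expect_equal(nrow(single), 1)
  ties <- tornado(data.frame(parameter = c("z", "y"), low = 0, high = 1,
                             nmb_low = 0, nmb_high = 2, nmb_base = 1,
                             width = c(2, 2)))
  expect_equal(ties$parameter, c("y", "z"))
})

test_that("downstream disease costs out-rank upfront intervention costs", {
  m <- trial_model()
  torn <- tornado(owsa_all(m, pair = c("collaborative_surveillance", "assistance")))
  rank_of <- function(id) match(id, torn$parameter)
  disease_costs <- c("cost.aki_episode", "cost.annual.ckd", "cost.annual.esrd")
  upfronts <- paste0("cost.upfront.", strategy_names())
  expect_lt(max(rank_of(disease_costs)), min(rank_of(upfronts)))
  # the AKI rates of the compared pair are among the influential parameters
  expect_lt(rank_of("p_aki.collaborative_surveillance"), min(rank_of(upfronts)))
  expect_lt(rank_of("p_aki.assistance"), min(rank_of(upfronts)))
})

test_that("a degenerate PSA reproduces the base case in every iteration", {
  m <- point_mass_model()
  psa <- run_psa(m, n = 20, seed = 5)
  base <- evaluate_strategies(m)
  for (s in strategy_names()) {
    d <- psa$draws[psa$draws$strategy == s, ]
    expect_equal(d$cost, rep(base$cost[base$strategy == s], 20))
    expect_equal(d$qaly, rep(base$qaly[base$strategy == s], 20))
  }
  expect_equal(psa_preferred_fraction(psa, "collaborative_surveillance", 1e5), 1)
})

test_that("PSA runs are reproducible from their seed", {
  m <- trial_model()
  a <- run_psa(m, n = 30, seed = 17)
  b <- run_psa(m, n = 30, seed = 17)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(m, n = 30, seed = 18)
  expect_false(identical(a$draws, c_$draws))
})

test_that("acceptability frequencies sum to one at every wtp", {
  m <- trial_model()
  psa <- run_psa(m, n = 100, seed = 3)
  grid <- c(0, 5e4, 1e5)
  cc <- ceac(psa, grid)
  sums <- tapply(cc$acceptability, cc$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(grid)))
  # at wtp 0 NMB reduces to -cost: the cheapest strategy per draw wins
  d0 <- psa$draws
  cheapest <- tapply(seq_len(nrow(d0)), d0$iteration, function(ix) {
    d0$strategy[ix][which.min(d0$cost[ix])]
  })
  frac_cheapest <- mean(cheapest == "collaborative_surveillance")
  expect_equal(cc$acceptability[cc$wtp == 0 &
                                cc$strategy == "collaborative_surveillance"],
               frac_cheapest)
  # the dominant strategy is highly likely to be preferred at policy wtps
  expect_gte(cc$acceptability[cc$wtp == 5e4 &
                              cc$strategy == "collaborative_surveillance"], 0.95)
  expect_gte(cc$acceptability[cc$wtp == 1e5 &
                              cc$strategy == "collaborative_surveillance"], 0.95)
})
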