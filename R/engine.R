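#' Run the decision-tree phase of the model
#'
#' Branches the cohort on 7-day AKI with the strategy's AKI probability, then
#' distributes each branch over the four 30-day health states using the
#' AKI-conditional disposition row. The tree also accrues the upfront
#' per-person intervention cost and the expected AKI episode cost; both land
#' at time zero and are not discounted.
#'
#' @param m An `aki_model`.
#' @param strategy One of [strategy_names()].
#' @return List with `occupancy` (length-8 named vector over
#'   [stratified_states()], summing to 1) and `tree_cost`
#'   (`upfront + p_aki * aki_episode_cost`).
#' @export
#' @examples
#' run_decision_tree(aki_model_improve(), "collaborative_surveillance")
run_decision_tree <- function(m, strategy) {
  strategy <- match.arg(strategy, strategy_names())
  p <- get_param(m, paste0("p_aki.", strategy))
  d30 <- thirty_day_matrix(m)
  occ <- c(p * d30["aki", ], (1 - p) * d30["no_aki", ])
  names(occ) <- stratified_states()
  tree_cost <- get_param(m, paste0("cost.upfront.", strategy)) +
    p * get_param(m, "cost.aki_episode")
  list(occupancy = occ, tree_cost = tree_cost)
}

# 8x8 block-diagonal stratified annual transition matrix; the AKI-history
# label never changes, death is absorbing within its stratum.
stratified_annual_matrix <- function(m) {
  P <- matrix(0, 8, 8, dimnames = list(stratified_states(), stratified_states()))
  P[1:4, 1:4] <- annual_matrix(m, "post_aki")
  P[5:8, 5:8] <- annual_matrix(m, "no_aki")
  P
}

#' Advance a stratified occupancy vector by one yearly cycle
#'
#' @param occupancy Named length-8 vector over [stratified_states()],
#'   summing to 1.
#' @param m An `aki_model` supplying the annual transition tables.
#' @return The post-transition occupancy vector (sums to 1 exactly up to
#'   floating point).
#' @export
step_markov <- function(occupancy, m) {
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must sum to 1, got ", signif(sum(occupancy), 8), call. = FALSE)
  }
  P <- stratified_annual_matrix(m)
  out <- as.vector(occupancy %*% P)
  names(out) <- stratified_states()
  out
}

# per-stratified-state reward vectors
reward_vectors <- function(m) {
  e <- economics(m)
  list(cost = rep(e$annual_state_costs, 2L),
       qaly = rep(e$utilities, 2L))
}

#' Evaluate one strategy: expected discounted cost and QALYs
#'
#' Runs the decision tree, then propagates the 30-day cohort through
#' `horizon_years` yearly Markov cycles, accruing state costs and utilities
#' under a configurable cycle convention:
#'
#' * `accrual = "pre"` (default): each cycle's reward is earned by the
#'   occupancy at the start of the year and discounted at that time point
#'   (`(1+r)^-(t-1)` for cycle `t`); the state a patient is in at day 30
#'   determines the first year's accrual.
#' * `accrual = "post"`: rewards are earned by the end-of-year occupancy,
#'   discounted at `(1+r)^-t`.
#' * `half_cycle = TRUE`: trapezoid (half-cycle) correction — the average of
#'   the two conventions, each half discounted at its own time point.
#'
#' The first 30 days contribute no QALYs (the horizon counts the Markov
#' years only); patients dead at day 30 enter the Markov dead and accrue
#' nothing; 30-day CKD/ESRD states accrue their first annual state cost in
#' the first Markov year, not within the 30-day window.
#'
#' @param m An `aki_model`.
#' @param strategy One of [strategy_names()].
#' @param accrual `"pre"` or `"post"` cycle-reward convention.
#' @param half_cycle Apply half-cycle correction (overrides `accrual`).
#' @return List with `total_cost`, `total_qaly`, and `trace`, a data frame
#'   with one row per cycle 0..H: the eight occupancy columns plus the
#'   cycle's discounted cost and QALY accrual (cycle 0 carries the tree
#'   cost).
#' @export
#' @examples
#' ev <- evaluate_strategy(aki_model_improve(), "collaborative_surveillance")
#' c(ev$total_cost, ev$total_qaly)
evaluate_strategy <- function(m, strategy, accrual = c("pre", "post"),
                              half_cycle = FALSE) {
  accrual <- match.arg(accrual)
  tree <- run_decision_tree(m, strategy)
  e <- economics(m)
  rw <- reward_vectors(m)
  H <- e$horizon_years
  r <- e$discount_rate
  P <- stratified_annual_matrix(m)

  occ <- tree$occupancy
  trace <- matrix(0, H + 1L, 8L, dimnames = list(NULL, stratified_states()))
  trace[1L, ] <- occ
  disc_cost <- c(tree$tree_cost, numeric(H))
  disc_qaly <- numeric(H + 1L)

  for (t in seq_len(H)) {
    pre <- occ
    post <- as.vector(pre %*% P)
    names(post) <- stratified_states()
    d_pre <- (1 + r)^(-(t - 1L))
    d_post <- (1 + r)^(-t)
    if (half_cycle) {
      cost_t <- 0.5 * (d_pre * sum(pre * rw$cost) + d_post * sum(post * rw$cost))
      qaly_t <- 0.5 * (d_pre * sum(pre * rw$qaly) + d_post * sum(post * rw$qaly))
    } else if (accrual == "pre") {
      cost_t <- d_pre * sum(pre * rw$cost)
      qaly_t <- d_pre * sum(pre * rw$qaly)
    } else {
      cost_t <- d_post * sum(post * rw$cost)
      qaly_t <- d_post * sum(post * rw$qaly)
    }
    disc_cost[t + 1L] <- cost_t
    disc_qaly[t + 1L] <- qaly_t
    occ <- post
    trace[t + 1L, ] <- occ
  }
  trace_df <- data.frame(cycle = 0:H, trace, disc_cost = disc_cost,
                         disc_qaly = disc_qaly, check.names = FALSE)
  list(total_cost = sum(disc_cost), total_qaly = sum(disc_qaly),
       trace = trace_df, strategy = strategy,
       convention = list(accrual = accrual, half_cycle = half_cycle))
}

#' Downstream outcomes of the two decision-tree branches
#'
#' Discounted post-30-day Markov cost and QALYs per person, conditional on
#' the 7-day AKI branch (excluding upfront and AKI-episode costs). A
#' strategy's totals are affine in its AKI probability:
#' `total = upfront + p * episode + p * branch_aki + (1 - p) * branch_no_aki`,
#' which [evaluate_strategies()] exploits so all four strategies share two
#' branch evaluations.
#'
#' @inheritParams evaluate_strategy
#' @return List with numeric `cost` and `qaly`, each named by branch
#'   (`aki`, `no_aki`).
#' @export
branch_outcomes <- function(m, accrual = c("pre", "post"), half_cycle = FALSE) {
  accrual <- match.arg(accrual)
  d30 <- thirty_day_matrix(m)
  e <- economics(m)
  rw <- reward_vectors(m)
  H <- e$horizon_years
  r <- e$discount_rate
  P <- stratified_annual_matrix(m)
  one <- function(branch) {
    occ <- numeric(8L)
    names(occ) <- stratified_states()
    block <- if (branch == "aki") 1:4 else 5:8
    occ[block] <- d30[if (branch == "aki") "aki" else "no_aki", ]
    cost <- 0; qaly <- 0
    for (t in seq_len(H)) {
      pre <- occ
      post <- as.vector(pre %*% P)
      d_pre <- (1 + r)^(-(t - 1L)); d_post <- (1 + r)^(-t)
      if (half_cycle) {
        cost <- cost + 0.5 * (d_pre * sum(pre * rw$cost) + d_post * sum(post * rw$cost))
        qaly <- qaly + 0.5 * (d_pre * sum(pre * rw$qaly) + d_post * sum(post * rw$qaly))
      } else if (accrual == "pre") {
        cost <- cost + d_pre * sum(pre * rw$cost)
        qaly <- qaly + d_pre * sum(pre * rw$qaly)
      } else {
        cost <- cost + d_post * sum(post * rw$cost)
        qaly <- qaly + d_post * sum(post * rw$qaly)
      }
      occ <- post
      names(occ) <- stratified_states()
    }
    c(cost = cost, qaly = qaly)
  }
  a <- one("aki"); n <- one("no_aki")
  list(cost = c(aki = a[["cost"]], no_aki = n[["cost"]]),
       qaly = c(aki = a[["qaly"]], no_aki = n[["qaly"]]))
}

#' Evaluate all strategies of a model
#'
#' Uses the branch decomposition of [branch_outcomes()]; agrees with
#' per-strategy [evaluate_strategy()] runs to floating-point accuracy.
#'
#' @inheritParams evaluate_strategy
#' @param strategies_to_run Character vector of strategy names (default all
#'   four).
#' @return Data frame with one row per strategy: `strategy`, `cost`, `qaly`.
#' @export
evaluate_strategies <- function(m, strategies_to_run = strategy_names(),
                                accrual = c("pre", "post"), half_cycle = FALSE) {
  accrual <- match.arg(accrual)
  br <- branch_outcomes(m, accrual = accrual, half_cycle = half_cycle)
  episode <- get_param(m, "cost.aki_episode")
  rows <- lapply(strategies_to_run, function(s) {
    s <- match.arg(s, strategy_names())
    p <- get_param(m, paste0("p_aki.", s))
    upfront <- get_param(m, paste0("cost.upfront.", s))
    data.frame(
      strategy = s,
      cost = upfront + p * episode +
        p * br$cost[["aki"]] + (1 - p) * br$cost[["no_aki"]],
      qaly = p * br$qaly[["aki"]] + (1 - p) * br$qaly[["no_aki"]])
  })
  do.call(rbind, rows)
}

#' Export a cohort trace in tidy (long) form
#'
#' @param ev Result of [evaluate_strategy()].
#' @return Data frame with columns `cycle`, `state`, `aki_history`,
#'   `occupancy`, `disc_cost`, `disc_qaly` (accruals repeated per cycle).
#' @export
tidy_trace <- function(ev) {
  tr <- ev$trace
  long <- do.call(rbind, lapply(stratified_states(), function(col) {
    parts <- strsplit(col, ".", fixed = TRUE)[[1]]
    data.frame(cycle = tr$cycle, state = parts[1], aki_history = parts[2],
               occupancy = tr[[col]], disc_cost = tr$disc_cost,
               disc_qaly = tr$disc_qaly)
  }))
  long[order(long$cycle, long$aki_history, long$state), , drop = FALSE]
}
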