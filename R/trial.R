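#' Simulate patient-level trial data
#'
#' Generates per-arm cohorts with the statistical structure the cohort model
#' assumes: a Bernoulli 7-day AKI event at the arm's AKI probability, a
#' categorical 30-day disposition conditional on AKI status, and yearly
#' categorical state transitions from the AKI-history-stratified annual
#' tables, with death absorbing. Each arm uses its own deterministic
#' substream derived from the master seed and the arm name, so adding or
#' dropping an arm does not perturb the others.
#'
#' @param m An `aki_model` supplying the data-generating probabilities.
#' @param n_per_arm Patients per strategy arm (>= 1).
#' @param seed Master integer seed.
#' @param arms Strategy arms to simulate (default all four).
#' @return Data frame of patient records: `patient_id`, `strategy`,
#'   `aki_at_7d` (logical), `state_30d`, and `year1` ... `yearH` state
#'   columns.
#' @export
#' @examples
#' head(simulate_trial(aki_model_improve(), 100, seed = 1))
simulate_trial <- function(m, n_per_arm, seed = 1L, arms = strategy_names()) {
  stopifnot(n_per_arm >= 1)
  H <- m$settings$horizon_years
  d30 <- thirty_day_matrix(m)
  P <- list(post_aki = annual_matrix(m, "post_aki"),
            no_aki = annual_matrix(m, "no_aki"))
  st <- health_states()
  out <- lapply(arms, function(arm) {
    set.seed(arm_substream_seed(seed, arm))
    p <- get_param(m, paste0("p_aki.", arm))
    aki <- stats::runif(n_per_arm) < p
    state <- character(n_per_arm)
    for (grp in c(TRUE, FALSE)) {
      ix <- which(aki == grp)
      if (length(ix)) {
        row <- d30[if (grp) "aki" else "no_aki", ]
        state[ix] <- sample(st, length(ix), replace = TRUE, prob = row)
      }
    }
    years <- matrix("", n_per_arm, H)
    cur <- state
    for (t in seq_len(H)) {
      nxt <- cur
      for (grp in c(TRUE, FALSE)) {
        Pm <- P[[if (grp) "post_aki" else "no_aki"]]
        for (origin in c("normal", "ckd", "esrd")) {
          ix <- which(aki == grp & cur == origin)
          if (length(ix)) {
            nxt[ix] <- sample(st, length(ix), replace = TRUE, prob = Pm[origin, ])
          }
        }
      }
      years[, t] <- nxt
      cur <- nxt
    }
    df <- data.frame(patient_id = paste0(arm, "_", seq_len(n_per_arm)),
                     strategy = arm, aki_at_7d = aki, state_30d = state)
    for (t in seq_len(H)) df[[paste0("year", t)]] <- years[, t]
    df
  })
  do.call(rbind, out)
}

# name-keyed substream: independent of the set or order of other arms
arm_substream_seed <- function(seed, arm) {
  h <- 0
  for (k in utf8ToInt(arm)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% .Machine$integer.max
}

wald_ci <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
}

year_cols <- function(records) grep("^year[0-9]+$", names(records), value = TRUE)

#' Re-estimate model probabilities from patient records
#'
#' The inverse of [simulate_trial()]: empirical proportions with Wald 95%
#' confidence intervals (`p +/- 1.96 * sqrt(p(1-p)/n)`, truncated to
#' `[0, 1]`) for every AKI probability, 30-day disposition cell, and annual
#' transition cell, pooled over years. Economic inputs are carried over from
#' the template model unchanged.
#'
#' @param records Patient records as produced by [simulate_trial()].
#' @param template An `aki_model` supplying costs, utilities and settings.
#' @return A new validated `aki_model` with re-estimated probability
#'   parameters.
#' @export
estimate_parameters <- function(records, template) {
  m <- template
  yc <- year_cols(records)
  set_est <- function(model, id, p, n) {
    i <- match(id, model$params$id)
    ci <- wald_ci(p, n)
    model$params$value[i] <- p
    model$params$low[i] <- ci[1]
    model$params$high[i] <- ci[2]
    model
  }
  for (arm in strategy_names()) {
    sub <- records[records$strategy == arm, ]
    if (!nrow(sub)) stop("empty cell: no records for arm '", arm, "'", call. = FALSE)
    m <- set_est(m, paste0("p_aki.", arm), mean(sub$aki_at_7d), nrow(sub))
  }
  for (h in c("aki", "no_aki")) {
    sub <- records[records$aki_at_7d == (h == "aki"), ]
    if (!nrow(sub)) stop("empty cell: no records with AKI status '", h, "'", call. = FALSE)
    for (stt in health_states()) {
      m <- set_est(m, paste0("p30.", h, ".", stt),
                   mean(sub$state_30d == stt), nrow(sub))
    }
  }
  # annual transitions pooled over cycle years; the year-1 origin is the
  # 30-day state
  from <- c(records$state_30d,
            if (length(yc) > 1) unlist(records[yc[-length(yc)]], use.names = FALSE))
  to <- unlist(records[yc], use.names = FALSE)
  hist <- rep(ifelse(records$aki_at_7d, "post_aki", "no_aki"), times = length(yc))
  for (origin in c("normal", "ckd", "esrd")) {
    for (hh in c("post_aki", "no_aki")) {
      ix <- which(from == origin & hist == hh)
      if (!length(ix)) {
        stop("empty cell: no transitions out of '", origin, "' (", hh, ")",
             call. = FALSE)
      }
      for (dest in annual_exits(origin)) {
        m <- set_est(m, paste0("annual.", origin, ".", hh, ".", dest),
                     mean(to[ix] == dest), length(ix))
      }
    }
  }
  validate_aki_model(m)
}

#' Pooled 7-day AKI proportion across all arms
#'
#' Empirical proportion of patients with a 7-day AKI, with a Wald 95% CI,
#' pooled over every strategy arm.
#'
#' @param records Patient records with an `aki_at_7d` column.
#' @return A [prob_estimate()].
#' @export
pooled_aki_fraction <- function(records) {
  n <- nrow(records)
  if (!n) stop("empty cell: no patient records", call. = FALSE)
  p <- mean(records$aki_at_7d)
  ci <- wald_ci(p, n)
  prob_estimate(p, ci[1], ci[2], name = "pooled 7-day AKI fraction")
}

#' Write patient records to CSV
#'
#' Header: `patient_id, strategy, aki_at_7d, state_30d, year1..yearH`;
#' `aki_at_7d` is written as TRUE/FALSE, states by their labels.
#'
#' @param records Patient records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read patient records written by [write_trial()]
#' @param path CSV path.
#' @return Patient records data frame.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$aki_at_7d <- as.logical(df$aki_at_7d)
  df
}

#' Patient-level (microsimulation) cost and QALY accrual
#'
#' Accrues each simulated patient's discounted cost and QALYs under exactly
#' the cohort engine's cycle convention, so sample means converge to the
#' cohort-model expectations. Used to cross-check the cohort engine against
#' first-order simulation.
#'
#' @param records Patient records for a single strategy arm.
#' @param m The `aki_model` the records were simulated from.
#' @param accrual,half_cycle Cycle convention toggles (see
#'   [evaluate_strategy()]).
#' @return Data frame with per-patient `cost` and `qaly`.
#' @export
accrue_records <- function(records, m, accrual = c("pre", "post"),
                           half_cycle = FALSE) {
  accrual <- match.arg(accrual)
  stopifnot(length(unique(records$strategy)) == 1)
  arm <- records$strategy[1]
  e <- economics(m)
  H <- e$horizon_years
  r <- e$discount_rate
  upfront <- get_param(m, paste0("cost.upfront.", arm))
  u <- e$utilities
  cst <- e$annual_state_costs
  yc <- year_cols(records)
  states_at <- function(t) {       # state occupied at time t (years post day 30)
    if (t == 0) records$state_30d else records[[yc[t]]]
  }
  cost <- rep(upfront, nrow(records)) + records$aki_at_7d * e$aki_episode_cost
  qaly <- numeric(nrow(records))
  for (t in seq_len(H)) {
    d_pre <- (1 + r)^(-(t - 1))
    d_post <- (1 + r)^(-t)
    pre <- states_at(t - 1)
    post <- states_at(t)
    if (half_cycle) {
      cost <- cost + 0.5 * (d_pre * cst[pre] + d_post * cst[post])
      qaly <- qaly + 0.5 * (d_pre * u[pre] + d_post * u[post])
    } else if (accrual == "pre") {
      cost <- cost + d_pre * cst[pre]
      qaly <- qaly + d_pre * u[pre]
    } else {
      cost <- cost + d_post * cst[post]
      qaly <- qaly + d_post * u[post]
    }
  }
  data.frame(cost = unname(cost), qaly = unname(qaly))
}
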