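#' One-way sensitivity analysis for one parameter
#'
#' Re-evaluates the full model at each bound of the parameter's range (all
#' other parameters at base case) and records the incremental net monetary
#' benefit of a strategy pair at each bound. Thirty-day disposition rows are
#' renormalized proportionally after the edit; an edit that drives an annual
#' row's exits past 1 is an error naming the bound.
#'
#' @param m An `aki_model`.
#' @param id Parameter id (see [param_table()]).
#' @param low,high Bounds to evaluate; default the stored one-way range.
#' @param pair Length-2 character: (strategy, comparator); incremental NMB
#'   is strategy minus comparator.
#' @param wtp Willingness to pay (USD/QALY); default the model's primary
#'   threshold.
#' @param ... Passed to [evaluate_strategy()] (accrual convention toggles).
#' @return One-row data frame: `parameter`, `low`, `high`, `nmb_low`,
#'   `nmb_high`, `nmb_base`, `width`.
#' @export
run_owsa <- function(m, id, low = NULL, high = NULL,
                     pair = c("collaborative_surveillance", "assistance"),
                     wtp = NULL, ...) {
  i <- match(id, m$params$id)
  if (is.na(i)) stop("unknown parameter '", id, "'", call. = FALSE)
  if (is.null(low)) low <- m$params$low[i]
  if (is.null(high)) high <- m$params$high[i]
  if (low > high) stop("'", id, "': low > high", call. = FALSE)
  if (is.null(wtp)) wtp <- m$settings$wtp
  inc_nmb <- function(model) {
    res <- evaluate_strategies(model, strategies_to_run = pair, ...)
    nmb <- compute_nmb(res$qaly, res$cost, wtp)
    nmb[1] - nmb[2]
  }
  at <- function(v) {
    mod <- tryCatch(set_param(m, id, v),
                    error = function(e) stop("bound ", v, " for '", id, "' invalid: ",
                                             conditionMessage(e), call. = FALSE))
    inc_nmb(mod)
  }
  data.frame(parameter = id, low = low, high = high,
             nmb_low = at(low), nmb_high = at(high), nmb_base = inc_nmb(m),
             width = abs(at(high) - at(low)))
}

#' One-way sensitivity analysis over every parameter with a range
#'
#' @inheritParams run_owsa
#' @return Data frame with one [run_owsa()] row per parameter whose one-way
#'   range is non-degenerate.
#' @export
owsa_all <- function(m, pair = c("collaborative_surveillance", "assistance"),
                     wtp = NULL, ...) {
  p <- param_table(m)
  ids <- p$id[p$low < p$high]
  do.call(rbind, lapply(ids, function(id) run_owsa(m, id, pair = pair, wtp = wtp, ...)))
}

#' Order one-way results for a tornado diagram
#'
#' Stable descending sort by bar width (the absolute swing in incremental
#' NMB between the two bounds); ties broken by parameter name.
#'
#' @param owsa Data frame of [run_owsa()] rows.
#' @return The same rows, widest bar first.
#' @export
tornado <- function(owsa) {
  stopifnot(nrow(owsa) >= 1)
  out <- owsa[order(-owsa$width, owsa$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Draw one full parameter set: every uncertain parameter sampled once from
# its fitted distribution; 30-day rows renormalized afterwards (the printed
# inputs are marginal distributions, drawn independently).
draw_param_set <- function(m, dists) {
  v <- vapply(dists, psa_sample, numeric(1), n = 1)
  mod <- m
  mod$params$value <- unname(v[match(mod$params$id, names(v))])
  mod
}

psa_feasible <- function(m) {
  ok <- tryCatch({
    thirty_day_matrix(m)
    annual_matrix(m, "post_aki")
    annual_matrix(m, "no_aki")
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: each iteration draws every uncertain parameter
#' once from its moment-matched beta/gamma distribution (independently —
#' the inputs carry no correlation information), renormalizes the 30-day
#' disposition rows, and evaluates all four strategies. An iteration whose
#' draw is structurally infeasible (negative stay residual) is redrawn, up
#' to 100 times before erroring; redraw counts are recorded.
#'
#' @param m An `aki_model`.
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed; identical seeds give identical runs.
#' @param ... Accrual convention toggles passed to [evaluate_strategies()].
#' @return A `psa_run`: list with `draws` (data frame `iteration`,
#'   `strategy`, `cost`, `qaly`), `n`, `seed`, `redraws`.
#' @export
run_psa <- function(m, n = 1000, seed = 1L, ...) {
  stopifnot(n >= 1)
  dists <- fit_psa_distributions(m)
  set.seed(seed)
  strat <- strategy_names()
  cost <- matrix(NA_real_, n, length(strat), dimnames = list(NULL, strat))
  qaly <- cost
  redraws <- 0L
  for (it in seq_len(n)) {
    tries <- 0L
    repeat {
      mod <- draw_param_set(m, dists)
      if (psa_feasible(mod)) break
      tries <- tries + 1L
      redraws <- redraws + 1L
      if (tries >= 100L) stop("iteration ", it, ": 100 infeasible draws", call. = FALSE)
    }
    res <- evaluate_strategies(mod, ...)
    cost[it, res$strategy] <- res$cost
    qaly[it, res$strategy] <- res$qaly
  }
  draws <- data.frame(iteration = rep(seq_len(n), times = length(strat)),
                      strategy = rep(strat, each = n),
                      cost = as.vector(cost), qaly = as.vector(qaly))
  structure(list(draws = draws, n = n, seed = seed, redraws = redraws),
            class = "psa_run")
}

#' @export
print.psa_run <- function(x, ...) {
  cat(sprintf("PSA run: %d iterations, seed %d, %d redraws\n", x$n, x$seed, x$redraws))
  invisible(x)
}

# winner per iteration at one wtp; ties by lower cost then name
psa_winners <- function(psa, wtp) {
  d <- psa$draws
  nmb <- compute_nmb(d$qaly, d$cost, wtp)
  split_idx <- split(seq_len(nrow(d)), d$iteration)
  vapply(split_idx, function(ix) {
    sub <- d[ix, ]
    ord <- order(-nmb[ix], sub$cost, sub$strategy)
    sub$strategy[ord[1]]
  }, character(1))
}

#' Fraction of PSA iterations in which a strategy is preferred
#'
#' @param psa A `psa_run`.
#' @param strategy Strategy name.
#' @param wtp Willingness to pay (USD/QALY).
#' @return Fraction in `[0, 1]`.
#' @export
psa_preferred_fraction <- function(psa, strategy, wtp) {
  mean(psa_winners(psa, wtp) == strategy)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on the grid, the fraction of PSA
#' iterations in which each strategy attains the maximal net monetary
#' benefit. Frequencies sum to 1 at every grid point.
#'
#' @param psa A `psa_run`.
#' @param wtp_grid Non-empty numeric vector of non-negative WTP values.
#' @return Data frame `wtp`, `strategy`, `acceptability`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1, all(wtp_grid >= 0))
  strat <- strategy_names()
  rows <- lapply(wtp_grid, function(w) {
    win <- psa_winners(psa, w)
    data.frame(wtp = w, strategy = strat,
               acceptability = vapply(strat, function(s) mean(win == s), numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
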