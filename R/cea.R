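#' Net monetary benefit
#'
#' `NMB = effect * wtp - cost`: converts health effects into dollars at the
#' willingness-to-pay threshold so strategies can be ranked on one scale.
#'
#' @param effect QALYs.
#' @param cost Total cost (USD).
#' @param wtp Willingness to pay (USD/QALY).
#' @return Net monetary benefit in USD (vectorized).
#' @export
#' @examples
#' compute_nmb(2.314, 2480.32, 1e5)
compute_nmb <- function(effect, cost, wtp) {
  effect * wtp - cost
}

# Strong dominance: a beats b if cost <= and qaly >= with one strict.
dominates <- function(cost_a, qaly_a, cost_b, qaly_b) {
  cost_a <= cost_b & qaly_a >= qaly_b & (cost_a < cost_b | qaly_a > qaly_b)
}

# Efficiency frontier with extended dominance: strategies ordered by cost;
# a strategy is extendedly dominated when the ICER to the previous frontier
# member exceeds the ICER of a later one.
frontier_members <- function(df) {
  nd <- df[!df$strongly_dominated, , drop = FALSE]
  nd <- nd[order(nd$cost, -nd$qaly, nd$strategy), , drop = FALSE]
  repeat {
    if (nrow(nd) <= 2) break
    icers <- diff(nd$cost) / diff(nd$qaly)
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    nd <- nd[-(bad[1] + 1L), , drop = FALSE]
  }
  nd$strategy
}

#' Build the cost-effectiveness league table
#'
#' Labels each strategy's dominance status, computes increments against a
#' reference strategy (by convention `other - reference`, so a dominated
#' strategy shows positive incremental cost and negative incremental
#' effect), reports ICERs between adjacent members of the efficiency
#' frontier, and attaches the net monetary benefit at the given
#' willingness-to-pay.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly` (from
#'   [evaluate_strategies()]); at least two strategies, no duplicates.
#' @param reference Reference strategy for increments; defaults to the
#'   strategy with maximal NMB (ties broken by lower cost, then name).
#' @param wtp Willingness to pay (USD/QALY).
#' @return A `cea_table` data frame: `strategy`, `cost`, `qaly`,
#'   `inc_cost`, `inc_qaly`, `dominance`, `icer`, `nmb`, sorted by
#'   decreasing NMB.
#' @export
build_cea_table <- function(results, reference = NULL, wtp) {
  stopifnot(is.data.frame(results), nrow(results) >= 2)
  if (anyDuplicated(results$strategy)) {
    stop("duplicate strategy names in results", call. = FALSE)
  }
  df <- results[, c("strategy", "cost", "qaly")]
  n <- nrow(df)
  df$nmb <- compute_nmb(df$qaly, df$cost, wtp)
  df$strongly_dominated <- vapply(seq_len(n), function(i) {
    any(dominates(df$cost[-i], df$qaly[-i], df$cost[i], df$qaly[i]))
  }, logical(1))
  front <- frontier_members(df)
  df$dominance <- ifelse(df$strongly_dominated, "dominated",
                         ifelse(df$strategy %in% front, "non-dominated",
                                "extendedly dominated"))
  is_best <- vapply(seq_len(n), function(i) {
    all(dominates(df$cost[i], df$qaly[i], df$cost[-i], df$qaly[-i]))
  }, logical(1))
  df$dominance[is_best] <- "dominant"

  if (is.null(reference)) {
    ord <- order(-df$nmb, df$cost, df$strategy)
    reference <- df$strategy[ord[1]]
  }
  ri <- match(reference, df$strategy)
  if (is.na(ri)) stop("reference strategy '", reference, "' not in results", call. = FALSE)
  df$inc_cost <- df$cost - df$cost[ri]
  df$inc_qaly <- df$qaly - df$qaly[ri]

  # ICERs along the frontier, between adjacent non-dominated strategies
  df$icer <- NA_real_
  fr <- df[df$strategy %in% front, , drop = FALSE]
  fr <- fr[order(fr$cost, fr$qaly), , drop = FALSE]
  if (nrow(fr) > 1) {
    for (k in 2:nrow(fr)) {
      i <- match(fr$strategy[k], df$strategy)
      dq <- fr$qaly[k] - fr$qaly[k - 1]
      df$icer[i] <- if (dq == 0) Inf else (fr$cost[k] - fr$cost[k - 1]) / dq
    }
  }
  out <- df[order(-df$nmb, df$cost, df$strategy),
            c("strategy", "cost", "qaly", "inc_cost", "inc_qaly",
              "dominance", "icer", "nmb")]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_table", class(out))
  out
}

#' @export
print.cea_table <- function(x, ...) {
  cat(sprintf("Cost-effectiveness league table (WTP $%s/QALY; increments vs %s)\n",
              format(attr(x, "wtp"), big.mark = ",", scientific = FALSE),
              attr(x, "reference")))
  disp <- data.frame(
    strategy = x$strategy,
    dominance = x$dominance,
    cost = sprintf("%.2f", x$cost),
    inc_cost = ifelse(x$inc_cost == 0, "NA", sprintf("%.2f", x$inc_cost)),
    qaly = sprintf("%.3f", x$qaly),
    inc_qaly = ifelse(x$inc_qaly == 0, "NA", sprintf("%.3f", x$inc_qaly)),
    icer = ifelse(is.na(x$icer), "NA", sprintf("%.0f", x$icer)),
    nmb = sprintf("%.2f", x$nmb))
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Preferred strategy at a willingness-to-pay
#'
#' Maximal NMB; ties broken by lower cost, then strategy name.
#'
#' @inheritParams build_cea_table
#' @return Strategy name (length-1 character).
#' @export
preferred_strategy <- function(results, wtp) {
  nmb <- compute_nmb(results$qaly, results$cost, wtp)
  ord <- order(-nmb, results$cost, results$strategy)
  results$strategy[ord[1]]
}
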