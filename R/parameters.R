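#' Probability estimate with a 95% confidence interval
#'
#' Bundles a point probability with its interval bounds and checks ordering
#' and range at construction time, so invalid inputs fail loudly with the
#' offending parameter named.
#'
#' @param mean Point estimate, a probability in `[0, 1]`.
#' @param ci_low,ci_high Interval bounds; must satisfy
#'   `0 <= ci_low <= mean <= ci_high <= 1`.
#' @param name Parameter name used in error messages.
#' @return An object of class `prob_estimate`.
#' @export
#' @examples
#' prob_estimate(0.079, 0.064, 0.095, "p_aki.collaborative_surveillance")
prob_estimate <- function(mean, ci_low = mean, ci_high = mean, name = "probability") {
  vals <- c(ci_low, mean, ci_high)
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("'", name, "': non-numeric or missing value", call. = FALSE)
  }
  if (vals[1] < 0 || vals[3] > 1 || is.unsorted(vals)) {
    stop("'", name, "': requires 0 <= ci_low <= mean <= ci_high <= 1, got (",
         paste(signif(c(mean, ci_low, ci_high), 6), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(mean = mean, ci_low = ci_low, ci_high = ci_high, name = name),
            class = "prob_estimate")
}

#' @export
print.prob_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g (95%% CI %.4g-%.4g)\n", x$name, x$mean, x$ci_low, x$ci_high))
  invisible(x)
}

# Registry of every uncertain model parameter: id, sampling family, and the
# structural slot it feeds. Probabilities and utilities get beta
# distributions in the PSA, costs get gamma; a parameter whose bounds
# coincide collapses to a point mass.
canonical_params <- function() {
  strat <- strategy_names()
  rows <- list()
  add <- function(id, family) rows[[length(rows) + 1L]] <<- data.frame(id = id, family = family)
  for (s in strat) add(paste0("p_aki.", s), "beta")
  for (h in c("aki", "no_aki")) {
    for (st in health_states()) add(paste0("p30.", h, ".", st), "beta")
  }
  for (origin in c("normal", "ckd", "esrd")) {
    for (h in c("post_aki", "no_aki")) {
      for (dest in annual_exits(origin)) {
        add(paste0("annual.", origin, ".", h, ".", dest), "beta")
      }
    }
  }
  for (st in c("normal", "ckd", "esrd")) add(paste0("utility.", st), "beta")
  for (s in strat) add(paste0("cost.upfront.", s), "gamma")
  add("cost.aki_episode", "gamma")
  add("cost.annual.ckd", "gamma")
  add("cost.annual.esrd", "gamma")
  do.call(rbind, rows)
}

#' Assemble an AKI cost-effectiveness model bundle
#'
#' Low-level constructor: most users load a model file with [load_model()] or
#' start from the bundled IMPROVE AKI trial inputs via [aki_model_improve()].
#'
#' @param params Data frame with columns `id`, `value`, `low`, `high`,
#'   `family` covering every canonical parameter exactly once (see
#'   [param_table()] for the expected ids).
#' @param settings List with `discount_rate` (fraction/year),
#'   `horizon_years` (integer >= 1), `wtp` and `wtp_secondary` (USD/QALY).
#' @param meta Optional list of provenance fields (e.g. `currency_year`).
#' @return Validated object of class `aki_model`.
#' @export
aki_model <- function(params, settings, meta = list()) {
  m <- structure(list(params = params, settings = settings, meta = meta),
                 class = "aki_model")
  validate_aki_model(m)
}

#' @export
print.aki_model <- function(x, ...) {
  cat("AKI prevention cost-effectiveness model\n")
  cat(sprintf("  %d parameters, %d strategies\n",
              nrow(x$params), length(strategy_names())))
  cat(sprintf("  horizon %d y, discount %.1f%%/y, WTP $%s/QALY\n",
              x$settings$horizon_years, 100 * x$settings$discount_rate,
              format(x$settings$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Validate a model bundle
#'
#' Checks that every canonical parameter is present exactly once, that all
#' probabilities and their bounds lie in `[0, 1]` in the right order, that
#' each 30-day disposition row sums to 1 within 0.005 (rows are renormalized
#' proportionally at use; a larger deviation is an error), that annual exit
#' probabilities leave a non-negative stay residual, and that economic
#' settings are admissible.
#'
#' @param m An `aki_model`.
#' @return `m`, invisibly, if valid; otherwise an error naming the offending
#'   parameter.
#' @export
validate_aki_model <- function(m) {
  stopifnot(inherits(m, "aki_model"))
  p <- m$params
  need <- c("id", "value", "low", "high", "family")
  if (!all(need %in% names(p))) {
    stop("params must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  reg <- canonical_params()
  dup <- p$id[duplicated(p$id)]
  if (length(dup)) stop("duplicated parameter(s): ", paste(dup, collapse = ", "), call. = FALSE)
  missing <- setdiff(reg$id, p$id)
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(p$id, reg$id)
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(p))) {
    id <- p$id[i]
    fam <- reg$family[match(id, reg$id)]
    if (fam == "beta") {
      prob_estimate(p$value[i], p$low[i], p$high[i], name = id)
    } else {
      if (p$value[i] < 0) stop("'", id, "': cost must be >= 0", call. = FALSE)
      if (p$low[i] > p$value[i] || p$high[i] < p$value[i]) {
        stop("'", id, "': range [", p$low[i], ", ", p$high[i],
             "] does not bracket base value ", p$value[i], call. = FALSE)
      }
    }
  }
  u <- p$value[grepl("^utility\\.", p$id)]
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  # 30-day rows: conservation within rounding tolerance
  for (h in c("aki", "no_aki")) {
    row <- p$value[match(paste0("p30.", h, ".", health_states()), p$id)]
    if (abs(sum(row) - 1) > 0.005) {
      stop("30-day disposition row '", h, "' sums to ", signif(sum(row), 6),
           "; conservation violated beyond tolerance 0.005", call. = FALSE)
    }
  }
  # annual rows: non-negative stay residual
  for (origin in c("normal", "ckd", "esrd")) {
    for (h in c("post_aki", "no_aki")) {
      ids <- paste0("annual.", origin, ".", h, ".", annual_exits(origin))
      s <- sum(p$value[match(ids, p$id)])
      if (s > 1) {
        stop("annual exits from '", origin, "' (", h, ") sum to ",
             signif(s, 6), " > 1: negative stay residual", call. = FALSE)
      }
    }
  }
  s <- m$settings
  if (is.null(s$discount_rate) || s$discount_rate < 0) {
    stop("discount_rate must be >= 0", call. = FALSE)
  }
  if (is.null(s$horizon_years) || s$horizon_years < 1) {
    stop("horizon_years must be >= 1", call. = FALSE)
  }
  if (is.null(s$wtp) || s$wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  invisible(m)
}

#' Parameter table of a model
#'
#' @param m An `aki_model`.
#' @return Data frame with one row per uncertain parameter: `id`, base-case
#'   `value`, one-way range `low`/`high`, and PSA `family`.
#' @export
param_table <- function(m) {
  stopifnot(inherits(m, "aki_model"))
  m$params
}

#' Read a single parameter value
#' @param m An `aki_model`.
#' @param id Parameter id (see [param_table()]).
#' @return The base-case value.
#' @export
get_param <- function(m, id) {
  i <- match(id, m$params$id)
  if (is.na(i)) stop("unknown parameter '", id, "'", call. = FALSE)
  m$params$value[i]
}

#' Set a single parameter value
#'
#' Returns a modified copy; the stored one-way range is left untouched so a
#' sensitivity loop can restore the base case. Structural validity (row
#' conservation, stay residuals) is re-checked.
#'
#' @inheritParams get_param
#' @param value New base-case value.
#' @param revalidate Set `FALSE` to skip full validation (used internally by
#'   samplers that renormalize afterwards).
#' @return Modified `aki_model`.
#' @export
set_param <- function(m, id, value, revalidate = TRUE) {
  i <- match(id, m$params$id)
  if (is.na(i)) stop("unknown parameter '", id, "'", call. = FALSE)
  m$params$value[i] <- value
  if (revalidate) check_structural(m, id)
  m
}

# Cheap structural re-check after a single-parameter edit: bounds, the
# affected annual stay residual. Thirty-day rows are renormalized at use so
# only negativity matters there.
check_structural <- function(m, id) {
  v <- get_param(m, id)
  fam <- canonical_params()$family[match(id, canonical_params()$id)]
  if (fam == "beta" && (v < 0 || v > 1)) {
    stop("'", id, "': probability ", v, " outside [0, 1]", call. = FALSE)
  }
  if (fam == "gamma" && v < 0) stop("'", id, "': cost must be >= 0", call. = FALSE)
  if (grepl("^annual\\.", id)) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    origin <- parts[2]; h <- parts[3]
    ids <- paste0("annual.", origin, ".", h, ".", annual_exits(origin))
    s <- sum(m$params$value[match(ids, m$params$id)])
    if (s > 1) {
      stop("setting '", id, "' = ", v, " drives annual exits from '",
           origin, "' (", h, ") to ", signif(s, 6), " > 1", call. = FALSE)
    }
  }
  invisible(m)
}

# ---- structural views ------------------------------------------------------

#' Thirty-day disposition matrix
#'
#' Rows are 7-day AKI status (`aki`, `no_aki`), columns the four health
#' states at day 30. Rows are renormalized proportionally to sum to exactly
#' 1 (printed inputs can carry rounding residue of up to 0.005).
#'
#' @param m An `aki_model`.
#' @return 2x4 row-stochastic matrix.
#' @export
thirty_day_matrix <- function(m) {
  out <- matrix(0, 2, 4, dimnames = list(c("aki", "no_aki"), health_states()))
  for (h in rownames(out)) {
    row <- m$params$value[match(paste0("p30.", h, ".", health_states()), m$params$id)]
    if (any(row < 0)) stop("negative 30-day probability in row '", h, "'", call. = FALSE)
    out[h, ] <- row / sum(row)
  }
  out
}

#' Annual transition matrix for one AKI-history stratum
#'
#' Builds the 4x4 yearly transition matrix over (normal, CKD, ESRD, death)
#' for patients with (`"post_aki"`) or without (`"no_aki"`) a 7-day AKI.
#' Stay probabilities are the residual after the permitted exits; death is
#' absorbing and backward transitions are structurally zero.
#'
#' @param m An `aki_model`.
#' @param history `"post_aki"` or `"no_aki"`.
#' @return 4x4 row-stochastic matrix.
#' @export
annual_matrix <- function(m, history = c("post_aki", "no_aki")) {
  history <- match.arg(history)
  st <- health_states()
  P <- matrix(0, 4, 4, dimnames = list(st, st))
  for (origin in c("normal", "ckd", "esrd")) {
    dests <- annual_exits(origin)
    pr <- m$params$value[match(paste0("annual.", origin, ".", history, ".", dests),
                               m$params$id)]
    if (any(pr < 0)) stop("negative annual probability from '", origin, "'", call. = FALSE)
    stay <- 1 - sum(pr)
    if (stay < 0) {
      stop("annual exits from '", origin, "' (", history, ") exceed 1", call. = FALSE)
    }
    P[origin, dests] <- pr
    P[origin, origin] <- stay
  }
  P["death", "death"] <- 1
  P
}

#' Strategy specifications
#'
#' @param m An `aki_model`.
#' @return Data frame with one row per implementation strategy: 7-day AKI
#'   probability with CI and per-person upfront cost with one-way range
#'   (2020 USD).
#' @export
strategies <- function(m) {
  s <- strategy_names()
  pick <- function(prefix, col) {
    i <- match(paste0(prefix, s), m$params$id)
    m$params[[col]][i]
  }
  data.frame(strategy = s,
             p_aki = pick("p_aki.", "value"),
             p_aki_low = pick("p_aki.", "low"),
             p_aki_high = pick("p_aki.", "high"),
             upfront = pick("cost.upfront.", "value"),
             upfront_low = pick("cost.upfront.", "low"),
             upfront_high = pick("cost.upfront.", "high"))
}

#' Economic inputs of a model
#'
#' @param m An `aki_model`.
#' @return List with per-state annual utilities (death fixed at 0), the AKI
#'   episode cost, annual CKD/ESRD state costs (normal and death cost 0),
#'   discount rate, horizon and willingness-to-pay thresholds. All money in
#'   2020 USD.
#' @export
economics <- function(m) {
  st <- health_states()
  u <- c(m$params$value[match(paste0("utility.", c("normal", "ckd", "esrd")), m$params$id)], 0)
  names(u) <- st
  costs <- c(0,
             m$params$value[match("cost.annual.ckd", m$params$id)],
             m$params$value[match("cost.annual.esrd", m$params$id)],
             0)
  names(costs) <- st
  list(utilities = u,
       annual_state_costs = costs,
       aki_episode_cost = m$params$value[match("cost.aki_episode", m$params$id)],
       discount_rate = m$settings$discount_rate,
       horizon_years = m$settings$horizon_years,
       wtp = m$settings$wtp,
       wtp_secondary = m$settings$wtp_secondary)
}

#' Transition tables of a model
#'
#' @param m An `aki_model`.
#' @return List with the 2x4 `thirty_day` disposition matrix and the two
#'   4x4 `annual` matrices (one per AKI-history stratum).
#' @export
transition_tables <- function(m) {
  list(thirty_day = thirty_day_matrix(m),
       annual = list(post_aki = annual_matrix(m, "post_aki"),
                     no_aki = annual_matrix(m, "no_aki")))
}

# ---- file I/O --------------------------------------------------------------

pe_from_node <- function(node, id, scale) {
  if (is.null(node)) stop("missing parameter '", id, "' in model file", call. = FALSE)
  if (is.numeric(node) && length(node) == 1) {
    v <- node * scale
    return(c(value = v, low = v, high = v))
  }
  mean <- node$mean
  if (is.null(mean)) stop("parameter '", id, "': no 'mean' field", call. = FALSE)
  lo <- if (!is.null(node$ci)) node$ci[[1]] else node$low
  hi <- if (!is.null(node$ci)) node$ci[[2]] else node$high
  if (is.null(lo)) lo <- mean
  if (is.null(hi)) hi <- mean
  c(value = mean * scale, low = lo * scale, high = hi * scale)
}

#' Load a declarative model file
#'
#' Reads a YAML model file (see the bundled
#' `system.file("extdata", "improve_aki.yaml", package = "akicea")` for the
#' canonical layout), converts percentages to fractions when the file
#' declares `units: percent`, and validates every structural invariant.
#'
#' @param path Path to a YAML model file.
#' @return Validated `aki_model`.
#' @export
#' @examples
#' m <- load_model(system.file("extdata", "improve_aki.yaml", package = "akicea"))
#' strategies(m)
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  scale <- if (identical(doc$units, "percent")) 0.01 else 1
  reg <- canonical_params()
  rows <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    node <- switch(parts[1],
      p_aki = doc$strategies[[parts[2]]]$p_aki,
      p30 = doc$thirty_day[[parts[2]]][[parts[3]]],
      annual = doc$annual[[paste(parts[2], parts[3], sep = "_")]][[parts[4]]],
      utility = doc$utilities[[parts[2]]],
      cost = if (parts[2] == "upfront") doc$strategies[[parts[3]]]$upfront_cost
             else if (parts[2] == "aki_episode") doc$costs$aki_episode
             else doc$costs[[paste0(parts[3], "_annual")]])
    sc <- if (reg$family[i] == "beta") scale else 1  # money never in percent
    v <- pe_from_node(node, id, sc)
    rows[[i]] <- data.frame(id = id, value = v[["value"]], low = v[["low"]],
                            high = v[["high"]], family = reg$family[i])
  }
  params <- do.call(rbind, rows)
  settings <- doc$settings
  if (is.null(settings)) stop("model file has no 'settings' block", call. = FALSE)
  for (h in c("aki", "no_aki")) {
    row <- params$value[match(paste0("p30.", h, ".", health_states()), params$id)]
    if (abs(sum(row) - 1) > 1e-9 && abs(sum(row) - 1) <= 0.005) {
      warning("30-day '", h, "' disposition row sums to ", signif(sum(row), 6),
              "; renormalizing proportionally (rounding artifact)", call. = FALSE)
    }
  }
  aki_model(params, settings,
            meta = list(currency_year = doc$currency_year, source = path))
}

#' Write a model back to YAML
#'
#' Inverse of [load_model()]: numeric fields round-trip to full double
#' precision. Values are always written as fractions.
#'
#' @param m An `aki_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  validate_aki_model(m)
  p <- m$params
  node <- function(id) {
    i <- match(id, p$id)
    list(mean = p$value[i], low = p$low[i], high = p$high[i])
  }
  doc <- list(
    model = "aki-prevention-cea",
    currency_year = m$meta$currency_year %||% 2020,
    units = "fraction",
    settings = m$settings,
    strategies = stats::setNames(lapply(strategy_names(), function(s) {
      list(p_aki = node(paste0("p_aki.", s)),
           upfront_cost = node(paste0("cost.upfront.", s)))
    }), strategy_names()),
    thirty_day = stats::setNames(lapply(c("aki", "no_aki"), function(h) {
      stats::setNames(lapply(health_states(), function(st) node(paste0("p30.", h, ".", st))),
                      health_states())
    }), c("aki", "no_aki")),
    annual = local({
      keys <- character(); vals <- list()
      for (origin in c("normal", "ckd", "esrd")) for (h in c("post_aki", "no_aki")) {
        keys <- c(keys, paste(origin, h, sep = "_"))
        vals <- c(vals, list(stats::setNames(
          lapply(annual_exits(origin),
                 function(d) node(paste0("annual.", origin, ".", h, ".", d))),
          annual_exits(origin))))
      }
      stats::setNames(vals, keys)
    }),
    utilities = stats::setNames(
      lapply(c("normal", "ckd", "esrd"), function(s) node(paste0("utility.", s))),
      c("normal", "ckd", "esrd")),
    costs = list(aki_episode = node("cost.aki_episode"),
                 ckd_annual = node("cost.annual.ckd"),
                 esrd_annual = node("cost.annual.esrd"))
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled IMPROVE AKI trial model
#'
#' Loads the canonical model file shipped with the package: per-strategy
#' 7-day AKI probabilities and per-person intervention costs from the
#' IMPROVE AKI cluster-randomized trial, 30-day dispositions and averaged
#' annual transition probabilities stratified by AKI history, literature
#' utilities, and 2020-USD health-state costs, with a 3-year horizon, 3%
#' annual discounting and willingness-to-pay thresholds of $100,000 and
#' $50,000 per QALY.
#'
#' @return Validated `aki_model`.
#' @export
#' @examples
#' m <- aki_model_improve()
#' economics(m)$utilities
aki_model_improve <- function() {
  path <- system.file("extdata", "improve_aki.yaml", package = "akicea")
  suppressWarnings(load_model(path))  # known 0.999 rounding residue in the no-AKI row
}
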