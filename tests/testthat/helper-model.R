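# Shared fixtures built in code.

# The bundled trial model, loaded once per test file.
trial_model <- function() aki_model_improve()

# Degenerate single-state model: everyone healthy forever, utility 0.85,
# no costs beyond upfront. Useful for closed-form discounting checks.
degenerate_model <- function(discount_rate = 0) {
  m <- trial_model()
  m$settings$discount_rate <- discount_rate
  p <- m$params
  p$value[grepl("^p_aki\\.", p$id)] <- 0
  p$value[grepl("^p30\\.", p$id)] <- 0
  p$value[p$id %in% paste0("p30.", c("aki", "no_aki"), ".normal")] <- 1
  p$value[grepl("^annual\\.", p$id)] <- 0
  p$value[grepl("^cost\\.", p$id)] <- 0
  p$value[p$id == "utility.normal"] <- 0.85
  p$low <- pmin(p$low, p$value)
  p$high <- pmax(p$high, p$value)
  m$params <- p
  validate_aki_model(m)
}

# Random valid model: jitter every parameter uniformly within its one-way
# range; 30-day rows redrawn from normalized gamma variates so they sum to
# one exactly.
random_model <- function(seed) {
  set.seed(seed)
  m <- trial_model()
  p <- m$params
  for (i in seq_len(nrow(p))) {
    p$value[i] <- runif(1, p$low[i], p$high[i])
  }
  for (h in c("aki", "no_aki")) {
    ix <- match(paste0("p30.", h, ".", health_states()), p$id)
    w <- rgamma(4, shape = 2) * c(20, 1, 0.2, 1)
    p$value[ix] <- w / sum(w)
    p$low[ix] <- pmin(p$low[ix], p$value[ix])
    p$high[ix] <- pmax(p$high[ix], p$value[ix])
  }
  m$params <- p
  validate_aki_model(m)
}

# Collapse every parameter to a point mass at its base value.
point_mass_model <- function(m = trial_model()) {
  m$params$low <- m$params$value
  m$params$high <- m$params$value
  m
}
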