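#' Health states of the kidney-disease progression model
#'
#' The model tracks four health states after cardiac catheterization: normal
#' kidney function, chronic kidney disease (CKD), end-stage renal disease
#' (ESRD), and death. Death is absorbing. The Markov phase stratifies the
#' three living states by 7-day AKI history because post-AKI patients carry
#' different annual transition probabilities.
#'
#' @return Character vector of the four state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() c("normal", "ckd", "esrd", "death")

#' Stratified state labels used by the cohort engine
#'
#' Each living state exists in a post-AKI and a no-AKI copy; death is carried
#' within its stratum so that occupancy over all eight labels sums to one.
#'
#' @return Character vector of eight `state.history` labels.
#' @export
stratified_states <- function() {
  as.vector(outer(health_states(), c("post_aki", "no_aki"),
                  function(s, h) paste(s, h, sep = ".")))
}

# permitted annual exits (no backward transitions; death absorbing)
annual_exits <- function(origin) {
  switch(origin,
         normal = c("ckd", "esrd", "death"),
         ckd    = c("esrd", "death"),
         esrd   = "death",
         stop("no annual exits defined for state '", origin, "'"))
}

#' Implementation strategy names
#'
#' The four protocol-implementation strategies compared by the model:
#' technical assistance, assistance with automated surveillance reporting,
#' virtual learning collaborative, and collaborative with surveillance.
#'
#' @return Character vector of the four strategy names.
#' @export
strategy_names <- function() {
  c("assistance", "assistance_surveillance",
    "collaborative", "collaborative_surveillance")
}
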