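#' @importFrom rlang %||% .data
#' @importFrom stats rnorm rbinom runif quantile median sd qnorm predict
#' @importFrom utils head write.csv read.csv
NULL

# canonical "a|b" key for an unordered feature pair
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

pair_label <- function(a, b) {
  paste0("(", pmin(a, b), ", ", pmax(a, b), ")")
}

# draw from a normal truncated to [lo, hi] by inverse-cdf sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

risk_levels <- c("low", "medium", "high", "attack")
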