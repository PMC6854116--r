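#' Logit and inverse-logit
#'
#' The log-odds transform and its inverse, used throughout the risk models.
#' `logit()` and `inv_logit()` are exact mutual inverses to machine precision
#' over probabilities away from 0 and 1.
#'
#' @param p probability in (0, 1).
#' @param x real number (log-odds).
#' @return `logit()` returns log(p / (1 - p)); `inv_logit()` returns
#'   1 / (1 + exp(-x)).
#' @examples
#' inv_logit(logit(0.072))
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  stopifnot(is.numeric(x))
  # stats::plogis is numerically stable for large |x|
  stats::plogis(x)
}

#' Clamp probabilities away from exactly 0 and 1
#'
#' The composite model works in logit space, so probabilities of exactly 0 or
#' 1 must be clamped first. The lower bound is deliberately tiny (1e-300):
#' extremely small predicted risks (down to ~1e-28 for deeply diverged
#' sap-feeder hosts) are scientifically meaningful and must survive the
#' round trip through logit space un-clamped.
#'
#' @param p numeric vector of probabilities.
#' @param lower,upper clamping bounds.
#' @return clamped numeric vector.
#' @export
clamp_prob <- function(p, lower = 1e-300, upper = 1 - 1e-15) {
  pmin(pmax(p, lower), upper)
}

# round-half-up for non-negative x (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
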