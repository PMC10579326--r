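#' Redfield phosphate demand of a carbon fixation rate
#'
#' Converts a carbon fixation rate into the phosphate uptake needed to
#' sustain it at the canonical planktonic C:P ratio (106:1 by default):
#' `demand = cfix_rate / c_to_p`.
#'
#' @param cfix_rate Carbon fixation rate, nmol C L^-1 d^-1 (>= 0).
#' @param c_to_p Molar C:P ratio (> 0, default 106).
#' @return Phosphate demand, nmol P L^-1 d^-1.
#' @export
redfield_pi_demand <- function(cfix_rate, c_to_p = 106) {
  if (c_to_p <= 0) stop("invalid ratio: c_to_p must be > 0", call. = FALSE)
  if (any(cfix_rate < 0)) stop("cfix_rate must be >= 0", call. = FALSE)
  cfix_rate / c_to_p
}

#' Percent of the phosphate demand supportable by methane formation
#'
#' Methylphosphonate demethylation liberates methane and phosphate 1:1, so
#' a methane formation rate doubles as a phosphate liberation rate:
#' `percent = 100 * ch4_rate / pi_demand`, deliberately unclamped (values
#' above 100 mean supply exceeds the Redfield demand).
#'
#' @param ch4_rate Methane formation rate, nmol CH4 L^-1 d^-1.
#' @param pi_demand Phosphate demand, nmol P L^-1 d^-1 (> 0).
#' @return Percent support (may exceed 100).
#' @export
percent_support <- function(ch4_rate, pi_demand) {
  if (any(pi_demand <= 0)) {
    stop("undefined support: pi_demand must be > 0", call. = FALSE)
  }
  100 * ch4_rate / pi_demand
}

#' Distribution of percent support over a set of measured rates
#'
#' Elementwise [percent_support()] of each methane formation rate against
#' the Redfield demand of one carbon fixation rate, summarized by order
#' statistics. Quartiles use linear interpolation (quantile type 7); the
#' median is the midpoint of the middle two values for even n.
#'
#' @param rates Numeric vector of net methane formation rates (nmol CH4
#'   L^-1 d^-1), zeros included.
#' @param cfix_rate Carbon fixation rate, nmol C L^-1 d^-1.
#' @param c_to_p Molar C:P ratio (default 106).
#' @return List with `pi_demand`, `support` (per-rate percents), and
#'   `summary` (named vector: min, q1, median, q3, max) plus `n`.
#' @export
support_distribution <- function(rates, cfix_rate, c_to_p = 106) {
  if (!length(rates)) stop("nonempty rate set required", call. = FALSE)
  demand <- redfield_pi_demand(cfix_rate, c_to_p)
  support <- percent_support(rates, demand)
  qs <- stats::quantile(support, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                        names = FALSE)
  list(pi_demand = demand,
       support = support,
       summary = c(min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
                   max = qs[5]),
       n = length(rates))
}
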