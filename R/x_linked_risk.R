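# Algebra of X-linked excess male mortality. Males have one X, so a
# deleterious X-linked mutation acts as a recessive disease in males
# only. Attributing the whole male excess in infant deaths to such
# carriers links three quantities exactly: the male:female death-rate
# ratio rho, the relative risk rr of carrier males versus non-carrier
# males, and the carrier prevalence p. Non-carrier males are assumed to
# share the female baseline risk, so
#
#   rho = 1 + p * (rr - 1)
#
# and the carrier fraction among male deaths is rr * p / rho.

check_xrisk <- function(rr, sex_ratio) {
  stopifnot_scalar_number(sex_ratio, "sex_ratio", min = 1)
  stopifnot_scalar_number(rr, "rr")
  if (rr <= 1) abort_domain("`rr` must exceed 1 for a male excess")
  p <- (sex_ratio - 1) / (rr - 1)
  if (p > 1)
    abort_domain(sprintf(
      "infeasible parameters: rr = %g cannot produce sex ratio %g with p <= 1",
      rr, sex_ratio))
  p
}

#' Carrier prevalence implied by a relative risk and the sex ratio
#'
#' Solves `1 + p * (rr - 1) = sex_ratio` for the population carrier
#' prevalence `p` of a deleterious X-linked mutation among males,
#' assuming the whole male death excess is carried by them. At the
#' observed 3:2 male:female ratio, a 3-fold relative risk needs a
#' quarter of males to be carriers; an 11-fold risk needs only 5%.
#'
#' @param rr Relative risk of death for carrier males (> 1).
#' @param sex_ratio Male:female death-rate ratio (default 1.5).
#' @return The carrier prevalence `p` (a proportion; this is the
#'   control-male carrier frequency).
#' @examples
#' carrier_freq_from_rr(3)    # 0.25
#' carrier_freq_from_rr(11)   # 0.05
#' @export
carrier_freq_from_rr <- function(rr, sex_ratio = 1.5) {
  check_xrisk(rr, sex_ratio)
}

#' Carrier fraction among male deaths
#'
#' Of the male deaths, carriers contribute in proportion to their
#' prevalence times their risk: the fraction is `rr * p / sex_ratio`
#' with `p` from [carrier_freq_from_rr()]. This is the carrier
#' percentage expected among male cases if the attribution model holds.
#'
#' @inheritParams carrier_freq_from_rr
#' @return Proportion of male cases who carry the X-linked mutation.
#' @examples
#' case_carrier_fraction(3)    # 0.50
#' case_carrier_fraction(11)   # 0.3667
#' @export
case_carrier_fraction <- function(rr, sex_ratio = 1.5) {
  p <- check_xrisk(rr, sex_ratio)
  rr * p / sex_ratio
}

#' Relative risk implied by a carrier prevalence
#'
#' Exact inverse of [carrier_freq_from_rr()]:
#' `rr = 1 + (sex_ratio - 1) / p`. Carrier prevalences between 25% and
#' 5% bracket the relative risk between 3- and 11-fold at the 3:2 sex
#' ratio.
#'
#' @param p Carrier prevalence among males, in `(0, 1]`.
#' @param sex_ratio Male:female death-rate ratio (default 1.5).
#' @return The relative risk.
#' @examples
#' rr_from_carrier_freq(0.25)   # 3
#' rr_from_carrier_freq(0.05)   # 11
#' @export
rr_from_carrier_freq <- function(p, sex_ratio = 1.5) {
  stopifnot_scalar_number(sex_ratio, "sex_ratio", min = 1)
  stopifnot_scalar_number(p, "p", max = 1)
  if (p <= 0) abort_domain("`p` must be positive")
  1 + (sex_ratio - 1) / p
}

#' Sex ratio implied by a carrier prevalence and relative risk
#'
#' @param p Carrier prevalence among males, in `[0, 1]`.
#' @param rr Relative risk of death for carrier males.
#' @return The male:female death-rate ratio `1 + p * (rr - 1)`.
#' @examples
#' implied_sex_ratio(0.25, 3)   # 1.5
#' implied_sex_ratio(0.10, 6)   # 1.5
#' @export
implied_sex_ratio <- function(p, rr) {
  stopifnot_scalar_number(p, "p", min = 0, max = 1)
  stopifnot_scalar_number(rr, "rr", min = 0)
  1 + p * (rr - 1)
}

#' Tabulate carrier percentages over a set of relative risks
#'
#' Builds the case/control carrier table: for each relative risk, the
#' carrier percentage among male cases and among control males implied
#' by the sex ratio. Displayed percentages are rounded (nearest whole
#' percent by default); the raw values are kept alongside.
#'
#' @param rr_list Relative risks (each > `sex_ratio` for feasibility).
#' @param sex_ratio Male:female death-rate ratio (default 1.5).
#' @param digits Decimals for the display columns (default 0).
#' @return A data frame of class `xrisk_table` with columns `rr`,
#'   `pct_cases`, `pct_controls` (rounded) and `pct_cases_raw`,
#'   `pct_controls_raw`.
#' @examples
#' build_table(c(3, 6, 11))
#' @export
build_table <- function(rr_list = c(3, 6, 11), sex_ratio = 1.5,
                        digits = 0) {
  if (length(rr_list) == 0L) {
    out <- data.frame(rr = numeric(0), pct_cases = numeric(0),
                      pct_controls = numeric(0),
                      pct_cases_raw = numeric(0),
                      pct_controls_raw = numeric(0))
    class(out) <- c("xrisk_table", "data.frame")
    return(out)
  }
  controls <- 100 * vapply(rr_list, carrier_freq_from_rr, numeric(1),
                           sex_ratio = sex_ratio)
  cases <- 100 * vapply(rr_list, case_carrier_fraction, numeric(1),
                        sex_ratio = sex_ratio)
  out <- data.frame(
    rr = rr_list,
    pct_cases = round(cases, digits),
    pct_controls = round(controls, digits),
    pct_cases_raw = cases,
    pct_controls_raw = controls
  )
  attr(out, "sex_ratio") <- sex_ratio
  class(out) <- c("xrisk_table", "data.frame")
  out
}

#' @export
print.xrisk_table <- function(x, ...) {
  cat(sprintf(
    "X-linked carrier percentages at male:female death ratio %g\n",
    attr(x, "sex_ratio") %||% NA))
  print.data.frame(x[, c("rr", "pct_cases", "pct_controls")],
                   row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the relative risk from case/control carrier counts
#'
#' Under the attribution model the carrier odds among cases equal `rr`
#' times the carrier odds among controls, so the sample odds ratio of
#' the 2x2 carrier table is the consistent estimator of the relative
#' risk; its confidence interval uses the Wald normal approximation on
#' the log odds ratio.
#'
#' @param n_carrier_cases,n_cases Carrier count and total among male
#'   cases.
#' @param n_carrier_controls,n_controls Carrier count and total among
#'   control males.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `rr_hat`, `ci_lower`, `ci_upper`, `conf_level`.
#' @examples
#' estimate_rr(50, 100, 25, 100)   # rr_hat = 3
#' @export
estimate_rr <- function(n_carrier_cases, n_cases, n_carrier_controls,
                        n_controls, conf_level = 0.95) {
  a <- n_carrier_cases; b <- n_cases - n_carrier_cases
  c <- n_carrier_controls; d <- n_controls - n_carrier_controls
  if (min(a, b, c, d) < 0) abort_domain("inconsistent 2x2 counts")
  if (min(a, b, c, d) == 0) {           # Haldane-Anscombe correction
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rr_hat = exp(log_or),
       ci_lower = exp(log_or - z * se),
       ci_upper = exp(log_or + z * se),
       conf_level = conf_level)
}
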