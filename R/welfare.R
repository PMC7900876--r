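#' Translog distance function value
#'
#' The IAIDS distance function
#' \deqn{\ln D(q, u) = a(q) - u\, b(q),}
#' with \eqn{a(q) = \alpha_0 + \sum_i \alpha_i \ln q_i + \tfrac12 \sum_{ij}
#' \gamma_{ij} \ln q_i \ln q_j} and \eqn{b(q) = \beta_0 \prod_i
#' q_i^{\beta_i}}.  \eqn{D} measures the factor by which the bundle `q` must
#' be scaled down to just attain utility `u`; the restriction set makes it
#' linearly homogeneous in `q` (\eqn{D(\lambda q, u) = \lambda D(q, u)}) and,
#' since \eqn{b > 0}, strictly decreasing in `u`.
#'
#' Quantities are expressed relative to the base-period bundle (the package
#' normalisation), so `q = 1`-vector is the benchmark bundle.
#'
#' @param p an [iaids_params()] object (with the `alpha0`, `beta0`
#'   normalisations).
#' @param q positive quantity vector relative to base.
#' @param u utility level.
#' @return numeric scalar D.
#' @export
distance_value <- function(p, q, u) {
  stopifnot(all(q > 0))
  lnq <- log(q)
  a <- translog_index(p, lnq)
  b <- p$beta0 * exp(sum(p$beta * lnq))
  exp(a - u * b)
}

#' Benchmark utility at the base-period bundle
#'
#' The unique `u0` solving \eqn{D(q_{base}, u_0) = 1}:
#' \eqn{u_0 = a(q_{base})/b(q_{base})}.
#'
#' @param p an [iaids_params()] object.
#' @param q_base base bundle (relative quantities; default the 1-vector).
#' @return numeric scalar.
#' @export
benchmark_utility <- function(p, q_base = rep(1, p$n)) {
  stopifnot(all(q_base > 0))
  lnq <- log(q_base)
  a <- translog_index(p, lnq)
  b <- p$beta0 * exp(sum(p$beta * lnq))
  a / b
}

#' Annual consumer-welfare impact from a quantity change
#'
#' Money-metric monetisation of the distance between the year's bundle and
#' the benchmark utility:
#' \deqn{W_t = E_t (1 - 1/D(q_t, u_0))}
#' (the default, compensating-style measure), or the equivalent-style
#' variant \eqn{W_t = E_t (D - 1)}.  Both are zero at the benchmark bundle,
#' share the sign of \eqn{u(q_t) - u_0}, and are exact for proportional
#' bundle changes.
#'
#' @param p an [iaids_params()] object.
#' @param q_t quantity vector (relative to base) in year t.
#' @param u0 benchmark utility from [benchmark_utility()].
#' @param E_t expenditure used to monetise the change (MM 2018 US$).
#' @param monetization `"cv"` (default) or `"ev"`.
#' @return numeric scalar W_t (negative = loss).
#' @export
annual_welfare <- function(p, q_t, u0, E_t, monetization = c("cv", "ev")) {
  monetization <- match.arg(monetization)
  stopifnot(E_t > 0)
  D <- distance_value(p, q_t, u0)
  if (monetization == "cv") E_t * (1 - 1 / D) else E_t * (D - 1)
}

#' Net present value of welfare series
#'
#' Discounts each group's annual welfare series to the base year and sums;
#' the total NPV equals the sum of group NPVs.
#'
#' @param series data.frame with a `year` column and one numeric column per
#'   group (annual welfare, MM 2018 US$).
#' @param r real discount rate (default 0.03).
#' @param base_year discounting base (default 2020).
#' @return named numeric: one NPV per group plus `total`.
#' @export
welfare_npv <- function(series, r = 0.03, base_year = 2020) {
  groups <- setdiff(names(series), "year")
  npv <- vapply(groups, function(g)
    present_value(stats::setNames(series[[g]], series$year), r, base_year),
    numeric(1))
  c(npv, total = sum(npv))
}
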