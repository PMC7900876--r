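#' Forecast total expenditures on the modeled species
#'
#' Projects real expenditures from a GDP path through an income elasticity
#' of demand for seafood:
#' \deqn{E_t = E_{anchor} (GDP_t / GDP_{anchor})^{\eta}.}
#' Growth by 2100 is reported relative to the 2007--2016 baseline average
#' expenditure when supplied.
#'
#' @param gdp a `gdp_path` (see [packaged_gdp_path()]) or a data.frame with
#'   columns `year` and `gdp` covering the anchor year through 2100.
#' @param eta income elasticity of demand (default 0.11).
#' @param anchor_year year at which the path is anchored (default 2020).
#' @param anchor_expenditure expenditure at the anchor year, MM 2018 US$;
#'   defaults to the packaged anchor when `gdp` is a `gdp_path`.
#' @param base_expenditure baseline-average expenditure used for the
#'   growth-by-2100 figure (optional).
#' @return data.frame of class `expenditure_path` (year, expenditure) with
#'   attributes `anchor_year`, `anchor_expenditure`, `base_expenditure`,
#'   `growth_vs_base` (fraction, `NA` without a base).
#' @export
forecast_expenditures <- function(gdp, eta = 0.11, anchor_year = 2020,
                                  anchor_expenditure = NULL,
                                  base_expenditure = NULL) {
  if (inherits(gdp, "gdp_path")) {
    if (is.null(anchor_expenditure)) anchor_expenditure <- gdp$anchor_expenditure
    if (is.null(base_expenditure)) base_expenditure <- gdp$base_expenditure
    gdp <- gdp$annual
  }
  if (is.null(anchor_expenditure))
    stop("anchor_expenditure must be supplied", call. = FALSE)
  if (!anchor_year %in% gdp$year)
    stop("GDP path does not cover the anchor year ", anchor_year,
         call. = FALSE)
  g0 <- gdp$gdp[gdp$year == anchor_year]
  out <- data.frame(year = gdp$year,
                    expenditure = anchor_expenditure * (gdp$gdp / g0)^eta)
  growth <- if (!is.null(base_expenditure) && 2100 %in% out$year)
    out$expenditure[out$year == 2100] / base_expenditure - 1 else NA_real_
  structure(out, class = c("expenditure_path", "data.frame"),
            anchor_year = anchor_year,
            anchor_expenditure = anchor_expenditure,
            base_expenditure = base_expenditure,
            growth_vs_base = growth)
}

#' First-stage budget allocation across fishery groups
#'
#' Evaluates the first-stage IAIDS share equations at the projected group
#' quantity indices and multiplies the shares by total expenditures.  Shares
#' are Stone-index consistent ([solve_shares()]), so group expenditures sum
#' to the total identically.
#'
#' @param p1 first-stage [iaids_params()].
#' @param group_lnq matrix (years x groups) of group log-quantity indices
#'   relative to the base period.
#' @param E numeric vector of total expenditures, one per row of
#'   `group_lnq`.
#' @return matrix (years x groups) of group expenditures.
#' @export
allocate_stage1 <- function(p1, group_lnq, E) {
  group_lnq <- as.matrix(group_lnq)
  stopifnot(nrow(group_lnq) == length(E))
  w <- solve_shares(p1, group_lnq)
  bad <- which(w <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("predicted non-positive share for group ",
         p1$labels[bad[1, 2]], " in row ", bad[1, 1],
         " (out-of-sample extrapolation failure)", call. = FALSE)
  out <- w * E
  colnames(out) <- p1$labels
  out
}

#' Second-stage budget allocation within a fishery group
#'
#' As [allocate_stage1()], but allocating one group's expenditure across its
#' member species with the group's second-stage parameters.
#'
#' @param p2 second-stage [iaids_params()] for the group.
#' @param species_lnq matrix (years x species) of log quantities relative to
#'   the base period.
#' @param group_E numeric vector of group expenditures per year.
#' @return matrix (years x species) of species expenditures.
#' @export
allocate_stage2 <- function(p2, species_lnq, group_E) {
  allocate_stage1(p2, species_lnq, group_E)
}

#' Implied ex-vessel prices from expenditures and harvests
#'
#' `p_t = E_t / q_t` per species and year (MM 2018 US$ over MM lb gives
#' US$/lb), with the percent change by 2100 relative to the baseline price.
#'
#' @param species_E matrix (years x species) of expenditures, rownames are
#'   years.
#' @param q matrix (years x species) of harvests (MM lb), same shape.
#' @param baseline_price named vector of baseline prices (US$/lb).
#' @return list of class `price_path`: `prices` (years x species),
#'   `baseline_price`, `pct_change_2100`.
#' @export
implied_prices <- function(species_E, q, baseline_price) {
  stopifnot(all(dim(species_E) == dim(q)))
  if (any(q <= 0))
    stop("non-positive harvest: price undefined (exclude the record upstream)",
         call. = FALSE)
  prices <- species_E / q
  pct <- if ("2100" %in% rownames(prices))
    100 * (prices["2100", ] / baseline_price[colnames(prices)] - 1)
  else NULL
  structure(list(prices = prices, baseline_price = baseline_price,
                 pct_change_2100 = pct), class = "price_path")
}

#' @export
print.price_path <- function(x, ...) {
  cat("Implied ex-vessel prices,", nrow(x$prices), "years x",
      ncol(x$prices), "species\n")
  if (!is.null(x$pct_change_2100)) {
    cat("percent change by 2100:\n")
    print(round(x$pct_change_2100, 2))
  }
  invisible(x)
}
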