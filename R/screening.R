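#' Deflate nominal ex-vessel revenues to constant dollars
#'
#' Multiplies each record's revenue by `cpi[base_year]/cpi[year]`.
#' Quantities are untouched.  The returned panel carries the attribute
#' `deflated = TRUE`.
#'
#' @param panel landings panel with columns `year` and
#'   `revenue_mm_2018usd` (nominal on input).
#' @param cpi named numeric vector, year -> index; must cover every panel
#'   year and the base year.
#' @param base_year constant-dollar base (default 2018).
#' @return the panel with real revenues.
#' @export
deflate <- function(panel, cpi, base_year = 2018) {
  yrs <- as.character(sort(unique(panel$year)))
  missing <- setdiff(c(yrs, as.character(base_year)), names(cpi))
  if (length(missing))
    stop("CPI missing for year(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  panel$revenue_mm_2018usd <- panel$revenue_mm_2018usd *
    cpi[[as.character(base_year)]] / cpi[as.character(panel$year)]
  attr(panel, "deflated") <- TRUE
  panel
}

#' Baseline annual landings statistics per species-region
#'
#' Collapses a monthly panel to annual totals per (species, region, year),
#' then to one record per species-region: the mean and sample standard
#' deviation (n-1 denominator) of the annual totals, in both weight and real
#' value.  The per-year annual totals are retained for bootstrap resampling.
#'
#' @param panel a deflated landings panel.
#' @return list of class `baseline_stats`: `summary` (one row per
#'   species-region: mean/sd of pounds and revenue, n_years) and `annual`
#'   (per-year totals).  SDs are `NA` when fewer than 2 years are present.
#' @export
baseline_stats <- function(panel) {
  if (!isTRUE(attr(panel, "deflated")))
    warning("panel not flagged as deflated; treating revenues as real",
            call. = FALSE)
  annual <- stats::aggregate(
    cbind(pounds_mm, revenue_mm_2018usd) ~ species + region + year,
    data = panel, FUN = sum)
  summ <- do.call(rbind, lapply(
    split(annual, list(annual$species, annual$region), drop = TRUE),
    function(d) data.frame(
      species = d$species[1], region = d$region[1],
      n_years = nrow(d),
      mean_pounds = mean(d$pounds_mm),
      sd_pounds = if (nrow(d) >= 2) stats::sd(d$pounds_mm) else NA_real_,
      mean_revenue = mean(d$revenue_mm_2018usd),
      sd_revenue = if (nrow(d) >= 2) stats::sd(d$revenue_mm_2018usd)
                   else NA_real_)))
  rownames(summ) <- NULL
  structure(list(summary = summ, annual = annual), class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat("Baseline statistics for", nrow(x$summary), "species-region records (",
      x$summary$n_years[1], "years )\n")
  print(utils::head(x$summary), digits = 4)
  if (nrow(x$summary) > 6) cat("...\n")
  invisible(x)
}

#' Match landings records to habitat projections
#'
#' Classifies each species-region landings record exactly once, mirroring
#' the published record-matching workflow: automated name match against the
#' habitat table, manual match via a synonym map, exclusion of multi-species
#' aggregate records, a de minimis exclusion (mean annual revenue strictly
#' below $100,000, i.e. 0.1 MM) applied only to records not otherwise
#' matched, and exclusion for lack of a habitat projection.
#'
#' @param landings a [baseline_stats()] object or its `summary` data.frame.
#' @param habitat habitat projection table with `species` and `region`
#'   columns.
#' @param synonyms named character vector: landings name -> habitat name.
#' @param multi_species_flags character vector of multi-species record names.
#' @param de_minimis revenue threshold in MM 2018 US$ (default 0.1).
#' @return list of class `disposition_table`: `records` (one row per
#'   species-region with its disposition) and `summary` (count and revenue
#'   share per class).
#' @export
match_records <- function(landings, habitat, synonyms = character(),
                          multi_species_flags = character(),
                          de_minimis = 0.1) {
  if (inherits(landings, "baseline_stats")) landings <- landings$summary
  both <- intersect(names(synonyms), multi_species_flags)
  if (length(both))
    stop("ambiguous curation: in both synonym map and multi-species set: ",
         paste(both, collapse = ", "), call. = FALSE)
  hab_keys <- unique(paste(habitat$species, habitat$region, sep = "\r"))
  rec <- landings
  key <- paste(rec$species, rec$region, sep = "\r")
  syn_key <- paste(unname(synonyms[rec$species]), rec$region, sep = "\r")
  rec$disposition <- ifelse(
    key %in% hab_keys, "matched-automated",
    ifelse(rec$species %in% names(synonyms) & syn_key %in% hab_keys,
           "matched-manual",
    ifelse(rec$species %in% multi_species_flags, "excluded-multi-species",
    ifelse(rec$mean_revenue < de_minimis, "excluded-de-minimis",
           "excluded-no-projection"))))
  classes <- c("matched-automated", "matched-manual", "excluded-multi-species",
               "excluded-no-projection", "excluded-de-minimis")
  total_rev <- sum(rec$mean_revenue)
  summ <- data.frame(
    disposition = classes,
    count = vapply(classes, function(cl) sum(rec$disposition == cl), 0L),
    revenue_share_pct = vapply(classes, function(cl)
      100 * sum(rec$mean_revenue[rec$disposition == cl]) /
        max(total_rev, .Machine$double.eps), numeric(1)),
    row.names = NULL)
  structure(list(records = rec, summary = summ), class = "disposition_table")
}

#' @export
print.disposition_table <- function(x, ...) {
  cat("Record disposition (", nrow(x$records), "species-region records ):\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fractional habitat change versus the baseline bin
#'
#' For each (species, region, RCP, GCM) computes the per-bin fractional
#' change \eqn{\Delta h = (H(bin) - H(B0))/H(B0)}, and the 5-GCM ensemble
#' mean of the per-GCM fractional changes (mean of ratios: the ensemble
#' average is taken after the percent-change step).
#'
#' @param habitat habitat projection table (species, region, rcp, gcm, bin,
#'   habitat_total) with a complete bin set per (species, region, rcp, gcm).
#' @return data.frame of class `habitat_trajectory` with rows per GCM plus
#'   `gcm = "ensemble"`: species, region, rcp, gcm, bin, delta.
#' @export
habitat_change <- function(habitat) {
  parts <- split(habitat,
                 list(habitat$species, habitat$region, habitat$rcp,
                      habitat$gcm), drop = TRUE)
  per_gcm <- do.call(rbind, lapply(parts, function(d) {
    h0 <- d$habitat_total[d$bin == "B0"]
    if (length(h0) != 1)
      stop("incomplete bin set for ", d$species[1], " / ", d$region[1],
           call. = FALSE)
    if (h0 == 0)
      stop("baseline habitat is zero for ", d$species[1], " (", d$region[1],
           ", ", d$rcp[1], ", ", d$gcm[1],
           "): percent change undefined; exclude the record upstream",
           call. = FALSE)
    data.frame(species = d$species[1], region = d$region[1], rcp = d$rcp[1],
               gcm = d$gcm[1], bin = d$bin,
               delta = (d$habitat_total - h0) / h0)
  }))
  ens <- stats::aggregate(delta ~ species + region + rcp + bin,
                          data = per_gcm, FUN = mean)
  ens$gcm <- "ensemble"
  out <- rbind(per_gcm, ens[, names(per_gcm)])
  rownames(out) <- NULL
  class(out) <- c("habitat_trajectory", "data.frame")
  out
}

#' Annualize binned habitat changes into yearly multipliers
#'
#' Anchors the per-bin fractional changes at the bin midpoints (B0 at
#' 2013.5, T1 at 2030.5, T2 at 2050.5, T3 at 2070.5, T4 at 2090.5),
#' interpolates linearly between anchors and extrapolates flat beyond the
#' last anchor, and returns the multipliers \eqn{m_t = 1 + \Delta h(t)}.
#'
#' @param delta named numeric vector of per-bin fractional changes; names
#'   among B0, T1, T2, T3, T4 (B0 defaults to 0 when absent).
#' @param years integer years to evaluate (default 2021:2100).
#' @return named numeric vector of multipliers per year.
#' @export
annualize <- function(delta, years = 2021:2100) {
  midpoints <- c(B0 = 2013.5, T1 = 2030.5, T2 = 2050.5, T3 = 2070.5,
                 T4 = 2090.5)
  if (!"B0" %in% names(delta)) delta <- c(B0 = 0, delta)
  bins <- intersect(names(midpoints), names(delta))
  if (length(bins) < 2) stop("need at least two bins", call. = FALSE)
  y <- stats::approx(midpoints[bins], delta[bins], xout = years, rule = 2)$y
  stats::setNames(1 + y, years)
}

#' Project annual landings proportionally to habitat multipliers
#'
#' `landings_t = baseline_mean * m_t` — landings (and, at constant ex-vessel
#' prices, revenues) change in direct proportion to thermally available
#' habitat.
#'
#' @param baseline_mean baseline mean annual landings (or revenue).
#' @param multipliers named year -> multiplier vector from [annualize()].
#' @return named numeric vector, one value per year.
#' @export
project_landings <- function(baseline_mean, multipliers) {
  baseline_mean * multipliers
}

#' Present value of an annual series
#'
#' \eqn{PV = \sum_t v_t (1+r)^{-(t - base\_year)}}; with the default base
#' year 2020, the first projection year 2021 is discounted one period.
#'
#' @param series named numeric vector, names are years.
#' @param r real annual discount rate (default 0.03).
#' @param base_year discounting base (default 2020).
#' @return numeric scalar.
#' @export
present_value <- function(series, r = 0.03, base_year = 2020) {
  years <- as.numeric(names(series))
  sum(series * (1 + r)^(-(years - base_year)))
}

#' Annuity factor over the projection horizon
#'
#' \eqn{\sum_{k=1}^{K} (1+r)^{-k}} for the years following the base year —
#' the present value of one dollar per year over 2021--2100 at the default
#' settings (30.2008 at r = 0.03).
#'
#' @param r real annual discount rate.
#' @param years projection years (default 2021:2100).
#' @param base_year discounting base (default 2020).
#' @return numeric scalar.
#' @export
annuity_factor <- function(r = 0.03, years = 2021:2100, base_year = 2020) {
  sum((1 + r)^(-(years - base_year)))
}

#' Aggregate per-species present-value changes by region
#'
#' Sums present-value changes over species within regions and adds Atlantic
#' (East + Gulf Coast) and Pacific (West Coast + Alaska) subtotals and a
#' grand total.  Percentage change is \eqn{\Delta PV / (baseline \times
#' annuity\ factor)}.
#'
#' @param species_pv data.frame with columns region, baseline_mean (mean
#'   annual revenue) and delta_pv, one row per species-region.
#' @param r,years,base_year passed to [annuity_factor()].
#' @return data.frame: region, baseline_mean, delta_pv, pct_change.
#' @export
aggregate_regions <- function(species_pv, r = 0.03, years = 2021:2100,
                              base_year = 2020) {
  af <- annuity_factor(r, years, base_year)
  basin <- c("East Coast" = "Atlantic", "Gulf Coast" = "Atlantic",
             "West Coast" = "Pacific", "Alaska" = "Pacific")
  row_for <- function(label, d) data.frame(
    region = label,
    baseline_mean = sum(d$baseline_mean),
    delta_pv = sum(d$delta_pv),
    pct_change = 100 * sum(d$delta_pv) / (sum(d$baseline_mean) * af))
  regions <- intersect(names(basin), unique(species_pv$region))
  out <- do.call(rbind, lapply(regions, function(rg)
    row_for(rg, species_pv[species_pv$region == rg, ])))
  for (bs in unique(basin[regions])) {
    d <- species_pv[basin[species_pv$region] %in% bs, ]
    out <- rbind(out, row_for(paste("Subtotal:", bs), d))
  }
  out <- rbind(out, row_for("Total", species_pv))
  rownames(out) <- NULL
  out
}

#' Monte Carlo confidence interval for a projected percent change
#'
#' Propagates the two uncertainty sources of the screening analysis: each
#' draw bootstraps the baseline annual values with replacement (interannual
#' variation) and picks one GCM's multiplier uniformly (climate-model
#' spread).  The draw's percent change is
#' `(mean_draw * m - mean_full)/mean_full`; the interval is the 2.5th/97.5th
#' percentile across draws.  The point estimate is the ensemble-mean percent
#' change `mean(multipliers) - 1`.
#'
#' @param annual_values baseline annual values (>= 2 years).
#' @param gcm_multipliers the five per-GCM multipliers at the target year.
#' @param n_draws number of draws (default 10000).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return named numeric: `point`, `lower`, `upper` (percent).
#' @export
monte_carlo_ci <- function(annual_values, gcm_multipliers, n_draws = 10000L,
                           seed = 1L) {
  stopifnot(length(annual_values) >= 2, length(gcm_multipliers) >= 1)
  mean_full <- mean(annual_values)
  n <- length(annual_values)
  with_local_seed(seed, 3L, {
    idx <- matrix(sample.int(n, n_draws * n, replace = TRUE), n_draws, n)
    mean_draw <- rowMeans(matrix(annual_values[idx], n_draws, n))
    m <- gcm_multipliers[sample.int(length(gcm_multipliers), n_draws,
                                    replace = TRUE)]
    pct <- 100 * (mean_draw * m - mean_full) / mean_full
    qs <- stats::quantile(pct, c(0.025, 0.975), names = FALSE)
    c(point = 100 * (mean(gcm_multipliers) - 1), lower = qs[1],
      upper = qs[2])
  })
}
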