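#' Configuration for an end-to-end run
#'
#' @param synthetic a [synthetic_config()] describing the inputs (or `NULL`
#'   if panels are supplied directly to the stages).
#' @param rcp `"RCP4.5"`, `"RCP8.5"` or `"both"`.
#' @param discount_rate real discount rate (> -1), default 0.03.
#' @param income_elasticity income elasticity of seafood demand, default
#'   0.11.
#' @param n_draws Monte Carlo draws for screening confidence intervals.
#' @param seed integer run seed (stage-partitioned substreams are derived
#'   from it, so adding draws in one stage does not perturb another).
#' @param base_year discounting base year.
#' @param monetization welfare monetisation, `"cv"` or `"ev"`.
#' @param output_dir optional directory for CSV reports and the JSON run
#'   manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       rcp = "both",
                       discount_rate = 0.03,
                       income_elasticity = 0.11,
                       n_draws = 10000L,
                       seed = synthetic$seed,
                       base_year = 2020,
                       monetization = "cv",
                       output_dir = NULL) {
  stopifnot(discount_rate > -1, n_draws >= 1,
            rcp %in% c("RCP4.5", "RCP8.5", "both"))
  structure(list(synthetic = synthetic, rcp = rcp,
                 discount_rate = discount_rate,
                 income_elasticity = income_elasticity,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 base_year = base_year, monetization = monetization,
                 output_dir = output_dir),
            class = "run_config")
}

rcps_of <- function(cfg) if (cfg$rcp == "both") c("RCP4.5", "RCP8.5") else cfg$rcp

ensemble_deltas <- function(traj, sp, rg, rcp, gcm = "ensemble") {
  d <- traj[traj$species == sp & traj$region == rg & traj$rcp == rcp &
              traj$gcm == gcm, ]
  stats::setNames(d$delta, d$bin)
}

write_manifest <- function(cfg, dir, stage) {
  manifest <- list(
    stage = stage,
    package = "fishclim",
    version = as.character(utils::packageVersion("fishclim")),
    seed = cfg$seed, rcp = cfg$rcp,
    discount_rate = cfg$discount_rate,
    income_elasticity = cfg$income_elasticity,
    n_draws = cfg$n_draws, base_year = cfg$base_year,
    monetization = cfg$monetization,
    annualization = "bin-midpoint anchors, linear interpolation, flat tails",
    synthetic_seed = cfg$synthetic$seed,
    n_months = cfg$synthetic$n_months,
    share_noise_sd = cfg$synthetic$share_noise_sd,
    gcm_spread_sd = cfg$synthetic$gcm_spread_sd)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the habitat-proportional screening analysis
#'
#' Generates (or accepts) the landings panel and habitat ensemble, collapses
#' the panel to baseline statistics, converts habitat bins to annual
#' multipliers, projects revenues to 2100, computes present-value changes at
#' the configured discount rate, aggregates by region, and attaches Monte
#' Carlo confidence intervals for the projected harvest changes at 2050 and
#' 2090.
#'
#' @param cfg a [run_config()].
#' @param panel optional landings panel (defaults to
#'   [gen_demand_history()]).
#' @param habitat optional habitat table (defaults to
#'   [gen_habitat_table()]).
#' @return list of class `screening_result`: `species` (per species-region
#'   PV changes per RCP), `regions` (regional aggregation per RCP),
#'   `harvest` (baseline, 2050/2090 projections with CIs per RCP),
#'   `baseline` (the [baseline_stats()]).  CSVs and a JSON manifest are
#'   written when `cfg$output_dir` is set.
#' @export
run_screening <- function(cfg, panel = NULL, habitat = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(panel)) panel <- gen_demand_history(cfg$synthetic)
  if (is.null(habitat)) habitat <- gen_habitat_table(cfg$synthetic)
  stats <- baseline_stats(panel)
  traj <- habitat_change(habitat)
  years <- 2021:2100
  af <- annuity_factor(cfg$discount_rate, years, cfg$base_year)
  gcms <- setdiff(unique(traj$gcm), "ensemble")

  species_rows <- list(); harvest_rows <- list()
  for (rcp in rcps_of(cfg)) {
    for (k in seq_len(nrow(stats$summary))) {
      rec <- stats$summary[k, ]
      sp <- rec$species; rg <- rec$region
      m_ens <- annualize(ensemble_deltas(traj, sp, rg, rcp), years)
      pv_base <- rec$mean_revenue * af
      pv_proj <- present_value(project_landings(rec$mean_revenue, m_ens),
                               cfg$discount_rate, cfg$base_year)
      species_rows[[length(species_rows) + 1L]] <- data.frame(
        rcp = rcp, species = sp, region = rg,
        baseline_mean = rec$mean_revenue, sd = rec$sd_revenue,
        delta_pv = pv_proj - pv_base,
        pct_change = 100 * (pv_proj - pv_base) / pv_base)

      ann_lb <- stats$annual$pounds_mm[stats$annual$species == sp &
                                         stats$annual$region == rg]
      proj <- list()
      for (yr in c(2050, 2090)) {
        m_gcm <- vapply(gcms, function(g)
          annualize(ensemble_deltas(traj, sp, rg, rcp, g), yr), numeric(1))
        ci <- monte_carlo_ci(ann_lb, m_gcm, cfg$n_draws,
                             seed = cfg$seed + 13L * k +
                               (yr == 2090) + 2L * (rcp == "RCP8.5"))
        proj[[as.character(yr)]] <- c(
          landings = unname(rec$mean_pounds * m_ens[as.character(yr)]),
          pct = unname(100 * (m_ens[as.character(yr)] - 1)), ci)
      }
      harvest_rows[[length(harvest_rows) + 1L]] <- data.frame(
        rcp = rcp, species = sp, region = rg,
        baseline_mmlb = rec$mean_pounds,
        landings_2050 = proj[["2050"]][["landings"]],
        pct_2050 = proj[["2050"]][["pct"]],
        ci_lower_2050 = proj[["2050"]][["lower"]],
        ci_upper_2050 = proj[["2050"]][["upper"]],
        landings_2090 = proj[["2090"]][["landings"]],
        pct_2090 = proj[["2090"]][["pct"]],
        ci_lower_2090 = proj[["2090"]][["lower"]],
        ci_upper_2090 = proj[["2090"]][["upper"]])
    }
  }
  species_tab <- do.call(rbind, species_rows)
  harvest_tab <- do.call(rbind, harvest_rows)
  regions_tab <- do.call(rbind, lapply(rcps_of(cfg), function(rcp) {
    d <- species_tab[species_tab$rcp == rcp, ]
    cbind(rcp = rcp,
          aggregate_regions(d, cfg$discount_rate, years, cfg$base_year))
  }))
  out <- structure(list(species = species_tab, regions = regions_tab,
                        harvest = harvest_tab, baseline = stats),
                   class = "screening_result")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(species_tab,
                     file.path(cfg$output_dir, "screening_species.csv"),
                     row.names = FALSE)
    utils::write.csv(regions_tab,
                     file.path(cfg$output_dir, "screening_regions.csv"),
                     row.names = FALSE)
    utils::write.csv(harvest_tab,
                     file.path(cfg$output_dir, "harvest_projections.csv"),
                     row.names = FALSE)
    write_manifest(cfg, cfg$output_dir, "screening")
  }
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening analysis:", length(unique(x$species$species)),
      "species,", paste(unique(x$species$rcp), collapse = " & "), "\n")
  print(x$regions, digits = 3)
  invisible(x)
}

#' Run estimation, forecasting and the welfare analysis
#'
#' Chains the full demand-side pipeline: estimates the four second-stage
#' IAIDS systems and (using the estimated stage-2 share intercepts as frozen
#' group-index weights) the first-stage system by iterated SUR; computes
#' own-price flexibilities/elasticities with delta-method bounds; forecasts
#' total expenditures from the packaged GDP path; simulates the two-stage
#' budget allocation along the habitat-driven harvest trajectories to get
#' implied prices; and measures annual consumer welfare per fishery group
#' with the group distance functions, monetised by the forecast group
#' expenditures, plus net present values.
#'
#' @param cfg a [run_config()].
#' @param panel optional landings panel (defaults to
#'   [gen_demand_history()]).
#' @param habitat optional habitat table (defaults to
#'   [gen_habitat_table()]).
#' @param gdp optional GDP path (defaults to [packaged_gdp_path()] anchored
#'   at the panel's own baseline expenditure).
#' @return list of class `welfare_result`: `stage1_fit`, `stage2_fits`,
#'   `elasticities` (own-term table for both stages), `expenditure`
#'   (forecast path), `prices` (baseline price and percent change by 2100
#'   per RCP), `welfare_annual` (year x group x RCP), `npv` (per group and
#'   total per RCP).  CSVs and a manifest are written when `cfg$output_dir`
#'   is set.
#' @export
run_welfare <- function(cfg, panel = NULL, habitat = NULL, gdp = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  scfg <- cfg$synthetic
  if (is.null(panel)) panel <- gen_demand_history(scfg)
  if (is.null(habitat)) habitat <- gen_habitat_table(scfg)
  if (is.null(gdp)) gdp <- packaged_gdp_path()

  # --- estimation -----------------------------------------------------
  s2obs <- stage2_observations(panel)
  groups <- names(s2obs)
  stage2_fits <- lapply(s2obs, function(o) estimate_sur(o$w, o$lnq))
  weights <- lapply(stage2_fits, function(p) p$alpha)
  s1obs <- stage1_observations(panel, weights)
  stage1_fit <- estimate_sur(s1obs$w, s1obs$lnq)

  elas1 <- flexibilities(stage1_fit, colMeans(s1obs$w))$own
  elas1 <- cbind(stage = "stage1", group = elas1$good, species = NA, elas1[-1])
  elas2 <- do.call(rbind, lapply(groups, function(g) {
    e <- flexibilities(stage2_fits[[g]], colMeans(s2obs[[g]]$w))$own
    cbind(stage = "stage2", group = g, species = e$good, e[-1])
  }))
  elasticities <- rbind(elas1, elas2)

  # --- expenditure forecast -------------------------------------------
  stats <- baseline_stats(panel)
  E0 <- sum(stats$summary$mean_revenue)   # baseline annual expenditure
  Epath <- forecast_expenditures(gdp$annual, eta = cfg$income_elasticity,
                                 anchor_year = 2020,
                                 anchor_expenditure = E0,
                                 base_expenditure = E0)
  years <- 2020:2100
  Epath <- Epath[Epath$year %in% years, ]
  E_t <- Epath$expenditure

  # --- harvest trajectories -------------------------------------------
  traj <- habitat_change(habitat)
  species_order <- unlist(lapply(groups, function(g)
    colnames(s2obs[[g]]$w)), use.names = FALSE)
  region_of <- stats::setNames(stats$summary$region, stats$summary$species)
  q_base <- stats::setNames(stats$summary$mean_pounds,
                            stats$summary$species)[species_order]

  out_prices <- list(); out_annual <- list(); out_npv <- list()
  for (rcp in rcps_of(cfg)) {
    mult <- vapply(species_order, function(sp)
      annualize(ensemble_deltas(traj, sp, region_of[sp], rcp), years),
      numeric(length(years)))
    lnm <- log(mult)

    lnQg <- vapply(groups, function(g) {
      sp <- colnames(s2obs[[g]]$w)
      drop(lnm[, sp, drop = FALSE] %*% weights[[g]][sp])
    }, numeric(length(years)))
    groupE <- allocate_stage1(stage1_fit, lnQg, E_t)

    speciesE <- matrix(NA_real_, length(years), length(species_order),
                       dimnames = list(years, species_order))
    for (g in groups) {
      sp <- colnames(s2obs[[g]]$w)
      speciesE[, sp] <- allocate_stage2(stage2_fits[[g]],
                                        lnm[, sp, drop = FALSE],
                                        groupE[, g])
    }
    q_abs <- sweep(mult, 2, q_base, "*")
    rownames(q_abs) <- years
    w1_base <- drop(solve_shares(stage1_fit, rep(0, length(groups))))
    names(w1_base) <- groups
    base_price <- unlist(lapply(groups, function(g) {
      sp <- colnames(s2obs[[g]]$w)
      w1_base[g] * E0 * stage2_fits[[g]]$alpha[sp] / q_base[sp]
    }))
    names(base_price) <- species_order
    pp <- implied_prices(speciesE, q_abs, base_price)
    out_prices[[rcp]] <- data.frame(
      rcp = rcp,
      group = rep(groups, vapply(groups, function(g)
        ncol(s2obs[[g]]$w), 0L)),
      species = species_order,
      baseline_price = unname(base_price),
      pct_change_2100 = unname(pp$pct_change_2100[species_order]))

    W <- matrix(NA_real_, length(years), length(groups),
                dimnames = list(years, groups))
    for (g in groups) {
      sp <- colnames(s2obs[[g]]$w)
      p2 <- stage2_fits[[g]]
      u0 <- benchmark_utility(p2)
      for (ti in seq_along(years))
        W[ti, g] <- annual_welfare(p2, mult[ti, sp], u0, groupE[ti, g],
                                   monetization = cfg$monetization)
    }
    ann <- data.frame(rcp = rcp, year = years, W, total = rowSums(W),
                      check.names = FALSE)
    out_annual[[rcp]] <- ann
    npv_in <- ann[ann$year >= 2021, c("year", groups)]
    out_npv[[rcp]] <- data.frame(
      rcp = rcp, group = c(groups, "total"),
      npv = unname(welfare_npv(npv_in, cfg$discount_rate, cfg$base_year)))
  }

  out <- structure(list(
    stage1_fit = stage1_fit, stage2_fits = stage2_fits,
    elasticities = elasticities, expenditure = Epath,
    prices = do.call(rbind, out_prices),
    welfare_annual = do.call(rbind, out_annual),
    npv = do.call(rbind, out_npv),
    baseline = stats), class = "welfare_result")
  rownames(out$prices) <- rownames(out$welfare_annual) <-
    rownames(out$npv) <- NULL

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(elasticities,
                     file.path(cfg$output_dir, "elasticities.csv"),
                     row.names = FALSE)
    utils::write.csv(Epath,
                     file.path(cfg$output_dir, "expenditure_forecast.csv"),
                     row.names = FALSE)
    utils::write.csv(out$prices, file.path(cfg$output_dir, "price_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(out$welfare_annual,
                     file.path(cfg$output_dir, "welfare_annual.csv"),
                     row.names = FALSE)
    utils::write.csv(out$npv, file.path(cfg$output_dir, "welfare_npv.csv"),
                     row.names = FALSE)
    write_manifest(cfg, cfg$output_dir, "welfare")
  }
  out
}

#' @export
print.welfare_result <- function(x, ...) {
  cat("Two-stage IAIDS welfare analysis\n")
  cat("Own-price elasticities (stage 1):\n")
  print(x$elasticities[x$elasticities$stage == "stage1",
                       c("group", "elasticity", "elas_lower", "elas_upper")],
        digits = 3)
  cat("Welfare NPV (MM 2018 US$):\n")
  print(x$npv, digits = 4)
  invisible(x)
}
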