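make_panel <- function(revenue_by_year, species = "sp", region = "East Coast") {
  years <- as.integer(names(revenue_by_year))
  panel <- data.frame(species = species, region = region, group = "g",
                      year = rep(years, each = 12),
                      month = rep(1:12, length(years)),
                      pounds_mm = 1,
                      revenue_mm_2018usd = rep(revenue_by_year / 12,
                                               each = 12))
  attr(panel, "deflated") <- TRUE
  panel
}

test_that("deflation rescales revenues by the CPI ratio and round-trips", {
  panel <- make_panel(c("2010" = 100))
  attr(panel, "deflated") <- NULL

  cpi_const <- c("2010" = 100, "2018" = 100)
  expect_equal(deflate(panel, cpi_const)$revenue_mm_2018usd,
               panel$revenue_mm_2018usd)

  cpi <- c("2010" = 200, "2018" = 250)
  out <- deflate(panel, cpi)
  expect_equal(sum(out$revenue_mm_2018usd), 125)
  expect_true(attr(out, "deflated"))

  # deflate then re-inflate restores the input
  back <- deflate(out, c("2010" = 250, "2018" = 200))
  expect_equal(back$revenue_mm_2018usd, panel$revenue_mm_2018usd,
               tolerance = 1e-12)

  expect_error(deflate(panel, c("2018" = 250)), "2010")
})

test_that("baseline statistics use annual totals and the sample SD", {
  st <- baseline_stats(make_panel(c("2010" = 100, "2011" = 120)))
  expect_equal(st$summary$mean_revenue, 110)
  expect_equal(st$summary$sd_revenue, sqrt((10^2 + 10^2) / 1))
  expect_equal(st$summary$mean_pounds, 12)

  flat <- baseline_stats(make_panel(c("2010" = 80, "2011" = 80, "2012" = 80)))
  expect_equal(flat$summary$sd_revenue, 0)

  one <- baseline_stats(make_panel(c("2010" = 80)))
  expect_true(is.na(one$summary$sd_revenue))

  # brute-force oracle on a synthetic panel
  panel <- gen_demand_history(synthetic_config(seed = 6))
  st2 <- baseline_stats(panel)
  for (k in c(1, 9)) {
    sp <- st2$summary$species[k]
    oracle <- sum(panel$revenue_mm_2018usd[panel$species == sp]) /
      length(unique(panel$year))
    expect_equal(st2$summary$mean_revenue[k], oracle)
  }
})

test_that("record matching classifies the hand-built fixture correctly", {
  landings <- data.frame(
    species = c("alpha fish", "beta fish", "skates", "tiny fish", "ghost fish"),
    region = "East Coast",
    mean_revenue = c(10, 5, 2, 0.05, 1))
  habitat <- data.frame(species = c("alpha fish", "beta-fish-syn"),
                        region = "East Coast")
  disp <- match_records(landings, habitat,
                        synonyms = c("beta fish" = "beta-fish-syn"),
                        multi_species_flags = "skates")
  expect_equal(disp$summary$count, c(1L, 1L, 1L, 1L, 1L))
  got <- setNames(disp$records$disposition, disp$records$species)
  expect_equal(got[["alpha fish"]], "matched-automated")
  expect_equal(got[["beta fish"]], "matched-manual")
  expect_equal(got[["skates"]], "excluded-multi-species")
  expect_equal(got[["tiny fish"]], "excluded-de-minimis")
  expect_equal(got[["ghost fish"]], "excluded-no-projection")
  # classes partition the records; revenue shares sum to 100
  expect_equal(sum(disp$summary$count), nrow(landings))
  expect_equal(sum(disp$summary$revenue_share_pct), 100)
})

test_that("de minimis is strict and curation conflicts are rejected", {
  landings <- data.frame(species = "edge fish", region = "Alaska",
                         mean_revenue = 0.1)
  disp <- match_records(landings, data.frame(species = character(),
                                             region = character()))
  expect_equal(disp$records$disposition, "excluded-no-projection")

  landings$mean_revenue <- 0.0999
  disp2 <- match_records(landings, data.frame(species = character(),
                                              region = character()))
  expect_equal(disp2$records$disposition, "excluded-de-minimis")

  expect_error(
    match_records(landings, data.frame(species = "x", region = "Alaska"),
                  synonyms = c("edge fish" = "x"),
                  multi_species_flags = "edge fish"),
    "ambiguous")
})

test_that("habitat percent changes and the GCM ensemble are mean-of-ratios", {
  bins <- c("B0", "T1", "T2", "T3", "T4")
  flat <- data.frame(species = "s", region = "r", rcp = "RCP4.5",
                     gcm = "CanESM2", bin = bins, habitat_total = 100)
  expect_equal(habitat_change(flat)$delta, rep(0, 10))

  one <- flat; one$habitat_total <- c(100, 100, 100, 100, 150)
  tr <- habitat_change(one)
  expect_equal(tr$delta[tr$bin == "T4" & tr$gcm == "ensemble"], 0.5)

  five <- do.call(rbind, lapply(1:5, function(k) {
    d <- flat; d$gcm <- paste0("gcm", k)
    d$habitat_total[d$bin == "T4"] <- 100 * (1 + k / 10)
    d
  }))
  tr5 <- habitat_change(five)
  expect_equal(tr5$delta[tr5$bin == "T4" & tr5$gcm == "ensemble"], 0.3)

  zero <- flat; zero$habitat_total[1] <- 0
  expect_error(habitat_change(zero), "baseline habitat is zero")
})

test_that("annualization anchors bin midpoints with flat tails", {
  expect_equal(unname(annualize(c(T1 = 0, T2 = 0, T3 = 0, T4 = 0))),
               rep(1, 80))
  m <- annualize(c(T1 = 0.10, T2 = 0.20, T3 = 0.20, T4 = 0.20))
  expect_equal(m[["2040"]], 1 + 0.10 + 0.10 * (2040 - 2030.5) / 20)
  m2 <- annualize(c(T1 = 0.1, T2 = 0.2, T3 = 0.3, T4 = 0.4))
  expect_equal(m2[["2095"]], m2[["2091"]])
  expect_equal(m2[["2095"]], 1.4)
  # between the baseline midpoint and T1 the path starts from zero change
  expect_lt(m2[["2021"]], m2[["2030"]])
})

test_that("proportional projection reproduces the blue-crab arithmetic", {
  m <- setNames(rep(1, 80), 2021:2100)
  expect_equal(unname(project_landings(50, m)), rep(50, 80))
  expect_equal(unname(project_landings(168.3, c("2090" = 1.156))),
               194.6, tolerance = 0.05)
  expect_equal(unname(project_landings(100, c("2090" = 0))), 0)
})

test_that("present value follows the closed-form annuity and is linear", {
  ones <- setNames(rep(1, 80), 2021:2100)
  expect_equal(present_value(ones), (1 - 1.03^-80) / 0.03, tolerance = 1e-10)
  expect_equal(annuity_factor(), 30.2008, tolerance = 5e-5)
  expect_equal(present_value(0 * ones), 0)
  set.seed(8)
  x <- setNames(runif(80), 2021:2100); y <- setNames(runif(80), 2021:2100)
  expect_equal(present_value(2 * x + 3 * y),
               2 * present_value(x) + 3 * present_value(y))
})

test_that("regional aggregation reproduces the printed totals arithmetic", {
  t5 <- packaged_table("table05_screening_regions_rcp45")
  species_pv <- data.frame(region = t5$region,
                           baseline_mean = 1000 * t5$baseline_bn,
                           delta_pv = 1000 * t5$delta_pv_bn)
  agg <- aggregate_regions(species_pv)
  expect_equal(agg$pct_change[agg$region == "Total"], -0.9, tolerance = 0.05)
  # single species per region: regional rows equal the species rows
  expect_equal(agg$delta_pv[1:4], species_pv$delta_pv)
  # regional totals are exact sums of members
  expect_equal(agg$delta_pv[agg$region == "Total"], sum(species_pv$delta_pv))
  # all-negative species values give negative regional totals
  neg <- species_pv; neg$delta_pv <- -abs(neg$delta_pv)
  expect_true(all(aggregate_regions(neg)$delta_pv < 0))
})

test_that("Monte Carlo interval behaves like the normal-theory oracle", {
  # degenerate case: no interannual variance, identical GCMs
  ci0 <- monte_carlo_ci(rep(100, 10), rep(1.1, 5), n_draws = 500, seed = 1)
  expect_equal(unname(ci0["lower"]), unname(ci0["point"]))
  expect_equal(unname(ci0["upper"]), 10)

  # reproducibility
  x <- c(95, 103, 99, 101, 97, 104, 100, 98, 102, 96)
  m <- c(1.05, 1.08, 1.10, 1.12, 1.15)
  expect_identical(monte_carlo_ci(x, m, 2000, seed = 9),
                   monte_carlo_ci(x, m, 2000, seed = 9))
  expect_false(identical(monte_carlo_ci(x, m, 2000, seed = 9),
                         monte_carlo_ci(x, m, 2000, seed = 10)))

  # normal-theory width with a single multiplier
  mu <- 100; sigma <- 5; n <- 10
  set.seed(33)
  yrs <- rnorm(n, mu, sigma)
  ci <- monte_carlo_ci(yrs, rep(1.1, 5), n_draws = 20000, seed = 3)
  s_boot <- sqrt(mean((yrs - mean(yrs))^2) / n)  # bootstrap sd of the mean
  width_theory <- 100 * 2 * qnorm(0.975) * 1.1 * s_boot / mean(yrs)
  expect_equal(unname(ci["upper"] - ci["lower"]), width_theory,
               tolerance = 0.1)

  # point estimate is the ensemble-mean percent change
  expect_equal(unname(monte_carlo_ci(x, m, 100, seed = 2)["point"]),
               100 * (mean(m) - 1))
})
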