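#' Read a packaged baseline table
#'
#' The package ships small CSV versions of the published baseline and
#' screening summaries (regional revenue coverage, top-20 screening results,
#' the 16-species group assignment, harvest projections, the expenditure
#' forecast and welfare present values).  They serve as calibration inputs
#' for the synthetic generator and as printed-number inputs for the
#' reproduction scripts.
#'
#' @param name table name, e.g. `"table09_species_groups"`.
#' @return a data.frame.
#' @export
packaged_table <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "fishclim")
  if (path == "") stop("no packaged table called ", name, call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}

#' Packaged GDP path with annual interpolation
#'
#' Returns the decadal GDP forecast (billions of 2018 US$) used to project
#' seafood expenditures, linearly interpolated to annual resolution over
#' 2020--2100, together with the 2007--2016 average GDP and the baseline and
#' anchor expenditures on the modeled species.
#'
#' @return list of class `gdp_path`: `annual` (data.frame year/gdp),
#'   `decadal`, `base_gdp`, `base_expenditure`, `anchor_year`,
#'   `anchor_expenditure`.
#' @export
packaged_gdp_path <- function() {
  tab <- packaged_table("table14_expenditure_forecast")
  dec <- tab[!is.na(tab$year), ]
  years <- seq(min(dec$year), max(dec$year))
  ann <- stats::approx(dec$year, dec$gdp_billion_2018usd, xout = years)
  structure(list(
    annual = data.frame(year = years, gdp = ann$y),
    decadal = dec[, c("year", "gdp_billion_2018usd")],
    base_gdp = tab$gdp_billion_2018usd[is.na(tab$year)],
    base_expenditure = tab$expenditure_mm_2018usd[is.na(tab$year)],
    anchor_year = 2020,
    anchor_expenditure = dec$expenditure_mm_2018usd[dec$year == 2020]),
    class = "gdp_path")
}

#' @export
print.gdp_path <- function(x, ...) {
  cat("GDP path", min(x$annual$year), "-", max(x$annual$year),
      "(annual, linear between decadal values)\n")
  cat("base GDP:", x$base_gdp, " anchor expenditure:",
      x$anchor_expenditure, "MM 2018US$ at", x$anchor_year, "\n")
  invisible(x)
}

# deterministic symmetric matrix with zero row/column sums: double-centred
# diagonal seed.
centered_gamma <- function(d) {
  n <- length(d)
  H <- diag(n) - 1 / n
  H %*% diag(d) %*% H
}

# share-proportional quantity-response matrix: c (diag(a) - a a').
# Symmetric with zero row/column sums, and scales each good's own term with
# its share, so every true own flexibility sits near -(1 - c) regardless of
# how small the share is.
share_gamma <- function(a, c = 0.35) {
  c * (diag(a) - outer(a, a))
}

default_region_map <- c(
  "American lobster" = "East Coast", "Blue crab" = "Gulf Coast",
  "Dungeness crab" = "West Coast", "Florida stone crab (claws)" = "Gulf Coast",
  "Sea scallop" = "East Coast", "White shrimp" = "Gulf Coast",
  "Brown shrimp" = "Gulf Coast", "California market squid" = "West Coast",
  "Pacific halibut" = "Alaska", "Sablefish" = "Alaska",
  "Chinook salmon" = "West Coast", "Summer flounder" = "East Coast",
  "Walleye pollock" = "Alaska", "Pacific cod" = "Alaska",
  "Yellowfin sole" = "Alaska", "Chum salmon" = "Alaska")

#' Configuration for the synthetic fisheries inputs
#'
#' Assembles the full specification of a synthetic study: the 4-group x
#' 4-species panel layout (defaulting to the 16 modeled fisheries and their
#' published group assignment), true two-stage IAIDS parameters calibrated so
#' that the share intercepts equal the observed baseline revenue shares,
#' baseline quantities, per-bin habitat trends per RCP (defaulting to the
#' published ensemble-mean harvest changes), and the noise levels.
#'
#' Default parameter choices: stage-1 gamma diagonals around 0.05 and stage-2
#' around 0.02 (diagonal-dominant, so all own-price elasticities are
#' negative); betas are small with zero sum; quantity dynamics are a 12-month
#' sinusoid plus AR(1) (rho = 0.5) noise on log quantities, so drawn
#' quantities are positive by construction.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_months number of monthly observations (default 120, i.e.
#'   2007--2016).
#' @param start_year first calendar year of the panel.
#' @param species_groups named list: group label -> character vector of
#'   member species.
#' @param regions named character vector species -> region.
#' @param true_params_stage1 [iaids_params()] for the 4 groups.
#' @param true_params_stage2 named list of [iaids_params()], one per group.
#' @param share_noise_sd sd of the additive share noise (first n-1 goods;
#'   the last share is the residual so adding-up holds by construction).
#' @param habitat_trend data.frame with columns species, rcp, bin
#'   (T1..T4) and trend (fractional change vs the baseline bin).
#' @param gcm_spread_sd sd of the log-normal across-GCM noise.
#' @param total_expenditure_level monthly total expenditure, MM 2018 US$.
#' @param baseline_quantities named vector of baseline annual landings
#'   (MM lb) per species.
#' @param seasonal_amplitude,ar_rho,ar_sd log-quantity dynamics.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_months = 120L,
                             start_year = 2007L,
                             species_groups = NULL,
                             regions = default_region_map,
                             true_params_stage1 = NULL,
                             true_params_stage2 = NULL,
                             share_noise_sd = 0.01,
                             habitat_trend = NULL,
                             gcm_spread_sd = 0.05,
                             total_expenditure_level = 3079.6 / 12,
                             baseline_quantities = NULL,
                             seasonal_amplitude = 0.15,
                             ar_rho = 0.5,
                             ar_sd = 0.1) {
  t9 <- packaged_table("table09_species_groups")
  if (is.null(species_groups)) {
    species_groups <- split(t9$fishery, t9$group)
    # stable presentation order
    species_groups <- species_groups[c("Lobster/crab", "Shrimp/mollusk",
                                       "High-value fish", "Low-value fish")]
  }
  groups <- names(species_groups)
  species <- unlist(species_groups, use.names = FALSE)
  sizes <- lengths(species_groups)

  rev_mean <- stats::setNames(t9$mean_mm, t9$fishery)
  if (is.null(true_params_stage1)) {
    grev <- vapply(species_groups, function(s)
      sum(rev_mean[s], na.rm = TRUE), numeric(1))
    a1 <- grev / sum(grev)
    true_params_stage1 <- iaids_params(
      alpha = a1,
      beta = c(0.04, -0.02, -0.01, -0.01)[seq_along(groups)],
      gamma = share_gamma(unname(a1), c = 0.35),
      labels = groups)
  }
  if (is.null(true_params_stage2)) {
    true_params_stage2 <- lapply(seq_along(groups), function(g) {
      s <- species_groups[[g]]
      a <- rev_mean[s]
      if (anyNA(a)) a <- rep(1, length(s))
      a <- a / sum(a)
      b <- c(0.02, -0.01, -0.005, -0.005)[seq_along(s)]
      b <- b - mean(b)
      iaids_params(alpha = a, beta = b,
                   gamma = share_gamma(unname(a), c = 0.3 + 0.02 * g),
                   labels = s)
    })
    names(true_params_stage2) <- groups
  }
  if (is.null(baseline_quantities)) {
    t10 <- packaged_table("table10_harvest_rcp45")
    baseline_quantities <- stats::setNames(t10$baseline_mmlb, t10$fishery)
    missing <- setdiff(species, names(baseline_quantities))
    if (length(missing))
      baseline_quantities[missing] <- 50
    baseline_quantities <- baseline_quantities[species]
  }
  if (is.null(habitat_trend)) {
    habitat_trend <- do.call(rbind, lapply(c("RCP4.5", "RCP8.5"), function(r) {
      tab <- packaged_table(if (r == "RCP4.5") "table10_harvest_rcp45"
                            else "table11_harvest_rcp85")
      p50 <- stats::setNames(tab$pct_2050 / 100, tab$fishery)[species]
      p90 <- stats::setNames(tab$pct_2090 / 100, tab$fishery)[species]
      p50[is.na(p50)] <- 0; p90[is.na(p90)] <- 0
      data.frame(species = rep(species, 4L),
                 rcp = r,
                 bin = rep(c("T1", "T2", "T3", "T4"), each = length(species)),
                 trend = c(0.5 * p50, p50, (p50 + p90) / 2, p90))
    }))
  }
  stopifnot(share_noise_sd >= 0, gcm_spread_sd >= 0,
            all(species %in% names(regions)))
  cfg <- structure(list(
    seed = as.integer(seed), n_months = as.integer(n_months),
    start_year = as.integer(start_year),
    species_groups = species_groups, groups = groups, species = species,
    regions = regions[species],
    true_params_stage1 = true_params_stage1,
    true_params_stage2 = true_params_stage2,
    share_noise_sd = share_noise_sd,
    habitat_trend = habitat_trend, gcm_spread_sd = gcm_spread_sd,
    total_expenditure_level = total_expenditure_level,
    baseline_quantities = baseline_quantities,
    seasonal_amplitude = seasonal_amplitude, ar_rho = ar_rho, ar_sd = ar_sd),
    class = "synthetic_config")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic fisheries configuration:", length(x$species), "species in",
      length(x$groups), "groups,", x$n_months, "months, seed", x$seed, "\n")
  invisible(x)
}

# evaluate an expression under a local RNG state derived from (seed, offset),
# restoring the caller's state afterwards
with_local_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((seed * 101L + offset) %% .Machine$integer.max)
  force(expr)
}

#' Generate a synthetic monthly landings panel
#'
#' Draws log quantities per species (species mean + 12-month sinusoid +
#' AR(1) noise), computes expenditure shares from the true two-stage IAIDS
#' share equations (Stone-index consistent, via [solve_shares()]) with
#' additive mean-zero noise on the first n-1 shares (the last share is the
#' residual, so shares sum to 1 exactly within each stage), and derives
#' revenues as share x stage expenditure.  Log-quantity arguments to the
#' share equations are centred at the panel's per-species geometric mean, the
#' package-wide quantity normalisation.  The stage-1 group quantity index is
#' the Stone index with the true stage-2 share intercepts as frozen weights.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return a `LandingsPanel` data.frame with columns species, region, group,
#'   year, month, pounds_mm, revenue_mm_2018usd; attribute `deflated = TRUE`
#'   (values are 2018 US$).
#' @export
gen_demand_history <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_sp <- length(cfg$species)
  tt <- seq_len(cfg$n_months)
  with_local_seed(cfg$seed, 1L, {
    lnq_raw <- matrix(0, cfg$n_months, n_sp,
                      dimnames = list(NULL, cfg$species))
    for (i in seq_len(n_sp)) {
      eps <- stats::rnorm(cfg$n_months, 0, cfg$ar_sd)
      ar <- stats::filter(eps, cfg$ar_rho, method = "recursive")
      lnq_raw[, i] <- log(cfg$baseline_quantities[i] / 12) +
        cfg$seasonal_amplitude * sin(2 * pi * (tt + i) / 12) + as.numeric(ar)
    }
    lnq <- scale(lnq_raw, center = TRUE, scale = FALSE)  # geometric-mean centring

    # stage-2 shares within each group
    w2 <- matrix(NA_real_, cfg$n_months, n_sp,
                 dimnames = list(NULL, cfg$species))
    for (g in cfg$groups) {
      sp <- cfg$species_groups[[g]]
      p2 <- cfg$true_params_stage2[[g]]
      shares <- solve_shares(p2, lnq[, sp, drop = FALSE])
      shares <- add_share_noise(shares, cfg$share_noise_sd)
      w2[, sp] <- shares
    }

    # stage-1 group quantity indices and shares
    lnQg <- vapply(cfg$groups, function(g) {
      sp <- cfg$species_groups[[g]]
      a2 <- cfg$true_params_stage2[[g]]$alpha
      drop(lnq[, sp, drop = FALSE] %*% a2)
    }, numeric(cfg$n_months))
    w1 <- solve_shares(cfg$true_params_stage1, lnQg)
    w1 <- add_share_noise(w1, cfg$share_noise_sd)

    if (any(w2 <= 0) || any(w1 <= 0))
      stop("non-positive expenditure share drawn; lower share_noise_sd or ",
           "gamma magnitudes", call. = FALSE)

    E <- cfg$total_expenditure_level
    group_of <- rep(cfg$groups, lengths(cfg$species_groups))
    revenue <- w2 * w1[, group_of, drop = FALSE] * E

    panel <- data.frame(
      species = rep(cfg$species, each = cfg$n_months),
      region = rep(unname(cfg$regions), each = cfg$n_months),
      group = rep(group_of, each = cfg$n_months),
      year = rep(cfg$start_year + (tt - 1L) %/% 12L, n_sp),
      month = rep((tt - 1L) %% 12L + 1L, n_sp),
      pounds_mm = as.numeric(exp(lnq_raw)),
      revenue_mm_2018usd = as.numeric(revenue))
    attr(panel, "deflated") <- TRUE
    panel
  })
}

# additive Gaussian noise on the first n-1 shares; last share is the
# residual, so adding-up holds by construction.  Rows that would emit a
# non-positive share are redrawn (truncation), mirroring the positivity rule
# for quantities.
add_share_noise <- function(w, sd) {
  if (sd == 0) return(w)
  n <- ncol(w)
  out <- w
  perturb <- function(rows) {
    noise <- matrix(stats::rnorm(length(rows) * (n - 1L), 0, sd),
                    length(rows), n - 1L)
    v <- w[rows, seq_len(n - 1L), drop = FALSE] + noise
    cbind(v, 1 - rowSums(v))
  }
  todo <- seq_len(nrow(w))
  for (try in 1:1000) {
    out[todo, ] <- perturb(todo)
    todo <- which(apply(out, 1, function(r) any(r <= 0)))
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not draw positive shares; lower share_noise_sd or gamma ",
         "magnitudes", call. = FALSE)
  out
}

#' Generate a synthetic habitat projection table
#'
#' Emits per (species, region, RCP, GCM, bin) habitat totals: a common
#' baseline level times `(1 + trend(bin))` times log-normal GCM noise.  The
#' baseline bin (B0) is shared exactly across the five GCMs; the future bins
#' T1--T4 carry independent noise per GCM and bin.
#'
#' @param cfg a [synthetic_config()].
#' @param baseline_level habitat total in the baseline bin (dimensionless).
#' @return a `HabitatProjectionTable` data.frame with columns species,
#'   region, rcp, gcm, bin, habitat_total.
#' @export
gen_habitat_table <- function(cfg, baseline_level = 100) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gcms <- c("CanESM2", "CCSM4", "GISS-E2-R", "HadGEM2-ES", "MIROC5")
  bins <- c("B0", "T1", "T2", "T3", "T4")
  with_local_seed(cfg$seed, 2L, {
    grid <- expand.grid(species = cfg$species, rcp = c("RCP4.5", "RCP8.5"),
                        gcm = gcms, bin = bins,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$region <- unname(cfg$regions[grid$species])
    grid <- merge(grid, cfg$habitat_trend, all.x = TRUE,
                  by = c("species", "rcp", "bin"))
    grid$trend[grid$bin == "B0"] <- 0
    if (anyNA(grid$trend))
      stop("habitat_trend must cover every species x rcp x bin", call. = FALSE)
    noise <- exp(stats::rnorm(nrow(grid), 0, cfg$gcm_spread_sd))
    noise[grid$bin == "B0"] <- 1
    grid$habitat_total <- baseline_level * (1 + grid$trend) * noise
    grid <- grid[order(grid$species, grid$rcp, grid$gcm,
                       match(grid$bin, bins)),
                 c("species", "region", "rcp", "gcm", "bin", "habitat_total")]
    rownames(grid) <- NULL
    grid
  })
}

#' Write the synthetic inputs as CSV files with a JSON sidecar
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- gen_demand_history(cfg)
  habitat <- gen_habitat_table(cfg)
  gdp <- packaged_gdp_path()
  paths <- file.path(dir, c("landings.csv", "habitat.csv", "gdp.csv",
                            "synthetic_config.json"))
  utils::write.csv(panel, paths[1], row.names = FALSE)
  utils::write.csv(habitat, paths[2], row.names = FALSE)
  utils::write.csv(
    data.frame(year = gdp$annual$year, gdp_billion_2018usd = gdp$annual$gdp),
    paths[3], row.names = FALSE)
  sidecar <- list(
    seed = cfg$seed, n_months = cfg$n_months, start_year = cfg$start_year,
    species_groups = cfg$species_groups,
    share_noise_sd = cfg$share_noise_sd, gcm_spread_sd = cfg$gcm_spread_sd,
    total_expenditure_level = cfg$total_expenditure_level,
    stage1 = list(alpha = cfg$true_params_stage1$alpha,
                  beta = cfg$true_params_stage1$beta,
                  gamma = cfg$true_params_stage1$gamma),
    stage2 = lapply(cfg$true_params_stage2, function(p)
      list(alpha = p$alpha, beta = p$beta, gamma = p$gamma)))
  jsonlite::write_json(sidecar, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Share/log-quantity observations for second-stage estimation
#'
#' Converts a landings panel into the per-group estimation inputs: monthly
#' within-group expenditure shares and per-species log quantities centred at
#' the panel geometric mean (the package quantity normalisation).
#'
#' @param panel a landings panel (see [gen_demand_history()]).
#' @return named list per group: `w` (T x n shares), `lnq` (T x n centred
#'   log quantities), `E` (monthly group expenditure).
#' @export
stage2_observations <- function(panel) {
  split_g <- split(panel, panel$group)
  lapply(split_g, function(d) {
    q <- stats::xtabs(pounds_mm ~ interaction(year, month, lex.order = TRUE)
                      + species, data = d)
    r <- stats::xtabs(revenue_mm_2018usd ~
                        interaction(year, month, lex.order = TRUE) + species,
                      data = d)
    q <- matrix(q, nrow(q), ncol(q), dimnames = dimnames(q))
    r <- matrix(r, nrow(r), ncol(r), dimnames = dimnames(r))
    lnq <- scale(log(q), center = TRUE, scale = FALSE)
    E <- rowSums(r)
    list(w = r / E, lnq = lnq, E = E)
  })
}

#' Share/quantity-index observations for first-stage estimation
#'
#' Builds monthly group expenditure shares and group log-quantity indices
#' (Stone index over member species with frozen weights, typically the
#' estimated stage-2 share intercepts).
#'
#' @param panel a landings panel.
#' @param weights named list per group of member-species weights summing
#'   to 1.
#' @return list: `w` (T x G shares), `lnq` (T x G group indices), `E`
#'   (monthly total expenditure).
#' @export
stage1_observations <- function(panel, weights) {
  s2 <- stage2_observations(panel)
  groups <- names(s2)
  lnq <- vapply(groups, function(g) {
    wt <- weights[[g]][colnames(s2[[g]]$lnq)]
    drop(s2[[g]]$lnq %*% wt)
  }, numeric(nrow(s2[[1]]$lnq)))
  Eg <- vapply(groups, function(g) s2[[g]]$E, numeric(nrow(lnq)))
  E <- rowSums(Eg)
  list(w = Eg / E, lnq = lnq, E = E)
}
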