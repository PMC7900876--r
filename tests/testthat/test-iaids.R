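test_that("constructor enforces the utility-theoretic restriction set", {
  p <- tiny_params()
  expect_s3_class(p, "iaids_params")
  expect_equal(sum(p$alpha), 1)
  expect_equal(sum(p$beta), 0)
  expect_equal(unname(rowSums(p$gamma)), rep(0, 4))

  expect_error(iaids_params(c(0.5, 0.4), c(0.1, -0.1), matrix(0, 2, 2)),
               "adding-up")
  expect_error(iaids_params(c(0.5, 0.5), c(0.1, 0.1), matrix(0, 2, 2)),
               "adding-up")
  g <- matrix(c(0.1, -0.1, 0.1, -0.1), 2, 2)
  expect_error(iaids_params(c(0.5, 0.5), c(0.1, -0.1), g), "symmetry")
  g2 <- matrix(c(0.1, 0.1, 0.1, 0.1), 2, 2)
  expect_error(iaids_params(c(0.5, 0.5), c(0.1, -0.1), g2), "homogeneity")
  expect_error(iaids_params(c(0.5, 0.5), c(0, 0), matrix(0, 2, 2), beta0 = 0),
               "beta0")
})

test_that("free-parameter packing round-trips and counts 12 for n = 4", {
  set.seed(11)
  for (n in c(3, 4, 5)) {
    p <- tiny_params(n, d = 0.04)
    th <- fishclim:::iaids_free(p)
    expect_length(th, (n - 1) + (n - 1) + n * (n - 1) / 2)
    p2 <- fishclim:::iaids_from_free(th, n)
    expect_equal(unname(p2$alpha), unname(p$alpha))
    expect_equal(unname(p2$beta), unname(p$beta))
    expect_equal(unname(p2$gamma), unname(p$gamma))
  }
  expect_identical(fishclim:::n_free_params(4L), 12)
})

test_that("Stone index is the share-weighted mean of log quantities", {
  expect_equal(stone_index(c(0.5, 0.5), c(log(2), log(8))), log(4))
  expect_equal(stone_index(c(0.25, 0.25, 0.25, 0.25), c(1, 2, 3, 4)), 2.5)
  expect_equal(stone_index(c(0.3, 0.7), c(0, 0)), 0)
})

test_that("predicted shares respect the share equations and sum to one", {
  p <- tiny_params()
  expect_equal(unname(predict_shares(p, rep(0, 4))), unname(p$alpha))

  p0 <- iaids_params(c(0.4, 0.3, 0.2, 0.1), rep(0, 4), matrix(0, 4, 4))
  set.seed(3)
  for (k in 1:20) {
    lnq <- rnorm(4)
    expect_equal(unname(predict_shares(p0, lnq)), c(0.4, 0.3, 0.2, 0.1))
    expect_equal(sum(predict_shares(p, lnq)), 1, tolerance = 1e-12)
    w <- solve_shares(p, lnq)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # Stone-consistent fixed point
    expect_equal(unname(w),
                 unname(drop(p$alpha + p$gamma %*% lnq -
                               p$beta * stone_index(w, lnq))),
                 tolerance = 1e-12)
  }
})

test_that("SUR recovers the truth exactly on a noise-free panel", {
  cfg <- noise_free_cfg()
  panel <- gen_demand_history(cfg)
  s2 <- stage2_observations(panel)
  for (g in names(s2)) {
    fit <- estimate_sur(s2[[g]]$w, s2[[g]]$lnq)
    tr <- align_params(cfg$true_params_stage2[[g]], fit$labels)
    expect_lt(max(abs(fit$alpha - tr$alpha)), 1e-6)
    expect_lt(max(abs(fit$beta - tr$beta)), 1e-6)
    expect_lt(max(abs(fit$gamma - tr$gamma)), 1e-6)
  }
  weights <- lapply(s2, function(o) estimate_sur(o$w, o$lnq)$alpha)
  s1 <- stage1_observations(panel, weights)
  fit1 <- estimate_sur(s1$w, s1$lnq)
  tr1 <- align_params(cfg$true_params_stage1, fit1$labels)
  expect_lt(max(abs(fit1$alpha - tr1$alpha)), 1e-6)
  expect_lt(max(abs(fit1$gamma - tr1$gamma)), 1e-6)
})

test_that("estimation is equivariant to which equation is dropped", {
  cfg <- noise_free_cfg()
  panel <- gen_demand_history(cfg)
  o <- stage2_observations(panel)[["Shrimp/mollusk"]]
  f_last <- estimate_sur(o$w, o$lnq, drop = 4)
  f_first <- estimate_sur(o$w, o$lnq, drop = 1)
  expect_lt(max(abs(f_last$alpha - f_first$alpha)), 1e-6)
  expect_lt(max(abs(f_last$beta - f_first$beta)), 1e-6)
  expect_lt(max(abs(f_last$gamma - f_first$gamma)), 1e-6)
})

test_that("noisy-panel estimates stay within three standard errors of truth", {
  cfg <- synthetic_config(seed = 42, n_months = 120, share_noise_sd = 0.01)
  panel <- gen_demand_history(cfg)
  s2 <- stage2_observations(panel)
  for (g in names(s2)) {
    fit <- estimate_sur(s2[[g]]$w, s2[[g]]$lnq)
    tr <- align_params(cfg$true_params_stage2[[g]], fit$labels)
    z <- abs(fishclim:::iaids_free(fit) - fishclim:::iaids_free(tr)) /
      sqrt(diag(fit$vcov))
    expect_lt(max(z), 3)
    # restrictions hold exactly by construction on the estimates
    expect_equal(sum(fit$alpha), 1, tolerance = 1e-12)
    expect_equal(sum(fit$beta), 0, tolerance = 1e-12)
    expect_equal(max(abs(fit$gamma - t(fit$gamma))), 0, tolerance = 1e-12)
    expect_equal(max(abs(rowSums(fit$gamma))), 0, tolerance = 1e-12)
  }
})

test_that("estimator guards against unusable inputs", {
  p <- tiny_params()
  set.seed(9)
  lnq <- matrix(rnorm(20 * 4), 20, 4)
  w <- solve_shares(p, lnq)
  expect_error(estimate_sur(w, lnq), "at least")
  lnq2 <- matrix(rnorm(120 * 4), 120, 4)
  lnq2[, 2] <- 0
  expect_error(estimate_sur(solve_shares(p, lnq2), lnq2), "degenerate")
})

test_that("flexibility matrix is -I when gamma and beta vanish", {
  p0 <- iaids_params(c(0.4, 0.3, 0.2, 0.1), rep(0, 4), matrix(0, 4, 4))
  ft <- flexibilities(p0, c(0.4, 0.3, 0.2, 0.1), conf = FALSE)
  expect_equal(unname(ft$flex), -diag(4))
  expect_equal(unname(ft$elas), -diag(4))
  expect_equal(ft$own$flexibility, rep(-1, 4), ignore_attr = TRUE)
})

test_that("analytic flexibilities match finite differences of inverse demand", {
  p <- synthetic_config(seed = 1)$true_params_stage2[[1]]
  wbar <- unname(p$alpha)
  Fa <- flexibilities(p, wbar, conf = FALSE)$flex
  # implied inverse demand p_i = w_i E / q_i at the base point lnq = 0,
  # with shares from the exact translog-index share equations
  lnp <- function(lnq) log(predict_shares(p, lnq)) - lnq
  h <- 1e-5
  for (i in 1:4) for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    fd <- (lnp(e)[i] - lnp(-e)[i]) / (2 * h)
    expect_equal(unname(Fa[i, j]), unname(fd), tolerance = 1e-4)
  }
})

test_that("delta method matches closed forms and degenerates sensibly", {
  cfg <- synthetic_config(seed = 42)
  panel <- gen_demand_history(cfg)
  o <- stage2_observations(panel)[["Lobster/crab"]]
  fit <- estimate_sur(o$w, o$lnq)
  th <- fishclim:::iaids_free(fit)

  # single free parameter: interval is theta_hat +/- 1.96 sqrt(vcov entry)
  ci <- delta_method_ci(fit, function(p) p$alpha[[1]])
  expect_equal(unname(ci["point"]), unname(th[1]), tolerance = 1e-8)
  expect_equal(unname(ci["se"]), sqrt(fit$vcov[1, 1]), tolerance = 1e-6)

  # linear statistic c'theta: closed-form c' V c
  cvec <- c(1, -2, 0.5, rep(0, 9))
  stat <- function(p) sum(cvec * fishclim:::iaids_free(p))
  ci2 <- delta_method_ci(fit, stat)
  expect_equal(unname(ci2["se"]),
               sqrt(drop(t(cvec) %*% fit$vcov %*% cvec)), tolerance = 1e-6)
  expect_equal(unname(ci2["upper"] - ci2["lower"]),
               2 * qnorm(0.975) * sqrt(drop(t(cvec) %*% fit$vcov %*% cvec)),
               tolerance = 1e-6)

  # zero covariance: zero-width interval
  fit0 <- fit; fit0$vcov <- matrix(0, 12, 12)
  ci0 <- delta_method_ci(fit0, function(p) p$alpha[[1]])
  expect_equal(unname(ci0["lower"]), unname(ci0["upper"]))

  fit_na <- fit; fit_na$vcov <- NULL
  expect_error(delta_method_ci(fit_na, stat), "covariance")
})

test_that("delta-method interval width shrinks like 1/sqrt(T)", {
  width_at <- function(n_months) {
    cfg <- synthetic_config(seed = 5, n_months = n_months,
                            share_noise_sd = 0.01)
    o <- stage2_observations(gen_demand_history(cfg))[["Lobster/crab"]]
    fit <- estimate_sur(o$w, o$lnq)
    ci <- delta_method_ci(fit, function(p) p$gamma[1, 1])
    unname(ci["upper"] - ci["lower"])
  }
  ratio <- width_at(480) / width_at(120)
  expect_equal(ratio, 0.5, tolerance = 0.25)
})
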