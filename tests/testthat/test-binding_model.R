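test_that("the exact isotherm reproduces limiting and worked values", {
  expect_equal(isotherm(0.1, 0, 10, 0.2), 0)
  # hand evaluation: S = 20.1, sqrt(S^2 - 4*0.1*10) = 20.000250, so the
  # bound fraction is 0.498750
  expect_equal(isotherm(0.1, 10, 10, 0.2), 0.099750, tolerance = 1e-6)
  # saturation: kd ~ 0, huge ligand excess
  expect_equal(isotherm(0.1, 1000, 1e-9, 0.2), 0.2, tolerance = 1e-9)
  expect_error(isotherm(0, 10, 10, 0.2), "positive")
  expect_error(isotherm(-1, 10, 10, 0.2), "positive")
  expect_error(isotherm(0.1, -5, 10, 0.2), ">= 0")
})

test_that("the isotherm is monotone, concave and bounded in L", {
  for (kd in c(0.5, 8.7, 100)) {
    L <- seq(0, 200, length.out = 400)
    y <- isotherm(0.1, L, kd, 1)
    expect_true(all(diff(y) >= -1e-12))            # monotone
    expect_true(all(diff(diff(y)) <= 1e-10))       # concave
    expect_true(all(y >= 0 & y <= pmin(1, L / 0.1) + 1e-12))
  }
  # stoichiometric cap: less ligand than protein sites
  expect_lte(isotherm(1, 0.5, 1e-9, 1), 0.5 + 1e-9)
})

test_that("the isotherm collapses to the hyperbola when protein is dilute", {
  for (kd in c(5, 32.7)) {
    T0 <- 1e-3 * kd
    L <- seq(0, 100 * kd, length.out = 500)
    expect_lt(max(abs(isotherm(T0, L, kd, 1) - L / (L + kd))), 1e-3)
  }
})

test_that("noiseless global fits recover the shared Kd", {
  tabs <- make_isotherm_tables(c("7" = 0.10, "8" = 0.25), kd = 10)
  fit <- fit_site(build_profile(tabs), binding_site("toy", c(7, 8)),
                  T0 = 0.1)
  expect_true(fit$converged)
  expect_equal(fit$kd, 10, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.999999)
  expect_equal(unname(fit$dmax), c(0.10, 0.25), tolerance = 1e-4)
  expect_lt(fit$p_value, 1e-10)
  # fitted/residuals/predict are coherent
  expect_equal(fitted(fit) + residuals(fit), fit$data$observed)
  pr <- predict(fit, c(0, 10))
  expect_equal(dim(pr), c(2, 2))
  expect_equal(pr[, 1], c("7" = 0, "8" = 0), ignore_attr = TRUE)
})

test_that("single-residue fits agree with the brute-force grid oracle", {
  set.seed(20)
  for (i in 1:8) {
    kd_true <- runif(1, 2, 60)
    dmax_true <- runif(1, 0.05, 0.3)
    L <- c(0, 5, 10, 20, 40, 60, 80, 100)
    y <- isotherm(0.1, L, kd_true, dmax_true) +
      rnorm(length(L), 0, 0.002)
    y <- pmax(y, 0)
    tabs <- lapply(seq_along(L), function(j)
      shift_table(50, "A", 120, 8 + y[j], condition(L[j], 0.1)))
    prof <- build_profile(tabs)
    fit <- fit_site(prof, binding_site("one", 50), T0 = 0.1)
    kd_grid <- grid_fit_kd(prof$ligand_conc, prof$delta_combined[1, ], 0.1)
    expect_equal(fit$kd, kd_grid, tolerance = 1e-3)
  }
})

test_that("under-determined site fits fail loudly", {
  tabs <- make_isotherm_tables(c("7" = 0.10), kd = 10,
                               points = c(0, 20, 100))
  prof <- build_profile(tabs)
  prof$tracked[1, 3] <- FALSE     # residue now tracked at only 2 points
  expect_error(fit_site(prof, binding_site("x", 7), T0 = 0.1),
               "< 3 titration points")
  prof2 <- build_profile(make_isotherm_tables(c("7" = 0.1), kd = 10,
                                              points = c(0, 20)))
  expect_error(fit_site(prof2, binding_site("x", 7), T0 = 0.1),
               "titration points")
  prof3 <- build_profile(make_isotherm_tables(c("7" = 0.1), kd = 10))
  expect_error(fit_site(prof3, binding_site("x", 99), T0 = 0.1),
               "not in profile")
})

test_that("standard errors calibrate against replicate scatter", {
  # over seeds, the empirical sd of recovered kd should be within a
  # factor of 2 of the mean reported kd_se
  kds <- ses <- numeric(30)
  for (s in seq_len(30)) {
    sim <- simulate_titration(titration_sim_spec(seed = 400 + s))
    prof <- build_profile(sim$tables)
    f <- fit_site(prof, binding_site("site-1", c(66, 99)), T0 = 0.1)
    kds[s] <- f$kd; ses[s] <- f$kd_se
  }
  ratio <- sd(kds) / mean(ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("occupancy follows the ligand-excess hyperbola", {
  oc <- fraction_bound(2.4, 32.7)
  expect_equal(oc$fraction_bound, 0.068376, tolerance = 1e-5)
  expect_equal(oc$percent, 7)
  expect_equal(fraction_bound(5, 5)$fraction_bound, 0.5)
  expect_equal(fraction_bound(0, 10)$fraction_bound, 0)
  expect_error(fraction_bound(2.4, 0), "positive")
  expect_error(fraction_bound(-1, 10), ">= 0")
  # monotone in ligand, antitone in kd
  fr <- vapply(c(0.1, 1, 10, 100), function(L)
    fraction_bound(L, 10)$fraction_bound, numeric(1))
  expect_true(all(diff(fr) > 0))
  fk <- vapply(c(1, 10, 100), function(k)
    fraction_bound(2.4, k)$fraction_bound, numeric(1))
  expect_true(all(diff(fk) < 0))
})

test_that("Kd fold changes round half away from zero", {
  r <- kd_ratio(32.7, 8.7)
  expect_equal(unname(r["fold"]), 3.7586, tolerance = 1e-4)
  expect_equal(unname(r["rounded"]), 4)
  expect_equal(unname(kd_ratio(10, 10)), c(1, 1))
  r2 <- kd_ratio(1, 3)
  expect_equal(unname(r2["fold"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(r2["rounded"]), 0)
  # half-away-from-zero, not banker's rounding
  expect_equal(unname(kd_ratio(5, 2)["rounded"]), 3)   # 2.5 -> 3
  expect_error(kd_ratio(10, 0), "positive")
})

test_that("site presets and YAML definitions round-trip", {
  sites <- ttr_sites()
  expect_named(sites, paste0("site-", 1:6))
  expect_equal(sites[["site-1"]]$residues, c(66, 99))
  expect_equal(sites[["site-2"]]$residues, c(10, 104, 126))
  expect_equal(sites[["site-6"]]$residues, c(14, 15, 25, 53, 54, 55, 109))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sites_yaml(sites, f)
  back <- read_sites_yaml(f)
  expect_equal(lapply(back, `[[`, "residues"),
               lapply(sites, `[[`, "residues"))
  expect_error(binding_site("x", integer(0)), "non-empty")
})

test_that("site_fit methods expose the model object idiomatically", {
  sim <- simulate_titration(titration_sim_spec(seed = 99))
  fit <- fit_site(build_profile(sim$tables),
                  binding_site("site-1", c(66, 99)), T0 = 0.1)
  cf <- coef(fit)
  expect_named(cf, c("kd", "dmax_66", "dmax_99"))
  expect_equal(dim(vcov(fit)), c(3, 3))
  ci <- confint(fit, "kd")
  expect_lt(ci[1], fit$kd); expect_gt(ci[2], fit$kd)
  sm <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sm), c(fit$n_obs, 3))
  expect_true(all(sm >= 0))
  expect_identical(simulate(fit, 2, seed = 7), simulate(fit, 2, seed = 7))
  expect_output(print(summary(fit)), "Kd")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
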