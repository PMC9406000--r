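test_that("combined CSP matches hand arithmetic and is sign-symmetric", {
  expect_equal(combined_csp(0, 0), 0)
  # hand arithmetic: sqrt(0.0009 + 0.0004) = 0.0360555
  expect_equal(combined_csp(0.03, 0.13), 0.0360555, tolerance = 1e-5)
  expect_equal(combined_csp(-0.03, -0.13), combined_csp(0.03, 0.13))
  expect_equal(combined_csp(0.03, -0.13), combined_csp(0.03, 0.13))
  expect_error(combined_csp(0.1, 0.1, scale_N = 0), "positive")
  expect_error(combined_csp(0.1, 0.1, scale_N = -6.5), "positive")
})

test_that("combined CSP is monotone in |delta_H| and |delta_N|", {
  set.seed(5)
  h <- sort(abs(rnorm(30, 0, 0.1)))
  n <- sort(abs(rnorm(30, 0, 0.5)))
  expect_true(all(diff(combined_csp(h, 0.2)) >= 0))
  expect_true(all(diff(combined_csp(0.02, n)) >= 0))
})

test_that("profiles are referenced to the apo point", {
  # identical tables: every CSP exactly zero
  tabs <- make_pair_tables(c(1, 2, 3), c(8, 8.5, 9), c(110, 115, 120),
                           c(0, 0, 0), c(0, 0, 0))
  prof <- build_profile(tabs)
  expect_true(all(prof$delta_combined == 0))
  expect_true(all(prof$delta_combined[, prof$reference_index] == 0))

  # worked example: D99 moves (0.03 ppm 1H, 0.13 ppm 15N)
  tabs <- make_pair_tables(99, 8.41, 115.20, 0.03, 0.13)
  prof <- build_profile(tabs)
  expect_equal(prof$delta_H[1, 2], 0.03)
  expect_equal(prof$delta_N[1, 2], 0.13, tolerance = 1e-12)
  expect_equal(prof$delta_combined[1, 2], 0.0360555, tolerance = 1e-5)
})

test_that("tracking bookkeeping marks per-point losses only", {
  T0 <- 0.1
  mk <- function(res, L, dh = 0)
    shift_table(res, rep("A", length(res)), rep(120, length(res)),
                rep(8 + dh, length(res)), condition(L, T0))
  tabs <- list(mk(c(1, 2, 3), 0), mk(c(1, 2, 3), 20, 0.01),
               mk(c(1, 3), 60, 0.02), mk(c(1, 2, 3), 100, 0.03))
  prof <- build_profile(tabs)
  expect_equal(unname(prof$tracked["2", ]), c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(prof$tracked[c("1", "3"), ]))

  # residue absent from the reference: warned and excluded
  tabs2 <- list(mk(c(1, 2), 0), mk(c(1, 2, 9), 100, 0.02))
  expect_warning(p2 <- build_profile(tabs2), "absent from the reference")
  expect_false(9 %in% p2$residues)

  expect_error(build_profile(tabs[1]), ">= 2 shift_table")
  expect_error(build_profile(tabs, reference_index = 9),
               "reference table missing")
})

test_that("significance applies the mean + 2 sd rule with strict inequality", {
  mk_prof <- function(values) {
    n <- length(values)
    tabs <- make_pair_tables(seq_len(n), rep(8, n), rep(120, n),
                             delta_H = values, delta_N = rep(0, n))
    build_profile(tabs)
  }
  # zero variance: nothing can exceed mean + 2*0
  sg <- significance(mk_prof(rep(0.02, 5)), 2)
  expect_equal(sg$sd, 0)
  expect_equal(sg$threshold, 0.02)
  expect_length(sg$flagged, 0)

  # ten at 0.01, one at 0.20 (hand arithmetic, n-1 variance)
  sg <- significance(mk_prof(c(rep(0.01, 10), 0.20)), 2)
  expect_equal(sg$mean, 0.027273, tolerance = 1e-4)
  expect_equal(sg$sd, 0.057286, tolerance = 1e-4)
  expect_equal(sg$threshold, 0.141844, tolerance = 1e-4)
  expect_equal(sg$flagged, 11)

  # {0.01, 0.01, 0.01, 0.05}: threshold lands exactly on the outlier
  sg <- significance(mk_prof(c(0.01, 0.01, 0.01, 0.05)), 2)
  expect_equal(sg$threshold, 0.06, tolerance = 1e-12)
  expect_length(sg$flagged, 0)

  one <- make_pair_tables(1, 8, 120, 0.01, 0)
  expect_error(significance(build_profile(one), 2), ">= 2 tracked")
})

test_that("CSP statistics are scale-equivariant and flags scale-invariant", {
  set.seed(42)
  n <- 15
  dh <- rnorm(n, 0, 0.02); dn <- rnorm(n, 0, 0.1)
  for (c_scale in c(0.5, 3)) {
    p1 <- build_profile(make_pair_tables(1:n, rep(8, n), rep(120, n),
                                         dh, dn))
    p2 <- build_profile(make_pair_tables(1:n, rep(8, n), rep(120, n),
                                         c_scale * dh, c_scale * dn))
    expect_equal(p2$delta_combined, c_scale * p1$delta_combined,
                 tolerance = 1e-10)
    s1 <- significance(p1, 2); s2 <- significance(p2, 2)
    expect_equal(s2$mean, c_scale * s1$mean, tolerance = 1e-10)
    expect_equal(s2$sd, c_scale * s1$sd, tolerance = 1e-10)
    expect_equal(s2$threshold, c_scale * s1$threshold, tolerance = 1e-10)
    expect_equal(s2$flagged, s1$flagged)
  }
})

test_that("noiseless CSPs grow monotonically with ligand concentration", {
  spec <- titration_sim_spec(noise_sd_H = 0, noise_sd_N = 0, seed = 3)
  prof <- build_profile(simulate_titration(spec)$tables)
  truth <- simulate_titration(spec)$truth
  active <- truth$residue[truth$dmax_combined > 0]
  for (r in active)
    expect_true(all(diff(prof$delta_combined[as.character(r), ]) >= -1e-12))
})

test_that("salt comparison separates cation-specific from generic effects", {
  n <- 30
  set.seed(8)
  base_h <- runif(n, 7.5, 9); base_n <- runif(n, 110, 125)
  # control: small uniform drift; test: same drift plus two real binders
  drift_h <- rnorm(n, -0.005, 0.004); drift_n <- rnorm(n, 0, 0.02)
  bind_h <- rep(0, n); bind_h[c(3, 7)] <- c(0.15, 0.14)
  ctrl <- build_profile(make_pair_tables(1:n, base_h, base_n,
                                         drift_h, drift_n, ligand = 100))
  test <- build_profile(make_pair_tables(1:n, base_h, base_n,
                                         drift_h + bind_h, drift_n,
                                         ligand = 100))
  cmp <- salt_comparison(test, ctrl, 100)
  expect_true(all(c(3, 7) %in% cmp$specific))
  expect_true(all(cmp$specific %in% cmp$flagged_test))

  # identical profiles: nothing is specific
  cmp0 <- salt_comparison(ctrl, ctrl, 100)
  expect_length(cmp0$specific, 0)

  # the control summary statistic is the plain mean over tracked residues
  ctrl3 <- build_profile(make_pair_tables(c(1, 2, 3), rep(8, 3),
                                          rep(120, 3),
                                          c(-0.01, 0, -0.008),
                                          c(0, 0, 0), ligand = 100))
  cmp3 <- salt_comparison(ctrl3, ctrl3, 100)
  expect_equal(unname(cmp3$mean_delta_H["control"]), -0.006,
               tolerance = 1e-9)

  expect_error(salt_comparison(test, ctrl, 55), "within 10%")
  far <- build_profile(make_pair_tables(100:105, rep(8, 6), rep(120, 6),
                                        rep(0.01, 6), rep(0, 6),
                                        ligand = 100))
  expect_error(salt_comparison(test, far, 100), "no overlapping")
})
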