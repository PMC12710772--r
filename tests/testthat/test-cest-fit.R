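# CEST fitting: per-residue and grouped two-state fits, minor-state shift
# reconstruction, comparison tables.

test_that("noiseless identifiable profile is recovered to 3 significant figures", {
  probe <- std_probe()
  truth <- two_state_model(100, 0.10, 2, R1 = 1.2, R2A = 10)
  prof <- simulate_cest(probe, truth, std_cest_acq())
  fit <- fit_cest_residue(prof)
  expect_equal(fit$model$kex, 100, tolerance = 1e-3)
  expect_equal(fit$model$pB, 0.10, tolerance = 1e-3)
  expect_equal(fit$model$dW, 2, tolerance = 1e-3)
  expect_true(fit$minor_dip_detected)
  # sign of dW resolved when |dW| is well above the offset spacing
  prof_neg <- simulate_cest(probe, two_state_model(100, 0.10, -2,
                                                   R1 = 1.2, R2A = 10),
                            std_cest_acq())
  expect_lt(fit_cest_residue(prof_neg)$model$dW, 0)
})

test_that("no-exchange profile yields minor_dip_detected = FALSE", {
  prof <- simulate_cest(std_probe(), two_state_model(0, 0, 0, R1 = 1.2,
                                                     R2A = 10),
                        std_cest_acq())
  fit <- fit_cest_residue(prof)
  expect_false(fit$minor_dip_detected)
})

test_that("profiles violating the offset preconditions are rejected", {
  probe <- std_probe()
  acq_few <- cest_acquisition(25, 0.4, seq(112, 124, length.out = 10))
  prof <- cest_profile(probe, acq_few, rep(0.5, 10))
  expect_error(fit_cest_residue(prof), ">= 15 offsets")
  acq_onesided <- cest_acquisition(25, 0.4, seq(119, 125, length.out = 20))
  prof2 <- cest_profile(probe, acq_onesided, rep(0.5, 20))
  expect_error(fit_cest_residue(prof2), "both sides")
})

test_that("grouped fit recovers shared truth within 2x quoted errors (5 seeds)", {
  # 4-residue group at the slow-exchange group-1 truth, 1% noise
  cfg <- nmr_scenario("bound_wt_cest_group1")
  cfg$n_residues <- 4L
  kex <- pB <- chi2 <- numeric(5)
  for (s in 1:5) {
    cfg$seed <- 300L + s
    ds <- gen_cest_dataset(cfg)
    f <- fit_cest_group(ds$profiles, n_mc = 0)[[1]]
    kex[s] <- f$shared[["kex"]]; pB[s] <- f$shared[["pB"]]
    chi2[s] <- f$chi2_reduced
  }
  expect_lt(abs(median(kex) - 104), 2 * 8.5)
  expect_lt(abs(median(pB) - 0.11), 2 * 0.003)
  # with a matching noise model the reduced chi-square sits near 1
  expect_true(all(abs(chi2 - 1) < 0.4))
})

test_that("a group of one residue degrades to the per-residue fit", {
  cfg <- nmr_scenario("bound_wt_cest_group2", seed = 9)
  cfg$n_residues <- 1L
  ds <- gen_cest_dataset(cfg)
  g <- fit_cest_group(ds$profiles, n_mc = 0)[[1]]
  r <- fit_cest_residue(ds$profiles[[1]])
  expect_equal(g$shared[["kex"]], r$model$kex, tolerance = 1e-2)
  expect_equal(g$shared[["pB"]], r$model$pB, tolerance = 1e-2)
})

test_that("Monte-Carlo errors are seeded and of the covariance order", {
  cfg <- nmr_scenario("bound_wt_cest_group2", seed = 5)
  ds <- gen_cest_dataset(cfg)
  f1 <- fit_cest_group(ds$profiles, n_mc = 8L, mc_seed = 3L)[[1]]
  f2 <- fit_cest_group(ds$profiles, n_mc = 8L, mc_seed = 3L)[[1]]
  expect_identical(f1$shared_se, f2$shared_se)
  expect_gt(f1$shared_se[["kex"]], 0)
  expect_equal(f1$n_mc, 8L)
})

test_that("inconsistent acquisition metadata within a group is an error", {
  probe <- std_probe(1); acq1 <- std_cest_acq()
  acq2 <- cest_acquisition(50, 0.4, acq1$offsets)
  p1 <- cest_profile(probe, acq1, rep(0.5, 61))
  p2 <- cest_profile(std_probe(2), acq2, rep(0.5, 61))
  expect_error(fit_cest_group(list(p1, p2), n_mc = 0), "acquisition")
  expect_error(fit_cest_group(list(p1), data.frame(residue = 99,
                                                   group = "g")),
               "missing residues")
})

test_that("minor-state shifts reconstruct as omega_A + dW and round-trip", {
  probe <- residue_probe(41, 115.0)
  expect_equal(reconstruct_minor_shift(probe, two_state_model(100, .1, 0)),
               115.0)
  expect_equal(reconstruct_minor_shift(probe, two_state_model(100, .1, 1.5)),
               116.5)
  # simulate at omega_B, fit, reconstruct
  truth <- two_state_model(104, 0.11, -1.8, R1 = 1.2, R2A = 11)
  prof <- simulate_cest(probe, truth, default_cest_acq(115))
  fit <- fit_cest_residue(prof)
  expect_equal(reconstruct_minor_shift(probe, fit$model), 115 - 1.8,
               tolerance = 0.2)
})

test_that("comparison table reports |differences| and lists unmatched residues", {
  recon <- data.frame(residue = c(41, 56, 40, 99),
                      shift = c(116.5, 122.1, 119.0, 110.0))
  ref <- data.frame(residue = c(41, 56, 40),
                    shift = c(116.4, 122.4, 118.8))
  tab <- compare_minor_to_reference(recon, ref)
  expect_equal(tab$abs_diff[tab$residue == 41], 0.1, tolerance = 1e-10)
  expect_equal(tab$abs_diff[tab$residue == 40], 0.2, tolerance = 1e-10)
  expect_equal(attr(tab, "unmatched"), 99)
  expect_equal(attr(tab, "max_abs_diff"), 0.3, tolerance = 1e-10)
  ident <- compare_minor_to_reference(ref, ref)
  expect_true(all(ident$abs_diff == 0))
})
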