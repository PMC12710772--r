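# Synthetic-data generators: zero-noise fidelity, seed determinism, noise
# calibration, format validity.

test_that("zero-noise CEST and CPMG datasets equal the simulators exactly", {
  cfg <- nmr_scenario("bound_wt_cest_group2", seed = 1)
  ds <- gen_cest_dataset(cfg, noise = 0)
  tt <- ds$truth$per_residue
  for (i in seq_along(ds$profiles)) {
    p <- ds$profiles[[i]]
    ref <- simulate_cest(p$probe,
                         two_state_model(cfg$kex, cfg$pB, tt$dW[i],
                                         tt$R1[i], tt$R2[i]), p$acq)
    expect_identical(p$intensity, ref$intensity)
  }
  cfg2 <- nmr_scenario("bound_wt_cpmg_group2", seed = 1)
  ds2 <- gen_cpmg_dataset(cfg2, noise = 0)
  tt2 <- ds2$truth$per_residue
  ref2 <- simulate_cpmg(ds2$profiles[[1]]$probe,
                        two_state_model(cfg2$kex, cfg2$pB, tt2$dW[1],
                                        R2A = tt2$R2[1]),
                        ds2$profiles[[1]]$acq)
  expect_identical(ds2$profiles[[1]]$r2eff, as.numeric(ref2$r2eff))
})

test_that("the same seed reproduces every dataset byte-identically", {
  for (scen in c("bound_wt_cest_group2", "apo_t42a_cpmg_group1",
                 "titration_wt_ptyr", "shp2_wt_volumes",
                 "nsh2_relaxation")) {
    cfg <- nmr_scenario(scen, seed = 17)
    gen <- switch(cfg$kind, cest = gen_cest_dataset,
                  cpmg2 = gen_cpmg_dataset, titration = gen_titration_dataset,
                  volumes = gen_volume_dataset,
                  relaxation = gen_relaxation_dataset)
    expect_identical(gen(cfg), gen(cfg))
  }
  cfgE <- nmr_scenario("bound_wt_ensemble", seed = 17)
  expect_identical(gen_toy_ensemble(cfgE), gen_toy_ensemble(cfgE))
})

test_that("different seeds give different noise", {
  c1 <- gen_cest_dataset(nmr_scenario("bound_wt_cest_group2", seed = 1))
  c2 <- gen_cest_dataset(nmr_scenario("bound_wt_cest_group2", seed = 2))
  expect_false(identical(c1$profiles[[1]]$intensity,
                         c2$profiles[[1]]$intensity))
})

test_that("empirical noise matches nominal sigma within 10% over >500 points", {
  cfg <- nmr_scenario("bound_wt_cest_group1", seed = 8)
  noisy <- gen_cest_dataset(cfg)
  clean <- gen_cest_dataset(cfg, noise = 0)
  z <- unlist(lapply(seq_along(noisy$profiles), function(i)
    (noisy$profiles[[i]]$intensity - clean$profiles[[i]]$intensity) /
      noisy$profiles[[i]]$sigma))
  expect_gt(length(z), 500)
  expect_gt(sd(z), 0.9); expect_lt(sd(z), 1.1)
})

test_that("toy ensemble PDB parses under a strict reader", {
  f <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_ensemble(nmr_scenario("bound_wt_ensemble", seed = 2), file = f)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$xyz), 20)
  expect_true(all(c("N", "O", "CA", "OH") %in% pdb$atom$elety))
  # fixed-width geometry: every ATOM record is 78 characters
  lines <- readLines(f)
  atoms <- grep("^ATOM", lines, value = TRUE)
  expect_true(all(nchar(atoms) == 78))
})

test_that("bound-T42A scenario shows no second-state dip and no Rex flags", {
  cfg <- nmr_scenario("bound_t42a_cest", seed = 5)
  cfg$n_residues <- 3L
  ds <- gen_cest_dataset(cfg)
  dips <- vapply(ds$profiles, function(p)
    fit_cest_residue(p)$minor_dip_detected, logical(1))
  expect_false(any(dips))
  # quenched dispersions: no residue flagged by the Rex screen
  cfg2 <- nmr_scenario("apo_t42a_cpmg_group1", seed = 5)
  cfg2$kex <- 0; cfg2$pB <- 0
  flat <- gen_cpmg_dataset(cfg2)
  expect_false(any(screen_rex(flat$profiles)$flagged))
})

test_that("full-pipeline recovery holds for the volume and titration scenarios", {
  # median over 5 seeds within 2x the quoted uncertainty
  p_open <- sapply(1:5, function(s)
    quantify_open_population(
      gen_volume_dataset(nmr_scenario("shp2_wt_volumes", seed = 800 + s))$pairs)$mean)
  expect_lt(abs(median(p_open) - 0.15), 2 * 0.06)
  kd <- sapply(1:5, function(s)
    fit_kd_fast_exchange(
      gen_titration_dataset(nmr_scenario("titration_t42a_ptyr",
                                         seed = 900 + s))$series)$KD)
  expect_lt(abs(median(kd) - 250e-6) / 250e-6, 0.15)
})
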