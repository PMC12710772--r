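# Ensemble geometry: distances from multi-model PDBs, zipped/unzipped
# classification, short-hydrogen-bond summary, survey mode.

test_that("toy ensembles round-trip prescribed distances to 1e-3 A", {
  d_true <- c(2.9, 3.0, 3.35, 4.5, 5.0)
  f <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_ensemble(d_true, file = f)
  eds <- extract_pair_distances(f, atom_pair_spec("F41N-I56O", 41, "N",
                                                  56, "O"))
  expect_equal(eds$distances, d_true, tolerance = 1e-3)
  expect_equal(eds$n_models, 5)
  expect_equal(eds$labels, c("zipped", "zipped", "ambiguous", "unzipped",
                             "unzipped"))
})

test_that("distances equal an independent fixed-width text oracle to 1e-6", {
  cfg <- nmr_scenario("bound_wt_ensemble", seed = 3)
  cfg$jitter <- 0.15
  lines <- gen_toy_ensemble(cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  eds <- extract_pair_distances(f, atom_pair_spec("F41N-I56O", 41, "N",
                                                  56, "O"))
  for (m in c(1, 7, 20)) {
    oracle <- pdb_text_distance(lines, m, 41, "N", 56, "O")
    expect_equal(eds$distances[m], oracle, tolerance = 1e-6)
  }
})

test_that("degenerate and 3-4-5 geometries give exact distances", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               "ATOM      1  N   PHE A  41       0.000   0.000   0.000  1.00  0.00           N",
               "ATOM      2  O   ILE A  56       3.000   4.000   0.000  1.00  0.00           O",
               "ENDMDL",
               "MODEL        2",
               "ATOM      1  N   PHE A  41       1.000   2.000   3.000  1.00  0.00           N",
               "ATOM      2  O   ILE A  56       1.000   2.000   3.000  1.00  0.00           O",
               "ENDMDL", "END"), f)
  eds <- extract_pair_distances(f, atom_pair_spec("p", 41, "N", 56, "O"))
  expect_equal(eds$distances, c(5.0, 0.0), tolerance = 1e-10)
})

test_that("carboxylate acceptors take the nearer of OD1/OD2", {
  cfg <- nmr_scenario("bound_t42a_ensemble", seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_ensemble(cfg, file = f)
  hb <- extract_pair_distances(f, atom_pair_spec("Y66OH-D40OD", 66, "OH",
                                                 40, "OD"))
  expect_equal(hb$distances, rep(2.6, 20), tolerance = 1e-3)
  rep <- short_hbond_report(hb$distances)
  expect_true(rep$short_hbond)
  expect_equal(rep$mean, 2.6, tolerance = 1e-3)
  expect_false(short_hbond_report(3.0)$short_hbond)
  # missing atom names the failing endpoint
  expect_error(extract_pair_distances(f, atom_pair_spec("x", 41, "ND2",
                                                        56, "O")),
               "atom not found")
})

test_that("alternate locations resolve by occupancy then altLoc A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               "ATOM      1  N   PHE A  41       0.000   0.000   0.000  1.00  0.00           N",
               "ATOM      2  O  AILE A  56       2.000   0.000   0.000  0.30  0.00           O",
               "ATOM      3  O  BILE A  56       6.000   0.000   0.000  0.70  0.00           O",
               "ENDMDL", "END"), f)
  eds <- extract_pair_distances(f, atom_pair_spec("p", 41, "N", 56, "O"))
  expect_equal(eds$distances, 6.0, tolerance = 1e-10)  # higher occupancy wins
})

test_that("classification is a pure threshold function with an ambiguous band", {
  expect_identical(classify_conformation(2.9), "zipped")
  expect_identical(classify_conformation(4.5), "unzipped")
  expect_identical(classify_conformation(3.35), "ambiguous")
  expect_identical(classify_conformation(c(3.3, 3.4)),
                   c("zipped", "unzipped"))
  d <- c(2.8, 3.1, 3.35, 3.9, 4.8)
  expect_identical(classify_conformation(rev(d)),
                   rev(classify_conformation(d)))
  expect_identical(classify_conformation(d), classify_conformation(d))
  expect_error(classify_conformation(-1), "distance")
})

test_that("survey mode tabulates per-structure classes from generator truth", {
  dir <- withr::local_tempdir()
  d_true <- c(rep(2.9, 6), rep(4.5, 4))
  files <- character(10)
  for (i in 1:10) {
    files[i] <- file.path(dir, sprintf("s%02d.pdb", i))
    gen_toy_ensemble(d_true[i], file = files[i])
  }
  mapping <- data.frame(file = basename(files), resno_a = 41, atom_a = "N",
                        resno_b = 56, atom_b = "O")
  sv <- survey_sh2(files, mapping)
  expect_equal(unname(sv$counts["zipped"]), 6L)
  expect_equal(unname(sv$counts["unzipped"]), 4L)
  expect_equal(sum(sv$histogram$count), 10)
  # empty survey and degenerate single-structure survey
  empty <- survey_sh2(character(0), mapping)
  expect_equal(nrow(empty$table), 0)
  one <- survey_sh2(files[1], mapping)
  expect_equal(one$table$distance,
               min(extract_pair_distances(files[1],
                     atom_pair_spec("p", 41, "N", 56, "O"))$distances))
  # unresolvable mapping is skipped with a log entry
  bad_map <- mapping; bad_map$atom_a[2] <- "XX1"
  sv2 <- survey_sh2(files[1:2], bad_map)
  expect_equal(nrow(sv2$table), 1)
  expect_length(sv2$skipped, 1)
})
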