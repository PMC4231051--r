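test_that("detection respects the 4-Angstrom cutoff and reports one record per residue pair", {
  sp <- fixture_spec(tibble::tibble(pair_type = "K-D", ca_dist = 8, theta1 = 40,
                                    theta2 = 60, atom_dist = 3.5),
                     n_decoys = 0, seed = 1)
  br <- detect_salt_bridges(generate_fixture(sp)$atoms)
  expect_equal(nrow(br), 1)
  expect_equal(br$pair_type, "K-D")
  expect_equal(br$min_atom_dist, 3.5, tolerance = 1e-9)

  sp_far <- fixture_spec(tibble::tibble(pair_type = "K-D", ca_dist = 9, theta1 = 40,
                                        theta2 = 60, atom_dist = 4.2),
                         n_decoys = 0, seed = 1)
  expect_equal(nrow(detect_salt_bridges(generate_fixture(sp_far)$atoms)), 0)

  # R-E: both NH1 and NH2 within the cutoff still yields a single record
  # carrying the minimum atom distance (NH2 is planted 0.8 A behind NH1)
  sp_r <- fixture_spec(tibble::tibble(pair_type = "R-E", ca_dist = 7, theta1 = 30,
                                      theta2 = 30, atom_dist = 3.0),
                       n_decoys = 0, seed = 1)
  br_r <- detect_salt_bridges(generate_fixture(sp_r)$atoms)
  expect_equal(nrow(br_r), 1)
  expect_equal(br_r$min_atom_dist, 3.0, tolerance = 1e-9)
})

test_that("candidates with missing charged-group atoms are skipped silently", {
  sp <- fixture_spec(tibble::tibble(pair_type = "K-D", ca_dist = 6, theta1 = 40,
                                    theta2 = 60, atom_dist = 3.0),
                     n_decoys = 0, seed = 1)
  at <- generate_fixture(sp)$atoms
  at_trunc <- at[at$elety != "NZ", ]
  expect_equal(nrow(detect_salt_bridges(at_trunc)), 0)
})

test_that("pseudo-angles hit the collinear limits and reject degenerate vectors", {
  ca1 <- c(0, 0, 0); ca2 <- c(10, 0, 0)
  g0 <- pair_geometry(ca1, c(1.5, 0, 0), ca2, c(10, 1.5, 0))
  expect_equal(g0$theta1, 0)
  g180 <- pair_geometry(ca1, c(-1.5, 0, 0), ca2, c(11.5, 0, 0))
  expect_equal(g180$theta1, 180)
  expect_equal(g180$theta2, 180)
  expect_equal(g180$ca_dist, 10)
  expect_error(pair_geometry(ca1, ca1, ca2, c(10, 1.5, 0)), "degenerate")
})

test_that("exposure classes follow the RSA rules and partition every bridge", {
  cfg <- sb_config()
  expect_equal(classify_exposure(0.40, 0.30, cfg), "exposed")
  expect_equal(classify_exposure(0.30, 0.40, cfg), "exposed")  # symmetric
  expect_equal(classify_exposure(0.05, 0.05, cfg), "buried")
  expect_equal(classify_exposure(0.20, 0.20, cfg), "intermediate")
  expect_equal(classify_exposure(0.40, 0.20, cfg), "intermediate")  # one high, one low

  set.seed(3)
  r1 <- stats::runif(500); r2 <- stats::runif(500)
  cls <- classify_exposure(r1, r2, cfg)
  expect_true(all(cls %in% c("exposed", "buried", "intermediate")))
})

test_that("detection and geometry are invariant under rigid-body motion", {
  sp <- fixture_spec(
    tibble::tibble(pair_type = c("K-D", "R-E", "K-E"),
                   ca_dist = c(5, 9, 12), theta1 = c(20, 80, 100),
                   theta2 = c(40, 30, 60), atom_dist = c(3.0, 3.5, 3.9),
                   inter_subunit = c(FALSE, FALSE, TRUE)),
    n_decoys = 5, seed = 21
  )
  at <- generate_fixture(sp)$atoms
  br0 <- detect_salt_bridges(at)
  set.seed(99)
  for (k in 1:5) {
    at2 <- apply_motion_atoms(at, random_rigid_motion())
    br2 <- detect_salt_bridges(at2)
    expect_equal(br2$resno_i, br0$resno_i)
    expect_equal(br2$min_atom_dist, br0$min_atom_dist, tolerance = 1e-9)
    expect_equal(br2$ca_dist, br0$ca_dist, tolerance = 1e-9)
    expect_equal(br2$theta1, br0$theta1, tolerance = 1e-9)
    expect_equal(br2$theta2, br0$theta2, tolerance = 1e-9)
  }
})

test_that("a survey aggregates planted bridges and tolerates broken structures", {
  dir <- file.path(tempdir(), "survey_small")
  unlink(dir, recursive = TRUE)
  cats <- tibble::tibble(pair_type = c("K-E", "K-E", "R-D"),
                         ss_i = c("H", "H", "C"), ss_j = c("H", "H", "C"),
                         bin_lo = c(4, 4, 6), bin_hi = c(5, 5, 7),
                         count = c(1L, 1L, 1L))
  ss <- generate_survey_set(2, cats, seed = 8, dir = dir)
  bad <- file.path(dir, "broken.pdb")
  writeLines("not a pdb at all", bad)
  sv <- suppressMessages(
    survey_structures(c(ss$paths$pdb, bad), dssp = c(ss$paths$dssp, NA))
  )
  expect_equal(nrow(sv$bridges), 3)
  expect_equal(sv$failed, bad)
  expect_equal(sum(sv$bridges$exposure == "exposed"), 3)
  # planted K-E on two helix fixtures: the H-H cell of the K-E matrix is 2
  kehh <- dplyr::filter(sv$ss_matrix, pair_type == "K-E", ss_i == "H", ss_j == "H")
  expect_equal(kehh$n, 2L)
  expect_error(suppressMessages(survey_structures(bad)), "every structure")
})

test_that("buried + exposed never exceeds the total in a mixed survey", {
  sp <- fixture_spec(
    tibble::tibble(pair_type = c("K-D", "K-E", "R-D"),
                   ca_dist = c(5, 7, 9), theta1 = 30, theta2 = 40,
                   atom_dist = 3.4,
                   exposure = c("exposed", "buried", "intermediate")),
    n_decoys = 0, seed = 4
  )
  fx <- generate_fixture(sp)
  p <- write_fixture(fx, tempdir(), "mix1")
  sv <- survey_structure(read_structure(p$pdb), dssp = p$dssp)
  tab <- table(sv$exposure)
  expect_equal(unname(tab[c("buried", "exposed", "intermediate")]), rep(1L, 3), ignore_attr = TRUE)
  expect_lt(sum(sv$exposure == "buried") + sum(sv$exposure == "exposed"), nrow(sv))
})
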