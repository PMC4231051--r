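# a reusable design scenario: polar position P on a helix with an acidic
# partner at separation 10 (qualifying), one at separation 2 (short), and
# one across the interface; Cbeta vectors point along the pair axes so the
# angular restraint is satisfied
design_scenario <- function() {
  dplyr::bind_rows(
    mk_desc_row("A", 100, "N", "H", c(0, 0, 0), c(1.2, 0.9, 0)),
    mk_desc_row("A", 110, "D", "C", c(8, 0, 0), c(7, 0.9, 0), cons = 9L),
    mk_desc_row("A", 102, "E", "C", c(5, 0, 0), c(4.2, 0.9, 0), cons = 9L),
    mk_desc_row("B", 300, "D", "H", c(0, 10, 0), c(0.4, 9.1, 0), cons = 9L)
  )
}

scenario_index <- function() {
  build_pair_index(tibble::tibble(
    pair_type = c("K-D", "K-D", "R-D", "K-E", "K-D"),
    ss_i = c("H", "H", "H", "H", "H"),
    ss_j = c("C", "C", "C", "C", "H"),
    ca_dist = c(8.5, 8.2, 8.3, 5.5, 10.2)
  ))
}

test_that("the pre-filter cascade matches an explicit filter oracle", {
  set.seed(31)
  n <- 60
  d <- tibble::tibble(
    chain = "A", resno = seq_len(n), insert = "",
    aa = sample(c("S", "T", "N", "Q", "K", "D", "A", "L", "G", "F"), n, TRUE),
    ss3 = "C", ss8 = "T", asa = 100,
    rsa = stats::runif(n, 0, 1), b = 20,
    z_b = stats::rnorm(n), wcn = 0.1, rwcn = 10, z_rwcn = stats::rnorm(n),
    conservation = sample(c(1:9, NA), n, TRUE),
    ca_x = stats::runif(n, 0, 50), ca_y = 0, ca_z = 0,
    cb_x = stats::runif(n, 0, 50), cb_y = 1, cb_z = 0
  )
  pos <- prefilter_positions(d)
  oracle <- d[d$aa %in% c("S", "T", "C", "N", "Q", "K", "R", "D", "E") &
                d$rsa > 0.35 & d$z_b > 0 & d$z_rwcn > 0 &
                !is.na(d$conservation) & d$conservation < 4, ]
  expect_equal(pos$resno, oracle$resno)
  cc <- attr(pos, "cascade")
  expect_equal(unname(cc["conservation"]), nrow(oracle))
  expect_true(all(diff(cc) <= 0))  # each step can only shrink the set

  # unsatisfiable RSA threshold empties the set
  expect_equal(nrow(prefilter_positions(d, sb_config(rsa_min = max(d$rsa) + 1))), 0)

  # relaxing any single threshold yields a superset
  base <- prefilter_positions(d)$resno
  for (cfg in list(sb_config(rsa_min = 0.2), sb_config(z_b_min = -1),
                   sb_config(z_rwcn_min = -1), sb_config(cons_max = 7))) {
    expect_true(all(base %in% prefilter_positions(d, cfg)$resno))
  }

  # three residues engineered to pass exactly
  d3 <- d
  d3[, c("rsa", "z_b", "z_rwcn")] <- 0
  d3$conservation <- 9L
  d3[1:3, c("rsa", "z_b", "z_rwcn")] <- list(0.5, 1, 1)
  d3$conservation[1:3] <- 2L
  d3$aa[1:3] <- c("S", "Q", "E")
  expect_equal(prefilter_positions(d3)$resno, 1:3)
})

test_that("neighbour search honours the 15-Angstrom boundary across chains", {
  d <- dplyr::bind_rows(
    mk_desc_row("A", 1, "N", "C", c(0, 0, 0), c(1, 1, 0)),
    mk_desc_row("A", 20, "D", "C", c(14.9, 0, 0), c(14, 1, 0)),
    mk_desc_row("B", 5, "E", "C", c(0, 15.1, 0), c(0, 14.2, 1)),
    mk_desc_row("B", 6, "K", "C", c(0, 0, 15.0), c(0, 1, 14.2)),
    mk_desc_row("A", 30, "S", "C", c(3, 0, 0), c(3, 1, 0))  # uncharged: never a neighbour
  )
  nb <- find_charged_neighbors(d, "A", 1)
  expect_setequal(paste(nb$chain, nb$resno), c("A 20", "B 6"))
  expect_error(find_charged_neighbors(d, "Z", 9), "not found")
})

test_that("the angular restraint gates only pairs spanning more than 7 Angstrom", {
  expect_true(check_angular_constraint(150, 150, 6.5))
  expect_true(check_angular_constraint(120, 80, 9))
  expect_false(check_angular_constraint(120, 130, 9))
  expect_true(check_angular_constraint(109.9, 170, 14))
})

test_that("electrostatic scores equal the index weight and zero out repulsion", {
  d <- design_scenario()
  idx <- scenario_index()
  nb <- find_charged_neighbors(d, "A", 100)
  es <- electrostatic_score(d[1, ], "K", nb, idx)
  # each attractive neighbour contributes exactly its category weight
  expect_equal(es$score[es$partner_resno == 110], 40)
  expect_equal(es$score[es$partner_resno == 102], 20)
  expect_equal(es$score[es$partner_resno == 300], 20)
  expect_equal(attr(es, "total"), 80)
  # acidic substitution against acidic partners scores zero everywhere
  es_d <- electrostatic_score(d[1, ], "D", nb, idx)
  expect_equal(attr(es_d, "total"), 0)
  expect_true(all(es_d$score == 0))
})

test_that("scoring equals a brute-force oracle over random neighbourhoods", {
  set.seed(17)
  idx <- build_pair_index(tibble::tibble(
    pair_type = sample(c("K-D", "K-E", "R-D", "R-E"), 60, TRUE),
    ss_i = sample(c("H", "S", "C"), 60, TRUE),
    ss_j = sample(c("H", "S", "C"), 60, TRUE),
    ca_dist = stats::runif(60, 3.2, 14.8)
  ))
  for (rep in 1:10) {
    pos <- mk_desc_row("A", 1, "Q", sample(c("H", "S", "C"), 1),
                       c(0, 0, 0), c(1, 1, 0))
    n <- 20
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- stats::runif(n, 3.5, 14.5)
    nb <- purrr::map_dfr(seq_len(n), function(i) {
      ca <- c(rad[i] * cos(ang[i]), rad[i] * sin(ang[i]), 0)
      mk_desc_row("A", 10 + i, sample(c("K", "R", "D", "E"), 1),
                  sample(c("H", "S", "C"), 1), ca, ca + c(0.3, 0.9, 1.1))
    })
    sub <- sample(c("K", "R", "D", "E"), 1)
    es <- electrostatic_score(pos, sub, nb, idx)
    oracle <- 0
    for (i in seq_len(n)) {
      if (charge_of(sub) * charge_of(nb$aa[i]) < 0) {
        dd <- sqrt(sum((c(0, 0, 0) - c(nb$ca_x[i], nb$ca_y[i], nb$ca_z[i]))^2))
        if (charge_of(sub) > 0) {
          oracle <- oracle + lookup_brute(tidy(idx), paste0(sub, "-", nb$aa[i]),
                                          pos$ss3, nb$ss3[i], dd)
        } else {
          oracle <- oracle + lookup_brute(tidy(idx), paste0(nb$aa[i], "-", sub),
                                          nb$ss3[i], pos$ss3, dd)
        }
      }
    }
    expect_equal(attr(es, "total"), oracle, tolerance = 1e-12)
  }
})

test_that("adding an attractive neighbour never lowers the score; like charges never change it", {
  d <- design_scenario()
  idx <- scenario_index()
  nb <- find_charged_neighbors(d, "A", 100)
  base <- attr(electrostatic_score(d[1, ], "K", nb, idx), "total")
  extra_attr <- mk_desc_row("A", 140, "E", "C", c(-5.5, 0, 0), c(-4.7, 0.9, 0), cons = 9L)
  more <- attr(electrostatic_score(d[1, ], "K", dplyr::bind_rows(nb, extra_attr), idx), "total")
  expect_gte(more, base)
  extra_rep <- mk_desc_row("A", 141, "K", "C", c(0, -6, 0), c(0, -5.1, 0.9), cons = 9L)
  same <- attr(electrostatic_score(d[1, ], "K", dplyr::bind_rows(nb, extra_rep), idx), "total")
  expect_equal(same, base)
})

test_that("a single qualifying option yields exactly that suggestion, deterministically", {
  d <- dplyr::bind_rows(
    mk_desc_row("A", 100, "N", "H", c(0, 0, 0), c(1.2, 0.9, 0)),
    mk_desc_row("A", 110, "D", "C", c(8, 0, 0), c(7, 0.9, 0), cons = 9L)
  )
  idx <- build_pair_index(tibble::tibble(pair_type = "K-D", ss_i = "H",
                                         ss_j = "C", ca_dist = 8.5))
  sug <- suggest_mutations(d, idx)
  expect_equal(nrow(sug), 1)
  expect_equal(sug$substitution, "K")
  expect_equal(sug$partner_resno, 110L)
  expect_equal(sug$score, 100)
  expect_false(sug$alt_rule)
  sug2 <- suggest_mutations(d, idx)
  expect_identical(as.data.frame(sug), as.data.frame(sug2))
})

test_that("equal top scores emit all tied substitutions", {
  d <- dplyr::bind_rows(
    mk_desc_row("A", 96, "E", "H", c(0, 0, 0), c(1.2, 0.9, 0)),
    mk_desc_row("A", 28, "D", "C", c(8, 0, 0), c(7, 0.9, 0), cons = 9L)
  )
  # K-D and R-D weights equal in the relevant category: a charge-reversal
  # position suggests both basic substitutions
  idx <- build_pair_index(tibble::tibble(
    pair_type = c("K-D", "R-D"), ss_i = "H", ss_j = "C", ca_dist = c(8.5, 8.5)
  ))
  sug <- suggest_mutations(d, idx)
  expect_setequal(sug$substitution, c("K", "R"))
  expect_equal(unique(sug$partner_resno), 28L)
  expect_equal(sug$score, rep(50, 2))
})

test_that("positions whose pairs are all short-separation are not scored", {
  d <- dplyr::bind_rows(
    mk_desc_row("A", 100, "N", "H", c(0, 0, 0), c(1.2, 0.9, 0)),
    mk_desc_row("A", 102, "D", "C", c(6, 0, 0), c(5.2, 0.9, 0), cons = 9L)
  )
  idx <- build_pair_index(tibble::tibble(pair_type = "K-D", ss_i = "H",
                                         ss_j = "C", ca_dist = 6.5))
  sug <- suggest_mutations(d, idx)
  expect_equal(nrow(sug), 0)
})

test_that("the alternative-substitution rule rescues a different charge type", {
  d <- dplyr::bind_rows(
    mk_desc_row("A", 100, "S", "H", c(0, 0, 0), c(1.2, 0.9, 0)),
    mk_desc_row("A", 102, "D", "C", c(5, 0, 0), c(4.2, 0.9, 0), cons = 9L),  # short sep
    mk_desc_row("A", 110, "D", "C", c(8, 0, 0), c(7, 0.9, 0), cons = 9L)     # qualifying
  )
  # weights: K-D short (bin 5) dominates globally; for R the qualifying
  # pair outscores its own short pair, for K it does not
  idx <- build_pair_index(tibble::tibble(
    pair_type = c(rep("K-D", 8), rep("R-D", 3)),
    ss_i = "H", ss_j = "C",
    ca_dist = c(rep(5.5, 5), rep(8.5, 3), 5.5, 8.5, 8.5)
  ))
  sug <- suggest_mutations(d, idx)
  expect_equal(sug$substitution, "R")
  expect_equal(sug$partner_resno, 110L)
  expect_true(sug$alt_rule)
  # and the rejected substitution K appears in the full pair dump
  ap <- attr(sug, "all_pairs")
  expect_true(any(ap$substitution == "K" & ap$partner_resno == 102))
})

test_that("emitted suggestions always satisfy the separation and angular constraints", {
  set.seed(23)
  for (rep in 1:8) {
    n_nb <- sample(3:8, 1)
    rows <- list(mk_desc_row("A", 100, sample(c("S", "T", "N", "Q"), 1), "H",
                             c(0, 0, 0), c(1.2, 0.9, 0)))
    for (i in seq_len(n_nb)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      ca <- u * stats::runif(1, 3.5, 14.5)
      chain <- sample(c("A", "B"), 1)
      rows[[i + 1]] <- mk_desc_row(chain, 95 + i, sample(c("K", "R", "D", "E"), 1),
                                   sample(c("H", "S", "C"), 1),
                                   ca, ca + stats::rnorm(3, sd = 1), cons = 9L)
    }
    d <- dplyr::bind_rows(rows)
    idx <- build_pair_index(tibble::tibble(
      pair_type = sample(c("K-D", "K-E", "R-D", "R-E"), 40, TRUE),
      ss_i = sample(c("H", "S", "C"), 40, TRUE),
      ss_j = sample(c("H", "S", "C"), 40, TRUE),
      ca_dist = stats::runif(40, 3.2, 14.8)
    ))
    sug <- suggest_mutations(d, idx)
    if (nrow(sug) > 0) {
      expect_true(all(sug$seq_sep >= 5 | sug$inter_subunit))
      expect_true(all(check_angular_constraint(sug$theta1, sug$theta2, sug$ca_dist)))
      expect_true(all(charge_of(sug$substitution) * charge_of(sug$partner_aa) < 0))
      expect_true(all(sug$score >= 0))
    }
  }
})
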