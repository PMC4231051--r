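#' Specify a synthetic structure with planted salt bridges
#'
#' Describes a small PDB-format fixture whose salt-bridge geometry is known
#' exactly by construction: each planted bridge realizes a requested pair
#' type, Calpha--Calpha distance, pseudo-angles theta1/theta2, and minimum
#' charged-atom distance; decoy residues (including charged ones placed far
#' apart) are guaranteed to form no bridge. Residues use ideal minimal
#' geometry — backbone N/CA/C/O, Cbeta, and the charged-group atoms the
#' pipeline reads — and are not physically realistic conformers.
#'
#' @param bridges tibble with columns `pair_type` (e.g. `"K-D"`), `ca_dist`,
#'   `theta1`, `theta2` (degrees), `atom_dist` (planted minimum charged-atom
#'   distance), and optionally `ss_i`, `ss_j` (3-state labels, default
#'   `"C"`), `exposure` (`"exposed"`/`"buried"`/`"intermediate"`, default
#'   exposed), `inter_subunit` (default `FALSE`).
#' @param n_decoys number of non-bridging filler residues.
#' @param decoy_aa amino-acid pool for decoys.
#' @param b_factors optional per-residue B-factor vector (recycled);
#'   default drawn from the seed.
#' @param seed integer; fully determines the output.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(bridges, n_decoys = 4,
                         decoy_aa = c("A", "S", "L", "G", "K", "D"),
                         b_factors = NULL, seed = 1L) {
  bridges <- tibble::as_tibble(bridges)
  stopifnot(all(c("pair_type", "ca_dist", "theta1", "theta2", "atom_dist") %in% names(bridges)))
  if (!"ss_i" %in% names(bridges)) bridges$ss_i <- "C"
  if (!"ss_j" %in% names(bridges)) bridges$ss_j <- "C"
  if (!"exposure" %in% names(bridges)) bridges$exposure <- "exposed"
  if (!"inter_subunit" %in% names(bridges)) bridges$inter_subunit <- FALSE
  aa_split <- strsplit(bridges$pair_type, "-", fixed = TRUE)
  bridges$aa_i <- vapply(aa_split, `[`, "", 1)
  bridges$aa_j <- vapply(aa_split, `[`, "", 2)
  stopifnot(all(bridges$aa_i %in% c("K", "R")), all(bridges$aa_j %in% c("D", "E")))
  if (any(bridges$atom_dist > bridges$ca_dist + 10)) {
    stop("unrealizable geometry: atom_dist far exceeds ca_dist")
  }
  stopifnot(all(bridges$theta1 >= 0 & bridges$theta1 <= 180),
            all(bridges$theta2 >= 0 & bridges$theta2 <= 180),
            all(bridges$ca_dist > 0), all(bridges$atom_dist > 0))
  structure(list(bridges = bridges, n_decoys = n_decoys, decoy_aa = decoy_aa,
                 b_factors = b_factors, seed = as.integer(seed)),
            class = "fixture_spec")
}

# minimal residue: backbone + CB + charged-group atoms at given positions
fixture_residue <- function(chain, resno, aa, ca, cb = NULL, charged = list(), b = 10) {
  atoms <- list(N = ca + c(-0.95, 0.35, 1.05), CA = ca,
                C = ca + c(0.95, 0.35, -1.05), O = ca + c(0.95, 1.55, -1.25))
  if (!is.null(cb)) atoms$CB <- cb
  atoms <- c(atoms, charged)
  tibble::tibble(
    chain = chain, resno = as.integer(resno), insert = "", aa = aa,
    resid = unname(AA1TO3[aa]),
    elety = names(atoms),
    element = substr(names(atoms), 1, 1),
    x = vapply(atoms, `[`, 0, 1), y = vapply(atoms, `[`, 0, 2),
    z = vapply(atoms, `[`, 0, 3),
    b = b, occ = 1
  )
}

#' Generate a synthetic PDB fixture with known ground truth
#'
#' Realizes a [fixture_spec()]: returns the atom table, PDB text, a matching
#' synthetic DSSP annotation carrying the planted secondary structure and
#' accessibility, and a ground-truth table of every planted bridge and
#' decoy. Planted geometry is exact to construction (well under 0.01
#' Angstrom / 0.1 degree when re-measured).
#'
#' @param spec a [fixture_spec()].
#' @param id structure identifier.
#' @return list of class `sb_fixture` with elements `atoms`
#'   (`sb_structure`), `pdb` (character lines), `dssp` (annotation tibble),
#'   `dssp_text`, `truth`.
#' @export
generate_fixture <- function(spec, id = "SYN") {
  set.seed(spec$seed)
  br <- spec$bridges
  res_list <- list()
  truth <- list()
  ann <- list()
  resno_a <- 0L; resno_b <- 500L
  for (k in seq_len(nrow(br))) {
    o <- c(0, 60 * (k - 1), 0)
    r <- br$ca_dist[k]; t1 <- br$theta1[k] * pi / 180; t2 <- br$theta2[k] * pi / 180
    d <- br$atom_dist[k]
    ca1 <- o
    ca2 <- o + c(r, 0, 0)
    cb1 <- ca1 + 1.53 * c(cos(t1), sin(t1), 0)
    cb2 <- ca2 + 1.53 * c(-cos(t2), sin(t2), 0)
    mid <- o + c(r / 2, 0, 0)
    A <- mid - c(d / 2, 0, 0)   # basic charged atom
    B <- mid + c(d / 2, 0, 0)   # acidic charged atom
    charged_i <- switch(br$aa_i[k],
                        K = list(NZ = A),
                        R = list(NH1 = A, NH2 = A - c(0.8, 0, 0)))
    charged_j <- switch(br$aa_j[k],
                        D = list(OD1 = B, OD2 = B + c(0.8, 0, 0)),
                        E = list(OE1 = B, OE2 = B + c(0.8, 0, 0)))
    chain_i <- "A"
    chain_j <- if (br$inter_subunit[k]) "B" else "A"
    resno_a <- resno_a + 10L
    ri <- resno_a
    if (br$inter_subunit[k]) {
      resno_b <- resno_b + 10L
      rj <- resno_b
    } else {
      resno_a <- resno_a + 7L
      rj <- resno_a
    }
    res_list[[length(res_list) + 1]] <- fixture_residue(chain_i, ri, br$aa_i[k], ca1, cb1, charged_i)
    res_list[[length(res_list) + 1]] <- fixture_residue(chain_j, rj, br$aa_j[k], ca2, cb2, charged_j)
    rsa_pair <- switch(br$exposure[k],
                       exposed = c(0.60, 0.50),
                       buried = c(0.05, 0.05),
                       intermediate = c(0.20, 0.20))
    ss8 <- c(H = "H", S = "E", C = "T")
    ann[[length(ann) + 1]] <- tibble::tibble(
      chain = c(chain_i, chain_j), resno = c(ri, rj), insert = "",
      aa = c(br$aa_i[k], br$aa_j[k]),
      ss8 = c(ss8[[br$ss_i[k]]], ss8[[br$ss_j[k]]]),
      asa = c(rsa_pair[1] * max_asa_table()[[br$aa_i[k]]],
              rsa_pair[2] * max_asa_table()[[br$aa_j[k]]])
    )
    truth[[length(truth) + 1]] <- tibble::tibble(
      structure_id = id, kind = "bridge",
      chain_i = chain_i, resno_i = ri, aa_i = br$aa_i[k],
      chain_j = chain_j, resno_j = rj, aa_j = br$aa_j[k],
      pair_type = br$pair_type[k], ca_dist = r,
      theta1 = br$theta1[k], theta2 = br$theta2[k], atom_dist = d,
      ss_i = br$ss_i[k], ss_j = br$ss_j[k], exposure = br$exposure[k],
      inter_subunit = br$inter_subunit[k]
    )
  }
  # decoys: far compact grid (6 A spacing keeps charged atoms > 4 A apart
  # while making the decoy cluster the densely packed baseline)
  if (spec$n_decoys > 0) {
    for (m in seq_len(spec$n_decoys)) {
      aa <- spec$decoy_aa[1 + (m - 1) %% length(spec$decoy_aa)]
      ca <- c(-30 - 6 * ((m - 1) %% 8), 6 * ((m - 1) %/% 8), 0)
      charged <- switch(aa,
                        K = list(NZ = ca + c(0, 0, 3)),
                        R = list(NH1 = ca + c(0, 0, 3), NH2 = ca + c(0.8, 0, 3)),
                        D = list(OD1 = ca + c(0, 0, 3), OD2 = ca + c(0.8, 0, 3)),
                        E = list(OE1 = ca + c(0, 0, 3), OE2 = ca + c(0.8, 0, 3)),
                        list())
      cb <- if (aa == "G") NULL else ca + c(0, 0.77, 1.32)
      resno_a <- resno_a + 10L
      res_list[[length(res_list) + 1]] <- fixture_residue("A", resno_a, aa, ca, cb, charged)
      ann[[length(ann) + 1]] <- tibble::tibble(
        chain = "A", resno = resno_a, insert = "", aa = aa, ss8 = "T",
        asa = 0.4 * (max_asa_table()[aa] %||% 150))
      truth[[length(truth) + 1]] <- tibble::tibble(
        structure_id = id, kind = "decoy",
        chain_i = "A", resno_i = resno_a, aa_i = aa,
        chain_j = NA_character_, resno_j = NA_integer_, aa_j = NA_character_,
        pair_type = NA_character_, ca_dist = NA_real_, theta1 = NA_real_,
        theta2 = NA_real_, atom_dist = NA_real_, ss_i = NA_character_,
        ss_j = NA_character_, exposure = NA_character_, inter_subunit = NA)
    }
  }
  atoms <- dplyr::bind_rows(res_list)
  nres <- length(unique(paste(atoms$chain, atoms$resno)))
  bvals <- spec$b_factors %||% stats::runif(nres, 5, 30)
  bmap <- stats::setNames(rep_len(bvals, nres),
                          unique(paste(atoms$chain, atoms$resno)))
  atoms$b <- unname(bmap[paste(atoms$chain, atoms$resno)])
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resno)
  atoms <- structure(atoms, class = c("sb_structure", class(atoms)), id = id)
  ann <- dplyr::arrange(dplyr::bind_rows(ann), .data$chain, .data$resno)
  structure(list(atoms = atoms,
                 pdb = write_structure(atoms),
                 dssp = ann,
                 dssp_text = write_dssp(ann),
                 truth = dplyr::bind_rows(truth)),
            class = "sb_fixture")
}

#' Write a fixture to disk
#'
#' @param fx an `sb_fixture`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named list of paths (`pdb`, `dssp`, `truth`).
#' @export
write_fixture <- function(fx, dir, name = attr(fx$atoms, "id")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(pdb = file.path(dir, paste0(name, ".pdb")),
                dssp = file.path(dir, paste0(name, ".dssp")),
                truth = file.path(dir, paste0(name, "_truth.tsv")))
  writeLines(fx$pdb, paths$pdb)
  writeLines(fx$dssp_text, paths$dssp)
  utils::write.table(as.data.frame(fx$truth), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Generate a synthetic survey set with exact planted category counts
#'
#' Plants a requested distribution of exposed surface bridges over
#' categories (pair type, secondary-structure pair, distance bin) across
#' `n_structures` fixtures. Counts are planted exactly — proportions are
#' converted to integers by largest remainder — so that
#' [build_pair_index()] on the surveyed set recovers `100 * proportion` for
#' every category; coordinates (within-bin distances, angles) are randomized
#' under the seed.
#'
#' @param n_structures number of fixture structures.
#' @param categories tibble with `pair_type`, `ss_i`, `ss_j`, `bin_lo`,
#'   `bin_hi` and either `count` (integers) or `prop` (with `n_bridges`).
#' @param n_bridges total bridges when `prop` is given.
#' @param seed integer seed.
#' @param dir optional directory: fixtures are written as PDB + DSSP files.
#' @return list of class `sb_survey_set`: `fixtures` (list of
#'   `sb_fixture`), `truth` (combined ground truth), `categories` (with the
#'   planted `count`), and when written, `paths` (tibble of `pdb`, `dssp`).
#' @export
generate_survey_set <- function(n_structures, categories, n_bridges = NULL,
                                seed = 1L, dir = NULL) {
  categories <- tibble::as_tibble(categories)
  if (!"count" %in% names(categories)) {
    stopifnot(!is.null(n_bridges), "prop" %in% names(categories))
    p <- categories$prop / sum(categories$prop)
    base <- floor(p * n_bridges)
    rem <- n_bridges - sum(base)
    frac_order <- order(p * n_bridges - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
    categories$count <- as.integer(base)
  }
  stopifnot(sum(categories$count) >= 1, n_structures >= 1)
  set.seed(seed)
  plan <- categories[rep(seq_len(nrow(categories)), categories$count), , drop = FALSE]
  plan$structure <- rep_len(seq_len(n_structures), nrow(plan))
  plan$ca_dist <- stats::runif(nrow(plan), plan$bin_lo + 0.05, plan$bin_hi - 0.05)
  plan$theta1 <- stats::runif(nrow(plan), 5, 100)   # always satisfies the angular envelope
  plan$theta2 <- stats::runif(nrow(plan), 5, 170)
  plan$atom_dist <- stats::runif(nrow(plan), 2.7, 3.9)
  fixtures <- vector("list", n_structures)
  seeds <- sample.int(.Machine$integer.max, n_structures)
  for (s in seq_len(n_structures)) {
    rows <- plan[plan$structure == s, , drop = FALSE]
    if (nrow(rows) == 0) {
      rows <- plan[0, , drop = FALSE]
    }
    sp <- fixture_spec(
      bridges = tibble::tibble(
        pair_type = rows$pair_type, ca_dist = rows$ca_dist,
        theta1 = rows$theta1, theta2 = rows$theta2,
        atom_dist = rows$atom_dist, ss_i = rows$ss_i, ss_j = rows$ss_j,
        exposure = "exposed"
      ),
      n_decoys = 3, seed = seeds[s]
    )
    id <- sprintf("SYN%04d", s)
    fixtures[[s]] <- if (nrow(rows) > 0) generate_fixture(sp, id = id) else NULL
  }
  fixtures <- fixtures[!vapply(fixtures, is.null, logical(1))]
  out <- list(fixtures = fixtures,
              truth = dplyr::bind_rows(lapply(fixtures, `[[`, "truth")),
              categories = categories)
  if (!is.null(dir)) {
    paths <- lapply(fixtures, write_fixture, dir = dir)
    out$paths <- tibble::tibble(
      pdb = vapply(paths, `[[`, "", "pdb"),
      dssp = vapply(paths, `[[`, "", "dssp")
    )
  }
  structure(out, class = "sb_survey_set")
}
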