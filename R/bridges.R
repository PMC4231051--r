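#' Detect salt bridges in a structure
#'
#' A salt bridge is an attractive pair between a basic residue (Lys NZ; Arg
#' NH1/NH2) and an acidic residue (Asp OD1/OD2; Glu OE1/OE2) with any
#' qualifying side-chain atom pair closer than the cutoff (default 4
#' Angstrom). His is excluded by construction (ambiguous protonation at pH
#' 7), so only four pair types exist: K-D, K-E, R-D, R-E. One record is
#' emitted per residue pair (the minimum over qualifying atom pairs); pairs
#' within a chain and across chains are both reported, and the orientation
#' is canonicalized with the basic residue first. Candidate residues whose
#' charged-group atoms are absent from the model are silently skipped.
#'
#' @param atoms an `sb_structure` tibble.
#' @param config an [sb_config()].
#' @return tibble of bridges: residue identities (`chain_i`, `resno_i`,
#'   `insert_i`, `aa_i` = basic; `_j` = acidic), `pair_type`,
#'   `min_atom_dist`, `ca_dist`, `theta1`, `theta2` (degrees),
#'   `inter_subunit`. Zero rows when no bridge exists.
#' @export
detect_salt_bridges <- function(atoms, config = sb_config()) {
  charged <- atoms |>
    dplyr::filter(
      (.data$aa == "K" & .data$elety == "NZ") |
        (.data$aa == "R" & .data$elety %in% c("NH1", "NH2")) |
        (.data$aa == "D" & .data$elety %in% c("OD1", "OD2")) |
        (.data$aa == "E" & .data$elety %in% c("OE1", "OE2"))
    )
  basic <- charged[charged$aa %in% c("K", "R"), , drop = FALSE]
  acidic <- charged[charged$aa %in% c("D", "E"), , drop = FALSE]
  empty <- tibble::tibble(
    chain_i = character(), resno_i = integer(), insert_i = character(), aa_i = character(),
    chain_j = character(), resno_j = integer(), insert_j = character(), aa_j = character(),
    pair_type = character(), min_atom_dist = double(), ca_dist = double(),
    theta1 = double(), theta2 = double(), inter_subunit = logical()
  )
  if (nrow(basic) == 0 || nrow(acidic) == 0) return(empty)

  d <- sqrt(outer(basic$x, acidic$x, `-`)^2 +
              outer(basic$y, acidic$y, `-`)^2 +
              outer(basic$z, acidic$z, `-`)^2)
  hit <- which(d < config$bridge_atom_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)

  pairs <- tibble::tibble(
    chain_i = basic$chain[hit[, 1]], resno_i = basic$resno[hit[, 1]],
    insert_i = basic$insert[hit[, 1]], aa_i = basic$aa[hit[, 1]],
    chain_j = acidic$chain[hit[, 2]], resno_j = acidic$resno[hit[, 2]],
    insert_j = acidic$insert[hit[, 2]], aa_j = acidic$aa[hit[, 2]],
    min_atom_dist = d[hit]
  ) |>
    dplyr::group_by(.data$chain_i, .data$resno_i, .data$insert_i, .data$aa_i,
                    .data$chain_j, .data$resno_j, .data$insert_j, .data$aa_j) |>
    dplyr::summarise(min_atom_dist = min(.data$min_atom_dist), .groups = "drop")

  res <- residue_table(atoms)
  res <- ensure_cb(res, atoms)
  key <- function(ch, no, ins) paste(ch, no, ins)
  rk <- key(res$chain, res$resno, res$insert)
  i <- match(key(pairs$chain_i, pairs$resno_i, pairs$insert_i), rk)
  j <- match(key(pairs$chain_j, pairs$resno_j, pairs$insert_j), rk)
  geo <- pair_geometry(
    cbind(res$ca_x[i], res$ca_y[i], res$ca_z[i]),
    cbind(res$cb_x[i], res$cb_y[i], res$cb_z[i]),
    cbind(res$ca_x[j], res$ca_y[j], res$ca_z[j]),
    cbind(res$cb_x[j], res$cb_y[j], res$cb_z[j])
  )
  pairs |>
    dplyr::mutate(
      pair_type = pair_type_of(.data$aa_i, .data$aa_j),
      ca_dist = geo$ca_dist, theta1 = geo$theta1, theta2 = geo$theta2,
      inter_subunit = .data$chain_i != .data$chain_j
    ) |>
    dplyr::arrange(.data$chain_i, .data$resno_i, .data$chain_j, .data$resno_j) |>
    dplyr::relocate("pair_type", "min_atom_dist", "ca_dist", "theta1", "theta2",
                    "inter_subunit", .after = "aa_j")
}

#' Pseudo-angle geometry of a residue pair
#'
#' Given Calpha and Cbeta coordinates of two residues, computes the
#' Calpha--Calpha distance `r` and the two pseudo-angles describing the
#' mutual orientation of the Calpha-Cbeta vectors: `theta1` is the angle at
#' Calpha1 between the rays to Cbeta1 and to Calpha2 (and symmetrically
#' `theta2`). Both lie in [0, 180] degrees.
#'
#' @param ca1,cb1,ca2,cb2 n x 3 coordinate matrices (rows are pairs).
#' @return tibble with `ca_dist`, `theta1`, `theta2`.
#' @export
pair_geometry <- function(ca1, cb1, ca2, cb2) {
  ca1 <- rbind(ca1); cb1 <- rbind(cb1); ca2 <- rbind(ca2); cb2 <- rbind(cb2)
  v12 <- ca2 - ca1
  r <- sqrt(rowSums(v12^2))
  ang <- function(u, v) {
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    if (any(is.finite(nu) & nu < 1e-9) || any(is.finite(nv) & nv < 1e-9)) {
      stop("degenerate geometry: zero-length CA-CB or CA-CA vector")
    }
    cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    acos(cosang) * 180 / pi
  }
  tibble::tibble(
    ca_dist = unname(r),
    theta1 = unname(ang(cb1 - ca1, v12)),
    theta2 = unname(ang(cb2 - ca2, -v12))
  )
}

# fill missing Cbeta with a virtual one from ideal backbone tetrahedral
# geometry (needed for Gly and for models with truncated side chains)
ensure_cb <- function(res, atoms) {
  miss <- which(is.na(res$cb_x))
  for (k in miss) {
    sel <- atoms$chain == res$chain[k] & atoms$resno == res$resno[k] &
      atoms$insert == res$insert[k]
    get <- function(name) {
      i <- which(sel & atoms$elety == name)
      if (length(i) == 0) return(NULL)
      c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
    }
    N <- get("N"); CA <- get("CA"); C <- get("C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    b1 <- CA - N; b2 <- C - CA
    nrm <- vcross(b1, b2)
    cb <- -0.58273431 * nrm + 0.56802827 * b1 - 0.54067466 * b2 + CA
    res$cb_x[k] <- cb[1]; res$cb_y[k] <- cb[2]; res$cb_z[k] <- cb[3]
  }
  res
}

#' Classify a bridge's burial state from residue RSA
#'
#' Exposed: one residue's RSA above the high threshold (default 35%) and the
#' other's above the low one (25%). Buried: both below 9%. Everything else
#' is intermediate. The three classes partition all bridges.
#'
#' @param rsa_i,rsa_j RSA fractions of the two residues (vectorized).
#' @param config an [sb_config()].
#' @return character vector over `{"exposed","buried","intermediate"}`.
#' @export
classify_exposure <- function(rsa_i, rsa_j, config = sb_config()) {
  hi <- pmax(rsa_i, rsa_j)
  lo <- pmin(rsa_i, rsa_j)
  dplyr::case_when(
    hi > config$exposure_rsa_hi & lo > config$exposure_rsa_lo ~ "exposed",
    hi < config$exposure_rsa_buried ~ "buried",
    TRUE ~ "intermediate"
  )
}

#' Survey salt bridges in one annotated structure
#'
#' Runs detection, geometry, secondary-structure assignment of both
#' residues, and exposure classification for a single structure.
#'
#' @param atoms an `sb_structure` tibble.
#' @param dssp optional DSSP path or tibble.
#' @param config an [sb_config()].
#' @return bridge tibble with added `ss_i`, `ss_j`, `rsa_i`, `rsa_j`,
#'   `exposure`, `structure_id`.
#' @export
survey_structure <- function(atoms, dssp = NULL, config = sb_config()) {
  ann <- annotate_structure(atoms, dssp = dssp, config = config)
  ann <- compute_rsa(ann, reference = max_asa_table(config$rsa_reference))
  br <- detect_salt_bridges(atoms, config)
  key <- function(ch, no, ins) paste(ch, no, ins)
  ak <- key(ann$chain, ann$resno, ann$insert)
  i <- match(key(br$chain_i, br$resno_i, br$insert_i), ak)
  j <- match(key(br$chain_j, br$resno_j, br$insert_j), ak)
  br$ss_i <- ann$ss3[i]
  br$ss_j <- ann$ss3[j]
  br$rsa_i <- ann$rsa[i]
  br$rsa_j <- ann$rsa[j]
  br$exposure <- if (nrow(br)) classify_exposure(br$rsa_i, br$rsa_j, config) else character(0)
  br$structure_id <- rep(attr(atoms, "id") %||% NA_character_, nrow(br))
  dplyr::relocate(br, "structure_id")
}

#' Survey salt bridges across a set of structures
#'
#' Applies [survey_structure()] to each PDB file, tolerating per-structure
#' failures (logged to stderr; the survey errors only if every structure
#' fails), and aggregates counts by pair type x exposure and, for the
#' exposed subset, by pair type x secondary-structure pair.
#'
#' @param paths character vector of PDB files.
#' @param dssp optional parallel vector of DSSP files (NA/NULL entries fall
#'   back to internal annotation).
#' @param config an [sb_config()].
#' @return list of class `sb_survey` with elements `bridges` (per-bridge
#'   tibble), `by_exposure` (pair_type x exposure counts), `ss_matrix`
#'   (exposed bridges by pair_type, ss_i, ss_j), `failed` (paths that could
#'   not be processed).
#' @export
survey_structures <- function(paths, dssp = NULL, config = sb_config()) {
  stopifnot(length(paths) >= 1)
  if (!is.null(dssp)) stopifnot(length(dssp) == length(paths))
  out <- vector("list", length(paths))
  failed <- character(0)
  for (k in seq_along(paths)) {
    dk <- if (is.null(dssp) || is.na(dssp[[k]])) NULL else dssp[[k]]
    out[[k]] <- tryCatch(
      survey_structure(read_structure(paths[k]), dssp = dk, config = config),
      error = function(e) {
        message("survey: skipping ", paths[k], ": ", conditionMessage(e))
        failed <<- c(failed, paths[k])
        NULL
      }
    )
  }
  if (all(vapply(out, is.null, logical(1)))) stop("survey failed for every structure")
  bridges <- dplyr::bind_rows(out)
  by_exposure <- bridges |>
    dplyr::count(.data$pair_type, .data$exposure) |>
    tidyr::pivot_wider(names_from = "exposure", values_from = "n", values_fill = 0L)
  ss_matrix <- bridges |>
    dplyr::filter(.data$exposure == "exposed") |>
    dplyr::count(.data$pair_type, .data$ss_i, .data$ss_j)
  structure(list(bridges = bridges, by_exposure = by_exposure,
                 ss_matrix = ss_matrix, failed = failed),
            class = "sb_survey")
}

#' @export
print.sb_survey <- function(x, ...) {
  cat("Salt-bridge survey:", nrow(x$bridges), "bridges,",
      sum(x$bridges$exposure == "exposed"), "exposed,",
      length(x$failed), "structure(s) failed\n")
  print(x$by_exposure)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
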