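#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a tidy one-row-per-atom tibble. Only the first
#' model of a multi-model file is used; HETATM records and waters are
#' dropped, except selenomethionine (MSE) which is kept and mapped to Met;
#' alternate locations are resolved by highest occupancy (ties: first
#' encountered). Residues lacking a Calpha atom are excluded with a warning,
#' since every downstream descriptor (weighted contact number, B-factor,
#' bridge geometry) is anchored on Calpha.
#'
#' @param path a PDB-format file.
#' @param id structure identifier; defaults to the file base name.
#' @return a tibble of class `sb_structure` with columns `chain`, `resno`,
#'   `insert`, `aa` (one-letter), `resid` (three-letter), `elety` (atom
#'   name), `element`, `x`, `y`, `z`, `b`, `occ`, and attributes `id` and
#'   `source_path`.
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ", conditionMessage(e))
  )
  at <- tibble::as_tibble(pdb$atom)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep & at$resid != "HOH", , drop = FALSE]
  at$aa <- unname(AA3TO1[at$resid])
  at <- at[!is.na(at$aa), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no standard protein residues in '", path, "'")

  atoms <- tibble::tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = as.character(at$insert),
    aa = at$aa,
    resid = ifelse(at$resid == "MSE", "MET", at$resid),
    elety = ifelse(at$resid == "MSE" & at$elety == "SE", "SD", as.character(at$elety)),
    element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z,
    b = at$b,
    occ = at$o,
    alt = as.character(at$alt)
  )

  # altloc policy: highest occupancy wins, ties -> first encountered
  atoms <- atoms |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord", -"alt")

  # drop residues without a Calpha
  atoms <- atoms |> dplyr::group_by(.data$chain, .data$resno, .data$insert)
  no_ca <- dplyr::filter(atoms, !any(.data$elety == "CA"))
  atoms <- dplyr::filter(atoms, any(.data$elety == "CA")) |> dplyr::ungroup()
  if (nrow(no_ca) > 0) {
    dropped <- dplyr::distinct(dplyr::ungroup(no_ca), .data$chain, .data$resno)
    warning(sprintf("excluded %d residue(s) lacking a CA atom (e.g. %s:%d)",
                    nrow(dropped), dropped$chain[1], dropped$resno[1]))
  }
  if (nrow(atoms) == 0) stop("empty structure: no residues with CA in '", path, "'")

  structure(atoms,
            class = c("sb_structure", class(atoms)),
            id = if (is.null(id)) sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE) else id,
            source_path = path)
}

guess_element <- function(elesy, elety) {
  el <- toupper(as.character(elesy))
  bad <- is.na(el) | el == "" | !el %in% c("C", "N", "O", "S", "H", "P", "SE")
  if (any(bad)) {
    nm <- gsub("[0-9']", "", toupper(as.character(elety[bad])))
    el[bad] <- substr(nm, 1, 1)
  }
  el[el == "SE"] <- "S"
  el
}

#' Per-residue view of a structure
#'
#' Collapses the atom table to one row per residue carrying the Calpha
#' coordinates and B-factor, the Cbeta coordinates where present, and the
#' coordinates of the charged side-chain group atoms used for bridge
#' detection.
#'
#' @param atoms an `sb_structure` tibble from [read_structure()].
#' @return a tibble with one row per residue, ordered as in the file.
#' @export
residue_table <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$aa) |>
    dplyr::summarise(
      ca_x = .data$x[match("CA", .data$elety)],
      ca_y = .data$y[match("CA", .data$elety)],
      ca_z = .data$z[match("CA", .data$elety)],
      cb_x = .data$x[match("CB", .data$elety)],
      cb_y = .data$y[match("CB", .data$elety)],
      cb_z = .data$z[match("CB", .data$elety)],
      b_ca = .data$b[match("CA", .data$elety)],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}

#' Serialize an atom table to PDB text
#'
#' Writes standard fixed-width ATOM records (plus TER/END) from the columns
#' of an `sb_structure` tibble. Round-trips through [read_structure()]:
#' re-parsing the serialized text reproduces the retained atoms exactly at
#' PDB coordinate precision (3 decimals).
#'
#' @param atoms an `sb_structure` tibble.
#' @param path optional file to write; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path = NULL`) the character vector of
#'   PDB lines.
#' @export
write_structure <- function(atoms, path = NULL) {
  res3 <- if ("resid" %in% names(atoms)) atoms$resid else unname(AA1TO3[atoms$aa])
  elety <- atoms$elety
  # atom-name column alignment: names of <4 chars start in column 14
  name_fmt <- ifelse(nchar(elety) >= 4, elety, sprintf(" %-3s", elety))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name_fmt, res3, atoms$chain, atoms$resno,
    ifelse(atoms$insert == "", " ", atoms$insert),
    atoms$x, atoms$y, atoms$z,
    if ("occ" %in% names(atoms)) atoms$occ else 1,
    if ("b" %in% names(atoms)) atoms$b else 0,
    if ("element" %in% names(atoms)) atoms$element else ""
  )
  # TER after each chain
  out <- unlist(lapply(split(lines, factor(atoms$chain, levels = unique(atoms$chain))),
                       function(l) c(l, "TER")))
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- DSSP -------------------------------------------------------------

#' Read a classic DSSP output file
#'
#' Parses the fixed-width per-residue block of a DSSP text file: author
#' residue number and insertion code, chain, one-letter amino acid, 8-state
#' secondary-structure code, and the absolute solvent accessibility (ACC,
#' Angstrom^2). Chain-break rows (`!`) are skipped.
#'
#' @param path DSSP text file.
#' @return tibble with columns `chain`, `resno`, `insert`, `aa`, `ss8`,
#'   `asa`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file (missing '  #  RESIDUE' header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & nchar(trimws(substr(body, 6, 10))) > 0
  body <- body[keep]
  tibble::tibble(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    insert = trimws(substr(body, 11, 11)),
    aa = toupper(substr(body, 14, 14)),  # lowercase = SS-bonded Cys
    ss8 = substr(body, 17, 17),
    asa = as.numeric(substr(body, 35, 38))
  )
}

#' Write a minimal classic-format DSSP file
#'
#' Emits the per-residue block with the columns [read_dssp()] consumes
#' (residue number, chain, amino acid, 8-state code, ACC). Used by the
#' synthetic-fixture generator so that planted secondary structure and
#' accessibility flow through the same input path as real DSSP output.
#'
#' @param ann tibble with columns `chain`, `resno`, `insert`, `aa`, `ss8`,
#'   `asa`.
#' @param path optional output file.
#' @return the character vector of lines, invisibly when written to a file.
#' @export
write_dssp <- function(ann, path = NULL) {
  insert <- if ("insert" %in% names(ann)) ifelse(ann$insert == "", " ", ann$insert) else " "
  rows <- sprintf("%5d%5d%1s%1s %1s  %1s %s%4d",
                  seq_len(nrow(ann)), ann$resno, insert, ann$chain, ann$aa,
                  ifelse(ann$ss8 == "", " ", ann$ss8),
                  strrep(" ", 16), pmin(round(ann$asa), 9999))
  out <- c("==== Secondary Structure Definition (synthetic) ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC", rows)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Collapse 8-state DSSP codes to helix/sheet/coil
#'
#' H, G and I become helix (`"H"`); B and E become sheet (`"S"`); T, S,
#' blank and any other code become coil (`"C"`). The mapping is total and
#' deterministic.
#'
#' @param ss8 character vector of DSSP codes.
#' @return character vector over `{"H","S","C"}`.
#' @export
#' @examples
#' ss3_from_ss8(c("H", "G", "B", "T", " "))
ss3_from_ss8 <- function(ss8) {
  dplyr::case_when(
    ss8 %in% c("H", "G", "I") ~ "H",
    ss8 %in% c("B", "E") ~ "S",
    TRUE ~ "C"
  )
}

#' Annotate a structure with secondary structure and solvent accessibility
#'
#' When a DSSP file is supplied its 8-state codes and ACC values are used
#' verbatim (DSSP is the reference annotator; bit-compatibility is preferred
#' when its output is available). Otherwise an internal fallback computes
#' per-residue ASA with the Shrake-Rupley method and assigns secondary
#' structure from backbone phi/psi torsions. Either way the 8-state code is
#' collapsed to helix/sheet/coil with [ss3_from_ss8()].
#'
#' @param atoms an `sb_structure` tibble.
#' @param dssp path to a DSSP file for this structure, or `NULL`.
#' @param config an [sb_config()].
#' @return residue tibble ([residue_table()] columns) plus `ss8`, `ss3`,
#'   `asa`.
#' @export
annotate_structure <- function(atoms, dssp = NULL, config = sb_config()) {
  res <- residue_table(atoms)
  if (!is.null(dssp)) {
    d <- if (is.character(dssp)) read_dssp(dssp) else dssp
    key <- function(t) paste(t$chain, t$resno, t$insert)
    i <- match(key(res), key(d))
    if (anyNA(i)) {
      miss <- res[is.na(i), c("chain", "resno")]
      stop("DSSP/structure mismatch: no DSSP row for residue(s) ",
           paste(utils::head(paste0(miss$chain, ":", miss$resno), 5), collapse = ", "),
           if (nrow(miss) > 5) sprintf(" (and %d more)", nrow(miss) - 5) else "")
    }
    res$ss8 <- d$ss8[i]
    res$asa <- d$asa[i]
  } else {
    res$ss8 <- assign_ss_fallback(atoms)
    sasa <- sasa_shrake_rupley(atoms, n_points = config$sasa_n_points)
    key <- function(t) paste(t$chain, t$resno, t$insert)
    res$asa <- sasa$asa[match(key(res), key(sasa))]
  }
  res$ss3 <- ss3_from_ss8(res$ss8)
  res
}

# torsion-based fallback secondary-structure heuristic: phi/psi in the
# alpha basin over runs of >=4 -> H, beta basin over runs of >=3 -> E,
# everything else T (coil). Crude next to DSSP's hydrogen-bond assignment,
# but total and deterministic; DSSP input takes precedence when provided.
assign_ss_fallback <- function(atoms) {
  res <- residue_table(atoms)
  n <- nrow(res)
  get_atom <- function(chain, resno, insert, name) {
    i <- which(atoms$chain == chain & atoms$resno == resno &
                 atoms$insert == insert & atoms$elety == name)
    if (length(i) == 0) return(NULL)
    c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
  }
  phi <- psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ch <- res$chain[k]
    Nk <- get_atom(ch, res$resno[k], res$insert[k], "N")
    CAk <- get_atom(ch, res$resno[k], res$insert[k], "CA")
    Ck <- get_atom(ch, res$resno[k], res$insert[k], "C")
    if (k > 1 && res$chain[k - 1] == ch) {
      Cp <- get_atom(ch, res$resno[k - 1], res$insert[k - 1], "C")
      if (!is.null(Cp) && !is.null(Nk) && !is.null(CAk) && !is.null(Ck))
        phi[k] <- dihedral4(Cp, Nk, CAk, Ck)
    }
    if (k < n && res$chain[k + 1] == ch) {
      Nn <- get_atom(ch, res$resno[k + 1], res$insert[k + 1], "N")
      if (!is.null(Nn) && !is.null(Nk) && !is.null(CAk) && !is.null(Ck))
        psi[k] <- dihedral4(Nk, CAk, Ck, Nn)
    }
  }
  raw <- dplyr::case_when(
    !is.na(phi) & !is.na(psi) & phi > -120 & phi < -20 & psi > -90 & psi < 40 ~ "H",
    !is.na(phi) & !is.na(psi) & phi > -180 & phi < -40 & (psi > 60 | psi < -150) ~ "E",
    TRUE ~ "T"
  )
  min_run <- c(H = 4L, E = 3L)
  r <- rle(raw)
  r$values <- ifelse(r$values %in% c("H", "E") & r$lengths < min_run[r$values],
                     "T", r$values)
  inverse.rle(r)
}

dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Download a PDB entry into a local cache
#'
#' Fetches `https://files.rcsb.org/download/<ID>.pdb` into `dir` unless the
#' file is already cached. Requires network access; offline use must supply
#' pre-downloaded files.
#'
#' @param id 4-character PDB identifier.
#' @param dir cache directory.
#' @return path to the cached file.
#' @export
fetch_pdb <- function(id, dir = file.path(tempdir(), "pdb_cache")) {
  id <- toupper(id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("could not download PDB entry ", id,
           " (no network access?); place ", id, ".pdb in ", dir, " manually")
    }
  }
  dest
}
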