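#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA on heavy atoms: each atom's sphere (van der Waals radius +
#' probe radius) is sampled with an approximately uniform Fibonacci point
#' set, and the accessible fraction is the share of points not buried inside
#' any neighbouring atom's probe-expanded sphere. Per-residue ASA is the sum
#' over the residue's heavy atoms. Serves as the internal fallback when no
#' DSSP accessibility file is supplied.
#'
#' @param atoms an `sb_structure` tibble.
#' @param n_points sphere sample points per atom; the discretization error
#'   scales roughly as 1/n_points.
#' @param probe probe (water) radius, Angstrom.
#' @return list-free tibble: one row per residue with `chain`, `resno`,
#'   `insert`, `aa`, `asa` (Angstrom^2), plus attribute `atom_area` (per-atom
#'   areas, file order).
#' @export
sasa_shrake_rupley <- function(atoms, n_points = 240, probe = 1.4) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  n <- nrow(heavy)
  if (n == 0) stop("no heavy atoms")
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  rad <- vdw_radius(heavy$element) + probe
  pts <- fibonacci_sphere(n_points)

  # neighbour lists via a single distance matrix (fixtures and single chains
  # are small; the survey path feeds structures one at a time)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (rad[i] + rad)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0) {
      frac <- 1
    } else {
      sp <- sweep(pts * rad[i], 2, xyz[i, ], `+`)   # n_points x 3
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dd <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
          (sp[free, 3] - xyz[j, 3])^2
        free[free] <- dd > rad[j]^2
      }
      frac <- mean(free)
    }
    area[i] <- 4 * pi * rad[i]^2 * frac
  }
  out <- heavy |>
    dplyr::mutate(.area = area) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$aa) |>
    dplyr::summarise(asa = sum(.data$.area), .groups = "drop")
  attr(out, "atom_area") <- area
  out
}

vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

# deterministic, approximately uniform unit-sphere point set
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build an extended Gly-X-Gly tripeptide
#'
#' Constructs an idealized extended (phi = psi = 180 degrees, trans)
#' tripeptide with heavy backbone atoms and the full heavy side chain of the
#' centre residue X, as used to define the maximal-ASA normalization for
#' relative solvent accessibility.
#'
#' @param x one-letter code of the centre residue.
#' @return an `sb_structure`-shaped tibble.
#' @export
build_gxg <- function(x = "A") {
  stopifnot(x %in% names(AA1TO3))
  # extended backbone template: repeat unit along +x, standard bond geometry
  unit <- 3.63  # Calpha-Calpha rise in the fully extended conformation
  mk_res <- function(resno, aa, x0, flip) {
    s <- if (flip) -1 else 1
    bb <- rbind(
      N  = c(x0 - 1.20, s * 0.60, 0),
      CA = c(x0, 0, 0),
      C  = c(x0 + 1.26, s * -0.45, 0),
      O  = c(x0 + 1.30, s * -1.67, 0)
    )
    sc <- sidechain_template(aa, s)
    sc[, 1] <- sc[, 1] + x0
    coords <- rbind(bb, sc)
    tibble::tibble(
      chain = "A", resno = resno, insert = "", aa = aa,
      resid = unname(AA1TO3[aa]), elety = rownames(coords),
      element = substr(rownames(coords), 1, 1),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      b = 10, occ = 1
    )
  }
  out <- dplyr::bind_rows(
    mk_res(1, "G", 0, FALSE),
    mk_res(2, x, unit, TRUE),
    mk_res(3, "G", 2 * unit, FALSE)
  )
  structure(out, class = c("sb_structure", class(out)), id = paste0("GXG_", x))
}

# heavy side-chain atoms in a local frame (CA at origin); geometry is
# idealized (tetrahedral branches, standard bond lengths), adequate for
# surface-area work, not for covalent-geometry validation
sidechain_template <- function(aa, s = 1) {
  up <- function(k) c(0, s * 0.7 * k, 1.1 * k)  # rough chain extension off the backbone plane
  tmpl <- switch(aa,
    G = matrix(numeric(0), ncol = 3),
    A = rbind(CB = up(1.4) / 1.4 * 1.53),
    S = rbind(CB = up(1.4), OG = up(1.4) + c(0.9, 0, 1.0)),
    C = rbind(CB = up(1.4), SG = up(1.4) + c(1.0, 0, 1.3)),
    T = rbind(CB = up(1.4), OG1 = up(1.4) + c(0.95, 0, 0.95), CG2 = up(1.4) + c(-0.95, s * 0.6, 0.95)),
    V = rbind(CB = up(1.4), CG1 = up(1.4) + c(1.0, 0, 1.05), CG2 = up(1.4) + c(-1.0, s * 0.6, 1.05)),
    L = rbind(CB = up(1.4), CG = up(2.6), CD1 = up(2.6) + c(1.05, 0, 1.0), CD2 = up(2.6) + c(-1.05, s * 0.6, 1.0)),
    I = rbind(CB = up(1.4), CG1 = up(2.6), CG2 = up(1.4) + c(-1.0, s * 0.6, 1.05), CD1 = up(3.9)),
    M = rbind(CB = up(1.4), CG = up(2.6), SD = up(3.95), CE = up(5.2)),
    F = ring6("CB", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), up, s),
    Y = rbind(ring6("CB", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), up, s), OH = up(6.6)),
    W = rbind(CB = up(1.4), CG = up(2.6), CD1 = up(2.6) + c(1.1, 0, 0.8), CD2 = up(3.7),
              NE1 = up(3.7) + c(1.3, 0, 0.6), CE2 = up(4.4) + c(0.8, 0, 0), CE3 = up(4.4) + c(-1.1, 0, 0),
              CZ2 = up(5.5) + c(0.6, 0, 0), CZ3 = up(5.5) + c(-1.0, 0, 0), CH2 = up(6.2)),
    P = rbind(CB = up(1.4), CG = up(1.4) + c(-1.2, 0, 0.8), CD = c(-1.5, s * 1.2, 0.8)),
    D = rbind(CB = up(1.4), CG = up(2.6), OD1 = up(2.6) + c(1.1, 0, 0.6), OD2 = up(2.6) + c(-1.1, s * 0.5, 0.6)),
    N = rbind(CB = up(1.4), CG = up(2.6), OD1 = up(2.6) + c(1.1, 0, 0.6), ND2 = up(2.6) + c(-1.1, s * 0.5, 0.6)),
    E = rbind(CB = up(1.4), CG = up(2.6), CD = up(3.9), OE1 = up(3.9) + c(1.1, 0, 0.6), OE2 = up(3.9) + c(-1.1, s * 0.5, 0.6)),
    Q = rbind(CB = up(1.4), CG = up(2.6), CD = up(3.9), OE1 = up(3.9) + c(1.1, 0, 0.6), NE2 = up(3.9) + c(-1.1, s * 0.5, 0.6)),
    K = rbind(CB = up(1.4), CG = up(2.6), CD = up(3.9), CE = up(5.2), NZ = up(6.5)),
    R = rbind(CB = up(1.4), CG = up(2.6), CD = up(3.9), NE = up(5.2), CZ = up(6.4),
              NH1 = up(6.4) + c(1.15, 0, 0.5), NH2 = up(6.4) + c(-1.15, s * 0.5, 0.5)),
    H = rbind(CB = up(1.4), CG = up(2.6), ND1 = up(2.6) + c(1.2, 0, 0.7), CD2 = up(2.6) + c(-1.2, s * 0.5, 0.7),
              CE1 = up(3.9) + c(1.2, 0, 0.3), NE2 = up(3.9) + c(-1.0, 0, 0.3)),
    stop("no side-chain template for '", aa, "'")
  )
  if (nrow(tmpl) > 0) tmpl[, , drop = FALSE] else tmpl
}

ring6 <- function(cb, names6, up, s) {
  base <- rbind(up(2.6), up(2.6) + c(1.2, 0, 0.7), up(2.6) + c(-1.2, s * 0.5, 0.7),
                up(3.9) + c(1.2, 0, 0.7), up(3.9) + c(-1.2, s * 0.5, 0.7), up(4.6))
  rownames(base) <- names6
  rbind(CB = up(1.4), base)
}
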