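#' Run configuration for salt-bridge survey and design
#'
#' Collects every tunable threshold of the pipeline in one list so that a run
#' is a pure function of (inputs, config, seed). Defaults are the conventions
#' used throughout: a salt bridge is a basic/acidic side-chain atom pair under
#' 4 Angstrom; candidate partners are searched within a 15 Angstrom
#' Calpha--Calpha radius; for pairs spanning more than 7 Angstrom at least one
#' of the two pseudo-angles (theta1, theta2) must be under 110 degrees;
#' designable positions require RSA > 35%, positive B-factor and rWCN
#' z-scores, and a ConSurf conservation grade under 4; sequence separation of
#' a designed pair must be at least 5 residues unless the pair crosses a
#' subunit interface.
#'
#' @param bridge_atom_cutoff maximum side-chain N--O distance (Angstrom) that
#'   defines a salt bridge.
#' @param neighbor_radius Calpha--Calpha search radius (Angstrom) for partner
#'   residues, including residues on other chains of an oligomer.
#' @param angle_cutoff,angle_distance_gate the angular restraint: for
#'   Calpha--Calpha distances above `angle_distance_gate` (Angstrom) at least
#'   one pseudo-angle must be below `angle_cutoff` (degrees).
#' @param rsa_min,z_b_min,z_rwcn_min,cons_max pre-filter thresholds on
#'   relative solvent accessibility (fraction), the two structural z-scores,
#'   and the conservation grade (grades strictly below `cons_max` pass).
#' @param seq_sep_min minimum |residue-number difference| for an intra-chain
#'   designed pair.
#' @param exposure_rsa_hi,exposure_rsa_lo a surveyed bridge is *exposed* when
#'   one residue's RSA exceeds `exposure_rsa_hi` and the other's exceeds
#'   `exposure_rsa_lo`; *buried* when both are below `exposure_rsa_buried`.
#' @param exposure_rsa_buried see above.
#' @param bin_edges distance-bin edges (Angstrom) of the pair index, applied
#'   to the Calpha--Calpha distance.
#' @param rsa_reference which maximal-ASA reference table to use, see
#'   [max_asa_table()].
#' @param sd_type z-score normalization convention, `"population"` (divide by
#'   the root mean squared deviation) or `"sample"` (n-1 denominator).
#' @param sasa_n_points number of sphere sample points for the internal
#'   Shrake-Rupley solvent-accessibility fallback.
#' @return a named list of class `sb_config`.
#' @export
#' @examples
#' cfg <- sb_config()
#' cfg$neighbor_radius
sb_config <- function(bridge_atom_cutoff = 4.0,
                      neighbor_radius = 15.0,
                      angle_cutoff = 110,
                      angle_distance_gate = 7.0,
                      rsa_min = 0.35,
                      z_b_min = 0,
                      z_rwcn_min = 0,
                      cons_max = 4,
                      seq_sep_min = 5,
                      exposure_rsa_hi = 0.35,
                      exposure_rsa_lo = 0.25,
                      exposure_rsa_buried = 0.09,
                      bin_edges = seq(3, 15, by = 1),
                      rsa_reference = c("tien2013_theoretical", "tien2013_empirical"),
                      sd_type = c("population", "sample"),
                      sasa_n_points = 240) {
  rsa_reference <- match.arg(rsa_reference)
  sd_type <- match.arg(sd_type)
  stopifnot(
    bridge_atom_cutoff > 0, neighbor_radius > 0, angle_cutoff > 0,
    angle_distance_gate > 0, seq_sep_min >= 1,
    length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE)
  )
  structure(
    list(
      bridge_atom_cutoff = bridge_atom_cutoff,
      neighbor_radius = neighbor_radius,
      angle_cutoff = angle_cutoff,
      angle_distance_gate = angle_distance_gate,
      rsa_min = rsa_min,
      z_b_min = z_b_min,
      z_rwcn_min = z_rwcn_min,
      cons_max = cons_max,
      seq_sep_min = seq_sep_min,
      exposure_rsa_hi = exposure_rsa_hi,
      exposure_rsa_lo = exposure_rsa_lo,
      exposure_rsa_buried = exposure_rsa_buried,
      bin_edges = bin_edges,
      rsa_reference = rsa_reference,
      sd_type = sd_type,
      sasa_n_points = sasa_n_points
    ),
    class = "sb_config"
  )
}

#' Maximal accessible surface area in an extended Gly-X-Gly tripeptide
#'
#' Published reference values (Tien et al. 2013, PLOS ONE 8:e80635) used to
#' normalize a residue's absolute solvent accessibility to a relative one
#' (RSA). The "theoretical" set is the conformational maximum; the
#' "empirical" set is the maximum observed in crystal structures.
#'
#' @param which `"tien2013_theoretical"` (default) or `"tien2013_empirical"`.
#' @return named numeric vector, one-letter amino-acid codes, Angstrom^2.
#' @export
#' @examples
#' max_asa_table()[["A"]]
max_asa_table <- function(which = c("tien2013_theoretical", "tien2013_empirical")) {
  which <- match.arg(which)
  if (which == "tien2013_theoretical") {
    c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
      E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
      L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
      S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
  } else {
    c(A = 121.0, R = 265.0, N = 187.0, D = 187.0, C = 148.0,
      E = 214.0, Q = 214.0, G = 97.0,  H = 216.0, I = 195.0,
      L = 191.0, K = 230.0, M = 203.0, F = 228.0, P = 154.0,
      S = 143.0, T = 163.0, W = 264.0, Y = 255.0, V = 165.0)
  }
}

#' Electrostatic charge of an amino acid at neutral pH
#'
#' +1 for the basic residues Lys and Arg, -1 for the acidic residues Asp and
#' Glu, 0 otherwise. Histidine is deliberately uncharged: its protonation
#' state at pH 7 is ambiguous, so it takes no part in bridge detection or
#' design.
#'
#' @param aa character vector of one-letter codes.
#' @return integer vector of charges.
#' @export
#' @examples
#' charge_of(c("K", "E", "H", "A"))
charge_of <- function(aa) {
  ifelse(aa %in% c("K", "R"), 1L, ifelse(aa %in% c("D", "E"), -1L, 0L))
}

# side-chain atoms whose pairwise distance defines a bridge
bridge_atoms_of <- function(aa) {
  switch(aa,
    K = "NZ",
    R = c("NH1", "NH2"),
    D = c("OD1", "OD2"),
    E = c("OE1", "OE2"),
    character(0)
  )
}

# canonical pair-type label, basic residue first: "K-D", "R-E", ...
pair_type_of <- function(aa_basic, aa_acidic) paste0(aa_basic, "-", aa_acidic)

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
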