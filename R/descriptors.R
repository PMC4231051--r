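#' Weighted contact number per residue
#'
#' The weighted contact number (WCN) of residue *i* is the sum over all
#' other residues *j* of the inverse squared Calpha--Calpha distance,
#' `wcn_i = sum_j 1/d_ij^2`; its reciprocal rWCN is a per-residue measure of
#' *low* packing density (large rWCN = loosely packed). The sum runs over the
#' whole assembly — every chain present — because packing at subunit
#' interfaces matters for inter-subunit design.
#'
#' @param atoms an `sb_structure` tibble, or a residue tibble with `ca_x`,
#'   `ca_y`, `ca_z` columns.
#' @return residue tibble with `wcn` (Angstrom^-2) and `rwcn` (Angstrom^2).
#' @export
compute_wcn <- function(atoms) {
  res <- if (all(c("ca_x", "ca_y", "ca_z") %in% names(atoms))) atoms else residue_table(atoms)
  n <- nrow(res)
  if (n < 2) stop("WCN undefined: need at least 2 residues with CA")
  xyz <- cbind(res$ca_x, res$ca_y, res$ca_z)
  d2 <- as.matrix(stats::dist(xyz))^2
  inv <- 1 / d2
  diag(inv) <- 0
  res$wcn <- unname(rowSums(inv))
  res$rwcn <- 1 / res$wcn
  res
}

#' Grouped z-scores
#'
#' Standardizes `values` within each `group` (typically one chain) to zero
#' mean and unit spread: `z = (x - mean) / sd`. The default uses the
#' population (divide-by-n) standard deviation, so that within a group
#' `mean(z) = 0` and the population sd of `z` is exactly 1.
#'
#' @param values numeric vector.
#' @param group grouping vector (recycled length-1 allowed); default one
#'   group.
#' @param sd_type `"population"` or `"sample"`.
#' @return numeric vector of z-scores.
#' @export
#' @examples
#' zscore(c(1, 3))
zscore <- function(values, group = rep(1L, length(values)),
                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(group) == 1L) group <- rep(group, length(values))
  stopifnot(length(group) == length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(group)) {
    i <- which(group == g)
    x <- values[i]
    ok <- is.finite(x)
    if (sum(ok) < 2) stop("z-score needs >= 2 finite values in group '", g, "'")
    m <- mean(x[ok])
    s <- stats::sd(x[ok])
    if (sd_type == "population") s <- s * sqrt((sum(ok) - 1) / sum(ok))
    if (!is.finite(s) || s == 0) stop("degenerate distribution (sd = 0) in group '", g, "'")
    out[i] <- (x - m) / s
  }
  out
}

#' Relative solvent accessibility
#'
#' Divides each residue's absolute solvent accessibility (ASA) by the
#' maximal ASA of that amino acid in an extended Gly-X-Gly tripeptide
#' ([max_asa_table()]). Values above 1 are retained, not clamped. Residues
#' whose amino acid has no reference value are skipped with a warning.
#'
#' @param annotation residue tibble with `aa` and `asa` columns (from
#'   [annotate_structure()]).
#' @param reference named vector of maximal ASA values per amino acid.
#' @return the annotation tibble with an added `rsa` column (fraction).
#' @export
compute_rsa <- function(annotation, reference = max_asa_table()) {
  ref <- reference[annotation$aa]
  if (anyNA(ref)) {
    bad <- unique(annotation$aa[is.na(ref)])
    warning("no maximal-ASA reference for: ", paste(bad, collapse = ", "),
            " (rsa set NA)")
  }
  annotation$rsa <- annotation$asa / unname(ref)
  annotation
}

#' Load a per-residue conservation table
#'
#' Reads ConSurf-style conservation grades (integers 1 = most variable to
#' 9 = most conserved) from a whitespace- or tab-delimited file with columns
#' `chain`, `resnum`, `grade` (header optional).
#'
#' @param path TSV file.
#' @return tibble with `chain`, `resno`, `grade`.
#' @export
read_conservation <- function(path) {
  empty <- tibble::tibble(chain = character(), resno = integer(), grade = integer())
  if (length(readLines(path, warn = FALSE)) == 0) return(empty)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("chain", "resno", "grade"))
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.integer(raw$grade[1])))) {
    raw <- raw[-1, , drop = FALSE]  # header row
  }
  out <- tibble::tibble(
    chain = raw$chain,
    resno = as.integer(raw$resno),
    grade = as.integer(raw$grade)
  )
  if (anyNA(out$grade) || any(out$grade < 1 | out$grade > 9)) {
    stop("conservation grades must be integers in 1..9: ", path)
  }
  if (anyDuplicated(paste(out$chain, out$resno))) {
    stop("duplicate conservation rows for the same residue in ", path)
  }
  out
}

#' Per-residue descriptor table
#'
#' Assembles everything the design pre-filters consume: 3-state secondary
#' structure, ASA and RSA, Calpha B-factor, WCN/rWCN, z-scores of B-factor
#' and rWCN (normalized per chain), and the conservation grade where
#' available. Mirrors the per-residue characteristics table of a design run
#' (columns `chain, resno, aa, ss3, asa, rsa, b, z_b, wcn, rwcn, z_rwcn,
#' conservation`).
#'
#' @param atoms an `sb_structure` tibble.
#' @param dssp optional DSSP file path (or pre-read tibble) for SS/ASA.
#' @param conservation optional conservation tibble or file path.
#' @param config an [sb_config()].
#' @return tibble, one row per residue.
#' @export
compute_descriptors <- function(atoms, dssp = NULL, conservation = NULL,
                                config = sb_config()) {
  ann <- annotate_structure(atoms, dssp = dssp, config = config)
  ann <- compute_rsa(ann, reference = max_asa_table(config$rsa_reference))
  res <- compute_wcn(ann)
  res <- ensure_cb(res, atoms)  # virtual Cbeta for Gly / truncated side chains
  res$b <- res$b_ca
  res$z_b <- zscore(res$b, res$chain, sd_type = config$sd_type)
  res$z_rwcn <- zscore(res$rwcn, res$chain, sd_type = config$sd_type)
  res$conservation <- NA_integer_
  if (!is.null(conservation)) {
    cons <- if (is.character(conservation)) read_conservation(conservation) else conservation
    i <- match(paste(res$chain, res$resno), paste(cons$chain, cons$resno))
    res$conservation <- cons$grade[i]
    unmatched <- sum(!paste(cons$chain, cons$resno) %in% paste(res$chain, res$resno))
    if (unmatched > 0) {
      warning(unmatched, " conservation row(s) matched no residue in the structure")
    }
  }
  dplyr::select(
    res, "chain", "resno", "insert", "aa", "ss3", "ss8", "asa", "rsa",
    "b", "z_b", "wcn", "rwcn", "z_rwcn", "conservation",
    "ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z"
  )
}

#' Write a descriptor table as TSV
#'
#' @param descriptors tibble from [compute_descriptors()].
#' @param path output file.
#' @export
write_descriptors <- function(descriptors, path) {
  cols <- c("chain", "resno", "aa", "ss3", "rsa", "b", "z_b", "rwcn",
            "z_rwcn", "conservation")
  utils::write.table(descriptors[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
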