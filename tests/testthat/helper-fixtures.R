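# shared builders and independent oracles for the test suite

# one descriptor row with explicit coordinates (design-engine tests build
# scenarios directly at the descriptor level)
mk_desc_row <- function(chain, resno, aa, ss3, ca, cb,
                        rsa = 0.6, z_b = 1, z_rwcn = 1, cons = 2L, b = 20) {
  tibble::tibble(
    chain = chain, resno = as.integer(resno), insert = "", aa = aa,
    ss3 = ss3, ss8 = "T", asa = 100, rsa = rsa, b = b, z_b = z_b,
    wcn = 0.1, rwcn = 10, z_rwcn = z_rwcn, conservation = as.integer(cons),
    ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
    cb_x = cb[1], cb_y = cb[2], cb_z = cb[3]
  )
}

# random rigid-body motion (rotation from QR of a gaussian matrix + shift)
random_rigid_motion <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- stats::rnorm(3, sd = 20)
  function(xyz) sweep(as.matrix(xyz) %*% t(R), 2, t, `+`)
}

apply_motion_atoms <- function(atoms, motion) {
  m <- motion(cbind(atoms$x, atoms$y, atoms$z))
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

# O(n^2) double-loop weighted contact number, independent of the
# distance-matrix implementation
wcn_brute <- function(xyz) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i != j) s <- s + 1 / sum((xyz[i, ] - xyz[j, ])^2)
    }
    out[i] <- s
  }
  out
}

# manual pair-index lookup walking the tidy weight table with explicit
# bin comparisons (independent of findInterval-based index_weight)
lookup_brute <- function(idx_tab, pair_type, ss_i, ss_j, d) {
  row <- idx_tab[idx_tab$pair_type == pair_type & idx_tab$ss_i == ss_i &
                   idx_tab$ss_j == ss_j & idx_tab$bin_lo <= d & d < idx_tab$bin_hi, ]
  if (nrow(row) == 0) 0 else row$weight[1]
}

# a small random survey-set category table over all four pair types
random_categories <- function(n_cat = 8) {
  pts <- c("K-D", "K-E", "R-D", "R-E")
  ss <- c("H", "S", "C")
  cats <- tibble::tibble(
    pair_type = sample(pts, n_cat, replace = TRUE),
    ss_i = sample(ss, n_cat, replace = TRUE),
    ss_j = sample(ss, n_cat, replace = TRUE),
    bin_lo = sample(3:13, n_cat, replace = TRUE)
  )
  cats$bin_hi <- cats$bin_lo + 1
  cats <- dplyr::distinct(cats)
  cats$count <- sample(1:6, nrow(cats), replace = TRUE)
  cats
}

# minimal PDB text builder for parser edge-case tests
pdb_line <- function(serial, name, res3, chain, resno, x, y, z,
                     occ = 1, b = 10, altloc = " ", type = "ATOM  ", el = NULL) {
  if (is.null(el)) el <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%s%5d %4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, altloc, res3, chain, resno, x, y, z, occ, b, el)
}
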