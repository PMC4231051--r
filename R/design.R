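#' Pre-filter designable positions
#'
#' Applies the design cascade to a descriptor table: residue type must be
#' polar (S, T, C, N, Q) or charged (K, R, D, E); RSA above 35%; B-factor
#' z-score above 0 (flexibility above the chain average); rWCN z-score above
#' 0 (packing density below average); conservation grade below 4 (variable
#' positions only — residues with no grade fail the filter). The survivor
#' count after each step is attached as attribute `cascade`.
#'
#' @param descriptors tibble from [compute_descriptors()].
#' @param config an [sb_config()].
#' @return the surviving rows, with attribute `cascade` (named integer
#'   vector: `type`, `rsa`, `z_b`, `z_rwcn`, `conservation`).
#' @export
prefilter_positions <- function(descriptors, config = sb_config()) {
  d0 <- dplyr::filter(descriptors, .data$aa %in% c("S", "T", "C", "N", "Q", "K", "R", "D", "E"))
  d1 <- dplyr::filter(d0, .data$rsa > config$rsa_min)
  d2 <- dplyr::filter(d1, .data$z_b > config$z_b_min)
  d3 <- dplyr::filter(d2, .data$z_rwcn > config$z_rwcn_min)
  d4 <- dplyr::filter(d3, !is.na(.data$conservation) & .data$conservation < config$cons_max)
  if (nrow(d4) == 0 && all(is.na(descriptors$conservation))) {
    warning("no conservation grades attached to any residue; pre-filter returns no positions")
  }
  structure(d4, cascade = c(type = nrow(d0), rsa = nrow(d1), z_b = nrow(d2),
                            z_rwcn = nrow(d3), conservation = nrow(d4)))
}

#' Charged residues within the design radius of a position
#'
#' Returns every Lys/Arg/Asp/Glu residue — on any chain, so residues across
#' a subunit interface are included — whose Calpha lies within
#' `config$neighbor_radius` (default 15 Angstrom) of the position's Calpha,
#' excluding the position itself.
#'
#' @param descriptors descriptor tibble (needs `ca_*` coordinates).
#' @param chain,resno,insert identify the position.
#' @param config an [sb_config()].
#' @return the neighbour rows with an added `ca_dist` column.
#' @export
find_charged_neighbors <- function(descriptors, chain, resno, insert = "",
                                   config = sb_config()) {
  self <- descriptors$chain == chain & descriptors$resno == resno &
    descriptors$insert == insert
  if (!any(self)) stop("position ", chain, ":", resno, " not found")
  p <- descriptors[which(self)[1], ]
  cand <- descriptors[!self & descriptors$aa %in% c("K", "R", "D", "E"), , drop = FALSE]
  if (nrow(cand) == 0) return(dplyr::mutate(cand, ca_dist = double(0)))
  cand$ca_dist <- sqrt((cand$ca_x - p$ca_x)^2 + (cand$ca_y - p$ca_y)^2 +
                         (cand$ca_z - p$ca_z)^2)
  dplyr::filter(cand, .data$ca_dist <= config$neighbor_radius)
}

#' Angular restraint on a designed pair
#'
#' A pair passes when its Calpha--Calpha distance is at most the gate
#' (default 7 Angstrom), or at least one of the two pseudo-angles is below
#' the cutoff (default 110 degrees) — the empirical envelope of surveyed
#' surface bridges, ensuring the side chains can point toward each other
#' over longer spans.
#'
#' @param theta1,theta2 pseudo-angles, degrees.
#' @param ca_dist Calpha--Calpha distance, Angstrom.
#' @param config an [sb_config()].
#' @return logical vector.
#' @export
check_angular_constraint <- function(theta1, theta2, ca_dist, config = sb_config()) {
  ca_dist <= config$angle_distance_gate | pmin(theta1, theta2) < config$angle_cutoff
}

#' Weighted electrostatic attraction score of a hypothetical substitution
#'
#' Scores a position, assumed substituted to the charged amino acid
#' `substitution`, against a set of neighbouring residues: each neighbour of
#' opposite charge contributes the pair-index weight of (pair type,
#' secondary-structure pair, Calpha--Calpha distance bin); neighbours of
#' like charge or no charge contribute 0 (repulsive pairings carry no
#' weight). The position total is the sum over neighbours. Geometry uses the
#' native backbone only (Calpha/Cbeta of the unmutated residues) — no
#' side-chain modelling.
#'
#' @param position one descriptor row (the site being designed).
#' @param substitution one of `"K"`, `"R"`, `"D"`, `"E"`.
#' @param neighbors descriptor rows of nearby residues (see
#'   [find_charged_neighbors()]).
#' @param index a `pair_index`.
#' @param config an [sb_config()].
#' @return tibble of per-pair records (partner identity, geometry,
#'   `seq_sep`, `inter_subunit`, `score`) with the position total in
#'   attribute `total`.
#' @export
electrostatic_score <- function(position, substitution, neighbors, index,
                                config = sb_config()) {
  stopifnot(substitution %in% c("K", "R", "D", "E"), nrow(position) == 1)
  if (nrow(neighbors) == 0) {
    out <- tibble::tibble(
      partner_chain = character(), partner_resno = integer(),
      partner_aa = character(), ca_dist = double(), theta1 = double(),
      theta2 = double(), seq_sep = double(), inter_subunit = logical(),
      score = double()
    )
    return(structure(out, total = 0))
  }
  geo <- pair_geometry(
    matrix(c(position$ca_x, position$ca_y, position$ca_z), nrow(neighbors), 3, byrow = TRUE),
    matrix(c(position$cb_x, position$cb_y, position$cb_z), nrow(neighbors), 3, byrow = TRUE),
    cbind(neighbors$ca_x, neighbors$ca_y, neighbors$ca_z),
    cbind(neighbors$cb_x, neighbors$cb_y, neighbors$cb_z)
  )
  q_sub <- charge_of(substitution)
  q_nb <- charge_of(neighbors$aa)
  attractive <- q_sub * q_nb < 0
  # canonical orientation: basic residue first in the pair label, and its
  # secondary structure is the first of the SS pair
  if (q_sub > 0) {
    pt <- paste0(substitution, "-", neighbors$aa)
    ssi <- rep(position$ss3, nrow(neighbors))
    ssj <- neighbors$ss3
  } else {
    pt <- paste0(neighbors$aa, "-", substitution)
    ssi <- neighbors$ss3
    ssj <- rep(position$ss3, nrow(neighbors))
  }
  w <- rep(0, nrow(neighbors))
  if (any(attractive)) {
    w[attractive] <- index_weight(index, pt[attractive], ssi[attractive],
                                  ssj[attractive], geo$ca_dist[attractive])
  }
  out <- tibble::tibble(
    partner_chain = neighbors$chain,
    partner_resno = neighbors$resno,
    partner_aa = neighbors$aa,
    ca_dist = geo$ca_dist,
    theta1 = geo$theta1,
    theta2 = geo$theta2,
    seq_sep = ifelse(neighbors$chain == position$chain,
                     abs(neighbors$resno - position$resno), Inf),
    inter_subunit = neighbors$chain != position$chain,
    score = w
  )
  structure(out, total = sum(w))
}

#' Suggest thermostabilizing charged substitutions
#'
#' For each candidate position (default: the [prefilter_positions()]
#' survivors) every substitution K, R, D, E is scored against every charged
#' neighbour that passes the angular restraint. A position is dropped when
#' all of its putative pairs sit closer than `seq_sep_min` residues in
#' sequence (such local pairs are not expected to rigidify the fold);
#' inter-chain pairs always satisfy the separation rule. The predicted pair
#' is the highest-scoring pair with adequate separation. When the globally
#' best pair of a position is a short-separation one, the alternative-
#' substitution rule applies: a substitution is still acceptable if its best
#' adequately-separated pair outscores that same substitution's best
#' short-separation pair; the highest-scoring such alternative is suggested.
#' Equal top scores yield multiple suggestions.
#'
#' @param descriptors descriptor tibble for the whole assembly.
#' @param index a `pair_index`.
#' @param positions optional tibble of positions to design (descriptor
#'   rows); default applies the pre-filter cascade.
#' @param config an [sb_config()].
#' @return tibble of suggestions, one row per (position, substitution,
#'   predicted partner): `chain`, `resno`, `aa`, `substitution`, partner
#'   identity, `score`, geometry, `seq_sep`, `inter_subunit`, `alt_rule`.
#'   The full score matrix over all putative pairs is in attribute
#'   `all_pairs`.
#' @export
suggest_mutations <- function(descriptors, index, positions = NULL,
                              config = sb_config()) {
  if (is.null(positions)) positions <- prefilter_positions(descriptors, config)
  all_pairs <- list()
  suggestions <- list()
  for (k in seq_len(nrow(positions))) {
    p <- positions[k, ]
    nb <- find_charged_neighbors(descriptors, p$chain, p$resno, p$insert, config)
    if (nrow(nb) == 0) next
    pos_pairs <- purrr::map(c("D", "E", "K", "R"), function(sub) {
      pp <- electrostatic_score(p, sub, nb, index, config)
      pp <- pp[charge_of(sub) * charge_of(pp$partner_aa) < 0, , drop = FALSE]
      if (nrow(pp) == 0) return(NULL)
      tibble::tibble(chain = p$chain, resno = p$resno, aa = p$aa,
                     substitution = sub, pp)
    }) |> dplyr::bind_rows()
    if (nrow(pos_pairs) == 0) next
    pos_pairs <- pos_pairs[check_angular_constraint(pos_pairs$theta1, pos_pairs$theta2,
                                                    pos_pairs$ca_dist, config), , drop = FALSE]
    if (nrow(pos_pairs) == 0) next
    all_pairs[[length(all_pairs) + 1]] <- pos_pairs

    qual <- pos_pairs$seq_sep >= config$seq_sep_min  # Inf across chains
    if (!any(qual)) next                              # only local pairs: not scored
    best_all <- max(pos_pairs$score)
    best_qual <- max(pos_pairs$score[qual])
    eps <- 1e-9
    if (best_qual >= best_all - eps) {
      sel <- qual & pos_pairs$score >= best_qual - eps
      sug <- dplyr::mutate(pos_pairs[sel, , drop = FALSE], alt_rule = FALSE)
    } else {
      # global best is a short-separation pair: per-substitution rescue
      sug <- pos_pairs |>
        dplyr::group_by(.data$substitution) |>
        dplyr::group_modify(function(d, key) {
          q <- d$seq_sep >= config$seq_sep_min
          if (!any(q)) return(d[0, , drop = FALSE])
          bq <- max(d$score[q])
          bs <- if (any(!q)) max(d$score[!q]) else -Inf
          if (bq > bs + eps || bs == -Inf) d[q & d$score >= bq - eps, , drop = FALSE]
          else d[0, , drop = FALSE]
        }) |>
        dplyr::ungroup()
      if (nrow(sug) == 0) next
      top <- max(sug$score)
      sug <- dplyr::mutate(sug[sug$score >= top - eps, , drop = FALSE], alt_rule = TRUE)
    }
    if (nrow(sug) > 0 && max(sug$score) > 0) {
      suggestions[[length(suggestions) + 1]] <- sug
    }
  }
  out <- dplyr::bind_rows(suggestions)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, .data$chain, .data$resno, .data$substitution,
                          .data$partner_chain, .data$partner_resno)
    out <- dplyr::relocate(out, "chain", "resno", "aa", "substitution",
                           "partner_chain", "partner_resno", "partner_aa", "score")
  } else {
    out <- tibble::tibble(
      chain = character(), resno = integer(), aa = character(),
      substitution = character(), partner_chain = character(),
      partner_resno = integer(), partner_aa = character(), score = double(),
      ca_dist = double(), theta1 = double(), theta2 = double(),
      seq_sep = double(), inter_subunit = logical(), alt_rule = logical()
    )
  }
  structure(out, all_pairs = dplyr::bind_rows(all_pairs))
}

#' Write a suggestion table as TSV
#'
#' @param suggestions tibble from [suggest_mutations()].
#' @param path output file.
#' @param all_pairs also dump the full putative-pair score matrix to
#'   `<path>.all_pairs.tsv`.
#' @export
write_suggestions <- function(suggestions, path, all_pairs = FALSE) {
  utils::write.table(as.data.frame(suggestions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (all_pairs && !is.null(attr(suggestions, "all_pairs"))) {
    utils::write.table(as.data.frame(attr(suggestions, "all_pairs")),
                       paste0(path, ".all_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Scatter plot of designed-pair geometry
#'
#' Pseudo-angles of every putative pair, coloured by whether the pair
#' passes the angular restraint, sized by score.
#'
#' @param suggestions result of [suggest_mutations()] (uses the `all_pairs`
#'   attribute) or any pair tibble with `theta1`, `theta2`, `ca_dist`,
#'   `score`.
#' @param config an [sb_config()].
#' @return a ggplot object.
#' @export
plot_pair_geometry <- function(suggestions, config = sb_config()) {
  d <- attr(suggestions, "all_pairs") %||% suggestions
  d <- dplyr::mutate(d, pass = check_angular_constraint(.data$theta1, .data$theta2,
                                                        .data$ca_dist, config))
  ggplot2::ggplot(d, ggplot2::aes(.data$theta1, .data$theta2,
                                  colour = .data$pass, size = .data$score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = config$angle_cutoff, linetype = 2) +
    ggplot2::geom_vline(xintercept = config$angle_cutoff, linetype = 2) +
    ggplot2::labs(x = expression(theta[1] ~ "(deg)"), y = expression(theta[2] ~ "(deg)"),
                  colour = "angular restraint", size = "pair score",
                  title = "Putative-pair orientation")
}
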