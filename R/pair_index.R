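#' Build the empirical salt-bridge pair index
#'
#' Classifies surveyed (exposed) salt bridges by pair type (K-D, K-E, R-D,
#' R-E), secondary-structure pair of the basic and acidic residues, and
#' Calpha--Calpha distance bin, and converts the category frequencies into
#' weights `w = 100 * count / total`. The weights over all categories sum to
#' 100; categories never observed have weight 0 (and are not stored).
#' Repulsive pairings are absent by construction — only attractive pairs are
#' surveyed.
#'
#' @param bridges bridge tibble (normally the exposed subset of a survey)
#'   with columns `pair_type`, `ss_i`, `ss_j`, `ca_dist`.
#' @param bin_edges distance-bin edges, Angstrom; bridges outside the range
#'   are dropped with a warning.
#' @return a `pair_index` object: a tibble with `pair_type`, `ss_i`, `ss_j`,
#'   `bin_lo`, `bin_hi`, `count`, `weight`, and attributes `n_bridges` and
#'   `bin_edges`.
#' @export
build_pair_index <- function(bridges, bin_edges = sb_config()$bin_edges) {
  if (is.null(bridges) || nrow(bridges) == 0) stop("cannot build a pair index from zero bridges")
  bin <- findInterval(bridges$ca_dist, bin_edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin < length(bin_edges)
  if (any(!inside)) {
    warning(sum(!inside), " bridge(s) outside the distance-bin range [",
            min(bin_edges), ", ", max(bin_edges), "] dropped from the index")
  }
  b <- bridges[inside, , drop = FALSE]
  bin <- bin[inside]
  if (nrow(b) == 0) stop("no bridges inside the distance-bin range")
  tab <- b |>
    dplyr::mutate(bin_lo = bin_edges[bin], bin_hi = bin_edges[bin + 1]) |>
    dplyr::count(.data$pair_type, .data$ss_i, .data$ss_j, .data$bin_lo,
                 .data$bin_hi, name = "count") |>
    dplyr::mutate(weight = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(.data$pair_type, .data$ss_i, .data$ss_j, .data$bin_lo)
  structure(tab,
            class = c("pair_index", class(tab)),
            n_bridges = nrow(b),
            bin_edges = bin_edges)
}

#' Look up pair-index weights
#'
#' Vectorized lookup of the empirical weight for (pair type, secondary
#' structure pair, Calpha--Calpha distance). Unobserved categories score 0;
#' distances outside the bin range contribute 0 with a warning.
#'
#' @param index a `pair_index`.
#' @param pair_type,ss_i,ss_j,ca_dist vectors (recycled to common length).
#' @return numeric vector of weights.
#' @export
index_weight <- function(index, pair_type, ss_i, ss_j, ca_dist) {
  edges <- attr(index, "bin_edges")
  n <- max(length(pair_type), length(ss_i), length(ss_j), length(ca_dist))
  pair_type <- rep_len(pair_type, n); ss_i <- rep_len(ss_i, n)
  ss_j <- rep_len(ss_j, n); ca_dist <- rep_len(ca_dist, n)
  bin <- findInterval(ca_dist, edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin < length(edges)
  if (any(!inside)) {
    warning(sum(!inside), " distance(s) outside the pair-index bin range; contribution 0")
  }
  key <- paste(pair_type, ss_i, ss_j, ifelse(inside, edges[pmax(bin, 1)], NA))
  ikey <- paste(index$pair_type, index$ss_i, index$ss_j, index$bin_lo)
  w <- index$weight[match(key, ikey)]
  w[is.na(w) | !inside] <- 0
  w
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pair index into its weight table
#'
#' @param x a `pair_index`.
#' @param ... unused.
#' @return tibble of categories and weights.
#' @export
tidy.pair_index <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("pair_type", "ss_i", "ss_j", "bin_lo", "bin_hi",
                                 "count", "weight")])
}

#' One-row summary of a pair index
#'
#' @param x a `pair_index`.
#' @param ... unused.
#' @return tibble with the number of bridges, categories, bin range and the
#'   (checksum) total weight.
#' @export
glance.pair_index <- function(x, ...) {
  edges <- attr(x, "bin_edges")
  tibble::tibble(
    n_bridges = attr(x, "n_bridges"),
    n_categories = nrow(x),
    bin_lo = min(edges),
    bin_hi = max(edges),
    total_weight = sum(x$weight)
  )
}

#' @export
print.pair_index <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Salt-bridge pair index: %d bridges, %d non-empty categories, bins [%g, %g] A, sum(w) = %g\n",
              g$n_bridges, g$n_categories, g$bin_lo, g$bin_hi, g$total_weight))
  print(tidy(x), ...)
  invisible(x)
}

#' Heatmap of pair-index weights
#'
#' Distance bin against secondary-structure pair, faceted by residue pair
#' type, filled by empirical weight.
#'
#' @param object a `pair_index`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pair_index <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(ss_pair = paste0(.data$ss_i, "-", .data$ss_j),
                  bin_mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_mid, .data$ss_pair, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~pair_type) +
    ggplot2::scale_fill_viridis_c(name = "weight") +
    ggplot2::labs(x = expression(C*alpha - C*alpha ~ "distance (Å)"),
                  y = "secondary-structure pair (basic-acidic)",
                  title = "Salt-bridge pairing-preference index")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write / read a pair index as TSV
#'
#' The file carries `# n_bridges=` and `# bin_edges=` header comments and
#' one row per non-empty category; writing then reading reproduces the
#' object exactly.
#'
#' @param index a `pair_index`.
#' @param path file path.
#' @return `write_pair_index()` the path, invisibly; `read_pair_index()` a
#'   `pair_index`.
#' @export
write_pair_index <- function(index, path) {
  hdr <- c(
    sprintf("# n_bridges=%d", attr(index, "n_bridges")),
    sprintf("# bin_edges=%s", paste(format(attr(index, "bin_edges"), digits = 17, trim = TRUE), collapse = ","))
  )
  body <- utils::capture.output(
    utils::write.table(
      dplyr::mutate(tidy(index), weight = format(.data$weight, digits = 17, trim = TRUE)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pair_index
#' @export
read_pair_index <- function(path) {
  if (!file.exists(path)) stop("cannot read pair index file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nb <- as.integer(sub("^# n_bridges=", "", grep("^# n_bridges=", hdr, value = TRUE)))
  edges <- as.numeric(strsplit(sub("^# bin_edges=", "",
                                   grep("^# bin_edges=", hdr, value = TRUE)), ",")[[1]])
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", colClasses = c(
                             pair_type = "character", ss_i = "character",
                             ss_j = "character", bin_lo = "numeric",
                             bin_hi = "numeric", count = "integer",
                             weight = "numeric"))
  tab <- tibble::as_tibble(tab)
  if (abs(sum(tab$weight) - 100) > 1e-6) {
    stop("pair-index weights in ", path, " do not sum to 100")
  }
  structure(tab, class = c("pair_index", class(tab)),
            n_bridges = nb, bin_edges = edges)
}
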