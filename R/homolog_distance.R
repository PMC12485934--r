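#' Pairwise sequence identity under pairwise deletion
#'
#' Fraction of identical columns among the columns where both aligned
#' sequences carry a residue (gaps `-` and `.` are deleted pairwise).
#'
#' @param seq_a,seq_b aligned sequences of equal length (character strings
#'   or character vectors of single letters).
#' @return identity fraction `q` in `(0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- to_chars(seq_a); b <- to_chars(seq_b)
  if (length(a) != length(b)) stop("aligned lengths differ")
  gap <- c("-", ".")
  ok <- !(a %in% gap) & !(b %in% gap)
  if (!any(ok)) stop("zero comparable columns (all-gap overlap)")
  mean(a[ok] == b[ok])
}

to_chars <- function(s) {
  if (length(s) == 1 && nchar(s) > 1) strsplit(toupper(s), "")[[1]] else toupper(as.character(s))
}

#' Parameters for Grishin distances
#'
#' @param max_mismatch_fraction pairs more diverged than this mismatch
#'   fraction are capped and flagged excluded rather than dropped, so the
#'   distance matrix stays complete for tree building. Default 0.85.
#' @param max_distance distance assigned to capped pairs; default the
#'   Grishin distance at the cap boundary (`q = 1 - max_mismatch_fraction`),
#'   the largest finite value the cap admits.
#' @return list of class `distance_params`.
#' @export
distance_params <- function(max_mismatch_fraction = 0.85, max_distance = NULL) {
  if (max_mismatch_fraction <= 0 || max_mismatch_fraction >= 1) {
    stop("max_mismatch_fraction must be in (0, 1)")
  }
  if (is.null(max_distance)) {
    max_distance <- grishin_root(1 - max_mismatch_fraction)
  }
  structure(list(max_mismatch_fraction = max_mismatch_fraction,
                 max_distance = max_distance,
                 gap_policy = "pairwise-delete"),
            class = "distance_params")
}

# forward map of the Grishin protein distance: expected identity at distance d
grishin_q <- function(d) ifelse(d == 0, 1, log(1 + 2 * d) / (2 * d))

# monotone root-finding for q = ln(1+2d)/(2d); q in (0, 1)
grishin_root <- function(q) {
  f <- function(d) grishin_q(d) - q
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Grishin protein distance from an identity fraction
#'
#' Solves `q = ln(1 + 2d) / (2d)` for the evolutionary distance `d`
#' (substitutions per site, accounting for rate variation across sites) by
#' monotone root-finding to `|delta q| < 1e-9`. `q = 1` gives `d = 0`.
#' Pairs whose mismatch fraction `1 - q` exceeds the allowed maximum
#' receive the capped `max_distance` and carry an `excluded` attribute.
#'
#' @param q identity fraction in `(0, 1]`.
#' @param params a [distance_params()].
#' @return distance in substitutions/site, with logical attribute
#'   `excluded`.
#' @export
grishin_distance <- function(q, params = distance_params()) {
  if (!is.finite(q) || q <= 0) stop("q must be in (0, 1]")
  if (q > 1) stop("q must be <= 1")
  if ((1 - q) > params$max_mismatch_fraction) {
    return(structure(params$max_distance, excluded = TRUE))
  }
  d <- if (q == 1) 0 else grishin_root(q)
  structure(d, excluded = FALSE)
}

#' Pairwise Grishin distance matrix from an alignment
#'
#' @param alignment named character vector (or list) of aligned sequences
#'   of equal length, or a path-free object from [read_alignment()].
#' @param params a [distance_params()].
#' @return symmetric matrix of class `grishin_dist` with zero diagonal and
#'   a logical `excluded` attribute matrix flagging capped pairs.
#' @export
distance_matrix <- function(alignment, params = distance_params()) {
  seqs <- lapply(alignment, to_chars)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (length(unique(lengths(seqs))) != 1) stop("aligned lengths differ")
  taxa <- names(alignment) %||% paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  ex <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      q <- pairwise_identity(seqs[[i]], seqs[[j]])
      g <- grishin_distance(q, params)
      d[i, j] <- d[j, i] <- as.numeric(g)
      ex[i, j] <- ex[j, i] <- attr(g, "excluded")
    }
  }
  structure(d, excluded = ex, class = c("grishin_dist", "matrix", "array"))
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned protein FASTA file.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- ape::read.FASTA(path, type = "AA")
  out <- vapply(as.character(aln), paste0, character(1), collapse = "")
  toupper(out)
}

#' Build an unrooted distance tree in Newick form
#'
#' Neighbor joining (a minimum-evolution-family distance method) on a
#' complete distance matrix. Negative branch lengths are clamped to zero.
#' Taxa are sorted by name before joining so tie-breaking is deterministic.
#' Two taxa yield the degenerate single-edge tree with the distance split
#' evenly.
#'
#' @param dm distance matrix (e.g. from [distance_matrix()]).
#' @return Newick text (character scalar, terminated with `;`).
#' @export
build_tree <- function(dm) {
  m <- unclass(dm)
  attributes(m) <- list(dim = dim(dm), dimnames = dimnames(dm))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  if (n == 2) {
    h <- m[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", rownames(m)[1], format(h), rownames(m)[2], format(h)))
  }
  tr <- ape::nj(m)
  tr$edge.length <- pmax(tr$edge.length, 0)
  ape::write.tree(tr)
}

#' Write Newick text to a file
#'
#' @param newick Newick text from [build_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}
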