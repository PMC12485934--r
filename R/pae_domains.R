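#' Domain partition
#'
#' Per-residue domain assignment for a single chain. Label `0` marks linker
#' residues (residues not assigned to any compact domain); labels `1..K`
#' are domains, numbered by order of first occurrence along the sequence.
#' Domains may be non-contiguous.
#'
#' @param assignments integer vector over residues `1..n`; `0` = linker.
#' @return integer vector of class `domain_partition`.
#' @export
domain_partition <- function(assignments) {
  a <- as.integer(assignments)
  if (any(is.na(a)) || any(a < 0)) stop("assignments must be non-negative integers")
  structure(a, class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  s <- segments_of(x)
  cat(sprintf("<domain_partition> %d residues, %d domain(s) (%d non-contiguous), %d linker residue(s)\n",
              length(x), length(unique(x[x > 0])), s$multi_segment_count, sum(x == 0)))
  invisible(x)
}

#' Build a partition from a segment table
#'
#' Inverse of [segments_of()] / [write_segments()]. Segment intervals are
#' 1-based and closed on both ends. Overlapping printed ranges are resolved
#' first-come (the lower domain id keeps the shared residues) with a warning.
#'
#' @param segments data.frame with columns `domain`, `start`, `end`.
#' @param n chain length in residues (default: largest `end`).
#' @return a [domain_partition()].
#' @export
partition_from_segments <- function(segments, n = max(segments$end)) {
  stopifnot(all(c("domain", "start", "end") %in% names(segments)))
  if (any(segments$start > segments$end)) stop("segment start > end")
  if (any(segments$start < 1) || any(segments$end > n)) stop("segment outside 1..n")
  a <- rep(0L, n)
  seg <- segments[order(segments$domain, segments$start), , drop = FALSE]
  n_clash <- 0L
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start[i]:seg$end[i]
    clash <- a[idx] != 0L
    n_clash <- n_clash + sum(clash)
    a[idx[!clash]] <- as.integer(seg$domain[i])
  }
  if (n_clash > 0) {
    warning(sprintf("%d residue(s) claimed by more than one domain; first assignment kept",
                    n_clash))
  }
  domain_partition(a)
}

#' Per-domain segments of a partition
#'
#' Segments are maximal runs of identical domain label along the sequence.
#'
#' @param partition a [domain_partition()].
#' @return list with `segments` (data.frame `domain`, `start`, `end`, sorted
#'   by domain then start) and `multi_segment_count`, the number of domains
#'   composed of two or more non-contiguous segments.
#' @export
segments_of <- function(partition) {
  a <- as.integer(partition)
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  seg <- data.frame(domain = r$values[keep], start = starts[keep], end = ends[keep])
  seg <- seg[order(seg$domain, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  multi <- sum(table(seg$domain) >= 2)
  list(segments = seg, multi_segment_count = as.integer(multi))
}

#' Confidence weights from a PAE matrix
#'
#' Transforms pairwise expected position errors into symmetric confidence
#' weights in `[0,1]`:
#' `w(i,j) = max(0, 1 - min(PAE(i,j), PAE(j,i)) / cutoff)`.
#' Asymmetry is resolved optimistically by the minimum of the two
#' directions: a low error in either direction indicates rigid relative
#' placement of the pair. The diagonal is set to zero and ignored.
#'
#' @param pae a [pae_matrix()].
#' @param cutoff PAE value (Angstrom) at and beyond which confidence is
#'   zero; default 12.
#' @return symmetric matrix of class `confidence_matrix`.
#' @export
confidence_from_pae <- function(pae, cutoff = 12) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  p <- unclass(pae)
  attributes(p) <- list(dim = dim(p))
  w <- 1 - pmin(p, t(p)) / cutoff
  w[w < 0] <- 0
  diag(w) <- 0
  structure(w, class = c("confidence_matrix", "matrix", "array"))
}

#' Clustering parameters for domain segmentation
#'
#' @param pae_cutoff PAE cutoff (Angstrom) for [confidence_from_pae()];
#'   default 12.
#' @param resolution modularity resolution of the community step; larger
#'   values give more, smaller domains. Default 1.
#' @param min_segment shortest contiguous run (residues) allowed to stand
#'   alone; shorter runs are reassigned to the flanking domain with the
#'   larger mean weight. Default 5, the scale of the shortest segments seen
#'   in real multi-segment domains.
#' @param min_domain smallest total residue count of a domain; smaller
#'   clusters are merged into the cluster they are most strongly connected
#'   to. Default 40.
#' @param linker_threshold residues whose mean weight to their own domain
#'   falls below this are relabeled linker. Default 0.2.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(pae_cutoff = 12, resolution = 1.0, min_segment = 5,
                           min_domain = 40, linker_threshold = 0.2) {
  stopifnot(pae_cutoff > 0, resolution > 0, min_segment > 0, min_domain > 0,
            linker_threshold > 0)
  structure(list(pae_cutoff = pae_cutoff, resolution = resolution,
                 min_segment = min_segment, min_domain = min_domain,
                 linker_threshold = linker_threshold),
            class = "cluster_params")
}

# mean confidence between residue sets (0 when either is empty)
mean_w <- function(w, i, j) {
  if (!length(i) || !length(j)) return(0)
  mean(w[i, j, drop = FALSE])
}

#' Segment a chain into domains from confidence weights
#'
#' Community detection on the weighted residue graph (modularity objective,
#' Leiden refinement, fixed internal RNG for deterministic output), followed
#' by three cleanup passes: (i) contiguous runs shorter than `min_segment`
#' are reassigned to the flanking domain with the larger mean weight;
#' (ii) domains smaller than `min_domain` are merged into the cluster with
#' the largest inter-cluster mean weight; (iii) residues whose mean weight
#' to their own domain falls below `linker_threshold` are relabeled linker.
#' Domains are renumbered 1..K in order of first residue.
#'
#' @param conf a [confidence_from_pae()] matrix.
#' @param params a [cluster_params()].
#' @return a [domain_partition()].
#' @export
cluster_domains <- function(conf, params = cluster_params()) {
  w <- unclass(conf)
  attributes(w) <- list(dim = dim(w))
  n <- nrow(w)
  if (n < 2) stop("need at least 2 residues")
  if (all(w == 0)) {
    warning("degenerate all-zero weight matrix: all residues labeled linker")
    return(domain_partition(rep(0L, n)))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  m <- with_seed(20260929, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = params$resolution,
                                 weights = igraph::E(g)$weight,
                                 n_iterations = 5)
    as.integer(igraph::membership(cl))
  })

  # (i) absorb short contiguous runs into the better-connected flank
  for (pass in 1:20) {
    r <- rle(m)
    if (length(r$values) == 1) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < params$min_segment)
    changed <- FALSE
    for (k in short) {
      idx <- starts[k]:ends[k]
      cand <- unique(c(if (k > 1) r$values[k - 1L],
                       if (k < length(r$values)) r$values[k + 1L]))
      cand <- setdiff(cand, r$values[k])
      if (!length(cand)) next
      mw <- vapply(cand, function(d) mean_w(w, idx, which(m == d)), numeric(1))
      m[idx] <- cand[which.max(mw)]
      changed <- TRUE
    }
    if (!changed) break
  }

  # (ii) merge undersized clusters into their strongest neighbor
  unmergeable <- integer(0)
  repeat {
    sizes <- table(m)
    small <- as.integer(names(sizes)[sizes < params$min_domain])
    small <- setdiff(small, unmergeable)
    if (!length(small) || length(sizes) == 1) break
    d <- small[order(sizes[as.character(small)], small)][1]
    others <- setdiff(unique(m), d)
    mw <- vapply(others, function(o) mean_w(w, which(m == d), which(m == o)),
                 numeric(1))
    if (max(mw) <= 0) {
      unmergeable <- c(unmergeable, d)  # no connection anywhere; left for (iii)
      next
    }
    best <- max(mw)
    tied <- others[mw >= best - 1e-12]
    # ties broken toward the cluster containing the lowest residue index
    target <- tied[which.min(vapply(tied, function(o) min(which(m == o)), numeric(1)))]
    m[m == d] <- target
  }

  # (iii) weakly attached residues become linkers
  own <- vapply(seq_len(n), function(i) {
    j <- which(m == m[i]); j <- setdiff(j, i)
    if (!length(j)) 0 else mean(w[i, j])
  }, numeric(1))
  m[own < params$linker_threshold] <- 0L

  # renumber by first occurrence
  lab <- unique(m[m > 0])
  m[m > 0] <- match(m[m > 0], lab)
  domain_partition(m)
}

#' Segment a chain into domains directly from a PAE matrix
#'
#' Convenience wrapper: [confidence_from_pae()] then [cluster_domains()].
#'
#' @param pae a [pae_matrix()].
#' @param params a [cluster_params()].
#' @return a [domain_partition()].
#' @export
pae_domains <- function(pae, params = cluster_params()) {
  cluster_domains(confidence_from_pae(pae, params$pae_cutoff), params)
}

#' Pairwise agreement between two partitions
#'
#' Fraction of unordered residue pairs classified concordantly: same-domain
#' in both partitions or different-domain in both (the Rand index). The
#' measure is invariant to domain label permutations. Linker residues are
#' treated as singletons, so two linker residues never count as same-domain.
#'
#' @param a,b [domain_partition()]s of equal length.
#' @return fraction in `[0, 1]`.
#' @export
partition_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("partitions have different lengths")
  n <- length(a)
  la <- as.integer(a); lb <- as.integer(b)
  la[la == 0] <- n + seq_len(sum(la == 0))
  lb[lb == 0] <- n + seq_len(sum(lb == 0))
  tab <- table(la, lb)
  s_ab <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  as.numeric((tot + 2 * s_ab - s_a - s_b) / tot)
}
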