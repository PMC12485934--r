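#' C-alpha to C-alpha distance
#'
#' Euclidean distance between the C-alpha atoms of two residues.
#'
#' @param model an [atomic_model()].
#' @param a,b length-2 vectors `c(chain, resno)`.
#' @return distance in Angstrom, or `NA_real_` when either residue is
#'   absent or lacks a C-alpha (the unmappable signal).
#' @export
ca_distance <- function(model, a, b) {
  pa <- ca_of(model, a[1], as.integer(a[2]))
  pb <- ca_of(model, b[1], as.integer(b[2]))
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  sqrt(sum((pa - pb)^2))
}

ca_of <- function(model, chain, resno) {
  r <- model$residues
  i <- which(r$chain == chain & r$resno == resno)
  if (!length(i) || is.na(r$x[i[1]])) return(NULL)
  c(r$x[i[1]], r$y[i[1]], r$z[i[1]])
}

# chains that can host a given protein identifier
chains_for <- function(model, protein) {
  if (is.null(model$entities)) chain_ids(model)
  else names(model$entities)[model$entities == protein]
}

#' Resolve one cross-link onto a (homo-oligomeric) model
#'
#' In a homo-oligomer the two linked residues cannot be attributed to
#' specific chains by mass spectrometry, so geometry arbitrates: the intra
#' candidate is the minimum over chains `c` of `d(c:res_a, c:res_b)` and the
#' inter candidate the minimum over ordered chain pairs `c != c'` of
#' `d(c:res_a, c':res_b)`. The smaller candidate sets the class; candidates
#' within `tie_margin` of each other demote the call to `"ambiguous"` (the
#' distance is then the overall minimum). The restraint is satisfied when
#' the best distance is less than or equal to `threshold` (inclusive, as
#' expected for amine-reactive cleavable cross-linkers at 35 Angstrom).
#'
#' @param model an [atomic_model()]; chains of a homo-oligomer are assumed
#'   to share one sequence numbering. Heteromeric models match the link's
#'   protein identifiers against the model's `entities`.
#' @param link one-row data.frame or list with `protein_a`, `res_a`,
#'   `protein_b`, `res_b`.
#' @param threshold distance restraint in Angstrom (default 35).
#' @param tie_margin ambiguity margin in Angstrom (default 1).
#' @return list of class `link_assignment`: `best_class` (one of intra,
#'   inter, ambiguous, unmappable), `best_distance`, `best_chain_pair`,
#'   `satisfied`, `margin`.
#' @export
assign_link <- function(model, link, threshold = 35, tie_margin = 1) {
  stopifnot(threshold > 0)
  res_a <- as.integer(link$res_a); res_b <- as.integer(link$res_b)
  ch_a <- chains_for(model, as.character(link$protein_a))
  ch_b <- chains_for(model, as.character(link$protein_b))
  pa <- lapply(ch_a, ca_of, model = model, resno = res_a)
  pb <- lapply(ch_b, ca_of, model = model, resno = res_b)
  names(pa) <- ch_a; names(pb) <- ch_b
  pa <- pa[!vapply(pa, is.null, logical(1))]
  pb <- pb[!vapply(pb, is.null, logical(1))]
  if (!length(pa) || !length(pb)) {
    return(structure(list(best_class = "unmappable", best_distance = NA_real_,
                          best_chain_pair = c(NA_character_, NA_character_),
                          satisfied = NA, margin = NA_real_),
                     class = "link_assignment"))
  }
  best_intra <- Inf; intra_pair <- NULL
  best_inter <- Inf; inter_pair <- NULL
  for (ca in names(pa)) {
    for (cb in names(pb)) {
      d <- sqrt(sum((pa[[ca]] - pb[[cb]])^2))
      if (ca == cb) {
        if (d < best_intra) { best_intra <- d; intra_pair <- c(ca, cb) }
      } else {
        if (d < best_inter) { best_inter <- d; inter_pair <- c(ca, cb) }
      }
    }
  }
  if (is.finite(best_intra) && is.finite(best_inter) &&
      abs(best_intra - best_inter) <= tie_margin) {
    cls <- "ambiguous"
    d <- min(best_intra, best_inter)
    pair <- if (best_intra <= best_inter) intra_pair else inter_pair
  } else if (best_intra <= best_inter) {
    cls <- "intra"; d <- best_intra; pair <- intra_pair
  } else {
    cls <- "inter"; d <- best_inter; pair <- inter_pair
  }
  structure(list(best_class = cls, best_distance = d, best_chain_pair = pair,
                 satisfied = d <= threshold, margin = threshold - d),
            class = "link_assignment")
}

#' Satisfaction report for a cross-link table
#'
#' Aggregates [assign_link()] over every link in the table. Links whose
#' residues cannot be placed on the model are reported as unmappable, never
#' dropped.
#'
#' @param model an [atomic_model()].
#' @param table a [crosslink_table()].
#' @param threshold distance restraint in Angstrom (default 35, inclusive).
#' @param tie_margin passed to [assign_link()].
#' @return list of class `satisfaction_report`: counts (`n_links`,
#'   `n_satisfied`, `n_violated`, `n_unmappable`), `max_satisfied_distance`,
#'   and `assignments`, a data.frame with one row per link in table order.
#' @export
satisfaction_report <- function(model, table, threshold = 35, tie_margin = 1) {
  n <- nrow(table)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- assign_link(model, table[i, ], threshold, tie_margin)
    rows[[i]] <- data.frame(protein_a = table$protein_a[i], res_a = table$res_a[i],
                            protein_b = table$protein_b[i], res_b = table$res_b[i],
                            class = a$best_class, distance = a$best_distance,
                            chain_a = a$best_chain_pair[1], chain_b = a$best_chain_pair[2],
                            satisfied = a$satisfied, margin = a$margin,
                            stringsAsFactors = FALSE)
  }
  asg <- if (n) do.call(rbind, rows) else
    data.frame(protein_a = character(), res_a = integer(),
               protein_b = character(), res_b = integer(),
               class = character(), distance = numeric(),
               chain_a = character(), chain_b = character(),
               satisfied = logical(), margin = numeric())
  n_un <- sum(asg$class == "unmappable")
  n_sat <- sum(asg$satisfied, na.rm = TRUE)
  n_vio <- n - n_sat - n_un
  structure(list(n_links = n, n_satisfied = n_sat, n_violated = n_vio,
                 n_unmappable = n_un,
                 max_satisfied_distance = if (n_sat) max(asg$distance[asg$satisfied %in% TRUE]) else NA_real_,
                 threshold = threshold, assignments = asg),
            class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat(sprintf("<satisfaction_report> %d link(s): %d satisfied (<= %g A), %d violated, %d unmappable\n",
              x$n_links, x$n_satisfied, x$threshold, x$n_violated, x$n_unmappable))
  if (!is.na(x$max_satisfied_distance)) {
    cat(sprintf("  max satisfied distance: %.1f A\n", x$max_satisfied_distance))
  }
  invisible(x)
}

#' Interior/exterior placement of interaction partners
#'
#' For each partner protein cross-linked to the cage, counts how many links
#' touch interior-, exterior-, or buried-labeled cage residues (labels from
#' [classify_surface_residues()]) and calls the binding face: `interior`
#' when every interior/exterior-labeled link is interior, `exterior` when
#' all are exterior, otherwise `ambiguous`. Links to residues with no
#' surface label are counted as unlabeled.
#'
#' @param model an [atomic_model()] of the cage.
#' @param partner_links a [crosslink_table()] in which one endpoint of each
#'   link is `cage_protein` and the other a partner protein. Self-links
#'   (both endpoints the cage) are ignored with a message.
#' @param surface a `surface_classification` from
#'   [classify_surface_residues()].
#' @param cage_protein identifier of the cage protein in the table.
#' @return data.frame with one row per partner: link counts per label and
#'   the called `face`.
#' @export
partner_face <- function(model, partner_links, surface, cage_protein) {
  lab <- consensus_labels(surface)
  is_cage_a <- partner_links$protein_a == cage_protein
  is_cage_b <- partner_links$protein_b == cage_protein
  self <- is_cage_a & is_cage_b
  if (any(self)) {
    message(sprintf("ignoring %d self-link(s) of the cage protein", sum(self)))
  }
  keep <- xor(is_cage_a, is_cage_b)
  pl <- partner_links[keep, , drop = FALSE]
  cage_res <- ifelse(is_cage_a[keep], pl$res_a, pl$res_b)
  partner <- ifelse(is_cage_a[keep], pl$protein_b, pl$protein_a)
  link_lab <- lab[as.character(cage_res)]
  link_lab[is.na(link_lab)] <- "unlabeled"
  out <- do.call(rbind, lapply(sort(unique(partner)), function(p) {
    l <- link_lab[partner == p]
    n_int <- sum(l == "interior"); n_ext <- sum(l == "exterior")
    face <- if (n_int > 0 && n_ext == 0) "interior"
      else if (n_ext > 0 && n_int == 0) "exterior"
      else "ambiguous"
    data.frame(partner = p, n_interior = n_int, n_exterior = n_ext,
               n_buried = sum(l == "buried"), n_unlabeled = sum(l == "unlabeled"),
               face = face, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# majority surface label per residue number across chain copies (ties and
# disagreement involving interior vs exterior fall back to buried)
consensus_labels <- function(surface) {
  sp <- split(surface$label, surface$resno)
  vapply(sp, function(l) {
    tl <- sort(table(l), decreasing = TRUE)
    if (length(tl) > 1 && tl[1] == tl[2]) "buried" else names(tl)[1]
  }, character(1))
}
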