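# Literature-derived reference values for the Tetrahymena CAGE complex, the
# hollow homotetrameric assembly this package was built to characterize.

#' Reference constants for the Tetrahymena CAGE complex
#'
#' Reported values for the CAGE protein family of *Tetrahymena thermophila*:
#' the three paralog lengths (CAGE1, UniProt I7MLD7, 2,216 aa; CAGE2,
#' I7M9Z0, 2,418 aa; CAGE3, I7MGF4, 1,890 aa), the CAGE1 monomer mass
#' (258 kDa), the homotetrameric copy number, and the cavity dimensions of
#' the assembled cage (full axes 18 x 8 x 8 nm).
#'
#' @return list: `monomer_residues`, `monomer_kda`, `copies`,
#'   `paralog_lengths` (named integer vector), `cavity_axes_nm`,
#'   `outer_axes_nm`.
#' @export
cage_reference <- function() {
  list(monomer_residues = 2216L,
       monomer_kda = 258,
       copies = 4L,
       paralog_lengths = c(CAGE1 = 2216L, CAGE2 = 2418L, CAGE3 = 1890L),
       cavity_axes_nm = c(18, 8, 8),
       outer_axes_nm = c(22, 16, 12))
}

#' Reference domain parsing of CAGE1
#'
#' The 15-domain segmentation of the 2,216-residue CAGE1 chain, with five
#' domains (3, 8, 9, 10, 11) composed of non-contiguous segments. Shipped
#' as a data fixture: the original parsing combined visual inspection with
#' PAE boundaries, so it serves as a reference partition rather than an
#' algorithmic target. Domains 10 and 11 overlap at residue 1244 as
#' printed; the lower domain id keeps the residue.
#'
#' @return a [domain_partition()] over 2,216 residues.
#' @export
cage1_domains <- function() {
  path <- system.file("extdata", "cage1_domains.tsv", package = "cagekit")
  suppressWarnings(read_segments(path))
}
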