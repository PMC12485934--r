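#' Atomic model container
#'
#' A light-weight container for the coordinate substrate used throughout the
#' package: ordered chains of residues with C-alpha coordinates in Angstrom.
#' Pseudo-atom models produced by [gen_shell()] use the same container, with
#' one pseudo-atom per residue and a single radius class.
#'
#' @param residues data.frame with columns `chain`, `resno` (1-based integer),
#'   `resname` (3-letter code), and `x`, `y`, `z` C-alpha coordinates in
#'   Angstrom (`NA` when the residue has no C-alpha).
#' @param model_id character scalar naming the model.
#' @param entities optional named character vector mapping `chain` ->
#'   protein identifier, for heteromeric models. `NULL` (the default) means
#'   all chains are copies of the same protein (a homo-oligomer).
#' @param radius_class atomic radius class in Angstrom used when voxelizing
#'   models that carry only one point per residue.
#' @param atoms optional data.frame of all-atom records (`chain`, `resno`,
#'   `elety`, `x`, `y`, `z`) used preferentially by [voxelize()].
#'
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(residues, model_id = "model", entities = NULL,
                         radius_class = 2.0, atoms = NULL) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "resno", "resname", "x", "y", "z") %in% names(residues)))
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  if (any(residues$resno < 1L)) stop("residue indices must be >= 1")
  # chain blocks must be contiguous and chain ids unique within the model
  blocks <- rle(residues$chain)$values
  if (anyDuplicated(blocks)) stop("chain ids must be unique within a model")
  for (ch in blocks) {
    r <- residues$resno[residues$chain == ch]
    if (anyDuplicated(r)) {
      stop(sprintf("duplicate residue index within chain %s", ch))
    }
    if (is.unsorted(r, strictly = TRUE)) {
      warning(sprintf("residue indices in chain %s are not strictly increasing", ch))
    }
  }
  co <- as.matrix(residues[, c("x", "y", "z")])
  if (any(!is.na(co) & !is.finite(co))) stop("non-finite C-alpha coordinate")
  if (!is.null(entities)) {
    stopifnot(!is.null(names(entities)), all(blocks %in% names(entities)))
  }
  structure(list(model_id = as.character(model_id),
                 residues = residues,
                 entities = entities,
                 radius_class = radius_class,
                 atoms = atoms),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  ch <- chain_ids(x)
  n_ca <- sum(!is.na(x$residues$x))
  cat(sprintf("<atomic_model> %s: %d chain(s), %d residues (%d with C-alpha)\n",
              x$model_id, length(ch), nrow(x$residues), n_ca))
  invisible(x)
}

#' Chain identifiers of a model, in file order
#' @param model an [atomic_model()].
#' @return character vector of chain ids.
#' @export
chain_ids <- function(model) rle(model$residues$chain)$values

#' C-alpha coordinates of one chain
#'
#' @param model an [atomic_model()].
#' @param chain chain identifier.
#' @return numeric matrix with columns x,y,z and rownames the residue
#'   numbers; residues without a C-alpha are dropped.
#' @export
ca_coords <- function(model, chain) {
  r <- model$residues[model$residues$chain == chain & !is.na(model$residues$x), ]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- r$resno
  m
}

# all coordinate points used for voxelization: all-atom records if present,
# else the per-residue points
model_points <- function(model) {
  if (!is.null(model$atoms)) {
    as.matrix(model$atoms[, c("x", "y", "z")])
  } else {
    r <- model$residues[!is.na(model$residues$x), ]
    as.matrix(r[, c("x", "y", "z")])
  }
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses the coordinate records of a structure file into an
#' [atomic_model()]. Chains and residues are preserved in file order;
#' residues lacking a C-alpha are retained with missing coordinates and
#' counted in a warning. Only alternate location 'A' (or blank) is kept.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (detect by extension, then first-record sniffing),
#'   `"pdb"`, or `"mmcif"`.
#' @param model_id model identifier; defaults to the file name.
#' @return An [atomic_model()] whose `atoms` slot carries every kept atom
#'   record (used by [voxelize()]); C-alpha coordinates populate `residues`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        first <- readLines(path, n = 50L, warn = FALSE)
        if (any(grepl("^data_|_atom_site", first))) "mmcif" else "pdb"
      }
  }
  pdb <- suppressWarnings(
    if (format == "mmcif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  )
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop("zero ATOM records in ", path)
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      elety = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  # one row per (chain, residue) in file order, C-alpha coordinates if present
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  first_idx <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first_idx],
                    resno = atoms$resno[first_idx],
                    resname = as.character(at$resid)[first_idx],
                    stringsAsFactors = FALSE)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, sep = "\r")
  if (anyDuplicated(ca_key)) {
    stop("duplicate residue index within a chain")
  }
  m <- match(paste(res$chain, res$resno, sep = "\r"), ca_key)
  res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]
  n_missing <- sum(is.na(res$x))
  if (n_missing > 0) {
    warning(sprintf("%d residue(s) lack a C-alpha and are excluded from distance operations",
                    n_missing))
  }
  atomic_model(res, model_id = model_id %||% basename(path), atoms = atoms)
}

#' Write an atomic model as PDB
#'
#' Thin wrapper over [bio3d::write.pdb()]; per-residue C-alpha records only
#' when the model has no all-atom table.
#'
#' @param model an [atomic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (!is.null(model$atoms)) {
    a <- model$atoms
    ele <- a$elety
  } else {
    a <- model$residues[!is.na(model$residues$x), ]
    ele <- rep("CA", nrow(a))
  }
  # bio3d chain ids are single characters; map longer ids deterministically
  ch <- a$chain
  if (any(nchar(ch) > 1)) ch <- LETTERS[match(ch, unique(ch))]
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = ch,
                   resid = rep("GLY", nrow(a)), elety = ele)
  invisible(path)
}
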