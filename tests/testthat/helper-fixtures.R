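# Shared fixtures, built in code. Shell models are cached per seed because
# several files exercise the same geometry.

.fixtures <- new.env()

# unique scratch path per call; files land in the session tempdir
withr_local_file <- function(name) tempfile(fileext = paste0("-", name))

small_shell <- function(seed = 3, openings = list()) {
  key <- paste0("shell-", seed, "-",
                paste(vapply(openings, function(o) o$width_deg, numeric(1)),
                      collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- gen_shell(shell_spec(axes_nm = c(12, 10, 8),
                                             thickness_nm = 1.6, spacing = 4,
                                             openings = openings, seed = seed))
  }
  .fixtures[[key]]
}

sphere_shell <- function(seed = 1, openings = list()) {
  key <- paste0("sphere-", seed, "-", length(openings))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- gen_shell(shell_spec(axes_nm = c(12, 12, 12),
                                             thickness_nm = 2, spacing = 4,
                                             openings = openings, seed = seed))
  }
  .fixtures[[key]]
}

# fixed-column PDB ATOM record (C-alpha unless elety given)
pdb_atom <- function(serial, chain, resno, x, y, z, elety = "CA", resname = "GLY") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", elety), " ", resname, chain, resno, " ",
          x, y, z, 1.0, 0.0, substr(elety, 1, 1))
}

write_mini_pdb <- function(path, atoms) {
  writeLines(c(atoms, "END"), path)
  path
}

# minimal mmCIF with n_chain identical two-residue chains
write_mini_cif <- function(path, n_chain = 4) {
  hdr <- c("data_test", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- character(0)
  id <- 0
  for (ci in seq_len(n_chain)) {
    ch <- LETTERS[ci]
    for (ri in 1:2) {
      id <- id + 1
      rows <- c(rows, sprintf(
        "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s CA 1",
        id, ch, ri, 3.8 * ri, 5 * ci, 0, ri, ch))
    }
  }
  writeLines(c(hdr, rows), path)
  path
}

# independent minimum link distance: exhaustive scan over all chain pairs
brute_min_distance <- function(model, ra, rb) {
  ch <- chain_ids(model)
  best <- Inf
  for (c1 in ch) for (c2 in ch) {
    d <- ca_distance(model, c(c1, ra), c(c2, rb))
    if (!is.na(d) && d < best) best <- d
  }
  best
}

# random rigid-body transform of all model coordinates
rigid_transform <- function(model, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% ry %*% rz
  shift <- runif(3, -20, 20)
  r <- model$residues
  xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(rot)
  r$x <- xyz[, 1] + shift[1]; r$y <- xyz[, 2] + shift[2]; r$z <- xyz[, 3] + shift[3]
  atomic_model(r, model_id = model$model_id, radius_class = model$radius_class)
}
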