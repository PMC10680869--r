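# Structure ingest and output. Atom tables are plain data.frames with one
# row per heavy atom and columns:
#   atom_name, resid (3-letter type), chain, resno, insert, x, y, z,
#   occupancy, alt, element
# PDB reading and writing is delegated to bio3d.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into the package's atom table. Hydrogens and waters
#' are dropped; alternate locations are resolved to the highest-occupancy
#' conformer (first on ties). Residue types outside the 20 canonical
#' amino acids are flagged in the `canonical` column and otherwise kept.
#'
#' @param path PDB file path.
#' @return atom data.frame (see file header for columns).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  elem <- ifelse(!is.na(a$elesy) & nzchar(trimws(a$elesy)),
                 toupper(trimws(a$elesy)),
                 atom_element(trimws(a$elety)))
  keep <- elem != "H" & elem != "D" & !a$resid %in% c("HOH", "WAT")
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  out <- data.frame(
    atom_name = trimws(a$elety),
    resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    element = elem,
    stringsAsFactors = FALSE
  )
  out$canonical <- out$resid %in% AA3
  resolve_altlocs(out)
}

# Keep, per (residue, atom name), the highest-occupancy altloc (first wins
# ties because of the stable ordering of the input).
resolve_altlocs <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(residue_keys(atoms), atoms$atom_name)
  ord <- order(match(key, unique(key)), -atoms$occupancy)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(residue_keys(atoms), atoms$atom_name)), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Residue identifiers of an atom table
#'
#' @param atoms atom data.frame.
#' @return character vector "chain_resno_insert", one entry per atom row.
#' @export
residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "_")
}

#' Split an atom table into residues
#'
#' @param atoms atom data.frame.
#' @return named list of per-residue data.frames, in order of appearance.
#' @export
split_residues <- function(atoms) {
  keys <- residue_keys(atoms)
  split(atoms, factor(keys, levels = unique(keys)))
}

#' Write an atom table to a PDB file
#'
#' @param atoms atom data.frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(atoms, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)),
    resno = atoms$resno,
    resid = atoms$resid,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain,
    insert = ifelse(atoms$insert == "", NA, atoms$insert),
    o = atoms$occupancy,
    b = rep(0, nrow(atoms)),
    elesy = atoms$element
  )
  invisible(path)
}

# Does this residue have its full canonical heavy-atom complement?
residue_complete <- function(res) {
  rt <- res$resid[1]
  if (!rt %in% AA3) return(FALSE)
  needed <- c("N", "CA", "C", sidechain_atom_names(rt))
  all(needed %in% res$atom_name)
}

#' Bundled example structures
#'
#' Paths of the small real protein structures shipped with bio3d, used as
#' reference data for fitting internal coordinates in examples and tests.
#'
#' @return character vector of PDB file paths.
#' @export
example_structure_paths <- function() {
  c(system.file("examples", "1hel.pdb", package = "bio3d"),
    system.file("examples", "1dpx.pdb", package = "bio3d"),
    system.file("examples", "hivp.pdb", package = "bio3d"))
}
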