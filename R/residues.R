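# Canonical residue topology: chi-angle atom quadruples, side-chain build
# order with parent triplets, and the symmetry tables used for loss
# correction and symmetry-aware RMSD.
#
# Atom naming follows the PDB convention. Every side-chain heavy atom is
# placed from a parent triplet (a, b, c) bonded along the chain; its torsion
# a-b-c-d is either one of the chi angles (possibly plus a constant offset,
# e.g. the second branch of an isopropyl group) or an approximately constant
# "redundant" dihedral whose median is fitted from data.

#' @name residue_topology
#' @title Canonical residue topology tables
#' @description `chi_atom_names()` returns the defining atom quadruples of
#'   each chi angle; `sidechain_build_spec()` the dependency-ordered atom
#'   placement recipe; `sidechain_atom_names()` the canonical heavy-atom
#'   complement of a side chain; `n_chi()` the number of chi angles.
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.chi_defs <- list(
  ALA = list(),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLY = list(),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# One entry per placed atom: atom, parents a/b/c, dihedral type.
# dtype "chi<k>" means torsion = chi_k + fitted offset (offset identically 0
# for the atom that defines chi_k); "fixed" means a fitted median torsion.
.sc_entry <- function(atom, a, b, c, dtype) {
  list(atom = atom, a = a, b = b, c = c, dtype = dtype)
}

.build_specs <- local({
  cb <- .sc_entry("CB", "C", "N", "CA", "fixed")
  specs <- list(
    ALA = list(cb),
    ARG = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD", "CA", "CB", "CG", "chi2"),
      .sc_entry("NE", "CB", "CG", "CD", "chi3"),
      .sc_entry("CZ", "CG", "CD", "NE", "chi4"),
      .sc_entry("NH1", "CD", "NE", "CZ", "fixed"),
      .sc_entry("NH2", "CD", "NE", "CZ", "fixed")),
    ASN = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("OD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("ND2", "CA", "CB", "CG", "chi2")),
    ASP = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("OD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("OD2", "CA", "CB", "CG", "chi2")),
    CYS = list(cb, .sc_entry("SG", "N", "CA", "CB", "chi1")),
    GLN = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD", "CA", "CB", "CG", "chi2"),
      .sc_entry("OE1", "CB", "CG", "CD", "chi3"),
      .sc_entry("NE2", "CB", "CG", "CD", "chi3")),
    GLU = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD", "CA", "CB", "CG", "chi2"),
      .sc_entry("OE1", "CB", "CG", "CD", "chi3"),
      .sc_entry("OE2", "CB", "CG", "CD", "chi3")),
    GLY = list(),
    HIS = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("ND1", "CA", "CB", "CG", "chi2"),
      .sc_entry("CD2", "CA", "CB", "CG", "chi2"),
      .sc_entry("CE1", "CB", "CG", "ND1", "fixed"),
      .sc_entry("NE2", "CG", "ND1", "CE1", "fixed")),
    ILE = list(cb,
      .sc_entry("CG1", "N", "CA", "CB", "chi1"),
      .sc_entry("CG2", "N", "CA", "CB", "chi1"),
      .sc_entry("CD1", "CA", "CB", "CG1", "chi2")),
    LEU = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("CD2", "CA", "CB", "CG", "chi2")),
    LYS = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD", "CA", "CB", "CG", "chi2"),
      .sc_entry("CE", "CB", "CG", "CD", "chi3"),
      .sc_entry("NZ", "CG", "CD", "CE", "chi4")),
    MET = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("SD", "CA", "CB", "CG", "chi2"),
      .sc_entry("CE", "CB", "CG", "SD", "chi3")),
    PHE = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("CD2", "CA", "CB", "CG", "chi2"),
      .sc_entry("CE1", "CB", "CG", "CD1", "fixed"),
      .sc_entry("CE2", "CB", "CG", "CD2", "fixed"),
      .sc_entry("CZ", "CG", "CD1", "CE1", "fixed")),
    PRO = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD", "CA", "CB", "CG", "chi2")),
    SER = list(cb, .sc_entry("OG", "N", "CA", "CB", "chi1")),
    THR = list(cb,
      .sc_entry("OG1", "N", "CA", "CB", "chi1"),
      .sc_entry("CG2", "N", "CA", "CB", "chi1")),
    TRP = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("CD2", "CA", "CB", "CG", "chi2"),
      .sc_entry("NE1", "CB", "CG", "CD1", "fixed"),
      .sc_entry("CE2", "CB", "CG", "CD2", "fixed"),
      .sc_entry("CE3", "CB", "CG", "CD2", "fixed"),
      .sc_entry("CZ2", "CG", "CD2", "CE2", "fixed"),
      .sc_entry("CZ3", "CG", "CD2", "CE3", "fixed"),
      .sc_entry("CH2", "CD2", "CE2", "CZ2", "fixed")),
    TYR = list(cb,
      .sc_entry("CG", "N", "CA", "CB", "chi1"),
      .sc_entry("CD1", "CA", "CB", "CG", "chi2"),
      .sc_entry("CD2", "CA", "CB", "CG", "chi2"),
      .sc_entry("CE1", "CB", "CG", "CD1", "fixed"),
      .sc_entry("CE2", "CB", "CG", "CD2", "fixed"),
      .sc_entry("CZ", "CG", "CD1", "CE1", "fixed"),
      .sc_entry("OH", "CD1", "CE1", "CZ", "fixed")),
    VAL = list(cb,
      .sc_entry("CG1", "N", "CA", "CB", "chi1"),
      .sc_entry("CG2", "N", "CA", "CB", "chi1"))
  )
  specs
})

#' @rdname residue_topology
#' @param residue_type 3-letter amino-acid code.
#' @return `chi_atom_names()`: list of character(4) atom-name quadruples.
#' @export
chi_atom_names <- function(residue_type) {
  if (!residue_type %in% AA3) {
    stop("unsupported residue type: ", residue_type)
  }
  .chi_defs[[residue_type]]
}

#' @rdname residue_topology
#' @return `n_chi()`: integer count of chi angles (0 for Gly/Ala).
#' @export
n_chi <- function(residue_type) length(chi_atom_names(residue_type))

#' @rdname residue_topology
#' @return `sidechain_build_spec()`: list of placement entries with fields
#'   `atom`, parent names `a`, `b`, `c`, and `dtype` ("fixed" or "chi1".."chi4").
#' @export
sidechain_build_spec <- function(residue_type) {
  if (!residue_type %in% AA3) {
    stop("unsupported residue type: ", residue_type)
  }
  .build_specs[[residue_type]]
}

#' @rdname residue_topology
#' @return `sidechain_atom_names()`: character vector of side-chain heavy
#'   atoms in build order (empty for Gly).
#' @export
sidechain_atom_names <- function(residue_type) {
  vapply(sidechain_build_spec(residue_type), function(e) e$atom, character(1))
}

#' @rdname residue_topology
#' @return `chi_bearing_types()`: the 18 residue types with at least one chi.
#' @export
chi_bearing_types <- function() AA3[vapply(AA3, n_chi, integer(1)) > 0]

#' Symmetry table for chi angles and atom naming
#'
#' Describes the physical degeneracies of side-chain naming: chi angles with
#' a 180-degree rotational degeneracy (e.g. the benzene ring of Phe), and
#' atom-name swap groups that leave the structure physically identical.
#' The `base` groups exchange atoms of the same chemical element (e.g. the
#' two carboxylate oxygens of Asp); the `extended` groups add the
#' cross-element flips (Asn/Gln amide, His ring) that some evaluation
#' protocols also allow.
#'
#' @return list with `pi_symmetric_chi` (data.frame residue_type/chi_index),
#'   `name_swap_groups_base`, `name_swap_groups_extended` (per residue type,
#'   a list of swap groups; each group is a list of atom-name pairs swapped
#'   together).
#' @export
symmetry_table <- function() {
  base <- list(
    ASP = list(list(c("OD1", "OD2"))),
    GLU = list(list(c("OE1", "OE2"))),
    ARG = list(list(c("NH1", "NH2"))),
    PHE = list(list(c("CD1", "CD2"), c("CE1", "CE2"))),
    TYR = list(list(c("CD1", "CD2"), c("CE1", "CE2")))
  )
  ext_extra <- list(
    ASN = list(list(c("OD1", "ND2"))),
    GLN = list(list(c("OE1", "NE2"))),
    HIS = list(list(c("ND1", "CD2"), c("CE1", "NE2")))
  )
  extended <- base
  for (nm in names(ext_extra)) {
    extended[[nm]] <- c(if (is.null(extended[[nm]])) list() else extended[[nm]],
                        ext_extra[[nm]])
  }
  list(
    pi_symmetric_chi = data.frame(
      residue_type = c("PHE", "TYR", "ASP", "GLU"),
      chi_index = c(2L, 2L, 2L, 3L),
      stringsAsFactors = FALSE
    ),
    name_swap_groups_base = base,
    name_swap_groups_extended = extended
  )
}

# Chemical element of a canonical protein heavy atom from its PDB name.
atom_element <- function(atom_name) {
  substr(gsub("^[0-9]+", "", atom_name), 1, 1)
}
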