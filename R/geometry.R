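# Dihedral geometry: torsion computation, internal-coordinate atom placement
# (natural extension of reference frame), chi-angle extraction, side-chain
# reconstruction, symmetry-aware RMSD and burial classification.

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Wrap angles into (-180, 180]
#'
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC right-handed torsion about the p2-p3 axis: 0 for the eclipsed (cis)
#' arrangement, 180 for anti (trans). Invariant under rigid-body motion of
#' all four points.
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates in Angstrom.
#' @return angle in degrees in (-180, 180].
#' @export
#' @examples
#' compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) # 0 (cis)
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- vnorm(b2)
  if (nb2 < 1e-10) stop("compute_dihedral: p2 and p3 coincide")
  if (vnorm(n1) < 1e-10 * vnorm(b1) * nb2 ||
      vnorm(n2) < 1e-10 * vnorm(b3) * nb2) {
    stop("compute_dihedral: collinear atom triplet, torsion undefined")
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-of-reference-frame (NeRF) placement: returns the point d
#' bonded to c with the requested bond length, bond angle b-c-d, and torsion
#' a-b-c-d.
#'
#' @param a,b,c numeric(3) frame atoms (non-collinear).
#' @param bond_length distance c-d in Angstrom, positive.
#' @param bond_angle angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric(3) position of the new atom.
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, dihedral) {
  stopifnot(bond_length > 0)
  b1 <- b - a
  b2 <- c - b
  e1 <- b2 / vnorm(b2)
  n <- vcross(b1, b2)
  nn <- vnorm(n)
  if (nn < 1e-10 * vnorm(b1) * vnorm(b2)) {
    stop("place_atom: collinear reference frame")
  }
  n <- n / nn
  m <- vcross(n, e1)
  th <- bond_angle * pi / 180
  tau <- dihedral * pi / 180
  d_local <- bond_length * c(-cos(th), sin(th) * cos(tau), sin(th) * sin(tau))
  c + d_local[1] * e1 + d_local[2] * m + d_local[3] * n
}

# Coordinate lookup helpers for residue atom tables -------------------------

# Named coordinate matrix (rows = atom names) from an atom data.frame.
atom_coords <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(m) <- atoms$atom_name
  m
}

#' Extract chi angles from a residue's atoms
#'
#' Computes the canonical chi dihedrals of a residue from its atom
#' coordinates. Chi angles whose defining atoms are missing are returned as
#' NA with the corresponding mask entry FALSE.
#'
#' @param residue_atoms data.frame of one residue's atoms with columns
#'   `atom_name`, `x`, `y`, `z` (and `resid` if `residue_type` not given).
#' @param residue_type 3-letter code; defaults to the table's `resid`.
#' @return object of class `chi_angles`: list with `residue_type`,
#'   `chi` (numeric(4), degrees, NA where undefined) and `defined_mask`
#'   (logical(4): which chi exist for the type *and* could be computed).
#' @export
extract_chi_angles <- function(residue_atoms, residue_type = NULL) {
  if (is.null(residue_type)) residue_type <- residue_atoms$resid[1]
  quads <- chi_atom_names(residue_type)
  chi <- rep(NA_real_, 4)
  mask <- rep(FALSE, 4)
  if (length(quads) > 0) {
    cm <- atom_coords(residue_atoms)
    for (k in seq_along(quads)) {
      q <- quads[[k]]
      if (all(q %in% rownames(cm))) {
        chi[k] <- compute_dihedral(cm[q[1], ], cm[q[2], ], cm[q[3], ], cm[q[4], ])
        mask[k] <- TRUE
      }
    }
  }
  structure(list(residue_type = residue_type, chi = chi, defined_mask = mask),
            class = "chi_angles")
}

#' @export
print.chi_angles <- function(x, ...) {
  cat(x$residue_type, " chi:",
      paste(ifelse(x$defined_mask[seq_len(4)],
                   sprintf("%.1f", x$chi), "-")[seq_len(max(1, n_chi(x$residue_type)))],
            collapse = ", "), "\n")
  invisible(x)
}

#' Rebuild a side chain from chi angles and median internal coordinates
#'
#' Places every side-chain heavy atom of the residue in dependency order via
#' [place_atom()], using the bond lengths, bond angles and fixed dihedral
#' medians of the supplied internal-coordinate table; torsions tied to a chi
#' angle take the requested chi value plus the table's constant offset.
#'
#' @param backbone named 3-column matrix (or data.frame convertible via
#'   `atom_coords`) containing at least rows N, CA, C; CB is rebuilt if
#'   absent.
#' @param residue_type 3-letter code.
#' @param chi numeric vector of chi angles in degrees (length >= number of
#'   chi of the type), or a `chi_angles` object.
#' @param ics internal-coordinate table from [fit_redundant_ics()] or
#'   [ideal_ic_table()].
#' @return data.frame of placed side-chain atoms (`atom_name`, `element`,
#'   `x`, `y`, `z`); zero rows for Gly.
#' @export
reconstruct_side_chain <- function(backbone, residue_type, chi, ics) {
  if (inherits(chi, "chi_angles")) chi <- chi$chi
  spec <- sidechain_build_spec(residue_type)
  if (length(spec) == 0) {
    return(data.frame(atom_name = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(backbone)) backbone <- atom_coords(backbone)
  coords <- list(
    N = backbone["N", ], CA = backbone["CA", ], C = backbone["C", ]
  )
  if ("CB" %in% rownames(backbone)) coords$CB <- backbone["CB", ]
  tab <- ics[ics$resid == residue_type, , drop = FALSE]
  out_names <- character(0)
  out_xyz <- matrix(0, 0, 3)
  for (e in spec) {
    if (e$atom == "CB" && !is.null(coords$CB)) {
      next  # deposited CB kept as part of the backbone frame
    }
    row <- tab[tab$atom_name == e$atom, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("reconstruct_side_chain: no internal-coordinate entry for ",
           residue_type, " ", e$atom)
    }
    tors <- if (e$dtype == "fixed") {
      row$dihedral
    } else {
      k <- as.integer(substr(e$dtype, 4, 4))
      if (is.na(chi[k])) {
        stop("reconstruct_side_chain: chi", k, " required for ",
             residue_type, " ", e$atom, " is undefined")
      }
      chi[k] + row$dihedral
    }
    d <- place_atom(coords[[e$a]], coords[[e$b]], coords[[e$c]],
                    row$bond, row$angle, tors)
    coords[[e$atom]] <- d
    out_names <- c(out_names, e$atom)
    out_xyz <- rbind(out_xyz, d)
  }
  # CB present in the input backbone is still part of the side chain proper
  if (!"CB" %in% out_names && "CB" %in% rownames(backbone)) {
    out_names <- c("CB", out_names)
    out_xyz <- rbind(backbone["CB", ], out_xyz)
  }
  data.frame(atom_name = out_names,
             element = atom_element(out_names),
             x = out_xyz[, 1], y = out_xyz[, 2], z = out_xyz[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# All atom-name relabelings allowed for a residue under a symmetry mode.
# Returns a list of named character vectors (new name keyed by old name).
symmetry_permutations <- function(residue_type, mode = c("base", "extended"),
                                  table = symmetry_table()) {
  mode <- match.arg(mode)
  groups <- if (mode == "base") {
    table$name_swap_groups_base[[residue_type]]
  } else {
    table$name_swap_groups_extended[[residue_type]]
  }
  if (is.null(groups)) groups <- list()
  perms <- list(character(0))
  for (g in groups) {
    swapped <- unlist(lapply(g, function(pair) {
      stats::setNames(c(pair[2], pair[1]), c(pair[1], pair[2]))
    }))
    perms <- c(perms, lapply(perms, function(p) c(p, swapped)))
  }
  perms
}

#' Symmetry-aware side-chain RMSD
#'
#' Root-mean-square deviation between two placements of a residue's
#' side-chain heavy atoms, matched by atom name and minimized over the
#' physically equivalent atom-name relabelings of the chosen symmetry mode.
#' Coordinates are compared in the shared global frame (no superposition).
#'
#' @param true_atoms,pred_atoms data.frames with `atom_name`, `x`, `y`, `z`
#'   covering the same side-chain atoms.
#' @param symmetry_mode "base" (same-element swaps only) or "extended"
#'   (additionally the cross-element amide/imidazole flips).
#' @param residue_type 3-letter code; defaults to `true_atoms$resid[1]`.
#' @param table symmetry table, see [symmetry_table()].
#' @return RMSD in Angstrom.
#' @export
side_chain_rmsd <- function(true_atoms, pred_atoms,
                            symmetry_mode = c("base", "extended"),
                            residue_type = NULL, table = symmetry_table()) {
  symmetry_mode <- match.arg(symmetry_mode)
  if (is.null(residue_type)) residue_type <- true_atoms$resid[1]
  tm <- atom_coords(true_atoms)
  pm <- atom_coords(pred_atoms)
  if (!setequal(rownames(tm), rownames(pm))) {
    stop("side_chain_rmsd: atom names differ between true and predicted set")
  }
  nms <- rownames(tm)
  best <- Inf
  for (perm in symmetry_permutations(residue_type, symmetry_mode, table)) {
    relabel <- nms
    hit <- relabel %in% names(perm)
    relabel[hit] <- perm[relabel[hit]]
    d2 <- rowSums((tm[nms, , drop = FALSE] - pm[relabel, , drop = FALSE])^2)
    best <- min(best, sqrt(mean(d2)))
  }
  best
}

#' Classify a residue as core or surface by beta-carbon burial
#'
#' Counts the beta-carbons of all other residues within 10 Angstrom of this
#' residue's beta-carbon (alpha-carbon for Gly). At most 15 neighbors makes
#' a surface residue, at least 20 a core residue, anything between neither.
#'
#' @param structure atom data.frame of the full structure.
#' @param residue_id character residue key "chain_resno_insert" (see
#'   [residue_keys()]), or an integer index into `residue_keys(structure)`.
#' @param radius neighborhood radius in Angstrom (default 10).
#' @return one of "core", "surface", "neither".
#' @export
classify_core_surface <- function(structure, residue_id, radius = 10) {
  keys <- residue_keys(structure)
  if (is.numeric(residue_id)) residue_id <- unique(keys)[residue_id]
  cb <- cbeta_proxies(structure)
  if (!residue_id %in% rownames(cb)) {
    stop("classify_core_surface: residue ", residue_id,
         " has no beta-carbon proxy")
  }
  centre <- cb[residue_id, ]
  others <- cb[rownames(cb) != residue_id, , drop = FALSE]
  n <- if (nrow(others) == 0) 0 else {
    sum(sqrt(rowSums(sweep(others, 2, centre)^2)) <= radius)
  }
  if (n <= 15) "surface" else if (n >= 20) "core" else "neither"
}

# Beta-carbon (CA for Gly) coordinates per residue, rownames = residue key.
cbeta_proxies <- function(structure) {
  keys <- residue_keys(structure)
  uk <- unique(keys)
  out <- matrix(NA_real_, length(uk), 3, dimnames = list(uk, c("x", "y", "z")))
  for (i in seq_along(uk)) {
    res <- structure[keys == uk[i], , drop = FALSE]
    want <- if (res$resid[1] == "GLY") "CA" else "CB"
    hit <- which(res$atom_name == want)
    if (length(hit) == 0 && want == "CB") hit <- which(res$atom_name == "CA")
    if (length(hit) > 0) {
      out[i, ] <- as.numeric(res[hit[1], c("x", "y", "z")])
    }
  }
  out[stats::complete.cases(out), , drop = FALSE]
}
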