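# Deterministic generator of synthetic residues and mini-proteins with
# known chi angles, built from ideal backbone templates and the bundled
# internal-coordinate table. Every stage of the package is testable against
# these fixtures without downloading structures.

# Backbone geometry used by the templates (Angstrom / degrees).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5
)

# Backbone dihedrals per template.
.bb_templates <- list(
  helix = list(phi = -57, psi = -47, omega = 180),
  strand = list(phi = -120, psi = 120, omega = 180)
)

#' Fixture specification
#'
#' @param residue_types character vector of 3-letter codes, one per chain
#'   position (recycled to `n`).
#' @param n chain length (default: length of `residue_types`).
#' @param chi_mode chi sampling scheme: "uniform" (independent uniform over
#'   (-180, 180]), "fixed" (use `chi_values`), or "shared" (per-chain draw
#'   per chi index plus Gaussian jitter `chi_jitter`, giving residues whose
#'   conformations are mutually informative).
#' @param chi_values optional n x 4 matrix of chi angles for "fixed" mode.
#' @param template "helix" or "strand" backbone geometry.
#' @param sigma isotropic Gaussian noise on all atom positions (Angstrom).
#' @param chi_jitter jitter (degrees) around the shared chi draw.
#' @param seed RNG seed; generation is fully determined by (spec, seed).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(residue_types, n = length(residue_types),
                         chi_mode = c("uniform", "fixed", "shared"),
                         chi_values = NULL,
                         template = c("helix", "strand"),
                         sigma = 0, chi_jitter = 15, seed = 1) {
  chi_mode <- match.arg(chi_mode)
  template <- match.arg(template)
  stopifnot(sigma >= 0, n >= 1)
  residue_types <- rep(residue_types, length.out = n)
  stopifnot(all(residue_types %in% AA3))
  structure(list(residue_types = residue_types, n = n, chi_mode = chi_mode,
                 chi_values = chi_values, template = template, sigma = sigma,
                 chi_jitter = chi_jitter, seed = seed),
            class = "fixture_spec")
}

# Ideal backbone chain: N, CA, C, O atoms for n residues on the template.
ideal_backbone <- function(n, template = "helix", phi = NULL, psi = NULL) {
  g <- .bb_geom
  tp <- .bb_templates[[template]]
  if (is.null(phi)) phi <- rep(tp$phi, n)
  if (is.null(psi)) psi <- rep(tp$psi, n)
  omega <- tp$omega
  # seed the first three atoms
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, g$ca_c, g$ang_n_ca_c, 60)
  coords <- list()
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)) {
    cur <- coords[[i]]
    if (i < n) {
      Nn <- place_atom(cur$N, cur$CA, cur$C, g$c_n, g$ang_ca_c_n, psi[i])
      CAn <- place_atom(cur$CA, cur$C, Nn, g$n_ca, g$ang_c_n_ca, omega)
      Cn <- place_atom(cur$C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
      coords[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
    }
    # carbonyl O anti to the next amide nitrogen: torsion N-CA-C-O = psi+180
    coords[[i]]$O <- place_atom(cur$N, cur$CA, cur$C, g$c_o, g$ang_ca_c_o,
                                wrap_angle(psi[i] + 180))
  }
  coords
}

#' Build one synthetic residue with requested chi angles
#'
#' Places an ideal backbone fragment, reconstructs the side chain from the
#' requested chi angles with the given internal-coordinate table, and
#' optionally jitters all atom positions with isotropic Gaussian noise.
#'
#' @param residue_type 3-letter code.
#' @param chi numeric chi angles in degrees (length >= n_chi of the type);
#'   ignored entries may be NA.
#' @param ics internal-coordinate table (default the bundled ideal table).
#' @param sigma positional noise in Angstrom.
#' @param seed RNG seed (only used when sigma > 0).
#' @param template backbone template.
#' @return atom data.frame of one residue (chain A, resno 1).
#' @export
make_residue <- function(residue_type, chi, ics = ideal_ic_table(),
                         sigma = 0, seed = 1, template = "helix") {
  stopifnot(residue_type %in% AA3)
  bb <- ideal_backbone(1, template)[[1]]
  bbm <- rbind(N = bb$N, CA = bb$CA, C = bb$C)
  sc <- reconstruct_side_chain(bbm, residue_type, chi, ics)
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", sc$atom_name),
    resid = residue_type, chain = "A", resno = 1L, insert = "",
    x = c(bb$N[1], bb$CA[1], bb$C[1], bb$O[1], sc$x),
    y = c(bb$N[2], bb$CA[2], bb$C[2], bb$O[2], sc$y),
    z = c(bb$N[3], bb$CA[3], bb$C[3], bb$O[3], sc$z),
    occupancy = 1, alt = "", stringsAsFactors = FALSE
  )
  atoms$element <- atom_element(atoms$atom_name)
  atoms$canonical <- TRUE
  if (sigma > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, sigma)
  }
  atoms
}

#' Generate a synthetic mini-protein with known chi angles
#'
#' Builds a connected chain on the ideal backbone template, samples chi
#' angles per the fixture specification, reconstructs all side chains from
#' the bundled internal-coordinate table, and returns the ground truth
#' alongside the structure. Output is fully determined by (spec, seed).
#'
#' @param spec a `fixture_spec`.
#' @param ics internal-coordinate table (default the bundled ideal table).
#' @return list with `atoms` (PDB-writable data.frame), `chi` (n x 4 matrix,
#'   NA where undefined), `mask` (n x 4 logical), `spec`.
#' @export
make_mini_protein <- function(spec, ics = ideal_ic_table()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n
  bb <- ideal_backbone(n, spec$template)
  chi <- matrix(NA_real_, n, 4)
  mask <- matrix(FALSE, n, 4)
  shared <- stats::runif(4, -180, 180)
  rows <- list()
  for (i in seq_len(n)) {
    rt <- spec$residue_types[i]
    nc <- n_chi(rt)
    mask[i, seq_len(nc)] <- nc > 0
    if (nc > 0) {
      chi[i, 1:nc] <- switch(spec$chi_mode,
        uniform = stats::runif(nc, -180, 180),
        fixed = spec$chi_values[i, 1:nc],
        shared = wrap_angle(shared[1:nc] +
                            stats::rnorm(nc, 0, spec$chi_jitter)))
    }
    bbm <- rbind(N = bb[[i]]$N, CA = bb[[i]]$CA, C = bb[[i]]$C)
    sc <- if (rt == "GLY") {
      data.frame(atom_name = character(0), element = character(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
    } else {
      reconstruct_side_chain(bbm, rt, chi[i, ], ics)
    }
    res <- data.frame(
      atom_name = c("N", "CA", "C", "O", sc$atom_name),
      resid = rt, chain = "A", resno = i, insert = "",
      x = c(bb[[i]]$N[1], bb[[i]]$CA[1], bb[[i]]$C[1], bb[[i]]$O[1], sc$x),
      y = c(bb[[i]]$N[2], bb[[i]]$CA[2], bb[[i]]$C[2], bb[[i]]$O[2], sc$y),
      z = c(bb[[i]]$N[3], bb[[i]]$CA[3], bb[[i]]$C[3], bb[[i]]$O[3], sc$z),
      occupancy = 1, alt = "", stringsAsFactors = FALSE
    )
    rows[[i]] <- res
  }
  atoms <- do.call(rbind, rows)
  atoms$element <- atom_element(atoms$atom_name)
  atoms$canonical <- TRUE
  if (spec$sigma > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$sigma)
  }
  rownames(atoms) <- NULL
  list(atoms = atoms, chi = chi, mask = mask, spec = spec)
}

#' Generate a fixture set on disk
#'
#' Writes `n_structures` mini-proteins as PDB files plus a ground-truth chi
#' table (TSV) to a directory.
#'
#' @param dir output directory (created if needed).
#' @param n_structures number of mini-proteins.
#' @param residue_types residue composition of each chain.
#' @param chain_length residues per chain.
#' @param sigma positional noise (Angstrom).
#' @param seed base seed; structure i uses seed + i.
#' @param ... further arguments to [fixture_spec()].
#' @return invisibly, a data.frame of the ground-truth chi angles.
#' @export
make_fixture_set <- function(dir, n_structures = 10,
                             residue_types = chi_bearing_types(),
                             chain_length = 9, sigma = 0, seed = 7, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (i in seq_len(n_structures)) {
    spec <- fixture_spec(residue_types, n = chain_length, sigma = sigma,
                         seed = seed + i, ...)
    mp <- make_mini_protein(spec)
    write_structure(mp$atoms, file.path(dir, sprintf("fixture_%03d.pdb", i)))
    for (r in seq_len(chain_length)) {
      truth[[length(truth) + 1]] <- data.frame(
        structure = sprintf("fixture_%03d", i), resno = r,
        resid = spec$residue_types[r],
        chi1 = mp$chi[r, 1], chi2 = mp$chi[r, 2],
        chi3 = mp$chi[r, 3], chi4 = mp$chi[r, 4]
      )
    }
  }
  tdf <- do.call(rbind, truth)
  utils::write.table(tdf, file.path(dir, "truth_chi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tdf)
}
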