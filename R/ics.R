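# Redundant internal coordinates: fitting medians from structures, table
# serialization, and the null-reconstruction error (the RMSD floor of any
# chi-based packer: rebuild side chains from their *true* chi angles with
# median bond lengths/angles/fixed torsions and compare to the deposited
# coordinates).

# Median of angular data in degrees, robust to wrap-around: values are
# unwrapped about the circular mean before taking the ordinary median.
circular_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  rad <- x * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  wrap_angle(stats::median(wrap_angle(x - mu)) + mu)
}

#' Fit median redundant internal coordinates from structures
#'
#' For every (residue type, side-chain atom) placement of the canonical
#' build specification, collects the observed bond length, bond angle and
#' torsion over all complete residues in the input structures and records
#' their medians. Torsions tied to a chi angle are stored as the median
#' *offset* from the observed chi (identically zero for the atom defining
#' the chi); all other torsions are stored as median absolute values.
#' The observed distributions are narrow and unimodal, which is what makes
#' the median a faithful single value.
#'
#' @param structures a list of atom data.frames ([read_structure()]), or a
#'   single data.frame.
#' @param min_count drop entries observed fewer than this many times
#'   (default 1).
#' @return internal-coordinate table: data.frame with columns `resid`,
#'   `atom_name`, `a`, `b`, `c`, `dtype`, `bond`, `angle`, `dihedral`,
#'   `n_obs`. Residue types never observed are absent.
#' @export
fit_redundant_ics <- function(structures, min_count = 1) {
  if (is.data.frame(structures)) structures <- list(structures)
  acc <- new.env(parent = emptyenv())
  push <- function(key, vals) {
    cur <- acc[[key]]
    acc[[key]] <- if (is.null(cur)) list(vals) else c(cur, list(vals))
  }
  for (s in structures) {
    for (res in split_residues(s)) {
      rt <- res$resid[1]
      if (!rt %in% AA3 || !residue_complete(res)) next
      cm <- atom_coords(res)
      chi <- extract_chi_angles(res, rt)$chi
      for (e in sidechain_build_spec(rt)) {
        pa <- cm[e$a, ]; pb <- cm[e$b, ]; pc <- cm[e$c, ]; pd <- cm[e$atom, ]
        bond <- vnorm(pd - pc)
        u <- pb - pc; v <- pd - pc
        angle <- acos(min(1, max(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
        tors <- compute_dihedral(pa, pb, pc, pd)
        dih <- if (e$dtype == "fixed") {
          tors
        } else {
          wrap_angle(tors - chi[as.integer(substr(e$dtype, 4, 4))])
        }
        push(paste(rt, e$atom, sep = "|"), c(bond = bond, angle = angle, dih = dih))
      }
    }
  }
  rows <- list()
  for (rt in AA3) {
    for (e in sidechain_build_spec(rt)) {
      key <- paste(rt, e$atom, sep = "|")
      obs <- acc[[key]]
      if (is.null(obs) || length(obs) < min_count) next
      m <- do.call(rbind, obs)
      rows[[key]] <- data.frame(
        resid = rt, atom_name = e$atom, a = e$a, b = e$b, c = e$c,
        dtype = e$dtype,
        bond = stats::median(m[, "bond"]),
        angle = stats::median(m[, "angle"]),
        dihedral = circular_median(m[, "dih"]),
        n_obs = nrow(m),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an internal-coordinate table
#'
#' Tab-separated text with a version header line, one row per
#' (residue type, atom).
#'
#' @param ics internal-coordinate table.
#' @param path file path.
#' @return `read_ic_table()` returns the table; `write_ic_table()` the path,
#'   invisibly.
#' @export
write_ic_table <- function(ics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chipacker internal-coordinate table v1", con)
  utils::write.table(ics, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ic_table
#' @export
read_ic_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Bundled ideal internal-coordinate table
#'
#' Median internal coordinates fitted from the small real reference
#' structures bundled with bio3d (see [example_structure_paths()]). Used as
#' the generating geometry of the synthetic fixtures and as a default when
#' no user-fitted table is supplied.
#'
#' @return internal-coordinate table data.frame.
#' @export
ideal_ic_table <- function() {
  read_ic_table(system.file("extdata", "ideal_ics.tsv", package = "chipacker",
                            mustWork = TRUE))
}

#' Null-reconstruction RMSD
#'
#' Rebuilds every complete chi-bearing residue of the given structures from
#' its *true* chi angles using the internal-coordinate table, and reports
#' the per-residue symmetry-aware RMSD against the deposited side-chain
#' coordinates. This measures the information lost by fixing the redundant
#' internal coordinates to medians, and lower-bounds the reconstruction
#' error of any chi-based packing method.
#'
#' @param structures list of atom data.frames (or one data.frame).
#' @param ics internal-coordinate table.
#' @param symmetry_mode RMSD symmetry handling, see [side_chain_rmsd()].
#' @return list with `mean_rmsd` (Angstrom), `per_residue` data.frame.
#' @export
null_reconstruction_rmsd <- function(structures, ics,
                                     symmetry_mode = "base") {
  if (is.data.frame(structures)) structures <- list(structures)
  rows <- list()
  for (si in seq_along(structures)) {
    for (res in split_residues(structures[[si]])) {
      rt <- res$resid[1]
      if (!rt %in% AA3 || n_chi(rt) == 0 || !residue_complete(res)) next
      chi <- extract_chi_angles(res, rt)
      if (!all(chi$defined_mask[seq_len(n_chi(rt))])) next
      bb <- atom_coords(res)
      rebuilt <- reconstruct_side_chain(bb[c("N", "CA", "C"), ], rt, chi, ics)
      truth <- res[res$atom_name %in% rebuilt$atom_name, , drop = FALSE]
      r <- side_chain_rmsd(truth, rebuilt, symmetry_mode, residue_type = rt)
      rows[[length(rows) + 1]] <- data.frame(
        structure = si, residue = residue_keys(res)[1], resid = rt, rmsd = r,
        stringsAsFactors = FALSE
      )
    }
  }
  per <- do.call(rbind, rows)
  list(mean_rmsd = mean(per$rmsd), per_residue = per)
}
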