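# End-to-end two-stage packing: neighborhood gathering, dataset building,
# initial-guess prediction from backbone-only neighborhoods, iterative
# synchronous refinement against the current predicted side chains, and
# reconstruction of the full-atom structure.

BACKBONE_LIKE <- c("N", "CA", "C", "O", "CB", "OXT")

#' Gather the atomic neighborhood of a residue
#'
#' All heavy atoms within `radius` of the residue's alpha-carbon, filtered
#' by mode: backbone-only keeps N, CA, C, O and CB of every residue;
#' full-atom keeps everything. The central residue's own side chain (beyond
#' CB) is always excluded. Positions are returned relative to the central
#' alpha-carbon.
#'
#' @param structure atom data.frame.
#' @param center_key residue key ("chain_resno_insert").
#' @param mode "backbone_only" or "full_atom".
#' @param radius neighborhood radius in Angstrom (default 10).
#' @return atom data.frame with centred coordinates, or NULL (with a
#'   warning) when the residue has no alpha-carbon.
#' @export
gather_neighborhood <- function(structure, center_key,
                                mode = c("backbone_only", "full_atom"),
                                radius = 10) {
  mode <- match.arg(mode)
  keys <- residue_keys(structure)
  centre_rows <- structure[keys == center_key, , drop = FALSE]
  ca <- centre_rows[centre_rows$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) {
    warning("gather_neighborhood: residue ", center_key, " has no CA; skipped")
    return(NULL)
  }
  centre <- as.numeric(ca[1, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(structure))
  if (mode == "backbone_only") keep <- structure$atom_name %in% BACKBONE_LIKE
  own_sc <- keys == center_key & !structure$atom_name %in% BACKBONE_LIKE
  keep <- keep & !own_sc
  d2 <- (structure$x - centre[1])^2 + (structure$y - centre[2])^2 +
        (structure$z - centre[3])^2
  keep <- keep & d2 <= radius^2 * (1 + 1e-12)
  out <- structure[keep, , drop = FALSE]
  out$x <- out$x - centre[1]
  out$y <- out$y - centre[2]
  out$z <- out$z - centre[3]
  attr(out, "center") <- centre
  out
}

#' Build an encoded chi-angle dataset from structures
#'
#' For every complete chi-bearing residue, encodes its neighborhood and
#' records the chi-angle targets. Modes follow the two-stage design:
#' "initial" uses backbone-only neighborhoods with both channel sets (the
#' initial-guess model also sees amino-acid channels), "refine" uses
#' full-atom neighborhoods with atomic channels only, and "self" encodes
#' just the residue's own conformation (the toy setting of predicting chi
#' from the residue's true atoms).
#'
#' @param structures list of atom data.frames, or one data.frame.
#' @param mode "initial", "refine" or "self".
#' @param config an `encoding_config`; its channel set should match the
#'   mode (checked, warning on mismatch with the recommended set).
#' @param with_normals also store the true dihedral-plane normals (needed
#'   for the plane-normal objective).
#' @param types restrict to these residue types (default: all chi-bearing).
#' @return dataset list: `X` (batched steerable input), `chi` (n x 4 deg),
#'   `mask` (n x 4), `residue_type`, `type_ids`, `type_levels`,
#'   `struct_id`, `residue`, `in_mults`, `encoding_config`, `mode`,
#'   optionally `normals`.
#' @export
build_dataset <- function(structures, mode = c("initial", "refine", "self"),
                          config, with_normals = FALSE,
                          types = chi_bearing_types()) {
  mode <- match.arg(mode)
  if (is.data.frame(structures)) structures <- list(structures)
  recommended <- c(initial = "both", refine = "atomic", self = "atomic")
  if (config$channel_set != recommended[[mode]]) {
    warning("build_dataset: channel set '", config$channel_set,
            "' differs from the recommended '", recommended[[mode]],
            "' for mode ", mode)
  }
  tensors <- list(); chis <- list(); masks <- list(); rts <- character(0)
  sids <- integer(0); keys <- character(0); normals <- list()
  for (si in seq_along(structures)) {
    s <- structures[[si]]
    for (res in split_residues(s)) {
      rt <- res$resid[1]
      if (!rt %in% types || n_chi(rt) == 0 || !residue_complete(res)) next
      key <- residue_keys(res)[1]
      if (mode == "self") {
        ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
        nb <- res
        nb$x <- nb$x - ca[1]; nb$y <- nb$y - ca[2]; nb$z <- nb$z - ca[3]
      } else {
        nb <- gather_neighborhood(
          s, key, if (mode == "initial") "backbone_only" else "full_atom",
          radius = config$r_cut)
        if (is.null(nb)) next
      }
      cl <- channelize(nb, c(0, 0, 0), config$channel_set)
      tensors[[length(tensors) + 1]] <- encode(cl, config)
      ca_chi <- extract_chi_angles(res, rt)
      chis[[length(chis) + 1]] <- ifelse(is.na(ca_chi$chi), 0, ca_chi$chi)
      masks[[length(masks) + 1]] <- ca_chi$defined_mask
      rts <- c(rts, rt)
      sids <- c(sids, si)
      keys <- c(keys, key)
      if (with_normals) {
        pn <- chi_plane_normals(res, rt)
        nm <- matrix(0, 4, 3)
        nm[seq_len(nrow(pn) - 1), ] <- pn[-1, , drop = FALSE]
        normals[[length(normals) + 1]] <- nm
      }
    }
  }
  if (length(tensors) == 0) {
    return(list(X = NULL, chi = matrix(0, 0, 4), mask = matrix(FALSE, 0, 4),
                residue_type = character(0), type_ids = integer(0),
                type_levels = AA3, struct_id = integer(0),
                residue = character(0),
                in_mults = encoding_multiplicities(config),
                encoding_config = config, mode = mode))
  }
  out <- list(
    X = batch_tensors(tensors),
    chi = do.call(rbind, chis),
    mask = do.call(rbind, masks),
    residue_type = rts,
    type_ids = match(rts, AA3),
    type_levels = AA3,
    struct_id = sids,
    residue = keys,
    in_mults = encoding_multiplicities(config),
    encoding_config = config,
    mode = mode
  )
  if (with_normals) {
    arr <- array(0, c(length(normals), 4, 3))
    for (i in seq_along(normals)) arr[i, , ] <- normals[[i]]
    out$normals <- arr
  }
  out
}

#' Packing run configuration
#'
#' @param rounds number of refinement iterations (0 = initial guess only).
#' @param model_initial initial-guess model (backbone-only input); may be
#'   NULL when `upper_bound` is TRUE.
#' @param model_refine refinement model (full-atom input); required when
#'   `rounds` > 0 or `upper_bound`.
#' @param upper_bound feed the refinement model the *true* neighboring side
#'   chains (requires a full-atom input structure); one pass, no iteration.
#' @param seed RNG seed (inference is deterministic; kept for provenance).
#' @return object of class `packing_run`.
#' @export
packing_run <- function(rounds = 5, model_initial = NULL,
                        model_refine = NULL, upper_bound = FALSE, seed = 1) {
  stopifnot(rounds >= 0)
  if (upper_bound && is.null(model_refine)) {
    stop("packing_run: upper_bound needs the refinement model")
  }
  structure(list(rounds = rounds, model_initial = model_initial,
                 model_refine = model_refine, upper_bound = upper_bound,
                 seed = seed),
            class = "packing_run")
}

# Predict chi for all packable residues of `structure` using `model`,
# gathering neighborhoods of the given mode from `context` (the structure
# providing the neighbor atoms). Returns a named list of chi_angles.
predict_structure_chi <- function(model, structure, context, mode,
                                  ics = NULL) {
  config <- model$encoding_config
  res_list <- split_residues(structure)
  packable <- names(res_list)[vapply(res_list, function(r) {
    rt <- r$resid[1]
    rt %in% AA3 && n_chi(rt) > 0 &&
      all(c("N", "CA", "C") %in% r$atom_name)
  }, logical(1))]
  if (length(packable) == 0) return(list())
  tensors <- vector("list", length(packable))
  rts <- character(length(packable))
  for (i in seq_along(packable)) {
    nb <- gather_neighborhood(context, packable[i], mode, radius = config$r_cut)
    cl <- channelize(nb, c(0, 0, 0), config$channel_set)
    tensors[[i]] <- encode(cl, config)
    rts[i] <- res_list[[packable[i]]]$resid[1]
  }
  X <- batch_tensors(tensors)
  pred <- predict_chi(model, X, residue_type = rts)
  frames <- NULL
  if (model$config$output_mode == "plane_normals") {
    frames <- lapply(packable, function(k) atom_coords(res_list[[k]]))
  }
  angles <- angles_from_prediction(pred, rts, frame = frames, ics = ics)
  stats::setNames(angles, packable)
}

# Rebuild the full-atom structure from backbone + per-residue chi.
rebuild_structure <- function(structure, chi_by_residue, ics) {
  out_rows <- list()
  for (res in split_residues(structure)) {
    key <- residue_keys(res)[1]
    rt <- res$resid[1]
    keep <- res   # residues without a prediction pass through unpacked
    if (!is.null(chi_by_residue[[key]]) && rt %in% AA3 && n_chi(rt) > 0 &&
        all(c("N", "CA", "C") %in% res$atom_name)) {
      keep <- res[res$atom_name %in% BACKBONE_LIKE, , drop = FALSE]
      bb <- atom_coords(res)
      sc <- reconstruct_side_chain(bb[intersect(c("N", "CA", "C", "CB"),
                                                rownames(bb)), , drop = FALSE],
                                   rt, chi_by_residue[[key]], ics)
      keep <- keep[!keep$atom_name %in% sc$atom_name, , drop = FALSE]
      sc_rows <- keep[rep(1, nrow(sc)), , drop = FALSE]
      sc_rows$atom_name <- sc$atom_name
      sc_rows$element <- sc$element
      sc_rows$x <- sc$x; sc_rows$y <- sc$y; sc_rows$z <- sc$z
      keep <- rbind(keep, sc_rows)
    }
    out_rows[[key]] <- keep
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  out
}

#' Pack side chains onto a backbone
#'
#' Two-stage inference. Stage 1 predicts every chi-bearing residue's angles
#' from its backbone-only neighborhood and rebuilds all side chains. Each
#' refinement round then re-encodes every residue's full-atom neighborhood
#' from the *previous* round's coordinates (synchronous update, so the
#' result does not depend on residue order), re-predicts the chi angles and
#' rebuilds. In upper-bound mode the refinement model instead sees the true
#' neighboring side chains of a full-atom input, giving the ceiling of the
#' refinement process.
#'
#' @param structure atom data.frame: backbone (with or without side chains).
#' @param run a `packing_run`.
#' @param ics internal-coordinate table.
#' @return object of class `packing_result`: list with `structure` (packed
#'   full-atom data.frame), `chi` (named list of `chi_angles`), `rounds`.
#' @export
pack <- function(structure, run, ics) {
  stopifnot(inherits(run, "packing_run"))
  unknown <- setdiff(unique(structure$resid), AA3)
  if (length(unknown) > 0) {
    warning("pack: noncanonical residues passed through unpacked: ",
            paste(unknown, collapse = ", "))
  }
  if (run$upper_bound) {
    chi <- predict_structure_chi(run$model_refine, structure, structure,
                                 "full_atom", ics)
    packed <- rebuild_structure(structure, chi, ics)
    return(structure(list(structure = packed, chi = chi, rounds = 0,
                          upper_bound = TRUE), class = "packing_result"))
  }
  if (is.null(run$model_initial)) stop("pack: initial-guess model missing")
  chi <- predict_structure_chi(run$model_initial, structure, structure,
                               "backbone_only", ics)
  packed <- rebuild_structure(structure, chi, ics)
  r <- 0
  while (r < run$rounds) {
    if (is.null(run$model_refine)) stop("pack: refinement model missing")
    snapshot <- packed
    chi <- predict_structure_chi(run$model_refine, snapshot, snapshot,
                                 "full_atom", ics)
    packed <- rebuild_structure(snapshot, chi, ics)
    r <- r + 1
  }
  structure(list(structure = packed, chi = chi, rounds = r,
                 upper_bound = FALSE), class = "packing_result")
}

#' Fit and serialize an internal-coordinate table
#'
#' Thin orchestration over [fit_redundant_ics()]: reads the structures,
#' fits the medians and writes a versioned tabular text file with
#' provenance (structure count, package version) in the header.
#'
#' @param paths PDB file paths (or a list of already-parsed atom tables).
#' @param out_path output TSV path.
#' @return the fitted table, invisibly.
#' @export
fit_and_cache_ics <- function(paths, out_path) {
  structures <- if (is.character(paths)) lapply(paths, read_structure) else paths
  ics <- fit_redundant_ics(structures)
  con <- file(out_path, "w")
  writeLines(c("# chipacker internal-coordinate table v1",
               paste0("# structures: ", length(structures)),
               paste0("# package: chipacker ",
                      as.character(utils::packageVersion("chipacker")))), con)
  utils::write.table(ics, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(ics)
}
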