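# Holographic encoding: a residue neighborhood is represented as a sum of
# weighted Dirac deltas split over channels, then projected onto the
# orthonormal 3D Zernike basis (radial polynomials x real spherical
# harmonics), giving a rotationally steerable coefficient tensor.

ATOMIC_CHANNELS <- c("C", "N", "O", "S", "X", "charge")

#' Encoding configuration
#'
#' @param l_max maximum spherical-harmonic degree kept in the expansion.
#' @param n_max maximum radial frequency (must be >= l_max). The default 12
#'   keeps at least one radial basis function with wavelength below the
#'   minimum heavy-atom interatomic distance at the default cutoff.
#' @param r_cut neighborhood radius in Angstrom; atom radii are scaled by
#'   this value onto the unit ball (closed: atoms at exactly `r_cut` kept).
#' @param channel_set "atomic" (C/N/O/S, wildcard element, partial charge;
#'   6 channels) or "amino_acid" (the 20 canonical types plus wildcard; 21
#'   channels) or "both" (27 channels).
#' @param per_delta_normalize divide each atom's unit-weight coefficient
#'   vector by its own L2 norm before the weighted sum over atoms. A
#'   "squared_norm" variant of `normalize_mode` divides by the squared norm
#'   instead.
#' @param normalize_mode "norm" or "squared_norm".
#' @return object of class `encoding_config`.
#' @export
encoding_config <- function(l_max, n_max = 12, r_cut = 10,
                            channel_set = c("atomic", "amino_acid", "both"),
                            per_delta_normalize = TRUE,
                            normalize_mode = c("norm", "squared_norm")) {
  channel_set <- match.arg(channel_set)
  normalize_mode <- match.arg(normalize_mode)
  stopifnot(l_max >= 0, n_max >= l_max, r_cut > 0)
  structure(list(l_max = l_max, n_max = n_max, r_cut = r_cut,
                 channel_set = channel_set,
                 per_delta_normalize = per_delta_normalize,
                 normalize_mode = normalize_mode),
            class = "encoding_config")
}

channel_names <- function(channel_set) {
  switch(channel_set,
         atomic = ATOMIC_CHANNELS,
         amino_acid = c(AA3, "X"),
         both = c(ATOMIC_CHANNELS, paste0("AA_", c(AA3, "X"))))
}

#' Bundled partial-charge table
#'
#' Approximate heavy-atom partial charges patterned on the Amber99sb force
#' field, one value per (residue type, atom name); used as the weights of
#' the charge channel.
#'
#' @return data.frame with columns `resid`, `atom_name`, `charge`.
#' @export
charge_table <- function() {
  ct <- .pkg_cache$charge_table
  if (is.null(ct)) {
    ct <- utils::read.table(
      system.file("extdata", "partial_charges.tsv", package = "chipacker",
                  mustWork = TRUE),
      sep = "\t", header = TRUE, comment.char = "#", stringsAsFactors = FALSE)
    .pkg_cache$charge_table <- ct
  }
  ct
}

.pkg_cache <- new.env(parent = emptyenv())

#' Split neighborhood atoms into weighted channels
#'
#' Re-expresses atom positions relative to the central alpha-carbon and
#' assigns each atom to channels. In atomic mode each atom lands in exactly
#' one element channel (its own of C/N/O/S, otherwise the wildcard) with
#' unit weight, and additionally in the charge channel with its partial
#' charge as weight. In amino-acid mode each atom lands in the channel of
#' its parent residue type (wildcard for noncanonical) with unit weight.
#'
#' @param atoms atom data.frame of the neighborhood (columns `atom_name`,
#'   `resid`, `element`, `x`, `y`, `z`).
#' @param center numeric(3) position of the central residue's alpha-carbon.
#' @param channel_set "atomic", "amino_acid" or "both".
#' @param charges charge lookup table, see [charge_table()].
#' @return object of class `channelized_cloud`: named list of channels, each
#'   a list with `pos` (n x 3 matrix, centred) and `w` (weights).
#' @export
channelize <- function(atoms, center, channel_set = "atomic",
                       charges = charge_table()) {
  stopifnot(channel_set %in% c("atomic", "amino_acid", "both"))
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  pos <- sweep(pos, 2, as.numeric(center))
  elem <- if ("element" %in% names(atoms)) atoms$element else atom_element(atoms$atom_name)
  out <- list()
  nms <- channel_names(channel_set)
  for (ch in nms) out[[ch]] <- list(pos = pos[0, , drop = FALSE], w = numeric(0))
  add <- function(ch, idx, w) {
    if (!any(idx)) return()
    out[[ch]]$pos <<- rbind(out[[ch]]$pos, pos[idx, , drop = FALSE])
    out[[ch]]$w <<- c(out[[ch]]$w, w)
  }
  if (channel_set %in% c("atomic", "both")) {
    for (el in c("C", "N", "O", "S")) {
      add(el, elem == el, rep(1, sum(elem == el)))
    }
    wild <- !elem %in% c("C", "N", "O", "S")
    add("X", wild, rep(1, sum(wild)))
    q <- charges$charge[match(paste(atoms$resid, atoms$atom_name),
                              paste(charges$resid, charges$atom_name))]
    if (anyNA(q)) {
      warning("channelize: ", sum(is.na(q)),
              " atom(s) missing from the charge table; charge weight 0")
      q[is.na(q)] <- 0
    }
    add("charge", rep(TRUE, nrow(atoms)), q)
  }
  if (channel_set %in% c("amino_acid", "both")) {
    aach <- ifelse(atoms$resid %in% AA3, atoms$resid, "X")
    pref <- if (channel_set == "both") "AA_" else ""
    for (aa in c(AA3, "X")) {
      hit <- aach == aa
      out[[paste0(pref, aa)]] <-
        list(pos = pos[hit, , drop = FALSE], w = rep(1, sum(hit)))
    }
  }
  out <- out[channel_names(channel_set)]
  structure(out, class = "channelized_cloud", center = as.numeric(center))
}

#' Per-degree input multiplicities of an encoding configuration
#'
#' @param config an `encoding_config`.
#' @return integer vector of multiplicities (channels x radial count) per
#'   degree 0..l_max.
#' @export
encoding_multiplicities <- function(config) {
  nch <- length(channel_names(config$channel_set))
  vapply(0:config$l_max,
         function(l) nch * length(zernike_n_values(l, config$n_max)),
         numeric(1))
}

#' Holographic (3D Zernike) encoding of a channelized cloud
#'
#' Projects each channel's weighted point cloud onto the truncated Zernike
#' basis: for every kept (n, l, m) with n - l even and non-negative,
#' coefficient = sum_i w_i R_nl(r_i / r_cut) Y_lm(theta_i, phi_i). With
#' per-delta normalization each atom's unit-weight coefficient vector is
#' divided by its own L2 norm (or squared norm) before the weighted sum.
#'
#' @param cloud a `channelized_cloud` from [channelize()].
#' @param config an `encoding_config`.
#' @return object of class `steerable_tensor`: list of arrays, element
#'   l + 1 of dimension (n_channels, n_radial(l), 2 l + 1); attributes
#'   `config` and `channels`.
#' @export
encode <- function(cloud, config) {
  stopifnot(inherits(cloud, "channelized_cloud"),
            inherits(config, "encoding_config"))
  l_max <- config$l_max
  chn <- names(cloud)
  nls <- lapply(0:l_max, function(l) zernike_n_values(l, config$n_max))
  blocks <- lapply(0:l_max, function(l) {
    array(0, c(length(chn), length(nls[[l + 1]]), 2 * l + 1))
  })
  for (ci in seq_along(chn)) {
    ch <- cloud[[ci]]
    np <- nrow(ch$pos)
    if (np == 0) next
    r <- sqrt(rowSums(ch$pos^2))
    if (any(r > config$r_cut * (1 + 1e-9))) {
      stop("encode: atom beyond the cutoff radius; filter the neighborhood first")
    }
    rs <- pmin(1, r / config$r_cut)
    theta <- acos(pmin(1, pmax(-1, ifelse(r > 0, ch$pos[, 3] / r, 1))))
    phi <- atan2(ch$pos[, 2], ch$pos[, 1])
    Y <- sph_harm_all(l_max, theta, phi)
    Rmat <- lapply(0:l_max, function(l) {
      vapply(nls[[l + 1]], function(n) zernike_radial(n, l, rs),
             numeric(np))
    })
    # per-point products, arranged point x (n, l, m)
    prods <- lapply(0:l_max, function(l) {
      R <- matrix(Rmat[[l + 1]], nrow = np)
      yl <- Y[, (l^2 + 1):((l + 1)^2), drop = FALSE]
      # array np x n_radial x (2l+1)
      out <- array(0, c(np, ncol(R), 2 * l + 1))
      for (j in seq_len(ncol(R))) out[, j, ] <- R[, j] * yl
      out
    })
    w <- ch$w
    if (config$per_delta_normalize) {
      ss <- Reduce(`+`, lapply(prods, function(p) {
        rowSums(matrix(p, nrow = np)^2)
      }))
      nrm <- sqrt(ss)
      if (config$normalize_mode == "squared_norm") nrm <- ss
      nrm[nrm < 1e-30] <- 1
      w <- w / nrm
    }
    for (l in 0:l_max) {
      p <- prods[[l + 1]]
      nr <- dim(p)[2]
      if (nr == 0) next
      wp <- array(w * matrix(p, nrow = np), dim(p))
      blocks[[l + 1]][ci, , ] <- apply(wp, c(2, 3), sum)
    }
  }
  structure(blocks, class = "steerable_tensor",
            config = config, channels = chn)
}

#' Flatten a steerable tensor into per-degree feature matrices
#'
#' Collapses the (channel, radial) indices into a single multiplicity axis,
#' the input layout expected by the equivariant network.
#'
#' @param tensor a `steerable_tensor`.
#' @return list per degree l (element l + 1) of matrices
#'   (multiplicity x (2l + 1)).
#' @export
st_flatten <- function(tensor) {
  lapply(tensor, function(b) {
    d <- dim(b)
    matrix(b, d[1] * d[2], d[3])
  })
}

#' Rotate a steerable tensor by a rotation matrix
#'
#' Applies the block-diagonal real Wigner-D action degree by degree; by the
#' equivariance of the encoding this equals encoding the rotated cloud.
#'
#' @param tensor a `steerable_tensor` (or flattened list of matrices).
#' @param R 3x3 rotation matrix.
#' @return tensor of the same shape.
#' @export
rotate_tensor <- function(tensor, R) {
  out <- tensor
  for (li in seq_along(tensor)) {
    l <- li - 1
    D <- wigner_d_real(l, R)
    b <- tensor[[li]]
    if (is.matrix(b)) {
      out[[li]] <- b %*% t(D)
    } else {
      d <- dim(b)
      m <- matrix(b, d[1] * d[2], d[3]) %*% t(D)
      out[[li]] <- array(m, d)
    }
  }
  out
}
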