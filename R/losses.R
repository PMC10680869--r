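# Training objectives over chi angles and their symmetry correction.
# All three losses are separable sums over angles, which is what makes the
# per-angle minimum over physically equivalent targets valid.

#' Wrapped absolute error between two angles
#'
#' Minimum absolute difference over the 360-degree period, so that -179 and
#' 179 degrees are 2 degrees apart.
#'
#' @param a,b angles in degrees (vectorized).
#' @return error in degrees in [0, 180].
#' @export
#' @examples
#' wrapped_angle_error(-179, 179) # 2
wrapped_angle_error <- function(a, b) {
  abs(wrap_angle(a - b))
}

# Per-angle squared periodic error in the scaled [0, 2) domain (period 2).
# wrap_then_square = FALSE reproduces the literal min(E, 2 - E) form with
# E the squared modded difference.
.angle_err2 <- function(pred, true, wrap_then_square = TRUE) {
  d <- abs((pred - true) %% 2)
  d <- pmin(d, 2 - d)
  if (wrap_then_square) d^2 else pmin((abs((pred - true) %% 2))^2,
                                      2 - (abs((pred - true) %% 2))^2)
}

#' Periodic squared-error loss on scaled angles
#'
#' Both arguments live in the scaled domain [0, 2) (degrees mapped by
#' (chi + 180) / 180). The per-angle error is the squared *wrapped*
#' difference: the difference is reduced modulo the period before squaring,
#' so antipodal pairs score the maximal 1, not the naive 4. Per residue the
#' defined angles are averaged; the batch value is the mean over residues.
#'
#' @param pred,true numeric matrices (n x 4) in [0, 2) (vectors accepted).
#' @param mask logical matrix of defined chi angles.
#' @param wrap_then_square if FALSE, use the literal form min(E, 2 - E)
#'   with E the squared difference (kept for comparison; mixes units).
#' @return scalar loss.
#' @export
angle_loss <- function(pred, true, mask, wrap_then_square = TRUE) {
  pred <- rbind(pred); true <- rbind(true); mask <- rbind(mask)
  if (!any(mask)) stop("angle_loss: empty chi mask")
  pred[is.na(pred) | !mask] <- 0
  true[is.na(true) | !mask] <- 0
  e2 <- .angle_err2(pred, true, wrap_then_square)
  per_res <- rowSums(e2 * mask) / pmax(1, rowSums(mask))
  mean(per_res[rowSums(mask) > 0])
}

#' Sine/cosine loss on chi angles
#'
#' Mean squared error between predicted (sin, cos) pairs and the unit-circle
#' embedding of the true angles: per residue
#' (1 / 2 N_chi) * sum[(cos p - cos t)^2 + (sin p - sin t)^2]. For
#' predictions on the unit circle this equals the cosine loss
#' (1 / N_chi) * sum(1 - cos(p - t)).
#'
#' @param pred numeric matrix (n x 8): (sin1, cos1, ..., sin4, cos4).
#' @param true numeric matrix (n x 4) of true angles in degrees.
#' @param mask logical matrix (n x 4) of defined chi angles.
#' @return scalar loss.
#' @export
sincos_loss <- function(pred, true, mask) {
  pred <- rbind(pred); true <- rbind(true); mask <- rbind(mask)
  if (!any(mask)) stop("sincos_loss: empty chi mask")
  true[is.na(true) | !mask] <- 0
  pred[is.na(pred)] <- 0
  rad <- true * pi / 180
  ds <- pred[, c(1, 3, 5, 7), drop = FALSE] - sin(rad)
  dc <- pred[, c(2, 4, 6, 8), drop = FALSE] - cos(rad)
  per_angle <- (ds^2 + dc^2)
  per_res <- rowSums(per_angle * mask) / (2 * pmax(1, rowSums(mask)))
  mean(per_res[rowSums(mask) > 0])
}

#' Cosine loss on dihedral-plane normals
#'
#' Per defined chi, 1 - <predicted normal, true normal>; predictions are
#' L2-normalized first.
#'
#' @param pred numeric array (n x 4 x 3) of predicted normals.
#' @param true numeric array (n x 4 x 3) of true unit normals.
#' @param mask logical matrix (n x 4).
#' @return scalar loss.
#' @export
plane_normal_loss <- function(pred, true, mask) {
  if (length(dim(pred)) == 2) pred <- array(pred, c(1, dim(pred)))
  if (length(dim(true)) == 2) true <- array(true, c(1, dim(true)))
  mask <- rbind(mask)
  if (!any(mask)) stop("plane_normal_loss: empty chi mask")
  nrm <- sqrt(pred[, , 1]^2 + pred[, , 2]^2 + pred[, , 3]^2)
  nrm <- rbind(nrm)
  if (any(nrm[mask] < 1e-12)) stop("plane_normal_loss: zero-length predicted normal")
  dot <- (rbind(pred[, , 1] * true[, , 1]) + rbind(pred[, , 2] * true[, , 2]) +
          rbind(pred[, , 3] * true[, , 3])) / pmax(nrm, 1e-12)
  per_res <- rowSums((1 - dot) * mask) / pmax(1, rowSums(mask))
  mean(per_res[rowSums(mask) > 0])
}

#' Symmetry-corrected loss
#'
#' For chi angles with a 180-degree rotational degeneracy (see
#' [symmetry_table()]), the per-angle contribution is the minimum over the
#' two physically equivalent targets (chi and chi + 180, or the flipped
#' normal in plane-normal mode). Applied identically at training and
#' evaluation. Because all three objectives are separable sums over angles,
#' the per-angle minimum equals the brute-force minimum over all target
#' combinations.
#'
#' @param loss_fn one of [angle_loss()], [sincos_loss()],
#'   [plane_normal_loss()] (matched by identity).
#' @param pred,true,mask as for the wrapped loss.
#' @param residue_type character vector of residue types (length n or 1).
#' @param table symmetry table.
#' @return scalar loss.
#' @export
symmetry_corrected_loss <- function(loss_fn, pred, true, mask, residue_type,
                                    table = symmetry_table()) {
  sym <- table$pi_symmetric_chi
  true_alt <- flip_symmetric_targets(true, residue_type, sym)
  is_normals <- length(dim(pred)) == 3 || identical(loss_fn, plane_normal_loss)
  n <- nrow(rbind(mask))
  if (length(residue_type) == 1) residue_type <- rep(residue_type, n)
  flip <- matrix(FALSE, n, 4)
  for (j in seq_len(nrow(sym))) {
    flip[residue_type == sym$residue_type[j], sym$chi_index[j]] <- TRUE
  }
  if (!any(flip)) return(loss_fn(pred, true, mask))
  # evaluate each angle's contribution under both targets and keep the min;
  # done by masking one angle at a time (cheap: at most 4 columns)
  total <- 0; denom <- 0
  mask <- rbind(mask)
  for (k in 1:4) {
    mk <- mask & col(mask) == k
    if (!any(mk)) next
    base <- per_angle_contrib(loss_fn, pred, true, mk)
    alt <- per_angle_contrib(loss_fn, pred, true_alt, mk)
    contrib <- ifelse(flip[, k] & mk[, k], pmin(base, alt), base)
    total <- total + ifelse(mk[, k], contrib, 0)
    denom <- denom + mk[, k]
  }
  scalef <- if (identical(loss_fn, sincos_loss)) 2 else 1
  mean((total / pmax(1, denom))[denom > 0]) / scalef
}

# Per-residue, single-angle contribution of a loss (unnormalized by the
# 1/(2 N) prefactors; the caller reassembles the normalization).
per_angle_contrib <- function(loss_fn, pred, true, mk) {
  n <- nrow(mk)
  out <- numeric(n)
  rows <- which(rowSums(mk) > 0)
  if (identical(loss_fn, sincos_loss)) {
    pred <- rbind(pred); true <- rbind(true)
    true[is.na(true)] <- 0; pred[is.na(pred)] <- 0
    rad <- true * pi / 180
    ds <- pred[, c(1, 3, 5, 7), drop = FALSE] - sin(rad)
    dc <- pred[, c(2, 4, 6, 8), drop = FALSE] - cos(rad)
    pa <- ds^2 + dc^2
    out[rows] <- (pa * mk)[rows, , drop = FALSE] %*% rep(1, 4)
  } else if (identical(loss_fn, angle_loss)) {
    pred <- rbind(pred); true <- rbind(true)
    true[is.na(true)] <- 0; pred[is.na(pred)] <- 0
    pa <- .angle_err2(pred, true)
    out[rows] <- (pa * mk)[rows, , drop = FALSE] %*% rep(1, 4)
  } else {
    if (length(dim(pred)) == 2) pred <- array(pred, c(1, dim(pred)))
    if (length(dim(true)) == 2) true <- array(true, c(1, dim(true)))
    nrm <- rbind(sqrt(pred[, , 1]^2 + pred[, , 2]^2 + pred[, , 3]^2))
    dot <- (rbind(pred[, , 1] * true[, , 1]) + rbind(pred[, , 2] * true[, , 2]) +
            rbind(pred[, , 3] * true[, , 3])) / pmax(nrm, 1e-12)
    out[rows] <- ((1 - dot) * mk)[rows, , drop = FALSE] %*% rep(1, 4)
  }
  out
}

# The pi-rotated target: angles gain 180 degrees (any representation);
# plane normals flip sign. Flipping is applied to *all* columns; the caller
# selects which angles may use the alternative.
flip_symmetric_targets <- function(true, residue_type, sym) {
  if (length(dim(true)) == 3) return(-true)
  rbind(true) + 180
}

#' Per-chi wrapped absolute error with symmetry correction
#'
#' The evaluation-side error: wrapped absolute difference, taking for the
#' pi-symmetric chi angles the smaller of the errors against chi and
#' chi + 180.
#'
#' @param pred_chi,true_chi numeric matrices (n x 4) of angles in degrees.
#' @param residue_type character vector length n (or 1).
#' @param table symmetry table.
#' @return matrix (n x 4) of errors in degrees (NA where either input NA).
#' @export
chi_errors <- function(pred_chi, true_chi, residue_type,
                       table = symmetry_table()) {
  pred_chi <- rbind(pred_chi); true_chi <- rbind(true_chi)
  n <- nrow(pred_chi)
  if (length(residue_type) == 1) residue_type <- rep(residue_type, n)
  err <- wrapped_angle_error(pred_chi, true_chi)
  sym <- table$pi_symmetric_chi
  for (j in seq_len(nrow(sym))) {
    rows <- which(residue_type == sym$residue_type[j])
    k <- sym$chi_index[j]
    if (length(rows) > 0) {
      alt <- wrapped_angle_error(pred_chi[rows, k], true_chi[rows, k] + 180)
      err[rows, k] <- pmin(err[rows, k], alt)
    }
  }
  err
}
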