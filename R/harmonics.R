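# Angular and radial basis functions for the holographic encoding, plus the
# SO(3) representation machinery (Clebsch-Gordan couplings, Wigner-D matrices)
# used by the equivariant layers and the equivariance tests.
#
# Conventions: real spherical harmonics without the Condon-Shortley phase,
# L2-orthonormal over the sphere; 3D Zernike radial polynomials orthonormal on
# the unit ball with weight r^2.

#' Associated Legendre functions without the Condon-Shortley phase
#'
#' Evaluates P_l^m(x) for all 0 <= m <= l <= l_max by stable upward
#' recurrence. The Condon-Shortley factor (-1)^m is omitted, matching the
#' real spherical harmonic convention used throughout the package.
#'
#' @param l_max maximum degree.
#' @param x numeric vector in [-1, 1] (cosine of the polar angle).
#' @return matrix with `length(x)` rows and one column per (l, m) pair,
#'   ordered l = 0..l_max, m = 0..l within each l.
#' @keywords internal
assoc_legendre_all <- function(l_max, x) {
  stopifnot(l_max >= 0, all(abs(x) <= 1 + 1e-12))
  x <- pmin(1, pmax(-1, x))
  np <- length(x)
  ncol_total <- (l_max + 1) * (l_max + 2) / 2
  out <- matrix(0, np, ncol_total)
  idx <- function(l, m) l * (l + 1) / 2 + m + 1
  sx <- sqrt(pmax(0, 1 - x^2))
  # P_m^m = (2m-1)!! (1-x^2)^{m/2}  (no (-1)^m phase)
  pmm <- rep(1, np)
  for (m in 0:l_max) {
    if (m > 0) pmm <- pmm * (2 * m - 1) * sx
    out[, idx(m, m)] <- pmm
    if (m < l_max) {
      # P_{m+1}^m = x (2m+1) P_m^m
      pprev <- pmm
      pcur <- x * (2 * m + 1) * pmm
      out[, idx(m + 1, m)] <- pcur
      if (m + 2 <= l_max) {
        for (l in (m + 2):l_max) {
          pnew <- ((2 * l - 1) * x * pcur - (l + m - 1) * pprev) / (l - m)
          out[, idx(l, m)] <- pnew
          pprev <- pcur
          pcur <- pnew
        }
      }
    }
  }
  out
}

#' Real orthonormal spherical harmonic
#'
#' Computes the real spherical harmonic Y_lm(theta, phi), L2-normalized over
#' the unit sphere (so Y_00 = 1 / (2 sqrt(pi))). For m > 0 the function is
#' proportional to cos(m phi), for m < 0 to sin(|m| phi).
#'
#' @param l degree, non-negative integer.
#' @param m order, integer with |m| <= l.
#' @param theta polar angle in [0, pi].
#' @param phi azimuthal angle.
#' @return numeric vector of harmonic values.
#' @export
#' @examples
#' spherical_harmonic(0, 0, 0.3, 1.2) # 1 / (2 sqrt(pi))
spherical_harmonic <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("spherical_harmonic: |m| must not exceed l")
  if (any(theta < -1e-12 | theta > pi + 1e-12)) {
    stop("spherical_harmonic: theta must lie in [0, pi]")
  }
  Y <- sph_harm_all(l, theta, phi)
  Y[, lm_index(l, m)]
}

# Flat column index of (l, m) in the l-major, m = -l..l layout.
lm_index <- function(l, m) l^2 + l + m + 1

#' All real spherical harmonics up to a maximum degree
#'
#' @param l_max maximum degree.
#' @param theta,phi spherical angles (vectors of equal length).
#' @return matrix of dimension `length(theta)` x `(l_max + 1)^2`; columns are
#'   ordered by l, then m = -l..l.
#' @keywords internal
sph_harm_all <- function(l_max, theta, phi) {
  np <- length(theta)
  stopifnot(length(phi) == np)
  P <- assoc_legendre_all(l_max, cos(theta))
  pidx <- function(l, m) l * (l + 1) / 2 + m + 1
  out <- matrix(0, np, (l_max + 1)^2)
  for (l in 0:l_max) {
    # m = 0
    n0 <- sqrt((2 * l + 1) / (4 * pi))
    out[, lm_index(l, 0)] <- n0 * P[, pidx(l, 0)]
    if (l > 0) {
      for (m in 1:l) {
        nlm <- sqrt((2 * l + 1) / (2 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        plm <- P[, pidx(l, m)]
        out[, lm_index(l, m)] <- nlm * plm * cos(m * phi)
        out[, lm_index(l, -m)] <- nlm * plm * sin(m * phi)
      }
    }
  }
  out
}

#' 3D Zernike radial polynomial, orthonormal on the unit ball
#'
#' R_nl(r) with the normalization \eqn{\int_0^1 R_{nl} R_{n'l} r^2 dr =
#' \delta_{nn'}}. Non-zero only when n - l is even and non-negative; by the
#' parity selection rule the function returns 0 otherwise.
#'
#' @param n radial frequency, non-negative integer.
#' @param l degree, non-negative integer.
#' @param r radii scaled to [0, 1].
#' @return numeric vector of radial polynomial values.
#' @export
zernike_radial <- function(n, l, r) {
  if (any(r < -1e-12 | r > 1 + 1e-12)) {
    stop("zernike_radial: r must lie in [0, 1] (scale by the cutoff radius)")
  }
  if (n < l || (n - l) %% 2 != 0) return(rep(0, length(r)))
  k <- (n - l) / 2
  # R_nl(r) = sqrt(2n + 3) r^l P_k^{(0, l + 1/2)}(2 r^2 - 1)
  sqrt(2 * n + 3) * r^l * jacobi_poly(k, 0, l + 0.5, 2 * r^2 - 1)
}

# Jacobi polynomial P_k^{(a,b)}(x) by the standard three-term recurrence.
jacobi_poly <- function(k, a, b, x) {
  if (k == 0) return(rep(1, length(x)))
  p0 <- rep(1, length(x))
  p1 <- 0.5 * (a - b + (a + b + 2) * x)
  if (k == 1) return(p1)
  for (j in 2:k) {
    c1 <- 2 * j * (j + a + b) * (2 * j + a + b - 2)
    c2 <- (2 * j + a + b - 1) * (a^2 - b^2)
    c3 <- (2 * j + a + b - 2) * (2 * j + a + b - 1) * (2 * j + a + b)
    c4 <- 2 * (j + a - 1) * (j + b - 1) * (2 * j + a + b)
    pn <- ((c2 + c3 * x) * p1 - c4 * p0) / c1
    p0 <- p1
    p1 <- pn
  }
  p1
}

# Radial frequencies kept for a given degree: n in {l, l+2, ...} <= n_max.
zernike_n_values <- function(l, n_max) {
  if (n_max < l) return(integer(0))
  seq(l, n_max, by = 2)
}

#' Complex-basis Clebsch-Gordan coefficient
#'
#' <l1 m1 l2 m2 | l3 m3> via the Racah closed form. Used to assemble the
#' real-basis coupling tensors that drive the tensor-product nonlinearity.
#'
#' @param l1,l2,l3 degrees satisfying the triangle inequality.
#' @param m1,m2,m3 orders; zero unless m3 = m1 + m2.
#' @return a single numeric coefficient.
#' @keywords internal
clebsch_gordan <- function(l1, m1, l2, m2, l3, m3) {
  if (m1 + m2 != m3) return(0)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) return(0)
  if (abs(m1) > l1 || abs(m2) > l2 || abs(m3) > l3) return(0)
  lf <- function(x) lgamma(x + 1)
  delta <- 0.5 * (lf(l1 + l2 - l3) + lf(l1 - l2 + l3) + lf(-l1 + l2 + l3) -
                  lf(l1 + l2 + l3 + 1))
  pref <- 0.5 * (log(2 * l3 + 1) + lf(l3 + m3) + lf(l3 - m3) +
                 lf(l1 - m1) + lf(l1 + m1) + lf(l2 - m2) + lf(l2 + m2))
  ks <- max(0, l2 - l3 - m1, l1 - l3 + m2):min(l1 + l2 - l3, l1 - m1, l2 + m2)
  if (length(ks) == 0 || ks[1] > ks[length(ks)]) return(0)
  s <- 0
  for (k in ks) {
    term <- -(lf(k) + lf(l1 + l2 - l3 - k) + lf(l1 - m1 - k) + lf(l2 + m2 - k) +
              lf(l3 - l2 + m1 + k) + lf(l3 - l1 - m2 + k))
    s <- s + (-1)^k * exp(term)
  }
  exp(delta + pref) * s
}

# Unitary change of basis from complex to real spherical harmonics:
# Y^real_mu = sum_m U[mu, m] Y^complex_m, rows/cols indexed mu, m = -l..l.
real_basis_matrix <- function(l) {
  d <- 2 * l + 1
  U <- matrix(0 + 0i, d, d)
  ix <- function(m) m + l + 1
  U[ix(0), ix(0)] <- 1
  if (l > 0) {
    for (m in 1:l) {
      U[ix(m), ix(m)] <- (-1)^m / sqrt(2)
      U[ix(m), ix(-m)] <- 1 / sqrt(2)
      U[ix(-m), ix(m)] <- -1i * (-1)^m / sqrt(2)
      U[ix(-m), ix(-m)] <- 1i / sqrt(2)
    }
  }
  U
}

#' Real-basis Clebsch-Gordan coupling tensor
#'
#' Returns the 3-index array C with C[m3, m1, m2] such that contracting two
#' steerable features of degrees l1 and l2 yields a degree-l3 feature:
#' if x transforms by D^{l1}(R) and y by D^{l2}(R) (real Wigner matrices),
#' then z[m3] = sum C[m3, m1, m2] x[m1] y[m2] transforms by D^{l3}(R).
#' Results are cached per session.
#'
#' @param l1,l2,l3 coupled degrees.
#' @return numeric array of dimension (2 l3 + 1, 2 l1 + 1, 2 l2 + 1).
#' @export
real_cg <- function(l1, l2, l3) {
  key <- paste(l1, l2, l3, sep = "_")
  cached <- .cg_cache[[key]]
  if (!is.null(cached)) return(cached)
  d1 <- 2 * l1 + 1; d2 <- 2 * l2 + 1; d3 <- 2 * l3 + 1
  CG <- array(0, c(d3, d1, d2))
  for (m1 in -l1:l1) for (m2 in -l2:l2) {
    m3 <- m1 + m2
    if (abs(m3) <= l3) {
      CG[m3 + l3 + 1, m1 + l1 + 1, m2 + l2 + 1] <-
        clebsch_gordan(l1, m1, l2, m2, l3, m3)
    }
  }
  U1 <- real_basis_matrix(l1); U2 <- real_basis_matrix(l2)
  U3 <- real_basis_matrix(l3)
  Tc <- array(0 + 0i, c(d3, d1, d2))
  for (mu3 in 1:d3) for (mu1 in 1:d1) for (mu2 in 1:d2) {
    acc <- 0 + 0i
    for (m3 in 1:d3) {
      row <- U3[mu3, m3]
      if (row == 0) next
      for (m1 in 1:d1) {
        cu1 <- Conj(U1[mu1, m1])
        if (cu1 == 0) next
        for (m2 in 1:d2) {
          cg <- CG[m3, m1, m2]
          if (cg == 0) next
          acc <- acc + row * cg * cu1 * Conj(U2[mu2, m2])
        }
      }
    }
    Tc[mu3, mu1, mu2] <- acc
  }
  # The transformed tensor is purely real or purely imaginary depending on
  # the parity of l1 + l2 + l3; either part is a valid real intertwiner.
  re <- Re(Tc); im <- Im(Tc)
  out <- if (sum(re^2) >= sum(im^2)) re else im
  if (max(abs(if (sum(re^2) >= sum(im^2)) im else re)) > 1e-10) {
    stop("real_cg: unexpected mixed real/imaginary coupling")
  }
  assign(key, out, envir = .cg_cache)
  out
}

.cg_cache <- new.env(parent = emptyenv())

# ZYZ Euler angles (alpha, beta, gamma) of a rotation matrix, active
# convention R = Rz(alpha) Ry(beta) Rz(gamma).
euler_zyz <- function(R) {
  beta <- acos(min(1, max(-1, R[3, 3])))
  if (abs(sin(beta)) > 1e-9) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else if (R[3, 3] > 0) {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(-R[2, 1], R[2, 2])
    gamma <- 0
  }
  c(alpha, beta, gamma)
}

# Wigner little-d matrix d^l_{m' m}(beta) in the complex basis.
wigner_little_d <- function(l, beta) {
  d <- 2 * l + 1
  out <- matrix(0, d, d)
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  lf <- function(x) lgamma(x + 1)
  for (mp in -l:l) for (m in -l:l) {
    smin <- max(0, m - mp)
    smax <- min(l + m, l - mp)
    if (smin > smax) next
    pref <- 0.5 * (lf(l + mp) + lf(l - mp) + lf(l + m) + lf(l - m))
    acc <- 0
    for (s in smin:smax) {
      denom <- lf(l + m - s) + lf(s) + lf(mp - m + s) + lf(l - mp - s)
      pw_c <- 2 * l + m - mp - 2 * s
      pw_s <- mp - m + 2 * s
      term <- exp(pref - denom)
      if (pw_c > 0) term <- term * cb^pw_c
      if (pw_s > 0) term <- term * sb^pw_s
      acc <- acc + (-1)^(mp - m + s) * term
    }
    out[mp + l + 1, m + l + 1] <- acc
  }
  out
}

#' Real Wigner-D matrix of a rotation
#'
#' Returns the (2l + 1) x (2l + 1) orthogonal matrix D^l(R) acting on
#' degree-l steerable features in the real spherical-harmonic basis, with the
#' convention that rotating a point cloud by R transforms its holographic
#' coefficients as z -> D^l(R) z (see [encode()]).
#'
#' @param l degree.
#' @param R 3x3 rotation matrix (active).
#' @return orthogonal matrix of dimension (2l + 1).
#' @export
wigner_d_real <- function(l, R) {
  if (l == 0) return(matrix(1, 1, 1))
  ang <- euler_zyz(R)
  dmat <- wigner_little_d(l, ang[2])
  m <- -l:l
  Dc <- exp(-1i * outer(m, rep(1, 2 * l + 1)) * ang[1]) * dmat *
        exp(-1i * outer(rep(1, 2 * l + 1), m) * ang[3])
  U <- real_basis_matrix(l)
  # In the complex basis, point-cloud coefficients transform by Conj(Dc).
  W <- U %*% Conj(Dc) %*% Conj(t(U))
  if (max(abs(Im(W))) > 1e-9) stop("wigner_d_real: non-real result")
  Re(W)
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (via a normalized quaternion).
#'
#' @param n number of matrices.
#' @return a 3x3 matrix if n = 1, otherwise a list of matrices.
#' @export
random_rotation <- function(n = 1) {
  one <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  if (n == 1) one() else replicate(n, one(), simplify = FALSE)
}
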