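# Angular/radial basis functions and the SO(3) representation machinery.

test_that("real spherical harmonics are orthonormal over the sphere", {
  gl <- gauss_legendre(60, -1, 1)      # polar quadrature in cos(theta)
  nph <- 64
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  grid <- expand.grid(ct = gl$x, phi = phi)
  wq <- rep(gl$w, nph) * (2 * pi / nph)
  Y <- chipacker:::sph_harm_all(6, acos(grid$ct), grid$phi)
  G <- t(Y) %*% (Y * wq)
  expect_lt(max(abs(G - diag(ncol(Y)))), 1e-8)
})

test_that("Y00 is the constant mode of the unit-normalized basis", {
  expect_equal(spherical_harmonic(0, 0, 0.7, 2.1), 1 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_error(spherical_harmonic(2, 3, 0.5, 0.5), "exceed")
})

test_that("addition theorem holds at random directions", {
  set.seed(5)
  for (i in 1:10) {
    th <- runif(1, 0, pi); ph <- runif(1, -pi, pi)
    for (l in 0:5) {
      s <- sum(vapply(-l:l, function(m) spherical_harmonic(l, m, th, ph)^2,
                      numeric(1)))
      expect_equal(s, (2 * l + 1) / (4 * pi), tolerance = 1e-10)
    }
  }
})

test_that("Zernike radial polynomials obey the parity rule and orthonormality", {
  r <- seq(0, 1, length.out = 11)
  expect_equal(zernike_radial(3, 2, r), rep(0, 11))
  expect_equal(zernike_radial(1, 2, r), rep(0, 11))
  expect_error(zernike_radial(2, 0, c(0.5, 1.2)), "0, 1")
  gl <- gauss_legendre(80, 0, 1)
  for (l in c(0, 1, 3, 5)) {
    ns <- chipacker:::zernike_n_values(l, 12)
    M <- vapply(ns, function(n) zernike_radial(n, l, gl$x), numeric(80))
    G <- t(M) %*% (M * gl$x^2 * gl$w)
    expect_lt(max(abs(G - diag(length(ns)))), 1e-8)
  }
})

test_that("Zernike radial values match a Gram-Schmidt construction", {
  # orthonormalize monomials r^l, r^(l+2), ... on the ball independently
  gl <- gauss_legendre(100, 0, 1)
  for (l in c(0, 2)) {
    ns <- chipacker:::zernike_n_values(l, 8)
    basis <- vapply(ns, function(n) gl$x^(l + (n - l)), numeric(100))
    ip <- function(u, v) sum(u * v * gl$x^2 * gl$w)
    Q <- basis
    for (j in seq_along(ns)) {
      v <- basis[, j]
      if (j > 1) for (k in 1:(j - 1)) v <- v - ip(Q[, k], v) * Q[, k]
      Q[, j] <- v / sqrt(ip(v, v))
    }
    for (j in seq_along(ns)) {
      got <- zernike_radial(ns[j], l, gl$x)
      sgn <- sign(sum(got * Q[, j]))
      expect_lt(max(abs(got - sgn * Q[, j])), 1e-7)
    }
  }
  # R_00 at r = 0 fixed by the normalization: sqrt(3)
  expect_equal(zernike_radial(0, 0, 0), sqrt(3), tolerance = 1e-12)
})

test_that("real Wigner-D matrices act on spherical harmonics and compose", {
  set.seed(11)
  sph <- function(v) c(acos(min(1, max(-1, v[3]))), atan2(v[2], v[1]))
  for (i in 1:5) {
    R1 <- random_rotation(); R2 <- random_rotation()
    x <- rnorm(3); x <- x / sqrt(sum(x^2))
    for (l in 1:5) {
      a <- sph(x)
      y <- chipacker:::sph_harm_all(l, a[1], a[2])[1, (l^2 + 1):((l + 1)^2)]
      b <- sph(as.vector(R1 %*% x))
      yR <- chipacker:::sph_harm_all(l, b[1], b[2])[1, (l^2 + 1):((l + 1)^2)]
      D <- wigner_d_real(l, R1)
      expect_lt(max(abs(D %*% y - yR)), 1e-10)
      expect_lt(max(abs(t(D) %*% D - diag(2 * l + 1))), 1e-10)
      if (l <= 3) {
        expect_lt(max(abs(wigner_d_real(l, R1 %*% R2) -
                          wigner_d_real(l, R1) %*% wigner_d_real(l, R2))),
                  1e-10)
      }
    }
  }
})

test_that("real Clebsch-Gordan tensors intertwine the Wigner action", {
  set.seed(12)
  for (tri in list(c(1, 1, 2), c(1, 2, 1), c(2, 2, 2), c(1, 1, 0),
                   c(2, 3, 4), c(0, 0, 0))) {
    l1 <- tri[1]; l2 <- tri[2]; l3 <- tri[3]
    C <- real_cg(l1, l2, l3)
    R <- random_rotation()
    x1 <- rnorm(2 * l1 + 1); x2 <- rnorm(2 * l2 + 1)
    z <- apply(C, 1, function(M) sum(M * outer(x1, x2)))
    zr <- apply(C, 1, function(M) {
      sum(M * outer(as.vector(wigner_d_real(l1, R) %*% x1),
                    as.vector(wigner_d_real(l2, R) %*% x2)))
    })
    expect_lt(max(abs(zr - as.vector(wigner_d_real(l3, R) %*% z))), 1e-10)
  }
  expect_equal(as.numeric(real_cg(0, 0, 0)), 1)
})
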