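# Channelized clouds and the steerable Zernike encoding.

test_that("channel sets have the documented sizes and partition atoms", {
  res <- make_residue("MET", c(60, 180, -60, NA), ics_tab)
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  cl_at <- channelize(res, ca, "atomic")
  expect_length(cl_at, 6)
  cl_aa <- channelize(res, ca, "amino_acid")
  expect_length(cl_aa, 21)
  cl_both <- channelize(res, ca, "both")
  expect_length(cl_both, 27)
  # element channels partition the heavy atoms
  k <- nrow(res)
  sizes <- vapply(cl_at[c("C", "N", "O", "S", "X")],
                  function(ch) nrow(ch$pos), numeric(1))
  expect_equal(sum(sizes), k)
  expect_equal(unname(sizes["S"]), 1)   # MET SD
  # charge channel covers every atom with its tabulated charge
  expect_equal(length(cl_at$charge$w), k)
  ct <- charge_table()
  expect_equal(sort(cl_at$charge$w),
               sort(ct$charge[ct$resid == "MET"]))
})

test_that("non-CNOS heavy elements fall into the wildcard channel", {
  res <- make_residue("MET", c(60, 180, -60, NA), ics_tab)
  res$element[res$atom_name == "SD"] <- "SE"   # selenomethionine-like
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  cl <- expect_warning(channelize(res, ca, "atomic"), NA)
  expect_equal(nrow(cl$X$pos), 1)
  expect_equal(nrow(cl$S$pos), 0)
})

test_that("empty channels encode to all-zero blocks", {
  res <- make_residue("SER", c(55, NA, NA, NA), ics_tab)  # no sulfur
  cfg <- encoding_config(l_max = 3, n_max = 6)
  z <- encode_residue(res, cfg, "atomic")
  schan <- which(attr(z, "channels") == "S")
  for (li in seq_along(z)) expect_true(all(z[[li]][schan, , ] == 0))
})

test_that("a single atom on the polar axis excites only m = 0 real modes", {
  atoms <- data.frame(atom_name = "CA", resid = "GLY", x = 0, y = 0, z = 4,
                      element = "C", stringsAsFactors = FALSE)
  cl <- channelize(atoms, c(0, 0, 0), "atomic")
  cfg <- encoding_config(l_max = 4, n_max = 8)
  z <- encode(cl, cfg)
  cchan <- which(attr(z, "channels") == "C")
  for (l in 0:4) {
    for (m in -l:l) {
      coefs <- z[[l + 1]][cchan, , m + l + 1]
      if (m != 0) expect_lt(max(abs(coefs)), 1e-12)
    }
    # m = 0 coefficients match direct basis evaluation at theta = 0
    direct <- vapply(chipacker:::zernike_n_values(l, 8), function(n) {
      zernike_radial(n, l, 0.4) * spherical_harmonic(l, 0, 0, 0)
    }, numeric(1))
    nrm <- sqrt(sum(vapply(0:4, function(ll) {
      sum(vapply(chipacker:::zernike_n_values(ll, 8), function(n) {
        zernike_radial(n, ll, 0.4)^2 * spherical_harmonic(ll, 0, 0, 0)^2
      }, numeric(1)))
    }, numeric(1))))
    expect_equal(as.numeric(z[[l + 1]][cchan, , l + 1]), direct / nrm,
                 tolerance = 1e-10)
  }
})

test_that("encoding is SO(3)-equivariant through the Wigner-D action", {
  set.seed(61)
  res <- make_residue("TRP", c(-70, 100, NA, NA), ics_tab)
  cfg <- encoding_config(l_max = 5, n_max = 8)
  z <- encode_residue(res, cfg, "atomic")
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  res0 <- res
  res0[, c("x", "y", "z")] <- sweep(as.matrix(res[, c("x", "y", "z")]), 2, ca)
  for (i in 1:5) {
    R <- random_rotation()
    zr <- encode(channelize(transform_atoms(res0, R), c(0, 0, 0), "atomic"),
                 cfg)
    zrot <- rotate_tensor(z, R)
    err <- max(vapply(seq_along(z), function(li) {
      max(abs(zr[[li]] - zrot[[li]]))
    }, numeric(1)))
    expect_lt(err, 1e-10)
  }
})

test_that("encoding is linear in the weights without per-delta normalization", {
  res <- make_residue("LYS", c(60, 180, -60, 90), ics_tab)
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  cl <- channelize(res, ca, "atomic")
  cfg <- encoding_config(l_max = 3, n_max = 6, per_delta_normalize = FALSE)
  cl2 <- cl
  for (i in seq_along(cl2)) cl2[[i]]$w <- 2 * cl2[[i]]$w
  class(cl2) <- "channelized_cloud"
  z1 <- encode(cl, cfg); z2 <- encode(cl2, cfg)
  for (li in seq_along(z1)) expect_equal(z2[[li]], 2 * z1[[li]])
})

test_that("truncation nests: low-degree blocks agree across l_max", {
  res <- make_residue("HIS", c(-60, 90, NA, NA), ics_tab)
  cfgA <- encoding_config(l_max = 3, n_max = 8, per_delta_normalize = FALSE)
  cfgB <- encoding_config(l_max = 5, n_max = 8, per_delta_normalize = FALSE)
  zA <- encode_residue(res, cfgA, "atomic")
  zB <- encode_residue(res, cfgB, "atomic")
  for (li in 1:4) expect_equal(zA[[li]], zB[[li]])
})

test_that("atoms beyond the cutoff are the caller's error", {
  atoms <- data.frame(atom_name = "CA", resid = "GLY", x = 0, y = 0, z = 11,
                      element = "C", stringsAsFactors = FALSE)
  cl <- channelize(atoms, c(0, 0, 0), "atomic")
  expect_error(encode(cl, encoding_config(l_max = 1, n_max = 4, r_cut = 10)),
               "cutoff")
})
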