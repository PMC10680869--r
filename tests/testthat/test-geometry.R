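# Dihedral computation, atom placement, chi extraction/reconstruction,
# symmetry-aware RMSD and burial classification.

test_that("dihedral convention: eclipsed is 0, anti is 180", {
  expect_equal(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                c(0, 1, 0)), 0)
  expect_equal(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                c(2, 1, 0)), 180)
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "collinear")
})

test_that("dihedral agrees with the frame-rotation oracle", {
  # oracle: build the orthonormal frame of (p2 -> p3) with p1 defining the
  # reference half-plane, express p4 in it and read the azimuth
  oracle <- function(p1, p2, p3, p4) {
    e1 <- (p3 - p2); e1 <- e1 / sqrt(sum(e1^2))
    u <- (p1 - p2) - sum((p1 - p2) * e1) * e1
    u <- u / sqrt(sum(u^2))
    w <- c(e1[2] * u[3] - e1[3] * u[2],
           e1[3] * u[1] - e1[1] * u[3],
           e1[1] * u[2] - e1[2] * u[1])   # e1 x u: right-handed about the axis
    v <- (p4 - p3) - sum((p4 - p3) * e1) * e1
    atan2(sum(v * w), sum(v * u)) * 180 / pi
  }
  set.seed(3)
  for (i in 1:100) {
    p <- matrix(rnorm(12), 4, 3)
    got <- compute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    want <- oracle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_lt(abs(wrap_angle(got - want)), 1e-9)
  }
})

test_that("dihedral is invariant to rigid motion", {
  set.seed(4)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    R <- random_rotation(); tr <- rnorm(3)
    pr <- p %*% t(R) + matrix(tr, 4, 3, byrow = TRUE)
    expect_lt(abs(compute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]) -
                  compute_dihedral(pr[1, ], pr[2, ], pr[3, ], pr[4, ])),
              1e-6)
  }
})

test_that("place_atom reproduces its internal coordinates", {
  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
    L <- runif(1, 0.9, 2.2); th <- runif(1, 30, 150)
    tau <- runif(1, -179.9, 179.9)
    d <- place_atom(a, b, cc, L, th, tau)
    expect_lt(abs(sqrt(sum((d - cc)^2)) - L), 1e-9)
    u <- b - cc; v <- d - cc
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_lt(abs(ang - th), 1e-6)
    expect_lt(abs(wrap_angle(compute_dihedral(a, b, cc, d) - tau)), 1e-6)
  }
  # anti placement is coplanar with the frame
  d <- place_atom(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), 1.5, 109, 180)
  expect_lt(abs(d[3]), 1e-9)
})

test_that("chi extraction knows the canonical angle counts", {
  gly <- make_residue("GLY", rep(NA, 4), ics_tab)
  expect_equal(sum(extract_chi_angles(gly)$defined_mask), 0)
  ala <- make_residue("ALA", rep(NA, 4), ics_tab)
  expect_equal(sum(extract_chi_angles(ala)$defined_mask), 0)
  gln <- make_residue("GLN", c(-60, 175, 40, NA), ics_tab)
  expect_equal(sum(extract_chi_angles(gln)$defined_mask), 3)
  lys <- make_residue("LYS", c(60, 180, -60, 90), ics_tab)
  got <- extract_chi_angles(lys)
  expect_lt(max(abs(wrap_angle(got$chi - c(60, 180, -60, 90)))), 1e-6)
  expect_error(chi_atom_names("XYZ"), "unsupported")
})

test_that("missing atoms mask the affected chi only", {
  lys <- make_residue("LYS", c(60, 180, -60, 90), ics_tab)
  lys <- lys[lys$atom_name != "NZ", ]
  got <- extract_chi_angles(lys, "LYS")
  expect_equal(got$defined_mask, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("reconstruct-then-extract is the identity on chi", {
  set.seed(6)
  for (rt in chi_bearing_types()) {
    nc <- n_chi(rt)
    chi <- runif(4, -180, 180)
    res <- make_residue(rt, chi, ics_tab)
    got <- extract_chi_angles(res, rt)
    expect_lt(max(abs(wrap_angle(got$chi[1:nc] - chi[1:nc]))), 1e-6,
              label = paste("chi round trip for", rt))
    expect_setequal(res$atom_name,
                    c("N", "CA", "C", "O", sidechain_atom_names(rt)))
  }
  expect_equal(nrow(reconstruct_side_chain(
    rbind(N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2, 1.4, 0)),
    "GLY", rep(NA, 4), ics_tab)), 0)
})

test_that("chi extraction and reconstruction are rigid-motion equivariant", {
  set.seed(7)
  chi <- c(-170, 60, 55, -80)
  res <- make_residue("ARG", chi, ics_tab)
  R <- random_rotation(); tr <- rnorm(3, 0, 5)
  rotated <- transform_atoms(res, R, tr)
  a <- extract_chi_angles(res, "ARG")$chi
  b <- extract_chi_angles(rotated, "ARG")$chi
  expect_lt(max(abs(wrap_angle(a - b))), 1e-6)
})

test_that("symmetry-aware RMSD minimizes over allowed relabelings only", {
  set.seed(8)
  phe <- make_residue("PHE", c(-65, 80, NA, NA), ics_tab)
  sc <- phe[phe$atom_name %in% sidechain_atom_names("PHE"), ]
  expect_equal(side_chain_rmsd(sc, sc, "base"), 0)
  # exchange the ring labels, coordinates fixed: still zero under base mode
  flipped <- sc
  swap <- c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")
  hit <- flipped$atom_name %in% names(swap)
  flipped$atom_name[hit] <- swap[flipped$atom_name[hit]]
  expect_equal(side_chain_rmsd(sc, flipped, "base", residue_type = "PHE"), 0)
  # a single displaced atom reports its displacement exactly
  ser <- make_residue("SER", c(55, NA, NA, NA), ics_tab)
  ssc <- ser[ser$atom_name %in% c("CB", "OG"), ]
  moved <- ssc
  moved$x[moved$atom_name == "OG"] <- moved$x[moved$atom_name == "OG"] + 1
  expect_equal(side_chain_rmsd(ssc, moved, "base", residue_type = "SER"),
               sqrt(1 / 2), tolerance = 1e-12)
  just_og <- ssc[ssc$atom_name == "OG", ]
  moved_og <- moved[moved$atom_name == "OG", ]
  expect_equal(side_chain_rmsd(just_og, moved_og, "base",
                               residue_type = "SER"), 1)
  expect_error(side_chain_rmsd(ssc, ssc[ssc$atom_name != "OG", ], "base",
                               residue_type = "SER"), "differ")
})

test_that("extended symmetry mode also allows cross-element flips", {
  his <- make_residue("HIS", c(-60, 90, NA, NA), ics_tab)
  sc <- his[his$atom_name %in% sidechain_atom_names("HIS"), ]
  # flip the imidazole naming (ND1<->CD2, CE1<->NE2)
  flipped <- sc
  swap <- c(ND1 = "CD2", CD2 = "ND1", CE1 = "NE2", NE2 = "CE1")
  hit <- flipped$atom_name %in% names(swap)
  flipped$atom_name[hit] <- swap[flipped$atom_name[hit]]
  base <- side_chain_rmsd(sc, flipped, "base", residue_type = "HIS")
  ext <- side_chain_rmsd(sc, flipped, "extended", residue_type = "HIS")
  expect_gt(base, 0.5)
  expect_equal(ext, 0)
})

test_that("burial classification counts beta-carbons in a 10 A ball", {
  # central residue plus k neighbors inside the shell and some outside
  mk <- function(n_in, n_out) {
    rows <- list()
    add_res <- function(i, cb) {
      data.frame(atom_name = c("N", "CA", "C", "CB"), resid = "ALA",
                 chain = "A", resno = i, insert = "",
                 x = cb[1] + c(-0.5, 0, 0.5, 0), y = cb[2] + c(0, 0, 0, 0),
                 z = cb[3] + c(0, 0.2, 0, 1.5),
                 occupancy = 1, alt = "", element = "C",
                 stringsAsFactors = FALSE)
    }
    rows[[1]] <- add_res(1, c(0, 0, -1.5))  # CB at origin
    set.seed(9)
    for (i in seq_len(n_in)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1, 2, 9.5)
      rows[[length(rows) + 1]] <- add_res(i + 1, u - c(0, 0, 1.5))
    }
    for (i in seq_len(n_out)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1, 11, 30)
      rows[[length(rows) + 1]] <- add_res(n_in + i + 1, u - c(0, 0, 1.5))
    }
    do.call(rbind, rows)
  }
  expect_equal(classify_core_surface(mk(21, 5), "A_1_"), "core")
  expect_equal(classify_core_surface(mk(20, 5), "A_1_"), "core")
  expect_equal(classify_core_surface(mk(15, 5), "A_1_"), "surface")
  expect_equal(classify_core_surface(mk(17, 5), "A_1_"), "neither")
})
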