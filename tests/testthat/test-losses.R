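# The periodic training objectives, symmetry correction, and evaluation
# metrics.

test_that("wrapped angle error honours the period", {
  expect_equal(wrapped_angle_error(-179, 179), 2)
  expect_equal(wrapped_angle_error(42.5, 42.5), 0)
  expect_equal(wrapped_angle_error(-179, 179), wrapped_angle_error(179, -179))
  set.seed(131)
  a <- runif(1000, -720, 720); b <- runif(1000, -720, 720)
  brute <- sapply(seq_along(a), function(i) {
    min(abs(a[i] - b[i] + 360 * (-5:5)))
  })
  expect_equal(wrapped_angle_error(a, b), brute, tolerance = 1e-10)
})

test_that("angle loss wraps before squaring", {
  t0 <- c(0.1, 1.9, 0.5, 1.0)
  expect_equal(angle_loss(t0, t0, rep(TRUE, 4)), 0)
  # half-period error gives the maximal squared wrapped error of 1
  expect_equal(angle_loss(c(1.7, 0, 0, 0), c(0.7, 0, 0, 0),
                          c(TRUE, FALSE, FALSE, FALSE)), 1)
  # near-antipodal pair across the seam: 0.05 and 1.95 are 0.1 apart
  expect_equal(angle_loss(c(0.05, 0, 0, 0), c(1.95, 0, 0, 0),
                          c(TRUE, FALSE, FALSE, FALSE)), 0.01,
               tolerance = 1e-12)
  # enumeration oracle: min over all whole-period shifts
  set.seed(132)
  for (i in 1:50) {
    p <- runif(4, 0, 2); t <- runif(4, 0, 2)
    brute <- mean(sapply(1:4, function(k) {
      min((p[k] - t[k] + 2 * (-3:3))^2)
    }))
    expect_equal(angle_loss(p, t, rep(TRUE, 4)), brute, tolerance = 1e-10)
  }
  expect_error(angle_loss(rep(1, 4), rep(1, 4), rep(FALSE, 4)), "empty")
})

test_that("sincos loss equals the cosine loss on the unit circle", {
  chi <- c(-179, 45, 120, 3)
  emb <- as.numeric(rbind(sin(chi * pi / 180), cos(chi * pi / 180)))
  expect_equal(sincos_loss(matrix(emb, 1, 8), chi, rep(TRUE, 4)), 0)
  # single antipodal chi contributes 2
  one <- c(TRUE, FALSE, FALSE, FALSE)
  flip <- emb; flip[1:2] <- -flip[1:2]
  expect_equal(sincos_loss(matrix(flip, 1, 8), chi, one), 2)
  set.seed(133)
  for (i in 1:50) {
    p_ang <- runif(4, -180, 180); t_ang <- runif(4, -180, 180)
    pr <- p_ang * pi / 180
    pred <- as.numeric(rbind(sin(pr), cos(pr)))
    got <- sincos_loss(matrix(pred, 1, 8), t_ang, rep(TRUE, 4))
    want <- mean(1 - cos((p_ang - t_ang) * pi / 180))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("plane-normal loss is the mean cosine distance", {
  set.seed(134)
  tn <- array(rnorm(12), c(1, 4, 3))
  tn <- tn / array(sqrt(apply(tn^2, c(1, 2), sum)), c(1, 4, 3))
  expect_equal(plane_normal_loss(tn, tn, rep(TRUE, 4)), 0)
  expect_equal(plane_normal_loss(-tn, tn, rep(TRUE, 4)), 2)
  pn <- array(rnorm(12, sd = 2), c(1, 4, 3))
  dots <- sapply(1:4, function(k) {
    sum(pn[1, k, ] * tn[1, k, ]) / sqrt(sum(pn[1, k, ]^2))
  })
  expect_equal(plane_normal_loss(pn, tn, rep(TRUE, 4)), mean(1 - dots),
               tolerance = 1e-12)
  bad <- pn; bad[1, 2, ] <- 0
  expect_error(plane_normal_loss(bad, tn, rep(TRUE, 4)), "zero-length")
})

test_that("ring-flip targets cost nothing after symmetry correction", {
  chi <- c(-65, 80, NA, NA)
  pred_ang <- c(-65, wrap_angle(80 + 180), 0, 0)
  pr <- pred_ang * pi / 180
  pred_sc <- matrix(as.numeric(rbind(sin(pr), cos(pr))), 1, 8)
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  uncorrected <- sincos_loss(pred_sc, chi, mask)
  corrected <- symmetry_corrected_loss(sincos_loss, pred_sc, chi, mask, "PHE")
  expect_gt(uncorrected, 0.9)
  expect_lt(corrected, 1e-12)
  # a residue with no symmetric chi is untouched
  expect_equal(symmetry_corrected_loss(sincos_loss, pred_sc, chi, mask, "LEU"),
               uncorrected)
})

test_that("symmetry correction never increases any loss", {
  set.seed(135)
  for (rt in c("PHE", "TYR", "ASP", "GLU", "LYS")) {
    for (i in 1:10) {
      chi <- runif(4, -180, 180)
      mask <- c(rep(TRUE, n_chi(rt)), rep(FALSE, 4 - n_chi(rt)))
      pr <- runif(4, -pi, pi)
      pred_sc <- matrix(as.numeric(rbind(sin(pr), cos(pr))), 1, 8)
      expect_lte(symmetry_corrected_loss(sincos_loss, pred_sc, chi, mask, rt),
                 sincos_loss(pred_sc, chi, mask) + 1e-12)
      pred_a <- runif(4, 0, 2)
      expect_lte(symmetry_corrected_loss(angle_loss, pred_a, (chi + 180) / 180,
                                         mask, rt),
                 angle_loss(pred_a, (chi + 180) / 180, mask) + 1e-12)
    }
  }
})

test_that("per-angle symmetry minimization equals brute-force enumeration", {
  set.seed(136)
  sym <- symmetry_table()$pi_symmetric_chi
  for (rt in c("PHE", "GLU", "ASP", "TYR")) {
    k_sym <- sym$chi_index[sym$residue_type == rt]
    mask <- c(rep(TRUE, n_chi(rt)), rep(FALSE, 4 - n_chi(rt)))
    for (i in 1:10) {
      chi <- runif(4, -180, 180)
      pr <- runif(4, -pi, pi)
      pred <- matrix(as.numeric(rbind(sin(pr), cos(pr))), 1, 8)
      # brute force over the 2^k combinations of flipped targets
      combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(k_sym)))
      brute <- min(apply(combos, 1, function(fl) {
        t2 <- chi
        t2[k_sym[as.logical(fl)]] <- t2[k_sym[as.logical(fl)]] + 180
        sincos_loss(pred, t2, mask)
      }))
      got <- symmetry_corrected_loss(sincos_loss, pred, chi, mask, rt)
      expect_equal(got, brute, tolerance = 1e-10)
    }
  }
})

test_that("evaluation aggregates a hand-built three-residue set correctly", {
  ics <- ics_tab
  types <- c("SER", "LEU", "PHE")
  true_chi <- rbind(c(60, NA, NA, NA), c(-65, 170, NA, NA),
                    c(-70, 90, NA, NA))
  pred_chi <- rbind(c(75, NA, NA, NA),      # 15 deg error
                    c(-46, 192, NA, NA),    # 19 / 22 deg errors
                    c(-70, wrap_angle(90 + 185), NA, NA))  # 0 / 5 after flip
  truth <- make_mini_protein(fixture_spec(types, chi_mode = "fixed",
                                          chi_values = true_chi, seed = 9),
                             ics)$atoms
  pred <- make_mini_protein(fixture_spec(types, chi_mode = "fixed",
                                         chi_values = pred_chi, seed = 9),
                            ics)$atoms
  rep <- evaluate_packing(pred, truth, ics)
  # chi1 MAE: mean(15, 19, 0); chi2 MAE: mean(22, 5) with the Phe flip
  expect_equal(rep$chi_mae[1], mean(c(15, 19, 0)), tolerance = 1e-6)
  expect_equal(rep$chi_mae[2], mean(c(22, 5)), tolerance = 1e-6)
  # residue 2 has chi2 error 22 > 20, so only residues 1 and 3 are accurate
  expect_equal(rep$accuracy[["All"]], 100 * 2 / 3, tolerance = 1e-6)
  expect_equal(rep$counts[["All"]], 3)
  # perfect prediction: all zeros and full accuracy
  perfect <- evaluate_packing(truth, truth, ics)
  expect_equal(max(perfect$chi_mae, na.rm = TRUE), 0)
  expect_equal(perfect$accuracy[["All"]], 100)
  expect_equal(max(perfect$rmsd["base", ], na.rm = TRUE), 0)
})

test_that("a 19/21 degree split counts as inaccurate", {
  types <- c("LEU")
  truth <- make_mini_protein(fixture_spec(types, chi_mode = "fixed",
                                          chi_values = rbind(c(-60, 170, NA, NA)),
                                          seed = 10), ics_tab)$atoms
  pred <- make_mini_protein(fixture_spec(types, chi_mode = "fixed",
                                         chi_values = rbind(c(-41, 191, NA, NA)),
                                         seed = 10), ics_tab)$atoms
  rep <- evaluate_packing(pred, truth, ics_tab)
  expect_equal(rep$accuracy[["All"]], 0)
})

test_that("evaluation is invariant to shared rigid motion", {
  set.seed(137)
  spec_t <- fixture_spec(c("LYS", "TRP", "GLN"), seed = 21)
  truth <- make_mini_protein(spec_t)$atoms
  pred <- make_mini_protein(fixture_spec(c("LYS", "TRP", "GLN"), seed = 22))$atoms
  r1 <- evaluate_packing(pred, truth, ics_tab)
  R <- random_rotation(); tr <- rnorm(3, 0, 10)
  r2 <- evaluate_packing(transform_atoms(pred, R, tr),
                         transform_atoms(truth, R, tr), ics_tab)
  expect_equal(r1$chi_mae, r2$chi_mae, tolerance = 1e-6)
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-6)
})
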