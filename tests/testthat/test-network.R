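# Equivariant network layers: projection/conditioning, blocks, prediction
# modes, angle conversion, and a finite-difference check of the hand-written
# backward passes.

enc_cfg <- encoding_config(l_max = 2, n_max = 6, r_cut = 10,
                           channel_set = "atomic")
in_mults <- encoding_multiplicities(enc_cfg)

rand_input <- function(B, mults, l_max, sd = 0.5) {
  lapply(0:l_max, function(l) {
    array(rnorm(B * mults[l + 1] * (2 * l + 1), sd = sd),
          c(B, mults[l + 1], 2 * l + 1))
  })
}

rotate_batch <- function(X, R) {
  lapply(seq_along(X), function(li) {
    D <- wigner_d_real(li - 1, R)
    d <- dim(X[[li]])
    arr <- X[[li]]
    for (b in seq_len(d[1])) {
      arr[b, , ] <- matrix(arr[b, , ], d[2]) %*% t(D)
    }
    arr
  })
}

test_that("projection conditions only the invariant features", {
  cfg <- network_config(l_max = 2, hidden = 5, n_blocks = 1, cond_dim = 3,
                        n_types = 20, seed = 7)
  params <- chipacker:::net_init(cfg, in_mults)
  set.seed(71)
  X <- rand_input(2, in_mults, 2)
  # same geometry, different residue types
  X[[1]][2, , ] <- X[[1]][1, , ]; X[[2]][2, , ] <- X[[2]][1, , ]
  X[[3]][2, , ] <- X[[3]][1, , ]
  ep <- embed_and_project(params, X, c(3L, 9L), cfg)
  expect_gt(max(abs(ep$out[[1]][1, , ] - ep$out[[1]][2, , ])), 1e-8)
  expect_equal(ep$out[[2]][1, , ], ep$out[[2]][2, , ])
  expect_equal(ep$out[[3]][1, , ], ep$out[[3]][2, , ])
  # zero input: l > 0 hidden features are zero (no bias off the invariants)
  X0 <- rand_input(1, in_mults, 2, sd = 0)
  ep0 <- embed_and_project(params, X0, 5L, cfg)
  expect_equal(max(abs(ep0$out[[2]])), 0)
  expect_equal(max(abs(ep0$out[[3]])), 0)
  expect_error(embed_and_project(params, X[1:2], c(3L, 9L), cfg), "l_max")
})

test_that("the equivariant block commutes with rotations and kills zero", {
  cfg <- network_config(l_max = 2, hidden = 6, n_blocks = 1, cond_dim = 0,
                        seed = 8)
  params <- chipacker:::net_init(cfg, in_mults)
  set.seed(81)
  h <- cfg$hidden
  x <- rand_input(3, rep(h, 3), 2, sd = 1)
  out <- equivariant_block(params, x, 1, cfg)$out
  for (i in 1:5) {
    R <- random_rotation()
    xr <- rotate_batch(x, R)
    outr <- equivariant_block(params, xr, 1, cfg)$out
    rot_out <- rotate_batch(out, R)
    err <- max(vapply(1:3, function(li) max(abs(outr[[li]] - rot_out[[li]])),
                      numeric(1)))
    expect_lt(err, 1e-5)
  }
  x0 <- rand_input(2, rep(h, 3), 2, sd = 0)
  out0 <- equivariant_block(params, x0, 1, cfg)$out
  for (li in 2:3) expect_equal(max(abs(out0[[li]])), 0)
})

test_that("the scalar coupling path reduces to multiplication", {
  C <- real_cg(0, 0, 0)
  expect_equal(as.numeric(C) * 1 * 2, 2)
})

test_that("sincos predictions are bounded and deterministic", {
  cfg <- network_config(l_max = 2, hidden = 6, n_blocks = 2,
                        output_mode = "sincos", head_widths = c(16),
                        cond_dim = 4, seed = 9)
  model <- fresh_model(cfg, enc_cfg)
  res <- make_residue("GLN", c(-60, 170, 40, NA), ics_tab)
  z <- encode_residue(res, enc_cfg, "atomic")
  p1 <- predict_chi(model, z, "GLN")
  p2 <- predict_chi(model, z, "GLN")
  expect_true(all(abs(p1$sincos) <= 1))
  expect_identical(p1$sincos, p2$sincos)
  expect_error(predict_chi(model, z, "ZZZ"), "unknown residue type")
})

test_that("invariant-mode predictions are rotation-invariant end to end", {
  cfg <- network_config(l_max = 2, hidden = 6, n_blocks = 2,
                        output_mode = "sincos", head_widths = c(16),
                        cond_dim = 0, seed = 10)
  model <- fresh_model(cfg, enc_cfg)
  res <- make_residue("LEU", c(-70, 160, NA, NA), ics_tab)
  z <- encode_residue(res, enc_cfg, "atomic")
  p0 <- predict_chi(model, z)$sincos
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  res0 <- res
  res0[, c("x", "y", "z")] <- sweep(as.matrix(res[, c("x", "y", "z")]), 2, ca)
  set.seed(101)
  for (i in 1:5) {
    zr <- encode(channelize(transform_atoms(res0, random_rotation()),
                            c(0, 0, 0), "atomic"), enc_cfg)
    expect_lt(max(abs(predict_chi(model, zr)$sincos - p0)), 1e-9)
  }
})

test_that("plane-normal predictions co-rotate with the input", {
  cfg <- network_config(l_max = 2, hidden = 6, n_blocks = 2,
                        output_mode = "plane_normals", cond_dim = 0,
                        seed = 11)
  model <- fresh_model(cfg, enc_cfg)
  res <- make_residue("MET", c(55, -170, 70, NA), ics_tab)
  z <- encode_residue(res, enc_cfg, "atomic")
  n0 <- predict_chi(model, z)$normals
  ca <- as.numeric(res[res$atom_name == "CA", c("x", "y", "z")][1, ])
  res0 <- res
  res0[, c("x", "y", "z")] <- sweep(as.matrix(res[, c("x", "y", "z")]), 2, ca)
  set.seed(111)
  for (i in 1:5) {
    R <- random_rotation()
    zr <- encode(channelize(transform_atoms(res0, R), c(0, 0, 0), "atomic"),
                 enc_cfg)
    nr <- predict_chi(model, zr)$normals
    for (k in 1:4) {
      expect_lt(max(abs(as.vector(R %*% n0[1, k, ]) - nr[1, k, ])), 1e-9)
    }
  }
})

test_that("angle conversion handles the axis cases and both scaled modes", {
  p <- structure(list(mode = "sincos",
                      sincos = matrix(c(0, 1, 1, 0, -1, 0, 0, -1), 1, 8)),
                 class = "chi_prediction")
  a <- angles_from_prediction(p, "LYS")[[1]]
  expect_equal(a$chi, c(0, 90, -90, 180))
  p2 <- structure(list(mode = "angle",
                       angle_scaled = matrix(c(1, 1.5, 0.5, 2), 1, 4)),
                  class = "chi_prediction")
  a2 <- angles_from_prediction(p2, "LYS")[[1]]
  expect_equal(a2$chi, c(0, 90, -90, 180))
})

test_that("chi angles decode from true plane normals through the backbone frame", {
  set.seed(121)
  for (rt in c("MET", "LYS", "SER", "TRP")) {
    nc <- n_chi(rt)
    chi <- runif(4, -180, 180)
    res <- make_residue(rt, chi, ics_tab)
    pn <- chi_plane_normals(res, rt)
    nm <- matrix(0, 4, 3)
    nm[seq_len(nc), ] <- pn[-1, , drop = FALSE][seq_len(nc), ]
    bb <- res[res$atom_name %in% c("N", "CA", "C", "CB"), ]
    m <- as.matrix(bb[, c("x", "y", "z")]); rownames(m) <- bb$atom_name
    dec <- chi_from_plane_normals(nm, m, rt, ics_tab)
    expect_lt(max(abs(wrap_angle(dec[seq_len(nc)] - chi[seq_len(nc)]))), 1e-4)
  }
})

test_that("hand-written gradients match finite differences", {
  cfg <- network_config(l_max = 2, hidden = 4, n_blocks = 2,
                        output_mode = "sincos", head_widths = c(8),
                        cond_dim = 3, seed = 12)
  params <- chipacker:::net_init(cfg, in_mults)
  set.seed(122)
  B <- 4
  batch <- list(X = rand_input(B, in_mults, 2),
                chi = matrix(runif(B * 4, -180, 180), B, 4),
                mask = matrix(TRUE, B, 4),
                residue_type = rep("LYS", B),
                type_ids = sample(20, B, replace = TRUE))
  lc <- loss_config("sincos", symmetry_correction = FALSE)
  bl <- chipacker:::batch_loss(params, batch, cfg, lc)
  g <- chipacker:::net_backward(params, bl$cache, bl$grad_out, cfg)
  f <- function(p) chipacker:::batch_loss(p, batch, cfg, lc)$loss
  for (nm in names(params)) {
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-5
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (f(pp) - f(pm)) / (2 * eps)
    expect_lt(abs(fd - g[[nm]][i]), 1e-6 + 1e-3 * abs(fd),
              label = paste("gradient of", nm))
  }
})

test_that("parameter budgets at adjacent l_max can be matched within 1%", {
  target_cfg <- network_config(l_max = 5, hidden = 12, n_blocks = 2,
                               output_mode = "sincos",
                               head_widths = c(64, 64), cond_dim = 8,
                               seed = 1)
  enc5 <- encoding_config(l_max = 5, n_max = 12)
  enc4 <- encoding_config(l_max = 4, n_max = 12)
  target <- n_params(chipacker:::net_init(target_cfg,
                                          encoding_multiplicities(enc5)))
  # tune both the hidden multiplicity and the head width of the l_max = 4
  # model to close the parameter gap
  grid <- expand.grid(h = 8:18, w = seq(32, 96, by = 4))
  counts4 <- mapply(function(h, w) {
    cfg <- network_config(l_max = 4, hidden = h, n_blocks = 2,
                          output_mode = "sincos", head_widths = c(w, w),
                          cond_dim = 8, seed = 1)
    n_params(chipacker:::net_init(cfg, encoding_multiplicities(enc4)))
  }, grid$h, grid$w)
  expect_lt(min(abs(counts4 - target)) / target, 0.01)
})
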