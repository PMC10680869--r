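# SO(3)-equivariant regression network. Steerable feature maps are lists
# indexed by degree l (element l + 1), each an array (batch, multiplicity,
# 2l + 1). The network is:
#   1. a per-degree linear projection of the encoded input (with a linear
#      embedding of the one-hot residue type concatenated to the l = 0
#      features) to a hidden map with the same multiplicity at every degree;
#   2. a stack of equivariant blocks (feature-wise Clebsch-Gordan tensor
#      product of the map with itself, norm-based layer normalization with a
#      silu gate, a shape-preserving per-degree linear layer, additive skip);
#   3. an invariant feed-forward head with silu and dropout on the l = 0
#      features (sincos / angle modes), or a linear readout of the l = 1
#      features (plane-normal mode).
# Gradients are computed by hand-written reverse-mode passes; every layer
# returns a cache consumed by its backward function.

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' Network configuration
#'
#' @param l_max maximum feature degree (matches the encoding).
#' @param hidden multiplicity of the hidden steerable features per degree.
#' @param n_blocks number of equivariant blocks.
#' @param output_mode "sincos" (8 bounded outputs, sine/cosine pairs),
#'   "angle" (4 outputs in the scaled [0, 2) periodic domain), or
#'   "plane_normals" (4 degree-1 vectors).
#' @param head_widths integer vector of hidden widths of the invariant
#'   feed-forward head (ignored in plane-normal mode).
#' @param dropout dropout rate of the head at training time.
#' @param cond_dim width of the residue-type embedding concatenated to the
#'   l = 0 input features; 0 disables conditioning.
#' @param n_types number of residue types for the conditioning one-hot.
#' @param seed RNG seed used for parameter initialization.
#' @return object of class `network_config`.
#' @export
network_config <- function(l_max, hidden = 16, n_blocks = 2,
                           output_mode = c("sincos", "angle", "plane_normals"),
                           head_widths = c(128, 128), dropout = 0,
                           cond_dim = 0, n_types = 20, seed = 1) {
  output_mode <- match.arg(output_mode)
  structure(list(l_max = l_max, hidden = hidden, n_blocks = n_blocks,
                 output_mode = output_mode, head_widths = head_widths,
                 dropout = dropout, cond_dim = cond_dim, n_types = n_types,
                 seed = seed),
            class = "network_config")
}

# Degree-1 features live in the real spherical-harmonic component order
# (m = -1, 0, 1) = (y, z, x); these helpers convert Cartesian vectors of a
# (batch, copies, 3) array to and from that layout.
feat_to_xyz <- function(a) a[, , c(3, 1, 2), drop = FALSE]
xyz_to_feat <- function(a) a[, , c(2, 3, 1), drop = FALSE]

# Tensor-product path table for self-interaction at a given l_max: pairs
# l1 <= l2 with output degree l3 <= l_max; paths that are antisymmetric
# under exchange (l1 == l2 with odd l1 + l2 - l3) vanish for x (x) x and are
# dropped. Each path carries the nonzero entries of its real coupling tensor.
tp_paths <- function(l_max) {
  key <- paste0("paths_", l_max)
  cached <- .pkg_cache[[key]]
  if (!is.null(cached)) return(cached)
  paths <- list()
  for (l1 in 0:l_max) for (l2 in l1:l_max) {
    for (l3 in abs(l1 - l2):min(l_max, l1 + l2)) {
      if (l1 == l2 && (l1 + l2 - l3) %% 2 == 1) next
      C <- real_cg(l1, l2, l3)
      nz <- which(abs(C) > 1e-12, arr.ind = TRUE)
      paths[[length(paths) + 1]] <- list(
        l1 = l1, l2 = l2, l3 = l3,
        m3 = nz[, 1], m1 = nz[, 2], m2 = nz[, 3],
        val = C[nz]
      )
    }
  }
  .pkg_cache[[key]] <- paths
  paths
}

# Number of tensor-product output copies feeding each degree l3 (per hidden
# feature), including the identity skip of the input map itself.
tp_out_mults <- function(l_max) {
  counts <- rep(1, l_max + 1)  # the concatenated input map
  for (p in tp_paths(l_max)) {
    counts[p$l3 + 1] <- counts[p$l3 + 1] + 1
  }
  counts
}

# ---------------------------------------------------------------------------
# Parameter initialization

rand_mat <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

#' Initialize network parameters
#'
#' Variance-scaled Gaussian initialization: each linear map is scaled by
#' 1/sqrt(fan-in) so pre-activation variances stay near one.
#'
#' @param config a `network_config`.
#' @param in_mults integer vector of input multiplicities per degree
#'   (from [encoding_multiplicities()]).
#' @return named list of parameter matrices.
#' @export
net_init <- function(config, in_mults) {
  stopifnot(length(in_mults) == config$l_max + 1)
  set.seed(config$seed)
  L <- config$l_max
  h <- config$hidden
  p <- list()
  if (config$cond_dim > 0) {
    p$embed <- rand_mat(config$cond_dim, config$n_types, 1)
  }
  in0 <- in_mults[1] + config$cond_dim
  p$proj_W_l0 <- rand_mat(h, in0, 1 / sqrt(in0))
  p$proj_b_l0 <- matrix(0, h, 1)
  if (L > 0) for (l in 1:L) {
    p[[paste0("proj_W_l", l)]] <- rand_mat(h, in_mults[l + 1],
                                           1 / sqrt(max(1, in_mults[l + 1])))
  }
  tpm <- tp_out_mults(L)
  for (b in seq_len(config$n_blocks)) {
    for (l in 0:L) {
      fan <- h * tpm[l + 1]
      p[[sprintf("blk%d_W_l%d", b, l)]] <- rand_mat(h, fan, 1 / sqrt(fan))
      p[[sprintf("blk%d_gamma_l%d", b, l)]] <- matrix(1, h * tpm[l + 1], 1)
      p[[sprintf("blk%d_beta_l%d", b, l)]] <- matrix(0, h * tpm[l + 1], 1)
    }
    p[[sprintf("blk%d_b_l0", b)]] <- matrix(0, h, 1)
  }
  if (config$output_mode == "plane_normals") {
    p$head_W <- rand_mat(4, h, 1 / sqrt(h))
  } else {
    widths <- c(h, config$head_widths,
                if (config$output_mode == "sincos") 8 else 4)
    for (i in seq_len(length(widths) - 1)) {
      p[[paste0("head_W", i)]] <- rand_mat(widths[i + 1], widths[i],
                                           1 / sqrt(widths[i]))
      p[[paste0("head_b", i)]] <- matrix(0, widths[i + 1], 1)
    }
  }
  p
}

#' Count trainable parameters
#'
#' @param params parameter list from [net_init()].
#' @return integer total number of scalar parameters.
#' @export
n_params <- function(params) sum(vapply(params, length, numeric(1)))

# ---------------------------------------------------------------------------
# Layer primitives (each forward returns list(out, cache))

# Per-degree linear map: y[b, o, m] = sum_i W[o, i] x[b, i, m].
lin_deg_fwd <- function(W, x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
  ym <- xm %*% t(W)
  y <- aperm(array(ym, c(d[1], d[3], nrow(W))), c(1, 3, 2))
  list(out = y, cache = list(xm = xm, d = d, W = W))
}

lin_deg_bwd <- function(cache, gy) {
  d <- dim(gy)
  gym <- matrix(aperm(gy, c(1, 3, 2)), d[1] * d[3], d[2])
  gW <- t(gym) %*% cache$xm
  gxm <- gym %*% cache$W
  gx <- aperm(array(gxm, c(cache$d[1], cache$d[3], cache$d[2])), c(1, 3, 2))
  list(gW = gW, gx = gx)
}

# Feature-wise tensor product of the map with itself. Output per degree l3:
# array (B, h * n_copies(l3), 2 l3 + 1) where the first copy block is the
# input map itself (identity path) followed by one block per CG path.
self_tp_fwd <- function(x, l_max) {
  paths <- tp_paths(l_max)
  B <- dim(x[[1]])[1]
  h <- dim(x[[1]])[2]
  blocks <- lapply(0:l_max, function(l) list(x[[l + 1]]))
  for (p in paths) {
    x1 <- x[[p$l1 + 1]]; x2 <- x[[p$l2 + 1]]
    # elementwise pair products once per nonzero coupling, then one GEMM
    # against the sparse coefficient matrix (nonzeros x output m)
    Z <- matrix(0, B * h, length(p$val))
    for (i in seq_along(p$val)) {
      Z[, i] <- x1[, , p$m1[i]] * x2[, , p$m2[i]]
    }
    S <- matrix(0, length(p$val), 2 * p$l3 + 1)
    S[cbind(seq_along(p$val), p$m3)] <- p$val
    y <- array(Z %*% S, c(B, h, 2 * p$l3 + 1))
    blocks[[p$l3 + 1]] <- c(blocks[[p$l3 + 1]], list(y))
  }
  out <- lapply(blocks, function(bl) {
    B <- dim(bl[[1]])[1]; M <- dim(bl[[1]])[3]
    arr <- array(0, c(B, h * length(bl), M))
    for (j in seq_along(bl)) arr[, ((j - 1) * h + 1):(j * h), ] <- bl[[j]]
    arr
  })
  list(out = out, cache = list(x = x, l_max = l_max, h = h))
}

self_tp_bwd <- function(cache, gy) {
  x <- cache$x; l_max <- cache$l_max; h <- cache$h
  gx <- lapply(x, function(a) array(0, dim(a)))
  # identity path occupies the first copy block at each degree
  pos <- rep(1L, l_max + 1)
  for (l in 0:l_max) {
    gx[[l + 1]] <- gx[[l + 1]] + gy[[l + 1]][, 1:h, , drop = FALSE]
  }
  for (p in tp_paths(l_max)) {
    pos[p$l3 + 1] <- pos[p$l3 + 1] + 1L
    off <- (pos[p$l3 + 1] - 1L) * h
    g3 <- gy[[p$l3 + 1]][, (off + 1):(off + h), , drop = FALSE]
    x1 <- x[[p$l1 + 1]]; x2 <- x[[p$l2 + 1]]
    g1 <- array(0, dim(x1)); g2 <- array(0, dim(x2))
    B <- dim(x1)[1]
    gslice <- lapply(seq_len(2 * p$l3 + 1), function(m) g3[, , m])
    acc1 <- vector("list", dim(x1)[3]); acc2 <- vector("list", dim(x2)[3])
    for (i in seq_along(p$val)) {
      gv <- p$val[i] * gslice[[p$m3[i]]]
      t1 <- gv * x2[, , p$m2[i]]
      t2 <- gv * x1[, , p$m1[i]]
      m1 <- p$m1[i]; m2 <- p$m2[i]
      acc1[[m1]] <- if (is.null(acc1[[m1]])) t1 else acc1[[m1]] + t1
      acc2[[m2]] <- if (is.null(acc2[[m2]])) t2 else acc2[[m2]] + t2
    }
    for (m in seq_along(acc1)) if (!is.null(acc1[[m]])) g1[, , m] <- acc1[[m]]
    for (m in seq_along(acc2)) if (!is.null(acc2[[m]])) g2[, , m] <- acc2[[m]]
    gx[[p$l1 + 1]] <- gx[[p$l1 + 1]] + g1
    gx[[p$l2 + 1]] <- gx[[p$l2 + 1]] + g2
  }
  gx
}

# Norm gate for l > 0: each copy is rescaled by silu(gamma * n + beta) / n
# where n is the copy's vector norm; for l = 0 a plain silu on the affine-
# transformed scalars. Equivariant because only norms enter nonlinearly.
gate_fwd <- function(gamma, beta, x, l) {
  if (l == 0) {
    z <- sweep(sweep(x, 2, as.numeric(gamma), "*"), 2, as.numeric(beta), "+")
    list(out = silu(z), cache = list(l = 0, z = z, x = x, gamma = gamma))
  } else {
    n2 <- matrix(x[, , 1], dim(x)[1])^2
    for (m in 2:dim(x)[3]) n2 <- n2 + matrix(x[, , m], dim(x)[1])^2
    n <- sqrt(pmax(n2, 1e-24))
    s <- sweep(sweep(n, 2, as.numeric(gamma), "*"), 2, as.numeric(beta), "+")
    q <- silu(s) / n
    y <- x * array(q, dim(x))
    list(out = y, cache = list(l = l, x = x, n = n, s = s, q = q,
                               gamma = gamma))
  }
}

gate_bwd <- function(cache, gy) {
  if (cache$l == 0) {
    dz <- gy * dsilu(cache$z)
    ggamma <- matrix(colSums(matrix(dz * cache$x, nrow = dim(gy)[1])), ncol = 1)
    gbeta <- matrix(colSums(matrix(dz, nrow = dim(gy)[1])), ncol = 1)
    gx <- sweep(dz, 2, as.numeric(cache$gamma), "*")
    list(ggamma = ggamma, gbeta = gbeta, gx = gx)
  } else {
    x <- cache$x; n <- cache$n; s <- cache$s; q <- cache$q
    B <- dim(x)[1]
    dq <- matrix(gy[, , 1] * x[, , 1], B)
    for (m in 2:dim(x)[3]) dq <- dq + matrix(gy[, , m] * x[, , m], B)
    gx <- gy * array(q, dim(x))
    dqdn <- (dsilu(s) * sweep(n, 2, as.numeric(cache$gamma), "*") - silu(s)) / n^2
    dn <- dq * dqdn
    ds_gamma <- dq * dsilu(s) / n   # ds contribution via gamma: s = g*n + b
    ggamma <- matrix(colSums(ds_gamma * n), ncol = 1)
    gbeta <- matrix(colSums(ds_gamma), ncol = 1)
    # dn splits into the s-channel (already in dqdn) and the 1/n channel;
    # dqdn above contains both, so only the x-direction term remains:
    gx <- gx + x * array(dn / n, dim(x))
    list(ggamma = ggamma, gbeta = gbeta, gx = gx)
  }
}

# ---------------------------------------------------------------------------
# Full network forward/backward

#' Project encoded input and conditioning to the hidden representation
#'
#' Embeds the one-hot residue type, concatenates it to the invariant (l = 0)
#' input features, and applies a per-degree linear map to the hidden
#' multiplicity. Only the l = 0 path sees the conditioning, so features of
#' degree l > 0 are unaffected by residue identity.
#'
#' @param params parameters from [net_init()].
#' @param X input batch: list per degree of arrays (batch, mult, 2l + 1).
#' @param type_ids integer residue-type ids in 1..n_types (NULL when
#'   conditioning is disabled).
#' @param config the `network_config`.
#' @return list(out = hidden steerable map, cache = backward cache).
#' @export
embed_and_project <- function(params, X, type_ids, config) {
  L <- config$l_max
  if (length(X) != L + 1) stop("embed_and_project: l_max mismatch between input and config")
  B <- dim(X[[1]])[1]
  x0 <- X[[1]]
  if (config$cond_dim > 0) {
    onehot <- matrix(0, B, config$n_types)
    onehot[cbind(seq_len(B), type_ids)] <- 1
    emb <- onehot %*% t(params$embed)       # B x cond_dim
    x0 <- array(c(x0, emb), c(B, dim(X[[1]])[2] + config$cond_dim, 1))
    cache_onehot <- onehot
  } else cache_onehot <- NULL
  out <- vector("list", L + 1)
  caches <- vector("list", L + 1)
  lp <- lin_deg_fwd(params$proj_W_l0, x0)
  out[[1]] <- lp$out + array(rep(as.numeric(params$proj_b_l0), each = B),
                             dim(lp$out))
  caches[[1]] <- lp$cache
  if (L > 0) for (l in 1:L) {
    lp <- lin_deg_fwd(params[[paste0("proj_W_l", l)]], X[[l + 1]])
    out[[l + 1]] <- lp$out
    caches[[l + 1]] <- lp$cache
  }
  list(out = out, cache = list(lin = caches, onehot = cache_onehot,
                               in0_mult = dim(X[[1]])[2]))
}

embed_and_project_bwd <- function(params, cache, gy, config) {
  L <- config$l_max
  g <- list()
  B <- dim(gy[[1]])[1]
  bw <- lin_deg_bwd(cache$lin[[1]], gy[[1]])
  g$proj_W_l0 <- bw$gW
  g$proj_b_l0 <- matrix(apply(gy[[1]], 2, sum), ncol = 1)
  if (config$cond_dim > 0) {
    m <- cache$in0_mult
    gemb <- matrix(bw$gx[, (m + 1):(m + config$cond_dim), 1], nrow = B)
    g$embed <- t(gemb) %*% cache$onehot
  }
  if (L > 0) for (l in 1:L) {
    bw2 <- lin_deg_bwd(cache$lin[[l + 1]], gy[[l + 1]])
    g[[paste0("proj_W_l", l)]] <- bw2$gW
  }
  g
}

#' One equivariant block
#'
#' Feature-wise tensor product of the hidden map with itself (all coupling
#' paths with output degree <= l_max, each hidden copy interacting only with
#' itself), norm-gated layer normalization, a shape-preserving per-degree
#' linear layer, and an additive skip connection.
#'
#' @param params,config as in [embed_and_project()].
#' @param x hidden steerable map.
#' @param b block index (1-based), selecting the parameter group.
#' @return list(out, cache).
#' @export
equivariant_block <- function(params, x, b, config) {
  L <- config$l_max
  tp <- self_tp_fwd(x, L)
  gates <- vector("list", L + 1)
  lins <- vector("list", L + 1)
  out <- vector("list", L + 1)
  B <- dim(x[[1]])[1]
  for (l in 0:L) {
    gm <- params[[sprintf("blk%d_gamma_l%d", b, l)]]
    bt <- params[[sprintf("blk%d_beta_l%d", b, l)]]
    gt <- gate_fwd(gm, bt, tp$out[[l + 1]], l)
    gates[[l + 1]] <- gt$cache
    lp <- lin_deg_fwd(params[[sprintf("blk%d_W_l%d", b, l)]], gt$out)
    lins[[l + 1]] <- lp$cache
    y <- lp$out
    if (l == 0) {
      y <- y + array(rep(as.numeric(params[[sprintf("blk%d_b_l0", b)]]),
                         each = B), dim(y))
    }
    out[[l + 1]] <- y + x[[l + 1]]
  }
  list(out = out, cache = list(tp = tp$cache, gates = gates, lins = lins,
                               b = b))
}

equivariant_block_bwd <- function(params, cache, gy, config) {
  L <- config$l_max
  b <- cache$b
  g <- list()
  gtp <- vector("list", L + 1)
  for (l in 0:L) {
    bw <- lin_deg_bwd(cache$lins[[l + 1]], gy[[l + 1]])
    g[[sprintf("blk%d_W_l%d", b, l)]] <- bw$gW
    if (l == 0) {
      g[[sprintf("blk%d_b_l0", b)]] <- matrix(apply(gy[[1]], 2, sum), ncol = 1)
    }
    gb <- gate_bwd(cache$gates[[l + 1]], bw$gx)
    g[[sprintf("blk%d_gamma_l%d", b, l)]] <- gb$ggamma
    g[[sprintf("blk%d_beta_l%d", b, l)]] <- gb$gbeta
    gtp[[l + 1]] <- gb$gx
  }
  gx <- self_tp_bwd(cache$tp, gtp)
  for (l in 0:L) gx[[l + 1]] <- gx[[l + 1]] + gy[[l + 1]]  # skip connection
  list(gparams = g, gx = gx)
}

# Full forward pass. dropout_rng: NULL at inference; an integer seed during
# training makes the dropout masks reproducible.
net_forward <- function(params, X, type_ids, config, train = FALSE) {
  ep <- embed_and_project(params, X, type_ids, config)
  x <- ep$out
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    bl <- equivariant_block(params, x, b, config)
    x <- bl$out
    blocks[[b]] <- bl$cache
  }
  B <- dim(x[[1]])[1]
  if (config$output_mode == "plane_normals") {
    if (config$l_max < 1) stop("plane-normal head requires l_max >= 1")
    lp <- lin_deg_fwd(params$head_W, x[[2]])
    out <- lp$out  # B x 4 x 3
    head_cache <- list(mode = "plane_normals", lin = lp$cache)
  } else {
    h0 <- matrix(x[[1]], B)   # B x hidden
    acts <- list(h0)
    zs <- list()
    masks <- list()
    nlayer <- length(config$head_widths) + 1
    a <- h0
    for (i in seq_len(nlayer)) {
      z <- a %*% t(params[[paste0("head_W", i)]])
      z <- sweep(z, 2, as.numeric(params[[paste0("head_b", i)]]), "+")
      zs[[i]] <- z
      if (i < nlayer) {
        a <- silu(z)
        if (train && config$dropout > 0) {
          mk <- matrix(stats::rbinom(length(a), 1, 1 - config$dropout),
                       nrow(a)) / (1 - config$dropout)
          a <- a * mk
          masks[[i]] <- mk
        }
        acts[[i + 1]] <- a
      }
    }
    zlast <- zs[[nlayer]]
    out <- if (config$output_mode == "sincos") tanh(zlast) else zlast
    head_cache <- list(mode = config$output_mode, acts = acts, zs = zs,
                       masks = masks, nlayer = nlayer, out = out)
  }
  list(out = out,
       cache = list(ep = ep$cache, blocks = blocks, head = head_cache,
                    final = x))
}

net_backward <- function(params, cache, gout, config) {
  g <- list()
  x <- cache$final
  B <- if (is.matrix(gout)) nrow(gout) else dim(gout)[1]
  gx <- lapply(x, function(a) array(0, dim(a)))
  hc <- cache$head
  if (hc$mode == "plane_normals") {
    bw <- lin_deg_bwd(hc$lin, gout)
    g$head_W <- bw$gW
    gx[[2]] <- gx[[2]] + bw$gx
  } else {
    gz <- if (hc$mode == "sincos") gout * (1 - hc$out^2) else gout
    for (i in hc$nlayer:1) {
      g[[paste0("head_W", i)]] <- t(gz) %*% hc$acts[[i]]
      g[[paste0("head_b", i)]] <- matrix(colSums(gz), ncol = 1)
      ga <- gz %*% params[[paste0("head_W", i)]]
      if (i > 1) {
        if (length(hc$masks) >= i - 1 && !is.null(hc$masks[[i - 1]])) {
          ga <- ga * hc$masks[[i - 1]]
        }
        gz <- ga * dsilu(hc$zs[[i - 1]])
      } else {
        gh0 <- ga
      }
    }
    gx[[1]] <- gx[[1]] + array(gh0, dim(x[[1]]))
  }
  for (b in config$n_blocks:1) {
    bw <- equivariant_block_bwd(params, cache$blocks[[b]], gx, config)
    g <- c(g, bw$gparams)
    gx <- bw$gx
  }
  gp <- embed_and_project_bwd(params, cache$ep, gx, config)
  c(g, gp)
}

# ---------------------------------------------------------------------------
# Prediction interface

#' Predict chi angles from an encoded neighborhood
#'
#' Runs the network in inference mode (dropout disabled) on one or more
#' encoded neighborhoods.
#'
#' @param model a trained model (list with `params`, `config`,
#'   `encoding_config`, `type_levels`), e.g. from [train_network()].
#' @param X a single `steerable_tensor`, or a batched input list.
#' @param residue_type character vector of residue types (required when the
#'   model is conditioned).
#' @return object of class `chi_prediction`: list with `mode` and payload
#'   `sincos` (n x 8), `angle_scaled` (n x 4) or `normals` (n x 4 x 3).
#' @export
predict_chi <- function(model, X, residue_type = NULL) {
  config <- model$config
  if (inherits(X, "steerable_tensor")) X <- batch_tensors(list(X))
  type_ids <- NULL
  if (config$cond_dim > 0) {
    if (is.null(residue_type)) stop("predict_chi: residue_type required for a conditioned model")
    type_ids <- match(residue_type, model$type_levels)
    if (anyNA(type_ids)) {
      stop("predict_chi: unknown residue type ",
           paste(unique(residue_type[is.na(type_ids)]), collapse = ", "))
    }
  }
  fw <- net_forward(model$params, X, type_ids, config, train = FALSE)
  out <- fw$out
  res <- list(mode = config$output_mode)
  if (config$output_mode == "sincos") {
    res$sincos <- out
  } else if (config$output_mode == "angle") {
    res$angle_scaled <- out %% 2
  } else {
    res$normals <- feat_to_xyz(out)
  }
  structure(res, class = "chi_prediction")
}

#' Stack encoded tensors into a batch
#'
#' @param tensors list of `steerable_tensor`s (flattened automatically).
#' @return list per degree of arrays (batch, mult, 2l + 1).
#' @export
batch_tensors <- function(tensors) {
  flat <- lapply(tensors, function(t) {
    if (inherits(t, "steerable_tensor")) st_flatten(t) else t
  })
  L <- length(flat[[1]])
  lapply(seq_len(L), function(li) {
    mats <- lapply(flat, `[[`, li)
    B <- length(mats)
    arr <- array(0, c(B, nrow(mats[[1]]), ncol(mats[[1]])))
    for (i in seq_len(B)) arr[i, , ] <- mats[[i]]
    arr
  })
}

#' Convert a network prediction to chi angles
#'
#' sincos mode: atan2 of each (sin, cos) pair, no renormalization. Angle
#' mode: the scaled [0, 2) domain is mapped back to degrees in (-180, 180].
#' Plane-normal mode: chi angles are decoded sequentially against the
#' residue's backbone frame, reconstructing each side-chain atom as its chi
#' becomes known (see [chi_from_plane_normals()]); `frame` and `ics` are
#' then required.
#'
#' @param pred a `chi_prediction`.
#' @param residue_type 3-letter codes, one per prediction row.
#' @param frame,ics backbone coordinate matrices (list, one per row) and an
#'   internal-coordinate table, needed in plane-normal mode.
#' @return list of `chi_angles` objects, one per prediction row.
#' @export
angles_from_prediction <- function(pred, residue_type, frame = NULL,
                                   ics = NULL) {
  stopifnot(inherits(pred, "chi_prediction"))
  n <- switch(pred$mode,
              sincos = nrow(pred$sincos),
              angle = nrow(pred$angle_scaled),
              plane_normals = dim(pred$normals)[1])
  if (length(residue_type) == 1) residue_type <- rep(residue_type, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rt <- residue_type[i]
    nch <- n_chi(rt)
    chi <- rep(NA_real_, 4)
    if (pred$mode == "sincos") {
      sc <- pred$sincos[i, ]
      for (k in seq_len(4)) {
        chi[k] <- atan2(sc[2 * k - 1], sc[2 * k]) * 180 / pi
      }
    } else if (pred$mode == "angle") {
      chi <- wrap_angle(pred$angle_scaled[i, ] * 180 - 180)
    } else {
      if (is.null(frame) || is.null(ics)) {
        stop("angles_from_prediction: plane-normal mode needs frame and ics")
      }
      nr <- matrix(pred$normals[i, , ], 4, 3)
      chi <- chi_from_plane_normals(nr, frame[[i]], rt, ics)
    }
    mask <- rep(FALSE, 4)
    mask[seq_len(nch)] <- TRUE
    chi[!mask] <- NA_real_
    out[[i]] <- structure(list(residue_type = rt, chi = wrap_angle(chi),
                               defined_mask = mask),
                          class = "chi_angles")
  }
  out
}

#' Plane normals of a residue's dihedral planes
#'
#' Returns the unit normals of the planes spanned by consecutive atom
#' triplets along the side chain: row k is the normal of the plane of the
#' last three atoms of the chi-k quadruple (the plane shared with chi k+1).
#' Row 0 (the backbone N-CA-CB plane) is prepended as the redundant
#' reference normal.
#'
#' @param residue_atoms one residue's atom data.frame.
#' @param residue_type 3-letter code (default from the table).
#' @return matrix (n_chi + 1) x 3 of unit normals.
#' @export
chi_plane_normals <- function(residue_atoms, residue_type = NULL) {
  if (is.null(residue_type)) residue_type <- residue_atoms$resid[1]
  quads <- chi_atom_names(residue_type)
  cm <- atom_coords(residue_atoms)
  nrm <- function(a, b, c) {
    v <- vcross(cm[b, ] - cm[a, ], cm[c, ] - cm[b, ])
    v / vnorm(v)
  }
  out <- matrix(NA_real_, length(quads) + 1, 3)
  q1 <- quads[[1]]
  out[1, ] <- nrm(q1[1], q1[2], q1[3])
  for (k in seq_along(quads)) {
    q <- quads[[k]]
    out[k + 1, ] <- nrm(q[2], q[3], q[4])
  }
  out
}

#' Decode chi angles from predicted plane normals
#'
#' Reconstructs the side chain atom by atom: chi k is the signed angle
#' between the previous plane normal and normal k about the current bond
#' axis; once chi k is known the next atom is placed and provides the axis
#' for chi k+1. The redundant first normal comes from the backbone frame.
#'
#' @param normals 4 x 3 matrix of (possibly unnormalized) predicted normals.
#' @param backbone named coordinate matrix with rows N, CA, C (CB rebuilt if
#'   absent).
#' @param residue_type 3-letter code.
#' @param ics internal-coordinate table.
#' @return numeric(4) chi angles in degrees (NA beyond the residue's count).
#' @export
chi_from_plane_normals <- function(normals, backbone, residue_type, ics) {
  nch <- n_chi(residue_type)
  chi <- rep(NA_real_, 4)
  if (nch == 0) return(chi)
  quads <- chi_atom_names(residue_type)
  coords <- list(N = backbone["N", ], CA = backbone["CA", ], C = backbone["C", ])
  tab <- ics[ics$resid == residue_type, , drop = FALSE]
  place_from_tab <- function(atom, chi_sofar) {
    spec <- sidechain_build_spec(residue_type)
    for (e in spec) {
      if (e$atom != atom) next
      row <- tab[tab$atom_name == e$atom, , drop = FALSE]
      tors <- if (e$dtype == "fixed") row$dihedral else {
        k <- as.integer(substr(e$dtype, 4, 4))
        chi_sofar[k] + row$dihedral
      }
      return(place_atom(coords[[e$a]], coords[[e$b]], coords[[e$c]],
                        row$bond, row$angle, tors))
    }
    stop("chi_from_plane_normals: no build entry for ", atom)
  }
  if (!"CB" %in% rownames(backbone)) {
    coords$CB <- place_from_tab("CB", chi)
  } else coords$CB <- backbone["CB", ]
  prev_n <- {
    v <- vcross(coords$CA - coords$N, coords$CB - coords$CA)
    v / vnorm(v)
  }
  for (k in seq_len(nch)) {
    q <- quads[[k]]
    axis <- coords[[q[3]]] - coords[[q[2]]]
    axis <- axis / vnorm(axis)
    nk <- normals[k, ]
    nn <- vnorm(nk)
    if (nn < 1e-8) stop("chi_from_plane_normals: zero-length normal for chi", k)
    nk <- nk / nn
    chi[k] <- atan2(sum(vcross(prev_n, nk) * axis), sum(prev_n * nk)) * 180 / pi
    # place the atom that chi k defines so the next axis exists
    coords[[q[4]]] <- place_from_tab(q[4], chi)
    prev_n <- nk
  }
  wrap_angle(chi)
}
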