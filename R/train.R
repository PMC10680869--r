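# Gradient-based training of the equivariant chi-angle regressors: loss
# gradients for the three objectives (with optional pi-symmetry target
# correction), an Adam optimizer over the flat parameter list, and the
# epoch loop with structure-level validation and best-checkpoint retention.

#' Loss configuration
#'
#' @param objective "sincos", "angle" or "plane_normals".
#' @param symmetry_correction apply the per-angle minimum over the
#'   pi-equivalent targets for the symmetric chi angles.
#' @param chi_weights optional positive weights over chi 1..4 (frequency
#'   weighting); NULL for uniform.
#' @param wrap_then_square angle objective only; see [angle_loss()].
#' @return object of class `loss_config`.
#' @export
loss_config <- function(objective = c("sincos", "angle", "plane_normals"),
                        symmetry_correction = TRUE, chi_weights = NULL,
                        wrap_then_square = TRUE) {
  objective <- match.arg(objective)
  if (!is.null(chi_weights)) {
    stopifnot(length(chi_weights) == 4, all(is.finite(chi_weights)),
              all(chi_weights > 0))
  }
  structure(list(objective = objective,
                 symmetry_correction = symmetry_correction,
                 chi_weights = chi_weights,
                 wrap_then_square = wrap_then_square),
            class = "loss_config")
}

# Effective targets after the symmetry correction: for each symmetric chi,
# pick whichever of {chi, chi + 180} (or {n, -n}) has the smaller per-angle
# contribution against the current prediction.
effective_targets <- function(out, chi, mask, residue_type, loss_cfg) {
  n <- if (length(dim(chi)) == 3) dim(chi)[1] else nrow(rbind(chi))
  flip <- matrix(FALSE, n, 4)
  if (loss_cfg$symmetry_correction) {
    sym <- symmetry_table()$pi_symmetric_chi
    for (j in seq_len(nrow(sym))) {
      flip[residue_type == sym$residue_type[j], sym$chi_index[j]] <- TRUE
    }
  }
  if (loss_cfg$objective == "sincos") {
    rad <- chi * pi / 180
    s <- sin(rad); cs <- cos(rad)
    ps <- out[, c(1, 3, 5, 7), drop = FALSE]
    pc <- out[, c(2, 4, 6, 8), drop = FALSE]
    base <- (ps - s)^2 + (pc - cs)^2
    alt <- (ps + s)^2 + (pc + cs)^2   # chi + 180 flips both sin and cos
    use_alt <- flip & (alt < base)
    list(sin = ifelse(use_alt, -s, s), cos = ifelse(use_alt, -cs, cs))
  } else if (loss_cfg$objective == "angle") {
    t0 <- (chi + 180) / 180
    d <- abs((out - t0) %% 2); e0 <- pmin(d, 2 - d)
    t1 <- t0 + 1
    d1 <- abs((out - t1) %% 2); e1 <- pmin(d1, 2 - d1)
    use_alt <- flip & (e1 < e0)
    list(t = ifelse(use_alt, t1, t0))
  } else {
    # out: B x 4 x 3 raw normals; chi here is the true normal array
    tn <- chi
    nrm <- sqrt(out[, , 1]^2 + out[, , 2]^2 + out[, , 3]^2)
    dot <- (out[, , 1] * tn[, , 1] + out[, , 2] * tn[, , 2] +
            out[, , 3] * tn[, , 3]) / pmax(rbind(nrm), 1e-12)
    use_alt <- flip & (rbind(dot) < 0)
    sgn <- ifelse(use_alt, -1, 1)
    list(n = tn * array(sgn, dim(tn)))
  }
}

# Loss value and gradient with respect to the network output for one batch.
loss_and_grad <- function(out, batch, loss_cfg) {
  mask <- batch$mask
  n <- nrow(mask)
  w <- if (is.null(loss_cfg$chi_weights)) rep(1, 4) else loss_cfg$chi_weights
  wm <- mask * matrix(w, n, 4, byrow = TRUE)
  denom <- pmax(1e-12, rowSums(wm))
  if (loss_cfg$objective == "sincos") {
    tg <- effective_targets(out, batch$chi, mask, batch$residue_type, loss_cfg)
    ps <- out[, c(1, 3, 5, 7), drop = FALSE]
    pc <- out[, c(2, 4, 6, 8), drop = FALSE]
    pa <- (ps - tg$sin)^2 + (pc - tg$cos)^2
    loss <- mean(rowSums(pa * wm) / (2 * denom))
    gs <- 2 * (ps - tg$sin) * wm / (2 * denom) / n
    gc <- 2 * (pc - tg$cos) * wm / (2 * denom) / n
    g <- matrix(0, n, 8)
    g[, c(1, 3, 5, 7)] <- gs
    g[, c(2, 4, 6, 8)] <- gc
    list(loss = loss, grad = g)
  } else if (loss_cfg$objective == "angle") {
    tg <- effective_targets(out, batch$chi, mask, batch$residue_type, loss_cfg)
    delta <- (out - tg$t) %% 2
    d <- abs(delta)
    e <- pmin(d, 2 - d)
    if (loss_cfg$wrap_then_square) {
      pa <- e^2
      # d(e^2)/d(out): 2 e with sign + for delta < 1, - beyond
      de <- 2 * e * ifelse(delta < 1, 1, -1)
    } else {
      pa <- pmin(d^2, 2 - d^2)
      de <- ifelse(d^2 < 2 - d^2, 2 * d, -2 * d) * ifelse(delta < 1, 1, -1)
    }
    loss <- mean(rowSums(pa * wm) / denom)
    g <- de * wm / denom / n
    list(loss = loss, grad = g)
  } else {
    tg <- effective_targets(out, batch$normals, mask, batch$residue_type,
                            loss_cfg)
    tn <- tg$n
    nrm <- pmax(sqrt(out[, , 1]^2 + out[, , 2]^2 + out[, , 3]^2), 1e-12)
    dot <- out[, , 1] * tn[, , 1] + out[, , 2] * tn[, , 2] +
           out[, , 3] * tn[, , 3]
    cosang <- dot / nrm
    pa <- 1 - cosang
    loss <- mean(rowSums(rbind(pa) * wm) / denom)
    g <- array(0, dim(out))
    for (ax in 1:3) {
      # d(1 - <v/|v|, t>)/dv_ax = -(t_ax - v_ax <v,t>/|v|^2) / |v|
      g[, , ax] <- -(tn[, , ax] - out[, , ax] * dot / nrm^2) / nrm *
        wm / denom / n
    }
    list(loss = loss, grad = g)
  }
}

# Adam update in place on flat parameter lists.
adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gnm * 0
      state$v[[nm]] <- gnm * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

subset_batch <- function(dataset, idx) {
  list(
    X = lapply(dataset$X, function(a) a[idx, , , drop = FALSE]),
    chi = dataset$chi[idx, , drop = FALSE],
    mask = dataset$mask[idx, , drop = FALSE],
    residue_type = dataset$residue_type[idx],
    type_ids = dataset$type_ids[idx],
    normals = if (!is.null(dataset$normals))
      dataset$normals[idx, , , drop = FALSE] else NULL
  )
}

batch_loss <- function(params, batch, net_cfg, loss_cfg, train = FALSE) {
  fw <- net_forward(params, batch$X, batch$type_ids, net_cfg, train = train)
  if (loss_cfg$objective == "plane_normals") {
    # degree-1 features are in (y, z, x) component order; the loss and its
    # targets work in Cartesian order
    lg <- loss_and_grad(feat_to_xyz(fw$out), batch, loss_cfg)
    lg$grad <- xyz_to_feat(lg$grad)
  } else {
    lg <- loss_and_grad(fw$out, batch, loss_cfg)
  }
  list(loss = lg$loss, grad_out = lg$grad, cache = fw$cache)
}

#' Train a chi-angle regression network
#'
#' Minimizes the chosen objective with Adam. The dataset is split into
#' training and validation at the structure level (residues of one
#' structure never straddle the split); after each epoch the validation
#' loss is computed and the parameters with the lowest validation loss are
#' returned.
#'
#' @param dataset an encoded dataset from [build_dataset()] (fields `X`,
#'   `chi`, `mask`, `residue_type`, `type_ids`, `struct_id`, optionally
#'   `normals`, plus `encoding_config` and `type_levels` attributes).
#' @param net_cfg a `network_config`.
#' @param loss_cfg a `loss_config`.
#' @param epochs number of epochs (default 10).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (the peak rate under the cosine schedule).
#' @param lr_schedule "cosine" anneals the rate to lr/20 over the epochs;
#'   "constant" keeps it fixed.
#' @param val_frac fraction of structures held out for validation.
#' @param seed RNG seed controlling the split, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a model: list with `params` (best epoch), `config`,
#'   `encoding_config`, `type_levels`, `loss_cfg`, and `history`
#'   (per-epoch train/validation losses).
#' @export
train_network <- function(dataset, net_cfg, loss_cfg, epochs = 10,
                          batch_size = 32, lr = 1e-3,
                          lr_schedule = c("cosine", "constant"),
                          val_frac = 0.2, seed = 1, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  set.seed(seed)
  n <- nrow(dataset$chi)
  sid <- dataset$struct_id
  us <- unique(sid)
  nval <- max(1, round(length(us) * val_frac))
  val_structs <- sample(us, nval)
  val_idx <- which(sid %in% val_structs)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) stop("train_network: empty training split")
  params <- net_init(net_cfg, in_mults = dataset$in_mults)
  state <- list(t = 0, m = list(), v = list())
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params)
  val_batch <- subset_batch(dataset, val_idx)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "cosine") {
      lr / 20 + 0.5 * (lr - lr / 20) * (1 + cos(pi * (ep - 1) / epochs))
    } else lr
    ord <- sample(train_idx)
    tl <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(length(ord), start + batch_size - 1)]
      batch <- subset_batch(dataset, idx)
      bl <- batch_loss(params, batch, net_cfg, loss_cfg, train = TRUE)
      if (!is.finite(bl$loss)) {
        stop("train_network: non-finite training loss at epoch ", ep)
      }
      grads <- net_backward(params, bl$cache, bl$grad_out, net_cfg)
      upd <- adam_step(state, params, grads, lr_ep)
      state <- upd$state
      params <- upd$params
      tl <- tl + bl$loss; nb <- nb + 1
    }
    vl <- if (length(val_idx) > 0) {
      batch_loss(params, val_batch, net_cfg, loss_cfg, train = FALSE)$loss
    } else tl / nb
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                         val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", ep, tl / nb, vl,
                      if (vl <= best$loss) " *" else ""))
    }
  }
  list(params = best$params, config = net_cfg,
       encoding_config = dataset$encoding_config,
       type_levels = dataset$type_levels, loss_cfg = loss_cfg,
       history = history, best_epoch = best$epoch, seed = seed)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain-text serialization (base R `dput`-style via
#' serialized RDS) of the parameters plus the full network and encoding
#' configurations; loading refuses a file whose configurations are
#' inconsistent with each other.
#'
#' @param model model list from [train_network()].
#' @param path file path (.rds).
#' @return `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!all(c("params", "config", "encoding_config") %in% names(model))) {
    stop("load_model: not a chipacker checkpoint")
  }
  if (model$config$l_max > model$encoding_config$l_max) {
    stop("load_model: network l_max exceeds the encoding l_max")
  }
  model
}
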