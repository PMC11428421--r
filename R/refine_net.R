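# The coarse-registration refinement network: a dual-branch, global-feature
# point-cloud regressor that predicts the corrective rigid transform
# (unit quaternion + translation) aligning coarse-registered landmarks with
# the true patient geometry, applied iteratively with the per-iteration
# transforms composed right-to-left into a cumulative correction.
#
# Inputs per case: X, the coarse-registered picked landmarks (source), and
# Y, the candidate-region reference cloud — the surface patches around the
# reference landmarks. Y carries the local surface geometry (normal tilt,
# curvature) that makes the correction identifiable: undoing a coarse
# misregistration is exactly re-docking the pick constellation onto those
# patches.
#
# Architecture (per branch; one rotational, one translational branch, both
# seeing both clouds through a shared-weight encoder):
#   * point-wise MLP encoder (3, 64, 128, 256, 512) with batch norm + ReLU,
#     channel-wise max-pooling after every stage (multi-level global
#     features, the skip path), and a point-wise feature interaction (PFI)
#     module every two stages that mixes each cloud's per-point features
#     with the other cloud's pooled feature;
#   * the rotational branch sees per-sample centroid-subtracted coordinates
#     (translation-invariant), the translational branch raw coordinates plus
#     the centroid-difference vector;
#   * pooled multi-level features of both clouds are projected and refined
#     by the fusion stack (2048, 2048, 1024); the two branches' fused
#     features (plus the centroid difference) feed a regression trunk
#     (2048, 1024, 512, 256) with a normalized-quaternion head and a
#     3-vector translation head. `width_scale` shrinks every hidden width
#     proportionally without changing topology.

#' Refinement-network architecture configuration
#'
#' @param encoder_dims Per-stage encoder channel widths (input 3 first).
#' @param fusion_dims Fusion-stack hidden widths.
#' @param regression_dims Regression-trunk block widths.
#' @param pfi_every Insert a point-wise feature interaction module every
#'   this many encoder stages (default 2).
#' @param n_iterations Iterative-refinement steps (default 3).
#' @param loss_weights Named weights `c(rot, trans, chamfer)` for the
#'   composite loss. Rotation error is measured in degrees and translation
#'   in mm, which puts the two on comparable scales (1 degree of facial
#'   rotation displaces points by roughly 1-2 mm); the Chamfer term gets a
#'   smaller default weight because its patch-coverage half penalizes even
#'   a perfect docking (six picks cannot cover whole patches) and so
#'   carries a bias near the optimum.
#' @param width_scale Fraction applied to every hidden width (1 = full size;
#'   smaller values give CPU-friendly models of identical topology).
#' @return A `refine_net_config` list.
#' @export
refine_net_config <- function(encoder_dims = c(3, 64, 128, 256, 512),
                              fusion_dims = c(2048, 2048, 1024),
                              regression_dims = c(2048, 1024, 512, 256),
                              pfi_every = 2,
                              n_iterations = 3,
                              loss_weights = c(rot = 1, trans = 1,
                                               chamfer = 0.2),
                              width_scale = 1) {
  if (any(c(encoder_dims, fusion_dims, regression_dims) <= 0)) {
    stop("config error: all layer dimensions must be positive")
  }
  if (n_iterations < 1) stop("config error: n_iterations must be >= 1")
  if (any(loss_weights < 0) || all(loss_weights == 0)) {
    stop("config error: loss weights must be >= 0 and not all zero")
  }
  sc <- function(d) pmax(4L, as.integer(round(d * width_scale)))
  structure(list(
    encoder_dims = c(3L, sc(encoder_dims[-1])),
    fusion_dims = sc(fusion_dims),
    regression_dims = sc(regression_dims),
    pfi_every = as.integer(pfi_every),
    n_iterations = as.integer(n_iterations),
    loss_weights = loss_weights,
    width_scale = width_scale
  ), class = "refine_net_config")
}

#' Training schedule configuration
#'
#' Adam with weight decay and a step learning-rate schedule (decay factor
#' `lr_gamma` every `lr_step` epochs).
#'
#' @param learning_rate Initial learning rate (default 1e-3).
#' @param weight_decay L2 penalty added to weight-matrix gradients
#'   (default 1e-4).
#' @param epochs Training epochs (default 500).
#' @param batch_size Mini-batch size (default 50).
#' @param lr_step Epoch interval between learning-rate decays (default 100,
#'   i.e. one decay per fifth of the default epoch budget; shorter runs
#'   scale it proportionally).
#' @param lr_gamma Multiplicative decay factor (default 0.1).
#' @param bn_freeze_frac Fraction of the epoch budget after which the
#'   batch-norm statistics are calibrated (cumulative average over the
#'   training split) and frozen; the remaining epochs train under the
#'   frozen statistics, so inference sees exactly the normalization the
#'   final weights were fitted to (default 0.5).
#' @param seed RNG seed for initialization and shuffling.
#' @return A `refine_net_train_config` list.
#' @export
refine_net_train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                                    epochs = 500, batch_size = 50,
                                    lr_step = 100, lr_gamma = 0.1,
                                    bn_freeze_frac = 0.5, seed = 1) {
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 1, batch_size >= 1,
            lr_step >= 1, lr_gamma > 0, lr_gamma < 1,
            bn_freeze_frac > 0, bn_freeze_frac <= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 bn_freeze_frac = bn_freeze_frac,
                 seed = as.integer(seed)),
            class = "refine_net_train_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' @param train_config A [refine_net_train_config()].
#' @param epoch 1-based epoch number.
#' @return The learning rate in effect during `epoch`.
#' @export
lr_at_epoch <- function(train_config, epoch) {
  train_config$learning_rate *
    train_config$lr_gamma^floor((epoch - 1) / train_config$lr_step)
}

# --- parameter initialization --------------------------------------------

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

new_bn_state <- function(k) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, k)
  st$var <- rep(1, k)
  st$momentum <- 0.1
  st
}

# One block's parameters, prefixed names in a flat list. Blocks followed by
# batch norm carry no bias (the mean subtraction makes it inert).
init_block <- function(params, name, nin, nout, bn = TRUE) {
  params[[paste0(name, ".W")]] <- he_init(nin, nout)
  if (bn) {
    params[[paste0(name, ".gamma")]] <- matrix(1, 1, nout)
    params[[paste0(name, ".beta")]] <- matrix(0, 1, nout)
  } else {
    params[[paste0(name, ".b")]] <- matrix(0, 1, nout)
  }
  params
}

#' Initialize an untrained refinement network
#'
#' @param config A [refine_net_config()].
#' @param n_landmarks Points in the source cloud X (default 6).
#' @param n_region_points Points in the reference region cloud Y (default
#'   48 = 6 landmarks x 8 points).
#' @param seed RNG seed for weight initialization.
#' @return A `refine_net` model object (parameters, batch-norm state,
#'   config).
#' @export
refine_net_init <- function(config = refine_net_config(), n_landmarks = 6,
                            n_region_points = 48, seed = 1) {
  enc <- config$encoder_dims
  n_stage <- length(enc) - 1
  pfi_at <- which(seq_len(n_stage) %% config$pfi_every == 0)
  pooled_dim <- sum(enc[-1])

  params <- list()
  bn_names <- character(0)
  with_seed(derive_seed(seed, "init"), {
    for (br in c("rot", "trans")) {
      for (l in seq_len(n_stage)) {
        nm <- sprintf("%s.enc%d", br, l)
        params <- init_block(params, nm, enc[l], enc[l + 1])
        bn_names <- c(bn_names, nm)
      }
      for (l in pfi_at) {
        params <- init_block(params, sprintf("%s.pfi%d", br, l),
                             2 * enc[l + 1], enc[l + 1], bn = FALSE)
      }
      dims <- c(2 * pooled_dim, config$fusion_dims)
      for (j in seq_along(config$fusion_dims)) {
        nm <- sprintf("%s.fus%d", br, j)
        params <- init_block(params, nm, dims[j], dims[j + 1])
        bn_names <- c(bn_names, nm)
      }
    }
    trunk_in <- 2 * utils::tail(config$fusion_dims, 1) + 3
    dims <- c(trunk_in, config$regression_dims)
    for (j in seq_along(config$regression_dims)) {
      nm <- sprintf("trunk%d", j)
      params <- init_block(params, nm, dims[j], dims[j + 1])
      bn_names <- c(bn_names, nm)
    }
    last <- utils::tail(config$regression_dims, 1)
    params[["head_q.W"]] <- he_init(last, 4) * 0.01
    params[["head_q.b"]] <- matrix(0, 1, 4)
    params[["head_t.W"]] <- he_init(last, 3) * 0.01
    params[["head_t.b"]] <- matrix(0, 1, 3)
  })

  # Shared weights are applied in several statistical contexts: encoder
  # blocks see the source cloud (once per refinement iteration, whose input
  # distribution changes as alignment improves) and the reference cloud;
  # fusion and trunk blocks run once per iteration. Each context keeps its
  # own batch-norm statistics so frozen-statistics inference reproduces the
  # batch-statistics behaviour.
  n_it <- config$n_iterations
  enc_names <- grep("\\.enc", bn_names, value = TRUE)
  other <- setdiff(bn_names, enc_names)
  state_names <- c(
    paste0(rep(enc_names, each = n_it), ".src.it", seq_len(n_it)),
    paste0(enc_names, ".ref"),
    paste0(rep(other, each = n_it), ".it", seq_len(n_it))
  )
  bn_state <- lapply(stats::setNames(state_names, state_names), function(nm) {
    base <- sub("\\.(src\\.it[0-9]+|ref|it[0-9]+)$", "", nm)
    new_bn_state(ncol(params[[paste0(base, ".W")]]))
  })

  structure(list(params = params, bn_state = bn_state, config = config,
                 n_landmarks = as.integer(n_landmarks),
                 n_region_points = as.integer(n_region_points),
                 pfi_at = pfi_at),
            class = "refine_net")
}

#' @export
print.refine_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1))
  cat(sprintf("<refine_net> width_scale %.3g, %d iterations, %s parameters\n",
              x$config$width_scale, x$config$n_iterations,
              format(np, big.mark = ",")))
  invisible(x)
}

# --- forward pass ---------------------------------------------------------

# Leaf nodes for every parameter (one tape per batch).
param_nodes <- function(tape, params, req = TRUE) {
  lapply(params, function(p) ad_leaf(tape, p, req = req))
}

block_forward <- function(tape, x, pn, name, bn_state, mode, role = NULL) {
  key <- if (is.null(role)) name else paste0(name, ".", role)
  ad_dense_bn_relu(tape, x, pn[[paste0(name, ".W")]],
                   pn[[paste0(name, ".gamma")]], pn[[paste0(name, ".beta")]],
                   bn_state[[key]], mode)
}

# Encode the reference (candidate-region) clouds of one branch: plain
# point-wise MLP stages with per-stage max-pooled features — pooled both
# globally (for the fusion stack) and per landmark region (for the PFI
# exchange, which pairs each pick with its own region). The reference
# encoding is independent of the source cloud, so it is computed once per
# batch over the distinct clouds and shared across records and refinement
# iterations.
encode_ref_branch <- function(tape, model, pn, branch, Yn, mY, k_region,
                              mode) {
  n_stage <- length(model$config$encoder_dims) - 1
  h <- Yn
  pools <- vector("list", n_stage)
  region_pools <- vector("list", n_stage)
  for (l in seq_len(n_stage)) {
    h <- block_forward(tape, h, pn, sprintf("%s.enc%d", branch, l),
                       model$bn_state, mode, role = "ref")
    pools[[l]] <- ad_pool_max(tape, h, mY)
    if (l %in% model$pfi_at) {
      region_pools[[l]] <- ad_pool_max(tape, h, k_region)
    }
  }
  list(global = pools, region = region_pools)
}

# Encode the source cloud of one branch with point-wise feature
# interaction: at every `pfi_every`-th stage each pick's features are
# concatenated with the pooled feature of *its own* candidate region
# (landmark correspondence between picks and regions is known by
# construction) and mixed back to the stage width.
encode_src_branch <- function(tape, model, pn, branch, Xn, mX, ref_region,
                              src_idx, mode, it) {
  n_stage <- length(model$config$encoder_dims) - 1
  h <- Xn
  pools <- vector("list", n_stage)
  for (l in seq_len(n_stage)) {
    h <- block_forward(tape, h, pn, sprintf("%s.enc%d", branch, l),
                       model$bn_state, mode, role = paste0("src.it", it))
    if (l %in% model$pfi_at) {
      pnm <- sprintf("%s.pfi%d", branch, l)
      h <- ad_linear_bias_relu(
        tape,
        ad_concat_cols(tape, list(h, ad_gather_rows(tape, ref_region[[l]],
                                                    src_idx))),
        pn[[paste0(pnm, ".W")]], pn[[paste0(pnm, ".b")]])
    }
    pools[[l]] <- ad_pool_max(tape, h, mX)
  }
  pools
}

fusion_forward <- function(tape, model, pn, branch, feat, mode, it) {
  h <- feat
  for (j in seq_along(model$config$fusion_dims)) {
    h <- block_forward(tape, h, pn, sprintf("%s.fus%d", branch, j),
                       model$bn_state, mode, role = paste0("it", it))
  }
  h
}

# Reference-side context, computed once per batch: per-stage pooled
# features and centroids of the distinct reference clouds, gathered to one
# row per sample.
ref_context <- function(tape, model, pn, Yu, mY, y_of, mode) {
  mX <- model$n_landmarks
  k_region <- mY %/% mX
  G <- length(y_of)
  Yn <- ad_const(tape, Yu)
  cy_u <- ad_pool_mean(tape, Yn, mY)
  Yc <- ad_sub(tape, Yn, ad_repeat_rows(tape, cy_u, mY))
  rot <- encode_ref_branch(tape, model, pn, "rot", Yc, mY, k_region, mode)
  tra <- encode_ref_branch(tape, model, pn, "trans", Yn, mY, k_region, mode)
  gather <- function(ps) lapply(ps, function(p) {
    if (is.null(p)) NULL else ad_gather_rows(tape, p, y_of)
  })
  # source row (sample g, landmark i) pairs with region row i of g's cloud
  src_idx <- rep((y_of - 1L) * mX, each = mX) + rep(seq_len(mX), G)
  list(rot = gather(rot$global), trans = gather(tra$global),
       rot_region = rot$region, trans_region = tra$region,
       src_idx = src_idx,
       cy = ad_gather_rows(tape, cy_u, y_of))
}

# Single-step prediction: q (G x 4, unit rows), t (G x 3), both nodes.
forward_step <- function(tape, model, pn, Xn, refs, mX, mode, it) {
  cx <- ad_pool_mean(tape, Xn, mX)
  # rotational branch: translation-invariant (centroid-subtracted) inputs
  Xc <- ad_sub(tape, Xn, ad_repeat_rows(tape, cx, mX))
  pool_rot <- encode_src_branch(tape, model, pn, "rot", Xc, mX,
                                refs$rot_region, refs$src_idx, mode, it)
  pool_tra <- encode_src_branch(tape, model, pn, "trans", Xn, mX,
                                refs$trans_region, refs$src_idx, mode, it)
  fr <- fusion_forward(tape, model, pn, "rot",
                       ad_concat_cols(tape, c(pool_rot, refs$rot)), mode, it)
  ft <- fusion_forward(tape, model, pn, "trans",
                       ad_concat_cols(tape, c(pool_tra, refs$trans)),
                       mode, it)
  cdiff <- ad_sub(tape, refs$cy, cx)
  h <- ad_concat_cols(tape, list(fr, ft, cdiff))
  for (j in seq_along(model$config$regression_dims)) {
    h <- block_forward(tape, h, pn, sprintf("trunk%d", j), model$bn_state,
                       mode, role = paste0("it", it))
  }
  q_raw <- ad_linear_fused(tape, h, pn[["head_q.W"]], pn[["head_q.b"]])
  # canonical offset toward the identity quaternion: the cold-started
  # network predicts (1,0,0,0) and learns residual rotations around it
  q_off <- ad_add_rowvec(tape, q_raw,
                         ad_const(tape, matrix(c(1, 0, 0, 0), 1)))
  q <- ad_normalize_rows(tape, q_off)
  t <- ad_linear_fused(tape, h, pn[["head_t.W"]], pn[["head_t.b"]])
  list(q = q, t = t)
}

# Full iterative forward pass on one batch.
# X: (G*mX) x 3; Yu: (U*mY) x 3 distinct reference clouds; y_of: length-G
# map from sample to reference cloud (standardized frame). Returns nodes:
# cumulative q (G x 4), t (G x 3), per-iteration predictions, the source
# cloud under the cumulative transform.
forward_iterative <- function(tape, model, pn, X, Yu, y_of = NULL, mode = "eval",
                              n_iterations = model$config$n_iterations) {
  mX <- model$n_landmarks
  mY <- model$n_region_points
  G <- nrow(X) %/% mX
  if (is.null(y_of)) y_of <- seq_len(G)
  refs <- ref_context(tape, model, pn, Yu, mY, y_of, mode)
  X0 <- ad_const(tape, X)
  Xc <- X0
  q_cum <- NULL
  t_cum <- NULL
  iters <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    st <- forward_step(tape, model, pn, Xc, refs, mX, mode,
                       min(it, model$config$n_iterations))
    if (it == 1) {
      q_cum <- st$q
      t_cum <- st$t
    } else {
      # T_cum <- T_it o T_cum  (right-to-left composition)
      q_cum <- ad_normalize_rows(tape,
                                 ad_quat_multiply_fused(tape, st$q, q_cum))
      t_cum <- ad_add(tape, ad_quat_rotate_fused(tape, st$q, t_cum, 1), st$t)
    }
    Xc <- ad_add(tape, ad_quat_rotate_fused(tape, q_cum, X0, mX),
                 ad_repeat_rows(tape, t_cum, mX))
    iters[[it]] <- list(q = q_cum, t = t_cum, X = Xc)
  }
  list(q = q_cum, t = t_cum, X = Xc, iterations = iters, y_of = y_of)
}

# Composite loss accumulated across iterations (rotation MSE on Euler
# degrees, translation MSE in mm, Chamfer distance vs the region cloud in
# mm^2). scale_g: G x 1; scale_rx: per-row scales for the X cloud;
# scale_ry: per-row scales for the distinct reference clouds. Returns list
# of scalar nodes.
batch_loss <- function(tape, model, fw, Yu, euler_gt, t_gt, scale_g, scale_rx,
                       scale_ry) {
  w <- model$config$loss_weights
  mX <- model$n_landmarks
  mY <- model$n_region_points
  eg <- ad_const(tape, euler_gt)
  tg <- ad_const(tape, t_gt)
  Ymm <- Yu * as.numeric(scale_ry)
  l_rot <- NULL; l_tra <- NULL; l_cd <- NULL
  add <- function(a, b) if (is.null(a)) b else ad_add(tape, a, b)
  for (it in fw$iterations) {
    eul <- ad_quat_to_euler_fused(tape, it$q)
    de <- ad_sub(tape, eul, eg)
    l_rot <- add(l_rot, ad_mean(tape, ad_mul(tape, de, de)))
    dt <- ad_scale_rows(tape, ad_sub(tape, it$t, tg), ad_const(tape, scale_g))
    l_tra <- add(l_tra, ad_mean(tape, ad_mul(tape, dt, dt)))
    Xmm <- ad_scale_rows(tape, it$X, ad_const(tape, scale_rx))
    l_cd <- add(l_cd, ad_mean(tape, ad_chamfer(tape, Xmm, Ymm, mX, mY,
                                               fw$y_of)))
  }
  total <- ad_add(tape, ad_add(tape, ad_scalar_mul(tape, l_rot, w[["rot"]]),
                               ad_scalar_mul(tape, l_tra, w[["trans"]])),
                  ad_scalar_mul(tape, l_cd, w[["chamfer"]]))
  list(total = total, rot = l_rot, trans = l_tra, chamfer = l_cd)
}

# --- dataset staging ------------------------------------------------------

# Stack a record subset into dense arrays for batching. Region clouds stay
# one block per distinct phantom; `y_of` maps records to blocks.
stage_records <- function(dataset, split = NULL) {
  df <- dataset$records
  if (!is.null(split)) df <- df[df$split == split, ]
  if (nrow(df) == 0) stop("no records in split '", split, "'")
  m <- nrow(df$X[[1]])
  scales <- vapply(dataset$manifest$standardization, function(s) s$scale, 1)
  names(scales) <- sub("^phantom_", "", names(scales))
  rc <- dataset$manifest$region_clouds
  names(rc) <- sub("^phantom_", "", names(rc))
  my <- nrow(rc[[1]])
  key <- as.character(df$phantom)
  ukey <- unique(key)
  list(
    n = nrow(df), m = m, my = my,
    X = do.call(rbind, df$X),
    Yu = do.call(rbind, rc[ukey]),
    y_of = match(key, ukey),
    y_scale = as.numeric(scales[ukey]),
    q_gt = do.call(rbind, df$q_gt),
    t_gt = do.call(rbind, df$t_gt),
    euler_gt = t(vapply(df$q_gt, quat_to_euler, numeric(3))),
    scale = as.numeric(scales[key]),
    phantom = df$phantom, trial = df$trial
  )
}

rows_of <- function(idx, m) {
  as.integer(outer(seq_len(m), (idx - 1) * m, "+"))
}

# Subset a staged split to `idx` records, keeping only the reference-cloud
# blocks the subset touches.
stage_batch <- function(st, idx) {
  rx <- rows_of(idx, st$m)
  gsel <- st$y_of[idx]
  u <- sort(unique(gsel))
  ry <- rows_of(u, st$my)
  list(
    X = st$X[rx, , drop = FALSE],
    Yu = st$Yu[ry, , drop = FALSE],
    y_of = match(gsel, u),
    euler_gt = st$euler_gt[idx, , drop = FALSE],
    t_gt = st$t_gt[idx, , drop = FALSE],
    scale_g = matrix(st$scale[idx], ncol = 1),
    scale_rx = matrix(rep(st$scale[idx], each = st$m), ncol = 1),
    scale_ry = matrix(rep(st$y_scale[u], each = st$my), ncol = 1)
  )
}

# --- training -------------------------------------------------------------

#' Train the refinement network
#'
#' Adam with weight decay and a step learning-rate schedule; the composite
#' loss (Euler-angle MSE + translation MSE + Chamfer distance against the
#' candidate-region cloud) is summed across refinement iterations with
#' gradients flowing through all of them. The model with the best
#' validation loss is returned. Training is deterministic for a fixed seed
#' on one machine.
#'
#' @param dataset A [generate_dataset()] result (standardized records).
#' @param config Architecture config ([refine_net_config()]).
#' @param train_config Schedule config ([refine_net_train_config()]).
#' @param verbose Print per-epoch losses (default FALSE).
#' @return A `refine_net_fit`: the trained `model`, `curves` tibble (epoch,
#'   lr, train/validation losses and components), `best_epoch`, the dataset
#'   manifest, and held-out metrics computed on the test split.
#' @export
train_refine_net <- function(dataset, config = refine_net_config(),
                             train_config = refine_net_train_config(),
                             verbose = FALSE) {
  tr <- stage_records(dataset, "train")
  va <- stage_records(dataset, "validation")
  m <- tr$m
  model <- refine_net_init(config, n_landmarks = m, n_region_points = tr$my,
                           seed = train_config$seed)

  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  wd <- train_config$weight_decay
  is_weight <- grepl("\\.W$", names(model$params))

  # parameters are updated in place by .adam_step, so snapshots deep-copy
  deep_copy <- function(ps) lapply(ps, function(p) p + 0)
  curves <- vector("list", train_config$epochs)
  best_val <- Inf
  best <- list(params = deep_copy(model$params),
               bn = snapshot_bn(model$bn_state), epoch = 0L)

  freeze_epoch <- min(max(1L, ceiling(train_config$epochs *
                                        train_config$bn_freeze_frac)),
                      max(1L, train_config$epochs - 1L))
  for (epoch in seq_len(train_config$epochs)) {
    lr <- lr_at_epoch(train_config, epoch)
    if (epoch == freeze_epoch + 1L) calibrate_bn(model, tr,
                                                 train_config$batch_size)
    frozen <- epoch > freeze_epoch
    ord <- with_seed(derive_seed(train_config$seed, "shuffle", epoch),
                     sample.int(tr$n))
    batches <- split(ord, ceiling(seq_along(ord) / train_config$batch_size))
    ep_loss <- c(total = 0, rot = 0, trans = 0, chamfer = 0)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      b <- stage_batch(tr, idx)
      tape <- ad_tape()
      pn <- param_nodes(tape, model$params)
      fw <- forward_iterative(tape, model, pn, b$X, b$Yu, b$y_of,
                              mode = if (frozen) "eval" else "train")
      ls <- batch_loss(tape, model, fw, b$Yu, b$euler_gt, b$t_gt,
                       b$scale_g, b$scale_rx, b$scale_ry)
      if (!is.finite(ls$total$v)) {
        stop("divergence: non-finite training loss at epoch ", epoch)
      }
      ad_backward(tape, ls$total)
      step <- step + 1L
      nms <- names(model$params)
      for (j in seq_along(nms)) {
        g <- pn[[nms[j]]]$g
        if (is.null(g)) next
        .adam_step(model$params[[j]], adam_m[[j]], adam_v[[j]], g,
                   lr, beta1, beta2, eps, step,
                   if (is_weight[j]) wd else 0)
      }
      w <- length(idx) / tr$n
      ep_loss <- ep_loss + w * c(ls$total$v, ls$rot$v, ls$trans$v, ls$chamfer$v)
    }

    val <- evaluate_loss(model, va, mode = if (frozen) "eval" else "batch")
    curves[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss[["total"]], val_loss = val[["total"]],
      train_rot = ep_loss[["rot"]], train_trans = ep_loss[["trans"]],
      train_chamfer = ep_loss[["chamfer"]],
      val_rot = val[["rot"]], val_trans = val[["trans"]],
      val_chamfer = val[["chamfer"]]
    )
    # only frozen-statistics epochs are candidates for the returned model:
    # their validation loss is measured under the inference-time
    # normalization
    if (frozen && val[["total"]] < best_val) {
      best_val <- val[["total"]]
      best <- list(params = deep_copy(model$params),
                   bn = snapshot_bn(model$bn_state), epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.1e  train %.4f  val %.4f",
                      epoch, lr, ep_loss[["total"]], val[["total"]]))
    }
  }

  if (best$epoch == 0L) {
    # no frozen epoch improved on infinity (degenerate single-epoch runs):
    # ship the final weights
    best <- list(params = deep_copy(model$params),
                 epoch = train_config$epochs)
  }
  model$params <- best$params
  fit <- structure(list(model = model,
                        curves = dplyr::bind_rows(curves),
                        best_epoch = best$epoch,
                        train_config = train_config,
                        manifest = dataset$manifest),
                   class = "refine_net_fit")
  fit$test_metrics <- tryCatch(
    component_metrics(evaluate_components(fit, dataset, "test")),
    error = function(e) NULL)
  fit
}

snapshot_bn <- function(bn_state) {
  lapply(bn_state, function(st) list(mean = st$mean, var = st$var))
}
restore_bn <- function(bn_state, snap) {
  for (nm in names(snap)) {
    bn_state[[nm]]$mean <- snap[[nm]]$mean
    bn_state[[nm]]$var <- snap[[nm]]$var
  }
  invisible(NULL)
}

# Loss over a staged split without gradients. mode "batch" evaluates with
# per-batch normalization statistics (used for validation during training,
# where the running statistics are not yet calibrated); mode "eval" uses
# the frozen running statistics.
evaluate_loss <- function(model, staged, batch_size = 200, mode = "eval") {
  total <- c(total = 0, rot = 0, trans = 0, chamfer = 0)
  idx_all <- seq_len(staged$n)
  batches <- split(idx_all, ceiling(idx_all / batch_size))
  for (idx in batches) {
    b <- stage_batch(staged, idx)
    tape <- ad_tape()
    pn <- param_nodes(tape, model$params, req = FALSE)
    fw <- forward_iterative(tape, model, pn, b$X, b$Yu, b$y_of, mode = mode)
    ls <- batch_loss(tape, model, fw, b$Yu, b$euler_gt, b$t_gt,
                     b$scale_g, b$scale_rx, b$scale_ry)
    w <- length(idx) / staged$n
    total <- total + w * c(ls$total$v, ls$rot$v, ls$trans$v, ls$chamfer$v)
  }
  total
}

# Recalibrate the batch-norm running statistics of a trained model: one
# pass over the training split in training-statistics mode, with the
# momentum schedule set to exact cumulative averaging (momentum 1/k at the
# k-th batch). Deep stacks drift badly under exponentially-averaged
# statistics gathered while the weights were still moving; calibrating
# against the final weights makes frozen-statistics inference agree with
# batch-statistics behaviour.
calibrate_bn <- function(model, staged, batch_size = 50) {
  for (st in model$bn_state) {
    st$mean <- st$mean * 0
    st$var <- st$var * 0
  }
  idx_all <- seq_len(staged$n)
  batches <- split(idx_all, ceiling(idx_all / batch_size))
  for (k in seq_along(batches)) {
    for (st in model$bn_state) st$momentum <- 1 / k
    b <- stage_batch(staged, batches[[k]])
    tape <- ad_tape()
    pn <- param_nodes(tape, model$params, req = FALSE)
    forward_iterative(tape, model, pn, b$X, b$Yu, b$y_of, mode = "train")
  }
  for (st in model$bn_state) st$momentum <- 0.1
  invisible(model)
}

# --- inference ------------------------------------------------------------

#' Predict refinement transforms for a batch of standardized inputs
#'
#' Low-level inference: runs the iterative forward pass in eval mode
#' (frozen batch-norm statistics, deterministic, order-invariant in the
#' input points).
#'
#' @param model A `refine_net` or `refine_net_fit`.
#' @param X (n*mX) x 3 matrix of coarse-registered landmark coordinates
#'   (standardized frame), samples stacked in consecutive mX-row groups.
#' @param Y (U*mY) x 3 matrix of distinct candidate-region clouds.
#' @param y_of Optional length-n map from sample to reference cloud block
#'   (default: one block per sample).
#' @param n_iterations Override the config's iteration count (optional).
#' @return A list: `q` (n x 4 unit quaternions), `t` (n x 3 standardized
#'   translations), and per-iteration transforms.
#' @export
refine_net_forward <- function(model, X, Y, y_of = NULL,
                               n_iterations = NULL) {
  if (inherits(model, "refine_net_fit")) model <- model$model
  stopifnot(nrow(X) %% model$n_landmarks == 0,
            nrow(Y) %% model$n_region_points == 0)
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params, req = FALSE)
  n_it <- if (is.null(n_iterations)) model$config$n_iterations else n_iterations
  fw <- forward_iterative(tape, model, pn, X, Y, y_of, mode = "eval",
                          n_iterations = n_it)
  list(q = fw$q$v, t = fw$t$v,
       iterations = lapply(fw$iterations, function(it) {
         list(q = it$q$v, t = it$t$v)
       }))
}

#' Predict the mm-space refinement transform for one case
#'
#' `X_coarse` and `Y_region` are expected in the image cloud's standardized
#' frame (as produced during mode); the predicted standardized-frame
#' transform is conjugated back to mm space through `standardization`.
#'
#' @param model A `refine_net_fit` (or raw `refine_net`).
#' @param X_coarse mX x 3 coarse-registered landmarks, standardized frame.
#' @param Y_region mY x 3 candidate-region cloud, standardized frame.
#' @param standardization The `standardization_info` of the image cloud.
#' @return A list: `transform_mm` (`rigid_transform` in mm space, T_REF),
#'   `transform_std` (standardized frame).
#' @export
predict_refinement <- function(model, X_coarse, Y_region, standardization) {
  if (standardization$scale <= 0) stop("config error: scale must be > 0")
  out <- refine_net_forward(model, as_point_matrix(X_coarse),
                            as_point_matrix(Y_region))
  t_std <- rigid_transform(out$q[1, ], out$t[1, ])
  list(transform_mm = destandardize_transform(standardization, t_std),
       transform_std = t_std)
}

# Per-record predicted vs ground-truth components on a split.
evaluate_components <- function(fit, dataset, split = "test") {
  model <- if (inherits(fit, "refine_net_fit")) fit$model else fit
  st <- stage_records(dataset, split)
  out <- refine_net_forward(model, st$X, st$Yu, st$y_of)
  pred_euler <- t(apply(out$q, 1, quat_to_euler))
  tibble::tibble(
    phantom = st$phantom, trial = st$trial,
    yaw_pred = pred_euler[, 1], pitch_pred = pred_euler[, 2],
    roll_pred = pred_euler[, 3],
    yaw_gt = st$euler_gt[, 1], pitch_gt = st$euler_gt[, 2],
    roll_gt = st$euler_gt[, 3],
    tx_pred_mm = out$t[, 1] * st$scale, ty_pred_mm = out$t[, 2] * st$scale,
    tz_pred_mm = out$t[, 3] * st$scale,
    tx_gt_mm = st$t_gt[, 1] * st$scale, ty_gt_mm = st$t_gt[, 2] * st$scale,
    tz_gt_mm = st$t_gt[, 3] * st$scale
  )
}

# Per-axis RMSE and R^2 summaries from evaluate_components() output.
component_metrics <- function(comp) {
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  r2 <- function(pred, gt) {
    1 - sum((gt - pred)^2) / sum((gt - mean(gt))^2)
  }
  tibble::tibble(
    component = c("yaw", "pitch", "roll", "tx", "ty", "tz"),
    kind = rep(c("rotation_deg", "translation_mm"), each = 3),
    rmse = c(rmse(comp$yaw_pred, comp$yaw_gt),
             rmse(comp$pitch_pred, comp$pitch_gt),
             rmse(comp$roll_pred, comp$roll_gt),
             rmse(comp$tx_pred_mm, comp$tx_gt_mm),
             rmse(comp$ty_pred_mm, comp$ty_gt_mm),
             rmse(comp$tz_pred_mm, comp$tz_gt_mm)),
    r_squared = c(r2(comp$yaw_pred, comp$yaw_gt),
                  r2(comp$pitch_pred, comp$pitch_gt),
                  r2(comp$roll_pred, comp$roll_gt),
                  r2(comp$tx_pred_mm, comp$tx_gt_mm),
                  r2(comp$ty_pred_mm, comp$ty_gt_mm),
                  r2(comp$tz_pred_mm, comp$tz_gt_mm))
  )
}

#' Held-out accuracy of a trained refinement network
#'
#' Per-axis RMSE (rotation in degrees, translation de-standardized to mm)
#' and R-squared of predicted vs ground-truth components on a dataset
#' split.
#'
#' @param fit A `refine_net_fit`.
#' @param dataset The dataset to evaluate on.
#' @param split Which split (default `"test"`).
#' @return A tibble with columns component, kind, rmse, r_squared.
#' @export
refine_net_metrics <- function(fit, dataset, split = "test") {
  component_metrics(evaluate_components(fit, dataset, split))
}

#' @export
print.refine_net_fit <- function(x, ...) {
  cat(sprintf("<refine_net_fit> best epoch %d/%d, val loss %.4f\n",
              x$best_epoch, nrow(x$curves),
              min(x$curves$val_loss)))
  if (!is.null(x$test_metrics)) {
    rot <- x$test_metrics$rmse[x$test_metrics$kind == "rotation_deg"]
    tra <- x$test_metrics$rmse[x$test_metrics$kind == "translation_mm"]
    cat(sprintf("  test RMSE: rotation %.3f/%.3f/%.3f deg, translation %.3f/%.3f/%.3f mm\n",
                rot[1], rot[2], rot[3], tra[1], tra[2], tra[3]))
  }
  invisible(x)
}

#' Tidy / glance / plot methods for trained refinement networks
#'
#' `tidy()` returns the per-epoch training curves; `glance()` a one-row
#' summary; `autoplot()` the loss curves.
#'
#' @param x,object A `refine_net_fit`.
#' @param ... Unused.
#' @return Tibbles / a ggplot, respectively.
#' @export
tidy.refine_net_fit <- function(x, ...) x$curves

#' @rdname tidy.refine_net_fit
#' @export
glance.refine_net_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$curves),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$curves$val_loss),
    final_train_loss = utils::tail(x$curves$train_loss, 1),
    mean_rot_rmse_deg = if (!is.null(x$test_metrics)) {
      mean(x$test_metrics$rmse[x$test_metrics$kind == "rotation_deg"])
    } else NA_real_,
    mean_trans_rmse_mm = if (!is.null(x$test_metrics)) {
      mean(x$test_metrics$rmse[x$test_metrics$kind == "translation_mm"])
    } else NA_real_
  )
}

#' @rdname tidy.refine_net_fit
#' @export
autoplot.refine_net_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curves[c("epoch", "train_loss", "val_loss")],
                            cols = -"epoch", names_to = "series",
                            values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "composite loss (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained refinement network
#'
#' The checkpoint is a binary RDS plus a JSON sidecar carrying the
#' architecture config and a metric summary for audit.
#'
#' @param fit A `refine_net_fit`.
#' @param path Checkpoint path (`.rds`); the sidecar gets `.json` appended.
#' @return `save_refine_net`: `path` invisibly; `load_refine_net`: the fit.
#' @export
save_refine_net <- function(fit, path) {
  # environments (BN state) serialize fine via RDS
  saveRDS(fit, path)
  sidecar <- list(
    config = unclass(fit$model$config),
    best_epoch = fit$best_epoch,
    metrics = if (!is.null(fit$test_metrics)) {
      as.list(stats::setNames(fit$test_metrics$rmse, fit$test_metrics$component))
    }
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_refine_net
#' @export
load_refine_net <- function(path) readRDS(path)
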