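# The refinement network: configuration, structural invariants of the
# forward pass, the iterative composition, losses and the training path.

test_that("configurations validate and scale widths", {
  cfg <- refine_net_config(width_scale = 0.25)
  expect_equal(cfg$encoder_dims, c(3L, 16L, 32L, 64L, 128L))
  expect_equal(cfg$fusion_dims, c(512L, 512L, 256L))
  expect_equal(cfg$regression_dims, c(512L, 256L, 128L, 64L))
  expect_error(refine_net_config(n_iterations = 0), "config error")
  expect_error(refine_net_config(loss_weights = c(rot = -1, trans = 1,
                                                  chamfer = 1)),
               "config error")
  expect_error(refine_net_train_config(lr_gamma = 1.5), "gamma")
})

test_that("the step schedule decays tenfold every hundred epochs", {
  tc <- refine_net_train_config()
  expect_equal(lr_at_epoch(tc, 1), 1e-3)
  expect_equal(lr_at_epoch(tc, 100), 1e-3)
  expect_equal(lr_at_epoch(tc, 101), 1e-4)
  expect_equal(lr_at_epoch(tc, 200), 1e-4)
  expect_equal(lr_at_epoch(tc, 201), 1e-5)
  expect_equal(lr_at_epoch(tc, 301), 1e-6)
})

test_that("predictions are unit quaternions for arbitrary inputs", {
  model <- test_tiny_model()
  set.seed(61)
  X <- matrix(rnorm(4 * 6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(4 * 48 * 3, sd = 0.3), ncol = 3)
  out <- refine_net_forward(model, X, Y)
  expect_equal(rowSums(out$q^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(dim(out$t), c(4L, 3L))
})

test_that("zeroed output heads give the identity cold start", {
  model <- test_tiny_model()
  model$params[["head_q.W"]][] <- 0
  model$params[["head_q.b"]][] <- 0
  model$params[["head_t.W"]][] <- 0
  model$params[["head_t.b"]][] <- 0
  set.seed(62)
  X <- matrix(rnorm(6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  out <- refine_net_forward(model, X, Y)
  expect_equal(as.numeric(out$q), c(1, 0, 0, 0))
  expect_equal(as.numeric(out$t), c(0, 0, 0))
})

test_that("inference respects the landmark-set structure invariances", {
  # the inputs are ordered landmark sets: picks correspond to candidate
  # regions by position. The architecture must be invariant to reordering
  # points *within* a region, to relabelling landmarks jointly in both
  # clouds, and to structure-preserving duplication (max-pool symmetry) —
  # but it is allowed to use the pick-to-region correspondence itself.
  model <- test_tiny_model()
  set.seed(63)
  X <- matrix(rnorm(6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  base <- refine_net_forward(model, X, Y)

  # permute points inside each region block of Y
  idx <- as.integer(unlist(lapply(0:5, function(r) r * 8 + sample(8))))
  perm <- refine_net_forward(model, X, Y[idx, ])
  expect_equal(perm$q, base$q, tolerance = 1e-12)
  expect_equal(perm$t, base$t, tolerance = 1e-12)

  # relabel the landmarks jointly (same permutation of picks and regions)
  ord <- sample(6)
  yord <- as.integer(unlist(lapply(ord, function(r) (r - 1) * 8 + 1:8)))
  joint <- refine_net_forward(model, X[ord, ], Y[yord, ])
  expect_equal(joint$q, base$q, tolerance = 1e-12)
  expect_equal(joint$t, base$t, tolerance = 1e-12)

  # duplicate every landmark block (picks and regions consistently)
  model2 <- model
  model2$n_landmarks <- 12L
  model2$n_region_points <- 96L
  xdup <- rep(1:6, each = 2)
  ydup <- as.integer(unlist(lapply(xdup, function(r) (r - 1) * 8 + 1:8)))
  dup <- refine_net_forward(model2, X[xdup, ], Y[ydup, ])
  expect_equal(dup$q, base$q, tolerance = 1e-12)
  expect_equal(dup$t, base$t, tolerance = 1e-12)
})

test_that("distinct inputs give distinct predictions (no feature collapse)", {
  model <- test_tiny_model()
  set.seed(64)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  preds <- vapply(1:20, function(i) {
    X <- matrix(rnorm(18, sd = 0.3), ncol = 3)
    refine_net_forward(model, X, Y)$t[1, 1]
  }, numeric(1))
  expect_equal(anyDuplicated(round(preds, 12)), 0L)
})

test_that("batched and one-at-a-time inference agree in eval mode", {
  model <- test_tiny_model()
  set.seed(65)
  B <- 5
  X <- matrix(rnorm(B * 6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(B * 48 * 3, sd = 0.3), ncol = 3)
  batch <- refine_net_forward(model, X, Y)
  for (i in seq_len(B)) {
    one <- refine_net_forward(model, X[((i - 1) * 6 + 1):(i * 6), ],
                              Y[((i - 1) * 48 + 1):(i * 48), ])
    expect_equal(one$q[1, ], batch$q[i, ], tolerance = 1e-6)
    expect_equal(one$t[1, ], batch$t[i, ], tolerance = 1e-6)
  }
})

test_that("a single iteration equals the first step of many", {
  model <- test_tiny_model()
  set.seed(66)
  X <- matrix(rnorm(6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  one <- refine_net_forward(model, X, Y, n_iterations = 1)
  three <- refine_net_forward(model, X, Y, n_iterations = 3)
  expect_equal(one$q, three$iterations[[1]]$q, tolerance = 1e-12)
  expect_equal(one$t, three$iterations[[1]]$t, tolerance = 1e-12)
})

test_that("iterations compose right-to-left as a transform product", {
  # a model whose heads are constant (zero weights, fixed biases) predicts
  # the same step transform every iteration; the cumulative result must be
  # that transform composed with itself
  model <- test_tiny_model()
  model$params[["head_q.W"]][] <- 0
  model$params[["head_t.W"]][] <- 0
  model$params[["head_q.b"]][] <- c(0.05, 0.02, -0.01, 0.03)
  model$params[["head_t.b"]][] <- c(0.01, -0.02, 0.005)
  set.seed(67)
  X <- matrix(rnorm(6 * 3, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  out <- refine_net_forward(model, X, Y, n_iterations = 3)
  T0 <- rigid_transform(out$iterations[[1]]$q, out$iterations[[1]]$t)
  cum <- rt_compose(T0, rt_compose(T0, T0))
  expect_equal(quat_normalize(out$q[1, ]), cum$q, tolerance = 1e-9)
  expect_equal(as.numeric(out$t), cum$t, tolerance = 1e-9)
})

test_that("the composite loss is zero exactly at a perfect prediction", {
  ad <- asNamespace("navreg")
  model <- test_tiny_model()
  # target: identity correction of an already-aligned configuration
  set.seed(68)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  X <- Y[seq(1, 48, by = 8), ] # picks are region members: chamfer X->Y = 0
  tape <- ad$ad_tape()
  fake_q <- ad$ad_const(tape, matrix(c(1, 0, 0, 0), 1))
  fake_t <- ad$ad_const(tape, matrix(0, 1, 3))
  fw <- list(iterations = list(list(q = fake_q, t = fake_t,
                                    X = ad$ad_const(tape, X))),
             y_of = 1L)
  ls <- ad$batch_loss(tape, model, fw, Y,
                      euler_gt = matrix(0, 1, 3), t_gt = matrix(0, 1, 3),
                      scale_g = matrix(1), scale_rx = matrix(1, 6),
                      scale_ry = matrix(1, 48))
  expect_equal(as.numeric(ls$rot$v), 0)
  expect_equal(as.numeric(ls$trans$v), 0)
  # the patch-coverage half of the Chamfer term stays positive by design
  expect_gt(as.numeric(ls$chamfer$v), 0)
})

test_that("training descends on a 200-record toy set", {
  ds <- test_tiny_dataset(n_trials = 200)
  cfg <- refine_net_config(width_scale = 0.25)
  tc <- refine_net_train_config(epochs = 30, batch_size = 50, lr_step = 10,
                                seed = 9)
  fit <- train_refine_net(ds, cfg, tc)
  .fixtures$toy_fit <- fit
  expect_s3_class(fit, "refine_net_fit")
  expect_lt(utils::tail(fit$curves$train_loss, 1), fit$curves$train_loss[1])
  expect_equal(nrow(fit$curves), 30)
  expect_true(all(c("val_loss", "lr") %in% names(fit$curves)))
  expect_gte(fit$best_epoch, 16) # selected among frozen-statistics epochs

  # tidy/glance/plot surfaces
  expect_equal(nrow(tidy(fit)), 30)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("test-split records never contribute a gradient", {
  ds <- test_tiny_dataset(n_trials = 60)
  cfg <- refine_net_config(width_scale = 0.0625, n_iterations = 2)
  tc <- refine_net_train_config(epochs = 2, batch_size = 16, lr_step = 100,
                                seed = 9)
  fit <- train_refine_net(ds, cfg, tc)
  ds2 <- ds
  flip <- ds2$records$split == "test"
  ds2$records$X[flip] <- lapply(ds2$records$X[flip], function(m) m + 0.5)
  fit2 <- train_refine_net(ds2, cfg, tc)
  expect_identical(fit$model$params[["head_t.W"]],
                   fit2$model$params[["head_t.W"]])
})

test_that("checkpoints round-trip through disk", {
  ds <- test_tiny_dataset(n_trials = 60)
  cfg <- refine_net_config(width_scale = 0.0625, n_iterations = 2)
  tc <- refine_net_train_config(epochs = 2, batch_size = 16, seed = 9)
  fit <- train_refine_net(ds, cfg, tc)
  path <- tempfile(fileext = ".rds")
  save_refine_net(fit, path)
  back <- load_refine_net(path)
  st <- navreg:::stage_records(ds, "test")
  a <- refine_net_forward(fit, st$X, st$Yu, st$y_of)
  b <- refine_net_forward(back, st$X, st$Yu, st$y_of)
  expect_equal(a$q, b$q, tolerance = 1e-12)
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$best_epoch, fit$best_epoch)
})

test_that("mm-space predictions de-standardize by exact conjugation", {
  model <- test_tiny_model()
  set.seed(69)
  X <- matrix(rnorm(18, sd = 0.3), ncol = 3)
  Y <- matrix(rnorm(48 * 3, sd = 0.3), ncol = 3)
  # identity standardization: mm transform equals the raw prediction
  ident <- structure(list(rotation = diag(3), centroid = c(0, 0, 0),
                          scale = 1), class = "standardization_info")
  pred <- predict_refinement(model, X, Y, ident)
  expect_transforms_equal(pred$transform_mm, pred$transform_std, tol = 1e-9)
  # generic standardization: conjugation identity holds on points
  info <- structure(list(rotation = quat_to_matrix(euler_to_quat(c(30, 10, -20))),
                         centroid = c(5, -8, 12), scale = 117),
                    class = "standardization_info")
  pred2 <- predict_refinement(model, X, Y, info)
  P <- matrix(rnorm(15, sd = 40), ncol = 3)
  via_std <- destandardize_points(
    info, rt_apply(pred2$transform_std, standardize_points(info, P)))
  expect_equal(rt_apply(pred2$transform_mm, P), via_std, tolerance = 1e-8)
  bad <- info
  bad$scale <- 0
  expect_error(predict_refinement(model, X, Y, bad), "config error")
})
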