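# A small tape-based reverse-mode automatic-differentiation engine over
# numeric matrices. This is the training machinery behind the refinement
# network: a forward pass builds a tape of primitive operations; backward()
# walks it in reverse, accumulating gradients into the leaves. All values
# are plain matrices; the op set is exactly what the dual-branch network,
# its batch-norm layers and the composite loss require. Every op's gradient
# is verified against central finite differences in the test suite.
#
# Internal API (not exported): networks in this package are the consumers.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), back = NULL, req = NA) {
  if (is.na(req)) {
    req <- FALSE
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$back <- back
  nd$req <- req
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# leaf carrying parameters (gradient wanted) or constants (not)
ad_leaf <- function(tape, value, req = TRUE) {
  ad_node(tape, value, parents = list(), back = NULL, req = req)
}

ad_const <- function(tape, value) ad_leaf(tape, value, req = FALSE)

ad_accum <- function(nd, g) {
  if (!nd$req) return(invisible(NULL))
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

# Run the backward sweep from a scalar (1x1) node.
ad_backward <- function(tape, loss) {
  loss$g <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$back) && !is.null(nd$g) && nd$req) nd$back(nd)
  }
  invisible(NULL)
}

# --- arithmetic -----------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$v %*% b$v, list(a, b), function(nd) {
    ad_accum(a, tcrossprod(nd$g, b$v))
    ad_accum(b, crossprod(a$v, nd$g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$v + b$v, list(a, b), function(nd) {
    ad_accum(a, nd$g); ad_accum(b, nd$g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$v - b$v, list(a, b), function(nd) {
    ad_accum(a, nd$g); ad_accum(b, -nd$g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$v * b$v, list(a, b), function(nd) {
    ad_accum(a, nd$g * b$v); ad_accum(b, nd$g * a$v)
  })
}

# x (n x k) + row vector b (1 x k), broadcast over rows
ad_add_rowvec <- function(tape, x, b) {
  n <- nrow(x$v)
  ad_node(tape, x$v + rep(as.numeric(b$v), each = n), list(x, b), function(nd) {
    ad_accum(x, nd$g)
    ad_accum(b, matrix(colSums(nd$g), 1))
  })
}

ad_sub_rowvec <- function(tape, x, b) {
  n <- nrow(x$v)
  ad_node(tape, x$v - rep(as.numeric(b$v), each = n), list(x, b), function(nd) {
    ad_accum(x, nd$g)
    ad_accum(b, matrix(-colSums(nd$g), 1))
  })
}

ad_mul_rowvec <- function(tape, x, r) {
  n <- nrow(x$v)
  rv <- rep(as.numeric(r$v), each = n)
  ad_node(tape, x$v * rv, list(x, r), function(nd) {
    ad_accum(x, nd$g * rv)
    ad_accum(r, matrix(colSums(nd$g * x$v), 1))
  })
}

ad_div_rowvec <- function(tape, x, r) {
  n <- nrow(x$v)
  inv <- rep(1 / as.numeric(r$v), each = n)
  val <- x$v * inv
  ad_node(tape, val, list(x, r), function(nd) {
    ad_accum(x, nd$g * inv)
    ad_accum(r, matrix(-colSums(nd$g * val * inv) * as.numeric(r$v), 1))
  })
}

# multiply each row i of x (n x k) by v[i] (v is n x 1)
ad_scale_rows <- function(tape, x, v) {
  vv <- as.numeric(v$v)
  ad_node(tape, x$v * vv, list(x, v), function(nd) {
    ad_accum(x, nd$g * vv)
    ad_accum(v, matrix(rowSums(nd$g * x$v), ncol = 1))
  })
}

ad_scalar_mul <- function(tape, x, c) {
  ad_node(tape, x$v * c, list(x), function(nd) ad_accum(x, nd$g * c))
}

ad_add_scalar <- function(tape, x, c) {
  ad_node(tape, x$v + c, list(x), function(nd) ad_accum(x, nd$g))
}

ad_pow <- function(tape, x, p) {
  ad_node(tape, x$v^p, list(x), function(nd) {
    ad_accum(x, nd$g * p * x$v^(p - 1))
  })
}

ad_relu <- function(tape, x) {
  mask <- x$v > 0
  ad_node(tape, x$v * mask, list(x), function(nd) ad_accum(x, nd$g * mask))
}

ad_clamp <- function(tape, x, lo, hi) {
  mask <- x$v > lo & x$v < hi
  v <- x$v
  v[v < lo] <- lo
  v[v > hi] <- hi
  ad_node(tape, v, list(x), function(nd) {
    ad_accum(x, nd$g * mask)
  })
}

ad_asin <- function(tape, x) {
  ad_node(tape, asin(x$v), list(x), function(nd) {
    ad_accum(x, nd$g / sqrt(pmax(1e-12, 1 - x$v^2)))
  })
}

ad_atan2 <- function(tape, y, x) {
  ad_node(tape, atan2(y$v, x$v), list(y, x), function(nd) {
    den <- x$v^2 + y$v^2
    ad_accum(y, nd$g * x$v / den)
    ad_accum(x, -nd$g * y$v / den)
  })
}

# --- reductions and shape ops --------------------------------------------

ad_rowsums <- function(tape, x) {
  k <- ncol(x$v)
  ad_node(tape, matrix(rowSums(x$v), ncol = 1), list(x), function(nd) {
    ad_accum(x, matrix(nd$g, nrow(x$v), k))
  })
}

ad_colmeans <- function(tape, x) {
  n <- nrow(x$v); k <- ncol(x$v)
  ad_node(tape, matrix(.colMeans(x$v, n, k), 1), list(x), function(nd) {
    ad_accum(x, matrix(rep(as.numeric(nd$g) / n, each = n), n))
  })
}

ad_mean <- function(tape, x) {
  n <- length(x$v)
  ad_node(tape, matrix(mean(x$v), 1, 1), list(x), function(nd) {
    ad_accum(x, matrix(as.numeric(nd$g) / n, nrow(x$v), ncol(x$v)))
  })
}

ad_sum <- function(tape, x) {
  ad_node(tape, matrix(sum(x$v), 1, 1), list(x), function(nd) {
    ad_accum(x, matrix(as.numeric(nd$g), nrow(x$v), ncol(x$v)))
  })
}

ad_concat_cols <- function(tape, xs) {
  widths <- vapply(xs, function(x) ncol(x$v), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(xs, function(x) x$v)), xs, function(nd) {
    for (j in seq_along(xs)) {
      ad_accum(xs[[j]], nd$g[, starts[j]:ends[j], drop = FALSE])
    }
  })
}

ad_slice_cols <- function(tape, x, idx) {
  k <- ncol(x$v)
  ad_node(tape, x$v[, idx, drop = FALSE], list(x), function(nd) {
    g <- matrix(0, nrow(x$v), k)
    g[, idx] <- nd$g
    ad_accum(x, g)
  })
}

# Max-pool over consecutive groups of m rows: (G*m x k) -> (G x k).
# Channel-wise max with argmax routing in the backward pass.
ad_pool_max <- function(tape, x, m) {
  n <- nrow(x$v)
  stopifnot(n %% m == 0)
  f <- .pool_max_fwd(x$v, m)
  ad_node(tape, f$val, list(x), function(nd) {
    ad_accum(x, .pool_max_bwd(nd$g, f$arg, n, m))
  })
}

# Mean-pool over consecutive groups of m rows: (G*m x k) -> (G x k).
ad_pool_mean <- function(tape, x, m) {
  n <- nrow(x$v); k <- ncol(x$v)
  stopifnot(n %% m == 0)
  G <- n %/% m
  v <- x$v
  dim(v) <- c(m, G * k)
  ad_node(tape, matrix(.colSums(v, m, G * k) / m, G, k), list(x), function(nd) {
    idx <- rep(seq_len(G), each = m)
    ad_accum(x, nd$g[idx, , drop = FALSE] / m)
  })
}

# Repeat each row of x (G x k) m times consecutively -> (G*m x k).
ad_repeat_rows <- function(tape, x, m) {
  G <- nrow(x$v); k <- ncol(x$v)
  idx <- rep(seq_len(G), each = m)
  ad_node(tape, x$v[idx, , drop = FALSE], list(x), function(nd) {
    g <- nd$g
    dim(g) <- c(m, G * k)
    ad_accum(x, matrix(.colSums(g, m, G * k), G, k))
  })
}

# --- composite helpers used by the network --------------------------------

# Fully-connected layer: y = x W + b (W: in x out, b: 1 x out)
ad_linear <- function(tape, x, W, b) {
  ad_add_rowvec(tape, ad_matmul(tape, x, W), b)
}

# Row-wise L2 normalization (used by the quaternion output head).
ad_normalize_rows <- function(tape, x, eps = 1e-30) {
  n2 <- ad_rowsums(tape, ad_mul(tape, x, x))
  inv <- ad_pow(tape, ad_add_scalar(tape, n2, eps), -0.5)
  ad_scale_rows(tape, x, inv)
}

# Rotate per-sample 3-D points by per-sample unit quaternions.
# q: G x 4 node; p: (G*m) x 3 node; returns (G*m) x 3 node.
# Uses p' = p + 2 w (v x p) + 2 v x (v x p).
ad_quat_rotate <- function(tape, q, p, m) {
  qr <- ad_repeat_rows(tape, q, m)
  w <- ad_slice_cols(tape, qr, 1)
  v <- ad_slice_cols(tape, qr, 2:4)
  cross <- function(a, b) {
    a1 <- ad_slice_cols(tape, a, 1); a2 <- ad_slice_cols(tape, a, 2)
    a3 <- ad_slice_cols(tape, a, 3)
    b1 <- ad_slice_cols(tape, b, 1); b2 <- ad_slice_cols(tape, b, 2)
    b3 <- ad_slice_cols(tape, b, 3)
    ad_concat_cols(tape, list(
      ad_sub(tape, ad_mul(tape, a2, b3), ad_mul(tape, a3, b2)),
      ad_sub(tape, ad_mul(tape, a3, b1), ad_mul(tape, a1, b3)),
      ad_sub(tape, ad_mul(tape, a1, b2), ad_mul(tape, a2, b1))
    ))
  }
  vxp <- cross(v, p)
  vvxp <- cross(v, vxp)
  w3 <- ad_concat_cols(tape, list(w, w, w))
  ad_add(tape, p,
         ad_scalar_mul(tape, ad_add(tape, ad_mul(tape, w3, vxp), vvxp), 2))
}

# Hamilton product of two G x 4 quaternion nodes.
ad_quat_multiply <- function(tape, a, b) {
  aw <- ad_slice_cols(tape, a, 1); ax <- ad_slice_cols(tape, a, 2)
  ay <- ad_slice_cols(tape, a, 3); az <- ad_slice_cols(tape, a, 4)
  bw <- ad_slice_cols(tape, b, 1); bx <- ad_slice_cols(tape, b, 2)
  by <- ad_slice_cols(tape, b, 3); bz <- ad_slice_cols(tape, b, 4)
  mul <- function(p, q) ad_mul(tape, p, q)
  ad_concat_cols(tape, list(
    ad_sub(tape, ad_sub(tape, ad_sub(tape, mul(aw, bw), mul(ax, bx)),
                        mul(ay, by)), mul(az, bz)),
    ad_sub(tape, ad_add(tape, ad_add(tape, mul(aw, bx), mul(ax, bw)),
                        mul(ay, bz)), mul(az, by)),
    ad_add(tape, ad_add(tape, ad_sub(tape, mul(aw, by), mul(ax, bz)),
                        mul(ay, bw)), mul(az, bx)),
    ad_add(tape, ad_sub(tape, ad_add(tape, mul(aw, bz), mul(ax, by)),
                        mul(ay, bx)), mul(az, bw))
  ))
}

# Euler angles (intrinsic z-y'-x'', degrees) of G x 4 unit quaternions,
# matching quat_to_euler(): columns yaw, pitch, roll.
ad_quat_to_euler_deg <- function(tape, q) {
  w <- ad_slice_cols(tape, q, 1); x <- ad_slice_cols(tape, q, 2)
  y <- ad_slice_cols(tape, q, 3); z <- ad_slice_cols(tape, q, 4)
  mul <- function(p, r) ad_mul(tape, p, r)
  two <- function(nd) ad_scalar_mul(tape, nd, 2)
  one_minus <- function(nd) ad_add_scalar(tape, ad_scalar_mul(tape, nd, -1), 1)
  yaw <- ad_atan2(tape, two(ad_add(tape, mul(x, y), mul(w, z))),
                  one_minus(two(ad_add(tape, mul(y, y), mul(z, z)))))
  sp <- ad_clamp(tape, two(ad_sub(tape, mul(w, y), mul(x, z))),
                 -1 + 1e-9, 1 - 1e-9)
  pitch <- ad_asin(tape, sp)
  roll <- ad_atan2(tape, two(ad_add(tape, mul(y, z), mul(w, x))),
                   one_minus(two(ad_add(tape, mul(x, x), mul(y, y)))))
  ad_scalar_mul(tape, ad_concat_cols(tape, list(yaw, pitch, roll)), 180 / pi)
}

# Symmetric Chamfer distance between per-sample point sets (squared-distance
# form, means over each set; the two sets may differ in size). x: (G*mx) x 3
# node; Y: (U*my) x 3 fixed matrix of U distinct reference clouds; y_of maps
# each sample group to its reference cloud. Nearest neighbours are
# recomputed each forward pass; the backward pass routes gradients through
# the matched pairs. Returns G x 1 node.
ad_chamfer <- function(tape, x, Y, mx, my = mx, y_of = NULL) {
  n <- nrow(x$v)
  G <- n %/% mx
  if (is.null(y_of)) y_of <- seq_len(G)
  X <- x$v
  cd <- numeric(G)
  grad_pairs <- vector("list", G)
  for (g in seq_len(G)) {
    rx <- ((g - 1) * mx + 1):(g * mx)
    ry <- ((y_of[g] - 1) * my + 1):(y_of[g] * my)
    Xg <- X[rx, , drop = FALSE]
    Yg <- Y[ry, , drop = FALSE]
    D2 <- outer(rowSums(Xg^2), rep(1, my)) + outer(rep(1, mx), rowSums(Yg^2)) -
      2 * tcrossprod(Xg, Yg)
    D2[D2 < 0] <- 0
    jx <- max.col(-D2, ties.method = "first")       # nearest Y for each X
    iy <- max.col(-t(D2), ties.method = "first")    # nearest X for each Y
    cd[g] <- mean(D2[cbind(seq_len(mx), jx)]) + mean(D2[cbind(iy, seq_len(my))])
    grad_pairs[[g]] <- list(rx = rx, jx = jx, iy = iy, Xg = Xg, Yg = Yg)
  }
  ad_node(tape, matrix(cd, ncol = 1), list(x), function(nd) {
    gx <- matrix(0, n, 3)
    for (g in seq_len(G)) {
      gp <- grad_pairs[[g]]
      gv <- as.numeric(nd$g[g, 1])
      # d/dX of mean_i ||x_i - y_{jx(i)}||^2
      gx[gp$rx, ] <- gx[gp$rx, ] +
        gv * 2 / mx * (gp$Xg - gp$Yg[gp$jx, , drop = FALSE])
      # d/dX of mean_j ||y_j - x_{iy(j)}||^2 (accumulate per matched x)
      diffs <- -2 / my * (gp$Yg - gp$Xg[gp$iy, , drop = FALSE]) * gv
      for (j in seq_len(my)) {
        r <- gp$rx[gp$iy[j]]
        gx[r, ] <- gx[r, ] + diffs[j, ]
      }
    }
    ad_accum(x, gx)
  })
}

# --- batch normalization --------------------------------------------------

# Batch norm over rows (feature columns), with running statistics. `bn` is a
# mutable environment (gamma/beta leaves come from the caller; running_mean/
# running_var/momentum live in `state`). In training mode batch statistics
# enter the graph; in eval mode the frozen running statistics are constants,
# so single-sample and batched inference agree exactly.
ad_batchnorm <- function(tape, x, gamma, beta, state, training, eps = 1e-5) {
  if (training) {
    nd <- ad_batchnorm_train(tape, x, gamma, beta, eps)
    # update running stats outside the graph
    n <- nrow(x$v)
    unbias <- if (n > 1) n / (n - 1) else 1
    state$mean <- (1 - state$momentum) * state$mean +
      state$momentum * attr(nd, "batch_mean")
    state$var <- (1 - state$momentum) * state$var +
      state$momentum * attr(nd, "batch_var") * unbias
    nd
  } else {
    ad_batchnorm_eval(tape, x, gamma, beta, state$mean, state$var, eps)
  }
}

# Batch norm in inference mode: frozen running statistics, so the layer is
# a per-column affine map and batched/single-sample results agree exactly.
ad_batchnorm_eval <- function(tape, x, gamma, beta, mean, var, eps = 1e-5) {
  n <- nrow(x$v)
  istd <- 1 / sqrt(var + eps)
  xhat <- (x$v - rep(mean, each = n)) * rep(istd, each = n)
  gv <- as.numeric(gamma$v)
  y <- xhat * rep(gv, each = n) + rep(as.numeric(beta$v), each = n)
  ad_node(tape, y, list(x, gamma, beta), function(nd) {
    ad_accum(gamma, matrix(colSums(nd$g * xhat), 1))
    ad_accum(beta, matrix(colSums(nd$g), 1))
    ad_accum(x, nd$g * rep(gv * istd, each = n))
  })
}

# --- fused ops ------------------------------------------------------------
# Hand-derived backward passes for the hottest composites. Each is
# numerically equivalent to the primitive-op composition above (the test
# suite checks both against finite differences); fusing cuts the number of
# full-matrix passes per layer severalfold.

# y = x W + b
ad_linear_fused <- function(tape, x, W, b) {
  n <- nrow(x$v)
  ad_node(tape, x$v %*% W$v + rep(as.numeric(b$v), each = n),
          list(x, W, b), function(nd) {
    ad_accum(x, tcrossprod(nd$g, W$v))
    ad_accum(W, crossprod(x$v, nd$g))
    ad_accum(b, matrix(colSums(nd$g), 1))
  })
}

# Batch norm (training mode) with the standard fused backward.
ad_batchnorm_train <- function(tape, x, gamma, beta, eps = 1e-5) {
  n <- nrow(x$v); k <- ncol(x$v)
  mu <- .colMeans(x$v, n, k)
  xc <- x$v - rep(mu, each = n)
  va <- .colMeans(xc * xc, n, k)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = n)
  gv <- as.numeric(gamma$v)
  y <- xhat * rep(gv, each = n) + rep(as.numeric(beta$v), each = n)
  nd <- ad_node(tape, y, list(x, gamma, beta), function(nd) {
    g <- nd$g
    ad_accum(gamma, matrix(colSums(g * xhat), 1))
    ad_accum(beta, matrix(colSums(g), 1))
    dxhat <- g * rep(gv, each = n)
    s1 <- .colMeans(dxhat, n, k)
    s2 <- .colMeans(dxhat * xhat, n, k)
    ad_accum(x, (dxhat - rep(s1, each = n) - xhat * rep(s2, each = n)) *
                  rep(istd, each = n))
  })
  attr(nd, "batch_mean") <- mu
  attr(nd, "batch_var") <- va
  nd
}

# Hamilton product c = a (x) b on G x 4 rows, fused.
ad_quat_multiply_fused <- function(tape, a, b) {
  A <- a$v; B <- b$v
  aw <- A[, 1]; ax <- A[, 2]; ay <- A[, 3]; az <- A[, 4]
  bw <- B[, 1]; bx <- B[, 2]; by <- B[, 3]; bz <- B[, 4]
  val <- cbind(aw * bw - ax * bx - ay * by - az * bz,
               aw * bx + ax * bw + ay * bz - az * by,
               aw * by - ax * bz + ay * bw + az * bx,
               aw * bz + ax * by - ay * bx + az * bw)
  ad_node(tape, val, list(a, b), function(nd) {
    gw <- nd$g[, 1]; gx <- nd$g[, 2]; gy <- nd$g[, 3]; gz <- nd$g[, 4]
    ad_accum(a, cbind(
       gw * bw + gx * bx + gy * by + gz * bz,
      -gw * bx + gx * bw - gy * bz + gz * by,
      -gw * by + gx * bz + gy * bw - gz * bx,
      -gw * bz - gx * by + gy * bx + gz * bw))
    ad_accum(b, cbind(
       gw * aw + gx * ax + gy * ay + gz * az,
      -gw * ax + gx * aw + gy * az - gz * ay,
      -gw * ay - gx * az + gy * aw + gz * ax,
      -gw * az + gx * ay - gy * ax + gz * aw))
  })
}

# Rotate p ((G*m) x 3) by per-sample quaternions q (G x 4), fused.
# p' = (w^2 - v.v) p + 2 (v.p) v + 2 w (v x p)
ad_quat_rotate_fused <- function(tape, q, p, m) {
  Q <- q$v[rep(seq_len(nrow(q$v)), each = m), , drop = FALSE]
  w <- Q[, 1]; vx <- Q[, 2]; vy <- Q[, 3]; vz <- Q[, 4]
  P <- p$v
  px <- P[, 1]; py <- P[, 2]; pz <- P[, 3]
  vv <- vx^2 + vy^2 + vz^2
  vdp <- vx * px + vy * py + vz * pz
  cx <- vy * pz - vz * py
  cy <- vz * px - vx * pz
  cz <- vx * py - vy * px
  a <- w^2 - vv
  val <- cbind(a * px + 2 * (vdp * vx + w * cx),
               a * py + 2 * (vdp * vy + w * cy),
               a * pz + 2 * (vdp * vz + w * cz))
  ad_node(tape, val, list(q, p), function(nd) {
    gx <- nd$g[, 1]; gy <- nd$g[, 2]; gz <- nd$g[, 3]
    gdp <- gx * px + gy * py + gz * pz
    gdv <- gx * vx + gy * vy + gz * vz
    # v x g and p x g for the w / v gradients
    vxg_x <- vy * gz - vz * gy; vxg_y <- vz * gx - vx * gz
    vxg_z <- vx * gy - vy * gx
    pxg_x <- py * gz - pz * gy; pxg_y <- pz * gx - px * gz
    pxg_z <- px * gy - py * gx
    gw <- 2 * w * gdp + 2 * (gx * cx + gy * cy + gz * cz)
    gvx <- -2 * gdp * vx + 2 * gdv * px + 2 * vdp * gx + 2 * w * pxg_x
    gvy <- -2 * gdp * vy + 2 * gdv * py + 2 * vdp * gy + 2 * w * pxg_y
    gvz <- -2 * gdp * vz + 2 * gdv * pz + 2 * vdp * gz + 2 * w * pxg_z
    gq <- matrix(.colSums(matrix(cbind(gw, gvx, gvy, gvz), nrow = m),
                          m, length(gw) / m * 4), ncol = 4)
    ad_accum(q, gq)
    ad_accum(p, cbind(a * gx + 2 * (gdv * vx - w * vxg_x),
                      a * gy + 2 * (gdv * vy - w * vxg_y),
                      a * gz + 2 * (gdv * vz - w * vxg_z)))
  })
}

# Euler angles (deg, intrinsic z-y'-x'') from G x 4 unit quaternions, fused.
ad_quat_to_euler_fused <- function(tape, q) {
  Q <- q$v
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  A <- 2 * (x * y + w * z); B <- 1 - 2 * (y^2 + z^2)
  S <- pmin(1 - 1e-9, pmax(-1 + 1e-9, 2 * (w * y - x * z)))
  Cc <- 2 * (y * z + w * x); D <- 1 - 2 * (x^2 + y^2)
  k <- 180 / pi
  val <- cbind(atan2(A, B), asin(S), atan2(Cc, D)) * k
  ad_node(tape, val, list(q), function(nd) {
    g1 <- nd$g[, 1] * k; g2 <- nd$g[, 2] * k; g3 <- nd$g[, 3] * k
    den1 <- A^2 + B^2
    c1 <- g1 / den1
    dpit <- g2 / sqrt(1 - S^2)
    den3 <- Cc^2 + D^2
    c3 <- g3 / den3
    # dA = 2(z,y,x,w); dB = (0,0,-4y,-4z); dS = 2(y,-z,w,-x);
    # dC = 2(x,w,z,y); dD = (0,-4x,-4y,0)
    gw <- c1 * B * 2 * z + dpit * 2 * y + c3 * D * 2 * x
    gx <- c1 * B * 2 * y - dpit * 2 * z + c3 * (D * 2 * w + Cc * 4 * x)
    gy <- c1 * (B * 2 * x + A * 4 * y) + dpit * 2 * w +
      c3 * (D * 2 * z + Cc * 4 * y)
    gz <- c1 * (B * 2 * w + A * 4 * z) - dpit * 2 * x + c3 * D * 2 * y
    ad_accum(q, cbind(gw, gx, gy, gz))
  })
}

# Dense layer fused with batch norm and ReLU: y = relu(BN(x W)). The bias
# is omitted — batch norm's mean subtraction makes an additive bias inert.
# Matrix products run through BLAS; everything elementwise is one C++ pass.
# `mode`: "train" = batch statistics + running-stat update; "batch" = batch
# statistics without updating (used for validation during training);
# "eval" = frozen running statistics (inference).
ad_dense_bn_relu <- function(tape, x, W, gamma, beta, state, mode,
                             eps = 1e-5) {
  if (isTRUE(mode)) mode <- "train"
  if (identical(mode, FALSE)) mode <- "eval"
  z <- x$v %*% W$v
  if (mode %in% c("train", "batch")) {
    f <- .bnrelu_train_fwd(z, as.numeric(gamma$v), as.numeric(beta$v), eps)
    if (mode == "train") {
      n <- nrow(z)
      unbias <- if (n > 1) n / (n - 1) else 1
      state$mean <- (1 - state$momentum) * state$mean + state$momentum * f$mean
      state$var <- (1 - state$momentum) * state$var +
        state$momentum * f$var * unbias
    }
    ad_node(tape, f$y, list(x, W, gamma, beta), function(nd) {
      bw <- .bnrelu_train_bwd(nd$g, f$y, f$xhat, f$istd, as.numeric(gamma$v))
      ad_accum(x, tcrossprod(bw$gz, W$v))
      ad_accum(W, crossprod(x$v, bw$gz))
      ad_accum(gamma, matrix(bw$ggamma, 1))
      ad_accum(beta, matrix(bw$gbeta, 1))
    })
  } else {
    y <- .bnrelu_eval_fwd(z, as.numeric(gamma$v), as.numeric(beta$v),
                          state$mean, state$var, eps)
    ad_node(tape, y, list(x, W, gamma, beta), function(nd) {
      gz <- .bnrelu_eval_bwd(nd$g, y, as.numeric(gamma$v), state$var, eps)
      ad_accum(x, tcrossprod(gz, W$v))
      ad_accum(W, crossprod(x$v, gz))
      if (gamma$req || beta$req) {
        n <- nrow(z)
        g1 <- nd$g * (y > 0)
        zhat <- (z - rep(state$mean, each = n)) *
          rep(1 / sqrt(state$var + eps), each = n)
        ad_accum(gamma, matrix(colSums(g1 * zhat), 1))
        ad_accum(beta, matrix(colSums(g1), 1))
      }
    })
  }
}

# Linear layer fused with bias and ReLU (no batch norm): y = relu(x W + b).
ad_linear_bias_relu <- function(tape, x, W, b) {
  y <- .bias_relu_fwd(x$v %*% W$v, as.numeric(b$v))
  ad_node(tape, y, list(x, W, b), function(nd) {
    bw <- .bias_relu_bwd(nd$g, y)
    ad_accum(x, tcrossprod(bw$gz, W$v))
    ad_accum(W, crossprod(x$v, bw$gz))
    ad_accum(b, matrix(bw$gb, 1))
  })
}

# Duplicate rows of x (U x k) into an arbitrary per-row index pattern
# (length n); backward sums gradients per source row. Used to share one
# reference-cloud encoding across the batch records that reference it.
ad_gather_rows <- function(tape, x, idx) {
  U <- nrow(x$v)
  ad_node(tape, x$v[idx, , drop = FALSE], list(x), function(nd) {
    agg <- rowsum(nd$g, group = idx, reorder = TRUE)
    g <- matrix(0, U, ncol(x$v))
    g[as.integer(rownames(agg)), ] <- agg
    ad_accum(x, g)
  })
}
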