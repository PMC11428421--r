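# The reverse-mode autodiff engine: every primitive and fused op is checked
# against central finite differences, and fused ops against their
# primitive-op compositions.

ad <- asNamespace("navreg")

grad_check <- function(build, x0, tol = 1e-6) {
  # build(tape, leaf) must return a scalar node
  f <- function(v) {
    tape <- ad$ad_tape()
    leaf <- ad$ad_leaf(tape, matrix(v, nrow(x0), ncol(x0)))
    as.numeric(build(tape, leaf)$v)
  }
  tape <- ad$ad_tape()
  leaf <- ad$ad_leaf(tape, x0)
  out <- build(tape, leaf)
  ad$ad_backward(tape, out)
  gnum <- num_grad(f, as.numeric(x0))
  expect_lt(max(abs(as.numeric(leaf$g) - gnum)) /
              max(1, max(abs(gnum))), tol)
}

test_that("core matrix ops differentiate correctly", {
  set.seed(51)
  X <- matrix(rnorm(20), 5, 4)
  W <- matrix(rnorm(12), 4, 3)
  grad_check(function(tp, x) {
    h <- ad$ad_relu(tp, ad$ad_matmul(tp, x, ad$ad_const(tp, W)))
    ad$ad_mean(tp, ad$ad_mul(tp, h, h))
  }, X)
  grad_check(function(tp, x) {
    p <- ad$ad_pool_max(tp, x, 5)      # one group of 5 rows
    s <- ad$ad_pool_mean(tp, x, 5)
    ad$ad_sum(tp, ad$ad_mul(tp, ad$ad_concat_cols(tp, list(p, s)),
                            ad$ad_concat_cols(tp, list(p, s))))
  }, X)
  grad_check(function(tp, x) {
    r <- ad$ad_repeat_rows(tp, ad$ad_slice_cols(tp, x, 1:2), 3)
    ad$ad_mean(tp, ad$ad_mul(tp, r, r))
  }, X)
  grad_check(function(tp, x) {
    g <- ad$ad_gather_rows(tp, x, c(2L, 2L, 5L, 1L))
    ad$ad_mean(tp, ad$ad_mul(tp, g, g))
  }, X)
})

test_that("rowvec broadcasting ops differentiate correctly", {
  set.seed(52)
  X <- matrix(rnorm(24), 6, 4)
  b <- matrix(rnorm(4), 1)
  r <- matrix(runif(4, 0.5, 2), 1)
  grad_check(function(tp, x) {
    h <- ad$ad_add_rowvec(tp, x, ad$ad_const(tp, b))
    h <- ad$ad_mul_rowvec(tp, h, ad$ad_const(tp, r))
    h <- ad$ad_div_rowvec(tp, h, ad$ad_const(tp, r * 2))
    ad$ad_mean(tp, ad$ad_mul(tp, h, h))
  }, X)
  # gradients w.r.t. the row vector itself
  f <- function(v) {
    tp <- ad$ad_tape()
    h <- ad$ad_mul_rowvec(tp, ad$ad_const(tp, X),
                          ad$ad_leaf(tp, matrix(v, 1)))
    as.numeric(ad$ad_mean(tp, ad$ad_mul(tp, h, h))$v)
  }
  tp <- ad$ad_tape()
  rn <- ad$ad_leaf(tp, r)
  h <- ad$ad_mul_rowvec(tp, ad$ad_const(tp, X), rn)
  out <- ad$ad_mean(tp, ad$ad_mul(tp, h, h))
  ad$ad_backward(tp, out)
  expect_equal(as.numeric(rn$g), num_grad(f, as.numeric(r)),
               tolerance = 1e-6)
})

test_that("fused dense+batchnorm+relu matches finite differences", {
  set.seed(53)
  n <- 10; nin <- 4; nout <- 5
  X <- matrix(rnorm(n * nin), n, nin)
  W <- matrix(rnorm(nin * nout) * 0.7, nin, nout)
  gam <- matrix(runif(nout, 0.5, 1.5), 1)
  bet <- matrix(rnorm(nout) * 0.2, 1)
  mkst <- function() {
    st <- new.env()
    st$mean <- rep(0, nout); st$var <- rep(1, nout); st$momentum <- 0.1
    st
  }
  loss_of <- function(Wm, Xm, gm, bm, training) {
    tp <- ad$ad_tape()
    y <- ad$ad_dense_bn_relu(tp, ad$ad_leaf(tp, Xm), ad$ad_leaf(tp, Wm),
                             ad$ad_leaf(tp, gm), ad$ad_leaf(tp, bm),
                             mkst(), training)
    list(tape = tp, out = ad$ad_mean(tp, ad$ad_mul(tp, y, y)))
  }
  for (training in c(TRUE, FALSE)) {
    got <- loss_of(W, X, gam, bet, training)
    nodes <- got$tape$nodes[seq_len(got$tape$n)]
    leaves <- Filter(function(nd) is.null(nd$back) && nd$req, nodes)
    ad$ad_backward(got$tape, got$out)
    packed <- c(as.numeric(X), as.numeric(W), as.numeric(gam),
                as.numeric(bet))
    f <- function(v) {
      Xm <- matrix(v[1:(n * nin)], n, nin)
      Wm <- matrix(v[n * nin + 1:(nin * nout)], nin, nout)
      gm <- matrix(v[n * nin + nin * nout + 1:nout], 1)
      bm <- matrix(utils::tail(v, nout), 1)
      as.numeric(loss_of(Wm, Xm, gm, bm, training)$out$v)
    }
    gnum <- num_grad(f, packed)
    gan <- unlist(lapply(leaves, function(nd) {
      as.numeric(if (is.null(nd$g)) nd$v * 0 else nd$g)
    }))
    # eval mode: gamma/beta gradients exist only through the affine map
    expect_lt(max(abs(gan - gnum)), 1e-5)
  }
})

test_that("fused quaternion ops agree with reference math and gradients", {
  set.seed(54)
  G <- 4
  A <- matrix(rnorm(G * 4), G, 4)
  B <- matrix(rnorm(G * 4), G, 4)
  tp <- ad$ad_tape()
  prod <- ad$ad_quat_multiply_fused(tp, ad$ad_const(tp, A),
                                    ad$ad_const(tp, B))
  for (g in 1:G) {
    expect_equal(as.numeric(prod$v[g, ]),
                 ad$quat_multiply(A[g, ], B[g, ]), tolerance = 1e-12)
  }
  grad_check(function(tp, a) {
    p <- ad$ad_quat_multiply_fused(tp, a, ad$ad_const(tp, B))
    ad$ad_mean(tp, ad$ad_mul(tp, p, p))
  }, A)

  # rotation op matches rt_apply and differentiates in q and p
  m <- 3
  Q <- t(replicate(G, quat_normalize(rnorm(4))))
  P <- matrix(rnorm(G * m * 3), ncol = 3)
  tp <- ad$ad_tape()
  rot <- ad$ad_quat_rotate_fused(tp, ad$ad_const(tp, Q),
                                 ad$ad_const(tp, P), m)
  for (g in 1:G) {
    rows <- ((g - 1) * m + 1):(g * m)
    expect_equal(rot$v[rows, ],
                 P[rows, ] %*% t(quat_to_matrix(Q[g, ])), tolerance = 1e-9)
  }
  grad_check(function(tp, q) {
    r <- ad$ad_quat_rotate_fused(tp, q, ad$ad_const(tp, P), m)
    ad$ad_mean(tp, ad$ad_mul(tp, r, r))
  }, Q, tol = 1e-5)
  grad_check(function(tp, p) {
    r <- ad$ad_quat_rotate_fused(tp, ad$ad_const(tp, Q), p, m)
    ad$ad_mean(tp, ad$ad_mul(tp, r, r))
  }, P)
})

test_that("fused euler conversion matches quat_to_euler and its gradient", {
  set.seed(55)
  Q <- t(replicate(5, quat_normalize(rnorm(4))))
  tp <- ad$ad_tape()
  eu <- ad$ad_quat_to_euler_fused(tp, ad$ad_const(tp, Q))
  for (g in 1:5) {
    expect_equal(as.numeric(eu$v[g, ]), as.numeric(quat_to_euler(Q[g, ])),
                 tolerance = 1e-9)
  }
  grad_check(function(tp, q) {
    qn <- ad$ad_normalize_rows(tp, q)
    e <- ad$ad_quat_to_euler_fused(tp, qn)
    ad$ad_mean(tp, ad$ad_mul(tp, e, e))
  }, Q + 0.1, tol = 1e-5)
})

test_that("chamfer distance equals the hand-evaluated definition", {
  # one-point sets: CD({0}, {(1,0,0)}) = 1^2 + 1^2 = 2
  tp <- ad$ad_tape()
  cd <- ad$ad_chamfer(tp, ad$ad_const(tp, rbind(c(0, 0, 0))),
                      rbind(c(1, 0, 0)), 1, 1)
  expect_equal(as.numeric(cd$v), 2)

  # random sets vs brute-force double loop
  set.seed(56)
  for (rep in 1:5) {
    X <- matrix(rnorm(15), 5, 3)
    Y <- matrix(rnorm(21), 7, 3)
    tp <- ad$ad_tape()
    cd <- ad$ad_chamfer(tp, ad$ad_const(tp, X), Y, 5, 7)
    d2 <- function(a, b) sum((a - b)^2)
    fwd <- mean(apply(X, 1, function(x) {
      min(apply(Y, 1, d2, b = x))
    }))
    bwd <- mean(apply(Y, 1, function(y) {
      min(apply(X, 1, d2, b = y))
    }))
    expect_equal(as.numeric(cd$v), fwd + bwd, tolerance = 1e-12)
  }

  # gradient w.r.t. the movable set
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(18), 6, 3)
  grad_check(function(tp, x) {
    ad$ad_mean(tp, ad$ad_chamfer(tp, x, Y, 4, 6))
  }, X, tol = 1e-5)
})

test_that("backward sweep accumulates through shared sub-expressions", {
  X <- matrix(1:6 / 10, 2, 3)
  tp <- ad$ad_tape()
  leaf <- ad$ad_leaf(tp, X)
  # leaf feeds two consumers; gradients must sum
  a <- ad$ad_scalar_mul(tp, leaf, 2)
  b <- ad$ad_mul(tp, leaf, leaf)
  out <- ad$ad_sum(tp, ad$ad_add(tp, a, b))
  ad$ad_backward(tp, out)
  expect_equal(leaf$g, matrix(2 + 2 * as.numeric(X), 2, 3),
               tolerance = 1e-12)
})
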