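# Shared fixtures: a small phantom (coarser surface than the default so the
# suite stays fast) and a few geometry helpers. Heavyweight objects are
# cached per session.

.fixtures <- new.env(parent = emptyenv())

test_phantom <- function(seed = 101, n_points = 4000) {
  key <- sprintf("phantom_%d_%d", seed, n_points)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_phantom(
      seed = seed, params = phantom_params(n_surface_points = n_points))
  }
  .fixtures[[key]]
}

# unit tetrahedron vertices: the canonical non-degenerate 4-point set
tetrahedron <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

expect_transforms_equal <- function(a, b, tol = 1e-9) {
  expect_lt(quat_angle_deg(a$q, b$q), tol * 180 / pi)
  expect_lt(max(abs(a$t - b$t)), tol)
}

# numeric central-difference gradient of f: R^n -> R
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# tiny network + dataset for training-path tests
test_tiny_dataset <- function(n_trials = 60, seed = 21) {
  key <- sprintf("tinyds_%d_%d", n_trials, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_dataset(test_phantom(), n_trials, seed = seed)
  }
  .fixtures[[key]]
}

test_tiny_model <- function() {
  if (is.null(.fixtures$tiny_model)) {
    .fixtures$tiny_model <- refine_net_init(
      refine_net_config(width_scale = 0.0625, n_iterations = 2),
      n_landmarks = 6, n_region_points = 48, seed = 3)
  }
  .fixtures$tiny_model
}
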