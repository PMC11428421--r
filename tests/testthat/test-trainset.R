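# Training-set generation: PCA standardization, candidate regions, trial
# simulation, supervised records, dataset splits.

test_that("pca standardization centres, diagonalizes and fits a unit sphere", {
  ph <- test_phantom()
  std <- pca_standardize(ph$surface)
  X <- std$cloud
  expect_lt(max(abs(colMeans(X))), 1e-9)
  expect_lte(max(sqrt(rowSums(X^2))), 1 + 1e-12)
  C <- crossprod(X) / nrow(X)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-9)
  expect_true(all(diff(diag(C)) <= 1e-12)) # descending variances
  expect_equal(det(std$info$rotation), 1, tolerance = 1e-9)
})

test_that("standardized covariance matches the eigendecomposition oracle", {
  set.seed(19)
  X <- matrix(rnorm(900), ncol = 3) %*% diag(c(40, 15, 4)) +
    matrix(rep(c(10, -5, 30), each = 300), ncol = 3)
  std <- pca_standardize(X)
  ev <- sort(eigen(stats::cov(X) * (nrow(X) - 1) / nrow(X))$values,
             decreasing = TRUE)
  C <- crossprod(std$cloud) / nrow(X)
  expect_equal(diag(C) * std$info$scale^2, ev, tolerance = 1e-9)
})

test_that("standardization is idempotent and invertible", {
  ph <- test_phantom()
  std <- pca_standardize(ph$surface)
  again <- pca_standardize(std$cloud)
  expect_equal(abs(diag(again$info$rotation)), rep(1, 3), tolerance = 1e-6)
  back <- destandardize_points(std$info, std$cloud)
  expect_equal(back, ph$surface$points, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_standardize(cbind(1:9, (1:9) * 2, 0 * 1:9)), "degeneracy")
})

test_that("transform conjugation between frames is exact", {
  ph <- test_phantom()
  std <- pca_standardize(ph$surface)
  set.seed(29)
  T_mm <- random_rigid_transform(40)
  T_std <- standardize_transform(std$info, T_mm)
  expect_transforms_equal(destandardize_transform(std$info, T_std), T_mm,
                          tol = 1e-9)
  # acting in either frame agrees
  P <- ph$surface$points[1:50, ]
  via_std <- destandardize_points(
    std$info, rt_apply(T_std, standardize_points(std$info, P)))
  expect_equal(via_std, rt_apply(T_mm, P), tolerance = 1e-8)
  # the scale-only special case: identity rotation, zero centroid
  info <- structure(list(rotation = diag(3), centroid = c(0, 0, 0),
                         scale = 120), class = "standardization_info")
  out <- destandardize_transform(info, rigid_transform(
    translation = c(0.01, 0, 0)))
  expect_equal(out$t, c(1.2, 0, 0), tolerance = 1e-12)
})

test_that("candidate regions are euclidean-ball surface intersections", {
  grid <- as.matrix(expand.grid(x = seq(-10, 10), y = 0, z = seq(-10, 10)))
  lm <- landmark_set("c", 0, 0, 0)
  regions <- build_candidate_regions(grid, lm, radius_mm = 5)
  brute <- sum(sqrt(rowSums(grid^2)) <= 5)
  expect_equal(length(regions$c$index), brute)
  expect_true(all(sqrt(rowSums(regions$c$points^2)) <= 5))
  # shrinking radius leaves only the landmark itself
  tiny <- build_candidate_regions(grid, lm, radius_mm = 0.5)
  expect_equal(nrow(tiny$c$points), 1)
  expect_equal(as.numeric(tiny$c$points), c(0, 0, 0))
  expect_error(build_candidate_regions(grid, lm, radius_mm = 12),
               "config error")
  far <- landmark_set("f", 100, 100, 100)
  expect_error(build_candidate_regions(grid, far, 5), "geometry error")
})

test_that("region clouds have fixed size and span centre to rim", {
  ph <- test_phantom()
  rc <- candidate_region_cloud(ph$surface, ph$landmarks, 10, k_per_region = 8)
  expect_equal(nrow(rc$points), 6 * 8)
  expect_equal(rc$region, rep(1:6, each = 8))
  L <- as.matrix(ph$landmarks[, c("x", "y", "z")])
  for (i in 1:6) {
    d <- sqrt(rowSums(sweep(rc$points[rc$region == i, ], 2, L[i, ])^2))
    expect_lt(min(d), 1e-9)   # the landmark itself is included
    expect_lte(max(d), 10)
  }
})

test_that("trial simulation is seeded, stratified and surface-bound", {
  ph <- test_phantom()
  regions <- build_candidate_regions(ph$surface, ph$landmarks, 10)
  t1 <- simulate_trial(regions, 0, seed = 5)
  t2 <- simulate_trial(regions, 0, seed = 5)
  expect_identical(as_tibble(t1$landmarks), as_tibble(t2$landmarks))
  # picks are region members when no deformation is applied
  for (i in seq_along(regions)) {
    d2 <- rowSums(sweep(regions[[i]]$points, 2,
                        as.matrix(t1$landmarks[i, c("x", "y", "z")]))^2)
    expect_lt(min(d2), 1e-18)
  }
  # drawn magnitudes cover the five 2 mm bins near-uniformly
  bins <- unlist(lapply(1:300, function(s) {
    simulate_trial(regions, 0, seed = s)$bin
  }))
  prop <- as.numeric(table(factor(bins, levels = 1:5))) / length(bins)
  expect_true(all(prop > 0.12 & prop < 0.30))
})

test_that("deformation displaces picks along normals at the configured scale", {
  ph <- test_phantom()
  regions <- build_candidate_regions(ph$surface, ph$landmarks, 10)
  disp <- unlist(lapply(1:200, function(s) {
    a <- simulate_trial(regions, 0, seed = s)$landmarks
    b <- simulate_trial(regions, 0.5, seed = s)$landmarks # same RNG draws
    sqrt(rowSums((as.matrix(a[, c("x", "y", "z")]) -
                    as.matrix(b[, c("x", "y", "z")]))^2))
  }))
  # |N(0, 0.5)| has mean 0.5 * sqrt(2/pi) ~ 0.399
  expect_equal(mean(disp), 0.5 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("records store the corrective transform that undoes the coarse fit", {
  ph <- test_phantom()
  # zero localization error: picks equal the landmarks, correction = identity
  rec0 <- make_record(ph$landmarks, ph$landmarks)
  expect_transforms_equal(rec0$T_gt, rt_identity(), tol = 1e-9)
  expect_equal(rec0$X_coarse, as.matrix(ph$landmarks[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)

  regions <- build_candidate_regions(ph$surface, ph$landmarks, 10)
  tr <- simulate_trial(regions, 0, seed = 77)
  rec <- make_record(tr$landmarks, ph$landmarks)
  # applying the label to the coarse-registered picks recovers the true
  # patient geometry (the picks), i.e. T_gt o T_coarse = identity
  expect_equal(rt_apply(rec$T_gt, rec$X_coarse),
               as.matrix(tr$landmarks[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_transforms_equal(rt_compose(rec$T_gt, rec$T_coarse), rt_identity(),
                          tol = 1e-9)
})

test_that("the label beats 10,000 random corrections at pose recovery", {
  ph <- test_phantom()
  regions <- build_candidate_regions(ph$surface, ph$landmarks, 10)
  tr <- simulate_trial(regions, 0, seed = 13)
  rec <- make_record(tr$landmarks, ph$landmarks)
  truth <- as.matrix(tr$landmarks[, c("x", "y", "z")])
  mse_label <- paired_mse(rt_apply(rec$T_gt, rec$X_coarse), truth)
  set.seed(14)
  mse_rand <- replicate(10000, {
    paired_mse(rt_apply(random_rigid_transform(10), rec$X_coarse), truth)
  })
  expect_true(all(mse_label <= mse_rand))
})

test_that("datasets split per the ratio with zero duplicates", {
  ds <- test_tiny_dataset(n_trials = 60)
  tab <- table(ds$records$split)
  expect_equal(as.integer(tab[c("train", "validation", "test")]),
               c(48L, 6L, 6L))
  keys <- vapply(ds$records$X, function(m) {
    paste(round(m * 1e4), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(generate_dataset(test_phantom(), 60, ratios = c(0, 0, 0)),
               "config error")
  ds10 <- generate_dataset(test_phantom(), 10, seed = 4)
  expect_equal(as.integer(table(ds10$records$split)[c("train", "validation",
                                                      "test")]),
               c(8L, 1L, 1L))
})

test_that("dataset generation is deterministic and round-trips to disk", {
  a <- generate_dataset(test_phantom(), 20, seed = 6)
  b <- generate_dataset(test_phantom(), 20, seed = 6)
  expect_identical(a$records$X, b$records$X)
  expect_identical(a$records$split, b$records$split)

  dir <- tempfile()
  write_dataset(a, dir)
  back <- read_dataset(dir)
  expect_equal(back$records$X[[7]], a$records$X[[7]], tolerance = 1e-10)
  expect_equal(back$records$q_gt[[3]], a$records$q_gt[[3]],
               tolerance = 1e-10)
  expect_equal(back$manifest$standardization[[1]]$scale,
               a$manifest$standardization[[1]]$scale, tolerance = 1e-10)
  expect_equal(back$manifest$region_clouds[[1]],
               a$manifest$region_clouds[[1]], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("labels transported back to mm reproduce the mm-space alignment", {
  ph <- test_phantom()
  std <- pca_standardize(ph$surface)
  regions <- build_candidate_regions(ph$surface, ph$landmarks, 10)
  tr <- simulate_trial(regions, 0, seed = 23)
  sim_mm <- as.matrix(tr$landmarks[, c("x", "y", "z")])
  ref_mm <- as.matrix(ph$landmarks[, c("x", "y", "z")])
  # record built in the standardized frame, as during dataset generation
  rec_std <- make_record(
    landmark_set(tr$landmarks$name,
                 standardize_points(std$info, sim_mm)[, 1],
                 standardize_points(std$info, sim_mm)[, 2],
                 standardize_points(std$info, sim_mm)[, 3]),
    landmark_set(ph$landmarks$name,
                 standardize_points(std$info, ref_mm)[, 1],
                 standardize_points(std$info, ref_mm)[, 2],
                 standardize_points(std$info, ref_mm)[, 3]))
  T_mm <- destandardize_transform(std$info, rec_std$T_gt)
  X_coarse_mm <- destandardize_points(std$info, rec_std$X_coarse)
  expect_equal(rt_apply(T_mm, X_coarse_mm), sim_mm, tolerance = 1e-6,
               ignore_attr = TRUE)
})
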