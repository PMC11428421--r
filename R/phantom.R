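# Synthetic head phantoms for desk-scale validation of the registration
# protocol: a parametric face-like surface (superellipsoid cranium + nose
# ridge + brow/orbit/cheek features), six anatomical landmarks, a 27-point
# internal target grid at three depths, and five surface acquisition
# patterns mimicking restricted intraoperative probing.

# --- deterministic RNG scoping -------------------------------------------

#' Evaluate code under a fixed seed without touching the caller's RNG
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`; the global RNG state is left as it was.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and stream labels
#'
#' All randomness in a study flows from one master seed; per-trial seeds are
#' derived with an integer hash so every trial is independently reproducible.
#' Results stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param ... Further integer or character labels identifying the stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    ks <- if (is.character(p)) utf8ToInt(p) else as.numeric(p)
    for (k in ks) h <- (h * 1000003 + (as.numeric(k) %% 2147483647) + 12289) %% 2147483647
  }
  as.integer(h %% 2147483562 + 1)
}

# --- parametric surface ---------------------------------------------------

# Evenly distributed directions on the unit sphere (deterministic).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (1 + sqrt(5)) * pi * i
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# Angular Gaussian bump profile. Isotropic: amp * exp(-angle^2 / (2 s^2)).
# Anisotropic (sigma2 given): the angular offset is split into components
# along two tangent axes at `dir` (t1 ~ azimuthal/left-right, t2 ~ its
# complement), with separate widths — this shapes ridges and creases
# (nasal bridge, orbital rims) rather than round bosses.
ang_bump <- function(U, dir, amp, sigma, sigma2 = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  if (is.null(sigma2)) {
    cosang <- pmin(1, pmax(-1, U %*% dir))
    out <- amp * exp(-(acos(cosang))^2 / (2 * sigma^2))
    out[cosang < 0] <- 0
    return(out)
  }
  up <- c(0, 0, 1)
  t1 <- c(dir[2] * up[3] - dir[3] * up[2],
          dir[3] * up[1] - dir[1] * up[3],
          dir[1] * up[2] - dir[2] * up[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(dir[2] * t1[3] - dir[3] * t1[2],
          dir[3] * t1[1] - dir[1] * t1[3],
          dir[1] * t1[2] - dir[2] * t1[1])
  a1 <- asin(pmin(1, pmax(-1, U %*% t1)))
  a2 <- asin(pmin(1, pmax(-1, U %*% t2)))
  behind <- U %*% dir < 0
  out <- amp * exp(-a1^2 / (2 * sigma^2) - a2^2 / (2 * sigma2^2))
  out[behind] <- 0
  out
}

# Radial-distance function factory for one phantom's head shape.
# U: n x 3 unit directions; returns radius in mm per direction.
make_radial_fn <- function(half_axes, exponent, features) {
  force(half_axes); force(exponent); force(features)
  function(U) {
    if (is.null(dim(U))) U <- matrix(U, ncol = 3)
    base <- (abs(U[, 1] / half_axes[1])^exponent +
             abs(U[, 2] / half_axes[2])^exponent +
             abs(U[, 3] / half_axes[3])^exponent)^(-1 / exponent)
    bump <- 0
    for (f in features) {
      bump <- bump + ang_bump(U, f$dir, f$amp, f$sigma, f$sigma2)
    }
    base + bump
  }
}

# Continuous surface point in a given direction.
surface_point_at <- function(phantom, dir) {
  if (is.null(dim(dir))) dir <- matrix(dir, ncol = 3)
  U <- dir / sqrt(rowSums(dir^2))
  r <- phantom$radial_fn(U)
  U * r
}

# Outward unit normal of the continuous surface at direction(s) U (n x 3),
# by finite differences of the radial parameterization.
surface_normal_at <- function(phantom, U, eps = 1e-5) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  # two tangent directions per point
  ref <- matrix(rep(c(0, 0, 1), each = nrow(U)), ncol = 3)
  flip <- abs(U[, 3]) > 0.9
  ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  t1 <- cbind(U[, 2] * ref[, 3] - U[, 3] * ref[, 2],
              U[, 3] * ref[, 1] - U[, 1] * ref[, 3],
              U[, 1] * ref[, 2] - U[, 2] * ref[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(U[, 2] * t1[, 3] - U[, 3] * t1[, 2],
              U[, 3] * t1[, 1] - U[, 1] * t1[, 3],
              U[, 1] * t1[, 2] - U[, 2] * t1[, 1])
  p0 <- surface_point_at(phantom, U)
  p1 <- surface_point_at(phantom, U + eps * t1)
  p2 <- surface_point_at(phantom, U + eps * t2)
  v1 <- p1 - p0
  v2 <- p2 - p0
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # orient outward
  s <- sign(rowSums(nrm * U))
  s[s == 0] <- 1
  nrm * s
}

# --- phantom construction -------------------------------------------------

#' Default shape parameters for the synthetic head phantom
#'
#' Half-axes are in mm (adult-head scale: ~144 mm wide, ~184 mm deep,
#' ~200 mm tall); the face looks along +y, +z is superior, +x is the
#' subject's left. `perturb_sd` is the relative standard deviation applied
#' (per seed) to half-axes and feature amplitudes so that different seeds
#' give the distinct head shapes of a multi-phantom study.
#'
#' @param n_surface_points Number of surface sample points (default 8000).
#' @param half_axes Superellipsoid half-axes (x, y, z) in mm.
#' @param exponent Superellipsoid exponent (2 = ellipsoid; higher = boxier).
#' @param perturb_sd Relative sd of per-seed shape perturbations.
#' @param points_per_trial Probe points collected per acquisition trial.
#' @return A named list of parameters for [make_phantom()].
#' @export
phantom_params <- function(n_surface_points = 8000,
                           half_axes = c(72, 92, 100),
                           exponent = 2.3,
                           perturb_sd = 0.04,
                           points_per_trial = 200) {
  if (any(half_axes <= 0) || n_surface_points <= 0) {
    stop("phantom size parameters must be positive")
  }
  list(n_surface_points = as.integer(n_surface_points),
       half_axes = half_axes, exponent = exponent,
       perturb_sd = perturb_sd,
       points_per_trial = as.integer(points_per_trial))
}

# Facial feature set (directions in canonical frame, amplitudes mm).
# Widths are chosen so landmark neighbourhoods carry realistic curvature
# (nasal tip radius ~5-10 mm, bridge ridge, orbital rim creases at the
# canthi): the localization-error correction is only identifiable from the
# local surface shape at the picks, as on a real face.
base_features <- function() {
  iso <- function(dir, amp, sigma) list(dir = dir, amp = amp, sigma = sigma,
                                        sigma2 = NULL)
  ani <- function(dir, amp, s1, s2) list(dir = dir, amp = amp, sigma = s1,
                                         sigma2 = s2)
  list(
    nose        = iso(c(0, 1, -0.12), 22, 0.16),
    nose_tip    = iso(c(0, 1, -0.12), 7, 0.055),
    # narrow vertical ridge: the nasal bridge (x-width < z-extent)
    bridge      = ani(c(0, 1, 0.04), 10, 0.07, 0.22),
    brow_l      = ani(c(0.28, 1, 0.25), 6, 0.16, 0.07),
    brow_r      = ani(c(-0.28, 1, 0.25), 6, 0.16, 0.07),
    orbit_l     = iso(c(0.30, 1, 0.10), -7, 0.11),
    orbit_r     = iso(c(-0.30, 1, 0.10), -7, 0.11),
    # orbital-rim creases: sharp grooves at the inner/outer eye corners
    crease_il   = ani(c(0.15, 1, 0.08), -4, 0.05, 0.10),
    crease_ir   = ani(c(-0.15, 1, 0.08), -4, 0.05, 0.10),
    crease_ol   = ani(c(0.43, 1, 0.12), -3.5, 0.055, 0.11),
    crease_or   = ani(c(-0.43, 1, 0.12), -3.5, 0.055, 0.11),
    # canthal pits: the eye corners are point-like anatomy (lacrimal
    # caruncle medially, the meeting of the lid margins laterally) —
    # locally bowl-shaped, which is what makes them pickable landmarks
    pit_il      = iso(c(0.15, 1, 0.08), -2.5, 0.033),
    pit_ir      = iso(c(-0.15, 1, 0.08), -2.5, 0.033),
    pit_ol      = iso(c(0.43, 1, 0.12), -2.5, 0.033),
    pit_or      = iso(c(-0.43, 1, 0.12), -2.5, 0.033),
    # nasofrontal depression at the nasion, and the sharp nasal apex
    pit_nasion  = iso(c(0, 1, 0.12), -2, 0.03),
    apex        = iso(c(0, 1, -0.12), 2.5, 0.025),
    cheek_l     = iso(c(0.45, 1, -0.25), 4, 0.20),
    cheek_r     = iso(c(-0.45, 1, -0.25), 4, 0.20),
    chin        = iso(c(0, 1, -0.75), 6, 0.18),
    # ears and the occiput anchor rotation for surface matching, as on a
    # real head; the occiput is offset to one side so no mirror symmetry
    # survives
    ear_l       = ani(c(1, -0.02, 0.03), 16, 0.10, 0.16),
    ear_r       = ani(c(-1, -0.02, 0.03), 16, 0.10, 0.16),
    occiput     = iso(c(0.18, -1, -0.15), 9, 0.35),
    # one-sided feature so the face has no mirror symmetry either
    asym        = iso(c(0.55, 0.8, 0.05), 2.5, 0.25)
  )
}

# Nominal landmark directions (canonical frame).
landmark_directions <- function() {
  rbind(
    nasion             = c(0, 1, 0.12),
    nose_tip           = c(0, 1, -0.12),
    inner_canthus_left = c(0.15, 1, 0.08),
    inner_canthus_right = c(-0.15, 1, 0.08),
    outer_canthus_left = c(0.43, 1, 0.12),
    outer_canthus_right = c(-0.43, 1, 0.12)
  )
}

#' Generate a synthetic head phantom
#'
#' Builds a face-like asymmetric surface (superellipsoid cranium with nose,
#' brow, orbit, cheek and chin features plus a one-sided bump that removes
#' mirror symmetry), six anatomical landmarks snapped onto sampled surface
#' points (nasion, nose tip, inner/outer canthi), a 3 layers x 3 rows x
#' 3 depths internal target grid at 30/70/110 mm beneath the facial surface,
#' and five boolean acquisition-pattern masks. Identical `(params, seed)`
#' give a bit-identical phantom.
#'
#' @param seed Integer seed; different seeds perturb the head shape, playing
#'   the role of distinct phantoms in a multi-phantom study.
#' @param params Parameter list from [phantom_params()].
#' @return A `phantom_model`: list with `surface` ([point_cloud()] with
#'   normals), `landmarks` ([landmark_set()]), `targets` (tibble with layer,
#'   row, depth_mm, x, y, z and entry point), `patterns` (named list of
#'   logical masks), `seed`, `params`, and the continuous radial/normal
#'   functions used for resampling.
#' @export
make_phantom <- function(seed = 1, params = phantom_params()) {
  if (params$n_surface_points < 500) {
    stop("resolution error: need at least 500 surface points for a usable phantom")
  }
  feats <- base_features()
  half_axes <- params$half_axes
  with_seed(derive_seed(seed, "shape"), {
    half_axes <- half_axes * (1 + stats::rnorm(3, 0, params$perturb_sd))
    for (i in seq_along(feats)) {
      feats[[i]]$amp <- feats[[i]]$amp * (1 + stats::rnorm(1, 0, 3 * params$perturb_sd))
    }
  })

  radial_fn <- make_radial_fn(half_axes, params$exponent, feats)
  phantom <- list(radial_fn = radial_fn, params = params, seed = seed,
                  half_axes = half_axes, features = feats)

  U <- fibonacci_sphere(params$n_surface_points)
  pts <- surface_point_at(phantom, U)
  nrm <- surface_normal_at(phantom, U)
  phantom$surface <- point_cloud(pts, nrm, space = "synthetic")
  phantom$directions <- U

  # landmarks: snap nominal directions to exact sampled surface points
  lm_dirs <- landmark_directions()
  lm_cont <- surface_point_at(phantom, lm_dirs)
  nn <- .nn_kdtree(lm_cont, pts)
  phantom$landmark_index <- nn$index
  phantom$landmarks <- landmark_set(rownames(lm_dirs),
                                    pts[nn$index, 1], pts[nn$index, 2],
                                    pts[nn$index, 3])

  # internal target grid: 3 layers (z) x 3 rows (x) x 3 depths along the
  # inward surface normal from mid-face entry points
  grid <- expand.grid(layer = c("top", "middle", "bottom"),
                      row = 1:3, depth_mm = c(30, 70, 110),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  zlev <- c(top = 0.30, middle = 0.0, bottom = -0.30)
  xlev <- c(-0.25, 0, 0.25)
  entry_dir <- cbind(xlev[grid$row], 1, zlev[grid$layer])
  entry <- surface_point_at(phantom, entry_dir)
  en <- surface_normal_at(phantom, entry_dir)
  tp <- entry - en * grid$depth_mm
  phantom$targets <- tibble::tibble(
    layer = grid$layer, row = grid$row, depth_mm = grid$depth_mm,
    x = tp[, 1], y = tp[, 2], z = tp[, 3],
    entry_x = entry[, 1], entry_y = entry[, 2], entry_z = entry[, 3]
  )

  phantom$patterns <- build_pattern_masks(phantom)
  class(phantom) <- "phantom_model"
  phantom
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> seed %d: %d surface points, %d landmarks, %d targets\n",
              x$seed, n_points(x$surface), nrow(x$landmarks), nrow(x$targets)))
  cat("  patterns:",
      paste(sprintf("%s(%d)", names(x$patterns), vapply(x$patterns, sum, 1L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Acquisition pattern names
#'
#' The five probing patterns of the validation design, from the full face to
#' deliberately restricted regions: `forehead_nose` (#1), `entire_face`
#' (#2), `face_borderline` (#3), `forehead` (#4), `above_lip` (#5 — above
#' the lip: forehead + nose + around the orbits).
#'
#' @return Character vector of the five pattern names, in order.
#' @export
pattern_names <- function() {
  c("forehead_nose", "entire_face", "face_borderline", "forehead", "above_lip")
}

# Region predicates in the canonical frame over sampled surface points.
build_pattern_masks <- function(phantom) {
  U <- phantom$directions
  pts <- phantom$surface$points
  zn <- pts[, 3] / phantom$half_axes[3]
  # angle to the facing direction (+y)
  alpha <- acos(pmin(1, pmax(-1, U[, 2])))
  ang_to <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    acos(pmin(1, pmax(-1, U %*% dir)))
  }
  forehead <- alpha < (65 * pi / 180) & zn >= 0.25 & zn <= 0.66
  nose <- ang_to(c(0, 1, -0.05)) < 0.24 | ang_to(c(0, 1, 0.05)) < 0.18
  orbits <- ang_to(c(0.32, 1, 0.11)) < 0.26 | ang_to(c(-0.32, 1, 0.11)) < 0.26
  entire_face <- alpha < (62 * pi / 180) & zn >= -0.62 & zn <= 0.66
  borderline <- alpha >= (55 * pi / 180) & alpha <= (75 * pi / 180) &
    zn >= -0.62 & zn <= 0.80
  above_lip <- (entire_face & zn > -0.15) | forehead | nose | orbits
  masks <- list(
    forehead_nose = forehead | nose,
    entire_face = entire_face,
    face_borderline = borderline,
    forehead = forehead,
    above_lip = above_lip
  )
  empty <- vapply(masks, sum, 1L) == 0L
  if (any(empty)) {
    stop("pattern error: empty acquisition mask(s): ",
         paste(names(masks)[empty], collapse = ", "))
  }
  masks
}

#' Simulate an intraoperative surface acquisition
#'
#' Subsamples the phantom surface within one acquisition-pattern mask, maps
#' the points into patient space by `true_pose`, and adds isotropic Gaussian
#' probe noise — the synthetic stand-in for collecting surface points with a
#' tracked probe.
#'
#' @param phantom A [make_phantom()] model.
#' @param pattern Pattern name (see [pattern_names()]).
#' @param true_pose `rigid_transform` mapping image space to patient space
#'   (the unknown the registration pipeline must recover).
#' @param noise_sigma_mm Isotropic Gaussian noise sd in mm (default 0.3,
#'   typical optical-tracker jitter).
#' @param n_points Points to sample (default: phantom's `points_per_trial`).
#' @param seed Integer seed for subsampling and noise.
#' @return A patient-space [point_cloud()]; the sampled image-space indices
#'   and `true_pose` are attached as fields `index` and `true_pose`.
#' @export
acquire_patient_cloud <- function(phantom, pattern, true_pose = rt_identity(),
                                  noise_sigma_mm = 0.3, n_points = NULL,
                                  seed = 1) {
  stopifnot(inherits(phantom, "phantom_model"))
  if (noise_sigma_mm < 0) stop("noise_sigma_mm must be >= 0")
  if (is.character(pattern)) {
    if (!pattern %in% names(phantom$patterns)) {
      stop("pattern error: unknown pattern '", pattern, "'")
    }
    mask <- phantom$patterns[[pattern]]
  } else {
    mask <- pattern
  }
  idx_pool <- which(mask)
  if (length(idx_pool) == 0) stop("pattern error: empty acquisition mask")
  n_points <- if (is.null(n_points)) phantom$params$points_per_trial else n_points
  with_seed(derive_seed(seed, "acquire"), {
    idx <- if (length(idx_pool) > n_points) {
      sort(sample(idx_pool, n_points))
    } else idx_pool
    P <- phantom$surface$points[idx, , drop = FALSE]
    P <- rt_apply(true_pose, P)
    if (noise_sigma_mm > 0) {
      P <- P + matrix(stats::rnorm(length(P), 0, noise_sigma_mm), ncol = 3)
    }
    out <- point_cloud(P, space = "patient")
    out$index <- idx
    out$true_pose <- true_pose
    out
  })
}

#' Simulate manual landmark picking with localization error
#'
#' Each landmark is re-picked on the continuous phantom surface at an offset
#' drawn uniformly from `localization_error_mm = c(lo, hi)` (mm, Euclidean
#' distance from the true landmark, measured on the surface as a probe pick
#' would land), then mapped into patient space by `true_pose`.
#'
#' @inheritParams acquire_patient_cloud
#' @param localization_error_mm Length-2 range `c(lo, hi)` in mm within
#'   `[0, 10]`.
#' @return A patient-space [landmark_set()] of noisy picks.
#' @export
pick_landmarks <- function(phantom, localization_error_mm = c(1, 5),
                           true_pose = rt_identity(), seed = 1) {
  stopifnot(inherits(phantom, "phantom_model"))
  rng <- sort(as.numeric(localization_error_mm))
  if (length(rng) != 2 || rng[1] < 0 || rng[2] > 10) {
    stop("config error: localization error range must lie within [0, 10] mm")
  }
  lm <- phantom$landmarks
  L <- cbind(lm$x, lm$y, lm$z)
  picks <- L
  with_seed(derive_seed(seed, "pick"), {
    for (i in seq_len(nrow(L))) {
      r <- stats::runif(1, rng[1], rng[2])
      if (r > 0) picks[i, ] <- surface_offset_point(phantom, L[i, ], r)
    }
  })
  picks <- rt_apply(true_pose, picks)
  landmark_set(lm$name, picks[, 1], picks[, 2], picks[, 3])
}

# A point on the continuous surface at Euclidean distance r from p0, found by
# stepping along a random tangent direction and reprojecting radially.
surface_offset_point <- function(phantom, p0, r) {
  u0 <- p0 / sqrt(sum(p0^2))
  n0 <- as.numeric(surface_normal_at(phantom, u0))
  # random tangent direction
  v <- stats::rnorm(3)
  v <- v - sum(v * n0) * n0
  v <- v / sqrt(sum(v^2))
  f <- function(s) {
    p <- as.numeric(surface_point_at(phantom, p0 + s * v))
    sqrt(sum((p - p0)^2)) - r
  }
  # bracket the offset; the radial map is locally near-isometric so the
  # solution is near s = r
  hi <- r
  while (f(hi) < 0 && hi < 8 * r + 10) hi <- hi * 1.6
  s <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  as.numeric(surface_point_at(phantom, p0 + s * v))
}

#' Write a phantom to plain-text files
#'
#' Surface as ASCII PLY, landmarks and targets as CSV, pattern masks as CSV
#' of surface point indices, and a YAML manifest with seed and parameters.
#'
#' @param phantom A `phantom_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ply(phantom$surface, file.path(dir, "surface.ply"))
  write_landmarks_csv(phantom$landmarks, file.path(dir, "landmarks.csv"))
  utils::write.csv(as.data.frame(phantom$targets),
                   file.path(dir, "targets.csv"), row.names = FALSE)
  masks <- dplyr::bind_rows(lapply(names(phantom$patterns), function(nm) {
    tibble::tibble(pattern = nm, point_index = which(phantom$patterns[[nm]]))
  }))
  utils::write.csv(masks, file.path(dir, "pattern_masks.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = phantom$seed,
                        params = phantom$params,
                        half_axes = as.numeric(phantom$half_axes)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
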