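# Automatic training-set generation for the refinement network: PCA
# standardization of the image cloud into the unit sphere, candidate
# localization-error regions around each landmark, stratified simulation of
# noisy landmark picks, coarse registration of each simulated set, and
# supervised records whose label is the corrective transform that undoes the
# localization-error-induced misregistration.

# --- PCA standardization --------------------------------------------------

#' Standardize a point cloud into the unit sphere via PCA
#'
#' Centers the cloud, rotates its principal axes onto the Cartesian axes
#' (descending variance), and scales by the maximum point norm so the result
#' fits inside the unit sphere. Axis signs are canonicalized (largest-
#' magnitude component of each axis positive) and the rotation is forced to
#' det +1, so standardization is deterministic and idempotent.
#'
#' @param cloud A [point_cloud()] or N x 3 matrix (N >= 4, non-coplanar).
#' @return A list: `cloud` (standardized N x 3 matrix), `info` (a
#'   `standardization_info` with `rotation` (3x3), `centroid` (mm), `scale`
#'   (mm, the unit-sphere radius divisor)).
#' @export
pca_standardize <- function(cloud) {
  X <- as_point_matrix(cloud)
  if (nrow(X) < 4) stop("degeneracy error: need at least 4 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  C <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[3] < 1e-12 * max(eg$values[1], 1)) {
    stop("degeneracy error: rank-deficient covariance (coplanar or collinear cloud)")
  }
  V <- eg$vectors
  # canonical axis signs: largest-|component| of each eigenvector positive
  for (j in 1:3) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  R <- t(V) # rotation mapping cloud axes onto Cartesian axes
  Xr <- Xc %*% V
  s <- max(sqrt(rowSums(Xr^2)))
  info <- structure(list(rotation = R, centroid = ctr, scale = s),
                    class = "standardization_info")
  list(cloud = Xr / s, info = info)
}

#' Apply / invert / conjugate a standardization
#'
#' `standardize_points` maps mm coordinates into the standardized
#' (unit-sphere) frame, `destandardize_points` maps back;
#' `destandardize_transform` converts a rigid transform expressed in the
#' standardized frame into the equivalent mm-space transform by conjugation
#' `T_mm = S^-1 T_std S` (rotations conjugate by the PCA rotation;
#' translations pick up the scale), and `standardize_transform` is its
#' inverse.
#'
#' @param info A `standardization_info`.
#' @param points N x 3 matrix.
#' @param transform A `rigid_transform`.
#' @return Transformed points / transform.
#' @export
standardize_points <- function(info, points) {
  P <- as_point_matrix(points)
  sweep(P, 2, info$centroid) %*% t(info$rotation) / info$scale
}

#' @rdname standardize_points
#' @export
destandardize_points <- function(info, points) {
  P <- as_point_matrix(points)
  sweep((P * info$scale) %*% info$rotation, 2, info$centroid, "+")
}

#' @rdname standardize_points
#' @export
destandardize_transform <- function(info, transform) {
  if (info$scale <= 0) stop("config error: standardization scale must be > 0")
  Rs <- info$rotation
  Rt <- quat_to_matrix(transform$q)
  R_mm <- t(Rs) %*% Rt %*% Rs
  t_mm <- info$centroid - as.numeric(R_mm %*% info$centroid) +
    info$scale * as.numeric(t(Rs) %*% transform$t)
  rigid_transform(matrix_to_quat(R_mm), t_mm)
}

#' @rdname standardize_points
#' @export
standardize_transform <- function(info, transform) {
  if (info$scale <= 0) stop("config error: standardization scale must be > 0")
  Rs <- info$rotation
  Rt <- quat_to_matrix(transform$q)
  R_std <- Rs %*% Rt %*% t(Rs)
  t_std <- as.numeric(Rs %*% (as.numeric(Rt %*% info$centroid) + transform$t -
                                info$centroid)) / info$scale
  rigid_transform(matrix_to_quat(R_std), t_std)
}

# --- candidate regions ----------------------------------------------------

#' Build candidate localization-error regions around landmarks
#'
#' A candidate region is the set of surface points within `radius_mm` of a
#' landmark — the places an operator's probe pick could plausibly land.
#' The working range extends the known 1–5 mm manual localization error up
#' to 10 mm.
#'
#' @param surface A [point_cloud()] (or N x 3 matrix) of the image surface.
#' @param landmarks A [landmark_set()].
#' @param radius_mm Region radius in mm, in (0, 10].
#' @return A named list of `candidate_region`s: `name`, `index` (surface row
#'   indices), `points` (member coordinates, mm), `normals` (if the surface
#'   has them), `landmark` (mm), `radius_mm`.
#' @export
build_candidate_regions <- function(surface, landmarks, radius_mm = 10) {
  if (radius_mm <= 0 || radius_mm > 10) {
    stop("config error: radius_mm must be in (0, 10]")
  }
  P <- as_point_matrix(surface)
  normals <- if (inherits(surface, "point_cloud")) surface$normals else NULL
  L <- as_point_matrix(landmarks)
  out <- lapply(seq_len(nrow(L)), function(i) {
    d2 <- (P[, 1] - L[i, 1])^2 + (P[, 2] - L[i, 2])^2 + (P[, 3] - L[i, 3])^2
    idx <- which(d2 <= radius_mm^2)
    if (length(idx) == 0) {
      stop("geometry error: landmark '", landmarks$name[i],
           "' has no surface points within ", radius_mm, " mm")
    }
    structure(list(name = landmarks$name[i], index = idx,
                   points = P[idx, , drop = FALSE],
                   normals = if (!is.null(normals)) normals[idx, , drop = FALSE],
                   landmark = L[i, ], radius_mm = radius_mm),
              class = "candidate_region")
  })
  names(out) <- landmarks$name
  out
}

#' Build the fixed-size candidate-region reference cloud
#'
#' The refinement network's reference input: for each landmark,
#' `k_per_region` surface points spanning its candidate region (members
#' sorted by distance to the landmark, sampled evenly across that ranking
#' so the patch is covered from centre to rim; short regions pad by
#' repetition, which max-pooled global features ignore). The same builder
#' runs at training and at inference so the two see identical geometry.
#'
#' @inheritParams build_candidate_regions
#' @param k_per_region Points kept per landmark region (default 8).
#' @return A list: `points` ((n_landmarks * k_per_region) x 3, mm),
#'   `region` (integer region index per row), `k_per_region`.
#' @export
candidate_region_cloud <- function(surface, landmarks, radius_mm = 10,
                                   k_per_region = 8) {
  regions <- build_candidate_regions(surface, landmarks, radius_mm)
  pts <- lapply(regions, function(rg) {
    d <- sqrt(rowSums(sweep(rg$points, 2, rg$landmark)^2))
    ord <- order(d)
    idx <- ord[pmin(length(ord),
                    unique(round(seq(1, length(ord),
                                     length.out = k_per_region))))]
    while (length(idx) < k_per_region) {
      idx <- c(idx, idx[seq_len(min(length(idx), k_per_region - length(idx)))])
    }
    rg$points[idx[seq_len(k_per_region)], , drop = FALSE]
  })
  list(points = do.call(rbind, pts),
       region = rep(seq_along(regions), each = k_per_region),
       k_per_region = as.integer(k_per_region))
}

# --- trial simulation -----------------------------------------------------

n_error_bins <- 5L # 2 mm bins covering (0, 10] mm

#' Simulate one landmark-picking trial
#'
#' For each landmark, draws an error magnitude from a stratified bin (five
#' 2 mm bins over the region radius, bin chosen uniformly so the difficulty
#' distribution is balanced), offsets the landmark by that magnitude in a
#' random direction, and snaps to the nearest candidate-region surface
#' point. Optionally displaces the pick along the local surface normal by
#' Gaussian noise of sd `deform_sigma_mm`, emulating soft-tissue
#' deformation.
#'
#' @param regions Candidate regions from [build_candidate_regions()], one
#'   per landmark.
#' @param deform_sigma_mm Normal-direction deformation sd in mm (0 = off).
#' @param seed Integer seed.
#' @return A list: `landmarks` ([landmark_set()] of simulated picks, mm),
#'   `drawn_mm` (stratified magnitudes drawn), `actual_mm` (realized
#'   offsets), `bin` (per-landmark bin index), `deformed` (flag).
#' @export
simulate_trial <- function(regions, deform_sigma_mm = 0, seed = 1) {
  with_seed(derive_seed(seed, "trial"), simulate_trial_impl(regions, deform_sigma_mm))
}

# RNG-bare core so dataset generation can manage one stream across redraws.
simulate_trial_impl <- function(regions, deform_sigma_mm = 0) {
  k <- length(regions)
  picks <- matrix(0, k, 3)
  drawn <- numeric(k)
  actual <- numeric(k)
  bins <- integer(k)
  members <- integer(k)
  deformed <- deform_sigma_mm > 0
  for (i in seq_len(k)) {
    rg <- regions[[i]]
    width <- rg$radius_mm / n_error_bins
    b <- sample.int(n_error_bins, 1)
    r <- stats::runif(1, (b - 1) * width, b * width)
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    target <- rg$landmark + r * u
    d2 <- rowSums(sweep(rg$points, 2, target)^2)
    j <- which.min(d2)
    picks[i, ] <- rg$points[j, ]
    members[i] <- j
    drawn[i] <- r
    bins[i] <- b
  }
  # deformation noise is drawn after all picks so that the same seed gives
  # the same pick positions with and without augmentation
  if (deformed) {
    for (i in seq_len(k)) {
      rg <- regions[[i]]
      if (!is.null(rg$normals)) {
        picks[i, ] <- picks[i, ] +
          stats::rnorm(1, 0, deform_sigma_mm) * rg$normals[members[i], ]
      }
    }
  }
  for (i in seq_len(k)) {
    actual[i] <- sqrt(sum((picks[i, ] - regions[[i]]$landmark)^2))
  }
  list(landmarks = landmarks_from_matrix(picks, names(regions)),
       drawn_mm = drawn, actual_mm = actual, bin = bins, deformed = deformed)
}

# --- supervised records ---------------------------------------------------

#' Build one supervised training record from a simulated trial
#'
#' The simulated picks are coarse-registered onto the reference landmarks
#' with the SVD paired-point solve (`T_coarse`), giving the model input
#' `X_coarse`. The ground-truth label is the corrective transform
#' `T_gt = invert(T_coarse)`: because the simulated picks live on the true
#' surface, the coarse misregistration is entirely induced by localization
#' error, and undoing it maps the coarse-registered geometry back onto the
#' true patient geometry (applying `T_gt` to `X_coarse` recovers the
#' original picks exactly). Predicting `T_gt` from `(X_coarse, Y_ref)` is
#' the supervised task.
#'
#' @param simulated [landmark_set()] of simulated noisy picks.
#' @param reference [landmark_set()] of reference landmarks (same order).
#' @return A `training_record`: `X_coarse` (N x 3), `Y_ref` (N x 3), `T_gt`,
#'   `T_coarse` (both `rigid_transform`s).
#' @export
make_record <- function(simulated, reference) {
  S <- as_point_matrix(simulated)
  Rf <- as_point_matrix(reference)
  if (nrow(S) != nrow(Rf)) stop("correspondence error: landmark sets differ in length")
  T_coarse <- svd_paired_point_register(S, Rf)
  X_coarse <- rt_apply(T_coarse, S)
  structure(list(X_coarse = X_coarse, Y_ref = Rf,
                 T_gt = rt_invert(T_coarse), T_coarse = T_coarse),
            class = "training_record")
}

# --- dataset generation ---------------------------------------------------

#' Generate the supervised refinement dataset from phantoms
#'
#' Runs `n_trials_per_phantom` unique simulated landmark-picking trials per
#' phantom (duplicates — pick coordinate tuples rounded to 0.1 mm — are
#' redrawn so the requested count of unique combinations is reached),
#' coarse-registers each trial, and stores standardized-frame records with
#' ground-truth corrective transforms. Records are split per phantom into
#' train/validation/test by `ratios`.
#'
#' Trials are simulated in mm space on the image surface; model-facing
#' coordinates (`X`, `Y`) and labels are expressed in each phantom's
#' PCA-standardized unit-sphere frame, with the scale kept in the manifest
#' so translations convert back to mm.
#'
#' @param phantoms List of [make_phantom()] models (or a single one).
#' @param n_trials_per_phantom Trials per phantom (>= 10).
#' @param ratios Length-3 positive split ratios (default `c(8, 1, 1)`).
#' @param radius_mm Candidate-region radius (default 10 mm).
#' @param deform_sigma_mm Deformation-augmentation sd (default 0.5 mm).
#' @param deform_fraction Fraction of trials with deformation (default 0.5).
#' @param seed Master seed.
#' @return A `navreg_dataset`: `records` tibble (one row per trial: split,
#'   phantom seed, trial index, deformed flag, error summaries, list-columns
#'   `X`, `Y` with 6 x 3 standardized coordinates, `q_gt`, `t_gt`) and
#'   `manifest` (seeds, radii, ratios, per-phantom standardization info).
#' @export
generate_dataset <- function(phantoms, n_trials_per_phantom = 5000,
                             ratios = c(8, 1, 1), radius_mm = 10,
                             k_per_region = 8,
                             deform_sigma_mm = 0.5, deform_fraction = 0.5,
                             seed = 1) {
  if (inherits(phantoms, "phantom_model")) phantoms <- list(phantoms)
  if (n_trials_per_phantom < 10) stop("need n_trials_per_phantom >= 10")
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) <= 0) {
    stop("config error: ratios must be 3 non-negative numbers with positive sum")
  }

  per_phantom <- vector("list", length(phantoms))
  std_infos <- vector("list", length(phantoms))
  region_clouds <- vector("list", length(phantoms))

  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    std <- pca_standardize(ph$surface)
    std_infos[[pi]] <- std$info
    regions <- build_candidate_regions(ph$surface, ph$landmarks, radius_mm)
    rc <- candidate_region_cloud(ph$surface, ph$landmarks, radius_mm,
                                 k_per_region)
    region_clouds[[pi]] <- standardize_points(std$info, rc$points)
    Lstd <- standardize_points(std$info, as_point_matrix(ph$landmarks))

    rows <- vector("list", n_trials_per_phantom)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    count <- 0L
    attempt <- 0L
    with_seed(derive_seed(seed, "dataset", ph$seed), {
      while (count < n_trials_per_phantom) {
        attempt <- attempt + 1L
        if (attempt > 50L * n_trials_per_phantom) {
          stop("could not find enough unique landmark combinations")
        }
        deform <- stats::runif(1) < deform_fraction
        tr <- simulate_trial_impl(regions, if (deform) deform_sigma_mm else 0)
        key <- paste(round(as_point_matrix(tr$landmarks) * 10), collapse = ",")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        count <- count + 1L

        sim_std <- standardize_points(std$info, as_point_matrix(tr$landmarks))
        rec <- make_record(landmarks_from_matrix(sim_std, tr$landmarks$name),
                           landmarks_from_matrix(Lstd, tr$landmarks$name))
        rows[[count]] <- tibble::tibble(
          phantom = ph$seed, trial = count, deformed = tr$deformed,
          err_mean_mm = mean(tr$actual_mm), err_max_mm = max(tr$actual_mm),
          X = list(rec$X_coarse), Y = list(rec$Y_ref),
          q_gt = list(rec$T_gt$q), t_gt = list(rec$T_gt$t)
        )
      }
    })
    per_phantom[[pi]] <- dplyr::bind_rows(rows)
  }

  # per-phantom stratified split
  counts <- split_counts(n_trials_per_phantom, ratios)
  records <- dplyr::bind_rows(lapply(seq_along(per_phantom), function(pi) {
    df <- per_phantom[[pi]]
    idx <- with_seed(derive_seed(seed, "split", phantoms[[pi]]$seed),
                     sample.int(nrow(df)))
    lab <- rep(c("train", "validation", "test"), counts)
    df$split <- lab[order(idx)]
    df
  }))

  structure(list(
    records = records,
    manifest = list(
      phantom_seeds = vapply(phantoms, function(p) p$seed, 1),
      n_trials_per_phantom = n_trials_per_phantom,
      ratios = ratios, radius_mm = radius_mm,
      k_per_region = as.integer(k_per_region),
      deform_sigma_mm = deform_sigma_mm, deform_fraction = deform_fraction,
      seed = seed,
      landmark_names = phantoms[[1]]$landmarks$name,
      standardization = stats::setNames(
        std_infos, paste0("phantom_", vapply(phantoms, function(p) p$seed, 1))),
      region_clouds = stats::setNames(
        region_clouds,
        paste0("phantom_", vapply(phantoms, function(p) p$seed, 1)))
    )
  ), class = "navreg_dataset")
}

split_counts <- function(n, ratios) {
  frac <- ratios / sum(ratios)
  base <- floor(n * frac)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), c("train", "validation", "test"))
}

#' @export
print.navreg_dataset <- function(x, ...) {
  tab <- table(x$records$split)[c("train", "validation", "test")]
  cat(sprintf("<navreg_dataset> %d records (%s), %d phantom(s)\n",
              nrow(x$records),
              paste(names(tab), as.integer(tab), sep = "=", collapse = " "),
              length(x$manifest$phantom_seeds)))
  invisible(x)
}

#' Persist / load a dataset as plain text
#'
#' Records go to one CSV (flattened coordinates and labels), the manifest —
#' including per-phantom standardization — to YAML.
#'
#' @param dataset A `navreg_dataset`.
#' @param dir Directory to write into / read from.
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: a
#'   `navreg_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- dataset$records
  flat <- cbind(
    df[c("phantom", "trial", "split", "deformed", "err_mean_mm", "err_max_mm")],
    flatten_coord_col(df$X, "X"), flatten_coord_col(df$Y, "Y"),
    stats::setNames(as.data.frame(do.call(rbind, df$q_gt)),
                    paste0("q_", c("w", "x", "y", "z"))),
    stats::setNames(as.data.frame(do.call(rbind, df$t_gt)),
                    paste0("t_", c("x", "y", "z")))
  )
  utils::write.csv(flat, file.path(dir, "records.csv"), row.names = FALSE)
  rc <- dplyr::bind_rows(lapply(names(dataset$manifest$region_clouds),
                                function(nm) {
    M <- dataset$manifest$region_clouds[[nm]]
    tibble::tibble(phantom = nm, x = M[, 1], y = M[, 2], z = M[, 3])
  }))
  utils::write.csv(rc, file.path(dir, "region_clouds.csv"), row.names = FALSE)
  man <- dataset$manifest
  man$region_clouds <- NULL
  man$standardization <- lapply(man$standardization, function(s) {
    list(rotation = as.numeric(s$rotation), centroid = as.numeric(s$centroid),
         scale = s$scale)
  })
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"), precision = 15)
  invisible(dir)
}

flatten_coord_col <- function(col, prefix) {
  n_lm <- nrow(col[[1]])
  M <- t(vapply(col, function(m) as.numeric(t(m)), numeric(3 * n_lm)))
  colnames(M) <- paste0(prefix, rep(seq_len(n_lm), each = 3), "_", c("x", "y", "z"))
  as.data.frame(M)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  flat <- utils::read.csv(file.path(dir, "records.csv"))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  man$standardization <- lapply(man$standardization, function(s) {
    structure(list(rotation = matrix(unlist(s$rotation), 3, 3),
                   centroid = unlist(s$centroid), scale = s$scale),
              class = "standardization_info")
  })
  rc <- utils::read.csv(file.path(dir, "region_clouds.csv"))
  man$region_clouds <- lapply(split(rc, rc$phantom), function(d) {
    cbind(d$x, d$y, d$z)
  })[unique(rc$phantom)]
  n_lm <- length(man$landmark_names)
  unflat <- function(prefix) {
    cols <- paste0(prefix, rep(seq_len(n_lm), each = 3), "_", c("x", "y", "z"))
    lapply(seq_len(nrow(flat)), function(i) {
      matrix(as.numeric(flat[i, cols]), ncol = 3, byrow = TRUE)
    })
  }
  records <- tibble::tibble(
    phantom = flat$phantom, trial = flat$trial, deformed = flat$deformed,
    err_mean_mm = flat$err_mean_mm, err_max_mm = flat$err_max_mm,
    X = unflat("X"), Y = unflat("Y"),
    q_gt = lapply(seq_len(nrow(flat)), function(i) {
      as.numeric(flat[i, c("q_w", "q_x", "q_y", "q_z")])
    }),
    t_gt = lapply(seq_len(nrow(flat)), function(i) {
      as.numeric(flat[i, c("t_x", "t_y", "t_z")])
    }),
    split = flat$split
  )
  structure(list(records = records, manifest = man), class = "navreg_dataset")
}
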