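# End-to-end registration protocol and the phantom-study evaluation harness.
#
# Conventional pipeline: SVD landmark coarse registration (T_PAT) -> ICP.
# Proposed pipeline: coarse registration -> learned refinement (T_REF, so
# the pre-ICP alignment is T_REF x T_PAT) -> ICP. Evaluation reports SRE
# (mean distance of registered surface points to their matched image
# points) and TRE (distance of held-out internal targets after the final
# transform), stratified by acquisition pattern and target depth.

#' Coarse registration from paired anatomical landmarks
#'
#' Matches landmarks by name and solves the SVD paired-point problem,
#' yielding the patient-to-image transform T_PAT.
#'
#' @param patient_landmarks,image_landmarks [landmark_set()]s sharing names.
#' @return A `rigid_transform` mapping patient space into image space.
#' @export
coarse_register <- function(patient_landmarks, image_landmarks) {
  image_matched <- match_landmarks(patient_landmarks, image_landmarks)
  svd_paired_point_register(patient_landmarks, image_matched)
}

#' Run the full registration pipeline on one case
#'
#' Coarse landmark registration, optional learned refinement, then ICP fine
#' registration. With `model = NULL` this is the conventional pipeline; with
#' a trained [train_refine_net()] fit, the refinement transform T_REF is
#' predicted from the coarse-registered landmarks (standardized into the
#' image cloud's unit-sphere frame) and composed as T_REF x T_PAT before
#' ICP.
#'
#' @param patient_cloud Patient-space surface [point_cloud()] (mm).
#' @param patient_landmarks Patient-space picked [landmark_set()].
#' @param image_cloud Image-space surface [point_cloud()] (mm).
#' @param image_landmarks Image-space reference [landmark_set()].
#' @param model Optional `refine_net_fit` for the proposed pipeline.
#' @param icp_max_iterations,icp_tolerance_mm ICP settings.
#' @return A `registration_run`: transforms `T_PAT`, `T_REF`, `T_ICP`,
#'   `T_final` (all `rigid_transform`s, with
#'   `T_final = T_ICP o T_REF o T_PAT`), the `icp` result, the `method`
#'   label, and metadata (including the true pose when the patient cloud
#'   carries one).
#' @export
register_surfaces <- function(patient_cloud, patient_landmarks,
                              image_cloud, image_landmarks,
                              model = NULL,
                              icp_max_iterations = 100,
                              icp_tolerance_mm = 1e-6) {
  T_pat <- tryCatch(coarse_register(patient_landmarks, image_landmarks),
                    error = function(e) stop("coarse stage: ",
                                             conditionMessage(e)))
  if (!is.null(model)) {
    T_ref <- tryCatch({
      std <- pca_standardize(image_cloud)
      Xc <- rt_apply(T_pat, as_point_matrix(patient_landmarks))
      image_matched <- match_landmarks(patient_landmarks, image_landmarks)
      manifest <- if (inherits(model, "refine_net_fit")) model$manifest
      rc <- candidate_region_cloud(
        image_cloud, image_matched,
        radius_mm = if (!is.null(manifest)) manifest$radius_mm else 10,
        k_per_region = if (!is.null(manifest)) manifest$k_per_region else 8)
      predict_refinement(model,
                         standardize_points(std$info, Xc),
                         standardize_points(std$info, rc$points),
                         std$info)$transform_mm
    }, error = function(e) stop("refinement stage: ", conditionMessage(e)))
    method <- "proposed"
  } else {
    T_ref <- rt_identity()
    method <- "conventional"
  }
  init <- rt_compose(T_ref, T_pat)
  icp <- tryCatch(
    icp_register(patient_cloud, image_cloud, init = init,
                 max_iterations = icp_max_iterations,
                 tolerance_mm = icp_tolerance_mm),
    error = function(e) stop("icp stage: ", conditionMessage(e)))
  structure(list(
    T_PAT = T_pat, T_REF = T_ref,
    T_ICP = rt_compose(icp$transform, rt_invert(init)),
    T_final = icp$transform,
    icp = icp, method = method,
    true_pose = if (inherits(patient_cloud, "point_cloud")) {
      patient_cloud$true_pose
    }
  ), class = "registration_run")
}

#' @export
print.registration_run <- function(x, ...) {
  cat(sprintf("<registration_run> method %s, icp %d iterations, final rms %.4f mm\n",
              x$method, x$icp$iterations_run,
              utils::tail(x$icp$rms_history, 1)))
  invisible(x)
}

#' Target registration error for a registration run
#'
#' TRE is the Euclidean distance between each image-space internal target
#' and the final-transform-mapped patient-space target — targets never
#' participate in the registration itself. Patient-space target positions
#' come from the phantom's true pose (recorded on the acquired cloud or
#' passed explicitly).
#'
#' @param run A [register_surfaces()] result.
#' @param phantom The [make_phantom()] model the trial was generated from.
#' @param true_pose Image-to-patient `rigid_transform` (defaults to the one
#'   recorded in `run`).
#' @return A tibble with one row per target: layer, row, depth_mm, tre_mm.
#' @export
evaluate_tre <- function(run, phantom, true_pose = run$true_pose) {
  if (is.null(true_pose)) stop("input error: no true pose available for TRE")
  tg <- phantom$targets
  if (nrow(tg) == 0) stop("input error: phantom has no targets")
  P_img <- unname(cbind(tg$x, tg$y, tg$z))
  P_pat <- rt_apply(true_pose, P_img)
  P_back <- rt_apply(run$T_final, P_pat)
  tibble::tibble(layer = tg$layer, row = tg$row, depth_mm = tg$depth_mm,
                 tre_mm = as.numeric(sqrt(rowSums((P_back - P_img)^2))))
}

#' Surface registration error for a registration run
#'
#' SRE is the mean Euclidean distance between the final-transformed patient
#' surface points and their nearest-neighbour image points — the quantity
#' the ICP stage itself minimizes, reported over the points used in
#' registration.
#'
#' @param run A [register_surfaces()] result.
#' @param patient_cloud,image_cloud The clouds the run registered.
#' @return SRE in mm (single number).
#' @export
evaluate_sre <- function(run, patient_cloud, image_cloud) {
  moved <- rt_apply(run$T_final, as_point_matrix(patient_cloud))
  nn <- nearest_correspondences(moved, as_point_matrix(image_cloud))
  mean(nn$distance_mm)
}

# --- study configuration --------------------------------------------------

#' Configuration for a phantom validation study
#'
#' The factorial design: phantoms x acquisition patterns x trials x methods,
#' with 27 internal targets evaluated per trial. Defaults reproduce the full
#' study design (4 phantoms, 5 patterns, 5 trials); pass subsets for reduced
#' designs.
#'
#' @param phantom_seeds Integer seeds, one phantom each (default 4).
#' @param patterns Acquisition pattern names (default all 5).
#' @param n_trials Trials per phantom x pattern cell (default 5).
#' @param methods Subset of `c("conventional", "proposed")`.
#' @param noise_sigma_mm Probe jitter sd (default 0.3 mm).
#' @param landmark_error_mm Localization-error range for picked landmarks
#'   (default `c(1, 5)` mm).
#' @param points_per_trial Surface points collected per trial (default 200).
#' @param pose_translation_mm Half-range of the random true-pose
#'   translation (default 150 mm; rotations are uniform on SO(3)).
#' @param icp `list(max_iterations, tolerance_mm)`.
#' @param permutation_test Run a permutation test on the method difference
#'   in mean TRE (default FALSE).
#' @param n_permutations Resamples for the permutation test.
#' @param seed Master seed; every trial derives its own stream from it.
#' @return A `study_config` list.
#' @export
study_config <- function(phantom_seeds = c(101, 102, 103, 104),
                         patterns = pattern_names(),
                         n_trials = 5,
                         methods = c("conventional", "proposed"),
                         noise_sigma_mm = 0.3,
                         landmark_error_mm = c(1, 5),
                         points_per_trial = 200,
                         pose_translation_mm = 150,
                         icp = list(max_iterations = 100, tolerance_mm = 1e-6),
                         permutation_test = FALSE,
                         n_permutations = 1000,
                         seed = 1) {
  methods <- match.arg(methods, c("conventional", "proposed"),
                       several.ok = TRUE)
  stopifnot(all(patterns %in% pattern_names()), n_trials >= 1)
  structure(list(phantom_seeds = phantom_seeds, patterns = patterns,
                 n_trials = as.integer(n_trials), methods = methods,
                 noise_sigma_mm = noise_sigma_mm,
                 landmark_error_mm = landmark_error_mm,
                 points_per_trial = as.integer(points_per_trial),
                 pose_translation_mm = pose_translation_mm,
                 icp = icp, permutation_test = isTRUE(permutation_test),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [study_config()].
#' @return `read_study_config`: a `study_config`; `write_study_config`:
#'   `path`, invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# --- study execution ------------------------------------------------------

#' Run the phantom validation study
#'
#' Executes the full factorial design: for every phantom, pattern and trial
#' a random true pose is drawn, a patient cloud is acquired with probe
#' noise, landmarks are picked with 1–5 mm localization error, and each
#' method registers the case. Per-target TRE (27 targets per trial) and SRE
#' are recorded.
#'
#' @param config A [study_config()].
#' @param model A trained `refine_net_fit` (required when `"proposed"` is
#'   among the methods).
#' @param out_dir Optional directory: per-trial transforms (JSON), the TRE
#'   table (CSV) and a summary (JSON) are written there.
#' @param verbose Print one line per phantom (default FALSE).
#' @return A `navreg_study`: `tre` tibble (phantom, pattern, trial, method,
#'   layer, row, depth_mm, tre_mm), `sre` tibble, the `config`, and the
#'   optional permutation-test result.
#' @export
run_study <- function(config = study_config(), model = NULL, out_dir = NULL,
                      verbose = FALSE) {
  if ("proposed" %in% config$methods && is.null(model)) {
    stop("config error: the proposed arm needs a trained refinement model")
  }
  tre_rows <- list()
  sre_rows <- list()
  transforms <- list()
  for (ps in config$phantom_seeds) {
    phantom <- make_phantom(seed = ps)
    if (verbose) message("phantom ", ps)
    for (pat in config$patterns) {
      for (tr in seq_len(config$n_trials)) {
        tseed <- derive_seed(config$seed, "study", ps, pat, tr)
        true_pose <- with_seed(tseed, random_rigid_transform(
          config$pose_translation_mm))
        pcloud <- acquire_patient_cloud(
          phantom, pat, true_pose = true_pose,
          noise_sigma_mm = config$noise_sigma_mm,
          n_points = config$points_per_trial, seed = tseed)
        picks <- pick_landmarks(phantom, config$landmark_error_mm,
                                true_pose = true_pose, seed = tseed)
        for (method in config$methods) {
          run <- register_surfaces(
            pcloud, picks, phantom$surface, phantom$landmarks,
            model = if (method == "proposed") model,
            icp_max_iterations = config$icp$max_iterations,
            icp_tolerance_mm = config$icp$tolerance_mm)
          tre <- evaluate_tre(run, phantom)
          tre_rows[[length(tre_rows) + 1L]] <- dplyr::mutate(
            tre, phantom = ps, pattern = pat, trial = tr, method = method,
            .before = 1)
          pre_err <- pose_error_mm(
            rt_compose(rt_compose(run$T_REF, run$T_PAT), true_pose), phantom)
          fin_err <- pose_error_mm(rt_compose(run$T_final, true_pose),
                                   phantom)
          sre_val <- evaluate_sre(run, pcloud, phantom$surface)
          sre_rows[[length(sre_rows) + 1L]] <- tibble::tibble(
            phantom = ps, pattern = pat, trial = tr, method = method,
            sre_mm = sre_val,
            icp_iterations = run$icp$iterations_run,
            pre_icp_pose_error_mm = pre_err,
            final_pose_error_mm = fin_err)
          transforms[[sprintf("%d_%s_%d_%s", ps, pat, tr, method)]] <- list(
            seed = tseed,
            T_PAT = unclass(run$T_PAT), T_REF = unclass(run$T_REF),
            T_ICP = unclass(run$T_ICP), T_final = unclass(run$T_final),
            rms_history = run$icp$rms_history)
        }
      }
    }
  }
  study <- structure(list(tre = dplyr::bind_rows(tre_rows),
                          sre = dplyr::bind_rows(sre_rows),
                          config = config),
                     class = "navreg_study")
  if (config$permutation_test && length(config$methods) == 2) {
    study$permutation <- permutation_test_tre(study, config$n_permutations,
                                              config$seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(study$tre, file.path(out_dir, "tre.csv"),
                     row.names = FALSE)
    utils::write.csv(study$sre, file.path(out_dir, "sre.csv"),
                     row.names = FALSE)
    jsonlite::write_json(transforms, file.path(out_dir, "transforms.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary_to_list(study),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

# Mean displacement of the phantom surface under a residual transform:
# 0 when the composed patient->image estimate equals the true inverse pose.
pose_error_mm <- function(residual, phantom) {
  P <- phantom$surface$points
  mean(sqrt(rowSums((rt_apply(residual, P) - P)^2)))
}

#' @export
print.navreg_study <- function(x, ...) {
  cat(sprintf("<navreg_study> %d TRE records (%d phantoms x %d patterns x %d trials x %d methods)\n",
              nrow(x$tre), length(x$config$phantom_seeds),
              length(x$config$patterns), x$config$n_trials,
              length(x$config$methods)))
  print(summarize_study(x))
  invisible(x)
}

#' Descriptive summaries of a phantom study
#'
#' Aggregates TRE by method (`by = "method"`), by acquisition pattern, or
#' by target depth; SRE by method via `summarize_sre()`.
#'
#' @param study A [run_study()] result.
#' @param by One of `"method"`, `"pattern"`, `"depth"`.
#' @return A tibble of means, sd, min, max and counts.
#' @export
summarize_study <- function(study, by = c("method", "pattern", "depth")) {
  by <- match.arg(by)
  groups <- switch(by,
                   method = "method",
                   pattern = c("method", "pattern"),
                   depth = c("method", "depth_mm"))
  dplyr::summarise(
    dplyr::group_by(study$tre, dplyr::across(dplyr::all_of(groups))),
    mean_tre_mm = mean(.data$tre_mm), sd_tre_mm = stats::sd(.data$tre_mm),
    min_tre_mm = min(.data$tre_mm), max_tre_mm = max(.data$tre_mm),
    n = dplyr::n(), .groups = "drop")
}

#' @rdname summarize_study
#' @export
summarize_sre <- function(study) {
  dplyr::summarise(
    dplyr::group_by(study$sre, .data$method),
    mean_sre_mm = mean(.data$sre_mm), sd_sre_mm = stats::sd(.data$sre_mm),
    min_sre_mm = min(.data$sre_mm), max_sre_mm = max(.data$sre_mm),
    n = dplyr::n(), .groups = "drop")
}

summary_to_list <- function(study) {
  list(by_method = summarize_study(study, "method"),
       by_pattern = summarize_study(study, "pattern"),
       by_depth = summarize_study(study, "depth"),
       sre = summarize_sre(study))
}

#' Permutation test on the method difference in mean TRE
#'
#' Exchanges method labels within (phantom, pattern, trial) blocks — the
#' paired design — and compares the observed difference in mean TRE to the
#' permutation distribution.
#'
#' @param study A two-method [run_study()] result.
#' @param n_permutations Number of label permutations.
#' @param seed RNG seed.
#' @return A one-row tibble: observed difference (conventional - proposed),
#'   two-sided p-value, permutations.
#' @export
permutation_test_tre <- function(study, n_permutations = 1000, seed = 1) {
  wide <- tidyr::pivot_wider(study$tre,
                             names_from = "method", values_from = "tre_mm")
  if (!all(c("conventional", "proposed") %in% names(wide))) {
    stop("permutation test needs both methods")
  }
  d <- wide$conventional - wide$proposed
  obs <- mean(d)
  n <- length(d)
  perm <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_permutations), function(i) {
      mean(d * sample(c(-1, 1), n, replace = TRUE))
    }, numeric(1))
  })
  tibble::tibble(observed_diff_mm = obs,
                 p_value = (1 + sum(abs(perm) >= abs(obs))) /
                   (n_permutations + 1),
                 n_permutations = n_permutations)
}

#' Tidy / glance / plot methods for phantom studies
#'
#' `tidy()` returns the per-target TRE records; `glance()` one row per
#' method; `autoplot()` TRE by pattern or depth.
#'
#' @param x,object A `navreg_study`.
#' @param by For `autoplot`: `"pattern"` or `"depth"`.
#' @param ... Unused.
#' @return Tibbles / a ggplot.
#' @export
tidy.navreg_study <- function(x, ...) x$tre

#' @rdname tidy.navreg_study
#' @export
glance.navreg_study <- function(x, ...) {
  tre <- summarize_study(x, "method")
  sre <- summarize_sre(x)
  dplyr::left_join(tre, sre, by = "method")
}

#' @rdname tidy.navreg_study
#' @export
autoplot.navreg_study <- function(object, by = c("pattern", "depth"), ...) {
  by <- match.arg(by)
  df <- summarize_study(object, by)
  xvar <- if (by == "pattern") "pattern" else "depth_mm"
  if (by == "depth") df$depth_mm <- factor(df$depth_mm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$mean_tre_mm,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_tre_mm - .data$sd_tre_mm,
                   ymax = .data$mean_tre_mm + .data$sd_tre_mm),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = if (by == "pattern") "acquisition pattern" else
      "target depth (mm)", y = "TRE (mm)", fill = NULL) +
    ggplot2::theme_minimal()
}
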