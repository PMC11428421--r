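# Point-to-point iterative closest point (ICP) fine registration.
#
# Plain ICP: alternate exact nearest-neighbour correspondence (k-d tree) with
# the closed-form SVD paired-point solve, until the change in RMS
# correspondence distance falls below a tolerance or an iteration cap is hit.
# No outlier trimming or weighting by default, matching the conventional
# navigation pipeline this package models; a trim fraction is available as a
# config-gated extension.

#' Exact nearest-neighbour correspondences between two clouds
#'
#' For each source point, the index of the closest target point (exact
#' Euclidean metric, ties broken by the lowest target index) and the
#' distance in mm.
#'
#' @param source,target [point_cloud()]s or N x 3 matrices (mm).
#' @return A tibble with columns `source` (row index), `target` (matched
#'   target row), `distance_mm`.
#' @export
nearest_correspondences <- function(source, target) {
  S <- as_point_matrix(source)
  T <- as_point_matrix(target)
  if (nrow(S) == 0 || nrow(T) == 0) stop("input error: empty point cloud")
  nn <- .nn_kdtree(S, T)
  tibble::tibble(source = seq_len(nrow(S)),
                 target = nn$index,
                 distance_mm = nn$distance)
}

#' ICP fine registration
#'
#' Iteratively refines the rigid alignment of `source` onto `target`,
#' starting from `init` (typically the coarse or refined transform). Each
#' iteration finds nearest-neighbour correspondences under the current
#' cumulative transform, records their RMS distance, and updates the
#' transform with the SVD paired-point solve on those correspondences.
#' Convergence is declared when the change in RMS between successive
#' iterations drops below `tolerance_mm`.
#'
#' The RMS history is non-increasing (the classic point-to-point ICP
#' guarantee): re-matching can only shorten per-point distances and the SVD
#' solve is optimal for the matched pairs. ICP converges to a local optimum —
#' a bad initialization on an asymmetric surface converges, but to a large
#' RMS; that dependence on initialization is what the learned refinement
#' stage addresses.
#'
#' @param source Patient-space cloud to move (>= 3 points).
#' @param target Image-space cloud held fixed.
#' @param init Initial `rigid_transform` (default identity).
#' @param max_iterations Iteration cap (default 100).
#' @param tolerance_mm Convergence threshold on the change in RMS (default
#'   1e-6 mm).
#' @param trim_fraction Config-gated extension: fraction (0 to <1) of the
#'   worst correspondences dropped from each solve; 0 (default) is plain ICP.
#' @return An `icp_result`: list with `transform` (cumulative
#'   `rigid_transform`), `rms_history` (mm, one entry per iteration),
#'   `iterations_run`, `converged`.
#' @export
icp_register <- function(source, target, init = rt_identity(),
                         max_iterations = 100, tolerance_mm = 1e-6,
                         trim_fraction = 0) {
  S <- as_point_matrix(source)
  T <- as_point_matrix(target)
  if (nrow(S) < 3) stop("ICP needs at least 3 source points")
  if (trim_fraction < 0 || trim_fraction >= 1) stop("trim_fraction must be in [0, 1)")
  stopifnot(is_rigid_transform(init))

  current <- init
  rms_history <- numeric(0)
  converged <- FALSE
  iterations <- 0L

  for (k in seq_len(max_iterations)) {
    moved <- rt_apply(current, S)
    nn <- .nn_kdtree(moved, T)
    keep <- seq_len(nrow(S))
    if (trim_fraction > 0) {
      n_keep <- max(3L, floor((1 - trim_fraction) * nrow(S)))
      keep <- order(nn$distance)[seq_len(n_keep)]
    }
    rms <- sqrt(mean(nn$distance[keep]^2))
    rms_history <- c(rms_history, rms)
    iterations <- k

    if (length(unique(nn$index[keep])) < 3) {
      stop("degeneracy error: correspondences collapse onto fewer than 3 target points")
    }
    step <- svd_paired_point_register(moved[keep, , drop = FALSE],
                                      T[nn$index[keep], , drop = FALSE])
    current <- rt_compose(step, current)

    if (k > 1 && abs(rms_history[k - 1] - rms_history[k]) < tolerance_mm) {
      converged <- TRUE
      break
    }
  }

  structure(list(transform = current,
                 rms_history = rms_history,
                 iterations_run = iterations,
                 converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %d iterations, %s, final rms %.6f mm\n",
              x$iterations_run,
              if (x$converged) "converged" else "not converged",
              utils::tail(x$rms_history, 1)))
  invisible(x)
}

#' Tidy an ICP result
#'
#' @param x An `icp_result`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `rms_mm`.
#' @export
tidy.icp_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$rms_history), rms_mm = x$rms_history)
}

#' Glance at an ICP result
#'
#' @param x An `icp_result`.
#' @param ... Unused.
#' @return A one-row tibble: `iterations`, `converged`, `final_rms_mm`.
#' @export
glance.icp_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations_run,
                 converged = x$converged,
                 final_rms_mm = utils::tail(x$rms_history, 1))
}

#' Plot ICP convergence
#'
#' @param object An `icp_result`.
#' @param ... Unused.
#' @return A ggplot of RMS correspondence distance per iteration.
#' @export
autoplot.icp_result <- function(object, ...) {
  df <- tidy.icp_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$rms_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ICP iteration", y = "RMS correspondence distance (mm)") +
    ggplot2::theme_minimal()
}
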