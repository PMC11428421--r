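# Point clouds and landmark tables, plus the plain-text interchange formats
# used around surgical navigation pipelines (ASCII PLY, XYZ-CSV, landmark CSV).

#' Construct a point cloud
#'
#' @param points N x 3 matrix of coordinates in mm (N >= 1, finite).
#' @param normals Optional N x 3 matrix of unit normals.
#' @param space Provenance label: `"image"`, `"patient"`, or `"synthetic"`.
#' @return An object of class `point_cloud` (list with `points`, `normals`,
#'   `space`).
#' @export
point_cloud <- function(points, normals = NULL,
                        space = c("image", "patient", "synthetic")) {
  space <- match.arg(space)
  P <- as_point_matrix(points)
  if (nrow(P) < 1) stop("a point cloud needs at least one point")
  if (!all(is.finite(P))) stop("point coordinates must be finite")
  if (!is.null(normals)) {
    Nm <- as_point_matrix(normals)
    if (nrow(Nm) != nrow(P)) stop("normals must match points row-for-row")
    len <- sqrt(rowSums(Nm^2))
    if (any(abs(len - 1) > 1e-6)) stop("normals must be unit length")
  } else {
    Nm <- NULL
  }
  structure(list(points = P, normals = Nm, space = space),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (%s space)%s\n",
              nrow(x$points), x$space,
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

n_points <- function(pc) nrow(pc$points)

#' Construct a named, ordered landmark set
#'
#' Landmarks are ordered, named 3-D points; index-wise (or name-wise)
#' correspondence across image and patient spaces is what paired-point
#' registration consumes. Stored as a tibble so landmark tables pipe straight
#' into dplyr.
#'
#' @param name Character vector of unique landmark names.
#' @param x,y,z Coordinates in mm.
#' @return A tibble of class `landmark_set` with columns name, x, y, z.
#' @export
landmark_set <- function(name, x, y, z) {
  if (anyDuplicated(name)) stop("landmark names must be unique")
  stopifnot(length(name) == length(x), length(x) == length(y),
            length(y) == length(z))
  out <- tibble::tibble(name = as.character(name),
                        x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z))
  class(out) <- c("landmark_set", class(out))
  out
}

landmarks_from_matrix <- function(P, names) {
  landmark_set(names, P[, 1], P[, 2], P[, 3])
}

#' Match two landmark sets by name
#'
#' Reorders `b` into `a`'s landmark order; unmatched names are an error.
#'
#' @param a,b `landmark_set` tibbles.
#' @return `b` reordered to `a$name`.
#' @export
match_landmarks <- function(a, b) {
  idx <- match(a$name, b$name)
  if (anyNA(idx)) {
    stop("correspondence error: landmark names do not match (missing: ",
         paste(a$name[is.na(idx)], collapse = ", "), ")")
  }
  b[idx, ]
}

#' Read/write point clouds as ASCII PLY
#'
#' A minimal ASCII PLY codec covering vertex elements with x/y/z and optional
#' nx/ny/nz properties — the subset surface-extraction tools emit for bare
#' point clouds.
#'
#' @param path File path.
#' @param pc A [point_cloud()].
#' @param space Provenance label to attach on read.
#' @return `read_ply`: a `point_cloud`; `write_ply`: `path`, invisibly.
#' @export
read_ply <- function(path, space = "image") {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") stop("not a PLY file")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY: no end_header")
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!grepl("ascii", fmt[1])) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property", header, value = TRUE))
  body <- lines[(end + 1):(end + nv)]
  M <- matrix(scan(text = body, quiet = TRUE), nrow = nv, byrow = TRUE)
  colnames(M) <- props[seq_len(ncol(M))]
  pts <- M[, c("x", "y", "z"), drop = FALSE]
  nrm <- if (all(c("nx", "ny", "nz") %in% colnames(M))) {
    M[, c("nx", "ny", "nz"), drop = FALSE]
  } else NULL
  point_cloud(pts, nrm, space = space)
}

#' @rdname read_ply
#' @export
write_ply <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  has_n <- !is.null(pc$normals)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", n_points(pc)),
    "property double x", "property double y", "property double z",
    if (has_n) c("property double nx", "property double ny", "property double nz"),
    "end_header"
  )
  M <- if (has_n) cbind(pc$points, pc$normals) else pc$points
  body <- apply(M, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write point clouds as XYZ-CSV
#'
#' CSV with header `x,y,z` and optionally `nx,ny,nz`.
#'
#' @inheritParams read_ply
#' @return `read_xyz_csv`: a `point_cloud`; `write_xyz_csv`: `path`,
#'   invisibly.
#' @export
read_xyz_csv <- function(path, space = "image") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) stop("XYZ-CSV needs x,y,z columns")
  nrm <- if (all(c("nx", "ny", "nz") %in% names(df))) {
    cbind(df$nx, df$ny, df$nz)
  } else NULL
  point_cloud(cbind(df$x, df$y, df$z), nrm, space = space)
}

#' @rdname read_xyz_csv
#' @export
write_xyz_csv <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  df <- as.data.frame(pc$points)
  names(df) <- c("x", "y", "z")
  if (!is.null(pc$normals)) {
    df$nx <- pc$normals[, 1]; df$ny <- pc$normals[, 2]; df$nz <- pc$normals[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write landmark tables as CSV
#'
#' CSV with header `name,x,y,z` (coordinates in mm).
#'
#' @param path File path.
#' @param lm A [landmark_set()].
#' @return `read_landmarks_csv`: a `landmark_set`; `write_landmarks_csv`:
#'   `path`, invisibly.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_set(df$name, df$x, df$y, df$z)
}

#' @rdname read_landmarks_csv
#' @export
write_landmarks_csv <- function(lm, path) {
  utils::write.csv(as.data.frame(lm)[, c("name", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}
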