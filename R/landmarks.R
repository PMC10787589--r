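#' Named 3D landmark points
#'
#' Landmarks (typically vessel branching points) used for target
#' registration error. Points carry a coordinate-frame tag: `"voxel"`
#' (0-based indices), `"mm"` (millimetres, origin at voxel 0,0,0) or
#' `"normalized"` (the `[-1, 1]^3` cube).
#'
#' @param names character vector of unique labels.
#' @param points N x 3 numeric matrix.
#' @param frame `"voxel"`, `"mm"` or `"normalized"`.
#' @param volume_ref optional identifier of the associated volume.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(names, points, frame = c("voxel", "mm", "normalized"),
                         volume_ref = "") {
  frame <- match.arg(frame)
  points <- as_coord_matrix(points)
  names <- as.character(names)
  if (length(names) != nrow(points)) {
    stop("`names` and `points` disagree in length", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("landmark names must be unique", call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  structure(list(names = names, points = points, frame = frame,
                 volume_ref = as.character(volume_ref)[1L]),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d point(s) in '%s' frame", length(x$names),
              x$frame))
  if (nzchar(x$volume_ref)) cat(sprintf(" (volume '%s')", x$volume_ref))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.landmark_set <- function(x, ...) {
  data.frame(name = x$names, x = x$points[, 1], y = x$points[, 2],
             z = x$points[, 3], frame = x$frame, stringsAsFactors = FALSE)
}

#' Convert a landmark set to another coordinate frame
#'
#' @param landmarks a [landmark_set].
#' @param volume the [pa_volume] defining the grid geometry.
#' @param frame target frame.
#' @return a [landmark_set] in the requested frame.
#' @export
convert_landmarks <- function(landmarks, volume,
                              frame = c("voxel", "mm", "normalized")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  frame <- match.arg(frame)
  pts <- landmarks$points
  if (!identical(landmarks$frame, frame)) {
    vox <- switch(landmarks$frame,
      voxel = pts,
      mm = mm_to_voxel(volume, pts),
      normalized = normalized_to_voxel(volume, pts))
    pts <- switch(frame,
      voxel = vox,
      mm = voxel_to_mm(volume, vox),
      normalized = voxel_to_normalized(volume, vox))
  }
  landmark_set(landmarks$names, pts, frame = frame,
               volume_ref = landmarks$volume_ref)
}

#' Read landmarks from CSV
#'
#' Expects the dialect `name,x,y,z,frame` with `frame` one of
#' voxel/mm/normalized (constant over the file).
#'
#' @param path CSV file path.
#' @param volume_ref identifier stored on the returned set.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path, volume_ref = "") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "frame")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have header name,x,y,z,frame", call. = FALSE)
  }
  fr <- unique(df$frame)
  if (length(fr) != 1L) {
    stop("landmark CSV mixes coordinate frames", call. = FALSE)
  }
  landmark_set(df$name, cbind(df$x, df$y, df$z), frame = fr,
               volume_ref = volume_ref)
}

#' Write landmarks to CSV
#'
#' @inheritParams convert_landmarks
#' @param path destination CSV.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# internal: error if any point falls outside the normalized cube
assert_landmarks_in_cube <- function(landmarks, volume, tol = 1e-9) {
  lm_norm <- convert_landmarks(landmarks, volume, "normalized")
  bad <- rowSums(abs(lm_norm$points) > 1 + tol) > 0
  if (any(bad)) {
    stop(sprintf("landmark(s) outside the [-1,1]^3 domain: %s",
                 paste(landmarks$names[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(lm_norm)
}
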