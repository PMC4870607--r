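#' Construct a voxel grid
#'
#' The universal input container: a 3D binary pore/wall image with isotropic
#' physical voxel spacing. Internally the pore phase is stored as a logical
#' array (`TRUE` = pore, `FALSE` = wall) indexed `[z, y, x]`, where `z` is
#' the solidification/invasion axis.
#'
#' @param pore logical (or coercible) 3D array, `TRUE`/nonzero for pore
#'   voxels, `FALSE`/zero for solid wall voxels. All three dimensions must
#'   be at least 3 voxels.
#' @param spacing_um positive scalar, isotropic voxel edge length in
#'   micrometers.
#' @param provenance free-text metadata carried through analyses.
#' @return An object of class `voxel_grid` with elements `pore`,
#'   `spacing_um`, `axes` (`c("z","y","x")`) and `provenance`.
#' @examples
#' g <- voxel_grid(array(TRUE, c(4, 4, 4)), spacing_um = 3.74)
#' porosity(g)
#' @export
voxel_grid <- function(pore, spacing_um, provenance = "") {
  if (is.null(dim(pore)) || length(dim(pore)) != 3L)
    stop("`pore` must be a 3D array", call. = FALSE)
  if (!is.logical(pore)) {
    if (!is.numeric(pore))
      stop("`pore` must be logical or numeric", call. = FALSE)
    pore <- array(pore != 0, dim = dim(pore))
  }
  if (anyNA(pore))
    stop("`pore` contains NA: every voxel must be pore or wall", call. = FALSE)
  if (any(dim(pore) < 3L))
    stop("all three dimensions must be >= 3 voxels", call. = FALSE)
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L ||
      !is.finite(spacing_um) || spacing_um <= 0)
    stop("`spacing_um` must be a positive scalar", call. = FALSE)
  structure(
    list(pore = pore, spacing_um = as.numeric(spacing_um),
         axes = c("z", "y", "x"), provenance = as.character(provenance)[1]),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$pore)
  cat(sprintf("voxel_grid: %d x %d x %d voxels (z,y,x), %.4g um/voxel\n",
              d[1], d[2], d[3], x$spacing_um))
  cat(sprintf("  porosity %.1f%%, physical extent %.4g x %.4g x %.4g um\n",
              100 * mean(x$pore),
              d[1] * x$spacing_um, d[2] * x$spacing_um, d[3] * x$spacing_um))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$pore)

#' Pore volume fraction of a grid
#' @param grid a [voxel_grid()].
#' @return scalar in `[0, 1]`: pore voxels / total voxels.
#' @export
porosity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  mean(grid$pore)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

assert_grid <- function(grid) {
  if (!is_voxel_grid(grid)) stop("expected a `voxel_grid`", call. = FALSE)
  invisible(grid)
}

ALL_FACES <- c("z-", "z+", "y-", "y+", "x-", "x+")

#' Define the set of open faces for a directional analysis
#'
#' Sphere accessibility is measured for an object entering from the open
#' faces; all other faces are artificially sealed with wall voxels. All six
#' faces open corresponds to the 3D (omnidirectional) shrink-wrap mode;
#' exactly one open face is the directional mode.
#'
#' @param faces character vector, subset of
#'   `c("z-","z+","y-","y+","x-","x+")`, or `"3d"`/`"all"` for all six.
#' @return character vector of class `face_set`.
#' @examples
#' face_set("z-")        # directional: enter from the z- surface only
#' face_set("3d")        # omnidirectional
#' @export
face_set <- function(faces) {
  if (length(faces) == 1L && tolower(faces) %in% c("3d", "all"))
    faces <- ALL_FACES
  faces <- unique(as.character(faces))
  bad <- setdiff(faces, ALL_FACES)
  if (length(bad))
    stop("unknown face(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(ALL_FACES, collapse = ", "), ")", call. = FALSE)
  if (length(faces) == 0L)
    stop("face set must contain at least one open face", call. = FALSE)
  structure(faces, class = "face_set")
}

# face label -> list(axis = 1|2|3, side = -1|+1)
face_info <- function(face) {
  axis <- match(substr(face, 1, 1), c("z", "y", "x"))
  side <- if (substr(face, 2, 2) == "-") -1L else 1L
  list(axis = axis, side = side)
}

faces_label <- function(faces) {
  if (setequal(faces, ALL_FACES)) "3d" else paste(sort(unclass(faces)),
                                                  collapse = "+")
}
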