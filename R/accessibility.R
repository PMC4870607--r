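# Sphere accessibility ("shrink-wrap") analysis. A virtual sphere of
# diameter d fits at a pore voxel iff no wall voxel center lies strictly
# within d/2 of it (center-to-center Euclidean distance, micrometers);
# accessibility additionally requires a connected path of fitting center
# positions from an open face. Distances come from an exact squared EDT, so
# the discrete-ball definition used here matches the brute-force oracle
# (`brute_force_accessible`) exactly, not approximately.

# Pad a pore array: `pad` layers on every face, open faces free space (pore)
# and sealed faces wall. Sealed plates span the full padded extent — the
# enclosure is effectively infinite, so approach paths outside a sealed edge
# are blocked even within an open face's pad region.
pad_volume <- function(pore, pad, open_faces) {
  d <- dim(pore)
  nd <- d + 2L * pad
  out <- array(TRUE, dim = nd)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- pore
  for (f in setdiff(ALL_FACES, open_faces)) {
    fi <- face_info(f)
    idx <- if (fi$side < 0L) seq_len(pad)
           else (nd[fi$axis] - pad + 1L):nd[fi$axis]
    if (fi$axis == 1L) out[idx, , ] <- FALSE
    else if (fi$axis == 2L) out[, idx, ] <- FALSE
    else out[, , idx] <- FALSE
  }
  out
}

crop_volume <- function(a, pad, d) {
  a[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]),
    drop = FALSE]
}

edt_sq_vox <- function(feature) {
  array(cpp_edt_sq(as.vector(feature), dim(feature)), dim = dim(feature))
}

#' Largest connected pore fraction (flood fill)
#'
#' Size of the largest continuous pore-space component relative to the total
#' pore volume, in percent. This is the most permissive connectivity
#' statistic: any path counts, no matter how narrow.
#'
#' @param grid a [voxel_grid()] with at least one pore voxel.
#' @param connectivity 26 (default) or 6.
#' @return percent in `(0, 100]`.
#' @export
flood_fill_fraction <- function(grid, connectivity = 26L) {
  assert_grid(grid)
  npore <- sum(grid$pore)
  if (npore == 0) stop("grid contains no pore space", call. = FALSE)
  lab <- cpp_label_components(as.vector(grid$pore), dim(grid$pore),
                              as.integer(connectivity))
  100 * max(tabulate(lab)) / npore
}

#' Sphere center space
#'
#' Mask of pore voxels where a sphere of the given diameter can sit: the
#' Euclidean distance to the nearest wall voxel center is at least
#' `diameter_um / 2`. Connectivity to a surface is not required; see
#' [accessible_region()] for that. For `diameter_um <= spacing` this is the
#' full pore mask.
#'
#' @param grid a [voxel_grid()].
#' @param diameter_um sphere diameter, micrometers (`>= 0`).
#' @return logical 3D mask.
#' @export
center_space <- function(grid, diameter_um) {
  assert_grid(grid)
  if (diameter_um < 0) stop("`diameter_um` must be >= 0", call. = FALSE)
  r2 <- (diameter_um / (2 * grid$spacing_um))^2
  edt2 <- edt_sq_vox(!grid$pore)
  grid$pore & (edt2 >= r2 - EPS_R2)
}

#' Accessible pore region for a virtual sphere
#'
#' Computes where a sphere of diameter `diameter_um` can travel when it may
#' enter only through the open faces of `faces` (all other faces are sealed
#' with wall voxels). Open faces are padded with `ceiling(d/2) + 1` layers
#' of free space so the sphere can approach from outside and touch surface
#' pores; sealed faces are padded with wall. The center mask is the set of
#' fitting positions (EDT threshold) connected to an open face's entry
#' region; the access mask is the pore volume swept by the sphere, i.e. the
#' center mask dilated by the ball of radius d/2 intersected with pore.
#'
#' @param grid a [voxel_grid()].
#' @param diameter_um sphere diameter, micrometers (`>= 0`).
#' @param faces a [face_set()] (or anything `face_set()` accepts).
#' @param connectivity connectivity of the center space: 6 (default; a
#'   sphere sliding diagonally between voxel positions could clip walls
#'   under 26) or 26.
#' @return an object of class `accessibility_result`: list with
#'   `diameter_um`, `faces`, `center_mask`, `access_mask`,
#'   `accessible_volume_um3`, `spacing_um`.
#' @export
accessible_region <- function(grid, diameter_um, faces, connectivity = 6L) {
  assert_grid(grid)
  faces <- face_set(faces)
  if (diameter_um < 0) stop("`diameter_um` must be >= 0", call. = FALSE)
  d <- dim(grid$pore)
  s <- grid$spacing_um
  r_vox <- diameter_um / (2 * s)
  r2 <- r_vox^2
  pad <- as.integer(ceiling(r_vox)) + 1L

  pp <- pad_volume(grid$pore, pad, faces)
  nd <- dim(pp)
  edt2 <- edt_sq_vox(!pp)
  fits <- pp & (edt2 >= r2 - EPS_R2)

  seed <- array(FALSE, dim = nd)
  for (f in faces) {
    fi <- face_info(f)
    idx <- if (fi$side < 0L) seq_len(pad)
           else (nd[fi$axis] - pad + 1L):nd[fi$axis]
    if (fi$axis == 1L) seed[idx, , ] <- TRUE
    else if (fi$axis == 2L) seed[, idx, ] <- TRUE
    else seed[, , idx] <- TRUE
  }

  lab <- array(cpp_label_components(as.vector(fits), nd,
                                    as.integer(connectivity)), dim = nd)
  seed_labs <- setdiff(unique(lab[seed]), 0L)
  if (length(seed_labs)) {
    center_p <- array(lab %in% seed_labs, dim = nd)
    edt2c <- edt_sq_vox(center_p)
    access_p <- pp & (edt2c <= r2 + EPS_R2)
  } else {
    center_p <- array(FALSE, dim = nd)
    access_p <- center_p
  }

  center <- crop_volume(center_p, pad, d)
  access <- crop_volume(access_p, pad, d)
  if (!any(center) && diameter_um > min(d) * s)
    warning("sphere diameter exceeds the volume's physical extent; ",
            "result is empty", call. = FALSE)
  structure(
    list(diameter_um = diameter_um, faces = faces,
         center_mask = center, access_mask = access,
         accessible_volume_um3 = sum(access) * s^3,
         spacing_um = s, grid_dim = d),
    class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat(sprintf(
    "accessibility_result: d = %.4g um, faces = %s\n", x$diameter_um,
    faces_label(x$faces)))
  cat(sprintf("  %d center voxels, %d swept pore voxels (%.4g um^3)\n",
              sum(x$center_mask), sum(x$access_mask),
              x$accessible_volume_um3))
  invisible(x)
}

#' Percent interconnectivity
#'
#' The fraction of pore volume accessible to the virtual object, in percent:
#' `100 * (V - Vs) / (V - Vm)`, where `V` is the total ROI volume, `Vs` the
#' inaccessible volume after shrink-wrap (so `V - Vs` is the accessible pore
#' volume) and `Vm` the solid material volume (so `V - Vm` is the total pore
#' volume).
#'
#' @param grid the [voxel_grid()] the result was computed on.
#' @param result an [accessible_region()] result.
#' @return percent in `[0, 100]`.
#' @export
interconnectivity_percent <- function(grid, result) {
  assert_grid(grid)
  if (!inherits(result, "accessibility_result"))
    stop("`result` must come from accessible_region()", call. = FALSE)
  if (!identical(dim(grid$pore), result$grid_dim))
    stop("grid and result shapes differ", call. = FALSE)
  npore <- sum(grid$pore)
  if (npore == 0) stop("grid contains no pore space", call. = FALSE)
  100 * sum(result$access_mask) / npore
}

#' Interconnectivity as a function of virtual object diameter
#'
#' Evaluates [interconnectivity_percent()] over a strictly increasing list
#' of sphere diameters under one face mode, producing the characteristic
#' (usually sigmoidal) accessibility curve.
#'
#' @inheritParams accessible_region
#' @param diameters_um strictly increasing vector of at least 2 diameters.
#' @param accounting `"swept"` (default; Eq.-style accessible pore volume)
#'   or `"center"` (center-position counting, exactly monotone in d).
#' @return a data.frame of class `interconn_curve` with columns
#'   `diameter_um`, `interconnectivity_percent`; attributes `faces`,
#'   `grid_shape`, `spacing_um`, `accounting`.
#' @export
interconnectivity_curve <- function(grid, diameters_um, faces,
                                    connectivity = 6L,
                                    accounting = c("swept", "center")) {
  assert_grid(grid)
  accounting <- match.arg(accounting)
  faces <- face_set(faces)
  if (length(diameters_um) < 2L)
    stop("need at least 2 diameters", call. = FALSE)
  if (any(diff(diameters_um) <= 0))
    stop("`diameters_um` must be strictly increasing", call. = FALSE)
  npore <- sum(grid$pore)
  if (npore == 0) stop("grid contains no pore space", call. = FALSE)
  pct <- vapply(diameters_um, function(dum) {
    res <- accessible_region(grid, dum, faces, connectivity)
    n <- if (accounting == "swept") sum(res$access_mask)
         else sum(res$center_mask)
    100 * n / npore
  }, numeric(1))
  structure(
    data.frame(diameter_um = diameters_um, interconnectivity_percent = pct),
    faces = faces, grid_shape = dim(grid$pore), spacing_um = grid$spacing_um,
    accounting = accounting,
    class = c("interconn_curve", "data.frame"))
}

#' Export an interconnectivity curve as CSV
#'
#' Writes `diameter_um,interconnectivity_percent,faces` rows.
#'
#' @param curve an [interconnectivity_curve()] result.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "interconn_curve"))
  df <- data.frame(diameter_um = curve$diameter_um,
                   interconnectivity_percent = curve$interconnectivity_percent,
                   faces = faces_label(attr(curve, "faces")))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
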