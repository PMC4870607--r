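# Percolation analysis: maximum accessible distance L(d) from one face and
# extrapolation of the percolation diameter d_c via the 3D percolation
# scaling L ~ (d - d_c)^(-0.88). Plotting d against L^(-1/0.88) makes the
# relationship linear with intercept d_c.

DEFAULT_EXPONENT <- 0.88

#' Maximum accessible distance for one sphere diameter
#'
#' Runs a single-face [accessible_region()] and measures how deep into the
#' volume the sphere's *center* can travel from the entry face. Depth is
#' counted over center positions, not the swept volume, so the reported
#' reach is not inflated by the sphere radius. A point "percolates" when an
#' accessible center reaches the last center-feasible slab before the sealed
#' far face (a sphere of radius r cannot center itself within r of a sealed
#' boundary); percolating points report the full physical span as `L`.
#'
#' @param grid a [voxel_grid()].
#' @param diameter_um sphere diameter, micrometers.
#' @param face exactly one open face, e.g. `"z-"`.
#' @param connectivity center-space connectivity (6 or 26).
#' @return an object of class `percolation_point`: list with `diameter_um`,
#'   `max_distance_um`, `percolates`, `face`.
#' @export
max_accessible_distance <- function(grid, diameter_um, face,
                                    connectivity = 6L) {
  assert_grid(grid)
  face <- face_set(face)
  if (length(face) != 1L)
    stop("percolation analysis needs exactly one open face", call. = FALSE)
  res <- accessible_region(grid, diameter_um, face, connectivity)
  fi <- face_info(face)
  n_axis <- dim(grid$pore)[fi$axis]
  s <- grid$spacing_um
  r_vox <- diameter_um / (2 * s)
  if (!any(res$center_mask)) {
    L <- 0
    percolates <- FALSE
  } else {
    idx <- which(res$center_mask, arr.ind = TRUE)[, fi$axis]
    depth <- if (fi$side < 0L) idx - 1L else n_axis - idx  # 0-based
    maxd <- max(depth)
    # deepest slab a sphere center could occupy given the sealed far face
    k_last <- min(n_axis - 1, floor(n_axis - r_vox + EPS_R2))
    percolates <- maxd >= k_last
    L <- if (percolates) n_axis * s else (1 + maxd) * s
  }
  structure(list(diameter_um = diameter_um, max_distance_um = L,
                 percolates = percolates, face = unclass(face)[1]),
            class = "percolation_point")
}

region_of <- function(L, d, percolates, floor_radii) {
  if (percolates) 1L
  else if (L < floor_radii * d / 2) 3L
  else 2L
}

#' Scan maximum accessible distance over a diameter series
#'
#' One [max_accessible_distance()] measurement per diameter, with each point
#' classified into the three length-scale regimes: Region 1 (the sphere
#' crosses the finite volume, so L is censored at the dataset span), Region
#' 2 (0 < L < span; the regime usable for percolation fitting), Region 3 (L
#' below a depth floor of `floor_radii` sphere radii — only surface pores
#' are reached).
#'
#' @inheritParams max_accessible_distance
#' @param diameters_um strictly increasing vector of at least 3 diameters.
#' @param floor_radii depth floor separating Region 3 from Region 2, in
#'   units of the sphere radius (default 3).
#' @return a data.frame of class `percolation_scan` with columns
#'   `diameter_um`, `max_distance_um`, `percolates`, `region`; attributes
#'   `face`, `spacing_um`, `span_um`, `floor_radii`.
#' @export
percolation_scan <- function(grid, face, diameters_um, connectivity = 6L,
                             floor_radii = 3) {
  assert_grid(grid)
  face <- face_set(face)
  if (length(face) != 1L)
    stop("percolation analysis needs exactly one open face", call. = FALSE)
  if (length(diameters_um) < 3L)
    stop("need at least 3 diameters", call. = FALSE)
  if (any(diff(diameters_um) <= 0))
    stop("`diameters_um` must be strictly increasing", call. = FALSE)
  pts <- lapply(diameters_um, function(dum)
    max_accessible_distance(grid, dum, face, connectivity))
  L <- vapply(pts, `[[`, numeric(1), "max_distance_um")
  perc <- vapply(pts, `[[`, logical(1), "percolates")
  region <- mapply(region_of, L, diameters_um, perc,
                   MoreArgs = list(floor_radii = floor_radii))
  fi <- face_info(face)
  structure(
    data.frame(diameter_um = diameters_um, max_distance_um = L,
               percolates = perc, region = as.integer(region)),
    face = unclass(face)[1], spacing_um = grid$spacing_um,
    span_um = dim(grid$pore)[fi$axis] * grid$spacing_um,
    floor_radii = floor_radii,
    class = c("percolation_scan", "data.frame"))
}

#' Pooled percolation scan over sub-volumes
#'
#' A single small volume often shows a staircase L(d) pinned by one
#' bottleneck, which defeats the scaling fit. Splitting the dataset into
#' `splits^3` blocks and pooling the Region-2 points samples the ensemble of
#' bottleneck configurations, recovering the scaling relationship — the
#' small-volume analogue of measuring a larger dataset.
#'
#' @inheritParams percolation_scan
#' @param splits blocks per axis (each sub-volume is about `dim/splits`;
#'   trailing remainder voxels are dropped).
#' @return a `percolation_scan` data.frame with an extra `subvolume` column.
#' @export
subvolume_scan <- function(grid, face, diameters_um, splits = 2L,
                           connectivity = 6L, floor_radii = 3) {
  assert_grid(grid)
  splits <- as.integer(splits)
  stopifnot(splits >= 1L)
  d <- dim(grid$pore)
  blk <- d %/% splits
  if (any(blk < 3L)) stop("sub-volumes would be smaller than 3 voxels",
                          call. = FALSE)
  pts <- NULL
  sv <- 0L
  for (i in seq_len(splits)) for (j in seq_len(splits))
    for (k in seq_len(splits)) {
      sv <- sv + 1L
      sub <- voxel_grid(
        grid$pore[(i - 1) * blk[1] + seq_len(blk[1]),
                  (j - 1) * blk[2] + seq_len(blk[2]),
                  (k - 1) * blk[3] + seq_len(blk[3])],
        grid$spacing_um)
      sc <- as.data.frame(percolation_scan(sub, face, diameters_um,
                                           connectivity, floor_radii))
      sc$subvolume <- sv
      pts <- rbind(pts, sc)
    }
  fi <- face_info(face_set(face))
  structure(pts, face = unclass(face_set(face))[1],
            spacing_um = grid$spacing_um,
            span_um = blk[fi$axis] * grid$spacing_um,
            floor_radii = floor_radii, splits = splits,
            class = c("percolation_scan", "data.frame"))
}

#' Fit the percolation diameter from (d, L) measurements
#'
#' Ordinary least squares of diameter `d` on `L^(-1/exponent)`: under the
#' percolation scaling `L ~ C (d - d_c)^(-exponent)` this relationship is
#' exactly linear, and the intercept is the percolation diameter `d_c` — the
#' largest sphere able to travel infinitely far through the structure. The
#' slope ("gradient") relates to the smallest representative volume, or
#' repeat length, of the structure. Only Region-2 points enter the fit:
#' Region-1 points have L censored at the dataset span and Region-3 points
#' reflect only surface roughness. The exponent is fixed (3D percolation
#' theory value 0.88), never fitted.
#'
#' @param points a [percolation_scan()] result, or a data.frame with columns
#'   `diameter_um`, `max_distance_um`, `percolates` (and optionally
#'   `region`; rows without a region column are treated as usable when
#'   non-percolating with positive L).
#' @param exponent positive scaling exponent (default 0.88).
#' @return an object of class `percolation_fit`: list with `points` (the
#'   rows used), `d_c_um`, `gradient`, `exponent`, `r_squared`, `face`,
#'   `n_used`, `warnings` (character vector; contains
#'   `"negative_intercept_clamped"` if the raw intercept was negative).
#' @export
fit_percolation_diameter <- function(points, exponent = DEFAULT_EXPONENT) {
  if (inherits(points, "percolation_point")) points <- list(points)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "percolation_point"))) {
    points <- data.frame(
      diameter_um = vapply(points, `[[`, numeric(1), "diameter_um"),
      max_distance_um = vapply(points, `[[`, numeric(1), "max_distance_um"),
      percolates = vapply(points, `[[`, logical(1), "percolates"),
      face = vapply(points, `[[`, character(1), "face"))
  }
  stopifnot(is.data.frame(points), exponent > 0)
  need <- c("diameter_um", "max_distance_um", "percolates")
  if (!all(need %in% names(points)))
    stop("`points` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (all(points$percolates))
    stop2_class("poreperc_all_percolating",
                "all points percolate (Region 1): no finite L to fit; ",
                "increase the diameter range")
  usable <- !points$percolates & points$max_distance_um > 0
  if ("region" %in% names(points)) usable <- usable & points$region == 2L
  if (sum(usable) < 3L)
    stop2_class("poreperc_insufficient_region2",
                "insufficient Region-2 data (", sum(usable), " of ",
                nrow(points), " points usable) - enlarge the volume")
  use <- points[usable, , drop = FALSE]
  x <- use$max_distance_um^(-1 / exponent)
  fit <- lm(use$diameter_um ~ x)
  dc <- unname(coef(fit)[1])
  grad <- unname(coef(fit)[2])
  warnings <- character()
  if (dc < 0) {
    warnings <- "negative_intercept_clamped"
    warning("fitted intercept was negative (", signif(dc, 4),
            " um); clamped to 0", call. = FALSE)
    dc <- 0
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # "perfect fit" chatter
  face <- if (!is.null(attr(points, "face"))) attr(points, "face")
          else if ("face" %in% names(points)) points$face[1] else NA_character_
  structure(list(points = use, d_c_um = dc, gradient = grad,
                 exponent = exponent, r_squared = r2, face = face,
                 n_used = sum(usable), warnings = warnings),
            class = "percolation_fit")
}

stop2_class <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' @export
print.percolation_fit <- function(x, ...) {
  cat(sprintf(
    "percolation_fit (face %s): d_c = %.4g um, gradient = %.4g, r^2 = %.5f\n",
    x$face, x$d_c_um, x$gradient, x$r_squared))
  cat(sprintf("  %d Region-2 points, exponent %.2f%s\n", x$n_used, x$exponent,
              if (length(x$warnings))
                paste0(" [", paste(x$warnings, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Direct percolation threshold by bisection
#'
#' The model-free counterpart of [fit_percolation_diameter()]: bisects on
#' the sphere diameter, using the `percolates` flag of
#' [max_accessible_distance()], to find the largest diameter that can cross
#' the finite volume from the given face to the opposite side. Used as the
#' ground-truth oracle when validating the scaling-law extrapolation on
#' synthetic structures.
#'
#' @inheritParams max_accessible_distance
#' @param tol_um bisection tolerance in micrometers (must be at least a
#'   quarter voxel).
#' @return the crossing diameter in micrometers. If the structure does not
#'   percolate even at `d = spacing`, returns 0 with attribute
#'   `never_percolates = TRUE`.
#' @export
percolation_threshold_direct <- function(grid, face, tol_um = NULL,
                                         connectivity = 6L) {
  assert_grid(grid)
  face <- face_set(face)
  if (length(face) != 1L)
    stop("percolation analysis needs exactly one open face", call. = FALSE)
  s <- grid$spacing_um
  if (is.null(tol_um)) tol_um <- s / 2
  if (tol_um < s / 4)
    stop("`tol_um` must be at least spacing/4", call. = FALSE)
  perc <- function(dum) suppressWarnings(
    max_accessible_distance(grid, dum, face, connectivity)$percolates)
  lo <- 2 * s  # all pore voxels fit for any d <= 2*spacing
  if (!perc(lo)) {
    out <- 0
    attr(out, "never_percolates") <- TRUE
    return(out)
  }
  edt2 <- edt_sq_vox(!grid$pore)
  maxd <- suppressWarnings(max(edt2[grid$pore]))
  hi <- if (is.finite(maxd)) 2 * s * sqrt(maxd) + s
        else (max(dim(grid$pore)) + 2) * s  # no walls at all
  if (perc(hi)) return(hi)
  while (hi - lo > tol_um) {
    mid <- (lo + hi) / 2
    if (perc(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Export a percolation fit as JSON
#'
#' Writes `{face, exponent, points: [{d_um, L_um, region}], d_c_um,
#' gradient, r_squared, warnings}`.
#'
#' @param fit a [fit_percolation_diameter()] result.
#' @param path destination JSON path.
#' @param scan optional full [percolation_scan()] to report all scanned
#'   points (with regions) rather than only the fitted ones.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path, scan = NULL) {
  stopifnot(inherits(fit, "percolation_fit"))
  pts <- if (!is.null(scan)) scan else fit$points
  plist <- lapply(seq_len(nrow(pts)), function(i) list(
    d_um = pts$diameter_um[i], L_um = pts$max_distance_um[i],
    region = if ("region" %in% names(pts)) pts$region[i] else 2L))
  jsonlite::write_json(
    list(face = fit$face, exponent = fit$exponent, points = plist,
         d_c_um = fit$d_c_um, gradient = fit$gradient,
         r_squared = fit$r_squared, warnings = fit$warnings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
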