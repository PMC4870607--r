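# Synthetic porous structures with known ground truth, plus the brute-force
# accessibility oracle. These phantoms replace real micro-CT volumes as the
# test substrate: throat lattices have a percolation diameter equal to the
# throat width by construction, lamellar structures are strongly
# anisotropic (wide channels along z, narrow wall holes along x), and
# equiaxed foams are statistically isotropic.

# width-w run of voxel indices centered at c
centered_run <- function(c, w) (c - floor((w - 1) / 2)):(c + ceiling((w - 1) / 2))

lattice_centers <- function(n, pitch) {
  k <- seq(floor(pitch / 2), n, by = pitch)
  k[k >= 1 & k <= n]
}

phantom_grid <- function(pore, spacing_um, kind, params, seed,
                         ground_truth = NULL) {
  g <- voxel_grid(pore, spacing_um,
                  provenance = sprintf("phantom:%s seed=%s", kind,
                                       as.character(seed %||% "none")))
  g$phantom_spec <- c(list(kind = kind, shape = dim(pore),
                           spacing_um = spacing_um, seed = seed), params)
  g$ground_truth <- ground_truth
  g
}

#' Regular throat-lattice phantom
#'
#' A cubic lattice of spherical pores joined along each axis by square-
#' section prismatic throats of fixed width. By construction the percolation
#' diameter along every axis equals the throat width (up to one voxel of
#' discretization).
#'
#' @param shape voxel dimensions `(z, y, x)`.
#' @param spacing_um voxel edge length, micrometers.
#' @param pitch lattice period in voxels (`> pore_diameter`).
#' @param pore_diameter spherical pore diameter in voxels
#'   (`> throat_width`).
#' @param throat_width throat width in voxels (`>= 2`).
#' @param seed unused (the lattice is deterministic); kept for a uniform
#'   generator interface.
#' @return a [voxel_grid()] with elements `phantom_spec` and `ground_truth`
#'   (named list, face label to nominal percolation diameter in um).
#' @export
make_throat_lattice <- function(shape = c(96, 96, 96), spacing_um = 1,
                                pitch = 16, pore_diameter = 12,
                                throat_width = 6, seed = NULL) {
  if (throat_width < 2) stop("`throat_width` must be >= 2 voxels",
                             call. = FALSE)
  if (pore_diameter <= throat_width)
    stop("`pore_diameter` must exceed `throat_width`", call. = FALSE)
  if (pitch <= pore_diameter)
    stop("`pitch` must exceed `pore_diameter`", call. = FALSE)
  shape <- as.integer(shape)
  ctr <- lapply(shape, lattice_centers, pitch = pitch)
  pore <- array(FALSE, dim = shape)
  # full-length square channels along each axis through every center row
  for (cy in ctr[[2]]) for (cx in ctr[[3]]) {
    ry <- centered_run(cy, throat_width); rx <- centered_run(cx, throat_width)
    pore[, ry[ry >= 1 & ry <= shape[2]], rx[rx >= 1 & rx <= shape[3]]] <- TRUE
  }
  for (cz in ctr[[1]]) for (cx in ctr[[3]]) {
    rz <- centered_run(cz, throat_width); rx <- centered_run(cx, throat_width)
    pore[rz[rz >= 1 & rz <= shape[1]], , rx[rx >= 1 & rx <= shape[3]]] <- TRUE
  }
  for (cz in ctr[[1]]) for (cy in ctr[[2]]) {
    rz <- centered_run(cz, throat_width); ry <- centered_run(cy, throat_width)
    pore[rz[rz >= 1 & rz <= shape[1]], ry[ry >= 1 & ry <= shape[2]], ] <- TRUE
  }
  pore <- pore | carve_spheres(shape, ctr, pore_diameter)
  gt <- as.list(stats::setNames(rep(throat_width * spacing_um, 6), ALL_FACES))
  phantom_grid(pore, spacing_um, "throat_lattice",
               list(pitch = pitch, pore_diameter = pore_diameter,
                    throat_width = throat_width),
               seed, ground_truth = gt)
}

carve_spheres <- function(shape, ctr, pore_diameter) {
  pore <- array(FALSE, dim = shape)
  r <- (pore_diameter - 1) / 2
  off <- -ceiling(r):ceiling(r)
  ball <- expand.grid(dz = off, dy = off, dx = off)
  ball <- ball[ball$dz^2 + ball$dy^2 + ball$dx^2 <= r^2 + EPS_R2, ]
  for (cz in ctr[[1]]) for (cy in ctr[[2]]) for (cx in ctr[[3]]) {
    z <- cz + ball$dz; y <- cy + ball$dy; x <- cx + ball$dx
    ok <- z >= 1 & z <= shape[1] & y >= 1 & y <= shape[2] &
      x >= 1 & x <= shape[3]
    pore[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  pore
}

#' Disordered throat-lattice phantom
#'
#' As [make_throat_lattice()], but every throat segment (pore-to-pore and
#' pore-to-surface) gets an independent random integer width drawn uniformly
#' from `throat_range`. The spread of throat widths produces a genuine
#' finite percolation transition, so the phantom exercises Region-2 scaling
#' fits. Ground truth is *not* assumed from construction: measure it with
#' [percolation_threshold_direct()] on the generated volume.
#'
#' @inheritParams make_throat_lattice
#' @param throat_range integer 2-vector `(t_min, t_max)`, voxels;
#'   `t_min >= 2`.
#' @param seed RNG seed; identical specs give bit-identical volumes.
#' @export
make_disordered_throat_lattice <- function(shape = c(128, 128, 128),
                                           spacing_um = 1, pitch = 16,
                                           pore_diameter = 14,
                                           throat_range = c(4, 12),
                                           seed = 1) {
  if (throat_range[1] < 2) stop("`throat_range[1]` must be >= 2 voxels",
                                call. = FALSE)
  if (pore_diameter <= throat_range[2])
    stop("`pore_diameter` must exceed the widest throat", call. = FALSE)
  if (pitch <= pore_diameter)
    stop("`pitch` must exceed `pore_diameter`", call. = FALSE)
  shape <- as.integer(shape)
  ctr <- lapply(shape, lattice_centers, pitch = pitch)
  pore <- array(FALSE, dim = shape)
  rand_w <- function() sample(seq(throat_range[1], throat_range[2]), 1L)

  with_seed(seed, {
    carve_seg <- function(zr, yr, xr) {
      zr <- zr[zr >= 1 & zr <= shape[1]]
      yr <- yr[yr >= 1 & yr <= shape[2]]
      xr <- xr[xr >= 1 & xr <= shape[3]]
      pore[zr, yr, xr] <<- TRUE
    }
    # axis 1 (z) segments at every (cy, cx) column, including face stubs
    for (cy in ctr[[2]]) for (cx in ctr[[3]]) {
      bounds <- c(1L, ctr[[1]], shape[1])
      for (i in seq_len(length(bounds) - 1)) {
        w <- rand_w()
        carve_seg(bounds[i]:bounds[i + 1], centered_run(cy, w),
                  centered_run(cx, w))
      }
    }
    for (cz in ctr[[1]]) for (cx in ctr[[3]]) {
      bounds <- c(1L, ctr[[2]], shape[2])
      for (i in seq_len(length(bounds) - 1)) {
        w <- rand_w()
        carve_seg(centered_run(cz, w), bounds[i]:bounds[i + 1],
                  centered_run(cx, w))
      }
    }
    for (cz in ctr[[1]]) for (cy in ctr[[2]]) {
      bounds <- c(1L, ctr[[3]], shape[3])
      for (i in seq_len(length(bounds) - 1)) {
        w <- rand_w()
        carve_seg(centered_run(cz, w), centered_run(cy, w),
                  bounds[i]:bounds[i + 1])
      }
    }
  })
  pore <- pore | carve_spheres(shape, ctr, pore_diameter)
  phantom_grid(pore, spacing_um, "disordered_throat_lattice",
               list(pitch = pitch, pore_diameter = pore_diameter,
                    throat_range = throat_range),
               seed)
}

#' Lamellar (plate-like) phantom
#'
#' Parallel solid walls normal to x, separated by open channels of width
#' `channel_width` that run unobstructed along z (and y). Each wall is
#' pierced by `holes_per_wall` circular holes of diameter `hole_diameter` at
#' random positions. By construction the percolation diameter along z is the
#' channel width and along x the hole diameter (up to discretization of the
#' circular hole), giving a strongly anisotropic structure reminiscent of
#' directionally solidified, plate-like pore architectures.
#'
#' @inheritParams make_disordered_throat_lattice
#' @param channel_width gap between walls, voxels (`> hole_diameter`).
#' @param wall_thickness wall thickness, voxels.
#' @param hole_diameter hole diameter, voxels (`>= 2`); 0 for no holes
#'   (the x direction then never percolates).
#' @param holes_per_wall number of random holes in each wall.
#' @export
make_lamellar <- function(shape = c(64, 64, 84), spacing_um = 1,
                          channel_width = 12, wall_thickness = 2,
                          hole_diameter = 5, holes_per_wall = 4, seed = 1) {
  if (hole_diameter != 0 && hole_diameter < 2)
    stop("`hole_diameter` must be >= 2 voxels (or 0 for none)", call. = FALSE)
  if (channel_width <= hole_diameter)
    stop("`channel_width` must exceed `hole_diameter`", call. = FALSE)
  shape <- as.integer(shape)
  period <- channel_width + wall_thickness
  xpos <- seq_len(shape[3])
  in_wall <- ((xpos - 1) %% period) >= channel_width
  pore <- array(TRUE, dim = shape)
  pore[, , in_wall] <- FALSE
  wall_starts <- xpos[in_wall & !c(FALSE, in_wall[-length(in_wall)])]
  if (hole_diameter >= 2 && holes_per_wall > 0) {
    rh <- hole_diameter / 2
    off <- -ceiling(rh):ceiling(rh)
    disc <- expand.grid(dz = off, dy = off)
    disc <- disc[disc$dz^2 + disc$dy^2 <= rh^2 + EPS_R2, ]
    with_seed(seed, {
      for (x0 in wall_starts) {
        xr <- x0:min(x0 + wall_thickness - 1, shape[3])
        for (h in seq_len(holes_per_wall)) {
          cz <- sample(seq_len(shape[1]), 1L)
          cy <- sample(seq_len(shape[2]), 1L)
          z <- cz + disc$dz; y <- cy + disc$dy
          ok <- z >= 1 & z <= shape[1] & y >= 1 & y <= shape[2]
          for (x in xr) pore[cbind(z[ok], y[ok], x)] <- TRUE
        }
      }
    })
  }
  gt <- list(channel_width * spacing_um, channel_width * spacing_um,
             channel_width * spacing_um, channel_width * spacing_um,
             if (hole_diameter >= 2) hole_diameter * spacing_um else 0,
             if (hole_diameter >= 2) hole_diameter * spacing_um else 0)
  names(gt) <- c("z-", "z+", "y-", "y+", "x-", "x+")
  phantom_grid(pore, spacing_um, "lamellar",
               list(channel_width = channel_width,
                    wall_thickness = wall_thickness,
                    hole_diameter = hole_diameter,
                    holes_per_wall = holes_per_wall),
               seed, ground_truth = gt)
}

#' Equiaxed foam phantom
#'
#' Thresholded smoothed Gaussian random field: statistically isotropic,
#' with roughly equiaxed pores whose size scales with `correlation_length`.
#' The threshold is the porosity quantile of the field, so the target pore
#' fraction is met exactly before despeckling. Both phases are then
#' despeckled; at the default porosity the achieved pore fraction stays
#' within 2 percentage points of the target. Much above ~0.8 porosity the
#' random field's solid phase falls below its percolation threshold and
#' fragments, so wall despeckling would inflate porosity — real freeze-dried
#' scaffolds reach far higher porosity only because their walls are
#' connected sheets, which this generator does not emulate.
#'
#' @inheritParams make_disordered_throat_lattice
#' @param porosity target pore volume fraction, in `(0.5, 0.99)`;
#'   default 0.75.
#' @param correlation_length feature length scale in voxels (`>= 3`); the
#'   Gaussian smoothing kernel uses `sigma = correlation_length / 2`.
#' @export
make_equiaxed_foam <- function(shape = c(64, 64, 64), spacing_um = 1,
                               porosity = 0.75, correlation_length = 4,
                               seed = 1) {
  if (porosity <= 0.5 || porosity >= 0.99)
    stop("`porosity` must be in (0.5, 0.99)", call. = FALSE)
  if (correlation_length < 3)
    stop("`correlation_length` must be >= 3 voxels", call. = FALSE)
  shape <- as.integer(shape)
  field <- with_seed(seed, rnorm(prod(shape)))
  sm <- cpp_gaussian_smooth(field, shape, correlation_length / 2)
  thr <- quantile(sm, 1 - porosity, names = FALSE)
  pore <- array(sm >= thr, dim = shape)
  g <- phantom_grid(pore, spacing_um, "equiaxed_foam",
                    list(porosity = porosity,
                         correlation_length = correlation_length),
                    seed)
  g2 <- despeckle_keep_largest(g, "pore")
  g2 <- despeckle_keep_largest(g2, "wall")
  g2$phantom_spec <- g$phantom_spec
  g2
}

# ---- brute-force oracle -----------------------------------------------------

# Independent padding used by the oracle (same contract as the analysis
# path, separate code): open faces get free space, sealed faces get
# full-extent wall plates.
oracle_pad <- function(pore, pad, open_faces) {
  d <- dim(pore)
  nd <- d + 2L * pad
  big <- array(TRUE, dim = nd)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- pore
  for (f in setdiff(ALL_FACES, open_faces)) {
    fi <- face_info(f)
    idx <- if (fi$side < 0L) seq_len(pad) else (nd[fi$axis] - pad + 1L):nd[fi$axis]
    if (fi$axis == 1L) big[idx, , ] <- FALSE
    else if (fi$axis == 2L) big[, idx, ] <- FALSE
    else big[, , idx] <- FALSE
  }
  big
}

# Connected-component labels via igraph (independent of the C++ labeling).
oracle_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  nv <- sum(mask)
  lab <- array(0L, dim = d)
  if (nv == 0) return(lab)
  vid <- array(0L, dim = d)
  vid[mask] <- seq_len(nv)
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity == 26L) {
    offs <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      o <- c(dz, dy, dx)
      nzro <- which(o != 0)
      if (length(nzro) && o[nzro[1]] > 0) offs[[length(offs) + 1]] <- o
    }
  }
  edges <- integer(0)
  for (o in offs) {
    both <- mask & shift_array(mask, -o, fill = FALSE)
    if (!any(both)) next
    from <- vid[both]
    to <- shift_array(vid, -o, fill = 0L)[both]
    edges <- c(edges, as.vector(rbind(from, to)))
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  lab[mask] <- igraph::components(g)$membership
  lab
}

#' Brute-force sphere accessibility oracle
#'
#' Definitional reimplementation of [accessible_region()] by explicit
#' discrete-ball enumeration: a sphere fits at a voxel iff no wall voxel
#' center lies strictly within d/2 of it (checked offset by offset with
#' array shifts); reachable centers are the fit-voxel components (labeled by
#' igraph, not the package's C++ labeler) containing an open-face entry
#' voxel; the access mask is the explicit union of balls around reachable
#' centers, intersected with pore. Intended for validating
#' [accessible_region()] on small grids: the cost is O(voxels x ball
#' volume).
#'
#' @inheritParams accessible_region
#' @return list with `center_mask` and `access_mask` (logical arrays of the
#'   grid's dimensions).
#' @export
brute_force_accessible <- function(grid, diameter_um, faces,
                                   connectivity = 6L) {
  assert_grid(grid)
  faces <- face_set(faces)
  d <- dim(grid$pore)
  if (prod(d) > 300000)
    stop("grid too large for the brute-force oracle (> ~64^3 voxels)",
         call. = FALSE)
  s <- grid$spacing_um
  r_vox <- diameter_um / (2 * s)
  r2 <- r_vox^2
  pad <- as.integer(ceiling(r_vox)) + 1L
  pp <- oracle_pad(grid$pore, pad, faces)
  nd <- dim(pp)
  wall <- !pp

  m <- as.integer(ceiling(r_vox))
  offg <- expand.grid(dz = -m:m, dy = -m:m, dx = -m:m)
  q2 <- offg$dz^2 + offg$dy^2 + offg$dx^2

  fits <- pp
  forb <- offg[q2 < r2 - EPS_R2, , drop = FALSE]
  for (i in seq_len(nrow(forb))) {
    o <- as.integer(forb[i, ])
    # no wall allowed at c + o: pull the wall flag at c + o onto c
    fits <- fits & !shift_array(wall, -o, fill = FALSE)
    if (!any(fits)) break
  }

  seed <- array(FALSE, dim = nd)
  for (f in faces) {
    fi <- face_info(f)
    idx <- if (fi$side < 0L) seq_len(pad) else (nd[fi$axis] - pad + 1L):nd[fi$axis]
    if (fi$axis == 1L) seed[idx, , ] <- TRUE
    else if (fi$axis == 2L) seed[, idx, ] <- TRUE
    else seed[, , idx] <- TRUE
  }

  lab <- oracle_components(fits, connectivity)
  keep <- setdiff(unique(lab[seed & fits]), 0L)
  center_p <- array(lab %in% keep, dim = nd)

  if (any(center_p)) {
    sweep <- offg[q2 <= r2 + EPS_R2, , drop = FALSE]
    acc <- array(FALSE, dim = nd)
    for (i in seq_len(nrow(sweep))) {
      o <- as.integer(sweep[i, ])
      acc <- acc | shift_array(center_p, o, fill = FALSE)
    }
    acc <- acc & pp
  } else {
    acc <- center_p
  }
  list(center_mask = crop_volume(center_p, pad, d),
       access_mask = crop_volume(acc, pad, d))
}
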