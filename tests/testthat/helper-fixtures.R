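# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures are stored.

# iid random pore grid (pore probability p), seeded
rand_grid <- function(shape = c(32, 32, 32), p = 0.65, seed = 1,
                      spacing_um = 2) {
  pore <- withr::with_seed(seed,
    array(runif(prod(shape)) < p, dim = shape))
  voxel_grid(pore, spacing_um = spacing_um)
}

# straight square channel of `width` voxels along z, walls elsewhere
channel_grid <- function(nz = 20, side = 11, width = 5, spacing_um = 1) {
  pore <- array(FALSE, dim = c(nz, side, side))
  mid <- (side - width) %/% 2
  pore[, mid + seq_len(width), mid + seq_len(width)] <- TRUE
  voxel_grid(pore, spacing_um = spacing_um)
}

all_pore_grid <- function(n = 10, spacing_um = 1)
  voxel_grid(array(TRUE, dim = c(n, n, n)), spacing_um = spacing_um)

# Independent explicit-ball center-space oracle: for every pore voxel, test
# whether any wall voxel center lies strictly within d/2 (walls inside the
# volume only, matching center_space()).
explicit_center_space <- function(grid, diameter_um) {
  d <- dim(grid$pore)
  s <- grid$spacing_um
  r2 <- (diameter_um / (2 * s))^2
  wall <- which(!grid$pore, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  for (i in which(grid$pore)) {
    co <- arrayInd(i, d)
    dist2 <- (wall[, 1] - co[1])^2 + (wall[, 2] - co[2])^2 +
      (wall[, 3] - co[3])^2
    out[i] <- nrow(wall) == 0 || min(dist2) >= r2 - 1e-9
  }
  out
}

# Synthetic scaling-law points L = C * (d - d_c)^(-exponent)
scaling_points <- function(d, d_c, C, exponent = 0.88, face = "z-") {
  data.frame(diameter_um = d,
             max_distance_um = C * (d - d_c)^(-exponent),
             percolates = FALSE, face = face)
}
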