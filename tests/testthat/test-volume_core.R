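# Domain types, volume I/O, and minimal preprocessing.

test_that("voxel_grid validates its invariants", {
  expect_error(voxel_grid(matrix(TRUE, 3, 3), 1), "3D")
  expect_error(voxel_grid(array(TRUE, c(2, 3, 3)), 1), ">= 3")
  expect_error(voxel_grid(array(TRUE, c(3, 3, 3)), 0), "positive")
  expect_error(voxel_grid(array(TRUE, c(3, 3, 3)), -1), "positive")
  expect_error(voxel_grid(array(c(NA, rep(TRUE, 26)), c(3, 3, 3)), 1), "NA")
  # numeric input is binarized nonzero -> pore
  g <- voxel_grid(array(c(0, 2, rep(1, 25)), c(3, 3, 3)), 1.5)
  expect_identical(sum(g$pore), 26L)
  expect_identical(dim(g), c(3L, 3L, 3L))
})

test_that("TIFF and raw round trips preserve data and spacing", {
  for (seed in 1:25) {
    shape <- withr::with_seed(seed, sample(3:12, 3, replace = TRUE))
    g <- rand_grid(shape, p = 0.5, seed = seed, spacing_um = seed / 7)
    tf <- withr::local_tempfile(fileext = ".tif")
    write_volume(g, tf)
    g2 <- read_volume(tf)
    expect_identical(g2$pore, g$pore)
    expect_equal(g2$spacing_um, g$spacing_um)
    rf <- withr::local_tempfile(fileext = ".raw")
    write_volume(g, rf)
    g3 <- read_volume(rf)
    expect_identical(g3$pore, g$pore)
    expect_equal(g3$spacing_um, g$spacing_um)
  }
})

test_that("spacing metadata records the written value exactly", {
  g <- all_pore_grid(3, spacing_um = 3.74)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, tf)
  expect_equal(read_volume(tf)$spacing_um, 3.74)
  # all-pore grid -> pages of zeros on disk
  raw <- readBin(tf, "raw", n = file.info(tf)$size)
  expect_true(any(raw == as.raw(0)))
  g2 <- voxel_grid(array(FALSE, c(3, 3, 3)), 1)  # all wall
  write_volume(g2, tf)
  expect_identical(read_volume(tf)$pore, g2$pore)
})

test_that("our TIFF agrees with Python tifffile in both directions", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  g <- rand_grid(c(5, 7, 6), p = 0.4, seed = 42, spacing_um = 3.74)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, tf)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread(%s)\n",
    "np.savetxt(%s, a.reshape(a.shape[0], -1), fmt='%%d')\n",
    "print(a.shape)"), deparse(tf), deparse(out))
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  expect_match(paste(res, collapse = " "), "(5, 7, 6)", fixed = TRUE)
  vals <- as.matrix(read.table(out))
  arr <- array(0L, dim = c(5, 7, 6))
  for (z in 1:5) arr[z, , ] <- matrix(vals[z, ], nrow = 7, byrow = TRUE)
  expect_identical(array(arr == 0L, dim = dim(arr)), g$pore)

  # reverse: a grayscale stack written by tifffile, read with a threshold
  tf2 <- withr::local_tempfile(fileext = ".tif")
  script2 <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = np.zeros((4, 5, 6), dtype=np.uint8)\n",
    "a[0] = 0; a[1] = 100; a[2] = 128; a[3] = 255\n",
    "tifffile.imwrite(%s, a, photometric='minisblack')\n"), deparse(tf2))
  writeLines(script2, sf)
  system2(py, sf, stdout = TRUE, stderr = TRUE)
  g2 <- suppressWarnings(read_volume(tf2, spacing_um = 1, threshold = 128))
  # z slices 1,2 below threshold -> pore; 3,4 at/above -> wall
  expect_true(all(g2$pore[1:2, , ]))
  expect_false(any(g2$pore[3:4, , ]))
})

test_that("despeckle keeps only the largest component of the chosen phase", {
  pore <- array(FALSE, dim = c(10, 10, 10))
  pore[2:8, 2:6, 2:3] <- TRUE            # 70-voxel blob
  pore[2:6, 8:10, 9:10] <- TRUE          # 30-voxel blob
  g <- voxel_grid(pore, 1)
  out <- despeckle_keep_largest(g, "pore")
  expect_identical(sum(out$pore), 70L)
  expect_true(all(out$pore[2:8, 2:6, 2:3]))
  # idempotent, never increases the phase count
  expect_identical(despeckle_keep_largest(out, "pore")$pore, out$pore)
  for (seed in 1:10) {
    g <- rand_grid(c(12, 12, 12), p = 0.4, seed = seed)
    d1 <- despeckle_keep_largest(g, "pore")
    expect_lte(sum(d1$pore), sum(g$pore))
    expect_identical(despeckle_keep_largest(d1, "pore")$pore, d1$pore)
  }
  # equal-size tie: the component with the lowest scan-order voxel wins
  pore <- array(FALSE, dim = c(9, 3, 3))
  pore[1:2, 1, 1] <- TRUE
  pore[8:9, 3, 3] <- TRUE
  out <- despeckle_keep_largest(voxel_grid(pore, 1), "pore")
  expect_true(all(out$pore[1:2, 1, 1]))
  expect_false(any(out$pore[8:9, 3, 3]))
  # wall despeckling flips wall speckles to pore
  pore <- array(TRUE, dim = c(8, 8, 8))
  pore[4, 4, 4] <- FALSE
  pore[1:8, 1, 1] <- FALSE
  out <- despeckle_keep_largest(voxel_grid(pore, 1), "wall")
  expect_true(out$pore[4, 4, 4])
  expect_false(any(out$pore[1:8, 1, 1]))
  expect_error(despeckle_keep_largest(all_pore_grid(4), "wall"), "no wall")
})

test_that("median filter follows the anchored-window majority/tie contract", {
  # uniform grids are fixed points
  g <- all_pore_grid(5)
  expect_identical(median_filter_small(g)$pore, g$pore)
  gw <- voxel_grid(array(FALSE, c(5, 5, 5)), 1)
  expect_identical(median_filter_small(gw)$pore, gw$pore)
  # isolated wall speckle in a pore sea disappears
  pore <- array(TRUE, dim = c(7, 7, 7))
  pore[4, 4, 4] <- FALSE
  out <- median_filter_small(voxel_grid(pore, 1))
  expect_true(all(out$pore))
  # 4/4 ties resolve to WALL: explicit per-voxel oracle on a checkerboard
  idx <- expand.grid(z = 1:4, y = 1:4, x = 1:4)
  pore <- array((idx$z + idx$y + idx$x) %% 2 == 0, dim = c(4, 4, 4))
  g <- voxel_grid(pore, 1)
  expected <- array(NA, dim = c(4, 4, 4))
  for (z in 1:4) for (y in 1:4) for (x in 1:4) {
    win <- pore[z:min(z + 1, 4), y:min(y + 1, 4), x:min(x + 1, 4)]
    expected[z, y, x] <- sum(win) * 2 > length(win)  # tie -> WALL
  }
  expect_identical(median_filter_small(g)$pore, expected)
  # interior windows of a checkerboard are all 4/4 ties -> wall
  expect_false(any(median_filter_small(g)$pore[1:3, 1:3, 1:3]))
})

test_that("voxel/um conversions match the printed shrink-wrap range", {
  expect_equal(voxels_to_um(2, 3.74), 7.48)       # reported as 7.5 um
  expect_equal(voxels_to_um(16, 3.74), 59.84)     # reported as 60 um
  expect_equal(voxels_to_um(1, 1.0), 1.0)
  expect_equal(um_to_voxels(7.48, 3.74), 2)
  expect_equal(um_to_voxels(10, 4), 2.5)          # no rounding
  expect_error(voxels_to_um(0, 1), "positive")
  expect_error(voxels_to_um(2, -1), "positive")
  expect_error(um_to_voxels(-3, 1), "positive")
})
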