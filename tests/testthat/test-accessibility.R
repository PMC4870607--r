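# Flood fill, center space, shrink-wrap accessibility, interconnectivity.

test_that("flood_fill_fraction matches counts and an independent labeler", {
  expect_equal(flood_fill_fraction(all_pore_grid(6)), 100)
  pore <- array(FALSE, dim = c(10, 10, 10))
  pore[2:8, 2:6, 2:3] <- TRUE   # 70 voxels
  pore[2:6, 8:10, 9:10] <- TRUE # 30 voxels
  expect_equal(flood_fill_fraction(voxel_grid(pore, 1)), 70)
  expect_error(flood_fill_fraction(voxel_grid(array(FALSE, c(3, 3, 3)), 1)),
               "no pore")
  # independent igraph-based label-and-count oracle on random phantoms
  for (seed in 1:5) {
    g <- rand_grid(c(16, 16, 16), p = 0.4, seed = seed)
    lab <- poreperc:::oracle_components(g$pore, 26L)
    expect_equal(flood_fill_fraction(g),
                 100 * max(tabulate(lab[lab > 0])) / sum(g$pore))
    lab6 <- poreperc:::oracle_components(g$pore, 6L)
    expect_equal(flood_fill_fraction(g, connectivity = 6),
                 100 * max(tabulate(lab6[lab6 > 0])) / sum(g$pore))
  }
})

test_that("center_space matches the explicit discrete-ball definition", {
  g <- channel_grid(nz = 12, side = 9, width = 5, spacing_um = 2)
  expect_identical(center_space(g, 0), g$pore)
  for (d_vox in c(3, 5)) {
    got <- center_space(g, d_vox * g$spacing_um)
    expect_identical(got, explicit_center_space(g, d_vox * g$spacing_um))
  }
  # d = 5 voxels in a 5-wide square channel: only the 1-voxel axial core
  cs <- center_space(g, 5 * g$spacing_um)
  expect_identical(sum(cs), 12L)
  expect_true(all(cs[, 5, 5]))
  # diameter beyond twice the maximum EDT: empty
  expect_false(any(center_space(g, 100 * g$spacing_um)))
  expect_error(center_space(g, -1), ">= 0")
  # random phantoms against the explicit oracle
  for (seed in 1:5) {
    g <- rand_grid(c(10, 10, 10), p = 0.7, seed = seed, spacing_um = 1.5)
    for (d_vox in c(2, 3.5)) {
      dum <- d_vox * g$spacing_um
      expect_identical(center_space(g, dum), explicit_center_space(g, dum))
    }
  }
})

test_that("accessible_region handles full and blocked volumes", {
  g <- all_pore_grid(8)
  res <- accessible_region(g, 4, face_set("z-"))
  expect_identical(res$access_mask, g$pore)
  expect_equal(res$accessible_volume_um3, 512)
  expect_equal(interconnectivity_percent(g, res), 100)

  # channel narrower than the sphere: no center position inside the volume;
  # the sphere may still *touch* the channel mouth from outside the open
  # face, so any swept voxels are confined to within ceiling(d/2) of it
  g <- channel_grid(nz = 10, side = 9, width = 3, spacing_um = 1)
  res <- accessible_region(g, 6, face_set("z-"))
  expect_false(any(res$center_mask))
  expect_false(any(res$access_mask[4:10, , ]))
  expect_lt(interconnectivity_percent(g, res), 15)
  expect_error(accessible_region(g, 4, character(0)))
})

test_that("accessible_region equals the brute-force oracle", {
  modes <- list(face_set("3d"), face_set("z-"))
  for (seed in 1:12) {
    g <- rand_grid(c(14, 14, 14), p = 0.7, seed = seed, spacing_um = 2)
    for (d_vox in c(2, 3, 4)) {
      dum <- d_vox * g$spacing_um
      for (faces in modes) {
        got <- accessible_region(g, dum, faces)
        want <- brute_force_accessible(g, dum, faces)
        expect_identical(got$center_mask, want$center_mask)
        expect_identical(got$access_mask, want$access_mask)
      }
    }
  }
})

test_that("interconnectivity_percent implements the accessible/pore ratio", {
  # constructed fixture: V = 1000, V_m = 200 (wall), accessible = 600
  pore <- array(TRUE, dim = c(10, 10, 10))
  pore[, , 9:10] <- FALSE                       # 200 wall voxels
  g <- voxel_grid(pore, 1)
  res <- accessible_region(g, 0, face_set("3d"))
  res$access_mask[, , 7:8] <- FALSE             # leave 600 accessible
  expect_equal(interconnectivity_percent(g, res), 75)
  expect_error(interconnectivity_percent(all_pore_grid(4), res), "shapes")
})

test_that("interconnectivity curves behave per contract", {
  g <- all_pore_grid(10)
  cur <- interconnectivity_curve(g, c(1, 2, 4), face_set("z-"))
  expect_equal(cur$interconnectivity_percent, rep(100, 3))
  expect_error(interconnectivity_curve(g, c(4, 2), face_set("z-")),
               "increasing")
  expect_error(interconnectivity_curve(g, c(2, 2, 4), face_set("z-")),
               "increasing")
  expect_error(interconnectivity_curve(g, 3, face_set("z-")), "at least 2")

  # throat lattice: sigmoidal drop across the throat width
  tl <- make_throat_lattice(shape = c(48, 48, 48), pitch = 16,
                            pore_diameter = 12, throat_width = 6)
  cur <- interconnectivity_curve(tl, c(4, 6, 8, 10), face_set("3d"))
  expect_gt(cur$interconnectivity_percent[2],
            cur$interconnectivity_percent[3] + 30)
})

test_that("center masks nest in d and face removal only shrinks access", {
  for (seed in 1:6) {
    g <- rand_grid(c(14, 14, 14), p = 0.75, seed = seed)
    prev <- NULL
    for (d in c(2, 3, 4, 5)) {
      res <- accessible_region(g, d, face_set("3d"))
      if (!is.null(prev))
        expect_true(all(prev$center_mask | !res$center_mask))  # subset
      prev <- res
    }
    # Method B (all faces) dominates every Method C (single face)
    d <- 3
    b <- accessible_region(g, d, face_set("3d"))
    for (f in c("z-", "y+", "x-")) {
      cres <- accessible_region(g, d, face_set(f))
      expect_true(all(b$access_mask | !cres$access_mask))
      expect_lte(interconnectivity_percent(g, cres),
                 interconnectivity_percent(g, b))
    }
  }
})

test_that("monotonicity: center accounting exact, swept within tolerance", {
  for (seed in 1:4) {
    g <- rand_grid(c(14, 14, 14), p = 0.75, seed = seed)
    cc <- interconnectivity_curve(g, c(2, 3, 4, 5, 6), face_set("3d"),
                                  accounting = "center")
    expect_true(all(diff(cc$interconnectivity_percent) <= 0))
    cs <- interconnectivity_curve(g, c(2, 3, 4, 5, 6), face_set("3d"))
    expect_true(all(diff(cs$interconnectivity_percent) <= 0.5))
    expect_true(all(cs$interconnectivity_percent >= 0 &
                      cs$interconnectivity_percent <= 100))
  }
})
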