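test_that("voxel volume converges to mesh volume within the surface bound", {
  shapes <- list(cube = cuboid_mesh(c(0, 0, 0), c(10, 10, 10)),
                 sphere = icosphere(10, 3),
                 blob = rand_blob(11))
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    vol <- enclosed_volume(s)
    sa <- surface_area(s)
    for (sp in c(2, 1, 0.5)) {
      m <- voxelize(s, sp)
      expect_lt(abs(mask_volume(m) - vol), sa * sp,
                label = sprintf("%s at %g mm: |voxel-mesh| vs bound", nm, sp))
    }
  }
  # sphere at 1 mm: volume error < 3%
  s <- icosphere(10, 3)
  m <- voxelize(s, 1)
  expect_lt(abs(mask_volume(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.03)
})

test_that("voxelization is exact for a grid-aligned cube", {
  m <- voxelize(cuboid_mesh(), 0.25)
  expect_equal(mask_volume(m), 1)
})

test_that("too-coarse voxelization raises a degenerate-resolution error", {
  small <- icosphere(0.3, 1)
  expect_error(voxelize(small, 5), "degenerate resolution")
})

test_that("distance field equals the brute-force scan on small grids", {
  for (seed in 1:3) {
    set.seed(seed)
    dims <- c(18L, 15L, 12L)
    occ <- array(runif(prod(dims)) < 0.01, dims)
    occ[1, 1, 1] <- TRUE   # never empty
    m <- voxel_mask(c(0, 0, 0), 0.8, occ)
    expect_equal(distance_to_region(m), brute_distance_field(m),
                 tolerance = 1e-9)
  }
  # all-occupied mask: identically zero
  m1 <- voxel_mask(c(0, 0, 0), 1, array(TRUE, c(4, 4, 4)))
  expect_true(all(distance_to_region(m1) == 0))
  # single occupied voxel: plain Euclidean distance to its center
  occ <- array(FALSE, c(9, 9, 9)); occ[5, 5, 5] <- TRUE
  m2 <- voxel_mask(c(0, 0, 0), 2, occ)
  d <- distance_to_region(m2)
  expect_equal(d[1, 1, 1], 2 * sqrt(3 * 16))
  expect_equal(d[5, 5, 9], 8)
})

test_that("distance field requires matching grids", {
  a <- voxelize(icosphere(6, 2), 2)
  b <- voxelize(icosphere(6, 2, center = c(40, 0, 0)), 2)
  expect_error(distance_to_region(a, within = b), "grid geometry")
})

test_that("expand_uniform: identity at zero, monotone, Euclidean ball", {
  set.seed(21)
  occ <- array(runif(16^3) < 0.02, c(16, 16, 16))
  occ[8, 8, 8] <- TRUE
  m <- voxel_mask(c(0, 0, 0), 1, occ, pad_mm = 20)
  expect_identical(expand_uniform(m, 0)$occupancy, m$occupancy)
  e1 <- expand_uniform(m, 1.4)
  e2 <- expand_uniform(m, 3.1)
  expect_true(all(e1$occupancy[m$occupancy]))           # grows
  expect_true(all(e2$occupancy[e1$occupancy]))          # monotone
  expect_error(expand_uniform(m, -1), "non-negative")

  # single voxel -> discrete Euclidean ball
  occ1 <- array(FALSE, c(11, 11, 11)); occ1[6, 6, 6] <- TRUE
  ball <- expand_uniform(voxel_mask(c(0, 0, 0), 1, occ1, pad_mm = 10), 2.5)
  ctr <- expand.grid(i = 1:11, j = 1:11, k = 1:11)
  inside <- sqrt((ctr$i - 6)^2 + (ctr$j - 6)^2 + (ctr$k - 6)^2) <= 2.5
  expect_identical(as.vector(ball$occupancy), inside)

  # sphere r = 10 expanded by 5 ~ sphere r = 15
  ms <- voxelize(icosphere(10, 3), 1, pad = 7)
  e <- expand_uniform(ms, 5)
  expect_lt(abs(mask_volume(e) - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3),
            0.06)
})

test_that("grid operations are translation-invariant within one voxel", {
  b <- rand_blob(31)
  t <- c(0.37, -0.61, 0.29) * 3
  bt <- transform_contour(b, translation = t)
  for (sp in c(1, 2)) {
    va <- mask_volume(voxelize(b, sp))
    vb <- mask_volume(voxelize(bt, sp))
    expect_lt(abs(va - vb), surface_area(b) * sp)
  }
})

test_that("mask export writes raw + sidecar that reload consistently", {
  m <- voxelize(icosphere(6, 2), 2)
  stem <- file.path(withr::local_tempdir(), "mask")
  write_mask(m, stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  raw <- readBin(paste0(stem, ".bin"), "integer", n = prod(meta$shape),
                 size = 1L)
  expect_equal(meta$spacing_mm, m$spacing)
  expect_equal(meta$shape, dim(m$occupancy))
  expect_identical(as.logical(raw), as.vector(m$occupancy))
})
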