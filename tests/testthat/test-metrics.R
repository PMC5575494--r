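test_that("identical contours are perfect on all four metrics", {
  b <- rand_blob(1)
  expect_equal(dc(b, b), 0)
  expect_equal(dsc(b, b), 1)
  expect_equal(mssd(b, b), 0)
  expect_equal(um95(b, b), 0)
})

test_that("DC is the centroid distance and is symmetric", {
  a <- icosphere(5, 3)
  b <- icosphere(5, 3, center = c(3, 4, 0))
  expect_equal(dc(a, b), 5, tolerance = 1e-9)
  expect_equal(dc(a, b), dc(b, a))
  # translation of a synthetic uterus moves DC by exactly the shift
  u <- generate_true_shape(uterus_params(seed = 3), subdiv = 3)
  expect_equal(dc(u, transform_contour(u, translation = c(3, 4, 0))), 5,
               tolerance = 1e-9)
})

test_that("DSC matches analytic overlaps and is symmetric in [0,1]", {
  # concentric spheres radius r and 2r: 2*1/(1+8)
  a <- icosphere(10, 3)
  b <- icosphere(20, 3)
  expect_equal(dsc(a, b, spacing = 0.5), 2 / 9, tolerance = 2 / 9 * 0.01)
  expect_equal(dsc(a, b, spacing = 1), dsc(b, a, spacing = 1))
  # unit cubes offset by half an edge: overlap 0.5 -> DSC 0.5
  c1 <- cuboid_mesh()
  c2 <- cuboid_mesh(c(0.5, 0, 0), c(1.5, 1, 1))
  expect_equal(dsc(c1, c2, spacing = 0.05), 0.5, tolerance = 0.02)
  # disjoint meshes: 0
  expect_equal(dsc(icosphere(3, 2), icosphere(3, 2, center = c(20, 0, 0)),
                   spacing = 1), 0)
})

test_that("DSC decreases monotonically as one contour translates away", {
  a <- icosphere(8, 2)
  prev <- 1
  for (shift in c(0, 3, 6, 9, 12, 16, 20)) {
    d <- dsc(a, transform_contour(a, translation = c(shift, 0, 0)),
             spacing = 1)
    expect_lte(d, prev + 1e-9)
    expect_gte(d, 0); expect_lte(d, 1)
    prev <- d
  }
  expect_equal(prev, 0)
})

test_that("MSSD: radial correspondence, exact oracle equality, directedness", {
  # concentric icospheres at equal subdivision: vertex-to-vertex ~ 10 mm
  a <- icosphere(10, 3)
  b <- icosphere(20, 3)
  expect_equal(mssd(a, b), 10, tolerance = 0.05)
  # accelerated path equals exhaustive scan bit-exactly on irregular meshes
  for (seed in 1:4) {
    x <- rand_blob(seed, radius = 9, subdiv = 2)
    y <- rand_blob(seed + 50, radius = 14, subdiv = 1)
    expect_identical(mssd(x, y, method = "grid"),
                     mssd(x, y, method = "brute"))
    expect_identical(mssd(y, x, method = "grid"),
                     mssd(y, x, method = "brute"))
  }
  # directed metric: sphere inside a flat ellipsoid
  sph <- icosphere(5, 2)
  ell <- icosphere(1, 2)
  ell$vertices <- ell$vertices %*% diag(c(20, 10, 5))
  expect_false(isTRUE(all.equal(mssd(sph, ell), mssd(ell, sph))))
  # surface variant is never larger than the vertex variant
  expect_lte(mssd(sph, ell, target = "surface"), mssd(sph, ell))
})

test_that("UM95 matches the analytic concentric-sphere margin", {
  a <- icosphere(10, 3)
  b <- icosphere(20, 3)
  m_exp <- 20 * 0.95^(1 / 3) - 10            # ~9.66 mm
  expect_equal(um95(a, b, spacing = 1), m_exp, tolerance = 1)
  expect_equal(um95(a, b, spacing = 0.5), m_exp, tolerance = 0.5)
  # B inside A: zero margin
  expect_equal(um95(b, a, spacing = 1), 0)
  expect_error(um95(a, b, coverage = 0), "coverage")
  expect_error(um95(a, b, coverage = 1.2), "coverage")
})

test_that("UM95 agrees with a margin-sweep oracle and certifies coverage", {
  for (seed in c(7, 17)) {
    a <- rand_blob(seed, radius = 10, subdiv = 2)
    b <- rand_blob(seed + 3, radius = 12, subdiv = 2)
    sp <- 1.2
    g <- uscontour:::grid_for(list(a, b), sp, pad = 6)
    ma <- voxelize(a, sp, grid = g)
    mb <- voxelize(b, sp, grid = g)
    m <- uscontour:::um95_masks(ma, mb, 0.95)
    # oracle: brute-force distance field + margin sweep in 0.05 mm steps
    dfield <- brute_distance_field(ma)
    dvals <- dfield[mb$occupancy]
    sweep <- seq(0, max(dvals) + 0.05, by = 0.05)
    cov <- vapply(sweep, function(mm) mean(dvals <= mm), numeric(1))
    m_oracle <- sweep[which(cov >= 0.95)[1]]
    expect_lte(abs(m - m_oracle), 0.05 + 1e-9)
    # coverage certificate on the expanded mask
    cov_m <- sum(expand_uniform(ma, m)$occupancy & mb$occupancy) /
      sum(mb$occupancy)
    expect_gte(cov_m, 0.95)
    if (m > 2 * sp) {
      cov_lo <- sum(expand_uniform(ma, m - 2 * sp)$occupancy & mb$occupancy) /
        sum(mb$occupancy)
      expect_lt(cov_lo, 0.95)
    }
  }
})

test_that("deviation map is the per-vertex max over others", {
  b <- rand_blob(9)
  expect_true(all(deviation_map(b, list(b)) == 0))
  shifted <- transform_contour(b, translation = c(2, 0, 0))
  d1 <- deviation_map(b, list(shifted))
  expect_true(all(d1 <= 2 + 1e-9))
  expect_gt(max(d1), 1.5)
  other2 <- transform_contour(b, translation = c(0, -1, 0))
  d2 <- deviation_map(b, list(other2))
  d12 <- deviation_map(b, list(shifted, other2))
  expect_equal(as.numeric(d12), pmax(as.numeric(d1), as.numeric(d2)))
  expect_error(deviation_map(b, list()), "at least one")
})

test_that("all four metrics are rigid-motion invariant (pair moved together)", {
  set.seed(5)
  u <- generate_true_shape(uterus_params(seed = 77), subdiv = 3)
  v <- perturb_contour(u, observer_model(), seed = 5)
  R <- rotation_matrix(c(0.2, 1, -0.5), 1.1)
  t <- c(12, -8, 25)
  u2 <- transform_contour(u, R, t)
  v2 <- transform_contour(v, R, t)
  sp <- 1.5
  expect_equal(dc(u2, v2), dc(u, v), tolerance = 1e-6)
  expect_equal(mssd(u2, v2), mssd(u, v), tolerance = 1e-6)
  expect_equal(dsc(u2, v2, sp), dsc(u, v, sp), tolerance = 0.05)
  expect_equal(um95(u2, v2, spacing = sp), um95(u, v, spacing = sp),
               tolerance = sp)
})
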