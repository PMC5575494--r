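test_that("enclosed volume and centroid are exact on closed-form shapes", {
  cb <- cuboid_mesh()
  expect_equal(enclosed_volume(cb), 1)
  expect_equal(volume_centroid(cb), c(0.5, 0.5, 0.5))

  # icosphere approaches the analytic ball volume from below
  ic <- icosphere(10, subdiv = 4)
  expect_lt(abs(enclosed_volume(ic) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.01)
  expect_lt(enclosed_volume(ic), 4 / 3 * pi * 1000)  # inscribed polyhedron

  # L-shaped union of two boxes: analytic centroid
  L <- l_shape_mesh()
  expect_equal(enclosed_volume(L), 3)
  expect_equal(volume_centroid(L), c(5 / 6, 0.5, 5 / 6), tolerance = 1e-12)
})

test_that("centroid is translation-equivariant and volume rigid-invariant", {
  b <- rand_blob(4)
  t <- c(-7.3, 11.1, 2.5)
  bt <- transform_contour(b, translation = t)
  expect_equal(volume_centroid(bt), volume_centroid(b) + t, tolerance = 1e-9)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  br <- transform_contour(b, rotation = R)
  expect_equal(enclosed_volume(br), enclosed_volume(b), tolerance = 1e-9)
  expect_equal(surface_area(br), surface_area(b), tolerance = 1e-9)
})

test_that("watertightness violations are rejected with informative errors", {
  cb <- cuboid_mesh()
  open_box <- surface_contour(cb$vertices, cb$faces[-1, , drop = FALSE],
                              validate = FALSE)
  expect_error(enclosed_volume(open_box), "not watertight")
  expect_error(assert_watertight(open_box), "2 faces")
  expect_error(surface_contour(cb$vertices, cb$faces[-1, , drop = FALSE]),
               "not watertight")
  expect_error(surface_contour(cb$vertices[1:3, ], cb$faces),
               "at least 4")
  v <- cb$vertices; v[1, 1] <- NA
  expect_error(surface_contour(v, cb$faces), "finite")
})

test_that("construction repairs inverted and inconsistent winding", {
  cb <- cuboid_mesh()
  # globally inverted: fixed silently by the sign of the enclosed volume
  inv <- surface_contour(cb$vertices, cb$faces[, c(1, 3, 2)])
  expect_equal(enclosed_volume(inv), 1)
  # a single flipped face: repaired by propagation
  f <- cb$faces; f[3, ] <- f[3, c(1, 3, 2)]
  fixed <- surface_contour(cb$vertices, f)
  expect_equal(enclosed_volume(fixed), 1)
})

test_that("icosphere tessellation is watertight at several subdivisions", {
  for (s in 0:3) {
    ic <- icosphere(5, s)
    expect_true(is_watertight(ic))
    expect_equal(nrow(ic$faces), 20 * 4^s)
  }
})
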