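# Fixtures are built in code; nothing is read from disk.

# L-shaped prism: union of boxes [0,2]x[0,1]x[0,1] and [0,1]x[0,1]x[1,2].
# Volume 3; centroid (2*(1,.5,.5) + 1*(.5,.5,1.5))/3 = (5/6, 1/2, 5/6).
l_shape_mesh <- function() {
  xz <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  v <- rbind(cbind(xz[, 1], 0, xz[, 2]), cbind(xz[, 1], 1, xz[, 2]))
  fan <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 6))
  caps <- rbind(fan[, c(1, 3, 2)], fan + 6L)   # y = 0 and y = 1 caps
  sides <- do.call(rbind, lapply(1:6, function(i) {
    j <- if (i == 6) 1L else i + 1L
    rbind(c(i, j, i + 6L), c(j, j + 6L, i + 6L))
  }))
  surface_contour(v, rbind(caps, sides))
}

# random smooth blob: perturbed icosphere (star-shaped, watertight)
rand_blob <- function(seed, radius = 12, subdiv = 2, wobble = 0.25) {
  set.seed(seed)
  s <- icosphere(radius, subdiv)
  d <- s$vertices / sqrt(rowSums(s$vertices^2))
  f <- 1 + wobble * (sin(3 * d[, 1] + runif(1, 0, 2)) *
                     cos(2 * d[, 2] + runif(1, 0, 2)) +
                     0.5 * sin(2 * d[, 3] + runif(1, 0, 2)))
  surface_contour(s$vertices * f, s$faces)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# brute-force Euclidean distance field on a small grid (independent of the
# package's distance transform)
brute_distance_field <- function(mask) {
  dims <- dim(mask$occupancy)
  sp <- mask$spacing
  idx <- which(mask$occupancy, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0)
  centers <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                         k = seq_len(dims[3]))
  d2 <- matrix(Inf, nrow(centers), 1)
  for (r in seq_len(nrow(idx))) {
    di <- (centers$i - idx[r, 1])^2 + (centers$j - idx[r, 2])^2 +
          (centers$k - idx[r, 3])^2
    d2 <- pmin(d2, di)
  }
  array(sqrt(d2) * sp, dim = dims)
}

# tiny manifest construction without the generator (for bookkeeping tests)
tiny_manifest <- function(n_images = 2, n_obs = 2, fail = integer(0),
                          rating = 3, seed = 99) {
  om <- observer_model(sigma_obs = 1.5)
  images <- lapply(seq_len(n_images), function(i) {
    truth <- generate_true_shape(uterus_params(seed = seed + i), subdiv = 2)
    id <- sprintf("t%02d", i)
    truth$image_id <- id
    manual <- list(); ags <- list()
    for (j in seq_len(n_obs)) {
      ob <- paste0("obs", j)
      m <- perturb_contour(truth, om, seed = seed + 10 * i + j)
      m$image_id <- id; m$delineator <- ob; m$method <- "manual"
      manual[[ob]] <- m
      if ((i * 10 + j) %in% fail) { ags[ob] <- list(NULL) } else {
        a <- perturb_contour(truth, om, seed = seed + 100 * i + j)
        a$image_id <- id; a$delineator <- ob; a$method <- "ags"
        ags[[ob]] <- a
      }
    }
    list(image_id = id, rating = rating, truth = truth,
         manual = manual, ags = ags)
  })
  ratings <- finalize_ratings(data.frame(
    image_id = vapply(images, `[[`, "", "image_id"),
    session1 = rating, session2 = rating))
  list(images = images, ratings = ratings)
}
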