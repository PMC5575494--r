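#' Closed 3D surface contour
#'
#' A `surface_contour` is a watertight triangle mesh delineating one organ in
#' the patient frame (+x Left, +y Anterior, +z Superior), coordinates in mm.
#' Every edge must be shared by exactly two faces and face winding must be
#' consistent with outward normals (signed enclosed volume positive; a mesh
#' with globally inverted winding is flipped silently on construction).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param image_id identifier of the source image (optional).
#' @param delineator observer label (optional).
#' @param method `"manual"` or `"ags"` (optional).
#' @param validate if `FALSE`, skip the watertightness check (internal use
#'   when the caller guarantees topology, e.g. after a radial perturbation
#'   that reuses the faces of a validated mesh).
#' @return an object of class `surface_contour`.
#' @export
surface_contour <- function(vertices, faces, image_id = NA_character_,
                            delineator = NA_character_,
                            method = NA_character_, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns", call. = FALSE)
  if (nrow(vertices) < 4L || nrow(faces) < 4L)
    stop("a closed surface needs at least 4 vertices and 4 faces",
         call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  x <- structure(
    list(vertices = vertices, faces = faces,
         image_id = as.character(image_id),
         delineator = as.character(delineator),
         method = as.character(method)),
    class = "surface_contour")
  if (validate) {
    x <- orient_outward(x)
    assert_watertight(x)
  }
  x
}

#' @export
print.surface_contour <- function(x, ...) {
  cat(sprintf(
    "surface_contour: %d vertices, %d faces, volume %.1f mm^3\n",
    nrow(x$vertices), nrow(x$faces), enclosed_volume(x)))
  if (!is.na(x$image_id))
    cat(sprintf("  image %s, delineator %s, method %s\n",
                x$image_id, x$delineator, x$method))
  invisible(x)
}

# undirected edge keys (integer, unique per vertex pair)
edge_keys <- function(faces, nv) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  (as.double(lo) - 1) * nv + (as.double(hi) - 1)
}

#' Check that a contour is a closed, consistently oriented 2-manifold
#'
#' Errors with a description of the defect (listing up to five offending
#' edges) if any edge is not shared by exactly two faces, or if two adjacent
#' faces traverse their shared edge in the same direction (inconsistent
#' winding).
#'
#' @param contour a `surface_contour` (or a bare vertices/faces list).
#' @return invisibly `TRUE`.
#' @export
assert_watertight <- function(contour) {
  faces <- contour$faces
  nv <- nrow(contour$vertices)
  keys <- edge_keys(faces, nv)
  cnt <- table(keys)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    k <- as.double(bad[seq_len(min(5L, length(bad)))])
    pairs <- sprintf("(%d,%d)", floor(k / nv) + 1, k %% nv + 1)
    stop(sprintf(
      "mesh is not watertight: %d edge(s) not shared by exactly 2 faces, e.g. %s",
      length(bad), paste(pairs, collapse = " ")), call. = FALSE)
  }
  # consistent orientation: each directed half-edge must appear exactly once
  de <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  dkeys <- (as.double(de[, 1L]) - 1) * nv + (as.double(de[, 2L]) - 1)
  if (anyDuplicated(dkeys))
    stop("mesh faces are not consistently oriented", call. = FALSE)
  invisible(TRUE)
}

is_watertight <- function(contour) {
  !inherits(try(assert_watertight(contour), silent = TRUE), "try-error")
}

# Repair face orientation: greedy breadth-first propagation across shared
# edges, then a global flip if the signed volume comes out negative.
orient_outward <- function(contour) {
  faces <- contour$faces
  nv <- nrow(contour$vertices)
  de <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  dkeys <- (as.double(de[, 1L]) - 1) * nv + (as.double(de[, 2L]) - 1)
  if (anyDuplicated(dkeys)) {
    faces <- propagate_orientation(faces, nv)
    contour$faces <- faces
  }
  v <- signed_volume(contour)
  if (is.finite(v) && v < 0) {
    contour$faces <- contour$faces[, c(1L, 3L, 2L)]
  }
  contour
}

propagate_orientation <- function(faces, nv) {
  nf <- nrow(faces)
  keys <- edge_keys(faces, nv)              # 3*nf undirected keys
  ord <- order(keys)
  # adjacency: faces sharing each undirected edge (expect pairs)
  runs <- rle(keys[ord])
  if (any(runs$lengths != 2L)) return(faces)  # not manifold; let check fail
  idx <- matrix(ord, nrow = 2L)               # columns = the two half-edges
  face_of <- function(h) ((h - 1L) %% nf) + 1L
  adj <- vector("list", nf)
  for (c_ in seq_len(ncol(idx))) {
    f1 <- face_of(idx[1L, c_]); f2 <- face_of(idx[2L, c_])
    adj[[f1]] <- c(adj[[f1]], f2)
    adj[[f2]] <- c(adj[[f2]], f1)
  }
  directed <- function(fc) {
    rbind(fc[c(1L, 2L)], fc[c(2L, 3L)], fc[c(3L, 1L)])
  }
  seen <- rep(FALSE, nf)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    f <- queue[1L]; queue <- queue[-1L]
    df <- directed(faces[f, ])
    for (g in adj[[f]]) {
      if (seen[g]) next
      dg <- directed(faces[g, ])
      # consistent iff the shared edge appears with opposite direction
      same_dir <- any(
        outer(seq_len(3L), seq_len(3L), Vectorize(function(a, b)
          df[a, 1L] == dg[b, 1L] && df[a, 2L] == dg[b, 2L])))
      if (same_dir) faces[g, ] <- faces[g, c(1L, 3L, 2L)]
      seen[g] <- TRUE
      queue <- c(queue, g)
    }
  }
  faces
}

signed_volume <- function(contour) {
  v <- contour$vertices
  f <- contour$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  # sum of signed tetrahedron volumes against the origin
  det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det3) / 6
}

#' Volume enclosed by a watertight contour
#'
#' Exact signed-volume sum over faces (divergence theorem), returned
#' positive.
#'
#' @param contour a `surface_contour`.
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(contour) {
  assert_watertight(contour)
  v <- signed_volume(contour)
  if (v <= 0) stop("mesh encloses non-positive volume", call. = FALSE)
  v
}

#' Volume centroid of a watertight contour
#'
#' First moment of the enclosed volume divided by the volume (not the mean
#' of the vertices, which would be biased by non-uniform tessellation).
#' Translation-equivariant by construction.
#'
#' @param contour a `surface_contour`.
#' @return numeric length-3 point in mm.
#' @export
volume_centroid <- function(contour) {
  assert_watertight(contour)
  v <- contour$vertices
  f <- contour$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  vol <- sum(det3) / 6
  if (vol <= 0) stop("mesh encloses non-positive volume", call. = FALSE)
  # centroid of each tet (origin, a, b, c) is (a+b+c)/4
  m <- colSums((a + b + c_) / 4 * (det3 / 6))
  as.numeric(m / vol)
}

#' Total surface area of a contour
#' @param contour a `surface_contour`.
#' @return area in mm^2.
#' @export
surface_area <- function(contour) {
  v <- contour$vertices
  f <- contour$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE] - a
  c_ <- v[f[, 3L], , drop = FALSE] - a
  cr <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
              b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
              b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Rigidly transform a contour
#' @param contour a `surface_contour`.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 translation in mm (default zero).
#' @return the transformed `surface_contour`.
#' @export
transform_contour <- function(contour, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  contour$vertices <- contour$vertices %*% t(rotation) +
    matrix(translation, nrow(contour$vertices), 3, byrow = TRUE)
  contour
}

# area-weighted outward vertex normals
vertex_normals <- function(contour) {
  v <- contour$vertices
  f <- contour$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE] - a
  c_ <- v[f[, 3L], , drop = FALSE] - a
  cr <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
              b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
              b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      s <- rowsum(cr[, d], f[, j])
      n[as.integer(rownames(s)), d] <- n[as.integer(rownames(s)), d] + s
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Axis-aligned cuboid mesh
#'
#' 8 vertices, 12 triangles, outward orientation. Useful as an exact-volume
#' fixture.
#'
#' @param lo,hi opposite corners (length-3, mm).
#' @return a `surface_contour`.
#' @export
cuboid_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  colnames(v) <- NULL
  # vertex order: 1:(000) 2:(100) 3:(010) 4:(110) 5:(001) 6:(101) 7:(011) 8:(111)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z = lo), normal -z
    c(5, 6, 7), c(6, 8, 7),   # top (z = hi), normal +z
    c(1, 2, 5), c(2, 6, 5),   # front (y = lo), normal -y
    c(3, 7, 4), c(4, 7, 8),   # back (y = hi), normal +y
    c(1, 5, 3), c(3, 5, 7),   # left (x = lo), normal -x
    c(2, 4, 6), c(4, 8, 6))   # right (x = hi), normal +x
  surface_contour(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; vertices are nearly
#' uniformly spaced, making it the natural parameterization for radial
#' shape models. Subdivision s gives 20*4^s faces.
#'
#' @param radius sphere radius in mm.
#' @param subdiv number of 4-to-1 subdivisions (default 3: 642 vertices).
#' @param center sphere center (length-3, mm).
#' @return a `surface_contour`.
#' @export
icosphere <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    e12 <- cbind(f[, 1L], f[, 2L])
    e23 <- cbind(f[, 2L], f[, 3L])
    e31 <- cbind(f[, 3L], f[, 1L])
    alledges <- rbind(e12, e23, e31)
    key <- (pmin(alledges[, 1L], alledges[, 2L]) - 1) * nv +
           (pmax(alledges[, 1L], alledges[, 2L]) - 1)
    ukey <- sort(unique(key))
    mid_id <- nv + match(key, ukey)          # midpoint vertex index per half-edge
    lo <- floor(ukey / nv) + 1
    hi <- ukey %% nv + 1
    mids <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    a <- mid_id[seq_len(nf)]                 # midpoints of edge 1-2
    b <- mid_id[nf + seq_len(nf)]            # 2-3
    c_ <- mid_id[2L * nf + seq_len(nf)]      # 3-1
    f <- rbind(cbind(f[, 1L], a, c_),
               cbind(f[, 2L], b, a),
               cbind(f[, 3L], c_, b),
               cbind(a, b, c_))
  }
  vv <- v * radius
  vv <- vv + matrix(center, nrow(vv), 3, byrow = TRUE)
  surface_contour(vv, f)
}
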