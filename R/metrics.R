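#' Distance between centroids (DC)
#'
#' Euclidean distance (mm) between the volume centroids of two contours.
#' Symmetric; 0 mm is perfect agreement.
#'
#' @param a,b watertight `surface_contour`s.
#' @return distance in mm.
#' @export
dc <- function(a, b) {
  sqrt(sum((volume_centroid(a) - volume_centroid(b))^2))
}

#' Dice similarity coefficient (DSC)
#'
#' `2|A n B| / (|A| + |B|)` with volumes realized on a voxel grid shared by
#' both contours. Symmetric; 1 is perfect overlap, 0 none.
#'
#' @param a,b watertight `surface_contour`s.
#' @param spacing voxel edge in mm (default 1).
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b, spacing = 1) {
  g <- grid_for(list(a, b), spacing, pad = 2 * spacing)
  ma <- voxelize(a, spacing, grid = g)
  mb <- voxelize(b, spacing, grid = g)
  dsc_masks(ma, mb)
}

dsc_masks <- function(ma, mb) {
  na <- sum(ma$occupancy)
  nb <- sum(mb$occupancy)
  if (na == 0 || nb == 0)
    stop("degenerate resolution: empty mask in DSC", call. = FALSE)
  2 * sum(ma$occupancy & mb$occupancy) / (na + nb)
}

#' Mean surface-to-surface distance (MSSD)
#'
#' Directed mean, over the vertices of `a`, of the Euclidean distance to the
#' nearest vertex of `b` (vertex-to-vertex by definition; set
#' `target = "surface"` for a point-to-triangle variant useful for
#' sensitivity analysis). `mssd(a, b)` and `mssd(b, a)` generally differ.
#'
#' @param a,b `surface_contour`s with non-empty vertex sets.
#' @param method `"grid"` (spatial-index accelerated, default) or `"brute"`
#'   (exhaustive scan); both return bit-identical values.
#' @param target `"vertex"` (default, the study definition) or `"surface"`
#'   (distance to the closest point of any triangle of `b`).
#' @return mean distance in mm.
#' @export
mssd <- function(a, b, method = c("grid", "brute"),
                 target = c("vertex", "surface")) {
  method <- match.arg(method)
  target <- match.arg(target)
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    stop("empty vertex set", call. = FALSE)
  mean(surface_distances(a, b, method, target))
}

surface_distances <- function(a, b, method = "grid", target = "vertex") {
  if (target == "surface")
    return(cpp_point_surface_dist(a$vertices, b$vertices, b$faces))
  if (method == "brute")
    cpp_nn_dist_brute(a$vertices, b$vertices)
  else
    cpp_nn_dist_grid(a$vertices, b$vertices)
}

#' Uniform margin for 95% coverage (UM95)
#'
#' The smallest uniform expansion margin `m` (mm) such that the expansion of
#' `a` by `m` contains at least `coverage` (default 95%) of the volume of
#' `b`, both realized on a shared voxel grid. Computed as the
#' coverage-quantile (nearest-rank, ceiling) of the Euclidean distance field
#' of `a` sampled at `b`'s occupied voxels; this is the minimal
#' grid-realizable margin meeting the coverage, so
#' `expand_uniform(voxelize(a), m)` is certified to cover `>= coverage` of
#' `b`. Directed: `um95(a, b)` and `um95(b, a)` generally differ.
#'
#' @param a,b watertight `surface_contour`s.
#' @param coverage required volume fraction of `b`, in `(0, 1]` (default
#'   0.95).
#' @param spacing voxel edge in mm (default 1).
#' @return margin in mm (`0` if `b` is already covered).
#' @export
um95 <- function(a, b, coverage = 0.95, spacing = 1) {
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]", call. = FALSE)
  pad <- max(5, 2 * spacing)
  g <- grid_for(list(a, b), spacing, pad = pad)
  ma <- voxelize(a, spacing, grid = g)
  mb <- voxelize(b, spacing, grid = g)
  um95_masks(ma, mb, coverage)
}

um95_masks <- function(ma, mb, coverage = 0.95, dfield_a = NULL) {
  nb <- sum(mb$occupancy)
  if (nb == 0)
    stop("degenerate resolution: target mask empty in UM95", call. = FALSE)
  if (is.null(dfield_a)) {
    vals <- distance_to_region(ma, within = mb)
  } else {
    vals <- dfield_a[as.logical(mb$occupancy)]
  }
  k <- ceiling(coverage * nb)
  sort(vals, partial = k)[k]
}

#' Per-vertex interobserver deviation map
#'
#' For each vertex of the reference contour, the maximum over the other
#' contours of the nearest-vertex distance — the per-vertex disagreement
#' envelope rendered as a heatmap on the organ isosurface. Raw values are
#' returned unclamped; `clamp_mm` only caps the display scale written by
#' [write_deviation_ply()] (default 10 mm).
#'
#' @param reference a `surface_contour`.
#' @param others a non-empty list of `surface_contour`s.
#' @return numeric vector of per-vertex deviations in mm, with attribute
#'   `"clamp_mm"` = 10.
#' @export
deviation_map <- function(reference, others) {
  if (inherits(others, "surface_contour")) others <- list(others)
  if (length(others) < 1) stop("need at least one other contour", call. = FALSE)
  d <- rep(0, nrow(reference$vertices))
  for (o in others)
    d <- pmax(d, surface_distances(reference, o))
  attr(d, "clamp_mm") <- 10
  d
}

#' All four agreement metrics for one ordered contour pair
#'
#' Convenience wrapper computing DC, DSC, MSSD and UM95 for the ordered pair
#' (`a`, `b`) on one shared voxel grid.
#'
#' @param a,b watertight `surface_contour`s (source and target).
#' @param spacing voxel edge in mm.
#' @param coverage UM95 coverage fraction.
#' @param kind comparison kind recorded in the result
#'   (`"manual_vs_manual"` or `"ags_vs_manual"`).
#' @return one-row data.frame: image_id, source, target, kind, dc_mm, dsc,
#'   mssd_mm, um95_mm, spacing_mm.
#' @export
compare_pair <- function(a, b, spacing = 1, coverage = 0.95,
                         kind = NA_character_) {
  g <- grid_for(list(a, b), spacing, pad = max(5, 2 * spacing))
  ma <- voxelize(a, spacing, grid = g)
  mb <- voxelize(b, spacing, grid = g)
  data.frame(
    image_id = a$image_id,
    source = contour_label(a),
    target = contour_label(b),
    kind = kind,
    dc_mm = dc(a, b),
    dsc = dsc_masks(ma, mb),
    mssd_mm = mssd(a, b),
    um95_mm = um95_masks(ma, mb, coverage),
    spacing_mm = spacing,
    stringsAsFactors = FALSE)
}

contour_label <- function(x) {
  if (is.na(x$delineator) && is.na(x$method)) return(NA_character_)
  paste0(ifelse(is.na(x$method), "?", x$method), ":",
         ifelse(is.na(x$delineator), "?", x$delineator))
}

# Evaluate all ordered pairs among the contours of one image on a single
# shared grid, reusing each source contour's distance field across pairs.
# `pairs` is a 2-column integer matrix of (source, target) indices into
# `contours`; `kinds` a character vector per pair.
evaluate_pairs <- function(contours, pairs, kinds, spacing = 1,
                           coverage = 0.95) {
  stopifnot(length(kinds) == nrow(pairs))
  if (nrow(pairs) == 0) return(empty_records())
  g <- grid_for(contours, spacing, pad = max(5, 2 * spacing))
  masks <- lapply(contours, voxelize, spacing = spacing, grid = g)
  cents <- lapply(contours, volume_centroid)
  dfields <- vector("list", length(contours))
  need_df <- sort(unique(pairs[, 1L]))
  for (i in need_df)
    dfields[[i]] <- distance_to_region(masks[[i]])
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    a <- contours[[i]]; b <- contours[[j]]
    out[[r]] <- data.frame(
      image_id = a$image_id,
      source = contour_label(a),
      target = contour_label(b),
      kind = kinds[r],
      dc_mm = sqrt(sum((cents[[i]] - cents[[j]])^2)),
      dsc = dsc_masks(masks[[i]], masks[[j]]),
      mssd_mm = mssd(a, b),
      um95_mm = um95_masks(masks[[i]], masks[[j]], coverage,
                           dfield_a = dfields[[i]]),
      spacing_mm = spacing,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_records <- function() {
  data.frame(image_id = character(), source = character(),
             target = character(), kind = character(),
             dc_mm = numeric(), dsc = numeric(), mssd_mm = numeric(),
             um95_mm = numeric(), spacing_mm = numeric(),
             stringsAsFactors = FALSE)
}
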