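# Mesh I/O. Coordinates are always interpreted as mm in the patient frame
# (+x Left, +y Anterior, +z Superior). On read, face orientation is
# repaired (consistent winding, outward normals) and watertightness is
# enforced; defects raise errors naming the offending edges.

#' Read a surface contour from PLY or STL
#'
#' Supports ascii and binary-little-endian PLY and ascii STL. Meshes with
#' inconsistent or inverted winding are auto-reoriented with a warning;
#' non-watertight meshes raise a format error listing open edges.
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"` or `NULL` (from extension).
#' @param ... labels passed to [surface_contour()] (`image_id`,
#'   `delineator`, `method`).
#' @return a `surface_contour`.
#' @export
read_contour <- function(path, format = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  mesh <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported format: ", format, call. = FALSE))
  raw <- surface_contour(mesh$vertices, mesh$faces, validate = FALSE, ...)
  fixed <- orient_outward(raw)
  if (!identical(fixed$faces, raw$faces))
    warning("face orientation repaired on read: ", path)
  assert_watertight(fixed)
  fixed
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL; elems <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated PLY header: ", path, call. = FALSE)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        elems[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                             item_type = tok[4])
      else
        elems[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY missing vertex or face element: ", path, call. = FALSE)
  if (identical(fmt, "ascii")) {
    read_ply_ascii(con, elems, path)
  } else if (identical(fmt, "binary_little_endian")) {
    read_ply_binary(con, elems, path)
  } else stop("unsupported PLY format: ", fmt, call. = FALSE)
}

ply_type_size <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
         float32 = 4L, double = 8L, float64 = 8L,
         stop("unknown PLY type: ", t, call. = FALSE))
}

ply_read_bin <- function(con, t, n) {
  sz <- ply_type_size(t)
  what <- if (t %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
  out <- readBin(con, what, n = n, size = sz, endian = "little",
                 signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")))
  if (length(out) < n) stop("truncated PLY data", call. = FALSE)
  out
}

read_ply_ascii <- function(con, elems, path) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  nv <- elems$vertex$n; nf <- elems$face$n
  if (length(txt) < nv + nf) stop("truncated PLY data: ", path, call. = FALSE)
  vprops <- names(elems$vertex$props)
  vdat <- do.call(rbind, lapply(txt[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(vdat) < 3) stop("PLY vertex rows malformed: ", path, call. = FALSE)
  xyz <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz))) xyz <- 1:3
  verts <- vdat[, xyz, drop = FALSE]
  faces <- lapply(txt[nv + seq_len(nf)], function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (v[1] != 3) stop("only triangle faces supported", call. = FALSE)
    v[2:4] + 1
  })
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_ply_binary <- function(con, elems, path) {
  vp <- elems$vertex$props
  nv <- elems$vertex$n
  vals <- matrix(0, nv, length(vp))
  # vertex properties are scalars; read row-wise
  types <- vapply(vp, function(p) p$type, character(1))
  if (length(unique(types)) == 1) {
    vals <- matrix(ply_read_bin(con, types[1], nv * length(vp)),
                   nv, length(vp), byrow = TRUE)
  } else {
    for (i in seq_len(nv))
      for (j in seq_along(vp))
        vals[i, j] <- ply_read_bin(con, types[j], 1)
  }
  xyz <- match(c("x", "y", "z"), names(vp))
  if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z: ", path, call. = FALSE)
  verts <- vals[, xyz, drop = FALSE]
  fp <- elems$face$props[[1]]
  nf <- elems$face$n
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- ply_read_bin(con, fp$count_type, 1)
    if (cnt != 3) stop("only triangle faces supported", call. = FALSE)
    faces[i, ] <- ply_read_bin(con, fp$item_type, 3) + 1L
  }
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0) stop("empty STL file: ", path, call. = FALSE)
  if (!grepl("^\\s*solid", first))
    return(read_stl_binary(path))
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ascii STL: ", path, call. = FALSE)
  pts <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  if (any(is.na(pts))) stop("malformed ascii STL: ", path, call. = FALSE)
  stl_weld(pts)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nf) || nf <= 0) stop("malformed binary STL: ", path, call. = FALSE)
  pts <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("truncated binary STL: ", path, call. = FALSE)
    pts[3 * i - 2, ] <- rec[4:6]
    pts[3 * i - 1, ] <- rec[7:9]
    pts[3 * i, ] <- rec[10:12]
    readBin(con, "raw", 2)
  }
  stl_weld(pts)
}

# weld duplicated vertices of an STL triangle soup
stl_weld <- function(pts) {
  key <- apply(round(pts, 9), 1, paste, collapse = "_")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  list(vertices = pts[uk, , drop = FALSE],
       faces = matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a surface contour to PLY or STL
#'
#' @param contour a `surface_contour`.
#' @param path output file; extension selects the format unless `format`
#'   is given.
#' @param format `"ply"` (ascii) or `"stl"` (ascii).
#' @param scalar optional per-vertex numeric vector written as a PLY
#'   property.
#' @param scalar_name PLY property name for `scalar`.
#' @return invisibly `path`.
#' @export
write_contour <- function(contour, path, format = NULL, scalar = NULL,
                          scalar_name = "deviation_mm") {
  format <- format %||% tolower(tools::file_ext(path))
  v <- contour$vertices
  f <- contour$faces
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             "comment units mm, frame +x Left +y Anterior +z Superior",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z")
    if (!is.null(scalar))
      hdr <- c(hdr, sprintf("property double %s", scalar_name))
    hdr <- c(hdr, sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vmat <- if (is.null(scalar)) v else cbind(v, scalar)
    vlines <- apply(vmat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    flines <- apply(f - 1L, 1, function(r) paste(c(3, r), collapse = " "))
    writeLines(c(hdr, vlines, flines), path)
  } else if (format == "stl") {
    lines <- c("solid contour")
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c_ - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    fmt3 <- function(p) paste(sprintf("%.17g", p), collapse = " ")
    body <- vapply(seq_len(nrow(f)), function(i) paste(
      sprintf("facet normal %s", fmt3(n[i, ])),
      "  outer loop",
      sprintf("    vertex %s", fmt3(a[i, ])),
      sprintf("    vertex %s", fmt3(b[i, ])),
      sprintf("    vertex %s", fmt3(c_[i, ])),
      "  endloop", "endfacet", sep = "\n"), character(1))
    writeLines(c(lines, body, "endsolid contour"), path)
  } else stop("unsupported format: ", format, call. = FALSE)
  invisible(path)
}

#' Write a deviation heatmap as PLY
#'
#' The raw per-vertex deviations (mm) are stored unclamped in a
#' `deviation_mm` property; a second `deviation_display` property clamps at
#' the display ceiling (10 mm by default, or the map's own maximum when
#' `autoscale = TRUE`).
#'
#' @param reference the reference `surface_contour`.
#' @param deviations per-vertex deviations from [deviation_map()].
#' @param path output PLY path.
#' @param autoscale clamp at the per-image maximum instead of the fixed
#'   10 mm ceiling.
#' @return invisibly `path`.
#' @export
write_deviation_ply <- function(reference, deviations, path,
                                autoscale = FALSE) {
  clamp <- if (autoscale) max(deviations) else
    attr(deviations, "clamp_mm") %||% 10
  v <- reference$vertices
  f <- reference$faces
  disp <- pmin(as.numeric(deviations), clamp)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment display clamp %g mm", clamp),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           "property double deviation_mm", "property double deviation_display",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  vlines <- apply(cbind(v, as.numeric(deviations), disp), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  flines <- apply(f - 1L, 1, function(r) paste(c(3, r), collapse = " "))
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

# ---- cohort manifest -----------------------------------------------------

#' Write a generated cohort to disk
#'
#' Writes every contour as ascii PLY under `contours/`, the session ratings
#' as `ratings.csv`, and `manifest.json` linking images to observers,
#' contour files and AGS attempt status, together with all generator
#' parameters and seeds.
#'
#' @param manifest a cohort manifest from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly the manifest path.
#' @export
write_cohort <- function(manifest, out_dir) {
  dir.create(file.path(out_dir, "contours"), recursive = TRUE,
             showWarnings = FALSE)
  entries <- lapply(manifest$images, function(img) {
    tf <- file.path("contours", paste0(img$image_id, "_truth.ply"))
    write_contour(img$truth, file.path(out_dir, tf))
    manual <- list(); ags <- list()
    for (ob in names(img$manual)) {
      mf <- file.path("contours", paste0(img$image_id, "_", ob, "_manual.ply"))
      write_contour(img$manual[[ob]], file.path(out_dir, mf))
      manual[[ob]] <- mf
    }
    for (ob in names(img$ags)) {
      if (is.null(img$ags[[ob]])) { ags[ob] <- list(NULL); next }
      af <- file.path("contours", paste0(img$image_id, "_", ob, "_ags.ply"))
      write_contour(img$ags[[ob]], file.path(out_dir, af))
      ags[[ob]] <- af
    }
    list(image_id = img$image_id, rating = img$rating,
         params = img$params[!vapply(img$params, is.null, logical(1))],
         truth_file = tf, manual = manual, ags = ags)
  })
  sessions <- manifest$ratings[, c("image_id", "session1", "session2")]
  write.csv(sessions, file.path(out_dir, "ratings.csv"), row.names = FALSE)
  cfg <- manifest$config
  meta <- list(
    master_seed = manifest$master_seed,
    units = "mm", frame = "+x Left, +y Anterior, +z Superior",
    config = list(
      n_retained = cfg$n_retained, rating_mix = cfg$rating_mix,
      n_excluded = cfg$n_excluded, n_observers = cfg$n_observers,
      subdiv = cfg$subdiv,
      observer = unclass(cfg$observer)[c("sigma_obs", "correlation_length",
                                         "edge_boost")],
      ags = unclass(cfg$ags)[c("failure_prob", "corruption_mm",
                               "extrusion_rate", "extrusion_length",
                               "extrusion_width")]),
    images = entries)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}

#' Read a cohort manifest (and its contours) from disk
#'
#' @param path path to `manifest.json` (the companion `ratings.csv` and
#'   `contours/` directory are resolved relative to it).
#' @param ratings_csv optional explicit path to the ratings CSV.
#' @return a cohort manifest usable by [evaluate_cohort()].
#' @export
read_manifest <- function(path, ratings_csv = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  root <- dirname(path)
  meta <- jsonlite::read_json(path)
  ratings_csv <- ratings_csv %||% file.path(root, "ratings.csv")
  ratings <- finalize_ratings(read.csv(ratings_csv,
                                       colClasses = c(image_id = "character")))
  images <- lapply(meta$images, function(e) {
    truth <- read_contour(file.path(root, e$truth_file),
                          image_id = e$image_id, method = "truth")
    manual <- lapply(e$manual, function(f)
      read_contour(file.path(root, f), image_id = e$image_id,
                   method = "manual"))
    for (ob in names(manual)) manual[[ob]]$delineator <- ob
    ags <- list()
    for (ob in names(e$ags)) {
      if (is.null(e$ags[[ob]])) { ags[ob] <- list(NULL); next }
      a <- read_contour(file.path(root, e$ags[[ob]]), image_id = e$image_id,
                        method = "ags")
      a$delineator <- ob
      ags[[ob]] <- a
    }
    list(image_id = e$image_id, rating = e$rating, truth = truth,
         manual = manual, ags = ags)
  })
  list(images = images, ratings = ratings, config = meta$config,
       master_seed = meta$master_seed)
}

# ---- reporting -----------------------------------------------------------

#' Write the analysis report for a cohort evaluation
#'
#' Writes, under `out_dir`: the raw agreement records
#' (`records.csv`), the median-[IQR] summary table (`summary.csv`), the two
#' statistics tables (`stats_rating_groups.csv`,
#' `stats_ags_vs_manual.csv`), the failure ledger (`failures.json`), a
#' provenance block (`provenance.json`: conventions, parameters, package
#' and R versions), and one boxplot figure per metric grouped by rating
#' with shaded manual vs white AGS boxes (`boxplots.pdf`).
#'
#' @param results output of [evaluate_cohort()] (`records`, `failures`,
#'   `ratings`).
#' @param out_dir output directory (created if needed).
#' @param alpha significance level for the statistics tables.
#' @param extra named list merged into the provenance block.
#' @return invisibly the vector of files written.
#' @export
write_report <- function(results, out_dir, alpha = 0.05, extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- results$records
  ratings <- results$ratings
  if (is.null(records) || nrow(records) == 0)
    stop("no agreement records to report", call. = FALSE)
  files <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(records, "records.csv")
  summ <- suppressWarnings(summarize_agreement(records, ratings))
  # explicit no-data rows for absent strata (e.g. all AGS attempts failed)
  kinds <- c("manual_vs_manual", "ags_vs_manual")
  grid <- expand.grid(metric = unname(metric_cols),
                      group = c("All Images", "Rating 1", "Rating 2",
                                "Rating 3"),
                      kind = kinds, stringsAsFactors = FALSE)
  summ <- merge(grid, summ, all.x = TRUE,
                by = c("metric", "group", "kind"))
  summ$cell <- ifelse(is.na(summ$median), "no data",
                      sprintf("%.2f [%.2f]", summ$median, summ$iqr_width))
  w(summ[order(summ$metric, summ$kind, summ$group), ], "summary.csv")
  man <- records[records$kind == "manual_vs_manual", , drop = FALSE]
  w(compare_rating_groups(man, ratings, alpha), "stats_rating_groups.csv")
  w(compare_ags_manual(records, ratings, alpha), "stats_ags_vs_manual.csv")

  jsonlite::write_json(unclass(results$failures),
                       file.path(out_dir, "failures.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "failures.json"))

  prov <- c(list(
    package = "uscontour",
    package_version = as.character(utils::packageVersion("uscontour")),
    r_version = R.version.string,
    alpha = alpha,
    conventions = list(
      rating_rounding = "round half up",
      iqr = "Q3 - Q1, linear interpolation (type 7)",
      pooling = "pooled pairwise records",
      mssd = "directed, vertex-to-vertex",
      um95 = "directed, nearest-rank quantile of the distance field",
      bonferroni_factor = 3)), extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "provenance.json"))

  pdf_path <- file.path(out_dir, "boxplots.pdf")
  grDevices::pdf(pdf_path, width = 8, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  rt <- ratings$final_rating[match(records$image_id, ratings$image_id)]
  for (m in names(metric_cols)) {
    vals <- list(); cols <- character(); names_ <- character()
    for (grp in c("All", 1:3)) {
      sel <- if (grp == "All") rep(TRUE, nrow(records)) else rt == as.integer(grp)
      for (kind in kinds) {
        x <- records[[m]][sel & records$kind == kind]
        vals[[length(vals) + 1L]] <- if (length(x)) x else NA_real_
        cols <- c(cols, if (kind == "manual_vs_manual") "grey70" else "white")
        names_ <- c(names_, paste0(grp, if (kind == "manual_vs_manual")
          "\nmanual" else "\nAGS"))
      }
    }
    graphics::boxplot(vals, col = cols, names = names_,
                      main = metric_cols[[m]], ylab = metric_cols[[m]],
                      xlab = "image quality rating", cex.axis = 0.7)
  }
  files <- c(files, pdf_path)
  invisible(files)
}

# ---- command line --------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR --seed S [--config C.json]`,
#' `evaluate --manifest M [--ratings R] --spacing 1.0 --coverage 0.95 --out DIR`,
#' `summarize --records CSV --ratings CSV --out DIR`,
#' `stats --records CSV --ratings CSV --alpha 0.05 --out DIR`,
#' `report --records CSV --ratings CSV --out DIR`.
#' Exit codes: 0 success, 2 validation error, 3 I/O error.
#'
#' @param args character vector of arguments (default: the command line).
#' @return the exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: uscontour <simulate|evaluate|summarize|stats|report> [options]"
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(rest),
      evaluate = cli_evaluate(rest),
      summarize = cli_summarize(rest, what = "summary"),
      stats = cli_summarize(rest, what = "stats"),
      report = cli_summarize(rest, what = "report"),
      { message(usage); 2L })
  }, validation_error = function(e) { message("error: ", conditionMessage(e)); 2L },
     error = function(e) {
       message("error: ", conditionMessage(e))
       if (grepl("file not found|cannot open|unwritable|truncated",
                 conditionMessage(e))) 3L else 2L
     })
  invisible(as.integer(status))
}

cli_opts <- function(args, spec) {
  out <- lapply(spec, function(s) s$default)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(spec)) stop("unknown option: ", args[i], call. = FALSE)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

cli_simulate <- function(args) {
  o <- cli_opts(args, list(out = list(default = NULL),
                           seed = list(default = "1"),
                           config = list(default = NULL)))
  if (is.null(o$out)) stop("simulate requires --out", call. = FALSE)
  cfg <- cohort_config()
  if (!is.null(o$config)) {
    j <- jsonlite::read_json(o$config)
    cfg <- cohort_config(
      n_retained = j$n_retained %||% 35,
      rating_mix = unlist(j$rating_mix %||% list(6, 18, 11)),
      n_excluded = j$n_excluded %||% 9,
      n_observers = j$n_observers %||% 4,
      subdiv = j$subdiv %||% 4)
  }
  generate_cohort(cfg, master_seed = as.integer(o$seed), out_dir = o$out)
  message("cohort written to ", o$out)
  0L
}

cli_evaluate <- function(args) {
  o <- cli_opts(args, list(manifest = list(default = NULL),
                           ratings = list(default = NULL),
                           spacing = list(default = "1.0"),
                           coverage = list(default = "0.95"),
                           out = list(default = NULL)))
  if (is.null(o$manifest) || is.null(o$out))
    stop("evaluate requires --manifest and --out", call. = FALSE)
  man <- read_manifest(o$manifest, ratings_csv = o$ratings)
  res <- evaluate_cohort(man, spacing = as.numeric(o$spacing),
                         coverage = as.numeric(o$coverage))
  write_report(res, o$out,
               extra = list(spacing_mm = as.numeric(o$spacing),
                            coverage = as.numeric(o$coverage),
                            manifest = normalizePath(o$manifest),
                            master_seed = man$master_seed))
  message("report written to ", o$out)
  0L
}

cli_summarize <- function(args, what) {
  o <- cli_opts(args, list(records = list(default = NULL),
                           ratings = list(default = NULL),
                           alpha = list(default = "0.05"),
                           out = list(default = NULL)))
  if (is.null(o$records) || is.null(o$ratings) || is.null(o$out))
    stop(what, " requires --records, --ratings and --out", call. = FALSE)
  records <- read.csv(o$records, colClasses = c(image_id = "character"))
  ratings <- finalize_ratings(read.csv(o$ratings,
                                       colClasses = c(image_id = "character")))
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  if (what %in% c("summary", "report")) {
    s <- suppressWarnings(summarize_agreement(records, ratings))
    write.csv(s, file.path(o$out, "summary.csv"), row.names = FALSE)
  }
  if (what %in% c("stats", "report")) {
    man <- records[records$kind == "manual_vs_manual", , drop = FALSE]
    write.csv(compare_rating_groups(man, ratings, as.numeric(o$alpha)),
              file.path(o$out, "stats_rating_groups.csv"), row.names = FALSE)
    write.csv(compare_ags_manual(records, ratings, as.numeric(o$alpha)),
              file.path(o$out, "stats_ags_vs_manual.csv"), row.names = FALSE)
  }
  message(what, " written to ", o$out)
  0L
}
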