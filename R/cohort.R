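#' Finalize image-quality ratings
#'
#' Each image is rated twice on the 0-3 scale (0 unusable ... 3 excellent).
#' Any image rated 0 in either session is excluded; otherwise the final
#' rating is the mean of the two sessions rounded to the nearest integer,
#' half-ratings rounding up (1.5 -> 2).
#'
#' @param sessions data.frame with columns `image_id`, `session1`,
#'   `session2` (integers in 0..3, one row per image).
#' @return data.frame with columns `image_id`, `session1`, `session2`,
#'   `excluded` (logical), `final_rating` (integer, `NA` when excluded);
#'   attributes `n_acquired`, `n_retained`, `retained_pct` (1 decimal).
#' @export
finalize_ratings <- function(sessions) {
  req <- c("image_id", "session1", "session2")
  if (!all(req %in% names(sessions)))
    stop("sessions must have columns image_id, session1, session2",
         call. = FALSE)
  s1 <- sessions$session1
  s2 <- sessions$session2
  if (anyDuplicated(sessions$image_id))
    stop("duplicate image_id in ratings", call. = FALSE)
  if (!all(s1 %in% 0:3) || !all(s2 %in% 0:3))
    stop("session ratings must be integers in 0..3", call. = FALSE)
  excluded <- s1 == 0 | s2 == 0
  # round half up: floor(x + 0.5); means here are k or k + 0.5
  final <- ifelse(excluded, NA_integer_,
                  as.integer(floor((s1 + s2) / 2 + 0.5)))
  out <- data.frame(image_id = as.character(sessions$image_id),
                    session1 = as.integer(s1), session2 = as.integer(s2),
                    excluded = excluded, final_rating = final,
                    stringsAsFactors = FALSE)
  attr(out, "n_acquired") <- nrow(out)
  attr(out, "n_retained") <- sum(!excluded)
  attr(out, "retained_pct") <- round(100 * sum(!excluded) / nrow(out), 1)
  out
}

#' Enumerate ordered manual-vs-manual pairs
#'
#' Every observer contour is compared against each of the other observers'
#' contours, so n observers give n(n-1) ordered pairs (4 observers -> 12),
#' the directed metrics being recorded once per direction.
#'
#' @param labels character vector of observer labels (length >= 2).
#' @return data.frame `source`, `target`.
#' @export
enumerate_manual_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 manual contours", call. = FALSE)
  idx <- expand.grid(source = seq_len(n), target = seq_len(n))
  idx <- idx[idx$source != idx$target, ]
  data.frame(source = labels[idx$source], target = labels[idx$target],
             stringsAsFactors = FALSE)
}

#' Enumerate AGS-vs-manual pairs
#'
#' Full cross product of successful semiautomated (AGS) contours with the
#' manual contours of the same image (4 x 4 -> 16 pairs); failed attempts
#' contribute no pairs.
#'
#' @param ags_labels labels of successful AGS contours (may be empty).
#' @param manual_labels labels of manual contours.
#' @return data.frame `source` (AGS), `target` (manual); zero rows if no
#'   AGS contour succeeded.
#' @export
enumerate_ags_pairs <- function(ags_labels, manual_labels) {
  if (length(manual_labels) < 1)
    stop("need at least one manual contour", call. = FALSE)
  if (length(ags_labels) == 0)
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  idx <- expand.grid(source = seq_along(ags_labels),
                     target = seq_along(manual_labels))
  data.frame(source = ags_labels[idx$source],
             target = manual_labels[idx$target],
             stringsAsFactors = FALSE)
}

#' Semiautomated segmentation failure ledger
#'
#' @param attempts data.frame with columns `image_id`, `observer`,
#'   `success` (logical, no `NA`s).
#' @return list: `n_images`, `n_observers`, `n_attempts`, `n_failures`,
#'   `failure_pct`, `success_pct` (percentages to 1 decimal).
#' @export
failure_report <- function(attempts) {
  req <- c("image_id", "observer", "success")
  if (!all(req %in% names(attempts)))
    stop("attempts must have columns image_id, observer, success",
         call. = FALSE)
  if (any(is.na(attempts$success)))
    stop("every attempt must be marked success or failure", call. = FALSE)
  n_att <- nrow(attempts)
  n_fail <- sum(!attempts$success)
  structure(list(
    n_images = length(unique(attempts$image_id)),
    n_observers = length(unique(attempts$observer)),
    n_attempts = n_att,
    n_failures = n_fail,
    failure_pct = round(100 * n_fail / n_att, 1),
    success_pct = round(100 * (n_att - n_fail) / n_att, 1)),
    class = "failure_ledger")
}

#' @export
print.failure_ledger <- function(x, ...) {
  cat(sprintf(
    "AGS attempts: %d (%d images x %d observers): %d succeeded (%.1f%%), %d failed (%.1f%%)\n",
    x$n_attempts, x$n_images, x$n_observers,
    x$n_attempts - x$n_failures, x$success_pct, x$n_failures, x$failure_pct))
  invisible(x)
}

metric_cols <- c(dc_mm = "DC (mm)", dsc = "DSC", mssd_mm = "MSSD (mm)",
                 um95_mm = "UM95 (mm)")

#' Median [IQR] agreement summaries by quality group
#'
#' Pools all pairwise agreement records within each group (All Images and
#' the three rating strata), per metric and comparison kind, and reports
#' the median and the IQR width (Q3 - Q1, linear-interpolation quantiles).
#'
#' @param records data.frame of agreement records (see [compare_pair()]).
#' @param ratings finalized ratings (see [finalize_ratings()]).
#' @param per_image if `TRUE`, aggregate records to per-image means before
#'   summarizing (default `FALSE`: pooled pairs).
#' @return data.frame: `metric`, `group`, `kind`, `median`, `iqr_width`,
#'   `n_pairs`.
#' @export
summarize_agreement <- function(records, ratings, per_image = FALSE) {
  rt <- ratings$final_rating[match(records$image_id, ratings$image_id)]
  if (any(is.na(rt)))
    stop("every record's image needs a final rating", call. = FALSE)
  out <- list()
  for (kind in unique(records$kind)) {
    for (grp in c("All Images", "Rating 1", "Rating 2", "Rating 3")) {
      sel <- records$kind == kind
      if (grp != "All Images")
        sel <- sel & rt == as.integer(sub("Rating ", "", grp))
      sub <- records[sel, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning(sprintf("no records for %s / %s; group omitted", kind, grp))
        next
      }
      for (m in names(metric_cols)) {
        x <- sub[[m]]
        if (per_image)
          x <- as.numeric(tapply(x, sub$image_id, mean))
        q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
        out[[length(out) + 1L]] <- data.frame(
          metric = metric_cols[[m]], group = grp, kind = kind,
          median = q[2], iqr_width = q[3] - q[1],
          n_pairs = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Wilcoxon rank sum: exact enumeration for small untied samples, normal
# approximation with tie correction otherwise.
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Rank-sum tests between quality-rating groups
#'
#' Two-sided Wilcoxon rank sum for each of the three rating-group pairings
#' (1-2, 1-3, 2-3) per metric, Bonferroni-corrected by a factor 3 (capped
#' at 1), significance flagged at adjusted p < `alpha`.
#'
#' @param records agreement records of one comparison kind.
#' @param ratings finalized ratings.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `metric`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `p_raw`, `p_adj`, `significant`, `skipped`.
#' @export
compare_rating_groups <- function(records, ratings, alpha = 0.05) {
  rt <- ratings$final_rating[match(records$image_id, ratings$image_id)]
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- list()
  for (m in names(metric_cols)) {
    for (pr in pairs) {
      x <- records[[m]][rt == pr[1]]
      y <- records[[m]][rt == pr[2]]
      skipped <- length(x) < 2 || length(y) < 2
      p <- if (skipped) NA_real_ else rank_sum_p(x, y)
      padj <- if (is.na(p)) NA_real_ else min(1, 3 * p)
      out[[length(out) + 1L]] <- data.frame(
        metric = metric_cols[[m]], group_a = paste("Rating", pr[1]),
        group_b = paste("Rating", pr[2]), n_a = length(x), n_b = length(y),
        p_raw = p, p_adj = padj,
        significant = !is.na(padj) & padj < alpha,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rank-sum tests of AGS accuracy against interobserver variability
#'
#' Compares the `ags_vs_manual` metric distributions against
#' `manual_vs_manual`, for all images (uncorrected) and within each rating
#' stratum (Bonferroni factor 3 over the strata).
#'
#' @param records agreement records carrying both comparison kinds.
#' @param ratings finalized ratings.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `metric`, `group`, `n_manual`, `n_ags`, `p_raw`,
#'   `p_adj`, `significant`, `skipped`.
#' @export
compare_ags_manual <- function(records, ratings, alpha = 0.05) {
  rt <- ratings$final_rating[match(records$image_id, ratings$image_id)]
  out <- list()
  for (m in names(metric_cols)) {
    for (grp in c("All Images", "Rating 1", "Rating 2", "Rating 3")) {
      sel <- rep(TRUE, nrow(records))
      if (grp != "All Images")
        sel <- rt == as.integer(sub("Rating ", "", grp))
      x <- records[[m]][sel & records$kind == "manual_vs_manual"]
      y <- records[[m]][sel & records$kind == "ags_vs_manual"]
      skipped <- length(x) < 2 || length(y) < 2
      p <- if (skipped) NA_real_ else rank_sum_p(x, y)
      fac <- if (grp == "All Images") 1 else 3
      padj <- if (is.na(p)) NA_real_ else min(1, fac * p)
      out[[length(out) + 1L]] <- data.frame(
        metric = metric_cols[[m]], group = grp,
        n_manual = length(x), n_ags = length(y),
        p_raw = p, p_adj = padj,
        significant = !is.na(padj) & padj < alpha,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Evaluate every contour pair of a cohort
#'
#' For each retained image: all ordered manual pairs plus the cross product
#' of successful AGS contours with manual contours. All contours of one
#' image share one voxel grid and each source contour's distance field is
#' computed once. Total record count is
#' `sum over images of n_manual * (n_manual - 1) + n_ags * n_manual`.
#'
#' @param manifest a cohort manifest (see [generate_cohort()] or
#'   [read_manifest()]); each image entry carries `manual` (named list of
#'   contours) and `ags` (named list of contours or `NULL` for failures).
#' @param spacing voxel edge in mm.
#' @param coverage UM95 coverage fraction.
#' @param progress print one line per image.
#' @return list: `records` (data.frame of agreement records), `failures`
#'   (the [failure_report()] ledger), `ratings`.
#' @export
evaluate_cohort <- function(manifest, spacing = 1, coverage = 0.95,
                            progress = FALSE) {
  recs <- list()
  att <- list()
  for (img in manifest$images) {
    contours <- c(unname(img$manual), unname(Filter(Negate(is.null), img$ags)))
    nm <- length(img$manual)
    succ <- !vapply(img$ags, is.null, logical(1))
    att[[length(att) + 1L]] <- data.frame(
      image_id = img$image_id, observer = names(img$ags),
      success = succ, stringsAsFactors = FALSE)
    mp <- enumerate_manual_pairs(seq_len(nm))
    pairs <- cbind(as.integer(mp$source), as.integer(mp$target))
    kinds <- rep("manual_vs_manual", nrow(pairs))
    ns <- sum(succ)
    if (ns > 0) {
      ap <- enumerate_ags_pairs(seq_len(ns), seq_len(nm))
      pairs <- rbind(pairs,
                     cbind(nm + as.integer(ap$source), as.integer(ap$target)))
      kinds <- c(kinds, rep("ags_vs_manual", nrow(ap)))
    }
    if (progress)
      message(sprintf("image %s: %d contours, %d pairs",
                      img$image_id, length(contours), nrow(pairs)))
    recs[[length(recs) + 1L]] <-
      evaluate_pairs(contours, pairs, kinds, spacing, coverage)
  }
  list(records = do.call(rbind, recs),
       failures = failure_report(do.call(rbind, att)),
       ratings = manifest$ratings)
}
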