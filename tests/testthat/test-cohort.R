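test_that("rating finalization applies exclusion and round-half-up rules", {
  r <- finalize_ratings(data.frame(
    image_id = c("a", "b", "c", "d", "e"),
    session1 = c(0, 2, 1, 3, 2),
    session2 = c(3, 2, 2, 0, 3)))
  expect_identical(r$excluded, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(r$final_rating, c(NA_integer_, 2L, 2L, NA_integer_, 3L))
  expect_equal(attr(r, "n_acquired"), 5)
  expect_equal(attr(r, "n_retained"), 3)
  expect_error(finalize_ratings(data.frame(image_id = "a", session1 = 4,
                                           session2 = 1)), "0..3")
  expect_error(finalize_ratings(data.frame(image_id = c("a", "a"),
                                           session1 = 1, session2 = 1)),
               "duplicate")
})

test_that("pair enumeration gives n(n-1) manual and ns*nm AGS pairs", {
  expect_equal(nrow(enumerate_manual_pairs(paste0("o", 1:4))), 12)
  expect_equal(nrow(enumerate_manual_pairs(paste0("o", 1:2))), 2)
  expect_equal(nrow(enumerate_manual_pairs(paste0("o", 1:5))), 20)
  expect_error(enumerate_manual_pairs("o1"), "at least 2")
  p <- enumerate_manual_pairs(paste0("o", 1:4))
  expect_true(all(p$source != p$target))
  expect_equal(anyDuplicated(paste(p$source, p$target)), 0)

  expect_equal(nrow(enumerate_ags_pairs(paste0("a", 1:4), paste0("m", 1:4))),
               16)
  expect_equal(nrow(enumerate_ags_pairs(paste0("a", 1:3), paste0("m", 1:4))),
               12)
  expect_equal(nrow(enumerate_ags_pairs(character(0), paste0("m", 1:4))), 0)
})

test_that("failure ledger reproduces the attempt arithmetic", {
  att <- expand.grid(image_id = sprintf("i%02d", 1:35),
                     observer = paste0("o", 1:4), stringsAsFactors = FALSE)
  att$success <- TRUE
  att$success[1:27] <- FALSE
  fr <- failure_report(att)
  expect_equal(fr$n_attempts, 140)
  expect_equal(fr$n_failures, 27)
  expect_equal(fr$failure_pct, 19.3)
  expect_equal(fr$success_pct, 80.7)

  att$success <- TRUE
  fr0 <- failure_report(att)
  expect_equal(fr0$failure_pct, 0)
  expect_equal(fr0$success_pct, 100)

  att2 <- expand.grid(image_id = sprintf("i%02d", 1:10),
                      observer = paste0("o", 1:4), stringsAsFactors = FALSE)
  att2$success <- rep(c(FALSE, TRUE), c(6, 34))
  expect_equal(failure_report(att2)$failure_pct, 15.0)
  att2$success[1] <- NA
  expect_error(failure_report(att2), "marked")
})

make_records <- function(vals, kind = "manual_vs_manual",
                         image_id = "img1") {
  data.frame(image_id = image_id, source = "a", target = "b", kind = kind,
             dc_mm = vals, dsc = pmin(1, vals / 10), mssd_mm = vals,
             um95_mm = vals, spacing_mm = 1, stringsAsFactors = FALSE)
}

test_that("summaries use median and IQR width with type-7 quantiles", {
  ratings <- finalize_ratings(data.frame(image_id = "img1", session1 = 2,
                                         session2 = 2))
  rec <- make_records(c(1, 2, 3, 4, 5))
  s <- suppressWarnings(summarize_agreement(rec, ratings))
  row <- s[s$metric == "MSSD (mm)" & s$group == "All Images", ]
  expect_equal(row$median, 3)
  expect_equal(row$iqr_width, 2)       # Q3 - Q1 = 4 - 2, linear interpolation
  expect_equal(row$n_pairs, 5)
  # constant records: IQR 0
  s2 <- suppressWarnings(summarize_agreement(make_records(rep(4.2, 8)),
                                             ratings))
  expect_true(all(s2$iqr_width[s2$metric == "DC (mm)"] == 0))
  # permutation invariance
  rec_shuffled <- rec[c(4, 1, 5, 3, 2), ]
  s3 <- suppressWarnings(summarize_agreement(rec_shuffled, ratings))
  expect_equal(s3$median, s$median)
  expect_equal(s3$iqr_width, s$iqr_width)
})

test_that("rank-sum group comparisons behave on degenerate and separated data", {
  ratings <- finalize_ratings(data.frame(
    image_id = c("i1", "i2"), session1 = c(1, 2), session2 = c(1, 2)))
  rec <- rbind(make_records(1:10, image_id = "i1"),
               make_records(101:110, image_id = "i2"))
  out <- compare_rating_groups(rec, ratings)
  r12 <- out[out$metric == "DC (mm)" & out$group_b == "Rating 2", ]
  expect_false(r12$skipped)
  # complete separation: exact two-sided p = 2/choose(20,10), times 3
  expect_equal(r12$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r12$p_adj, 3 * 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r12$significant)
  # missing rating-3 stratum is skipped, not an error
  r13 <- out[out$metric == "DC (mm)" & out$group_a == "Rating 1" &
               out$group_b == "Rating 3", ]
  expect_true(r13$skipped)

  # two identical samples: p = 1 (no difference)
  vals <- rep(c(1, 2, 3, 4, 5), 3)
  same <- rbind(make_records(vals, image_id = "i1"),
                make_records(vals, image_id = "i2"))
  p_same <- compare_rating_groups(same, ratings)
  expect_gt(min(p_same$p_raw[p_same$metric == "DC (mm)"], na.rm = TRUE), 0.9)
})

test_that("AGS-vs-manual tests separate shifted strata and skip empty ones", {
  ratings <- finalize_ratings(data.frame(image_id = "i1", session1 = 3,
                                         session2 = 3))
  rec <- rbind(make_records(rnorm(30, 3, 0.3), kind = "manual_vs_manual",
                            image_id = "i1"),
               make_records(rnorm(30, 8, 0.3), kind = "ags_vs_manual",
                            image_id = "i1"))
  out <- compare_ags_manual(rec, ratings)
  all3 <- out[out$group == "Rating 3" & out$metric == "MSSD (mm)", ]
  expect_true(all3$significant)
  expect_equal(all3$p_adj, min(1, 3 * all3$p_raw))
  allimg <- out[out$group == "All Images" & out$metric == "MSSD (mm)", ]
  expect_equal(allimg$p_adj, allimg$p_raw)   # uncorrected overall test
  # all AGS failed: stratum skipped with flag
  manual_only <- rec[rec$kind == "manual_vs_manual", ]
  out2 <- compare_ags_manual(manual_only, ratings)
  expect_true(all(out2$skipped))
})

test_that("cohort evaluation conserves pair counts and excludes failures", {
  man <- tiny_manifest(n_images = 2, n_obs = 3, fail = c(11, 12, 13, 21))
  res <- evaluate_cohort(man, spacing = 2)
  # image 1: 0 AGS success -> 6 manual pairs; image 2: 2 AGS -> 6 + 6
  expect_equal(nrow(res$records), 6 + 6 + 2 * 3)
  expect_equal(res$failures$n_attempts, 6)
  expect_equal(res$failures$n_failures, 4)
  expect_equal(sum(res$records$kind == "ags_vs_manual" &
                     res$records$image_id == "t01"), 0)
  counts <- table(res$records$kind)
  expect_equal(unname(counts[["manual_vs_manual"]]), 12)
  expect_equal(unname(counts[["ags_vs_manual"]]), 6)
  expect_true(all(is.finite(res$records$dc_mm)))
  expect_true(all(res$records$dsc >= 0 & res$records$dsc <= 1))
})
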