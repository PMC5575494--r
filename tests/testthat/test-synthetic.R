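test_that("shape generation is deterministic and anteversion preserves volume", {
  p <- uterus_params(seed = 42)
  s1 <- generate_true_shape(p, subdiv = 3)
  s2 <- generate_true_shape(p, subdiv = 3)
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$faces, s2$faces)

  base <- list(body_length = 80, fundal_width = 45, cervix_length = 28,
               cervix_radius = 11)
  p0 <- do.call(uterus_params, c(base, list(anteversion_deg = 0)))
  p45 <- do.call(uterus_params, c(base, list(anteversion_deg = 45)))
  v0 <- enclosed_volume(generate_true_shape(p0, subdiv = 3))
  v45 <- enclosed_volume(generate_true_shape(p45, subdiv = 3))
  expect_lt(abs(v45 - v0) / v0, 0.01)
})

test_that("random shapes stay watertight with plausible organ volumes", {
  vols <- vapply(1:100, function(i) {
    s <- generate_true_shape(uterus_params(seed = 5000 + i), subdiv = 2)
    assert_watertight(s)
    enclosed_volume(s) / 1000   # cm^3
  }, numeric(1))
  expect_true(all(vols > 30))
  expect_true(all(vols < 300))
})

test_that("zero-amplitude observers reproduce the truth exactly", {
  truth <- generate_true_shape(uterus_params(seed = 8), subdiv = 3)
  m0 <- perturb_contour(truth, observer_model(sigma_obs = 0), seed = 4)
  expect_identical(m0$vertices, truth$vertices)
  expect_equal(dc(truth, m0), 0)
  expect_equal(mssd(truth, m0), 0)
  expect_equal(dsc(truth, m0, 2), 1)
  expect_equal(um95(truth, m0, spacing = 2), 0)
})

test_that("perturbation determinism and seed independence", {
  truth <- generate_true_shape(uterus_params(seed = 9), subdiv = 3)
  om <- observer_model()
  a1 <- perturb_contour(truth, om, seed = 11)
  a2 <- perturb_contour(truth, om, seed = 11)
  b <- perturb_contour(truth, om, seed = 12)
  expect_identical(a1$vertices, a2$vertices)
  expect_gt(mssd(a1, b), 0.5)
})

test_that("metric scale is strictly monotone in the observer amplitude", {
  meds <- vapply(c(1, 3, 6), function(sig) {
    om <- observer_model(sigma_obs = sig)
    vals <- vapply(1:12, function(i) {
      truth <- generate_true_shape(uterus_params(seed = 600 + i), subdiv = 3)
      a <- perturb_contour(truth, om, seed = 70 + 2 * i)
      b <- perturb_contour(truth, om, seed = 71 + 2 * i)
      c(mssd = mssd(a, b), dsc = dsc(a, b, spacing = 2),
        um95 = um95(a, b, spacing = 2))
    }, numeric(3))
    apply(vals, 1, median)
  }, numeric(3))
  expect_true(all(diff(meds["mssd", ]) > 0))
  expect_true(all(diff(meds["um95", ]) > 0))
  expect_true(all(diff(meds["dsc", ]) < 0))
})

test_that("AGS simulation honors failure probabilities and rating structure", {
  truth <- generate_true_shape(uterus_params(seed = 10), subdiv = 3)
  always_fail <- ags_error_model(failure_prob = c("1" = 1, "2" = 1, "3" = 0))
  expect_null(simulate_ags(truth, 1, always_fail, seed = 1))
  expect_null(simulate_ags(truth, 2, always_fail, seed = 2))
  expect_false(is.null(simulate_ags(truth, 3, always_fail, seed = 3)))
  expect_error(simulate_ags(truth, 0, always_fail), "rating")
  expect_error(ags_error_model(failure_prob = c("1" = 1, "2" = 1, "3" = 0.5)),
               "rating-3")
  # expected failure fraction of the default model under the 6/18/11 mix
  m <- ags_error_model()
  expected <- sum(c(6, 18, 11) * 4 *
                    m$failure_prob[c("1", "2", "3")]) / 140
  expect_equal(expected, 0.189, tolerance = 0.01)  # ~19% by design
})

test_that("default cohort reproduces the study bookkeeping structure", {
  man <- generate_cohort(cohort_config(subdiv = 2), master_seed = 31)
  expect_length(man$images, 35)
  ratings_tab <- table(vapply(man$images, `[[`, 0, "rating"))
  expect_equal(as.integer(ratings_tab[c("1", "2", "3")]), c(6, 18, 11))
  expect_equal(attr(man$ratings, "n_acquired"), 44)
  expect_equal(attr(man$ratings, "n_retained"), 35)
  expect_equal(attr(man$ratings, "retained_pct"), 79.5)
  n_manual <- sum(vapply(man$images, function(i) length(i$manual), 0L))
  n_attempt <- sum(vapply(man$images, function(i) length(i$ags), 0L))
  expect_equal(n_manual, 140)
  expect_equal(n_attempt, 140)
  # rating-3 attempts never fail
  for (img in man$images)
    if (img$rating == 3)
      expect_false(any(vapply(img$ags, is.null, logical(1))))
  # finalized ratings agree with the per-image ratings
  fr <- man$ratings$final_rating[match(
    vapply(man$images, `[[`, "", "image_id"), man$ratings$image_id)]
  expect_identical(fr, vapply(man$images, function(i) as.integer(i$rating),
                              integer(1)))
})

test_that("cohort generation is bit-reproducible and subsets regenerate", {
  cfg <- cohort_config(n_retained = 3, rating_mix = c(1, 1, 1),
                       n_excluded = 1, subdiv = 2)
  m1 <- generate_cohort(cfg, master_seed = 7)
  m2 <- generate_cohort(cfg, master_seed = 7)
  expect_identical(m1$ratings, m2$ratings)
  for (i in seq_along(m1$images)) {
    expect_identical(m1$images[[i]]$truth$vertices,
                     m2$images[[i]]$truth$vertices)
    expect_identical(lapply(m1$images[[i]]$manual, `[[`, "vertices"),
                     lapply(m2$images[[i]]$manual, `[[`, "vertices"))
  }
  m3 <- generate_cohort(cfg, master_seed = 8)
  expect_false(identical(m1$images[[1]]$truth$vertices,
                         m3$images[[1]]$truth$vertices))
})

test_that("calibration curve is usable and roughly linear at low amplitude", {
  sig <- calibrate_sigma(2.5, n_pairs = 6, levels = c(1, 2, 3, 4), seed = 3,
                         subdiv = 2)
  curve <- attr(sig, "curve")
  expect_true(all(diff(curve$median_mssd) > 0))
  expect_gt(sig, curve$sigma_obs[1])
  expect_lt(sig, curve$sigma_obs[4])
})
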