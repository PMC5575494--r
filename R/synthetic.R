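# Counter-based seed derivation: every artifact of a cohort gets its own
# 31-bit seed from (master_seed, indices), so any subset regenerates in
# isolation.  Arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (i in seq_along(idx))
    h <- (h * 48271 + as.double(idx[i]) * 9973 + i) %% 2147483647
  as.integer(h + 1)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- real spherical harmonics -------------------------------------------

# Orthonormal real spherical harmonics up to degree lmax, evaluated at unit
# directions (n x 3).  Returns n x (lmax+1)^2 with columns ordered
# (l, m = -l..l).
sh_basis <- function(dirs, lmax = 6) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  ct <- pmin(1, pmax(-1, z))
  phi <- atan2(y, x)
  st2 <- pmax(0, 1 - ct^2)
  n <- length(ct)
  # associated Legendre P_l^m(ct), m >= 0, via standard recursions
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- matrix(0, n, l + 1)
  P[[1]][, 1] <- 1
  if (lmax >= 1) {
    for (m in 1:lmax) {
      # P_m^m = (-1)^m (2m-1)!! (1-x^2)^(m/2)
      P[[m + 1]][, m + 1] <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) *
        st2^(m / 2)
    }
    for (m in 0:(lmax - 1)) {
      P[[m + 2]][, m + 1] <- ct * (2 * m + 1) * P[[m + 1]][, m + 1]
      if (m + 2 <= lmax) {
        for (l in (m + 2):lmax) {
          P[[l + 1]][, m + 1] <-
            ((2 * l - 1) * ct * P[[l]][, m + 1] -
             (l + m - 1) * P[[l - 1]][, m + 1]) / (l - m)
        }
      }
    }
  }
  B <- matrix(0, n, (lmax + 1)^2)
  col <- 1L
  for (l in 0:lmax) {
    for (m in (-l):l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- P[[l + 1]][, am + 1]
      B[, col] <-
        if (m == 0) nrm * p
        else if (m > 0) sqrt(2) * nrm * p * cos(m * phi)
        else sqrt(2) * nrm * p * sin(am * phi)
      col <- col + 1L
    }
  }
  B
}

# ---- shape model ---------------------------------------------------------

#' Parameters of the synthetic uterus shape model
#'
#' A pear-like organ: a superellipsoid body (fundus) blended with a tapered
#' cervical tube protruding inferiorly, the whole bent anteriorly by the
#' anteversion angle. Called with no arguments it draws one parameter set
#' from the default ranges; pass explicit values to fix them.
#'
#' @param body_length superior-inferior body extent, mm (drawn from 60-100).
#' @param fundal_width left-right fundal extent, mm (drawn from 30-60).
#' @param cervix_length cervical tube length below the body, mm (20-35).
#' @param cervix_radius cervical tube radius, mm (8-15).
#' @param anteversion_deg anterior bend of the body axis, degrees (0-90).
#' @param seed RNG seed used for any parameter left `NULL`.
#' @return a list of class `uterus_params`.
#' @export
uterus_params <- function(body_length = NULL, fundal_width = NULL,
                          cervix_length = NULL, cervix_radius = NULL,
                          anteversion_deg = NULL, seed = NULL) {
  p <- with_seed(seed, list(
    body_length = body_length %||% runif(1, 60, 100),
    fundal_width = fundal_width %||% runif(1, 30, 60),
    cervix_length = cervix_length %||% runif(1, 20, 35),
    cervix_radius = cervix_radius %||% runif(1, 8, 15),
    anteversion_deg = anteversion_deg %||% runif(1, 0, 90),
    seed = seed))
  stopifnot(p$body_length > 0, p$fundal_width > 0, p$cervix_length > 0,
            p$cervix_radius > 0)
  class(p) <- "uterus_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic uterus-like surface
#'
#' Deterministic given its parameters. The body is a superellipsoid
#' (exponent 2.5, anterior-posterior axis 0.9 of the transverse axis) and
#' the cervix an ellipsoidal tube below it; the two star-shaped radial maps
#' are blended by a smooth maximum on an icosphere parameterization, which
#' guarantees a watertight, self-intersection-free mesh. Anteversion is a
#' cylindrical bend of the long axis toward anterior, which preserves
#' cross-sections (and hence volume to first order).
#'
#' @param params a [uterus_params()] list.
#' @param subdiv icosphere subdivision (default 4: 2562 vertices).
#' @return a `surface_contour` in the patient frame, centered near the
#'   origin.
#' @export
generate_true_shape <- function(params, subdiv = 4) {
  base <- icosphere(1, subdiv)
  d <- base$vertices            # unit directions
  a <- params$fundal_width / 2                  # x semi-axis (L-R)
  b <- 0.9 * a                                  # y semi-axis (A-P)
  cz <- params$body_length / 2                  # z semi-axis (S-I)
  p <- 2.5
  r_body <- (abs(d[, 1] / a)^p + abs(d[, 2] / b)^p +
             abs(d[, 3] / cz)^p)^(-1 / p)
  # cervix: narrow ellipsoid reaching cervix_length below the body
  rc <- params$cervix_radius
  czc <- cz + params$cervix_length
  r_cerv <- (abs(d[, 1] / rc)^2 + abs(d[, 2] / rc)^2 +
             abs(d[, 3] / czc)^2)^(-1 / 2)
  # only the inferior half contributes the cervix lobe
  r_cerv[d[, 3] > 0.1] <- 0
  k <- 8   # smooth-union sharpness
  r <- (r_body^k + r_cerv^k)^(1 / k)
  v <- d * r

  alpha <- params$anteversion_deg * pi / 180
  if (alpha > 1e-6) {
    zmin <- min(v[, 3]); zmax <- max(v[, 3])
    Rc <- (zmax - zmin) / alpha          # bend radius
    zt <- v[, 3] - zmin
    theta <- zt / Rc
    ynew <- Rc - (Rc - v[, 2]) * cos(theta)
    znew <- (Rc - v[, 2]) * sin(theta) + zmin
    v[, 2] <- ynew
    v[, 3] <- znew
  }
  out <- surface_contour(v, base$faces, validate = FALSE)
  out <- orient_outward(out)
  vol <- signed_volume(out)
  if (!is.finite(vol) || vol <= 0)
    stop("shape generation produced a degenerate mesh", call. = FALSE)
  out
}

# ---- observer and AGS error models ---------------------------------------

#' Interobserver contour perturbation model
#'
#' Manual contours are emulated by displacing the true surface along its
#' outward normals by a smooth correlated random field (spherical harmonics
#' up to degree 6), scaled so the field RMS equals `sigma_obs`, with extra
#' amplitude (`edge_boost`) at the left-right organ edges and the cervix
#' base, where experts disagree most.
#'
#' @param sigma_obs RMS radial perturbation, mm. The default (2.6 mm) was
#'   calibrated once so that the cohort median manual-manual MSSD lands near
#'   the 3.2 mm interobserver scale.
#' @param correlation_length smoothness of the field along the surface, mm.
#' @param edge_boost amplitude multiplier (>= 1) at lateral edges and cervix
#'   base.
#' @param seed optional RNG seed.
#' @return a list of class `observer_model`.
#' @export
observer_model <- function(sigma_obs = 2.6, correlation_length = 25,
                           edge_boost = 1.8, seed = NULL) {
  stopifnot(sigma_obs >= 0, correlation_length > 0, edge_boost >= 1)
  structure(list(sigma_obs = sigma_obs,
                 correlation_length = correlation_length,
                 edge_boost = edge_boost, seed = seed),
            class = "observer_model")
}

#' Quality-dependent semiautomated (AGS-style) error model
#'
#' Per-rating Bernoulli failure, per-rating shape corruption amplitude, and
#' Poisson-distributed thin radial extrusions emulating shadow- and
#' speckle-driven artifacts. Rating-3 images never fail and are corrupted
#' at the interobserver amplitude (the algorithm matches experts on
#' excellent images); the default failure probabilities (0.5 / 0.2 / 0)
#' give an expected overall failure fraction of about 19% under the
#' 6/18/11 rating mix.
#'
#' @param failure_prob named numeric, failure probability per rating
#'   ("1", "2", "3"); rating-3 probability must be 0.
#' @param corruption_mm named numeric, perturbation RMS per rating, mm.
#' @param extrusion_rate named numeric, expected artifact extrusions per
#'   contour per rating.
#' @param extrusion_length extrusion length, mm.
#' @param extrusion_width angular half-width of an extrusion, radians.
#' @param correlation_length smoothness of the corruption field, mm.
#' @param edge_boost corruption amplitude multiplier at lateral edges and
#'   cervix base (setting `corruption_mm`, `correlation_length` and
#'   `edge_boost` to the observer model's values with zero extrusions makes
#'   the AGS error distribution identical to the interobserver one).
#' @param seed optional RNG seed.
#' @return a list of class `ags_error_model`.
#' @export
ags_error_model <- function(failure_prob = c("1" = 0.5, "2" = 0.2, "3" = 0),
                            corruption_mm = c("1" = 6.5, "2" = 4.5,
                                              "3" = 2.6),
                            extrusion_rate = c("1" = 3, "2" = 1.5, "3" = 0),
                            extrusion_length = 20,
                            extrusion_width = 0.05,
                            correlation_length = 25, edge_boost = 1.5,
                            seed = NULL) {
  stopifnot(all(failure_prob >= 0), all(failure_prob <= 1),
            all(corruption_mm >= 0), all(extrusion_rate >= 0),
            extrusion_length >= 0, extrusion_width > 0,
            correlation_length > 0, edge_boost >= 1)
  if (failure_prob[["3"]] != 0)
    stop("rating-3 failure probability must be 0 (failures occur only on degraded images)",
         call. = FALSE)
  structure(list(failure_prob = failure_prob, corruption_mm = corruption_mm,
                 extrusion_rate = extrusion_rate,
                 extrusion_length = extrusion_length,
                 extrusion_width = extrusion_width,
                 correlation_length = correlation_length,
                 edge_boost = edge_boost, seed = seed),
            class = "ags_error_model")
}

# Smooth correlated normal-displacement field; shared by the observer and
# AGS corruption paths.
smooth_field <- function(contour, sigma, correlation_length, edge_boost) {
  v <- contour$vertices
  ctr <- volume_centroid(contour)
  rel <- sweep(v, 2, ctr)
  rad <- sqrt(rowSums(rel^2))
  dirs <- rel / rad
  r_eff <- mean(rad)
  lmax <- 6
  B <- sh_basis(dirs, lmax)
  l_of <- rep(0:lmax, times = 2 * (0:lmax) + 1)
  l_c <- max(0.5, 2 * pi * r_eff / correlation_length)
  w <- exp(-(l_of / l_c)^2)
  coef <- rnorm(length(w)) * w
  f <- as.numeric(B %*% coef)
  f <- f / max(sd(f), 1e-12) * sigma
  # boost at lateral (|x|) extremes and at the cervix base (inferior tip)
  gx <- (abs(rel[, 1]) / max(abs(rel[, 1])))^4
  ztip <- min(v[, 3])
  span <- diff(range(v[, 3]))
  gz <- exp(-((v[, 3] - ztip) / (0.15 * span))^2 / 2)
  f * (1 + (edge_boost - 1) * pmax(gx, gz))
}

#' Perturb a contour like an independent observer
#'
#' Displaces vertices along outward normals by the [observer_model()] random
#' field. With `sigma_obs = 0` the input is returned unchanged. If the
#' displacement inverts the mesh the amplitude is halved and retried (three
#' attempts), then an error is raised.
#'
#' @param contour a watertight `surface_contour`.
#' @param model an [observer_model()].
#' @param seed optional seed (overrides `model$seed`).
#' @return a perturbed `surface_contour` with the same topology.
#' @export
perturb_contour <- function(contour, model, seed = NULL) {
  seed <- seed %||% model$seed
  if (model$sigma_obs == 0) return(contour)
  with_seed(seed, {
    nrm <- vertex_normals(contour)
    f <- smooth_field(contour, model$sigma_obs, model$correlation_length,
                      model$edge_boost)
    amp <- 1
    for (try_ in 1:3) {
      out <- contour
      out$vertices <- contour$vertices + nrm * (amp * f)
      vol <- signed_volume(out)
      if (is.finite(vol) && vol > 0.2 * signed_volume(contour)) return(out)
      amp <- amp / 2
    }
    stop("perturbation produced a self-intersecting mesh even after damping",
         call. = FALSE)
  })
}

#' Simulate one semiautomated (AGS-style) segmentation attempt
#'
#' With the rating's failure probability, returns `NULL` (failed attempt).
#' Otherwise returns the true surface corrupted at the rating's amplitude
#' plus a Poisson number of thin radial extrusions (narrow Gaussian bumps
#' of the model's length), emulating shadow-driven contour errors.
#'
#' @param contour the true organ surface.
#' @param rating final image-quality rating, 1, 2 or 3.
#' @param model an [ags_error_model()].
#' @param seed optional seed (overrides `model$seed`).
#' @return a `surface_contour`, or `NULL` on failure.
#' @export
simulate_ags <- function(contour, rating, model, seed = NULL) {
  if (!rating %in% 1:3) stop("rating must be 1, 2 or 3", call. = FALSE)
  seed <- seed %||% model$seed
  key <- as.character(rating)
  with_seed(seed, {
    if (runif(1) < model$failure_prob[[key]]) return(NULL)
    out <- contour
    sig <- model$corruption_mm[[key]]
    if (sig > 0) {
      nrm <- vertex_normals(contour)
      f <- smooth_field(contour, sig, model$correlation_length,
                        model$edge_boost)
      out$vertices <- contour$vertices + nrm * f
    }
    n_ext <- rpois(1, model$extrusion_rate[[key]])
    if (n_ext > 0)
      out <- add_extrusions(out, n_ext, model$extrusion_length,
                            model$extrusion_width)
    vol <- signed_volume(out)
    if (!is.finite(vol) || vol <= 0)
      stop("AGS corruption produced a degenerate mesh", call. = FALSE)
    out
  })
}

# Thin radial Gaussian spikes at random surface directions. Each artifact
# deflects the contour either outward (protrusion) or inward (intrusion)
# with equal probability, as shadowing pulls the gradient-based contour to
# either side of the true boundary; the random sign keeps the artifacts
# centroid-neutral in expectation.
add_extrusions <- function(contour, n, length_mm, width_rad) {
  ctr <- volume_centroid(contour)
  rel <- sweep(contour$vertices, 2, ctr)
  dirs <- rel / sqrt(rowSums(rel^2))
  nrm <- vertex_normals(contour)
  h <- rep(0, nrow(dirs))
  for (i in seq_len(n)) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    sgn <- if (runif(1) < 0.5) 1 else -1
    cosang <- pmin(1, pmax(-1, dirs %*% u))
    ang <- acos(cosang)
    h <- h + sgn * length_mm * exp(-(ang / width_rad)^2 / 2)
  }
  contour$vertices <- contour$vertices + nrm * as.numeric(h)
  contour
}

# ---- cohort --------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design: 44 acquired images of which 9 are
#' unusable (rated 0 at least once) and excluded, leaving 35 retained with
#' a 6/18/11 rating-1/2/3 mix; 4 observers contour every retained image
#' manually and attempt one AGS segmentation each.
#'
#' @param n_retained retained images (default 35).
#' @param rating_mix integer counts of ratings 1/2/3 among retained images
#'   (must sum to `n_retained`).
#' @param n_excluded additional acquired-but-unusable images (default 9).
#' @param n_observers observers per image (default 4).
#' @param observer an [observer_model()].
#' @param ags an [ags_error_model()].
#' @param subdiv icosphere subdivision of generated meshes (default 4).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_retained = 35, rating_mix = c(6, 18, 11),
                          n_excluded = 9, n_observers = 4,
                          observer = observer_model(),
                          ags = ags_error_model(), subdiv = 4) {
  if (sum(rating_mix) != n_retained)
    stop("rating_mix must sum to n_retained", call. = FALSE)
  structure(list(n_retained = n_retained, rating_mix = rating_mix,
                 n_excluded = n_excluded, n_observers = n_observers,
                 observer = observer, ags = ags, subdiv = subdiv),
            class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' For every retained image: one latent true shape, one manual contour per
#' observer (independent observer perturbations), and one AGS attempt per
#' observer (quality-dependent corruption or failure). Ratings include the
#' excluded images (one session rated 0). Bit-exactly reproducible from
#' `(config, master_seed)`; every artifact's seed is derived by a counter
#' scheme so subsets regenerate in isolation.
#'
#' @param config a [cohort_config()].
#' @param master_seed integer master seed.
#' @param out_dir if non-`NULL`, write meshes (ascii PLY), `ratings.csv`
#'   and `manifest.json` under this directory.
#' @return the cohort manifest: list with `images` (each: `image_id`,
#'   `rating`, `truth`, `manual` named list, `ags` named list with `NULL`
#'   for failed attempts), `ratings` (finalized ratings data.frame),
#'   `config`, `master_seed`.
#' @export
generate_cohort <- function(config = cohort_config(), master_seed = 1,
                            out_dir = NULL) {
  nr <- config$n_retained
  ratings_vec <- rep(1:3, times = config$rating_mix)
  ratings_vec <- with_seed(derive_seed(master_seed, 1),
                           sample(ratings_vec))
  ids <- sprintf("img%03d", seq_len(nr + config$n_excluded))
  retained_ids <- ids[seq_len(nr)]
  # session ratings consistent with the final rating under round-half-up
  sess <- with_seed(derive_seed(master_seed, 2), {
    t(vapply(ratings_vec, function(r) {
      if (r == 1) c(1L, 1L)
      else if (runif(1) < 0.5) c(r, r) else c(r - 1L, r)
    }, integer(2)))
  })
  excl_sess <- with_seed(derive_seed(master_seed, 3), {
    t(vapply(seq_len(config$n_excluded), function(i) {
      other <- sample(0:3, 1)
      if (runif(1) < 0.5) c(0L, other) else c(other, 0L)
    }, integer(2)))
  })
  sessions <- data.frame(
    image_id = ids,
    session1 = c(sess[, 1], if (config$n_excluded) excl_sess[, 1]),
    session2 = c(sess[, 2], if (config$n_excluded) excl_sess[, 2]),
    stringsAsFactors = FALSE)
  ratings <- finalize_ratings(sessions)
  stopifnot(identical(ratings$final_rating[seq_len(nr)], as.integer(ratings_vec)))

  obs_names <- paste0("obs", seq_len(config$n_observers))
  images <- vector("list", nr)
  for (i in seq_len(nr)) {
    params <- uterus_params(seed = derive_seed(master_seed, 10, i))
    truth <- generate_true_shape(params, subdiv = config$subdiv)
    truth$image_id <- retained_ids[i]
    truth$method <- "truth"
    manual <- list()
    ags <- list()
    for (j in seq_len(config$n_observers)) {
      m <- perturb_contour(truth, config$observer,
                           seed = derive_seed(master_seed, 20, i, j))
      m$delineator <- obs_names[j]; m$method <- "manual"
      manual[[obs_names[j]]] <- m
      a <- simulate_ags(truth, ratings_vec[i], config$ags,
                        seed = derive_seed(master_seed, 30, i, j))
      if (!is.null(a)) {
        a$delineator <- obs_names[j]; a$method <- "ags"
      }
      ags[obs_names[j]] <- list(a)   # keeps NULL entries
    }
    images[[i]] <- list(image_id = retained_ids[i], rating = ratings_vec[i],
                        params = params, truth = truth,
                        manual = manual, ags = ags)
  }
  manifest <- list(images = images, ratings = ratings, config = config,
                   master_seed = master_seed)
  if (!is.null(out_dir)) write_cohort(manifest, out_dir)
  manifest
}

#' Calibrate the observer amplitude to a target median MSSD
#'
#' Builds a Monte Carlo calibration curve (median directed MSSD between two
#' independent observer perturbations of random shapes, per amplitude) and
#' inverts it by monotone interpolation.
#'
#' @param target_mssd requested cohort median MSSD, mm (in roughly 1-6 mm).
#' @param n_pairs Monte Carlo pairs per amplitude level (default 25).
#' @param levels amplitude grid, mm.
#' @param seed RNG seed.
#' @param subdiv mesh resolution for the calibration (default 3; the curve
#'   is insensitive to it).
#' @return the calibrated `sigma_obs` (mm), with the curve as attribute
#'   `"curve"`.
#' @export
calibrate_sigma <- function(target_mssd, n_pairs = 25,
                            levels = c(0.5, 1, 2, 3, 4, 5, 6),
                            seed = 1, subdiv = 3) {
  med <- vapply(seq_along(levels), function(k) {
    sig <- levels[k]
    vals <- vapply(seq_len(n_pairs), function(i) {
      p <- uterus_params(seed = derive_seed(seed, k, i, 1))
      truth <- generate_true_shape(p, subdiv = subdiv)
      om <- observer_model(sigma_obs = sig)
      a <- perturb_contour(truth, om, seed = derive_seed(seed, k, i, 2))
      b <- perturb_contour(truth, om, seed = derive_seed(seed, k, i, 3))
      mssd(a, b)
    }, numeric(1))
    median(vals)
  }, numeric(1))
  med_mono <- cummax(med)   # the curve saturates at high amplitude
  if (target_mssd < min(med_mono) || target_mssd > max(med_mono))
    warning("target MSSD outside the calibrated range; clamping")
  sig <- stats::approx(med_mono, levels, xout = target_mssd, rule = 2,
                       ties = "ordered")$y
  structure(sig, curve = data.frame(sigma_obs = levels, median_mssd = med))
}
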