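# Synthetic thorax-phantom cohort. The generator emulates the modeled study
# conditions: 148 patients, ~33.1% Grade >= 2 radiation dermatitis, published
# covariate marginals, DVH distributions centred on the published cohort
# means, and a configurable logistic dose/texture/clinical -> label link whose
# "signal" covariates are known ground truth for recovery testing.
#
# Two paths share one covariate and label model:
#   images = TRUE  — full phantoms (CT + structures + dose grid); the skin DVH
#                    entering the label model is computed geometrically.
#   images = FALSE — the DVH profile is drawn from a parametric surrogate
#                    (patient-level lognormal scale on the published mean
#                    profile with a dose-tail tilt, monotonicity enforced),
#                    for desk-scale simulations at n in the hundreds.

DVH_LEVELS <- seq(5, 50, by = 5)
DVH_REF_MEAN <- c(325.0, 258.1, 225.9, 204.9, 187.4, 171.8, 156.9, 141.4,
                  118.2, 47.6)
DVH_REF_SD <- c(120.9, 89.3, 74.0, 62.2, 53.8, 46.8, 41.0, 36.6, 31.1, 24.6)

#' Cohort generator configuration
#'
#' Defaults reproduce the modeled study conditions: cohort size 148,
#' Grade >= 2 prevalence 0.331, 50 Gy prescription, covariate marginals and
#' DVH location/scale from the published cohort summaries. Spreads that the
#' publication does not report (age and BMI SD, texture correlation length)
#' are package defaults.
#'
#' @param n_patients cohort size (>= 10).
#' @param prevalence_target target Grade >= 2 fraction in (0, 1).
#' @param prescription_dose prescription in Gy.
#' @param grid_shape,spacing phantom CT grid (default 96 x 96 x 24 voxels at
#'   2 x 2 x 2.5 mm).
#' @param p_left,p_bcs,p_scf,p_imn,p_chemo Bernoulli covariate marginals.
#' @param ajcc_probs multinomial probabilities for AJCC stage 0-4.
#' @param age_mean,age_sd,bmi_mean,bmi_sd continuous covariate parameters.
#' @param texture_meanlog,texture_sdlog log-normal parameters of the latent
#'   CT texture correlation length (mm).
#' @param betas named effect sizes on the logistic risk scale:
#'   `b0` (NA = auto-calibrated to `prevalence_target`), `age` (per SD),
#'   `imn` (indicator), `v25` (per SD of skin V25Gy), `texture` (per SD of
#'   log correlation length).
#' @param seed integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 148, prevalence_target = 0.331,
                          prescription_dose = 50,
                          grid_shape = c(96, 96, 24), spacing = c(2, 2, 2.5),
                          p_left = 0.473, p_bcs = 0.804, p_scf = 0.257,
                          p_imn = 0.223, p_chemo = 0.50,
                          ajcc_probs = c(34, 46, 48, 17, 3) / 148,
                          age_mean = 56, age_sd = 10,
                          bmi_mean = 24.73, bmi_sd = 3.5,
                          texture_meanlog = log(6), texture_sdlog = 0.3,
                          betas = c(b0 = NA, age = 0.35, imn = 0.6,
                                    v25 = 0.35, texture = 0.3),
                          seed = 1) {
  if (n_patients < 10) stop("n_patients must be >= 10")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0,1)")
  probs <- c(p_left, p_bcs, p_scf, p_imn, p_chemo, ajcc_probs)
  if (any(probs < 0 | probs > 1)) stop("marginal probabilities must be in [0,1]")
  structure(as.list(environment()), class = "cohort_config")
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds b0 such that the Monte-Carlo mean of sigma(b0 + x' beta) over draws
#' from `covariate_sampler` matches `target`. The mean is monotone in b0, so
#' bounded bisection always converges.
#'
#' @param betas named numeric vector of effects (no intercept).
#' @param covariate_sampler function(n) returning a numeric matrix with
#'   columns matching `names(betas)`.
#' @param target desired mean risk in (0, 1).
#' @param n_mc Monte-Carlo sample size.
#' @param seed seed for the sampler draws.
#' @param tol tolerance on the achieved mean risk (default 0.005).
#' @return The calibrated intercept b0 (scalar).
#' @export
calibrate_intercept <- function(betas, covariate_sampler, target,
                                n_mc = 20000, seed = 1, tol = 0.005) {
  if (target <= 0 || target >= 1) stop("target must be in (0,1)")
  X <- run_with_seed(seed, covariate_sampler(n_mc))
  X <- as.matrix(X)[, names(betas), drop = FALSE]
  lp <- drop(X %*% betas)
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -30; hi <- 30
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  b0 <- (lo + hi) / 2
  if (abs(f(b0)) > tol)
    warning("calibration failed: achieved mean risk off target by ",
            signif(abs(f(b0)), 3))
  b0
}

sample_clinical <- function(n, cfg) {
  data.frame(
    patient_id = sprintf("pat%03d", seq_len(n)),
    age = round(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 1),
    bmi = round(stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 2),
    laterality = ifelse(stats::runif(n) < cfg$p_left, "left", "right"),
    surgery = ifelse(stats::runif(n) < cfg$p_bcs, "BCS", "TM/MRM"),
    ajcc_stage = sample(0:4, n, replace = TRUE, prob = cfg$ajcc_probs),
    scf = stats::runif(n) < cfg$p_scf,
    imn = stats::runif(n) < cfg$p_imn,
    chemotherapy = stats::runif(n) < cfg$p_chemo,
    stringsAsFactors = FALSE
  )
}

# parametric skin-DVH surrogate: lognormal patient scale + dose-tail tilt on
# the published mean profile; monotone in dose level by construction
sample_dvh_tabular <- function(n, cfg) {
  a <- stats::rnorm(n, 0, 0.28)
  b <- stats::rnorm(n, 0, 0.25)
  w <- (DVH_LEVELS - 27.5) / 22.5
  lv <- matrix(log(DVH_REF_MEAN), n, 10, byrow = TRUE) +
    a + outer(b, w) + matrix(stats::rnorm(n * 10, 0, 0.05), n)
  V <- exp(lv)
  V <- t(apply(V, 1, cummin))
  ptv100 <- stats::rlnorm(n, log(703.1) - 0.52^2 / 2, 0.52)
  ptv105 <- stats::rlnorm(n, log(69.2) - 1.25^2 / 2, 1.25)
  out <- cbind(V, ptv100, ptv105)
  colnames(out) <- c(paste0("dvh_skin5mm_V", DVH_LEVELS, "Gy"),
                     "dvh_ptv100", "dvh_ptv105")
  out
}

#' Stationary Gaussian random field by spectral synthesis
#'
#' White noise filtered in Fourier space with a Gaussian spectral envelope,
#' giving an approximately Gaussian covariance with the requested correlation
#' length; the field is standardised to zero mean, unit SD.
#'
#' @param dims integer length-3 grid shape.
#' @param spacing voxel spacing in mm.
#' @param corr_len correlation length in mm.
#' @return 3-D numeric array.
#' @export
gaussian_random_field <- function(dims, spacing, corr_len) {
  noise <- array(stats::rnorm(prod(dims)), dims)
  kx <- 2 * pi * c(0:(dims[1] %/% 2), -((ceiling(dims[1] / 2) - 1):1)) /
    (dims[1] * spacing[1])
  ky <- 2 * pi * c(0:(dims[2] %/% 2), -((ceiling(dims[2] / 2) - 1):1)) /
    (dims[2] * spacing[2])
  kz <- 2 * pi * c(0:(dims[3] %/% 2), -((ceiling(dims[3] / 2) - 1):1)) /
    (dims[3] * spacing[3])
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  H <- exp(-k2 * corr_len^2 / 4)
  f <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / prod(dims)
  (f - mean(f)) / stats::sd(f)
}

# star-shaped body: radius about the body centre is the max of the thorax
# ellipse radius and the breast-bulge ellipsoid ray intersection
ray_ellipse_exit <- function(px, py, vx, vy) {
  A <- vx^2 + vy^2
  B <- 2 * (px * vx + py * vy)
  C <- px^2 + py^2 - 1
  disc <- B^2 - 4 * A * C
  t <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
  ifelse(disc < 0 | t < 0, 0, t)
}

body_radius <- function(theta, z, geom) {
  ux <- cos(theta); uy <- sin(theta)
  re <- 1 / sqrt((ux / geom$a)^2 + (uy / geom$b)^2)
  zz <- (z - geom$bz) / geom$cz
  rb <- rep(0, length(theta))
  if (abs(zz) < 1) {
    sc <- sqrt(1 - zz^2)
    ea <- geom$ba * sc; eb <- geom$bb * sc
    rb <- ray_ellipse_exit((geom$cx - geom$qx) / ea, (geom$cy - geom$qy) / eb,
                           ux / ea, uy / eb)
  }
  pmax(re, rb)
}

make_phantom <- function(cfg, pat, texture_scale) {
  d <- cfg$grid_shape; sp <- cfg$spacing
  ext <- d * sp
  geom <- list(
    cx = ext[1] / 2, cy = ext[2] * 0.55,
    a = ext[1] * 0.38 * pat$size, b = ext[2] * 0.26 * pat$size,
    qx = ext[1] / 2 + (if (pat$left) -1 else 1) * ext[1] * 0.22,
    qy = ext[2] * 0.55 - ext[2] * 0.18,
    ba = 34 * pat$size, bb = 30 * pat$size,
    bz = ext[3] / 2, cz = ext[3] * 0.45
  )
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  body <- array(FALSE, d)
  for (iz in seq_len(d[3])) {
    dx <- outer(xs - geom$cx, rep(1, d[2]))
    dy <- outer(rep(1, d[1]), ys - geom$cy)
    th <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)
    R <- body_radius(as.vector(th), zs[iz], geom)
    body[, , iz] <- r <= matrix(R, d[1], d[2])
  }
  # lungs: two ellipsoids inside the thorax ellipse
  lung <- array(FALSE, d)
  for (side in c(-1, 1)) {
    lx <- geom$cx + side * geom$a * 0.45
    ly <- geom$cy + geom$b * 0.15
    q <- outer(outer(((xs - lx) / (geom$a * 0.30))^2,
                     ((ys - ly) / (geom$b * 0.45))^2, "+"),
               ((zs - ext[3] / 2) / (ext[3] * 0.40))^2, "+")
    lung <- lung | (q <= 1 & body)
  }
  tex <- gaussian_random_field(d, sp, texture_scale)
  ct <- array(-1000, d)
  ct[body] <- 40 + 15 * tex[body]
  ct[lung] <- -750
  ct_grid <- image_grid(ct, sp, origin = c(0, 0, 0),
                        frame_id = paste0("frame-", pat$id))
  # PTV inside the bulge
  pcx <- geom$qx; pcy <- geom$qy - 6; pcz <- ext[3] / 2
  pa <- 24 * pat$size; pb <- 18 * pat$size; pc <- 18 * pat$size
  q <- outer(outer(((xs - pcx) / pa)^2, ((ys - pcy) / pb)^2, "+"),
             ((zs - pcz) / pc)^2, "+")
  ptv <- structure_mask("ptv", q <= 1 & body, ct_grid)
  # tangential-style dose: logistic fall-off with distance from the PTV,
  # normalised to the prescription at the PTV surface, mild heterogeneity
  dist_mm <- sqrt(distance_sq_mm(ptv$mask, sp, max_mm = 60))
  shape <- stats::plogis((pat$r_fall - dist_mm) / pat$w_fall) /
    stats::plogis(pat$r_fall / pat$w_fall)
  dnoise <- gaussian_random_field(d, sp, 20)
  dose_ct <- cfg$prescription_dose * pat$amp * shape *
    (1 + 0.015 * dnoise)
  dose_ct <- pmax(dose_ct, 0)
  dose_ct <- pmin(dose_ct, 1.15 * cfg$prescription_dose)
  # exchange dose grid is 2x coarser in-plane than the CT
  ci <- seq(1, d[1], by = 2); cj <- seq(1, d[2], by = 2)
  dose_grid <- image_grid(dose_ct[ci, cj, , drop = FALSE],
                          spacing = c(sp[1] * 2, sp[2] * 2, sp[3]),
                          origin = c(0, 0, 0), frame_id = ct_grid$frame_id)
  # polygonal contours (body outline and PTV) for the RT-STRUCT exchange file
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  contours <- list(body = list(), ptv = list())
  for (iz in seq_len(d[3])) {
    R <- body_radius(theta, zs[iz], geom)
    contours$body[[length(contours$body) + 1]] <-
      list(z = zs[iz], xy = cbind(geom$cx + R * cos(theta),
                                  geom$cy + R * sin(theta)))
    zz <- (zs[iz] - pcz) / pc
    if (abs(zz) < 1) {
      sc <- sqrt(1 - zz^2)
      contours$ptv[[length(contours$ptv) + 1]] <-
        list(z = zs[iz], xy = cbind(pcx + pa * sc * cos(theta),
                                    pcy + pb * sc * sin(theta)))
    }
  }
  dose_on_ct <- image_grid(dose_ct, sp, c(0, 0, 0), ct_grid$frame_id)
  list(ct = ct_grid, dose = dose_grid, dose_on_ct = dose_on_ct, ptv = ptv,
       contours = contours)
}

#' Generate a synthetic phantom cohort
#'
#' Draws clinical covariates and latent texture scales, builds (optionally)
#' per-patient phantoms with a tangential-style dose field, computes or draws
#' the 12 DVH features, and assigns Grade >= 2 labels from the logistic risk
#' model sigma(b0 + b_age z(age) + b_imn imn + b_v25 z(V25Gy) +
#' b_texture z(texture)). When `betas["b0"]` is NA it is calibrated so the
#' expected prevalence matches `prevalence_target`.
#'
#' @param config a [cohort_config()].
#' @param images build full image phantoms (TRUE) or use the tabular DVH
#'   surrogate (FALSE, fast; suited to n in the hundreds).
#' @return List with `clinical` (covariates + `rd_grade_ge2` label), `dvh`
#'   (n x 12 matrix), `latent` (texture scale, risk), `config`, `beta0`, and
#'   — with images — `patients` (ct, dose, dose_on_ct, ptv, contours each).
#' @export
generate_cohort <- function(config = cohort_config(), images = FALSE) {
  cfg <- config
  run_with_seed(cfg$seed, {
    n <- cfg$n_patients
    clin <- sample_clinical(n, cfg)
    ts <- stats::rlnorm(n, cfg$texture_meanlog, cfg$texture_sdlog)
    patients <- NULL
    if (images) {
      pars <- data.frame(
        id = clin$patient_id,
        left = clin$laterality == "left",
        size = exp(stats::rnorm(n, 0, 0.08)),
        r_fall = pmax(stats::rnorm(n, 14, 3), 6),
        w_fall = pmax(stats::rnorm(n, 9, 2), 4),
        amp = stats::runif(n, 1.00, 1.08)
      )
      patients <- lapply(seq_len(n), function(i) {
        p <- make_phantom(cfg, pars[i, ], ts[i])
        p$clinical <- clin[i, ]
        p
      })
      dvh <- t(vapply(patients, function(p) {
        body <- build_body_mask(p$ct)
        skin <- build_skin5mm(body, cfg$spacing)
        compute_dvh_features(p$dose_on_ct, list(skin5mm = skin, ptv = p$ptv),
                             cfg$prescription_dose)
      }, numeric(12)))
    } else {
      dvh <- sample_dvh_tabular(n, cfg)
    }
    betas <- cfg$betas
    z_age <- (clin$age - cfg$age_mean) / cfg$age_sd
    # V25 is standardised against the realized cohort so the planted effect
    # size is per cohort SD regardless of phantom scale
    v25 <- dvh[, "dvh_skin5mm_V25Gy"]
    z_v25 <- if (stats::sd(v25) > 0) (v25 - mean(v25)) / stats::sd(v25) else v25 * 0
    z_tex <- (log(ts) - cfg$texture_meanlog) / cfg$texture_sdlog
    X <- cbind(age = z_age, imn = as.numeric(clin$imn), v25 = z_v25,
               texture = z_tex)
    bvec <- betas[c("age", "imn", "v25", "texture")]
    lp <- drop(X %*% bvec)
    b0 <- betas[["b0"]]
    if (is.na(b0)) {
      b0 <- calibrate_intercept(
        bvec, function(m) X[sample.int(n, m, replace = TRUE), , drop = FALSE],
        target = cfg$prevalence_target, n_mc = max(20000, 10 * n),
        seed = cfg$seed + 1)
    }
    risk <- stats::plogis(b0 + lp)
    clin$rd_grade_ge2 <- stats::runif(n) < risk
    list(clinical = clin, dvh = dvh,
         latent = data.frame(texture_scale = ts, risk = risk),
         beta0 = b0, config = cfg, patients = patients)
  })
}

#' One-hot encode the clinical covariate block
#'
#' Numeric age/BMI pass through; every categorical level gets its own
#' indicator (full dummy coding; downstream regularisation absorbs the
#' collinearity).
#'
#' @param clinical clinical data frame from [generate_cohort()].
#' @return Numeric matrix with `clinical_` prefixed columns.
#' @export
encode_clinical <- function(clinical) {
  out <- cbind(
    age = clinical$age,
    bmi = clinical$bmi,
    laterality_left = as.numeric(clinical$laterality == "left"),
    laterality_right = as.numeric(clinical$laterality == "right"),
    surgery_bcs = as.numeric(clinical$surgery == "BCS"),
    surgery_tm = as.numeric(clinical$surgery == "TM/MRM"),
    sapply(0:4, function(s) as.numeric(clinical$ajcc_stage == s)),
    scf = as.numeric(clinical$scf),
    imn = as.numeric(clinical$imn),
    chemotherapy = as.numeric(clinical$chemotherapy)
  )
  colnames(out) <- paste0("clinical_",
    c("age", "bmi", "laterality_left", "laterality_right", "surgery_bcs",
      "surgery_tm", paste0("ajcc_", 0:4), "scf", "imn", "chemotherapy"))
  rownames(out) <- clinical$patient_id
  out
}
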