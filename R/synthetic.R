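#' Configuration for the synthetic biometry cohort generator
#'
#' Defaults emulate the marginal statistics of a large single-center
#' cataract cohort: axial length 24.02 +/- 1.57 mm, mean corneal radius
#' 7.63 +/- 0.27 mm, ACD 3.10 +/- 0.41 mm, lens thickness 4.57 +/- 0.43 mm,
#' white-to-white 11.74 +/- 0.41 mm, with a Haigis-style ground-truth ELP
#' model (a0 = -1.72, a1 = 0.277, a2 = 0.260) so that the implanted power
#' targets a mildly myopic refraction and the observed mean power comes out
#' near 19.6 D. Correlations between biometric variables are stipulated
#' (physiologically plausible signs), not estimated: corr(AL, ACD) = 0.4,
#' corr(ACD, LT) = -0.4, corr(AL, WTW) = 0.3, others 0.
#'
#' @param n_patients Number of patients.
#' @param bilateral_fraction Fraction of patients contributing both eyes.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param marginals Named list per variable of `c(mean, sd)` for
#'   `axial_length`, `corneal_radius`, `acd`, `lens_thickness`, `wtw`.
#' @param correlations 5x5 correlation matrix over those variables (in that
#'   order); must be symmetric positive definite.
#' @param truth_formula Generative ELP model: `"haigis"` (default; the
#'   linear `truth_constants` predictor with Haigis vergence conventions,
#'   deliberately mis-specified relative to SRK/T so a stacked learner has
#'   headroom over it) or `"srkt"` (the SRK/T corneal-height ELP at
#'   `truth_A`, with SRK/T conventions — used to test A-constant recovery).
#' @param truth_constants Ground-truth Haigis triple `c(a0, a1, a2)` of the
#'   generative ELP model (used when `truth_formula = "haigis"`).
#' @param truth_A Ground-truth A constant (used when
#'   `truth_formula = "srkt"`).
#' @param elp_noise_sd Per-eye ELP noise, mm.
#' @param refraction_noise_sd Measurement noise on the observed
#'   postoperative spherical equivalent, diopters.
#' @param target_refraction `c(mean, sd)` of the surgeon's target
#'   refraction, diopters; truncated to `target_bounds`.
#' @param target_bounds Truncation interval for the target refraction.
#' @param power_step Commercial IOL power step, diopters.
#' @param iol_models Data frame with columns `model`, `elp_shift` (mm) and
#'   `prob`: the synthetic lens labels, their ground-truth ELP offsets and
#'   sampling weights.
#' @param between_eye_corr Correlation of the latent biometry between the
#'   two eyes of a bilateral patient.
#' @param age `c(mean, sd, lower, upper)` of the truncated normal patient
#'   age distribution, years.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 2159,
                             bilateral_fraction = 0.706,
                             seed = 1,
                             marginals = list(
                               axial_length = c(24.02, 1.57),
                               corneal_radius = c(7.63, 0.27),
                               acd = c(3.10, 0.41),
                               lens_thickness = c(4.57, 0.43),
                               wtw = c(11.74, 0.41)
                             ),
                             correlations = default_biometry_correlations(),
                             truth_formula = c("haigis", "srkt"),
                             truth_constants = c(a0 = -1.72, a1 = 0.277, a2 = 0.260),
                             truth_A = 119.2,
                             elp_noise_sd = 0.1,
                             refraction_noise_sd = 0.25,
                             target_refraction = c(mean = -0.3, sd = 0.3),
                             target_bounds = c(-3.5, 0.5),
                             power_step = 0.5,
                             iol_models = data.frame(
                               model = c("YP2.2", "SZ-1", "ZCB00V"),
                               elp_shift = c(0, 0.15, -0.15),
                               prob = c(0.5, 0.25, 0.25)
                             ),
                             between_eye_corr = 0.7,
                             age = c(mean = 72, sd = 9, lower = 40, upper = 95)) {
  stopifnot(
    n_patients >= 1, bilateral_fraction >= 0, bilateral_fraction <= 1,
    power_step > 0, elp_noise_sd >= 0, refraction_noise_sd >= 0,
    between_eye_corr >= 0, between_eye_corr <= 1,
    all(vapply(marginals, function(m) m[2] > 0, TRUE)),
    target_refraction[["sd"]] > 0,
    nrow(iol_models) >= 1, all(iol_models$prob > 0)
  )
  correlations <- as.matrix(correlations)
  if (!isSymmetric(unname(correlations)) ||
    any(eigen(correlations, symmetric = TRUE, only.values = TRUE)$values <= 1e-10)) {
    stop("correlation matrix must be symmetric positive definite", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      bilateral_fraction = bilateral_fraction,
      seed = as.integer(seed),
      marginals = marginals,
      correlations = correlations,
      truth_formula = match.arg(truth_formula),
      truth_constants = truth_constants,
      truth_A = truth_A,
      elp_noise_sd = elp_noise_sd,
      refraction_noise_sd = refraction_noise_sd,
      target_refraction = target_refraction,
      target_bounds = target_bounds,
      power_step = power_step,
      iol_models = iol_models,
      between_eye_corr = between_eye_corr,
      age = age
    ),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_biometry_correlations <- function() {
  v <- c("axial_length", "corneal_radius", "acd", "lens_thickness", "wtw")
  R <- diag(5)
  dimnames(R) <- list(v, v)
  R["axial_length", "acd"] <- R["acd", "axial_length"] <- 0.4
  R["acd", "lens_thickness"] <- R["lens_thickness", "acd"] <- -0.4
  R["axial_length", "wtw"] <- R["wtw", "axial_length"] <- 0.3
  R
}

mvn0 <- function(n, R) {
  m <- MASS::mvrnorm(n, rep(0, nrow(R)), R)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- which(x < lower | x > upper)
    if (length(bad) == 0L) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic biometry cohort with a known optical ground truth
#'
#' Biometry is drawn from a truncated multivariate normal with the
#' configured marginals and correlations; bilateral patients share a
#' patient-level latent component so their two eyes are correlated. The
#' ground truth links biometry to outcome through a Haigis-style ELP:
#' `d* = a0 + a1*ACD + a2*AL + model_shift + N(0, elp_noise_sd)`; the
#' implanted power targets a truncated-normal draw of the surgeon's target
#' refraction under the Haigis vergence conventions (K = 331.5/r, optical
#' axial length = measured), rounded to the commercial power step; the
#' observed refraction is the vergence-chain refraction at the rounded
#' power plus measurement noise.
#'
#' @param cfg A [synthetic_config()].
#' @return A `cohort` data frame; one row per eye, validated.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set_seed(cfg$seed)
  np <- cfg$n_patients
  vars <- names(cfg$marginals)
  mu <- vapply(cfg$marginals, `[`, 0, 1)
  sdv <- vapply(cfg$marginals, `[`, 0, 2)

  n_bi <- round(np * cfg$bilateral_fraction)
  bilateral <- rep(FALSE, np)
  if (n_bi > 0) bilateral[sample.int(np, n_bi)] <- TRUE
  n_eyes <- np + n_bi
  patient <- rep(seq_len(np), times = 1L + bilateral)

  # latent standardized biometry: eye = sqrt(w)*patient + sqrt(1-w)*eye-resid,
  # both MVN(0, R), preserving the per-eye marginal covariance
  w <- cfg$between_eye_corr
  z_pat <- mvn0(np, cfg$correlations)
  z_eye <- mvn0(n_eyes, cfg$correlations)
  z <- sqrt(w) * z_pat[patient, , drop = FALSE] +
    sqrt(1 - w) * z_eye
  x <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
  colnames(x) <- vars

  # truncate to the record bounds by redrawing eye-level residuals (rare)
  for (iter in 1:100) {
    bad <- rep(FALSE, n_eyes)
    for (j in seq_along(vars)) {
      b <- biometry_bounds[[vars[j]]]
      bad <- bad | x[, j] <= b[1] | x[, j] >= b[2]
    }
    if (!any(bad)) break
    nb <- sum(bad)
    z_eye[bad, ] <- mvn0(nb, cfg$correlations)
    if (iter > 20) z_pat[patient[bad], ] <- mvn0(nb, cfg$correlations)
    z[bad, ] <- sqrt(w) * z_pat[patient[bad], , drop = FALSE] + sqrt(1 - w) * z_eye[bad, , drop = FALSE]
    x[bad, ] <- sweep(sweep(z[bad, , drop = FALSE], 2, sdv, "*"), 2, mu, "+")
  }

  age_pat <- rtruncnorm1(
    np, cfg$age[["mean"]], cfg$age[["sd"]],
    cfg$age[["lower"]], cfg$age[["upper"]]
  )
  lat <- character(n_eyes)
  first <- !duplicated(patient)
  lat[first & patient %in% which(bilateral)] <- "right"
  lat[!first] <- "left"
  lat[lat == ""] <- sample(c("left", "right"), sum(lat == ""), replace = TRUE)

  im <- cfg$iol_models
  model_idx <- sample.int(nrow(im), n_eyes, replace = TRUE, prob = im$prob)
  iol_model <- im$model[model_idx]

  if (cfg$truth_formula == "haigis") {
    tc <- cfg$truth_constants
    d_model <- tc[["a0"]] + tc[["a1"]] * x[, "acd"] + tc[["a2"]] * x[, "axial_length"]
    K <- corneal_power(x[, "corneal_radius"], 331.5)
    al_opt <- x[, "axial_length"]
  } else {
    d_model <- elp_srkt(x[, "axial_length"], x[, "corneal_radius"], cfg$truth_A)
    K <- corneal_power(x[, "corneal_radius"], 337.5)
    al_opt <- optical_axial_length(formula_engine("srkt"), x[, "axial_length"])
  }
  d_true <- d_model + im$elp_shift[model_idx] +
    stats::rnorm(n_eyes, 0, cfg$elp_noise_sd)
  target <- rtruncnorm1(
    n_eyes, cfg$target_refraction[["mean"]], cfg$target_refraction[["sd"]],
    cfg$target_bounds[1], cfg$target_bounds[2]
  )
  p_exact <- solve_power_chain(K, d_true, al_opt, target)
  power <- round(p_exact / cfg$power_step) * cfg$power_step
  # keep within the commercial/plausible power range
  pb <- biometry_bounds$iol_power
  power <- pmin(pmax(power, pb[1] + cfg$power_step), pb[2] - cfg$power_step)
  postop <- vergence_chain(K, d_true, al_opt, power) +
    stats::rnorm(n_eyes, 0, cfg$refraction_noise_sd)

  df <- data.frame(
    patient_id = sprintf("P%04d", patient),
    eye_id = sprintf("P%04d-%s", patient, ifelse(lat == "left", "L", "R")),
    laterality = lat,
    age = round(age_pat[patient], 1),
    axial_length = x[, "axial_length"],
    corneal_radius = x[, "corneal_radius"],
    acd = x[, "acd"],
    lens_thickness = x[, "lens_thickness"],
    wtw = x[, "wtw"],
    iol_model = iol_model,
    iol_power = power,
    postop_se = postop,
    row.names = NULL
  )
  validate_cohort_df(df, file = "synthetic cohort")
  new_cohort(df, provenance = sprintf(
    "synthetic cohort: %d patients, %d eyes, seed %d",
    np, n_eyes, cfg$seed
  ))
}

#' Patient-wise train/test split with fellow-eye exclusion
#'
#' Samples `n_test` distinct patients, takes exactly one eye from each into
#' the test set, and discards those patients' fellow eyes entirely, so that
#' no patient appears in both sets. All eyes of the remaining patients
#' (including bilateral pairs) form the training set.
#'
#' @param cohort A cohort data frame.
#' @param n_test Number of test patients (one eye each).
#' @param seed Integer seed for patient and eye sampling.
#' @param require_train Error if the training set would be empty
#'   (default TRUE).
#' @return List with `train` and `test` cohorts.
#' @export
split_patientwise <- function(cohort, n_test, seed = 1, require_train = TRUE) {
  patients <- unique(cohort$patient_id)
  if (n_test > length(patients)) {
    stop(sprintf(
      "n_test (%d) exceeds patient count (%d)", n_test, length(patients)
    ), call. = FALSE)
  }
  set_seed(seed)
  test_patients <- sample(patients, n_test)
  test_rows <- vapply(test_patients, function(p) {
    rows <- which(cohort$patient_id == p)
    if (length(rows) == 1L) rows else sample(rows, 1L)
  }, 0L)
  train <- cohort[!(cohort$patient_id %in% test_patients), , drop = FALSE]
  test <- cohort[test_rows, , drop = FALSE]
  if (require_train && nrow(train) == 0L) {
    stop("training set is empty (all patients assigned to test)", call. = FALSE)
  }
  rownames(train) <- rownames(test) <- NULL
  list(
    train = new_cohort(train, provenance = sprintf(
      "%s | train split (seed %d)", attr(cohort, "provenance"), seed
    )),
    test = new_cohort(test, provenance = sprintf(
      "%s | test split: %d patients, one eye each (seed %d)",
      attr(cohort, "provenance"), n_test, seed
    ))
  )
}
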