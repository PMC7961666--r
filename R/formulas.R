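#' Formula engine: the optical conventions of a vergence IOL formula
#'
#' Bundles the conventions under which one of the four supported
#' intraocular-lens power formulas evaluates the thin-lens vergence chain:
#' the aqueous/vitreous refractive index, the keratometric numerator used to
#' convert corneal radius to corneal power, the spectacle vertex distance,
#' the measured-to-optical axial length adjustment, and any fixed shift
#' applied to the effective lens position (ELP) inside the chain.
#'
#' Conventions frozen here (the single largest interoperability pitfall
#' between published implementations): corneal power is 337.5/r for SRK/T
#' and Hoffer Q, 1000/3 / r (net power, index 4/3) for Holladay 1, and
#' 331.5/r for Haigis. The optical axial length is
#' `AL + 0.65696 - 0.02029*AL` for SRK/T, `AL + 0.2` for Holladay 1, and
#' the measured length for Hoffer Q and Haigis. Hoffer Q adds +0.05 mm to
#' the ELP inside the chain.
#'
#' @param formula_id One of `"srkt"`, `"holladay1"`, `"hofferq"`, `"haigis"`.
#' @param vertex_distance Spectacle vertex distance in mm (default 12).
#' @return An object of class `formula_engine`.
#' @examples
#' eng <- formula_engine("srkt")
#' eng$keratometric_index_constant  # 337.5
#' @export
formula_engine <- function(formula_id = c("srkt", "holladay1", "hofferq", "haigis"),
                           vertex_distance = 12) {
  formula_id <- match.arg(formula_id)
  stopifnot(is.numeric(vertex_distance), vertex_distance > 0)
  structure(
    list(
      formula_id = formula_id,
      n_aqueous = 1.336,
      keratometric_index_constant = switch(formula_id,
        srkt = 337.5, holladay1 = 1000 / 3, hofferq = 337.5, haigis = 331.5
      ),
      vertex_distance = vertex_distance,
      elp_shift = if (formula_id == "hofferq") 0.05 else 0
    ),
    class = "formula_engine"
  )
}

#' @export
print.formula_engine <- function(x, ...) {
  cat(sprintf(
    "<formula_engine %s>  K = %.4f/r  vertex %g mm  elp_shift %+g mm\n",
    x$formula_id, x$keratometric_index_constant, x$vertex_distance, x$elp_shift
  ))
  invisible(x)
}

#' Optical axial length under a formula's convention
#'
#' @param engine A [formula_engine()].
#' @param axial_length Measured axial length, mm.
#' @return Optical axial length in mm (vectorized).
#' @export
optical_axial_length <- function(engine, axial_length) {
  stopifnot(inherits(engine, "formula_engine"))
  switch(engine$formula_id,
    srkt = axial_length + 0.65696 - 0.02029 * axial_length,
    holladay1 = axial_length + 0.2,
    axial_length
  )
}

#' Corneal power from corneal radius
#'
#' @param r Corneal radius of curvature, mm (mean of the principal radii).
#' @param numerator Keratometric numerator in diopter-mm (e.g. 337.5).
#' @return Corneal power in diopters, `numerator / r`.
#' @examples
#' corneal_power(7.5, 337.5)  # 45
#' @export
corneal_power <- function(r, numerator = 337.5) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("corneal radius must be positive and finite", call. = FALSE)
  }
  numerator / r
}

#' Thin-lens vergence chain: predicted spectacle-plane refraction
#'
#' Propagates vergence from the retina to the spectacle plane of a
#' pseudophakic eye: the retinal image vergence `1000*n/(AL_opt - d)` minus
#' the IOL power gives the vergence incident on the IOL; converting to a
#' focal distance, stepping the ELP distance `d` to the cornea, adding the
#' corneal power, and stepping the vertex distance to the spectacle plane
#' yields the predicted spherical-equivalent refraction.
#'
#' @param K Corneal power, diopters (under the engine's convention).
#' @param d Effective lens position, mm, including any engine `elp_shift`.
#' @param al_opt Optical axial length, mm.
#' @param power IOL power, diopters.
#' @param n Aqueous/vitreous refractive index (default 1.336).
#' @param vertex Spectacle vertex distance, mm (default 12).
#' @return Predicted refraction at the spectacle plane, diopters (vectorized).
#' @examples
#' # emmetropic-ish eye
#' vergence_chain(K = 43.83, d = 5.16, al_opt = 23.68, power = 19.5)
#' @export
vergence_chain <- function(K, d, al_opt, power, n = 1.336, vertex = 12) {
  if (any(d >= al_opt)) {
    stop("ELP must lie in front of the retina (d < optical axial length)",
      call. = FALSE
    )
  }
  if (any(d <= 0)) stop("ELP must be positive", call. = FALSE)
  z_ret <- 1000 * n / (al_opt - d)
  z_in <- z_ret - power
  if (any(abs(z_in) < 1e-9)) {
    stop("unphysical configuration: IOL power equals the retinal vergence",
      call. = FALSE
    )
  }
  f_iol <- 1000 * n / z_in
  f_c <- f_iol + d
  v_c <- 1000 * n / f_c
  z <- v_c - K
  denom <- 1 + (vertex / 1000) * z
  if (any(abs(denom) < 1e-9)) {
    stop("unphysical configuration: vertex singularity", call. = FALSE)
  }
  z / denom
}

#' SRK/T effective lens position
#'
#' Corneal-height ELP model: `K = 337.5/r`; corrected axial length
#' `LCOR = AL` for `AL <= 24.2`, else `-3.446 + 1.715*AL - 0.0237*AL^2`;
#' computed corneal width `Cw = -5.41 + 0.58412*LCOR + 0.098*K`; corneal
#' height `H = r - sqrt(max(0, r^2 - Cw^2/4))`;
#' `ELP = H + (0.62467*A - 68.747) - 3.336`.
#'
#' @param axial_length Measured axial length, mm.
#' @param r Corneal radius, mm.
#' @param A SRK/T A constant.
#' @return ELP in mm (vectorized).
#' @examples
#' elp_srkt(23.5, 7.7, 118.4)  # ~5.159
#' @export
elp_srkt <- function(axial_length, r, A) {
  K <- corneal_power(r, 337.5)
  lcor <- ifelse(axial_length <= 24.2,
    axial_length,
    -3.446 + 1.715 * axial_length - 0.0237 * axial_length^2
  )
  cw <- -5.41 + 0.58412 * lcor + 0.098 * K
  h <- r - sqrt(pmax(0, r^2 - cw^2 / 4))
  h + (0.62467 * A - 68.747) - 3.336
}

#' Holladay 1 effective lens position
#'
#' Anatomic ACD plus surgeon factor: anterior-segment size
#' `AG = min(12.5*AL/23.45, 13.5)`;
#' `ELP = 0.56 + r - sqrt(max(0, r^2 - AG^2/4)) + SF`.
#'
#' @param axial_length Measured axial length, mm.
#' @param r Corneal radius, mm.
#' @param SF Holladay surgeon factor, mm.
#' @return ELP in mm (vectorized).
#' @export
elp_holladay1 <- function(axial_length, r, SF) {
  ag <- pmin(12.5 * axial_length / 23.45, 13.5)
  0.56 + r - sqrt(pmax(0, r^2 - ag^2 / 4)) + SF
}

#' Hoffer Q effective lens position
#'
#' `AL` is clamped to \[18.5, 31\] for this computation. With `M = +1,
#' G = 28` for `AL <= 23` and `M = -1, G = 23.5` otherwise:
#' `ELP = pACD + 0.3*(AL - 23.5) + tan2(K) +
#'  0.1*M*(23.5 - AL)^2 * tan(0.1*(G - AL)^2) - 0.99166`,
#' with tangent arguments in degrees.
#'
#' @param axial_length Measured axial length, mm.
#' @param K Corneal power, diopters (337.5/r convention).
#' @param pACD Personalized anterior chamber depth constant, mm.
#' @return ELP in mm (vectorized).
#' @examples
#' elp_hofferq(23.5, 45, 5)  # 5.00834 (tan(45 deg) = 1)
#' @export
elp_hofferq <- function(axial_length, K, pACD) {
  al <- pmin(pmax(axial_length, 18.5), 31)
  m <- ifelse(al <= 23, 1, -1)
  g <- ifelse(al <= 23, 28, 23.5)
  tand <- function(deg) tan(deg * pi / 180)
  pACD + 0.3 * (al - 23.5) + tand(K)^2 +
    0.1 * m * (23.5 - al)^2 * tand(0.1 * (g - al)^2) - 0.99166
}

#' Haigis effective lens position
#'
#' Linear predictor `d = a0 + a1*ACD + a2*AL` on preoperative anterior
#' chamber depth and axial length.
#'
#' @param acd Preoperative anterior chamber depth, mm.
#' @param axial_length Measured axial length, mm.
#' @param a0,a1,a2 Haigis constants.
#' @return ELP in mm (vectorized).
#' @export
elp_haigis <- function(acd, axial_length, a0, a1, a2) {
  a0 + a1 * acd + a2 * axial_length
}

#' Default Haigis triple derived from an A constant
#'
#' Standard initialization used before data-driven optimization:
#' `a0 = 0.62467*A - 72.434`, `a1 = 0.4`, `a2 = 0.1`.
#'
#' @param A SRK/T-style A constant.
#' @return Named list with `a0`, `a1`, `a2`.
#' @export
haigis_constants_from_A <- function(A) {
  list(a0 = 0.62467 * A - 72.434, a1 = 0.4, a2 = 0.1)
}

# Per-eye ELP under an engine, given per-eye constants (each a list with
# whichever of A/SF/pACD/a0/a1/a2 the engine needs). Internal.
engine_elp <- function(engine, axial_length, corneal_radius, acd, const) {
  switch(engine$formula_id,
    srkt = elp_srkt(axial_length, corneal_radius, const$A),
    holladay1 = elp_holladay1(axial_length, corneal_radius, const$SF),
    hofferq = elp_hofferq(
      axial_length, corneal_power(corneal_radius, 337.5), const$pACD
    ),
    haigis = elp_haigis(acd, axial_length, const$a0, const$a1, const$a2)
  )
}

# Which constant fields an engine needs. Internal.
engine_constant_fields <- function(formula_id) {
  switch(formula_id,
    srkt = "A", holladay1 = "SF", hofferq = "pACD",
    haigis = c("a0", "a1", "a2")
  )
}

# Resolve per-eye constants from a per-lens-model map; errors name the
# formula and lens model. Returns a list of per-field numeric vectors.
resolve_constants <- function(engine, iol_model, constants) {
  fields <- engine_constant_fields(engine$formula_id)
  models <- unique(iol_model)
  per_model <- lapply(models, function(m) {
    entry <- constants[[m]]
    if (is.null(entry)) {
      stop(sprintf(
        "no constants for lens model '%s' (formula %s)", m, engine$formula_id
      ), call. = FALSE)
    }
    vals <- entry[fields]
    bad <- vapply(vals, function(v) is.null(v) || !is.finite(as.numeric(v)), TRUE)
    if (any(bad)) {
      stop(sprintf(
        "constant '%s' missing for formula %s, lens model '%s'",
        paste(fields[bad], collapse = ","), engine$formula_id, m
      ), call. = FALSE)
    }
    vapply(vals, as.numeric, 0)
  })
  names(per_model) <- models
  idx <- match(iol_model, models)
  out <- lapply(seq_along(fields), function(j) {
    vapply(idx, function(i) per_model[[i]][j], 0)
  })
  names(out) <- fields
  out
}

#' Predicted postoperative refraction under a formula
#'
#' Composes corneal power, the engine's ELP model, the axial-length
#' adjustment and the vergence chain for every eye of a cohort.
#'
#' @param engine A [formula_engine()].
#' @param cohort A cohort data frame (see [read_cohort()]) or any data frame
#'   with columns `axial_length`, `corneal_radius`, `acd`, `iol_model`,
#'   `iol_power`.
#' @param constants Per-lens-model constants map, as returned by
#'   [optimize_constants()] or [read_constants()].
#' @return Predicted spherical-equivalent refraction per eye, diopters.
#' @export
predict_refraction <- function(engine, cohort, constants) {
  stopifnot(inherits(engine, "formula_engine"))
  const <- resolve_constants(engine, cohort$iol_model, constants)
  K <- corneal_power(cohort$corneal_radius, engine$keratometric_index_constant)
  d <- engine_elp(
    engine, cohort$axial_length, cohort$corneal_radius, cohort$acd, const
  ) + engine$elp_shift
  vergence_chain(
    K, d, optical_axial_length(engine, cohort$axial_length),
    cohort$iol_power,
    n = engine$n_aqueous, vertex = engine$vertex_distance
  )
}

#' Solve the IOL power achieving a target refraction
#'
#' Closed-form inverse of the vergence chain:
#' `z = target/(1 - (V/1000)*target)`, `V_c = z + K`, `f_c = 1000*n/V_c`,
#' `P = 1000*n/(AL_opt - d) - 1000*n/(f_c - d)`. The round trip through
#' [predict_refraction()] returns the target to numerical precision.
#'
#' @inheritParams predict_refraction
#' @param target Target postoperative refraction, diopters (|target| < 25).
#' @return Exact (unrounded) IOL power per eye, diopters.
#' @export
solve_iol_power <- function(engine, cohort, constants, target = 0) {
  stopifnot(inherits(engine, "formula_engine"))
  if (any(abs(target) >= 25)) {
    stop("target refraction out of physical range (|target| < 25 D)",
      call. = FALSE
    )
  }
  const <- resolve_constants(engine, cohort$iol_model, constants)
  K <- corneal_power(cohort$corneal_radius, engine$keratometric_index_constant)
  d <- engine_elp(
    engine, cohort$axial_length, cohort$corneal_radius, cohort$acd, const
  ) + engine$elp_shift
  al_opt <- optical_axial_length(engine, cohort$axial_length)
  solve_power_chain(K, d, al_opt, target,
    n = engine$n_aqueous, vertex = engine$vertex_distance
  )
}

# As predict_refraction, but with the ELP clamped into [0.5, AL_opt - 2] mm
# so that objective evaluations at extreme constants stay defined during
# bracket expansion; no clamping is active near the optimum for plausible
# biometry. Internal (constant optimization only).
predict_refraction_bounded <- function(engine, cohort, constants) {
  const <- resolve_constants(engine, cohort$iol_model, constants)
  K <- corneal_power(cohort$corneal_radius, engine$keratometric_index_constant)
  al_opt <- optical_axial_length(engine, cohort$axial_length)
  d <- engine_elp(
    engine, cohort$axial_length, cohort$corneal_radius, cohort$acd, const
  ) + engine$elp_shift
  d <- pmin(pmax(d, 0.5), al_opt - 2)
  vergence_chain(K, d, al_opt, cohort$iol_power,
    n = engine$n_aqueous, vertex = engine$vertex_distance
  )
}

# Inverse chain on raw optical quantities; shared with the synthetic
# generator's truth model. Internal.
solve_power_chain <- function(K, d, al_opt, target, n = 1.336, vertex = 12) {
  z <- target / (1 - (vertex / 1000) * target)
  v_c <- z + K
  f_c <- 1000 * n / v_c
  if (any(f_c <= d)) {
    stop("target refraction unreachable: corneal focal plane inside ELP",
      call. = FALSE
    )
  }
  1000 * n / (al_opt - d) - 1000 * n / (f_c - d)
}

#' Mean-offset correction of externally supplied predictions
#'
#' Subtracts the training-set mean prediction error (predicted minus
#' observed) from a set of test predictions, so that the corrected training
#' predictions have exactly zero mean error. This is the standard handling
#' for a formula whose internal constant cannot be optimized directly
#' (e.g. predictions obtained from an external calculator).
#'
#' @param test_pred Predicted refractions to correct, diopters.
#' @param train_pred Training-set predictions from the same method, diopters.
#' @param train_obs Observed training-set refractions, diopters.
#' @return Corrected `test_pred` (same length).
#' @examples
#' mean_offset_correct(1.0, c(0.5, 0.5), c(0, 0))  # 0.5
#' @export
mean_offset_correct <- function(test_pred, train_pred, train_obs) {
  if (length(train_pred) == 0L) stop("empty training set", call. = FALSE)
  if (length(train_pred) != length(train_obs)) {
    stop("training predictions and observations differ in length", call. = FALSE)
  }
  test_pred - mean(train_pred - train_obs)
}
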