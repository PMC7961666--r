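test_that("corneal power is the keratometric numerator over the radius", {
  expect_equal(corneal_power(7.5, 337.5), 45.0)
  expect_equal(corneal_power(7.5, 331.5), 44.2)
  expect_equal(corneal_power(6.75, 337.5), 50.0)
  expect_error(corneal_power(0), "positive")
  expect_error(corneal_power(-7.5), "positive")
})

test_that("SRK/T ELP matches hand evaluation and is linear in A", {
  # hand evaluation of the sub-expressions for AL 23.5, r 7.7, A 118.4:
  # K = 43.83117, LCOR = 23.5, Cw = 12.61227, H = 3.28152, ELP = 5.15949
  expect_equal(elp_srkt(23.5, 7.7, 118.4), 5.159, tolerance = 1e-3)
  # long-eye branch is nearly continuous at the LCOR boundary (the jump is
  # ~0.011 mm at r = 7.6, shrinks with flatter corneas, and grows sharply
  # only where the corneal-height square root approaches its clamp)
  for (r in seq(7.2, 8.8, by = 0.4)) {
    expect_lt(abs(elp_srkt(24.2, r, 119) - elp_srkt(24.2 + 1e-9, r, 119)), 0.02)
  }
  expect_lt(abs(elp_srkt(24.2, 8.0, 119) - elp_srkt(24.2 + 1e-9, 8.0, 119)), 0.01)
  # exactly linear in A with slope 0.62467
  expect_equal(
    elp_srkt(23.5, 7.7, 119.4) - elp_srkt(23.5, 7.7, 118.4), 0.62467
  )
  expect_equal(
    elp_srkt(26.1, 8.0, 121.0) - elp_srkt(26.1, 8.0, 118.0), 3 * 0.62467
  )
})

test_that("Holladay 1 ELP caps the anterior segment size and is additive in SF", {
  # AL 26: 12.5*26/23.45 = 13.859 > 13.5, so AG caps at 13.5
  r <- 7.7
  expect_equal(
    elp_holladay1(26, r, 1.5),
    0.56 + r - sqrt(r^2 - 13.5^2 / 4) + 1.5
  )
  # hand evaluation at AL 23.5, r 7.7, SF 1.5: AG = 12.52665, ELP = 5.28090
  ag <- 12.5 * 23.5 / 23.45
  expect_equal(
    elp_holladay1(23.5, 7.7, 1.5),
    0.56 + 7.7 - sqrt(7.7^2 - ag^2 / 4) + 1.5
  )
  expect_equal(elp_holladay1(23.5, 7.7, 2.5) - elp_holladay1(23.5, 7.7, 1.5), 1)
})

test_that("Hoffer Q ELP follows the branch, clamp and degree-tangent rules", {
  # tan(45 deg) = 1 and the quartic term vanishes at AL 23.5
  expect_equal(elp_hofferq(23.5, 45, 5), 5.00834)
  # AL = 23 exactly uses the short-eye branch (M = +1, G = 28)
  tand <- function(x) tan(x * pi / 180)
  expect_equal(
    elp_hofferq(23, 44, 5.6),
    5.6 + 0.3 * (23 - 23.5) + tand(44)^2 +
      0.1 * 1 * (23.5 - 23)^2 * tand(0.1 * (28 - 23)^2) - 0.99166
  )
  # axial length clamped to 31 mm
  expect_equal(elp_hofferq(35, 44, 5.6), elp_hofferq(31, 44, 5.6))
  expect_equal(elp_hofferq(16, 44, 5.6), elp_hofferq(18.5, 44, 5.6))
})

test_that("Haigis ELP is the linear predictor, with the standard A-derived start", {
  expect_equal(elp_haigis(3.10, 23.5, -1.72, 0.277, 0.260), 5.2487)
  expect_equal(elp_haigis(2.8, 24.0, 1.5, 0, 0), 1.5)
  init <- haigis_constants_from_A(118.4)
  expect_equal(init$a0, 0.62467 * 118.4 - 72.434)
  expect_equal(init$a0, 1.52692, tolerance = 1e-5)
  expect_equal(init$a1, 0.4)
  expect_equal(init$a2, 0.1)
})

test_that("vergence chain reproduces the worked SRK/T eye", {
  # AL 23.5, r 7.7, A 118.4, P 21: K 43.83117, AL_opt 23.680145, d 5.15948
  K <- 337.5 / 7.7
  al_opt <- 23.5 + 0.65696 - 0.02029 * 23.5
  d <- elp_srkt(23.5, 7.7, 118.4)
  expect_equal(vergence_chain(K, d, al_opt, 21), -1.144, tolerance = 1e-3)
  eng <- formula_engine("srkt")
  eye <- eye_grid(1)
  eye$axial_length <- 23.5
  eye$corneal_radius <- 7.7
  eye$iol_power <- 21
  expect_equal(
    predict_refraction(eng, eye, fixed_constants("YP2.2", A = 118.4)),
    -1.144,
    tolerance = 1e-3
  )
})

test_that("chain agrees with the independently derived closed form to 1e-8", {
  set.seed(11)
  al <- runif(1000, 20, 30)
  r <- runif(1000, 6.8, 8.8)
  p <- runif(1000, 5, 34)
  d <- elp_srkt(al, r, 119.2)
  al_opt <- al + 0.65696 - 0.02029 * al
  chain <- vergence_chain(337.5 / r, d, al_opt, p)
  oracle <- srkt_closed_form(al, r, 119.2, p)
  expect_lt(max(abs(chain - oracle)), 1e-8)
})

test_that("chain collapses to a single thin lens as the ELP goes to zero", {
  K <- 43.5
  al_opt <- 23.9
  p <- 20
  lim <- vergence_chain(K, 1e-9, al_opt, p)
  z <- 1000 * 1.336 / al_opt - p - K
  expect_equal(lim, z / (1 + 0.012 * z), tolerance = 1e-6)
})

test_that("chain rejects unphysical configurations", {
  expect_error(vergence_chain(43, 24, 23.7, 20), "retina")
  expect_error(vergence_chain(43, -1, 23.7, 20), "positive")
  # IOL power equal to the retinal vergence has no finite focal length
  zret <- 1000 * 1.336 / (23.7 - 5)
  expect_error(vergence_chain(43, 5, 23.7, zret), "unphysical")
})

test_that("refraction falls with implanted power and rises with lens depth", {
  eyes <- eye_grid(100)
  const <- fixed_constants("YP2.2")
  for (f in c("srkt", "holladay1", "hofferq", "haigis")) {
    eng <- formula_engine(f)
    base <- predict_refraction(eng, eyes, const)
    up <- eyes
    up$iol_power <- up$iol_power + 1
    expect_true(all(predict_refraction(eng, up, const) < base),
      label = sprintf("%s: refraction decreases in P", f)
    )
  }
  # a more posterior lens is effectively weaker: hyperopic shift with d
  d <- seq(3, 6.5, by = 0.25)
  ref <- vergence_chain(43.8, d, 23.68, 21)
  expect_true(all(diff(ref) > 0))
})

test_that("solve_iol_power inverts predict_refraction to 1e-9 for all engines", {
  eyes <- small_cohort(n_patients = 60, seed = 4)
  const <- fixed_constants(unique(eyes$iol_model))
  targets <- seq(-2.5, 0.5, length.out = nrow(eyes))
  for (f in c("srkt", "holladay1", "hofferq", "haigis")) {
    eng <- formula_engine(f)
    p <- solve_iol_power(eng, eyes, const, target = targets)
    eyes2 <- eyes
    eyes2$iol_power <- p
    expect_lt(max(abs(predict_refraction(eng, eyes2, const) - targets)), 1e-9)
  }
  # the worked eye: target -1.144 needs ~21 D
  eye <- eye_grid(1)
  eye$axial_length <- 23.5
  eye$corneal_radius <- 7.7
  p <- solve_iol_power(
    formula_engine("srkt"), eye, fixed_constants("YP2.2", A = 118.4),
    target = -1.143945
  )
  expect_equal(p, 21.0, tolerance = 1e-3)
  # more myopic targets need more power
  p0 <- solve_iol_power(formula_engine("srkt"), eye, fixed_constants("YP2.2"), 0)
  p1 <- solve_iol_power(formula_engine("srkt"), eye, fixed_constants("YP2.2"), -1)
  expect_gt(p1, p0)
})

test_that("missing constants raise a configuration error naming formula and lens", {
  eye <- eye_grid(1)
  const <- list("YP2.2" = list(A = 119.2)) # no SF
  expect_silent(predict_refraction(formula_engine("srkt"), eye, const))
  expect_error(
    predict_refraction(formula_engine("holladay1"), eye, const),
    "SF.*holladay1.*YP2.2"
  )
  expect_error(
    predict_refraction(formula_engine("srkt"), eye, list()),
    "YP2.2"
  )
})

test_that("mean-offset correction zeroes the training mean error exactly", {
  expect_equal(mean_offset_correct(1.0, c(0.5, 0.5), c(0, 0)), 0.5)
  # zero training error leaves predictions unchanged
  expect_equal(mean_offset_correct(c(1, 2), c(0.3, -0.3), c(0.3, -0.3)), c(1, 2))
  set.seed(9)
  train_pred <- rnorm(50)
  train_obs <- rnorm(50)
  corrected <- mean_offset_correct(train_pred, train_pred, train_obs)
  expect_lt(abs(mean(corrected - train_obs)), 1e-12)
  expect_error(mean_offset_correct(1, numeric(0), numeric(0)), "empty")
  expect_error(mean_offset_correct(1, 1:3, 1:2), "length")
})
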