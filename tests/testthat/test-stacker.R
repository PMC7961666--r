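test_that("standardizer centers and scales with the population convention", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  std <- fit_standardizer(x)
  xs <- apply_standardizer(std, x)
  expect_equal(xs[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(xs^2)) - 1)), 1e-9)
  # invert: x = xs * sd + mean
  back <- sweep(sweep(xs, 2, std$sd, "*"), 2, std$mean, "+")
  expect_equal(back, x, ignore_attr = TRUE)
  expect_error(fit_standardizer(cbind(a = c(1, 1, 1), b = 1:3)), "zero-variance.*a")
})

test_that("feature assembly composes formula predictions and per-lens constants", {
  co <- small_cohort(n_patients = 40, seed = 10)
  const <- optimize_constants(co, min_eyes = 5)
  fx <- assemble_features(co, const,
    features = c("axial_length", "formula_prediction"), base_formula = "srkt"
  )
  expect_equal(dim(fx$x), c(nrow(co), 2))
  expect_equal(
    fx$x[, "formula_prediction"],
    predict_refraction(formula_engine("srkt"), co, const)
  )
  expect_equal(fx$y, co$postop_se)

  # different lens models carry different optimized constants
  fx2 <- assemble_features(co, const, features = "iol_constant")
  by_model <- tapply(fx2$x[, 1], co$iol_model, unique)
  expect_gt(length(unique(unlist(by_model))), 1)

  # the six-variable explanatory set of the final model assembles intact
  final <- c(
    "axial_length", "corneal_radius", "acd", "lens_thickness",
    "iol_power", "formula_prediction"
  )
  expect_equal(colnames(assemble_features(co, const, features = final)$x), final)

  co$postop_se[3] <- NA
  expect_error(assemble_features(co, const), co$eye_id[3], fixed = TRUE)
  expect_silent(assemble_features(co, const, require_target = FALSE))
  expect_error(assemble_features(co, const, features = "iol_constants"), "unknown")
})

test_that("the base formula with the dominant signal is selected", {
  co <- small_cohort(n_patients = 150, seed = 11)
  const <- optimize_constants(co)
  # rebuild the outcome as a noisy monotone function of the SRK/T prediction
  srkt_pred <- predict_refraction(formula_engine("srkt"), co, const)
  set.seed(42)
  co$postop_se <- 1.3 * srkt_pred - 0.1 + rnorm(nrow(co), 0, 0.03)
  sel <- select_base_formula(co, const)
  expect_equal(sel$formula_id, "srkt")
  expect_true(all(sel$importance >= 0))
  expect_equal(which.max(sel$importance), c(srkt = 1))
  # deterministic: same inputs, same answer
  expect_identical(sel, select_base_formula(co, const))
})

test_that("subset selection finds the informative feature and reports all importances", {
  co <- small_cohort(n_patients = 120, seed = 12)
  const <- optimize_constants(co)
  set.seed(7)
  co$postop_se <- -0.3 + 0.5 * (co$axial_length - 24) + rnorm(nrow(co), 0, 0.1)
  cands <- c("axial_length", "wtw", "age")
  rep <- select_feature_subset(co, const,
    base_formula = "srkt", candidates = cands, cv_folds = 5, seed = 2
  )
  expect_true("axial_length" %in% rep$best_subset)
  expect_named(rep$importance, cands)
  expect_true(all(rep$importance >= 0))
  expect_equal(nrow(rep$results), 2^3 - 1)
  # pure-noise additions do not beat the informative subset by > 1 SE
  al_row <- rep$results[rep$results$subset == "axial_length", ]
  best_row <- rep$results[order(rep$results$mae)[1], ]
  expect_gt(best_row$mae, al_row$mae - al_row$se)
  # reproducible fold assignment
  rep2 <- select_feature_subset(co, const,
    base_formula = "srkt", candidates = cands, cv_folds = 5, seed = 2
  )
  expect_identical(rep$results, rep2$results)
  expect_error(
    select_feature_subset(co[1:20, ], const, candidates = cands),
    "too few"
  )
})

test_that("a one-point grid is a direct fit, and grids must be non-empty", {
  co <- small_cohort(n_patients = 80, seed = 13)
  const <- optimize_constants(co)
  fx <- assemble_features(co, const)
  std <- fit_standardizer(fx$x)
  xs <- apply_standardizer(std, fx$x)
  grid <- data.frame(eta = 0.1, nrounds = 50, max_depth = 3)
  m <- fit_regressor("gbr", xs, fx$y, grid = grid, seed = 1)
  expect_equal(m$hyperparameters$nrounds, 50)
  direct <- iolstack:::fit_xgb(xs, fx$y, eta = 0.1, max_depth = 3, nrounds = 50)
  expect_equal(
    iolstack:::predict_one("gbr", m$fit, xs),
    iolstack:::predict_xgb(direct, xs)
  )
  expect_error(fit_regressor("gbr", xs, fx$y, grid = data.frame()), "empty")
})

test_that("svr and gbr fits are invariant to training row order", {
  co <- small_cohort(n_patients = 60, seed = 14)
  const <- optimize_constants(co)
  fx <- assemble_features(co, const)
  std <- fit_standardizer(fx$x)
  xs <- apply_standardizer(std, fx$x)
  set.seed(3)
  perm <- sample(nrow(xs))
  for (kind in c("svr", "gbr")) {
    grid <- switch(kind,
      svr = data.frame(cost = 10, epsilon = 0.1, gamma = 0.1),
      gbr = data.frame(eta = 0.1, nrounds = 50, max_depth = 3)
    )
    m1 <- fit_regressor(kind, xs, fx$y, grid = grid, seed = 1)
    m2 <- fit_regressor(kind, xs[perm, ], fx$y[perm], grid = grid, seed = 1)
    expect_lt(
      max(abs(
        iolstack:::predict_one(kind, m1$fit, xs) -
          iolstack:::predict_one(kind, m2$fit, xs)
      )), 1e-9
    )
  }
  # the forest is deterministic for repeated fits on identical data
  g <- data.frame(num_trees = 50, max_depth = 0)
  r1 <- fit_regressor("rfr", xs, fx$y, grid = g, seed = 1)
  r2 <- fit_regressor("rfr", xs, fx$y, grid = g, seed = 1)
  expect_identical(
    iolstack:::predict_one("rfr", r1$fit, xs),
    iolstack:::predict_one("rfr", r2$fit, xs)
  )
})

test_that("the NN ensemble averages its members and is seed-deterministic", {
  co <- small_cohort(n_patients = 60, seed = 15)
  const <- optimize_constants(co)
  fx <- assemble_features(co, const)
  std <- fit_standardizer(fx$x)
  xs <- apply_standardizer(std, fx$x)

  one <- fit_nn_ensemble(xs, fx$y, n_repeats = 1, seed = 4)
  expect_length(one$fit, 1)
  expect_equal(
    iolstack:::predict_members(one, xs),
    as.numeric(stats::predict(one$fit[[1]], xs))
  )

  ens <- fit_nn_ensemble(xs, fx$y, n_repeats = 5, seed = 4)
  expect_length(ens$fit, 5)
  member_preds <- vapply(
    ens$fit, function(m) as.numeric(stats::predict(m, xs)),
    numeric(nrow(xs))
  )
  expect_equal(iolstack:::predict_members(ens, xs), rowMeans(member_preds))

  ens2 <- fit_nn_ensemble(xs, fx$y, n_repeats = 5, seed = 4)
  expect_identical(
    iolstack:::predict_members(ens, xs),
    iolstack:::predict_members(ens2, xs)
  )
})

test_that("stacker predictions are pure functions of the cohort", {
  co <- small_cohort(n_patients = 120, seed = 16)
  sp <- split_patientwise(co, n_test = 30, seed = 2)
  const <- optimize_constants(sp$train)
  m <- train_stacker("rfr", sp$train, const,
    grid = data.frame(num_trees = 300, max_depth = 0), seed = 5
  )
  p1 <- predict_stacker(m, sp$test, const)
  expect_length(p1, 30)
  expect_identical(p1, predict_stacker(m, sp$test, const))
  expect_identical(predict_stacker(m, sp$test[0, ], const), numeric(0))
  # unlimited-depth forest memorizes its training data well below noise level
  expect_lt(
    mean(abs(predict_stacker(m, sp$train, const) - sp$train$postop_se)),
    0.25
  )
  # lens model without constants is rejected
  stranger <- sp$test
  stranger$iol_model <- "UNSEEN"
  expect_error(predict_stacker(m, stranger, const), "UNSEEN")
})
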