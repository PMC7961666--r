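#' Candidate explanatory variables for the stacked predictor
#'
#' The nine candidates: age, axial length, corneal radius, anterior chamber
#' depth, lens thickness, white-to-white, the optimized IOL constant of the
#' base formula (per lens model), implanted IOL power, and the base
#' formula's predicted refraction.
#'
#' @return Character vector of candidate ids.
#' @export
feature_candidates <- function() {
  c(
    "age", "axial_length", "corneal_radius", "acd", "lens_thickness",
    "wtw", "iol_constant", "iol_power", "formula_prediction"
  )
}

# scalar constant of a formula per lens model (haigis -> a0). Internal.
scalar_constant_of <- function(formula_id, constants, iol_model) {
  field <- switch(formula_id,
    srkt = "A", holladay1 = "SF", hofferq = "pACD", haigis = "a0"
  )
  vapply(iol_model, function(m) {
    v <- constants[[m]][[field]]
    if (is.null(v) || !is.finite(as.numeric(v))) {
      stop(sprintf(
        "constant '%s' missing for formula %s, lens model '%s'",
        field, formula_id, m
      ), call. = FALSE)
    }
    as.numeric(v)
  }, 0, USE.NAMES = FALSE)
}

#' Assemble the feature table and target vector for the stacker
#'
#' One row per eye. `formula_prediction` is the base formula's predicted
#' refraction under the supplied constants; `iol_constant` is the base
#' formula's optimized scalar constant for the eye's lens model (A, SF,
#' pACD, or a0 for Haigis). The target is the observed postoperative
#' spherical equivalent.
#'
#' @param cohort A cohort data frame.
#' @param constants Per-lens-model constants map.
#' @param features Character subset of [feature_candidates()].
#' @param base_formula Formula id feeding `formula_prediction` and
#'   `iol_constant`.
#' @param require_target Error on missing `postop_se` (training mode).
#' @return List with `x` (numeric matrix) and `y` (targets, or NULL when
#'   `require_target = FALSE` and observations are absent).
#' @export
assemble_features <- function(cohort, constants,
                              features = feature_candidates(),
                              base_formula = "srkt",
                              require_target = TRUE) {
  bad <- setdiff(features, feature_candidates())
  if (length(bad) > 0) {
    stop(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")),
      call. = FALSE
    )
  }
  if (length(features) == 0L) stop("empty feature set", call. = FALSE)
  n <- nrow(cohort)
  cols <- lapply(features, function(f) {
    switch(f,
      formula_prediction = predict_refraction(
        formula_engine(base_formula), cohort, constants
      ),
      iol_constant = scalar_constant_of(base_formula, constants, cohort$iol_model),
      cohort[[f]]
    )
  })
  x <- matrix(unlist(cols), nrow = n, dimnames = list(NULL, features))
  y <- NULL
  if (require_target) {
    if (is.null(cohort$postop_se) || anyNA(cohort$postop_se)) {
      miss <- if (is.null(cohort$postop_se)) {
        cohort$eye_id
      } else {
        cohort$eye_id[is.na(cohort$postop_se)]
      }
      stop(sprintf(
        "missing postop_se for eye(s): %s",
        paste(utils::head(miss, 5), collapse = ", ")
      ), call. = FALSE)
    }
    y <- cohort$postop_se
  }
  list(x = x, y = y)
}

#' Feature standardization (training-set mean 0, sd 1)
#'
#' Uses the population standard deviation (divide by n). Test data are
#' transformed with the training statistics only.
#'
#' @param x Numeric training feature matrix.
#' @return A `standardizer` with per-feature `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  if (any(s <= 0)) {
    stop(sprintf(
      "zero-variance feature(s): %s",
      paste(colnames(x)[s <= 0], collapse = ", ")
    ), call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param stats A fitted `standardizer`.
#' @export
apply_standardizer <- function(stats, x) {
  sweep(sweep(x[, names(stats$mean), drop = FALSE], 2, stats$mean), 2, stats$sd, "/")
}

# deterministic xgboost regressor used as the gradient-boosted selector and
# as the gbr model kind. Internal.
fit_xgb <- function(x, y, eta = 0.1, max_depth = 3, nrounds = 100) {
  xgboost::xgb.train(
    params = list(
      eta = eta, max_depth = max_depth, objective = "reg:squarederror",
      nthread = 1, tree_method = "exact", subsample = 1, colsample_bytree = 1
    ),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

predict_xgb <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

xgb_gain <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  gain[imp$Feature] <- imp$Gain
  gain
}

make_folds <- function(n, k, seed) {
  set_seed(seed)
  sample(rep_len(seq_len(k), n))
}

cv_mae <- function(x, y, folds, fit_fun, predict_fun) {
  k <- max(folds)
  maes <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- fit_fun(x[tr, , drop = FALSE], y[tr])
    mean(abs(predict_fun(m, x[!tr, , drop = FALSE]) - y[!tr]))
  }, 0)
  c(mae = mean(maes), se = stats::sd(maes) / sqrt(k))
}

#' Choose the base formula by gradient-boosted feature importance
#'
#' Fits the gradient-boosted selector on the biometric candidates plus the
#' predicted refractions of all four conventional formulas and returns the
#' formula whose prediction carries the largest importance (gain). Ties
#' break to the earlier id in (srkt, holladay1, hofferq, haigis).
#'
#' @param train Training cohort with observed outcomes.
#' @param constants Constants map covering all four formulas.
#' @param selector List of selector hyperparameters
#'   (`eta`, `max_depth`, `nrounds`).
#' @return List with `formula_id` and the named `importance` of the four
#'   formula-prediction columns.
#' @export
select_base_formula <- function(train, constants,
                                selector = list(eta = 0.1, max_depth = 3, nrounds = 200)) {
  formulas <- c("srkt", "holladay1", "hofferq", "haigis")
  base_feats <- c(
    "age", "axial_length", "corneal_radius", "acd",
    "lens_thickness", "wtw", "iol_power"
  )
  x <- as.matrix(as.data.frame(train)[, base_feats])
  preds <- vapply(
    formulas,
    function(f) predict_refraction(formula_engine(f), train, constants),
    numeric(nrow(train))
  )
  colnames(preds) <- paste0("pred_", formulas)
  x <- cbind(x, preds)
  if (anyNA(train$postop_se)) {
    stop("observed postop_se required to select the base formula", call. = FALSE)
  }
  fit <- fit_xgb(x, train$postop_se,
    eta = selector$eta, max_depth = selector$max_depth, nrounds = selector$nrounds
  )
  gain <- xgb_gain(fit, colnames(x))[paste0("pred_", formulas)]
  names(gain) <- formulas
  list(formula_id = formulas[which.max(gain)], importance = gain)
}

#' Exhaustive feature-subset selection by cross-validated MAE
#'
#' Evaluates every non-empty subset of the candidate features by
#' `cv_folds`-fold cross-validated mean absolute error of the
#' gradient-boosted regressor, with a shared fold assignment. The winning
#' subset (lowest CV MAE; ties to fewer features, then lexical order) is
#' reused unchanged by all four model kinds.
#'
#' @param train Training cohort.
#' @param constants Constants map.
#' @param base_formula Formula feeding `formula_prediction`/`iol_constant`.
#' @param candidates Candidate ids (default all nine).
#' @param cv_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param selector Gradient-boosted selector hyperparameters.
#' @return A `feature_selection_report`: per-candidate `importance`
#'   (gain, all >= 0), per-subset `results` (subset, size, mae, se),
#'   `best_subset`, `base_formula`.
#' @export
select_feature_subset <- function(train, constants, base_formula = "srkt",
                                  candidates = feature_candidates(),
                                  cv_folds = 5, seed = 0,
                                  selector = list(eta = 0.3, max_depth = 3, nrounds = 60)) {
  n <- nrow(train)
  if (n < cv_folds * 10) {
    stop(sprintf("too few training eyes (%d) for %d-fold selection", n, cv_folds),
      call. = FALSE
    )
  }
  full <- assemble_features(train, constants,
    features = candidates, base_formula = base_formula
  )
  folds <- make_folds(n, cv_folds, seed)
  fit_fun <- function(x, y) {
    fit_xgb(x, y,
      eta = selector$eta, max_depth = selector$max_depth,
      nrounds = selector$nrounds
    )
  }
  importance <- xgb_gain(fit_fun(full$x, full$y), candidates)

  subsets <- lapply(seq_len(2^length(candidates) - 1), function(mask) {
    candidates[as.logical(bitwAnd(mask, 2^(seq_along(candidates) - 1)))]
  })
  res <- vapply(subsets, function(sub) {
    cv_mae(full$x[, sub, drop = FALSE], full$y, folds, fit_fun, predict_xgb)
  }, c(mae = 0, se = 0))
  results <- data.frame(
    subset = vapply(subsets, paste, "", collapse = "+"),
    size = lengths(subsets),
    mae = res["mae", ],
    se = res["se", ]
  )
  best <- order(results$mae, results$size)[1]
  structure(list(
    importance = importance,
    results = results,
    best_subset = subsets[[best]],
    base_formula = base_formula,
    cv_folds = cv_folds, seed = seed
  ), class = "feature_selection_report")
}

#' Default hyperparameter grids for the stacker regressors
#'
#' @param kind `"svr"`, `"rfr"` or `"gbr"`.
#' @return Data frame, one row per grid point.
#' @export
default_grid <- function(kind = c("svr", "rfr", "gbr")) {
  kind <- match.arg(kind)
  switch(kind,
    svr = expand.grid(
      cost = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1),
      gamma = c(0.01, 0.1, 1)
    ),
    rfr = expand.grid(num_trees = c(100, 300), max_depth = c(0, 4, 8)),
    gbr = expand.grid(
      eta = c(0.01, 0.1), nrounds = c(100, 500), max_depth = c(2, 3, 4)
    )
  )
}

fit_one <- function(kind, x, y, hp, seed) {
  switch(kind,
    svr = e1071::svm(
      x = x, y = y, type = "eps-regression", kernel = "radial",
      cost = hp$cost, epsilon = hp$epsilon, gamma = hp$gamma, scale = FALSE
    ),
    rfr = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = hp$num_trees,
      max.depth = if (hp$max_depth == 0) NULL else hp$max_depth,
      seed = seed, num.threads = 1
    ),
    gbr = fit_xgb(x, y,
      eta = hp$eta, max_depth = hp$max_depth, nrounds = hp$nrounds
    )
  )
}

predict_one <- function(kind, model, x) {
  switch(kind,
    svr = as.numeric(stats::predict(model, x)),
    rfr = stats::predict(model, as.data.frame(x), num.threads = 1)$predictions,
    gbr = predict_xgb(model, x)
  )
}

#' Grid-search-tuned regressor (SVR, random forest, or gradient boosting)
#'
#' Exhaustive search over the hyperparameter grid by `cv_folds`-fold
#' cross-validated MAE, then a refit on the full training data at the
#' winning point (ties break to the earlier grid row).
#'
#' @param kind `"svr"`, `"rfr"` or `"gbr"`.
#' @param x Standardized feature matrix.
#' @param y Target refractions, diopters.
#' @param grid Hyperparameter grid (data frame); see [default_grid()].
#' @param cv_folds Folds (default 5).
#' @param seed Seed for fold assignment and the forest.
#' @return A `trained_stacker` (without standardizer/feature metadata;
#'   see [train_stacker()] for the full pipeline object).
#' @export
fit_regressor <- function(kind = c("svr", "rfr", "gbr"), x, y,
                          grid = NULL, cv_folds = 5, seed = 0) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  if (nrow(grid) == 1L) {
    cv <- cbind(grid, mae = NA_real_, se = NA_real_)
    best <- 1L
  } else {
    folds <- make_folds(nrow(x), cv_folds, seed)
    res <- vapply(seq_len(nrow(grid)), function(i) {
      hp <- grid[i, , drop = FALSE]
      cv_mae(
        x, y, folds,
        function(xx, yy) fit_one(kind, xx, yy, hp, seed),
        function(m, xx) predict_one(kind, m, xx)
      )
    }, c(mae = 0, se = 0))
    cv <- cbind(grid, mae = res["mae", ], se = res["se", ])
    best <- which.min(cv$mae)
  }
  fit <- fit_one(kind, x, y, grid[best, , drop = FALSE], seed)
  structure(list(
    kind = kind, fit = fit,
    hyperparameters = as.list(grid[best, , drop = FALSE]),
    cv = cv, cv_folds = cv_folds, seed = seed
  ), class = "trained_stacker")
}

#' Seed-averaged neural-network ensemble
#'
#' Trains `n_repeats` single-hidden-layer networks (nnet; linear output,
#' squared-error loss, weight decay, BFGS up to `maxit` iterations) that
#' differ only by their weight-initialization seed; the ensemble prediction
#' is the arithmetic mean of the members. A member whose fit is non-finite
#' is retrained once with a fresh seed, then errors.
#'
#' @param x Standardized feature matrix.
#' @param y Target refractions, diopters.
#' @param n_repeats Ensemble size (default 30).
#' @param seeds Optional explicit seeds (length `n_repeats`; default: a
#'   block of `n_repeats` consecutive seeds disjoint between base seeds).
#' @param seed Base seed when `seeds` is not given.
#' @param size Hidden units (default 8).
#' @param decay Weight decay (default 0.01).
#' @param maxit Optimizer iteration cap (default 200).
#' @return A `trained_stacker` of kind `"nn"` whose `fit` is the member list.
#' @export
fit_nn_ensemble <- function(x, y, n_repeats = 30, seeds = NULL, seed = 0,
                            size = 8, decay = 0.01, maxit = 200) {
  # member seeds from disjoint blocks per base seed, so ensembles trained at
  # different base seeds share no members
  if (is.null(seeds)) seeds <- seed * 100000 + seq_len(n_repeats) - 1
  stopifnot(length(seeds) == n_repeats)
  train_member <- function(s) {
    set_seed(s)
    fit <- nnet::nnet(
      x = x, y = y, size = size, linout = TRUE, decay = decay,
      maxit = maxit, trace = FALSE, MaxNWts = 5000
    )
    if (any(!is.finite(fit$fitted.values))) NULL else fit
  }
  members <- lapply(seeds, function(s) {
    fit <- train_member(s)
    if (is.null(fit)) fit <- train_member(s + 1000003L)
    if (is.null(fit)) {
      stop(sprintf("NN member with seed %d diverged twice", s), call. = FALSE)
    }
    fit
  })
  structure(list(
    kind = "nn", fit = members,
    hyperparameters = list(
      size = size, decay = decay, maxit = maxit, n_repeats = n_repeats
    ),
    seeds = seeds
  ), class = "trained_stacker")
}

#' @export
print.trained_stacker <- function(x, ...) {
  hp <- paste(sprintf("%s=%s", names(x$hyperparameters), x$hyperparameters),
    collapse = ", "
  )
  cat(sprintf(
    "<trained_stacker %s> %s%s\n", x$kind, hp,
    if (!is.null(x$features)) {
      sprintf("  features: %s (base %s)",
        paste(x$features, collapse = "+"), x$base_formula)
    } else {
      ""
    }
  ))
  invisible(x)
}

# raw-matrix prediction shared by predict_stacker and tests. Internal.
predict_members <- function(model, x_std) {
  if (model$kind == "nn") {
    p <- vapply(model$fit, function(m) as.numeric(stats::predict(m, x_std)),
      numeric(nrow(x_std))
    )
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    rowMeans(p)
  } else {
    predict_one(model$kind, model$fit, x_std)
  }
}

#' Train a full stacked predictor on a cohort
#'
#' Convenience wrapper: assembles the features, fits the standardizer on
#' the training rows, and trains the requested model kind; the returned
#' object carries everything [predict_stacker()] needs.
#'
#' @param kind `"svr"`, `"rfr"`, `"gbr"` or `"nn"`.
#' @param train Training cohort with observed outcomes.
#' @param constants Constants map.
#' @param features Selected feature ids.
#' @param base_formula Base formula for `formula_prediction`.
#' @param grid Hyperparameter grid for svr/rfr/gbr (NULL = defaults).
#' @param cv_folds Folds for the grid search.
#' @param seed Seed (folds, forest, NN member seeds).
#' @param nn Named list of NN settings passed to [fit_nn_ensemble()]
#'   (`n_repeats`, `size`, `decay`, `maxit`).
#' @return A `trained_stacker` with standardizer and feature metadata.
#' @export
train_stacker <- function(kind = c("svr", "rfr", "gbr", "nn"),
                          train, constants,
                          features = feature_candidates(),
                          base_formula = "srkt",
                          grid = NULL, cv_folds = 5, seed = 0,
                          nn = list()) {
  kind <- match.arg(kind)
  fx <- assemble_features(train, constants,
    features = features, base_formula = base_formula
  )
  std <- fit_standardizer(fx$x)
  xs <- apply_standardizer(std, fx$x)
  model <- if (kind == "nn") {
    do.call(fit_nn_ensemble, c(list(x = xs, y = fx$y, seed = seed), nn))
  } else {
    fit_regressor(kind, xs, fx$y, grid = grid, cv_folds = cv_folds, seed = seed)
  }
  model$standardizer <- std
  model$features <- features
  model$base_formula <- base_formula
  model
}

#' Predict postoperative refraction with a trained stacker
#'
#' Assembles the model's feature set for the new cohort, applies the stored
#' training standardization, and returns predictions on the diopter scale.
#'
#' @param model A `trained_stacker` from [train_stacker()].
#' @param cohort Cohort to predict (observations not required).
#' @param constants Constants map covering every lens model present.
#' @return Predicted spherical-equivalent refraction per eye, diopters.
#' @export
predict_stacker <- function(model, cohort, constants) {
  stopifnot(inherits(model, "trained_stacker"))
  if (is.null(model$standardizer)) {
    stop("model lacks standardizer/feature metadata; train with train_stacker()",
      call. = FALSE
    )
  }
  if (nrow(cohort) == 0L) {
    return(numeric(0))
  }
  fx <- assemble_features(cohort, constants,
    features = model$features, base_formula = model$base_formula,
    require_target = FALSE
  )
  predict_members(model, apply_standardizer(model$standardizer, fx$x))
}
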