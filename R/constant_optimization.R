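#' Optimize a scalar lens constant by zeroing the mean prediction error
#'
#' Personalizes the SRK/T A constant, Holladay 1 surgeon factor, or
#' Hoffer Q pACD on a training cohort: finds the constant at which the mean
#' signed prediction error (predicted minus observed refraction) is zero.
#' A larger ELP-type constant places the lens more posteriorly, which
#' weakens its effective power and shifts every prediction hyperopically,
#' so the mean error is strictly increasing in the constant and a
#' bracketing root method applies; the bracket is expanded
#' up to +/- 10 units when it does not straddle a sign change. A
#' mean-absolute-error criterion is available behind `criterion = "mae"`
#' (golden-section minimization) but zero mean error is the default and the
#' standard personalization convention.
#'
#' @param formula_id `"srkt"`, `"holladay1"` or `"hofferq"`.
#' @param train Training cohort; every record must carry `postop_se`.
#' @param bracket Initial `c(lo, hi)` search interval for the constant;
#'   defaults per formula (A in (113, 125), SF in (-2, 5), pACD in (2, 9)).
#' @param criterion `"zero_mean_error"` (default) or `"mae"`.
#' @param tol Root tolerance on the constant.
#' @return An `optimization_result` list: `formula_id`, `iol_model`,
#'   `value`, `n_train`, `residual_mean_error`, `iterations`.
#' @export
optimize_scalar_constant <- function(formula_id = c("srkt", "holladay1", "hofferq"),
                                     train,
                                     bracket = NULL,
                                     criterion = c("zero_mean_error", "mae"),
                                     tol = 1e-10) {
  formula_id <- match.arg(formula_id)
  criterion <- match.arg(criterion)
  if (anyNA(train$postop_se)) {
    stop("every training record needs an observed postop_se", call. = FALSE)
  }
  if (is.null(bracket)) {
    bracket <- switch(formula_id,
      srkt = c(113, 125), holladay1 = c(-2, 5), hofferq = c(2, 9)
    )
  }
  engine <- formula_engine(formula_id)
  field <- engine_constant_fields(formula_id)
  models <- unique(train$iol_model)
  const_map <- function(value) {
    cl <- stats::setNames(list(value), field)
    stats::setNames(rep(list(cl), length(models)), models)
  }
  mean_err <- function(value) {
    mean(
      predict_refraction_bounded(engine, train, const_map(value)) -
        train$postop_se
    )
  }

  if (criterion == "mae") {
    obj <- function(value) {
      mean(abs(predict_refraction(engine, train, const_map(value)) - train$postop_se))
    }
    opt <- stats::optimize(obj, interval = bracket, tol = tol)
    value <- opt$minimum
    return(structure(list(
      formula_id = formula_id, iol_model = paste(models, collapse = ","),
      value = value, n_train = nrow(train),
      residual_mean_error = mean_err(value), iterations = NA_integer_
    ), class = "optimization_result"))
  }

  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- mean_err(lo)
  f_hi <- mean_err(hi)
  expand <- 0
  # mean error increases in the constant: need f(lo) < 0 < f(hi)
  while (f_lo * f_hi > 0 && expand < 10) {
    step <- max(1, hi - lo)
    if (f_lo > 0) {
      lo <- lo - step
      f_lo <- mean_err(lo)
    } else {
      hi <- hi + step
      f_hi <- mean_err(hi)
    }
    expand <- expand + 1
  }
  if (f_lo * f_hi > 0) {
    stop(sprintf(
      "no sign change of mean error for %s in [%g, %g]: %.4g and %.4g",
      formula_id, lo, hi, f_lo, f_hi
    ), call. = FALSE)
  }
  root <- stats::uniroot(mean_err, c(lo, hi),
    f.lower = f_lo, f.upper = f_hi, tol = tol
  )
  structure(list(
    formula_id = formula_id,
    iol_model = paste(models, collapse = ","),
    value = root$root,
    n_train = nrow(train),
    residual_mean_error = mean_err(root$root),
    iterations = root$iter
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  vals <- if (length(x$value) > 1) {
    paste(sprintf("%s = %.4f", names(x$value), x$value), collapse = ", ")
  } else {
    sprintf("%.4f", x$value)
  }
  cat(sprintf(
    "<optimization_result %s [%s]> %s  (n = %d, residual mean error %.2e)\n",
    x$formula_id, x$iol_model, vals, x$n_train, x$residual_mean_error
  ))
  invisible(x)
}

#' Back-solve the effective lens position from an observed refraction
#'
#' Inverts the vergence chain for the ELP `d` given corneal power, implanted
#' power and the observed refraction: with
#' `z = obs/(1 - (V/1000)*obs)` and `f_c = 1000*n/(z + K)`, `d` solves
#' `d^2 - (AL + f_c)*d + AL*f_c - 1000*n*(f_c - AL)/P = 0`.
#' The root lying in `(0, AL)` is returned; when both roots qualify the
#' anterior (smaller) root is preferred, matching the physiologic ELP range.
#'
#' @param axial_length Optical axial length, mm (for the Haigis convention
#'   this equals the measured axial length).
#' @param K Corneal power, diopters.
#' @param power Implanted IOL power, diopters (nonzero).
#' @param obs_ref Observed postoperative refraction, diopters.
#' @param n Refractive index (default 1.336).
#' @param vertex Vertex distance, mm (default 12).
#' @param strict Error on eyes with no physical root (default TRUE);
#'   otherwise those eyes return `NA`.
#' @return ELP per eye, mm (vectorized).
#' @export
back_solve_elp <- function(axial_length, K, power, obs_ref,
                           n = 1.336, vertex = 12, strict = TRUE) {
  zero_p <- abs(power) < 1e-9
  if (strict && any(zero_p)) {
    stop("IOL power must be nonzero to back-solve the ELP", call. = FALSE)
  }
  power[zero_p] <- NA_real_ # refraction carries no ELP information at P = 0
  z <- obs_ref / (1 - (vertex / 1000) * obs_ref)
  f_c <- 1000 * n / (z + K)
  b <- axial_length + f_c
  cc <- axial_length * f_c - 1000 * n * (f_c - axial_length) / power
  disc <- b^2 - 4 * cc
  ok <- !is.na(disc) & disc >= 0
  disc[is.na(disc)] <- -1
  d <- rep(NA_real_, length(b))
  sq <- sqrt(pmax(disc, 0))
  r1 <- (b - sq) / 2
  r2 <- (b + sq) / 2
  in1 <- ok & r1 > 0 & r1 < axial_length
  in2 <- ok & r2 > 0 & r2 < axial_length
  d[in2] <- r2[in2]
  d[in1] <- r1[in1] # anterior root preferred when both qualify
  if (strict && anyNA(d)) {
    stop(sprintf(
      "no physical ELP for %d of %d eyes (complex roots or root outside (0, AL))",
      sum(is.na(d)), length(d)
    ), call. = FALSE)
  }
  d
}

#' Fit the Haigis constants by ELP back-solve and least squares
#'
#' Recovers the per-lens Haigis triple from outcomes: each training eye's
#' ELP is back-solved from its observed refraction under the Haigis
#' conventions (K = 331.5/r, optical axial length = measured), then the
#' back-solved ELP is regressed on `(1, ACD, AL)` by ordinary least
#' squares. Eyes whose back-solve has no physical root are dropped with a
#' message; more than `max_failure_rate` failures is an error under
#' `strict`.
#'
#' @param train Training cohort with observed `postop_se`.
#' @param min_eyes Minimum usable eyes (default 30).
#' @param strict Escalate a high back-solve failure rate to an error.
#' @param max_failure_rate Failure-rate threshold (default 0.1).
#' @return An `optimization_result` whose `value` is `c(a0, a1, a2)`, plus
#'   `residual_sd` and `n_dropped`.
#' @export
fit_haigis_constants <- function(train, min_eyes = 30, strict = FALSE,
                                 max_failure_rate = 0.1) {
  if (anyNA(train$postop_se)) {
    stop("every training record needs an observed postop_se", call. = FALSE)
  }
  K <- corneal_power(train$corneal_radius, 331.5)
  d <- back_solve_elp(train$axial_length, K, train$iol_power, train$postop_se,
    strict = FALSE
  )
  dropped <- sum(is.na(d))
  if (dropped > 0) {
    message(sprintf("fit_haigis_constants: dropped %d eye(s) with no physical ELP", dropped))
    rate <- dropped / length(d)
    if (strict && rate > max_failure_rate) {
      stop(sprintf(
        "back-solve failure rate %.1f%% exceeds %.0f%%",
        100 * rate, 100 * max_failure_rate
      ), call. = FALSE)
    }
  }
  keep <- !is.na(d)
  if (sum(keep) < min_eyes) {
    stop(sprintf(
      "too few usable eyes (%d < %d) for Haigis regression", sum(keep), min_eyes
    ), call. = FALSE)
  }
  X <- cbind(1, train$acd[keep], train$axial_length[keep])
  if (qr(X)$rank < 3) {
    stop("rank-deficient design: ACD and axial length are collinear", call. = FALSE)
  }
  fit <- stats::lm.fit(X, d[keep])
  coefs <- stats::setNames(fit$coefficients, c("a0", "a1", "a2"))
  structure(list(
    formula_id = "haigis",
    iol_model = paste(unique(train$iol_model), collapse = ","),
    value = coefs,
    n_train = sum(keep),
    n_dropped = dropped,
    residual_mean_error = mean(fit$residuals),
    residual_sd = stats::sd(fit$residuals),
    se = sqrt(diag(chol2inv(qr.R(qr(X))) * sum(fit$residuals^2) / (sum(keep) - 3))),
    iterations = 1L
  ), class = "optimization_result")
}

#' Optimize all constants for every lens model of a training cohort
#'
#' Runs [optimize_scalar_constant()] for SRK/T, Holladay 1 and Hoffer Q and
#' [fit_haigis_constants()] per lens model, producing the constants map
#' consumed by [predict_refraction()] and [write_constants()]. Lens models
#' with fewer than `min_eyes` training eyes fall back to cohort-wide
#' constants (all eyes pooled), which mirrors how sparse lens models are
#' handled in practice.
#'
#' @param train Training cohort with observed outcomes.
#' @param formulas Formulas to optimize (default all four).
#' @param min_eyes Per-lens minimum for lens-specific optimization.
#' @return Named list by lens model: `list(A=, SF=, pACD=, a0=, a1=, a2=)`.
#' @export
optimize_constants <- function(train,
                               formulas = c("srkt", "holladay1", "hofferq", "haigis"),
                               min_eyes = 30) {
  models <- unique(train$iol_model)
  pooled <- NULL
  fit_set <- function(sub) {
    out <- list()
    if ("srkt" %in% formulas) {
      out$A <- optimize_scalar_constant("srkt", sub)$value
    }
    if ("holladay1" %in% formulas) {
      out$SF <- optimize_scalar_constant("holladay1", sub)$value
    }
    if ("hofferq" %in% formulas) {
      out$pACD <- optimize_scalar_constant("hofferq", sub)$value
    }
    if ("haigis" %in% formulas) {
      h <- fit_haigis_constants(sub, min_eyes = min(min_eyes, nrow(sub)))
      out$a0 <- unname(h$value["a0"])
      out$a1 <- unname(h$value["a1"])
      out$a2 <- unname(h$value["a2"])
    }
    out
  }
  res <- lapply(models, function(m) {
    sub <- train[train$iol_model == m, , drop = FALSE]
    if (nrow(sub) < min_eyes) {
      if (is.null(pooled)) pooled <<- fit_set(train)
      pooled
    } else {
      fit_set(sub)
    }
  })
  stats::setNames(res, models)
}
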