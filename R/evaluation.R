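#' Summarize the prediction errors of one method
#'
#' Errors follow the convention predicted minus observed, in diopters.
#' Within-threshold counts use a strict inequality (an error of exactly
#' 0.5 D does not count as "less than 0.5 D").
#'
#' @param errors Signed per-eye prediction errors, diopters.
#' @return List with `n`, `mae`, `medae`, `sd` (of signed errors), `me`
#'   (mean signed error), and `within` (named counts below 0.25/0.5/1.0 D).
#' @examples
#' summarize_errors(c(0.1, -0.3, 0.6))  # MAE 0.333, 2 of 3 within 0.5 D
#' @export
summarize_errors <- function(errors) {
  if (length(errors) == 0L) stop("no errors to summarize", call. = FALSE)
  a <- abs(errors)
  list(
    n = length(errors),
    mae = mean(a),
    medae = stats::median(a),
    sd = stats::sd(errors),
    me = mean(errors),
    within = c(
      "0.25" = sum(a < 0.25), "0.5" = sum(a < 0.5), "1.0" = sum(a < 1.0)
    )
  )
}

# Shapiro-Wilk normality p-value, robust to degenerate input and to the
# test's n <= 5000 limit (a deterministic subsample is used above it).
shapiro_p <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) {
    return(0) # degenerate: treat as non-normal
  }
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value
}

#' Paired statistical comparison of prediction methods
#'
#' Takes the absolute errors of two or more methods aligned by eye (paired
#' design). Runs (1) the Friedman test across all methods, and (2) pairwise
#' comparisons of every other method against the designated reference:
#' Wilcoxon signed-rank when Shapiro-Wilk rejects normality at 0.05 (by
#' default in either group's absolute errors; set
#' `normality_on = "differences"` to gate on the paired differences), else
#' the paired t test. Raw p-values are Bonferroni-adjusted by the number of
#' pairwise comparisons performed, capped at 1. Pairwise results are
#' reported regardless of the Friedman outcome but flagged when the
#' Friedman test is not significant at `alpha`.
#'
#' With completely tied columns the Friedman statistic is 0 and p = 1, and
#' degenerate pairwise comparisons (all differences zero) report p = 1.
#'
#' @param abs_errors Named list (or matrix with named columns) of absolute
#'   errors, one element per method, equal lengths.
#' @param reference Name of the reference method (default: first).
#' @param alpha Significance level for the Friedman flag and the normality
#'   gate (default 0.05).
#' @param normality_on `"either_group"` (default) or `"differences"`.
#' @return List with `friedman` (statistic, p, flag), `pairwise` data frame
#'   (a, b, test, raw_p, adj_p), and `n_comparisons`.
#' @export
compare_paired <- function(abs_errors, reference = NULL, alpha = 0.05,
                           normality_on = c("either_group", "differences")) {
  normality_on <- match.arg(normality_on)
  if (is.matrix(abs_errors)) {
    abs_errors <- as.data.frame(abs_errors)
  }
  abs_errors <- lapply(abs_errors, as.numeric)
  if (length(abs_errors) < 2L) stop("need at least two methods", call. = FALSE)
  lens <- lengths(abs_errors)
  if (length(unique(lens)) != 1L) {
    stop("pairing error: methods have unequal numbers of eyes", call. = FALSE)
  }
  if (lens[1] < 2L) {
    stop("need at least two paired observations per method", call. = FALSE)
  }
  if (is.null(names(abs_errors)) || any(!nzchar(names(abs_errors)))) {
    names(abs_errors) <- paste0("method", seq_along(abs_errors))
  }
  if (is.null(reference)) reference <- names(abs_errors)[1]
  if (!reference %in% names(abs_errors)) {
    stop(sprintf("reference '%s' not among the methods", reference), call. = FALSE)
  }

  m <- do.call(cbind, abs_errors)
  # Friedman; completely tied rows make the tie-corrected statistic 0/0,
  # whose limit is statistic 0, p 1
  if (all(apply(m, 1, function(r) length(unique(r)) == 1L))) {
    friedman <- list(statistic = 0, p = 1)
  } else {
    ft <- stats::friedman.test(m)
    friedman <- list(
      statistic = unname(ft$statistic),
      p = ft$p.value
    )
  }
  friedman$significant <- is.finite(friedman$p) && friedman$p <= alpha

  others <- setdiff(names(abs_errors), reference)
  n_comp <- length(others)
  rows <- lapply(others, function(b) {
    xa <- abs_errors[[b]]
    xb <- abs_errors[[reference]]
    d <- xa - xb
    if (all(d == 0)) {
      return(data.frame(
        a = b, b = reference, test = "degenerate", raw_p = 1, adj_p = 1
      ))
    }
    nonnormal <- switch(normality_on,
      either_group = shapiro_p(xa) < alpha || shapiro_p(xb) < alpha,
      differences = shapiro_p(d) < alpha
    )
    if (nonnormal) {
      p <- stats::wilcox.test(xa, xb, paired = TRUE)$p.value
      test <- "wilcoxon"
    } else {
      p <- stats::t.test(xa, xb, paired = TRUE)$p.value
      test <- "paired_t"
    }
    data.frame(a = b, b = reference, test = test, raw_p = p, adj_p = NA_real_)
  })
  pairwise <- do.call(rbind, rows)
  pairwise$adj_p <- pmin(1, pairwise$raw_p * n_comp)
  pairwise$friedman_ns <- !friedman$significant
  list(friedman = friedman, pairwise = pairwise, n_comparisons = n_comp)
}

#' Chi-squared comparison of two within-threshold proportions
#'
#' Pearson chi-squared on the 2x2 table of successes/failures, WITHOUT
#' continuity correction — the convention pinned by the worked examples
#' below. Returns the two-sided p-value.
#'
#' @param k1,n1 Successes and total of the first group.
#' @param k2,n2 Successes and total of the second group.
#' @return Two-sided p-value.
#' @examples
#' round(proportion_chi2(406, 500, 422, 500), 4)  # 0.1800
#' round(proportion_chi2(406, 500, 412, 500), 4)  # 0.6229
#' @export
proportion_chi2 <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, n1 > 0, n2 > 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: zero margin", call. = FALSE)
  }
  if (k1 * n2 == k2 * n1) {
    return(1) # identical proportions: statistic exactly 0
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Axial-length subgroup analysis
#'
#' Bins eyes into short (< 22 mm), middle (22 to < 24 mm) and long
#' (>= 24 mm) axial-length groups (left-closed bins) and reports per-bin
#' error summaries and, where at least `min_n` eyes fall in a bin, the
#' paired comparison battery.
#'
#' @param cohort Cohort the errors refer to (row-aligned with each error
#'   vector).
#' @param errors Named list of signed error vectors, one per method, each
#'   aligned with `cohort` rows.
#' @param reference Reference method for pairwise tests (default: first).
#' @param min_n Minimum bin size for running the tests (default 5).
#' @return Named list (`short`, `middle`, `long`); each bin holds `n`,
#'   per-method `methods` summaries and `tests` (NULL when skipped).
#' @export
subgroup_by_axial <- function(cohort, errors, reference = NULL, min_n = 5) {
  stopifnot(all(lengths(errors) == nrow(cohort)))
  bins <- list(
    short = cohort$axial_length < 22,
    middle = cohort$axial_length >= 22 & cohort$axial_length < 24,
    long = cohort$axial_length >= 24
  )
  lapply(bins, function(idx) {
    n <- sum(idx)
    if (n == 0L) {
      return(list(n = 0L, methods = NULL, tests = NULL))
    }
    sub_err <- lapply(errors, function(e) e[idx])
    list(
      n = n,
      methods = lapply(sub_err, summarize_errors),
      tests = if (n >= min_n && length(sub_err) >= 2) {
        compare_paired(lapply(sub_err, abs), reference = reference)
      } else {
        NULL
      }
    )
  })
}

#' Run the full simulate-train-evaluate pipeline
#'
#' Executes the end-to-end flow: simulate (or load) a cohort, split it
#' patient-wise with fellow-eye exclusion, optimize the constants of all
#' four formulas on the training set, compute formula predictions on the
#' test set (plus mean-offset-corrected external predictions, if
#' supplied), select the base formula and feature subset (optional),
#' train the four stacked model kinds, predict the test set, and assemble
#' the evaluation report. Each stage logs a message with its seed.
#'
#' @param config List of settings:
#'   \describe{
#'     \item{cohort}{A cohort object or CSV path; NULL (default) simulates
#'       with `synthetic` settings.}
#'     \item{synthetic}{List of [synthetic_config()] overrides.}
#'     \item{n_test}{Test patients (default 500).}
#'     \item{seed}{Master seed (default 0); the simulation, split, fold and
#'       model seeds derive from it.}
#'     \item{formulas}{Formulas to evaluate (default all four).}
#'     \item{model_kinds}{Stacker kinds (default svr/rfr/gbr/nn).}
#'     \item{features}{Fixed feature subset; NULL runs
#'       [select_feature_subset()].}
#'     \item{base_formula}{Fixed base formula; NULL runs
#'       [select_base_formula()].}
#'     \item{grids}{Named list of hyperparameter grids by kind.}
#'     \item{nn}{NN settings (see [train_stacker()]).}
#'     \item{selector}{Gradient-boosted selector settings.}
#'     \item{subset_candidates}{Candidates for subset search.}
#'     \item{cv_folds}{Folds (default 5).}
#'     \item{external}{Optional data frame `eye_id, method, predicted_se`
#'       covering train+test eyes, passed through [mean_offset_correct()].}
#'   }
#' @param out_dir Optional directory; writes `constants.json`, `pred.csv`
#'   and `report.json` there.
#' @return An `evaluation_report` list: `methods` (per-method summaries),
#'   `friedman`, `pairwise`, `chi2`, `subgroups`, `selection`, `constants`,
#'   `errors`, `seeds`, `sizes`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    cohort = NULL, synthetic = list(), n_test = 500, seed = 0,
    formulas = c("srkt", "holladay1", "hofferq", "haigis"),
    model_kinds = c("svr", "rfr", "gbr", "nn"),
    features = NULL, base_formula = NULL,
    grids = list(), nn = list(),
    selector = list(eta = 0.3, max_depth = 3, nrounds = 60),
    subset_candidates = feature_candidates(),
    cv_folds = 5, external = NULL
  ), config)
  seed <- as.integer(cfg$seed)

  stage <- function(name) message(sprintf("[iolstack] stage %s (seed %d)", name, seed))

  stage("cohort")
  cohort <- if (is.null(cfg$cohort)) {
    do.call(synthetic_config, utils::modifyList(list(seed = seed), cfg$synthetic)) |>
      generate_cohort()
  } else if (is.character(cfg$cohort)) {
    read_cohort(cfg$cohort)
  } else {
    cfg$cohort
  }

  stage("split")
  sp <- split_patientwise(cohort, n_test = cfg$n_test, seed = seed + 1)
  train <- sp$train
  test <- sp$test

  stage("optimize-constants")
  constants <- optimize_constants(train, formulas = cfg$formulas)

  stage("formula-predictions")
  obs <- test$postop_se
  preds <- list()
  for (f in cfg$formulas) {
    preds[[f]] <- predict_refraction(formula_engine(f), test, constants)
  }
  if (!is.null(cfg$external)) {
    ext <- cfg$external
    for (mname in unique(ext$method)) {
      sub <- ext[ext$method == mname, ]
      tr <- sub[match(train$eye_id, sub$eye_id), "predicted_se"]
      te <- sub[match(test$eye_id, sub$eye_id), "predicted_se"]
      if (anyNA(tr) || anyNA(te)) {
        stop(sprintf("external method '%s' does not cover all eyes", mname),
          call. = FALSE
        )
      }
      preds[[mname]] <- mean_offset_correct(te, tr, train$postop_se)
    }
  }

  base_formula <- cfg$base_formula
  importance <- NULL
  if (is.null(base_formula)) {
    stage("select-base-formula")
    sel <- select_base_formula(train, constants, selector = cfg$selector)
    base_formula <- sel$formula_id
    importance <- sel$importance
  }

  features <- cfg$features
  selection <- NULL
  if (is.null(features)) {
    stage("select-feature-subset")
    selection <- select_feature_subset(train, constants,
      base_formula = base_formula, candidates = cfg$subset_candidates,
      cv_folds = cfg$cv_folds, seed = seed + 2, selector = cfg$selector
    )
    features <- selection$best_subset
  }

  stage("train-stackers")
  for (kind in cfg$model_kinds) {
    model <- train_stacker(kind, train, constants,
      features = features, base_formula = base_formula,
      grid = cfg$grids[[kind]], cv_folds = cfg$cv_folds,
      seed = seed + 3, nn = cfg$nn
    )
    preds[[kind]] <- predict_stacker(model, test, constants)
  }

  stage("evaluate")
  errors <- lapply(preds, function(p) p - obs)
  methods <- lapply(errors, summarize_errors)
  reference <- if ("srkt" %in% names(errors)) "srkt" else names(errors)[1]
  tests <- compare_paired(lapply(errors, abs), reference = reference)
  chi2 <- lapply(setdiff(names(errors), reference), function(mname) {
    list(a = mname, b = reference, p = proportion_chi2(
      methods[[mname]]$within[["0.5"]], methods[[mname]]$n,
      methods[[reference]]$within[["0.5"]], methods[[reference]]$n
    ))
  })
  subgroups <- subgroup_by_axial(test, errors, reference = reference)

  report <- structure(list(
    methods = methods,
    friedman = tests$friedman,
    pairwise = tests$pairwise,
    chi2 = chi2,
    subgroups = subgroups,
    selection = list(
      base_formula = base_formula,
      base_importance = importance,
      features = features,
      subset_results = if (!is.null(selection)) selection$results else NULL
    ),
    constants = constants,
    errors = errors,
    reference = reference,
    seeds = list(master = seed, split = seed + 1, folds = seed + 2, models = seed + 3),
    sizes = list(
      n_total = nrow(cohort), n_train = nrow(train), n_test = nrow(test)
    )
  ), class = "evaluation_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_constants(constants, file.path(out_dir, "constants.json"))
    pred_tab <- do.call(rbind, lapply(names(preds), function(mname) {
      data.frame(
        eye_id = test$eye_id, method = mname,
        predicted_se = preds[[mname]], error = preds[[mname]] - obs
      )
    }))
    write_predictions(pred_tab, file.path(out_dir, "pred.csv"))
    jsonlite::write_json(
      report_to_json(report), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

# plain-list view of the report for JSON serialization. Internal.
report_to_json <- function(report) {
  list(
    methods = lapply(report$methods, function(s) {
      list(
        n = s$n, mae = s$mae, medae = s$medae, sd = s$sd, me = s$me,
        within = as.list(s$within)
      )
    }),
    friedman = list(stat = report$friedman$statistic, p = report$friedman$p),
    pairwise = lapply(seq_len(nrow(report$pairwise)), function(i) {
      as.list(report$pairwise[i, c("a", "b", "test", "raw_p", "adj_p")])
    }),
    chi2 = report$chi2,
    subgroups = lapply(report$subgroups, function(b) {
      if (b$n == 0L) {
        return(list(n = 0))
      }
      list(n = b$n, methods = lapply(b$methods, function(s) {
        list(mae = s$mae, medae = s$medae, within_0.5 = unname(s$within["0.5"]))
      }))
    }),
    selection = list(
      base_formula = report$selection$base_formula,
      features = report$selection$features
    ),
    seeds = report$seeds,
    sizes = report$sizes
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n_train %d, n_test %d, reference %s\n",
    x$sizes$n_train, x$sizes$n_test, x$reference
  ))
  tab <- do.call(rbind, lapply(names(x$methods), function(m) {
    s <- x$methods[[m]]
    data.frame(
      method = m, mae = round(s$mae, 4), medae = round(s$medae, 4),
      within_0.5 = sprintf("%d/%d", s$within[["0.5"]], s$n)
    )
  }))
  print(tab, row.names = FALSE)
  cat(sprintf(
    "Friedman chi-sq %.3f, p %.4g\n", x$friedman$statistic, x$friedman$p
  ))
  invisible(x)
}
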