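test_that("error summaries use MAE, median AE and strict threshold counts", {
  s <- summarize_errors(c(0.1, -0.3, 0.6))
  expect_equal(s$mae, 1 / 3, tolerance = 1e-9)
  expect_equal(unname(s$within["0.5"]), 2)
  expect_equal(s$medae, 0.3)

  z <- summarize_errors(rep(0, 7))
  expect_equal(z$mae, 0)
  expect_equal(unname(z$within), c(7, 7, 7))

  # 0.5 exactly is NOT below 0.5
  expect_equal(unname(summarize_errors(c(0.5, -0.5, 0.49))$within["0.5"]), 1)

  set.seed(1)
  e <- rnorm(200)
  s <- summarize_errors(e)
  expect_gte(s$mae, abs(s$me))
  expect_lte(s$medae, max(abs(e)))
})

test_that("identical methods give a degenerate Friedman and unit p-values", {
  set.seed(2)
  e <- abs(rnorm(40))
  res <- compare_paired(list(a = e, b = e, c = e, d = e))
  expect_equal(res$friedman$statistic, 0)
  expect_equal(res$friedman$p, 1)
  expect_true(all(res$pairwise$raw_p == 1))
  expect_true(all(res$pairwise$adj_p == 1))
  expect_true(all(res$pairwise$test == "degenerate"))
})

test_that("Bonferroni multiplies by the comparisons performed and caps at 1", {
  set.seed(3)
  ref <- abs(rnorm(60))
  methods <- c(list(ref = ref), lapply(1:4, function(i) abs(rnorm(60, 0.2 * i))))
  names(methods) <- c("ref", paste0("m", 1:4))
  res <- compare_paired(methods, reference = "ref")
  expect_equal(res$n_comparisons, 4)
  expect_equal(res$pairwise$adj_p, pmin(1, res$pairwise$raw_p * 4))
  expect_true(all(res$pairwise$adj_p >= res$pairwise$raw_p))
  expect_true(all(res$pairwise$adj_p <= 1))
  expect_error(compare_paired(list(a = 1:3, b = 1:4)), "pairing")
  expect_error(compare_paired(list(a = 1:3)), "two methods")
})

test_that("the Wilcoxon branch matches exact sign-flip enumeration for n <= 10", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(5:10, 1)
    xa <- round(abs(rnorm(n, 0.4, 0.2)), 6)
    xb <- round(abs(rnorm(n, 0.3, 0.2)), 6)
    d <- xa - xb
    if (any(d == 0) || anyDuplicated(abs(d))) next
    expect_equal(
      stats::wilcox.test(xa, xb, paired = TRUE)$p.value,
      wilcoxon_exact_enum(d),
      tolerance = 1e-12,
      label = sprintf("enumeration oracle, seed %d", s)
    )
  }
})

test_that("chi-squared proportion comparison uses no continuity correction", {
  expect_equal(round(proportion_chi2(406, 500, 422, 500), 4), 0.1800)
  expect_equal(round(proportion_chi2(406, 500, 412, 500), 4), 0.6229)
  expect_equal(round(proportion_chi2(406, 500, 414, 500), 4), 0.5102)
  # symmetric in group order, identical proportions give p = 1
  expect_equal(
    proportion_chi2(406, 500, 422, 500),
    proportion_chi2(422, 500, 406, 500)
  )
  expect_equal(proportion_chi2(37, 50, 37, 50), 1)
  expect_error(proportion_chi2(0, 50, 0, 50), "zero margin")
  expect_error(proportion_chi2(50, 50, 50, 50), "zero margin")
})

test_that("axial-length subgroups use left-closed bins at 22 and 24 mm", {
  co <- eye_grid(3)
  co$axial_length <- c(21, 23, 25)
  errs <- list(m1 = c(0.1, 0.2, 0.3), m2 = c(0.2, 0.1, 0.4))
  sg <- subgroup_by_axial(co, errs)
  expect_equal(vapply(sg, `[[`, 0L, "n"), c(short = 1L, middle = 1L, long = 1L))
  expect_equal(sg$long$methods$m1$mae, 0.3)

  co$axial_length <- c(22.0, 24.0, 30)
  sg <- subgroup_by_axial(co, errs)
  expect_equal(sg$short$n, 0L)
  expect_equal(sg$middle$n, 1L) # 22.0 exactly is middle
  expect_equal(sg$long$n, 2L) # 24.0 exactly is long
  expect_null(sg$short$tests)
})

test_that("the pipeline runs end to end, deterministically, and writes artifacts", {
  grids <- list(
    svr = data.frame(cost = 10, epsilon = 0.1, gamma = 0.1),
    rfr = data.frame(num_trees = 100, max_depth = 0),
    gbr = data.frame(eta = 0.1, nrounds = 60, max_depth = 3)
  )
  config <- list(
    synthetic = list(n_patients = 260), n_test = 60, seed = 1,
    features = c(
      "axial_length", "corneal_radius", "acd", "lens_thickness",
      "iol_power", "formula_prediction"
    ),
    grids = grids, nn = list(n_repeats = 3),
    selector = list(eta = 0.3, max_depth = 3, nrounds = 40)
  )
  out <- withr::local_tempdir()
  rep <- suppressMessages(run_pipeline(config, out_dir = out))

  expect_setequal(
    names(rep$methods),
    c("srkt", "holladay1", "hofferq", "haigis", "svr", "rfr", "gbr", "nn")
  )
  expect_true(all(file.exists(file.path(
    out, c("constants.json", "pred.csv", "report.json")
  ))))
  expect_equal(rep$sizes$n_test, 60)
  expect_true(rep$selection$base_formula %in%
    c("srkt", "holladay1", "hofferq", "haigis"))
  expect_equal(length(rep$chi2), 7)

  # deterministic rerun
  rep2 <- suppressMessages(run_pipeline(config))
  expect_identical(
    vapply(rep$methods, `[[`, 0, "mae"),
    vapply(rep2$methods, `[[`, 0, "mae")
  )
  expect_identical(rep$friedman, rep2$friedman)

  # the prediction table round-trips and aligns with the report errors
  pred <- read_predictions(file.path(out, "pred.csv"))
  expect_setequal(unique(pred$method), names(rep$methods))
  srkt_err <- pred$error[pred$method == "srkt"]
  expect_equal(mean(abs(srkt_err)), rep$methods$srkt$mae, tolerance = 1e-9)
})
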