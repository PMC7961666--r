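#' @keywords internal
"_PACKAGE"

# Fixed cohort CSV schema: comma separator, '.' decimal, UTF-8, mandatory
# header. postop_se may be empty (prediction-only records).
cohort_columns <- c(
  "patient_id", "eye_id", "laterality", "age", "axial_length",
  "corneal_radius", "acd", "lens_thickness", "wtw", "iol_model",
  "iol_power", "postop_se"
)
cohort_numeric <- c(
  "age", "axial_length", "corneal_radius", "acd", "lens_thickness",
  "wtw", "iol_power", "postop_se"
)

# Open-interval plausibility bounds per measured field (mm / diopters / years).
biometry_bounds <- list(
  axial_length = c(15, 40),
  corneal_radius = c(5.5, 11),
  acd = c(1.0, 6.0),
  lens_thickness = c(2.0, 7.5),
  wtw = c(8, 14),
  iol_power = c(-10, 45)
)

new_cohort <- function(df, provenance = "") {
  attr(df, "provenance") <- provenance
  class(df) <- c("cohort", "data.frame")
  df
}

#' Validate one biometry record
#'
#' Total function: returns a data frame of violations (possibly empty),
#' one row per out-of-bounds field, naming the field, its value and the
#' open-interval bounds. Bounds: axial length (15, 40) mm, corneal radius
#' (5.5, 11) mm, ACD (1, 6) mm, lens thickness (2, 7.5) mm, white-to-white
#' (8, 14) mm, IOL power (-10, 45) D.
#'
#' @param rec A list or one-row data frame with the cohort columns.
#' @return Data frame with columns `field`, `value`, `lower`, `upper`.
#' @examples
#' validate_record(list(
#'   axial_length = 24.02, corneal_radius = 7.63, acd = 3.10,
#'   lens_thickness = 4.57, wtw = 11.74, iol_power = 19.63
#' )) # zero rows
#' @export
validate_record <- function(rec) {
  out <- data.frame(
    field = character(), value = numeric(),
    lower = numeric(), upper = numeric()
  )
  for (f in names(biometry_bounds)) {
    v <- suppressWarnings(as.numeric(rec[[f]]))
    if (length(v) == 0L || is.na(v)) next # absence handled by schema checks
    b <- biometry_bounds[[f]]
    if (v <= b[1] || v >= b[2]) {
      out <- rbind(out, data.frame(field = f, value = v, lower = b[1], upper = b[2]))
    }
  }
  out
}

validate_cohort_df <- function(df, file = "cohort") {
  msgs <- character()
  for (i in seq_len(nrow(df))) {
    viol <- validate_record(df[i, ])
    if (nrow(viol) > 0) {
      msgs <- c(msgs, sprintf(
        "row %d (%s): %s", i, df$eye_id[i],
        paste(sprintf(
          "%s = %g outside (%g, %g)",
          viol$field, viol$value, viol$lower, viol$upper
        ), collapse = "; ")
      ))
    }
  }
  if (length(msgs) > 0) {
    stop(sprintf(
      "validation error in %s:\n  %s", file,
      paste(msgs, collapse = "\n  ")
    ), call. = FALSE)
  }
  key <- paste(df$patient_id, df$eye_id)
  if (anyDuplicated(key)) {
    stop(sprintf(
      "validation error in %s: duplicated (patient_id, eye_id): %s",
      file, paste(unique(key[duplicated(key)]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

#' Read a biometry cohort CSV
#'
#' Fixed dialect: comma separator, '.' decimal, UTF-8, mandatory header with
#' columns `patient_id, eye_id, laterality, age, axial_length,
#' corneal_radius, acd, lens_thickness, wtw, iol_model, iol_power,
#' postop_se`. An empty `postop_se` cell marks a prediction-only record.
#' Every row is validated against the biometry bounds; row order is
#' preserved.
#'
#' @param path CSV file path.
#' @return A `cohort` object (a validated data frame).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "schema error in %s: missing column(s) %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("empty cohort: %s", path), call. = FALSE)
  df <- df[, cohort_columns]
  for (col in cohort_numeric) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & nzchar(trimws(raw)))
    if (length(bad) > 0) {
      stop(sprintf(
        "parse error in %s: non-numeric '%s' in column %s, row %d",
        path, raw[bad[1]], col, bad[1]
      ), call. = FALSE)
    }
    if (col != "postop_se" && anyNA(num)) {
      stop(sprintf(
        "parse error in %s: empty cell in column %s, row %d",
        path, col, which(is.na(num))[1]
      ), call. = FALSE)
    }
    df[[col]] <- num
  }
  validate_cohort_df(df, file = path)
  new_cohort(df, provenance = sprintf("read from %s", path))
}

#' Write a biometry cohort CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path. Missing `postop_se` is written as an empty cell.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns], path,
    row.names = FALSE, na = "", fileEncoding = "UTF-8", quote = FALSE
  )
  invisible(path)
}

#' Read / write per-lens-model IOL constants (JSON)
#'
#' The JSON maps each lens model label to an object with any of the fields
#' `A` (SRK/T), `SF` (Holladay 1), `pACD` (Hoffer Q), `a0`, `a1`, `a2`
#' (Haigis); a formula's constant may be independently absent.
#'
#' @param path JSON file path.
#' @return Named list (by lens model) of named numeric constant lists.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(entry) {
    entry <- entry[!vapply(entry, is.null, TRUE)]
    out <- lapply(entry, as.numeric)
    if ("A" %in% names(out) && (out$A <= 100 || out$A >= 130)) {
      stop("A constant outside (100, 130)", call. = FALSE)
    }
    out
  })
}

#' @rdname read_constants
#' @param constants Named list as produced by [optimize_constants()].
#' @export
write_constants <- function(constants, path) {
  jsonlite::write_json(constants, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a predictions table
#'
#' Long-format CSV with columns `eye_id, method, predicted_se, error`
#' (error = predicted - observed; empty when the observation is absent).
#'
#' @param pred Data frame with those columns.
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(all(c("eye_id", "method", "predicted_se", "error") %in% names(pred)))
  utils::write.csv(pred[, c("eye_id", "method", "predicted_se", "error")],
    path,
    row.names = FALSE, na = "", fileEncoding = "UTF-8", quote = FALSE
  )
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("eye_id", "method", "predicted_se", "error")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "schema error in %s: missing column(s) %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  df
}
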