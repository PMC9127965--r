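# Domain tables and their CSV I/O: per-food nutrient records, per-subject
# glucose curves, and the bundled study fixtures.

.FOOD_COLS <- c("food_id", "name", "category", "serving_g", "energy_kcal",
                "carbohydrate_g", "fiber_g", "protein_g", "fat_g")
.GLUCOSE_COLS <- c("subject_id", "food_id", "test_id", "time_min",
                   "glucose_mg_dl")

#' Validate a food nutrient table
#'
#' Checks the invariants every nutrient-label record must satisfy: all
#' nutrient masses non-negative, dietary fiber not exceeding total
#' carbohydrate, and a positive serving mass.
#'
#' @param foods data frame with at least the nutrient columns
#'   `carbohydrate_g`, `fiber_g`, `protein_g`, `fat_g` and `serving_g`.
#' @return `foods`, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_food_table <- function(foods) {
  stopifnot(is.data.frame(foods))
  need <- setdiff(.FOOD_COLS, names(foods))
  if (length(need) > 0)
    stop("food table is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(foods) == 0) return(invisible(foods))
  num <- c("serving_g", "energy_kcal", "carbohydrate_g", "fiber_g",
           "protein_g", "fat_g")
  for (col in num) .assert_numeric(foods[[col]], col)
  bad <- which(foods$carbohydrate_g < 0 | foods$fiber_g < 0 |
                 foods$protein_g < 0 | foods$fat_g < 0)
  if (length(bad) > 0)
    stop("negative nutrient mass in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(foods$fiber_g > foods$carbohydrate_g)
  if (length(bad) > 0)
    stop("fiber exceeds carbohydrate in row(s): ",
         paste(bad, collapse = ", "),
         " (", paste(foods$food_id[bad], collapse = ", "), ")",
         call. = FALSE)
  bad <- which(foods$serving_g <= 0)
  if (length(bad) > 0)
    stop("non-positive serving mass in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(foods)
}

#' Read a food nutrient table from CSV
#'
#' The expected format is UTF-8, comma-separated, dot decimal, with header
#' columns `food_id,name,category,serving_g,energy_kcal,carbohydrate_g,
#' fiber_g,protein_g,fat_g`. Rows violating the nutrient invariants are
#' rejected with an error naming the row.
#'
#' @param path path to a CSV file.
#' @return data frame with one row per food.
#' @seealso [write_food_table()], [validation_foods()]
#' @export
read_food_table <- function(path) {
  foods <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_food_table(foods)
  foods
}

#' Write a food nutrient table to CSV
#'
#' @param foods valid food table (see [validate_food_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(foods, path) {
  validate_food_table(foods)
  out <- foods[, union(.FOOD_COLS, names(foods)), drop = FALSE]
  # full 17-digit precision so numeric fields round-trip bit-exactly
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a blood-glucose response curve
#'
#' One curve is one subject consuming one food (or a reference food, tagged
#' with the reserved ids [GLUCOSE_REF] or [RICE_REF]) followed by capillary
#' glucose measurements on a fixed schedule. The default study schedule is
#' 0 min (fasting baseline, immediately before consumption) and 15, 30, 45,
#' 60, 90 and 120 min after consumption.
#'
#' @param subject_id,food_id identifiers; `test_id` separates repeated tests
#'   of the same (subject, food) pair.
#' @param time_min strictly increasing times in minutes, starting at 0.
#' @param glucose_mg_dl glucose concentrations (mg/dL), all positive, one
#'   per time point.
#' @param test_id test identifier (default `"t1"`).
#' @return an object of class `glucose_curve`.
#' @examples
#' glucose_curve("S01", GLUCOSE_REF, c(0, 15, 30, 45, 60, 90, 120),
#'               c(90, 120, 150, 140, 120, 100, 92))
#' @export
glucose_curve <- function(subject_id, food_id, time_min, glucose_mg_dl,
                          test_id = "t1") {
  .assert_numeric(time_min, "time_min")
  .assert_numeric(glucose_mg_dl, "glucose_mg_dl")
  if (length(time_min) != length(glucose_mg_dl))
    stop("time and glucose vectors must have equal length", call. = FALSE)
  if (length(time_min) < 1) stop("empty curve", call. = FALSE)
  if (time_min[1] != 0)
    stop("first measurement must be the fasting baseline at time 0",
         call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(glucose_mg_dl <= 0))
    stop("glucose values must be positive", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 food_id = as.character(food_id),
                 test_id = as.character(test_id),
                 time_min = as.numeric(time_min),
                 glucose_mg_dl = as.numeric(glucose_mg_dl)),
            class = "glucose_curve")
}

#' @export
print.glucose_curve <- function(x, ...) {
  cat(sprintf("<glucose_curve> subject %s, food %s, test %s\n",
              x$subject_id, x$food_id, x$test_id))
  print(setNames(x$glucose_mg_dl, x$time_min))
  invisible(x)
}

#' Read long-format glucose measurements from CSV
#'
#' Expects columns `subject_id,food_id,test_id,time_min,glucose_mg_dl`.
#' Rows sharing (subject, food, test) form one curve; repeated reference
#' tests for a subject are distinguished by `test_id`. Rows are sorted by
#' time within each test; duplicated times within a test are rejected.
#'
#' @param path path to a CSV file.
#' @return list of [glucose_curve()] objects.
#' @export
read_glucose_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- setdiff(.GLUCOSE_COLS, names(df))
  if (length(need) > 0)
    stop("glucose table is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$time_min < 0))
    stop("negative measurement times are not allowed", call. = FALSE)
  key <- paste(df$subject_id, df$food_id, df$test_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$time_min), ]
    if (anyDuplicated(g$time_min))
      stop(sprintf("duplicated time point in test (%s, %s, %s)",
                   g$subject_id[1], g$food_id[1], g$test_id[1]),
           call. = FALSE)
    glucose_curve(g$subject_id[1], g$food_id[1], g$time_min,
                  g$glucose_mg_dl, g$test_id[1])
  })
}

#' Write glucose curves to a long-format CSV
#'
#' Inverse of [read_glucose_long()].
#'
#' @param curves list of [glucose_curve()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_glucose_long <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(subject_id = cv$subject_id, food_id = cv$food_id,
               test_id = cv$test_id, time_min = cv$time_min,
               glucose_mg_dl = cv$glucose_mg_dl)
  }))
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "egload")
  if (path == "") stop("bundled fixture not found: ", file, call. = FALSE)
  path
}

#' Bundled 24-food validation table
#'
#' Transcription of the published per-food table of the validation study:
#' nutrient label per serving (carbohydrate, fiber, protein, fat in g;
#' serving mass and energy), measured IAUC and GI (mean and SD over the
#' eight subjects who consumed each food), measured GL (mean and SD per
#' serving), GI/GL class labels, and the published eGL prediction. Values
#' are stored as plain numbers (thousands separators stripped at
#' transcription time).
#'
#' @return data frame with 24 rows and columns `food_id, name, category,
#'   serving_g, energy_kcal, carbohydrate_g, fiber_g, protein_g, fat_g,
#'   iauc_mean, iauc_sd, gi_mean, gi_sd, gi_class, gl_mean, gl_sd,
#'   gl_class, egl`.
#' @examples
#' t4 <- validation_foods()
#' t4[t4$food_id == "corn_salad", c("gi_mean", "gl_mean", "egl")]
#' @export
validation_foods <- function() {
  foods <- read.csv(.extdata("validation_foods.csv"),
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_food_table(foods)
  foods
}

#' Bundled cohort comparison summaries
#'
#' Summary statistics (mean, SD, n) of the validation cohort (20 subjects,
#' 192 food-consumption events) and of the earlier development cohort
#' (34 subjects, 239 events) for the subject characteristics and the
#' per-event nutrient contents entering the eGL model. These are the
#' inputs of the transportability assessment.
#'
#' @return named list with elements `validation` and `development`, each a
#'   data frame with columns `characteristic, block, type, n, mean, sd`.
#'   `block` is `"subjects"` or `"events"`; `type` is `"continuous"` or
#'   `"proportion"` (percent scale).
#' @examples
#' cohort_summaries()$validation[1:3, ]
#' @export
cohort_summaries <- function() {
  df <- read.csv(.extdata("cohort_summaries.csv"), stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  pick <- function(side) {
    out <- data.frame(characteristic = df$characteristic, block = df$block,
                      type = df$type,
                      n = df[[paste0(side, "_n")]],
                      mean = df[[paste0(side, "_mean")]],
                      sd = df[[paste0(side, "_sd")]],
                      stringsAsFactors = FALSE)
    stopifnot(all(out$n > 1), all(is.na(out$sd) | out$sd >= 0))
    out
  }
  list(validation = pick("validation"), development = pick("development"))
}

#' Validate subject profiles
#'
#' Checks internal consistency of a table of subject characteristics: BMI
#' must agree with height and weight within 0.2 kg/m2 when all three are
#' present. Fasting glucose at or above 100 mg/dL (the study's inclusion
#' cut-off for normal fasting glucose) triggers a warning only.
#'
#' @param subjects data frame with columns `subject_id, sex, age_y,
#'   height_cm, weight_kg, bmi_kg_m2, ...` (see [simulate_cohort()]).
#' @return `subjects`, invisibly.
#' @export
validate_subjects <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  if (all(c("height_cm", "weight_kg", "bmi_kg_m2") %in% names(subjects))) {
    bmi <- subjects$weight_kg / (subjects$height_cm / 100)^2
    ok <- is.na(bmi) | is.na(subjects$bmi_kg_m2) |
      abs(bmi - subjects$bmi_kg_m2) <= 0.2
    if (!all(ok))
      stop("BMI inconsistent with height/weight in row(s): ",
           paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  if ("sex" %in% names(subjects) && !all(subjects$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  if ("fasting_glucose_mg_dl" %in% names(subjects)) {
    hi <- which(subjects$fasting_glucose_mg_dl >= 100)
    if (length(hi) > 0)
      warning("fasting glucose >= 100 mg/dL (outside the inclusion ",
              "criterion) in row(s): ", paste(hi, collapse = ", "),
              call. = FALSE)
  }
  invisible(subjects)
}
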