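test_that("food table CSV round-trips exactly and rejects invalid rows", {
  set.seed(11)
  foods <- random_foods(6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(foods, path)
  back <- read_food_table(path)
  expect_equal(back, foods, tolerance = 0)

  # header-only file -> empty table
  writeLines(paste(colnames(foods), collapse = ","), path)
  expect_equal(nrow(read_food_table(path)), 0)

  bad <- foods
  bad$fiber_g[3] <- bad$carbohydrate_g[3] + 2
  expect_error(validate_food_table(bad), "fiber exceeds carbohydrate.*3")
  expect_error(validate_food_table(foods[, -match("fiber_g", names(foods))]),
               "fiber_g")
  bad <- foods; bad$protein_g[2] <- -1
  expect_error(validate_food_table(bad), "negative")
})

test_that("long glucose CSV is grouped into curves with per-test validation", {
  set.seed(21)
  df <- data.frame(subject_id = "S01",
                   food_id = c(rep("tteok", 7), rep(GLUCOSE_REF, 14)),
                   test_id = c(rep("t1", 7), rep("ref1", 7), rep("ref2", 7)),
                   time_min = rep(c(0, 15, 30, 45, 60, 90, 120), 3),
                   glucose_mg_dl = 90 + rpois(21, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  curves <- read_glucose_long(path)
  expect_length(curves, 3)
  expect_equal(length(curves[[1]]$time_min), 7)
  refs <- Filter(function(cv) cv$food_id == GLUCOSE_REF, curves)
  expect_length(refs, 2)  # repeated reference tests stay separate

  df2 <- df; df2$time_min[2] <- -5
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_glucose_long(path), "negative")

  df3 <- df; df3$time_min[3] <- 15  # duplicate time within a test
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_glucose_long(path), "duplicated time")
})

test_that("glucose_curve enforces the measurement-schedule invariants", {
  expect_error(glucose_curve("S", "F", c(15, 30), c(100, 110)), "time 0")
  expect_error(glucose_curve("S", "F", c(0, 15, 15), c(100, 110, 100)),
               "increasing")
  expect_error(glucose_curve("S", "F", c(0, 15), c(100, 0)), "positive")
})

test_that("bundled 24-food table matches the published entries", {
  t4 <- validation_foods()
  expect_equal(nrow(t4), 24)
  corn <- t4[t4$food_id == "corn_salad", ]
  expect_equal(corn$gi_mean, 23)
  expect_equal(corn$gl_mean, 4)
  expect_equal(corn$egl, 11)
  soup <- t4[t4$food_id == "button_mushroom_soup", ]
  expect_equal(soup$gl_mean, 3)
  expect_equal(soup$gl_class, "low")
  tteok <- t4[t4$food_id == "wheat_noodle_tteokbokki", ]
  expect_equal(tteok$carbohydrate_g, 91)
  expect_equal(tteok$fiber_g, 3.3)
  expect_equal(tteok$serving_g, 140)
})

test_that("bundled table classes are self-consistent with the classifiers", {
  t4 <- validation_foods()
  expect_identical(classify_gi(t4$gi_mean), t4$gi_class)
  expect_identical(classify_gl(t4$gl_mean), t4$gl_class)
})

test_that("bundled cohort summaries carry the published means and sizes", {
  tc <- cohort_summaries()
  val <- tc$validation; dev <- tc$development
  expect_equal(val$n[val$characteristic == "age_y"], 20)
  expect_equal(dev$n[dev$characteristic == "age_y"], 34)
  expect_equal(val$n[val$characteristic == "fat_g"], 192)
  expect_equal(dev$n[dev$characteristic == "fat_g"], 239)
  expect_equal(
    dev$mean[dev$characteristic == "available_carbohydrate_g"], 47.6)
  expect_equal(
    dev$sd[dev$characteristic == "available_carbohydrate_g"], 20.32)
  expect_equal(
    val$mean[val$characteristic == "fasting_glucose_mg_dl"], 92.8)
})

test_that("subject validation flags inconsistent BMI and high fasting glucose", {
  subj <- data.frame(subject_id = "S01", sex = "M", height_cm = 170,
                     weight_kg = 65, bmi_kg_m2 = 65 / 1.7^2,
                     fasting_glucose_mg_dl = 95)
  expect_silent(validate_subjects(subj))
  subj$bmi_kg_m2 <- 30
  expect_error(validate_subjects(subj), "BMI inconsistent")
  subj$bmi_kg_m2 <- 65 / 1.7^2
  subj$fasting_glucose_mg_dl <- 105
  expect_warning(validate_subjects(subj), "fasting glucose")
})
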