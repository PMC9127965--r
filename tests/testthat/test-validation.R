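test_that("transportability reproduces the published significance pattern", {
  tc <- cohort_summaries()
  tr <- transportability_compare(tc$validation, tc$development)
  p <- setNames(tr$p_value, tr$characteristic)
  expect_lt(p[["available_carbohydrate_g"]], 0.001)
  expect_lt(p[["protein_g"]], 0.001)
  expect_lt(p[["fiber_g"]], 0.001)
  expect_gt(p[["fat_g"]], 0.05)
  expect_gt(p[["height_cm"]], 0.05)
  expect_gt(p[["weight_kg"]], 0.05)
  expect_gt(p[["bmi_kg_m2"]], 0.05)
  # height from the printed summaries: t = 0.19 on 52 df
  expect_equal(unname(p[["height_cm"]]), 0.849, tolerance = 0.002)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("identical cohorts give p = 1 and missing SDs are skipped", {
  tc <- cohort_summaries()
  tr <- transportability_compare(tc$validation, tc$validation)
  tt <- tr[tr$test == "t (pooled)", ]
  expect_true(all(tt$p_value == 1))
  broken <- tc$development
  broken$sd[broken$characteristic == "age_y"] <- NA
  expect_warning(tr2 <- transportability_compare(tc$validation, broken),
                 "age_y")
  expect_false("age_y" %in% tr2$characteristic)
})

test_that("Welch and pooled t-tests differ under unequal variances", {
  a <- data.frame(characteristic = "x", block = "subjects",
                  type = "continuous", n = 10, mean = 5, sd = 1)
  b <- data.frame(characteristic = "x", block = "subjects",
                  type = "continuous", n = 40, mean = 6, sd = 8)
  pooled <- transportability_compare(a, b, var_equal = TRUE)
  welch <- transportability_compare(a, b, var_equal = FALSE)
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
  expect_lt(welch$df, pooled$df)
})

test_that("logistic fit recovers known parameters and rejects degenerate input", {
  set.seed(107)
  x <- runif(2000, 0, 40)
  p <- plogis(-2 + 0.15 * x)
  y <- rbinom(2000, 1, p)
  fit <- logistic_fit(x, y)
  expect_lt(abs(fit$intercept - (-2)), 3 * fit$se[1])
  expect_lt(abs(fit$slope - 0.15), 3 * fit$se[2])

  # under the null the slope is centred at zero
  y0 <- rbinom(2000, 1, 0.4)
  fit0 <- logistic_fit(x, y0)
  expect_lt(abs(fit0$slope), 3 * fit0$se[2])

  expect_error(logistic_fit(x, rep(0, 2000)), "both outcome classes")
  expect_error(logistic_fit(1:5, c(0, 1, 0, 1, 0)), "at least 10")
  xs <- c(rnorm(50, -5), rnorm(50, 5))
  expect_error(logistic_fit(xs, as.integer(xs > 0)), "separation")
})

test_that("Hosmer-Lemeshow is exact under perfect calibration", {
  # ten risk groups of 20 whose observed event counts equal n * p exactly
  p <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  y <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(pk) {
    rep(c(1, 0), c(round(20 * pk), 20 - round(20 * pk)))
  }))
  hl <- hosmer_lemeshow(y, p)
  expect_equal(hl$chi2, 0)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 8)
})

test_that("Hosmer-Lemeshow bookkeeping invariants hold", {
  set.seed(108)
  p <- runif(300, 0.05, 0.95)
  y <- rbinom(300, 1, p)
  hl <- hosmer_lemeshow(y, p)
  expect_equal(sum(hl$table$expected), sum(p), tolerance = 1e-9)
  expect_equal(sum(hl$table$n), 300)
  # invariant to the order subjects arrive in
  perm <- sample(300)
  expect_equal(hosmer_lemeshow(y[perm], p[perm])$chi2, hl$chi2,
               tolerance = 1e-12)
  expect_gte(hl$chi2, 0)
  expect_error(hosmer_lemeshow(y, p * 2), "in \\(0, 1\\)")
  expect_error(hosmer_lemeshow(y[1:15], p[1:15]), "at least 2")
})

test_that("Hosmer-Lemeshow detects a miscalibrated model", {
  set.seed(109)
  rejections <- replicate(50, {
    p_true <- runif(2000, 0.1, 0.9)
    y <- rbinom(2000, 1, p_true)
    hosmer_lemeshow(y, p_true^2)$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.8)
})

test_that("AUROC equals exhaustive pairwise concordance", {
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  set.seed(110)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    score <- sample(round(rnorm(n), 1))  # coarse values force ties
    outcome <- rbinom(n, 1, 0.5)
    if (length(unique(outcome)) < 2) next
    got <- auroc(score, outcome)
    expect_equal(got$auc, auc_brute(score, outcome))
    expect_true(got$ci_low <= got$auc && got$auc <= got$ci_high)
    expect_gte(got$ci_low, 0)
    expect_lte(got$ci_high, 1)
  }
  expect_error(auroc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(111)
  score <- rnorm(200)
  outcome <- rbinom(200, 1, plogis(score))
  got <- auroc(score, outcome)$auc
  want <- as.numeric(pROC::auc(pROC::roc(outcome, score, levels = c(0, 1),
                                         direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("AUROC of an uninformative score is near one half", {
  set.seed(112)
  score <- rnorm(4000)
  outcome <- rbinom(4000, 1, 0.5)
  got <- auroc(score, outcome)
  expect_lt(abs(got$auc - 0.5), 3 * got$se)
})

test_that("agreement reports correlation and regression consistently", {
  ag <- agreement(2 * (1:10), 1:10)
  expect_equal(ag$pearson_r, 1)
  expect_equal(ag$slope, 2)
  expect_equal(ag$intercept, 0)
  ag2 <- agreement(c(1, 2, 4), c(1, 2, 3))
  expect_equal(ag2$pearson_r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(ag2$pearson_r, 0.982, tolerance = 1e-3)
  expect_error(agreement(rep(1, 5), 1:5), "zero variance")
  expect_error(agreement(1:2, 1:2), "at least 3")

  # slope * sd(x) / sd(y) = r, and R^2 = r^2, for any data
  set.seed(113)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ag3 <- agreement(y, x)
  expect_equal(ag3$slope * sd(x) / sd(y), ag3$pearson_r, tolerance = 1e-12)
  expect_equal(ag3$r_squared, ag3$pearson_r^2, tolerance = 1e-12)
})

test_that("per-food-mean agreement matches the published regression line", {
  t4 <- validation_foods()
  ag <- agreement(t4$gl_mean, t4$egl)
  expect_lt(abs(ag$slope - 1.64), 0.05)
  expect_lt(abs(ag$intercept + 9.27), 0.5)
  expect_equal(ag$n, 24)
})

test_that("subgroup validation partitions events and matches direct calls", {
  set.seed(114)
  bundle <- generate_validation_dataset(simulation_config(seed = 31))
  ev <- bundle$events
  res <- subgroup_validation(ev)
  expect_s3_class(res, "subgroup_validation")
  # strata partition the events: men + women = overall, bmi bands too
  n_of <- function(s) res$n[res$stratum == s]
  expect_equal(n_of("men") + n_of("women"), n_of("overall"))
  expect_equal(n_of("bmi<=23") + n_of("bmi>23"), n_of("overall"))
  expect_equal(n_of("body_fat_average") + n_of("body_fat_above_average"),
               n_of("overall"))

  overall_only <- subgroup_validation(ev, strata = character(0))
  expect_equal(nrow(overall_only), 1)
  outcome <- as.integer(ev$measured_gl >= 20)
  lf <- logistic_fit(ev$egl, outcome)
  hl <- hosmer_lemeshow(outcome, lf$fitted)
  au <- auroc(ev$egl, outcome)
  expect_equal(overall_only$hl_chi2, hl$chi2)
  expect_equal(overall_only$auc, au$auc)
})

test_that("a stratum with one outcome class is reported, not an error", {
  set.seed(115)
  ev <- data.frame(measured_gl = c(runif(30, 0, 10), runif(30, 25, 40)),
                   egl = rnorm(60, 20, 5),
                   sex = rep(c("M", "F"), each = 30))
  # men never exceed the high-GL threshold, women always do
  res <- subgroup_validation(ev, strata = "sex")
  expect_false(res$estimable[res$stratum == "men"])
  expect_false(res$estimable[res$stratum == "women"])
  expect_true(res$stratum[1] == "overall")
})

test_that("identical score distributions across sexes give similar AUROCs", {
  set.seed(116)
  n <- 500
  mk <- function(sex) {
    egl <- runif(n, 5, 40)
    gl <- egl + rnorm(n, 0, 10)
    data.frame(measured_gl = pmax(gl, 0), egl = egl, sex = sex)
  }
  ev <- rbind(mk("M"), mk("F"))
  res <- subgroup_validation(ev, strata = "sex")
  aucs <- res$auc[res$stratum %in% c("men", "women")]
  expect_lt(abs(diff(aucs)), 0.1)
})

test_that("validate_egl assembles a full report", {
  bundle <- generate_validation_dataset(simulation_config(seed = 32))
  rep <- validate_egl(bundle$events)
  expect_s3_class(rep, "egl_validation")
  expect_s3_class(rep$transportability, "transportability")
  expect_equal(sum(rep$grid$counts), 24)
  expect_equal(rep$agreement$n, 24)
  expect_gt(rep$agreement$pearson_r, rep$agreement_events$pearson_r)
  expect_output(print(rep), "classification grid")
})
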