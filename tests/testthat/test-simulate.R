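test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 9)
  expect_identical(simulate_gl_events(cfg), simulate_gl_events(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_glucose_curve(cfg, 3000),
                   simulate_glucose_curve(cfg, 3000))
  b1 <- generate_validation_dataset(cfg)
  b2 <- generate_validation_dataset(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  # different seeds diverge
  expect_false(identical(simulate_gl_events(simulation_config(seed = 10)),
                         simulate_gl_events(cfg)))
})

test_that("simulated curves hit their target incremental area", {
  cfg <- simulation_config(seed = 11, noise_sd = 0)
  for (target in c(500, 1500, 3000, 5000)) {
    cv <- simulate_glucose_curve(cfg, target)
    expect_equal(incremental_auc(cv), target, tolerance = 0.01)
  }
  flat <- simulate_glucose_curve(cfg, 0)
  expect_equal(incremental_auc(flat), 0)
  expect_error(simulate_glucose_curve(cfg, -10), ">= 0")
  # with noise the curve still centres on the target shape
  noisy <- simulate_glucose_curve(simulation_config(seed = 12), 3000)
  expect_equal(length(noisy$time_min), 7)
  expect_true(all(noisy$glucose_mg_dl > 0))
})

test_that("per-event draws reproduce the per-food distributions", {
  ev <- simulate_gl_events(simulation_config(seed = 13))
  expect_equal(nrow(ev), 192)
  expect_true(all(ev$measured_gl >= 0))
  t4 <- validation_foods()
  expect_equal(ev$egl, rep(t4$egl, each = 8))

  # law of large numbers: sample means approach the (truncated) food means
  big <- simulate_gl_events(simulation_config(seed = 14, n_per_food = 1e4))
  sample_means <- tapply(big$measured_gl, big$food_id, mean)[t4$food_id]
  low_trunc <- t4$gl_mean / t4$gl_sd > 2.5  # truncation negligible here
  expect_true(all(abs(sample_means[low_trunc] -
                        t4$gl_mean[low_trunc]) / t4$gl_mean[low_trunc]
                  < 0.01))
})

test_that("event correlation matches the analytic attenuation prediction", {
  set.seed(117)
  rs <- vapply(1:200, function(s) {
    ev <- simulate_gl_events(simulation_config(seed = 1000 + s))
    cor(ev$measured_gl, ev$egl)
  }, numeric(1))
  pred <- attenuated_event_correlation()
  mc_se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - pred), 4 * mc_se)
  # removing within-food dispersion removes the attenuation entirely
  t4 <- validation_foods()
  t0 <- t4; t0$gl_sd <- 0
  ev0 <- simulate_gl_events(simulation_config(seed = 15), t0)
  expect_equal(cor(ev0$measured_gl, ev0$egl), cor(t4$gl_mean, t4$egl),
               tolerance = 1e-12)
  expect_equal(attenuated_event_correlation(t0),
               cor(t4$gl_mean, t4$egl), tolerance = 1e-12)
})

test_that("simulated cohorts mirror the published characteristics", {
  cohort <- simulate_cohort(simulation_config(seed = 16))
  expect_equal(nrow(cohort), 20)
  expect_equal(sum(cohort$sex == "M"), 10)
  expect_equal(cohort$weight_kg,
               cohort$bmi_kg_m2 * (cohort$height_cm / 100)^2)
  # grand mean BMI over replicates within 3 SE of the printed 21.8
  set.seed(118)
  bmis <- vapply(1:50, function(s) {
    mean(simulate_cohort(simulation_config(seed = 2000 + s))$bmi_kg_m2)
  }, numeric(1))
  se <- 1.92 / sqrt(20 * 50)
  expect_lt(abs(mean(bmis) - 21.8), 3 * se)
})

test_that("GI recomputed through the pipeline is unbiased", {
  # curves simulated at known target GI; the IAUC -> reference -> ratio
  # path should recover it without systematic error
  set.seed(119)
  true_gi <- 52
  gi_hat <- vapply(1:200, function(i) {
    cfg <- simulation_config(noise_sd = 5)  # no seed: draws from the stream
    ref1 <- simulate_glucose_curve(cfg, 3800, "S", GLUCOSE_REF, "r1")
    ref2 <- simulate_glucose_curve(cfg, 3800, "S", GLUCOSE_REF, "r2")
    food <- simulate_glucose_curve(cfg, true_gi / 100 * 3800, "S", "f", "t1")
    gi_per_subject(incremental_auc(food),
                   reference_iauc(list(ref1, ref2), "S"))
  }, numeric(1))
  expect_lt(abs(mean(gi_hat) - true_gi), 3 * sd(gi_hat) / sqrt(200))
})

test_that("a generated bundle feeds the whole pipeline", {
  cfg <- simulation_config(seed = 17, noise_sd = 0)
  bundle <- generate_validation_dataset(cfg)
  expect_equal(length(bundle$curves), 20 * 2 + 24 * 8)
  expect_equal(nrow(bundle$events), 192)
  expect_true(all(c("sex", "bmi_kg_m2", "percent_body_fat")
                  %in% names(bundle$events)))

  # noiseless curves: recomputed per-food GI equals the fixture GI
  summary <- run_compute(bundle$foods, bundle$curves)
  m <- match(summary$food_id, bundle$foods$food_id)
  expect_equal(summary$gi_mean, bundle$foods$gi_mean[m], tolerance = 1e-6)

  report <- validate_egl(bundle$events)
  expect_s3_class(report, "egl_validation")
})
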