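# Synthetic study generator: glucose curves on the study's sampling grid,
# per-event GL observations, and cohorts with the published summary
# structure, so the whole pipeline runs and is testable with no external
# data.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-cohort generator. The defaults are
#' the validation study's own conditions: 20 subjects, 8 events per food,
#' measurements at 0/15/30/45/60/90/120 min, fasting baseline
#' Normal(92.8, 4.78) mg/dL, and per-event GL drawn from each food's
#' printed mean and SD truncated at zero. The excess-glucose pulse shape
#' (gamma-like rise to a peak near 30-45 min, return toward baseline by
#' 120 min) and the reference-IAUC scale are configuration, not science:
#' the study reports only the sampling grid and summary statistics.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param n_subjects cohort size.
#' @param n_per_food events (subjects) per food, >= 2.
#' @param times_min measurement grid (min), starting at 0.
#' @param baseline_mean,baseline_sd fasting glucose distribution (mg/dL).
#' @param peak_time_min time of the excess-glucose peak.
#' @param pulse_shape shape exponent of the gamma-like pulse.
#' @param noise_sd measurement noise SD added to each point (mg/dL).
#' @param ref_iauc_mean,ref_iauc_sd distribution of a subject's
#'   glucose-solution reference IAUC (mg.min/dL). 3800 is a typical
#'   2-hour IAUC for 50 g glucose in healthy adults and sits near the
#'   centre of the values implied by the bundled food table.
#' @param gl_floor truncation floor for simulated GL (0).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = NULL,
                              n_subjects = 20,
                              n_per_food = 8,
                              times_min = c(0, 15, 30, 45, 60, 90, 120),
                              baseline_mean = 92.8,
                              baseline_sd = 4.78,
                              peak_time_min = 35,
                              pulse_shape = 2,
                              noise_sd = 5,
                              ref_iauc_mean = 3800,
                              ref_iauc_sd = 600,
                              gl_floor = 0) {
  stopifnot(n_per_food >= 2, n_subjects >= 1,
            length(times_min) >= 2, times_min[1] == 0,
            all(diff(times_min) > 0),
            baseline_mean > 0, baseline_sd >= 0,
            peak_time_min > 0, pulse_shape > 0, noise_sd >= 0,
            ref_iauc_mean > 0, gl_floor >= 0)
  structure(list(seed = seed, n_subjects = n_subjects,
                 n_per_food = n_per_food, times_min = times_min,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 peak_time_min = peak_time_min, pulse_shape = pulse_shape,
                 noise_sd = noise_sd, ref_iauc_mean = ref_iauc_mean,
                 ref_iauc_sd = ref_iauc_sd, gl_floor = gl_floor),
            class = "simulation_config")
}

.maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
}

# Unimodal gamma-like pulse, 0 at t = 0, peaking at 1 at peak_time.
.pulse <- function(t, peak_time, shape) {
  u <- t / peak_time
  (u^shape) * exp(shape * (1 - u))
}

# Trapezoidal area of a non-negative shape on the grid.
.trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

.sim_curve <- function(config, target_iauc, subject_id, food_id, test_id) {
  t <- config$times_min
  baseline <- rnorm(1, config$baseline_mean, config$baseline_sd)
  f <- .pulse(t, config$peak_time_min, config$pulse_shape)
  area_unit <- .trapz(t, f)
  if (area_unit <= 0)
    stop("pulse shape has zero area on this grid: target unreachable",
         call. = FALSE)
  amp <- target_iauc / area_unit
  g <- baseline + amp * f
  if (config$noise_sd > 0)
    g <- g + c(0, rnorm(length(t) - 1, 0, config$noise_sd))
  g <- pmax(g, 1)  # glucose must stay positive
  glucose_curve(subject_id, food_id, t, g, test_id)
}

#' Simulate one blood-glucose response curve
#'
#' Draws a fasting baseline, adds a unimodal excess-glucose pulse scaled
#' so that the noiseless curve's [incremental_auc()] equals
#' `target_iauc` exactly (the pulse is non-negative and zero at time 0,
#' so trapezoidal scaling is exact), then adds measurement noise to the
#' post-baseline points.
#'
#' @param config a [simulation_config()]; its `seed`, if set, seeds the
#'   draw.
#' @param target_iauc target incremental area (mg.min/dL), >= 0.
#' @param subject_id,food_id,test_id identifiers for the resulting curve.
#' @return a [glucose_curve()].
#' @examples
#' cv <- simulate_glucose_curve(simulation_config(seed = 1, noise_sd = 0), 3000)
#' incremental_auc(cv)
#' @export
simulate_glucose_curve <- function(config = simulation_config(),
                                   target_iauc,
                                   subject_id = "S01", food_id = "FOOD",
                                   test_id = "t1") {
  stopifnot(inherits(config, "simulation_config"))
  .assert_numeric(target_iauc, "target_iauc")
  if (target_iauc < 0) stop("target_iauc must be >= 0", call. = FALSE)
  .maybe_seed(config)
  .sim_curve(config, target_iauc, subject_id, food_id, test_id)
}

#' Simulate per-event glycemic load observations
#'
#' For each food, draws `n_per_food` measured-GL values from
#' Normal(`gl_mean`, `gl_sd`) truncated at the floor (zero), and pairs
#' each with the food's fixed eGL -- the event-level structure of the
#' validation study (8 subjects per food, 24 x 8 = 192 events by
#' default). Truncation introduces a small positive bias for foods whose
#' printed SD is large relative to the mean; this is documented, not
#' corrected.
#'
#' @param config a [simulation_config()].
#' @param foods food table with `gl_mean`, `gl_sd` and `egl` columns
#'   (default [validation_foods()]).
#' @return data frame with columns `food_id, subject_slot, measured_gl,
#'   egl`.
#' @examples
#' ev <- simulate_gl_events(simulation_config(seed = 1))
#' nrow(ev)  # 192
#' @export
simulate_gl_events <- function(config = simulation_config(),
                               foods = validation_foods()) {
  stopifnot(inherits(config, "simulation_config"),
            all(c("food_id", "gl_mean", "gl_sd", "egl") %in% names(foods)))
  .maybe_seed(config)
  ev <- .draw_gl_events(foods, config$n_per_food, config$gl_floor)
  ev$egl <- rep(foods$egl, each = config$n_per_food)
  ev
}

#' Simulate a subject cohort
#'
#' Generates subject profiles with the summary structure of the
#' validation cohort: sex balanced to the published proportion, and
#' characteristics drawn independently from Normal(published mean,
#' published SD). Height and BMI are drawn and weight recomputed as
#' `BMI * (height/100)^2`, so BMI is internally consistent with height
#' and weight. Correlations between characteristics are not emulated.
#'
#' @param config a [simulation_config()].
#' @param characteristics cohort summary data frame (default the
#'   validation block of [cohort_summaries()]).
#' @return data frame of subject profiles, one row per subject.
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 1))
#' table(cohort$sex)
#' @export
simulate_cohort <- function(config = simulation_config(),
                            characteristics = cohort_summaries()$validation) {
  stopifnot(inherits(config, "simulation_config"))
  .maybe_seed(config)
  .sim_cohort(config, characteristics)
}

.sim_cohort <- function(config, characteristics) {
  n <- config$n_subjects
  ch <- function(name) {
    row <- characteristics[characteristics$characteristic == name, ][1, ]
    rnorm(n, row$mean, row$sd)
  }
  men_pct <- characteristics$mean[
    characteristics$characteristic == "men_pct"][1]
  n_men <- round(n * men_pct / 100)
  height <- ch("height_cm")
  bmi <- ch("bmi_kg_m2")
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = rep(c("M", "F"), c(n_men, n - n_men)),
    age_y = ch("age_y"),
    height_cm = height,
    bmi_kg_m2 = bmi,
    weight_kg = bmi * (height / 100)^2,
    skeletal_muscle_kg = ch("skeletal_muscle_kg"),
    percent_body_fat = ch("percent_body_fat"),
    waist_hip_ratio = ch("waist_hip_ratio"),
    basal_metabolism_kcal = ch("basal_metabolism_kcal"),
    fasting_glucose_mg_dl = ch("fasting_glucose_mg_dl"))
  suppressWarnings(validate_subjects(out))
  out
}

#' Generate a complete synthetic study bundle
#'
#' End-to-end generator: a cohort, two glucose-solution reference curves
#' per subject, one test-food curve per (food, subject slot) targeting
#' the food's published GI times the subject's reference IAUC, and the
#' per-event GL table with subject attributes attached -- everything the
#' computation and validation stages consume.
#'
#' @param config a [simulation_config()].
#' @param foods food table (default [validation_foods()]).
#' @return list of class `egl_study`: `cohort`, `curves` (list of
#'   [glucose_curve()]), `events` (with subject columns merged in),
#'   `foods`, `config`.
#' @export
generate_validation_dataset <- function(config = simulation_config(),
                                        foods = validation_foods()) {
  stopifnot(inherits(config, "simulation_config"))
  .maybe_seed(config)
  cohort <- .sim_cohort(config, cohort_summaries()$validation)
  n <- config$n_subjects
  ref_target <- pmax(rnorm(n, config$ref_iauc_mean, config$ref_iauc_sd), 500)
  curves <- list()
  for (i in seq_len(n)) {
    for (k in 1:2) {
      curves[[length(curves) + 1]] <-
        .sim_curve(config, ref_target[i], cohort$subject_id[i],
                   GLUCOSE_REF, paste0("ref", k))
    }
  }
  for (f in seq_len(nrow(foods))) {
    for (s in seq_len(config$n_per_food)) {
      subj <- ((f + s - 2) %% n) + 1  # spread foods across subjects
      target <- foods$gi_mean[f] / 100 * ref_target[subj]
      curves[[length(curves) + 1]] <-
        .sim_curve(config, target, cohort$subject_id[subj],
                   foods$food_id[f], "t1")
    }
  }
  events <- .draw_gl_events(foods, config$n_per_food, config$gl_floor)
  events$egl <- rep(foods$egl, each = config$n_per_food)
  subj_idx <- ((rep(seq_len(nrow(foods)), each = config$n_per_food) +
                  events$subject_slot - 2) %% n) + 1
  events$subject_id <- cohort$subject_id[subj_idx]
  for (col in c("sex", "bmi_kg_m2", "percent_body_fat"))
    events[[col]] <- cohort[[col]][subj_idx]
  structure(list(cohort = cohort, curves = curves, events = events,
                 foods = foods, config = config),
            class = "egl_study")
}

#' @export
print.egl_study <- function(x, ...) {
  cat(sprintf("<egl_study> %d subjects, %d curves, %d events, %d foods\n",
              nrow(x$cohort), length(x$curves), nrow(x$events),
              nrow(x$foods)))
  invisible(x)
}

#' Analytic per-event correlation under the simulation model
#'
#' Closed-form prediction of the Pearson correlation between per-event
#' measured GL and per-food eGL when events are drawn from truncated
#' Normal(`gl_mean`, `gl_sd`) per food: the between-food covariance and
#' variance of the (truncated) means, attenuated by the mean within-food
#' (truncated) variance,
#' \deqn{r = cov_B(\mu^*, eGL) / \sqrt{var(eGL)\,(var_B(\mu^*) +
#'   \overline{var_W})}.}
#' Used to cross-check the simulator against theory.
#'
#' @param foods food table with `gl_mean`, `gl_sd`, `egl`.
#' @param floor truncation floor (default 0).
#' @return predicted Pearson correlation (population value, equal food
#'   weights).
#' @export
attenuated_event_correlation <- function(foods = validation_foods(), floor = 0) {
  mo <- t(mapply(function(m, s) .tnorm_moments(m, s, floor),
                 foods$gl_mean, foods$gl_sd))
  k <- nrow(foods)
  pvar <- function(x) var(x) * (k - 1) / k
  pcov <- function(x, y) cov(x, y) * (k - 1) / k
  v_between <- pvar(mo[, "mean"])
  v_within <- mean(mo[, "var"])
  v_egl <- pvar(foods$egl)
  pcov(mo[, "mean"], foods$egl) / sqrt(v_egl * (v_between + v_within))
}
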