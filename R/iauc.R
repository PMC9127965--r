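# Incremental area under the glucose curve and per-subject GI.

#' Incremental area under a blood-glucose curve
#'
#' Computes the incremental area under the curve (IAUC) above the fasting
#' baseline, the standard quantity of GI methodology. The baseline is the
#' glucose value at time 0. The curve is linearly interpolated between
#' measurements; area below the baseline is ignored, and segments that
#' cross the baseline are split at the interpolated crossing so only the
#' positive part contributes. With excess values \eqn{d_1 = g_1 - b} and
#' \eqn{d_2 = g_2 - b} over a segment of width \eqn{\Delta t}:
#' both non-negative contributes \eqn{(d_1+d_2)/2\,\Delta t}; a
#' downward crossing contributes \eqn{d_1^2/(d_1-d_2)\,\Delta t/2}; an
#' upward crossing contributes \eqn{d_2^2/(d_2-d_1)\,\Delta t/2}; both
#' negative contributes 0. The result is always non-negative and is
#' invariant to adding a constant to all glucose values.
#'
#' @param time numeric vector of measurement times (min), strictly
#'   increasing, or a [glucose_curve()] object.
#' @param glucose glucose concentrations (mg/dL), same length as `time`;
#'   ignored when `time` is a curve object.
#' @return area in mg.min/dL, a non-negative scalar.
#' @references Brouns F. et al. (2005) Glycaemic index methodology.
#'   Nutrition Research Reviews 18:145-171.
#' @examples
#' incremental_auc(c(0, 15, 30), c(100, 110, 100))  # 150
#' @export
incremental_auc <- function(time, glucose = NULL) {
  if (inherits(time, "glucose_curve")) {
    glucose <- time$glucose_mg_dl
    time <- time$time_min
  }
  .assert_numeric(time, "time")
  .assert_numeric(glucose, "glucose")
  n <- length(time)
  if (n != length(glucose))
    stop("time and glucose must have equal length", call. = FALSE)
  if (n < 2) stop("at least two measurements are required", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  d <- glucose - glucose[1]
  area <- 0
  for (i in seq_len(n - 1)) {
    d1 <- d[i]; d2 <- d[i + 1]; dt <- time[i + 1] - time[i]
    seg <- if (d1 >= 0 && d2 >= 0) {
      (d1 + d2) / 2 * dt
    } else if (d1 >= 0 && d2 < 0) {
      d1^2 / (d1 - d2) * dt / 2
    } else if (d2 >= 0 && d1 < 0) {
      d2^2 / (d2 - d1) * dt / 2
    } else 0
    area <- area + seg
  }
  area
}

#' Reference IAUC for one subject
#'
#' A subject's GI denominator is the mean IAUC over that subject's repeated
#' reference-food tests (glucose solution by default). The study protocol
#' asks for at least two reference tests on separate days; a single test is
#' accepted with a warning, none is an error because GI is then undefined
#' for the subject.
#'
#' @param curves list of [glucose_curve()] objects (any foods; filtered
#'   internally).
#' @param subject_id subject to evaluate.
#' @param reference reserved reference `food_id` (default [GLUCOSE_REF]).
#' @return mean reference IAUC (mg.min/dL).
#' @export
reference_iauc <- function(curves, subject_id, reference = GLUCOSE_REF) {
  keep <- vapply(curves, function(cv) {
    inherits(cv, "glucose_curve") && cv$subject_id == subject_id &&
      cv$food_id == reference
  }, logical(1))
  refs <- curves[keep]
  if (length(refs) == 0)
    stop(sprintf("no %s reference tests for subject %s: GI undefined",
                 reference, subject_id), call. = FALSE)
  if (length(refs) < 2)
    warning(sprintf("only one reference test for subject %s (protocol asks for two)",
                    subject_id), call. = FALSE)
  mean(vapply(refs, incremental_auc, numeric(1)))
}

#' Per-subject glycemic index
#'
#' GI is the IAUC after consuming the test food divided by the same
#' subject's IAUC after consuming the glucose-solution reference,
#' expressed in percent:
#' \deqn{GI = 100 \cdot IAUC_{food} / IAUC_{reference}.}
#'
#' @param food_iauc IAUC after the test food (mg.min/dL), non-negative.
#' @param ref_iauc the subject's reference IAUC, strictly positive.
#' @return GI in percent (vectorized).
#' @examples
#' gi_per_subject(1770, 3540)  # 50
#' @export
gi_per_subject <- function(food_iauc, ref_iauc) {
  .assert_numeric(food_iauc, "food_iauc")
  .assert_numeric(ref_iauc, "ref_iauc")
  if (any(ref_iauc <= 0))
    stop("reference IAUC must be positive", call. = FALSE)
  if (any(food_iauc < 0))
    stop("food IAUC must be non-negative", call. = FALSE)
  100 * food_iauc / ref_iauc
}

#' Summarize per-subject GI values for one food
#'
#' Each food is consumed by several subjects (eight in the validation
#' study); the per-food GI is reported as the arithmetic mean and sample
#' standard deviation (n - 1 denominator) of the per-subject GI ratios.
#'
#' @param gi numeric vector of per-subject GI values, length >= 2.
#' @return list with `mean`, `sd` and `n`.
#' @export
food_gi_summary <- function(gi) {
  .assert_numeric(gi, "gi")
  if (length(gi) < 2)
    stop("at least two per-subject values are required for an SD",
         call. = FALSE)
  list(mean = mean(gi), sd = sd(gi), n = length(gi))
}
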