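# External-validation machinery: transportability, logistic calibration
# with the Hosmer-Lemeshow test, ROC/AUROC discrimination, and GL-eGL
# agreement, overall and by subgroup.

# Two-sample t-test from summary statistics. Pooled variance by default
# (the classical default of the statistical packages of the study's era);
# Welch available via var_equal = FALSE.
.t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                            var_equal = TRUE) {
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- (mean1 - mean2) / se
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

#' Transportability comparison of two cohorts
#'
#' Compares every characteristic of two cohort summaries (means, SDs and
#' sample sizes, e.g. from [cohort_summaries()]): continuous characteristics
#' by a two-sample t-test computed from the summary statistics, and the
#' sex proportion by a chi-square test on the implied counts. A model
#' developed on one cohort is "transportable" when it keeps working on a
#' cohort that differs from the development one; the comparison documents
#' where the cohorts differ.
#'
#' @param cohort_a,cohort_b data frames with columns
#'   `characteristic, block, type, n, mean, sd`.
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return data frame of class `transportability` with one row per
#'   characteristic: means, SDs, ns, test name, statistic, df and
#'   two-sided p-value. Characteristics with a missing SD are skipped
#'   with a warning (proportions excepted).
#' @examples
#' tc <- cohort_summaries()
#' transportability_compare(tc$validation, tc$development)
#' @export
transportability_compare <- function(cohort_a, cohort_b, var_equal = TRUE) {
  stopifnot(is.data.frame(cohort_a), is.data.frame(cohort_b))
  common <- intersect(cohort_a$characteristic, cohort_b$characteristic)
  rows <- lapply(common, function(ch) {
    a <- cohort_a[cohort_a$characteristic == ch, ][1, ]
    b <- cohort_b[cohort_b$characteristic == ch, ][1, ]
    if (a$n < 2 || b$n < 2)
      stop("cohort sizes must be at least 2", call. = FALSE)
    if (identical(a$type, "proportion")) {
      counts <- rbind(c(round(a$n * a$mean / 100),
                        a$n - round(a$n * a$mean / 100)),
                      c(round(b$n * b$mean / 100),
                        b$n - round(b$n * b$mean / 100)))
      ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
      data.frame(characteristic = ch, block = a$block,
                 mean_a = a$mean, sd_a = NA_real_, n_a = a$n,
                 mean_b = b$mean, sd_b = NA_real_, n_b = b$n,
                 test = "chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = if (is.nan(ht$p.value)) 1 else ht$p.value)
    } else {
      if (is.na(a$sd) || is.na(b$sd)) {
        warning("skipping '", ch, "': SD missing", call. = FALSE)
        return(NULL)
      }
      tt <- .t_test_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n, var_equal)
      data.frame(characteristic = ch, block = a$block,
                 mean_a = a$mean, sd_a = a$sd, n_a = a$n,
                 mean_b = b$mean, sd_b = b$sd, n_b = b$n,
                 test = if (var_equal) "t (pooled)" else "t (Welch)",
                 statistic = tt$statistic, df = tt$df,
                 p_value = tt$p_value)
    }
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$p_value >= 0 & out$p_value <= 1))
  class(out) <- c("transportability", "data.frame")
  out
}

#' @export
print.transportability <- function(x, digits = 3, ...) {
  cat("Transportability comparison\n")
  y <- as.data.frame(x)
  y$p_value <- signif(y$p_value, digits)
  y$statistic <- signif(y$statistic, digits)
  print(y[, c("characteristic", "mean_a", "mean_b", "test", "statistic",
              "p_value")], row.names = FALSE)
  invisible(x)
}

#' Univariable logistic regression of an outcome on a score
#'
#' Maximum-likelihood logistic regression (fitted by iteratively
#' reweighted least squares through [stats::glm()]) of a binary outcome
#' on a single score, as used to relate the eGL prediction to the
#' observed high-load events before calibration testing. The fit is
#' checked for convergence (score-equation gradient below `1e-8`) and for
#' complete separation, both reported as errors.
#'
#' @param score numeric predictor.
#' @param outcome binary outcome (0/1 or logical), both classes present,
#'   n >= 10.
#' @return list of class `egl_logistic`: `intercept`, `slope`, `se`
#'   (length-2), `fitted` probabilities, and the underlying `glm` object.
#' @export
logistic_fit <- function(score, outcome) {
  .assert_numeric(score, "score")
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L)))
    stop("outcome must be binary (0/1)", call. = FALSE)
  if (length(score) != length(outcome))
    stop("score and outcome lengths differ", call. = FALSE)
  if (length(outcome) < 10)
    stop("at least 10 observations are required", call. = FALSE)
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(outcome ~ score, family = binomial(),
        control = glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation && abs(coef(fit)[2]) > 10 / max(sd(score), 1e-12))
    stop("complete separation: the score perfectly divides the outcomes",
         call. = FALSE)
  if (!fit$converged)
    stop("logistic regression did not converge", call. = FALSE)
  p <- fitted(fit)
  grad <- crossprod(cbind(1, score), outcome - p)
  if (max(abs(grad)) > 1e-8 * length(outcome))
    stop("score equations not solved to tolerance", call. = FALSE)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 se = unname(sqrt(diag(vcov(fit)))),
                 fitted = unname(p),
                 glm = fit),
            class = "egl_logistic")
}

#' @export
print.egl_logistic <- function(x, ...) {
  cat(sprintf("logistic fit: logit(p) = %.4g + %.4g * score (SE %.3g, %.3g)\n",
              x$intercept, x$slope, x$se[1], x$se[2]))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Calibration test for predicted probabilities: subjects are sorted by
#' predicted probability and split into near-equal groups ("deciles of
#' risk", 10 by default); the statistic sums `(O - E)^2 / E` over events
#' and non-events in each group and is referred to a chi-square
#' distribution with `groups - 2` degrees of freedom. Groups whose
#' expected event (or non-event) count is zero are merged into their
#' neighbour with a warning.
#'
#' @param outcome binary outcome vector.
#' @param prob predicted probabilities in (0, 1); `n >= 2 * groups`.
#' @param groups number of risk groups (default 10).
#' @return list of class `hl_test`: `chi2`, `df`, `p_value`, `groups`
#'   (number used after merging) and `table` (per-group n, observed and
#'   expected events, mean predicted probability).
#' @export
hosmer_lemeshow <- function(outcome, prob, groups = 10) {
  outcome <- as.integer(outcome)
  .assert_numeric(prob, "prob")
  if (any(prob <= 0 | prob >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  if (!all(outcome %in% c(0L, 1L)))
    stop("outcome must be binary (0/1)", call. = FALSE)
  n <- length(outcome)
  if (length(prob) != n) stop("length mismatch", call. = FALSE)
  if (n < 2 * groups)
    stop("need at least 2 observations per risk group", call. = FALSE)
  ord <- order(prob)
  bin <- ceiling(seq_len(n) * groups / n)[order(ord)]  # near-equal sizes
  tab <- data.frame(
    n = as.vector(tapply(outcome, bin, length)),
    observed = as.vector(tapply(outcome, bin, sum)),
    expected = as.vector(tapply(prob, bin, sum)),
    mean_prob = as.vector(tapply(prob, bin, mean)))
  # merge groups with a degenerate expected count into the neighbour above
  repeat {
    bad <- which(tab$expected < 1e-10 |
                   (tab$n - tab$expected) < 1e-10)
    if (length(bad) == 0 || nrow(tab) <= 3) break
    i <- bad[1]
    j <- if (i < nrow(tab)) i + 1 else i - 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$mean_prob[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, , drop = FALSE]
    warning("merged a risk group with zero expected count", call. = FALSE)
  }
  g <- nrow(tab)
  chi2 <- sum((tab$observed - tab$expected)^2 / tab$expected +
                ((tab$n - tab$observed) - (tab$n - tab$expected))^2 /
                (tab$n - tab$expected))
  df <- g - 2
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 groups = g, table = tab),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi^2 = %.3f, df = %d, p = %.3f (%d groups)\n",
              x$chi2, x$df, x$p_value, x$groups))
  invisible(x)
}

#' AUROC (C-statistic) with Hanley-McNeil confidence interval
#'
#' Discrimination of a score for a binary outcome: the area under the ROC
#' curve equals the Mann-Whitney concordance probability (ties between a
#' positive and a negative score count one half). The 95% confidence
#' interval uses the Hanley-McNeil standard-error formula, clipped to
#' \[0, 1\].
#'
#' @param score numeric score (higher = more likely positive).
#' @param outcome binary outcome; both classes must be present.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `auroc_result`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @references Hanley J.A., McNeil B.J. (1982) The meaning and use of the
#'   area under a receiver operating characteristic (ROC) curve.
#'   Radiology 143:29-36.
#' @export
auroc <- function(score, outcome, conf_level = 0.95) {
  .assert_numeric(score, "score")
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L)))
    stop("outcome must be binary (0/1)", call. = FALSE)
  n_pos <- sum(outcome == 1L); n_neg <- sum(outcome == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(score)  # midranks handle ties as half-concordances
  auc <- (sum(r[outcome == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 n_pos = n_pos, n_neg = n_neg),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (95%% CI %.3f-%.3f; %d pos / %d neg)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Agreement between measured and estimated glycemic load
#'
#' Pearson correlation (with a two-sided t-distribution p-value) and the
#' simple linear regression `measured = intercept + slope * estimated`,
#' with `R^2 = r^2`.
#'
#' @param measured,estimated numeric vectors of equal length >= 3, each
#'   with positive variance.
#' @return list of class `gl_agreement`: `pearson_r`, `r_p_value`,
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' t4 <- validation_foods()
#' agreement(t4$gl_mean, t4$egl)
#' @export
agreement <- function(measured, estimated) {
  .assert_numeric(measured, "measured")
  .assert_numeric(estimated, "estimated")
  n <- length(measured)
  if (length(estimated) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (sd(measured) == 0 || sd(estimated) == 0)
    stop("zero variance in measured or estimated values", call. = FALSE)
  ct <- cor.test(measured, estimated, method = "pearson")
  fit <- lm(measured ~ estimated)
  structure(list(pearson_r = unname(ct$estimate),
                 r_p_value = ct$p.value,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = unname(ct$estimate)^2,
                 n = n),
            class = "gl_agreement")
}

#' @export
print.gl_agreement <- function(x, ...) {
  cat(sprintf("GL ~ eGL agreement (n = %d):\n", x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g), R^2 = %.3f\n",
              x$pearson_r, x$r_p_value, x$r_squared))
  cat(sprintf("  measured = %.2f + %.2f * estimated\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Calibration and discrimination by subgroup
#'
#' Runs the performance assessment within strata of the event table:
#' events are dichotomised as "observed high GL" (measured GL at or above
#' the high-GL band edge, 20 by default -- the outcome definition is this
#' package's interpretation, the original analysis did not state one), the
#' eGL score enters a univariable logistic fit, and each stratum gets a
#' Hosmer-Lemeshow calibration test (on the fitted probabilities) and an
#' AUROC for the eGL score. The overall stratum is always included.
#' A stratum with a single outcome class (or too few events) is reported
#' as not estimable rather than raising an error.
#'
#' @param events data frame with columns `measured_gl`, `egl`, and (for
#'   the corresponding strata) `sex`, `bmi_kg_m2`, `percent_body_fat`.
#' @param strata subset of `c("sex", "bmi", "body_fat")`; `character(0)`
#'   for overall only.
#' @param bands [glycemic_bands()]; `gl_high_min` defines the outcome.
#' @param bmi_cut BMI cut between normal and overweight/obese (default 23,
#'   the Asian-population convention used in the study).
#' @param fat_cut_m,fat_cut_f percent-body-fat thresholds above which a
#'   subject counts as "above average" (defaults 25 for men, 32 for
#'   women; the original analysis did not print its thresholds).
#' @param hl_groups risk groups for the Hosmer-Lemeshow test.
#' @return data frame of class `subgroup_validation`: one row per stratum
#'   with n, event count, H-L chi-square/df/p, AUROC with CI, and an
#'   `estimable` flag.
#' @export
subgroup_validation <- function(events,
                                strata = c("sex", "bmi", "body_fat"),
                                bands = glycemic_bands(),
                                bmi_cut = 23,
                                fat_cut_m = 25, fat_cut_f = 32,
                                hl_groups = 10) {
  stopifnot(is.data.frame(events),
            all(c("measured_gl", "egl") %in% names(events)))
  if (length(strata) > 0)
    strata <- match.arg(strata, c("sex", "bmi", "body_fat"),
                        several.ok = TRUE)
  outcome <- as.integer(events$measured_gl >= bands$gl_high_min)
  groups <- list(overall = rep(TRUE, nrow(events)))
  if ("sex" %in% strata && "sex" %in% names(events)) {
    groups[["men"]] <- events$sex == "M"
    groups[["women"]] <- events$sex == "F"
  }
  if ("bmi" %in% strata && "bmi_kg_m2" %in% names(events)) {
    groups[[sprintf("bmi<=%g", bmi_cut)]] <- events$bmi_kg_m2 <= bmi_cut
    groups[[sprintf("bmi>%g", bmi_cut)]] <- events$bmi_kg_m2 > bmi_cut
  }
  if ("body_fat" %in% strata && "percent_body_fat" %in% names(events)) {
    cut <- ifelse(events$sex == "M", fat_cut_m, fat_cut_f)
    groups[["body_fat_average"]] <- events$percent_body_fat <= cut
    groups[["body_fat_above_average"]] <- events$percent_body_fat > cut
  }
  rows <- lapply(names(groups), function(nm) {
    sel <- groups[[nm]] & !is.na(groups[[nm]])
    y <- outcome[sel]; s <- events$egl[sel]
    base <- data.frame(stratum = nm, n = sum(sel), n_events = sum(y),
                       hl_chi2 = NA_real_, hl_df = NA_integer_,
                       hl_p = NA_real_, auc = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       estimable = FALSE)
    if (sum(sel) < 2 * hl_groups || length(unique(y)) < 2 ||
        sd(s) == 0)
      return(base)
    ok <- try({
      lf <- logistic_fit(s, y)
      hl <- suppressWarnings(hosmer_lemeshow(y, lf$fitted, hl_groups))
      au <- auroc(s, y)
      base$hl_chi2 <- hl$chi2; base$hl_df <- hl$df; base$hl_p <- hl$p_value
      base$auc <- au$auc; base$ci_low <- au$ci_low; base$ci_high <- au$ci_high
      base$estimable <- TRUE
      base
    }, silent = TRUE)
    if (inherits(ok, "try-error")) base else ok
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subgroup_validation", "data.frame")
  out
}

#' Full external-validation report
#'
#' Runs the complete validation sequence on an event table:
#' transportability of the two cohorts, calibration and discrimination by
#' subgroup, per-food-mean agreement between measured GL and eGL, and the
#' GL x GI classification grid of the food table.
#'
#' @param events per-event data frame (see [subgroup_validation()]); the
#'   per-food agreement uses the mean measured GL by `food_id`.
#' @param foods food summary table (default [validation_foods()]).
#' @param cohorts list with `validation` and `development` summaries
#'   (default [cohort_summaries()]).
#' @param strata passed to [subgroup_validation()]; `character(0)`
#'   restricts the performance table to the overall stratum.
#' @param bands [glycemic_bands()].
#' @param ... further arguments to [subgroup_validation()].
#' @return list of class `egl_validation` with elements
#'   `transportability`, `performance`, `agreement`, `agreement_events`
#'   and `grid`.
#' @export
validate_egl <- function(events, foods = validation_foods(),
                         cohorts = cohort_summaries(),
                         strata = c("sex", "bmi", "body_fat"),
                         bands = glycemic_bands(), ...) {
  trans <- transportability_compare(cohorts$validation, cohorts$development)
  strata_used <- intersect(strata, c("sex", "bmi", "body_fat"))
  perf <- subgroup_validation(events, strata_used, bands = bands, ...)
  per_food <- tapply(events$measured_gl, events$food_id, mean)
  egl_by_food <- tapply(events$egl, events$food_id, mean)
  agr <- agreement(as.numeric(per_food), as.numeric(egl_by_food))
  agr_ev <- agreement(events$measured_gl, events$egl)
  structure(list(transportability = trans, performance = perf,
                 agreement = agr, agreement_events = agr_ev,
                 grid = classification_grid(foods, bands)),
            class = "egl_validation")
}

#' @export
print.egl_validation <- function(x, ...) {
  print(x$transportability)
  cat("\nCalibration / discrimination by stratum:\n")
  print(as.data.frame(x$performance), row.names = FALSE, digits = 3)
  cat("\nPer-food means: ")
  print(x$agreement)
  cat("Per-event pairs: ")
  print(x$agreement_events)
  cat("\n")
  print(x$grid)
  invisible(x)
}
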