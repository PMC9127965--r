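# The estimated glycemic load (eGL) prediction model: a linear model in
# available carbohydrate and fat with quadratic penalties in protein and
# fiber, fitted by ordinary least squares.

#' eGL model coefficients
#'
#' The eGL equation predicts the glycemic load of a serving from its
#' nutrient label alone:
#' \deqn{eGL = a + b(carb - fiber) - c \cdot fat - d \cdot protein^2
#'       - e \cdot fiber^2.}
#' `a` is an intercept in GL units; `b` weights available carbohydrate
#' (g); `c` weights fat (g); `d` and `e` weight squared protein and fiber
#' (g^2). `b` must be positive: carbohydrate raises the predicted load.
#'
#' @param a,b,c,d,e finite numeric coefficients.
#' @return named numeric vector of class `egl_coefficients`.
#' @export
egl_coefficients <- function(a, b, c, d, e) {
  x <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         e = unname(e))
  x <- vapply(x, as.numeric, numeric(1))
  .assert_numeric(x, "coefficients")
  if (x[["b"]] <= 0)
    stop("coefficient b must be positive (carbohydrate raises the load)",
         call. = FALSE)
  structure(x, class = "egl_coefficients")
}

#' @export
print.egl_coefficients <- function(x, ...) {
  cat("eGL coefficients: eGL = a + b*(carb - fiber) - c*fat",
      "- d*protein^2 - e*fiber^2\n")
  print(unclass(x), ...)
  invisible(x)
}

.egl_env <- new.env(parent = emptyenv())

#' Default eGL coefficients
#'
#' The constants of the published eGL equation were not printed; the
#' package recovers them once by least squares on the bundled 24-food
#' table (see [fit_egl()]) and stores the result as a packaged config
#' file, which this function reads. Pass your own [egl_coefficients()] to
#' any function that accepts a `coefficients` argument to override.
#'
#' @return an [egl_coefficients()] object.
#' @export
default_egl_coefficients <- function() {
  if (is.null(.egl_env$default)) {
    cfg <- read.csv(.extdata("egl_coefficients.csv"),
                    stringsAsFactors = FALSE)
    .egl_env$default <- do.call(egl_coefficients,
                                as.list(setNames(cfg$value, cfg$name)))
  }
  .egl_env$default
}

# Design matrix of the eGL equation: {1, carb - fiber, -fat, -protein^2,
# -fiber^2}, so that OLS coefficients land directly on (a, b, c, d, e).
.egl_design <- function(foods) {
  validate_food_table(foods)
  cbind("(a)" = rep(1, nrow(foods)),
        "(b) avail_carb" = foods$carbohydrate_g - foods$fiber_g,
        "(c) -fat" = -foods$fat_g,
        "(d) -protein^2" = -foods$protein_g^2,
        "(e) -fiber^2" = -foods$fiber_g^2)
}

#' Predicted glycemic load from a nutrient label
#'
#' Evaluates the eGL equation for one or more foods.
#'
#' @param foods a food table (see [read_food_table()]).
#' @param coefficients an [egl_coefficients()] object; defaults to the
#'   packaged coefficients.
#' @return numeric vector of eGL predictions (full precision).
#' @examples
#' estimated_gl(validation_foods()[1:3, ])
#' @export
estimated_gl <- function(foods, coefficients = default_egl_coefficients()) {
  stopifnot(inherits(coefficients, "egl_coefficients"))
  drop(.egl_design(foods) %*% as.numeric(coefficients))
}

#' Fit the eGL equation by ordinary least squares
#'
#' Regresses observed (or published) glycemic load values on the eGL
#' regressors \{1, carb - fiber, -fat, -protein^2, -fiber^2\}. At least
#' five foods with linearly independent nutrient profiles are required;
#' a rank-deficient design is an error. On data generated exactly from
#' the equation the coefficients are recovered exactly (up to numerical
#' precision); on the bundled 24-food table the fit recovers the unprinted
#' constants of the published model.
#'
#' @param foods food table with the nutrient columns.
#' @param gl response vector: the GL value to be predicted for each food.
#'   Defaults to the table's `egl` column when present.
#' @return an object of class `egl_model` with `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' fit <- fit_egl(validation_foods())
#' coef(fit)
#' range(residuals(fit))
#' @export
fit_egl <- function(foods, gl = foods$egl) {
  if (is.null(gl)) stop("no response: supply 'gl' or an 'egl' column",
                        call. = FALSE)
  .assert_numeric(gl, "gl")
  X <- .egl_design(foods)
  if (nrow(X) != length(gl))
    stop("response length does not match the food table", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop(sprintf(paste("rank-deficient design (rank %d < 5): need at least",
                       "five foods with distinct nutrient profiles"),
                 qr_x$rank), call. = FALSE)
  beta <- qr.coef(qr_x, gl)
  cf <- egl_coefficients(beta[1], beta[2], beta[3], beta[4], beta[5])
  fitted <- drop(X %*% beta)
  res <- gl - fitted
  tss <- sum((gl - mean(gl))^2)
  structure(list(coefficients = cf,
                 fitted.values = fitted,
                 residuals = res,
                 response = gl,
                 foods = foods,
                 df.residual = nrow(X) - ncol(X),
                 sigma = sqrt(sum(res^2) / max(nrow(X) - ncol(X), 1)),
                 r.squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                 call = match.call()),
            class = "egl_model")
}

#' @export
print.egl_model <- function(x, digits = 5, ...) {
  cat("eGL prediction model (ordinary least squares)\n")
  cat(sprintf("  %d foods, residual SD %.3g, R^2 %.3f\n",
              length(x$response), x$sigma, x$r.squared))
  cat("  coefficients:\n")
  print(signif(unclass(x$coefficients), digits))
  invisible(x)
}

#' @export
coef.egl_model <- function(object, ...) object$coefficients

#' @export
residuals.egl_model <- function(object, ...) object$residuals

#' @rdname fit_egl
#' @param object,x an `egl_model`.
#' @param newdata food table to predict for; omit for fitted values.
#' @param ... unused.
#' @export
predict.egl_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  estimated_gl(newdata, coef(object))
}

#' @export
summary.egl_model <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 n = length(object$response),
                 sigma = object$sigma,
                 r.squared = object$r.squared,
                 max_abs_residual = max(abs(object$residuals)),
                 residual_quartiles = quantile(object$residuals),
                 call = object$call),
            class = "summary.egl_model")
}

#' @export
print.summary.egl_model <- function(x, ...) {
  cat("eGL prediction model fitted by OLS\n\nCall: ")
  print(x$call)
  cat("\nCoefficients:\n")
  print(unclass(x$coefficients))
  cat(sprintf("\nn = %d, residual SD = %.4g, R^2 = %.4f, max|resid| = %.4g\n",
              x$n, x$sigma, x$r.squared, x$max_abs_residual))
  invisible(x)
}

#' @rdname fit_egl
#' @export
plot.egl_model <- function(x, ...) {
  plot(x$fitted.values, x$response,
       xlab = "estimated GL (model)", ylab = "observed GL",
       main = "eGL model: observed vs estimated", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate per-event glycemic loads from an eGL model
#'
#' Draws event-level measured GL values for each food (Normal with the
#' food's `gl_mean`/`gl_sd`, truncated at zero) and pairs them with the
#' model's eGL prediction, mirroring the study design of several subjects
#' consuming each food.
#'
#' @param object an `egl_model`.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed (restores the prior RNG state on exit,
#'   following the [stats::simulate()] convention).
#' @param newdata food table with `gl_mean` and `gl_sd` columns; defaults
#'   to the foods the model was fitted on.
#' @param n_per_food events (subjects) per food, default 8.
#' @param ... unused.
#' @return a data frame (or list of `nsim` data frames) with columns
#'   `replicate, food_id, subject_slot, measured_gl, egl`.
#' @export
simulate.egl_model <- function(object, nsim = 1, seed = NULL,
                               newdata = object$foods, n_per_food = 8, ...) {
  if (!all(c("gl_mean", "gl_sd") %in% names(newdata)))
    stop("'newdata' needs gl_mean and gl_sd columns", call. = FALSE)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  egl <- predict(object, newdata)
  sims <- lapply(seq_len(nsim), function(r) {
    dr <- .draw_gl_events(newdata, n_per_food, floor = 0)
    dr$egl <- rep(egl, each = n_per_food)
    cbind(replicate = r, dr)
  })
  if (nsim == 1) sims[[1]] else sims
}

# Event-level draws shared by simulate.egl_model and simulate_gl_events.
.draw_gl_events <- function(foods, n_per_food, floor = 0) {
  do.call(rbind, lapply(seq_len(nrow(foods)), function(i) {
    data.frame(food_id = foods$food_id[i],
               subject_slot = seq_len(n_per_food),
               measured_gl = .rtnorm(n_per_food, foods$gl_mean[i],
                                     foods$gl_sd[i], floor))
  }))
}
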