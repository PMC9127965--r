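# Glycemic load, class bands and the GI x GL classification grid.

#' GI/GL classification bands
#'
#' The conventional cut-offs: a food is low-GI at GI <= 55 and high-GI at
#' GI >= 70; low-GL at GL <= 10 and high-GL at GL >= 20; medium otherwise.
#' The closed bounds are the ones that generated the published class
#' labels; an alternative open convention ("exceeding 70") can be emulated
#' by shifting the bounds, so the bands are configurable.
#'
#' @param gi_low_max,gi_high_min,gl_low_max,gl_high_min band edges.
#' @return object of class `glycemic_bands`.
#' @export
glycemic_bands <- function(gi_low_max = 55, gi_high_min = 70,
                           gl_low_max = 10, gl_high_min = 20) {
  stopifnot(gi_low_max < gi_high_min, gl_low_max < gl_high_min)
  structure(list(gi_low_max = gi_low_max, gi_high_min = gi_high_min,
                 gl_low_max = gl_low_max, gl_high_min = gl_high_min),
            class = "glycemic_bands")
}

.classify <- function(x, low_max, high_min, what) {
  .assert_numeric(x, what)
  if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
  ifelse(x <= low_max, "low", ifelse(x >= high_min, "high", "medium"))
}

#' Classify foods by glycemic index
#'
#' @param gi GI values (percent), non-negative.
#' @param bands a [glycemic_bands()] object.
#' @return character vector in `{"low", "medium", "high"}`.
#' @examples
#' classify_gi(c(55, 69, 83))
#' @export
classify_gi <- function(gi, bands = glycemic_bands()) {
  .classify(gi, bands$gi_low_max, bands$gi_high_min, "gi")
}

#' Classify foods by glycemic load
#'
#' @param gl GL values per serving, non-negative.
#' @inheritParams classify_gi
#' @return character vector in `{"low", "medium", "high"}`.
#' @examples
#' classify_gl(c(9, 15, 21))
#' @export
classify_gl <- function(gl, bands = glycemic_bands()) {
  .classify(gl, bands$gl_low_max, bands$gl_high_min, "gl")
}

#' Glycemic load of a serving
#'
#' GL quantifies the glycemic effect of one portion:
#' \deqn{GL = GI \times (carbohydrate - fiber) / 100,}
#' where carbohydrate minus dietary fiber is the available carbohydrate in
#' grams per serving.
#'
#' @param gi glycemic index (percent), non-negative.
#' @param carbohydrate_g,fiber_g total carbohydrate and dietary fiber per
#'   serving (g); fiber must not exceed carbohydrate.
#' @return GL (vectorized, full precision; see [round_glycemic()] for the
#'   display convention).
#' @examples
#' glycemic_load(74, 63, 2)   # 45.14, printed as 45
#' glycemic_load(50, 91, 3.3) # 43.85, printed as 44
#' @export
glycemic_load <- function(gi, carbohydrate_g, fiber_g) {
  .assert_numeric(gi, "gi")
  .assert_numeric(carbohydrate_g, "carbohydrate_g")
  .assert_numeric(fiber_g, "fiber_g")
  if (any(gi < 0)) stop("gi must be non-negative", call. = FALSE)
  avail <- carbohydrate_g - fiber_g
  if (any(avail < 0))
    stop("available carbohydrate (carbohydrate - fiber) is negative",
         call. = FALSE)
  gi * avail / 100
}

#' Cross-tabulate foods by GL and GI class
#'
#' Builds the 3 x 3 grid of food names by (GL class, GI class), the layout
#' used to summarise which foods combine, say, a low GI with a high
#' per-serving load.
#'
#' @param summaries data frame with columns `name`, and either
#'   `gi_class`/`gl_class` or `gi_mean`/`gl_mean` (classified on the fly
#'   with `bands`).
#' @param bands a [glycemic_bands()] object, used when class columns are
#'   absent.
#' @return object of class `glycemic_grid`: a list with `counts` (3 x 3
#'   integer matrix, rows = GL class, columns = GI class) and `foods`
#'   (matching matrix of character vectors).
#' @examples
#' grid <- classification_grid(validation_foods())
#' grid$counts
#' @export
classification_grid <- function(summaries, bands = glycemic_bands()) {
  stopifnot(is.data.frame(summaries))
  lv <- c("low", "medium", "high")
  if (nrow(summaries) == 0) {
    gi_cls <- gl_cls <- character(0)
  } else if (all(c("gi_class", "gl_class") %in% names(summaries))) {
    gi_cls <- summaries$gi_class
    gl_cls <- summaries$gl_class
  } else {
    gi_cls <- classify_gi(summaries$gi_mean, bands)
    gl_cls <- classify_gl(summaries$gl_mean, bands)
  }
  stopifnot(all(gi_cls %in% lv), all(gl_cls %in% lv))
  counts <- matrix(0L, 3, 3, dimnames = list(gl = lv, gi = lv))
  foods <- matrix(vector("list", 9), 3, 3, dimnames = list(gl = lv, gi = lv))
  for (i in lv) for (j in lv) {
    sel <- gl_cls == i & gi_cls == j
    counts[i, j] <- sum(sel)
    foods[[i, j]] <- summaries$name[sel]
  }
  structure(list(counts = counts, foods = foods), class = "glycemic_grid")
}

#' @export
print.glycemic_grid <- function(x, ...) {
  cat("GL x GI classification grid (counts):\n")
  print(x$counts)
  for (i in rownames(x$counts)) for (j in colnames(x$counts)) {
    if (x$counts[i, j] > 0)
      cat(sprintf("  %s GL / %s GI: %s\n", i, j,
                  paste(x$foods[[i, j]], collapse = "; ")))
  }
  invisible(x)
}
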