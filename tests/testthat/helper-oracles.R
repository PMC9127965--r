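# Independent oracles and small generators used across the suite.

# Fine-grid numeric integration of max(linear interpolation - baseline, 0).
# Independent of the segment-splitting formulas in incremental_auc():
# evaluates the interpolated excess on a dense grid (original knots
# included so the only error source is the baseline crossing inside a
# subinterval) and applies the trapezoidal rule.
iauc_oracle <- function(time, glucose, step = 0.001) {
  grid <- sort(unique(c(time, seq(min(time), max(time), by = step))))
  g <- approx(time, glucose, xout = grid)$y
  excess <- pmax(g - glucose[1], 0)
  sum(diff(grid) * (head(excess, -1) + tail(excess, -1)) / 2)
}

# Brute-force AUROC: exhaustive pairwise concordance, ties count 1/2.
auc_brute <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random glucose curve on the study grid that can dip below baseline.
random_curve <- function(times = c(0, 15, 30, 45, 60, 90, 120)) {
  baseline <- runif(1, 80, 100)
  excess <- cumsum(rnorm(length(times) - 1, 0, 15))
  c_values <- pmax(c(baseline, baseline + excess), 5)
  list(time = times, glucose = c_values)
}

# Foods with random but valid nutrient profiles.
random_foods <- function(n) {
  carb <- runif(n, 10, 90)
  fiber <- pmin(runif(n, 0, 10), carb)
  data.frame(food_id = sprintf("F%02d", seq_len(n)),
             name = sprintf("food %d", seq_len(n)),
             category = "synthetic",
             serving_g = runif(n, 30, 300),
             energy_kcal = runif(n, 100, 600),
             carbohydrate_g = carb, fiber_g = fiber,
             protein_g = runif(n, 0, 20), fat_g = runif(n, 0, 30))
}
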