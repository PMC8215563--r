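# Power and sample-size arithmetic for meal studies with repeated meals.

#' Standard deviation of per-meal starting food weight
#'
#' @param summaries data frame from [summarize_meals()] (needs column
#'   `start_weight`), or a numeric vector of starting weights.
#' @return sample SD in grams.
#' @export
sd_food_weight <- function(summaries) {
  w <- if (is.data.frame(summaries)) summaries$start_weight else summaries
  if (is.null(w) || length(w) < 2L)
    stop("need at least 2 meals to estimate the SD of food weight")
  sd(w)
}

#' Standard deviation of BLUP eating speeds
#'
#' @param speeds data frame from [extract_meal_speeds()] (column `speed`), or
#'   a numeric vector of per-meal eating speeds in g/s.
#' @return sample SD in g/s.
#' @export
sd_eating_speed <- function(speeds) {
  s <- if (is.data.frame(speeds)) speeds$speed else speeds
  if (is.null(s) || length(s) < 2L)
    stop("need at least 2 meals to estimate the SD of eating speed")
  sd(s)
}

#' Per-group sample size for a two-sample comparison
#'
#' Smallest integer group size giving the requested power for a two-sided
#' two-sample test of a mean difference `delta` when the outcome SD is `sd`.
#' The default closed form is the normal approximation
#' \deqn{n = 2 (z_{1-\alpha/2} + z_{power})^2 (sd/\delta)^2,} rounded up.
#' `method = "t"` instead solves the noncentral-t power equation
#' ([stats::power.t.test()]), which is slightly more conservative.
#'
#' @param sd outcome standard deviation.
#' @param delta true mean difference to detect (same units as `sd`).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param method `"normal"` (closed form, default) or `"t"`.
#' @return integer sample size per group.
#' @examples
#' n_per_group(sd = 123, delta = 61.5)   # 0.5-SD effect -> 63 per group
#' @export
n_per_group <- function(sd, delta, alpha = 0.05, power = 0.80,
                        method = c("normal", "t")) {
  method <- match.arg(method)
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive")
  if (!is.numeric(delta) || delta <= 0) stop("delta must be positive")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (method == "normal") {
    n <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * (sd / delta)^2
    max(1L, as.integer(ceiling(n - 1e-9)))
  } else {
    n <- stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                             power = power, type = "two.sample",
                             alternative = "two.sided")$n
    max(2L, as.integer(ceiling(n - 1e-9)))
  }
}

#' Design effect for k meals per person
#'
#' Clustered observations (several meals from the same person) inflate the
#' required number of meals by `1 + (k - 1) * icc`, where `icc` is the
#' intra-class correlation of meals within participants and `k` the number of
#' meals per person.
#'
#' @param icc intra-class correlation in \[0, 1\].
#' @param k meals per person (>= 1); may be a vector.
#' @return design effect(s).
#' @examples
#' design_effect(0.97, 2:4)   # 1.97 2.94 3.91
#' @export
design_effect <- function(icc, k) {
  if (!is.numeric(icc) || any(icc < 0 | icc > 1))
    stop("icc must be in [0, 1]")
  if (!is.numeric(k) || any(k < 1)) stop("k must be >= 1")
  1 + (k - 1) * icc
}

#' Total meals and individuals needed with k meals per person
#'
#' Scales a base number of meals (the sample size for independent,
#' one-meal-per-person observations) by the design effect, then converts to
#' individuals. Ceilings are applied at each step: meals first, then
#' individuals.
#'
#' @param base_meals meals needed at one meal per person (>= 1).
#' @param icc intra-class correlation of meals within participants.
#' @param k meals per person; may be a vector.
#' @return data frame with columns `k`, `design_effect`, `total_meals`,
#'   `individuals`.
#' @examples
#' clustered_plan(base_meals = 219, icc = 0.97, k = 2:4)
#' @export
clustered_plan <- function(base_meals, icc, k) {
  if (!is.numeric(base_meals) || base_meals < 1)
    stop("base_meals must be >= 1")
  de <- design_effect(icc, k)
  total <- ceiling(de * base_meals - 1e-9)
  data.frame(k = k, design_effect = de, total_meals = as.integer(total),
             individuals = as.integer(ceiling(total / k - 1e-9)))
}

#' Full power analysis for a three-group meal study
#'
#' Combines the pieces: per-group sample sizes for a `effect_sd`-SD difference
#' in starting food weight and in BLUP eating speed, the base number of meals
#' across all groups at one meal per person, and the clustered meals/people
#' trade-off for k meals per person.
#'
#' @param sd_weight SD of starting food weight, grams.
#' @param sd_speed SD of BLUP eating speed, g/s.
#' @param icc intra-class correlation of meals within participants.
#' @param effect_sd standardized effect size to detect (default 0.5 SD).
#' @param alpha two-sided level (default 0.05).
#' @param power target power (default 0.80).
#' @param n_groups number of exposure groups (default 3).
#' @param k meals-per-person values to tabulate (default 2:4).
#' @param base_meals base number of meals for the clustered plan; default
#'   `n_groups * n_per_group(...)` for the eating-speed outcome, but it can be
#'   supplied explicitly.
#' @param method passed to [n_per_group()].
#' @return list of class `power_result`.
#' @export
power_analysis <- function(sd_weight, sd_speed, icc, effect_sd = 0.5,
                           alpha = 0.05, power = 0.80, n_groups = 3,
                           k = 2:4, base_meals = NULL,
                           method = c("normal", "t")) {
  method <- match.arg(method)
  n_w <- n_per_group(sd_weight, effect_sd * sd_weight, alpha, power, method)
  n_s <- n_per_group(sd_speed, effect_sd * sd_speed, alpha, power, method)
  if (is.null(base_meals)) base_meals <- n_groups * n_s
  plan <- clustered_plan(base_meals, icc, k)
  out <- list(sd_weight = sd_weight, sd_speed = sd_speed, icc = icc,
              effect_sd = effect_sd, alpha = alpha, power = power,
              n_groups = n_groups,
              n_per_group_weight = n_w, n_per_group_speed = n_s,
              base_meals = as.integer(base_meals), plan = plan)
  class(out) <- "power_result"
  out
}

#' @exportS3Method base::print
print.power_result <- function(x, ...) {
  cat("Power analysis for a", x$n_groups, "group meal study\n")
  cat(sprintf("  effect: %.2f SD, alpha = %.3f (two-sided), power = %.2f\n",
              x$effect_sd, x$alpha, x$power))
  cat(sprintf("  food weight: SD %.4g g -> %d per group\n",
              x$sd_weight, x$n_per_group_weight))
  cat(sprintf("  eating speed: SD %.4g g/s -> %d per group\n",
              x$sd_speed, x$n_per_group_speed))
  cat(sprintf("  base meals (1 meal/person): %d;  ICC = %.4g\n",
              x$base_meals, x$icc))
  cat("  k meals per person:\n")
  print(x$plan, row.names = FALSE)
  invisible(x)
}
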