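# Synthetic cohorts of within-meal food-removal curves.
#
# Generative model, per participant i, meal j, snapshot k:
#   weight_ijk = (b0 + gI[g(i)] + u0_i + v0_ij)
#              + (b1 + gS[g(i)] + u1_i + v1_ij) * t_ijk
#              + decel * t_ijk^2 + e_ijk,      e_ijk ~ N(0, sigma_e^2)
# with (u0_i, u1_i) and (v0_ij, v1_ij) bivariate normal at the participant
# and meal level respectively. The curve is truncated at the first snapshot
# where the (noise-free) expected weight is no longer positive, then spike
# artifacts are superimposed and weights are floored at 0.

#' Simulation configuration for a meal-curve cohort
#'
#' Bundles the fixed effects, variance components, device-artifact settings
#' and exposure model that define a synthetic cohort. The defaults describe a
#' cohort of young adults eating self-selected ~356 g meals over ~545 s
#' (baseline eating rate 0.653 g/s), with variance dominated by the meal
#' level: marginal start-weight SD sqrt(500 + 14600 + 25) = 123 g, slope SD
#' sqrt(0.002 + 0.088) = 0.3 g/s, and between-meal intra-class correlation
#' about 0.97 at the mean meal duration.
#'
#' @param n_participants number of participants.
#' @param meals_per_participant meals recorded per participant (cluster size k).
#' @param sampling_interval seconds between weight snapshots (> 0).
#' @param max_duration hard cap on meal length, seconds.
#' @param fixed_effects list with elements `intercept` (g), `slope` (g/s,
#'   negative: food is removed), and optional named vectors `group_intercept`
#'   (g) and `group_slope` (g/s) giving per-exposure-level offsets from the
#'   reference level (reference offset 0).
#' @param var_participant_intercept,var_participant_slope,cov_participant
#'   participant-level (co)variances of the random intercept (g^2) and random
#'   slope ((g/s)^2).
#' @param var_meal_intercept,var_meal_slope,cov_meal meal-level analogues.
#' @param var_residual within-meal snapshot noise variance, g^2.
#' @param spike_rate rate of upward "cutlery" spike artifacts, events/second
#'   (homogeneous Poisson; 0 disables).
#' @param spike_mass mass added by a spike, grams.
#' @param spike_duration number of consecutive snapshots a spike persists.
#' @param deceleration optional quadratic term, g/s^2 (<= 0); 0 keeps curves
#'   linear.
#' @param exposure_model list describing participant exposure assignment:
#'   `list(type = "genotype", maf = 0.44)` for Hardy-Weinberg FTO rs9939609
#'   genotypes, or `list(type = "bmi3", probs = c(...))` /
#'   `list(type = "fat3", probs = c(...))` for three-level BMI or dietary-fat
#'   classes with the given class probabilities.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_participants = 10, meals_per_participant = 2)
#' cohort <- simulate_cohort(cfg, seed = 1)
#' head(cohort$curves)
#' @export
sim_config <- function(n_participants = 54,
                       meals_per_participant = 3,
                       sampling_interval = 5,
                       max_duration = 1800,
                       fixed_effects = list(intercept = 355.74, slope = -0.653),
                       var_participant_intercept = 500,
                       var_participant_slope = 0.002,
                       cov_participant = 0,
                       var_meal_intercept = 14600,
                       var_meal_slope = 0.088,
                       cov_meal = 0,
                       var_residual = 25,
                       spike_rate = 0.01,
                       spike_mass = 40,
                       spike_duration = 2,
                       deceleration = 0,
                       exposure_model = list(type = "genotype", maf = 0.44)) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    meals_per_participant = as.integer(meals_per_participant),
    sampling_interval = sampling_interval,
    max_duration = max_duration,
    fixed_effects = fixed_effects,
    var_participant_intercept = var_participant_intercept,
    var_participant_slope = var_participant_slope,
    cov_participant = cov_participant,
    var_meal_intercept = var_meal_intercept,
    var_meal_slope = var_meal_slope,
    cov_meal = cov_meal,
    var_residual = var_residual,
    spike_rate = spike_rate,
    spike_mass = spike_mass,
    spike_duration = as.integer(spike_duration),
    deceleration = deceleration,
    exposure_model = exposure_model
  )
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1, cfg$meals_per_participant >= 1,
    cfg$sampling_interval > 0, cfg$max_duration > 0,
    cfg$var_participant_intercept >= 0, cfg$var_participant_slope >= 0,
    cfg$var_meal_intercept >= 0, cfg$var_meal_slope >= 0,
    cfg$var_residual >= 0, cfg$spike_rate >= 0, cfg$spike_mass > 0,
    cfg$spike_duration >= 1, cfg$deceleration <= 0
  )
  if (!is.list(cfg$fixed_effects) ||
      !all(c("intercept", "slope") %in% names(cfg$fixed_effects)))
    stop("fixed_effects must be a list with 'intercept' and 'slope'")
  if (cfg$fixed_effects$slope >= 0)
    stop("fixed slope must be negative: weight is removed from the plate")
  # covariance matrices must be positive semi-definite
  .chol_psd(cfg$var_participant_intercept, cfg$var_participant_slope,
            cfg$cov_participant)
  .chol_psd(cfg$var_meal_intercept, cfg$var_meal_slope, cfg$cov_meal)
  em <- cfg$exposure_model
  if (!is.list(em) || is.null(em$type) ||
      !em$type %in% c("genotype", "bmi3", "fat3"))
    stop("exposure_model$type must be one of 'genotype', 'bmi3', 'fat3'")
  if (em$type == "genotype") {
    if (is.null(em$maf) || em$maf < 0 || em$maf > 1)
      stop("genotype exposure model needs maf in [0, 1]")
  } else {
    if (is.null(em$probs) || length(em$probs) != 3 || any(em$probs < 0) ||
        abs(sum(em$probs) - 1) > 1e-8)
      stop("three-class exposure model needs 3 probabilities summing to 1")
  }
  invisible(cfg)
}

# square-root factor of a 2x2 covariance matrix; errors if not PSD
.chol_psd <- function(v1, v2, cv) {
  S <- matrix(c(v1, cv, cv, v2), 2L, 2L)
  e <- eigen(S, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(e$values[1]))
  if (any(e$values < -tol))
    stop("covariance matrix (intercept, slope) is not positive semi-definite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2L) %*% t(e$vectors)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Samples FTO rs9939609-style genotype labels with allele frequencies in
#' Hardy-Weinberg proportions: P(A/A) = maf^2, P(A/T) = 2 maf (1 - maf),
#' P(T/T) = (1 - maf)^2, where `maf` is the frequency of the A allele.
#'
#' @param n number of participants.
#' @param maf A-allele frequency in \[0, 1\].
#' @param seed optional integer seed; if supplied the draw is reproducible.
#' @return factor of length `n` with levels `T/T`, `A/T`, `A/A`.
#' @examples
#' table(assign_genotypes(1000, maf = 0.44, seed = 1))
#' @export
assign_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf < 0 || maf > 1)
    stop("maf must be a single number in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  lev <- c("T/T", "A/T", "A/A")
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  factor(sample(lev, n, replace = TRUE, prob = p), levels = lev)
}

#' Exposure levels used by each exposure model
#' @noRd
.exposure_levels <- function(type) {
  switch(type,
    genotype = c("T/T", "A/T", "A/A"),
    bmi3 = c("normal", "overweight", "obese"),
    fat3 = c("low", "medium", "high"),
    stop("unknown exposure type: ", type)
  )
}

.assign_exposure <- function(n, em) {
  lev <- .exposure_levels(em$type)
  if (em$type == "genotype") {
    assign_genotypes(n, em$maf)
  } else {
    factor(sample(lev, n, replace = TRUE, prob = em$probs), levels = lev)
  }
}

#' Superimpose upward spike artifacts on a meal curve
#'
#' Emulates the transient weight increases seen in raw plate-scale recordings
#' when a user rests cutlery (or a hand) on the plate: spike events occur as a
#' homogeneous Poisson process over the meal; each adds `mass` grams to
#' `duration` consecutive snapshots, after which the weight reverts.
#'
#' @param curve data frame for one meal with columns `time_s` and `weight_g`
#'   (additional columns are carried through).
#' @param rate events per second (>= 0); 0 returns the curve unchanged.
#' @param mass grams added per spike.
#' @param duration snapshots a spike persists (>= 1).
#' @param seed optional integer seed.
#' @return The curve with spiked `weight_g`.
#' @examples
#' crv <- data.frame(time_s = 0:10, weight_g = seq(300, 200, by = -10))
#' inject_spikes(crv, rate = 0.2, mass = 40, duration = 1, seed = 3)
#' @export
inject_spikes <- function(curve, rate, mass = 40, duration = 2L, seed = NULL) {
  stopifnot(is.data.frame(curve), all(c("time_s", "weight_g") %in% names(curve)),
            rate >= 0, mass > 0, duration >= 1)
  if (!is.null(seed)) set.seed(seed)
  curve$weight_g <- .spike_weights(curve$weight_g, curve$time_s, rate, mass,
                                   as.integer(duration))
  curve
}

.spike_weights <- function(w, t, rate, mass, duration) {
  if (rate == 0 || length(w) < 2L) return(w)
  span <- t[length(t)] - t[1L]
  n_events <- rpois(1L, rate * span)
  if (n_events == 0L) return(w)
  at <- runif(n_events, min = t[1L], max = t[length(t)])
  for (a in at) {
    i0 <- findInterval(a, t)           # snapshot at or before the event
    idx <- i0:min(i0 + duration - 1L, length(w))
    w[idx] <- w[idx] + mass
  }
  w
}

#' Simulate a cohort of meal curves
#'
#' Runs the hierarchical generative model forward: participant-level random
#' intercepts/slopes, meal-level random intercepts/slopes nested within
#' participants, per-group fixed intercept and eating-rate offsets, Gaussian
#' snapshot noise, truncation of each meal at the first snapshot where the
#' expected plate weight is no longer positive (or at `max_duration`), spike
#' artifacts, and flooring of weights at 0 grams.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; all randomness (exposures, random
#'   effects, noise, spikes) flows from it.
#' @return A list of class `sim_cohort` with elements
#'   \describe{
#'     \item{curves}{long data frame: `participant_id`, `meal_id`, `time_s`,
#'       `weight_g`, one row per snapshot.}
#'     \item{exposures}{data frame: `participant_id`, `exposure`.}
#'     \item{truth}{generating parameters and realized random effects:
#'       `config`, `participants` (u0, u1 per participant) and `meals`
#'       (v0, v1 and the realized noise-free intercept/slope per meal).}
#'   }
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_participants
  k <- config$meals_per_participant
  fe <- config$fixed_effects
  lev <- .exposure_levels(config$exposure_model$type)
  gI <- .group_offsets(fe$group_intercept, lev)
  gS <- .group_offsets(fe$group_slope, lev)

  exposure <- .assign_exposure(np, config$exposure_model)
  Lp <- .chol_psd(config$var_participant_intercept,
                  config$var_participant_slope, config$cov_participant)
  Lm <- .chol_psd(config$var_meal_intercept, config$var_meal_slope,
                  config$cov_meal)

  up <- t(Lp %*% matrix(rnorm(2L * np), 2L))           # u0, u1 per participant
  pid <- sprintf("P%04d", seq_len(np))
  participants <- data.frame(participant_id = pid, exposure = exposure,
                             u0 = up[, 1L], u1 = up[, 2L],
                             stringsAsFactors = FALSE)

  grid_t <- seq(0, config$max_duration, by = config$sampling_interval)
  sde <- sqrt(config$var_residual)
  curves <- vector("list", np * k)
  meals <- vector("list", np * k)
  m <- 0L
  for (i in seq_len(np)) {
    g <- as.character(exposure[i])
    for (j in seq_len(k)) {
      m <- m + 1L
      v <- Lm %*% rnorm(2L)
      a <- fe$intercept + gI[[g]] + up[i, 1L] + v[1L]
      b <- fe$slope + gS[[g]] + up[i, 2L] + v[2L]
      mu <- a + b * grid_t + config$deceleration * grid_t^2
      # truncate at the first snapshot where the expected weight reaches 0
      # (that snapshot is kept: the plate has just been emptied)
      cross <- which(mu <= 0)
      keep <- if (length(cross)) max(min(cross), 2L) else length(grid_t)
      tt <- grid_t[seq_len(keep)]
      w <- mu[seq_len(keep)] + rnorm(keep, 0, sde)
      w <- .spike_weights(w, tt, config$spike_rate, config$spike_mass,
                          config$spike_duration)
      w <- pmax(w, 0)
      mid <- sprintf("M%02d", j)
      curves[[m]] <- data.frame(participant_id = pid[i], meal_id = mid,
                                time_s = tt, weight_g = w,
                                stringsAsFactors = FALSE)
      meals[[m]] <- data.frame(participant_id = pid[i], meal_id = mid,
                               v0 = v[1L], v1 = v[2L],
                               intercept = a, slope = b,
                               duration = tt[length(tt)],
                               stringsAsFactors = FALSE)
    }
  }
  out <- list(
    curves = do.call(rbind, curves),
    exposures = participants[, c("participant_id", "exposure")],
    truth = list(config = config,
                 participants = participants,
                 meals = do.call(rbind, meals))
  )
  rownames(out$curves) <- NULL
  class(out) <- "sim_cohort"
  out
}

.group_offsets <- function(x, lev) {
  out <- setNames(as.list(rep(0, length(lev))), lev)
  if (!is.null(x)) {
    if (is.null(names(x)) || !all(names(x) %in% lev))
      stop("group offsets must be named with exposure levels: ",
           paste(lev, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' @exportS3Method base::print
print.sim_cohort <- function(x, ...) {
  nm <- nrow(unique(x$curves[c("participant_id", "meal_id")]))
  cat("Simulated meal-curve cohort\n")
  cat(sprintf("  participants: %d   meals: %d   snapshots: %d\n",
              nrow(x$exposures), nm, nrow(x$curves)))
  cat(sprintf("  exposure model: %s\n", x$truth$config$exposure_model$type))
  invisible(x)
}
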