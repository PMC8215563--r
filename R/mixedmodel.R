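# Three-level linear mixed model for smoothed meal curves.
#
# weight_ijk = b0 + u0_i + v0_ij + (b1 + u1_i + v1_ij) t_ijk
#            + b2 1[g2] + b3 1[g3] + b4 t 1[g2] + b5 t 1[g3] + e_ijk
# Participants i carry (u0, u1); meals j within participants carry (v0, v1);
# e_ijk has constant variance sigma_e^2. Estimated by REML via lme4. The
# sensitivity variant drops the random slopes and keeps only the two random
# intercepts.

#' Fit the three-level meal-curve model
#'
#' Fits plate weight against time with a three-level exposure (genotype, BMI
#' class or fat class) shifting both the average starting weight and the
#' average eating rate, random intercepts and (optionally) random time slopes
#' for participants and for meals nested within participants, and constant
#' within-meal residual variance. Estimation is by REML (default) through
#' [lme4::lmer()].
#'
#' @param curves long data frame of (smoothed) curves: `participant_id`,
#'   `meal_id`, `time_s`, `weight_g`.
#' @param exposures optional data frame `participant_id`, `exposure` (factor
#'   or character with up to 3 levels). `NULL` fits the unconditional model
#'   (no exposure terms).
#' @param random_slopes `TRUE` for the full model with random eating-rate
#'   slopes at both levels; `FALSE` for the random-intercepts-only
#'   sensitivity model (slope variance terms are omitted entirely, not pinned
#'   at zero).
#' @param reference reference exposure level (default: first level — `T/T`,
#'   `normal` or `low` for the built-in exposure codings).
#' @param REML use REML (default) or ML.
#' @param estimate_cov estimate the intercept-slope covariance at each level
#'   (default); `FALSE` constrains both covariances to zero.
#' @param control an [lme4::lmerControl()] object.
#' @return Object of class `meal_fit`: list with `coefficients` (term,
#'   estimate, se, lower, upper, p — Wald normal 95% intervals),
#'   `vcov_participant`, `vcov_meal` (2x2, or 1x1 without random slopes),
#'   `sigma2_resid`, `reml_loglik`, `blups` (`$participants`: u0/u1 per
#'   participant; `$meals`: v0/v1 per meal), `random_slopes`, `reference`,
#'   `mean_duration` (mean meal duration in the data, the default reference
#'   time for [compute_icc()]), and `model` (the underlying `lmerMod`).
#' @export
fit_meal_model <- function(curves, exposures = NULL, random_slopes = TRUE,
                           reference = NULL, REML = TRUE, estimate_cov = TRUE,
                           control = lme4::lmerControl(optimizer = "bobyqa")) {
  .check_curves(curves)
  d <- curves[, c("participant_id", "meal_id", "time_s", "weight_g")]
  d$participant_id <- as.character(d$participant_id)

  has_exposure <- !is.null(exposures)
  if (has_exposure) {
    stopifnot(all(c("participant_id", "exposure") %in% names(exposures)))
    exposures <- exposures[!duplicated(exposures$participant_id), ]
    miss <- setdiff(unique(d$participant_id),
                    as.character(exposures$participant_id))
    if (length(miss))
      stop("no exposure label for participant(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    expo <- exposures$exposure
    if (!is.factor(expo)) expo <- factor(expo)
    if (!is.null(reference)) expo <- stats::relevel(expo, ref = reference)
    names(expo) <- as.character(exposures$participant_id)
    # a level with no participants in the data makes the design singular
    present <- expo[unique(d$participant_id)]
    empty <- setdiff(levels(expo), as.character(unique(present)))
    if (length(empty))
      stop("exposure level(s) with no participants in the data: ",
           paste(empty, collapse = ", "))
    d$exposure <- expo[d$participant_id]
  }
  if (length(unique(d$participant_id)) < 2L)
    stop("need at least 2 participants")

  d$meal_uid <- factor(paste(d$participant_id, d$meal_id, sep = "\r"))
  d$participant_id <- factor(d$participant_id)

  # Seconds put intercept (~10^2 g) and slope (~10^-1 g/s) scales four orders
  # of magnitude apart, which defeats the optimizer; fit on time scaled to
  # [0, 1] and convert every slope-scale quantity back to per-second units.
  t_scale <- max(d$time_s)
  if (t_scale <= 0) stop("all snapshots at time 0; nothing to fit")
  d$time_sc <- d$time_s / t_scale

  fixed <- if (has_exposure) "weight_g ~ time_sc * exposure" else
    "weight_g ~ time_sc"
  bar <- if (estimate_cov) "|" else "||"
  ran <- if (random_slopes)
    sprintf("(1 + time_sc %s participant_id) + (1 + time_sc %s meal_uid)",
            bar, bar)
  else "(1 | participant_id) + (1 | meal_uid)"
  form <- as.formula(paste(fixed, "+", ran))

  fit <- lme4::lmer(form, data = d, REML = REML, control = control)
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("mixed-model optimizer did not converge (code ",
         fit@optinfo$conv$opt, "): ",
         paste(unlist(fit@optinfo$conv$messages), collapse = "; "))

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  slope_term <- grepl("time_sc", names(beta))
  beta[slope_term] <- beta[slope_term] / t_scale
  se[slope_term] <- se[slope_term] / t_scale
  names(beta) <- sub("time_sc", "time_s", names(beta))
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      lower = unname(beta - z * se),
                      upper = unname(beta + z * se),
                      p = unname(2 * pnorm(-abs(beta / se))),
                      stringsAsFactors = FALSE)

  # rescale variance components: slope variance by 1/t_scale^2, covariance
  # by 1/t_scale; rescaling m slope design columns shifts the restricted
  # log-likelihood by m*log(t_scale) through the log|X'V^-1X| term
  unscale <- function(V) {
    if (nrow(V) == 2L) {
      V[2L, 2L] <- V[2L, 2L] / t_scale^2
      V[1L, 2L] <- V[2L, 1L] <- V[1L, 2L] / t_scale
    }
    V
  }
  vc <- lme4::VarCorr(fit)
  Vp <- unscale(.strip_vc(vc$participant_id))
  Vm <- unscale(.strip_vc(vc$meal_uid))
  ll <- as.numeric(stats::logLik(fit))
  if (REML) ll <- ll - sum(slope_term) * log(t_scale)

  re <- lme4::ranef(fit, condVar = FALSE)
  bp <- re$participant_id
  blup_p <- data.frame(participant_id = rownames(bp),
                       u0 = bp[["(Intercept)"]],
                       u1 = if (random_slopes) bp[["time_sc"]] / t_scale
                            else NA_real_,
                       stringsAsFactors = FALSE)
  bm <- re$meal_uid
  ids <- do.call(rbind, strsplit(rownames(bm), "\r", fixed = TRUE))
  blup_m <- data.frame(participant_id = ids[, 1L], meal_id = ids[, 2L],
                       v0 = bm[["(Intercept)"]],
                       v1 = if (random_slopes) bm[["time_sc"]] / t_scale
                            else NA_real_,
                       stringsAsFactors = FALSE)

  durs <- tapply(d$time_s, d$meal_uid, function(x) max(x) - min(x))
  expo_map <- if (has_exposure)
    setNames(as.character(expo), names(expo)) else NULL

  out <- list(
    coefficients = coefs,
    vcov_participant = Vp,
    vcov_meal = Vm,
    sigma2_resid = stats::sigma(fit)^2,
    reml_loglik = ll,
    blups = list(participants = blup_p, meals = blup_m),
    random_slopes = random_slopes,
    REML = REML,
    reference = if (has_exposure) levels(expo)[1L] else NA_character_,
    exposure_levels = if (has_exposure) levels(expo) else NULL,
    exposure_map = expo_map,
    mean_duration = mean(durs),
    n_participants = nlevels(d$participant_id),
    n_meals = nlevels(d$meal_uid),
    n_snapshots = nrow(d),
    model = fit
  )
  class(out) <- "meal_fit"
  out
}

# variance-covariance block as a plain matrix, attributes dropped
.strip_vc <- function(v) {
  m <- as.matrix(v)
  attr(m, "stddev") <- NULL
  attr(m, "correlation") <- NULL
  dimnames(m) <- lapply(dimnames(m), function(nm) sub("time_sc", "time_s", nm))
  m
}

#' @exportS3Method base::print
print.meal_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Three-level meal-curve model (%s, %s)\n",
              if (x$random_slopes) "random intercepts + slopes"
              else "random intercepts only",
              if (x$REML) "REML" else "ML"))
  cat(sprintf("  %d participants, %d meals, %d snapshots;  logLik = %.4f\n\n",
              x$n_participants, x$n_meals, x$n_snapshots, x$reml_loglik))
  cc <- x$coefficients
  cat("Fixed effects (estimate, 95% CI, p):\n")
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-28s %10.*f  (%.*f, %.*f)  p=%.3g\n", cc$term[i],
                digits, cc$estimate[i], digits, cc$lower[i], digits,
                cc$upper[i], cc$p[i]))
  cat("\nVariance components:\n")
  cat("  participant level:\n")
  print(round(x$vcov_participant, digits))
  cat("  meal level:\n")
  print(round(x$vcov_meal, digits))
  cat(sprintf("  residual: %.*f\n", digits, x$sigma2_resid))
  invisible(x)
}

#' Per-meal BLUP eating speeds
#'
#' The model-implied eating rate of each meal is the negative of its fitted
#' weight slope: the fixed slope for the participant's exposure group plus the
#' participant's and the meal's best linear unbiased predictors (BLUPs) of the
#' random slope. Reported as a positive consumption rate in g/s.
#'
#' @param fit a `meal_fit` from [fit_meal_model()] with `random_slopes = TRUE`.
#' @return data frame `participant_id`, `meal_id`, `speed` (g/s), one row per
#'   meal.
#' @export
extract_meal_speeds <- function(fit) {
  stopifnot(inherits(fit, "meal_fit"))
  if (!fit$random_slopes)
    stop("meal-level slope BLUPs do not exist in a random-intercepts-only fit")
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  b1 <- beta[["time_s"]]
  group_slope <- function(g) {
    if (is.null(fit$exposure_levels) || g == fit$reference) return(b1)
    term <- paste0("time_s:exposure", g)
    b1 + if (term %in% names(beta)) beta[[term]] else 0
  }
  bm <- fit$blups$meals
  bp <- fit$blups$participants
  u1 <- setNames(bp$u1, bp$participant_id)
  gslope <- if (is.null(fit$exposure_map))
    rep(b1, nrow(bm))
  else
    vapply(fit$exposure_map[bm$participant_id], group_slope, numeric(1))
  data.frame(participant_id = bm$participant_id, meal_id = bm$meal_id,
             speed = -(gslope + u1[bm$participant_id] + bm$v1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intra-class correlation of meals within participants
#'
#' Proportion of total plate-weight variance attributable to the meal level.
#' With random slopes the contribution of each level depends on time, so the
#' ICC is evaluated at a reference time t:
#' \deqn{ICC(t) = \frac{\sigma^2_{v0} + t^2 \sigma^2_{v1} + 2 t \sigma_{v01}}
#'   {\sigma^2_{u0} + t^2 \sigma^2_{u1} + 2 t \sigma_{u01} +
#'    \sigma^2_{v0} + t^2 \sigma^2_{v1} + 2 t \sigma_{v01} + \sigma^2_e}}
#' The default reference time is the mean meal duration of the fitted data.
#' For a random-intercepts-only fit the slope terms vanish and the reference
#' time is irrelevant.
#'
#' @param fit a `meal_fit`.
#' @param at_time reference time in seconds (default: mean meal duration).
#' @return ICC in \[0, 1\].
#' @export
compute_icc <- function(fit, at_time = NULL) {
  stopifnot(inherits(fit, "meal_fit"))
  t0 <- if (is.null(at_time)) fit$mean_duration else at_time
  stopifnot(is.numeric(t0), length(t0) == 1L, t0 >= 0)
  lvl_var <- function(V) {
    if (nrow(V) == 1L) return(V[1L, 1L])
    V[1L, 1L] + t0^2 * V[2L, 2L] + 2 * t0 * V[1L, 2L]
  }
  meal <- lvl_var(fit$vcov_meal)
  total <- lvl_var(fit$vcov_participant) + meal + fit$sigma2_resid
  if (total <= 0) stop("total variance is zero; ICC undefined")
  meal / total
}
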