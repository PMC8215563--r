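# Independent oracles and fixture builders shared across tests.

# element-wise running minimum by an explicit loop (oracle for smooth_monotone)
running_min_loop <- function(x) {
  out <- numeric(length(x))
  m <- Inf
  for (i in seq_along(x)) {
    if (x[i] < m) m <- x[i]
    out[i] <- m
  }
  out
}

# Restricted log-likelihood evaluated through the explicitly assembled
# marginal covariance matrix V = Z_p G_p Z_p' + Z_m G_m Z_m' + s2 I.
# Vp/Vm are 2x2 (intercept, slope) or 1x1 (intercept only) matrices.
reml_loglik_direct <- function(curves, exposures = NULL, Vp, Vm, s2) {
  d <- curves
  d$pm <- paste(d$participant_id, d$meal_id)
  if (!is.null(exposures)) {
    d <- merge(d, exposures, by = "participant_id")
    X <- model.matrix(~ time_s * exposure, d)
  } else {
    X <- model.matrix(~ time_s, d)
  }
  Vp <- as.matrix(Vp); Vm <- as.matrix(Vm)
  n <- nrow(d); p <- ncol(X); y <- d$weight_g
  V <- diag(s2, n)
  zcols <- function(idx, G) if (nrow(G) == 2L) cbind(1, d$time_s[idx]) else
    matrix(1, length(idx), 1L)
  for (i in unique(d$participant_id)) {
    idx <- which(d$participant_id == i)
    Z <- zcols(idx, Vp)
    V[idx, idx] <- V[idx, idx] + Z %*% Vp %*% t(Z)
  }
  for (m in unique(d$pm)) {
    idx <- which(d$pm == m)
    Z <- zcols(idx, Vm)
    V[idx, idx] <- V[idx, idx] + Z %*% Vm %*% t(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
                       determinant(XtViX)$modulus + t(r) %*% Vi %*% r))
}

# deterministic single-line cohort: no random effects, no noise, no spikes
line_config <- function(n = 4, meals = 2, intercept = 300, slope = -1,
                        interval = 1, max_dur = 400) {
  sim_config(n_participants = n, meals_per_participant = meals,
             sampling_interval = interval, max_duration = max_dur,
             fixed_effects = list(intercept = intercept, slope = slope),
             var_participant_intercept = 0, var_participant_slope = 0,
             var_meal_intercept = 0, var_meal_slope = 0, var_residual = 0,
             spike_rate = 0)
}

# moderate-variance cohort with a short fixed observation window so that no
# meal is truncated before max_duration (keeps the design non-informative)
recovery_config <- function(n = 100, meals = 3) {
  sim_config(
    n_participants = n, meals_per_participant = meals,
    sampling_interval = 15, max_duration = 180,
    fixed_effects = list(
      intercept = 356, slope = -1,
      group_intercept = c("A/T" = 50, "A/A" = 100),
      group_slope = c("A/T" = -0.15, "A/A" = -0.25)),
    var_participant_intercept = 400, var_participant_slope = 0.01,
    var_meal_intercept = 225, var_meal_slope = 0.0025,
    var_residual = 25, spike_rate = 0,
    exposure_model = list(type = "genotype", maf = 0.44))
}

recovery_truth <- function() {
  c("(Intercept)" = 356, "time_s" = -1, "exposureA/T" = 50,
    "exposureA/A" = 100, "time_s:exposureA/T" = -0.15,
    "time_s:exposureA/A" = -0.25)
}

# non-increasing step curve (flat runs between bites) plus spike positions
# strictly inside flat runs: the setting in which the running-minimum rule
# removes cutlery spikes exactly
step_curve_with_spikes <- function(n_steps = 8, run = 5, mass = 40) {
  w <- rep(seq(300, by = -25, length.out = n_steps), each = run)
  spiked <- w
  flat_interior <- which(seq_along(w) %% run %in% c(2, 3) &
                           seq_along(w) > 1)
  at <- sample(flat_interior, 3)
  spiked[at] <- spiked[at] + mass
  list(clean = w, spiked = spiked, at = at)
}
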