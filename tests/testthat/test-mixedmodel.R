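# three-participant fixture with one participant per genotype
tiny_cohort <- function(seed = 7, n = 3, meals = 2) {
  cfg <- sim_config(n_participants = n, meals_per_participant = meals,
                    sampling_interval = 30, max_duration = 120,
                    fixed_effects = list(intercept = 350, slope = -1),
                    var_participant_intercept = 100,
                    var_participant_slope = 0.01,
                    var_meal_intercept = 50, var_meal_slope = 0.005,
                    var_residual = 9, spike_rate = 0)
  co <- simulate_cohort(cfg, seed = seed)
  if (n == 3)
    co$exposures$exposure <- factor(c("T/T", "A/T", "A/A"),
                                    levels = c("T/T", "A/T", "A/A"))
  co
}

test_that("zero-variance zero-noise data reduce the fit to the true line", {
  co <- simulate_cohort(line_config(n = 6, meals = 2, interval = 20,
                                    max_dur = 300), seed = 2)
  fit <- suppressWarnings(suppressMessages(
    fit_meal_model(co$curves, co$exposures)))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 300, tolerance = 1e-6)
  expect_equal(unname(est["time_s"]), -1, tolerance = 1e-6)
  expect_lt(max(abs(est[!names(est) %in% c("(Intercept)", "time_s")])), 1e-6)
  expect_lt(fit$vcov_participant[1, 1], 1e-4)
  expect_lt(fit$vcov_meal[1, 1], 1e-4)
  expect_lt(fit$sigma2_resid, 1e-4)
  # speeds collapse to the common fixed eating rate
  sp <- extract_meal_speeds(fit)
  expect_equal(sp$speed, rep(1, nrow(sp)), tolerance = 1e-6)
})

test_that("REML log-likelihood matches the assembled-covariance oracle", {
  co <- tiny_cohort()
  fit <- fit_meal_model(co$curves, co$exposures)
  ll <- reml_loglik_direct(co$curves, co$exposures, fit$vcov_participant,
                           fit$vcov_meal, fit$sigma2_resid)
  expect_equal(fit$reml_loglik, ll, tolerance = 1e-8)

  # unconditional and intercepts-only variants against the same oracle
  f0 <- fit_meal_model(co$curves)
  expect_equal(f0$reml_loglik,
               reml_loglik_direct(co$curves, NULL, f0$vcov_participant,
                                  f0$vcov_meal, f0$sigma2_resid),
               tolerance = 1e-8)
  f1 <- suppressMessages(fit_meal_model(co$curves, co$exposures,
                                        random_slopes = FALSE))
  expect_equal(dim(f1$vcov_meal), c(1L, 1L))
  expect_equal(f1$reml_loglik,
               reml_loglik_direct(co$curves, co$exposures,
                                  f1$vcov_participant, f1$vcov_meal,
                                  f1$sigma2_resid),
               tolerance = 1e-8)
})

test_that("the random-slopes model never has lower REML likelihood than the
           nested intercepts-only model", {
  co <- tiny_cohort(seed = 11, n = 6)
  co$exposures$exposure <- factor(rep(c("T/T", "A/T", "A/A"), 2),
                                  levels = c("T/T", "A/T", "A/A"))
  full <- fit_meal_model(co$curves, co$exposures)
  red <- suppressMessages(fit_meal_model(co$curves, co$exposures,
                                         random_slopes = FALSE))
  expect_gte(full$reml_loglik, red$reml_loglik)
})

test_that("estimates are invariant to relabeling of identifiers", {
  co <- tiny_cohort(seed = 13, n = 5)
  co$exposures$exposure <- factor(c("T/T", "A/T", "A/A", "A/T", "T/T"),
                                  levels = c("T/T", "A/T", "A/A"))
  fit1 <- fit_meal_model(co$curves, co$exposures)
  relab <- c(P0001 = "zz9", P0002 = "k", P0003 = "alpha", P0004 = "m2",
             P0005 = "b")
  c2 <- co$curves
  c2$participant_id <- unname(relab[c2$participant_id])
  c2$meal_id <- paste0("meal-", c2$meal_id)
  e2 <- co$exposures
  e2$participant_id <- unname(relab[e2$participant_id])
  fit2 <- fit_meal_model(c2, e2)
  expect_equal(fit2$reml_loglik, fit1$reml_loglik, tolerance = 1e-8)
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-6)
  expect_lt(max(abs(sort(fit2$blups$meals$v1) - sort(fit1$blups$meals$v1))),
            1e-6)
})

test_that("single-replicate recovery tightens as the cohort grows", {
  truth <- recovery_truth()
  for (n in c(25, 100, 400)) {
    co <- simulate_cohort(recovery_config(n = n), seed = 400 + n)
    fit <- fit_meal_model(co$curves, co$exposures)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    se <- setNames(fit$coefficients$se, fit$coefficients$term)
    # each estimate within a 99.7% Wald interval of the generating value
    expect_true(all(abs(est[names(truth)] - truth) <
                      3 * se[names(truth)] + 1e-12),
                info = paste("n =", n))
  }
})

test_that("meal-speed BLUPs shrink and balance within participants", {
  co <- simulate_cohort(recovery_config(n = 40), seed = 77)
  fit <- fit_meal_model(co$curves, co$exposures)
  sp <- extract_meal_speeds(fit)
  expect_equal(nrow(sp), 120)
  expect_true(all(is.finite(sp$speed)))

  # BLUPs shrink: per-meal OLS slope deviations from the group fixed slope
  # dominate the meal-level slope BLUPs on average
  ols <- vapply(split(co$curves, paste(co$curves$participant_id,
                                       co$curves$meal_id, sep = "\r")),
                function(d) unname(coef(lm(weight_g ~ time_s, d))[2]),
                numeric(1))
  ids <- do.call(rbind, strsplit(names(ols), "\r", fixed = TRUE))
  ols_dev <- ols - mean(ols)
  ord <- order(ids[, 1], ids[, 2])
  v1 <- fit$blups$meals$v1[order(fit$blups$meals$participant_id,
                                 fit$blups$meals$meal_id)]
  expect_lt(mean(abs(v1)), mean(abs(ols_dev[ord])))

  # balanced design: meal-level slope BLUPs largely cancel within each
  # participant (their sums are well below the scale of independent draws)
  sums <- tapply(fit$blups$meals$v1, fit$blups$meals$participant_id, sum)
  expect_lt(mean(abs(sums)), 0.5 * sqrt(3) * sd(fit$blups$meals$v1))
})

test_that("ICC limits and domain errors behave as defined", {
  fake <- function(Vp, Vm, s2, dur = 500) {
    structure(list(vcov_participant = Vp, vcov_meal = Vm, sigma2_resid = s2,
                   mean_duration = dur), class = "meal_fit")
  }
  two <- function(a, b, c = 0) matrix(c(a, c, c, b), 2, 2)
  # all variance at the meal level -> ICC 1; none -> ICC 0
  expect_equal(compute_icc(fake(two(0, 0), two(100, 0.01), 0)), 1)
  expect_equal(compute_icc(fake(two(50, 0.1), two(0, 0), 10)), 0)
  expect_error(compute_icc(fake(two(0, 0), two(0, 0), 0)), "zero")
  # time-referenced: slope variance counts more at later reference times
  f <- fake(two(100, 0), two(100, 0.001), 25)
  expect_gt(compute_icc(f, at_time = 1000), compute_icc(f, at_time = 10))
  # closed-form check at one reference time
  expect_equal(compute_icc(f, at_time = 100),
               (100 + 1e4 * 0.001) / (100 + 100 + 1e4 * 0.001 + 25))
})

test_that("estimation errors are explicit", {
  co <- tiny_cohort()
  # an exposure level with no participants is a singular design
  e <- co$exposures
  e$exposure <- factor(c("T/T", "A/T", "A/T"),
                       levels = c("T/T", "A/T", "A/A"))
  expect_error(fit_meal_model(co$curves, e), "A/A")
  # missing exposure labels
  expect_error(fit_meal_model(co$curves, e[1:2, ]), "P0003")
  # speeds require meal-level slope BLUPs
  f1 <- suppressMessages(fit_meal_model(co$curves, co$exposures,
                                        random_slopes = FALSE))
  expect_error(extract_meal_speeds(f1), "random-intercepts-only")
  one <- co$curves[co$curves$participant_id == "P0001", ]
  expect_error(fit_meal_model(one), "2 participants")
})
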