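test_that("genotype draws follow Hardy-Weinberg proportions", {
  n <- 10000
  g <- assign_genotypes(n, maf = 0.44, seed = 1)
  expect_setequal(levels(g), c("T/T", "A/T", "A/A"))
  # closed-form HWE expectation: P(A/A) = maf^2 = 0.1936
  p_aa <- mean(g == "A/A")
  expect_lt(abs(p_aa - 0.1936), 3 * sqrt(0.1936 * (1 - 0.1936) / n))
  # chi-square goodness of fit against HWE proportions over repeated seeds
  expected <- c(0.56^2, 2 * 0.44 * 0.56, 0.44^2)
  for (s in 1:3) {
    tab <- table(assign_genotypes(n, 0.44, seed = s))
    expect_gt(chisq.test(tab, p = expected)$p.value, 0.01)
  }
})

test_that("genotype boundaries and domain errors", {
  expect_true(all(assign_genotypes(100, 0, seed = 1) == "T/T"))
  expect_true(all(assign_genotypes(100, 1, seed = 1) == "A/A"))
  expect_error(assign_genotypes(10, -0.1), "maf")
  expect_error(assign_genotypes(10, 1.5), "maf")
})

test_that("degenerate config yields exact straight lines down to zero", {
  co <- simulate_cohort(line_config(), seed = 5)
  for (key in split(seq_len(nrow(co$curves)),
                    paste(co$curves$participant_id, co$curves$meal_id))) {
    expect_identical(co$curves$weight_g[key], seq(300, 0, by = -1))
    expect_identical(co$curves$time_s[key], seq(0, 300, by = 1))
  }
})

test_that("fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_participants = 8, meals_per_participant = 2)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$curves, b$curves)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$truth$meals, b$truth$meals)
})

test_that("simulated variance decomposes into configured components", {
  cfg <- sim_config(
    n_participants = 500, meals_per_participant = 2,
    sampling_interval = 30, max_duration = 240,
    fixed_effects = list(intercept = 500, slope = -1),
    var_participant_intercept = 400, var_participant_slope = 0.005,
    var_meal_intercept = 225, var_meal_slope = 0.0025,
    var_residual = 1, spike_rate = 0)
  co <- simulate_cohort(cfg, seed = 21)
  # per-meal OLS intercepts: variance ~ participant + meal intercept variance
  ints <- vapply(split(co$curves, paste(co$curves$participant_id,
                                        co$curves$meal_id)),
                 function(d) unname(coef(lm(weight_g ~ time_s, d))[1]),
                 numeric(1))
  expect_lt(abs(var(ints) - 625) / 625, 0.15)
  # realized random effects match their generating variances
  expect_lt(abs(var(co$truth$participants$u0) - 400) / 400, 0.2)
  expect_lt(abs(var(co$truth$meals$v1) - 0.0025) / 0.0025, 0.2)
})

test_that("simulated cohorts match the configured marginal moments", {
  co <- simulate_cohort(sim_config(n_participants = 80), seed = 31)
  su <- summarize_meals(smooth_monotone(co$curves))
  # marginal start-weight mean 355.74 g, SD sqrt(500+14600+25) = 123 g
  expect_lt(abs(mean(su$start_weight) - 355.74), 25)
  expect_lt(abs(sd(su$start_weight) - 123) / 123, 0.15)
  # meals last minutes, not seconds: duration of the order of 545 s
  expect_gt(mean(su$duration), 300)
  expect_lt(mean(su$duration), 1100)
})

test_that("spike injection is a no-op at rate 0 and adds local increases", {
  crv <- data.frame(time_s = 0:20, weight_g = seq(300, 100, by = -10))
  expect_identical(inject_spikes(crv, rate = 0), crv)
  spiked <- inject_spikes(crv, rate = 0.3, mass = 40, duration = 1, seed = 8)
  expect_gt(sum(diff(spiked$weight_g) > 0), 0)   # at least one upward jump
  expect_true(all(spiked$weight_g >= crv$weight_g))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(var_residual = -1))
  expect_error(sim_config(fixed_effects = list(intercept = 300, slope = 1)),
               "negative")
  expect_error(sim_config(var_participant_intercept = 1,
                          var_participant_slope = 1, cov_participant = 2),
               "positive semi-definite")
  expect_error(sim_config(exposure_model = list(type = "bmi3",
                                                probs = c(0.5, 0.5, 0.5))))
})
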