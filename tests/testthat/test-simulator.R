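test_that("covariates have the designed marginals", {
  expect_error(draw_covariates(0), "n must be")
  set.seed(1)
  cv <- draw_covariates(5)
  expect_true(all(cv$x1 %in% c(0, 1)))
  set.seed(42)
  cv <- draw_covariates(100000)
  expect_lt(abs(mean(cv$x1) - 0.5), 0.01)
  expect_lt(abs(mean(cv$x2)), 0.02)
  expect_lt(abs(var(cv$x2) - 1), 0.03)
})

test_that("membership probabilities follow the two-class logistic model", {
  p <- lcj_parameters()
  ## closed form at the origin: expit(-0.5)
  expect_equal(class_membership_probability(0, 0, p)[1, 1],
               exp(-0.5) / (1 + exp(-0.5)), tolerance = 1e-12)
  ## zero coefficients -> uniform over classes
  p0 <- lcj_parameters(membership = matrix(0, 1, 3))
  expect_equal(unname(class_membership_probability(1, 2, p0)[1, ]),
               c(0.5, 0.5), tolerance = 1e-12)
  pr <- class_membership_probability(c(0, 1), c(-1, 2), p)
  expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-12)
})

test_that("latent class draws hit the designed ~50% balance and are reproducible", {
  p <- lcj_parameters()
  ## degenerate: overwhelming intercept forces class 1
  pd <- lcj_parameters(membership = matrix(c(50, 0, 0), 1, 3))
  set.seed(2)
  expect_true(all(assign_latent_classes(draw_covariates(50), pd) == 1L))
  set.seed(7)
  cv <- draw_covariates(200000)
  cl <- assign_latent_classes(cv, p)
  expect_lt(abs(mean(cl == 1) - 0.5), 0.01)
  set.seed(11); a <- assign_latent_classes(cv[1:100, ], p)
  set.seed(11); b <- assign_latent_classes(cv[1:100, ], p)
  expect_identical(a, b)
})

test_that("trajectory function is the linear predictor plus random intercept", {
  p <- lcj_parameters()
  expect_equal(trajectory_value(p, 1, b = 0, x1 = 0, x2 = 0, t = 0), 1.0)
  expect_equal(trajectory_value(p, 1, b = 0, x1 = 0, x2 = 0, t = 1), 0.0)
  expect_equal(trajectory_value(p, 2, b = 0.3, x1 = 1, x2 = -1, t = 2), 1.8)
})

test_that("longitudinal measurements are trajectory plus class-specific noise", {
  p <- lcj_parameters()
  p0 <- lcj_parameters(resid_variance = c(1e-12, 1e-12))
  set.seed(3)
  sim <- simulate_longitudinal(p0, 1, b = 0.4, x1 = 1, x2 = 0, grid = c(0, 1, 2))
  expect_equal(sim$values,
               trajectory_value(p0, 1, 0.4, 1, 0, c(0, 1, 2)), tolerance = 1e-5)
  expect_length(simulate_longitudinal(p, 1, 0, 0, 0, seq(0, 5, 0.5))$values, 11L)
  set.seed(4)
  y <- trajectory_value(p, 1, 0, 0, 0, 0) + rnorm(1e5, 0, sqrt(p$resid_variance[1]))
  expect_lt(abs(mean(y) - 1), 0.011)
  expect_lt(abs(var(y) - 1), 0.02)
})

test_that("cumulative hazard matches closed forms and brute-force integration", {
  p <- lcj_parameters()
  expect_equal(cumulative_hazard(0, p, 1, 0, 0, 0), 0)
  expect_error(cumulative_hazard(-1, p, 1, 0, 0, 0), "t must be")
  ## gamma=0, alpha=1, lambda=0.001, delta x1 = 0: H(2) = 0.002
  p_exp <- lcj_parameters(weibull_shape = c(1, 1), treatment_effect = c(0, 0))
  expect_equal(cumulative_hazard(2, p_exp, 1, x1 = 0, x2 = 0, b = 0), 0.002,
               tolerance = 1e-12)
  ## alpha=0.6, gamma=0.5: brute-force Riemann oracle (midpoint rule on the
  ## singularity-removing substitution s = w^(1/alpha)), 1e6 panels
  p5 <- lcj_parameters(association = c(0.5, 0.5))
  alpha <- 0.6; cc <- 0.5 * (-1)
  wmax <- 3^alpha; h <- wmax / 1e6
  w <- (seq_len(1e6) - 0.5) * h
  I_rie <- sum(exp(cc * w^(1 / alpha))) * h / alpha
  eta0 <- 0.5 * 1 + 0.5 * (1 + 0.5 * 1 + 1 * 0 + 0)
  H_rie <- alpha * 0.001 * exp(eta0) * I_rie
  H_pkg <- cumulative_hazard(3, p5, 1, x1 = 1, x2 = 0, b = 0)
  expect_lt(abs(H_pkg / H_rie - 1), 1e-6)
  ## adaptive-quadrature path agrees
  expect_equal(cumulative_hazard(3, p5, 1, 1, 0, 0, method = "adaptive"),
               H_pkg, tolerance = 1e-9)
  ## nondecreasing and continuous in t
  tt <- seq(0, 6, by = 0.01)
  H <- cumulative_hazard(tt, p5, 1, 1, 0.3, -0.2)
  expect_true(all(diff(H) >= 0))
  expect_lt(max(abs(diff(H))), 0.05)
})

test_that("event-time inversion solves H(T) = -log(u)", {
  ## closed-form exponential inversion
  p_exp <- lcj_parameters(weibull_shape = c(1, 1), treatment_effect = c(0, 0))
  expect_equal(simulate_event_time(exp(-0.002), p_exp, 1, 0, 0, 0), 2,
               tolerance = 1e-9)
  expect_error(simulate_event_time(0, p_exp, 1, 0, 0, 0), "strictly in")
  ## gamma=0, alpha=0.6 Weibull closed form vs the package's inversion
  p_w <- lcj_parameters()
  u <- c(0.9, 0.5, 0.2)
  T_cf <- (-log(u) / 0.001)^(1 / 0.6)
  expect_equal(simulate_event_time(u, p_w, 1, 0, 0, 0), T_cf, tolerance = 1e-6)
  ## numeric root-finding path (gamma != 0): uniroot oracle + defining property
  p5 <- lcj_parameters(association = c(0.5, 0.5),
                       weibull_scale = c(0.5, 0.15))
  set.seed(5)
  u <- runif(200); x1 <- rbinom(200, 1, 0.5); x2 <- rnorm(200); b <- rnorm(200)
  for (g in 1:2) {
    T_ <- simulate_event_time(u, p5, g, x1, x2, b)
    fin <- is.finite(T_)
    H <- vapply(which(fin), function(i)
      cumulative_hazard(T_[i], p5, g, x1[i], x2[i], b[i]), numeric(1))
    expect_lt(max(abs(H + log(u[fin]))), 1e-8)
  }
  i <- which(fin)[1]
  oracle <- uniroot(function(t)
    cumulative_hazard(t, p5, 2, x1[i], x2[i], b[i]) + log(u[i]),
    c(1e-12, 100), tol = 1e-12)$root
  expect_equal(simulate_event_time(u[i], p5, 2, x1[i], x2[i], b[i]), oracle,
               tolerance = 1e-6)
})

test_that("censoring is uniform on [2.5, 5.5] and the minimum is observed", {
  des <- lcj_design(10)
  set.seed(6)
  one <- apply_censoring(0.1, des)
  expect_equal(one$observed_time, 0.1)
  expect_equal(one$event, 1L)
  inf <- apply_censoring(Inf, des)
  expect_equal(inf$event, 0L)
  expect_true(inf$observed_time >= 2.5 && inf$observed_time <= 5.5)
  many <- apply_censoring(rep(Inf, 1e5), des)
  expect_lt(abs(mean(many$observed_time) - 4), 0.01)
})

test_that("generated datasets respect the design contracts and the seed", {
  p5 <- calibrated_params(0.5)
  d <- generate_dataset(lcj_design(150, seed = 31), p5)
  expect_s3_class(d, "lcj_data")
  expect_equal(nrow(d$survival), 150L)
  ni <- table(d$longitudinal$subject_id)
  expect_true(all(ni >= 1 & ni <= 11))
  expect_true(all(d$survival$observed_time <= 5.5))
  expect_true(all(d$longitudinal$time %in% seq(0, 5, 0.5)))
  obs <- d$survival$observed_time[d$longitudinal$subject_id]
  expect_true(all(d$longitudinal$time <= obs))
  expect_equal(d$survival$observed_time,
               pmin(d$survival$true_event_time, d$survival$censoring_time))
  expect_equal(d$survival$event,
               as.integer(d$survival$true_event_time <= d$survival$censoring_time))
  ## byte-identical CSV export for identical seeds
  d2 <- generate_dataset(lcj_design(150, seed = 31), p5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  s1 <- tempfile(fileext = ".csv"); s2 <- tempfile(fileext = ".csv")
  write_dataset(d, f1, s1); write_dataset(d2, f2, s2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(s1), readLines(s2))
  rt <- read_dataset(f1, s1)
  expect_equal(rt$longitudinal$value, d$longitudinal$value)
})

test_that("simulated event times follow the closed-form Weibull law when gamma = 0", {
  p <- lcj_parameters(weibull_scale = c(0.15, 0.15),
                      treatment_effect = c(0, 0))
  set.seed(8)
  u <- runif(1e5)
  T_ <- simulate_event_time(u, p, 1, x1 = 0, x2 = 0, b = 0)
  ks <- suppressWarnings(
    stats::ks.test(T_, function(q) 1 - exp(-0.15 * q^0.6)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("scale calibration reaches the target censoring rate", {
  p5 <- lcj_parameters(association = c(0.5, 0.5))
  des <- lcj_design(600)
  cal <- calibrate_scale(p5, des, 0.6, seed = 9)
  expect_true(all(abs(cal$achieved - 0.6) < 0.02))
  ## fixed point: recalibrating the calibrated profile is a no-op
  cal2 <- calibrate_scale(cal$params, des, mean(cal$achieved), seed = 9)
  expect_lt(abs(log(cal2$multiplier)), 0.2)
  expect_error(calibrate_scale(p5, des, 1e-9), "calibration-failure")
  expect_error(calibrate_scale(p5, des, 1.2), "target_censoring")
  ## per-class calibration balances the classes
  calp <- calibrate_scale(p5, des, 0.6, seed = 9, per_class = TRUE)
  expect_length(calp$achieved, 2L)
  expect_true(all(abs(calp$achieved - 0.6) < 0.03))
})
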