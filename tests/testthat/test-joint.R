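test_that("the joint likelihood factorises exactly when gamma = 0", {
  p <- calibrated_params(0)
  d <- generate_dataset(lcj_design(40, seed = 71), p)
  sub <- class_subset(d, 1)
  pre <- lcjoint:::lmm_precompute(sub$longitudinal)
  sv <- lcjoint:::joint_align_surv(pre, sub$survival)
  th <- list(beta = c(1, -1, 0.5, 1), vb = 1, s2 = 1, delta = 0.5,
             gamma = 0, alpha = 0.6, lambda = p$weibull_scale[1])
  joint <- sum(lcjoint:::joint_ll_subjects(th, pre, sv, 15))
  sep <- lmm_loglik(list(beta = th$beta, vb = 1, s2 = 1), sub$longitudinal) +
    sum(lcjoint:::weibull_ll_terms(sv$T, sv$e, 0.5 * sv$x1, 0.6, th$lambda))
  expect_lt(abs(joint - sep), 1e-9)
})

test_that("quadrature agrees with brute-force Monte-Carlo integration", {
  ## three hand-built subjects, alpha = 1 so the oracle hazard is closed form
  th <- list(beta = c(0.5, -0.4, 0.3, 0.8), vb = 0.8, s2 = 0.9,
             delta = 0.4, gamma = 0.5, alpha = 1, lambda = 0.2)
  subs <- list(
    toy_subject(c(0, 0.5, 1), c(0.7, 0.2, 0.1), 1, -0.3, 1.4, 1L),
    toy_subject(c(0, 1, 2, 3), c(0.4, 0, -0.6, -1.2), 0, 0.8, 3.2, 0L),
    toy_subject(0, 1.1, 1, 1.5, 0.6, 1L))
  set.seed(72)
  z <- rnorm(5e5); z <- c(z, -z)           # antithetic draws
  b <- sqrt(th$vb) * z
  cc <- th$gamma * th$beta[2]
  for (s in subs) {
    ll_pkg <- subject_joint_loglik(th, s)
    mu <- th$beta[1] + th$beta[2] * s$times + th$beta[3] * s$x1 + th$beta[4] * s$x2
    M <- outer(b, mu, "+")
    Y <- matrix(s$values, nrow = length(b), ncol = length(mu), byrow = TRUE)
    ll_long <- rowSums(dnorm(Y, M, sqrt(th$s2), log = TRUE))
    zfix <- th$beta[1] + th$beta[3] * s$x1 + th$beta[4] * s$x2
    H <- th$lambda * exp(th$delta * s$x1 + th$gamma * (zfix + b)) *
      expm1(cc * s$observed_time) / cc
    logh <- log(th$lambda) + th$delta * s$x1 +
      th$gamma * (zfix + th$beta[2] * s$observed_time + b)
    w <- exp(ll_long + s$event * logh - H)
    mc <- mean(w)
    se_log <- sd(w) / (mc * sqrt(length(w)))
    expect_lt(abs(ll_pkg - log(mc)), 3 * se_log + 1e-12)
  }
})

test_that("a vanishing random-intercept variance gives the plug-in likelihood", {
  th <- list(beta = c(0.5, -0.4, 0.3, 0.8), vb = 1e-12, s2 = 0.9,
             delta = 0.4, gamma = 0.5, alpha = 1, lambda = 0.2)
  s <- toy_subject(c(0, 0.5, 1), c(0.7, 0.2, 0.1), 1, -0.3, 1.4, 1L)
  mu <- th$beta[1] + th$beta[2] * s$times + th$beta[3] * s$x1 + th$beta[4] * s$x2
  zfix <- th$beta[1] + th$beta[3] * s$x1 + th$beta[4] * s$x2
  cc <- th$gamma * th$beta[2]
  H0 <- th$lambda * exp(th$delta * s$x1 + th$gamma * zfix) *
    expm1(cc * s$observed_time) / cc
  logh0 <- log(th$lambda) + th$delta * s$x1 +
    th$gamma * (zfix + th$beta[2] * s$observed_time)
  plug <- sum(dnorm(s$values, mu, sqrt(th$s2), log = TRUE)) + logh0 - H0
  expect_lt(abs(subject_joint_loglik(th, s) - plug), 1e-6)
})

test_that("the fit is quadrature-converged and has a vanishing score", {
  p1 <- single_class_params(gamma = 0.5, scale = 0.15)
  d <- generate_dataset(lcj_design(120, seed = 73), p1)
  f <- fit_joint(d, se = FALSE)
  pre <- lcjoint:::lmm_precompute(d$longitudinal)
  sv <- lcjoint:::joint_align_surv(pre, d$survival)
  th <- list(beta = unname(f$fixed_effects), vb = f$ranef_variance,
             s2 = f$resid_variance, delta = f$treatment_effect,
             gamma = f$association, alpha = f$weibull_shape,
             lambda = f$weibull_scale)
  ll15 <- sum(lcjoint:::joint_ll_subjects(th, pre, sv, 15))
  ll30 <- sum(lcjoint:::joint_ll_subjects(th, pre, sv, 30))
  expect_lt(abs(ll15 - ll30), 1e-4)
  ## natural-scale finite-difference score at the optimum
  v0 <- c(th$beta, th$vb, th$s2, th$delta, th$gamma, th$alpha, th$lambda)
  fll <- function(v) {
    thv <- list(beta = v[1:4], vb = v[5], s2 = v[6], delta = v[7],
                gamma = v[8], alpha = v[9], lambda = v[10])
    sum(lcjoint:::joint_ll_subjects(thv, pre, sv, 15))
  }
  g <- vapply(seq_along(v0), function(j) {
    h <- 1e-6 * (1 + abs(v0[j])); e <- numeric(10); e[j] <- h
    (fll(v0 + e) - fll(v0 - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)), 1e-5)
})

test_that("generating parameters are recovered within Monte-Carlo error", {
  p1 <- single_class_params(gamma = 0.5, scale = 0.15)
  d <- generate_dataset(lcj_design(2000, seed = 74), p1)
  f <- fit_joint(d)
  est <- c(f$fixed_effects, f$ranef_variance, f$resid_variance,
           f$treatment_effect, f$association, f$weibull_shape, f$weibull_scale)
  truth <- c(1, -1, 0.5, 1, 1, 1, 0.5, 0.5, 0.6, 0.15)
  expect_true(all(abs(est - truth) < 3 * f$se))
  ## no-association data: the association estimate stays near zero
  p0 <- single_class_params(gamma = 0, scale = 0.15)
  d0 <- generate_dataset(lcj_design(600, seed = 75), p0)
  f0 <- fit_joint(d0)
  expect_lt(abs(f0$association), 3 * f0$se[["gamma"]])
})

test_that("event-free data fall back to the longitudinal fit with a warning", {
  p1 <- single_class_params(gamma = 0, scale = 1e-6)
  d <- generate_dataset(lcj_design(40, seed = 76), p1)
  expect_true(all(d$survival$event == 0))
  expect_warning(f <- fit_joint(d), "no events")
  expect_true(is.na(f$association))
  expect_false(f$converged)
})
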