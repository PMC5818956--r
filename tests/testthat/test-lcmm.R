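test_that("single-class latent-class model reduces to the plain mixed model", {
  p1 <- single_class_params(gamma = 0, scale = 0.15)
  d <- generate_dataset(lcj_design(80, seed = 41), p1)
  lmm <- fit_lmm(d$longitudinal, se = FALSE)
  lcmm <- fit_lcmm(d$longitudinal, 1)
  expect_lt(abs(lcmm$loglik - lmm$loglik), 1e-8 * abs(lmm$loglik))
  expect_equal(dim(lcmm$posterior), c(80L, 1L))
  expect_true(all(lcmm$posterior == 1))
})

test_that("EM is monotone, posteriors normalise, and classes are well ordered", {
  p <- calibrated_params(0)
  d <- generate_dataset(lcj_design(150, seed = 42), p)
  f <- fit_lcmm(d$longitudinal, 2, n_starts = 3, seed = 1)
  expect_true(all(diff(f$loglik_trace) > -1e-7 * abs(f$loglik)))
  expect_lt(max(abs(rowSums(f$posterior) - 1)), 1e-10)
  slopes <- vapply(f$class_fits, function(cl) cl$fixed_effects[["time"]],
                   numeric(1))
  expect_true(slopes[1] < slopes[2])   # declining-trajectory class first
  expect_equal(f$bic, -2 * f$loglik + 15 * log(150), tolerance = 1e-8)
})

test_that("posterior probabilities match a direct Bayes-rule evaluation", {
  p <- calibrated_params(0)
  d <- generate_dataset(lcj_design(60, seed = 43), p)
  f <- fit_lcmm(d$longitudinal, 2, n_starts = 2, seed = 2)
  post <- posterior_class_probabilities(f, d$longitudinal)
  expect_equal(dim(post), dim(f$posterior))
  expect_equal(post, f$posterior, tolerance = 1e-8)
  ## independent Bayes-rule oracle on three subjects
  ids <- as.integer(f$subject_ids)[1:3]
  W <- unique(d$longitudinal[c("subject_id", "x1", "x2")])
  for (i in ids) {
    di <- d$longitudinal[d$longitudinal$subject_id == i, ]
    wi <- W[W$subject_id == i, ]
    eta <- f$membership_coefs
    lp <- c(eta %*% c(1, wi$x1, wi$x2), 0)
    pri <- exp(lp) / sum(exp(lp))
    fg <- vapply(f$class_fits, function(cl)
      exp(lmm_loglik(list(beta = cl$fixed_effects, vb = cl$ranef_variance,
                          s2 = cl$resid_variance), di)), numeric(1))
    oracle <- pri * fg / sum(pri * fg)
    expect_equal(unname(post[which(as.integer(f$subject_ids) == i), ]),
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("symmetric mixtures give uninformative posteriors", {
  ## two identical classes with equal priors: every posterior entry is 1/2
  d <- data.frame(subject_id = rep(1:5, each = 3), time = rep(0:2, 5),
                  value = rnorm(15), x1 = 0, x2 = 0)
  pre <- lcjoint:::lmm_precompute(d)
  logf <- lcjoint:::lmm_ll_subjects(pre, c(0.5, 0.1, 0, 0), 1, 1)
  lp <- cbind(logf, logf) + log(0.5)
  post <- exp(lp - lcjoint:::logsumexp_rows(lp))
  expect_equal(unname(post), matrix(0.5, 5, 2), tolerance = 1e-12)
})

test_that("modal assignment takes the first maximal class", {
  expect_equal(assign_modal_class(rbind(c(0.9, 0.1))), 1L)
  expect_equal(assign_modal_class(rbind(c(0.5, 0.5))), 1L)
  m <- rbind(c(0.2, 0.8), c(0.7, 0.3))
  expect_equal(assign_modal_class(m[, 2:1]), 3L - assign_modal_class(m))
})

test_that("misclassification is permutation-minimised", {
  expect_equal(misclassification_rate(c(1, 2, 1), c(1, 2, 1)), 0)
  expect_equal(misclassification_rate(c(1, 2, 1, 2), c(2, 1, 2, 1)), 0)
  expect_equal(misclassification_rate(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.25)
  expect_error(misclassification_rate(1:3, 1:4), "length")
  ## relabeling invariance with three classes
  set.seed(44)
  truth <- sample(1:3, 60, replace = TRUE)
  noisy <- ifelse(runif(60) < 0.2, sample(1:3, 60, TRUE), truth)
  pm <- c(3L, 1L, 2L)
  expect_equal(misclassification_rate(truth, noisy),
               misclassification_rate(truth, pm[noisy]))
})

test_that("classification improves with the sample size on average", {
  p <- calibrated_params(0)
  mis <- sapply(c(150, 600), function(N) {
    mean(sapply(1:4, function(r) {
      d <- generate_dataset(lcj_design(N, seed = 500 + r), p)
      f <- fit_lcmm(d$longitudinal, 2, n_starts = 3, seed = r)
      misclassification_rate(d$survival$true_class,
                             assign_modal_class(f$posterior))
    }))
  })
  expect_lte(mis[2], mis[1])
})
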