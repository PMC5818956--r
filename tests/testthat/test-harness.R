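fake_result <- function(est, se, assigned, truth_G = 2) {
  r <- lcjoint:::lcj_result_skeleton("PA", truth_G)
  r$estimates[] <- est
  r$ses[] <- se
  r$assigned <- assigned
  r
}

test_that("coverage indicator implements the 95% Wald interval", {
  expect_equal(coverage_indicator(1, 0.5, 1), 1L)
  expect_equal(coverage_indicator(1, 0, 1.01), 0L)
  expect_equal(coverage_indicator(1, 0.5, 2.0), 0L)  # 2.0 > 1 + 1.96*0.5
  expect_equal(coverage_indicator(1, 0.5, 1.97), 1L)
  expect_error(coverage_indicator(1, -0.1, 1), "se must be")
})

test_that("class alignment resolves label switching", {
  truth <- c(1L, 1L, 2L, 2L)
  est <- rbind(class1 = 1:7, class2 = 8:14)
  r <- fake_result(est, est * 0 + 1, assigned = c(1L, 1L, 2L, 2L))
  a <- align_classes(r, truth)
  expect_equal(a$misclassification, 0)
  expect_equal(a$estimates, r$estimates)          # identity when aligned
  r2 <- fake_result(est, est * 0 + 1, assigned = c(2L, 2L, 1L, 1L))
  a2 <- align_classes(r2, truth)
  expect_equal(a2$misclassification, 0)           # fully swapped -> permuted
  expect_equal(unname(a2$estimates[1, ]), unname(est[2, ]))
  ## estimates unchanged as a multiset
  expect_equal(sort(as.vector(a2$estimates)), sort(as.vector(est)))
})

test_that("replication summaries compute the study metrics", {
  p <- lcj_parameters()
  truth <- lcjoint:::true_parameter_matrix(p)
  exact <- lapply(1:3, function(i)
    fake_result(truth, truth * 0 + 0.5, assigned = c(1L, 2L)))
  s <- summarize_replications(exact, p)
  expect_true(all(abs(s$table$bias) < 1e-12))
  expect_true(all(s$table$cp == 1))
  expect_equal(unname(s$ab_pe["longitudinal"]), 0)
  ## two replications at truth +/- d: zero bias, empirical sd d*sqrt(2)
  d <- 0.3
  two <- list(fake_result(truth + d, truth * 0 + 1, c(1L, 2L)),
              fake_result(truth - d, truth * 0 + 1, c(1L, 2L)))
  s2 <- summarize_replications(two, p)
  expect_true(all(abs(s2$table$bias) < 1e-12))
  expect_equal(s2$table$empirical_sd, rep(d * sqrt(2), 14), tolerance = 1e-12)
  expect_error(summarize_replications(two[1], p), "at least 2")
  expect_equal(s2$n_reps_used, 2L)
  expect_equal(s2$n_failed, 0L)
  s3 <- summarize_replications(c(two, list(NULL)), p)
  expect_equal(s3$n_failed, 1L)
})

test_that("PA recovers the per-class fits when classes are far apart", {
  ## widely separated trajectories: classification is error-free and the
  ## two-stage estimates equal the oracle per-class joint fits
  p <- lcj_parameters(beta = rbind(c(8, -1, 0.5, 1), c(-8, 1, -0.5, -1)),
                      association = c(0.2, 0.2),
                      weibull_scale = c(0.15, 0.1))
  d <- generate_dataset(lcj_design(120, seed = 91), p)
  res <- run_pa(d, 2, n_starts = 2, se = FALSE, seed = 5)
  res <- align_classes(res, d$survival$true_class)
  expect_equal(res$misclassification, 0)
  oracle <- fit_joint(class_subset(d, 1), se = FALSE)
  expect_equal(unname(res$estimates[1, 1:4]),
               unname(oracle$fixed_effects), tolerance = 1e-6)
  ## determinism: same data and seed, same result
  res2 <- align_classes(run_pa(d, 2, n_starts = 2, se = FALSE, seed = 5),
                        d$survival$true_class)
  expect_identical(res$estimates, res2$estimates)
})

test_that("the experiment loop produces well-formed summaries", {
  out_dir <- tempfile("exp")
  res <- run_experiment(gammas = 0, sample_sizes = 150, n_reps = 2,
                        approaches = c("PA", "SA"), seed = 77,
                        n_starts = 2, se = TRUE, out_dir = out_dir)
  s <- res$gamma0$N150
  expect_named(s, c("PA", "SA"))
  expect_s3_class(s$PA, "lcj_summary")
  expect_equal(nrow(s$PA$table), 14L)
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "summary_PA_gamma0_N150.csv")))
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(man$seed, 77L)
  expect_equal(length(man$scenarios), 1L)
})

test_that("SA and PA longitudinal estimates agree closely when gamma = 0", {
  p <- calibrated_params(0)
  diffs <- sapply(1:3, function(r) {
    d <- generate_dataset(lcj_design(300, seed = 900 + r), p)
    pa <- align_classes(run_pa(d, 2, n_starts = 2, se = FALSE, seed = r),
                        d$survival$true_class)
    sa <- align_classes(run_sa(d, 2, n_starts = 2, se = FALSE, seed = r),
                        d$survival$true_class)
    mean(abs(pa$estimates[, 1:4] - sa$estimates[, 1:4]))
  })
  expect_lt(mean(diffs), 0.01)
})
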