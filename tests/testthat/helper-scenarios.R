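## Shared fixtures: memoised calibrated study scenarios and small helpers.

.lcj_test_cache <- new.env(parent = emptyenv())

## two-class study profile with scales calibrated to ~60% censoring per class
calibrated_params <- function(gamma) {
  key <- paste0("g", gamma)
  if (is.null(.lcj_test_cache[[key]])) {
    p <- lcj_parameters(association = rep(gamma, 2))
    .lcj_test_cache[[key]] <- calibrate_scale(
      p, lcj_design(600), 0.6, seed = 9, per_class = TRUE)$params
  }
  .lcj_test_cache[[key]]
}

class_subset <- function(d, g) {
  keep <- d$survival$subject_id[d$survival$true_class == g]
  list(longitudinal = d$longitudinal[d$longitudinal$subject_id %in% keep, ],
       survival = d$survival[d$survival$subject_id %in% keep, ])
}

single_class_params <- function(beta = c(1, -1, 0.5, 1), vb = 1, s2 = 1,
                                delta = 0.5, gamma = 0, shape = 0.6,
                                scale = 0.15) {
  lcj_parameters(n_classes = 1, membership = matrix(numeric(0), 0, 3),
                 beta = rbind(beta), ranef_variance = vb, resid_variance = s2,
                 treatment_effect = delta, association = gamma,
                 weibull_shape = shape, weibull_scale = scale)
}

## hand-built toy subject for oracle checks
toy_subject <- function(times, values, x1, x2, obs, event) {
  list(times = times, values = values, x1 = x1, x2 = x2,
       observed_time = obs, event = event)
}

## memoised replication runs shared by the acceptance checks
acceptance_pa_run <- function(gamma, n_reps = 50L) {
  key <- paste0("pa", gamma)
  if (is.null(.lcj_test_cache[[key]])) {
    params <- calibrated_params(gamma)
    results <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      seed <- 20180000L + r
      d <- generate_dataset(lcj_design(600, seed = seed), params)
      res <- try(run_pa(d, 2, n_starts = 5, seed = seed), silent = TRUE)
      if (!inherits(res, "try-error"))
        results[[r]] <- align_classes(res, d$survival$true_class)
    }
    .lcj_test_cache[[key]] <- list(results = results, params = params)
  }
  .lcj_test_cache[[key]]
}

acceptance_jlcm_misclassification <- function(gamma, n_reps = 50L) {
  key <- paste0("jlcm", gamma)
  if (is.null(.lcj_test_cache[[key]])) {
    params <- calibrated_params(gamma)
    .lcj_test_cache[[key]] <- vapply(seq_len(n_reps), function(r) {
      seed <- 20190000L + r
      d <- generate_dataset(lcj_design(600, seed = seed), params)
      f <- fit_jlcm(d, 2, n_starts = 5, seed = seed, se = FALSE)
      misclassification_rate(d$survival$true_class,
                             assign_modal_class(f$posterior))
    }, numeric(1))
  }
  .lcj_test_cache[[key]]
}
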