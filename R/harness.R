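## Replication harness: run the proposed approach (PA), the separate
## approach (SA) and the one-stage JLCM on a dataset, align estimated
## classes with the simulation truth, and aggregate bias / SE / coverage
## / misclassification across replications.

LCJ_PARAM_NAMES <- c("Intercept", "t_ij", "X1", "X2", "var(b)", "surv_X1", "gamma")

lcj_result_skeleton <- function(approach, G) {
  m <- matrix(NA_real_, G, length(LCJ_PARAM_NAMES),
              dimnames = list(paste0("class", seq_len(G)), LCJ_PARAM_NAMES))
  structure(list(approach = approach, n_classes = G,
                 estimates = m, ses = m, assigned = NULL, posterior = NULL,
                 misclassification = NA_real_, skipped = logical(G),
                 fits = vector("list", G), lcmm = NULL, notes = character(0)),
            class = "lcj_result")
}

subset_class <- function(data, members) {
  long <- data$longitudinal
  surv <- data$survival
  list(longitudinal = long[long$subject_id %in% members, , drop = FALSE],
       survival = surv[surv$subject_id %in% members, , drop = FALSE])
}

#' Run the proposed two-stage approach (PA)
#'
#' Stage one classifies subjects with a latent-class linear mixed model
#' on the longitudinal data; stage two fits the shared current-value
#' joint model separately within each modal class.  Classes with fewer
#' than `min_class_size` subjects or without events are skipped and
#' flagged.
#'
#' @param data an `lcj_data` object (or compatible list).
#' @param n_classes number of latent classes for the classification
#'   stage.
#' @param n_starts,seed EM starts and seed passed to [fit_lcmm()].
#' @param n_quad,se passed to [fit_joint()].
#' @param min_class_size smallest class size that is still fitted.
#' @return An object of class `lcj_result` holding per-class estimate and
#'   SE matrices on the canonical parameter grid
#'   (Intercept, t_ij, X1, X2, var(b), surv_X1, gamma).
#' @export
run_pa <- function(data, n_classes = 2L, n_starts = 5L, n_quad = 15L,
                   se = TRUE, min_class_size = 5L, seed = NULL) {
  lc <- fit_lcmm(data$longitudinal, n_classes, n_starts = n_starts, seed = seed)
  assigned <- assign_modal_class(lc$posterior)
  ids <- as.integer(lc$subject_ids)
  res <- lcj_result_skeleton("PA", n_classes)
  res$assigned <- assigned
  res$posterior <- lc$posterior
  res$lcmm <- lc
  for (g in seq_len(n_classes)) {
    members <- ids[assigned == g]
    sub <- subset_class(data, members)
    if (length(members) < min_class_size || sum(sub$survival$event) < 1L) {
      res$skipped[g] <- TRUE
      res$notes <- c(res$notes, sprintf("class %d skipped (n=%d, events=%d)",
        g, length(members), sum(sub$survival$event)))
      next
    }
    jf <- fit_joint(sub, n_quad = n_quad, se = se)
    res$fits[[g]] <- jf
    res$estimates[g, ] <- c(jf$fixed_effects, jf$ranef_variance,
                            jf$treatment_effect, jf$association)
    res$ses[g, ] <- jf$se[c("Intercept", "time", "x1", "x2", "var(b)",
                            "surv_x1", "gamma")]
  }
  res
}

#' Run the separate approach (SA)
#'
#' Same classification stage as [run_pa()], but within each class the
#' longitudinal and survival outcomes are modelled separately: a linear
#' mixed model, and an extended Cox model with the observed measurements
#' as a time-varying covariate (whose coefficient plays the role of the
#' association parameter).
#'
#' @inheritParams run_pa
#' @export
run_sa <- function(data, n_classes = 2L, n_starts = 5L, se = TRUE,
                   min_class_size = 5L, seed = NULL) {
  lc <- fit_lcmm(data$longitudinal, n_classes, n_starts = n_starts, seed = seed)
  assigned <- assign_modal_class(lc$posterior)
  ids <- as.integer(lc$subject_ids)
  res <- lcj_result_skeleton("SA", n_classes)
  res$assigned <- assigned
  res$posterior <- lc$posterior
  res$lcmm <- lc
  for (g in seq_len(n_classes)) {
    members <- ids[assigned == g]
    sub <- subset_class(data, members)
    if (length(members) < min_class_size || sum(sub$survival$event) < 2L) {
      res$skipped[g] <- TRUE
      res$notes <- c(res$notes, sprintf("class %d skipped (n=%d, events=%d)",
        g, length(members), sum(sub$survival$event)))
      next
    }
    lf <- fit_lmm(sub$longitudinal, se = se)
    cp <- suppressWarnings(expand_counting_process(sub$survival, sub$longitudinal))
    cf <- fit_extended_cox_tv(cp)
    res$fits[[g]] <- list(lmm = lf, cox = cf)
    res$estimates[g, ] <- c(lf$fixed_effects, lf$ranef_variance,
                            cf$coefs["x1"], cf$coefs["tv_value"])
    res$ses[g, ] <- c(lf$se[c("(Intercept)", "time", "x1", "x2", "var(b)")],
                      cf$se)
  }
  res
}

#' Run the one-stage JLCM approach
#'
#' Selects the number of classes by BIC over `G_range` (via
#' [select_num_classes()]) and reports the chosen fit's per-class
#' parameters.  The hazard has no trajectory term, so the `gamma` column
#' is absent (NA) by construction.
#'
#' @inheritParams run_pa
#' @param G_range candidate class counts.
#' @param G_report if not `NULL`, report the fit with this many classes
#'   (when available) regardless of the BIC winner, as done when
#'   comparing against approaches run at a fixed class count.
#' @export
run_jlcm_approach <- function(data, G_range = 1:3, G_report = NULL,
                              n_starts = 5L, se = TRUE, seed = NULL) {
  sel <- select_num_classes(data, G_range, n_starts = n_starts, se = se,
                            seed = seed)
  fit <- sel$best_fit
  if (!is.null(G_report)) {
    i <- match(G_report, G_range)
    if (!is.na(i) && !is.null(sel$fits[[i]])) fit <- sel$fits[[i]]
  }
  G <- fit$n_classes
  res <- lcj_result_skeleton("JLCM", G)
  res$assigned <- assign_modal_class(fit$posterior)
  res$posterior <- fit$posterior
  res$fits <- list(fit)
  res$bic_table <- sel$bic_table
  res$best_G <- sel$best_G
  for (g in seq_len(G)) {
    cl <- fit$class_longitudinal[[g]]; cs <- fit$class_survival[[g]]
    res$estimates[g, ] <- c(cl$fixed_effects, cl$ranef_variance,
                            cs$coefs["x1"], NA_real_)
    if (!is.null(cl$se))
      res$ses[g, ] <- c(cl$se[seq_len(4)], cl$se["var(b)"], cs$se["x1"], NA_real_)
  }
  res
}

#' Align estimated classes with the simulation truth
#'
#' Applies the class-label permutation that minimises the
#' misclassification rate against the true labels, re-keys all per-class
#' estimates accordingly, and stores the achieved misclassification.
#'
#' @param result an `lcj_result`.
#' @param truth integer vector of true class labels, in subject order.
#' @export
align_classes <- function(result, truth) {
  G <- result$n_classes
  P <- perms(max(G, max(truth)))
  P <- P[apply(P, 1L, function(pm) all(pm[seq_len(G)] <= G)), , drop = FALSE]
  rates <- apply(P, 1L, function(pm) mean(pm[result$assigned] != truth))
  pm <- P[which.min(rates), ]
  ## pm maps old label -> new label; reorder rows so row g holds class g
  inv <- order(pm[seq_len(G)])
  result$estimates <- result$estimates[inv, , drop = FALSE]
  result$ses <- result$ses[inv, , drop = FALSE]
  result$skipped <- result$skipped[inv]
  result$fits <- result$fits[inv]
  result$assigned <- pm[result$assigned]
  if (!is.null(result$posterior))
    result$posterior <- result$posterior[, inv, drop = FALSE]
  rownames(result$estimates) <- rownames(result$ses) <-
    paste0("class", seq_len(G))
  result$misclassification <- min(rates)
  result
}

#' 95% Wald-interval coverage indicator
#'
#' Returns 1 when `truth` lies in `estimate +/- 1.96 * se`.
#'
#' @param estimate,se,truth numeric (vectorised).
#' @export
coverage_indicator <- function(estimate, se, truth) {
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0")
  as.integer(abs(estimate - truth) <= 1.96 * se)
}

#' Aggregate aligned replication results into the study metrics
#'
#' For every (class, parameter) cell: bias (mean estimate minus truth),
#' empirical SD of the estimates, mean model-based SE, and the coverage
#' probability of the 95% Wald interval.  Submodel aggregates follow the
#' reporting convention of the replication study: AB-PE / ASE-PE of the
#' longitudinal submodel average |bias| / mean SE over
#' `{Intercept, t_ij, X1, X2, var(b)}` of all classes, the survival
#' submodel covers the treatment effect, and the association parameter is
#' reported on its own.
#'
#' @param results list of aligned `lcj_result` objects from the same
#'   approach (failed replications may be `NULL`; they are counted, not
#'   imputed).
#' @param params the generating [lcj_parameters()].
#' @return An object of class `lcj_summary`: `table` (one row per class
#'   and parameter), `ab_pe`, `ase_pe`, `avg_misclassification`,
#'   `n_reps_used`, `n_failed`.
#' @export
summarize_replications <- function(results, params) {
  ok <- !vapply(results, is.null, logical(1))
  n_failed <- sum(!ok)
  results <- results[ok]
  if (length(results) < 2L) stop("need at least 2 successful replications")
  truth <- true_parameter_matrix(params)
  G <- nrow(truth); K <- length(LCJ_PARAM_NAMES)
  R <- length(results)
  est <- array(NA_real_, c(R, G, K))
  ses <- array(NA_real_, c(R, G, K))
  for (r in seq_len(R)) {
    Gr <- min(G, results[[r]]$n_classes)
    est[r, seq_len(Gr), ] <- results[[r]]$estimates[seq_len(Gr), ]
    ses[r, seq_len(Gr), ] <- results[[r]]$ses[seq_len(Gr), ]
  }
  mean_est <- apply(est, c(2, 3), mean, na.rm = TRUE)
  bias <- mean_est - truth
  emp_sd <- apply(est, c(2, 3), sd, na.rm = TRUE)
  mean_se <- apply(ses, c(2, 3), mean, na.rm = TRUE)
  cov <- array(NA_real_, c(R, G, K))
  for (r in seq_len(R))
    cov[r, , ] <- as.numeric(abs(est[r, , ] - truth) <= 1.96 * ses[r, , ])
  cp <- apply(cov, c(2, 3), mean, na.rm = TRUE)
  tab <- data.frame(class = rep(seq_len(G), each = K),
                    parameter = rep(LCJ_PARAM_NAMES, G),
                    true = as.vector(t(truth)),
                    bias = as.vector(t(bias)),
                    empirical_sd = as.vector(t(emp_sd)),
                    mean_se = as.vector(t(mean_se)),
                    cp = as.vector(t(cp)))
  long_idx <- LCJ_PARAM_NAMES %in% c("Intercept", "t_ij", "X1", "X2", "var(b)")
  surv_idx <- LCJ_PARAM_NAMES == "surv_X1"
  gam_idx <- LCJ_PARAM_NAMES == "gamma"
  mis <- vapply(results, function(r)
    if (is.null(r$misclassification)) NA_real_ else r$misclassification,
    numeric(1))
  structure(list(
    table = tab,
    ab_pe = c(longitudinal = mean(abs(bias[, long_idx]), na.rm = TRUE),
              survival = mean(abs(bias[, surv_idx]), na.rm = TRUE),
              gamma = mean(abs(bias[, gam_idx]), na.rm = TRUE)),
    ase_pe = c(longitudinal = mean(mean_se[, long_idx], na.rm = TRUE),
               survival = mean(mean_se[, surv_idx], na.rm = TRUE),
               gamma = mean(mean_se[, gam_idx], na.rm = TRUE)),
    avg_misclassification = mean(mis, na.rm = TRUE),
    n_reps_used = R, n_failed = n_failed),
    class = "lcj_summary")
}

## deterministic per-replication seed stream below 2^31
lcj_rep_seed <- function(master, scenario, rep) {
  as.integer((as.numeric(master) + 7919 * rep + 104729 * scenario) %% 2147483629)
}

#' Run a full simulation experiment
#'
#' Loops over association-parameter and sample-size scenarios, generates
#' `n_reps` datasets per scenario from per-replication derived seeds,
#' runs the requested approaches, aligns classes with the truth and
#' aggregates the metrics.  Before simulating, each scenario's Weibull
#' scales are calibrated to the target censoring rate (see
#' [calibrate_scale()]); set `target_censoring = NULL` to simulate from
#' the profile's scales verbatim.
#'
#' @param gammas association-parameter values, one scenario per value.
#' @param sample_sizes cohort sizes, crossed with `gammas`.
#' @param n_reps replications per scenario.
#' @param approaches subset of `c("PA", "SA", "JLCM")`.
#' @param seed master seed; every replication derives its own stream.
#' @param target_censoring censoring rate the scales are calibrated to,
#'   or `NULL`.
#' @param n_classes classes generated and fitted (JLCM additionally
#'   reports its BIC-selected count).
#' @param n_starts,n_quad,se fitting controls.
#' @param out_dir if not `NULL`, per-scenario summary CSVs and a run
#'   manifest (JSON) are written there.
#' @return nested list `result[[gamma]][[N]][[approach]]` of
#'   `lcj_summary` objects, with a `manifest` attribute.
#' @export
run_experiment <- function(gammas = c(0, 0.2, 0.5),
                           sample_sizes = c(150, 300, 600),
                           n_reps = 1000L,
                           approaches = c("PA", "SA", "JLCM"),
                           seed = 20180101L,
                           target_censoring = 0.6,
                           n_classes = 2L, n_starts = 5L, n_quad = 15L,
                           se = TRUE, out_dir = NULL) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  out <- list()
  manifest <- list(seed = seed, n_reps = n_reps, gammas = gammas,
                   sample_sizes = sample_sizes, approaches = approaches,
                   target_censoring = target_censoring,
                   scenarios = list(), failures = list())
  scen <- 0L
  for (gam in gammas) {
    params <- lcj_parameters(association = rep(gam, n_classes))
    if (!is.null(target_censoring)) {
      cal <- calibrate_scale(params, lcj_design(1000, seed = seed),
                             target_censoring, seed = seed)
      params <- cal$params
      cal_info <- list(multiplier = cal$multiplier, achieved = cal$achieved)
    } else cal_info <- NULL
    gkey <- paste0("gamma", gam)
    out[[gkey]] <- list()
    for (N in sample_sizes) {
      scen <- scen + 1L
      runs <- setNames(vector("list", length(approaches)), approaches)
      for (a in approaches) runs[[a]] <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        rs <- lcj_rep_seed(seed, scen, r)
        d <- generate_dataset(lcj_design(N, seed = rs), params)
        truth <- d$survival$true_class
        for (a in approaches) {
          res <- try(switch(a,
            PA = run_pa(d, n_classes, n_starts = n_starts, n_quad = n_quad,
                        se = se, seed = rs),
            SA = run_sa(d, n_classes, n_starts = n_starts, se = se, seed = rs),
            JLCM = run_jlcm_approach(d, G_range = seq_len(max(2L, n_classes)),
                                     G_report = n_classes,
                                     n_starts = n_starts, se = se, seed = rs)),
            silent = TRUE)
          if (inherits(res, "try-error")) {
            manifest$failures[[length(manifest$failures) + 1L]] <-
              list(gamma = gam, N = N, rep = r, approach = a,
                   message = conditionMessage(attr(res, "condition")))
          } else {
            runs[[a]][[r]] <- align_classes(res, truth)
          }
        }
      }
      sums <- lapply(runs, summarize_replications, params = params)
      out[[gkey]][[paste0("N", N)]] <- sums
      manifest$scenarios[[length(manifest$scenarios) + 1L]] <-
        list(gamma = gam, N = N, calibration = cal_info,
             first_seed = lcj_rep_seed(seed, scen, 1L))
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        for (a in approaches) {
          tb <- sums[[a]]$table
          write.csv(tb, file.path(out_dir,
            sprintf("summary_%s_gamma%s_N%d.csv", a, gam, N)),
            row.names = FALSE)
        }
      }
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  attr(out, "manifest") <- manifest
  out
}
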