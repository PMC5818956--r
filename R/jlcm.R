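## One-stage joint latent class model under conditional independence:
## multinomial-logistic membership, class-specific random-intercept LMM,
## class-specific Weibull proportional hazards with baseline covariates
## only (no trajectory term in the hazard).  Estimated by EM; given the
## class, the longitudinal and survival factors multiply, so the E-step
## posterior is proportional to pi_ig * f_long,g(Y_i) * f_surv,g(T_i,e_i).

jlcm_surv_logf <- function(sv, cls) {
  xb <- cls$delta * sv$x1
  weibull_ll_terms(sv$T, sv$e, xb, cls$alpha, cls$lambda)
}

#' Observed-data log-likelihood of a joint latent class model
#'
#' \deqn{\sum_i \log \sum_g \pi_{ig}(\eta)\, f_{g}(Y_i)\,
#'   h_g(T_i)^{e_i} e^{-H_g(T_i)},}
#' with the random intercept integrated out of the longitudinal density
#' in closed form and no trajectory term in the hazard (conditional
#' independence).
#'
#' @param params list with `eta` ((G-1) x membership-design matrix) and
#'   `classes`, a list of per-class lists `beta`, `vb`, `s2`, `alpha`,
#'   `lambda`, `delta`.
#' @param data `lcj_data` object or list with `longitudinal`, `survival`.
#' @param fixed,membership covariate columns as in [fit_lcmm()].
#' @export
jlcm_observed_loglik <- function(params, data, fixed = c("time", "x1", "x2"),
                                 membership = c("x1", "x2")) {
  long <- data$longitudinal; surv <- data$survival
  pre <- lmm_precompute(long, fixed)
  sv <- joint_align_surv(pre, surv)
  ids <- factor(long$subject_id)
  first <- !duplicated(ids)
  W <- cbind(1, as.matrix(long[first, membership, drop = FALSE]))
  W <- W[order(ids[first]), , drop = FALSE]
  G <- length(params$classes)
  logf <- vapply(params$classes, function(cl)
    lmm_ll_subjects(pre, cl$beta, cl$vb, cl$s2) + jlcm_surv_logf(sv, cl),
    numeric(pre$n))
  logf <- matrix(logf, nrow = pre$n)
  lp <- lcmm_log_prior(W, rbind(params$eta), G) + logf
  out <- sum(logsumexp_rows(lp))
  if (!is.finite(out)) stop("numeric-failure: non-finite JLCM likelihood")
  out
}

jlcm_em_run <- function(pre, sv, W, G, resp, max_iter, tol, warm = NULL) {
  eta <- if (is.null(warm$eta)) matrix(0, G - 1L, ncol(W)) else warm$eta
  lfits <- warm$lfits; sfits <- warm$sfits
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  X1 <- cbind(sv$x1)
  for (iter in seq_len(max_iter)) {
    if (any(colSums(resp) < 1)) stop("degenerate-class: a class has emptied")
    wmat <- pmax(resp, 1e-10)
    lfits <- lapply(seq_len(G), function(g)
      lmm_fit_core(pre, w = wmat[, g],
                   init = if (is.null(lfits)) NULL else lfits[[g]]$theta,
                   max_iter = 100L))
    sfits <- lapply(seq_len(G), function(g)
      weibull_fit_core(sv$T, sv$e, X1, w = wmat[, g],
                       init = if (is.null(sfits)) NULL else sfits[[g]]$theta))
    eta <- lcmm_eta_update(W, eta, resp)
    logf <- vapply(seq_len(G), function(g)
      lmm_ll_subjects(pre, lfits[[g]]$beta, lfits[[g]]$vb, lfits[[g]]$s2) +
        jlcm_surv_logf(sv, list(delta = sfits[[g]]$delta,
                                alpha = sfits[[g]]$alpha,
                                lambda = sfits[[g]]$lambda)),
      numeric(pre$n))
    lp <- lcmm_log_prior(W, eta, G) + logf
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    resp <- exp(lp - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  list(lfits = lfits, sfits = sfits, eta = eta, resp = resp, loglik = ll,
       trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit a joint latent class model by EM
#'
#' Joint mixture of class-specific random-intercept linear mixed models
#' and class-specific Weibull proportional-hazards models, with
#' multinomial-logistic membership, estimated by EM under the
#' conditional-independence assumption.  M-steps are posterior-weighted
#' maximum-likelihood updates (weights below `1e-10` truncated); the
#' membership coefficients take one step-halved Newton-Raphson update per
#' iteration.  Starts, ordering and convergence rules follow
#' [fit_lcmm()].
#'
#' @inheritParams fit_lcmm
#' @param surv_covariates baseline covariates of the class-specific
#'   hazards.
#' @param se compute standard errors from the numerically differentiated
#'   observed information of the observed-data likelihood?  (Costly for
#'   large `G`; switch off inside replication loops that only need
#'   classification.)
#' @return An object of class `lcj_jlcm`: `membership_coefs`,
#'   `class_longitudinal`, `class_survival`, `se`, `posterior`,
#'   `loglik`, `bic`, `converged`, `loglik_trace`.
#' @export
fit_jlcm <- function(data, n_classes, fixed = c("time", "x1", "x2"),
                     membership = c("x1", "x2"), surv_covariates = "x1",
                     n_starts = 5L, max_iter = 500L, tol = 1e-8,
                     short_iter = 30L, se = TRUE, seed = NULL) {
  G <- as.integer(n_classes)
  if (G < 1L) stop("n_classes must be >= 1")
  long <- data$longitudinal; surv <- data$survival
  if (sum(surv$event) < 1L) stop("no events in the data")
  if (!is.null(seed)) set.seed(seed)
  pre <- lmm_precompute(long, fixed)
  pre <- lmm_pre_s2(pre)
  sv <- joint_align_surv(pre, surv)
  ids <- factor(long$subject_id)
  first <- !duplicated(ids)
  W <- cbind(1, as.matrix(long[first, membership, drop = FALSE]))
  W <- W[order(ids[first]), , drop = FALSE]
  colnames(W) <- c("(Intercept)", membership)

  if (G == 1L) {
    lf <- lmm_fit_core(pre)
    sf <- weibull_fit_core(sv$T, sv$e, cbind(sv$x1))
    run <- list(lfits = list(lf), sfits = list(sf),
                eta = matrix(0, 0, ncol(W)), resp = matrix(1, pre$n, 1),
                loglik = lf$loglik + sf$loglik, trace = lf$loglik + sf$loglik,
                converged = lf$converged && sf$converged, n_iter = 1L)
  } else {
    cand <- vector("list", n_starts)
    for (k in seq_len(n_starts)) {
      resp0 <- lcmm_init_resp(long, G, k)
      cand[[k]] <- tryCatch(jlcm_em_run(pre, sv, W, G, resp0, short_iter, tol),
                            error = function(e) list(loglik = -Inf, error = e))
    }
    lls <- vapply(cand, `[[`, numeric(1), "loglik")
    if (all(!is.finite(lls))) stop(conditionMessage(cand[[1]]$error))
    best <- which.max(lls)
    run <- tryCatch(jlcm_em_run(pre, sv, W, G, cand[[best]]$resp,
                                max_iter, tol, warm = cand[[best]]),
                    error = function(e) cand[[best]])
  }

  slope_col <- match("time", pre$names)
  ord <- if (!is.na(slope_col) && G > 1L)
    order(vapply(run$lfits, function(f) f$beta[slope_col], numeric(1)))
  else seq_len(G)
  lfits <- run$lfits[ord]; sfits <- run$sfits[ord]
  resp <- run$resp[, ord, drop = FALSE]
  eta_full <- rbind(run$eta, 0)[ord, , drop = FALSE]
  eta <- sweep(eta_full[-G, , drop = FALSE], 2L, eta_full[G, ], "-")
  if (G > 1L) colnames(eta) <- colnames(W)

  q <- ncol(W); r <- length(surv_covariates)
  p_free <- (G - 1L) * q + G * (pre$p + 2L) + G * (2L + r)
  params <- list(eta = eta, classes = lapply(seq_len(G), function(g)
    list(beta = lfits[[g]]$beta, vb = lfits[[g]]$vb, s2 = lfits[[g]]$s2,
         alpha = sfits[[g]]$alpha, lambda = sfits[[g]]$lambda,
         delta = sfits[[g]]$delta)))

  ## observed-information SEs over all natural-scale free parameters
  se_list <- NULL
  if (se) {
    pk <- function(pr) c(as.vector(pr$eta),
                         unlist(lapply(pr$classes, function(cl)
                           c(cl$beta, cl$vb, cl$s2, cl$alpha, cl$lambda, cl$delta))))
    upk <- function(v) {
      ne <- (G - 1L) * q
      eta2 <- matrix(v[seq_len(ne)], G - 1L, q)
      rest <- v[-seq_len(ne)]
      k <- pre$p + 4L + r
      classes <- lapply(seq_len(G), function(g) {
        vv <- rest[(g - 1L) * k + seq_len(k)]
        list(beta = vv[seq_len(pre$p)], vb = vv[pre$p + 1L], s2 = vv[pre$p + 2L],
             alpha = vv[pre$p + 3L], lambda = vv[pre$p + 4L],
             delta = vv[pre$p + 4L + seq_len(r)])
      })
      list(eta = eta2, classes = classes)
    }
    nll_nat <- function(v) {
      pr <- upk(v)
      bad <- any(vapply(pr$classes, function(cl)
        cl$vb < 0 || cl$s2 <= 0 || cl$alpha <= 0 || cl$lambda <= 0, logical(1)))
      if (bad) return(1e10)
      out <- try(-jlcm_observed_loglik(pr, data, fixed, membership), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) 1e10 else out
    }
    v0 <- pk(params)
    H <- try(optimHess(v0, nll_nat), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error")) {
        dv <- diag(V)
        sev <- rep(NA_real_, length(v0))
        sev[dv > 0] <- sqrt(dv[dv > 0])
        se_list <- upk(sev)
      }
    }
  }

  class_long <- lapply(seq_len(G), function(g)
    list(fixed_effects = lfits[[g]]$beta, ranef_variance = lfits[[g]]$vb,
         resid_variance = lfits[[g]]$s2,
         se = if (is.null(se_list)) NULL else
           c(se_list$classes[[g]]$beta, "var(b)" = se_list$classes[[g]]$vb,
             sigma2 = se_list$classes[[g]]$s2)))
  class_surv <- lapply(seq_len(G), function(g)
    list(shape = sfits[[g]]$alpha, scale = sfits[[g]]$lambda,
         coefs = setNames(sfits[[g]]$delta, surv_covariates),
         se = if (is.null(se_list)) NULL else
           c(shape = se_list$classes[[g]]$alpha,
             scale = se_list$classes[[g]]$lambda,
             setNames(se_list$classes[[g]]$delta, surv_covariates))))

  structure(list(n_classes = G, membership_coefs = eta,
                 class_longitudinal = class_long, class_survival = class_surv,
                 posterior = unname(resp), loglik = run$loglik,
                 bic = -2 * run$loglik + p_free * log(pre$n),
                 converged = run$converged, n_starts_used = if (G == 1L) 1L else n_starts,
                 n_iter = run$n_iter, loglik_trace = run$trace,
                 params = params, fixed = fixed, membership = membership,
                 surv_covariates = surv_covariates,
                 subject_ids = pre$ids, n_subjects = pre$n),
            class = "lcj_jlcm")
}

#' Choose the number of latent classes by BIC
#'
#' Fits the joint latent class model for each candidate number of classes
#' and returns the fit minimising the Bayesian information criterion
#' (`-2 loglik + p log N`).  A class count whose fit fails is recorded in
#' the table and skipped.
#'
#' @inheritParams fit_jlcm
#' @param G_range candidate class counts (default `1:3`).
#' @return list with `best_G`, `best_fit`, `fits` and the `bic_table`
#'   data.frame (one row per attempted `G`).
#' @export
select_num_classes <- function(data, G_range = 1:3, n_starts = 5L,
                               se = FALSE, seed = NULL, ...) {
  if (length(G_range) < 1L) stop("G_range must be nonempty")
  fits <- vector("list", length(G_range))
  tab <- data.frame(G = G_range, loglik = NA_real_, bic = NA_real_,
                    converged = NA, error = NA_character_)
  for (i in seq_along(G_range)) {
    f <- try(fit_jlcm(data, G_range[i], n_starts = n_starts, se = se,
                      seed = seed, ...), silent = TRUE)
    if (inherits(f, "try-error")) {
      tab$error[i] <- conditionMessage(attr(f, "condition"))
    } else {
      fits[[i]] <- f
      tab$loglik[i] <- f$loglik; tab$bic[i] <- f$bic
      tab$converged[i] <- f$converged
    }
  }
  if (all(is.na(tab$bic))) stop("no class count could be fitted")
  best <- which.min(tab$bic)
  list(best_G = G_range[best], best_fit = fits[[best]],
       fits = fits, bic_table = tab)
}
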