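## Latent-class linear mixed model: multinomial-logistic membership plus
## class-specific random-intercept LMMs, estimated by EM.  The E-step is
## closed form (Bayes rule over the marginal Gaussian class densities);
## the M-step reweights the LMM core fitter per class and takes one
## step-halved Newton-Raphson update of the membership coefficients.

logsumexp_rows <- function(M) {
  mx <- M[, 1L]
  for (j in seq_len(ncol(M))[-1L]) mx <- pmax(mx, M[, j])
  fin <- is.finite(mx)
  out <- mx
  if (any(fin))
    out[fin] <- mx[fin] + log(rowSums(exp(M[fin, , drop = FALSE] - mx[fin])))
  out   # rows with max -Inf stay -Inf
}

## class log-prior matrix (n x G) from membership design W and eta
lcmm_log_prior <- function(W, eta, G) {
  n <- nrow(W)
  lin <- matrix(0, n, G)
  if (G > 1L) lin[, seq_len(G - 1L)] <- W %*% t(eta)
  lin - logsumexp_rows(lin)
}

## Q(eta) = sum_i sum_g resp_ig log pi_ig, and one NR step with halving
lcmm_eta_q <- function(W, eta, resp) {
  sum(resp * lcmm_log_prior(W, eta, ncol(resp)))
}

lcmm_eta_update <- function(W, eta, resp) {
  G <- ncol(resp); q <- ncol(W)
  if (G == 1L) return(eta)
  pi_ <- exp(lcmm_log_prior(W, eta, G))
  score <- as.vector(vapply(seq_len(G - 1L), function(g)
    colSums((resp[, g] - pi_[, g]) * W), numeric(q)))
  H <- matrix(0, (G - 1L) * q, (G - 1L) * q)
  for (g in seq_len(G - 1L)) for (h in seq_len(G - 1L)) {
    wgh <- pi_[, g] * ((g == h) - pi_[, h])
    blk <- crossprod(W, W * wgh)
    H[(g - 1L) * q + seq_len(q), (h - 1L) * q + seq_len(q)] <- blk
  }
  step <- try(solve(H, score), silent = TRUE)
  if (inherits(step, "try-error")) return(eta)
  q0 <- lcmm_eta_q(W, eta, resp)
  fac <- 1
  for (k in seq_len(20)) {
    eta_new <- eta + matrix(fac * step, G - 1L, q, byrow = TRUE)
    if (lcmm_eta_q(W, eta_new, resp) >= q0) return(eta_new)
    fac <- fac / 2
  }
  eta
}

## one EM run from an initial responsibility matrix
lcmm_em_run <- function(pre, W, G, resp, max_iter, tol, warm = NULL) {
  eta <- if (is.null(warm$eta)) matrix(0, G - 1L, ncol(W)) else warm$eta
  fits <- warm$fits
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    wmat <- pmax(resp, 1e-10)        # truncate vanishing responsibilities
    fits <- lapply(seq_len(G), function(g)
      lmm_fit_core(pre, w = wmat[, g],
                   init = if (is.null(fits)) NULL else fits[[g]]$theta,
                   max_iter = 100L))
    eta <- lcmm_eta_update(W, eta, resp)
    logf <- vapply(fits, function(f)
      lmm_ll_subjects(pre, f$beta, f$vb, f$s2), numeric(pre$n))
    lp <- lcmm_log_prior(W, eta, G) + logf
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    resp <- exp(lp - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(fits = fits, eta = eta, resp = resp, loglik = ll, trace = trace,
       converged = converged, n_iter = length(trace))
}

## initial responsibilities: per-subject OLS summaries + k-means for the
## first start, Dirichlet-perturbed hard assignments afterwards
lcmm_init_resp <- function(data, G, start_index) {
  ids <- factor(data$subject_id)
  n <- nlevels(ids)
  sp <- split(seq_len(nrow(data)), ids)
  feat <- t(vapply(sp, function(ix) {
    t_ <- data$time[ix]; y <- data$value[ix]
    if (length(ix) >= 2L && sd(t_) > 0) {
      sl <- stats::cov(t_, y) / stats::var(t_)
      c(mean(y) - sl * mean(t_), sl)
    } else c(mean(y), 0)
  }, numeric(2)))
  feat <- scale(feat)
  feat[!is.finite(feat)] <- 0
  km <- suppressWarnings(kmeans(feat, centers = G, nstart = 3L))
  hard <- matrix(0, n, G)
  hard[cbind(seq_len(n), km$cluster)] <- 1
  if (start_index == 1L) return(hard)
  noise <- matrix(rgamma(n * G, shape = 1), n, G)
  noise <- noise / rowSums(noise)
  resp <- 0.5 * hard + 0.5 * noise
  resp / rowSums(resp)
}

#' Fit a latent-class linear mixed model by EM
#'
#' Mixture of `n_classes` random-intercept linear mixed models with a
#' multinomial-logistic class-membership model.  Estimation alternates an
#' exact E-step (posterior class probabilities by Bayes rule over the
#' closed-form marginal Gaussian densities) with an M-step consisting of
#' one weighted LMM maximisation per class and a step-halved
#' Newton-Raphson update of the membership coefficients, so the observed
#' log-likelihood is nondecreasing.  Multiple random starts guard against
#' local maxima: each start runs a capped number of EM iterations and the
#' best is polished to convergence.  Classes are reported in increasing
#' order of the time slope, so the declining-trajectory class comes
#' first.
#'
#' @inheritParams fit_lmm
#' @param n_classes number of latent classes `G >= 1`.
#' @param membership names of covariate columns entering the membership
#'   model (an intercept is always included).
#' @param n_starts number of EM initialisations (first from k-means on
#'   per-subject OLS intercepts/slopes, the rest Dirichlet-perturbed).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param short_iter iteration cap for the non-polished starts.
#' @param seed optional seed for the random starts.
#' @return An object of class `lcj_lcmm`: `membership_coefs`,
#'   `class_fits` (per-class `beta`, `vb`, `s2`), `posterior`, `loglik`,
#'   `bic`, `converged`, `n_starts_used`, `loglik_trace`.
#' @examples
#' d <- generate_dataset(lcj_design(150, seed = 11), lcj_parameters())
#' f <- fit_lcmm(d$longitudinal, 2, n_starts = 2, seed = 1)
#' f$bic
#' @export
fit_lcmm <- function(data, n_classes, fixed = c("time", "x1", "x2"),
                     membership = c("x1", "x2"), n_starts = 5L,
                     max_iter = 500L, tol = 1e-8, short_iter = 30L,
                     seed = NULL) {
  G <- as.integer(n_classes)
  if (G < 1L) stop("n_classes must be >= 1")
  if (nrow(data) == 0L) stop("data must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  pre <- lmm_precompute(data, fixed)
  pre <- lmm_pre_s2(pre)
  ids <- factor(data$subject_id)
  first <- !duplicated(ids)
  W <- cbind(1, as.matrix(data[first, membership, drop = FALSE]))
  W <- W[order(ids[first]), , drop = FALSE]
  colnames(W) <- c("(Intercept)", membership)

  if (G == 1L) {
    core <- lmm_fit_core(pre)
    run <- list(fits = list(core), eta = matrix(0, 0, ncol(W)),
                resp = matrix(1, pre$n, 1), loglik = core$loglik,
                trace = core$loglik, converged = core$converged, n_iter = 1L)
    starts_used <- 1L
  } else {
    cand <- vector("list", n_starts)
    for (k in seq_len(n_starts)) {
      resp0 <- lcmm_init_resp(data, G, k)
      cand[[k]] <- tryCatch(lcmm_em_run(pre, W, G, resp0, short_iter, tol),
                            error = function(e) list(loglik = -Inf))
    }
    lls <- vapply(cand, `[[`, numeric(1), "loglik")
    if (all(!is.finite(lls))) stop("all EM starts failed")
    best <- which.max(lls)
    run <- tryCatch(lcmm_em_run(pre, W, G, cand[[best]]$resp,
                                max_iter, tol, warm = cand[[best]]),
                    error = function(e) cand[[best]])
    starts_used <- n_starts
  }

  ## canonical order: ascending time slope (declining class first)
  slope_col <- match("time", pre$names)
  ord <- if (!is.na(slope_col) && G > 1L)
    order(vapply(run$fits, function(f) f$beta[slope_col], numeric(1)))
  else seq_len(G)
  fits <- run$fits[ord]
  resp <- run$resp[, ord, drop = FALSE]
  ## re-reference membership coefficients after permutation
  eta_full <- rbind(run$eta, 0)[ord, , drop = FALSE]
  eta <- sweep(eta_full[-G, , drop = FALSE], 2L, eta_full[G, ], "-")
  colnames(eta) <- colnames(W)

  p_free <- (G - 1L) * ncol(W) + G * (pre$p + 2L)
  class_fits <- lapply(fits, function(f)
    list(fixed_effects = f$beta, ranef_variance = f$vb,
         resid_variance = f$s2, boundary = f$boundary))
  structure(list(n_classes = G, membership_coefs = eta,
                 class_fits = class_fits, posterior = unname(resp),
                 loglik = run$loglik,
                 bic = -2 * run$loglik + p_free * log(pre$n),
                 converged = run$converged, n_starts_used = starts_used,
                 n_iter = run$n_iter, loglik_trace = run$trace,
                 fixed = fixed, membership = membership,
                 subject_ids = pre$ids, n_subjects = pre$n),
            class = "lcj_lcmm")
}

#' Posterior class-membership probabilities
#'
#' Bayes-rule posterior of class membership given a subject's data, under
#' a fitted latent-class mixed model (`lcj_lcmm`; longitudinal data only)
#' or a fitted joint latent class model (`lcj_jlcm`; longitudinal and
#' survival outcomes).
#'
#' @param fit an `lcj_lcmm` or `lcj_jlcm` object.
#' @param data for an `lcj_lcmm` fit, long-format longitudinal data as in
#'   [fit_lcmm()]; for an `lcj_jlcm` fit, a list with `longitudinal` and
#'   `survival` components.
#' @return matrix (subjects x classes); rows sum to one.
#' @export
posterior_class_probabilities <- function(fit, data) {
  if (inherits(fit, "lcj_jlcm")) {
    pre <- lmm_precompute(data$longitudinal, fit$fixed)
    sv <- joint_align_surv(pre, data$survival)
    ids <- factor(data$longitudinal$subject_id)
    first <- !duplicated(ids)
    W <- cbind(1, as.matrix(data$longitudinal[first, fit$membership, drop = FALSE]))
    W <- W[order(ids[first]), , drop = FALSE]
    G <- fit$n_classes
    logf <- vapply(fit$params$classes, function(cl)
      lmm_ll_subjects(pre, cl$beta, cl$vb, cl$s2) + jlcm_surv_logf(sv, cl),
      numeric(pre$n))
    lp <- lcmm_log_prior(W, fit$membership_coefs, G) + matrix(logf, nrow = pre$n)
    return(unname(exp(lp - logsumexp_rows(lp))))
  }
  pre <- lmm_precompute(data, fit$fixed)
  ids <- factor(data$subject_id)
  first <- !duplicated(ids)
  W <- cbind(1, as.matrix(data[first, fit$membership, drop = FALSE]))
  W <- W[order(ids[first]), , drop = FALSE]
  G <- fit$n_classes
  logf <- vapply(fit$class_fits, function(f)
    lmm_ll_subjects(pre, f$fixed_effects, f$ranef_variance, f$resid_variance),
    numeric(pre$n))
  logf <- matrix(logf, nrow = pre$n)
  lp <- lcmm_log_prior(W, fit$membership_coefs, G) + logf
  post <- exp(lp - logsumexp_rows(lp))
  unname(post)
}

#' Modal class assignment
#'
#' Argmax of each posterior row; ties resolve to the lower class index.
#'
#' @param posterior matrix of posterior probabilities.
#' @return integer class labels.
#' @export
assign_modal_class <- function(posterior) {
  posterior <- rbind(posterior)
  max.col(posterior, ties.method = "first")
}

## all permutations of 1..k (k small)
perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(j, sub + (sub >= j))
  }))
}

#' Label-switching-invariant misclassification rate
#'
#' Minimum over all class-label permutations of the fraction of subjects
#' whose assigned class differs from the true class.
#'
#' @param true,assigned integer label vectors of equal length.
#' @return proportion in `[0, 1 - 1/G]`.
#' @export
misclassification_rate <- function(true, assigned) {
  if (length(true) != length(assigned)) stop("label vectors differ in length")
  G <- max(true, assigned)
  P <- perms(G)
  min(apply(P, 1L, function(pm) mean(pm[assigned] != true)))
}
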