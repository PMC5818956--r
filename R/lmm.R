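## Random-intercept linear mixed model by direct maximum likelihood.
##
## With a single random intercept the marginal covariance of subject i's
## measurement vector is compound symmetric, V_i = s2*I + vb*J, whose
## determinant and inverse are available in closed form:
##   log|V_i|      = n_i log s2 + log(1 + n_i r),        r = vb/s2
##   e' V_i^{-1} e = (e'e - a_i (1'e)^2)/s2,             a_i = r/(1+n_i r)
## Everything the likelihood needs reduces to per-subject crossproducts
## (X'X, X'y, X'1, 1'y, y'y, n_i), precomputed once so that repeated
## evaluations inside EM loops cost a handful of vectorised operations.

## Precompute per-subject crossproducts for design (Intercept, fixed...).
lmm_precompute <- function(data, fixed = c("time", "x1", "x2")) {
  if (!all(c("subject_id", "value") %in% names(data)))
    stop("longitudinal data needs subject_id and value columns")
  miss <- setdiff(fixed, names(data))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  id <- factor(data$subject_id)
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  if (length(fixed)) X <- cbind(X, as.matrix(data[fixed]))
  y <- data$value
  p <- ncol(X)
  iL <- rep(seq_len(p), p); iR <- rep(seq_len(p), each = p)
  list(ni   = as.numeric(table(id)),
       XtX  = rowsum(X[, iL, drop = FALSE] * X[, iR, drop = FALSE], id),
       Xty  = rowsum(X * y, id),
       s    = rowsum(X, id),                       # X'1
       S2   = NULL,                                 # filled lazily below
       sy   = drop(rowsum(y, id)),                 # 1'y
       yty  = drop(rowsum(y * y, id)),
       p    = p, n = nlevels(id), N = nrow(data),
       ids  = levels(id),
       names = colnames(X))
}

lmm_pre_s2 <- function(pre) {
  if (is.null(pre$S2)) {
    p <- pre$p
    iL <- rep(seq_len(p), p); iR <- rep(seq_len(p), each = p)
    pre$S2 <- pre$s[, iL, drop = FALSE] * pre$s[, iR, drop = FALSE]
  }
  pre
}

## Per-subject marginal log-density at (beta, vb, s2); vector of length n.
lmm_ll_subjects <- function(pre, beta, vb, s2) {
  r <- vb / s2
  a <- r / (1 + pre$ni * r)
  quad <- drop(pre$XtX %*% as.vector(outer(beta, beta)))
  sse <- pre$yty - 2 * drop(pre$Xty %*% beta) + quad
  S <- pre$sy - drop(pre$s %*% beta)
  -0.5 * (pre$ni * log(2 * pi * s2) + log1p(pre$ni * r) + (sse - a * S^2) / s2)
}

## Weighted GLS fixed effects for given variance ratio r = vb/s2.
lmm_gls <- function(pre, r, w) {
  a <- r / (1 + pre$ni * r)
  A <- matrix(colSums(w * (pre$XtX - a * pre$S2)), pre$p, pre$p)
  rhs <- colSums(w * (pre$Xty - (a * pre$sy) * pre$s))
  qr_A <- qr(A)
  if (qr_A$rank < pre$p) stop("rank-deficient fixed-effect design")
  qr.coef(qr_A, rhs)
}

## Core fitter on precomputed structures with subject weights.
lmm_fit_core <- function(pre, w = NULL, init = NULL, max_iter = 200L) {
  pre <- lmm_pre_s2(pre)
  if (is.null(w)) w <- rep(1, pre$n)
  if (is.null(init)) {
    ## moment start: pooled within/between split of the response variance
    beta0 <- lmm_gls(pre, 0, w)
    s_all <- sum(w * (pre$yty - 2 * drop(pre$Xty %*% beta0) +
                        drop(pre$XtX %*% as.vector(outer(beta0, beta0)))))
    v_tot <- max(s_all / sum(w * pre$ni), 1e-4)
    init <- c(log(v_tot / 2), log(v_tot / 2))
  }
  nll <- function(th) {
    th <- pmin(pmax(th, -25), 25)    # keep exp() finite under wild steps
    vb <- exp(th[1]); s2 <- exp(th[2])
    beta <- try(lmm_gls(pre, vb / s2, w), silent = TRUE)
    if (inherits(beta, "try-error")) return(1e10)
    v <- -sum(w * lmm_ll_subjects(pre, beta, vb, s2))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optim(init, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-10))
  opt$par <- pmin(pmax(opt$par, -25), 25)
  vb <- exp(opt$par[1]); s2 <- exp(opt$par[2])
  beta <- lmm_gls(pre, vb / s2, w)
  list(beta = setNames(beta, pre$names), vb = vb, s2 = s2,
       loglik = -opt$value, theta = opt$par,
       converged = opt$convergence == 0L,
       boundary = opt$par[1] < -11,
       n_iter = opt$counts[["function"]])
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Direct maximisation of the marginal Gaussian likelihood over the fixed
#' effects, the random-intercept variance and the residual variance, using
#' the closed-form compound-symmetry factorisation of each subject's
#' covariance.  Standard errors (including the variance parameters, on the
#' variance scale) come from the inverse of the numerically evaluated
#' observed information.
#'
#' When every subject contributes a single measurement the two variance
#' components are identified only through their sum; the fit then pins the
#' random-intercept variance to zero and flags `boundary = TRUE`.
#'
#' @param data long-format data.frame with columns `subject_id`, `value`
#'   and the covariates named in `fixed`.
#' @param fixed names of fixed-effect covariate columns (an intercept is
#'   always included); use `character(0)` for an intercept-only model.
#' @param weights optional subject-level weights, aligned with
#'   `sort(unique(subject_id))`.
#' @param se compute standard errors (numeric observed information)?
#' @return An object of class `lcj_lmm` with elements `fixed_effects`,
#'   `ranef_variance`, `resid_variance`, `se`, `loglik`, `converged`,
#'   `boundary`, `n_iter`.
#' @examples
#' d <- generate_dataset(lcj_design(150, seed = 7), lcj_parameters())
#' d1 <- d$longitudinal[d$survival$true_class[d$longitudinal$subject_id] == 1, ]
#' fit_lmm(d1)
#' @export
fit_lmm <- function(data, fixed = c("time", "x1", "x2"), weights = NULL,
                    se = TRUE) {
  pre <- lmm_precompute(data, fixed)
  if (pre$n < 2L) stop("need at least 2 subjects")
  if (!is.null(weights) && length(weights) != pre$n)
    stop("weights must have one entry per subject")
  w <- if (is.null(weights)) rep(1, pre$n) else weights
  single <- all(pre$ni == 1)
  if (single) {
    pre <- lmm_pre_s2(pre)
    beta <- lmm_gls(pre, 0, w)
    sse <- sum(w * (pre$yty - 2 * drop(pre$Xty %*% beta) +
                      drop(pre$XtX %*% as.vector(outer(beta, beta)))))
    s2 <- sse / sum(w)
    core <- list(beta = setNames(beta, pre$names), vb = 0, s2 = s2,
                 loglik = sum(w * lmm_ll_subjects(pre, beta, 0, s2)),
                 converged = TRUE, boundary = TRUE, n_iter = 1L)
    warning("all subjects have a single measurement; var(b) fixed at 0 (boundary)")
  } else {
    core <- lmm_fit_core(pre, w)
  }
  nms <- c(pre$names, "var(b)", "sigma2")
  ses <- rep(NA_real_, length(nms))
  if (se && !single) {
    nll_nat <- function(th) {
      beta <- th[seq_len(pre$p)]
      vb <- th[pre$p + 1]; s2 <- th[pre$p + 2]
      if (vb < 0 || s2 <= 0) return(1e10)
      -sum(w * lmm_ll_subjects(pre, beta, vb, s2))
    }
    H <- try(optimHess(c(core$beta, core$vb, core$s2), nll_nat), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error")) {
        dv <- diag(V)
        ses[dv > 0] <- sqrt(dv[dv > 0])
      }
    }
  }
  structure(list(fixed_effects = core$beta,
                 ranef_variance = core$vb, resid_variance = core$s2,
                 se = setNames(ses, nms),
                 loglik = core$loglik, converged = core$converged,
                 boundary = core$boundary, n_iter = core$n_iter,
                 n_subjects = pre$n, n_obs = pre$N, fixed = fixed),
            class = "lcj_lmm")
}

#' Marginal log-likelihood of a random-intercept mixed model
#'
#' Sum over subjects of the log joint Gaussian density of each subject's
#' measurement vector under compound-symmetric covariance
#' `s2 * I + vb * 11'`.
#'
#' @param params list with `beta` (aligned with `(Intercept, fixed)`),
#'   `vb` (>= 0) and `s2` (> 0).
#' @inheritParams fit_lmm
#' @export
lmm_loglik <- function(params, data, fixed = c("time", "x1", "x2")) {
  if (params$vb < 0 || params$s2 <= 0)
    stop("covariance not positive definite: need vb >= 0 and s2 > 0")
  if (nrow(data) == 0L) return(0)
  pre <- lmm_precompute(data, fixed)
  sum(lmm_ll_subjects(pre, params$beta, params$vb, params$s2))
}
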