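## Weibull proportional hazards by maximum likelihood:
##   h(t) = alpha * lambda * t^(alpha-1) * exp(x'delta),
##   H(t) = lambda * t^alpha * exp(x'delta).
## Optimised on (log alpha, log lambda, delta) with analytic gradients;
## standard errors from the observed information on the natural scale.

weibull_ll_terms <- function(T_, e, xb, alpha, lambda) {
  e * (log(alpha) + log(lambda) + (alpha - 1) * log(T_) + xb) -
    lambda * T_^alpha * exp(xb)
}

weibull_fit_core <- function(T_, e, X, w = NULL, init = NULL,
                             fix_shape = NULL) {
  n <- length(T_)
  if (is.null(w)) w <- rep(1, n)
  r <- if (is.null(X)) 0L else ncol(X)
  free_shape <- is.null(fix_shape)
  lt <- log(T_)
  nll <- function(th) {
    th <- pmin(pmax(th, -30), 30)
    alpha <- if (free_shape) exp(th[1]) else fix_shape
    lambda <- exp(th[1 + free_shape])
    delta <- if (r) th[(1 + free_shape) + seq_len(r)] else numeric(0)
    xb <- if (r) drop(X %*% delta) else 0
    v <- -sum(w * weibull_ll_terms(T_, e, xb, alpha, lambda))
    if (!is.finite(v)) 1e10 else v
  }
  grad <- function(th) {
    th <- pmin(pmax(th, -30), 30)
    alpha <- if (free_shape) exp(th[1]) else fix_shape
    lambda <- exp(th[1 + free_shape])
    delta <- if (r) th[(1 + free_shape) + seq_len(r)] else numeric(0)
    xb <- if (r) drop(X %*% delta) else 0
    Ht <- pmin(lambda * T_^alpha * exp(xb), 1e12)
    g_la <- sum(w * (e * (1 + alpha * lt) - Ht * alpha * lt))
    g_ll <- sum(w * (e - Ht))
    g_d <- if (r) colSums(w * (e - Ht) * X) else numeric(0)
    -c(if (free_shape) g_la, g_ll, g_d)
  }
  if (is.null(init)) {
    lam0 <- sum(w * e) / sum(w * T_)
    init <- c(if (free_shape) 0, log(max(lam0, 1e-8)), rep(0, r))
  }
  opt <- optim(init, nll, grad, method = "BFGS",
               control = list(maxit = 500L, reltol = 1e-12))
  opt$par <- pmin(pmax(opt$par, -30), 30)
  alpha <- if (free_shape) exp(opt$par[1]) else fix_shape
  lambda <- exp(opt$par[1 + free_shape])
  delta <- if (r) opt$par[(1 + free_shape) + seq_len(r)] else numeric(0)
  list(alpha = alpha, lambda = lambda, delta = delta,
       loglik = -opt$value, theta = opt$par,
       converged = opt$convergence == 0L)
}

#' Fit a Weibull proportional-hazards model
#'
#' Maximises \eqn{\sum_i w_i [e_i \log(\alpha\lambda T_i^{\alpha-1}
#' e^{x_i'\delta}) - \lambda T_i^{\alpha} e^{x_i'\delta}]} by quasi-Newton
#' on `(log alpha, log lambda, delta)`.
#'
#' @param data one-row-per-subject data.frame with `observed_time`,
#'   `event` and the covariates named in `covariates`.
#' @param covariates names of covariate columns (may be empty).
#' @param weights optional per-subject weights.
#' @param fix_shape fix the shape `alpha` at this value instead of
#'   estimating it (e.g. `1` for the exponential model).
#' @param se compute standard errors from the observed information
#'   (natural scale)?
#' @return An object of class `lcj_weibull` with `shape`, `scale`,
#'   `coefs`, `se`, `loglik`, `converged`.
#' @export
fit_weibull_ph <- function(data, covariates = c("x1"), weights = NULL,
                           fix_shape = NULL, se = TRUE) {
  T_ <- data$observed_time; e <- data$event
  if (sum(e) < 1) stop("no events: survival parameters are inestimable")
  if (any(T_ <= 0)) stop("observed times must be positive")
  X <- if (length(covariates)) as.matrix(data[covariates]) else NULL
  core <- weibull_fit_core(T_, e, X, w = weights, fix_shape = fix_shape)
  nms <- c("shape", "scale", covariates)
  ses <- rep(NA_real_, length(nms))
  if (se) {
    w <- if (is.null(weights)) rep(1, length(T_)) else weights
    free_shape <- is.null(fix_shape)
    free_idx <- if (free_shape) seq_along(nms) else seq_along(nms)[-1L]
    nll_nat <- function(th_free) {
      th <- c(if (!free_shape) fix_shape, th_free)
      alpha <- th[1]; lambda <- th[2]
      if (alpha <= 0 || lambda <= 0) return(1e10)
      delta <- if (length(covariates)) th[2 + seq_along(covariates)] else numeric(0)
      xb <- if (length(covariates)) drop(X %*% delta) else 0
      -sum(w * weibull_ll_terms(T_, e, xb, alpha, lambda))
    }
    par_nat <- c(if (free_shape) core$alpha, core$lambda, core$delta)
    H <- try(optimHess(par_nat, nll_nat), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error")) {
        dv <- diag(V)
        ok <- dv > 0
        ses[free_idx[ok]] <- sqrt(dv[ok])
      }
    }
  }
  structure(list(shape = core$alpha, scale = core$lambda,
                 coefs = setNames(core$delta, covariates),
                 se = setNames(ses, nms),
                 loglik = core$loglik, converged = core$converged,
                 n_events = sum(e), n_subjects = length(T_),
                 fixed_shape = !is.null(fix_shape)),
            class = "lcj_weibull")
}
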