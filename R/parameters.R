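#' Generating parameters for a heterogeneous joint-model population
#'
#' Bundles everything needed to simulate (or describe) a population made of
#' `n_classes` latent subgroups.  Class membership follows a multinomial
#' logistic model on covariates (last class is the reference, with all
#' coefficients fixed at zero for identifiability).  Within class `g` the
#' longitudinal marker follows a linear mixed model with a random intercept,
#' \deqn{Y_i(t) = \beta_{0g} + \beta_{1g} t + \beta_{2g} x_1 + \beta_{3g} x_2
#'   + b_i + \varepsilon,}
#' and the hazard is Weibull proportional hazards linked to the error-free
#' trajectory \eqn{Z^*_i(t)} through the association parameter \eqn{\gamma}:
#' \deqn{h_i(t \mid g) = \alpha_g \lambda_g t^{\alpha_g - 1}
#'   \exp(\delta_g x_1 + \gamma_g Z^*_i(t)).}
#'
#' The defaults are the two-class simulation profile used throughout the
#' package's replication studies: a declining-trajectory class 1 with
#' \eqn{\beta = (1, -1, 0.5, 1)}, residual variance 1, Weibull shape 0.6,
#' and a rising-trajectory class 2 with \eqn{\beta = (-1, 1, -0.5, -1)},
#' residual variance 0.5, shape 1; both classes have unit random-intercept
#' variance, scale 0.001, treatment effects \eqn{\delta = (0.5, -0.5)} and
#' membership model \eqn{\mathrm{logit}\,\pi_1 = -0.5 + x_1 + x_2}.
#'
#' @param n_classes integer number of latent classes `G`.
#' @param membership numeric matrix with `G - 1` rows and columns
#'   `(Intercept, x1, x2)`: multinomial-logistic coefficients of classes
#'   `1..G-1` against the reference class `G`.
#' @param beta numeric `G x 4` matrix of fixed effects
#'   `(Intercept, time, x1, x2)` per class.
#' @param ranef_variance,resid_variance numeric vectors of length `G`;
#'   variances of the random intercept and the residual error.
#' @param treatment_effect numeric vector of length `G`; log hazard ratio
#'   \eqn{\delta_g} of the binary covariate `x1` in the survival submodel.
#' @param association numeric vector of length `G`; the link \eqn{\gamma_g}
#'   between the trajectory and the log hazard.
#' @param weibull_shape,weibull_scale positive numeric vectors of length
#'   `G`; \eqn{\alpha_g} and \eqn{\lambda_g} of the baseline hazard
#'   \eqn{h_{0g}(t) = \alpha_g \lambda_g t^{\alpha_g - 1}}.
#'
#' @return An object of class `lcj_parameters`.
#' @seealso [lcj_design()], [generate_dataset()], [calibrate_scale()]
#' @examples
#' p <- lcj_parameters(association = c(0.5, 0.5))
#' p
#' @export
lcj_parameters <- function(n_classes = 2L,
                           membership = matrix(c(-0.5, 1, 1), nrow = 1,
                             dimnames = list(NULL, c("(Intercept)", "x1", "x2"))),
                           beta = rbind(c(1, -1, 0.5, 1), c(-1, 1, -0.5, -1)),
                           ranef_variance = c(1, 1),
                           resid_variance = c(1, 0.5),
                           treatment_effect = c(0.5, -0.5),
                           association = c(0, 0),
                           weibull_shape = c(0.6, 1),
                           weibull_scale = c(0.001, 0.001)) {
  G <- as.integer(n_classes)
  if (G < 1L) stop("n_classes must be >= 1")
  membership <- rbind(membership)
  if (G == 1L) membership <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (nrow(membership) != G - 1L)
    stop("membership must have n_classes - 1 rows (last class is the reference)")
  beta <- rbind(beta)
  colnames(beta) <- c("Intercept", "time", "x1", "x2")
  for (nm in c("ranef_variance", "resid_variance", "treatment_effect",
               "association", "weibull_shape", "weibull_scale")) {
    v <- get(nm)
    if (length(v) != G) stop(sprintf("%s must have length n_classes", nm))
    if (any(!is.finite(v))) stop(sprintf("%s must be finite", nm))
  }
  if (nrow(beta) != G) stop("beta must have n_classes rows")
  if (any(ranef_variance < 0)) stop("ranef_variance must be >= 0")
  if (any(resid_variance <= 0)) stop("resid_variance must be > 0")
  if (any(weibull_shape <= 0) || any(weibull_scale <= 0))
    stop("weibull_shape and weibull_scale must be > 0")
  structure(list(
    n_classes = G, membership = membership, beta = beta,
    ranef_variance = as.numeric(ranef_variance),
    resid_variance = as.numeric(resid_variance),
    treatment_effect = as.numeric(treatment_effect),
    association = as.numeric(association),
    weibull_shape = as.numeric(weibull_shape),
    weibull_scale = as.numeric(weibull_scale)),
    class = "lcj_parameters")
}

#' Simulation design: cohort size, visit schedule, censoring
#'
#' @param n_subjects number of subjects to simulate.
#' @param measurement_grid strictly increasing vector of scheduled visit
#'   times; default eleven visits at `0, 0.5, ..., 5`.
#' @param censoring_offset,censoring_width the censoring time is drawn as
#'   `censoring_offset + U(0, censoring_width)`, by default uniform on
#'   `[2.5, 5.5]`.
#' @param seed integer seed making [generate_dataset()] deterministic.
#' @param drop_post_event_measurements if `TRUE` (default) scheduled
#'   measurements strictly after the observed follow-up time are removed,
#'   so each subject contributes between 1 and `length(measurement_grid)`
#'   measurements.
#'
#' @return An object of class `lcj_design`.
#' @export
lcj_design <- function(n_subjects,
                       measurement_grid = seq(0, 5, by = 0.5),
                       censoring_offset = 2.5,
                       censoring_width = 3,
                       seed = 1L,
                       drop_post_event_measurements = TRUE) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) stop("n_subjects must be >= 2")
  if (length(measurement_grid) < 1L || any(diff(measurement_grid) <= 0))
    stop("measurement_grid must be nonempty and strictly increasing")
  if (censoring_offset < 0 || censoring_width < 0)
    stop("censoring parameters must be >= 0")
  structure(list(
    n_subjects = n_subjects,
    measurement_grid = as.numeric(measurement_grid),
    censoring_offset = censoring_offset,
    censoring_width = censoring_width,
    seed = as.integer(seed),
    drop_post_event_measurements = isTRUE(drop_post_event_measurements)),
    class = "lcj_design")
}

#' @export
print.lcj_parameters <- function(x, ...) {
  cat(sprintf("Generating parameters: %d latent class(es)\n", x$n_classes))
  tab <- data.frame(class = seq_len(x$n_classes), x$beta,
                    var.b = x$ranef_variance, sigma2 = x$resid_variance,
                    delta = x$treatment_effect, gamma = x$association,
                    shape = x$weibull_shape, scale = x$weibull_scale,
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  if (x$n_classes > 1L) {
    cat("Membership model (reference = last class):\n")
    print(x$membership)
  }
  invisible(x)
}

#' @export
print.lcj_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation design: %d subjects, %d scheduled visits on [%g, %g],\n",
    "censoring ~ %g + U(0, %g), seed %d\n"),
    x$n_subjects, length(x$measurement_grid), min(x$measurement_grid),
    max(x$measurement_grid), x$censoring_offset, x$censoring_width, x$seed))
  invisible(x)
}

## per-class truth on the harness's canonical parameter grid
true_parameter_matrix <- function(params) {
  G <- params$n_classes
  out <- cbind(params$beta,
               `var(b)` = params$ranef_variance,
               surv_X1 = params$treatment_effect,
               gamma = params$association)
  colnames(out) <- c("Intercept", "t_ij", "X1", "X2", "var(b)", "surv_X1", "gamma")
  rownames(out) <- paste0("class", seq_len(G))
  out
}
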