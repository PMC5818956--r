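## print / summary / coef / logLik methods for the fitted-model classes.

#' @export
print.lcj_lmm <- function(x, ...) {
  cat("Linear mixed model (random intercept), ML\n")
  cat(sprintf("  %d subjects, %d observations, logLik %.3f%s\n",
              x$n_subjects, x$n_obs, x$loglik,
              if (x$boundary) " [variance boundary]" else ""))
  est <- c(x$fixed_effects, "var(b)" = x$ranef_variance,
           sigma2 = x$resid_variance)
  print(cbind(estimate = est, se = x$se))
  invisible(x)
}

#' @export
coef.lcj_lmm <- function(object, ...) object$fixed_effects

#' @export
logLik.lcj_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$fixed_effects) + 2L,
            class = "logLik")
}

#' @export
print.lcj_lcmm <- function(x, ...) {
  cat(sprintf("Latent-class mixed model: G = %d, logLik %.3f, BIC %.3f%s\n",
              x$n_classes, x$loglik, x$bic,
              if (x$converged) "" else " [not converged]"))
  for (g in seq_len(x$n_classes)) {
    f <- x$class_fits[[g]]
    cat(sprintf("  class %d (%.1f%%): ", g, 100 * mean(
      assign_modal_class(x$posterior) == g)))
    cat(sprintf("%s=%.3f ", names(f$fixed_effects), f$fixed_effects))
    cat(sprintf("var(b)=%.3f sigma2=%.3f\n", f$ranef_variance, f$resid_variance))
  }
  if (x$n_classes > 1L) {
    cat("Membership coefficients (reference = last class):\n")
    print(x$membership_coefs)
  }
  invisible(x)
}

#' @export
logLik.lcj_lcmm <- function(object, ...) {
  p <- (object$n_classes - 1L) * (length(object$membership) + 1L) +
    object$n_classes * (length(object$class_fits[[1]]$fixed_effects) + 2L)
  structure(object$loglik, df = p, class = "logLik")
}

#' @export
print.lcj_weibull <- function(x, ...) {
  cat(sprintf("Weibull proportional hazards: %d subjects, %d events, logLik %.3f\n",
              x$n_subjects, x$n_events, x$loglik))
  est <- c(shape = x$shape, scale = x$scale, x$coefs)
  print(cbind(estimate = est, se = x$se))
  invisible(x)
}

#' @export
coef.lcj_weibull <- function(object, ...) object$coefs

#' @export
logLik.lcj_weibull <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefs) + 2L - object$fixed_shape,
            class = "logLik")
}

#' @export
print.lcj_coxtv <- function(x, ...) {
  cat(sprintf("Extended Cox model (LOCF time-varying covariate), %d events\n",
              x$n_events))
  print(cbind(coef = x$coefs, se = x$se))
  invisible(x)
}

#' @export
coef.lcj_coxtv <- function(object, ...) object$coefs

#' @export
print.lcj_joint <- function(x, ...) {
  cat("Shared current-value joint model\n")
  cat(sprintf("  %d subjects, %d events, %d quadrature nodes, logLik %.3f%s\n",
              x$n_subjects, x$n_events, x$n_quad, x$loglik,
              if (x$converged) "" else " [not converged]"))
  est <- c(x$fixed_effects, "var(b)" = x$ranef_variance,
           sigma2 = x$resid_variance, surv_x1 = x$treatment_effect,
           gamma = x$association, shape = x$weibull_shape,
           scale = x$weibull_scale)
  print(cbind(estimate = est, se = x$se))
  invisible(x)
}

#' @export
coef.lcj_joint <- function(object, ...) {
  c(object$fixed_effects, surv_x1 = object$treatment_effect,
    gamma = object$association)
}

#' @export
logLik.lcj_joint <- function(object, ...) {
  structure(object$loglik, df = 10L, class = "logLik")
}

#' @export
print.lcj_jlcm <- function(x, ...) {
  cat(sprintf("Joint latent class model: G = %d, logLik %.3f, BIC %.3f%s\n",
              x$n_classes, x$loglik, x$bic,
              if (x$converged) "" else " [not converged]"))
  for (g in seq_len(x$n_classes)) {
    cl <- x$class_longitudinal[[g]]; cs <- x$class_survival[[g]]
    cat(sprintf("  class %d: ", g))
    cat(sprintf("%s=%.3f ", names(cl$fixed_effects), cl$fixed_effects))
    cat(sprintf("var(b)=%.3f sigma2=%.3f | shape=%.3f scale=%.4f %s=%.3f\n",
                cl$ranef_variance, cl$resid_variance,
                cs$shape, cs$scale, names(cs$coefs)[1], cs$coefs[1]))
  }
  invisible(x)
}

#' @export
logLik.lcj_jlcm <- function(object, ...) {
  structure(object$loglik, df = NA_integer_, class = "logLik")
}

#' @export
print.lcj_result <- function(x, ...) {
  cat(sprintf("%s approach result (%d classes%s)\n", x$approach, x$n_classes,
              if (any(x$skipped)) ", some skipped" else ""))
  if (!is.na(x$misclassification))
    cat(sprintf("  misclassification vs truth: %.3f\n", x$misclassification))
  cat("Estimates:\n"); print(round(x$estimates, 4))
  invisible(x)
}

#' @export
print.lcj_summary <- function(x, ...) {
  cat(sprintf("Replication summary (%d used, %d failed)\n",
              x$n_reps_used, x$n_failed))
  print(transform(x$table, bias = round(bias, 4),
                  empirical_sd = round(empirical_sd, 4),
                  mean_se = round(mean_se, 4), cp = round(cp, 4)),
        row.names = FALSE)
  cat(sprintf("AB-PE: longitudinal %.4f, survival %.4f, gamma %.4f\n",
              x$ab_pe[1], x$ab_pe[2], x$ab_pe[3]))
  cat(sprintf("ASE-PE: longitudinal %.4f, survival %.4f, gamma %.4f\n",
              x$ase_pe[1], x$ase_pe[2], x$ase_pe[3]))
  if (!is.na(x$avg_misclassification))
    cat(sprintf("Average misclassification: %.4f\n", x$avg_misclassification))
  invisible(x)
}

#' @export
summary.lcj_lmm <- function(object, ...) {
  est <- c(object$fixed_effects, "var(b)" = object$ranef_variance,
           sigma2 = object$resid_variance)
  out <- data.frame(estimate = est, se = object$se,
                    z = est / object$se,
                    row.names = names(object$se))
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' @export
summary.lcj_joint <- function(object, ...) {
  est <- c(object$fixed_effects, "var(b)" = object$ranef_variance,
           sigma2 = object$resid_variance, surv_x1 = object$treatment_effect,
           gamma = object$association, shape = object$weibull_shape,
           scale = object$weibull_scale)
  out <- data.frame(estimate = est, se = object$se,
                    z = est / object$se, row.names = names(object$se))
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' @export
summary.lcj_weibull <- function(object, ...) {
  est <- c(shape = object$shape, scale = object$scale, object$coefs)
  out <- data.frame(estimate = est, se = object$se,
                    z = est / object$se, row.names = names(object$se))
  out$p <- 2 * pnorm(-abs(out$z))
  out
}
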