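# Confidence intervals for the summary treatment effect: standard normal,
# Kenward-Roger (bias-adjusted variance + t quantile) and Satterthwaite
# (unadjusted variance + t quantile).  For a single parameter the KR and
# Satterthwaite denominator degrees of freedom coincide, so one
# moment-matching df is computed and shared.

new_ci <- function(method, theta_hat, lower, upper, df, var_used, alpha,
                   kr_deflated = FALSE) {
  structure(list(method = method, theta_hat = theta_hat,
                 lower = lower, upper = upper, df = df,
                 var_used = var_used, alpha = alpha,
                 kr_deflated = kr_deflated),
            class = "ipd_ci")
}

#' @export
print.ipd_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%s %.0f%% CI for theta: (%s, %s)   df = %s\n",
              x$method, 100 * (1 - x$alpha),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              if (is.finite(x$df)) format(x$df, digits = digits) else "Inf"))
  invisible(x)
}

check_fit <- function(fit) {
  stopifnot(inherits(fit, "onestage_fit"))
  if (!isTRUE(fit$converged)) {
    stop("inference error: the model fit did not converge", call. = FALSE)
  }
  invisible(fit)
}

check_reml <- function(fit) {
  if (fit$spec$estimation != "REML") {
    stop("usage error: small-sample corrections implemented for REML only",
         call. = FALSE)
  }
  invisible(fit)
}

vc_hat_vector <- function(fit) {
  qn <- fit$design$vc_names
  v <- c(sigma2 = fit$sigma2_hat,
         tau2 = if (!is.null(fit$tau2_hat)) fit$tau2_hat,
         tau_beta2 = if (!is.null(fit$tau_beta2_hat)) fit$tau_beta2_hat)
  v <- v[qn]
  v["sigma2"] <- max(v["sigma2"], 1e-10)
  v
}

#' Asymptotic covariance of the variance-component estimates
#'
#' Inverts the expected information matrix of the variance components
#' \eqn{(\sigma^2, \tau^2, \tau_\beta^2)} at the estimates, REML-adjusted
#' (based on the residual projection \eqn{P = V^{-1} -
#' V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}) when the fit used REML.  Boundary
#' components estimated at exactly 0 are retained using the one-sided
#' curvature at 0; if that leaves the information singular the boundary
#' components are dropped with a warning (their rows/columns are zero in the
#' returned matrix).
#'
#' @param fit a converged [fit_onestage()] result.
#' @param design the fit's design; defaults to `fit$design`.
#' @return A symmetric positive semi-definite `q x q` matrix `W` with
#'   dimnames `fit$design$vc_names`, plus attribute `dropped` naming any
#'   boundary components excluded from the inversion.
#' @export
varcomp_information <- function(fit, design = fit$design) {
  check_fit(fit)
  varcomp_information_ev(fit, design, NULL)
}

# internal workhorse; `ev` lets callers reuse an inference evaluation
varcomp_information_ev <- function(fit, design, ev = NULL) {
  qn <- design$vc_names
  q <- length(qn)
  vc <- vc_hat_vector(fit)
  if (is.null(ev)) {
    ev <- ll_eval(design, vc, fit$spec$estimation, inference = TRUE)
  }

  info <- 0.5 * ev$trVV
  if (fit$spec$estimation == "REML") {
    Phi <- ev$Phi
    for (k in seq_len(q)) for (l in seq_len(q)) {
      info[k, l] <- info[k, l] +
        0.5 * (-2 * sum(Phi * ev$Q[[k]][[l]]) +
                 sum((Phi %*% ev$H[[k]]) * t(Phi %*% ev$H[[l]])))
    }
  }
  dimnames(info) <- list(qn, qn)

  inv_or_null <- function(m) tryCatch(solve(m), error = function(e) NULL)
  W <- inv_or_null(info)
  dropped <- character(0)
  if (is.null(W)) {
    keep <- !(qn != "sigma2" & vc[qn] == 0)
    dropped <- qn[!keep]
    if (length(dropped) > 0L) {
      warning("singular variance-component information; dropping boundary ",
              "component(s): ", paste(dropped, collapse = ", "),
              call. = FALSE)
      Wk <- inv_or_null(info[keep, keep, drop = FALSE])
      if (!is.null(Wk)) {
        W <- matrix(0, q, q, dimnames = list(qn, qn))
        W[keep, keep] <- Wk
      }
    }
    if (is.null(W)) {
      stop("inference error: singular variance-component information; ",
           "consider the standard confidence interval", call. = FALSE)
    }
  }
  W <- (W + t(W)) / 2
  attr(W, "dropped") <- dropped
  W
}

#' Standard normal (large-sample) confidence interval for theta
#'
#' \eqn{\hat\theta \pm z_{1-\alpha/2}\sqrt{Var(\hat\theta)}} using the
#' model-based GLS variance, for either ML or REML fits.
#'
#' @param fit a converged [fit_onestage()] result.
#' @param alpha two-sided error level, default taken from the fit's spec.
#' @return An `ipd_ci` object with `df = Inf`.
#' @export
ci_standard <- function(fit, alpha = fit$spec$alpha) {
  check_fit(fit)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * sqrt(fit$var_theta)
  new_ci("standard", fit$theta_hat, fit$theta_hat - hw, fit$theta_hat + hw,
         Inf, fit$var_theta, alpha)
}

# shared df / gradient machinery for the two t-based corrections; one
# inference evaluation serves the information matrix, the Satterthwaite
# gradient and the KR variance adjustment
satt_parts <- function(fit, design) {
  qn <- design$vc_names
  q <- length(qn)
  th <- design$theta_index
  vc <- vc_hat_vector(fit)
  ev <- ll_eval(design, vc, fit$spec$estimation, inference = TRUE)
  W <- varcomp_information_ev(fit, design, ev)
  Phi <- ev$Phi
  phi_t <- Phi[, th]
  # g_k = d Var(theta_hat) / d psi_k = [Phi H_k Phi]_(theta,theta)
  g <- vapply(seq_len(q), function(k) {
    drop(crossprod(phi_t, ev$H[[k]] %*% phi_t))
  }, numeric(1))
  var_theta <- Phi[th, th]
  denom <- drop(crossprod(g, W %*% g))
  df <- if (denom > 0) 2 * var_theta^2 / denom else Inf
  if (!is.finite(df) || df <= 0) {
    stop("inference error: degrees of freedom are not positive and finite",
         call. = FALSE)
  }
  list(ev = ev, W = W, g = g, df = df, var_theta = var_theta, th = th, q = q)
}

#' Satterthwaite-corrected confidence interval for theta
#'
#' Moment-matching degrees of freedom \eqn{\nu = 2\,Var(\hat\theta)^2 /
#' (g'Wg)} with \eqn{g_k = \partial Var(\hat\theta)/\partial\psi_k} and `W`
#' the asymptotic covariance of the variance components, combined with the
#' unadjusted model-based variance:
#' \eqn{\hat\theta \pm t_{\nu;1-\alpha/2}\sqrt{Var(\hat\theta)}}.
#' Available after REML estimation only.
#'
#' @inheritParams ci_standard
#' @param design the fit's design; defaults to `fit$design`.
#' @return An `ipd_ci` object.
#' @export
ci_satterthwaite <- function(fit, design = fit$design,
                             alpha = fit$spec$alpha) {
  check_fit(fit); check_reml(fit)
  ci_satt_from_parts(fit, satt_parts(fit, design), alpha)
}

ci_satt_from_parts <- function(fit, sp, alpha) {
  tq <- stats::qt(1 - alpha / 2, df = sp$df)
  hw <- tq * sqrt(sp$var_theta)
  new_ci("satterthwaite", fit$theta_hat, fit$theta_hat - hw,
         fit$theta_hat + hw, sp$df, sp$var_theta, alpha)
}

#' Kenward-Roger-corrected confidence interval for theta
#'
#' First-order Kenward-Roger adjustment: the fixed-effect covariance is
#' inflated to \eqn{\Phi_A = \Phi + 2\Phi\{\sum_{k,l} W_{kl}(Q_{kl} -
#' H_k \Phi H_l)\}\Phi} with \eqn{H_k = X'V^{-1}(\partial V/\partial\psi_k)
#' V^{-1}X} and \eqn{Q_{kl} = X'V^{-1}(\partial V/\partial\psi_k)V^{-1}
#' (\partial V/\partial\psi_l)V^{-1}X} (second-derivative terms vanish
#' because `V` is linear in the variance components), and the interval uses
#' the same moment-matching degrees of freedom as the Satterthwaite
#' correction, which coincide for a single-parameter test:
#' \eqn{\hat\theta \pm t_{\nu;1-\alpha/2}\sqrt{(\Phi_A)_{\theta\theta}}}.
#' Available after REML estimation only.  If the adjusted variance falls
#' below the unadjusted one the interval is still returned, flagged via
#' `kr_deflated = TRUE`.
#'
#' @inheritParams ci_satterthwaite
#' @return An `ipd_ci` object.
#' @export
ci_kenward_roger <- function(fit, design = fit$design,
                             alpha = fit$spec$alpha) {
  check_fit(fit); check_reml(fit)
  ci_kr_from_parts(fit, satt_parts(fit, design), alpha)
}

ci_kr_from_parts <- function(fit, sp, alpha) {
  Phi <- sp$ev$Phi
  q <- sp$q
  Lambda <- matrix(0, nrow(Phi), ncol(Phi))
  for (k in seq_len(q)) for (l in seq_len(q)) {
    if (sp$W[k, l] != 0) {
      Lambda <- Lambda + sp$W[k, l] *
        (sp$ev$Q[[k]][[l]] - sp$ev$H[[k]] %*% Phi %*% sp$ev$H[[l]])
    }
  }
  Phi_A <- Phi + 2 * Phi %*% Lambda %*% Phi
  var_kr <- Phi_A[sp$th, sp$th]
  deflated <- var_kr < sp$var_theta
  if (var_kr < 0) {
    stop("inference error: Kenward-Roger adjusted variance is negative",
         call. = FALSE)
  }
  tq <- stats::qt(1 - alpha / 2, df = sp$df)
  hw <- tq * sqrt(var_kr)
  new_ci("kr", fit$theta_hat, fit$theta_hat - hw, fit$theta_hat + hw,
         sp$df, var_kr, alpha, kr_deflated = deflated)
}

#' Does a confidence interval contain the true effect?
#'
#' Closed-interval decision: returns 1 iff
#' `lower <= theta_true <= upper`.
#'
#' @param ci an `ipd_ci` object (or any list with `lower` and `upper`).
#' @param theta_true the true summary treatment effect.
#' @return Integer 0 or 1.
#' @export
coverage_indicator <- function(ci, theta_true) {
  as.integer(ci$lower <= theta_true && theta_true <= ci$upper)
}
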