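# Method-of-moments starting values for the variance components.
# sigma2: pooled within-trial, within-arm residual variance;
# tau2:   variance of per-trial mean differences minus the mean of their
#         sampling variances, floored at 0;
# tau_beta2: variance of per-trial control-arm means.
start_values <- function(design) {
  K <- design$K
  md <- var_md <- cmean <- numeric(K)
  rss <- 0
  dfree <- 0
  for (i in seq_len(K)) {
    bl <- design$blocks[[i]]
    tvec <- bl$Z[, ncol(bl$Z)]
    y1 <- bl$y[tvec == 1]
    y0 <- bl$y[tvec == 0]
    md[i] <- mean(y1) - mean(y0)
    cmean[i] <- mean(y0)
    ss_i <- sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
    rss <- rss + ss_i
    dfree <- dfree + length(bl$y) - 2L
    s2_i <- if (length(bl$y) > 2L) ss_i / (length(bl$y) - 2L) else ss_i
    var_md[i] <- s2_i * (1 / length(y1) + 1 / length(y0))
  }
  sigma2 <- if (dfree > 0) rss / dfree else stats::var(unlist(lapply(design$blocks, `[[`, "y")))
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  tau2 <- if (K >= 2L) max(0, stats::var(md) - mean(var_md)) else 0
  tau_beta2 <- if (K >= 2L) max(0, stats::var(cmean)) else 0
  stats::setNames(c(sigma2, tau2, tau_beta2),
                  c("sigma2", "tau2", "tau_beta2"))[design$vc_names]
}

SNAP_TOL <- 1e-10  # variance estimates at or below this are reported as 0

#' Fit a one-stage IPD meta-analysis linear mixed model
#'
#' Maximizes the ML or REML criterion over the variance components (subject
#' to non-negativity, with the zero boundary attainable) using a bounded
#' quasi-Newton optimizer with analytic gradients on the block marginal
#' likelihood; the fixed effects are profiled out by GLS at each step.
#' Variance estimates at or below `1e-10` are snapped to exactly 0.
#' Optimizer failure is reported through `converged = FALSE`, not as an
#' error: in simulation studies non-convergence is an outcome.
#'
#' @param data an [ipd_dataset()] object.
#' @param spec an [model_spec()] object.
#' @return An object of class `onestage_fit` with elements `theta_hat`
#'   (summary treatment effect), `var_theta` (its model-based variance),
#'   `fixed_effects` (labelled GLS estimates), `fixed_cov`, `sigma2_hat`,
#'   `tau2_hat` (random treatment effect only), `tau_beta2_hat` (random
#'   intercept only), `loglik` (criterion value at the optimum), `converged`,
#'   `n_iter`, `runtime_seconds`, `spec` and the `design`.
#' @examples
#' cfg <- scenario_config("Base", "normal_random")
#' set.seed(42); d <- generate_ipd(cfg)
#' fit <- fit_onestage(d, model_spec(intercept = "stratified"))
#' fit
#' @export
fit_onestage <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "ipd_model_spec"))
  design <- build_design(data, spec)
  if (spec$treatment == "random" && design$K < 2L) {
    stop("identifiability error: a random treatment effect requires at ",
         "least 2 trials", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]

  qn <- design$vc_names
  start <- start_values(design)
  start["sigma2"] <- max(start["sigma2"], 1e-8)
  lower <- stats::setNames(rep(0, length(qn)), qn)
  lower["sigma2"] <- 1e-10
  start <- pmax(start, lower)

  est <- spec$estimation
  # L-BFGS-B asks for the value and the gradient at the same point; one
  # cached evaluation serves both
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$ev)
    ev <- tryCatch(
      ll_eval(design, stats::setNames(pmax(par, lower), qn), est,
              deriv = TRUE),
      error = function(e) NULL)
    cache$par <- par
    cache$ev <- ev
    ev
  }
  nll <- function(par) {
    ev <- eval_at(par)
    if (is.null(ev) || !is.finite(ev$criterion)) return(1e10)
    -ev$criterion
  }
  ngr <- function(par) {
    ev <- eval_at(par)
    if (is.null(ev) || any(!is.finite(ev$grad))) return(rep(0, length(par)))
    -ev$grad
  }

  factr <- max(spec$rel_tol / .Machine$double.eps, 10)
  parscale <- pmax(start, 1)
  opt <- tryCatch(
    stats::optim(start, nll, ngr, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = spec$max_iter, factr = factr,
                                pgtol = 1e-5, parscale = parscale)),
    error = function(e) NULL)
  if (is.null(opt)) {
    # fall back to a derivative-free simplex search on the clamped scale
    opt <- tryCatch(
      stats::optim(start, nll, method = "Nelder-Mead",
                   control = list(maxit = 50L * spec$max_iter,
                                  reltol = spec$rel_tol)),
      error = function(e) NULL)
    if (!is.null(opt)) opt$par <- pmax(opt$par, lower)
  }

  if (is.null(opt)) {
    return(structure(list(theta_hat = NA_real_, var_theta = NA_real_,
                          fixed_effects = NULL, fixed_cov = NULL,
                          sigma2_hat = NA_real_,
                          tau2_hat = if ("tau2" %in% qn) NA_real_,
                          tau_beta2_hat = if ("tau_beta2" %in% qn) NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          n_iter = NA_integer_,
                          runtime_seconds = proc.time()[["elapsed"]] - t0,
                          spec = spec, design = design),
                     class = "onestage_fit"))
  }

  vc_hat <- stats::setNames(pmax(opt$par, lower), qn)
  vc_hat[vc_hat <= SNAP_TOL] <- 0
  vc_eval <- vc_hat
  vc_eval["sigma2"] <- max(vc_eval["sigma2"], 1e-10)

  ev <- ll_eval(design, vc_eval, est)
  n_iter <- if (!is.na(opt$counts["gradient"])) {
    as.integer(opt$counts[["gradient"]])
  } else {
    as.integer(opt$counts[["function"]])
  }
  converged <- identical(opt$convergence, 0L) && n_iter <= spec$max_iter
  if (!converged && identical(opt$convergence, 52L) &&
      n_iter <= spec$max_iter) {
    # a line-search abort at a stationary point (no improvement possible
    # beyond machine precision) is convergence: check the projected gradient
    g <- ngr(opt$par)
    at_bound <- opt$par <= lower + 1e-12
    g[at_bound & g > 0] <- 0
    converged <- max(abs(g * parscale)) < 1e-3
  }

  structure(list(
    theta_hat = ev$beta[design$theta_index],
    var_theta = ev$Phi[design$theta_index, design$theta_index],
    fixed_effects = stats::setNames(ev$beta, design$fixed_labels),
    fixed_cov = ev$Phi,
    sigma2_hat = unname(vc_hat[["sigma2"]]),
    tau2_hat = if ("tau2" %in% qn) unname(vc_hat[["tau2"]]),
    tau_beta2_hat = if ("tau_beta2" %in% qn) unname(vc_hat[["tau_beta2"]]),
    loglik = ev$criterion,
    converged = converged,
    n_iter = n_iter,
    runtime_seconds = proc.time()[["elapsed"]] - t0,
    spec = spec, design = design),
    class = "onestage_fit")
}

#' Fit stratified and random intercept models under ML and REML
#'
#' Convenience fan-out fitting the four intercept-by-estimation
#' combinations to the same dataset, in the deterministic order
#' stratified-ML, stratified-REML, random-ML, random-REML.
#'
#' @param data an [ipd_dataset()] object.
#' @param treatment `"random"` or `"common"` treatment effect, applied to
#'   all four fits.
#' @param ... further arguments passed to [model_spec()].
#' @return A named list of four [fit_onestage()] results.
#' @export
fit_all_combinations <- function(data, treatment = c("random", "common"),
                                 ...) {
  treatment <- match.arg(treatment)
  combos <- list(
    stratified_ML   = c("stratified", "ML"),
    stratified_REML = c("stratified", "REML"),
    random_ML       = c("random", "ML"),
    random_REML     = c("random", "REML"))
  lapply(combos, function(cm) {
    fit_onestage(data, model_spec(intercept = cm[1], treatment = treatment,
                                  estimation = cm[2], ...))
  })
}

#' @export
print.onestage_fit <- function(x, digits = 4, ...) {
  sp <- x$spec
  cat("One-stage IPD meta-analysis fit (", sp$intercept, " intercept, ",
      sp$treatment, " treatment effect, ", sp$estimation, ")\n", sep = "")
  if (!x$converged) cat("  ** did not converge **\n")
  cat("  summary treatment effect theta: ",
      format(x$theta_hat, digits = digits),
      "  (SE ", format(sqrt(x$var_theta), digits = digits), ")\n", sep = "")
  cat("  sigma2: ", format(x$sigma2_hat, digits = digits), sep = "")
  if (!is.null(x$tau2_hat)) cat("   tau2: ", format(x$tau2_hat, digits = digits), sep = "")
  if (!is.null(x$tau_beta2_hat)) {
    cat("   tau_beta2: ", format(x$tau_beta2_hat, digits = digits), sep = "")
  }
  cat("\n  ", sp$estimation, " criterion: ", format(x$loglik, digits = 8),
      "  (", x$n_iter, " iterations)\n", sep = "")
  invisible(x)
}
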