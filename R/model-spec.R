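#' Specify a one-stage IPD meta-analysis model
#'
#' A one-stage linear mixed model for a continuous outcome measured in `K`
#' randomized trials, of the general form
#' \deqn{Y_{ij} = \beta_i + \lambda_i (Y_{Bij} - \bar Y_{Bi}) +
#'       (\theta + u_i)\, treat_{ij} + e_{ij},}
#' where the trial intercepts \eqn{\beta_i} are either separate fixed effects
#' ("stratified") or normal random effects \eqn{\beta_i = \beta + u_{1i}},
#' \eqn{u_{1i} \sim N(0, \tau_\beta^2)} ("random"); the treatment effect is
#' either heterogeneous, \eqn{u_i \sim N(0, \tau^2)} ("random"), or common
#' across trials (\eqn{\tau^2} constrained to 0); and residuals share a common
#' variance \eqn{e_{ij} \sim N(0, \sigma^2)}.  Baseline adjustment terms
#' \eqn{\lambda_i}, when requested, are centred at each trial's own baseline
#' mean and may be trial-specific ("stratified") or shared ("common").
#'
#' @param intercept `"stratified"` (one fixed intercept per trial) or
#'   `"random"` (normal trial intercepts with mean \eqn{\beta} and variance
#'   \eqn{\tau_\beta^2}).
#' @param treatment `"random"` (between-trial variance \eqn{\tau^2}
#'   estimated) or `"common"` (\eqn{\tau^2 = 0}, not estimated).
#' @param baseline `"none"`, `"stratified"` (one adjustment slope per trial)
#'   or `"common"` (shared slope); requires a baseline outcome in the data.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param alpha two-sided type-I error level for confidence intervals,
#'   strictly inside (0, 1); default 0.05.
#' @param max_iter optimizer iteration cap counted towards the convergence
#'   flag; default 100.
#' @param rel_tol relative convergence tolerance on the (restricted)
#'   log-likelihood; default 1e-9.
#'
#' @return An object of class `ipd_model_spec`.
#' @examples
#' model_spec()                                   # stratified + random, REML
#' model_spec(intercept = "random", estimation = "ML")
#' @export
model_spec <- function(intercept = c("stratified", "random"),
                       treatment = c("random", "common"),
                       baseline = c("none", "stratified", "common"),
                       estimation = c("REML", "ML"),
                       alpha = 0.05, max_iter = 100L, rel_tol = 1e-9) {
  intercept <- match.arg(intercept)
  treatment <- match.arg(treatment)
  baseline <- match.arg(baseline)
  estimation <- match.arg(estimation)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be a positive integer", call. = FALSE)
  if (!is.numeric(rel_tol) || rel_tol <= 0) {
    stop("`rel_tol` must be positive", call. = FALSE)
  }
  structure(list(intercept = intercept, treatment = treatment,
                 baseline = baseline, estimation = estimation,
                 alpha = alpha, max_iter = max_iter, rel_tol = rel_tol),
            class = "ipd_model_spec")
}

#' @export
print.ipd_model_spec <- function(x, ...) {
  cat("One-stage IPD model specification\n")
  cat("  intercept:  ", x$intercept, "\n", sep = "")
  cat("  treatment:  ", x$treatment, " effect\n", sep = "")
  cat("  baseline:   ", x$baseline, "\n", sep = "")
  cat("  estimation: ", x$estimation, " (alpha = ", format(x$alpha), ")\n",
      sep = "")
  invisible(x)
}
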