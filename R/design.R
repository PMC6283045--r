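#' Build the per-trial design structure for a one-stage model
#'
#' Translates an IPD dataset and a model specification into the block
#' structure consumed by the block-likelihood fitter: for each trial a local
#' fixed-effect design matrix (trial intercept dummy or shared grand
#' intercept, optional within-trial-centred baseline column, treatment column
#' last), the random-effect directions scaled by each variance component
#' (an all-ones vector for a random intercept with variance
#' \eqn{\tau_\beta^2}, the treatment indicator for a random treatment effect
#' with variance \eqn{\tau^2}), and pre-computed cross-products so that each
#' marginal likelihood evaluation costs O(K) small-matrix operations after a
#' single O(n) pass over the data.
#'
#' Global fixed-effect column order is deterministic: intercept column(s),
#' baseline column(s), treatment last, so the summary treatment effect
#' \eqn{\theta} is always the final coordinate.
#'
#' @param data an [ipd_dataset()] object.
#' @param spec an [model_spec()] object.
#' @return An object of class `ipd_design` with elements `blocks` (per-trial
#'   structure), `p` (fixed-effect count), `q` (variance-parameter count),
#'   `vc_names` (active variance components, `sigma2` first), `fixed_labels`,
#'   `theta_index` (`= p`), `K`, `N` and a `spec` echo.
#' @examples
#' cfg <- scenario_config("Base", "normal_random")
#' set.seed(1); d <- generate_ipd(cfg)
#' des <- build_design(d, model_spec())
#' c(p = des$p, q = des$q)
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "ipd_data"), inherits(spec, "ipd_model_spec"))
  has_baseline <- "yb" %in% names(data)
  if (spec$baseline != "none" && !has_baseline) {
    stop("configuration error: baseline adjustment requested but the ",
         "dataset has no baseline outcome", call. = FALSE)
  }
  labels <- levels(data$trial)
  K <- length(labels)

  # every trial must have both arms: theta is always in the model
  arm_tab <- table(data$trial, data$treat)
  single <- labels[arm_tab[, "0"] == 0L | arm_tab[, "1"] == 0L]
  if (length(single) > 0L) {
    stop("validation error: trial(s) with a single arm: ",
         paste(single, collapse = ", "), call. = FALSE)
  }

  n_int <- if (spec$intercept == "stratified") K else 1L
  n_bas <- switch(spec$baseline, none = 0L, common = 1L, stratified = K)
  p <- n_int + n_bas + 1L
  theta_index <- p

  fixed_labels <- c(
    if (spec$intercept == "stratified") paste0("beta[", labels, "]") else "beta",
    switch(spec$baseline,
           none = character(0),
           common = "lambda",
           stratified = paste0("lambda[", labels, "]")),
    "theta")

  vc_names <- c("sigma2",
                if (spec$treatment == "random") "tau2",
                if (spec$intercept == "random") "tau_beta2")

  blocks <- vector("list", K)
  for (i in seq_len(K)) {
    rows <- which(as.integer(data$trial) == i)
    y <- data$yf[rows]
    tvec <- as.double(data$treat[rows])
    n <- length(rows)

    cols <- list()
    idx <- integer(0)
    # intercept
    cols[[length(cols) + 1L]] <- rep(1, n)
    idx <- c(idx, if (spec$intercept == "stratified") i else 1L)
    # baseline, centred at this trial's own baseline mean
    if (n_bas > 0L) {
      bc <- data$yb[rows] - mean(data$yb[rows])
      if (spec$baseline == "stratified" && stats::sd(bc) == 0) {
        stop("design error: baseline outcome is constant within trial '",
             labels[i], "'; its stratified adjustment slope is not ",
             "identifiable", call. = FALSE)
      }
      cols[[length(cols) + 1L]] <- bc
      idx <- c(idx, n_int + if (spec$baseline == "stratified") i else 1L)
    }
    # treatment, always last
    cols[[length(cols) + 1L]] <- tvec
    idx <- c(idx, theta_index)

    Z <- do.call(cbind, cols)

    # random-effect directions, one column per active non-residual component
    U <- NULL
    vc <- character(0)
    if (spec$intercept == "random") {
      U <- cbind(U, rep(1, n)); vc <- c(vc, "tau_beta2")
    }
    if (spec$treatment == "random") {
      U <- cbind(U, tvec); vc <- c(vc, "tau2")
    }

    ss <- list(n = n,
               ZtZ = crossprod(Z),
               Zty = drop(crossprod(Z, y)),
               yty = sum(y * y),
               UtU = if (!is.null(U)) crossprod(U),
               UtZ = if (!is.null(U)) crossprod(U, Z),
               Uty = if (!is.null(U)) drop(crossprod(U, y)))

    blocks[[i]] <- list(label = labels[i], y = y, Z = Z, U = U,
                        idx = idx, vc = vc, ss = ss)
  }

  # global identifiability check on X'X
  XtX <- matrix(0, p, p)
  for (bl in blocks) XtX[bl$idx, bl$idx] <- XtX[bl$idx, bl$idx] + bl$ss$ZtZ
  if (qr(XtX)$rank < p) {
    stop("design error: rank-deficient fixed-effect design (collinear ",
         "columns); check baseline variation within trials", call. = FALSE)
  }

  structure(list(blocks = blocks, p = p, q = length(vc_names),
                 vc_names = vc_names, fixed_labels = fixed_labels,
                 theta_index = theta_index, K = K, N = nrow(data),
                 trial_labels = labels, spec = spec),
            class = "ipd_design")
}

#' @export
print.ipd_design <- function(x, ...) {
  cat("One-stage IPD design: K = ", x$K, ", N = ", x$N,
      ", p = ", x$p, " fixed effects, q = ", x$q,
      " variance components (", paste(x$vc_names, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
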