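# Synthetic IPD generation.  All functions draw from R's global RNG stream;
# callers (the replication engine) seed it deterministically per replicate.

#' Draw per-trial sample sizes for a scenario
#'
#' Fixed rules return the constant; uniform rules draw independent
#' integer-uniform sizes inclusive of both endpoints.  When a scenario mixes
#' rules (the B2 family), the rules are applied in order: e.g. in B2 trials
#' 1-5 come from U(30, 100) and trials 6-10 from U(900, 1000).
#'
#' @param config a [scenario_config()] object.
#' @return Integer vector of `config$K` trial sizes.
#' @export
draw_trial_sizes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  unlist(lapply(config$size_spec, function(r) {
    if (r$min == r$max) rep(r$min, r$k)
    else sample(seq.int(r$min, r$max), r$k, replace = TRUE)
  }))
}

#' Allocate participants 1:1 to treatment and control
#'
#' Exactly balanced allocation: `floor(n/2)` treated and `ceiling(n/2)`
#' control participants (the extra participant under odd `n` goes to
#' control), in a random order.
#'
#' @param n_i number of participants in the trial, at least 2.
#' @return Integer 0/1 vector of length `n_i`.
#' @export
allocate_treatment <- function(n_i) {
  if (n_i < 2L) stop("a trial needs at least 2 participants", call. = FALSE)
  sample(rep(c(1L, 0L), c(floor(n_i / 2), ceiling(n_i / 2))))
}

#' Generate one synthetic IPD meta-analysis dataset
#'
#' Implements the scenario's data-generating mechanism for the final
#' (end-of-trial) outcome; no baseline outcome is generated.
#' Under the normal variants,
#' \deqn{Y_{ij} = \beta + u_{1i} + (\theta + u_{2i}) treat_{ij} + e_{ij}}
#' with \eqn{u_{1i} \sim N(0, \tau_\beta^2)}, \eqn{u_{2i} \sim N(0, \tau^2)}
#' and \eqn{e_{ij} \sim N(0, \sigma^2)}.  Under the beta variant the trial
#' intercept \eqn{\beta + u_{1i}} is replaced by \eqn{\beta_i \sim 220 \cdot
#' Beta(15, 3)}, a negatively skewed law scaled to plausible systolic blood
#' pressure values.  Under the common-effect variant \eqn{u_{2i} \equiv 0}.
#'
#' @param config a [scenario_config()] object.
#' @param truth if `TRUE`, attach the drawn trial-level effects as attribute
#'   `"truth"` (a data frame with `intercept_i` and `u2_i`) for diagnostics;
#'   the fitters never see it.
#' @return An [ipd_dataset()] object with columns `trial`, `treat`, `yf`.
#' @examples
#' set.seed(7)
#' d <- generate_ipd(scenario_config("Base", "normal_random"))
#' nrow(d)   # 1000
#' @export
generate_ipd <- function(config, truth = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  K <- config$K
  sizes <- draw_trial_sizes(config)

  # trial-level draws first, then participant-level noise trial by trial
  intercept_i <- if (config$dgm_variant == "beta_random") {
    config$beta_scale * stats::rbeta(K, config$beta_shape[1],
                                     config$beta_shape[2])
  } else {
    config$beta + stats::rnorm(K, 0, sqrt(config$tau_beta2))
  }
  u2_i <- if (config$dgm_variant == "normal_common") {
    rep(0, K)
  } else {
    stats::rnorm(K, 0, sqrt(config$tau2))
  }

  parts <- vector("list", K)
  for (i in seq_len(K)) {
    n <- sizes[i]
    tr <- allocate_treatment(n)
    e <- stats::rnorm(n, 0, sqrt(config$sigma2))
    y <- intercept_i[i] + (config$theta + u2_i[i]) * tr + e
    parts[[i]] <- data.frame(trial = rep(i, n), treat = tr, yf = y)
  }
  df <- do.call(rbind, parts)
  out <- ipd_dataset(df)
  if (truth) {
    attr(out, "truth") <- data.frame(trial = seq_len(K), n_i = sizes,
                                     intercept_i = intercept_i, u2_i = u2_i)
  }
  out
}
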