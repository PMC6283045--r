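# Simulation scenario grid.
#
# Fourteen scenarios vary the number of trials K, the per-trial sample-size
# rules, and the magnitude of the intercept / treatment-effect heterogeneity
# around a base case of K = 10 trials of n = 100 participants with
# theta = -9.66, tau2 = 7.79, beta = 159.73, tau_beta2 = 233.99 and
# sigma2 = 333.74.  Each scenario is crossed with three data-generating
# mechanisms: a random treatment effect with normal trial intercepts, a
# random treatment effect with 220 * Beta(15, 3) trial intercepts (C1/C2 do
# not apply: there is no tau_beta2 to vary), and a common treatment effect
# (tau2 = 0) with normal intercepts (D1/D2 do not apply: tau2 cannot be
# halved or doubled), giving 38 scenario cells in total.

BASE_PARAMS <- list(theta = -9.66, tau2 = 7.79, beta = 159.73,
                    tau_beta2 = 233.99, sigma2 = 333.74)

SCENARIO_IDS <- c("Base", "A1", "A2", "B1", "B2", "B1-A1", "B1-A2",
                  "B2-A1", "B2-A2", "B3", "C1", "C2", "D1", "D2")

DGM_VARIANTS <- c("normal_random", "beta_random", "normal_common")

# size rule: list(k = number of trials, min =, max =) drawn integer-uniform
size_rules <- function(id) {
  switch(id,
    "Base" = , "A1" = , "A2" = , "C1" = , "C2" = , "D1" = , "D2" = {
      K <- switch(id, "A1" = 5L, "A2" = 20L, 10L)
      list(list(k = K, min = 100L, max = 100L))
    },
    "B1" = list(list(k = 10L, min = 30L, max = 1000L)),
    "B1-A1" = list(list(k = 5L, min = 30L, max = 1000L)),
    "B1-A2" = list(list(k = 20L, min = 30L, max = 1000L)),
    "B2" = list(list(k = 5L, min = 30L, max = 100L),
                list(k = 5L, min = 900L, max = 1000L)),
    "B2-A1" = list(list(k = 2L, min = 30L, max = 100L),
                   list(k = 3L, min = 900L, max = 1000L)),
    "B2-A2" = list(list(k = 10L, min = 30L, max = 100L),
                   list(k = 10L, min = 900L, max = 1000L)),
    "B3" = list(list(k = 10L, min = 30L, max = 100L)),
    stop("unknown scenario id: ", id, call. = FALSE))
}

#' One cell of the simulation grid
#'
#' Returns the full set of true parameter values and trial-size rules for
#' one scenario under one data-generating mechanism (DGM).
#'
#' @param scenario_id one of `"Base"`, `"A1"`, `"A2"`, `"B1"`, `"B2"`,
#'   `"B1-A1"`, `"B1-A2"`, `"B2-A1"`, `"B2-A2"`, `"B3"`, `"C1"`, `"C2"`,
#'   `"D1"`, `"D2"`.
#' @param dgm_variant `"normal_random"` (normal trial intercepts, random
#'   treatment effect), `"beta_random"` (scaled-beta trial intercepts,
#'   random treatment effect; excludes C1/C2) or `"normal_common"` (normal
#'   intercepts, common treatment effect with `tau2 = 0`; excludes D1/D2).
#' @return An object of class `scenario_config`: a list with
#'   `scenario_id`, `dgm_variant`, `K`, `size_spec` (list of
#'   `(k, min, max)` integer-uniform rules applied in order),
#'   `theta`, `tau2`, `beta`, `tau_beta2`, `sigma2`, and for the beta
#'   variant `beta_shape = c(15, 3)` and `beta_scale = 220`.
#' @examples
#' scenario_config("B2", "normal_random")
#' @export
scenario_config <- function(scenario_id, dgm_variant = "normal_random") {
  scenario_id <- match.arg(scenario_id, SCENARIO_IDS)
  dgm_variant <- match.arg(dgm_variant, DGM_VARIANTS)
  if (dgm_variant == "beta_random" && scenario_id %in% c("C1", "C2")) {
    stop("scenario ", scenario_id, " is not defined under the beta-intercept ",
         "mechanism (no tau_beta2 to vary)", call. = FALSE)
  }
  if (dgm_variant == "normal_common" && scenario_id %in% c("D1", "D2")) {
    stop("scenario ", scenario_id, " is not defined under the common-effect ",
         "mechanism (tau2 is fixed at 0)", call. = FALSE)
  }
  pars <- BASE_PARAMS
  pars$tau_beta2 <- switch(scenario_id, "C1" = 117, "C2" = 468,
                           pars$tau_beta2)
  pars$tau2 <- switch(scenario_id, "D1" = 3.9, "D2" = 15.6, pars$tau2)
  if (dgm_variant == "normal_common") pars$tau2 <- 0

  rules <- size_rules(scenario_id)
  cfg <- c(list(scenario_id = scenario_id, dgm_variant = dgm_variant,
                K = sum(vapply(rules, `[[`, integer(1), "k")),
                size_spec = rules),
           pars)
  if (dgm_variant == "beta_random") {
    cfg$beta_shape <- c(15, 3)
    cfg$beta_scale <- 220
    cfg$tau_beta2 <- NA_real_   # intercept spread set by the beta law
  }
  structure(cfg, class = "scenario_config")
}

#' Expand the full simulation scenario grid
#'
#' The crossing of the 14 scenarios with the 3 data-generating mechanisms,
#' minus the 4 undefined cells (`C1`/`C2` under the beta-intercept variant,
#' `D1`/`D2` under the common-effect variant): 38 cells in deterministic
#' scenario-major order.
#'
#' @return A named list of [scenario_config()] objects; names are
#'   `"<scenario>/<variant>"`.
#' @examples
#' length(scenario_grid())   # 38
#' @export
scenario_grid <- function() {
  out <- list()
  for (id in SCENARIO_IDS) {
    for (v in DGM_VARIANTS) {
      if (v == "beta_random" && id %in% c("C1", "C2")) next
      if (v == "normal_common" && id %in% c("D1", "D2")) next
      out[[paste(id, v, sep = "/")]] <- scenario_config(id, v)
    }
  }
  out
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario ", x$scenario_id, " (", x$dgm_variant, "): K = ", x$K, "\n",
      sep = "")
  for (r in x$size_spec) {
    cat("  ", r$k, " trial(s) with n ",
        if (r$min == r$max) paste0("= ", r$min)
        else paste0("~ U(", r$min, ", ", r$max, ")"), "\n", sep = "")
  }
  cat(sprintf("  theta = %g, tau2 = %g, sigma2 = %g\n",
              x$theta, x$tau2, x$sigma2))
  if (x$dgm_variant == "beta_random") {
    cat(sprintf("  intercepts: %g * Beta(%g, %g)\n", x$beta_scale,
                x$beta_shape[1], x$beta_shape[2]))
  } else {
    cat(sprintf("  intercepts: N(%g, %g)\n", x$beta, x$tau_beta2))
  }
  invisible(x)
}
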