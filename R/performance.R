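# Performance summaries over replication tables: bias, empirical SE, MSE,
# coverage, convergence and Monte-Carlo error, computed per
# (model, estimation, CI-method) cell.  Estimate-based metrics condition on
# model convergence; the convergence percentage itself does not.

#' Monte-Carlo standard error of a coverage estimate
#'
#' `100 * sqrt(p * (1 - p) / n_reps)`, in percentage points.  At a true
#' coverage of 0.95 and 1000 replicates this is about 0.7.
#'
#' @param p coverage proportion in `[0, 1]`.
#' @param n_reps number of replicates.
#' @return Monte-Carlo standard error in percentage points.
#' @examples
#' mc_error_coverage(0.95, 1000)
#' @export
mc_error_coverage <- function(p, n_reps) {
  stopifnot(p >= 0, p <= 1, n_reps >= 1)
  100 * sqrt(p * (1 - p) / n_reps)
}

#' Summarize a replication table into performance metrics
#'
#' For every (model, estimation, CI-method) cell of the replication table,
#' computes, conditional on model convergence:
#' * `mean_pct_bias_theta`: `100 * (mean(theta_hat) - theta) / theta`,
#'   signed relative to the true (negative) effect, so an estimate more
#'   negative than the truth yields a negative percentage;
#' * `median_pct_bias_tau2`: `100 * (median(tau2_hat) - tau2) / tau2`
#'   (absent when `tau2 = 0`), using the sample median (midpoint
#'   interpolation for even counts);
#' * `emp_se`: sample standard deviation of `theta_hat` (divisor R - 1);
#' * `mse`: `mean((theta_hat - theta)^2)` (divisor R);
#' * `coverage_pct` and its Monte-Carlo error `mc_se_coverage`;
#' and, over all replicates, `convergence_pct`.  The algebraic identity
#' `mse = (mean bias)^2 + emp_se^2 * (R - 1) / R` holds exactly.
#'
#' @param table a replication table from [run_scenario()].
#' @param truth the [scenario_config()] the table was generated under.
#' @return A data frame keyed by
#'   `(scenario_id, dgm_variant, model, estimation, ci_method)`.
#' @export
summarize_replications <- function(table, truth) {
  stopifnot(nrow(table) > 0L, inherits(truth, "scenario_config"))
  theta <- truth$theta
  tau2 <- truth$tau2
  key <- interaction(table$model, table$estimation, table$ci_method,
                     drop = TRUE)
  rows <- lapply(split(table, key), function(g) {
    R_all <- nrow(g)
    conv <- g[g$converged == 1L, , drop = FALSE]
    R <- nrow(conv)
    base <- data.frame(
      scenario_id = g$scenario_id[1], dgm_variant = g$dgm_variant[1],
      model = g$model[1], estimation = g$estimation[1],
      ci_method = g$ci_method[1],
      convergence_pct = 100 * mean(g$converged),
      n_converged = R, stringsAsFactors = FALSE)
    if (R == 0L) {
      warning("no converged replicates for ", key[1], call. = FALSE)
      return(cbind(base, mean_pct_bias_theta = NA_real_,
                   median_pct_bias_tau2 = NA_real_, emp_se = NA_real_,
                   mse = NA_real_, coverage_pct = NA_real_,
                   mc_se_coverage = NA_real_, mean_runtime = NA_real_))
    }
    cov_ok <- conv$covered[!is.na(conv$covered)]
    cov_p <- if (length(cov_ok) > 0L) mean(cov_ok) else NA_real_
    cbind(base,
          mean_pct_bias_theta = 100 * (mean(conv$theta_hat) - theta) / theta,
          median_pct_bias_tau2 = if (!is.na(tau2) && tau2 > 0 &&
                                     any(!is.na(conv$tau2_hat))) {
            100 * (stats::median(conv$tau2_hat) - tau2) / tau2
          } else NA_real_,
          emp_se = stats::sd(conv$theta_hat),
          mse = mean((conv$theta_hat - theta)^2),
          coverage_pct = 100 * cov_p,
          mc_se_coverage = if (is.na(cov_p)) NA_real_ else
            mc_error_coverage(cov_p, length(cov_ok)),
          mean_runtime = mean(conv$runtime_seconds, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model, out$estimation, out$ci_method), , drop = FALSE]
}

#' Write wide-format result tables from performance summaries
#'
#' Produces CSV files mirroring the usual presentation of a simulation
#' study of this design: a treatment-effect bias table and a heterogeneity
#' bias table keyed scenario x (stratified, random) x (ML, REML), and a
#' coverage table keyed scenario x model x CI combination.
#'
#' @param summaries a data frame of (possibly row-bound) results from
#'   [summarize_replications()] over one or more scenarios.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the files written: `bias_theta.csv`,
#'   `bias_tau2.csv`, `coverage.csv`.
#' @export
render_tables <- function(summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  std <- summaries[summaries$ci_method == "standard", , drop = FALSE]

  wide <- function(df, value) {
    ids <- unique(df$scenario_id)
    combos <- unique(df[, c("model", "estimation")])
    out <- data.frame(scenario = ids, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(combos))) {
      cn <- paste(combos$model[j], combos$estimation[j], sep = "_")
      out[[cn]] <- vapply(ids, function(id) {
        v <- df[[value]][df$scenario_id == id &
                           df$model == combos$model[j] &
                           df$estimation == combos$estimation[j]]
        if (length(v) == 1L) v else NA_real_
      }, numeric(1))
    }
    out
  }

  p1 <- file.path(dir, "bias_theta.csv")
  utils::write.csv(wide(std, "mean_pct_bias_theta"), p1, row.names = FALSE)
  p2 <- file.path(dir, "bias_tau2.csv")
  utils::write.csv(wide(std, "median_pct_bias_tau2"), p2, row.names = FALSE)

  cv <- summaries[!(summaries$estimation == "ML" &
                      summaries$ci_method != "standard"), , drop = FALSE]
  ids <- unique(cv$scenario_id)
  combos <- unique(cv[, c("model", "estimation", "ci_method")])
  covw <- data.frame(scenario = ids, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(combos))) {
    cn <- paste(combos$model[j], combos$estimation[j], combos$ci_method[j],
                sep = "_")
    covw[[cn]] <- vapply(ids, function(id) {
      v <- cv$coverage_pct[cv$scenario_id == id &
                             cv$model == combos$model[j] &
                             cv$estimation == combos$estimation[j] &
                             cv$ci_method == combos$ci_method[j]]
      if (length(v) == 1L) v else NA_real_
    }, numeric(1))
  }
  p3 <- file.path(dir, "coverage.csv")
  utils::write.csv(covw, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Plot coverage by scenario and method
#'
#' Simple dot chart of coverage percentages per scenario for each
#' model/estimation/CI combination, with a reference line at the nominal
#' level.
#'
#' @param summaries output of [summarize_replications()] (row-bound over
#'   scenarios).
#' @param nominal nominal coverage percentage (default 95).
#' @return Invisibly, `NULL`; draws on the active graphics device.
#' @export
plot_coverage <- function(summaries, nominal = 95) {
  cv <- summaries[!(summaries$estimation == "ML" &
                      summaries$ci_method != "standard"), , drop = FALSE]
  combo <- paste(cv$model, cv$estimation, cv$ci_method, sep = "+")
  ids <- unique(cv$scenario_id)
  x <- match(cv$scenario_id, ids)
  graphics::plot(x, cv$coverage_pct, pch = as.integer(factor(combo)),
                 xaxt = "n", xlab = "scenario", ylab = "coverage (%)",
                 ylim = range(c(cv$coverage_pct, nominal), na.rm = TRUE))
  graphics::axis(1, at = seq_along(ids), labels = ids, las = 2)
  graphics::abline(h = nominal, lty = 2)
  graphics::legend("bottomright", legend = levels(factor(combo)),
                   pch = seq_along(levels(factor(combo))), cex = 0.7)
  invisible(NULL)
}
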