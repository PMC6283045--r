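make_toy_table <- function(theta_hats, tau2_hats = NULL, covered = NULL,
                           converged = NULL) {
  R <- length(theta_hats)
  data.frame(scenario_id = "Base", dgm_variant = "normal_random",
             rep_index = seq_len(R), model = "stratified",
             estimation = "REML", ci_method = "standard",
             theta_hat = theta_hats, var_theta = 1,
             ci_lower = theta_hats - 2, ci_upper = theta_hats + 2,
             df = Inf,
             covered = if (is.null(covered)) 1L else covered,
             tau2_hat = if (is.null(tau2_hats)) NA_real_ else tau2_hats,
             tau_beta2_hat = NA_real_, sigma2_hat = 300,
             converged = if (is.null(converged)) 1L else converged,
             n_iter = 5L, runtime_seconds = 0.01)
}

test_that("the Monte-Carlo coverage error formula is exact", {
  expect_equal(round(mc_error_coverage(0.95, 1000), 1), 0.7)
  expect_equal(mc_error_coverage(0.5, 1), 50)
  expect_equal(mc_error_coverage(1, 250), 0)
})

test_that("degenerate and hand-computed tables summarize exactly", {
  cfg <- scenario_config("Base", "normal_random")
  # every estimate equal to the truth: all error metrics vanish
  s0 <- summarize_replications(make_toy_table(rep(-9.66, 10)), cfg)
  expect_equal(s0$mean_pct_bias_theta, 0)
  expect_equal(s0$emp_se, 0)
  expect_equal(s0$mse, 0)
  # spreadsheet oracle on four hand-picked values
  th <- c(-9, -10, -11, -8.5)
  s <- summarize_replications(make_toy_table(th, covered = c(1L, 1L, 0L, 1L)),
                              cfg)
  expect_equal(s$mean_pct_bias_theta, 100 * (mean(th) + 9.66) / (-9.66))
  expect_equal(s$emp_se, sd(th))
  expect_equal(s$mse, mean((th + 9.66)^2))
  expect_equal(s$coverage_pct, 75)
  expect_equal(s$mc_se_coverage, 100 * sqrt(0.75 * 0.25 / 4))
  expect_equal(s$convergence_pct, 100)
  # a tau2 median at the zero boundary is reported as exactly -100
  s2 <- summarize_replications(
    make_toy_table(th, tau2_hats = c(0, 0, 0, 5)), cfg)
  expect_identical(s2$median_pct_bias_tau2, -100)
})

test_that("the mse identity in terms of bias and empirical SE holds exactly", {
  cfg <- scenario_config("Base", "normal_random")
  set.seed(6)
  th <- rnorm(101, -9.2, 1.3)
  s <- summarize_replications(make_toy_table(th), cfg)
  R <- s$n_converged
  bias_abs <- mean(th) - (-9.66)
  expect_equal(s$mse, bias_abs^2 + s$emp_se^2 * (R - 1) / R,
               tolerance = 1e-12)
})

test_that("metrics condition on convergence while the convergence rate does not", {
  cfg <- scenario_config("Base", "normal_random")
  tab <- make_toy_table(c(-9, -10, -50, -9.5),
                        converged = c(1L, 1L, 0L, 1L))
  tab$theta_hat[3] <- NA
  s <- summarize_replications(tab, cfg)
  expect_equal(s$convergence_pct, 75)
  expect_equal(s$n_converged, 3L)
  expect_equal(s$mean_pct_bias_theta,
               100 * (mean(c(-9, -10, -9.5)) + 9.66) / (-9.66))
})

test_that("rendered tables have the expected wide shapes", {
  dir <- withr::local_tempdir()
  tab <- get_sim("Base", "normal_random", 1000)
  s <- summarize_replications(tab, scenario_config("Base", "normal_random"))
  paths <- render_tables(s, dir)
  expect_true(all(file.exists(paths)))
  bias <- read.csv(file.path(dir, "bias_theta.csv"))
  expect_equal(nrow(bias), 1)
  expect_setequal(names(bias), c("scenario", "stratified_ML",
                                 "stratified_REML", "random_ML",
                                 "random_REML"))
  cov <- read.csv(file.path(dir, "coverage.csv"))
  expect_equal(ncol(cov), 9)   # scenario + 2 models x 4 CI combinations
})

test_that("common-effect coverage is near nominal and KR tracks Satterthwaite", {
  sc <- get_summary("Base", "normal_common", 1000)
  expect_true(all(sc$coverage_pct >= 92 & sc$coverage_pct <= 98))
  sb <- get_summary("Base", "normal_random", 1000)
  for (m in c("stratified", "random")) {
    kr <- pick_metric(sb, m, "REML", "kr", "coverage_pct")
    sat <- pick_metric(sb, m, "REML", "satterthwaite", "coverage_pct")
    expect_lt(abs(kr - sat), 2)
  }
})
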