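# single balanced trial, common effect: the classical two-sample setting
make_single_trial <- function(n = 40, seed = 5) {
  set.seed(seed)
  ipd_dataset(data.frame(trial = 1,
                         treat = rep(c(1L, 0L), each = n / 2),
                         yf = rnorm(n, 160, 15) - 9 * rep(c(1, 0), each = n / 2)))
}

test_that("the variance of the residual-variance estimate matches the chi-square law", {
  d <- make_single_trial(n = 40)
  f <- fit_onestage(d, model_spec("stratified", "common", estimation = "REML"))
  W <- varcomp_information(f)
  # REML sigma2_hat ~ sigma2 * chi2_(n-p) / (n-p): variance 2 sigma^4 / (n-p)
  expect_equal(W[["sigma2", "sigma2"]], 2 * f$sigma2_hat^2 / (40 - 2),
               tolerance = 1e-6)
})

test_that("the information inverse is symmetric PSD and matches a dense evaluation", {
  cfg <- scenario_config("Base", "normal_random")
  set.seed(12)
  d <- generate_ipd(cfg)
  dsmall <- make_small_ipd(K = 4, n_max = 12, seed = 41)
  for (case in list(list(d, "stratified"), list(d, "random"),
                    list(dsmall, "stratified"), list(dsmall, "random"))) {
    f <- fit_onestage(case[[1]], model_spec(case[[2]], "random",
                                            estimation = "REML"))
    W <- suppressWarnings(varcomp_information(f))
    expect_equal(W, t(W))
    expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  # dense oracle for the expected REML information on the small fixture
  f <- fit_onestage(dsmall, model_spec("random", "random", estimation = "REML"))
  vc <- c(sigma2 = f$sigma2_hat, tau2 = f$tau2_hat,
          tau_beta2 = f$tau_beta2_hat)
  vc["sigma2"] <- max(vc["sigma2"], 1e-10)
  des <- f$design
  ev <- ipdlmm:::ll_eval(des, vc[des$vc_names], "REML", inference = TRUE)
  info_block <- 0.5 * ev$trVV
  for (k in 1:des$q) for (l in 1:des$q) {
    info_block[k, l] <- info_block[k, l] +
      0.5 * (-2 * sum(ev$Phi * ev$Q[[k]][[l]]) +
               sum((ev$Phi %*% ev$H[[k]]) * t(ev$Phi %*% ev$H[[l]])))
  }
  info_dense <- dense_varcomp_info(des, vc[des$vc_names], "REML")
  expect_equal(unname(info_block), unname(info_dense), tolerance = 1e-8)
})

test_that("the standard CI is theta plus/minus z times the model SE", {
  d <- make_single_trial()
  f <- fit_onestage(d, model_spec("stratified", "common", estimation = "REML"))
  # forced-value check: theta = -9.66, Var = 1 gives (-11.62, -7.70) to 2 dp
  fake <- f
  fake$theta_hat <- -9.66
  fake$var_theta <- 1
  ci <- ci_standard(fake)
  expect_equal(round(c(ci$lower, ci$upper), 2), c(-11.62, -7.70))
  expect_identical(ci$df, Inf)
  ci2 <- ci_standard(f, alpha = 0.1)
  expect_equal(ci2$upper - ci2$lower, 2 * qnorm(0.95) * sqrt(f$var_theta))
  expect_error(ci_standard(f, alpha = 1), "alpha")
})

test_that("single-trial corrected intervals reproduce the pooled two-sample t interval", {
  d <- make_single_trial(n = 30, seed = 9)
  f <- fit_onestage(d, model_spec("stratified", "common", estimation = "REML"))
  tt <- t.test(d$yf[d$treat == 1], d$yf[d$treat == 0], var.equal = TRUE)
  for (ci in list(ci_satterthwaite(f), ci_kenward_roger(f))) {
    expect_equal(ci$df, 28, tolerance = 1e-6)
    expect_equal(ci$lower, tt$conf.int[1], tolerance = 1e-6)
    expect_equal(ci$upper, tt$conf.int[2], tolerance = 1e-6)
  }
})

test_that("KR and Satterthwaite share degrees of freedom; interval orderings hold", {
  cfg <- scenario_config("Base", "normal_random")
  set.seed(77)
  d <- generate_ipd(cfg)
  for (im in c("stratified", "random")) {
    f <- fit_onestage(d, model_spec(im, "random", estimation = "REML"))
    std <- ci_standard(f)
    sat <- ci_satterthwaite(f)
    kr <- ci_kenward_roger(f)
    expect_equal(kr$df, sat$df, tolerance = 1e-6)
    expect_gt(sat$df, 0)
    expect_lt(sat$df, f$design$N)
    # same centre and variance, t quantile beats z: strict containment
    expect_lt(sat$lower, std$lower)
    expect_gt(sat$upper, std$upper)
    # KR inflates the variance on this fixture
    expect_gte(kr$upper - kr$lower, sat$upper - sat$lower)
    for (ci in list(std, sat, kr)) {
      expect_lt(ci$lower, ci$upper)
      expect_true(ci$lower < f$theta_hat && f$theta_hat < ci$upper)
    }
  }
})

test_that("corrections are refused after ML estimation", {
  d <- make_small_ipd(K = 4, seed = 55)
  f <- fit_onestage(d, model_spec("stratified", "random", estimation = "ML"))
  expect_error(ci_satterthwaite(f), "REML")
  expect_error(ci_kenward_roger(f), "REML")
  expect_s3_class(ci_standard(f), "ipd_ci")
})

test_that("corrected intervals approach the standard interval in large samples", {
  set.seed(31)
  n <- 10000
  d <- ipd_dataset(data.frame(trial = 1, treat = rep(c(1L, 0L), n / 2),
                              yf = rnorm(n, 160, 15)))
  f <- fit_onestage(d, model_spec("stratified", "common", estimation = "REML"))
  w_std <- with(ci_standard(f), upper - lower)
  w_sat <- with(ci_satterthwaite(f), upper - lower)
  w_kr <- with(ci_kenward_roger(f), upper - lower)
  expect_lt(abs(w_sat - w_std) / w_std, 0.01)
  expect_lt(abs(w_kr - w_std) / w_std, 0.01)
})

test_that("coverage decisions use the closed interval", {
  ci <- list(lower = -11.62, upper = -7.70)
  expect_identical(coverage_indicator(ci, -9.66), 1L)
  expect_identical(coverage_indicator(list(lower = -9, upper = -7), -9.66), 0L)
  expect_identical(coverage_indicator(list(lower = -9.66, upper = -7), -9.66), 1L)
})
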