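test_that("noise-free data are recovered exactly with variance at the zero boundary", {
  d <- make_noise_free()
  fits <- fit_all_combinations(d, "random")
  expect_named(fits, c("stratified_ML", "stratified_REML",
                       "random_ML", "random_REML"))
  for (f in fits) {
    expect_equal(f$theta_hat, -9.66, tolerance = 1e-8)
    expect_identical(f$tau2_hat, 0)
    expect_identical(f$sigma2_hat, 0)   # snapped at the boundary
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  cfg <- scenario_config("Base", "normal_random")
  set.seed(5)
  d <- generate_ipd(cfg)
  for (est in c("ML", "REML")) {
    f <- fit_onestage(d, model_spec("stratified", "random", estimation = est))
    m <- lme4::lmer(yf ~ 0 + trial + treat + (0 + treat | trial), data = d,
                    REML = (est == "REML"))
    expect_equal(f$theta_hat, unname(lme4::fixef(m)["treat"]),
                 tolerance = 1e-5)
    tau2_lmer <- as.data.frame(lme4::VarCorr(m))$vcov[1]
    expect_equal(f$tau2_hat, tau2_lmer, tolerance = 2e-4 * max(tau2_lmer, 1))

    f2 <- fit_onestage(d, model_spec("random", "random", estimation = est))
    m2 <- lme4::lmer(yf ~ treat + (1 | trial) + (0 + treat | trial), data = d,
                     REML = (est == "REML"))
    expect_equal(f2$theta_hat, unname(lme4::fixef(m2)["treat"]),
                 tolerance = 1e-5)
    vc2 <- as.data.frame(lme4::VarCorr(m2))
    tb_lmer <- vc2$vcov[vc2$grp == "trial" & !is.na(vc2$var1) &
                          vc2$var1 == "(Intercept)"]
    expect_equal(f2$tau_beta2_hat, tb_lmer, tolerance = 2e-4 * max(tb_lmer, 1))
  }
})

test_that("ANCOVA with a common baseline slope matches lme4 on baseline-adjusted data", {
  skip_if_not_installed("lme4")
  set.seed(17)
  df <- do.call(rbind, lapply(1:6, function(i) {
    n <- 40
    tr <- sample(rep(c(1L, 0L), each = 20))
    yb <- rnorm(n, 150, 12)
    data.frame(trial = i, treat = tr,
               yf = 20 + 5 * i + 0.8 * yb - 10 * tr + rnorm(n, 0, 8),
               yb = yb)
  }))
  d <- ipd_dataset(df, baseline = "yb")
  f <- fit_onestage(d, model_spec("stratified", "random", baseline = "common",
                                  estimation = "REML"))
  # lme4 with trial-centred baseline reproduces the same fixed effects
  dc <- transform(df, ybc = ave(yb, trial, FUN = function(x) x - mean(x)))
  m <- lme4::lmer(yf ~ 0 + factor(trial) + ybc + treat + (0 + treat | trial),
                  data = dc, REML = TRUE)
  expect_equal(f$theta_hat, unname(lme4::fixef(m)["treat"]), tolerance = 1e-5)
  expect_equal(unname(f$fixed_effects["lambda"]),
               unname(lme4::fixef(m)["ybc"]), tolerance = 1e-5)
})

test_that("common-effect stratified REML equals the closed-form weighted mean difference", {
  d <- make_small_ipd(K = 5, n_max = 14, seed = 23)
  f <- fit_onestage(d, model_spec("stratified", "common", estimation = "REML"))
  md <- w <- numeric(5)
  for (i in 1:5) {
    g <- d[as.integer(d$trial) == i, ]
    md[i] <- mean(g$yf[g$treat == 1]) - mean(g$yf[g$treat == 0])
    nT <- sum(g$treat == 1); nC <- sum(g$treat == 0)
    w[i] <- nT * nC / (nT + nC)
  }
  expect_equal(f$theta_hat, sum(w * md) / sum(w), tolerance = 1e-8)
})

test_that("the gradient is stationary at interior optima", {
  cfg <- scenario_config("Base", "normal_random")
  set.seed(8)
  d <- generate_ipd(cfg)
  for (im in c("stratified", "random")) {
    f <- fit_onestage(d, model_spec(im, "random", estimation = "REML"))
    expect_true(f$converged)
    vc <- c(sigma2 = f$sigma2_hat, tau2 = f$tau2_hat,
            tau_beta2 = f$tau_beta2_hat)[f$design$vc_names]
    interior <- vc > 0
    if (any(interior)) {
      g <- ipdlmm:::ll_eval(f$design, vc, "REML", deriv = TRUE)$grad
      expect_lt(max(abs(g[interior])), 1e-4)
    }
  }
})

test_that("a random treatment effect needs at least two trials", {
  one <- ipd_dataset(data.frame(trial = 1, treat = rep(c(0, 1), 10),
                                yf = rnorm(20)))
  expect_error(fit_onestage(one, model_spec("stratified", "random")),
               "at least 2 trials")
  expect_s3_class(fit_onestage(one, model_spec("stratified", "common")),
                  "onestage_fit")
})

test_that("stratified ML shrinks tau2 at least as hard as the random-intercept model", {
  tab <- get_sim("Base", "normal_random", 1000)
  std <- tab[tab$ci_method == "standard" & tab$estimation == "ML", ]
  s <- std[std$model == "stratified", ]
  r <- std[std$model == "random", ]
  stopifnot(identical(s$rep_index, r$rep_index))
  expect_gt(mean(s$tau2_hat <= r$tau2_hat, na.rm = TRUE), 0.5)
})

test_that("mean theta estimates are unbiased and ML tau2 medians sit below REML", {
  tab <- get_sim("Base", "normal_random", 1000)
  std <- tab[tab$ci_method == "standard", ]
  for (m in c("stratified", "random")) {
    for (e in c("ML", "REML")) {
      th <- std$theta_hat[std$model == m & std$estimation == e &
                            std$converged == 1L]
      mcse <- sd(th) / sqrt(length(th))
      expect_lt(abs(mean(th) - (-9.66)), 3 * mcse)
    }
    med_ml <- median(std$tau2_hat[std$model == m & std$estimation == "ML"],
                     na.rm = TRUE)
    med_reml <- median(std$tau2_hat[std$model == m & std$estimation == "REML"],
                       na.rm = TRUE)
    expect_lte(med_ml, med_reml)
  }
})
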