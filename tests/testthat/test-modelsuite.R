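test_that("AIC identity reproduces published cells", {
  expect_equal(aic_reml(-1584.44, 3), 3174.88)
  expect_equal(aic_reml(-1189.63, 4), 2387.26)
  expect_equal(aic_reml(0, 0), 0)
})

test_that("named models carry the advertised parameter counts", {
  sm <- small_st_sim(seed = 1, s = 5, c = 3, n_blocks = 4)
  m1 <- famclone(sm$pheno, "STMpF", trait = "Y", pev = FALSE)
  expect_equal(m1$n_params, 4)  # block, family, clone, residual
  m0 <- famclone(sm$pheno, "STMwF", trait = "Y", pev = FALSE)
  expect_equal(m0$n_params, 3)
  ms <- met_sim(seed = 2, s = 5, c = 3, t_ = 3, n_blocks = 4)
  mm <- famclone(ms$pheno, "METMpF", trait = "Y", pev = FALSE,
                 control = list(max_iter = 40))
  expect_equal(mm$n_params, 3 + 3 + 6 + 6)
  mw <- famclone(ms$pheno, "METMwF", trait = "Y", pev = FALSE,
                 control = list(max_iter = 40))
  expect_equal(mw$n_params, 3 + 3 + 6)
  ## scope misuse
  expect_error(famclone(sm$pheno, "METMpF", trait = "Y"), "at least two")
  expect_error(famclone(ms$pheno, "STMpF", trait = "Y"), "exactly one")
})

test_that("likelihood-ratio test follows the chi-square reference", {
  eq <- lrt_reml(-10, -10, df = 1)
  expect_equal(eq$lrt_stat, 0)
  expect_equal(eq$p_value, 1)
  ## the 1.92 log-likelihood increment is the 5% critical point at df = 1
  crit <- lrt_reml(-100, -100 + 1.92, df = 1)
  expect_equal(crit$lrt_stat, 3.84)
  expect_equal(crit$p_value, 0.05, tolerance = 2e-3)
  expect_equal(round(qchisq(0.95, 1) / 2, 2), 1.92)
  ## clipping of negative statistics
  expect_warning(neg <- lrt_reml(-5, -6, df = 1), "clipped")
  expect_equal(neg$lrt_stat, 0)
  expect_error(lrt_reml(-5, -4, df = 0), "df")
  ## boundary mixture halves the p-value
  pb <- lrt_reml(-100, -99, df = 1, boundary = TRUE)$p_value
  pp <- lrt_reml(-100, -99, df = 1)$p_value
  expect_equal(pb, pp / 2)
})

test_that("anova on nested fits matches the explicit LRT", {
  sm <- small_st_sim(seed = 5)
  m0 <- famclone(sm$pheno, "STMwF", trait = "Y", pev = FALSE)
  m1 <- famclone(sm$pheno, "STMpF", trait = "Y", pev = FALSE)
  a <- anova(m1, m0)
  expect_equal(a$df, 1)
  expect_equal(a$lrt_stat, max(0, 2 * (m1$loglik - m0$loglik)))
  expect_equal(AIC(logLik(m1)), aic_reml(m1$loglik, m1$n_params))
})

test_that("chi-square variance intervals behave at limits", {
  z <- varcomp_ci_chisq(0, se = 1)
  expect_true(z$intercepts_zero)
  ## large effective df shrinks the interval onto the estimate
  big <- varcomp_ci_chisq(2, df = 1e7)
  expect_equal(big$lower, 2, tolerance = 1e-2)
  expect_equal(big$upper, 2, tolerance = 1e-2)
  ci <- varcomp_ci_chisq(3, se = 1)
  expect_lt(ci$lower, 3); expect_gt(ci$upper, 3)
  expect_error(varcomp_ci_chisq(1), "se")
})

test_that("normal correlation intervals are symmetric and truncated", {
  ci <- corr_ci_normal(0, 0.1)
  expect_equal(ci$lower, -0.196, tolerance = 1e-3)
  expect_equal(ci$upper, 0.196, tolerance = 1e-3)
  tr <- corr_ci_normal(0.99, 0.5)
  expect_equal(tr$upper, 1)
  expect_error(corr_ci_normal(1.2, 0.1), "correlation")
  expect_error(corr_ci_normal(0.5, 0), "se")
})

test_that("nested-model AIC behaves under a true null family effect", {
  ## sigma2_s = 0: adding the family parameter should cost ~2 AIC units
  d_aic <- c()
  for (seed in 1:6) {
    sm <- small_st_sim(seed = 200 + seed, s = 12, c = 6, n_blocks = 8,
                       sigma2_s = 0, sigma2_c = 12, sigma2_b = 1,
                       sigma2_e = 10)
    m0 <- famclone(sm$pheno, "STMwF", trait = "Y", pev = FALSE)
    m1 <- famclone(sm$pheno, "STMpF", trait = "Y", pev = FALSE)
    d_aic <- c(d_aic, aic_reml(m1$loglik, m1$n_params) -
                 aic_reml(m0$loglik, m0$n_params))
  }
  expect_lt(abs(median(d_aic) - 2), 2)
})
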