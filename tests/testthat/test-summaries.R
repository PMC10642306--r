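test_that("rho_s matches published worked examples and its properties", {
  expect_equal(round_2 <- round(rho_s(7.18, 34.42), 2), 0.17)
  expect_equal(round(rho_s(11.26, 36.45), 2), 0.24)
  expect_equal(rho_s(0, 3), 0)
  expect_equal(rho_s(4, 4), 0.5)
  ## scale invariance: percent inputs give the same answer
  expect_equal(rho_s(7.18, 34.42), rho_s(71.8, 344.2))
  expect_error(rho_s(0, 0), "undefined")
})

test_that("percent contributions normalise to 100", {
  pc <- percent_contributions(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(pc$percent, rep(25, 4))
  sm <- small_st_sim(seed = 3)
  fit <- famclone(sm$pheno, "STMpF", trait = "Y", pev = FALSE)
  pc <- percent_contributions(fit)
  expect_equal(sum(pc$percent), 100)
  expect_setequal(pc$component, c("block", "family", "clone", "resid"))
})

test_that("MET percent contributions use each trial's own components", {
  ms <- met_sim(seed = 4, t_ = 2, s = 8, c = 4)
  fit <- famclone(ms$pheno, "METMpF", trait = "Y", pev = FALSE,
                  control = list(max_iter = 60))
  pc <- percent_contributions(fit)
  for (j in 1:2) {
    tl <- fit$trials[j]
    own <- unname(c(fit$vc$block[j], diag(fit$vc$family)[j],
                    diag(fit$vc$clone)[j], fit$vc$resid[j]))
    expect_equal(pc$percent[pc$trial == tl], 100 * own / sum(own),
                 tolerance = 1e-10)
    expect_equal(sum(pc$percent[pc$trial == tl]), 100)
  }
})

test_that("total genotypic composition is family plus clone", {
  u_s <- c(f = 1.0)
  u_c <- c(a = 0.2, b = -0.2)
  expect_equal(total_genotypic(u_s, u_c, c(a = "f", b = "f")),
               c(a = 1.2, b = 0.8))
  ## zero family effects reduce to the clone vector
  expect_equal(total_genotypic(c(f = 0), u_c, c(a = "f", b = "f")), u_c)
  ## matrix (MET) form against the dense composition oracle
  set.seed(9)
  s <- 4; c_ <- 3; t_ <- 2
  fams <- sprintf("F%d", 1:s)
  clones <- as.vector(outer(1:c_, fams, function(i, f) paste0(f, "_", i)))
  fam_of <- stats::setNames(rep(fams, each = c_), sort(clones))
  us <- matrix(rnorm(s * t_), s, t_, dimnames = list(fams, c("A", "B")))
  uc <- matrix(rnorm(s * c_ * t_), s * c_, t_,
               dimnames = list(sort(clones), c("A", "B")))
  got <- total_genotypic(us, uc, fam_of)
  ## dense oracle: per trial, incidence matrix times the family vector
  A <- matrix(0, nrow(uc), s, dimnames = list(rownames(uc), fams))
  A[cbind(rownames(uc), fam_of[rownames(uc)])] <- 1
  for (j in 1:t_)
    expect_equal(unname(got[, j]), unname(drop(A %*% us[, j]) + uc[, j]),
                 tolerance = 1e-12)
  expect_error(total_genotypic(us, uc, fam_of[-1]), "family")
})

test_that("environment correlations standardise the covariance", {
  expect_equal(env_genetic_correlations(diag(c(2, 3))), diag(2))
  G <- matrix(c(4, 2 * 3 * 1, 2 * 3 * 1, 9), 2)  # rho = 1
  expect_equal(env_genetic_correlations(G)[1, 2], 1)
  set.seed(10)
  for (k in 1:5) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(0.5, 3)
    expect_equal(env_genetic_correlations(A), cov2cor(A), tolerance = 1e-12)
  }
  z <- env_genetic_correlations(diag(c(1, 0)))
  expect_true(is.na(z[1, 2]))
})

test_that("accuracy formula and its limits", {
  expect_equal(accuracy(0, 2), 1)
  expect_equal(accuracy(2, 2), 0)
  expect_equal(accuracy(1, 4), sqrt(0.75))
  expect_warning(a <- accuracy(2.1, 2), "clip")
  expect_equal(a, 0)
  expect_error(accuracy(0, 0), "undefined")
})

test_that("relative efficiency reproduces published ratios", {
  expect_equal(round_half_up(relative_efficiency(0.67, 0.60), 2), 1.12)
  expect_equal(relative_efficiency(0.5, 0.5), 1)
  expect_equal(round_half_up(relative_efficiency(0.78, 0.70), 2), 1.11)
  expect_error(relative_efficiency(0.5, 0), "zero")
})

test_that("total-effect accuracy dominates clone accuracy given family signal", {
  ## matches the efficiency >= 1 pattern whenever families are informative
  for (seed in c(11, 12, 13)) {
    sm <- small_st_sim(seed = seed, s = 20, c = 10, n_blocks = 12,
                       sigma2_s = 6, sigma2_c = 15, sigma2_b = 2,
                       sigma2_e = 15)
    fit <- famclone(sm$pheno, "STMpF", trait = "Y")
    a <- accuracy_summary(fit)
    if (fit$vc$family > 0 && mean(fit$pev_s) < fit$vc$family)
      expect_gte(a$acc_total, a$acc_clone - 1e-8)
  }
})

test_that("MET fits recover the generating genetic correlations", {
  ## moderate Monte-Carlo check (tighter recovery runs in the acceptance suite)
  rs <- c()
  for (seed in 1:3) {
    ms <- met_sim(seed = 400 + seed, s = 20, c = 8, t_ = 2, n_blocks = 10,
                  r_s = 0.6, r_c = 0.5, design = "PREP")
    fit <- famclone(ms$pheno, "METMpF", trait = "Y", pev = FALSE,
                    control = list(max_iter = 80))
    rs <- c(rs, env_genetic_correlations(fit$vc$clone)[1, 2])
  }
  expect_lt(abs(median(rs) - 0.5), 0.25)
})
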