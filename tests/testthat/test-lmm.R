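test_that("MME likelihood equals the dense marginal-covariance oracle", {
  set.seed(11)
  for (rep in 1:5) {
    N <- 20 + 5 * rep
    g1 <- factor(sample(letters[1:4], N, replace = TRUE))
    g2 <- factor(sample(LETTERS[1:6], N, replace = TRUE))
    X <- cbind(1, rnorm(N))
    Z1 <- model.matrix(~ g1 - 1); Z2 <- model.matrix(~ g2 - 1)
    y <- rnorm(N)
    vc <- list(resid = 0.8 + 0.2 * rep, t1 = 1.1, t2 = 0.4)
    ll <- reml_loglik(y, X, list(reml_term("t1", Z1, "idv"),
                                 reml_term("t2", Z2, "idv")), vc)
    V <- vc$t1 * tcrossprod(Z1) + vc$t2 * tcrossprod(Z2) +
      vc$resid * diag(N)
    expect_equal(ll, dense_reml_loglik(y, X, V), tolerance = 1e-10)
  }
})

test_that("unstructured Kronecker terms match the dense oracle", {
  set.seed(21)
  t_ <- 2; L <- 5; N <- 40
  trial <- rep(1:t_, each = N / t_)
  lev <- sample(L, N, replace = TRUE)
  ## trial-major columns: (trial1: levels, trial2: levels)
  Z <- matrix(0, N, t_ * L)
  Z[cbind(seq_len(N), (trial - 1) * L + lev)] <- 1
  G_t <- matrix(c(1, 0.5, 0.5, 2), 2)
  X <- matrix(1, N, 1)
  y <- rnorm(N)
  vc <- list(resid = c(1.5, 0.7), g = G_t)
  ll <- reml_loglik(y, X, list(reml_term("g", Z, "un", n_trials = t_)),
                    vc, resid_group = trial)
  G <- kronecker(G_t, diag(L))
  R <- diag(vc$resid[trial])
  expect_equal(ll, dense_reml_loglik(y, X, Z %*% G %*% t(Z) + R),
               tolerance = 1e-10)
  ## the assembled covariance has the cross-trial covariance between the
  ## same level's two columns
  expect_equal(G[1, L + 1], 0.5)
  expect_equal(G[1, 2], 0)
})

test_that("REML is invariant to translation and row permutation", {
  set.seed(31)
  N <- 30
  g <- factor(rep(1:6, each = 5))
  Z <- model.matrix(~ g - 1)
  X <- matrix(1, N, 1)
  y <- rnorm(N)
  vc <- list(resid = 1, g = 0.5)
  tm <- reml_term("g", Z, "idv")
  l0 <- reml_loglik(y, X, list(tm), vc)
  expect_equal(reml_loglik(y + 7.3, X, list(tm), vc), l0, tolerance = 1e-9)
  p <- sample(N)
  expect_equal(reml_loglik(y[p], X[p, , drop = FALSE],
                           list(reml_term("g", Z[p, ], "idv")), vc),
               l0, tolerance = 1e-9)
})

test_that("balanced one-way REML equals the ANOVA estimators", {
  set.seed(41)
  g <- 20; m <- 5
  fg <- factor(rep(seq_len(g), each = m))
  y <- rnorm(g, sd = 2)[fg] + rnorm(g * m, sd = 1.5)
  fit <- reml_fit(y, matrix(1, g * m, 1),
                  reml_term("g", model.matrix(~ fg - 1), "idv"))
  a <- anova(stats::lm(y ~ fg))
  msb <- a[1, 3]; msw <- a[2, 3]
  expect_true(fit$converged)
  expect_equal(fit$vc$resid, msw, tolerance = 1e-6)
  expect_equal(fit$vc$g, (msb - msw) / m, tolerance = 1e-6)
  ## closed-form shrinkage accuracy sqrt(m / (m + lambda)) holds exactly
  ## when the mean is known: fit with a zero-column fixed design
  fit0 <- reml_fit(y - mean(y), matrix(0, g * m, 0),
                   reml_term("g", model.matrix(~ fg - 1), "idv"))
  lambda <- fit0$vc$resid / fit0$vc$g
  expect_equal(accuracy(mean(fit0$pev$g), fit0$vc$g),
               sqrt(m / (m + lambda)), tolerance = 1e-6)
})

test_that("MME solution equals the dense GLS/BLUP closed form", {
  set.seed(51)
  for (rep in 1:4) {
    sm <- small_st_sim(seed = rep, s = 4, c = 2, n_blocks = 3, checks = 1)
    fit <- famclone(sm$pheno, "STMpF", trait = "Y")
    d <- sm$pheno
    is_check <- d$is_check
    X <- cbind(1, as.numeric(is_check))
    fam_f <- factor(ifelse(is_check, NA, d$family))
    ent_f <- factor(ifelse(is_check, NA, d$entry))
    blk_f <- factor(d$block)
    oneh <- function(f) {
      M <- matrix(0, nrow(d), nlevels(f))
      M[cbind(which(!is.na(f)), as.integer(f[!is.na(f)]))] <- 1
      colnames(M) <- levels(f); M
    }
    Z <- cbind(oneh(fam_f), oneh(ent_f), oneh(blk_f))
    vc <- fit$vc
    ## boundary estimates are solved at the same tiny positive floor the
    ## MME solver uses, so the oracle applies it too
    thr <- var(d$value) * 1e-7
    G <- diag(c(rep(max(vc$family, thr), nlevels(fam_f)),
                rep(max(vc$clone, thr), nlevels(ent_f)),
                rep(max(vc$block, thr), nlevels(blk_f))))
    R <- vc$resid * diag(nrow(d))
    oracle <- dense_blup(d$value, X, Z, G, R)
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-8)
    u_hat <- c(fit$u_s[levels(fam_f)], fit$u_c[levels(ent_f)],
               fit$u_b[paste(d$trial[1], levels(blk_f), sep = ":")])
    expect_equal(unname(u_hat), unname(oracle$u), tolerance = 1e-8)
    ## PEVs from the dense inverse MME agree too
    Ci <- dense_pev(X, Z, G, R)
    expect_equal(unname(fit$pev$family), unname(diag(Ci)[seq_len(nlevels(fam_f))]),
                 tolerance = 1e-8)
  }
})

test_that("PEV is bounded by the prior variance and shrinkage is coherent", {
  sm <- small_st_sim(seed = 7)
  fit <- famclone(sm$pheno, "STMpF", trait = "Y")
  expect_true(all(fit$pev$family >= 0))
  expect_true(all(fit$pev$family <= fit$vc$family + 1e-10))
  expect_true(all(fit$pev$clone <= fit$vc$clone + 1e-10))
  expect_true(all(fit$pev_g >= 0))
  ## BLUP vectors centre near zero under shrinkage
  expect_lt(abs(mean(fit$u_s)), 3 * sqrt(fit$vc$family / length(fit$u_s)))
})

test_that("degenerate fits behave: constant response, zero-variance prior", {
  d <- abd_design(3, c(A = 4), checks = 1, seed = 8)
  fb <- field_book(d)
  pheno <- data.frame(trial = "T1", block = fb$block, entry = fb$entry,
                      family = fb$family, is_check = fb$type == "check",
                      trait = "Y", value = 5)
  fit <- suppressWarnings(famclone(pheno, "STMpF", trait = "Y"))
  expect_equal(unname(fit$vc$family), 0, tolerance = 1e-6)
  expect_equal(unname(fit$vc$clone), 0, tolerance = 1e-6)
  ## a term whose prior variance is ~0 has ~0 BLUPs
  expect_lt(max(abs(fit$u_c)), 1e-4)
})

test_that("without the family term the clone variance absorbs both", {
  ## sigma2_s > 0: the no-family model's clone variance estimates s + c
  diffs <- c(); absorbed <- c()
  for (seed in 1:8) {
    sm <- small_st_sim(seed = seed, s = 30, c = 15, n_blocks = 20,
                       checks = 3, sigma2_s = 5, sigma2_c = 20,
                       sigma2_b = 2, sigma2_e = 25)
    m0 <- famclone(sm$pheno, "STMwF", trait = "Y", pev = FALSE)
    absorbed <- c(absorbed, m0$vc$clone)
  }
  expect_lt(abs(median(absorbed) / 25 - 1), 0.15)  # sigma2_s + sigma2_c = 25
})

test_that("with no family variance the two ST models agree", {
  rel <- c()
  for (seed in 1:6) {
    sm <- small_st_sim(seed = 100 + seed, s = 15, c = 8, n_blocks = 10,
                       checks = 2, sigma2_s = 0, sigma2_c = 15,
                       sigma2_b = 1, sigma2_e = 12)
    m0 <- famclone(sm$pheno, "STMwF", trait = "Y", pev = FALSE)
    m1 <- famclone(sm$pheno, "STMpF", trait = "Y", pev = FALSE)
    rel <- c(rel, abs(m0$vc$clone - (m1$vc$clone + m1$vc$family)) /
               m0$vc$clone)
    expect_gte(m1$loglik, m0$loglik - 1e-4)
  }
  expect_lt(median(rel), 0.05)
})

test_that("the nested single-trial fit agrees with an independent REML solver", {
  skip_if_not_installed("lme4")
  ## partially replicated layout so the clone factor is not saturated, and
  ## no check plots so the model is expressible as a plain lme4 formula
  des <- prep_design(8, even_families(50, 10), checks = 1,
                     target_p_n = 0.3, seed = 77)
  sim <- simulate_phenotypes(des, st_params(4, 12, 2, 10), seed = 78)
  d <- sim$pheno[!sim$pheno$is_check, , drop = FALSE]
  fit <- famclone(d, "STMpF", trait = "Y")
  lf <- lme4::lmer(value ~ 1 + (1 | family) + (1 | entry) + (1 | block),
                   data = d, REML = TRUE)
  vcl <- as.data.frame(lme4::VarCorr(lf))
  get <- function(g) vcl$vcov[vcl$grp == g]
  expect_equal(unname(fit$vc$family), get("family"), tolerance = 1e-4)
  expect_equal(unname(fit$vc$clone), get("entry"), tolerance = 1e-4)
  expect_equal(unname(fit$vc$block), get("block"), tolerance = 1e-4)
  expect_equal(unname(fit$vc$resid), vcl$vcov[vcl$grp == "Residual"],
               tolerance = 1e-4)
  ## identical log-likelihood convention (constant included)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  re <- lme4::ranef(lf)
  expect_equal(unname(fit$u_s[rownames(re$family)]),
               unname(re$family[[1]]), tolerance = 1e-3)
  expect_equal(unname(fit$u_c[rownames(re$entry)]),
               unname(re$entry[[1]]), tolerance = 1e-3)
})

test_that("rank-deficient fixed effects are reported as such", {
  sm <- small_st_sim(seed = 9, s = 3, c = 2, n_blocks = 3, checks = 1)
  d <- sm$pheno
  X <- cbind(1, 1 - as.numeric(d$is_check), as.numeric(d$is_check))
  expect_error(reml_fit(d$value, X,
                        reml_term("b", model.matrix(~ factor(d$block) - 1),
                                  "idv")),
               "rank")
})
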