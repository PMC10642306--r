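# Independent dense oracles and small fixture builders used across tests.
# The oracles deliberately avoid the package's mixed-model-equation path:
# they work from the marginal covariance V = Z G Z' + R.

## residual log-likelihood from the marginal covariance (dense)
dense_reml_loglik <- function(y, X, V) {
  N <- length(y); o <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * ((N - o) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
            drop(t(y) %*% P %*% y))
}

## GLS fixed effects and BLUP u = G Z' V^-1 (y - X beta), dense
dense_blup <- function(y, X, Z, G, R) {
  V <- Z %*% G %*% t(Z) + R
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- G %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), u = drop(u))
}

## PEV of random effects from the inverse MME coefficient matrix, dense
dense_pev <- function(X, Z, G, R) {
  Ri <- solve(R)
  C <- rbind(cbind(t(X) %*% Ri %*% X, t(X) %*% Ri %*% Z),
             cbind(t(Z) %*% Ri %*% X, t(Z) %*% Ri %*% Z + solve(G)))
  Ci <- solve(C)
  idx <- ncol(X) + seq_len(ncol(Z))
  Ci[idx, idx, drop = FALSE]
}

## split `total` clones over `k` families as evenly as possible
even_families <- function(total, k, prefix = "F") {
  sizes <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(sizes, sprintf("%s%02d", prefix, seq_len(k)))
}

## one-trait single-trial parameter set with explicit scalar components
st_params <- function(sigma2_s, sigma2_c, sigma2_b, sigma2_e, mean = 20,
                      check_means = NULL, trial = "T1") {
  sim_params(trials = trial,
             traits = list(Y = list(mean = mean, sigma2_block = sigma2_b,
                                    sigma2_resid = sigma2_e,
                                    G_ts = matrix(sigma2_s),
                                    G_tc = matrix(sigma2_c),
                                    check_means = check_means)))
}

## small single-trial simulated dataset (ABD) for fitting tests
small_st_sim <- function(seed = 1, s = 12, c = 6, n_blocks = 8, checks = 2,
                         sigma2_s = 4, sigma2_c = 12, sigma2_b = 2,
                         sigma2_e = 10) {
  d <- abd_design(n_blocks, even_families(s * c, s), checks = checks,
                  seed = seed)
  p <- st_params(sigma2_s, sigma2_c, sigma2_b, sigma2_e)
  sim <- simulate_phenotypes(d, p, seed = seed + 1000)
  list(design = d, params = p, pheno = sim$pheno, truth = sim$truth$Y)
}

## multi-trial simulated dataset with unstructured G matrices
met_sim <- function(seed = 1, s = 10, c = 4, n_blocks = 6, checks = 2,
                    t_ = 2, r_s = 0.5, r_c = 0.5,
                    d_s = rep(4, t_), d_c = rep(12, t_),
                    sigma2_b = rep(2, t_), sigma2_e = rep(10, t_),
                    design = "ABD", target_p_n = 0.25) {
  trials <- paste0("E", seq_len(t_))
  un <- function(d, r) (r + diag(1 - r, length(d))) * tcrossprod(sqrt(d))
  pars <- sim_params(trials = trials,
                     traits = list(Y = list(mean = seq(20, by = -2,
                                                       length.out = t_),
                                            sigma2_block = sigma2_b,
                                            sigma2_resid = sigma2_e,
                                            G_ts = un(d_s, r_s),
                                            G_tc = un(d_c, r_c))))
  fams <- even_families(s * c, s)
  des <- lapply(seq_len(t_), function(j) {
    if (design == "ABD")
      abd_design(n_blocks, fams, checks = checks, trial = trials[j],
                 seed = seed + j)
    else
      prep_design(n_blocks, fams, checks = checks, target_p_n = target_p_n,
                  trial = trials[j], seed = seed + j)
  })
  sim <- simulate_phenotypes(des, pars, seed = seed + 500)
  list(designs = des, params = pars, pheno = sim$pheno, truth = sim$truth$Y)
}
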