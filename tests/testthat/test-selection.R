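test_that("top-fraction selection is deterministic under ties", {
  s <- c(a = 3, b = 2, c = 1, d = 0.5, e = 0.1, f = 0, g = -1, h = -2,
         i = -3, j = -4)
  expect_equal(top_fraction(s, 0.2), c("a", "b"))
  expect_equal(length(top_fraction(s, 1)), 10)
  tied <- stats::setNames(rep(1, 5), c("e", "c", "a", "d", "b"))
  expect_equal(top_fraction(tied, 0.4), c("a", "b"))
  expect_error(top_fraction(numeric(0)), "empty")
})

test_that("Czekanowski coincidence counts shared selections", {
  expect_equal(czekanowski(c("a", "b"), c("a", "b")), 1)
  expect_equal(czekanowski(c("a", "b"), c("c", "d")), 0)
  expect_equal(czekanowski(letters[1:5], c(letters[1:4], "z")), 0.8)
  expect_error(czekanowski(letters[1:3], letters[1:4]), "equal size")
})

test_that("Spearman correlation is tie-aware", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rank(x, x^3), 1)        # monotone transform
  expect_equal(spearman_rank(x, rev(x)), -1)
  ## ties: mid-rank brute force
  xt <- c(1, 2, 2, 3); yt <- c(2, 1, 3, 3)
  brute <- stats::cor(rank(xt), rank(yt))
  expect_equal(spearman_rank(xt, yt), brute, tolerance = 1e-12)
  expect_error(spearman_rank(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("strategy comparison bundles CC and rank agreement", {
  set.seed(5)
  sc <- stats::setNames(rnorm(50), paste0("c", 1:50))
  cmp <- compare_strategies(sc, sc, f = 0.2)
  expect_equal(cmp$cc, 1)
  expect_equal(cmp$spearman, 1)
  ## CC is invariant to monotone transforms of either score vector
  cmp2 <- compare_strategies(sc, exp(sc), f = 0.2)
  expect_equal(cmp2$cc, 1)
  expect_error(compare_strategies(sc, sc[-1]), "same entries")
})

test_that("random independent rankings overlap near the selected fraction", {
  set.seed(6)
  cc <- replicate(200, {
    a <- stats::setNames(rnorm(500), paste0("g", 1:500))
    b <- stats::setNames(rnorm(500), paste0("g", 1:500))
    czekanowski(top_fraction(a, 0.2), top_fraction(b, 0.2))
  })
  expect_lt(abs(mean(cc) - 0.2), 0.02)
})

test_that("FAI-BLUP index matches an independent factor-analysis chain", {
  ## distances in Bartlett score space are invariant to the varimax
  ## rotation, so an unrotated re-derivation is a genuine oracle
  set.seed(7)
  n <- 12; m <- 4
  B <- matrix(rnorm(n * m), n, m,
              dimnames = list(paste0("g", 1:n), paste0("v", 1:m)))
  B[, 2] <- B[, 1] * 0.6 + rnorm(n, sd = 0.5)
  res <- fai_blup(B, n_factors = 2)
  Z <- scale(B)
  R <- stats::cor(B)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  psi <- pmax(1 - rowSums(L^2), 1e-6)
  Aop <- solve(t(L) %*% (L / psi), t(L / psi))
  S <- Z %*% t(Aop)
  ideal <- apply(Z, 2, max)
  Si <- drop(Aop %*% ideal)
  d <- sqrt(colSums((t(S) - Si)^2))
  d <- pmax(d, 1e-12)
  P <- (1 / d) / sum(1 / d)
  expect_equal(unname(res$index), unname(P), tolerance = 1e-8)
  expect_equal(order(-res$index), order(-P))
})

test_that("FAI-BLUP invariants: communalities, normalisation, symmetry", {
  set.seed(8)
  B <- matrix(rnorm(60), 15, 4)
  r <- fai_blup(B, n_factors = 2)
  ## varimax preserves communalities
  expect_equal(rowSums(r$loadings^2), rowSums(r$loadings_unrotated^2),
               tolerance = 1e-10)
  expect_true(all(r$communalities >= 0 & r$communalities <= 1 + 1e-8))
  ## index columns are probability vectors over genotypes
  expect_equal(unname(colSums(r$P)), rep(1, ncol(r$P)))
  ## a genotype at the ideotype dominates the index
  Z <- scale(B)
  B2 <- rbind(B, best = apply(B, 2, max))
  r2 <- fai_blup(B2, n_factors = 2)
  expect_equal(names(which.max(r2$index)), "best")
  ## constant variables are rejected
  expect_error(fai_blup(cbind(B, 1)), "constant")
})

test_that("two genotypes symmetric about the ideotype score equally", {
  ## exchangeable variables: swapping the two columns permutes rows
  ## (1,2), (3,4), (5,6), so genotypes 1 and 2 are mirror images
  B <- rbind(c(1, 0), c(0, 1), c(2, 3), c(3, 2), c(-1, -2), c(-2, -1))
  colnames(B) <- c("x", "y")
  r <- fai_blup(B, n_factors = 2)
  expect_equal(unname(r$index[1]), unname(r$index[2]), tolerance = 1e-8)
  expect_equal(unname(r$index[3]), unname(r$index[4]), tolerance = 1e-8)
})
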