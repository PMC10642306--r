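#' Top-fraction selection
#'
#' The ceiling(f * n) highest-scored entries; ties at the cutoff are broken
#' by entry label so selection is deterministic.
#'
#' @param scores named numeric vector (higher is better).
#' @param f selection fraction in (0, 1].
#' @return character vector of selected entry labels.
#' @export
top_fraction <- function(scores, f = 0.20) {
  fc_assert(length(scores) > 0, "empty score vector")
  fc_assert(f > 0 && f <= 1, "f must lie in (0, 1]")
  nm <- names(scores) %||% as.character(seq_along(scores))
  k <- ceiling(f * length(scores))
  ord <- order(-scores, nm)
  nm[ord[seq_len(k)]]
}

#' Czekanowski coincidence of two selected sets
#'
#' CC = a / (a + b), with a the number of entries common to both equal-size
#' selections and b the number selected by one strategy but not the other.
#'
#' @param set_a,set_b character vectors of equal length (the two selected
#'   sets).
#' @return proportion in `[0, 1]`.
#' @examples
#' czekanowski(c("x", "y", "z"), c("x", "z", "w"))
#' @export
czekanowski <- function(set_a, set_b) {
  fc_assert(length(set_a) > 0, "empty selection")
  fc_assert(length(set_a) == length(set_b),
            "the two selections must have equal size")
  a <- length(intersect(set_a, set_b))
  a / length(set_a)
}

#' Spearman rank correlation
#'
#' Tie-aware rank correlation: the Pearson correlation of mid-ranks.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rank <- function(x, y) {
  fc_assert(length(x) == length(y), "length mismatch")
  fc_assert(length(x) >= 3, "need at least 3 observations")
  fc_assert(stats::sd(x) > 0 && stats::sd(y) > 0,
            "rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Compare two selection strategies
#'
#' Bundles the top-fraction coincidence (Czekanowski) and the overall rank
#' agreement (Spearman) between two score vectors over the same entries —
#' e.g. clone-only BLUPs versus total genotypic values.
#'
#' @param scores_a,scores_b named score vectors over the same entry set.
#' @param f selection fraction for the coincidence measure.
#' @param labels strategy labels for printing.
#' @return object of class `fc_strategy`: selected sets, `cc`, `spearman`.
#' @export
compare_strategies <- function(scores_a, scores_b, f = 0.20,
                               labels = c("A", "B")) {
  fc_assert(!is.null(names(scores_a)) && !is.null(names(scores_b)),
            "score vectors must be named by entry")
  fc_assert(setequal(names(scores_a), names(scores_b)),
            "the two strategies must score the same entries")
  scores_b <- scores_b[names(scores_a)]
  sel_a <- top_fraction(scores_a, f)
  sel_b <- top_fraction(scores_b, f)
  structure(list(labels = labels, f = f, selected_a = sel_a,
                 selected_b = sel_b,
                 cc = czekanowski(sel_a, sel_b),
                 spearman = spearman_rank(scores_a, scores_b)),
            class = "fc_strategy")
}

#' @export
print.fc_strategy <- function(x, ...) {
  cat(sprintf("%s vs %s (top %.0f%%): CC = %.2f, Spearman r_S = %.2f\n",
              x$labels[1], x$labels[2], 100 * x$f, x$cc, x$spearman))
  invisible(x)
}

#' FAI-BLUP: factor-analytic ideotype-distance selection index
#'
#' Ranks genotypes on several variables (typically BLUPs per trait and
#' season) through exploratory factor analysis: variables are standardised;
#' loadings are extracted by principal components of the correlation
#' matrix; the retained factors (eigenvalue >= `min_eigenvalue`, or a fixed
#' `n_factors`) are varimax-rotated; factor scores are computed by weighted
#' least squares (Bartlett). Ideotypes are placed in variable space — the
#' all-desirable ideotype takes every variable at its desirable pole
#' (observed maximum for higher-is-better variables, minimum otherwise) and
#' the full set of 2^k pole combinations over factors is also available —
#' and projected into score space with the same operator. The index of
#' genotype i against ideotype j is the normalised inverse distance
#' P_ij = (1/d_ij) / sum_i (1/d_ij), and genotypes are ranked by their
#' index against the all-desirable ideotype.
#'
#' @param blups genotypes x variables numeric matrix (>= 3 genotypes,
#'   >= 2 non-constant variables).
#' @param n_factors number of factors to retain; default: eigenvalues of
#'   the correlation matrix >= `min_eigenvalue`.
#' @param higher_is_better logical, recycled over variables.
#' @param min_eigenvalue retention threshold for the default rule.
#' @return object of class `fai_blup`: loadings (unrotated and rotated),
#'   communalities, factor scores, ideotype scores, index matrix `P`
#'   (genotypes x ideotypes; each column sums to 1), the index against the
#'   all-desirable ideotype (`$index`) and the implied `$ranking`.
#' @export
fai_blup <- function(blups, n_factors = NULL, higher_is_better = TRUE,
                     min_eigenvalue = 1) {
  blups <- as.matrix(blups)
  n <- nrow(blups); m <- ncol(blups)
  fc_assert(n >= 3, "need at least 3 genotypes")
  fc_assert(m >= 2, "need at least 2 variables")
  if (is.null(rownames(blups))) rownames(blups) <- paste0("G", seq_len(n))
  if (is.null(colnames(blups))) colnames(blups) <- paste0("V", seq_len(m))
  hib <- rep_len(higher_is_better, m)
  sds <- apply(blups, 2, stats::sd)
  fc_assert(all(sds > 0), "constant variable(s): ",
            paste(colnames(blups)[sds == 0], collapse = ", "))
  Z <- scale(blups)
  R <- stats::cor(blups)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10)
    fc_stop("singular correlation matrix; prune redundant variables")
  k <- n_factors %||% max(1L, sum(ev$values >= min_eigenvalue))
  fc_assert(k >= 1 && k <= m, "n_factors out of range")
  L0 <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k)]), k)
  rownames(L0) <- colnames(blups)
  L <- if (k > 1) {
    rot <- stats::varimax(L0, normalize = FALSE)
    unclass(rot$loadings)
  } else L0
  h2 <- rowSums(L^2)
  psi <- pmax(1 - h2, 1e-6)
  ## Bartlett weighted-least-squares scoring operator
  A <- solve(crossprod(L, L / psi), t(L / psi))   # k x m
  scores <- Z %*% t(A)
  colnames(scores) <- paste0("FA", seq_len(k))
  ## variable-space ideotype poles
  pole_hi <- ifelse(hib, apply(Z, 2, max), apply(Z, 2, min))
  pole_lo <- ifelse(hib, apply(Z, 2, min), apply(Z, 2, max))
  fac_of_var <- apply(abs(L), 1, which.max)
  combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))[,
                                                                 k:1,
                                                                 drop = FALSE]
  ## order so the first ideotype is the all-desirable one
  combos <- combos[order(-rowSums(combos)), , drop = FALSE]
  ideo_vars <- t(apply(combos, 1, function(d) {
    ifelse(d[fac_of_var], pole_hi, pole_lo)
  }))
  rownames(ideo_vars) <- apply(combos, 1, function(d)
    paste0(ifelse(d, "D", "U"), collapse = ""))
  ideo_scores <- ideo_vars %*% t(A)
  d <- sqrt(outer(rowSums(scores^2), rowSums(ideo_scores^2), "+") -
              2 * scores %*% t(ideo_scores))
  d[!is.finite(d) | d < 1e-12] <- 1e-12
  P <- sweep(1 / d, 2, colSums(1 / d), "/")
  dimnames(P) <- list(rownames(blups), rownames(ideo_vars))
  index <- P[, 1]
  structure(list(loadings_unrotated = L0, loadings = L, n_factors = k,
                 communalities = h2, mean_communality = mean(h2),
                 scores = scores, ideotypes = ideo_vars,
                 ideotype_scores = ideo_scores, P = P, index = index,
                 ranking = names(sort(index, decreasing = TRUE)),
                 higher_is_better = hib),
            class = "fai_blup")
}

#' @export
print.fai_blup <- function(x, ...) {
  cat(sprintf("FAI-BLUP index: %d variables, %d factors, mean communality %.2f\n",
              nrow(x$loadings), x$n_factors, x$mean_communality))
  cat("top of the ranking:", paste(utils::head(x$ranking, 5), collapse = ", "),
      "\n")
  invisible(x)
}
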