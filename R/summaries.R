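#' Total genotypic value of clones
#'
#' Composes the total genotypic effect of each clone as the BLUP of its
#' family plus its clone-within-family BLUP — per trial for MET fits, so
#' the composition capitalises on genotype-by-environment interaction.
#'
#' @param x a `famclone` fit with a family term, or a vector/matrix of
#'   family BLUPs (see `u_s` below).
#' @param ... passed on.
#' @return named vector (single trial) or clones x trials matrix.
#' @export
total_genotypic <- function(x, ...) UseMethod("total_genotypic")

#' @rdname total_genotypic
#' @param u_c clone-within-family BLUPs: named vector, or levels x trials
#'   matrix for MET.
#' @param family_of_clone named character vector mapping clone to family.
#' @export
total_genotypic.default <- function(x, u_c, family_of_clone, ...) {
  u_s <- x
  if (is.matrix(u_c)) {
    fams <- family_of_clone[rownames(u_c)]
    fc_assert(all(!is.na(fams)) && all(fams %in% rownames(u_s)),
              "data error: clone without a family BLUP")
    fc_assert(identical(colnames(u_s), colnames(u_c)),
              "data error: trial mismatch between family and clone BLUPs")
    out <- u_s[fams, , drop = FALSE] + u_c
    rownames(out) <- rownames(u_c)
    out
  } else {
    fams <- family_of_clone[names(u_c)]
    fc_assert(all(!is.na(fams)) && all(fams %in% names(u_s)),
              "data error: clone without a family BLUP")
    stats::setNames(u_s[fams] + u_c, names(u_c))
  }
}

#' @rdname total_genotypic
#' @export
total_genotypic.famclone <- function(x, ...) {
  fc_assert(!is.null(x$u_s), "model '", x$model, "' has no family term")
  total_genotypic.default(x$u_s, x$u_c, x$family_of_clone)
}

#' Proportion of genetic variance among families
#'
#' rho_S = sigma2_s / (sigma2_s + sigma2_c): the share of the total genetic
#' variance attributable to differences among full-sib families. Scale
#' invariant, so percent contributions can be supplied directly.
#'
#' @param sigma2_s,sigma2_c family and clone-within-family variances (or
#'   percent contributions); vectorized.
#' @return proportion(s) in `[0, 1]`.
#' @examples
#' rho_s(7.18, 34.42)
#' @export
rho_s <- function(sigma2_s, sigma2_c) {
  fc_assert(all(sigma2_s >= 0) && all(sigma2_c >= 0),
            "variances must be nonnegative")
  fc_assert(all(sigma2_s + sigma2_c > 0),
            "rho_s undefined when both variances are zero")
  sigma2_s / (sigma2_s + sigma2_c)
}

#' Percent variance contributions
#'
#' Expresses each variance component as a percentage of the total
#' variation. For MET fits the decomposition is per trial, using that
#' trial's block and residual variances and the trial's diagonal entries
#' of the genetic covariance matrices.
#'
#' @param fit a `famclone` fit (or a plain named numeric vector of
#'   components).
#' @param trial optional trial label (MET fits); default all trials.
#' @return data frame with columns `trial`, `component`, `variance`,
#'   `percent`; percentages sum to 100 within each trial.
#' @export
percent_contributions <- function(fit, trial = NULL) {
  if (is.numeric(fit)) {
    fc_assert(sum(fit) > 0, "zero total variance")
    return(data.frame(component = names(fit) %||%
                        paste0("v", seq_along(fit)),
                      variance = as.numeric(fit),
                      percent = 100 * fit / sum(fit), row.names = NULL))
  }
  stopifnot(inherits(fit, "famclone"))
  trials <- trial %||% fit$trials
  rows <- lapply(trials, function(tl) {
    j <- match(tl, fit$trials)
    comp <- c(block = unname(if (length(fit$vc$block) > 1)
      fit$vc$block[j] else fit$vc$block))
    if (!is.null(fit$vc$family))
      comp <- c(comp, family = unname(diag_or_scalar(fit$vc$family, j)))
    comp <- c(comp, clone = unname(diag_or_scalar(fit$vc$clone, j)),
              resid = unname(fit$vc$resid[j]))
    data.frame(trial = tl, percent_contributions(comp), row.names = NULL)
  })
  do.call(rbind, rows)
}

diag_or_scalar <- function(v, j) if (is.matrix(v)) diag(v)[j] else v

#' Across-environment genetic correlation matrix
#'
#' Standardises an across-trial genetic covariance matrix to correlations,
#' rho_ij = sigma_ij / sqrt(sigma_ii * sigma_jj). Pairs involving a zero
#' variance are reported as `NA` (undefined).
#'
#' @param G symmetric PSD covariance matrix (e.g. the fitted `G_ts` or
#'   `G_tc` of a MET model).
#' @return correlation matrix with unit diagonal.
#' @export
env_genetic_correlations <- function(G) {
  G <- as.matrix(G)
  fc_assert(is_psd(G), "G must be symmetric positive semidefinite")
  d <- diag(G)
  sd_ <- sqrt(d)
  R <- G / tcrossprod(sd_)
  R[d == 0, ] <- NA_real_
  R[, d == 0] <- NA_real_
  diag(R)[d > 0] <- 1
  R
}

#' Selection accuracy from prediction error variance
#'
#' r = sqrt(1 - v / sigma2), where v is the average prediction error
#' variance of an effect and sigma2 its prior variance (family, clone, or
#' family + clone for the total genotypic effect). Values of v marginally
#' above sigma2 are clipped to sigma2 with a warning.
#'
#' @param pev_mean average prediction error variance (vectorized).
#' @param prior_variance the matching variance component (> 0).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(pev_mean, prior_variance) {
  fc_assert(all(prior_variance > 0),
            "accuracy undefined for zero prior variance")
  fc_assert(all(pev_mean >= 0), "PEV must be nonnegative")
  if (any(pev_mean > prior_variance)) {
    warning("PEV above the prior variance; clipping (accuracy 0)")
    pev_mean <- pmin(pev_mean, prior_variance)
  }
  sqrt(1 - pev_mean / prior_variance)
}

#' Relative efficiency of total-genotypic over clone-only selection
#'
#' RE = r_g / r_c: the ratio of the accuracy of the total genotypic effect
#' (family + clone within family) to the accuracy of the clone-within-family
#' effect alone.
#'
#' @param acc_total,acc_clone accuracies in `(0, 1]`.
#' @return ratio (vectorized).
#' @examples
#' relative_efficiency(0.67, 0.60)
#' @export
relative_efficiency <- function(acc_total, acc_clone) {
  fc_assert(all(acc_clone > 0), "zero clone accuracy")
  acc_total / acc_clone
}

#' Per-trial accuracies and relative efficiency of a fit
#'
#' Average prediction error variances per effect are turned into
#' accuracies; for models with a family term the total genotypic accuracy
#' uses the joint PEV of the summed family + clone effect (including their
#' PEV covariance) against sigma2_s + sigma2_c.
#'
#' @param fit a `famclone` fit with PEVs.
#' @return data frame with one row per trial: `acc_family`, `acc_clone`,
#'   `acc_total`, `efficiency` (NA where the model has no family term).
#' @export
accuracy_summary <- function(fit) {
  stopifnot(inherits(fit, "famclone"))
  fc_assert(!is.null(fit$pev), "fit was computed with pev = FALSE")
  t_ <- length(fit$trials)
  col_j <- function(x, j) if (is.matrix(x)) x[, j] else x
  rows <- lapply(seq_len(t_), function(j) {
    s2c <- diag_or_scalar(fit$vc$clone, j)
    r_c <- accuracy(mean(col_j(fit$pev_c, j)), s2c)
    if (is.null(fit$vc$family)) {
      return(data.frame(trial = fit$trials[j], acc_family = NA_real_,
                        acc_clone = r_c, acc_total = NA_real_,
                        efficiency = NA_real_))
    }
    s2s <- diag_or_scalar(fit$vc$family, j)
    if (s2s <= 0) {  # family variance on the boundary: no family accuracy
      return(data.frame(trial = fit$trials[j], acc_family = NA_real_,
                        acc_clone = r_c, acc_total = NA_real_,
                        efficiency = NA_real_))
    }
    r_s <- accuracy(mean(col_j(fit$pev_s, j)), s2s)
    r_g <- accuracy(mean(col_j(fit$pev_g, j)), s2s + s2c)
    data.frame(trial = fit$trials[j], acc_family = r_s, acc_clone = r_c,
               acc_total = r_g, efficiency = relative_efficiency(r_g, r_c))
  })
  do.call(rbind, rows)
}
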