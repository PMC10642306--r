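#' Akaike information criterion from a residual log-likelihood
#'
#' AIC = -2 l + 2 p, with l the maximised residual log-likelihood and p
#' the number of free covariance parameters.
#'
#' @param loglik residual log-likelihood at the optimum.
#' @param n_params number of free covariance parameters (>= 0).
#' @return numeric AIC (vectorized).
#' @examples
#' aic_reml(-1584.44, 3)
#' @export
aic_reml <- function(loglik, n_params) {
  fc_assert(all(n_params >= 0), "n_params must be nonnegative")
  -2 * loglik + 2 * n_params
}

#' Likelihood-ratio test between nested REML fits
#'
#' The statistic is 2 (l2 - l1) for the full (l2) versus reduced (l1)
#' residual log-likelihoods, referred to a chi-square with `df` degrees of
#' freedom. At df = 1 and 5% the test rejects when the log-likelihood
#' increment exceeds 1.92 (half of 3.84). For a single variance component
#' the boundary-corrected reference (an equal mixture of chi-square 0 and
#' chi-square 1) is available via `boundary = TRUE`; the default is the
#' plain chi-square test.
#'
#' @param loglik_reduced,loglik_full residual log-likelihoods of the nested
#'   pair fitted to the same data.
#' @param df difference in free covariance parameters (> 0).
#' @param boundary use the 50:50 chi-square mixture reference (df = 1 only).
#' @param labels optional model labels for printing.
#' @return object of class `fc_lrt`: a one-row data frame with the models,
#'   log-likelihoods, statistic, df, p-value and a significance code
#'   (`**` p < 0.01, `*` p < 0.05, `ns` otherwise).
#' @examples
#' lrt_reml(-1031.07, -1030.43, df = 1)
#' @export
lrt_reml <- function(loglik_reduced, loglik_full, df = 1, boundary = FALSE,
                     labels = c("reduced", "full")) {
  fc_assert(df > 0, "df must be positive")
  stat <- 2 * (loglik_full - loglik_reduced)
  if (stat < 0) {
    warning("negative LRT statistic (non-nested or non-converged fits); ",
            "clipped to 0")
    stat <- 0
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (boundary) {
    fc_assert(df == 1, "boundary mixture reference applies to df = 1")
    p <- 0.5 * p
    if (stat == 0) p <- 1
  }
  res <- data.frame(reduced = labels[1], full = labels[2],
                    loglik_reduced = loglik_reduced,
                    loglik_full = loglik_full,
                    lrt_stat = stat, df = df, p_value = p,
                    signif = signif_code(p),
                    stringsAsFactors = FALSE)
  class(res) <- c("fc_lrt", "data.frame")
  res
}

signif_code <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))

#' Chi-square confidence interval for a variance component
#'
#' Satterthwaite interval: with effective degrees of freedom
#' nu = 2 (estimate / se)^2, the `level` interval is
#' [nu s2 / qchisq(1 - a/2, nu), nu s2 / qchisq(a/2, nu)]. An estimate at
#' the zero boundary, or nu < 1, is flagged as intercepting zero.
#'
#' @param estimate variance estimate (>= 0).
#' @param se its standard error (from the inverse information matrix); or
#'   give `df` directly.
#' @param df optional effective degrees of freedom (overrides `se`).
#' @param level confidence level.
#' @return data frame: estimate, lower, upper, df, `intercepts_zero` flag.
#' @export
varcomp_ci_chisq <- function(estimate, se = NULL, df = NULL, level = 0.95) {
  fc_assert(estimate >= 0, "variance estimate must be nonnegative")
  if (is.null(df)) {
    fc_assert(!is.null(se) && is.finite(se) && se > 0,
              "se (or df) is required; refit with an information matrix")
    df <- 2 * (estimate / se)^2
  }
  a <- 1 - level
  if (estimate == 0 || !is.finite(df) || df < 1) {
    return(data.frame(estimate = estimate, lower = 0,
                      upper = if (estimate == 0) 0 else NA_real_,
                      df = df, intercepts_zero = TRUE))
  }
  lower <- df * estimate / stats::qchisq(1 - a / 2, df)
  upper <- df * estimate / stats::qchisq(a / 2, df)
  data.frame(estimate = estimate, lower = lower, upper = upper, df = df,
             intercepts_zero = FALSE)
}

#' Normal confidence interval for a genetic correlation
#'
#' estimate +/- z_(1-a/2) se, truncated to `[-1, 1]`; `se` typically comes
#' from the delta method on the fitted covariance parameters.
#'
#' @param correlation estimated correlation, |r| <= 1.
#' @param se its standard error (> 0).
#' @param level confidence level.
#' @return data frame: estimate, lower, upper.
#' @export
corr_ci_normal <- function(correlation, se, level = 0.95) {
  fc_assert(abs(correlation) <= 1, "correlation outside [-1, 1]")
  fc_assert(is.finite(se) && se > 0, "se must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(estimate = correlation,
             lower = max(-1, correlation - z * se),
             upper = min(1, correlation + z * se))
}

#' Confidence intervals for the variance components of a fit
#'
#' Standard errors come from the numerically inverted observed information
#' on the natural (variance/covariance) scale; variance components get
#' Satterthwaite chi-square intervals ([varcomp_ci_chisq()]).
#'
#' @param fit a `famclone` (or `reml_fit`) object.
#' @param level confidence level.
#' @return data frame, one row per variance parameter.
#' @export
varcomp_intervals <- function(fit, level = 0.95) {
  V <- vcov_varcomp(fit)
  nat <- vc_natural_pack(fit$vc, fit$prep$terms)
  rows <- list()
  for (k in seq_along(nat$par)) {
    lb <- nat$labels[k]
    if (grepl("\\[([0-9]+),([0-9]+)\\]", lb)) {
      ij <- as.integer(strsplit(gsub("^.*\\[|\\]$", "", lb), ",")[[1]])
      if (ij[1] != ij[2]) next  # covariances: see correlation_intervals()
    }
    se <- sqrt(V[k, k])
    ci <- if (is.finite(se) && se > 0)
      varcomp_ci_chisq(max(nat$par[k], 0), se = se, level = level)
    else data.frame(estimate = nat$par[k], lower = NA_real_,
                    upper = NA_real_, df = NA_real_, intercepts_zero = NA)
    rows[[length(rows) + 1L]] <- data.frame(parameter = lb, ci,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Normal intervals for across-season genetic correlations
#'
#' For each trial pair of an unstructured genetic covariance matrix the
#' correlation rho_ij = s_ij / sqrt(s_ii s_jj) gets a delta-method standard
#' error from the fitted covariance parameters and a normal interval
#' truncated to `[-1, 1]`.
#'
#' @param fit a MET `famclone` fit.
#' @param term `"family"` or `"clone"`.
#' @param level confidence level.
#' @return data frame with one row per trial pair.
#' @export
correlation_intervals <- function(fit, term = c("clone", "family"),
                                  level = 0.95) {
  term <- match.arg(term)
  G <- fit$vc[[term]]
  fc_assert(is.matrix(G), "term '", term, "' has no across-trial matrix")
  V <- vcov_varcomp(fit)
  labs <- colnames(V)
  t_ <- nrow(G)
  rows <- list()
  for (i in seq_len(t_ - 1)) for (j in (i + 1):t_) {
    sij <- G[j, i]; sii <- G[i, i]; sjj <- G[j, j]
    if (sii <= 0 || sjj <= 0) next
    r <- sij / sqrt(sii * sjj)
    k_ij <- match(sprintf("%s[%d,%d]", term, j, i), labs)
    k_ii <- match(sprintf("%s[%d,%d]", term, i, i), labs)
    k_jj <- match(sprintf("%s[%d,%d]", term, j, j), labs)
    g <- c(1 / sqrt(sii * sjj), -r / (2 * sii), -r / (2 * sjj))
    idx <- c(k_ij, k_ii, k_jj)
    se <- sqrt(drop(t(g) %*% V[idx, idx] %*% g))
    ci <- if (is.finite(se) && se > 0) corr_ci_normal(max(-1, min(1, r)),
                                                     se, level)
    else data.frame(estimate = r, lower = NA_real_, upper = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, pair = paste(fit$trials[i], fit$trials[j], sep = ":"),
      ci, se = se, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
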