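## S3 methods for famclone fits

#' @export
print.famclone <- function(x, ...) {
  cat(sprintf("%s fit for trait '%s' (%s)\n", x$model, x$trait,
              paste(x$trials, collapse = ", ")))
  cat(sprintf("logLik = %.4f  covariance parameters = %d  AIC = %.4f\n",
              x$loglik, x$n_params, aic_reml(x$loglik, x$n_params)))
  if (!x$converged) cat("** optimiser did not converge **\n")
  if (length(x$boundary))
    cat("variance at the zero boundary:",
        paste(x$boundary, collapse = ", "), "\n")
  cat("\nVariance components:\n")
  for (nm in names(x$vc)) {
    v <- x$vc[[nm]]
    if (is.matrix(v)) {
      cat(" ", nm, "(unstructured):\n")
      print(signif(v, 4))
    } else {
      cat(sprintf("  %-7s %s\n", nm, paste(signif(v, 4), collapse = "  ")))
    }
  }
  invisible(x)
}

#' Summarise a clonal-selection fit
#'
#' @param object a `famclone` fit.
#' @param ... unused.
#' @return list of class `summary.famclone`: fit statistics, percent
#'   variance contributions per trial with rho_S, per-trial accuracies and
#'   relative efficiency, and (MET) across-season genetic correlation
#'   matrices.
#' @export
summary.famclone <- function(object, ...) {
  pc <- percent_contributions(object)
  rs <- NULL
  if (!is.null(object$vc$family)) {
    rs <- vapply(object$trials, function(tl) {
      p <- pc[pc$trial == tl, ]
      rho_s(p$percent[p$component == "family"],
            p$percent[p$component == "clone"])
    }, numeric(1))
  }
  acc <- if (!is.null(object$pev)) accuracy_summary(object)
  cors <- list()
  if (length(object$trials) > 1L) {
    for (nm in c("family", "clone")) {
      if (is.matrix(object$vc[[nm]]))
        cors[[nm]] <- env_genetic_correlations(object$vc[[nm]])
    }
  }
  structure(list(model = object$model, trait = object$trait,
                 trials = object$trials, loglik = object$loglik,
                 n_params = object$n_params,
                 aic = aic_reml(object$loglik, object$n_params),
                 converged = object$converged,
                 contributions = pc, rho_s = rs, accuracy = acc,
                 correlations = cors),
            class = "summary.famclone")
}

#' @export
print.summary.famclone <- function(x, ...) {
  cat(sprintf("%s / %s: logLik = %.4f, p = %d, AIC = %.4f\n",
              x$model, x$trait, x$loglik, x$n_params, x$aic))
  cat("\nPercent of total variation:\n")
  tab <- x$contributions
  tab$percent <- round_half_up(tab$percent, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$rho_s)) {
    cat("\nrho_S (family share of genetic variance):\n")
    print(round_half_up(x$rho_s, 2))
  }
  if (!is.null(x$accuracy)) {
    cat("\nAccuracies and relative efficiency:\n")
    a <- x$accuracy
    a[-1] <- lapply(a[-1], round_half_up, 2)
    print(a, row.names = FALSE)
  }
  for (nm in names(x$correlations)) {
    cat("\nAcross-season genetic correlations (", nm, "):\n", sep = "")
    print(round_half_up(x$correlations[[nm]], 2))
  }
  invisible(x)
}

#' @export
coef.famclone <- function(object, ...) object$beta

#' @export
logLik.famclone <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$N - object$o, class = "logLik")
}

#' @export
fitted.famclone <- function(object, ...) {
  as.numeric(object$prep$W %*% object$mme$sol)
}

#' @export
residuals.famclone <- function(object, ...) {
  object$prep$y - fitted(object)
}

#' Predicted genetic effects of a fit
#'
#' @param object a `famclone` fit.
#' @param type `"total"` (family + clone within family; models with a
#'   family term only), `"clone"`, `"family"` or `"block"`.
#' @param ... unused.
#' @return named vector (single trial) or levels x trials matrix.
#' @export
predict.famclone <- function(object, type = c("total", "clone", "family",
                                              "block"), ...) {
  type <- match.arg(type)
  switch(type,
         total = {
           fc_assert(!is.null(object$u_g),
                     "model '", object$model, "' has no family term; ",
                     "use type = 'clone'")
           object$u_g
         },
         clone = object$u_c,
         family = {
           fc_assert(!is.null(object$u_s), "no family term in this model")
           object$u_s
         },
         block = object$u_b)
}

#' Simulate new phenotypes from a fitted model
#'
#' Draws new response vectors at the fitted variance components and fixed
#' effects, over the same design rows that were analysed (parametric
#' bootstrap draws).
#'
#' @param object a `famclone` fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated responses.
#' @export
simulate.famclone <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prep <- object$prep
  mu <- as.numeric(prep$W[, seq_len(prep$o), drop = FALSE] %*%
                     object$beta)
  resid_sd <- sqrt(object$vc$resid)
  rg <- prep$resid_group
  out <- matrix(NA_real_, prep$N, nsim)
  for (k in seq_len(nsim)) {
    y <- mu
    for (tm in prep$terms) {
      v <- object$vc[[tm$label]]
      qk <- ncol(tm$Z)
      u <- if (is.matrix(v)) {
        as.vector(rmvn_rows(tm$n_levels, v))  # columns are trials: trial-major
      } else if (tm$structure == "dsum") {
        stats::rnorm(qk, sd = sqrt(v[tm$group]))
      } else stats::rnorm(qk, sd = sqrt(v))
      y <- y + as.numeric(tm$Z %*% u)
    }
    y <- y + stats::rnorm(prep$N, sd = resid_sd[rg])
    out[, k] <- y
  }
  as.data.frame(out)
}

#' Diagnostic / selection plot for a fit
#'
#' For models with a family term, plots the clone-within-family BLUPs
#' against the composed total genotypic values (averaged across trials for
#' MET fits), highlighting the top selection fraction by total genotypic
#' value; otherwise plots a histogram of the clone BLUPs.
#'
#' @param x a `famclone` fit.
#' @param f selection fraction highlighted.
#' @param ... graphical parameters passed through.
#' @export
plot.famclone <- function(x, f = 0.2, ...) {
  uc <- if (is.matrix(x$u_c)) rowMeans(x$u_c) else x$u_c
  if (is.null(x$u_g)) {
    graphics::hist(uc, main = paste(x$model, x$trait),
                   xlab = "clone BLUP", ...)
    return(invisible(x))
  }
  ug <- if (is.matrix(x$u_g)) rowMeans(x$u_g) else x$u_g
  sel <- names(ug) %in% top_fraction(ug, f)
  graphics::plot(uc, ug, pch = ifelse(sel, 19, 1),
                 col = ifelse(sel, "firebrick", "grey40"),
                 xlab = "clone-within-family BLUP",
                 ylab = "total genotypic value",
                 main = paste(x$model, x$trait), ...)
  graphics::abline(0, 1, lty = 2, col = "grey70")
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Compares two fits of nested models on the same data (e.g. STMwF vs
#' STMpF) by the residual-likelihood ratio test, with the degrees of
#' freedom taken as the difference in free covariance parameters.
#'
#' @param object,... two `famclone` fits (reduced first is not required;
#'   they are ordered by parameter count).
#' @return the [lrt_reml()] comparison table.
#' @export
anova.famclone <- function(object, ...) {
  others <- list(...)
  fc_assert(length(others) >= 1 && inherits(others[[1]], "famclone"),
            "anova needs two famclone fits")
  b <- others[[1]]
  a <- object
  if (a$n_params > b$n_params) { tmp <- a; a <- b; b <- tmp }
  lrt_reml(a$loglik, b$loglik, df = b$n_params - a$n_params,
           labels = c(a$model, b$model))
}
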