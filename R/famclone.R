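#' Fit a family/clone clonal-selection mixed model
#'
#' Fits one of the four early-generation selection models by REML on a
#' long-format phenotype table. The single-trial models treat one trial;
#' `"STMpF"` includes a family effect and a clone-within-family effect
#' (both with a single variance each), `"STMwF"` drops the family term so
#' its clone effect (and variance) absorbs the family component. The
#' multi-environment models (`"METMpF"`, `"METMwF"`) analyse two or more
#' trials jointly in one stage: block and residual variances are
#' heterogeneous across trials (direct-sum structure) and each genetic term
#' carries an unstructured t x t across-trial covariance (`G_ts` for
#' family, `G_tc` for clone within family), i.e. G_t Kronecker I with
#' trial-major column ordering.
#'
#' Fixed effects are the intercept (the clone population mean) plus one
#' coefficient per check cultivar; MET models add environment and
#' check-by-environment effects with first-level reference coding. Check
#' plots carry no family or clone random effect.
#'
#' @param data long-format phenotype data frame with columns `trial`,
#'   `block`, `entry`, `family`, `is_check`, `trait`, `value` (see
#'   [read_phenotypes()]).
#' @param model one of `"STMpF"`, `"STMwF"`, `"METMpF"`, `"METMwF"`.
#' @param trait trait to analyse (required if `data` holds several).
#' @param trials optional subset/order of trials; single-trial models
#'   require exactly one trial, MET models at least two.
#' @param pev compute prediction error variances (needed for accuracies);
#'   see [reml_fit()].
#' @param init,control passed to [reml_fit()].
#' @return object of class `famclone` (also `reml_fit` internals are kept):
#'   variance components, log-likelihood, number of free covariance
#'   parameters, fixed effects, BLUPs of family / clone / block effects,
#'   PEVs, and the composed total genotypic values where the model has a
#'   family term. Use [summary.famclone()], [coef()], [logLik()], [AIC()],
#'   [predict.famclone()], [anova.famclone()].
#' @examples
#' d <- abd_design(8, c(A = 8, B = 8, C = 8), checks = 2, seed = 2)
#' sim <- simulate_phenotypes(d, default_sim_params(1, "TTY"), seed = 3)
#' fit <- famclone(sim$pheno, "STMpF", trait = "TTY")
#' fit
#' @export
famclone <- function(data, model = c("STMpF", "STMwF", "METMpF", "METMwF"),
                     trait = NULL, trials = NULL, pev = TRUE, init = NULL,
                     control = list()) {
  model <- match.arg(model)
  des <- fc_model_frame(data, trait, trials, met = grepl("^MET", model))
  terms <- fc_terms(des, model)
  fit <- reml_fit(des$y, des$X, terms, resid_group = des$resid_group,
                  init = init, pev = pev, control = control)
  out <- fc_package_fit(fit, des, model)
  out$call <- match.call()
  out
}

## ---- model frame: factors, design matrices, orderings ----
fc_model_frame <- function(data, trait, trials, met) {
  req <- c("trial", "block", "entry", "family", "is_check", "trait", "value")
  miss <- setdiff(req, names(data))
  fc_assert(length(miss) == 0, "missing columns: ", paste(miss, collapse = ", "))
  if (is.null(trait)) {
    tr <- unique(data$trait)
    fc_assert(length(tr) == 1L, "several traits present; pick one with trait=")
    trait <- tr
  }
  d <- data[data$trait == trait, , drop = FALSE]
  fc_assert(nrow(d) > 0, "no rows for trait '", trait, "'")
  if (!is.null(trials)) d <- d[d$trial %in% trials, , drop = FALSE]
  dropped <- sum(is.na(d$value))
  if (dropped > 0) {
    message(dropped, " rows with missing values dropped")
    d <- d[!is.na(d$value), , drop = FALSE]
  }
  trial_levels <- trials %||% unique(as.character(d$trial))
  t_ <- length(trial_levels)
  if (met) fc_assert(t_ >= 2, "MET models require at least two trials")
  else fc_assert(t_ == 1, "single-trial models require exactly one trial")

  is_check <- as.logical(d$is_check)
  clone_rows <- !is_check
  fam_of_row <- as.character(d$family)
  fc_assert(all(!is.na(fam_of_row[clone_rows])),
            "data error: clone rows must carry a family")
  ## clone -> family map; a clone in two families is a data error
  map <- unique(data.frame(entry = as.character(d$entry[clone_rows]),
                           family = fam_of_row[clone_rows],
                           stringsAsFactors = FALSE))
  dupc <- map$entry[duplicated(map$entry)]
  fc_assert(length(dupc) == 0,
            "data error: clone(s) in more than one family: ",
            paste(unique(dupc), collapse = ", "))
  families <- sort(unique(map$family))
  map <- map[order(map$family, map$entry), , drop = FALSE]
  clones <- map$entry
  checks <- sort(unique(as.character(d$entry[is_check])))

  trial_f <- factor(as.character(d$trial), levels = trial_levels)
  ## block levels: grouped by trial (trial-major, sorted within trial)
  blk_lev <- unlist(lapply(trial_levels, function(tl) {
    b <- unique(as.character(d$block[trial_f == tl]))
    paste(tl, sort(b), sep = ":")
  }))
  block_f <- factor(paste(trial_f, as.character(d$block), sep = ":"),
                    levels = blk_lev)

  N <- nrow(d)
  ## fixed effects: intercept + one column per check (+ env terms for MET)
  X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  for (ck in checks)
    X <- cbind(X, as.numeric(d$entry == ck & is_check))
  colnames(X) <- c("(Intercept)", if (length(checks)) paste0("check", checks))
  if (met) {
    for (j in 2:t_)
      X <- cbind(X, as.numeric(trial_f == trial_levels[j]))
    colnames(X)[(ncol(X) - t_ + 2):ncol(X)] <-
      paste0("env", trial_levels[2:t_])
    for (ck in checks) for (j in 2:t_) {
      X <- cbind(X, as.numeric(d$entry == ck & is_check &
                                 trial_f == trial_levels[j]))
      colnames(X)[ncol(X)] <- paste0("check", ck, ":env", trial_levels[j])
    }
  }

  ind <- function(f) {   # sparse one-hot of a factor, NA rows all-zero
    keep <- !is.na(f)
    Matrix::sparseMatrix(i = which(keep), j = as.integer(f[keep]), x = 1,
                         dims = c(N, nlevels(f)),
                         dimnames = list(NULL, levels(f)))
  }
  fam_f <- factor(ifelse(clone_rows, fam_of_row, NA), levels = families)
  clone_f <- factor(ifelse(clone_rows, as.character(d$entry), NA),
                    levels = clones)
  Zs1 <- ind(fam_f); Zc1 <- ind(clone_f); Zb <- ind(block_f)
  if (met) {
    ## trial-major expansion: columns (trial1: all levels, trial2: ...)
    expand <- function(Z1, lev) {
      cols <- lapply(seq_len(t_), function(j) {
        Zj <- Z1
        Zj[trial_f != trial_levels[j], ] <- 0
        Zj
      })
      Z <- do.call(cbind, cols)
      colnames(Z) <- as.vector(outer(lev, trial_levels,
                                     function(l, tl) paste(tl, l, sep = ":")))
      Matrix::drop0(Z)
    }
    Zs <- expand(Zs1, families)
    Zc <- expand(Zc1, clones)
  } else {
    Zs <- Zs1; Zc <- Zc1
  }
  list(y = d$value, X = X, Zs = Zs, Zc = Zc, Zb = Zb,
       resid_group = as.integer(trial_f),
       trial = trial_f, trials = trial_levels, t = t_,
       families = families, clones = clones, checks = checks,
       family_of_clone = stats::setNames(map$family, map$entry),
       block_trial = rep(seq_len(t_), times = tabulate_blocks(blk_lev,
                                                              trial_levels)),
       trait = trait, n_check_plots = sum(is_check))
}

tabulate_blocks <- function(blk_lev, trial_levels) {
  tl <- sub(":.*$", "", blk_lev)
  as.integer(table(factor(tl, levels = trial_levels)))
}

fc_terms <- function(des, model) {
  t_ <- des$t
  met <- t_ > 1L
  terms <- list()
  if (model %in% c("STMpF", "METMpF")) {
    terms <- c(terms, list(
      if (met) reml_term("family", des$Zs, "un", n_trials = t_)
      else reml_term("family", des$Zs, "idv")))
  }
  terms <- c(terms, list(
    if (met) reml_term("clone", des$Zc, "un", n_trials = t_)
    else reml_term("clone", des$Zc, "idv")))
  terms <- c(terms, list(
    if (met) reml_term("block", des$Zb, "dsum", group = des$block_trial)
    else reml_term("block", des$Zb, "idv")))
  terms
}

## reshape a trial-major MET BLUP vector into levels x trials
fold_met <- function(u, levels_, trials) {
  m <- matrix(u, nrow = length(levels_), ncol = length(trials),
              dimnames = list(levels_, trials))
  m
}

fc_package_fit <- function(fit, des, model) {
  met <- des$t > 1L
  has_family <- model %in% c("STMpF", "METMpF")
  vc <- fit$vc
  out <- fit
  class(out) <- c("famclone", "reml_fit")
  out$model <- model
  out$trait <- des$trait
  out$trials <- des$trials
  out$family_of_clone <- des$family_of_clone
  out$checks <- des$checks
  names(out$vc$resid) <- des$trials
  names(out$vc$block) <- if (met) des$trials else NULL
  if (met) {
    if (has_family) {
      out$u_s <- fold_met(fit$u$family, des$families, des$trials)
      out$pev_s <- if (!is.null(fit$pev))
        fold_met(fit$pev$family, des$families, des$trials)
    }
    out$u_c <- fold_met(fit$u$clone, des$clones, des$trials)
    out$pev_c <- if (!is.null(fit$pev))
      fold_met(fit$pev$clone, des$clones, des$trials)
  } else {
    if (has_family) {
      out$u_s <- fit$u$family
      out$pev_s <- fit$pev$family
    }
    out$u_c <- fit$u$clone
    out$pev_c <- fit$pev$clone
  }
  out$u_b <- fit$u$block
  if (has_family) {
    out$u_g <- total_genotypic(out)
    if (!is.null(fit$pev)) out$pev_g <- fc_pev_total(out, des)
  }
  out
}

## joint PEV of the summed family + clone effect per clone (per trial),
## including the PEV covariance between the two BLUPs
fc_pev_total <- function(out, des) {
  prep <- out$prep
  fam_idx_all <- prep$term_cols$family
  clo_idx_all <- prep$term_cols$clone
  t_ <- des$t
  s <- length(des$families)
  nc <- length(des$clones)
  fam_pos <- match(des$family_of_clone[des$clones], des$families)
  pev <- matrix(NA_real_, nc, t_, dimnames = list(des$clones, des$trials))
  for (j in seq_len(t_)) {
    fi <- fam_idx_all[(j - 1) * s + fam_pos]
    ci <- clo_idx_all[(j - 1) * nc + seq_len(nc)]
    pev[, j] <- pmax(pev_entry(out, fi, fi) + pev_entry(out, ci, ci) +
                       2 * pev_entry(out, fi, ci), 0)
  }
  if (t_ == 1L) stats::setNames(pev[, 1], des$clones) else pev
}
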