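#' Read / write long-format phenotype tables
#'
#' The on-disk schema is delimited text with header
#' `trial,block,entry,family,is_check,trait,value`. Reading validates the
#' table: required columns present, non-empty, no clone assigned to two
#' families; unknown extra columns are kept with a warning.
#'
#' @param path file path.
#' @return data frame in the package's long format.
#' @export
read_phenotypes <- function(path) {
  fc_assert(file.exists(path), "no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  fc_assert(nrow(d) > 0, "empty phenotype file: ", path)
  req <- c("trial", "block", "entry", "family", "is_check", "trait", "value")
  miss <- setdiff(req, names(d))
  fc_assert(length(miss) == 0,
            "missing required columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(d), req)
  if (length(extra))
    warning("unknown columns kept as-is: ", paste(extra, collapse = ", "))
  d$is_check <- as.logical(d$is_check)
  d$family[d$family %in% c("", "NA")] <- NA
  map <- unique(d[!d$is_check, c("entry", "family")])
  dup <- unique(map$entry[duplicated(map$entry)])
  fc_assert(length(dup) == 0,
            "data error: clone(s) assigned to more than one family: ",
            paste(dup, collapse = ", "))
  key <- paste(d$trial, d$block, d$entry, d$trait)
  fc_assert(!anyDuplicated(key),
            "data error: duplicated (trial, block, entry, trait) rows")
  d
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_pheno <- function(x) {
  ## a study input is a data frame, a file path, or a config list with
  ## either $pheno / $path or simulation instructions ($designs, $params)
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(read_phenotypes(x))
  if (is.list(x)) {
    if (!is.null(x$pheno)) return(resolve_pheno(x$pheno))
    if (!is.null(x$path)) return(read_phenotypes(x$path))
    if (!is.null(x$params)) {
      designs <- x$designs %||% fc_stop("config needs $designs")
      return(simulate_phenotypes(designs, x$params, seed = x$seed)$pheno)
    }
  }
  fc_stop("cannot interpret the phenotype input")
}

#' Run the single-trial selection study
#'
#' For every trial and trait in the data: fits the single-trial models
#' without (STMwF) and with (STMpF) the family effect, compares them by
#' AIC and the likelihood-ratio test, summarises percent variance
#' contributions and rho_S, computes accuracies and the relative
#' efficiency of total-genotypic over clone-only selection, and measures
#' the agreement (Czekanowski on the top fraction, Spearman overall)
#' between clone-only rankings and the total genotypic ranking.
#'
#' @param x phenotype data frame, a file path, or a config list (fields
#'   `pheno`/`path`, or `designs` + `params` + `seed` for simulation).
#' @param f selection fraction for the coincidence comparison.
#' @param control optimiser control passed to [famclone()].
#' @return object of class `fc_study`: named tables `fits`, `lrt`,
#'   `contributions`, `accuracy`, `strategies`, plus the fitted models in
#'   `$models`. Non-converged fits are flagged in `fits`, not fatal.
#' @export
run_st_study <- function(x, f = 0.20, control = list()) {
  pheno <- resolve_pheno(x)
  traits <- unique(pheno$trait)
  trials <- unique(as.character(pheno$trial))
  fits <- list(); lrt <- list(); contrib <- list(); acc <- list()
  strat <- list(); models <- list()
  for (tr in traits) for (tl in trials) {
    dat <- pheno[pheno$trait == tr & pheno$trial == tl, , drop = FALSE]
    m0 <- famclone(dat, "STMwF", trait = tr, control = control)
    m1 <- famclone(dat, "STMpF", trait = tr, control = control)
    models[[paste(tr, tl, sep = ":")]] <- list(STMwF = m0, STMpF = m1)
    fits[[length(fits) + 1L]] <- data.frame(
      trait = tr, trial = tl, model = c("STMwF", "STMpF"),
      loglik = c(m0$loglik, m1$loglik),
      p = c(m0$n_params, m1$n_params),
      AIC = aic_reml(c(m0$loglik, m1$loglik), c(m0$n_params, m1$n_params)),
      converged = c(m0$converged, m1$converged))
    cmp <- lrt_reml(m0$loglik, m1$loglik, df = m1$n_params - m0$n_params,
                    labels = c("STMwF", "STMpF"))
    lrt[[length(lrt) + 1L]] <- data.frame(trait = tr, trial = tl, cmp)
    pc1 <- percent_contributions(m1)
    pc1$model <- "STMpF"
    pc0 <- percent_contributions(m0)
    pc0$model <- "STMwF"
    pc <- rbind(pc0, pc1)
    pc$trait <- tr
    s1 <- summary(m1)
    pc$rho_s <- ifelse(pc$model == "STMpF", unname(s1$rho_s[tl]), NA)
    contrib[[length(contrib) + 1L]] <- pc
    a <- accuracy_summary(m1)
    a$trait <- tr
    acc[[length(acc) + 1L]] <- a
    ug <- predict(m1, "total")
    s_a <- compare_strategies(predict(m0, "clone"), ug, f = f,
                              labels = c("u_c'", "u_g"))
    s_b <- compare_strategies(predict(m1, "clone"), ug, f = f,
                              labels = c("u_c", "u_g"))
    strat[[length(strat) + 1L]] <- data.frame(
      trait = tr, trial = tl,
      strategy = c("u_c' vs u_g", "u_c vs u_g"),
      cc = c(s_a$cc, s_b$cc), spearman = c(s_a$spearman, s_b$spearman))
  }
  structure(list(scope = "ST",
                 fits = do.call(rbind, fits),
                 lrt = do.call(rbind, lrt),
                 contributions = do.call(rbind, contrib),
                 accuracy = do.call(rbind, acc),
                 strategies = do.call(rbind, strat),
                 models = models, f = f),
            class = "fc_study")
}

#' Run the multi-environment selection study
#'
#' Fits the MET models without (METMwF) and with (METMpF) the family
#' effect on all trials jointly — one-stage analysis of the plot data —
#' and reports fit statistics, per-trial variance contributions with
#' rho_S, accuracies with relative efficiency, across-season genetic
#' correlations with normal confidence intervals, chi-square intervals for
#' the variance components, and the FAI-BLUP selection comparison between
#' the clone-only and total-genotypic strategies across all trait-season
#' combinations.
#'
#' If the single-trial family LRT is non-significant (5%) in every trial
#' for a trait, the family effect is dropped for that trait (METMpF is
#' skipped with a notice).
#'
#' @inheritParams run_st_study
#' @param level confidence level for the intervals.
#' @param drop_ns_family apply the family screening rule above.
#' @return object of class `fc_study` with tables `fits`,
#'   `contributions`, `accuracy`, `correlations`, `varcomp_ci`, `fai`
#'   (strategy comparison on index scores) and `notes`.
#' @export
run_met_study <- function(x, f = 0.20, level = 0.95,
                          drop_ns_family = TRUE, control = list()) {
  pheno <- resolve_pheno(x)
  trials <- unique(as.character(pheno$trial))
  fc_assert(length(trials) >= 2, "a MET study needs at least two trials")
  traits <- unique(pheno$trait)
  notes <- character(0)
  fits <- list(); contrib <- list(); acc <- list(); cors <- list()
  vci <- list(); models <- list()
  fai_scores <- list()
  for (tr in traits) {
    keep_family <- TRUE
    if (drop_ns_family) {
      sig <- vapply(trials, function(tl) {
        dat <- pheno[pheno$trait == tr & pheno$trial == tl, , drop = FALSE]
        m0 <- famclone(dat, "STMwF", trait = tr, pev = FALSE,
                       control = control)
        m1 <- famclone(dat, "STMpF", trait = tr, pev = FALSE,
                       control = control)
        lrt_reml(m0$loglik, m1$loglik, df = 1)$p_value < 0.05
      }, logical(1))
      if (!any(sig)) {
        keep_family <- FALSE
        notes <- c(notes, paste0(
          "trait ", tr, ": family effect not significant in any trial; ",
          "dropped from the MET analysis"))
      }
    }
    m0 <- famclone(pheno, "METMwF", trait = tr, trials = trials,
                   control = control)
    models[[tr]] <- list(METMwF = m0)
    row0 <- data.frame(trait = tr, model = "METMwF", loglik = m0$loglik,
                       p = m0$n_params,
                       AIC = aic_reml(m0$loglik, m0$n_params),
                       converged = m0$converged)
    if (keep_family) {
      m1 <- famclone(pheno, "METMpF", trait = tr, trials = trials,
                     control = control)
      models[[tr]]$METMpF <- m1
      fits[[length(fits) + 1L]] <- rbind(row0, data.frame(
        trait = tr, model = "METMpF", loglik = m1$loglik, p = m1$n_params,
        AIC = aic_reml(m1$loglik, m1$n_params), converged = m1$converged))
      s1 <- summary(m1)
      pc <- s1$contributions
      pc$trait <- tr
      pc$rho_s <- unname(s1$rho_s[pc$trial])
      contrib[[length(contrib) + 1L]] <- pc
      a <- accuracy_summary(m1)
      a$trait <- tr
      acc[[length(acc) + 1L]] <- a
      for (term in c("family", "clone")) {
        ci <- correlation_intervals(m1, term, level = level)
        ci$trait <- tr
        cors[[length(cors) + 1L]] <- ci
      }
      vc <- varcomp_intervals(m1, level = level)
      vc$trait <- tr
      vci[[length(vci) + 1L]] <- vc
      ## per-season BLUPs become separate index variables
      fai_scores[[tr]] <- list(
        uc_prime = predict(m0, "clone"),
        uc = predict(m1, "clone"),
        ug = predict(m1, "total"))
    } else {
      fits[[length(fits) + 1L]] <- row0
      pc <- percent_contributions(m0)
      pc$trait <- tr; pc$rho_s <- NA_real_
      contrib[[length(contrib) + 1L]] <- pc
      a <- accuracy_summary(m0)
      a$trait <- tr
      acc[[length(acc) + 1L]] <- a
    }
  }
  ## FAI-BLUP over all traits x seasons, for traits carrying a family term
  fai_tab <- NULL; fai_objects <- NULL
  if (length(fai_scores)) {
    bind_vars <- function(which) {
      do.call(cbind, lapply(names(fai_scores), function(tr) {
        m <- fai_scores[[tr]][[which]]
        colnames(m) <- paste(tr, colnames(m), sep = ":")
        m
      }))
    }
    fai_objects <- list(uc_prime = fai_blup(bind_vars("uc_prime")),
                        uc = fai_blup(bind_vars("uc")),
                        ug = fai_blup(bind_vars("ug")))
    cmp1 <- compare_strategies(fai_objects$uc_prime$index,
                               fai_objects$ug$index, f = f,
                               labels = c("u_c'", "u_g"))
    cmp2 <- compare_strategies(fai_objects$uc$index,
                               fai_objects$ug$index, f = f,
                               labels = c("u_c", "u_g"))
    fai_tab <- data.frame(
      strategy = c("u_c' vs u_g", "u_c vs u_g"),
      cc = c(cmp1$cc, cmp2$cc),
      spearman = c(cmp1$spearman, cmp2$spearman),
      mean_communality = c(fai_objects$uc_prime$mean_communality,
                           fai_objects$uc$mean_communality))
  }
  structure(list(scope = "MET",
                 fits = do.call(rbind, fits),
                 contributions = do.call(rbind, contrib),
                 accuracy = do.call(rbind, acc),
                 correlations = if (length(cors)) do.call(rbind, cors),
                 varcomp_ci = if (length(vci)) do.call(rbind, vci),
                 fai = fai_tab, fai_objects = fai_objects,
                 models = models, notes = notes, f = f),
            class = "fc_study")
}

#' @export
print.fc_study <- function(x, ...) {
  cat(sprintf("%s study (selection fraction %.0f%%)\n\n", x$scope,
              100 * x$f))
  cat("Fit statistics:\n")
  tab <- x$fits
  tab$loglik <- round(tab$loglik, 2); tab$AIC <- round(tab$AIC, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$accuracy)) {
    cat("\nAccuracy / relative efficiency:\n")
    a <- x$accuracy
    num <- vapply(a, is.numeric, logical(1))
    a[num] <- lapply(a[num], round_half_up, 2)
    print(a, row.names = FALSE)
  }
  if (!is.null(x$fai)) {
    cat("\nFAI-BLUP strategy comparison:\n")
    fa <- x$fai
    fa[-1] <- lapply(fa[-1], round_half_up, 2)
    print(fa, row.names = FALSE)
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Write the study tables to delimited text files
#'
#' Each table of an `fc_study` is written as a tab-separated file in
#' `dir`, together with a `MANIFEST` listing the files and the package
#' version. Re-running the same study on the same data reproduces the
#' files byte for byte.
#'
#' @param study an `fc_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "fc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- Filter(is.data.frame, study[setdiff(names(study),
                                              c("models", "fai_objects"))])
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(tolower(study$scope), "_", nm, ".tsv"))
    utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "MANIFEST")
  writeLines(c(paste("famclone study report, package version",
                     as.character(utils::packageVersion("famclone"))),
               paste("scope:", study$scope),
               paste("selection fraction:", study$f),
               "files:", basename(paths)), manifest)
  invisible(c(paths, manifest))
}
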