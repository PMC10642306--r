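#' Simulation parameters for synthetic clonal trials
#'
#' Bundles, per trait, the data-generating parameters of the nested
#' family/clone mixed model: per-trial means, block and residual variances,
#' across-trial covariance matrices for the family (`G_ts`) and
#' clone-within-family (`G_tc`) effects, and fixed per-trial check means.
#'
#' @param trials character vector of trial labels (columns of the covariance
#'   matrices follow this order).
#' @param seasons season label per trial.
#' @param traits named list; each element describes one trait with fields
#'   `mean` (per-trial trait mean), `sigma2_block`, `sigma2_resid`
#'   (per-trial variances), `G_ts`, `G_tc` (t x t symmetric PSD covariance
#'   matrices; scalars are accepted for a single trial) and `check_means`
#'   (checks x trials matrix of fixed check expectations).
#' @param missing_rate probability that a plot observation is dropped
#'   (uniform missingness; default 0).
#' @param seed default seed used by [simulate_phenotypes()].
#' @return object of class `sim_params`.
#' @seealso [default_sim_params()] for the packaged heat-stress scenario.
#' @export
sim_params <- function(trials, seasons = rep("WHS", length(trials)),
                       traits, missing_rate = 0, seed = 1L) {
  t_ <- length(trials)
  fc_assert(t_ >= 1 && !anyDuplicated(trials), "trials must be unique labels")
  fc_assert(length(seasons) == t_, "one season per trial")
  fc_assert(missing_rate >= 0 && missing_rate < 1, "missing_rate in [0,1)")
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    for (f in c("mean", "sigma2_block", "sigma2_resid", "G_ts", "G_tc"))
      fc_assert(!is.null(tr[[f]]), "trait '", nm, "' lacks field '", f, "'")
    traits[[nm]]$G_ts <- as_cov_matrix(tr$G_ts, t_, trials, "G_ts")
    traits[[nm]]$G_tc <- as_cov_matrix(tr$G_tc, t_, trials, "G_tc")
    fc_assert(length(tr$mean) == t_, "trait '", nm, "': one mean per trial")
    fc_assert(all(tr$sigma2_block >= 0) && all(tr$sigma2_resid >= 0),
              "variances must be nonnegative")
    fc_assert(length(tr$sigma2_block) %in% c(1L, t_) &&
                length(tr$sigma2_resid) %in% c(1L, t_),
              "block/residual variances: one value or one per trial")
    traits[[nm]]$sigma2_block <- rep(tr$sigma2_block, length.out = t_)
    traits[[nm]]$sigma2_resid <- rep(tr$sigma2_resid, length.out = t_)
    if (!is.null(tr$check_means)) {
      cm <- tr$check_means
      if (is.null(dim(cm))) cm <- matrix(cm, ncol = t_, nrow = length(cm))
      fc_assert(ncol(cm) == t_, "check_means needs one column per trial")
      traits[[nm]]$check_means <- cm
    }
  }
  structure(list(trials = trials, seasons = seasons, traits = traits,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_params")
}

as_cov_matrix <- function(g, t_, trials, what) {
  g <- as.matrix(g)
  fc_assert(nrow(g) == t_ && ncol(g) == t_,
            what, " must be ", t_, "x", t_)
  fc_assert(is_psd(g), "parameter error: ", what,
            " must be symmetric positive semidefinite")
  dimnames(g) <- list(trials, trials)
  g
}

#' Default heat-stress simulation scenario
#'
#' The packaged study conditions: three seasons contrasting in heat stress
#' (WHS, MHS, HHS), 30 full-sib families of 15 clones each, three replicated
#' checks, and two traits. Total tuber yield (TTY, Mg/ha) has season means
#' declining with heat stress (30, 25, 17.4; a ~42% reduction under high
#' stress), a family variance shrinking with stress (5.7, 3.7, 1.8), a
#' clone-within-family variance growing with stress, and across-season
#' genetic correlations of 0.4 (complex genotype-by-environment
#' interaction). Specific gravity (SG, dimensionless, ~1.08) has stable
#' means, family/clone variance fractions of roughly 14%/30% and
#' across-season genetic correlations of 0.7 (simple interaction). Block and
#' residual variances are heterogeneous across seasons.
#'
#' @param n_trials use the first 1, 2 or 3 seasons of the scenario.
#' @param traits subset of `c("TTY", "SG")`.
#' @param seed default seed stored in the parameter object.
#' @return a [sim_params()] object.
#' @export
default_sim_params <- function(n_trials = 3, traits = c("TTY", "SG"),
                               seed = 1L) {
  fc_assert(n_trials %in% 1:3, "the scenario has at most 3 seasons")
  idx <- seq_len(n_trials)
  trials <- c("WHS", "MHS", "HHS")[idx]
  un <- function(d, r) {  # unstructured from sds and a common correlation
    s <- sqrt(d)
    (r + diag(1 - r, length(d))) * tcrossprod(s)
  }
  tty <- list(
    mean = c(30, 25, 17.4)[idx],
    sigma2_block = c(3.0, 2.5, 0.5)[idx],
    sigma2_resid = c(28, 33, 21)[idx],
    G_ts = un(c(5.7, 3.7, 1.8)[idx], 0.4),
    G_tc = un(c(20, 19, 45)[idx], 0.4),
    check_means = rbind(c(34, 28, 20), c(30, 25, 17), c(26, 22, 14))[, idx,
                                                                    drop = FALSE]
  )
  sg <- list(
    mean = c(1.082, 1.080, 1.078)[idx],
    sigma2_block = c(4.0, 1.5, 3.0)[idx] * 1e-6,
    sigma2_resid = c(33, 35, 28)[idx] * 1e-6,
    G_ts = un(c(9.5, 9.0, 8.5)[idx] * 1e-6, 0.7),
    G_tc = un(c(18, 19, 29)[idx] * 1e-6, 0.7),
    check_means = rbind(c(1.090, 1.088, 1.086),
                        c(1.082, 1.080, 1.078),
                        c(1.074, 1.073, 1.072))[, idx, drop = FALSE]
  )
  all_tr <- list(TTY = tty, SG = sg)[traits]
  sim_params(trials = trials, seasons = trials, traits = all_tr, seed = seed)
}

#' Simulate phenotypes for one or more trial designs
#'
#' Draws phenotypes under the nested family/clone linear mixed model:
#' y = trial mean (or fixed check mean) + family effect +
#' clone-within-family effect + block effect + residual. For several trials
#' the per-family and per-clone effect vectors across trials are multivariate
#' normal with covariances `G_ts` and `G_tc`, so the generated data carry
#' exactly the unstructured genotype-by-environment covariance assumed by
#' the MET models; block and residual effects are independent within trial
#' with trial-specific variances. Checks receive no genetic draw: their
#' expectation is the fixed per-trial check mean.
#'
#' @param designs a `trial_design` or list of them, one per trial in
#'   `params$trials` (same order). For multi-trial simulation all designs
#'   must share the same entry catalog.
#' @param params a [sim_params()] object.
#' @param seed integer; overrides `params$seed`. The same seed always
#'   reproduces the same table.
#' @return list with `pheno` (long-format data frame: trial, block, entry,
#'   family, is_check, trait, value) and `truth` (per-trait list of the
#'   realized `family_effects`, `clone_effects`, `total_genotypic` matrices
#'   (levels x trials), per-trial `block_effects` and per-plot `residuals`).
#' @examples
#' d <- abd_design(6, c(A = 6, B = 6), checks = 2, seed = 1)
#' sim <- simulate_phenotypes(d, default_sim_params(1, "TTY"), seed = 7)
#' head(sim$pheno)
#' @export
simulate_phenotypes <- function(designs, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(designs, "trial_design")) designs <- list(designs)
  t_ <- length(params$trials)
  fc_assert(length(designs) == t_, "one design per trial in params")
  cat0 <- designs[[1]]$entries
  if (t_ > 1L) {
    for (d in designs[-1])
      fc_assert(identical(d$entries[order(d$entries$entry), ],
                          cat0[order(cat0$entry), ]),
                "multi-trial simulation requires a shared entry catalog")
  }
  clones <- cat0$entry[cat0$type == "clone"]
  fam_of <- cat0$family[cat0$type == "clone"]
  families <- sort(unique(fam_of))
  checks <- cat0$entry[cat0$type == "check"]
  set.seed(seed %||% params$seed)

  truth <- list()
  out <- list()
  for (trait in names(params$traits)) {
    tr <- params$traits[[trait]]
    fam_eff <- rmvn_rows(length(families), tr$G_ts)
    dimnames(fam_eff) <- list(families, params$trials)
    clo_eff <- rmvn_rows(length(clones), tr$G_tc)
    dimnames(clo_eff) <- list(clones, params$trials)
    tot <- fam_eff[fam_of, , drop = FALSE] + clo_eff
    rownames(tot) <- clones
    blocks <- list()
    resid <- list()
    rows <- vector("list", t_)
    for (j in seq_len(t_)) {
      fb <- field_book(designs[[j]])
      nb <- designs[[j]]$n_blocks
      b_eff <- stats::rnorm(nb, sd = sqrt(tr$sigma2_block[j]))
      e_eff <- stats::rnorm(nrow(fb), sd = sqrt(tr$sigma2_resid[j]))
      blocks[[params$trials[j]]] <- b_eff
      resid[[params$trials[j]]] <- e_eff
      is_check <- fb$type == "check"
      mu <- rep(tr$mean[j], nrow(fb))
      if (any(is_check)) {
        cm <- tr$check_means
        if (is.null(cm)) cm <- matrix(tr$mean[j], length(checks), t_)
        cm <- cm[rep(seq_len(nrow(cm)), length.out = length(checks)), ,
                 drop = FALSE]
        rownames(cm) <- checks
        mu[is_check] <- cm[fb$entry[is_check], j]
      }
      gen <- numeric(nrow(fb))
      gen[!is_check] <- tot[fb$entry[!is_check], j]
      rows[[j]] <- data.frame(
        trial = params$trials[j],
        block = fb$block,
        entry = fb$entry,
        family = fb$family,
        is_check = is_check,
        trait = trait,
        value = mu + gen + b_eff[fb$block] + e_eff,
        stringsAsFactors = FALSE
      )
    }
    out[[trait]] <- do.call(rbind, rows)
    truth[[trait]] <- list(family_effects = fam_eff, clone_effects = clo_eff,
                           total_genotypic = tot, block_effects = blocks,
                           residuals = resid)
  }
  pheno <- do.call(rbind, out)
  rownames(pheno) <- NULL
  if (params$missing_rate > 0) {
    keep <- stats::runif(nrow(pheno)) >= params$missing_rate
    pheno <- pheno[keep, , drop = FALSE]
  }
  list(pheno = pheno, truth = truth)
}

#' Compensated daily mean temperature
#'
#' Weighted mean of four daily readings with weight two on the 9 p.m.
#' observation: (T9am + 2*T9pm + TMAX + TMIN)/5, in degrees Celsius.
#'
#' @param t9am,t9pm,tmax,tmin air temperatures (degrees C); vectorized.
#' @return numeric vector of compensated means.
#' @examples
#' tmean(18, 15, 28, 12)  # 17.6
#' @export
tmean <- function(t9am, t9pm, tmax, tmin) {
  fc_assert(all(tmin <= tmax), "input error: tmin exceeds tmax")
  (t9am + 2 * t9pm + tmax + tmin) / 5
}

#' Tuber specific gravity from hydrostatic weighing
#'
#' SG = mass in air / (mass in air - mass in water), the buoyancy-based
#' density ratio used as a proxy for tuber dry-matter content.
#'
#' @param mass_air,mass_water sample masses (kg); vectorized.
#' @return dimensionless ratio, > 1 whenever `mass_water` > 0.
#' @examples
#' specific_gravity(2.0, 0.2)
#' @export
specific_gravity <- function(mass_air, mass_water) {
  fc_assert(all(mass_water >= 0), "input error: negative mass in water")
  fc_assert(all(mass_air > mass_water),
            "input error: mass in air must exceed mass in water")
  mass_air / (mass_air - mass_water)
}
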