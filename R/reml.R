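## Residual maximum likelihood engine.
##
## The likelihood is evaluated through Henderson's mixed-model equations
## (MME).  With W = [X Z], R the (block-)diagonal residual covariance and
## G the random-effect covariance, the MME coefficient matrix is
##   C = W' R^-1 W + blockdiag(0, G^-1),
## and the residual log-likelihood is
##   l = -1/2 [ (N - o) log(2*pi) + log|R| + log|G| + log|C| + y' P y ],
## using |V| |X'V^-1 X| = |R| |G| |C| and y'Py = y'R^-1 y - b' C^-1 b with
## b = W'R^-1 y.  Per-residual-group crossproducts of W are precomputed
## once, so each likelihood evaluation costs one sparse Cholesky of C.
##
## Covariance parameters are optimised on an unconstrained scale: log
## variances for scalar components and the log-Cholesky factor for
## unstructured matrices, which keeps every iterate valid.

#' Random-term specification for the REML engine
#'
#' Describes one random term: its (sparse) incidence matrix and covariance
#' structure. Three structures are supported: `"idv"` (a single variance,
#' sigma^2 I), `"dsum"` (independent groups of levels, one variance each —
#' the direct-sum structure used for blocks and residuals across trials)
#' and `"un"` (levels carry one correlated effect per trial; the t x t
#' across-trial covariance is unstructured, G_t Kronecker I, with columns
#' of `Z` ordered trial-major).
#'
#' @param label term name.
#' @param Z incidence matrix (N x q), dense or sparse; rows with all zeros
#'   are allowed (observations not carrying the effect, e.g. check plots
#'   for genetic terms).
#' @param structure one of `"idv"`, `"dsum"`, `"un"`.
#' @param group for `"dsum"`: integer vector (length q) mapping each column
#'   to its variance group.
#' @param n_trials for `"un"`: the number of trials t; `q` must equal
#'   t * n_levels and columns must be ordered trial-major (all levels of
#'   trial 1, then trial 2, ...).
#' @return an object of class `reml_term`.
#' @seealso [reml_fit()]
#' @export
reml_term <- function(label, Z, structure = c("idv", "dsum", "un"),
                      group = NULL, n_trials = NULL) {
  structure <- match.arg(structure)
  Z <- as(as(Matrix::Matrix(Z, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  q <- ncol(Z)
  if (structure == "dsum") {
    fc_assert(!is.null(group) && length(group) == q,
              "dsum term needs one group index per column")
    group <- as.integer(group)
  }
  if (structure == "un") {
    fc_assert(!is.null(n_trials) && q %% n_trials == 0,
              "un term: ncol(Z) must be a multiple of n_trials")
  }
  structure(list(label = label, Z = Z, structure = structure,
                 group = group, n_trials = n_trials,
                 n_levels = if (structure == "un") q %/% n_trials else q),
            class = "reml_term")
}

n_par_term <- function(tm) {
  switch(tm$structure,
         idv = 1L,
         dsum = length(unique(tm$group)),
         un = (tm$n_trials * (tm$n_trials + 1L)) %/% 2L)
}

## ---- log-Cholesky packing for unstructured t x t matrices ----
## column-wise lower triangle; diagonal entries on the log scale
logchol_pack <- function(G) {
  G <- as.matrix(G)
  L <- t(chol(G + diag(1e-10 * max(mean(diag(G)), 1e-12), nrow(G))))
  idx <- which(lower.tri(L, diag = TRUE))
  th <- L[idx]
  diag_pos <- match(which(row(L) == col(L)), idx)
  th[diag_pos] <- log(pmax(th[diag_pos], 1e-10))
  th
}

logchol_unpack <- function(th, t_) {
  L <- matrix(0, t_, t_)
  idx <- which(lower.tri(L, diag = TRUE))
  L[idx] <- th
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

## ---- parameter vector <-> variance components ----
## layout: residual parameters first, then one slice per term
par_layout <- function(terms, n_resid_groups) {
  slices <- list(resid = seq_len(n_resid_groups))
  at <- n_resid_groups
  for (tm in terms) {
    k <- n_par_term(tm)
    slices[[tm$label]] <- at + seq_len(k)
    at <- at + k
  }
  attr(slices, "n_par") <- at
  slices
}

par_to_vc <- function(par, terms, layout) {
  vc <- list(resid = exp(par[layout$resid]))
  for (tm in terms) {
    th <- par[layout[[tm$label]]]
    vc[[tm$label]] <- switch(tm$structure,
      idv = exp(th),
      dsum = exp(th),
      un = logchol_unpack(th, tm$n_trials))
  }
  vc
}

vc_to_par <- function(vc, terms, layout) {
  par <- numeric(attr(layout, "n_par"))
  par[layout$resid] <- log(pmax(vc$resid, 1e-12))
  for (tm in terms) {
    v <- vc[[tm$label]]
    par[layout[[tm$label]]] <- switch(tm$structure,
      idv = log(max(v, 1e-12)),
      dsum = log(pmax(v, 1e-12)),
      un = logchol_pack(v))
  }
  par
}

## ---- one-time preparation: per-residual-group crossproducts ----
reml_prep <- function(y, X, terms, resid_group) {
  X <- as(as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  N <- length(y)
  o <- ncol(X)
  fc_assert(nrow(X) == N, "X and y sizes differ")
  qrX <- qr(as.matrix(X))
  if (qrX$rank < o)
    fc_stop("fixed-effect design is rank deficient; use full-rank coding")
  W <- X
  col_at <- o
  term_cols <- list()
  for (tm in terms) {
    fc_assert(nrow(tm$Z) == N, "term '", tm$label, "': Z rows != length(y)")
    term_cols[[tm$label]] <- col_at + seq_len(ncol(tm$Z))
    W <- cbind(W, tm$Z)
    col_at <- col_at + ncol(tm$Z)
  }
  if (is.null(resid_group)) resid_group <- rep(1L, N)
  g <- sort(unique(resid_group))
  Ct <- list(); bt <- list(); yy <- numeric(length(g)); ng <- integer(length(g))
  for (k in seq_along(g)) {
    r <- resid_group == g[k]
    Wk <- W[r, , drop = FALSE]
    Ct[[k]] <- Matrix::forceSymmetric(Matrix::crossprod(Wk), "U")
    bt[[k]] <- as.numeric(Matrix::crossprod(Wk, y[r]))
    yy[k] <- sum(y[r]^2)
    ng[k] <- sum(r)
  }
  prep <- list(y = y, N = N, o = o, q = col_at - o, terms = terms,
               term_cols = term_cols, W = W, Ct = Ct, bt = bt, yy = yy,
               ng = ng, n_resid_groups = length(g), resid_levels = g,
               resid_group = match(resid_group, g))
  prep$fast <- fast_assembly(prep)
  prep
}

## Precomputed scatter-add assembly of the MME coefficient matrix: the
## sparsity pattern of C is fixed across likelihood evaluations, so each
## contribution (per-trial crossproducts, G^-1 blocks) is mapped once onto
## positions of the x slot, and the numeric factorisation reuses the
## symbolic Cholesky analysis.
fast_assembly <- function(prep) {
  n <- prep$o + prep$q
  key <- function(A) A@i + as.numeric(n) * rep.int(0:(n - 1L), diff(A@p))
  csp <- function(A) as(Matrix::forceSymmetric(A, "U"), "CsparseMatrix")
  pieces <- lapply(prep$Ct, csp)
  patt <- Reduce(`+`, lapply(pieces, function(A) {
    A@x[] <- 1; A
  }))
  patt <- patt + Matrix::Diagonal(n)
  un_info <- list()
  for (tm in prep$terms) {
    if (tm$structure != "un") next
    t_ <- tm$n_trials
    idxmat <- matrix(seq_len(t_ * t_), t_, t_)
    K <- Matrix::kronecker(Matrix::Matrix(idxmat, sparse = TRUE),
                           Matrix::Diagonal(tm$n_levels))
    K <- as(K, "CsparseMatrix")
    cols <- prep$term_cols[[tm$label]]
    ## embed into the full dimension
    Kfull <- Matrix::sparseMatrix(
      i = cols[K@i + 1L],
      j = cols[rep.int(0:(ncol(K) - 1L), diff(K@p)) + 1L],
      x = K@x, dims = c(n, n))
    Kfull <- csp(Kfull)
    un_info[[tm$label]] <- Kfull
    kp <- Kfull
    kp@x[] <- 1
    patt <- patt + kp
  }
  patt <- csp(patt)
  kT <- key(patt)
  maps <- lapply(pieces, function(A) match(key(A), kT))
  diag_slot <- match((seq_len(n) - 1L) + as.numeric(n) * (seq_len(n) - 1L), kT)
  un_maps <- lapply(un_info, function(K) {
    list(slot = match(key(K), kT), pair = as.integer(K@x))
  })
  list(patt = patt, nx = length(patt@x), maps = maps,
       diag_slot = diag_slot, un_maps = un_maps, n = n,
       chol = new.env(parent = emptyenv()))
}

reml_loglik_vc <- function(vc, prep, keep = FALSE) {
  rv <- vc$resid
  if (any(!is.finite(rv)) || any(rv <= 0)) return(-Inf)
  fast <- prep$fast
  x <- numeric(fast$nx)
  b <- numeric(fast$n)
  yyw <- 0; logdetR <- 0
  for (k in seq_len(prep$n_resid_groups)) {
    x[fast$maps[[k]]] <- x[fast$maps[[k]]] + prep$Ct[[k]]@x / rv[k]
    b <- b + prep$bt[[k]] / rv[k]
    yyw <- yyw + prep$yy[k] / rv[k]
    logdetR <- logdetR + prep$ng[k] * log(rv[k])
  }
  logdetG <- 0
  for (tm in prep$terms) {
    v <- vc[[tm$label]]
    cols <- prep$term_cols[[tm$label]]
    if (tm$structure == "idv") {
      if (!is.finite(v) || v <= 0) return(-Inf)
      sl <- fast$diag_slot[cols]
      x[sl] <- x[sl] + 1 / v
      logdetG <- logdetG + length(cols) * log(v)
    } else if (tm$structure == "dsum") {
      if (any(!is.finite(v)) || any(v <= 0)) return(-Inf)
      sl <- fast$diag_slot[cols]
      x[sl] <- x[sl] + 1 / v[tm$group]
      logdetG <- logdetG + sum(log(v[tm$group]))
    } else {
      ld <- determinant(v, logarithm = TRUE)
      if (ld$sign <= 0) return(-Inf)
      Gi <- tryCatch(solve(v), error = function(e) NULL)
      if (is.null(Gi)) return(-Inf)
      um <- fast$un_maps[[tm$label]]
      x[um$slot] <- x[um$slot] + as.vector(Gi)[um$pair]
      logdetG <- logdetG + tm$n_levels * as.numeric(ld$modulus)
    }
  }
  M <- fast$patt
  M@x <- x
  M@factors <- list()
  env <- fast$chol
  ch <- tryCatch({
    if (is.null(env$sym)) {
      env$sym <- Matrix::Cholesky(M, LDL = FALSE)
      env$sym
    } else Matrix::update(env$sym, M)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ch)) return(-Inf)
  logdetC <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                            sqrt = FALSE)$modulus)
  if (!is.finite(logdetC)) return(-Inf)
  sol <- as.numeric(Matrix::solve(ch, b))
  yPy <- yyw - sum(b * sol)
  ll <- -0.5 * ((prep$N - prep$o) * log(2 * pi) +
                  logdetR + logdetG + logdetC + yPy)
  if (!keep) return(ll)
  list(loglik = ll, chol = ch, M = M, sol = sol, b = b)
}

#' Residual log-likelihood of a variance-component configuration
#'
#' Evaluates the REML log-likelihood (including the constant
#' -(N-o)/2 log(2 pi)) for given variance components, via the sparse
#' mixed-model-equation factorisation. Mostly useful for profiling and
#' testing; [reml_fit()] maximises it.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank).
#' @param terms list of [reml_term()] objects.
#' @param vc variance components: list with `resid` (vector of residual
#'   variances, one per residual group) and one entry per term label
#'   (scalar, vector, or t x t matrix as dictated by the term structure).
#' @param resid_group optional integer vector (length N) of residual
#'   variance groups; default a single group.
#' @return scalar log-likelihood (`-Inf` for an invalid configuration).
#' @export
reml_loglik <- function(y, X, terms, vc, resid_group = NULL) {
  if (inherits(terms, "reml_term")) terms <- list(terms)
  prep <- reml_prep(y, X, terms, resid_group)
  reml_loglik_vc(vc, prep)
}

#' Fit variance components by REML
#'
#' Maximises the residual log-likelihood over the covariance parameters of
#' an arbitrary set of random terms, then solves Henderson's mixed-model
#' equations at the optimum for fixed-effect estimates, BLUPs and
#' prediction error variances (PEV).
#'
#' Optimisation uses a quasi-Newton search (`nlminb`) on transformed
#' parameters — log variances, log-Cholesky factors for unstructured
#' matrices — so every iterate is a valid covariance configuration.
#' Variance estimates that collapse towards zero are reported as 0 with a
#' boundary flag.
#'
#' @inheritParams reml_loglik
#' @param init optional starting variance components (same shape as `vc`
#'   in [reml_loglik()]); by default half the phenotypic variance is split
#'   equally among the random terms and identity-scaled matrices start the
#'   unstructured components.
#' @param pev compute per-level PEVs and the family/clone PEV cross-block
#'   (moderately expensive; disable in large simulation loops).
#' @param control list: `rel_tol` (default 1e-8), `max_iter` (default 500).
#' @return object of class `reml_fit`: variance components (`$vc`),
#'   log-likelihood, number of free covariance parameters, fixed effects
#'   (`$beta`), per-term BLUPs (`$u`), PEVs (`$pev`), convergence and
#'   boundary flags. The MME factorisation is retained for downstream PEV
#'   queries within the session.
#' @export
reml_fit <- function(y, X, terms, resid_group = NULL, init = NULL,
                     pev = TRUE, control = list()) {
  if (inherits(terms, "reml_term")) terms <- list(terms)
  fc_assert(length(terms) >= 1, "at least one random term is required")
  prep <- reml_prep(y, X, terms, resid_group)
  fc_assert(prep$N > prep$o, "more fixed effects than observations")
  layout <- par_layout(terms, prep$n_resid_groups)
  ctrl <- utils::modifyList(list(rel_tol = 1e-8, max_iter = 500L), control)

  vy <- stats::var(y)
  if (vy <= 0) vy <- 1e-8  # degenerate: all observations equal
  if (is.null(init)) init <- default_start(terms, prep, vy)
  par0 <- vc_to_par(init, terms, layout)
  ll0 <- reml_loglik_vc(par_to_vc(par0, terms, layout), prep)

  nll <- function(par) {
    ll <- reml_loglik_vc(par_to_vc(par, terms, layout), prep)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ## keep log-variances (and log-chol diagonals) in a sane range
  lower <- rep(log(vy) - 30, attr(layout, "n_par"))
  upper <- rep(30 + abs(log(vy)), attr(layout, "n_par"))
  ## off-diagonal log-chol entries are unconstrained in sign
  for (tm in terms) if (tm$structure == "un") {
    sl <- layout[[tm$label]]
    t_ <- tm$n_trials
    L <- matrix(0, t_, t_)
    idx <- which(lower.tri(L, diag = TRUE))
    offd <- match(which(row(L) != col(L) & lower.tri(L)), idx)
    lower[sl[offd]] <- -exp((30 + abs(log(vy))) / 2)
    upper[sl[offd]] <- exp((30 + abs(log(vy))) / 2)
  }
  opt <- stats::nlminb(par0, nll, lower = lower, upper = upper,
                       control = list(rel.tol = ctrl$rel_tol,
                                      iter.max = ctrl$max_iter,
                                      eval.max = 4L * ctrl$max_iter))
  ## Newton polish with central-difference derivatives: the quasi-Newton
  ## stopping rule leaves parameters at ~1e-6 relative accuracy; a couple
  ## of Newton steps sharpen interior optima (cheap for small parameter
  ## counts, skipped by default for the large MET parameterisations)
  polish <- ctrl$polish %||% (attr(layout, "n_par") <= 8L)
  if (polish && opt$convergence == 0) {
    p <- opt$par
    fbest <- opt$objective
    ngrad <- function(p) {
      h <- 1e-6 * (1 + abs(p))
      vapply(seq_along(p), function(i) {
        e <- numeric(length(p)); e[i] <- h[i]
        (nll(p + e) - nll(p - e)) / (2 * h[i])
      }, numeric(1))
    }
    for (it in 1:2) {
      H <- tryCatch(stats::optimHess(p, nll,
                                     control = list(ndeps = rep(1e-5,
                                                                length(p)))),
                    error = function(e) NULL)
      if (is.null(H)) break
      step <- tryCatch(solve(H, ngrad(p)), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- pmin(pmax(p - step, lower), upper)
      fc_ <- nll(cand)
      if (fc_ <= fbest + 1e-10) { p <- cand; fbest <- fc_ } else break
    }
    opt$par <- p
    opt$objective <- fbest
  }
  vc <- par_to_vc(opt$par, terms, layout)
  ll <- -opt$objective
  converged <- opt$convergence == 0 && ll >= ll0 - 1e-6
  ## boundary handling: variances collapsed to ~0
  boundary <- character(0)
  thr <- vy * 1e-7
  for (tm in terms) {
    if (tm$structure %in% c("idv", "dsum")) {
      z <- vc[[tm$label]] < thr
      if (any(z)) {
        vc[[tm$label]][z] <- 0
        boundary <- c(boundary, tm$label)
      }
    }
  }
  sol <- reml_loglik_vc(replace_zero(vc, thr), prep, keep = TRUE)
  fit <- structure(list(
    vc = vc, loglik = ll, n_params = attr(layout, "n_par"),
    converged = converged, boundary = boundary,
    beta = stats::setNames(sol$sol[seq_len(prep$o)], colnames_or_idx(X, prep$o)),
    u = split_u(sol$sol, prep), N = prep$N, o = prep$o,
    prep = prep, mme = sol, layout = layout, opt = opt
  ), class = "reml_fit")
  if (pev) fit$pev <- reml_pev(fit)
  fit
}

## zero variances make the MME singular; solve at a tiny positive floor
replace_zero <- function(vc, thr) {
  for (nm in names(vc)) if (is.numeric(vc[[nm]]) && is.null(dim(vc[[nm]])))
    vc[[nm]][vc[[nm]] <= 0] <- thr
  vc
}

colnames_or_idx <- function(X, o) {
  if (o == 0L) return(character(0))
  cn <- colnames(X)
  if (is.null(cn)) paste0("b", seq_len(o)) else cn
}

split_u <- function(sol, prep) {
  u <- list()
  for (tm in prep$terms) {
    v <- sol[prep$term_cols[[tm$label]]]
    names(v) <- colnames(tm$Z)
    u[[tm$label]] <- v
  }
  u
}

default_start <- function(terms, prep, vy) {
  K <- length(terms)
  share <- 0.5 * vy / (K + 1)
  vc <- list(resid = rep(0.5 * vy, prep$n_resid_groups))
  for (tm in terms) {
    vc[[tm$label]] <- switch(tm$structure,
      idv = share,
      dsum = rep(share, length(unique(tm$group))),
      un = diag(share, tm$n_trials))
  }
  vc
}

## prediction error variances: diagonal of C^-1 over the random-effect
## columns, plus the family x clone cross-entries needed for the PEV of the
## summed (total genotypic) effect
reml_pev <- function(fit, cross = NULL) {
  prep <- fit$prep
  ch <- fit$mme$chol
  q_all <- prep$o + prep$q
  cols <- unlist(prep$term_cols, use.names = FALSE)
  E <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                            dims = c(q_all, length(cols)))
  S <- as.matrix(Matrix::solve(ch, E))
  out <- list()
  for (tm in prep$terms) {
    tc <- prep$term_cols[[tm$label]]
    j <- match(tc, cols)
    d <- S[cbind(tc, j)]
    names(d) <- colnames(tm$Z)
    out[[tm$label]] <- pmax(d, 0)
  }
  attr(out, "Cinv_cols") <- S
  attr(out, "col_index") <- cols
  out
}

## C^-1 entries for arbitrary (i, j) column pairs of random effects
pev_entry <- function(fit, i, j) {
  S <- attr(fit$pev, "Cinv_cols")
  cols <- attr(fit$pev, "col_index")
  S[cbind(i, match(j, cols))]
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit: logLik =", format(x$loglik, digits = 8),
      " (", x$n_params, "covariance parameters )\n")
  if (!x$converged) cat("** optimiser did not converge **\n")
  if (length(x$boundary))
    cat("boundary (zero) variance for:", paste(x$boundary, collapse = ", "), "\n")
  for (nm in names(x$vc)) {
    v <- x$vc[[nm]]
    if (is.matrix(v)) {
      cat(nm, ":\n"); print(signif(v, 5))
    } else cat(nm, ":", paste(signif(v, 5), collapse = " "), "\n")
  }
  invisible(x)
}

## numerical observed information for the variance components on the
## natural scale; returns the vcov matrix and the parameter labels
vcov_varcomp <- function(fit) {
  prep <- fit$prep
  terms <- prep$terms
  nat <- vc_natural_pack(fit$vc, terms)
  f <- function(p) {
    vc <- vc_natural_unpack(p, fit$vc, terms)
    ll <- reml_loglik_vc(vc, prep)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  H <- stats::optimHess(nat$par, f)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(nat$par),
                                                     length(nat$par)))
  dimnames(V) <- list(nat$labels, nat$labels)
  V
}

vc_natural_pack <- function(vc, terms) {
  par <- vc$resid
  labels <- paste0("resid", seq_along(vc$resid))
  for (tm in terms) {
    v <- vc[[tm$label]]
    if (is.matrix(v)) {
      idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
      par <- c(par, v[lower.tri(v, diag = TRUE)])
      labels <- c(labels, paste0(tm$label, "[", idx[, 1], ",", idx[, 2], "]"))
    } else {
      par <- c(par, v)
      labels <- c(labels, if (length(v) == 1L) tm$label else
        paste0(tm$label, seq_along(v)))
    }
  }
  list(par = par, labels = labels)
}

vc_natural_unpack <- function(par, template, terms) {
  vc <- template
  at <- length(template$resid)
  vc$resid <- par[seq_len(at)]
  for (tm in terms) {
    v <- template[[tm$label]]
    if (is.matrix(v)) {
      k <- nrow(v) * (nrow(v) + 1) / 2
      m <- matrix(0, nrow(v), ncol(v))
      m[lower.tri(m, diag = TRUE)] <- par[at + seq_len(k)]
      m <- m + t(m) - diag(diag(m))
      vc[[tm$label]] <- m
      at <- at + k
    } else {
      vc[[tm$label]] <- par[at + seq_along(v)]
      at <- at + length(v)
    }
  }
  vc
}
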