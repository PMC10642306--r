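#' Trial layouts for early-generation clonal testing
#'
#' Generators for the two field layouts used in first-stage clonal
#' evaluation: the augmented block design (ABD), in which every check
#' cultivar is replicated once per block while test clones are unreplicated,
#' and the partially replicated (P-REP) design, in which a fraction of the
#' entries carries a second replicate placed in a different block.
#'
#' @param n_blocks number of incomplete blocks (at least 2).
#' @param families named integer vector mapping family labels to the number
#'   of clones in each family, or a plain integer vector (labels generated).
#' @param checks character vector of check cultivar names, or an integer
#'   count of checks.
#' @param trial,season labels attached to the design; `season` is typically
#'   one of `"WHS"`, `"MHS"`, `"HHS"` (without / moderate / high heat
#'   stress).
#' @param seed optional integer seed controlling the randomisation of
#'   entries to blocks.
#'
#' @return An object of class `trial_design`: a list with the plot table
#'   (`$plots`: plot, block, entry), the entry catalog (`$entries`: entry,
#'   type, family) and the layout counts.
#'
#' @details Clones are divided as evenly as possible across blocks (any
#'   remainder goes to the first blocks) after a seeded shuffle, and each
#'   clone occurs exactly once in the trial. The replication fraction
#'   p_N = (N - N_treat)/N, with N the number of plots and N_treat the
#'   number of distinct treatments (clones + checks), is available through
#'   [p_rep_fraction()].
#'
#' @examples
#' d <- abd_design(n_blocks = 6, families = c(A = 10, B = 12), checks = 2,
#'                 seed = 1)
#' p_rep_fraction(d)
#' @seealso [prep_design()], [p_rep_fraction()], [field_book()]
#' @export
abd_design <- function(n_blocks, families, checks, trial = "T1",
                       season = "WHS", seed = NULL) {
  cat_ <- entry_catalog(families, checks)
  fc_assert(n_blocks >= 2, "an ABD needs at least 2 blocks")
  fc_assert(nrow(cat_$checks) >= 1L, "invalid design: at least one check is required")
  fc_assert(nrow(cat_$clones) >= 1L, "invalid design: at least one clone is required")
  clones <- cat_$clones$entry
  if (!is.null(seed)) {
    clones <- withr_seed(seed, sample(clones))
  }
  ## deal shuffled clones across blocks; remainder to the first blocks
  sizes <- rep(length(clones) %/% n_blocks, n_blocks)
  extra <- length(clones) %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block_of <- rep(seq_len(n_blocks), times = sizes)
  plots <- data.frame(
    block = c(block_of, rep(seq_len(n_blocks), each = nrow(cat_$checks))),
    entry = c(clones, rep(cat_$checks$entry, times = n_blocks)),
    stringsAsFactors = FALSE
  )
  plots <- plots[order(plots$block, plots$entry), , drop = FALSE]
  plots <- data.frame(plot = seq_len(nrow(plots)), plots, row.names = NULL)
  new_trial_design(trial, season, "ABD", plots, cat_, n_blocks)
}

#' @rdname abd_design
#' @param target_p_n target replication fraction p_N in (0, 0.5); the
#'   realized fraction is the closest achievable given the integer number
#'   of duplicated entries, d = round(p_N * N_treat / (1 - p_N)).
#' @details In the P-REP layout the entries to duplicate are sampled
#'   uniformly without replacement under the seed, and the two replicates
#'   of an entry are always placed in distinct blocks.
#' @export
prep_design <- function(n_blocks, families, checks, target_p_n = 0.2,
                        trial = "T1", season = "WHS", seed = NULL) {
  cat_ <- entry_catalog(families, checks)
  fc_assert(n_blocks >= 2, "a P-REP needs at least 2 blocks")
  fc_assert(target_p_n > 0 && target_p_n < 0.5,
            "invalid design: target_p_n must lie in (0, 0.5)")
  entries <- c(cat_$clones$entry, cat_$checks$entry)
  n_treat <- length(entries)
  d <- round(target_p_n * n_treat / (1 - target_p_n))
  fc_assert(d >= 1, "invalid design: target_p_n too small to replicate any entry")
  n_plots <- n_treat + d
  sizes <- rep(n_plots %/% n_blocks, n_blocks)
  extra <- n_plots %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  dup <- if (!is.null(seed)) withr_seed(seed, sample(entries, d)) else
    entries[seq_len(d)]
  ## copies of each entry: 2 for duplicated, 1 otherwise; assign greedily to
  ## the block with most remaining capacity that does not hold the entry yet
  copies <- ifelse(entries %in% dup, 2L, 1L)
  ord <- order(-copies, entries)
  remaining <- sizes
  occupants <- vector("list", n_blocks)
  rows <- vector("list", n_plots)
  k <- 0L
  for (i in ord) {
    used <- integer(0)
    for (r in seq_len(copies[i])) {
      cand <- setdiff(order(-remaining), used)
      cand <- cand[remaining[cand] > 0]
      if (!length(cand))
        fc_stop("invalid design: block capacities cannot hold the replicates")
      b <- cand[1]
      used <- c(used, b)
      remaining[b] <- remaining[b] - 1L
      k <- k + 1L
      rows[[k]] <- data.frame(block = b, entry = entries[i],
                              stringsAsFactors = FALSE)
    }
  }
  plots <- do.call(rbind, rows)
  plots <- plots[order(plots$block, plots$entry), , drop = FALSE]
  plots <- data.frame(plot = seq_len(nrow(plots)), plots, row.names = NULL)
  new_trial_design(trial, season, "PREP", plots, cat_, n_blocks)
}

## normalise the families/checks arguments into an entry catalog
entry_catalog <- function(families, checks) {
  if (length(families) == 0L || any(families < 1))
    fc_stop("invalid design: every family must contain at least one clone")
  if (is.null(names(families)))
    names(families) <- sprintf("F%02d", seq_along(families))
  if (is.numeric(checks) && length(checks) == 1L) {
    fc_assert(checks >= 0, "number of checks cannot be negative")
    checks <- if (checks > 0) sprintf("CK%d", seq_len(checks)) else character(0)
  }
  clone_rows <- do.call(rbind, lapply(names(families), function(f) {
    data.frame(entry = sprintf("%s_C%03d", f, seq_len(families[[f]])),
               type = "clone", family = f, stringsAsFactors = FALSE)
  }))
  check_rows <- if (length(checks))
    data.frame(entry = checks, type = "check", family = NA_character_,
               stringsAsFactors = FALSE)
  else data.frame(entry = character(0), type = character(0),
                  family = character(0), stringsAsFactors = FALSE)
  fc_assert(!anyDuplicated(c(clone_rows$entry, check_rows$entry)),
            "entry labels must be unique")
  list(clones = clone_rows, checks = check_rows)
}

new_trial_design <- function(trial, season, kind, plots, cat_, n_blocks) {
  entries <- rbind(cat_$clones, cat_$checks)
  structure(list(
    trial = trial, season = season, design = kind,
    plots = plots, entries = entries,
    n_blocks = n_blocks,
    n_families = length(unique(cat_$clones$family)),
    n_clones = nrow(cat_$clones),
    n_checks = nrow(cat_$checks),
    n_plots = nrow(plots)
  ), class = "trial_design")
}

## evaluate `expr` under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Replication fraction of a trial layout
#'
#' The proportion of plots occupied by the extra replicates of treatments,
#' p_N = (N - N_treat)/N, where N is the number of plots and N_treat the
#' number of distinct treatments (clones plus checks).
#'
#' @param design a `trial_design`.
#' @param percent return a percentage instead of a proportion.
#' @return numeric scalar.
#' @examples
#' d <- abd_design(4, c(A = 8, B = 8), checks = 2)
#' p_rep_fraction(d, percent = TRUE)
#' @export
p_rep_fraction <- function(design, percent = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  n_treat <- design$n_clones + design$n_checks
  p <- (design$n_plots - n_treat) / design$n_plots
  if (percent) 100 * p else p
}

#' Field book of a trial design
#'
#' @param design a `trial_design`.
#' @return data frame with one row per plot (plot order preserved):
#'   plot, block, entry, type, family.
#' @export
field_book <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  m <- match(design$plots$entry, design$entries$entry)
  data.frame(design$plots,
             type = design$entries$type[m],
             family = design$entries$family[m],
             stringsAsFactors = FALSE)
}

#' Check the structural invariants of a trial design
#'
#' Verifies that every plot references a cataloged entry, every clone maps
#' to exactly one family, and the design-specific replication rules hold:
#' in an ABD every check occurs once per block and every clone once overall;
#' in a P-REP every entry occurs once or twice, never twice in one block.
#'
#' @param design a `trial_design`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  fb <- field_book(design)
  fc_assert(!anyNA(fb$type), "plot references an entry missing from the catalog")
  fc_assert(all(!is.na(fb$family[fb$type == "clone"])),
            "clone entry without a family")
  fc_assert(all(is.na(fb$family[fb$type == "check"])),
            "check entry carrying a family")
  tab <- table(fb$entry)
  if (design$design == "ABD") {
    for (ck in design$entries$entry[design$entries$type == "check"]) {
      per_block <- table(factor(fb$block[fb$entry == ck],
                                levels = seq_len(design$n_blocks)))
      fc_assert(all(per_block == 1L),
                "ABD: check ", ck, " must appear exactly once per block")
    }
    clone_counts <- tab[design$entries$entry[design$entries$type == "clone"]]
    fc_assert(all(clone_counts == 1L), "ABD: clones must be unreplicated")
  } else {
    fc_assert(all(tab %in% c(1L, 2L)),
              "P-REP: entries must appear once or twice")
    dup_in_block <- any(duplicated(fb[c("block", "entry")]))
    fc_assert(!dup_in_block, "P-REP: an entry appears twice in the same block")
  }
  invisible(TRUE)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("%s trial '%s' (%s): %d plots, %d blocks, %d families, %d clones, %d checks\n",
              x$design, x$trial, x$season, x$n_plots, x$n_blocks,
              x$n_families, x$n_clones, x$n_checks))
  cat(sprintf("replication fraction p_N = %.2f%%\n",
              p_rep_fraction(x, percent = TRUE)))
  invisible(x)
}
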