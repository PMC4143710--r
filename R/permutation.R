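#' Pre-drawn genotype permutation plan
#'
#' One plan is shared by every window of a run so genome-wide null statistics
#' are comparable and runs reproduce bit-for-bit from the seed. Each of the L
#' permutations is a bijection of the n individuals applied jointly to the
#' rows of Z and V only; labels, covariates and the kinship matrix stay
#' fixed, which preserves the response-covariate relationship.
#'
#' @param n number of individuals.
#' @param L number of permutations (default 1000).
#' @param seed integer seed.
#' @param scope `"all"` permutes across all individuals (default; destroys
#'   the genotype-phenotype link while the kinship denominator stays fixed);
#'   `"within_family"` permutes only within families for users concerned
#'   about exchangeability.
#' @param fid family ids (cases-first order), required for
#'   `scope = "within_family"`.
#' @return A `permutation_plan`: list with `perms` (L x n integer matrix),
#'   `L`, `n`, `seed`, `scope`.
#' @export
permutation_plan <- function(n, L = 1000, seed = 1L,
                             scope = c("all", "within_family"), fid = NULL) {
  scope <- match.arg(scope)
  stopifnot(L >= 1, n >= 2)
  set.seed(seed)
  perms <- matrix(0L, L, n)
  if (scope == "all") {
    for (l in seq_len(L)) perms[l, ] <- sample.int(n)
  } else {
    if (is.null(fid) || length(fid) != n)
      stop("within_family scope requires per-individual family ids")
    groups <- split(seq_len(n), fid)
    for (l in seq_len(L)) {
      p <- integer(n)
      for (g in groups) p[g] <- g[sample.int(length(g))]
      perms[l, ] <- p
    }
  }
  structure(list(perms = perms, L = L, n = n, seed = seed, scope = scope),
            class = "permutation_plan")
}

#' Empirical p-value by genotype-only permutation
#'
#' Recomputes the T2 statistic for each permuted genotype assignment and
#' returns `p = #\{T2_perm >= T2_obs\} / L` (ties count; with
#' `pseudo_count = 1` the small-sample corrected `(r + 1)/(L + 1)` is
#' returned instead). Only the genotype rows move, so the covariance of the
#' genetic blocks is re-estimated per permutation while the covariate term
#' and its covariance are fixed at their observed values. A permuted
#' replicate whose statistic cannot be computed (fully degenerate genotype
#' block) is replaced by a freshly drawn permutation, with a warning.
#'
#' @param blocks a [collapse_window()] result (cases-first rows).
#' @param design,phi,method,A,phi_star,df_mode as in [t2_statistic()].
#' @param plan a [permutation_plan()].
#' @param pseudo_count 0 (paper formula, default) or 1.
#' @return list with `p` (empirical p-value), `t2_obs`, `t2_perm`
#'   (length-L vector), `observed` (the full `t2_result`).
#' @export
permutation_pvalue <- function(blocks, design, phi, method = "T2", A = NULL,
                               phi_star = "identity", df_mode = "rank",
                               plan, pseudo_count = 0) {
  obs <- t2_statistic(blocks, design, phi, method, A, phi_star, df_mode)
  t2p <- perm_statistics(blocks, design, phi, method, plan)
  # covariate term is invariant under genotype-only permutation
  t2p <- t2p + obs$covariate
  # ties count as >=; allow for eigenvalue round-off between paths
  r <- sum(t2p >= obs$t2 * (1 - 1e-9) - 1e-12)
  p <- if (pseudo_count > 0) (r + pseudo_count) / (plan$L + pseudo_count)
       else r / plan$L
  list(p = p, t2_obs = obs$t2, t2_perm = t2p, observed = obs)
}

# Genetic-term statistics across all permutations of a plan.
#
# Row-permuting [Z | V] and taking the first n_c rows as cases is the same
# as picking the case set pm[1:n_c]; group scatter for controls then comes
# by subtraction from the fixed totals, which roughly halves the work.
# Constant columns are permutation-invariant, so they are dropped once.
perm_statistics <- function(blocks, design, phi, method, plan) {
  split <- grepl("^CMC\\.ZXpaper", method)
  q_phi <- quad_weight(design, phi)
  Z <- drop_constant_cols(blocks$Z)
  V <- drop_constant_cols(blocks$V)
  X <- cbind(Z, V)
  p <- ncol(X)
  zcols <- seq_len(ncol(Z))
  vcols <- setdiff(seq_len(p), zcols)
  n <- design$n; nc <- design$n_c; nd <- design$n_d
  t2p <- perm_genetic_stats(X, plan$perms, nc, ncol(Z), q_phi, split, 1e-10)
  bad <- which(!is.finite(t2p))
  for (l in bad) {
    # degenerate replicate: redraw, using the R reference path
    warning("degenerate permuted replicate; redrawing permutation")
    val <- NA_real_
    while (!is.finite(val)) {
      pm <- sample.int(n)
      val <- tryCatch(
        genetic_term(X[pm, zcols, drop = FALSE], X[pm, vcols, drop = FALSE],
                     design, q_phi, split)$term,
        error = function(e) NA_real_)
    }
    t2p[l] <- val
  }
  t2p
}

# R reference implementation of the compiled loop; kept for cross-checking.
perm_statistics_r <- function(blocks, design, phi, method, plan) {
  split <- grepl("^CMC\\.ZXpaper", method)
  q_phi <- quad_weight(design, phi)
  Z <- drop_constant_cols(blocks$Z)
  V <- drop_constant_cols(blocks$V)
  X <- cbind(Z, V)
  p <- ncol(X)
  zcols <- seq_len(ncol(Z))
  vcols <- setdiff(seq_len(p), zcols)
  n <- design$n; nc <- design$n_c; nd <- design$n_d
  Ctot <- crossprod(X)
  Stot <- colSums(X)
  one_stat <- function(idx) {
    Xc <- X[idx, , drop = FALSE]
    Cc <- crossprod(Xc)
    Sc <- colSums(Xc)
    mc <- Sc / nc; md <- (Stot - Sc) / nd
    scatter <- (Cc - nc * tcrossprod(mc)) +
      ((Ctot - Cc) - nd * tcrossprod(md))
    sig <- scatter / (n - 2)
    d <- (nc * nd / n) * (mc - md)
    if (split) {
      num <- 0
      for (cols in list(zcols, vcols)) {
        if (!length(cols)) next
        num <- num + pinv_quad(sig[cols, cols, drop = FALSE], d[cols])$q
      }
    } else num <- pinv_quad(sig, d)$q
    num / q_phi
  }
  t2p <- numeric(plan$L)
  for (l in seq_len(plan$L)) {
    idx <- plan$perms[l, seq_len(nc)]
    val <- tryCatch(one_stat(idx), error = function(e) NA_real_)
    while (is.na(val)) {
      warning("degenerate permuted replicate; redrawing permutation")
      val <- tryCatch(one_stat(sample.int(n, nc)), error = function(e) NA_real_)
    }
    t2p[l] <- val
  }
  t2p
}

#' Power / type-I error over p-value cutoffs
#'
#' `power(c) = #\{true windows with p <= c\} / #true`. The type-I error rate
#' is the same quantity computed on a dataset whose genotypes were permuted
#' to destroy the genetic associations (pass that scan's p-values with all
#' windows marked true).
#'
#' @param p per-window p-values.
#' @param truth logical per-window truth labels.
#' @param cutoffs p-value cutoffs.
#' @return data frame with columns `cutoff`, `rate`, `n_true`; `rate` is
#'   `NA` when no window is labelled true.
#' @export
type1_power_scan <- function(p, truth, cutoffs = c(0.01, 0.05, 0.1)) {
  stopifnot(length(p) == length(truth))
  nt <- sum(truth)
  rate <- if (nt == 0) rep(NA_real_, length(cutoffs))
          else vapply(cutoffs, function(cc) mean(p[truth] <= cc), 0)
  data.frame(cutoff = cutoffs, rate = rate, n_true = nt)
}
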