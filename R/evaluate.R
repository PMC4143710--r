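#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower.tail = FALSE)) / 0.4549364`,
#' the median 1-df chi-square quantile of the observed p-values over the
#' null median. Calibrated p-values give lambda ~ 1; lambda > 1 flags
#' anti-conservative (inflated) tests.
#'
#' @param p p-values in (0, 1].
#' @return lambda (> 0).
#' @export
genomic_inflation <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Exact one-sided binomial tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, 1/2)` by direct pmf summation; used for
#' the sign-test comparison of two methods' per-window powers.
#'
#' @param k observed count.
#' @param n number of trials.
#' @return tail probability.
#' @export
binomial_tail <- function(k, n) {
  stopifnot(k >= 0, k <= n)
  sum(stats::dbinom(k:n, n, 0.5))
}

#' Compare two methods' per-window powers
#'
#' Windows where neither method reaches `no_power` are excluded ("no power
#' for any test"); the rest are classified better / similar / worse for
#' method A by the margin rule `|powerA - powerB| <= margin`, where the
#' default margin is 2 Monte-Carlo standard errors of the difference given
#' `R` power-estimation replicates. The headline significance is the exact
#' one-sided binomial tail `P(X >= max(n_better, n_worse))` with
#' `X ~ Binomial(n_better + n_worse, 1/2)` (set `two_sided = TRUE` to
#' double it).
#'
#' @param powerA,powerB per-window power estimates on the same windows.
#' @param R number of replicates behind each power estimate (used for the
#'   default margin); ignored when `margin` is given.
#' @param margin absolute similarity margin; overrides the 2-SE rule.
#' @param cutoff the p-value cutoff the powers refer to (documentation
#'   only; the default `no_power` is `2 * cutoff`).
#' @param no_power both-below-this threshold for exclusion.
#' @param two_sided double the tail probability.
#' @return list with `n_better`, `n_similar`, `n_worse`, `n_excluded`,
#'   `tail_prob` (`NA` when no window is decisive).
#' @export
compare_methods <- function(powerA, powerB, R = NULL, margin = NULL,
                            cutoff = 0.05, no_power = 2 * cutoff,
                            two_sided = FALSE) {
  stopifnot(length(powerA) == length(powerB))
  if (is.null(margin)) {
    if (is.null(R)) stop("give either margin or R")
    se <- sqrt((powerA * (1 - powerA) + powerB * (1 - powerB)) / R)
    margin <- 2 * se
  }
  excl <- pmax(powerA, powerB) < no_power
  d <- powerA - powerB
  better <- !excl & d > margin
  worse <- !excl & d < -margin
  similar <- !excl & !better & !worse
  nb <- sum(better); nw <- sum(worse)
  tail <- if (nb + nw == 0) NA_real_
          else binomial_tail(max(nb, nw), nb + nw) * (1 + two_sided)
  list(n_better = nb, n_similar = sum(similar), n_worse = nw,
       n_excluded = sum(excl), tail_prob = min(tail, 1))
}

#' Default scan configuration
#'
#' @param ... overrides of: `methods`, `maf_threshold` (0.05), `width`
#'   (10000), `phi_star` ("identity"), `df_mode` ("rank"), `L` (1000),
#'   `seed` (1), `perm_scope` ("all"), `pseudo_count` (0), `permute`
#'   (TRUE; FALSE skips permutation p-values for speed).
#' @return named list.
#' @export
scan_config <- function(...) {
  cfg <- list(methods = c("T2", "T2.longi"),
              maf_threshold = 0.05, width = 10000,
              phi_star = "identity", df_mode = "rank",
              L = 1000, seed = 1L, perm_scope = "all",
              pseudo_count = 0, permute = TRUE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  cfg[names(over)] <- over
  cfg
}

#' Genome scan: windowing, collapsing, T2, asymptotic and permutation p
#'
#' The driver behind the CLI. Longitudinal (`.longi`) methods use the
#' any-time response and include the covariate block; the single-time-point
#' comparators use the time-1 response and omit it. Genotype, covariate and
#' kinship rows are reordered cases-first per response definition; one
#' shared permutation plan (per response definition) is reused across
#' windows. Windows without variants, or whose blocks are entirely
#' constant, are reported with NA statistics.
#'
#' @param vt a [variant_table].
#' @param ped a [pedigree] covering the same individuals.
#' @param pheno list with `outcomes` (n x J) and `A` (n x (C*J)) in
#'   `vt$samples` row order (see [read_phenotypes_long()]).
#' @param config a [scan_config()] list.
#' @return data frame, one row per window per method: window id, chrom,
#'   start, end, method, t2, df, p_asym, p_perm, n_common, n_rare_groups.
#' @export
run_scan <- function(vt, ped, pheno, config = scan_config()) {
  if (!setequal(vt$samples, ped$id))
    stop("individual sets differ between genotypes and pedigree: ",
         paste(c(setdiff(vt$samples, ped$id),
                 setdiff(ped$id, vt$samples)), collapse = ", "))
  if (!is.null(rownames(pheno$outcomes)) &&
      !setequal(rownames(pheno$outcomes), vt$samples))
    stop("individual sets differ between genotypes and phenotypes: ",
         paste(c(setdiff(vt$samples, rownames(pheno$outcomes)),
                 setdiff(rownames(pheno$outcomes), vt$samples)),
               collapse = ", "))
  phi_full <- compute_kinship(ped)[vt$samples, vt$samples]
  windows <- make_windows(vt, config$width)
  rare <- classify_by_maf(vt, config$maf_threshold)
  bed <- windows_bed(windows)
  out <- list()
  for (longi in unique(grepl("\\.longi$", config$methods))) {
    design <- build_response(pheno$outcomes,
                             mode = if (longi) "any" else "time", time = 1L)
    ord <- design$order
    phi <- phi_full[ord, ord]
    A <- if (longi) pheno$A[ord, , drop = FALSE] else NULL
    fid <- ped$fid[match(vt$samples[ord], ped$id)]
    plan <- if (config$permute)
      permutation_plan(design$n, config$L, config$seed,
                       scope = config$perm_scope, fid = fid)
    else NULL
    for (method in config$methods[grepl("\\.longi$", config$methods) == longi]) {
      strat <- method_strategy(method)
      for (wi in seq_along(windows)) {
        w <- windows[[wi]]
        row <- data.frame(window = bed$id[wi], chrom = w$chrom,
                          start = w$start, end = w$end, method = method,
                          t2 = NA_real_, df = NA_integer_,
                          p_asym = NA_real_, p_perm = NA_real_,
                          n_common = NA_integer_, n_rare_groups = NA_integer_)
        res <- tryCatch({
          blocks <- collapse_window(vt, w, rare, strat)
          blocks$Z <- blocks$Z[ord, , drop = FALSE]
          blocks$V <- blocks$V[ord, , drop = FALSE]
          if (config$permute) {
            pr <- permutation_pvalue(blocks, design, phi, method, A,
                                     config$phi_star, config$df_mode,
                                     plan, config$pseudo_count)
            list(obs = pr$observed, p_perm = pr$p)
          } else {
            list(obs = t2_statistic(blocks, design, phi, method, A,
                                    config$phi_star, config$df_mode),
                 p_perm = NA_real_)
          }
        }, error = function(e) NULL)
        if (!is.null(res)) {
          row$t2 <- res$obs$t2; row$df <- res$obs$df
          row$p_asym <- res$obs$p_asym; row$p_perm <- res$p_perm
          row$n_common <- res$obs$n_common
          row$n_rare_groups <- res$obs$n_rare_groups
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$method, config$methods), res$start), ]
}

#' Per-method genomic inflation from a scan table
#'
#' @param scan a [run_scan()] result.
#' @param column `"p_asym"` or `"p_perm"`.
#' @return named numeric vector of lambda per method (NA p-values and
#'   p = 0 rows dropped, since lambda is defined on (0, 1]).
#' @export
scan_inflation <- function(scan, column = "p_asym") {
  vapply(split(scan[[column]], scan$method),
         function(p) genomic_inflation(p[!is.na(p) & p > 0]),
         0)
}
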