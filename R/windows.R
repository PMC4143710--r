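#' Tile chromosomes into fixed-width windows
#'
#' Windows are 0-based half-open `[k*w, (k+1)*w)` on position - 1 (i.e. BED
#' coordinates), tiling each chromosome contiguously from position 1 to the
#' last variant position; the last window of a chromosome is truncated at
#' that position. Every variant falls in exactly one window; windows holding
#' no variant are kept (they are reported as untestable downstream).
#'
#' @param vt a [variant_table].
#' @param width window width in base pairs (> 0), default 10000.
#' @return A `window_list`: list of windows, each a list with `chrom`,
#'   `start`, `end` (0-based half-open) and `variants` (integer indices into
#'   `vt`).
#' @export
make_windows <- function(vt, width = 10000) {
  stopifnot(width > 0)
  out <- list()
  for (ch in unique(vt$chrom)) {
    vi <- which(vt$chrom == ch)
    if (!length(vi)) next
    k <- (vt$pos[vi] - 1L) %/% width          # window index per variant
    kmax <- (max(vt$pos[vi]) - 1L) %/% width
    grp <- split(vi, factor(k, levels = 0:kmax))
    for (kk in 0:kmax) {
      out[[length(out) + 1L]] <- list(
        chrom = ch,
        start = kk * width,
        end = min((kk + 1) * width, max(vt$pos[vi])),
        variants = as.integer(grp[[kk + 1L]]))
    }
  }
  structure(out, class = "window_list")
}

#' @export
print.window_list <- function(x, ...) {
  nv <- vapply(x, function(w) length(w$variants), 1L)
  cat(sprintf("window_list: %d windows (%d non-empty), %d variants\n",
              length(x), sum(nv > 0), sum(nv)))
  invisible(x)
}

#' Export windows as a BED table
#'
#' @param windows a `window_list` from [make_windows()].
#' @param path optional path; when given, written as headerless BED
#'   (chrom, start, end, windowID).
#' @return data frame with columns chrom, start, end, id (invisibly when
#'   written to file).
#' @export
windows_bed <- function(windows, path = NULL) {
  df <- data.frame(
    chrom = vapply(windows, `[[`, "", "chrom"),
    start = vapply(windows, `[[`, 0, "start"),
    end = vapply(windows, `[[`, 0, "end"),
    id = paste0("win", seq_along(windows) - 1L))
  if (!is.null(path)) {
    utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
    return(invisible(df))
  }
  df
}

#' Flag rare variants by MAF
#'
#' A variant is rare iff MAF < threshold (strict: MAF exactly at the
#' threshold is common). Monomorphic variants (MAF 0) are rare.
#'
#' @param vt a [variant_table].
#' @param threshold MAF threshold, default 0.05.
#' @return logical vector, `TRUE` = rare.
#' @export
classify_by_maf <- function(vt, threshold = 0.05) {
  unname(vt$maf < threshold)
}

#' Collapse rare variants within a window (CMC)
#'
#' Within a window, maximal runs of consecutive rare variants (in position
#' order) delimited by common variants each form one collapsed group; a run
#' before the first or after the last common variant also forms its own
#' group. Each group is aggregated per individual by the row-wise sum
#' (`"sum"`, the CMC scheme used by the T2 / CMC.ZXpaper tests) or row-wise
#' maximum (`"max"`, the pedCMC-style CMC.ZXcode scheme). Common variants
#' pass through untouched as the Z block.
#'
#' @param vt a [variant_table].
#' @param window one element of a [make_windows()] result.
#' @param rare logical rare mask over all variants (see [classify_by_maf()]).
#' @param strategy `"sum"` or `"max"`.
#' @return A `collapsed_blocks`: list with `Z` (n x T common dosages), `V`
#'   (n x S collapsed scores), `groups` (list of S integer vectors of
#'   variant indices), `strategy`, `window`.
#' @export
collapse_window <- function(vt, window, rare, strategy = c("sum", "max")) {
  strategy <- match.arg(strategy)
  idx <- window$variants
  if (!length(idx)) stop("window contains no variants (untestable)")
  r <- rare[idx]
  n <- nrow(vt$dosage)
  Z <- vt$dosage[, idx[!r], drop = FALSE]
  groups <- list()
  V <- matrix(numeric(0), n, 0)
  if (any(r)) {
    run <- cumsum(!r)[r]                     # rare runs keyed by preceding common count
    groups <- lapply(split(idx[r], run), as.integer)
    names(groups) <- NULL
    agg <- if (strategy == "sum") rowSums else
      function(x) apply(x, 1, max)
    V <- vapply(groups,
                function(g) agg(vt$dosage[, g, drop = FALSE]),
                numeric(n))
    if (is.null(dim(V))) V <- matrix(V, n, length(groups))
    colnames(V) <- paste0("collapsed", seq_along(groups))
  }
  rownames(V) <- rownames(vt$dosage)
  structure(list(Z = Z, V = V, groups = groups, strategy = strategy,
                 window = window),
            class = "collapsed_blocks")
}

#' @export
print.collapsed_blocks <- function(x, ...) {
  cat(sprintf("collapsed_blocks [%s:%d-%d]: %d common + %d collapsed group(s) (%s)\n",
              x$window$chrom, x$window$start, x$window$end,
              ncol(x$Z), ncol(x$V), x$strategy))
  invisible(x)
}
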