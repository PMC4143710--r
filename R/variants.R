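#' Variant dosage table
#'
#' Container for dosage genotypes of M variants over n individuals. Dosages
#' are expected alternate-allele counts in [0, 2]; fractional values (imputed
#' "dose" data) are allowed. The per-variant minor allele frequency is the
#' mean dosage / 2, folded so MAF <= 0.5.
#'
#' @param chrom character vector of chromosome names (length M).
#' @param pos integer positions, 1-based, non-decreasing within a chromosome.
#' @param id variant ids (length M); defaults to `chrom:pos`.
#' @param dosage n x M numeric matrix, rownames = individual ids.
#' @return A `variant_table`: list with elements `chrom`, `pos`, `id`,
#'   `dosage`, `maf`, `samples`.
#' @export
variant_table <- function(chrom, pos, dosage, id = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  m <- length(pos)
  stopifnot(length(chrom) == m, is.matrix(dosage), ncol(dosage) == m)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("positions not sorted within chromosome ", ch)
  }
  af <- colMeans(dosage) / 2
  structure(list(chrom = chrom, pos = pos, id = as.character(id),
                 dosage = dosage, maf = pmin(af, 1 - af),
                 samples = rownames(dosage)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d individuals on %s\n",
              length(x$pos), nrow(x$dosage),
              paste(unique(x$chrom), collapse = ",")))
  invisible(x)
}

#' Read dosage genotypes from a VCF file
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise as
#' alternate-allele counts from `GT`. Multiallelic records are rejected.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return A [variant_table].
#' @export
read_dosage_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    ds <- g$DS
    mode(ds) <- "numeric"
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    cnt <- function(s) {
      if (s %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    }
    ds <- apply(gt, c(1, 2), cnt)
  } else stop("VCF has neither DS nor GT FORMAT fields")
  if (anyNA(ds)) stop("missing dosages are not supported")
  variant_table(chrom = as.character(GenomicRanges::seqnames(rr)),
                pos = GenomicRanges::start(rr),
                dosage = t(ds),
                id = rownames(vcf))
}

#' Write dosage genotypes as a VCF file
#'
#' Minimal VCFv4.2 writer emitting `GT` (rounded dosage, unphased) and `DS`
#' per sample; used by the simulator so fixtures are plain text.
#'
#' @param vt a [variant_table].
#' @param path output path (plain text `.vcf`).
#' @export
write_dosage_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  m <- length(vt$pos)
  rows <- character(m)
  for (j in seq_len(m)) {
    d <- vt$dosage[, j]
    cells <- paste0(gt_codes[pmin(pmax(round(d), 0), 2) + 1], ":",
                    formatC(d, format = "g", digits = 6))
    rows[j] <- paste(c(vt$chrom[j], vt$pos[j], vt$id[j], "A", "T", ".",
                       "PASS", ".", "GT:DS", cells), collapse = "\t")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read a plain dosage matrix file
#'
#' Tab-separated: columns `chrom`, `pos`, `id`, then one column per sample;
#' one row per variant. The transpose-free sibling of [write_dosage_matrix()].
#'
#' @param path input path.
#' @return A [variant_table].
#' @export
read_dosage_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "id") %in% names(tab)))
  samp <- setdiff(names(tab), c("chrom", "pos", "id"))
  d <- t(as.matrix(tab[, samp, drop = FALSE]))
  rownames(d) <- samp
  variant_table(tab$chrom, tab$pos, d, tab$id)
}

#' @rdname read_dosage_matrix
#' @param vt a [variant_table].
#' @export
write_dosage_matrix <- function(vt, path) {
  tab <- data.frame(chrom = vt$chrom, pos = vt$pos, id = vt$id,
                    t(vt$dosage), check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
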