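#' Pedigree objects
#'
#' A `pedigree` is a validated table of individuals with parent links, used to
#' derive the kinship-based individual correlation matrix. Founders have both
#' parents absent. Identifiers are unique across the whole file; parent
#' references must resolve within the same family.
#'
#' @param fid character vector of family ids.
#' @param id character vector of individual ids (unique).
#' @param father,mother character vectors of parent ids; `NA` for founders.
#' @param sex integer sex codes (1 = male, 2 = female, 0 = unknown).
#' @return An object of class `pedigree`: a data frame with columns
#'   `fid`, `id`, `father`, `mother`, `sex` plus a logical `founder` column.
#' @export
pedigree <- function(fid, id, father, mother, sex = 0L) {
  fid <- as.character(fid); id <- as.character(id)
  father <- as.character(father); mother <- as.character(mother)
  n <- length(id)
  stopifnot(length(fid) == n, length(father) == n, length(mother) == n)
  sex <- rep_len(as.integer(sex), n)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  ped <- data.frame(fid = fid, id = id, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    known <- !is.na(p)
    bad <- known & !(p %in% id)
    if (any(bad))
      stop("unknown ", col, " id(s): ", paste(unique(p[bad]), collapse = ", "))
    # parent must live in the same family
    pf <- ped$fid[match(p[known], ped$id)]
    if (any(pf != ped$fid[known]))
      stop(col, " reference crosses family boundary for individual(s): ",
           paste(ped$id[known][pf != ped$fid[known]], collapse = ", "))
  }
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  depth <- ped_depth(ped)           # errors on cyclic ancestry
  attr(ped, "depth") <- depth
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Generation depth: founders 0, child = 1 + max(parent depths).
# Detects cycles (an individual that is its own ancestor never resolves).
ped_depth <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- ifelse(is.na(fa) & is.na(mo), 0L, NA_integer_)
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      df <- if (is.na(fa[i])) -1L else depth[fa[i]]
      dm <- if (is.na(mo[i])) -1L else depth[mo[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("cyclic ancestry involving individual(s): ",
           paste(ped$id[is.na(depth)], collapse = ", "))
  }
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals in %d famil%s (%d founders)\n",
              nrow(x), length(unique(x$fid)),
              if (length(unique(x$fid)) == 1L) "y" else "ies",
              sum(x$founder)))
  invisible(x)
}

#' Read a PED/FAM pedigree file
#'
#' Whitespace-delimited file with at least six columns: family id, individual
#' id, father id, mother id, sex, phenotype. The phenotype column is ignored;
#' case/control status comes from the longitudinal outcome table. Parent ids
#' equal to `missing_code` denote founders.
#'
#' @param path path to the PED/FAM file.
#' @param missing_code code used for an absent parent (default `"0"`).
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, missing_code = "0") {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6)
    stop("PED file must have >= 6 columns (family, id, father, mother, sex, phenotype)")
  fa <- tab[[3]]; mo <- tab[[4]]
  fa[fa == missing_code] <- NA
  mo[mo == missing_code] <- NA
  pedigree(fid = tab[[1]], id = tab[[2]], father = fa, mother = mo,
           sex = suppressWarnings(as.integer(tab[[5]])))
}

#' Write a pedigree as a PED file
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @param missing_code code written for absent parents.
#' @export
write_pedigree <- function(ped, path, missing_code = "0") {
  fa <- ifelse(is.na(ped$father), missing_code, ped$father)
  mo <- ifelse(is.na(ped$mother), missing_code, ped$mother)
  out <- data.frame(ped$fid, ped$id, fa, mo, ped$sex, 0L)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Kinship-derived individual correlation matrix
#'
#' Computes the classical kinship coefficients phi_ij by the recursive
#' algorithm (founders assumed non-inbred and unrelated), processing
#' individuals parents-before-children. By default the returned matrix is the
#' additive relationship 2*phi, so that it equals the expected additive
#' genotype correlation matrix under no inbreeding: diagonal 1, parent-
#' offspring and full sibs 0.5, half sibs 0.25, and the identity for unrelated
#' samples (which makes the classical two-sample Hotelling reduction of the
#' T2 statistic exact). `scale = "kinship"` returns raw phi (diagonal 1/2).
#'
#' The matrix is block-diagonal across families and positive semi-definite.
#'
#' @param ped a [pedigree].
#' @param scale `"additive"` (2*phi, default) or `"kinship"` (phi).
#' @return n x n symmetric matrix with dimnames = individual ids.
#' @export
compute_kinship <- function(ped, scale = c("additive", "kinship")) {
  scale <- match.arg(scale)
  n <- nrow(ped)
  ord <- order(attr(ped, "depth"))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  done <- integer(0)
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    if (is.na(f) && is.na(m)) {
      phi[i, i] <- 0.5
    } else {
      # parents always precede children in depth order
      pf <- if (is.na(f)) 0 else phi[f, done]
      pm <- if (is.na(m)) 0 else phi[m, done]
      if (length(done)) {
        v <- 0.5 * (pf + pm)
        phi[i, done] <- v
        phi[done, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else phi[f, m])
    }
    done <- c(done, i)
  }
  if (scale == "additive") 2 * phi else phi
}

#' Write a kinship matrix as TSV
#'
#' Tab-separated with a header row of individual ids and an `id` first column.
#'
#' @param k kinship matrix with dimnames.
#' @param path output path.
#' @export
write_kinship <- function(k, path) {
  df <- data.frame(id = rownames(k), k, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
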