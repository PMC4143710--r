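# Shared fixtures and independent oracles.

# Three-generation demo pedigree containing parent-offspring, full-sib,
# half-sib and avuncular pairs:
#   gp1 x gp2 -> A, B (full sibs); A x s1 -> C; A x s2 -> D (C,D half sibs);
#   B is C's uncle/aunt (avuncular).
demo_pedigree <- function() {
  pedigree(
    fid = rep("F1", 8),
    id = c("gp1", "gp2", "A", "B", "s1", "s2", "C", "D"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "A", "A"),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2))
}

# Independent single-marker gene-dropping oracle: drops one biallelic marker
# (allele frequency f) through the pedigree n_drops times and returns the
# empirical genotype correlation matrix. Deliberately minimal and separate
# from both compute_kinship() and the package simulator.
drop_marker_corr <- function(ped, n_drops = 1e4, f = 0.5) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  ord <- order(attr(ped, "depth"))
  G <- matrix(0L, n_drops, n)
  for (r in seq_len(n_drops)) {
    a1 <- integer(n); a2 <- integer(n)
    for (i in ord) {
      a1[i] <- if (is.na(fa[i])) rbinom(1, 1, f)
               else if (runif(1) < 0.5) a1[fa[i]] else a2[fa[i]]
      a2[i] <- if (is.na(mo[i])) rbinom(1, 1, f)
               else if (runif(1) < 0.5) a1[mo[i]] else a2[mo[i]]
    }
    G[r, ] <- a1 + a2
  }
  dimnames(G) <- list(NULL, ped$id)
  stats::cor(G)
}

# Random valid multi-family pedigree for property tests.
random_pedigree <- function(n_families = 3, seed = 1) {
  set.seed(seed)
  tabs <- lapply(seq_len(n_families), function(k) {
    s <- sample(2:4, 1)
    fid <- paste0("R", k)
    id <- function(j) paste0(fid, "-", j)
    rows <- list(c(id(1), NA, NA), c(id(2), NA, NA))
    nxt <- 2
    for (ch in seq_len(s)) {
      nxt <- nxt + 1
      rows[[length(rows) + 1]] <- c(id(nxt), id(1), id(2))
    }
    m <- do.call(rbind, rows)
    data.frame(fid = fid, id = m[, 1], father = m[, 2], mother = m[, 3])
  })
  tab <- do.call(rbind, tabs)
  pedigree(tab$fid, tab$id, tab$father, tab$mother)
}

# Small dense variant table with a controlled rare/common layout.
toy_variant_table <- function(n = 12, pos = c(500, 2000, 3500, 5000, 9000),
                              maf_targets = c(0.3, 0.02, 0.02, 0.4, 0.02),
                              seed = 42) {
  set.seed(seed)
  m <- length(pos)
  d <- sapply(maf_targets, function(f) rbinom(n, 2, f))
  # force at least one copy so rare columns are not monomorphic
  d[1, ] <- pmax(d[1, ], 1)
  rownames(d) <- paste0("I", seq_len(n))
  variant_table(rep("chr1", m), pos, d)
}

# Classical two-sample Hotelling T2, straight from the textbook formula;
# serves as the independent oracle for the Phi = I reduction.
classic_hotelling <- function(X, case) {
  nc <- sum(case); nd <- sum(!case)
  xc <- colMeans(X[case, , drop = FALSE])
  xd <- colMeans(X[!case, , drop = FALSE])
  S <- ((nc - 1) * stats::cov(X[case, , drop = FALSE]) +
        (nd - 1) * stats::cov(X[!case, , drop = FALSE])) / (nc + nd - 2)
  drop(nc * nd / (nc + nd) * t(xc - xd) %*% solve(S) %*% (xc - xd))
}

# Blocks/design/phi bundle on random data for engine tests.
random_engine_input <- function(n = 20, p = 3, seed = 1, n_c = NULL) {
  set.seed(seed)
  if (is.null(n_c)) n_c <- n %/% 2
  X <- matrix(rnorm(n * p), n, p)
  rownames(X) <- paste0("I", seq_len(n))
  case <- c(rep(TRUE, n_c), rep(FALSE, n - n_c))
  Y <- matrix(as.integer(case), n, 1, dimnames = list(rownames(X), NULL))
  design <- build_response(Y, mode = "time", time = 1)
  blocks <- structure(list(Z = X, V = matrix(numeric(0), n, 0),
                           groups = list(), strategy = "sum",
                           window = list(chrom = "chr1", start = 0, end = 1e4,
                                         variants = seq_len(p))),
                      class = "collapsed_blocks")
  list(X = X, case = case, design = design, blocks = blocks,
       phi = diag(n))
}
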