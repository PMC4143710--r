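#' Simulation scenario
#'
#' Generative parameters for the gene-dropping fixture simulator. Defaults
#' emulate the structure of the study data the methods were evaluated on:
#' 20 three-generation families averaging ~40 members (sibships drawn from
#' `sibship`), a 70/30 rare/common MAF spectrum with rare MAF in
#' [0.001, 0.05), C = 3 covariates (age-like trend, medication use, smoking)
#' measured at J = 3 visits with strong serial correlation, and a logistic
#' per-visit event model calibrated so the any-time prevalence hits
#' `prevalence`.
#'
#' @param n_families number of families.
#' @param sibship integer range `c(lo, hi)`; sibship sizes are drawn
#'   uniformly from it, at both generations.
#' @param n_windows number of 10 kbp windows to cover with variants.
#' @param variants_per_window average variants per window.
#' @param window_width window width in bp.
#' @param pool_size founder haplotype pool size K.
#' @param ld_decay AR(1) correlation of the latent Gaussian generating pool
#'   haplotypes; larger = stronger LD between adjacent variants.
#' @param pool_switch per-adjacent-pair probability that a founder haplotype
#'   switches to a fresh pool template (Li-Stephens-style mosaic). Keeps
#'   haplotype sharing among founders local (blockwise LD) instead of
#'   chromosome-length, which would act as cryptic relatedness.
#' @param recomb per-adjacent-pair crossover probability at meiosis.
#' @param frac_common fraction of variants drawn from the common MAF range.
#' @param maf_common,maf_rare MAF ranges `c(lo, hi)` for common and rare
#'   variants.
#' @param causal_index indices of causal variants (into the variant table).
#' @param causal_beta log-odds effect per alternate allele, recycled over
#'   `causal_index`.
#' @param n_covariates C.
#' @param n_times J.
#' @param cov_trend per-covariate per-visit mean increment (age-like drift).
#' @param cov_rho AR(1) correlation of covariate noise across visits.
#' @param cov_beta log-odds effect of each (standardized) covariate on the
#'   per-visit event probability.
#' @param prevalence target any-time case fraction.
#' @param liability_sd sd of the shared individual random intercept.
#' @param seed integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_families = 20, sibship = c(3, 7),
                         n_windows = 10, variants_per_window = 8,
                         window_width = 10000,
                         pool_size = 200, ld_decay = 0.5, pool_switch = 0.1,
                         recomb = 0.01,
                         frac_common = 0.3,
                         maf_common = c(0.05, 0.5),
                         maf_rare = c(0.001, 0.05),
                         causal_index = integer(0), causal_beta = 0,
                         n_covariates = 3, n_times = 3,
                         cov_trend = c(1, 0, 0), cov_rho = 0.8,
                         cov_beta = c(0.3, 0.3, 0.3),
                         prevalence = 0.3, liability_sd = 1,
                         seed = 1L) {
  sc <- list(n_families = n_families, sibship = sibship,
             n_windows = n_windows,
             variants_per_window = variants_per_window,
             window_width = window_width,
             pool_size = pool_size, ld_decay = ld_decay,
             pool_switch = pool_switch, recomb = recomb,
             frac_common = frac_common, maf_common = maf_common,
             maf_rare = maf_rare,
             causal_index = causal_index,
             causal_beta = rep_len(causal_beta,
                                   max(1L, length(causal_index))),
             n_covariates = n_covariates, n_times = n_times,
             cov_trend = rep_len(cov_trend, n_covariates),
             cov_rho = cov_rho,
             cov_beta = rep_len(cov_beta, n_covariates),
             prevalence = prevalence, liability_sd = liability_sd,
             seed = as.integer(seed))
  stopifnot(sc$prevalence > 0, sc$prevalence < 1, abs(sc$cov_rho) < 1,
            sc$recomb >= 0, sc$recomb <= 0.5)
  structure(sc, class = "sim_scenario")
}

# One three-generation family: founder couple; their children each marry an
# incoming founder and have children of their own.
sim_family <- function(fid, sibship) {
  s1 <- sample(seq(sibship[1], sibship[2]), 1)
  id <- function(k) sprintf("%s-%d", fid, k)
  rows <- list(c(id(1), NA, NA, 1L), c(id(2), NA, NA, 2L))
  k <- 2L
  for (ch in seq_len(s1)) {
    k <- k + 1L; child <- id(k)
    sexc <- sample(1:2, 1)
    rows[[length(rows) + 1L]] <- c(child, id(1), id(2), sexc)
    k <- k + 1L; spouse <- id(k)
    rows[[length(rows) + 1L]] <- c(spouse, NA, NA, 3L - sexc)
    s2 <- sample(seq(sibship[1], sibship[2]), 1)
    for (gc in seq_len(s2)) {
      k <- k + 1L
      fa <- if (sexc == 1) child else spouse
      mo <- if (sexc == 1) spouse else child
      rows[[length(rows) + 1L]] <- c(id(k), fa, mo, sample(1:2, 1))
    }
  }
  m <- do.call(rbind, rows)
  data.frame(fid = fid, id = m[, 1], father = m[, 2], mother = m[, 3],
             sex = as.integer(m[, 4]), stringsAsFactors = FALSE)
}

#' Simulate a pedigree from a scenario
#'
#' @param scenario a [sim_scenario()].
#' @return A [pedigree].
#' @export
simulate_pedigree <- function(scenario) {
  fams <- lapply(sprintf("F%02d", seq_len(scenario$n_families)),
                 sim_family, sibship = scenario$sibship)
  tab <- do.call(rbind, fams)
  pedigree(tab$fid, tab$id, tab$father, tab$mother, tab$sex)
}

# Founder haplotype pool with blockwise LD: allele m of haplotype h is
# 1{z_m > qnorm(1 - f_m)} where z is a stationary AR(1) Gaussian chain with
# parameter ld_decay; marginal allele frequencies are exact.
sim_pool <- function(K, freqs, rho) {
  m <- length(freqs)
  z <- matrix(stats::rnorm(K * m), K, m)
  if (m > 1 && rho != 0)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  t(t(z) > stats::qnorm(1 - freqs)) + 0L
}

# Founder haplotype: a mosaic over pool templates, switching to a fresh
# uniformly drawn template with probability `switch` per adjacent pair.
# With switch = 0 this reduces to copying one template verbatim.
sim_founder_hap <- function(pool, switch) {
  m <- ncol(pool); K <- nrow(pool)
  if (switch <= 0) return(pool[sample.int(K, 1), ])
  sw <- c(TRUE, stats::runif(m - 1) < switch)
  seg <- cumsum(sw)
  idx <- sample.int(K, max(seg), replace = TRUE)[seg]
  pool[cbind(idx, seq_len(m))]
}

# Meiosis: transmit a recombinant of the parent's two haplotypes; a single
# crossover process with per-adjacent-pair switch probability r.
sim_meiosis <- function(h1, h2, r) {
  m <- length(h1)
  cur <- sample(1:2, 1)
  if (r > 0 && m > 1) {
    sw <- stats::runif(m - 1) < r
    track <- cumsum(c(cur - 1L, sw)) %% 2L + 1L
  } else track <- rep(cur, m)
  ifelse(track == 1L, h1, h2)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders draw two haplotypes from a pool of `pool_size` haplotypes with
#' AR(1)-latent LD; non-founders inherit one recombinant haplotype from each
#' parent (crossover probability `recomb` per adjacent variant pair).
#' Dosages are alternate-allele counts. Variant positions are placed
#' uniformly over `n_windows * window_width` bp of one chromosome.
#'
#' @param scenario a [sim_scenario()].
#' @param ped optional [pedigree]; generated from the scenario when absent.
#' @return list with `vt` (a [variant_table], haplotypes kept in
#'   `attr(, "haplotypes")` for Mendelian checks), `ped`, `freqs` (pool
#'   allele frequencies).
#' @export
simulate_genotypes <- function(scenario, ped = NULL) {
  set.seed(scenario$seed)
  if (is.null(ped)) ped <- simulate_pedigree(scenario)
  m <- scenario$n_windows * scenario$variants_per_window
  span <- scenario$n_windows * scenario$window_width
  pos <- sort(sample.int(span, m))
  common <- stats::runif(m) < scenario$frac_common
  freqs <- ifelse(common,
                  stats::runif(m, scenario$maf_common[1], scenario$maf_common[2]),
                  stats::runif(m, scenario$maf_rare[1], scenario$maf_rare[2]))
  pool <- sim_pool(scenario$pool_size, freqs, scenario$ld_decay)
  n <- nrow(ped)
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  for (i in order(attr(ped, "depth"))) {
    H1[i, ] <- if (is.na(fa[i])) sim_founder_hap(pool, scenario$pool_switch)
               else sim_meiosis(H1[fa[i], ], H2[fa[i], ], scenario$recomb)
    H2[i, ] <- if (is.na(mo[i])) sim_founder_hap(pool, scenario$pool_switch)
               else sim_meiosis(H1[mo[i], ], H2[mo[i], ], scenario$recomb)
  }
  d <- H1 + H2
  storage.mode(d) <- "double"
  rownames(d) <- ped$id
  vt <- variant_table(rep("chrS", m), pos, d)
  attr(vt, "haplotypes") <- list(H1 = H1, H2 = H2)
  list(vt = vt, ped = ped, freqs = freqs)
}

#' Simulate longitudinal covariates and binary events
#'
#' Covariates: C series of length J per individual, mean trajectory
#' `j * cov_trend[c]` plus AR(1) noise (unit marginal variance, correlation
#' `cov_rho` between adjacent visits). Events: per-visit logistic model on
#' the causal dosage burden, the current covariate values and a shared
#' individual intercept `N(0, liability_sd^2)`; the visit intercept is
#' calibrated so the realized any-time prevalence matches the target. A
#' draw with 0 or n cases is resampled (with a warning).
#'
#' @param scenario a [sim_scenario()].
#' @param vt the [variant_table] from [simulate_genotypes()].
#' @return list with `outcomes` (n x J 0/1 matrix), `A` (n x (C*J)
#'   covariate matrix, covariate-major column order), `burden` (the causal
#'   linear predictor).
#' @export
simulate_phenotypes <- function(scenario, vt) {
  set.seed(scenario$seed + 1L)
  n <- nrow(vt$dosage)
  C <- scenario$n_covariates; J <- scenario$n_times
  burden <- if (length(scenario$causal_index))
    drop(vt$dosage[, scenario$causal_index, drop = FALSE] %*%
           scenario$causal_beta)
  else rep(0, n)
  A <- matrix(0, n, C * J)
  colnames(A) <- paste0("cov", rep(seq_len(C), each = J), "_t",
                        rep(seq_len(J), C))
  for (cc in seq_len(C)) {
    e <- matrix(stats::rnorm(n * J), n, J)
    if (J > 1)
      for (j in 2:J)
        e[, j] <- scenario$cov_rho * e[, j - 1] +
          sqrt(1 - scenario$cov_rho^2) * e[, j]
    A[, (cc - 1) * J + seq_len(J)] <-
      sweep(e, 2, seq_len(J) * scenario$cov_trend[cc], `+`)
  }
  per_time <- 1 - (1 - scenario$prevalence)^(1 / J)
  for (attempt in 1:20) {
    b <- stats::rnorm(n, 0, scenario$liability_sd)
    Y <- matrix(0L, n, J, dimnames = list(rownames(vt$dosage), NULL))
    for (j in seq_len(J)) {
      covpart <- rowSums(sweep(A[, (seq_len(C) - 1) * J + j, drop = FALSE],
                               2, scenario$cov_beta, `*`))
      eta <- burden + covpart + b
      # calibrate the visit intercept to the per-visit prevalence target
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - per_time,
                              c(-50, 50))$root
      Y[, j] <- stats::rbinom(n, 1, stats::plogis(alpha + eta))
    }
    nc <- sum(rowSums(Y) > 0)
    if (nc > 0 && nc < n)
      return(list(outcomes = Y, A = A, burden = burden))
    warning("degenerate prevalence draw (", nc, " cases); resampling")
  }
  stop("could not draw a non-degenerate phenotype sample")
}

#' Write / read the long-format phenotype table
#'
#' CSV with columns `id`, `time`, `outcome`, then one column per covariate.
#'
#' @param pheno a [simulate_phenotypes()] result.
#' @param ids individual ids (row order of the matrices).
#' @param path output path.
#' @export
write_phenotypes_long <- function(pheno, ids, path) {
  J <- ncol(pheno$outcomes)
  C <- ncol(pheno$A) / J
  long <- do.call(rbind, lapply(seq_len(J), function(j) {
    df <- data.frame(id = ids, time = j, outcome = pheno$outcomes[, j])
    for (cc in seq_len(C))
      df[[paste0("cov", cc)]] <- pheno$A[, (cc - 1) * J + j]
    df
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_long
#' @param path path of a long-format phenotype CSV.
#' @return list with `outcomes` (n x J), `A` (n x (C*J), covariate-major),
#'   `ids`.
#' @export
read_phenotypes_long <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "time", "outcome") %in% names(long)))
  covs <- setdiff(names(long), c("id", "time", "outcome"))
  ids <- unique(long$id)
  times <- sort(unique(long$time))
  J <- length(times); C <- length(covs)
  Y <- matrix(NA_integer_, length(ids), J, dimnames = list(ids, NULL))
  A <- matrix(NA_real_, length(ids), C * J)
  colnames(A) <- paste0(rep(covs, each = J), "_t", rep(times, C))
  for (j in seq_len(J)) {
    sub <- long[long$time == times[j], ]
    rows <- match(sub$id, ids)
    Y[rows, j] <- sub$outcome
    for (cc in seq_len(C)) A[rows, (cc - 1) * J + j] <- sub[[covs[cc]]]
  }
  if (anyNA(Y) || anyNA(A))
    stop("every individual needs outcomes and covariates at every time")
  list(outcomes = Y, A = A, ids = ids)
}
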