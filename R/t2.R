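#' Build the case/control design from longitudinal binary outcomes
#'
#' The response is binary: under `mode = "any"` (the longitudinal tests) an
#' individual is a case iff the event occurred at any of the J measurement
#' points; under `mode = "time"` a case iff the event occurred at measurement
#' `time` (the single-time-point comparator uses `time = 1`). Individuals are
#' reordered cases-first (the Dr = (u_1,...,u_n)' convention, u_i = 1 for
#' cases) and the permutation is recorded so genotype/covariate/kinship rows
#' can follow.
#'
#' @param outcomes n x J binary matrix (0/1), rownames = individual ids.
#' @param mode `"any"` or `"time"`.
#' @param time measurement index used when `mode = "time"`.
#' @return A `cc_design`: list with `case` (logical, input order), `order`
#'   (integer permutation putting cases first), `u` (0/1 vector in
#'   cases-first order), `n`, `n_c`, `n_d`, `ids`.
#' @export
build_response <- function(outcomes, mode = c("any", "time"), time = 1L) {
  mode <- match.arg(mode)
  outcomes <- as.matrix(outcomes)
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  case <- if (mode == "any") rowSums(outcomes) > 0 else outcomes[, time] == 1
  n_c <- sum(case); n_d <- sum(!case)
  if (n_c == 0 || n_d == 0)
    stop("degenerate response: ", n_c, " cases and ", n_d,
         " controls (statistic undefined)")
  ord <- order(!case)                       # stable: cases first
  structure(list(case = case, order = ord,
                 u = as.numeric(case[ord]),
                 n = length(case), n_c = n_c, n_d = n_d,
                 ids = rownames(outcomes)[ord]),
            class = "cc_design")
}

#' @export
print.cc_design <- function(x, ...) {
  cat(sprintf("cc_design: %d cases, %d controls (n = %d)\n",
              x$n_c, x$n_d, x$n))
  invisible(x)
}

#' Pooled within-group covariance (Hotelling-style)
#'
#' `sigma_hat = [sum_cases (x - xbar_c)(x - xbar_c)' +
#'              sum_controls (x - xbar_d)(x - xbar_d)'] / (n - 2)`
#'
#' @param X n x p matrix in the design's cases-first row order.
#' @param design a [build_response()] design.
#' @return p x p matrix.
#' @export
pooled_covariance <- function(X, design) {
  stopifnot(nrow(X) == design$n, design$n_c >= 2, design$n_d >= 2)
  ic <- seq_len(design$n_c)
  Xc <- scale(X[ic, , drop = FALSE], scale = FALSE)
  Xd <- scale(X[-ic, , drop = FALSE], scale = FALSE)
  (crossprod(Xc) + crossprod(Xd)) / (design$n - 2)
}

# Pooled within-group cross-covariance between two blocks (same pooling and
# divisor as pooled_covariance).
pooled_cross <- function(X, Y, design) {
  ic <- seq_len(design$n_c)
  (crossprod(scale(X[ic, , drop = FALSE], scale = FALSE),
             scale(Y[ic, , drop = FALSE], scale = FALSE)) +
   crossprod(scale(X[-ic, , drop = FALSE], scale = FALSE),
             scale(Y[-ic, , drop = FALSE], scale = FALSE))) / (design$n - 2)
}

# Symmetric rank-revealing pseudo-inverse quadratic form d' S^+ d.
# Eigenvalues below tol * max(eigenvalue) are dropped; their count defines
# the retained rank (the "rank of data matrix" DF convention).
pinv_quad <- function(S, d, tol = 1e-10) {
  p <- length(d)
  if (p == 0L) return(list(q = 0, rank = 0L))
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(list(q = 0, rank = 0L))
  y <- crossprod(e$vectors[, keep, drop = FALSE], d)
  list(q = sum(y^2 / e$values[keep]), rank = sum(keep))
}

# q_M = (Dr - (n_c/n) 1)' M (Dr - (n_c/n) 1); with M = I this is n_c n_d / n.
quad_weight <- function(design, M = NULL) {
  w <- design$u - design$n_c / design$n
  if (is.null(M)) return(design$n_c * design$n_d / design$n)
  drop(crossprod(w, M %*% w))
}

# H-row contraction: d = (n_c n_d / n) (xbar_cases - xbar_controls).
# Equals (I(p) %x% w') eta for w = Dr - (n_c/n) 1.
mean_diff_contrast <- function(X, design) {
  ic <- seq_len(design$n_c)
  (design$n_c * design$n_d / design$n) *
    (colMeans(X[ic, , drop = FALSE]) - colMeans(X[-ic, , drop = FALSE]))
}

drop_constant_cols <- function(X) {
  if (ncol(X) == 0L) return(X)
  rng <- apply(X, 2, function(x) diff(range(x)))
  X[, rng > 1e-12, drop = FALSE]
}

# Genetic-block quadratic form: returns the Z+V contribution (numerator
# already divided by q_phi) together with retained column and rank counts.
# split = TRUE estimates separate covariances for Z and V ("assuming they
# are uncorrelated", the CMC.ZXpaper convention); FALSE pools [Z | V].
genetic_term <- function(Z, V, design, q_phi, split, tol = 1e-10) {
  Z <- drop_constant_cols(Z); V <- drop_constant_cols(V)
  p_ret <- ncol(Z) + ncol(V)
  if (p_ret == 0L)
    return(list(term = 0, p_retained = 0L, rank = 0L))
  if (split) {
    num <- 0; rank <- 0L
    for (X in list(Z, V)) {
      if (ncol(X) == 0L) next
      pq <- pinv_quad(pooled_covariance(X, design),
                      mean_diff_contrast(X, design), tol)
      num <- num + pq$q
      rank <- rank + pq$rank
    }
  } else {
    X <- cbind(Z, V)
    pq <- pinv_quad(pooled_covariance(X, design),
                    mean_diff_contrast(X, design), tol)
    num <- pq$q
    rank <- pq$rank
  }
  list(term = num / q_phi, p_retained = p_ret, rank = rank)
}

#' Generalized and extended T2 statistics
#'
#' Computes the family-based Hotelling-type statistic
#' `T2 = (Heta)' Gamma^-1 (Heta)` for one genome window, where `Heta` stacks
#' the scaled case-minus-control mean differences of the common-variant
#' block Z, the collapsed rare-variant block V and (for the `.longi`
#' methods) the longitudinal covariate block A, and
#' `Gamma = H Lambda H'` with the Kronecker-structured
#' `Lambda = diag(Sigma_Z %x% Phi, Sigma_V %x% Phi, Sigma_A %x% Phi*)`.
#' The contraction reduces each block's contribution to
#' `d' Sigma^+ d / q_M` with `d = (n_c n_d / n)(xbar_c - xbar_d)` and
#' `q_M = (Dr - (n_c/n)1)' M (Dr - (n_c/n)1)` (M = Phi for genotypes,
#' Phi* for covariates). With Phi = Phi* = I, a single block and an
#' invertible covariance this is exactly the classical two-sample Hotelling
#' T2.
#'
#' Methods: `T2` (sum-collapsed V, one joint covariance over \[Z|V\]),
#' `CMC.ZXpaper` (sum-collapsed, separate Sigma_Z and Sigma_V),
#' `CMC.ZXcode` (max-collapsed, joint covariance), and their `.longi`
#' counterparts which add the covariate term (Sigma_A always estimated
#' separately). The collapsing strategy itself is applied upstream by
#' [collapse_window()]; see [method_strategy()].
#'
#' Zero-variance columns are dropped before covariance estimation; singular
#' covariances use a rank-revealing pseudo-inverse (relative eigenvalue
#' cutoff 1e-10).
#'
#' @param blocks a [collapse_window()] result, rows in cases-first order.
#' @param design a [build_response()] design.
#' @param phi kinship matrix in the same cases-first order.
#' @param method one of `"T2"`, `"CMC.ZXpaper"`, `"CMC.ZXcode"`,
#'   `"T2.longi"`, `"CMC.ZXpaper.longi"`, `"CMC.ZXcode.longi"`.
#' @param A n x (C*J) longitudinal covariate matrix (covariate-major column
#'   order), cases-first rows; required for `.longi` methods.
#' @param phi_star `"identity"` or `"kinship"` — the individual correlation
#'   assumed for covariates.
#' @param df_mode `"rank"` (retained pseudo-inverse rank) or
#'   `"n_variables"` (count of retained columns).
#' @return A `t2_result`: list with `t2`, `df`, `p_asym`, `method`,
#'   `genetic` and `covariate` block contributions, and the two quadratic
#'   denominators `q_phi`, `q_star`.
#' @export
t2_statistic <- function(blocks, design, phi, method = "T2", A = NULL,
                         phi_star = c("identity", "kinship"),
                         df_mode = c("rank", "n_variables")) {
  phi_star <- match.arg(phi_star)
  df_mode <- match.arg(df_mode)
  method <- match.arg(method, c("T2", "CMC.ZXpaper", "CMC.ZXcode",
                                "T2.longi", "CMC.ZXpaper.longi",
                                "CMC.ZXcode.longi"))
  longi <- grepl("\\.longi$", method)
  split <- grepl("^CMC\\.ZXpaper", method)
  if (longi && is.null(A))
    stop("method ", method, " requires the longitudinal covariate block A")
  Z <- blocks$Z; V <- blocks$V
  if (ncol(Z) + ncol(V) == 0L) stop("empty Z and V blocks")
  stopifnot(nrow(Z) == design$n, nrow(phi) == design$n)
  q_phi <- quad_weight(design, phi)
  if (q_phi <= 0)
    stop("(Dr - (n_c/n)1)' Phi (Dr - (n_c/n)1) <= 0: Phi is not PSD")
  g <- genetic_term(Z, V, design, q_phi, split)
  q_star <- if (phi_star == "identity") quad_weight(design)
            else q_phi
  cov_term <- 0; a_ret <- 0L; a_rank <- 0L
  if (longi) {
    Ar <- drop_constant_cols(A)
    if (ncol(Ar)) {
      pq <- pinv_quad(pooled_covariance(Ar, design),
                      mean_diff_contrast(Ar, design))
      cov_term <- pq$q / q_star
      a_ret <- ncol(Ar); a_rank <- pq$rank
    }
  }
  t2 <- g$term + cov_term
  df <- if (df_mode == "rank") g$rank + a_rank else g$p_retained + a_ret
  structure(list(t2 = t2, df = df,
                 p_asym = if (df > 0) stats::pchisq(t2, df, lower.tail = FALSE)
                          else NA_real_,
                 method = method, genetic = g$term, covariate = cov_term,
                 q_phi = q_phi, q_star = q_star,
                 n_common = ncol(Z), n_rare_groups = ncol(V)),
            class = "t2_result")
}

#' @export
print.t2_result <- function(x, ...) {
  cat(sprintf("%s: T2 = %.4f on df = %d, asymptotic p = %.4g\n",
              x$method, x$t2, x$df, x$p_asym))
  invisible(x)
}

#' Upper-tail chi-square p-value for a T2 result
#'
#' DF conventions: `"n_variables"` — the number of tested variables
#' (retained columns); `"rank"` — the rank of the (centered) data matrix as
#' retained by the pseudo-inverse. Both conventions are reported as inflated
#' under family structure; the permutation p-value is the calibrated one.
#'
#' @param t2 statistic value (>= 0).
#' @param df degrees of freedom (> 0).
#' @return p-value in \[0, 1\].
#' @export
asymptotic_pvalue <- function(t2, df) {
  stopifnot(t2 >= 0)
  if (df <= 0) stop("df must be positive")
  stats::pchisq(t2, df, lower.tail = FALSE)
}

#' Collapsing strategy implied by a method name
#'
#' `T2`, `CMC.ZXpaper` (and `.longi`) sum rare genotypes within adjacency
#' runs; `CMC.ZXcode` (and `.longi`) takes the maximum.
#'
#' @param method method name as in [t2_statistic()].
#' @return `"sum"` or `"max"`.
#' @export
method_strategy <- function(method) {
  if (grepl("^CMC\\.ZXcode", method)) "max" else "sum"
}
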