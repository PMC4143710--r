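test_that("build_response implements any-time and time-k rules", {
  Y <- rbind(a = c(0, 0, 1), b = c(0, 0, 0), c = c(1, 1, 0), d = c(0, 1, 0))
  any <- build_response(Y, "any")
  expect_equal(any$case, c(a = TRUE, b = FALSE, c = TRUE, d = TRUE))
  expect_equal(any$n_c, 3); expect_equal(any$n_d, 1)
  t1 <- build_response(Y, "time", time = 1)
  expect_equal(unname(t1$case), c(FALSE, FALSE, TRUE, FALSE))
  # cases-first reorder with recorded permutation
  expect_equal(t1$order, c(3L, 1L, 2L, 4L))
  expect_equal(t1$u, c(1, 0, 0, 0))
  expect_equal(t1$ids, c("c", "a", "b", "d"))
  expect_error(build_response(matrix(0, 4, 3)), "degenerate")
  expect_error(build_response(matrix(1, 4, 3)), "degenerate")
  expect_error(build_response(matrix(2, 4, 3)), "binary")
})

test_that("pooled covariance follows the two-sample Hotelling formula", {
  # 1-D hand computation: cases {0,2}, controls {0,0,2,2}
  X <- matrix(c(0, 2, 0, 0, 2, 2), 6, 1)
  Y <- matrix(c(1, 1, 0, 0, 0, 0), 6, 1)
  design <- build_response(Y, "time")
  expect_equal(pooled_covariance(X, design)[1, 1], (2 + 4) / 4)
  # identical rows within both groups -> zero matrix
  X0 <- matrix(rep(c(3, 7), times = c(2, 4)), 6, 2)
  expect_equal(pooled_covariance(X0, design), matrix(0, 2, 2))
  # equals the textbook pooled S on random data
  inp <- random_engine_input(n = 24, p = 4, seed = 5)
  S <- ((inp$design$n_c - 1) * cov(inp$X[inp$case, ]) +
        (inp$design$n_d - 1) * cov(inp$X[!inp$case, ])) / (24 - 2)
  expect_equal(pooled_covariance(inp$X, inp$design), S)
})

test_that("with Phi = I the statistic is the classical two-sample Hotelling T2", {
  for (s in 1:10) {
    inp <- random_engine_input(n = 20, p = 3, seed = s)
    res <- t2_statistic(inp$blocks, inp$design, inp$phi, "T2")
    expect_lt(abs(res$t2 - classic_hotelling(inp$X, inp$case)), 1e-10)
    expect_equal(res$df, 3)
  }
})

test_that("identical group means give T2 = 0 and asymptotic p = 1", {
  inp <- random_engine_input(n = 20, p = 3, seed = 2)
  X <- inp$X
  X[!inp$case, ] <- X[inp$case, ]           # mirror cases into controls
  inp$blocks$Z <- X
  res <- t2_statistic(inp$blocks, inp$design, inp$phi, "T2")
  expect_equal(res$t2, 0)
  expect_equal(res$p_asym, 1)
})

test_that("q scales linearly in Phi: Phi = 2I halves the genetic term", {
  inp <- random_engine_input(n = 20, p = 3, seed = 3)
  r1 <- t2_statistic(inp$blocks, inp$design, inp$phi, "T2")
  r2 <- t2_statistic(inp$blocks, inp$design, 2 * inp$phi, "T2")
  expect_equal(r2$t2, r1$t2 / 2)
})

test_that("q_I equals n_c n_d / n in closed form", {
  for (nc in c(2, 5, 9)) for (nd in c(2, 3, 11)) {
    Y <- matrix(rep(c(1, 0), c(nc, nd)), ncol = 1)
    design <- build_response(Y, "time")
    w <- design$u - design$n_c / design$n
    expect_equal(sum(w^2), nc * nd / (nc + nd))
    expect_equal(pedT2:::quad_weight(design), nc * nd / (nc + nd))
    expect_equal(pedT2:::quad_weight(design, diag(nc + nd)),
                 nc * nd / (nc + nd))
  }
})

test_that("the H contraction of Eq-style block form matches the mean-difference shortcut", {
  set.seed(8)
  n <- 14; p <- 4; nc <- 6
  inp <- random_engine_input(n = n, p = p, seed = 8, n_c = nc)
  w <- inp$design$u - nc / n
  H <- kronecker(diag(p), t(w))
  eta <- as.vector(inp$X)                    # column-major stacking
  expect_lt(max(abs(drop(H %*% eta) -
                    pedT2:::mean_diff_contrast(inp$X, inp$design))), 1e-12)
})

test_that("block contributions are invariant to invertible column maps and additive", {
  set.seed(9)
  n <- 30
  Z <- matrix(rnorm(n * 3), n, 3)
  V <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  A <- matrix(rnorm(n * 6), n, 6)
  Y <- matrix(rep(c(1, 0), c(12, 18)), ncol = 1)
  design <- build_response(Y, "time")
  blocks <- structure(list(Z = Z, V = V, groups = list(4L, 5L),
                           strategy = "sum",
                           window = list(chrom = "c", start = 0, end = 1,
                                         variants = 1:5)),
                      class = "collapsed_blocks")
  phi <- diag(n)
  r <- t2_statistic(blocks, design, phi, "T2.longi", A = A)
  expect_equal(r$genetic + r$covariate, r$t2)
  expect_gte(r$t2, 0)
  # invertible map on the covariate block leaves its contribution unchanged
  M <- matrix(rnorm(36), 6, 6) + 6 * diag(6)
  r2 <- t2_statistic(blocks, design, phi, "T2.longi", A = A %*% M)
  expect_equal(r2$covariate, r$covariate, tolerance = 1e-8)
  expect_equal(r2$genetic, r$genetic)
  # and on the joint genetic block
  G <- matrix(rnorm(25), 5, 5) + 5 * diag(5)
  ZV <- cbind(Z, V) %*% G
  blocks3 <- blocks; blocks3$Z <- ZV; blocks3$V <- matrix(numeric(0), n, 0)
  r3 <- t2_statistic(blocks3, design, phi, "T2")
  expect_equal(r3$t2, r$genetic, tolerance = 1e-8)
})

test_that("switching Phi* rescales only the covariate term by q_I/q_Phi", {
  set.seed(10)
  n <- 16
  ped <- demo_pedigree()
  phi <- compute_kinship(ped)
  idx <- rep(1:8, 2)
  # stack two copies of the family as unrelated blocks to get n = 16
  Phi <- matrix(0, n, n)
  Phi[1:8, 1:8] <- phi; Phi[9:16, 9:16] <- phi
  Z <- matrix(rnorm(n * 2), n, 2)
  A <- matrix(rnorm(n * 4), n, 4)
  Y <- matrix(rep(c(1, 0), c(7, 9)), ncol = 1)
  design <- build_response(Y, "time")
  blocks <- structure(list(Z = Z, V = matrix(numeric(0), n, 0),
                           groups = list(), strategy = "sum",
                           window = list(chrom = "c", start = 0, end = 1,
                                         variants = 1:2)),
                      class = "collapsed_blocks")
  ri <- t2_statistic(blocks, design, Phi, "T2.longi", A = A,
                     phi_star = "identity")
  rk <- t2_statistic(blocks, design, Phi, "T2.longi", A = A,
                     phi_star = "kinship")
  expect_equal(rk$genetic, ri$genetic)
  expect_equal(rk$covariate, ri$covariate * ri$q_star / rk$q_star)
  expect_equal(ri$q_star, design$n_c * design$n_d / design$n)
  expect_equal(rk$q_star, rk$q_phi)
})

test_that("CMC.ZXpaper splits the covariance; equals joint when blocks are uncorrelated in estimate", {
  set.seed(12)
  n <- 40
  Z <- matrix(rnorm(n * 2), n, 2)
  V <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(rep(c(1, 0), each = n / 2), ncol = 1)
  design <- build_response(Y, "time")
  blocks <- structure(list(Z = Z, V = V, groups = list(3L, 4L),
                           strategy = "sum",
                           window = list(chrom = "c", start = 0, end = 1,
                                         variants = 1:4)),
                      class = "collapsed_blocks")
  phi <- diag(n)
  rj <- t2_statistic(blocks, design, phi, "T2")
  rs <- t2_statistic(blocks, design, phi, "CMC.ZXpaper")
  # split and joint differ in general (off-diagonal blocks ignored)...
  expect_false(isTRUE(all.equal(rj$t2, rs$t2)))
  # ...but agree when the empirical cross-covariance is forced to zero
  Vo <- V - Z %*% solve(pooled_covariance(Z, design),
                        pedT2:::pooled_cross(Z, V, design))
  blocks$V <- Vo
  rj2 <- t2_statistic(blocks, design, phi, "T2")
  rs2 <- t2_statistic(blocks, design, phi, "CMC.ZXpaper")
  expect_lt(abs(rj2$t2 - rs2$t2), 1e-8)
})

test_that("degrees of freedom follow the two conventions under rank deficiency", {
  inp <- random_engine_input(n = 20, p = 3, seed = 4)
  blocks <- inp$blocks
  blocks$Z <- cbind(inp$X, inp$X[, 1])       # duplicated column
  rr <- t2_statistic(blocks, inp$design, diag(20), "T2", df_mode = "rank")
  rn <- t2_statistic(blocks, inp$design, diag(20), "T2",
                     df_mode = "n_variables")
  expect_equal(rr$df, 3)
  expect_equal(rn$df, 4)
  # the pseudo-inverse keeps the statistic equal to the full-rank one
  r0 <- t2_statistic(inp$blocks, inp$design, diag(20), "T2")
  expect_equal(rr$t2, r0$t2, tolerance = 1e-8)
})

test_that("asymptotic p-values match an independent chi-square oracle", {
  expect_equal(asymptotic_pvalue(0, 5), 1)
  # survival function via numerical integration of the density
  for (df in c(2, 7)) {
    t2 <- df
    oracle <- integrate(function(x) dchisq(x, df), t2, Inf,
                        rel.tol = 1e-12)$value
    expect_equal(asymptotic_pvalue(t2, df), oracle, tolerance = 1e-9)
  }
  expect_error(asymptotic_pvalue(3, 0), "df")
  expect_error(asymptotic_pvalue(-1, 3))
})

test_that("engine guards fire on bad inputs", {
  inp <- random_engine_input()
  empty <- inp$blocks
  empty$Z <- matrix(numeric(0), 20, 0)
  expect_error(t2_statistic(empty, inp$design, inp$phi, "T2"), "empty")
  expect_error(t2_statistic(inp$blocks, inp$design, -inp$phi, "T2"),
               "not PSD")
  expect_error(t2_statistic(inp$blocks, inp$design, inp$phi, "T2.longi"),
               "requires")
})
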