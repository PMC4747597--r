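test_that("fixed-effect conditional mean reduces to OLS in the decoupled case", {
  set.seed(20)
  n <- 10L
  X <- cbind(intercept = 1, g = rbinom(n, 1, 0.5))
  y <- rnorm(n, X %*% c(2, -1), 1)
  XtXi <- solve(crossprod(X))
  # u = 0, diagonal R: conditional mean must equal the OLS estimate
  bm <- nsetrait:::beta_cond_moments(X, XtXi, y, numeric(n), rnorm(n),
                                     r_self = 1.3, r_other = 2.1, r12 = 0)
  expect_equal(bm$mean, drop(XtXi %*% crossprod(X, y)))
  expect_equal(bm$s2c, 1.3)
  # intercept-only design: mean of the u-adjusted working response
  X1 <- matrix(1, n, 1)
  u <- rnorm(n)
  bm1 <- nsetrait:::beta_cond_moments(X1, solve(crossprod(X1)), y, u,
                                      numeric(n), 1, 1, 0)
  expect_equal(bm1$mean, mean(y - u))
  # correlated residuals shift the working response by (r12/r_other) e_other
  e_o <- rnorm(n)
  bm2 <- nsetrait:::beta_cond_moments(X, XtXi, y, numeric(n), e_o, 2, 4, 1)
  expect_equal(bm2$mean, drop(XtXi %*% crossprod(X, y - 0.25 * e_o)))
  expect_equal(bm2$s2c, 2 - 1 / 4)
})

test_that("polygenic conditional decouples into scalar ridge draws when K = I", {
  set.seed(21)
  n <- 12L
  lam <- rep(1, n)                     # K = I
  g1 <- 3; g2 <- 5; r1 <- 2; r2 <- 4
  dtP <- rnorm(n); dtA <- rnorm(n)
  um <- nsetrait:::u_cond_moments(dtP, dtA, lam, diag(c(g1, g2)),
                                  diag(c(r1, r2)))
  expect_equal(um$m1, dtP * g1 / (g1 + r1))
  expect_equal(um$m2, dtA * g2 / (g2 + r2))
  expect_equal(um$l11, rep(sqrt(1 / (1 / r1 + 1 / g1)), n))
  expect_equal(um$l21, rep(0, n))
  # G -> 0 limit: prior dominates, conditional mean -> 0
  um0 <- nsetrait:::u_cond_moments(dtP, dtA, lam, diag(1e-12, 2),
                                   diag(c(r1, r2)))
  expect_lt(max(abs(c(um0$m1, um0$m2))), 1e-10)
  # conditional mean is linear in the working response (superposition)
  umA <- nsetrait:::u_cond_moments(dtP, dtA, lam, diag(c(g1, g2)),
                                   matrix(c(2, 1, 1, 4), 2))
  umB <- nsetrait:::u_cond_moments(2 * dtP, -dtA, lam, diag(c(g1, g2)),
                                   matrix(c(2, 1, 1, 4), 2))
  umAB <- nsetrait:::u_cond_moments(3 * dtP, 0 * dtA, lam, diag(c(g1, g2)),
                                    matrix(c(2, 1, 1, 4), 2))
  expect_equal(umA$m1 + umB$m1, umAB$m1, tolerance = 1e-12)
  expect_equal(umA$m2 + umB$m2, umAB$m2, tolerance = 1e-12)
})

test_that("inverse-Wishart prior draws have the documented mean (nu - p - 1 = 1)", {
  set.seed(22)
  S <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  draws <- replicate(20000L, nsetrait:::riwish(4L, S))
  m <- apply(draws, 1:2, mean)
  expect_lt(max(abs(m - S) / abs(S)), 0.12)
  # every draw symmetric positive definite
  expect_true(all(apply(draws[, , 1:200], 3L, function(M)
    M[1, 2] == M[2, 1] && det(M) > 0 && M[1, 1] > 0)))
})

test_that("covariance conditionals concentrate at truth (conjugate simulation)", {
  set.seed(23)
  n <- 500L
  G_true <- matrix(c(2, 0.8, 0.8, 3), 2)
  U <- matrix(rnorm(2L * n), n) %*% chol(G_true)
  S0 <- 0.5 * diag(2)
  g_draws <- replicate(400L, nsetrait:::g_cond_draw(U[, 1], U[, 2],
                                                    rep(1, n), S0))
  expect_lt(max(abs(apply(g_draws, 1:2, mean) - G_true) / abs(G_true)), 0.15)

  R_true <- matrix(c(1.5, -0.4, -0.4, 2.5), 2)
  E <- matrix(rnorm(2L * n), n) %*% chol(R_true)
  r_draws <- replicate(400L, nsetrait:::r_cond_draw(E[, 1], E[, 2], S0))
  expect_lt(max(abs(apply(r_draws, 1:2, mean) - R_true) / abs(R_true)), 0.15)
  # zero-covariance constraint holds exactly in every draw
  rz <- replicate(50L, nsetrait:::r_cond_draw(E[, 1], E[, 2], S0,
                                              zero_rescov = TRUE))
  expect_true(all(rz[1, 2, ] == 0))
})

test_that("local-support Metropolis ratio equals full-data evaluation", {
  d <- tiny_data(n = 15, seed = 30)
  kv <- build_knots(min(d$y_P), max(d$y_P))
  Phi <- spline_basis(kv, d$y_P)
  Phi_y <- Phi * d$y_P
  supp <- lapply(1:8, function(m) which(Phi[, m] > 0))
  for (s in 1:100) {
    p <- random_params(d, kv, with_spline = TRUE, seed = 100 + s)
    s2P <- runif(1, 0.01, 1)
    E <- nsetrait:::structural_residuals(d, p, kv)
    mu_c <- (p$R[1, 2] / p$R[1, 1]) * E[, 1]
    sd_c <- sqrt(p$R[2, 2] - p$R[1, 2]^2 / p$R[1, 1])
    m <- sample(8L, 1L)
    prop <- p$P[m] + rnorm(1, 0, 0.5)
    mh <- nsetrait:::mh_weight_logratio(m, prop, p$P, E[, 2], mu_c, sd_c,
                                        Phi_y, supp[[m]], s2P)
    # oracle: full likelihood over all lines plus the full prior difference
    p_new <- p; p_new$P[m] <- prop
    full <- total_loglik(d, p_new, kv) - total_loglik(d, p, kv) +
      nsetrait:::log_prior_weights(p_new$P, s2P) -
      nsetrait:::log_prior_weights(p$P, s2P)
    expect_lt(abs(mh$logratio - full), 1e-10)
  }
  # a proposal equal to the current value is always accepted
  p <- random_params(d, kv, seed = 1)
  E <- nsetrait:::structural_residuals(d, p, kv)
  mh0 <- nsetrait:::mh_weight_logratio(3L, p$P[3], p$P, E[, 2],
                                       numeric(d$n), 1, Phi_y, supp[[3]], 0.5)
  expect_equal(mh0$logratio, 0)
})

test_that("smoothness-variance conditional has the documented form", {
  # P linear in m: all second differences vanish; boundary terms remain
  Pw <- 0.3 + 0.2 * (0:7)
  sp <- nsetrait:::sigmaP2_cond_draw(Pw, nu0 = 0)
  expect_false(sp$guard)
  set.seed(24)
  draws <- replicate(20000L, nsetrait:::sigmaP2_cond_draw(Pw, nu0 = 0)$draw)
  ssum <- (Pw[1]^2 + Pw[2]^2) / 1000
  expect_equal(mean(draws), ssum / (8 - 2), tolerance = 0.05)
  # general weights: Inv-chi-square(nu0 + nb, .) mean = total scale / (df - 2)
  Pw2 <- c(0.5, -0.2, 0.9, 0.1, 0, 0.4, -0.3, 0.2)
  d2 <- diff(Pw2, differences = 2)
  tot <- 1 * 0.01 + sum(d2^2) + (Pw2[1]^2 + Pw2[2]^2) / 1000
  draws2 <- replicate(20000L,
                      nsetrait:::sigmaP2_cond_draw(Pw2, nu0 = 1,
                                                   s02 = 0.01)$draw)
  expect_equal(mean(draws2), tot / (9 - 2), tolerance = 0.05)
  # degenerate statistics under the improper limit trigger the guard
  expect_true(nsetrait:::sigmaP2_cond_draw(rep(0, 8), nu0 = 0)$guard)
  expect_false(nsetrait:::sigmaP2_cond_draw(rep(0, 8))$guard)
})

test_that("identical seeds give bit-identical chains, different seeds differ", {
  d <- tiny_data(n = 12, seed = 31)
  f1 <- nse(d, "nse", n_iter = 600, burn_in = 100, thin = 5, seed = 99)
  f2 <- nse(d, "nse", n_iter = 600, burn_in = 100, thin = 5, seed = 99)
  expect_identical(f1$samples, f2$samples)
  f3 <- nse(d, "nse", n_iter = 600, burn_in = 100, thin = 5, seed = 100)
  expect_false(identical(f1$samples$G, f3$samples$G))
})

test_that("chain settings are validated and rank deficiency is reported", {
  d <- tiny_data(n = 12, seed = 32)
  expect_error(nse(d, n_iter = 100, burn_in = 100), "burn_in")
  expect_error(nse(d, n_iter = 100, burn_in = 10, thin = 0), "thin")
  expect_error(nse(d, n_iter = 100, burn_in = 10, sigma_prop2 = 0),
               "sigma_prop2")
  d2 <- d
  d2$X_P <- cbind(d$X_P, dup = d$X_P[, 2])
  expect_error(nse(d2, n_iter = 100, burn_in = 10), "rank deficient.*dup")
})

test_that("successive-conditional sampling preserves the (u, G) joint law", {
  # Geweke-style check on a tiny instance: forward draws from
  # G ~ IW(4, S0), u | G ~ N(0, G x K), y | u ~ N(u, R x I) must match the
  # stationary law of the Gibbs kernel that alternates u | y, G and G | u,
  # with y resimulated between sweeps. IW(4, .) has no finite variance, so
  # medians are compared.
  set.seed(25)
  n <- 8L
  X <- matrix(sample(c(-1, 1), n * 30, replace = TRUE), n)
  K <- regularize_kinship(grm(X, quiet = TRUE))
  ek <- eigen(K, symmetric = TRUE)
  Q <- ek$vectors; lam <- pmax(ek$values, 1e-10)
  S0 <- matrix(c(1, 0.2, 0.2, 1.5), 2)
  R <- matrix(c(0.8, 0.1, 0.1, 1.2), 2)
  LK <- t(chol(K))
  n_mc <- 4000L

  fwd_G11 <- numeric(n_mc); fwd_u <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    G <- nsetrait:::riwish(4L, S0)
    U <- LK %*% matrix(rnorm(2 * n), n) %*% chol(G)
    fwd_G11[i] <- G[1, 1]; fwd_u[i] <- abs(U[1, 1])
  }

  bwd_G11 <- numeric(n_mc); bwd_u <- numeric(n_mc)
  G <- nsetrait:::riwish(4L, S0)
  U <- LK %*% matrix(rnorm(2 * n), n) %*% chol(G)
  LR <- t(chol(R))
  for (i in seq_len(n_mc)) {
    Y <- U + t(LR %*% matrix(rnorm(2 * n), 2))          # resimulate data
    um <- nsetrait:::u_cond_moments(drop(crossprod(Q, Y[, 1])),
                                    drop(crossprod(Q, Y[, 2])), lam, G, R)
    z1 <- rnorm(n); z2 <- rnorm(n)
    utP <- um$m1 + um$l11 * z1
    utA <- um$m2 + um$l21 * z1 + um$l22 * z2
    U <- cbind(drop(Q %*% utP), drop(Q %*% utA))
    G <- nsetrait:::g_cond_draw(utP, utA, lam, S0)
    bwd_G11[i] <- G[1, 1]; bwd_u[i] <- abs(U[1, 1])
  }
  expect_equal(median(bwd_G11), median(fwd_G11), tolerance = 0.2)
  expect_equal(median(bwd_u), median(fwd_u), tolerance = 0.2)
})
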