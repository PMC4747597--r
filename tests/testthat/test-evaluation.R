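# Minimal hand-built fit objects let the summary functions be tested without
# running chains.
fake_fit <- function(P = NULL, beta_P, beta_A, u_P, u_A, kv, y_P,
                     R = NULL, model = if (is.null(P)) "olm" else "nse") {
  n <- length(y_P)
  S <- nrow(beta_P)
  ids <- sprintf("F%02d", seq_len(n))
  colnames(u_A) <- ids
  structure(list(
    model = model, kv = kv, M = 7L,
    samples = list(P = P, beta_P = beta_P, beta_A = beta_A,
                   u_P = u_P, u_A = u_A,
                   R = if (is.null(R)) matrix(1, S, 3,
                                              dimnames = list(NULL, c("R11", "R12", "R22")))
                   else R),
    data = list(y_P = y_P, line_ids = ids, n = n,
                X_P = matrix(1, n, 1, dimnames = list(ids, "intercept")),
                X_A = matrix(1, n, 1, dimnames = list(ids, "intercept")),
                means = c(mean_P = 0, mean_A = 0)),
    n_draws = S), class = "nse_fit")
}

test_that("WAIC matches a direct unstabilized reference and hand example", {
  ll <- rbind(c(-1.0, -2.0), c(-1.5, -2.5))   # 2 draws x 2 lines
  w <- waic(ll)
  # independent route: plain log of the mean of exponentials, apply-based
  lppd_ref <- sum(apply(ll, 2, function(x) log(mean(exp(x)))))
  p_ref <- sum(apply(ll, 2, var))
  expect_equal(w$lppd, lppd_ref, tolerance = 1e-12)
  expect_equal(w$p_waic, p_ref, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd_ref - p_ref), tolerance = 1e-12)
  expect_equal(w$mean_loglik, mean(rowSums(ll)))
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic))
})

test_that("WAIC limiting and equivariance properties hold", {
  ll1 <- matrix(rep(c(-1.3, -0.7), each = 3), 3)   # identical draws
  w1 <- waic(ll1)
  expect_equal(w1$p_waic, 0)
  expect_equal(w1$waic, -2 * sum(ll1[1, ]))
  # adding a constant shifts lppd by n*c and leaves p_waic alone
  set.seed(40)
  ll <- matrix(rnorm(50 * 4, -2), 50)
  w <- waic(ll); wc <- waic(ll + 3)
  expect_equal(wc$lppd, w$lppd + 4 * 3, tolerance = 1e-10)
  expect_equal(wc$p_waic, w$p_waic, tolerance = 1e-10)
  expect_error(waic(ll[1, , drop = FALSE]), "at least 2 draws")
})

test_that("delta WAIC is zero for identical fits and tracks predictive gain", {
  set.seed(41)
  ll <- matrix(rnorm(100 * 6, -2), 100)
  expect_equal(delta_waic(waic(ll), waic(ll)), 0)
  # uniformly higher log-likelihood with equal variance favors the first fit
  expect_lt(delta_waic(waic(ll + 0.5), waic(ll)), 0)
  w1 <- waic(rbind(c(-1.0, -2.0), c(-1.5, -2.5)))
  w2 <- waic(rbind(c(-1.2, -2.2), c(-1.9, -2.9)))
  expect_equal(delta_waic(w1, w2), w1$waic - w2$waic)
})

test_that("trajectory summarizes draws pointwise with type-7 quantiles", {
  kv <- build_knots(-2, 2)
  y_P <- seq(-2, 2, length.out = 9)
  S <- 50L
  # all draws constant c: flat mean, zero-width band
  f1 <- fake_fit(P = matrix(0.8, S, 8), beta_P = matrix(0, S, 1),
                 beta_A = matrix(0, S, 1), u_P = matrix(0, S, 9),
                 u_A = matrix(0, S, 9), kv = kv, y_P = y_P)
  tr <- trajectory(f1, grid_size = 21)
  expect_equal(tr$mean_L, rep(0.8, 21))
  expect_equal(tr$q025_L, tr$q975_L)
  # two alternating draws 0 and 2: mean 1, band = type-7 quantiles of c(0,2)
  P2 <- matrix(rep(rep(c(0, 2), 25), 8), 50, 8)
  f2 <- fake_fit(P = P2, beta_P = matrix(0, 50, 1), beta_A = matrix(0, 50, 1),
                 u_P = matrix(0, 50, 9), u_A = matrix(0, 50, 9),
                 kv = kv, y_P = y_P)
  tr2 <- trajectory(f2, grid_size = 11)
  expect_equal(tr2$mean_L, rep(1, 11))
  qs <- quantile(rep(c(0, 2), 25), c(0.025, 0.975), names = FALSE)
  expect_equal(unique(round(tr2$q025_L, 12)), qs[1])
  expect_equal(unique(round(tr2$q975_L, 12)), qs[2])
  # band always brackets the mean
  expect_true(all(tr2$q025_L <= tr2$mean_L & tr2$mean_L <= tr2$q975_L))
  expect_error(trajectory(f2, range = c(-10, 10)), "knot range")
  f_olm <- fake_fit(P = NULL, beta_P = matrix(0, 50, 1),
                    beta_A = matrix(0, 50, 1), u_P = matrix(0, 50, 9),
                    u_A = matrix(0, 50, 9), kv = kv, y_P = y_P)
  expect_error(trajectory(f_olm), "NSE")
})

test_that("significance calls follow the 95% quantile rule", {
  set.seed(42)
  expect_true(significance_call(runif(100, 1, 2))$significant)
  expect_false(significance_call(c(rnorm(500), -rnorm(500)))$significant)
  s1 <- significance_call(rnorm(1000, 3, 1))
  expect_true(s1$significant)
  expect_equal(s1$mean_x2, 2 * s1$mean)
  expect_false(significance_call(rnorm(1000, 0.5, 1))$significant)
  # invariant to permutation of draws
  x <- rnorm(200, 1.5)
  expect_identical(significance_call(x), significance_call(sample(x)))
  expect_error(significance_call(rnorm(10)), "at least 40")
})

test_that("identifiability diagnostic is the weight/R12 chain correlation", {
  kv <- build_knots(-2, 2)
  set.seed(43)
  S <- 400L
  r12 <- rnorm(S)
  P <- matrix(rnorm(S * 8), S)
  P[, 1] <- r12                        # perfectly coupled
  P[, 2] <- -r12
  R <- cbind(R11 = rep(1, S), R12 = r12, R22 = rep(1, S))
  f <- fake_fit(P = P, beta_P = matrix(0, S, 1), beta_A = matrix(0, S, 1),
                u_P = matrix(0, S, 9), u_A = matrix(0, S, 9), kv = kv,
                y_P = seq(-2, 2, length.out = 9), R = R)
  id <- identifiability(f)
  expect_equal(unname(id$per_weight[1]), 1)
  expect_equal(unname(id$per_weight[2]), -1)
  expect_true(all(abs(id$per_weight[3:8]) < 3 / sqrt(S)))
})

test_that("recovery metrics are exact at truth and sign-flip at -truth", {
  kv <- build_knots(-2, 2)
  n <- 9L; S <- 60L
  y_P <- seq(-2, 2, length.out = n)
  P_true <- c(1.2, 1.0, 0.7, 0.4, 0.2, 0, -0.2, -0.3)
  L_true <- influence_eval(kv, P_true, y_P)
  u_true <- rnorm(n)
  truth <- list(L = L_true, u_A = u_true,
                beta_A = c(intercept = 0, g1 = 1, g2 = -2, g3 = 0.5))
  mk <- function(sgn) {
    bA <- matrix(rep(sgn * c(0, 1, -2, 0.5), each = S), S)
    colnames(bA) <- c("intercept", "g1", "g2", "g3")
    f <- fake_fit(P = matrix(rep(sgn * P_true, each = S), S),
                  beta_P = matrix(0, S, 1), beta_A = bA,
                  u_P = matrix(0, S, n),
                  u_A = matrix(rep(sgn * u_true, each = S), S),
                  kv = kv, y_P = y_P)
    f
  }
  r1 <- recovery_metrics(truth, mk(1))
  expect_equal(unname(r1), c(1, 1, 1), tolerance = 1e-12)
  r2 <- recovery_metrics(truth, mk(-1))
  expect_equal(unname(r2), c(-1, -1, -1), tolerance = 1e-12)
  # noise of matched variance attenuates the correlation towards 1/sqrt(2)
  set.seed(44)
  reps <- replicate(200, {
    est <- u_true + rnorm(n, 0, sd(u_true) * sqrt((n - 1) / n))
    cor(u_true, est)
  })
  expect_equal(mean(reps), 1 / sqrt(2), tolerance = 0.1)
})

test_that("counterfactual prediction handles empty and named edits", {
  kv <- build_knots(-2, 2)
  n <- 9L; S <- 80L
  y_P <- seq(-2, 2, length.out = n)
  set.seed(45)
  bP <- cbind(intercept = rnorm(S, 0, 0.01), gP = rnorm(S, -1.5, 0.01))
  bA <- cbind(intercept = rnorm(S, 0, 0.01), gP = rnorm(S, 2, 0.01))
  f <- fake_fit(P = matrix(0.5, S, 8), beta_P = bP, beta_A = bA,
                u_P = matrix(0, S, n), u_A = matrix(0.3, S, n),
                kv = kv, y_P = y_P)
  f$data$X_P <- cbind(intercept = 1, gP = rep(c(0, 1), length.out = n))
  f$data$X_A <- cbind(intercept = 1, gP = rep(c(0, 1), length.out = n))
  rownames(f$data$X_P) <- rownames(f$data$X_A) <- f$data$line_ids
  # empty edit: no phenology shift, deviation equals the fitted mean parts
  pe <- predict_edit(f, 1L)
  expect_equal(unname(pe$delta_P["mean"]), 0)
  expect_equal(unname(pe$A_dev["mean"]),
               0.5 * y_P[1] + mean(bA[, 1]) + 0.3, tolerance = 1e-6)
  # removing the allele of a carrier line shifts phenology by -beta
  pe2 <- predict_edit(f, 2L, edits = c(gP = -1))
  expect_equal(unname(pe2$delta_P["mean"]), 1.5, tolerance = 0.01)
  expect_error(predict_edit(f, 2L, edits = c(nope = 1)), "not in either")
  expect_error(predict_edit(f, "missing-line"), "unknown line")
  # OLM: influence is identically zero, deviation ignores the phenology shift
  f_olm <- f; f_olm$samples$P <- NULL; f_olm$model <- "olm"
  pe3 <- predict_edit(f_olm, 2L, edits = c(gP = -1))
  expect_equal(unname(pe3$L_new["mean"]), 0)
  expect_equal(unname(pe3$A_dev["mean"]),
               mean(bA[, 1]) + 0.3, tolerance = 1e-6)
})
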