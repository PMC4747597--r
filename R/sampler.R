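# Draw from an inverse-Wishart(df, S): if X ~ Wishart(df, S^-1) then
# X^-1 ~ IW(df, S), with E[IW] = S / (df - p - 1).
riwish <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  V <- solve(W)
  (V + t(V)) / 2
}

# Joint log prior density of the spline weights given the smoothness
# variance: P0, P1 ~ N(0, 1000 s2); Pm | Pm-1, Pm-2 ~ N(2Pm-1 - Pm-2, s2).
log_prior_weights <- function(Pw, s2) {
  nb <- length(Pw)
  sum(stats::dnorm(Pw[1:2], 0, sqrt(1000 * s2), log = TRUE)) +
    sum(stats::dnorm(Pw[3:nb], 2 * Pw[2:(nb - 1L)] - Pw[1:(nb - 2L)],
                     sqrt(s2), log = TRUE))
}

solve2 <- function(M) {
  det <- M[1, 1] * M[2, 2] - M[1, 2]^2
  matrix(c(M[2, 2], -M[1, 2], -M[1, 2], M[1, 1]), 2) / det
}

check_design_rank <- function(X, trait) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("design for trait ", trait, " is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Full-conditional moments of the fixed effects of one trait: flat prior,
# conditioning trait-on-trait through the bivariate residual. w is the
# working response with the other trait's residual regressed out; the
# conditional residual variance s2c is homoscedastic, so the mean is the OLS
# solution on w.
beta_cond_moments <- function(X, XtXi, y_self, u_self, e_other,
                              r_self, r_other, r12) {
  w <- y_self - u_self - (r12 / r_other) * e_other
  list(mean = drop(XtXi %*% crossprod(X, w)),
       s2c = r_self - r12^2 / r_other)
}

# Full-conditional moments of the polygenic pair in the eigenbasis of K:
# for eigenvalue lam_j the prior is N(0, lam_j G) and the data term has
# residual covariance R, giving 2x2 precision R^-1 + G^-1 / lam_j per j.
# Returns vectorized means and lower-Cholesky elements of the conditional
# covariance.
u_cond_moments <- function(dtP, dtA, lam, Gm, Rm) {
  Rinv <- solve2(Rm); Ginv <- solve2(Gm)
  a <- Rinv[1, 1] + Ginv[1, 1] / lam
  b <- Rinv[1, 2] + Ginv[1, 2] / lam
  cc <- Rinv[2, 2] + Ginv[2, 2] / lam
  det <- a * cc - b^2
  S11 <- cc / det; S12 <- -b / det; S22 <- a / det
  h1 <- Rinv[1, 1] * dtP + Rinv[1, 2] * dtA
  h2 <- Rinv[1, 2] * dtP + Rinv[2, 2] * dtA
  l11 <- sqrt(S11)
  l21 <- S12 / l11
  l22 <- sqrt(pmax(S22 - l21^2, 0))
  list(m1 = S11 * h1 + S12 * h2,
       m2 = S12 * h1 + S22 * h2,
       l11 = l11, l21 = l21, l22 = l22)
}

# Conditional draw of the genetic covariance: IW(4 + n, S0 + U' K^-1 U),
# with U' K^-1 U computed in the eigenbasis.
g_cond_draw <- function(utP, utA, lam, S0) {
  n <- length(utP)
  s12 <- sum(utP * utA / lam)
  SG <- S0 + matrix(c(sum(utP^2 / lam), s12, s12, sum(utA^2 / lam)), 2)
  riwish(4L + n, SG)
}

# Conditional draw of the residual covariance: IW(4 + n, S0 + E'E); under the
# zero-covariance constraint the two variances come from independent scaled
# inverse-chi-square conditionals with the same degrees of freedom.
r_cond_draw <- function(eP, eA, S0, zero_rescov = FALSE) {
  n <- length(eP)
  if (zero_rescov) {
    return(diag(c((S0[1, 1] + sum(eP^2)) / stats::rchisq(1L, 4L + n),
                  (S0[2, 2] + sum(eA^2)) / stats::rchisq(1L, 4L + n))))
  }
  sPA <- sum(eP * eA)
  SR <- S0 + matrix(c(sum(eP^2), sPA, sPA, sum(eA^2)), 2)
  riwish(4L + n, SR)
}

# Log Metropolis ratio for weight m -> prop: prior ratio (every prior term in
# which P_m appears, obtained as the full joint prior difference) plus the
# likelihood ratio over the lines in the support of basis m only. eP is
# unchanged by the move, so the bivariate ratio reduces to the conditional
# density of e_A given e_P.
mh_weight_logratio <- function(m, prop, Pw, eA, mu_c, sd_c, Phi_y, idx, s2P) {
  delta <- prop - Pw[m]
  eA_new <- eA[idx] - delta * Phi_y[idx, m]
  llr <- sum(stats::dnorm(eA_new, mu_c[idx], sd_c, log = TRUE)) -
    sum(stats::dnorm(eA[idx], mu_c[idx], sd_c, log = TRUE))
  Pnew <- Pw; Pnew[m] <- prop
  lpr <- log_prior_weights(Pnew, s2P) - log_prior_weights(Pw, s2P)
  list(logratio = llr + lpr, eA_new = eA_new)
}

# Conditional draw of the smoothness variance under a scaled-inv-chi-square
# (nu0, s02) prior and nb Gaussian terms (nb - 2 second differences with
# variance s2, two boundary terms with variance 1000 s2):
# Inv-chi-square(nu0 + nb, (nu0 s02 + ssum) / (nu0 + nb)). nu0 = 0 is the
# p(s2) ~ 1/s2 limit, which makes the joint posterior improper (the marginal
# weight prior diverges at P = 0); the default is a proper weakly informative
# choice on the curvature scale of the influence function. Degenerate all-zero
# statistics under nu0 = 0 fall back to a floor scale.
sigmaP2_cond_draw <- function(Pw, nu0 = 1, s02 = 1e-4, floor = 1e-8) {
  nb <- length(Pw)
  d2 <- diff(Pw, differences = 2L)
  ssum <- nu0 * s02 + sum(d2^2) + (Pw[1L]^2 + Pw[2L]^2) / 1000
  guard <- ssum < 1e-12
  if (guard) ssum <- floor
  list(draw = ssum / stats::rchisq(1L, df = nu0 + nb), guard = guard)
}

#' Fit the nonlinear structural equation or the bi-trait linear model
#'
#' Metropolis-within-Gibbs sampler for the recursive bivariate model
#' \deqn{y_P = X_P \beta_P + u_P + e_P, \quad
#'       y_A = L(y_P)\,y_P + X_A \beta_A + u_A + e_A,}
#' where \eqn{L} is a cubic B-spline with \code{M + 1} weights (the NSE), a
#' zero function (the OLM), and \eqn{(u_P, u_A) \sim N(0, G \otimes K)},
#' \eqn{(e_P, e_A) \sim N(0, R \otimes I)}. Priors: flat on fixed effects;
#' inverse-Wishart with 4 degrees of freedom and scale half the phenotypic
#' covariance matrix on both \eqn{G} and \eqn{R} (so the prior mean equals the
#' scale); a second-order random-walk prior on the spline weights with
#' smoothness variance \eqn{\sigma_P^2} carrying a weakly informative
#' scaled-inverse-chi-square prior (see \code{sigmaP2_prior}). Fixed effects,
#' polygenic
#' effects and the covariance matrices are updated by Gibbs draws from their
#' full conditionals (trait A entering through the influence-adjusted working
#' response \eqn{y_A - L(y_P) y_P}, which is refreshed after every accepted
#' weight move); each spline weight is updated by a random-walk Metropolis
#' step whose likelihood ratio is evaluated only over lines inside the support
#' of the corresponding basis function.
#'
#' @param data an \code{nse_data} object from \code{\link{bivariate_data}}.
#' @param model \code{"nse"}, \code{"olm"}, or \code{"nse-zero-rescov"} (the
#'   NSE with the residual covariance constrained to zero, the identifiability
#'   constraint for constant influences).
#' @param M highest spline basis index (\code{M + 1} basis functions).
#' @param n_iter,burn_in,thin chain length, burn-in, and sampling interval.
#'   The defaults are the full-scale settings (1.1e6 / 1e5 / 100); reduced
#'   values (e.g. 5e4 / 5e3 / 10) are appropriate for desk-scale runs.
#' @param sigma_prop2 Metropolis proposal variance for the spline weights.
#' @param sigmaP2_prior length-2 numeric \code{c(nu, scale)}: degrees of
#'   freedom and scale of the scaled-inverse-chi-square prior on the
#'   smoothness variance \eqn{\sigma_P^2}. The default (1, 1e-4) is a proper,
#'   weakly informative prior whose scale sits well below the curvature of a
#'   plausible influence trajectory, so it smooths only in the absence of
#'   signal; \code{nu = 0} gives the improper \eqn{1/\sigma_P^2} limit,
#'   under which the posterior degenerates at \eqn{P = 0} (not recommended).
#' @param seed integer seed; identical seeds give bit-identical chains.
#' @param knots optional \code{knot_vector} overriding the per-dataset knot
#'   rule (knots built from the observed range of the centered \code{y_P}).
#' @param verbose print progress every \code{log_every} iterations.
#' @param log_every progress-logging interval.
#' @return an object of class \code{nse_fit}; see Details. The \code{samples}
#'   element holds the thinned post-burn-in draws of every parameter block
#'   plus total and per-line log-likelihoods; \code{accept} holds per-weight
#'   Metropolis acceptance rates.
#' @details The returned object contains \code{model}, \code{kv} (knot
#'   vector), \code{samples} (matrices with one row per retained draw),
#'   \code{accept}, \code{config}, \code{prior} (scale matrix), \code{data},
#'   and \code{n_draws}. Initialization: \eqn{\beta = 0}, \eqn{u = 0},
#'   \eqn{G = R =} prior scale, \eqn{P = 0}, \eqn{\sigma_P^2 = 1}. Update
#'   order per iteration: \eqn{\beta_P, \beta_A, u, G, R}, then the weights
#'   \eqn{P_0 \ldots P_M} in index order and \eqn{\sigma_P^2}.
#' @export
nse <- function(data, model = c("nse", "olm", "nse-zero-rescov"),
                M = 7L, n_iter = 1.1e6, burn_in = 1e5, thin = 100L,
                sigma_prop2 = 0.04, sigmaP2_prior = c(1, 1e-4),
                seed = 1L, knots = NULL,
                verbose = FALSE, log_every = 10000L) {
  stopifnot(inherits(data, "nse_data"))
  model <- match.arg(model)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  if (sigma_prop2 <= 0) stop("sigma_prop2 must be positive")
  is_nse <- model != "olm"
  zero_rescov <- model == "nse-zero-rescov"

  yP <- data$y_P; yA <- data$y_A
  XP <- data$X_P; XA <- data$X_A
  n <- data$n
  pP <- ncol(XP); pA <- ncol(XA)
  check_design_rank(XP, "P"); check_design_rank(XA, "A")

  S0 <- 0.5 * stats::cov(cbind(yP, yA))
  dimnames(S0) <- list(c("P", "A"), c("P", "A"))

  kv <- if (is.null(knots)) build_knots(min(yP), max(yP), M) else knots
  nb <- kv$n_basis
  Phi <- spline_basis(kv, yP)
  Phi_y <- Phi * yP
  supp <- lapply(seq_len(nb), function(m) which(Phi[, m] > 0))

  ek <- eigen(data$K, symmetric = TRUE)
  Q <- ek$vectors
  lam <- pmax(ek$values, 1e-10)

  XPtXPi <- solve(crossprod(XP))
  XAtXAi <- solve(crossprod(XA))
  cholP <- t(chol(XPtXPi))
  cholA <- t(chol(XAtXAi))

  # initial state
  betaP <- numeric(pP); betaA <- numeric(pA)
  uP <- uA <- numeric(n)
  Gm <- S0; Rm <- S0
  Pw <- numeric(nb); s2P <- 1
  LyP <- numeric(n)
  yAw <- yA
  acc <- integer(nb)
  acc_shift <- 0L
  guard_hits <- 0L

  n_draws <- floor((n_iter - burn_in) / thin)
  if (n_draws < 1L) stop("chain settings leave no retained draws")
  sm <- list(
    beta_P = matrix(NA_real_, n_draws, pP, dimnames = list(NULL, colnames(XP))),
    beta_A = matrix(NA_real_, n_draws, pA, dimnames = list(NULL, colnames(XA))),
    u_P = matrix(NA_real_, n_draws, n, dimnames = list(NULL, data$line_ids)),
    u_A = matrix(NA_real_, n_draws, n, dimnames = list(NULL, data$line_ids)),
    G = matrix(NA_real_, n_draws, 3L, dimnames = list(NULL, c("G11", "G12", "G22"))),
    R = matrix(NA_real_, n_draws, 3L, dimnames = list(NULL, c("R11", "R12", "R22"))),
    P = if (is_nse) matrix(NA_real_, n_draws, nb,
                           dimnames = list(NULL, paste0("P", 0:(nb - 1L)))) else NULL,
    sigma_P2 = if (is_nse) numeric(n_draws) else NULL,
    loglik = numeric(n_draws),
    ll_lines = matrix(NA_real_, n_draws, n, dimnames = list(NULL, data$line_ids))
  )

  set.seed(as.integer(seed))
  s <- 0L
  for (it in seq_len(n_iter)) {
    ## fixed effects, trait P (condition on trait A's residual)
    eA <- yAw - drop(XA %*% betaA) - uA
    bm <- beta_cond_moments(XP, XPtXPi, yP, uP, eA,
                            Rm[1, 1], Rm[2, 2], Rm[1, 2])
    betaP <- bm$mean + sqrt(bm$s2c) * drop(cholP %*% stats::rnorm(pP))

    ## fixed effects, trait A
    eP <- yP - drop(XP %*% betaP) - uP
    bm <- beta_cond_moments(XA, XAtXAi, yAw, uA, eP,
                            Rm[2, 2], Rm[1, 1], Rm[1, 2])
    betaA <- bm$mean + sqrt(bm$s2c) * drop(cholA %*% stats::rnorm(pA))

    ## polygenic effects: joint 2n conditional in the eigenbasis of K
    dP <- yP - drop(XP %*% betaP)
    dA <- yAw - drop(XA %*% betaA)
    dt <- crossprod(Q, cbind(dP, dA))
    um <- u_cond_moments(dt[, 1L], dt[, 2L], lam, Gm, Rm)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    utP <- um$m1 + um$l11 * z1
    utA <- um$m2 + um$l21 * z1 + um$l22 * z2
    uu <- Q %*% cbind(utP, utA)
    uP <- uu[, 1L]; uA <- uu[, 2L]

    ## covariance matrices
    Gm <- g_cond_draw(utP, utA, lam, S0)
    eP <- dP - uP
    eA <- dA - uA
    Rm <- r_cond_draw(eP, eA, S0, zero_rescov)

    ## spline weights (Metropolis, local-support likelihood) and sigma_P2
    if (is_nse) {
      mu_c <- (Rm[1, 2] / Rm[1, 1]) * eP
      sd_c <- sqrt(Rm[2, 2] - Rm[1, 2]^2 / Rm[1, 1])
      for (m in seq_len(nb)) {
        prop <- Pw[m] + sqrt(sigma_prop2) * stats::rnorm(1L)
        idx <- supp[[m]]
        mh <- mh_weight_logratio(m, prop, Pw, eA, mu_c, sd_c, Phi_y, idx, s2P)
        if (log(stats::runif(1L)) < mh$logratio) {
          LyP[idx] <- LyP[idx] + (prop - Pw[m]) * Phi_y[idx, m]
          Pw[m] <- prop
          eA[idx] <- mh$eA_new
          acc[m] <- acc[m] + 1L
        }
      }
      # joint level-shift move: propose P + delta * 1, which by partition of
      # unity shifts L by delta at every line. The level of L is only weakly
      # identified (a constant influence trades off against the residual
      # covariance), so per-weight moves diffuse along this direction very
      # slowly; the joint move mixes it directly while leaving the target
      # posterior untouched (plain Metropolis with a symmetric proposal).
      delta <- sqrt(sigma_prop2) * stats::rnorm(1L)
      eA_new <- eA - delta * yP
      llr <- sum(stats::dnorm(eA_new, mu_c, sd_c, log = TRUE)) -
        sum(stats::dnorm(eA, mu_c, sd_c, log = TRUE))
      lpr <- log_prior_weights(Pw + delta, s2P) -
        log_prior_weights(Pw, s2P)
      if (log(stats::runif(1L)) < llr + lpr) {
        Pw <- Pw + delta
        LyP <- LyP + delta * yP
        eA <- eA_new
        acc_shift <- acc_shift + 1L
      }
      yAw <- yA - LyP

      sp <- sigmaP2_cond_draw(Pw, sigmaP2_prior[1L], sigmaP2_prior[2L])
      s2P <- sp$draw
      if (sp$guard) guard_hits <- guard_hits + 1L
    }

    if (!all(is.finite(c(betaP, betaA, Gm, Rm, Pw, s2P))))
      stop("non-finite state at iteration ", it, "; G = ",
           paste(format(Gm), collapse = " "), ", R = ",
           paste(format(Rm), collapse = " "))

    if (it > burn_in && (it - burn_in) %% thin == 0 && s < n_draws) {
      s <- s + 1L
      sm$beta_P[s, ] <- betaP
      sm$beta_A[s, ] <- betaA
      sm$u_P[s, ] <- uP
      sm$u_A[s, ] <- uA
      sm$G[s, ] <- Gm[c(1L, 2L, 4L)]
      sm$R[s, ] <- Rm[c(1L, 2L, 4L)]
      if (is_nse) {
        sm$P[s, ] <- Pw
        sm$sigma_P2[s] <- s2P
      }
      ll <- dbvn_log(eP, eA, Rm)
      sm$ll_lines[s, ] <- ll
      sm$loglik[s] <- sum(ll)
    }

    if (verbose && it %% log_every == 0L)
      message(sprintf("iter %d | loglik %.2f | mean accept %.2f", it,
                      sum(dbvn_log(eP, eA, Rm)),
                      if (is_nse) mean(acc) / it else NA_real_))
  }

  structure(list(
    model = model, kv = kv, M = kv$n_basis - 1L,
    samples = sm,
    accept = if (is_nse) stats::setNames(acc / n_iter,
                                         paste0("P", 0:(nb - 1L))) else NULL,
    accept_shift = if (is_nse) acc_shift / n_iter else NULL,
    config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                  sigma_prop2 = sigma_prop2,
                  sigmaP2_prior = sigmaP2_prior, seed = as.integer(seed)),
    prior = list(df = 4L, scale = S0),
    data = data,
    n_draws = n_draws,
    sigmaP2_guard_hits = guard_hits
  ), class = "nse_fit")
}
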