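#' Widely applicable information criterion
#'
#' Computes WAIC from stored per-line log-likelihood draws using the variance
#' form of the effective number of parameters:
#' \deqn{lppd = \sum_i \log \frac{1}{S}\sum_s \exp \ell_{is}, \quad
#'       p_{waic} = \sum_i \mathrm{Var}_s(\ell_{is}), \quad
#'       WAIC = -2 (lppd - p_{waic}).}
#' The log-mean-exp is computed with max-shift stabilization. Lower WAIC
#' indicates greater predictive ability.
#'
#' @param x an \code{nse_fit}, or a draws-by-lines matrix of per-line
#'   log-likelihoods.
#' @return object of class \code{nse_waic}: list with \code{mean_loglik}
#'   (posterior mean of the total log-likelihood), \code{lppd},
#'   \code{p_waic}, \code{waic}, and per-line \code{pointwise} contributions.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "nse_fit")) x$samples$ll_lines else as.matrix(x)
  if (nrow(ll) < 2L) stop("need at least 2 draws to compute WAIC")
  mx <- apply(ll, 2L, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2L, mx))))
  p_i <- apply(ll, 2L, stats::var)
  structure(list(
    mean_loglik = mean(rowSums(ll)),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    waic = -2 * (sum(lppd_i) - sum(p_i)),
    pointwise = data.frame(lppd = lppd_i, p_waic = p_i)
  ), class = "nse_waic")
}

#' @export
print.nse_waic <- function(x, ...) {
  cat(sprintf("mean log-likelihood %.2f | lppd %.2f | p_waic %.2f | WAIC %.2f\n",
              x$mean_loglik, x$lppd, x$p_waic, x$waic))
  invisible(x)
}

#' Delta WAIC between the NSE and the OLM
#'
#' Returns \code{WAIC(NSE) - WAIC(OLM)}; negative values favor the nonlinear
#' structural equation (the NSE value subtracted from the linear model's is
#' how the comparison is conventionally tabulated).
#'
#' @param fit_nse,fit_olm \code{nse_fit} or \code{nse_waic} objects for the
#'   two models fitted to the same dataset.
#' @return scalar delta WAIC.
#' @export
delta_waic <- function(fit_nse, fit_olm) {
  w1 <- if (inherits(fit_nse, "nse_waic")) fit_nse else waic(fit_nse)
  w2 <- if (inherits(fit_olm, "nse_waic")) fit_olm else waic(fit_olm)
  w1$waic - w2$waic
}

#' Posterior trajectory of the influence function
#'
#' Evaluates \eqn{L(y)} for every retained draw on a uniform grid over the
#' observed range of the phenological trait and summarizes it pointwise by
#' the posterior mean and the empirical 2.5\% and 97.5\% quantiles (type-7
#' linear interpolation).
#'
#' @param fit an NSE \code{nse_fit}.
#' @param grid_size number of grid points.
#' @param range optional numeric length-2 evaluation range; must lie within
#'   the knot range. Defaults to the observed range of \code{y_P}.
#' @return data.frame with columns \code{y}, \code{mean_L}, \code{q025_L},
#'   \code{q975_L}.
#' @export
trajectory <- function(fit, grid_size = 100L, range = NULL) {
  stopifnot(inherits(fit, "nse_fit"))
  if (is.null(fit$samples$P)) stop("trajectory requires an NSE fit")
  if (is.null(range)) range <- base::range(fit$data$y_P)
  kr <- base::range(fit$kv$knots)
  if (range[1] < kr[1] || range[2] > kr[2])
    stop("grid extends outside the knot range")
  grid <- seq(range[1], range[2], length.out = grid_size)
  Lg <- spline_basis(fit$kv, grid) %*% t(fit$samples$P)   # grid x draws
  data.frame(y = grid,
             mean_L = rowMeans(Lg),
             q025_L = apply(Lg, 1L, stats::quantile, probs = 0.025),
             q975_L = apply(Lg, 1L, stats::quantile, probs = 0.975))
}

#' Significance call from posterior draws
#'
#' An effect is called non-significant when zero lies within the 2.5\% and
#' 97.5\% posterior quantiles. The reported scale is twice the allele
#' substitution effect, so doubled quantiles are returned alongside.
#'
#' @param effect_draws numeric vector of posterior draws (at least 40).
#' @return list with \code{significant} (logical), \code{q025}, \code{q975},
#'   \code{mean}, and the doubled reporting-scale \code{mean_x2},
#'   \code{q025_x2}, \code{q975_x2}.
#' @export
significance_call <- function(effect_draws) {
  if (length(effect_draws) < 40L)
    stop("need at least 40 draws for a quantile-based significance call")
  q <- stats::quantile(effect_draws, c(0.025, 0.975), names = FALSE)
  list(significant = !(0 >= q[1] && 0 <= q[2]),
       q025 = q[1], q975 = q[2], mean = mean(effect_draws),
       mean_x2 = 2 * mean(effect_draws), q025_x2 = 2 * q[1], q975_x2 = 2 * q[2])
}

#' Major-gene effect table
#'
#' Posterior summary of every non-intercept fixed effect on both traits, on
#' the raw coefficient scale and on the reported scale (twice the allele
#' substitution effect), with the quantile-based significance flag.
#'
#' @param fit an \code{nse_fit}.
#' @return data.frame with one row per trait/term.
#' @export
gene_effects <- function(fit) {
  stopifnot(inherits(fit, "nse_fit"))
  one <- function(draws, trait, term) {
    s <- significance_call(draws)
    data.frame(trait = trait, term = term, mean = s$mean,
               q025 = s$q025, q975 = s$q975,
               mean_x2 = s$mean_x2, q025_x2 = s$q025_x2, q975_x2 = s$q975_x2,
               significant = s$significant)
  }
  rows <- list()
  for (blk in c("P", "A")) {
    B <- fit$samples[[paste0("beta_", blk)]]
    for (j in seq_len(ncol(B)))
      if (colnames(B)[j] != "intercept")
        rows[[length(rows) + 1L]] <- one(B[, j], blk, colnames(B)[j])
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Identifiability diagnostic
#'
#' Pearson correlation between each spline-weight chain and the residual
#' covariance chain. Strong negative correlations indicate that the influence
#' and the residual covariance are not separable (the failure mode of a
#' constant influence); weak correlations indicate identifiability.
#'
#' @param fit an NSE \code{nse_fit}.
#' @return list with \code{per_weight} (named numeric; \code{NA} for a
#'   constant chain), \code{mean} and \code{sd} across weights.
#' @export
identifiability <- function(fit) {
  stopifnot(inherits(fit, "nse_fit"))
  if (is.null(fit$samples$P)) stop("identifiability requires an NSE fit")
  r12 <- fit$samples$R[, "R12"]
  cors <- apply(fit$samples$P, 2L, function(p) {
    if (stats::sd(p) == 0 || stats::sd(r12) == 0) NA_real_
    else stats::cor(p, r12)
  })
  list(per_weight = cors, mean = mean(cors, na.rm = TRUE),
       sd = stats::sd(cors, na.rm = TRUE))
}

#' Counterfactual gene-edit prediction
#'
#' Predicts, per retained posterior draw, the consequence of editing a line's
#' major-gene genotype: the shift of the phenological trait
#' \eqn{\Delta y_P = \Delta x_P^\top \beta_P}, the influence at the shifted
#' phenology \eqn{L(y_P + \Delta y_P)} (clamped to the knot range, with the
#' clamped fraction reported, since the spline is undefined outside it), and
#' the influenced trait's deviation from the overall mean
#' \eqn{L(y_P')\,y_P' + x_A'^\top \beta_A + u_A}.
#'
#' @param fit an \code{nse_fit} (for an OLM fit \eqn{L \equiv 0}).
#' @param line line ID or index.
#' @param edits named numeric vector of changes to design columns (e.g.
#'   \code{c(Ghd7 = -1)} to revert a non-reference allele); names must match
#'   columns of at least one design matrix. An empty edit predicts the line
#'   as it stands.
#' @return list of posterior summaries (\code{mean}, \code{q025},
#'   \code{q975}) for \code{delta_P}, \code{L_new} and \code{A_dev} (deviation
#'   of the influenced trait from its overall mean, on the centered scale),
#'   plus \code{clamped_frac}.
#' @export
predict_edit <- function(fit, line, edits = NULL) {
  stopifnot(inherits(fit, "nse_fit"))
  d <- fit$data
  i <- if (is.character(line)) match(line, d$line_ids) else as.integer(line)
  if (is.na(i) || i < 1L || i > d$n) stop("unknown line: ", line)
  dxP <- numeric(ncol(d$X_P)); names(dxP) <- colnames(d$X_P)
  dxA <- numeric(ncol(d$X_A)); names(dxA) <- colnames(d$X_A)
  if (length(edits)) {
    if (is.null(names(edits))) stop("edits must be a named vector")
    for (nm in names(edits)) {
      hit <- FALSE
      if (nm %in% names(dxP)) { dxP[nm] <- edits[[nm]]; hit <- TRUE }
      if (nm %in% names(dxA)) { dxA[nm] <- edits[[nm]]; hit <- TRUE }
      if (!hit) stop("edit column not in either design: ", nm)
    }
  }
  S <- fit$n_draws
  dP <- drop(fit$samples$beta_P %*% dxP)
  yP_new <- d$y_P[i] + dP
  kr <- range(fit$kv$knots)
  clamped <- yP_new < kr[1] | yP_new > kr[2]
  yP_cl <- pmin(pmax(yP_new, kr[1]), kr[2])
  if (!is.null(fit$samples$P)) {
    Phi_new <- spline_basis(fit$kv, yP_cl)               # S x nb
    L_new <- rowSums(Phi_new * fit$samples$P)
  } else L_new <- numeric(S)
  xA_new <- d$X_A[i, ] + dxA
  A_dev <- L_new * yP_cl + drop(fit$samples$beta_A %*% xA_new) +
    fit$samples$u_A[, i]
  summ <- function(v) c(mean = mean(v),
                        q025 = unname(stats::quantile(v, 0.025)),
                        q975 = unname(stats::quantile(v, 0.975)))
  list(delta_P = summ(dP), L_new = summ(L_new), A_dev = summ(A_dev),
       clamped_frac = mean(clamped))
}

#' Recovery metrics against simulation truth
#'
#' Pearson correlations between true and posterior-mean values of the
#' per-line influence \eqn{L(y_{i,P})}, the per-line polygenic effect on the
#' influenced trait, and the influenced trait's major-gene coefficients.
#'
#' @param truth list with elements \code{L} (per-line true influence values),
#'   \code{u_A}, and \code{beta_A} (named, including the intercept, which is
#'   excluded from the correlation); typically the \code{"truth"} attribute
#'   of a simulated dataset.
#' @param fit an \code{nse_fit} for that dataset.
#' @return named numeric: \code{cor_L} (\code{NA} for an OLM fit or a
#'   zero-variance truth), \code{cor_uA}, \code{cor_betaA}.
#' @export
recovery_metrics <- function(truth, fit) {
  stopifnot(inherits(fit, "nse_fit"))
  safe_cor <- function(a, b) {
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }
  cor_L <- if (is.null(fit$samples$P)) NA_real_ else {
    L_hat <- drop(spline_basis(fit$kv, fit$data$y_P) %*% colMeans(fit$samples$P))
    safe_cor(truth$L, L_hat)
  }
  uA_hat <- colMeans(fit$samples$u_A)
  bA_hat <- colMeans(fit$samples$beta_A)
  keep <- colnames(fit$samples$beta_A) != "intercept"
  bA_true <- truth$beta_A[names(bA_hat)[keep]]
  c(cor_L = cor_L,
    cor_uA = safe_cor(truth$u_A, uA_hat),
    cor_betaA = safe_cor(unname(bA_true), unname(bA_hat[keep])))
}
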