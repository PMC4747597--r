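#' @export
print.nse_fit <- function(x, ...) {
  lab <- switch(x$model, nse = "Nonlinear structural equation",
                olm = "Ordinary bi-trait linear model",
                `nse-zero-rescov` = "NSE, residual covariance fixed at zero")
  cat(lab, "\n")
  cat(sprintf("  %d lines, %d retained draws (chain %g, burn-in %g, thin %d)\n",
              x$data$n, x$n_draws, x$config$n_iter, x$config$burn_in,
              x$config$thin))
  Gm <- colMeans(x$samples$G); Rm <- colMeans(x$samples$R)
  cat(sprintf("  posterior mean G: [%.2f, %.2f; %.2f, %.2f]\n",
              Gm[1], Gm[2], Gm[2], Gm[3]))
  cat(sprintf("  posterior mean R: [%.2f, %.2f; %.2f, %.2f]\n",
              Rm[1], Rm[2], Rm[2], Rm[3]))
  if (!is.null(x$accept))
    cat(sprintf("  weight acceptance rates: %.2f-%.2f\n",
                min(x$accept), max(x$accept)))
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object an \code{nse_fit}.
#' @param scale \code{"raw"} for the fitted allele-substitution coefficients,
#'   \code{"reported"} for twice the allele-substitution effects (the
#'   conventional reporting scale; intercepts are never doubled).
#' @param ... unused.
#' @return list with named numeric vectors \code{beta_P} and \code{beta_A}.
#' @export
coef.nse_fit <- function(object, scale = c("raw", "reported"), ...) {
  scale <- match.arg(scale)
  out <- lapply(c(P = "beta_P", A = "beta_A"), function(b) {
    est <- colMeans(object$samples[[b]])
    if (scale == "reported") {
      dbl <- names(est) != "intercept"
      est[dbl] <- 2 * est[dbl]
    }
    est
  })
  names(out) <- c("beta_P", "beta_A")
  out
}

#' Posterior-mean fitted values
#'
#' Mean structure per line on the centered scale:
#' \eqn{\hat y_P = X_P \bar\beta_P + \bar u_P} and
#' \eqn{\hat y_A = \bar{L(y_P) y_P} + X_A \bar\beta_A + \bar u_A}, where bars
#' denote posterior means (the influence term is averaged draw-wise).
#'
#' @param object an \code{nse_fit}.
#' @param ... unused.
#' @return two-column matrix \code{(fit_P, fit_A)}.
#' @export
fitted.nse_fit <- function(object, ...) {
  d <- object$data
  fit_P <- drop(d$X_P %*% colMeans(object$samples$beta_P)) +
    colMeans(object$samples$u_P)
  Ly <- if (!is.null(object$samples$P)) {
    Phi <- spline_basis(object$kv, d$y_P)
    drop(Phi %*% colMeans(object$samples$P)) * d$y_P
  } else 0
  fit_A <- Ly + drop(d$X_A %*% colMeans(object$samples$beta_A)) +
    colMeans(object$samples$u_A)
  cbind(fit_P = fit_P, fit_A = fit_A)
}

#' @export
residuals.nse_fit <- function(object, ...) {
  f <- fitted(object)
  cbind(res_P = object$data$y_P - f[, 1L],
        res_A = object$data$y_A - f[, 2L])
}

#' Plot the posterior influence trajectory
#'
#' Draws the posterior mean of the influence function \eqn{L(y)} over the
#' observed range of the phenological trait with dashed 95\% quantile bands
#' and a dotted zero line.
#'
#' @param x an NSE \code{nse_fit}.
#' @param grid_size grid resolution.
#' @param ... further arguments passed to \code{plot}.
#' @return the trajectory data.frame, invisibly.
#' @export
plot.nse_fit <- function(x, grid_size = 100L, ...) {
  tr <- trajectory(x, grid_size)
  graphics::plot(tr$y, tr$mean_L, type = "l", col = "red", lwd = 2,
                 ylim = range(tr[, c("q025_L", "q975_L")], 0),
                 xlab = "phenological trait (centered)",
                 ylab = "influence L(y)", ...)
  graphics::lines(tr$y, tr$q025_L, col = "red", lty = 2)
  graphics::lines(tr$y, tr$q975_L, col = "red", lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(tr)
}

#' Counterfactual prediction method
#'
#' Convenience wrapper around \code{\link{predict_edit}}.
#'
#' @param object an \code{nse_fit}.
#' @param line line ID or index.
#' @param edits named numeric vector of design-column changes.
#' @param ... unused.
#' @export
predict.nse_fit <- function(object, line, edits = NULL, ...) {
  predict_edit(object, line, edits)
}

#' @export
summary.nse_fit <- function(object, ...) {
  w <- waic(object)
  structure(list(fit = object, waic = w,
                 effects = tryCatch(gene_effects(object),
                                    error = function(e) NULL)),
            class = "summary.nse_fit")
}

#' @export
print.summary.nse_fit <- function(x, ...) {
  print(x$fit)
  cat("\nModel fit: ")
  print(x$waic)
  if (!is.null(x$effects) && nrow(x$effects)) {
    cat("\nMajor-gene effects (reported scale = 2x allele substitution):\n")
    print(x$effects[, c("trait", "term", "mean_x2", "q025_x2", "q975_x2",
                        "significant")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
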