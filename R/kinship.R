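#' Genomic relationship matrix from biallelic markers
#'
#' Computes the additive genomic relationship matrix (VanRaden method 1) from
#' a matrix of biallelic genotypes of (essentially homozygous) inbred lines
#' coded \{-1, 0, +1\} (heterozygotes as 0). Missing genotypes are
#' mean-imputed per marker, monomorphic markers are dropped, columns are
#' centered at their means, and
#' \deqn{K = W W^\top / (2 \sum_k p_k (1 - p_k))}
#' with \eqn{p_k} the allele frequency of marker \eqn{k}.
#'
#' @param markers numeric matrix, lines in rows and markers in columns, coded
#'   \{-1, 0, +1\}; row names are taken as line identifiers if present.
#' @param line_ids optional character vector of line identifiers overriding
#'   row names.
#' @param quiet suppress the message reporting dropped/imputed markers.
#' @return symmetric n x n matrix of class \code{matrix} with line IDs as
#'   dimnames and attributes \code{n_dropped} (monomorphic markers removed)
#'   and \code{frac_imputed} (fraction of imputed genotype calls).
#' @export
grm <- function(markers, line_ids = NULL, quiet = FALSE) {
  X <- as.matrix(markers)
  if (nrow(X) < 2L) stop("need at least 2 lines")
  if (is.null(line_ids)) line_ids <- rownames(X)
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(X)))
  storage.mode(X) <- "double"
  if (any(!is.na(X) & !(X %in% c(-1, 0, 1))))
    stop("marker genotypes must be coded -1, 0, +1 (NA allowed)")

  n_missing <- sum(is.na(X))
  frac_imputed <- n_missing / length(X)
  if (n_missing > 0L) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }

  v <- apply(X, 2L, function(col) max(col) - min(col))
  mono <- v == 0
  n_dropped <- sum(mono)
  if (all(mono)) stop("all markers are monomorphic")
  X <- X[, !mono, drop = FALSE]
  if (!quiet && (n_dropped > 0L || n_missing > 0L))
    message(sprintf("grm: dropped %d monomorphic markers; imputed %.2f%% of calls",
                    n_dropped, 100 * frac_imputed))

  p <- (colMeans(X) + 1) / 2            # frequency of the +1 allele
  W <- sweep(X, 2L, colMeans(X))
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(line_ids, line_ids)
  attr(K, "n_dropped") <- n_dropped
  attr(K, "frac_imputed") <- frac_imputed
  K
}

#' Regularize a kinship matrix
#'
#' Adds a small diagonal jitter \code{eps * I} to a relationship matrix so
#' that a symmetric factorization succeeds even when lines are duplicated or
#' markers are few. The jitter is escalated tenfold until \code{chol()}
#' succeeds, up to a cap.
#'
#' @param K symmetric relationship matrix.
#' @param eps starting jitter; default \code{1e-6} times the mean diagonal.
#' @return the regularized matrix with attribute \code{eps} recording the
#'   jitter actually applied (0 if none was needed).
#' @export
regularize_kinship <- function(K, eps = NULL) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  K <- (K + t(K)) / 2
  if (is.null(eps)) eps <- 1e-6 * mean(diag(K))
  if (eps < 0) stop("eps must be non-negative")
  ok <- function(M) !inherits(try(chol(M), silent = TRUE), "try-error")
  if (ok(K)) {
    attr(K, "eps") <- 0
    return(K)
  }
  cap <- 1e-2 * mean(diag(K))
  e <- max(eps, .Machine$double.eps)
  while (e <= cap) {
    Kj <- K + diag(e, nrow(K))
    if (ok(Kj)) {
      attr(Kj, "eps") <- e
      return(Kj)
    }
    e <- e * 10
  }
  stop("kinship matrix still indefinite after maximum jitter escalation")
}
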