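#' Knot vector for the influence spline
#'
#' Builds the knot sequence used to model the influence of the phenological
#' trait as a cubic B-spline. The boundary knots have full multiplicity
#' (repeated \code{order} times) so the basis is pinned at the range ends, and
#' the interior knots are equally spaced such that \code{y_min} falls at the
#' midpoint of the first inter-knot interval and \code{y_max} at the midpoint
#' of the last. With the default \code{M = 7} (eight basis functions of order
#' four) this gives 12 knots in total: four at the lower boundary, four
#' interior, four at the upper boundary, all five spans equal.
#'
#' @param y_min,y_max observed range of the (centered) phenological trait.
#' @param M highest basis index; \code{M + 1} basis functions are used.
#'   Must be at least 4 so that at least one interior knot exists.
#' @return an object of class \code{knot_vector}: a list with elements
#'   \code{knots} (numeric vector of length \code{M + 5}), \code{order}
#'   (always 4) and \code{n_basis} (\code{M + 1}).
#' @examples
#' kv <- build_knots(-2, 2)
#' kv$knots
#' @export
build_knots <- function(y_min, y_max, M = 7L) {
  if (!is.finite(y_min) || !is.finite(y_max))
    stop("knot range must be finite")
  if (y_min >= y_max)
    stop("invalid range: y_min must be strictly less than y_max")
  M <- as.integer(M)
  if (M < 4L)
    stop("M must be at least 4 (one interior knot)")
  order <- 4L
  n_basis <- M + 1L
  n_interior <- n_basis - order          # M - 3 interior knots
  # y_min midway between lower boundary and first interior knot, y_max midway
  # between last interior knot and upper boundary, all spans equal:
  delta <- (y_max - y_min) / n_interior
  t_lower <- y_min - delta / 2
  t_upper <- y_max + delta / 2
  interior <- t_lower + delta * seq_len(n_interior)
  knots <- c(rep(t_lower, order), interior, rep(t_upper, order))
  structure(list(knots = knots, order = order, n_basis = n_basis),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat("B-spline knot vector: order", x$order, "with", x$n_basis,
      "basis functions\n")
  cat("knots:", format(x$knots, digits = 6), "\n")
  invisible(x)
}

# Cox-de Boor evaluation of all basis functions at a single point.
# `knots` is the full (possibly multiple) knot sequence, `order` the spline
# order (degree + 1). Returns a vector of length(knots) - order. Points
# outside [knots[1], knots[K]] get all zeros; the maximum knot is treated as
# belonging to the last non-empty interval so the basis sums to one there.
# Plain textbook recursion with the 0/0 := 0 convention, valid for arbitrary
# (also unclamped) knot sequences.
deboor_point <- function(knots, order, y) {
  K <- length(knots)
  nb <- K - order
  if (!is.finite(y) || y < knots[1L] || y > knots[K]) return(numeric(nb))
  if (y == knots[K]) {
    jstar <- max(which(knots < knots[K]))
  } else {
    jstar <- findInterval(y, knots)      # knots[jstar] <= y < knots[jstar+1]
    while (jstar < K && knots[jstar + 1L] == knots[jstar]) jstar <- jstar + 1L
  }
  B <- as.numeric(seq_len(K - 1L) == jstar)      # order-1 indicators
  if (order > 1L) {
    for (k in 2:order) {
      nB <- numeric(K - k)
      for (i in seq_len(K - k)) {
        d1 <- knots[i + k - 1L] - knots[i]
        d2 <- knots[i + k] - knots[i + 1L]
        v <- 0
        if (d1 > 0) v <- (y - knots[i]) / d1 * B[i]
        if (d2 > 0) v <- v + (knots[i + k] - y) / d2 * B[i + 1L]
        nB[i] <- v
      }
      B <- nB
    }
  }
  B
}

#' Evaluate the B-spline basis matrix
#'
#' Evaluates all \code{M + 1} cubic basis functions at the given points by the
#' Cox-de Boor recursion. Points outside the knot range yield zero rows; the
#' upper boundary knot is mapped into the last non-empty interval so that the
#' basis forms a partition of unity on the whole closed range.
#'
#' @param kv a \code{knot_vector} from \code{\link{build_knots}}.
#' @param y numeric vector of evaluation points.
#' @return numeric matrix, \code{length(y)} rows by \code{kv$n_basis} columns.
#' @export
spline_basis <- function(kv, y) {
  stopifnot(inherits(kv, "knot_vector"))
  out <- matrix(0, length(y), kv$n_basis)
  for (i in seq_along(y))
    out[i, ] <- deboor_point(kv$knots, kv$order, y[i])
  colnames(out) <- paste0("phi", seq_len(kv$n_basis) - 1L)
  out
}

#' Evaluate a single basis function
#'
#' @param kv a \code{knot_vector}.
#' @param m basis index in \code{0:M} (zero-based, matching the usual
#'   \eqn{\sum_m P_m \phi_m} notation).
#' @param y numeric vector of evaluation points.
#' @return numeric vector of basis values; zero outside the support of basis
#'   \code{m}.
#' @export
basis_eval <- function(kv, m, y) {
  stopifnot(inherits(kv, "knot_vector"))
  m <- as.integer(m)
  if (m < 0L || m >= kv$n_basis)
    stop("basis index m must be in 0..", kv$n_basis - 1L)
  spline_basis(kv, y)[, m + 1L]
}

#' Evaluate the influence function L(y)
#'
#' Computes \eqn{L(y) = \sum_m P_m \phi_m(y)}, the trait-value-dependent
#' slope (e.g. cm/day) with which the phenological phenotype enters the
#' influenced trait's equation.
#'
#' @param kv a \code{knot_vector}.
#' @param P numeric vector of \code{kv$n_basis} basis weights.
#' @param y numeric vector of evaluation points; must lie within the knot
#'   range (the model never evaluates L outside it).
#' @return numeric vector of influence values.
#' @export
influence_eval <- function(kv, P, y) {
  stopifnot(inherits(kv, "knot_vector"))
  if (length(P) != kv$n_basis)
    stop("P must have length ", kv$n_basis)
  rng <- range(kv$knots)
  if (any(y < rng[1] | y > rng[2]))
    stop("evaluation point outside the knot range [", rng[1], ", ", rng[2], "]")
  drop(spline_basis(kv, y) %*% P)
}

#' Read and write knot vectors
#'
#' Knot vectors are stored as a plain single-column text file so a fit can be
#' reproduced exactly.
#'
#' @param kv a \code{knot_vector}.
#' @param path file path.
#' @param order spline order assumed on read (cubic = 4).
#' @return \code{read_knots} returns a \code{knot_vector};
#'   \code{write_knots} returns \code{path} invisibly.
#' @export
write_knots <- function(kv, path) {
  stopifnot(inherits(kv, "knot_vector"))
  writeLines(format(kv$knots, digits = 17, scientific = TRUE, trim = TRUE),
             path)
  invisible(path)
}

#' @rdname write_knots
#' @export
read_knots <- function(path, order = 4L) {
  knots <- as.numeric(readLines(path))
  if (anyNA(knots) || is.unsorted(knots))
    stop("malformed knot file: ", path)
  structure(list(knots = knots, order = as.integer(order),
                 n_basis = length(knots) - as.integer(order)),
            class = "knot_vector")
}
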