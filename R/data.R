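#' Center the two phenotypes
#'
#' Both traits are mean-centered before modelling; the means are retained so
#' fitted values and counterfactual predictions can be reported on the
#' original scale.
#'
#' @param raw_P,raw_A numeric vectors of the phenological and influenced
#'   trait, no missing values.
#' @return list with \code{y_P}, \code{y_A} (centered) and \code{means}
#'   (named numeric of length 2).
#' @export
center_phenotypes <- function(raw_P, raw_A) {
  if (length(raw_P) != length(raw_A)) stop("trait vectors differ in length")
  if (length(raw_P) < 2L) stop("need at least 2 lines to center")
  if (anyNA(raw_P) || anyNA(raw_A))
    stop("missing phenotypes: drop incomplete lines before centering")
  m_P <- mean(raw_P); m_A <- mean(raw_A)
  list(y_P = raw_P - m_P, y_A = raw_A - m_A,
       means = c(mean_P = m_P, mean_A = m_A))
}

#' Major-gene design matrices
#'
#' Builds the fixed-effect design matrices of the two traits from a table of
#' major-gene genotypes. Numeric columns must already be 0/1 incidence
#' relative to the reference line; character or factor columns (multi-allelic
#' loci, e.g. haplotypes) are expanded into k-1 dummy columns against the
#' reference line's level. Each column is assigned to the phenological trait
#' ("P"), the influenced trait ("A"), or both ("both"); with the default
#' assignment every gene affects both traits.
#'
#' @param genes data.frame with a \code{line_id} column (or first column taken
#'   as IDs) plus one column per polymorphism.
#' @param manifest named character vector mapping gene-table column names to
#'   \code{"P"}, \code{"A"} or \code{"both"}; unnamed columns default to
#'   \code{"both"}.
#' @param reference line ID of the reference; its genotype row must be
#'   all-reference (all zeros after coding). \code{NULL} skips the check.
#' @return list with design matrices \code{X_P} and \code{X_A} (each with a
#'   leading intercept column of ones) and \code{line_ids}.
#' @export
build_design <- function(genes, manifest = NULL, reference = NULL) {
  genes <- as.data.frame(genes)
  idcol <- if ("line_id" %in% names(genes)) "line_id" else names(genes)[1L]
  ids <- as.character(genes[[idcol]])
  if (anyDuplicated(ids)) stop("duplicate line IDs in gene table")
  g <- genes[, setdiff(names(genes), idcol), drop = FALSE]
  if (!is.null(reference) && !(reference %in% ids))
    stop("unknown reference line: ", reference)

  cols <- list(); assign <- character(0)
  get_assign <- function(nm) {
    a <- if (!is.null(manifest) && nm %in% names(manifest)) manifest[[nm]] else "both"
    if (!a %in% c("P", "A", "both")) stop("manifest entry for ", nm,
                                          " must be P, A or both")
    a
  }
  for (nm in names(g)) {
    col <- g[[nm]]
    a <- get_assign(nm)
    if (is.numeric(col)) {
      if (anyNA(col) || !all(col %in% c(0, 1)))
        stop("non-{0,1} entry in gene column ", nm)
      cols[[nm]] <- as.numeric(col)
      assign <- c(assign, a)
    } else {
      # multi-allelic locus: dummy-code against the reference line's level
      col <- as.character(col)
      if (anyNA(col)) stop("missing genotype in gene column ", nm)
      base <- if (!is.null(reference)) col[ids == reference] else
        names(sort(table(col), decreasing = TRUE))[1L]
      for (lev in setdiff(sort(unique(col)), base)) {
        cols[[paste0(nm, ".", lev)]] <- as.numeric(col == lev)
        assign <- c(assign, a)
      }
    }
  }
  Xall <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(ids), 0)
  if (!is.null(reference)) {
    ref_row <- Xall[ids == reference, ]
    if (length(ref_row) && any(ref_row != 0))
      stop("reference line ", reference,
           " carries a non-reference allele after coding")
  }
  mk <- function(keep) {
    X <- cbind(intercept = 1, Xall[, keep, drop = FALSE])
    rownames(X) <- ids
    X
  }
  list(X_P = mk(assign %in% c("P", "both")),
       X_A = mk(assign %in% c("A", "both")),
       line_ids = ids)
}

#' Assemble a bivariate trait dataset
#'
#' Aligns phenotypes, major-gene genotypes and kinship by line ID
#' (intersection, preserving phenotype order), drops lines missing either
#' trait, centers both traits, and builds the design matrices. The result is
#' the data container every model-fitting function consumes.
#'
#' @param pheno data.frame with columns \code{line_id}, then the phenological
#'   trait and the influenced trait (by name or position 2 and 3).
#' @param genes optional gene-genotype data.frame (see
#'   \code{\link{build_design}}); \code{NULL} gives intercept-only designs.
#' @param manifest,reference passed to \code{\link{build_design}}.
#' @param K precomputed kinship matrix with line IDs as dimnames; exactly one
#'   of \code{K} and \code{markers} must be given.
#' @param markers marker matrix (lines x markers, coded -1/0/1, row names =
#'   line IDs) from which the kinship is computed via \code{\link{grm}}.
#' @param min_lines minimum number of complete, aligned lines required.
#' @return an object of class \code{nse_data}: list with \code{line_ids},
#'   centered \code{y_P}, \code{y_A}, designs \code{X_P}, \code{X_A},
#'   regularized kinship \code{K}, \code{means}, \code{n}, and the counts of
#'   lines dropped by alignment/completeness.
#' @export
bivariate_data <- function(pheno, genes = NULL, manifest = NULL,
                           reference = NULL, K = NULL, markers = NULL,
                           min_lines = 2L) {
  pheno <- as.data.frame(pheno)
  if (ncol(pheno) < 3L) stop("phenotype table needs line_id + two traits")
  ids <- as.character(pheno[[1L]])
  if (anyDuplicated(ids)) stop("duplicate line IDs in phenotype table")
  raw_P <- pheno[[2L]]; raw_A <- pheno[[3L]]
  if (!is.numeric(raw_P) || !is.numeric(raw_A))
    stop("non-numeric phenotype column")

  if (is.null(K) == is.null(markers))
    stop("provide exactly one of K or markers")
  if (is.null(K)) K <- grm(markers, quiet = TRUE)
  K <- as.matrix(K)
  if (is.null(rownames(K))) stop("kinship matrix must carry line IDs")

  keep_ids <- intersect(ids, rownames(K))
  if (!is.null(genes)) {
    gid <- if ("line_id" %in% names(genes)) genes[["line_id"]] else genes[[1L]]
    keep_ids <- intersect(keep_ids, as.character(gid))
  }
  sel <- ids %in% keep_ids & !is.na(raw_P) & !is.na(raw_A)
  n_dropped <- sum(!sel)
  ids <- ids[sel]
  n <- length(ids)
  if (n < min_lines)
    stop("only ", n, " aligned complete lines; need at least ", min_lines)

  ctr <- center_phenotypes(raw_P[sel], raw_A[sel])

  if (!is.null(genes)) {
    des <- build_design(genes, manifest, reference)
    idx <- match(ids, des$line_ids)
    X_P <- des$X_P[idx, , drop = FALSE]
    X_A <- des$X_A[idx, , drop = FALSE]
  } else {
    X_P <- X_A <- matrix(1, n, 1, dimnames = list(ids, "intercept"))
  }
  K <- regularize_kinship(K[ids, ids])

  structure(list(line_ids = ids, y_P = ctr$y_P, y_A = ctr$y_A,
                 X_P = X_P, X_A = X_A, K = K, means = ctr$means,
                 n = n, n_dropped = n_dropped),
            class = "nse_data")
}

#' @export
print.nse_data <- function(x, ...) {
  cat("Bivariate trait dataset:", x$n, "lines\n")
  cat("  trait means:", format(x$means, digits = 6), "\n")
  cat("  design columns: P =", ncol(x$X_P), ", A =", ncol(x$X_A), "\n")
  cat("  kinship jitter:", attr(x$K, "eps"), "\n")
  invisible(x)
}
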