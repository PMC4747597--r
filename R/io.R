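# Shared I/O helpers. TSV with headers is the canonical dialect; CSV is
# accepted on read (detected from the first line). Numeric output keeps 10
# significant digits.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = detect_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path, digits = 10L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV or CSV with a header; the first column is the line ID, the second the
#' phenological trait, the third the influenced trait.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_table_auto(path)
  if (ncol(df) < 3L) stop("phenotype table needs line_id + two trait columns")
  for (j in 2:3) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "" & v != "NA")
      if (length(bad))
        stop("non-numeric phenotype at row ", bad[1L], ", column ",
             names(df)[j], " of ", path)
      df[[j]] <- coerced
    }
  }
  df
}

#' Read a major-gene genotype table and its manifest
#'
#' The gene table is line_id + one column per polymorphism. The manifest is a
#' two-column table (\code{column}, \code{assign}) assigning each gene column
#' to trait \code{P}, trait \code{A}, or \code{both}.
#'
#' @param path file path.
#' @return \code{read_gene_table}: data.frame; \code{read_manifest}: named
#'   character vector.
#' @export
read_gene_table <- function(path) read_table_auto(path)

#' @rdname read_gene_table
#' @export
read_manifest <- function(path) {
  df <- read_table_auto(path)
  if (!all(c("column", "assign") %in% names(df)))
    stop("manifest needs columns 'column' and 'assign'")
  stats::setNames(as.character(df$assign), as.character(df$column))
}

#' Read a marker matrix
#'
#' Lines x markers with a header row of marker IDs; the first column holds
#' line IDs. Genotypes coded -1/0/+1 (NA allowed).
#'
#' @param path file path.
#' @return numeric matrix with line IDs as row names.
#' @export
read_markers <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate line IDs in marker file")
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Read and write kinship matrices
#'
#' CSV with line IDs as both header row and first column.
#'
#' @param K kinship matrix with dimnames.
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(line_id = rownames(K),
                   signif(unname(as.matrix(K)), 10L),
                   check.names = FALSE)
  names(df) <- c("line_id", colnames(K))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1L]])
  K <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  dimnames(K) <- list(ids, ids)
  K
}

#' Read a key = value run configuration file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment. Values
#' that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Assemble a dataset from configured input files
#'
#' Reads the phenotype, gene (+ manifest) and marker-or-kinship files named in
#' a run configuration, aligns line IDs across them (intersection, reporting
#' dropped lines), applies complete-case filtering, centers the phenotypes and
#' builds the designs and kinship.
#'
#' @param config named list (or path to a config file) with entries
#'   \code{pheno}, optionally \code{genes} and \code{manifest}, exactly one of
#'   \code{markers} / \code{kinship}, and optionally \code{reference}.
#' @param min_lines minimum aligned complete lines (default 10).
#' @return an \code{nse_data} object.
#' @export
read_inputs <- function(config, min_lines = 10L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$pheno)) stop("config must name a 'pheno' file")
  has_m <- !is.null(config$markers); has_k <- !is.null(config$kinship)
  if (has_m == has_k) stop("provide exactly one of 'markers' and 'kinship'")
  pheno <- read_phenotypes(config$pheno)
  genes <- if (!is.null(config$genes)) read_gene_table(config$genes) else NULL
  manifest <- if (!is.null(config$manifest)) read_manifest(config$manifest)
  else NULL
  K <- if (has_k) read_kinship(config$kinship) else NULL
  markers <- if (has_m) read_markers(config$markers) else NULL
  dat <- bivariate_data(pheno, genes = genes, manifest = manifest,
                        reference = config$reference, K = K,
                        markers = markers, min_lines = min_lines)
  if (dat$n_dropped > 0L)
    message("read_inputs: dropped ", dat$n_dropped,
            " lines (ID mismatch or missing trait)")
  dat
}

#' Write a fitted model to a directory
#'
#' Emits one CSV per posterior parameter block, the per-line log-likelihood
#' draws, the knot vector, the WAIC summary, the gene-effect table, the
#' influence trajectory (NSE fits only) and a JSON manifest containing
#' everything needed to rerun the fit (seed, chain settings, knots, prior
#' scale, acceptance rates).
#'
#' @param fit an \code{nse_fit}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wr <- function(M, f) write_tsv(as.data.frame(M), p(f))
  wr(fit$samples$beta_P, "samples_beta_P.tsv")
  wr(fit$samples$beta_A, "samples_beta_A.tsv")
  wr(fit$samples$u_P, "samples_u_P.tsv")
  wr(fit$samples$u_A, "samples_u_A.tsv")
  wr(fit$samples$G, "samples_G.tsv")
  wr(fit$samples$R, "samples_R.tsv")
  wr(fit$samples$ll_lines, "loglik_lines.tsv")
  scal <- data.frame(loglik = fit$samples$loglik)
  if (!is.null(fit$samples$P)) {
    wr(fit$samples$P, "samples_weights.tsv")
    scal$sigma_P2 <- fit$samples$sigma_P2
    write_tsv(trajectory(fit), p("trajectory.tsv"))
  }
  wr(scal, "samples_scalars.tsv")
  eff <- tryCatch(gene_effects(fit), error = function(e) NULL)
  if (!is.null(eff) && nrow(eff)) write_tsv(eff, p("gene_effects.tsv"))
  w <- waic(fit)
  write_tsv(data.frame(model = fit$model, mean_loglik = w$mean_loglik,
                       lppd = w$lppd, p_waic = w$p_waic, waic = w$waic),
            p("fit_summary.tsv"))
  write_knots(fit$kv, p("knots.txt"))
  manifest <- list(model = fit$model, config = fit$config, M = fit$M,
                   knots = fit$kv$knots,
                   prior = list(df = fit$prior$df,
                                scale = as.vector(fit$prior$scale)),
                   accept = as.list(fit$accept),
                   kinship_eps = attr(fit$data$K, "eps"),
                   n_lines = fit$data$n,
                   centering_means = as.list(fit$data$means))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Fit a model from a run configuration
#'
#' End-to-end command: read the configured inputs, run the sampler, and write
#' all outputs to the configured directory.
#'
#' @param config named list or path to a key = value config file; in addition
#'   to the input-file entries of \code{\link{read_inputs}} it may set
#'   \code{model}, \code{M}, \code{n_iter}, \code{burn_in}, \code{thin},
#'   \code{sigma_prop2}, \code{seed} and must set \code{out}.
#' @return the output directory, invisibly.
#' @export
fit_command <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$out)) stop("config must name an 'out' directory")
  dat <- read_inputs(config)
  get <- function(key, default) if (is.null(config[[key]])) default
  else config[[key]]
  fit <- nse(dat,
             model = get("model", "nse"),
             M = get("M", 7L),
             n_iter = get("n_iter", 1.1e6),
             burn_in = get("burn_in", 1e5),
             thin = get("thin", 100L),
             sigma_prop2 = get("sigma_prop2", 0.04),
             seed = get("seed", 1L))
  write_fit(fit, config$out)
}

#' Compare two stored fits by WAIC
#'
#' Recomputes WAIC from the per-line log-likelihood draws stored in two fit
#' directories and emits a one-row comparison table (mean log-likelihood and
#' WAIC per model, plus delta WAIC = first minus second, negative favoring
#' the first).
#'
#' @param dir_nse,dir_olm fit directories written by \code{\link{write_fit}}.
#' @param out optional path for the comparison TSV.
#' @return the comparison data.frame.
#' @export
compare_command <- function(dir_nse, dir_olm, out = NULL) {
  rd <- function(dir) {
    f <- file.path(dir, "loglik_lines.tsv")
    if (!file.exists(f)) stop("missing per-line log-likelihood file: ", f)
    as.matrix(read_table_auto(f))
  }
  ll1 <- rd(dir_nse); ll2 <- rd(dir_olm)
  if (!identical(colnames(ll1), colnames(ll2)))
    stop("the two fits cover different line sets")
  w1 <- waic(ll1); w2 <- waic(ll2)
  res <- data.frame(mean_loglik_nse = w1$mean_loglik, waic_nse = w1$waic,
                    mean_loglik_olm = w2$mean_loglik, waic_olm = w2$waic,
                    delta_waic = w1$waic - w2$waic)
  if (!is.null(out)) write_tsv(res, out)
  res
}
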