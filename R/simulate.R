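#' Default nonlinear influence weights
#'
#' A canonical "bump" weight vector for the nonlinear simulation regime: a
#' monotone-decreasing influence (cm/day) that is strongly positive for early
#' phenology and crosses zero towards late phenology, qualitatively matching
#' the trajectories estimated on real rice data.
#'
#' @param M highest basis index; only the default cubic setting (\code{M = 7},
#'   eight weights) is defined.
#' @return numeric vector of \code{M + 1} weights.
#' @export
bump_weights <- function(M = 7L) {
  if (M != 7L) stop("default bump weights are defined for M = 7 only")
  c(1.6, 1.3, 0.9, 0.5, 0.2, 0.0, -0.2, -0.3)
}

#' Simulate a genotype fixture
#'
#' Generates biallelic homozygous marker genotypes, 0/1 major-gene incidence
#' columns (carrier frequencies uniform on [0.1, 0.5]), and the genomic
#' relationship matrix. Per-marker allele frequencies are uniform on
#' [0.1, 0.9], optionally split into two subpopulations with frequency
#' offsets. Lines are additionally grouped into small families that share a
#' founder genotype (each member copies a founder allele with probability
#' \code{fam_copy}, else redraws from the population frequency), emulating the
#' clusters of closely related cultivars found in real diversity panels --
#' without such relatedness structure the genetic and residual covariances
#' are barely separable. The default shape mirrors a rice panel: 110 lines,
#' 3,102 markers, six phenology genes affecting both traits and three genes
#' affecting only the influenced trait.
#'
#' @param n_lines,n_markers fixture dimensions (\code{n_lines >= 10}).
#' @param n_genes_P number of phenology-gene columns (assigned "both": they
#'   affect the phenological trait and, directly, the influenced trait's
#'   design as well).
#' @param n_genes_A number of influenced-trait-only gene columns.
#' @param n_subpop 1 (panmictic) or 2 (two subpopulations with allele
#'   frequency offsets).
#' @param fam_size number of lines per founder family (1 = unrelated lines).
#' @param fam_copy probability that a family member carries the founder
#'   allele at a marker.
#' @param seed integer seed.
#' @return list with \code{markers} (-1/+1 matrix), \code{genes} (data.frame
#'   with \code{line_id}), \code{manifest}, \code{K}, \code{line_ids},
#'   \code{group} (subpopulation labels) and \code{family}.
#' @export
sim_fixture <- function(n_lines = 110L, n_markers = 3102L,
                        n_genes_P = 6L, n_genes_A = 3L,
                        n_subpop = 1L, fam_size = 5L, fam_copy = 0.9,
                        seed = NULL) {
  if (n_lines < 10L) stop("n_lines must be at least 10")
  if (n_markers < 1L) stop("n_markers must be at least 1")
  if (!n_subpop %in% 1:2) stop("n_subpop must be 1 or 2")
  if (fam_size < 1L) stop("fam_size must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- sprintf("L%03d", seq_len(n_lines))
  family <- rep(seq_len(ceiling(n_lines / fam_size)), each = fam_size,
                length.out = n_lines)
  group <- (family %% n_subpop) + 1L

  p <- stats::runif(n_markers, 0.1, 0.9)
  off <- if (n_subpop == 2L) stats::runif(n_markers, 0, 0.3) else
    numeric(n_markers)
  draw_col <- function(k) {
    pk <- pmin(pmax(c(p[k] + off[k], p[k] - off[k]), 0.05), 0.95)
    founder <- stats::rbinom(max(family), 1L, pk[(seq_len(max(family)) %%
                                                    n_subpop) + 1L])
    copy <- stats::rbinom(n_lines, 1L, fam_copy)
    fresh <- stats::rbinom(n_lines, 1L, pk[group])
    2L * ifelse(copy == 1L, founder[family], fresh) - 1L
  }
  markers <- vapply(seq_len(n_markers), draw_col, numeric(n_lines))
  # guarantee polymorphism: redraw fixed columns
  for (k in which(apply(markers, 2L, function(x) max(x) == min(x)))) {
    repeat {
      g <- draw_col(k)
      if (max(g) > min(g)) { markers[, k] <- g; break }
    }
  }
  dimnames(markers) <- list(ids, sprintf("m%04d", seq_len(n_markers)))

  gene_col <- function(f = stats::runif(1L, 0.1, 0.5)) {
    repeat {
      g <- stats::rbinom(n_lines, 1L, f)
      if (max(g) > min(g)) return(g)
    }
  }
  # the first phenology gene mimics a strong photoperiod-insensitivity allele
  # carried by a small early-heading minority of the panel
  gp <- if (n_genes_P > 0L) vapply(seq_len(n_genes_P), function(j)
    if (j == 1L) gene_col(0.1) else gene_col(),
    numeric(n_lines)) else NULL
  ga <- if (n_genes_A > 0L) vapply(seq_len(n_genes_A), function(j) gene_col(),
                                   numeric(n_lines)) else NULL
  genes <- data.frame(line_id = ids)
  manifest <- character(0)
  if (!is.null(gp)) {
    colnames(gp) <- sprintf("geneP%d", seq_len(n_genes_P))
    genes <- cbind(genes, gp)
    manifest <- c(manifest, stats::setNames(rep("both", n_genes_P),
                                            colnames(gp)))
  }
  if (!is.null(ga)) {
    colnames(ga) <- sprintf("geneA%d", seq_len(n_genes_A))
    genes <- cbind(genes, ga)
    manifest <- c(manifest, stats::setNames(rep("A", n_genes_A),
                                            colnames(ga)))
  }
  list(markers = markers, genes = genes, manifest = manifest,
       K = grm(markers, quiet = TRUE), line_ids = ids, group = group,
       family = family)
}

#' Draw true simulation parameters
#'
#' Samples polygenic effects \eqn{u \sim N(0, G \otimes K)} and (unless
#' supplied) major-gene effects from normal effect-size distributions, for use
#' as the generating truth of a simulated dataset. Default covariances are on
#' a rice-like scale: days for the phenological trait, centimetres for the
#' influenced trait, with high heritability and a modest positive genetic and
#' residual covariance.
#'
#' @param fixture a fixture from \code{\link{sim_fixture}}.
#' @param G,R 2x2 genetic and residual covariance matrices (trait order P, A).
#' @param beta_P,beta_A fixed-effect vectors matching the design columns
#'   (including intercept); \code{NULL} draws gene effects from
#'   \code{N(0, sd_beta^2)} with zero intercepts, except that the first
#'   phenology gene receives \code{major_effect_P}.
#' @param sd_beta_P,sd_beta_A effect-size standard deviations used when
#'   effects are drawn.
#' @param major_effect_P phenology effect (days) of the first phenology gene,
#'   emulating a strong photoperiod-insensitivity allele whose carriers head
#'   much earlier than the rest of the panel; set \code{NA} to draw it like
#'   the others.
#' @param seed integer seed.
#' @return list of class contents: \code{beta_P}, \code{beta_A} (named),
#'   \code{u_P}, \code{u_A}, \code{G}, \code{R}.
#' @export
sim_params <- function(fixture,
                       G = matrix(c(80, 18, 18, 90), 2),
                       R = matrix(c(16, 5, 5, 25), 2),
                       beta_P = NULL, beta_A = NULL,
                       sd_beta_P = 4, sd_beta_A = 3,
                       major_effect_P = -15, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  chk <- function(M, nm) {
    if (!all(dim(M) == c(2L, 2L)) || abs(M[1, 2] - M[2, 1]) > 1e-12)
      stop(nm, " must be a symmetric 2x2 matrix")
    if (any(diag(M) < 0) || M[1, 1] * M[2, 2] - M[1, 2]^2 < 0)
      stop(nm, " must be positive (semi-)definite")
  }
  chk(G, "G"); chk(R, "R")
  des <- build_design(fixture$genes, fixture$manifest)
  n <- length(fixture$line_ids)
  mk_beta <- function(beta, X, sd) {
    if (!is.null(beta)) {
      if (length(beta) != ncol(X)) stop("beta length mismatch with design")
      return(stats::setNames(as.numeric(beta), colnames(X)))
    }
    b <- c(0, stats::rnorm(ncol(X) - 1L, 0, sd))
    stats::setNames(b, colnames(X))
  }
  bP <- mk_beta(beta_P, des$X_P, sd_beta_P)
  if (is.null(beta_P) && !is.na(major_effect_P) &&
      "geneP1" %in% names(bP))
    bP["geneP1"] <- major_effect_P
  bA <- mk_beta(beta_A, des$X_A, sd_beta_A)
  if (max(abs(G)) == 0) {
    U <- matrix(0, n, 2L)
  } else {
    LK <- t(chol(regularize_kinship(fixture$K)))
    LG <- t(chol(G))
    U <- LK %*% matrix(stats::rnorm(2L * n), n, 2L) %*% t(LG)
  }
  list(beta_P = bP, beta_A = bA, u_P = U[, 1L], u_A = U[, 2L], G = G, R = R)
}

#' Extract generating parameters from a fitted model
#'
#' Returns the posterior means of a fit as a truth object for simulation:
#' fixed effects, per-line polygenic effects, the residual covariance, and
#' (for an NSE fit) the spline weights and knot vector. Simulating from a
#' fitted model's posterior means is the canonical way to build a
#' recovery study whose truth is self-consistent with the estimator: the
#' weakly identified level component of the influence function then sits at
#' the estimator's own equilibrium rather than at an arbitrary value.
#'
#' @param fit an \code{nse_fit}.
#' @return truth list as produced by \code{\link{sim_params}}, with
#'   additional elements \code{weights} and \code{kv} for an NSE fit.
#' @export
sim_params_from_fit <- function(fit) {
  stopifnot(inherits(fit, "nse_fit"))
  Rm <- colMeans(fit$samples$R)
  Gm <- colMeans(fit$samples$G)
  out <- list(beta_P = colMeans(fit$samples$beta_P),
              beta_A = colMeans(fit$samples$beta_A),
              u_P = unname(colMeans(fit$samples$u_P)),
              u_A = unname(colMeans(fit$samples$u_A)),
              G = matrix(Gm[c(1, 2, 2, 3)], 2),
              R = matrix(Rm[c(1, 2, 2, 3)], 2))
  if (!is.null(fit$samples$P)) {
    out$weights <- colMeans(fit$samples$P)
    out$kv <- fit$kv
  }
  out
}

#' Simulate a bivariate phenotype dataset under an influence scheme
#'
#' Generates phenotypes from the structural model under one of three
#' regimes for the influence of the phenological trait: \code{"nonlinear"}
#' (a B-spline influence with the given weights), \code{"linear"} (a constant
#' influence, default 1.2 cm/day), or \code{"none"}. Residual pairs are drawn
#' from \eqn{N(0, R)}; a line whose phenological value falls outside the knot
#' bounds has its residual pair redrawn (truncation, at most
#' \code{max_redraw} rounds), since the influence function is undefined
#' outside the knots. Phenotypes are then re-centered and packed into an
#' \code{nse_data} object; the generating truth (including the per-line true
#' influence values) is attached as attribute \code{"truth"}.
#'
#' @param fixture fixture from \code{\link{sim_fixture}}.
#' @param truth parameters from \code{\link{sim_params}}.
#' @param scheme \code{"nonlinear"}, \code{"linear"} or \code{"none"}.
#' @param weights spline weights of the nonlinear scheme.
#' @param constant the constant influence of the linear scheme.
#' @param kv generation knot vector; by default built from the range of the
#'   genetic mean structure widened by three residual standard deviations.
#' @param max_redraw maximum rejection rounds for out-of-bounds lines.
#' @param seed integer seed.
#' @return an \code{nse_data} object with attribute \code{"truth"}: list with
#'   \code{L}, \code{u_P}, \code{u_A}, \code{beta_P}, \code{beta_A}, \code{G},
#'   \code{R}, \code{scheme}, \code{kv_gen} and \code{redraw_frac}.
#' @export
sim_dataset <- function(fixture, truth,
                        scheme = c("nonlinear", "linear", "none"),
                        weights = bump_weights(), constant = 1.2,
                        kv = NULL, max_redraw = 1000L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(as.integer(seed))
  des <- build_design(fixture$genes, fixture$manifest)
  n <- length(fixture$line_ids)
  mu_P <- drop(des$X_P %*% truth$beta_P) + truth$u_P
  mu_A <- drop(des$X_A %*% truth$beta_A) + truth$u_A
  sd_eP <- sqrt(truth$R[1, 1])
  if (is.null(kv))
    kv <- build_knots(min(mu_P) - 3 * sd_eP, max(mu_P) + 3 * sd_eP)
  kr <- range(kv$knots)
  LR <- t(chol(truth$R))

  eP <- numeric(n); eA <- numeric(n)
  todo <- seq_len(n)
  redraws <- 0L
  for (round in seq_len(max_redraw)) {
    Z <- matrix(stats::rnorm(2L * length(todo)), 2L)
    E <- LR %*% Z
    eP[todo] <- E[1L, ]; eA[todo] <- E[2L, ]
    yP_try <- mu_P[todo] + eP[todo]
    bad <- yP_try < kr[1] | yP_try > kr[2]
    redraws <- redraws + sum(bad)
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("phenological values persistently exceed the knot bounds; ",
         "widen the generation knots")

  y_P <- mu_P + eP
  L_true <- switch(scheme,
                   nonlinear = influence_eval(kv, weights, y_P),
                   linear = rep(constant, n),
                   none = rep(0, n))
  y_A <- L_true * y_P + mu_A + eA

  pheno <- data.frame(line_id = fixture$line_ids, trait_P = y_P,
                      trait_A = y_A)
  dat <- bivariate_data(pheno, genes = fixture$genes,
                        manifest = fixture$manifest, K = fixture$K)
  attr(dat, "truth") <- list(
    L = L_true, u_P = truth$u_P, u_A = truth$u_A,
    beta_P = truth$beta_P, beta_A = truth$beta_A,
    G = truth$G, R = truth$R, scheme = scheme,
    weights = if (scheme == "nonlinear") weights else NULL,
    constant = if (scheme == "linear") constant else NULL,
    kv_gen = kv, redraw_frac = redraws / n)
  dat
}

#' Replicate parameter-recovery study
#'
#' Simulates \code{n_reps} datasets under one influence scheme from a single
#' fixture/truth pair, fits the requested models to each, and tabulates the
#' recovery correlations (per-line influence, polygenic effects on the
#' influenced trait, major-gene effects on the influenced trait) and the
#' delta WAIC per replicate, with a mean (SD) summary per model.
#'
#' @param scheme influence scheme; see \code{\link{sim_dataset}}.
#' @param n_reps number of simulated datasets.
#' @param fixture,truth optional pre-built fixture/truth (generated from
#'   \code{seed} otherwise).
#' @param n_lines,n_markers,n_genes_P,n_genes_A fixture shape when generated
#'   internally.
#' @param weights,constant influence parameters of the scheme.
#' @param models subset of \code{c("nse", "olm", "nse-zero-rescov")}.
#' @param calibrate if \code{TRUE} (the default), the generating truth is
#'   taken from a pilot fit: a dataset is simulated under the requested
#'   scheme, the NSE (nonlinear scheme) or OLM (linear / none) is fitted to
#'   it with the same chain settings, and the posterior means become the
#'   truth of the replicate study — the standard construction in which the
#'   simulation truth is self-consistent with the estimator (see
#'   \code{\link{sim_params_from_fit}}). \code{FALSE} uses the raw
#'   \code{truth} parameters directly.
#' @param zero_rescov_data set the generating residual covariance to zero
#'   (used with the constrained model variant).
#' @param n_iter,burn_in,thin,sigma_prop2 chain settings passed to
#'   \code{\link{nse}}.
#' @param seed master seed; replicate and chain seeds are derived from it.
#' @param verbose print per-replicate progress.
#' @return object of class \code{nse_study}: list with \code{replicates}
#'   (one row per replicate x model), \code{summary} (mean and SD per model),
#'   \code{delta_waic} (mean, SD across replicates, when both nse and olm were
#'   fitted) and \code{failed} (count of failed replicate fits).
#' @export
run_study <- function(scheme = c("nonlinear", "linear", "none"),
                      n_reps = 20L, fixture = NULL, truth = NULL,
                      n_lines = 110L, n_markers = 1000L,
                      n_genes_P = 6L, n_genes_A = 3L,
                      weights = bump_weights(), constant = 1.2,
                      models = c("nse", "olm"), calibrate = TRUE,
                      zero_rescov_data = FALSE,
                      n_iter = 1.1e6, burn_in = 1e5, thin = 100L,
                      sigma_prop2 = 0.04, seed = 1L, verbose = FALSE) {
  scheme <- match.arg(scheme)
  seed <- as.integer(seed)
  if (is.null(fixture))
    fixture <- sim_fixture(n_lines, n_markers, n_genes_P, n_genes_A,
                           seed = seed)
  if (is.null(truth)) {
    truth <- sim_params(fixture, seed = seed + 1L)
    if (zero_rescov_data) truth$R[1, 2] <- truth$R[2, 1] <- 0
  }
  kv_gen <- NULL
  if (calibrate) {
    pilot <- sim_dataset(fixture, truth, scheme, weights = weights,
                         constant = constant, seed = seed + 99L)
    cal_model <- if (scheme == "nonlinear") "nse" else "olm"
    if (verbose) message("calibration fit (", cal_model, ")")
    cal_fit <- nse(pilot, model = cal_model, n_iter = n_iter,
                   burn_in = burn_in, thin = thin,
                   sigma_prop2 = sigma_prop2, seed = seed + 999L)
    truth <- sim_params_from_fit(cal_fit)
    if (zero_rescov_data) truth$R[1, 2] <- truth$R[2, 1] <- 0
    if (scheme == "nonlinear") {
      weights <- truth$weights
      kv_gen <- truth$kv
    } else {
      kv_gen <- cal_fit$kv
    }
  }
  rows <- list(); dws <- numeric(0); failed <- 0L
  for (r in seq_len(n_reps)) {
    dat <- sim_dataset(fixture, truth, scheme, weights = weights,
                       constant = constant, kv = kv_gen,
                       seed = seed + 100L + r)
    tr <- attr(dat, "truth")
    fits <- list()
    for (mod in models) {
      fit <- tryCatch(
        nse(dat, model = mod, n_iter = n_iter, burn_in = burn_in,
            thin = thin, sigma_prop2 = sigma_prop2,
            seed = seed + 1000L + r),
        error = function(e) {
          warning("replicate ", r, " (", mod, ") failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) { failed <- failed + 1L; next }
      fits[[mod]] <- fit
      rm <- recovery_metrics(tr, fit)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, model = mod, cor_L = rm[["cor_L"]],
        cor_uA = rm[["cor_uA"]], cor_betaA = rm[["cor_betaA"]],
        waic = waic(fit)$waic)
    }
    if (!is.null(fits$nse) && !is.null(fits$olm))
      dws <- c(dws, delta_waic(fits$nse, fits$olm))
    if (verbose) message("replicate ", r, " done")
  }
  reps <- do.call(rbind, rows)
  agg <- function(v) if (sum(!is.na(v)) < 2L)
    c(mean = mean(v, na.rm = TRUE), sd = NA_real_)
  else c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  summ <- do.call(rbind, lapply(split(reps, reps$model), function(dd) {
    data.frame(model = dd$model[1L],
               cor_L_mean = agg(dd$cor_L)[1L], cor_L_sd = agg(dd$cor_L)[2L],
               cor_uA_mean = agg(dd$cor_uA)[1L], cor_uA_sd = agg(dd$cor_uA)[2L],
               cor_betaA_mean = agg(dd$cor_betaA)[1L],
               cor_betaA_sd = agg(dd$cor_betaA)[2L],
               waic_mean = agg(dd$waic)[1L], waic_sd = agg(dd$waic)[2L])
  }))
  structure(list(scheme = scheme, replicates = reps, summary = summ,
                 delta_waic = if (length(dws))
                   c(mean = mean(dws),
                     sd = if (length(dws) > 1L) stats::sd(dws) else NA_real_)
                 else NULL,
                 failed = failed, truth = truth),
            class = "nse_study")
}

#' @export
print.nse_study <- function(x, ...) {
  cat("Replicate recovery study, scheme:", x$scheme, "\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$delta_waic))
    cat(sprintf("delta WAIC (NSE - OLM): mean %.2f (SD %.2f)\n",
                x$delta_waic[1L], x$delta_waic[2L]))
  if (x$failed > 0L) cat(x$failed, "replicate fits failed\n")
  invisible(x)
}
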