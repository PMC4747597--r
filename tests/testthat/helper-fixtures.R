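# Small in-code fixtures shared across test files.

# Tiny deterministic dataset: n lines, intercept-only or gene designs,
# identity-ish kinship from a handful of markers.
tiny_data <- function(n = 10L, seed = 42L, genes = TRUE) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  markers <- matrix(sample(c(-1, 1), n * 40L, replace = TRUE), n,
                    dimnames = list(ids, paste0("m", 1:40)))
  pheno <- data.frame(line_id = ids,
                      dh = rnorm(n, 100, 8),
                      cl = rnorm(n, 90, 10))
  g <- if (genes) data.frame(line_id = ids,
                             g1 = rbinom(n, 1, 0.4),
                             g2 = rbinom(n, 1, 0.3)) else NULL
  if (genes) {                      # keep the design full rank
    g$g1[1:2] <- c(0, 1); g$g2[1:2] <- c(1, 0)
  }
  bivariate_data(pheno, genes = g,
                 manifest = if (genes) c(g1 = "both", g2 = "A") else NULL,
                 markers = markers)
}

# A random valid parameter state for likelihood tests.
random_params <- function(data, kv = NULL, with_spline = TRUE, seed = 1L) {
  set.seed(seed)
  A <- matrix(rnorm(4), 2); R <- crossprod(A) + diag(0.5, 2)
  list(beta_P = rnorm(ncol(data$X_P)),
       beta_A = rnorm(ncol(data$X_A)),
       u_P = rnorm(data$n), u_A = rnorm(data$n),
       G = diag(2), R = R,
       P = if (with_spline) rnorm(kv$n_basis, 0, 0.5) else NULL)
}

# Independent oracle for the bivariate normal log-density: conditional
# factorization through dnorm, a different route than the quadratic form.
oracle_bvn_log <- function(e1, e2, R) {
  dnorm(e1, 0, sqrt(R[1, 1]), log = TRUE) +
    dnorm(e2, (R[1, 2] / R[1, 1]) * e1,
          sqrt(R[2, 2] - R[1, 2]^2 / R[1, 1]), log = TRUE)
}
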