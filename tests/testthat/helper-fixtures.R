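# Shared fixtures, built in code. The small cohort keeps most unit tests
# fast; heavier simulations build their own inputs.

small_config <- function(seed = 7, ...) {
  cohort_config(n_subjects = 98, n_probes = 400, n_modules = 3,
                module_size = 20, seed = seed, ...)
}

# Cached default small cohort + methylation (regenerated once per test run).
.fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_config())
  }
  .fixture_env$cohort
}
small_meth <- function() {
  if (is.null(.fixture_env$meth)) {
    .fixture_env$meth <- generate_methylation(small_cohort())
  }
  .fixture_env$meth
}

# Correlated-block matrix: `blocks` latent factors, `per_block` probes each,
# plus independent noise probes. Used for network and eigengene tests.
planted_blocks <- function(seed, n = 80, blocks = 3, per_block = 20,
                           n_noise = 40, load_lo = 0.8, load_hi = 1.2,
                           noise_sd = 0.4) {
  set.seed(seed)
  cols <- list()
  labels <- integer(0)
  for (b in seq_len(blocks)) {
    z <- rnorm(n)
    load <- runif(per_block, load_lo, load_hi)
    cols[[b]] <- outer(z, load) + matrix(rnorm(n * per_block, sd = noise_sd), n)
    labels <- c(labels, rep(b, per_block))
  }
  X <- cbind(do.call(cbind, cols), matrix(rnorm(n * n_noise), n))
  labels <- c(labels, rep(0L, n_noise))
  colnames(X) <- sprintf("p%03d", seq_len(ncol(X)))
  names(labels) <- colnames(X)
  list(x = X, labels = labels)
}

# Single-factor loading ladder whose connectivity follows a truncated power
# law at soft power `beta0` (loadings l_i with l_i^beta0 ~ Pareto).
planted_scale_free <- function(seed, n = 150, m = 1000, beta0 = 6,
                               gamma = 2.5, lmax = 0.95, kcap = 50) {
  set.seed(seed)
  kraw <- pmin((runif(m))^(-1 / (gamma - 1)), kcap)
  l <- lmax * (kraw / kcap)^(1 / beta0)
  z <- rnorm(n)
  X <- outer(z, l) + matrix(rnorm(n * m), n) * rep(sqrt(1 - l^2), each = n)
  colnames(X) <- sprintf("p%04d", seq_len(m))
  X
}

# Direct triple-loop TOM oracle (independent of build_network's matrix path).
tom_oracle <- function(resid, power) {
  A <- abs(stats::cor(resid))^power
  diag(A) <- 0
  p <- ncol(A)
  TOM <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { TOM[i, j] <- 1; next }
      l_ij <- 0
      for (u in seq_len(p)) {
        if (u != i && u != j) l_ij <- l_ij + A[i, u] * A[u, j]
      }
      k_i <- sum(A[i, -i]); k_j <- sum(A[j, -j])
      TOM[i, j] <- (l_ij + A[i, j]) / (min(k_i, k_j) + 1 - A[i, j])
    }
  }
  1 - TOM
}

# Brute-force BH step-up oracle: evaluate every cutoff explicitly.
bh_oracle <- function(p, m, fdr) {
  ord <- order(p)
  ps <- p[ord]
  crit <- seq_along(ps) / m * fdr
  pass <- which(ps <= crit)
  sig <- logical(length(p))
  if (length(pass)) sig[ord[seq_len(max(pass))]] <- TRUE
  sig
}

# Closed-form OLS via normal equations (oracle for lm-based fits).
ols_oracle <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# Phenotype table with volumes replaced by pure noise (null exposure effect).
null_phenos <- function(seed, n = 98) {
  cfg <- cohort_config(n_subjects = n, a_effect = 0, b_effect = 0,
                       c_direct = 0, seed = seed)
  generate_cohort(cfg)$phenotypes
}
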