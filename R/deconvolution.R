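# Reference-free cell-type deconvolution by alternating constrained least
# squares: B (samples x probes) ~ P F' with P rows on the simplex (mixing
# proportions) and F entries in [0,1] (cell-type methylation profiles).
# Both block updates are solved exactly (small active-set enumerations), so
# the reconstruction error never increases.

#' Select the most variable probes
#'
#' @param beta samples x probes matrix.
#' @param k number of probes to keep.
#' @return character vector of the k probe ids with largest across-sample
#'   variance; ties broken by probe id (ascending), so the choice is
#'   deterministic.
#' @export
select_variable_probes <- function(beta, k) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(beta)) stop("k exceeds probe count")
  v <- apply(beta, 2, stats::var)
  ids <- colnames(beta)
  ord <- order(-v, ids)
  sort_back <- ids[ord][seq_len(k)]
  sort_back
}

# Exact min ||A x - b|| subject to x >= 0, sum(x) = 1, via an active-set
# iteration on the support (clamp the most negative coordinate, re-solve the
# KKT system, release zeros whose multiplier is negative). Falls back to
# support enumeration if the iteration cycles.
simplex_ls <- function(A, b) {
  K <- ncol(A)
  AtA <- crossprod(A)
  Atb <- as.numeric(crossprod(A, b))
  zero <- logical(K)
  for (iter in seq_len(2^K + K)) {
    free <- which(!zero)
    nf <- length(free)
    if (nf == 0) break
    M <- rbind(cbind(2 * AtA[free, free, drop = FALSE], 1),
               c(rep(1, nf), 0))
    sol <- tryCatch(solve(M, c(2 * Atb[free], 1)), error = function(e) NULL)
    if (is.null(sol)) break
    xf <- sol[seq_len(nf)]
    if (any(xf < -1e-10)) {
      zero[free[which.min(xf)]] <- TRUE
      next
    }
    x <- numeric(K)
    x[free] <- pmax(xf, 0)
    x <- x / sum(x)
    if (!any(zero)) return(x)
    # Multiplier check: zeroed coords need gradient above the free level.
    g <- 2 * (AtA %*% x - Atb)
    mu <- -mean(g[free])
    viol <- which(zero & (g + mu < -1e-10))
    if (!length(viol)) return(x)
    zero[viol[which.min((g + mu)[viol])]] <- FALSE
  }
  simplex_ls_enum(A, b)
}

# Exhaustive support enumeration; exact but exponential in K.
simplex_ls_enum <- function(A, b) {
  K <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^K - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    M <- rbind(cbind(2 * crossprod(As), 1), c(rep(1, length(S)), 0))
    rhs <- c(2 * crossprod(As, b), 1)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    xs <- sol[seq_along(S)]
    if (any(xs < -1e-9)) next
    x <- numeric(K)
    x[S] <- pmax(xs, 0)
    x <- x / sum(x)
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj) { best_obj <- obj; best <- x }
  }
  best
}

# Exact min ||A x - b|| subject to 0 <= x <= 1 via an active-set iteration
# (clamp violated bounds, re-solve the free block, release bounds whose KKT
# multiplier has the wrong sign). Falls back to full enumeration of bound
# patterns if the iteration cycles; K is small either way.
box_ls <- function(A, b) {
  K <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  state <- integer(K)  # 0 free, 1 at lower (0), 2 at upper (1)
  for (iter in seq_len(3^K)) {
    free <- which(state == 0L)
    x <- ifelse(state == 2L, 1, 0)
    if (length(free)) {
      rhs <- Atb[free] - AtA[free, state == 2L, drop = FALSE] %*%
        rep(1, sum(state == 2L))
      xf <- tryCatch(solve(AtA[free, free, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(xf)) break
      if (any(xf < -1e-10) || any(xf > 1 + 1e-10)) {
        # Clamp the worst violator and re-solve.
        lo_viol <- ifelse(xf < 0, -xf, 0)
        hi_viol <- ifelse(xf > 1, xf - 1, 0)
        j <- which.max(pmax(lo_viol, hi_viol))
        state[free[j]] <- if (lo_viol[j] >= hi_viol[j]) 1L else 2L
        next
      }
      x[free] <- pmin(pmax(as.numeric(xf), 0), 1)
    }
    # KKT check on bound coordinates: gradient must push outward.
    g <- 2 * (AtA %*% x - Atb)
    release <- which((state == 1L & g < -1e-10) | (state == 2L & g > 1e-10))
    if (!length(release)) return(as.numeric(x))
    worst <- release[which.max(abs(g[release]))]
    state[worst] <- 0L
  }
  box_ls_enum(A, b)
}

# Exhaustive bound-pattern enumeration; exact but exponential in K.
box_ls_enum <- function(A, b) {
  K <- ncol(A)
  best <- NULL
  best_obj <- Inf
  states <- expand.grid(rep(list(0:2), K))  # 0 free, 1 at 0, 2 at 1
  for (row in seq_len(nrow(states))) {
    st <- as.integer(states[row, ])
    free <- which(st == 0L)
    x <- ifelse(st == 2L, 1, 0)
    resid_b <- b - A %*% x
    if (length(free)) {
      Af <- A[, free, drop = FALSE]
      xf <- tryCatch(qr.solve(Af, resid_b), error = function(e) NULL)
      if (is.null(xf)) next
      if (any(xf < -1e-9) || any(xf > 1 + 1e-9)) next
      x[free] <- pmin(pmax(xf, 0), 1)
    }
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj) { best_obj <- obj; best <- x }
  }
  best
}

#' Reference-free estimation of cell mixture proportions
#'
#' Alternating constrained least squares with multiple random restarts: given
#' proportions, profiles are solved probe-wise under box constraints `[0,1]`;
#' given profiles, each sample's proportions are solved under simplex
#' constraints. Each block update is an exact constrained minimizer, so the
#' reconstruction error is non-increasing across iterations. Components are
#' relabeled by descending mean proportion for deterministic output.
#'
#' @param beta samples x probes beta matrix (typically the top most-variable
#'   probes, e.g. 15k on a full array).
#' @param K number of cell types (default 5).
#' @param max_iter maximum alternations per restart.
#' @param tol relative Frobenius improvement below which iteration stops.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of random restarts; the lowest-error fit is kept.
#' @return object of class `cell_mixture`: `proportions` (samples x K, rows
#'   sum to 1), `profiles` (probes x K in `[0,1]`), `recon_error`,
#'   `error_trace`, `converged`, `K`.
#' @export
estimate_cell_mixture <- function(beta, K = 5, max_iter = 100, tol = 1e-6,
                                  seed = 1, n_starts = 10) {
  n <- nrow(beta); p <- ncol(beta)
  if (K < 1) stop("K must be >= 1")
  if (K > min(n, p)) stop("K exceeds min(samples, probes)")
  B <- as.matrix(beta)

  if (K == 1) {
    profiles <- matrix(pmin(pmax(colMeans(B), 0), 1), ncol = 1,
                       dimnames = list(colnames(beta), "cell1"))
    proportions <- matrix(1, n, 1,
                          dimnames = list(rownames(beta), "cell1"))
    err <- sqrt(sum((B - proportions %*% t(profiles))^2))
    return(structure(list(proportions = proportions, profiles = profiles,
                          recon_error = err, error_trace = err,
                          converged = TRUE, K = 1L),
                     class = "cell_mixture"))
  }
  if (K > qr(B)$rank)
    warning("K exceeds the numerical rank of the beta matrix")

  set.seed(seed)
  # Draw initial proportions in canonical (sorted sample id) order so the
  # result is invariant to the input row order, up to row permutation.
  canon <- if (!is.null(rownames(B))) order(rownames(B)) else seq_len(n)
  best <- NULL
  for (start in seq_len(n_starts)) {
    g <- matrix(stats::rgamma(n * K, 1), n, K)
    P <- matrix(0, n, K)
    P[canon, ] <- g / rowSums(g)
    errs <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # Profiles step: probe-wise box-constrained LS on P.
      Fun <- tryCatch(t(solve(crossprod(P), crossprod(P, B))),
                      error = function(e) NULL)
      if (is.null(Fun)) {
        Fun <- t(solve(crossprod(P) + 1e-8 * diag(K), crossprod(P, B)))
      }
      bad <- which(apply(Fun, 1, function(f)
        any(f < -1e-9 | f > 1 + 1e-9)))
      Fmat <- pmin(pmax(Fun, 0), 1)
      for (j in bad) Fmat[j, ] <- box_ls(P, B[, j])

      # Proportions step: sample-wise simplex-constrained LS on F.
      M <- crossprod(Fmat)
      KKT <- rbind(cbind(2 * M, 1), c(rep(1, K), 0))
      rhs <- rbind(2 * crossprod(Fmat, t(B)), 1)
      sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
      if (is.null(sol)) {
        KKT[seq_len(K), seq_len(K)] <- 2 * M + 1e-8 * diag(K)
        sol <- solve(KKT, rhs)
      }
      Pnew <- t(sol[seq_len(K), , drop = FALSE])
      bad_i <- which(apply(Pnew, 1, function(x) any(x < -1e-9)))
      Pnew[Pnew < 0] <- 0
      Pnew <- Pnew / rowSums(Pnew)
      for (i in bad_i) Pnew[i, ] <- simplex_ls(Fmat, B[i, ])
      P <- Pnew

      err <- sqrt(sum((B - P %*% t(Fmat))^2))
      errs <- c(errs, err)
      # converged: relative improvement below tol, or error at numerical zero
      # (noiseless mixtures drive the error to machine precision)
      if (err < 1e-7 * sqrt(sum(B^2)) ||
          (is.finite(prev) && (prev - err) / max(prev, 1e-12) < tol)) {
        converged <- TRUE
        break
      }
      prev <- err
    }
    if (is.null(best) || err < best$recon_error) {
      best <- list(P = P, F = Fmat, recon_error = err, error_trace = errs,
                   converged = converged)
    }
  }
  if (!best$converged)
    warning("deconvolution did not converge; returning best iterate")

  ord <- order(-colMeans(best$P))
  P <- best$P[, ord, drop = FALSE]
  Fmat <- best$F[, ord, drop = FALSE]
  colnames(P) <- colnames(Fmat) <- paste0("cell", seq_len(K))
  rownames(P) <- rownames(beta)
  rownames(Fmat) <- colnames(beta)
  structure(list(proportions = P, profiles = Fmat,
                 recon_error = best$recon_error,
                 error_trace = best$error_trace,
                 converged = best$converged, K = as.integer(K)),
            class = "cell_mixture")
}

#' @export
print.cell_mixture <- function(x, ...) {
  cat("Reference-free cell mixture: K =", x$K, ",", nrow(x$proportions),
      "samples,", nrow(x$profiles), "probes\n")
  cat("Reconstruction error (Frobenius):", signif(x$recon_error, 5),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  cat("Mean proportions:",
      paste(signif(colMeans(x$proportions), 3), collapse = ", "), "\n")
  invisible(x)
}
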