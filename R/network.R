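# Weighted co-methylation network: covariate residualization, soft-threshold
# selection by scale-free topology fit, unsigned adjacency, topological
# overlap dissimilarity, average-linkage module detection, and module
# eigengenes (first principal component per module).

#' Residualize M-values on nuisance covariates
#'
#' Per-probe ordinary least squares of the M-value on the covariates (age,
#' sex, cell proportions, ancestry components, ...); the intercept is always
#' included. With no covariates the values are mean-centered.
#'
#' @param m samples x probes M-value matrix.
#' @param covariates data.frame or matrix of covariates (rows aligned with
#'   `m`), or NULL for centering only.
#' @return samples x probes residual matrix; every probe's residual vector is
#'   orthogonal to each design column.
#' @export
residualize <- function(m, covariates = NULL) {
  n <- nrow(m)
  if (is.null(covariates) || (!is.null(ncol(covariates)) && ncol(covariates) == 0)) {
    return(scale(m, center = TRUE, scale = FALSE))
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != n) stop("covariates do not align with the matrix rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  if (n <= ncol(X)) stop("more covariates than samples")
  res <- qr.resid(qx, m)
  dimnames(res) <- dimnames(m)
  res
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, probe connectivity `k_i = sum_j |cor_ij|^power`
#' is binned on the log10 scale and `log10 p(k)` is regressed on `log10 k`;
#' the signed fit statistic is `-sign(slope) * adjusted R^2`. The lowest
#' power whose signed fit exceeds `r2_min` is chosen; if none qualifies the
#' best-fitting power is returned with a warning.
#'
#' @param resid samples x probes residual matrix (>= 30 probes).
#' @param candidate_powers numeric vector of powers to scan (>= 2 values).
#' @param r2_min scale-free fit threshold (default 0.90).
#' @param n_bins histogram bins for the degree distribution.
#' @return object of class `soft_threshold`: `power` (chosen), `fit_table`
#'   (power, signed_r2, slope, mean_k), `r2_min`.
#' @export
pick_soft_threshold <- function(resid, candidate_powers = 1:20,
                                r2_min = 0.90, n_bins = 10) {
  if (length(candidate_powers) < 2) stop("need at least 2 candidate powers")
  if (ncol(resid) < 30) stop("need at least 30 probes")
  sds <- apply(resid, 2, stats::sd)
  if (any(sds == 0)) stop("constant probes present; remove before scanning")
  C <- abs(stats::cor(resid))
  diag(C) <- 0
  rows <- lapply(candidate_powers, function(pw) {
    k <- colSums(C^pw)
    ok <- k > 0
    k <- k[ok]
    if (length(unique(k)) < 3) {
      return(data.frame(power = pw, signed_r2 = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    }
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = breaks, include.lowest = TRUE)
    cnt <- tabulate(bin, nbins = n_bins)
    kmid <- tapply(k, bin, mean)
    keep <- cnt > 0 & !is.na(kmid) & kmid > 0
    pk <- cnt[keep] / sum(cnt)
    km <- kmid[keep]
    if (sum(keep) < 3) {
      return(data.frame(power = pw, signed_r2 = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    }
    fit <- stats::lm(log10(pk) ~ log10(km))
    sm <- summary(fit)
    slope <- stats::coef(fit)[2]
    data.frame(power = pw, signed_r2 = -sign(slope) * sm$adj.r.squared,
               slope = unname(slope), mean_k = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  qualifying <- which(!is.na(fit_table$signed_r2) &
                        fit_table$signed_r2 > r2_min)
  if (length(qualifying)) {
    power <- fit_table$power[min(qualifying)]
  } else {
    power <- fit_table$power[which.max(fit_table$signed_r2)]
    warning("no candidate power reached the scale-free fit threshold; ",
            "returning the best-fitting power (", power, ")")
  }
  structure(list(power = power, fit_table = fit_table, r2_min = r2_min),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("Soft threshold chosen: power =", x$power,
      "(scale-free fit threshold", x$r2_min, ")\n")
  print(x$fit_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build the weighted co-methylation network
#'
#' Unsigned adjacency `A_ij = |cor(probe_i, probe_j)|^power` (diagonal 0),
#' topological overlap
#' `TOM_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' `l_ij = sum_u A_iu A_uj` and `TOM_ii = 1`, and dissimilarity `D = 1 - TOM`.
#'
#' @param resid samples x probes residual matrix.
#' @param power soft-threshold exponent (> 0).
#' @return object of class `cometh_network`: `power`, `adjacency`,
#'   `dissimilarity` (both probes x probes).
#' @export
build_network <- function(resid, power) {
  if (power <= 0) stop("power must be positive")
  C <- suppressWarnings(stats::cor(resid))  # zero-sd warning becomes an error
  if (any(!is.finite(C))) stop("non-finite correlations (constant probes?)")
  A <- abs(C)^power
  diag(A) <- 0
  k <- colSums(A)
  L <- A %*% A  # l_ij: diagonal of A is 0, so u = i, j are excluded
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  D <- 1 - TOM
  D <- (D + t(D)) / 2  # enforce exact symmetry against rounding
  diag(D) <- 0
  dimnames(A) <- dimnames(D) <- list(colnames(resid), colnames(resid))
  structure(list(power = power, adjacency = A, dissimilarity = D),
            class = "cometh_network")
}

#' @export
print.cometh_network <- function(x, ...) {
  cat("Co-methylation network:", nrow(x$adjacency), "probes, power =",
      x$power, "\n")
  cat("Mean adjacency:", signif(mean(x$adjacency), 3),
      "| mean dissimilarity:", signif(mean(x$dissimilarity), 3), "\n")
  invisible(x)
}

#' Detect co-methylation modules by hierarchical clustering
#'
#' Average-linkage clustering of the TOM dissimilarity with a static cut at a
#' fixed height on the `1 - TOM` scale (uncorrelated probes merge at heights
#' near 1, so the default cut of 0.99 leaves background probes unclustered
#' while tight modules, which merge far below, survive). Clusters smaller
#' than `min_size` are dissolved to label 0 (unassigned); surviving modules
#' are renumbered by descending size and named from a fixed color palette.
#'
#' @param network a `cometh_network`.
#' @param min_size minimum module size (>= 2; default 10).
#' @param cut_height static dendrogram cut height on the dissimilarity scale
#'   (default 0.99).
#' @return object of class `module_set`: `labels` (named integer, 0 =
#'   unassigned), `module_names`, `sizes`, `cut_height`, `n_modules`.
#' @export
detect_modules <- function(network, min_size = 10, cut_height = 0.99) {
  if (min_size < 2) stop("min_size must be >= 2")
  D <- network$dissimilarity
  probes <- rownames(D)
  n <- nrow(D)
  if (n < min_size) {
    labels <- stats::setNames(integer(n), probes)
    return(structure(list(labels = labels, module_names = character(0),
                          sizes = integer(0), cut_height = NA_real_,
                          n_modules = 0L), class = "module_set"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cut_h <- cut_height
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(n)
  if (length(keep)) {
    kept_sizes <- sizes[as.character(keep)]
    # Renumber by descending size; ties broken by first-appearing probe.
    first_probe <- vapply(keep, function(cl) min(which(raw == cl)), integer(1))
    ord <- keep[order(-as.integer(kept_sizes), first_probe)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  names(labels) <- probes
  n_mod <- max(labels, 0L)
  structure(list(labels = labels,
                 module_names = module_color_names(n_mod),
                 sizes = if (n_mod) tabulate(labels, n_mod) else integer(0),
                 cut_height = cut_h, n_modules = as.integer(n_mod)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", x$n_modules, "modules,",
      sum(x$labels == 0), "unassigned probes (cut height",
      signif(x$cut_height, 3), ")\n")
  if (x$n_modules)
    print(stats::setNames(x$sizes, x$module_names))
  invisible(x)
}

#' Module eigengenes (first principal component per module)
#'
#' Probes in each module are standardized; the module eigengene is the sample
#' score vector of the first right singular direction, scaled to unit
#' variance, with sign chosen so its mean correlation with the module's
#' probes is positive.
#'
#' @param resid samples x probes residual matrix containing every module
#'   probe.
#' @param modules a `module_set` (or named integer vector of labels).
#' @return samples x modules matrix; `attr(, "var_explained")` holds the
#'   fraction of standardized module variance captured by each eigengene.
#' @export
module_eigengenes <- function(resid, modules) {
  labels <- if (inherits(modules, "module_set")) modules$labels else modules
  mod_names <- if (inherits(modules, "module_set")) modules$module_names
               else module_color_names(max(labels, 0L))
  n_mod <- max(labels, 0L)
  if (n_mod == 0) stop("no modules to summarize")
  missing <- setdiff(names(labels)[labels > 0], colnames(resid))
  if (length(missing)) stop("module probes missing from residual matrix")
  me <- matrix(NA_real_, nrow(resid), n_mod,
               dimnames = list(rownames(resid), mod_names[seq_len(n_mod)]))
  ve <- numeric(n_mod)
  for (m in seq_len(n_mod)) {
    probes <- names(labels)[labels == m]
    if (length(probes) < 1) stop("module ", m, " has no probes")
    Z <- scale(resid[, probes, drop = FALSE])
    if (any(!is.finite(Z))) stop("constant probe in module ", m)
    if (length(probes) == 1) {
      scores <- Z[, 1]
      ve[m] <- 1
    } else {
      sv <- svd(Z, nu = 1, nv = 0)
      scores <- sv$u[, 1] * sv$d[1]
      ve[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    scores <- scores / stats::sd(scores)
    if (mean(stats::cor(scores, Z)) < 0) scores <- -scores
    me[, m] <- scores
  }
  attr(me, "var_explained") <- stats::setNames(ve, colnames(me))
  me
}
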