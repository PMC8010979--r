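# Methylation array preprocessing: M-value transform, quantile normalization,
# probe filters (X/Y/rs/cross-hybridizing), and the cross-tissue correlation
# filter that restricts analysis to probes with saliva-brain concordance.

#' Beta to M-value transform (and back)
#'
#' Beta values are clipped to `[eps, 1 - eps]` and logit-transformed in base
#' 2: `M = log2(beta / (1 - beta))`. The transform is monotone and
#' `m_to_beta(beta_to_m(x)) == x` away from the clipping bounds.
#'
#' @param beta numeric vector/matrix of beta values.
#' @param eps clipping bound in (0, 0.5); keeps M finite at the boundaries.
#' @return numeric object of the same shape on the M scale.
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8, 0.2))  # 0, 2, -2
beta_to_m <- function(beta, eps = 1e-6) {
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  if (any(!is.finite(beta))) stop("non-finite beta values")
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (!is.null(dim(beta))) dim(m) <- dim(beta)
  dimnames(m) <- dimnames(beta)
  m
}

#' @rdname beta_to_m
#' @param m numeric vector/matrix of M-values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("non-finite M-values")
  2^m / (1 + 2^m)
}

#' Quantile-normalize a samples-by-probes beta matrix
#'
#' Forces every sample's value distribution onto the across-sample mean of
#' sorted vectors, preserving within-sample ranks (ties share the mean of the
#' tied positions). Delegates to [limma::normalizeQuantiles()].
#'
#' @param beta samples x probes matrix (>= 2 samples).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(beta) {
  if (nrow(beta) < 2) stop("need at least 2 samples")
  out <- t(limma::normalizeQuantiles(t(beta), ties = TRUE))
  dimnames(out) <- dimnames(beta)
  out
}

#' Remove X/Y/rs-mapped (and optionally cross-hybridizing) probes
#'
#' @param m samples x probes matrix (M-values or betas).
#' @param manifest probe manifest covering every matrix probe (columns:
#'   probe_id, chromosome, is_rs_probe, is_crosshyb).
#' @param drop_crosshyb also remove cross-hybridizing probes?
#' @return list: `matrix` (filtered), `report` (data.frame reason/count; a
#'   probe flagged for several reasons is counted once per reason but removed
#'   once).
#' @export
filter_probes <- function(m, manifest, drop_crosshyb = TRUE) {
  probes <- colnames(m)
  idx <- match(probes, manifest$probe_id)
  if (anyNA(idx)) stop("probe(s) missing from manifest: ",
                       paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  man <- manifest[idx, ]
  is_x <- man$chromosome == "X"
  is_y <- man$chromosome == "Y"
  is_rs <- as.logical(man$is_rs_probe)
  is_ch <- as.logical(man$is_crosshyb)
  drop <- is_x | is_y | is_rs | (drop_crosshyb & is_ch)
  report <- data.frame(
    reason = c("chrX", "chrY", "rs_mapped", "cross_hybridizing",
               "removed_total", "retained"),
    count = c(sum(is_x), sum(is_y), sum(is_rs),
              if (drop_crosshyb) sum(is_ch) else 0L,
              sum(drop), sum(!drop)),
    stringsAsFactors = FALSE)
  list(matrix = m[, !drop, drop = FALSE], report = report)
}

#' Retain probes correlated between saliva and a cross-tissue reference
#'
#' For each shared probe, the two-sided Pearson correlation p-value (t
#' transform, n - 2 df) between the saliva column and the paired reference
#' column is computed; probes with p < alpha are retained. Constant columns
#' cannot be tested and are dropped with a warning.
#'
#' @param saliva samples x probes matrix (M-values or betas).
#' @param reference paired cross-tissue matrix sharing probe ids (and sample
#'   pairing by row).
#' @param alpha retention threshold on the correlation p-value.
#' @return list: `retained` (character probe ids), `table` (per-probe r, p),
#'   `matrix` (saliva matrix restricted to retained probes).
#' @export
brain_saliva_filter <- function(saliva, reference, alpha = 0.05) {
  shared <- intersect(colnames(saliva), colnames(reference))
  if (length(shared) == 0) stop("no shared probes between saliva and reference")
  n <- nrow(saliva)
  if (n < 3) stop("need at least 3 paired samples")
  s <- saliva[, shared, drop = FALSE]
  r <- reference[, shared, drop = FALSE]
  rr <- paired_column_cor(s, r)
  if (anyNA(rr)) {
    warning(sum(is.na(rr)), " constant probe(s) dropped from correlation filter")
  }
  p <- rep(NA_real_, length(shared))
  ok <- !is.na(rr)
  p[ok] <- cor_pvalue(rr[ok], n)
  tab <- data.frame(probe_id = shared, r = rr, p = p,
                    stringsAsFactors = FALSE)
  retained <- shared[ok & p < alpha]
  list(retained = retained, table = tab,
       matrix = saliva[, retained, drop = FALSE])
}
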