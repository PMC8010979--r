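# Association stage: descriptive statistics (pairwise correlations, paired
# hemisphere t-tests) and the three gated regression arms with
# Benjamini-Hochberg control. Arm A: exposure -> regional volume with full
# covariates. Arm B: exposure -> module eigengene with the stress score as
# the only covariate (other nuisance effects were removed upstream by
# residualization). Arm C: module eigengene -> regional volume with the Arm A
# covariates.

.arm_a_covariates <- function(include_tbv = TRUE) {
  c("age", "sex", "sle", paste0("mds", 1:4), if (include_tbv) "tbv")
}

# Extract a tidy coefficient table + model stats from an lm fit.
.arm_result <- function(fit, arm, outcome, focal_term) {
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(arm = arm, outcome = outcome, focal_term = focal_term,
                 coefficients = coefs, adj_r_squared = sm$adj.r.squared,
                 rse = sm$sigma, n = length(stats::fitted(fit)),
                 focal = coefs[coefs$term == focal_term, , drop = FALSE]),
            class = "arm_fit")
}

#' @export
print.arm_fit <- function(x, ...) {
  cat("Arm", x$arm, "model:", x$outcome, "~ ...,",
      "n =", x$n, "\n")
  cat(sprintf("Adj. R^2 = %.3f, RSE = %.1f\n", x$adj_r_squared, x$rse))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

# Shared model-frame builder: female coded 1, listwise deletion.
.assoc_frame <- function(phenos, extra = NULL) {
  df <- data.frame(feh = phenos$feh,
                   age = phenos$age,
                   sex = as.numeric(phenos$sex == "female"),
                   sle = phenos$sle,
                   phenos[, paste0("mds", 1:4)],
                   tbv = phenos$tbv)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

#' Pairwise Pearson correlation map
#'
#' Symmetric correlation and p-value matrices over the numeric columns of a
#' table (phenotypes, optionally cbound with module eigengenes); p-values via
#' the t transform on pairwise-complete observations.
#'
#' @param table data.frame or matrix; non-numeric columns are dropped.
#' @return object of class `cor_map`: `r`, `p`, `n` matrices.
#' @export
correlation_heatmap <- function(table) {
  df <- as.data.frame(table)
  num <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  x <- as.matrix(num)
  if (any(apply(x, 2, stats::sd, na.rm = TRUE) == 0))
    stop("constant variable in correlation map")
  r <- stats::cor(x, use = "pairwise.complete.obs")
  nmat <- crossprod(!is.na(x))
  if (any(nmat < 3)) stop("need at least 3 complete observations per pair")
  p <- cor_pvalue(r, nmat)
  diag(p) <- 0
  structure(list(r = r, p = p, n = nmat), class = "cor_map")
}

#' @export
print.cor_map <- function(x, ...) {
  cat("Pairwise Pearson correlations over", ncol(x$r), "variables\n")
  print(round(x$r, 2))
  invisible(x)
}

#' @export
plot.cor_map <- function(x, ...) {
  k <- ncol(x$r)
  graphics::image(seq_len(k), seq_len(k), t(x$r[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(51, "Blue-Red"), ...)
  graphics::axis(1, seq_len(k), colnames(x$r), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(colnames(x$r)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Paired t-test between hemisphere volumes
#'
#' @param left,right equal-length paired volume vectors (mm^3).
#' @return list: `t`, `df`, `p`, `mean_left`, `mean_right`, `mean_diff`.
#' @export
paired_t <- function(left, right) {
  if (length(left) != length(right)) stop("paired vectors differ in length")
  if (length(left) < 2) stop("need at least 2 pairs")
  d <- left - right
  if (stats::sd(d) == 0) stop("zero-variance difference")
  tt <- stats::t.test(left, right, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_left = mean(left), mean_right = mean(right),
       mean_diff = mean(d))
}

#' Arm A: exposure predicts regional volume
#'
#' OLS of a regional volume on the FEH score plus age, sex (female = 1),
#' past-year SLE score, four ancestry components, and (by default) total
#' brain volume. Unstandardized coefficients.
#'
#' @param phenos phenotype table (see [generate_cohort()] for columns).
#' @param region name of the volume column to model.
#' @param include_tbv include total brain volume as a covariate?
#' @return an `arm_fit` (focal term: `feh`).
#' @export
fit_arm_a <- function(phenos, region, include_tbv = TRUE) {
  df <- .assoc_frame(phenos)
  df$.outcome <- phenos[[region]]
  form <- stats::reformulate(c("feh", .arm_a_covariates(include_tbv)),
                             response = ".outcome")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design in Arm A model")
  .arm_result(fit, "A", region, "feh")
}

#' Arm B: exposure predicts a module eigengene
#'
#' OLS of the eigengene on FEH with the SLE score as the only covariate
#' (age/sex/cell/ancestry effects were removed by residualization upstream).
#'
#' @param me numeric eigengene vector aligned with `phenos` rows.
#' @param phenos phenotype table.
#' @param me_name label for the eigengene (reporting only).
#' @return an `arm_fit` (focal term: `feh`).
#' @export
fit_arm_b <- function(me, phenos, me_name = "ME") {
  if (stats::sd(me) == 0) stop("constant eigengene")
  df <- data.frame(me = me, feh = phenos$feh, sle = phenos$sle)
  fit <- stats::lm(me ~ feh + sle, data = df)
  .arm_result(fit, "B", me_name, "feh")
}

#' Arm C: a module eigengene predicts regional volume
#'
#' Same covariates as Arm A, with the eigengene replacing FEH as the focal
#' predictor.
#'
#' @inheritParams fit_arm_a
#' @param me numeric eigengene vector aligned with `phenos` rows.
#' @param me_name label for the eigengene; becomes the focal term name.
#' @return an `arm_fit` (focal term: the eigengene).
#' @export
fit_arm_c <- function(phenos, region, me, me_name = "ME",
                      include_tbv = TRUE) {
  df <- .assoc_frame(phenos)
  df$.me <- me
  df$.outcome <- phenos[[region]]
  form <- stats::reformulate(c(".me", .arm_a_covariates(include_tbv)),
                             response = ".outcome")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design in Arm C model")
  res <- .arm_result(fit, "C", region, ".me")
  res$coefficients$term[res$coefficients$term == ".me"] <- me_name
  res$focal_term <- me_name
  res$focal <- res$coefficients[res$coefficients$term == me_name, ,
                                drop = FALSE]
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Each p-value gets a rank-based critical value `rank / m * fdr`; the
#' step-up rule flags every test up to the largest rank whose p-value is at
#' or below its critical value. `m_tests` may exceed the number of supplied
#' p-values when correcting within a larger declared family.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m_tests family size (>= `length(pvals)`).
#' @param fdr accepted false discovery rate in (0, 1).
#' @return data.frame in input order: `p`, `rank`, `critical`, `significant`.
#' @export
bh_adjust <- function(pvals, m_tests = length(pvals), fdr = 0.10) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (any(pvals < 0 | pvals > 1)) stop("p-values outside [0, 1]")
  if (m_tests < length(pvals)) stop("m_tests smaller than number of p-values")
  rk <- rank(pvals, ties.method = "first")
  critical <- rk / m_tests * fdr
  adj <- stats::p.adjust(pvals, method = "BH", n = m_tests)
  data.frame(p = pvals, rank = rk, critical = critical,
             significant = adj <= fdr)
}

#' Gate models to the next study arm
#'
#' Selects the fits whose focal-term p-value is below `alpha`, preserving
#' input order; dependent variables passing the gate graduate to the next
#' arm.
#'
#' @param results list of `arm_fit` objects.
#' @param alpha gate threshold in (0, 1) (default 0.05).
#' @return data.frame of all fits in input order: `outcome`, `focal_term`,
#'   `estimate`, `p`, `selected`.
#' @export
gate <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(results) == 0) {
    return(data.frame(outcome = character(0), focal_term = character(0),
                      estimate = numeric(0), p = numeric(0),
                      selected = logical(0)))
  }
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(outcome = r$outcome, focal_term = r$focal_term,
               estimate = r$focal$estimate, p = r$focal$p,
               stringsAsFactors = FALSE)
  }))
  out$selected <- out$p < alpha
  out
}
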