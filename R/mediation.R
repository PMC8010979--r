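# Nonparametric-bootstrap causal mediation. The mediator model is the Arm B
# regression (ME ~ FEH + SLE); the outcome model is the Arm A regression with
# the ME added (volume ~ FEH + ME + covariates). With a treatment contrast
# Delta = treat - control on the FEH scale:
#   IDE = a * b * Delta   (a: FEH slope of the mediator model,
#                          b: ME slope of the outcome model)
#   DE  = c' * Delta      (c': FEH slope of the outcome model)
#   TE  = IDE + DE        (exact additivity; no exposure-mediator interaction)
# Uncertainty via case-resampling bootstrap (subjects resampled with
# replacement, both models refit per draw), percentile CIs, and a two-sided
# bootstrap p with a 1/(B+1) continuity floor.

.boot_p <- function(draws, n_boot) {
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  max(min(p, 1), 1 / (n_boot + 1))
}

.effects_from_fits <- function(coef_med, coef_out, delta) {
  a <- coef_med["feh"]
  b <- coef_out[".me"]
  cprime <- coef_out["feh"]
  ide <- unname(a * b * delta)
  de <- unname(cprime * delta)
  c(ide = ide, de = de, te = ide + de)
}

#' Bootstrap mediation of the exposure-volume effect through one mediator
#'
#' @param phenos phenotype table.
#' @param me mediator vector aligned with `phenos` rows (a module eigengene
#'   or a residualized probe M-value).
#' @param region name of the outcome volume column.
#' @param treat_value,control_value exposure contrast endpoints on the FEH
#'   scale; defaults are the observed minimum (poor FEH) and maximum (high
#'   FEH), so effects read as "volume difference under poor vs high FEH".
#' @param n_boot number of bootstrap draws (>= 1).
#' @param seed integer seed for resampling.
#' @param include_tbv include total brain volume in the outcome model?
#' @param mediator_name label for reporting.
#' @return object of class `mediation_fit`: `effects` (data.frame with
#'   estimate, CI bounds, bootstrap p for IDE/DE/TE), `classification`,
#'   `proportion_mediated`, `draws` (n_boot x 3), `treat_value`,
#'   `control_value`, `n_boot`, `seed`, `n_redraws`.
#' @export
mediate <- function(phenos, me, region, treat_value = NULL,
                    control_value = NULL, n_boot = 1000, seed = 1,
                    include_tbv = TRUE, mediator_name = "ME") {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (stats::sd(me) == 0) stop("degenerate (constant) mediator")
  if (is.null(treat_value)) treat_value <- min(phenos$feh)
  if (is.null(control_value)) control_value <- max(phenos$feh)
  if (treat_value == control_value)
    stop("treat_value and control_value must differ")
  delta <- treat_value - control_value

  df <- .assoc_frame(phenos)
  df$.me <- me
  X_med <- cbind(1, feh = df$feh, sle = df$sle)
  out_terms <- c("feh", ".me", .arm_a_covariates(include_tbv))
  X_out <- cbind(1, as.matrix(df[, out_terms]))
  colnames(X_out) <- c("(Intercept)", out_terms)
  y_med <- me
  y_out <- phenos[[region]]
  n <- nrow(df)
  if (qr(X_out)$rank < ncol(X_out)) stop("rank-deficient outcome design")

  p_out <- ncol(X_out)
  fit_pair <- function(idx) {
    fo <- stats::.lm.fit(X_out[idx, , drop = FALSE], y_out[idx])
    if (fo$rank < p_out) return(NULL)  # rank-deficient resample
    cm <- stats::.lm.fit(X_med[idx, , drop = FALSE], y_med[idx])$coefficients
    co <- fo$coefficients
    names(cm) <- colnames(X_med)
    names(co) <- colnames(X_out)
    .effects_from_fits(cm, co, delta)
  }

  point <- fit_pair(seq_len(n))

  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("ide", "de", "te")))
  n_redraws <- 0L
  for (bdx in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      eff <- fit_pair(idx)
      if (!is.null(eff)) break
      n_redraws <- n_redraws + 1L
    }
    draws[bdx, ] <- eff
  }

  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  effects <- data.frame(
    effect = c("IDE", "DE", "TE"),
    estimate = unname(point),
    ci_lower = unname(ci[1, ]),
    ci_upper = unname(ci[2, ]),
    p = c(.boot_p(draws[, "ide"], n_boot),
          .boot_p(draws[, "de"], n_boot),
          .boot_p(draws[, "te"], n_boot)),
    stringsAsFactors = FALSE)

  fit <- structure(list(mediator = mediator_name, outcome = region,
                        effects = effects, draws = draws,
                        treat_value = treat_value,
                        control_value = control_value,
                        n_boot = as.integer(n_boot), seed = as.integer(seed),
                        n_redraws = n_redraws, include_tbv = include_tbv),
                   class = "mediation_fit")
  fit$classification <- classify_mediation(fit)
  fit$proportion_mediated <-
    if (point["te"] != 0) unname(point["ide"] / point["te"]) else NA_real_
  fit
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s (FEH contrast %s vs %s, %d bootstrap draws)\n",
              x$mediator, x$outcome, x$treat_value, x$control_value, x$n_boot))
  ef <- x$effects
  for (i in seq_len(nrow(ef))) {
    cat(sprintf("  %-3s %9.1f  [%8.1f, %8.1f]  p = %.4g\n", ef$effect[i],
                ef$estimate[i], ef$ci_lower[i], ef$ci_upper[i], ef$p[i]))
  }
  cat("  classification:", x$classification)
  if (!is.na(x$proportion_mediated))
    cat(sprintf("  (proportion mediated %.1f%%)",
                100 * x$proportion_mediated))
  cat("\n")
  invisible(x)
}

#' Classify a mediation result as full, partial, or none
#'
#' An effect is "nonzero" when its 95% CI excludes 0. Full mediation: IDE and
#' TE nonzero while DE is not; partial: all three nonzero; otherwise none.
#'
#' @param result a `mediation_fit`, or a list with elements `ide`, `de`, `te`
#'   each a length-2 CI `c(lower, upper)`.
#' @return one of `"none"`, `"partial"`, `"full"`.
#' @export
classify_mediation <- function(result) {
  if (inherits(result, "mediation_fit")) {
    ef <- result$effects
    cis <- list(ide = c(ef$ci_lower[1], ef$ci_upper[1]),
                de = c(ef$ci_lower[2], ef$ci_upper[2]),
                te = c(ef$ci_lower[3], ef$ci_upper[3]))
  } else {
    cis <- result
  }
  nz <- vapply(cis[c("ide", "de", "te")],
               function(ci) ci[1] > 0 || ci[2] < 0, logical(1))
  if (nz[["ide"]] && nz[["te"]] && !nz[["de"]]) return("full")
  if (all(nz)) return("partial")
  "none"
}

#' Proportion of the total effect carried by the mediator
#'
#' @param result a `mediation_fit`, or a list/data.frame with `ide` and `te`
#'   point estimates.
#' @return signed fraction IDE / TE.
#' @export
proportion_mediated <- function(result) {
  if (inherits(result, "mediation_fit")) {
    ide <- result$effects$estimate[1]
    te <- result$effects$estimate[3]
  } else {
    ide <- result$ide
    te <- result$te
  }
  if (te == 0) stop("total effect is zero; proportion undefined")
  ide / te
}

#' Screen candidate mediators over (ME, region) pairs
#'
#' Runs [mediate()] for every candidate pair (as dictated by the gating
#' arms), then applies a single Benjamini-Hochberg correction across all
#' IDE/DE/TE bootstrap p-values (family size = 3 x number of pairs).
#'
#' @param candidates data.frame with columns `me` (eigengene column name)
#'   and `region` (outcome volume column).
#' @param phenos phenotype table.
#' @param me_matrix samples x modules eigengene matrix.
#' @param n_boot,seed,include_tbv passed to [mediate()]; each pair gets an
#'   independent sub-seed derived from `seed`.
#' @param fdr accepted false discovery rate for the BH family.
#' @param ... further arguments passed to [mediate()].
#' @return object of class `mediation_screen`: `report` (long data.frame:
#'   me, region, effect, estimate, ci_lower, ci_upper, p, bh_significant,
#'   classification, proportion_mediated), `fits` (list of `mediation_fit`),
#'   `family_size`.
#' @export
mediation_screen <- function(candidates, phenos, me_matrix, n_boot = 1000,
                             seed = 1, include_tbv = TRUE, fdr = 0.10, ...) {
  if (nrow(candidates) == 0) {
    return(structure(list(report = data.frame(), fits = list(),
                          family_size = 0L), class = "mediation_screen"))
  }
  fits <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fits[[i]] <- mediate(phenos, me_matrix[, candidates$me[i]],
                         candidates$region[i], n_boot = n_boot,
                         seed = seed + i, include_tbv = include_tbv,
                         mediator_name = candidates$me[i], ...)
  }
  report <- do.call(rbind, lapply(fits, function(f) {
    cbind(data.frame(me = f$mediator, region = f$outcome,
                     stringsAsFactors = FALSE),
          f$effects,
          classification = f$classification,
          proportion_mediated = f$proportion_mediated)
  }))
  family_size <- 3L * nrow(candidates)
  bh <- bh_adjust(report$p, m_tests = family_size, fdr = fdr)
  report$bh_significant <- bh$significant
  structure(list(report = report, fits = fits,
                 family_size = family_size),
            class = "mediation_screen")
}

#' @export
print.mediation_screen <- function(x, ...) {
  cat("Mediation screen:", length(x$fits), "mediator/outcome pairs,",
      "BH family of", x$family_size, "tests\n")
  if (nrow(x$report)) {
    print(x$report[, c("me", "region", "effect", "estimate", "p",
                       "bh_significant", "classification")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Probe-wise mediation follow-up within a full-mediator module
#'
#' Applies [mediate()] to each residualized probe M-value in the module, with
#' a BH family of 3 x probe count, and reports each probe's Pearson
#' correlation with the module eigengene.
#'
#' @param probe_resid samples x probes residual M-value matrix restricted to
#'   the module's probes.
#' @param phenos phenotype table.
#' @param region outcome volume column.
#' @param me the module's eigengene (for the probe-ME correlation report).
#' @param n_boot,seed,include_tbv,fdr as in [mediation_screen()].
#' @param ... further arguments passed to [mediate()].
#' @return object of class `mediation_screen` whose report has a `probe_id`
#'   column and an `r_with_me` column.
#' @export
probe_mediation <- function(probe_resid, phenos, region, me, n_boot = 1000,
                            seed = 1, include_tbv = TRUE, fdr = 0.10, ...) {
  probes <- colnames(probe_resid)
  fits <- vector("list", length(probes))
  for (i in seq_along(probes)) {
    fits[[i]] <- mediate(phenos, probe_resid[, i], region, n_boot = n_boot,
                         seed = seed + i, include_tbv = include_tbv,
                         mediator_name = probes[i], ...)
  }
  r_me <- as.numeric(stats::cor(me, probe_resid))
  report <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cbind(data.frame(probe_id = f$mediator, region = f$outcome,
                     r_with_me = r_me[i], stringsAsFactors = FALSE),
          f$effects,
          classification = f$classification)
  }))
  family_size <- 3L * length(probes)
  bh <- bh_adjust(report$p, m_tests = family_size, fdr = fdr)
  report$bh_significant <- bh$significant
  structure(list(report = report, fits = fits, family_size = family_size),
            class = "mediation_screen")
}
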