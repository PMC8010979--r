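# End-to-end pipeline on a synthetic cohort: generate -> preprocess ->
# deconvolve -> network/modules/eigengenes -> gated association arms ->
# mediation screen -> enrichment. Mirrors the analysis flow the package
# implements stage by stage; mainly a convenience for reproducibility
# scripts and the vignette.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param frac_correlated fraction of probes given a true cross-tissue
#'   signal in the synthetic brain/saliva reference.
#' @param alpha gate threshold for graduating dependent variables between
#'   arms.
#' @param fdr accepted false discovery rate for BH corrections.
#' @param n_boot bootstrap draws per mediation fit.
#' @param K number of cell types for the reference-free deconvolution.
#' @param deconv_probes number of most-variable probes fed to deconvolution.
#' @param n_starts deconvolution restarts.
#' @param powers candidate soft-threshold powers.
#' @param min_module_size minimum module size.
#' @return object of class `pipeline_run`; a list with the intermediate
#'   products of every stage (see elements `cohort`, `meth`, `preprocess`,
#'   `mixture`, `network`, `modules`, `eigengenes`, `arm_a`, `gate_a`,
#'   `arm_b`, `gate_b`, `arm_c`, `gate_c`, `mediation`, `enrichment`).
#' @export
run_pipeline <- function(config = cohort_config(), frac_correlated = 0.7,
                         alpha = 0.05, fdr = 0.10, n_boot = 1000, K = 5,
                         deconv_probes = 300, n_starts = 5, powers = 1:12,
                         min_module_size = 10) {
  cohort <- generate_cohort(config)
  phenos <- cohort$phenotypes
  meth <- generate_methylation(cohort)
  ref <- generate_brain_saliva_reference(meth$beta, frac_correlated,
                                         seed = config$seed + 2L)

  # Preprocess: quantile normalize betas, M transform, probe filters,
  # cross-tissue correlation filter.
  qn <- quantile_normalize(meth$beta)
  m <- beta_to_m(qn)
  filt <- filter_probes(m, meth$manifest)
  ref_m <- beta_to_m(ref$reference)
  bsf <- brain_saliva_filter(filt$matrix,
                             ref_m[, colnames(filt$matrix), drop = FALSE],
                             alpha = 0.05)
  m_kept <- bsf$matrix

  # Cellular heterogeneity: reference-free mixture on most-variable probes.
  top <- select_variable_probes(qn, min(deconv_probes, ncol(qn)))
  mixture <- estimate_cell_mixture(qn[, top, drop = FALSE], K = K,
                                   seed = config$seed + 3L,
                                   n_starts = n_starts)
  # Drop one proportion column: rows sum to 1, so the full set is collinear
  # with the intercept.
  cell_covs <- mixture$proportions[, -K, drop = FALSE]

  # Network: residualize on age, sex, cell proportions, ancestry.
  covs <- data.frame(age = phenos$age,
                     sex = as.numeric(phenos$sex == "female"),
                     cell_covs,
                     phenos[, paste0("mds", 1:4)])
  resid <- residualize(m_kept, covs)
  sft <- withCallingHandlers(
    pick_soft_threshold(resid, candidate_powers = powers),
    warning = function(w) invokeRestart("muffleWarning"))
  # If no candidate reached the scale-free fit threshold, the scan's arg-max
  # fallback can land on a power too low to separate modules from background;
  # fall back to the conventional unsigned-network default instead.
  chosen_fit <- sft$fit_table$signed_r2[sft$fit_table$power == sft$power]
  power_use <- if (isTRUE(chosen_fit > sft$r2_min)) sft$power
               else max(sft$power, 6)
  network <- build_network(resid, power_use)
  modules <- detect_modules(network, min_size = min_module_size)
  me <- if (modules$n_modules > 0) module_eigengenes(resid, modules) else NULL

  regions <- .region_table$region
  arm_a <- lapply(regions, function(r) fit_arm_a(phenos, r))
  gate_a <- gate(arm_a, alpha)
  regions_sel <- gate_a$outcome[gate_a$selected]

  arm_b <- gate_b <- arm_c <- gate_c <- NULL
  mediation <- NULL
  if (!is.null(me)) {
    arm_b <- lapply(colnames(me), function(nm)
      fit_arm_b(me[, nm], phenos, me_name = nm))
    gate_b <- gate(arm_b, alpha)
    mes_sel <- gate_b$outcome[gate_b$selected]

    pairs <- expand.grid(me = mes_sel, region = regions_sel,
                         stringsAsFactors = FALSE)
    if (nrow(pairs)) {
      arm_c <- lapply(seq_len(nrow(pairs)), function(i)
        fit_arm_c(phenos, pairs$region[i], me[, pairs$me[i]],
                  me_name = pairs$me[i]))
      gc_tab <- gate(arm_c, alpha)
      gc_tab$me <- pairs$me
      gc_tab$region <- pairs$region
      gate_c <- gc_tab
      cand <- gc_tab[gc_tab$selected, c("me", "region"), drop = FALSE]
      mediation <- mediation_screen(cand, phenos, me, n_boot = n_boot,
                                    seed = config$seed + 10L, fdr = fdr)
    }
  }

  # Enrichment over the retained residualized probes; gene sets include one
  # planted set built from the mediator modules' genes.
  assoc <- probe_association(resid, phenos)
  gs <- gene_scores(assoc, meth$manifest)
  universe <- manifest_gene_universe(meth$manifest)
  hi <- max(10L, min(40L, length(universe) - 2L))
  sets <- generate_gene_sets(meth$manifest, n_sets = 30,
                             size_range = c(min(10L, hi), hi),
                             seed = config$seed + 4L)
  med_probes <- names(meth$true_modules)[
    meth$true_modules %in% config$mediator_module_ids]
  planted <- manifest_gene_universe(
    meth$manifest[meth$manifest$probe_id %in% med_probes, , drop = FALSE])
  if (length(planted) >= 2) sets$PLANTED <- planted
  enr <- test_gene_sets(gs, sets, min_size = 5,
                        max_size = length(universe) - 1, fdr = fdr)
  enr_reduced <- reduce_redundancy(enr, sets, jaccard_max = 0.5)

  structure(list(cohort = cohort, meth = meth, reference = ref,
                 preprocess = list(filter_report = filt$report,
                                   retained = bsf$retained),
                 mixture = mixture, soft_threshold = sft, network = network,
                 modules = modules, eigengenes = me,
                 arm_a = arm_a, gate_a = gate_a,
                 arm_b = arm_b, gate_b = gate_b,
                 arm_c = arm_c, gate_c = gate_c,
                 mediation = mediation,
                 enrichment = list(probe = assoc, genes = gs, sets = sets,
                                   result = enr, reduced = enr_reduced)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$cohort$phenotypes), "subjects,",
      ncol(x$meth$beta), "probes (", length(x$preprocess$retained),
      "retained after filtering)\n")
  cat("Modules detected:", x$modules$n_modules,
      "| regions passing Arm A:", sum(x$gate_a$selected), "\n")
  if (!is.null(x$mediation) && nrow(x$mediation$report)) {
    cls <- unique(x$mediation$report[, c("me", "region", "classification")])
    cat("Mediation classifications:\n")
    print(cls, row.names = FALSE)
  }
  invisible(x)
}
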