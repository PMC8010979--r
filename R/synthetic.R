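# Synthetic cohort generator. Every downstream stage of the pipeline is
# exercised on seeded data with planted structure: correlated probe modules,
# covariate effects, and direct plus module-mediated exposure effects on
# regional brain volumes. Planted truth is returned alongside the data so
# recovery can be tested.

# Region volume means/SDs (mm^3) on the scale of a young-adult university
# cohort (n = 98, ages 18-22).
.region_table <- data.frame(
  region = c("hipp_left", "hipp_right", "dlpfc_left", "dlpfc_right",
             "mpfc_left", "mpfc_right", "amyg_left", "amyg_right"),
  mean = c(4650, 4741, 11980, 10639, 5745, 5790, 1655, 1859),
  sd = c(446, 392, 1785, 1585, 853, 717, 186, 210),
  stringsAsFactors = FALSE
)
.tbv_mean <- 1.2e6
.tbv_sd <- 1.2e5

# One-factor probit item model for the 70-item family-history questionnaire:
# P(item = "no" | u) = pnorm(tau + lambda * u), u ~ N(0,1). Calibrated so the
# item sum has mean ~60 and SD ~8.5 over the latent distribution.
.feh_item_loading <- 0.55
.feh_item_threshold <- stats::qnorm(60 / 70) * sqrt(1 + .feh_item_loading^2)

#' Configuration for the synthetic cohort generator
#'
#' Bundles the sample size, planted module geometry, and planted effect sizes
#' used by [generate_cohort()] and [generate_methylation()]. Defaults describe
#' the study conditions the pipeline is designed for: 98 subjects, an exposure
#' score summing 70 binary items (mean 60, SD 8.5), an exposure/stress-score
#' correlation of -0.44, and mediation effects sized so the total planted
#' exposure effect on volume is ~10 mm^3 per exposure unit.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_probes total probes, including background probes.
#' @param n_modules number of planted correlated-probe modules.
#' @param module_size probes per planted module (>= 2).
#' @param mediator_module_ids indices of modules whose latent carries the
#'   exposure signal into methylation (and into volumes).
#' @param a_effect exposure -> module-latent slope (latent units per FEH unit).
#' @param b_effect module-latent -> volume slope (mm^3 per latent unit).
#' @param c_direct exposure -> volume direct slope (mm^3 per FEH unit).
#' @param feh_sle_corr target correlation between the FEH and SLE scores
#'   (|r| < 1).
#' @param latent_noise_sd SD of the noise on mediator-module latents.
#' @param probe_noise_sd probe-level noise SD on the M-value scale.
#' @param volume_noise_frac residual volume noise as a fraction of each
#'   region's SD.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 98, n_probes = 1200, n_modules = 3,
                          module_size = 20, mediator_module_ids = 1,
                          a_effect = 0.05, b_effect = 60, c_direct = 7,
                          feh_sle_corr = -0.44, latent_noise_sd = 1,
                          probe_noise_sd = 0.4, volume_noise_frac = 0.7,
                          seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_probes = as.integer(n_probes),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              mediator_module_ids = as.integer(mediator_module_ids),
              a_effect = a_effect, b_effect = b_effect, c_direct = c_direct,
              feh_sle_corr = feh_sle_corr,
              latent_noise_sd = latent_noise_sd,
              probe_noise_sd = probe_noise_sd,
              volume_noise_frac = volume_noise_frac,
              seed = as.integer(seed))
  if (cfg$n_subjects <= 0 || cfg$n_probes <= 0 || cfg$n_modules <= 0)
    stop("all counts must be positive")
  if (cfg$module_size < 2) stop("module_size must be >= 2")
  if (cfg$n_modules * cfg$module_size > cfg$n_probes)
    stop("planted modules do not fit into n_probes")
  if (abs(cfg$feh_sle_corr) >= 1) stop("|feh_sle_corr| must be < 1")
  if (length(cfg$mediator_module_ids) &&
      (any(cfg$mediator_module_ids < 1) ||
       any(cfg$mediator_module_ids > cfg$n_modules)))
    stop("mediator_module_ids out of range")
  structure(cfg, class = "cohort_config")
}

#' Score the 70-item family-history questionnaire
#'
#' Each "no" answer adds one point, so higher scores mean better family
#' emotional health; the score ranges 0-70.
#'
#' @param item_responses character vector of exactly 70 "yes"/"no" answers.
#' @return integer score in `[0, 70]`.
#' @export
#' @examples
#' score_feh(rep("no", 70))   # 70
#' score_feh(rep("yes", 70))  # 0
score_feh <- function(item_responses) {
  if (length(item_responses) != 70)
    stop("expected exactly 70 item responses, got ", length(item_responses))
  if (!all(item_responses %in% c("yes", "no")))
    stop("item responses must be \"yes\" or \"no\"")
  sum(item_responses == "no")
}

#' Generate a synthetic cohort phenotype table with planted effects
#'
#' Draws age uniform on 18-22, sex Bernoulli(0.69 female), an FEH score as the
#' sum of 70 correlated binary items (single latent liability), an SLE score
#' linearly tied to the FEH latent to hit the target correlation, four
#' ancestry components, and regional volumes carrying a direct FEH slope, a
#' total-brain-volume component, and module-mediated effects through latent
#' module scores.
#'
#' @param config a [cohort_config()].
#' @return an object of class `meth_cohort`: list with `phenotypes`
#'   (data.frame), `latents` (subjects x modules matrix of latent module
#'   scores), `feh_items` (subjects x 70 "yes"/"no" matrix), `config`, and
#'   `truth` (the planted slopes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n < 3) stop("need at least 3 subjects")
  set.seed(config$seed)

  subject_id <- sprintf("S%03d", seq_len(n))
  age <- stats::runif(n, 18, 22)
  sex <- factor(ifelse(stats::rbinom(n, 1, 0.69) == 1, "female", "male"),
                levels = c("male", "female"))

  # FEH: one-factor probit items, score = count of "no" answers.
  u <- stats::rnorm(n)
  p_no <- stats::pnorm(.feh_item_threshold + .feh_item_loading * u)
  items <- matrix(stats::rbinom(n * 70, 1, rep(p_no, 70)), nrow = n)
  feh_items <- matrix(ifelse(items == 1, "no", "yes"), nrow = n,
                      dimnames = list(subject_id, sprintf("item%02d", 1:70)))
  feh <- apply(feh_items, 1, score_feh)

  # SLE: linear in the standardized FEH score plus noise, truncated at 0, so
  # the sample correlation lands near the target.
  rho <- config$feh_sle_corr
  zfeh <- as.numeric(scale(feh))
  sle_raw <- 11 + 7.6 * (rho * zfeh + sqrt(1 - rho^2) * stats::rnorm(n))
  sle <- pmax(round(sle_raw), 0)

  mds <- matrix(stats::rnorm(n * 4, sd = 0.05), nrow = n,
                dimnames = list(NULL, paste0("mds", 1:4)))

  # Latent module scores; mediator modules carry the exposure signal.
  latents <- matrix(stats::rnorm(n * config$n_modules), nrow = n,
                    dimnames = list(subject_id,
                                    paste0("module", seq_len(config$n_modules))))
  feh_c <- feh - mean(feh)
  for (m in config$mediator_module_ids) {
    latents[, m] <- config$a_effect * feh_c +
      stats::rnorm(n, sd = config$latent_noise_sd)
  }

  tbv <- stats::rnorm(n, .tbv_mean, .tbv_sd)
  mediator_sum <- if (length(config$mediator_module_ids)) {
    rowSums(latents[, config$mediator_module_ids, drop = FALSE])
  } else rep(0, n)

  vols <- sapply(seq_len(nrow(.region_table)), function(i) {
    mu <- .region_table$mean[i]
    sd_r <- .region_table$sd[i]
    gamma <- 0.5 * sd_r / .tbv_sd  # TBV share of regional variance
    v <- mu + gamma * (tbv - .tbv_mean) + config$c_direct * feh_c +
      config$b_effect * mediator_sum +
      stats::rnorm(n, sd = sd_r * config$volume_noise_frac)
    pmax(v, 1)
  })
  colnames(vols) <- .region_table$region

  phenotypes <- data.frame(subject_id = subject_id, age = age, sex = sex,
                           feh = feh, sle = sle, mds,
                           vols, tbv = tbv, stringsAsFactors = FALSE)
  rownames(phenotypes) <- subject_id

  structure(list(phenotypes = phenotypes, latents = latents,
                 feh_items = feh_items, config = config,
                 truth = list(a_effect = config$a_effect,
                              b_effect = config$b_effect,
                              c_direct = config$c_direct,
                              mediator_module_ids = config$mediator_module_ids)),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort:", nrow(x$phenotypes), "subjects,",
      x$config$n_modules, "planted modules (mediators:",
      paste(x$config$mediator_module_ids, collapse = ","), ")\n")
  cat("FEH mean", round(mean(x$phenotypes$feh), 1), "SD",
      round(stats::sd(x$phenotypes$feh), 1), "| corr(FEH, SLE) =",
      round(stats::cor(x$phenotypes$feh, x$phenotypes$sle), 2), "\n")
  invisible(x)
}

#' Generate a synthetic beta-value matrix with planted probe modules
#'
#' Module probes load on their module's latent score (mediator-module latents
#' carry the exposure signal); age, sex, and true cell-proportion effects are
#' added on the M-value scale; values are inverse-logit transformed to beta in
#' (0,1). The manifest deliberately includes X/Y/rs/cross-hybridizing probes
#' to exercise the preprocessing filters.
#'
#' @param cohort a `meth_cohort` from [generate_cohort()].
#' @param config a [cohort_config()]; defaults to the cohort's own.
#' @param n_cell_types number of true cell types mixed into each sample.
#' @return list of class `meth_data`: `beta` (subjects x probes), `manifest`
#'   (data.frame: probe_id, chromosome, position, gene_symbols, is_rs_probe,
#'   is_crosshyb), `true_modules` (named integer vector, 0 = background),
#'   `cell_props` (true subjects x K proportions), `cell_coef` (probe x K
#'   effect sizes).
#' @export
generate_methylation <- function(cohort, config = cohort$config,
                                 n_cell_types = 5) {
  stopifnot(inherits(cohort, "meth_cohort"))
  n <- nrow(cohort$phenotypes)
  p <- config$n_probes
  if (config$n_modules * config$module_size > p)
    stop("planted modules do not fit into n_probes")
  set.seed(config$seed + 1L)

  probe_id <- sprintf("cg%06d", seq_len(p))
  # True cell mixture (Dirichlet; saliva-like, with substantial
  # subject-to-subject variation in composition).
  alpha <- c(2, 1, 0.7, 0.5, 0.3)[seq_len(n_cell_types)]
  g <- matrix(stats::rgamma(n * n_cell_types, shape = rep(alpha, each = n)),
              nrow = n)
  cell_props <- g / rowSums(g)
  colnames(cell_props) <- paste0("cell", seq_len(n_cell_types))
  rownames(cell_props) <- cohort$phenotypes$subject_id

  # Bimodal baseline methylation, as on arrays.
  base_beta <- stats::rbeta(p, 0.4, 0.4)
  base_beta <- pmin(pmax(base_beta, 0.02), 0.98)
  base_m <- log2(base_beta / (1 - base_beta))

  true_modules <- integer(p)
  names(true_modules) <- probe_id
  M <- matrix(rep(base_m, each = n), nrow = n)

  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    cols <- idx:(idx + config$module_size - 1L)
    true_modules[cols] <- m
    loadings <- stats::runif(config$module_size, 0.8, 1.2)
    M[, cols] <- M[, cols] + outer(cohort$latents[, m], loadings)
    idx <- idx + config$module_size
  }

  # Covariate structure: small age/sex effects everywhere; 30% of probes are
  # cell-type markers with one dominant cell-specific effect (large, as for
  # real lineage-marker CpGs) plus small effects on the other types.
  age_coef <- stats::rnorm(p, sd = 0.02)
  sex_coef <- stats::rnorm(p, sd = 0.1)
  cell_coef <- matrix(0, p, n_cell_types)
  cell_idx <- sample.int(p, size = round(0.3 * p))
  cell_coef[cell_idx, ] <- stats::rnorm(length(cell_idx) * n_cell_types,
                                        sd = 0.3)
  dominant <- sample.int(n_cell_types, length(cell_idx), replace = TRUE)
  cell_coef[cbind(cell_idx, dominant)] <-
    stats::rnorm(length(cell_idx), sd = 5)
  age_c <- cohort$phenotypes$age - mean(cohort$phenotypes$age)
  female <- as.numeric(cohort$phenotypes$sex == "female")
  # Probe-level noise is heterogeneous for background probes (heavy-tailed
  # per-probe variance, as on real arrays, where the most variable sites are
  # dominated by composition and intrinsically noisy probes rather than by
  # any single co-methylation module); module probes keep the nominal noise
  # so planted co-methylation stays tight.
  noise_sd <- rep(config$probe_noise_sd, p)
  bg_probes <- which(true_modules == 0L)
  noise_sd[bg_probes] <- config$probe_noise_sd *
    stats::runif(length(bg_probes), 0.5, 4)
  M <- M + outer(age_c, age_coef) + outer(female, sex_coef) +
    cell_props %*% t(cell_coef) +
    matrix(stats::rnorm(n * p), nrow = n) * rep(noise_sd, each = n)
  beta <- 2^M / (1 + 2^M)
  dimnames(beta) <- list(cohort$phenotypes$subject_id, probe_id)

  # Manifest: background/module probes on autosomes; flag a few deliberate
  # X/Y/rs/cross-hybridizing probes among the background.
  chromosome <- as.character(sample(1:22, p, replace = TRUE))
  is_rs <- logical(p)
  is_crosshyb <- logical(p)
  n_flag <- max(2L, round(0.02 * p))
  bg <- which(true_modules == 0L)
  flagged <- sample(bg, min(length(bg), 4L * n_flag))
  x_idx <- flagged[seq_len(n_flag)]
  y_idx <- flagged[n_flag + seq_len(n_flag)]
  rs_idx <- flagged[2L * n_flag + seq_len(n_flag)]
  ch_idx <- flagged[3L * n_flag + seq_len(n_flag)]
  chromosome[x_idx] <- "X"
  chromosome[y_idx] <- "Y"
  is_rs[rs_idx] <- TRUE
  is_crosshyb[ch_idx] <- TRUE

  n_genes <- max(10L, ceiling(p / 3))
  gene_pool <- sprintf("GENE%04d", seq_len(n_genes))
  n_map <- sample(0:2, p, replace = TRUE, prob = c(0.1, 0.8, 0.1))
  gene_symbols <- vapply(n_map, function(k) {
    if (k == 0) "" else paste(sample(gene_pool, k), collapse = ";")
  }, character(1))

  manifest <- data.frame(probe_id = probe_id, chromosome = chromosome,
                         position = sample.int(2e8, p),
                         gene_symbols = gene_symbols,
                         is_rs_probe = is_rs, is_crosshyb = is_crosshyb,
                         stringsAsFactors = FALSE)

  structure(list(beta = beta, manifest = manifest,
                 true_modules = true_modules, cell_props = cell_props,
                 cell_coef = cell_coef),
            class = "meth_data")
}

#' Generate a paired cross-tissue reference matrix
#'
#' Emulates a paired saliva/brain methylation resource: for a flagged fraction
#' of probes the reference column is the saliva column plus noise on the M
#' scale (a true cross-tissue correlation); the remainder are drawn
#' independently with matched per-probe moments.
#'
#' @param beta subjects x probes beta matrix (the "saliva" tissue).
#' @param frac_correlated fraction of probes with a true cross-tissue signal.
#' @param noise_sd M-scale noise SD added to correlated reference probes.
#' @param seed integer seed.
#' @return list: `reference` (matrix like `beta`), `correlated` (named logical
#'   truth flags).
#' @export
generate_brain_saliva_reference <- function(beta, frac_correlated,
                                            noise_sd = 0.5, seed = 1) {
  if (length(beta) == 0) stop("empty beta matrix")
  if (frac_correlated < 0 || frac_correlated > 1)
    stop("frac_correlated must be in [0, 1]")
  set.seed(seed)
  n <- nrow(beta); p <- ncol(beta)
  m <- beta_to_m(beta)
  correlated <- logical(p)
  names(correlated) <- colnames(beta)
  n_cor <- round(frac_correlated * p)
  if (n_cor > 0) correlated[sample.int(p, n_cor)] <- TRUE

  ref_m <- m
  if (any(correlated)) {
    idx <- which(correlated)
    ref_m[, idx] <- m[, idx] +
      matrix(stats::rnorm(n * length(idx), sd = noise_sd), nrow = n)
  }
  if (any(!correlated)) {
    idx <- which(!correlated)
    mu <- colMeans(m[, idx, drop = FALSE])
    sd_j <- apply(m[, idx, drop = FALSE], 2, stats::sd)
    ref_m[, idx] <- matrix(stats::rnorm(n * length(idx)), nrow = n) *
      rep(pmax(sd_j, 1e-3), each = n) + rep(mu, each = n)
  }
  reference <- 2^ref_m / (1 + 2^ref_m)
  dimnames(reference) <- dimnames(beta)
  list(reference = reference, correlated = correlated)
}

#' Generate synthetic gene sets (with out-of-range decoys)
#'
#' Draws gene sets from the manifest's gene universe, plus one decoy below the
#' size floor and one above the size ceiling so downstream size filtering is
#' exercised.
#'
#' @param manifest probe manifest with a `gene_symbols` column
#'   (semicolon-separated).
#' @param n_sets number of in-range sets.
#' @param size_range length-2 integer vector (floor, ceiling); the ceiling
#'   must be below the universe size so an oversized decoy can be built.
#' @param seed integer seed.
#' @return named list of character vectors (class `gene_sets`); decoys are
#'   named `DECOY_SMALL` / `DECOY_LARGE`.
#' @export
generate_gene_sets <- function(manifest, n_sets = 30, size_range = c(10, 40),
                               seed = 1) {
  universe <- manifest_gene_universe(manifest)
  if (length(universe) == 0) stop("empty gene universe")
  lo <- size_range[1]; hi <- size_range[2]
  if (hi + 1 > length(universe))
    stop("size_range ceiling must be below the universe size (",
         length(universe), ")")
  set.seed(seed)
  sizes <- sample(lo:hi, n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  sets$DECOY_SMALL <- sample(universe, max(1, lo - 1))
  sets$DECOY_LARGE <- sample(universe, hi + 1)
  structure(sets, class = "gene_sets")
}

#' Gene universe of a probe manifest
#' @param manifest probe manifest data.frame.
#' @return sorted character vector of unique gene symbols.
#' @export
manifest_gene_universe <- function(manifest) {
  g <- unlist(strsplit(manifest$gene_symbols, ";", fixed = TRUE))
  sort(unique(g[nzchar(g)]))
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  structure(sets, class = "gene_sets")
}
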