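# Bootstrap mediation: analytic product-of-coefficients recovery, additivity,
# classification, proportion mediated, screens and BH families.

# Phenotypes with an exactly linear mediation structure: the mediator is
# a*feh + b_sle*sle plus a component orthogonal to the mediator design, and
# the outcome is exactly c'*feh + b*me (zero residual), so OLS recovers the
# planted coefficients without sampling error.
exact_mediation_phenos <- function(seed, n = 98, a = 2, b = 3, cprime = 1) {
  ph <- generate_cohort(cohort_config(n_subjects = n, seed = seed))$phenotypes
  set.seed(seed + 1)
  X <- cbind(1, ph$feh, ph$sle)
  z <- qr.resid(qr(X), rnorm(n))
  me <- a * ph$feh + 0.5 * ph$sle + z
  ph$hipp_right <- cprime * ph$feh + b * me
  list(phenos = ph, me = me)
}

test_that("noiseless planted effects are recovered exactly (a*b*delta etc.)", {
  em <- exact_mediation_phenos(seed = 1)
  fit <- mediate(em$phenos, em$me, "hipp_right", treat_value = 34,
                 control_value = 70, n_boot = 50, seed = 2)
  est <- setNames(fit$effects$estimate, fit$effects$effect)
  expect_equal(est[["IDE"]], 2 * 3 * -36, tolerance = 1e-8)
  expect_equal(est[["DE"]], 1 * -36, tolerance = 1e-8)
  expect_equal(est[["TE"]], -252, tolerance = 1e-8)
  # the outcome model has zero residual, so the direct effect is exact in
  # every bootstrap draw (only the mediator model varies with the resample)
  expect_lt(max(abs(fit$draws[, "de"] + 36)), 1e-6)
  expect_lt(diff(range(fit$draws[, "ide"])), 30)  # tight around -216
})

test_that("IDE + DE = TE exactly, per draw and for point estimates", {
  ph <- small_cohort()$phenotypes
  me <- small_cohort()$latents[, 1]
  fit <- mediate(ph, me, "amyg_right", n_boot = 200, seed = 3)
  est <- setNames(fit$effects$estimate, fit$effects$effect)
  expect_equal(est[["IDE"]] + est[["DE"]], est[["TE"]], tolerance = 1e-10)
  expect_lt(max(abs(fit$draws[, "ide"] + fit$draws[, "de"] -
                    fit$draws[, "te"])), 1e-10)
  expect_true(all(fit$effects$ci_lower <= fit$effects$estimate + 1e-8))
  expect_true(all(fit$effects$ci_upper >= fit$effects$estimate - 1e-8))
})

test_that("bootstrap is reproducible under a fixed seed and varies across seeds", {
  ph <- small_cohort()$phenotypes
  me <- small_cohort()$latents[, 1]
  f1 <- mediate(ph, me, "hipp_right", n_boot = 100, seed = 4)
  f2 <- mediate(ph, me, "hipp_right", n_boot = 100, seed = 4)
  expect_identical(f1$draws, f2$draws)
  f3 <- mediate(ph, me, "hipp_right", n_boot = 100, seed = 5)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("default exposure contrast spans the observed FEH range", {
  ph <- small_cohort()$phenotypes
  me <- small_cohort()$latents[, 1]
  fit <- mediate(ph, me, "hipp_right", n_boot = 10, seed = 6)
  expect_identical(fit$treat_value, min(ph$feh))
  expect_identical(fit$control_value, max(ph$feh))
  expect_error(mediate(ph, me, "hipp_right", treat_value = 40,
                       control_value = 40), "differ")
  expect_error(mediate(ph, rep(1, nrow(ph)), "hipp_right"), "degenerate")
  expect_error(mediate(ph, me, "hipp_right", n_boot = 0), "n_boot")
})

test_that("null mediator: IDE centers on zero with nominal CI coverage", {
  covered <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_subjects = 120, a_effect = 0, seed = 9000 + s)
    co <- generate_cohort(cfg)
    fit <- mediate(co$phenotypes, co$latents[, 1], "hipp_right",
                   n_boot = 300, seed = s)
    ide <- fit$effects[fit$effects$effect == "IDE", ]
    ide$ci_lower <= 0 && ide$ci_upper >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.85)
})

test_that("classification follows the CI rule on reference CI patterns", {
  # full: direct effect CI spans 0 while indirect and total do not
  expect_identical(classify_mediation(list(
    ide = c(-117.4, -3.7), de = c(-338.9, 12.9), te = c(-380.1, -44.2))),
    "full")
  # partial: all three CIs exclude 0
  expect_identical(classify_mediation(list(
    ide = c(-161.3, -1.6), de = c(-553.6, -84.3), te = c(-623.6, -152.7))),
    "partial")
  # none: total effect CI spans 0
  expect_identical(classify_mediation(list(
    ide = c(-50, 10), de = c(-100, 50), te = c(-120, 30))), "none")
  # none: only the direct path is nonzero
  expect_identical(classify_mediation(list(
    ide = c(-20, 5), de = c(-300, -50), te = c(-400, -60))), "none")
})

test_that("proportion mediated matches the printed-scale arithmetic", {
  expect_equal(proportion_mediated(list(ide = -111.2, te = -365.7)), 0.304,
               tolerance = 1e-3)
  expect_equal(proportion_mediated(list(ide = -47.9, te = -204.1)), 0.2347,
               tolerance = 1e-3)
  # full mediation (DE = 0) -> the mediator carries the whole effect
  expect_equal(proportion_mediated(list(ide = -5, te = -5)), 1.0)
  expect_error(proportion_mediated(list(ide = 1, te = 0)), "zero")
})

test_that("mediation screen: BH family is 3 x candidate count", {
  ph <- small_cohort()$phenotypes
  me_mat <- cbind(small_cohort()$latents,
                  extra1 = rnorm(98), extra2 = rnorm(98),
                  extra3 = rnorm(98), extra4 = rnorm(98),
                  extra5 = rnorm(98), extra6 = rnorm(98),
                  extra7 = rnorm(98), extra8 = rnorm(98))
  cand <- data.frame(me = colnames(me_mat),
                     region = rep(c("hipp_right", "amyg_right"),
                                  length.out = 11),
                     stringsAsFactors = FALSE)
  scr <- mediation_screen(cand, ph, me_mat, n_boot = 20, seed = 7)
  expect_identical(scr$family_size, 33L)
  expect_identical(nrow(scr$report), 33L)
  empty <- mediation_screen(cand[0, ], ph, me_mat)
  expect_identical(empty$family_size, 0L)
  expect_identical(nrow(empty$report), 0L)
})

test_that("planted mediator classifies as mediator; decoys do not", {
  hits_planted <- logical(0)
  hits_decoy <- logical(0)
  for (s in 1:15) {
    cfg <- cohort_config(n_subjects = 400, seed = 400 + s)
    co <- generate_cohort(cfg)
    scr <- mediation_screen(
      data.frame(me = c("module1", "module2"),
                 region = "hipp_right", stringsAsFactors = FALSE),
      co$phenotypes, co$latents, n_boot = 400, seed = s)
    cls <- tapply(as.character(scr$report$classification),
                  scr$report$me, unique)
    hits_planted <- c(hits_planted, cls[["module1"]] %in% c("full", "partial"))
    hits_decoy <- c(hits_decoy, cls[["module2"]] == "none")
  }
  expect_gte(mean(hits_planted), 0.9)
  expect_gte(mean(hits_decoy), 0.9)
})

test_that("probe-wise follow-up: family size, ME correlation, substitution", {
  co <- small_cohort()
  meth <- small_meth()
  ph <- co$phenotypes
  resid <- residualize(beta_to_m(meth$beta),
                       data.frame(age = ph$age,
                                  sex = as.numeric(ph$sex == "female")))
  probes <- c(names(meth$true_modules)[meth$true_modules == 1],
              names(meth$true_modules)[meth$true_modules == 0][1])
  stopifnot(length(probes) == 21)
  labels <- setNames(rep(1L, 21), probes)
  me <- module_eigengenes(resid[, probes], labels)[, 1]
  pm <- probe_mediation(resid[, probes], ph, "amyg_right", me,
                        n_boot = 50, seed = 8)
  expect_identical(pm$family_size, 63L)
  expect_identical(nrow(pm$report), 63L)
  expect_true(all(abs(pm$report$r_with_me) <= 1))
  # a probe identical to the ME reproduces the module-level IDE
  pseudo <- cbind(me_copy = me, noise = rnorm(98))
  pm2 <- probe_mediation(pseudo, ph, "amyg_right", me, n_boot = 300,
                         seed = 9)
  module_fit <- mediate(ph, me, "amyg_right", n_boot = 300, seed = 10)
  ide_probe <- pm2$report$estimate[pm2$report$probe_id == "me_copy" &
                                   pm2$report$effect == "IDE"]
  ide_module <- module_fit$effects$estimate[1]
  expect_equal(ide_probe, ide_module, tolerance = 1e-8)
})

test_that("planted driver probes out-mediate pure-noise probes", {
  wins <- vapply(1:15, function(s) {
    cfg <- cohort_config(n_subjects = 150, seed = 600 + s)
    co <- generate_cohort(cfg)
    set.seed(s)
    probes <- cbind(driver = co$latents[, 1] + rnorm(150, sd = 0.2),
                    noise = rnorm(150))
    pm <- probe_mediation(probes, co$phenotypes, "hipp_right",
                          co$latents[, 1], n_boot = 30, seed = s)
    ides <- with(pm$report, setNames(estimate[effect == "IDE"],
                                     probe_id[effect == "IDE"]))
    abs(ides[["driver"]]) > abs(ides[["noise"]])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
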