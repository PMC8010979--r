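# Association stage: correlation map, paired t, regression arms, BH, gating.

test_that("correlation map anchors: self, negation, symmetry", {
  set.seed(1)
  x <- rnorm(30)
  tab <- data.frame(x = x, neg = -x + 0, z = rnorm(30))
  cm <- correlation_heatmap(tab)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r["x", "neg"], -1)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$p >= 0 & cm$p <= 1))
  expect_error(correlation_heatmap(data.frame(a = rep(1, 5), b = rnorm(5))),
               "constant")
})

test_that("correlation map on the synthetic cohort shows the planted FEH-SLE link", {
  ph <- small_cohort()$phenotypes
  cm <- correlation_heatmap(ph[, c("feh", "sle", "hipp_right", "tbv")])
  expect_gt(cm$r["feh", "sle"], -0.60)
  expect_lt(cm$r["feh", "sle"], -0.28)
  expect_lt(cm$p["feh", "sle"], 0.01)
})

test_that("paired t-test matches the hand formula and is antisymmetric", {
  left <- c(2, 4, 6); right <- c(1, 2, 3)
  out <- paired_t(left, right)
  # d = (1, 2, 3): t = mean/ (sd/sqrt(3)) = 2 / (1/sqrt(3)) = 2*sqrt(3)
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  swapped <- paired_t(right, left)
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  zero <- paired_t(left, left + c(-1, 0, 1))  # zero-mean difference
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(paired_t(left, right[1:2]), "length")
  expect_error(paired_t(left, left + 1), "zero-variance")
})

test_that("hemisphere asymmetries in the synthetic cohort are testable", {
  ph <- small_cohort()$phenotypes
  out <- paired_t(ph$hipp_left, ph$hipp_right)
  expect_equal(out$df, 97)
  expect_equal(out$mean_diff, out$mean_left - out$mean_right)
})

test_that("Arm A recovers a planted total exposure effect", {
  # a_effect = 0 so the planted total slope is c_direct alone
  cfg <- cohort_config(n_subjects = 5000, a_effect = 0, c_direct = 10,
                       volume_noise_frac = 0.15, seed = 11)
  ph <- generate_cohort(cfg)$phenotypes
  fit <- fit_arm_a(ph, "hipp_right")
  expect_equal(nrow(fit$coefficients), 10L)  # intercept + 9 predictors
  expect_lt(abs(fit$focal$estimate - 10), 0.5)
  expect_lt(fit$focal$p, 1e-10)
})

test_that("Arm A focal p-values are uniform under the null", {
  ps <- vapply(1:60, function(s) {
    ph <- null_phenos(seed = 5000 + s, n = 80)
    fit_arm_a(ph, "amyg_left")$focal$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("regression arms agree with the normal-equations oracle", {
  ph <- small_cohort()$phenotypes
  me <- rnorm(nrow(ph))
  fa <- fit_arm_a(ph, "hipp_right")
  X <- cbind(1, ph$feh, ph$age, as.numeric(ph$sex == "female"), ph$sle,
             as.matrix(ph[, paste0("mds", 1:4)]), ph$tbv)
  expect_equal(unname(fa$coefficients$estimate),
               unname(ols_oracle(X, ph$hipp_right)), tolerance = 1e-8)
  fb <- fit_arm_b(me, ph)
  Xb <- cbind(1, ph$feh, ph$sle)
  expect_equal(unname(fb$coefficients$estimate),
               unname(ols_oracle(Xb, me)), tolerance = 1e-8)
  fc <- fit_arm_c(ph, "hipp_right", me, me_name = "turquoise")
  Xc <- cbind(1, me, ph$age, as.numeric(ph$sex == "female"), ph$sle,
              as.matrix(ph[, paste0("mds", 1:4)]), ph$tbv)
  expect_equal(unname(fc$coefficients$estimate),
               unname(ols_oracle(Xc, ph$hipp_right)), tolerance = 1e-8)
  expect_identical(fc$focal_term, "turquoise")
})

test_that("coefficients rescale inversely with predictor units", {
  ph <- small_cohort()$phenotypes
  fit1 <- fit_arm_a(ph, "amyg_right")
  ph2 <- ph
  ph2$feh <- ph$feh / 10
  fit2 <- fit_arm_a(ph2, "amyg_right")
  expect_equal(fit2$focal$estimate, 10 * fit1$focal$estimate,
               tolerance = 1e-8)
  expect_equal(fit2$focal$p, fit1$focal$p, tolerance = 1e-10)
})

test_that("Arm B recovers the planted exposure-module slope sign", {
  hits <- vapply(1:30, function(s) {
    cfg <- cohort_config(n_subjects = 500, n_probes = 80, module_size = 10,
                         seed = 6000 + s)
    co <- generate_cohort(cfg)
    # latent module score with planted positive a_effect, standardized as an ME
    me <- scale(co$latents[, 1])[, 1]
    fit <- fit_arm_b(me, co$phenotypes)
    sign_ok <- fit$focal$estimate > 0
    sig <- fit$focal$p < 0.05
    sign_ok && sig
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("Arm B type-I rate is nominal when the exposure is permuted", {
  ps <- vapply(1:200, function(s) {
    set.seed(7000 + s)
    ph <- small_cohort()$phenotypes
    ph$feh <- sample(ph$feh)
    fit_arm_b(rnorm(nrow(ph)), ph)$focal$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_error(fit_arm_b(rep(1, 98), small_cohort()$phenotypes), "constant")
})

test_that("Arm C under the null yields uniform focal p-values", {
  ps <- vapply(1:60, function(s) {
    set.seed(8000 + s)
    ph <- null_phenos(seed = 8000 + s, n = 80)
    fit_arm_c(ph, "mpfc_left", rnorm(80))$focal$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH step-up matches the worked examples", {
  out <- bh_adjust(c(0.01, 0.02, 0.9), m_tests = 3, fdr = 0.1)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))
  expect_equal(out$critical, c(1, 2, 3) / 3 * 0.1)
  expect_identical(bh_adjust(0.04, 1, 0.1)$significant, TRUE)
  expect_identical(bh_adjust(rep(1, 5), 5, 0.1)$significant, rep(FALSE, 5))
  expect_error(bh_adjust(c(0.1, 2)), "outside")
  expect_error(bh_adjust(0.5, fdr = 1.5), "fdr")
  expect_error(bh_adjust(c(0.1, 0.2), m_tests = 1), "smaller")
})

test_that("BH step-up equals brute-force enumeration, incl. larger families", {
  set.seed(2)
  for (i in 1:200) {
    k <- sample(1:20, 1)
    p <- round(runif(k), 3)
    m <- k + sample(0:10, 1)
    fdr <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(bh_adjust(p, m, fdr)$significant, bh_oracle(p, m, fdr))
  }
})

test_that("gating keeps sub-alpha fits in input order", {
  ph <- small_cohort()$phenotypes
  fits <- list(fit_arm_a(ph, "hipp_right"), fit_arm_a(ph, "mpfc_left"))
  g <- gate(fits, alpha = 0.999)
  expect_identical(g$outcome, c("hipp_right", "mpfc_left"))
  expect_true(all(g$selected))
  g2 <- gate(fits, alpha = 1e-12)
  expect_false(any(g2$selected))
  expect_identical(nrow(gate(list())), 0L)
  expect_error(gate(fits, alpha = 2), "alpha")
})
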