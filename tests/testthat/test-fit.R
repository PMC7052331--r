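test_that("model stress interpolates exactly on and between grid points", {
  cfg <- fast_cfg(n = 200, d = 0.01, ms = 0.3)
  m <- tissue_moduli(5, 0.5)
  curve <- simulate_curve(cfg, m)$curve
  on_grid <- predict_at_strains(m, cfg, c(0, 0.10, 0.30))
  expect_equal(on_grid, curve$stress[match(c(0, 0.10, 0.30), curve$strain)])
  expect_identical(on_grid[1], 0)
  mid <- predict_at_strains(m, cfg, 0.105)
  expect_equal(mid, mean(curve$stress[match(c(0.10, 0.11), curve$strain)]))
  expect_error(predict_at_strains(m, cfg, 0.31), "exceeds")
})

test_that("noiseless round trips recover the moduli across modulus ratios", {
  cfg <- fit_cfg()
  for (r in c(1, 10, 100)) {
    truth <- tissue_moduli(5, 5 / r)
    crv <- generate_noisy_curve(truth, cfg, seq(0, 0.6, 0.02), 0)
    fit <- fit_moduli(crv, cfg)
    expect_true(fit$converged)
    expect_lt(abs(fit$moduli$y_ae - truth$y_ae) / truth$y_ae, 0.01)
    expect_lt(abs(fit$moduli$y_be - truth$y_be) / truth$y_be, 0.01)
    expect_equal(fit$sse, sum(fit$residuals^2))
  }
})

test_that("fitted moduli scale with a uniformly scaled stress axis", {
  cfg <- fit_cfg()
  crv <- generate_noisy_curve(tissue_moduli(5, 0.5), cfg, seq(0, 0.6, 0.02), 0)
  f1 <- fit_moduli(crv, cfg)
  f2 <- fit_moduli(stress_strain_curve(crv$strain, crv$stress * 2), cfg)
  expect_equal(f2$moduli$y_ae / f1$moduli$y_ae, 2, tolerance = 0.01)
  expect_equal(f2$moduli$y_be / f1$moduli$y_be, 2, tolerance = 0.15)
})

test_that("a near-linear curve still converges but flags Y_be as unidentified", {
  cfg <- fit_cfg()
  crv <- generate_noisy_curve(tissue_moduli(0.01, 1), cfg, seq(0, 0.6, 0.02), 0)
  fit <- fit_moduli(crv, cfg)
  expect_true(fit$converged)
  expect_true(fit$y_be_flat)
  # a strongly stiffening curve must not be flagged
  crv2 <- generate_noisy_curve(young_moduli(), cfg, seq(0, 0.6, 0.02), 0)
  expect_false(fit_moduli(crv2, cfg)$y_be_flat)
})

test_that("fit input validation rejects bad curves", {
  cfg <- fit_cfg()
  expect_error(fit_moduli(data.frame(strain = c(0, 0.1, 0.05),
                                     stress = c(0, 1, 2)), cfg), "increasing")
  expect_error(fit_moduli(data.frame(strain = c(0, 0.1),
                                     stress = c(0, 1)), cfg), ">= 3 points")
})

test_that("volume-fraction conversion matches the reported fiber modulus", {
  d <- derived_moduli(young_moduli(), volume_fractions(0.35, 0.04))
  expect_equal(d$y_a, 4.36 / 0.35)          # ~12.46 kPa per wall
  expect_equal(d$y_f, 311, tolerance = 0.005) # ~311 kPa per fiber
  # identity fractions change nothing
  ident <- derived_moduli(tissue_moduli(1, 1), volume_fractions(1, 1))
  expect_equal(unlist(ident), c(y_a = 1, y_b = 1, y_f = 1))
  # exact inverse linearity: halving the fiber fraction doubles Y_f
  half <- derived_moduli(young_moduli(), volume_fractions(0.35, 0.02))
  expect_equal(half$y_f, 2 * d$y_f)
  expect_error(volume_fractions(0, 0.04), "delta_v_w")
})

test_that("group comparison reproduces hand-computable t-tests", {
  # identical groups: t = 0, p = 1
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3)), 1)
  # 3-point groups, hand-computed Welch t = -1.2247, df = 4, p = 0.2878
  expect_equal(group_compare(c(1, 2, 3), c(2, 3, 4)), 0.28786, tolerance = 1e-4)
  # paired shift with slight jitter is detected at n = 5
  a <- c(1.0, 1.2, 0.9, 1.1, 1.05)
  expect_lt(group_compare(a, a + 10 + c(0.01, -0.02, 0.015, -0.01, 0.005),
                          paired = TRUE), 0.05)
  # degenerate variance warns and returns p = 1
  expect_warning(p <- group_compare(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_equal(p, 1)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("type-I error rate of the group comparison is near nominal", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    group_compare(rnorm(10), rnorm(10)) < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("cohort fitting and group statistics have the reporting shape", {
  cfg <- fast_cfg(n = 300)
  spec_a <- cohort_spec("a", 3, tissue_moduli(4.36, 0.114), moduli_cv = 0.1,
                        noise_sd_fraction = 0.005, seed = 5)
  spec_b <- cohort_spec("b", 3, tissue_moduli(5.86, 0.161), moduli_cv = 0.1,
                        noise_sd_fraction = 0.005, seed = 6)
  cohort <- c(generate_cohort(spec_a, cfg), generate_cohort(spec_b, cfg))
  class(cohort) <- "cohort"
  fits <- fit_cohort(cohort, cfg)
  expect_equal(nrow(fits), 6)
  expect_true(all(c("y_ae", "y_be", "true_y_ae", "converged") %in% names(fits)))
  tab <- group_stats(fits, baseline = "a")
  expect_equal(nrow(tab), 4)  # 2 groups x 2 moduli
  expect_true(all(is.na(tab$p_value[tab$group == "a"])))
  expect_true(all(!is.na(tab$p_value[tab$group == "b"])))
  # single-sample group suppresses statistics with a warning per modulus
  solo <- fits[c(1, 2, 4), ]
  w <- capture_warnings(tab1 <- group_stats(solo, baseline = "a"))
  expect_length(w, 2)
  expect_match(w, "suppressed", all = TRUE)
  expect_true(all(is.na(tab1$se[tab1$group == "b"])))
})
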