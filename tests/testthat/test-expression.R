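test_that("noiseless ddCt recovers planted folds exactly", {
  ct <- generateCtTable(planted_folds = c(APOB = 0.5, CETP = 1.0),
                        noise_sd = 0, seed = 1)
  fa <- ddctFoldChange(ct, "APOB", "GAPDH", "control")
  fc <- ddctFoldChange(ct, "CETP", "GAPDH", "control")
  expect_equal(fa$fold_change, 0.5, tolerance = 1e-12)
  expect_equal(fc$fold_change, 1.0, tolerance = 1e-12)
  expect_equal(fa$sd, 0, tolerance = 1e-12)
})

test_that("ddCt = +1 in every replicate halves expression", {
  # hand-built table: treated target Ct one cycle above control
  mk <- function(g, b, a, ct) data.frame(
    sample = paste0(g, b), group = g, bio_rep = b, tech_rep = 1L,
    assay = a, ct = ct, stringsAsFactors = FALSE)
  ct <- rbind(
    mk("ctl", 1, "REF", 18), mk("ctl", 1, "TGT", 24),
    mk("ctl", 2, "REF", 18), mk("ctl", 2, "TGT", 24),
    mk("trt", 1, "REF", 18), mk("trt", 1, "TGT", 25),
    mk("trt", 2, "REF", 18), mk("trt", 2, "TGT", 25))
  r <- ddctFoldChange(ct, "TGT", "REF", "ctl")
  expect_equal(r$fold_change, 0.5, tolerance = 1e-12)
})

test_that("ddCt is invariant to a constant shift of one sample's Ct values", {
  ct <- generateCtTable(planted_folds = c(APOB = 0.29), noise_sd = 0.05,
                        seed = 3)
  r0 <- ddctFoldChange(ct, "APOB", "GAPDH", "control")
  shifted <- ct
  pick <- shifted$sample == shifted$sample[1]
  shifted$ct[pick] <- shifted$ct[pick] + 3.7   # e.g. different input amount
  r1 <- ddctFoldChange(shifted, "APOB", "GAPDH", "control")
  expect_equal(r1$fold_change, r0$fold_change, tolerance = 1e-12)
})

test_that("planted fold 0.29 with 0.1-cycle noise is recovered within 0.1", {
  ct <- generateCtTable(planted_folds = c(APOB = 0.29), noise_sd = 0.1,
                        n_bio = 3, n_tech = 3, seed = 11)
  r <- ddctFoldChange(ct, "APOB", "GAPDH", "control")
  expect_lt(abs(r$fold_change - 0.29), 0.1)
  expect_identical(r$tier, "**")   # strong knockdown, tiny noise
})

test_that("Ct table validation catches structural problems", {
  ct <- generateCtTable(planted_folds = c(APOB = 0.5), seed = 1)
  expect_silent(validateCtTable(ct, "GAPDH"))
  expect_error(validateCtTable(ct, "SNORD47"), "normalization error")
  bad <- rbind(ct, ct[1, ])
  expect_error(validateCtTable(bad), "duplicate")
  ct$ct[1] <- -1
  expect_error(validateCtTable(ct), "positive")
  expect_error(ddctFoldChange(generateCtTable(c(APOB = 0.5), seed = 1),
                              "LPA", "GAPDH", "control"), "absent")
})

test_that("SD is undefined (flagged) with a single biological replicate", {
  ct <- generateCtTable(planted_folds = c(APOB = 0.5), n_bio = 1,
                        noise_sd = 0, seed = 1)
  expect_warning(r <- ddctFoldChange(ct, "APOB", "GAPDH", "control"),
                 "SD undefined")
  expect_true(is.na(r$sd))
  expect_equal(r$fold_change, 0.5, tolerance = 1e-12)
})

test_that("group comparison separates shifted groups and rejects degenerate input", {
  set.seed(42)
  shifted <- list(ctrl = rnorm(6, 0, 0.1), trt = rnorm(6, 5, 0.1))
  cmp <- groupCompare(shifted, "ctrl")
  expect_lt(cmp$p_vs_control[["trt"]], 0.01)
  expect_lt(cmp$p_anova, 0.01)
  expect_error(groupCompare(list(a = rnorm(5)), "a"), "at least 2 groups")
  expect_error(groupCompare(list(a = 1, b = rnorm(5)), "b"), "degenerate")
  expect_error(groupCompare(list(a = c(1, 1), b = c(1, 1)), "a"),
               "degenerate")
})

test_that("null group comparison keeps type-I error near nominal", {
  set.seed(7)
  rej <- mean(replicate(400, {
    cmp <- groupCompare(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)), "a")
    cmp$p_anova < 0.05
  }))
  # binomial 99% band around 0.05 at n = 400
  expect_gt(rej, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rej, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("normality check accepts normal and rejects exponential samples", {
  set.seed(5)
  pn <- replicate(40, normalityCheck(rnorm(60)))
  pe <- replicate(40, normalityCheck(rexp(60)))
  expect_gte(mean(pn > 0.05), 0.9)
  expect_gte(mean(pe < 0.05), 0.9)
  expect_error(normalityCheck(rnorm(4)), "insufficient data")
  expect_error(normalityCheck(rep(1, 10)), "degenerate")
})

test_that("viability normalization: identity, halving, and planted recovery", {
  v <- generateViabilityPlate(planted_fractions = c(same = 1.0),
                              well_noise = 0, seed = 1)
  r <- viabilityPercent(v, "control")
  expect_true(all(abs(r$viability_percent - 100) < 1e-9))
  v2 <- generateViabilityPlate(planted_fractions = c(half = 0.5),
                               well_noise = 0, seed = 1)
  r2 <- viabilityPercent(v2, "control")
  expect_true(all(abs(r2$viability_percent - 50) < 1e-9))
  # planted 70% viability with 2% well noise, recovered within 5 points
  v3 <- generateViabilityPlate(planted_fractions = c(trt = 0.7),
                               well_noise = 0.02, seed = 9)
  r3 <- viabilityPercent(v3, "control")
  expect_true(all(abs(r3$viability_percent - 70) < 5))
})

test_that("viability error paths: negative signal flag, dead control", {
  v <- generateViabilityPlate(planted_fractions = c(trt = 0.7),
                              well_noise = 0, seed = 1)
  v$a570[1] <- v$a630[1] - 0.01
  expect_warning(validateViabilityTable(v), "negative background")
  dead <- generateViabilityPlate(planted_fractions = c(trt = 0.5),
                                 control_signal = 0, well_noise = 0,
                                 seed = 1)
  expect_error(suppressWarnings(viabilityPercent(dead, "control")),
               "normalization error")
})
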