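test_that("glucose tolerance classification applies the diagnostic rules", {
  expect_equal(classify_glucose_tolerance(7.5, 6.0, FALSE), "T2D")
  expect_equal(classify_glucose_tolerance(5.5, 6.0, FALSE), "NGT")
  expect_equal(classify_glucose_tolerance(6.5, 7.0, FALSE), "INDETERMINATE")
  # strict inequalities at the boundaries
  expect_equal(classify_glucose_tolerance(7.0, 6.0, FALSE), "INDETERMINATE")
  expect_equal(classify_glucose_tolerance(5.0, 11.1, FALSE), "INDETERMINATE")
  expect_equal(classify_glucose_tolerance(6.1, 6.0, FALSE), "INDETERMINATE")
  expect_equal(classify_glucose_tolerance(5.0, 7.8, FALSE), "INDETERMINATE")
  # self-report overrides a measured normal OGTT
  expect_equal(classify_glucose_tolerance(5.0, 5.0, TRUE), "T2D")
  # 2 h criterion alone can make a case even with fasting missing
  expect_equal(classify_glucose_tolerance(NA, 12.0, FALSE), "T2D")
  # cannot confirm NGT with a missing measurement
  expect_equal(classify_glucose_tolerance(5.0, NA, FALSE), "INDETERMINATE")
  expect_error(classify_glucose_tolerance(NA, NA, NA), "missing")
  # partition: no record is both case and control
  sim <- small_cohort(n = 400, m = 20, seed = 41)
  cls <- classify_glucose_tolerance(sim$pheno$fpg_mmol_l,
                                    sim$pheno$glu2h_mmol_l,
                                    sim$pheno$selfreport_dm)
  expect_true(all(cls %in% c("T2D", "NGT", "INDETERMINATE")))
  expect_length(cls, 400)
})

test_that("HOMA-IR matches hand arithmetic and is pure", {
  expect_equal(homa_ir(5.0, 69.45), 2.22222222, tolerance = 1e-8)
  expect_equal(homa_ir(4.5, 6.945), 0.2)
  expect_equal(homa_ir(1e-9, 50), 1e-9 * (50 / 6.945) / 22.5)
  expect_identical(homa_ir(5.3, 48), homa_ir(5.3, 48))
  expect_true(is.na(homa_ir(NA, 50)))
  expect_error(homa_ir(0, 50), "positive")
  expect_error(homa_ir(5, -1), "positive")
})

test_that("ISI(0,120) reproduces the worked example and its structure", {
  expect_equal(as.numeric(isi_0_120(5, 6, 60, 300, 70)), 34.80,
               tolerance = 0.01 / 34.80)
  # glucose-disposal term collapses to 625 when fasting equals 2 h glucose
  m_term <- function(w) (75000 + (6 - 6) * 18 * 0.19 * w) / 120
  expect_equal(m_term(50), 625)
  expect_equal(m_term(120), 625)
  # monotone decreasing in 2 h insulin
  lo <- as.numeric(isi_0_120(5, 6, 60, 200, 70))
  hi <- as.numeric(isi_0_120(5, 6, 60, 400, 70))
  expect_gt(lo, hi)
  # low-insulin records are flagged, not fatal
  out <- isi_0_120(c(5, 5), c(6, 6), c(60, 3), c(300, 3), c(70, 70))
  expect_false(is.na(out[1]))
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "n_flagged"), 1)
  expect_error(isi_0_120(5, -6, 60, 300, 70), "positive")
})

test_that("quantile transform maps ranks to normal scores within strata", {
  z <- quantile_transform(c(10, 20, 30), rep("a", 3))
  expect_equal(z, c(qnorm(1 / 6), 0, qnorm(5 / 6)))
  # strictly increasing input -> strictly increasing output
  x <- sort(rnorm(50))
  expect_true(all(diff(quantile_transform(x, rep("s", 50))) > 0))
  # rank-only dependence: different raw scales, same z by stratum
  x1 <- c(1, 5, 9, 12)
  x2 <- c(0.1, 0.2, 0.5, 0.9) * 1000
  z12 <- quantile_transform(c(x1, x2), rep(c("a", "b"), each = 4))
  expect_equal(z12[1:4], z12[5:8])
  # brute-force rank check
  set.seed(51)
  v <- rnorm(30)
  zz <- quantile_transform(v, rep("s", 30))
  expect_equal(zz, qnorm((rank(v) - 0.5) / 30))
  # missing stays missing; strata processed independently
  v2 <- c(3, NA, 1, 2, 100, -100)
  st <- c("a", "a", "a", "a", "b", "b")
  z2 <- quantile_transform(v2, st)
  expect_true(is.na(z2[2]))
  expect_equal(z2[5], qnorm((2 - 0.5) / 2))
  expect_error(quantile_transform(c(1, NA), c("a", "a")), "stratum")
})

test_that("normal-scores property holds for moderate strata", {
  set.seed(52)
  v <- rexp(120)  # skewed input
  z <- quantile_transform(v, rep(c("m", "f"), 60))
  for (s in c("m", "f")) {
    zs <- z[rep(c("m", "f"), 60) == s]
    expect_lt(abs(mean(zs)), 0.05)
    expect_gt(var(zs), 0.8)
    expect_lt(var(zs), 1.2)
  }
})

test_that("derive_traits appends classes, indices and z-columns", {
  sim <- small_cohort(n = 240, m = 20, seed = 61)
  ph <- derive_traits(sim$pheno)
  expect_true(all(c("gt_class", "homa_ir", "isi_0_120", "z_homa_ir",
                    "z_isi_0_120", "z_fpg_mmol_l") %in% names(ph)))
  # transformed trait is standard-normal-ish within each stratum
  strat <- interaction(ph$sex, ph$cohort)
  for (s in levels(strat)) {
    zs <- ph$z_fpg_mmol_l[strat == s & !is.na(ph$z_fpg_mmol_l)]
    if (length(zs) >= 50) expect_lt(abs(mean(zs)), 0.05)
  }
  expect_error(derive_traits(sim$pheno, traits = "nope"), "not present")
})

test_that("Friedewald LDL is the documented arithmetic", {
  expect_equal(friedewald_ldl(5.2, 1.3, 2.2), 5.2 - 1.3 - 1.0)
})
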