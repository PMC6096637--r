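test_that("ancestry sampling lives on the simplex and is reproducible", {
  Q <- sample_ancestry(500, K = 2, mix_params = c(2, 2), seed = 7)
  expect_equal(dim(Q), c(500, 2))
  expect_true(all(Q >= 0 & Q <= 1))
  expect_lt(max(abs(rowSums(Q) - 1)), 1e-12)
  expect_identical(Q, sample_ancestry(500, K = 2, mix_params = c(2, 2),
                                      seed = 7))
  # degenerate concentration pins a component out entirely
  Qpin <- sample_ancestry(3, K = 2, mix_params = c(5, 0), seed = 1)
  expect_equal(unname(Qpin), matrix(c(1, 0), 3, 2, byrow = TRUE))
  # symmetric concentration gives balanced mean ancestry
  Qbig <- sample_ancestry(10000, K = 2, mix_params = c(2, 2), seed = 3)
  expect_lt(max(abs(colMeans(Qbig) - 0.5)), 0.02)
  expect_error(sample_ancestry(0, 2), "positive")
  expect_error(sample_ancestry(10, 1), "K")
})

test_that("ancestral frequencies follow the Balding-Nichols divergence law", {
  # near-zero divergence: both components hug the base frequency
  Fm <- sample_ancestral_frequencies(10000, divergence = 1e-6, seed = 2)
  expect_gt(cor(Fm[, 1], Fm[, 2]), 0.99)
  base <- sample_ancestral_frequencies(10000, divergence = 1e-6,
                                       base_freqs = 0.4, seed = 2)
  expect_lt(max(abs(base - 0.4)), 1e-2)
  # variance of the draw is divergence * p * (1 - p)
  draws <- sample_ancestral_frequencies(20000, divergence = 0.2,
                                        base_freqs = 0.5, seed = 4)
  expect_equal(var(draws[, 1]), 0.2 * 0.25, tolerance = 0.05)
  expect_identical(draws,
                   sample_ancestral_frequencies(20000, divergence = 0.2,
                                                base_freqs = 0.5, seed = 4))
  expect_error(sample_ancestral_frequencies(10, divergence = 1.2), "divergence")
})

test_that("genotypes follow the admixture binomial law", {
  # Q mass entirely on a component with frequency 0 -> dosage always 0
  Q <- matrix(c(1, 0), 50, 2, byrow = TRUE)
  Fm <- matrix(c(0 + 1e-9, 0.9), 1, 2)
  G <- sample_genotypes(Q, Fm, seed = 1)
  expect_true(all(G$dosages == 0))
  # 50/50 admixture of fixed/absent allele -> Binomial(2, 0.5)
  Qh <- matrix(0.5, 10000, 2)
  Fh <- matrix(c(1 - 1e-9, 1e-9), 1, 2)
  gh <- sample_genotypes(Qh, Fh, seed = 2)$dosages[, 1]
  props <- as.numeric(table(factor(gh, levels = 0:2))) / 10000
  expect_equal(props, c(0.25, 0.5, 0.25), tolerance = 0.05)
  expect_false(anyNA(sample_genotypes(Q, Fm, missing_rate = 0,
                                      seed = 3)$dosages))
  gm <- sample_genotypes(Qh, Fh, missing_rate = 0.1, seed = 4)
  expect_lt(abs(mean(is.na(gm$dosages)) - 0.1), 0.01)
  expect_error(sample_genotypes(Q, matrix(0.5, 1, 3)), "components")
})

test_that("realized frequency in unadmixed individuals converges to F", {
  Q <- matrix(c(1, 0), 5000, 2, byrow = TRUE)
  Fm <- matrix(c(0.31, 0.03), 1, 2)
  g <- sample_genotypes(Q, Fm, seed = 9)$dosages[, 1]
  se <- sqrt(0.31 * 0.69 / (2 * 5000))
  expect_lt(abs(mean(g) / 2 - 0.31), 3 * se)
})

test_that("disease model applies odds-multiplied risk to homozygotes", {
  spec <- disease_spec(eaf = 0.25, or_effect = 3, baseline_risk = 0.1,
                       n = 100)
  expect_equal(homozygote_risk(0.1, 3), 0.25)
  expect_equal(homozygote_risk(0.1, 1), 0.1)
  expect_gt(homozygote_risk(0.1, 1e9), 0.999)
  # OR = 1: everyone at baseline
  s0 <- simulate_disease_status(rbinom(100000, 2, 0.3),
                                disease_spec(0.3, 1, 0.1, 100000),
                                seed = 5)
  expect_lt(abs(mean(s0) - 0.1), 3 * sqrt(0.1 * 0.9 / 100000))
  # Monte-Carlo frequency among homozygotes matches the odds algebra
  g <- rep(2L, 100000)
  s2 <- simulate_disease_status(g, spec, seed = 6)
  expect_lt(abs(mean(s2) - 0.25), 3 * sqrt(0.25 * 0.75 / 100000))
  expect_error(simulate_disease_status(c(0L, NA), spec), "missing")
  expect_error(disease_spec(0, 3), "eaf")
  expect_error(disease_spec(0.2, -1), "or_effect")
})

test_that("non-homozygote prevalence stays at baseline across grid cells", {
  for (cell in list(c(0.1, 2), c(0.25, 5), c(0.3, 8))) {
    spec <- disease_spec(cell[1], cell[2], 0.1, 20000)
    g <- rbinom(20000, 2, cell[1])
    s <- simulate_disease_status(g, spec, seed = round(100 * cell[1] + cell[2]))
    nh <- g != 2
    se <- sqrt(0.1 * 0.9 / sum(nh))
    expect_lt(abs(mean(s[nh]) - 0.1), 3 * se)
  }
})

test_that("quantitative trait has the designed recessive shift", {
  Q <- matrix(c(1, 0), 10000, 2, byrow = TRUE)
  Fm <- matrix(c(0.5, 0.5), 1, 2)
  G <- sample_genotypes(Q, Fm, seed = 11)
  y0 <- simulate_quantitative_trait(G, 1, beta_rec = 0, seed = 12)
  expect_equal(var(y0), 1, tolerance = 0.06)
  y <- simulate_quantitative_trait(G, 1, beta_rec = 0.5, seed = 12)
  hom <- G$dosages[, 1] == 2
  expect_lt(abs(mean(y[hom]) - mean(y[!hom]) - 0.5), 0.05)
  expect_identical(y, simulate_quantitative_trait(G, 1, beta_rec = 0.5,
                                                  seed = 12))
  expect_error(simulate_quantitative_trait(G, 99, 0.5), "out of range")
})

test_that("genotypes are exchangeable across individuals with equal Q", {
  # identical Q rows: per-individual mean dosages should not distinguish
  # any individual beyond binomial noise (compare to permuted labels)
  Q <- matrix(0.5, 60, 2)
  Fm <- sample_ancestral_frequencies(400, divergence = 0.1, seed = 21)
  G <- sample_genotypes(Q, Fm, seed = 22)
  means <- rowMeans(G$dosages)
  set.seed(23)
  perm_spread <- replicate(200, {
    diff(range(colMeans(matrix(sample(as.vector(G$dosages)),
                               nrow = 400))))
  })
  expect_gt(mean(perm_spread >= diff(range(means))), 0.01)
})

test_that("simulate_cohort produces a coherent cohort", {
  sim <- small_cohort(n = 300, m = 100, seed = 31)
  expect_equal(nrow(sim$pheno), 300)
  expect_equal(dim(sim$G$dosages), c(300, 100))
  expect_false(anyNA(sim$G$dosages[, sim$causal_index]))
  expect_true(all(sim$pheno$status %in% 0:1))
  # reproducibility
  sim2 <- small_cohort(n = 300, m = 100, seed = 31)
  expect_identical(sim$G$dosages, sim2$G$dosages)
  expect_identical(sim$pheno, sim2$pheno)
})
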