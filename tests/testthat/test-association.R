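test_that("genotype coding follows the genetic model", {
  expect_equal(encode_genotype(c(0, 1, 2, NA), "additive"),
               c(0, 1, 2, NA))
  expect_equal(encode_genotype(c(0, 1, 2, NA), "recessive"),
               c(0, 0, 1, NA))
  expect_error(encode_genotype(3, "additive"), "dosages")
})

test_that("recessive coding depends only on homozygosity", {
  g <- c(0L, 1L, 2L, 1L, 2L, 0L)
  # relabel heterozygotes arbitrarily through the additive channel: the
  # recessive coding must be untouched by anything but dosage == 2
  expect_equal(encode_genotype(g, "recessive"),
               as.numeric(g == 2L))
})

test_that("GRM is a PSD Gram matrix with the expected structure", {
  set.seed(71)
  dos <- matrix(rbinom(200 * 500, 2, runif(500, 0.1, 0.9)[rep(1:500,
                                                              each = 200)]),
                200, 500)
  K <- compute_grm(dos)
  expect_lt(max(abs(K$matrix - t(K$matrix))), 1e-10)
  expect_gt(min(eigen(K$matrix, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  # unrelated individuals: off-diagonals near 0; centering makes their
  # mean exactly -mean(diag)/(n-1) (columns of X_c sum to zero)
  off <- K$matrix[upper.tri(K$matrix)]
  expect_equal(mean(off), -mean(diag(K$matrix)) / (200 - 1),
               tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.01)
  # identical genotype rows give identical similarity entries
  dos2 <- rbind(dos[1, ], dos[1, ], dos[2:10, ])
  K2 <- compute_grm(dos2)$matrix
  expect_equal(K2[1, 1], K2[1, 2])
  expect_equal(K2[1, 2], K2[2, 2])
  # standardized flavour: diagonal mean near 1
  Ks <- compute_grm(dos, method = "standardized")$matrix
  expect_gt(mean(diag(Ks)), 0.5)
  expect_lt(mean(diag(Ks)), 2)
  expect_error(compute_grm(matrix(2L, 5, 3)), "polymorphic")
})

test_that("PCA separates two unadmixed populations on PC1", {
  Q <- two_group_Q(100)
  Fm <- sample_ancestral_frequencies(500, divergence = 0.2, seed = 72)
  G <- sample_genotypes(Q, Fm, seed = 73)
  pcs <- compute_pcs(G, 2)
  m1 <- mean(pcs[1:100, 1]); m2 <- mean(pcs[101:200, 1])
  expect_true(sign(m1) != sign(m2))
  # scores orthogonal
  expect_lt(abs(crossprod(pcs[, 1], pcs[, 2])), 1e-6)
  expect_equal(ncol(compute_pcs(G, 0)), 0)
  expect_error(compute_pcs(G, 1000), "min")
})

test_that("logistic association reproduces the closed-form 2x2 OR", {
  status <- c(rep(1, 20), rep(0, 30), rep(1, 100), rep(0, 600))
  carrier <- c(rep(1, 50), rep(0, 700))
  res <- logistic_assoc(status, carrier, model = "recessive")
  expect_equal(res$odds_ratio, (20 * 600) / (30 * 100), tolerance = 1e-6)
  expect_equal(res$n_used, 750)
  expect_equal(res$n_homozygous, 50)
  # constant regressor flagged non-estimable
  res0 <- logistic_assoc(status, rep(1, 750))
  expect_false(res0$estimable)
  # orthogonal covariate leaves beta unchanged
  set.seed(74)
  x <- rbinom(400, 1, 0.3)
  y <- rbinom(400, 1, plogis(-1 + x))
  cov_orth <- rnorm(400)
  cov_orth <- cov_orth - mean(cov_orth)
  cov_orth <- residuals(lm(cov_orth ~ x))
  b0 <- logistic_assoc(y, x)$beta
  b1 <- logistic_assoc(y, x, covars = cbind(cov_orth))$beta
  expect_equal(b0, b1, tolerance = 1e-2)
  # perfect separation flagged
  ysep <- as.numeric(x == 1)
  expect_false(logistic_assoc(ysep, x)$estimable)
})

test_that("logistic fit matches a generic-optimizer reference", {
  set.seed(75)
  n <- 150
  x <- rbinom(n, 2, 0.4)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * (x == 2) + 0.3 * z))
  res <- logistic_assoc(y, as.numeric(x == 2), covars = cbind(z))
  ref <- ref_logistic(cbind(1, as.numeric(x == 2), z), y)
  expect_equal(res$beta, ref[2], tolerance = 1e-4)
})

test_that("genomic inflation has the exact null and scaling behaviour", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1.0)
  set.seed(76)
  p <- runif(100000)
  expect_equal(genomic_inflation(p), 1.0, tolerance = 0.02)
  # doubling the chi-square statistics doubles lambda
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2.0, tolerance = 0.05)
  expect_error(genomic_inflation(numeric(0)), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "p values")
})

test_that("Bonferroni threshold matches the study-wide value", {
  expect_equal(signif(bonferroni_threshold(115182, 0.05), 2), 4.3e-7)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(10), 0.005)
  # closure: threshold times test count returns the family level
  expect_equal(bonferroni_threshold(115182, 0.05) * 115182, 0.05)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("genotype-stratified disease frequencies recover the model", {
  expect_equal(genotype_stratified_frequency(rep(0, 10),
                                             rep(0:2, c(4, 3, 3)))$freq,
               c(0, 0, 0))
  set.seed(77)
  g <- rbinom(20000, 2, 0.4)
  s <- simulate_disease_status(g, disease_spec(0.4, 3, 0.1, 20000),
                               seed = 78)
  tab <- genotype_stratified_frequency(s, g)
  expect_equal(tab$freq, c(0.10, 0.10, 0.25), tolerance = 0.12)
  expect_equal(sum(tab$n), 20000)
  # empty class reported missing
  tab2 <- genotype_stratified_frequency(c(1, 0), c(0, 1))
  expect_true(is.na(tab2$freq[3]))
})
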