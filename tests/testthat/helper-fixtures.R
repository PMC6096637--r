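# Shared fixtures, all generated in code.

# two unadmixed groups of equal size
two_group_Q <- function(n_per_group = 200) {
  rbind(matrix(c(1, 0), n_per_group, 2, byrow = TRUE),
        matrix(c(0, 1), n_per_group, 2, byrow = TRUE))
}

# small admixed cohort for association-scale tests
small_cohort <- function(n = 200, m = 300, seed = 101, ...) {
  simulate_cohort(n = n, m = m, seed = seed, ...)
}

# write a minimal 3-sample VCF (one multi-allelic site, one missing call)
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "A", "G,T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "300", "rs3", "C", "T", ".", "PASS", ".", "GT",
            "./.", "1|1", "0/1"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# reference logistic fit by direct likelihood maximization (generic
# optimizer), independent of glm's IRLS path
ref_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-12))$par
}

# reference mixed-model fit: REML by generic optimizer over log-lambda,
# using dense solves of V = lambda K + I (no eigendecomposition)
ref_lmm <- function(y, X, K) {
  n <- length(y); p <- ncol(X)
  reml <- function(loglam) {
    V <- 10^loglam * K + diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rss <- as.numeric(t(r) %*% Vi %*% r)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
              determinant(V)$modulus +
              determinant(XtViX)$modulus -
              determinant(t(X) %*% X)$modulus)
  }
  opt <- optimize(function(l) -reml(l), c(-5, 5), tol = 1e-7)
  lam <- 10^opt$minimum
  V <- lam * K + diag(n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(lambda = lam, beta = as.vector(b))
}

# brute-force grid maximization of the fixed-Q binomial likelihood
grid_mle <- function(g, Q, step = 0.01) {
  fs <- seq(0, 1, by = step)
  fs <- pmin(pmax(fs, 1e-9), 1 - 1e-9)
  ok <- !is.na(g)
  g <- g[ok]; Q <- Q[ok, , drop = FALSE]
  best <- c(-Inf, NA, NA)
  for (f1 in fs) {
    p <- Q[, 1] * f1 + Q[, 2] %o% fs      # n x length(fs)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- colSums(g * log(p) + (2 - g) * log1p(-p))
    j <- which.max(ll)
    if (ll[j] > best[1]) best <- c(ll[j], f1, fs[j])
  }
  list(loglik = best[1], f = best[2:3])
}
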