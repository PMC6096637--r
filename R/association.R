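# Per-SNP association machinery: genotype coding, GRM and PCA
# construction, covariate-adjusted logistic regression for odds ratios,
# genomic-inflation diagnostics and the study-wide Bonferroni threshold.
# Discovery p values come from the linear mixed model (lmm.R), mirroring
# the design in which the mixed model supplies relatedness-aware p values
# and logistic regression supplies the odds ratios.

#' Encode genotype dosages under a genetic model
#'
#' Additive: the 0/1/2 dosage itself. Recessive: indicator of homozygosity
#' for the effect allele (1 if dosage == 2, else 0). Missing stays missing.
#'
#' @param dosage integer vector of 0/1/2/NA dosages.
#' @param model `"additive"` or `"recessive"`.
#' @return Numeric regressor vector.
#' @export
encode_genotype <- function(dosage, model = c("additive", "recessive")) {
  model <- match.arg(model)
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop_invalid("dosages must be 0, 1, 2 or NA")
  if (model == "additive") as.numeric(dosage)
  else ifelse(is.na(dosage), NA_real_, as.numeric(dosage == 2))
}

#' Compute a genetic relatedness matrix
#'
#' Centered construction (the default of the GWAS mixed-model software
#' this mirrors): missing dosages are imputed by the SNP mean, columns are
#' mean-centered, and K = X_c X_c' / m. The `"standardized"` flavour also
#' divides each column by its binomial SD.
#'
#' @param G a [genotype_matrix()] or a plain dosage matrix.
#' @param method `"centered"` (default) or `"standardized"`.
#' @return List of class `grm`: `matrix` (n x n), `n_snps_used`, `method`.
#' @export
compute_grm <- function(G, method = c("centered", "standardized")) {
  method <- match.arg(method)
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (nrow(X) < 2) stop_invalid("GRM needs at least 2 individuals")
  mu <- colMeans(X, na.rm = TRUE)
  keep <- which(!is.na(mu) & mu > 0 & mu < 2)   # drop monomorphic SNPs
  if (length(keep) == 0)
    stop_invalid("no informative (polymorphic) SNPs for the GRM")
  X <- X[, keep, drop = FALSE]; mu <- mu[keep]
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0          # mean imputation after centering
  if (method == "standardized") {
    p <- mu / 2
    X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  }
  K <- tcrossprod(X) / length(keep)
  structure(list(matrix = K, n_snps_used = length(keep), method = method),
            class = "grm")
}

#' Principal components of the genotype matrix
#'
#' Top-k left singular directions of the standardized (binomial-SD),
#' mean-imputed genotype matrix; the classical population-structure PCA.
#' Sign convention: within each component the loading of largest magnitude
#' is positive.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param k number of components (0 <= k < min(n, m)).
#' @return n x k matrix of PC scores.
#' @export
compute_pcs <- function(G, k = 10) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (k >= min(dim(X))) stop_invalid("k must be < min(n, m)")
  if (k == 0) return(matrix(numeric(0), nrow = nrow(X), ncol = 0))
  mu <- colMeans(X, na.rm = TRUE)
  keep <- which(!is.na(mu) & mu > 0 & mu < 2)
  X <- X[, keep, drop = FALSE]; mu <- mu[keep]
  X <- sweep(X, 2, mu)
  X[is.na(X)] <- 0
  p <- mu / 2
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

assoc_result <- function(snp_id = NA, model, beta = NA_real_,
                         se = NA_real_, p_value = NA_real_,
                         odds_ratio = NA_real_, beta_sd = NA_real_,
                         n_used = NA_integer_, n_homozygous = NA_integer_,
                         estimable = TRUE) {
  data.frame(snp_id = snp_id, model = model, beta = beta, se = se,
             p_value = p_value, odds_ratio = odds_ratio, beta_sd = beta_sd,
             n_used = n_used, n_homozygous = n_homozygous,
             estimable = estimable)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of case-control status on an
#' encoded genotype plus covariates (intercept always included), two-sided
#' Wald p, OR = exp(beta). Missing genotypes/covariates are dropped
#' case-wise. Constant regressors and separated fits are returned flagged
#' non-estimable rather than failing.
#'
#' @param status 0/1 vector.
#' @param x encoded genotype regressor (see [encode_genotype()]).
#' @param covars optional numeric covariate matrix/data frame.
#' @param snp_id label carried into the result.
#' @param model label carried into the result.
#' @return One-row `AssociationResult` data frame.
#' @export
logistic_assoc <- function(status, x, covars = NULL, snp_id = NA,
                           model = "recessive") {
  df <- data.frame(y = status, x = x)
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars))
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_used <- nrow(df)
  hom_level <- if (identical(model, "recessive")) 1 else 2
  n_hom <- sum(df$x == hom_level)
  base <- assoc_result(snp_id, model, n_used = n_used,
                       n_homozygous = n_hom, estimable = FALSE)
  if (n_used == 0 || length(unique(df$y)) < 2 ||
      length(unique(df$x)) < 2)
    return(base)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, -1, drop = FALSE]))
  fit <- suppressWarnings(glm.fit(X, df$y, family = binomial()))
  b <- fit$coefficients
  if (!fit$converged || anyNA(b) || abs(b[2]) > 15) return(base)
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(base)
  se <- sqrt(diag(cov))[2]
  z <- b[2] / se
  assoc_result(snp_id, model, beta = unname(b[2]), se = unname(se),
               p_value = 2 * pnorm(-abs(z)),
               odds_ratio = exp(unname(b[2])),
               n_used = n_used, n_homozygous = n_hom, estimable = TRUE)
}

#' Genomic inflation factor
#'
#' lambda = median of the chi-square(1) quantiles of the p values divided
#' by the null median 0.4549364.
#'
#' @param p_values vector of p values in (0, 1].
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0) stop_invalid("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_invalid("p values must lie in (0, 1]")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Study-wide Bonferroni threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param family_alpha family-wise level in (0, 1), default 0.05.
#' @return family_alpha / n_tests.
#' @export
bonferroni_threshold <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop_invalid("n_tests must be >= 1")
  if (family_alpha <= 0 || family_alpha >= 1)
    stop_invalid("family_alpha must lie in (0, 1)")
  family_alpha / n_tests
}

#' Disease frequency stratified by genotype
#'
#' Frequency of status == 1 within each dosage class (0, 1, 2), with
#' counts and binomial standard errors; empty classes are reported NA.
#'
#' @param status 0/1 vector.
#' @param dosages 0/1/2/NA dosage vector.
#' @return Data frame with rows for dosage 0, 1, 2: `dosage`, `n`,
#'   `n_cases`, `freq`, `se`.
#' @export
genotype_stratified_frequency <- function(status, dosages) {
  if (any(!is.na(dosages) & !(dosages %in% 0:2)))
    stop_invalid("dosages must be 0, 1, 2 or NA")
  out <- lapply(0:2, function(d) {
    idx <- which(!is.na(dosages) & dosages == d & !is.na(status))
    n <- length(idx)
    ncase <- sum(status[idx] == 1)
    f <- if (n > 0) ncase / n else NA_real_
    se <- if (n > 0) sqrt(f * (1 - f) / n) else NA_real_
    data.frame(dosage = d, n = n, n_cases = ncase, freq = f, se = se)
  })
  do.call(rbind, out)
}
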